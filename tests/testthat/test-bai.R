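test_that("reg2bin matches the exhaustive smallest-containing-bin search", {
  expect_identical(reg2bin(0, 16384), 4681L)
  expect_identical(reg2bin(0, 536870912), 0L)
  expect_identical(reg2bin(16384, 32768), 4682L)
  expect_identical(oracle_reg2bin(0, 16384), 4681)
  expect_identical(oracle_reg2bin(16384, 32768), 4682)
  set.seed(19)
  n <- 300
  beg <- floor(runif(n, 0, 2^29 - 1))
  len <- pmax(1, floor(rexp(n, 1 / 5000)))
  end <- pmin(beg + len, 2^29)
  got <- reg2bin(beg, end)
  for (i in seq_len(n)) {
    expect_identical(got[i], as.integer(oracle_reg2bin(beg[i], end[i])))
  }
  expect_error(reg2bin(10, 10), class = "bamkit_range_error")
  expect_error(reg2bin(-1, 10), class = "bamkit_range_error")
})

test_that("reg2bins lists every overlapping bin, ascending", {
  expect_identical(reg2bins(0, 1), c(0L, 1L, 9L, 73L, 585L, 4681L))
  # the six levels hold (8^6 - 1) / 7 = 37449 bins in all (ids 0..37448),
  # and every one of them overlaps the full 2^29 span
  expect_identical(length(reg2bins(0, 2^29)), 37449L)
  expect_identical(as.numeric(reg2bins(0, 2^29)), full_bin_table()$id)
  set.seed(23)
  for (i in 1:25) {
    beg <- sample(0:(2^29 - 2), 1)
    end <- min(beg + sample(1:100000, 1), 2^29)
    bins <- reg2bins(beg, end)
    expect_identical(as.numeric(bins), oracle_reg2bins(beg, end))
    expect_true(reg2bin(beg, end) %in% bins)
    expect_false(is.unsorted(bins))
  }
})

test_that("BAI write/read round-trips, and empty indexes have the skeleton size", {
  fx <- cached_fixture(104, n_reads = 400L)
  idx <- build_index(fx$bam)
  path <- tempfile(fileext = ".bai")
  write_bai(idx, path)
  expect_identical(read_bai(path), idx)
  # an index of 2 record-less references: magic+n_ref plus per-ref
  # n_bin=0, n_intv=0 -> 8 + 2*8 octets
  empty_bam <- tempfile(fileext = ".bam")
  write_bam(empty_bam, tiny_header())
  eidx <- build_index(empty_bam)
  epath <- tempfile(fileext = ".bai")
  write_bai(eidx, epath)
  expect_identical(file.size(epath), 8 + 2 * 8)
  expect_identical(read_bai(epath), eidx)
  # wrong magic
  bad <- tempfile(fileext = ".bai")
  writeBin(c(charToRaw("BAM"), as.raw(1), raw(4)), bad)
  expect_error(read_bai(bad), class = "bamkit_format_error")
})

test_that("index-backed region retrieval equals a brute-force linear scan", {
  set.seed(29)
  for (seed in c(105, 106)) {
    fx <- cached_fixture(seed, n_reads = 300L)
    idx <- build_index(fx$bam)
    rr <- bam_region_reader(fx$bam)
    all_recs <- core_fields(read_bam(fx$bam)$alignments)
    refs <- header_references(fx$header)
    for (k in 1:40) {
      ri <- sample(nrow(refs), 1)
      a <- sample(refs$length[ri], 1)
      b <- min(a + sample(1:500, 1), refs$length[ri])
      got <- rr$query(list(refs$name[ri], a, b), idx)
      want <- oracle_region_scan(all_recs, refs$name[ri], a, b)
      expect_identical(got, want)
    }
  }
})

test_that("single-record chunk queries resolve by overlap arithmetic", {
  hdr <- tiny_header()
  rec <- tiny_record(pos = 101L, cigar = "50M", seq = strrep("A", 50),
                     qual = strrep("I", 50))       # covers pos0 100..149
  bam <- tempfile(fileext = ".bam")
  write_bam(bam, hdr, rec)
  idx <- build_index(bam)
  hit <- query_chunks(idx, 0L, 120, 130)
  expect_identical(nrow(hit), 1L)
  expect_identical(nrow(read_bam_region(bam, list("chr1", 121, 130), idx)), 1L)
  expect_identical(nrow(read_bam_region(bam, list("chr1", 201, 300), idx)), 0L)
  expect_error(query_chunks(idx, 5L, 0, 10), class = "bamkit_lookup_error")
})

test_that("empty BAM indexes to all-empty references", {
  bam <- tempfile(fileext = ".bam")
  write_bam(bam, tiny_header())
  idx <- build_index(bam)
  expect_identical(idx$n_ref, 2L)
  for (r in idx$refs) {
    expect_length(r$bins, 0L)
    expect_length(r$linear, 0L)
  }
  expect_identical(nrow(query_chunks(idx, 0L, 0, 1000)), 0L)
})

test_that("index construction is invariant to worker count", {
  fx <- cached_fixture(104, n_reads = 400L)
  i1 <- build_index(fx$bam, workers = 1L)
  i2 <- build_index(fx$bam, workers = 2L)
  i4 <- build_index(fx$bam, workers = 4L)
  expect_identical(i1, i2)
  expect_identical(i1, i4)
})

test_that("unsorted input is rejected with the offending record named", {
  hdr <- tiny_header()
  recs <- rbind(tiny_record(qname = "a", pos = 500L),
                tiny_record(qname = "b", pos = 100L))
  bam <- tempfile(fileext = ".bam")
  write_bam(bam, hdr, recs)
  err <- tryCatch(build_index(bam), error = identity)
  expect_s3_class(err, "bamkit_sort_error")
  expect_match(conditionMessage(err), "record 2")
  # a reference id reappearing is also unsorted
  recs2 <- rbind(tiny_record(qname = "a", rname = "chr1", pos = 10L),
                 tiny_record(qname = "b", rname = "chr2", pos = 10L),
                 tiny_record(qname = "c", rname = "chr1", pos = 20L))
  write_bam(bam, hdr, recs2)
  expect_error(build_index(bam), class = "bamkit_sort_error")
})

test_that("linear index entries are non-decreasing and chunk lists are merged", {
  fx <- cached_fixture(104, n_reads = 400L)
  idx <- build_index(fx$bam)
  for (r in idx$refs) {
    if (length(r$linear)) expect_false(is.unsorted(r$linear))
    for (m in r$bins) {
      expect_true(all(m[, 2L] > m[, 1L]))
      if (nrow(m) > 1L) {
        expect_true(all(m[-1L, 1L] > m[-nrow(m), 2L]))
      }
    }
  }
})
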