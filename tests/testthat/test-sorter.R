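test_that("coordinate sort orders by reference then position", {
  hdr <- tiny_header()
  recs <- rbind(tiny_record(qname = "a", rname = "chr1", pos = 300L),
                tiny_record(qname = "b", rname = "chr1", pos = 100L),
                tiny_record(qname = "c", rname = "chr2", pos = 50L))
  input <- tempfile(fileext = ".sam")
  write_sam(input, hdr, recs)
  out <- tempfile(fileext = ".sam")
  sort_by_coordinate(input, out)
  x <- read_sam(out)
  expect_identical(x$alignments$qname, c("b", "a", "c"))
  # sort-order marker set
  hd <- Filter(function(r) r$type == "HD", x$header$records)[[1]]
  expect_identical(hd$fields[["SO"]], "coordinate")
})

test_that("fully unplaced records go last in input order; placed mates sort at the mate", {
  hdr <- tiny_header()
  un <- function(q) tiny_record(qname = q, flag = 4L, rname = "*", pos = 0L,
                                cigar = "*", seq = "ACGT", qual = "IIII")
  mate <- tiny_record(qname = "m", flag = 12L, rname = "*", pos = 0L,
                      cigar = "*", seq = "ACGT", qual = "IIII",
                      rnext = "chr1", pnext = 150L)
  recs <- rbind(un("u1"), tiny_record(qname = "p2", pos = 200L), mate,
                un("u2"), tiny_record(qname = "p1", pos = 100L))
  input <- tempfile(fileext = ".sam")
  write_sam(input, hdr, recs)
  out <- tempfile(fileext = ".sam")
  sort_by_coordinate(input, out)
  expect_identical(read_sam(out)$alignments$qname,
                   c("p1", "m", "p2", "u1", "u2"))
})

test_that("queryname sort uses plain byte order and is stable", {
  hdr <- tiny_header()
  recs <- rbind(tiny_record(qname = "r10"), tiny_record(qname = "r2"),
                tiny_record(qname = "r1"))
  input <- tempfile(fileext = ".sam")
  write_sam(input, hdr, recs)
  out <- tempfile(fileext = ".sam")
  sort_by_queryname(input, out)
  x <- read_sam(out)
  expect_identical(x$alignments$qname, c("r1", "r10", "r2"))
  hd <- Filter(function(r) r$type == "HD", x$header$records)[[1]]
  expect_identical(hd$fields[["SO"]], "queryname")
  # single record is untouched
  write_sam(input, hdr, tiny_record(qname = "only"))
  sort_by_queryname(input, out)
  expect_identical(read_sam(out)$alignments$qname, "only")
})

test_that("external merge equals the in-memory sort for any chunk size", {
  fx <- cached_fixture(107, n_reads = 800L, sorted = FALSE)
  x <- read_sam(fx$sam)
  refs <- header_references(x$header)
  # independent in-memory oracle: order by (refid, pos), unplaced last,
  # ties in input order
  kr <- ifelse(x$alignments$rname == "*", Inf,
               match(x$alignments$rname, refs$name))
  kp <- ifelse(x$alignments$rname == "*", Inf, x$alignments$pos)
  want <- x$alignments[order(kr, kp), , drop = FALSE]
  rownames(want) <- NULL
  outs <- lapply(c(43L, 100000L), function(chunk) {
    out <- tempfile(fileext = ".sam")
    sort_by_coordinate(fx$sam, out, chunk_records = chunk)
    a <- read_sam(out)$alignments
    unlink(out)
    a
  })
  expect_identical(outs[[1]], want)
  expect_identical(outs[[2]], want)
  # conservation: same record multiset as input
  expect_identical(record_multiset(outs[[1]]), record_multiset(x$alignments))
})

test_that("sorting an already-sorted file is a no-op on record order", {
  fx <- cached_fixture(108, n_reads = 300L)
  out <- tempfile(fileext = ".sam")
  sort_by_coordinate(fx$sam, out, chunk_records = 57L)
  a1 <- read_sam(out)$alignments
  expect_identical(a1, read_sam(fx$sam)$alignments)
})

test_that("sorted BAM output is accepted by the indexer", {
  fx <- cached_fixture(107, n_reads = 800L, sorted = FALSE)
  out <- tempfile(fileext = ".bam")
  sort_by_coordinate(fx$sam, out, chunk_records = 111L)
  idx <- build_index(out)
  expect_s3_class(idx, "bai_index")
})

test_that("merging sorted runs picks minima with run-ordinal tie-breaks", {
  hdr <- tiny_header()
  run1 <- tempfile(fileext = ".sam")
  run2 <- tempfile(fileext = ".sam")
  write_sam(run1, hdr, rbind(tiny_record(qname = "a", pos = 10L),
                             tiny_record(qname = "c", pos = 30L)))
  write_sam(run2, hdr, rbind(tiny_record(qname = "b", pos = 20L),
                             tiny_record(qname = "d", pos = 40L)))
  out <- tempfile(fileext = ".sam")
  merge_sorted_runs(c(run1, run2), out, by = "coordinate")
  expect_identical(read_sam(out)$alignments$qname, c("a", "b", "c", "d"))
  # merge of one run is the identity
  merge_sorted_runs(run1, out, by = "coordinate")
  expect_identical(read_sam(out)$alignments$qname, c("a", "c"))
  # ties: equal keys emit run 1 first
  write_sam(run2, hdr, rbind(tiny_record(qname = "a2", pos = 10L)))
  merge_sorted_runs(c(run1, run2), out, by = "coordinate")
  expect_identical(read_sam(out)$alignments$qname, c("a", "a2", "c"))
  # an unsorted run is detected
  write_sam(run2, hdr, rbind(tiny_record(qname = "x", pos = 50L),
                             tiny_record(qname = "y", pos = 10L)))
  expect_error(merge_sorted_runs(c(run1, run2), out, by = "coordinate"),
               class = "bamkit_consistency_error")
})

test_that("merging many random runs equals sorting the concatenation", {
  set.seed(37)
  hdr <- tiny_header()
  runs <- character(12)
  all_recs <- list()
  for (i in seq_along(runs)) {
    n <- sample(3:20, 1)
    recs <- tiny_record(qname = sprintf("q%02d_%02d", i, seq_len(n)),
                        rname = sample(c("chr1", "chr2"), n, TRUE),
                        pos = sample(1:4000, n, TRUE))
    refs <- header_references(hdr)
    kr <- match(recs$rname, refs$name)
    recs <- recs[order(kr, recs$pos), , drop = FALSE]
    runs[i] <- tempfile(fileext = ".sam")
    write_sam(runs[i], hdr, recs)
    all_recs[[i]] <- recs
  }
  out <- tempfile(fileext = ".sam")
  merge_sorted_runs(runs, out, by = "coordinate")
  merged <- read_sam(out)$alignments
  pool <- do.call(rbind, all_recs)
  refs <- header_references(hdr)
  want <- pool[order(match(pool$rname, refs$name), pool$pos), , drop = FALSE]
  rownames(want) <- NULL
  expect_identical(merged$pos, want$pos)
  expect_identical(record_multiset(merged), record_multiset(pool))
  unlink(runs)
})
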