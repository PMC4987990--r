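test_that("two overlapping reads give the textbook depth profile", {
  hdr <- tiny_header()
  recs <- rbind(
    tiny_record(qname = "r1", pos = 100L),   # 10M: covers 100-109
    tiny_record(qname = "r2", pos = 105L))   # 10M: covers 105-114
  bam <- tempfile(fileext = ".bam")
  write_bam(bam, hdr, recs)
  d <- simple_pileup(bam, list("chr1", 100, 114))
  expect_identical(d$pos, 100:114)
  expect_identical(d$depth, c(rep(1L, 5), rep(2L, 5), rep(1L, 5)))
})

test_that("empty BAMs and unmapped reads contribute nothing", {
  bam <- tempfile(fileext = ".bam")
  write_bam(bam, tiny_header())
  d <- simple_pileup(bam, list("chr1", 1, 10))
  expect_identical(d$depth, rep(0L, 10))
  write_bam(bam, tiny_header(),
            tiny_record(flag = 4L, rname = "chr1", pos = 100L))
  d <- simple_pileup(bam, list("chr1", 95, 115))
  expect_identical(sum(d$depth), 0L)
  expect_error(simple_pileup(bam, list("chrZ", 1, 10)),
               class = "bamkit_lookup_error")
  expect_error(simple_pileup(bam, list("chr1", 10, 5)),
               class = "bamkit_range_error")
})

test_that("depths match the brute-force CIGAR-expansion counter", {
  for (seed in c(109, 110)) {
    fx <- cached_fixture(seed, n_reads = 250L)
    idx <- build_index(fx$bam)
    recs <- core_fields(read_bam(fx$bam)$alignments)
    refs <- header_references(fx$header)
    for (ri in seq_len(nrow(refs))) {
      d <- simple_pileup(fx$bam, list(refs$name[ri], 1, refs$length[ri]), idx)
      want <- oracle_pileup_depth(recs, refs$name[ri], 1, refs$length[ri])
      expect_identical(d$depth, want)
    }
  }
})

test_that("depth mass equals covered reference length for interior reads", {
  fx <- cached_fixture(109, n_reads = 250L)
  recs <- core_fields(read_bam(fx$bam)$alignments)
  refs <- header_references(fx$header)
  # restrict to records wholly inside the region and passing the filter
  reg_end <- refs$length[1]
  span <- pmax(vapply(recs$cigar, oracle_ref_span, 0, USE.NAMES = FALSE), 1)
  inside <- recs$rname == "chr1" & recs$pos >= 1 &
    recs$pos + span - 1 <= reg_end & bitwAnd(recs$flag, 0x704L) == 0L
  d <- simple_pileup(fx$bam, list("chr1", 1, reg_end))
  expect_identical(sum(d$depth), as.integer(sum(span[inside])))
})

test_that("mpileup tokens for a clean forward read are dots with ^/$ marks", {
  fx_dir <- tempfile()
  dir.create(fx_dir)
  fasta <- file.path(fx_dir, "ref.fa")
  writeLines(c(">chr1", "ACGTACGTACGTACGTACGT"), fasta)
  hdr <- sam_header(list(list(type = "SQ", fields = c(SN = "chr1", LN = "20"))))
  rec <- tiny_record(pos = 3L, cigar = "5M", seq = "GTACG", qual = "IJKLM",
                     mapq = 40L)
  bam <- file.path(fx_dir, "one.bam")
  write_bam(bam, hdr, rec)
  cols <- mpileup(bam, fasta, list("chr1", 1, 20))
  expect_identical(cols$pos, 3:7)
  expect_identical(cols$ref, c("G", "T", "A", "C", "G"))
  expect_identical(cols$depth, rep(1L, 5))
  expect_identical(cols$bases, c("^I.", ".", ".", ".", ".$"))
  expect_identical(cols$quals, c("I", "J", "K", "L", "M"))
})

test_that("deletions show '*' columns annotated on the preceding base", {
  fx_dir <- tempfile()
  dir.create(fx_dir)
  fasta <- file.path(fx_dir, "ref.fa")
  writeLines(c(">chr1", "AACCGGTTAACC"), fasta)
  hdr <- sam_header(list(list(type = "SQ", fields = c(SN = "chr1", LN = "12"))))
  # 2M1D2M at pos 3: covers ref 3,4 (CC), deletes 5 (G), covers 6,7 (GT)
  rec <- tiny_record(pos = 3L, cigar = "2M1D2M", seq = "CCGT", qual = "FFFF",
                     mapq = 30L)
  bam <- file.path(fx_dir, "del.bam")
  write_bam(bam, hdr, rec)
  cols <- mpileup(bam, fasta, list("chr1", 1, 12))
  expect_identical(cols$pos, 3:7)
  expect_identical(cols$bases, c("^?.", ".-1G", "*", ".", ".$"))
  expect_identical(cols$depth, rep(1L, 5))
  # deleted position carries no quality character
  expect_identical(cols$quals, c("F", "F", "", "F", "F"))
  # reverse-strand read: commas, and lowercase deletion annotation stays
  rec$flag <- 16L
  write_bam(bam, hdr, rec)
  cols <- mpileup(bam, fasta, list("chr1", 1, 12))
  expect_identical(cols$bases, c("^?,", ",-1g", "*", ",", ",$"))
})

test_that("insertions annotate the preceding base; mismatches use letters", {
  fx_dir <- tempfile()
  dir.create(fx_dir)
  fasta <- file.path(fx_dir, "ref.fa")
  writeLines(c(">chr1", "AAAAAAAAAA"), fasta)
  hdr <- sam_header(list(list(type = "SQ", fields = c(SN = "chr1", LN = "10"))))
  rec <- tiny_record(pos = 2L, cigar = "2M2I2M", seq = "AGTCAA",
                     qual = "123456", mapq = 20L)
  bam <- file.path(fx_dir, "ins.bam")
  write_bam(bam, hdr, rec)
  cols <- mpileup(bam, fasta, list("chr1", 1, 10))
  expect_identical(cols$pos, 2:5)
  expect_identical(cols$bases, c("^5.", "G+2TC", ".", ".$"))
  expect_identical(cols$quals, c("1", "2", "5", "6"))
})

test_that("without a FASTA the reference shows N and bases show letters", {
  hdr <- tiny_header()
  rec <- tiny_record(pos = 10L, cigar = "3M", seq = "ACG", qual = "III")
  bam <- tempfile(fileext = ".bam")
  write_bam(bam, hdr, rec)
  cols <- mpileup(bam, NULL, list("chr1", 10, 12))
  expect_identical(cols$ref, rep("N", 3))
  expect_identical(cols$bases, c("^]A", "C", "G$"))
})

test_that("zero-coverage positions are omitted unless all_positions", {
  hdr <- tiny_header()
  rec <- tiny_record(pos = 10L, cigar = "3M", seq = "ACG", qual = "III")
  bam <- tempfile(fileext = ".bam")
  write_bam(bam, hdr, rec)
  cols <- mpileup(bam, NULL, list("chr1", 1, 20))
  expect_identical(cols$pos, 10:12)
  all_cols <- mpileup(bam, NULL, list("chr1", 1, 20), all_positions = TRUE)
  expect_identical(nrow(all_cols), 20L)
  expect_identical(all_cols$bases[1], "*")
  expect_identical(all_cols$depth[all_cols$pos == 11], 1L)
})

test_that("mpileup is the same with and without the index", {
  fx <- cached_fixture(110, n_reads = 250L)
  idx <- build_index(fx$bam)
  with_idx <- mpileup(fx$bam, fx$fasta, list("chr1", 1, 1500), idx)
  without <- mpileup(fx$bam, fx$fasta, list("chr1", 1, 1500), NULL)
  expect_identical(with_idx, without)
})

test_that("region-parallel pileup is byte-identical for any worker count", {
  fx <- cached_fixture(110, n_reads = 250L)
  idx <- build_index(fx$bam)
  regions <- list(list("chr1", 1, 1200), list("chr1", 1201, 3000),
                  list("chr2", 1, 2000))
  seq1 <- parallel_pileup(fx$bam, regions, workers = 1L,
                          fasta_path = fx$fasta, index = idx)
  par2 <- parallel_pileup(fx$bam, regions, workers = 2L,
                          fasta_path = fx$fasta, index = idx)
  par4 <- parallel_pileup(fx$bam, regions, workers = 4L,
                          fasta_path = fx$fasta, index = idx)
  expect_identical(mpileup_text(seq1), mpileup_text(par2))
  expect_identical(mpileup_text(seq1), mpileup_text(par4))
  # one region equals a direct mpileup call
  one <- parallel_pileup(fx$bam, regions[1], workers = 2L,
                         fasta_path = fx$fasta, index = idx)
  direct <- mpileup(fx$bam, fx$fasta, regions[[1]], idx)
  expect_identical(one, direct)
  # empty region list and overlap contract
  expect_identical(nrow(parallel_pileup(fx$bam, list(), workers = 2L)), 0L)
  expect_error(parallel_pileup(fx$bam, list(list("chr1", 1, 100),
                                            list("chr1", 50, 200))),
               class = "bamkit_contract_error")
})
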