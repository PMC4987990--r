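test_that("flag decoding names exactly the set bits", {
  expect_setequal(decode_flag(99),
                  c("paired", "proper_pair", "mate_reverse", "first_of_pair"))
  expect_identical(decode_flag(4), "unmapped")
  expect_identical(decode_flag(0), character(0))
  expect_error(decode_flag(65536), class = "bamkit_range_error")
  expect_error(decode_flag(-1), class = "bamkit_range_error")
  # injective: distinct flags give distinct predicate sets
  flags <- 0:255
  sets <- vapply(flags, function(f) paste(decode_flag(f), collapse = "|"), "")
  expect_identical(anyDuplicated(sets), 0L)
})

test_that("CIGAR parsing and serialization are mutually inverse", {
  ops <- parse_cigar("8M2I4M1D3M")
  expect_identical(ops$length, c(8L, 2L, 4L, 1L, 3L))
  expect_identical(ops$op, c("M", "I", "M", "D", "M"))
  expect_identical(nrow(parse_cigar("*")), 0L)
  expect_identical(cigar_string(parse_cigar("*")), "*")
  expect_identical(parse_cigar("5H")$op, "H")
  expect_error(parse_cigar("M5"), class = "bamkit_parse_error")
  expect_error(parse_cigar("5Q"), class = "bamkit_parse_error")
  set.seed(7)
  for (i in 1:50) {
    n <- sample(1:8, 1)
    txt <- paste0(sample(1:200, n, TRUE),
                  sample(c("M", "I", "D", "N", "S", "H", "P", "=", "X"),
                         n, TRUE), collapse = "")
    expect_identical(cigar_string(parse_cigar(txt)), txt)
  }
})

test_that("CIGAR query/reference lengths follow the consume table", {
  expect_identical(cigar_lengths(parse_cigar("8M2I4M1D3M")),
                   c(query = 17, ref = 16))
  expect_identical(cigar_lengths(parse_cigar("*")), c(query = 0, ref = 0))
  expect_identical(cigar_lengths(parse_cigar("5S10M")), c(query = 15, ref = 10))
  expect_identical(cigar_lengths(parse_cigar("5H"))[["query"]], 0)
})

test_that("alignment_end is pos plus reference span minus one", {
  expect_identical(alignment_end(100, "10M"), 109)
  expect_identical(alignment_end(100, "5S10M"), 109)
  expect_identical(alignment_end(1, "1M"), 1)
  expect_identical(alignment_end(100, "4M2D4M"), 109)
  expect_error(alignment_end(100, "*"), class = "bamkit_range_error")
})

test_that("reference-name normalization canonicalizes, is idempotent, detects collisions", {
  hdr <- sam_header(list(
    list(type = "SQ", fields = c(SN = "1", LN = "1000")),
    list(type = "SQ", fields = c(SN = "MT", LN = "500")),
    list(type = "SQ", fields = c(SN = "scaffold_7", LN = "200"))))
  aln <- rbind(tiny_record(rname = "1", pos = 5L),
               tiny_record(rname = "MT", pos = 5L, rnext = "1", pnext = 2L),
               tiny_record(qname = "u", flag = 4L, rname = "*", pos = 0L,
                           cigar = "*", seq = "*", qual = "*"))
  out <- normalize_reference_names(hdr, aln)
  refs <- header_references(out$header)
  expect_identical(refs$name, c("chr1", "chrM", "scaffold_7"))
  expect_identical(out$alignments$rname, c("chr1", "chrM", "*"))
  expect_identical(out$alignments$rnext, c("*", "chr1", "*"))
  # idempotent
  again <- normalize_reference_names(out$header, out$alignments)
  expect_identical(again, out)
  # canonical names pass through
  hdr2 <- sam_header(list(list(type = "SQ", fields = c(SN = "chr1", LN = "10"))))
  expect_identical(
    header_references(normalize_reference_names(hdr2)$header)$name, "chr1")
  # collision
  hdr3 <- sam_header(list(
    list(type = "SQ", fields = c(SN = "1", LN = "10")),
    list(type = "SQ", fields = c(SN = "chr1", LN = "10"))))
  expect_error(normalize_reference_names(hdr3),
               class = "bamkit_collision_error")
})

test_that("validation reports violations as data", {
  hdr <- tiny_header()
  bad_len <- tiny_record(seq = "ACGT", qual = "III", cigar = "4M")
  v <- validate_alignments(bad_len, hdr)[[1]]
  expect_match(v, "seq length", all = FALSE)
  unplaced <- tiny_record(flag = 0L, rname = "*", pos = 0L, cigar = "*",
                          seq = "*", qual = "*")
  v <- validate_alignments(unplaced, hdr)[[1]]
  expect_match(v, "mapped record", all = FALSE)
  unknown <- tiny_record(rname = "chrZ")
  v <- validate_alignments(unknown, hdr)[[1]]
  expect_match(v, "not declared", all = FALSE)
  beyond <- tiny_record(pos = 99999L)
  v <- validate_alignments(beyond, hdr)[[1]]
  expect_match(v, "beyond reference length", all = FALSE)
  clean <- tiny_record()
  expect_length(validate_alignments(clean, hdr)[[1]], 0L)
})

test_that("headers require consistent @SQ records", {
  expect_error(sam_header(list(list(type = "SQ", fields = c(SN = "a")))),
               class = "bamkit_format_error")
  expect_error(sam_header(list(
    list(type = "SQ", fields = c(SN = "a", LN = "5")),
    list(type = "SQ", fields = c(SN = "a", LN = "9")))),
    class = "bamkit_format_error")
  expect_error(sam_header(list(list(type = "SQ", fields = c(SN = "a", LN = "0")))),
               class = "bamkit_format_error")
})
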