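test_that("4-bit sequence packing follows the published nibble table", {
  expect_identical(encode_seq("ACGT"), as.raw(c(0x12, 0x48)))
  expect_identical(encode_seq("A"), as.raw(0x10))
  expect_identical(decode_seq(as.raw(c(0x12, 0x48)), 4L), "ACGT")
  expect_error(encode_seq("ACQT"), class = "bamkit_parse_error")
  set.seed(13)
  alphabet <- strsplit("=ACMGRSVTWYHKDBN", "")[[1]]
  for (i in 1:30) {
    s <- paste(sample(alphabet, sample(1:40, 1), TRUE), collapse = "")
    expect_identical(decode_seq(encode_seq(s), nchar(s)), toupper(s))
    expect_identical(decode_seq(encode_seq(tolower(s)), nchar(s)), toupper(s))
  }
})

test_that("binary CIGAR words are length*16 + opcode", {
  expect_identical(bamkit:::encode_cigar_words(parse_cigar("8M")), 128)
  expect_identical(bamkit:::encode_cigar_words(parse_cigar("2I")), 33)
  set.seed(17)
  for (i in 1:30) {
    n <- sample(1:6, 1)
    ops <- data.frame(length = sample(1:5000, n, TRUE),
                      op = sample(c("M", "I", "D", "N", "S", "H", "P", "=", "X"),
                                  n, TRUE), stringsAsFactors = FALSE)
    expect_identical(bamkit:::decode_cigar_words(bamkit:::encode_cigar_words(ops)),
                     ops)
  }
  too_long <- data.frame(length = 2^28, op = "M", stringsAsFactors = FALSE)
  expect_error(bamkit:::encode_cigar_words(too_long), class = "bamkit_size_error")
})

test_that("SAM -> BAM -> SAM is the identity on all fields and tags", {
  fx <- cached_fixture(102, n_reads = 200L)
  x <- read_sam(fx$sam)
  bam <- tempfile(fileext = ".bam")
  write_bam(bam, x$header, x$alignments)
  y <- read_bam(bam)
  expect_identical(core_fields(y$alignments), x$alignments)
  expect_identical(header_lines(y$header), header_lines(x$header))
})

test_that("typed tags survive the binary round trip", {
  hdr <- tiny_header()
  rec <- tiny_record(
    tags = paste("XA:A:c", "XI:i:-300", "XJ:i:70000", "XF:f:1.5",
                 "XZ:Z:hello world", "XH:H:1AFF",
                 "XB:B:c,-1,2,-3", "XS:B:S,1,65535", "XD:B:f,0.5,1.5",
                 sep = "\t"))
  bam <- tempfile(fileext = ".bam")
  write_bam(bam, hdr, rec)
  back <- read_bam(bam)$alignments
  expect_identical(back$tags,
                   paste("XA:A:c", "XI:i:-300", "XJ:i:70000", "XF:f:1.5",
                         "XZ:Z:hello world", "XH:H:1AFF",
                         "XB:B:c,-1,2,-3", "XS:B:S,1,65535", "XD:B:f,0.5,1.5",
                         sep = "\t"))
})

test_that("BAM failure modes raise typed errors", {
  bam <- tempfile(fileext = ".bam")
  write_bam(bam, tiny_header(), tiny_record())
  # corrupt the magic inside the first block
  stream <- readBin(bam, "raw", n = file.size(bam))
  payload <- bamkit:::bgzf_inflate_all(stream)$data
  payload[1:4] <- charToRaw("BAI\1")
  bad <- tempfile(fileext = ".bam")
  writeBin(bgzf_compress(payload), bad)
  expect_error(read_bam(bad), class = "bamkit_format_error")
  # record referencing an undeclared name refuses before writing
  out <- tempfile(fileext = ".bam")
  expect_error(write_bam(out, tiny_header(), tiny_record(rname = "chr9")),
               class = "bamkit_error")
  expect_false(file.exists(out))
})

test_that("header-only BAM files read back as such", {
  bam <- tempfile(fileext = ".bam")
  write_bam(bam, tiny_header())
  x <- read_bam(bam)
  expect_identical(nrow(x$alignments), 0L)
  expect_identical(header_references(x$header)$name, c("chr1", "chr2"))
})

test_that("record virtual offsets increase in file order and bins match reg2bin", {
  fx <- cached_fixture(103, n_reads = 300L)
  x <- read_bam(fx$bam)
  expect_true(all(diff(x$alignments$voffset) > 0))
  expect_true(all(x$alignments$voffset_end > x$alignments$voffset))
  # stored bin equals reg2bin over the record's reference span
  stream <- readBin(fx$bam, "raw", n = file.size(fx$bam))
  data <- bamkit:::bgzf_inflate_all(stream)$data
  a <- x$alignments
  placed <- a$rname != "*"
  tbl <- bamkit:::bgzf_block_table(stream)
  for (i in which(placed)[1:50]) {
    u <- bamkit:::voffset_to_uoffset(a$voffset[i], tbl)
    stored_bin <- bamkit:::read_u16(data, u + 1 + 14)
    pos0 <- a$pos[i] - 1
    span <- max(bamkit:::cigar_ref_span(a$cigar[i]), 1)
    expect_identical(stored_bin, reg2bin(pos0, pos0 + span))
  }
})

test_that("unplaced records with a placed mate are stored at the mate's coordinates", {
  hdr <- tiny_header()
  rec <- tiny_record(qname = "m", flag = 4L + 8L, rname = "*", pos = 0L,
                     cigar = "*", seq = "ACGT", qual = "IIII",
                     rnext = "chr2", pnext = 777L)
  bam <- tempfile(fileext = ".bam")
  write_bam(bam, hdr, rec)
  back <- read_bam(bam)$alignments
  expect_identical(back$rname, "chr2")
  expect_identical(back$pos, 777L)
})
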