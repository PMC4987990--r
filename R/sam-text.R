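# SAM text format reader/writer. Reading is line-oriented and chunked so
# memory stays bounded by the chunk size, not the file; writing streams.
# CR/LF is tolerated on input, LF emitted on output. Optional tags are kept
# in input order for byte-stable round trips.

parse_header_line <- function(line) {
  type <- substr(line, 2L, 3L)
  if (!(type %in% c("HD", "SQ", "RG", "PG", "CO"))) {
    bamkit_stop(sprintf("unknown header record type '@%s'", type),
                "bamkit_parse_error")
  }
  if (type == "CO") {
    return(list(type = "CO", text = substr(line, 5L, nchar(line))))
  }
  parts <- strsplit(substr(line, 5L, nchar(line)), "\t", fixed = TRUE)[[1]]
  tags <- substr(parts, 1L, 2L)
  vals <- substr(parts, 4L, nchar(parts))
  list(type = type, fields = stats::setNames(vals, tags))
}

check_tags <- function(tags, line_no) {
  if (tags == "") return(invisible())
  for (t in strsplit(tags, "\t", fixed = TRUE)[[1]]) {
    if (!grepl("^[A-Za-z][A-Za-z0-9]:[AifZHB]:", t)) {
      bamkit_stop(sprintf("malformed or unknown-typed tag '%s' at line %d",
                          t, line_no), "bamkit_parse_error")
    }
  }
}

parse_sam_lines <- function(lines, first_line_no) {
  n <- length(lines)
  if (n == 0L) return(empty_alignments())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 11L)) {
    bad <- which(nf < 11L)[1]
    bamkit_stop(sprintf("SAM record with %d fields (11 required) at line %d",
                        nf[bad], first_line_no + bad - 1L),
                "bamkit_parse_error")
  }
  get <- function(k) vapply(parts, `[[`, "", k)
  tags <- vapply(seq_len(n), function(i) {
    if (nf[i] > 11L) paste(parts[[i]][12:nf[i]], collapse = "\t") else ""
  }, "")
  for (i in seq_len(n)) check_tags(tags[i], first_line_no + i - 1L)
  data.frame(
    qname = get(1L),
    flag = int_or_stop(get(2L), "flag", first_line_no),
    rname = get(3L),
    pos = int_or_stop(get(4L), "pos", first_line_no),
    mapq = int_or_stop(get(5L), "mapq", first_line_no),
    cigar = get(6L),
    rnext = get(7L),
    pnext = int_or_stop(get(8L), "pnext", first_line_no),
    tlen = int_or_stop(get(9L), "tlen", first_line_no),
    seq = get(10L),
    qual = get(11L),
    tags = tags,
    stringsAsFactors = FALSE)
}

#' Open a SAM file for chunked reading
#'
#' Parses the contiguous '@' header prefix immediately; alignment lines are
#' parsed on demand in chunks via the returned reader's `read(n)` function,
#' so memory use is independent of file length.
#'
#' @param path path to a SAM text file.
#' @return a reader: list with `header` (a [sam_header()]), `read(n)`
#'   returning a data.frame of at most n records (zero rows at end of file),
#'   and `close()`.
#' @export
sam_open <- function(path) {
  con <- file(path, "r")
  hdr_lines <- character(0)
  pushback <- NULL
  line_no <- 0L   # lines fully consumed so far (header included)
  repeat {
    ln <- readLines(con, n = 1L, warn = FALSE)
    if (length(ln) == 0L) break
    ln <- sub("\r$", "", ln)
    if (startsWith(ln, "@")) {
      line_no <- line_no + 1L
      hdr_lines <- c(hdr_lines, ln)
    } else {
      pushback <- ln   # first alignment line, not yet counted
      break
    }
  }
  header <- sam_header(lapply(hdr_lines, parse_header_line))
  env <- new.env(parent = emptyenv())
  env$header <- header
  env$read <- function(n = 1e5L) {
    lines <- character(0)
    if (!is.null(pushback)) {
      lines <- pushback
      pushback <<- NULL
    }
    want <- n - length(lines)
    if (want > 0L) {
      more <- readLines(con, n = want, warn = FALSE)
      lines <- c(lines, sub("\r$", "", more))
    }
    first <- line_no + 1L
    line_no <<- line_no + length(lines)
    parse_sam_lines(lines[nzchar(lines)], first)
  }
  env$close <- function() close(con)
  env
}

#' Read a SAM file
#'
#' @param path path to a SAM text file.
#' @return list with `header` (a [sam_header()]) and `alignments` (a
#'   data.frame, see [empty_alignments()] for the columns).
#' @export
read_sam <- function(path) {
  rdr <- sam_open(path)
  on.exit(rdr$close())
  chunks <- list()
  repeat {
    ch <- rdr$read(1e5L)
    if (nrow(ch) == 0L) break
    chunks[[length(chunks) + 1L]] <- ch
  }
  aln <- if (length(chunks)) do.call(rbind, chunks) else empty_alignments()
  rownames(aln) <- NULL
  list(header = rdr$header, alignments = aln)
}

# one SAM text line per record (no newline)
format_sam_records <- function(alignments) {
  if (nrow(alignments) == 0L) return(character(0))
  base <- paste(alignments$qname, alignments$flag, alignments$rname,
                alignments$pos, alignments$mapq, alignments$cigar,
                alignments$rnext, alignments$pnext, alignments$tlen,
                alignments$seq, alignments$qual, sep = "\t")
  ifelse(alignments$tags == "", base, paste(base, alignments$tags, sep = "\t"))
}

#' Write a SAM file
#'
#' Emits header lines then one tab-separated line per record. Records are
#' validated against the header first; any violation refuses the write. A
#' zero-length CIGAR operation is also refused (lenient-in, strict-out).
#'
#' @param path output path.
#' @param header a [sam_header()].
#' @param alignments alignment data.frame.
#' @param validate set FALSE to skip validation (internal use by the sorter,
#'   whose inputs were validated on read).
#' @return invisibly, the path.
#' @export
write_sam <- function(path, header, alignments = empty_alignments(),
                      validate = TRUE) {
  if (validate && nrow(alignments)) {
    refuse_invalid(alignments, header)
  }
  con <- file(path, "wb")   # binary: exact LF line endings
  on.exit(close(con))
  lines <- c(header_lines(header), format_sam_records(alignments))
  if (length(lines)) writeLines(lines, con, sep = "\n")
  invisible(path)
}

refuse_invalid <- function(alignments, header) {
  v <- validate_alignments(alignments, header)
  bad <- which(lengths(v) > 0L)
  if (length(bad)) {
    bamkit_stop(sprintf("refusing to write %d invalid record(s); first: %s",
                        length(bad), v[[bad[1]]][1]),
                "bamkit_validation_error")
  }
  if (any(grepl("(^|[MIDNSHP=X])0[MIDNSHP=X]", alignments$cigar))) {
    bamkit_stop("refusing to write zero-length CIGAR operation",
                "bamkit_validation_error")
  }
  invisible()
}
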