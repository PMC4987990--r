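# faidx-style FASTA indexing and O(1) region fetch, plus FASTQ I/O with
# Phred+33 qualities. A FAI record stores, per sequence: name (header token
# up to the first whitespace), base count, file offset of the first sequence
# octet, bases per full line and octets per full line including the
# terminator; from those any base's file position is plain arithmetic.
# CRLF files are supported (linewidth - linebases = 2).

#' Build a FAI index for a FASTA file
#'
#' Scans the file once, byte-counting. Within a sequence every line except
#' the last must share the first line's width; ragged interior lines and
#' duplicate names are format errors.
#'
#' @param fasta_path path to a FASTA file.
#' @return data.frame with columns `name`, `length`, `offset`, `linebases`,
#'   `linewidth` (one row per sequence, file order).
#' @export
build_fai <- function(fasta_path) {
  bytes <- readBin(fasta_path, "raw", n = file.size(fasta_path))
  # line ends (LF positions), tolerant of a missing final newline
  nl <- which(bytes == as.raw(0x0a))
  n <- length(bytes)
  if (length(nl) == 0L || nl[length(nl)] != n) nl <- c(nl, n + 1L)
  starts <- c(1L, head(nl, -1L) + 1L)
  ends <- nl - 1L                          # inclusive, before LF
  is_crlf <- ends >= starts & bytes[pmax(ends, 1L)] == as.raw(0x0d)
  content_ends <- ends - as.integer(is_crlf)
  widths <- pmax(content_ends - starts + 1L, 0L)
  line_oct <- nl - starts + 1L             # octets incl terminator
  is_hdr <- widths > 0L & bytes[starts] == as.raw(0x3e)   # '>'
  if (!any(is_hdr) || !is_hdr[1]) {
    bamkit_stop("not a FASTA file: first line does not start with '>'",
                "bamkit_format_error")
  }
  hdr_idx <- which(is_hdr)
  out <- vector("list", length(hdr_idx))
  for (k in seq_along(hdr_idx)) {
    h <- hdr_idx[k]
    hdr_txt <- rawToChar(bytes[(starts[h] + 1L):content_ends[h]])
    name <- strsplit(hdr_txt, "[ \t]")[[1]][1]
    last <- if (k < length(hdr_idx)) hdr_idx[k + 1L] - 1L else length(starts)
    seq_lines <- if (last >= h + 1L) (h + 1L):last else integer(0)
    while (length(seq_lines) && widths[seq_lines[length(seq_lines)]] == 0L) {
      seq_lines <- seq_lines[-length(seq_lines)]
    }
    if (length(seq_lines) && any(widths[seq_lines] == 0L)) {
      bamkit_stop(sprintf("blank line inside FASTA record '%s'", name),
                  "bamkit_format_error")
    }
    if (length(seq_lines)) {
      w <- widths[seq_lines]
      if (length(w) > 1L && any(w[-length(w)] != w[1])) {
        bamkit_stop(sprintf("ragged sequence lines in FASTA record '%s'", name),
                    "bamkit_format_error")
      }
      if (w[length(w)] > w[1]) {
        bamkit_stop(sprintf("interior/terminal line longer than first in record '%s'",
                            name), "bamkit_format_error")
      }
      out[[k]] <- data.frame(
        name = name, length = sum(w),
        offset = starts[seq_lines[1]] - 1L,
        linebases = w[1], linewidth = line_oct[seq_lines[1]],
        stringsAsFactors = FALSE)
    } else {
      out[[k]] <- data.frame(name = name, length = 0L,
                             offset = nl[h],
                             linebases = 0L, linewidth = 1L,
                             stringsAsFactors = FALSE)
    }
  }
  fai <- do.call(rbind, out)
  if (anyDuplicated(fai$name)) {
    bamkit_stop(sprintf("duplicate sequence name '%s' in FASTA",
                        fai$name[duplicated(fai$name)][1]),
                "bamkit_format_error")
  }
  fai
}

#' Write / read a 5-column FAI file
#'
#' @param fai data.frame from [build_fai()].
#' @param path FAI path (conventionally the FASTA path plus ".fai").
#' @return `write_fai`: invisibly, the path; `read_fai`: the data.frame.
#' @export
write_fai <- function(fai, path) {
  lines <- sprintf("%s\t%d\t%d\t%d\t%d", fai$name, fai$length, fai$offset,
                   fai$linebases, fai$linewidth)
  con <- file(path, "wb")
  on.exit(close(con))
  if (length(lines)) writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' @rdname write_fai
#' @export
read_fai <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 5L)) {
    bamkit_stop("FAI lines must have 5 tab-separated columns",
                "bamkit_format_error")
  }
  data.frame(name = vapply(parts, `[[`, "", 1L),
             length = as.integer(vapply(parts, `[[`, "", 2L)),
             offset = as.integer(vapply(parts, `[[`, "", 3L)),
             linebases = as.integer(vapply(parts, `[[`, "", 4L)),
             linewidth = as.integer(vapply(parts, `[[`, "", 5L)),
             stringsAsFactors = FALSE)
}

#' Fetch a reference subsequence by offset arithmetic
#'
#' Reads exactly the file bytes covering positions `start1..end1` of the
#' named sequence (newlines stripped), without reading the rest of the file.
#' Case is preserved, so soft-masking survives.
#'
#' @param fasta_path path to the FASTA file.
#' @param fai its index, from [build_fai()] or [read_fai()].
#' @param region "name:start-end" (1-based inclusive) or
#'   list(name, start1, end1).
#' @return single base string of length `end1 - start1 + 1`.
#' @export
fetch_region <- function(fasta_path, fai, region) {
  reg <- parse_region(region)
  i <- match(reg$rname, fai$name)
  if (is.na(i)) {
    bamkit_stop(sprintf("sequence '%s' not in FAI index", reg$rname),
                "bamkit_lookup_error")
  }
  if (reg$start1 < 1 || reg$end1 > fai$length[i] || reg$start1 > reg$end1) {
    bamkit_stop(sprintf("region %s:%d-%d outside 1..%d", reg$rname,
                        reg$start1, reg$end1, fai$length[i]),
                "bamkit_range_error")
  }
  lb <- fai$linebases[i]
  lw <- fai$linewidth[i]
  p0 <- reg$start1 - 1
  file_beg <- fai$offset[i] + (p0 %/% lb) * lw + p0 %% lb
  pN <- reg$end1 - 1
  file_end <- fai$offset[i] + (pN %/% lb) * lw + pN %% lb
  con <- file(fasta_path, "rb")
  on.exit(close(con))
  seek(con, file_beg)
  chunk <- readBin(con, "raw", n = file_end - file_beg + 1)
  keep <- chunk != as.raw(0x0a) & chunk != as.raw(0x0d)
  rawToChar(chunk[keep])
}

#' Read a FASTQ file
#'
#' Expects 4-line records with '+' opening the third line; sequence and
#' quality strings must agree in length; qualities are Phred+33.
#'
#' @param path FASTQ path.
#' @return data.frame with `name`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  if (length(lines) && !nzchar(lines[length(lines)])) {
    lines <- lines[-length(lines)]
  }
  if (length(lines) %% 4L != 0L) {
    bamkit_stop(sprintf("FASTQ record truncated: %d lines is not a multiple of 4",
                        length(lines)), "bamkit_parse_error")
  }
  n <- length(lines) %/% 4L
  at <- 4L * (seq_len(n) - 1L)
  heads <- lines[at + 1L]
  seqs <- lines[at + 2L]
  plus <- lines[at + 3L]
  quals <- lines[at + 4L]
  if (any(!startsWith(heads, "@"))) {
    bamkit_stop("FASTQ record does not start with '@'", "bamkit_parse_error")
  }
  if (any(!startsWith(plus, "+"))) {
    bamkit_stop("FASTQ third line does not start with '+'", "bamkit_parse_error")
  }
  if (any(nchar(seqs) != nchar(quals))) {
    bamkit_stop("FASTQ seq/qual length mismatch", "bamkit_parse_error")
  }
  data.frame(name = substring(heads, 2L), seq = seqs, qual = quals,
             stringsAsFactors = FALSE)
}

#' Write a FASTQ file
#'
#' @param records data.frame with `name`, `seq`, `qual` (Phred+33).
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_fastq <- function(records, path) {
  if (any(nchar(records$seq) != nchar(records$qual))) {
    bamkit_stop("FASTQ seq/qual length mismatch", "bamkit_parse_error")
  }
  con <- file(path, "wb")
  on.exit(close(con))
  if (nrow(records)) {
    lines <- as.vector(rbind(paste0("@", records$name), records$seq,
                             "+", records$qual))
    writeLines(lines, con, sep = "\n")
  }
  invisible(path)
}

#' Phred+33 quality conversions
#'
#' @param qual quality string(s).
#' @return `phred_scores`: list of integer vectors (character code minus
#'   33); `phred_string`: character vector encoding integer scores.
#' @export
phred_scores <- function(qual) {
  lapply(qual, function(q) as.integer(charToRaw(q)) - 33L)
}

#' @rdname phred_scores
#' @param scores integer vector of Phred scores.
#' @export
phred_string <- function(scores) {
  rawToChar(as.raw(scores + 33L))
}

#' Index a FASTA file and write the conventional .fai beside it
#'
#' @param fasta_path path to the FASTA file.
#' @param fai_path output path; defaults to `<fasta_path>.fai`.
#' @return invisibly, the FAI data.frame.
#' @export
index_fasta <- function(fasta_path, fai_path = paste0(fasta_path, ".fai")) {
  fai <- build_fai(fasta_path)
  write_fai(fai, fai_path)
  invisible(fai)
}
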