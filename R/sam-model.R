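# Core SAM domain model: headers, alignment tables, flag and CIGAR
# semantics, validation, and reference-name normalization. Coordinates are
# 1-based inclusive throughout the model (SAM convention); the BAM binary
# layer and BAI binning convert to 0-based half-open at their boundary.

FLAG_BITS <- c(paired = 1L, proper_pair = 2L, unmapped = 4L,
               mate_unmapped = 8L, reverse = 16L, mate_reverse = 32L,
               first_of_pair = 64L, second_of_pair = 128L, secondary = 256L,
               qc_fail = 512L, duplicate = 1024L, supplementary = 2048L)

CIGAR_OPS <- c("M", "I", "D", "N", "S", "H", "P", "=", "X")

field_get <- function(fields, tag) {
  if (tag %in% names(fields)) fields[[tag]] else NA_character_
}
CIGAR_CONSUMES_QUERY <- c("M", "I", "S", "=", "X")
CIGAR_CONSUMES_REF <- c("M", "D", "N", "=", "X")

#' Construct a SAM header
#'
#' A SAM header is an ordered list of records. Each record is a list with
#' `type` (one of HD, SQ, RG, PG, CO) and either `fields` (a named character
#' vector of tag values, order preserved) or, for CO, `text`. The position of
#' an SQ record in file order defines its reference id, which is the id
#' space BAM and BAI files use.
#'
#' @param records list of header records as described above.
#' @return an object of class `sam_header`.
#' @export
sam_header <- function(records = list()) {
  sq <- Filter(function(r) r$type == "SQ", records)
  sn <- vapply(sq, function(r) field_get(r$fields, "SN"), "")
  ln <- vapply(sq, function(r) field_get(r$fields, "LN"), "")
  if (anyNA(sn) || anyNA(ln)) {
    bamkit_stop("every @SQ record needs SN and LN", "bamkit_format_error")
  }
  if (anyDuplicated(sn)) {
    bamkit_stop("duplicate SN in @SQ records", "bamkit_format_error")
  }
  lnum <- suppressWarnings(as.numeric(ln))
  if (anyNA(lnum) || any(lnum <= 0)) {
    bamkit_stop("@SQ LN must be a positive integer", "bamkit_format_error")
  }
  structure(list(records = records), class = "sam_header")
}

#' @export
print.sam_header <- function(x, ...) {
  cat(header_lines(x), sep = "\n")
  invisible(x)
}

#' Reference sequences declared by a header
#'
#' @param header a [sam_header()].
#' @return data.frame with `name` and `length`, in @SQ order; row i - 1 is
#'   reference id i - 1 (0-based, as BAM stores it).
#' @export
header_references <- function(header) {
  sq <- Filter(function(r) r$type == "SQ", header$records)
  data.frame(
    name = vapply(sq, function(r) r$fields[["SN"]], ""),
    length = vapply(sq, function(r) as.numeric(r$fields[["LN"]]), 0),
    stringsAsFactors = FALSE)
}

#' Serialize a header to SAM text lines
#'
#' @param header a [sam_header()].
#' @return character vector, one "@TY\\tTAG:value..." line per record.
#' @export
header_lines <- function(header) {
  vapply(header$records, function(r) {
    if (r$type == "CO") {
      paste0("@CO\t", r$text)
    } else {
      paste0("@", r$type, "\t",
             paste0(names(r$fields), ":", r$fields, collapse = "\t"))
    }
  }, "")
}

# set or update the @HD SO: field (sort order marker)
header_set_sort_order <- function(header, order) {
  recs <- header$records
  hd <- which(vapply(recs, function(r) r$type, "") == "HD")
  if (length(hd)) {
    f <- recs[[hd[1]]]$fields
    f[["SO"]] <- order
    recs[[hd[1]]]$fields <- f
  } else {
    recs <- c(list(list(type = "HD", fields = c(VN = "1.6", SO = order))), recs)
  }
  sam_header(recs)
}

#' An empty alignment table
#'
#' Alignments are held as a plain data.frame with one row per record and the
#' 11 mandatory SAM columns plus `tags`, a character column holding the
#' record's optional fields in SAM text form ("TAG:TYPE:VALUE", tab-joined,
#' "" when absent).
#'
#' @return zero-row alignment data.frame.
#' @export
empty_alignments <- function() {
  data.frame(qname = character(0), flag = integer(0), rname = character(0),
             pos = integer(0), mapq = integer(0), cigar = character(0),
             rnext = character(0), pnext = integer(0), tlen = integer(0),
             seq = character(0), qual = character(0), tags = character(0),
             stringsAsFactors = FALSE)
}

#' Decode a SAM flag into named predicates
#'
#' @param flag integer in 0..65535.
#' @return character vector of the predicate names whose bits are set, among
#'   paired, proper_pair, unmapped, mate_unmapped, reverse, mate_reverse,
#'   first_of_pair, second_of_pair, secondary, qc_fail, duplicate,
#'   supplementary.
#' @examples
#' decode_flag(99)  # paired, proper_pair, mate_reverse, first_of_pair
#' @export
decode_flag <- function(flag) {
  if (length(flag) != 1L || is.na(flag) || flag < 0 || flag > 65535 ||
      flag != floor(flag)) {
    bamkit_stop("flag must be a single integer in 0..65535", "bamkit_range_error")
  }
  names(FLAG_BITS)[bitwAnd(as.integer(flag), FLAG_BITS) != 0L]
}

# vectorized bit test used internally
flag_has <- function(flags, bit) bitwAnd(as.integer(flags), bit) != 0L

#' Parse and serialize CIGAR strings
#'
#' `parse_cigar` tokenizes a CIGAR string into an operation table;
#' `cigar_string` is its inverse. `"*"` parses to the empty table. On the
#' parse side zero-length operations are tolerated; [write_sam()] and
#' [write_bam()] reject them.
#'
#' @param text CIGAR string, `"*"` for none.
#' @return data.frame with integer `length` and character `op` columns, one
#'   row per operation.
#' @examples
#' parse_cigar("8M2I4M1D3M")
#' @export
parse_cigar <- function(text) {
  stopifnot(length(text) == 1L)
  if (text == "*") {
    return(data.frame(length = integer(0), op = character(0),
                      stringsAsFactors = FALSE))
  }
  if (!grepl("^([0-9]+[MIDNSHP=X])+$", text)) {
    bamkit_stop(sprintf("malformed CIGAR string '%s'", text),
                "bamkit_parse_error")
  }
  toks <- regmatches(text, gregexpr("[0-9]+[MIDNSHP=X]", text))[[1]]
  data.frame(length = as.integer(substr(toks, 1L, nchar(toks) - 1L)),
             op = substring(toks, nchar(toks)),
             stringsAsFactors = FALSE)
}

#' @rdname parse_cigar
#' @param ops an operation table as returned by `parse_cigar`.
#' @export
cigar_string <- function(ops) {
  if (nrow(ops) == 0L) return("*")
  paste0(ops$length, ops$op, collapse = "")
}

#' Query and reference lengths consumed by a CIGAR
#'
#' M, I, S, =, X consume query; M, D, N, =, X consume reference.
#'
#' @param ops operation table from [parse_cigar()].
#' @return named numeric vector `c(query = , ref = )`.
#' @export
cigar_lengths <- function(ops) {
  c(query = as.numeric(sum(ops$length[ops$op %in% CIGAR_CONSUMES_QUERY])),
    ref = as.numeric(sum(ops$length[ops$op %in% CIGAR_CONSUMES_REF])))
}

# vectorized reference-consumed length over a character vector of CIGARs;
# "*" yields 0
cigar_ref_span <- function(cigars) {
  vapply(cigars, function(cg) {
    if (cg == "*") return(0)
    toks <- regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]", cg))[[1]]
    op <- substring(toks, nchar(toks))
    keep <- op %in% CIGAR_CONSUMES_REF
    sum(as.numeric(substr(toks[keep], 1L, nchar(toks[keep]) - 1L)))
  }, 0, USE.NAMES = FALSE)
}

cigar_query_span <- function(cigars) {
  vapply(cigars, function(cg) {
    if (cg == "*") return(0)
    toks <- regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]", cg))[[1]]
    op <- substring(toks, nchar(toks))
    keep <- op %in% CIGAR_CONSUMES_QUERY
    sum(as.numeric(substr(toks[keep], 1L, nchar(toks[keep]) - 1L)))
  }, 0, USE.NAMES = FALSE)
}

#' 1-based inclusive reference end of a mapped alignment
#'
#' @param pos 1-based leftmost position.
#' @param cigar CIGAR string (not `"*"`).
#' @return `pos + reference-consumed length - 1`.
#' @export
alignment_end <- function(pos, cigar) {
  if (length(cigar) == 1L && cigar == "*" || any(pos < 1)) {
    bamkit_stop("alignment end is undefined for unmapped or CIGAR-less records",
                "bamkit_range_error")
  }
  pos + cigar_ref_span(cigar) - 1
}

# default canonicalization map: bare GRCh-style chromosome tokens gain the
# "chr" prefix; mitochondrion MT/M map to chrM
default_name_map <- function() {
  bare <- c(as.character(1:22), "X", "Y", "M", "MT")
  stats::setNames(paste0("chr", c(as.character(1:22), "X", "Y", "M", "M")), bare)
}

canonical_name <- function(x, map) {
  hit <- match(x, names(map))
  out <- x
  out[!is.na(hit)] <- unname(map[hit[!is.na(hit)]])
  out
}

#' Normalize reference names in a header and its alignments
#'
#' Applies a canonicalization map to the SN of every @SQ record and to the
#' rname/rnext of every alignment, keeping header and records linked. The
#' default map adds the "chr" prefix to the bare chromosome tokens 1-22, X,
#' Y and maps M/MT to "chrM"; already-canonical names pass through, so the
#' operation is idempotent. Two distinct input names collapsing onto one
#' output name is an error.
#'
#' @param header a [sam_header()].
#' @param alignments alignment data.frame.
#' @param map named character vector mapping input names to canonical names;
#'   defaults to the chr-prefix map above.
#' @return list with normalized `header` and `alignments`.
#' @export
normalize_reference_names <- function(header, alignments = empty_alignments(),
                                      map = default_name_map()) {
  refs <- header_references(header)
  new_names <- canonical_name(refs$name, map)
  if (anyDuplicated(new_names)) {
    dup <- new_names[duplicated(new_names)][1]
    bamkit_stop(sprintf("normalization collision: multiple references map to '%s'",
                        dup), "bamkit_collision_error")
  }
  recs <- lapply(header$records, function(r) {
    if (r$type == "SQ") r$fields[["SN"]] <- canonical_name(r$fields[["SN"]], map)
    r
  })
  keep_star <- function(x) ifelse(x %in% c("*", "="), x, canonical_name(x, map))
  alignments$rname <- keep_star(alignments$rname)
  alignments$rnext <- keep_star(alignments$rnext)
  list(header = sam_header(recs), alignments = alignments)
}

#' Validate alignment records against a header
#'
#' Checks the record-level invariants (seq/qual length agreement, CIGAR
#' query length vs seq length, mapped records having a reference and a
#' positive position) and the referential ones (rname declared in the
#' header, pos within the reference length). Violations are returned as
#' data, not raised.
#'
#' @param alignments alignment data.frame.
#' @param header a [sam_header()].
#' @return list (one element per record) of character vectors of violation
#'   messages; an empty vector means the record is consistent.
#' @export
validate_alignments <- function(alignments, header) {
  refs <- header_references(header)
  lens <- stats::setNames(refs$length, refs$name)
  lapply(seq_len(nrow(alignments)), function(i) {
    r <- alignments[i, ]
    v <- character(0)
    if (r$seq != "*" && r$qual != "*" && nchar(r$seq) != nchar(r$qual)) {
      v <- c(v, sprintf("seq length %d != qual length %d",
                        nchar(r$seq), nchar(r$qual)))
    }
    if (r$cigar != "*" && r$seq != "*") {
      ql <- cigar_query_span(r$cigar)
      if (ql != nchar(r$seq)) {
        v <- c(v, sprintf("CIGAR query length %d != seq length %d",
                          ql, nchar(r$seq)))
      }
    }
    mapped <- !flag_has(r$flag, 4L)
    if (mapped && (r$rname == "*" || r$pos < 1)) {
      v <- c(v, "mapped record lacks reference name or position")
    }
    if (r$rname != "*") {
      if (!(r$rname %in% refs$name)) {
        v <- c(v, sprintf("rname '%s' not declared in header", r$rname))
      } else if (r$pos > lens[[r$rname]]) {
        v <- c(v, sprintf("pos %d beyond reference length %d",
                          r$pos, as.integer(lens[[r$rname]])))
      }
    }
    v
  })
}
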