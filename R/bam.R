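# BAM binary encoding/decoding layered on the BGZF codec: little-endian
# throughout, magic "BAM\1", 4-bit packed sequences, binary CIGAR words and
# typed optional tags. Conversion SAM<->BAM is reading with one writer and
# writing with the other.

BAM_MAGIC <- as.raw(c(0x42, 0x41, 0x4d, 0x01))
SEQ_NT16 <- strsplit("=ACMGRSVTWYHKDBN", "")[[1]]

#' Pack a base string into BAM 4-bit nibbles
#'
#' Two bases per octet, high nibble first, using the 16-symbol IUPAC code
#' ('='->0, A->1, C->2, M->3, G->4, ..., N->15); an odd-length sequence pads
#' the final low nibble with zero. Case-insensitive.
#'
#' @param seq base string over "=ACMGRSVTWYHKDBN" (either case).
#' @return raw vector of ceiling(nchar(seq) / 2) octets.
#' @export
encode_seq <- function(seq) {
  if (seq == "" ) return(raw(0))
  chars <- strsplit(toupper(seq), "")[[1]]
  codes <- match(chars, SEQ_NT16) - 1L
  if (anyNA(codes)) {
    bamkit_stop(sprintf("sequence character '%s' outside the 16-symbol alphabet",
                        chars[which(is.na(codes))[1]]), "bamkit_parse_error")
  }
  if (length(codes) %% 2L == 1L) codes <- c(codes, 0L)
  as.raw(codes[c(TRUE, FALSE)] * 16L + codes[c(FALSE, TRUE)])
}

#' @rdname encode_seq
#' @param packed raw vector of packed nibbles.
#' @param l_seq number of bases to take.
#' @export
decode_seq <- function(packed, l_seq) {
  if (l_seq == 0L) return("")
  v <- as.integer(packed)
  codes <- as.vector(rbind(v %/% 16L, v %% 16L))[seq_len(l_seq)]
  paste(SEQ_NT16[codes + 1L], collapse = "")
}

# CIGAR <-> 32-bit words: word = length * 16 + opcode, opcodes MIDNSHP=X -> 0..8
encode_cigar_words <- function(ops) {
  if (nrow(ops) == 0L) return(numeric(0))
  if (any(ops$length >= 2^28)) {
    bamkit_stop("CIGAR operation length >= 2^28 cannot be encoded",
                "bamkit_size_error")
  }
  code <- match(ops$op, CIGAR_OPS) - 1L
  if (anyNA(code)) bamkit_stop("unknown CIGAR opcode", "bamkit_parse_error")
  as.numeric(ops$length) * 16 + code
}

decode_cigar_words <- function(words) {
  data.frame(length = as.integer(words %/% 16),
             op = CIGAR_OPS[words %% 16 + 1],
             stringsAsFactors = FALSE)
}

# ---- optional tags: SAM text form <-> BAM binary form -----------------------

# smallest integer subtype that holds v (unsigned preferred for non-negatives,
# as samtools writes them); text SAM re-serializes them all as 'i'
int_subtype <- function(v) {
  if (v >= 0) {
    if (v <= 255) "C" else if (v <= 65535) "S" else "I"
  } else {
    if (v >= -128) "c" else if (v >= -32768) "s" else "i"
  }
}

tag_int_raw <- function(v, sub) {
  switch(sub,
         c = , C = as.raw(v %% 256),
         s = , S = u16_raw(v %% 65536),
         i = , I = u32_raw(v))
}

encode_tags <- function(tagstr) {
  if (tagstr == "") return(raw(0))
  parts <- strsplit(tagstr, "\t", fixed = TRUE)[[1]]
  out <- lapply(parts, function(t) {
    tag <- charToRaw(substr(t, 1L, 2L))
    type <- substr(t, 4L, 4L)
    val <- substr(t, 6L, nchar(t))
    switch(type,
      A = c(tag, charToRaw("A"), charToRaw(val)),
      i = {
        v <- as.numeric(val)
        if (is.na(v) || v != floor(v)) {
          bamkit_stop(sprintf("bad integer tag value '%s'", val),
                      "bamkit_parse_error")
        }
        sub <- int_subtype(v)
        c(tag, charToRaw(sub), tag_int_raw(v, sub))
      },
      f = c(tag, charToRaw("f"),
            writeBin(as.numeric(val), raw(), size = 4L, endian = "little")),
      Z = c(tag, charToRaw("Z"), charToRaw(val), as.raw(0L)),
      H = c(tag, charToRaw("H"), charToRaw(val), as.raw(0L)),
      B = {
        items <- strsplit(val, ",", fixed = TRUE)[[1]]
        sub <- items[1]
        vals <- as.numeric(items[-1])
        body <- switch(sub,
          c = , C = as.raw(vals %% 256),
          s = , S = unlist(lapply(vals %% 65536, u16_raw)),
          i = , I = unlist(lapply(vals, u32_raw)),
          f = writeBin(vals, raw(), size = 4L, endian = "little"),
          bamkit_stop(sprintf("unknown B-array subtype '%s'", sub),
                      "bamkit_parse_error"))
        c(tag, charToRaw("B"), charToRaw(sub), u32_raw(length(vals)),
          if (length(vals)) body else raw(0))
      },
      bamkit_stop(sprintf("unknown tag type '%s'", type), "bamkit_parse_error"))
  })
  unlist(out)
}

read_tag_int <- function(r, at, sub) {
  switch(sub,
         C = as.numeric(r[at]),
         c = { v <- as.numeric(r[at]); ifelse(v >= 128, v - 256, v) },
         S = as.numeric(read_u16(r, at)),
         s = { v <- read_u16(r, at); ifelse(v >= 32768, v - 65536, v) },
         I = read_u32(r, at),
         i = read_i32(r, at))
}

int_size <- function(sub) c(c = 1L, C = 1L, s = 2L, S = 2L, i = 4L, I = 4L,
                            f = 4L)[[sub]]

fmt_num <- function(v) {
  if (v == floor(v) && abs(v) < 2^53) sprintf("%.0f", v) else sprintf("%g", v)
}

decode_tags <- function(r) {
  out <- character(0)
  p <- 1L
  n <- length(r)
  while (p <= n) {
    if (p + 2L > n) bamkit_stop("truncated tag block", "bamkit_truncation_error")
    tag <- rawToChar(r[p:(p + 1L)])
    type <- rawToChar(r[p + 2L])
    p <- p + 3L
    if (type == "A") {
      out <- c(out, sprintf("%s:A:%s", tag, rawToChar(r[p])))
      p <- p + 1L
    } else if (type %in% c("c", "C", "s", "S", "i", "I")) {
      v <- read_tag_int(r, p, type)
      out <- c(out, sprintf("%s:i:%s", tag, fmt_num(v)))
      p <- p + int_size(type)
    } else if (type == "f") {
      v <- readBin(r[p:(p + 3L)], "numeric", size = 4L, endian = "little")
      out <- c(out, sprintf("%s:f:%g", tag, v))
      p <- p + 4L
    } else if (type %in% c("Z", "H")) {
      z <- p
      while (z <= n && r[z] != as.raw(0L)) z <- z + 1L
      if (z > n) bamkit_stop("unterminated string tag", "bamkit_truncation_error")
      out <- c(out, sprintf("%s:%s:%s", tag, type,
                            if (z > p) rawToChar(r[p:(z - 1L)]) else ""))
      p <- z + 1L
    } else if (type == "B") {
      sub <- rawToChar(r[p])
      cnt <- read_u32(r, p + 1L)
      p <- p + 5L
      sz <- int_size(sub)
      vals <- if (cnt == 0) numeric(0)
      else if (sub == "f") {
        readBin(r[p:(p + 4L * cnt - 1L)], "numeric", n = cnt, size = 4L,
                endian = "little")
      } else {
        vapply(seq_len(cnt), function(k) read_tag_int(r, p + (k - 1L) * sz, sub),
               0)
      }
      txt <- if (sub == "f") sprintf("%g", vals) else vapply(vals, fmt_num, "")
      out <- c(out, paste0(tag, ":B:", sub,
                           if (cnt) paste0(",", paste(txt, collapse = ","))
                           else ""))
      p <- p + sz * cnt
    } else {
      bamkit_stop(sprintf("unknown binary tag type '%s'", type),
                  "bamkit_parse_error")
    }
  }
  paste(out, collapse = "\t")
}

# ---- record encode/decode ---------------------------------------------------

# resolve refid for one rname given the reference table; "*" -> -1
rname_to_refid <- function(rname, refs) {
  refid <- match(rname, refs$name) - 1L
  refid[rname == "*"] <- -1L
  if (anyNA(refid)) {
    bamkit_stop(sprintf("record references '%s', absent from header @SQ",
                        rname[which(is.na(refid))[1]]), "bamkit_lookup_error")
  }
  refid
}

# encode one alignment row to its BAM byte layout (without the leading
# block_size word; the caller prepends it)
encode_bam_record <- function(r, refs) {
  refid <- rname_to_refid(r$rname, refs)
  pos0 <- r$pos - 1L            # SAM pos 0 (unavailable) -> -1
  # placement convention: an unplaced record with a placed mate is stored at
  # the mate's coordinates so coordinate sorting keeps the pair adjacent
  rnext_name <- if (r$rnext == "=") r$rname else r$rnext
  next_refid <- rname_to_refid(rnext_name, refs)
  next_pos0 <- r$pnext - 1L
  if (refid == -1L && next_refid != -1L && next_pos0 >= 0L) {
    refid <- next_refid
    pos0 <- next_pos0
  }
  ops <- parse_cigar(r$cigar)
  if (nrow(ops) > 65535L) {
    bamkit_stop("more than 65535 CIGAR operations", "bamkit_size_error")
  }
  ref_span <- sum(ops$length[ops$op %in% CIGAR_CONSUMES_REF])
  bin <- if (pos0 >= 0L) reg2bin(pos0, pos0 + max(ref_span, 1)) else 0L
  l_seq <- if (r$seq == "*") 0L else nchar(r$seq)
  qual_raw <- if (r$qual == "*" || l_seq == 0L) {
    as.raw(rep(0xff, l_seq))
  } else {
    as.raw(as.integer(charToRaw(r$qual)) - 33L)
  }
  name_raw <- c(charToRaw(r$qname), as.raw(0L))
  cig_raw <- if (nrow(ops)) {
    w <- encode_cigar_words(ops)
    unlist(lapply(w, u32_raw))
  } else raw(0)
  c(i32_raw(refid), i32_raw(pos0),
    as.raw(length(name_raw)), as.raw(r$mapq),
    u16_raw(bin), u16_raw(nrow(ops)), u16_raw(r$flag),
    i32_raw(l_seq),
    i32_raw(next_refid), i32_raw(next_pos0), i32_raw(r$tlen),
    name_raw, cig_raw,
    if (l_seq) encode_seq(r$seq) else raw(0),
    qual_raw,
    encode_tags(r$tags))
}

encode_bam_records <- function(alignments, refs) {
  if (nrow(alignments) == 0L) return(raw(0))
  parts <- lapply(seq_len(nrow(alignments)), function(i) {
    body <- encode_bam_record(alignments[i, ], refs)
    c(i32_raw(length(body)), body)
  })
  unlist(parts)
}

# decode one record body (after block_size) starting at 1-based `at` with
# length `len`; returns a one-row list of fields
decode_bam_record <- function(r, at, len, ref_names) {
  refid <- read_i32(r, at)
  pos0 <- read_i32(r, at + 4L)
  l_read_name <- as.integer(r[at + 8L])
  mapq <- as.integer(r[at + 9L])
  n_cigar <- read_u16(r, at + 12L)
  flag <- read_u16(r, at + 14L)
  l_seq <- read_i32(r, at + 16L)
  next_refid <- read_i32(r, at + 20L)
  next_pos0 <- read_i32(r, at + 24L)
  tlen <- read_i32(r, at + 28L)
  p <- at + 32L
  qname <- if (l_read_name > 1L) rawToChar(r[p:(p + l_read_name - 2L)]) else ""
  p <- p + l_read_name
  cigar <- if (n_cigar > 0L) {
    words <- read_u32(r, p + 4L * (seq_len(n_cigar) - 1L))
    p <- p + 4L * n_cigar
    cigar_string(decode_cigar_words(words))
  } else "*"
  nseq_bytes <- (l_seq + 1L) %/% 2L
  seq <- if (l_seq > 0L) decode_seq(r[p:(p + nseq_bytes - 1L)], l_seq) else "*"
  p <- p + nseq_bytes
  qual <- if (l_seq > 0L) {
    q <- r[p:(p + l_seq - 1L)]
    if (all(q == as.raw(0xff))) "*" else rawToChar(as.raw(as.integer(q) + 33L))
  } else "*"
  p <- p + l_seq
  tags <- if (p <= at + len - 1L) decode_tags(r[p:(at + len - 1L)]) else ""
  ref_of <- function(id) if (id >= 0L) ref_names[id + 1L] else "*"
  list(qname = qname, flag = flag,
       rname = ref_of(refid), pos = pos0 + 1L, mapq = mapq, cigar = cigar,
       rnext = ref_of(next_refid), pnext = next_pos0 + 1L, tlen = tlen,
       seq = seq, qual = qual, tags = tags)
}

# ---- whole-file writer ------------------------------------------------------

encode_bam_header <- function(header) {
  refs <- header_references(header)
  text <- paste0(paste(header_lines(header), collapse = "\n"),
                 if (length(header$records)) "\n" else "")
  ref_raw <- unlist(lapply(seq_len(nrow(refs)), function(i) {
    nm <- charToRaw(refs$name[i])
    c(i32_raw(length(nm) + 1L), nm, as.raw(0L), i32_raw(refs$length[i]))
  }))
  c(BAM_MAGIC, i32_raw(nchar(text)), charToRaw(text),
    i32_raw(nrow(refs)), if (is.null(ref_raw)) raw(0) else ref_raw)
}

#' Incremental BAM writer
#'
#' Opens `path` for writing, emits the BAM header immediately and then
#' accepts alignment batches via `write_records(df)`; `close()` flushes the
#' final partial block and the BGZF end-of-file sentinel. Bytes are packed
#' into BGZF blocks of at most 65280 uncompressed octets irrespective of
#' record boundaries.
#'
#' @param path output path.
#' @param header a [sam_header()].
#' @param level deflate level 0-9.
#' @param validate validate records against the header before encoding.
#' @return a writer: list with `write_records(alignments)` and `close()`.
#' @export
bam_writer <- function(path, header, level = 6L, validate = TRUE) {
  con <- file(path, "wb")
  refs <- header_references(header)
  env <- new.env(parent = emptyenv())
  env$pending <- encode_bam_header(header)
  flush_full <- function(final = FALSE) {
    while (length(env$pending) >= BGZF_MAX_PAYLOAD) {
      writeBin(bgzf_encode_block(env$pending[seq_len(BGZF_MAX_PAYLOAD)], level),
               con)
      env$pending <- env$pending[-seq_len(BGZF_MAX_PAYLOAD)]
    }
    if (final) {
      if (length(env$pending)) {
        writeBin(bgzf_encode_block(env$pending, level), con)
        env$pending <- raw(0)
      }
      writeBin(bgzf_encode_block(raw(0), level), con)
    }
  }
  list(
    write_records = function(alignments) {
      if (nrow(alignments) == 0L) return(invisible())
      if (validate) refuse_invalid(alignments, header)
      env$pending <- c(env$pending, encode_bam_records(alignments, refs))
      flush_full()
      invisible()
    },
    close = function() {
      flush_full(final = TRUE)
      close(con)
      invisible(path)
    })
}

#' Write a BAM file
#'
#' Encodes the header (magic, header text, reference directory in @SQ order)
#' and all records, BGZF-compressed and sentinel-terminated. A record whose
#' rname/rnext is not declared in the header refuses the write before any
#' output is produced.
#'
#' @inheritParams bam_writer
#' @param alignments alignment data.frame.
#' @return invisibly, the path.
#' @export
write_bam <- function(path, header, alignments = empty_alignments(),
                      level = 6L, validate = TRUE) {
  if (nrow(alignments)) {
    if (validate) refuse_invalid(alignments, header)
    refs <- header_references(header)
    rname_to_refid(unique(alignments$rname), refs)       # fail fast
    rname_to_refid(setdiff(unique(alignments$rnext), "="), refs)
  }
  w <- bam_writer(path, header, level, validate = FALSE)
  if (nrow(alignments)) w$write_records(alignments)
  w$close()
  invisible(path)
}

# ---- whole-file / chunked readers -------------------------------------------

decode_bam_header <- function(data) {
  if (length(data) < 12L || !identical(data[1:4], BAM_MAGIC)) {
    bamkit_stop("not a BAM stream: magic \"BAM\\1\" missing",
                "bamkit_format_error")
  }
  l_text <- read_i32(data, 5L)
  text <- if (l_text > 0L) rawToChar(data[9L:(8L + l_text)]) else ""
  p <- 9L + l_text
  n_ref <- read_i32(data, p)
  p <- p + 4L
  names <- character(n_ref)
  lens <- numeric(n_ref)
  for (i in seq_len(n_ref)) {
    l_name <- read_i32(data, p)
    names[i] <- rawToChar(data[(p + 4L):(p + 4L + l_name - 2L)])
    lens[i] <- read_i32(data, p + 4L + l_name)
    p <- p + 8L + l_name
  }
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  recs <- lapply(lines, parse_header_line)
  header <- sam_header(recs)
  refs <- header_references(header)
  if (nrow(refs)) {
    if (nrow(refs) != n_ref || !identical(refs$name, names)) {
      bamkit_stop("BAM reference directory disagrees with header @SQ records",
                  "bamkit_format_error")
    }
  } else if (n_ref > 0L) {
    # header text without @SQ lines: synthesize from the binary directory
    sq <- lapply(seq_len(n_ref), function(i) {
      list(type = "SQ", fields = c(SN = names[i],
                                   LN = sprintf("%.0f", lens[i])))
    })
    header <- sam_header(c(recs, sq))
  }
  list(header = header, ref_names = names, next_offset = p)
}

#' Open a BAM file for chunked reading
#'
#' Decodes the header immediately; records are decoded on demand in batches
#' via `read(n)`. BGZF blocks are inflated as the read position reaches them
#' and dropped once consumed, so memory stays bounded. Each returned record
#' carries its starting virtual offset in the `voffset` column (and the
#' virtual offset just past it in `voffset_end`), which is what the BAI
#' builder stores as chunk bounds.
#'
#' @param path path to a BAM file.
#' @return a reader: list with `header`, `read(n)` and `close()`.
#' @export
bam_open <- function(path) {
  stream <- readBin(path, "raw", n = file.size(path))
  tbl <- bgzf_block_table(stream)
  env <- new.env(parent = emptyenv())
  env$stream <- stream
  env$tbl <- tbl
  env$next_block <- 1L
  env$buf <- raw(0)
  env$buf_u0 <- 0          # uncompressed offset of buf[1]
  env$cursor <- 0L         # consumed octets within buf
  ensure <- function(nbytes) {
    while (length(env$buf) - env$cursor < nbytes &&
           env$next_block <= nrow(env$tbl)) {
      blk <- bgzf_decode_block(env$stream, env$tbl$coffset[env$next_block] + 1L)
      env$buf <- c(env$buf, blk$payload)
      env$next_block <- env$next_block + 1L
    }
    length(env$buf) - env$cursor >= nbytes
  }
  compact <- function() {
    if (env$cursor > 0L) {
      env$buf <- env$buf[-seq_len(env$cursor)]
      env$buf_u0 <- env$buf_u0 + env$cursor
      env$cursor <- 0L
    }
  }
  if (!ensure(12L)) {
    bamkit_stop("truncated BAM stream", "bamkit_truncation_error")
  }
  # pull in blocks until the whole header structure is buffered
  repeat {
    ok <- tryCatch({
      hd <- decode_bam_header(env$buf)
      TRUE
    }, error = function(e) {
      if (inherits(e, "bamkit_format_error")) stop(e)
      FALSE
    })
    if (ok) break
    if (env$next_block > nrow(env$tbl)) {
      bamkit_stop("truncated BAM header", "bamkit_truncation_error")
    }
    ensure(length(env$buf) - env$cursor + 1L)
  }
  env$cursor <- hd$next_offset - 1L
  header <- hd$header
  ref_names <- hd$ref_names
  list(
    header = header,
    read = function(n = 1e5L) {
      out <- list()
      k <- 0L
      while (k < n) {
        if (!ensure(4L)) break
        sz <- read_i32(env$buf, env$cursor + 1L)
        if (!ensure(4L + sz)) {
          bamkit_stop("truncated BAM record", "bamkit_truncation_error")
        }
        u <- env$buf_u0 + env$cursor
        rec <- decode_bam_record(env$buf, env$cursor + 5L, sz, ref_names)
        rec$u <- u
        rec$u_end <- u + 4 + sz
        out[[length(out) + 1L]] <- rec
        env$cursor <- env$cursor + 4L + sz
        k <- k + 1L
      }
      compact()
      df <- records_to_df(out)
      df$voffset <- uoffset_to_voffset(df$u, env$tbl)
      df$voffset_end <- uoffset_to_voffset(df$u_end, env$tbl)
      df$u <- NULL
      df$u_end <- NULL
      df
    },
    close = function() invisible(NULL))
}

records_to_df <- function(recs) {
  if (length(recs) == 0L) {
    df <- empty_alignments()
    df$u <- numeric(0)
    df$u_end <- numeric(0)
    return(df)
  }
  grab <- function(f, mode) vapply(recs, `[[`, mode, f)
  data.frame(
    qname = grab("qname", ""), flag = as.integer(grab("flag", 0)),
    rname = grab("rname", ""), pos = as.integer(grab("pos", 0)),
    mapq = as.integer(grab("mapq", 0)), cigar = grab("cigar", ""),
    rnext = grab("rnext", ""), pnext = as.integer(grab("pnext", 0)),
    tlen = as.integer(grab("tlen", 0)), seq = grab("seq", ""),
    qual = grab("qual", ""), tags = grab("tags", ""),
    u = grab("u", 0), u_end = grab("u_end", 0),
    stringsAsFactors = FALSE)
}

#' Read a BAM file
#'
#' @param path path to a BAM file.
#' @return list with `header` and `alignments`; the alignment data.frame
#'   carries `voffset`/`voffset_end` columns giving each record's packed
#'   virtual-offset span in the file.
#' @export
read_bam <- function(path) {
  rdr <- bam_open(path)
  chunks <- list()
  repeat {
    ch <- rdr$read(2e4L)
    if (nrow(ch) == 0L) break
    chunks[[length(chunks) + 1L]] <- ch
  }
  aln <- if (length(chunks)) do.call(rbind, chunks) else {
    df <- empty_alignments()
    df$voffset <- numeric(0)
    df$voffset_end <- numeric(0)
    df
  }
  rownames(aln) <- NULL
  list(header = rdr$header, alignments = aln)
}

# ---- format-agnostic convenience --------------------------------------------

is_bam_path <- function(path) grepl("\\.bam$", path, ignore.case = TRUE)

#' Read alignments from SAM or BAM, by file extension
#'
#' @param path input path ending in .sam or .bam.
#' @return list with `header` and `alignments`.
#' @export
read_alignments <- function(path) {
  if (is_bam_path(path)) read_bam(path) else read_sam(path)
}

#' Write alignments to SAM or BAM, by file extension
#'
#' @param path output path ending in .sam or .bam.
#' @param header a [sam_header()].
#' @param alignments alignment data.frame.
#' @param validate validate before writing.
#' @return invisibly, the path.
#' @export
write_alignments <- function(path, header, alignments = empty_alignments(),
                             validate = TRUE) {
  if (is_bam_path(path)) write_bam(path, header, alignments, validate = validate)
  else write_sam(path, header, alignments, validate = validate)
}

#' Open a SAM or BAM file for chunked reading, by file extension
#'
#' @param path input path.
#' @return a reader as from [sam_open()] / [bam_open()].
#' @export
alignment_open <- function(path) {
  if (is_bam_path(path)) bam_open(path) else sam_open(path)
}
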