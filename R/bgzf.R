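# BGZF: blocked gzip as used by BAM. Each block is an independent gzip
# member whose FEXTRA subfield (SI1='B', SI2='C') stores the total on-disk
# block length minus one, so a reader can hop block to block without
# inflating. A 64-bit "virtual offset" addresses any uncompressed byte as
# (compressed block start << 16) | offset within the inflated payload.

BGZF_HEADER_LEN <- 18L
BGZF_FOOTER_LEN <- 8L
BGZF_MAX_BLOCK <- 65536L
# write-side payload cap: leaves headroom so that even incompressible
# payloads stay within the 65536-octet on-disk block bound
BGZF_MAX_PAYLOAD <- 65280L

# The canonical 28-octet end-of-file sentinel is encode_block(raw(0)) at any
# level; emitted by writers, consumed (and required, with a warning fallback)
# by readers.

#' Encode one BGZF block
#'
#' Compresses a payload of at most 65280 octets into a complete BGZF block:
#' an 18-octet gzip header carrying the BSIZE extra subfield, the raw-deflate
#' stream, and the CRC32/ISIZE footer. The empty payload yields the 28-octet
#' end-of-file sentinel block.
#'
#' @param payload raw vector, at most 65280 octets.
#' @param level deflate compression level, 0-9.
#' @return raw vector holding the complete on-disk block (at most 65536
#'   octets).
#' @seealso [bgzf_decode_block()], [bgzf_compress()]
#' @export
bgzf_encode_block <- function(payload, level = 6L) {
  stopifnot(is.raw(payload))
  if (length(payload) > BGZF_MAX_PAYLOAD) {
    bamkit_stop(sprintf("BGZF payload of %d octets exceeds the %d-octet cap",
                        length(payload), BGZF_MAX_PAYLOAD),
                "bamkit_size_error")
  }
  deflated <- .zdeflate_raw(payload, as.integer(level))
  bsize <- BGZF_HEADER_LEN + length(deflated) + BGZF_FOOTER_LEN
  if (bsize > BGZF_MAX_BLOCK) {
    # cannot occur for payloads <= 65280 (deflate stored-block overhead is
    # ~5 octets per 16 KiB plus constant), but guard the format invariant
    bamkit_stop("compressed BGZF block exceeds 65536 octets", "bamkit_size_error")
  }
  header <- as.raw(c(0x1f, 0x8b, 0x08, 0x04,    # magic, CM=deflate, FLG=FEXTRA
                     0x00, 0x00, 0x00, 0x00,    # MTIME
                     0x00, 0xff,                # XFL, OS=unknown
                     0x06, 0x00,                # XLEN = 6
                     0x42, 0x43, 0x02, 0x00))   # 'B','C', SLEN=2
  c(header, u16_raw(bsize - 1L), deflated,
    u32_raw(.zcrc32(payload)), u32_raw(length(payload)))
}

#' Decode one BGZF block from a stream
#'
#' Reads the gzip member starting at `offset` in `stream`, validates the
#' magic, the BC extra subfield, the CRC32 and the ISIZE footer, and returns
#' the inflated payload together with the on-disk block length (so the caller
#' can resume at `offset + bsize`).
#'
#' @param stream raw vector containing one or more concatenated BGZF blocks.
#' @param offset 1-based position of the block's first octet in `stream`.
#' @return list with elements `payload` (raw) and `bsize` (integer).
#' @export
bgzf_decode_block <- function(stream, offset = 1L) {
  stopifnot(is.raw(stream), is_count(offset))
  n_avail <- length(stream) - offset + 1L
  if (n_avail < BGZF_HEADER_LEN) {
    bamkit_stop("truncated BGZF stream: incomplete block header",
                "bamkit_truncation_error")
  }
  h <- stream[offset + 0:17]
  if (h[1] != as.raw(0x1f) || h[2] != as.raw(0x8b)) {
    bamkit_stop("not a BGZF stream: gzip magic 0x1f 0x8b missing",
                "bamkit_format_error")
  }
  if (h[3] != as.raw(0x08) || (as.integer(h[4]) %% 8L) < 4L) {
    bamkit_stop("not a BGZF block: FEXTRA flag unset", "bamkit_format_error")
  }
  # locate the BC subfield within the extra area (BGZF allows other subfields)
  xlen <- read_u16(stream, offset + 10L)
  if (n_avail < 12L + xlen + BGZF_FOOTER_LEN) {
    bamkit_stop("truncated BGZF stream: incomplete extra field",
                "bamkit_truncation_error")
  }
  bsize <- NA_integer_
  p <- offset + 12L
  xend <- offset + 12L + xlen
  while (p + 3L <= xend) {
    slen <- read_u16(stream, p + 2L)
    if (stream[p] == as.raw(0x42) && stream[p + 1L] == as.raw(0x43) &&
        slen == 2L) {
      bsize <- read_u16(stream, p + 4L) + 1L
      break
    }
    p <- p + 4L + slen
  }
  if (is.na(bsize)) {
    bamkit_stop("not a BGZF block: BC extra subfield missing",
                "bamkit_format_error")
  }
  if (n_avail < bsize) {
    bamkit_stop(sprintf("truncated BGZF stream: block claims %d octets, %d available",
                        bsize, n_avail), "bamkit_truncation_error")
  }
  data_start <- offset + 12L + xlen
  data_len <- bsize - (12L + xlen) - BGZF_FOOTER_LEN
  crc_at <- offset + bsize - 8L
  isize <- read_u32(stream, offset + bsize - 4L)
  payload <- tryCatch(
    .zinflate_raw(stream[data_start + seq_len(data_len) - 1L],
                  as.integer(isize)),
    error = function(e) bamkit_stop(
      paste0("corrupt BGZF block: ", conditionMessage(e)),
      "bamkit_corruption_error"))
  if (.zcrc32(payload) != read_u32(stream, crc_at)) {
    bamkit_stop("corrupt BGZF block: CRC32 mismatch", "bamkit_corruption_error")
  }
  list(payload = payload, bsize = bsize)
}

#' Pack / unpack BGZF virtual offsets
#'
#' A virtual offset addresses an uncompressed byte inside a BGZF file as
#' `coffset * 2^16 + uoffset`, where `coffset` is the file offset of the
#' containing block (below 2^48) and `uoffset` the position within its
#' inflated payload (below 2^16). Packed offsets order exactly like the
#' (coffset, uoffset) pairs, which is what BAI chunk bounds rely on. Values
#' are held as doubles; they are exact below 2^53, far beyond any file this
#' package writes.
#'
#' @param coffset compressed file offset(s) of the block start, `0 <= coffset < 2^48`.
#' @param uoffset offset(s) within the inflated block payload, `0 <= uoffset < 2^16`.
#' @return `pack_voffset`: numeric packed offset(s); `unpack_voffset`: list
#'   with numeric `coffset` and `uoffset`.
#' @export
pack_voffset <- function(coffset, uoffset) {
  if (any(coffset < 0 | coffset >= 2^48 | coffset != floor(coffset))) {
    bamkit_stop("coffset out of range [0, 2^48)", "bamkit_range_error")
  }
  if (any(uoffset < 0 | uoffset >= 65536 | uoffset != floor(uoffset))) {
    bamkit_stop("uoffset out of range [0, 2^16)", "bamkit_range_error")
  }
  coffset * 65536 + uoffset
}

#' @rdname pack_voffset
#' @param v packed virtual offset(s), non-negative.
#' @export
unpack_voffset <- function(v) {
  if (any(v < 0)) bamkit_stop("virtual offset must be non-negative",
                              "bamkit_range_error")
  list(coffset = v %/% 65536, uoffset = v %% 65536)
}

#' Compress a payload into a BGZF stream
#'
#' Splits `payload` into pieces of at most 65280 octets, encodes each as one
#' block (optionally across forked workers; block order always equals payload
#' order, so output is a deterministic function of payload and level), and
#' appends the end-of-file sentinel block.
#'
#' @param payload raw vector of any length.
#' @param level deflate level 0-9.
#' @param workers number of processes for block compression.
#' @return raw vector: the complete BGZF stream, sentinel-terminated.
#' @export
bgzf_compress <- function(payload, level = 6L, workers = 1L) {
  stopifnot(is.raw(payload))
  n <- length(payload)
  if (n == 0L) return(bgzf_encode_block(raw(0), level))
  starts <- seq.int(1L, n, by = BGZF_MAX_PAYLOAD)
  pieces <- lapply(starts, function(s) {
    payload[s:min(n, s + BGZF_MAX_PAYLOAD - 1L)]
  })
  blocks <- if (workers > 1L) {
    parallel::mclapply(pieces, bgzf_encode_block, level = level,
                       mc.cores = workers)
  } else {
    lapply(pieces, bgzf_encode_block, level = level)
  }
  c(unlist(blocks), bgzf_encode_block(raw(0), level))
}

# Scan a BGZF stream without inflating: hop header to header using BSIZE and
# read ISIZE from each footer. Returns per-block coffset (0-based file
# offset), bsize, isize and ustart (0-based offset of the block's payload in
# the concatenated uncompressed stream). The terminal sentinel block is
# excluded from the table; its absence triggers a warning, not an error.
bgzf_block_table <- function(stream) {
  stopifnot(is.raw(stream))
  coffs <- numeric(0)
  bsizes <- integer(0)
  isizes <- numeric(0)
  off <- 0
  n <- length(stream)
  saw_sentinel <- FALSE
  while (off < n) {
    if (n - off < BGZF_HEADER_LEN) {
      bamkit_stop("truncated BGZF stream mid-header", "bamkit_truncation_error")
    }
    if (stream[off + 1L] != as.raw(0x1f) || stream[off + 2L] != as.raw(0x8b)) {
      bamkit_stop("not a BGZF stream: gzip magic missing", "bamkit_format_error")
    }
    xlen <- read_u16(stream, off + 11L)
    bsize <- NA_integer_
    p <- off + 13L
    xend <- off + 13L + xlen
    while (p + 3L <= xend) {
      slen <- read_u16(stream, p + 2L)
      if (stream[p] == as.raw(0x42) && stream[p + 1L] == as.raw(0x43) &&
          slen == 2L) {
        bsize <- read_u16(stream, p + 4L) + 1L
        break
      }
      p <- p + 4L + slen
    }
    if (is.na(bsize)) {
      bamkit_stop("not a BGZF block: BC subfield missing", "bamkit_format_error")
    }
    if (off + bsize > n) {
      bamkit_stop("truncated BGZF stream: incomplete block", "bamkit_truncation_error")
    }
    isize <- read_u32(stream, off + bsize - 3L)
    if (isize == 0 && off + bsize == n) {
      saw_sentinel <- TRUE
    } else if (isize > 0) {
      coffs <- c(coffs, off)
      bsizes <- c(bsizes, bsize)
      isizes <- c(isizes, isize)
    }
    off <- off + bsize
  }
  if (!saw_sentinel) {
    warning("BGZF stream lacks the end-of-file sentinel block; ",
            "treating it as complete", call. = FALSE)
  }
  ustart <- if (length(isizes)) cumsum(c(0, isizes[-length(isizes)])) else numeric(0)
  data.frame(coffset = coffs, bsize = bsizes, isize = isizes, ustart = ustart)
}

# Inflate every data block of a BGZF stream. Returns the concatenated
# payload and the block table (for uncompressed-offset -> virtual-offset
# mapping).
bgzf_inflate_all <- function(stream) {
  tbl <- bgzf_block_table(stream)
  parts <- lapply(seq_len(nrow(tbl)), function(i) {
    bgzf_decode_block(stream, tbl$coffset[i] + 1L)$payload
  })
  list(data = if (length(parts)) unlist(parts) else raw(0), blocks = tbl)
}

# Map 0-based uncompressed offsets to packed virtual offsets using a block
# table. An offset at the exact end of a block maps into the next block at
# uoffset 0 (the convention BAI chunk bounds use); the stream-end offset maps
# to (coffset of end-of-data, 0).
uoffset_to_voffset <- function(u, tbl) {
  if (nrow(tbl) == 0L) return(rep(0, length(u)))
  uend <- tbl$ustart[nrow(tbl)] + tbl$isize[nrow(tbl)]
  idx <- findInterval(u, c(tbl$ustart, uend), rightmost.closed = FALSE)
  past <- idx > nrow(tbl)   # offsets at/after end of data
  idx[past] <- nrow(tbl)
  co <- tbl$coffset[idx]
  uo <- u - tbl$ustart[idx]
  at_block_end <- uo == tbl$isize[idx]
  co[at_block_end] <- tbl$coffset[idx[at_block_end]] + tbl$bsize[idx[at_block_end]]
  uo[at_block_end] <- 0
  pack_voffset(co, uo)
}

#' Open a BGZF file for random-access reading
#'
#' Returns a lightweight reader over a BGZF file. [bgzf_seek()] positions it
#' at a packed virtual offset and [bgzf_read()] then returns uncompressed
#' octets from that point, transparently crossing block boundaries; blocks
#' are inflated on demand and cached.
#'
#' @param path path to a BGZF-compressed file.
#' @return an opaque reader object.
#' @export
bgzf_open <- function(path) {
  stream <- readBin(path, "raw", n = file.size(path))
  tbl <- bgzf_block_table(stream)
  env <- new.env(parent = emptyenv())
  env$stream <- stream
  env$tbl <- tbl
  env$cache <- vector("list", nrow(tbl))
  env$block <- if (nrow(tbl)) 1L else 0L   # current block row; 0 = EOF
  env$uo <- 0
  class(env) <- "bgzf_reader"
  env
}

bgzf_get_block <- function(rdr, i) {
  if (is.null(rdr$cache[[i]])) {
    rdr$cache[[i]] <- bgzf_decode_block(rdr$stream, rdr$tbl$coffset[i] + 1L)$payload
  }
  rdr$cache[[i]]
}

#' @rdname bgzf_open
#' @param rdr a reader from [bgzf_open()].
#' @param voffset packed virtual offset to position at.
#' @export
bgzf_seek <- function(rdr, voffset) {
  vo <- unpack_voffset(voffset)
  i <- match(vo$coffset, rdr$tbl$coffset)
  if (is.na(i)) {
    # seeking to end-of-data (coffset of the sentinel) is legal
    last <- nrow(rdr$tbl)
    if (last > 0L && vo$coffset == rdr$tbl$coffset[last] + rdr$tbl$bsize[last] &&
        vo$uoffset == 0) {
      rdr$block <- 0L
      rdr$uo <- 0
      return(invisible(rdr))
    }
    bamkit_stop("virtual offset does not address a block start",
                "bamkit_range_error")
  }
  if (vo$uoffset > rdr$tbl$isize[i]) {
    bamkit_stop("uoffset beyond block payload", "bamkit_range_error")
  }
  rdr$block <- i
  rdr$uo <- vo$uoffset
  invisible(rdr)
}

#' @rdname bgzf_open
#' @param n number of uncompressed octets to read; fewer are returned at
#'   end of stream.
#' @export
bgzf_read <- function(rdr, n) {
  out <- list()
  got <- 0
  while (got < n && rdr$block != 0L) {
    pay <- bgzf_get_block(rdr, rdr$block)
    avail <- length(pay) - rdr$uo
    take <- min(avail, n - got)
    if (take > 0) {
      out[[length(out) + 1L]] <- pay[rdr$uo + seq_len(take)]
      rdr$uo <- rdr$uo + take
      got <- got + take
    }
    if (rdr$uo >= length(pay)) {
      rdr$block <- if (rdr$block < nrow(rdr$tbl)) rdr$block + 1L else 0L
      rdr$uo <- 0
    }
  }
  if (length(out)) unlist(out) else raw(0)
}

# current position of a reader as a packed virtual offset
bgzf_tell <- function(rdr) {
  if (rdr$block == 0L) {
    last <- nrow(rdr$tbl)
    if (last == 0L) return(0)
    return(pack_voffset(rdr$tbl$coffset[last] + rdr$tbl$bsize[last], 0))
  }
  pack_voffset(rdr$tbl$coffset[rdr$block], rdr$uo)
}
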