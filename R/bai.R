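# BAI: the hierarchical binning index over coordinate-sorted BAM. Six bin
# levels tile the 0..2^29 coordinate space (level sizes 2^29 down to 2^14,
# level offsets 0, 1, 9, 73, 585, 4681; 37449 bins, ids 0..37448); each occupied
# bin holds merged chunks of virtual offsets, and a 16 kb-granularity linear
# index stores, per window, the smallest virtual offset of any record
# overlapping it. Bin 37450 is the conventional metadata pseudo-bin
# (mapped/unmapped counts and the record span); it is written, tolerated on
# read, and never used in queries.

BAI_MAGIC <- as.raw(c(0x42, 0x41, 0x49, 0x01))
BIN_LEVEL_OFFSETS <- c(0L, 1L, 9L, 73L, 585L, 4681L)
BIN_LEVEL_SHIFTS <- c(29L, 26L, 23L, 20L, 17L, 14L)
PSEUDO_BIN <- 37450L
LINEAR_SHIFT <- 14L   # 16384-base windows

check_region0 <- function(beg0, end0) {
  if (any(beg0 < 0 | end0 > 2^29 | beg0 >= end0)) {
    bamkit_stop("require 0 <= beg0 < end0 <= 2^29", "bamkit_range_error")
  }
}

#' Smallest bin fully containing a zero-based half-open interval
#'
#' @param beg0,end0 0-based half-open interval, `0 <= beg0 < end0 <= 2^29`.
#' @return integer bin id(s) in 0..37448. Vectorized over parallel
#'   `beg0`/`end0`.
#' @examples
#' reg2bin(0, 16384)   # 4681, the first level-5 bin
#' @export
reg2bin <- function(beg0, end0) {
  check_region0(beg0, end0)
  b <- as.numeric(beg0)
  e <- as.numeric(end0) - 1
  out <- integer(length(b))
  done <- rep(FALSE, length(b))
  for (lvl in 6:2) {
    sh <- 2^BIN_LEVEL_SHIFTS[lvl]
    hit <- !done & (b %/% sh == e %/% sh)
    out[hit] <- BIN_LEVEL_OFFSETS[lvl] + as.integer(b[hit] %/% sh)
    done <- done | hit
  }
  out[!done] <- 0L
  out
}

#' All bins overlapping a zero-based half-open interval
#'
#' @inheritParams reg2bin
#' @return ascending integer vector of every bin id (across all 6 levels)
#'   whose interval overlaps `[beg0, end0)`.
#' @export
reg2bins <- function(beg0, end0) {
  stopifnot(length(beg0) == 1L, length(end0) == 1L)
  check_region0(beg0, end0)
  b <- as.numeric(beg0)
  e <- as.numeric(end0) - 1
  out <- 0L
  for (lvl in 2:6) {
    sh <- 2^BIN_LEVEL_SHIFTS[lvl]
    out <- c(out, seq.int(BIN_LEVEL_OFFSETS[lvl] + b %/% sh,
                          BIN_LEVEL_OFFSETS[lvl] + e %/% sh))
  }
  as.integer(out)
}

# merge sorted-by-beg chunks whose voffset ranges touch or overlap
merge_chunks <- function(m) {
  if (nrow(m) <= 1L) return(m)
  m <- m[order(m[, 1L], m[, 2L]), , drop = FALSE]
  beg <- m[, 1L]
  end <- m[, 2L]
  keep_beg <- beg[1]
  out <- list()
  cur_b <- beg[1]
  cur_e <- end[1]
  for (i in seq_len(nrow(m))[-1]) {
    if (beg[i] <= cur_e) {
      cur_e <- max(cur_e, end[i])
    } else {
      out[[length(out) + 1L]] <- c(cur_b, cur_e)
      cur_b <- beg[i]
      cur_e <- end[i]
    }
  }
  out[[length(out) + 1L]] <- c(cur_b, cur_e)
  matrix(unlist(out), ncol = 2L, byrow = TRUE,
         dimnames = list(NULL, c("beg", "end")))
}

empty_ref_index <- function() {
  list(bins = stats::setNames(list(), character(0)),
       linear = numeric(0),
       n_mapped = 0, n_unmapped = 0,
       off_beg = NA_real_, off_end = NA_real_)
}

# build the per-reference structure from that reference's records
build_ref_index <- function(pos0, span, voff, voff_end, unmapped_flag) {
  ref <- empty_ref_index()
  if (length(pos0) == 0L) return(ref)
  end0 <- pos0 + pmax(span, 1)
  bins <- reg2bin(pos0, end0)
  ord <- order(bins)
  groups <- split(seq_along(bins)[ord], bins[ord])
  ref$bins <- lapply(groups, function(ix) {
    merge_chunks(cbind(beg = voff[ix], end = voff_end[ix]))
  })
  n_win <- max(end0 - 1) %/% 2^LINEAR_SHIFT + 1
  lin <- rep(0, n_win)
  for (i in seq_along(pos0)) {
    w <- (pos0[i] %/% 2^LINEAR_SHIFT):((end0[i] - 1) %/% 2^LINEAR_SHIFT) + 1
    upd <- lin[w] == 0 | lin[w] > voff[i]
    lin[w[upd]] <- voff[i]
  }
  # forward-fill empty interior windows so entries are non-decreasing
  for (i in seq_along(lin)[-1]) if (lin[i] == 0) lin[i] <- lin[i - 1]
  ref$linear <- lin
  ref$n_mapped <- as.numeric(sum(!unmapped_flag))
  ref$n_unmapped <- as.numeric(sum(unmapped_flag))
  ref$off_beg <- min(voff)
  ref$off_end <- max(voff_end)
  ref
}

#' Build a BAI index for a coordinate-sorted BAM file
#'
#' Performs one pass over the records; each placed record contributes the
#' chunk `[its start virtual offset, the next record's start virtual offset)`
#' to the bin containing its reference span and updates the linear-index
#' windows it overlaps. Per-reference work may run across forked workers;
#' references are assembled in reference-id order, so the result is the same
#' for every worker count.
#'
#' @param bam_path path to a coordinate-sorted BAM file.
#' @param workers number of worker processes.
#' @return an object of class `bai_index`.
#' @export
build_index <- function(bam_path, workers = 1L) {
  rdr <- bam_open(bam_path)
  refs <- header_references(rdr$header)
  n_ref <- nrow(refs)
  cols <- list()
  repeat {
    ch <- rdr$read(2e4L)
    if (nrow(ch) == 0L) break
    cols[[length(cols) + 1L]] <- data.frame(
      refid = rname_to_refid(ch$rname, refs),
      pos0 = ch$pos - 1L,
      span = cigar_ref_span(ch$cigar),
      unmapped = flag_has(ch$flag, 4L),
      voff = ch$voffset, voff_end = ch$voffset_end,
      stringsAsFactors = FALSE)
  }
  rec <- if (length(cols)) do.call(rbind, cols) else
    data.frame(refid = integer(0), pos0 = integer(0), span = numeric(0),
               unmapped = logical(0), voff = numeric(0), voff_end = numeric(0))
  check_sorted(rec$refid, rec$pos0)
  placed <- rec$refid >= 0L
  n_no_coor <- as.numeric(sum(!placed))
  rec <- rec[placed, , drop = FALSE]
  build_one <- function(id) {
    ix <- which(rec$refid == id)
    build_ref_index(rec$pos0[ix], rec$span[ix], rec$voff[ix],
                    rec$voff_end[ix], rec$unmapped[ix])
  }
  ids <- seq_len(n_ref) - 1L
  per_ref <- if (workers > 1L && n_ref > 1L) {
    parallel::mclapply(ids, build_one, mc.cores = workers)
  } else {
    lapply(ids, build_one)
  }
  structure(list(n_ref = n_ref, refs = per_ref, n_no_coor = n_no_coor),
            class = "bai_index")
}

# coordinate-sortedness: each reference id forms one contiguous run (placed
# runs before the unplaced tail) and positions never decrease within a run
check_sorted <- function(refid, pos0) {
  if (length(refid) <= 1L) return(invisible())
  prev_ref <- refid[-length(refid)]
  cur_ref <- refid[-1L]
  bad_pos <- which(prev_ref == cur_ref & pos0[-1L] < pos0[-length(pos0)])
  if (length(bad_pos)) {
    bamkit_stop(sprintf("BAM not coordinate-sorted: position decreases at record %d",
                        bad_pos[1] + 1L), "bamkit_sort_error")
  }
  runs <- rle(refid)$values
  if (anyDuplicated(runs[runs >= 0L])) {
    dup <- runs[runs >= 0L][duplicated(runs[runs >= 0L])][1]
    at <- which(refid == dup)
    gap <- at[which(diff(at) > 1L)[1] + 1L]
    bamkit_stop(sprintf("BAM not coordinate-sorted: reference id %d reappears at record %d",
                        dup, gap), "bamkit_sort_error")
  }
  invisible()
}

#' @export
print.bai_index <- function(x, ...) {
  cat(sprintf("BAI index: %d reference(s), %d unplaced record(s)\n",
              x$n_ref, x$n_no_coor))
  for (i in seq_len(x$n_ref)) {
    r <- x$refs[[i]]
    cat(sprintf("  ref %d: %d bin(s), %d linear window(s), %d mapped, %d unmapped\n",
                i - 1L, length(r$bins), length(r$linear),
                r$n_mapped, r$n_unmapped))
  }
  invisible(x)
}

#' Write / read a BAI index file
#'
#' On-disk layout: magic "BAI\1", n_ref, then per reference n_bin followed by
#' (bin id, n_chunk, chunk voffset pairs) and n_intv followed by the linear
#' offsets; all little-endian. The metadata pseudo-bin 37450 is emitted for
#' every reference holding records; the trailing unplaced-record count is
#' emitted only when non-zero. `read_bai(write_bai(x))` reproduces `x`.
#'
#' @param index a `bai_index`.
#' @param path file path (conventionally the BAM path plus ".bai").
#' @return `write_bai`: invisibly, the path; `read_bai`: a `bai_index`.
#' @export
write_bai <- function(index, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(BAI_MAGIC, con)
  writeBin(i32_raw(index$n_ref), con)
  for (ref in index$refs) {
    has_data <- length(ref$bins) > 0L || ref$n_mapped > 0 || ref$n_unmapped > 0
    ids <- as.integer(names(ref$bins))
    ord <- order(ids)
    writeBin(i32_raw(length(ref$bins) + as.integer(has_data)), con)
    for (k in ord) {
      m <- ref$bins[[k]]
      writeBin(i32_raw(ids[k]), con)
      writeBin(i32_raw(nrow(m)), con)
      for (i in seq_len(nrow(m))) {
        writeBin(u64d_raw(m[i, 1L]), con)
        writeBin(u64d_raw(m[i, 2L]), con)
      }
    }
    if (has_data) {
      writeBin(i32_raw(PSEUDO_BIN), con)
      writeBin(i32_raw(2L), con)
      writeBin(u64d_raw(ref$off_beg %||% 0), con)
      writeBin(u64d_raw(ref$off_end %||% 0), con)
      writeBin(u64d_raw(ref$n_mapped), con)
      writeBin(u64d_raw(ref$n_unmapped), con)
    }
    writeBin(i32_raw(length(ref$linear)), con)
    if (length(ref$linear)) writeBin(u64d_raw(ref$linear), con)
  }
  if (index$n_no_coor > 0) writeBin(u64d_raw(index$n_no_coor), con)
  invisible(path)
}

#' @rdname write_bai
#' @export
read_bai <- function(path) {
  r <- readBin(path, "raw", n = file.size(path))
  if (length(r) < 8L || !identical(r[1:4], BAI_MAGIC)) {
    bamkit_stop("not a BAI file: magic \"BAI\\1\" missing", "bamkit_format_error")
  }
  n_ref <- as.integer(read_i32(r, 5L))
  p <- 9L
  refs <- vector("list", n_ref)
  for (i in seq_len(n_ref)) {
    ref <- empty_ref_index()
    n_bin <- read_i32(r, p); p <- p + 4L
    bins <- stats::setNames(list(), character(0))
    for (b in seq_len(n_bin)) {
      bin_id <- read_u32(r, p)
      n_chunk <- read_i32(r, p + 4L)
      p <- p + 8L
      m <- matrix(read_u64d(r, p + 8 * (seq_len(2L * n_chunk) - 1L)),
                  ncol = 2L, byrow = TRUE, dimnames = list(NULL, c("beg", "end")))
      p <- p + 16L * n_chunk
      if (bin_id == PSEUDO_BIN) {
        if (n_chunk >= 2L) {
          ref$off_beg <- unname(m[1L, 1L])
          ref$off_end <- unname(m[1L, 2L])
          ref$n_mapped <- unname(m[2L, 1L])
          ref$n_unmapped <- unname(m[2L, 2L])
        }
      } else {
        bins[[as.character(bin_id)]] <- m
      }
    }
    ref$bins <- bins
    n_intv <- read_i32(r, p); p <- p + 4L
    if (n_intv > 0L) {
      ref$linear <- read_u64d(r, p + 8 * (seq_len(n_intv) - 1L))
      p <- p + 8L * n_intv
    }
    refs[[i]] <- ref
  }
  n_no_coor <- if (p + 7L <= length(r)) read_u64d(r, p) else 0
  structure(list(n_ref = n_ref, refs = refs, n_no_coor = n_no_coor),
            class = "bai_index")
}

#' Resolve a region to the BAI chunks that may contain overlapping records
#'
#' Unions the chunk lists of every bin overlapping the region, prunes chunks
#' wholly before the linear-index lower bound for the region's first 16 kb
#' window, and returns the merged, sorted chunk set.
#'
#' @param index a `bai_index`.
#' @param refid 0-based reference id.
#' @param beg0,end0 0-based half-open query interval.
#' @return two-column matrix (`beg`, `end`) of packed virtual offsets,
#'   possibly with zero rows.
#' @export
query_chunks <- function(index, refid, beg0, end0) {
  if (refid < 0 || refid >= index$n_ref) {
    bamkit_stop(sprintf("reference id %d not in index (0..%d)",
                        refid, index$n_ref - 1L), "bamkit_lookup_error")
  }
  ref <- index$refs[[refid + 1L]]
  none <- matrix(numeric(0), ncol = 2L, dimnames = list(NULL, c("beg", "end")))
  if (length(ref$bins) == 0L) return(none)
  cand <- intersect(as.character(reg2bins(beg0, end0)), names(ref$bins))
  if (length(cand) == 0L) return(none)
  m <- do.call(rbind, ref$bins[cand])
  win <- beg0 %/% 2^LINEAR_SHIFT + 1
  if (length(ref$linear)) {
    min_off <- ref$linear[min(win, length(ref$linear))]
    m <- m[m[, 2L] > min_off, , drop = FALSE]
  }
  if (nrow(m) == 0L) return(none)
  merge_chunks(m)
}

# parse "name:start-end" (1-based inclusive; commas tolerated in numbers)
parse_region <- function(region) {
  if (is.list(region)) {
    return(list(rname = region[[1]], start1 = as.numeric(region[[2]]),
                end1 = as.numeric(region[[3]])))
  }
  m <- regmatches(region, regexec("^(.+):([0-9,]+)-([0-9,]+)$", region))[[1]]
  if (length(m) != 4L) {
    bamkit_stop(sprintf("cannot parse region '%s' (want name:start-end)", region),
                "bamkit_parse_error")
  }
  list(rname = m[2],
       start1 = as.numeric(gsub(",", "", m[3], fixed = TRUE)),
       end1 = as.numeric(gsub(",", "", m[4], fixed = TRUE)))
}

# sequential range reads over the uncompressed stream of a BGZF file,
# inflating blocks on demand with caching
ustream_open <- function(stream) {
  tbl <- bgzf_block_table(stream)
  env <- new.env(parent = emptyenv())
  env$stream <- stream
  env$tbl <- tbl
  env$cache <- vector("list", nrow(tbl))
  env$usize <- if (nrow(tbl)) tbl$ustart[nrow(tbl)] + tbl$isize[nrow(tbl)] else 0
  env
}

ustream_read <- function(us, u, len) {
  if (len <= 0) return(raw(0))
  if (u + len > us$usize) {
    bamkit_stop("read past end of BGZF data", "bamkit_truncation_error")
  }
  first <- findInterval(u, us$tbl$ustart)
  out <- list()
  got <- 0
  i <- first
  while (got < len) {
    if (is.null(us$cache[[i]])) {
      us$cache[[i]] <- bgzf_decode_block(us$stream, us$tbl$coffset[i] + 1L)$payload
    }
    pay <- us$cache[[i]]
    from <- if (i == first) u - us$tbl$ustart[i] else 0
    take <- min(length(pay) - from, len - got)
    out[[length(out) + 1L]] <- pay[from + seq_len(take)]
    got <- got + take
    i <- i + 1L
  }
  unlist(out)
}

voffset_to_uoffset <- function(v, tbl) {
  vo <- unpack_voffset(v)
  i <- match(vo$coffset, tbl$coffset)
  if (anyNA(i)) {
    # chunk ends may point at the sentinel (end of data)
    last <- nrow(tbl)
    end_co <- if (last) tbl$coffset[last] + tbl$bsize[last] else 0
    i[is.na(i) & vo$coffset == end_co] <- last + 1L
    if (anyNA(i)) {
      bamkit_stop("virtual offset does not address a block", "bamkit_range_error")
    }
  }
  ustart <- c(tbl$ustart, if (nrow(tbl)) tbl$ustart[nrow(tbl)] + tbl$isize[nrow(tbl)] else 0)
  ustart[i] + vo$uoffset
}

#' Read the alignments overlapping a region from an indexed BAM file
#'
#' With an index, only the BGZF blocks addressed by the region's chunks are
#' inflated; without one, the whole file is scanned. Either way the result
#' is exactly the records whose reference span (CIGAR-derived; length 1 for
#' placed records without a CIGAR) overlaps the 1-based inclusive region.
#'
#' @param path BAM file path.
#' @param region a "name:start-end" string or list(rname, start1, end1).
#' @param index a `bai_index`, or NULL for a linear scan.
#' @return alignment data.frame of the overlapping records, in file order.
#' @export
read_bam_region <- function(path, region, index = NULL) {
  bam_region_reader(path)$query(region, index)
}

#' Open a BAM file for repeated region queries
#'
#' Keeps the block table, header and an inflated-block cache alive across
#' queries, so querying many regions of one file inflates each BGZF block at
#' most once.
#'
#' @param path BAM file path.
#' @return list with `header` and `query(region, index = NULL)`; `query`
#'   behaves exactly like [read_bam_region()].
#' @export
bam_region_reader <- function(path) {
  stream <- readBin(path, "raw", n = file.size(path))
  us <- ustream_open(stream)
  hd_raw <- ustream_read(us, 0, min(us$usize, 65536 * 4))
  hd <- tryCatch(decode_bam_header(hd_raw), error = function(e) {
    if (inherits(e, "bamkit_format_error")) stop(e)
    decode_bam_header(ustream_read(us, 0, us$usize))
  })
  rec_u0 <- hd$next_offset - 1            # first record's uncompressed offset
  scan_cache <- new.env(parent = emptyenv())
  scan_all <- function() {
    if (is.null(scan_cache$df)) {
      recs <- list()
      u <- rec_u0
      while (u < us$usize) {
        sz <- read_i32(ustream_read(us, u, 4L), 1L)
        recs[[length(recs) + 1L]] <-
          decode_bam_record(ustream_read(us, u + 4L, sz), 1L, sz, hd$ref_names)
        u <- u + 4L + sz
      }
      scan_cache$df <- finish_records(recs)
    }
    scan_cache$df
  }
  list(
    header = hd$header,
    query = function(region, index = NULL) {
      reg <- parse_region(region)
      refid <- match(reg$rname, hd$ref_names) - 1L
      if (is.na(refid)) {
        bamkit_stop(sprintf("reference '%s' not in BAM header", reg$rname),
                    "bamkit_lookup_error")
      }
      if (is.null(index)) {
        return(overlap_filter(scan_all(), reg))
      }
      chunks <- query_chunks(index, refid, reg$start1 - 1, reg$end1)
      recs <- list()
      for (ci in seq_len(nrow(chunks))) {
        u <- voffset_to_uoffset(chunks[ci, 1L], us$tbl)
        u_end <- voffset_to_uoffset(chunks[ci, 2L], us$tbl)
        while (u < u_end) {
          sz <- read_i32(ustream_read(us, u, 4L), 1L)
          recs[[length(recs) + 1L]] <-
            decode_bam_record(ustream_read(us, u + 4L, sz), 1L, sz, hd$ref_names)
          u <- u + 4L + sz
        }
      }
      overlap_filter(finish_records(recs), reg)
    })
}

finish_records <- function(recs) {
  for (i in seq_along(recs)) { recs[[i]]$u <- 0; recs[[i]]$u_end <- 0 }
  df <- records_to_df(recs)
  df$u <- NULL
  df$u_end <- NULL
  df
}

# records whose reference span overlaps the 1-based inclusive region
overlap_filter <- function(alignments, reg) {
  if (nrow(alignments) == 0L) return(alignments)
  placed <- alignments$rname == reg$rname & alignments$pos >= 1L
  span <- pmax(cigar_ref_span(alignments$cigar), 1)
  keep <- placed & alignments$pos <= reg$end1 &
    (alignments$pos + span - 1) >= reg$start1
  out <- alignments[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Index a BAM file and write the conventional .bai beside it
#'
#' @param bam_path path to a coordinate-sorted BAM file.
#' @param bai_path output path; defaults to `<bam_path>.bai`.
#' @param workers number of worker processes.
#' @return invisibly, the `bai_index`.
#' @export
index_bam <- function(bam_path, bai_path = paste0(bam_path, ".bai"),
                      workers = 1L) {
  idx <- build_index(bam_path, workers = workers)
  write_bai(idx, bai_path)
  invisible(idx)
}
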