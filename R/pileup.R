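# Pileup: per-reference-position accounting of the reads covering that
# position, and the samtools-style mpileup text rendering. Reads failing
# the filter mask (default: unmapped 0x4, secondary 0x100, QC-fail 0x200,
# duplicate 0x400) are excluded. Deleted positions ('*') count toward
# depth; N-skipped positions do not. No base-quality floor and no BAQ.

DEFAULT_FILTER_MASK <- 0x704L

region_span <- function(reg) {
  if (reg$start1 > reg$end1 || reg$start1 < 1) {
    bamkit_stop(sprintf("bad region %s:%d-%d", reg$rname, reg$start1, reg$end1),
                "bamkit_range_error")
  }
  reg$end1 - reg$start1 + 1
}

filter_records <- function(alignments, filter_mask) {
  keep <- bitwAnd(alignments$flag, filter_mask) == 0L & alignments$pos >= 1L &
    alignments$cigar != "*"
  alignments[keep, , drop = FALSE]
}

#' Simple pileup: per-position read depth over a region
#'
#' Depth at a position counts the filter-passing reads whose CIGAR consumes
#' the reference there via M, D, = or X (N-skipped stretches are not
#' covered). Every position of the region is reported, zeros included.
#'
#' @param bam_path coordinate-sorted BAM path.
#' @param region "name:start-end" (1-based inclusive) or
#'   list(rname, start1, end1).
#' @param index a `bai_index` for random access, or NULL for a linear scan
#'   (the result is identical either way).
#' @param filter_mask flag bits that exclude a read; default drops unmapped,
#'   secondary, QC-fail and duplicate reads.
#' @return data.frame with `pos` and `depth`, one row per region position.
#' @export
simple_pileup <- function(bam_path, region, index = NULL,
                          filter_mask = DEFAULT_FILTER_MASK) {
  reg <- parse_region(region)
  width <- region_span(reg)
  recs <- filter_records(read_bam_region(bam_path, reg, index), filter_mask)
  delta <- numeric(width + 1L)
  for (i in seq_len(nrow(recs))) {
    for (seg in covered_segments(recs$pos[i], recs$cigar[i])) {
      a <- max(seg[1], reg$start1) - reg$start1 + 1
      b <- min(seg[2], reg$end1) - reg$start1 + 1
      if (a <= b) {
        delta[a] <- delta[a] + 1
        delta[b + 1L] <- delta[b + 1L] - 1
      }
    }
  }
  data.frame(pos = as.integer(seq.int(reg$start1, reg$end1)),
             depth = as.integer(cumsum(delta[seq_len(width)])))
}

# maximal runs of reference positions covered by M/D/=/X, as a list of
# c(start1, end1); N splits runs, I/S/H/P are invisible here
covered_segments <- function(pos, cigar) {
  ops <- parse_cigar(cigar)
  segs <- list()
  rpos <- pos
  run_start <- NA
  for (i in seq_len(nrow(ops))) {
    op <- ops$op[i]
    len <- ops$length[i]
    if (op %in% c("M", "D", "=", "X")) {
      if (is.na(run_start)) run_start <- rpos
      rpos <- rpos + len
    } else if (op == "N") {
      if (!is.na(run_start)) {
        segs[[length(segs) + 1L]] <- c(run_start, rpos - 1)
        run_start <- NA
      }
      rpos <- rpos + len
    }
    # I, S, H, P: no reference movement
  }
  if (!is.na(run_start)) segs[[length(segs) + 1L]] <- c(run_start, rpos - 1)
  segs
}

# per-read mpileup events: for every covered reference position a token
# (".", ",", base letter, or "*"), an optional quality char, with ^/$
# markers and +/- indel annotations already attached
read_events <- function(pos, cigar, seq, qual, flag, mapq, ref_seq, ref_at) {
  ops <- parse_cigar(cigar)
  rev_strand <- bitwAnd(flag, 16L) != 0L
  has_seq <- seq != "*"
  bases <- if (has_seq) strsplit(seq, "")[[1]] else character(0)
  qchars <- if (qual != "*") strsplit(qual, "")[[1]] else NULL
  n_ops <- nrow(ops)
  ev_pos <- numeric(0)
  ev_tok <- character(0)
  ev_qual <- character(0)
  rpos <- pos
  qpos <- 1L
  casefn <- if (rev_strand) tolower else toupper
  ref_base_at <- function(p) {
    if (is.null(ref_seq)) return(NA_character_)
    k <- p - ref_at + 1
    if (k < 1 || k > nchar(ref_seq)) NA_character_ else substr(ref_seq, k, k)
  }
  for (i in seq_len(n_ops)) {
    op <- ops$op[i]
    len <- ops$length[i]
    if (op %in% c("M", "=", "X")) {
      for (k in seq_len(len)) {
        b <- if (has_seq) bases[qpos + k - 1L] else "N"
        rb <- ref_base_at(rpos + k - 1L)
        tok <- if (!is.na(rb) && toupper(b) == toupper(rb)) {
          if (rev_strand) "," else "."
        } else {
          casefn(b)
        }
        ev_pos <- c(ev_pos, rpos + k - 1)
        ev_tok <- c(ev_tok, tok)
        ev_qual <- c(ev_qual,
                     if (!is.null(qchars)) qchars[qpos + k - 1L] else "~")
      }
      rpos <- rpos + len
      qpos <- qpos + len
    } else if (op == "D") {
      # annotate the preceding emitted token, then '*' per deleted position
      del_ref <- vapply(seq_len(len), function(k) {
        rb <- ref_base_at(rpos + k - 1)
        if (is.na(rb)) "N" else rb
      }, "")
      if (length(ev_tok)) {
        ev_tok[length(ev_tok)] <- paste0(
          ev_tok[length(ev_tok)], "-", len, casefn(paste(del_ref, collapse = "")))
      }
      ev_pos <- c(ev_pos, rpos + seq_len(len) - 1)
      ev_tok <- c(ev_tok, rep("*", len))
      ev_qual <- c(ev_qual, rep(NA_character_, len))
      rpos <- rpos + len
    } else if (op == "I") {
      ins <- if (has_seq) paste(bases[qpos + seq_len(len) - 1L], collapse = "")
             else strrep("N", len)
      if (length(ev_tok)) {
        ev_tok[length(ev_tok)] <- paste0(ev_tok[length(ev_tok)], "+", len,
                                         casefn(ins))
      }
      qpos <- qpos + len
    } else if (op == "N") {
      rpos <- rpos + len
    } else if (op == "S") {
      qpos <- qpos + len
    }
    # H, P: nothing moves
  }
  if (length(ev_tok)) {
    ev_tok[1] <- paste0("^", rawToChar(as.raw(min(mapq, 93L) + 33L)), ev_tok[1])
    ev_tok[length(ev_tok)] <- paste0(ev_tok[length(ev_tok)], "$")
  }
  list(pos = ev_pos, tok = ev_tok, qual = ev_qual)
}

#' samtools-style mpileup over a region
#'
#' Emits one column per covered reference position with the usual token
#' alphabet: '.'/',' for matches on the forward/reverse strand, upper/lower
#' case letters for mismatches, '*' for a deleted position, `+n<seq>` /
#' `-n<seq>` indel annotations attached to the preceding position, `^` plus
#' the mapping-quality character at a read's first position and `$` at its
#' last. Without a FASTA the reference base is reported as 'N' and every
#' aligned base as its letter. Qualities are emitted for non-deletion
#' tokens. Zero-coverage positions are omitted unless `all_positions`.
#'
#' @inheritParams simple_pileup
#' @param fasta_path optional reference FASTA (a .fai beside it is used if
#'   present, else built on the fly).
#' @param region NULL processes every reference whole.
#' @param all_positions emit zero-depth positions too (with `*` placeholders).
#' @return data.frame with `rname`, `pos`, `ref`, `depth`, `bases`, `quals`.
#' @export
mpileup <- function(bam_path, fasta_path = NULL, region = NULL, index = NULL,
                    filter_mask = DEFAULT_FILTER_MASK, all_positions = FALSE) {
  if (is.null(region)) {
    hdr <- alignment_open(bam_path)$header
    refs <- header_references(hdr)
    out <- lapply(seq_len(nrow(refs)), function(i) {
      mpileup(bam_path, fasta_path,
              list(refs$name[i], 1, refs$length[i]), index,
              filter_mask, all_positions)
    })
    return(do.call(rbind, out))
  }
  reg <- parse_region(region)
  region_span(reg)
  ref_seq <- NULL
  if (!is.null(fasta_path)) {
    fai_path <- paste0(fasta_path, ".fai")
    fai <- if (file.exists(fai_path)) read_fai(fai_path) else build_fai(fasta_path)
    if (!(reg$rname %in% fai$name)) {
      bamkit_stop(sprintf("reference '%s' absent from FASTA", reg$rname),
                  "bamkit_lookup_error")
    }
    # fetch a margin past the region end so deletion annotations near the
    # boundary see their reference bases
    fend <- min(reg$end1 + 1000, fai$length[fai$name == reg$rname])
    ref_seq <- fetch_region(fasta_path, fai,
                            list(reg$rname, reg$start1, max(fend, reg$start1)))
  }
  recs <- filter_records(read_bam_region(bam_path, reg, index), filter_mask)
  evs <- lapply(seq_len(nrow(recs)), function(i) {
    read_events(recs$pos[i], recs$cigar[i], recs$seq[i], recs$qual[i],
                recs$flag[i], recs$mapq[i], ref_seq, reg$start1)
  })
  pos <- unlist(lapply(evs, `[[`, "pos"))
  tok <- unlist(lapply(evs, `[[`, "tok"))
  qual <- unlist(lapply(evs, `[[`, "qual"))
  inside <- which(pos >= reg$start1 & pos <= reg$end1)
  pos <- pos[inside]; tok <- tok[inside]; qual <- qual[inside]
  ref_base <- function(p) {
    if (is.null(ref_seq)) rep("N", length(p))
    else toupper(substring(ref_seq, p - reg$start1 + 1, p - reg$start1 + 1))
  }
  if (length(pos)) {
    o <- order(pos, method = "radix")    # stable: keeps read order in ties
    pos <- pos[o]; tok <- tok[o]; qual <- qual[o]
    f <- factor(pos, levels = sort(unique(pos)))
    bases <- vapply(split(tok, f), paste, "", collapse = "")
    quals <- vapply(split(qual, f), function(q) {
      paste(q[!is.na(q)], collapse = "")
    }, "")
    depth <- as.integer(table(f))
    upos <- sort(unique(pos))
  } else {
    bases <- character(0); quals <- character(0)
    depth <- integer(0); upos <- numeric(0)
  }
  out <- data.frame(rname = rep(reg$rname, length(upos)),
                    pos = as.integer(upos),
                    ref = ref_base(upos), depth = depth,
                    bases = unname(bases), quals = unname(quals),
                    stringsAsFactors = FALSE)
  if (all_positions) {
    allp <- seq.int(reg$start1, reg$end1)
    miss <- setdiff(allp, upos)
    if (length(miss)) {
      pad <- data.frame(rname = reg$rname, pos = as.integer(miss),
                        ref = ref_base(miss),
                        depth = 0L, bases = "*", quals = "*",
                        stringsAsFactors = FALSE)
      out <- rbind(out, pad)
      out <- out[order(out$pos), , drop = FALSE]
      rownames(out) <- NULL
    }
  }
  out
}

#' Render mpileup columns as samtools-compatible text lines
#'
#' @param columns data.frame from [mpileup()].
#' @return character vector, one tab-separated line per column.
#' @export
mpileup_text <- function(columns) {
  if (nrow(columns) == 0L) return(character(0))
  paste(columns$rname, columns$pos, columns$ref, columns$depth,
        columns$bases, columns$quals, sep = "\t")
}

#' Region-parallel mpileup
#'
#' Runs [mpileup()] over each region (optionally across forked workers) and
#' concatenates the results in region order; the output is identical to the
#' sequential run for any worker count. Regions must be sorted and
#' non-overlapping.
#'
#' @inheritParams mpileup
#' @param regions list of regions ("name:start-end" strings or
#'   list(rname, start1, end1)).
#' @param workers number of worker processes.
#' @return concatenated mpileup data.frame.
#' @export
parallel_pileup <- function(bam_path, regions, workers = 1L,
                            fasta_path = NULL, index = NULL,
                            filter_mask = DEFAULT_FILTER_MASK,
                            all_positions = FALSE) {
  regs <- lapply(regions, parse_region)
  if (length(regs) == 0L) {
    return(data.frame(rname = character(0), pos = numeric(0),
                      ref = character(0), depth = integer(0),
                      bases = character(0), quals = character(0),
                      stringsAsFactors = FALSE))
  }
  if (length(regs) > 1L) {
    for (i in seq_along(regs)[-1]) {
      a <- regs[[i - 1L]]; b <- regs[[i]]
      if (a$rname == b$rname &&
          (b$start1 <= a$end1 || b$start1 < a$start1)) {
        bamkit_stop("regions must be sorted and non-overlapping",
                    "bamkit_contract_error")
      }
    }
  }
  one <- function(r) mpileup(bam_path, fasta_path, r, index,
                             filter_mask, all_positions)
  parts <- if (workers > 1L) {
    parallel::mclapply(regs, one, mc.cores = workers)
  } else {
    lapply(regs, one)
  }
  for (p in parts) if (inherits(p, "try-error")) stop(p)
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}
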