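# Deterministic synthetic-data generator: random reference FASTA plus a
# coherent single-end alignment set over it, with tunable indel, mismatch
# and unmapped rates. One seeded Mersenne-Twister stream drives everything
# (saved and restored around each call), so a given spec always yields
# byte-identical files. The generated data emulates idealized short-read
# alignments: uniform coverage, uniform base composition, no quality-by-
# cycle structure, no mate pairs.

#' Describe a synthetic alignment fixture
#'
#' @param seed integer seed for the generator's private RNG stream.
#' @param n_refs number of reference sequences.
#' @param ref_lengths integer vector of reference lengths (recycled to
#'   `n_refs`).
#' @param n_reads number of alignment records.
#' @param read_length query length of each read.
#' @param indel_rate per-interior-base probability of opening a 1-3 base
#'   insertion or deletion.
#' @param mismatch_rate per-aligned-base substitution probability.
#' @param unmapped_fraction fraction of records emitted unmapped.
#' @param sorted emit records in coordinate order (with the header marker).
#' @return a `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L, n_refs = 2L, ref_lengths = c(3000L, 2000L),
                         n_reads = 500L, read_length = 80L,
                         indel_rate = 0.02, mismatch_rate = 0.01,
                         unmapped_fraction = 0.02, sorted = TRUE) {
  rates <- c(indel_rate, mismatch_rate, unmapped_fraction)
  if (any(rates < 0 | rates > 1)) {
    bamkit_stop("rates must be probabilities in [0, 1]", "bamkit_spec_error")
  }
  ref_lengths <- rep_len(as.integer(ref_lengths), n_refs)
  if (n_refs > 0L && any(ref_lengths <= 0L)) {
    bamkit_stop("reference lengths must be positive", "bamkit_spec_error")
  }
  structure(list(seed = as.integer(seed), n_refs = as.integer(n_refs),
                 ref_lengths = ref_lengths, n_reads = as.integer(n_reads),
                 read_length = as.integer(read_length),
                 indel_rate = indel_rate, mismatch_rate = mismatch_rate,
                 unmapped_fraction = unmapped_fraction, sorted = sorted),
            class = "fixture_spec")
}

# run expr under the spec's private RNG stream, leaving the caller's RNG
# state untouched; `salt` decouples the reference and alignment streams
with_fixture_rng <- function(seed, salt, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed((seed * 7L + salt) %% .Machine$integer.max, kind = "Mersenne-Twister")
  expr
}

fixture_ref_names <- function(spec) {
  if (spec$n_refs == 0L) character(0) else paste0("chr", seq_len(spec$n_refs))
}

#' Generate a random reference FASTA
#'
#' Uniform A/C/G/T sequences named chr1..chrN, wrapped at 60 bases per line.
#' The same spec always produces identical octets.
#'
#' @param spec a [fixture_spec()].
#' @param path if non-NULL, write the FASTA there.
#' @return character vector of FASTA lines (invisibly when `path` given).
#' @export
generate_reference <- function(spec, path = NULL) {
  lines <- with_fixture_rng(spec$seed, 1L, {
    out <- character(0)
    for (i in seq_len(spec$n_refs)) {
      bases <- sample(c("A", "C", "G", "T"), spec$ref_lengths[i], replace = TRUE)
      s <- paste(bases, collapse = "")
      wrapped <- substring(s, seq(1L, nchar(s), 60L),
                           pmin(seq(1L, nchar(s), 60L) + 59L, nchar(s)))
      out <- c(out, paste0(">", fixture_ref_names(spec)[i]), wrapped)
    }
    out
  })
  if (!is.null(path)) {
    con <- file(path, "wb")
    if (length(lines)) writeLines(lines, con, sep = "\n")
    close(con)
    return(invisible(lines))
  }
  lines
}

# reference lines -> named list of sequences
fasta_lines_to_seqs <- function(lines) {
  hdr <- grepl("^>", lines)
  if (!any(hdr)) return(list())
  grp <- cumsum(hdr)
  names <- sub("^>([^ \t]+).*$", "\\1", lines[hdr])
  seqs <- vapply(split(lines[!hdr], grp[!hdr]), paste, "", collapse = "")
  stats::setNames(as.list(seqs), names)
}

random_cigar_and_seq <- function(ref_seq, pos, spec) {
  L <- spec$read_length
  bases <- character(0)
  ops <- character(0)
  lens <- integer(0)
  push <- function(op, len) {
    n <- length(ops)
    if (n > 0L && ops[n] == op) lens[n] <<- lens[n] + len
    else { ops[n + 1L] <<- op; lens[n + 1L] <<- len }
  }
  q <- 0L          # query bases produced
  r <- pos         # next reference position to consume
  while (q < L) {
    remaining <- L - q
    event <- q > 0L && remaining > 3L && runif(1) < spec$indel_rate
    if (event) {
      ilen <- sample(1:3, 1L)
      # a deletion needs enough reference left for itself plus the rest of
      # the read's matches
      can_delete <- r + ilen + (L - q) <= nchar(ref_seq)
      if (runif(1) < 0.5 || !can_delete) {      # insertion
        ilen <- min(ilen, remaining - 1L)
        push("I", ilen)
        bases <- c(bases, sample(c("A", "C", "G", "T"), ilen, replace = TRUE))
        q <- q + ilen
      } else {                                  # deletion
        push("D", ilen)
        r <- r + ilen
      }
    } else {
      b <- substr(ref_seq, r, r)
      if (runif(1) < spec$mismatch_rate) {
        b <- sample(setdiff(c("A", "C", "G", "T"), b), 1L)
      }
      push("M", 1L)
      bases <- c(bases, b)
      q <- q + 1L
      r <- r + 1L
    }
  }
  list(cigar = paste0(lens, ops, collapse = ""),
       seq = paste(bases, collapse = ""),
       ref_end = r - 1L)
}

#' Generate a coherent synthetic alignment set
#'
#' Reads are placed uniformly over references, positions and strands;
#' CIGARs mix matches with indels at `indel_rate`; sequences copy the
#' reference with substitutions at `mismatch_rate` (so with both rates zero
#' a mapped read's seq equals the reference slice); `unmapped_fraction` of
#' records are unmapped. Every record validates cleanly against the header.
#'
#' @param spec a [fixture_spec()].
#' @param reference FASTA lines from [generate_reference()] (or a path to
#'   a FASTA file).
#' @param path if non-NULL, write the SAM there.
#' @return list with `header` and `alignments` (and the file written when
#'   `path` is given).
#' @export
generate_alignments <- function(spec, reference, path = NULL) {
  lines <- if (length(reference) == 1L && file.exists(reference)) {
    readLines(reference, warn = FALSE)
  } else reference
  seqs <- fasta_lines_to_seqs(lines)
  if (spec$n_reads > 0L && length(seqs) &&
      spec$read_length > min(nchar(unlist(seqs)))) {
    bamkit_stop("read_length exceeds the shortest reference", "bamkit_spec_error")
  }
  if (spec$n_reads > 0L && length(seqs) == 0L) {
    bamkit_stop("cannot place reads on an empty reference", "bamkit_spec_error")
  }
  sq <- lapply(names(seqs), function(nm) {
    list(type = "SQ", fields = c(SN = nm, LN = as.character(nchar(seqs[[nm]]))))
  })
  hd <- list(type = "HD",
             fields = c(VN = "1.6",
                        SO = if (spec$sorted) "coordinate" else "unsorted"))
  header <- sam_header(c(list(hd), sq))
  aln <- if (spec$n_reads == 0L) empty_alignments() else
    with_fixture_rng(spec$seed, 2L, {
    n <- spec$n_reads
    n_unmapped <- round(n * spec$unmapped_fraction)
    is_un <- seq_len(n) > n - n_unmapped
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      qn <- sprintf("read%06d", i)
      qual <- paste(sample(strsplit("!#$%&'()*+,-./0123456789:;<=>?@ABCDEFGHI",
                                    "")[[1]], spec$read_length, replace = TRUE),
                    collapse = "")
      if (is_un[i]) {
        sq_rand <- paste(sample(c("A", "C", "G", "T"), spec$read_length,
                                replace = TRUE), collapse = "")
        rows[[i]] <- data.frame(
          qname = qn, flag = 4L, rname = "*", pos = 0L, mapq = 0L,
          cigar = "*", rnext = "*", pnext = 0L, tlen = 0L,
          seq = sq_rand, qual = qual, tags = "",
          stringsAsFactors = FALSE)
      } else {
        ref_i <- sample(length(seqs), 1L)
        ref_seq <- seqs[[ref_i]]
        # leave indel headroom so the reference span stays inside the contig
        max_pos <- nchar(ref_seq) - spec$read_length - 10L
        pos <- sample(max(max_pos, 1L), 1L)
        cs <- random_cigar_and_seq(ref_seq, pos, spec)
        flag <- if (runif(1) < 0.5) 0L else 16L
        nm <- sum(strsplit(cs$seq, "")[[1]][
          cigar_query_positions_m(cs$cigar)] !=
            strsplit(substr(ref_seq, pos, cs$ref_end), "")[[1]][
              cigar_ref_positions_m(cs$cigar)])
        rows[[i]] <- data.frame(
          qname = qn, flag = flag, rname = names(seqs)[ref_i],
          pos = pos, mapq = sample(20:60, 1L), cigar = cs$cigar,
          rnext = "*", pnext = 0L, tlen = 0L,
          seq = cs$seq, qual = qual,
          tags = sprintf("NM:i:%d", nm),
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
  if (spec$sorted && nrow(aln)) {
    refs <- header_references(header)
    keys <- sort_keys(aln, "coordinate", refs)
    aln <- aln[order_by_keys(keys), , drop = FALSE]
    rownames(aln) <- NULL
  }
  if (!is.null(path)) write_sam(path, header, aln)
  list(header = header, alignments = aln)
}

# query indices of M-aligned bases, and the matching 1-based offsets into
# the reference slice starting at pos (used for the NM tag)
cigar_query_positions_m <- function(cigar) {
  ops <- parse_cigar(cigar)
  q <- 0L
  out <- integer(0)
  for (i in seq_len(nrow(ops))) {
    if (ops$op[i] %in% c("M", "=", "X")) {
      out <- c(out, q + seq_len(ops$length[i]))
      q <- q + ops$length[i]
    } else if (ops$op[i] %in% c("I", "S")) {
      q <- q + ops$length[i]
    }
  }
  out
}

cigar_ref_positions_m <- function(cigar) {
  ops <- parse_cigar(cigar)
  r <- 0L
  out <- integer(0)
  for (i in seq_len(nrow(ops))) {
    if (ops$op[i] %in% c("M", "=", "X")) {
      out <- c(out, r + seq_len(ops$length[i]))
      r <- r + ops$length[i]
    } else if (ops$op[i] %in% c("D", "N")) {
      r <- r + ops$length[i]
    }
  }
  out
}

#' Write a complete fixture to disk: FASTA (+ .fai), SAM and sorted BAM
#'
#' @param spec a [fixture_spec()].
#' @param dir output directory (created if needed).
#' @return list of paths: `fasta`, `fai`, `sam`, `bam`, plus the in-memory
#'   `header` and `alignments`.
#' @export
generate_fixture <- function(spec, dir = tempfile("fixture")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, "ref.fa")
  sam <- file.path(dir, "reads.sam")
  bam <- file.path(dir, "reads.bam")
  generate_reference(spec, fasta)
  gen <- generate_alignments(spec, fasta, sam)
  write_bam(bam, gen$header, gen$alignments)
  fai <- index_fasta(fasta)
  list(fasta = fasta, fai = paste0(fasta, ".fai"), sam = sam, bam = bam,
       header = gen$header, alignments = gen$alignments)
}
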