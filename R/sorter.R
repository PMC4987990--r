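# External merge sort of SAM/BAM with bounded memory: the input is read in
# chunks of `chunk_records`, each chunk is sorted in memory (stable radix
# order) and spilled to a temporary BAM run, and the runs are k-way merged.
# Ties are broken by run ordinal then within-run order, which together with
# stable chunk sorts makes the whole sort stable in input order — and makes
# the output independent of chunk_records.
#
# Coordinate order: reference id in header @SQ order, then leftmost
# position. An unplaced record whose mate is placed sorts at the mate's
# coordinate; fully unplaced records go to the tail in input order.
# Queryname order: plain byte order on the name (no numeric-aware
# splitting), then a flag-derived ordinal (unpaired, then first-of-pair,
# then second-of-pair).

MERGE_BUFFER <- 2000L

# numeric sort keys; character keys for queryname mode are byte-ordered by
# the radix sort itself
sort_keys <- function(alignments, by, refs) {
  if (by == "coordinate") {
    placed <- alignments$rname != "*"
    kr <- rep(Inf, nrow(alignments))
    kp <- rep(Inf, nrow(alignments))
    kr[placed] <- match(alignments$rname[placed], refs$name) - 1
    kp[placed] <- alignments$pos[placed] - 1
    mate <- !placed & alignments$rnext != "*" & alignments$rnext != "=" &
      alignments$pnext >= 1L
    kr[mate] <- match(alignments$rnext[mate], refs$name) - 1
    kp[mate] <- alignments$pnext[mate] - 1
    if (anyNA(kr)) {
      bamkit_stop("record references a name absent from the header",
                  "bamkit_lookup_error")
    }
    list(kr, kp)
  } else {
    list(alignments$qname, bitwAnd(alignments$flag, 192L))
  }
}

order_by_keys <- function(keys, extra = list()) {
  do.call(order, c(keys, extra, list(method = "radix")))
}

# non-decreasing check for the keys of one run (consistency guard mid-merge)
keys_sorted <- function(keys) {
  n <- length(keys[[1]])
  if (n <= 1L) return(TRUE)
  identical(order_by_keys(keys), seq_len(n))
}

open_sink <- function(path, header) {
  if (is_bam_path(path)) {
    w <- bam_writer(path, header, validate = FALSE)
    list(write = w$write_records, close = w$close)
  } else {
    con <- file(path, "wb")
    writeLines(header_lines(header), con, sep = "\n")
    list(write = function(df) {
      if (nrow(df)) writeLines(format_sam_records(df), con, sep = "\n")
    },
    close = function() close(con))
  }
}

#' Merge internally sorted alignment runs
#'
#' K-way merge of files that are each already sorted under the same key.
#' The minimum key is taken first; ties are broken by run ordinal, then
#' within-run order. A run found to be unsorted mid-merge raises a
#' consistency error. The merged header is the first run's header with the
#' sort-order marker set.
#'
#' @param runs character vector of SAM/BAM paths, each internally sorted.
#' @param output output SAM/BAM path (by extension).
#' @param by "coordinate" or "queryname".
#' @return invisibly, the output path.
#' @export
merge_sorted_runs <- function(runs, output, by = c("coordinate", "queryname")) {
  by <- match.arg(by)
  stopifnot(length(runs) >= 1L)
  readers <- lapply(runs, alignment_open)
  on.exit(for (r in readers) try(r$close(), silent = TRUE), add = TRUE)
  header <- header_set_sort_order(readers[[1]]$header, by)
  refs <- header_references(header)
  n_run <- length(readers)
  bufs <- vector("list", n_run)
  done <- logical(n_run)        # disk-exhausted
  refill <- function(i) {
    ch <- readers[[i]]$read(MERGE_BUFFER)
    if (nrow(ch) < MERGE_BUFFER) done[i] <<- TRUE
    keys <- sort_keys(ch, by, refs)
    if (!keys_sorted(keys)) {
      bamkit_stop(sprintf("run %d is not sorted by %s", i, by),
                  "bamkit_consistency_error")
    }
    bufs[[i]] <<- ch
  }
  for (i in seq_len(n_run)) refill(i)
  sink <- open_sink(output, header)
  on.exit(sink$close(), add = TRUE)
  repeat {
    for (i in seq_len(n_run)) if (!done[i] && nrow(bufs[[i]]) == 0L) refill(i)
    sizes <- vapply(bufs, nrow, 0L)
    if (all(sizes == 0L)) break
    run_id <- rep.int(seq_len(n_run), sizes)
    combined <- do.call(rbind, bufs[sizes > 0L])
    keys <- sort_keys(combined, by, refs)
    ord <- order_by_keys(keys, extra = list(run_id))
    # rows past the last buffered record of a still-unread run cannot be
    # emitted yet: an unbuffered record of that run might sort before them
    pending <- which(!done & sizes > 0L)
    cut <- length(ord)
    if (length(pending)) {
      tail_rows <- cumsum(sizes)[pending]   # row index of each run's tail
      cut <- min(match(tail_rows, ord))
    }
    emit <- ord[seq_len(cut)]
    sink$write(combined[emit, , drop = FALSE])
    keep <- sort(ord[-seq_len(cut)])        # residue, in original row order
    kept_run <- run_id[keep]
    bufs <- lapply(seq_len(n_run), function(i) {
      combined[keep[kept_run == i], , drop = FALSE]
    })
  }
  invisible(output)
}

sort_alignments <- function(input, output, by, chunk_records = 500000L,
                            tmpdir = tempdir()) {
  stopifnot(is_count(chunk_records))
  rdr <- alignment_open(input)
  header <- header_set_sort_order(rdr$header, by)
  refs <- header_references(header)
  run_paths <- character(0)
  on.exit(unlink(run_paths), add = TRUE)
  first_chunk <- NULL
  repeat {
    ch <- rdr$read(as.integer(chunk_records))
    if (nrow(ch) == 0L && (length(run_paths) || !is.null(first_chunk))) break
    ord <- order_by_keys(sort_keys(ch, by, refs))
    ch <- ch[ord, , drop = FALSE]
    if (is.null(first_chunk) && length(run_paths) == 0L) {
      first_chunk <- ch
      if (nrow(ch) < chunk_records) break   # everything fit in one chunk
      next
    }
    # second chunk arrived: spill the first, then keep spilling
    if (!is.null(first_chunk)) {
      run_paths <- c(run_paths, spill_run(first_chunk, header, tmpdir))
      first_chunk <- NULL
    }
    if (nrow(ch)) run_paths <- c(run_paths, spill_run(ch, header, tmpdir))
  }
  rdr$close()
  if (length(run_paths) == 0L) {
    # single in-memory run
    sink <- open_sink(output, header)
    sink$write(first_chunk %||% empty_alignments())
    sink$close()
  } else {
    merge_sorted_runs(run_paths, output, by = by)
  }
  invisible(output)
}

spill_run <- function(chunk, header, tmpdir) {
  path <- tempfile("run_", tmpdir = tmpdir, fileext = ".bam")
  write_bam(path, header, chunk, validate = FALSE)
  path
}

#' Sort a SAM/BAM file by coordinate
#'
#' Records are ordered by reference id (header @SQ order) then leftmost
#' position; unplaced records with a placed mate sort at the mate's
#' coordinate, fully unplaced records go last in stable input order. The
#' header gains the sort-order marker "coordinate". The output record
#' multiset equals the input's, and the result does not depend on
#' `chunk_records`.
#'
#' @param input,output SAM/BAM paths (format by extension).
#' @param chunk_records records held in memory per sort chunk; lower values
#'   trade speed for memory by spilling more temporary runs.
#' @param tmpdir directory for temporary runs (stored as BAM).
#' @return invisibly, the output path.
#' @export
sort_by_coordinate <- function(input, output, chunk_records = 500000L,
                               tmpdir = tempdir()) {
  sort_alignments(input, output, "coordinate", chunk_records, tmpdir)
}

#' Sort a SAM/BAM file by query name
#'
#' Records are grouped by qname under plain byte order, with paired-end
#' ordinal (unpaired, first-of-pair, second-of-pair) breaking ties; the
#' header gains the sort-order marker "queryname".
#'
#' @inheritParams sort_by_coordinate
#' @return invisibly, the output path.
#' @export
sort_by_queryname <- function(input, output, chunk_records = 500000L,
                              tmpdir = tempdir()) {
  sort_alignments(input, output, "queryname", chunk_records, tmpdir)
}
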