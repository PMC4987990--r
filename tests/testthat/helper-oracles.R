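# Shared fixtures and independent oracles. The oracles deliberately avoid
# the package's own code paths: the bin oracle enumerates the whole bin
# hierarchy, the pileup oracle counts position-by-position, the region
# oracle is a plain overlap filter on the in-memory record table.

# memoized fixtures: test files in one run share generated data
.fx_cache <- new.env(parent = emptyenv())

cached_fixture <- function(seed, n_reads = 200L, ...) {
  key <- paste(seed, n_reads, ..., sep = "_")
  if (is.null(.fx_cache[[key]])) {
    .fx_cache[[key]] <- generate_fixture(
      fixture_spec(seed = seed, n_reads = n_reads, ...))
  }
  .fx_cache[[key]]
}

# strip the voffset bookkeeping columns read_bam adds
core_fields <- function(df) {
  df$voffset <- NULL
  df$voffset_end <- NULL
  rownames(df) <- NULL
  df
}

# the full 37450-bin table: every bin id with its 0-based half-open interval
full_bin_table <- local({
  tbl <- NULL
  function() {
    if (is.null(tbl)) {
      shifts <- c(29, 26, 23, 20, 17, 14)
      offsets <- c(0, 1, 9, 73, 585, 4681)
      rows <- lapply(1:6, function(lvl) {
        n <- 8^(lvl - 1)
        size <- 2^shifts[lvl]
        data.frame(id = offsets[lvl] + seq_len(n) - 1,
                   beg = (seq_len(n) - 1) * size,
                   end = seq_len(n) * size,
                   size = size)
      })
      tbl <<- do.call(rbind, rows)
    }
    tbl
  }
})

# smallest bin fully containing [beg0, end0): exhaustive search
oracle_reg2bin <- function(beg0, end0) {
  tbl <- full_bin_table()
  hit <- tbl$beg <= beg0 & tbl$end >= end0
  cand <- tbl[hit, ]
  cand$id[which.min(cand$size)]
}

# every bin overlapping [beg0, end0): exhaustive scan
oracle_reg2bins <- function(beg0, end0) {
  tbl <- full_bin_table()
  sort(tbl$id[tbl$beg < end0 & tbl$end > beg0])
}

# reference span of a CIGAR, written independently of the package helpers
oracle_ref_span <- function(cigar) {
  if (cigar == "*") return(0)
  toks <- regmatches(cigar, gregexpr("[0-9]+.", cigar))[[1]]
  sum(vapply(toks, function(t) {
    op <- substr(t, nchar(t), nchar(t))
    if (op %in% c("M", "D", "N", "=", "X"))
      as.numeric(substr(t, 1, nchar(t) - 1)) else 0
  }, 0))
}

# records overlapping a 1-based inclusive region: plain linear filter
oracle_region_scan <- function(alignments, rname, start1, end1) {
  span <- vapply(alignments$cigar, oracle_ref_span, 0, USE.NAMES = FALSE)
  span <- pmax(span, 1)
  keep <- alignments$rname == rname & alignments$pos >= 1 &
    alignments$pos <= end1 & alignments$pos + span - 1 >= start1
  out <- alignments[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# per-position depth by expanding every record's CIGAR position by position
oracle_pileup_depth <- function(alignments, rname, start1, end1,
                                mask = 0x704L) {
  depth <- integer(end1 - start1 + 1)
  for (i in seq_len(nrow(alignments))) {
    if (alignments$rname[i] != rname) next
    if (bitwAnd(alignments$flag[i], mask) != 0) next
    if (alignments$cigar[i] == "*" || alignments$pos[i] < 1) next
    toks <- regmatches(alignments$cigar[i],
                       gregexpr("[0-9]+.", alignments$cigar[i]))[[1]]
    rpos <- alignments$pos[i]
    for (t in toks) {
      op <- substr(t, nchar(t), nchar(t))
      len <- as.integer(substr(t, 1, nchar(t) - 1))
      if (op %in% c("M", "D", "=", "X")) {
        for (p in rpos:(rpos + len - 1)) {
          if (p >= start1 && p <= end1) {
            depth[p - start1 + 1] <- depth[p - start1 + 1] + 1L
          }
        }
        rpos <- rpos + len
      } else if (op == "N") {
        rpos <- rpos + len
      }
    }
  }
  depth
}

# multiset fingerprint of an alignment table (order-insensitive)
record_multiset <- function(alignments) {
  sort(paste(alignments$qname, alignments$flag, alignments$rname,
             alignments$pos, alignments$mapq, alignments$cigar,
             alignments$rnext, alignments$pnext, alignments$tlen,
             alignments$seq, alignments$qual, alignments$tags, sep = "\r"))
}

# a minimal header + hand-built records for targeted cases
tiny_header <- function(lens = c(chr1 = 10000L, chr2 = 5000L)) {
  sq <- lapply(names(lens), function(nm) {
    list(type = "SQ", fields = c(SN = nm, LN = as.character(lens[[nm]])))
  })
  sam_header(c(list(list(type = "HD", fields = c(VN = "1.6"))), sq))
}

tiny_record <- function(qname = "r1", flag = 0L, rname = "chr1", pos = 100L,
                        mapq = 60L, cigar = "10M", rnext = "*", pnext = 0L,
                        tlen = 0L, seq = strrep("A", 10), qual = strrep("I", 10),
                        tags = "") {
  data.frame(qname = qname, flag = flag, rname = rname, pos = pos,
             mapq = mapq, cigar = cigar, rnext = rnext, pnext = pnext,
             tlen = tlen, seq = seq, qual = qual, tags = tags,
             stringsAsFactors = FALSE)
}
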