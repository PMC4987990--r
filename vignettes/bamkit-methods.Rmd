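---
title: "bamkit: design and methods of a native SAM/BAM stack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{bamkit: design and methods of a native SAM/BAM stack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bamkit)
```

bamkit implements the alignment-file stack — BGZF, SAM, BAM, BAI, pileup,
FASTA/FAI, FASTQ — natively in R (with one small zlib binding for raw
deflate/inflate/CRC32). This vignette records the model each layer
implements, the parameters that matter, the numerical and design choices
made where the formats or conventions leave room, and what the synthetic
test data does and does not establish about behavior on real data.

## The BGZF layer and virtual offsets

BAM files are BGZF streams: a concatenation of independent gzip members of
at most 65,536 on-disk octets, each carrying its own total length in a
`BC` extra subfield so a reader can hop between blocks without inflating
them, terminated by a canonical 28-octet empty-payload sentinel. Because
each block is independently decompressible, any uncompressed byte is
addressable by the pair (file offset of its block, offset within the
inflated payload), packed into one 64-bit *virtual offset*
`coffset * 2^16 + uoffset`. Packed values order exactly like the pairs,
which is the property BAI chunk bounds rely on.

Choices made here:

* **Write-side payload cap of 65,280 octets.** Deflate can expand
  incompressible input slightly; capping the payload 256 octets below the
  64 KiB block bound guarantees `bsize <= 65536` for any input without a
  retry path. Stored-block overhead is about 5 octets per 16 KiB plus a
  constant, so the headroom is ample; a defensive check remains.
* **Compression level 6** (zlib default), configurable per writer.
  Correctness tests use round-trip equality, never byte-identity of
  compressed output, so the level is a pure speed/size trade-off.
* **Missing sentinel tolerated with a warning.** Truncated-but-complete
  files exist in the wild; the block table can still prove the stream
  self-consistent, so reading proceeds.
* **Virtual offsets as doubles.** R has no native 64-bit integer; doubles
  are exact below 2^53, i.e. for compressed offsets up to 128 GiB —
  far beyond anything this package is intended to write. The pack/unpack
  routines validate the 2^48/2^16 field bounds explicitly.
* **Block-boundary convention.** An uncompressed offset landing exactly at
  the end of a block maps to the *next* block at `uoffset = 0`. Writer
  (index construction) and reader use the same mapping function, so chunk
  bounds always resolve.

Parallel block compression is permitted on write, but blocks are emitted
in payload order regardless of worker count: the output stream is a pure
function of (payload, level).

## Domain model: flags, CIGAR, validation, normalization

Coordinates are 1-based inclusive throughout the in-memory model (the SAM
convention); the BAM binary layer and BAI binning convert to 0-based
half-open at their boundaries only, keeping conversions localized.
Alignments travel as a plain data.frame with the 11 mandatory columns plus
a `tags` column holding optional fields in SAM text form — this makes
SAM round trips trivially byte-stable and keeps the table idiomatic for R
users.

CIGAR semantics follow the standard consume table (M, I, S, =, X consume
query; M, D, N, =, X consume reference). Zero-length operations are
accepted on read and refused on write (lenient in, strict out).
Validation returns violations as data rather than raising, so callers can
triage; writers refuse on any violation.

"Normalization" is implemented as reference-name canonicalization with a
user-overridable mapping table, defaulting to the chr-prefix map (bare
`1..22`, `X`, `Y` gain `chr`; `M`/`MT` map to `chrM`). The map is applied
to header @SQ names and record rname/rnext together so the reference-id
space stays linked; two input names collapsing to one output is an error,
and the operation is idempotent. @SQ order is never changed, since that
order *is* the BAM reference-id space.

## BAM binary encoding

Records are encoded little-endian per the standard layout: 4-bit packed
sequences over the 16-symbol code `=ACMGRSVTWYHKDBN`, CIGAR as
`length*16 + opcode` words, qualities as raw Phred values (0xff-filled
when absent), and typed tags. Two policies are worth stating:

* **Integer tag subtypes.** On write, the smallest fitting subtype is
  chosen (unsigned preferred for non-negative values); on conversion back
  to text every integer subtype re-serializes as `i`, because text SAM has
  a single integer type. Round-tripping therefore canonicalizes subtypes
  while preserving values exactly.
* **Placement of unplaced mates.** An unplaced record whose mate is placed
  is stored at the mate's coordinates, which keeps pairs adjacent under
  coordinate sort. Fully unplaced records keep reference id −1.

Each decoded record exposes the virtual offset where it starts (and the
one just past it); these are exactly the chunk bounds the indexer stores.

## BAI: binning, linear index, and queries

The 6-level binning hierarchy tiles 0..2^29 with bins of 2^29 down to
2^14 bases (level offsets 0, 1, 9, 73, 585, 4681; 37,449 bins, ids
0..37448). Each placed record lands in the smallest bin containing its
reference span (`reg2bin`); records with a mapped position but no CIGAR
are binned with span 1 so they remain retrievable. A 16 kb-granularity
linear index stores, per window, the smallest start offset of any record
overlapping it; empty interior windows are forward-filled so the array is
non-decreasing. Chunks within a bin that touch or overlap in virtual-
offset space are merged. The metadata pseudo-bin 37450 (record span and
mapped/unmapped counts) is written because mainstream readers expect it,
tolerated when absent, and never consulted by queries. The trailing
count of fully unplaced records is written only when non-zero.

Region queries union the chunk lists of every bin overlapping the region
(`reg2bins`), drop chunks entirely before the linear-index lower bound of
the region's first window, merge, inflate only the addressed blocks, and
overlap-filter the decoded records. Correctness is established against a
brute-force linear-scan oracle rather than against another library.

**Parallelism.** Index construction partitions records by reference;
workers build per-reference sub-indexes that are reassembled in reference-
id order. The merge is a fixed-order, associative assembly, so the result
is deeply equal for every worker count — that determinism contract, not a
speed number, is what the tests enforce. Sortedness is checked up front
(positions never decrease within a reference; no reference id reappears),
naming the first offending record.

## External-merge sort

Input is read in chunks of `chunk_records` (default 500,000 — a memory
bound, not a tuning claim), each chunk stably sorted and spilled as a
compressed BAM run, and the runs k-way merged. The merge works in rounds:
all buffered records are radix-ordered by (key, run ordinal, within-run
position) and the prefix up to the first still-unread run's last buffered
record is emitted — everything later could still be preceded by an
unbuffered record. Stable chunk sorts plus ordinal tie-breaks make the
whole pipeline stable in input order, which in turn makes output
independent of `chunk_records`; the tests assert that equality outright.

Coordinate keys are (reference id in @SQ order, leftmost position);
unplaced records with a placed mate adopt the mate's coordinates, fully
unplaced records sort to the tail in input order. Queryname order is
plain byte order (radix sort semantics, locale-independent), with a
paired-end ordinal (unpaired, first-of-pair, second-of-pair) breaking
name ties — byte order is the simplest total order that every platform
reproduces identically; no numeric-aware splitting is attempted.

## Pileup and mpileup

Depth at a position counts filter-passing reads whose CIGAR consumes the
reference there: M, D, =, X cover; N-skipped stretches do not. Deleted
positions therefore count toward depth and render as `*`. The default
filter mask excludes unmapped (0x4), secondary (0x100), QC-fail (0x200)
and duplicate (0x400) reads and is configurable. No base-quality floor is
applied and BAQ is out of scope by design.

The text rendering follows the samtools token alphabet: `.`/`,` for
strand-coded matches, case-coded letters for mismatches, `+n<seq>` /
`-n<seq>` attached to the position preceding an indel (case again coding
strand), `^` plus the mapq character at a read's first emitted position
and `$` at its last. Without a reference FASTA the reference column shows
`N` and every aligned base is reported as its letter. Zero-coverage
positions are omitted unless the all-positions mode is requested (the
simple per-position depth profile always reports every position).
One deliberate divergence: quality characters are emitted only for
non-deletion tokens, so a column's `quals` length equals its count of
base tokens; `*` placeholders carry no quality. In a development
cross-check against `samtools mpileup -B -Q0 -x` on a 300-read fixture,
every column of rname/pos/ref/depth/bases was byte-identical; only the
deletion-placeholder quality characters differ.

Parallel pileup is region-parallel only: regions (which must be sorted
and non-overlapping) are processed independently and concatenated in
region order, so output is byte-identical to the sequential run for any
worker count. No within-region sharding is attempted — the determinism
contract stays trivial to uphold, and region granularity already gives
the useful parallelism.

## FASTA/FAI and FASTQ

FAI records store name (header token up to the first whitespace), base
count, offset of the first sequence octet, bases per full line, and
octets per full line including the terminator; CRLF files simply have
`linewidth - linebases = 2`. `fetch_region` turns a 1-based inclusive
region into two file offsets by line arithmetic and reads only those
bytes, stripping terminators; lowercase (soft-masked) bases are
preserved. Ragged interior lines, blank lines inside a record and
duplicate names are format errors, mirroring faidx conventions. FASTQ is
strict 4-line records, Phred+33 only — a Phred+64 file is rejected, not
converted.

## The synthetic fixture generator

All tests run on data from a seeded generator: uniform-composition
references (chr1, chr2, ... wrapped at 60 bases), reads placed uniformly
over references, positions and strands, CIGARs mixing matches with 1–3
base indels opened at `indel_rate` per interior base, substitutions at
`mismatch_rate`, a deterministic `unmapped_fraction` of unplaced records,
and an NM tag computed from the actual substitutions. One
Mersenne–Twister stream, derived from the spec's seed and restored after
use, drives everything, so a spec maps to byte-identical files — the
property the acceptance checks depend on. Defaults (2 references of
3,000/2,000 bases, 500 reads of 80 bases, 2% indel, 1% mismatch, 2%
unmapped) give roughly 10–20× coverage with all CIGAR op classes well
represented, the regime short-read pileup and indexing are designed for.

What the generator does *not* emulate: mate pairs (flags are still
coherent for single-end data), quality-by-cycle structure, GC bias,
N-skip (spliced) alignments, clipped reads and supplementary/secondary
records. Passing tests therefore establish format-level and algorithmic
correctness — round trips, index/oracle agreement, sort and determinism
contracts — on idealized data; they do not constitute a benchmark of
variant-calling-grade behavior on production sequencing runs. The token
renderer handles S/H/P and N ops by the consume table regardless, and the
cross-checks against samtools on generated data cover the shared surface.

## Test and acceptance problem sizes

The standing test conditions, chosen once as realistic desk-scale
workloads: 50 seeded fixtures of 30–150 records for round-trip, index and
pileup properties (with 200 random regions per fixture for index/oracle
agreement and 10^4 random intervals for the binning oracle); a
10,000-record fixture sorted at chunk sizes 10, 100 and 10^5; BGZF round
trips on random payloads up to 10 MB; worker counts 1, 2 and 4 for the
determinism contracts. `scripts/acceptance.R` re-runs the same measures
end to end on freshly generated data (10 fixtures, 100 regions each,
2,000 intervals, a 3,000-record sort) and reports each agreement rate
with its problem size.

## Known limitations

* No CRAM, CSI indexes, long-CIGAR (>65,535 ops) records, or bgzipped
  FASTA.
* Virtual offsets (and 64-bit BAI fields) are exact only below 2^53 —
  petabyte-scale files are out of scope.
* Whole-file readers hold the decoded table in memory; the streaming
  readers bound memory by chunk size but the BAI builder currently keeps
  per-record bookkeeping for one pass.
* Queryname order is byte order, which differs from samtools' natural
  sort for mixed alpha-numeric names.
* mpileup emits no quality for deletion placeholders (see above) and
  implements no BAQ and no overlap-pair quality de-duplication.
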