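# bamkit

bamkit is a self-contained R toolkit for the file stack of short-read DNA
sequence alignment: SAM text, BAM binary, BGZF block compression, BAI
indexes, FASTA/FAI and FASTQ. It is aimed at people who need to read,
write, convert, sort, index and pile up alignment data from R (or from a
shell) without shelling out to an external SAM/BAM library — every format
here is encoded and decoded natively, from the octets up, with the
high-cost operations (BAM indexing, pileup) optionally running across
parallel workers under a strict determinism contract.

## What it implements

* **BGZF codec** — BAM's block compression: concatenated ≤64 KiB gzip
  members, each independently decompressible, addressed by 64-bit *virtual
  offsets* `coffset · 2^16 + uoffset` (compressed block start, offset
  within the inflated payload). Random access via `bgzf_open()` /
  `bgzf_seek()` / `bgzf_read()`.
* **SAM/BAM I/O and conversion** — streaming readers and writers for both
  formats (`read_sam()`, `write_bam()`, …) with the 4-bit sequence
  packing, binary CIGAR words and typed optional tags of the BAM layout;
  flag decoding, CIGAR arithmetic, validation and reference-name
  normalization (`"1" → "chr1"`) in the domain model.
* **BAI indexing and region queries** — the 6-level hierarchical binning
  scheme over the 0..2^29 coordinate space (bin ids 0..37448, level
  offsets 0, 1, 9, 73, 585, 4681) plus the 16 kb linear index.
  `build_index()` accumulates, per mapped record, the chunk
  `[record start voffset, next record start voffset)` into
  `reg2bin(pos0, pos0 + reference_span)`; `query_chunks()` unions
  `reg2bins()` over a region, prunes by the linear index, and
  `read_bam_region()` inflates only the addressed blocks.
* **External-merge sorting** — coordinate (reference id, then leftmost
  position; unplaced reads last) or queryname (byte order) sorting with
  bounded memory: chunks of `chunk_records` are sorted in memory, spilled
  as BAM runs, and k-way merged with run-ordinal tie-breaks, so output is
  independent of the chunk size.
* **Pileup / mpileup** — per-position depth counting reads whose CIGAR
  consumes the reference (M, D, =, X; N-skips excluded) and the
  samtools-compatible text rendering: `.`/`,` matches, case-coded
  mismatch letters, `*` deleted positions, `+n<seq>`/`-n<seq>` indel
  annotations, `^`+mapq / `$` read boundaries. Region-parallel execution
  is byte-identical to sequential for any worker count.
* **FASTA/FAI and FASTQ** — faidx-style indexing (name, length, offset,
  bases per line, octets per line) with O(1) `fetch_region()`, and
  Phred+33 FASTQ I/O.
* **Fixture generator** — a deterministic, seeded simulator of reference
  FASTA plus coherent alignment sets (tunable indel/mismatch/unmapped
  rates) used throughout the tests.

## Worked example

```r
library(bamkit)
fx  <- generate_fixture(fixture_spec(seed = 11, n_reads = 300), "/tmp/demo")
idx <- index_bam(fx$bam)                     # writes /tmp/demo/reads.bam.bai

head(read_bam(fx$bam)$alignments[, c("qname","flag","rname","pos","mapq","cigar")], 3)
#>        qname flag rname pos mapq              cigar
#> 1 read000245   16  chr1  25   59            3M1D77M
#> 2 read000248    0  chr1  30   39           58M3D22M
#> 3 read000109   16  chr1  31   33 10M1I18M2I29M3D20M

simple_pileup(fx$bam, "chr1:1-10", idx)      # depth for the first 10 positions
#>    pos depth
#> 1    1     0
#> ...
#> 10  10     0

writeLines(mpileup_text(mpileup(fx$bam, fx$fasta, "chr1:201-206", idx)))
#> chr1  201  T  2  ,,      C9
#> chr1  202  C  2  ,,      7+
#> chr1  203  G  2  ,,      ;:
#> chr1  204  A  3  ,,^G,   F&!
#> chr1  205  A  3  ,,,     A1G
#> chr1  206  T  3  ,,,+2gt .>A

nrow(read_bam_region(fx$bam, "chr1:1000-1200", idx))
#> [1] 15
```

Reading the mpileup columns: position 204 has depth 3 because a third read
starts there (`^G` carries its mapping quality, G = Q38); all three reads
are reverse-strand matches (`,`), and the read ending the block at 206
carries a 2-base insertion (`+2gt`, lowercase = reverse strand) after that
position. The depth-0 rows from `simple_pileup` show the all-positions
mode used for scanning a fixed window.

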