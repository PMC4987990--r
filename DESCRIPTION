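Package: bamkit
Title: Pure-R Toolkit for SAM/BAM Alignment Files with Parallel Indexing and Pileup
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained implementation of the SAM/BAM alignment file
    stack: BGZF block compression with 64-bit virtual offsets for random
    access, SAM text and BAM binary reading/writing and conversion,
    reference-name normalization, external-merge coordinate and queryname
    sorting, BAI hierarchical-binning index construction (optionally
    parallel) with region queries, samtools-style pileup and mpileup text
    generation, FASTA faidx indexing with region fetch, and FASTQ I/O.
    Includes a deterministic synthetic fixture generator and a command-line
    interface. No existing SAM/BAM API is wrapped; all formats are encoded
    and decoded natively.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    parallel,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
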