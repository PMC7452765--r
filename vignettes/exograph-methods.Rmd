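---
title: "Methods: reference-free exon and splice-graph prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reference-free exon and splice-graph prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exograph)
```

## Model

`exograph` decomposes each transcript of an assembled transcriptome into
exons using only shotgun WGS reads.  The signal is structural: a
transcript k-mer that spans an intron–exon boundary (IEB) is a
concatenation artifact of splicing — it does not occur in the genome and
therefore cannot occur in genomic reads (up to chance collisions,
discussed below).  Conversely, k-mers interior to an exon are genomic
substrings and, at adequate coverage, are observed repeatedly.  Scanning
a transcript against the set of read k-mers thus yields runs of positive
windows separated by dark stretches of width `k − 1` at each IEB, and the
runs map directly to exon intervals.

Three probabilistic complications shape the pipeline:

* **Sequencing errors** create spurious k-mers.  These are overwhelmingly
  singletons, so solidity is defined as presence in the last level of a
  cascading Bloom filter: each occurrence of a k-mer advances it one
  level, and only k-mers seen at least `levels` times (default 2) count.
* **Bloom false positives** can light up junction windows, producing
  short spurious exons (length about `k`) and shrunken dark gaps.  The
  length filter (`< k + q` dropped, `q = 5`) removes the former; the
  relaxed merge (overlap `> 10` bases merges) absorbs the latter when the
  flanking exons bleed into each other.
* **Irrelevant reads** (intronic, intergenic) contribute nothing but
  occupancy.  Baiting discards every read sharing no k-mer with the
  transcriptome before the cascade is built, which at equal memory lowers
  the analysis-level FPR by an order of magnitude on exon-sparse genomes.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `k` | 25 | bases | window length; larger k is more specific (precision) but more error-fragile (recall) |
| `levels` | 2 | — | solidity threshold: occurrences needed to trust a k-mer |
| `memory_bits` | user | bits | total filter budget, split equally across cascade levels; the achieved FPR `(1 − e^{−hn/m})^h` is reported, not requested |
| `h` | 4 | — | hash functions per filter |
| `min_shared_kmers` | 1 | — | k-mers a read must share with the transcriptome to survive baiting |
| `q` | 5 | bases | length-filter slack: exons shorter than `k + q` are dropped |
| `max_overlap` | 10 | bases | relaxed-merge threshold (strictly greater merges) |
| `polish` | off | — | trim overlapping exon pairs at the `AGGT` motif |
| `n_gap` | 100 | bases | Ns between exons in gapped-transcript FASTA |

The defaults for `k`, `q`, `max_overlap` and `h` are the operating points
at which this family of methods is known to balance precision and recall
on vertebrate-scale data; they are exposed, not hard-coded.

## Design choices where the design was open

* **Hashing.**  Two independent 64-bit hashes (FNV-1a with distinct
  seeds, finalized with a splitmix mix) combined by double hashing
  `h_i = (h1 + i·h2) mod m`.  This is reproducible across platforms and
  recorded in the filter file header (`fnv1a64x2-double`), so a filter
  built once is loadable anywhere.
* **Canonicalization.**  Membership is strand-neutral: every window is
  replaced by the lexicographic minimum of itself and its reverse
  complement, the standard convention for mixed-strand read sets.
  Windows containing non-ACGT characters are skipped with positions
  preserved.
* **FPR accounting.**  `n` in the FPR formula is the number of insert
  calls, not distinct elements.  Repeats therefore make the estimate
  conservative (never optimistic); for the cascade the insert rule routes
  the i-th occurrence of a k-mer to level i, so per-level counts
  approximate distinct cardinalities anyway.
* **Relaxed merge uses strict inequality** (an overlap of exactly
  `max_overlap` is kept) and iterates left-to-right to a fixpoint, so the
  result is independent of how many merges a single pass performs.  Note
  the direction of the monotonicity this yields: a *larger* threshold
  merges fewer pairs and can only leave the exon count equal or higher.
* **Polishing** searches the literal overlap substring for the leftmost
  `AGGT` and splits between the `AG` and `GT`.  In transcript space the
  upstream exon's acceptor `AG` abuts the downstream exon's donor `GT`,
  which is why the motif is searched as spelled (the genomic donor is
  `GT`, `GU` in pre-mRNA terms).  Pairs overlapping by fewer than 4 bases
  cannot contain the motif and are left alone; nothing is polished across
  gaps.
* **Node identity is exact sequence equality** (case-folded).  Identical
  exons from different transcripts collapse into one node, which is what
  makes genes appear as connected components without any alignment step.
  Exon ids (`EXON` + 8-digit counter) are assigned in first-encounter
  order, so output is reproducible.
* **Evaluation matching is one-to-one greedy** by reciprocal overlap
  fraction, ties to the leftmost truth interval.  Pairwise intersection
  counting (as `bedtools intersect` reports) can count one truth interval
  for several predictions; one-to-one matching guarantees
  `TP ≤ min(|pred|, |truth|)` and makes `TP + FP = |pred|`,
  `TP + FN = |truth|` identities hold exactly.
* **Paired reads are treated as independent sequences** during baiting;
  keeping a pair when either mate matches would retain slightly more
  flanking sequence but makes the kept-read count depend on pairing
  metadata the rest of the pipeline never uses.
* **The CLI is a thin wrapper.**  All subcommands call the exported
  functions; `exec/exograph` adds only argument parsing and exit codes,
  so everything is testable in-process.

## The simulator, and what passing tests do not show

`simulate_genome()` lays spliced genes on one chromosome: exons and
intergenic spacers are i.i.d. draws from the requested base composition,
introns are random sequence wrapped in canonical `GT..AG` signals, and
transcripts are the exon concatenations.  Minus-strand genes (optional)
are inserted as reverse complements with correctly flipped annotation.
`simulate_reads()` samples fragment starts uniformly, flips strand with
probability 0.5, and applies i.i.d. substitutions; read count is
`ceiling(coverage × genome_len / (read_len × mates))`.

Two constructions make the exact-recovery tests clean rather than merely
probable:

* **Exon terminal bases avoid `G`.**  A transcript k-mer overhanging a
  junction by `d` bases coincides with a genomic k-mer exactly when the
  exon's terminal `d` bases reproduce the intron's flanking signal
  prefix/suffix — and every such collision requires the first (or last)
  exon base to be `G`, matching the intron's `GT` (or `AG`).  Drawing
  terminal bases from `{A, C, T}` eliminates the entire family of
  adjacent-context collisions at every depth.
* **A rejection screen** regenerates any genome in which a
  junction-spanning transcript k-mer still occurs elsewhere in the genome
  (distant repeats, reverse-complement coincidences).  At the default
  scale this triggers rarely.

The default fixture is 20 genes × 2–4 exons, exons 100–300 bp, introns
200–500 bp, intergenic spacers 200–500 bp, GC 0.5 — about 34 kb of
genome, small enough that the full pipeline runs in seconds at 30x.
These were chosen once as a desk-scale caricature of a compact eukaryotic
gene neighborhood.

What the simulator does **not** emulate — and therefore what green tests
do not certify about real data: heterozygosity and diploidy (a variant
k-mer halves its effective coverage), indel errors, coverage bias,
repetitive DNA beyond chance repeats (real genomes share k-mers between
paralogs and transposons, which can bridge junction gaps), alternative
splicing (two isoforms of one gene are simulated as distinct genes), and
fragmented or chimeric transcriptome assemblies.  On real data precision
and recall in the mid-90s, not 100%, are the realistic ceiling.

## Numerical and degenerate-input conventions

* All engine coordinates are 0-based half-open; conversion to 1-based
  inclusive happens only at the GFF3 boundary, and BED-like outputs stay
  0-based half-open with the transcript as reference name.
* Transcripts shorter than `k` yield a warning and no exons (they appear
  in `dropped`, not in paths); an empty transcriptome is an error.
* `precision`, `recall` and `f1` with zero denominators are reported as 0
  with a `degenerate` flag rather than NaN.
* Filter files are written little-endian with a magic string, format
  version and hash identifier, and reject anything they cannot have
  produced.
* Problem sizes in the test suite (10^4–10^5 k-mers for the
  no-false-negative and FPR-calibration checks, 100 random graphs for
  round trips, the 34 kb default fixture for end-to-end checks) keep the
  whole suite under a minute while leaving each statistical assertion
  comfortable margins — e.g. the empirical-vs-analytic FPR check runs at
  an expected 240 false positives over 10^5 probes, where the asserted
  factor-of-two band is about 15 standard deviations wide.

## Known limitations

* Exons shorter than `k + q` (microexons) are invisible by construction.
* Only the `AG‑GT` signal is polished; minor splice classes (`GC‑AG`,
  `AT‑AC`) are not searched.
* Boundary placement uses membership only, never read pairing or depth;
  two junctions closer than `k` bases apart blur together.
* The cascade counts occurrences at most `levels` deep; it is a solidity
  test, not a k-mer counter.
* `bedtools`-style multi-match counting is deliberately not reproduced
  (see the matching note above); comparisons with tools that count pairs
  will differ in the third decimal on large sets.
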