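---
title: "Window-based HERV alignment: methods and design notes"
author: "WHAseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Window-based HERV alignment: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(WHAseq)
```

## The problem

The human genome carries roughly 3,200 near-full-length ("autonomous")
endogenous retrovirus (HERV) loci whose long terminal repeats can drive
transcription. Because HERV copies are highly similar to one another,
conventional read counting cannot safely say *which* locus is
transcribed, and a handful of spurious multi-mapped reads can make a
silent locus look active. Window-based HERV Alignment (WHA) addresses
both problems at once by demanding *extended* transcription evidence:
a locus is only called transcribed when sustained read depth is seen
across many consecutive sections of the locus, from reads that match
that locus nearly perfectly.

## The WHA procedure

1. **Window tiling.** Each locus of length $L$ is divided into
   $\lfloor L / w \rfloor$ sequential, non-overlapping windows of
   exactly $w$ bp starting at the locus 5' end. The trailing partial
   remainder is discarded rather than rescaled, so all windows are the
   same length and a single depth threshold applies uniformly. Users
   should pick a window size that divides typical locus lengths well;
   the default $w = 500$ bp gives at least 16 full windows for the
   8--10 kb loci the method targets, so the 9-window criterion below
   remains demanding.
2. **Identity-filtered locus attribution.** Reads are aligned against
   the locus catalogue and only alignments with percent identity
   *strictly greater than* 99 are kept — a read at exactly 99.0% is
   discarded. Identity is `matches / aligned_length * 100` where the
   denominator is the aligned (non-soft-clipped) span, and every
   inserted or deleted base counts as a mismatch. A read whose best
   identity is tied across two or more distinct loci is discarded as
   ambiguous (and counted in the filter log), because locus-specific
   attribution is the point of the method.
3. **Per-window depth.** The depth of a window is the mean per-base
   coverage within it: total retained aligned bases falling in the
   window divided by $w$. The mean (rather than read-start counts or
   the per-base minimum) makes the threshold scale-free in window
   size; a per-base *minimum* depth variant can be obtained by
   summarising the coverage vector differently, and the per-base
   coverage is exposed through `computeWindowCoverage()`.
4. **Positive/negative call.** A window is *usable* when its depth is
   at least 3. A locus is **positive** when at least 9 windows are
   usable and **negative** otherwise (8 or fewer usable windows, or
   depth everywhere below 3). With 500 bp windows, 9 usable windows
   correspond to at least 4.5 kb of covered transcript — extended
   transcription, not isolated read pileups.
5. **Duplicate-run consensus.** Each sample is processed as duplicate
   technical runs. The default consensus is the *intersection* rule: a
   locus is positive for the sample only when positive in every run,
   with the consensus usable-window count reported as the minimum
   across runs. This is the conservative choice for an analysis whose
   conclusions rest on robust positives; `union` and `single` modes
   are available through the `consensus` argument.

## Cohort analysis

* **Control exclusion.** Any locus with *any detectable signal* in any
  healthy-control sample is removed before patient-cohort analysis.
  "Detectable signal" is deliberately weaker than a positive call: one
  identity-filtered retained read in one control (any cell type, any
  run) suffices. Controls are pooled donor-wide for this trigger; the
  per-cell-type structure is retained in the index for inspection, and
  `buildControlIndex(level = "call")` switches to call-level exclusion
  for users who prefer the laxer filter.
* **Ranking.** Surviving loci are scored by the number of patient
  samples in which they are positive, sorted descending with ties
  broken by ascending genomic position (a deterministic,
  permutation-stable order), and the top 10 are kept for display.
* **Subset intersection.** For monocyte subsets (CD14+ vs CD16+), a
  locus belongs to a subset when positive in at least one sample of
  that subset; every detected locus then falls into exactly one
  membership pattern, whose counts are the numbers an UpSet plot
  displays.
* **Cross-cell-type summary.** Per-locus patient-detection counts per
  cell type, with loci detected in exactly one cell type flagged
  `exclusive_cell_type` — the monocyte-exclusive candidate set.

## Host-gene statistics

Host genes hosting a HERV locus (e.g. the chemokine receptor gene
xCR1) are profiled with the *same* machinery: reads are realigned to
the gene sequence under the same identity filter and windowing, giving
a per-sample usable-window count and mean per-base depth. Groups
(e.g. patients vs controls, or lavage samples stratified into
HERV-positive and HERV-negative subsets by a key locus call) are
compared by one-way ANOVA followed by Tukey's HSD over all group
pairs at $\alpha = 0.05$; no further multiple-testing correction is
applied beyond Tukey's family-wise control. Depths are raw (not
library-size normalised); with duplicate runs, the per-sample metric
is the mean of the two run profiles. When neither metric varies at
all, the F statistic is undefined and the comparison is reported
non-significant with a warning rather than an error.

## The synthetic-data generator

Real cohorts of this kind live in controlled-access repositories, so
the package ships a generator that produces a complete, fully
deterministic cohort with planted ground truth:

* a locus catalogue of random sequences, 8--10 kb, on cycling
  chromosomes;
* a cohort of 12 patients and 30 controls (the default cohort shape),
  each with a barcode-to-cell-type annotation table over seven PBMC
  cell types and a mapping score in [0.8, 1];
* per-sample duplicate-run FASTQ files whose reads carry their cell
  barcode in the read name (`<id>|<barcode>`), drawn from an
  *expression plan* stating expected per-window depth and expressed
  fraction per (group, cell type, locus);
* a truth table of every planted positive (sample, cell type, locus)
  triple.

Reads are drawn uniformly over a covered prefix of the locus spanning
`round(fraction * nWindows)` windows, so a fraction of $8/16$ plants
*exactly* 8 covered windows and probes the 9-window boundary directly.
Read counts are Poisson with mean `depth * coveredLength /
readLength`, so the mean depth over the covered region converges to
the planned value; the first and last ~read-length of the covered
region have slightly lower expected coverage (edge effect), which is
why planted depths in tests sit comfortably above the threshold.
Substitution errors are i.i.d. per base. Note an arithmetic
consequence of the strict identity rule: at the default 90 bp read
length, a single substitution already drops a read to 98.9% identity,
below the >99% cutoff, so the retained fraction is $(1-e)^{90}$ — about
0.91 at the default error rate $e = 0.001$ and about 0.64 at
$e = 0.005$. The generator's default error rate is therefore 0.001,
and planted depths of 8 keep effective depths well above 3 even at
0.5% error.

What the generator does *not* emulate: UMIs and PCR duplication,
cell-type misannotation, transcript-length and positional bias,
indels (substitution-only by default), and the paralogous-family
structure of real HERV copies (loci are independent random sequences,
so cross-locus ambiguity is rare rather than pervasive). Passing
tests on synthetic data therefore demonstrate the correctness of the
calling logic and thresholds, not the adequacy of the >99% filter for
separating real paralogs.

## The built-in aligner

The package includes a small exact-k-mer-seeded, ungapped
seed-and-extend aligner (Rcpp) adequate for the synthetic reads the
generator produces: seeds are non-overlapping k-mers of the read
(default k = 21) plus the final k-mer, each hit proposes a diagonal,
and the full read is scored base-by-base on that diagonal, clipped at
locus boundaries. It is not a production short-read aligner; real
data should be aligned externally and ingested as SAM via
`readSamAlignments()`, which recomputes identity from CIGAR and `NM`
(or by direct comparison to the reference when `NM` is absent) and
applies the identical strict filter.

## Numerical and design choices

* Thresholds default to the method's published operating point:
  identity > 99 (strict), window depth ≥ 3, ≥ 9 usable windows,
  top-10 ranking, $\alpha = 0.05$, intersection consensus, 500 bp
  windows.
* Identity ties across loci are resolved by discarding the read;
  within a locus, the best diagonal wins.
* Window depths are compared to the threshold with plain `>=` on
  doubles; depths are ratios of integer base counts to the window
  size, so the 2.9/3.0 boundary is exact.
* All randomness flows from a single integer seed through
  per-(sample, run) derived sub-seeds below $2^{31}$; outputs are
  byte-identical across repeated runs, and the run manifest records
  the configuration and its digest (no timestamps, so manifests are
  reproducible too).
* Locus identifiers are 1-based inclusive (`Chr3:46046256-46054342`);
  BED input/output is 0-based half-open; the identifier parser
  tolerates thousands separators and en-dashes.

## Problem sizes used in the test suite

The package's own checks run a full 12-patient/30-control cohort with
planted CD14-exclusive, shared-monocyte and B-cell loci (about
140,000 reads per condition, at 0% and 0.5% substitution error) plus
many small targeted fixtures; the complete suite runs in about a
minute on one CPU. These sizes were chosen as the smallest cohort
that exercises every stage at the default cohort shape.

## Known limitations

* The ungapped built-in aligner under-scores reads containing indels
  (they surface as runs of mismatches); use external SAM input for
  indel-aware identity.
* Control exclusion is donor-wide: a locus with signal in any control
  cell type is excluded for all patient cell types. This is the
  stricter reading; per-cell-type exclusion can be emulated by
  building per-cell-type control indices from the alignment table.
* Host-gene depths are not normalised for library size; comparisons
  assume broadly comparable sequencing depth across groups.
* How duplicate runs are best combined is a genuinely open choice;
  the intersection rule is the package's conservative default, not an
  assertion about the only valid analysis.
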