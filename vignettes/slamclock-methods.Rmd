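---
title: "Metabolic RNA labeling analysis with slamclock: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metabolic RNA labeling analysis with slamclock: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slamclock)
```

## Overview

SLAM-seq and its single-cell variant label newly transcribed RNA with
4-thiouridine (4sU). After iodoacetamide alkylation, incorporated 4sU
misreads during reverse transcription and appears in sequencing data as a
thymine-to-cytosine substitution in transcript sense (a genomic A-to-G for
genes on the minus strand). `slamclock` turns that chemical signal into
three quantitative layers:

1. **Conversion calling** — per-read and per-position T-to-C counting with
   quality filtering and single-nucleotide-variant (SNV) masking;
2. **Molecule classification** — labeled/unlabeled calls per molecule
   (UMI) and paired count matrices;
3. **Inference** — per-gene RNA half-lives from a labeling time course,
   and a background-corrected injury-response statistic comparing nascent
   transcription between paired conditions.

A synthetic-data generator with fully known ground truth backs every layer,
so each guarantee the package makes is tested against an independent
oracle.

## Conversion calling

A read contributes, at each aligned position, its reference base, read
base and Phred quality. Only substitutions can carry label signal:
deleted reference bases yield no events, insertions consume no reference
coordinate, and `N` bases are ignored. Counting is strand aware — for a
minus-strand gene the transcript-sense T-to-C is the genomic A-to-G.

Three filters act on a position before it is counted:

* **Quality**: bases below Phred 20 are excluded (the default mirrors the
  common Q20 practice for conversion-based methods).
* **SNV blacklist**: a position with at least 10 reads of coverage of
  which at least 25% carry the conversion is far more likely a genetic
  variant than labeling, and is masked. Positions with fewer than 10
  reads cannot be classified; by default they remain usable for
  conversion counting and are only excluded from SNV classification,
  because discarding them outright costs signal at the ends of coverage
  islands. A `strict_low_coverage` mode masks them as well for users who
  prefer the conservative reading.
* Masked positions are removed from **both the numerator and the
  denominator** of every conversion rate, keeping the rate an unbiased
  per-eligible-site estimate. (Whether the denominator should also be
  reduced is genuinely ambiguous in the field; including masked sites in
  the denominator would bias rates downward at heavily masked genes,
  which is why we exclude them.)

The conversion rate of a group of reads is the pooled ratio
`sum(n_tc) / sum(n_t_covered)`; groups with an empty denominator are
reported as missing rather than zero, since "no eligible sites" and "no
conversions" are different observations.

Coordinates are 0-based half-open internally; SAM input (1-based) is
converted at ingest. Mismatch information is reconstructed from the MD
tag and CIGAR string, or from a reference FASTA when MD tags are absent.

## Molecule classification and detection model

All reads sharing a (cell barcode, UMI, gene) key sample the same original
molecule, so the molecule's evidence is the **union of distinct converted
positions** across its reads — two reads confirming the same position are
one conversion, not two. A molecule is labeled when it shows at least
`k_min` distinct conversions; the default `k_min = 1` is the primary
analysis mode, and `k_min = 2` is exposed as a stringency check (it
suppresses false positives at the cost of a marked drop in labeled
fraction).

A truly labeled molecule converts each of its `n_t` observed thymines
independently with probability `p_c`, so detection fails with probability
`(1 - p_c)^{n_t}`. At the working point `p_c = 0.037` and `n_t = 50`
(about 50 thymines in a 200 nt read of uniform base composition) the
false negative rate is

```{r}
detection_probability(detection_model(p_c = 0.037, n_t = 50))$fnr
```

i.e. roughly 15% of newly transcribed molecules go undetected. Because
labeled calls condition on at least one conversion, the naive per-thymine
rate among labeled reads overestimates `p_c`;
`estimate_pc_zero_truncated()` corrects this with a zero-truncated
binomial maximum-likelihood fit. Where the thymine count per read varies,
the expectation is taken over a zero-truncated Poisson with the stated
mean; the default is a point mass at 50 because only the mean is usually
known.

## Half-life estimation

Under steady-state transcription and first-order decay at rate
$\lambda$, the labeled fraction of a gene's molecules after a labeling
time $t$ follows the exponential-saturation curve

$$ f(t) = \alpha\,(1 - e^{-\lambda t}), \qquad \tau = \ln 2 / \lambda . $$

The plateau $\alpha$ absorbs incomplete 4sU incorporation and detection
false negatives. The default mode leaves $\alpha$ free in $(0.05, 1]$;
`alpha_mode = "fixed_1"` provides the textbook model, which also permits
single-point closed-form inversion. Fits are weighted by the molecule
counts behind each observed fraction, replicates enter as separate points,
and half-lives are constrained to 0.5–48 h. Points after 12 h are excluded
by default: a single label injection is exhausted around a day, which
flattens late points below the model curve (the generator reproduces this
with an optional availability-decay term).

Numerically, the plateau has a closed-form weighted least-squares solution
at fixed $\lambda$, so the fit reduces to a one-dimensional search over
$\log \lambda$: a deterministic 25-point log-spaced grid across the
half-life bounds followed by local refinement with `stats::optimize()`.
No randomness is involved, noiseless curves are inverted to better than
$10^{-6}$ relative accuracy, and a fit that lands on a bound or has zero
total variance is flagged `converged = FALSE` rather than reported.
Genes with fewer than 4 usable points (3 distinct times) produce explicit
"unfittable" rows. Summaries count only converged fits with $R^2 > 0.7$
and in-bounds half-lives.

On the package's own benchmark — 200 genes with half-lives log-uniform on
0.5–48 h, timepoints {0.5, 1, 3, 6, 12} h, 3 replicates, 500 molecules per
gene and timepoint — the fitter recovers half-lives with a median absolute
relative error of about 3% and no systematic sign bias (both measured by
`scripts/acceptance.R`). These sizes were chosen as representative of a
well-powered bulk time course while keeping the benchmark fast.

## Injury-response statistic

The experimental design pairs a sham and an injured sample with identical
4sU injection and labeling windows. Molecules transcribed after the
intervention are labeled; pre-existing RNA is not. The response of a gene
in a cell type is the ratio of its **labeled** pseudo-bulk expression in
the injured condition over sham:

* pseudo-bulk labeled counts per gene over the cell type's cells;
* expected falsely-labeled counts subtracted (floored at zero);
* normalization to counts per 10^4 of the corrected labeled library;
* a pseudocount added; then the ratio $R$ and $\log_2 R$.

Under the assumption that decay rates do not change upon injury, $R$
depends only on labeled molecules: it is exactly invariant to arbitrary
changes of the unlabeled pools and to global rescaling of either
condition's labeled library. The implementation preserves both
invariances bit-for-bit, which dictated one ordering choice: the
pseudocount is added **after** library normalization, because an offset
added before normalization would break the exact cancellation of library
scale in the ratio. (With the pseudocount taken to zero the statistic
reduces to the plain normalized labeled ratio.) The pseudocount of 1 on
the counts-per-10k scale stabilizes low-count genes and keeps
zero-in-sham genes reportable; it also shrinks large ratios of weakly
expressed genes toward 1, which is intentional — a 4-fold induction
measured on a handful of molecules should not outrank a 3-fold induction
measured on hundreds.

**Background model.** Sequencing and chemistry errors convert thymines in
unlabeled molecules too, so a fraction
$1 - (1-\varepsilon)^{n_t}$ of the unlabeled pool is miscalled labeled.
When pre-existing pools differ between conditions — and after an injury
they generally do — this leakage biases the uncorrected ratio. The
per-thymine error probability $\varepsilon$ is estimated as the median
rate of the 11 substitution types other than transcript-sense T-to-C,
none of which carries label signal; the expected false-labeled count per
gene and condition is then subtracted before the ratio. The interface
also accepts a directly supplied $\varepsilon$ (e.g. from a no-4sU
control library). With $\varepsilon = 0$ the corrected and uncorrected
statistics coincide exactly.

**Significance.** The null distribution is built by permuting condition
labels across the cell type's pooled cells (preserving group sizes) and
recomputing the entire statistic — background correction and
normalization included — for each permutation;
$p = (1 + \#\{|\log_2 R_\text{null}| \ge |\log_2 R_\text{obs}|\}) /
(1 + n_\text{perm})$, with Benjamini–Hochberg correction across tested
genes. For small cell numbers an exact mode enumerates every assignment.
Genes whose corrected labeled counts sum below 5 across both conditions
are reported as untested rather than silently dropped; a ratio of
near-zero counts is noise, not evidence. The default responsive-gene call
(q < 0.05 and $\log_2 R > 1$) is a convention, exposed as parameters.

**Pathway layers.** For interpreting responses along a signaling cascade
(receptors, adaptors, effectors), `pathway_layer_score()` reports, per
cell, the percentage of total counts falling on a gene set, aggregated as
mean ± SEM per cell group.

## What the synthetic data emulates — and what it does not

`simulate_bulk_timecourse()` generates aligned reads from a synthetic
two-strand genome: Poisson steady-state molecule counts, labeling
probability $1 - e^{-\lambda t}$, per-thymine conversions at `p_c`,
uniform per-base substitution errors at `epsilon` per specific type,
optional homozygous SNV positions, optional 4sU-availability decay, and a
constant base quality. Default reads are 200 nt so that a uniform base
composition yields the stated mean of 50 thymines per read.
`simulate_sc_injury()` generates paired sham/injured labeled+unlabeled
matrices over at least two cell types, with a known induced gene set
(default 50 genes at fold 4 in the first cell type), log-normal expression
profiles, deliberately **unequal** pre-existing unlabeled pools between
conditions (to exercise the invariance claims and the background model),
detection thinning by the false-negative rate, and false labeling at the
error rate. Defaults (500 cells per condition in the focal type, 2,000
genes, ~22% labeled fraction, labeling window 7 h) reflect a realistic
single-run droplet experiment. A single seeded RNG stream makes every
simulation byte-reproducible.

Deliberately not modeled: position-dependent quality and error profiles,
indels, UMI sequencing errors (collapsing is assumed upstream), ambient
RNA, doublets, and cell-type abundance shifts. Passing tests on this
generator therefore demonstrate correctness of the statistical machinery
under its stated assumptions — not robustness to every artifact of real
libraries. The SNV masking and background layers address the two
artifacts the method is most sensitive to; the rest are upstream QC
concerns.

One consequence observed in the package's own calibration check: with
unequal unlabeled pools and $\varepsilon > 0$, the *uncorrected*
permutation test is measurably anti-conservative (type-I error ~0.06–0.07
at $\alpha = 0.05$), while the background-corrected test is calibrated.
This is the expected behavior, and it is why the background model is on
by default in the acceptance pipeline.

## Numerical and design choices

* 0-based half-open coordinates internally; conversion at SAM ingest.
* Ties at thresholds are inclusive: exactly 25% conversion fraction at
  exactly 10 reads is blacklisted; `qual == min_qual` passes.
* Reads overlapping no annotated gene contribute to global conversion
  rates but not to per-gene tallies or matrices.
* The decay optimizer's grid/refine search is deterministic; confidence
  intervals come from the Gauss–Newton curvature at the optimum and are
  omitted (NA) when the information matrix is singular.
* The permutation test vectorizes all permutations as one sparse
  matrix–matrix product, which keeps 1,000 permutations over 1,000 cells
  and 2,000 genes in a few seconds.
* Problem sizes in tests and in `scripts/acceptance.R` (200-gene time
  courses, 2,000-gene/1,200-cell injury simulations, 3 pooled null
  replicates) were fixed once as representative desk-scale versions of
  the designs above.

## Known limitations

* The half-life model assumes steady state during labeling; transcription
  bursts or labeling-time misrecording bias $\tau$.
* For half-lives far above the last timepoint (here 12 h), $\alpha$ and
  $\lambda$ are weakly identified in free-plateau mode; such fits
  typically fail the $R^2$ filter and are excluded from summaries.
* The injury-response statistic assumes decay rates are injury-invariant
  over the labeling window; a gene whose induction acts through
  stabilization rather than transcription will be under-called.
* The background model treats errors as uniform across positions and
  molecules; a position-specific error process is better handled by
  SNV-style masking or a matched no-label control, which the pluggable
  `epsilon` input supports.
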