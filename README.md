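# slamclock

Analysis toolkit for metabolic RNA labeling experiments (SLAM-seq and
single-cell scSLAM-seq). In these experiments, 4-thiouridine (4sU)
incorporates into RNA transcribed during a labeling window; after
iodoacetamide alkylation, incorporated 4sU misreads during reverse
transcription and shows up in sequencing data as transcript-sense
**T-to-C substitutions**. Reading those substitutions separates each
gene's RNA into *new* (transcribed during the window) and *old*
(pre-existing) — a two-timepoint measurement inside every sample, and in
single cells, inside every cell.

`slamclock` is for groups applying this readout in vivo — e.g. to the
early injury response of a regenerating organ — and covers:

* **Conversion calling**: per-read and per-position transcript-sense
  T-to-C counting from SAM/BAM (MD-tag or reference-FASTA mismatch
  reconstruction), Phred quality filtering, and SNV masking (positions
  with ≥ 25% conversion at ≥ 10 reads of coverage are blacklisted as
  probable variants).
* **Molecule classification**: labeled/unlabeled calls per UMI (union of
  distinct conversions across reads, threshold `k_min`), paired
  labeled/unlabeled count matrices (Matrix Market output), and a
  detection model — a labeled molecule with `n_t` thymines is missed with
  probability `(1 − p_c)^{n_t}`, about 15% at `p_c = 0.037`, `n_t = 50`.
* **RNA half-lives**: per-gene fits of the saturation model
  `f(t) = α(1 − e^(−λt))`, `τ = ln2/λ`, to labeled-fraction time
  courses, with bounded deterministic optimization, `R²` quality
  filtering and half-life summaries.
* **Injury-response statistic**: per gene and cell type, the ratio `R`
  of background-corrected, library-normalized *labeled* pseudo-bulk
  expression in injured over sham condition — by construction independent
  of pre-existing unlabeled RNA — with permutation significance and BH
  correction, plus pathway-layer "percent of transcriptome" scores.
* **Synthetic data**: read-level bulk time courses and paired
  sham/injured single-cell matrices with fully known ground truth, used
  throughout the test suite.

## Worked example: half-lives from a labeling time course

```r
library(slamclock)

cfg <- sim_config(n_genes = 20, timepoints = c(0.5, 1, 3, 6, 12),
                  replicates = 3)
sim <- simulate_timecourse_counts(cfg, seed = 42, n_molecules = 500)
fits <- fit_decay_all(sim$counts)
head(fits[, c("gene_id", "tau", "alpha", "r2", "converged")], 5)
#>   gene_id    tau alpha    r2 converged
#> 1 gene001  2.802 0.997 0.997      TRUE
#> 2 gene002  3.641 1.000 0.998      TRUE
#> 3 gene003  0.569 0.998 0.991      TRUE
#> 4 gene004 39.917 1.000 0.984      TRUE
#> 5 gene005  3.534 1.000 0.993      TRUE

sm <- summarize_halflives(fits)       # converged, r2 > 0.7, tau in bounds
#> 20 of 20 genes pass r2 > 0.7; median half-life 4.41 h
#> (true median half-life of the same genes: 4.44 h)
```

`tau` is the half-life in hours, `alpha` the labeling plateau (absorbing
incomplete incorporation and detection false negatives), `r2` the fit
quality; the generating half-lives are recovered within a few percent.

## Worked example: injury response in single cells

```r
sim <- simulate_sc_injury(n_genes = 500,
                          cell_types = c(macrophage_like = 100,
                                         endothelial = 30),
                          n_induced = 10, induced_fold = 4, seed = 42)
ann <- sim$annotations
ctm <- function(cond) setNames(ann$cell_type[ann$condition == cond],
                               ann$barcode[ann$condition == cond])
pair <- condition_pair(sim$sham, sim$injured, ctm("sham"), ctm("injured"))
bg <- estimate_background(epsilon = 1e-3, n_t = 50)
res <- permutation_test(pair, "macrophage_like", bg = bg,
                        n_perm = 5000, seed = 43)
head(responsive_genes(res)[, c("gene_id", "response_ratio", "log2_r",
                               "p_perm", "q", "responsive")], 5)
#>      gene_id response_ratio log2_r p_perm      q responsive
#> 76  gene0076           4.51   2.17  2e-04 0.0132       TRUE
#> 448 gene0448           3.98   1.99  2e-04 0.0132       TRUE
#> 88  gene0088           3.91   1.97  2e-04 0.0132       TRUE
#> 20  gene0020           3.77   1.91  2e-04 0.0132       TRUE
#> 298 gene0298           3.40   1.77  2e-04 0.0132       TRUE
```

Here every gene called responsive (q < 0.05, log2 R > 1) is one of the
ten genes the simulation truly induced. `response_ratio` is the
labeled-RNA ratio injured/sham after background correction, library
normalization and a pseudocount, so large ratios on tiny counts are
shrunk toward 1.

The full pipeline (conversion calling → SNV masking → quantification →
half-lives / injury response) is also available as one call,
`run_pipeline(pipeline_config(...), out_dir)`, which writes TSV/MTX/BED
artifacts, a YAML config echo and a JSON run manifest.

See the methods vignette (`vignettes/slamclock-methods.Rmd`) for the
models, their assumptions, and the numerical choices.

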