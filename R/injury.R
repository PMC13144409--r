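#' Paired sham/injured condition data
#'
#' Bundles the labeled/unlabeled matrices of the two conditions of a
#' labeling-matched injury experiment: label injected at steady state, the
#' injury (or sham operation) applied during the labeling window, both
#' conditions sampled after the identical labeling time. That symmetry is
#' what makes the labeled-RNA ratio interpretable as an injury response.
#'
#' @param sham,injured [labeled_matrices()] of each condition.
#' @param sham_cell_types,injured_cell_types named character vectors mapping
#'   cell barcode to cell type (names = barcodes).
#' @param labeling_time labeling window in hours (identical by design).
#' @return Object of class `condition_pair` with a shared, intersected gene
#'   index.
#' @export
condition_pair <- function(sham, injured, sham_cell_types,
                           injured_cell_types, labeling_time = 7) {
  stopifnot(inherits(sham, "labeled_matrices"),
            inherits(injured, "labeled_matrices"))
  genes <- intersect(rownames(sham$labeled), rownames(injured$labeled))
  if (length(genes) == 0L) stopf("conditions share no genes")
  sub <- function(m, cells_map) {
    cells <- intersect(colnames(m$labeled), names(cells_map))
    if (length(cells) == 0L) stopf("no annotated cells found in matrix")
    labeled_matrices(m$labeled[genes, cells, drop = FALSE],
                     m$unlabeled[genes, cells, drop = FALSE])
  }
  structure(list(sham = sub(sham, sham_cell_types),
                 injured = sub(injured, injured_cell_types),
                 sham_cell_types = sham_cell_types,
                 injured_cell_types = injured_cell_types,
                 labeling_time = labeling_time,
                 genes = genes),
            class = "condition_pair")
}

#' Background model for false labeled calls
#'
#' Sequencing and chemistry errors convert thymines in unlabeled molecules
#' too, so some unlabeled molecules are miscalled labeled. The background
#' per-thymine error probability is estimated as the median rate of the 11
#' substitution types other than transcript-sense T-to-C (which carries the
#' label signal); the expected number of falsely labeled molecules in a
#' pool of `U` unlabeled molecules is then `U * (1 - (1 - epsilon)^n_t)`.
#'
#' @param x either a list of [slam_read()] or a spectrum data.frame from
#'   [substitution_spectrum()]. Alternatively pass `epsilon` directly (e.g.
#'   from a no-label control library) and leave `x` NULL.
#' @param n_t mean thymines covered per molecule read (default 50).
#' @param min_qual quality filter used when tallying the spectrum.
#' @param epsilon directly supplied background probability (overrides `x`).
#' @return Object of class `background_model` with `epsilon_hat`, `n_t`,
#'   and the spectrum used (or NULL).
#' @export
estimate_background <- function(x = NULL, n_t = 50, min_qual = 20,
                                epsilon = NULL) {
  spec <- NULL
  if (is.null(epsilon)) {
    if (is.null(x)) stopf("supply reads, a substitution spectrum, or epsilon")
    spec <- if (is.data.frame(x)) x else substitution_spectrum(x, min_qual)
    non_tc <- spec[!(spec$ref == "T" & spec$alt == "C"), , drop = FALSE]
    rates <- non_tc$rate[!is.na(non_tc$rate)]
    if (length(rates) == 0L) {
      stopf("no non-(T-to-C) sites observed; cannot estimate background")
    }
    epsilon <- median(rates)
  }
  if (!is_prob(epsilon) || epsilon > 0.05) {
    stopf("background epsilon must lie in [0, 0.05]; got %g", epsilon)
  }
  structure(list(epsilon_hat = epsilon, n_t = n_t, spectrum = spec),
            class = "background_model")
}

#' Expected falsely-labeled molecule count
#'
#' @param bg a [background_model()].
#' @param unlabeled_counts numeric vector/matrix of unlabeled molecule
#'   counts.
#' @param k_min conversions required for a labeled call (default 1).
#' @return expected count of unlabeled molecules miscalled labeled, same
#'   shape as `unlabeled_counts`.
#' @export
expected_false_labeled <- function(bg, unlabeled_counts, k_min = 1) {
  eps <- bg$epsilon_hat
  n <- bg$n_t
  p_false <- if (k_min == 1) {
    1 - (1 - eps)^n
  } else if (k_min == 2) {
    1 - (1 - eps)^n - n * eps * (1 - eps)^(n - 1)
  } else {
    stats::pbinom(k_min - 1, size = round(n), prob = eps, lower.tail = FALSE)
  }
  unlabeled_counts * p_false
}

# pseudo-bulk labeled/unlabeled counts of one cell type in one condition
pseudobulk_ct <- function(m, cell_types, cell_type) {
  cells <- names(cell_types)[cell_types == cell_type]
  cells <- intersect(colnames(m$labeled), cells)
  list(cells = cells,
       labeled = Matrix::rowSums(m$labeled[, cells, drop = FALSE]),
       unlabeled = Matrix::rowSums(m$unlabeled[, cells, drop = FALSE]))
}

# corrected, normalized, pseudocounted labeled expression.
# Normalization precedes the pseudocount so that a global scaling of the
# labeled counts cancels exactly in the ratio.
l_hat <- function(labeled, unlabeled, bg, pseudocount, scale) {
  corrected <- if (is.null(bg)) labeled else {
    pmax(labeled - expected_false_labeled(bg, unlabeled), 0)
  }
  lib <- sum(corrected)
  if (lib <= 0) stopf("corrected labeled library size is zero")
  list(l_hat = corrected / lib * scale + pseudocount, corrected = corrected)
}

#' Injury-response ratio of nascent RNA
#'
#' Per-gene response statistic for one cell type: the ratio of
#' background-corrected, library-normalized pseudo-bulk *labeled* (newly
#' transcribed) expression in the injured condition over the sham
#' condition. Because only molecules transcribed during the shared labeling
#' window enter the statistic, it is independent of the pre-existing
#' unlabeled RNA pool and, under the assumption that decay rates do not
#' change upon injury, of mRNA stability.
#'
#' Per condition: labeled pseudo-bulk counts are background-subtracted
#' (floored at 0), normalized to counts per `scale` of the corrected
#' labeled library, and offset by `pseudocount`; the response is
#' `R = l_hat_injured / l_hat_sham`.
#'
#' @param pair a [condition_pair()].
#' @param cell_type cell type to test (must be present in both conditions).
#' @param bg a [background_model()] or `NULL` for no correction.
#' @param pseudocount offset added to normalized expression (default 1).
#' @param min_count a gene is tested only when its corrected labeled counts
#'   summed over both conditions reach this value (default 5); other genes
#'   are reported with `tested = FALSE`, not dropped.
#' @param min_cells minimum cells of the type per condition (default 2).
#' @param scale library normalization target (default 1e4).
#' @return data.frame with `gene_id`, `cell_type`, `l_hat_sham`,
#'   `l_hat_inj`, `response_ratio`, `log2_r`, `tested`, `pseudocount`.
#' @export
injury_response <- function(pair, cell_type, bg = NULL, pseudocount = 1,
                            min_count = 5, min_cells = 2, scale = 1e4) {
  stopifnot(inherits(pair, "condition_pair"))
  pb_s <- pseudobulk_ct(pair$sham, pair$sham_cell_types, cell_type)
  pb_i <- pseudobulk_ct(pair$injured, pair$injured_cell_types, cell_type)
  if (length(pb_s$cells) < min_cells || length(pb_i$cells) < min_cells) {
    stopf("cell type '%s' has fewer than %d cells in one condition",
          cell_type, min_cells)
  }
  hs <- l_hat(pb_s$labeled, pb_s$unlabeled, bg, pseudocount, scale)
  hi <- l_hat(pb_i$labeled, pb_i$unlabeled, bg, pseudocount, scale)
  tested <- (hs$corrected + hi$corrected) >= min_count
  r <- hi$l_hat / hs$l_hat
  data.frame(gene_id = pair$genes, cell_type = cell_type,
             l_hat_sham = as.numeric(hs$l_hat),
             l_hat_inj = as.numeric(hi$l_hat),
             response_ratio = as.numeric(r), log2_r = log2(as.numeric(r)),
             tested = as.logical(tested), pseudocount = pseudocount,
             stringsAsFactors = FALSE, row.names = NULL)
}

# response ratios for many condition assignments at once.
# labeled/unlabeled: gene x cell matrices over the pooled cells;
# assign: cells x n_assignments logical matrix, TRUE = injured.
ratio_matrix <- function(labeled, unlabeled, assign, bg, pseudocount, scale) {
  a <- 1 * assign
  li <- as.matrix(labeled %*% a)
  ls <- as.matrix(labeled %*% (1 - a))
  if (!is.null(bg)) {
    ui <- as.matrix(unlabeled %*% a)
    us <- as.matrix(unlabeled %*% (1 - a))
    li <- pmax(li - expected_false_labeled(bg, ui), 0)
    ls <- pmax(ls - expected_false_labeled(bg, us), 0)
  }
  li <- sweep(li, 2L, colSums(li), "/") * scale + pseudocount
  ls <- sweep(ls, 2L, colSums(ls), "/") * scale + pseudocount
  li / ls
}

#' Permutation significance for the injury response
#'
#' Builds the null distribution of the response ratio by permuting the
#' condition labels across the pooled cells of one cell type (keeping the
#' group sizes) and recomputing the full statistic — including background
#' correction and normalization — for every permutation. The empirical
#' p-value uses the add-one estimator
#' `p = (1 + #\{|log2 R_null| >= |log2 R_obs|\}) / (1 + n_perm)`;
#' Benjamini-Hochberg correction is applied across tested genes.
#'
#' With `exact = TRUE` every distinct condition assignment is enumerated
#' (feasible for small cell numbers) and `p` is the exact fraction of
#' assignments at least as extreme as the observed one.
#'
#' @inheritParams injury_response
#' @param n_perm number of permutations (default 1000; at least 10).
#' @param seed RNG seed (required unless `exact = TRUE`).
#' @param exact enumerate all assignments instead of sampling.
#' @param max_exact refuse exact enumeration beyond this many assignments.
#' @return the [injury_response()] table with extra columns `p_perm` and
#'   `q` (`NA` for untested genes), plus attributes `n_perm` and `seed`.
#' @export
permutation_test <- function(pair, cell_type, bg = NULL, n_perm = 1000,
                             seed = NULL, pseudocount = 1, min_count = 5,
                             min_cells = 2, scale = 1e4, exact = FALSE,
                             max_exact = 20000) {
  if (!exact) {
    if (!is_count(n_perm) || n_perm < 10) stopf("n_perm must be >= 10")
    if (is.null(seed)) stopf("a seed is required for the permutation test")
  }
  obs <- injury_response(pair, cell_type, bg = bg, pseudocount = pseudocount,
                         min_count = min_count, min_cells = min_cells,
                         scale = scale)
  pb_s <- pseudobulk_ct(pair$sham, pair$sham_cell_types, cell_type)
  pb_i <- pseudobulk_ct(pair$injured, pair$injured_cell_types, cell_type)
  labeled <- cbind(pair$sham$labeled[, pb_s$cells, drop = FALSE],
                   pair$injured$labeled[, pb_i$cells, drop = FALSE])
  unlabeled <- cbind(pair$sham$unlabeled[, pb_s$cells, drop = FALSE],
                     pair$injured$unlabeled[, pb_i$cells, drop = FALSE])
  n_s <- length(pb_s$cells); n_i <- length(pb_i$cells)
  n_cells <- n_s + n_i
  if (min(n_s, n_i) < 2L) stopf("need >= 2 cells per condition")

  if (exact) {
    if (choose(n_cells, n_i) > max_exact) {
      stopf("exact enumeration infeasible: %g assignments",
            choose(n_cells, n_i))
    }
    sets <- combn(n_cells, n_i)
    assign <- matrix(FALSE, n_cells, ncol(sets))
    assign[cbind(as.vector(sets), rep(seq_len(ncol(sets)), each = n_i))] <- TRUE
    n_perm <- ncol(sets)
  } else {
    set.seed(seed)
    assign <- matrix(FALSE, n_cells, n_perm)
    for (j in seq_len(n_perm)) {
      assign[sample.int(n_cells, n_i), j] <- TRUE
    }
  }
  r_null <- ratio_matrix(labeled, unlabeled, assign, bg, pseudocount, scale)
  stat_obs <- abs(obs$log2_r)
  exceed <- rowSums(abs(log2(r_null)) >= stat_obs)
  p <- if (exact) exceed / n_perm else (1 + exceed) / (1 + n_perm)
  obs$p_perm <- ifelse(obs$tested, p, NA_real_)
  obs$q <- NA_real_
  obs$q[obs$tested] <- p.adjust(obs$p_perm[obs$tested], method = "BH")
  attr(obs, "n_perm") <- n_perm
  attr(obs, "seed") <- if (exact) NA_integer_ else seed
  obs
}

#' Call injury-responsive genes
#'
#' @param result table from [permutation_test()].
#' @param q_max,log2_min significance and effect-size cutoffs (defaults
#'   0.05 and 1, i.e. q < 0.05 and a more than 2-fold labeled-RNA
#'   increase).
#' @return the tested subset with a logical `responsive` column, ordered by
#'   decreasing `log2_r`.
#' @export
responsive_genes <- function(result, q_max = 0.05, log2_min = 1) {
  sub <- result[result$tested & !is.na(result$q), , drop = FALSE]
  sub$responsive <- sub$q < q_max & sub$log2_r > log2_min
  sub[order(-sub$log2_r), , drop = FALSE]
}

#' Gene-set layer of a signaling pathway
#'
#' @param name set name (e.g. `"TLR_layer1"`).
#' @param gene_ids nonempty character vector of member genes.
#' @param layer `"receptors"`, `"adaptors"` or `"effectors"`.
#' @return Object of class `gene_set_layer`.
#' @export
gene_set_layer <- function(name, gene_ids,
                           layer = c("receptors", "adaptors", "effectors")) {
  layer <- match.arg(layer)
  gene_ids <- unique(as.character(gene_ids))
  if (length(gene_ids) == 0L) stopf("gene set '%s' is empty", name)
  structure(list(name = name, gene_ids = gene_ids, layer = layer),
            class = "gene_set_layer")
}

#' Pathway-layer score: percent of transcriptome
#'
#' Per cell, the percentage of all counts that falls on the genes of one
#' pathway layer; aggregated as mean and standard error per cell group
#' (e.g. timepoint, or usage split of an expression program).
#'
#' @param mat gene x cell count matrix (labeled, unlabeled or total).
#' @param layer a [gene_set_layer()] or plain character vector of genes.
#' @param groups factor/character vector of length `ncol(mat)` assigning
#'   each cell to a group; default one group.
#' @return data.frame with `group`, `n_cells`, `mean_pct`, `sem_pct`.
#'   Cells with zero total counts are excluded with a warning; layer genes
#'   missing from the matrix trigger a warning.
#' @export
pathway_layer_score <- function(mat, layer, groups = NULL) {
  genes <- if (inherits(layer, "gene_set_layer")) layer$gene_ids else
    as.character(layer)
  missing <- setdiff(genes, rownames(mat))
  if (length(missing) > 0L) {
    warnf("%d of %d layer genes absent from the matrix", length(missing),
          length(genes))
  }
  genes <- intersect(genes, rownames(mat))
  if (length(genes) == 0L) stopf("no layer genes present in the matrix")
  if (is.null(groups)) groups <- rep("all", ncol(mat))
  if (length(groups) != ncol(mat)) stopf("groups must match ncol(mat)")
  total <- Matrix::colSums(mat)
  keep <- total > 0
  if (any(!keep)) {
    warnf("%d cells with zero total counts excluded", sum(!keep))
  }
  pct <- 100 * Matrix::colSums(mat[genes, keep, drop = FALSE]) / total[keep]
  g <- as.character(groups)[keep]
  out <- data.frame(group = sort(unique(g)), stringsAsFactors = FALSE)
  out$n_cells <- as.integer(table(g)[out$group])
  out$mean_pct <- as.numeric(tapply(pct, g, mean)[out$group])
  out$sem_pct <- as.numeric(tapply(pct, g, sem)[out$group])
  out
}
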