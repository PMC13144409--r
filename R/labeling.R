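#' Classify one molecule as labeled or unlabeled
#'
#' All reads of one (cell barcode, UMI, gene) key sample the same original
#' molecule, so the molecule's conversion evidence is the union of distinct
#' converted positions across its reads. The molecule is called labeled when
#' at least `k_min` distinct quality-passing, non-blacklisted conversions
#' are observed (default 1; `k_min = 2` is the stringent robustness mode).
#'
#' @param reads list of [slam_read()] sharing one (cell, UMI, gene) key. For
#'   bulk data the read id stands in for the UMI.
#' @param blacklist an [snv_blacklist()] or `NULL`.
#' @param min_qual minimum Phred quality (default 20).
#' @param k_min distinct conversions required to call the molecule labeled.
#' @param strict_low_coverage see [count_tc()].
#' @return Object of class `molecule_call`: `gene_id`, `unit` (cell barcode
#'   or sample id), `molecule_id` (UMI or read id), `n_tc_distinct`,
#'   `n_t_covered` (distinct covered T positions), `labeled`.
#' @export
classify_molecule <- function(reads, blacklist = NULL, min_qual = 20,
                              k_min = 1, strict_low_coverage = FALSE) {
  if (length(reads) == 0L) stopf("no reads supplied")
  if (!is_count(k_min) || k_min < 1) stopf("k_min must be a count >= 1")
  key <- vapply(reads, function(r) {
    paste(r$cell_barcode, r$umi, r$gene_id, sep = "\r")
  }, "")
  if (length(unique(key)) != 1L) {
    stopf("reads of one molecule must share the (cell, umi, gene) key")
  }
  conv_pos <- character(); t_pos <- character()
  for (read in reads) {
    call <- count_tc(read, blacklist = blacklist, min_qual = min_qual,
                     strict_low_coverage = strict_low_coverage)
    conv_pos <- c(conv_pos, call$converted_positions)
    bases <- t_sense_bases(read$strand)
    eligible <- read$ref == bases[["ref"]] & read$qual >= min_qual &
      read$alt %in% DNA_BASES
    keys <- pos_key(read$chrom, read$ref_pos[eligible])
    if (!is.null(blacklist)) {
      drop <- keys %in% blacklist$positions
      if (strict_low_coverage) drop <- drop | keys %in% blacklist$low_coverage_positions
      keys <- keys[!drop]
    }
    t_pos <- c(t_pos, keys)
  }
  n_tc_distinct <- length(unique(conv_pos))
  r1 <- reads[[1L]]
  unit <- if (is.na(r1$cell_barcode)) r1$read_id else r1$cell_barcode
  molecule_id <- if (is.na(r1$umi)) r1$read_id else r1$umi
  structure(list(gene_id = r1$gene_id, unit = unit,
                 molecule_id = molecule_id,
                 n_tc_distinct = n_tc_distinct,
                 n_t_covered = length(unique(t_pos)),
                 labeled = n_tc_distinct >= k_min),
            class = "molecule_call")
}

#' Classify every molecule in a read set
#'
#' Groups reads by (cell barcode, UMI, gene) — falling back to the read id
#' as molecule id for bulk reads without UMIs — and calls
#' [classify_molecule()] on each group. Reads without a gene assignment are
#' skipped (they cannot enter a per-gene matrix).
#'
#' For bulk libraries the sample id travels in the barcode slot of the read
#' records, so the matrices come out gene x sample.
#'
#' @inheritParams classify_molecule
#' @return list of `molecule_call`.
#' @export
classify_molecules <- function(reads, blacklist = NULL, min_qual = 20,
                               k_min = 1, strict_low_coverage = FALSE) {
  keep <- vapply(reads, function(r) !is.na(r$gene_id), NA)
  reads <- reads[keep]
  if (length(reads) == 0L) return(list())
  key <- vapply(reads, function(r) {
    mol <- if (is.na(r$umi)) r$read_id else r$umi
    unit <- if (is.na(r$cell_barcode)) "" else r$cell_barcode
    paste(unit, mol, r$gene_id, sep = "\r")
  }, "")
  groups <- split(reads, key)
  unname(lapply(groups, classify_molecule, blacklist = blacklist,
                min_qual = min_qual, k_min = k_min,
                strict_low_coverage = strict_low_coverage))
}

#' Paired labeled/unlabeled count matrices
#'
#' @param labeled,unlabeled gene x unit count matrices (coerced to sparse
#'   `dgCMatrix`) with identical dimnames.
#' @return Object of class `labeled_matrices`.
#' @export
labeled_matrices <- function(labeled, unlabeled) {
  to_sparse <- function(x) {
    if (!inherits(x, "Matrix")) x <- Matrix::Matrix(x, sparse = TRUE)
    as(as(as(x, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  }
  labeled <- to_sparse(labeled)
  unlabeled <- to_sparse(unlabeled)
  if (!identical(dim(labeled), dim(unlabeled))) {
    stopf("labeled and unlabeled matrices must have identical dimensions")
  }
  if (!identical(dimnames(labeled), dimnames(unlabeled))) {
    stopf("labeled and unlabeled matrices must share dimnames")
  }
  if (any(labeled@x < 0) || any(unlabeled@x < 0)) {
    stopf("counts must be non-negative")
  }
  structure(list(labeled = labeled, unlabeled = unlabeled),
            class = "labeled_matrices")
}

#' @export
print.labeled_matrices <- function(x, ...) {
  cat(sprintf("<labeled_matrices> %d genes x %d units; %s labeled / %s total molecules\n",
              nrow(x$labeled), ncol(x$labeled),
              format(sum(x$labeled)), format(sum(x$labeled) + sum(x$unlabeled))))
  invisible(x)
}

#' @export
dim.labeled_matrices <- function(x) dim(x$labeled)

#' Build labeled/unlabeled matrices from molecule calls
#'
#' @param calls list of `molecule_call` from [classify_molecule()], one per
#'   molecule (deduplicated upstream per (cell, umi, gene)).
#' @return A [labeled_matrices()] with genes and units in sorted order;
#'   `labeled + unlabeled` equals the total molecule count per entry.
#' @export
build_matrices <- function(calls) {
  if (length(calls) == 0L) {
    z <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                              dims = c(0L, 0L),
                              dimnames = list(character(), character()))
    return(labeled_matrices(z, z))
  }
  gene <- vapply(calls, function(x) x$gene_id, "")
  unit <- vapply(calls, function(x) x$unit, "")
  mol <- vapply(calls, function(x) x$molecule_id, "")
  lab <- vapply(calls, function(x) x$labeled, NA)
  key <- paste(gene, unit, mol, sep = "\r")
  if (anyDuplicated(key)) {
    stopf("duplicate (cell, umi, gene) molecule calls; deduplicate upstream")
  }
  genes <- sort(unique(gene)); units <- sort(unique(unit))
  gi <- match(gene, genes); ui <- match(unit, units)
  mk <- function(sel) {
    Matrix::sparseMatrix(i = gi[sel], j = ui[sel], x = rep(1, sum(sel)),
                         dims = c(length(genes), length(units)),
                         dimnames = list(genes, units))
  }
  labeled_matrices(mk(lab), mk(!lab))
}

#' Labeled fraction per group
#'
#' Fraction of molecules carrying at least the configured number of
#' conversions: `labeled / (labeled + unlabeled)`.
#'
#' @param m a [labeled_matrices()].
#' @param scope `"global"`, `"per_unit"` (cell/sample) or `"per_gene"`.
#' @return data.frame with `group`, `labeled`, `total`, `fraction`; groups
#'   with zero total are reported with `fraction = NA`, never 0.
#' @export
labeled_fraction <- function(m, scope = c("global", "per_unit", "per_gene")) {
  scope <- match.arg(scope)
  l <- switch(scope,
    global = sum(m$labeled),
    per_unit = Matrix::colSums(m$labeled),
    per_gene = Matrix::rowSums(m$labeled))
  u <- switch(scope,
    global = sum(m$unlabeled),
    per_unit = Matrix::colSums(m$unlabeled),
    per_gene = Matrix::rowSums(m$unlabeled))
  group <- if (scope == "global") "global" else names(l)
  total <- l + u
  data.frame(group = group, labeled = as.numeric(l), total = as.numeric(total),
             fraction = ifelse(total > 0, l / total, NA_real_),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Detection model for labeled molecules
#'
#' A labeled molecule converts each of its `n_t` observed thymines
#' independently with probability `p_c`; an unlabeled molecule converts each
#' with the background error probability `epsilon`. Detection (at least one
#' conversion) therefore fails with probability `(1 - p_c)^{n_t}`.
#'
#' @param p_c per-thymine conversion probability in labeled molecules.
#' @param n_t thymines per read: either a single number (point mass, default
#'   50) or a list `list(mean = , type = "poisson_zt")` for a
#'   zero-truncated Poisson thymine count.
#' @param epsilon background per-thymine error-conversion probability.
#' @return Object of class `detection_model`.
#' @export
detection_model <- function(p_c, n_t = 50, epsilon = 0) {
  if (!is_prob(p_c)) stopf("p_c must be a probability in [0, 1]")
  if (!is_prob(epsilon)) stopf("epsilon must be a probability in [0, 1]")
  if (epsilon > p_c) stopf("epsilon must not exceed p_c")
  if (is.numeric(n_t)) {
    if (length(n_t) != 1L || n_t < 1) stopf("n_t must be >= 1")
    n_t <- list(type = "point", mean = as.numeric(n_t))
  } else if (!is.list(n_t) || !n_t$type %in% c("point", "poisson_zt")) {
    stopf("n_t must be a number or list(type = 'point'|'poisson_zt', mean = )")
  }
  structure(list(p_c = p_c, n_t = n_t, epsilon = epsilon),
            class = "detection_model")
}

# E[(1-p)^N] under the model's thymine-count distribution
miss_probability <- function(n_t, p) {
  q <- 1 - p
  switch(n_t$type,
    point = q^n_t$mean,
    poisson_zt = {
      lam <- n_t$mean
      # N ~ Poisson(lam) truncated at >= 1: E[q^N] = (e^{lam q} - 1)/(e^lam - 1)
      expm1(lam * q) / expm1(lam)
    })
}

#' Detection probability and false-negative rate
#'
#' Probability that a truly labeled molecule shows at least one conversion,
#' `p_detect = 1 - E[(1 - p_c)^{n_t}]`, and its complement, the false
#' negative rate. With the observed per-thymine conversion probability and
#' an average of 50 thymines per read this lands near 15%.
#'
#' @param model a [detection_model()].
#' @return list with `p_detect` and `fnr`.
#' @examples
#' detection_probability(detection_model(p_c = 0.037, n_t = 50))$fnr  # ~0.152
#' @export
detection_probability <- function(model) {
  if (!inherits(model, "detection_model")) stopf("expected a detection_model")
  miss <- miss_probability(model$n_t, model$p_c)
  list(p_detect = 1 - miss, fnr = miss)
}

#' Estimate the per-thymine conversion probability, zero-truncated
#'
#' Maximum-likelihood estimate of `p_c` from per-molecule conversion counts.
#' When counts come only from molecules already called labeled (at least one
#' conversion), the sample is zero-truncated and the naive ratio
#' overestimates `p_c`; the zero-truncated binomial likelihood corrects
#' this. With `truncated = FALSE` (zero counts included) the estimate is the
#' closed-form binomial MLE `sum(k)/sum(n)`.
#'
#' @param k integer vector of conversion counts per molecule.
#' @param n_t integer vector (or scalar) of covered thymines per molecule.
#' @param truncated whether `k` was conditioned on `k >= 1` (default TRUE).
#' @return list with `p_c` (the estimate), `boundary` (TRUE when the
#'   estimate sits at 1, e.g. a single fully converted molecule), and
#'   `n_molecules`.
#' @export
estimate_pc_zero_truncated <- function(k, n_t, truncated = TRUE) {
  if (length(n_t) == 1L) n_t <- rep(n_t, length(k))
  if (length(k) != length(n_t)) stopf("k and n_t lengths differ")
  if (length(k) == 0L) stopf("no molecules supplied")
  if (any(n_t < 1)) stopf("all molecules must cover at least one thymine")
  if (any(k > n_t)) stopf("conversion count exceeds thymine count")
  if (!truncated) {
    if (sum(n_t) == 0) stopf("no covered thymines")
    return(list(p_c = sum(k) / sum(n_t), boundary = FALSE,
                n_molecules = length(k)))
  }
  if (any(k < 1)) stopf("zero-truncated sample must have k >= 1 everywhere")
  if (all(k == n_t)) {
    return(list(p_c = 1, boundary = TRUE, n_molecules = length(k)))
  }
  negll <- function(p) {
    -sum(k * log(p) + (n_t - k) * log1p(-p) - log1p(-(1 - p)^n_t))
  }
  opt <- optimize(negll, interval = c(1e-12, 1 - 1e-12), tol = 1e-12)
  p <- opt$minimum
  list(p_c = p, boundary = p > 1 - 1e-6, n_molecules = length(k))
}
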