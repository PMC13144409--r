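#' Labeling time-course ratios
#'
#' Turns per-sample labeled/unlabeled counts into the observed labeled
#' fraction per gene and timepoint. Under steady-state transcription and
#' first-order decay at rate `lambda`, the expected fraction follows the
#' exponential-saturation curve `f(t) = alpha * (1 - exp(-lambda * t))`.
#'
#' @param counts data.frame with columns `gene_id`, `time_h`, `replicate`,
#'   `labeled`, `unlabeled`. Replicates are kept separate, never averaged
#'   before fitting.
#' @return The same table with `f_obs = labeled / (labeled + unlabeled)`
#'   (`NA` when the total is zero — a missing point, not 0) and
#'   `n_molecules = labeled + unlabeled`.
#' @export
timecourse_ratios <- function(counts) {
  need <- c("gene_id", "time_h", "replicate", "labeled", "unlabeled")
  if (!all(need %in% names(counts))) {
    stopf("counts must have columns %s", paste(need, collapse = ", "))
  }
  if (any(counts$time_h < 0)) stopf("labeling times must be >= 0")
  if (any(counts$labeled < 0 | counts$unlabeled < 0)) stopf("negative counts")
  counts$n_molecules <- counts$labeled + counts$unlabeled
  counts$f_obs <- ifelse(counts$n_molecules > 0,
                         counts$labeled / counts$n_molecules, NA_real_)
  counts
}

# weighted SS of the saturation model at fixed lambda, with alpha profiled
# out in closed form (clipped to its bounds); returns list(ss, alpha)
profile_alpha_ss <- function(lambda, t, f, w, alpha_mode, alpha_bounds) {
  u <- 1 - exp(-lambda * t)
  if (alpha_mode == "fixed_1") {
    alpha <- 1
  } else {
    den <- sum(w * u * u)
    alpha <- if (den > 0) sum(w * f * u) / den else alpha_bounds[2L]
    alpha <- min(max(alpha, alpha_bounds[1L]), alpha_bounds[2L])
  }
  list(ss = sum(w * (f - alpha * u)^2), alpha = alpha)
}

#' Fit first-order decay kinetics for one gene
#'
#' Weighted least-squares fit of `f(t) = alpha * (1 - exp(-lambda * t))` to
#' the labeled-fraction time course of one gene, with the half-life
#' `tau = ln(2) / lambda` constrained to `tau_bounds`. The plateau `alpha`
#' absorbs incomplete 4sU incorporation and detection false negatives; fix
#' it at 1 with `alpha_mode = "fixed_1"` for the textbook saturation model.
#'
#' For fixed `lambda` the optimal `alpha` has a closed form, so the fit is a
#' deterministic one-dimensional search over `log(lambda)`: a log-spaced
#' grid across the half-life bounds followed by local refinement. No RNG is
#' involved.
#'
#' Timepoints later than `max_time` (default 12 h) are excluded: a single
#' label injection is exhausted by 24 h, which flattens late points below
#' the model curve.
#'
#' @param points data.frame for one gene as produced by
#'   [timecourse_ratios()] (columns `time_h`, `f_obs`, `n_molecules`).
#' @param tau_bounds half-life search interval in hours (default
#'   `c(0.5, 48)`).
#' @param alpha_mode `"free"` (default, `alpha` in `alpha_bounds`) or
#'   `"fixed_1"`.
#' @param alpha_bounds plateau bounds for the free mode.
#' @param max_time latest labeling time (hours) included in the fit.
#' @param weighted weight points by their supporting molecule counts
#'   (default TRUE).
#' @param min_points,min_times minimum usable points / distinct times for a
#'   free fit (defaults 4 and 3; a fixed-plateau fit needs only one point).
#' @return One-row data.frame of class `decay_fit`: `gene_id`, `lambda`
#'   (per hour), `tau` (hours, `= log(2)/lambda` exactly), `alpha`, `r2`,
#'   `n_points`, `converged`, `ci_tau_lo`, `ci_tau_hi`, `reason`.
#' @examples
#' tt <- c(0.5, 1, 3, 6, 12)
#' pts <- data.frame(gene_id = "g", time_h = tt, replicate = 1L,
#'                   f_obs = 1 - exp(-tt * log(2) / 2.5), n_molecules = 500)
#' fit_decay(pts)  # recovers tau = 2.5 h
#' @export
fit_decay <- function(points, tau_bounds = c(0.5, 48),
                      alpha_mode = c("free", "fixed_1"),
                      alpha_bounds = c(0.05, 1), max_time = 12,
                      weighted = TRUE, min_points = 4, min_times = 3) {
  alpha_mode <- match.arg(alpha_mode)
  if (!is.numeric(tau_bounds) || length(tau_bounds) != 2L ||
      tau_bounds[1L] <= 0 || tau_bounds[1L] >= tau_bounds[2L]) {
    stopf("tau_bounds must be an increasing positive pair")
  }
  gene <- if ("gene_id" %in% names(points) && nrow(points) > 0) {
    points$gene_id[1L]
  } else NA_character_
  unfit <- function(reason, n) {
    data.frame(gene_id = gene, lambda = NA_real_, tau = NA_real_,
               alpha = NA_real_, r2 = NA_real_, n_points = n,
               converged = FALSE, ci_tau_lo = NA_real_, ci_tau_hi = NA_real_,
               reason = reason, stringsAsFactors = FALSE)
  }
  ok <- !is.na(points$f_obs) & points$time_h <= max_time
  pts <- points[ok, , drop = FALSE]
  need_pts <- if (alpha_mode == "fixed_1") 1L else min_points
  need_times <- if (alpha_mode == "fixed_1") 1L else min_times
  if (nrow(pts) < need_pts || length(unique(pts$time_h)) < need_times) {
    return(unfit("too_few_points", nrow(pts)))
  }
  t <- pts$time_h
  f <- pts$f_obs
  w <- if (weighted && "n_molecules" %in% names(pts)) {
    as.numeric(pts$n_molecules)
  } else rep(1, length(f))
  if (all(w == 0)) w <- rep(1, length(f))

  ss_tot <- sum(w * (f - weighted.mean(f, w))^2)
  if (ss_tot == 0 && stats::var(f) == 0 && f[1L] == 0) {
    return(unfit("all_zero", nrow(pts)))
  }

  lam_lo <- log(2) / tau_bounds[2L]
  lam_hi <- log(2) / tau_bounds[1L]
  grid <- exp(seq(log(lam_lo), log(lam_hi), length.out = 25L))
  obj <- function(loglam) {
    profile_alpha_ss(exp(loglam), t, f, w, alpha_mode, alpha_bounds)$ss
  }
  gss <- vapply(log(grid), obj, 0)
  i <- which.min(gss)
  lo <- log(grid[max(1L, i - 1L)])
  hi <- log(grid[min(length(grid), i + 1L)])
  opt <- if (hi > lo) optimize(obj, c(lo, hi), tol = 1e-12) else
    list(minimum = log(grid[i]))
  lambda <- exp(opt$minimum)
  prof <- profile_alpha_ss(lambda, t, f, w, alpha_mode, alpha_bounds)
  alpha <- prof$alpha
  ss_res <- prof$ss
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  tau <- log(2) / lambda

  at_bound <- tau <= tau_bounds[1L] * (1 + 1e-6) ||
    tau >= tau_bounds[2L] * (1 - 1e-6)
  converged <- !at_bound && ss_tot > 0

  # 95% CI for tau via the Gauss-Newton curvature of the weighted SS
  ci <- c(NA_real_, NA_real_)
  n_par <- if (alpha_mode == "fixed_1") 1L else 2L
  if (converged && length(f) > n_par) {
    u <- 1 - exp(-lambda * t)
    J <- cbind(alpha * t * exp(-lambda * t),
               if (n_par == 2L) u)
    JtWJ <- crossprod(J * sqrt(w))
    sigma2 <- ss_res / (length(f) - n_par)
    cov_try <- try(solve(JtWJ) * sigma2, silent = TRUE)
    if (!inherits(cov_try, "try-error") && cov_try[1L, 1L] >= 0) {
      se_lam <- sqrt(cov_try[1L, 1L])
      lam_ci <- lambda + c(-1, 1) * qnorm(0.975) * se_lam
      if (lam_ci[1L] > 0) ci <- rev(log(2) / lam_ci) else ci <- c(NA, log(2) / lam_ci[2L])
    }
  }
  data.frame(gene_id = gene, lambda = lambda, tau = tau, alpha = alpha,
             r2 = r2, n_points = nrow(pts), converged = converged,
             ci_tau_lo = ci[1L], ci_tau_hi = ci[2L],
             reason = if (converged) "ok" else
               if (at_bound) "at_bound" else "degenerate",
             stringsAsFactors = FALSE)
}

#' Fit decay kinetics for every gene in a time-course table
#'
#' @param tc data.frame from [timecourse_ratios()] covering many genes.
#' @param ... passed to [fit_decay()].
#' @return data.frame with one `decay_fit` row per gene; genes with too few
#'   usable points appear as explicit unfittable rows, never silently
#'   dropped.
#' @export
fit_decay_all <- function(tc, ...) {
  fits <- lapply(split(tc, tc$gene_id), fit_decay, ...)
  out <- do.call(rbind, fits)
  rownames(out) <- NULL
  out
}

#' Summarize half-life fits
#'
#' @param fits data.frame from [fit_decay_all()].
#' @param r2_min minimum coefficient of determination for a gene to count
#'   (default 0.7).
#' @param tau_bounds half-life window in hours; fits outside are excluded.
#' @return list with `n_genes` (converged fits passing the filters),
#'   `mean_tau`, `median_tau`, `quartiles` (hours) and the passing subset
#'   as `fits`.
#' @export
summarize_halflives <- function(fits, r2_min = 0.7, tau_bounds = c(0.5, 48)) {
  pass <- !is.na(fits$r2) & fits$converged & fits$r2 > r2_min &
    fits$tau >= tau_bounds[1L] & fits$tau <= tau_bounds[2L]
  sub <- fits[pass, , drop = FALSE]
  list(n_genes = nrow(sub),
       mean_tau = if (nrow(sub)) mean(sub$tau) else NA_real_,
       median_tau = if (nrow(sub)) median(sub$tau) else NA_real_,
       quartiles = if (nrow(sub)) quantile(sub$tau, c(0.25, 0.5, 0.75)) else
         setNames(rep(NA_real_, 3), c("25%", "50%", "75%")),
       fits = sub)
}
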