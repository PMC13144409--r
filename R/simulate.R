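#' Simulation configuration
#'
#' Ground-truth parameters for the synthetic data generators. Defaults
#' describe the labeling conditions the package models: a per-thymine
#' conversion probability of 0.037 in labeled molecules (which at 50
#' thymines per read puts the per-molecule false negative rate near 15%), a
#' uniform per-base, per-substitution-type sequencing error of 1e-3, mean
#' 50 thymines per read, labeling times up to 12 h, and half-lives
#' log-uniform between 0.5 and 48 h.
#'
#' @param n_genes number of genes.
#' @param tau_range half-life range in hours; half-lives are drawn
#'   log-uniformly.
#' @param mean_molecules mean steady-state molecule count per gene per
#'   sample (expression is log-normal around it, sdlog
#'   `expr_sdlog`).
#' @param expr_sdlog log-sd of expression across genes.
#' @param expr_tau_cor correlation between log-expression and log-half-life
#'   (housekeeping genes are both stable and highly expressed).
#' @param timepoints labeling times in hours.
#' @param replicates biological replicates per timepoint.
#' @param p_c per-thymine conversion probability in labeled molecules.
#' @param epsilon per-base probability of each specific substitution error
#'   (so the T-to-C error rate equals `epsilon`).
#' @param n_t_mean mean thymines covered per read (thymine counts are
#'   zero-truncated Poisson around it where reads are simulated
#'   implicitly).
#' @param gene_len,read_len,qual read-level simulation geometry and the
#'   constant Phred quality written. The default 200 nt reads carry 50
#'   thymines on average at uniform base composition, matching `n_t_mean`.
#' @param n_snv number of homozygous SNV positions to plant (appear as
#'   100% T-to-C sites).
#' @param fourSU_halflife 4sU availability decay time in hours, or `NULL`
#'   (off). When on, the effective labeling time is
#'   `h * (1 - exp(-t/h))`, flattening labeling between 12 and 24 h.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 40, tau_range = c(0.5, 48),
                       mean_molecules = 25, expr_sdlog = 1,
                       expr_tau_cor = 0.3,
                       timepoints = c(0.5, 1, 3, 6, 12), replicates = 3,
                       p_c = 0.037, epsilon = 1e-3, n_t_mean = 50,
                       gene_len = 500, read_len = 200, qual = 37,
                       n_snv = 0, fourSU_halflife = NULL) {
  stopifnot(is_count(n_genes), n_genes >= 1,
            length(tau_range) == 2L, tau_range[1L] > 0,
            tau_range[2L] > tau_range[1L],
            mean_molecules > 0, is_prob(p_c), is_prob(epsilon),
            n_t_mean >= 1, gene_len > read_len, read_len >= 20,
            all(timepoints >= 0), is_count(replicates), replicates >= 1,
            is_count(n_snv))
  if (!is.null(fourSU_halflife) && fourSU_halflife <= 0) {
    stopf("fourSU_halflife must be positive or NULL")
  }
  structure(as.list(environment()), class = "sim_config")
}

# effective labeling time under optional 4sU exhaustion
effective_time <- function(t, fourSU_halflife) {
  if (is.null(fourSU_halflife)) return(t)
  fourSU_halflife * (1 - exp(-t / fourSU_halflife))
}

# draw per-gene truth: half-life, decay rate, expression
draw_gene_truth <- function(config) {
  n <- config$n_genes
  z_tau <- rnorm(n)
  log_tau <- log(config$tau_range[1L]) +
    (log(config$tau_range[2L]) - log(config$tau_range[1L])) * runif(n)
  # expression correlated with stability on the log scale
  rho <- config$expr_tau_cor
  z_t <- scale(log_tau)[, 1L]
  z_e <- rho * z_t + sqrt(1 - rho^2) * z_tau
  expr <- config$mean_molecules * exp(config$expr_sdlog * z_e -
                                        config$expr_sdlog^2 / 2)
  data.frame(gene_id = sprintf("gene%03d", seq_len(n)),
             tau = exp(log_tau), lambda = log(2) / exp(log_tau),
             expr = expr, stringsAsFactors = FALSE)
}

#' Simulate a count-level labeling time course
#'
#' Lightweight generator for half-life benchmarking: per gene, timepoint
#' and replicate, the number of labeled molecules among `n_molecules` is
#' binomial with success probability `1 - exp(-lambda * t_eff)`. No reads
#' are materialized.
#'
#' @param config a [sim_config()]; `n_molecules` fixes the sampling depth
#'   per gene/timepoint/replicate.
#' @param seed RNG seed (mandatory).
#' @param n_molecules molecules sampled per gene per timepoint per
#'   replicate (default 500).
#' @return list with `counts` (a [timecourse_ratios()]-ready table) and
#'   `truth` (per-gene `tau`, `lambda`).
#' @export
simulate_timecourse_counts <- function(config, seed, n_molecules = 500) {
  stopifnot(inherits(config, "sim_config"), is_count(seed))
  set.seed(seed)
  truth <- draw_gene_truth(config)
  grid <- expand.grid(gene_id = truth$gene_id, time_h = config$timepoints,
                      replicate = seq_len(config$replicates),
                      stringsAsFactors = FALSE)
  lam <- truth$lambda[match(grid$gene_id, truth$gene_id)]
  t_eff <- effective_time(grid$time_h, config$fourSU_halflife)
  f_true <- 1 - exp(-lam * t_eff)
  grid$labeled <- rbinom(nrow(grid), n_molecules, f_true)
  grid$unlabeled <- n_molecules - grid$labeled
  list(counts = timecourse_ratios(grid), truth = truth, seed = seed)
}

# lay genes on one synthetic chromosome, alternating strands
build_sim_genome <- function(config) {
  gap <- 10L
  n <- config$n_genes
  starts <- (seq_len(n) - 1L) * (config$gene_len + gap)
  seq_chars <- sample(DNA_BASES, n * (config$gene_len + gap), replace = TRUE)
  genes <- data.frame(
    gene_id = sprintf("gene%03d", seq_len(n)),
    chrom = "chrS", start = starts, end = starts + config$gene_len,
    strand = rep(c("+", "-"), length.out = n), stringsAsFactors = FALSE)
  list(genes = genes, seq = seq_chars, chrom = "chrS",
       chrom_len = length(seq_chars))
}

#' Simulate a read-level bulk labeling time course
#'
#' Full generative model behind the bulk pipeline: a synthetic genome with
#' genes on both strands; per sample a Poisson number of steady-state
#' molecules per gene, each labeled with probability
#' `1 - exp(-lambda * t_eff)`; one aligned read per molecule; labeled
#' molecules convert each transcript-sense thymine with probability `p_c`,
#' every base suffers each substitution error with probability `epsilon`,
#' and optional homozygous SNV positions show T-to-C in every read.
#' Identical seeds give byte-identical output.
#'
#' @param config a [sim_config()].
#' @param seed RNG seed (mandatory).
#' @param dir if non-NULL, one SAM file per sample plus truth/annotation
#'   TSVs and a YAML config echo are written there.
#' @return list with `samples` (per sample: `sample_id`, `time_h`,
#'   `replicate`, `reads` (list of [slam_read()]), observed
#'   labeled/unlabeled counts per gene), `genes` (annotation with true
#'   `tau`, `lambda`, `expr`), `counts` (time-course table of *observed*
#'   labeled calls, at least one planted conversion), `truth_counts`
#'   (same table for *true* labels), `snv_keys`, `config`, `seed`.
#' @export
simulate_bulk_timecourse <- function(config, seed, dir = NULL) {
  stopifnot(inherits(config, "sim_config"), is_count(seed))
  set.seed(seed)
  genome <- build_sim_genome(config)
  truth <- draw_gene_truth(config)
  genes <- cbind(genome$genes, truth[, c("tau", "lambda", "expr")])

  # transcript-sense T positions per gene (genomic coordinates)
  t_sense_ref <- ifelse(genes$strand == "+", "T", "A")
  gene_t_pos <- lapply(seq_len(nrow(genes)), function(i) {
    idx <- genes$start[i]:(genes$end[i] - 1L)
    idx[genome$seq[idx + 1L] == t_sense_ref[i]]
  })
  snv_pos <- integer(0)
  if (config$n_snv > 0) {
    all_t <- unlist(gene_t_pos)
    snv_pos <- sort(sample(all_t, min(config$n_snv, length(all_t))))
  }

  samples <- list()
  count_rows <- list()
  for (t in config$timepoints) {
    t_eff <- effective_time(t, config$fourSU_halflife)
    f_true <- 1 - exp(-genes$lambda * t_eff)
    for (rep_i in seq_len(config$replicates)) {
      sample_id <- sprintf("t%g_r%d", t, rep_i)
      reads <- list()
      obs_lab <- integer(nrow(genes)); obs_unl <- integer(nrow(genes))
      true_lab <- integer(nrow(genes)); tot <- integer(nrow(genes))
      ridx <- 0L
      for (gi in seq_len(nrow(genes))) {
        m <- rpois(1L, genes$expr[gi])
        if (m == 0L) { tot[gi] <- 0L; next }
        n_labeled <- rbinom(1L, m, f_true[gi])
        true_lab[gi] <- n_labeled
        tot[gi] <- m
        conv_base <- if (genes$strand[gi] == "+") "C" else "G"
        for (mi in seq_len(m)) {
          ridx <- ridx + 1L
          start <- genes$start[gi] +
            sample.int(config$gene_len - config$read_len + 1L, 1L) - 1L
          pos <- start:(start + config$read_len - 1L)
          ref <- genome$seq[pos + 1L]
          alt <- ref
          labeled <- mi <= n_labeled
          tpos <- gene_t_pos[[gi]]
          tpos <- tpos[tpos >= start & tpos < start + config$read_len]
          if (labeled && length(tpos) > 0L) {
            hit <- tpos[runif(length(tpos)) < config$p_c]
            alt[match(hit, pos)] <- conv_base
          }
          # uniform sequencing errors: each base to each other base w.p. epsilon
          err <- which(runif(length(alt)) < 3 * config$epsilon)
          for (e in err) {
            alt[e] <- sample(setdiff(DNA_BASES, alt[e]), 1L)
          }
          # homozygous SNVs look converted in every read
          sv <- intersect(snv_pos, tpos)
          if (length(sv) > 0L) alt[match(sv, pos)] <- conv_base
          reads[[ridx]] <- slam_read(
            read_id = sprintf("%s_%s_m%04d", sample_id, genes$gene_id[gi], mi),
            chrom = genome$chrom, ref_pos = pos, ref = ref, alt = alt,
            qual = rep(config$qual, length(pos)),
            gene_id = genes$gene_id[gi], strand = genes$strand[gi],
            cell_barcode = sample_id)
          # observed label: at least one transcript-sense T->C in the final read
          called <- any(ref == t_sense_ref[gi] & alt == conv_base)
          if (called) obs_lab[gi] <- obs_lab[gi] + 1L
          else obs_unl[gi] <- obs_unl[gi] + 1L
        }
      }
      samples[[sample_id]] <- list(sample_id = sample_id, time_h = t,
                                   replicate = rep_i, reads = reads,
                                   labeled = setNames(obs_lab, genes$gene_id),
                                   unlabeled = setNames(obs_unl, genes$gene_id),
                                   true_labeled = setNames(true_lab, genes$gene_id))
      count_rows[[sample_id]] <- data.frame(
        gene_id = genes$gene_id, time_h = t, replicate = rep_i,
        labeled = obs_lab, unlabeled = obs_unl, true_labeled = true_lab,
        stringsAsFactors = FALSE)
    }
  }
  counts <- do.call(rbind, count_rows)
  rownames(counts) <- NULL
  out <- list(samples = samples, genes = genes,
              counts = timecourse_ratios(counts[, c("gene_id", "time_h",
                                                    "replicate", "labeled",
                                                    "unlabeled")]),
              truth_counts = counts,
              snv_keys = pos_key(genome$chrom, snv_pos),
              genome = genome, config = config, seed = seed)
  if (!is.null(dir)) write_bulk_sim(out, dir)
  out
}

#' Simulate paired sham/injured single-cell labeled matrices
#'
#' Generative model for the injury-response statistic: several cell types
#' with log-normal baseline nascent-transcription profiles; the injured
#' condition multiplies the transcription of a known induced gene set by
#' `induced_fold` in the induced cell types; pre-existing unlabeled pools
#' get condition-specific scale factors (deliberately unequal, to exercise
#' the claim that the response ratio ignores pre-existing RNA). Observed
#' labels are thinned by the detection probability
#' `1 - (1 - p_c)^{n_t}` (missed molecules count as unlabeled) and
#' unlabeled molecules are falsely called labeled with probability
#' `1 - (1 - epsilon)^{n_t}`.
#'
#' @param n_genes genes simulated.
#' @param cell_types named integer vector: cells per cell type per
#'   condition (at least two types).
#' @param n_induced,induced_fold size of and fold induction on the injury
#'   gene set.
#' @param induced_cell_types cell types in which induction acts (default:
#'   the first type).
#' @param labeled_per_cell,unlabeled_per_cell mean labeled / unlabeled
#'   molecules per cell (defaults 400 and 1400, i.e. a labeled fraction
#'   near 22%).
#' @param unlabeled_scale named vector: condition-specific scaling of the
#'   pre-existing pools, `c(sham = , injured = )`.
#' @param p_c,epsilon,n_t detection model parameters (see [sim_config()]).
#' @param labeling_time labeling window in hours (recorded, default 7).
#' @param seed RNG seed (mandatory).
#' @return list with `sham`, `injured` ([labeled_matrices()]),
#'   `annotations` (barcode, cell_type, condition), and `truth`
#'   (induced genes, fold, per-cell-type baseline rates, expected response
#'   ratio per gene after library normalization, config echo, seed).
#' @export
simulate_sc_injury <- function(n_genes = 2000,
                               cell_types = c(macrophage_like = 500,
                                              endothelial = 100),
                               n_induced = 50, induced_fold = 4,
                               induced_cell_types = names(cell_types)[1L],
                               labeled_per_cell = 400,
                               unlabeled_per_cell = 1400,
                               unlabeled_scale = c(sham = 1, injured = 1.5),
                               p_c = 0.037, epsilon = 1e-3, n_t = 50,
                               labeling_time = 7, seed) {
  if (length(cell_types) < 2L) stopf("need at least two cell types")
  if (is.null(names(cell_types))) stopf("cell_types must be named")
  stopifnot(is_count(seed), is_prob(p_c), is_prob(epsilon),
            n_induced >= 0, induced_fold > 0,
            all(c("sham", "injured") %in% names(unlabeled_scale)))
  set.seed(seed)
  genes <- sprintf("gene%04d", seq_len(n_genes))
  base_w <- rlnorm(n_genes, sdlog = 1.5)
  induced <- if (n_induced > 0) sort(sample(genes, n_induced)) else character()
  p_detect <- 1 - (1 - p_c)^n_t
  p_false <- 1 - (1 - epsilon)^n_t

  # per-cell-type labeled and unlabeled rate profiles (molecules/cell)
  w_lab <- list(); w_unl <- list()
  for (ct in names(cell_types)) {
    wl <- base_w * rlnorm(n_genes, sdlog = 0.3)
    wu <- base_w * rlnorm(n_genes, sdlog = 0.5)
    w_lab[[ct]] <- wl / sum(wl) * labeled_per_cell
    w_unl[[ct]] <- wu / sum(wu) * unlabeled_per_cell
  }

  sim_cond <- function(condition) {
    mats_l <- list(); mats_u <- list(); barcodes <- list()
    for (ct in names(cell_types)) {
      n_cells <- cell_types[[ct]]
      lam_l <- w_lab[[ct]]
      if (condition == "injured" && ct %in% induced_cell_types) {
        lam_l[genes %in% induced] <- lam_l[genes %in% induced] * induced_fold
      }
      lam_u <- w_unl[[ct]] * unlabeled_scale[[condition]]
      true_l <- matrix(rpois(n_genes * n_cells, lam_l), n_genes, n_cells)
      true_u <- matrix(rpois(n_genes * n_cells, lam_u), n_genes, n_cells)
      det <- matrix(rbinom(length(true_l), true_l, p_detect),
                    n_genes, n_cells)
      fls <- matrix(rbinom(length(true_u), true_u, p_false),
                    n_genes, n_cells)
      mats_l[[ct]] <- det + fls
      mats_u[[ct]] <- true_u - fls + (true_l - det)
      barcodes[[ct]] <- sprintf("%s_%s_c%04d",
                                substr(condition, 1, 3), ct,
                                seq_len(n_cells))
    }
    lab <- do.call(cbind, mats_l); unl <- do.call(cbind, mats_u)
    bc <- unlist(barcodes, use.names = FALSE)
    dimnames(lab) <- dimnames(unl) <- list(genes, bc)
    list(m = labeled_matrices(lab, unl),
         ann = data.frame(barcode = bc,
                          cell_type = rep(names(cell_types), cell_types),
                          condition = condition, stringsAsFactors = FALSE))
  }
  sham <- sim_cond("sham")
  injured <- sim_cond("injured")

  # expected response after library normalization, for the induced cell type
  ct1 <- induced_cell_types[1L]
  fold_vec <- ifelse(genes %in% induced, induced_fold, 1)
  lib_ratio <- sum(w_lab[[ct1]]) / sum(w_lab[[ct1]] * fold_vec)
  truth <- list(induced_genes = induced, induced_fold = induced_fold,
                induced_cell_types = induced_cell_types,
                w_labeled = w_lab, w_unlabeled = w_unl,
                expected_ratio = setNames(fold_vec * lib_ratio, genes),
                p_detect = p_detect, p_false = p_false,
                labeling_time = labeling_time,
                unlabeled_scale = unlabeled_scale, seed = seed)
  list(sham = sham$m, injured = injured$m,
       annotations = rbind(sham$ann, injured$ann), truth = truth)
}
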