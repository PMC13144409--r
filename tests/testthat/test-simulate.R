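test_that("bulk time-course labeling matches its closed-form expectation", {
  # tau = 2 h at t = 7 h: expected labeled fraction 1 - 2^(-7/2) ~ 0.9116
  cfg <- sim_config(n_genes = 30, tau_range = c(1.999, 2.001),
                    timepoints = 7, replicates = 1, mean_molecules = 60,
                    expr_sdlog = 0.2, p_c = 0.3, epsilon = 0)
  sim <- simulate_bulk_timecourse(cfg, seed = 2)
  tc <- sim$truth_counts
  n <- sum(tc$labeled + tc$unlabeled)
  f_expect <- 1 - exp(-7 * log(2) / 2)
  se <- sqrt(f_expect * (1 - f_expect) / n)
  f_true <- sum(tc$true_labeled) / n
  expect_lt(abs(f_true - f_expect), 3 * se)
})

test_that("no labeling occurs at time zero and no conversions without error", {
  cfg <- sim_config(n_genes = 10, timepoints = 0, replicates = 1,
                    mean_molecules = 20)
  sim <- simulate_bulk_timecourse(cfg, seed = 3)
  expect_equal(sum(sim$truth_counts$true_labeled), 0L)
  # p_c = 0 and epsilon = 0: not a single mismatch anywhere
  cfg0 <- sim_config(n_genes = 10, timepoints = c(1, 6), replicates = 1,
                     mean_molecules = 20, p_c = 0, epsilon = 0)
  sim0 <- simulate_bulk_timecourse(cfg0, seed = 4)
  mm <- vapply(sim0$samples, function(s) {
    sum(vapply(s$reads, function(r) sum(r$ref != r$alt), 0L))
  }, 0L)
  expect_equal(sum(mm), 0L)
  expect_equal(sum(sim0$counts$labeled), 0L)
})

test_that("identical seeds reproduce the simulation byte-identically", {
  cfg <- sim_config(n_genes = 8, timepoints = c(1, 6), replicates = 1,
                    mean_molecules = 10, n_snv = 3)
  a <- simulate_bulk_timecourse(cfg, seed = 11)
  b <- simulate_bulk_timecourse(cfg, seed = 11)
  expect_identical(a$counts, b$counts)
  expect_identical(a$samples[[1]]$reads, b$samples[[1]]$reads)
  expect_identical(a$snv_keys, b$snv_keys)
  c_ <- simulate_bulk_timecourse(cfg, seed = 12)
  expect_false(identical(a$counts, c_$counts))
  # sc generator likewise
  s1 <- simulate_sc_injury(n_genes = 50, cell_types = c(a = 10, b = 5),
                           n_induced = 5, seed = 7)
  s2 <- simulate_sc_injury(n_genes = 50, cell_types = c(a = 10, b = 5),
                           n_induced = 5, seed = 7)
  expect_identical(as.matrix(s1$sham$labeled), as.matrix(s2$sham$labeled))
  expect_identical(s1$truth$induced_genes, s2$truth$induced_genes)
})

test_that("4sU exhaustion flattens labeling at late times", {
  cfg_on <- sim_config(n_genes = 40, tau_range = c(2.9, 3.1),
                       timepoints = c(12, 24), replicates = 1,
                       mean_molecules = 50, fourSU_halflife = 8)
  sim <- simulate_timecourse_counts(cfg_on, seed = 5, n_molecules = 2000)
  tc <- sim$counts
  f12 <- mean(tc$f_obs[tc$time_h == 12])
  f24 <- mean(tc$f_obs[tc$time_h == 24])
  # saturating availability: the 12 -> 24 h gain is far below the
  # availability-free expectation
  f24_free <- 1 - exp(-24 * log(2) / 3)
  expect_lt(f24 - f12, 0.5 * (f24_free - f12))
  expect_gte(f24, f12 - 0.05)
})

test_that("simulated per-molecule miss rate brackets the expected FNR", {
  # with p_c in the working range and ~50 thymines per read, between 10 and
  # 20% of truly labeled molecules show no conversion
  for (p_c in c(0.032, 0.037, 0.045)) {
    cfg <- sim_config(n_genes = 25, tau_range = c(0.9, 1.1),
                      timepoints = 24, replicates = 2, mean_molecules = 60,
                      expr_sdlog = 0.2, p_c = p_c, epsilon = 0)
    sim <- simulate_bulk_timecourse(cfg, seed = round(p_c * 1000))
    tc <- sim$truth_counts
    n_true <- sum(tc$true_labeled)
    n_called <- sum(tc$labeled)
    fnr_obs <- 1 - n_called / n_true
    expect_gt(fnr_obs, 0.10 - 3 * sqrt(0.15 * 0.85 / n_true))
    expect_lt(fnr_obs, 0.20 + 3 * sqrt(0.15 * 0.85 / n_true))
  }
})

test_that("planted SNV positions are fully converted and get blacklisted", {
  cfg <- sim_config(n_genes = 10, timepoints = 6, replicates = 1,
                    mean_molecules = 80, n_snv = 5, epsilon = 0, p_c = 0.02)
  sim <- simulate_bulk_timecourse(cfg, seed = 23)
  reads <- unlist(lapply(sim$samples, `[[`, "reads"), recursive = FALSE)
  tally <- build_position_tally(reads)
  bl <- call_snv_blacklist(tally)
  keys <- pos_key(tally$chrom, tally$pos)
  covered_snvs <- sim$snv_keys[sim$snv_keys %in%
                                 keys[tally$coverage >= 10]]
  expect_gt(length(covered_snvs), 0)
  expect_true(all(covered_snvs %in% bl$positions))
  # blacklisting the SNVs lowers the measured conversion rate
  r_raw <- conversion_rate(reads, "global")$rate
  r_masked <- conversion_rate(reads, "global", blacklist = bl)$rate
  expect_lt(r_masked, r_raw)
})

test_that("sc injury simulation carries its ground truth into the observed ratios", {
  sim <- simulate_sc_injury(n_genes = 400, cell_types = c(mac = 150, endo = 30),
                            n_induced = 15, induced_fold = 4,
                            labeled_per_cell = 600, unlabeled_per_cell = 1200,
                            epsilon = 0, p_c = 1, n_t = 1, seed = 31)
  # epsilon 0 and p_detect 1: observed matrices equal the true molecule counts
  ann <- sim$annotations
  pair <- condition_pair(sim$sham, sim$injured,
                         setNames(ann$cell_type[ann$condition == "sham"],
                                  ann$barcode[ann$condition == "sham"]),
                         setNames(ann$cell_type[ann$condition == "injured"],
                                  ann$barcode[ann$condition == "injured"]))
  res <- injury_response(pair, "mac", pseudocount = 1e-6)
  ind <- res$gene_id %in% sim$truth$induced_genes
  exp_r <- sim$truth$expected_ratio[res$gene_id]
  # deep pseudobulk: mean observed ratio of induced genes near its
  # library-normalized expectation
  expect_equal(mean(res$response_ratio[ind] / exp_r[ind]), 1, tolerance = 0.1)
  expect_equal(median(res$response_ratio[!ind] / exp_r[!ind]), 1,
               tolerance = 0.05)
  # null configuration: every expected ratio is exactly 1
  null_sim <- simulate_sc_injury(n_genes = 50, cell_types = c(a = 5, b = 5),
                                 n_induced = 0, seed = 1)
  expect_true(all(null_sim$truth$expected_ratio == 1))
})

test_that("generator output passes the ingest validators of the other modules", {
  cfg <- sim_config(n_genes = 6, timepoints = 3, replicates = 1,
                    mean_molecules = 15)
  sim <- simulate_bulk_timecourse(cfg, seed = 41)
  reads <- sim$samples[[1]]$reads
  expect_true(all(vapply(reads, inherits, NA, "slam_read")))
  calls <- classify_molecules(reads)
  m <- build_matrices(calls)
  expect_equal(sum(m$labeled + m$unlabeled), length(reads))
  sc <- simulate_sc_injury(n_genes = 30, cell_types = c(a = 4, b = 4),
                           n_induced = 3, seed = 13)
  expect_s3_class(sc$sham, "labeled_matrices")
  expect_equal(nrow(sc$annotations), 16L)
})
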