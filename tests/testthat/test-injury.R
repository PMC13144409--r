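test_that("background epsilon comes from the non-T-to-C substitution spectrum", {
  # error-free reads: epsilon_hat = 0, expected false labeled = 0
  clean <- lapply(1:20, function(i) {
    mk_read("TACG", "TACG", id = paste0("c", i))
  })
  bg0 <- estimate_background(clean)
  expect_equal(bg0$epsilon_hat, 0)
  expect_equal(expected_false_labeled(bg0, 1000), 0)
  # arithmetic: eps 0.001, n_t 50, U 1000 -> ~48.8 expected false calls
  bg <- estimate_background(epsilon = 0.001, n_t = 50)
  expect_equal(expected_false_labeled(bg, 1000), 1000 * (1 - 0.999^50),
               tolerance = 1e-12)
  expect_equal(expected_false_labeled(bg, 1000), 48.8, tolerance = 1e-2)
  # requiring two conversions shrinks the false-call probability
  expect_lt(expected_false_labeled(bg, 1000, k_min = 2),
            expected_false_labeled(bg, 1000, k_min = 1))
  # no quality-passing sites at all -> no background information
  low_q <- list(mk_read("TACG", "TACG", qual = 10L))
  expect_error(estimate_background(low_q), "non-")
  expect_error(estimate_background(epsilon = 0.2), "0.05")
})

test_that("uniform simulated sequencing errors are recovered as epsilon_hat", {
  cfg <- sim_config(n_genes = 12, timepoints = 6, replicates = 1,
                    mean_molecules = 60, p_c = 0.037, epsilon = 0.001)
  sim <- simulate_bulk_timecourse(cfg, seed = 17)
  reads <- sim$samples[[1]]$reads
  bg <- estimate_background(reads, min_qual = 20)
  # ~700 reads x 100 bases x ~25 sites per base type: binomial SE per rate
  n_sites <- median(bg$spectrum$n_sites)
  se <- sqrt(0.001 * 0.999 / n_sites)
  expect_lt(abs(bg$epsilon_hat - 0.001), 3 * se + 1e-9)
})

test_that("identical labeled profiles give a flat response of exactly 1", {
  genes <- paste0("g", 1:5)
  lab <- cmat(c(10, 20, 30, 40, 50), genes, c("c1", "c2"))
  pair <- mk_pair(lab, lab * 3, lab, lab * 7)
  res <- injury_response(pair, "mac")
  expect_true(all(res$response_ratio == 1))
  expect_true(all(res$log2_r == 0))
})

test_that("the response ratio is the normalized labeled ratio as pseudocount vanishes", {
  genes <- c("g", paste0("f", 1:9))
  sham_lab <- cmat(c(100, rep(1100, 9)), genes, "s1")        # total 10000
  inj_lab <- cmat(c(300, rep((15000 - 300) / 9, 9)), genes, "i1")  # total 15000
  pair <- mk_pair(sham_lab, sham_lab, inj_lab, inj_lab)
  res <- injury_response(pair, "mac", pseudocount = 1e-9, min_cells = 1)
  # 300/15000 over 100/10000 = 2
  expect_equal(res$response_ratio[res$gene_id == "g"], 2, tolerance = 1e-6)
})

test_that("the response is bit-identical under unlabeled inflation and labeled scaling", {
  set.seed(8)
  genes <- paste0("g", 1:50)
  cells_s <- paste0("s", 1:6); cells_i <- paste0("i", 1:6)
  lab_s <- cmat(rpois(300, 5), genes, cells_s)
  lab_i <- cmat(rpois(300, 8), genes, cells_i)
  unl_s <- cmat(rpois(300, 20), genes, cells_s)
  unl_i <- cmat(rpois(300, 20), genes, cells_i)
  base <- injury_response(mk_pair(lab_s, unl_s, lab_i, unl_i), "mac")
  # (a) arbitrary inflation of pre-existing unlabeled RNA changes nothing
  infl <- injury_response(mk_pair(lab_s, unl_s * 10L,
                                  lab_i, unl_i + 1000L), "mac")
  expect_identical(base$response_ratio, infl$response_ratio)
  # (b) global scaling of one condition's labeled library cancels exactly
  scaled <- injury_response(mk_pair(lab_s, unl_s, lab_i * 2L, unl_i), "mac")
  expect_identical(base$response_ratio, scaled$response_ratio)
  # with zero background the corrected and uncorrected response coincide
  bg0 <- estimate_background(epsilon = 0, n_t = 50)
  with_bg <- injury_response(mk_pair(lab_s, unl_s, lab_i, unl_i), "mac",
                             bg = bg0)
  expect_identical(base$response_ratio, with_bg$response_ratio)
})

test_that("background subtraction removes false labeled signal before the ratio", {
  genes <- paste0("g", 1:4)
  lab <- cmat(c(50, 60, 70, 80), genes, "s1")
  # injured condition has the same labeling but a hugely inflated unlabeled
  # pool; with epsilon > 0 that pool leaks false labeled counts
  eps <- 0.001; n_t <- 50
  p_false <- 1 - (1 - eps)^n_t
  unl_s <- cmat(rep(1000, 4), genes, "s1")
  unl_i <- cmat(rep(5000, 4), genes, "i1")
  leak_s <- cmat(lab + 1000 * p_false, genes, "s1")
  leak_i <- cmat(lab + 5000 * p_false, genes, "i1")
  bg <- estimate_background(epsilon = eps, n_t = n_t)
  corrected <- injury_response(mk_pair(leak_s, unl_s, leak_i, unl_i), "mac",
                               bg = bg, min_cells = 1)
  expect_equal(corrected$response_ratio, rep(1, 4), tolerance = 1e-12)
})

test_that("permutation p-values match exhaustive enumeration on 2v2 cells", {
  genes <- paste0("g", 1:6)
  set.seed(12)
  lab_s <- cmat(rpois(12, 10), genes, c("s1", "s2"))
  lab_i <- cmat(rpois(12, 25), genes, c("i1", "i2"))
  pair <- mk_pair(lab_s, cmat(5, genes, c("s1", "s2")),
                  lab_i, cmat(5, genes, c("i1", "i2")))
  res <- permutation_test(pair, "mac", exact = TRUE, min_count = 0)
  expect_equal(attr(res, "n_perm"), choose(4, 2))
  # independent oracle: enumerate the 6 assignments by hand
  pooled <- cbind(lab_s, lab_i)
  sets <- combn(4, 2)
  null_stats <- sapply(seq_len(ncol(sets)), function(j) {
    inj <- sets[, j]
    li <- rowSums(pooled[, inj, drop = FALSE])
    ls <- rowSums(pooled[, -inj, drop = FALSE])
    hi <- li / sum(li) * 1e4 + 1
    hs <- ls / sum(ls) * 1e4 + 1
    abs(log2(hi / hs))
  })
  obs <- abs(res$log2_r)
  p_oracle <- unname(rowMeans(null_stats >= obs))
  expect_equal(res$p_perm, p_oracle)
  expect_true(all(res$p_perm > 0 & res$p_perm <= 1))
})

test_that("permutation testing is seed-reproducible and flat for constant genes", {
  genes <- paste0("g", 1:8)
  lab <- cmat(7, genes, paste0("c", 1:5))   # every cell identical
  unl <- cmat(3, genes, paste0("c", 1:5))
  lab2 <- cmat(7, genes, paste0("d", 1:5))
  unl2 <- cmat(3, genes, paste0("d", 1:5))
  pair <- mk_pair(lab, unl, lab2, unl2)
  res <- permutation_test(pair, "mac", n_perm = 200, seed = 4)
  expect_true(all(res$p_perm == 1))
  res2 <- permutation_test(pair, "mac", n_perm = 200, seed = 4)
  expect_identical(res$p_perm, res2$p_perm)
  expect_error(permutation_test(pair, "mac", n_perm = 5, seed = 1), "n_perm")
  # BH-adjusted values never drop below raw p
  expect_true(all(res$q >= res$p_perm - 1e-12))
})

test_that("pathway layer scores are percentages of the per-cell transcriptome", {
  genes <- paste0("g", 1:10)
  mat <- cmat(10, genes, paste0("c", 1:4))
  layer <- gene_set_layer("toy_receptors", genes[1:5], "receptors")
  sc <- pathway_layer_score(mat, layer)
  expect_equal(sc$mean_pct, 50)
  # a layer of all genes is 100% everywhere
  all_sc <- pathway_layer_score(mat, genes)
  expect_equal(all_sc$mean_pct, 100)
  expect_equal(all_sc$sem_pct, 0)
  # 5 of 100 counts -> 5%; group means and SEM from per-cell percents
  m2 <- cmat(c(5, 95, 4, 96, 6, 94), c("in_set", "out"), paste0("c", 1:3))
  sc2 <- pathway_layer_score(m2, "in_set",
                             groups = c("a", "b", "b"))
  expect_equal(sc2$mean_pct[sc2$group == "a"], 5)
  expect_equal(sc2$mean_pct[sc2$group == "b"], 5)
  expect_equal(sc2$sem_pct[sc2$group == "b"], 1)
  # zero-count cells excluded with a warning; missing genes warned
  m3 <- cmat(c(5, 95, 0, 0), c("in_set", "out"), c("c1", "c2"))
  expect_warning(pathway_layer_score(m3, "in_set"), "zero total")
  expect_warning(pathway_layer_score(m2, c("in_set", "absent")), "absent")
})

test_that("responsive-gene calls respect the q and fold cutoffs", {
  res <- data.frame(gene_id = c("a", "b", "c"), cell_type = "mac",
                    l_hat_sham = 1, l_hat_inj = 1,
                    response_ratio = c(8, 8, 1.2),
                    log2_r = log2(c(8, 8, 1.2)), tested = TRUE,
                    pseudocount = 1,
                    p_perm = c(0.001, 0.2, 0.001),
                    q = c(0.003, 0.3, 0.003))
  called <- responsive_genes(res)
  expect_equal(called$gene_id[called$responsive], "a")
})
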