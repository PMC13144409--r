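test_that("extract_mismatches returns exactly the substitution events", {
  # identity case
  r <- mk_read("ACGT", "ACGT")
  expect_equal(nrow(extract_mismatches(r)), 0L)
  # direct string comparison: T->C at offset 1, A->G at offset 3 (0-based)
  r <- mk_read("TTGA", "TCGG")
  ev <- extract_mismatches(r)
  expect_equal(ev$pos, c(1L, 3L))
  expect_equal(ev$ref, c("T", "A"))
  expect_equal(ev$alt, c("C", "G"))
  # N bases never yield events
  r <- mk_read("NTGA", "CTGA")
  expect_equal(nrow(extract_mismatches(r)), 0L)
  r <- mk_read("TTGA", "TNGA")
  expect_equal(nrow(extract_mismatches(r)), 0L)
})

test_that("malformed reads raise structured errors naming the read", {
  expect_error(slam_read("badread", "chr1", 0:2, c("A", "C"), c("A", "C", "G"),
                         rep(30L, 3)), "badread")
  expect_error(slam_read("rev", "chr1", c(3L, 2L), c("A", "C"), c("A", "C"),
                         c(30L, 30L)), "increasing")
})

test_that("count_tc counts transcript-sense conversions with masks", {
  # plus strand: 2 of 4 T positions converted
  r <- mk_read("TTTT", "TCTC", qual = 30L)
  cc <- count_tc(r)
  expect_equal(cc$n_t_covered, 4L)
  expect_equal(cc$n_tc, 2L)
  # quality mask removes positions from numerator AND denominator
  r2 <- slam_read("r1", "chr1", 0:3, rep("T", 4), c("T", "C", "T", "C"),
                  c(30L, 19L, 30L, 19L), gene_id = "g1", strand = "+")
  cc2 <- count_tc(r2, min_qual = 20)
  expect_equal(cc2$n_t_covered, 2L)
  expect_equal(cc2$n_tc, 0L)
  # minus strand: genomic A->G is transcript-sense T->C
  r3 <- mk_read("AAAA", "AGAG", strand = "-")
  cc3 <- count_tc(r3)
  expect_equal(cc3$n_t_covered, 4L)
  expect_equal(cc3$n_tc, 2L)
  # blacklisted position excluded from both counts
  bl <- snv_blacklist(positions = "chr1:1")
  cc4 <- count_tc(mk_read("TTTT", "TCTT"), blacklist = bl)
  expect_equal(cc4$n_tc, 0L)
  expect_equal(cc4$n_t_covered, 3L)
  # unknown strand is an error
  expect_error(count_tc(mk_read("TTTT", "TTTT", strand = NA)), "strand")
})

test_that("count_tc matches the brute-force oracle on randomized reads", {
  set.seed(42)
  bl_keys <- paste0("chr1:", sample.int(1100L, 60L))
  bl <- snv_blacklist(positions = bl_keys)
  for (i in 1:300) {
    strand <- sample(c("+", "-"), 1L)
    r <- random_read(sample(20:100, 1L), strand = strand, p_mm = 0.08,
                     id = paste0("rr", i))
    got <- count_tc(r, blacklist = bl, min_qual = 20)
    want <- oracle_count_tc(r, bl_keys, min_qual = 20)
    expect_identical(got$n_t_covered, want$n_t_covered)
    expect_identical(got$n_tc, want$n_tc)
  }
})

test_that("reverse-complementing reference and read and flipping strand is a no-op", {
  set.seed(7)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (i in 1:50) {
    r <- random_read(60, strand = "+", p_mm = 0.1, id = paste0("s", i))
    flipped <- slam_read(r$read_id, r$chrom, r$ref_pos,
                         unname(comp[r$ref]), unname(comp[r$alt]), r$qual,
                         gene_id = r$gene_id, strand = "-")
    a <- count_tc(r); b <- count_tc(flipped)
    expect_identical(a$n_t_covered, b$n_t_covered)
    expect_identical(a$n_tc, b$n_tc)
  }
})

test_that("raising min_qual never increases either count", {
  set.seed(11)
  for (i in 1:30) {
    r <- random_read(80, p_mm = 0.1, id = paste0("q", i))
    prev <- count_tc(r, min_qual = 0)
    for (q in c(10, 20, 30, 41)) {
      cur <- count_tc(r, min_qual = q)
      expect_lte(cur$n_tc, prev$n_tc)
      expect_lte(cur$n_t_covered, prev$n_t_covered)
      prev <- cur
    }
  }
})

test_that("position tally aggregates reads additively and order-invariantly", {
  r <- mk_read("TTAT", "TCAT")
  reads <- list(r, r, r)
  tally <- build_position_tally(reads)
  conv_row <- tally[tally$pos == 1L, ]
  expect_equal(conv_row$coverage, 3L)
  expect_equal(conv_row$conversions, 3L)
  # empty stream -> empty tally
  expect_equal(nrow(build_position_tally(list())), 0L)
  # disjoint reads tally independently
  r2 <- mk_read("TTTT", "TTCT", start = 100L, id = "r2")
  t2 <- build_position_tally(list(r, r2))
  expect_equal(sum(t2$conversions), 2L)
  # order invariance
  set.seed(3)
  many <- lapply(1:40, function(i) random_read(50, id = paste0("t", i)))
  t_a <- build_position_tally(many)
  t_b <- build_position_tally(rev(many))
  expect_identical(t_a, t_b)
})

test_that("SNV blacklist membership matches the coverage/fraction predicate", {
  tally <- data.frame(chrom = "chr1", pos = 1:4,
                      coverage = c(20L, 20L, 9L, 10L),
                      conversions = c(5L, 4L, 9L, 2L))
  bl <- call_snv_blacklist(tally)
  expect_true("chr1:1" %in% bl$positions)        # 25% at coverage 20
  expect_false("chr1:2" %in% bl$positions)       # 20% < 25%
  expect_true("chr1:3" %in% bl$low_coverage_positions)  # 9 reads: unclassifiable
  expect_false("chr1:3" %in% bl$positions)
  expect_false("chr1:4" %in% bl$positions)       # 20% at exactly min_cov
  # config validation
  expect_error(call_snv_blacklist(tally, min_frac = 0), "min_frac")
  expect_error(call_snv_blacklist(tally, min_cov = 0), "min_cov")
  # empty tally is fine
  expect_length(call_snv_blacklist(build_position_tally(list()))$positions, 0L)
})

test_that("conversion rates pool within groups and conserve the numerator", {
  mk50 <- function(ntc, id, gene) {
    alt <- rep("T", 50); if (ntc > 0) alt[seq_len(ntc)] <- "C"
    mk_read(strrep("T", 50), paste(alt, collapse = ""), id = id, gene = gene)
  }
  reads <- list(mk50(2L, "a", "g1"), mk50(0L, "b", "g2"))
  glob <- conversion_rate(reads, "global")
  expect_equal(glob$rate, 0.02)
  per_gene <- conversion_rate(reads, "per_gene")
  expect_equal(sum(per_gene$n_tc), glob$n_tc)
  expect_equal(sum(per_gene$n_t_covered), glob$n_t_covered)
  # conversion-free reads give rate exactly 0
  expect_equal(conversion_rate(list(mk50(0L, "c", "g1")), "global")$rate, 0)
  # empty denominator reported missing, not 0
  gless <- conversion_rate(list(mk_read("GGGG", "GGGG")), "global")
  expect_true(is.na(gless$rate))
})

test_that("substitution spectrum is transcript-sense and complete", {
  # plus strand: one T->C and one G->A over known site counts
  r <- mk_read("TGCA", "CACA")
  sp <- substitution_spectrum(list(r))
  expect_equal(nrow(sp), 12L)
  expect_equal(sp$n_sub[sp$ref == "T" & sp$alt == "C"], 1L)
  expect_equal(sp$n_sub[sp$ref == "G" & sp$alt == "A"], 1L)
  expect_equal(sum(sp$n_sub), 2L)
  # minus strand: genomic A->G shows up as T->C
  rm <- mk_read("AAAA", "AGAA", strand = "-")
  spm <- substitution_spectrum(list(rm))
  expect_equal(spm$n_sub[spm$ref == "T" & spm$alt == "C"], 1L)
  expect_equal(spm$n_sites[spm$ref == "T"][1L], 4L)
})
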