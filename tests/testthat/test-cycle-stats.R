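test_that("fold change is computed within animal against the reference", {
  d <- data.frame(
    animal_id = rep(c("m1", "m2"), each = 3),
    phase = rep(c("F", "L", "LL"), 2),
    population = "NK",
    value = c(50, 100, 25, 40, 40, 80)
  )
  ft <- fold_change_vs_reference(d, reference = "F")
  expect_s3_class(ft, "fold_change_table")
  expect_equal(ft$fold[ft$animal_id == "m1" & ft$phase == "L"], 2)
  expect_equal(ft$fold[ft$animal_id == "m1" & ft$phase == "LL"], 0.5)
  expect_equal(ft$fold[ft$animal_id == "m2" & ft$phase == "LL"], 2)
  # reference phase is identically 1
  expect_true(all(ft$fold[ft$phase == "F"] == 1))
  # zero reference: the whole (animal, population) group is excluded
  d$value[d$animal_id == "m2" & d$phase == "F"] <- 0
  expect_warning(ft2 <- fold_change_vs_reference(d, reference = "F"),
                 "excluded")
  expect_false("m2" %in% ft2$animal_id)
  # duplicated reference rows: mean baseline, one fold-1 row emitted
  d3 <- data.frame(animal_id = "m1", phase = c("F", "F", "L"),
                   population = "NK", value = c(40, 60, 100))
  ft3 <- fold_change_vs_reference(d3, reference = "F")
  expect_equal(ft3$fold[ft3$phase == "L"], 2)
  expect_equal(ft3$fold[ft3$phase == "F"], 1)
})

test_that("planted immune fold change is recovered across a cohort", {
  hs <- hormone_cycle_spec(period = 10, amplitude = 1, baseline = 5,
                           phase_offset = 2.5, sampling_days = c(7.5, 2.5),
                           n_animals = 200L)
  imm <- generate_immune_counts(
    immune_count_spec("NK", 300, 4, pi / 2, dispersion = 50,
                      hormone_spec = hs, seed = 31))
  # antiphase day 7.5 is each animal's first sample = the reference
  ft <- suppressWarnings(fold_change_vs_reference(imm, reference = "day_7.5"))
  est <- stats::median(ft$fold[ft$phase == "day_2.5"])
  expect_lt(abs(est - 4) / 4, 0.10)
})

test_that("signed-rank test matches enumeration, wilcox.test, and its flags", {
  # five all-positive differences: p = 2/2^5
  expect_equal(test_fold_vs_unity(c(2, 2, 2, 2, 2))$p_value, 0.0625)
  # degenerate: all folds at the null value
  t0 <- test_fold_vs_unity(c(1, 1, 1))
  expect_equal(t0$p_value, 1)
  expect_true(t0$degenerate)
  # exact path equals the brute-force 2^n enumeration oracle
  set.seed(101)
  for (i in 1:20) {
    f <- rlnorm(sample(4:10, 1), 0, 0.4)
    expect_equal(test_fold_vs_unity(f)$p_value, oracle_signed_rank_p(f),
                 tolerance = 1e-12)
  }
  # and (for untied data) R's own wilcox.test
  set.seed(102)
  for (i in 1:20) {
    f <- rlnorm(sample(6:12, 1), 0, 0.4)
    expect_equal(test_fold_vs_unity(f)$p_value,
                 stats::wilcox.test(f, mu = 1, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
  # zeros are dropped before ranking under the default convention
  tz <- test_fold_vs_unity(c(1, 1, 2, 3, 0.5))
  expect_identical(tz$n, 3L)
})

test_that("exact and normal signed-rank paths agree near the crossover", {
  set.seed(201)
  worst <- 0
  for (i in 1:150) {
    f <- rlnorm(sample(12:15, 1), 0, 0.3)
    pe <- test_fold_vs_unity(f)$p_value
    pn <- test_fold_vs_unity(f, exact_max = 0)$p_value
    worst <- max(worst, abs(pe - pn))
  }
  expect_lt(worst, 0.01)
})

test_that("BH adjustment reproduces the hand example and its properties", {
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_fdr(0.034), 0.034)
  set.seed(5)
  p <- runif(40)^2
  adj <- adjust_fdr(p)
  expect_true(all(adj >= p & adj <= 1))
  # monotone: p_i <= p_j implies adj_i <= adj_j
  ord <- order(p)
  expect_true(all(diff(adj[ord]) >= -1e-15))
  # BKY is never more conservative than plain BH
  expect_true(all(adjust_fdr(p, method = "BKY") <= adj + 1e-12))
  expect_identical(adjust_fdr(numeric(0)), numeric(0))
  expect_error(adjust_fdr(c(0.5, 0)), "0, 1")
})

test_that("panel ordering sorts by mean fold with alphabetical ties", {
  expect_identical(
    order_by_fold_increase(c("IFNg" = 12, "IL-6" = 3, "IP-10" = 20)),
    c("IP-10", "IFNg", "IL-6"))
  expect_identical(order_by_fold_increase(c(b = 2, a = 2, c = 2)),
                   c("a", "b", "c"))
  expect_identical(order_by_fold_increase(numeric(0)), character(0))
  # data.frame input aggregates by mean across animals
  df <- data.frame(population = c("x", "x", "y"), fold = c(1, 3, 10))
  expect_identical(order_by_fold_increase(df), c("y", "x"))
})

test_that("DEG filter applies both thresholds strictly", {
  tab <- data.frame(
    gene = c("g1", "g2", "g3", "g4"),
    log2FC = c(1.01, 3, -1.2, -1),
    FDR = c(0.049, 0.05, 0.01, 0.01)
  )
  kept <- filter_significant_genes(tab)
  # g1 passes both strict thresholds; g2 fails FDR boundary; g4 fails |FC|
  expect_identical(kept$gene, c("g1", "g3"))
  expect_identical(nrow(filter_significant_genes(generate_deg_table(100, 10, 1))),
                   10L)
})

test_that("fold significance tables carry FDR-adjusted p-values", {
  hs <- hormone_cycle_spec(period = 10, amplitude = 1, baseline = 5,
                           phase_offset = 2.5,
                           sampling_days = c(0, 2.5, 5, 7.5), n_animals = 8L)
  imm <- generate_immune_counts(
    immune_count_spec("NK", 200, 4, pi / 2, dispersion = 20,
                      hormone_spec = hs, seed = 13))
  ft <- fold_change_vs_reference(imm, reference = "day_0")
  tab <- fold_significance_table(ft)
  expect_true(all(c("population", "phase", "n", "statistic", "p_raw",
                    "p_adjusted") %in% names(tab)))
  expect_true(all(tab$p_adjusted >= tab$p_raw))
  expect_true(all(tab$p_raw > 0 & tab$p_adjusted <= 1))
  expect_identical(nrow(tab), 3L)  # three non-reference phases
})
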