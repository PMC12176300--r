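test_that("mean normalization divides by the series mean", {
  expect_equal(normalize_series(cycle_series(0:2, c(5, 10, 15)))$values,
               c(0.5, 1.0, 1.5))
  expect_equal(normalize_series(cycle_series(0:2, c(3, 3, 3)))$values,
               c(1, 1, 1))
  out <- normalize_series(cycle_series(0:1, c(2, 4)))
  expect_identical(mean(out$values), 1)
  expect_error(normalize_series(cycle_series(0:1, c(-1, 1))), "degenerate")
})

test_that("single-frequency fit recovers a noiseless sinusoid exactly", {
  t <- 0:181
  ts <- cycle_series(t, sin(2 * pi * t / 11))
  fit <- ls_fit_at_frequency(ts, 1 / 11)
  expect_equal(fit$power, 1, tolerance = 1e-12)
  expect_equal(fit$A, 1, tolerance = 1e-10)
  expect_equal(fit$B, 0, tolerance = 1e-10)
  expect_equal(fit$C, 0, tolerance = 1e-10)
  expect_false(fit$rank_deficient)
  # constant series has SSR0 = 0 and no defined power
  expect_error(ls_fit_at_frequency(cycle_series(0:5, rep(2, 6)), 0.1),
               "constant")
})

test_that("single-frequency fit matches the normal-equations oracle", {
  t <- c(0, 1, 2, 4, 7, 9)
  y <- c(1.2, 0.7, 0.4, 1.5, 0.2, 1.1)
  ts <- cycle_series(t, y)
  fit <- ls_fit_at_frequency(ts, 0.2)
  expect_equal(unname(c(fit$A, fit$B, fit$C)),
               unname(oracle_coefs(t, y, 0.2)), tolerance = 1e-10)
  expect_equal(fit$power, oracle_power(t, y, 0.2), tolerance = 1e-12)
})

test_that("frequency grid follows the span / pseudo-Nyquist formulas", {
  # daily sampling with a 182-day span
  g <- build_frequency_grid(cycle_series(0:182, rnorm(183)), oversample = 5)
  expect_equal(g$f_min, 1 / 182)
  expect_equal(max(g$frequencies), 0.5, tolerance = 1e-9)
  expect_equal(diff(g$frequencies)[1], 1 / 910, tolerance = 1e-12)
  expect_true(all(diff(g$frequencies) > 0))
  # macaque-like design: span 63 d, spacing 3.5 d -> f_max = 1/7
  gm <- build_frequency_grid(cycle_series(seq(0, 63, 3.5), rnorm(19)))
  expect_equal(gm$f_max, 1 / 7, tolerance = 1e-9)
  # too few distinct times
  expect_error(build_frequency_grid(cycle_series(c(0, 5), c(1, 2))))
  expect_error(build_frequency_grid(cycle_series(c(0, 0, 5, 5), c(1, 2, 1, 2))))
})

test_that("periodogram peaks at the true frequency and is affine invariant", {
  t <- 0:100
  y <- 3 + 0.8 * sin(2 * pi * t / 20 + 0.7)
  ts <- cycle_series(t, y)
  grid <- build_frequency_grid(ts)
  # put the true frequency on the grid
  grid$frequencies <- sort(unique(c(grid$frequencies, 1 / 20)))
  grid$n_freq <- length(grid$frequencies)
  pg <- compute_periodogram(ts, grid)
  pk <- find_dominant_peak(pg)
  expect_equal(pk$frequency, 1 / 20)
  expect_equal(pk$power, 1, tolerance = 1e-10)
  expect_true(all(pg$power >= 0 & pg$power <= 1))
  # affine invariance: y -> a*y + b leaves the whole power vector unchanged
  ts2 <- cycle_series(t, 10 * y)
  ts3 <- cycle_series(t, -2.5 * y + 40)
  expect_equal(compute_periodogram(ts2, grid)$power, pg$power,
               tolerance = 1e-10)
  expect_equal(compute_periodogram(ts3, grid)$power, pg$power,
               tolerance = 1e-10)
})

test_that("periodogram equals the lm() oracle on random irregular series", {
  set.seed(301)
  for (i in 1:25) {
    ts <- random_series(n = sample(8:16, 1))
    grid <- build_frequency_grid(ts, oversample = 2)
    pg <- compute_periodogram(ts, grid)
    j <- sample(length(grid$frequencies), 4L)
    for (f_idx in j) {
      expect_equal(pg$power[f_idx],
                   oracle_power(ts$times, ts$values, grid$frequencies[f_idx]),
                   tolerance = 1e-10)
    }
  }
})

test_that("dominant-peak extraction breaks ties toward the longest period", {
  pg <- structure(list(frequency = c(0.05, 0.09, 0.2),
                       period = 1 / c(0.05, 0.09, 0.2),
                       power = c(0.1, 0.9, 0.3)),
                  class = "periodogram")
  pk <- find_dominant_peak(pg)
  expect_equal(pk$frequency, 0.09)
  expect_equal(pk$period, 1 / 0.09, tolerance = 1e-12)
  expect_false(pk$tie)
  # exact tie: lower frequency wins, flag set
  pg$power <- c(0.5, 0.5, 0.2)
  pk2 <- find_dominant_peak(pg)
  expect_equal(pk2$frequency, 0.05)
  expect_true(pk2$tie)
  expect_false(pk2$degenerate)
  # flat periodogram: degenerate flag
  pg$power <- rep(0.3, 3)
  expect_true(find_dominant_peak(pg)$degenerate)
})

test_that("bootstrap FAP hits the add-one floor for a perfect sinusoid", {
  t <- 0:181
  ts <- normalize_series(cycle_series(t, 10 + 8 * sin(2 * pi * t / 11)))
  grid <- build_frequency_grid(ts)
  pk <- find_dominant_peak(compute_periodogram(ts, grid))
  fap <- false_alarm_probability(ts, pk, grid, n_resamples = 99, seed = 1)
  # no permutation reproduces SSR = 0, so the count is 0 and fap = 1/(R+1)
  expect_equal(fap$fap, 1 / 100)
  expect_error(false_alarm_probability(ts, pk, grid, n_resamples = 50),
               "99")
})

test_that("bootstrap FAP is seeded and monotone in the observed power", {
  set.seed(77)
  ts <- cycle_series(0:49, rnorm(50))
  grid <- build_frequency_grid(ts)
  pk <- find_dominant_peak(compute_periodogram(ts, grid))
  f1 <- false_alarm_probability(ts, pk, grid, n_resamples = 199, seed = 5)
  f2 <- false_alarm_probability(ts, pk, grid, n_resamples = 199, seed = 5)
  expect_identical(f1$fap, f2$fap)
  # same null draws, increasing claimed power -> non-increasing fap
  faps <- vapply(c(0.1, 0.3, 0.5, 0.8, 1.0), function(pow) {
    fake <- pk
    fake$power <- pow
    false_alarm_probability(ts, fake, grid, n_resamples = 199, seed = 5)$fap
  }, numeric(1L))
  expect_true(all(diff(faps) <= 0))
  expect_true(all(faps > 0 & faps <= 1))
})

test_that("analytic FAP bound is a sane approximation", {
  t <- 0:99
  strong <- cycle_fit(cycle_series(t, 5 + 2 * sin(2 * pi * t / 12)),
                      fap = "baluev")
  expect_lt(strong$fap$fap, 1e-6)
  set.seed(8)
  noise <- cycle_fit(cycle_series(t, rnorm(100)), fap = "baluev")
  expect_gt(noise$fap$fap, 0.01)
  expect_lte(noise$fap$fap, 1)
})
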