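norm_ts <- function(times, values, ...) {
  ts <- cycle_series(times, values, ...)
  ts$normalized <- TRUE   # already on the scale fit_waveform expects
  ts
}

test_that("waveform fit recovers pure sine and cosine exactly", {
  t <- seq(0, 50, by = 0.25)
  fs <- fit_waveform(norm_ts(t, sin(2 * pi * t / 10)), 1 / 10)
  expect_equal(c(fs$A, fs$B, fs$C), c(1, 0, 0), tolerance = 1e-8)
  expect_equal(fs$amplitude, 1, tolerance = 1e-8)
  expect_equal(fs$phase_offset, 0, tolerance = 1e-8)
  fc <- fit_waveform(norm_ts(t, cos(2 * pi * t / 10)), 1 / 10)
  expect_equal(c(fc$A, fc$B), c(0, 1), tolerance = 1e-8)
  expect_equal(fc$phase_offset, pi / 2, tolerance = 1e-8)
})

test_that("waveform coefficients match the normal-equations oracle", {
  t <- c(0, 1, 2, 4, 7, 9)
  y <- c(1.2, 0.7, 0.4, 1.5, 0.2, 1.1)
  ts <- normalize_series(cycle_series(t, y))
  pg <- compute_periodogram(ts, build_frequency_grid(ts, oversample = 3))
  pk <- find_dominant_peak(pg)
  fw <- fit_waveform(ts, pk)
  expect_equal(unname(coef(fw)),
               unname(oracle_coefs(ts$times, ts$values, pk$frequency)),
               tolerance = 1e-10)
})

test_that("amplitude-phase identity holds on random coefficients", {
  set.seed(42)
  t <- seq(0, 30, length.out = 57)
  for (i in 1:50) {
    fit <- sinusoid_fit(frequency = runif(1, 0.02, 0.5),
                        A = rnorm(1), B = rnorm(1), C = rnorm(1))
    lhs <- predict(fit, t)
    rhs <- fit$amplitude * sin(2 * pi * fit$frequency * t + fit$phase_offset) +
      fit$C
    expect_equal(lhs, rhs, tolerance = 1e-10)
  }
})

test_that("phase angle places the fitted peak at pi/2 and trough at 3pi/2", {
  fit <- sinusoid_fit(frequency = 1 / 10, A = 1, B = 0, C = 0)
  expect_equal(phase_angle(fit, 2.5), pi / 2, tolerance = 1e-12)
  expect_equal(phase_angle(fit, 7.5), 3 * pi / 2, tolerance = 1e-12)
  # periodicity
  expect_equal(phase_angle(fit, 3.1 + 10), phase_angle(fit, 3.1),
               tolerance = 1e-12)
  # randomized fits: argmax/argmin of the reconstruction land on pi/2, 3pi/2
  set.seed(7)
  for (i in 1:25) {
    f <- sinusoid_fit(frequency = runif(1, 0.05, 0.4),
                      A = rnorm(1), B = rnorm(1), C = rnorm(1))
    if (f$amplitude < 1e-6) next
    tt <- seq(0, f$period, length.out = 20001)
    y <- predict(f, tt)
    res <- 2 * pi / 20000
    expect_equal(phase_angle(f, tt[which.max(y)]), pi / 2,
                 tolerance = 2 * res)
    th_min <- phase_angle(f, tt[which.min(y)])
    expect_equal(th_min, 3 * pi / 2, tolerance = 2 * res)
    expect_equal(max(y), f$C + f$amplitude, tolerance = 1e-6)
    expect_equal(min(y), f$C - f$amplitude, tolerance = 1e-6)
  }
  # zero amplitude: phase undefined
  expect_error(phase_angle(sinusoid_fit(0.1, 0, 0, 1), 1), "amplitude")
})

test_that("day windows map to the printed angular windows and back", {
  fit <- sinusoid_fit(frequency = 1 / 10, A = 1, B = 0, C = 0) # peak day 2.5
  pw <- day_window_to_phase(fit, day_window("luteal", 10 / 6, 10 / 3, 10))
  expect_equal(pw$angle_start, pi / 3, tolerance = 1e-9)
  expect_equal(pw$angle_end, 2 * pi / 3, tolerance = 1e-9)
  # full cycle spans 2*pi radians
  full <- day_window_to_phase(fit, day_window("cycle", 0, 10, 10))
  arc <- (full$angle_end - full$angle_start) %% (2 * pi)
  expect_true(arc == 0 || abs(arc - 2 * pi) < 1e-9)
  # inverse mapping
  dw <- phase_to_day_window(fit, phase_window("luteal", pi / 3, 2 * pi / 3))
  expect_equal(dw$day_start, 10 / 6, tolerance = 1e-9)
  expect_equal(dw$day_end, 10 / 3, tolerance = 1e-9)
  # cycle-length mismatch beyond 20% warns
  expect_warning(day_window_to_phase(fit, day_window("w", 1, 3, 32)),
                 "cycle_length")
})

test_that("day -> angle -> day round trip is exact on randomized fits", {
  set.seed(11)
  for (i in 1:40) {
    fit <- sinusoid_fit(frequency = runif(1, 0.02, 0.3),
                        A = rnorm(1), B = rnorm(1))
    if (fit$amplitude < 1e-6) next
    T_ <- fit$period
    d0 <- runif(1, 0, 0.8 * T_)
    d1 <- runif(1, d0 + 0.05 * T_, T_)
    dw <- day_window("w", d0, d1, T_)
    back <- phase_to_day_window(fit, day_window_to_phase(fit, dw))
    expect_equal(((back$day_start - dw$day_start) %% T_ + T_ / 2) %% T_ - T_ / 2,
                 0, tolerance = 1e-9)
    expect_equal(back$day_end - back$day_start, d1 - d0, tolerance = 1e-9)
  }
})

test_that("cross-species alignment composes, scales, and inverts", {
  src <- sinusoid_fit(frequency = 1 / 32, A = 0.3, B = 0.4, C = 1)
  # identical fits: identity mapping
  w <- day_window("luteal", 16, 25, 32)
  same <- align_species(src, list(w), src)[[1]]
  expect_equal(((same$day_start - 16) %% 32 + 16) %% 32, 16, tolerance = 1e-9)
  expect_equal(same$day_end - same$day_start, 9, tolerance = 1e-9)
  # half the period halves the day widths
  half <- sinusoid_fit(frequency = 2 / 32, A = 0.3, B = 0.4, C = 1)
  mapped <- align_species(src, list(w), half)[[1]]
  expect_equal(mapped$day_end - mapped$day_start, 4.5, tolerance = 1e-9)
  # macaque -> mouse with known offsets vs the closed-form answer
  mac <- sinusoid_fit(frequency = 1 / 32, A = cos(0.4), B = sin(0.4))
  mou <- sinusoid_fit(frequency = 1 / 11, A = cos(1.1), B = sin(1.1))
  got <- align_species(mac, list(w), mou)[[1]]
  theta16 <- (2 * pi * 16 / 32 + 0.4) %% (2 * pi)
  t_exp <- ((theta16 - 1.1) %% (2 * pi)) * 11 / (2 * pi)
  expect_equal(got$day_start, t_exp, tolerance = 1e-9)
  expect_equal(got$day_end - got$day_start, 9 * 11 / 32, tolerance = 1e-9)
  # invertibility: target -> source recovers the original window
  back <- align_species(mou, got, mac)[[1]]
  expect_equal(((back$day_start - 16) %% 32 + 16) %% 32, 16, tolerance = 1e-9)
  expect_equal(back$day_end - back$day_start, 9, tolerance = 1e-9)
})

test_that("wrapped windows split cleanly at day zero", {
  fit <- sinusoid_fit(frequency = 1 / 10, A = 0, B = 1) # phi = pi/2, peak day 0
  # window straddling the peak wraps past day 0 on this fit
  dw <- phase_to_day_window(fit, phase_window("peri_peak", pi / 4, 3 * pi / 4))
  expect_gt(dw$day_end, dw$cycle_length)
  parts <- split_day_window(dw)
  expect_length(parts, 2L)
  total <- sum(vapply(parts, function(p) p$day_end - p$day_start, numeric(1)))
  expect_equal(total, dw$day_end - dw$day_start, tolerance = 1e-9)
  expect_true(all(vapply(parts, function(p) p$day_end <= p$cycle_length,
                         logical(1))))
})
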