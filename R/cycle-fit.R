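#' Fit an oscillation model to a hormone time series
#'
#' The package's central fitting function. Composes the full single-series
#' analysis: mean-normalization, frequency-grid construction, generalized
#' (floating-mean) least-squares periodogram, dominant-peak extraction,
#' false-alarm-probability estimation, and sinusoid waveform reconstruction
#' at the dominant frequency.
#'
#' @param ts A [cycle_series()] (raw scale; normalization happens inside).
#' @param oversample Frequency-grid oversampling factor (default 5).
#' @param max_period_fraction Longest period searched as a fraction of the
#'   observation span (default 1).
#' @param fap `"bootstrap"` (default), `"baluev"`, or `"none"` to skip the
#'   significance computation.
#' @param n_resamples Permutations for the bootstrap FAP (>= 99).
#' @param seed Seed for the FAP permutation stream.
#' @return An object of class `cycle_fit` with components `series` (the
#'   normalized series), `series_mean`, `grid`, `periodogram`, `peak`,
#'   `fap` (a `fap_result` or NULL), and `waveform` (a `sinusoid_fit`).
#'   Methods: [print()], [summary()], [coef()] (A, B, C), [predict()]
#'   (reconstructed waveform), [fitted()], [residuals()], [plot()].
#' @examples
#' sp <- cycle_preset("mouse-pseudopregnancy", seed = 7)
#' fit <- cycle_fit(generate_hormone_series(sp, 1), fap = "none")
#' fit$peak$period # close to 11 days
#' @export
cycle_fit <- function(ts, oversample = 5, max_period_fraction = 1,
                      fap = c("bootstrap", "baluev", "none"),
                      n_resamples = 999L, seed = 1L) {
  fap <- match.arg(fap)
  .check_spectral_series(ts)
  series_mean <- mean(ts$values)
  nts <- normalize_series(ts)
  grid <- build_frequency_grid(nts, oversample = oversample,
                               max_period_fraction = max_period_fraction)
  pg <- compute_periodogram(nts, grid)
  peak <- find_dominant_peak(pg)
  fap_res <- if (fap == "none") NULL else {
    false_alarm_probability(nts, peak, grid, method = fap,
                            n_resamples = n_resamples, seed = seed)
  }
  wf <- suppressWarnings(fit_waveform(nts, peak))
  wf$animal_id <- ts$animal_id
  structure(
    list(series = nts, series_mean = series_mean, grid = grid,
         periodogram = pg, peak = peak, fap = fap_res, waveform = wf,
         call = match.call()),
    class = "cycle_fit"
  )
}

#' @export
print.cycle_fit <- function(x, ...) {
  cat(sprintf("<cycle_fit> %s / %s\n", x$series$animal_id, x$series$analyte))
  cat(sprintf("  dominant period: %.4g d (power %.4f)\n",
              x$peak$period, x$peak$power))
  if (!is.null(x$fap)) {
    cat(sprintf("  false alarm probability: %.4g (%s)\n",
                x$fap$fap, x$fap$method))
  }
  cat(sprintf("  waveform: R = %.4g, phi = %.4g rad, C = %.4g (normalized scale)\n",
              x$waveform$amplitude, x$waveform$phase_offset, x$waveform$C))
  invisible(x)
}

#' @export
summary.cycle_fit <- function(object, ...) {
  wf <- object$waveform
  peak_day <- ((pi / 2 - wf$phase_offset) %% (2 * pi)) * wf$period / (2 * pi)
  out <- list(
    animal_id = object$series$animal_id,
    analyte = object$series$analyte,
    n_obs = length(object$series$times),
    span_days = diff(range(object$series$times)),
    series_mean = object$series_mean,
    n_freq = object$grid$n_freq,
    period = object$peak$period,
    frequency = object$peak$frequency,
    power = object$peak$power,
    fap = if (is.null(object$fap)) NA_real_ else object$fap$fap,
    fap_method = if (is.null(object$fap)) NA_character_ else object$fap$method,
    amplitude = wf$amplitude,
    phase_offset = wf$phase_offset,
    offset = wf$C,
    peak_day = peak_day,
    trough_day = (peak_day + wf$period / 2) %% wf$period
  )
  class(out) <- "summary.cycle_fit"
  out
}

#' @export
print.summary.cycle_fit <- function(x, ...) {
  cat(sprintf("Oscillation fit for %s / %s\n", x$animal_id, x$analyte))
  cat(sprintf("  %d observations over %.4g days (series mean %.4g)\n",
              x$n_obs, x$span_days, x$series_mean))
  cat(sprintf("  dominant period %.4g d at power %.4f over %d frequencies\n",
              x$period, x$power, x$n_freq))
  if (!is.na(x$fap)) {
    cat(sprintf("  false alarm probability %.4g (%s)\n", x$fap, x$fap_method))
  }
  cat(sprintf("  normalized amplitude %.4g, offset %.4g\n", x$amplitude, x$offset))
  cat(sprintf("  waveform peak at cycle day %.4g (theta = pi/2), trough at %.4g (3pi/2)\n",
              x$peak_day, x$trough_day))
  invisible(x)
}

#' @export
coef.cycle_fit <- function(object, ...) coef(object$waveform)

#' Predict from a fitted oscillation model
#'
#' @param object A [cycle_fit()].
#' @param newdata Times in days (vector or data.frame with a `day` column);
#'   default: the observed sampling times.
#' @param scale `"normalized"` (mean-1 scale of the fit) or `"original"`
#'   (multiplied back by the series mean).
#' @param ... Unused.
#' @return Reconstructed waveform values.
#' @export
predict.cycle_fit <- function(object, newdata = NULL,
                              scale = c("normalized", "original"), ...) {
  scale <- match.arg(scale)
  if (is.null(newdata)) newdata <- object$series$times
  y <- predict(object$waveform, newdata)
  if (scale == "original") y <- y * object$series_mean
  y
}

#' @export
fitted.cycle_fit <- function(object, ...) {
  predict(object, object$series$times)
}

#' @export
residuals.cycle_fit <- function(object, ...) {
  object$series$values - fitted(object)
}

#' @export
plot.cycle_fit <- function(x, which = c("both", "periodogram", "waveform"),
                           ...) {
  which <- match.arg(which)
  if (which == "both") {
    op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
    on.exit(graphics::par(op), add = TRUE)
  }
  if (which %in% c("both", "periodogram")) plot(x$periodogram)
  if (which %in% c("both", "waveform")) {
    ts <- x$series
    graphics::plot(ts$times, ts$values, pch = 16, cex = 0.6,
                   xlab = "day", ylab = "mean-normalized value",
                   main = sprintf("Reconstructed waveform (T = %.3g d)",
                                  x$peak$period))
    tt <- seq(min(ts$times), max(ts$times), length.out = 500L)
    graphics::lines(tt, predict(x$waveform, tt), col = "red3", lwd = 1.5)
  }
  invisible(x)
}
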