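#' Fit the sinusoid waveform at a dominant frequency
#'
#' Reconstructs the cycle waveform by least squares at the dominant
#' periodogram frequency:
#' \deqn{\hat y(t) = A\sin(2\pi f t) + B\cos(2\pi f t) + C
#'                = R\sin(2\pi f t + \varphi) + C,}
#' with amplitude `R = sqrt(A^2 + B^2)` and phase offset
#' `phi = atan2(B, A)`. On this convention the waveform attains its maximum
#' exactly at phase angle `pi/2` and its minimum at `3pi/2` (see
#' [phase_angle()]).
#'
#' @param ts A mean-normalized [cycle_series()] (see [normalize_series()]);
#'   a non-normalized series is accepted with a warning since the
#'   coefficients then live on the raw scale.
#' @param peak A [find_dominant_peak()] result, or a single frequency in
#'   cycles/day.
#' @return An object of class `sinusoid_fit`: `frequency`, `period`, `A`,
#'   `B`, `C`, `amplitude`, `phase_offset` (radians), `fit_domain`,
#'   `rank_deficient`.
#' @examples
#' t <- seq(0, 40, by = 0.5)
#' fw <- fit_waveform(cycle_series(t, 1 + 0.4 * sin(2 * pi * t / 10)), 1 / 10)
#' c(fw$amplitude, fw$phase_offset) # 0.4, 0
#' @export
fit_waveform <- function(ts, peak) {
  f <- if (inherits(peak, "periodogram_peak")) peak$frequency else as.numeric(peak)
  if (!isTRUE(ts$normalized)) {
    warning("series is not mean-normalized; coefficients are on the raw scale")
  }
  co <- ls_fit_at_frequency(ts, f)
  structure(
    list(
      frequency = f, period = 1 / f,
      A = co$A, B = co$B, C = co$C,
      amplitude = sqrt(co$A^2 + co$B^2),
      phase_offset = atan2(co$B, co$A),
      power = co$power,
      fit_domain = range(ts$times),
      rank_deficient = co$rank_deficient,
      animal_id = ts$animal_id
    ),
    class = "sinusoid_fit"
  )
}

#' Construct a sinusoid fit from known coefficients
#'
#' Mostly useful for tests and for phase-window arithmetic on analytically
#' specified waveforms.
#'
#' @param frequency Cycles/day, > 0.
#' @param A,B,C Sine, cosine and offset coefficients.
#' @param fit_domain Optional day range the fit applies to.
#' @return A `sinusoid_fit` object, as from [fit_waveform()].
#' @export
sinusoid_fit <- function(frequency, A, B, C = 0,
                         fit_domain = c(0, 1 / frequency)) {
  if (frequency <= 0) stop("'frequency' must be > 0")
  structure(
    list(frequency = frequency, period = 1 / frequency,
         A = A, B = B, C = C,
         amplitude = sqrt(A^2 + B^2), phase_offset = atan2(B, A),
         power = NA_real_, fit_domain = fit_domain,
         rank_deficient = FALSE, animal_id = NA_character_),
    class = "sinusoid_fit"
  )
}

#' @export
print.sinusoid_fit <- function(x, ...) {
  cat(sprintf(
    paste0("<sinusoid_fit> period %.4g d: A = %.4g, B = %.4g, C = %.4g\n",
           "  amplitude R = %.4g, phase offset phi = %.4g rad",
           " (peak at day %.4g of the cycle)\n"),
    x$period, x$A, x$B, x$C, x$amplitude, x$phase_offset,
    ((pi / 2 - x$phase_offset) %% (2 * pi)) * x$period / (2 * pi)
  ))
  invisible(x)
}

#' @export
coef.sinusoid_fit <- function(object, ...) {
  c(A = object$A, B = object$B, C = object$C)
}

#' Evaluate the reconstructed waveform
#'
#' @param object A `sinusoid_fit`.
#' @param newdata Times (days) at which to evaluate; a numeric vector or a
#'   data.frame with a `day` column. Default: 200 points over the fit
#'   domain.
#' @param ... Unused.
#' @return Numeric vector `A sin(2 pi f t) + B cos(2 pi f t) + C`.
#' @export
predict.sinusoid_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) {
    seq(object$fit_domain[1L], object$fit_domain[2L], length.out = 200L)
  } else if (is.data.frame(newdata)) {
    newdata$day
  } else {
    as.numeric(newdata)
  }
  w <- 2 * pi * object$frequency * t
  object$A * sin(w) + object$B * cos(w) + object$C
}

.check_oscillating <- function(fit) {
  if (!inherits(fit, "sinusoid_fit")) stop("expected a 'sinusoid_fit' object")
  if (!is.finite(fit$amplitude) || fit$amplitude <= 0) {
    stop("fit has zero amplitude: phase angle is undefined")
  }
  invisible(fit)
}

#' Cycle phase angle of a day
#'
#' Maps a time in days onto the cycle phase angle
#' \deqn{\theta(t) = (2\pi f t + \varphi) \bmod 2\pi,}
#' under which the reconstructed waveform attains its maximum `C + R`
#' exactly at `theta = pi/2` and its minimum `C - R` at `theta = 3pi/2` —
#' the peak/trough radian convention used for cross-species phase mapping.
#'
#' @param fit A `sinusoid_fit` with positive amplitude.
#' @param t Time(s) in days.
#' @return Phase angle(s) in radians, in `[0, 2pi)`.
#' @export
phase_angle <- function(fit, t) {
  .check_oscillating(fit)
  (2 * pi * fit$frequency * t + fit$phase_offset) %% (2 * pi)
}

#' A named cycle-phase window as an angle interval
#'
#' @param name Window label (e.g. `"luteal"`).
#' @param angle_start Start angle, radians in `[0, 2pi)`.
#' @param angle_end End angle, radians in `(0, 2pi]`; a window with
#'   `angle_end <= angle_start` wraps past `2pi`.
#' @return An object of class `phase_window`.
#' @export
phase_window <- function(name, angle_start, angle_end) {
  if (angle_start < 0 || angle_start >= 2 * pi) {
    stop("'angle_start' must be in [0, 2*pi)")
  }
  if (angle_end <= 0 || angle_end > 2 * pi) {
    stop("'angle_end' must be in (0, 2*pi]")
  }
  structure(
    list(name = as.character(name)[1L],
         angle_start = angle_start, angle_end = angle_end),
    class = "phase_window"
  )
}

# angular window length in (0, 2*pi]
.window_arc <- function(pw) {
  len <- (pw$angle_end - pw$angle_start) %% (2 * pi)
  if (len == 0) 2 * pi else len
}

#' @export
print.phase_window <- function(x, ...) {
  cat(sprintf("<phase_window> %s: %.4g-%.4g rad (%.1f-%.1f deg)%s\n",
              x$name, x$angle_start, x$angle_end,
              x$angle_start * 180 / pi, x$angle_end * 180 / pi,
              if (x$angle_end <= x$angle_start) " [wraps]" else ""))
  invisible(x)
}

#' A named cycle-phase window as a day interval
#'
#' @param name Window label.
#' @param day_start,day_end Day interval within the cycle;
#'   `day_end > day_start`. `day_end` may exceed `cycle_length` for a
#'   window that wraps past day 0 (see [split_day_window()]).
#' @param cycle_length Cycle length in days.
#' @return An object of class `day_window`.
#' @export
day_window <- function(name, day_start, day_end, cycle_length) {
  if (cycle_length <= 0) stop("'cycle_length' must be > 0")
  if (day_start < 0 || day_start >= cycle_length) {
    stop("'day_start' must be in [0, cycle_length)")
  }
  if (day_end <= day_start) stop("'day_end' must exceed 'day_start'")
  if (day_end - day_start > cycle_length) {
    stop("window longer than one cycle")
  }
  structure(
    list(name = as.character(name)[1L], day_start = day_start,
         day_end = day_end, cycle_length = cycle_length),
    class = "day_window"
  )
}

#' @export
print.day_window <- function(x, ...) {
  cat(sprintf("<day_window> %s: days %.4g-%.4g of a %.4g-day cycle%s\n",
              x$name, x$day_start, x$day_end, x$cycle_length,
              if (x$day_end > x$cycle_length) " [wraps]" else ""))
  invisible(x)
}

#' Split a wrapped day window at day 0
#'
#' Windows are carried wrapped (with `day_end > cycle_length`) internally;
#' for serialization they can be split into at most two in-cycle segments.
#'
#' @param dw A [day_window()].
#' @return A list of one or two `day_window` objects within
#'   `[0, cycle_length]`.
#' @export
split_day_window <- function(dw) {
  if (dw$day_end <= dw$cycle_length) return(list(dw))
  list(
    day_window(dw$name, dw$day_start, dw$cycle_length, dw$cycle_length),
    day_window(paste0(dw$name, "_wrap"), 0, dw$day_end - dw$cycle_length,
               dw$cycle_length)
  )
}

#' Map a day window to a phase-angle window
#'
#' Under the uniform-angular-rate convention (one cycle of `2pi` radians per
#' fitted period `T`), a day interval maps to the angle interval bounded by
#' [phase_angle()] of its endpoints.
#'
#' @param fit A `sinusoid_fit` with positive amplitude.
#' @param dw A [day_window()]. A warning is issued when `dw$cycle_length`
#'   differs from the fitted period by more than 20%.
#' @return A [phase_window()].
#' @export
day_window_to_phase <- function(fit, dw) {
  .check_oscillating(fit)
  if (!inherits(dw, "day_window")) stop("expected a 'day_window' object")
  if (abs(dw$cycle_length - fit$period) / fit$period > 0.2) {
    warning(sprintf(
      "window cycle_length (%.4g d) differs from fitted period (%.4g d) by > 20%%",
      dw$cycle_length, fit$period
    ))
  }
  a0 <- phase_angle(fit, dw$day_start)
  a1 <- phase_angle(fit, dw$day_end)
  if (a1 == 0 && dw$day_end > dw$day_start) a1 <- 2 * pi
  phase_window(dw$name, a0, a1)
}

#' Map a phase-angle window to a day window
#'
#' Inverse of [day_window_to_phase()] under the uniform-rate convention:
#' `t(theta) = ((theta - phi) mod 2pi) * T/(2pi)`. Windows that wrap past
#' day 0 are returned with `day_end > cycle_length`; split them with
#' [split_day_window()] for reporting.
#'
#' @param fit A `sinusoid_fit` with positive amplitude.
#' @param pw A [phase_window()].
#' @return A [day_window()] with `cycle_length = fit$period`.
#' @export
phase_to_day_window <- function(fit, pw) {
  .check_oscillating(fit)
  if (!inherits(pw, "phase_window")) stop("expected a 'phase_window' object")
  T_ <- fit$period
  t0 <- ((pw$angle_start - fit$phase_offset) %% (2 * pi)) * T_ / (2 * pi)
  len_days <- .window_arc(pw) * T_ / (2 * pi)
  day_window(pw$name, t0, t0 + len_days, T_)
}

#' Translate cycle-phase windows between species
#'
#' Maps named day windows defined on a source species' fitted cycle (e.g.
#' the macaque luteal and late-luteal windows) onto a target species' cycle
#' (e.g. mouse pseudopregnancy): each window goes day -> angle through the
#' source fit, then angle -> day through the target fit. Window order and
#' non-overlap on the circle are preserved, and the composition
#' source -> target -> source is the identity.
#'
#' @param fit_source,fit_target `sinusoid_fit` objects with positive
#'   amplitude.
#' @param windows_source A list of [day_window()] objects on the source
#'   cycle (a single window is accepted).
#' @return A list of [day_window()] objects on the target cycle.
#' @export
align_species <- function(fit_source, windows_source, fit_target) {
  .check_oscillating(fit_source)
  .check_oscillating(fit_target)
  if (inherits(windows_source, "day_window")) {
    windows_source <- list(windows_source)
  }
  lapply(windows_source, function(dw) {
    phase_to_day_window(fit_target, day_window_to_phase(fit_source, dw))
  })
}

#' The printed macaque cycle-phase windows
#'
#' Convenience constructor for the two named luteal-stage windows used in
#' cross-species mapping, as angle intervals: luteal 60-120 degrees
#' (`pi/3`-`2pi/3`) and late luteal 120-210 degrees (`2pi/3`-`7pi/6`).
#'
#' @return A named list of two [phase_window()] objects.
#' @export
luteal_phase_windows <- function() {
  list(
    luteal = phase_window("luteal", pi / 3, 2 * pi / 3),
    late_luteal = phase_window("late_luteal", 2 * pi / 3, 7 * pi / 6)
  )
}
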