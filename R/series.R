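#' Construct an irregularly sampled hormone time series
#'
#' The basic data container of the package: one animal's trajectory of a
#' single analyte (e.g. plasma progesterone), sampled at arbitrary,
#' possibly duplicated, non-negative times in days.
#'
#' @param times Numeric vector of sampling times in days. Finite,
#'   non-negative; duplicates are allowed (same-day technical duplicates are
#'   treated as independent observations throughout, never averaged).
#' @param values Numeric vector of measurements, same length as `times`.
#' @param animal_id Label identifying the animal.
#' @param analyte Label for the measured analyte.
#' @param units Measurement units (informational).
#' @return An object of class `cycle_series` with components `times`
#'   (sorted increasing), `values`, `animal_id`, `analyte`, `units` and
#'   `normalized` (logical; see [normalize_series()]).
#' @examples
#' ts <- cycle_series(0:9, 5 + sin(2 * pi * (0:9) / 10))
#' ts
#' @export
cycle_series <- function(times, values, animal_id = "animal_1",
                         analyte = "progesterone", units = "ng/mL") {
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) != length(values)) {
    stop("'times' and 'values' must have the same length")
  }
  if (length(times) < 1L) stop("empty series")
  if (!all(is.finite(times)) || !all(is.finite(values))) {
    stop("'times' and 'values' must be finite")
  }
  if (any(times < 0)) stop("'times' must be non-negative (days)")
  ord <- order(times)
  structure(
    list(
      animal_id = as.character(animal_id)[1L],
      analyte = as.character(analyte)[1L],
      times = times[ord],
      values = values[ord],
      units = as.character(units)[1L],
      normalized = FALSE
    ),
    class = "cycle_series"
  )
}

#' @export
print.cycle_series <- function(x, ...) {
  cat(sprintf(
    "<cycle_series> %s / %s: %d observations over days %.4g-%.4g%s\n",
    x$animal_id, x$analyte, length(x$times), min(x$times), max(x$times),
    if (isTRUE(x$normalized)) " (mean-normalized)" else ""
  ))
  invisible(x)
}

#' @export
as.data.frame.cycle_series <- function(x, ...) {
  data.frame(
    animal_id = x$animal_id,
    day = x$times,
    analyte = x$analyte,
    value = x$values,
    stringsAsFactors = FALSE
  )
}

#' @export
length.cycle_series <- function(x) length(x$times)

# n distinct time points; spectral ops require >= 3 obs at >= 3 distinct times
.n_distinct_times <- function(ts) length(unique(ts$times))

.check_spectral_series <- function(ts) {
  if (!inherits(ts, "cycle_series")) stop("expected a 'cycle_series' object")
  if (length(ts$times) < 3L) stop("spectral operations need at least 3 observations")
  if (.n_distinct_times(ts) < 3L) {
    stop("spectral operations need at least 3 distinct time points")
  }
  invisible(ts)
}

#' Mean-normalize a series
#'
#' Divides values by the series mean so the normalized series has mean
#' exactly 1. This is the scale on which waveforms are reconstructed and
#' fold changes are plotted; periodogram power is affine-invariant so
#' normalization never changes the spectrum.
#'
#' @param ts A [cycle_series()].
#' @return The series with `values` divided by their mean and the
#'   `normalized` flag set.
#' @examples
#' normalize_series(cycle_series(0:2, c(5, 10, 15)))$values # 0.5 1.0 1.5
#' @export
normalize_series <- function(ts) {
  if (!inherits(ts, "cycle_series")) stop("expected a 'cycle_series' object")
  m <- mean(ts$values)
  if (abs(m) < .Machine$double.eps * max(abs(ts$values), 1)) {
    stop("degenerate series: mean is zero or numerically indistinguishable from zero")
  }
  ts$values <- ts$values / m
  ts$normalized <- TRUE
  ts
}

#' Write a cohort of series as tidy CSV
#'
#' Long format with columns `animal_id, day, analyte, value`. If the cohort
#' carries a generating spec (see [generate_cohort()]) a JSON sidecar
#' `<path>.json` records it, including the seed, for provenance.
#'
#' @param cohort A list of [cycle_series()] objects (class `cycle_cohort`
#'   or plain list).
#' @param path Output CSV path.
#' @param sidecar Write the JSON provenance sidecar? Default `TRUE` when a
#'   spec is attached.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path, sidecar = TRUE) {
  if (inherits(cohort, "cycle_series")) cohort <- list(cohort)
  df <- do.call(rbind, lapply(cohort, as.data.frame))
  utils::write.csv(df, path, row.names = FALSE)
  spec <- attr(cohort, "spec")
  if (sidecar && !is.null(spec)) {
    jsonlite::write_json(unclass(spec), paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read one series from a tidy CSV
#'
#' Expects columns `animal_id, day, analyte, value` as written by
#' [write_cohort_csv()]; selects one `(animal_id, analyte)` pair.
#'
#' @param path CSV path.
#' @param animal_id Animal to select; default: the first in file order.
#' @param analyte Analyte to select; default: the first in file order.
#' @param units Units label to attach.
#' @return A [cycle_series()].
#' @export
read_series_csv <- function(path, animal_id = NULL, analyte = NULL,
                            units = "ng/mL") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "day", "analyte", "value")
  if (!all(need %in% names(df))) {
    stop("CSV must have columns: ", paste(need, collapse = ", "))
  }
  if (is.null(animal_id)) animal_id <- df$animal_id[1L]
  if (is.null(analyte)) analyte <- df$analyte[1L]
  sel <- df$animal_id == animal_id & df$analyte == analyte
  if (!any(sel)) stop("no rows for animal_id=", animal_id, ", analyte=", analyte)
  cycle_series(df$day[sel], df$value[sel],
               animal_id = animal_id, analyte = analyte, units = units)
}
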