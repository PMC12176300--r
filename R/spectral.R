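#' Least-squares sinusoid fit at a single frequency
#'
#' Fits the floating-mean sinusoid
#' \deqn{\phi(t) = A\sin(2\pi f t) + B\cos(2\pi f t) + C}
#' by ordinary least squares and returns the coefficients together with the
#' least-squares spectral power at `f`,
#' \deqn{P(f) = 1 - SSR(f)/SSR_0,}
#' where `SSR(f)` is the residual sum of squares of the three-parameter fit
#' and `SSR_0` the sum of squares about the series mean. The floating mean
#' `C` is what makes the periodogram valid for data with non-zero mean;
#' it also makes `P` invariant under affine transformations of the values.
#'
#' @param ts A [cycle_series()] with at least 3 observations at 3 distinct
#'   times.
#' @param f Frequency in cycles/day, > 0.
#' @return A list with components `A`, `B`, `C`, `power` (in `[0, 1]`) and
#'   `rank_deficient` (TRUE when the sampling aliases the sinusoid so the
#'   design loses rank; the minimum-norm solution is returned then).
#' @examples
#' t <- 0:49
#' fit <- ls_fit_at_frequency(cycle_series(t, sin(2 * pi * t / 11)), 1 / 11)
#' round(c(fit$A, fit$B, fit$C, fit$power), 6) # 1 0 0 1
#' @export
ls_fit_at_frequency <- function(ts, f) {
  .check_spectral_series(ts)
  if (!is.numeric(f) || length(f) != 1L || !is.finite(f) || f <= 0) {
    stop("'f' must be a single positive frequency (cycles/day)")
  }
  t <- ts$times
  y <- ts$values
  ssr0 <- sum((y - mean(y))^2)
  if (ssr0 <= .Machine$double.eps * sum(y^2)) {
    stop("constant series: SSR0 = 0, spectral power undefined")
  }
  X <- cbind(sin = sin(2 * pi * f * t), cos = cos(2 * pi * f * t), C = 1)
  qx <- qr(X)
  rank_deficient <- qx$rank < 3L
  if (!rank_deficient) {
    beta <- qr.coef(qx, y)
    res <- y - X %*% beta
  } else {
    # minimum-norm solution via the pseudoinverse
    sv <- svd(X)
    pos <- sv$d > max(sv$d) * 1e-12
    beta <- sv$v[, pos, drop = FALSE] %*%
      ((crossprod(sv$u[, pos, drop = FALSE], y)) / sv$d[pos])
    beta <- drop(beta)
    names(beta) <- colnames(X)
    res <- y - X %*% beta
  }
  power <- 1 - sum(res^2) / ssr0
  power <- min(max(power, 0), 1)
  list(A = unname(beta["sin"]), B = unname(beta["cos"]),
       C = unname(beta["C"]), power = power,
       rank_deficient = rank_deficient)
}

#' Frequency grid for an unevenly sampled series
#'
#' Standard construction for least-squares spectra of irregular series:
#' the lowest frequency resolves one cycle over a chosen fraction of the
#' observation span, the highest is a pseudo-Nyquist limit from the median
#' spacing of distinct sampling times, and the grid is oversampled relative
#' to the natural resolution `1/span`:
#' `f_min = 1/(max_period_fraction * span)`,
#' `f_max = 1/(2 * median spacing)`, spacing `1/(oversample * span)`.
#'
#' @param ts A [cycle_series()] with at least two distinct times.
#' @param oversample Oversampling factor, >= 1 (default 5).
#' @param max_period_fraction Longest period searched, as a fraction of the
#'   span (default 1 = one cycle over the whole record).
#' @return An object of class `frequency_grid` with components
#'   `frequencies`, `f_min`, `f_max`, `n_freq`, `oversample`.
#' @export
build_frequency_grid <- function(ts, oversample = 5, max_period_fraction = 1) {
  if (!inherits(ts, "cycle_series")) stop("expected a 'cycle_series' object")
  if (oversample < 1) stop("'oversample' must be >= 1")
  if (max_period_fraction <= 0) stop("'max_period_fraction' must be > 0")
  tu <- sort(unique(ts$times))
  if (length(tu) < 3L) {
    stop("need at least 3 distinct time points to build a frequency grid")
  }
  span <- max(tu) - min(tu)
  dt_med <- stats::median(diff(tu))
  f_min <- 1 / (max_period_fraction * span)
  f_max <- 1 / (2 * dt_med)
  if (f_max <= f_min) {
    stop("degenerate sampling: pseudo-Nyquist limit does not exceed 1/span")
  }
  spacing <- 1 / (oversample * span)
  freqs <- seq(f_min, f_max, by = spacing)
  structure(
    list(frequencies = freqs, f_min = f_min, f_max = max(freqs),
         n_freq = length(freqs), oversample = oversample,
         max_period_fraction = max_period_fraction),
    class = "frequency_grid"
  )
}

#' @export
print.frequency_grid <- function(x, ...) {
  cat(sprintf(
    "<frequency_grid> %d frequencies in [%.6g, %.6g] cycles/day (periods %.4g-%.4g d)\n",
    x$n_freq, x$f_min, x$f_max, 1 / x$f_max, 1 / x$f_min
  ))
  invisible(x)
}

# Orthonormal bases of span{1, sin(2 pi f t), cos(2 pi f t)} for every grid
# frequency, stacked column-wise. Shared by the periodogram and the
# permutation null so resampling reuses one QR pass.
.ls_basis <- function(times, freqs) {
  n <- length(times)
  qs <- vector("list", length(freqs))
  ranks <- integer(length(freqs))
  for (j in seq_along(freqs)) {
    w <- 2 * pi * freqs[j] * times
    X <- cbind(1, sin(w), cos(w))
    qx <- qr(X)
    r <- qx$rank
    qs[[j]] <- qr.Q(qx)[, seq_len(r), drop = FALSE]
    ranks[j] <- r
  }
  list(Q = do.call(cbind, qs), ranks = ranks,
       idx_end = cumsum(ranks), n = n)
}

# Power matrix (n_freq x n_series) from a precomputed basis. Y is a matrix
# with one series per column. P = (||Q_f' y||^2 - n ybar^2) / SSR0, clamped
# into [0,1] against roundoff.
.ls_power_matrix <- function(basis, Y) {
  Y <- as.matrix(Y)
  n <- basis$n
  if (nrow(Y) != n) stop("series length does not match basis")
  tot <- colSums(Y^2)
  meanpart <- colSums(Y)^2 / n
  ssr0 <- tot - meanpart
  if (any(ssr0 <= .Machine$double.eps * pmax(tot, 1))) {
    stop("constant series: SSR0 = 0, spectral power undefined")
  }
  QtY2 <- crossprod(basis$Q, Y)^2              # (sum ranks) x m
  start <- c(1L, utils::head(basis$idx_end, -1L) + 1L)
  nf <- length(basis$ranks)
  P <- matrix(NA_real_, nf, ncol(Y))
  for (j in seq_len(nf)) {
    rows <- start[j]:basis$idx_end[j]
    fitSS <- if (length(rows) == 1L) QtY2[rows, ] else colSums(QtY2[rows, , drop = FALSE])
    P[j, ] <- (fitSS - meanpart) / ssr0
  }
  P[P < 0] <- 0
  P[P > 1] <- 1
  P
}

#' Generalized least-squares periodogram
#'
#' Computes the floating-mean least-squares power `P(f) = 1 - SSR(f)/SSR0`
#' (see [ls_fit_at_frequency()]) over a frequency grid. Power is bounded in
#' `[0, 1]` and unchanged by affine rescaling of the series values, so it
#' may be computed on raw or mean-normalized data interchangeably.
#'
#' @param ts A [cycle_series()].
#' @param grid A [build_frequency_grid()] result; default: built from `ts`
#'   with the given `oversample`.
#' @param oversample Passed to [build_frequency_grid()] when `grid` is NULL.
#' @return An object of class `periodogram`: `frequency`, `period`,
#'   `power`, `grid`, `normalization = "least-squares"`, `animal_id`.
#' @export
compute_periodogram <- function(ts, grid = NULL, oversample = 5) {
  .check_spectral_series(ts)
  if (is.null(grid)) grid <- build_frequency_grid(ts, oversample = oversample)
  if (!inherits(grid, "frequency_grid")) stop("'grid' must be a frequency_grid")
  basis <- .ls_basis(ts$times, grid$frequencies)
  power <- drop(.ls_power_matrix(basis, matrix(ts$values, ncol = 1L)))
  structure(
    list(frequency = grid$frequencies, period = 1 / grid$frequencies,
         power = power, grid = grid, normalization = "least-squares",
         animal_id = ts$animal_id),
    class = "periodogram"
  )
}

#' @export
print.periodogram <- function(x, ...) {
  pk <- find_dominant_peak(x)
  cat(sprintf(
    "<periodogram> %s: %d frequencies, max power %.4f at period %.4g d\n",
    x$animal_id, length(x$frequency), pk$power, pk$period
  ))
  invisible(x)
}

#' @export
as.data.frame.periodogram <- function(x, ...) {
  data.frame(frequency = x$frequency, period = x$period, power = x$power)
}

#' @export
plot.periodogram <- function(x, ...) {
  graphics::plot(x$frequency, x$power, type = "l",
                 xlab = "frequency (cycles/day)",
                 ylab = "least-squares power",
                 main = sprintf("Periodogram (%s)", x$animal_id), ...)
  pk <- find_dominant_peak(x)
  graphics::abline(v = pk$frequency, lty = 2, col = "grey40")
  invisible(x)
}

#' Dominant periodogram peak
#'
#' Global argmax of power; exact ties are broken toward the lowest
#' frequency (the longest biological period), and an all-flat periodogram
#' is returned with a degenerate flag.
#'
#' @param pg A [compute_periodogram()] result.
#' @return An object of class `periodogram_peak`: `frequency`, `period`,
#'   `power`, `grid_index`, `tie`, `degenerate`.
#' @export
find_dominant_peak <- function(pg) {
  if (!inherits(pg, "periodogram")) stop("expected a 'periodogram' object")
  if (length(pg$power) < 1L) stop("empty periodogram")
  pmax_ <- max(pg$power)
  hits <- which(pg$power == pmax_)
  idx <- hits[1L]                      # frequencies increase: first = lowest f
  degenerate <- length(hits) == length(pg$power) && length(pg$power) > 1L
  structure(
    list(frequency = pg$frequency[idx], period = pg$period[idx],
         power = pmax_, grid_index = idx,
         tie = length(hits) > 1L, degenerate = degenerate),
    class = "periodogram_peak"
  )
}

#' @export
print.periodogram_peak <- function(x, ...) {
  cat(sprintf(
    "<periodogram_peak> period %.4g d (f = %.6g cycles/day), power %.4f%s%s\n",
    x$period, x$frequency, x$power,
    if (x$tie) " [tie: lowest frequency kept]" else "",
    if (x$degenerate) " [degenerate: flat periodogram]" else ""
  ))
  invisible(x)
}

#' False alarm probability of a periodogram peak
#'
#' Probability of seeing at least the observed maximum power in a
#' signal-free series. The default is a seeded permutation bootstrap:
#' values are permuted over the fixed sampling times `n_resamples` times,
#' the maximum power over the grid is recomputed for each permutation, and
#' \deqn{FAP = (1 + \#\{max\ null\ power \ge observed\}) / (n_{resamples} + 1).}
#' The add-one rule keeps the estimate away from exactly 0 and gives it
#' resolution `1/(n_resamples + 1)`. Permutations are exchangeable under
#' the white-noise null, so the bootstrap FAP is uniformly distributed for
#' signal-free input. A Baluev-style analytic upper bound is available as
#' `method = "baluev"`; it is an aliasing-free approximation, labelled as
#' such in the result.
#'
#' @param ts The [cycle_series()] the peak was computed from.
#' @param peak A [find_dominant_peak()] result; default: recomputed.
#' @param grid The [build_frequency_grid()] used; default: rebuilt from `ts`.
#' @param method `"bootstrap"` (default) or `"baluev"`.
#' @param n_resamples Number of permutations, >= 99 (bootstrap only).
#' @param seed Seed for the permutation stream.
#' @return An object of class `fap_result`: `fap`, `method`, `n_resamples`
#'   (NA for analytic), `seed`, `observed_power`.
#' @export
false_alarm_probability <- function(ts, peak = NULL, grid = NULL,
                                    method = c("bootstrap", "baluev"),
                                    n_resamples = 999L, seed = 1L) {
  method <- match.arg(method)
  .check_spectral_series(ts)
  if (is.null(grid)) grid <- build_frequency_grid(ts)
  if (is.null(peak)) peak <- find_dominant_peak(compute_periodogram(ts, grid))
  if (method == "bootstrap") {
    n_resamples <- as.integer(n_resamples)
    if (n_resamples < 99L) stop("'n_resamples' must be >= 99")
    old <- .save_rng_state()
    on.exit(.restore_rng_state(old), add = TRUE)
    set.seed(as.integer(seed))
    y <- ts$values
    n <- length(y)
    Y <- matrix(0, n, n_resamples)
    for (b in seq_len(n_resamples)) Y[, b] <- y[sample.int(n)]
    basis <- .ls_basis(ts$times, grid$frequencies)
    null_max <- apply(.ls_power_matrix(basis, Y), 2L, max)
    k <- sum(null_max >= peak$power)
    fap <- (1 + k) / (n_resamples + 1)
    structure(
      list(fap = fap, method = "bootstrap", n_resamples = n_resamples,
           seed = as.integer(seed), observed_power = peak$power),
      class = "fap_result"
    )
  } else {
    structure(
      list(fap = .fap_baluev(ts, peak, grid), method = "baluev",
           n_resamples = NA_integer_, seed = NA_integer_,
           observed_power = peak$power),
      class = "fap_result"
    )
  }
}

# Baluev/Davies upper bound for the floating-mean least-squares power
# (standard normalization, z in [0,1]). Approximation: extreme-value tail
# without aliasing corrections.
.fap_baluev <- function(ts, peak, grid) {
  n <- length(ts$values)
  if (n <= 4L) return(1)
  z <- peak$power
  NH <- n - 1
  NK <- n - 3
  p_single <- (1 - z)^(NK / 2)
  gam <- sqrt(2 / NH) * exp(lgamma((NH + 1) / 2) - lgamma(NH / 2))
  teff <- sqrt(4 * pi * stats::var(ts$times) * (n - 1) / n)
  tau <- gam * grid$f_max * teff * sqrt(z) * (1 - z)^((NK - 1) / 2)
  fap <- 1 - (1 - p_single) * exp(-tau)
  min(max(fap, 0), 1)
}

#' @export
print.fap_result <- function(x, ...) {
  cat(sprintf(
    "<fap_result> FAP = %.4g (%s%s) for observed power %.4f\n",
    x$fap, x$method,
    if (x$method == "bootstrap") sprintf(", %d resamples, seed %d",
                                         x$n_resamples, x$seed)
    else ", analytic upper bound",
    x$observed_power
  ))
  invisible(x)
}
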