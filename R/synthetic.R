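#' Specification of a synthetic hormone cycle
#'
#' Describes the stated world from which synthetic hormone trajectories are
#' drawn: a sinusoid with its peak at `phase_offset` days,
#' \deqn{y(t) = baseline + amplitude \cdot \sin(2\pi (t - phase\_offset)/period + \pi/2),}
#' observed at `sampling_days` under multiplicative log-normal or additive
#' Gaussian noise.
#'
#' @param period Cycle period in days, > 0.
#' @param amplitude Oscillation amplitude in concentration units, >= 0.
#' @param baseline Mean concentration, > 0.
#' @param phase_offset Day at which the noiseless waveform peaks.
#' @param noise_sigma Noise scale: log-sd of the multiplicative factor
#'   (`noise_kind = "lognormal"`) or additive sd in concentration units
#'   (`"gaussian"`). `0` gives the exact closed-form sinusoid.
#' @param noise_kind `"lognormal"` (default; concentrations are positive and
#'   right-skewed) or `"gaussian"`.
#' @param sampling_days Non-negative sampling times (days); duplicates
#'   allowed (same-day technical replicates).
#' @param n_animals Number of animals in the cohort.
#' @param phase_jitter_sd Per-animal jitter (sd, days) on `phase_offset`
#'   drawn once per animal; default 0 (all animals share the phase).
#' @param seed Master seed; identical spec + seed reproduce output exactly.
#' @return A validated object of class `hormone_cycle_spec`.
#' @seealso [cycle_preset()] for the shipped mouse/macaque designs.
#' @export
hormone_cycle_spec <- function(period, amplitude, baseline, phase_offset = 0,
                               noise_sigma = 0,
                               noise_kind = c("lognormal", "gaussian"),
                               sampling_days, n_animals = 1L,
                               phase_jitter_sd = 0, seed = 1L) {
  noise_kind <- match.arg(noise_kind)
  if (!is.numeric(period) || length(period) != 1L || !is.finite(period) ||
      period <= 0) {
    stop("'period' must be a single positive number (days)")
  }
  if (!is.numeric(baseline) || length(baseline) != 1L || !is.finite(baseline) ||
      baseline <= 0) {
    stop("'baseline' must be a single positive concentration")
  }
  if (!is.numeric(amplitude) || amplitude < 0) stop("'amplitude' must be >= 0")
  if (!is.numeric(noise_sigma) || noise_sigma < 0) stop("'noise_sigma' must be >= 0")
  if (length(sampling_days) < 1L || any(!is.finite(sampling_days)) ||
      any(sampling_days < 0)) {
    stop("'sampling_days' must be non-empty, finite and non-negative")
  }
  if (is.unsorted(sampling_days)) sampling_days <- sort(sampling_days)
  n_animals <- as.integer(n_animals)
  if (is.na(n_animals) || n_animals < 1L) stop("'n_animals' must be >= 1")
  if (phase_jitter_sd < 0) stop("'phase_jitter_sd' must be >= 0")
  structure(
    list(
      period = period, amplitude = amplitude, baseline = baseline,
      phase_offset = phase_offset, noise_sigma = noise_sigma,
      noise_kind = noise_kind, sampling_days = as.numeric(sampling_days),
      n_animals = n_animals, phase_jitter_sd = phase_jitter_sd,
      seed = as.integer(seed)
    ),
    class = "hormone_cycle_spec"
  )
}

#' @export
print.hormone_cycle_spec <- function(x, ...) {
  cat(sprintf(
    paste0("<hormone_cycle_spec> period %.4g d, baseline %.4g, amplitude %.4g, ",
           "peak at day %.4g\n  %s noise sigma %.4g; %d animal(s), %d sampling days; seed %d\n"),
    x$period, x$baseline, x$amplitude, x$phase_offset, x$noise_kind,
    x$noise_sigma, x$n_animals, length(x$sampling_days), x$seed
  ))
  invisible(x)
}

# Noiseless waveform: peak (baseline + amplitude) at t = phase_offset.
.hormone_mean <- function(spec, t) {
  spec$baseline +
    spec$amplitude * sin(2 * pi * (t - spec$phase_offset) / spec$period + pi / 2)
}

# Cycle phase angle of the generating sinusoid, peak at pi/2 by convention.
.hormone_theta <- function(spec, t) {
  (2 * pi * (t - spec$phase_offset) / spec$period + pi / 2) %% (2 * pi)
}

# Deterministic per-animal stream seed (kept well below 2^31).
.animal_seed <- function(seed, animal_index) {
  (abs(as.integer(seed)) + 7919L * as.integer(animal_index)) %% 2147483647L
}

#' Generate one animal's synthetic hormone series
#'
#' @param spec A [hormone_cycle_spec()].
#' @param animal_index Which animal (1-based, <= `spec$n_animals`).
#' @return A [cycle_series()] sampled exactly at `spec$sampling_days`. With
#'   `noise_sigma = 0` the values equal the closed-form sinusoid to machine
#'   precision.
#' @examples
#' sp <- hormone_cycle_spec(period = 10, amplitude = 1, baseline = 5,
#'                          phase_offset = 2.5, sampling_days = c(2.5, 7.5))
#' generate_hormone_series(sp, 1)$values # 6 (peak), 4 (trough)
#' @export
generate_hormone_series <- function(spec, animal_index = 1L) {
  if (!inherits(spec, "hormone_cycle_spec")) {
    stop("'spec' must be a hormone_cycle_spec")
  }
  animal_index <- as.integer(animal_index)
  if (animal_index < 1L || animal_index > spec$n_animals) {
    stop("'animal_index' must be in 1..n_animals")
  }
  t <- spec$sampling_days
  offset <- spec$phase_offset
  needs_rng <- spec$noise_sigma > 0 || spec$phase_jitter_sd > 0
  if (needs_rng) {
    old <- .save_rng_state()
    on.exit(.restore_rng_state(old), add = TRUE)
    set.seed(.animal_seed(spec$seed, animal_index))
    if (spec$phase_jitter_sd > 0) {
      offset <- offset + stats::rnorm(1L, 0, spec$phase_jitter_sd)
    }
  }
  mu <- spec$baseline +
    spec$amplitude * sin(2 * pi * (t - offset) / spec$period + pi / 2)
  y <- if (spec$noise_sigma == 0) {
    mu
  } else if (spec$noise_kind == "lognormal") {
    mu * exp(stats::rnorm(length(t), 0, spec$noise_sigma))
  } else {
    mu + stats::rnorm(length(t), 0, spec$noise_sigma)
  }
  cycle_series(t, y, animal_id = sprintf("animal_%d", animal_index))
}

.save_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

#' Generate a cohort of synthetic hormone series
#'
#' One series per animal with independent noise streams derived
#' deterministically from the master seed, so the cohort is reproducible and
#' `generate_cohort(spec)[[i]]` equals `generate_hormone_series(spec, i)`.
#'
#' @param spec A [hormone_cycle_spec()].
#' @return A list of [cycle_series()] (class `cycle_cohort`) with the
#'   generating spec attached as attribute `"spec"`.
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "hormone_cycle_spec")) {
    stop("'spec' must be a hormone_cycle_spec")
  }
  cohort <- lapply(seq_len(spec$n_animals),
                   function(i) generate_hormone_series(spec, i))
  attr(cohort, "spec") <- spec
  class(cohort) <- c("cycle_cohort", "list")
  cohort
}

#' @export
print.cycle_cohort <- function(x, ...) {
  cat(sprintf("<cycle_cohort> %d series\n", length(x)))
  for (ts in x) print(ts)
  invisible(x)
}

#' Shipped sampling-design presets
#'
#' Two named designs emulating the study systems:
#' \describe{
#'   \item{`"mouse-pseudopregnancy"`}{3 mice re-mated over 26 weeks: daily
#'     progesterone sampling on days 0..181, true period 11 d, baseline 10,
#'     amplitude 8 ng/mL, peak at day 6 of the cycle, log-normal sigma 0.2.}
#'   \item{`"macaque"`}{6 pig-tailed macaques sampled twice weekly (every
#'     3.5 d) over 9 weeks (days 0..63), 32-day menstrual cycle, baseline 4,
#'     amplitude 3 ng/mL progesterone, mid-luteal peak at day 20.5,
#'     log-normal sigma 0.2.}
#' }
#'
#' @param name Preset name.
#' @param seed Master seed.
#' @param ... Overrides passed on to [hormone_cycle_spec()].
#' @return A [hormone_cycle_spec()].
#' @export
cycle_preset <- function(name = c("mouse-pseudopregnancy", "macaque"),
                         seed = 1L, ...) {
  name <- match.arg(name)
  args <- switch(name,
    "mouse-pseudopregnancy" = list(
      period = 11, amplitude = 8, baseline = 10, phase_offset = 6,
      noise_sigma = 0.2, noise_kind = "lognormal",
      sampling_days = 0:181, n_animals = 3L
    ),
    "macaque" = list(
      period = 32, amplitude = 3, baseline = 4, phase_offset = 20.5,
      noise_sigma = 0.2, noise_kind = "lognormal",
      sampling_days = seq(0, 63, by = 3.5), n_animals = 6L
    )
  )
  args$seed <- seed
  over <- list(...)
  args[names(over)] <- over
  do.call(hormone_cycle_spec, args)
}

#' Specification of phase-locked synthetic immune counts
#'
#' Counts are negative-binomially distributed with mean
#' `baseline_count * fold(theta)`, where the fold profile interpolates
#' cosine-smoothly from 1 at the antiphase of `peak_angle` to
#' `fold_amplitude` at `peak_angle`:
#' \deqn{fold(\theta) = 1 + (fold\_amplitude - 1)(1 + \cos(\theta - peak\_angle))/2.}
#' The cycle phase angle `theta(t)` comes from the linked hormone spec
#' (hormone peak at `pi/2`).
#'
#' @param population Cell-population label (e.g. `"NK"`).
#' @param baseline_count Expected count at antiphase, >= 0.
#' @param fold_amplitude Peak-to-baseline fold, >= 0 (1 = flat profile).
#' @param peak_angle Cycle phase of maximal count, radians in `[0, 2pi)`.
#' @param dispersion Negative-binomial size parameter, > 0; large values
#'   approach Poisson.
#' @param hormone_spec The linked [hormone_cycle_spec()] supplying period
#'   and phase.
#' @param seed Seed for count draws.
#' @return An object of class `immune_count_spec`.
#' @export
immune_count_spec <- function(population, baseline_count, fold_amplitude,
                              peak_angle = pi / 2, dispersion = 10,
                              hormone_spec, seed = 1L) {
  if (!inherits(hormone_spec, "hormone_cycle_spec")) {
    stop("'hormone_spec' must be a hormone_cycle_spec")
  }
  if (baseline_count < 0) stop("'baseline_count' must be >= 0")
  if (fold_amplitude < 0) stop("'fold_amplitude' must be >= 0")
  if (!is.finite(dispersion) || dispersion <= 0) {
    stop("'dispersion' must be > 0")
  }
  if (peak_angle < 0 || peak_angle >= 2 * pi) {
    peak_angle <- peak_angle %% (2 * pi)
  }
  structure(
    list(
      population = as.character(population)[1L],
      baseline_count = baseline_count, fold_amplitude = fold_amplitude,
      peak_angle = peak_angle, dispersion = dispersion,
      hormone_spec = hormone_spec, seed = as.integer(seed)
    ),
    class = "immune_count_spec"
  )
}

#' Generate phase-locked immune cell counts
#'
#' Draws one count per animal and sampling day from the negative-binomial
#' model of [immune_count_spec()]. The true per-day fold is recorded
#' alongside so recovery of fold-change statistics can be tested against
#' ground truth.
#'
#' @param ispec An [immune_count_spec()].
#' @param sampling_days Days at which counts are measured; default: the
#'   linked hormone spec's sampling days.
#' @param n_animals Number of animals; default: from the linked hormone spec.
#' @return A data.frame with columns `animal_id, day, phase, phase_angle,
#'   population, value, true_fold`; `phase` is a `"day_<d>"` label usable as
#'   a stratification phase, `value` is a non-negative integer count.
#' @export
generate_immune_counts <- function(ispec, sampling_days = NULL,
                                   n_animals = NULL) {
  if (!inherits(ispec, "immune_count_spec")) {
    stop("'ispec' must be an immune_count_spec")
  }
  hspec <- ispec$hormone_spec
  if (is.null(sampling_days)) sampling_days <- hspec$sampling_days
  if (is.null(n_animals)) n_animals <- hspec$n_animals
  theta <- .hormone_theta(hspec, sampling_days)
  fold <- 1 + (ispec$fold_amplitude - 1) * (1 + cos(theta - ispec$peak_angle)) / 2
  mu <- ispec$baseline_count * fold
  old <- .save_rng_state()
  on.exit(.restore_rng_state(old), add = TRUE)
  set.seed(ispec$seed)
  out <- lapply(seq_len(n_animals), function(i) {
    counts <- if (all(mu == 0)) {
      integer(length(mu))
    } else {
      stats::rnbinom(length(mu), size = ispec$dispersion, mu = mu)
    }
    data.frame(
      animal_id = sprintf("animal_%d", i),
      day = sampling_days,
      phase = sprintf("day_%g", sampling_days),
      phase_angle = theta,
      population = ispec$population,
      value = as.integer(counts),
      true_fold = fold,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

#' Generate a planted differential-expression table
#'
#' Fixture generator for [filter_significant_genes()]: exactly `n_true`
#' genes satisfy the strict significance thresholds (FDR < 0.05 and
#' |log2FC| > 1); every other gene fails at least one of them.
#'
#' @param n_genes Total number of genes.
#' @param n_true Number of planted significant genes, `0 <= n_true <= n_genes`.
#' @param seed Seed.
#' @return A data.frame with columns `gene, log2FC, FDR` and a logical
#'   `planted` column marking the true positives.
#' @export
generate_deg_table <- function(n_genes, n_true, seed = 1L) {
  n_genes <- as.integer(n_genes)
  n_true <- as.integer(n_true)
  if (n_true < 0L || n_true > n_genes) stop("need 0 <= n_true <= n_genes")
  old <- .save_rng_state()
  on.exit(.restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  planted <- rep(FALSE, n_genes)
  if (n_true > 0L) planted[sample.int(n_genes, n_true)] <- TRUE
  fdr <- numeric(n_genes)
  lfc <- numeric(n_genes)
  # true positives: strictly inside both thresholds
  k <- sum(planted)
  if (k > 0L) {
    fdr[planted] <- stats::runif(k, 0, 0.049)
    lfc[planted] <- sample(c(-1, 1), k, replace = TRUE) *
      stats::runif(k, 1.1, 5)
  }
  # negatives fail FDR, fold change, or both
  k <- sum(!planted)
  if (k > 0L) {
    mode <- sample.int(3L, k, replace = TRUE)
    fdr[!planted] <- ifelse(mode != 2L, stats::runif(k, 0.05, 1),
                            stats::runif(k, 0, 0.049))
    lfc[!planted] <- ifelse(mode != 1L, stats::runif(k, -1, 1),
                            sample(c(-1, 1), k, replace = TRUE) *
                              stats::runif(k, 1.1, 5))
  }
  data.frame(
    gene = sprintf("gene_%04d", seq_len(n_genes)),
    log2FC = lfc,
    FDR = fdr,
    planted = planted,
    stringsAsFactors = FALSE
  )
}
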