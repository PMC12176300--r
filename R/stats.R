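#' Per-animal fold change against a reference phase
#'
#' Converts longitudinal measurements into within-animal fold changes to
#' control for animal-to-animal variation: for each `(animal_id,
#' population)` group, every value is divided by the animal's own value at
#' the reference phase. When a group carries several reference-phase rows
#' (technical duplicates) their mean defines the baseline and a single
#' reference row with fold exactly 1 is emitted; groups whose reference
#' value is missing or non-positive are excluded with a warning that counts
#' the exclusions.
#'
#' @param data A data.frame with columns `animal_id`, `phase`,
#'   `population`, `value` (counts or concentrations, >= 0). Extra columns
#'   are ignored.
#' @param reference The reference phase label, or `"first"` (default) to
#'   use each animal's first sampled phase (ties to the `phase` order of
#'   appearance within the animal).
#' @return A data.frame of class `fold_change_table` with columns
#'   `animal_id`, `phase`, `population`, `fold` and attribute
#'   `reference_phase`.
#' @export
fold_change_vs_reference <- function(data, reference = "first") {
  need <- c("animal_id", "phase", "population", "value")
  if (!all(need %in% names(data))) {
    stop("'data' must have columns: ", paste(need, collapse = ", "))
  }
  if (any(!is.finite(data$value)) || any(data$value < 0)) {
    stop("'value' must be finite and non-negative")
  }
  key <- interaction(data$animal_id, data$population, drop = TRUE)
  pieces <- split(seq_len(nrow(data)), key)
  excluded <- 0L
  out <- lapply(pieces, function(idx) {
    d <- data[idx, , drop = FALSE]
    ref_phase <- if (identical(reference, "first")) d$phase[1L] else reference
    ref_rows <- d$phase == ref_phase
    if (!any(ref_rows)) {
      excluded <<- excluded + 1L
      return(NULL)
    }
    baseline <- mean(d$value[ref_rows])
    if (!is.finite(baseline) || baseline <= 0) {
      excluded <<- excluded + 1L
      return(NULL)
    }
    other <- d[!ref_rows, , drop = FALSE]
    rbind(
      data.frame(animal_id = d$animal_id[1L], phase = ref_phase,
                 population = d$population[1L], fold = 1,
                 stringsAsFactors = FALSE),
      data.frame(animal_id = other$animal_id, phase = other$phase,
                 population = other$population,
                 fold = other$value / baseline,
                 stringsAsFactors = FALSE)
    )
  })
  if (excluded > 0L) {
    warning(sprintf(
      "%d (animal, population) group(s) excluded: reference value missing or non-positive",
      excluded
    ))
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(animal_id = character(), phase = character(),
                      population = character(), fold = numeric(),
                      stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  attr(res, "reference_phase") <- if (identical(reference, "first"))
    "first" else reference
  class(res) <- c("fold_change_table", "data.frame")
  res
}

# Exact null distribution of the signed-rank statistic V = sum of ranks of
# positive differences, conditional on the observed |d| ranks (average
# ranks for ties). Ranks are doubled so tied half-ranks become integers,
# then the distribution is built by generating-function convolution over
# the 2^n sign assignments without enumerating them.
.signed_rank_exact_p <- function(v, ranks) {
  r2 <- as.integer(round(2 * ranks))
  smax <- sum(r2)
  dist <- numeric(smax + 1L)
  dist[1L] <- 1
  for (r in r2) {
    shifted <- c(numeric(r), dist[seq_len(smax + 1L - r)])
    dist <- dist + shifted
  }
  dist <- dist / sum(dist)
  v2 <- round(2 * v)
  # two-sided by the doubling rule (the null distribution is symmetric)
  p_le <- sum(dist[seq_len(min(v2, smax) + 1L)])
  p_ge <- sum(dist[(v2 + 1L):(smax + 1L)])
  min(1, 2 * min(p_le, p_ge))
}

# Normal-approximation path. Mean and variance are conditional on the
# observed (possibly tied, average) ranks; the Gaussian tail carries a 0.5
# continuity correction plus the Edgeworth kurtosis term, which brings it
# within ~1e-3 of the exact enumeration already at n = 12.
.signed_rank_normal_p <- function(v, ranks) {
  ev <- sum(ranks) / 2
  varv <- sum(ranks^2) / 4
  g2 <- -2 * sum(ranks^4) / (sum(ranks^2))^2   # excess kurtosis of V
  tail_ge <- function(vv) {                    # P(V >= vv)
    z <- (vv - 0.5 - ev) / sqrt(varv)
    p <- stats::pnorm(z, lower.tail = FALSE) +
      stats::dnorm(z) * g2 / 24 * (z^3 - 3 * z)
    min(max(p, 0), 1)
  }
  p_ge <- tail_ge(v)
  p_le <- 1 - tail_ge(v + 1)
  min(1, 2 * min(p_le, p_ge))
}

#' One-sample Wilcoxon signed-rank test of fold changes against unity
#'
#' Tests whether per-animal fold changes deviate from 1 (no change).
#' Differences `fold - 1` that are exactly zero are dropped before ranking
#' (Wilcoxon's convention; `zero_method = "pratt"` keeps them in the
#' ranking instead). The two-sided p-value comes from the exact null
#' distribution — built by enumeration over all sign assignments of the
#' observed ranks — when the number of non-zero differences is at most 15,
#' and above that from the tie-corrected normal approximation (continuity
#' correction plus an Edgeworth kurtosis term).
#'
#' @param folds Numeric vector of fold changes, > 0.
#' @param mu Null value, default 1.
#' @param zero_method `"drop"` (default) or `"pratt"`.
#' @param exact_max Largest n for the exact path (default 15).
#' @return An object of class `fold_test`: `statistic` (the signed-rank
#'   sum V), `p_value`, `n` (non-zero differences used), `method`
#'   (`"exact"` or `"normal"`), `degenerate` (TRUE when every fold equals
#'   `mu`, in which case `p_value = 1`).
#' @examples
#' test_fold_vs_unity(c(2, 2, 2, 2, 2))$p_value # 2/2^5 = 0.0625
#' @export
test_fold_vs_unity <- function(folds, mu = 1,
                               zero_method = c("drop", "pratt"),
                               exact_max = 15L) {
  zero_method <- match.arg(zero_method)
  folds <- as.numeric(folds)
  if (length(folds) < 1L) stop("need at least one fold change")
  if (any(!is.finite(folds))) stop("fold changes must be finite")
  d <- folds - mu
  if (all(d == 0)) {
    return(structure(
      list(statistic = 0, p_value = 1, n = 0L, method = "degenerate",
           degenerate = TRUE),
      class = "fold_test"
    ))
  }
  if (zero_method == "drop") {
    d <- d[d != 0]
    ranks <- rank(abs(d))
  } else {
    ranks_all <- rank(abs(folds - mu))
    keep <- d != 0
    ranks <- ranks_all[keep]
    d <- d[keep]
  }
  n <- length(d)
  v <- sum(ranks[d > 0])
  if (n <= exact_max) {
    p <- .signed_rank_exact_p(v, ranks)
    method <- "exact"
  } else {
    p <- .signed_rank_normal_p(v, ranks)
    method <- "normal"
  }
  structure(
    list(statistic = v, p_value = p, n = n, method = method,
         degenerate = FALSE),
    class = "fold_test"
  )
}

#' @export
print.fold_test <- function(x, ...) {
  cat(sprintf(
    "<fold_test> signed-rank V = %.4g, n = %d, two-sided p = %.4g (%s)%s\n",
    x$statistic, x$n, x$p_value, x$method,
    if (x$degenerate) " [degenerate: all folds at the null value]" else ""
  ))
  invisible(x)
}

#' False-discovery-rate adjustment
#'
#' Benjamini-Hochberg step-up adjusted p-values (default), or the two-stage
#' Benjamini-Krieger-Yekutieli variant (`method = "BKY"`, the default of
#' some commercial packages). Order-preserving with the input; adjusted
#' values are monotone in the raw values, never below them and never above
#' 1.
#'
#' @param p_values Raw p-values in `(0, 1]`.
#' @param method `"BH"` (default) or `"BKY"`.
#' @return Adjusted p-values in input order (empty in, empty out).
#' @examples
#' adjust_fdr(c(0.01, 0.02, 0.03, 0.04)) # all 0.04
#' @export
adjust_fdr <- function(p_values, method = c("BH", "BKY")) {
  method <- match.arg(method)
  p <- as.numeric(p_values)
  if (length(p) == 0L) return(numeric(0))
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  if (method == "BH") return(stats::p.adjust(p, method = "BH"))
  # BKY two-stage: estimate m0 from a first BH pass at q/(1+q), then BH
  # with m0 in place of m.
  m <- length(p)
  alpha <- 0.05
  stage1 <- stats::p.adjust(p, method = "BH")
  r1 <- sum(stage1 <= alpha / (1 + alpha))
  m0 <- m - r1
  if (m0 == 0L) m0 <- 1L
  ord <- order(p)
  adj <- p[ord] * m0 / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(pmax(adj, p[ord]), 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

#' Fold-change significance table
#'
#' Runs [test_fold_vs_unity()] for every `(population, phase)` cell of a
#' fold-change table (the reference phase, identically 1, is skipped) and
#' adjusts the p-values for multiple comparisons.
#'
#' @param ft A [fold_change_vs_reference()] result.
#' @param adjust FDR method passed to [adjust_fdr()].
#' @param ... Passed to [test_fold_vs_unity()].
#' @return A data.frame with columns `population`, `phase`, `n`,
#'   `statistic`, `p_raw`, `p_adjusted`.
#' @export
fold_significance_table <- function(ft, adjust = "BH", ...) {
  ref <- attr(ft, "reference_phase")
  cells <- unique(ft[, c("population", "phase")])
  cells <- cells[cells$phase != ref | identical(ref, "first"), , drop = FALSE]
  if (identical(ref, "first")) {
    # per-animal references differ; skip cells where every fold is 1
    keep <- vapply(seq_len(nrow(cells)), function(i) {
      f <- ft$fold[ft$population == cells$population[i] &
                     ft$phase == cells$phase[i]]
      any(f != 1)
    }, logical(1L))
    cells <- cells[keep, , drop = FALSE]
  }
  if (nrow(cells) == 0L) {
    return(data.frame(population = character(), phase = character(),
                      n = integer(), statistic = numeric(),
                      p_raw = numeric(), p_adjusted = numeric()))
  }
  res <- lapply(seq_len(nrow(cells)), function(i) {
    f <- ft$fold[ft$population == cells$population[i] &
                   ft$phase == cells$phase[i]]
    tst <- test_fold_vs_unity(f, ...)
    data.frame(population = cells$population[i], phase = cells$phase[i],
               n = tst$n, statistic = tst$statistic, p_raw = tst$p_value,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$p_adjusted <- adjust_fdr(res$p_raw, method = adjust)
  rownames(res) <- NULL
  res
}

#' Order analytes by their mean fold increase
#'
#' Panel ordering for heat-map style displays: one summary fold per analyte
#' (arithmetic mean across animals and phases), sorted in decreasing order
#' with ties broken alphabetically.
#'
#' @param panel Either a [fold_change_vs_reference()] result (or any
#'   data.frame with `population` and `fold` columns) or a named numeric
#'   vector of summary folds.
#' @return Character vector of analyte names, greatest fold increase first.
#' @examples
#' order_by_fold_increase(c("IFNg" = 12, "IL-6" = 3, "IP-10" = 20))
#' @export
order_by_fold_increase <- function(panel) {
  if (is.data.frame(panel)) {
    if (!all(c("population", "fold") %in% names(panel))) {
      stop("data.frame 'panel' needs 'population' and 'fold' columns")
    }
    if (nrow(panel) == 0L) return(character(0))
    sm <- tapply(panel$fold, panel$population, mean)
    folds <- as.numeric(sm)
    names(folds) <- names(sm)
  } else {
    folds <- panel
    if (length(folds) == 0L) return(character(0))
    if (is.null(names(folds))) stop("'panel' must be named")
  }
  names(folds)[order(-folds, names(folds))]
}

#' Significance filter for differential-expression tables
#'
#' Keeps genes with `FDR < 0.05` and `|log2FC| > 1` — both thresholds
#' strict, so boundary values are dropped.
#'
#' @param table A data.frame with columns `gene`, `log2FC`, `FDR` (extra
#'   columns pass through).
#' @param fdr_threshold,lfc_threshold The strict thresholds.
#' @return The filtered data.frame.
#' @export
filter_significant_genes <- function(table, fdr_threshold = 0.05,
                                     lfc_threshold = 1) {
  need <- c("gene", "log2FC", "FDR")
  if (!all(need %in% names(table))) {
    stop("'table' must have columns: ", paste(need, collapse = ", "))
  }
  if (any(table$FDR < 0 | table$FDR > 1, na.rm = TRUE)) {
    stop("'FDR' must lie in [0, 1]")
  }
  keep <- table$FDR < fdr_threshold & abs(table$log2FC) > lfc_threshold
  keep[is.na(keep)] <- FALSE
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
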