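---
title: "Detecting and aligning hormone-cycle oscillations with cyclewave"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and aligning hormone-cycle oscillations with cyclewave}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyclewave)
```

## The problem

Reproductive hormone cycles — the ~32-day macaque menstrual cycle, the
~11-day hormone cycle of mice induced to undergo repeat pseudopregnancy —
drive periodic remodeling of the reproductive tract and, with it, periodic
changes in local immune populations. Characterizing that periodicity from
real sampling designs poses three coupled problems:

1. the series are **irregularly sampled** (bi-weekly macaque draws,
   occasional missed days, same-day technical duplicates), ruling out FFT
   methods;
2. cross-species comparison needs a **common clock**: calendar days mean
   different things in an 11-day and a 32-day cycle, so named stages must
   be expressed as phase angles of the fitted oscillation;
3. the downstream immunology is a **longitudinal fold-change** question —
   does a cell population deviate from its within-animal baseline at
   particular cycle phases?

`cyclewave` implements this workflow end to end, with a synthetic-data
module that provides ground truth for every stage.

## The spectral model

At a trial frequency $f$ the three-parameter sinusoid

$$\phi(t) = A\sin(2\pi f t) + B\cos(2\pi f t) + C$$

is fitted by ordinary least squares, and the power at $f$ is the fraction
of variance explained,

$$P(f) = 1 - \frac{SSR(f)}{SSR_0}, \qquad
  SSR_0 = \sum_i (y_i - \bar y)^2 .$$

This is the generalized ("floating-mean") form of the Lomb–Scargle
periodogram: because $C$ is fitted jointly rather than assuming a
pre-centred series, the estimator is correct for data with non-zero mean
and biased sampling, and $P$ is exactly invariant under affine maps
$y \mapsto a y + b$ ($a \neq 0$).

Among the common power normalizations we fix the least-squares one above
because it is bounded in $[0, 1]$, affine-invariant, and makes the
implementation exactly checkable against an independent regression oracle
(`lm()` on the sine/cosine design); the test suite enforces agreement to
$10^{-10}$. Internally each frequency's power is computed by projecting
onto an orthonormal basis of $\mathrm{span}\{1, \sin, \cos\}$ (a per-
frequency QR decomposition); when sampling aliases the sinusoid and the
design loses rank — e.g. integer daily sampling evaluated exactly at the
Nyquist frequency — the projection is onto the reduced span, and the
coefficient route (`ls_fit_at_frequency()`) returns the minimum-norm
solution with a `rank_deficient` flag.

### Frequency grid

The defaults follow standard practice for unevenly sampled series:
$f_{\min} = 1/\mathrm{span}$ (at most one cycle across the record;
`max_period_fraction` relaxes this), a pseudo-Nyquist
$f_{\max} = 1/(2\,\Delta t_{med})$ with $\Delta t_{med}$ the median spacing
of *distinct* sampling times (so duplicates do not inflate the limit), and
spacing $1/(\mathrm{oversample} \times \mathrm{span})$ with oversampling 5.
For the daily 182-day mouse design this yields 448 frequencies and a period
resolution of about 0.13 d near the 11-day peak. Exact ties at the maximum
are broken toward the lowest frequency — the longest biological period —
deterministically, and an all-flat periodogram is flagged degenerate rather
than guessed at.

### False alarm probability

The probability of a peak at least as strong arising from a signal-free
series is estimated by a permutation bootstrap: values are shuffled over
the fixed time stamps (exchangeability is exact under the white-noise
null), the maximum power over the grid is recomputed for each of
$R \geq 99$ permutations, and

$$\mathrm{FAP} = \frac{1 + \#\{\max P^{*} \geq P_{obs}\}}{R + 1}.$$

The add-one rule gives resolution $1/(R+1)$ and keeps the estimate away
from exactly zero — a perfect noiseless sinusoid reports $1/(R+1)$, not 0.
For white-noise input the estimator is uniform on $(0, 1]$, which the
acceptance suite verifies on 500 null series (Kolmogorov–Smirnov). A
Baluev-style analytic upper bound (`method = "baluev"`) is provided for
speed; it ignores aliasing structure and is labelled an approximation in
its result.

## Waveform reconstruction and the phase convention

Refitting at the dominant frequency gives the reconstructed waveform

$$\hat y(t) = A\sin(2\pi f t) + B\cos(2\pi f t) + C
            = R\sin(2\pi f t + \varphi) + C,$$

with $R = \sqrt{A^2+B^2}$, $\varphi = \mathrm{atan2}(B, A)$. Defining the
phase angle as $\theta(t) = (2\pi f t + \varphi) \bmod 2\pi$ puts the
waveform maximum exactly at $\theta = \pi/2$ and the minimum at $3\pi/2$ —
the peak/trough radian convention used when cycle stages are drawn on a
circular axis. This is the only convention under which those radian labels
are identities rather than approximations, and it is tested as such on
randomized fits.

Day $\leftrightarrow$ angle mapping assumes a **uniform angular rate**
$2\pi/T$. Real cycle-stage tables are not always consistent with that
assumption: the published macaque stage boundaries imply ~6.7°/day across
the luteal window but ~11.3°/day across the late-luteal window, so no
uniform mapping can reproduce both simultaneously. We implement the
uniform convention — the only rule that is well-defined from a fitted
sinusoid alone — and surface the tension rather than fit a per-stage
warping for which no placement rule is available. Cross-species alignment
(`align_species()`) is then the composition day → angle (source fit) →
day (target fit); it preserves window order and arc length ratios and is
exactly invertible, which the suite checks to $10^{-9}$ days. Windows that
wrap past day 0 are carried wrapped and split only at serialization
(`split_day_window()`). Day-0 anchoring (vaginal-plug day for mouse
pseudopregnancy, menses onset for the macaque) only shifts $\varphi$ and
is configurable through the generator's `phase_offset`.

## Fold-change statistics

`fold_change_vs_reference()` divides each measurement by the same animal's
value at a reference phase (configurable; default the animal's first
sampled phase, since longitudinal designs normalize "over the course of
the cycle" without naming a stage). Groups with a missing or non-positive
reference are excluded with a counted warning. When duplicates exist at
the reference phase their mean defines the baseline and a single fold-1
reference row is emitted, keeping the fold-at-reference $\equiv 1$
invariant.

Deviation from unity is tested with the one-sample Wilcoxon signed-rank
test. (Published figure legends sometimes call this a "rank sum" test, but
a rank-sum test needs two samples; against a fixed value of 1 the
signed-rank test is the only coherent reading, and that is what is
implemented.) Zero differences are dropped before ranking (Wilcoxon's
convention; Pratt's is available behind `zero_method = "pratt"`). For
$n \leq 15$ the two-sided p-value comes from the exact null distribution,
built by generating-function convolution over all $2^n$ sign assignments
of the observed (possibly tied, average) ranks, with the doubling rule for
two-sidedness. Above 15 a normal approximation is used with the
tie-corrected conditional variance $\sum r_i^2/4$, a 0.5 continuity
correction, and an Edgeworth kurtosis term; the last brings agreement with
the exact path to about $10^{-3}$ at the crossover ($n = 12$–$15$), an
order of magnitude inside the suite's 0.01 requirement.

Multiple comparisons use Benjamini–Hochberg by default; the two-stage
Benjamini–Krieger–Yekutieli variant sits behind `method = "BKY"` because
some commercial packages default to it, but BH is kept as the transparent
default. Panel ordering (`order_by_fold_increase()`) summarizes each
analyte by the arithmetic mean fold across animals (matching mean-based
displays) with alphabetical tie-breaks. The differential-expression filter
retains rows with FDR $< 0.05$ **and** $|\log_2 FC| > 1$, both strict.

## The synthetic world

The generator encodes the two study designs as named presets:

| preset | period | baseline | amplitude | peak day | noise | sampling | animals |
|---|---|---|---|---|---|---|---|
| `mouse-pseudopregnancy` | 11 d | 10 | 8 | 6 | log-normal σ 0.2 | daily, days 0–181 | 3 |
| `macaque` | 32 d | 4 | 3 | 20.5 | log-normal σ 0.2 | every 3.5 d, days 0–63 | 6 |

Choices where the source designs are silent, made once: hormone noise is
multiplicative log-normal (concentrations are positive and right-skewed;
additive Gaussian is available), with σ = 0.2 — a ±20% assay-plus-biology
scale typical of immunoassay panels; the mouse baseline/amplitude (10 ± 8)
keeps trough concentrations positive while spanning the sharp
pseudopregnancy peak; the macaque peak sits mid-luteal (day 20.5 of 32).
Immune counts are negative-binomial with a cosine-interpolated mean —
fold 1 at the antiphase rising to `fold_amplitude` at `peak_angle` — since
no generative count model is published; the truth is recorded per row
(`true_fold`) for recovery tests. Per-animal noise streams derive
deterministically from one master seed, so cohorts are reproducible
element-for-element.

What the generator does **not** emulate: assay floors/ceilings and
left-censoring, per-animal period heterogeneity (only phase jitter is
available), cycle-to-cycle period drift, and missing-visit structure. A
green simulation-recovery test therefore establishes correctness of the
estimators under the stated model, not robustness to those artifacts.

## Numerical and degenerate-input policy

- Constant series ($SSR_0 = 0$) are rejected by every spectral operation,
  as is normalization of a zero-mean series (tolerance: machine epsilon
  scaled by the largest absolute value).
- Power is clamped into $[0,1]$ against roundoff at the $10^{-15}$ level.
- Spectral operations require $\geq 3$ observations at $\geq 3$ distinct
  times (three free coefficients); the grid needs $\geq 3$ distinct times.
- Phase operations require strictly positive fitted amplitude; $R = 0$
  has no defined phase and errors.
- The permutation FAP requires $R \geq 99$ resamples and is reported with
  its resolution; seeds are recorded in every result object.
- Pipeline stages fail atomically with a stage-labelled error; nothing is
  written on failure, and rerunning a config reproduces the bundle
  exactly (the provenance block carries a content hash of the config and
  deliberately no timestamps).

## A compact end-to-end run

```{r pipeline, eval = FALSE}
cfg <- pipeline_config(
  hormone = cycle_preset("mouse-pseudopregnancy", seed = 7),
  fap = "bootstrap", n_resamples = 999, seed = 7
)
res <- run_pipeline(cfg)
res$summary          # mean and range of per-animal dominant periods
res$mapped_windows   # luteal / late-luteal day windows per animal
```

The cohort summary reports the arithmetic mean of per-animal peak periods
together with the range — the scale on which multi-animal dominant
frequencies are conventionally quoted.

## Known limitations

- The uniform-rate day–angle convention cannot reproduce stage tables
  built with non-uniform per-stage rates (see above); mapped windows are
  exact under the stated convention only.
- The Baluev-style FAP is an upper bound without aliasing corrections;
  for strongly clumped sampling prefer the bootstrap.
- The exact signed-rank path is conditional on observed ranks; with heavy
  ties at very small $n$ the discrete p-value jumps are large, which is a
  property of the statistic, not the implementation.
- Period uncertainty is limited by the grid step $\approx T^2 / (\mathrm{
  oversample} \times \mathrm{span})$; quoting a recovered period finer
  than that resolution is not meaningful.
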