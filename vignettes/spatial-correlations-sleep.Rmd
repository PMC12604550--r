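---
title: "Spatial LFP correlations and slow-wave sleep: models and methods"
author: "slowwave"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial LFP correlations and slow-wave sleep: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slowwave)
```

This vignette is the package's own account of its science: the estimators
and models, the tunable parameters that matter, what the synthetic
generator does and does not emulate, the numerical choices, and the known
limitations. Nothing here states an empirical result that the test suite
or `scripts/acceptance.R` does not itself compute.

## 1. The estimand: correlation as a function of distance

The data are multichannel LFP recordings from a planar electrode grid
(`utahArrayLayout()`: 10 x 10 sites at 400 um pitch, four corner sites
unwired, 96 electrodes, 4560 electrode pairs). For each non-overlapping
epoch of duration `epochS` (default 10 s) the Pearson correlation matrix
of all retained channels is computed, Fisher z-transformed
(`z = atanh(r)`), and summarized as a *correlation by distance function*:

* pairwise distances come from the grid geometry (`electrodeDistances()`);
* distances are binned into half-open intervals `(lower, upper]` of
  600 um (`distanceBinEdges()`; 400 um is the supported alternative), and
  a bin is labelled by its **upper edge**;
* for each *source* electrode, the z values of its pairings are averaged
  within each bin (`binByDistance()`), so a given pair contributes once to
  each of its two sources;
* the per-source functions are pooled with weights proportional to the
  number of pairs each source contributes to the bin
  (`arrayAverage()`).

The Fisher transform is used because the sampling distribution of `r` is
skewed and variance-unstable near |r| = 1; averaging and regressing on the
z scale is the statistically defensible choice, and it frees the
zero-distance intercept of the decay model to be a fitted parameter rather
than pinned at 1.

Working per epoch on the session-level z-scored signal is equivalent to
per-epoch standardization for this purpose: the Pearson formula re-centers
and re-scales internally, so the choice of z-scoring scope does not change
`r`.

**Analytic confidence intervals.** `correlationSignificance()` uses the
large-sample Fisher interval `z ± 1.96/sqrt(n − 3)` with `n` the nominal
sample count of the epoch (`epochS * fs`). LFP signals are strongly
autocorrelated, so the effective sample size is smaller and these
intervals are anti-conservative; they are reported as the conventional
analytic device, not as exact coverage.

## 2. Spatial decay models

Per epoch, four models are fit to `(d, z)` with weights proportional to
per-bin pair counts (`fitDecayModels()`):

* **Exponential** `f(d) = A exp(−d/lambda)`, fit by weighted linear
  regression of `ln z` on `d`. `A` (Fisher-z units) is the initial value;
  `lambda` (um) the spatial decay constant.
* **Power law** `f(d) = A d^(−b)`, fit in `ln z` vs `ln d`. The decaying
  form `d^(−b)` is used; `A` is the value at 1 um.
* **Gaussian** `f(d) = A exp(−d²/(2σ²)) + c`, by weighted
  Levenberg–Marquardt (`minpack.lm::nlsLM`), multi-started over
  σ ∈ {1, 2, 4} mm with `A = max z − min z`, `c = min z`; the best
  candidate by weighted SSE is kept and non-convergence is flagged rather
  than fatal.
* **Linear**, by weighted least squares.

Numerical conventions:

* log-domain fits require positive bin means; non-positive bins are
  dropped with a warning, and fewer than two usable bins is a recorded
  per-epoch fit failure, not an error;
* a non-negative log-domain slope means a flat profile: `lambda` is capped
  at 10^6 um and a `flat` flag set, avoiding infinities downstream;
* weights enter the log-domain regression unchanged (proportional to
  counts); no error model is invented to propagate variances;
* the reported MSE is always computed in the original z domain against
  the model curve, so model families with different link scales are
  comparable (`compareModels()` adds Silverman-bandwidth kernel densities
  of the per-epoch MSE distributions);
* the optional low-count rule (`excludeLowCountBins()`) drops bins with
  fewer than 20% of the mean count of the other bins before fitting. It
  is off by default — count weighting already downweights sparse far
  bins — and the rule can never empty a profile, because the
  largest-count bin always survives a threshold fraction below 1.

**Parameter scatter.** The per-epoch `(A, lambda)` cloud is summarized by
a Type-2 (model II) regression acknowledging variance in both
coordinates. Among the Type-2 variants the standardized major axis is
used — `slope = sign(r)·sd(y)/sd(x)` — because it is invariant under
rescaling of either axis; the 95% CI comes from 1000 percentile bootstrap
case resamples (`type2Regression()`).

## 3. Sleep staging from band power

`stageSleep()` implements the conventional LFP-only staging:

1. the **virtual LFP** is the sample-wise mean of the z-scored retained
   channels (`makeVirtualLFP()`);
2. per epoch, band power is the mean of the one-sided PSD at frequencies
   inside SO/delta (0.1–4 Hz) and gamma (30–60 Hz), inclusive edges
   (`multitaperBandPower()`);
3. a 3-component full-covariance Gaussian mixture is fit to the
   column-standardized `log10` band powers (`clusterStates()`, backed by
   `mclust`);
4. clusters map to states by the mean standardized delta-minus-gamma
   score: maximum → SWS, minimum → REM/awake, middle → null
   (`labelClusters()`), with deterministic index tie-breaks.

The multitaper estimator uses the **sine-taper family** (orthonormal
closed-form tapers), default K = 5 tapers — the variance-reduction
equivalent of a time–bandwidth-3 design. Log powers are clustered because
band power is strongly right-skewed; standardization puts both bands on
the cluster-relevant scale. `mclust`'s EM is initialized by deterministic
model-based hierarchical clustering, so staging is reproducible without
random restarts.

A 0.1 Hz lower band edge is only resolvable when `epochS ≥ 10` s (the DFT
spacing is `1/epochS`); at shorter epochs the band effectively widens to
the first resolvable bin, and a band containing no resolvable frequency
at all is an error.

## 4. State analysis

`joinEpochs()` inner-joins fits and states on the epoch index and forms
two per-epoch ratios: the **parameter ratio** `lambda/A` (um per z-unit;
`b/A` for power-law fits) and the **band-power ratio**, by default
gamma/delta. This orientation is deliberate: both ratios are then *low*
in SWS (short decay constant, high initial value, delta-dominated power)
and *high* in REM/awake, which is the only direction in which their
correlation is positive; the delta/gamma orientation is exposed as an
option. `correlateRatios()` reports Pearson r with the Fisher analytic
CI and the Type-2 slope with bootstrap CI; per-state summaries add the
mean/SD of lambda, d-prime `|Δmean|/sqrt((var_a+var_b)/2)` (the pooled-SD
form, with n−1 variances), coefficients of variation with percentile
bootstrap CIs (iid epoch-level resampling; no block structure is
assumed), and shared-grid kernel densities.

## 5. The simple threshold classifier

As a deliberately minimal predictor of SWS, `trainThresholdLOO()`
thresholds a temporally smoothed fit parameter. Smoothing (centered
moving average, shrinking windows at the edges) precedes thresholding.
The grid is 50 pooled-parameter quantiles plus the midpoints of adjacent
quantiles — the midpoints guarantee that a wide separating gap between
classes is never skipped by the quantile spacing — crossed with smoothing
widths {1, 3, 5, 7, 9} epochs and both decision directions; the error
metric is the unweighted misclassification rate averaged per session, and
ties prefer less smoothing, then smaller thresholds, then the "below"
direction (the SWS-typical side for ratio parameters). Significance is
assessed against a label-shuffle null (`shuffleNull()`), which is exact
under epoch exchangeability.

## 6. The synthetic generator

`generateSession()` provides ground truth for every stage. Each channel
is a sum over two band components (SO/delta 0.1–4 Hz, gamma 30–60 Hz) of

```
x_i(t) = sg·g(t) + ss·s_i(t) + sn·n_i(t)
```

with `g` shared across channels, `s_i` a spatial field with channel
covariance `exp(−d_ij/ell)` (realized exactly by a Cholesky factor, with
diagonal jitter up to 1e−5 if numerically needed), and `n_i` independent.
The expected pairwise correlation is the closed form

```
rho*(d) = Σ_b (sg² + ss²·exp(−d/ell)) / Σ_b (sg² + ss² + sn²),
```

a distance-decaying profile over a nonzero plateau. Band-limiting applies
the zero-phase 4th-order Butterworth magnitude response **in the
frequency domain** at the epoch's DFT frequencies: a direct time-domain
band-pass of this order is numerically unstable at a 0.1 Hz edge, the
low-pass + high-pass cascade magnitude is applied exactly, there are no
edge transients, and unit-variance normalization of each component is
exact in expectation. The analysis path (`bandLimit()`,
`lowpassDownsample()`, `narrowbandDistanceCorrelations()`) keeps
time-domain forward–backward filtering, with its usual edge transients.

**Defaults are the study conditions.** fs = 250 Hz (the content is
band-limited below 60 Hz, so this halves nothing but cost), 10 s epochs,
and per-state amplitude sets calibrated once so that a default session
reproduces the regime the pipeline targets: pooled Pearson correlation
≈ 0.8 at 600 um falling to ≈ 0.5 at 4200 um; SWS delta-dominated with
fitted lambda ≈ 4.1 mm; REM/awake gamma-dominated, weaker and flatter,
lambda ≈ 6.5–7 mm; the null state an amplitude mixture midway between the
two (intermediate/transitional interpretation). Within-state
heterogeneity is modelled by a per-epoch lognormal jitter of the spatial
length constant (`ellJitterSd` 0.10/0.30/0.45 for SWS/null/REM): real
states are not homogeneous, and without this the gamma-band REM fits are
implausibly precise. The jitter also produces the within-state
anticorrelated `(A, lambda)` continuum and makes the SWS parameter-ratio
CV smaller than the REM/awake CV, as per-state dispersion statistics
require. States follow a Markov chain (default dwell ≈ 2 min for SWS and
REM/awake, brief null visits, stationary start).

**Dropouts.** Wireless dropouts are all-channel constant intervals marked
invalid in the mask. Onsets follow a renewal process whose gaps mix a
short "burst" exponential (probability `burstiness`, default 0.5) with a
longer exponential matched so the overall rate is `dropoutRateHz`
(default 0.02 Hz) — dropouts cluster in time, as telemetry dropouts do.
Durations are log-normal, median 0.3 s with multi-second tails. With
`burstiness = 0` the onset process is Poisson, which is the tested case
for count statistics. Epochs overlapping any invalid sample are excluded
from all statistics; the tests enforce this by poisoning invalid samples
with NaN and asserting that no downstream quantity becomes NaN.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: no spindles or up/down-state structure, no 1/f
spectral background beyond the two band components, no volume-conduction
model, stationary within-epoch statistics with independence across
epochs, and channel-exchangeable noise (no per-electrode impedance
heterogeneity). Conclusions about the *estimators* transfer; conclusions
about marmoset physiology do not.

## 7. Problem sizes and tolerances

The test suite runs on synthetic sessions of 12–360 epochs; the
acceptance checks use a 360-epoch (1-hour) default session for staging
and state-coupling properties, 110 epochs for closed-form correlation
recovery (agreement within 0.02 of `rho*` pooled at the actual pair
distances — comparing against the bin's upper-edge label instead would
conflate the model with binning discretization, a +0.02 artifact at
600 um bins), three 120-epoch sessions for the leave-one-out classifier,
and dense grid searches as independent oracles for the weighted fits.
These sizes were chosen as the smallest at which the targeted properties
are stable; all are package choices, not external constraints.

## 8. Known limitations

* The analytic correlation CIs ignore autocorrelation (Section 1).
* Log-domain weighted least squares is not maximum likelihood for the
  z-scale noise; it is the conventional linearization, kept deliberately.
* The Gaussian decay fit can sit in a local optimum despite the
  multi-start; convergence is flagged per epoch.
* Staging assumes exactly three clusters; recordings dominated by a
  single state will produce a degenerate mixture and should be staged
  jointly with more heterogeneous sessions.
* `lambda` estimates beyond the array extent (≈ 5 mm) are extrapolations;
  the flat-profile cap at 10^6 um marks the point where the data no
  longer constrain them.
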