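---
title: "Methods: relating plankton functional diversity to lake state across time lags"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: relating plankton functional diversity to lake state across time lags}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(planklag)
```

## The question and the pipeline

Ecosystem managers would like an indicator that moves *before* a lake
changes state.  Trait-based (functional) diversity of the plankton is a
candidate: if the mix of traits in the community reorganizes ahead of
abundance-based state metrics, functional diversity (FD) could serve as an
early warning.  `planklag` implements the full chain needed to ask whether
FD leads, lags, or is synchronous with lake state:

1. **Standardize** monthly plankton density panels (zero-fill unrecorded
   taxa, monthly means, drop taxa that are >99% zeros).
2. **State metrics** (five): community composition (PC1 scores), log total
   density, windowed Fisher information (FI), the log multivariate
   variability index (MVI), and the log zooplankton:phytoplankton ratio.
3. **Functional diversity** (three per guild): FRic, FDis, FEve from a
   fuzzy-coded, Gower-dissimilarity trait space, computed monthly on the
   taxa present.
4. **Lagged cross-correlation** of every FD series against every state
   series, judged against red-noise (AR(1)) surrogate nulls.
5. **Lagged convergent cross mapping (CCM)** in both directions, with a
   paired-lag rule that classifies each FD-state pair as synchronous,
   FD-leading, state-leading, bidirectional, or unrelated.

Everything runs on synthetic data from seeded generators, so the whole
pipeline is testable end to end without any external download.

## Transform order and sign conventions

All series are linearly detrended, then deseasonalized by subtracting the
centred mean of each calendar month computed on the detrend residuals, then
scaled to zero mean and unit variance (sample, `n - 1`, denominator).  The
seasonal means are centred to sum to zero so the seasonal estimate carries
no level shift.  This order — detrend, deseasonalize, scale — is fixed;
each step records a flag on the series and `deseasonalize()` refuses
un-detrended input.

The cross-correlation statistic at lag `k` is `cor(x[t+k], y[t])` with `x`
the FD series and `y` the state series, so **negative lags mean FD moves
earlier than state** and positive lags mean FD trails it.  The profile is
computed on the symmetric grid −60…+60 months: leading and lagging
relationships are only distinguishable if both signs are scanned, and the
grid bound is a configuration knob.

## The red-noise null

Serial dependence alone produces large spurious cross-correlations, so
observed statistics are compared with ensembles (default 10,000) of AR(1)
surrogates matched to the FD series.  Each surrogate follows

```
x[1]   = w[1]
x[t+1] = r x[t] + sqrt(1 - r^2) w[t+1]
```

with `r` the maximum-likelihood AR(1) coefficient of the observed series
and `w` Gaussian noise with the observed mean and variance.  The
`sqrt(1 - r^2)` innovation scale is the stationary choice: it is the only
scale under which the surrogate variance equals the driving-noise variance,
i.e. the only one consistent with a null that "has the observed mean and
variance".  A variant with a `sqrt(1 + r^2)` scale is provided
(`as_printed = TRUE`) for comparison; it inflates the stationary variance
by `(1 + r^2)/(1 - r^2)` and is not used by default.

Two further choices are worth stating explicitly:

* **Moment matching.** After the recurrence, each surrogate is affinely
  rescaled to the observed mean and standard deviation
  (`match_moments = TRUE`).  The sample variance of an AR(1) path of
  length 396 with `r = 0.7` fluctuates by roughly 12% around its target,
  so raw surrogates only match the observed variance in expectation.
  Every statistic the package tests — Pearson correlation and cross-map
  skill — is invariant to per-series affine maps, so matching changes no
  test outcome while making the null exact; the raw recurrence remains
  available and is itself property-tested.
* **Multiplicity at LagX.** The "strongest correlation across lags" is
  selected over 121 lags, so it is judged against the surrogate
  distribution of *maxima* of |r| across the same grid, not against the
  per-lag 2.5%/97.5% envelope.  The per-lag envelope is still used for the
  Lag0 test and is available for LagX via `multiplicity = "per_lag"`, but
  the maximum-statistic null is the default because it controls selection
  over lags; its threshold is never below any single-lag band.

## State-metric choices

* **Community (PC1).** PCA on centred and scaled taxon series (the
  correlation matrix), so abundant taxa do not dominate composition.  The
  score sign is fixed so the loading-weighted mean density correlates
  non-negatively with the scores; sign conventions cannot affect any
  downstream significance call because correlations enter through their
  magnitude against symmetric nulls.
* **Log transforms with an explicit offset rule.**  Total density, MVI and
  the trophic ratio are natural-log transformed.  Sparse panels can
  produce zero monthly sums; when (and only when) a quantity contains
  zeros, half its smallest positive observed value is added before
  logging.  On strictly positive data the log is exact.
* **MVI** is the square root of the dominant eigenvalue of the taxon
  covariance matrix on a rolling window (default 12 months — a full-series
  covariance would give a single number, not a monthly series).  The
  covariance may be singular; the dominant eigenvalue is still defined.
* **Fisher information** is computed on sliding windows (default 48
  months, step 1).  Months are grouped into discrete system states: two
  months share a state when every taxon differs by less than
  `bin_tolerance` × that taxon's scale.  With `p_s` the state occupancy
  ordered by first appearance and `q_s = sqrt(p_s)`, FI is
  `4 * sum((q_s - q_{s+1})^2)` with boundary terms `q_0 = q_{m+1} = 0`:
  a one-state (stable) window scores 8, and FI decays as `8/window` when
  every month is its own state.  The taxon scale is the standard deviation
  of the taxon's **full** series, computed once.  An order-free scale is
  essential: a scale derived from within-window first differences grows
  when months are shuffled, which can merge all states and paradoxically
  *raise* FI for disordered data.  With the global scale, ordered regimes
  score above shuffled versions of the same panel, which is the behaviour
  the stability literature requires of FI.  The default
  `bin_tolerance = 0.5` makes two regimes separated by more than about one
  within-regime standard deviation resolvable as distinct states; window,
  step and tolerance are all exposed knobs.

## Functional diversity choices

Trait tables are fuzzy-coded: a taxon's affinity to each category of a
trait block is the fraction of its member species in that category, so a
genus identified only to genus level carries the plasticity of its species
rather than a forced single label.  Numeric traits are species means.
Dissimilarity is Gower-style over blocks: numeric traits contribute
`|x_i - x_j| / range`, fuzzy blocks half the Manhattan distance between
affinity rows (which is in [0, 1] because rows sum to 1), combined as a
weighted mean over the blocks where both taxa have data (equal weights by
default; no weighting scheme is imposed on users).

The trait space is a principal-coordinates embedding of that dissimilarity
with a Cailliez correction for negative eigenvalues (deterministic, and
disable-able), truncated at `min(10, n_taxa - 1, positive eigenvalues)`
axes.  Ten axes is the ceiling because convex-hull estimation degenerates
in high dimensions.

* **FRic** is the convex-hull volume of the present taxa divided by the
  hull volume of *all* taxa in the same axes, so monthly values are
  comparable on [0, 1].  Because zooplankton panels can have as few as 4
  taxa, the hull dimension falls back to `min(m, S_present - 1)`;
  degenerate (affinely dependent) point sets yield missing values, never
  zero.  Hull volumes in one and two dimensions are computed natively
  (range length; shoelace area on the hull cycle); three or more
  dimensions delegate to Qhull through the system SciPy, with all months
  of a series batched into a single subprocess call.
* **FDis** is the abundance-weighted mean distance to the weighted
  centroid; **FEve** is the minimum-spanning-tree evenness index on
  [0, 1].  Both are invariant to uniform abundance scaling, so the choice
  of raw density versus relative abundance as weights is immaterial for
  them; raw density is used.  Presence is `density > 0` exactly — rare
  species are deliberately retained upstream, so no abundance cutoff is
  applied here.

## Empirical dynamic modelling

Simplex projection forecasts a delay-embedded series from its `E + 1`
nearest neighbours with weights `exp(-d/d_min)`; distance ties at zero
fall back to uniform weights over the tied set.  Neighbours within the
Theiler window `max(tau * E, |tp|)` of the target time are excluded to
prevent serial-correlation leakage.  The embedding dimension is chosen per
series by one-step forecast skill over `E = 1…10` (ties to the smallest
`E`), once, on the standardized series, and reused across prediction
offsets.

CCM cross-maps a target series from the predictor's manifold across
library sizes (a geometric grid from `E + 2` to the full library, 100
random subsamples per size, full library evaluated once).  The
**convergence** flag requires the full-library skill to exceed the 95th
percentile of the smallest-library skills by at least 0.05 — skill must
genuinely grow with the library, the namesake property of CCM.

Lagged CCM evaluates full-library skill over `tp = -60…+60` and reports
the optimal offset.  One numerical subtlety: a delay vector carries the
predictor's `E - 1` past values, so when the target is (close to) a lagged
copy of the predictor the skill profile is flat over a plateau of width
`E` ending at the true alignment lag.  A bare argmax is therefore biased
low by up to `E - 1` months; the implementation reports the right-most
offset within `E - 1` steps of the argmax whose skill lies within 0.03 of
the peak — the plateau's upper edge.  This restores ±1-month lag recovery
in simulation without affecting sharply peaked profiles, whose shoulders
fall off far faster than the tolerance.

Significance of the optimal offset uses the same red-noise machinery,
with the same selection correction as the LagX correlation test: the
observed statistic is a maximum over the whole offset grid, so each
surrogate (substituted for the predictor; substitution of both series is
available) contributes its own maximum-over-offsets skill to the null,
and the observed optimal skill must exceed the 95th percentile of those
maxima.  Judging the observed maximum against a single-offset null is
badly anti-conservative — in simulation roughly half of independent
red-noise pairs would be flagged causal.  The surrogate profiles reuse
one neighbour computation per surrogate (with the exclusion radius fixed
at the grid maximum), which makes the corrected null barely more
expensive than the single-offset one.

**Paired-lag classification.** For each FD-state pair, the forward
("FD xmap state") and reverse mappings are compared with precedence:
(1) if neither mapping is significant the pair is *none*; (2) if the two
optimal offsets have strictly opposite signs, the pairing line crosses
zero and the variable with the negative offset leads (*FD-leads* /
*state-leads*); (3) otherwise, offsets both within ±12 months are
*synchronous* (the ±1-year band conventionally read as synchrony), and
same-side offsets beyond the band are *bidirectional-equal*.

## The synthetic generators

The community generator emulates what the real monitoring panels look like
statistically, not mechanistically: per-taxon log density is a constant
level plus a 12-month sinusoid (random per-taxon amplitude and phase) plus
stationary AR(1) noise, exponentiated (hence never negative), with true
zeros injected by Bernoulli masking and an optional step change in mean
log density for a designated taxon subset (a regime shift).  Defaults are
fixed once: 18 phytoplankton and 6 zooplankton taxa, 396 months (33
years, the median length of the long-term lake programmes this emulates),
seasonal log-amplitude 0.8, AR coefficient 0.45, noise sd 0.6, 15% zero
inflation.  The guild sizes sit inside the ranges seen across real lake
panels while keeping monthly 10-dimensional hull computation affordable.
What the generator does **not** emulate: nutrient/temperature forcing,
taxon interactions, observation-method changes, and non-stationary
seasonality — so green tests demonstrate the statistical machinery, not
ecological realism.

The coupled logistic map pair
(`x(t+1) = x(t)(r_x - r_x x(t) - b_xy y(t))`, and symmetrically for `y`)
is the standard CCM ground-truth benchmark: with `b_xy = 0, b_yx = 0.32`,
`x` drives `y` unidirectionally and the `y`-manifold must cross-map `x`
far better than the reverse.  The lag-injection generator shifts a
red-noise base by a known number of months to test lag recovery.

All generators expand one global seed into per-stream child seeds
(`child_seed()`), so adding a call does not perturb other streams, and
fixed seeds give bit-identical output.

## Problem sizes and determinism

The test-suite and acceptance-script simulation sizes are the package's
operating points: type-I error uses 500 replicate pairs × 1,000
surrogates at T = 396; surrogate fidelity uses 1,000 surrogates at
r = 0.7; lag recovery uses lags {−24, −12, −3, 0, 3, 12, 24} at n = 480
and noise sd 0.25; direction recovery uses 50 seeds of the n = 1000
coupled logistic map.  The full pipeline defaults to the analysis-scale
knobs (±60-month lags, 10,000 surrogates); a documented smoke profile
(200 surrogates, ±24 months) exists for continuous testing, and every
result table is byte-identical under a fixed seed.

## Known limitations

* FI windowing details (window, step, tolerance) are declared package
  choices; other implementations of the windowed-FI idea bin states
  differently, and absolute FI values are not comparable across
  implementations — only the limits (8 and →0) and orderings are.
* FRic depends on the PCoA correction and the all-taxa normalization;
  values are comparable within a run, not across different trait tables.
* CCM assumes deterministic coupling observed through delay maps; on
  strongly stochastic series "significance" means only
  better-than-red-noise, not mechanism.
* The CSV reader expects tidy long input with one guild per taxon; taxa
  with unidentified or placeholder names are removed only via a
  user-supplied exclusion list.
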