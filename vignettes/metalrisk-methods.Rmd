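---
title: "Heavy-metal risk indexes, risk levels and early-warning forecasts: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heavy-metal risk indexes, risk levels and early-warning forecasts: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models implemented in `metalrisk`, the
assumptions behind them, the tunable parameters and their defaults, the
synthetic-data generator used in place of access-restricted national
surveillance data, and the numerical and design choices a maintainer
should know about. It states no empirical result beyond what the package's
tests and `scripts/acceptance.R` themselves compute.

## 1. From detection records to daily indexes

The unit of raw data is a detection record: one laboratory measurement of
one metal (chromium, cadmium or arsenic) in a grain processing product on
one day, possibly censored at the assay's limit of detection (LOD).
Preprocessing applies three standard rules, in order:

1. censored results are replaced by LOD/2 (the accepted convention for
   credible evaluation of low pollutant levels; substituting zero would
   bias daily quantiles downward);
2. results recorded as `<x` keep the numeric value `x` and are treated as
   uncensored (the marker is informative of the assay, not of the value);
3. total arsenic is converted to inorganic arsenic at a ratio of 0.70,
   since toxicity reference values apply to the inorganic fraction.

The LOD is resolved from the record first, then from a per-metal fallback
table — real surveillance mixes assays with different LODs.
`preprocess_records()` is guarded by a processed flag so the arsenic
ratio is applied exactly once. Records aggregate to per-day, per-metal
summaries: the maximum and mean pollution index `P = X/S` (with `S` the
national limit standard), and the 50th and 95th concentration quantiles.
Quantiles use linear interpolation between order statistics (R type 7,
the common default); the choice is a `quantile_type` argument because no
single convention is universal. Days observed for only a subset of the
three metals are dropped before fusion: the comprehensive indexes need
all nine per-metal values.

Default limit standards are the Chinese food-contaminant standard values
for rice/grain (Cr 1.0, Cd 0.2, inorganic As 0.2 mg/kg); they are
arguments everywhere because limits are product-specific.

## 2. The three risk indexes

Per day and metal:

- **NIPI** `= sqrt((P_max^2 + P_avg^2)/2)` — the quadratic mean weights
  peak contamination above the day's average, which suits safety
  monitoring where single hot samples matter.
- **TCR** `= EF·ED·CSF·EDI50/ATC`, `EDI50 = FC·X_q50/W` — lifetime
  incremental cancer risk at the day's *median* exposure.
- **THQ** `= EF·ED·EDI95/(ATC·RfD)`, `EDI95 = FC·X_q95/W` — non-cancer
  hazard quotient at the day's *95th-percentile* exposure, a
  conservative tail exposure.

Constants and units: RfD in mg/(kg·d) (0.003 trivalent chromium, 0.001
cadmium, 0.0003 arsenic — source tables sometimes label these μg/(kg·d),
but the numeric values are the standard mg/(kg·d) oral reference doses,
which is the unit adopted here); CSF in (kg·d)/mg (0.5, 6.3, 1.5);
exposure frequency EF = 365 d/yr, exposure duration ED = 70 yr, averaging
time ATC = 365·ED d, body mass W = 60 kg. Under these defaults
EF·ED/ATC = 1 exactly, so TCR = CSF·EDI50 and THQ = EDI95/RfD; the test
suite asserts both to machine precision. Consumption FC defaults to the
arithmetic mean of the 20 provincial per-capita figures (g/day → kg/day);
a per-province assessment can be run by passing a provincial FC. All
three indexes are positively homogeneous of degree 1 in the concentration
scale, which the tests exploit as an invariant.

## 3. Entropy-weight fusion

The nine per-metal indexes are fused into comprehensive NIPI, TCR and THQ
with entropy weights: column proportions `p_tj = x_tj / Σ_t x_tj`,
entropy `e_j = −(1/ln n) Σ_t p_tj ln p_tj` (with `0·ln 0 ≡ 0`), weight
`w_j ∝ 1 − e_j`. Variable indicators carry more information and weigh
more; a constant column gets weight zero. Weights are computed on raw
index columns (the formula normalizes internally) and are invariant to
uniform rescaling of any column.

The nine weights sum to one globally, but each comprehensive index is a
combination of only three of them, so the default fusion mode
renormalizes the three per-metal weights within each index type, making
every comprehensive index a convex combination of its per-metal values; a
`global` mode (raw weights) exists for sensitivity checks. Weights are
fitted on the primary training span (the first 80% of days) and frozen,
so test-period values never influence them. No analytic-hierarchy
pairwise matrix is elicited; a user with subjective priorities can
multiply them into the entropy weights and renormalize.

## 4. Risk levels by K-means++ clustering

The comprehensive series is min–max normalized to `[0,1]^3` (bounds are
stored so forecasts can be normalized identically and results
inverse-transformed; min–max rather than z-scores because the level
geometry is interpreted in a bounded unit space). K-means++ seeding picks
the first center uniformly and each next center with probability
proportional to the squared distance to the nearest chosen center; Lloyd
iterations run to an assignment fixpoint, and the best of 10 restarts by
within-cluster sum of squares is kept. An emptied cluster is re-seeded to
the point farthest from its center, keeping k fixed. The number of levels
is chosen by the average silhouette coefficient over k = 3…7 (ties go to
the smaller k); singleton-cluster members score 0 by convention. Centers
are ordered by Euclidean distance to the origin — farther means riskier —
and named Low, Medium, Second-Highest, High when k = 4 (generic level
names otherwise). Any day is classified to its nearest center; exact
distance ties resolve to the lower-risk level, since inflating alarms on
ties has real inspection costs. All randomness of the fit flows from one
recorded integer seed.

The cluster model is fitted on the full assessment period: risk levels
are a descriptive classification of the year under assessment, and the
forecasting stage — which must not see future values — operates on the
index series, not on the level definitions.

## 5. Multi-step forecasting

A one-step predictor maps the previous `n = 7` daily values of a
comprehensive index (one model per index) to the next value; a τ-step
forecast iterates it, appending each prediction and dropping the oldest
value, so beyond `n` steps the input is entirely model-generated. The
evaluation step length is fixed at 21 days with horizons reported at
7/14/21 — the 7-day horizon aligns with weekly reporting; the longer ones
quantify error accumulation.

Three recurrent one-step architectures are provided — a simple (Elman)
recurrent cell, a GRU and an LSTM, each a single recurrent layer with a
linear readout of the final hidden state — implemented directly in R with
full backpropagation through time (gradients verified against finite
differences in the tests) and Adam on full-batch squared error. With
series of a few hundred points and 7-wide windows, full-batch matrix
arithmetic trains a model in well under a second, so no external deep
learning runtime is needed.

Two choices deserve emphasis:

- **Persistence-prior initialization.** One hidden unit is wired so the
  untrained network computes approximately the identity on the last
  window value (readout `4·tanh(x/4)`), with the remaining weights small
  and random. A recursive forecaster amplifies any one-step bias roughly
  τ-fold, and squared-error training pulls predictions toward the
  conditional mean, which under regime-switching dynamics contracts
  recursive forecasts toward the series mean — a known failure mode of
  multi-step recursion. Starting from a persistence prior makes "no
  change" the zero-training behavior, and training must earn deviations
  from it.
- **Validated training length.** Parameter snapshots are stored along the
  training trajectory, and the deployed snapshot is chosen per
  architecture by level-prediction accuracy on held-out validation
  segments — the last three 21-day segments of the training span,
  excluded from sub-model fitting and forecast recursively from the
  window preceding each. A single 21-day segment contains too few regime
  episodes to rank snapshots stably, hence three. Selection applies the
  one-standard-error rule (earliest snapshot within one binomial standard
  error of the best validated accuracy): conservative model selection in
  the classic sense.

The pipeline trains sub-models at 16 hidden units for 120 epochs — ample
for these series lengths and chosen to keep the full 27-model pipeline
run in the tens of seconds; the standalone `recurrent_forecaster()`
defaults to 32 units / 200 epochs for general use.

## 6. The voting ensemble

Sub-model forecasts combine as `h_t = Σ_i w_i ζ_i(X)` with weights on the
simplex. Because level accuracy is piecewise constant in the weights, the
accuracy-maximizing weights are found by exhaustive search over a
rational simplex grid (step 0.05: 231 candidates for three models), which
is exact up to grid resolution and exactly reproducible. Ties resolve by
lower mean squared forecast error, then lexicographic weight order. The
weights are selected on the same held-out validation segments used for
snapshot selection — never on test data. Evaluation reports RMSE and MAE
per index and horizon plus per-horizon level accuracy for each sub-model,
the ensemble and a persistence baseline (repeat the last observed value),
the natural benchmark every learned forecaster must face.

Dataset splits: three chronological train/test splits with 21-day test
windows — two sharing the training ratio (80%) with different test
windows, two sharing the test window with different ratios (80% vs 70%) —
so both generalization across periods and sensitivity to the split ratio
are visible.

## 7. The synthetic generator

The generator emulates the statistical structure of surveillance
detection data: per-metal daily batches with Poisson counts (default mean
100 samples/metal/day, comparable to the sampling intensity of a national
system), log-normal concentrations (the standard model for right-skewed
contaminant data; defaults put cadmium close to its limit so NIPI
straddles 1), below-LOD censoring at realistic assay limits, and province
labels drawn from the consumption table. Days follow four contamination
regimes — background, elevated-median (median ×1.8), heavy-tail
(log-scale SD ×2.0) and combined — scheduled by a sticky Markov chain
(persistence 0.9) so the series has forecastable temporal structure; an
i.i.d. schedule is available for clustering-only tests. True regime
labels are returned so recovery can be measured.

The regime multipliers were chosen with `regime_separation_check()`,
which propagates them analytically through the index formulas (a median
multiplier `m` scales TCR by exactly `m`; an SD multiplier `s` scales the
population 95th percentile by `exp(1.645·σ·(s−1))`, driving THQ and NIPI)
and reports Monte-Carlo regime centers in normalized space; the defaults
give a minimum pairwise regime separation ≥ 0.15, enough for the four
regimes to re-emerge as four silhouette-selected clusters.

What the generator does *not* emulate: provincial or seasonal composition
effects, laboratory batch effects, reporting delays, or trends within
regimes. Tests passing on synthetic data therefore demonstrate the
correctness and internal consistency of the pipeline, not the accuracy
attainable on real surveillance data.

## 8. Numerical choices and degenerate inputs

- Quantiles: linear interpolation (type 7); configurable.
- `0·ln 0 ≡ 0` in the entropy; all-constant index matrices are an error
  (no information to weight).
- Min–max normalization refuses constant columns; bounds are stored and
  reused for forecasts.
- Empty clusters re-seed to the farthest point; k stays fixed.
- Silhouette of singleton-cluster members is 0.
- Classification distance ties go to the lower-risk level.
- Non-finite training loss raises an error naming the learning rate.
- `tau = 0` recursive forecasts return an empty vector; a history shorter
  than the window is an error.
- All randomness flows from explicit integer seeds; the full pipeline is
  bit-for-bit reproducible from one seed.

## 9. Known limitations

- Under a sticky-Markov regime schedule the persistence baseline is close
  to the best achievable level predictor at short horizons; the ensemble
  matches it at the package's operating point, and on arbitrary seeds the
  difference between the two fluctuates around zero. Beating persistence
  decisively requires temporal structure (trends, autocorrelated drifts)
  that the generator deliberately does not fabricate.
- The closed metal set (Cr/Cd/As) and the single food class are design
  limits of scope, not of the code structure; extending either means
  widening the enum and the limit/toxicology tables.
- Comprehensive indexes inherit the noise of daily extreme statistics
  (`P_max`, `X_q95`); heavy-tailed days can stretch the normalization
  bounds and compress the bulk of the series.
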