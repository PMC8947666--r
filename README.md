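# metalrisk

Food-safety early warning from heavy-metal surveillance data: daily dietary
risk indexes, data-driven risk levels, and multi-step risk-level forecasts.

## The problem

National food-safety surveillance systems collect thousands of laboratory
detections of heavy metals — chromium, cadmium and arsenic — in grain
processing products every day. Regulators need more than raw
concentrations: they need a daily, interpretable risk level ("is today a
high-risk day?") and a forecast of that level over the coming week, so
that inspection resources can be targeted before hazards become incidents.
`metalrisk` is written for risk-assessment teams and for researchers
building early-warning models on detection-record data.

## The method

For each day *t* and metal *j*, three standard dietary risk indexes are
computed from the day's detection batch:

- **NIPI** (Nemerow integrated pollution index), emphasizing peak
  contamination:
  `NIPI = sqrt((P_max^2 + P_avg^2) / 2)`, where `P = X / S` is the
  concentration over the national limit standard;
- **TCR** (target cancer risk):
  `TCR = EF·ED·CSF·EDI50 / ATC` with `EDI50 = FC · X_q50 / W`, the
  estimated daily intake at the day's median concentration;
- **THQ** (target hazard quotient):
  `THQ = EF·ED·EDI95 / (ATC·RfD)` with `EDI95` the intake at the day's
  95th-percentile concentration.

Censored ("not detected") results are replaced by half the limit of
detection, `<x` results keep `x`, and total arsenic is converted to
inorganic arsenic at 70%.

The nine per-metal indexes are fused into comprehensive daily NIPI, TCR
and THQ by **entropy weights** (`w_j ∝ 1 − e_j`, where `e_j` is the
information entropy of indicator *j* across days). The comprehensive
triples are min–max normalized and clustered with **K-means++**, the
number of clusters selected by the **average silhouette coefficient**;
cluster centers are ordered into risk levels (Low < Medium <
Second-Highest < High) by their Euclidean distance to the origin, and any
day — observed or forecast — is classified to the level of its nearest
center.

Future levels are forecast with a **voting ensemble of recurrent one-step
predictors** (simple recurrent, GRU and LSTM cells, implemented in the
package with backpropagation through time) applied **recursively**: each
predicted value is appended to the input window, so a τ-step forecast
needs no future observations. Ensemble weights live on the simplex
(`Σ w_i = 1`) and are selected by exhaustive grid search maximizing the
**level prediction accuracy** `PA = Σ_t I(K(h_t) = K(y_t)) / t` on
held-out validation segments, with RMSE/MAE reported per index and
horizon.

Because national detection records are access-restricted, the package
ships a seeded synthetic generator (`simulate_detections()`) reproducing
their structure: Poisson daily batches, right-skewed log-normal
concentrations with below-LOD censoring, province labels, and four
sticky-Markov contamination regimes (background, elevated-median,
heavy-tail, combined) whose true labels are returned for validation.

## Worked example

```r
library(metalrisk)

run <- run_early_warning(seed = 0)   # synthetic 300-day surveillance year
print(run)
```

```
Early-warning pipeline run (seed 0 )
  300 assessed days; k = 4 risk levels (silhouette 0.6975)
  Risk-level distribution:
           Low-Risk         Medium-Risk Second-Highest Risk           High-Risk
             0.2733              0.3600              0.2233              0.1433
  Mean level-prediction accuracy across datasets:
       model horizon        pa
    ensemble       7 1.0000000
         gru       7 1.0000000
        lstm       7 1.0000000
 persistence       7 1.0000000
         rnn       7 1.0000000
    ensemble      14 0.8571429
         ...
    ensemble      21 0.7936508
         ...
```

Reading the output: the silhouette criterion selects four risk levels
(average silhouette 0.70), days split roughly 63/37 between the two lower
and two upper levels, and over the three chronological dataset splits the
voting ensemble classifies 100% of the next 7 days to the correct risk
level, degrading to 79% at 21 days as recursive error accumulates — the
expected multi-step pattern. Individual stages are available separately:

```r
gen     <- simulate_detections(sim_config(n_days = 300), seed = 0)
records <- preprocess_records(gen$records)
idx     <- assess_days(summarize_daily(records))   # per-day, per-metal indexes
comp    <- fuse_indexes(idx, entropy_weights(idx)) # comprehensive series
model   <- risk_clusters(comp, seed = 1)           # risk levels
predict(model, comp)                               # level per day
```

A command-line front end is installed at
`system.file("cli", "metalrisk.R", package = "metalrisk")` with
`simulate`, `assess` and `evaluate` subcommands.

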