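# edcast

Early-warning forecasting of **mortality-associated emergency department
(ED) crowding** from anonymous administrative time series.

## The problem

ED crowding is repeatedly associated with excess mortality. For a sectioned
Nordic-style ED, the occupancy ratio

EDOR<sub>s</sub>(t) = occupancy<sub>s</sub>(t) / capacity<sub>s</sub>

(per section *s*: bedoccupying = all bed patients, medical, surgical,
critical) crossing **90%** marks the level linked to elevated 10-day
mortality, and a calendar day with **≥ 3 hours at EDOR ≥ 0.90** is a crisis
("crowded") day. `edcast` implements the full early-warning pipeline around
that definition, for researchers and ED analysts who want to study or deploy
crowding prediction without patient-level data:

1. **Simulate** (`simulatePanel`): an M(t)/G/∞-style queue — Poisson
   arrivals with hour-of-day / weekday / holiday / seasonal intensity and
   shared lognormal day- and hour-level load effects, geometric
   whole-hour lengths of stay — generates hourly sectioned occupancy plus
   daily weather, bed-availability and holiday covariates. The shipped
   defaults are calibrated so long-run daily crowding prevalence is close to
   28% / 36% / 25% (bedoccupying / medical / surgical) with crowding
   essentially absent 8–11 a.m.
2. **Label** (`crowdingLabels`): hourly indicators EDOR ≥ 0.90 and daily
   crisis labels (≥ 3 crowded hours).
3. **Features** (`buildDesignMatrix`): one row per (date, subgroup,
   forecast origin 8 a.m.–1 p.m.); 22 base variables (calendar triple,
   weekday, month, beds, 7/14-day lagged daily labels of all four subgroups,
   five weather values, subgroup and origin codes, label) plus a 168-hour
   lookback block of hourly crowding indicators and occupancy for every
   subgroup — 1,344 lookback columns, window strictly before the origin
   hour. A 790-day panel yields the reference 18,960 × 1,366 matrix.
   `leakageAudit` verifies every lookback cell against the panel.
4. **Forecast** (`expandingWindowForecast`): a gradient-boosted tree
   classifier (xgboost, histogram method, native missing-value handling) is
   refit at the start of each test day on all preceding data — expanding
   window cross-validation, 365-day initial training window by default.
5. **Evaluate** (`metricsTable`): F1, TPR, TNR, PPV, NPV, FPR, FNR,
   accuracy, AUROC (Mann–Whitney, ties ½) and AUPRC (step-wise average
   precision) per (subgroup, origin), with 95% percentile-bootstrap
   confidence intervals (200 resamples); critical is an explanatory
   variable only, never a target.
6. **Attribute** (`shapleyImportance`, `surrogateImportance`): tree-exact
   Shapley values φ<sub>i</sub> (local accuracy: baseValue + Σφ<sub>i</sub>
   equals the raw model output) and LIME-style locality-weighted sparse
   linear surrogates, aggregated to global rankings by mean |attribution|.

`runPipeline` chains the six stages through serialized CSV/JSON
intermediates with a single fanned-out seed, so every stage is inspectable
and reproducible.

## Worked example

```r
library(edcast)

sim <- simulatePanel(edSimConfig(nDays = 200, seed = 5))
labels <- crowdingLabels(sim$panel)
rowMeans(dailyCrowding(labels))[c("bedoccupying", "medical", "surgical")]
#> bedoccupying      medical     surgical
#>        0.315        0.395        0.360

dm <- buildDesignMatrix(sim$panel, sim$covariates, labels)
dim(dm)
#> [1] 4800 1366

start <- min(designDates(dm))
run <- expandingWindowForecast(
    dm, splitConfig(start + 119, start + 199, strideDays = 7),
    defaultHyperparameters(50, max_depth = 4), seed = 1)
tab <- metricsTable(run, bootstrapConfig(seed = 2))
tab[tab$origin == 11, c("target", "f1", "acc", "auroc", "auroc_lo", "auroc_hi")]
#>          target        f1    acc     auroc  auroc_lo  auroc_hi
#>    bedoccupying 0.3200000 0.7875 0.7161346 0.5839835 0.8576687
#>         medical 0.3783784 0.7125 0.6909091 0.5626061 0.8063766
#>        surgical 0.3243243 0.6875 0.5694545 0.4372847 0.7025369
```

Read: on purely synthetic data the 11 a.m. forecast separates crowded from
calm afternoons with AUROC ≈ 0.57–0.72 depending on the section (the
synthetic signal is weaker than real data, where day-to-day structure is
richer); the bootstrap interval shows the sampling uncertainty of an
80-day test window.

A shell entry point for the whole pipeline ships in `inst/cli/edcast`
(`edcast run --config cfg.yaml --out dir --seed 1`).

## Package layout

- `R/` — S4 classes (`EDPanel` extends `SummarizedExperiment`;
  `EDCovariates`, `CrowdingLabels`, `EDDesignMatrix`, `ForecastRun`,
  `AttributionResult`) and the stage functions.
- `vignettes/edcast-methods.Rmd` — the model, its assumptions, parameter
  choices and limitations.
- `tests/testthat/` — unit, property and acceptance suites with independent
  oracles (pair-counting AUROC, threshold-sweep AUPRC, brute-force subset
  enumeration for Shapley values).
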