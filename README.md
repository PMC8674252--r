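# esrindex

Data-driven construction of an **epidemiological susceptibility risk (ESR)
index**: one score per country and year summarizing a panel of preparedness
indicators (health, water/sanitation, transport, communications,
demographics, economic activity, governance), for researchers and analysts
who need a defensible one-dimensional risk summary for ranking countries,
tracking preparedness over time, or feeding downstream regressions —
without hand-picked aggregation weights.

## What it computes

Given a long-format panel of indicator values keyed by (country, year,
variable), the package imputes missing cells, standardizes each year's
cross-section, and builds the index with four methods on equal footing:

* **PCA** per year: minimize ‖X − XCCᵀ‖²_F s.t. CᵀC = I; the index is the
  first-component score.
* **Robust PCA** per year (principal component pursuit): minimize ‖L‖\* +
  λ‖S‖₁ s.t. L + S = X; gross anomalies land in the sparse part S and
  classical PCA of the low-rank part L gives an outlier-resistant index.
* **Robust sparse PCA** per year: minimize ‖X − WCᵀ − S‖²_F + ψ(C) + φ(W) +
  λ‖S‖₁ s.t. CᵀC = I, with elastic-net ψ for sparse, interpretable
  loadings.
* **Dynamic factor model** over the whole history: F_t = A F_{t−1} +
  N(0, Q), X_t = C F_t + N(0, R), estimated in three stages — per-country
  EM fits, a lasso-penalized one-lag VAR coupling the country factors
  (sparsity coefficient α, default 0.2), and joint Kalman smoothing with
  block-diagonal loadings. The smoothed factors are the index.

All indices are sign-oriented **risk-increasing** (the constituent
indicators are protective, so the base orientation makes larger = riskier).
Evaluation machinery ships alongside: reconstruction R² with 95th/99th
percentile trimming, augmented Dickey–Fuller stationarity (MacKinnon
p-values), the Kaiser–Meyer–Olkin adequacy measure, per-country Spearman
correlation against incidence series, and a cross-validated RMSE harness
comparing the single index against the original variables across linear and
nonlinear learners. A synthetic-panel generator with ground truth makes
every stage testable offline.

## Worked example

```r
library(esrindex)

cfg <- sim_config(n_countries = 20, outlier_fraction = 0.05,
                  missing_fraction = 0.05, seed = 42)
sim  <- simulate_panel(cfg)              # panel + ground truth
prep <- preprocess_panel(sim$panel)      # drop/impute/standardize
res  <- pca_index(prep$panel, "robpca")  # per-year robust PCA index
metric_report(prep$panel, res$index, res$fits)
#> metric_report [robpca]
#>   mean explained variance: 94.0 +/- 1.3%
#>   mean R2 (full): 44.5 +/- 5.8%
#>   mean R2 (99th): 48.4 +/- 6.7%
#>   mean R2 (95th): 66.8 +/- 7.2%
#>   ADF on index: stat -7.805, p 7.341e-12
#>   trimming by |original value|; R2 target: data
```

Reading it: the retained component carries 94% of per-year variance, so one
score per country-year loses little; trimmed R² rising from 44.5% to 66.8%
quantifies how much the 5% planted gross outliers cost the reconstruction;
the ADF p-value ≪ 0.01 certifies the index series is stationary (its
movements are signal, not trend). Against the generator's ground truth this
index tracks the latent factor at mean per-country |Spearman ρ| = 0.93:

```r
round(res$index$values[1:3, 1:5], 2)
#>      2010  2011  2012  2013  2014
#> C01  0.92  0.35 -0.06 -2.97 -4.47
#> C02 -1.10 -2.23 -2.49 -0.97 -0.35
#> C03 -4.81 -2.56  1.32  1.03 -0.42
```

Higher values mean higher susceptibility risk; country C01's risk rises
sharply toward 2014 in this draw... with the sign convention, that is a
*decline* in the protective indicators. The DFM variant is one call:
`dfm_index(prep$panel, alpha = 0.2, q_structure = "diagonal")`.

## The analysis workflow

Numbered drivers under `analysis/` re-run the full study on the reference
synthetic conditions and write their tables under `results/`:

1. `01_simulate.R` — generate the reference panel (+ ground truth)
2. `02_build_index.R` — preprocess and build all four indices
3. `03_evaluate.R` — explained variance / R² / ADF / KMO / recovery table
4. `04_dfm_tuning.R` — α × Q-structure grid, factor reconstruction error
5. `05_validate.R` — index-vs-original-variables RMSE comparison

```sh
for f in analysis/0*.R; do Rscript "$f"; done
```

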