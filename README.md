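# spawnsel

Tools for asking whether spawning salmon select habitat in response to
their own density or to density-independent habitat features, across a
riverscape split into *core* (concentrated central spawning) and
*periphery* reaches. The package is aimed at riverine population
ecologists who have reach-scale count panels, sub-reach geomorphic
attributes, and daily flow/temperature series, and want the complete
inference chain rather than isolated model fits.

## The models at the core

**Resource selection function (bootstrap used/available design).** Redd
counts of used sub-reaches, plus an equal-sized random draw of available
sub-reaches assigned a count of zero, are modelled per permutation as

> y ~ NegBin(μ, θ), log μ = β₀ + β₁·VWI + β₂·BFW + β₃·GRAD

over 1000 permutations; medians and 90% percentile intervals summarize the
coefficients, and predicted counts rescaled by their maximum give 0–1
suitability scores.

**Candidate count models.** Peak spawner counts per reach-year follow a
negative binomial GLM with a log stream-length offset,

> log μ = Xβ + log(length_km),

where X ranges over a canonical set of 15 formulas in escapement (E, E²),
the core/periphery factor (CP), and the density-independent covariates
RSF, TEMP, FLOW. Models are ranked by AICc = −2ℓ + 2k + 2k(k+1)/(n−k−1)
(k counts the dispersion) with Akaike weights w_i ∝ exp(−Δᵢ/2), validated
by the 0.632+ bootstrap (corrected r, ρ, mean error, RMSE), and the best
predictive model is chosen by mean metric rank.

**Isodar analysis.** Predicted periphery counts are regressed on predicted
core counts across escapement levels, with prediction uncertainty
propagated through 10,000 bootstrap isodars (one truncated-normal draw per
habitat and escapement per iteration). The 90% CIs decide: intercept
excluding 0 → habitat *quantity* differs; slope excluding 1 → habitat
*quality* differs. An additive best count model reads as ideal-free (IFD)
selection; interactions or nonlinearity as despotic (IDD).

A synthetic riverscape generator with a known truth record (attributes,
counts, escapement, daily climate/temperature/flow series) drives the test
suite and the worked examples: no external data are needed.

## Worked example

Ranking a published-style summary table (logLik, df) at n = 40 reach-years:

```r
library(spawnsel)
tab <- data.frame(name = c("E+E^2+CP", "E+CP", "E*CP"),
                  df = c(5L, 4L, 5L),
                  loglik = c(-254.38, -255.72, -255.69))
rank_models(tab, n = 40)
#>      Model Model_num Type df logLik  AICc   delta weight
#> 1 E+E^2+CP        NA <NA>  5 -254.4 520.5 0.00000 0.4462
#> 2     E+CP        NA <NA>  4 -255.7 520.6 0.05815 0.4334
#> 3     E*CP        NA <NA>  5 -255.7 523.1 2.62000 0.1204
```

The full synthetic pipeline — simulate, RSF, covariates, count models,
validation, isodars — in one call:

```r
res <- run_pipeline(pipeline_config(out_dir = "run1", seed = 1))
head(res$ranking[, c("Model", "Type", "df", "logLik", "AICc", "delta", "weight")], 5)
#>      Model Type df logLik  AICc delta  weight
#> 1     E+CP   DD  4 -218.7 446.5 0.000 0.39911
#> 2     E*CP   DD  5 -218.0 447.8 1.306 0.20770
#> 3 E+E^2+CP   DD  5 -218.2 448.2 1.758 0.16575
#> 4 E*CP+E^2   DD  6 -217.5 449.5 3.023 0.08802
#> 5      RSF   DI  3 -221.9 450.6 4.085 0.05176

res$best_model
#> [1] "E+CP"
res$isodar
#> Isodar bootstrap (10000 isodars, periphery_on_core)
#>   slope       0.109  90% CI [-0.143, 0.364]  quality differs: TRUE
#>   intercept  56.490  90% CI [3.580, 109.442]  quantity differs: TRUE
res$verdict$selection_regime
#> [1] "IFD-consistent linear isodar"
```

Read: the density-dependent additive model E+CP wins the ranking and the
validation; the isodar slope sits well below 1, so core habitat quality
exceeds periphery quality — densities in the core rise faster as the run
size grows — while the additive model structure is consistent with
ideal-free rather than despotic selection. Every stage writes its tables
(`model_ranking.csv`, `isodar_summary.csv`, ...) plus a provenance record
into `out_dir`, and `plot_isodar(res$isodar, res$preds)` /
`plot_isodar_coefs(res$isodar)` draw the spaghetti-isodar and
coefficient-histogram figures.

A thin command-line wrapper lives at `inst/scripts/run-pipeline.R`:

```sh
Rscript inst/scripts/run-pipeline.R --out run1 --seed 42 --n-iso 10000
```

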