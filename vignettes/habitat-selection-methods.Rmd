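---
title: "Separating density-dependent from density-independent spawning habitat selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating density-dependent from density-independent spawning habitat selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question and the model chain

Declines in a salmon population can come from density-independent (DI)
degradation of habitat — flow, temperature, geomorphology — or from
density-dependent (DD) processes that cap the population at a carrying
capacity. The two call for very different management responses, so this
package implements a chain of models that separates them for spawning
habitat selection across a riverscape divided into *core* reaches (the
concentrated central spawning area, labelled C1 and C2) and *periphery*
reaches (outlying spawning areas, P1 and P2):

1. a **resource selection function (RSF)** scoring sub-reach spawning
   suitability from geomorphic attributes;
2. **DI covariates**: spawning-window flow metrics from daily hydrographs
   and stream temperatures backcast from climate regressions;
3. a **negative binomial candidate-model set** for peak spawner counts
   per reach and year, containing purely DD models (escapement, the
   core/periphery contrast), purely DI models, and combinations, ranked by
   small-sample-corrected AIC;
4. **0.632+ bootstrap validation** to choose the best *predictive* model;
5. **isodar analysis**: the regression of predicted periphery counts on
   predicted core counts across escapement levels, whose intercept and
   slope diagnose differences in habitat *quantity* and *quality* and
   whether selection is consistent with an ideal free distribution (IFD)
   or suggests despotic defense of the core (IDD).

Everything runs on a synthetic riverscape whose generating parameters are
known, so every stage is testable end to end without field data.

```{r, eval = FALSE}
library(spawnsel)
res <- run_pipeline(pipeline_config(out_dir = "run1", seed = 1))
res$ranking
res$isodar
```

## Resource selection function

The RSF follows the used/available count-regression design: the response is
the redd (nest) count of a sub-reach, modelled as negative binomial in
three geomorphic covariates — channel gradient (GRAD, %), bankfull width
(BFW, m), and valley width index (VWI, a unitless measure of valley
confinement). Each of the (default) 1000 bootstrap permutations combines
*all* used sub-reaches with an equal-sized draw, without replacement, from
the available pool; the availability rows are given a pseudo-response of
zero. The availability pseudo-response is not stated explicitly in the
used/available literature's applied descriptions; assigning zero is the
natural reading of the count-regression design and is what we implement.
Per-coefficient medians and 90% percentile intervals (plain percentile, not
BCa — nothing in the design justifies the extra machinery) summarize the
permutations. Dispersion is re-estimated in every permutation; permutations
that fail to converge are skipped with a warning and the run aborts if more
than 10% fail.

Scores are predicted counts from the median coefficients divided by the
maximum predicted count over the scored set, so scores live in [0, 1] with
at least one exact 1. Dividing by the maximum rather than min–max scaling
preserves the zero point of intensity of use: a sub-reach predicted to
attract no spawning keeps a score near 0 regardless of the score spread.
Study reaches are summarized by the mean score of their nested sub-reaches
after a configurable minimum-length filter (default 50 m; sub-reaches are
generated at 20–200 m but only 50–200 m segments enter reach summaries).

**A limitation worth knowing.** Because the used rows are held fixed and
only the availability draw is resampled, the bootstrap intervals quantify
availability-sampling uncertainty *conditional on the realized used
sample*. In simulation with a flat (null) selection surface, the 90%
intervals cover zero for roughly half to two-thirds of outer replicates,
not 90%: the variability of the used sample itself is not propagated. The
intervals are therefore read as describing the stability of the fitted
surface, not as frequentist coverage statements about the generating
process, and the test suite checks the null-centring of the medians rather
than interval coverage.

## Flow and temperature covariates

Flow metrics are computed over the spawning window (default 01 July–31
August, inclusive): maximum daily flow, mean daily flow, and flow
variability as the coefficient of variation of the window's daily flows.
The CV uses the sample (n−1) standard deviation, and a window with zero
mean flow is an error rather than a silent `NaN`. The candidate set's FLOW
covariate is configurable between the window mean and the window maximum
(`flow_covariate`), defaulting to the mean; the pipeline logs the choice.

Stream temperature is regressed on five daily climate covariates (mean air
temperature, maximum humidity, square-root-transformed minimum humidity,
barometric pressure, wind velocity) after a greedy pairwise correlation
screen at |r| > 0.6: the worse member of the worst-correlated pair — the
one with the larger mean absolute correlation to everything else — is
dropped until all pairs pass, with alphabetical tie-breaking so the result
does not depend on column order. Model reduction is backward-only deletion:
at each step the term whose deletion F-test has the largest p ≥ 0.15 is
removed (largest-p-first, alphabetical tie-break), exactly the "deletion
test" scheme, not bidirectional stepwise. A term whose deletion leaves the
residual sum of squares unchanged (an undefined F) is treated as droppable.
Fitted models backcast daily temperatures over historic climate, summarized
to window mean/min/max per reach-year; covariate values outside the
training range warn about extrapolation but do not fail.

Collinearity among the three DI covariates entering the count models is
screened by variance inflation factors, `VIF = 1/(1 − R²)`, with the
conventional threshold of 3.

## The candidate set and AICc

Fifteen negative binomial models (log link) predict reach-year peak counts:
five DD (all combinations of escapement E, its quadratic, and the
core/periphery factor CP, including the E×CP interaction), four DI (TEMP,
FLOW, RSF singly and additively), and six combinations with DI×E or DI×CP
interactions. Every model carries an offset of `log(length_km)`, so
coefficients describe counts per kilometre of stream and unequal reach
lengths cannot masquerade as habitat effects.

AICc is `−2ℓ + 2k + 2k(k+1)/(n−k−1)` with `k` counting *every* estimated
parameter including the NB dispersion θ, and `n` the number of reach-year
rows. Akaike weights are `exp(−Δi/2)` normalized over the set. Both
conventions are pinned by arithmetic: recomputing AICc from a published
15-model table's (logLik, df) pairs at n = 40 reproduces its printed AICc
column at one decimal place for all rows — which only works if df includes
the dispersion — and reproduces the printed weights.

Escapement enters the fits as a z-score by default. This is a linear
reparameterization: it changes coefficient values but not likelihoods, so
AICc ranking is invariant (tested), and it stabilizes the quadratic
models. A raw-scale toggle exists for coefficient-level work such as the
recovery tests. When the dispersion estimate diverges because the data
show no overdispersion (exact-fit corner cases), the fit is taken at the
Poisson limit with a fixed large dispersion, still counted in df.

## 0.632+ validation

Predictive performance of the top models (default: top four) is estimated
by the 0.632+ bootstrap with 200 resamples: each resample refits the model
and scores it on its out-of-bag rows, and the corrected metric blends
apparent and out-of-bag performance with weight `w = 0.632/(1 − 0.368R)`,
where the relative overfitting rate `R` is clipped to [0, 1] and computed
against a no-information benchmark. The estimator is defined for losses,
so the four metrics are mapped to losses and back: correlations through
`1 − r` (and `1 − ρ`), RMSE directly, and the signed mean error through its
absolute value (the blend itself stays on the signed scale, which is why
corrected mean errors can be negative). The no-information benchmark
scores predictions against all pairings of observed responses; for the
correlation losses this pairwise grid has correlation exactly zero — the
covariance factorizes into two centered sums — so their no-information
loss is identically 1, and for the signed mean error the grid benchmark
equals the apparent mean error, which forces `R = 0` and a fixed 0.632
weight for that metric. Resampling is by reach-year row; nothing in the
design implies a year-block structure, and blocking would starve the small
panel. The best predictive model minimizes the mean rank over the four
corrected metrics, with ties going to fewer parameters.

A separate detection-bias check regresses annual total peak density
(summed counts per total stream km) on escapement and tabulates residuals
by survey condition: a strong positive relationship is evidence that
detection efficiency did not drift across years.

## Isodars

The isodar stage asks the selection question directly. Using the best
predictive model, counts are predicted for each habitat type at each
observed escapement, over a *common* offset length (the mean of the four
study-reach lengths, 21.8 km under the default geometry) so the comparison
is density-like. For each of 10,000 bootstrap iterations, one count per
(escapement, habitat) is drawn from Normal(mean, SE) truncated at zero
(counts cannot be negative; the truncated fraction is recorded), and an
ordinary least-squares line of periphery on core is fitted across
escapements. The 90% percentile intervals of the slope and intercept draws
drive two closed-interval rules:

* intercept CI excluding 0 → habitat **quantity** differs;
* slope CI excluding 1 → habitat **quality** differs.

Axis orientation is a genuine open choice — nothing forces one habitat
onto either axis — so it is exposed as configuration. The default
regresses periphery on core: then a slope below 1 means core density rises
faster than periphery density as total abundance grows, i.e. the core is
the higher-quality habitat, which is the orientation under which a
published slope of 0.230 reads as core-favoring. OLS is the default line
(reduced major axis is a known alternative in the isodar literature, but
the plain regression is what the source analysis reports). The selection
*regime* is read from the structure of the best count model, not from
isodar curvature: an additive best model (no E×CP interaction, no
quadratic term) is consistent with IFD and a linear isodar, while
interactions or nonlinearity suggest despotic (IDD) selection. The "mean
isodar" is the average of the slope and intercept draws, not the isodar of
the mean counts; with 10,000 draws the two differ negligibly for these
smooth summaries.

`observed_isodar()` provides the raw-data companion: observed counts
converted to densities (per km) for one core and one periphery reach,
paired by year, fitted by a single OLS line.

## The synthetic riverscape

The generator is a first-class module, and its defaults are the study
conditions: 2,536 available sub-reaches with 176 used; four study reaches
with fixed stream lengths 40.5, 20.0, 16.1, 10.6 km (spanning the reported
10.6–40.5 km and averaging 21.8 km); ten fitting years (plus configurable
held-out years); and peak counts generated negative-binomially with a
log-length offset from escapement and a core effect, with default
coefficients chosen so counts span roughly 25–1,800 over an escapement
range of 2,000–12,000 — the magnitude of the published count span (32 to
1,797). The RSF truth defaults to the published coefficient triple
(−0.008, 0.069, −0.590 for VWI, BFW, GRAD) so sign-recovery tests target
realistic effect sizes.

Choices the source leaves open, fixed here once: GRAD and BFW are
lognormal and VWI gamma (strictly positive, right-skewed — the realistic
shapes for these attributes), with smooth downstream trends (gradient
falling, width growing downstream) plus an AR(1) field for spatial
autocorrelation, which automatically makes the downstream core blocks more
suitable, mirroring the reported core–periphery RSF contrast (means 0.259
vs 0.079); escapement is truncated-lognormal over its range; daily water
temperature is an exact linear function of the climate covariates plus
Normal(0, `noise_sd`) noise and a fixed upstream cooling offset; flow is a
snowmelt-plus-rain seasonal baseflow with exponentially decaying storm
pulses, non-negative by construction; the per-study-reach sub-reach count
is a configuration knob (the source never states it). Redd simulation
reconciles two constraints that cannot hold simultaneously under free NB
sampling — NB-distributed counts *and* an exact number of used
sub-reaches — by sampling the used set without replacement with
probability proportional to the NB probability of at least one redd, then
drawing used counts zero-truncated. All randomness flows from one integer
seed through fixed per-stage substreams, so any stage can be rerun
independently and reruns are byte-identical.

What the generator does *not* emulate — and hence what passing tests do
not establish about real data: no spatial geometry beyond reach ordering
(no confluences or network topology), no physically based hydrology or
heat budget, no observation error in the counts (detection is implicitly
perfect), no temporal autocorrelation in escapement, and independence of
counts across reaches within a year, which real synchrony would violate.

## Numerical and testing choices

Problem sizes in the test suite are chosen to exercise each property at
the smallest scale that still measures it: likelihood agreement with an
independent grid-search oracle on 6-row instances (tolerance 1e-3, with
over-dispersed fixtures so the dispersion optimum is interior and
reachable by a bounded grid); coefficient recovery over 200 replicates at
25 panel years; isodar CI coverage over 100 outer replicates. The isodar
coverage experiment deserves a note: the bootstrap draws directly from
Normal(mean, SE), so with literally fixed inputs its CI is non-random and
"coverage" would be degenerate. The meaningful experiment perturbs the
habitat means by the same Normal(0, SE) noise the SEs describe in each
outer replicate and asks whether that replicate's CI covers the true slope
of 1 and intercept of 0; regression attenuation (noise in the predictor)
biases the slope slightly below 1, so observed coverage sits a little
under nominal, and the test band (0.82–0.98 at 100 replicates) reflects
that analysis plus binomial Monte Carlo error. The 0.632+ estimator of the
true generating model converges to the generator's irreducible RMSE,
`sqrt(mean(mu + mu²/θ))`, checked within 10% at 400 rows.

Known limitations, summarized: the RSF bootstrap's conditional coverage
(above); the no-information rate degeneracy for the signed mean error
(above); Wald intervals for NB coefficients at n = 40 are approximate; and
the isodar inherits whatever misspecification the best count model has —
it is a statement about predicted, not observed, densities. The
`observed_isodar()` check is the corresponding reality anchor.
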