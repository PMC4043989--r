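---
title: "Splitting conflated whale catches with acoustic occurrence models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Splitting conflated whale catches with acoustic occurrence models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bluesplit)
```

## The problem

Commercial whaling records for North Pacific blue whales (1905–1971) report
catches of a single species, but two acoustically distinct populations were
being caught: an eastern population (ENP) whose song call differs from that of
blue whales in the western North Pacific (WNP). Assessing either population's
depletion and recovery requires splitting the conflated catch series between
them. `bluesplit` implements a two-stage inference that does this with modern
passive-acoustic data:

1. **Acoustic stage.** For each call type, fit a model of the probability
   $\mu(x, y, m)$ of hearing at least one song call in an hour at longitude
   $x$, latitude $y$, month $m$, from hydrophone presence-hour counts.
2. **Prediction stage.** Combine the two fitted surfaces into a per-catch
   assignment probability
   $$P(\text{ENP} \mid x, y, m) = \frac{p_E(x,y,m)}{p_E(x,y,m) + \lambda\, p_W(x,y,m)},$$
   where $\lambda$ is the unknown scaling between the ratio of call
   probabilities and the ratio of population densities (base case
   $\lambda = 1$).

Catch, statistical and ecological uncertainty are propagated by an ensemble:
each iteration draws a Monte Carlo realization of the uncertain catch
locations/dates, refits both acoustic models to a bootstrap resample of the
acoustic data, draws $\lambda$, splits the catches, and aggregates by year;
the ensemble is summarized by per-year 2.5/50/97.5 percentiles.

## The acoustic likelihood

The datum for one hydrophone-station month is $(k, n)$: of $n$ analyzed
hours, $k$ contained at least one call. Hours are not independent — a singing
whale is audible for many consecutive hours — so the counts are
over-dispersed relative to a binomial. We use a beta-binomial with mean
$\mu$ and over-dispersion $\sigma$, parameterized through shape parameters
$a = \mu/\sigma$, $b = (1-\mu)/\sigma$, giving variance
$$\mathrm{Var}(k) = n\mu(1-\mu)\Bigl(1 + \sigma \frac{n-1}{1+\sigma}\Bigr),$$
so $\sigma \to 0$ recovers the binomial exactly (`bb_logpmf()` switches to
the binomial form below $\sigma = 10^{-8}$, where the beta-binomial
expression loses precision to log-gamma cancellation).

Both distribution parameters carry additive predictors:
$\mathrm{logit}(\mu)$ and $\log(\sigma)$ are each modeled as intercept +
natural cubic spline in longitude (4 df) + natural cubic spline in latitude
(4 df) + an 11-contrast month factor (January reference). The full model
therefore uses $20 + 20 = 40$ coefficients; the six standard candidates
(`candidate_structures()`) replace one or both parameter predictors with
linear (14 columns) or constant (1 column) forms and/or drop the
over-dispersion entirely (binomial family), giving 40, 34, 21, 28, 20 and 14
coefficients. Candidates are ranked by AICc.

Numerical choices:

* **Links.** Logit for $\mu$, log for $\sigma$; both guarantee valid
  parameter values under unconstrained optimization.
* **Splines.** Natural cubic splines with interior knots at covariate
  quantiles (via `splines::ns`), unpenalized at fixed `spline_df = 4`.
  Natural splines extrapolate linearly beyond the boundary knots, which is
  the behaviour we want when predicting catches outside the hydrophone
  hull; predictions flag extrapolated points.
* **Optimization.** BFGS on the joint coefficient vector with analytic
  gradients; three deterministic starts (empirical-logit intercept and two
  offset variants; no RNG is consumed so fits are reproducible regardless of
  the caller's stream). A fit is `converged` when the optimizer reports
  success and the gradient infinity-norm is below `1e-5` relative to
  `max(1, |negative log-likelihood|)`; an absolute criterion would be
  meaninglessly strict for log-likelihoods of order $10^3$. Non-convergence
  is a flag, never an exception, because the ensemble discards and redraws
  such iterations.
* **Degenerate data.** All-absence (or all-presence) data push $\hat\mu$ to
  the boundary; the fit is flagged non-converged with a warning.
* **Months absent from training** predict through the January reference with
  a warning rather than erroring, since catch realizations can visit months
  a sparse array never recorded.

## Catch uncertainty and imputation

Historical records fall into five location-uncertainty categories, each with
a constraint payload honoured by `draw_realization()`:

| category | position | imputation |
|---|---|---|
| `certain` | exact | copied unchanged |
| `inferred` | recovered without uncertainty | copied unchanged |
| `soviet` | small rectangle | uniform draw in the rectangle |
| `iwc_region` | broad management region | drawn (with replacement) from donor catch locations in that region |
| `partial` | unknown, but same-expedition-year donors exist | drawn from donors in the record's month |

Donor pools are the reported locations of blue, fin, sei and common minke
whale catches — species with similar habitat hunted with the same effort —
kept as multisets and sampled with replacement. Missing months are sampled
first (partial locations are conditioned on the realized month), from
donor-derived monthly weights restricted to the expedition's operating
months; when an expedition's operating period is unrecorded, all twelve
months are allowed. A partial record whose sampled month has no donors falls
back, with a warning, to all months for that expedition-year. Unspecified
species catches are converted to blue whale counts by `allocate_unspecified()`:
same-year species proportions where available, otherwise adjacent-year
proportions with a window expanding one year at a time (default cap ±3 —
the sources leave the window unstated), and a fixed 16.4% proportion for
flagged early coastal-Japan rows; allocations round to the nearest integer
(ties to even, also unstated in the sources).

## The ensemble

`run_ensemble()` repeats until `N` iterations succeed: draw a realization,
bootstrap-refit both call-type models (resampling station-month rows with
replacement; refits warm-start from the base fits), draw $\lambda$, split,
aggregate. If either refit fails to converge the *whole* iteration is
discarded and redrawn — realization included — which reproduces the
attempts-vs-successes accounting one expects when a few percent of refits
fail. A run aborts if more than half of a rolling 100-attempt window fails.
Every attempt derives its seeds arithmetically from the run seed, so runs
are exactly reproducible and iterations are independent of how many earlier
attempts failed.

Design choices that were genuinely open:

* **Assignment mode.** Default `expected` sums per-catch probabilities by
  year (conservation ENP + WNP = total holds to floating-point exactness and
  Monte Carlo noise is minimized); `bernoulli` draws a population label per
  catch, making the ensemble interval *predictive* for the realized count.
  Coverage checks against a known true count use `bernoulli` for exactly
  that reason.
* **$\lambda$ convention.** $\lambda$ multiplies the western call
  probability, so values above 1 shrink the eastern share; the sensitivity
  default draws $\log\lambda \sim U(\log 0.5, \log 2)$, one draw per
  iteration held constant across catches.
* **Percentiles.** Linear interpolation between order statistics (R type 7);
  totals rows are percentiles of per-iteration totals, not sums of per-year
  percentiles. Report tables round to whole catches only at serialization.
* **Uncertainty decomposition.** The widths of the nested total-catch
  intervals (catch only; catch + bootstrap; catch + bootstrap + $\lambda$)
  are expressed as integer percentages of the full-interval width.

## The synthetic world

All tests run against `world_config()` worlds with known truth. The
generator emulates the statistical structure the analysis assumes:

* **Occurrence surfaces**: logistic-quadratic in scaled longitude/latitude
  plus 12 month offsets peaking in late summer; the eastern surface rises
  toward the eastern basin and vice versa, with mid-basin overlap. Values
  span roughly 0.01–0.7, comparable to hourly call-presence rates.
* **Over-dispersion field**: log-quadratic in both coordinates, about 0.4
  mid-basin rising to several units at the basin margins — strong,
  smoothly varying temporal correlation in singing, which is what makes the
  full additive/additive structure identifiable in model selection.
* **Stations**: grids over 150–250°E, 25–57°N with 720 analyzed hours per
  station-month (a year-round analog of a ~30-hydrophone array).
* **Catches**: placed by an effort surface proportional to the summed
  occurrence surfaces plus a flat background, months April–November weighted
  by total occurrence; true labels are Bernoulli in the local density ratio.
  Constraint payloads are generated per category, and donor pools always
  contain each constrained catch's true location, so imputation can recover
  the truth in expectation. Background donors follow the same effort
  surface — they represent reported catches of similar species.
* **Lengths**: normal, means 22.00 m (east) and 22.91 m (west), common SD
  1 m, so the westward length excess is 0.91 m.

What the generator does **not** emulate: oceanographic covariates, acoustic
propagation and detection range, year-to-year drift in the surfaces, and the
coastal concentration of real whaling effort (effort here follows whale
density plus a flat term). Passing tests therefore demonstrate correctness
of the inference machinery under the model's own assumptions, not fidelity
to any particular historical dataset.

## Problem sizes used by the checks

The packaged checks and `scripts/acceptance.R` use sizes chosen to exercise
the method at realistic information content: 30–35 stations × 12 months ×
720 hours per call type for selection and ensembles; 200 station-months for
surface recovery (50 stations × 4 summer months, against a 20×20 grid);
300–500 catches; ensembles of N = 150–200 iterations (scaled down from the
1000 one would use in production, which changes only Monte Carlo precision);
20 independent worlds for coverage; 200 replicates for the length-validation
power checks. Recovery checks use a homogeneous moderate over-dispersion
(σ = 0.4) world, since surface recovery is the target there rather than
selection between dispersion structures.

## Known limitations

* The spline df is fixed, not selected; there is no penalized smoothness
  estimation and no spatial autocorrelation between stations.
* $\sigma$ comparisons across the binomial boundary rely on the optimizer
  pushing $\log\sigma$ to its lower clamp; the AICc of the beta-binomial on
  truly binomial data is accordingly penalty-dominated, as it should be.
* The length validation's mature-female criterion uses a configurable 21 m
  threshold when maturity is unrecorded; the underlying length-at-maturity
  rule comes from external studies and is deliberately not hard-coded.
* With heavily overlapping populations, threshold assignment at 0.5 mixes
  the groups and attenuates the observable length contrast; the validation
  is decisive only when catches concentrate where one population dominates.
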