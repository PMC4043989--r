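# bluesplit

Splitting conflated North Pacific blue whale catches between the eastern
(ENP) and western (WNP) populations using their distinct song call types.

Historical whaling records (1905–1971) report "blue whales" without
population identity, but the two populations sing different songs, and
hydrophone arrays across the North Pacific record where and when each call
type is heard. `bluesplit` is for quantitative ecologists and stock-assessment
analysts who need population-specific catch series with honest uncertainty:

1. **Acoustic occurrence models.** For each call type, hourly call-presence
   counts per station-month, `k` presence hours of `n` analyzed, are fitted
   with a beta-binomial likelihood (mean `mu`, over-dispersion `sigma`, so
   `Var(k) = n mu (1-mu) (1 + sigma (n-1)/(1+sigma))`; `sigma -> 0` is
   binomial). Both `logit(mu)` and `log(sigma)` carry additive predictors:
   natural cubic splines in longitude and latitude plus a month factor.
   Candidate structures are ranked by AICc.
2. **Prediction model.** The paired fits give a per-catch assignment
   probability `P(ENP) = p_E / (p_E + lambda * p_W)` at the catch's position
   and month, with `lambda` the unknown call-rate-to-density scaling (base
   case 1, sensitivity log-uniform on (0.5, 2)).
3. **Catch imputation.** Catches with uncertain positions/dates (five
   categories, from exact to region-level) get Monte Carlo realizations
   drawn from rectangles, donor catch locations, and donor-derived month
   weights restricted to expedition operating periods.
4. **Ensemble.** Each iteration: new catch realization, bootstrap refit of
   both acoustic models (failed refits discard the whole iteration), a
   `lambda` draw, split, per-year aggregation. Results are per-year
   2.5/50/97.5 percentile tables, an uncertainty decomposition, and a
   length-based validation (WNP whales are longer; assigned groups should
   differ and probability should decline with length).

A synthetic-data module (`world_config()`, `simulate_acoustic()`,
`simulate_catches()`, `simulate_lengths()`) generates all inputs with known
truth, so the whole pipeline is testable end to end without any external data.

## Worked example

```r
library(bluesplit)

w  <- world_config(seed = 7)                       # two-population world, known truth
st <- station_grid(n_lon = 6, n_lat = 5, hours_per_month = 720)
ac <- simulate_acoustic(w, st, rng_seed = 7)       # hourly presence per station-month
ae <- ac[ac$call_type == "east", ]
aw <- ac[ac$call_type == "west", ]

sim <- simulate_catches(w, 400, rng_seed = 8)      # catches + donor pools
cc  <- simulate_lengths(sim$catches, w, rng_seed = 9)

fit_bbgam(ae, model_structure("beta_binomial", "additive", "additive"))
#> beta-binomial additive fit (beta_binomial): mu ~ additive, sigma ~ additive
#>   n_obs = 360, df = 40, loglik = -1324.40, AICc = 2739.09, converged = TRUE

ens <- run_ensemble(cc, sim$donors, ae, aw,
                    model_structure("beta_binomial", "additive", "constant"),
                    N = 100, options = ensemble_options(bootstrap = TRUE),
                    rng_seed = 10)
tail(round(aggregate_percentiles(ens)[, -1]), 3)
#>    enp_lo enp_med enp_hi wnp_lo wnp_med wnp_hi
#> 66      2       2      3      1       2      2
#> 67      5       5      6      4       5      5
#> 68    181     197    210    190     203    219
sum(cc$true_population == "east")
#> [1] 194
```

The last percentile row is the total: the ensemble median of 197 expected
eastern catches (95% interval 181–210) brackets the true count of 194. The
length validation on the same ensemble:

```r
vset <- select_validation_set(cc)   # mature females with recorded lengths
summarize_validation(length_tests(vset, ensemble_prob_matrix(ens, vset$catch_id)))
#> length validation over 100 iterations (0 undefined):
#>   mean length difference (WNP - ENP): 0.33 m (95% range 0.12-0.55)
#>   fraction of iterations with t-test p < 0.001: 0.030
#>   regression slope (probability on length): -0.0698 (95% range -0.0833--0.0535)
#>   fraction with significant negative slope (p < 0.05): 1.000
```

Every iteration finds the expected negative probability-vs-length slope. The
mean difference (0.33 m) is attenuated below the world's true 0.91 m contrast
because this default world has heavy mid-basin overlap, where 0.5-threshold
assignment mixes the groups — see the methods vignette
(`vignettes/catch-splitting-methods.Rmd`) for when the validation is decisive.

`run_pipeline(run_config(...))` drives the same stages from CSV inputs
(acoustic, catches, donors schemas documented in `?read_acoustic`,
`?read_catches`, `?read_donors`) and writes percentile tables, an
uncertainty decomposition, validation results and run metadata.

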