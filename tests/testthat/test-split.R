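# Prediction model, lambda, splitting, ensemble, percentiles, decomposition.

# a pair of cheap converged fits for plumbing tests
make_fit_pair <- function(seed = 61, hours = 400) {
  w <- world_config(seed = seed)
  st <- station_grid(n_lon = 6, n_lat = 5, months_active = 1:12,
                     hours_per_month = hours)
  ac <- simulate_acoustic(w, st, rng_seed = seed)
  s <- model_structure("beta_binomial", "additive", "constant")
  list(east = fit_bbgam(ac[ac$call_type == "east", ], s),
       west = fit_bbgam(ac[ac$call_type == "west", ], s),
       world = w, acoustic = ac, structure = s)
}

test_that("p_enp has the stated boundary and symmetry behaviour", {
  fp <- make_fit_pair()
  # symmetry trivials via hand-built equal/zero predictions: use one fit as
  # both populations so p_E = p_W pointwise
  m_same <- prediction_model(fp$east, fp$east, lam = 1)
  p <- p_enp(m_same, c(170, 200, 240), c(30, 45, 55), c(3, 7, 11))
  expect_equal(p, rep(0.5, 3), tolerance = 1e-12)
  m_lam2 <- prediction_model(fp$east, fp$east, lam = 2)
  expect_equal(p_enp(m_lam2, 200, 45, 7), 1 / 3, tolerance = 1e-12)
  expect_error(prediction_model(fp$east, fp$west, lam = -1), "positive")
  # swap symmetry: p(lam, E, W) = 1 - p(1/lam, W, E), exactly
  m <- prediction_model(fp$east, fp$west, lam = 1.7)
  ms <- prediction_model(fp$west, fp$east, lam = 1 / 1.7)
  g <- expand.grid(lon = seq(155, 250, 15), lat = c(28, 40, 54), month = c(2, 7, 10))
  expect_equal(p_enp(m, g$lon, g$lat, g$month),
               1 - p_enp(ms, g$lon, g$lat, g$month), tolerance = 1e-12)
  expect_true(all(p_enp(m, g$lon, g$lat, g$month) >= 0 &
                    p_enp(m, g$lon, g$lat, g$month) <= 1))
})

test_that("lambda draws: fixed value, log-uniform support and geometric median", {
  expect_equal(draw_lambda(lambda_fixed(1)), 1)
  expect_equal(draw_lambda(lambda_fixed(0.25)), 0.25)
  set.seed(1)
  draws <- replicate(10000, draw_lambda(lambda_loguniform(0.5, 2)))
  expect_true(all(draws >= 0.5 & draws <= 2))
  expect_gt(median(draws), 0.97)  # geometric midpoint sqrt(0.5 * 2) = 1
  expect_lt(median(draws), 1.03)
  expect_error(lambda_loguniform(2, 0.5), "lo < hi")
  expect_error(lambda_fixed(0), "positive")
})

test_that("split conserves totals and does expected-mode arithmetic", {
  fp <- make_fit_pair()
  cc <- data.frame(catch_id = c("a", "b"), year = c(1950L, 1950L))
  real <- data.frame(catch_id = c("a", "b"), lon_east = c(200, 200),
                     lat = c(45, 45), month = c(7L, 7L), realization_seed = 1L)
  # two catches with p = 0.25 and 0.75 -> ENP 1.0, WNP 1.0: construct by
  # stubbing the probabilities through lambda choices on the same-fit model
  m_same <- prediction_model(fp$east, fp$east, lam = 3)   # p = 0.25
  s1 <- split_realization(cc, real, m_same)
  expect_equal(s1$by_year$enp, 0.5, tolerance = 1e-12)
  m_same2 <- prediction_model(fp$east, fp$east, lam = 1 / 3)  # p = 0.75
  s2 <- split_realization(cc, real, m_same2)
  expect_equal(s2$by_year$enp, 1.5, tolerance = 1e-12)
  # one catch at p = 0.25 plus one at p = 0.75 average to one expected ENP
  expect_equal((s1$by_year$enp + s2$by_year$enp) / 2, 1.0, tolerance = 1e-12)
  expect_equal(s1$by_year$enp + s1$by_year$wnp, s1$by_year$total)

  # conservation on a real synthetic split, both modes
  w <- fp$world
  sim <- simulate_catches(w, 300, rng_seed = 66)
  real2 <- draw_realization(sim$catches, sim$donors, rng_seed = 67)
  m <- prediction_model(fp$east, fp$west, 1)
  se <- split_realization(sim$catches, real2, m, "expected")
  expect_true(all(abs(se$by_year$enp + se$by_year$wnp - se$by_year$total) < 1e-9))
  sb <- split_realization(sim$catches, real2, m, "bernoulli", rng_seed = 5)
  expect_true(all(sb$by_year$enp + sb$by_year$wnp == sb$by_year$total))
  expect_true(all(sb$by_year$enp == round(sb$by_year$enp)))
})

test_that("bernoulli totals concentrate around the expected split", {
  fp <- make_fit_pair()
  n <- 10000
  cc <- data.frame(catch_id = as.character(1:n), year = rep(1950L, n))
  real <- data.frame(catch_id = as.character(1:n), lon_east = 200, lat = 45,
                     month = 7L, realization_seed = 1L)
  m <- prediction_model(fp$east, fp$east, lam = (1 - 0.35) / 0.35)  # p = 0.35
  sb <- split_realization(cc, real, m, "bernoulli", rng_seed = 11)
  expect_lt(abs(sb$by_year$enp - 3500), 3 * sqrt(n * 0.35 * 0.65))
})

test_that("ensemble returns exactly N series, counts attempts, redraws failures", {
  w <- world_config(seed = 70)
  st <- station_grid(n_lon = 5, n_lat = 5, months_active = 4:11,
                     hours_per_month = 300)
  ac <- simulate_acoustic(w, st, rng_seed = 70)
  ae <- ac[ac$call_type == "east", ]; aw <- ac[ac$call_type == "west", ]
  sim <- simulate_catches(w, 80, rng_seed = 71)
  s <- model_structure("beta_binomial", "constant", "constant")
  # inject a deterministic 10% failure: attempts divisible by 10 fail
  ens <- run_ensemble(sim$catches, sim$donors, ae, aw, s, N = 100,
                      options = ensemble_options(
                        bootstrap = TRUE,
                        inject_failure = function(a) a %% 10 == 0),
                      rng_seed = 72)
  expect_equal(length(ens$series), 100)
  expect_gte(ens$attempts, 100)
  # geometric trials: attempts/successes ~ 1/0.9
  expect_lt(abs(ens$attempts / 100 - 1 / 0.9), 0.08)
  expect_gte(ens$failures_east, ens$attempts - 100)
})

test_that("without bootstrap and with certain catches the ensemble is degenerate", {
  w <- world_config(seed = 75)
  st <- station_grid(n_lon = 5, n_lat = 5, months_active = 4:11,
                     hours_per_month = 300)
  ac <- simulate_acoustic(w, st, rng_seed = 75)
  sim <- simulate_catches(w, 60, category_mix = c(0, 0, 0, 0, 1), rng_seed = 76)
  s <- model_structure("beta_binomial", "constant", "constant")
  ens <- run_ensemble(sim$catches, sim$donors,
                      ac[ac$call_type == "east", ], ac[ac$call_type == "west", ],
                      s, N = 10,
                      options = ensemble_options(bootstrap = FALSE),
                      rng_seed = 77)
  totals <- vapply(ens$series, function(x) sum(x$by_year$enp), numeric(1))
  expect_equal(max(totals) - min(totals), 0)
  # percentile table of identical series has equal lo/med/hi
  pt <- aggregate_percentiles(ens)
  expect_equal(pt$enp_lo, pt$enp_hi)
  # N = 1: the percentile table equals the single series
  ens1 <- run_ensemble(sim$catches, sim$donors,
                       ac[ac$call_type == "east", ], ac[ac$call_type == "west", ],
                       s, N = 1,
                       options = ensemble_options(bootstrap = FALSE),
                       rng_seed = 78)
  pt1 <- aggregate_percentiles(ens1)
  yr <- ens1$series[[1]]$by_year
  expect_equal(pt1$enp_med[seq_len(nrow(yr))], yr$enp)
})

test_that("ensemble aborts when the failure rate exceeds 50% over 100 attempts", {
  w <- world_config(seed = 80)
  st <- station_grid(n_lon = 5, n_lat = 5, months_active = 7,
                     hours_per_month = 200)
  ac <- simulate_acoustic(w, st, rng_seed = 80)
  sim <- simulate_catches(w, 20, rng_seed = 81)
  s <- model_structure("beta_binomial", "constant", "constant")
  expect_error(suppressWarnings(
    run_ensemble(sim$catches, sim$donors,
                 ac[ac$call_type == "east", ], ac[ac$call_type == "west", ],
                 s, N = 200,
                 options = ensemble_options(bootstrap = TRUE,
                                            inject_failure = function(a) a %% 3 != 0),
                 rng_seed = 82)),
    "aborting")
})

test_that("total ENP is non-increasing in lambda", {
  fp <- make_fit_pair()
  sim <- simulate_catches(fp$world, 200, rng_seed = 90)
  real <- draw_realization(sim$catches, sim$donors, rng_seed = 91)
  tot <- vapply(c(0.5, 1, 2), function(l) {
    m <- prediction_model(fp$east, fp$west, l)
    sum(split_realization(sim$catches, real, m)$by_year$enp)
  }, numeric(1))
  expect_true(all(diff(tot) < 0))
})

test_that("percentile aggregation matches normal-theory quantiles and ordering", {
  # synthetic ensemble built directly: 1000 single-year series with normal totals
  set.seed(123)
  vals <- rnorm(1000, 3439, 300)
  series <- lapply(vals, function(v)
    structure(list(by_year = data.frame(year = 1950L, total = 5000,
                                        enp = v, wnp = 5000 - v)),
              class = "split_series"))
  ens <- structure(list(series = series, attempts = 1000L,
                        failures_east = 0L, failures_west = 0L,
                        options = ensemble_options(), seed = 1L),
                   class = "bb_ensemble")
  pt <- aggregate_percentiles(ens)
  tot_row <- pt[pt$year == "Total", ]
  expect_lt(abs(tot_row$enp_lo - qnorm(0.025, 3439, 300)), 40)
  expect_lt(abs(tot_row$enp_hi - qnorm(0.975, 3439, 300)), 40)
  expect_true(all(pt$enp_lo <= pt$enp_med & pt$enp_med <= pt$enp_hi))
  expect_true(all(pt$wnp_lo <= pt$wnp_med & pt$wnp_med <= pt$wnp_hi))
})

test_that("uncertainty decomposition reproduces the printed-bounds arithmetic", {
  pct <- uncertainty_decomposition(c(3430, 3470), c(2855, 3920), c(2593, 4114))
  expect_identical(unname(pct), c(3L, 70L, 100L))
  expect_identical(unname(uncertainty_decomposition(c(1, 2), c(1, 2), c(1, 2))),
                   c(100L, 100L, 100L))
  expect_identical(unname(uncertainty_decomposition(c(5, 5), c(4, 6), c(3, 7))),
                   c(0L, 50L, 100L))
  expect_error(uncertainty_decomposition(c(1, 1), c(1, 1), c(1, 1)),
               "positive width")
  expect_error(uncertainty_decomposition(c(2, 1), c(1, 2), c(1, 2)), "hi >= lo")
})
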