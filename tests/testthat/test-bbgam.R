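# Beta-binomial likelihood, design matrices, fitting, selection, prediction.

test_that("bb_logpmf matches hand cases: Bernoulli, binomial limit, quadrature", {
  # n = 1 beta-binomial is Bernoulli(mu) for any sigma
  expect_equal(bb_logpmf(1, 1, 0.3, 0.7), log(0.3), tolerance = 1e-12)
  expect_equal(bb_logpmf(0, 1, 0.3, 2.5), log(0.7), tolerance = 1e-12)
  # sigma -> 0 binomial limit: C(5,2) 0.4^2 0.6^3 = 0.3456
  expect_equal(bb_logpmf(2, 5, 0.4, 1e-10), log(0.3456), tolerance = 1e-6)
  # quadrature oracle at a genuinely over-dispersed point
  expect_equal(bb_logpmf(3, 10, 0.25, 0.5),
               log(bb_pmf_quadrature(3, 10, 0.25, 0.5)), tolerance = 1e-8)
})

test_that("bb_logpmf matches the quadrature oracle on a parameter grid", {
  set.seed(42)
  cases <- expand.grid(n = c(3, 10, 30), mu = c(0.05, 0.3, 0.7, 0.95),
                       sigma = c(0.01, 0.2, 0.8, 2))
  for (i in seq_len(nrow(cases))) {
    n <- cases$n[i]; mu <- cases$mu[i]; sg <- cases$sigma[i]
    k <- sample(0:n, 1)
    expect_equal(bb_logpmf(k, n, mu, sg),
                 log(bb_pmf_quadrature(k, n, mu, sg)),
                 tolerance = 1e-8,
                 label = sprintf("logpmf(k=%d, n=%d, mu=%g, sigma=%g)", k, n, mu, sg))
  }
})

test_that("bb pmf normalizes and has the stated mean and variance", {
  for (mu in c(0.05, 0.5, 0.95)) {
    for (sg in c(0.01, 0.5, 2)) {
      for (n in c(5, 50)) {
        p <- exp(bb_logpmf(0:n, n, mu, sg))
        expect_lt(abs(sum(p) - 1), 1e-10)
        m1 <- sum((0:n) * p)
        v <- sum((0:n)^2 * p) - m1^2
        expect_equal(m1, n * mu, tolerance = 1e-8)
        expect_equal(v, n * mu * (1 - mu) * (1 + sg * (n - 1) / (1 + sg)),
                     tolerance = 1e-6)
      }
    }
  }
})

test_that("bb_logpmf rejects out-of-domain arguments", {
  expect_error(bb_logpmf(6, 5, 0.3, 0.5), "0 <= k <= n")
  expect_error(bb_logpmf(-1, 5, 0.3, 0.5), "0 <= k <= n")
  expect_error(bb_logpmf(2, 5, 1.2, 0.5), "mu")
  expect_error(bb_logpmf(2, 5, 0.3, -0.1), "sigma")
})

test_that("aicc closed form, AIC limit, and domain error", {
  expect_equal(aicc(-100, 5, 30), 212.5)
  expect_equal(aicc(0, 1, 10), 2.5)
  expect_equal(aicc(-100, 5, 1e9), 210, tolerance = 1e-6)
  expect_error(aicc(-100, 5, 6), "n_obs")
})

test_that("design matrix column counts match the structure accounting", {
  dat <- make_acoustic(seed = 3, n_lon = 6, n_lat = 5, hours = 50)
  dat <- dat[dat$call_type == "east", ]
  # (family, mu, sigma) -> total df; additive param = 1 + 4 + 4 + 11 = 20,
  # linear = 14, constant = 1
  expected <- c(40L, 34L, 21L, 28L, 20L, 14L)
  cands <- candidate_structures(spline_df = 4)
  got <- vapply(cands, function(s) build_design(dat, s)$df_total, integer(1))
  expect_identical(got, expected)
})

test_that("design build errors when a covariate has too few distinct values", {
  dat <- make_acoustic(seed = 3, n_lon = 6, n_lat = 5, hours = 50)
  dat <- dat[dat$call_type == "east", ]
  dat$lat <- 40  # single value
  expect_error(build_design(dat, model_structure("beta_binomial", "additive", "constant")),
               "lat")
})

test_that("intercept-only fit recovers mu and sigma on a constant world", {
  w <- flat_world(mu = 0.2, sigma = 0.3)
  st <- station_grid(n_lon = 5, n_lat = 5, months_active = 1:4,
                     hours_per_month = 720)
  hits_mu <- 0; hits_sg <- 0; n_seeds <- 12
  s <- model_structure("beta_binomial", "constant", "constant")
  for (sd_ in seq_len(n_seeds)) {
    ac <- simulate_acoustic(w, st, rng_seed = sd_)
    dat <- ac[ac$call_type == "east", ]  # 100 station-months
    f <- fit_bbgam(dat, s)
    expect_true(f$converged)
    mu_hat <- plogis(f$beta_mu[1]); sg_hat <- exp(f$beta_sigma[1])
    if (abs(mu_hat - 0.2) < 0.03) hits_mu <- hits_mu + 1
    if (abs(sg_hat - 0.3) < 0.15) hits_sg <- hits_sg + 1
  }
  expect_gte(hits_mu, round(0.9 * n_seeds))
  expect_gte(hits_sg, round(0.9 * n_seeds))
})

test_that("all-absence data is flagged rather than erroring", {
  dat <- data.frame(lon_east = rep(seq(160, 240, 20), 3),
                    lat = rep(c(30, 40, 50), each = 5),
                    month = rep(1:3, 5), n_hours = 100L, k_hours = 0L)
  f <- suppressWarnings(
    fit_bbgam(dat, model_structure("beta_binomial", "constant", "constant")))
  expect_false(f$converged)
})

test_that("fit rejects empty or mixed-call-type data", {
  dat <- make_acoustic(seed = 5, n_lon = 6, n_lat = 5, hours = 50)
  s <- model_structure("beta_binomial", "constant", "constant")
  expect_error(fit_bbgam(dat[0, ], s), "empty")
  expect_error(fit_bbgam(dat, s), "call type")
})

test_that("richer nested structures attain at least the nested log-likelihood", {
  dat <- make_acoustic(seed = 11, n_lon = 6, n_lat = 5, hours = 300)
  dat <- dat[dat$call_type == "east", ]
  f_const <- fit_bbgam(dat, model_structure("beta_binomial", "additive", "constant"))
  f_lin <- fit_bbgam(dat, model_structure("beta_binomial", "additive", "linear"))
  f_add <- fit_bbgam(dat, model_structure("beta_binomial", "additive", "additive"))
  expect_gte(f_lin$loglik, f_const$loglik - 1e-4)
  expect_gte(f_add$loglik, f_lin$loglik - 1e-4)
  # binomial additive nested in beta-binomial additive/anything
  f_bin <- fit_bbgam(dat, model_structure("binomial", "additive"))
  expect_gte(f_add$loglik, f_bin$loglik - 1e-4)
})

test_that("fitted surface recovers a monotone longitude trend", {
  w <- world_config(seed = 2)
  ac <- make_acoustic(seed = 2, world = w)
  dat <- ac[ac$call_type == "east", ]  # eastern calls increase with longitude
  f <- fit_bbgam(dat, model_structure("beta_binomial", "additive", "constant"))
  expect_true(f$converged)
  expect_gt(predict_mu(f, 240, 40, 7), predict_mu(f, 160, 40, 7))
})

test_that("predict_mu is consistent in-sample and validates months", {
  dat <- make_acoustic(seed = 7, n_lon = 6, n_lat = 5, hours = 300)
  dat <- dat[dat$call_type == "east", ]
  f <- fit_bbgam(dat, model_structure("beta_binomial", "additive", "constant"))
  p <- predict_mu(f, dat$lon_east, dat$lat, dat$month)
  expect_true(all(p > 0 & p < 1))
  expect_error(predict_mu(f, 200, 40, 13), "month")
  # intercept-only fit with beta = 0 predicts 0.5 everywhere
  f0 <- f
  f0$structure <- model_structure("beta_binomial", "constant", "constant")
  f0$beta_mu <- 0; f0$basis_mu <- list(type = "constant")
  expect_equal(predict_mu(f0, c(150, 250), c(25, 55), c(1, 12)),
               c(0.5, 0.5), ignore_attr = TRUE)
})

test_that("prediction warns for months absent from training", {
  dat <- make_acoustic(seed = 9, n_lon = 6, n_lat = 5, hours = 300,
                       months = 4:11)
  dat <- dat[dat$call_type == "east", ]
  f <- fit_bbgam(dat, model_structure("beta_binomial", "additive", "constant"))
  expect_warning(predict_mu(f, 200, 40, 1), "absent")
})

test_that("model selection ranks converged candidates by AICc", {
  dat <- make_acoustic(seed = 13)
  dat <- dat[dat$call_type == "east", ]
  sel <- select_model(dat)
  expect_equal(nrow(sel), 6)
  conv <- sel[sel$converged, ]
  expect_true(!is.unsorted(conv$aicc))
  expect_equal(conv$delta_aicc[1], 0)
  # single candidate: delta is 0
  sel1 <- select_model(dat, list(model_structure("beta_binomial", "linear", "linear")))
  expect_equal(sel1$delta_aicc, 0)
})

test_that("binomial-truth data shows no large AICc gap for the beta-binomial", {
  w <- flat_world(mu = 0.25, sigma = 0)
  w$surface_east <- function(lon, lat, month)
    plogis(-1 + 0.5 * (lon - 200) / 40 + 0.3 * (lat - 40) / 15)
  w$dispersion <- function(lon, lat, month) rep(0, length(lon))
  st <- station_grid(n_lon = 6, n_lat = 5, hours_per_month = 300)
  ac <- simulate_acoustic(w, st, rng_seed = 21)
  dat <- ac[ac$call_type == "east", ]
  f_bin <- fit_bbgam(dat, model_structure("binomial", "additive"))
  f_bb <- fit_bbgam(dat, model_structure("beta_binomial", "additive", "additive"))
  # at sigma = 0 the beta-binomial gains no fit, only its extra 20 df of
  # penalty (plus small-sample correction): the gap stays modest
  expect_lt(f_bb$aicc - f_bin$aicc, 60)
  expect_gt(f_bb$aicc - f_bin$aicc, -10)
})

test_that("bootstrap resamples contain ~63.2% unique rows on average", {
  n <- 150
  uniq <- vapply(1:1000, function(s) length(unique(bootstrap_indices(n, s))) / n,
                 numeric(1))
  # P(row included) = 1 - (1 - 1/n)^n ~ 0.632
  expect_lt(abs(mean(uniq) - (1 - (1 - 1 / n)^n)), 0.01)
})

test_that("bootstrap refits vary around the base fit and flag degenerate input", {
  w <- flat_world(mu = 0.3, sigma = 0.4)
  st <- station_grid(n_lon = 5, n_lat = 5, months_active = 1:3,
                     hours_per_month = 400)
  ac <- simulate_acoustic(w, st, rng_seed = 31)
  dat <- ac[ac$call_type == "east", ]
  s <- model_structure("beta_binomial", "constant", "constant")
  mus <- vapply(1:100, function(i) {
    bf <- bootstrap_refit(dat, s, rng_seed = i)
    plogis(bf$beta_mu[1])
  }, numeric(1))
  ci <- quantile(mus, c(0.025, 0.975))
  expect_true(ci[1] <= 0.3 && 0.3 <= ci[2])  # truth inside the bootstrap interval
  expect_gt(sd(mus), 0)
  # a 1-row table resamples to itself; the fit is degenerate and flagged
  one <- dat[1, , drop = FALSE]
  one$k_hours <- 0L
  bf1 <- suppressWarnings(bootstrap_refit(one, s, rng_seed = 1))
  expect_false(bf1$converged)
})

test_that("fit JSON round-trips and reproduces predictions", {
  dat <- make_acoustic(seed = 17, n_lon = 6, n_lat = 5, hours = 300)
  dat <- dat[dat$call_type == "west", ]
  f <- fit_bbgam(dat, model_structure("beta_binomial", "additive", "constant"))
  path <- tempfile(fileext = ".json")
  write_fit_json(f, path)
  f2 <- read_fit_json(path)
  g <- expand.grid(lon = c(170, 210, 245), lat = c(30, 50), month = c(2, 8))
  expect_equal(predict_mu(f2, g$lon, g$lat, g$month),
               predict_mu(f, g$lon, g$lat, g$month), tolerance = 1e-12)
})
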