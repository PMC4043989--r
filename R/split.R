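# Splitting the conflated catch series between the two populations.
#
# The per-catch assignment probability is P(ENP) = p_E / (p_E + lambda * p_W),
# where p_E and p_W are the fitted hourly call probabilities of the eastern
# and western models at the catch's (realized) position and month, and lambda
# is the unknown scaling between the call-probability ratio and the density
# ratio (base case lambda = 1; sensitivity draws lambda log-uniform).
# The ensemble algorithm repeats: (1) draw a catch realization, (2) bootstrap
# the acoustic data, (3) refit both models (iteration redrawn whole if either
# refit fails to converge), (4) predict and split, (5) aggregate by year;
# then summarizes per-year percentiles over the successful iterations.

#' Pair the two population fits into a prediction model
#'
#' @param fit_east,fit_west Converged [fit_bbgam()] results for the eastern
#'   and western call types.
#' @param lam Positive scaling factor `lambda` applied to the western call
#'   probability (`lambda = c_W / c_E`); base case 1.
#' @return An object of class `prediction_model`.
#' @export
prediction_model <- function(fit_east, fit_west, lam = 1) {
  stopifnot(inherits(fit_east, "bb_fit"), inherits(fit_west, "bb_fit"))
  if (!isTRUE(fit_east$converged) || !isTRUE(fit_west$converged))
    stop("both fits must have converged", call. = FALSE)
  if (!is.finite(lam) || lam <= 0) stop("lam must be positive", call. = FALSE)
  structure(list(fit_east = fit_east, fit_west = fit_west, lam = lam),
            class = "prediction_model")
}

#' Probability a catch belongs to the eastern population
#'
#' `p_E / (p_E + lam * p_W)` evaluated at the given positions and months.
#' When both predicted call probabilities are numerically zero the ratio is
#' undefined and 0.5 is returned with a warning.
#'
#' @param model A [prediction_model()].
#' @param lon_east,lat,month Coordinates (vectorized); `month` in 1..12.
#' @return Probabilities in \[0, 1\].
#' @export
p_enp <- function(model, lon_east, lat, month) {
  stopifnot(inherits(model, "prediction_model"))
  pe <- as.numeric(predict_mu(model$fit_east, lon_east, lat, month))
  pw <- as.numeric(predict_mu(model$fit_west, lon_east, lat, month))
  den <- pe + model$lam * pw
  und <- den < 1e-300
  if (any(und)) {
    warning("both call probabilities numerically zero; returning 0.5")
    den[und] <- 1
    pe[und] <- 0.5
  }
  pe / den
}

#' Lambda specification helpers
#'
#' `lambda_fixed(value)` always returns `value`; `lambda_loguniform(lo, hi)`
#' draws `exp(Uniform(log lo, log hi))` - one draw per ensemble iteration,
#' constant across all catches within it.
#'
#' @param value,lo,hi Positive reals with `lo < hi`.
#' @return A lambda mode specification list.
#' @export
lambda_fixed <- function(value = 1) {
  if (!is.finite(value) || value <= 0) stop("lambda must be positive", call. = FALSE)
  list(mode = "fixed", value = value)
}

#' @rdname lambda_fixed
#' @export
lambda_loguniform <- function(lo = 0.5, hi = 2) {
  if (!is.finite(lo) || !is.finite(hi) || lo <= 0 || hi <= lo)
    stop("need 0 < lo < hi", call. = FALSE)
  list(mode = "loguniform", lo = lo, hi = hi)
}

#' Draw one lambda value
#'
#' @param mode A specification from [lambda_fixed()] or [lambda_loguniform()].
#' @param rng_seed Optional integer seed.
#' @return A positive scalar.
#' @export
draw_lambda <- function(mode, rng_seed = NULL) {
  if (!is.list(mode) || is.null(mode$mode))
    stop("mode must come from lambda_fixed() or lambda_loguniform()", call. = FALSE)
  if (mode$mode == "fixed") return(mode$value)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  exp(stats::runif(1, log(mode$lo), log(mode$hi)))
}

#' Split one catch realization into ENP and WNP series
#'
#' Computes the per-catch assignment probability at each realized position
#' and aggregates by year. In `expected` mode the yearly ENP count is the sum
#' of probabilities (and WNP its complement against the conflated count, so
#' conservation holds exactly); in `bernoulli` mode population labels are
#' drawn per catch.
#'
#' @param catches Catch records (provides `year` per `catch_id`).
#' @param realization A [draw_realization()] result covering all catches.
#' @param model A [prediction_model()].
#' @param assignment `"expected"` or `"bernoulli"`.
#' @param rng_seed Seed for `bernoulli` label draws.
#' @return An object of class `split_series`: `by_year` (year, total, enp,
#'   wnp), `probs` (catch_id, year, p_enp), `meta`.
#' @export
split_realization <- function(catches, realization, model,
                              assignment = c("expected", "bernoulli"),
                              rng_seed = NULL) {
  assignment <- match.arg(assignment)
  m <- match(catches$catch_id, realization$catch_id)
  if (anyNA(m))
    stop("realization does not cover all catches", call. = FALSE)
  lon <- realization$lon_east[m]; lat <- realization$lat[m]
  mon <- realization$month[m]
  if (anyNA(mon)) stop("realization has missing months", call. = FALSE)
  p <- p_enp(model, lon, lat, mon)

  yr <- catches$year
  years <- sort(unique(yr))
  total <- as.numeric(tapply(rep(1, length(yr)), factor(yr, levels = years), sum))
  if (assignment == "expected") {
    enp <- as.numeric(tapply(p, factor(yr, levels = years), sum))
  } else {
    if (!is.null(rng_seed)) set.seed(rng_seed)
    lab <- stats::rbinom(length(p), 1, p)
    enp <- as.numeric(tapply(lab, factor(yr, levels = years), sum))
  }
  enp[is.na(enp)] <- 0
  by_year <- data.frame(year = years, total = total, enp = enp,
                        wnp = total - enp)
  structure(list(
    by_year = by_year,
    probs = data.frame(catch_id = catches$catch_id, year = yr, p_enp = p),
    meta = list(assignment = assignment, lam = model$lam,
                realization_seed = realization$realization_seed[1])
  ), class = "split_series")
}

#' Ensemble options
#'
#' @param bootstrap Refit both acoustic models to a bootstrap resample each
#'   iteration (`FALSE` estimates catch uncertainty only).
#' @param lam Lambda mode ([lambda_fixed()] or [lambda_loguniform()]).
#' @param assignment `"expected"` or `"bernoulli"` per-catch assignment.
#' @param inject_failure Testing hook: `function(attempt) logical`, forcing a
#'   convergence failure on selected attempts.
#' @return An options list.
#' @export
ensemble_options <- function(bootstrap = TRUE, lam = lambda_fixed(1),
                             assignment = c("expected", "bernoulli"),
                             inject_failure = NULL) {
  list(bootstrap = isTRUE(bootstrap), lam = lam,
       assignment = match.arg(assignment), inject_failure = inject_failure)
}

.attempt_seed <- function(rng_seed, attempt) {
  as.integer((as.numeric(rng_seed) + as.numeric(attempt) * 1000003) %% 2147480000)
}

#' Run the catch-splitting ensemble
#'
#' Repeats until `N` successful iterations: draw a catch realization; if
#' `bootstrap`, refit both population models to a bootstrap resample of their
#' acoustic data (warm-started from the base fits) and discard the whole
#' iteration - redrawing the realization too - if either refit fails to
#' converge; draw lambda; split; aggregate by year. Aborts if more than half
#' of a rolling 100-attempt window fails.
#'
#' @param catches,donors Catch records and donor pool.
#' @param acoustic_east,acoustic_west Acoustic observations per call type.
#' @param structure A [model_structure()] used for all fits.
#' @param N Number of successful iterations required.
#' @param options An [ensemble_options()] list.
#' @param rng_seed Integer seed governing all randomness.
#' @param control A [bb_control()] for the base fits.
#' @return An object of class `bb_ensemble`: `series` (list of `N`
#'   [split_realization()] results), `attempts`, `failures_east`,
#'   `failures_west`, `lambdas`, `base_east`, `base_west`, `options`, `seed`.
#' @export
run_ensemble <- function(catches, donors, acoustic_east, acoustic_west,
                         structure, N, options = ensemble_options(),
                         rng_seed = 1L, control = bb_control()) {
  if (N < 1) stop("N must be >= 1", call. = FALSE)
  base_e <- fit_bbgam(acoustic_east, structure, control)
  base_w <- fit_bbgam(acoustic_west, structure, control)
  if (!base_e$converged || !base_w$converged)
    stop("base acoustic fit(s) failed to converge", call. = FALSE)
  warm <- bb_control(maxit = control$maxit, gtol = control$gtol, n_starts = 1L)

  series <- vector("list", N)
  lambdas <- numeric(N)
  attempts <- 0L; got <- 0L
  failures_east <- 0L; failures_west <- 0L
  window <- logical(0)

  while (got < N) {
    attempts <- attempts + 1L
    s0 <- .attempt_seed(rng_seed, attempts)
    failed <- FALSE

    if (options$bootstrap) {
      forced <- !is.null(options$inject_failure) &&
        isTRUE(options$inject_failure(attempts))
      warm_e <- warm; warm_e$start <- c(base_e$beta_mu, base_e$beta_sigma)
      warm_w <- warm; warm_w$start <- c(base_w$beta_mu, base_w$beta_sigma)
      fe <- bootstrap_refit(acoustic_east, structure, s0 + 2L, warm_e)
      fw <- bootstrap_refit(acoustic_west, structure, s0 + 3L, warm_w)
      if (forced || !fe$converged) { failures_east <- failures_east + 1L; failed <- TRUE }
      if (!fw$converged) { failures_west <- failures_west + 1L; failed <- TRUE }
    } else {
      fe <- base_e; fw <- base_w
    }

    if (!failed) {
      realization <- draw_realization(catches, donors, s0)
      lam <- draw_lambda(options$lam, rng_seed = s0 + 1L)
      model <- prediction_model(fe, fw, lam)
      got <- got + 1L
      ss <- split_realization(catches, realization, model,
                              assignment = options$assignment,
                              rng_seed = s0 + 4L)
      ss$meta$attempt <- attempts
      series[[got]] <- ss
      lambdas[got] <- lam
    }

    window <- c(window, failed)
    if (length(window) > 100) window <- window[-1]
    if (length(window) == 100 && mean(window) > 0.5)
      stop(sprintf(
        "aborting: %d of the last 100 ensemble attempts failed to converge",
        sum(window)), call. = FALSE)
  }

  structure(list(series = series, attempts = attempts,
                 failures_east = failures_east, failures_west = failures_west,
                 lambdas = lambdas, base_east = base_e, base_west = base_w,
                 options = options, seed = as.integer(rng_seed)),
            class = "bb_ensemble")
}

#' @export
print.bb_ensemble <- function(x, ...) {
  cat(sprintf(
    "catch-splitting ensemble: %d successful iterations in %d attempts\n",
    length(x$series), x$attempts))
  cat(sprintf("  refit failures: east %d (%.2f%%), west %d (%.2f%%); bootstrap = %s\n",
              x$failures_east, 100 * x$failures_east / x$attempts,
              x$failures_west, 100 * x$failures_west / x$attempts,
              x$options$bootstrap))
  invisible(x)
}

#' Per-year percentile summary of an ensemble
#'
#' 2.5/50/97.5 percentiles (linear interpolation between order statistics)
#' of the yearly ENP and WNP counts over the ensemble iterations, plus a
#' `Total` row computed by percentiling the per-iteration totals (not by
#' summing the per-year percentiles).
#'
#' @param ensemble A [run_ensemble()] result.
#' @return A data frame of class `percentile_table` with columns `year`
#'   (character, last row `"Total"`), `enp_lo`, `enp_med`, `enp_hi`,
#'   `wnp_lo`, `wnp_med`, `wnp_hi` (unrounded).
#' @export
aggregate_percentiles <- function(ensemble) {
  stopifnot(inherits(ensemble, "bb_ensemble"))
  if (length(ensemble$series) == 0) stop("empty ensemble", call. = FALSE)
  years <- ensemble$series[[1]]$by_year$year
  E <- vapply(ensemble$series, function(s) s$by_year$enp, numeric(length(years)))
  W <- vapply(ensemble$series, function(s) s$by_year$wnp, numeric(length(years)))
  if (length(years) == 1) { E <- matrix(E, 1); W <- matrix(W, 1) }
  q3 <- function(x) stats::quantile(x, c(0.025, 0.5, 0.975), type = 7, names = FALSE)
  qe <- t(apply(E, 1, q3)); qw <- t(apply(W, 1, q3))
  te <- q3(colSums(E)); tw <- q3(colSums(W))
  out <- data.frame(year = c(as.character(years), "Total"),
                    enp_lo = c(qe[, 1], te[1]), enp_med = c(qe[, 2], te[2]),
                    enp_hi = c(qe[, 3], te[3]),
                    wnp_lo = c(qw[, 1], tw[1]), wnp_med = c(qw[, 2], tw[2]),
                    wnp_hi = c(qw[, 3], tw[3]))
  class(out) <- c("percentile_table", "data.frame")
  out
}

#' Cumulative uncertainty decomposition
#'
#' Expresses the widths of nested total-catch intervals - catch uncertainty
#' only, catch + statistical (bootstrap), and catch + statistical +
#' ecological (lambda) - as percentages of the full-interval width, rounded
#' to the nearest integer. The final entry is 100 by construction.
#'
#' @param interval_catch,interval_catch_stat,interval_full Numeric `(lo, hi)`
#'   pairs.
#' @return Named integer percentages `(catch, catch_statistical,
#'   catch_statistical_ecological)`.
#' @export
uncertainty_decomposition <- function(interval_catch, interval_catch_stat,
                                      interval_full) {
  ints <- list(catch = interval_catch, catch_statistical = interval_catch_stat,
               catch_statistical_ecological = interval_full)
  for (nm in names(ints)) {
    v <- ints[[nm]]
    if (length(v) != 2 || v[2] < v[1])
      stop("interval '", nm, "' must be (lo, hi) with hi >= lo", call. = FALSE)
  }
  fw <- interval_full[2] - interval_full[1]
  if (fw <= 0) stop("full interval must have positive width", call. = FALSE)
  vapply(ints, function(v) as.integer(round(100 * (v[2] - v[1]) / fw)),
         integer(1))
}

#' Total-catch interval of an ensemble
#'
#' Convenience accessor: the (2.5%, 97.5%) interval and median of the
#' per-iteration total ENP counts.
#'
#' @param ensemble A [run_ensemble()] result.
#' @return Named vector `c(lo, med, hi)`.
#' @export
ensemble_total_interval <- function(ensemble) {
  tot <- vapply(ensemble$series, function(s) sum(s$by_year$enp), numeric(1))
  q <- stats::quantile(tot, c(0.025, 0.5, 0.975), type = 7, names = FALSE)
  c(lo = q[1], med = q[2], hi = q[3])
}
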