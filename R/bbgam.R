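# Beta-binomial additive occurrence models for hourly call-presence data.
#
# The acoustic datum is (k, n): of n analyzed hours at a hydrophone station in
# a month, k contained at least one song call of a given type. Consecutive
# hours are temporally correlated (a singing whale is audible for hours), so
# the counts are over-dispersed relative to a binomial; the likelihood is a
# beta-binomial with mean parameter mu (probability of hearing >= 1 call in an
# hour) and over-dispersion sigma, with additive predictors allowed on both.

# sigma below this is treated as exactly binomial; the beta-binomial form
# loses precision to lgamma cancellation for a = mu/sigma beyond ~1e8.
.bb_sigma_eps <- 1e-8

#' Beta-binomial log probability mass
#'
#' Log-density of the beta-binomial distribution parameterized by its mean
#' `mu` and over-dispersion `sigma`, i.e. shape parameters `a = mu/sigma`,
#' `b = (1-mu)/sigma`. The variance is `n*mu*(1-mu)*(1 + sigma*(n-1)/(1+sigma))`,
#' so `sigma = 0` recovers the binomial model exactly (and is computed as such).
#'
#' @param k Number of presence hours, `0 <= k <= n`.
#' @param n Number of analyzed hours.
#' @param mu Mean hourly presence probability, in (0, 1).
#' @param sigma Over-dispersion, `>= 0`.
#' @return Log probability mass, vectorized over arguments.
#' @examples
#' bb_logpmf(3, 10, 0.25, 0.5)
#' bb_logpmf(2, 5, 0.4, 0)          # dbinom(2, 5, 0.4, log = TRUE)
#' @export
bb_logpmf <- function(k, n, mu, sigma) {
  m <- max(length(k), length(n), length(mu), length(sigma))
  k <- rep_len(as.numeric(k), m)
  n <- rep_len(as.numeric(n), m)
  mu <- rep_len(as.numeric(mu), m)
  sigma <- rep_len(as.numeric(sigma), m)
  if (any(!is.finite(k)) || any(k < 0 | k > n))
    stop("k must satisfy 0 <= k <= n", call. = FALSE)
  if (any(mu <= 0 | mu >= 1)) stop("mu must lie in (0, 1)", call. = FALSE)
  if (any(sigma < 0)) stop("sigma must be >= 0", call. = FALSE)
  out <- numeric(m)
  bin <- sigma < .bb_sigma_eps
  if (any(bin))
    out[bin] <- stats::dbinom(k[bin], n[bin], mu[bin], log = TRUE)
  if (any(!bin)) {
    a <- mu[!bin] / sigma[!bin]
    b <- (1 - mu[!bin]) / sigma[!bin]
    out[!bin] <- lchoose(n[!bin], k[!bin]) +
      lbeta(k[!bin] + a, n[!bin] - k[!bin] + b) - lbeta(a, b)
  }
  out
}

#' Candidate model structure
#'
#' Describes one candidate occurrence model: the likelihood family and the
#' predictor structure on the mean (`mu_terms`) and, for the beta-binomial,
#' on the over-dispersion (`sigma_terms`). `additive` means intercept +
#' natural cubic spline bases (`spline_df` columns each) in longitude and
#' latitude + 11 month contrasts (January reference); `linear` replaces the
#' splines with plain linear terms; `constant` is intercept only.
#'
#' @param family `"beta_binomial"` or `"binomial"`.
#' @param mu_terms `"additive"`, `"linear"` or `"constant"`.
#' @param sigma_terms `"additive"`, `"linear"`, `"constant"`, or `"none"`
#'   (required, and implied, for the binomial family).
#' @param spline_df Degrees of freedom per spatial smoother (columns per
#'   spline basis), at least 3. Default 4.
#' @param month_as_factor Months enter as a 12-level factor (the only
#'   supported mode; kept for structure bookkeeping).
#' @return An object of class `bb_structure`.
#' @export
model_structure <- function(family = c("beta_binomial", "binomial"),
                            mu_terms = c("additive", "linear", "constant"),
                            sigma_terms = c("additive", "linear", "constant", "none"),
                            spline_df = 4L,
                            month_as_factor = TRUE) {
  family <- match.arg(family)
  mu_terms <- match.arg(mu_terms)
  sigma_given <- !missing(sigma_terms)
  sigma_terms <- match.arg(sigma_terms)
  if (family == "binomial") {
    if (sigma_given && sigma_terms != "none")
      stop("binomial family implies sigma_terms = 'none'", call. = FALSE)
    sigma_terms <- "none"
  } else if (sigma_terms == "none") {
    stop("beta_binomial family requires sigma_terms other than 'none'",
         call. = FALSE)
  }
  if (!is.numeric(spline_df) || spline_df < 3)
    stop("spline_df must be >= 3", call. = FALSE)
  if (!isTRUE(month_as_factor))
    stop("months must enter as a 12-level factor", call. = FALSE)
  structure(list(family = family, mu_terms = mu_terms,
                 sigma_terms = sigma_terms, spline_df = as.integer(spline_df),
                 month_as_factor = TRUE),
            class = "bb_structure")
}

#' @export
print.bb_structure <- function(x, ...) {
  cat(sprintf("model structure: %s, mu ~ %s, sigma ~ %s (spline_df = %d)\n",
              x$family, x$mu_terms, x$sigma_terms, x$spline_df))
  invisible(x)
}

#' The standard six-candidate set
#'
#' The candidate structures routinely compared by AICc: beta-binomial with
#' additive/additive, additive/linear, additive/constant and linear/linear
#' terms on (mu, sigma), plus binomial models with additive and linear mean
#' terms. With `spline_df = 4` their total coefficient counts are
#' 40, 34, 21, 28, 20 and 14.
#'
#' @param spline_df Degrees of freedom per spatial smoother.
#' @return A list of [model_structure()] objects.
#' @export
candidate_structures <- function(spline_df = 4L) {
  list(
    model_structure("beta_binomial", "additive", "additive", spline_df),
    model_structure("beta_binomial", "additive", "linear", spline_df),
    model_structure("beta_binomial", "additive", "constant", spline_df),
    model_structure("beta_binomial", "linear", "linear", spline_df),
    model_structure("binomial", "additive", "none", spline_df),
    model_structure("binomial", "linear", "none", spline_df)
  )
}

# ---- design matrices --------------------------------------------------------

.month_contrasts <- function(month) {
  X <- vapply(2:12, function(m) as.numeric(month == m), numeric(length(month)))
  if (is.null(dim(X))) X <- matrix(X, nrow = length(month))
  colnames(X) <- paste0("month", 2:12)
  X
}

.spline_def <- function(x, df, name) {
  if (length(unique(x)) < df + 1)
    stop(sprintf("covariate '%s' has %d distinct values; spline_df = %d needs at least %d",
                 name, length(unique(x)), df, df + 1), call. = FALSE)
  B <- splines::ns(x, df = df)
  list(knots = as.numeric(attr(B, "knots")),
       boundary = as.numeric(attr(B, "Boundary.knots")))
}

.spline_eval <- function(x, def) {
  unclass(splines::ns(x, knots = def$knots, Boundary.knots = def$boundary))
}

# Build (or, given a stored basis, re-evaluate) the design matrix for one
# distribution parameter.
.param_design <- function(data, terms, spline_df, basis = NULL) {
  nr <- nrow(data)
  if (terms == "constant") {
    X <- matrix(1, nr, 1, dimnames = list(NULL, "(Intercept)"))
    return(list(X = X, basis = list(type = "constant")))
  }
  if (terms == "linear") {
    if (is.null(basis)) {
      basis <- list(type = "linear",
                    lon_center = mean(data$lon_east), lon_scale = max(stats::sd(data$lon_east), 1e-8),
                    lat_center = mean(data$lat), lat_scale = max(stats::sd(data$lat), 1e-8))
    }
    X <- cbind(1,
               (data$lon_east - basis$lon_center) / basis$lon_scale,
               (data$lat - basis$lat_center) / basis$lat_scale,
               .month_contrasts(data$month))
    colnames(X)[1:3] <- c("(Intercept)", "lon", "lat")
    return(list(X = X, basis = basis))
  }
  # additive
  if (is.null(basis)) {
    basis <- list(type = "additive",
                  lon = .spline_def(data$lon_east, spline_df, "lon_east"),
                  lat = .spline_def(data$lat, spline_df, "lat"))
  }
  Blon <- .spline_eval(data$lon_east, basis$lon)
  Blat <- .spline_eval(data$lat, basis$lat)
  colnames(Blon) <- paste0("s(lon).", seq_len(ncol(Blon)))
  colnames(Blat) <- paste0("s(lat).", seq_len(ncol(Blat)))
  X <- cbind("(Intercept)" = 1, Blon, Blat, .month_contrasts(data$month))
  list(X = X, basis = basis)
}

#' Build design matrices for both distribution parameters
#'
#' @param data A data frame of acoustic observations with columns `lon_east`
#'   (degrees east in \[0, 360)), `lat`, `month` (1-12), `n_hours`, `k_hours`.
#' @param structure A [model_structure()].
#' @return A list with elements `mu` and `sigma` (each `list(X, basis)`;
#'   `sigma` is `NULL` for the binomial family) and the column counts
#'   `df_mu`, `df_sigma`, `df_total`.
#' @export
build_design <- function(data, structure) {
  stopifnot(inherits(structure, "bb_structure"))
  .check_acoustic(data)
  mu <- .param_design(data, structure$mu_terms, structure$spline_df)
  sg <- NULL
  if (structure$sigma_terms != "none")
    sg <- .param_design(data, structure$sigma_terms, structure$spline_df)
  list(mu = mu, sigma = sg,
       df_mu = ncol(mu$X),
       df_sigma = if (is.null(sg)) 0L else ncol(sg$X),
       df_total = ncol(mu$X) + if (is.null(sg)) 0L else ncol(sg$X))
}

.check_acoustic <- function(data) {
  need <- c("lon_east", "lat", "month", "n_hours", "k_hours")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("acoustic data lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(data) == 0) stop("acoustic data is empty", call. = FALSE)
  if (any(!data$month %in% 1:12)) stop("month must be in 1..12", call. = FALSE)
  if (any(data$k_hours < 0 | data$k_hours > data$n_hours))
    stop("k_hours must satisfy 0 <= k <= n_hours", call. = FALSE)
  invisible(TRUE)
}

# ---- likelihood and fitting -------------------------------------------------

#' Small-sample corrected Akaike information criterion
#'
#' `-2*loglik + 2*df + 2*df*(df+1)/(n_obs - df - 1)`.
#'
#' @param loglik Maximized log-likelihood.
#' @param df Number of estimated coefficients.
#' @param n_obs Number of observations; must exceed `df + 1`.
#' @return The AICc value.
#' @export
aicc <- function(loglik, df, n_obs) {
  if (n_obs <= df + 1)
    stop("AICc undefined: n_obs must exceed df + 1", call. = FALSE)
  -2 * loglik + 2 * df + 2 * df * (df + 1) / (n_obs - df - 1)
}

#' Optimization control for [fit_bbgam()]
#'
#' @param maxit Maximum BFGS iterations per start.
#' @param gtol Convergence criterion: the infinity norm of the negative
#'   log-likelihood gradient at the optimum must be below
#'   `gtol * max(1, |nll|)`.
#' @param start Optional warm-start coefficient vector
#'   `c(beta_mu, beta_sigma)`; used as the first start when supplied.
#' @param n_starts Number of starts (1-3): the empirical-logit start plus up
#'   to two deterministic offset starts.
#' @return A list of class `bb_control`.
#' @export
bb_control <- function(maxit = 500L, gtol = 1e-5, start = NULL, n_starts = 3L) {
  structure(list(maxit = as.integer(maxit), gtol = gtol, start = start,
                 n_starts = max(1L, min(3L, as.integer(n_starts)))),
            class = "bb_control")
}

# negative log-likelihood and analytic gradient closures
.bb_objective <- function(k, n, Xmu, Xsig) {
  p1 <- ncol(Xmu)
  bb <- !is.null(Xsig)
  parts <- function(theta) {
    eta1 <- pmin(pmax(drop(Xmu %*% theta[seq_len(p1)]), -30), 30)
    mu <- stats::plogis(eta1)
    if (bb) {
      eta2 <- pmin(pmax(drop(Xsig %*% theta[-seq_len(p1)]), -20), 10)
      sig <- exp(eta2)
    } else sig <- NULL
    list(mu = mu, sig = sig)
  }
  nll <- function(theta) {
    p <- parts(theta)
    ll <- if (bb) {
      a <- p$mu / p$sig; b <- (1 - p$mu) / p$sig
      lchoose(n, k) + lbeta(k + a, n - k + b) - lbeta(a, b)
    } else stats::dbinom(k, n, p$mu, log = TRUE)
    v <- -sum(ll)
    if (!is.finite(v)) v <- 1e10
    v
  }
  gr <- function(theta) {
    p <- parts(theta)
    mu <- p$mu
    if (!bb) {
      # canonical logit link: d(-ll)/d(eta) = n*mu - k
      return(drop(crossprod(Xmu, n * mu - k)))
    }
    sig <- p$sig
    a <- mu / sig; b <- (1 - mu) / sig
    dla <- digamma(k + a) - digamma(n + a + b) - digamma(a) + digamma(a + b)
    dlb <- digamma(n - k + b) - digamma(n + a + b) - digamma(b) + digamma(a + b)
    g1 <- crossprod(Xmu, -(dla - dlb) / sig * mu * (1 - mu))
    g2 <- crossprod(Xsig, a * dla + b * dlb)
    c(drop(g1), drop(g2))
  }
  list(nll = nll, gr = gr, p1 = p1, bb = bb)
}

#' Fit a beta-binomial (or binomial) additive occurrence model
#'
#' Maximizes the summed [bb_logpmf()] over the joint coefficient vector with
#' `mu = plogis(X_mu beta_mu)` and `sigma = exp(X_sigma beta_sigma)` using
#' BFGS with analytic gradients and multiple deterministic starts. Failure to
#' meet the gradient criterion is reported through the `converged` flag,
#' never as an error: downstream bootstrap ensembles discard and redraw
#' non-converged refits.
#'
#' @param data Acoustic observations for a single call type: columns
#'   `lon_east`, `lat`, `month`, `n_hours`, `k_hours` (and optionally
#'   `call_type`, which must then be constant).
#' @param structure A [model_structure()].
#' @param control A [bb_control()].
#' @return An object of class `bb_fit`: coefficients on the link scales,
#'   basis definitions, `loglik`, `df`, `aicc`, `converged`, `n_obs`.
#' @export
fit_bbgam <- function(data, structure, control = bb_control()) {
  stopifnot(inherits(structure, "bb_structure"))
  .check_acoustic(data)
  if ("call_type" %in% names(data) && length(unique(data$call_type)) > 1)
    stop("data mixes call types; fit one population model at a time",
         call. = FALSE)
  if (sum(data$n_hours) <= 0) stop("total n_hours must be positive", call. = FALSE)

  des <- build_design(data, structure)
  Xmu <- des$mu$X
  Xsig <- if (is.null(des$sigma)) NULL else des$sigma$X
  k <- as.numeric(data$k_hours); n <- as.numeric(data$n_hours)
  obj <- .bb_objective(k, n, Xmu, Xsig)
  p1 <- ncol(Xmu); p2 <- if (is.null(Xsig)) 0L else ncol(Xsig)

  mu0 <- stats::qlogis((sum(k) + 0.5) / (sum(n) + 1))
  base_start <- numeric(p1 + p2)
  base_start[1] <- mu0
  if (p2 > 0) base_start[p1 + 1] <- log(0.1)
  starts <- list(base_start)
  s2 <- base_start; s2[1] <- mu0 + 0.5; if (p2 > 0) s2[p1 + 1] <- log(0.3)
  s3 <- base_start; s3[1] <- mu0 - 0.5; if (p2 > 0) s3[p1 + 1] <- log(0.05)
  starts <- c(starts, list(s2, s3))[seq_len(control$n_starts)]
  if (!is.null(control$start)) {
    if (length(control$start) != p1 + p2)
      stop("control$start has wrong length", call. = FALSE)
    starts <- c(list(control$start), starts)
  }

  best <- NULL
  for (s in starts) {
    opt <- tryCatch(
      stats::optim(s, obj$nll, obj$gr, method = "BFGS",
                   control = list(maxit = control$maxit, reltol = 1e-12)),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best))
    stop("optimizer failed from every start", call. = FALSE)

  theta <- best$par
  g <- obj$gr(theta)
  converged <- best$convergence == 0 &&
    max(abs(g)) < control$gtol * max(1, abs(best$value))

  beta_mu <- theta[seq_len(p1)]
  beta_sigma <- if (p2 > 0) theta[p1 + seq_len(p2)] else numeric(0)
  mu_hat <- stats::plogis(pmin(pmax(drop(Xmu %*% beta_mu), -30), 30))
  if (max(mu_hat) < 1e-4 || min(mu_hat) > 1 - 1e-4) {
    warning("fitted mean surface is at the boundary (all-presence or all-absence data); flagging non-convergence")
    converged <- FALSE
  }

  loglik <- -best$value
  df <- p1 + p2
  n_obs <- nrow(data)
  aicc_val <- if (n_obs > df + 1) aicc(loglik, df, n_obs) else NA_real_
  if (is.na(aicc_val))
    warning("AICc undefined for n_obs <= df + 1; stored as NA")

  structure(list(
    structure = structure,
    beta_mu = beta_mu, beta_sigma = beta_sigma,
    basis_mu = des$mu$basis,
    basis_sigma = if (is.null(des$sigma)) NULL else des$sigma$basis,
    months_seen = sort(unique(data$month)),
    lon_range = range(data$lon_east), lat_range = range(data$lat),
    call_type = if ("call_type" %in% names(data)) data$call_type[1] else NA_character_,
    loglik = loglik, df = df, aicc = aicc_val,
    converged = converged, n_obs = n_obs
  ), class = "bb_fit")
}

#' @export
print.bb_fit <- function(x, ...) {
  cat(sprintf("beta-binomial additive fit (%s): mu ~ %s, sigma ~ %s\n",
              x$structure$family, x$structure$mu_terms, x$structure$sigma_terms))
  cat(sprintf("  n_obs = %d, df = %d, loglik = %.2f, AICc = %.2f, converged = %s\n",
              x$n_obs, x$df, x$loglik, x$aicc, x$converged))
  invisible(x)
}

#' Predict the hourly call probability surface
#'
#' Evaluates the fitted mean `mu` at new positions and months. Spline bases
#' extrapolate linearly beyond the boundary knots (natural cubic splines);
#' positions outside the training range are flagged in the `"extrapolated"`
#' attribute. Months never seen in training predict through the January
#' reference plus a zero contrast, with a warning.
#'
#' @param fit A converged [fit_bbgam()] result.
#' @param lon_east,lat,month Prediction coordinates (recycled to a common
#'   length); `month` must be in 1..12.
#' @return A numeric vector of probabilities in (0, 1).
#' @export
predict_mu <- function(fit, lon_east, lat, month) {
  stopifnot(inherits(fit, "bb_fit"))
  m <- max(length(lon_east), length(lat), length(month))
  lon_east <- rep_len(lon_east, m); lat <- rep_len(lat, m)
  month <- rep_len(as.integer(month), m)
  if (any(!month %in% 1:12)) stop("month must be in 1..12", call. = FALSE)
  unseen <- setdiff(unique(month), fit$months_seen)
  if (length(unseen))
    warning("predicting for months absent from training data (",
            paste(unseen, collapse = ", "),
            "); using reference-month level")
  nd <- data.frame(lon_east = lon_east, lat = lat, month = month)
  X <- .param_design(nd, fit$structure$mu_terms, fit$structure$spline_df,
                     basis = fit$basis_mu)$X
  eta <- pmin(pmax(drop(X %*% fit$beta_mu), -30), 30)
  p <- stats::plogis(eta)
  attr(p, "extrapolated") <- lon_east < fit$lon_range[1] | lon_east > fit$lon_range[2] |
    lat < fit$lat_range[1] | lat > fit$lat_range[2]
  p
}

#' Predict the over-dispersion surface
#'
#' @inheritParams predict_mu
#' @return Fitted `sigma` values (`0` for a binomial-family fit).
#' @export
predict_sigma <- function(fit, lon_east, lat, month) {
  stopifnot(inherits(fit, "bb_fit"))
  m <- max(length(lon_east), length(lat), length(month))
  if (fit$structure$sigma_terms == "none") return(rep(0, m))
  lon_east <- rep_len(lon_east, m); lat <- rep_len(lat, m)
  month <- rep_len(as.integer(month), m)
  if (any(!month %in% 1:12)) stop("month must be in 1..12", call. = FALSE)
  nd <- data.frame(lon_east = lon_east, lat = lat, month = month)
  X <- .param_design(nd, fit$structure$sigma_terms, fit$structure$spline_df,
                     basis = fit$basis_sigma)$X
  exp(pmin(pmax(drop(X %*% fit$beta_sigma), -20), 10))
}

#' Rank candidate structures by AICc
#'
#' Fits every candidate and returns them ranked by AICc (ascending), with
#' `delta_aicc` relative to the best converged fit. Candidates that fail to
#' converge (or error) are listed last and excluded from the reference AICc.
#'
#' @param data Acoustic observations for one call type.
#' @param candidates A list of [model_structure()] objects (default the
#'   standard six).
#' @param control A [bb_control()].
#' @return A data frame (one row per candidate, ranked) with an attribute
#'   `"fits"` holding the fit objects in the same order.
#' @export
select_model <- function(data, candidates = candidate_structures(),
                         control = bb_control()) {
  if (length(candidates) < 1) stop("need at least one candidate", call. = FALSE)
  fits <- lapply(candidates, function(s)
    tryCatch(fit_bbgam(data, s, control), error = function(e) NULL))
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) stop("all candidate fits failed", call. = FALSE)
  tab <- data.frame(
    family = vapply(candidates, function(s) s$family, character(1)),
    mu_terms = vapply(candidates, function(s) s$mu_terms, character(1)),
    sigma_terms = vapply(candidates, function(s) s$sigma_terms, character(1)),
    df = vapply(seq_along(fits), function(i) if (ok[i]) fits[[i]]$df else NA_integer_, integer(1)),
    loglik = vapply(seq_along(fits), function(i) if (ok[i]) fits[[i]]$loglik else NA_real_, numeric(1)),
    aicc = vapply(seq_along(fits), function(i) if (ok[i]) fits[[i]]$aicc else NA_real_, numeric(1)),
    converged = vapply(seq_along(fits), function(i) isTRUE(ok[i] && fits[[i]]$converged), logical(1))
  )
  ref <- suppressWarnings(min(tab$aicc[tab$converged], na.rm = TRUE))
  if (!is.finite(ref)) ref <- suppressWarnings(min(tab$aicc, na.rm = TRUE))
  tab$delta_aicc <- tab$aicc - ref
  ord <- order(!tab$converged, tab$aicc)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "fits") <- fits[ord]
  tab
}

#' Bootstrap resampling indices
#'
#' Row indices for one nonparametric bootstrap resample (station-month rows
#' drawn with replacement to the original row count).
#'
#' @param n Number of rows.
#' @param rng_seed Integer seed.
#' @return An integer vector of length `n`.
#' @export
bootstrap_indices <- function(n, rng_seed) {
  set.seed(rng_seed)
  sample.int(n, n, replace = TRUE)
}

#' Refit a model to a bootstrap resample of the acoustic data
#'
#' Resamples station-month rows with replacement and refits; non-convergence
#' is propagated through the `converged` flag.
#'
#' @inheritParams fit_bbgam
#' @param rng_seed Integer seed for the resample.
#' @return A `bb_fit`.
#' @export
bootstrap_refit <- function(data, structure, rng_seed, control = bb_control()) {
  idx <- bootstrap_indices(nrow(data), rng_seed)
  suppressWarnings(fit_bbgam(data[idx, , drop = FALSE], structure, control))
}

# ---- serialization ----------------------------------------------------------

#' Serialize a fit to JSON
#'
#' @param fit A `bb_fit`.
#' @param path Output file path.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "bb_fit"))
  obj <- list(
    structure = unclass(fit$structure),
    beta_mu = fit$beta_mu, beta_sigma = fit$beta_sigma,
    basis_mu = fit$basis_mu, basis_sigma = fit$basis_sigma,
    months_seen = fit$months_seen,
    lon_range = fit$lon_range, lat_range = fit$lat_range,
    call_type = fit$call_type,
    loglik = fit$loglik, df = fit$df, aicc = fit$aicc,
    converged = fit$converged, n_obs = fit$n_obs)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a fit serialized with [write_fit_json()]
#'
#' @param path JSON file path.
#' @return A `bb_fit`.
#' @export
read_fit_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$structure <- structure(obj$structure, class = "bb_structure")
  obj$beta_mu <- as.numeric(obj$beta_mu)
  obj$beta_sigma <- as.numeric(obj$beta_sigma)
  structure(obj, class = "bb_fit")
}
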