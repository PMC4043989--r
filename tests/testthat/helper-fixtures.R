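# Shared fixtures, built in code at test time.

# moderate-size acoustic dataset from the default synthetic world
make_acoustic <- function(seed = 1, n_lon = 6, n_lat = 5, hours = 720,
                          months = 1:12, world = world_config(seed = seed)) {
  st <- station_grid(n_lon = n_lon, n_lat = n_lat, months_active = months,
                     hours_per_month = hours)
  simulate_acoustic(world, st, rng_seed = seed)
}

# a tiny constant-surface world (flat mu, flat sigma) for calibration tests
flat_world <- function(mu = 0.2, sigma = 0.3) {
  world_config(
    surface_east = function(lon, lat, month) rep(mu, length(lon)),
    surface_west = function(lon, lat, month) rep(mu, length(lon)),
    dispersion = function(lon, lat, month) rep(sigma, length(lon)))
}

# quadrature oracle for the beta-binomial pmf: E_p[Binomial(k; n, p)] with
# p ~ Beta(mu/sigma, (1-mu)/sigma), integrated in probability space
# (u = F_Beta(p), so the integrand is bounded even for shape parameters < 1)
bb_pmf_quadrature <- function(k, n, mu, sigma) {
  a <- mu / sigma
  b <- (1 - mu) / sigma
  # two complementary quadratures: probability space (split at the binomial
  # spike; good unless the beta density is endpoint-singular) and beta-CDF
  # space u = F(p) (bounded integrand; good for small shape parameters).
  # Accept the first that converges; tolerances stay far below the 1e-8
  # comparison threshold.
  fp <- function(p) stats::dbinom(k, n, p) * stats::dbeta(p, a, b)
  fu <- function(u) stats::dbinom(k, n, stats::qbeta(u, a, b))
  mid <- min(max(k / n, 1e-6), 1 - 1e-6)
  for (tol in c(1e-12, 1e-11, 1e-10)) {
    v <- tryCatch(
      stats::integrate(fp, 0, mid, rel.tol = tol, abs.tol = 0,
                       subdivisions = 2000L)$value +
        stats::integrate(fp, mid, 1, rel.tol = tol, abs.tol = 0,
                         subdivisions = 2000L)$value,
      error = function(e) NULL)
    if (!is.null(v) && is.finite(v) && v > 0) return(v)
    v <- tryCatch(stats::integrate(fu, 0, 1, rel.tol = tol, abs.tol = 0,
                                   subdivisions = 2000L)$value,
                  error = function(e) NULL)
    if (!is.null(v) && is.finite(v) && v > 0) return(v)
  }
  stop("quadrature failed for k=", k, ", n=", n, ", mu=", mu, ", sigma=", sigma)
}

# hand-built catch table with explicit categories for imputation tests
make_catch_table <- function() {
  data.frame(
    catch_id = c("A1", "A2", "A3", "A4", "A5"),
    year = c(1950L, 1950L, 1951L, 1960L, 1960L),
    month = c(6L, NA, NA, 7L, NA),
    lon_east = c(210, NA, NA, NA, 190),
    lat = c(45, NA, NA, NA, 50),
    category = c("certain", "iwc_region", "partial", "soviet", "inferred"),
    region_id = c("R3", "R2", "R2", "R2", "R2"),
    rect_lat_min = c(NA, NA, NA, 50, NA),
    rect_lat_max = c(NA, NA, NA, 52, NA),
    rect_lon_min = c(NA, NA, NA, 170, NA),
    rect_lon_max = c(NA, NA, NA, 175, NA),
    expedition_id = c("E1", "E2", "E3", "E4", "E5"),
    op_month_start = c(4L, 5L, NA, 4L, 4L),
    op_month_end = c(11L, 10L, NA, 11L, 11L),
    sex = c("F", "M", "F", "F", "M"),
    length_m = c(22.5, NA, 21.7, 23.1, NA),
    maturity = c("mature", "unknown", "mature", "unknown", "immature"))
}

make_donor_table <- function() {
  data.frame(
    species = c("blue", "fin", "sei", "minke", "blue", "fin"),
    lon_east = c(185, 195, 200, 188, 192, 205),
    lat = c(48, 50, 52, 47, 49, 51),
    month = c(5L, 6L, 7L, 6L, 8L, 6L),
    year = c(1950L, 1950L, 1951L, 1951L, 1960L, 1951L),
    expedition_id = c("E2", "E2", "E3", "E3", "E4", "E3"),
    region_id = c("R2", "R2", "R2", "R2", "R2", "R3"))
}
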