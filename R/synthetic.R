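# Synthetic worlds with known truth.
#
# The generator emulates the structure of the real analysis inputs: two blue
# whale populations (an eastern and a western North Pacific population) with
# smooth spatial/monthly occurrence surfaces, hydrophone stations recording
# over-dispersed hourly call presence, whaling catches placed by an effort
# surface that overlaps both populations (with true population labels drawn
# from the local density ratio), the five location-uncertainty categories
# with their constraint payloads, donor-location pools for imputation, and
# population-specific length distributions.

.default_month_offsets <- c(-1.2, -1.0, -0.6, -0.2, 0.3, 0.7, 1.0, 1.0,
                            0.8, 0.4, -0.3, -0.9)

#' Configure a synthetic world
#'
#' Occurrence surfaces are logistic-quadratic in scaled (longitude, latitude)
#' plus 12 additive month offsets; the over-dispersion field is log-quadratic
#' in longitude. Each surface parameter list has elements `b0`, `b_lon`,
#' `b_lat`, `b_lon2`, `b_lat2` and `month_off` (length 12); coordinates are
#' centered at (200E, 40N) and scaled by (40, 15) degrees. A surface may
#' instead be a function `(lon_east, lat, month) -> mu` for full control.
#'
#' @param surface_east,surface_west Occurrence surface parameter lists (or
#'   functions) for the eastern and western population call types. Defaults
#'   put the eastern population in the eastern North Pacific and vice versa,
#'   both peaking in summer, overlapping mid-basin.
#' @param dispersion Over-dispersion field: a list with `c0`, `c_lon`,
#'   `c_lon2`, `c_lat`, `c_lat2` (log scale, quadratic in the same scaled
#'   coordinates), or a function `(lon_east, lat, month) -> sigma`. The
#'   default varies smoothly from about 0.4 mid-basin to several units at
#'   the margins, emulating strong spatial structure in the temporal
#'   correlation of singing.
#' @param length_mean_east,length_mean_west Mean total length (m) by true
#'   population. Western whales are longer by default (22.91 vs 22.0 m).
#' @param length_sd Length standard deviation (m), common to both populations.
#' @param seed Integer seed recorded with the world.
#' @return An object of class `world_config`.
#' @export
world_config <- function(
    surface_east = list(b0 = -1.5, b_lon = 1.4, b_lat = 0.2,
                        b_lon2 = -0.3, b_lat2 = -0.5,
                        month_off = .default_month_offsets),
    surface_west = list(b0 = -1.5, b_lon = -1.4, b_lat = 0.3,
                        b_lon2 = -0.3, b_lat2 = -0.5,
                        month_off = .default_month_offsets),
    dispersion = list(c0 = log(0.4), c_lon = 0, c_lon2 = 0.9,
                      c_lat = 0, c_lat2 = 0.9),
    length_mean_east = 22.0,
    length_mean_west = 22.91,
    length_sd = 1.0,
    seed = 1L) {
  if (length_sd < 0) stop("length_sd must be positive", call. = FALSE)
  w <- structure(list(surface_east = surface_east, surface_west = surface_west,
                      dispersion = dispersion,
                      length_mean_east = length_mean_east,
                      length_mean_west = length_mean_west,
                      length_sd = length_sd, seed = as.integer(seed)),
                 class = "world_config")
  w
}

.zlon <- function(lon) (lon - 200) / 40
.zlat <- function(lat) (lat - 40) / 15

#' Evaluate a world's true call-probability surface
#'
#' @param world A [world_config()].
#' @param population `"east"` or `"west"`.
#' @param lon_east,lat,month Coordinates (vectorized).
#' @return True hourly call probabilities `mu` in (0, 1).
#' @export
true_mu <- function(world, population = c("east", "west"), lon_east, lat, month) {
  population <- match.arg(population)
  s <- if (population == "east") world$surface_east else world$surface_west
  if (is.function(s)) return(s(lon_east, lat, month))
  z <- .zlon(lon_east); w <- .zlat(lat)
  stats::plogis(s$b0 + s$b_lon * z + s$b_lat * w +
                  s$b_lon2 * z^2 + s$b_lat2 * w^2 + s$month_off[month])
}

#' Evaluate a world's true over-dispersion field
#'
#' @inheritParams true_mu
#' @return True `sigma` values (> 0, or 0 for an exactly binomial world).
#' @export
true_sigma <- function(world, lon_east, lat, month) {
  d <- world$dispersion
  if (is.function(d)) return(d(lon_east, lat, month))
  z <- .zlon(lon_east)
  w <- .zlat(lat)
  cl <- if (is.null(d$c_lat)) 0 else d$c_lat
  cl2 <- if (is.null(d$c_lat2)) 0 else d$c_lat2
  exp(d$c0 + d$c_lon * z + d$c_lon2 * z^2 + cl * w + cl2 * w^2)
}

#' Lay out a grid of hydrophone stations
#'
#' @param n_lon,n_lat Grid dimensions.
#' @param lon_range,lat_range Extent in degrees east / degrees north.
#' @param months_active Months each station records (default all year).
#' @param hours_per_month Analyzed hours per station-month.
#' @return A data frame of station specifications with a `months_active`
#'   list column.
#' @export
station_grid <- function(n_lon = 8, n_lat = 4,
                         lon_range = c(150, 250), lat_range = c(25, 57),
                         months_active = 1:12, hours_per_month = 720L) {
  g <- expand.grid(lon_east = seq(lon_range[1], lon_range[2], length.out = n_lon),
                   lat = seq(lat_range[1], lat_range[2], length.out = n_lat))
  data.frame(station_id = sprintf("S%02d", seq_len(nrow(g))),
             lon_east = g$lon_east, lat = g$lat,
             hours_per_month = as.integer(hours_per_month),
             months_active = I(rep(list(as.integer(months_active)), nrow(g))))
}

#' Simulate acoustic presence data
#'
#' One row per station x active month x call type. Presence-hour counts are
#' beta-binomial: `p ~ Beta(mu/sigma, (1-mu)/sigma)`, `k ~ Binomial(n, p)`,
#' with `mu` from the population surface and `sigma` from the dispersion
#' field (`sigma = 0` gives exact binomial sampling).
#'
#' @param world A [world_config()].
#' @param stations A station data frame from [station_grid()] (or of the
#'   same shape); every station must have a non-empty `months_active`.
#' @param rng_seed Integer seed.
#' @return A data frame of acoustic observations (`station_id`, `lon_east`,
#'   `lat`, `month`, `n_hours`, `k_hours`, `call_type`).
#' @export
simulate_acoustic <- function(world, stations, rng_seed = world$seed) {
  if (nrow(stations) == 0) stop("stations must be non-empty", call. = FALSE)
  ma <- stations$months_active
  if (is.null(ma)) ma <- rep(list(1:12), nrow(stations))
  n_months <- vapply(ma, length, integer(1))
  if (any(n_months == 0))
    stop("station(s) with empty months_active: ",
         paste(stations$station_id[n_months == 0], collapse = ", "),
         call. = FALSE)
  if (any(stations$hours_per_month < 1))
    stop("hours_per_month must be >= 1", call. = FALSE)

  idx <- rep(seq_len(nrow(stations)), n_months)
  month <- unlist(ma)
  base <- data.frame(station_id = stations$station_id[idx],
                     lon_east = stations$lon_east[idx],
                     lat = stations$lat[idx],
                     month = month,
                     n_hours = stations$hours_per_month[idx])
  out <- rbind(cbind(base, call_type = "east"),
               cbind(base, call_type = "west"))
  mu <- ifelse(out$call_type == "east",
               true_mu(world, "east", out$lon_east, out$lat, out$month),
               true_mu(world, "west", out$lon_east, out$lat, out$month))
  sigma <- true_sigma(world, out$lon_east, out$lat, out$month)
  bad <- !is.finite(mu) | mu <= 0 | mu >= 1 | !is.finite(sigma) | sigma < 0
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf(
      "invalid surface value at (lon = %.2f, lat = %.2f, month = %d): mu = %g, sigma = %g",
      out$lon_east[i], out$lat[i], out$month[i], mu[i], sigma[i]), call. = FALSE)
  }
  set.seed(rng_seed)
  p <- ifelse(sigma < .bb_sigma_eps, mu,
              stats::rbeta(nrow(out), mu / pmax(sigma, .bb_sigma_eps),
                           (1 - mu) / pmax(sigma, .bb_sigma_eps)))
  out$k_hours <- stats::rbinom(nrow(out), out$n_hours, p)
  rownames(out) <- NULL
  out
}

# large management-style rectangles partitioning the simulated basin
.regions <- data.frame(
  region_id = c("R1", "R2", "R3", "R4"),
  lon_min = c(140, 180, 210, 235),
  lon_max = c(180, 210, 235, 260),
  lat_min = 20, lat_max = 60)

.region_of <- function(lon_east) {
  .regions$region_id[findInterval(lon_east, c(.regions$lon_min, 260),
                                  rightmost.closed = TRUE)]
}

.empty_catches <- function() {
  data.frame(catch_id = character(0), year = integer(0), month = integer(0),
             lon_east = numeric(0), lat = numeric(0), category = character(0),
             region_id = character(0), rect_lat_min = numeric(0),
             rect_lat_max = numeric(0), rect_lon_min = numeric(0),
             rect_lon_max = numeric(0), expedition_id = character(0),
             op_month_start = integer(0), op_month_end = integer(0),
             sex = character(0), length_m = numeric(0), maturity = character(0),
             true_population = character(0), true_lon_east = numeric(0),
             true_lat = numeric(0), true_month = integer(0))
}

#' Simulate catches with known true population labels
#'
#' Catches are placed by an effort surface (the sum of the two occurrence
#' surfaces plus a flat background term), months drawn from the whaling
#' season (April-November) weighted by total occurrence, and true population
#' labels drawn Bernoulli from the local density ratio
#' `mu_east / (mu_east + mu_west)`. Each catch is then degraded to one of the
#' five location-uncertainty categories with a consistent constraint payload,
#' and a donor table is generated that contains every constrained catch's
#' true location (so imputation can recover the truth in expectation):
#'
#' * `certain`: exact position and month retained;
#' * `inferred`: exact position retained (supplied without uncertainty),
#'   month missing;
#' * `soviet`: position replaced by an enclosing rectangle; month known for
#'   about half the records;
#' * `iwc_region`: position replaced by a region id; month missing;
#' * `partial`: position missing but same-expedition-year donor locations
#'   exist; month known for about half the records.
#'
#' @param world A [world_config()].
#' @param n_catches Number of catches.
#' @param category_mix Proportions for (iwc_region, partial, inferred,
#'   soviet, certain); must sum to 1. The default mirrors the observed shares
#'   of the five categories in the historical record (41/9/5/2/43 percent).
#' @param years Candidate catch years.
#' @param rng_seed Integer seed.
#' @return A list with `catches` (observed fields possibly `NA`, plus
#'   `true_population`, `true_lon_east`, `true_lat`, `true_month`) and
#'   `donors` (`species`, `lon_east`, `lat`, `month`, `year`,
#'   `expedition_id`, `region_id`).
#' @export
simulate_catches <- function(world, n_catches,
                             category_mix = c(iwc_region = 0.41, partial = 0.09,
                                              inferred = 0.05, soviet = 0.02,
                                              certain = 0.43),
                             years = 1905:1971,
                             rng_seed = world$seed) {
  if (abs(sum(category_mix) - 1) > 1e-9)
    stop("category_mix must sum to 1", call. = FALSE)
  if (any(category_mix < 0)) stop("category_mix must be non-negative", call. = FALSE)
  cats <- c("iwc_region", "partial", "inferred", "soviet", "certain")
  if (is.null(names(category_mix))) names(category_mix) <- cats

  empty_donors <- data.frame(species = character(0), lon_east = numeric(0),
                             lat = numeric(0), month = integer(0),
                             year = integer(0), expedition_id = character(0),
                             region_id = character(0))
  if (n_catches == 0)
    return(list(catches = .empty_catches(), donors = empty_donors))

  set.seed(rng_seed)
  op_months <- 4:11  # whaling season; all expeditions operate April-November

  # effort grid over the basin
  grid <- expand.grid(lon_east = seq(145, 255, by = 5),
                      lat = seq(22, 58, by = 4))
  month_w <- vapply(op_months, function(m) {
    mean(true_mu(world, "east", grid$lon_east, grid$lat, m) +
           true_mu(world, "west", grid$lon_east, grid$lat, m))
  }, numeric(1))
  month <- sample(op_months, n_catches, replace = TRUE, prob = month_w)

  pick_cell <- function(m) {
    eff <- true_mu(world, "east", grid$lon_east, grid$lat, m) +
      true_mu(world, "west", grid$lon_east, grid$lat, m) + 0.1
    sample.int(nrow(grid), 1, prob = eff)
  }
  cell <- vapply(month, pick_cell, integer(1))
  lon <- grid$lon_east[cell] + stats::runif(n_catches, -2.5, 2.5)
  lat <- grid$lat[cell] + stats::runif(n_catches, -2, 2)
  lon <- pmin(pmax(lon, 140.01), 259.99)
  lat <- pmin(pmax(lat, 20.01), 59.99)

  mu_e <- true_mu(world, "east", lon, lat, month)
  mu_w <- true_mu(world, "west", lon, lat, month)
  pop <- ifelse(stats::rbinom(n_catches, 1, mu_e / (mu_e + mu_w)) == 1,
                "east", "west")

  year <- sample(years, n_catches, replace = TRUE)
  region <- .region_of(lon)
  expedition <- paste0("EXP-", region, "-", year)
  category <- sample(cats, n_catches, replace = TRUE, prob = category_mix)

  catches <- data.frame(
    catch_id = sprintf("C%05d", seq_len(n_catches)),
    year = year, month = month, lon_east = lon, lat = lat,
    category = category, region_id = region,
    rect_lat_min = NA_real_, rect_lat_max = NA_real_,
    rect_lon_min = NA_real_, rect_lon_max = NA_real_,
    expedition_id = expedition,
    op_month_start = min(op_months), op_month_end = max(op_months),
    sex = sample(c("F", "M"), n_catches, replace = TRUE),
    length_m = NA_real_,
    maturity = sample(c("mature", "immature", "unknown"), n_catches,
                      replace = TRUE, prob = c(0.5, 0.3, 0.2)),
    true_population = pop, true_lon_east = lon, true_lat = lat,
    true_month = month)

  # degrade observed fields per category
  month_known <- stats::runif(n_catches) < 0.5
  is_cat <- function(cc) catches$category == cc
  i <- is_cat("iwc_region")
  catches$lon_east[i] <- NA; catches$lat[i] <- NA; catches$month[i] <- NA
  i <- is_cat("partial")
  catches$lon_east[i] <- NA; catches$lat[i] <- NA
  catches$month[i & !month_known] <- NA
  i <- is_cat("inferred")
  catches$month[i] <- NA
  i <- is_cat("soviet")
  if (any(i)) {
    dlat <- stats::runif(sum(i), 1, 4); dlon <- stats::runif(sum(i), 2, 6)
    catches$rect_lat_min[i] <- pmax(catches$true_lat[i] - dlat, 20)
    catches$rect_lat_max[i] <- pmin(catches$true_lat[i] + dlat, 60)
    catches$rect_lon_min[i] <- pmax(catches$true_lon_east[i] - dlon, 140)
    catches$rect_lon_max[i] <- pmin(catches$true_lon_east[i] + dlon, 260)
    catches$lon_east[i] <- NA; catches$lat[i] <- NA
    catches$month[i & !month_known] <- NA
  }

  # donors: background pool (one per expedition-year x operating month) plus
  # the true locations of constrained catches, so every pool contains truth.
  # Background donors are reported catches of similar species, so they follow
  # the same effort surface as the catches, restricted to their region.
  sp <- c("blue", "fin", "sei", "minke")
  exp_tab <- unique(catches[, c("expedition_id", "year", "region_id")])
  nb <- nrow(exp_tab) * length(op_months)
  bk_exp <- exp_tab[rep(seq_len(nrow(exp_tab)), each = length(op_months)), ]
  bk_month <- rep(op_months, nrow(exp_tab))
  bk_lon <- numeric(nb); bk_lat <- numeric(nb)
  grid_region <- .region_of(grid$lon_east)
  for (r in unique(bk_exp$region_id)) {
    cells_r <- which(grid_region == r)
    for (m in op_months) {
      rows <- which(bk_exp$region_id == r & bk_month == m)
      if (!length(rows)) next
      eff <- true_mu(world, "east", grid$lon_east[cells_r], grid$lat[cells_r], m) +
        true_mu(world, "west", grid$lon_east[cells_r], grid$lat[cells_r], m) + 0.1
      pick <- cells_r[sample.int(length(cells_r), length(rows),
                                 replace = TRUE, prob = eff)]
      bk_lon[rows] <- grid$lon_east[pick] + stats::runif(length(rows), -2.5, 2.5)
      bk_lat[rows] <- grid$lat[pick] + stats::runif(length(rows), -2, 2)
    }
  }
  bk <- data.frame(
    species = sample(sp, nb, replace = TRUE),
    lon_east = pmin(pmax(bk_lon, 140.01), 259.99),
    lat = pmin(pmax(bk_lat, 20.01), 59.99),
    month = bk_month,
    year = bk_exp$year,
    expedition_id = bk_exp$expedition_id,
    region_id = bk_exp$region_id)
  constrained <- catches$category %in% c("iwc_region", "partial")
  truth_donors <- data.frame(
    species = sample(sp, sum(constrained), replace = TRUE),
    lon_east = catches$true_lon_east[constrained],
    lat = catches$true_lat[constrained],
    month = catches$true_month[constrained],
    year = catches$year[constrained],
    expedition_id = catches$expedition_id[constrained],
    region_id = catches$region_id[constrained])
  donors <- rbind(bk, truth_donors)
  rownames(donors) <- NULL
  list(catches = catches, donors = donors)
}

#' Fill in catch lengths from the population-specific distributions
#'
#' Lengths are normal with mean `length_mean_east` or `length_mean_west`
#' according to the true population label, and common `length_sd`
#' (`length_sd = 0` gives exact means).
#'
#' @param catches The catches table from [simulate_catches()] (must carry
#'   `true_population`).
#' @param world A [world_config()].
#' @param rng_seed Integer seed.
#' @return The catches table with `length_m` filled.
#' @export
simulate_lengths <- function(catches, world, rng_seed = world$seed) {
  if (world$length_sd < 0) stop("length_sd must be non-negative", call. = FALSE)
  if (!"true_population" %in% names(catches))
    stop("catches must carry true_population labels", call. = FALSE)
  set.seed(rng_seed)
  mean_l <- ifelse(catches$true_population == "east",
                   world$length_mean_east, world$length_mean_west)
  catches$length_m <- stats::rnorm(nrow(catches), mean_l, world$length_sd)
  catches
}
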