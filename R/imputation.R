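# Monte Carlo imputation of uncertain catch locations and dates.
#
# Historical catch records fall into five location-uncertainty categories:
#   certain     exact position and month reported;
#   inferred    position recovered without uncertainty (e.g. a fixed land
#               station), supplied as fixed coordinates;
#   soviet      position known only to a (relatively small) rectangle;
#   iwc_region  position known only to a broad management region, imputed by
#               drawing from reported donor catch locations in that region;
#   partial     same-expedition-year donor locations exist; position drawn
#               from donors in the record's (known or sampled) month.
# Missing months are sampled from donor-derived month weights restricted to
# the expedition's operating months.

#' Allocate unspecified-species catches to blue whales
#'
#' Expedition-year totals sometimes report catches not identified to species.
#' Three rules convert these to added blue whale counts: (2) when
#' species-identified catches exist in the same expedition-year, apply that
#' year's blue whale proportion; (1) otherwise use the blue proportion in
#' adjacent years of the same expedition, expanding the window one year at a
#' time up to `max_window`; (3) rows flagged `japan_early` (coastal Japan at
#' the start of blue whaling) use the fixed proportion `japan_early_rate`.
#' Allocations are rounded to the nearest integer (ties to even).
#'
#' @param tab Data frame with columns `expedition_id`, `year`, `n_blue`,
#'   `n_other`, `n_unspecified`, and optionally logical `japan_early`.
#' @param japan_early_rate Proportion for rule (3). Default 0.164.
#' @param max_window Maximum adjacent-year half-width for rule (1).
#' @return `tab` with an `n_allocated` column appended.
#' @export
allocate_unspecified <- function(tab, japan_early_rate = 0.164, max_window = 3L) {
  need <- c("expedition_id", "year", "n_blue", "n_other", "n_unspecified")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  if (any(tab$n_blue < 0 | tab$n_other < 0 | tab$n_unspecified < 0))
    stop("counts must be non-negative", call. = FALSE)
  if (!"japan_early" %in% names(tab)) tab$japan_early <- FALSE

  alloc <- numeric(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    u <- tab$n_unspecified[i]
    if (u == 0) next
    if (isTRUE(tab$japan_early[i])) {
      alloc[i] <- round(u * japan_early_rate)
      next
    }
    spec <- tab$n_blue[i] + tab$n_other[i]
    if (spec > 0) {
      alloc[i] <- round(u * tab$n_blue[i] / spec)
      next
    }
    prop <- NA_real_
    for (w in seq_len(max_window)) {
      adj <- tab$expedition_id == tab$expedition_id[i] &
        abs(tab$year - tab$year[i]) <= w &
        (tab$n_blue + tab$n_other) > 0
      if (any(adj)) {
        prop <- sum(tab$n_blue[adj]) / sum(tab$n_blue[adj] + tab$n_other[adj])
        break
      }
    }
    if (is.na(prop)) {
      warning(sprintf(
        "no species-identified catches within %d years for expedition %s year %d; allocating 0",
        max_window, tab$expedition_id[i], tab$year[i]))
      prop <- 0
    }
    alloc[i] <- round(u * prop)
  }
  tab$n_allocated <- alloc
  tab
}

#' Monthly sampling weights from donor catches
#'
#' Weights proportional to donor catch counts per month, restricted to
#' `allowed_months` and renormalized; uniform over `allowed_months` when no
#' donor falls in any allowed month.
#'
#' @param donors Donor table with a `month` column (1-12).
#' @param allowed_months Non-empty subset of 1..12.
#' @return A numeric vector of length 12 summing to 1 (zero outside
#'   `allowed_months`).
#' @export
month_weights <- function(donors, allowed_months = 1:12) {
  allowed_months <- as.integer(allowed_months)
  if (length(allowed_months) == 0 || any(!allowed_months %in% 1:12))
    stop("allowed_months must be a non-empty subset of 1..12", call. = FALSE)
  counts <- tabulate(donors$month[!is.na(donors$month)], nbins = 12)
  w <- numeric(12)
  w[allowed_months] <- counts[allowed_months]
  if (sum(w) == 0) w[allowed_months] <- 1
  w / sum(w)
}

#' Average neighbour locations for the inferred category
#'
#' The inferred category uses fixed coordinates prepared upstream, most often
#' the average of adjacent catches of other species taken on the same dates;
#' this helper performs that averaging from an explicit neighbour list.
#'
#' @param lon_east,lat Neighbour coordinates.
#' @return Named vector `c(lon_east, lat)` of means.
#' @export
infer_location <- function(lon_east, lat) {
  if (length(lon_east) == 0) stop("need at least one neighbour", call. = FALSE)
  c(lon_east = mean(lon_east), lat = mean(lat))
}

.operating_months <- function(start, end) {
  if (is.na(start) || is.na(end)) return(1:12)
  seq(as.integer(start), as.integer(end))
}

#' Draw one Monte Carlo realization of the conflated catch series
#'
#' Produces a complete `(lon_east, lat, month)` for every catch, honouring
#' each record's uncertainty-category constraint. Known fields are never
#' modified. Missing months are sampled first, from [month_weights()] over
#' the record's operating months (all months when unrecorded); then missing
#' locations: `soviet` uniform in its rectangle, `iwc_region` drawn with
#' replacement from donor locations with matching `region_id`, `partial`
#' drawn with replacement from same-expedition-year donor locations in the
#' record's month (falling back, with a warning, to all months for that
#' expedition-year when the sampled month has no donors).
#'
#' @param catches Catch records (see [simulate_catches()] for the schema).
#' @param donors Donor table (`species`, `lon_east`, `lat`, `month`, `year`,
#'   `expedition_id`, `region_id`).
#' @param rng_seed Integer seed; recorded in the output.
#' @return A data frame of class `catch_realization`: `catch_id`,
#'   `lon_east`, `lat`, `month`, `realization_seed`.
#' @export
draw_realization <- function(catches, donors, rng_seed) {
  n <- nrow(catches)
  set.seed(rng_seed)
  out <- data.frame(catch_id = catches$catch_id,
                    lon_east = catches$lon_east,
                    lat = catches$lat,
                    month = as.integer(catches$month))

  # months first (partial locations are conditioned on month)
  mm <- which(is.na(out$month))
  if (length(mm)) {
    key <- paste(catches$op_month_start[mm], catches$op_month_end[mm])
    for (kk in unique(key)) {
      rows <- mm[key == kk]
      allowed <- .operating_months(catches$op_month_start[rows[1]],
                                   catches$op_month_end[rows[1]])
      w <- month_weights(donors, allowed)
      out$month[rows] <- sample.int(12, length(rows), replace = TRUE, prob = w)
    }
  }

  cat_of <- catches$category
  # soviet: uniform in rectangle
  i <- which(cat_of == "soviet")
  if (length(i)) {
    if (any(is.na(catches$rect_lon_min[i])))
      stop("soviet record(s) without rectangle: ",
           paste(catches$catch_id[i][is.na(catches$rect_lon_min[i])],
                 collapse = ", "), call. = FALSE)
    out$lon_east[i] <- stats::runif(length(i), catches$rect_lon_min[i],
                                    catches$rect_lon_max[i])
    out$lat[i] <- stats::runif(length(i), catches$rect_lat_min[i],
                               catches$rect_lat_max[i])
  }

  # iwc_region: draw (lon, lat) jointly from donors in the region
  i <- which(cat_of == "iwc_region")
  if (length(i)) {
    for (r in unique(catches$region_id[i])) {
      rows <- i[catches$region_id[i] == r]
      pool <- which(donors$region_id == r)
      if (!length(pool))
        stop("no donor locations for region ", r, " (catches: ",
             paste(catches$catch_id[rows], collapse = ", "), ")", call. = FALSE)
      pick <- pool[sample.int(length(pool), length(rows), replace = TRUE)]
      out$lon_east[rows] <- donors$lon_east[pick]
      out$lat[rows] <- donors$lat[pick]
    }
  }

  # partial: same expedition-year donors in the realized month
  i <- which(cat_of == "partial")
  for (j in i) {
    pool <- which(donors$expedition_id == catches$expedition_id[j] &
                    donors$year == catches$year[j] &
                    donors$month == out$month[j])
    if (!length(pool)) {
      pool <- which(donors$expedition_id == catches$expedition_id[j] &
                      donors$year == catches$year[j])
      if (length(pool))
        warning(sprintf(
          "catch %s: no donors for expedition %s in month %d; using all months",
          catches$catch_id[j], catches$expedition_id[j], out$month[j]))
    }
    if (!length(pool))
      stop("no donor locations for partial catch ", catches$catch_id[j],
           call. = FALSE)
    pick <- pool[sample.int(length(pool), 1)]
    out$lon_east[j] <- donors$lon_east[pick]
    out$lat[j] <- donors$lat[pick]
  }

  if (anyNA(out$lon_east) || anyNA(out$lat) || anyNA(out$month)) {
    bad <- out$catch_id[is.na(out$lon_east) | is.na(out$lat) | is.na(out$month)]
    stop("realization incomplete for catches: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  out$realization_seed <- as.integer(rng_seed)
  class(out) <- c("catch_realization", "data.frame")
  out
}
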