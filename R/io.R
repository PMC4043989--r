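# CSV schemas and readers/writers.
#
# Files store longitude as signed degrees in [-180, 180]; internally all
# longitudes are degrees east in [0, 360) so the North Pacific is contiguous
# across the dateline. CSV dialect: UTF-8, comma separator, header row,
# '.' decimal, empty field = missing.

.lon_to_east <- function(lon) ifelse(lon < 0, lon + 360, lon)
.lon_to_signed <- function(lon_east) ifelse(lon_east >= 180, lon_east - 360, lon_east)

#' Read an acoustic presence CSV
#'
#' Schema: `station_id, lon, lat, month, hours_analyzed, hours_present,
#' call_type`. Longitudes are accepted in `[-180, 180]` or `[0, 360)` and
#' normalized to degrees east; rows with `hours_present > hours_analyzed`
#' or months outside 1..12 are rejected with their row numbers.
#'
#' @param path CSV file path.
#' @return A data frame of acoustic observations (internal schema:
#'   `station_id`, `lon_east`, `lat`, `month`, `n_hours`, `k_hours`,
#'   `call_type`).
#' @export
read_acoustic <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("empty acoustic file: ", path, call. = FALSE)
  need <- c("station_id", "lon", "lat", "month", "hours_analyzed",
            "hours_present", "call_type")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("acoustic CSV lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- which(is.na(df$month) | !df$month %in% 1:12)
  if (length(bad))
    stop("invalid month at row(s): ", paste(bad, collapse = ", "), call. = FALSE)
  bad <- which(is.na(df$hours_present) | is.na(df$hours_analyzed) |
                 df$hours_present < 0 | df$hours_present > df$hours_analyzed)
  if (length(bad))
    stop("hours_present must satisfy 0 <= k <= hours_analyzed; bad row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  bad <- which(is.na(df$lon) | df$lon < -180 | df$lon >= 360)
  if (length(bad))
    stop("longitude out of range at row(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  data.frame(station_id = as.character(df$station_id),
             lon_east = .lon_to_east(df$lon), lat = df$lat,
             month = as.integer(df$month),
             n_hours = as.integer(df$hours_analyzed),
             k_hours = as.integer(df$hours_present),
             call_type = as.character(df$call_type))
}

#' Write an acoustic presence CSV
#'
#' @param acoustic Acoustic observations (internal schema).
#' @param path Output path.
#' @export
write_acoustic <- function(acoustic, path) {
  out <- data.frame(station_id = acoustic$station_id,
                    lon = .lon_to_signed(acoustic$lon_east),
                    lat = acoustic$lat, month = acoustic$month,
                    hours_analyzed = acoustic$n_hours,
                    hours_present = acoustic$k_hours,
                    call_type = acoustic$call_type)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

.catches_csv_cols <- c("catch_id", "year", "month", "lon", "lat", "category",
                       "region_id", "rect_lat_min", "rect_lat_max",
                       "rect_lon_min", "rect_lon_max", "expedition_id",
                       "op_month_start", "op_month_end", "sex", "length_m",
                       "maturity")

#' Read a catch-record CSV
#'
#' Schema: `catch_id, year, month, lon, lat, category, region_id,
#' rect_lat_min, rect_lat_max, rect_lon_min, rect_lon_max, expedition_id,
#' op_month_start, op_month_end, sex, length_m, maturity`. Longitudes
#' (including rectangle bounds) are normalized to degrees east. Category
#' invariants are enforced: `certain` requires position and month, `soviet`
#' a rectangle, `iwc_region` a region id, `inferred` a position.
#'
#' @param path CSV file path.
#' @return A catch-record data frame (internal schema with `lon_east`).
#' @export
read_catches <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("NA", ""))
  miss <- setdiff(.catches_csv_cols, names(df))
  if (length(miss))
    stop("catches CSV lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  out <- df
  out$lon_east <- .lon_to_east(df$lon)
  out$lon <- NULL
  out$rect_lon_min <- .lon_to_east(df$rect_lon_min)
  out$rect_lon_max <- .lon_to_east(df$rect_lon_max)
  chk <- function(cond, what) {
    bad <- which(cond)
    if (length(bad))
      stop(what, " for catch(es): ",
           paste(out$catch_id[bad], collapse = ", "), call. = FALSE)
  }
  chk(out$category == "certain" &
        (is.na(out$lon_east) | is.na(out$lat) | is.na(out$month)),
      "certain category requires lon, lat and month")
  chk(out$category == "soviet" &
        (is.na(out$rect_lat_min) | is.na(out$rect_lat_max) |
           is.na(out$rect_lon_min) | is.na(out$rect_lon_max)),
      "soviet category requires a rectangle")
  chk(out$category == "iwc_region" & is.na(out$region_id),
      "iwc_region category requires region_id")
  chk(out$category == "inferred" & (is.na(out$lon_east) | is.na(out$lat)),
      "inferred category requires lon and lat")
  out
}

#' Write a catch-record CSV
#'
#' Writes the observed-field schema (truth columns, if present, are dropped;
#' use [write_truth()] for those).
#'
#' @param catches Catch records (internal schema).
#' @param path Output path.
#' @export
write_catches <- function(catches, path) {
  out <- data.frame(catch_id = catches$catch_id, year = catches$year,
                    month = catches$month,
                    lon = .lon_to_signed(catches$lon_east), lat = catches$lat,
                    category = catches$category, region_id = catches$region_id,
                    rect_lat_min = catches$rect_lat_min,
                    rect_lat_max = catches$rect_lat_max,
                    rect_lon_min = .lon_to_signed(catches$rect_lon_min),
                    rect_lon_max = .lon_to_signed(catches$rect_lon_max),
                    expedition_id = catches$expedition_id,
                    op_month_start = catches$op_month_start,
                    op_month_end = catches$op_month_end,
                    sex = catches$sex, length_m = catches$length_m,
                    maturity = catches$maturity)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write the synthetic truth CSV (test use)
#'
#' @param catches A [simulate_catches()] table carrying truth columns.
#' @param path Output path.
#' @export
write_truth <- function(catches, path) {
  out <- data.frame(catch_id = catches$catch_id,
                    true_population = catches$true_population,
                    true_lon = .lon_to_signed(catches$true_lon_east),
                    true_lat = catches$true_lat,
                    true_month = catches$true_month)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a donor-location CSV
#'
#' Schema: `species, lon, lat, month, year, expedition_id, region_id`.
#'
#' @param path CSV file path.
#' @return A donor data frame (internal schema with `lon_east`).
#' @export
read_donors <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("NA", ""))
  need <- c("species", "lon", "lat", "month", "year", "expedition_id",
            "region_id")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("donors CSV lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  df$lon_east <- .lon_to_east(df$lon)
  df$lon <- NULL
  df
}

#' Write a donor-location CSV
#'
#' @param donors Donor table (internal schema).
#' @param path Output path.
#' @export
write_donors <- function(donors, path) {
  out <- data.frame(species = donors$species,
                    lon = .lon_to_signed(donors$lon_east), lat = donors$lat,
                    month = donors$month, year = donors$year,
                    expedition_id = donors$expedition_id,
                    region_id = donors$region_id)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write / read a catch realization CSV
#'
#' Schema: `catch_id, lon, lat, month, realization_seed`.
#'
#' @param realization A [draw_realization()] result.
#' @param path File path.
#' @export
write_realization <- function(realization, path) {
  out <- data.frame(catch_id = realization$catch_id,
                    lon = .lon_to_signed(realization$lon_east),
                    lat = realization$lat, month = realization$month,
                    realization_seed = realization$realization_seed)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_realization
#' @export
read_realization <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- data.frame(catch_id = df$catch_id, lon_east = .lon_to_east(df$lon),
                    lat = df$lat, month = as.integer(df$month),
                    realization_seed = as.integer(df$realization_seed))
  class(out) <- c("catch_realization", "data.frame")
  out
}

#' Write a percentile table CSV
#'
#' Per-year 2.5/50/97.5 percentiles of the split series. Values are rounded
#' to whole catches at serialization only.
#'
#' @param tab An [aggregate_percentiles()] result.
#' @param path Output path.
#' @param digits Rounding digits (default 0: whole catches).
#' @export
write_percentile_table <- function(tab, path, digits = 0) {
  out <- tab
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], round, digits = digits)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write an ensemble as a long-format CSV
#'
#' One row per iteration x year: `iteration, year, enp, wnp`.
#'
#' @param ensemble A [run_ensemble()] result.
#' @param path Output path.
#' @export
write_ensemble_csv <- function(ensemble, path) {
  rows <- lapply(seq_along(ensemble$series), function(i) {
    by <- ensemble$series[[i]]$by_year
    data.frame(iteration = i, year = by$year, enp = by$enp, wnp = by$wnp)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
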