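# End-to-end pipeline driver and report tables.

#' Pipeline configuration
#'
#' @param acoustic,catches,donors Input CSV paths (see [read_acoustic()],
#'   [read_catches()], [read_donors()]).
#' @param out_dir Output directory (created if absent).
#' @param N Ensemble iterations per mode.
#' @param seed Integer seed recorded in every output.
#' @param structure [model_structure()] used for the ensemble fits.
#' @param candidates Candidate list for the model-selection stage, or `NULL`
#'   to skip selection.
#' @param lam_range `(lo, hi)` for the ecological-uncertainty mode.
#' @param assignment Per-catch assignment mode.
#' @param decomposition Run the three nested uncertainty modes (catch only,
#'   catch + bootstrap, catch + bootstrap + lambda) and report the
#'   cumulative decomposition; otherwise run a single mode with
#'   `bootstrap = TRUE` and fixed lambda 1.
#' @param validation_criteria Passed to [select_validation_set()]; `NULL`
#'   skips validation.
#' @return A `run_config` list.
#' @export
run_config <- function(acoustic, catches, donors, out_dir,
                       N = 100L, seed = 1L,
                       structure = model_structure("beta_binomial", "additive", "additive"),
                       candidates = NULL,
                       lam_range = c(0.5, 2),
                       assignment = c("expected", "bernoulli"),
                       decomposition = TRUE,
                       validation_criteria = list(sex = "F", maturity = "mature",
                                                  min_length_m = 21)) {
  if (N < 1) stop("N must be >= 1", call. = FALSE)
  structure(list(acoustic = acoustic, catches = catches, donors = donors,
                 out_dir = out_dir, N = as.integer(N), seed = as.integer(seed),
                 structure = structure, candidates = candidates,
                 lam_range = lam_range, assignment = match.arg(assignment),
                 decomposition = isTRUE(decomposition),
                 validation_criteria = validation_criteria),
            class = "run_config")
}

#' Run the full catch-splitting pipeline
#'
#' Reads the three input CSVs; optionally ranks candidate model structures
#' by AICc; fits the base population models; runs the ensemble (three nested
#' uncertainty modes when `decomposition = TRUE`); aggregates per-year
#' percentile tables; runs the length validation when lengths are available;
#' writes all outputs (CSV/JSON, with seeds) into `out_dir`.
#'
#' @param config A [run_config()].
#' @param quiet Suppress per-stage messages.
#' @return The output bundle, invisibly: `selection`, `ensembles`,
#'   `percentiles`, `decomposition`, `validation`, `paths`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  say("stage 1/5: reading inputs")
  acoustic <- read_acoustic(config$acoustic)
  catches <- read_catches(config$catches)
  donors <- read_donors(config$donors)
  ae <- acoustic[acoustic$call_type == "east", , drop = FALSE]
  aw <- acoustic[acoustic$call_type == "west", , drop = FALSE]
  if (nrow(ae) == 0 || nrow(aw) == 0)
    stop("acoustic data must contain both call types", call. = FALSE)

  selection <- NULL
  if (!is.null(config$candidates)) {
    say("stage 2/5: model selection (%d candidates per call type)",
        length(config$candidates))
    selection <- list(east = select_model(ae, config$candidates),
                      west = select_model(aw, config$candidates))
    utils::write.csv(selection$east,
                     file.path(config$out_dir, "selection_east.csv"),
                     row.names = FALSE)
    utils::write.csv(selection$west,
                     file.path(config$out_dir, "selection_west.csv"),
                     row.names = FALSE)
  } else say("stage 2/5: model selection skipped")

  say("stage 3/5: ensembles (N = %d)", config$N)
  modes <- if (config$decomposition) {
    list(catch = ensemble_options(bootstrap = FALSE, lam = lambda_fixed(1),
                                  assignment = config$assignment),
         catch_statistical = ensemble_options(bootstrap = TRUE,
                                              lam = lambda_fixed(1),
                                              assignment = config$assignment),
         catch_statistical_ecological = ensemble_options(
           bootstrap = TRUE,
           lam = lambda_loguniform(config$lam_range[1], config$lam_range[2]),
           assignment = config$assignment))
  } else {
    list(base = ensemble_options(bootstrap = TRUE, lam = lambda_fixed(1),
                                 assignment = config$assignment))
  }
  ensembles <- lapply(modes, function(opt)
    run_ensemble(catches, donors, ae, aw, config$structure, config$N,
                 options = opt, rng_seed = config$seed))

  say("stage 4/5: percentile tables")
  percentiles <- lapply(ensembles, aggregate_percentiles)
  for (nm in names(percentiles)) {
    write_percentile_table(percentiles[[nm]],
                           file.path(config$out_dir,
                                     paste0("percentiles_", nm, ".csv")))
    write_ensemble_csv(ensembles[[nm]],
                       file.path(config$out_dir, paste0("ensemble_", nm, ".csv")))
  }
  decomposition <- NULL
  if (config$decomposition) {
    ints <- lapply(ensembles, ensemble_total_interval)
    decomposition <- uncertainty_decomposition(
      ints$catch[c("lo", "hi")],
      ints$catch_statistical[c("lo", "hi")],
      ints$catch_statistical_ecological[c("lo", "hi")])
    jsonlite::write_json(
      list(intervals = ints, cumulative_pct = as.list(decomposition)),
      file.path(config$out_dir, "decomposition.json"),
      auto_unbox = TRUE, digits = NA)
  }

  validation <- NULL
  if (!is.null(config$validation_criteria) && any(!is.na(catches$length_m))) {
    say("stage 5/5: length validation")
    vset <- select_validation_set(catches, config$validation_criteria)
    vens <- ensembles[[length(ensembles)]]
    probs <- ensemble_prob_matrix(vens, vset$catch_id)
    tests <- length_tests(vset, probs)
    validation <- list(set = vset, tests = tests,
                       summary = summarize_validation(tests))
    utils::write.csv(tests, file.path(config$out_dir, "validation.csv"),
                     row.names = FALSE)
    jsonlite::write_json(unclass(validation$summary),
                         file.path(config$out_dir, "validation_summary.json"),
                         auto_unbox = TRUE, digits = NA)
  } else say("stage 5/5: length validation skipped")

  meta <- list(seed = config$seed, N = config$N,
               assignment = config$assignment,
               structure = unclass(config$structure),
               attempts = lapply(ensembles, function(e) e$attempts),
               failures_east = lapply(ensembles, function(e) e$failures_east),
               failures_west = lapply(ensembles, function(e) e$failures_west))
  jsonlite::write_json(meta, file.path(config$out_dir, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(selection = selection, ensembles = ensembles,
                 percentiles = percentiles, decomposition = decomposition,
                 validation = validation, paths = config$out_dir))
}

#' Category count-and-share table
#'
#' Counts per location-uncertainty category with integer percentage shares
#' and a total row; shares and totals are recomputed from the counts.
#'
#' @param x Either a catch-record data frame (with a `category` column) or a
#'   named vector of counts.
#' @return A data frame `category`, `n`, `share_pct` whose last row is the
#'   total (share 100).
#' @export
category_share_table <- function(x) {
  counts <- if (is.data.frame(x)) {
    tab <- table(x$category)
    stats::setNames(as.integer(tab), names(tab))
  } else {
    stats::setNames(as.integer(x), names(x))
  }
  total <- sum(counts)
  if (total == 0) stop("no catches to tabulate", call. = FALSE)
  out <- data.frame(category = c(names(counts), "Total"),
                    n = c(unname(counts), total),
                    share_pct = c(as.integer(round(100 * counts / total)), 100L))
  rownames(out) <- NULL
  out
}

#' Percentage share rounded to one decimal
#'
#' @param part,total Non-negative counts, `total > 0`.
#' @return `100 * part / total` rounded to one decimal place.
#' @export
pct_share <- function(part, total) {
  if (total <= 0) stop("total must be positive", call. = FALSE)
  round(100 * part / total, 1)
}
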