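# Length-based validation of the split.
#
# Western North Pacific blue whales are longer than eastern ones, so if the
# acoustic split is right, catches assigned to the western population (low
# predicted ENP probability) should be longer. Per ensemble iteration:
# threshold the predicted probability at 0.5, Welch two-sample t-test on the
# group mean lengths (WNP minus ENP), and an ordinary least-squares
# regression of predicted probability on length (a negative slope validates
# the split). Results are summarized over iterations by percentiles.

#' Select the length-validation subset
#'
#' Mature females with a recorded length. When maturity is unrecorded, a
#' length threshold (default 21 m) stands in for the maturity criterion; the
#' threshold is configurable because the underlying length-at-maturity rule
#' comes from external studies.
#'
#' @param catches Catch records with `sex`, `maturity`, `length_m`.
#' @param criteria List with `sex` (default `"F"`), `maturity`
#'   (`"mature"`) and `min_length_m` (default 21) used as the maturity proxy
#'   for `maturity == "unknown"`.
#' @return A data frame (`catch_id`, `length_m`, `sex`, `maturity`).
#' @export
select_validation_set <- function(catches,
                                  criteria = list(sex = "F",
                                                  maturity = "mature",
                                                  min_length_m = 21)) {
  need <- c("sex", "maturity", "length_m")
  miss <- setdiff(need, names(catches))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  sexes <- if (is.null(criteria$sex)) "F" else criteria$sex
  mat <- if (is.null(criteria$maturity)) "mature" else criteria$maturity
  thr <- if (is.null(criteria$min_length_m)) 21 else criteria$min_length_m
  keep <- catches$sex %in% sexes & !is.na(catches$length_m) &
    (catches$maturity %in% mat |
       (catches$maturity %in% c("unknown", NA) & catches$length_m >= thr))
  if (!any(keep))
    stop("no catches satisfy the validation criteria; review the sex/maturity filters or the length threshold",
         call. = FALSE)
  out <- catches[keep, c("catch_id", "length_m", "sex", "maturity")]
  rownames(out) <- NULL
  out
}

#' Extract the per-iteration probability matrix for given catches
#'
#' @param ensemble A [run_ensemble()] result.
#' @param catch_ids Catch ids (rows of the returned matrix).
#' @return A numeric matrix, `length(catch_ids)` x iterations.
#' @export
ensemble_prob_matrix <- function(ensemble, catch_ids) {
  stopifnot(inherits(ensemble, "bb_ensemble"))
  vapply(ensemble$series, function(s)
    s$probs$p_enp[match(catch_ids, s$probs$catch_id)],
    numeric(length(catch_ids)))
}

#' Per-iteration length tests
#'
#' For each iteration (column of `probs`): assign catches to ENP when the
#' predicted probability exceeds `threshold`; Welch two-sample t-test of the
#' mean length difference (WNP minus ENP); OLS regression of probability on
#' length. Iterations with an empty group or degenerate variance are flagged
#' rather than erroring.
#'
#' @param samples A [select_validation_set()] result.
#' @param probs Probability matrix (`nrow(samples)` x iterations) or a
#'   vector for a single iteration.
#' @param threshold Assignment threshold on the ENP probability; default 0.5.
#' @return A data frame with one row per iteration: `iteration`,
#'   `mean_diff_m` (WNP minus ENP), `t_stat`, `t_p`, `slope`, `slope_p`,
#'   `t_defined`, `slope_defined`.
#' @export
length_tests <- function(samples, probs, threshold = 0.5) {
  if (is.null(dim(probs))) probs <- matrix(probs, ncol = 1)
  if (nrow(probs) != nrow(samples))
    stop("probs must have one row per validation sample", call. = FALSE)
  len <- samples$length_m
  n_it <- ncol(probs)
  out <- data.frame(iteration = seq_len(n_it), mean_diff_m = NA_real_,
                    t_stat = NA_real_, t_p = NA_real_,
                    slope = NA_real_, slope_p = NA_real_,
                    t_defined = FALSE, slope_defined = FALSE)
  for (j in seq_len(n_it)) {
    p <- probs[, j]
    enp <- p > threshold
    le <- len[enp]; lw <- len[!enp]
    if (length(le) >= 2 && length(lw) >= 2 &&
        stats::sd(le) > 0 && stats::sd(lw) > 0) {
      tt <- stats::t.test(lw, le)  # Welch; WNP minus ENP
      out$mean_diff_m[j] <- mean(lw) - mean(le)
      out$t_stat[j] <- unname(tt$statistic)
      out$t_p[j] <- tt$p.value
      out$t_defined[j] <- TRUE
    }
    if (stats::sd(len) > 0 && stats::sd(p) > 0) {
      fit <- stats::lm(p ~ len)
      sm <- summary(fit)$coefficients
      out$slope[j] <- sm["len", "Estimate"]
      out$slope_p[j] <- sm["len", "Pr(>|t|)"]
      out$slope_defined[j] <- TRUE
    }
  }
  out
}

#' Summarize per-iteration validation results
#'
#' @param results A [length_tests()] data frame.
#' @param alpha_t,alpha_slope Significance levels for the reported exceedance
#'   fractions (defaults 0.001 and 0.05).
#' @return A list of class `validation_summary`: median and 95% percentile
#'   range of the mean length difference, fraction of iterations with t-test
#'   p below `alpha_t`, median/range of the regression slope, fraction with
#'   a significant negative slope, and counts of undefined iterations.
#' @export
summarize_validation <- function(results, alpha_t = 0.001, alpha_slope = 0.05) {
  t_res <- results[results$t_defined, , drop = FALSE]
  s_res <- results[results$slope_defined, , drop = FALSE]
  n_undef <- nrow(results) - nrow(t_res)
  if (nrow(t_res) == 0 && nrow(s_res) == 0)
    stop("no defined validation iterations", call. = FALSE)
  if (n_undef > 0)
    warning(n_undef, " iteration(s) with undefined t-test excluded")
  q3 <- function(x) stats::quantile(x, c(0.025, 0.5, 0.975), type = 7, names = FALSE)
  qt_ <- if (nrow(t_res)) q3(t_res$mean_diff_m) else rep(NA_real_, 3)
  qs <- if (nrow(s_res)) q3(s_res$slope) else rep(NA_real_, 3)
  structure(list(
    mean_diff_median = qt_[2], mean_diff_lo = qt_[1], mean_diff_hi = qt_[3],
    frac_t_significant = if (nrow(t_res)) mean(t_res$t_p < alpha_t) else NA_real_,
    slope_median = qs[2], slope_lo = qs[1], slope_hi = qs[3],
    frac_slope_negative_significant =
      if (nrow(s_res)) mean(s_res$slope < 0 & s_res$slope_p < alpha_slope) else NA_real_,
    n_iterations = nrow(results), n_undefined_t = n_undef,
    alpha_t = alpha_t, alpha_slope = alpha_slope
  ), class = "validation_summary")
}

#' @export
print.validation_summary <- function(x, ...) {
  cat(sprintf(
    "length validation over %d iterations (%d undefined):\n", x$n_iterations,
    x$n_undefined_t))
  cat(sprintf("  mean length difference (WNP - ENP): %.2f m (95%% range %.2f-%.2f)\n",
              x$mean_diff_median, x$mean_diff_lo, x$mean_diff_hi))
  cat(sprintf("  fraction of iterations with t-test p < %g: %.3f\n",
              x$alpha_t, x$frac_t_significant))
  cat(sprintf("  regression slope (probability on length): %.4f (95%% range %.4f-%.4f)\n",
              x$slope_median, x$slope_lo, x$slope_hi))
  cat(sprintf("  fraction with significant negative slope (p < %g): %.3f\n",
              x$alpha_slope, x$frac_slope_negative_significant))
  invisible(x)
}
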