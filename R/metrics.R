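#' Average absolute relative bias (percent)
#'
#' Default mode is the absolute relative bias of the mean estimate,
#' `100 * |mean(estimates) - truth| / |truth|`.  The alternative
#' `"mean_absolute"` mode averages per-replication absolute relative
#' deviations instead (the phrase "average absolute relative bias" admits
#' both readings; the bias-of-the-mean reading is the conventional Monte
#' Carlo relative bias and is the default).
#'
#' @param estimates vector of replication estimates.
#' @param truth true effect (nonzero).
#' @param mode `"bias_of_mean"` (default) or `"mean_absolute"`.
#' @return nonnegative percentage.
#' @export
#' @examples
#' relative_bias(c(0.5, 0.3), 0.4055) # 1.356
relative_bias <- function(estimates, truth,
                          mode = c("bias_of_mean", "mean_absolute")) {
  mode <- match.arg(mode)
  stopifnot(length(estimates) >= 1)
  if (truth == 0) {
    stop("truth is zero: relative bias undefined, use absolute bias")
  }
  if (mode == "bias_of_mean") {
    100 * abs(mean(estimates) - truth) / abs(truth)
  } else {
    100 * mean(abs(estimates - truth)) / abs(truth)
  }
}

#' Empirical standard error
#'
#' Sample standard deviation (n - 1 denominator) of the replication
#' estimates.
#'
#' @param estimates vector of length >= 2.
#' @return positive scalar.
#' @export
#' @examples
#' empirical_se(c(0.5, 0.3)) # 0.1414
empirical_se <- function(estimates) {
  if (length(estimates) < 2) stop("need at least 2 estimates")
  stats::sd(estimates)
}

#' 95% confidence-interval coverage
#'
#' Fraction of replications whose interval `[ci_low, ci_high]` contains
#' the truth.
#'
#' @param results data frame with `ci_low` and `ci_high` columns.
#' @param truth true effect.
#' @return proportion in `[0, 1]`.
#' @export
coverage <- function(results, truth) {
  stopifnot(nrow(results) >= 1)
  mean(results$ci_low <= truth & truth <= results$ci_high)
}

#' Summarize a simulation run into per-scenario performance metrics
#'
#' One row per (scenario, estimator): relative bias, empirical SE and 95%
#' coverage, each with its Monte Carlo standard error (`mcse_bias_pct =
#' 100 * emp_se / (sqrt(n) |truth|)`, `mcse_empse = emp_se / sqrt(2(n-1))`,
#' `mcse_coverage = sqrt(cov (1 - cov) / n)`).  Non-converged replications
#' are excluded pairwise per estimator and counted in `n_excluded`; a cell
#' with fewer than two usable replications is emitted with missing metrics
#' and a warning.
#'
#' @param results long tibble of estimate rows with `scenario_id`, `rep`,
#'   `estimator`, `estimate`, `se`, `ci_low`, `ci_high`, `converged`.
#' @param truths a single number (shared truth), or a data frame with
#'   `scenario_id` and `truth` — optionally also `estimator`, for
#'   estimators that target different scales of the same effect.
#' @param rbias_mode passed to [relative_bias()].
#' @return tibble of metric rows.
#' @export
summarize_scenario <- function(results, truths = 0.4055,
                               rbias_mode = "bias_of_mean") {
  if (is.numeric(truths) && length(truths) == 1) {
    truths <- tibble::tibble(scenario_id = unique(results$scenario_id),
                             truth = truths)
  }
  join_keys <- intersect(c("scenario_id", "estimator"), names(truths))
  results |>
    dplyr::left_join(truths, by = join_keys) |>
    dplyr::group_by(.data$scenario_id, .data$estimator) |>
    dplyr::group_modify(function(d, key) {
      ok <- d$converged & is.finite(d$estimate)
      n_used <- sum(ok)
      truth <- d$truth[1]
      if (n_used < 2) {
        warning(sprintf("scenario %s / %s: fewer than 2 usable replications",
                        key$scenario_id, key$estimator))
        return(tibble::tibble(
          n_reps_used = n_used, n_excluded = nrow(d) - n_used,
          truth = truth, rbias_pct = NA_real_, emp_se = NA_real_,
          coverage = NA_real_, mcse_bias_pct = NA_real_,
          mcse_empse = NA_real_, mcse_coverage = NA_real_
        ))
      }
      est <- d$estimate[ok]
      emp <- empirical_se(est)
      cov <- coverage(d[ok, ], truth)
      tibble::tibble(
        n_reps_used = n_used,
        n_excluded = nrow(d) - n_used,
        truth = truth,
        rbias_pct = relative_bias(est, truth, rbias_mode),
        emp_se = emp,
        coverage = cov,
        mcse_bias_pct = 100 * emp / (sqrt(n_used) * abs(truth)),
        mcse_empse = emp / sqrt(2 * (n_used - 1)),
        mcse_coverage = sqrt(cov * (1 - cov) / n_used)
      )
    }) |>
    dplyr::ungroup()
}

#' Average metrics across cluster structures
#'
#' Unweighted mean of per-structure metrics for each (confounding level,
#' estimator), matching the structure-averaged summaries used to compare
#' estimators at a given confounding strength.  Scenario ids of the form
#' `m<m>_n<n>_or<OR>` are parsed for the grouping.
#'
#' @param metrics output of [summarize_scenario()].
#' @return tibble with one row per (or_label, estimator).
#' @export
average_over_structures <- function(metrics) {
  metrics |>
    dplyr::mutate(or_label = sub("^m\\d+_n\\d+_", "", .data$scenario_id)) |>
    dplyr::group_by(.data$or_label, .data$estimator) |>
    dplyr::summarise(
      n_structures = dplyr::n(),
      rbias_pct = mean(.data$rbias_pct),
      emp_se = mean(.data$emp_se),
      coverage = mean(.data$coverage),
      .groups = "drop"
    )
}
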