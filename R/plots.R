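#' Plot per-scenario performance metrics
#'
#' Panels of relative bias, empirical standard error or coverage by
#' cluster-confounding strength (x axis, odds-ratio labels) and cluster
#' structure (facets), one line per estimator — the layout used to compare
#' the estimators across the simulation grid.
#'
#' @param metrics output of [summarize_scenario()] on a grid run.
#' @param metric which metric to draw.
#' @return a ggplot object.
#' @export
plot_metrics <- function(metrics,
                         metric = c("rbias_pct", "emp_se", "coverage")) {
  metric <- match.arg(metric)
  d <- metrics |>
    tidyr::extract(
      "scenario_id", c("m", "n", "or"),
      "m(\\d+)_n(\\d+)_or([0-9.]+)", remove = FALSE, convert = TRUE
    ) |>
    dplyr::mutate(
      structure = factor(sprintf("(%d, %d)", .data$m, .data$n),
                         levels = unique(sprintf("(%d, %d)", .data$m,
                                                 .data$n))),
      or = factor(.data$or)
    )
  ylab <- c(rbias_pct = "relative bias (%)",
            emp_se = "empirical SE",
            coverage = "95% CI coverage")[[metric]]
  p <- ggplot2::ggplot(d, ggplot2::aes(
    x = .data$or, y = .data[[metric]],
    colour = .data$estimator, group = .data$estimator
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~structure) +
    ggplot2::labs(x = "cluster-confounder OR on treatment", y = ylab,
                  colour = NULL) +
    ggplot2::theme_bw()
  if (metric == "coverage") {
    p <- p + ggplot2::geom_hline(yintercept = 0.95, linetype = 2,
                                 colour = "grey40")
  }
  p
}

#' @method autoplot sim_run
#' @export
autoplot.sim_run <- function(object, metric = "rbias_pct", ...) {
  plot_metrics(object$metrics, metric)
}
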