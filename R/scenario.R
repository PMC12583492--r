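#' Define one parametric simulation scenario
#'
#' A scenario bundles the cluster structure, the log-odds coefficient
#' vectors of the treatment and outcome models, the true conditional
#' treatment effect, prevalence targets and replication bookkeeping for the
#' clustered-data generator.  The canonical study crosses five cluster
#' structures (10 x 1000, 50 x 200, 100 x 100, 200 x 50, 500 x 20 patients)
#' with four strengths of cluster-level confounding on treatment allocation
#' (odds ratios 1.01, 1.25, 1.5, 2.5, i.e. log-odds 0.01, 0.2231, 0.4055,
#' 0.9163).
#'
#' Covariates: `z1` (standard normal) and `z2` (Bernoulli 0.5) are
#' cluster-level confounders shared by every patient of a cluster;
#' `x1..x3` are Bernoulli(0.4, 0.45, 0.5) and `x4, x5` standard normal
#' patient-level confounders; `x6` is an outcome-only risk factor and `x7`
#' a treatment-only instrument (both Bernoulli 0.5).  A cross-level
#' interaction `z1 * x1` enters the treatment model only.
#'
#' @param n_clusters number of clusters `m` (>= 2).
#' @param mean_cluster_size Poisson mean cluster size `n` (>= 2).
#' @param total_target fixed total sample size (default 10000).
#' @param gamma_z log-odds effect of each of `z1`, `z2` on treatment.
#' @param beta_x_treat length-5 log-odds effects of `x1..x5` on treatment.
#' @param beta_x_out length-5 log-odds effects of `x1..x5` on outcome.
#' @param gamma_z_out log-odds effect of each of `z1`, `z2` on outcome.
#' @param beta_instrument effect of the instrument `x7` on treatment.
#' @param beta_riskfactor effect of the risk factor `x6` on outcome.
#' @param delta_interaction log-odds effect of `z1 * x1` on treatment.
#' @param tau true conditional treatment log odds ratio.
#' @param treat_prevalence_target,outcome_prevalence_target calibration
#'   targets in (0, 1) for the model intercepts.
#' @param n_reps number of Monte Carlo replications.
#' @param seed scenario base seed.
#' @param scenario_id optional label; a default is derived from the
#'   structure and `gamma_z`.
#' @return a list of class `scenario_config`.
#' @export
#' @examples
#' cfg <- scenario_config(n_clusters = 10, mean_cluster_size = 1000)
#' cfg$gamma_z
scenario_config <- function(n_clusters,
                            mean_cluster_size,
                            total_target = 10000L,
                            gamma_z = 0.4055,
                            beta_x_treat = c(0.35, 0.4, 0.45, 0.55, 0),
                            beta_x_out = c(0.35, 0.4, 0.45, 0.55, 0),
                            gamma_z_out = 0.4055,
                            beta_instrument = 0.5,
                            beta_riskfactor = 0.5,
                            delta_interaction = 0.4055,
                            tau = 0.4055,
                            treat_prevalence_target = 0.5,
                            outcome_prevalence_target = 0.5,
                            n_reps = 100L,
                            seed = 20231L,
                            scenario_id = NULL) {
  stopifnot(
    n_clusters >= 2, mean_cluster_size >= 2, total_target >= n_clusters,
    length(beta_x_treat) == 5, length(beta_x_out) == 5,
    treat_prevalence_target > 0, treat_prevalence_target < 1,
    outcome_prevalence_target > 0, outcome_prevalence_target < 1,
    n_reps >= 1
  )
  cfg <- list(
    n_clusters = as.integer(n_clusters),
    mean_cluster_size = as.integer(mean_cluster_size),
    total_target = as.integer(total_target),
    gamma_z = gamma_z,
    beta_x_treat = beta_x_treat,
    beta_x_out = beta_x_out,
    gamma_z_out = gamma_z_out,
    beta_instrument = beta_instrument,
    beta_riskfactor = beta_riskfactor,
    delta_interaction = delta_interaction,
    tau = tau,
    treat_prevalence_target = treat_prevalence_target,
    outcome_prevalence_target = outcome_prevalence_target,
    n_reps = as.integer(n_reps),
    seed = as.integer(seed),
    alpha0 = NULL,
    lambda0 = NULL
  )
  cfg$scenario_id <- scenario_id %||%
    sprintf("m%d_n%d_or%.2f", cfg$n_clusters, cfg$mean_cluster_size,
            exp(cfg$gamma_z))
  structure(cfg, class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf(
    "<scenario_config %s>  m=%d, mean n=%d, total=%d, gamma_z=%.4f, tau=%.4f, reps=%d\n",
    x$scenario_id, x$n_clusters, x$mean_cluster_size, x$total_target,
    x$gamma_z, x$tau, x$n_reps
  ))
  invisible(x)
}

# canonical grids
.cluster_structures <- function() {
  list(c(10L, 1000L), c(50L, 200L), c(100L, 100L), c(200L, 50L),
       c(500L, 20L))
}

.gamma_grid <- function() c(0.01, 0.2231, 0.4055, 0.9163)

#' Build the canonical 20-scenario grid
#'
#' Crosses the five cluster structures with the four cluster-confounding
#' strengths.  Every scenario receives a distinct derived seed from the
#' default configuration's seed.
#'
#' @param defaults a `scenario_config` supplying everything but the
#'   structure and `gamma_z` (its own structure/`gamma_z` are ignored).
#' @param structures list of `c(m, n)` pairs; defaults to the canonical
#'   five.
#' @param gamma_z_grid numeric vector of treatment-model log-odds for the
#'   cluster confounders; defaults to the canonical four.
#' @return list of `scenario_config`.
#' @export
#' @examples
#' grid <- make_scenario_grid()
#' length(grid) # 20
make_scenario_grid <- function(defaults = scenario_config(10, 1000),
                               structures = .cluster_structures(),
                               gamma_z_grid = .gamma_grid()) {
  idx <- 0L
  out <- list()
  for (st in structures) {
    for (g in gamma_z_grid) {
      idx <- idx + 1L
      cfg <- defaults
      cfg$n_clusters <- as.integer(st[1])
      cfg$mean_cluster_size <- as.integer(st[2])
      cfg$gamma_z <- g
      cfg$seed <- derive_seed(defaults$seed, idx)
      cfg$alpha0 <- NULL
      cfg$lambda0 <- NULL
      cfg$scenario_id <- sprintf("m%d_n%d_or%.2f", st[1], st[2], exp(g))
      out[[idx]] <- cfg
    }
  }
  out
}

#' Write / read a scenario grid as YAML
#'
#' Round-trips the scenario list through a plain YAML file so a grid can be
#' versioned or edited by hand.
#'
#' @param grid list of `scenario_config`.
#' @param path file path.
#' @return `scenario_grid_to_yaml` returns `path` invisibly;
#'   `scenario_grid_from_yaml` returns a list of `scenario_config`.
#' @export
scenario_grid_to_yaml <- function(grid, path) {
  plain <- purrr::map(grid, function(cfg) {
    cfg$alpha0 <- NULL
    cfg$lambda0 <- NULL
    unclass(cfg)
  })
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname scenario_grid_to_yaml
#' @export
scenario_grid_from_yaml <- function(path) {
  plain <- yaml::read_yaml(path)
  purrr::map(plain, function(x) {
    do.call(scenario_config, x[setdiff(names(x), c("alpha0", "lambda0"))])
  })
}
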