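# small, fast scenario used across tests (desk-scale cluster structure)
tiny_scenario <- function(m = 10, n_mean = 50, total = 500, gamma_z = 0.4055,
                          ...) {
  scenario_config(m, n_mean, total_target = total, gamma_z = gamma_z, ...)
}

# scenario with no covariate effects anywhere: treatment is randomized and
# the outcome depends on treatment only, so marginal and conditional
# effects coincide
null_covariate_scenario <- function(total = 2000, tau = 0.4055) {
  scenario_config(
    n_clusters = 20, mean_cluster_size = total / 20, total_target = total,
    gamma_z = 0, beta_x_treat = rep(0, 5), beta_x_out = rep(0, 5),
    gamma_z_out = 0, beta_instrument = 0, beta_riskfactor = 0,
    delta_interaction = 0, tau = tau
  )
}

fast_forest <- function(n_trees = 100L, seed = 1L, ...) {
  forest_options(n_trees = n_trees, seed = seed, ...)
}
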