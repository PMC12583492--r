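test_that("scenario grid crosses five structures with four confounding levels", {
  grid <- make_scenario_grid()
  expect_length(grid, 20)
  key <- vapply(grid, function(g) {
    sprintf("%d/%d/%.4f", g$n_clusters, g$mean_cluster_size, g$gamma_z)
  }, character(1))
  expect_length(unique(key), 20)
  expect_true("500/20/0.9163" %in% key)
  seeds <- vapply(grid, `[[`, integer(1), "seed")
  expect_length(unique(seeds), 20)
  # degenerate grid: one structure, one confounding level
  expect_length(
    make_scenario_grid(structures = list(c(10, 100)), gamma_z_grid = 0.4055),
    1
  )
})

test_that("cluster sizes are Poisson-like with an exact fixed total", {
  expect_equal(draw_cluster_sizes(1, 10, 10, rng_seed = 1), 10L)
  s <- draw_cluster_sizes(10, 1000, 10000, rng_seed = 2)
  expect_length(s, 10)
  expect_equal(sum(s), 10000)
  expect_true(all(s >= 1))
  expect_error(draw_cluster_sizes(10, 5, 9), "total_target")
  # MC check against the Poisson mean
  means <- vapply(1:300, function(i) {
    mean(draw_cluster_sizes(500, 20, 10000, rng_seed = i))
  }, numeric(1))
  expect_equal(mean(means), 20, tolerance = 0.01)
})

test_that("intercept calibration solves the logistic prevalence equation", {
  expect_equal(calibrate_intercept(function(n) rep(0, n), 0.5), 0,
               tolerance = 1e-4)
  expect_equal(calibrate_intercept(function(n) rep(0, n), 0.731),
               qlogis(0.731), tolerance = 1e-3)
  set.seed(1)
  lp <- rnorm(2e5)
  expect_equal(calibrate_intercept(function(n) lp, 0.5), 0, tolerance = 0.02)
})

test_that("simulated cohorts respect the scenario structure and targets", {
  cfg <- tiny_scenario(m = 10, n_mean = 100, total = 1000)
  cohort <- simulate_cohort(cfg, rep_seed = 5)
  expect_equal(nrow(cohort), 1000)
  expect_equal(nlevels(cohort$cluster_id), 10)
  # cluster-level covariates constant within cluster
  per_cluster <- cohort |>
    dplyr::group_by(cluster_id) |>
    dplyr::summarise(z1u = dplyr::n_distinct(z1),
                     z2u = dplyr::n_distinct(z2))
  expect_true(all(per_cluster$z1u == 1))
  expect_true(all(per_cluster$z2u == 1))
  # reproducibility: identical (config, seed) pairs give identical tables
  expect_identical(cohort, simulate_cohort(cfg, rep_seed = 5))
  expect_false(identical(cohort$outcome,
                         simulate_cohort(cfg, rep_seed = 6)$outcome))
})

test_that("marginal covariate distributions match their generators", {
  cfg <- tiny_scenario(m = 100, n_mean = 100, total = 10000)
  cohort <- simulate_cohort(cfg, rep_seed = 9)
  se3 <- function(p, n) 3 * sqrt(p * (1 - p) / n)
  expect_lt(abs(mean(cohort$x1) - 0.4), se3(0.4, 10000))
  expect_lt(abs(mean(cohort$x2) - 0.45), se3(0.45, 10000))
  expect_lt(abs(mean(cohort$x3) - 0.5), se3(0.5, 10000))
  expect_lt(abs(mean(cohort$x4)), 3 / sqrt(10000))
  expect_lt(abs(mean(cohort$x6) - 0.5), se3(0.5, 10000))
})

test_that("intercept-only treatment model hits the prevalence target", {
  cfg <- null_covariate_scenario(total = 2000)
  cohort <- simulate_cohort(cfg, rep_seed = 3)
  expect_lt(abs(mean(cohort$treatment) - 0.5), 3 * sqrt(0.25 / 2000))
  expect_lt(abs(mean(cohort$outcome) - 0.5), 4 * sqrt(0.25 / 2000))
})

test_that("strong cluster confounding pushes treatment towards high-z1 clusters", {
  cfg <- tiny_scenario(m = 60, n_mean = 50, total = 3000, gamma_z = 0.9163)
  cohort <- simulate_cohort(cfg, rep_seed = 21)
  by_cluster <- cohort |>
    dplyr::group_by(cluster_id) |>
    dplyr::summarise(z1 = z1[1], p_treat = mean(treatment))
  ct <- cor.test(by_cluster$z1, by_cluster$p_treat, method = "spearman",
                 exact = FALSE)
  expect_gt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.01)
})

test_that("treatment prevalence is increasing in the calibrated intercept", {
  cfg <- calibrate_scenario(tiny_scenario(m = 20, n_mean = 100, total = 2000))
  prev <- vapply(c(-1, 0, 1), function(shift) {
    c2 <- cfg
    c2$alpha0 <- cfg$alpha0 + shift
    mean(simulate_cohort(c2, rep_seed = 8)$treatment)
  }, numeric(1))
  expect_true(all(diff(prev) > 0))
})

test_that("true effects: conditional is tau, marginal is attenuated", {
  cfg <- tiny_scenario()
  expect_identical(true_effect(cfg, "conditional_logor"), 0.4055)
  # null effect stays null on the marginal scale
  cfg0 <- tiny_scenario(tau = 0)
  expect_lt(abs(true_effect(cfg0, "marginal_logor", seed = 2)), 0.01)
  # with no covariate-driven outcome variation there is nothing to collapse
  cfgnull <- null_covariate_scenario()
  expect_equal(true_effect(cfgnull, "marginal_logor", seed = 2), 0.4055,
               tolerance = 0.02)
  # noncollapsibility: |marginal| <= |conditional| when covariates matter
  for (g in c(0.01, 0.4055, 0.9163)) {
    cfg_g <- tiny_scenario(gamma_z = g)
    expect_lt(abs(true_effect(cfg_g, "marginal_logor", seed = 3)),
              abs(cfg_g$tau))
  }
  rd <- true_effect(cfg, "risk_difference", seed = 4)
  expect_gt(rd, 0)
  expect_lt(rd, 0.2)
})

test_that("scenario grids round-trip through YAML", {
  grid <- make_scenario_grid(structures = list(c(10, 100), c(50, 20)),
                             gamma_z_grid = c(0.01, 0.9163))
  path <- withr::local_tempfile(fileext = ".yaml")
  scenario_grid_to_yaml(grid, path)
  back <- scenario_grid_from_yaml(path)
  expect_length(back, 4)
  expect_equal(purrr::map_dbl(back, "gamma_z"),
               purrr::map_dbl(grid, "gamma_z"))
  expect_equal(purrr::map_chr(back, "scenario_id"),
               purrr::map_chr(grid, "scenario_id"))
})
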