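test_that("nuisance forests are out-of-bag, clipped, and track null signals", {
  cfg <- null_covariate_scenario(total = 4000)
  cohort <- simulate_cohort(cfg, rep_seed = 6)
  nuis <- fit_nuisance_forests(cohort, options = fast_forest())
  expect_true(all(nuis$e_hat >= 0.02 & nuis$e_hat <= 0.98))
  # treatment independent of covariates at prevalence 0.5
  expect_lt(abs(mean(nuis$e_hat) - 0.5), 0.02)
  expect_lt(sd(nuis$e_hat), 0.06)
})

test_that("nuisance outcome forest learns a step function", {
  set.seed(3)
  n <- 4000
  d <- tibble::tibble(
    cluster_id = factor(rep(1:10, each = n / 10)),
    z1 = rnorm(n), z2 = rbinom(n, 1, 0.5),
    x1 = rbinom(n, 1, 0.4), x2 = rbinom(n, 1, 0.45),
    x3 = rbinom(n, 1, 0.5), x4 = rnorm(n), x5 = rnorm(n),
    x6 = rbinom(n, 1, 0.5), x7 = rbinom(n, 1, 0.5),
    treatment = rbinom(n, 1, 0.5)
  )
  d$outcome <- as.integer(d$x4 > 0)
  nuis <- fit_nuisance_forests(d, options = fast_forest())
  expect_lt(mean((nuis$y_hat - d$outcome)^2), 0.02)
})

test_that("honesty: leaf splits never depend on estimate-half responses", {
  cfg <- tiny_scenario(m = 10, n_mean = 40, total = 400)
  cohort <- simulate_cohort(cfg, rep_seed = 9)
  opts <- fast_forest(n_trees = 8, seed = 42)
  nuis <- fit_nuisance_forests(cohort, options = opts)
  cf1 <- fit_causal_forest(cohort, options = opts, nuisances = nuis)
  # perturb the outcome residual of a row used only for estimation in tree 1
  est_row <- cf1$trees[[1]]$est_rows[1] + 1  # 0-based from C++
  cohort2 <- cohort
  cohort2$outcome[est_row] <- 1 - cohort2$outcome[est_row]
  nuis2 <- nuis
  cf2 <- fit_causal_forest(cohort2, options = opts, nuisances = nuis2)
  for (b in seq_along(cf1$trees)) {
    in_split <- (est_row - 1) %in% cf1$trees[[b]]$split_rows
    if (!in_split) {
      expect_identical(cf1$trees[[b]]$feature, cf2$trees[[b]]$feature)
      expect_identical(cf1$trees[[b]]$threshold, cf2$trees[[b]]$threshold)
    }
  }
})

test_that("forest fits are deterministic under a fixed seed", {
  cfg <- tiny_scenario(m = 10, n_mean = 50, total = 500)
  cohort <- simulate_cohort(cfg, rep_seed = 10)
  a <- fit_causal_forest(cohort, options = fast_forest(n_trees = 20, seed = 5))
  b <- fit_causal_forest(cohort, options = fast_forest(n_trees = 20, seed = 5))
  expect_identical(predict_cate(a), predict_cate(b))
  expect_identical(average_treatment_effect(a), average_treatment_effect(b))
})

test_that("no spurious heterogeneity under a homogeneous effect", {
  cfg <- null_covariate_scenario(total = 6000)
  cohort <- simulate_cohort(cfg, rep_seed = 12)
  cf <- fit_causal_forest(cohort, options = fast_forest(seed = 2))
  tau_hat <- predict_cate(cf)
  rd_true <- true_effect(cfg, "risk_difference")
  # unbiased on average, residual spread is unstructured leaf noise: the
  # covariates explain almost none of it
  expect_lt(abs(mean(tau_hat) - rd_true), 0.05)
  expect_lt(sd(tau_hat), 0.15)
  r2 <- summary(stats::lm(tau_hat ~ ., data = as.data.frame(cf$X)))$r.squared
  expect_lt(r2, 0.1)
})

test_that("a two-subgroup effect is recovered on the risk-difference scale", {
  set.seed(8)
  n <- 6000
  d <- tibble::tibble(
    cluster_id = factor(rep(1:20, each = n / 20)),
    z1 = rnorm(n), z2 = rbinom(n, 1, 0.5),
    x1 = rbinom(n, 1, 0.5), x2 = rbinom(n, 1, 0.45),
    x3 = rbinom(n, 1, 0.5), x4 = rnorm(n), x5 = rnorm(n),
    x6 = rbinom(n, 1, 0.5), x7 = rbinom(n, 1, 0.5),
    treatment = rbinom(n, 1, 0.5)
  )
  effect <- ifelse(d$x1 == 1, 0.2, 0)
  d$outcome <- rbinom(n, 1, 0.3 + effect * d$treatment)
  cf <- fit_causal_forest(d, options = forest_options(n_trees = 150, seed = 4))
  tau_hat <- predict_cate(cf)
  expect_lt(abs(mean(tau_hat[d$x1 == 1]) - 0.2), 0.05)
  expect_lt(abs(mean(tau_hat[d$x1 == 0]) - 0.0), 0.05)
})

test_that("cluster subsampling keeps whole clusters and honesty by cluster", {
  cfg <- tiny_scenario(m = 10, n_mean = 60, total = 600)
  cohort <- simulate_cohort(cfg, rep_seed = 13)
  cf <- fit_causal_forest(cohort, options = fast_forest(n_trees = 10),
                          clusters = cohort$cluster_id)
  cl <- as.integer(cohort$cluster_id)
  for (tr in cf$trees) {
    bag_clusters <- cl[tr$inbag + 1]
    # whole clusters: every selected cluster appears with all its members
    for (c_id in unique(bag_clusters)) {
      expect_equal(sum(bag_clusters == c_id), sum(cl == c_id))
    }
    # honesty split respects cluster boundaries
    expect_length(
      intersect(cl[tr$split_rows + 1], cl[tr$est_rows + 1]), 0
    )
  }
})

test_that("external propensities replace the internal ones exactly", {
  cfg <- tiny_scenario(m = 10, n_mean = 50, total = 500)
  cohort <- simulate_cohort(cfg, rep_seed = 14)
  opts <- fast_forest(n_trees = 20, seed = 9)
  nuis <- fit_nuisance_forests(cohort, options = opts)
  cf <- fit_causal_forest(cohort, options = opts, nuisances = nuis)
  cf_ps <- fit_causal_forest(cohort, options = opts, nuisances = nuis,
                             external_ps = nuis$e_hat)
  expect_identical(average_treatment_effect(cf)$estimate,
                   average_treatment_effect(cf_ps)$estimate)
})

test_that("prediction is the mean over trees and equivariant to row order", {
  cfg <- tiny_scenario(m = 10, n_mean = 40, total = 400)
  cohort <- simulate_cohort(cfg, rep_seed = 15)
  cf <- fit_causal_forest(cohort, options = fast_forest(n_trees = 7, seed = 3))
  newd <- cohort[c(5, 1, 17), ]
  p <- predict_cate(cf, newd)
  per_tree <- vapply(seq_along(cf$trees), function(b) {
    one <- cf
    one$trees <- cf$trees[b]
    predict_cate(one, newd)
  }, numeric(3))
  expect_equal(p, rowMeans(per_tree))
  expect_equal(predict_cate(cf, cohort[c(17, 1, 5), ]), p[c(3, 2, 1)])
})

test_that("AIPW with oracle nuisances is unbiased and degenerates correctly", {
  # oracle check: true e, true y, true tau supplied
  cfg <- calibrate_scenario(tiny_scenario(m = 20, n_mean = 100, total = 2000,
                                          gamma_z = 0.9163))
  rd_true <- true_effect(cfg, "risk_difference")
  ests <- vapply(1:20, function(i) {
    cohort <- simulate_cohort(cfg, rep_seed = 500 + i)
    d <- cohort
    lp_t <- cfg$alpha0 +
      as.matrix(d[paste0("x", 1:5)]) %*% cfg$beta_x_treat +
      cfg$beta_instrument * d$x7 + cfg$gamma_z * (d$z1 + d$z2) +
      cfg$delta_interaction * d$z1 * d$x1
    e_true <- plogis(as.numeric(lp_t))
    lp_y0 <- cfg$lambda0 +
      as.matrix(d[paste0("x", 1:5)]) %*% cfg$beta_x_out +
      cfg$beta_riskfactor * d$x6 + cfg$gamma_z_out * (d$z1 + d$z2)
    p0 <- plogis(as.numeric(lp_y0))
    p1 <- plogis(as.numeric(lp_y0) + cfg$tau)
    tau_true <- p1 - p0
    y_marg <- p0 + e_true * tau_true
    aipw_ate(d$outcome, d$treatment, tau_true, e_true, y_marg,
             scale = "risk_difference")$estimate
  }, numeric(1))
  mcse <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - rd_true), 3 * mcse)
  # degenerate input: outcomes equal to the model predictions in both arms
  # make every influence score identical, so SE is 0 and the ATE is that
  # constant effect
  res <- aipw_ate(c(1, 1, 0.8, 0.8), c(1, 1, 0, 0), rep(0.2, 4),
                  rep(0.5, 4), rep(0.9, 4), scale = "risk_difference")
  expect_equal(res$se, 0)
  expect_equal(res$estimate, 0.2)
})

test_that("cluster-robust SEs exceed iid SEs for correlated scores", {
  set.seed(11)
  m <- 20
  cl <- rep(1:m, each = 50)
  shared <- rnorm(m)[cl]
  y <- as.integer(shared + rnorm(1000) > 0)
  # treatment constant within cluster: influence scores are positively
  # intra-cluster correlated
  t <- as.integer(cl <= m / 2)
  tau0 <- rep(0, 1000)
  e <- rep(0.5, 1000)
  yh <- rep(mean(y), 1000)
  iid <- aipw_ate(y, t, tau0, e, yh, scale = "risk_difference")
  rob <- aipw_ate(y, t, tau0, e, yh, clusters = cl,
                  scale = "risk_difference")
  expect_equal(iid$estimate, rob$estimate)
  expect_gt(rob$se, iid$se)
})

test_that("marginal log odds ratio scale matches its potential-outcome means", {
  cfg <- tiny_scenario(m = 10, n_mean = 60, total = 600)
  cohort <- simulate_cohort(cfg, rep_seed = 16)
  cf <- fit_causal_forest(cohort, options = fast_forest(n_trees = 30))
  rd <- average_treatment_effect(cf, scale = "risk_difference")
  lo <- average_treatment_effect(cf, scale = "marginal_logor")
  expect_equal(rd$estimate, rd$mu1 - rd$mu0)
  expect_equal(lo$estimate, qlogis(lo$mu1) - qlogis(lo$mu0))
  expect_equal(rd$mu1, lo$mu1)
})

test_that("tidy and glance expose the fitted forest", {
  cfg <- tiny_scenario(m = 10, n_mean = 40, total = 400)
  cohort <- simulate_cohort(cfg, rep_seed = 17)
  cf <- fit_causal_forest(cohort, options = fast_forest(n_trees = 10))
  td <- tidy(cf)
  expect_named(td, c("term", "estimate", "std.error", "conf.low",
                     "conf.high"))
  gl <- glance(cf)
  expect_equal(gl$n, 400)
  expect_equal(gl$n_trees, 10)
  expect_equal(gl$ps_source, "internal")
})
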