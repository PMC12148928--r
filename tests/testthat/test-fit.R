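# Inference: the Polya-Gamma Gibbs sampler, its determinism, prior
# recovery, and the likelihood switch under perfect detection.

test_that("fit is reproducible under a fixed seed and chain count", {
  dat <- sim_occu_data(reduced_config(n_species = 4, n_sites = 25, seed = 2))
  mc <- mcmc_control(n_chains = 2, n_burn = 50, n_keep = 30, thin = 1)
  f1 <- suppressWarnings(spfocc(dat, mcmc = mc, seed = 99))
  f2 <- suppressWarnings(spfocc(dat, mcmc = mc, seed = 99))
  expect_identical(f1$posterior$beta, f2$posterior$beta)
  expect_identical(f1$posterior$tau_occ, f2$posterior$tau_occ)
})

test_that("posterior matches the ML logistic oracle without latent structure", {
  # single species, perfect detection, no spatial term: the model is a
  # Bayesian logistic regression, so posterior means must sit within a few
  # posterior sds of the ML fit
  mod <- occu_model(occupancy = ~ age + area + arable, n_factors = 0,
                    perfect_detection = TRUE)
  cfg <- sim_config(n_species = 1, n_sites = 800, n_visits = 1, model = mod,
                    n_factors = 0, perfect_detection = TRUE,
                    missing_visit_rate = 0, seed = 3)
  dat <- sim_occu_data(cfg)
  fit <- suppressWarnings(
    spfocc(dat, mcmc = mcmc_control(n_chains = 2, n_burn = 400, n_keep = 300,
                                    thin = 1), seed = 5))
  ml <- glm.fit(fit$design$X, dat$y[1, , 1], family = binomial())$coefficients
  pm <- apply(fit$posterior$beta, 3, mean)
  ps <- apply(fit$posterior$beta, 3, sd)
  expect_true(all(abs(pm - ml) < 3 * ps))
})

test_that("fully masked data return the prior for the community intercept", {
  # With every visit masked the posterior is the prior.  The species-level
  # intercepts have an infinite-variance marginal prior (inverse-gamma(0.1,
  # 0.1) community variance), so their sample mean is not a stable
  # statistic; recovery is checked on the light-tailed community mean
  # (prior Normal(0, 2.7^2)) against its own Monte-Carlo standard error.
  mod <- occu_model(occupancy = ~ area + arable, detection = ~ day,
                    n_factors = 0)
  cfg <- sim_config(n_species = 10, n_sites = 2, n_visits = 2, model = mod,
                    n_factors = 0, seed = 42)
  dat <- sim_occu_data(cfg)
  dat$y[] <- NA_integer_
  fit <- suppressWarnings(
    spfocc(dat, mcmc = mcmc_control(n_chains = 4, n_burn = 500,
                                    n_keep = 2000, thin = 1), seed = 42))
  mu0 <- fit$posterior$mu_occ[, 1]
  ess <- effective_size(mu0, fit$posterior$chain)
  expect_lt(abs(mean(mu0)), 3.5 * 2.7 / sqrt(ess))
  # prior mass brackets zero and has the prior's spread
  b0 <- as.vector(fit$posterior$beta[, , 1])
  expect_lt(quantile(b0, 0.25), 0)
  expect_gt(quantile(b0, 0.75), 0)
})

test_that("simulate-then-fit recovers species slopes with near-nominal coverage", {
  dat <- sim_occu_data(reduced_config(n_species = 8, n_sites = 50, seed = 21))
  fit <- suppressWarnings(
    spfocc(dat, mcmc = mcmc_control(n_chains = 2, n_burn = 600, n_keep = 400,
                                    thin = 1), seed = 22))
  ci <- coef_intervals(fit, 0.95)
  tr <- dat$truth$occupancy_coeffs
  cover <- mean(tr >= ci[, , "lower"] & tr <= ci[, , "upper"])
  expect_gte(cover, 0.80)
})

test_that("a convergence warning of the documented class is raised when chains disagree", {
  dat <- sim_occu_data(reduced_config(n_species = 6, n_sites = 30, seed = 7))
  expect_warning(
    spfocc(dat, mcmc = mcmc_control(n_chains = 2, n_burn = 0, n_keep = 10,
                                    thin = 1), seed = 8),
    class = "spfocc_convergence")
})

test_that("spatial factor fits keep the loading constraint and reconstruct w", {
  dat <- sim_occu_data(reduced_config(n_species = 6, n_sites = 30, seed = 31,
                                      n_factors = 2))
  fit <- suppressWarnings(
    spfocc(dat, mcmc = mcmc_control(n_chains = 2, n_burn = 150, n_keep = 80,
                                    thin = 1), seed = 32))
  lam <- fit$posterior$lambda
  # unit diagonal, zero upper triangle in every draw
  expect_true(all(lam[, 1, 1] == 1))
  expect_true(all(lam[, 2, 2] == 1))
  expect_true(all(lam[, 1, 2] == 0))
  # stored scores have the declared dimensions
  expect_equal(dim(fit$posterior$scores)[2:3], c(2, 30))
})

test_that("methods give coherent summaries and predictions", {
  dat <- sim_occu_data(reduced_config(n_species = 5, n_sites = 30, seed = 17))
  fit <- suppressWarnings(
    spfocc(dat, mcmc = mcmc_control(n_chains = 2, n_burn = 200, n_keep = 100,
                                    thin = 1), seed = 18))
  cm <- coef(fit)
  expect_equal(dim(cm), c(5, 6))
  s <- summary(fit)
  expect_s3_class(s, "summary.spfocc")
  expect_equal(nrow(s$community_occupancy), 6)
  pr <- predict(fit, dat$site_covs[1:3, ])
  expect_equal(dim(pr$mean), c(5, 3))
  expect_true(all(pr$mean >= 0 & pr$mean <= 1))
  expect_true(all(pr$lower <= pr$upper))
  ft <- fitted(fit)
  expect_equal(dim(ft), c(5, 30))
  rs <- residuals(fit)
  expect_equal(dim(rs), c(5, 30))
  expect_true(all(is.finite(rs)))
})
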