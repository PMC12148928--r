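# Synthetic-data generator: determinism, covariate ranges, hierarchical
# coefficient draws, spatial GP factors, occupancy and detection layers.

test_that("covariate generation is deterministic under a fixed seed", {
  cfg <- reduced_config(seed = 1)
  expect_identical(sim_site_covariates(cfg), sim_site_covariates(cfg))
  d1 <- sim_occu_data(reduced_config(seed = 33, n_species = 5, n_sites = 20))
  d2 <- sim_occu_data(reduced_config(seed = 33, n_species = 5, n_sites = 20))
  expect_identical(d1$y, d2$y)
  expect_identical(d1$site_covs, d2$site_covs)
  expect_identical(d1$truth, d2$truth)
})

test_that("covariates respect published ranges and proportion bounds", {
  covs <- sim_site_covariates(reduced_config(n_sites = 134, seed = 8))
  expect_true(all(covs$area >= 0.5 & covs$area <= 31.9))
  props <- c("current_woodland", "old_woodland", "lost_woodland",
             "trees_outside", "arable")
  for (p in props) expect_true(all(covs[[p]] >= 0 & covs[[p]] <= 1))
  # old woodland is a fraction of current woodland: its landscape area
  # never exceeds the current woodland area
  expect_true(all(covs$old_woodland * covs$current_woodland <=
                    covs$current_woodland))
  expect_true(all(covs$shape >= 1))
  expect_setequal(unique(covs$country), c(0, 1))
})

test_that("two sites get two rows with distinct coordinates", {
  cfg <- reduced_config(n_sites = 2, seed = 5)
  covs <- sim_site_covariates(cfg)
  expect_equal(nrow(covs), 2)
  expect_false(all(covs$x[1] == covs$x[2] & covs$y[1] == covs$y[2]))
  expect_error(sim_config(n_sites = 1), "at least 2")
  expect_error(sim_config(n_species = 0), "positive")
})

test_that("community draws collapse to the means at sd 0 and obey the CLT", {
  cfg <- reduced_config(n_species = 6, seed = 2)
  cfg$community_sds$occupancy[] <- 0
  cfg$community_sds$detection[] <- 0
  par <- sim_community_params(cfg)
  for (i in 2:6) {
    expect_equal(par$occupancy_coeffs[i, ], par$occupancy_coeffs[1, ])
  }
  expect_equal(unname(par$occupancy_coeffs[1, ]),
               unname(cfg$community_means$occupancy))
  # CLT: column mean of 2000 Normal(0.7, 0.5) draws within 4 sd/sqrt(n)
  cfg2 <- reduced_config(n_species = 2000, seed = 6)
  cfg2$community_means$occupancy[] <- 0.7
  cfg2$community_sds$occupancy[] <- 0.5
  par2 <- sim_community_params(cfg2)
  expect_true(all(abs(colMeans(par2$occupancy_coeffs) - 0.7) <
                    4 * 0.5 / sqrt(2000)))
  # reproducibility
  expect_identical(sim_community_params(cfg2), sim_community_params(cfg2))
  cfg$community_sds$occupancy[1] <- -1
  expect_error(sim_community_params(cfg), "non-negative")
})

test_that("spatial GP factors have unit variance, vanish correlation at high decay, and share scores at distance 0", {
  coords <- data.frame(x = c(0, 10, 35, 60), y = c(0, 5, 20, 40))
  # decay -> infinity: scores at distinct sites uncorrelated over replicates
  set.seed(4)
  reps <- t(sapply(1:2500, function(r)
    sim_spatial_factors(coords, 1, spatial_decay = 1e6)[1, ]))
  cc <- cor(reps)
  expect_true(all(abs(cc[upper.tri(cc)]) < 0.08))
  # unit marginal variance at a single site
  expect_equal(unname(apply(reps, 2, var)), rep(1, 4), tolerance = 0.15)
  # coincident sites with the zero-jitter override: identical scores
  co2 <- data.frame(x = c(3, 3, 9), y = c(1, 1, 4))
  sc <- sim_spatial_factors(co2, 2, spatial_decay = 0.1, seed = 2, jitter = 0)
  expect_equal(sc[, 1], sc[, 2], tolerance = 1e-6)
  expect_error(sim_spatial_factors(coords, 1, spatial_decay = 0), "positive")
})

test_that("occupancy states follow the logistic model", {
  cfg <- reduced_config(n_species = 1, n_sites = 50, seed = 3)
  covs <- sim_site_covariates(cfg)
  par <- sim_community_params(cfg)
  # eta = +inf proxy: huge intercept forces z = 1
  par$occupancy_coeffs[] <- 0
  par$occupancy_coeffs[, 1] <- 50
  z <- sim_occupancy_states(par, covs, cfg$model, seed = 1)
  expect_true(all(z == 1))
  # all coefficients 0: occupancy rate 0.5
  par$occupancy_coeffs[] <- 0
  set.seed(2)
  zs <- replicate(200, mean(sim_occupancy_states(par, covs, cfg$model)))
  expect_equal(mean(zs), 0.5, tolerance = 0.02)
  # b0 = 1: rate = inverse-logit(1) = 0.731 over 10,000 site-draws
  par$occupancy_coeffs[, 1] <- 1
  set.seed(7)
  zs <- replicate(200, mean(sim_occupancy_states(par, covs, cfg$model)))
  expect_equal(mean(zs), plogis(1), tolerance = 0.02)
  # dimension mismatch rejected
  par$occupancy_coeffs <- par$occupancy_coeffs[, 1:3, drop = FALSE]
  expect_error(sim_occupancy_states(par, covs, cfg$model), "match")
})

test_that("detection histories admit no false positives and match fixed P", {
  cfg <- reduced_config(n_species = 2, n_sites = 40, seed = 9,
                        missing_visit_rate = 0)
  covs <- sim_site_covariates(cfg)
  vc <- sim_visit_covariates(cfg)
  par <- sim_community_params(cfg)
  z0 <- matrix(0L, 2, 40)
  y <- sim_detection_histories(z0, vc, par, cfg, seed = 1)
  expect_true(all(y == 0, na.rm = TRUE))
  # a0 huge (P = 1) and z = 1: every visit detects
  z1 <- matrix(1L, 2, 40)
  par$detection_coeffs[] <- 0
  par$detection_coeffs[, 1] <- 50
  y1 <- sim_detection_histories(z1, vc, par, cfg, seed = 2)
  expect_true(all(y1 == 1, na.rm = TRUE))
  # P = 0.3 fixed, z = 1: detection frequency 0.3 over >= 10,000 trials
  cfg2 <- reduced_config(n_species = 100, n_sites = 40, seed = 10,
                         missing_visit_rate = 0)
  par2 <- sim_community_params(cfg2)
  par2$detection_coeffs[] <- 0
  par2$detection_coeffs[, 1] <- qlogis(0.3)
  zb <- matrix(1L, 100, 40)
  yb <- sim_detection_histories(zb, sim_visit_covariates(cfg2), par2, cfg2,
                                seed = 3)
  expect_equal(mean(yb), 0.3, tolerance = 0.015)
})

test_that("naive occupancy never exceeds true occupancy and masks are NA", {
  dat <- sim_occu_data(reduced_config(n_species = 10, n_sites = 50, seed = 12,
                                      missing_visit_rate = 0.15))
  naive <- apply(dat$y, 1, function(m) mean(apply(m, 1, function(v)
    any(v == 1, na.rm = TRUE))))
  true_occ <- rowMeans(dat$truth$z)
  expect_true(all(naive <= true_occ + 1e-12))
  # no detections where z = 0
  det <- apply(dat$y, c(1, 2), function(v) any(v == 1, na.rm = TRUE))
  expect_true(all(det[dat$truth$z == 0] == FALSE))
  # missing visits are NA for every species at once
  nas <- apply(dat$y, c(2, 3), function(v) mean(is.na(v)))
  expect_true(all(nas %in% c(0, 1)))
  expect_gt(mean(nas), 0)
})

test_that("without spatial factors, occupancy states are independent across sites", {
  cfg <- reduced_config(n_species = 1, n_sites = 6, seed = 14, n_factors = 0)
  covs <- sim_site_covariates(cfg)
  par <- sim_community_params(cfg)
  set.seed(15)
  zrep <- t(replicate(600, sim_occupancy_states(par, covs, cfg$model)[1, ]))
  p <- suppressWarnings(stats::chisq.test(table(zrep[, 1], zrep[, 2]))$p.value)
  expect_gt(p, 0.01)
})
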