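# Counterfactual scenario machinery: grids, assemblage simulation,
# richness summaries, response curves, probability of direction.

test_that("scenario grids are full factorials plus one background", {
  g3 <- scenario_grid(list(current_woodland = c(0.01, 0.3),
                           old_woodland = c(0.01, 0.85),
                           arable = c(0.01, 0.9)), n_draws = 10)
  expect_length(g3, 2^3 + 1)
  expect_equal(g3[[length(g3)]]$label, "background")
  g1 <- scenario_grid(list(arable = c(0.01, 0.9)), n_draws = 10)
  expect_length(g1, 3)
  # every non-background scenario fixes area at the 3.5-ha mean
  expect_true(all(vapply(g1, function(s) identical(s$fixed$area, 3.5),
                         logical(1))))
  expect_error(scenario_grid(list(arable = c(0.01, 0.5, 0.9))), "two levels")
  expect_error(scenario_spec(fixed = list(arable = 1, arable = 2)),
               "duplicate")
})

test_that("levels outside the observed covariate range are flagged", {
  dat <- data.frame(arable = runif(50, 0.2, 0.6))
  expect_warning(scenario_grid(list(arable = c(0.01, 0.9)), data = dat),
                 "outside the observed range")
  expect_silent(invisible(
    scenario_grid(list(arable = c(0.25, 0.55)), area = NULL, data = dat)))
  expect_error(scenario_grid(list(nope = c(0, 1)), data = dat), "unknown")
})

test_that("assemblage simulation follows the per-draw Bernoulli law", {
  # degenerate posterior: all coefficients 0 except the intercept
  coefs <- cbind(`(Intercept)` = c(0.6, -0.4), x = c(0, 0))
  post <- degenerate_posterior(coefs, n_draws = 20000)
  dat <- data.frame(x = rnorm(50))
  mod <- occu_model(occupancy = ~ x, n_factors = 0, perfect_detection = TRUE)
  sc <- scenario_spec(n_draws = 20000)
  ens <- simulate_assemblages(post, sc, seed = 1, data = dat, model = mod)
  rate <- colMeans(ens$presence)
  # 3.5 binomial standard errors at n = 20,000
  expect_lt(abs(rate[1] - plogis(0.6)), 0.0125)
  expect_lt(abs(rate[2] - plogis(-0.4)), 0.0125)
  # psi = 1 for every species: each assemblage is the full species list
  post1 <- degenerate_posterior(cbind(`(Intercept)` = c(60, 60), x = c(0, 0)),
                                n_draws = 200)
  ens1 <- simulate_assemblages(post1, scenario_spec(n_draws = 200), seed = 2,
                               data = dat, model = mod)
  expect_true(all(ens1$presence == 1))
  # fixed seed reproduces the ensemble exactly
  e1 <- simulate_assemblages(post, scenario_spec(n_draws = 500), seed = 9,
                             data = dat, model = mod)
  e2 <- simulate_assemblages(post, scenario_spec(n_draws = 500), seed = 9,
                             data = dat, model = mod)
  expect_identical(e1$presence, e2$presence)
  # unknown fixed predictor rejected; draw budget enforced
  expect_error(simulate_assemblages(post, scenario_spec(fixed = list(zz = 1),
                                                        n_draws = 10),
                                    data = dat, model = mod), "not in the model")
  expect_error(simulate_assemblages(post1, scenario_spec(n_draws = 1000),
                                    data = dat, model = mod), "recycle")
})

test_that("species richness summarises rows with smallest-value tie-breaking", {
  ones <- matrix(1L, 40, 7)
  r <- species_richness(ones)
  expect_true(all(r$richness == 7))
  expect_equal(r$mode, 7)
  zero <- matrix(0L, 10, 4)
  expect_equal(species_richness(zero)$mode, 0)
  # explicit tie: counts of 1 and 2 equal; mode must be the smaller
  m <- rbind(matrix(c(1, 0, 0), 3, 3, byrow = TRUE),
             matrix(c(1, 1, 0), 3, 3, byrow = TRUE))
  expect_equal(species_richness(m)$mode, 1)
  # Binomial(10, 0.5) mean within 3 standard errors over 20,000 draws
  coefs <- cbind(`(Intercept)` = rep(0, 10))
  post <- degenerate_posterior(coefs, n_draws = 20000)
  mod <- occu_model(occupancy = ~ 1, n_factors = 0, perfect_detection = TRUE)
  ens <- simulate_assemblages(post, scenario_spec(n_draws = 20000), seed = 3,
                              data = data.frame(x = 1:5), model = mod)
  r2 <- species_richness(ens)
  se <- sd(r2$richness) / sqrt(length(r2$richness))
  expect_lt(abs(r2$mean - 5), 3 * se)
})

test_that("analytic expected richness matches hand values and Monte Carlo", {
  fake <- structure(list(psi = matrix(c(0.2, 0.7), 1)),
                    class = "assemblage_ensemble")
  expect_equal(expected_richness(fake), 0.9)
  fake1 <- structure(list(psi = matrix(1, 5, 8)), class = "assemblage_ensemble")
  expect_equal(expected_richness(fake1), 8)
  fake0 <- structure(list(psi = matrix(0, 5, 8)), class = "assemblage_ensemble")
  expect_equal(expected_richness(fake0), 0)
  # Monte-Carlo richness vs analytic expectation, within 3 SE per scenario
  set.seed(4)
  coefs <- cbind(`(Intercept)` = rnorm(12, -0.2, 0.8),
                 arable = rnorm(12, -0.5, 0.3))
  post <- degenerate_posterior(coefs, n_draws = 5000)
  dat <- data.frame(arable = runif(100))
  mod <- occu_model(occupancy = ~ arable, n_factors = 0,
                    perfect_detection = TRUE)
  for (sc in scenario_grid(list(arable = c(0.05, 0.95)), area = NULL,
                           n_draws = 5000, data = dat)) {
    ens <- simulate_assemblages(post, sc, seed = 5, data = dat, model = mod)
    r <- species_richness(ens)
    se <- sd(r$richness) / sqrt(length(r$richness))
    expect_lt(abs(r$mean - expected_richness(ens)), 3 * se)
  }
})

test_that("uniformly positive slopes make the high scenario richer", {
  set.seed(6)
  coefs <- cbind(`(Intercept)` = rnorm(10, 0, 0.5),
                 arable = runif(10, 0.5, 1.5))   # all-positive slopes
  post <- degenerate_posterior(coefs, n_draws = 4000)
  dat <- data.frame(arable = runif(80, -2, 2))
  mod <- occu_model(occupancy = ~ arable, n_factors = 0,
                    perfect_detection = TRUE)
  lo <- simulate_assemblages(post, scenario_spec(list(arable = -1.5),
                                                 n_draws = 4000),
                             seed = 7, data = dat, model = mod)
  hi <- simulate_assemblages(post, scenario_spec(list(arable = 1.5),
                                                 n_draws = 4000),
                             seed = 7, data = dat, model = mod)
  expect_gt(expected_richness(hi), expected_richness(lo))
})

test_that("the background ensemble is the empty-fixed-set code path", {
  coefs <- cbind(`(Intercept)` = c(0.2, -0.2), arable = c(0.5, -0.5))
  post <- degenerate_posterior(coefs, n_draws = 300)
  dat <- data.frame(arable = runif(40))
  mod <- occu_model(occupancy = ~ arable, n_factors = 0,
                    perfect_detection = TRUE)
  bg <- simulate_assemblages(post, scenario_spec(label = "background",
                                                 n_draws = 300),
                             seed = 11, data = dat, model = mod)
  empty <- simulate_assemblages(post, scenario_spec(fixed = list(),
                                                    n_draws = 300),
                                seed = 11, data = dat, model = mod)
  expect_identical(bg$presence, empty$presence)
})

test_that("marginal response curves follow the posterior-mean logistic", {
  # flat slope: constant curve at invlogit(mean b0)
  coefs <- cbind(`(Intercept)` = c(0.8), area = c(0))
  post <- degenerate_posterior(coefs, n_draws = 100)
  dat <- data.frame(area = seq(-3, 3, length.out = 30))
  rc <- response_curve(post, "area", data = dat, n = 20)
  expect_true(all(abs(rc$psi - plogis(0.8)) < 1e-12))
  # positive slope: strictly increasing; value at x_scaled = 2 is 0.8808
  post2 <- degenerate_posterior(cbind(`(Intercept)` = 0, area = 1), 100)
  rc2 <- response_curve(post2, "area", data = dat, n = 50)
  expect_true(all(diff(rc2$psi[, 1]) > 0))
  at2 <- response_curve(post2, "area", grid = 2, data = dat)
  expect_equal(at2$psi[1, 1], plogis(2), tolerance = 1e-12)
  expect_equal(at2$psi[1, 1], 0.8808, tolerance = 1e-4)
  # grid beyond the observed range is rejected
  expect_error(response_curve(post2, "area", grid = 5, data = dat),
               "observed range")
  expect_error(response_curve(post2, "nope", data = dat), "not in the")
})

test_that("probability of direction counts the dominant sign", {
  expect_equal(prob_direction(c(0.2, 0.5, 1.3)), 1.0)
  expect_equal(prob_direction(c(-1, 1)), 0.5)
  expect_equal(prob_direction(c(1, 1, 1, -1)), 0.75)
  expect_equal(prob_direction(c(0, 0)), 0.5)      # zeros split evenly
  expect_error(prob_direction(numeric(0)), "empty")
})
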