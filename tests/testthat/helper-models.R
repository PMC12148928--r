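# Shared reduced-model builders used across the suite.

# intercept + 4 occupancy predictors + 1 interaction, 2 detection covariates
reduced_model <- function(n_factors = 0, perfect_detection = FALSE) {
  occu_model(
    occupancy = ~ age + area + current_woodland + arable + area:arable,
    detection = ~ day + year,
    n_factors = n_factors,
    perfect_detection = perfect_detection)
}

reduced_config <- function(n_species = 15, n_sites = 60, n_visits = 3,
                           seed = 1, n_factors = 0, ...) {
  sim_config(n_species = n_species, n_sites = n_sites, n_visits = n_visits,
             model = reduced_model(n_factors), n_factors = n_factors,
             seed = seed, ...)
}

# a posterior whose every draw has identical, hand-chosen coefficients
degenerate_posterior <- function(coefs, n_draws = 1000, occ_names = NULL) {
  N <- nrow(coefs); P <- ncol(coefs)
  beta <- array(rep(coefs, each = n_draws), c(n_draws, N, P))
  community_posterior(beta = beta,
                      occ_names = if (is.null(occ_names)) colnames(coefs)
                                  else occ_names)
}
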