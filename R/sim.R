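# Synthetic community data with the statistical structure the joint model
# assumes: hierarchical species coefficients, latent spatial GP factors,
# Bernoulli detection conditional on latent occupancy.  Ground truth is
# returned alongside the data for recovery experiments.

# design column names implied by a formula, without data in hand
.design_names <- function(formula) {
  vars <- all.vars(formula)
  dummy <- as.data.frame(setNames(rep(list(c(0, 1)), length(vars)), vars))
  colnames(model.matrix(formula, dummy))
}

.default_community <- function(names, intercept_mean, intercept_sd,
                               slope_mean = 0, slope_sd = 0.5) {
  m <- setNames(rep(slope_mean, length(names)), names)
  s <- setNames(rep(slope_sd, length(names)), names)
  m[["(Intercept)"]] <- intercept_mean
  s[["(Intercept)"]] <- intercept_sd
  list(mean = m, sd = s)
}

#' Configuration for the synthetic-data generator
#'
#' Defines the study conditions the generator emulates: community size and
#' survey effort in the range of the woodland surveys (tens of species,
#' 60-134 sites in two regions, 2-4 visits), community-level means and
#' standard deviations from which species coefficients are drawn, the
#' latent spatial factor structure, and the missing-visit rate.
#'
#' @param n_species,n_sites,n_visits community and survey dimensions.
#' @param model an [occu_model()] giving the occupancy/detection formulas;
#'   its `n_factors`, `perfect_detection` and `spatial_decay` are overridden
#'   by the arguments here so a config is self-contained.
#' @param community_means,community_sds lists with elements `occupancy` and
#'   `detection`: named vectors, one entry per design column.  Defaults:
#'   occupancy intercepts Normal(-0.3, 1), slopes Normal(0, 0.5); detection
#'   intercepts Normal(0.5, 0.7), slopes Normal(0, 0.3).
#' @param n_factors number of latent spatial factors (default 3).
#' @param spatial_decay exponential GP decay per km (default 0.05, an
#'   effective range of about 60 km — within-region correlation only).
#' @param factor_loading_scale sd of the free factor loadings; the GP has
#'   unit marginal variance, so amplitude lives in the loadings.
#' @param missing_visit_rate probability a site-visit is not surveyed.
#' @param perfect_detection single exhaustive survey (plants): the
#'   detection layer is dropped and the presence record equals occupancy.
#' @param seed integer seed making the whole dataset reproducible.
#' @return object of class `"sim_config"`.
#' @export
sim_config <- function(n_species = 20, n_sites = 60, n_visits = 3,
                       model = occu_model(),
                       community_means = NULL, community_sds = NULL,
                       n_factors = 3, spatial_decay = 0.05,
                       factor_loading_scale = 0.5,
                       missing_visit_rate = 0.05,
                       perfect_detection = FALSE, seed = NULL) {
  if (n_species < 1 || n_sites < 2 || n_visits < 1)
    stop("n_species, n_visits must be positive and n_sites at least 2")
  if (missing_visit_rate < 0 || missing_visit_rate >= 1)
    stop("missing_visit_rate must be in [0, 1)")
  if (n_factors > n_species)
    stop("n_factors cannot exceed n_species")
  model <- occu_model(occupancy = model$occupancy,
                      detection = model$detection,
                      n_factors = n_factors,
                      perfect_detection = perfect_detection,
                      spatial_decay = spatial_decay)
  occ_names <- .design_names(model$occupancy)
  det_names <- if (perfect_detection) character(0) else
    .design_names(model$detection)
  if (is.null(community_means) || is.null(community_sds)) {
    occ_def <- .default_community(occ_names, -0.3, 1, 0, 0.5)
    det_def <- .default_community(det_names, 0.5, 0.7, 0, 0.3)
    if (is.null(community_means))
      community_means <- list(occupancy = occ_def$mean, detection = det_def$mean)
    if (is.null(community_sds))
      community_sds <- list(occupancy = occ_def$sd, detection = det_def$sd)
  }
  if (length(community_means$occupancy) != length(occ_names) ||
      length(community_sds$occupancy) != length(occ_names))
    stop("occupancy community means/sds must have one entry per design column (",
         length(occ_names), ")")
  if (!perfect_detection &&
      (length(community_means$detection) != length(det_names) ||
       length(community_sds$detection) != length(det_names)))
    stop("detection community means/sds must have one entry per design column (",
         length(det_names), ")")
  if (any(unlist(community_sds) < 0))
    stop("community sds must be non-negative")
  structure(list(n_species = as.integer(n_species),
                 n_sites = as.integer(n_sites),
                 n_visits = as.integer(n_visits),
                 model = model,
                 community_means = community_means,
                 community_sds = community_sds,
                 factor_loading_scale = factor_loading_scale,
                 missing_visit_rate = missing_visit_rate,
                 seed = seed),
            class = "sim_config")
}

#' Generate site-scale and landscape-scale covariates
#'
#' Sites are placed uniformly in two disjoint rectangular regions
#' (coordinates in km; `country` labels the region).  Patch area is
#' log-uniform over 0.5-31.9 ha; proportion-type landscape covariates are
#' scaled Beta draws linked through a Gaussian copula so that, e.g., old
#' woodland correlates with current woodland — giving the collinearity
#' screen something to detect.  Old woodland is the fraction of the current
#' woodland that is old, so its landscape area never exceeds the current
#' woodland area.
#'
#' @param config a [sim_config()].
#' @param seed optional seed overriding `config$seed`.
#' @return data frame with one row per site: `site`, `country` (0/1),
#'   `x`, `y` (km), `age` (years), `area` (ha), `shape`, `structure`
#'   (sd of tree DBH, cm), `current_woodland`, `old_woodland`,
#'   `lost_woodland`, `trees_outside`, `arable` (proportions),
#'   `livestock` (livestock units per ha of grassland).
#' @export
sim_site_covariates <- function(config, seed = config$seed) {
  if (!inherits(config, "sim_config")) stop("config must be a sim_config")
  n <- config$n_sites
  if (n < 2) stop("need at least 2 sites")
  if (!is.null(seed)) set.seed(seed)
  n_a <- ceiling(n / 2)
  country <- c(rep(0L, n_a), rep(1L, n - n_a))
  x <- ifelse(country == 0L, runif(n, 0, 80), runif(n, 0, 95))
  y <- ifelse(country == 0L, runif(n, 120, 210), runif(n, 0, 90))

  # Gaussian copula over the six landscape covariates
  vars <- c("current_woodland", "old_woodland", "trees_outside",
            "lost_woodland", "arable", "livestock")
  R <- diag(6)
  dimnames(R) <- list(vars, vars)
  R["current_woodland", "old_woodland"] <- R["old_woodland", "current_woodland"] <- 0.5
  R["current_woodland", "trees_outside"] <- R["trees_outside", "current_woodland"] <- 0.35
  R["arable", "livestock"] <- R["livestock", "arable"] <- -0.3
  L <- chol(R)
  u <- pnorm(matrix(rnorm(n * 6), n, 6) %*% L)
  colnames(u) <- vars

  data.frame(
    site = seq_len(n),
    country = country,
    x = x, y = y,
    age = ifelse(runif(n) < 0.8, runif(n, 10, 160), runif(n, 250, 350)),
    area = exp(runif(n, log(0.5), log(31.9))),
    shape = 1 + rgamma(n, shape = 2, scale = 0.25),
    structure = rgamma(n, shape = 4, scale = 2.5),
    current_woodland = stats::qbeta(u[, "current_woodland"], 1.5, 6),
    old_woodland = stats::qbeta(u[, "old_woodland"], 1.05, 1.2),
    lost_woodland = stats::qbeta(u[, "lost_woodland"], 1.2, 5),
    trees_outside = stats::qbeta(u[, "trees_outside"], 1.5, 10),
    arable = stats::qbeta(u[, "arable"], 0.9, 0.9),
    livestock = stats::rlnorm(n, meanlog = log(0.8), sdlog = 0.6)
  )
}

#' Draw species-level coefficients from the community distributions
#'
#' Each species' coefficient for predictor k is Normal(community mean k,
#' community sd k), independently across species and predictors — the
#' hierarchical structure the model assumes.  Free factor loadings are
#' Normal(0, `factor_loading_scale`^2) under the lower-triangular
#' unit-diagonal identifiability constraint.
#'
#' @inheritParams sim_site_covariates
#' @return list with `occupancy_coeffs` (species x coefficients),
#'   `detection_coeffs`, and `factor_loadings` (species x n_factors).
#' @export
sim_community_params <- function(config, seed = config$seed) {
  if (!inherits(config, "sim_config")) stop("config must be a sim_config")
  if (any(unlist(config$community_sds) < 0)) stop("community sds must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  draw_block <- function(means, sds, n) {
    out <- sapply(seq_along(means), function(k) rnorm(n, means[k], sds[k]))
    out <- matrix(out, nrow = n)
    colnames(out) <- names(means)
    out
  }
  n <- config$n_species
  f <- config$model$n_factors
  lam <- matrix(0, n, f)
  if (f > 0) {
    for (i in seq_len(n)) for (j in seq_len(f)) {
      if (i == j) lam[i, j] <- 1
      else if (j < i || i > f)
        lam[i, j] <- rnorm(1, 0, config$factor_loading_scale)
    }
    lam[upper.tri(lam)] <- 0
  }
  list(
    occupancy_coeffs = draw_block(config$community_means$occupancy,
                                  config$community_sds$occupancy, n),
    detection_coeffs = if (config$model$perfect_detection) NULL else
      draw_block(config$community_means$detection,
                 config$community_sds$detection, n),
    factor_loadings = lam
  )
}

#' Draw latent spatial factor scores from a Gaussian process
#'
#' Each factor is one realisation of a zero-mean GP over the sites with
#' exponential correlation \eqn{\exp(-\phi d)} and unit marginal variance.
#' Sampling uses the (symmetric) eigendecomposition of the jittered
#' correlation matrix, so exactly coincident sites (with `jitter = 0`)
#' yield identical scores rather than an error.
#'
#' @param coordinates matrix or data frame with columns `x`, `y`.
#' @param n_factors number of independent GP draws.
#' @param spatial_decay positive decay \eqn{\phi} (1/distance units).
#' @param seed optional RNG seed.
#' @param jitter diagonal jitter added for numerical positive-definiteness.
#' @return n_factors x n_sites matrix of factor scores.
#' @export
sim_spatial_factors <- function(coordinates, n_factors, spatial_decay,
                                seed = NULL, jitter = 1e-8) {
  coords <- as.matrix(as.data.frame(coordinates)[, c("x", "y")])
  if (nrow(coords) < 2) stop("need at least 2 sites")
  if (spatial_decay <= 0) stop("spatial_decay must be positive")
  if (n_factors == 0) return(matrix(0, 0, nrow(coords)))
  if (!is.null(seed)) set.seed(seed)
  C <- exp(-spatial_decay * as.matrix(dist(coords))) + jitter * diag(nrow(coords))
  ev <- eigen(C, symmetric = TRUE)
  Lh <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), nrow(coords))
  t(sapply(seq_len(n_factors), function(f) drop(Lh %*% rnorm(nrow(coords)))))
}

#' Draw latent occupancy states
#'
#' \eqn{z_{ij} \sim Bernoulli(logit^{-1}(x_j' b_i + w_i(s_j)))}: the full
#' occupancy linear predictor (standardised covariates, interactions from
#' scaled mains, country indicator) plus the species' spatial effect.
#'
#' @param params coefficient list from [sim_community_params()].
#' @param covariates raw site covariate table ([sim_site_covariates()]).
#' @param model an [occu_model()].
#' @param w optional species x sites matrix of spatial effects (default 0).
#' @param seed optional RNG seed.
#' @param standardize centre/scale the formula's numeric covariates first
#'   (default TRUE; set FALSE if `covariates` are already standardised).
#' @return binary species x sites matrix with attribute `"psi"`, the
#'   occupancy probabilities used.
#' @export
sim_occupancy_states <- function(params, covariates, model = occu_model(),
                                 w = NULL, seed = NULL, standardize = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  if (standardize) {
    cols <- .scalable_vars(model$occupancy, covariates)
    if (length(cols)) covariates <- center_scale(covariates, cols)$table
  }
  X <- .occu_design(covariates, model)
  b <- params$occupancy_coeffs
  if (ncol(b) != ncol(X))
    stop("occupancy coefficient count ", ncol(b),
         " does not match design columns ", ncol(X))
  eta <- b %*% t(X)
  if (!is.null(w)) {
    if (!all(dim(w) == dim(eta))) stop("w must be species x sites")
    eta <- eta + w
  }
  psi <- .invlogit(eta)
  z <- matrix(rbinom(length(psi), 1, psi), nrow(psi), ncol(psi))
  attr(z, "psi") <- psi
  z
}

# numeric, non-indicator variables of a formula present in the table
.scalable_vars <- function(formula, table) {
  vars <- intersect(all.vars(formula), names(table))
  vars[vapply(vars, function(v) {
    x <- table[[v]]
    is.numeric(x) && !all(x %in% c(0, 1)) && sd(x) > 0
  }, logical(1))]
}

#' Generate visit-level detection covariates
#'
#' Ordinal day is uniform over a season window (days 120-200); survey year
#' (0/1) is a site-level property — each site is surveyed in a single year;
#' the taxon-specific covariate `var4` is a per-site trap count, an integer
#' between 3 and 15.
#'
#' @inheritParams sim_site_covariates
#' @return long data frame: `site`, `visit`, `day`, `year`, `var4`.
#' @export
sim_visit_covariates <- function(config, seed = config$seed) {
  if (!inherits(config, "sim_config")) stop("config must be a sim_config")
  if (!is.null(seed)) set.seed(seed)
  J <- config$n_sites; K <- config$n_visits
  year_site <- rbinom(J, 1, 0.5)
  traps_site <- sample(3:15, J, replace = TRUE)
  data.frame(
    site = rep(seq_len(J), each = K),
    visit = rep(seq_len(K), J),
    day = round(runif(J * K, 120, 200)),
    year = rep(year_site, each = K),
    var4 = rep(traps_site, each = K)
  )
}

#' Draw detection histories conditional on latent occupancy
#'
#' \eqn{Y_{ijk} \sim Bernoulli(P_{ijk} z_{ij})}: a species can only be
#' detected where it is present (no false positives).  Missing visits are
#' masked as NA across all species at the affected site-visit, never coded
#' as zeros.  Under perfect detection the record is a single exhaustive
#' survey: \eqn{Y_{ij} = z_{ij}}.
#'
#' @param z binary species x sites occupancy matrix.
#' @param visit_covs long visit covariate table ([sim_visit_covariates()]);
#'   its numeric non-indicator columns are standardised before forming the
#'   detection design.
#' @param params coefficient list with `detection_coeffs`.
#' @param config a [sim_config()].
#' @param seed optional RNG seed.
#' @return species x sites x visits binary array (NA = missing visit), with
#'   attribute `"p"`, the detection probabilities used.
#' @export
sim_detection_histories <- function(z, visit_covs, params, config,
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  N <- nrow(z); J <- ncol(z); K <- config$n_visits
  if (config$model$perfect_detection) {
    y <- array(z, dim = c(N, J, 1L))
    attr(y, "p") <- NULL
    return(y)
  }
  vc <- visit_covs
  cols <- .scalable_vars(config$model$detection, vc)
  if (length(cols)) vc <- center_scale(vc, cols)$table
  V <- .det_design(vc, config$model)
  a <- params$detection_coeffs
  if (ncol(a) != ncol(V))
    stop("detection coefficient count ", ncol(a),
         " does not match design columns ", ncol(V))
  p_flat <- .invlogit(a %*% t(V))   # N x (J*K), rows of V follow visit_covs
  y <- array(NA_integer_, dim = c(N, J, K))
  p <- array(NA_real_, dim = c(N, J, K))
  for (r in seq_len(nrow(vc))) {
    j <- visit_covs$site[r]; k <- visit_covs$visit[r]
    p[, j, k] <- p_flat[, r]
    y[, j, k] <- rbinom(N, 1, p_flat[, r] * z[, j])
  }
  if (config$missing_visit_rate > 0) {
    mask <- matrix(runif(J * K) < config$missing_visit_rate, J, K)
    for (j in seq_len(J)) for (k in seq_len(K))
      if (mask[j, k]) y[, j, k] <- NA_integer_
  }
  attr(y, "p") <- p
  y
}

#' Generate a complete synthetic occupancy dataset with known truth
#'
#' Runs the full generative process under one seed: site covariates,
#' community-draw coefficients, spatial GP factor scores, latent occupancy,
#' visit covariates, and detection histories.  The returned truth bundle
#' holds every latent quantity for parameter-recovery testing.
#'
#' @param config a [sim_config()].
#' @return object of class `"occu_data"`: `y` (species x sites x visits,
#'   NA-masked), `site_covs`, `visit_covs`, `coords`, `model`, `config`,
#'   and `truth` (coefficients, loadings, factor scores, `w`, `z`, `psi`).
#' @examples
#' dat <- sim_occu_data(sim_config(n_species = 5, n_sites = 20, seed = 1))
#' dim(dat$y)
#' @export
sim_occu_data <- function(config) {
  if (!inherits(config, "sim_config")) stop("config must be a sim_config")
  if (!is.null(config$seed)) set.seed(config$seed)
  covs <- sim_site_covariates(config, seed = NULL)
  params <- sim_community_params(config, seed = NULL)
  f <- config$model$n_factors
  scores <- sim_spatial_factors(covs[, c("x", "y")], f,
                                config$model$spatial_decay, seed = NULL)
  w <- if (f > 0) spatial_effects(params$factor_loadings, scores) else NULL
  z <- sim_occupancy_states(params, covs, config$model, w = w, seed = NULL)
  vc <- sim_visit_covariates(config, seed = NULL)
  y <- sim_detection_histories(z, vc, params, config, seed = NULL)
  structure(list(
    y = y,
    site_covs = covs,
    visit_covs = vc,
    coords = covs[, c("x", "y")],
    model = config$model,
    config = config,
    truth = list(occupancy_coeffs = params$occupancy_coeffs,
                 detection_coeffs = params$detection_coeffs,
                 factor_loadings = params$factor_loadings,
                 factor_scores = scores,
                 w = w, z = z, psi = attr(z, "psi"),
                 p = attr(y, "p"))
  ), class = "occu_data")
}
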