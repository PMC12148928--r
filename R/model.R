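#' Specify a spatial factor multispecies occupancy model
#'
#' Describes the structure of the joint model: the occupancy formula over
#' site-scale and landscape-scale predictors (interactions formed from the
#' scaled main effects), the detection formula over visit-level covariates,
#' the number of latent spatial factors, and whether detection is assumed
#' perfect (single exhaustive survey, as for plants), in which case the
#' occupancy layer is fit directly to the presence record — a joint species
#' distribution model.
#'
#' The default formulas reproduce the full woodland-biodiversity structure:
#' occupancy responds to four site-scale predictors (age, area, shape,
#' vegetation structure), six landscape-scale predictors within a 3-km
#' radius (proportions of current / old / lost woodland, trees outside
#' woodlands, arable fraction of farmland, livestock density), six
#' interactions, and a country indicator; detection responds to ordinal day
#' (linear + quadratic on the scaled day), survey year, and one
#' taxon-specific covariate.
#'
#' @param occupancy one-sided formula for the occupancy linear predictor.
#' @param detection one-sided formula for the detection linear predictor;
#'   ignored when `perfect_detection = TRUE`.
#' @param n_factors number of latent spatial factors (0 disables the
#'   spatial term).
#' @param perfect_detection logical; if TRUE the data are a single perfect
#'   survey and no detection layer is fit.
#' @param spatial_decay decay \eqn{\phi} of the exponential Gaussian-process
#'   correlation \eqn{\exp(-\phi d)} between sites at distance `d`
#'   (units: 1/distance, in the coordinate units).
#' @return an object of class `"occu_model"`.
#' @export
occu_model <- function(occupancy = ~ age + area + shape + structure +
                         current_woodland + old_woodland + lost_woodland +
                         trees_outside + arable + livestock +
                         area:shape + area:current_woodland + area:arable +
                         shape:arable + age:current_woodland +
                         trees_outside:current_woodland + country,
                       detection = ~ day + I(day^2) + year + var4,
                       n_factors = 0,
                       perfect_detection = FALSE,
                       spatial_decay = 0.05) {
  stopifnot(inherits(occupancy, "formula"))
  if (!perfect_detection) stopifnot(inherits(detection, "formula"))
  if (n_factors < 0 || n_factors != round(n_factors))
    stop("n_factors must be a non-negative integer")
  if (n_factors > 0 && spatial_decay <= 0)
    stop("spatial_decay must be positive")
  structure(list(occupancy = occupancy, detection = detection,
                 n_factors = as.integer(n_factors),
                 perfect_detection = isTRUE(perfect_detection),
                 spatial_decay = spatial_decay),
            class = "occu_model")
}

#' Prior specification
#'
#' Minimally informative defaults: community-level means of every species
#' coefficient (detection and occupancy) are Normal(0, 2.7^2); community
#' variances have inverse-gamma(0.1, 0.1) priors; free factor loadings are
#' standard normal.  The 2.7 standard deviation yields a near-uniform
#' implied distribution on the probability scale.
#'
#' @param mean_mu prior mean of the community-mean parameters.
#' @param mean_sd prior sd of the community-mean parameters.
#' @param var_shape,var_scale inverse-gamma shape and scale of community
#'   variances.
#' @param loading_sd prior sd of the free factor loadings.
#' @return object of class `"prior_spec"`.
#' @export
prior_spec <- function(mean_mu = 0, mean_sd = 2.7,
                       var_shape = 0.1, var_scale = 0.1, loading_sd = 1) {
  if (mean_sd <= 0 || var_shape <= 0 || var_scale <= 0 || loading_sd <= 0)
    stop("prior scale parameters must be positive")
  structure(list(mean_mu = mean_mu, mean_sd = mean_sd,
                 var_shape = var_shape, var_scale = var_scale,
                 loading_sd = loading_sd),
            class = "prior_spec")
}

# design matrix for the occupancy layer from (already standardised) site
# covariates; interactions are therefore products of scaled mains
.occu_design <- function(site_covs, model) {
  mf <- stats::model.frame(model$occupancy, site_covs, na.action = NULL)
  x <- model.matrix(model$occupancy, mf)
  if (anyNA(x)) stop("missing values in occupancy covariates")
  x
}

# design matrix for the detection layer from long-format visit covariates
.det_design <- function(visit_covs, model) {
  mf <- stats::model.frame(model$detection, visit_covs, na.action = NULL)
  v <- model.matrix(model$detection, mf)
  if (anyNA(v)) stop("missing values in detection covariates")
  v
}

#' Occupancy linear predictor
#'
#' \eqn{\eta_{ij} = x_j' b_i + w_i(s_j)} on the logit scale: the species'
#' coefficient vector applied to one site's standardised covariate row
#' (interaction columns formed from the scaled mains by the model formula),
#' plus the species' spatial factor effect at that site.
#'
#' @param coefs named coefficient vector matching the model's design columns
#'   (intercept first).
#' @param x one-row data frame of standardised site covariates.
#' @param w spatial factor effect \eqn{w_i(s_j)} (default 0).
#' @param model an [occu_model()].
#' @return linear predictor value(s) on the logit scale.
#' @export
occu_linear_predictor <- function(coefs, x, w = 0, model = occu_model()) {
  X <- .occu_design(as.data.frame(x), model)
  if (ncol(X) != length(coefs))
    stop("coefficient length ", length(coefs),
         " does not match design columns ", ncol(X))
  unname(drop(X %*% coefs)) + w
}

#' Detection linear predictor
#'
#' \eqn{logit(P_{ijk}) = a0 + a1\,day + a2\,day^2 + a3\,year + a4\,var4},
#' with the quadratic term taken as the square of the scaled ordinal day.
#'
#' @param coefs named coefficient vector matching the detection design.
#' @param v one-row data frame of standardised visit covariates.
#' @param model an [occu_model()].
#' @return linear predictor value(s) on the logit scale.
#' @export
det_linear_predictor <- function(coefs, v, model = occu_model()) {
  V <- .det_design(as.data.frame(v), model)
  if (ncol(V) != length(coefs))
    stop("coefficient length ", length(coefs),
         " does not match design columns ", ncol(V))
  unname(drop(V %*% coefs))
}

#' Observed-data likelihood for one species-site detection history
#'
#' Marginalises the latent occupancy state: with at least one detection the
#' site must be occupied, giving \eqn{\psi \prod_k P_k^{y_k}(1-P_k)^{1-y_k}};
#' with none, occupied-but-missed and unoccupied both contribute:
#' \eqn{\psi \prod_k (1-P_k) + (1-\psi)}.  Masked (NA) visits contribute a
#' factor of 1.
#'
#' @param y binary detection vector over visits; NA marks a missing visit.
#' @param P per-visit detection probabilities (same length as `y`).
#' @param psi occupancy probability.
#' @return the marginal likelihood of the history.
#' @export
site_likelihood <- function(y, P, psi) {
  stopifnot(length(y) == length(P), psi >= 0, psi <= 1)
  obs <- !is.na(y)
  y <- y[obs]; P <- P[obs]
  if (!all(y %in% c(0, 1))) stop("y must be binary (0/1) or NA")
  if (any(y == 1)) {
    psi * prod(P^y * (1 - P)^(1 - y))
  } else {
    psi * prod(1 - P) + (1 - psi)
  }
}

#' Likelihood under perfect detection
#'
#' With a single exhaustive survey the presence record is the occupancy
#' state itself: \eqn{\psi^y (1-\psi)^{1-y}}.
#'
#' @param y observed presence (0/1).
#' @param psi occupancy probability.
#' @return Bernoulli likelihood.
#' @export
perfect_detection_likelihood <- function(y, psi) {
  stopifnot(all(y %in% c(0, 1)), all(psi >= 0), all(psi <= 1))
  psi^y * (1 - psi)^(1 - y)
}

#' Reconstruct spatial factor effects from loadings and scores
#'
#' \eqn{w_i(s_j) = \sum_f \lambda_{if} u_{fj}}.  Loadings are constrained
#' lower-triangular with unit diagonal on the leading block for
#' identifiability.
#'
#' @param loadings species x n_factors loading matrix.
#' @param scores n_factors x n_sites factor score matrix.
#' @return species x n_sites matrix of spatial effects.
#' @export
spatial_effects <- function(loadings, scores) {
  if (ncol(loadings) != nrow(scores))
    stop("loadings columns must match scores rows")
  loadings %*% scores
}
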