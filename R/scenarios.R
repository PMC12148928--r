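# Counterfactual assemblage simulation: posterior draws are converted to
# species presence/absence under fixed driver combinations, with the
# remaining predictors drawn from their empirical marginal distributions.

#' Specify a counterfactual scenario
#'
#' Fixes a (possibly empty) set of focal predictors at raw-scale values; at
#' simulation time every other predictor in the occupancy formula is drawn
#' afresh, per posterior draw, from its empirical marginal distribution in
#' the original data.  The empty-fixed-set scenario is the "background"
#' landscape against which driver scenarios are compared (site area is
#' usually still fixed — at the 3.5-ha mean patch size — via `area`).
#'
#' @param fixed named list/vector of raw-scale values for focal predictors.
#' @param area if non-NULL, fixes the site area (ha) in addition to
#'   `fixed`; default NULL.
#' @param n_draws number of posterior draws / assemblages (survey-scale
#'   protocol: 20,000).
#' @param label scenario label.
#' @return object of class `"scenario_spec"`.
#' @export
scenario_spec <- function(fixed = list(), area = NULL, n_draws = 20000,
                          label = "scenario") {
  fixed <- as.list(fixed)
  if (!is.null(area)) fixed$area <- area
  if (length(fixed) && (is.null(names(fixed)) || any(names(fixed) == "")))
    stop("fixed values must be named by predictor")
  if (anyDuplicated(names(fixed)))
    stop("duplicate predictor in fixed values")
  if (n_draws < 1) stop("n_draws must be at least 1")
  structure(list(fixed = fixed, n_draws = as.integer(n_draws),
                 label = label),
            class = "scenario_spec")
}

#' Full-factorial scenario grid over driver levels
#'
#' Builds the 2^k crossed scenarios from low/high levels of k focal
#' drivers — e.g. woodland cover 0.01 vs 0.3, old woodland 0.01 vs 0.85,
#' lost woodland 0.01 vs 0.15, arable fraction 0.01 vs 0.9 — plus one
#' background scenario with no fixed drivers.  When `data` is supplied,
#' levels outside the observed covariate range are flagged with a warning
#' (they extrapolate beyond the data).
#'
#' @param driver_levels named list: each element a length-2 numeric
#'   `c(low, high)` for one predictor.
#' @param area fixed site area applied to every scenario (default 3.5 ha);
#'   NULL to leave area to the marginal sampler.
#' @param n_draws assemblages per scenario.
#' @param data optional raw covariate data frame for the range check.
#' @return list of [scenario_spec()]s: the 2^k factorial combinations
#'   (labelled `pred=low/high` joined by `;`) followed by `"background"`.
#' @export
scenario_grid <- function(driver_levels, area = 3.5, n_draws = 20000,
                          data = NULL) {
  if (anyDuplicated(names(driver_levels)))
    stop("duplicate predictor in driver levels")
  if (!all(vapply(driver_levels, length, integer(1)) == 2))
    stop("each driver needs exactly two levels c(low, high)")
  if (!is.null(data)) {
    for (nm in names(driver_levels)) {
      if (!nm %in% names(data)) stop("unknown predictor: ", nm)
      rng <- range(data[[nm]], na.rm = TRUE)
      lv <- driver_levels[[nm]]
      if (any(lv < rng[1] | lv > rng[2]))
        warning("level(s) for '", nm, "' outside the observed range [",
                signif(rng[1], 3), ", ", signif(rng[2], 3),
                "]: scenario extrapolates beyond the data")
    }
  }
  k <- length(driver_levels)
  grid <- expand.grid(lapply(driver_levels, function(lv)
    c(low = lv[1], high = lv[2])), KEEP.OUT.ATTRS = FALSE)
  lv_name <- expand.grid(lapply(driver_levels, function(lv)
    c("low", "high")), KEEP.OUT.ATTRS = FALSE)
  out <- lapply(seq_len(nrow(grid)), function(r) {
    scenario_spec(fixed = as.list(grid[r, , drop = FALSE]), area = area,
                  n_draws = n_draws,
                  label = paste(names(driver_levels), lv_name[r, ],
                                sep = "=", collapse = ";"))
  })
  c(out, list(scenario_spec(area = area, n_draws = n_draws,
                            label = "background")))
}

#' Simulate assemblages from posterior draws under a scenario
#'
#' One posterior draw per simulated assemblage, consumed in posterior
#' order: for draw d, the focal predictors take the scenario's fixed
#' raw-scale values (standardised through the stored transform), every
#' remaining predictor is drawn from its empirical marginal in the original
#' data, interaction columns are recomputed from these mains, the species
#' occupancy probabilities \eqn{\psi_{di}} are evaluated from that draw's
#' intercepts and coefficients, and presence is a Bernoulli trial.  The
#' spatial factor term is set to zero by default — the scenario describes a
#' new, hypothetical site at no particular location; `w = "gp_prior"`
#' instead draws it from the GP prior through the draw's loadings.
#'
#' @param object a fitted [spfocc()] model, or a `"community_posterior"`
#'   (then `data` and `model` are required and the transform is computed
#'   from `data` unless supplied).
#' @param scenario a [scenario_spec()].
#' @param seed optional RNG seed.
#' @param data raw covariate data frame providing the empirical marginals.
#' @param model an [occu_model()].
#' @param transform optional stored [center_scale()] transform.
#' @param w `"zero"` (default) or `"gp_prior"`.
#' @param recycle if TRUE, posterior draws are recycled cyclically when the
#'   scenario requests more assemblages than there are draws; otherwise
#'   this is an error.
#' @return object of class `"assemblage_ensemble"`: binary `presence`
#'   matrix (draws x species), matching `psi` matrix, `label`, `seed`.
#' @export
simulate_assemblages <- function(object, scenario, seed = NULL, data = NULL,
                                 model = NULL, transform = NULL,
                                 w = c("zero", "gp_prior"), recycle = FALSE) {
  w <- match.arg(w)
  stopifnot(inherits(scenario, "scenario_spec"))
  if (inherits(object, "spfocc")) {
    post <- object$posterior
    if (is.null(data)) data <- object$data$site_covs
    if (is.null(model)) model <- object$model
    if (is.null(transform)) transform <- object$transform
  } else if (inherits(object, "community_posterior")) {
    post <- object
    if (is.null(data) || is.null(model))
      stop("data and model are required with a bare posterior")
  } else stop("object must be a spfocc fit or community_posterior")
  if (!is.null(seed)) set.seed(seed)
  D <- n_draws(post)
  nd <- scenario$n_draws
  if (nd > D && !recycle)
    stop("scenario requests ", nd, " draws but the posterior holds ", D,
         "; set recycle = TRUE to reuse draws cyclically")
  use <- ((seq_len(nd) - 1L) %% D) + 1L

  vars <- all.vars(model$occupancy)
  fixed <- scenario$fixed
  unknown <- setdiff(names(fixed), vars)
  if (length(unknown))
    stop("fixed value for predictor not in the model: ",
         paste(unknown, collapse = ", "))
  free <- setdiff(vars, names(fixed))
  raw <- if (length(vars)) {
    as.data.frame(c(
      lapply(fixed, rep, nd),
      lapply(setNames(free, free), function(v) marginal_sampler(data, v)(nd))
    ))[, vars, drop = FALSE]
  } else {
    as.data.frame(matrix(nrow = nd, ncol = 0))   # intercept-only model
  }
  if (is.null(transform)) {
    cols <- .scalable_vars(model$occupancy, data)
    if (length(cols)) transform <- center_scale(data, cols)$transform
  }
  if (!is.null(transform)) raw_s <- apply_transform(raw, transform)
  else raw_s <- raw
  Xs <- .occu_design(raw_s, model)

  N <- dim(post$beta)[2]
  eta <- matrix(0, nd, N)
  for (p in seq_len(ncol(Xs)))
    eta <- eta + post$beta[use, , p, drop = FALSE][, , 1] * Xs[, p]
  if (w == "gp_prior" && !is.null(post$lambda)) {
    Fq <- dim(post$lambda)[3]
    u_new <- matrix(rnorm(nd * Fq), nd, Fq)   # unit-variance GP at a new site
    for (f in seq_len(Fq))
      eta <- eta + post$lambda[use, , f, drop = FALSE][, , 1] * u_new[, f]
  }
  psi <- .invlogit(eta)
  presence <- matrix(rbinom(length(psi), 1, psi), nd, N)
  structure(list(presence = presence, psi = psi, label = scenario$label,
                 scenario = scenario, seed = seed),
            class = "assemblage_ensemble")
}

#' @export
print.assemblage_ensemble <- function(x, ...) {
  cat(sprintf("Assemblage ensemble '%s': %d draws x %d species\n",
              x$label, nrow(x$presence), ncol(x$presence)))
  invisible(x)
}

#' Per-assemblage species richness and its mode
#'
#' Richness is the row sum of the presence matrix; the modal value is the
#' most frequent integer (ties broken towards the smallest value).
#'
#' @param ensemble an `"assemblage_ensemble"` (or bare binary matrix).
#' @return list of class `"richness_summary"`: `richness` (integer vector),
#'   `mode`, `mean`, and `table` (the integer histogram).
#' @export
species_richness <- function(ensemble) {
  m <- if (inherits(ensemble, "assemblage_ensemble")) ensemble$presence
       else as.matrix(ensemble)
  if (!nrow(m)) stop("empty ensemble")
  r <- as.integer(rowSums(m))
  tab <- table(r)
  mode <- as.integer(names(tab)[which.max(tab)])  # which.max: first = smallest
  structure(list(richness = r, mode = mode, mean = mean(r), table = tab),
            class = "richness_summary")
}

#' @export
print.richness_summary <- function(x, ...) {
  cat(sprintf("Species richness over %d assemblages: mode %d, mean %.2f\n",
              length(x$richness), x$mode, x$mean))
  invisible(x)
}

#' Analytic expected richness
#'
#' The expectation of assemblage richness is the mean over draws of
#' \eqn{\sum_i \psi_{di}} — no Bernoulli noise.  Given an ensemble, the
#' stored \eqn{\psi} matrix is used, so the Monte-Carlo richness mean of
#' the same ensemble must agree within sampling error; given a posterior
#' and scenario, the \eqn{\psi} pipeline is run without the Bernoulli
#' conversion.
#'
#' @param object an `"assemblage_ensemble"`, or a fit/posterior to combine
#'   with `scenario`.
#' @param scenario a [scenario_spec()] (ignored for an ensemble).
#' @param ... passed on to [simulate_assemblages()].
#' @return expected richness (a single number).
#' @export
expected_richness <- function(object, scenario = NULL, ...) {
  if (inherits(object, "assemblage_ensemble"))
    return(mean(rowSums(object$psi)))
  ens <- simulate_assemblages(object, scenario, ...)
  mean(rowSums(ens$psi))
}

#' Marginal occupancy response curves
#'
#' \eqn{\psi(x) = logit^{-1}(\bar{b0}_i + \bar{b_k}\,x_{scaled})} per
#' species, from the posterior means of the intercept and the relevant
#' slope only, all other predictors held at their mean (0 on the scaled
#' scale); the grid covers only the observed range of the predictor.
#'
#' @param object a fitted [spfocc()] model, or a `"community_posterior"`
#'   with `data`/`transform` supplied.
#' @param predictor occupancy predictor name.
#' @param grid optional raw-scale grid (must lie within the observed
#'   range); default: `n` points spanning it.
#' @param n grid resolution.
#' @param data,transform raw data and stored transform (taken from the fit
#'   when available).
#' @return list of class `"response_curve"`: `x` (raw grid), `x_scaled`,
#'   `psi` (grid x species); attributes `"pd"` (probability of direction
#'   per species) and `"slope_mean"`.
#' @export
response_curve <- function(object, predictor, grid = NULL, n = 100,
                           data = NULL, transform = NULL) {
  if (inherits(object, "spfocc")) {
    post <- object$posterior
    if (is.null(data)) data <- object$data$site_covs
    if (is.null(transform)) transform <- object$transform
  } else post <- object
  if (!predictor %in% post$occ_names)
    stop("predictor not in the occupancy model: ", predictor)
  if (is.null(data) || !predictor %in% names(data))
    stop("raw data with column '", predictor, "' required")
  rng <- range(data[[predictor]], na.rm = TRUE)
  if (is.null(grid)) grid <- seq(rng[1], rng[2], length.out = n)
  if (any(grid < rng[1] - 1e-12) || any(grid > rng[2] + 1e-12))
    stop("grid extends beyond the observed range of ", predictor)
  xs <- if (!is.null(transform) && predictor %in% names(transform$mean))
    (grid - transform$mean[[predictor]]) / transform$sd[[predictor]] else grid
  bmean <- apply(post$beta, c(2, 3), mean)
  colnames(bmean) <- post$occ_names
  b0 <- bmean[, "(Intercept)"]
  bk <- bmean[, predictor]
  psi <- .invlogit(outer(unname(xs), unname(bk)) +
                     rep(unname(b0), each = length(xs)))
  ki <- match(predictor, post$occ_names)
  pd <- apply(post$beta[, , ki, drop = FALSE], 2, prob_direction)
  structure(list(x = grid, x_scaled = xs, psi = psi),
            class = "response_curve", pd = pd, slope_mean = bk)
}

#' Probability of direction
#'
#' The fraction of a posterior sample sharing the dominant sign: 0.5 means
#' no directional evidence, 1.0 a sign-unanimous posterior.  Zeros are
#' split evenly between the two signs.
#'
#' @param draws numeric vector of posterior draws of one coefficient.
#' @return value in \[0.5, 1\].
#' @export
prob_direction <- function(draws) {
  draws <- as.numeric(draws)
  if (!length(draws)) stop("empty draws")
  fpos <- (sum(draws > 0) + 0.5 * sum(draws == 0)) / length(draws)
  max(fpos, 1 - fpos)
}
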