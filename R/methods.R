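# S3 methods for fitted spatial factor occupancy models.

#' @export
print.spfocc <- function(x, ...) {
  d <- dim(x$posterior$beta)
  cat("Spatial factor multispecies occupancy model\n")
  cat(sprintf("  species: %d   sites: %d   occupancy terms: %d\n",
              d[2], nrow(x$design$X), d[3]))
  if (!is.null(x$posterior$alpha))
    cat(sprintf("  detection terms: %d\n", dim(x$posterior$alpha)[3]))
  else
    cat("  perfect detection (joint species distribution model)\n")
  cat(sprintf("  latent spatial factors: %d\n", x$model$n_factors))
  cat(sprintf("  posterior draws: %d (%d chains)\n",
              d[1], x$mcmc$n_chains))
  if (!is.na(x$convergence$max_rhat))
    cat(sprintf("  max split R-hat: %.3f\n", x$convergence$max_rhat))
  invisible(x)
}

#' Posterior mean coefficients
#'
#' @param object a fitted [spfocc()] model.
#' @param layer `"occupancy"` or `"detection"`.
#' @param ... unused.
#' @return species x coefficient matrix of posterior means.
#' @export
coef.spfocc <- function(object, layer = c("occupancy", "detection"), ...) {
  layer <- match.arg(layer)
  post <- object$posterior
  a <- if (layer == "occupancy") post$beta else {
    if (is.null(post$alpha)) stop("model has no detection layer")
    post$alpha
  }
  out <- apply(a, c(2, 3), mean)
  colnames(out) <- if (layer == "occupancy") post$occ_names else post$det_names
  rownames(out) <- paste0("sp", seq_len(nrow(out)))
  out
}

#' Central credible intervals for species-level coefficients
#'
#' @param fit a fitted [spfocc()] model.
#' @param level interval mass (default 0.95).
#' @param layer `"occupancy"` or `"detection"`.
#' @return array species x coefficient x (lower, upper).
#' @export
coef_intervals <- function(fit, level = 0.95,
                           layer = c("occupancy", "detection")) {
  layer <- match.arg(layer)
  post <- fit$posterior
  a <- if (layer == "occupancy") post$beta else post$alpha
  pr <- c((1 - level) / 2, 1 - (1 - level) / 2)
  out <- apply(a, c(2, 3), quantile, probs = pr)
  out <- aperm(out, c(2, 3, 1))
  dimnames(out) <- list(paste0("sp", seq_len(dim(out)[1])),
                        if (layer == "occupancy") post$occ_names else post$det_names,
                        c("lower", "upper"))
  out
}

#' Summarise a fitted model
#'
#' Community-level posterior means and 95% intervals of the hyperparameters
#' plus convergence diagnostics.
#'
#' @param object a fitted [spfocc()] model.
#' @param ... unused.
#' @return object of class `"summary.spfocc"`.
#' @export
summary.spfocc <- function(object, ...) {
  post <- object$posterior
  smy <- function(m, names) {
    if (is.null(m)) return(NULL)
    data.frame(parameter = names,
               mean = colMeans(m),
               sd = apply(m, 2, sd),
               lower = apply(m, 2, quantile, 0.025),
               upper = apply(m, 2, quantile, 0.975),
               row.names = NULL)
  }
  out <- list(
    community_occupancy = smy(post$mu_occ, post$occ_names),
    community_occupancy_sd = if (!is.null(post$tau_occ))
      smy(sqrt(post$tau_occ), post$occ_names) else NULL,
    community_detection = smy(post$mu_det, post$det_names),
    n_draws = n_draws(post),
    n_chains = object$mcmc$n_chains,
    max_rhat = object$convergence$max_rhat,
    min_ess = NA_real_)
  ess <- tryCatch(effective_size(post), error = function(e) NULL)
  if (!is.null(ess)) out$min_ess <- min(ess, na.rm = TRUE)
  class(out) <- "summary.spfocc"
  out
}

#' @export
print.summary.spfocc <- function(x, ...) {
  cat("Community-level occupancy effects (posterior mean, 95% CrI):\n")
  print(x$community_occupancy, digits = 3)
  if (!is.null(x$community_detection)) {
    cat("\nCommunity-level detection effects:\n")
    print(x$community_detection, digits = 3)
  }
  cat(sprintf("\n%d draws, %d chains; max split R-hat %.3f; min ESS %.0f\n",
              x$n_draws, x$n_chains, x$max_rhat, x$min_ess))
  invisible(x)
}

#' Predict occupancy or detection probabilities
#'
#' Applies the stored standardisation transform to new raw-scale
#' covariates, rebuilds the design (interactions from scaled mains), and
#' evaluates the posterior of the probability for each species.  The
#' spatial factor term is set to zero: predictions refer to a new,
#' unobserved location.
#'
#' @param object a fitted [spfocc()] model.
#' @param newdata data frame of raw-scale covariates (site covariates for
#'   occupancy, visit covariates for detection).
#' @param type `"occupancy"` or `"detection"`.
#' @param level credible-interval mass.
#' @param ... unused.
#' @return list with arrays `mean`, `lower`, `upper` (species x rows).
#' @export
predict.spfocc <- function(object, newdata, type = c("occupancy", "detection"),
                           level = 0.95, ...) {
  type <- match.arg(type)
  post <- object$posterior
  if (type == "occupancy") {
    if (!is.null(object$transform))
      newdata <- apply_transform(newdata, object$transform)
    Xn <- .occu_design(newdata, object$model)
    arr <- post$beta
  } else {
    if (is.null(post$alpha)) stop("model has no detection layer")
    if (!is.null(object$det_transform))
      newdata <- apply_transform(newdata, object$det_transform)
    Xn <- .det_design(newdata, object$model)
    arr <- post$alpha
  }
  D <- dim(arr)[1]; N <- dim(arr)[2]; R <- nrow(Xn)
  eta <- array(0, c(D, N, R))
  for (p in seq_len(ncol(Xn)))
    eta <- eta + outer(arr[, , p], Xn[, p])
  prob <- .invlogit(eta)
  pr <- c((1 - level) / 2, 1 - (1 - level) / 2)
  list(mean = apply(prob, c(2, 3), mean),
       lower = apply(prob, c(2, 3), quantile, pr[1]),
       upper = apply(prob, c(2, 3), quantile, pr[2]))
}

#' Posterior-mean fitted occupancy probabilities
#'
#' @param object a fitted [spfocc()] model.
#' @param ... unused.
#' @return species x sites matrix of posterior mean occupancy
#'   probabilities (including the spatial factor term).
#' @export
fitted.spfocc <- function(object, ...) {
  post <- object$posterior
  X <- object$design$X
  D <- dim(post$beta)[1]; N <- dim(post$beta)[2]; J <- nrow(X)
  acc <- matrix(0, N, J)
  for (d in seq_len(D)) {
    eta <- matrix(post$beta[d, , ], N) %*% t(X)
    if (!is.null(post$lambda) && !is.null(post$scores))
      eta <- eta + matrix(post$lambda[d, , ], N) %*%
        matrix(post$scores[d, , ], dim(post$scores)[2])
    acc <- acc + .invlogit(eta)
  }
  acc / D
}

#' Pearson residuals of site-level detection counts
#'
#' Observed minus expected detection counts per species and site, scaled by
#' the binomial-mixture standard deviation, all under posterior-mean
#' parameters.  Large absolute values flag species-site combinations the
#' model reproduces poorly.
#'
#' @param object a fitted [spfocc()] model.
#' @param ... unused.
#' @return species x sites matrix of Pearson residuals.
#' @export
residuals.spfocc <- function(object, ...) {
  psi <- fitted(object)
  N <- nrow(psi); J <- ncol(psi)
  if (object$model$perfect_detection) {
    y <- matrix(object$data$y[, , 1], N, J)
    return((y - psi) / sqrt(pmax(psi * (1 - psi), 1e-12)))
  }
  V <- object$design$V; W <- object$design$W
  s_of_r <- object$design$s_of_r; yobs <- object$design$yobs
  p <- .invlogit(coef(object, "detection") %*% t(V))
  Smap <- matrix(0, nrow(V), J)
  Smap[cbind(seq_len(nrow(V)), s_of_r)] <- 1
  cnt <- ((yobs == 1L) & W) %*% Smap
  sum_p <- (p * W) %*% Smap
  sum_pq <- (p * (1 - p) * W) %*% Smap
  ex <- psi * sum_p
  vr <- psi * sum_pq + psi * (1 - psi) * sum_p^2
  (cnt - ex) / sqrt(pmax(vr, 1e-12))
}

#' Simulate assemblages from a fitted model
#'
#' Shorthand for [simulate_assemblages()] under the background scenario
#' (all predictors drawn from their empirical marginals).
#'
#' @param object a fitted [spfocc()] model.
#' @param nsim number of assemblage draws.
#' @param seed optional RNG seed.
#' @param scenario optional [scenario_spec()]; background by default.
#' @param ... passed to [simulate_assemblages()].
#' @return an `"assemblage_ensemble"`.
#' @export
simulate.spfocc <- function(object, nsim = 1, seed = NULL, scenario = NULL,
                            ...) {
  if (is.null(scenario))
    scenario <- scenario_spec(n_draws = nsim, label = "background")
  else scenario$n_draws <- nsim
  simulate_assemblages(object, scenario, seed = seed, ...)
}

#' Plot marginal response curves
#'
#' Species-level occupancy probability against one predictor over its
#' observed range, from posterior-mean intercepts and slopes with all other
#' predictors at their (scaled) mean; line shade reflects the probability
#' of direction (darkest = sign-unanimous posterior, palest = 50%).
#'
#' @param x a fitted [spfocc()] model.
#' @param predictor name of the occupancy predictor to vary.
#' @param n grid resolution.
#' @param ... further graphical arguments.
#' @return invisibly, the [response_curve()] result.
#' @export
plot.spfocc <- function(x, predictor = "area", n = 100, ...) {
  rc <- response_curve(x, predictor, n = n)
  pd <- attr(rc, "pd")
  slope_mean <- attr(rc, "slope_mean")
  plot(NA, xlim = range(rc$x), ylim = c(0, 1), xlab = predictor,
       ylab = expression(psi), ...)
  for (i in seq_len(ncol(rc$psi))) {
    col <- if (slope_mean[i] >= 0) "darkorange3" else "purple4"
    lines(rc$x, rc$psi[, i],
          col = adjustcolor(col, alpha.f = max(0, 2 * pd[i] - 1)))
  }
  invisible(rc)
}
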