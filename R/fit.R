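#' MCMC control settings
#'
#' The default is a test-scale protocol (4 chains, 2,000 burn-in sweeps,
#' 500 kept draws per chain at a thinning rate of 2); the survey-scale
#' protocol used for real communities (4 chains, 50,000 burn-in, 5,000 kept
#' per chain at thinning 10, i.e. 20,000 posterior samples in total) is
#' `mcmc_control(n_burn = 50000, n_keep = 5000, thin = 10)`.
#'
#' @param n_chains number of independent chains.
#' @param n_burn burn-in sweeps per chain, discarded.
#' @param n_keep kept draws per chain (after thinning).
#' @param thin thinning rate: one draw kept every `thin` sweeps.
#' @param update_decay if TRUE, the GP decay gets a random-walk
#'   Metropolis update under a uniform prior on `decay_range`; by default
#'   the decay is fixed at the model's value.
#' @param decay_range support of the uniform decay prior.
#' @param store_scores keep per-draw factor scores (needed only to inspect
#'   the latent surfaces).
#' @return object of class `"mcmc_control"`.
#' @export
mcmc_control <- function(n_chains = 4, n_burn = 2000, n_keep = 500,
                         thin = 2, update_decay = FALSE,
                         decay_range = c(0.005, 1), store_scores = TRUE) {
  stopifnot(n_chains >= 1, n_burn >= 0, n_keep >= 1, thin >= 1)
  structure(list(n_chains = as.integer(n_chains), n_burn = as.integer(n_burn),
                 n_keep = as.integer(n_keep), thin = as.integer(thin),
                 update_decay = isTRUE(update_decay),
                 decay_range = decay_range,
                 store_scores = isTRUE(store_scores)),
            class = "mcmc_control")
}

#' Fit a spatial factor multispecies occupancy model
#'
#' Gibbs sampler with Polya-Gamma augmentation for both logit layers.
#' Latent occupancy states are drawn from their Bernoulli full
#' conditionals, species coefficients and community hyperparameters from
#' conjugate Gaussian / inverse-gamma full conditionals, factor scores from
#' their Gaussian full conditionals under the (dense) exponential GP prior,
#' and free factor loadings from Gaussian full conditionals under the
#' lower-triangular unit-diagonal identifiability constraint.  With
#' `perfect_detection` the occupancy layer is fit directly to the single
#' survey (a joint species distribution model) and the detection layer is
#' dropped.
#'
#' Covariates are standardised internally with [center_scale()] (numeric,
#' non-indicator variables appearing in the formulas); the transform is
#' stored on the fit and reused by [predict.spfocc()] and the scenario
#' machinery, so interaction columns are always products of scaled mains.
#'
#' @param y detections: species x sites x visits binary array (NA =
#'   missing visit), or a species x sites matrix under perfect detection.
#'   Alternatively a full `"occu_data"` bundle from [sim_occu_data()], in
#'   which case the remaining data arguments are taken from it.
#' @param site_covs raw site covariate data frame.
#' @param visit_covs long visit covariate data frame (`site`, `visit`,
#'   covariates); not needed under perfect detection.
#' @param coords site coordinates (columns `x`, `y`); needed when
#'   `model$n_factors > 0`.
#' @param model an [occu_model()].
#' @param priors a [prior_spec()].
#' @param mcmc an [mcmc_control()].
#' @param seed integer seed; chains receive derived seeds.
#' @param verbose print chain progress.
#' @return object of class `"spfocc"` with elements `posterior` (a
#'   `"community_posterior"`), `transform`, `det_transform`, `model`,
#'   `priors`, `mcmc`, `data`, and `convergence` (max split R-hat).  A
#'   structured warning of class `"spfocc_convergence"` is raised when any
#'   split R-hat is 1.1 or above.
#' @export
spfocc <- function(y, site_covs = NULL, visit_covs = NULL, coords = NULL,
                   model = occu_model(), priors = prior_spec(),
                   mcmc = mcmc_control(), seed = NULL, verbose = FALSE) {
  if (inherits(y, "occu_data")) {
    dat <- y
    y <- dat$y
    if (is.null(site_covs)) site_covs <- dat$site_covs
    if (is.null(visit_covs)) visit_covs <- dat$visit_covs
    if (is.null(coords)) coords <- dat$coords
    if (missing(model)) model <- dat$model
  }
  if (is.matrix(y)) y <- array(y, dim = c(dim(y), 1L))
  stopifnot(length(dim(y)) == 3)
  N <- dim(y)[1]; J <- dim(y)[2]; K <- dim(y)[3]
  if (nrow(site_covs) != J)
    stop("site_covs rows (", nrow(site_covs), ") != sites in y (", J, ")")
  if (!all(y %in% c(0L, 1L) | is.na(y)))
    stop("y must be binary with NA for missing visits")

  # --- designs -------------------------------------------------------
  sc_cols <- .scalable_vars(model$occupancy, site_covs)
  transform <- NULL
  sc <- site_covs
  if (length(sc_cols)) {
    cs <- center_scale(site_covs, sc_cols)
    sc <- cs$table; transform <- cs$transform
  }
  X <- .occu_design(sc, model)
  P <- ncol(X)

  det_transform <- NULL
  if (!model$perfect_detection) {
    if (is.null(visit_covs)) stop("visit_covs required unless perfect_detection")
    vc_cols <- .scalable_vars(model$detection, visit_covs)
    vc <- visit_covs
    if (length(vc_cols)) {
      cs <- center_scale(visit_covs, vc_cols)
      vc <- cs$table; det_transform <- cs$transform
    }
    V_all <- .det_design(vc, model)
    Q <- ncol(V_all)
    # keep only site-visits that exist in covariates AND are not fully masked
    keep <- logical(nrow(vc))
    for (r in seq_len(nrow(vc))) {
      j <- visit_covs$site[r]; k <- visit_covs$visit[r]
      keep[r] <- j >= 1 && j <= J && k >= 1 && k <= K &&
        !all(is.na(y[, j, k]))
    }
    V <- V_all[keep, , drop = FALSE]
    s_of_r <- visit_covs$site[keep]
    k_of_r <- visit_covs$visit[keep]
    Robs <- nrow(V)
    yobs <- matrix(NA_integer_, N, max(Robs, 1))
    if (Robs > 0)
      for (r in seq_len(Robs)) yobs[, r] <- y[, s_of_r[r], k_of_r[r]]
    W <- !is.na(yobs)                     # species-level observation mask
    if (Robs == 0) { yobs <- matrix(integer(0), N, 0); W <- matrix(FALSE, N, 0) }
    S <- matrix(0, max(Robs, 1), J)       # site aggregation map
    if (Robs > 0) S[cbind(seq_len(Robs), s_of_r)] <- 1 else S <- matrix(0, 0, J)
  } else {
    if (anyNA(y)) stop("perfect detection admits no missing observations")
    V <- NULL; Q <- 0L; Robs <- 0L; yobs <- NULL; W <- NULL
    S <- NULL; s_of_r <- integer(0)
  }

  Fq <- model$n_factors
  Cinv <- NULL; Dmat <- NULL
  if (Fq > 0) {
    if (is.null(coords)) stop("coords required when n_factors > 0")
    Dmat <- as.matrix(dist(as.matrix(as.data.frame(coords)[, c("x", "y")])))
    Cinv <- .gp_precision(Dmat, model$spatial_decay)
  }

  if (!is.null(seed)) set.seed(seed)
  chain_seeds <- sample.int(.Machine$integer.max - 1L, mcmc$n_chains)

  chains <- vector("list", mcmc$n_chains)
  for (ch in seq_len(mcmc$n_chains)) {
    if (verbose) message("chain ", ch, "/", mcmc$n_chains)
    chains[[ch]] <- .run_chain(ch, chain_seeds[ch], y, X, V, yobs, W, S,
                               s_of_r, N, J, P, Q, Fq, model, priors, mcmc,
                               Dmat, Cinv, verbose)
  }

  posterior <- .bind_chains(chains, N, P, Q, Fq, J, colnames(X),
                            if (Q > 0) colnames(V) else NULL, mcmc)
  if (mcmc$n_chains >= 2) {
    rh <- split_rhat(posterior)
    maxrh <- max(rh$rhat, na.rm = TRUE)
  } else {
    rh <- NULL; maxrh <- NA_real_
  }
  fit <- structure(list(posterior = posterior, model = model, priors = priors,
                        mcmc = mcmc, transform = transform,
                        det_transform = det_transform,
                        data = list(y = y, site_covs = site_covs,
                                    visit_covs = visit_covs, coords = coords),
                        design = list(X = X, V = V, s_of_r = s_of_r,
                                      W = W, yobs = yobs),
                        convergence = list(rhat = rh, max_rhat = maxrh),
                        seed = seed, call = match.call()),
                   class = "spfocc")
  if (is.finite(maxrh) && maxrh >= 1.1) {
    w <- simpleWarning(sprintf(
      "chains may not have converged: max split R-hat = %.3f (>= 1.1)", maxrh))
    class(w) <- c("spfocc_convergence", class(w))
    warning(w)
  }
  fit
}

# inverse of the jittered exponential GP correlation matrix
.gp_precision <- function(Dmat, decay, jitter = 1e-6) {
  C <- exp(-decay * Dmat) + jitter * diag(nrow(Dmat))
  ch <- chol(C)
  list(Cinv = chol2inv(ch), logdet = 2 * sum(log(diag(ch))), C = C)
}

# one MCMC chain; returns a list of draw arrays
.run_chain <- function(ch, chain_seed, y, X, V, yobs, W, S, s_of_r,
                       N, J, P, Q, Fq, model, priors, mcmc, Dmat, Cinv,
                       verbose) {
  set.seed(chain_seed)
  n_iter <- mcmc$n_burn + mcmc$n_keep * mcmc$thin
  perfect <- model$perfect_detection
  Robs <- if (perfect) 0L else nrow(V)

  # --- initial state (overdispersed across chains) -------------------
  beta <- matrix(rnorm(N * P, 0, 0.5), N, P)
  alpha <- if (Q > 0) matrix(rnorm(N * Q, 0, 0.5), N, Q) else NULL
  mu_b <- rnorm(P, 0, 0.5); tau_b <- rep(1, P)
  mu_a <- if (Q > 0) rnorm(Q, 0, 0.5) else NULL
  tau_a <- if (Q > 0) rep(1, Q) else NULL
  lambda <- matrix(0, N, Fq)
  if (Fq > 0) for (i in seq_len(min(N, Fq))) lambda[i, i] <- 1
  u <- matrix(0, max(Fq, 1), J)[seq_len(Fq), , drop = FALSE]
  decay <- model$spatial_decay
  gp <- Cinv

  if (perfect) {
    z <- matrix(y[, , 1], N, J)
  } else {
    z <- matrix(as.integer(runif(N * J) < 0.5), N, J)
    if (Robs > 0) {
      det_any <- ((yobs == 1L) & W) %*% S > 0
      z[det_any] <- 1L
    }
  }

  prior_prec_mu <- 1 / priors$mean_sd^2
  ig_a <- priors$var_shape; ig_b <- priors$var_scale
  lprec <- 1 / priors$loading_sd^2

  keep <- 0L
  d_beta <- array(NA_real_, c(mcmc$n_keep, N, P))
  d_alpha <- if (Q > 0) array(NA_real_, c(mcmc$n_keep, N, Q)) else NULL
  d_mu_b <- matrix(NA_real_, mcmc$n_keep, P)
  d_tau_b <- matrix(NA_real_, mcmc$n_keep, P)
  d_mu_a <- if (Q > 0) matrix(NA_real_, mcmc$n_keep, Q) else NULL
  d_tau_a <- if (Q > 0) matrix(NA_real_, mcmc$n_keep, Q) else NULL
  d_lambda <- if (Fq > 0) array(NA_real_, c(mcmc$n_keep, N, Fq)) else NULL
  d_u <- if (Fq > 0 && mcmc$store_scores)
    array(NA_real_, c(mcmc$n_keep, Fq, J)) else NULL
  d_decay <- if (Fq > 0) numeric(mcmc$n_keep) else NULL

  tX <- t(X)
  for (it in seq_len(n_iter)) {
    w_mat <- if (Fq > 0) lambda %*% u else 0
    eta_occ <- beta %*% tX + w_mat          # N x J

    # --- latent occupancy state -----------------------------------
    if (!perfect) {
      psi <- .invlogit(eta_occ)
      if (Robs > 0) {
        p_det <- .invlogit(alpha %*% t(V))  # N x Robs
        log1mp <- log1p(-p_det) * W         # masked visits contribute 0
        qprod <- exp(log1mp %*% S)          # N x J
        det_any <- ((yobs == 1L) & W) %*% S > 0
      } else {
        qprod <- matrix(1, N, J)
        det_any <- matrix(FALSE, N, J)
      }
      pz <- psi * qprod / (psi * qprod + 1 - psi)
      z <- matrix(as.integer(runif(N * J) < pz), N, J)
      z[det_any] <- 1L
    }

    # --- occupancy layer (Polya-Gamma) -----------------------------
    omega <- matrix(.rpg(eta_occ), N, J)
    kappa <- z - 0.5
    for (i in seq_len(N)) {
      wi <- if (Fq > 0) w_mat[i, ] else 0
      Qm <- crossprod(X * omega[i, ], X)
      diag(Qm) <- diag(Qm) + 1 / tau_b
      rhs <- drop(tX %*% (kappa[i, ] - omega[i, ] * wi)) + mu_b / tau_b
      beta[i, ] <- .rmvnorm_prec(rhs, Qm)
    }

    # --- factor loadings and scores --------------------------------
    if (Fq > 0) {
      xb <- beta %*% tX                      # N x J
      for (i in seq_len(N)) {
        fr <- if (i <= Fq) seq_len(i - 1L) else seq_len(Fq)
        if (!length(fr)) next
        wfix <- if (i <= Fq) u[i, ] else 0
        Uf <- t(u[fr, , drop = FALSE])       # J x |fr|
        Qm <- crossprod(Uf * omega[i, ], Uf)
        diag(Qm) <- diag(Qm) + lprec
        rhs <- drop(crossprod(Uf, kappa[i, ] - omega[i, ] * (xb[i, ] + wfix)))
        lambda[i, fr] <- .rmvnorm_prec(rhs, Qm)
      }
      resid <- kappa - omega * xb
      for (f in seq_len(Fq)) {
        other <- lambda[, -f, drop = FALSE] %*% u[-f, , drop = FALSE]
        lf <- lambda[, f]
        d <- colSums(omega * lf^2)
        rhs <- colSums(lf * (resid - omega * other))
        Qm <- gp$Cinv
        diag(Qm) <- diag(Qm) + d
        u[f, ] <- .rmvnorm_prec(rhs, Qm)
      }
      if (mcmc$update_decay) {
        lo <- mcmc$decay_range[1]; hi <- mcmc$decay_range[2]
        prop <- decay + rnorm(1, 0, 0.05 * (hi - lo))
        if (prop > lo && prop < hi) {
          gp_p <- .gp_precision(Dmat, prop)
          ll <- function(g) -0.5 * sum(vapply(seq_len(Fq), function(f)
            drop(u[f, ] %*% g$Cinv %*% u[f, ]), numeric(1))) -
            0.5 * Fq * g$logdet
          if (log(runif(1)) < ll(gp_p) - ll(gp)) { decay <- prop; gp <- gp_p }
        }
      }
    }

    # --- detection layer (Polya-Gamma) -----------------------------
    if (!perfect && Robs > 0) {
      zr <- z[, s_of_r, drop = FALSE]        # N x Robs occupancy at each visit
      active <- W & (zr == 1L)
      eta_det <- alpha %*% t(V)
      for (i in seq_len(N)) {
        a_i <- active[i, ]
        if (any(a_i)) {
          Va <- V[a_i, , drop = FALSE]
          om <- .rpg(eta_det[i, a_i])
          Qm <- crossprod(Va * om, Va)
          diag(Qm) <- diag(Qm) + 1 / tau_a
          rhs <- drop(crossprod(Va, yobs[i, a_i] - 0.5)) + mu_a / tau_a
          alpha[i, ] <- .rmvnorm_prec(rhs, Qm)
        } else {
          alpha[i, ] <- rnorm(Q, mu_a, sqrt(tau_a))
        }
      }
    }

    # --- community hyperparameters ---------------------------------
    upd_hyper <- function(b, mu, tau) {
      n <- nrow(b)
      for (p in seq_len(ncol(b))) {
        prec <- n / tau[p] + prior_prec_mu
        mn <- (sum(b[, p]) / tau[p] + priors$mean_mu * prior_prec_mu) / prec
        mu[p] <- rnorm(1, mn, 1 / sqrt(prec))
        tau[p] <- 1 / rgamma(1, ig_a + n / 2,
                             ig_b + sum((b[, p] - mu[p])^2) / 2)
      }
      list(mu = mu, tau = tau)
    }
    h <- upd_hyper(beta, mu_b, tau_b); mu_b <- h$mu; tau_b <- h$tau
    if (Q > 0) {
      h <- upd_hyper(alpha, mu_a, tau_a); mu_a <- h$mu; tau_a <- h$tau
    }

    # --- bookkeeping ----------------------------------------------
    if (it > mcmc$n_burn && (it - mcmc$n_burn) %% mcmc$thin == 0) {
      keep <- keep + 1L
      d_beta[keep, , ] <- beta
      d_mu_b[keep, ] <- mu_b
      d_tau_b[keep, ] <- tau_b
      if (Q > 0) {
        d_alpha[keep, , ] <- alpha
        d_mu_a[keep, ] <- mu_a
        d_tau_a[keep, ] <- tau_a
      }
      if (Fq > 0) {
        d_lambda[keep, , ] <- lambda
        if (!is.null(d_u)) d_u[keep, , ] <- u
        d_decay[keep] <- decay
      }
    }
    if (verbose && it %% 1000 == 0)
      message("  iteration ", it, "/", n_iter)
  }
  list(beta = d_beta, alpha = d_alpha, mu_b = d_mu_b, tau_b = d_tau_b,
       mu_a = d_mu_a, tau_a = d_tau_a, lambda = d_lambda, u = d_u,
       decay = d_decay)
}

# stack per-chain draw lists into a community_posterior
.bind_chains <- function(chains, N, P, Q, Fq, J, occ_names, det_names, mcmc) {
  nk <- mcmc$n_keep; nc <- length(chains)
  bind3 <- function(name, d2, d3) {
    if (is.null(chains[[1]][[name]])) return(NULL)
    out <- array(NA_real_, c(nk * nc, d2, d3))
    for (ch in seq_len(nc))
      out[(ch - 1) * nk + seq_len(nk), , ] <- chains[[ch]][[name]]
    out
  }
  bind2 <- function(name, d2) {
    if (is.null(chains[[1]][[name]])) return(NULL)
    out <- matrix(NA_real_, nk * nc, d2)
    for (ch in seq_len(nc))
      out[(ch - 1) * nk + seq_len(nk), ] <- chains[[ch]][[name]]
    out
  }
  community_posterior(
    beta = bind3("beta", N, P),
    alpha = if (Q > 0) bind3("alpha", N, Q) else NULL,
    mu_occ = bind2("mu_b", P), tau_occ = bind2("tau_b", P),
    mu_det = if (Q > 0) bind2("mu_a", Q) else NULL,
    tau_det = if (Q > 0) bind2("tau_a", Q) else NULL,
    lambda = if (Fq > 0) bind3("lambda", N, Fq) else NULL,
    scores = if (Fq > 0 && mcmc$store_scores) bind3("u", Fq, J) else NULL,
    decay = if (Fq > 0) unlist(lapply(chains, `[[`, "decay")) else NULL,
    chain = rep(seq_len(nc), each = nk),
    occ_names = occ_names, det_names = det_names)
}

#' Container for community-model posterior draws
#'
#' Per-draw, per-species detection and occupancy coefficients, community
#' hyperparameters, and (when present) factor loadings and scores, with a
#' chain label per draw.  Usually produced by [spfocc()]; the constructor
#' is exported so posteriors can also be assembled directly (e.g. from
#' coefficient draws with known distribution when validating the
#' assemblage-simulation machinery).
#'
#' @param beta draws x species x coefficients occupancy array.
#' @param alpha draws x species x coefficients detection array, or NULL.
#' @param mu_occ,tau_occ draws x coefficients community mean / variance.
#' @param mu_det,tau_det detection-layer community draws, or NULL.
#' @param lambda draws x species x factors loadings, or NULL.
#' @param scores draws x factors x sites, or NULL.
#' @param decay per-draw GP decay, or NULL.
#' @param chain integer chain label per draw.
#' @param occ_names,det_names design column names.
#' @return object of class `"community_posterior"`.
#' @export
community_posterior <- function(beta, alpha = NULL, mu_occ = NULL,
                                tau_occ = NULL, mu_det = NULL,
                                tau_det = NULL, lambda = NULL, scores = NULL,
                                decay = NULL, chain = rep(1L, dim(beta)[1]),
                                occ_names = NULL, det_names = NULL) {
  stopifnot(length(dim(beta)) == 3, length(chain) == dim(beta)[1])
  if (is.null(occ_names))
    occ_names <- paste0("b", seq_len(dim(beta)[3]) - 1)
  structure(list(beta = beta, alpha = alpha, mu_occ = mu_occ,
                 tau_occ = tau_occ, mu_det = mu_det, tau_det = tau_det,
                 lambda = lambda, scores = scores, decay = decay,
                 chain = as.integer(chain), occ_names = occ_names,
                 det_names = det_names),
            class = "community_posterior")
}

#' @export
dim.community_posterior <- function(x) dim(x$beta)

#' Number of posterior draws
#' @param posterior a `"community_posterior"`.
#' @return integer draw count.
#' @export
n_draws <- function(posterior) dim(posterior$beta)[1]

# flatten monitored parameters into a draws x parameters matrix
.posterior_matrix <- function(post, include_scores = FALSE) {
  stopifnot(inherits(post, "community_posterior"))
  D <- dim(post$beta)[1]
  pieces <- list()
  flat3 <- function(a, prefix, cn) {
    m <- matrix(a, D, prod(dim(a)[-1]))
    colnames(m) <- as.vector(outer(seq_len(dim(a)[2]), cn,
                                   function(i, p) paste0(prefix, "[", i, ",", p, "]")))
    m
  }
  pieces$beta <- flat3(post$beta, "beta", post$occ_names)
  if (!is.null(post$alpha))
    pieces$alpha <- flat3(post$alpha, "alpha", post$det_names)
  named2 <- function(m, prefix, cn) {
    colnames(m) <- paste0(prefix, "[", cn, "]"); m
  }
  if (!is.null(post$mu_occ))
    pieces$mu_occ <- named2(post$mu_occ, "mu_occ", post$occ_names)
  if (!is.null(post$tau_occ))
    pieces$tau_occ <- named2(post$tau_occ, "tau_occ", post$occ_names)
  if (!is.null(post$mu_det))
    pieces$mu_det <- named2(post$mu_det, "mu_det", post$det_names)
  if (!is.null(post$tau_det))
    pieces$tau_det <- named2(post$tau_det, "tau_det", post$det_names)
  if (!is.null(post$lambda)) {
    lam <- flat3(post$lambda, "lambda", seq_len(dim(post$lambda)[3]))
    # drop constrained (constant) entries: upper triangle and unit diagonal
    keepcol <- apply(lam, 2, function(v) var(v) > 0)
    if (any(keepcol)) pieces$lambda <- lam[, keepcol, drop = FALSE]
  }
  if (include_scores && !is.null(post$scores))
    pieces$scores <- flat3(post$scores, "score", seq_len(dim(post$scores)[3]))
  do.call(cbind, pieces)
}
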