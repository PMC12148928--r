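# Convergence diagnostics and posterior predictive checks.

# basic potential-scale-reduction on an iterations x chains matrix
.rhat_basic <- function(sims) {
  n <- nrow(sims)
  var_c <- apply(sims, 2, var)
  W <- mean(var_c)
  B <- n * var(colMeans(sims))
  if (!is.finite(W) || W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# split each chain in half (dropping a trailing draw if odd)
.split_chains <- function(sims) {
  n <- nrow(sims)
  h <- floor(n / 2)
  cbind(sims[seq_len(h), , drop = FALSE],
        sims[h + seq_len(h), , drop = FALSE])
}

.rank_normalize <- function(sims) {
  s <- length(sims)
  z <- qnorm((rank(sims, ties.method = "average") - 3 / 8) / (s + 1 / 4))
  matrix(z, nrow(sims), ncol(sims))
}

.rhat_one <- function(sims) {
  if (all(sims == sims[1])) return(1)       # variance-zero guard
  sp <- .split_chains(sims)
  bulk <- .rhat_basic(.rank_normalize(sp))
  folded <- .rhat_basic(.rank_normalize(abs(sp - median(sp))))
  max(bulk, folded)
}

#' Rank-normalised split R-hat
#'
#' The rank-normalised split potential-scale-reduction diagnostic of
#' Vehtari, Gelman, Simpson, Carpenter & Buerkner (2021): each chain is
#' split in half, all draws are jointly rank-normalised, and the classic
#' between/within-chain variance ratio is computed on both the
#' rank-normalised draws and their folded (absolute-deviation-from-median)
#' version; the larger of the two is reported.  Values below 1.1 for every
#' parameter are the conventional convergence screen; below about 1.01 is
#' comfortable.  Chains of identical constants return exactly 1.
#'
#' @param draws a `"community_posterior"`, a draws x parameters matrix, or
#'   a numeric vector of draws for a single parameter.
#' @param chain integer chain label per draw (taken from the posterior
#'   object when one is supplied).  At least two chains with at least four
#'   draws each are required.
#' @return data frame with columns `parameter` and `rhat`; attribute
#'   `"max"` carries the maximum.
#' @export
split_rhat <- function(draws, chain = NULL) {
  if (inherits(draws, "community_posterior")) {
    chain <- draws$chain
    draws <- .posterior_matrix(draws)
  }
  if (is.null(dim(draws))) draws <- matrix(draws, ncol = 1,
                                           dimnames = list(NULL, "x"))
  if (is.null(chain)) stop("chain labels required")
  chains <- sort(unique(chain))
  if (length(chains) < 2) stop("split R-hat needs at least 2 chains")
  if (min(table(chain)) < 4) stop("each chain needs at least 4 draws")
  nm <- colnames(draws)
  if (is.null(nm)) nm <- paste0("par", seq_len(ncol(draws)))
  rh <- vapply(seq_len(ncol(draws)), function(p) {
    sims <- vapply(chains, function(ch) draws[chain == ch, p],
                   numeric(sum(chain == chains[1])))
    .rhat_one(sims)
  }, numeric(1))
  out <- data.frame(parameter = nm, rhat = rh, row.names = NULL)
  attr(out, "max") <- max(rh)
  out
}

#' Effective sample size
#'
#' Autocorrelation-based ESS combining chains (Vehtari et al. 2021 /
#' Geyer's initial monotone positive sequence): the total draw count is
#' deflated by the integrated autocorrelation time.  Independent draws give
#' ESS close to the number of draws; an AR(1) chain with correlation
#' \eqn{\rho} gives roughly \eqn{N(1-\rho)/(1+\rho)}.  A constant series
#' has no information about the stationary distribution and returns the
#' sentinel `NA`.
#'
#' @param draws numeric vector/matrix of draws, or a `"community_posterior"`
#'   (then a vector of per-parameter ESS values is returned).
#' @param chain optional chain labels; a single chain is assumed otherwise.
#' @return ESS value(s); `NA` for a degenerate (constant) series.
#' @export
effective_size <- function(draws, chain = NULL) {
  if (inherits(draws, "community_posterior")) {
    ch <- draws$chain
    m <- .posterior_matrix(draws)
    return(vapply(seq_len(ncol(m)), function(p)
      effective_size(m[, p], ch), numeric(1)))
  }
  draws <- as.numeric(draws)
  if (length(draws) < 8) stop("need at least 8 draws")
  if (is.null(chain)) chain <- rep(1L, length(draws))
  chains <- sort(unique(chain))
  sims <- vapply(chains, function(c) draws[chain == c],
                 numeric(sum(chain == chains[1])))
  sims <- matrix(sims, ncol = length(chains))
  n <- nrow(sims); m <- ncol(sims)
  if (all(sims == sims[1])) return(NA_real_)
  acov <- vapply(seq_len(m), function(c)
    drop(acf(sims[, c], lag.max = n - 1, type = "covariance",
             plot = FALSE, demean = TRUE)$acf) * (n - 1) / n,
    numeric(n))
  acov <- matrix(acov, ncol = m)
  mean_var <- mean(acov[1, ]) * n / (n - 1)
  var_plus <- mean_var * (n - 1) / n
  if (m > 1) var_plus <- var_plus + var(colMeans(sims))
  rho <- 1 - (mean_var - rowMeans(acov)) / var_plus   # rho[1] = lag 0
  # Geyer: sum consecutive pairs while positive, enforce monotone decrease
  tau <- 0; t <- 1
  pair_prev <- Inf
  while (t + 1 <= n) {
    pair <- rho[t] + if (t + 1 <= length(rho)) rho[t + 1] else 0
    if (pair < 0) break
    pair <- min(pair, pair_prev)
    pair_prev <- pair
    tau <- tau + pair
    t <- t + 2
  }
  tau <- max(2 * tau - 1, 1 / log10(n * m))   # tau >= small positive
  min(n * m / tau, n * m * log10(n * m))
}

#' Posterior predictive check
#'
#' For each retained posterior draw, replicate detection data are simulated
#' from the model at that draw's parameters (latent occupancy from
#' \eqn{\psi}, then Bernoulli detections), and a discrepancy between
#' site-level detection counts and their expectations is computed for both
#' the observed and the replicated data.  The Bayesian p-value is the
#' fraction of draws whose replicated discrepancy is at least the observed
#' one; values near 0 or 1 indicate misfit, and data truly generated by the
#' model yield p well inside (0, 1).
#'
#' @param fit a fitted [spfocc()] model.
#' @param discrepancy `"freeman_tukey"` (default,
#'   \eqn{\sum (\sqrt{c} - \sqrt{E[c]})^2}) or `"chi_squared"`.
#' @param draws number of posterior draws to use (default: up to 500,
#'   evenly spaced).
#' @param seed optional RNG seed for the replicate simulations.
#' @return list of class `"spfocc_ppc"`: `p_value`, `statistic` name, and
#'   the per-draw observed/replicated discrepancies.
#' @export
posterior_check <- function(fit, discrepancy = "freeman_tukey",
                            draws = NULL, seed = NULL) {
  stopifnot(inherits(fit, "spfocc"))
  disc <- switch(discrepancy,
    freeman_tukey = function(cnt, ex) sum((sqrt(cnt) - sqrt(ex))^2),
    chi_squared = function(cnt, ex) sum((cnt - ex)^2 / (ex + 1e-10)),
    stop("unknown discrepancy: ", discrepancy))
  if (!is.null(seed)) set.seed(seed)
  post <- fit$posterior
  D <- n_draws(post)
  nd <- if (is.null(draws)) min(500L, D) else min(draws, D)
  use <- unique(round(seq(1, D, length.out = nd)))
  X <- fit$design$X
  perfect <- fit$model$perfect_detection
  N <- dim(post$beta)[2]; J <- nrow(X)
  if (perfect) {
    yobs_js <- matrix(fit$data$y[, , 1], N, J)
    cnt_obs <- yobs_js
  } else {
    V <- fit$design$V; s_of_r <- fit$design$s_of_r
    W <- fit$design$W; yobs <- fit$design$yobs
    Robs <- nrow(V)
    Smap <- matrix(0, Robs, J); Smap[cbind(seq_len(Robs), s_of_r)] <- 1
    cnt_obs <- ((yobs == 1L) & W) %*% Smap
  }
  d_obs <- d_rep <- numeric(length(use))
  for (ii in seq_along(use)) {
    d <- use[ii]
    eta <- matrix(post$beta[d, , ], N) %*% t(X)
    if (!is.null(post$lambda) && !is.null(post$scores))
      eta <- eta + matrix(post$lambda[d, , ], N) %*%
        matrix(post$scores[d, , ], dim(post$scores)[2])
    psi <- .invlogit(eta)
    z_rep <- matrix(rbinom(N * J, 1, psi), N, J)
    if (perfect) {
      ex <- psi
      rep_cnt <- z_rep
      d_obs[ii] <- disc(cnt_obs, ex)
      d_rep[ii] <- disc(rep_cnt, ex)
    } else {
      p <- .invlogit(matrix(post$alpha[d, , ], N) %*% t(V))
      pW <- p * W
      ex <- psi * (pW %*% Smap)
      y_rep <- matrix(rbinom(length(p), 1,
                             p * z_rep[, s_of_r]), N) * W
      rep_cnt <- y_rep %*% Smap
      d_obs[ii] <- disc(cnt_obs, ex)
      d_rep[ii] <- disc(rep_cnt, ex)
    }
  }
  structure(list(p_value = mean(d_rep >= d_obs),
                 statistic = discrepancy,
                 observed = d_obs, replicated = d_rep),
            class = "spfocc_ppc")
}

#' @export
print.spfocc_ppc <- function(x, ...) {
  cat("Posterior predictive check (", x$statistic, ")\n", sep = "")
  cat("Bayesian p-value:", format(x$p_value, digits = 3),
      " [", length(x$observed), "draws ]\n")
  invisible(x)
}
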