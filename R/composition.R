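# Assemblage composition: binary Bray-Curtis (Sorensen) dissimilarity,
# NMDS ordination on a representative subsample, 89% ellipses.

#' Binary Bray-Curtis (Sorensen) dissimilarity
#'
#' For presence/absence rows u, v: \eqn{d = (b + c) / (2a + b + c)} with
#' `a` shared presences and `b`, `c` the presences unique to each row.
#' Assemblages with no species at all are removed first (the index is
#' undefined for a doubly-empty pair); their row indices are recorded in
#' the `"dropped"` attribute.
#'
#' @param presence binary matrix, assemblages in rows.
#' @return symmetric dissimilarity matrix in \[0, 1\] with zero diagonal;
#'   attribute `"dropped"` lists removed all-zero rows.
#' @export
bray_binary <- function(presence) {
  m <- if (inherits(presence, "assemblage_ensemble")) presence$presence
       else as.matrix(presence)
  if (!all(m %in% c(0, 1))) stop("presence matrix must be binary")
  zero <- which(rowSums(m) == 0)
  if (length(zero)) {
    message(length(zero), " empty assemblage(s) removed before dissimilarity")
    m <- m[-zero, , drop = FALSE]
  }
  a <- m %*% t(m)                       # shared presences
  rs <- rowSums(m)
  tot <- outer(rs, rs, "+")             # 2a + b + c
  d <- (tot - 2 * a) / tot
  diag(d) <- 0
  dimnames(d) <- NULL
  attr(d, "dropped") <- zero
  d
}

#' Representative random subsample of an ensemble
#'
#' Uniform sample of rows without replacement, size
#' `round(fraction * n)` — e.g. a representative 10% of 20,000 simulated
#' assemblages gives 2,000 rows.
#'
#' @param ensemble an `"assemblage_ensemble"` or binary matrix.
#' @param fraction subsample fraction in (0, 1].
#' @param seed optional RNG seed.
#' @return the subsampled presence matrix; attribute `"rows"` gives the
#'   selected indices.
#' @export
subsample_assemblages <- function(ensemble, fraction = 0.10, seed = NULL) {
  m <- if (inherits(ensemble, "assemblage_ensemble")) ensemble$presence
       else as.matrix(ensemble)
  if (!nrow(m)) stop("empty ensemble")
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  if (!is.null(seed)) set.seed(seed)
  size <- max(1L, round(fraction * nrow(m)))
  rows <- sort(sample.int(nrow(m), size))
  out <- m[rows, , drop = FALSE]
  attr(out, "rows") <- rows
  out
}

#' Non-metric multidimensional scaling
#'
#' Global NMDS minimising Kruskal's stress-1
#' \eqn{\sqrt{\sum(\hat d - \delta)^2 / \sum \hat d^2}} (monotone-regressed
#' disparities), via `vegan::monoMDS` started from the classical
#' metric-MDS configuration plus random restarts; the lowest-stress
#' solution is kept.  Coordinates are centred at the origin.
#'
#' @param d symmetric dissimilarity matrix (or `dist`) with zero diagonal.
#' @param k number of ordination axes (default 3).
#' @param n_restarts random restarts beyond the metric start (default 20).
#' @param seed optional RNG seed.
#' @param tol convergence tolerance passed to the optimiser.
#' @return object of class `"nmds_ord"`: `coordinates` (n x k), `stress`
#'   (in \[0, 1\]), `converged`, `n_restarts_used`.
#' @export
nmds_ord <- function(d, k = 3, n_restarts = 20, seed = NULL, tol = 1e-6) {
  dm <- as.matrix(d)
  if (!isSymmetric(unname(dm), tol = 1e-8) || any(abs(diag(dm)) > 1e-12))
    stop("d must be a symmetric dissimilarity matrix with zero diagonal")
  n <- nrow(dm)
  if (n < k + 2) stop("need at least k + 2 assemblages")
  off <- dm[lower.tri(dm)]
  if (max(off) - min(off) < 1e-12)
    warning("all dissimilarities are equal: ordination is non-informative")
  if (!is.null(seed)) set.seed(seed)
  dd <- stats::as.dist(dm)
  run1 <- function(init) {
    fit <- vegan::monoMDS(dd, y = init, k = k, model = "global",
                          smin = tol, sfgrmin = tol, maxit = 500)
    fit
  }
  init0 <- tryCatch(cmdscale(dd, k = k), error = function(e) NULL)
  if (!is.null(init0) && ncol(init0) < k)   # rank-deficient metric start
    init0 <- cbind(init0, matrix(rnorm(n * (k - ncol(init0)), 0, 1e-3),
                                 n, k - ncol(init0)))
  best <- NULL; used <- 0L
  starts <- c(if (!is.null(init0)) list(init0),
              replicate(n_restarts, matrix(rnorm(n * k), n, k),
                        simplify = FALSE))
  for (st in starts) {
    used <- used + 1L
    fit <- tryCatch(run1(st), error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$stress < best$stress) best <- fit
  }
  if (is.null(best)) stop("NMDS failed from every start")
  coords <- scale(best$points, center = TRUE, scale = FALSE)
  attr(coords, "scaled:center") <- NULL
  colnames(coords) <- paste0("NMDS", seq_len(k))
  structure(list(coordinates = coords, stress = best$stress,
                 converged = is.null(best$icause) || best$icause != 1,
                 n_restarts_used = used),
            class = "nmds_ord")
}

#' @export
print.nmds_ord <- function(x, ...) {
  cat(sprintf("NMDS (%d axes): stress = %.4f over %d points (%d starts)\n",
              ncol(x$coordinates), x$stress, nrow(x$coordinates),
              x$n_restarts_used))
  invisible(x)
}

#' 89% bivariate-normal ellipse of a point group
#'
#' Normal-theory ellipse at the chi-square (2 df) quantile of the chosen
#' mass: centre at the group mean, axes along the covariance
#' eigenvectors with half-lengths \eqn{\sqrt{\lambda_i \chi^2_{2;q}}}.
#' For large bivariate-normal samples the ellipse contains about the
#' requested fraction of points.
#'
#' @param coordinates matrix of points; the first two columns (or
#'   `axes`) are used.
#' @param level ellipse mass (default 0.89).
#' @param axes length-2 column selection (default `c(1, 2)`).
#' @return object of class `"ellipse89"`: `center`, `axes` (half-lengths),
#'   `angle` (radians, first axis), `cov`, `level`, `degenerate`.
#' @export
ellipse89 <- function(coordinates, level = 0.89, axes = c(1, 2)) {
  xy <- as.matrix(coordinates)[, axes, drop = FALSE]
  if (nrow(xy) < 3) stop("need at least 3 points")
  ctr <- colMeans(xy)
  S <- stats::cov(xy)
  ev <- eigen(S, symmetric = TRUE)
  degenerate <- ev$values[2] <= 1e-12 * max(ev$values[1], 1e-300)
  r2 <- qchisq(level, df = 2)
  structure(list(center = ctr, axes = sqrt(pmax(ev$values, 0) * r2),
                 angle = atan2(ev$vectors[2, 1], ev$vectors[1, 1]),
                 cov = S, level = level, degenerate = degenerate),
            class = "ellipse89")
}

#' Points on an ellipse outline
#'
#' @param e an [ellipse89()] object.
#' @param n number of points.
#' @return n x 2 matrix tracing the ellipse (for plotting).
#' @export
ellipse_points <- function(e, n = 100) {
  t <- seq(0, 2 * pi, length.out = n)
  circ <- cbind(e$axes[1] * cos(t), e$axes[2] * sin(t))
  rot <- matrix(c(cos(e$angle), sin(e$angle),
                  -sin(e$angle), cos(e$angle)), 2, 2)
  sweep(circ %*% t(rot), 2, e$center, "+")
}
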