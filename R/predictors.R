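#' Patch shape index
#'
#' Compactness of a habitat patch: the patch perimeter divided by the
#' perimeter of a circle with the same area, \eqn{P / (2\sqrt{\pi A})}.
#' A circle scores exactly 1; larger values indicate less-compact patches.
#' The index is dimensionless and invariant to rescaling all lengths.
#'
#' @param perimeter patch perimeter (length units, e.g. m).
#' @param area patch area in the squared length unit (e.g. m^2).
#' @return numeric vector of shape indices, always >= 1.
#' @examples
#' shape_index(400, 100 * 100)     # unit square: 2/sqrt(pi)
#' r <- 50; shape_index(2 * pi * r, pi * r^2)  # circle: 1
#' @export
shape_index <- function(perimeter, area) {
  if (any(!is.finite(perimeter)) || any(!is.finite(area)))
    stop("perimeter and area must be finite")
  if (any(perimeter <= 0)) stop("perimeter must be positive")
  if (any(area <= 0)) stop("area must be positive")
  circ <- 2 * sqrt(pi * area)
  # isoperimetric inequality: no plane figure has a shorter perimeter than
  # the equal-area circle; allow a sliver of numerical slack
  if (any(perimeter < circ * (1 - 1e-9)))
    stop("perimeter is below the equal-area circle's: geometrically impossible")
  pmax(perimeter / circ, 1)
}

#' Centre and scale predictor columns, keeping the transform
#'
#' Standardises the chosen columns of a predictor table to sample mean 0 and
#' sample (n-1) standard deviation 1, and returns the per-column means and
#' sds so the identical transform can be re-applied to new data (scenario
#' values, prediction grids) and inverted.  Binary indicator columns such as
#' country should be excluded via `cols`.
#'
#' @param table data frame of predictors.
#' @param cols character vector of columns to standardise; default: all
#'   numeric columns that are not 0/1 indicators.
#' @return list with elements `table` (standardised copy) and `transform`
#'   (object of class `"standardization"`: named `mean` and `sd` vectors).
#' @seealso [apply_transform()], [invert_transform()]
#' @export
center_scale <- function(table, cols = NULL) {
  stopifnot(is.data.frame(table))
  if (nrow(table) < 2) stop("need at least 2 rows to centre and scale")
  if (is.null(cols)) {
    num <- vapply(table, is.numeric, logical(1))
    indic <- vapply(table, function(x)
      is.numeric(x) && all(x %in% c(0, 1)), logical(1))
    cols <- names(table)[num & !indic]
  }
  missing_cols <- setdiff(cols, names(table))
  if (length(missing_cols))
    stop("unknown column(s): ", paste(missing_cols, collapse = ", "))
  mu <- vapply(table[cols], mean, numeric(1))
  s <- vapply(table[cols], sd, numeric(1))
  zero <- names(s)[s == 0 | !is.finite(s)]
  if (length(zero))
    stop("zero-variance column(s) cannot be scaled: ",
         paste(zero, collapse = ", "))
  tr <- structure(list(mean = mu, sd = s), class = "standardization")
  list(table = apply_transform(table, tr), transform = tr)
}

#' Apply a stored standardisation transform
#'
#' @param table data frame containing (at least) the transform's columns.
#' @param transform a `"standardization"` object from [center_scale()].
#' @return the table with the transform's columns standardised.
#' @export
apply_transform <- function(table, transform) {
  stopifnot(inherits(transform, "standardization"))
  for (nm in names(transform$mean)) {
    if (!nm %in% names(table)) stop("column missing from table: ", nm)
    table[[nm]] <- (table[[nm]] - transform$mean[[nm]]) / transform$sd[[nm]]
  }
  table
}

#' Invert a stored standardisation transform
#'
#' @inheritParams apply_transform
#' @return the table with the transform's columns mapped back to raw scale.
#' @export
invert_transform <- function(table, transform) {
  stopifnot(inherits(transform, "standardization"))
  for (nm in names(transform$mean)) {
    if (!nm %in% names(table)) stop("column missing from table: ", nm)
    table[[nm]] <- table[[nm]] * transform$sd[[nm]] + transform$mean[[nm]]
  }
  table
}

#' Variance inflation factor screen
#'
#' Computes VIF_k = 1 / (1 - R^2_k) for every column, where R^2_k comes from
#' the least-squares regression of column k on all remaining columns, and
#' flags columns at or above the threshold.  A VIF below 2.5 is commonly
#' taken to indicate that collinearity will not destabilise coefficient
#' estimates.
#'
#' @param table data frame or numeric matrix of candidate predictors
#'   (indicators allowed; no intercept column).
#' @param threshold flag columns with VIF at or above this value (default 2.5).
#' @return data frame with columns `variable`, `vif`, `flagged`, plus
#'   attribute `"pass"` (TRUE when nothing is flagged).
#' @export
vif_screen <- function(table, threshold = 2.5) {
  x <- as.matrix(as.data.frame(table))
  if (!is.numeric(x)) stop("all columns must be numeric")
  if (nrow(x) <= ncol(x))
    stop("need more rows than columns for the auxiliary regressions")
  qx <- qr(cbind(1, x))
  if (qx$rank < ncol(x) + 1) {
    dep <- setdiff(seq_len(ncol(x) + 1), qx$pivot[seq_len(qx$rank)]) - 1L
    stop("rank-deficient design; linearly dependent column(s): ",
         paste(colnames(x)[dep[dep > 0]], collapse = ", "))
  }
  vif <- vapply(seq_len(ncol(x)), function(k) {
    fit <- lm.fit(cbind(1, x[, -k, drop = FALSE]), x[, k])
    rss <- sum(fit$residuals^2)
    tss <- sum((x[, k] - mean(x[, k]))^2)
    1 / (rss / tss)
  }, numeric(1))
  out <- data.frame(variable = colnames(x), vif = vif,
                    flagged = vif >= threshold, row.names = NULL)
  attr(out, "pass") <- !any(out$flagged)
  out
}

#' Empirical marginal sampler for a predictor column
#'
#' Returns a function that draws values by resampling, with replacement, the
#' observed values of one column — the marginal distribution of the original
#' data with no distributional assumption.  Used to fill the non-focal
#' predictors when simulating counterfactual assemblages.
#'
#' @param table data frame of raw-scale predictors.
#' @param column column name to resample.
#' @return function `f(n)` returning `n` resampled values.
#' @export
marginal_sampler <- function(table, column) {
  if (!column %in% names(table)) stop("unknown column: ", column)
  v <- table[[column]]
  v <- v[!is.na(v)]
  if (!length(v)) stop("column has no non-missing values: ", column)
  function(n) v[sample.int(length(v), n, replace = TRUE)]
}
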