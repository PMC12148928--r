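# Plain-text serialisation of synthetic datasets and transforms: site
# covariates as one-row-per-site CSV, detection histories as long-format
# CSV, the truth bundle as a flat key=value file.

#' Write a synthetic occupancy dataset to plain-text files
#'
#' Creates `site_covariates.csv` (one row per site), `detections.csv`
#' (long format: `species_id`, `site_id`, `visit`, `detected` in 0/1, with
#' the visit covariates joined on; masked visits are omitted) and
#' `truth.txt` (flat `key = value` lines for every true parameter).
#'
#' @param data an `"occu_data"` bundle from [sim_occu_data()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_occu_data <- function(data, dir) {
  stopifnot(inherits(data, "occu_data"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "site_covariates.csv")
  write.csv(data$site_covs, p1, row.names = FALSE)

  y <- data$y
  N <- dim(y)[1]; J <- dim(y)[2]; K <- dim(y)[3]
  long <- expand.grid(species_id = seq_len(N), site_id = seq_len(J),
                      visit = seq_len(K), KEEP.OUT.ATTRS = FALSE)
  long$detected <- as.integer(y[cbind(long$species_id, long$site_id,
                                      long$visit)])
  long <- long[!is.na(long$detected), ]
  if (!is.null(data$visit_covs))
    long <- merge(long, data$visit_covs,
                  by.x = c("site_id", "visit"), by.y = c("site", "visit"),
                  sort = FALSE)
  long <- long[order(long$species_id, long$site_id, long$visit), ]
  p2 <- file.path(dir, "detections.csv")
  write.csv(long, p2, row.names = FALSE)

  p3 <- file.path(dir, "truth.txt")
  con <- file(p3, "w")
  on.exit(close(con))
  put <- function(key, value)
    writeLines(paste0(key, " = ", paste(format(value, digits = 17),
                                        collapse = ",")), con)
  tr <- data$truth
  flat <- function(prefix, m) {
    if (is.null(m)) return()
    m <- as.matrix(m)
    for (i in seq_len(nrow(m)))
      put(paste0(prefix, "[", i, "]"), m[i, ])
  }
  flat("occupancy_coeffs", tr$occupancy_coeffs)
  flat("detection_coeffs", tr$detection_coeffs)
  flat("factor_loadings", tr$factor_loadings)
  flat("factor_scores", tr$factor_scores)
  flat("z", tr$z)
  invisible(c(p1, p2, p3))
}

#' Read a synthetic occupancy dataset written by [write_occu_data()]
#'
#' @param dir directory holding `site_covariates.csv` and `detections.csv`.
#' @param model the [occu_model()] the data were generated under (used for
#'   array dimensions and the perfect-detection flag).
#' @return list with `y` (species x sites x visits array, NA = missing),
#'   `site_covs`, `visit_covs`.
#' @export
read_occu_data <- function(dir, model = occu_model()) {
  covs <- read.csv(file.path(dir, "site_covariates.csv"))
  long <- read.csv(file.path(dir, "detections.csv"))
  N <- max(long$species_id); J <- nrow(covs); K <- max(long$visit)
  y <- array(NA_integer_, c(N, J, K))
  y[cbind(long$species_id, long$site_id, long$visit)] <- long$detected
  vc_cols <- setdiff(names(long), c("species_id", "detected"))
  vc <- unique(long[long$species_id == 1, vc_cols])
  names(vc)[names(vc) == "site_id"] <- "site"
  list(y = y, site_covs = covs, visit_covs = vc[order(vc$site, vc$visit), ])
}

#' Serialise a standardisation transform to a text sidecar
#'
#' @param transform a `"standardization"` object from [center_scale()].
#' @param path output CSV path (columns `variable`, `mean`, `sd`).
#' @return invisibly, `path`.
#' @export
write_transform <- function(transform, path) {
  stopifnot(inherits(transform, "standardization"))
  write.csv(data.frame(variable = names(transform$mean),
                       mean = unname(transform$mean),
                       sd = unname(transform$sd)),
            path, row.names = FALSE)
  invisible(path)
}

#' Read a standardisation transform written by [write_transform()]
#'
#' @param path CSV path.
#' @return a `"standardization"` object.
#' @export
read_transform <- function(path) {
  df <- read.csv(path)
  structure(list(mean = setNames(df$mean, df$variable),
                 sd = setNames(df$sd, df$variable)),
            class = "standardization")
}
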