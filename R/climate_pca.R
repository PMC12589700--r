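# Principal component analysis of the 19 bioclimatic variables. Because the
# bioclim set mixes temperature (degrees C) and precipitation (mm), the PCA
# operates on the correlation matrix (all variables standardized).

#' Principal component analysis of bioclimatic variables
#'
#' Standardizes every variable to zero mean and unit variance and
#' eigen-decomposes the correlation matrix. Component signs are fixed so the
#' loading of the first variable (annual mean temperature, `bio1`) is
#' non-negative on each component where it is nonzero, making results stable
#' across linear-algebra backends.
#'
#' @param climate_table Data frame or matrix of samples x variables (no
#'   missing values, >= 3 samples); a `sample_id` column, if present, is
#'   used for score row names.
#' @return A `climate_pca` object: `loadings` (variables x components,
#'   orthonormal columns), `explained_variance` (fractions summing to 1),
#'   `scores` (samples x components), `variable_names`, `center`, `scale`.
#' @export
fit_pca <- function(climate_table) {
  climate_table <- as.data.frame(climate_table)
  sample_ids <- NULL
  if ("sample_id" %in% names(climate_table)) {
    sample_ids <- as.character(climate_table$sample_id)
    climate_table$sample_id <- NULL
  }
  Xraw <- as.matrix(climate_table)
  if (!is.numeric(Xraw)) stop("climate table must be numeric", call. = FALSE)
  if (nrow(Xraw) < 3) stop("need at least 3 samples", call. = FALSE)
  if (anyNA(Xraw)) stop("climate table contains missing values", call. = FALSE)
  sds <- apply(Xraw, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant variable(s): ", paste(colnames(Xraw)[sds == 0], collapse = ", "),
         call. = FALSE)
  }
  ctr <- colMeans(Xraw)
  Z <- scale(Xraw, center = ctr, scale = sds)
  pr <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  load <- pr$rotation
  # sign convention: first variable's loading non-negative per component
  flip <- ifelse(load[1, ] < 0, -1, 1)
  load <- sweep(load, 2, flip, `*`)
  scores <- Z %*% load
  if (!is.null(sample_ids)) rownames(scores) <- sample_ids
  ev <- pr$sdev^2
  structure(
    list(
      loadings = load,
      explained_variance = ev / sum(ev),
      eigenvalues = ev,
      scores = scores,
      variable_names = colnames(Xraw),
      center = ctr, scale = sds
    ),
    class = "climate_pca"
  )
}

#' @export
print.climate_pca <- function(x, ...) {
  k <- min(3, length(x$explained_variance))
  cat(sprintf(
    "<climate_pca> %d variables, %d samples; first %d PCs explain %.2f%% of variance\n",
    length(x$variable_names), nrow(x$scores), k,
    100 * sum(x$explained_variance[seq_len(k)])
  ))
  invisible(x)
}

#' Project new samples onto fitted climate components
#'
#' Standardizes new samples by the training means and standard deviations and
#' multiplies by the fitted loadings.
#'
#' @param pca A `climate_pca` from [fit_pca()].
#' @param new_samples Data frame or matrix with exactly the training
#'   variables, in the same order.
#' @return Matrix of component scores (samples x components).
#' @export
project <- function(pca, new_samples) {
  stopifnot(inherits(pca, "climate_pca"))
  new_samples <- as.data.frame(new_samples)
  if ("sample_id" %in% names(new_samples)) new_samples$sample_id <- NULL
  if (!identical(colnames(new_samples), pca$variable_names)) {
    stop("variables do not match the fitted PCA (same names, same order required)",
         call. = FALSE)
  }
  Z <- scale(as.matrix(new_samples), center = pca$center, scale = pca$scale)
  Z %*% pca$loadings
}

#' Scale columns to [-1, 1] for structural equation modelling
#'
#' Affinely maps each column so its minimum becomes -1 and its maximum +1
#' (the data scaling applied before path-model fitting). A z-scoring
#' alternative is available behind the `method` switch.
#'
#' @param columns Data frame or matrix of non-constant numeric columns.
#' @param method `"minmax"` (default) or `"zscore"`.
#' @return Object of the same shape with scaled columns.
#' @export
scale_for_sem <- function(columns, method = c("minmax", "zscore")) {
  method <- match.arg(method)
  is_df <- is.data.frame(columns)
  X <- as.matrix(columns)
  rng <- apply(X, 2, range)
  if (any(rng[1, ] == rng[2, ])) {
    stop("constant column(s): ",
         paste(colnames(X)[rng[1, ] == rng[2, ]], collapse = ", "),
         call. = FALSE)
  }
  out <- if (method == "minmax") {
    sweep(sweep(X, 2, rng[1, ]), 2, (rng[2, ] - rng[1, ]) / 2, `/`) - 1
  } else {
    scale(X)[, , drop = FALSE]
  }
  if (is_df) as.data.frame(out) else out
}
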