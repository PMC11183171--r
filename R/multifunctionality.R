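#' Z-standardize ecosystem functions
#'
#' Per-function z-transformation: `(x - mean) / sd`, with the sample
#' (n - 1) standard deviation.  A constant function column is an error (the
#' 12 functions are a fixed design, so silent dropping would corrupt the
#' averaging index).
#'
#' @param functions a [function_table] or numeric matrix (samples x
#'   functions), >= 2 samples, no missing values.
#' @return Matrix of z-scores, same dimensions and dimnames.
#' @export
z_standardize <- function(functions) {
  x <- unclass(as.matrix(functions))
  if (nrow(x) < 2) stop("need at least 2 samples")
  if (any(!is.finite(x))) stop("missing or non-finite function values")
  sds <- apply(x, 2, sd)
  if (any(sds == 0))
    stop("constant function column(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  scale(x, center = TRUE, scale = sds)[, , drop = FALSE]
}

#' Average multifunctionality index
#'
#' Per-sample mean of the standardized functions.  Because every column of
#' the input has mean zero, the index has grand mean zero across samples.
#'
#' @param standardized output of [z_standardize()].
#' @return Named numeric vector, one index per sample.
#' @export
average_multifunctionality <- function(standardized) {
  rowMeans(as.matrix(standardized))
}

#' Multidimensional functioning: principal axes of the standardized functions
#'
#' Principal component analysis of the z-scored function matrix (correlation
#' and covariance coincide on z-scores).  Explained variance per axis is its
#' eigenvalue divided by the total variance over all axes; axis orientation
#' is fixed by making the largest-magnitude loading of each axis positive.
#'
#' @param standardized output of [z_standardize()].
#' @param n_dims number of axes to return (<= min(n_samples - 1, n_functions)).
#' @return List with `scores` (samples x n_dims, centered),
#'   `explained_variance` (first `n_dims` fractions), `loadings`
#'   (functions x n_dims), and `explained_all` (all axes; sums to 1).
#' @export
multidimensional_functioning <- function(standardized, n_dims = 3) {
  x <- as.matrix(standardized)
  kmax <- min(nrow(x) - 1, ncol(x))
  if (n_dims < 1 || n_dims > kmax)
    stop("n_dims must be between 1 and min(n_samples - 1, n_functions) = ", kmax)
  pca <- prcomp(x, center = TRUE, scale. = FALSE)
  ev <- pca$sdev^2
  explained <- ev / sum(ev)
  scores <- pca$x
  loadings <- pca$rotation
  for (k in seq_len(ncol(loadings))) {
    i <- which.max(abs(loadings[, k]))
    if (loadings[i, k] < 0) {
      loadings[, k] <- -loadings[, k]
      scores[, k] <- -scores[, k]
    }
  }
  list(scores = scores[, seq_len(n_dims), drop = FALSE],
       explained_variance = explained[seq_len(n_dims)],
       loadings = loadings[, seq_len(n_dims), drop = FALSE],
       explained_all = explained)
}

#' All three multifunctionality facets at once
#'
#' @param functions a [function_table].
#' @param n_dims number of principal axes (default 3).
#' @return List with `standardized`, `average_mf`, `dim_scores`,
#'   `explained_variance`, `loadings`.
#' @export
multifunctionality <- function(functions, n_dims = 3) {
  z <- z_standardize(functions)
  dims <- multidimensional_functioning(z, n_dims = n_dims)
  list(standardized = z,
       average_mf = average_multifunctionality(z),
       dim_scores = dims$scores,
       explained_variance = dims$explained_variance,
       loadings = dims$loadings)
}
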