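# Principal-component screening of the standardized multi-feature event
# table for hidden sub-populations.

#' Fit a standardized PCA to an event table
#'
#' Z-scores each feature column (the features carry incommensurate units)
#' and eigendecomposes the covariance of the standardized data. Component
#' signs are fixed deterministically: within each loading column the entry
#' of largest magnitude is made positive.
#'
#' @param data Data frame of per-event features.
#' @param vars Feature columns to use (default: all numeric columns).
#' @return An `rtdc_pca` object: list with `loadings` (k x k, columns =
#'   components in decreasing eigenvalue order), `explained_variance`
#'   (eigenvalues; they sum to k), `feature_means`, `feature_sds`,
#'   `feature_names`, `n`.
#' @export
pca_fit <- function(data, vars = NULL) {
  X <- as_feature_matrix(data, vars)
  if (nrow(X) <= ncol(X)) stop("need more events than features", call. = FALSE)
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("constant feature column(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "), call. = FALSE)
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  load <- unname(pc$rotation)
  for (j in seq_len(ncol(load))) {
    top <- which.max(abs(load[, j]))
    if (load[top, j] < 0) load[, j] <- -load[, j]
  }
  dimnames(load) <- list(colnames(X), paste0("PC", seq_len(ncol(load))))
  structure(list(loadings = load,
                 explained_variance = unname(pc$sdev^2),
                 feature_means = colMeans(X),
                 feature_sds = sds,
                 feature_names = colnames(X),
                 n = nrow(X)),
            class = "rtdc_pca")
}

#' @export
print.rtdc_pca <- function(x, ...) {
  pct <- 100 * x$explained_variance / sum(x$explained_variance)
  cat(sprintf("<rtdc_pca> %d features, n = %d; PC1 %.1f%%, PC2 %.1f%%\n",
              length(x$feature_names), x$n, pct[1L],
              if (length(pct) > 1L) pct[2L] else NA))
  invisible(x)
}

#' Project events onto the principal components
#'
#' Standardizes `data` with the training means/SDs and multiplies by the
#' loadings. Projecting the training data gives scores with a diagonal
#' covariance (the eigenvalues).
#'
#' @param model An [pca_fit()] model.
#' @param data Data containing the model's feature columns.
#' @return Tibble of scores with columns `PC1 .. PCk`.
#' @export
pca_project <- function(model, data) {
  stopifnot(inherits(model, "rtdc_pca"))
  cn <- colnames_of(data)
  vars <- if (all(model$feature_names %in% cn)) model$feature_names else NULL
  X <- as_feature_matrix(data, vars)
  if (ncol(X) != length(model$feature_names)) {
    stop("data dimension does not match the fitted model", call. = FALSE)
  }
  Z <- sweep(sweep(X, 2L, model$feature_means), 2L, model$feature_sds, `/`)
  scores <- Z %*% model$loadings
  tibble::as_tibble(as.data.frame(scores))
}
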