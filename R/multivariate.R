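#' Principal components of gradient samples
#'
#' Samples (columns of the Z-score matrix) are the observations, genes the
#' variables. Components are those of the sample covariance; variance
#' fractions are eigenvalues over the total variance. The sign of each
#' component is fixed by making its largest-magnitude gene loading positive,
#' so scores are reproducible rather than reproducible-up-to-sign.
#'
#' @param z numeric matrix (genes x samples), typically from [zscore()].
#' @param n_components number of components to keep (default: all).
#' @return list of class `"PCAResult"`: `scores` (samples x components),
#'   `loadings` (genes x components), `variance_fraction`.
#' @export
pca_samples <- function(z, n_components = NULL) {
  if (!is.matrix(z) || ncol(z) < 2) stop("need a matrix with >= 2 samples")
  max_comp <- min(nrow(z), ncol(z) - 1)
  if (is.null(n_components)) n_components <- max_comp
  if (n_components > min(dim(z))) {
    stop("`n_components` exceeds the matrix dimensions")
  }
  fit <- stats::prcomp(t(z), center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(fit$rotation))
  ev <- fit$sdev^2
  frac <- ev / sum(ev)
  scores <- fit$x[, seq_len(k), drop = FALSE]
  loadings <- fit$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  structure(
    list(scores = scores, loadings = loadings,
         variance_fraction = frac[seq_len(k)],
         all_variance_fraction = frac),
    class = "PCAResult"
  )
}

#' @export
print.PCAResult <- function(x, ...) {
  cat("PCAResult:", nrow(x$scores), "samples,", ncol(x$scores),
      "components; variance fractions:",
      paste0(sprintf("%.1f%%", 100 * x$variance_fraction), collapse = ", "),
      "\n")
  invisible(x)
}

#' Sample-sample correlation with hierarchical ordering
#'
#' Pearson (default) correlation of `log2(x + 1)` expression between
#' samples, plus average-linkage hierarchical clustering on `1 - r` to order
#' the samples. Used to ask whether samples group first by species and then
#' by photosynthetic type.
#'
#' @param x a `StageMeanMatrix`, `ExpressionMatrix` or matrix.
#' @param log_transform apply `log2(x + 1)` first (disable for
#'   already-transformed values).
#' @param method `"pearson"` or `"spearman"`.
#' @return list of class `"SampleCorrelation"`: `correlation` (symmetric,
#'   unit diagonal), `leaf_order` (sample names in dendrogram order),
#'   `hclust`.
#' @export
sample_correlation <- function(x, log_transform = TRUE,
                               method = c("pearson", "spearman")) {
  method <- match.arg(method)
  values <- expr_values(x)
  if (ncol(values) < 2) stop("need at least 2 samples")
  if (log_transform) values <- log2(values + 1)
  sds <- apply(values, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance sample(s): ",
         paste(colnames(values)[sds == 0], collapse = ", "))
  }
  r <- stats::cor(values, method = method)
  hc <- stats::hclust(stats::as.dist(1 - r), method = "average")
  structure(
    list(correlation = r, leaf_order = hc$labels[hc$order], hclust = hc),
    class = "SampleCorrelation"
  )
}

#' @export
print.SampleCorrelation <- function(x, ...) {
  cat("SampleCorrelation:", nrow(x$correlation), "samples; leaf order:",
      paste(utils::head(x$leaf_order, 6), collapse = ", "),
      if (length(x$leaf_order) > 6) "...", "\n")
  invisible(x)
}
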