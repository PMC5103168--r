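# Upper-quartile normalization, the log2(x + 32) transform and PCA QC.

#' Per-sample upper-quartile scale factors
#'
#' For each sample the chosen quantile (default the 75th percentile) of its
#' nonzero count distribution is computed with linear interpolation between
#' order statistics. Factors are the sample quantiles divided by their
#' geometric mean across samples, so they are dimensionless, their
#' geometric mean is exactly 1, and dividing each column by its factor
#' removes library-size scaling.
#'
#' @param cm count matrix.
#' @param quantile quantile of the nonzero counts used as the size proxy.
#' @return named positive numeric vector of factors, one per sample.
#' @export
upper_quartile_factors <- function(cm, quantile = 0.75) {
  if (!(quantile > 0 && quantile < 1)) stop("quantile must lie in (0, 1)")
  q <- vapply(seq_len(ncol(cm)), function(j) {
    x <- cm[, j]
    x <- x[x > 0]
    if (length(x) == 0L) {
      stop("sample '", colnames(cm)[j], "' has all-zero counts")
    }
    stats::quantile(as.numeric(x), probs = quantile, names = FALSE, type = 7)
  }, numeric(1L))
  factors <- q / geometric_mean(q)
  stats::setNames(factors, colnames(cm))
}

#' Upper-quartile normalize a count matrix
#'
#' Divides each sample's counts by its [upper_quartile_factors()] factor.
#' Zeros stay zero; output is real-valued on the count scale.
#'
#' @param cm count matrix.
#' @param quantile quantile passed to [upper_quartile_factors()].
#' @return numeric matrix of normalized counts with the same dimnames.
#' @export
normalize_counts <- function(cm, quantile = 0.75) {
  factors <- upper_quartile_factors(cm, quantile)
  sweep(cm + 0, 2L, factors, "/")
}

#' Variance-stabilising log transform
#'
#' Applies `log2(x + offset)` elementwise. The offset (default 32)
#' moderates the variance of low-count genes so that deviation from
#' constant variance across the intensity range is minimised.
#'
#' @param m non-negative numeric matrix (normalized counts).
#' @param offset positive pseudo-count.
#' @return numeric matrix of log2 signal; every value is at least
#'   `log2(offset)`.
#' @export
log_transform <- function(m, offset = 32) {
  if (offset <= 0) stop("offset must be positive")
  if (any(m < 0)) stop("log_transform requires non-negative values")
  log2(m + offset)
}

#' Normalize and transform in one step
#'
#' @param cm count matrix.
#' @param config run configuration ([run_config()]) supplying the quantile
#'   and log offset.
#' @return log2-scale expression matrix.
#' @export
expression_matrix <- function(cm, config = run_config()) {
  log_transform(normalize_counts(cm, config$quantile), config$log_offset)
}

#' Principal-component sample QC
#'
#' Gene-centered (unscaled) PCA of the samples of a log-expression matrix.
#' Used to visualise sample similarity (for example tissue separation
#' along PC1); it feeds no downstream decision.
#'
#' @param em expression matrix (genes x samples, log2 scale).
#' @param n_components number of components to report; must be smaller
#'   than the number of samples.
#' @return list with `coordinates` (samples x components) and
#'   `variance_explained` (fractions of total variance, non-increasing).
#' @export
pca_qc <- function(em, n_components = 3L) {
  if (ncol(em) < 2L) stop("pca_qc needs at least 2 samples")
  n_components <- as.integer(n_components)
  if (n_components < 1L || n_components >= ncol(em)) {
    stop("n_components must be in [1, n_samples - 1]")
  }
  centered <- em - rowMeans(em)
  if (all(abs(centered) < .Machine$double.eps * 1e3)) {
    stop("degenerate expression matrix: all samples identical")
  }
  fit <- stats::prcomp(t(centered), center = FALSE, scale. = FALSE)
  k <- min(n_components, ncol(fit$x))
  coords <- fit$x[, seq_len(k), drop = FALSE]
  var_all <- fit$sdev^2
  list(
    coordinates = coords,
    variance_explained = (var_all / sum(var_all))[seq_len(k)]
  )
}
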