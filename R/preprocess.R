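#' Two-stage log2 quantile normalization of replicated expression arrays
#'
#' Raw probe intensities are log2-transformed, each individual's technical
#' replicate columns are quantile-normalized against each other and averaged,
#' and the resulting per-individual columns are quantile-normalized across all
#' individuals. After the second stage every column has the same sorted
#' values. Tied values receive the mean of the reference quantiles they span.
#'
#' @param raw an \code{expression_matrix} of raw positive intensities whose
#'   columns are technical replicates.
#' @param replicate_map named list mapping each individual id to the replicate
#'   column names belonging to it; every individual needs at least one
#'   replicate.
#' @return An \code{expression_matrix} with one column per individual.
#' @export
log2_quantile_normalize <- function(raw, replicate_map) {
  if (any(raw$values <= 0)) stop("non-positive intensity")
  if (any(lengths(replicate_map) < 1)) stop("individual with no replicates")
  miss <- setdiff(unlist(replicate_map), raw$sample_ids)
  if (length(miss) > 0)
    stop("replicate columns not in matrix: ", paste(miss, collapse = ", "))
  lg <- log2(raw$values)
  # stage 1: within-individual quantile normalization, then average
  stage1 <- vapply(replicate_map, function(cols) {
    sub <- lg[, cols, drop = FALSE]
    if (ncol(sub) > 1) sub <- limma::normalizeQuantiles(sub, ties = TRUE)
    rowMeans(sub)
  }, numeric(nrow(lg)))
  # stage 2: across individuals
  stage2 <- limma::normalizeQuantiles(stage1, ties = TRUE)
  expression_matrix(stage2, probe_ids = raw$probe_ids,
                    sample_ids = names(replicate_map))
}

#' Exclude samples that are outliers on leading expression principal components
#'
#' Principal components of the centered probes-by-samples matrix are computed
#' in sample space; sample \eqn{i} is excluded when its score on any of the
#' first \code{n_pcs} components deviates from the component mean by more than
#' \code{sd_mult} standard deviations.
#'
#' @param expr an \code{expression_matrix}.
#' @param n_pcs number of leading components checked (default 2).
#' @param sd_mult exclusion multiple of the component standard deviation
#'   (default 1, the literal one-standard-deviation rule; under Gaussian
#'   scores this excludes roughly a third of samples, so larger values are
#'   often more practical).
#' @return character vector of kept sample ids, in input order.
#' @export
pca_outlier_filter <- function(expr, n_pcs = 2, sd_mult = 1.0) {
  n <- length(expr$sample_ids)
  if (n < 3) stop("need at least 3 samples")
  if (n_pcs > n - 1) stop("n_pcs exceeds samples - 1")
  pc <- stats::prcomp(t(expr$values), center = TRUE, scale. = FALSE)
  keep <- rep(TRUE, n)
  for (k in seq_len(min(n_pcs, ncol(pc$x)))) {
    s <- pc$x[, k]
    sdk <- stats::sd(s)
    if (sdk == 0) next  # zero-variance component: no outliers on it
    keep <- keep & (abs(s - mean(s)) <= sd_mult * sdk)
  }
  expr$sample_ids[keep]
}

#' Rank-based inverse normal transform of one probe's expression
#'
#' Values are replaced by \eqn{\Phi^{-1}((rank - 0.5)/n)} with average ranks
#' for ties, yielding an approximately standard normal vector that is
#' invariant to any strictly increasing transform of the input.
#'
#' @param values numeric vector, length at least 2, not constant.
#' @return numeric vector of the same length.
#' @export
standard_normalize <- function(values) {
  n <- length(values)
  if (n < 2) stop("need at least 2 values")
  if (anyNA(values)) stop("missing values")
  if (max(values) == min(values)) stop("constant vector")
  stats::qnorm((rank(values, ties.method = "average") - 0.5) / n)
}
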