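# Storey pi1 estimation and replication/sharing analyses.

#' Estimate the fraction of true alternatives in a p-value collection
#'
#' Storey's estimator: \eqn{\pi_0(\lambda) = \#\{p > \lambda\}/(m(1-\lambda))}
#' is evaluated on the grid \eqn{\lambda = 0.05, 0.10, \ldots, 0.95}, smoothed
#' with a cubic smoothing spline (3 degrees of freedom) and read off at
#' \eqn{\lambda = 0.95}; the result is clamped to \[0, 1\] and
#' \eqn{\pi_1 = 1 - \pi_0}.
#'
#' @param pvalues numeric vector of at least 50 finite p-values in \[0, 1\].
#' @return An object of class \code{pi1_estimate}: list with \code{pi0},
#'   \code{pi1}, \code{lambda_grid}, \code{pi0_at_lambda}, \code{m}.
#' @export
storey_pi1 <- function(pvalues) {
  p <- pvalues[is.finite(pvalues)]
  if (length(p) < length(pvalues)) stop("non-finite p-values")
  m <- length(p)
  if (m < 50) stop("need at least 50 p-values (estimate unstable below)")
  if (any(p < 0 | p > 1)) stop("p-values outside [0, 1]")
  lambda <- seq(0.05, 0.95, by = 0.05)
  pi0_l <- vapply(lambda, function(l) sum(p > l) / (m * (1 - l)), numeric(1))
  fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
  pi0 <- stats::predict(fit, x = 0.95)$y
  pi0 <- min(max(pi0, 0), 1)
  structure(list(pi0 = pi0, pi1 = 1 - pi0, lambda_grid = lambda,
                 pi0_at_lambda = pi0_l, m = m),
            class = "pi1_estimate")
}

#' @export
print.pi1_estimate <- function(x, ...) {
  cat("pi1_estimate: pi1 =", signif(x$pi1, 4), "(m =", x$m, "p-values)\n")
  invisible(x)
}

#' Test replication of discovered associations in a second dataset
#'
#' Each (variant, probe) pair is re-tested by Spearman rank correlation in the
#' replication cohort; a pair replicates when its replication p-value is below
#' \code{alpha} and the correlation has the same sign as at discovery.
#'
#' @param pairs data.frame with columns \code{variant_id}, \code{probe_id} and
#'   discovery \code{rho}.
#' @param rep_geno,rep_expr replication \code{genotype_table} and
#'   \code{expression_matrix}.
#' @param alpha nominal replication threshold (default 0.05).
#' @return list with \code{per_pair} (data.frame: ids, discovery rho,
#'   replication rho/p, testable, replicated, opposite_sign), \code{n_tested},
#'   \code{n_replicated}, \code{n_untestable} and
#'   \code{frac_opposite_sign} among significant pairs.
#' @export
replication_test <- function(pairs, rep_geno, rep_expr, alpha = 0.05) {
  shared <- intersect_samples(rep_geno, rep_expr)
  g <- shared$geno; e <- shared$expr
  vi <- match(pairs$variant_id, g$variants$variant_id)
  pi <- match(pairs$probe_id, e$probe_ids)
  testable <- !is.na(vi) & !is.na(pi)
  rep_rho <- rep(NA_real_, nrow(pairs))
  rep_p <- rep(NA_real_, nrow(pairs))
  for (j in which(testable)) {
    st <- spearman_test(g$dosage[vi[j], ], e$values[pi[j], ])
    rep_rho[j] <- st$rho; rep_p[j] <- st$p
  }
  sig <- testable & rep_p < alpha
  same <- sig & sign(rep_rho) == sign(pairs$rho)
  per_pair <- data.frame(pairs[, c("variant_id", "probe_id", "rho")],
                         rep_rho = rep_rho, rep_p = rep_p,
                         testable = testable,
                         replicated = same,
                         opposite_sign = sig & !same,
                         stringsAsFactors = FALSE)
  list(per_pair = per_pair,
       n_tested = sum(testable),
       n_replicated = sum(same, na.rm = TRUE),
       n_untestable = sum(!testable),
       frac_opposite_sign = if (sum(sig, na.rm = TRUE) > 0)
         sum(sig & !same, na.rm = TRUE) / sum(sig, na.rm = TRUE) else 0)
}

#' Sharing (pi1) of an association list as a function of sample size
#'
#' For each requested sample size, individuals are repeatedly subsampled from
#' the target cohort, every pair's replication p-value is computed in the
#' subsample, and Storey's \eqn{\pi_1} summarizes the p-value collection; the
#' mean and the 5\%/95\% quantiles across draws are reported.
#'
#' @inheritParams replication_test
#' @param target_geno,target_expr the cohort subsampled for replication.
#' @param sample_sizes integer vector of subsample sizes (sizes below 50 give
#'   unstable pi1 and trigger a warning).
#' @param n_draws subsample draws per size (default 20).
#' @param seed integer seed.
#' @return data.frame with columns \code{n}, \code{pi1_mean}, \code{pi1_lo},
#'   \code{pi1_hi} (5\% and 95\% quantiles across draws).
#' @export
sharing_curve <- function(pairs, target_geno, target_expr, sample_sizes,
                          n_draws = 20, seed = 1) {
  shared <- intersect_samples(target_geno, target_expr)
  g <- shared$geno; e <- shared$expr
  n_all <- length(g$sample_ids)
  if (max(sample_sizes) > n_all)
    stop("requested sample size exceeds cohort size")
  if (any(sample_sizes < 50))
    warning("sample sizes below 50: pi1 unstable")
  vi <- match(pairs$variant_id, g$variants$variant_id)
  pi_ <- match(pairs$probe_id, e$probe_ids)
  ok <- !is.na(vi) & !is.na(pi_)
  vi <- vi[ok]; pi_ <- pi_[ok]
  set.seed(seed)
  out <- lapply(sample_sizes, function(nn) {
    pis <- vapply(seq_len(n_draws), function(d) {
      sub <- sample.int(n_all, nn)
      pv <- vapply(seq_along(vi), function(j) {
        x <- g$dosage[vi[j], sub]; y <- e$values[pi_[j], sub]
        if (max(x) == min(x) || max(y) == min(y)) return(1)
        spearman_test(x, y)$p
      }, numeric(1))
      storey_pi1(pv)$pi1
    }, numeric(1))
    data.frame(n = nn, pi1_mean = mean(pis),
               pi1_lo = unname(stats::quantile(pis, 0.05)),
               pi1_hi = unname(stats::quantile(pis, 0.95)))
  })
  do.call(rbind, out)
}

#' Trans load of one variant as a pi1 over all eligible trans probes
#'
#' The variant is tested by Spearman rank correlation against every probe
#' passing the trans filters (not multi-mapped, different chromosome or beyond
#' the exclusion distance), and Storey's \eqn{\pi_1} of the resulting p-value
#' collection estimates the fraction of probes the variant affects in trans.
#'
#' @param variant_id variant to profile.
#' @inheritParams trans_scan
#' @return A \code{pi1_estimate}.
#' @export
pi1_trans_profile <- function(variant_id, geno, expr, annot,
                              exclusion = 5e6) {
  shared <- intersect_samples(geno, expr)
  g <- shared$geno; e <- shared$expr
  vi <- match(variant_id, g$variants$variant_id)
  if (is.na(vi)) stop("variant not found: ", variant_id)
  ann <- .join_annotation(e, annot)
  elig <- which(!ann$multi_mapped &
                  (ann$chromosome != g$variants$chromosome[vi] |
                     abs(ann$tss - g$variants$position[vi]) > exclusion))
  if (length(elig) < 50) stop("fewer than 50 eligible trans probes")
  x <- g$dosage[vi, ]
  pv <- vapply(elig, function(i)
    spearman_test(x, e$values[i, ])$p, numeric(1))
  storey_pi1(pv)
}
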