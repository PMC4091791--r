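# Matched-variant resampling enrichment test.

#' Sample variants matched on MAF and distance to the closest gene
#'
#' Each target variant is matched with one pool variant whose minor allele
#' frequency lies within \code{maf_tol} and whose distance to the closest gene
#' lies within \code{dist_tol} of the target's; the match is drawn uniformly
#' among eligible pool variants. Targets with no eligible match are skipped
#' and counted.
#'
#' @param targets data.frame with columns \code{variant_id}, \code{maf} and
#'   \code{distance_to_closest_gene} (e.g. rows of a genotype table annotated
#'   with \code{\link{annotate_gene_distance}}).
#' @param pool data.frame of candidate variants with the same columns; must
#'   exclude the targets themselves.
#' @param maf_tol MAF window (default 0.01, i.e. +/- 1\%).
#' @param dist_tol distance window in bp (default 2000).
#' @param seed integer seed.
#' @return list with \code{matched} (character vector of matched variant ids,
#'   one per matchable target) and \code{n_unmatchable}.
#' @export
match_variants <- function(targets, pool, maf_tol = 0.01, dist_tol = 2000,
                           seed = NULL) {
  need <- c("variant_id", "maf", "distance_to_closest_gene")
  if (!all(need %in% names(targets)) || !all(need %in% names(pool)))
    stop("targets and pool need columns: ", paste(need, collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  matched <- character(0)
  n_unmatchable <- 0L
  for (i in seq_len(nrow(targets))) {
    elig <- which(abs(pool$maf - targets$maf[i]) <= maf_tol &
                    abs(pool$distance_to_closest_gene -
                          targets$distance_to_closest_gene[i]) <= dist_tol)
    if (length(elig) == 0) {
      n_unmatchable <- n_unmatchable + 1L
    } else {
      pick <- if (length(elig) == 1) elig else elig[sample.int(length(elig), 1)]
      matched <- c(matched, pool$variant_id[pick])
    }
  }
  list(matched = matched, n_unmatchable = n_unmatchable)
}

#' Enrichment of a target variant set among significant eQTL variants
#'
#' The observed overlap between the targets and the significant set is
#' compared with the overlaps of \code{n_perm} independently drawn matched
#' variant sets (matched on MAF and distance to the closest gene); the
#' empirical p-value is \eqn{(1 + \#\{null \ge observed\})/(n_{perm} + 1)}.
#'
#' @inheritParams match_variants
#' @param significant_set character vector of variant ids significant in the
#'   eQTL analysis.
#' @param n_perm number of matched sets drawn (default 1000).
#' @return An object of class \code{enrichment_result}: list with
#'   \code{observed_overlap}, \code{null_overlaps}, \code{null_median},
#'   \code{empirical_p}, \code{n_unmatchable}.
#' @export
enrichment_test <- function(targets, significant_set, pool, n_perm = 1000,
                            maf_tol = 0.01, dist_tol = 2000, seed = 1) {
  set.seed(seed)
  observed <- sum(targets$variant_id %in% significant_set)
  # eligibility per target computed once; each permutation resamples matches
  elig_list <- lapply(seq_len(nrow(targets)), function(i)
    which(abs(pool$maf - targets$maf[i]) <= maf_tol &
            abs(pool$distance_to_closest_gene -
                  targets$distance_to_closest_gene[i]) <= dist_tol))
  matchable <- lengths(elig_list) > 0
  if (!any(matchable)) stop("all targets unmatchable")
  sig_pool <- pool$variant_id %in% significant_set
  null_overlaps <- vapply(seq_len(n_perm), function(b) {
    sum(vapply(elig_list[matchable], function(e)
      sig_pool[if (length(e) == 1) e else e[sample.int(length(e), 1)]],
      logical(1)))
  }, integer(1))
  structure(list(observed_overlap = observed,
                 null_overlaps = null_overlaps,
                 null_median = stats::median(null_overlaps),
                 empirical_p = (1 + sum(null_overlaps >= observed)) /
                   (n_perm + 1),
                 n_unmatchable = sum(!matchable)),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("enrichment_result: observed overlap", x$observed_overlap,
      "vs null median", x$null_median,
      "(empirical p =", signif(x$empirical_p, 3), ")\n")
  if (x$n_unmatchable > 0)
    cat(" ", x$n_unmatchable, "target(s) unmatchable\n")
  invisible(x)
}
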