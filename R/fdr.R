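# Permutation null distributions and FDR threshold selection.
#
# Cis: a gene-based null — per permutation round one shared sample-label
# permutation is applied to all probes (preserving inter-probe correlation)
# and the minimum cis p-value per probe is recorded.  Trans: a genome-wide
# null — per probe per round the probe's genome-wide minimum trans p-value is
# recorded and all probe-by-round minima are pooled.
#
# Because ranks are invariant under relabeling, permuting sample labels of a
# probe is implemented by permuting its precomputed standardized rank vector;
# no re-ranking is needed, and per-probe correlations against all window
# variants for all rounds reduce to one matrix product.

#' Gene-based cis permutation null
#'
#' For each of \code{n_perm} rounds, a single random permutation of sample
#' labels is applied to the whole expression matrix, the cis scan is re-run,
#' and the minimum p-value per probe is recorded.
#'
#' @inheritParams cis_scan
#' @param n_perm number of permutation rounds (default 1000; fewer than 100
#'   gives unstable thresholds and triggers a warning).
#' @param seed integer seed fixing the permutations.
#' @return An object of class \code{cis_null}: list with \code{minp}
#'   (probes-by-\code{n_perm} matrix of per-probe minima, each row sorted
#'   ascending), \code{probe_ids}, \code{n_perm}, \code{seed}.
#' @export
cis_permutation_null <- function(geno, expr, annot, half_window = 1e6,
                                 n_perm = 1000, seed = 1) {
  if (n_perm < 100) warning("n_perm < 100: permutation thresholds unstable")
  shared <- intersect_samples(geno, expr)
  geno <- shared$geno; expr <- shared$expr
  n <- length(geno$sample_ids)
  ann <- .join_annotation(expr, annot)
  probes <- which(!ann$contains_common_snp)
  zg <- .rank_std_rows(geno$dosage)
  set.seed(seed)
  perms <- replicate(n_perm, sample.int(n))  # n x n_perm index matrix
  keep <- logical(length(probes))
  minp <- matrix(NA_real_, length(probes), n_perm)
  for (k in seq_along(probes)) {
    i <- probes[k]
    idx <- which(geno$variants$chromosome == ann$chromosome[i] &
                   abs(geno$variants$position - ann$tss[i]) <= half_window)
    if (length(idx) == 0) next
    keep[k] <- TRUE
    ze <- .rank_std(expr$values[i, ])
    zperm <- matrix(ze[perms], n, n_perm)
    rho <- zg[idx, , drop = FALSE] %*% zperm
    maxabs <- apply(abs(rho), 2, max)
    minp[k, ] <- .spearman_p(pmin(maxabs, 1), n)
  }
  minp <- minp[keep, , drop = FALSE]
  minp <- t(apply(minp, 1, sort))
  structure(list(minp = minp, probe_ids = ann$probe_id[probes[keep]],
                 n_perm = n_perm, seed = seed),
            class = "cis_null")
}

#' Select the per-gene cis permutation threshold controlling the FDR
#'
#' For permutation rank \eqn{r}, the threshold for probe \eqn{g} is the
#' \eqn{r}-th smallest of its permuted minima; the expected number of false
#' discoveries at rank \eqn{r} is \eqn{G r/(n_{perm}+1)} over \eqn{G} tested
#' probes, and FDR(r) is that expectation divided by the observed discovery
#' count. The largest rank with FDR at or below \code{target_fdr} is chosen.
#'
#' @param observed an \code{eqtl_scan} from \code{\link{cis_scan}}.
#' @param null a \code{cis_null} covering all observed probes.
#' @param target_fdr target false discovery rate (default 0.05).
#' @return An object of class \code{fdr_threshold}: list with
#'   \code{rank_used}, \code{per_probe_threshold} (named vector),
#'   \code{discoveries} (probe ids), \code{achieved_fdr}, \code{scope}.
#' @export
cis_fdr_select <- function(observed, null, target_fdr = 0.05) {
  best <- observed$best_per_probe
  if (is.null(best) || nrow(best) == 0)
    return(structure(list(rank_used = 0L, per_probe_threshold = numeric(0),
                          discoveries = character(0), achieved_fdr = 0,
                          target_fdr = target_fdr, scope = "cis"),
                     class = "fdr_threshold"))
  gi <- match(best$probe_id, null$probe_ids)
  if (anyNA(gi)) stop("null does not cover all observed probes")
  G <- nrow(best)
  n_perm <- null$n_perm
  obs <- best$p
  nullm <- null$minp[gi, , drop = FALSE]
  D <- vapply(seq_len(n_perm),
              function(r) sum(obs < nullm[, r]), integer(1))
  E <- G * seq_len(n_perm) / (n_perm + 1)
  fdr <- E / pmax(D, 1)
  ok <- which(fdr <= target_fdr & D > 0)
  if (length(ok) == 0)
    return(structure(list(rank_used = 0L, per_probe_threshold = stats::setNames(
      rep(0, G), best$probe_id), discoveries = character(0),
      achieved_fdr = 0, target_fdr = target_fdr, scope = "cis"),
      class = "fdr_threshold"))
  r <- max(ok)
  thr <- stats::setNames(nullm[, r], best$probe_id)
  structure(list(rank_used = r, per_probe_threshold = thr,
                 discoveries = best$probe_id[obs < thr],
                 achieved_fdr = fdr[r], target_fdr = target_fdr,
                 scope = "cis"),
            class = "fdr_threshold")
}

#' @export
print.fdr_threshold <- function(x, ...) {
  cat("fdr_threshold (", x$scope, "): ", length(x$discoveries),
      " discoveries at target FDR ", x$target_fdr,
      " (achieved ", signif(x$achieved_fdr, 3), ")\n", sep = "")
  if (x$scope == "trans")
    cat("genome-wide p threshold:", format(x$threshold, digits = 4), "\n")
  else cat("permutation rank used:", x$rank_used, "\n")
  invisible(x)
}

#' Genome-wide trans permutation null
#'
#' A set of probes (by default a random subset, one per gene) is permuted
#' \code{n_perm} times; for each probe and round the genome-wide minimum trans
#' p-value is recorded, and all probe-by-round minima are pooled into a single
#' sorted null vector — treating the rounds as if one probe had been permuted
#' \code{n_probes * n_perm} times.
#'
#' @inheritParams trans_scan
#' @param n_probes number of probes permuted, one per gene (default 288);
#'   ignored when \code{probes} is given.
#' @param n_perm permutation rounds per probe (default 1000).
#' @param seed integer seed.
#' @param probes optional character vector of probe ids to permute ("all
#'   probes" variant used for the trans analysis of cis-eQTLs).
#' @return An object of class \code{trans_null}: list with \code{pooled}
#'   (sorted vector of length \code{n_probes * n_perm}), \code{n_probes},
#'   \code{n_perm}, \code{seed}.
#' @export
trans_permutation_null <- function(geno, expr, annot, exclusion = 5e6,
                                   n_probes = 288, n_perm = 1000, seed = 1,
                                   probes = NULL, variant_subset = NULL) {
  if (!is.null(variant_subset)) {
    keep <- geno$variants$variant_id %in% variant_subset
    geno$variants <- geno$variants[keep, , drop = FALSE]
    geno$dosage <- geno$dosage[keep, , drop = FALSE]
  }
  shared <- intersect_samples(geno, expr)
  geno <- shared$geno; expr <- shared$expr
  n <- length(geno$sample_ids)
  ann <- .join_annotation(expr, annot)
  eligible <- which(!ann$multi_mapped)
  set.seed(seed)
  if (is.null(probes)) {
    # one probe per gene among eligible probes
    genes <- ann$gene_id[eligible]
    by_gene <- split(eligible, genes)
    pick <- vapply(by_gene, function(ix)
      if (length(ix) == 1) ix else ix[sample.int(length(ix), 1)], integer(1))
    if (length(pick) < n_probes)
      stop("fewer eligible probes (one per gene: ", length(pick),
           ") than requested (", n_probes, ")")
    sel <- sort(pick[sample.int(length(pick), n_probes)])
  } else {
    sel <- eligible[ann$probe_id[eligible] %in% probes]
    if (length(sel) == 0) stop("requested probes not eligible")
    n_probes <- length(sel)
  }
  zg <- .rank_std_rows(geno$dosage)
  perms <- replicate(n_perm, sample.int(n))
  pooled <- matrix(NA_real_, length(sel), n_perm)
  for (k in seq_along(sel)) {
    i <- sel[k]
    idx <- which(geno$variants$chromosome != ann$chromosome[i] |
                   abs(geno$variants$position - ann$tss[i]) > exclusion)
    if (length(idx) == 0) stop("probe ", ann$probe_id[i],
                               " has no trans variants")
    ze <- .rank_std(expr$values[i, ])
    zperm <- matrix(ze[perms], n, n_perm)
    rho <- zg[idx, , drop = FALSE] %*% zperm
    maxabs <- apply(abs(rho), 2, max)
    pooled[k, ] <- .spearman_p(pmin(maxabs, 1), n)
  }
  structure(list(pooled = sort(as.vector(pooled)), n_probes = n_probes,
                 n_perm = n_perm, seed = seed),
            class = "trans_null")
}

#' Select the genome-wide trans p-value threshold controlling the FDR
#'
#' The candidate threshold sweeps the pooled null values; at threshold
#' \eqn{\tau} the expected false discovery count is the null tail fraction at
#' \eqn{\tau} times the number of probes tested, and FDR is that expectation
#' over the number of probes whose observed minimum p is at or below
#' \eqn{\tau}. The largest \eqn{\tau} meeting the target is returned.
#'
#' @param observed an \code{eqtl_scan} from \code{\link{trans_scan}} (its
#'   best-per-probe minima are used).
#' @param null a \code{trans_null}.
#' @param n_probes_tested number of probes in the observed scan's universe;
#'   defaults to the number of probes with records in \code{observed}.
#' @param target_fdr target false discovery rate (default 0.05).
#' @return An object of class \code{fdr_threshold} with \code{threshold} (a
#'   pooled null value or 0), \code{discoveries} (data.frame of records with
#'   \code{p <= threshold}), \code{achieved_fdr}, \code{scope = "trans"}.
#' @export
trans_fdr_select <- function(observed, null, n_probes_tested = NULL,
                             target_fdr = 0.05) {
  best <- observed$best_per_probe
  empty <- structure(list(threshold = 0, rank_used = 0L,
                          discoveries = observed$records[0, , drop = FALSE],
                          achieved_fdr = 0, target_fdr = target_fdr,
                          scope = "trans"),
                     class = "fdr_threshold")
  if (is.null(best) || nrow(best) == 0) return(empty)
  if (is.null(n_probes_tested)) n_probes_tested <- nrow(best)
  pooled <- null$pooled
  m <- length(pooled)
  cand <- unique(pooled)
  n_le <- findInterval(cand, pooled)          # null values <= tau
  obs_sorted <- sort(best$p)
  D <- findInterval(cand, obs_sorted)         # probes with min p <= tau
  E <- n_le / m * n_probes_tested
  fdr <- E / pmax(D, 1)
  ok <- which(fdr <= target_fdr & D > 0)
  if (length(ok) == 0) return(empty)
  sel <- ok[which.max(cand[ok])]
  tau <- cand[sel]
  structure(list(threshold = tau, rank_used = n_le[sel],
                 discoveries = observed$records[observed$records$p <= tau, ,
                                                drop = FALSE],
                 achieved_fdr = fdr[sel],
                 target_fdr = target_fdr, scope = "trans"),
            class = "fdr_threshold")
}
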