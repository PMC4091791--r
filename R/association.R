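# Rank-based association engine.
#
# Spearman's rho is computed as the Pearson correlation of mid-ranks
# (average ranks for ties) and its two-sided p-value from the t
# approximation t = rho * sqrt((n-2)/(1-rho^2)) on n-2 degrees of freedom.
# All scans share one primitive: rank vectors standardized to mean 0 and
# unit variance (denominator n-1), so that rho is a dot product / (n-1).

# standardize the mid-ranks of each row of a matrix
.rank_std_rows <- function(m) {
  n <- ncol(m)
  r <- t(apply(m, 1, rank, ties.method = "average"))
  ctr <- r - rowMeans(r)
  s <- sqrt(rowSums(ctr^2) / (n - 1))
  if (any(s == 0)) stop("constant row encountered in rank standardization")
  ctr / (s * sqrt(n - 1))  # rows scaled so dot(x, y) = rho
}

.rank_std <- function(x) {
  n <- length(x)
  r <- rank(x, ties.method = "average")
  ctr <- r - mean(r)
  s <- sqrt(sum(ctr^2))
  if (s == 0) stop("constant vector")
  ctr / s
}

# two-sided t-approximation p-value for spearman rho; |rho| >= 1 maps to the
# smallest positive normal double
.spearman_p <- function(rho, n) {
  p <- numeric(length(rho))
  ext <- abs(rho) >= 1
  p[ext] <- .Machine$double.xmin
  if (any(!ext)) {
    r <- rho[!ext]
    tt <- abs(r) * sqrt((n - 2) / (1 - r^2))
    p[!ext] <- pmax(2 * stats::pt(-tt, df = n - 2), .Machine$double.xmin)
  }
  p
}

#' Spearman rank association test
#'
#' @param x numeric dosage vector.
#' @param y numeric expression vector of the same length.
#' @return list with \code{rho} (Pearson correlation of average ranks),
#'   \code{p} (two-sided t-approximation p-value; reported as the smallest
#'   positive normal double when \code{|rho| = 1}) and \code{n}.
#' @export
spearman_test <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  n <- length(x)
  if (n < 4) stop("need n >= 4")
  if (max(x) == min(x) || max(y) == min(y)) stop("constant input")
  rho <- sum(.rank_std(x) * .rank_std(y))
  rho <- max(min(rho, 1), -1)
  list(rho = rho, p = .spearman_p(rho, n), n = n)
}

#' -log10 p-value implied by a Spearman correlation and sample size
#'
#' Computed in log space so that very strong correlations (|t| up to about 60)
#' do not underflow.
#'
#' @param rho Spearman correlation, \code{|rho| < 1}.
#' @param n number of samples, at least 4.
#' @return \code{-log10} of the two-sided t-approximation p-value.
#' @export
neglog10_p_from_rho <- function(rho, n) {
  if (any(abs(rho) >= 1)) stop("|rho| must be < 1")
  if (any(n < 4)) stop("need n >= 4")
  tt <- abs(rho) * sqrt((n - 2) / (1 - rho^2))
  -(stats::pt(-tt, df = n - 2, log.p = TRUE) + log(2)) / log(10)
}

# assemble an eqtl_scan object from per-probe record blocks
.make_scan <- function(blocks, n, scope) {
  if (length(blocks) == 0) {
    records <- data.frame(variant_id = character(), probe_id = character(),
                          gene_id = character(), rho = numeric(),
                          p = numeric(), n = integer(), scope = character(),
                          stringsAsFactors = FALSE)
  } else {
    records <- do.call(rbind, blocks)
    rownames(records) <- NULL
  }
  best <- NULL
  tested <- integer(0)
  if (nrow(records) > 0) {
    ord <- order(records$probe_id, records$p)
    first <- !duplicated(records$probe_id[ord])
    best <- records[ord[first], , drop = FALSE]
    rownames(best) <- NULL
    tst <- table(records$probe_id)
    tested <- stats::setNames(as.integer(tst), names(tst))
  }
  structure(list(records = records, best_per_probe = best,
                 tested_counts = tested, n = n, scope = scope),
            class = "eqtl_scan")
}

#' @export
print.eqtl_scan <- function(x, ...) {
  cat("eqtl_scan (", x$scope, "): ", nrow(x$records), " tests, ",
      length(x$tested_counts), " probes, n = ", x$n, "\n", sep = "")
  if (!is.null(x$best_per_probe) && nrow(x$best_per_probe) > 0) {
    top <- x$best_per_probe[order(x$best_per_probe$p), ]
    cat("top associations:\n")
    print(utils::head(top, 5), row.names = FALSE)
  }
  invisible(x)
}

# generic scan: eligible(i) gives the variant indices tested for probe i
.scan <- function(geno, expr, annot, probe_keep, eligible, scope) {
  shared <- intersect_samples(geno, expr)
  geno <- shared$geno; expr <- shared$expr
  n <- length(geno$sample_ids)
  if (n < 4) stop("need at least 4 shared samples")
  ann <- .join_annotation(expr, annot)
  probes <- which(probe_keep(ann))
  if (length(probes) == 0) return(.make_scan(list(), n, scope))
  zg <- .rank_std_rows(geno$dosage)
  blocks <- vector("list", length(probes))
  for (k in seq_along(probes)) {
    i <- probes[k]
    idx <- eligible(ann[i, ], geno$variants)
    if (length(idx) == 0) next
    ze <- .rank_std(expr$values[i, ])
    rho <- as.vector(zg[idx, , drop = FALSE] %*% ze)
    rho <- pmax(pmin(rho, 1), -1)
    blocks[[k]] <- data.frame(
      variant_id = geno$variants$variant_id[idx],
      probe_id = ann$probe_id[i], gene_id = ann$gene_id[i],
      rho = rho, p = .spearman_p(rho, n), n = n, scope = scope,
      stringsAsFactors = FALSE)
  }
  .make_scan(blocks[!vapply(blocks, is.null, logical(1))], n, scope)
}

#' Cis eQTL scan
#'
#' Tests every variant within \code{half_window} base pairs of a probe's TSS
#' (same chromosome, window closed on both ends) against that probe's
#' expression using Spearman rank correlation. Probes flagged as containing a
#' common SNP are excluded.
#'
#' @param geno a \code{genotype_table}.
#' @param expr an \code{expression_matrix}.
#' @param annot a \code{probe_annotation} covering every probe.
#' @param half_window half-width of the cis window around the TSS in bp
#'   (default 1e6, i.e. a 2 Mb window).
#' @return An \code{eqtl_scan} with all records, the best record per probe and
#'   per-probe tested counts.
#' @export
cis_scan <- function(geno, expr, annot, half_window = 1e6) {
  .scan(geno, expr, annot,
        probe_keep = function(ann) !ann$contains_common_snp,
        eligible = function(a, v)
          which(v$chromosome == a$chromosome &
                  abs(v$position - a$tss) <= half_window),
        scope = "cis")
}

#' Trans eQTL scan
#'
#' Tests every variant on a different chromosome, or farther than
#' \code{exclusion} base pairs from the probe's TSS, against the probe's
#' expression. Multi-mapped probes are excluded.
#'
#' @inheritParams cis_scan
#' @param exclusion same-chromosome exclusion distance in bp (default 5e6).
#' @param variant_subset optional character vector restricting the variants
#'   tested (e.g. unique cis-eQTL variants for the trans-of-cis analysis).
#' @return An \code{eqtl_scan}.
#' @export
trans_scan <- function(geno, expr, annot, exclusion = 5e6,
                       variant_subset = NULL) {
  if (!is.null(variant_subset)) {
    keep <- geno$variants$variant_id %in% variant_subset
    geno$variants <- geno$variants[keep, , drop = FALSE]
    geno$dosage <- geno$dosage[keep, , drop = FALSE]
  }
  .scan(geno, expr, annot,
        probe_keep = function(ann) !ann$multi_mapped,
        eligible = function(a, v)
          which(v$chromosome != a$chromosome |
                  abs(v$position - a$tss) > exclusion),
        scope = "trans")
}

#' Filter artifact-prone CNV trans associations
#'
#' Removes CNV trans records when (a) the associated probe lies on the CNV's
#' own chromosome, (b) the probe's chromosome harbors at least one SNP whose
#' dosage is correlated with the CNV (squared Pearson correlation above
#' \code{ld_r2}), suggesting the CNV is mismapped, or (c) the CNV's dosage
#' differs between males and females (Wilcoxon rank-sum p below
#' \code{sex_alpha}), which manufactures associations with sex-differential
#' probes.
#'
#' @param scan an \code{eqtl_scan} containing trans records.
#' @param geno the \code{genotype_table} the scan used.
#' @param annot the \code{probe_annotation}.
#' @param sex integer/numeric vector (two levels, e.g. 0/1) aligned with the
#'   genotype table's samples; required for the sex-imbalance filter.
#' @param ld_r2 squared-correlation threshold for the mismapping filter
#'   (default 0.1).
#' @param sex_alpha p-value threshold for the sex-imbalance filter; default
#'   0.05 divided by the number of CNVs (Bonferroni).
#' @param sex_filter logical; apply the sex-imbalance filter (default TRUE,
#'   in which case \code{sex} is required).
#' @return list with \code{scan} (filtered \code{eqtl_scan}) and
#'   \code{removed} (data.frame of removed records with a \code{reason} code:
#'   \code{same_chrom}, \code{ld_chrom} or \code{sex_imbalance}).
#' @export
cnv_trans_filter <- function(scan, geno, annot, sex = NULL, ld_r2 = 0.1,
                             sex_alpha = NULL, sex_filter = TRUE) {
  if (sex_filter && is.null(sex))
    stop("sex vector required when the sex-imbalance filter is enabled")
  if (!sex_filter) sex <- NULL
  rec <- scan$records
  v <- geno$variants
  cnv_ids <- v$variant_id[v$variant_type == "CNV"]
  is_cnv_rec <- rec$variant_id %in% cnv_ids
  if (is.null(sex_alpha)) sex_alpha <- 0.05 / max(length(cnv_ids), 1)

  reason <- rep(NA_character_, nrow(rec))
  used_cnvs <- unique(rec$variant_id[is_cnv_rec])

  # per-CNV precomputations
  sex_imbalanced <- stats::setNames(rep(FALSE, length(used_cnvs)), used_cnvs)
  ld_chroms <- stats::setNames(vector("list", length(used_cnvs)), used_cnvs)
  snp_rows <- which(v$variant_type == "SNP")
  for (cv in used_cnvs) {
    ci <- match(cv, v$variant_id)
    d <- geno$dosage[ci, ]
    if (length(snp_rows) > 0) {
      r <- as.vector(stats::cor(d, t(geno$dosage[snp_rows, , drop = FALSE])))
      ld_chroms[[cv]] <- unique(v$chromosome[snp_rows[which(r^2 > ld_r2)]])
    } else ld_chroms[[cv]] <- character(0)
    if (!is.null(sex)) {
      if (length(sex) != ncol(geno$dosage))
        stop("sex vector not aligned to samples")
      g1 <- d[sex == sort(unique(sex))[1]]
      g2 <- d[sex != sort(unique(sex))[1]]
      pw <- suppressWarnings(stats::wilcox.test(g1, g2)$p.value)
      sex_imbalanced[cv] <- is.finite(pw) && pw < sex_alpha
    }
  }
  probe_chrom <- annot$chromosome[match(rec$probe_id, annot$probe_id)]
  cnv_chrom <- v$chromosome[match(rec$variant_id, v$variant_id)]
  for (j in which(is_cnv_rec)) {
    cv <- rec$variant_id[j]
    if (probe_chrom[j] == cnv_chrom[j]) reason[j] <- "same_chrom"
    else if (probe_chrom[j] %in% ld_chroms[[cv]]) reason[j] <- "ld_chrom"
    else if (sex_imbalanced[cv]) reason[j] <- "sex_imbalance"
  }
  removed <- cbind(rec[!is.na(reason), , drop = FALSE],
                   reason = reason[!is.na(reason)])
  rownames(removed) <- NULL
  kept <- rec[is.na(reason), , drop = FALSE]
  out <- .make_scan(if (nrow(kept) > 0) list(kept) else list(),
                    scan$n, scan$scope)
  out$tested_counts <- scan$tested_counts  # tested counts reflect the scan
  list(scan = out, removed = removed)
}
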