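#' Iterative conditional scan for independent cis-eQTLs of one gene
#'
#' The probe's standard-normalized expression is regressed jointly on all
#' previously accepted variants' dosages; the residuals are re-scanned across
#' the cis window with Spearman rank correlation, and the best variant is
#' accepted while its p-value stays below the gene's permutation threshold.
#' A candidate whose dosage is essentially collinear with the accepted set
#' (multiple R-squared above 0.999) stops the procedure with a warning.
#'
#' @param probe_id probe to dissect (must have a significant primary eQTL).
#' @inheritParams cis_scan
#' @param gene_threshold the gene's cis permutation p-value threshold; rounds
#'   stop when the best residual association is not below it.
#' @return An object of class \code{eqtl_call}: list with \code{probe_id},
#'   \code{gene_id}, \code{steps} (data.frame: step, variant_id, rho, p in
#'   discovery order) and \code{threshold}.
#' @export
conditional_scan <- function(probe_id, geno, expr, annot, gene_threshold,
                             half_window = 1e6) {
  shared <- intersect_samples(geno, expr)
  geno <- shared$geno; expr <- shared$expr
  n <- length(geno$sample_ids)
  i <- match(probe_id, expr$probe_ids)
  if (is.na(i)) stop("probe not in expression matrix: ", probe_id)
  a <- annot[match(probe_id, annot$probe_id), , drop = FALSE]
  if (is.na(a$probe_id[1])) stop("probe not annotated: ", probe_id)
  idx <- which(geno$variants$chromosome == a$chromosome &
                 abs(geno$variants$position - a$tss) <= half_window)
  y <- standard_normalize(expr$values[i, ])
  zg <- if (length(idx) > 0)
    .rank_std_rows(geno$dosage[idx, , drop = FALSE]) else NULL
  accepted <- integer(0)
  steps <- list()
  while (length(idx) > 0 && length(accepted) < length(idx)) {
    resid <- if (length(accepted) == 0) y else {
      X <- cbind(1, t(geno$dosage[idx[accepted], , drop = FALSE]))
      stats::lm.fit(X, y)$residuals
    }
    if (max(resid) == min(resid)) break
    zr <- .rank_std(resid)
    rho <- as.vector(zg %*% zr)
    rho[accepted] <- 0  # never re-accept
    p <- .spearman_p(pmax(pmin(rho, 1), -1), n)
    b <- which.min(p)
    if (p[b] >= gene_threshold) break
    if (length(accepted) > 0) {
      Xa <- t(geno$dosage[idx[accepted], , drop = FALSE])
      fit <- stats::lm.fit(cbind(1, Xa), geno$dosage[idx[b], ])
      r2 <- 1 - sum(fit$residuals^2) /
        sum((geno$dosage[idx[b], ] - mean(geno$dosage[idx[b], ]))^2)
      if (r2 > 0.999) {
        warning("candidate ", geno$variants$variant_id[idx[b]],
                " collinear with accepted set; stopping")
        break
      }
    }
    accepted <- c(accepted, b)
    steps[[length(steps) + 1]] <- data.frame(
      step = length(accepted),
      variant_id = geno$variants$variant_id[idx[b]],
      rho = pmax(pmin(rho[b], 1), -1), p = p[b], stringsAsFactors = FALSE)
  }
  steps <- if (length(steps) > 0) do.call(rbind, steps) else
    data.frame(step = integer(), variant_id = character(), rho = numeric(),
               p = numeric(), stringsAsFactors = FALSE)
  structure(list(probe_id = probe_id, gene_id = a$gene_id[1], steps = steps,
                 threshold = gene_threshold),
            class = "eqtl_call")
}

#' @export
print.eqtl_call <- function(x, ...) {
  cat("eqtl_call for", x$probe_id, "(", x$gene_id, "):",
      nrow(x$steps), "independent variant(s)\n")
  if (nrow(x$steps) > 0) print(x$steps, row.names = FALSE)
  invisible(x)
}

#' Variance of standard-normalized expression explained by dosages
#'
#' Coefficient of determination of the multiple linear regression of
#' expression on one or more dosage vectors.
#'
#' @param expr_std standard-normalized expression vector.
#' @param dosages numeric vector or matrix (samples in rows / one column per
#'   variant).
#' @return r-squared in \[0, 1\].
#' @export
variance_explained <- function(expr_std, dosages) {
  X <- as.matrix(dosages)
  if (nrow(X) != length(expr_std)) X <- t(X)
  if (nrow(X) != length(expr_std)) stop("dimension mismatch")
  if (length(expr_std) <= ncol(X) + 1)
    stop("need n > number of predictors + 1")
  Xd <- cbind(1, X)
  if (qr(Xd)$rank < ncol(Xd)) stop("singular design")
  fit <- stats::lm.fit(Xd, expr_std)
  1 - sum(fit$residuals^2) / sum((expr_std - mean(expr_std))^2)
}

#' Fraction of a probe's heritability explained by its cis-eQTL(s)
#'
#' The variance explained by the eQTL(s) divided by the probe's heritability,
#' capped at 1 when the variance explained exceeds the heritability estimate.
#'
#' @param r2 variance explained by the eQTL(s), in \[0, 1\].
#' @param h2 heritability estimate of the probe, in \[0, 1\].
#' @return \code{min(r2/h2, 1)}; 0 when both are 0.
#' @export
heritability_explained <- function(r2, h2) {
  if (any(r2 < 0 | r2 > 1) || any(h2 < 0 | h2 > 1))
    stop("r2 and h2 must be in [0, 1]")
  ifelse(h2 == 0, ifelse(r2 > 0, 1, 0), pmin(r2 / h2, 1))
}

#' Allelic concordance of an independent cis-eQTL on a trans gene
#'
#' Both variants are oriented so that their dosage increases the cis gene's
#' expression. The main variant's effect direction on the trans gene is
#' compared with the secondary variant's direction on the trans expression
#' residualized on the main variant's dosage; concordance means the
#' cis-expression-raising alleles push the trans gene the same way.
#'
#' @param main_dosage,secondary_dosage dosage vectors of the main and
#'   secondary (independent) cis-eQTL.
#' @param cis_expr,trans_expr expression vectors of the cis and trans gene.
#' @return TRUE if the oriented effect signs agree.
#' @export
allelic_concordance <- function(main_dosage, secondary_dosage,
                                cis_expr, trans_expr) {
  tol <- sqrt(.Machine$double.eps)
  # the main variant is concordant with itself by construction
  if (isTRUE(all.equal(main_dosage, secondary_dosage, tolerance = 1e-12)))
    return(TRUE)
  o_main <- spearman_test(main_dosage, cis_expr)$rho
  o_sec <- spearman_test(secondary_dosage, cis_expr)$rho
  if (abs(o_main) < tol || abs(o_sec) < tol)
    stop("undefined direction: cis effect is zero")
  g_main <- main_dosage * sign(o_main)
  g_sec <- secondary_dosage * sign(o_sec)
  s_main <- spearman_test(g_main, trans_expr)$rho
  resid <- stats::lm.fit(cbind(1, main_dosage), trans_expr)$residuals
  s_sec <- spearman_test(g_sec, resid)$rho
  if (abs(s_main) < tol || abs(s_sec) < tol)
    stop("undefined direction: trans effect is zero")
  sign(s_main) == sign(s_sec)
}
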