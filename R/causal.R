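# Causal classification of (variant G, cis gene C, trans gene T) triplets.
#
# Three fixed three-node Gaussian networks anchored on the genotype:
#   SCT:   G -> C -> T   (cis gene mediates the trans effect)
#   STC:   G -> T -> C   (reverse mediation)
#   INDEP: G -> C, G -> T (independent effects)
# Each network's maximum log-likelihood is the sum of its node terms: the
# root node under its ML Gaussian, each child under the ML linear regression
# on its parents (ML variance RSS/n).  Model comparison by AIC with k = 5 for
# every model, so AIC ranking equals likelihood ranking; a model is called
# only when the second-best is at most a tenth as likely.  A consensus with
# the causal inference test (CIT) gates the final call.

#' Construct a causal triplet
#'
#' @param G dosage vector of the anchoring variant.
#' @param C,T_ expression vectors of the cis and trans gene (standard
#'   normalized unless \code{standardize = TRUE} is used to do it here).
#' @param ids optional named character vector (variant, cis, trans labels).
#' @param standardize apply \code{\link{standard_normalize}} to C and T.
#' @return An object of class \code{causal_triplet}.
#' @export
causal_triplet <- function(G, C, T_, ids = NULL, standardize = FALSE) {
  if (length(G) != length(C) || length(C) != length(T_))
    stop("G, C, T must have equal length")
  if (standardize) {
    C <- standard_normalize(C)
    T_ <- standard_normalize(T_)
  }
  structure(list(G = as.numeric(G), C = as.numeric(C), T = as.numeric(T_),
                 ids = ids),
            class = "causal_triplet")
}

# ML Gaussian log-likelihood of y given a (possibly empty) parent design
.node_lnl <- function(y, parents = NULL) {
  n <- length(y)
  rss <- if (is.null(parents)) sum((y - mean(y))^2) else
    sum(stats::lm.fit(cbind(1, parents), y)$residuals^2)
  s2 <- rss / n
  if (s2 <= 0) stop("degenerate fit: zero residual variance")
  -n / 2 * (log(2 * pi * s2) + 1)
}

#' Fit the three anchored Gaussian networks and select by AIC
#'
#' @param triplet a \code{causal_triplet} (n at least 30, no constant vector).
#' @param k parameter count used in AIC (5 for all three models, following the
#'   convention that the constant shared terms are not counted; since k is
#'   equal across models it does not affect the ranking).
#' @return An object of class \code{bn_result}: list with \code{lnL} and
#'   \code{AIC} (named vectors over SCT/STC/INDEP), \code{k},
#'   \code{best_model}, \code{rel_lik_second_vs_best} and \code{bn_call}
#'   (the best model when the second best is at most a tenth as likely, else
#'   \code{"none"}).
#' @export
bn_fit <- function(triplet, k = 5) {
  G <- triplet$G; C <- triplet$C; Tv <- triplet$T
  n <- length(G)
  if (n < 30) stop("need n >= 30")
  if (max(G) == min(G) || max(C) == min(C) || max(Tv) == min(Tv))
    stop("constant vector in triplet")
  lnG <- .node_lnl(G)  # root term, identical across models
  lnL <- c(
    SCT = lnG + .node_lnl(C, cbind(G)) + .node_lnl(Tv, cbind(C)),
    STC = lnG + .node_lnl(Tv, cbind(G)) + .node_lnl(C, cbind(Tv)),
    INDEP = lnG + .node_lnl(C, cbind(G)) + .node_lnl(Tv, cbind(G)))
  aic <- 2 * k - 2 * lnL
  ord <- order(aic)
  rel <- exp((aic[ord[1]] - aic[ord[2]]) / 2)
  structure(list(lnL = lnL, AIC = aic, k = k,
                 best_model = names(aic)[ord[1]],
                 rel_lik_second_vs_best = unname(rel),
                 bn_call = if (rel <= 0.1) names(aic)[ord[1]] else "none"),
            class = "bn_result")
}

#' @export
print.bn_result <- function(x, ...) {
  cat("bn_result: best =", x$best_model,
      "(second-best relative likelihood",
      signif(x$rel_lik_second_vs_best, 3), ") -> call:", x$bn_call, "\n")
  print(data.frame(model = names(x$lnL), lnL = x$lnL, AIC = x$AIC,
                   row.names = NULL))
  invisible(x)
}

# F statistic and p-value for the extra predictors `test` given `base`
.f_test <- function(y, base, test) {
  n <- length(y)
  X0 <- if (is.null(base)) matrix(1, n, 1) else cbind(1, base)
  X1 <- cbind(X0, test)
  rss0 <- sum(stats::lm.fit(X0, y)$residuals^2)
  rss1 <- sum(stats::lm.fit(X1, y)$residuals^2)
  df1 <- ncol(X1) - ncol(X0)
  df2 <- n - ncol(X1)
  if (rss1 <= 0) return(list(F = Inf, p = .Machine$double.xmin,
                             df1 = df1, df2 = df2))
  Fst <- ((rss0 - rss1) / df1) / (rss1 / df2)
  list(F = Fst, p = stats::pf(Fst, df1, df2, lower.tail = FALSE),
       df1 = df1, df2 = df2)
}

#' Causal inference test for one mediation direction
#'
#' With mediator M and outcome O (direction \code{C_mediates}: M = cis gene,
#' O = trans gene, testing SCT; \code{T_mediates}: M = trans gene, O = cis
#' gene, testing STC), four component p-values are computed:
#' \itemize{
#'   \item p1: F-test of G in O ~ G (marginal association),
#'   \item p2: F-test of G in M ~ G + O against M ~ O,
#'   \item p3: F-test of M in O ~ M + G against O ~ G,
#'   \item p4: equivalence-type test that G is independent of O given M —
#'     the observed F of G in O ~ G + M is referred to a noncentral F whose
#'     noncentrality is estimated from \code{B} datasets in which M is
#'     permuted within rounded-dosage strata of G (preserving the G-O and G-M
#'     marginals while destroying mediation); small p4 means the conditional
#'     association is significantly weaker than a direct effect of the
#'     observed marginal strength would give.
#' }
#' The omnibus p-value is the maximum of the four.
#'
#' @param triplet a \code{causal_triplet}.
#' @param direction \code{"C_mediates"} or \code{"T_mediates"}.
#' @param B permutation replicates for p4 (at least 100).
#' @param seed integer seed for the stratified permutations.
#' @return list with \code{p1..p4}, \code{omnibus}, \code{direction}.
#' @export
cit <- function(triplet, direction = c("C_mediates", "T_mediates"),
                B = 500, seed = 1) {
  direction <- match.arg(direction)
  n <- length(triplet$G)
  if (n < 30) stop("need n >= 30")
  if (B < 100) stop("need B >= 100")
  G <- triplet$G
  if (direction == "C_mediates") { M <- triplet$C; O <- triplet$T }
  else { M <- triplet$T; O <- triplet$C }
  if (max(M) == min(M) || max(O) == min(O) || max(G) == min(G))
    stop("degenerate regression: constant vector")
  p1 <- .f_test(O, NULL, G)$p
  p2 <- .f_test(M, cbind(O), G)$p
  p3 <- .f_test(O, cbind(G), M)$p
  # p4: conditional-independence equivalence test
  obs <- .f_test(O, cbind(M), G)
  strata <- split(seq_len(n), round(G))
  set.seed(seed)
  f_ref <- vapply(seq_len(B), function(b) {
    idx <- seq_len(n)
    for (s in strata) if (length(s) > 1) idx[s] <- s[sample.int(length(s))]
    .f_test(O, cbind(M[idx]), G)$F
  }, numeric(1))
  df1 <- obs$df1; df2 <- obs$df2
  # mean of noncentral F(df1, df2, ncp) is (df1 + ncp)/df1 * df2/(df2 - 2)
  ncp <- max(0, mean(f_ref) * (df2 - 2) / df2 * df1 - df1)
  p4 <- stats::pf(obs$F, df1, df2, ncp = ncp)
  out <- list(p1 = p1, p2 = p2, p3 = p3, p4 = p4,
              omnibus = max(p1, p2, p3, p4), direction = direction)
  out
}

#' Consensus causal call for one triplet
#'
#' The CIT call uses Bonferroni-corrected significance
#' (\code{alpha / n_triplets_tested}): SCT when only the cis-mediator
#' direction is significant, STC when only the trans-mediator direction is,
#' INDEP when neither, and no call when both. The consensus is the BN call
#' when both methods agree, otherwise \code{"none"}.
#'
#' @param bn a \code{bn_result}.
#' @param cit_c CIT result for direction \code{C_mediates}.
#' @param cit_t CIT result for direction \code{T_mediates}.
#' @param n_triplets_tested Bonferroni denominator: number of triplets tested
#'   in the run.
#' @param alpha nominal CIT level before correction (default 0.05).
#' @return An object of class \code{causal_call}: list with \code{bn_call},
#'   \code{cit_call}, \code{consensus}, \code{alpha_used} and the inputs'
#'   evidence.
#' @export
causal_call <- function(bn, cit_c, cit_t, n_triplets_tested = 1,
                        alpha = 0.05) {
  a <- alpha / n_triplets_tested
  sig_c <- cit_c$omnibus < a
  sig_t <- cit_t$omnibus < a
  cit_call <- if (sig_c && sig_t) "nocall"
  else if (sig_c) "SCT"
  else if (sig_t) "STC"
  else "INDEP"
  consensus <- if (bn$bn_call != "none" && bn$bn_call == cit_call)
    bn$bn_call else "none"
  structure(list(bn_call = bn$bn_call, cit_call = cit_call,
                 consensus = consensus, alpha_used = a,
                 rel_lik = bn$rel_lik_second_vs_best,
                 omnibus_C_mediates = cit_c$omnibus,
                 omnibus_T_mediates = cit_t$omnibus),
            class = "causal_call")
}

#' @export
print.causal_call <- function(x, ...) {
  cat("causal_call: BN =", x$bn_call, "| CIT =", x$cit_call,
      "| consensus =", x$consensus, "\n")
  cat("  CIT omnibus p (C mediates):", signif(x$omnibus_C_mediates, 3),
      " (T mediates):", signif(x$omnibus_T_mediates, 3),
      " at alpha =", signif(x$alpha_used, 3), "\n")
  invisible(x)
}

#' Fraction of a variant's trans association explained by the cis gene
#'
#' Compares the variant's effect on the trans gene before and after
#' conditioning on the cis gene: one minus the squared ratio of the variant's
#' slope in \code{T ~ G + C} to its marginal slope in \code{T ~ G}, clamped
#' to \[0, 1\]. Full mediation drives the conditional slope to zero (value 1);
#' an independent trans effect leaves the slope unchanged (value near 0).
#' Simple residualization of T on C is not used because the cis gene is a
#' proxy for the variant, so it would absorb part of a purely direct effect.
#'
#' @param triplet a \code{causal_triplet} whose variant has a nonzero trans
#'   association.
#' @return numeric in \[0, 1\].
#' @export
trans_assoc_variance_explained <- function(triplet) {
  G <- triplet$G; C <- triplet$C; Tv <- triplet$T
  r2_marg <- variance_explained(Tv, G)
  if (r2_marg <= 0) stop("no trans association")
  b_marg <- stats::lm.fit(cbind(1, G), Tv)$coefficients[2]
  if (abs(b_marg) < .Machine$double.eps) stop("no trans association")
  b_cond <- stats::lm.fit(cbind(1, G, C), Tv)$coefficients[2]
  min(max(1 - (b_cond / b_marg)^2, 0), 1)
}

#' Classify a batch of triplets by BN/CIT consensus
#'
#' @param triplets list of \code{causal_triplet} objects.
#' @param B CIT permutation replicates (default 500).
#' @param alpha nominal CIT level (default 0.05); Bonferroni-corrected by the
#'   number of triplets.
#' @param seed integer seed.
#' @return data.frame with one row per triplet: ids, lnL and AIC per model,
#'   relative likelihood, bn_call, CIT omnibus p per direction, cit_call,
#'   consensus and the trans-association variance explained by the cis gene.
#' @export
classify_triplets <- function(triplets, B = 500, alpha = 0.05, seed = 1) {
  nt <- length(triplets)
  rows <- lapply(seq_len(nt), function(i) {
    tr <- triplets[[i]]
    bn <- bn_fit(tr)
    cc <- cit(tr, "C_mediates", B = B, seed = seed + i)
    ct <- cit(tr, "T_mediates", B = B, seed = seed + i + nt)
    call <- causal_call(bn, cc, ct, n_triplets_tested = nt, alpha = alpha)
    ve <- tryCatch(trans_assoc_variance_explained(tr), error = function(e) NA)
    data.frame(variant = if (!is.null(tr$ids)) tr$ids[["variant"]] else
                 as.character(i),
               cis_gene = if (!is.null(tr$ids)) tr$ids[["cis"]] else NA,
               trans_gene = if (!is.null(tr$ids)) tr$ids[["trans"]] else NA,
               lnL_SCT = bn$lnL[["SCT"]], lnL_STC = bn$lnL[["STC"]],
               lnL_INDEP = bn$lnL[["INDEP"]],
               rel_lik = bn$rel_lik_second_vs_best, bn_call = bn$bn_call,
               p_omnibus_C = cc$omnibus, p_omnibus_T = ct$omnibus,
               cit_call = call$cit_call, consensus = call$consensus,
               trans_var_explained = ve, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
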