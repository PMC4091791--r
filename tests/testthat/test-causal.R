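# helper: one planted triplet of a given type at the standard study scale
plant_triplet <- function(type, n = 800, ve1 = 0.2, ve2 = 0.2, seed = 1) {
  set.seed(seed)
  g <- rbinom(n, 2, 0.3)
  gs <- scale(g)[, 1]
  if (type == "SCT") {
    C <- sqrt(ve1) * gs + rnorm(n, 0, sqrt(1 - ve1))
    Tv <- sqrt(ve2) * scale(C)[, 1] + rnorm(n, 0, sqrt(1 - ve2))
  } else if (type == "STC") {
    Tv <- sqrt(ve1) * gs + rnorm(n, 0, sqrt(1 - ve1))
    C <- sqrt(ve2) * scale(Tv)[, 1] + rnorm(n, 0, sqrt(1 - ve2))
  } else {
    C <- sqrt(ve1) * gs + rnorm(n, 0, sqrt(1 - ve1))
    Tv <- sqrt(ve2) * gs + rnorm(n, 0, sqrt(1 - ve2))
  }
  causal_triplet(g, C, Tv, standardize = TRUE)
}

test_that("BN likelihoods match a direct joint-density factorization", {
  tr <- plant_triplet("SCT", n = 200, seed = 131)
  bn <- bn_fit(tr)
  direct <- function(y, x = NULL) {
    n <- length(y)
    res <- if (is.null(x)) y - mean(y) else lm(y ~ x)$residuals
    s2 <- sum(res^2) / n
    sum(dnorm(res, 0, sqrt(s2), log = TRUE))
  }
  lnl_sct <- direct(tr$G) + direct(tr$C, tr$G) + direct(tr$T, tr$C)
  lnl_stc <- direct(tr$G) + direct(tr$T, tr$G) + direct(tr$C, tr$T)
  lnl_ind <- direct(tr$G) + direct(tr$C, tr$G) + direct(tr$T, tr$G)
  expect_equal(bn$lnL[["SCT"]], lnl_sct, tolerance = 1e-8)
  expect_equal(bn$lnL[["STC"]], lnl_stc, tolerance = 1e-8)
  expect_equal(bn$lnL[["INDEP"]], lnl_ind, tolerance = 1e-8)
  # AIC bookkeeping: k constant, so AIC ranking equals likelihood ranking
  expect_equal(bn$AIC, 2 * 5 - 2 * bn$lnL)
  expect_equal(names(which.min(bn$AIC)), names(which.max(bn$lnL)))
})

test_that("copying C into T makes SCT and STC indistinguishable", {
  set.seed(132)
  n <- 100
  g <- rbinom(n, 2, 0.4)
  C <- 0.4 * scale(g)[, 1] + rnorm(n)
  tr <- causal_triplet(g, C, C)
  bn <- bn_fit(tr)
  expect_equal(bn$AIC[["SCT"]], bn$AIC[["STC"]], tolerance = 1e-8)
  expect_equal(bn$rel_lik_second_vs_best, 1, tolerance = 1e-6)
  expect_equal(bn$bn_call, "none")
})

test_that("BN model ranking is invariant to affine rescaling of C and T", {
  tr <- plant_triplet("STC", n = 300, seed = 133)
  tr2 <- causal_triplet(tr$G, 3 * tr$C + 7, -2 * tr$T + 1)
  b1 <- bn_fit(tr); b2 <- bn_fit(tr2)
  expect_equal(order(b1$AIC), order(b2$AIC))
  expect_equal(b1$rel_lik_second_vs_best, b2$rel_lik_second_vs_best,
               tolerance = 1e-8)
})

test_that("swapping C and T exchanges the SCT and STC results exactly", {
  tr <- plant_triplet("SCT", n = 250, seed = 134)
  sw <- causal_triplet(tr$G, tr$T, tr$C)
  b1 <- bn_fit(tr); b2 <- bn_fit(sw)
  expect_equal(b1$lnL[["SCT"]], b2$lnL[["STC"]], tolerance = 1e-10)
  expect_equal(b1$lnL[["STC"]], b2$lnL[["SCT"]], tolerance = 1e-10)
  expect_equal(b1$lnL[["INDEP"]], b2$lnL[["INDEP"]], tolerance = 1e-10)
})

test_that("BN recovers strong planted SCT structures", {
  calls <- vapply(1:20, function(s)
    bn_fit(plant_triplet("SCT", seed = 140 + s))$bn_call, character(1))
  expect_gte(mean(calls == "SCT"), 0.9)
})

test_that("CIT recovers mediation direction and respects the null", {
  hits_dir <- 0; hits_indep <- 0
  for (s in 1:10) {
    tr <- plant_triplet("SCT", seed = 150 + s)
    cc <- cit(tr, "C_mediates", B = 100, seed = s)
    ct <- cit(tr, "T_mediates", B = 100, seed = s)
    if (cc$omnibus < 0.05 && ct$omnibus >= 0.05) hits_dir <- hits_dir + 1
    ti <- plant_triplet("INDEP", seed = 160 + s)
    ci <- cit(ti, "C_mediates", B = 100, seed = s)
    cti <- cit(ti, "T_mediates", B = 100, seed = s)
    if (ci$omnibus >= 0.05 && cti$omnibus >= 0.05) hits_indep <- hits_indep + 1
  }
  expect_gte(hits_dir, 8)
  expect_gte(hits_indep, 8)
})

test_that("CIT p1 is uniform when the variant has no marginal effect", {
  set.seed(171)
  p1s <- replicate(400, {
    n <- 60
    g <- rbinom(n, 2, 0.4)
    tr <- causal_triplet(g, rnorm(n), rnorm(n))
    transmed:::.f_test(tr$T, NULL, tr$G)$p
  })
  ks <- suppressWarnings(ks.test(p1s, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("consensus calling follows the agreement rule", {
  bn_sct <- list(bn_call = "SCT", rel_lik_second_vs_best = 0.01)
  cit_sig <- list(omnibus = 1e-6)
  cit_ns <- list(omnibus = 0.5)
  cal <- causal_call(bn_sct, cit_sig, cit_ns, n_triplets_tested = 10)
  expect_equal(cal$cit_call, "SCT")
  expect_equal(cal$consensus, "SCT")
  # disagreement gives no consensus
  cal2 <- causal_call(bn_sct, cit_ns, cit_ns, n_triplets_tested = 10)
  expect_equal(cal2$cit_call, "INDEP")
  expect_equal(cal2$consensus, "none")
  # both directions significant: CIT makes no call
  cal3 <- causal_call(bn_sct, cit_sig, cit_sig, n_triplets_tested = 10)
  expect_equal(cal3$cit_call, "nocall")
  expect_equal(cal3$consensus, "none")
  # Bonferroni denominator applied
  border <- list(omnibus = 0.04)
  cal4 <- causal_call(bn_sct, border, cit_ns, n_triplets_tested = 10)
  expect_equal(cal4$cit_call, "INDEP")  # 0.04 > 0.05/10
})

test_that("trans-association variance explained spans mediation regimes", {
  # perfect mediation: T a noiseless function of C
  set.seed(181)
  n <- 500
  g <- rbinom(n, 2, 0.3)
  C <- 0.5 * scale(g)[, 1] + rnorm(n, 0, 0.8)
  tr_full <- causal_triplet(g, C, 2 * C)
  expect_equal(trans_assoc_variance_explained(tr_full), 1)
  # independence: conditioning on C barely moves the trans association
  ti <- plant_triplet("INDEP", n = 2000, seed = 182)
  expect_lt(trans_assoc_variance_explained(ti), 0.1)
  # monotone in mediation strength
  vals <- vapply(c(0.1, 0.3, 0.6), function(m) {
    set.seed(183)
    gg <- rbinom(2000, 2, 0.3)
    CC <- sqrt(0.3) * scale(gg)[, 1] + rnorm(2000, 0, sqrt(0.7))
    # trans gene: mediated part of strength m plus a direct genetic part
    TT <- sqrt(m) * scale(CC)[, 1] + sqrt(0.1) * scale(gg)[, 1] +
      rnorm(2000, 0, sqrt(max(1 - m - 0.1, 0.05)))
    trans_assoc_variance_explained(causal_triplet(gg, CC, TT))
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
})
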