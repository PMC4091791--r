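test_that("spearman test handles monotone, anti-monotone and tied inputs", {
  x <- 1:10
  st <- spearman_test(x, x^3)
  expect_equal(st$rho, 1)
  expect_equal(st$p, .Machine$double.xmin)
  # tied dosages with pairwise-reversed outcome: perfect anti-monotone ranks
  x2 <- c(0, 0, 1, 1, 2, 2)
  y2 <- c(3, 3, 2, 2, 1, 1)
  expect_equal(spearman_test(x2, y2)$rho, -1, tolerance = 1e-12)
  expect_error(spearman_test(rep(1, 5), 1:5), "constant")
  expect_error(spearman_test(1:4, 1:5), "mismatch")
  # invariance to strictly monotone transforms of either argument
  set.seed(21)
  a <- rnorm(30); b <- rnorm(30)
  expect_equal(spearman_test(a, b)$rho,
               spearman_test(exp(a), qnorm(pnorm(b)))$rho)
})

test_that("t-approximation p agrees with the exhaustive permutation null at n=7", {
  # all 7! = 5040 orderings enumerated once; compare where p > 0.01
  perms <- as.matrix(expand.grid(rep(list(1:7), 7)))
  perms <- perms[apply(perms, 1, function(r) length(unique(r)) == 7), ,
                 drop = FALSE]
  set.seed(22)
  for (rep in 1:3) {
    x <- rnorm(7); y <- rnorm(7)
    st <- spearman_test(x, y)
    rx <- rank(x)
    ry <- rank(y)
    null_rho <- apply(perms, 1, function(pp) cor(rx, ry[pp]))
    p_exact <- mean(abs(null_rho) >= abs(st$rho) - 1e-12)
    if (p_exact > 0.01)
      expect_lt(abs(st$p - p_exact) / p_exact, 0.10)
  }
})

test_that("t-approximation error at n=7 is bounded over the full discrete support", {
  # exhaustive characterization: over every achievable rho at n=7, the
  # t-approximation tracks the exact permutation p to within 0.03 absolute
  # everywhere, and to within 10% relative in the moderate range; in the
  # deep tail (p_exact near 0.01) it is conservative-to-liberal by a larger
  # relative factor, which is inherent to the approximation
  perms <- as.matrix(expand.grid(rep(list(1:7), 7)))
  perms <- perms[apply(perms, 1, function(r) length(unique(r)) == 7), ,
                 drop = FALSE]
  null_rho <- apply(perms, 1, function(pp) cor(1:7, pp))
  for (v in sort(unique(round(abs(null_rho), 12)))) {
    if (v >= 1) next
    p_exact <- mean(abs(null_rho) >= v - 1e-12)
    p_approx <- 2 * pt(-v * sqrt(5 / (1 - v^2)), df = 5)
    expect_lt(abs(p_approx - p_exact), 0.03)
    if (p_exact > 0.25)
      expect_lt(abs(p_approx - p_exact) / p_exact, 0.10)
  }
})

test_that("-log10 p is computed in log space without underflow", {
  expect_equal(neglog10_p_from_rho(0, 100), 0)
  # |t| ~ 60 regime: plain p would underflow, log-space must not
  big <- neglog10_p_from_rho(0.9, 900)
  expect_true(is.finite(big) && big > 300)
  expect_error(neglog10_p_from_rho(1, 100), "rho")
  # symmetric in sign
  expect_equal(neglog10_p_from_rho(-0.341, 869),
               neglog10_p_from_rho(0.341, 869))
})

test_that("cis scan respects window boundaries and probe SNP filter", {
  n <- 12
  set.seed(23)
  dos <- matrix(rbinom(3 * n, 2, 0.4), 3, n)
  g <- genotype_table(dos, c("in_edge", "out_edge", "other_chr"),
                      c("chr1", "chr1", "chr2"),
                      c(2500000, 2500001, 1500000),
                      rep("SNP", 3), paste0("s", 1:n))
  e <- expression_matrix(matrix(rnorm(2 * n), 2, n),
                         probe_ids = c("pA", "pB"),
                         sample_ids = paste0("s", 1:n))
  a <- probe_annotation(c("pA", "pB"), c("GA", "GB"), c("chr1", "chr1"),
                        c(1500000, 1500000),
                        contains_common_snp = c(FALSE, TRUE))
  sc <- cis_scan(g, e, a)
  # variant at exactly TSS + 1e6 tested; one bp further not; other chr not
  expect_identical(sort(unique(sc$records$variant_id)), "in_edge")
  # flagged probe absent
  expect_false("pB" %in% sc$records$probe_id)
  expect_equal(unname(sc$tested_counts["pA"]), 1L)
})

test_that("trans scan excludes the 5 Mb zone and multi-mapped probes", {
  n <- 12
  set.seed(24)
  dos <- matrix(rbinom(3 * n, 2, 0.4), 3, n)
  g <- genotype_table(dos, c("at_edge", "past_edge", "far_chr"),
                      c("chr1", "chr1", "chr2"),
                      c(6500000, 6500001, 1000000),
                      rep("SNP", 3), paste0("s", 1:n))
  e <- expression_matrix(matrix(rnorm(2 * n), 2, n),
                         probe_ids = c("pA", "pB"),
                         sample_ids = paste0("s", 1:n))
  a <- probe_annotation(c("pA", "pB"), c("GA", "GB"), c("chr1", "chr1"),
                        c(1500000, 1500000),
                        multi_mapped = c(FALSE, TRUE))
  sc <- trans_scan(g, e, a)
  expect_setequal(unique(sc$records$variant_id), c("past_edge", "far_chr"))
  expect_false("pB" %in% sc$records$probe_id)
})

test_that("cis and trans scans partition variant-probe pairs outside the 1-5 Mb gap", {
  co <- simulate_cohort(make_scenario("cis_only"), seed = 77)
  cs <- cis_scan(co$geno, co$expr, co$annot)
  ts <- trans_scan(co$geno, co$expr, co$annot)
  key <- function(s) paste(s$records$variant_id, s$records$probe_id)
  expect_length(intersect(key(cs), key(ts)), 0)
  # pairs in the 1-5 Mb gap appear in neither scan
  v <- co$geno$variants
  a1 <- co$annot[1, ]
  gap <- v$variant_id[v$chromosome == a1$chromosome &
                        abs(v$position - a1$tss) > 1e6 &
                        abs(v$position - a1$tss) <= 5e6]
  if (length(gap) > 0) {
    gap_keys <- paste(gap, a1$probe_id)
    expect_length(intersect(gap_keys, c(key(cs), key(ts))), 0)
  }
})

test_that("scan output does not depend on variant or probe input order", {
  co <- simulate_cohort(make_scenario("cis_only"), seed = 78)
  g <- co$geno
  set.seed(1)
  perm <- sample(nrow(g$variants))
  g2 <- g
  g2$variants <- g$variants[perm, ]
  g2$dosage <- g$dosage[perm, ]
  s1 <- cis_scan(g, co$expr, co$annot)
  s2 <- cis_scan(g2, co$expr, co$annot)
  o1 <- s1$records[order(s1$records$variant_id, s1$records$probe_id), ]
  o2 <- s2$records[order(s2$records$variant_id, s2$records$probe_id), ]
  rownames(o1) <- rownames(o2) <- NULL
  expect_equal(o1, o2)
})

test_that("null trans scan p-values are calibrated", {
  co <- simulate_cohort(make_scenario("null"), seed = 79)
  sub <- co$geno
  keep <- seq_len(200)
  sub$variants <- sub$variants[keep, ]
  sub$dosage <- sub$dosage[keep, ]
  sc <- trans_scan(sub, co$expr, co$annot)
  n_tests <- nrow(sc$records)
  frac <- mean(sc$records$p < 0.001)
  # binomial 99% envelope around 0.001
  expect_lt(abs(frac - 0.001), 3 * sqrt(0.001 * 0.999 / n_tests) + 1e-6)
})

test_that("CNV trans filter removes same-chromosome, LD and sex-imbalanced records", {
  co <- simulate_cohort(make_scenario("sex_cnv_confound"), seed = 80)
  sc <- trans_scan(co$geno, co$expr, co$annot)
  filt <- cnv_trans_filter(sc, co$geno, co$annot, sex = co$sex)
  imb <- co$config$sex_imbalanced_cnv_ids
  # every record of a planted sex-imbalanced CNV is removed
  expect_false(any(filt$scan$records$variant_id %in% imb))
  expect_true(all(filt$removed$reason %in%
                    c("same_chrom", "ld_chrom", "sex_imbalance")))
  expect_true(any(filt$removed$reason == "sex_imbalance"))
  # balanced CNVs and SNPs survive (geometry rules only)
  removed_sex <- unique(filt$removed$variant_id[
    filt$removed$reason == "sex_imbalance"])
  expect_true(all(removed_sex %in% imb))
  # significant confounded associations existed before filtering
  pre <- sc$records[sc$records$variant_id %in% imb, ]
  expect_true(any(pre$p < 1e-4))
  expect_error(cnv_trans_filter(sc, co$geno, co$annot, sex = NULL),
               "sex")
  # relaxing ld_r2 to 1 and disabling the sex filter leaves only
  # same-chromosome removals
  filt2 <- cnv_trans_filter(sc, co$geno, co$annot, ld_r2 = 1,
                            sex_filter = FALSE)
  expect_true(all(filt2$removed$reason == "same_chrom") ||
                nrow(filt2$removed) == 0)
})
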