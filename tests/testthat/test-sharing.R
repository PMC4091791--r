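test_that("pi1 estimates null, saturated and mixed p-value collections", {
  set.seed(101)
  expect_lt(abs(storey_pi1(runif(10000))$pi1), 0.03)
  expect_equal(storey_pi1(rep(1e-10, 100))$pi1, 1)
  p <- c(runif(7000), rbeta(3000, 0.1, 1))
  est <- storey_pi1(p)
  expect_gt(est$pi1, 0.25)
  expect_lt(est$pi1, 0.35)
  expect_error(storey_pi1(runif(20)), "at least 50")
  expect_error(storey_pi1(c(runif(100), 2)), "outside")
  # convergence on large uniform samples: the boundary estimate at one
  # draw has sd ~ 0.01, so average a few draws
  expect_lt(mean(replicate(5, abs(storey_pi1(runif(1e5))$pi1))), 0.01)
})

test_that("replication against the discovery data itself is perfect", {
  co <- simulate_cohort(make_scenario("cis_only"), seed = 102)
  sc <- cis_scan(co$geno, co$expr, co$annot)
  best <- sc$best_per_probe[order(sc$best_per_probe$p)[1:20], ]
  rep <- replication_test(best, co$geno, co$expr)
  expect_equal(rep$n_tested, 20)
  expect_equal(rep$n_replicated, 20)
  expect_equal(rep$per_pair$rep_rho, best$rho)
  expect_equal(rep$frac_opposite_sign, 0)
})

test_that("planted effects replicate across independent cohorts, nulls at alpha", {
  cfg <- make_scenario("cis_only")
  disc <- simulate_cohort(cfg, seed = 103)
  sc <- cis_scan(disc$geno, disc$expr, disc$annot)
  truth_probes <- paste0("p_", disc$truth$genes$gene_id)
  best <- sc$best_per_probe[sc$best_per_probe$probe_id %in% truth_probes, ]
  # an independent cohort drawn from the same truth
  rep_co <- simulate_cohort(cfg, seed = 104)
  rep1 <- replication_test(best, rep_co$geno, rep_co$expr)
  expect_gte(rep1$n_replicated / rep1$n_tested, 0.8)
  # permuting the replication expression kills replication down to ~alpha
  perm_expr <- rep_co$expr
  set.seed(105)
  perm_expr$values <- perm_expr$values[, sample(ncol(perm_expr$values))]
  rep0 <- replication_test(best, rep_co$geno, perm_expr)
  expect_lte(rep0$n_replicated / rep0$n_tested, 0.10)
  # pairs absent from the replication data are counted untestable
  best2 <- best
  best2$variant_id[1] <- "no_such_variant"
  rep2 <- replication_test(best2, rep_co$geno, rep_co$expr)
  expect_equal(rep2$n_untestable, 1)
  expect_equal(rep2$n_tested, nrow(best2) - 1)
})

test_that("sharing curve rises with sample size for real effects, stays flat for nulls", {
  cfg <- make_scenario("cis_only")
  disc <- simulate_cohort(cfg, seed = 106)
  sc <- cis_scan(disc$geno, disc$expr, disc$annot)
  truth_probes <- paste0("p_", disc$truth$genes$gene_id)
  best <- sc$best_per_probe[sc$best_per_probe$probe_id %in% truth_probes, ]
  target <- simulate_cohort(cfg, seed = 107)
  # small subsamples have limited power for 10% effects; 800 saturates
  curve <- suppressWarnings(
    sharing_curve(best, target$geno, target$expr,
                  sample_sizes = c(60, 150, 800), n_draws = 5, seed = 108))
  expect_equal(curve$n, c(60, 150, 800))
  # non-decreasing up to one small inversion, with genuine growth overall
  expect_gte(sum(diff(curve$pi1_mean) > -0.02), 2)
  expect_gte(curve$pi1_mean[3], curve$pi1_mean[1])
  expect_gt(curve$pi1_mean[3], 0.9)
  # full cohort, single draw equals the direct replication pi1
  full <- sharing_curve(best, target$geno, target$expr,
                        sample_sizes = 800, n_draws = 1, seed = 109)
  direct <- replication_test(best, target$geno, target$expr)
  expect_equal(full$pi1_mean,
               storey_pi1(direct$per_pair$rep_p)$pi1, tolerance = 1e-9)
})

test_that("sharing curve stays flat near zero for null pairs", {
  # the null scenario provides 500 probes, keeping the pi1 estimate stable
  cfg <- make_scenario("null")
  disc <- simulate_cohort(cfg, seed = 115)
  sc <- cis_scan(disc$geno, disc$expr, disc$annot)
  # all tested pairs (~2400) keep the boundary pi0 estimate stable; with
  # only a few hundred p-values its sampling sd alone approaches 0.1
  pairs <- sc$records
  target <- simulate_cohort(cfg, seed = 116)
  null_curve <- sharing_curve(pairs, target$geno, target$expr,
                              sample_sizes = c(100, 400), n_draws = 3,
                              seed = 117)
  expect_true(all(null_curve$pi1_mean < 0.15))
  expect_lt(abs(null_curve$pi1_mean[2] - null_curve$pi1_mean[1]), 0.15)
})

test_that("pi1 trans profile separates master regulators from null variants", {
  # a variant feeding 30% of probes weakly
  n <- 800
  n_genes <- 120
  genes <- lapply(seq_len(n_genes), function(j)
    list(gene_id = paste0("G", j), chromosome = "chr2",
         tss = j * 100000L))
  cfg <- simulation_config(n_samples = n, n_snps = 4, n_chrom = 2,
                           maf_range = c(0.3, 0.5), genes = genes,
                           seed = 111)
  co <- simulate_cohort(cfg)
  gs <- scale(co$geno$dosage["snp1", ])[, 1]
  set.seed(112)
  fed <- seq_len(round(0.3 * n_genes))
  for (j in fed)
    co$expr$values[j, ] <- sqrt(0.05) * gs +
      sqrt(0.95) * rnorm(n)
  prof <- pi1_trans_profile("snp1", co$geno, co$expr, co$annot)
  expect_gt(prof$pi1, 0.2)
  expect_lt(prof$pi1, 0.4)
  null_prof <- pi1_trans_profile("snp2", co$geno, co$expr, co$annot)
  expect_lt(null_prof$pi1, 0.1)
  # invariant to probe order
  perm <- sample(n_genes)
  co2 <- co
  co2$expr <- expression_matrix(co$expr$values[perm, ],
                                probe_ids = co$expr$probe_ids[perm],
                                sample_ids = co$expr$sample_ids)
  prof2 <- pi1_trans_profile("snp1", co2$geno, co2$expr, co$annot)
  expect_equal(prof2$pi1, prof$pi1)
})

test_that("the pipeline does not manufacture a cis-strength vs trans-load correlation", {
  # mediator effect sizes drawn independently of trans fan-out: the
  # correlation between cis strength and pi1 trans load should be ~0
  n <- 400
  set.seed(113)
  n_med <- 12; n_targets <- 60
  genes <- c(
    lapply(seq_len(n_med), function(j)
      list(gene_id = paste0("M", j), chromosome = "chr1",
           tss = j * 400000L,
           cis_variants = paste0("snp", j), cis_ve = runif(1, 0.05, 0.3),
           h2 = 0.4)),
    lapply(seq_len(n_targets), function(j)
      list(gene_id = paste0("T", j), chromosome = "chr2",
           tss = j * 100000L)))
  cfg <- simulation_config(n_samples = n, n_snps = n_med, n_chrom = 2,
                           spacing = 4e5, maf_range = c(0.2, 0.5),
                           genes = genes, seed = 114)
  co <- simulate_cohort(cfg)
  # each mediator feeds a fixed number of targets, unrelated to its cis ve
  fan <- split(seq_len(n_targets), rep(seq_len(n_med), length.out = n_targets))
  for (j in seq_len(n_med)) {
    m_expr <- scale(co$expr$values[paste0("p_M", j), ])[, 1]
    for (t in fan[[j]]) {
      pid <- paste0("p_T", t)
      co$expr$values[pid, ] <- sqrt(0.1) * m_expr + sqrt(0.9) * rnorm(n)
    }
  }
  cis_strength <- vapply(seq_len(n_med), function(j)
    abs(spearman_test(co$geno$dosage[paste0("snp", j), ],
                      co$expr$values[paste0("p_M", j), ])$rho), numeric(1))
  # trans load per variant over the target probes only
  sub_ids <- paste0("p_T", seq_len(n_targets))
  load <- vapply(seq_len(n_med), function(j) {
    pv <- vapply(sub_ids, function(pid)
      spearman_test(co$geno$dosage[paste0("snp", j), ],
                    co$expr$values[pid, ])$p, numeric(1))
    storey_pi1(pv)$pi1
  }, numeric(1))
  ct <- suppressWarnings(cor.test(cis_strength, load, method = "spearman"))
  expect_gt(ct$p.value, 0.01)
})
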