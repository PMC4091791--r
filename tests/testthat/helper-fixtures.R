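# Small in-code fixtures shared across test files.

# a tiny deterministic genotype table: SNPs on two chromosomes
toy_genotypes <- function(n = 8) {
  dos <- rbind(
    snpA = c(0, 1, 1, 2, 0, 1, 2, 1),
    snpB = c(2, 1, 0, 0, 1, 2, 1, 1),
    snpC = c(0, 0, 1, 1, 2, 2, 0, 1),
    cnvA = c(2, 2, 3, 2, 4, 3, 2, 2)
  )[, seq_len(n), drop = FALSE]
  genotype_table(dos,
                 variant_id = rownames(dos),
                 chromosome = c("chr1", "chr1", "chr2", "chr2"),
                 position = c(1e6, 2e6, 1e6, 3e6),
                 variant_type = c("SNP", "SNP", "SNP", "CNV"),
                 sample_ids = paste0("s", seq_len(n)))
}

toy_expression <- function(n = 8, probes = c("p1", "p2")) {
  set.seed(99)
  vals <- matrix(rnorm(length(probes) * n), length(probes), n)
  expression_matrix(vals, probe_ids = probes,
                    sample_ids = paste0("s", seq_len(n)))
}

toy_annotation <- function(probes = c("p1", "p2")) {
  probe_annotation(probe_id = probes,
                   gene_id = sub("^p", "G", probes),
                   chromosome = rep(c("chr1", "chr2"),
                                    length.out = length(probes)),
                   tss = rep(1500000L, length(probes)))
}

# independent reference implementation of quantile normalization
# (average reference distribution, ties get the mean of spanned quantiles)
ref_quantile_normalize <- function(m) {
  ref <- rowMeans(apply(m, 2, sort))
  apply(m, 2, function(col) {
    r <- rank(col, ties.method = "average")
    stats::approx(seq_len(length(ref)), ref, xout = r)$y
  })
}
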