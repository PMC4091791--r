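# Synthetic genotype-expression cohorts with planted ground truth.
#
# Genotypes: SNP dosages are binomial(2, f) allele counts with per-variant
# frequencies drawn from maf_range; variants inside an LD block copy a shared
# anchor haplotype with probability c, else draw independently at the block
# frequency, giving pairwise dosage correlation c^2 between block members
# (c = target_r2^(1/4) hits the target pairwise r^2 in expectation).  CNVs
# are integer copy numbers 2 + binomial(2, f); sex-imbalanced CNVs use
# different carrier frequencies for males and females.
#
# Expression: a cis gene is sum(sqrt(ve_i) * standardized dosage_i) plus a
# polygenic term of variance h2 - sum(ve) plus noise of variance 1 - h2, so
# variance-explained and heritability targets are hit exactly in expectation.
# Mediation triplets overwrite the involved genes: SCT builds the trans gene
# from the (standardized) cis gene, STC the reverse, INDEP regresses both on
# the variant with independent noise.

#' Construct and validate a simulation configuration
#'
#' @param n_samples,n_snps,n_cnvs cohort dimensions.
#' @param maf_range allele-frequency range for simulated variants, a subset
#'   of (0.01, 0.5\].
#' @param n_chrom number of synthetic chromosomes variants are laid out on.
#' @param spacing base-pair distance between consecutive variants.
#' @param ld_block_size consecutive SNPs per LD block (1 = no LD).
#' @param ld_r2 target pairwise dosage r-squared within a block.
#' @param genes list of per-gene architectures; each element a list with
#'   \code{gene_id}, \code{chromosome}, \code{tss} and optionally
#'   \code{cis_variants} (character), \code{cis_ve} (variance-explained
#'   targets), \code{h2}, \code{sex_effect} (additive mean shift in males),
#'   \code{contains_common_snp}, \code{multi_mapped}.
#' @param triplets data.frame of planted mediation structures with columns
#'   \code{variant_id}, \code{cis_gene}, \code{trans_gene}, \code{type}
#'   (SCT/STC/INDEP), \code{ve1} (variant on first gene in the chain),
#'   \code{ve2} (second edge).
#' @param sex_imbalanced_cnv_ids CNV ids given sex-dependent copy
#'   distributions.
#' @param seed integer seed fixing all randomness.
#' @return list of class \code{simulation_config}.
#' @export
simulation_config <- function(n_samples, n_snps, n_cnvs = 0,
                              maf_range = c(0.05, 0.5), n_chrom = 2,
                              spacing = 5e5, ld_block_size = 1, ld_r2 = NULL,
                              genes = list(), triplets = NULL,
                              sex_imbalanced_cnv_ids = character(0),
                              seed = 1) {
  if (maf_range[1] <= 0.01 || maf_range[2] > 0.5)
    stop("maf_range must be within (0.01, 0.5]")
  if (!is.null(ld_r2) && (ld_r2 < 0 || ld_r2 > 1))
    stop("unreachable target r2: must be in [0, 1]")
  gene_ids <- vapply(genes, `[[`, character(1), "gene_id")
  if (anyDuplicated(gene_ids)) stop("duplicate gene_id in architecture")
  for (g in genes) {
    ve <- g$cis_ve %||% numeric(0)
    h2 <- g$h2 %||% sum(ve)
    if (any(ve < 0 | ve >= 1)) stop("variance-explained targets must be in [0, 1)")
    if (sum(ve) >= 1) stop("inconsistent variance budget for ", g$gene_id,
                           ": sum of targets >= 1")
    if (h2 < sum(ve) - 1e-12 || h2 > 1)
      stop("h2 must satisfy sum(cis_ve) <= h2 <= 1 for ", g$gene_id)
  }
  if (!is.null(triplets)) {
    stopifnot(all(c("variant_id", "cis_gene", "trans_gene", "type",
                    "ve1", "ve2") %in% names(triplets)))
    if (!all(triplets$type %in% c("SCT", "STC", "INDEP")))
      stop("triplet type must be SCT, STC or INDEP")
    miss <- setdiff(c(triplets$cis_gene, triplets$trans_gene), gene_ids)
    if (length(miss) > 0)
      stop("triplet references unknown genes: ", paste(miss, collapse = ", "))
    if (any(triplets$ve1 <= 0 | triplets$ve1 >= 1 |
              triplets$ve2 <= 0 | triplets$ve2 >= 1))
      stop("triplet variance targets must be in (0, 1)")
  }
  structure(list(n_samples = n_samples, n_snps = n_snps, n_cnvs = n_cnvs,
                 maf_range = maf_range, n_chrom = n_chrom, spacing = spacing,
                 ld_block_size = ld_block_size, ld_r2 = ld_r2,
                 genes = genes, triplets = triplets,
                 sex_imbalanced_cnv_ids = sex_imbalanced_cnv_ids,
                 seed = seed),
            class = "simulation_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic layout: variants in order snp1..snpN, cnv1..cnvM laid out
# sequentially across chromosomes
variant_layout <- function(config) {
  ids <- c(if (config$n_snps > 0) paste0("snp", seq_len(config$n_snps)),
           if (config$n_cnvs > 0) paste0("cnv", seq_len(config$n_cnvs)))
  n <- length(ids)
  per_chrom <- ceiling(n / config$n_chrom)
  i <- seq_len(n) - 1L
  data.frame(variant_id = ids,
             chromosome = paste0("chr", i %/% per_chrom + 1L),
             position = as.integer((i %% per_chrom + 1L) * config$spacing),
             variant_type = rep(c("SNP", "CNV"),
                                c(config$n_snps, config$n_cnvs)),
             stringsAsFactors = FALSE)
}

#' Simulate a genotype table (and sample sexes)
#'
#' @param config a \code{simulation_config}.
#' @param seed overrides \code{config$seed}.
#' @return list with \code{geno} (a \code{genotype_table}) and \code{sex}
#'   (integer vector, 0 = female, 1 = male).
#' @export
simulate_genotypes <- function(config, seed = config$seed) {
  set.seed(seed)
  n <- config$n_samples
  layout <- variant_layout(config)
  sex <- stats::rbinom(n, 1, 0.5)
  dos <- matrix(0, nrow(layout), n)
  snp_rows <- which(layout$variant_type == "SNP")
  if (length(snp_rows) > 0) {
    bs <- max(1L, as.integer(config$ld_block_size))
    blocks <- split(snp_rows, (seq_along(snp_rows) - 1L) %/% bs)
    cc <- if (!is.null(config$ld_r2)) config$ld_r2^(1 / 4) else 0
    for (blk in blocks) {
      f <- stats::runif(1, config$maf_range[1], config$maf_range[2])
      if (length(blk) > 1 && cc > 0) {
        a1 <- stats::rbinom(n, 1, f); a2 <- stats::rbinom(n, 1, f)
        for (v in blk) {
          m1 <- stats::rbinom(n, 1, cc); m2 <- stats::rbinom(n, 1, cc)
          h1 <- ifelse(m1 == 1, a1, stats::rbinom(n, 1, f))
          h2 <- ifelse(m2 == 1, a2, stats::rbinom(n, 1, f))
          dos[v, ] <- h1 + h2
        }
      } else {
        for (v in blk) {
          fv <- if (length(blk) == 1)
            stats::runif(1, config$maf_range[1], config$maf_range[2]) else f
          dos[v, ] <- stats::rbinom(n, 2, fv)
        }
      }
    }
  }
  cnv_rows <- which(layout$variant_type == "CNV")
  for (v in cnv_rows) {
    f <- stats::runif(1, config$maf_range[1], config$maf_range[2])
    if (layout$variant_id[v] %in% config$sex_imbalanced_cnv_ids) {
      fm <- min(2 * f, 0.45); ff <- f / 2
      carriers <- ifelse(sex == 1, fm, ff)
      dos[v, ] <- 2 + stats::rbinom(n, 2, carriers)
    } else {
      dos[v, ] <- 2 + stats::rbinom(n, 2, f)
    }
  }
  geno <- genotype_table(dos, layout$variant_id, layout$chromosome,
                         layout$position, layout$variant_type,
                         paste0("s", seq_len(n)))
  list(geno = geno, sex = sex)
}

# standardized dosage of a named variant (realized mean/sd)
.g_std <- function(geno, id) {
  x <- geno$dosage[match(id, geno$variants$variant_id), ]
  if (is.na(x[1]) && !id %in% geno$variants$variant_id)
    stop("architecture references unknown variant: ", id)
  s <- stats::sd(x)
  if (s == 0) stop("variant ", id, " is monomorphic in this draw")
  (x - mean(x)) / s
}

#' Simulate expression with planted cis effects and mediation chains
#'
#' @param geno a \code{genotype_table} from \code{\link{simulate_genotypes}}.
#' @param config the same \code{simulation_config}.
#' @param sex integer sex vector (needed when any gene has a sex effect).
#' @param seed overrides \code{config$seed + 1}.
#' @return list with \code{expr} (an \code{expression_matrix}),
#'   \code{annot} (a \code{probe_annotation}) and \code{truth} (list with
#'   per-gene planted effects, mediation edges and the sex vector).
#' @export
simulate_expression <- function(geno, config, sex = NULL,
                                seed = config$seed + 1) {
  set.seed(seed)
  n <- length(geno$sample_ids)
  genes <- config$genes
  if (length(genes) == 0) stop("no genes in architecture")
  gene_ids <- vapply(genes, `[[`, character(1), "gene_id")
  vals <- matrix(NA_real_, length(genes), n)
  truth_rows <- list()
  for (k in seq_along(genes)) {
    g <- genes[[k]]
    ve <- g$cis_ve %||% numeric(0)
    h2 <- g$h2 %||% sum(ve)
    genetic <- 0
    if (length(ve) > 0) {
      for (j in seq_along(ve))
        genetic <- genetic + sqrt(ve[j]) * .g_std(geno, g$cis_variants[j])
    }
    poly <- if (h2 - sum(ve) > 1e-12)
      stats::rnorm(n, 0, sqrt(h2 - sum(ve))) else 0
    noise <- stats::rnorm(n, 0, sqrt(max(1 - h2, 0)))
    y <- genetic + poly + noise
    sx <- g$sex_effect %||% 0
    if (sx != 0) {
      if (is.null(sex)) stop("sex vector required for sex effects")
      y <- y + sx * sex
    }
    vals[k, ] <- y
    if (length(ve) > 0)
      truth_rows[[length(truth_rows) + 1]] <- data.frame(
        gene_id = g$gene_id, variant_id = g$cis_variants,
        beta = sqrt(ve), ve = ve, h2 = h2, stringsAsFactors = FALSE)
  }
  # mediation triplets overwrite the involved genes
  tr <- config$triplets
  if (!is.null(tr)) for (j in seq_len(nrow(tr))) {
    gs <- .g_std(geno, tr$variant_id[j])
    ci <- match(tr$cis_gene[j], gene_ids)
    ti <- match(tr$trans_gene[j], gene_ids)
    v1 <- tr$ve1[j]; v2 <- tr$ve2[j]
    if (tr$type[j] == "SCT") {
      C <- sqrt(v1) * gs + stats::rnorm(n, 0, sqrt(1 - v1))
      Tv <- sqrt(v2) * as.vector(scale(C)) + stats::rnorm(n, 0, sqrt(1 - v2))
    } else if (tr$type[j] == "STC") {
      Tv <- sqrt(v1) * gs + stats::rnorm(n, 0, sqrt(1 - v1))
      C <- sqrt(v2) * as.vector(scale(Tv)) + stats::rnorm(n, 0, sqrt(1 - v2))
    } else {  # INDEP
      C <- sqrt(v1) * gs + stats::rnorm(n, 0, sqrt(1 - v1))
      Tv <- sqrt(v2) * gs + stats::rnorm(n, 0, sqrt(1 - v2))
    }
    vals[ci, ] <- C
    vals[ti, ] <- Tv
  }
  probe_ids <- paste0("p_", gene_ids)
  expr <- expression_matrix(vals, probe_ids = probe_ids,
                            sample_ids = geno$sample_ids,
                            probe_to_gene = stats::setNames(gene_ids, probe_ids))
  annot <- probe_annotation(
    probe_id = probe_ids, gene_id = gene_ids,
    chromosome = vapply(genes, `[[`, character(1), "chromosome"),
    tss = vapply(genes, function(g) as.integer(g$tss), integer(1)),
    contains_common_snp = vapply(genes, function(g)
      isTRUE(g$contains_common_snp), logical(1)),
    multi_mapped = vapply(genes, function(g)
      isTRUE(g$multi_mapped), logical(1)))
  truth <- list(
    genes = if (length(truth_rows) > 0) do.call(rbind, truth_rows) else
      data.frame(gene_id = character(), variant_id = character(),
                 beta = numeric(), ve = numeric(), h2 = numeric()),
    edges = tr, sex = sex)
  list(expr = expr, annot = annot, truth = truth)
}

#' Simulate a full cohort (genotypes, sex, expression, annotation, truth)
#'
#' @inheritParams simulate_genotypes
#' @return list with \code{geno}, \code{sex}, \code{expr}, \code{annot},
#'   \code{truth}, \code{config}.
#' @export
simulate_cohort <- function(config, seed = config$seed) {
  gg <- simulate_genotypes(config, seed = seed)
  ee <- simulate_expression(gg$geno, config, sex = gg$sex, seed = seed + 1)
  list(geno = gg$geno, sex = gg$sex, expr = ee$expr, annot = ee$annot,
       truth = ee$truth, config = config)
}

#' Documented preset simulation scenarios
#'
#' \describe{
#'   \item{null}{500 probes with no genetic effects, 2000 SNPs, 400 samples
#'     — exercises FDR calibration.}
#'   \item{cis_only}{100 genes each with one cis variant explaining 10\% of
#'     variance (h2 = 0.3) plus 100 null genes, 800 samples.}
#'   \item{multi_cis}{50 genes each with two independent cis variants (10\%
#'     each, h2 = 0.3) plus 50 null genes, 800 samples.}
#'   \item{mediation}{10 SCT, 10 STC and 10 INDEP triplets with path
#'     variance-explained 0.2/0.2 at 800 samples, plus null genes.}
#'   \item{sex_cnv_confound}{sex-imbalanced CNVs together with
#'     sex-differential probes on other chromosomes, 400 samples — exercises
#'     the CNV trans filters.}
#' }
#'
#' @param name scenario name.
#' @return A \code{simulation_config} with a fixed seed; calling twice with
#'   the same name gives an identical object.
#' @export
make_scenario <- function(name = c("null", "cis_only", "multi_cis",
                                   "mediation", "sex_cnv_confound")) {
  if (!is.character(name) || !name[1] %in% c("null", "cis_only", "multi_cis",
                                             "mediation", "sex_cnv_confound"))
    stop("unknown scenario '", name[1], "'; options: null, cis_only, ",
         "multi_cis, mediation, sex_cnv_confound")
  name <- match.arg(name)
  null_gene <- function(id, chrom, tss)
    list(gene_id = id, chromosome = chrom, tss = tss)
  if (name == "null") {
    cfg <- simulation_config(n_samples = 400, n_snps = 2000, n_chrom = 4,
                             spacing = 5e5, maf_range = c(0.1, 0.5),
                             genes = list(), seed = 41)
    lay <- variant_layout(cfg)
    anchors <- round(seq(2, cfg$n_snps - 1, length.out = 500))
    cfg$genes <- lapply(seq_along(anchors), function(j)
      null_gene(paste0("G", j), lay$chromosome[anchors[j]],
                lay$position[anchors[j]]))
    cfg
  } else if (name == "cis_only") {
    cfg <- simulation_config(n_samples = 800, n_snps = 1500, n_chrom = 3,
                             spacing = 5e5, maf_range = c(0.1, 0.5),
                             genes = list(), seed = 42)
    lay <- variant_layout(cfg)
    anchors <- round(seq(2, cfg$n_snps - 1, length.out = 200))
    cfg$genes <- c(
      lapply(1:100, function(j)
        list(gene_id = paste0("G", j), chromosome = lay$chromosome[anchors[j]],
             tss = lay$position[anchors[j]],
             cis_variants = lay$variant_id[anchors[j]], cis_ve = 0.1,
             h2 = 0.3)),
      lapply(101:200, function(j)
        null_gene(paste0("G", j), lay$chromosome[anchors[j]],
                  lay$position[anchors[j]])))
    cfg
  } else if (name == "multi_cis") {
    cfg <- simulation_config(n_samples = 800, n_snps = 1000, n_chrom = 2,
                             spacing = 5e5, maf_range = c(0.1, 0.5),
                             genes = list(), seed = 43)
    lay <- variant_layout(cfg)
    anchors <- round(seq(2, cfg$n_snps - 2, length.out = 100))
    cfg$genes <- c(
      lapply(1:50, function(j)
        list(gene_id = paste0("G", j), chromosome = lay$chromosome[anchors[j]],
             tss = lay$position[anchors[j]],
             cis_variants = lay$variant_id[anchors[j] + 0:1],
             cis_ve = c(0.1, 0.1), h2 = 0.3)),
      lapply(51:100, function(j)
        null_gene(paste0("G", j), lay$chromosome[anchors[j]],
                  lay$position[anchors[j]])))
    cfg
  } else if (name == "mediation") {
    cfg <- simulation_config(n_samples = 800, n_snps = 120, n_chrom = 2,
                             spacing = 5e5, maf_range = c(0.1, 0.5),
                             genes = list(), seed = 44)
    lay <- variant_layout(cfg)
    types <- rep(c("SCT", "STC", "INDEP"), each = 10)
    # anchor variants on chr1, trans genes on chr2
    anchors <- seq(2, 60, by = 2)[1:30]
    chr2 <- which(lay$chromosome == "chr2")
    genes <- list(); tr <- list()
    for (j in 1:30) {
      cis_id <- paste0("C", j); trans_id <- paste0("T", j)
      genes[[length(genes) + 1]] <- list(
        gene_id = cis_id, chromosome = lay$chromosome[anchors[j]],
        tss = lay$position[anchors[j]],
        cis_variants = lay$variant_id[anchors[j]], cis_ve = 0.2, h2 = 0.2)
      genes[[length(genes) + 1]] <- null_gene(
        trans_id, lay$chromosome[chr2[j]], lay$position[chr2[j]])
      tr[[j]] <- data.frame(variant_id = lay$variant_id[anchors[j]],
                            cis_gene = cis_id, trans_gene = trans_id,
                            type = types[j], ve1 = 0.2, ve2 = 0.2,
                            stringsAsFactors = FALSE)
    }
    cfg$genes <- genes
    cfg$triplets <- do.call(rbind, tr)
    cfg
  } else {  # sex_cnv_confound
    cfg <- simulation_config(n_samples = 400, n_snps = 200, n_cnvs = 20,
                             n_chrom = 4, spacing = 5e5,
                             maf_range = c(0.15, 0.4),
                             sex_imbalanced_cnv_ids = paste0("cnv", 1:5),
                             genes = list(), seed = 45)
    lay <- variant_layout(cfg)
    # keep probes off the CNV-bearing chromosome so the same-chromosome rule
    # never fires in this scenario
    cnv_chroms <- unique(lay$chromosome[lay$variant_type == "CNV"])
    snp_lay <- lay[lay$variant_type == "SNP" &
                     !lay$chromosome %in% cnv_chroms, ]
    anchors <- round(seq(2, nrow(snp_lay) - 1, length.out = 100))
    cfg$genes <- lapply(seq_along(anchors), function(j) {
      g <- null_gene(paste0("G", j), snp_lay$chromosome[anchors[j]],
                     snp_lay$position[anchors[j]])
      if (j <= 20) g$sex_effect <- 0.8
      g
    })
    cfg
  }
}
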