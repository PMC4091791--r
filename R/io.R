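#' Construct a genotype table
#'
#' A genotype table holds per-variant additive dosages for a set of samples,
#' together with variant metadata. SNP dosages are expected alternate-allele
#' counts in \[0, 2\]; CNV dosages are (possibly continuous) copy-number values.
#' Minor allele frequency is computed from the dosages: for SNPs
#' \code{min(mean/2, 1 - mean/2)}, for CNVs one minus the frequency of the
#' modal rounded copy-number class (capped at 0.5).
#'
#' @param dosage numeric matrix, variants in rows, samples in columns.
#' @param variant_id character vector of unique variant identifiers.
#' @param chromosome character vector, one per variant.
#' @param position integer vector of 1-based base-pair positions.
#' @param variant_type character vector, each \code{"SNP"} or \code{"CNV"}.
#' @param sample_ids character vector naming the columns of \code{dosage}.
#' @return An object of class \code{genotype_table}: a list with elements
#'   \code{variants} (data.frame of metadata including computed \code{maf}),
#'   \code{dosage} (numeric matrix) and \code{sample_ids}.
#' @export
genotype_table <- function(dosage, variant_id, chromosome, position,
                           variant_type, sample_ids) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "double"
  n_var <- nrow(dosage)
  if (length(variant_id) != n_var)
    stop("variant_id length does not match dosage rows")
  if (anyDuplicated(variant_id))
    stop("duplicate variant_id: ",
         paste(unique(variant_id[duplicated(variant_id)]), collapse = ", "))
  if (length(sample_ids) != ncol(dosage))
    stop("sample_ids length does not match dosage columns")
  if (anyNA(dosage))
    stop("missing dosages are not allowed")
  variant_type <- as.character(variant_type)
  if (!all(variant_type %in% c("SNP", "CNV")))
    stop("variant_type must be 'SNP' or 'CNV'")
  is_snp <- variant_type == "SNP"
  if (any(is_snp) && (min(dosage[is_snp, ]) < 0 || max(dosage[is_snp, ]) > 2))
    stop("SNP dosages outside [0, 2]")
  position <- as.integer(position)
  if (any(position < 1)) stop("positions must be >= 1 (1-based)")
  rownames(dosage) <- variant_id
  colnames(dosage) <- sample_ids
  maf <- vapply(seq_len(n_var), function(i)
    compute_maf(dosage[i, ], variant_type[i]), numeric(1))
  variants <- data.frame(
    variant_id = as.character(variant_id),
    chromosome = as.character(chromosome),
    position = position,
    variant_type = variant_type,
    maf = maf,
    stringsAsFactors = FALSE
  )
  structure(list(variants = variants, dosage = dosage,
                 sample_ids = as.character(sample_ids)),
            class = "genotype_table")
}

#' Minor allele frequency from a dosage vector
#'
#' @param dosage numeric dosage vector for one variant.
#' @param variant_type \code{"SNP"} or \code{"CNV"}.
#' @return MAF in \[0, 0.5\].
#' @export
compute_maf <- function(dosage, variant_type = "SNP") {
  if (variant_type == "SNP") {
    f <- mean(dosage) / 2
    min(f, 1 - f)
  } else {
    cls <- table(round(dosage))
    min(1 - max(cls) / length(dosage), 0.5)
  }
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("genotype_table:", nrow(x$variants), "variants x",
      length(x$sample_ids), "samples\n")
  tab <- table(x$variants$variant_type)
  cat(" ", paste(names(tab), tab, sep = ": ", collapse = ", "), "\n")
  invisible(x)
}

#' Construct an expression matrix
#'
#' @param values numeric matrix, probes in rows, samples in columns.
#' @param probe_ids character vector of probe identifiers (rownames used if
#'   missing).
#' @param sample_ids character vector of sample identifiers (colnames used if
#'   missing).
#' @param probe_to_gene optional named character vector mapping probe to gene.
#' @return An object of class \code{expression_matrix} with elements
#'   \code{values}, \code{probe_ids}, \code{sample_ids}, \code{probe_to_gene}.
#' @export
expression_matrix <- function(values, probe_ids = rownames(values),
                              sample_ids = colnames(values),
                              probe_to_gene = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(probe_ids) || is.null(sample_ids))
    stop("probe_ids and sample_ids are required")
  if (anyDuplicated(probe_ids)) stop("duplicate probe_id")
  if (anyNA(values)) stop("missing expression values are not allowed")
  rownames(values) <- probe_ids
  colnames(values) <- sample_ids
  structure(list(values = values, probe_ids = as.character(probe_ids),
                 sample_ids = as.character(sample_ids),
                 probe_to_gene = probe_to_gene),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix:", length(x$probe_ids), "probes x",
      length(x$sample_ids), "samples\n")
  invisible(x)
}

#' Read a genotype table from TSV or dosage VCF
#'
#' The TSV dialect has a header row
#' \code{variant_id chromosome position variant_type <sample ids...>} and one
#' variant per row, metadata columns followed by per-sample dosages. VCF input
#' requires a per-sample dosage FORMAT field (default \code{DS}); records whose
#' REF and ALT are single bases are typed SNP, all others CNV.
#'
#' @param path file path.
#' @param format \code{"tsv"} or \code{"vcf_dosage"}.
#' @param dosage_field FORMAT field holding dosages in VCF input.
#' @return A \code{genotype_table}; row order equals file order.
#' @export
read_genotype_table <- function(path, format = c("tsv", "vcf_dosage"),
                                dosage_field = "DS") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             check.names = FALSE, stringsAsFactors = FALSE)
    meta_cols <- c("variant_id", "chromosome", "position", "variant_type")
    if (!all(meta_cols %in% names(tab)[1:4]))
      stop("malformed genotype TSV header; expected columns ",
           paste(meta_cols, collapse = ", "))
    dos <- as.matrix(tab[, -(1:4), drop = FALSE])
    if (!is.numeric(dos)) {
      bad <- which(apply(dos, 1, function(r) anyNA(suppressWarnings(as.numeric(r)))))[1]
      stop("non-numeric dosage at line ", bad + 1L)
    }
    genotype_table(dos, tab$variant_id, tab$chromosome, tab$position,
                   tab$variant_type, colnames(dos))
  } else {
    if (!requireNamespace("vcfR", quietly = TRUE))
      stop("vcfR is required for VCF input")
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    ds <- vcfR::extract.gt(v, element = dosage_field, as.numeric = TRUE)
    if (all(is.na(ds)))
      stop("VCF has no per-sample '", dosage_field, "' dosage field")
    fix <- vcfR::getFIX(v)
    ids <- fix[, "ID"]
    ids[is.na(ids) | ids == "."] <-
      paste0(fix[, "CHROM"], ":", fix[, "POS"])[is.na(ids) | ids == "."]
    single_base <- nchar(fix[, "REF"]) == 1L &
      grepl("^[ACGT]$", fix[, "ALT"])
    vtype <- ifelse(single_base, "SNP", "CNV")
    genotype_table(ds, ids, fix[, "CHROM"], as.integer(fix[, "POS"]),
                   vtype, colnames(ds))
  }
}

#' Write a genotype table as TSV
#'
#' Floats are serialized with 10 significant digits.
#' @param geno a \code{genotype_table}.
#' @param path output path.
#' @export
write_genotype_table <- function(geno, path) {
  dos <- format(geno$dosage, digits = 10, trim = TRUE, scientific = FALSE)
  out <- cbind(geno$variants[, c("variant_id", "chromosome", "position",
                                 "variant_type")], dos)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression matrix from TSV
#'
#' First column \code{probe_id}, remaining header fields are sample ids.
#' @param path file path.
#' @return An \code{expression_matrix}; probe and sample order preserved.
#' @export
read_expression_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(tab) == 0) stop("no probes")
  vals <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(vals)) stop("non-numeric expression value")
  expression_matrix(vals, probe_ids = tab[[1]], sample_ids = colnames(vals))
}

#' Write an expression matrix as TSV
#' @param expr an \code{expression_matrix}.
#' @param path output path.
#' @export
write_expression_matrix <- function(expr, path) {
  out <- data.frame(probe_id = expr$probe_ids,
                    format(expr$values, digits = 10, trim = TRUE,
                           scientific = FALSE),
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read probe annotation from a BED-like TSV
#'
#' Headerless columns: chromosome, TSS (1-based), probe_id, gene_id,
#' contains_common_snp (0/1), multi_mapped (0/1).
#'
#' @param path file path.
#' @return A data.frame of class \code{probe_annotation} with columns
#'   \code{probe_id, gene_id, chromosome, tss, contains_common_snp,
#'   multi_mapped}.
#' @export
read_probe_annotation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE,
                           col.names = c("chromosome", "tss", "probe_id",
                                         "gene_id", "contains_common_snp",
                                         "multi_mapped"))
  probe_annotation(tab$probe_id, tab$gene_id, tab$chromosome, tab$tss,
                   tab$contains_common_snp, tab$multi_mapped)
}

#' Construct probe annotation
#'
#' @param probe_id,gene_id,chromosome character vectors.
#' @param tss integer 1-based transcription start sites.
#' @param contains_common_snp,multi_mapped logical (or 0/1) probe QC flags.
#' @return data.frame of class \code{probe_annotation}.
#' @export
probe_annotation <- function(probe_id, gene_id, chromosome, tss,
                             contains_common_snp = FALSE,
                             multi_mapped = FALSE) {
  if (anyDuplicated(probe_id))
    stop("duplicate probe_id in annotation: ",
         paste(unique(probe_id[duplicated(probe_id)]), collapse = ", "))
  tss <- as.integer(tss)
  if (any(tss < 1)) stop("tss must be >= 1")
  ann <- data.frame(probe_id = as.character(probe_id),
                    gene_id = as.character(gene_id),
                    chromosome = as.character(chromosome),
                    tss = tss,
                    contains_common_snp = as.logical(contains_common_snp),
                    multi_mapped = as.logical(multi_mapped),
                    stringsAsFactors = FALSE)
  class(ann) <- c("probe_annotation", "data.frame")
  ann
}

#' Write probe annotation as BED-like TSV (headerless)
#' @param annot a \code{probe_annotation}.
#' @param path output path.
#' @export
write_probe_annotation <- function(annot, path) {
  out <- data.frame(annot$chromosome, annot$tss, annot$probe_id,
                    annot$gene_id, as.integer(annot$contains_common_snp),
                    as.integer(annot$multi_mapped))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# join annotation to an expression matrix; error if any probe lacks a row
.join_annotation <- function(expr, annot) {
  idx <- match(expr$probe_ids, annot$probe_id)
  if (anyNA(idx))
    stop("probes missing from annotation: ",
         paste(utils::head(expr$probe_ids[is.na(idx)], 5), collapse = ", "))
  annot[idx, , drop = FALSE]
}

#' Distance from a position to the closest annotated TSS on a chromosome
#'
#' @param position integer base-pair position.
#' @param chromosome chromosome of the variant.
#' @param annot a \code{probe_annotation}.
#' @return minimum \code{|position - tss|} over genes on the same chromosome;
#'   \code{Inf} if the chromosome has no annotated gene.
#' @export
distance_to_closest_gene <- function(position, chromosome, annot) {
  tss <- annot$tss[annot$chromosome == chromosome]
  if (length(tss) == 0) return(Inf)
  min(abs(position - tss))
}

#' Annotate every variant with its distance to the closest gene
#'
#' @param geno a \code{genotype_table}.
#' @param annot a \code{probe_annotation}.
#' @return the genotype table with a \code{distance_to_closest_gene} metadata
#'   column.
#' @export
annotate_gene_distance <- function(geno, annot) {
  geno$variants$distance_to_closest_gene <- vapply(
    seq_len(nrow(geno$variants)),
    function(i) distance_to_closest_gene(geno$variants$position[i],
                                         geno$variants$chromosome[i], annot),
    numeric(1))
  geno
}

#' Restrict genotype and expression tables to their common samples
#'
#' The intersection is sorted so the result does not depend on input file
#' order.
#'
#' @param geno a \code{genotype_table}.
#' @param expr an \code{expression_matrix}.
#' @return list with elements \code{geno} and \code{expr} subset to the
#'   shared, sorted sample ids.
#' @export
intersect_samples <- function(geno, expr) {
  common <- sort(intersect(geno$sample_ids, expr$sample_ids))
  if (length(common) == 0) stop("no shared samples")
  gi <- match(common, geno$sample_ids)
  ei <- match(common, expr$sample_ids)
  geno$dosage <- geno$dosage[, gi, drop = FALSE]
  geno$sample_ids <- common
  expr$values <- expr$values[, ei, drop = FALSE]
  expr$sample_ids <- common
  list(geno = geno, expr = expr)
}
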