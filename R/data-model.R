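# Shared data model: matrix-backed containers for the omics layers.
#
# Conventions used throughout the package:
#   * point positions (SNPs, CpGs, gene anchors) are 1-based;
#   * all intervals (loci, windows, hotspot output) are 0-based half-open BED;
#   * strains are fully inbred, so genotypes are coded {0, 1} for the two
#     homozygous classes; heterozygous input is rejected (or masked when a
#     permissive flag is set at read time);
#   * missing data is NA inside the matrices, never a numeric sentinel.

CONDITIONS <- c("control", "treated", "delta")
QTL_CLASSES <- c("eQTL", "mQTL", "emQTL")

check_feature_table <- function(tbl, id_col, what) {
  if (!all(c(id_col, "chrom", "pos") %in% names(tbl))) {
    stop_input(sprintf("%s table needs columns %s, chrom, pos", what, id_col))
  }
  ids <- tbl[[id_col]]
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop_input(sprintf("duplicate %s id(s): %s", what,
                       paste(head(dup, 5), collapse = ", ")))
  }
  if (any(is.na(tbl$chrom)) || any(is.na(tbl$pos)) || any(tbl$pos < 1)) {
    stop_input(sprintf("%s positions must have a chromosome and a positive 1-based coordinate", what))
  }
  tibble::as_tibble(tbl)
}

#' Genotype matrix for a fully inbred panel
#'
#' Bundles a strains x SNPs matrix of homozygous allele codes (0 = major
#' class, 1 = minor class, NA = missing) with per-SNP genomic positions.
#'
#' @param codes Numeric/integer matrix, strains in rows (rownames = strain
#'   ids), SNPs in columns (colnames = SNP ids); values in `{0, 1, NA}`.
#' @param snps Tibble with columns `snp_id`, `chrom`, `pos` (1-based),
#'   one row per column of `codes`, in matching order.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(codes, snps) {
  snps <- check_feature_table(snps, "snp_id", "SNP")
  codes <- as.matrix(codes)
  if (is.null(rownames(codes))) stop_input("genotype codes need strain rownames")
  if (ncol(codes) != nrow(snps)) {
    stop_input("genotype code matrix columns do not match the SNP table")
  }
  colnames(codes) <- snps$snp_id
  bad <- !(codes %in% c(0, 1)) & !is.na(codes)
  if (any(bad)) {
    idx <- which(bad)[1]
    rc <- arrayInd(idx, dim(codes))
    stop_input(sprintf(
      "genotype codes must be 0, 1 or missing; found %s at strain '%s', SNP '%s'",
      codes[idx], rownames(codes)[rc[1]], colnames(codes)[rc[2]]))
  }
  if (anyDuplicated(rownames(codes))) stop_input("duplicate strain ids in genotype matrix")
  structure(list(codes = codes, snps = snps), class = "genotype_matrix")
}

#' Expression matrix for one condition
#'
#' @param values Numeric matrix, strains x genes, with dimnames.
#' @param genes Tibble with `gene_id`, `chrom`, `pos` (representative 1-based
#'   coordinate), matching the columns of `values`.
#' @param condition One of `"control"`, `"treated"`, `"delta"`.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, genes, condition) {
  genes <- check_feature_table(genes, "gene_id", "gene")
  condition <- match.arg(condition, CONDITIONS)
  values <- as.matrix(values)
  if (is.null(rownames(values))) stop_input("expression values need strain rownames")
  if (ncol(values) != nrow(genes)) stop_input("expression matrix columns do not match the gene table")
  colnames(values) <- genes$gene_id
  if (any(is.infinite(values))) stop_input("expression values must be finite or missing")
  structure(list(values = values, genes = genes, condition = condition),
            class = "expression_matrix")
}

#' Paired methylated/total read counts per CpG
#'
#' @param meth,total Non-negative integer matrices, strains x CpGs, with
#'   `meth <= total` wherever both are observed. Missing cells are NA in both.
#' @param cpgs Tibble with `cpg_id`, `chrom`, `pos` (1-based coordinate of
#'   the CpG cytosine).
#' @return An object of class `methylation_counts`.
#' @export
methylation_counts <- function(meth, total, cpgs) {
  cpgs <- check_feature_table(cpgs, "cpg_id", "CpG")
  meth <- as.matrix(meth); total <- as.matrix(total)
  if (!identical(dim(meth), dim(total))) stop_input("meth and total matrices differ in shape")
  if (is.null(rownames(meth))) stop_input("methylation counts need strain rownames")
  if (ncol(meth) != nrow(cpgs)) stop_input("methylation matrix columns do not match the CpG table")
  colnames(meth) <- colnames(total) <- cpgs$cpg_id
  rownames(total) <- rownames(meth)
  # NA must be paired so that one mask covers both matrices
  na_mismatch <- xor(is.na(meth), is.na(total))
  if (any(na_mismatch)) {
    meth[na_mismatch] <- NA
    total[na_mismatch] <- NA
  }
  if (any(total < 0, na.rm = TRUE) || any(meth < 0, na.rm = TRUE)) {
    stop_input("read counts must be non-negative")
  }
  over <- which(meth > total)
  if (length(over)) {
    rc <- arrayInd(over[1], dim(meth))
    stop_input(sprintf(
      "methylated count exceeds total (%d > %d) at CpG '%s', strain '%s'",
      meth[over[1]], total[over[1]], colnames(meth)[rc[2]], rownames(meth)[rc[1]]))
  }
  structure(list(meth = meth, total = total, cpgs = cpgs),
            class = "methylation_counts")
}

#' Strain phenotype table
#'
#' A tibble with a `strain` column followed by one numeric column per trait.
#'
#' @param tbl Data frame with column `strain` and numeric trait columns.
#' @return A `phenotype_table` (tibble subclass).
#' @export
phenotype_table <- function(tbl) {
  tbl <- tibble::as_tibble(tbl)
  if (!"strain" %in% names(tbl)) stop_input("phenotype table needs a 'strain' column")
  if (anyDuplicated(tbl$strain)) stop_input("duplicate strain ids in phenotype table")
  if (anyDuplicated(names(tbl))) stop_input("duplicate trait ids in phenotype table")
  class(tbl) <- c("phenotype_table", class(tbl))
  tbl
}

#' Prior association locus list
#'
#' Intervals are 0-based half-open (BED convention).
#'
#' @param tbl Data frame with columns `locus_id`, `chrom`, `start`, `end`
#'   and optionally `source`.
#' @param genome Optional [genome_spec()] used to validate chromosome labels.
#' @return A `locus_list` tibble.
#' @export
locus_list <- function(tbl, genome = NULL) {
  tbl <- tibble::as_tibble(tbl)
  need <- c("locus_id", "chrom", "start", "end")
  if (!all(need %in% names(tbl))) {
    stop_input("locus list needs columns locus_id, chrom, start, end")
  }
  if (!"source" %in% names(tbl)) tbl$source <- NA_character_
  if (any(tbl$start >= tbl$end)) stop_input("locus intervals must satisfy start < end")
  if (any(tbl$start < 0)) stop_input("locus starts must be >= 0 (0-based half-open)")
  if (!is.null(genome)) {
    bad <- setdiff(unique(tbl$chrom), genome$chrom)
    if (length(bad)) {
      stop_input(sprintf("locus chromosome(s) not in genome: %s", paste(bad, collapse = ", ")))
    }
  }
  tbl <- tbl[, c("locus_id", "chrom", "start", "end", "source")]
  class(tbl) <- c("locus_list", class(tbl))
  tbl
}

#' Genome specification
#'
#' @param chrom Character vector of chromosome labels.
#' @param length Chromosome lengths in base pairs.
#' @return A `genome_spec` tibble with columns `chrom` and `length`.
#' @export
genome_spec <- function(chrom, length) {
  if (anyDuplicated(chrom)) stop_input("duplicate chromosome labels in genome spec")
  if (any(length <= 0)) stop_input("chromosome lengths must be positive")
  out <- tibble(chrom = as.character(chrom), length = as.numeric(length))
  class(out) <- c("genome_spec", class(out))
  out
}

# strain accessors -----------------------------------------------------------

#' Strain identifiers of an omics container
#' @param x A genotype, expression, methylation or phenotype object.
#' @return Character vector of strain ids.
#' @export
strain_ids <- function(x) UseMethod("strain_ids")

#' @export
strain_ids.genotype_matrix <- function(x) rownames(x$codes)
#' @export
strain_ids.expression_matrix <- function(x) rownames(x$values)
#' @export
strain_ids.methylation_counts <- function(x) rownames(x$meth)
#' @export
strain_ids.phenotype_table <- function(x) x$strain

restrict_strains <- function(x, ids) UseMethod("restrict_strains")
#' @export
restrict_strains.genotype_matrix <- function(x, ids) {
  genotype_matrix(x$codes[ids, , drop = FALSE], x$snps)
}
#' @export
restrict_strains.expression_matrix <- function(x, ids) {
  expression_matrix(x$values[ids, , drop = FALSE], x$genes, x$condition)
}
#' @export
restrict_strains.methylation_counts <- function(x, ids) {
  methylation_counts(x$meth[ids, , drop = FALSE], x$total[ids, , drop = FALSE], x$cpgs)
}
#' @export
restrict_strains.phenotype_table <- function(x, ids) {
  out <- x[match(ids, x$strain), , drop = FALSE]
  phenotype_table(out)
}

#' Restrict omics objects to their shared strains
#'
#' Different omics layers of a panel usually cover different strain subsets
#' (e.g. expression for 99 strains, methylation for 90). Cross-layer analyses
#' operate on the sorted intersection.
#'
#' @param ... Omics containers (genotype, expression, methylation, phenotype
#'   objects), or a single list of them.
#' @return A list of the same objects, each restricted to the sorted common
#'   strain set, in identical strain order. Idempotent.
#' @export
align_strains <- function(...) {
  objs <- list(...)
  if (length(objs) == 1 && is.list(objs[[1]]) && !inherits(objs[[1]], c(
    "genotype_matrix", "expression_matrix", "methylation_counts", "phenotype_table"))) {
    objs <- objs[[1]]
  }
  if (!length(objs)) stop_input("align_strains() needs at least one object")
  shared <- Reduce(intersect, lapply(objs, strain_ids))
  if (!length(shared)) stop_input("no strain is shared by all objects")
  if (length(shared) == 1) {
    warn("only one strain is shared by all objects")
  }
  shared <- sort(shared)
  lapply(objs, restrict_strains, ids = shared)
}

# printing -------------------------------------------------------------------

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d strains x %d SNPs on %d chromosome(s)\n",
              nrow(x$codes), ncol(x$codes), length(unique(x$snps$chrom))))
  invisible(x)
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d strains x %d genes (condition: %s)\n",
              nrow(x$values), ncol(x$values), x$condition))
  invisible(x)
}

#' @export
print.methylation_counts <- function(x, ...) {
  cat(sprintf("<methylation_counts> %d strains x %d CpGs, %.1f%% cells missing\n",
              nrow(x$meth), ncol(x$meth), 100 * mean(is.na(x$meth))))
  invisible(x)
}

# tidy views -----------------------------------------------------------------

#' @export
as_tibble.genotype_matrix <- function(x, ...) {
  long_matrix(x$codes, "strain", "snp_id", "code") %>%
    left_join(x$snps, by = "snp_id")
}

#' @export
as_tibble.expression_matrix <- function(x, ...) {
  long_matrix(x$values, "strain", "gene_id", "value") %>%
    left_join(x$genes, by = "gene_id") %>%
    mutate(condition = x$condition)
}

#' @export
as_tibble.methylation_counts <- function(x, ...) {
  out <- long_matrix(x$meth, "strain", "cpg_id", "meth")
  out$total <- as.vector(x$total)
  left_join(out, x$cpgs, by = "cpg_id")
}

long_matrix <- function(m, row_name, col_name, value_name) {
  tibble(
    !!row_name := rep(rownames(m), times = ncol(m)),
    !!col_name := rep(colnames(m), each = nrow(m)),
    !!value_name := as.vector(m)
  )
}
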