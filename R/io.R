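# Readers and writers for the package's plain-text dialects.
#
# Genotype / expression TSV:   <id> chrom pos <strain...>   (rows = features)
# Methylation:                 two parallel TSVs (meth, total), same layout
# Phenotype TSV:               strain <trait...>
# Loci:                        BED4+ (chrom start end locus_id [source]),
#                              0-based half-open
#
# Writers emit '#'-prefixed header lines recording the package version and
# generation parameters; readers skip them. Each reader is the inverse of the
# corresponding writer on valid objects.

io_header <- function(params = NULL) {
  h <- sprintf("# hotspotqtl %s", pkg_version_string())
  if (!is.null(params) && length(params)) {
    h <- c(h, sprintf("# %s", paste(names(params), unlist(params), sep = "=", collapse = " ")))
  }
  h
}

write_tsv_with_header <- function(tbl, path, params = NULL) {
  writeLines(io_header(params), path)
  readr::write_tsv(tbl, path, append = TRUE, col_names = TRUE, progress = FALSE)
  invisible(path)
}

read_tsv_plain <- function(path, col_types = NULL) {
  if (!file.exists(path)) stop_input(sprintf("file does not exist: %s", path))
  readr::read_tsv(path, comment = "#", col_types = col_types, progress = FALSE,
                  show_col_types = FALSE)
}

feature_matrix_to_tbl <- function(m, features, id_col) {
  tbl <- features
  vals <- t(m)                       # features x strains
  colnames(vals) <- rownames(m)
  dplyr::bind_cols(tbl, tibble::as_tibble(vals))
}

tbl_to_feature_matrix <- function(tbl, id_col, path, permissive = FALSE,
                                  allowed = NULL) {
  meta_cols <- c(id_col, "chrom", "pos")
  if (!all(meta_cols %in% names(tbl))) {
    stop_input(sprintf("%s needs columns %s and one column per strain",
                       path, paste(meta_cols, collapse = ", ")))
  }
  strain_cols <- setdiff(names(tbl), meta_cols)
  if (!length(strain_cols)) stop_input(sprintf("%s contains no strain columns", path))
  m <- matrix(NA_real_, nrow = length(strain_cols), ncol = nrow(tbl),
              dimnames = list(strain_cols, tbl[[id_col]]))
  for (j in seq_along(strain_cols)) {
    col <- tbl[[strain_cols[j]]]
    num <- suppressWarnings(as.numeric(col))
    bad <- is.na(num) & !is.na(col) & !(col %in% c("NA", ""))
    if (any(bad) && !permissive) {
      i <- which(bad)[1]
      stop_input(sprintf("non-numeric value '%s' in %s at row %d (feature '%s'), column '%s'",
                         col[i], path, i, tbl[[id_col]][i], strain_cols[j]))
    }
    if (!is.null(allowed)) {
      out_of_set <- !is.na(num) & !(num %in% allowed)
      if (any(out_of_set)) {
        if (!permissive) {
          i <- which(out_of_set)[1]
          stop_input(sprintf("code '%s' outside {%s} in %s at row %d (feature '%s'), column '%s'",
                             col[i], paste(allowed, collapse = ","), path, i,
                             tbl[[id_col]][i], strain_cols[j]))
        }
        num[out_of_set] <- NA_real_
      }
    }
    m[j, ] <- num
  }
  list(m = m, features = tbl[, meta_cols])
}

#' Read / write a genotype TSV
#'
#' Documented dialect: columns `snp_id chrom pos <strain...>` with codes in
#' `{0, 1}` (homozygous classes of a fully inbred panel) or `NA`.
#'
#' @param path File path.
#' @param permissive If `TRUE`, unparseable or out-of-set codes (e.g. a
#'   heterozygous `2`) become missing; otherwise they raise an error naming
#'   the offending row and column.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, permissive = FALSE) {
  tbl <- read_tsv_plain(path, col_types = readr::cols(
    snp_id = "c", chrom = "c", pos = "d", .default = "c"))
  parsed <- tbl_to_feature_matrix(tbl, "snp_id", path, permissive,
                                  allowed = c(0, 1))
  genotype_matrix(parsed$m, parsed$features)
}

#' @rdname read_genotypes
#' @param geno A [genotype_matrix()].
#' @export
write_genotypes <- function(geno, path) {
  write_tsv_with_header(feature_matrix_to_tbl(geno$codes, geno$snps, "snp_id"),
                        path, list(format = "genotype"))
}

#' Read / write an expression TSV
#'
#' Dialect: `gene_id chrom pos <strain...>`, log-scale abundances.
#'
#' @param path File path.
#' @param condition Condition label for the matrix.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, condition) {
  tbl <- read_tsv_plain(path, col_types = readr::cols(
    gene_id = "c", chrom = "c", pos = "d", .default = "c"))
  parsed <- tbl_to_feature_matrix(tbl, "gene_id", path, permissive = FALSE)
  expression_matrix(parsed$m, parsed$features, condition)
}

#' @rdname read_expression
#' @param expr An [expression_matrix()].
#' @export
write_expression <- function(expr, path) {
  write_tsv_with_header(feature_matrix_to_tbl(expr$values, expr$genes, "gene_id"),
                        path, list(format = "expression", condition = expr$condition))
}

#' Read / write paired methylation count TSVs
#'
#' Two parallel files (methylated and total read counts) with identical
#' layout `cpg_id chrom pos <strain...>`. The reader enforces `meth <= total`
#' and identical strain headers.
#'
#' @param meth_path,total_path Paths to the methylated / total count files.
#' @return A [methylation_counts()].
#' @export
read_methylation <- function(meth_path, total_path) {
  ct <- readr::cols(cpg_id = "c", chrom = "c", pos = "d", .default = "d")
  mt <- read_tsv_plain(meth_path, col_types = ct)
  tt <- read_tsv_plain(total_path, col_types = ct)
  if (!identical(names(mt), names(tt))) {
    stop_input("strain headers differ between methylated and total count files")
  }
  if (!identical(mt$cpg_id, tt$cpg_id)) {
    stop_input("CpG ids differ between methylated and total count files")
  }
  pm <- tbl_to_feature_matrix(mt, "cpg_id", meth_path, permissive = FALSE)
  pth <- tbl_to_feature_matrix(tt, "cpg_id", total_path, permissive = FALSE)
  methylation_counts(pm$m, pth$m, pm$features)
}

#' @rdname read_methylation
#' @param meth A [methylation_counts()].
#' @export
write_methylation <- function(meth, meth_path, total_path) {
  write_tsv_with_header(feature_matrix_to_tbl(meth$meth, meth$cpgs, "cpg_id"),
                        meth_path, list(format = "methylation", layer = "meth"))
  write_tsv_with_header(feature_matrix_to_tbl(meth$total, meth$cpgs, "cpg_id"),
                        total_path, list(format = "methylation", layer = "total"))
  invisible(c(meth_path, total_path))
}

#' Read / write a phenotype TSV (`strain <trait...>`)
#' @param path File path.
#' @return A [phenotype_table()].
#' @export
read_phenotypes <- function(path) {
  tbl <- read_tsv_plain(path, col_types = readr::cols(strain = "c", .default = "d"))
  phenotype_table(tbl)
}

#' @rdname read_phenotypes
#' @param pheno A [phenotype_table()].
#' @export
write_phenotypes <- function(pheno, path) {
  write_tsv_with_header(tibble::as_tibble(unclass(pheno)), path,
                        list(format = "phenotype"))
}

#' Read / write a locus list as BED4+
#'
#' BED convention: 0-based half-open, columns
#' `chrom start end locus_id [source]`, tab-separated, no column header.
#'
#' @param path File path.
#' @param genome Optional [genome_spec()] for chromosome validation.
#' @return A [locus_list()].
#' @export
read_loci <- function(path, genome = NULL) {
  if (!file.exists(path)) stop_input(sprintf("file does not exist: %s", path))
  tbl <- readr::read_tsv(path, comment = "#", col_names = FALSE, progress = FALSE,
                         show_col_types = FALSE)
  if (ncol(tbl) < 4) stop_input("locus BED needs at least 4 columns (chrom start end locus_id)")
  out <- tibble(locus_id = as.character(tbl[[4]]), chrom = as.character(tbl[[1]]),
                start = as.numeric(tbl[[2]]), end = as.numeric(tbl[[3]]),
                source = if (ncol(tbl) >= 5) as.character(tbl[[5]]) else NA_character_)
  locus_list(out, genome)
}

#' @rdname read_loci
#' @param loci A [locus_list()].
#' @export
write_loci <- function(loci, path) {
  writeLines(io_header(list(format = "bed4+")), path)
  bed <- tibble(chrom = loci$chrom, start = format(loci$start, scientific = FALSE, trim = TRUE),
                end = format(loci$end, scientific = FALSE, trim = TRUE),
                locus_id = loci$locus_id,
                source = ifelse(is.na(loci$source), ".", loci$source))
  readr::write_tsv(bed, path, append = TRUE, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Write an association result table
#'
#' Columns: `feature predictor chrom pos beta se p n class condition note`.
#'
#' @param results Association tibble from [assoc_scan()] or [emqtl_scan()].
#' @param path File path.
#' @param max_p Emit only rows with `p < max_p` (`Inf` keeps everything);
#'   bounds file size for genome-wide scans.
#' @export
write_assoc_results <- function(results, path, max_p = Inf) {
  keep <- is.na(results$p) | results$p < max_p
  write_tsv_with_header(results[keep, , drop = FALSE], path,
                        list(format = "assoc", max_p = max_p))
}
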