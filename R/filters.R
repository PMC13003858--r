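# Feature-selection rules deciding which genes, SNPs and CpGs enter each scan.
#
# Boundary conventions (documented and tested):
#   * gene mean / CV use strict ">" (thresholds are "expressed >5",
#     "varying >10%");
#   * MAF uses inclusive ">=" (the usual "MAF of 5%" cutoff convention);
#   * hypervariability: a CpG is kept when at least ceil(strain_frac * n)
#     non-missing strains deviate from the across-strain MEDIAN percent
#     methylation by strictly more than shift_min percentage points.

new_filter_report <- function(flags, filter, params) {
  flags <- tibble::as_tibble(flags)
  attr(flags, "filter") <- filter
  attr(flags, "params") <- params
  attr(flags, "n_input") <- nrow(flags)
  attr(flags, "n_output") <- sum(flags$pass)
  class(flags) <- c("filter_report", class(flags))
  flags
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("<filter_report> %s: %d of %d features pass (%s)\n",
              attr(x, "filter"), attr(x, "n_output"), attr(x, "n_input"),
              paste(names(attr(x, "params")), unlist(attr(x, "params")),
                    sep = "=", collapse = ", ")))
  NextMethod()
}

#' Serialize a filter report to TSV
#' @param report A `filter_report`.
#' @param path File path.
#' @export
write_filter_report <- function(report, path) {
  write_tsv_with_header(tibble::as_tibble(report), path,
                        c(list(filter = attr(report, "filter")), attr(report, "params")))
}

#' Select expressed, varying genes
#'
#' Keeps genes whose across-strain mean abundance exceeds `mean_min` and
#' whose coefficient of variation (sd/mean, computed on the values as stored)
#' exceeds `cv_min`, both strictly.
#'
#' @param expr An [expression_matrix()] with at least 2 strains.
#' @param mean_min Minimum mean abundance (default 5).
#' @param cv_min Minimum coefficient of variation (default 0.10).
#' @return A list with `keep` (gene ids) and `report` (per-gene flags).
#' @export
filter_genes <- function(expr, mean_min = 5, cv_min = 0.10) {
  v <- expr$values
  if (nrow(v) == 0) stop_input("expression matrix has zero strains")
  if (nrow(v) < 2) stop_input("gene filtering needs at least 2 strains")
  mu <- colMeans(v, na.rm = TRUE)
  sdv <- apply(v, 2, sd, na.rm = TRUE)
  cv <- sdv / mu
  pass <- !is.na(mu) & !is.na(cv) & mu > mean_min & cv > cv_min
  reason <- dplyr::case_when(
    pass ~ NA_character_,
    is.na(mu) | is.na(cv) ~ "not_evaluable",
    mu <= mean_min & (is.na(cv) | cv <= cv_min) ~ "low_mean_and_cv",
    mu <= mean_min ~ "low_mean",
    TRUE ~ "low_cv"
  )
  report <- new_filter_report(
    tibble(feature_id = colnames(v), mean = mu, cv = cv, pass = pass, reason = reason),
    "filter_genes", list(mean_min = mean_min, cv_min = cv_min))
  list(keep = colnames(v)[pass], report = report)
}

#' Select SNPs by minor allele frequency
#'
#' In a fully inbred panel the allele frequency equals the strain-class
#' frequency. MAF is computed over non-missing strains; SNPs with
#' `MAF >= maf_min` are kept (inclusive).
#'
#' @param geno A [genotype_matrix()].
#' @param maf_min Minimum minor allele frequency (default 0.05).
#' @return A list with `keep` (SNP ids) and `report`.
#' @export
filter_snps_maf <- function(geno, maf_min = 0.05) {
  g <- geno$codes
  n_obs <- colSums(!is.na(g))
  f <- colMeans(g, na.rm = TRUE)
  maf <- pmin(f, 1 - f)
  pass <- n_obs >= 2 & !is.na(maf) & maf >= maf_min
  reason <- dplyr::case_when(
    pass ~ NA_character_,
    n_obs == 0 ~ "all_missing",
    n_obs < 2 ~ "insufficient_strains",
    TRUE ~ "low_maf"
  )
  report <- new_filter_report(
    tibble(feature_id = colnames(g), maf = maf, n = n_obs, pass = pass, reason = reason),
    "filter_snps_maf", list(maf_min = maf_min))
  list(keep = colnames(g)[pass], report = report)
}

#' Mask low-depth methylation calls
#'
#' Cells with total read count below `min_reads` (the default keeps depth
#' `> 3`) are set missing; CpGs left with no observed strain are dropped.
#' Pure masking: idempotent.
#'
#' @param meth A [methylation_counts()].
#' @param min_reads Minimum total read count to keep a cell (default 4).
#' @return A filtered [methylation_counts()].
#' @export
filter_depth <- function(meth, min_reads = 4) {
  mask <- !is.na(meth$total) & meth$total < min_reads
  m <- meth$meth; tt <- meth$total
  m[mask] <- NA; tt[mask] <- NA
  keep <- colSums(!is.na(tt)) > 0
  methylation_counts(m[, keep, drop = FALSE], tt[, keep, drop = FALSE],
                     meth$cpgs[keep, , drop = FALSE])
}

#' Mask CpG calls carrying a SNP at the CpG site
#'
#' A SNP whose position equals the CpG coordinate or the next base (the
#' dyad's two cytosines) destroys the bisulfite signal in strains carrying
#' the minor allele; those cells are masked.
#'
#' @param meth A [methylation_counts()].
#' @param geno A [genotype_matrix()] sharing chromosome naming.
#' @return A [methylation_counts()] with affected cells masked.
#' @export
mask_snp_overlapped_cpgs <- function(meth, geno) {
  shared <- intersect(strain_ids(meth), strain_ids(geno))
  snp_key <- paste(geno$snps$chrom, geno$snps$pos)
  m <- meth$meth; tt <- meth$total
  for (offset in c(0, 1)) {
    cpg_key <- paste(meth$cpgs$chrom, meth$cpgs$pos + offset)
    hit <- match(cpg_key, snp_key)
    for (j in which(!is.na(hit))) {
      codes <- geno$codes[, hit[j]]
      f <- mean(codes, na.rm = TRUE)
      if (is.nan(f)) next
      minor <- if (f <= 0.5) 1 else 0
      carriers <- intersect(names(codes)[!is.na(codes) & codes == minor], shared)
      if (length(carriers)) {
        m[carriers, j] <- NA
        tt[carriers, j] <- NA
      }
    }
  }
  methylation_counts(m, tt, meth$cpgs)
}

#' Select hypervariable CpGs
#'
#' Percent methylation is `100 * meth / total` per non-missing strain. A CpG
#' is hypervariable when at least `ceil(strain_frac * n_nonmissing)` strains
#' deviate from the across-strain median percent methylation by strictly
#' more than `shift_min` percentage points.
#'
#' @param meth A depth-filtered [methylation_counts()].
#' @param shift_min Minimum shift in percentage points (default 25).
#' @param strain_frac Minimum fraction of non-missing strains that must show
#'   the shift (default 0.05, mirroring a 5% MAF cutoff).
#' @return A list with `keep` (CpG ids) and `report`.
#' @export
filter_hypervariable_cpgs <- function(meth, shift_min = 25, strain_frac = 0.05) {
  pct <- 100 * meth$meth / meth$total
  n_obs <- colSums(!is.na(pct))
  med <- apply(pct, 2, median, na.rm = TRUE)
  n_dev <- colSums(abs(sweep(pct, 2, med, "-")) > shift_min, na.rm = TRUE)
  need <- ceiling(strain_frac * n_obs)
  pass <- n_obs >= 2 & n_dev >= pmax(need, 1)
  reason <- dplyr::case_when(
    pass ~ NA_character_,
    n_obs < 2 ~ "insufficient_strains",
    TRUE ~ "not_hypervariable"
  )
  report <- new_filter_report(
    tibble(feature_id = colnames(pct), n = n_obs, n_deviant = n_dev,
           pass = pass, reason = reason),
    "filter_hypervariable_cpgs",
    list(shift_min = shift_min, strain_frac = strain_frac))
  list(keep = colnames(pct)[pass], report = report)
}
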