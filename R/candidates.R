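# Candidate-gene evidence assembly within hotspot flanks, and the gene-set
# correlation permutation test used to tie a candidate to a pathway.

#' Genes within a flank of a locus
#'
#' @param locus One row of a `merged_locus` tibble (or any list/row with
#'   `chrom`, `start`, `end`).
#' @param genes Gene position tibble (`gene_id, chrom, pos`, 1-based points).
#' @param flank Flank size in bp on either side (default 1 Mb, the typical
#'   extent of linkage disequilibrium in an inbred panel).
#' @return Character vector of gene ids whose coordinate lies in
#'   `[start - flank, end + flank)` (0-based; closed lower bound), clipped
#'   at zero.
#' @export
flank_genes <- function(locus, genes, flank = 1e6) {
  lo <- max(locus$start - flank, 0)
  hi <- locus$end + flank
  sel <- genes$chrom == locus$chrom & (genes$pos - 1) >= lo & (genes$pos - 1) < hi
  genes$gene_id[sel]
}

#' Minimum cis p-value for a gene inside a flank interval
#'
#' @param gene_id Gene id.
#' @param results Association tibble from an eQTL scan.
#' @param locus Locus (with `chrom`, `start`, `end`).
#' @param flank Flank in bp.
#' @return The minimum p among the gene's tests whose predictor lies in the
#'   flanked interval, or `NA` if none.
#' @export
cis_eqtl_min_p <- function(gene_id, results, locus, flank = 1e6) {
  lo <- max(locus$start - flank, 0)
  hi <- locus$end + flank
  sel <- results$feature == gene_id & results$chrom == locus$chrom &
    (results$pos - 1) >= lo & (results$pos - 1) < hi & !is.na(results$p)
  if (!any(sel)) return(NA_real_)
  min(results$p[sel])
}

#' Gene-phenotype Pearson correlations
#'
#' Standard Pearson correlation with a two-sided t-distribution p-value,
#' pairwise-complete strains (>= 3 required per pair).
#'
#' @param expr An [expression_matrix()].
#' @param pheno A [phenotype_table()].
#' @return A tibble `gene, trait, r, p, n, note`.
#' @export
trait_correlations <- function(expr, pheno) {
  aligned <- align_strains(expr, pheno)
  v <- aligned[[1]]$values
  ph <- aligned[[2]]
  traits <- setdiff(names(ph), "strain")
  out <- purrr::map(traits, function(tr) {
    y <- ph[[tr]]
    res <- purrr::map(colnames(v), function(g) {
      x <- v[, g]
      ok <- !is.na(x) & !is.na(y)
      n <- sum(ok)
      if (n < 3) return(list(r = NA_real_, p = NA_real_, n = n, note = "insufficient_strains"))
      if (sd(x[ok]) == 0 || sd(y[ok]) == 0) {
        return(list(r = NA_real_, p = NA_real_, n = n, note = "zero_variance"))
      }
      r <- cor(x[ok], y[ok])
      tval <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
      list(r = r, p = p_floor(2 * pt(-abs(tval), df = n - 2)), n = n, note = NA_character_)
    })
    tibble(gene = colnames(v), trait = tr,
           r = map_dbl(res, "r"), p = map_dbl(res, "p"),
           n = map_int(res, function(z) as.integer(z$n)),
           note = map_chr(res, function(z) z$note %||% NA_character_))
  })
  bind_rows(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Score candidate genes at a locus
#'
#' Evidence lines, one point each: (1) a coding variant in the gene, from an
#' input annotation table; (2) a cis eQTL below `cis_alpha` within the
#' flank; (3) a phenotype correlation below `trait_alpha`. Ranked by score,
#' then ascending cis p, then gene id (deterministic tie-break). Literature
#' evidence is outside this package's scope.
#'
#' @param locus Locus row (`chrom, start, end`, optionally `locus_id`).
#' @param gene_ids Genes to score (e.g. from [flank_genes()]).
#' @param coding_variants Tibble `gene_id, has_coding_variant` (logical).
#' @param cis_results eQTL association tibble for the cis lookup.
#' @param trait_cors Output of [trait_correlations()].
#' @param cis_alpha Cis significance cutoff (default genome-wide 4.2e-6).
#' @param trait_alpha Trait-correlation cutoff (default 0.05).
#' @param flank Flank in bp for the cis lookup.
#' @return A tibble `gene_id, locus_id, has_coding_variant, cis_min_p,
#'   best_trait, best_trait_r, best_trait_p, score` sorted by evidence.
#' @export
score_candidates <- function(locus, gene_ids, coding_variants, cis_results,
                             trait_cors, cis_alpha = 4.2e-6, trait_alpha = 0.05,
                             flank = 1e6) {
  locus_id <- if (!is.null(locus$locus_id)) locus$locus_id else NA_character_
  rows <- purrr::map(gene_ids, function(g) {
    cv <- coding_variants$has_coding_variant[match(g, coding_variants$gene_id)]
    cv <- isTRUE(cv)
    cis_p <- cis_eqtl_min_p(g, cis_results, locus, flank)
    tc <- trait_cors[trait_cors$gene == g & !is.na(trait_cors$p), , drop = FALSE]
    if (nrow(tc)) {
      i <- which.min(tc$p)
      bt <- tc$trait[i]; br <- tc$r[i]; bp <- tc$p[i]
    } else {
      bt <- NA_character_; br <- NA_real_; bp <- NA_real_
    }
    score <- cv + (!is.na(cis_p) && cis_p < cis_alpha) +
      (!is.na(bp) && bp < trait_alpha)
    tibble(gene_id = g, locus_id = locus_id, has_coding_variant = cv,
           cis_min_p = cis_p, best_trait = bt, best_trait_r = br,
           best_trait_p = bp, score = as.integer(score))
  })
  bind_rows(rows) %>%
    arrange(desc(.data$score), ifelse(is.na(.data$cis_min_p), Inf, .data$cis_min_p),
            .data$gene_id)
}

#' Pathway correlation permutation test
#'
#' Statistic: mean absolute Pearson correlation between a target gene's
#' expression and each pathway member. Null: random gene sets of the same
#' size drawn without replacement from all scanned genes (target excluded).
#' The p-value uses the add-one rule, `p = (1 + #{null >= observed}) /
#' (n_perm + 1)`, so it is bounded below by `1/(n_perm + 1)` and the test is
#' bit-reproducible under a fixed seed.
#'
#' @param target Target gene id (excluded from random draws and from its own
#'   pathway).
#' @param pathway Character vector of pathway gene ids present in `expr`.
#' @param expr An [expression_matrix()].
#' @param n_perm Number of permutations (>= 100; the reference analysis in
#'   the field uses 1e6).
#' @param seed Random seed (required).
#' @return A one-row `pathway_test` tibble: `target, n_pathway, observed,
#'   p, n_perm, seed`.
#' @export
pathway_permutation_test <- function(target, pathway, expr, n_perm = 10000,
                                     seed = 1) {
  if (n_perm < 100) stop_input("pathway permutation test needs n_perm >= 100")
  genes <- expr$genes$gene_id
  if (!target %in% genes) stop_input(sprintf("target gene '%s' not in expression matrix", target))
  pathway <- setdiff(unique(pathway), target)
  missing <- setdiff(pathway, genes)
  if (length(missing)) {
    stop_input(sprintf("pathway gene(s) not in expression matrix: %s",
                       paste(head(missing, 5), collapse = ", ")))
  }
  universe <- setdiff(genes, target)
  k <- length(pathway)
  if (k < 1) stop_input("pathway has no genes besides the target")
  if (k > length(universe)) stop_input("pathway is larger than the gene universe")
  y <- expr$values[, target]
  absr <- abs(suppressWarnings(cor(y, expr$values[, universe, drop = FALSE],
                                   use = "pairwise.complete.obs")))[1, ]
  names(absr) <- universe
  observed <- mean(absr[pathway], na.rm = TRUE)
  keep <- !is.na(absr)                 # zero-variance genes leave the universe
  universe <- universe[keep]
  absr <- absr[keep]
  if (k > length(universe)) stop_input("pathway is larger than the usable gene universe")
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  m <- length(universe)
  ge <- 0L
  for (b in seq_len(n_perm)) {
    stat <- mean(absr[sample.int(m, k)])
    if (stat >= observed) ge <- ge + 1L
  }
  out <- tibble(target = target, n_pathway = k, observed = observed,
                p = (1 + ge) / (n_perm + 1), n_perm = n_perm, seed = seed)
  class(out) <- c("pathway_test", class(out))
  out
}

#' @export
glance.pathway_test <- function(x, ...) tibble::as_tibble(x)
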