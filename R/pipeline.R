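# End-to-end orchestration: filters -> scans -> hotspots -> merge ->
# overlap -> candidates, with a reproducibility manifest.

#' Pipeline configuration
#'
#' @param input_dir Directory holding the standard-format input files (the
#'   layout written by [write_panel()]): `genotypes.tsv`,
#'   `expression_control.tsv`, `expression_treated.tsv`, `meth_counts.tsv`,
#'   `total_counts.tsv`, `phenotypes.tsv`, optionally `prior_loci.bed`.
#' @param out_dir Output directory.
#' @param genome A [genome_spec()].
#' @param conditions Conditions to scan (subset of control/treated/delta).
#' @param classes QTL classes to run (`"eQTL"` always; `"mQTL"` and
#'   `"emQTL"` optional — emQTL scans honour `emqtl_max_pairs`).
#' @param window_size,genomewide,suggestive_factor,bonferroni,mean_min,
#'   cv_min,maf_min,min_reads,shift_min,strain_frac Stage thresholds; the
#'   defaults are the reference analysis values (4.2e-6 genome-wide, x10
#'   suggestive, 9.3e-6 Bonferroni over 5400 windows of 500 kb, mean > 5,
#'   CV > 10%, MAF >= 5%, depth > 3, 25-point shifts in >= 5% of strains).
#' @param null_method Hotspot tail method (see [call_hotspots()]).
#' @param emqtl_max_pairs Budget for the emQTL pair set (pairs are chosen as
#'   the full grid when it fits, otherwise an error asks for an explicit
#'   pair list).
#' @param n_perm_overlap Permutations for the prior-locus overlap test.
#' @param seed Seed for every stochastic stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input_dir, out_dir,
                            genome = genome_spec(paste0("chr", 1:3), rep(5e7, 3)),
                            conditions = "delta", classes = "eQTL",
                            window_size = 5e5, genomewide = 4.2e-6,
                            suggestive_factor = 10, bonferroni = 9.3e-6,
                            mean_min = 5, cv_min = 0.10, maf_min = 0.05,
                            min_reads = 4, shift_min = 25, strain_frac = 0.05,
                            null_method = "poisson", emqtl_max_pairs = 20000,
                            n_perm_overlap = 1000, seed = 1) {
  classes <- match.arg(classes, QTL_CLASSES, several.ok = TRUE)
  conditions <- match.arg(conditions, CONDITIONS, several.ok = TRUE)
  structure(list(input_dir = input_dir, out_dir = out_dir, genome = genome,
                 conditions = conditions, classes = classes,
                 window_size = window_size, genomewide = genomewide,
                 suggestive_factor = suggestive_factor, bonferroni = bonferroni,
                 mean_min = mean_min, cv_min = cv_min, maf_min = maf_min,
                 min_reads = min_reads, shift_min = shift_min,
                 strain_frac = strain_frac, null_method = null_method,
                 emqtl_max_pairs = emqtl_max_pairs,
                 n_perm_overlap = n_perm_overlap, seed = seed),
            class = "pipeline_config")
}

pipeline_input <- function(cfg, name, required = TRUE) {
  p <- file.path(cfg$input_dir, name)
  if (!file.exists(p)) {
    if (required) stop_input(sprintf("missing pipeline input: %s", p))
    return(NULL)
  }
  p
}

#' Run the full hotspot pipeline
#'
#' Executes filters, the configured association scans, hotspot calling,
#' locus merging, and (when a prior locus BED is present) overlap
#' enrichment; writes every stage's table plus `manifest.json` with
#' checksums and the exact parameter set. Deterministic given the seed:
#' re-running with the same config yields identical checksums.
#'
#' @param cfg A [pipeline_config()].
#' @return Invisibly, the manifest as a list.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  inform(sprintf("[hotspotqtl] pipeline start (seed %d, conditions: %s, classes: %s)",
                 cfg$seed, paste(cfg$conditions, collapse = ","),
                 paste(cfg$classes, collapse = ",")))

  geno <- read_genotypes(pipeline_input(cfg, "genotypes.tsv"))
  expr_c <- read_expression(pipeline_input(cfg, "expression_control.tsv"), "control")
  expr_t <- read_expression(pipeline_input(cfg, "expression_treated.tsv"), "treated")
  need_meth <- any(c("mQTL", "emQTL") %in% cfg$classes)
  meth <- if (need_meth) {
    read_methylation(pipeline_input(cfg, "meth_counts.tsv"),
                     pipeline_input(cfg, "total_counts.tsv"))
  } else NULL

  objs <- c(list(geno, expr_c, expr_t), if (need_meth) list(meth))
  objs <- align_strains(objs)
  geno <- objs[[1]]; expr_c <- objs[[2]]; expr_t <- objs[[3]]
  if (need_meth) meth <- objs[[4]]

  # filters -------------------------------------------------------------
  snp_filter <- filter_snps_maf(geno, cfg$maf_min)
  geno_f <- genotype_matrix(geno$codes[, snp_filter$keep, drop = FALSE],
                            geno$snps[match(snp_filter$keep, geno$snps$snp_id), ])
  fg_c <- filter_genes(expr_c, cfg$mean_min, cfg$cv_min)
  fg_t <- filter_genes(expr_t, cfg$mean_min, cfg$cv_min)
  genes_union <- union(fg_c$keep, fg_t$keep)     # expressed+varying in either condition
  keep_expr <- function(e) {
    ids <- e$genes$gene_id[e$genes$gene_id %in% genes_union]
    expression_matrix(e$values[, ids, drop = FALSE],
                      e$genes[match(ids, e$genes$gene_id), ], e$condition)
  }
  expr_c <- keep_expr(expr_c); expr_t <- keep_expr(expr_t)

  out_files <- character(0)
  save_tbl <- function(tbl, name, params = NULL) {
    p <- file.path(cfg$out_dir, name)
    write_tsv_with_header(tbl, p, params)
    out_files <<- c(out_files, p)
    p
  }
  save_tbl(tibble::as_tibble(snp_filter$report), "filter_snps.tsv")
  save_tbl(tibble::as_tibble(fg_c$report), "filter_genes_control.tsv")
  save_tbl(tibble::as_tibble(fg_t$report), "filter_genes_treated.tsv")

  if (need_meth) {
    meth <- filter_depth(meth, cfg$min_reads)
    meth <- mask_snp_overlapped_cpgs(meth, geno_f)
    hv <- filter_hypervariable_cpgs(meth, cfg$shift_min, cfg$strain_frac)
    meth <- methylation_counts(meth$meth[, hv$keep, drop = FALSE],
                               meth$total[, hv$keep, drop = FALSE],
                               meth$cpgs[match(hv$keep, meth$cpgs$cpg_id), ])
    save_tbl(tibble::as_tibble(hv$report), "filter_cpgs.tsv")
  }

  if (ncol(geno_f$codes) < 1) stop_invariant("no SNP survives the MAF filter")
  if (ncol(expr_c$values) < 1) stop_invariant("no gene survives the expression filters")

  K <- compute_kinship(geno_f)
  windows <- make_windows(cfg$genome, cfg$window_size)
  suggestive <- suggestive_threshold(cfg$genomewide, cfg$suggestive_factor)

  trait_sets <- list()
  if ("control" %in% cfg$conditions) trait_sets$control <- expr_c
  if ("treated" %in% cfg$conditions) trait_sets$treated <- expr_t
  if ("delta" %in% cfg$conditions) trait_sets$delta <- delta_traits(expr_c, expr_t)

  manifest_results <- list()
  for (cond in names(trait_sets)) {
    for (cls in cfg$classes) {
      traits <- switch(cls,
        eQTL = trait_sets[[cond]],
        mQTL = methylation_to_traits(meth),
        emQTL = NULL)
      tag <- sprintf("%s_%s", cond, cls)
      inform(sprintf("[hotspotqtl] scan %s", tag))
      res <- if (cls == "emQTL") {
        n_pairs <- ncol(trait_sets[[cond]]$values) * ncol(meth$meth)
        if (n_pairs > cfg$emqtl_max_pairs) {
          stop_input(sprintf(
            "emQTL pair set (%d) exceeds the configured budget (%d); supply a pair list or raise emqtl_max_pairs",
            n_pairs, cfg$emqtl_max_pairs))
        }
        emqtl_scan(meth, trait_sets[[cond]], K, condition = cond)
      } else {
        assoc_scan(traits, geno_f, K, class = cls, condition = cond)
      }
      total_feat <- length(unique(res$feature))
      minp <- window_min_p(res, windows)
      hs <- call_hotspots(minp, suggestive = suggestive,
                          bonferroni = cfg$bonferroni,
                          null_method = cfg$null_method, seed = cfg$seed)
      prefix <- sprintf("%s_%s", tools::toTitleCase(cond), cls)
      loci <- merge_loci(hs, total_feat, prefix = prefix)
      save_tbl(res[!is.na(res$p) & res$p < 1e-3, , drop = FALSE],
               sprintf("assoc_%s.tsv", tag), list(max_p = 1e-3))
      hs_out <- file.path(cfg$out_dir, sprintf("hotspots_%s.bed", tag))
      write_hotspots_bed(hs[hs$significant, , drop = FALSE], hs_out)
      out_files <- c(out_files, hs_out)
      save_tbl(loci %>% mutate(features = map_chr(.data$features, paste, collapse = ","),
                               windows = map_chr(.data$windows, paste, collapse = ",")),
               sprintf("loci_%s.tsv", tag))
      manifest_results[[tag]] <- list(
        n_tests = nrow(res), n_features = total_feat,
        n_significant_windows = sum(hs$significant), n_loci = nrow(loci),
        max_pct_regulated = if (nrow(loci)) max(loci$pct_regulated) else 0)
    }
  }

  prior_path <- pipeline_input(cfg, "prior_loci.bed", required = FALSE)
  overlap <- NULL
  if (!is.null(prior_path)) {
    prior <- read_loci(prior_path, cfg$genome)
    all_loci <- bind_rows(lapply(names(trait_sets), function(cond) {
      lapply(cfg$classes, function(cls) {
        p <- file.path(cfg$out_dir, sprintf("loci_%s_%s.tsv", cond, cls))
        if (file.exists(p)) read_tsv_plain(p) else NULL
      }) %>% bind_rows()
    }))
    if (nrow(all_loci)) {
      overlap <- overlap_enrichment(all_loci, prior, cfg$genome,
                                    n_perm = cfg$n_perm_overlap, seed = cfg$seed)
      save_tbl(tibble::as_tibble(overlap), "overlap_enrichment.tsv")
    }
  }

  manifest <- list(
    package_version = pkg_version_string(),
    seed = cfg$seed,
    parameters = unclass(cfg)[setdiff(names(cfg), c("genome"))],
    genome = as.list(setNames(cfg$genome$length, cfg$genome$chrom)),
    results = manifest_results,
    overlap = if (!is.null(overlap)) as.list(tibble::as_tibble(overlap)),
    files = lapply(setNames(nm = basename(out_files)), function(b)
      unname(tools::md5sum(file.path(cfg$out_dir, b))))
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  inform("[hotspotqtl] pipeline done")
  invisible(manifest)
}
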