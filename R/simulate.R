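# Synthetic inbred-panel generator with known ground truth.
#
# Emulates the statistical structure the analysis assumes: a panel of fully
# inbred strains genotyped at SNPs with haplotype-block LD (founder mosaics
# with family structure, which automatically induces a non-trivial kinship),
# log-scale expression for control and treated conditions with planted cis
# effects, trans hotspots, a kinship-structured polygenic background and
# per-gene treatment shifts, beta-binomial RRBS-style CpG counts with planted
# cis mQTLs and a latent-factor emQTL hotspot, and phenotypes driven by a
# configured gene at a configured correlation.

#' Simulation configuration
#'
#' Defaults describe a 96-strain panel on 3 x 50 Mb chromosomes with 5000
#' SNPs in 2 Mb LD blocks, 1000 genes whose mean/CV straddle the expression
#' filters, and 10000 CpGs with negative-binomial depth (mean 20) and
#' beta-binomial overdispersion rho = 0.05.
#'
#' @param n_strains Number of fully inbred strains.
#' @param genome A [genome_spec()].
#' @param n_snps Total SNP count (spread across chromosomes by length).
#' @param ld_block_bp LD block length: SNPs within a block share one founder
#'   partition of the strains.
#' @param n_founders Founder haplotypes per block (allele-frequency
#'   granularity of the panel).
#' @param n_clusters Strain families; mosaic assignments are correlated
#'   within a family, inducing kinship structure.
#' @param cluster_fidelity Probability a strain inherits its family's
#'   founder in a block (vs a random founder).
#' @param maf_range Targeted minor-allele-frequency range.
#' @param n_genes Gene count. A fraction `gene_fail_frac` is designed to
#'   fail the expression filters (half by low mean, half by low CV); the
#'   rest draw mean from `gene_mean_range` and CV from `gene_cv_range`.
#' @param gene_fail_frac,gene_mean_range,gene_cv_range See `n_genes`.
#' @param h2_bg Polygenic background heritability of expression (shared
#'   strain-level genetic effect across conditions).
#' @param cis_frac Fraction of filter-passing genes given a cis eQTL at
#'   their nearest SNP.
#' @param cis_effect Cis allele effect in units of the gene's residual sd.
#' @param treatment_shift_sd SD of the per-gene strain-independent treatment
#'   shift (gene-sd units).
#' @param trans_hotspots Tibble of planted trans-eQTL hotspots: columns
#'   `chrom, pos, n_targets, effect, condition` (`effect` in gene-sd units
#'   per standardized allele; `condition = "delta"` plants the effect in the
#'   treated condition only so the contrast carries it).
#' @param n_cpgs CpG count.
#' @param depth_mean,depth_size Negative-binomial read-depth parameters.
#' @param bb_rho Beta-binomial overdispersion (makes the independent residual
#'   term of the binomial mixed model identifiable).
#' @param hyper_frac Fraction of CpGs designed hypervariable (a strain
#'   subset shifted on the logit scale); the rest sit near 0 or 1.
#' @param hyper_shift Logit shift of the affected strains.
#' @param hyper_strain_frac_range Range of the affected-strain fraction.
#' @param cis_mqtl_frac Fraction of hypervariable CpGs whose affected
#'   strains are the minor-allele carriers of the nearest SNP (planted cis
#'   mQTLs).
#' @param emqtl_hotspots Tibble of planted emQTL hotspots: `chrom, pos,
#'   n_cpgs, n_target_genes, cpg_loading, gene_loading` — a latent strain
#'   factor loads on a window of CpGs (logit scale) and on target genes
#'   (gene-sd units).
#' @param pathway_size,pathway_loading Planted correlated pathway: a latent
#'   factor shared by one target gene and `pathway_size` member genes.
#' @param pheno_cor Correlation between the phenotype driver gene's control
#'   expression and the `heart_weight`-like trait.
#' @param seed Random seed recorded in every output.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_strains = 96,
                       genome = genome_spec(paste0("chr", 1:3), rep(5e7, 3)),
                       n_snps = 5000, ld_block_bp = 2e6, n_founders = 16,
                       n_clusters = 6, cluster_fidelity = 0.7,
                       maf_range = c(0.05, 0.5),
                       n_genes = 1000, gene_fail_frac = 0.2,
                       gene_mean_range = c(6.5, 11), gene_cv_range = c(0.15, 0.35),
                       h2_bg = 0.3, cis_frac = 0.3, cis_effect = 1.0,
                       treatment_shift_sd = 0.5,
                       trans_hotspots = tibble(chrom = "chr2", pos = 25250000,
                                               n_targets = 100, effect = 1.5,
                                               condition = "delta"),
                       n_cpgs = 10000, depth_mean = 20, depth_size = 5,
                       bb_rho = 0.05, hyper_frac = 0.3, hyper_shift = 4.4,
                       hyper_strain_frac_range = c(0.08, 0.5),
                       cis_mqtl_frac = 0.3,
                       emqtl_hotspots = tibble(chrom = "chr3", pos = 10250000,
                                               n_cpgs = 5, n_target_genes = 40,
                                               cpg_loading = 2.5, gene_loading = 0.8),
                       pathway_size = 60, pathway_loading = 0.5,
                       pheno_cor = 0.6, seed = 1) {
  cfg <- list(n_strains = n_strains, genome = genome, n_snps = n_snps,
              ld_block_bp = ld_block_bp, n_founders = n_founders,
              n_clusters = n_clusters, cluster_fidelity = cluster_fidelity,
              maf_range = maf_range, n_genes = n_genes,
              gene_fail_frac = gene_fail_frac, gene_mean_range = gene_mean_range,
              gene_cv_range = gene_cv_range, h2_bg = h2_bg, cis_frac = cis_frac,
              cis_effect = cis_effect, treatment_shift_sd = treatment_shift_sd,
              trans_hotspots = tibble::as_tibble(trans_hotspots),
              n_cpgs = n_cpgs, depth_mean = depth_mean, depth_size = depth_size,
              bb_rho = bb_rho, hyper_frac = hyper_frac, hyper_shift = hyper_shift,
              hyper_strain_frac_range = hyper_strain_frac_range,
              cis_mqtl_frac = cis_mqtl_frac,
              emqtl_hotspots = tibble::as_tibble(emqtl_hotspots),
              pathway_size = pathway_size, pathway_loading = pathway_loading,
              pheno_cor = pheno_cor, seed = seed)
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  counts <- c(cfg$n_strains, cfg$n_snps, cfg$n_genes, cfg$n_cpgs,
              cfg$n_founders, cfg$n_clusters)
  if (any(counts <= 0)) stop_input("all counts in the simulation config must be positive")
  fracs <- c(cfg$cluster_fidelity, cfg$gene_fail_frac, cfg$h2_bg, cfg$cis_frac,
             cfg$hyper_frac, cfg$cis_mqtl_frac, cfg$bb_rho)
  if (any(fracs < 0 | fracs > 1)) stop_input("fractions in the simulation config must lie in [0, 1]")
  if (cfg$maf_range[1] <= 0 || cfg$maf_range[2] > 0.5) {
    stop_input("maf_range must lie in (0, 0.5]")
  }
  if (abs(cfg$pheno_cor) > 1) stop_input("pheno_cor must lie in [-1, 1]")
  if (nrow(cfg$trans_hotspots) &&
      any(cfg$trans_hotspots$n_targets > cfg$n_genes)) {
    stop_input("a trans hotspot has more targets than there are genes")
  }
  if (cfg$pathway_size >= cfg$n_genes) stop_input("pathway larger than the gene set")
  structure(cfg, class = "sim_config")
}

#' Demo configuration for the end-to-end pipeline
#'
#' A panel sized to run the full pipeline in minutes on one CPU: 96 strains,
#' 3 x 50 Mb chromosomes, 2000 SNPs, 1000 genes, 2000 CpGs; one planted
#' trans hotspot whose master SNP regulates 10% of the genes in the delta
#' condition, one emQTL hotspot, and one planted correlated pathway.
#'
#' @param seed Random seed.
#' @param null If `TRUE`, remove every planted effect (global-null panel for
#'   calibration runs).
#' @return A `sim_config`.
#' @export
default_demo_config <- function(seed = 1, null = FALSE) {
  cfg <- sim_config(
    n_strains = 96, n_snps = 2000, n_genes = 1000, n_cpgs = 2000,
    trans_hotspots = tibble(chrom = "chr2", pos = 25250000, n_targets = 100,
                            effect = 1.5, condition = "delta"),
    emqtl_hotspots = tibble(chrom = "chr3", pos = 10250000, n_cpgs = 5,
                            n_target_genes = 40, cpg_loading = 2.5,
                            gene_loading = 0.8),
    seed = seed)
  if (null) {
    cfg$trans_hotspots <- cfg$trans_hotspots[0, ]
    cfg$emqtl_hotspots <- cfg$emqtl_hotspots[0, ]
    cfg$cis_frac <- 0
    cfg$cis_mqtl_frac <- 0
    cfg$pathway_loading <- 0
    cfg$pheno_cor <- 0
  }
  validate_sim_config(unclass(cfg))
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("<sim_config> %d strains, %d SNPs, %d genes, %d CpGs on %d chromosome(s); ",
                     "%d trans hotspot(s), %d emQTL hotspot(s); seed %d\n"),
              x$n_strains, x$n_snps, x$n_genes, x$n_cpgs, nrow(x$genome),
              nrow(x$trans_hotspots), nrow(x$emqtl_hotspots), x$seed))
  invisible(x)
}

# founder-mosaic inbred genotypes with block LD and family structure -------
simulate_genotypes <- function(cfg) {
  n <- cfg$n_strains
  strains <- sprintf("S%03d", seq_len(n))
  clusters <- sample(rep_len(seq_len(cfg$n_clusters), n))
  per_chrom <- pmax(1, round(cfg$n_snps * cfg$genome$length / sum(cfg$genome$length)))
  snps <- purrr::pmap(list(cfg$genome$chrom, cfg$genome$length, per_chrom),
                      function(ch, len, k) {
                        tibble(chrom = ch, pos = sort(sample.int(len, k)))
                      }) %>% bind_rows()
  snps$snp_id <- sprintf("snp%05d", seq_len(nrow(snps)))
  snps <- snps[, c("snp_id", "chrom", "pos")]
  codes <- matrix(0, n, nrow(snps), dimnames = list(strains, snps$snp_id))

  lo <- cfg$maf_range[1]; hi <- cfg$maf_range[2]
  block_of <- paste(snps$chrom, (snps$pos - 1) %/% cfg$ld_block_bp)
  for (b in unique(block_of)) {
    cols <- which(block_of == b)
    founder_of_cluster <- sample.int(cfg$n_founders, cfg$n_clusters, replace = TRUE)
    inherit <- runif(n) < cfg$cluster_fidelity
    founder <- ifelse(inherit, founder_of_cluster[clusters],
                      sample.int(cfg$n_founders, n, replace = TRUE))
    usage <- tabulate(founder, cfg$n_founders) / n
    for (j in cols) {
      target <- runif(1, lo, hi)
      ord <- sample.int(cfg$n_founders)
      cum <- cumsum(usage[ord])
      feasible <- which(cum >= lo - 1e-9 & cum <= hi + 0.07)
      k <- if (length(feasible)) {
        feasible[which.min(abs(cum[feasible] - target))]
      } else {
        which.min(abs(cum - target))
      }
      minor <- ord[seq_len(k)]
      codes[, j] <- as.numeric(founder %in% minor)
    }
  }
  list(geno = genotype_matrix(codes, snps), clusters = clusters)
}

nearest_snp <- function(chrom, pos, snps) {
  sel <- which(snps$chrom == chrom)
  if (!length(sel)) return(NA_integer_)
  sel[which.min(abs(snps$pos[sel] - pos))]
}

# MVN(0, K) draws via one Cholesky of the (jittered) kinship
kinship_draws <- function(K, m) {
  R <- chol(unclass(K) + diag(1e-8, nrow(K)))
  crossprod(R, matrix(rnorm(nrow(K) * m), nrow(K), m))
}

#' Simulate a full multi-omic panel
#'
#' @param config A [sim_config()].
#' @return A list with elements `geno` ([genotype_matrix()]), `expr_control`
#'   and `expr_treated` ([expression_matrix()]), `meth`
#'   ([methylation_counts()]), `pheno` ([phenotype_table()]), and `truth`
#'   (a `synthetic_truth` list recording every planted effect and the
#'   expected filter outcomes). Deterministic given `config$seed`.
#' @export
simulate_panel <- function(config) {
  cfg <- validate_sim_config(unclass(config))
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(cfg$seed)

  gsim <- simulate_genotypes(cfg)
  geno <- gsim$geno
  n <- cfg$n_strains
  strains <- strain_ids(geno)
  K <- compute_kinship(geno)
  std_geno <- function(j) {
    x <- geno$codes[, j]
    if (sd(x) == 0) return(rep(0, length(x)))
    drop(scale(x))
  }

  # ---- genes ---------------------------------------------------------------
  ng <- cfg$n_genes
  gene_pos <- tibble(
    gene_id = sprintf("gene%04d", seq_len(ng)),
    chrom = sample(cfg$genome$chrom, ng, replace = TRUE,
                   prob = cfg$genome$length / sum(cfg$genome$length)),
    pos = NA_real_)
  gene_pos$pos <- vapply(gene_pos$chrom, function(ch)
    sample.int(cfg$genome$length[match(ch, cfg$genome$chrom)], 1), numeric(1))

  n_fail <- round(cfg$gene_fail_frac * ng)
  fail_idx <- sample.int(ng, n_fail)
  fail_low_mean <- fail_idx[seq_len(floor(n_fail / 2))]
  fail_low_cv <- setdiff(fail_idx, fail_low_mean)
  pass_idx <- setdiff(seq_len(ng), fail_idx)

  mu_g <- runif(ng, cfg$gene_mean_range[1], cfg$gene_mean_range[2])
  cv_g <- runif(ng, cfg$gene_cv_range[1], cfg$gene_cv_range[2])
  mu_g[fail_low_mean] <- runif(length(fail_low_mean), 2, 4)
  cv_g[fail_low_cv] <- runif(length(fail_low_cv), 0.02, 0.06)
  sd_g <- cv_g * mu_g

  # planted structure lives only in filter-passing genes
  cis_genes <- sample(pass_idx, round(cfg$cis_frac * length(pass_idx)))
  cis_snp <- vapply(cis_genes, function(i)
    nearest_snp(gene_pos$chrom[i], gene_pos$pos[i], geno$snps), integer(1))

  hotspot_truth <- list()
  remaining <- setdiff(pass_idx, integer(0))
  trans_targets <- list()
  if (nrow(cfg$trans_hotspots)) {
    for (hh in seq_len(nrow(cfg$trans_hotspots))) {
      h <- cfg$trans_hotspots[hh, ]
      cand <- which(geno$snps$chrom == h$chrom)
      maf <- pmin(colMeans(geno$codes), 1 - colMeans(geno$codes))
      good <- cand[maf[cand] >= 0.2]
      if (!length(good)) good <- cand
      master <- good[which.min(abs(geno$snps$pos[good] - h$pos))]
      targets <- sample(remaining, h$n_targets)
      remaining <- setdiff(remaining, targets)
      trans_targets[[hh]] <- list(master = master, targets = targets,
                                  effect = h$effect, condition = h$condition)
      hotspot_truth[[hh]] <- tibble(
        type = "trans-hotspot",
        snp_id = geno$snps$snp_id[master],
        chrom = geno$snps$chrom[master], pos = geno$snps$pos[master],
        condition = h$condition, effect = h$effect,
        targets = list(gene_pos$gene_id[targets]))
    }
  }

  # latent factors: planted pathway and emQTL hotspots
  f_path <- rnorm(n)
  path_target <- sample(setdiff(pass_idx, unlist(lapply(trans_targets, `[[`, "targets"))), 1)
  path_members <- sample(setdiff(pass_idx, path_target), cfg$pathway_size)

  em_truth <- list(); em_factors <- list()
  em_gene_load <- matrix(0, n, ng)
  if (nrow(cfg$emqtl_hotspots)) {
    for (hh in seq_len(nrow(cfg$emqtl_hotspots))) {
      h <- cfg$emqtl_hotspots[hh, ]
      f <- rnorm(n)
      tg <- sample(setdiff(pass_idx, path_target), h$n_target_genes)
      em_gene_load[, tg] <- em_gene_load[, tg] + h$gene_loading * f
      em_factors[[hh]] <- list(f = f, cfg = h, target_genes = tg)
    }
  }

  u_bg <- kinship_draws(K, ng) * sqrt(cfg$h2_bg)     # polygenic, shared by conditions
  e_sd <- sqrt(1 - cfg$h2_bg)
  z_control <- u_bg + matrix(rnorm(n * ng, sd = e_sd), n, ng)
  z_treated <- u_bg + matrix(rnorm(n * ng, sd = e_sd), n, ng)
  for (i in seq_along(cis_genes)) {
    x <- std_geno(cis_snp[i])
    z_control[, cis_genes[i]] <- z_control[, cis_genes[i]] + cfg$cis_effect * x
    z_treated[, cis_genes[i]] <- z_treated[, cis_genes[i]] + cfg$cis_effect * x
  }
  for (tt in trans_targets) {
    x <- std_geno(tt$master)
    sel <- tt$targets
    if (tt$condition == "control") {
      z_control[, sel] <- z_control[, sel] + tt$effect * x
    } else if (tt$condition == "treated") {
      z_treated[, sel] <- z_treated[, sel] + tt$effect * x
    } else {                                   # delta: treated only
      z_treated[, sel] <- z_treated[, sel] + tt$effect * x
    }
  }
  z_control[, c(path_target, path_members)] <-
    z_control[, c(path_target, path_members)] + cfg$pathway_loading * f_path
  z_treated[, c(path_target, path_members)] <-
    z_treated[, c(path_target, path_members)] + cfg$pathway_loading * f_path
  z_control <- z_control + em_gene_load
  z_treated <- z_treated + em_gene_load

  tau <- rnorm(ng, sd = cfg$treatment_shift_sd)      # strain-independent shift
  vals_control <- sweep(sweep(z_control, 2, sd_g, "*"), 2, mu_g, "+")
  vals_treated <- sweep(sweep(z_treated + rep(1, n) %o% tau, 2, sd_g, "*"), 2, mu_g, "+")
  dimnames(vals_control) <- dimnames(vals_treated) <- list(strains, gene_pos$gene_id)
  expr_control <- expression_matrix(vals_control, gene_pos, "control")
  expr_treated <- expression_matrix(vals_treated, gene_pos, "treated")

  # ---- CpGs ----------------------------------------------------------------
  nc <- cfg$n_cpgs
  cpg_pos <- tibble(
    cpg_id = sprintf("cpg%05d", seq_len(nc)),
    chrom = sample(cfg$genome$chrom, nc, replace = TRUE,
                   prob = cfg$genome$length / sum(cfg$genome$length)),
    pos = NA_real_)
  cpg_pos$pos <- vapply(cpg_pos$chrom, function(ch)
    sample.int(cfg$genome$length[match(ch, cfg$genome$chrom)], 1), numeric(1))

  n_hyper <- round(cfg$hyper_frac * nc)
  hyper_idx <- sample.int(nc, n_hyper)
  # non-hypervariable CpGs sit near fully (un)methylated, as RRBS islands do;
  # this keeps beta-binomial noise well inside the 25-point hypervariability band
  base_logit <- sample(c(-1, 1), nc, replace = TRUE) * 4.6 + rnorm(nc, sd = 0.3)
  eta_m <- matrix(rep(base_logit, each = n), n, nc)
  hyper_start_low <- runif(n_hyper) < 0.5
  eta_m[, hyper_idx] <- rep(1, n) %o% (ifelse(hyper_start_low, -1, 1) * 2.2 + rnorm(n_hyper, sd = 0.2))

  n_cis_m <- round(cfg$cis_mqtl_frac * n_hyper)
  cis_m_idx <- if (n_cis_m) hyper_idx[seq_len(n_cis_m)] else integer(0)
  rand_hyper_idx <- setdiff(hyper_idx, cis_m_idx)
  cis_mqtl <- tibble(cpg_id = character(), snp_id = character())
  for (j in cis_m_idx) {
    sj <- nearest_snp(cpg_pos$chrom[j], cpg_pos$pos[j], geno$snps)
    x <- geno$codes[, sj]
    f <- mean(x)
    carriers <- if (f <= 0.5) x == 1 else x == 0
    dir <- if (eta_m[1, j] < 0) 1 else -1
    eta_m[carriers, j] <- eta_m[carriers, j] + dir * cfg$hyper_shift
    cis_mqtl <- bind_rows(cis_mqtl, tibble(cpg_id = cpg_pos$cpg_id[j],
                                           snp_id = geno$snps$snp_id[sj]))
  }
  for (j in rand_hyper_idx) {
    frac <- runif(1, cfg$hyper_strain_frac_range[1], cfg$hyper_strain_frac_range[2])
    shifted <- sample.int(n, max(2, round(frac * n)))
    dir <- if (eta_m[1, j] < 0) 1 else -1
    eta_m[shifted, j] <- eta_m[shifted, j] + dir * cfg$hyper_shift
  }

  em_cpgs <- list()
  if (length(em_factors)) {
    for (hh in seq_along(em_factors)) {
      emh <- em_factors[[hh]]
      h <- emh$cfg
      # place the hotspot CpGs inside one 500 kb window and make them
      # hypervariable by the latent factor
      w0 <- ((h$pos - 1) %/% 5e5) * 5e5
      newpos <- w0 + sort(sample.int(5e5 - 2, h$n_cpgs))
      sel <- sample(rand_hyper_idx, h$n_cpgs)
      rand_hyper_idx <- setdiff(rand_hyper_idx, sel)
      cpg_pos$chrom[sel] <- h$chrom
      cpg_pos$pos[sel] <- newpos
      eta_m[, sel] <- rep(1, n) %o% rnorm(h$n_cpgs, sd = 0.2) + h$cpg_loading * emh$f
      em_cpgs[[hh]] <- tibble(type = "emQTL-hotspot", chrom = h$chrom,
                              window_start = w0, window_end = w0 + 5e5,
                              cpgs = list(cpg_pos$cpg_id[sel]),
                              targets = list(gene_pos$gene_id[emh$target_genes]),
                              cpg_loading = h$cpg_loading,
                              gene_loading = h$gene_loading)
    }
  }

  total <- matrix(rnbinom(n * nc, mu = cfg$depth_mean, size = cfg$depth_size), n, nc)
  pi_m <- 1 / (1 + exp(-eta_m))
  if (cfg$bb_rho > 0) {
    shape <- 1 / cfg$bb_rho - 1
    pdraw <- matrix(rbeta(n * nc, pi_m * shape, (1 - pi_m) * shape), n, nc)
  } else {
    pdraw <- pi_m
  }
  meth_counts <- matrix(rbinom(n * nc, total, pdraw), n, nc)
  dimnames(total) <- dimnames(meth_counts) <- list(strains, cpg_pos$cpg_id)
  meth <- methylation_counts(meth_counts, total, cpg_pos)

  # ---- phenotypes ----------------------------------------------------------
  driver <- path_target
  zc <- drop(scale(vals_control[, driver]))
  r <- cfg$pheno_cor
  pheno <- phenotype_table(tibble(
    strain = strains,
    heart_weight = 100 + 15 * (r * zc + sqrt(max(1 - r^2, 0)) * rnorm(n)),
    adrenal_weight = rnorm(n, 5, 1)))

  truth <- structure(list(
    seed = cfg$seed,
    trans_hotspots = if (length(hotspot_truth)) bind_rows(hotspot_truth) else tibble(),
    cis_eqtl = tibble(gene_id = gene_pos$gene_id[cis_genes],
                      snp_id = geno$snps$snp_id[cis_snp],
                      effect = cfg$cis_effect),
    cis_mqtl = cis_mqtl,
    emqtl_hotspots = if (length(em_cpgs)) bind_rows(em_cpgs) else tibble(),
    pathway = list(target = gene_pos$gene_id[path_target],
                   members = gene_pos$gene_id[path_members],
                   loading = cfg$pathway_loading),
    phenotype_driver = list(gene = gene_pos$gene_id[driver],
                            trait = "heart_weight", target_cor = cfg$pheno_cor),
    expected_gene_pass_control = gene_pos$gene_id[pass_idx],
    expected_hyper_cpgs = cpg_pos$cpg_id[sort(hyper_idx)]
  ), class = "synthetic_truth")

  list(geno = geno, expr_control = expr_control, expr_treated = expr_treated,
       meth = meth, pheno = pheno, truth = truth)
}

#' Write a simulated panel to a directory
#'
#' Emits the standard-format files (genotype/expression/methylation/phenotype
#' TSVs) plus `truth.json`.
#'
#' @param panel Output of [simulate_panel()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
write_panel <- function(panel, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    genotypes = file.path(dir, "genotypes.tsv"),
    expression_control = file.path(dir, "expression_control.tsv"),
    expression_treated = file.path(dir, "expression_treated.tsv"),
    meth = file.path(dir, "meth_counts.tsv"),
    total = file.path(dir, "total_counts.tsv"),
    phenotypes = file.path(dir, "phenotypes.tsv"),
    truth = file.path(dir, "truth.json"))
  write_genotypes(panel$geno, paths[["genotypes"]])
  write_expression(panel$expr_control, paths[["expression_control"]])
  write_expression(panel$expr_treated, paths[["expression_treated"]])
  write_methylation(panel$meth, paths[["meth"]], paths[["total"]])
  write_phenotypes(panel$pheno, paths[["phenotypes"]])
  truth <- panel$truth
  jsonlite::write_json(unclass(truth), paths[["truth"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
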