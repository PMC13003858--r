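# Shared fixtures, all built in code.

toy_genotype <- function() {
  codes <- matrix(c(0, 1, 1,
                    0, 0, 1), nrow = 3,
                  dimnames = list(c("S1", "S2", "S3"), NULL))
  genotype_matrix(codes, tibble::tibble(
    snp_id = c("s1", "s2"), chrom = "chr1", pos = c(100, 5000)))
}

toy_expression <- function(values = NULL, condition = "control") {
  if (is.null(values)) {
    values <- matrix(c(4, 6, 8,
                       5, 5, 5,
                       9, 10, 12), nrow = 3,
                     dimnames = list(c("S1", "S2", "S3"), NULL))
  }
  expression_matrix(values, tibble::tibble(
    gene_id = paste0("g", seq_len(ncol(values))),
    chrom = "chr1", pos = seq_len(ncol(values)) * 1000), condition)
}

toy_methylation <- function(meth = NULL, total = NULL, pos = NULL) {
  if (is.null(meth)) {
    meth <- matrix(c(2, 0, 4,
                     1, 3, 2), nrow = 3,
                   dimnames = list(c("S1", "S2", "S3"), NULL))
    total <- matrix(c(4, 5, 8,
                      3, 6, 4), nrow = 3,
                    dimnames = list(c("S1", "S2", "S3"), NULL))
  }
  if (is.null(pos)) pos <- c(100, 250)
  methylation_counts(meth, total, tibble::tibble(
    cpg_id = paste0("c", seq_len(ncol(meth))), chrom = "chr1", pos = pos))
}

# one small simulated panel shared across tests (built once per session)
.test_panel_env <- new.env(parent = emptyenv())
small_panel <- function(seed = 11) {
  key <- paste0("panel", seed)
  if (is.null(.test_panel_env[[key]])) {
    cfg <- sim_config(n_strains = 48, n_snps = 300, n_genes = 120, n_cpgs = 120,
                      trans_hotspots = tibble::tibble(
                        chrom = "chr2", pos = 25250000, n_targets = 20,
                        effect = 1.5, condition = "delta"),
                      emqtl_hotspots = tibble::tibble(
                        chrom = "chr3", pos = 10250000, n_cpgs = 3,
                        n_target_genes = 8, cpg_loading = 2.5,
                        gene_loading = 1.5),
                      pathway_size = 20, seed = seed)
    .test_panel_env[[key]] <- simulate_panel(cfg)
  }
  .test_panel_env[[key]]
}

test_genome <- function() genome_spec(paste0("chr", 1:3), rep(5e7, 3))

# dense-matrix restricted log-likelihood, independent of the eigen path
dense_reml_loglik <- function(h, y, K, X = matrix(1, length(y), 1)) {
  n <- length(y); q <- ncol(X)
  H <- h * K + (1 - h) * diag(n)
  Hi <- solve(H)
  XtHiX <- t(X) %*% Hi %*% X
  bhat <- solve(XtHiX, t(X) %*% Hi %*% y)
  r <- y - X %*% bhat
  rss <- drop(t(r) %*% Hi %*% r)
  sigma2 <- rss / (n - q)
  as.numeric(-0.5 * ((n - q) * (log(2 * pi * sigma2) + 1) +
                       determinant(H, logarithm = TRUE)$modulus +
                       determinant(XtHiX, logarithm = TRUE)$modulus -
                       determinant(crossprod(X), logarithm = TRUE)$modulus))
}

# nested-loop window assignment, independent of assign_windows()
assign_windows_oracle <- function(chrom, pos, windows) {
  vapply(seq_along(pos), function(i) {
    windows$window[windows$chrom == chrom[i] & windows$start <= pos[i] - 1 &
                     windows$end > pos[i] - 1]
  }, integer(1))
}
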