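test_that("kinship equals the trace-standardized centered cross-product", {
  g <- toy_genotype()
  K <- compute_kinship(g)
  # hand oracle: center columns, Z Z', rescale to trace n
  Z <- scale(g$codes, scale = FALSE)
  K0 <- Z %*% t(Z)
  K0 <- K0 * 3 / sum(diag(K0))
  expect_equal(unclass(K), K0, ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(sum(diag(K)) / nrow(K), 1, tolerance = 1e-8)
  ev <- eigen(unclass(K), symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev >= -1e-8 * max(ev)))
})

test_that("duplicate strains produce identical kinship rows and monomorphic panels error", {
  codes <- matrix(c(0, 0, 1,
                    1, 1, 0), nrow = 3, dimnames = list(c("A", "B", "C"), NULL))
  g <- genotype_matrix(codes, tibble::tibble(snp_id = c("s1", "s2"),
                                             chrom = "chr1", pos = c(1, 2)))
  K <- compute_kinship(g)
  expect_equal(K["A", ], K["B", ])

  mono <- genotype_matrix(matrix(1, 3, 2, dimnames = list(c("A", "B", "C"), NULL)),
                          tibble::tibble(snp_id = c("s1", "s2"), chrom = "chr1",
                                         pos = c(1, 2)))
  expect_error(compute_kinship(mono), class = "hotspotqtl_invariant_error")
})

test_that("REML finds the 1-D optimum of the dense-matrix restricted likelihood", {
  set.seed(7)
  for (rep in 1:10) {
    n <- 30
    A <- matrix(rnorm(n * n), n)
    K <- tcrossprod(A) / n
    K <- K * n / sum(diag(K))
    y <- drop(crossprod(chol(K + diag(1e-8, n)), rnorm(n))) + rnorm(n)
    fit <- reml_fit_null(y, K)
    grid <- seq(1e-6, 1 - 1e-6, length.out = 200)
    ll_grid <- vapply(grid, dense_reml_loglik, numeric(1), y = y, K = K)
    expect_gte(fit$loglik_reml, max(ll_grid) - 1e-4)
    # same likelihood value through the independent dense path
    expect_equal(fit$loglik_reml, dense_reml_loglik(fit$h2, y, K), tolerance = 1e-6)
  }
})

test_that("with no genetic structure the fit collapses to the sample variance", {
  set.seed(8)
  n <- 80
  K <- diag(n); dimnames(K) <- list(sprintf("S%02d", 1:n), sprintf("S%02d", 1:n))
  y <- rnorm(n)
  fit <- reml_fit_null(y, K)
  expect_lt(fit$h2, 0.15)
  expect_equal(fit$sigma_u_sq + fit$sigma_e_sq, var(y), tolerance = 0.05)
  expect_error(reml_fit_null(rep(1, n), K), class = "hotspotqtl_constant_trait")
})

test_that("heritability is recovered on a structured panel", {
  panel <- small_panel()
  K <- compute_kinship(panel$geno)
  n <- nrow(unclass(K))
  R <- chol(unclass(K) + diag(1e-8, n))
  set.seed(99)
  h_hat <- replicate(40, {
    y <- sqrt(0.5) * drop(crossprod(R, rnorm(n))) + sqrt(0.5) * rnorm(n)
    reml_fit_null(y, K)$h2
  })
  expect_lt(abs(mean(h_hat) - 0.5), 0.1)
})

test_that("with K = I the mixed-model scan matches ordinary least squares", {
  set.seed(21)
  n <- 40
  strains <- sprintf("S%02d", 1:n)
  codes <- matrix(rbinom(n * 5, 1, 0.4), n, 5, dimnames = list(strains, NULL))
  g <- genotype_matrix(codes, tibble::tibble(snp_id = paste0("s", 1:5),
                                             chrom = "chr1", pos = 1:5 * 1e5))
  K <- diag(n); dimnames(K) <- list(strains, strains)
  class(K) <- c("kinship_matrix", class(K))
  vals <- matrix(rnorm(n * 3), n, 3, dimnames = list(strains, NULL))
  vals[, 1] <- vals[, 1] + codes[, 2]
  e <- expression_matrix(vals, tibble::tibble(gene_id = paste0("g", 1:3),
                                              chrom = "chr1", pos = 1:3 * 1000),
                         "control")
  res <- assoc_scan(e, g, K, class = "eQTL")
  for (i in seq_len(nrow(res))) {
    ols <- summary(lm(e$values[, res$feature[i]] ~ g$codes[, res$predictor[i]]))
    expect_equal(res$p[i], ols$coefficients[2, 4], tolerance = 1e-6)
    expect_equal(res$beta[i], ols$coefficients[2, 1], tolerance = 1e-6)
  }
})

test_that("scan results are invariant to a consistent strain permutation", {
  panel <- small_panel()
  K <- compute_kinship(panel$geno)
  e <- panel$expr_control
  sub <- expression_matrix(e$values[, 1:5], e$genes[1:5, ], "control")
  res1 <- assoc_scan(sub, panel$geno, K, class = "eQTL")
  perm <- sample(strain_ids(panel$geno))
  g2 <- genotype_matrix(panel$geno$codes[perm, ], panel$geno$snps)
  e2 <- expression_matrix(sub$values[perm, ], sub$genes, "control")
  res2 <- assoc_scan(e2, g2, K, class = "eQTL")
  expect_equal(res1$p, res2$p, tolerance = 1e-8)
  expect_equal(res1$beta, res2$beta, tolerance = 1e-8)
})

test_that("constant SNPs and missing genotypes are handled pairwise", {
  set.seed(5)
  n <- 30
  strains <- sprintf("S%02d", 1:n)
  codes <- matrix(rbinom(n * 3, 1, 0.5), n, 3, dimnames = list(strains, NULL))
  codes[, 2] <- 0                              # constant
  codes[1:4, 3] <- NA                          # partial missing
  g <- genotype_matrix(codes, tibble::tibble(snp_id = paste0("s", 1:3),
                                             chrom = "chr1", pos = 1:3 * 1e5))
  K <- compute_kinship(genotype_matrix(
    matrix(rbinom(n * 20, 1, 0.5), n, 20, dimnames = list(strains, NULL)),
    tibble::tibble(snp_id = paste0("k", 1:20), chrom = "chr1", pos = 1:20)))
  vals <- matrix(rnorm(n), n, 1, dimnames = list(strains, NULL))
  e <- expression_matrix(vals, tibble::tibble(gene_id = "g1", chrom = "chr1",
                                              pos = 1000), "control")
  res <- assoc_scan(e, g, K, class = "eQTL")
  expect_true(is.na(res$p[res$predictor == "s2"]))
  expect_equal(res$note[res$predictor == "s2"], "constant_predictor")
  expect_equal(res$n[res$predictor == "s3"], n - 4)
  expect_false(is.na(res$p[res$predictor == "s3"]))
})

test_that("the exact per-SNP REML mode agrees with the approximation", {
  panel <- small_panel()
  K <- compute_kinship(panel$geno)
  e <- panel$expr_control
  sub <- expression_matrix(e$values[, 1:2], e$genes[1:2, ], "control")
  gsub <- genotype_matrix(panel$geno$codes[, 1:10], panel$geno$snps[1:10, ])
  res_a <- assoc_scan(sub, gsub, K, class = "eQTL")
  res_e <- assoc_scan(sub, gsub, K, class = "eQTL", exact = TRUE)
  # close p-values throughout, concordant ranking
  expect_equal(log10(res_a$p), log10(res_e$p), tolerance = 0.5)
  expect_gt(cor(log10(res_a$p), log10(res_e$p), method = "spearman"), 0.95)
})

test_that("delta traits subtract control from treated over shared strains", {
  e1 <- toy_expression()
  e2 <- expression_matrix(e1$values + 1, e1$genes, "treated")
  d <- delta_traits(e1, e2)
  expect_true(all(d$values == 1))
  expect_identical(d$condition, "delta")
  d0 <- delta_traits(e1, expression_matrix(e1$values, e1$genes, "treated"))
  expect_true(all(d0$values == 0))

  # hand-built 2x2 elementwise difference
  vc <- matrix(c(1, 2, 3, 4), 2, dimnames = list(c("S1", "S2"), NULL))
  vt <- matrix(c(2, 1, 7, 4), 2, dimnames = list(c("S1", "S2"), NULL))
  genes <- tibble::tibble(gene_id = c("g1", "g2"), chrom = "chr1", pos = c(1, 2))
  d2 <- delta_traits(expression_matrix(vc, genes, "control"),
                     expression_matrix(vt, genes, "treated"))
  expect_equal(unname(d2$values), matrix(c(1, -1, 4, 0), 2))

  # differing gene sets error with the discrepancy listed
  e3 <- expression_matrix(e1$values[, 1:2], e1$genes[1:2, ], "treated")
  expect_error(delta_traits(e1, e3), "g3", class = "hotspotqtl_input_error")
})

test_that("methylation converts to percent (or logit) traits with mask propagation", {
  m <- toy_methylation()
  tr <- methylation_to_traits(m)
  expect_equal(tr["S1", "c1"], 100 * 2 / 4)
  expect_equal(unname(tr[, "c2"]), 100 * c(1/3, 3/6, 2/4))
  meth <- m$meth; meth["S2", "c1"] <- NA
  total <- m$total; total["S2", "c1"] <- NA
  m2 <- methylation_counts(meth, total, m$cpgs)
  expect_true(is.na(methylation_to_traits(m2)["S2", "c1"]))
  lg <- methylation_to_traits(m, logit = TRUE)
  expect_equal(lg["S1", "c1"], log(2.5 / 2.5))
})
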