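test_that("flank membership uses a closed lower bound and half-open upper bound", {
  locus <- list(locus_id = "L1", chrom = "chr1", start = 5e6, end = 5.5e6)
  genes <- tibble::tibble(
    gene_id = c("at_lower", "inside", "at_upper", "below", "other_chrom"),
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr2"),
    pos = c(4e6 + 1, 5.2e6, 6.5e6 + 1, 4e6, 5.2e6))
  out <- flank_genes(locus, genes, flank = 1e6)
  expect_true("at_lower" %in% out)        # coordinate exactly at start - flank
  expect_true("inside" %in% out)
  expect_false("at_upper" %in% out)       # half-open upper bound
  expect_false("below" %in% out)
  expect_false("other_chrom" %in% out)

  # 20-gene fixture vs interval-scan oracle
  set.seed(14)
  g20 <- tibble::tibble(gene_id = sprintf("g%02d", 1:20),
                        chrom = sample(c("chr1", "chr2"), 20, replace = TRUE),
                        pos = sample.int(2e7, 20))
  got <- flank_genes(locus, g20)
  want <- g20$gene_id[g20$chrom == "chr1" &
                        g20$pos - 1 >= 4e6 & g20$pos - 1 < 6.5e6]
  expect_setequal(got, want)
})

test_that("cis minimum p is the brute-force minimum over flank predictors", {
  locus <- list(chrom = "chr1", start = 5e6, end = 5.5e6)
  res <- tibble::tibble(
    feature = c("g1", "g1", "g1", "g2"),
    predictor = paste0("s", 1:4),
    chrom = c("chr1", "chr1", "chr2", "chr1"),
    pos = c(5.1e6, 5.9e6, 5.1e6, 5.1e6),
    p = c(1e-3, 1e-7, 1e-12, 1e-9))
  expect_equal(cis_eqtl_min_p("g1", res, locus), 1e-7)
  expect_equal(cis_eqtl_min_p("g2", res, locus), 1e-9)
  expect_true(is.na(cis_eqtl_min_p("g3", res, locus)))
  one <- res[2, ]
  expect_equal(cis_eqtl_min_p("g1", one, locus), 1e-7)
})

test_that("trait correlations match the covariance-formula oracle exactly", {
  x <- c(1, 3, 4, 7)
  y <- c(2, 3, 7, 9)
  vals <- matrix(c(x, y, rep(5, 4)), 4,
                 dimnames = list(paste0("S", 1:4), NULL))
  e <- expression_matrix(vals, tibble::tibble(gene_id = c("gx", "gy", "gconst"),
                                              chrom = "chr1", pos = 1:3), "control")
  ph <- phenotype_table(tibble::tibble(strain = paste0("S", 1:4), trait1 = y))
  out <- trait_correlations(e, ph)
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(out$r[out$gene == "gx"], r_oracle, tolerance = 1e-12)
  ct <- cor.test(x, y)
  expect_equal(out$p[out$gene == "gx"], ct$p.value, tolerance = 1e-12)
  expect_equal(out$r[out$gene == "gy"], 1)          # y vs itself
  expect_equal(out$note[out$gene == "gconst"], "zero_variance")
})

test_that("null gene-phenotype correlations are small and p roughly uniform", {
  set.seed(20)
  n <- 100
  vals <- matrix(rnorm(n * 50), n, dimnames = list(sprintf("S%03d", 1:n), NULL))
  e <- expression_matrix(vals, tibble::tibble(gene_id = sprintf("g%02d", 1:50),
                                              chrom = "chr1", pos = 1:50), "control")
  ph <- phenotype_table(tibble::tibble(strain = sprintf("S%03d", 1:n),
                                       hw = rnorm(n)))
  out <- trait_correlations(e, ph)
  expect_lt(max(abs(out$r)), 0.5)
  expect_gt(ks.test(out$p, "punif")$p.value, 0.01)
})

test_that("candidate scoring counts evidence lines and breaks ties deterministically", {
  locus <- list(locus_id = "L1", chrom = "chr1", start = 5e6, end = 5.5e6)
  genes <- paste0("g", 1:5)
  cv <- tibble::tibble(gene_id = genes,
                       has_coding_variant = c(TRUE, TRUE, FALSE, FALSE, TRUE))
  cis <- tibble::tibble(
    feature = c("g1", "g2", "g3", "g5"),
    predictor = paste0("s", 1:4), chrom = "chr1",
    pos = rep(5.2e6, 4),
    p = c(1e-8, 1e-7, 1e-9, 0.5))
  tc <- tibble::tibble(gene = genes, trait = "hw",
                       r = c(0.5, 0.1, 0.6, 0.2, 0.4),
                       p = c(1e-4, 0.5, 1e-5, 0.9, 0.03),
                       n = 50, note = NA_character_)
  out <- score_candidates(locus, genes, cv, cis, tc)
  # hand-ranked oracle: g1 = 3; g2 = 2 (cv+cis); g3 = 2 (cis+trait); g5 = 2
  # (cv+trait); g4 = 0. Among score 2: order by cis p (g3 1e-9, g2 1e-7,
  # g5 NA->last)
  expect_equal(out$gene_id, c("g1", "g3", "g2", "g5", "g4"))
  expect_equal(out$score, c(3L, 2L, 2L, 2L, 0L))
  # permutation invariance of the input gene order
  out2 <- score_candidates(locus, rev(genes), cv[c(3, 1, 5, 2, 4), ], cis, tc)
  expect_equal(out2, out)
})

test_that("the pathway permutation test hits its bounds and is bit-reproducible", {
  set.seed(30)
  n <- 60
  target_vals <- rnorm(n)
  vals <- cbind(target_vals,
                matrix(rep(target_vals, 3), n, 3),        # exact copies
                matrix(rnorm(n * 200), n, 200))
  rownames(vals) <- sprintf("S%03d", 1:n)
  ids <- c("target", paste0("copy", 1:3), sprintf("bg%03d", 1:200))
  e <- expression_matrix(vals, tibble::tibble(gene_id = ids, chrom = "chr1",
                                              pos = seq_along(ids)), "control")
  res <- pathway_permutation_test("target", paste0("copy", 1:3), e,
                                  n_perm = 500, seed = 2)
  expect_equal(res$observed, 1.0, tolerance = 1e-12)
  expect_equal(res$p, 1 / 501)                     # add-one lower bound
  res2 <- pathway_permutation_test("target", paste0("copy", 1:3), e,
                                   n_perm = 500, seed = 2)
  expect_identical(res$p, res2$p)
  expect_identical(res$observed, res2$observed)

  sm_vals <- cbind(vals[, 1:2], const = rep(1, n))
  small <- expression_matrix(sm_vals,
                             tibble::tibble(gene_id = c("target", "copy1", "const"),
                                            chrom = "chr1", pos = 1:3), "control")
  expect_error(pathway_permutation_test("target", c("copy1", "const"), small,
                                        n_perm = 500, seed = 1),
               class = "hotspotqtl_input_error")  # pathway exceeds usable universe
  expect_error(pathway_permutation_test("nope", paste0("copy", 1:3), e,
                                        n_perm = 500, seed = 1),
               class = "hotspotqtl_input_error")
})

test_that("null pathways give uniform permutation p-values", {
  set.seed(40)
  n <- 60
  vals <- matrix(rnorm(n * 150), n, dimnames = list(sprintf("S%03d", 1:n), NULL))
  ids <- sprintf("g%03d", 1:150)
  e <- expression_matrix(vals, tibble::tibble(gene_id = ids, chrom = "chr1",
                                              pos = seq_along(ids)), "control")
  ps <- vapply(1:60, function(i) {
    pw <- sample(ids[-1], 20)
    pathway_permutation_test(ids[1], pw, e, n_perm = 200, seed = i)$p
  }, numeric(1))
  # discrete permutation p grid: ties expected, KS still informative
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
  expect_true(all(ps >= 1 / 201))
})
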