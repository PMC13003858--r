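test_that("window arithmetic tiles the genome with ceil(len/size) windows", {
  w <- make_windows(genome_spec("g", 2.7e9))
  expect_equal(nrow(w), 5400)
  expect_true(all(w$end - w$start == 5e5))

  w1 <- make_windows(genome_spec("c", 200000))
  expect_equal(nrow(w1), 1)
  expect_equal(c(w1$start, w1$end), c(0, 200000))

  w3 <- make_windows(genome_spec("c", 1200000))
  expect_equal(nrow(w3), 3)
  expect_equal(w3$start[3], 1000000)
  expect_equal(w3$end[3], 1200000)

  # partition property across a multi-chromosome genome
  gs <- genome_spec(paste0("chr", 1:4), c(1.7e6, 5e5, 123456, 2.5e6))
  ww <- make_windows(gs)
  expect_equal(nrow(ww), sum(ceiling(gs$length / 5e5)))
  by_chr <- split(ww, ww$chrom)
  for (ch in names(by_chr)) {
    wc <- by_chr[[ch]]
    expect_equal(wc$start, c(0, head(wc$end, -1)))   # no gaps, no overlaps
    expect_equal(max(wc$end), gs$length[gs$chrom == ch])
  }
  expect_error(make_windows(gs, size = 0), class = "hotspotqtl_input_error")
})

test_that("the suggestive threshold is one order of magnitude off genome-wide", {
  expect_equal(suggestive_threshold(), 4.2e-5)
  expect_equal(suggestive_threshold(factor = 1), 4.2e-6)
  expect_equal(suggestive_threshold(1e-8, 10), 1e-7)
  expect_error(suggestive_threshold(0.5, 10), class = "hotspotqtl_input_error")
})

make_fake_results <- function(n, windows, genome, seed = 1, n_features = 50) {
  set.seed(seed)
  chrom <- sample(genome$chrom, n, replace = TRUE,
                  prob = genome$length / sum(genome$length))
  pos <- vapply(chrom, function(ch)
    sample.int(genome$length[genome$chrom == ch], 1), numeric(1))
  tibble::tibble(
    feature = sample(sprintf("f%03d", seq_len(n_features)), n, replace = TRUE),
    predictor = sprintf("p%05d", seq_len(n)),
    chrom = chrom, pos = pos,
    p = 10^runif(n, -8, 0),
    class = "eQTL", condition = "control")
}

test_that("window minimum p-values match a brute-force nested loop", {
  genome <- test_genome()
  windows <- make_windows(genome)
  res <- make_fake_results(500, windows, genome, seed = 4)
  minp <- window_min_p(res, windows)
  # independent nested-loop oracle
  for (i in seq_len(nrow(minp))) {
    w <- windows[windows$window == minp$window[i], ]
    sel <- res$feature == minp$feature[i] & res$chrom == w$chrom &
      res$pos - 1 >= w$start & res$pos - 1 < w$end
    expect_equal(minp$min_p[i], min(res$p[sel]))
  }
  # every (feature, window) with a test appears
  expect_equal(nrow(minp),
               nrow(unique(tibble::tibble(
                 f = res$feature,
                 w = assign_windows_oracle(res$chrom, res$pos, windows)))))

  one <- res[1, ]; one$p <- 0.3
  m1 <- window_min_p(one, windows)
  expect_equal(m1$min_p, 0.3)

  trio <- res[c(1, 1, 1), ]
  trio$p <- c(0.5, 3e-6, 1e-4)
  expect_equal(window_min_p(trio, windows)$min_p, 3e-6)

  out <- res[1, ]; out$pos <- genome$length[genome$chrom == out$chrom] + 10
  expect_error(window_min_p(out, windows), "outside",
               class = "hotspotqtl_input_error")
})

test_that("hotspot counts match a brute-force recount and flat landscapes yield none", {
  genome <- test_genome()
  windows <- make_windows(genome)
  res <- make_fake_results(5000, windows, genome, seed = 12, n_features = 200)
  minp <- window_min_p(res, windows)
  hs <- call_hotspots(minp)
  sugg <- attr(hs, "suggestive")
  widx <- assign_windows_oracle(res$chrom, res$pos, windows)
  for (w in sample(hs$window[hs$count > 0], 10)) {
    brute <- 0
    for (f in unique(res$feature)) {
      sel <- res$feature == f & widx == w
      if (any(sel) && min(res$p[sel]) < sugg) brute <- brute + 1
    }
    expect_equal(hs$count[hs$window == w], brute)
    expect_setequal(hs$features[hs$window == w][[1]],
                    unique(res$feature[widx == w & res$p < sugg]))
  }

  flat <- minp; flat$min_p <- 0.5
  attr(flat, "windows") <- windows
  expect_warning(h0 <- call_hotspots(flat), "flat")
  expect_false(any(h0$significant))
})

test_that("a constructed 10-sd outlier is the only significant window under the normal tail", {
  genome <- genome_spec("g", 2.7e9)
  windows <- make_windows(genome)
  set.seed(2)
  # background counts ~ Poisson(20) in every window, one window forced high
  counts <- rpois(5400, 20)
  minp <- tibble::tibble(
    window = rep(windows$window, counts),
    feature = unlist(lapply(counts, function(k) sprintf("f%04d", seq_len(k)))),
    min_p = 1e-6)
  target <- 2700
  extra <- round(mean(counts) + 10 * sd(counts)) - counts[target + 1]
  minp <- dplyr::bind_rows(minp, tibble::tibble(
    window = target, feature = sprintf("x%04d", seq_len(extra)), min_p = 1e-6))
  attr(minp, "windows") <- windows
  class(minp) <- c("window_min_p", class(minp))
  hs <- call_hotspots(minp, null_method = "empirical")
  expect_equal(hs$window[hs$significant], target)
  expect_gt(hs$z[hs$window == target], 4.2)
})

test_that("the Poisson-tail default controls false hotspot calls on sparse nulls", {
  genome <- test_genome()
  windows <- make_windows(genome)
  set.seed(77)
  any_sig <- replicate(40, {
    counts <- rpois(nrow(windows), 0.3)
    minp <- tibble::tibble(
      window = rep(windows$window, counts),
      feature = sprintf("f%05d", seq_len(sum(counts))),
      min_p = 1e-6)
    attr(minp, "windows") <- windows
    class(minp) <- c("window_min_p", class(minp))
    any(call_hotspots(minp)$significant)
  })
  expect_lte(mean(any_sig), 0.10)
})

test_that("adjacent significant windows merge into loci with union feature sets", {
  genome <- test_genome()
  windows <- make_windows(genome)
  hs <- windows
  hs$count <- 0L; hs$z <- 0; hs$p <- 1; hs$significant <- FALSE
  hs$features <- rep(list(character(0)), nrow(hs))
  mark <- function(h, w, feats) {
    i <- which(h$window == w)
    h$count[i] <- length(feats); h$p[i] <- 1e-10; h$significant[i] <- TRUE
    h$features[[i]] <- feats
    h
  }
  hs <- mark(hs, 10, c("a", "b"))
  hs <- mark(hs, 11, c("b", "c"))
  hs <- mark(hs, 40, "d")
  hs <- mark(hs, 42, "e")
  class(hs) <- c("hotspot_result", class(hs))
  attr(hs, "suggestive") <- 4.2e-5; attr(hs, "bonferroni") <- 9.3e-6
  loci <- merge_loci(hs, total_features = 10, prefix = "Control_eQTL")
  expect_equal(nrow(loci), 3)
  two <- loci[loci$n_windows == 2, ]
  expect_equal(two$end - two$start, 1e6)          # two adjacent windows: 1000 kb
  expect_setequal(two$features[[1]], c("a", "b", "c"))
  expect_equal(two$pct_regulated, 30)
  singles <- loci[loci$n_windows == 1, ]
  expect_true(all(singles$end - singles$start == 5e5))
  expect_equal(loci$locus_id[1], "Control_eQTL_1")
})

test_that("overlap enrichment hits the add-one bounds on extreme configurations", {
  genome <- test_genome()
  loci <- tibble::tibble(locus_id = paste0("L", 1:6),
                         chrom = rep(c("chr1", "chr2"), each = 3),
                         start = rep(c(1e6, 20e6, 40e6), 2),
                         end = rep(c(1.5e6, 20.5e6, 41e6), 2))
  prior <- locus_list(dplyr::mutate(loci, source = "gwas"), genome)
  res <- overlap_enrichment(loci, prior, genome, n_perm = 200, seed = 5)
  expect_equal(res$observed, 6)
  expect_equal(res$p, 1 / 201)

  far <- locus_list(tibble::tibble(locus_id = "x", chrom = "chr3",
                                   start = 0, end = 1e6, source = "ewas"), genome)
  res2 <- overlap_enrichment(loci, far, genome, n_perm = 200, seed = 5)
  expect_equal(res2$observed, 0)
  expect_gt(res2$p, 0.5)

  expect_warning(res3 <- overlap_enrichment(loci, prior[0, ], genome,
                                            n_perm = 200, seed = 5))
  expect_equal(res3$p, 1)
  expect_error(overlap_enrichment(loci, prior, genome, n_perm = 10, seed = 1),
               class = "hotspotqtl_input_error")
})

test_that("a planted enrichment is detected against circular-shift placement", {
  genome <- test_genome()
  # loci placed inside prior intervals on all three chromosomes; the
  # circular-shift null moves each chromosome's loci jointly, so power
  # comes from independent shifts across chromosomes
  loci <- tibble::tibble(locus_id = paste0("L", 1:6),
                         chrom = rep(paste0("chr", 1:3), each = 2),
                         start = rep(c(5.1e6, 20.1e6), 3),
                         end = rep(c(5.1e6, 20.1e6), 3) + 5e5)
  prior <- locus_list(tibble::tibble(locus_id = paste0("P", 1:6),
                                     chrom = rep(paste0("chr", 1:3), each = 2),
                                     start = rep(c(5e6, 20e6), 3),
                                     end = rep(c(5e6, 20e6), 3) + 1e6,
                                     source = "gwas"), genome)
  res <- overlap_enrichment(loci, prior, genome, n_perm = 2000, seed = 8)
  expect_equal(res$observed, 6)
  expect_lt(res$p, 0.01)
})

test_that("the permutation p is monotone non-increasing in the observed overlap", {
  genome <- test_genome()
  base <- tibble::tibble(locus_id = paste0("L", 1:5), chrom = "chr1",
                         start = seq(2e6, 42e6, by = 1e7),
                         end = seq(2e6, 42e6, by = 1e7) + 5e5)
  prior <- locus_list(dplyr::mutate(base, source = "gwas"), genome)
  p_seen <- vapply(0:5, function(k) {
    loci <- base
    if (k < 5) {                     # shift 5-k loci away from their priors
      idx <- seq_len(5 - k)
      loci$start[idx] <- loci$start[idx] + 5e6
      loci$end[idx] <- loci$end[idx] + 5e6
    }
    overlap_enrichment(loci, prior, genome, n_perm = 500, seed = 33)$p
  }, numeric(1))
  expect_true(all(diff(p_seen) <= 1e-12))
})

test_that("hotspot results plot and print without error", {
  genome <- test_genome()
  windows <- make_windows(genome)
  res <- make_fake_results(2000, windows, genome, seed = 3)
  hs <- call_hotspots(window_min_p(res, windows))
  p <- autoplot(hs)
  expect_s3_class(p, "ggplot")
  expect_output(print(hs), "windows")
})
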