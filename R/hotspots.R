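# Windowed trans-hotspot detection.
#
# The genome is tiled into 500 kb windows (0-based half-open; the last window
# of each chromosome is truncated). Each feature's association profile is
# reduced to its lowest p-value per window; a window's hotspot strength is
# the number of features whose window minimum falls below the suggestive
# cutoff (default 4.2e-5, one order of magnitude above the genome-wide
# 4.2e-6). Window counts are z-transformed against the genome-wide empirical
# count distribution and windows are called significant below a Bonferroni
# threshold (default 9.3e-6 = 0.05 / 5400 windows on a 2.7 Gb genome).
#
# Significance tails: the package default converts a window's count to a
# p-value with a Poisson upper tail at the empirical mean. The normal tail
# of the z-score ("empirical") is available but is badly anti-conservative
# when per-window mean counts are small (<~5), where the discrete count
# distribution is strongly right-skewed; a feature-label permutation null
# ("permute") is also provided for sensitivity analysis. See the methods
# vignette.

#' Tile a genome into fixed-size windows
#'
#' @param genome A [genome_spec()].
#' @param size Window size in bp (default 500000). Windows are 0-based
#'   half-open, tile each chromosome without gaps or overlaps, and the last
#'   window of a chromosome is truncated at the chromosome length, so the
#'   total count is `sum(ceiling(length / size))`.
#' @return A tibble with columns `chrom, start, end, window` (`window` is a
#'   global 0-based index).
#' @export
make_windows <- function(genome, size = 500000) {
  if (size <= 0) stop_input("window size must be positive")
  out <- purrr::pmap(list(genome$chrom, genome$length), function(ch, len) {
    starts <- seq(0, len - 1, by = size)
    tibble(chrom = ch, start = starts, end = pmin(starts + size, len))
  }) %>% bind_rows()
  out$window <- seq_len(nrow(out)) - 1L
  out
}

#' Suggestive p-value cutoff from the genome-wide threshold
#'
#' @param genomewide Genome-wide significance threshold (default 4.2e-6).
#' @param factor Relaxation factor (default 10: one order of magnitude less
#'   stringent).
#' @return `genomewide * factor`, which must stay below 1.
#' @export
suggestive_threshold <- function(genomewide = 4.2e-6, factor = 10) {
  if (genomewide <= 0 || genomewide >= 1) stop_input("genome-wide threshold must lie in (0, 1)")
  out <- genomewide * factor
  if (out >= 1) stop_input("suggestive threshold would reach 1")
  out
}

assign_windows <- function(chrom, pos, windows) {
  widx <- rep(NA_integer_, length(pos))
  for (ch in unique(chrom)) {
    wc <- windows[windows$chrom == ch, , drop = FALSE]
    sel <- which(chrom == ch)
    if (!nrow(wc)) {
      stop_input(sprintf("predictor on chromosome '%s' outside the genome", ch))
    }
    i <- findInterval(pos[sel] - 1, wc$start)
    bad <- i < 1 | (pos[sel] - 1) >= wc$end[pmax(i, 1)]
    if (any(bad)) {
      b <- sel[which(bad)[1]]
      stop_input(sprintf("predictor position %s:%d outside genome bounds", chrom[b], pos[b]))
    }
    widx[sel] <- wc$window[i]
  }
  widx
}

#' Per-window minimum p-value per feature
#'
#' The lowest p-value among a feature's predictors located inside a window
#' represents that feature's relationship to the window as a whole.
#'
#' @param results Association tibble ([assoc_scan()] / [emqtl_scan()] rows;
#'   rows with missing p are ignored).
#' @param windows Window tibble from [make_windows()].
#' @return A tibble `window, feature, min_p` (sparse: absent where a feature
#'   has no test in a window), with the windows attached as an attribute.
#' @export
window_min_p <- function(results, windows) {
  res <- results[!is.na(results$p), , drop = FALSE]
  out <- if (nrow(res)) {
    res$window <- assign_windows(res$chrom, res$pos, windows)
    res %>%
      group_by(.data$window, .data$feature) %>%
      summarise(min_p = min(.data$p), .groups = "drop")
  } else {
    tibble(window = integer(), feature = character(), min_p = numeric())
  }
  attr(out, "windows") <- windows
  class(out) <- c("window_min_p", class(out))
  out
}

#' Call hotspot windows
#'
#' Counts, per window, the features whose window-minimum p-value is strictly
#' below the suggestive cutoff; converts counts to z-scores against the
#' empirical mean/sd over ALL windows (empty windows count as 0); and
#' assigns each window a one-sided upper-tail p-value, significant below the
#' Bonferroni threshold.
#'
#' @param minp Output of [window_min_p()].
#' @param suggestive Suggestive cutoff (default 4.2e-5); strict `<`.
#' @param bonferroni Significance threshold on the hotspot p-value (default
#'   9.3e-6, i.e. 0.05 Bonferroni-corrected for 5400 windows).
#' @param null_method How the upper-tail p-value is computed from the count
#'   landscape: `"poisson"` (default; Poisson tail at the empirical mean —
#'   calibrated for the sparse counts of desk-scale panels), `"empirical"`
#'   (standard-normal tail of the z-score), or `"permute"` (feature-label
#'   permutation of window assignments).
#' @param n_perm,seed Permutation controls for `null_method = "permute"`.
#' @return A `hotspot_result` tibble: `chrom, start, end, window, count, z,
#'   p, significant, features` (list-column of regulated feature ids), with
#'   the thresholds and method as attributes.
#' @export
call_hotspots <- function(minp, suggestive = 4.2e-5, bonferroni = 9.3e-6,
                          null_method = c("poisson", "empirical", "permute"),
                          n_perm = 1000, seed = 1) {
  null_method <- match.arg(null_method)
  windows <- attr(minp, "windows")
  if (is.null(windows)) stop_input("minp must come from window_min_p()")
  if (nrow(windows) < 10) stop_input("hotspot calling needs >= 10 windows")
  sugg <- minp[minp$min_p < suggestive, , drop = FALSE]
  counts <- sugg %>% group_by(.data$window) %>%
    summarise(count = dplyr::n(),
              features = list(sort(unique(.data$feature))), .groups = "drop")
  out <- windows %>%
    left_join(counts, by = "window") %>%
    mutate(count = ifelse(is.na(.data$count), 0L, .data$count))
  if (!"features" %in% names(out)) out$features <- list()
  out$features <- lapply(out$features, function(f) if (is.null(f)) character(0) else f)
  mu <- mean(out$count)
  sdv <- sd(out$count)
  if (is.na(sdv) || sdv == 0) {
    warn("flat hotspot landscape: count sd is zero, no hotspots called")
    out$z <- 0
    out$p <- 1
    out$significant <- FALSE
  } else {
    out$z <- (out$count - mu) / sdv
    out$p <- switch(null_method,
      poisson = ppois(out$count - 1, lambda = mu, lower.tail = FALSE),
      empirical = pnorm(out$z, lower.tail = FALSE),
      permute = permute_window_p(minp, windows, suggestive, out$count, n_perm, seed)
    )
    out$p <- p_floor(out$p)
    out$significant <- out$p < bonferroni
  }
  out <- out[, c("chrom", "start", "end", "window", "count", "z", "p",
                 "significant", "features")]
  attr(out, "suggestive") <- suggestive
  attr(out, "bonferroni") <- bonferroni
  attr(out, "null_method") <- null_method
  class(out) <- c("hotspot_result", class(out))
  out
}

# feature-label permutation: each feature keeps its number of suggestive
# windows but the window labels are redrawn uniformly; pooled permuted
# counts form the null for every window.
permute_window_p <- function(minp, windows, suggestive, counts, n_perm, seed) {
  n_win <- nrow(windows)
  sugg <- minp[minp$min_p < suggestive, , drop = FALSE]
  per_feature <- table(sugg$feature)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  null_counts <- integer(0)
  for (b in seq_len(n_perm)) {
    hits <- unlist(lapply(per_feature, function(k) sample.int(n_win, k)))
    tab <- tabulate(hits, nbins = n_win)
    null_counts <- c(null_counts, tab)
  }
  vapply(counts, function(cc) (1 + sum(null_counts >= cc)) / (length(null_counts) + 1),
         numeric(1))
}

#' @export
print.hotspot_result <- function(x, ...) {
  cat(sprintf("<hotspot_result> %d windows, %d significant (suggestive < %g, threshold %g, null: %s)\n",
              nrow(x), sum(x$significant), attr(x, "suggestive"),
              attr(x, "bonferroni"), attr(x, "null_method")))
  NextMethod()
}

#' Plot a hotspot landscape
#'
#' Per-window suggestive-feature counts along the genome, significant
#' hotspot windows highlighted.
#'
#' @param object A `hotspot_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hotspot_result <- function(object, ...) {
  df <- tibble::as_tibble(object) %>% mutate(mid = (.data$start + .data$end) / 2e6)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data$count)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$significant), size = 1) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40", `TRUE` = "red")) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom), scales = "free_x",
                        space = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "features regulated (suggestive)",
                  colour = "significant") +
    ggplot2::theme_bw()
}

#' Merge adjacent significant windows into loci
#'
#' Adjacent significant windows on one chromosome merge into a single locus;
#' the locus' regulated-feature set is the union over its member windows.
#'
#' @param hotspots A `hotspot_result` from one (class, condition) scan.
#' @param total_features Total number of scanned features, used for the
#'   percent-regulated summary.
#' @param prefix Locus id prefix (e.g. `"Delta_eQTL"`).
#' @return A `merged_locus` tibble: `locus_id, chrom, start, end, n_windows,
#'   windows` (list), `max_count, min_p, features` (list),
#'   `pct_regulated`.
#' @export
merge_loci <- function(hotspots, total_features, prefix = "locus") {
  sig <- hotspots[hotspots$significant, , drop = FALSE]
  if (!nrow(sig)) {
    out <- tibble(locus_id = character(), chrom = character(), start = numeric(),
                  end = numeric(), n_windows = integer(), windows = list(),
                  max_count = numeric(), min_p = numeric(), features = list(),
                  pct_regulated = numeric())
    class(out) <- c("merged_locus", class(out))
    return(out)
  }
  sig <- sig %>% arrange(.data$window)
  grp <- cumsum(c(1, diff(sig$window) != 1 | sig$chrom[-1] != sig$chrom[-nrow(sig)]))
  out <- sig %>%
    mutate(.grp = grp) %>%
    group_by(.data$.grp) %>%
    summarise(chrom = first(.data$chrom), start = min(.data$start),
              end = max(.data$end), n_windows = dplyr::n(),
              windows = list(.data$window),
              max_count = max(.data$count), min_p = min(.data$p),
              features = list(sort(unique(unlist(.data$features)))),
              .groups = "drop") %>%
    mutate(locus_id = sprintf("%s_%d", prefix, row_number()),
           pct_regulated = 100 * map_int(.data$features, length) / total_features) %>%
    select("locus_id", "chrom", "start", "end", "n_windows", "windows",
           "max_count", "min_p", "features", "pct_regulated")
  class(out) <- c("merged_locus", class(out))
  out
}

#' Hotspot overlap enrichment against prior loci
#'
#' Counts merged hotspot loci intersecting (any bp) at least one prior
#' GWAS/EWAS locus and compares the count with a circular-shift null: in
#' each permutation, the hotspot loci of each chromosome are shifted by one
#' uniform random offset (wrapping around the chromosome end), preserving
#' locus sizes and chromosome occupancy.
#'
#' @param loci A `merged_locus` tibble (or any tibble with `chrom, start,
#'   end`).
#' @param prior A [locus_list()] of prior loci.
#' @param genome A [genome_spec()].
#' @param n_perm Number of permutations (>= 100).
#' @param seed Random seed (required: the test is stochastic).
#' @return A one-row tibble of class `overlap_test`: `observed, n_loci,
#'   n_prior, p, n_perm, seed`. `p` uses the add-one rule, so it is bounded
#'   below by `1/(n_perm + 1)`.
#' @export
overlap_enrichment <- function(loci, prior, genome, n_perm = 1000, seed = 1) {
  if (n_perm < 100) stop_input("overlap enrichment needs n_perm >= 100")
  if (!nrow(prior)) {
    warn("empty prior locus list: overlap p-value is 1")
    out <- tibble(observed = 0L, n_loci = nrow(loci), n_prior = 0L, p = 1,
                  n_perm = n_perm, seed = seed)
    class(out) <- c("overlap_test", class(out))
    return(out)
  }
  chrom_len <- setNames(genome$length, genome$chrom)
  prior_by_chrom <- split(prior[, c("start", "end")], prior$chrom)

  count_overlaps <- function(chrom, start, end) {
    hit <- logical(length(start))
    for (i in seq_along(start)) {
      pb <- prior_by_chrom[[chrom[i]]]
      if (is.null(pb)) next
      hit[i] <- any(pb$start < end[i] & pb$end > start[i])
    }
    sum(hit)
  }
  wrap_intervals <- function(start, end, offset, L) {
    s <- (start + offset) %% L
    e <- s + (end - start)
    over <- e > L
    list(start = c(s[!over], s[over], rep(0, sum(over))),
         end = c(e[!over], rep(L, sum(over)), e[over] - L),
         # locus identity: a wrapped locus counts once if either piece overlaps
         id = c(which(!over), which(over), which(over)))
  }

  observed <- count_overlaps(loci$chrom, loci$start, loci$end)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  loci_by_chrom <- split(loci[, c("start", "end")], loci$chrom)
  perm_ge <- 0L
  for (b in seq_len(n_perm)) {
    tot <- 0L
    for (ch in names(loci_by_chrom)) {
      lb <- loci_by_chrom[[ch]]
      L <- chrom_len[[ch]]
      off <- runif(1, 0, L)
      w <- wrap_intervals(lb$start, lb$end, off, L)
      pb <- prior_by_chrom[[ch]]
      if (is.null(pb)) next
      hit_id <- unique(w$id[vapply(seq_along(w$start), function(i)
        any(pb$start < w$end[i] & pb$end > w$start[i]), logical(1))])
      tot <- tot + length(hit_id)
    }
    if (tot >= observed) perm_ge <- perm_ge + 1L
  }
  out <- tibble(observed = observed, n_loci = nrow(loci), n_prior = nrow(prior),
                p = (1 + perm_ge) / (n_perm + 1), n_perm = n_perm, seed = seed)
  class(out) <- c("overlap_test", class(out))
  out
}

#' Write hotspots or merged loci as BED6+
#'
#' Columns: `chrom start end id count p` (tab-separated, plus a `#` header).
#'
#' @param x A `hotspot_result` or `merged_locus` tibble.
#' @param path File path.
#' @export
write_hotspots_bed <- function(x, path) {
  id <- if ("locus_id" %in% names(x)) x$locus_id else sprintf("window_%d", x$window)
  cnt <- if ("max_count" %in% names(x)) x$max_count else x$count
  pp <- if ("min_p" %in% names(x)) x$min_p else x$p
  writeLines(io_header(list(format = "bed6+")), path)
  bed <- tibble(chrom = x$chrom,
                start = format(x$start, scientific = FALSE, trim = TRUE),
                end = format(x$end, scientific = FALSE, trim = TRUE),
                id = id, count = cnt, p = pp)
  readr::write_tsv(bed, path, append = TRUE, col_names = FALSE, progress = FALSE)
  invisible(path)
}
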