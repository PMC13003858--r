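# EMMA-style linear mixed model association engine.
#
# Model: y = m + x b + u + e with var(u) = sigma_u^2 K, var(e) = sigma_e^2 I.
# Variance components are estimated by REML through a single spectral
# decomposition of K and a 1-D search over the heritability ratio
# h = sigma_u^2 / (sigma_u^2 + sigma_e^2). Association scans fix the null
# variance components per trait and test each SNP by generalized least
# squares with a Wald F statistic on (1, n - q) degrees of freedom
# (EMMAX-style approximation; an exact mode re-fits REML per SNP).

#' Genotype-based kinship matrix
#'
#' `K = Z Z' / c` with `Z` the column-centered genotype matrix (missing codes
#' mean-imputed per SNP for this computation only) and `c` chosen so that
#' `trace(K)/n = 1`, the standardization under which the variance ratio is
#' interpretable as heritability.
#'
#' @param geno A [genotype_matrix()] with at least 2 strains and 1 SNP.
#' @return An n x n symmetric matrix of class `kinship_matrix` with strain
#'   dimnames, positive semi-definite, `trace(K)/n = 1`.
#' @export
compute_kinship <- function(geno) {
  g <- geno$codes
  if (nrow(g) < 2) stop_input("kinship needs at least 2 strains")
  if (ncol(g) < 1) stop_input("kinship needs at least 1 SNP")
  mu <- colMeans(g, na.rm = TRUE)
  z <- sweep(g, 2, mu, "-")
  z[is.na(z)] <- 0                      # mean imputation after centering
  K <- tcrossprod(z)
  tr <- sum(diag(K))
  if (tr <= 0) stop_invariant("all SNPs are monomorphic; kinship cannot be standardized")
  K <- K * nrow(g) / tr
  dimnames(K) <- list(rownames(g), rownames(g))
  class(K) <- c("kinship_matrix", class(K))
  K
}

kin_eigen <- function(K) {
  e <- eigen(unclass(K), symmetric = TRUE)
  e$values <- pmax(e$values, 0)
  e
}

# restricted log-likelihood of the transformed model at ratio h,
# profiled over the total variance. yt, Xt live in the eigenbasis of K.
reml_loglik_h <- function(h, yt, Xt, s, ldXX) {
  n <- length(yt); q <- ncol(Xt)
  w <- 1 / (h * s + (1 - h))
  if (q == 1) {                      # intercept-only fast path (scalar algebra)
    x <- Xt[, 1]
    a <- sum(x * x * w)
    bhat <- sum(x * yt * w) / a
    r <- yt - x * bhat
    rss <- sum(w * r^2)
    sigma2 <- rss / (n - 1)
    return(-0.5 * ((n - 1) * (log(2 * pi * sigma2) + 1) - sum(log(w)) +
                     log(a) - ldXX))
  }
  A <- crossprod(Xt, Xt * w)
  bhat <- solve(A, crossprod(Xt, yt * w))
  r <- yt - Xt %*% bhat
  rss <- sum(w * r^2)
  sigma2 <- rss / (n - q)
  -0.5 * ((n - q) * (log(2 * pi * sigma2) + 1) - sum(log(w)) +
            as.numeric(determinant(A, logarithm = TRUE)$modulus) - ldXX)
}

#' REML fit of the null mixed model
#'
#' Maximizes the restricted likelihood of `y = X alpha + u + e` over the
#' heritability ratio `h` in `[1e-6, 1 - 1e-6]` using one spectral
#' decomposition of K, a coarse grid, and bounded 1-D refinement (so the
#' 1-D profile cannot trap the optimizer in a local mode).
#'
#' @param y Named numeric trait vector (names = strains), finite on >= 3
#'   strains.
#' @param K Kinship matrix covering the strains of `y`.
#' @param X Optional fixed-effect design matrix (default intercept only).
#' @param eig Optional precomputed `eigen(K)` (internal reuse).
#' @return An object of class `lmm_fit`: mean/fixed effects, variance
#'   components `sigma_u_sq`, `sigma_e_sq`, their ratio `delta`, heritability
#'   `h2`, the restricted log-likelihood, and a convergence flag
#'   (`"converged"` or `"boundary"`).
#' @export
reml_fit_null <- function(y, K, X = NULL, eig = NULL) {
  if (!is.null(names(y))) {
    keep <- names(y)[!is.na(y)]
    y <- y[keep]
    K <- unclass(K)[keep, keep, drop = FALSE]
    if (!is.null(X)) X <- X[keep, , drop = FALSE]
    eig <- NULL
  } else if (anyNA(y)) {
    keep <- which(!is.na(y))
    y <- y[keep]
    K <- unclass(K)[keep, keep, drop = FALSE]
    if (!is.null(X)) X <- X[keep, , drop = FALSE]
    eig <- NULL
  }
  n <- length(y)
  if (n < 3) stop_input("REML needs at least 3 strains with observed trait values")
  if (sd(y) == 0) abort("constant_trait: trait has zero variance",
                        class = c("hotspotqtl_constant_trait", "hotspotqtl_error"))
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  if (is.null(eig)) eig <- kin_eigen(K)
  yt <- crossprod(eig$vectors, y)
  Xt <- crossprod(eig$vectors, X)
  s <- eig$values
  ldXX <- determinant(crossprod(X), logarithm = TRUE)$modulus

  lo <- 1e-6; hi <- 1 - 1e-6
  grid <- seq(lo, hi, length.out = 64)
  ll_grid <- vapply(grid, reml_loglik_h, numeric(1), yt = yt, Xt = Xt, s = s, ldXX = ldXX)
  i <- which.max(ll_grid)
  bracket <- c(grid[max(1, i - 1)], grid[min(length(grid), i + 1)])
  opt <- optimize(reml_loglik_h, interval = bracket, maximum = TRUE,
                  tol = .Machine$double.eps^0.5,
                  yt = yt, Xt = Xt, s = s, ldXX = ldXX)
  h <- opt$maximum
  ll <- opt$objective
  if (ll_grid[i] > ll) { h <- grid[i]; ll <- ll_grid[i] }

  d <- h * s + (1 - h)
  w <- 1 / d
  A <- crossprod(Xt, Xt * w)
  bhat <- drop(solve(A, crossprod(Xt, yt * w)))
  rss <- sum(w * (yt - Xt %*% solve(A, crossprod(Xt, yt * w)))^2)
  sigma2 <- rss / (n - ncol(X))
  boundary <- h <= lo + 1e-5 || h >= hi - 1e-5
  structure(list(
    beta = bhat, mean = unname(bhat[1]),
    sigma_u_sq = sigma2 * h, sigma_e_sq = sigma2 * (1 - h),
    delta = (1 - h) / h, h2 = h,
    loglik_reml = as.numeric(ll), n = n,
    converged = TRUE, flag = if (boundary) "boundary" else "converged"
  ), class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("<lmm_fit> n=%d  h2=%.3f  sigma_u^2=%.4g  sigma_e^2=%.4g  REML logLik=%.3f (%s)\n",
              x$n, x$h2, x$sigma_u_sq, x$sigma_e_sq, x$loglik_reml, x$flag))
  invisible(x)
}

#' @export
tidy.lmm_fit <- function(x, ...) {
  tibble(term = names(x$beta), estimate = unname(x$beta))
}

#' @export
glance.lmm_fit <- function(x, ...) {
  tibble(h2 = x$h2, sigma_u_sq = x$sigma_u_sq, sigma_e_sq = x$sigma_e_sq,
         delta = x$delta, logLik = x$loglik_reml, n = x$n, flag = x$flag)
}

trait_matrix <- function(traits) {
  if (inherits(traits, "expression_matrix")) {
    list(values = traits$values, condition = traits$condition)
  } else if (is.matrix(traits)) {
    list(values = traits, condition = NULL)
  } else {
    stop_input("traits must be an expression_matrix or a strains x features matrix")
  }
}

#' Mixed-model association scan
#'
#' For every (trait, SNP) pair, estimates the allele effect by generalized
#' least squares under the trait's null-model variance components (variance
#' components re-estimated once per trait; `exact = TRUE` re-fits REML per
#' SNP) and reports a Wald F test with `(1, n - 2)` denominator degrees of
#' freedom. Missing strains are dropped pairwise; SNPs constant after the
#' drop are flagged with a missing p-value.
#'
#' @param traits An [expression_matrix()] or a strains x features numeric
#'   matrix (e.g. percent methylation from [methylation_to_traits()]).
#' @param geno A [genotype_matrix()] (filters already applied).
#' @param K Kinship matrix aligned with the strains.
#' @param class QTL class tag: `"eQTL"`, `"mQTL"` or `"emQTL"`.
#' @param condition Condition tag (`"control"`, `"treated"`, `"delta"`);
#'   defaults to the condition of `traits` when available.
#' @param exact Re-fit REML per SNP instead of the EMMAX-style fixed null
#'   components (slow; for small scans).
#' @return A tibble with columns `feature, predictor, chrom, pos, beta, se,
#'   p, n, class, condition, note`. P-values are floored at the smallest
#'   positive double, so `p` lies in `(0, 1]`.
#' @export
assoc_scan <- function(traits, geno, K, class = c("eQTL", "mQTL", "emQTL"),
                       condition = NULL, exact = FALSE) {
  class <- match.arg(class)
  tm <- trait_matrix(traits)
  if (is.null(condition)) condition <- tm$condition
  if (is.null(condition)) stop_input("condition tag is required")
  condition <- match.arg(condition, CONDITIONS)

  Y <- tm$values
  G <- geno$codes
  strains <- rownames(Y)
  if (!identical(strains, rownames(G)) || !identical(strains, rownames(unclass(K)))) {
    common <- Reduce(intersect, list(strains, rownames(G), rownames(unclass(K))))
    if (!length(common)) stop_input("traits, genotypes and kinship share no strains")
    common <- sort(common)
    Y <- Y[common, , drop = FALSE]
    G <- G[common, , drop = FALSE]
    K <- unclass(K)[common, common, drop = FALSE]
  }
  n_snp <- ncol(G); n_trait <- ncol(Y)
  if (n_snp == 0 || n_trait == 0) stop_input("empty scan: no SNPs or no traits")

  snp_na <- colSums(is.na(G))
  beta_m <- se_m <- p_m <- matrix(NA_real_, n_trait, n_snp)
  n_m <- matrix(NA_integer_, n_trait, n_snp)
  note_m <- matrix(NA_character_, n_trait, n_snp)

  # group traits by missingness pattern so K is decomposed once per pattern
  obs <- !is.na(Y)
  pattern_key <- apply(obs, 2, function(z) paste(which(z), collapse = ","))
  for (key in unique(pattern_key)) {
    jj <- which(pattern_key == key)
    idx <- which(obs[, jj[1]])
    n <- length(idx)
    if (n < 3) { note_m[jj, ] <- "insufficient_strains"; next }
    Ksub <- unclass(K)[idx, idx, drop = FALSE]
    eig <- kin_eigen(Ksub)
    U <- eig$vectors; s <- eig$values
    Gsub <- G[idx, , drop = FALSE]
    sub_na <- colSums(is.na(Gsub))
    complete_snps <- which(sub_na == 0)
    na_snps <- which(sub_na > 0)
    G0 <- Gsub
    if (length(na_snps)) G0[is.na(G0)] <- 0   # NA-bearing columns handled below
    Gt <- crossprod(U, G0)
    at <- crossprod(U, rep(1, n))

    for (j in jj) {
      y <- Y[idx, j]
      fit <- tryCatch(
        reml_fit_null(unname(y), Ksub, eig = eig),
        hotspotqtl_constant_trait = function(e) NULL)
      if (is.null(fit)) { note_m[j, ] <- "constant_trait"; next }
      d <- fit$h2 * s + (1 - fit$h2)
      sw <- 1 / sqrt(d)
      yt <- drop(crossprod(U, y)) * sw
      av <- drop(at) * sw
      aa <- sum(av^2); ay <- sum(av * yt); yy <- sum(yt^2)
      if (exact) {
        for (k in seq_len(n_snp)) {
          res <- exact_snp_test(y, Gsub[, k], Ksub)
          beta_m[j, k] <- res$beta; se_m[j, k] <- res$se
          p_m[j, k] <- res$p; n_m[j, k] <- res$n; note_m[j, k] <- res$note
        }
        next
      }
      if (length(complete_snps)) {
        Gw <- Gt[, complete_snps, drop = FALSE] * sw
        ag <- drop(crossprod(Gw, av))
        gy <- drop(crossprod(Gw, yt))
        gg <- colSums(Gw^2)
        gpg <- gg - ag^2 / aa
        gpy <- gy - ag * ay / aa
        ypy <- yy - ay^2 / aa
        ok <- gpg > 1e-10 * n
        b <- gpy / gpg
        rssnum <- pmax(ypy - b^2 * gpg, 0)
        df <- n - 2
        se <- sqrt(rssnum / df / gpg)
        pv <- p_floor(pf((b / se)^2, 1, df, lower.tail = FALSE))
        b[!ok] <- NA_real_; se[!ok] <- NA_real_; pv[!ok] <- NA_real_
        beta_m[j, complete_snps] <- b
        se_m[j, complete_snps] <- se
        p_m[j, complete_snps] <- pv
        n_m[j, complete_snps] <- n
        if (any(!ok)) note_m[j, complete_snps[!ok]] <- "constant_predictor"
      }
      for (k in na_snps) {
        res <- gls_snp_test(y, Gsub[, k], Ksub, fit$h2)
        beta_m[j, k] <- res$beta; se_m[j, k] <- res$se
        p_m[j, k] <- res$p; n_m[j, k] <- res$n; note_m[j, k] <- res$note
      }
    }
  }

  tibble(
    feature = rep(colnames(Y), times = n_snp),
    predictor = rep(colnames(G), each = n_trait),
    chrom = rep(geno$snps$chrom, each = n_trait),
    pos = rep(geno$snps$pos, each = n_trait),
    beta = as.vector(beta_m), se = as.vector(se_m), p = as.vector(p_m),
    n = as.vector(n_m), class = class, condition = condition,
    note = as.vector(note_m)
  )
}

# GLS Wald test for one SNP with pairwise-complete strains, variance ratio
# fixed at the trait's null-model estimate (K sub-matrix not re-standardized).
gls_snp_test <- function(y, g, K, h) {
  keep <- which(!is.na(g) & !is.na(y))
  n <- length(keep)
  if (n < 3) return(list(beta = NA_real_, se = NA_real_, p = NA_real_, n = n,
                         note = "insufficient_strains"))
  g <- g[keep]; y <- y[keep]
  if (sd(g) == 0) return(list(beta = NA_real_, se = NA_real_, p = NA_real_, n = n,
                              note = "constant_predictor"))
  V <- h * K[keep, keep, drop = FALSE] + (1 - h) * diag(n)
  R <- chol(V)
  X <- cbind(1, g)
  Xw <- backsolve(R, X, transpose = TRUE)
  yw <- backsolve(R, y, transpose = TRUE)
  A <- crossprod(Xw)
  bhat <- solve(A, crossprod(Xw, yw))
  r <- yw - Xw %*% bhat
  df <- n - 2
  sigma2 <- sum(r^2) / df
  se <- sqrt(sigma2 * solve(A)[2, 2])
  Fstat <- (bhat[2] / se)^2
  list(beta = bhat[2], se = se, p = p_floor(pf(Fstat, 1, df, lower.tail = FALSE)),
       n = n, note = NA_character_)
}

# exact mode: REML re-fit with the SNP in the design
exact_snp_test <- function(y, g, K) {
  keep <- which(!is.na(g) & !is.na(y))
  n <- length(keep)
  if (n < 4) return(list(beta = NA_real_, se = NA_real_, p = NA_real_, n = n,
                         note = "insufficient_strains"))
  g <- g[keep]; y <- y[keep]
  if (sd(g) == 0) return(list(beta = NA_real_, se = NA_real_, p = NA_real_, n = n,
                              note = "constant_predictor"))
  Ksub <- K[keep, keep, drop = FALSE]
  X <- cbind(`(Intercept)` = 1, snp = g)
  fit <- reml_fit_null(unname(y), Ksub, X = X)
  res <- gls_snp_test(y, g, Ksub, fit$h2)
  res
}

#' Treatment-minus-control expression contrast
#'
#' Forms the per-strain, per-gene difference `treated - control` (the delta
#' condition, used as a trait in its own right). Strains present in only one
#' condition are dropped; the gene sets must match.
#'
#' @param control,treated [expression_matrix()] objects with identical genes.
#' @return An [expression_matrix()] with `condition = "delta"`.
#' @export
delta_traits <- function(control, treated) {
  if (!setequal(control$genes$gene_id, treated$genes$gene_id)) {
    only_c <- setdiff(control$genes$gene_id, treated$genes$gene_id)
    only_t <- setdiff(treated$genes$gene_id, control$genes$gene_id)
    stop_input(sprintf(
      "gene sets differ between conditions (only in control: %s; only in treated: %s)",
      paste(head(only_c, 5), collapse = ","), paste(head(only_t, 5), collapse = ",")))
  }
  shared <- sort(intersect(strain_ids(control), strain_ids(treated)))
  if (!length(shared)) stop_input("no strain shared between control and treated")
  genes <- control$genes
  d <- treated$values[shared, genes$gene_id, drop = FALSE] -
    control$values[shared, genes$gene_id, drop = FALSE]
  expression_matrix(d, genes, "delta")
}

#' Percent-methylation traits for mQTL scans
#'
#' Converts depth-filtered counts to percent methylation
#' (`100 * meth / total`) per strain; masked cells propagate as missing.
#' With `logit = TRUE`, returns the empirical logit with a 0.5 pseudo-count
#' on both counts instead.
#'
#' @param meth A depth-filtered [methylation_counts()].
#' @param logit Use the empirical logit scale (default `FALSE`).
#' @return A strains x CpGs numeric matrix suitable as `traits` for
#'   [assoc_scan()] with `class = "mQTL"`.
#' @export
methylation_to_traits <- function(meth, logit = FALSE) {
  if (logit) {
    log((meth$meth + 0.5) / (meth$total - meth$meth + 0.5))
  } else {
    100 * meth$meth / meth$total
  }
}
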