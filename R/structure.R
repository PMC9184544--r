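# Genotype-matrix container, site filtering, LD pruning, and PCA.

#' Construct a genotype matrix
#'
#' Biallelic-SNV dosage container: variants as rows (positions strictly
#' increasing within a contig), samples as columns, dosages in
#' `{0, 1, 2, NA}` plus per-genotype DP and GQ.
#'
#' @param samples Character vector of sample ids.
#' @param variants Data frame with `contig`, `pos` (1-based), `ref`, `alt`.
#' @param dosage,dp,gq Integer matrices, `nrow(variants)` x `length(samples)`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(samples, variants, dosage, dp = NULL, gq = NULL) {
  nv <- nrow(variants); ns <- length(samples)
  dosage <- matrix(as.integer(dosage), nv, ns)
  if (is.null(dp)) dp <- matrix(NA_integer_, nv, ns)
  if (is.null(gq)) gq <- matrix(NA_integer_, nv, ns)
  if (!all(dim(dp) == c(nv, ns)) || !all(dim(gq) == c(nv, ns)))
    stopf("dosage, dp and gq must all be %d x %d", nv, ns)
  if (any(!is.na(dosage) & (dosage < 0L | dosage > 2L)))
    stopf("dosages must be 0, 1, 2 or NA")
  for (ct in unique(variants$contig)) {
    p <- variants$pos[variants$contig == ct]
    if (any(diff(p) <= 0)) stopf("positions must be strictly increasing within contig '%s'", ct)
  }
  colnames(dosage) <- colnames(dp) <- colnames(gq) <- samples
  structure(list(samples = samples, variants = variants, dosage = dosage,
                 dp = dp, gq = gq),
            class = "genotype_matrix")
}

variant_ids <- function(gm) sprintf("%s:%d", gm$variants$contig, gm$variants$pos)

#' Subset a genotype matrix by variant index or id
#'
#' @param gm A [genotype_matrix()].
#' @param keep Logical/integer index over variants, or character ids
#'   (`"contig:pos"`).
#' @return A [genotype_matrix()].
#' @export
subset_variants <- function(gm, keep) {
  if (is.character(keep)) keep <- match(keep, variant_ids(gm))
  genotype_matrix(gm$samples, gm$variants[keep, , drop = FALSE],
                  gm$dosage[keep, , drop = FALSE],
                  gm$dp[keep, , drop = FALSE], gm$gq[keep, , drop = FALSE])
}

#' Site-level filters before LD pruning and PCA
#'
#' Retains sites with minor allele count at least `min_mac`, a fraction of
#' missing genotypes at most `max_missing` (default 0: no missing data), and
#' a mean depth within `depth_band` standard deviations of the across-site
#' mean depth.
#'
#' @param gm A [genotype_matrix()].
#' @param min_mac Minimum minor allele count (default 1, i.e. polymorphic).
#' @param max_missing Maximum fraction of missing genotypes per site
#'   (default 0).
#' @param depth_band Width of the allowed mean-depth band in SDs (default 1);
#'   `Inf` disables the depth filter.
#' @return A filtered [genotype_matrix()] (possibly empty, with a warning).
#' @export
site_filter <- function(gm, min_mac = 1L, max_missing = 0, depth_band = 1) {
  stopifnot(inherits(gm, "genotype_matrix"))
  nv <- nrow(gm$variants)
  if (nv == 0L) return(gm)
  miss_frac <- rowMeans(is.na(gm$dosage))
  alt_count <- rowSums(gm$dosage, na.rm = TRUE)
  called <- rowSums(!is.na(gm$dosage))
  mac <- pmin(alt_count, 2L * called - alt_count)
  keep <- miss_frac <= max_missing & mac >= min_mac
  if (is.finite(depth_band)) {
    mean_dp <- rowMeans(gm$dp)
    mu <- mean(mean_dp); sdv <- stats::sd(mean_dp)
    if (is.na(sdv)) sdv <- 0
    keep <- keep & abs(mean_dp - mu) <= depth_band * sdv
  }
  if (!any(keep)) warning("site_filter retained no sites")
  subset_variants(gm, keep)
}

#' Prune variants in linkage disequilibrium
#'
#' Within each window of `window_bp` base pairs (windows advance by
#' `step_variants` retained variants), the squared Pearson correlation
#' between dosage vectors is computed for every pair; while any pair exceeds
#' `r2_max`, the member with the lower minor allele frequency is removed
#' (ties remove the higher position).  Sweeps repeat until no window changes.
#' Missing dosages are mean-imputed for the correlation only; constant
#' vectors have r2 defined as 0.  Deterministic, and independent of sample
#' order.
#'
#' @param gm A [genotype_matrix()].
#' @param window_bp Window span in bp (default 50,000).
#' @param step_variants Window step in retained variants (default 5).
#' @param r2_max Pruning threshold on r2 (default 0.5).
#' @return Character vector of retained variant ids (`"contig:pos"`).
#' @export
ld_prune <- function(gm, window_bp = 50000L, step_variants = 5L, r2_max = 0.5) {
  stopifnot(inherits(gm, "genotype_matrix"))
  ids <- variant_ids(gm)
  keep <- rep(TRUE, length(ids))
  X <- impute_means(t(gm$dosage))        # samples x variants
  af <- colMeans(X) / 2
  maf <- pmin(af, 1 - af)
  for (ct in unique(gm$variants$contig)) {
    in_ct <- which(gm$variants$contig == ct)
    pos <- gm$variants$pos[in_ct]
    repeat {
      changed <- FALSE
      alive <- in_ct[keep[in_ct]]
      if (length(alive) < 2L) break
      apos <- gm$variants$pos[alive]
      p <- 1L
      while (p <= length(alive)) {
        if (!keep[alive[p]]) { p <- p + step_variants; next }
        win <- alive[apos >= apos[p] & apos < apos[p] + window_bp & keep[alive]]
        if (length(win) >= 2L) {
          R2 <- suppressWarnings(stats::cor(X[, win, drop = FALSE]))^2
          R2[!is.finite(R2)] <- 0
          loc_alive <- rep(TRUE, length(win))
          for (i in seq_len(length(win) - 1L)) {
            if (!loc_alive[i]) next
            for (j in which(loc_alive & R2[i, ] > r2_max & seq_along(win) > i)) {
              if (!loc_alive[i]) break
              if (!loc_alive[j]) next
              vi <- win[i]; vj <- win[j]
              drop <- if (maf[vi] < maf[vj]) i
              else if (maf[vj] < maf[vi]) j
              else j                      # tie: higher position goes
              loc_alive[drop] <- FALSE
              keep[win[drop]] <- FALSE
              changed <- TRUE
            }
          }
        }
        p <- p + step_variants
      }
      if (!changed) break
    }
  }
  ids[keep]
}

impute_means <- function(X) {
  X <- matrix(as.numeric(X), nrow(X), ncol(X))
  nas <- which(is.na(X), arr.ind = TRUE)
  if (nrow(nas)) {
    cm <- colMeans(X, na.rm = TRUE)
    X[nas] <- cm[nas[, 2]]
  }
  X
}

#' PCA of a genotype matrix
#'
#' Each variant's dosages are centered at twice the allele frequency and
#' scaled by `sqrt(2 p (1 - p))` (the standard genotype-PCA variance
#' standardisation; `scale = "unit"` switches to unit variance), then the
#' sample covariance is eigendecomposed.  Axes are ordered by decreasing
#' eigenvalue; for reproducible orientation each axis is flipped so that its
#' largest-magnitude variant loading is positive.
#'
#' @param gm A [genotype_matrix()] (typically site-filtered and LD-pruned).
#' @param k Number of axes to return (truncated to the matrix rank, with a
#'   warning).
#' @param scale `"binomial"` (default) or `"unit"`.
#' @return An object of class `pca_result`: `scores` (samples x k, centered),
#'   `eigenvalues`, `var_explained` (percent, all axes, sums to 100),
#'   `loadings`, `k`.
#' @export
pca_genotypes <- function(gm, k = 10L, scale = c("binomial", "unit")) {
  stopifnot(inherits(gm, "genotype_matrix"))
  scale <- match.arg(scale)
  if (length(gm$samples) < 2L || nrow(gm$variants) < 1L)
    stopf("need >= 2 samples and >= 1 variant")
  X <- impute_means(t(gm$dosage))
  p <- colMeans(X) / 2
  sc <- if (scale == "binomial") sqrt(2 * p * (1 - p)) else
    apply(X, 2, stats::sd)
  ok <- sc > 0
  if (!any(ok)) stopf("all variants are monomorphic")
  Xs <- sweep(X[, ok, drop = FALSE], 2, 2 * p[ok], "-")
  Xs <- sweep(Xs, 2, sc[ok], "/")
  pr <- stats::prcomp(Xs, center = FALSE, scale. = FALSE)
  eig <- pr$sdev^2
  rank <- sum(pr$sdev > max(pr$sdev) * 1e-10)
  if (k > rank) {
    warning(sprintf("k = %d exceeds rank %d; truncating", k, rank))
    k <- rank
  }
  scores <- pr$x[, seq_len(k), drop = FALSE]
  load <- pr$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) { load[, j] <- -load[, j]; scores[, j] <- -scores[, j] }
  }
  rownames(scores) <- gm$samples
  structure(list(scores = scores, eigenvalues = eig,
                 var_explained = 100 * eig / sum(eig),
                 loadings = load, k = k),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("Genotype PCA:", nrow(x$scores), "samples,", x$k, "axes;",
      sprintf("PC1 %.1f%%, PC2 %.1f%%\n",
              x$var_explained[1], ifelse(length(x$var_explained) > 1, x$var_explained[2], 0)))
  invisible(x)
}
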