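# Site filters, LD pruning, and genotype PCA.

test_that("site filter drops missing, monomorphic, and depth-outlier sites", {
  # one missing genotype -> dropped; monomorphic -> dropped
  dos <- rbind(c(0L, 1L, NA), c(0L, 0L, 0L), c(0L, 1L, 2L))
  gm <- make_gm(dos)
  kept <- site_filter(gm, depth_band = Inf)
  expect_identical(nrow(kept$variants), 1L)
  expect_identical(kept$variants$pos, 300L)

  # hand-built depth band: 20 sites, two depth outliers
  dos <- matrix(rep(c(0L, 1L, 2L), length.out = 60), 20, 3)
  dp <- matrix(20L, 20, 3)
  dp[1, ] <- 90L          # high outlier
  dp[2, ] <- 1L           # low outlier
  gm2 <- make_gm(dos, dp = dp)
  mean_dp <- rowMeans(dp)
  band <- mean(mean_dp) + c(-1, 1) * stats::sd(mean_dp)
  expected <- which(mean_dp >= band[1] & mean_dp <= band[2])
  kept2 <- site_filter(gm2, depth_band = 1)
  expect_identical(kept2$variants$pos, gm2$variants$pos[expected])
  expect_warning(site_filter(make_gm(matrix(0L, 2, 3))), "no sites")
})

test_that("duplicate variant columns in one window lose exactly one member", {
  dos <- cbind(s1 = c(0L, 0L), s2 = c(1L, 1L), s3 = c(1L, 1L), s4 = c(2L, 2L))
  gm <- make_gm(dos, pos = c(1000L, 2000L))   # 1 kb apart
  kept <- ld_prune(gm)
  expect_length(kept, 1L)

  # 100 kb apart with a 50 kb window: never co-windowed, both kept
  gm2 <- make_gm(dos, pos = c(1000L, 101000L))
  expect_length(ld_prune(gm2), 2L)
})

test_that("the hand-computed r2 pair prunes its lower-MAF member", {
  # x = (0,1,1,2), y = (0,1,1,1): r = 1/sqrt(1.5), r2 = 2/3 > 0.5
  x <- c(0L, 1L, 1L, 2L); y <- c(0L, 1L, 1L, 1L)
  expect_equal(stats::cor(x, y)^2, 2 / 3)
  gm <- make_gm(rbind(x, y), pos = c(500L, 900L))
  kept <- ld_prune(gm, r2_max = 0.5)
  expect_identical(kept, "c1:500")   # y has MAF 3/8 < 1/2, so y is removed
  # below the threshold nothing is pruned
  expect_length(ld_prune(gm, r2_max = 0.7), 2L)
})

test_that("pruning is independent of sample order", {
  set.seed(3)
  dos <- matrix(sample(0:2, 12 * 30, TRUE), 30, 12)
  dos[2, ] <- dos[1, ]                       # one perfect duplicate
  gm <- make_gm(dos, pos = seq(100L, by = 400L, length.out = 30))
  perm <- sample(12)
  gm_p <- genotype_matrix(gm$samples[perm], gm$variants,
                          gm$dosage[, perm], gm$dp[, perm], gm$gq[, perm])
  expect_identical(ld_prune(gm), ld_prune(gm_p))
})

test_that("PCA standardises, centers, and orders axes by variance", {
  # samples a and b identical -> coincide on all axes
  gm2 <- make_gm(cbind(a = c(0L, 1L, 2L), b = c(0L, 1L, 2L), c = c(2L, 1L, 0L),
                       d = c(1L, 2L, 0L)))
  p <- pca_genotypes(gm2, k = 2)
  expect_equal(p$scores["a", ], p$scores["b", ])
  # column means zero (scores centered)
  expect_equal(unname(colMeans(p$scores)), rep(0, ncol(p$scores)), tolerance = 1e-10)
  # variance explained sums to 100 over all axes, decreasing
  expect_equal(sum(p$var_explained), 100)
  expect_true(all(diff(p$eigenvalues) <= 1e-12))
  # sign convention: largest-magnitude loading positive
  for (j in seq_len(p$k)) expect_gte(p$loadings[which.max(abs(p$loadings[, j])), j], 0)
})

test_that("a rank-1 matrix loads everything on PC1 and k is truncated to rank", {
  # variants are copies/mirrors of one sample pattern -> rank 1 after standardisation
  dos <- matrix(c(0L, 1L, 2L, 1L,
                  0L, 1L, 2L, 1L,
                  2L, 1L, 0L, 1L), 3, 4, byrow = TRUE)
  gm <- make_gm(dos)
  expect_warning(p <- pca_genotypes(gm, k = 4), "truncat")
  expect_equal(p$var_explained[1], 100)
  expect_identical(p$k, 1L)
})

test_that("PCA coordinates are sign-stable under variant reordering", {
  set.seed(9)
  dos <- matrix(sample(0:2, 8 * 40, TRUE), 40, 8)
  gm <- make_gm(dos, pos = seq(100L, by = 100L, length.out = 40))
  p1 <- pca_genotypes(gm, k = 3)
  # positions are not used by PCA: permute the variant rows under fresh
  # ascending positions and expect the same sample coordinates up to sign
  ord <- sample(40)
  gm2 <- make_gm(dos[ord, ], pos = gm$variants$pos)
  p2 <- pca_genotypes(gm2, k = 3)
  for (j in 1:3)
    expect_true(isTRUE(all.equal(p1$scores[, j], p2$scores[, j], tolerance = 1e-8)) ||
                isTRUE(all.equal(p1$scores[, j], -p2$scores[, j], tolerance = 1e-8)))
})
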