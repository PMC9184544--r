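# Heterozygosity, segment differences, the normalised distance, and the
# distance-hierarchy classifier.

test_that("heterozygosity is het/callable with strict DP and GQ cut-offs", {
  # 1000 variant genotypes, 3 het, rest hom-ref
  dos <- matrix(0L, 1000, 1); dos[c(10, 20, 30), 1] <- 1L
  gm <- make_gm(dos)
  h <- estimate_heterozygosity(gm, min_depth = 0, min_gq = 0)
  expect_equal(h$h, 0.003)
  expect_identical(h$het_sites, 3L)

  # all homozygous
  gm0 <- make_gm(matrix(rep(c(0L, 2L), 5), 10, 1))
  expect_equal(estimate_heterozygosity(gm0, 0, 0)$h, 0)

  # DP/GQ boundaries: DP 5 fails, DP 6 passes; GQ 17 fails, GQ 18 passes
  dos <- matrix(1L, 4, 1)
  dp <- matrix(c(5L, 6L, 20L, 20L), 4, 1)
  gq <- matrix(c(60L, 60L, 17L, 18L), 4, 1)
  gm2 <- make_gm(dos, dp = dp, gq = gq)
  h2 <- estimate_heterozygosity(gm2)
  expect_identical(h2$callable, 2)
  expect_identical(h2$het_sites, 2L)

  # invariant sites enter only the denominator
  h3 <- estimate_heterozygosity(gm2, n_invariant = 98)
  expect_equal(h3$h, 2 / 100)
  expect_error(estimate_heterozygosity(make_gm(matrix(1L, 1, 1), dp = matrix(0L, 1, 1))),
               "no callable")
})

test_that("heterozygosity recovers the simulator's theta", {
  n <- 300000L
  spec <- species_tree_spec("(A:0);", theta = 0.002)
  sim <- simulate_radiation(sim_config(spec, contig_lengths = n, seed = 19))
  h <- estimate_heterozygosity(sim$genotypes, min_depth = 0, min_gq = 0,
                               n_invariant = n - nrow(sim$genotypes$variants))
  expect_lt(abs(h$h - 0.002), 3 * sqrt(0.002 * 0.998 / n))
})

test_that("segment differences exclude N from both counts", {
  expect_identical(segment_diff("ACGT", "ACGT"), list(a = 0L, S = 4L))
  expect_identical(segment_diff("ACGT", "ACTT"), list(a = 1L, S = 4L))
  expect_identical(segment_diff("ANGT", "ACGA"), list(a = 1L, S = 3L))
  expect_error(segment_diff("ACGT", "ACG"), "length")
})

test_that("the normalised distance averages ratios and scales as designed", {
  nd <- normalized_distance(data.frame(a = c(2, 3), S = c(100, 150)), 0.001, 0.003)
  expect_equal(nd$value, 10, tolerance = 1e-12)
  expect_equal(nd$raw, 0.02)
  expect_identical(nd$n, 2L)

  # symmetry in the pair
  nd_sw <- normalized_distance(data.frame(a = c(2, 3), S = c(100, 150)), 0.003, 0.001)
  expect_equal(nd_sw$value, nd$value)

  # identical sequences -> 0 for any positive h
  expect_equal(normalized_distance(data.frame(a = 0, S = 100), 0.01, 0.02)$value, 0)

  # mean of ratios, not ratio of sums
  d <- data.frame(a = c(1, 10), S = c(10, 1000))
  v <- normalized_distance(d, 0.001, 0.001)$value
  expect_equal(v, mean(c(0.1, 0.01)) / 0.001)
  expect_false(isTRUE(all.equal(v, (11 / 1010) / 0.001)))
  # equal-ratio segments may be merged without changing the value
  eq <- normalized_distance(data.frame(a = c(1, 2), S = c(100, 200)), 0.001, 0.001)
  mg <- normalized_distance(data.frame(a = 3, S = 300), 0.001, 0.001)
  expect_equal(eq$value, mg$value)

  # normalisation scaling: doubling both h halves; doubling a doubles
  base <- normalized_distance(d, 0.002, 0.004)$value
  expect_equal(normalized_distance(d, 0.004, 0.008)$value, base / 2)
  d2 <- data.frame(a = 2 * d$a, S = d$S)
  expect_equal(normalized_distance(d2, 0.002, 0.004)$value, 2 * base)

  # segment-order invariance; S = 0 segments skipped
  expect_equal(normalized_distance(d[2:1, ], 0.001, 0.001)$value, v)
  sk <- normalized_distance(data.frame(a = c(1, 0), S = c(10, 0)), 0.001, 0.001)
  expect_identical(sk$n, 1L)
  expect_identical(sk$n_skipped, 1L)
  expect_error(normalized_distance(data.frame(a = 0, S = 0), 0.001, 0.001), "usable")
  expect_error(normalized_distance(d, 0, 0), "undefined")
})

test_that("conspecific pairs have raw distance near theta and normalised value near 1", {
  spec <- species_tree_spec("(A:0.005,B:0.005);", theta = 0.002, n_individuals = 2)
  sim <- simulate_radiation(sim_config(spec, contig_lengths = 400000, seed = 29))
  seqs <- pseudo_haploidize(sim, seed = 3)
  plan <- plan_segments(sim$contig_lengths, L = 2000, G = 0, seed = 4)
  alns <- extract_alignments(seqs, plan)
  het <- estimate_heterozygosity(sim$genotypes, min_depth = 0, min_gq = 0,
                                 n_invariant = 400000 - nrow(sim$genotypes$variants))
  dd <- pairwise_segment_diffs(alns)
  dist_df <- pairwise_normalized_distances(dd, het)
  ab <- dist_df[dist_df$id1 == "A_1" & dist_df$id2 == "A_2", ]
  expect_lt(abs(ab$raw - 0.002), 3e-4)
  expect_lt(abs(ab$value - 1), 0.15)
  # monotonicity: conspecific < heterospecific
  ax <- dist_df[dist_df$id1 == "A_1" & dist_df$id2 == "B_1", ]
  expect_gt(ax$value, ab$value)
})

test_that("hierarchy strata partition pairs with the expected combinatorics", {
  ids <- paste0(rep(c("X", "Y", "Z"), each = 3), "_", 1:3)
  labels <- stats::setNames(rep(c("X", "Y", "Z"), each = 3), ids)
  pairs <- utils::combn(ids, 2)
  dist_df <- data.frame(id1 = pairs[1, ], id2 = pairs[2, ],
                        value = seq_len(ncol(pairs)))
  hier <- build_hierarchy(dist_df, labels)
  expect_identical(sum(hier$distances$stratum == "within"), 9L)
  expect_identical(sum(hier$distances$stratum == "between"), 27L)

  # single species: no between stratum
  one <- build_hierarchy(dist_df[1:3, ], stats::setNames(rep("X", 9), ids))
  expect_false("between" %in% one$distances$stratum)

  # focal pairs leave the other strata
  hf <- build_hierarchy(dist_df, labels, focal_ids = "X_1")
  expect_identical(sum(hf$distances$stratum == "focal"), 8L)
  expect_identical(sum(hf$distances$stratum == "within"), 7L)

  expect_error(build_hierarchy(dist_df, labels[-1]), "unlabeled")
})

test_that("the focal classifier follows the quantile and margin rules", {
  ids <- c("F", paste0(rep(c("X", "Y"), each = 3), "_", 1:3))
  labels <- stats::setNames(c("F", rep(c("X", "Y"), each = 3)), ids)
  pairs <- utils::combn(ids, 2)
  mk <- function(fx, fy, w, b) {
    v <- numeric(ncol(pairs))
    wi <- 0L
    for (k in seq_len(ncol(pairs))) {
      p <- pairs[, k]
      v[k] <- if ("F" %in% p) (if (any(grepl("^X", p))) fx else fy)
      else if (labels[p[1]] == labels[p[2]]) {
        wi <- wi + 1L
        w[(wi - 1L) %% length(w) + 1L]
      } else b
    }
    build_hierarchy(data.frame(id1 = pairs[1, ], id2 = pairs[2, ], value = v),
                    labels, focal_ids = "F")
  }
  # focal looks intraspecific with X
  a <- classify_focal(mk(fx = 1.0, fy = 6, w = 1.1, b = 6), "F")
  expect_identical(a$decision, "same-lineage")
  expect_identical(a$nearest, "X")
  # focal beyond every within-species value, clear margin
  a2 <- classify_focal(mk(fx = 3, fy = 6, w = 1.1, b = 6), "F")
  expect_identical(a2$decision, "novel")
  # in between: ambiguous (above the q-quantile but not above max within)
  a3 <- classify_focal(mk(fx = 1.15, fy = 6, w = seq(0.9, 1.2, length.out = 6), b = 6),
                       "F", q = 0.5)
  expect_identical(a3$decision, "ambiguous")
  # focal identical to a reference individual
  a4 <- classify_focal(mk(fx = 0, fy = 6, w = 1.1, b = 6), "F")
  expect_identical(a4$decision, "same-lineage")
  expect_identical(a4$min_distance, 0)
})
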