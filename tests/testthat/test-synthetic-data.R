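# The radiation simulator: calibration against closed-form oracles,
# determinism, and the missing-data run process.

test_that("zero branch lengths and zero theta give identical haplotypes everywhere", {
  spec <- species_tree_spec("((A:0,B:0):0,C:0);", theta = 0, n_individuals = 2)
  sim <- simulate_radiation(sim_config(spec, contig_lengths = 5000, seed = 3))
  ref <- sim$reference$contig_1
  for (id in sim$individuals$id) {
    expect_identical(sim$haplotypes[[id]]$contig_1[1], ref)
    expect_identical(sim$haplotypes[[id]]$contig_1[2], ref)
  }
  expect_identical(nrow(sim$genotypes$variants), 0L)
})

test_that("realized heterozygous-site count is binomial around theta", {
  n <- 300000L
  theta <- 0.002
  spec <- species_tree_spec("(A:0);", theta = theta)
  sim <- simulate_radiation(sim_config(spec, contig_lengths = n, seed = 7))
  h <- sim$haplotypes$A_1$contig_1
  het <- sum(charToRaw(h[1]) != charToRaw(h[2]))
  band <- 3 * sqrt(n * theta * (1 - theta))
  expect_lt(abs(het - n * theta), band)
})

test_that("inter-species mismatch matches the JC69 closed form", {
  n <- 300000L
  spec <- species_tree_spec("(A:0.005,B:0.005);", theta = 0)
  sim <- simulate_radiation(sim_config(spec, contig_lengths = n, seed = 11))
  a <- charToRaw(sim$haplotypes$A_1$contig_1[1])
  b <- charToRaw(sim$haplotypes$B_1$contig_1[1])
  p_exp <- jc_expected(0.01)               # ~0.009934
  mism <- sum(a != b)
  band <- 3 * sqrt(n * p_exp * (1 - p_exp))
  expect_lt(abs(mism - n * p_exp), band)
})

test_that("simulation is deterministic under the seed and validates its config", {
  cfg <- sim_config(demo_spec(), contig_lengths = 20000, p_ils = 0.3,
                    block_length = 2000, missing_rate = 0.05, seed = 5)
  expect_identical(simulate_radiation(cfg), simulate_radiation(cfg))
  expect_error(species_tree_spec("(A:0.1,B:0.1);", theta = 0.8), "theta")
  expect_error(species_tree_spec("(A:-0.1,B:0.1);", theta = 0.1), "branch length")
  expect_error(sim_config(demo_spec(), contig_lengths = 1000, missing_rate = 1),
               "missing_rate")
})

test_that("p_ils = 0 records the species topology for every segment", {
  spec <- demo_spec()
  sim <- simulate_radiation(sim_config(spec, contig_lengths = 30000, seed = 2))
  expect_true(all(sim$truth$segments$topology == ape::write.tree(spec$tree)))
})

test_that("p_ils > 0 produces NNI-discordant segment topologies at about the stated rate", {
  spec <- species_tree_spec("(((A:0.01,B:0.01):0.01,C:0.02):0.01,D:0.03);",
                            theta = 0.001)
  cfg <- sim_config(spec, contig_lengths = 400000, p_ils = 0.25,
                    block_length = 2000, seed = 13)
  sim <- simulate_radiation(cfg)
  segs <- sim$truth$segments
  frac <- mean(segs$topology != ape::write.tree(spec$tree))
  expect_lt(abs(frac - 0.25), 3 * sqrt(0.25 * 0.75 / nrow(segs)))
  # every discordant topology is still a tree over the same species
  for (nwk in unique(segs$topology)) {
    tr <- ape::read.tree(text = nwk)
    expect_setequal(tr$tip.label, spec$tree$tip.label)
  }
})

test_that("pseudo-haploid collapse: homozygous identity, fair coin at hets, determinism", {
  # all-homozygous individual: output equals either haplotype
  s <- strrep("ACGT", 25)
  gs <- make_genome_set(c(c1 = s), c(c1 = s))
  expect_identical(pseudo_haploidize(gs, seed = 1)$X_1[["c1"]], s)

  # fully heterozygous individual: ~half the sites match haplotype 1
  n <- 10000L
  h1 <- strrep("A", n); h2 <- strrep("C", n)
  gs <- make_genome_set(c(c1 = h1), c(c1 = h2))
  out <- pseudo_haploidize(gs, seed = 42)$X_1[["c1"]]
  frac1 <- mean(charToRaw(out) == charToRaw("A"))
  expect_lt(abs(frac1 - 0.5), 3 * sqrt(0.25 / n))

  # same seed -> identical output; masked sites -> N
  expect_identical(pseudo_haploidize(gs, seed = 42)$X_1, pseudo_haploidize(gs, seed = 42)$X_1)
  gs2 <- make_genome_set(c(c1 = h1), c(c1 = h1),
                         mask = list(c1 = data.frame(start = 10L, end = 20L)))
  out2 <- pseudo_haploidize(gs2, seed = 1)$X_1[["c1"]]
  expect_identical(substr(out2, 11, 20), strrep("N", 10))
  expect_identical(substr(out2, 1, 10), strrep("A", 10))
})

test_that("missingness: rate 0 is identity, N fraction calibrated, runs independent at run_length 1", {
  s <- c(x = strrep("ACGT", 25000))     # 100,000 sites
  expect_identical(apply_missingness(s, rate = 0, seed = 1), s)
  expect_error(apply_missingness(s, rate = 1), "rate")

  rate <- 0.1; rl <- 50
  out <- apply_missingness(s, rate = rate, run_length = rl, seed = 8)
  isN <- charToRaw(out[[1]]) == charToRaw("N")
  n <- length(isN)
  # autocorrelated run process: SD inflated by ~sqrt(2*run_length - 1)
  band <- 3 * sqrt(n * rate * (1 - rate) * (2 * rl - 1))
  expect_lt(abs(sum(isN) - n * rate), band)

  out1 <- apply_missingness(s, rate = rate, run_length = 1, seed = 9)
  isN <- charToRaw(out1[[1]]) == charToRaw("N")
  n1 <- sum(isN); n0 <- sum(!isN)
  runs <- 1L + sum(isN[-1] != isN[-length(isN)])
  mu <- 1 + 2 * n1 * n0 / (n1 + n0)
  v <- 2 * n1 * n0 * (2 * n1 * n0 - n1 - n0) /
    ((n1 + n0)^2 * (n1 + n0 - 1))
  z <- (runs - mu) / sqrt(v)
  expect_lt(abs(z), 4)   # Wald-Wolfowitz runs test, fixed seed
})

test_that("simulated genotype matrix matches a direct haplotype scan", {
  spec <- demo_spec()
  sim <- simulate_radiation(sim_config(spec, contig_lengths = 20000, seed = 21))
  gm <- sim$genotypes
  # direct scan oracle: biallelic-with-ref polymorphic sites
  ref <- charToRaw(sim$reference$contig_1)
  haps <- do.call(rbind, lapply(sim$individuals$id, function(id)
    rbind(charToRaw(sim$haplotypes[[id]]$contig_1[1]),
          charToRaw(sim$haplotypes[[id]]$contig_1[2]))))
  poly <- which(vapply(seq_along(ref), function(j) {
    al <- unique(haps[, j])
    length(al) == 2L && ref[j] %in% al
  }, TRUE))
  expect_identical(gm$variants$pos, as.integer(poly))
  # spot-check dosages at the first variant
  j <- gm$variants$pos[1]
  alt <- charToRaw(gm$variants$alt[1])
  for (i in seq_along(gm$samples)) {
    expected <- sum(haps[c(2 * i - 1, 2 * i), j] == alt)
    expect_identical(unname(gm$dosage[1, i]), as.integer(expected))
  }
})
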