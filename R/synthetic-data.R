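#' Specify the species tree of a simulated radiation
#'
#' Bundles the rooted species topology with per-species diversity and sampling
#' depth.  Branch lengths are in expected substitutions per site; `theta` is
#' the expected per-site heterozygosity of individuals of that species (the
#' probability that an individual's two haplotypes differ at a site).
#'
#' @param tree A rooted `phylo` object with branch lengths, or a Newick string.
#'   A single-species world can be written as `"(A:0);"`.
#' @param theta Per-species expected per-site heterozygosity, a scalar or a
#'   vector named by species.  Must lie in `[0, 0.75)`.
#' @param n_individuals Number of sampled individuals per species (scalar or
#'   named vector), each `>= 1`.
#' @return An object of class `species_tree_spec`.
#' @examples
#' species_tree_spec("((A:0.005,B:0.005):0.005,C:0.01);", theta = 0.002,
#'                   n_individuals = 2)
#' @export
species_tree_spec <- function(tree, theta, n_individuals = 1L) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  if (!inherits(tree, "phylo")) stopf("`tree` must be a phylo object or Newick string")
  if (!ape::is.rooted(tree)) stopf("species tree must be rooted")
  if (is.null(tree$edge.length)) stopf("species tree must have branch lengths")
  if (any(tree$edge.length < 0)) stopf("branch lengths must be >= 0")
  sp <- tree$tip.label
  if (anyDuplicated(sp)) stopf("species labels must be unique")
  theta <- rep_named(theta, sp, "theta")
  n_individuals <- rep_named(as.integer(n_individuals), sp, "n_individuals")
  if (any(theta < 0 | theta >= 0.75)) stopf("theta must lie in [0, 0.75)")
  if (any(n_individuals < 1L)) stopf("every species needs >= 1 individual")
  structure(list(tree = tree, theta = theta, n_individuals = n_individuals),
            class = "species_tree_spec")
}

#' Configure a radiation simulation
#'
#' All knobs of the generative model in one validated object.  The model: an
#' ancestral sequence is drawn from `base_comp`; it evolves down the species
#' tree under JC69; within each species every individual's two haplotypes
#' differ independently per site with probability `theta`; when `p_ils > 0`
#' each genome block of `block_length` bp evolves, with that probability,
#' under a random nearest-neighbor-interchange of the species topology
#' (a cheap stand-in for incomplete lineage sorting).  Missing data occur in
#' geometric runs (see [apply_missingness()]).
#'
#' @param species A [species_tree_spec()].
#' @param contig_lengths Integer vector of contig lengths in bp (named or not).
#' @param base_comp Probabilities of A, C, G, T in the ancestral sequence.
#' @param p_ils Per-block probability that the local gene tree is a random
#'   NNI rearrangement of the species tree.
#' @param block_length Length in bp of the independently evolving blocks used
#'   when `p_ils > 0`.
#' @param missing_rate Expected fraction of masked (N) sites per individual.
#' @param missing_run_length Mean length scale of masked runs, bp (see
#'   [apply_missingness()] for the exact parameterisation).
#' @param depth_mean Mean of the Poisson read-depth (DP) simulated per genotype.
#' @param gq_mean,gq_sd Mean and SD of the (rounded, clamped to 0..99) normal
#'   genotype-quality (GQ) simulated per genotype.
#' @param seed Integer seed; fixing it makes every output byte-identical.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(species, contig_lengths,
                       base_comp = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3),
                       p_ils = 0, block_length = 10000L,
                       missing_rate = 0, missing_run_length = 100,
                       depth_mean = 20, gq_mean = 60, gq_sd = 15,
                       seed = 1L) {
  if (!inherits(species, "species_tree_spec")) stopf("`species` must be a species_tree_spec")
  contig_lengths <- stats::setNames(as.integer(contig_lengths), names(contig_lengths))
  if (any(contig_lengths <= 0L)) stopf("contig lengths must be > 0")
  if (is.null(names(contig_lengths)))
    names(contig_lengths) <- paste0("contig_", seq_along(contig_lengths))
  base_comp <- as.numeric(base_comp)
  if (length(base_comp) != 4L || any(base_comp < 0) || abs(sum(base_comp) - 1) > 1e-8)
    stopf("base_comp must be 4 probabilities summing to 1")
  if (p_ils < 0 || p_ils > 1) stopf("p_ils must lie in [0, 1]")
  if (missing_rate < 0 || missing_rate >= 1) stopf("missing_rate must lie in [0, 1)")
  if (missing_run_length < 1) stopf("missing_run_length must be >= 1")
  if (block_length < 1) stopf("block_length must be >= 1")
  structure(list(species = species, contig_lengths = contig_lengths,
                 base_comp = base_comp, p_ils = p_ils,
                 block_length = as.integer(block_length),
                 missing_rate = missing_rate,
                 missing_run_length = missing_run_length,
                 depth_mean = depth_mean, gq_mean = gq_mean, gq_sd = gq_sd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Depth-first (preorder) edge ordering from the root; robust to edge
# matrices in arbitrary row order (reorder.phylo assumes too much).
preorder_edges <- function(tree) {
  e <- tree$edge
  ntip <- length(tree$tip.label)
  children <- split(seq_len(nrow(e)), e[, 1])
  out <- integer(0)
  stack <- ntip + 1L
  while (length(stack)) {
    nd <- stack[length(stack)]
    stack <- stack[-length(stack)]
    rows <- children[[as.character(nd)]]
    if (!is.null(rows)) {
      out <- c(out, rows)
      stack <- c(stack, e[rows, 2])
    }
  }
  out
}

# One random nearest-neighbor interchange of a rooted binary tree: pick an
# edge whose child is internal, then swap one grandchild with its "uncle".
rnni_rooted <- function(tree) {
  e <- tree$edge
  ntip <- length(tree$tip.label)
  cand <- which(e[, 2] > ntip)
  if (!length(cand)) return(tree)
  k <- cand[sample.int(length(cand), 1L)]
  p <- e[k, 1]; ch <- e[k, 2]
  kids <- which(e[, 1] == ch)
  sib <- setdiff(which(e[, 1] == p), k)
  if (length(sib) != 1L || length(kids) != 2L) return(tree)
  swap <- kids[sample.int(2L, 1L)]
  tree$edge[swap, 1] <- p
  tree$edge[sib, 1] <- ch
  ord <- preorder_edges(tree)
  tree$edge <- tree$edge[ord, , drop = FALSE]
  tree$edge.length <- tree$edge.length[ord]
  attr(tree, "order") <- "cladewise"
  tree
}

# Evolve a raw ancestral sequence down a rooted tree under JC69; returns a
# named list of tip sequences (raw vectors).  Consumes RNG.
evolve_raw <- function(tree, anc) {
  ntip <- length(tree$tip.label)
  seqs <- vector("list", ntip + tree$Nnode)
  seqs[[ntip + 1L]] <- anc
  e <- tree$edge
  el <- tree$edge.length
  for (k in preorder_edges(tree))
    seqs[[e[k, 2]]] <- mutate_sites(seqs[[e[k, 1]]], jc_mismatch(el[k]))
  stats::setNames(seqs[seq_len(ntip)], tree$tip.label)
}

# Stationary two-state Markov chain of missing runs.  P(miss) = rate exactly;
# runs of missing state are geometric with mean run_length/(1-rate), so
# run_length = 1 makes sites exactly independent.  Returns 0-based half-open
# intervals.  Consumes RNG.
missing_runs <- function(len, rate, run_length) {
  empty <- data.frame(start = integer(), end = integer())
  if (rate <= 0) return(empty)
  if (rate >= 1) stopf("missing rate must be < 1")
  p_enter <- rate / run_length        # leave good state
  p_leave <- (1 - rate) / run_length  # leave missing state
  if (p_enter > 1 || p_leave > 1) stopf("missing_run_length too small for this rate")
  cycle <- 1 / p_enter + 1 / p_leave
  miss_first <- stats::runif(1) < rate
  runs_g <- integer(0); runs_m <- integer(0); total <- 0
  while (total < len) {
    k <- max(16L, ceiling((len - total) / cycle * 1.5))
    runs_g <- c(runs_g, 1L + stats::rgeom(k, p_enter))
    runs_m <- c(runs_m, 1L + stats::rgeom(k, p_leave))
    total <- sum(runs_g) + sum(runs_m)
  }
  n <- min(length(runs_g), length(runs_m))
  if (miss_first) {
    lens <- as.vector(rbind(runs_m[seq_len(n)], runs_g[seq_len(n)]))
    miss_idx <- seq(1L, 2L * n, by = 2L)
  } else {
    lens <- as.vector(rbind(runs_g[seq_len(n)], runs_m[seq_len(n)]))
    miss_idx <- seq(2L, 2L * n, by = 2L)
  }
  ends <- cumsum(as.numeric(lens))
  starts <- ends - lens
  keep <- miss_idx[starts[miss_idx] < len]
  out <- data.frame(start = as.integer(starts[keep]),
                    end = as.integer(pmin(ends[keep], len)))
  out[out$end > out$start, , drop = FALSE]
}

mask_positions <- function(runs, pos1) {
  # which 1-based positions fall in 0-based half-open runs
  if (nrow(runs) == 0L || length(pos1) == 0L) return(logical(length(pos1)))
  i <- findInterval(pos1 - 1L, runs$start)
  i > 0L & (pos1 - 1L) < runs$end[pmax(i, 1L)]
}

#' Simulate a species radiation with diploid genomes and a truth record
#'
#' Runs the generative model described in [sim_config()] and returns a genome
#' set (per-individual haplotype pairs, callability masks, simulated genotype
#' matrix with DP/GQ) together with a truth record (species topology, true
#' heterozygosities, expected pairwise divergences, realized per-block gene
#' tree topologies).  Fully deterministic under `config$seed`.
#'
#' @param config A [sim_config()].
#' @return An object of class `genome_set`; its `$truth` element is the
#'   `truth_record`, `$genotypes` the [genotype_matrix()].
#' @examples
#' spec <- species_tree_spec("(A:0.01,B:0.01);", theta = 0.002, n_individuals = 2)
#' sim <- simulate_radiation(sim_config(spec, contig_lengths = 20000, seed = 7))
#' sim$individuals
#' @export
simulate_radiation <- function(config) {
  if (!inherits(config, "sim_config")) stopf("`config` must be a sim_config")
  withr::with_seed(config$seed, simulate_impl(config))
}

simulate_impl <- function(config) {
  spec <- config$species
  tree <- spec$tree
  sp <- tree$tip.label
  individuals <- data.frame(
    id = unlist(lapply(sp, function(s) paste0(s, "_", seq_len(spec$n_individuals[[s]])))),
    species = rep(sp, spec$n_individuals),
    stringsAsFactors = FALSE)

  reference <- list()
  species_seq <- list()
  seg_list <- list()
  for (contig in names(config$contig_lengths)) {
    len <- config$contig_lengths[[contig]]
    starts <- if (config$p_ils > 0) seq(1L, len, by = config$block_length) else 1L
    nb <- length(starts)
    refb <- character(nb)
    spb <- lapply(sp, function(s) character(nb)); names(spb) <- sp
    topo <- character(nb)
    for (b in seq_len(nb)) {
      blen <- min(config$block_length, len - starts[b] + 1L)
      if (config$p_ils == 0) blen <- len
      loc <- tree
      discordant <- config$p_ils > 0 && stats::runif(1) < config$p_ils
      if (discordant) loc <- rnni_rooted(tree)
      anc <- random_sequence_raw(blen, config$base_comp)
      tips <- evolve_raw(loc, anc)
      refb[b] <- rawToChar(anc)
      for (s in sp) spb[[s]][b] <- rawToChar(tips[[s]])
      topo[b] <- ape::write.tree(loc)
    }
    reference[[contig]] <- paste(refb, collapse = "")
    species_seq[[contig]] <- vapply(sp, function(s) paste(spb[[s]], collapse = ""), "")
    seg_list[[contig]] <- data.frame(
      contig = contig, start = starts - 1L,
      end = pmin(starts - 1L + config$block_length, len),
      topology = topo, stringsAsFactors = FALSE)
    if (config$p_ils == 0) seg_list[[contig]]$end <- len
  }

  haplotypes <- vector("list", nrow(individuals))
  names(haplotypes) <- individuals$id
  mask <- haplotypes
  for (i in seq_len(nrow(individuals))) {
    s <- individuals$species[i]
    th <- spec$theta[[s]]
    hl <- list(); ml <- list()
    for (contig in names(config$contig_lengths)) {
      h1 <- species_seq[[contig]][[s]]
      h2 <- rawToChar(mutate_sites(charToRaw(h1), th))
      hl[[contig]] <- c(h1, h2)
      ml[[contig]] <- missing_runs(config$contig_lengths[[contig]],
                                   config$missing_rate, config$missing_run_length)
    }
    haplotypes[[i]] <- hl
    mask[[i]] <- ml
  }

  genotypes <- build_genotypes(reference, haplotypes, mask, individuals, config)
  truth <- build_truth(spec, individuals, seg_list, config)

  structure(list(config = config, individuals = individuals,
                 contig_lengths = config$contig_lengths,
                 reference = reference, haplotypes = haplotypes, mask = mask,
                 genotypes = genotypes, truth = truth),
            class = "genome_set")
}

# Derive the biallelic-SNV genotype matrix (with simulated DP/GQ) from the
# haplotypes.  Only sites polymorphic among the sampled haplotypes, with the
# reference allele present, are emitted; others are counted and skipped.
build_genotypes <- function(reference, haplotypes, mask, individuals, config) {
  ids <- individuals$id
  n <- length(ids)
  vars <- list(); doss <- list()
  n_skipped <- 0L
  for (contig in names(reference)) {
    refr <- charToRaw(reference[[contig]])
    hapr <- vector("list", n)
    diff_any <- logical(length(refr))
    for (i in seq_len(n)) {
      h <- haplotypes[[ids[i]]][[contig]]
      hapr[[i]] <- list(charToRaw(h[1]), charToRaw(h[2]))
      diff_any <- diff_any | hapr[[i]][[1]] != refr | hapr[[i]][[2]] != refr
    }
    pos <- which(diff_any)
    if (!length(pos)) next
    A <- matrix(as.raw(0), nrow = 2L * n, ncol = length(pos))
    for (i in seq_len(n)) {
      A[2L * i - 1L, ] <- hapr[[i]][[1]][pos]
      A[2L * i, ] <- hapr[[i]][[2]][pos]
    }
    refp <- refr[pos]
    pres <- vapply(seq_along(.ACGT), function(b) colSums(A == .ACGT[b]), numeric(length(pos)))
    if (length(pos) == 1L) pres <- matrix(pres, nrow = 1L)
    nalleles <- rowSums(pres > 0)
    ref_code <- match(as.integer(refp), as.integer(.ACGT))
    ref_present <- pres[cbind(seq_along(pos), ref_code)] > 0
    ok <- nalleles == 2L & ref_present
    n_skipped <- n_skipped + sum(nalleles >= 2L & !ok)
    pos <- pos[ok]
    if (!length(pos)) next
    A <- A[, ok, drop = FALSE]
    pres <- pres[ok, , drop = FALSE]
    refp <- refp[ok]; ref_code <- ref_code[ok]
    alt_code <- apply(pres > 0, 1L, function(z) which(z))
    alt_code <- vapply(seq_along(pos), function(j) setdiff(which(pres[j, ] > 0), ref_code[j]), 1L)
    altp <- .ACGT[alt_code]
    dos <- matrix(0L, nrow = length(pos), ncol = n)
    for (i in seq_len(n)) {
      dos[, i] <- (A[2L * i - 1L, ] == altp) + (A[2L * i, ] == altp)
      m <- mask_positions(mask[[ids[i]]][[contig]], pos)
      dos[m, i] <- NA_integer_
    }
    vars[[contig]] <- data.frame(contig = contig, pos = pos,
                                 ref = strsplit(rawToChar(refp), "")[[1]],
                                 alt = strsplit(rawToChar(altp), "")[[1]],
                                 stringsAsFactors = FALSE)
    doss[[contig]] <- dos
  }
  if (length(vars)) {
    variants <- do.call(rbind, vars)
    rownames(variants) <- NULL
    dosage <- do.call(rbind, doss)
  } else {
    variants <- data.frame(contig = character(), pos = integer(),
                           ref = character(), alt = character())
    dosage <- matrix(integer(), nrow = 0L, ncol = n)
  }
  nv <- nrow(variants)
  dp <- matrix(stats::rpois(nv * n, config$depth_mean), nrow = nv, ncol = n)
  gq <- matrix(pmin(99, pmax(0, round(stats::rnorm(nv * n, config$gq_mean, config$gq_sd)))),
               nrow = nv, ncol = n)
  dp[is.na(dosage)] <- 0L
  gq[is.na(dosage)] <- 0L
  gm <- genotype_matrix(ids, variants, dosage, dp, gq)
  attr(gm, "n_skipped_nonbiallelic") <- n_skipped
  gm
}

build_truth <- function(spec, individuals, seg_list, config) {
  tree <- spec$tree
  ids <- individuals$id
  ind_theta <- spec$theta[individuals$species]
  names(ind_theta) <- ids
  n <- length(ids)
  ed <- matrix(0, n, n, dimnames = list(ids, ids))
  path <- if (length(tree$tip.label) > 1L) ape::cophenetic.phylo(tree) else
    matrix(0, 1, 1, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    si <- individuals$species[i]; sj <- individuals$species[j]
    p_sp <- if (si == sj) 0 else jc_mismatch(path[si, sj])
    # pseudo-haploid expectation: species divergence plus half of each theta
    ed[i, j] <- p_sp + ind_theta[i] / 2 + ind_theta[j] / 2
  }
  segments <- do.call(rbind, seg_list)
  rownames(segments) <- NULL
  structure(list(tree = tree,
                 individuals = data.frame(individuals, theta = as.numeric(ind_theta)),
                 expected_divergence = ed,
                 segments = segments,
                 p_ils = config$p_ils, seed = config$seed),
            class = "truth_record")
}

#' Collapse diploid genomes to pseudo-haploid consensus sequences
#'
#' Emits one base per site per individual: the shared base at homozygous
#' sites, a seeded fair-coin choice between the two alleles at heterozygous
#' sites (modelling the read-count tie of a balanced heterozygote under the
#' majority-read rule), and `N` at masked sites.
#'
#' @param genomes A `genome_set` from [simulate_radiation()].
#' @param seed Integer seed for the allele coin; same seed, same output.
#' @return A named list (one element per individual) of named character
#'   vectors of per-contig sequences.
#' @export
pseudo_haploidize <- function(genomes, seed = genomes$config$seed + 101L) {
  if (!inherits(genomes, "genome_set")) stopf("`genomes` must be a genome_set")
  withr::with_seed(seed, {
    out <- vector("list", nrow(genomes$individuals))
    names(out) <- genomes$individuals$id
    for (id in genomes$individuals$id) {
      seqs <- character(0)
      for (contig in names(genomes$contig_lengths)) {
        h <- genomes$haplotypes[[id]][[contig]]
        r1 <- charToRaw(h[1]); r2 <- charToRaw(h[2])
        het <- which(r1 != r2)
        if (length(het)) {
          take2 <- het[stats::runif(length(het)) < 0.5]
          r1[take2] <- r2[take2]
        }
        runs <- genomes$mask[[id]][[contig]]
        if (nrow(runs)) {
          idx <- unlist(Map(function(s, e) (s + 1L):e, runs$start, runs$end),
                        use.names = FALSE)
          r1[idx] <- .N
        }
        seqs[contig] <- rawToChar(r1)
      }
      out[[id]] <- seqs
    }
    out
  })
}

#' Mask sequences with runs of missing data
#'
#' Overlays `N` runs drawn from a stationary two-state Markov chain: the
#' expected fraction of `N` sites is exactly `rate` and missing runs are
#' geometric with mean `run_length / (1 - rate)` bp, so `run_length = 1`
#' yields independent per-site missingness.  Emulates the patchy coverage of
#' a degraded (museum) specimen.
#'
#' @param sequences Named character vector (or list of such vectors) of
#'   A/C/G/T/N sequences.
#' @param rate Target missing fraction, in `[0, 1)`.
#' @param run_length Mean run-length scale in bp (`>= 1`).
#' @param seed Integer seed.
#' @return Sequences of the same shape with `N` runs applied.
#' @export
apply_missingness <- function(sequences, rate, run_length = 100, seed = 1L) {
  if (rate < 0 || rate >= 1) stopf("rate must lie in [0, 1)")
  if (is.list(sequences))
    return(withr::with_seed(seed, lapply(sequences, function(s)
      apply_missingness_impl(s, rate, run_length))))
  withr::with_seed(seed, apply_missingness_impl(sequences, rate, run_length))
}

apply_missingness_impl <- function(sequences, rate, run_length) {
  if (rate == 0) return(sequences)
  out <- sequences
  for (i in seq_along(out)) {
    r <- charToRaw(out[[i]])
    runs <- missing_runs(length(r), rate, run_length)
    if (nrow(runs)) {
      idx <- unlist(Map(function(s, e) (s + 1L):e, runs$start, runs$end),
                    use.names = FALSE)
      r[idx] <- .N
    }
    out[[i]] <- rawToChar(r)
  }
  out
}

#' @export
print.genome_set <- function(x, ...) {
  cat("Simulated genome set:", nrow(x$individuals), "individuals,",
      length(x$contig_lengths), "contig(s),",
      sum(as.numeric(x$contig_lengths)), "bp;",
      nrow(x$genotypes$variants), "variant sites\n")
  invisible(x)
}
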