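# Fixtures built in code: hand-assembled genome sets, column-wise alignments,
# and small genotype matrices.

# A minimal single-individual genome_set with explicit haplotypes, bypassing
# the simulator (for pseudo-haploidisation edge cases).
make_genome_set <- function(h1, h2, id = "X_1", species = "X",
                            mask = NULL) {
  stopifnot(length(h1) == length(h2))
  if (is.null(names(h1))) names(h1) <- names(h2) <- paste0("c", seq_along(h1))
  empty <- data.frame(start = integer(), end = integer())
  haps <- list(); msk <- list()
  for (ct in names(h1)) {
    haps[[ct]] <- c(h1[[ct]], h2[[ct]])
    msk[[ct]] <- if (is.null(mask)) empty else mask[[ct]]
  }
  structure(list(
    config = list(seed = 1L),
    individuals = data.frame(id = id, species = species, stringsAsFactors = FALSE),
    contig_lengths = vapply(h1, nchar, 0L),
    reference = as.list(h1),
    haplotypes = stats::setNames(list(haps), id),
    mask = stats::setNames(list(msk), id),
    genotypes = NULL, truth = NULL), class = "genome_set")
}

# Build a windowed alignment column by column; cols is a list of character
# vectors (one state per row).
aln_from_cols <- function(cols, taxa = NULL) {
  n <- length(cols[[1]])
  rows <- vapply(seq_len(n), function(i)
    paste(vapply(cols, `[`, "", i), collapse = ""), "")
  if (is.null(taxa)) taxa <- paste0("t", seq_len(n))
  names(rows) <- taxa
  windowed_alignment(rows)
}

# Small genotype matrix from a dosage matrix (variants x samples).
make_gm <- function(dosage, pos = NULL, contig = "c1", dp = 20L, gq = 60L) {
  nv <- nrow(dosage); ns <- ncol(dosage)
  if (is.null(pos)) pos <- seq_len(nv) * 100L
  variants <- data.frame(contig = contig, pos = as.integer(pos),
                         ref = rep("A", nv), alt = rep("C", nv),
                         stringsAsFactors = FALSE)
  samples <- colnames(dosage)
  if (is.null(samples)) samples <- paste0("s", seq_len(ns))
  dpm <- if (length(dp) == 1L) matrix(dp, nv, ns) else dp
  gqm <- if (length(gq) == 1L) matrix(gq, nv, ns) else gq
  genotype_matrix(samples, variants, dosage, dpm, gqm)
}

# Default small radiation used by several tests.
demo_spec <- function(theta = 0.002, n_individuals = 2)
  species_tree_spec("((A:0.005,B:0.005):0.005,C:0.01);",
                    theta = theta, n_individuals = n_individuals)

# Expected mismatch fraction between two tips under JC69 at path length d.
jc_expected <- function(d) 0.75 * (1 - exp(-4 * d / 3))

# TRUE when two trees share the same unrooted topology.
topo_equal <- function(t1, t2)
  as.numeric(ape::dist.topo(ape::unroot(t1), ape::unroot(t2))) == 0
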