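# Gene-tree stage: uncorrected p-distances with pairwise N handling, the
# JC69 correction, and neighbor joining.  This is the desk-scale surrogate
# for a maximum-likelihood gene-tree engine: deterministic, and exact on
# additive distance matrices.

#' Pairwise mismatch proportions of an alignment
#'
#' Entry (i, j) is the number of mismatches divided by the number of sites at
#' which both rows are non-N.  Pairs with zero overlap get `NA` and are
#' flagged; such alignments are unusable for tree building.
#'
#' @param aln A `windowed_alignment` or named character vector (>= 3 rows).
#' @return Symmetric matrix of mismatch proportions with attribute `overlap`
#'   (matrix of pairwise non-N site counts).
#' @export
pdistance <- function(aln) {
  m <- aln_matrix(aln)
  if (nrow(m) < 3L) stopf("need >= 3 taxa for a distance matrix")
  valid <- m != .N
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  S <- matrix(0L, n, n, dimnames = dimnames(D))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- valid[i, ] & valid[j, ]
    s <- sum(ok)
    S[i, j] <- S[j, i] <- s
    D[i, j] <- D[j, i] <- if (s == 0L) NA_real_ else sum(m[i, ok] != m[j, ok]) / s
  }
  attr(D, "overlap") <- S
  D
}

#' Jukes-Cantor distance correction
#'
#' Inverts the JC69 saturation curve: `d = -(3/4) log(1 - (4/3) p)`.  The
#' correction always inflates (`d >= p`) and diverges as `p` approaches the
#' JC ceiling of 0.75.
#'
#' @param p Mismatch proportion(s) in `[0, 0.75)`; vectors and matrices keep
#'   their shape.  `NA` passes through.
#' @return Corrected distance(s) in substitutions per site.
#' @export
jc69_correct <- function(p) {
  bad <- !is.na(p) & (p < 0 | p >= 0.75)
  if (any(bad)) stopf("mismatch proportion saturated or invalid (p >= 0.75 or p < 0)")
  out <- -0.75 * log(1 - 4 * p / 3)
  attributes(out) <- attributes(p)
  out
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining (via the agglomeration in \pkg{ape}), with input
#' validation and negative branch lengths clamped to zero.  On additive
#' matrices the generating topology is recovered exactly.
#'
#' @param D Symmetric nonnegative distance matrix with zero diagonal,
#'   >= 3 taxa, finite entries.
#' @return An unrooted `phylo` tree.
#' @export
neighbor_joining <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) < 3L) stopf("need >= 3 taxa")
  if (any(!is.finite(D))) stopf("distance matrix must be finite (no NA)")
  if (any(abs(D - t(D)) > 1e-12)) stopf("distance matrix must be symmetric")
  if (any(D < 0)) stopf("distance matrix must be nonnegative")
  if (any(diag(D) != 0)) stopf("distance matrix must have zero diagonal")
  tr <- ape::nj(D)
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Build gene trees for retained alignments
#'
#' For each alignment: pairwise mismatch proportions, JC69 correction, and a
#' neighbor-joining tree.  Alignments that cannot support a tree are skipped
#' with a recorded reason: a pair with zero non-N overlap
#' (`"zero_overlap"`), a saturated pair (`"saturated"`), or no variation at
#' all (`"no_variation"`, the star tree being undefined).
#'
#' @param alignments List of QC-retained `windowed_alignment` objects.
#' @return An object of class `gene_tree_set`: `trees` (a `multiPhylo`),
#'   `skipped` (data frame of alignment id and reason), `avg_dist`
#'   (segment-averaged corrected distance matrix), `taxa`.
#' @export
build_gene_trees <- function(alignments) {
  trees <- list(); skipped <- list()
  dsum <- NULL; dcount <- NULL
  for (k in seq_along(alignments)) {
    aln <- alignments[[k]]
    id <- if (inherits(aln, "windowed_alignment") && !is.na(aln$contig))
      sprintf("%s:%d-%d", aln$contig, aln$start, aln$end) else sprintf("aln_%d", k)
    D <- pdistance(aln)
    if (any(is.na(D))) { skipped[[id]] <- "zero_overlap"; next }
    if (max(D) == 0) { skipped[[id]] <- "no_variation"; next }
    if (max(D) >= 0.75) { skipped[[id]] <- "saturated"; next }
    Dc <- jc69_correct(D)
    if (is.null(dsum)) {
      dsum <- Dc; dcount <- 1L
    } else {
      dsum <- dsum + Dc[rownames(dsum), colnames(dsum)]; dcount <- dcount + 1L
    }
    trees[[id]] <- neighbor_joining(Dc)
  }
  sk <- data.frame(alignment = names(skipped),
                   reason = unlist(skipped, use.names = FALSE))
  if (!nrow(sk)) sk <- data.frame(alignment = character(), reason = character())
  taxa <- if (!is.null(dsum)) rownames(dsum) else character(0)
  structure(list(trees = structure(trees, class = "multiPhylo"),
                 skipped = sk,
                 avg_dist = if (!is.null(dsum)) dsum / dcount else NULL,
                 taxa = taxa),
            class = "gene_tree_set")
}

#' @export
print.gene_tree_set <- function(x, ...) {
  cat("Gene tree set:", length(x$trees), "trees over", length(x$taxa),
      "taxa;", nrow(x$skipped), "alignment(s) skipped\n")
  invisible(x)
}

#' Write or read a gene-tree set as multi-line Newick
#'
#' @param gts A `gene_tree_set` (or `multiPhylo`).
#' @param path File path.
#' @return `write_gene_trees` invisibly returns `path`; `read_gene_trees`
#'   returns a `multiPhylo`.
#' @export
write_gene_trees <- function(gts, path) {
  trees <- if (inherits(gts, "gene_tree_set")) gts$trees else gts
  ape::write.tree(trees, file = path)
  invisible(path)
}

#' @rdname write_gene_trees
#' @export
read_gene_trees <- function(path) {
  tr <- ape::read.tree(path)
  if (inherits(tr, "phylo")) tr <- structure(list(tr), class = "multiPhylo")
  tr
}
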