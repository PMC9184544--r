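# Quartet-score species-tree consensus: the desk-scale surrogate for a
# coalescent-aware summary method.  The species tree is the topology that
# agrees with the largest number of 4-taxon subtrees induced by the gene
# trees; per-branch support is the fraction of gene-tree quartets spanning
# the branch that agree with it.

# Resolution codes for a quartet (a,b,c,d) with a<b<c<d:
#   1 = ab|cd, 2 = ac|bd, 3 = ad|bc, 0 = unresolved / quartet not spanned.
quartet_resolutions <- function(tree, taxa, quartets) {
  idx <- match(taxa, tree$tip.label)
  t2 <- tree
  t2$edge.length <- rep(1, nrow(t2$edge))
  ntip <- length(t2$tip.label)
  D <- ape::dist.nodes(t2)[seq_len(ntip), seq_len(ntip), drop = FALSE]
  a <- idx[quartets[1, ]]; b <- idx[quartets[2, ]]
  cc <- idx[quartets[3, ]]; d <- idx[quartets[4, ]]
  s1 <- D[cbind(a, b)] + D[cbind(cc, d)]
  s2 <- D[cbind(a, cc)] + D[cbind(b, d)]
  s3 <- D[cbind(a, d)] + D[cbind(b, cc)]
  res <- integer(ncol(quartets))
  ok <- !is.na(s1)
  r1 <- s1 < s2 & s1 < s3
  r2 <- s2 < s1 & s2 < s3
  r3 <- s3 < s1 & s3 < s2
  res[ok & r1] <- 1L; res[ok & r2] <- 2L; res[ok & r3] <- 3L
  res
}

# Aggregate gene-tree quartet resolutions into a count matrix (nquartet x 3).
quartet_counts <- function(gene_trees, taxa, quartets) {
  counts <- matrix(0L, ncol(quartets), 3L)
  for (tr in gene_trees) {
    r <- quartet_resolutions(tr, taxa, quartets)
    for (k in 1:3) counts[, k] <- counts[, k] + (r == k)
  }
  counts
}

score_from_counts <- function(res, counts) {
  use <- res > 0L
  sum(counts[cbind(which(use), res[use])])
}

#' Quartet score of a candidate species tree
#'
#' The number of 4-leaf subsets whose induced unrooted topology agrees
#' between the candidate and a gene tree, summed over all gene trees.  Gene
#' trees missing some leaves contribute only the quartets they span
#' (intersection semantics).
#'
#' @param candidate An unrooted `phylo` over the individuals of interest.
#' @param gene_trees A `gene_tree_set`, `multiPhylo`, or list of `phylo`.
#' @return Integer score.
#' @export
quartet_score <- function(candidate, gene_trees) {
  trees <- gene_tree_list(gene_trees)
  taxa <- sort(candidate$tip.label)
  if (length(taxa) < 4L) stopf("need >= 4 leaves")
  quartets <- utils::combn(length(taxa), 4L)
  counts <- quartet_counts(trees, taxa, quartets)
  res <- quartet_resolutions(candidate, taxa, quartets)
  score_from_counts(res, counts)
}

gene_tree_list <- function(gene_trees) {
  if (inherits(gene_trees, "gene_tree_set")) return(gene_trees$trees)
  if (inherits(gene_trees, "phylo")) return(list(gene_trees))
  gene_trees
}

#' Infer the species tree by quartet-score maximization
#'
#' Finds the unrooted topology over the union of gene-tree leaves that
#' maximizes the total quartet agreement with the gene trees.  With at most
#' `exhaustive_max` leaves every topology is enumerated; otherwise (or when
#' `mode = "greedy"`) a nearest-neighbor-interchange hill climb starts from
#' the neighbor-joining tree of the segment-averaged distances and moves
#' while any NNI neighbor improves the score.  Per-branch support is the
#' fraction of resolved gene-tree quartets spanning the branch (two leaves on
#' each side) that agree with it; values are stored as node labels.
#'
#' @param gene_trees A `gene_tree_set` (preferred; carries the averaged
#'   distance matrix used to seed the greedy search) or `multiPhylo`.
#' @param mode `"auto"` (exhaustive when feasible), `"exhaustive"`, or
#'   `"greedy"`.
#' @param exhaustive_max Leaf-count limit for exhaustive enumeration
#'   (default 7).
#' @return An object of class `species_tree_result`: `tree` (unrooted
#'   `phylo`, node labels = rounded support), `score`, `support` (data frame
#'   per internal branch), `mode`, `n_gene_trees`.
#' @export
infer_species_tree <- function(gene_trees, mode = c("auto", "exhaustive", "greedy"),
                               exhaustive_max = 7L) {
  mode <- match.arg(mode)
  trees <- gene_tree_list(gene_trees)
  if (!length(trees)) stopf("no gene trees supplied")
  taxa <- sort(unique(unlist(lapply(trees, function(t) t$tip.label))))
  m <- length(taxa)
  if (m < 4L) stopf("need >= 4 leaves to infer a species tree")
  quartets <- utils::combn(m, 4L)
  counts <- quartet_counts(trees, taxa, quartets)
  if (mode == "auto") mode <- if (m <= exhaustive_max) "exhaustive" else "greedy"

  if (mode == "exhaustive") {
    if (m > exhaustive_max)
      stopf("exhaustive search limited to %d leaves (got %d)", exhaustive_max, m)
    cands <- phangorn::allTrees(m, rooted = FALSE, tip.label = taxa)
    scores <- vapply(cands, function(tr)
      score_from_counts(quartet_resolutions(tr, taxa, quartets), counts), 0)
    best <- cands[[which.max(scores)]]
    best_score <- max(scores)
  } else {
    start <- greedy_start(gene_trees, trees, taxa)
    cur <- ape::unroot(start)
    cur_score <- score_from_counts(quartet_resolutions(cur, taxa, quartets), counts)
    repeat {
      nbs <- phangorn::nni(cur)
      # multiPhylo may compress tip labels; [[ reattaches them
      nbs <- lapply(seq_along(nbs), function(i) nbs[[i]])
      sc <- vapply(nbs, function(tr)
        score_from_counts(quartet_resolutions(tr, taxa, quartets), counts), 0)
      if (!length(sc) || max(sc) <= cur_score) break
      cur <- nbs[[which.max(sc)]]
      cur_score <- max(sc)
    }
    best <- cur
    best_score <- cur_score
  }
  best$edge.length <- NULL
  res_best <- quartet_resolutions(best, taxa, quartets)
  supp <- branch_support(best, taxa, quartets, counts, res_best)
  structure(list(tree = supp$tree, score = as.integer(round(best_score)),
                 support = supp$table, mode = mode,
                 n_gene_trees = length(trees)),
            class = "species_tree_result")
}

greedy_start <- function(gene_trees, trees, taxa) {
  if (inherits(gene_trees, "gene_tree_set") && !is.null(gene_trees$avg_dist) &&
      setequal(rownames(gene_trees$avg_dist), taxa))
    return(neighbor_joining(gene_trees$avg_dist))
  # fall back: average topological distances over gene trees spanning all taxa
  dsum <- matrix(0, length(taxa), length(taxa), dimnames = list(taxa, taxa))
  nfull <- 0L
  for (tr in trees) {
    if (!setequal(tr$tip.label, taxa)) next
    t2 <- tr; t2$edge.length <- rep(1, nrow(t2$edge))
    D <- ape::cophenetic.phylo(t2)[taxa, taxa]
    dsum <- dsum + D; nfull <- nfull + 1L
  }
  if (nfull == 0L) stopf("no gene tree spans all taxa; cannot seed greedy search")
  neighbor_joining(dsum / nfull)
}

# Support per internal branch: among quartets with exactly two leaves on each
# side of the branch, the fraction of resolved gene-tree quartets agreeing
# with the candidate's resolution.
branch_support <- function(tree, taxa, quartets, counts, res_cand) {
  ntip <- length(tree$tip.label)
  tree$node.label <- rep("", tree$Nnode)
  totals <- rowSums(counts)
  rows <- list()
  internal_edges <- which(tree$edge[, 2] > ntip)
  tipsets <- lapply(seq_len(tree$Nnode) + ntip, function(nd)
    tree$tip.label[unlist(phangorn::Descendants(tree, nd, type = "tips"))])
  for (e in internal_edges) {
    nd <- tree$edge[e, 2]
    side <- tipsets[[nd - ntip]]
    if (length(side) < 2L || length(side) > length(taxa) - 2L) next
    in_side <- matrix(taxa[quartets] %in% side, nrow = 4L)
    span <- colSums(in_side) == 2L
    use <- span & res_cand > 0L & totals > 0
    agree <- sum(counts[cbind(which(use), res_cand[use])])
    tot <- sum(totals[use])
    supp <- if (tot > 0) agree / tot else NA_real_
    tree$node.label[nd - ntip] <- ifelse(is.na(supp), "", sprintf("%.3f", supp))
    rows[[length(rows) + 1L]] <- data.frame(
      node = nd, clade = paste(sort(side), collapse = ","),
      support = supp, n_quartets = tot)
  }
  table <- if (length(rows)) do.call(rbind, rows) else
    data.frame(node = integer(), clade = character(), support = numeric(),
               n_quartets = numeric())
  list(tree = tree, table = table)
}

#' Does a tree contain a bipartition isolating the given tips?
#'
#' TRUE when some branch of the (unrooted) tree splits exactly `tips` from
#' the rest — the unrooted notion of monophyly.
#'
#' @param tree A `phylo`.
#' @param tips Character vector of tip labels.
#' @return Logical.
#' @export
has_split <- function(tree, tips) {
  all_tips <- tree$tip.label
  if (!all(tips %in% all_tips)) stopf("tips not in tree: %s",
                                      paste(setdiff(tips, all_tips), collapse = ", "))
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  for (p in parts) {
    side <- labs[p]
    if (setequal(side, tips) || setequal(setdiff(all_tips, side), tips)) return(TRUE)
  }
  # tip-adjacent cherries in unrooted trees are always in prop.part via nodes;
  # also allow the trivial 1-vs-rest case
  length(tips) == 1L || length(tips) == length(all_tips)
}

#' Quartet support of the branch isolating a set of tips
#'
#' Convenience lookup in a [infer_species_tree()] result: returns the support
#' of the branch whose bipartition isolates `tips` (or its complement), or
#' `NA` if no such branch exists.
#'
#' @param result A `species_tree_result`.
#' @param tips Character vector of tip labels.
#' @return Support in `[0, 1]` or `NA`.
#' @export
clade_support <- function(result, tips) {
  all_tips <- result$tree$tip.label
  key1 <- paste(sort(tips), collapse = ",")
  key2 <- paste(sort(setdiff(all_tips, tips)), collapse = ",")
  hit <- result$support$clade %in% c(key1, key2)
  if (!any(hit)) return(NA_real_)
  result$support$support[which(hit)[1]]
}

#' @export
print.species_tree_result <- function(x, ...) {
  cat("Quartet species tree (", x$mode, " search): score ", x$score,
      " over ", x$n_gene_trees, " gene trees\n", sep = "")
  cat(ape::write.tree(x$tree), "\n")
  invisible(x)
}
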