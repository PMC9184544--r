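# The headline computation: observed heterozygosity under depth/GQ filters,
# the heterozygosity-normalised pairwise genetic distance
#
#   Distance = ( (1/n) * sum_i a_i / S_i ) / ( (h1 + h2) / 2 )
#
# where a_i is the pairwise difference count in segment i, S_i the mutually
# non-N site count, and h1, h2 the per-bp genome-wide heterozygosities of the
# two individuals, and the distance-hierarchy classifier built on it.

#' Observed per-bp heterozygosity from genotype calls
#'
#' A genotype is callable when it is non-missing with depth `>= min_depth`
#' and genotype quality `>= min_gq` (the defaults encode "depth of at least
#' six reads and GQ strictly above 17").  `h` is the fraction of callable
#' genotypes that are heterozygous; `n_invariant` adds invariant-but-callable
#' sites to the denominator so `h` is per genome base pair, not per variant.
#'
#' @param gm A [genotype_matrix()].
#' @param min_depth Minimum DP (default 6).
#' @param min_gq Minimum GQ (default 18, i.e. GQ > 17).
#' @param n_invariant Scalar or per-sample named vector of invariant callable
#'   sites to include in the denominator (default 0: variant sites only).
#' @return Data frame: `individual`, `het_sites`, `callable`, `h`.
#' @export
estimate_heterozygosity <- function(gm, min_depth = 6L, min_gq = 18L,
                                    n_invariant = 0) {
  stopifnot(inherits(gm, "genotype_matrix"))
  n_invariant <- rep_named(n_invariant, gm$samples, "n_invariant")
  out <- lapply(seq_along(gm$samples), function(i) {
    pass <- !is.na(gm$dosage[, i]) & gm$dp[, i] >= min_depth & gm$gq[, i] >= min_gq
    het <- sum(gm$dosage[pass, i] == 1L)
    callable <- sum(pass) + n_invariant[[i]]
    if (callable <= 0) stopf("no callable sites for individual '%s'", gm$samples[i])
    data.frame(individual = gm$samples[i], het_sites = het,
               callable = callable, h = het / callable)
  })
  do.call(rbind, out)
}

#' Pairwise differences within one segment
#'
#' `S` counts the positions at which both sequences carry an unambiguous base
#' (A/C/G/T); `a` counts those positions where the bases differ.  N sites are
#' excluded from both numerator and denominator.
#'
#' @param seq_a,seq_b Equal-length sequence slices (character scalars).
#' @return List with integer `a` (differences) and `S` (comparable sites).
#' @export
segment_diff <- function(seq_a, seq_b) {
  ra <- charToRaw(seq_a); rb <- charToRaw(seq_b)
  if (length(ra) != length(rb)) stopf("segment slices differ in length (%d vs %d)",
                                      length(ra), length(rb))
  ok <- ra != .N & rb != .N
  list(a = sum(ok & ra != rb), S = sum(ok))
}

#' Heterozygosity-normalised genetic distance between two individuals
#'
#' Averages the per-segment mismatch ratios `a_i / S_i` over the `n` usable
#' segments and divides by the mean of the two individuals' heterozygosities.
#' The value is dimensionless: roughly 1 for two conspecifics (their distance
#' is about one heterozygosity unit) and grows with divergence.  Segments
#' with `S_i = 0` carry no information and are skipped (and counted).
#'
#' @param diffs Data frame (or list of lists) with columns/fields `a` and `S`,
#'   one row per segment.
#' @param h_a,h_b The two per-bp genome-wide heterozygosities; their mean
#'   must be positive.
#' @param pair Optional character vector of the two individual ids.
#' @return An object of class `normalized_distance`: `pair`, `n`, `raw`
#'   (mean of `a_i/S_i`), `value`, `n_skipped`.
#' @export
normalized_distance <- function(diffs, h_a, h_b, pair = c(NA, NA)) {
  if (is.data.frame(diffs)) {
    a <- diffs$a; S <- diffs$S
  } else {
    a <- vapply(diffs, `[[`, 0, "a"); S <- vapply(diffs, `[[`, 0, "S")
  }
  if (any(a < 0 | S < 0 | a > S)) stopf("invalid segment diffs: need 0 <= a <= S")
  usable <- S > 0
  if (!any(usable)) stopf("no usable segments (all have S = 0)")
  if (h_a + h_b <= 0) stopf("normalization undefined: both heterozygosities are zero")
  raw <- mean(a[usable] / S[usable])
  structure(list(pair = pair, n = sum(usable), raw = raw,
                 value = raw / ((h_a + h_b) / 2),
                 n_skipped = sum(!usable)),
            class = "normalized_distance")
}

#' All pairwise segment differences across a set of alignments
#'
#' @param alignments List of `windowed_alignment` objects over the same taxa.
#' @return Data frame: `segment`, `id1`, `id2`, `a`, `S`.
#' @export
pairwise_segment_diffs <- function(alignments) {
  if (!length(alignments)) stopf("no alignments supplied")
  taxa <- alignments[[1]]$taxa
  pairs <- utils::combn(taxa, 2L)
  rows <- vector("list", length(alignments) * ncol(pairs))
  k <- 0L
  for (s in seq_along(alignments)) {
    aln <- alignments[[s]]
    for (p in seq_len(ncol(pairs))) {
      d <- segment_diff(aln$seqs[[pairs[1, p]]], aln$seqs[[pairs[2, p]]])
      k <- k + 1L
      rows[[k]] <- data.frame(segment = s, id1 = pairs[1, p], id2 = pairs[2, p],
                              a = d$a, S = d$S, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Normalised distances for every pair of individuals
#'
#' @param diffs Output of [pairwise_segment_diffs()].
#' @param het Output of [estimate_heterozygosity()] covering all individuals.
#' @return Data frame: `id1`, `id2`, `n`, `raw`, `value`.
#' @export
pairwise_normalized_distances <- function(diffs, het) {
  h <- stats::setNames(het$h, het$individual)
  pairs <- unique(diffs[, c("id1", "id2")])
  rows <- lapply(seq_len(nrow(pairs)), function(k) {
    i1 <- pairs$id1[k]; i2 <- pairs$id2[k]
    dd <- diffs[diffs$id1 == i1 & diffs$id2 == i2, ]
    nd <- normalized_distance(dd, h[[i1]], h[[i2]], pair = c(i1, i2))
    data.frame(id1 = i1, id2 = i2, n = nd$n, raw = nd$raw, value = nd$value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Partition pairwise distances into focal / within- / between-species strata
#'
#' Every computed pair lands in exactly one stratum: pairs involving a focal
#' individual are `"focal"`, remaining conspecific pairs `"within"`, the rest
#' `"between"`.
#'
#' @param distances Data frame with `id1`, `id2`, `value` (e.g. from
#'   [pairwise_normalized_distances()]).
#' @param species_labels Named character vector: individual id -> species.
#' @param focal_ids Character vector of focal individuals (may be empty).
#' @return An object of class `distance_hierarchy`: `distances` (with a
#'   `stratum` column), `summary` (min/median/max per stratum), `labels`,
#'   `focal_ids`.
#' @export
build_hierarchy <- function(distances, species_labels, focal_ids = character()) {
  ids <- unique(c(distances$id1, distances$id2))
  missing <- setdiff(ids, names(species_labels))
  if (length(missing)) stopf("unlabeled individual(s): %s", paste(missing, collapse = ", "))
  is_focal <- distances$id1 %in% focal_ids | distances$id2 %in% focal_ids
  same_sp <- species_labels[distances$id1] == species_labels[distances$id2]
  stratum <- ifelse(is_focal, "focal", ifelse(same_sp, "within", "between"))
  d <- data.frame(distances, stratum = stratum, stringsAsFactors = FALSE)
  smry <- do.call(rbind, lapply(split(d$value, d$stratum), function(v)
    data.frame(n = length(v), min = min(v), median = stats::median(v), max = max(v))))
  smry <- data.frame(stratum = rownames(smry), smry, row.names = NULL)
  structure(list(distances = d, summary = smry,
                 labels = species_labels, focal_ids = focal_ids),
            class = "distance_hierarchy")
}

#' Assign a focal individual to a lineage from the distance hierarchy
#'
#' The nearest lineage is the species with the smallest mean normalised
#' distance to the focal individual.  The decision is `"same-lineage"` when
#' the focal's minimum distance is at most the `q`-quantile of the
#' within-species reference distribution (its distance looks intraspecific),
#' `"novel"` when it exceeds every within-species value and the margin to the
#' second-nearest lineage is positive, and `"ambiguous"` otherwise.  All
#' criterion values are recorded so the decision is a pure function of them.
#'
#' @param hierarchy A [build_hierarchy()] result containing the focal's pairs
#'   and a nonempty within-species stratum.
#' @param focal The focal individual id.
#' @param q Reference quantile (default 0.95).
#' @return An object of class `assignment`: `focal`, `nearest`, `decision`,
#'   `min_distance`, `q`, `q_threshold`, `max_within`, `margin`,
#'   `lineage_means`.
#' @export
classify_focal <- function(hierarchy, focal, q = 0.95) {
  stopifnot(inherits(hierarchy, "distance_hierarchy"))
  d <- hierarchy$distances
  fd <- d[d$stratum == "focal" & (d$id1 == focal | d$id2 == focal), ]
  if (!nrow(fd)) stopf("no focal distances for '%s'", focal)
  within <- d$value[d$stratum == "within"]
  if (!length(within)) stopf("empty within-species reference distribution")
  partner <- ifelse(fd$id1 == focal, fd$id2, fd$id1)
  lineage <- hierarchy$labels[partner]
  means <- vapply(split(fd$value, lineage), mean, 0)
  means <- sort(means)
  nearest <- names(means)[1]
  margin <- if (length(means) > 1L) means[[2]] - means[[1]] else Inf
  min_d <- min(fd$value)
  q_thr <- as.numeric(stats::quantile(within, q))
  decision <- if (min_d <= q_thr) "same-lineage"
  else if (min_d > max(within) && margin > 0) "novel"
  else "ambiguous"
  structure(list(focal = focal, nearest = nearest, decision = decision,
                 min_distance = min_d, q = q, q_threshold = q_thr,
                 max_within = max(within), margin = margin,
                 lineage_means = means),
            class = "assignment")
}

#' @export
print.assignment <- function(x, ...) {
  cat(sprintf("Focal '%s': %s (nearest lineage %s; min distance %.3f, within-species q%.0f%% = %.3f)\n",
              x$focal, x$decision, x$nearest, x$min_distance, 100 * x$q, x$q_threshold))
  invisible(x)
}

#' @export
print.normalized_distance <- function(x, ...) {
  cat(sprintf("Normalized distance %s-%s: %.4f (raw %.6f over %d segments)\n",
              x$pair[1], x$pair[2], x$value, x$raw, x$n))
  invisible(x)
}
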