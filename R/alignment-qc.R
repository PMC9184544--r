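# Per-alignment statistics and the retention filter.  N is never a state:
# it is excluded from parsimony-informativeness and from the GC denominator.

#' Count parsimony-informative sites
#'
#' A column is parsimony informative when at least two distinct non-N states
#' each occur in at least two rows; only such columns can favour one tree
#' topology over another under parsimony.
#'
#' @param aln A `windowed_alignment` or named character vector of rows.
#' @return Integer count of informative columns.
#' @examples
#' count_parsimony_informative(c(a = "AAC", b = "AAC", c = "ACA", d = "ACA"))
#' @export
count_parsimony_informative <- function(aln) {
  m <- aln_matrix(aln)
  counts <- vapply(seq_along(.ACGT),
                   function(b) colSums(matrix(m == .ACGT[b], nrow = nrow(m))),
                   numeric(ncol(m)))
  if (ncol(m) == 1L) counts <- matrix(counts, nrow = 1L)
  sum(rowSums(counts >= 2) >= 2)
}

#' Fraction of missing (N) cells in an alignment
#'
#' @inheritParams count_parsimony_informative
#' @return Missing fraction in `[0, 1]`.
#' @export
missing_fraction <- function(aln) {
  m <- aln_matrix(aln)
  mean(m == .N)
}

#' GC content of an alignment
#'
#' G+C cells divided by non-N cells.  Errors when the alignment is all N
#' (the statistic is undefined; such alignments auto-fail the filter).
#'
#' @inheritParams count_parsimony_informative
#' @return GC fraction in `[0, 1]`.
#' @export
gc_content <- function(aln) {
  m <- aln_matrix(aln)
  non_n <- sum(m != .N)
  if (non_n == 0L) stopf("GC content undefined: alignment contains only N")
  (sum(m == charToRaw("G")) + sum(m == charToRaw("C"))) / non_n
}

#' QC statistics for one alignment
#'
#' @inheritParams count_parsimony_informative
#' @param min_pi Retain only alignments with strictly more informative sites
#'   than this (default 5).
#' @param max_missing Strict upper bound on the missing fraction (default 0.10).
#' @param gc_range Open interval the GC fraction must fall in (default
#'   `c(0.30, 0.70)`).
#' @return One-row data frame: `pi_sites`, `missing_frac`, `gc_frac`, `pass`.
#' @export
alignment_qc <- function(aln, min_pi = 5L, max_missing = 0.10,
                         gc_range = c(0.30, 0.70)) {
  pi <- count_parsimony_informative(aln)
  mf <- missing_fraction(aln)
  gc <- if (mf == 1) NA_real_ else gc_content(aln)
  pass <- !is.na(gc) && pi > min_pi && mf < max_missing &&
    gc > gc_range[1] && gc < gc_range[2]
  data.frame(pi_sites = pi, missing_frac = mf, gc_frac = gc, pass = pass)
}

#' Apply the alignment retention filter
#'
#' Keeps alignments with more than `min_pi` parsimony-informative sites, less
#' than `max_missing` missing data, and GC content strictly inside
#' `gc_range`.  All three cut-offs are strict inequalities.
#'
#' @param alignments List of `windowed_alignment` objects.
#' @inheritParams alignment_qc
#' @return List with `retained` (input order preserved) and `report` (one
#'   row per input alignment, with an `alignment` id column).
#' @export
apply_filters <- function(alignments, min_pi = 5L, max_missing = 0.10,
                          gc_range = c(0.30, 0.70)) {
  report <- do.call(rbind, lapply(alignments, alignment_qc, min_pi = min_pi,
                                  max_missing = max_missing, gc_range = gc_range))
  if (is.null(report)) report <- data.frame(pi_sites = integer(),
                                            missing_frac = numeric(),
                                            gc_frac = numeric(), pass = logical())
  ids <- vapply(seq_along(alignments), function(k) {
    a <- alignments[[k]]
    if (inherits(a, "windowed_alignment") && !is.na(a$contig))
      sprintf("%s:%d-%d", a$contig, a$start, a$end) else sprintf("aln_%d", k)
  }, "")
  report <- data.frame(alignment = ids, report, stringsAsFactors = FALSE)
  rownames(report) <- NULL
  list(retained = alignments[report$pass], report = report)
}
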