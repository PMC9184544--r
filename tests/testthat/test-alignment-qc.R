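# Alignment statistics and the retention filter.

test_that("parsimony-informative sites follow the two-states-twice definition", {
  # column-by-column enumeration example: informative columns are 1 and 4
  aln <- aln_from_cols(list(c("A", "A", "C", "C"),
                            c("A", "A", "A", "C"),
                            c("A", "C", "G", "T"),
                            c("A", "A", "C", "C"),
                            c("N", "A", "C", "C")))
  expect_identical(count_parsimony_informative(aln), 2L)
  # no variation
  expect_identical(count_parsimony_informative(c(a = "AAAA", b = "AAAA", c = "AAAA")), 0L)
  # two rows can never reach two states twice
  expect_identical(count_parsimony_informative(c(a = "ACGTACGT", b = "TGCATGCA")), 0L)
  expect_error(count_parsimony_informative(c(a = "ACG", b = "AC")), "equal length")
})

test_that("PI count is invariant under row and column permutation", {
  set.seed(1)
  for (rep in 1:5) {
    m <- matrix(sample(c("A", "C", "G", "T", "N"), 6 * 40, TRUE,
                       prob = c(.3, .2, .2, .25, .05)), nrow = 6)
    rows <- apply(m, 1, paste, collapse = "")
    names(rows) <- paste0("t", 1:6)
    pi0 <- count_parsimony_informative(rows)
    rows_r <- rows[sample(6)]
    m_c <- m[, sample(40)]
    rows_c <- stats::setNames(apply(m_c, 1, paste, collapse = ""), names(rows))
    expect_identical(count_parsimony_informative(rows_r), pi0)
    expect_identical(count_parsimony_informative(rows_c), pi0)
  }
})

test_that("missing fraction and GC content count cells as defined", {
  expect_identical(missing_fraction(c(a = "ACGT", b = "ACGT")), 0)
  expect_identical(missing_fraction(c(a = "NNNN", b = "NNNN")), 1)
  # 4 x 10 alignment with 3 N cells
  aln <- c(a = "ACGTACGTNN", b = "ACGTACGTAC", c = "NCGTACGTAC", d = "ACGTACGTAC")
  expect_equal(missing_fraction(aln), 0.075)

  expect_identical(gc_content(c(a = "GGGG", b = "GGGG")), 1)
  expect_equal(gc_content(c(a = "ACGT", b = "ACGT")), 0.5)
  expect_equal(gc_content(c(a = "ACGTN", b = "GGCCN")), 0.75)   # 6 GC / 8 non-N
  expect_error(gc_content(c(a = "NNN", b = "NNN")), "only N")
})

test_that("adding an all-N column never raises PI and never lowers missingness", {
  rows <- c(a = "AACCA", b = "AACCT", c = "CACCA", d = "CTCCT")
  rows_n <- paste0(rows, "N")
  names(rows_n) <- names(rows)
  expect_lte(count_parsimony_informative(rows_n), count_parsimony_informative(rows))
  expect_gte(missing_fraction(rows_n), missing_fraction(rows))
})

test_that("the retention filter applies the three strict cut-offs", {
  inf <- c("A", "A", "C", "C")
  constA <- c("A", "A", "A", "A"); constG <- c("G", "G", "G", "G")
  constT <- c("T", "T", "T", "T"); allN <- c("N", "N", "N", "N")
  pi5 <- aln_from_cols(c(rep(list(inf), 5), rep(list(constG), 7), rep(list(constT), 8)))
  pi6 <- aln_from_cols(c(rep(list(inf), 6), rep(list(constG), 7), rep(list(constT), 7)))
  miss10 <- aln_from_cols(c(rep(list(inf), 6), rep(list(constG), 3), list(allN)))
  gc30 <- aln_from_cols(c(rep(list(inf), 6), rep(list(constG), 3), rep(list(constA), 11)))
  gc70 <- aln_from_cols(c(rep(list(c("C", "C", "G", "G")), 6), rep(list(constG), 8),
                          rep(list(constT), 6)))

  expect_identical(alignment_qc(pi5)$pi_sites, 5L)
  expect_false(alignment_qc(pi5)$pass)          # "more than 5" is strict
  expect_true(alignment_qc(pi6)$pass)
  expect_equal(alignment_qc(miss10)$missing_frac, 0.10)
  expect_false(alignment_qc(miss10)$pass)       # "less than 10%" is strict
  expect_equal(alignment_qc(gc30)$gc_frac, 0.30)
  expect_false(alignment_qc(gc30)$pass)         # "greater than 30%" is strict
  expect_equal(alignment_qc(gc70)$gc_frac, 0.70)
  expect_false(alignment_qc(gc70)$pass)

  res <- apply_filters(list(pi5, pi6, miss10, gc30, gc70))
  expect_identical(res$report$pass, c(FALSE, TRUE, FALSE, FALSE, FALSE))
  expect_length(res$retained, 1L)
  expect_identical(res$retained[[1]], pi6)
  # pure function of the report: re-running yields identical retention
  expect_identical(apply_filters(list(pi5, pi6, miss10, gc30, gc70))$report, res$report)
})
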