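# Byte-level sequence helpers.  Sequences travel as single character strings
# (one per contig per haplotype); per-site work happens on raw vectors, which
# keeps million-site simulations fast without compiled code.

.ACGT <- charToRaw("ACGT")
.N <- charToRaw("N")

seq_raw <- function(x) charToRaw(x)
raw_seq <- function(r) rawToChar(r)

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)

# JC69 per-site mismatch probability at branch length d (substitutions/site)
jc_mismatch <- function(d) 0.75 * (1 - exp(-4 * d / 3))

# Mutate each site independently with probability p to one of the three other
# bases, uniformly.  Operates on a raw vector over ACGT.  Consumes RNG.
mutate_sites <- function(r, p) {
  if (p <= 0 || length(r) == 0L) return(r)
  hit <- which(stats::runif(length(r)) < p)
  if (!length(hit)) return(r)
  old <- match(r[hit], .ACGT)
  shift <- sample.int(3L, length(hit), replace = TRUE)
  r[hit] <- .ACGT[(old - 1L + shift) %% 4L + 1L]
  r
}

random_sequence_raw <- function(n, base_comp) {
  sample(.ACGT, n, replace = TRUE, prob = base_comp)
}

# Error (naming record and offset) on any character outside A/C/G/T/N.
check_alphabet <- function(x, what = "sequence") {
  bad <- regexpr("[^ACGTN]", x)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    nm <- if (!is.null(names(x))) names(x)[i] else as.character(i)
    stopf("invalid character in %s '%s' at offset %d", what, nm, bad[i])
  }
  invisible(x)
}

# Recycle a scalar over `nm` or reorder a named vector to `nm`.
rep_named <- function(x, nm, what = "value") {
  if (is.null(names(x))) {
    if (length(x) == 1L) x <- rep(x, length(nm))
    if (length(x) != length(nm)) stopf("%s must be scalar or named per species", what)
    names(x) <- nm
  }
  if (!all(nm %in% names(x))) stopf("%s missing for species: %s", what,
                                    paste(setdiff(nm, names(x)), collapse = ", "))
  x[nm]
}
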