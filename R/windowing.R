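# Segment planning and extraction.  Coordinates are 0-based half-open
# internally (BED convention); 1-based only at the VCF boundary.

#' Tile one contig with fixed-length segments and fixed gaps
#'
#' Starting at `start` (0-based), take `L` bp, skip `G` bp, and repeat until
#' the next full segment would overrun the contig; any final partial segment
#' is discarded.
#'
#' @param contig_length Contig length in bp.
#' @param start 0-based start of the first segment.
#' @param L Segment length, bp (`> 0`).
#' @param G Gap between segments, bp (`>= 0`).
#' @return A data frame with columns `start`, `end` (0-based half-open).
#' @export
tile_contig <- function(contig_length, start, L, G) {
  if (L <= 0) stopf("segment length L must be > 0")
  if (G < 0) stopf("gap G must be >= 0")
  if (start + L > contig_length)
    return(data.frame(start = integer(), end = integer()))
  starts <- seq(from = start, to = contig_length - L, by = L + G)
  data.frame(start = as.integer(starts), end = as.integer(starts + L))
}

#' Plan homologous genome segments across contigs
#'
#' For each contig a starting point is drawn uniformly between position
#' 100,000 and 1,000,000 (clamped to `length - L`; this keeps segments away
#' from potential telomeres), then the contig is tiled with `L`-bp segments
#' separated by `G`-bp gaps.  Contigs too short for the minimum start
#' contribute no segments.  Deterministic under `seed`.
#'
#' @param contig_lengths Named integer vector of contig lengths (bp).
#' @param L Segment length, bp.  The reference scheme uses 10 kb or 100 kb.
#' @param G Inter-segment gap, bp.  The reference scheme uses 100 kb or 1 Mb.
#' @param seed Integer seed for the per-contig start draws.
#' @param min_start Minimum 0-based segment start (default 100,000).
#' @param max_start Maximum 0-based segment start before clamping (default
#'   1,000,000).
#' @return An object of class `segment_plan`: list with `L`, `G`, `seed`,
#'   per-contig `starts`, and a `segments` data frame (`contig`, `start`,
#'   `end`).
#' @export
plan_segments <- function(contig_lengths, L, G, seed = 1L,
                          min_start = 100000L, max_start = 1000000L) {
  if (L <= 0) stopf("segment length L must be > 0")
  if (G < 0) stopf("gap G must be >= 0")
  if (is.null(names(contig_lengths)))
    names(contig_lengths) <- paste0("contig_", seq_along(contig_lengths))
  withr::with_seed(seed, {
    starts <- integer(0)
    segs <- list()
    for (contig in names(contig_lengths)) {
      len <- contig_lengths[[contig]]
      hi <- min(max_start, len - L)
      if (min_start + L > len || hi < min_start) next
      s0 <- if (hi == min_start) min_start else
        sample(seq.int(min_start, hi), 1L)
      starts[contig] <- as.integer(s0)
      tiles <- tile_contig(len, s0, L, G)
      if (nrow(tiles)) segs[[contig]] <- data.frame(contig = contig, tiles,
                                                   stringsAsFactors = FALSE)
    }
    segments <- if (length(segs)) do.call(rbind, segs) else
      data.frame(contig = character(), start = integer(), end = integer())
    rownames(segments) <- NULL
    structure(list(L = as.integer(L), G = as.integer(G), seed = as.integer(seed),
                   starts = starts, segments = segments),
              class = "segment_plan")
  })
}

#' Extract windowed multi-taxon alignments at planned coordinates
#'
#' Slices every individual's sequence at each planned segment.  Because all
#' sequences live in reference coordinates, the slices are already aligned
#' and no re-alignment is performed.
#'
#' @param sequences Named list: individual id -> named character vector of
#'   per-contig sequences (e.g. from [pseudo_haploidize()] or [read_fasta()]).
#' @param plan A [plan_segments()] result.
#' @return A list of `windowed_alignment` objects (fields `taxa`, `seqs`,
#'   `contig`, `start`, `end`), one per planned segment, in plan order.
#' @export
extract_alignments <- function(sequences, plan) {
  if (!inherits(plan, "segment_plan")) stopf("`plan` must be a segment_plan")
  ids <- names(sequences)
  if (is.null(ids) || any(ids == "")) stopf("`sequences` must be a named list of individuals")
  segs <- plan$segments
  for (contig in unique(segs$contig))
    for (id in ids)
      if (!contig %in% names(sequences[[id]]))
        stopf("individual '%s' has no sequence for contig '%s'", id, contig)
  lapply(seq_len(nrow(segs)), function(k) {
    contig <- segs$contig[k]; s <- segs$start[k]; e <- segs$end[k]
    rows <- vapply(ids, function(id) substr(sequences[[id]][[contig]], s + 1L, e), "")
    windowed_alignment(rows, contig = contig, start = s, end = e)
  })
}

#' Construct a windowed alignment
#'
#' @param seqs Named character vector of equal-length rows over A/C/G/T/N.
#' @param contig,start,end Source coordinates (0-based half-open).
#' @return An object of class `windowed_alignment`.
#' @export
windowed_alignment <- function(seqs, contig = NA_character_, start = NA_integer_,
                               end = NA_integer_) {
  if (is.null(names(seqs))) names(seqs) <- paste0("t", seq_along(seqs))
  len <- unique(nchar(seqs))
  if (length(len) != 1L) stopf("alignment rows must have equal length")
  check_alphabet(seqs, "alignment row")
  structure(list(taxa = names(seqs), seqs = seqs, contig = contig,
                 start = start, end = end),
            class = "windowed_alignment")
}

# rows as a raw-byte matrix, taxa x sites
aln_matrix <- function(aln) {
  seqs <- if (inherits(aln, "windowed_alignment")) aln$seqs else aln
  len <- unique(nchar(seqs))
  if (length(len) != 1L) stopf("alignment rows must have equal length")
  if (length(seqs) == 0L || len == 0L) stopf("alignment is empty")
  m <- do.call(rbind, lapply(seqs, charToRaw))
  rownames(m) <- names(seqs)
  m
}

#' Write a segment plan as BED plus sidecar
#'
#' Writes the 0-based half-open segment coordinates as a 3-column BED file
#' and the plan parameters (`L`, `G`, `seed`, per-contig starts) as a JSON
#' sidecar next to it.
#'
#' @param plan A [plan_segments()] result.
#' @param path Output BED path; the sidecar gets `.json` appended.
#' @return Invisibly, the BED path.
#' @export
write_segment_bed <- function(plan, path) {
  utils::write.table(plan$segments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(L = plan$L, G = plan$G, seed = plan$seed,
                            starts = as.list(plan$starts)),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
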