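# Readers and writers for the interchange formats: FASTA (Biostrings), a
# minimal VCF v4.2 dialect (read via VariantAnnotation; written by simple
# line formatting), TSV tables, and the simulation export/import round trip.

#' Read a FASTA file of A/C/G/T/N sequences
#'
#' Lowercase input is uppercased; any character outside A/C/G/T/N raises an
#' error naming the record and offset.
#'
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stopf("FASTA file not found: %s", path)
  ss <- Biostrings::readBStringSet(path)
  out <- toupper(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(out))
  check_alphabet(out, "FASTA record")
  out
}

#' Write sequences as FASTA (wrapped at 80 columns)
#'
#' @param seqs Named character vector of A/C/G/T/N sequences.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path) {
  check_alphabet(seqs, "FASTA record")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path, width = 80L)
  invisible(path)
}

#' Read a VCF into a genotype matrix
#'
#' Accepts the minimal dialect this package writes: biallelic SNVs with
#' `GT:DP:GQ`.  Multi-allelic and indel records are skipped with a warning;
#' FORMAT fields required by downstream filters must be present or an error
#' names the missing field.
#'
#' @param path VCF path (plain text).
#' @param require_fields FORMAT fields that must exist (default GT, DP, GQ).
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path, require_fields = c("GT", "DP", "GQ")) {
  if (!file.exists(path)) stopf("VCF file not found: %s", path)
  v <- VariantAnnotation::readVcf(path)
  g <- VariantAnnotation::geno(v)
  for (f in require_fields)
    if (!f %in% names(g)) stopf("VCF is missing required FORMAT field '%s'", f)
  rr <- SummarizedExperiment::rowRanges(v)
  ref <- as.character(VariantAnnotation::ref(v))
  alt_l <- VariantAnnotation::alt(v)
  n_alt <- lengths(alt_l)
  alt <- rep(NA_character_, length(ref))
  alt[n_alt == 1L] <- as.character(unlist(alt_l[n_alt == 1L]))
  snv <- n_alt == 1L & nchar(ref) == 1L & !is.na(alt) & nchar(alt) == 1L
  if (any(!snv))
    warning(sprintf("skipped %d non-SNV or multi-allelic record(s)", sum(!snv)))
  gt <- g$GT[snv, , drop = FALSE]
  map <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L,
           "0|0" = 0L, "0|1" = 1L, "1|0" = 1L, "1|1" = 2L)
  dosage <- matrix(map[gt], nrow = nrow(gt), ncol = ncol(gt))
  dp <- if ("DP" %in% names(g))
    matrix(as.integer(g$DP[snv, , drop = FALSE]), nrow = nrow(gt), ncol = ncol(gt)) else NULL
  gq <- if ("GQ" %in% names(g))
    matrix(as.integer(g$GQ[snv, , drop = FALSE]), nrow = nrow(gt), ncol = ncol(gt)) else NULL
  variants <- data.frame(
    contig = as.character(GenomeInfoDb::seqnames(rr))[snv],
    pos = BiocGenerics::start(rr)[snv],
    ref = ref[snv], alt = alt[snv], stringsAsFactors = FALSE)
  genotype_matrix(colnames(gt), variants, dosage, dp, gq)
}

#' Write a genotype matrix as VCF v4.2
#'
#' Emits the minimal dialect: biallelic SNVs with unphased `GT:DP:GQ` per
#' sample, one `##contig` line per contig.
#'
#' @param gm A [genotype_matrix()].
#' @param path Output path.
#' @param contig_lengths Optional named lengths for the `##contig` headers.
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(gm, path, contig_lengths = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  contigs <- unique(gm$variants$contig)
  ctg_lines <- vapply(contigs, function(ct) {
    if (!is.null(contig_lengths) && ct %in% names(contig_lengths))
      sprintf("##contig=<ID=%s,length=%d>", ct, as.integer(contig_lengths[[ct]]))
    else sprintf("##contig=<ID=%s>", ct)
  }, "")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=islandrad",
    ctg_lines,
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$samples), collapse = "\t"))
  gt_map <- c("0/0", "0/1", "1/1")
  body <- character(nrow(gm$variants))
  if (nrow(gm$variants)) {
    cells <- matrix("", nrow(gm$variants), length(gm$samples))
    for (i in seq_along(gm$samples)) {
      dos <- gm$dosage[, i]
      gts <- ifelse(is.na(dos), "./.", gt_map[dos + 1L])
      cells[, i] <- sprintf("%s:%d:%d", gts,
                            ifelse(is.na(gm$dp[, i]), 0L, gm$dp[, i]),
                            ifelse(is.na(gm$gq[, i]), 0L, gm$gq[, i]))
    }
    left <- sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t.\tGT:DP:GQ",
                    gm$variants$contig, gm$variants$pos,
                    gm$variants$ref, gm$variants$alt)
    body <- paste(left, apply(cells, 1L, paste, collapse = "\t"), sep = "\t")
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Export a simulated radiation to files
#'
#' Writes, under `outdir`: one pseudo-haploid FASTA per individual
#' (`<id>.fa`), the variant genotypes as VCF (`variants.vcf`), the sample
#' table (`individuals.tsv`), contig lengths (`contigs.tsv`), and the truth
#' record (`truth_species_tree.nwk`, `truth_individuals.tsv`,
#' `truth_divergence.tsv`, `truth_segments.tsv`).
#'
#' @param sim A `genome_set` from [simulate_radiation()].
#' @param outdir Output directory (created if needed).
#' @param pseudohap_seed Seed for the pseudo-haploid allele coin.
#' @return Invisibly, a named list of written paths.
#' @export
export_simulation <- function(sim, outdir,
                              pseudohap_seed = sim$config$seed + 101L) {
  stopifnot(inherits(sim, "genome_set"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stopf("cannot create output directory: %s", outdir)
  seqs <- pseudo_haploidize(sim, seed = pseudohap_seed)
  fasta <- character(0)
  for (id in names(seqs)) {
    p <- file.path(outdir, paste0(id, ".fa"))
    write_fasta(seqs[[id]], p)
    fasta[id] <- p
  }
  vcf <- file.path(outdir, "variants.vcf")
  write_vcf(sim$genotypes, vcf, contig_lengths = sim$contig_lengths)
  tsv <- function(df, name) {
    p <- file.path(outdir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  ind <- tsv(sim$individuals, "individuals.tsv")
  ctg <- tsv(data.frame(contig = names(sim$contig_lengths),
                        length = as.integer(sim$contig_lengths)), "contigs.tsv")
  nwk <- file.path(outdir, "truth_species_tree.nwk")
  ape::write.tree(sim$truth$tree, file = nwk)
  t_ind <- tsv(sim$truth$individuals, "truth_individuals.tsv")
  ed <- sim$truth$expected_divergence
  t_div <- tsv(data.frame(id = rownames(ed), ed, check.names = FALSE),
               "truth_divergence.tsv")
  t_seg <- tsv(sim$truth$segments, "truth_segments.tsv")
  invisible(list(fasta = fasta, vcf = vcf, individuals = ind, contigs = ctg,
                 truth_tree = nwk, truth_individuals = t_ind,
                 truth_divergence = t_div, truth_segments = t_seg))
}

#' Re-import an exported simulation
#'
#' Reads back everything [export_simulation()] wrote, losslessly.
#'
#' @param dir Directory written by [export_simulation()].
#' @return List with `sequences` (per-individual per-contig pseudo-haploid),
#'   `genotypes` ([genotype_matrix()]), `individuals`, `contig_lengths`, and
#'   `truth` (`tree`, `individuals`, `expected_divergence`, `segments`).
#' @export
import_simulation <- function(dir) {
  if (!dir.exists(dir)) stopf("directory not found: %s", dir)
  ind <- utils::read.table(file.path(dir, "individuals.tsv"), header = TRUE,
                           sep = "\t", stringsAsFactors = FALSE)
  ctg <- utils::read.table(file.path(dir, "contigs.tsv"), header = TRUE,
                           sep = "\t", stringsAsFactors = FALSE)
  contig_lengths <- stats::setNames(as.integer(ctg$length), ctg$contig)
  sequences <- lapply(ind$id, function(id) read_fasta(file.path(dir, paste0(id, ".fa"))))
  names(sequences) <- ind$id
  genotypes <- read_vcf(file.path(dir, "variants.vcf"))
  div <- utils::read.table(file.path(dir, "truth_divergence.tsv"), header = TRUE,
                           sep = "\t", check.names = FALSE, stringsAsFactors = FALSE)
  ed <- as.matrix(div[, -1, drop = FALSE])
  rownames(ed) <- div$id
  truth <- list(
    tree = ape::read.tree(file.path(dir, "truth_species_tree.nwk")),
    individuals = utils::read.table(file.path(dir, "truth_individuals.tsv"),
                                    header = TRUE, sep = "\t", stringsAsFactors = FALSE),
    expected_divergence = ed,
    segments = utils::read.table(file.path(dir, "truth_segments.tsv"),
                                 header = TRUE, sep = "\t", stringsAsFactors = FALSE))
  list(sequences = sequences, genotypes = genotypes, individuals = ind,
       contig_lengths = contig_lengths, truth = truth)
}
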