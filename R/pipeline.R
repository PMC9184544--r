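# Configuration, the end-to-end pipeline, the run manifest, and a thin CLI.

#' Build a pipeline configuration
#'
#' One object drives every stage; defaults are the reference analysis values
#' (100 kb segments separated by 100 kb; PI > 5, missing < 10%,
#' 0.30 < GC < 0.70; DP >= 6, GQ > 17; MAC >= 1; LD window 50 kb, step 5
#' variants, r2 <= 0.5; reference quantile 0.95).  Either a `simulation`
#' block or `inputs` paths must be supplied.
#'
#' @param simulation A [sim_config()], or `NULL` when reading real inputs.
#' @param inputs `NULL`, or a list with `fasta` (named vector: individual ->
#'   FASTA path), `vcf`, `labels` (TSV with columns `id`, `species`).
#' @param L,G Segment length and gap in bp.
#' @param min_pi,max_missing_aln,gc_range Alignment retention thresholds.
#' @param min_depth,min_gq Genotype callability filters for heterozygosity.
#' @param min_mac,window_bp,step_variants,r2_max Site filter and LD pruning.
#' @param q Within-species reference quantile for the lineage decision.
#' @param tree_mode `"auto"`, `"exhaustive"` or `"greedy"`.
#' @param focal Character vector of focal individual ids.
#' @param seed Master seed; every stage derives its stream from it.
#' @param outdir Default output directory (optional).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = NULL, inputs = NULL,
                            L = 100000L, G = 100000L,
                            min_pi = 5L, max_missing_aln = 0.10,
                            gc_range = c(0.30, 0.70),
                            min_depth = 6L, min_gq = 18L,
                            min_mac = 1L, window_bp = 50000L,
                            step_variants = 5L, r2_max = 0.5,
                            q = 0.95, tree_mode = "auto",
                            focal = character(), seed = 1L, outdir = NULL) {
  if (is.null(simulation) && is.null(inputs))
    stopf("supply either a `simulation` block or `inputs` paths")
  if (!is.null(simulation) && !inherits(simulation, "sim_config"))
    stopf("`simulation` must be a sim_config")
  structure(list(simulation = simulation, inputs = inputs,
                 L = as.integer(L), G = as.integer(G),
                 min_pi = as.integer(min_pi), max_missing_aln = max_missing_aln,
                 gc_range = gc_range, min_depth = as.integer(min_depth),
                 min_gq = as.integer(min_gq), min_mac = as.integer(min_mac),
                 window_bp = as.integer(window_bp),
                 step_variants = as.integer(step_variants), r2_max = r2_max,
                 q = q, tree_mode = tree_mode, focal = focal,
                 seed = as.integer(seed), outdir = outdir),
            class = "pipeline_config")
}

#' Serialize / deserialize a pipeline configuration as JSON
#'
#' The species tree travels as a Newick string; the round trip is lossless.
#'
#' @param config A [pipeline_config()].
#' @param path JSON path.
#' @return `write_pipeline_config` invisibly returns `path`;
#'   `read_pipeline_config` returns a [pipeline_config()].
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  if (!is.null(x$simulation)) {
    s <- unclass(x$simulation)
    s$species <- list(tree = ape::write.tree(s$species$tree),
                      theta = as.list(s$species$theta),
                      n_individuals = as.list(s$species$n_individuals))
    s$contig_lengths <- as.list(s$contig_lengths)
    x$simulation <- s
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  sim <- NULL
  if (!is.null(x$simulation)) {
    s <- x$simulation
    spec <- species_tree_spec(s$species$tree,
                              unlist(s$species$theta),
                              unlist(s$species$n_individuals))
    sim <- sim_config(spec, unlist(s$contig_lengths),
                      base_comp = unlist(s$base_comp), p_ils = s$p_ils,
                      block_length = s$block_length,
                      missing_rate = s$missing_rate,
                      missing_run_length = s$missing_run_length,
                      depth_mean = s$depth_mean, gq_mean = s$gq_mean,
                      gq_sd = s$gq_sd, seed = s$seed)
  }
  pipeline_config(simulation = sim, inputs = x$inputs,
                  L = x$L, G = x$G, min_pi = x$min_pi,
                  max_missing_aln = x$max_missing_aln,
                  gc_range = unlist(x$gc_range),
                  min_depth = x$min_depth, min_gq = x$min_gq,
                  min_mac = x$min_mac, window_bp = x$window_bp,
                  step_variants = x$step_variants, r2_max = x$r2_max,
                  q = x$q, tree_mode = x$tree_mode,
                  focal = unlist(x$focal) %||% character(),
                  seed = x$seed, outdir = x$outdir)
}

#' Run the full lineage-assignment pipeline
#'
#' Simulates (or ingests) genomes, then runs the three analyses end to end:
#' segment planning and extraction, alignment QC, gene trees and the quartet
#' species tree; heterozygosity, normalised pairwise distances, the distance
#' hierarchy and focal classification; site filtering, LD pruning and PCA.
#' When `outdir` is given, writes per-stage outputs plus a run manifest.
#' Byte-reproducible from `(config, seed)`.
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory (overrides `config$outdir`; `NULL` skips
#'   file output).
#' @param verbose Log per-stage record counts (default TRUE).
#' @return An object of class `pipeline_result` with elements `sim` (when
#'   simulated), `plan`, `qc`, `gene_trees`, `species_tree`, `het`,
#'   `distances`, `hierarchy`, `assignments`, `pca`, `pruned_ids`,
#'   `manifest`.
#' @export
run_pipeline <- function(config, outdir = config$outdir, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  seed <- config$seed

  sim <- NULL
  if (!is.null(config$simulation)) {
    simcfg <- config$simulation
    simcfg$seed <- seed
    sim <- simulate_radiation(simcfg)
    sequences <- pseudo_haploidize(sim, seed = seed + 101L)
    gm <- sim$genotypes
    labels <- stats::setNames(sim$individuals$species, sim$individuals$id)
    contig_lengths <- sim$contig_lengths
    mask_bp <- vapply(sim$individuals$id, function(id)
      sum(vapply(sim$mask[[id]], function(r) sum(r$end - r$start), 0)), 0)
    say("simulated %d individuals over %d bp (%d variant sites)",
        nrow(sim$individuals), sum(as.numeric(contig_lengths)), nrow(gm$variants))
  } else {
    inp <- config$inputs
    for (f in c(unlist(inp$fasta), inp$vcf, inp$labels))
      if (!file.exists(f)) stopf("input path not found: %s", f)
    sequences <- lapply(inp$fasta, read_fasta)
    names(sequences) <- names(inp$fasta)
    gm <- read_vcf(inp$vcf)
    lab <- utils::read.table(inp$labels, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    labels <- stats::setNames(lab$species, lab$id)
    contig_lengths <- vapply(sequences[[1]], nchar, 0L)
    mask_bp <- stats::setNames(rep(0, length(sequences)), names(sequences))
  }

  plan <- plan_segments(contig_lengths, config$L, config$G, seed = seed + 1L)
  alns <- extract_alignments(sequences, plan)
  say("planned %d segments; extracted %d alignments", nrow(plan$segments), length(alns))

  qc <- apply_filters(alns, min_pi = config$min_pi,
                      max_missing = config$max_missing_aln,
                      gc_range = config$gc_range)
  say("alignment QC retained %d / %d", length(qc$retained), length(alns))

  gts <- build_gene_trees(qc$retained)
  say("built %d gene trees (%d skipped)", length(gts$trees), nrow(gts$skipped))
  st <- infer_species_tree(gts, mode = config$tree_mode)
  say("species tree (%s): quartet score %d", st$mode, st$score)

  n_inv <- pmax(0, sum(as.numeric(contig_lengths)) - nrow(gm$variants) -
                  mask_bp[gm$samples])
  het <- estimate_heterozygosity(gm, min_depth = config$min_depth,
                                 min_gq = config$min_gq, n_invariant = n_inv)

  diffs <- pairwise_segment_diffs(qc$retained)
  dist_df <- pairwise_normalized_distances(diffs, het)
  hier <- build_hierarchy(dist_df, labels, focal_ids = config$focal)
  assignments <- lapply(config$focal, function(f)
    classify_focal(hier, f, q = config$q))
  names(assignments) <- config$focal
  for (a in assignments)
    say("focal %s -> %s (nearest %s)", a$focal, a$decision, a$nearest)

  gm_f <- site_filter(gm, min_mac = config$min_mac, max_missing = 0,
                      depth_band = 1)
  pruned <- ld_prune(gm_f, window_bp = config$window_bp,
                     step_variants = config$step_variants,
                     r2_max = config$r2_max)
  gm_p <- subset_variants(gm_f, pruned)
  say("site filter kept %d / %d variants; LD pruning kept %d",
      nrow(gm_f$variants), nrow(gm$variants), length(pruned))
  pca <- pca_genotypes(gm_p, k = min(10L, length(gm$samples) - 1L))

  manifest <- list(
    tool = "islandrad", version = as.character(utils::packageVersion("islandrad")),
    seed = seed,
    counts = list(
      individuals = length(gm$samples),
      contigs = length(contig_lengths),
      segments_planned = nrow(plan$segments),
      alignments_retained = length(qc$retained),
      gene_trees = length(gts$trees),
      gene_trees_skipped = nrow(gts$skipped),
      pairs = nrow(dist_df),
      variants = nrow(gm$variants),
      variants_after_site_filter = nrow(gm_f$variants),
      variants_after_ld_prune = length(pruned)))

  result <- structure(list(sim = sim, sequences = sequences, plan = plan,
                           qc = qc, gene_trees = gts, species_tree = st,
                           het = het, distances = dist_df, hierarchy = hier,
                           assignments = assignments, pca = pca,
                           pruned_ids = pruned, manifest = manifest,
                           config = config),
                      class = "pipeline_result")
  if (!is.null(outdir)) write_pipeline_outputs(result, outdir)
  result
}

write_pipeline_outputs <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, name)
    utils::write.table(df, file.path(outdir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  write_segment_bed(result$plan, file.path(outdir, "segments.bed"))
  tsv(result$qc$report, "alignment_qc.tsv")
  write_gene_trees(result$gene_trees, file.path(outdir, "gene_trees.nwk"))
  ape::write.tree(result$species_tree$tree, file.path(outdir, "species_tree.nwk"))
  tsv(result$species_tree$support, "species_tree_support.tsv")
  tsv(result$het, "heterozygosity.tsv")
  tsv(result$hierarchy$distances, "distances.tsv")
  tsv(result$hierarchy$summary, "distance_summary.tsv")
  writeLines(result$pruned_ids, file.path(outdir, "pruned_variants.txt"))
  pc <- data.frame(individual = rownames(result$pca$scores), result$pca$scores)
  tsv(pc, "pca_scores.tsv")
  tsv(data.frame(axis = seq_along(result$pca$var_explained),
                 var_explained = result$pca$var_explained), "pca_variance.tsv")
  if (length(result$assignments))
    jsonlite::write_json(lapply(result$assignments, unclass),
                         file.path(outdir, "assignment.json"),
                         auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(result$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  m <- x$manifest$counts
  cat(sprintf("Pipeline run (seed %d): %d individuals, %d segments -> %d retained -> %d gene trees\n",
              x$manifest$seed, m$individuals, m$segments_planned,
              m$alignments_retained, m$gene_trees))
  cat(sprintf("  quartet species tree score %d (%s); %d variants -> %d after filters/pruning\n",
              x$species_tree$score, x$species_tree$mode, m$variants,
              m$variants_after_ld_prune))
  for (a in x$assignments) print(a)
  invisible(x)
}

#' Command-line entry point
#'
#' A thin shell over the package functions, used by
#' `inst/scripts/islandrad.R`.  Subcommands: `simulate` (run the config's
#' simulation block and export it) and `run-all` (the full pipeline).  Flags:
#' `--config <path>` (required), `--outdir <path>`, `--seed <int>`,
#' `--quiet`.  The per-stage operations are exposed as the exported R
#' functions.
#'
#' @param args Character vector of command-line arguments.
#' @return Integer exit status (0 on success), invisibly.
#' @export
run_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: islandrad <simulate|run-all> --config <path> [--outdir <path>]",
    "[--seed <int>] [--quiet]")
  fail <- function(msg, status = 1L) {
    message(msg)
    return(invisible(status))
  }
  if (!length(args)) return(fail(usage, 2L))
  cmd <- args[1]
  args <- args[-1]
  opts <- list(outdir = NULL, seed = NULL, quiet = FALSE)
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (a == "--quiet") { opts$quiet <- TRUE; i <- i + 1L; next }
    if (a %in% c("--config", "--outdir", "--seed")) {
      if (i == length(args)) return(fail(sprintf("missing value for %s\n%s", a, usage), 2L))
      opts[[sub("^--", "", a)]] <- args[i + 1L]
      i <- i + 2L
      next
    }
    return(fail(sprintf("unknown argument '%s'\n%s", a, usage), 2L))
  }
  if (!cmd %in% c("simulate", "run-all"))
    return(fail(sprintf("unknown subcommand '%s'\n%s", cmd, usage), 2L))
  if (is.null(opts$config)) return(fail(paste("--config is required;", usage), 2L))
  if (!file.exists(opts$config))
    return(fail(sprintf("config file not found: %s", opts$config), 1L))
  config <- read_pipeline_config(opts$config)
  if (!is.null(opts$seed)) config$seed <- as.integer(opts$seed)
  outdir <- opts$outdir %||% config$outdir
  status <- tryCatch({
    if (cmd == "simulate") {
      if (is.null(config$simulation)) stopf("config has no simulation block")
      if (is.null(outdir)) stopf("--outdir is required for simulate")
      simcfg <- config$simulation
      simcfg$seed <- config$seed
      export_simulation(simulate_radiation(simcfg), outdir)
    } else {
      if (is.null(outdir)) stopf("--outdir is required for run-all")
      run_pipeline(config, outdir = outdir, verbose = !opts$quiet)
    }
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
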