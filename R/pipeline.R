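# Orchestration: each run_* function ties a stage of the analysis together,
# writes its result files into an output directory, and records a manifest
# (parameters, seed, counts, package version) sufficient to reproduce the
# run exactly. Logs go to stderr via message(); result files never mix logs.

.write_manifest <- function(out_dir, command, params, outputs, counts = list()) {
  manifest <- list(command = command,
                   quartetscan_version =
                     as.character(utils::packageVersion("quartetscan")),
                   params = params, outputs = outputs, counts = counts)
  path <- file.path(out_dir, "manifest.yaml")
  yaml::write_yaml(manifest, path)
  path
}

.ensure_dir <- function(out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  out_dir
}

#' Simulate a dataset and write it to disk
#'
#' Writes `trees.tsv` (locus ID + newick), `loci.tsv` (locus table),
#' `truth.tsv` (block labels) and `manifest.yaml`. Reruns with the same
#' configuration produce byte-identical files.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @return the [simulate_genome()] result, invisibly.
#' @export
run_simulate <- function(config, out_dir) {
  .ensure_dir(out_dir)
  sim <- simulate_genome(config)
  f_trees <- file.path(out_dir, "trees.tsv")
  f_table <- file.path(out_dir, "loci.tsv")
  f_truth <- file.path(out_dir, "truth.tsv")
  write_locus_trees(sim$trees, f_trees)
  write_locus_table(sim$table, f_table)
  utils::write.table(sim$truth, f_truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cfg <- sim$config
  cfg$species_tree <- if (is.character(cfg$species_tree)) cfg$species_tree
                      else ape::write.tree(cfg$species_tree)
  cfg$block_topology <- if (is.character(cfg$block_topology)) cfg$block_topology
                        else ape::write.tree(cfg$block_topology)
  .write_manifest(out_dir, "simulate", unclass(cfg),
                  outputs = basename(c(f_trees, f_table, f_truth)),
                  counts = list(n_loci = nrow(sim$table),
                                n_block = sum(sim$truth$in_block)))
  message("simulated ", nrow(sim$table), " loci (",
          sum(sim$truth$in_block), " in block) -> ", out_dir)
  invisible(sim)
}

#' Run the genome scan and write result files
#'
#' For each scanned branch writes `track_<branch>.tsv` (per-locus QQS),
#' `windows_<branch>.tsv` (window means, Z, p, BH-adjusted p and
#' `neg_log10_p_adj` for Manhattan-style plots), `regions_<branch>.bed`, a
#' per-branch `summary.tsv`, and `manifest.yaml`.
#'
#' @param trees path to a locus-tree file or a named tree list.
#' @param table path to a locus table or a locus-table data.frame.
#' @param clades path to a clade config (YAML) or a [clade_model()].
#' @param out_dir output directory.
#' @inheritParams genome_scan
#' @return the [genome_scan()] object, invisibly.
#' @export
run_scan <- function(trees, table, clades, out_dir,
                     quads = NULL, w = 20, alpha = 0.01,
                     sex_chromosomes = character(0),
                     sigma_method = "window", max_gap_loci = 0) {
  .ensure_dir(out_dir)
  if (is.character(trees)) trees <- read_locus_trees(trees)
  if (is.character(table)) table <- read_locus_table(table)
  if (is.character(clades)) clades <- read_clade_config(clades)
  if (is.null(quads)) quads <- names(clades$quadripartitions)
  scan <- genome_scan(trees, table, clades, quads = quads, w = w,
                      alpha = alpha, sex_chromosomes = sex_chromosomes,
                      sigma_method = sigma_method,
                      max_gap_loci = max_gap_loci)
  outputs <- character(0)
  for (qn in names(scan$branches)) {
    b <- scan$branches[[qn]]
    f_track <- file.path(out_dir, paste0("track_", qn, ".tsv"))
    write_support_track(b$track, f_track)
    wr <- b$windows
    wr$neg_log10_p_adj <- -log10(wr$p_adj)
    f_win <- file.path(out_dir, paste0("windows_", qn, ".tsv"))
    utils::write.table(wr, f_win, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    f_bed <- file.path(out_dir, paste0("regions_", qn, ".bed"))
    write_regions_bed(b$regions, f_bed)
    outputs <- c(outputs, basename(c(f_track, f_win, f_bed)))
  }
  f_sum <- file.path(out_dir, "summary.tsv")
  utils::write.table(scan$summary, f_sum, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  outputs <- c(outputs, basename(f_sum))
  .write_manifest(out_dir, "scan",
                  params = list(quads = quads, w = w, alpha = alpha,
                                sex_chromosomes = sex_chromosomes,
                                sigma_method = sigma_method,
                                max_gap_loci = max_gap_loci),
                  outputs = outputs,
                  counts = list(n_loci = nrow(table),
                                n_branches = length(scan$branches)))
  message("scanned ", length(scan$branches), " branch(es) over ",
          nrow(table), " loci -> ", out_dir)
  invisible(scan)
}

#' Post-process coalescent-HMM posteriors and write fraction tracks
#'
#' Assigns each site to its maximum-posterior state, tiles fixed-width
#' windows, and writes `fractions.tsv` (counts and support fractions per
#' window), `ils.tsv` (per-chromosome deep and discordant-only fractions
#' with the MSC admissibility verdict), and `manifest.yaml`.
#'
#' @param posteriors path to a posterior TSV (see [read_site_posteriors()])
#'   or an equivalent data.frame.
#' @param out_dir output directory.
#' @param window_bp window width in bp.
#' @return the window-fractions data.frame, invisibly.
#' @export
run_coalhmm_post <- function(posteriors, out_dir, window_bp = 100000) {
  .ensure_dir(out_dir)
  if (is.character(posteriors)) posteriors <- read_site_posteriors(posteriors)
  states <- assign_states(posteriors)
  fr <- window_fractions(states, window_bp = window_bp)
  f_fr <- file.path(out_dir, "fractions.tsv")
  utils::write.table(fr, f_fr, sep = "\t", quote = FALSE, row.names = FALSE)
  ils <- do.call(rbind, lapply(split(fr, fr$chrom), function(x) {
    lv <- ils_level(x)
    data.frame(chrom = x$chrom[1L], deep = lv$deep,
               discordant = lv$discordant,
               admissible = as.character(msc_admissible(lv$discordant)),
               stringsAsFactors = FALSE)
  }))
  rownames(ils) <- NULL
  f_ils <- file.path(out_dir, "ils.tsv")
  utils::write.table(ils, f_ils, sep = "\t", quote = FALSE, row.names = FALSE)
  .write_manifest(out_dir, "coalhmm-post",
                  params = list(window_bp = window_bp),
                  outputs = basename(c(f_fr, f_ils)),
                  counts = list(n_sites = nrow(states), n_windows = nrow(fr)))
  message(nrow(states), " sites -> ", nrow(fr), " windows -> ", out_dir)
  invisible(fr)
}

#' Run a taxon-removal experiment and write its table
#'
#' Writes `taxon_removal.tsv` (per removal set: mean, median and SE of the
#' per-locus quartet-score difference between the two candidates) and
#' `manifest.yaml`.
#'
#' @param trees path to a locus-tree file or a named tree list.
#' @param candidate_a,candidate_b paths to newick files or `"phylo"` objects.
#' @param removal_sets named list of taxon vectors (see
#'   [taxon_removal_experiment()]).
#' @param out_dir output directory.
#' @return the experiment data.frame, invisibly.
#' @export
run_taxon_removal <- function(trees, candidate_a, candidate_b,
                              removal_sets = list(none = character(0)),
                              out_dir) {
  .ensure_dir(out_dir)
  if (is.character(trees)) trees <- read_locus_trees(trees)
  if (is.character(candidate_a)) candidate_a <- ape::read.tree(candidate_a)
  if (is.character(candidate_b)) candidate_b <- ape::read.tree(candidate_b)
  tab <- taxon_removal_experiment(trees, candidate_a, candidate_b,
                                  removal_sets)
  f_tab <- file.path(out_dir, "taxon_removal.tsv")
  utils::write.table(tab, f_tab, sep = "\t", quote = FALSE, row.names = FALSE)
  .write_manifest(out_dir, "taxon-removal",
                  params = list(removals = removal_sets),
                  outputs = basename(f_tab),
                  counts = list(n_loci = length(trees),
                                n_removal_sets = nrow(tab)))
  invisible(tab)
}
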