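#' Pipeline configuration
#'
#' Bundles the thresholds of a two-marker delimitation run. Defaults are
#' the standard working values for a fast mitochondrial barcode with a
#' slower nuclear companion: haplotypes collapsed below 1%, primary
#' lineages cut at 10%, a sublineage scan at 5%, the slow marker cut at
#' 3%, and 1000 NJ bootstrap replicates.
#'
#' @param collapse_t,delimit_t,sublineage_t,marker2_t Thresholds as
#'   proportions in (0, 1).
#' @param gap_mode Gap handling for K2P ([k2p_matrix()]).
#' @param abgd An [abgd_config()].
#' @param n_boot Bootstrap replicates for the NJ tree.
#' @param inter_mode Aggregator for [lineage_stats()].
#' @param build_network Build the slow-marker median-joining network in
#'   [run_compare()]. Worth disabling for large surveys, where the
#'   informative networks are the within-clade ones built separately on
#'   sister-lineage subsets.
#' @param seed Seed for the bootstrap.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(collapse_t = 0.01, delimit_t = 0.10,
                            sublineage_t = 0.05, marker2_t = 0.03,
                            gap_mode = "pairwise_deletion",
                            abgd = abgd_config(),
                            n_boot = 1000, inter_mode = "min_nearest",
                            build_network = TRUE,
                            seed = 1L) {
  for (t in c(collapse_t, delimit_t, sublineage_t, marker2_t)) {
    stopifnot(t > 0, t < 1)
  }
  structure(list(collapse_t = collapse_t, delimit_t = delimit_t,
                 sublineage_t = sublineage_t, marker2_t = marker2_t,
                 gap_mode = gap_mode, abgd = abgd, n_boot = n_boot,
                 inter_mode = inter_mode, build_network = build_network,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

write_manifest <- function(path, config, extra = list()) {
  flat <- function(x, prefix = "") {
    out <- character(0)
    for (nm in names(x)) {
      v <- x[[nm]]
      key <- if (prefix == "") nm else paste0(prefix, ".", nm)
      if (is.list(v)) out <- c(out, flat(v, key))
      else out <- c(out, paste0(key, "\t", paste(v, collapse = ",")))
    }
    out
  }
  lines <- c(paste0("package\tbarcodegap ",
                    as.character(utils::packageVersion("barcodegap"))),
             paste0("r_version\t", R.version.string),
             flat(unclass(config)), flat(extra))
  writeLines(lines, path)
  invisible(path)
}

#' Run the single-marker delimitation stage
#'
#' Computes the K2P matrix, collapses near-identical haplotypes,
#' partitions at the primary threshold, scans for sublineages, computes
#' lineage statistics (both inter-lineage aggregators), builds the NJ
#' tree with bootstrap support on the collapsed representatives, and
#' writes partition, report and newick outputs plus a run manifest.
#'
#' @param aligned An [aligned_set()].
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @return List with `dm`, `collapse`, `partition`, `sublineages`,
#'   `stats_min`, `stats_mean`, `tree` and the output paths.
#' @export
run_delimit <- function(aligned, config = pipeline_config(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dm <- k2p_matrix(aligned, gap_mode = config$gap_mode)
  coll <- collapse_haplotypes(dm, config$collapse_t)
  part <- threshold_partition(dm, config$delimit_t)
  subs <- sublineage_scan(dm, part, config$sublineage_t)
  stats_min <- lineage_stats(dm, part, "min_nearest")
  stats_mean <- lineage_stats(dm, part, "mean_nearest")
  rep_set <- subset_aligned(aligned, coll$representatives)
  tree <- if (length(coll$representatives) >= 3) {
    bootstrap_support(rep_set, n_reps = config$n_boot, seed = config$seed,
                      gap_mode = config$gap_mode)
  } else NULL
  paths <- c(partition = file.path(out_dir, "partition.tsv"),
             report = file.path(out_dir, "lineage_report.tsv"),
             report_mean = file.path(out_dir, "lineage_report_mean.tsv"),
             sublineages = file.path(out_dir, "sublineages.tsv"),
             tree = file.path(out_dir, "nj_tree.nwk"),
             manifest = file.path(out_dir, "manifest.tsv"))
  write_partition_tsv(part, paths["partition"])
  write_lineage_report(stats_min, paths["report"], aligned$meta, part)
  write_lineage_report(stats_mean, paths["report_mean"], aligned$meta, part)
  utils::write.table(subs, paths["sublineages"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(tree)) {
    write_newick(tree, paths["tree"], member_counts = coll$n_members)
  }
  write_manifest(paths["manifest"], config,
                 list(stage = "delimit", marker = aligned$marker,
                      n_sequences = length(aligned$ids),
                      n_haplotypes = length(coll$representatives),
                      n_lineages = part$n_lineages,
                      n_sublineage_splits = nrow(subs)))
  message("delimit [", aligned$marker, "]: ", length(aligned$ids),
          " sequences -> ", length(coll$representatives),
          " haplotypes (<", 100 * config$collapse_t, "%) -> ",
          part$n_lineages, " lineages at ",
          100 * config$delimit_t, "%; ", nrow(subs),
          " split(s) at ", 100 * config$sublineage_t, "%")
  list(dm = dm, collapse = coll, partition = part, sublineages = subs,
       stats_min = stats_min, stats_mean = stats_mean, tree = tree,
       paths = paths)
}

#' Run the two-marker comparison stage
#'
#' Partitions each marker at its own threshold, compares the partitions
#' over shared specimens, summarises morphological versus genetic
#' diversity from marker 1, and builds the marker-2 haplotype network
#' with per-lineage-pair separations.
#'
#' @param marker1,marker2 [aligned_set()]s for the two markers.
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @return List with `p1`, `p2`, `report` (a `concordance_report`),
#'   `diversity`, `network`, `separation` and output paths.
#' @export
run_compare <- function(marker1, marker2, config = pipeline_config(),
                        out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dm1 <- k2p_matrix(marker1, gap_mode = config$gap_mode)
  dm2 <- k2p_matrix(marker2, gap_mode = config$gap_mode)
  p1 <- threshold_partition(dm1, config$delimit_t)
  p2 <- threshold_partition(dm2, config$marker2_t)
  report <- compare_partitions(p1, p2, marker1$meta, marker2$meta)
  diversity <- diversity_summary(p1, marker1$meta)
  net <- NULL
  sep <- NULL
  paths <- c(discrepancies = file.path(out_dir, "discrepancies.tsv"),
             diversity = file.path(out_dir, "diversity_summary.tsv"),
             nodes = file.path(out_dir, "network_nodes.tsv"),
             edges = file.path(out_dir, "network_edges.tsv"),
             manifest = file.path(out_dir, "manifest.tsv"))
  utils::write.table(report$discrepancies, paths["discrepancies"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_diversity_tsv(diversity, paths["diversity"])
  if (isTRUE(config$build_network)) {
    net <- median_joining(encode_characters(marker2))
    sep <- lineage_separation(net, p2)
    write_network_tsv(net, paths["nodes"], paths["edges"], p2)
  }
  write_manifest(paths["manifest"], config,
                 list(stage = "compare",
                      n_shared_specimens = length(report$shared_specimens),
                      n_discrepancies = report$n_discrepancies,
                      n_lineages_marker1 = p1$n_lineages,
                      n_lineages_marker2 = p2$n_lineages))
  message("compare: ", p1$n_lineages, " marker-1 lineages at ",
          100 * config$delimit_t, "% vs ", p2$n_lineages,
          " marker-2 lineages at ", 100 * config$marker2_t, "%; ",
          report$n_discrepancies, " discrepancy(ies) over ",
          length(report$shared_specimens), " shared specimens")
  list(p1 = p1, p2 = p2, report = report, diversity = diversity,
       network = net, separation = sep, paths = paths)
}

#' Simulate a dataset and write it to disk
#'
#' @param cfg A [sim_config()].
#' @param out_dir Output directory.
#' @return The simulated dataset (see [simulate_dataset()]) with a
#'   `paths` element added.
#' @export
run_simulate <- function(cfg, out_dir) {
  sim <- simulate_dataset(cfg)
  sim$paths <- write_dataset(sim, out_dir)
  write_manifest(file.path(out_dir, "manifest.tsv"),
                 list(seed = cfg$seed, n_lineages = cfg$n_lineages,
                      seq_length = cfg$seq_length),
                 list(stage = "simulate",
                      n_marker1 = length(sim$marker1$ids),
                      n_marker2 = length(sim$marker2$ids)))
  message("simulate: ", cfg$n_lineages, " lineages -> ",
          length(sim$marker1$ids), " marker-1 and ",
          length(sim$marker2$ids), " marker-2 sequences (seed ",
          cfg$seed, ")")
  sim
}
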