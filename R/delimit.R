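components_below <- function(dm, t, ids = dm$ids) {
  # single-linkage components: edge iff defined distance < t (strict)
  m <- dm$d[ids, ids, drop = FALSE]
  adj <- !is.na(m) & m < t
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  split(ids, comp[ids])
}

#' Collapse near-identical haplotypes
#'
#' Sequences that are identical or diverge by less than `collapse_t`
#' (default 1%) are combined into one haplotype for display and tree
#' building; all sequences remain available for distance statistics.
#' Combination is by single-linkage connected components over edges
#' `d < collapse_t`, so chains of sub-threshold pairs collapse together.
#' The representative of each component is its lexicographically smallest
#' sequence id; member counts feed the `"Nind"` display suffix.
#'
#' @param dm A `dist_matrix`.
#' @param collapse_t Collapse threshold as a proportion (default 0.01).
#' @return List with `representatives` (character vector), `member_map`
#'   (named list representative -> member ids) and `n_members` (named
#'   integer vector).
#' @export
collapse_haplotypes <- function(dm, collapse_t = 0.01) {
  comps <- components_below(dm, collapse_t)
  reps <- vapply(comps, function(ids) sort(ids)[1], character(1))
  member_map <- stats::setNames(comps, reps)
  ord <- order(reps)
  reps <- reps[ord]; member_map <- member_map[ord]
  list(representatives = unname(reps),
       member_map = member_map,
       n_members = vapply(member_map, length, integer(1)))
}

#' Partition sequences into lineages at a distance threshold
#'
#' Lineages are the connected components of the graph with an edge between
#' two sequences iff their defined distance is strictly below `t`
#' (single linkage). By construction the minimum distance between any two
#' lineages is at least `t`, i.e. lineages are "separated by more than
#' `t`" up to ties at exactly `t`, which count as separated. Undefined
#' (saturated) pairs contribute no edge. Labels are deterministic
#' ordinals (`L1`, `L2`, ...) assigned by first appearance when member ids
#' are sorted.
#'
#' @param dm A `dist_matrix`.
#' @param t Threshold as a proportion in (0, 1).
#' @return An object of class `lineage_partition`: list with `assignment`
#'   (named character vector seq_id -> label), `threshold`, `n_lineages`,
#'   `representative` (named: label -> lowest member id) and `members`
#'   (named list label -> ids).
#' @export
threshold_partition <- function(dm, t) {
  stopifnot(t > 0, t < 1)
  comps <- components_below(dm, t)
  # canonical order: by smallest member id
  first <- vapply(comps, function(ids) sort(ids)[1], character(1))
  comps <- comps[order(first)]
  labels <- paste0("L", seq_along(comps))
  assignment <- character(0)
  for (k in seq_along(comps)) {
    assignment[comps[[k]]] <- labels[k]
  }
  assignment <- assignment[sort(dm$ids)]
  structure(list(assignment = assignment,
                 threshold = t,
                 n_lineages = length(comps),
                 representative = stats::setNames(sort(first), labels),
                 members = stats::setNames(lapply(comps, sort), labels)),
            class = "lineage_partition")
}

#' @export
print.lineage_partition <- function(x, ...) {
  cat("lineage_partition:", x$n_lineages, "lineages at threshold",
      x$threshold, "over", length(x$assignment), "sequences\n")
  invisible(x)
}

#' Build a lineage_partition from an assignment vector
#' @param assignment Named character vector seq_id -> label.
#' @param threshold Threshold recorded on the object (default NA).
#' @return A `lineage_partition`.
#' @export
as_lineage_partition <- function(assignment, threshold = NA_real_) {
  stopifnot(!is.null(names(assignment)))
  members <- split(names(assignment), assignment)
  members <- lapply(members, sort)
  members <- members[order(vapply(members, `[`, character(1), 1L))]
  structure(list(assignment = assignment[sort(names(assignment))],
                 threshold = threshold,
                 n_lineages = length(members),
                 representative = vapply(members, `[`, character(1), 1L),
                 members = members),
            class = "lineage_partition")
}

#' Scan lineages for sublineage structure at a lower threshold
#'
#' Re-partitions each lineage's members at `t2 < t` and reports the
#' lineages that split, together with the maximum distance observed
#' between the resulting sublineages — the divergence a lower threshold
#' would expose (e.g. cryptic sublineages at 6–10% hidden by a 10% cut).
#'
#' @param dm A `dist_matrix`.
#' @param partition A `lineage_partition` over `dm`'s ids.
#' @param t2 Secondary threshold, strictly below `partition$threshold`.
#' @return `data.frame` with columns `lineage`, `n_sublineages`,
#'   `max_between_divergence` — one row per splitting lineage (zero rows
#'   when nothing splits).
#' @export
sublineage_scan <- function(dm, partition, t2) {
  stopifnot(inherits(partition, "lineage_partition"))
  if (!is.na(partition$threshold) && t2 >= partition$threshold) {
    stop("t2 must be below the partition threshold")
  }
  out <- data.frame(lineage = character(0), n_sublineages = integer(0),
                    max_between_divergence = numeric(0),
                    stringsAsFactors = FALSE)
  for (lab in names(partition$members)) {
    ids <- partition$members[[lab]]
    if (length(ids) < 2) next
    subs <- components_below(dm, t2, ids)
    if (length(subs) < 2) next
    maxd <- 0
    for (i in seq_len(length(subs) - 1)) {
      for (j in (i + 1):length(subs)) {
        cross <- dm$d[subs[[i]], subs[[j]], drop = FALSE]
        if (any(!is.na(cross))) maxd <- max(maxd, cross, na.rm = TRUE)
      }
    }
    out <- rbind(out, data.frame(lineage = lab,
                                 n_sublineages = length(subs),
                                 max_between_divergence = maxd,
                                 stringsAsFactors = FALSE))
  }
  out
}

#' Per-lineage intra- and inter-lineage distance statistics
#'
#' For each lineage, the range of within-lineage pairwise distances
#' (`NA`/"NC" for singletons — never reported as 0), the number of
#' members, and the distance to the nearest other lineage. The nearest
#' lineage is the one minimising the chosen aggregator: `"min_nearest"`
#' uses the minimum cross-lineage pair distance, `"mean_nearest"` the mean
#' of all cross pairs to that nearest lineage. Published tables of this
#' kind do not always state their aggregator, so reports can emit both.
#'
#' @param dm A `dist_matrix`.
#' @param partition A `lineage_partition`.
#' @param inter_mode `"min_nearest"` (default) or `"mean_nearest"`.
#' @return `data.frame` with columns `lineage`, `n_members`, `intra_min`,
#'   `intra_max`, `inter_nearest`, `nearest_lineage`.
#' @export
lineage_stats <- function(dm, partition,
                          inter_mode = c("min_nearest", "mean_nearest")) {
  inter_mode <- match.arg(inter_mode)
  labs <- names(partition$members)
  n <- length(labs)
  res <- data.frame(lineage = labs,
                    n_members = vapply(partition$members, length, integer(1)),
                    intra_min = NA_real_, intra_max = NA_real_,
                    inter_nearest = NA_real_,
                    nearest_lineage = NA_character_,
                    stringsAsFactors = FALSE, row.names = NULL)
  agg <- function(cross) {
    vals <- cross[!is.na(cross)]
    if (length(vals) == 0) return(NA_real_)
    if (inter_mode == "min_nearest") min(vals) else mean(vals)
  }
  for (i in seq_len(n)) {
    ids <- partition$members[[i]]
    if (length(ids) >= 2) {
      within <- dm$d[ids, ids][upper.tri(matrix(0, length(ids), length(ids)))]
      within <- within[!is.na(within)]
      if (length(within) > 0) {
        res$intra_min[i] <- min(within)
        res$intra_max[i] <- max(within)
      }
    }
    if (n >= 2) {
      best <- NA_real_; best_lab <- NA_character_
      for (j in seq_len(n)) {
        if (j == i) next
        a <- agg(dm$d[ids, partition$members[[j]], drop = FALSE])
        if (!is.na(a) && (is.na(best) || a < best)) {
          best <- a; best_lab <- labs[j]
        }
      }
      res$inter_nearest[i] <- best
      res$nearest_lineage[i] <- best_lab
    }
  }
  res
}

#' Write a lineage report table
#'
#' A per-lineage summary in the style of barcoding survey tables:
#' lineage, member count, morphotaxon consensus, intra-lineage range and
#' nearest-lineage divergence, rendered as percentages with the `"NC"`
#' (not calculated) sentinel for singleton lineages.
#'
#' @param stats Output of [lineage_stats()].
#' @param path Output TSV path.
#' @param meta Optional metadata `data.frame` to derive a morphotaxon
#'   consensus per lineage (most frequent non-missing label).
#' @param partition The `lineage_partition` matching `stats` (required
#'   when `meta` is given).
#' @return The formatted `data.frame`, invisibly; written to `path`.
#' @export
write_lineage_report <- function(stats, path, meta = NULL, partition = NULL) {
  pct <- function(x) ifelse(is.na(x), "NC", sprintf("%.3f", 100 * x))
  out <- data.frame(lineage = stats$lineage,
                    n_members = stats$n_members,
                    morphotaxon = NA_character_,
                    intra_min_pct = pct(stats$intra_min),
                    intra_max_pct = pct(stats$intra_max),
                    inter_nearest_pct = pct(stats$inter_nearest),
                    nearest_lineage = stats$nearest_lineage,
                    stringsAsFactors = FALSE)
  if (!is.null(meta) && !is.null(partition)) {
    for (i in seq_len(nrow(out))) {
      ids <- partition$members[[out$lineage[i]]]
      labs <- meta$morphotaxon[match(ids, meta$seq_id)]
      labs <- labs[!is.na(labs) & labs != ""]
      if (length(labs) > 0) {
        out$morphotaxon[i] <- names(sort(table(labs), decreasing = TRUE))[1]
      }
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(out)
}

#' Write a partition assignment table
#' @param partition A `lineage_partition`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_partition_tsv <- function(partition, path) {
  df <- data.frame(seq_id = names(partition$assignment),
                   lineage = unname(partition$assignment),
                   representative = names(partition$assignment) %in%
                     partition$representative,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
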