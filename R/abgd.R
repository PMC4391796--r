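#' Configuration for automatic barcode gap partitioning
#'
#' Defaults follow the method's canonical web defaults: priors log-spaced
#' from 0.001 to 0.1 over 10 steps; the relative gap width `X` defaults to
#' 1.0. `n_bins` only controls the diagnostic histogram export.
#'
#' @param p_min,p_max Prior maximum intraspecific divergence range
#'   (proportions, `0 < p_min < p_max < 1`).
#' @param n_steps Number of log-spaced priors.
#' @param rel_gap_width Relative gap width `X`: a rank gap is significant
#'   when its width exceeds `X` times the local slope of the ranked
#'   distances.
#' @param n_bins Bins for the ranked-distance diagnostic histogram.
#' @return A list of class `abgd_config`.
#' @export
abgd_config <- function(p_min = 0.001, p_max = 0.1, n_steps = 10,
                        rel_gap_width = 1.0, n_bins = 20) {
  stopifnot(p_min > 0, p_min < p_max, p_max < 1, n_steps >= 1,
            rel_gap_width > 0, n_bins >= 1)
  structure(list(p_min = p_min, p_max = p_max, n_steps = n_steps,
                 rel_gap_width = rel_gap_width, n_bins = n_bins),
            class = "abgd_config")
}

#' Locate the barcode gap in a ranked distance list
#'
#' Scans the ascending pairwise distances for intervals `(d[i], d[i+1])`
#' that (a) reach beyond the prior maximum intraspecific divergence
#' (`d[i+1] > prior_p`, so the gap cannot fall wholly inside the prior
#' intraspecific range — intervals spanning the prior are eligible) and
#' (b) are significantly wider than the local spacing of the preceding
#' ranks: width greater than `X` times the local slope, estimated as the
#' mean rank-to-rank spacing over a sliding window of `max(10, 5%)` of
#' the pairs ending at rank `i`, floored at the prior itself (under a
#' prior maximum intraspecific divergence `P`, rank jumps smaller than
#' `P` are within the spacing scale the prior tolerates, so a significant
#' gap must exceed `X * P` as well). A zero local slope (tied ranks)
#' falls back to the global mean spacing. Among the significant
#' intervals, the most prominent one — the largest width-to-slope ratio,
#' earliest rank on ties — is the barcode gap; finer significant gaps
#' below it are left to the recursive within-group passes. Fewer than two
#' distinct distances yield no gap.
#'
#' @param sorted_d Ascending numeric vector of pairwise distances.
#' @param prior_p Prior maximum intraspecific divergence (proportion).
#' @param X Relative gap width.
#' @return `NULL` when no significant gap exists, else a list with
#'   `low`, `high` (the flanking distances) and `width`.
#' @export
find_gap <- function(sorted_d, prior_p, X = 1.0) {
  sorted_d <- sorted_d[!is.na(sorted_d)]
  n <- length(sorted_d)
  if (n < 2 || length(unique(sorted_d)) < 2) return(NULL)
  if (is.unsorted(sorted_d)) sorted_d <- sort(sorted_d)
  global_slope <- (sorted_d[n] - sorted_d[1]) / (n - 1)
  w <- max(10L, ceiling(0.05 * n))
  best <- NULL
  best_prom <- -Inf
  for (i in seq_len(n - 1)) {
    if (sorted_d[i + 1] <= prior_p) next
    width <- sorted_d[i + 1] - sorted_d[i]
    if (width <= 0) next
    lo <- max(1L, i - w + 1L)
    slope <- if (i - lo >= 1) (sorted_d[i] - sorted_d[lo]) / (i - lo)
             else 0
    if (slope <= 0) slope <- global_slope
    slope <- max(slope, prior_p)
    if (slope <= 0) next
    prom <- width / slope
    if (prom > X && prom > best_prom) {
      best_prom <- prom
      best <- list(low = sorted_d[i], high = sorted_d[i + 1],
                   width = width)
    }
  }
  best
}

abgd_split <- function(dm, ids, prior_p, X, recursive, depth = 0L) {
  # returns a list of id groups for the given subset
  if (length(ids) <= 2) return(list(ids))
  m <- dm$d[ids, ids]
  vals <- m[upper.tri(m)]
  gap <- find_gap(sort(vals[!is.na(vals)]), prior_p, X)
  if (is.null(gap)) return(list(ids))
  groups <- components_below(dm, gap$low + .Machine$double.eps^0.5, ids)
  # edges d <= gap low connect; strictly-below helper gets a nudged bound
  if (length(groups) <= 1) return(list(ids))
  # a refinement inside an established group needs support on both sides
  # of the gap: a lone divergent sequence is not gap evidence (singleton
  # groups are the initial global pass's business)
  if (depth > 0L && sum(vapply(groups, length, integer(1)) >= 2) < 2) {
    return(list(ids))
  }
  if (!recursive || depth >= 20L) return(groups)
  out <- list()
  for (g in groups) out <- c(out, abgd_split(dm, g, prior_p, X,
                                             recursive, depth + 1L))
  out
}

groups_to_partition <- function(groups, threshold = NA_real_) {
  assignment <- character(0)
  for (g in groups) assignment[g] <- sort(g)[1]
  first <- sort(unique(assignment))
  labs <- stats::setNames(paste0("G", seq_along(first)), first)
  assignment[] <- labs[assignment]
  as_lineage_partition(assignment, threshold)
}

#' Automatic barcode gap partitioning over a prior grid
#'
#' For each prior maximum intraspecific divergence on a log-spaced grid,
#' detects the barcode gap in the ranked pairwise distances
#' ([find_gap()]), partitions the sequences into the connected components
#' of the graph with edges `d <= gap low`, and recursively re-applies gap
#' detection within each component until no significant gap remains.
#' The single reported partition is the recursive partition at the modal
#' group count across the prior grid (earliest prior on ties) — the
#' partition stable over the widest prior range.
#'
#' @param dm A `dist_matrix` over at least 3 sequences.
#' @param cfg An [abgd_config()].
#' @return An object of class `gap_partition_result`: list with
#'   `priors`, `per_prior` (one element per prior: `prior`, `gap`,
#'   `initial` and `recursive` partitions), `chosen` (a
#'   `lineage_partition`) and `chosen_prior`.
#' @export
abgd_partition <- function(dm, cfg = abgd_config()) {
  stopifnot(inherits(dm, "dist_matrix"), inherits(cfg, "abgd_config"))
  n <- length(dm$ids)
  if (n < 3) {
    warning("fewer than 3 sequences: returning the trivial partition")
    triv <- groups_to_partition(list(dm$ids))
    return(structure(list(priors = numeric(0), per_prior = list(),
                          chosen = triv, chosen_prior = NA_real_),
                     class = "gap_partition_result"))
  }
  priors <- exp(seq(log(cfg$p_min), log(cfg$p_max),
                    length.out = cfg$n_steps))
  vals <- dm$d[upper.tri(dm$d)]
  sorted_d <- sort(vals[!is.na(vals)])
  per_prior <- vector("list", length(priors))
  for (k in seq_along(priors)) {
    p <- priors[k]
    gap <- find_gap(sorted_d, p, cfg$rel_gap_width)
    initial <- if (is.null(gap)) list(dm$ids) else
      abgd_split(dm, dm$ids, p, cfg$rel_gap_width, recursive = FALSE)
    recursive <- if (is.null(gap)) list(dm$ids) else
      abgd_split(dm, dm$ids, p, cfg$rel_gap_width, recursive = TRUE)
    per_prior[[k]] <- list(prior = p, gap = gap,
                           initial = groups_to_partition(initial),
                           recursive = groups_to_partition(recursive))
  }
  counts <- vapply(per_prior, function(x) x$recursive$n_lineages, integer(1))
  tab <- table(counts)
  cand <- as.integer(names(tab)[tab == max(tab)])
  # ties between equally frequent counts go to the one persisting at the
  # largest prior — the stable tail of the group-count staircase
  last_at <- vapply(cand, function(cc) max(which(counts == cc)), integer(1))
  modal <- cand[which.max(last_at)]
  pick <- which(counts == modal)[1]
  structure(list(priors = priors, per_prior = per_prior,
                 chosen = per_prior[[pick]]$recursive,
                 chosen_prior = priors[pick]),
            class = "gap_partition_result")
}

#' @export
print.gap_partition_result <- function(x, ...) {
  cat("gap_partition_result:", x$chosen$n_lineages,
      "groups (chosen at prior", format(x$chosen_prior, digits = 3), ")\n")
  if (length(x$priors)) {
    counts <- vapply(x$per_prior, function(p) p$recursive$n_lineages,
                     integer(1))
    cat("  groups per prior:", paste(counts, collapse = " "), "\n")
  }
  invisible(x)
}

#' Ranked-distance histogram data for gap diagnostics
#'
#' @param dm A `dist_matrix`.
#' @param n_bins Number of equal-width bins over the observed range.
#' @return `data.frame` with `bin_low`, `bin_high`, `count` — the
#'   histogram of all defined pairwise distances, in which a barcode gap
#'   appears as a run of empty bins.
#' @export
distance_histogram <- function(dm, n_bins = 20) {
  vals <- dm$d[upper.tri(dm$d)]
  vals <- vals[!is.na(vals)]
  breaks <- seq(0, max(vals) * (1 + 1e-9), length.out = n_bins + 1)
  bin <- findInterval(vals, breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  data.frame(bin_low = breaks[-length(breaks)],
             bin_high = breaks[-1],
             count = tabulate(bin, nbins = n_bins))
}
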