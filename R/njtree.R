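#' Neighbor-joining tree from a distance matrix
#'
#' Saitou–Nei agglomeration on the pairwise distances (via the standard
#' `ape` implementation), with the input canonicalised to sorted id order
#' so ties resolve reproducibly. Undefined pairs are a hard error: collapse
#' or drop saturated sequences before tree building. Negative branch
#' lengths — an artefact of non-additive noise — are clamped to zero and
#' the clamped deficit recorded in `attr(tree, "clamped")`, so additivity
#' tests can assert zero clamps.
#'
#' @param dm A `dist_matrix` with at least 3 ids and no undefined pairs.
#' @return An unrooted `ape::phylo` tree.
#' @export
nj_tree <- function(dm) {
  stopifnot(inherits(dm, "dist_matrix"))
  if (length(dm$ids) < 3) stop("need at least 3 sequences for NJ")
  if (nrow(dm$undefined_pairs) > 0) {
    stop("undefined distance between '", dm$undefined_pairs[1, 1],
         "' and '", dm$undefined_pairs[1, 2],
         "': collapse or remove saturated pairs before NJ")
  }
  ord <- sort(dm$ids)
  tree <- ape::nj(stats::as.dist(dm$d[ord, ord]))
  neg <- tree$edge.length < 0
  attr(tree, "clamped") <- sum(-tree$edge.length[neg])
  tree$edge.length[neg] <- 0
  tree
}

#' Nonparametric bootstrap support for an NJ tree
#'
#' Resamples alignment columns with replacement, recomputes the K2P
#' distance matrix and NJ tree per replicate, and scores each internal
#' bipartition of the original tree by the percentage of replicates
#' containing it. Replicates whose resampled matrix has undefined pairs
#' cannot be built into a tree; they are skipped and counted
#' (`attr(tree, "skipped")`), and support is expressed over the replicates
#' actually used. A single seed drives one RNG stream with a fixed
#' replicate order, so results are bit-identical across runs.
#'
#' @param aligned An [aligned_set()].
#' @param n_reps Bootstrap replicates (default 1000); 0 returns the plain
#'   tree without support values.
#' @param seed Mandatory integer seed.
#' @param gap_mode Passed to [k2p_matrix()].
#' @return The NJ tree on the original alignment with `node.label`
#'   containing support percentages (root/trivial label empty).
#' @export
bootstrap_support <- function(aligned, n_reps = 1000, seed,
                              gap_mode = "pairwise_deletion") {
  stopifnot(inherits(aligned, "aligned_set"))
  if (missing(seed)) stop("a seed is mandatory for bootstrap resampling")
  dm <- k2p_matrix(aligned, gap_mode = gap_mode)
  tree <- nj_tree(dm)
  if (n_reps == 0) return(tree)
  L <- aligned$length
  boot_trees <- vector("list", n_reps)
  skipped <- 0L
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  for (r in seq_len(n_reps)) {
    cols <- sample.int(L, L, replace = TRUE)
    rep_set <- aligned
    rep_set$mat <- aligned$mat[, cols, drop = FALSE]
    rep_dm <- tryCatch(k2p_matrix(rep_set, gap_mode = gap_mode),
                       error = function(e) NULL)
    if (is.null(rep_dm) || nrow(rep_dm$undefined_pairs) > 0) {
      skipped <- skipped + 1L
      next
    }
    boot_trees[[r]] <- nj_tree(rep_dm)
  }
  boot_trees <- boot_trees[!vapply(boot_trees, is.null, logical(1))]
  n_used <- length(boot_trees)
  if (n_used == 0) stop("all bootstrap replicates had undefined distances")
  class(boot_trees) <- "multiPhylo"
  counts <- ape::prop.clades(tree, boot_trees, rooted = FALSE)
  counts[is.na(counts)] <- 0
  support <- round(100 * counts / n_used, 1)
  tree$node.label <- as.character(support)
  tree$node.label[1] <- ""  # root pseudo-node of an unrooted tree
  attr(tree, "skipped") <- skipped
  attr(tree, "n_reps_used") <- n_used
  tree
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Write a tree to newick with display conventions
#'
#' Bootstrap support is printed as an internal node label only when it
#' reaches `support_floor` (default 80%, the usual display cut-off);
#' lower values are blanked. When `member_counts` is given (from
#' [collapse_haplotypes()]), leaves representing more than one collapsed
#' sequence get the count suffixed as e.g. `"x_6ind"`.
#'
#' @param tree An `ape::phylo`, typically from [bootstrap_support()].
#' @param path Output path.
#' @param support_floor Minimum support (percent) to display.
#' @param member_counts Optional named integer vector (leaf id -> number
#'   of collapsed members).
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path, support_floor = 80,
                         member_counts = NULL) {
  out <- tree
  if (!is.null(out$node.label)) {
    vals <- suppressWarnings(as.numeric(out$node.label))
    out$node.label <- ifelse(!is.na(vals) & vals >= support_floor,
                             out$node.label, "")
  }
  if (!is.null(member_counts)) {
    hit <- match(out$tip.label, names(member_counts))
    multi <- !is.na(hit) & member_counts[hit] > 1
    out$tip.label[multi] <- paste0(out$tip.label[multi], "_",
                                   member_counts[hit[multi]], "ind")
  }
  ape::write.tree(out, file = path)
  invisible(path)
}
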