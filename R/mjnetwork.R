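#' Recode an alignment into equal-weight network characters
#'
#' Produces the character matrix used for haplotype networks, in which
#' every change — a substitution, a multi-base indel block, or an
#' annotated structural mutation such as an inversion — counts as exactly
#' one step (simple indel coding):
#' * each distinct maximal gap run observed in any sequence becomes one
#'   presence/absence character (a 5-bp deletion is one step, not five);
#'   sequences whose gap pattern partially overlaps a run (e.g. a longer
#'   deletion containing it) get the inapplicable state `NA`;
#' * annotated structural intervals each become one multistate character
#'   (distinct interval contents = distinct states) and their columns are
#'   excluded from substitution coding, as are columns inside multi-base
#'   gap runs;
#' * every remaining column with two or more unambiguous states becomes
#'   one multistate substitution character (non-ACGT symbols = `NA`).
#'
#' @param aligned An [aligned_set()].
#' @param structural_annotations Optional list of `c(start, end)` column
#'   intervals (1-based, inclusive) marking known structural mutations;
#'   overlapping intervals are an error.
#' @return An object of class `character_matrix`: list with `ids`,
#'   `kind` (per character: `"substitution_site"`, `"indel_block"` or
#'   `"structural"`), `def` (column index or interval per character) and
#'   `states` (integer matrix, rows = ids).
#' @export
encode_characters <- function(aligned, structural_annotations = NULL) {
  stopifnot(inherits(aligned, "aligned_set"))
  mat <- aligned$mat
  n <- nrow(mat); L <- ncol(mat)
  ids <- aligned$ids

  if (!is.null(structural_annotations)) {
    iv <- do.call(rbind, lapply(structural_annotations, function(x) {
      stopifnot(length(x) == 2, x[1] >= 1, x[2] <= L, x[1] <= x[2])
      as.integer(x)
    }))
    iv <- iv[order(iv[, 1]), , drop = FALSE]
    if (nrow(iv) > 1 && any(iv[-1, 1] <= iv[-nrow(iv), 2])) {
      stop("overlapping structural annotations")
    }
  } else iv <- matrix(integer(0), ncol = 2)

  # maximal '-' runs per sequence, pooled into the distinct run set
  runs <- list()
  per_seq_runs <- vector("list", n)
  for (i in seq_len(n)) {
    r <- rle(mat[i, ] == "-")
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    gr <- cbind(starts[r$values], ends[r$values])
    per_seq_runs[[i]] <- gr
    if (nrow(gr)) for (k in seq_len(nrow(gr))) {
      runs[[paste(gr[k, 1], gr[k, 2])]] <- gr[k, ]
    }
  }
  runs <- runs[order(vapply(runs, `[`, integer(1), 1L),
                     vapply(runs, `[`, integer(1), 2L))]

  kind <- character(0); def <- list(); states <- NULL
  add_char <- function(k, d, s) {
    kind <<- c(kind, k); def[[length(def) + 1L]] <<- d
    states <<- cbind(states, s)
  }

  gap_at <- function(i, s, e) {
    gr <- per_seq_runs[[i]]
    if (nrow(gr) == 0) return(0L)            # no gaps at all
    exact <- any(gr[, 1] == s & gr[, 2] == e)
    if (exact) return(1L)
    overlap <- any(gr[, 1] <= e & gr[, 2] >= s)
    if (overlap) return(NA_integer_)          # different gap pattern here
    0L
  }
  for (rn in runs) {
    st <- vapply(seq_len(n), gap_at, integer(1), s = rn[1], e = rn[2])
    add_char("indel_block", rn, st)
  }

  excluded <- rep(FALSE, L)
  for (rn in runs) if (rn[2] > rn[1]) excluded[rn[1]:rn[2]] <- TRUE
  if (nrow(iv)) {
    for (k in seq_len(nrow(iv))) {
      cols <- iv[k, 1]:iv[k, 2]
      excluded[cols] <- TRUE
      frag <- apply(mat[, cols, drop = FALSE], 1, paste, collapse = "")
      add_char("structural", iv[k, ], as.integer(factor(frag)))
    }
  }

  acgt <- c("A", "C", "G", "T")
  for (col in which(!excluded)) {
    v <- mat[, col]
    st <- match(v, acgt)
    if (length(unique(st[!is.na(st)])) >= 2) {
      add_char("substitution_site", col, st)
    }
  }

  if (is.null(states)) states <- matrix(integer(0), nrow = n, ncol = 0)
  rownames(states) <- ids
  colnames(states) <- NULL
  structure(list(ids = ids, kind = kind, def = def, states = states),
            class = "character_matrix")
}

#' @export
print.character_matrix <- function(x, ...) {
  cat("character_matrix:", length(x$ids), "ids x", length(x$kind),
      "characters (", sum(x$kind == "substitution_site"), "subst,",
      sum(x$kind == "indel_block"), "indel,",
      sum(x$kind == "structural"), "structural )\n")
  invisible(x)
}

#' Write a character matrix as TSV
#' @param cm A [encode_characters()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_character_tsv <- function(cm, path) {
  defs <- vapply(cm$def, function(d) paste(d, collapse = "-"), character(1))
  df <- data.frame(seq_id = cm$ids, cm$states, check.names = FALSE)
  names(df)[-1] <- paste0(cm$kind, "_", defs)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "?")
  invisible(path)
}

hamming_rows <- function(M) {
  k <- nrow(M)
  D <- matrix(0L, k, k)
  if (k >= 2) for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    D[i, j] <- D[j, i] <- sum(M[i, ] != M[j, ])
  }
  D
}

mst_cost <- function(D) {
  k <- nrow(D)
  if (k < 2) return(0)
  g <- igraph::graph_from_adjacency_matrix(D, mode = "undirected",
                                           weighted = TRUE)
  sum(igraph::E(igraph::mst(g))$weight)
}

minimax_dists <- function(D) {
  # max edge weight on the MST path between every pair
  k <- nrow(D)
  g <- igraph::graph_from_adjacency_matrix(D, mode = "undirected",
                                           weighted = TRUE)
  mt <- igraph::mst(g)
  A <- igraph::as_adjacency_matrix(mt, attr = "weight", sparse = FALSE)
  mm <- matrix(Inf, k, k); diag(mm) <- 0
  for (s in seq_len(k)) {
    # DFS from s over the tree, carrying the running max edge
    stack <- list(c(s, 0)); seen <- rep(FALSE, k); seen[s] <- TRUE
    while (length(stack)) {
      cur <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      v <- cur[1]; mx <- cur[2]
      mm[s, v] <- mx
      for (u in which(A[v, ] > 0)) if (!seen[u]) {
        seen[u] <- TRUE
        stack[[length(stack) + 1L]] <- c(u, max(mx, A[v, u]))
      }
    }
  }
  mm
}

msn_edges <- function(D, epsilon = 0) {
  # union of all minimum spanning trees (within tolerance epsilon):
  # edge kept iff its weight <= minimax path weight + epsilon
  mm <- minimax_dists(D)
  keep <- D <= mm + epsilon
  keep[lower.tri(keep, diag = TRUE)] <- FALSE
  which(keep, arr.ind = TRUE)
}

majority_median <- function(M) {
  # per-character majority state of three rows; ties fall to the first row
  vapply(seq_len(ncol(M)), function(c) {
    v <- M[, c]
    tb <- sort(table(v), decreasing = TRUE)
    if (length(tb) == 3L) v[1] else as.integer(names(tb)[1])
  }, integer(1))
}

#' Median-joining haplotype network
#'
#' Builds the median-joining network of the distinct haplotypes in a
#' [encode_characters()] matrix: starting from the union of all minimum
#' spanning trees (at tolerance `epsilon`), median (consensus) vectors of
#' connected triplets are added whenever they reduce the total cost of
#' connecting the node set, and median vectors that no longer help are
#' pruned. Every character change weighs one step, so indel blocks and
#' substitutions contribute equally. With `epsilon = 0` and a fixed input
#' ordering the result is deterministic. Inapplicable states (`NA`) are
#' treated as one extra state per character for network purposes.
#'
#' @param cm A [character_matrix()].
#' @param epsilon Non-negative integer tolerance widening the candidate
#'   edge set (0 = strict minimum spanning network, the usual default).
#' @return An object of class `haplo_network`: list with `nodes`
#'   (`data.frame`: `name`, `is_median`, `multiplicity`), `members`
#'   (named list node -> seq ids; empty for medians), `states` (matrix of
#'   node state vectors), `edges` (`data.frame`: `from`, `to`, `steps`),
#'   `seq_node` (named vector seq_id -> node) and `epsilon`.
#' @export
median_joining <- function(cm, epsilon = 0) {
  stopifnot(inherits(cm, "character_matrix"), epsilon >= 0)
  S <- cm$states
  S[is.na(S)] <- -1L
  key <- apply(S, 1, paste, collapse = ",")
  uk <- unique(key)
  H <- S[match(uk, key), , drop = FALSE]
  members <- lapply(uk, function(k) cm$ids[key == k])
  k_obs <- length(uk)
  node_names <- paste0("H", seq_len(k_obs))
  rownames(H) <- node_names
  if (k_obs == 1) {
    warning("single haplotype: returning a one-node network")
    net <- structure(list(
      nodes = data.frame(name = node_names, is_median = FALSE,
                         multiplicity = length(members[[1]]),
                         stringsAsFactors = FALSE),
      members = stats::setNames(members, node_names),
      states = H,
      edges = data.frame(from = character(0), to = character(0),
                         steps = integer(0), stringsAsFactors = FALSE),
      seq_node = stats::setNames(rep(node_names, length(cm$ids)), cm$ids),
      epsilon = epsilon), class = "haplo_network")
    return(net)
  }

  is_median <- rep(FALSE, k_obs)
  n_mv <- 0L
  repeat {
    D <- hamming_rows(H)
    cost_now <- mst_cost(D)
    ed <- msn_edges(D, epsilon)
    if (nrow(ed) == 0) break
    adj <- matrix(FALSE, nrow(H), nrow(H))
    adj[ed] <- TRUE; adj <- adj | t(adj)
    # candidate triplets: share at least two network edges
    cand <- list()
    for (u in seq_len(nrow(H))) {
      nb <- which(adj[u, ])
      if (length(nb) >= 2) {
        pr <- utils::combn(nb, 2)
        for (c_ in seq_len(ncol(pr))) {
          tri <- sort(c(u, pr[1, c_], pr[2, c_]))
          cand[[paste(tri, collapse = "-")]] <- tri
        }
      }
    }
    if (length(cand) == 0) break
    cd <- vapply(cand, function(tr)
      D[tr[1], tr[2]] + D[tr[1], tr[3]] + D[tr[2], tr[3]], numeric(1))
    cand <- cand[order(cd, names(cand))]
    accepted <- FALSE
    for (tr in cand) {
      m <- majority_median(H[tr, , drop = FALSE])
      if (any(apply(H, 1, function(r) all(r == m)))) next
      H2 <- rbind(H, m)
      if (mst_cost(hamming_rows(H2)) < cost_now) {
        n_mv <- n_mv + 1L
        rownames(H2)[nrow(H2)] <- paste0("mv", n_mv)
        H <- H2
        is_median <- c(is_median, TRUE)
        accepted <- TRUE
        break
      }
    }
    if (!accepted) break
  }

  # prune obsolete medians: removal must not raise the connection cost
  repeat {
    removed <- FALSE
    cost_now <- mst_cost(hamming_rows(H))
    for (i in which(is_median)) {
      H2 <- H[-i, , drop = FALSE]
      if (mst_cost(hamming_rows(H2)) <= cost_now) {
        H <- H2; is_median <- is_median[-i]
        removed <- TRUE
        break
      }
    }
    if (!removed) break
  }

  D <- hamming_rows(H)
  ed <- msn_edges(D, epsilon)
  nm <- rownames(H)
  edges <- data.frame(from = nm[ed[, 1]], to = nm[ed[, 2]],
                      steps = D[ed], stringsAsFactors = FALSE)
  mult <- integer(nrow(H))
  mult[seq_len(k_obs)[!is_median[seq_len(k_obs)]]] <-
    vapply(members, length, integer(1))
  seq_node <- stats::setNames(node_names[match(key, uk)], cm$ids)
  structure(list(
    nodes = data.frame(name = nm, is_median = is_median,
                       multiplicity = mult, stringsAsFactors = FALSE),
    members = stats::setNames(members, node_names),
    states = H,
    edges = edges,
    seq_node = seq_node,
    epsilon = epsilon), class = "haplo_network")
}

#' @export
print.haplo_network <- function(x, ...) {
  cat("haplo_network:", sum(!x$nodes$is_median), "haplotypes +",
      sum(x$nodes$is_median), "median vector(s),", nrow(x$edges),
      "edges, total weight", sum(x$edges$steps), "\n")
  invisible(x)
}

network_graph <- function(net) {
  igraph::graph_from_data_frame(
    data.frame(from = net$edges$from, to = net$edges$to,
               weight = net$edges$steps),
    directed = FALSE,
    vertices = net$nodes$name)
}

#' Minimum mutational separation between lineages on a network
#'
#' For every pair of lineages, the minimum number of mutational steps
#' along network geodesics between any node of one lineage and any node of
#' the other — the "how many mutations separate these lineages" readout of
#' a haplotype network. Sequences map to haplotype nodes via the network's
#' `seq_node` table.
#'
#' @param net A [median_joining()] network.
#' @param partition A `lineage_partition` (or named seq_id -> lineage
#'   vector) covering the encoded sequences.
#' @return Symmetric numeric matrix of minimum step counts (0 diagonal).
#' @export
lineage_separation <- function(net, partition) {
  assignment <- if (inherits(partition, "lineage_partition"))
    partition$assignment else partition
  ids <- intersect(names(assignment), names(net$seq_node))
  if (length(ids) == 0) stop("no partition ids present in the network")
  g <- network_graph(net)
  sp <- igraph::distances(g, weights = igraph::E(g)$weight)
  labs <- sort(unique(assignment[ids]))
  out <- matrix(0, length(labs), length(labs), dimnames = list(labs, labs))
  node_sets <- lapply(labs, function(l)
    unique(net$seq_node[ids[assignment[ids] == l]]))
  for (i in seq_along(labs)) for (j in seq_along(labs)) {
    if (i < j) {
      v <- min(sp[node_sets[[i]], node_sets[[j]]])
      out[i, j] <- out[j, i] <- v
    }
  }
  out
}

#' Export network node and edge tables
#' @param net A [median_joining()] network.
#' @param node_path,edge_path Output TSV paths.
#' @param partition Optional `lineage_partition` to attach lineage labels
#'   to observed nodes.
#' @return Invisibly, a list with the two data frames.
#' @export
write_network_tsv <- function(net, node_path, edge_path, partition = NULL) {
  nodes <- net$nodes
  nodes$lineage <- NA_character_
  if (!is.null(partition)) {
    for (nm in names(net$members)) {
      ids <- intersect(net$members[[nm]], names(partition$assignment))
      if (length(ids)) {
        nodes$lineage[nodes$name == nm] <-
          paste(sort(unique(partition$assignment[ids])), collapse = ",")
      }
    }
  }
  utils::write.table(nodes, node_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  utils::write.table(net$edges, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(nodes = nodes, edges = net$edges))
}
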