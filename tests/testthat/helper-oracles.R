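# Independent oracles used across the suite. Each re-derives the quantity
# from first principles (loops, closures, exhaustive search) without
# touching the implementation under test.

# naive per-column walk: K2P distance of two character vectors
oracle_k2p <- function(a, b) {
  acgt <- c("A", "C", "G", "T")
  n <- 0L; ts <- 0L; tv <- 0L
  for (i in seq_along(a)) {
    if (a[i] %in% acgt && b[i] %in% acgt) {
      n <- n + 1L
      if (a[i] != b[i]) {
        pur <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)
        if (pur[a[i]] == pur[b[i]]) ts <- ts + 1L else tv <- tv + 1L
      }
    }
  }
  if (n == 0L) return(NA_real_)
  P <- ts / n; Q <- tv / n
  if (1 - 2 * P - Q <= 0 || 1 - 2 * Q <= 0) return(NA_real_)
  -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)
}

# transitive closure over the boolean sub-threshold adjacency matrix
oracle_components <- function(d, t) {
  adj <- !is.na(d) & d < t
  diag(adj) <- TRUE
  n <- nrow(adj)
  repeat {
    nxt <- (adj %*% adj) > 0
    if (identical(nxt, adj)) break
    adj <- nxt
  }
  comp <- integer(n)
  lab <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      lab <- lab + 1L
      comp[adj[i, ]] <- lab
    }
  }
  comp
}

# random symmetric toy distance matrix
random_dm <- function(n, max_d = 0.5) {
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- runif(n * (n - 1) / 2, 0, max_d)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  dimnames(m) <- list(sprintf("s%02d", 1:n), sprintf("s%02d", 1:n))
  as_dist_matrix(m)
}

# same-partition predicate (labels may differ)
same_partition <- function(a, b) {
  a <- a[names(b)]
  length(unique(paste(a, b))) == length(unique(a)) &&
    length(unique(a)) == length(unique(b))
}

# all set partitions of 1..n as membership vectors (restricted growth)
enumerate_partitions <- function(n) {
  out <- list()
  rec <- function(vec, k) {
    i <- length(vec) + 1L
    if (i > n) {
      out[[length(out) + 1L]] <<- vec
      return()
    }
    for (g in seq_len(k + 1L)) rec(c(vec, g), max(k, g))
  }
  rec(integer(0), 0L)
  out
}

# minimax path weights by dynamic programming (no MST involved)
oracle_minimax <- function(D) {
  n <- nrow(D)
  mm <- D
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        via <- max(mm[i, k], mm[k, j])
        if (via < mm[i, j]) mm[i, j] <- via
      }
    }
  }
  mm
}

# min-plus closure: all-pairs shortest path weights from an edge list
oracle_shortest_paths <- function(nodes, edges) {
  n <- length(nodes)
  sp <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(sp) <- 0
  for (r in seq_len(nrow(edges))) {
    sp[edges$from[r], edges$to[r]] <- edges$steps[r]
    sp[edges$to[r], edges$from[r]] <- edges$steps[r]
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (sp[i, k] + sp[k, j] < sp[i, j]) sp[i, j] <- sp[i, k] + sp[k, j]
  }
  sp
}

# hamming distance matrix of integer state rows
oracle_hamming <- function(M) {
  n <- nrow(M)
  D <- matrix(0L, n, n, dimnames = list(rownames(M), rownames(M)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    D[i, j] <- sum(M[i, ] != M[j, ])
  }
  D
}

# total weight of a minimum spanning tree by exhaustive Prim's growth
oracle_mst_cost <- function(D) {
  n <- nrow(D)
  if (n < 2) return(0)
  in_tree <- c(TRUE, rep(FALSE, n - 1))
  total <- 0
  while (!all(in_tree)) {
    best <- Inf
    bj <- NA
    for (i in which(in_tree)) for (j in which(!in_tree)) {
      if (D[i, j] < best) { best <- D[i, j]; bj <- j }
    }
    total <- total + best
    in_tree[bj] <- TRUE
  }
  total
}

# character-matrix constructor for binary haplotype instances
binary_cm <- function(rows) {
  M <- do.call(rbind, lapply(rows, function(s)
    as.integer(strsplit(s, "")[[1]])))
  ids <- sprintf("h%02d", seq_along(rows))
  rownames(M) <- ids
  structure(list(ids = ids,
                 kind = rep("substitution_site", ncol(M)),
                 def = as.list(seq_len(ncol(M))),
                 states = M),
            class = "character_matrix")
}

# two-cluster toy distance matrix with a clean gap
two_cluster_dm <- function(n1 = 3, n2 = 3, intra = 0.01, inter = 0.20,
                           jitter = 0) {
  n <- n1 + n2
  ids <- sprintf("s%02d", 1:n)
  m <- matrix(inter, n, n, dimnames = list(ids, ids))
  m[1:n1, 1:n1] <- intra
  m[(n1 + 1):n, (n1 + 1):n] <- intra
  if (jitter > 0) {
    jm <- matrix(runif(n * n, 0, jitter), n, n)
    jm[lower.tri(jm)] <- t(jm)[lower.tri(jm)]
    m <- m + jm
  }
  diag(m) <- 0
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  as_dist_matrix(m)
}

write_tmp_fasta <- function(lines) {
  f <- tempfile(fileext = ".fasta")
  writeLines(lines, f)
  f
}
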