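test_that("character recoding treats each change as one step", {
  # one 5-column gap run -> a single binary character
  al <- aligned_set(c(a = "ACGTACGTACGT", b = "ACG-----ACGT"))
  cm <- encode_characters(al)
  expect_equal(length(cm$kind), 1L)
  expect_equal(cm$kind, "indel_block")
  expect_equal(step_count_pair(cm, "a", "b"), 1L)

  # three substitution columns -> three characters
  al <- aligned_set(c(a = "ACGTACGT", b = "TCGAACGA"))
  cm <- encode_characters(al)
  expect_equal(sum(cm$kind == "substitution_site"), 3L)
  expect_equal(step_count_pair(cm, "a", "b"), 3L)

  # invariant alignment -> no characters
  al <- aligned_set(c(a = "ACGTACGT", b = "ACGTACGT", c = "ACGTACGT"))
  expect_equal(length(encode_characters(al)$kind), 0L)

  # length-1 gap also yields one character
  al <- aligned_set(c(a = "ACGTACGT", b = "ACG-ACGT"))
  cm <- encode_characters(al)
  expect_equal(cm$kind, "indel_block")
})

test_that("structural annotations recode intervals and exclude columns", {
  al <- aligned_set(c(a = "ACGTACGTAC", b = "ACTGACGTAC", c = "ACGTACGTAC"))
  cm <- encode_characters(al, structural_annotations = list(c(3, 4)))
  expect_true("structural" %in% cm$kind)
  # the two columns of the inversion leave no substitution characters
  expect_equal(sum(cm$kind == "substitution_site"), 0L)
  expect_equal(step_count_pair(cm, "a", "b"), 1L)
  expect_equal(step_count_pair(cm, "a", "c"), 0L)
  expect_error(
    encode_characters(al, structural_annotations = list(c(3, 4), c(4, 6))),
    "overlapping")
})

test_that("the median example resolves to the 3-step star", {
  cm <- binary_cm(c("000", "110", "011"))
  net <- median_joining(cm)
  expect_equal(sum(net$nodes$is_median), 1L)
  mv <- net$nodes$name[net$nodes$is_median]
  expect_equal(unname(net$states[mv, ]), c(0L, 1L, 0L))
  expect_equal(sum(net$edges$steps), 3)
  expect_equal(nrow(net$edges), 3L)
  expect_true(all(net$edges$steps == 1))
  # exhaustive Steiner check: no {0,1}^3 vector gives total cost < 3
  H <- cm$states
  best <- Inf
  for (bits in 0:7) {
    v <- as.integer(intToBits(bits))[1:3]
    M <- rbind(H, v)
    best <- min(best, oracle_mst_cost(oracle_hamming(M)))
  }
  expect_equal(best, 3)
})

test_that("two haplotypes connect by one edge of their full distance", {
  cm <- binary_cm(c("0000", "1111"))
  net <- median_joining(cm)
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$edges$steps, 4L)
  expect_equal(sum(net$nodes$is_median), 0L)
})

test_that("a single haplotype yields a one-node network with warning", {
  al <- aligned_set(c(a = "ACGT", b = "ACGT"))
  cm <- encode_characters(al)
  expect_warning(net <- median_joining(cm), "single haplotype")
  expect_equal(nrow(net$nodes), 1L)
  expect_equal(net$nodes$multiplicity, 2L)
})

test_that("the network is connected and contains every MST", {
  set.seed(77)
  for (rep in 1:15) {
    k <- sample(4:7, 1)
    nc <- sample(5:9, 1)
    rows <- unique(vapply(seq_len(k), function(i)
      paste(sample(0:1, nc, replace = TRUE), collapse = ""), character(1)))
    if (length(rows) < 2) next
    cm <- binary_cm(rows)
    net <- median_joining(cm)
    # connectivity
    g <- igraph::graph_from_data_frame(net$edges[, 1:2], directed = FALSE,
                                       vertices = net$nodes$name)
    expect_equal(igraph::components(g)$no, 1L)
    # every edge that belongs to some MST of the final node set (weight
    # equal to the minimax path weight, by the cycle property) is present
    D <- oracle_hamming(net$states)
    mm <- oracle_minimax(D)
    nm <- rownames(net$states)
    in_net <- matrix(FALSE, nrow(D), nrow(D), dimnames = list(nm, nm))
    for (r in seq_len(nrow(net$edges))) {
      in_net[net$edges$from[r], net$edges$to[r]] <- TRUE
      in_net[net$edges$to[r], net$edges$from[r]] <- TRUE
    }
    for (i in seq_len(nrow(D) - 1)) for (j in (i + 1):nrow(D)) {
      if (D[i, j] == mm[i, j]) expect_true(in_net[i, j])
    }
    # accepted medians never increased the connection cost
    obs <- net$states[!net$nodes$is_median, , drop = FALSE]
    expect_lte(oracle_mst_cost(D), oracle_mst_cost(oracle_hamming(obs)))
    # edge weights equal hamming distances between their endpoints
    for (r in seq_len(nrow(net$edges))) {
      expect_equal(net$edges$steps[r],
                   D[net$edges$from[r], net$edges$to[r]])
    }
  }
})

test_that("lineage separation follows network geodesics", {
  cm <- binary_cm(c("000000", "111000", "111111"))
  net <- median_joining(cm)
  part <- as_lineage_partition(c(h01 = "A", h02 = "A", h03 = "B"))
  sep <- lineage_separation(net, part)
  expect_equal(sep["A", "B"], 3)
  expect_equal(sep["A", "A"], 0)

  # geodesics agree with a brute-force min-plus closure
  set.seed(13)
  rows <- c("0000000", "1111000", "0001111", "1100110")
  cm <- binary_cm(rows)
  net <- median_joining(cm)
  sp <- oracle_shortest_paths(net$nodes$name, net$edges)
  part <- as_lineage_partition(stats::setNames(c("A", "A", "B", "C"),
                                               cm$ids))
  sep <- lineage_separation(net, part)
  nodes_of <- function(lab)
    unique(net$seq_node[names(part$assignment)[part$assignment == lab]])
  for (la in c("A", "B", "C")) for (lb in c("A", "B", "C")) {
    if (la < lb) {
      expect_equal(sep[la, lb], min(sp[nodes_of(la), nodes_of(lb)]))
    }
  }
})

test_that("deeply diverged clades stay many steps apart in the network", {
  sim <- simulate_dataset(sim_config(n_lineages = 2,
                                     lineage_sizes = c(3, 3),
                                     marker2_indel_rate = 1, seed = 31))
  cm <- encode_characters(sim$marker2)
  net <- median_joining(cm)
  sep <- lineage_separation(net, sim$truth2)
  off <- sep[upper.tri(sep)]
  expect_true(all(off > 10))
})
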