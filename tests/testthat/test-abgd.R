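test_that("gap detection flags an unambiguous jump and ignores ladders", {
  g <- find_gap(c(rep(0.01, 15), rep(0.20, 9)), prior_p = 0.01, X = 1.0)
  expect_false(is.null(g))
  expect_equal(g$low, 0.01)
  expect_equal(g$high, 0.20)

  # uniform ladder: no jump exceeds 10x the local spacing
  expect_null(find_gap(seq(0.01, 0.10, by = 0.01), 0.001, X = 10))

  # one tight cluster entirely below the prior
  expect_null(find_gap(rep(c(0.001, 0.002, 0.003), 5), 0.01, X = 1))

  # fewer than two distinct distances
  expect_null(find_gap(rep(0.05, 8), 0.01, X = 1))
  expect_null(find_gap(0.05, 0.01, X = 1))
})

test_that("two clean clusters give two groups at every prior", {
  set.seed(2)
  dm <- two_cluster_dm(4, 4, jitter = 0.002)
  res <- abgd_partition(dm, abgd_config())
  for (pp in res$per_prior) {
    expect_equal(pp$initial$n_lineages, 2L)
    expect_equal(pp$recursive$n_lineages, 2L)
  }
  expect_equal(res$chosen$n_lineages, 2L)
  expect_true(same_partition(res$chosen$assignment,
                             threshold_partition(dm, 0.10)$assignment))
})

test_that("single-gap matrices make ABGD equal any in-gap threshold cut", {
  set.seed(8)
  for (rep in 1:10) {
    sizes <- sample(2:4, 3, replace = TRUE)
    n <- sum(sizes)
    ids <- sprintf("s%02d", 1:n)
    m <- matrix(runif(n * n, 0.18, 0.30), n, dimnames = list(ids, ids))
    at <- 0
    for (k in seq_along(sizes)) {
      idx <- (at + 1):(at + sizes[k])
      m[idx, idx] <- runif(sizes[k]^2, 0, 0.02)
      at <- at + sizes[k]
    }
    m[lower.tri(m)] <- t(m)[lower.tri(m)]; diag(m) <- 0
    dm <- as_dist_matrix(m)
    res <- abgd_partition(dm)
    for (t in c(0.05, 0.10, 0.15)) {
      expect_true(same_partition(res$chosen$assignment,
                                 threshold_partition(dm, t)$assignment))
    }
  }
})

nested_dm <- function() {
  # scales 0.01 / 0.08 / 0.25: the dominant gap separates the far
  # cluster; the fine split between the two near clusters only emerges
  # within their merged group
  set.seed(1)
  ids <- c(paste0("a", 1:3), paste0("b", 1:3), paste0("c", 1:4))
  m <- matrix(0.25, 10, 10, dimnames = list(ids, ids))
  m[1:6, 1:6] <- 0.08
  m[1:3, 1:3] <- 0.01 + matrix(runif(9, 0, 0.002), 3)
  m[4:6, 4:6] <- 0.01 + matrix(runif(9, 0, 0.002), 3)
  m[7:10, 7:10] <- 0.01
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  diag(m) <- 0
  as_dist_matrix(m)
}

test_that("recursion resolves nested scales the initial pass misses", {
  dm <- nested_dm()
  res <- abgd_partition(dm)
  mid <- res$per_prior[[6]]            # a mid-grid prior
  expect_equal(mid$initial$n_lineages, 2L)
  expect_equal(mid$recursive$n_lineages, 3L)
  expect_equal(res$chosen$n_lineages, 3L)
  want <- threshold_partition(dm, 0.05)$assignment
  expect_true(same_partition(res$chosen$assignment, want))

  # recursive partitions refine their initial partitions at every prior
  for (pp in res$per_prior) {
    ini <- pp$initial$assignment
    rec <- pp$recursive$assignment[names(ini)]
    expect_true(all(tapply(ini, rec, function(x) length(unique(x))) == 1))
  }
})

test_that("the recovered nested partition is the unique gap-consistent one", {
  dm <- nested_dm()
  res <- abgd_partition(dm)
  got <- res$chosen$assignment[dm$ids]
  # exhaustive search: among all set partitions of the 10 sequences, those
  # whose largest within-group distance is below the smallest between-group
  # distance (a strict barcode-gap partition) with more than one group
  # singleton groups are excluded: carving out single sequences is
  # vacuously gap-consistent (an all-singleton partition has no
  # within-group distances at all)
  valid <- list()
  for (memb in enumerate_partitions(10)) {
    if (length(unique(memb)) < 2) next
    if (min(table(memb)) < 2) next
    within <- max(c(0, dm$d[outer(memb, memb, "==") &
                              upper.tri(dm$d)]))
    between <- min(dm$d[outer(memb, memb, "!=") & upper.tri(dm$d)])
    if (within < between) valid[[length(valid) + 1L]] <- memb
  }
  # the valid partitions are exactly the 2-group and 3-group nestings
  k_valid <- vapply(valid, function(m) length(unique(m)), integer(1))
  expect_equal(sort(k_valid), c(2L, 3L))
  fine <- valid[[which.max(k_valid)]]
  names(fine) <- dm$ids
  expect_true(same_partition(got, fine))
})

test_that("initial group counts never increase with the prior", {
  set.seed(31)
  for (rep in 1:5) {
    sim <- simulate_dataset(sim_config(seed = 100 + rep))
    dm <- k2p_matrix(sim$marker1)
    res <- abgd_partition(dm)
    counts <- vapply(res$per_prior, function(p) p$initial$n_lineages,
                     integer(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("degenerate inputs fall back to the trivial partition", {
  m <- matrix(c(0, 0.1, 0.1, 0), 2, dimnames = list(c("a", "b"),
                                                    c("a", "b")))
  expect_warning(res <- abgd_partition(as_dist_matrix(m)), "trivial")
  expect_equal(res$chosen$n_lineages, 1L)
})

test_that("the distance histogram shows the barcode gap as empty bins", {
  dm <- two_cluster_dm(4, 4)
  h <- distance_histogram(dm, n_bins = 20)
  expect_equal(sum(h$count), sum(upper.tri(dm$d)))
  gap_bins <- h$count[h$bin_low > 0.02 & h$bin_high < 0.19]
  expect_true(all(gap_bins == 0))
})
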