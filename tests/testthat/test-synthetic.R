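test_that("the generator is byte-deterministic under a fixed seed", {
  cfg <- sim_config(seed = 12)
  d1 <- tempfile(); d2 <- tempfile(); d3 <- tempfile()
  write_dataset(simulate_dataset(cfg), d1)
  write_dataset(simulate_dataset(cfg), d2)
  write_dataset(simulate_dataset(sim_config(seed = 13)), d3)
  for (f in c("marker1.fasta", "marker2.fasta", "metadata.tsv",
              "truth.tsv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  expect_false(identical(readLines(file.path(d1, "marker1.fasta")),
                         readLines(file.path(d3, "marker1.fasta"))))
})

test_that("a single lineage gives a single-lineage truth", {
  sim <- simulate_dataset(sim_config(n_lineages = 1,
                                     lineage_sizes = 4, seed = 2))
  expect_equal(sim$truth$n_lineages, 1L)
  expect_equal(length(sim$marker1$ids), 4L)
})

test_that("realized distances respect the planted barcode gap", {
  sim <- simulate_dataset(sim_config(seed = 7))
  dm <- k2p_matrix(sim$marker1)
  truth <- sim$truth$assignment[dm$ids]
  same <- outer(truth, truth, "==") & upper.tri(dm$d)
  diff <- outer(truth, truth, "!=") & upper.tri(dm$d)
  expect_true(all(dm$d[same] <= 0.04))
  expect_true(all(dm$d[diff] >= 0.08))
  # nominal target calibration: root-to-ancestor draws are 0.12-0.25, so
  # between-lineage distances concentrate near the (slightly
  # homoplasy-shrunk) sum of two draws
  expect_gt(mean(dm$d[diff]), 0.15)
  expect_lt(mean(dm$d[same]), 0.03)
})

test_that("evolved pairs land within 30% of their nominal K2P target", {
  set.seed(5)
  for (target in c(0.05, 0.15, 0.25)) {
    cfg <- sim_config(n_lineages = 2, lineage_sizes = c(1, 1),
                      inter_divergence = c(target, target),
                      intra_divergence = c(0, 0), seed = 50 + target * 100)
    sim <- simulate_dataset(cfg)
    dm <- k2p_matrix(sim$marker1)
    # two ancestors each `target` from the root: pairwise distance is
    # near 2 * target, within the binomial/homoplasy band
    expect_gt(dm$d[1, 2], 2 * target * 0.7)
    expect_lt(dm$d[1, 2], 2 * target * 1.3)
  }
})

test_that("transition bias follows kappa", {
  cfg <- sim_config(n_lineages = 2, lineage_sizes = c(1, 1),
                    inter_divergence = c(0.1, 0.1),
                    intra_divergence = c(0, 0), kappa = 4, seed = 8)
  sim <- simulate_dataset(cfg)
  dm <- k2p_matrix(sim$marker1)
  # realized transition/transversion proportions near the kappa/2 ratio
  expect_gt(dm$P[1, 2] / dm$Q[1, 2], 1.2)
})

test_that("marker 2 is slower and carries shared gap blocks", {
  sim <- simulate_dataset(sim_config(n_lineages = 4,
                                     lineage_sizes = c(3, 3, 3, 3),
                                     marker2_indel_rate = 1.5, seed = 14))
  dm1 <- k2p_matrix(sim$marker1)
  dm2 <- k2p_matrix(sim$marker2)
  m1 <- mean(dm1$d[upper.tri(dm1$d)], na.rm = TRUE)
  m2 <- mean(dm2$d[upper.tri(dm2$d)], na.rm = TRUE)
  expect_lt(m2, m1 * 0.6)
  # gap runs, when present, are identical within a lineage's clones
  has_gap <- apply(sim$marker2$mat == "-", 1, any)
  if (any(has_gap)) {
    gid <- names(which(has_gap))[1]
    lin <- sim$truth2$assignment[gid]
    mates <- names(sim$truth2$assignment)[sim$truth2$assignment == lin]
    cols <- which(sim$marker2$mat[gid, ] == "-")
    for (m in mates) {
      expect_true(all(sim$marker2$mat[m, cols] == "-"))
    }
  }
})

test_that("clone ids appear exactly when a specimen has several clones", {
  sim <- simulate_dataset(sim_config(seed = 16))
  m2 <- sim$meta[sim$meta$marker == "marker2", ]
  per_spec <- table(m2$specimen_id)
  multi <- names(per_spec)[per_spec > 1]
  single <- names(per_spec)[per_spec == 1]
  expect_true(all(!is.na(m2$clone_id[m2$specimen_id %in% multi])))
  expect_true(all(is.na(m2$clone_id[m2$specimen_id %in% single])))
})

test_that("an impossible gap configuration is refused", {
  expect_error(sim_config(intra_divergence = c(0, 0.15),
                          inter_divergence = c(0.12, 0.25), seed = 1),
               "barcode gap")
})

test_that("planted sublineages split at 5% but not 10%", {
  cfg <- degrade_gap(sim_config(n_lineages = 4,
                                lineage_sizes = c(4, 4, 4, 4), seed = 19),
                     lineages = 2L, divergences = 0.08)
  sim <- simulate_dataset(cfg)
  dm <- k2p_matrix(sim$marker1)
  p10 <- threshold_partition(dm, 0.10)
  expect_true(same_partition(p10$assignment, sim$truth$assignment))
  subs <- sublineage_scan(dm, p10, 0.05)
  expect_equal(nrow(subs), 1L)
  expect_equal(subs$n_sublineages, 2L)
  expect_gt(subs$max_between_divergence, 0.06)
  expect_lt(subs$max_between_divergence, 0.13)
  # the planted lineage is the one containing the sublineage split
  planted_ids <- names(sim$truth$assignment)[
    sim$truth$assignment == sim$truth$assignment[["sp005_m1"]]]
  expect_setequal(p10$members[[subs$lineage]], planted_ids)

  # without planting, nothing splits
  sim0 <- simulate_dataset(sim_config(n_lineages = 4,
                                      lineage_sizes = c(4, 4, 4, 4),
                                      seed = 19))
  dm0 <- k2p_matrix(sim0$marker1)
  p0 <- threshold_partition(dm0, 0.10)
  expect_equal(nrow(sublineage_scan(dm0, p0, 0.05)), 0L)

  # planting at 12% separates lineages already at the 10% threshold
  cfg12 <- degrade_gap(sim_config(n_lineages = 4,
                                  lineage_sizes = c(4, 4, 4, 4),
                                  seed = 19),
                       lineages = 2L, divergences = 0.13)
  sim12 <- simulate_dataset(cfg12)
  p12 <- threshold_partition(k2p_matrix(sim12$marker1), 0.10)
  expect_equal(p12$n_lineages, 5L)
})

test_that("planted marker-2 merges and tangles surface as discordances", {
  cfg <- sim_config(n_lineages = 5, lineage_sizes = rep(3, 5),
                    clones_per_specimen = 2:3,
                    marker2_merged_pairs = list(c(1, 2)),
                    marker2_tangled_pairs = list(c(3, 4)),
                    seed = 33)
  sim <- simulate_dataset(cfg)
  res <- run_compare(sim$marker1, sim$marker2,
                     pipeline_config(n_boot = 0), tempfile())
  types <- res$report$discrepancies$type
  expect_true("merge" %in% types)
  expect_true("tangled" %in% types)
  expect_equal(res$report$n_discrepancies, 2L)
})
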