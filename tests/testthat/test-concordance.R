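meta_of <- function(seq_ids, specimens, morpho = NULL, group = NULL,
                    maturity = NULL) {
  data.frame(seq_id = seq_ids, specimen_id = specimens,
             clone_id = NA_character_,
             morphotaxon = if (is.null(morpho)) NA_character_ else morpho,
             group = if (is.null(group)) "all" else group,
             maturity = if (is.null(maturity)) "identified" else maturity,
             stringsAsFactors = FALSE)
}

test_that("specimens map to lineage sets with polymorphism flags", {
  part <- as_lineage_partition(c(c1 = "L1", c2 = "L1", c3 = "L1",
                                 d1 = "L1", d2 = "L2"))
  meta <- meta_of(c("c1", "c2", "c3", "d1", "d2"),
                  c("spA", "spA", "spA", "spB", "spB"))
  sl <- specimen_lineage(part, meta)
  expect_equal(sl$n_lineages[sl$specimen_id == "spA"], 1L)
  expect_false(sl$polymorphic[sl$specimen_id == "spA"])
  expect_true(sl$polymorphic[sl$specimen_id == "spB"])
  expect_equal(sl$lineages[sl$specimen_id == "spB"], "L1,L2")
  expect_error(specimen_lineage(part, meta[-1, ]), "unknown seq_id")
})

test_that("identical partitions produce no discrepancies", {
  set.seed(3)
  for (rep in 1:10) {
    n <- sample(6:12, 1)
    ids <- sprintf("q%02d", 1:n)
    p <- as_lineage_partition(stats::setNames(
      sprintf("L%d", sample(1:4, n, replace = TRUE)), ids))
    meta <- meta_of(ids, sprintf("sp%02d", 1:n))
    rep_ <- compare_partitions(p, p, meta)
    expect_equal(rep_$n_discrepancies, 0L)
  }
})

test_that("a planted merge is reported once, and symmetrically as a split", {
  # marker A separates specimens x and y; marker B joins them
  pA <- as_lineage_partition(c(xa = "A1", ya = "A2", za = "A3"))
  pB <- as_lineage_partition(c(xb = "B1", yb = "B1", zb = "B2"))
  metaA <- meta_of(c("xa", "ya", "za"), c("x", "y", "z"))
  metaB <- meta_of(c("xb", "yb", "zb"), c("x", "y", "z"))
  rep_ <- compare_partitions(pA, pB, metaA, metaB)
  expect_equal(rep_$n_discrepancies, 1L)
  expect_equal(rep_$discrepancies$type, "merge")
  expect_equal(rep_$discrepancies$lineages_a, "A1,A2")

  rev_ <- compare_partitions(pB, pA, metaB, metaA)
  expect_equal(rev_$n_discrepancies, 1L)
  expect_equal(rev_$discrepancies$type, "split")
})

test_that("intra-individual polymorphism is tangled, not merge or split", {
  # specimen y carries clones in two B-lineages
  pA <- as_lineage_partition(c(xa = "A1", ya = "A2"))
  pB <- as_lineage_partition(c(xb = "B1", yb1 = "B1", yb2 = "B2"))
  metaA <- meta_of(c("xa", "ya"), c("x", "y"))
  metaB <- meta_of(c("xb", "yb1", "yb2"), c("x", "y", "y"))
  rep_ <- compare_partitions(pA, pB, metaA, metaB)
  expect_equal(rep_$discrepancies$type, "tangled")
  expect_true(grepl("y", rep_$discrepancies$specimens))
})

test_that("no shared specimens yields an empty report with warning", {
  pA <- as_lineage_partition(c(a = "A1"))
  pB <- as_lineage_partition(c(b = "B1"))
  expect_warning(
    rep_ <- compare_partitions(pA, pB, meta_of("a", "x"), meta_of("b", "y")),
    "no shared specimens")
  expect_equal(rep_$n_discrepancies, 0L)
})

test_that("diversity summary counts morphotaxa versus lineages", {
  # one morphotaxon spanning 4 lineages: a cryptic complex of depth 4
  ids <- sprintf("s%d", 1:8)
  part <- as_lineage_partition(stats::setNames(
    c("L1", "L2", "L3", "L4", "L5", "L5", "L6", "L7"), ids))
  meta <- meta_of(ids, sprintf("sp%d", 1:8),
                  morpho = c(rep("Tubifex tubifex", 4), "Nais elinguis",
                             "Nais elinguis", "Piguetiella blanci",
                             "Chaetogaster diaphanus"),
                  group = c(rep("Tubificinae", 4), rep("Naidinae", 4)))
  ds <- diversity_summary(part, meta)
  expect_equal(ds$totals$n_morphotaxa, 4L)
  expect_equal(ds$totals$n_lineages, 7L)
  tub <- ds$by_group[ds$by_group$group == "Tubificinae", ]
  expect_equal(tub$n_morphotaxa, 1L)
  expect_equal(tub$n_lineages, 4L)
  expect_equal(ds$cryptic_complexes$morphotaxon, "Tubifex tubifex")
  expect_equal(ds$cryptic_complexes$n_lineages, 4L)
  # group counts sum to totals (no double counting)
  expect_equal(sum(ds$by_group$n_lineages), ds$totals$n_lineages)
  expect_equal(sum(ds$by_group$n_morphotaxa), ds$totals$n_morphotaxa)
})

test_that("unlabeled immatures pool into one indeterminate taxon per group", {
  ids <- sprintf("s%d", 1:5)
  part <- as_lineage_partition(stats::setNames(
    c("L1", "L2", "L3", "L4", "L5"), ids))
  meta <- meta_of(ids, sprintf("sp%d", 1:5),
                  morpho = c("Eiseniella tetraedra", NA, NA,
                             "Tub_with_hair_setae", "Tub_with_hair_setae"),
                  group = c("Lumbricidae", "Lumbricidae", "Lumbricidae",
                            "Tubificinae", "Tubificinae"),
                  maturity = c("identified", "immature", "immature",
                               "immature", "immature"))
  ds <- diversity_summary(part, meta)
  lc <- ds$by_group[ds$by_group$group == "Lumbricidae", ]
  # E. tetraedra + one pooled indeterminate taxon
  expect_equal(lc$n_morphotaxa, 2L)
  expect_equal(lc$n_lineages, 3L)
  # the labeled immature morpho-group counts as one taxon over 2 lineages
  tub <- ds$by_group[ds$by_group$group == "Tubificinae", ]
  expect_equal(tub$n_morphotaxa, 1L)
  expect_equal(tub$n_lineages, 2L)
})
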