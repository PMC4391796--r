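#' Configuration mirroring a regional oligochaete barcoding survey
#'
#' Builds a [sim_config()] whose shape follows a representative aquatic
#' oligochaete COI/ITS2 barcoding survey of the kind used to benchmark
#' distance thresholds for biomonitoring: 185 barcode sequences falling
#' into 41 lineages across four families (Naididae split into
#' Tubificinae, Naidinae and Rhyacodrilinae, plus Lumbriculidae,
#' Enchytraeidae and Lumbricidae), per-lineage sample sizes ranging from
#' 1 to 44, cryptic complexes of 4, 5 and 2 lineages hiding inside three
#' common morphospecies, unidentifiable immature morpho-groups, four
#' planted sublineages sitting inside the 5–10% band of the barcode gap,
#' and two planted nuclear-marker discordances (one lineage pair with
#' identical slow-marker sequences; one pair whose specimens carry
#' divergent slow-marker copy classes).
#'
#' @param seed Integer seed passed through to [sim_config()].
#' @return A `sim_config`.
#' @export
survey_config <- function(seed) {
  sizes <- c(
    # Tubificinae lineages 1-23
    1, 6, 1, 1, 5, 1, 44, 4, 4, 4, 5, 3, 1, 1, 3, 1, 22, 5, 1, 5, 5, 5, 1,
    # Naidinae 24-29
    1, 1, 1, 9, 1, 3,
    # Rhyacodrilinae 30
    3,
    # Lumbriculidae 31-33
    2, 2, 22,
    # Enchytraeidae 34-37
    1, 1, 2, 1,
    # Lumbricidae 38-41
    1, 2, 2, 1)
  stopifnot(length(sizes) == 41, sum(sizes) == 185)
  group <- c(rep("Tubificinae", 23), rep("Naidinae", 6),
             rep("Rhyacodrilinae", 1), rep("Lumbriculidae", 3),
             rep("Enchytraeidae", 4), rep("Lumbricidae", 4))
  morpho <- character(41)
  morpho[1:3] <- "Tubificinae_hair_setae_group"    # immature morpho-group
  morpho[4:8] <- sprintf("Tubificinae_sp_%02d", 4:8)
  morpho[9:12] <- "Tubifex_like_sp"                # cryptic complex of 4
  morpho[13] <- "Tubificinae_sp_13"
  morpho[14:16] <- "Tubificinae_no_hair_setae_group"
  morpho[17:21] <- "Limnodrilus_like_sp"           # cryptic complex of 5
  morpho[22:23] <- sprintf("Tubificinae_sp_%02d", 22:23)
  morpho[24:29] <- sprintf("Naidinae_sp_%02d", 1:6)
  morpho[30] <- "Rhyacodrilinae_sp_01"
  morpho[31] <- "Lumbriculidae_immature_group"
  morpho[32:33] <- sprintf("Lumbriculidae_sp_%02d", 2:3)
  morpho[34:37] <- sprintf("Enchytraeidae_sp_%02d", 1:4)
  morpho[38] <- NA                                  # unlabeled immatures
  morpho[39:40] <- "Eiseniella_like_sp"             # cryptic complex of 2
  morpho[41] <- NA
  cfg <- sim_config(n_lineages = 41,
                    lineage_sizes = sizes,
                    morphotaxon_of = morpho,
                    group_of = group,
                    marker2_merged_pairs = list(c(14, 15)),
                    marker2_tangled_pairs = list(c(16, 17)),
                    seed = seed)
  # sublineages planted mid-gap (between the 5% and 10% working
  # thresholds) inside two cryptic-complex lineages, the large
  # Lumbriculidae lineage and one Lumbricidae lineage
  degrade_gap(cfg, lineages = c(10L, 17L, 33L, 40L),
              divergences = c(0.090, 0.085, 0.075, 0.065))
}
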