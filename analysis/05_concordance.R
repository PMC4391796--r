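#!/usr/bin/env Rscript
# Stage 5 — two-marker concordance and morphology-vs-genetics summary.
#
# Partitions the fast marker at 10% and the slow marker at 3%, maps the
# partitions onto each other through shared specimens, lists the
# discordances (merges, splits, clone tangles), and tabulates
# morphotaxa against genetic lineages per family/subfamily — the
# bottom-line accounting of how much diversity morphology misses.

library(barcodegap)

meta <- read_metadata(file.path("results", "data", "metadata.tsv"))
m1 <- read_fasta(file.path("results", "data", "marker1.fasta"),
                 marker = "COI-like", meta = meta)
m2 <- read_fasta(file.path("results", "data", "marker2.fasta"),
                 marker = "slow", meta = meta)

res <- run_compare(m1, m2, pipeline_config(delimit_t = 0.10, marker2_t = 0.03,
                                           n_boot = 0, build_network = FALSE),
                   file.path("results", "concordance"))

cat("\ndiscrepancy table:\n")
print(res$report$discrepancies)
cat("\nmorphological vs genetic diversity:\n")
print(rbind(res$diversity$by_group, res$diversity$totals))
cryptic <- res$diversity$cryptic_complexes
named_species <- !grepl("_group|_indet", cryptic$morphotaxon)
cat("\ncryptic lineages within named morphospecies:",
    sum(cryptic$n_lineages[named_species]), "in",
    sum(named_species), "complexes\n")
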