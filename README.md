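# barcodegap

Distance-based species delimitation from DNA barcodes, for the situation
every benthic-invertebrate monitoring lab knows: most specimens in a
sample are immature and morphologically unidentifiable, common
morphospecies hide cryptic lineages, and the practical identification
tool is a short mitochondrial marker (COI) plus a divergence threshold.
`barcodegap` implements the full computational chain of such a survey as
a tested R package with an analysis workflow on top, validated end to
end on simulated data with known lineage truth.

## What it computes

* **K2P distances.** For each aligned pair, over the columns where both
  sequences carry an unambiguous base, with transition proportion *P*
  and transversion proportion *Q*:
  *d* = −½·ln(1 − 2P − Q) − ¼·ln(1 − 2Q).
  Pairwise or complete gap deletion; saturated pairs carry an explicit
  undefined sentinel, never an imputed number.
* **MOTU delimitation.** Lineages are connected components of the graph
  with an edge wherever *d* < *t* (single linkage), so any two lineages
  are separated by more than *t* by construction. Standard working
  thresholds: 10% primary cut, 5% sublineage scan, 1% haplotype
  collapse, 3% for a slower nuclear marker (ITS2-like). Per-lineage
  intra/inter variability tables use the `NC` sentinel for singletons.
* **Automatic barcode-gap discovery.** A re-implementation of recursive
  gap partitioning: over a log-spaced grid of prior intraspecific
  divergences (0.001–0.1), detect the most prominent significant gap in
  the ranked distances (width > *X* × local slope, slope floored at the
  prior; *X* = 1 by default), split by connectivity below the gap,
  recurse within groups, and report the partition stable across the
  prior grid.
* **NJ trees with bootstrap.** Saitou–Nei trees (via `ape`) on collapsed
  haplotypes, seeded column-resampling bootstrap, newick output with
  support shown at ≥80% and collapsed representatives suffixed
  `"_Nind"`.
* **Median-joining networks.** Simple indel coding (a multi-base indel
  or annotated inversion is one step, same weight as a substitution),
  union of all minimum spanning trees plus cost-reducing median vectors,
  and minimum mutational separation between lineages along geodesics.
* **Two-marker and morphology concordance.** Specimen-mediated mapping
  between marker partitions with three discordance types (merge, split,
  clone tangle), and morphotaxa-versus-lineages accounting that exposes
  cryptic complexes.
* **A seeded simulator** generating two-marker datasets with known truth:
  transition-biased substitution at controlled K2P targets, a barcode
  gap by construction, lineage-level indel blocks and clone polymorphism
  on the slow marker, plus planted sublineages, marker merges and clone
  tangles for stress tests.

## Worked example

Simulate a small four-lineage dataset with one 8% sublineage planted
inside the first lineage, then delimit:

```r
library(barcodegap)

cfg <- degrade_gap(sim_config(n_lineages = 4, lineage_sizes = c(4, 3, 2, 1),
                              seed = 7),
                   lineages = 1L, divergences = 0.08)
sim  <- simulate_dataset(cfg)
dm   <- k2p_matrix(sim$marker1)
part <- threshold_partition(dm, 0.10)
lineage_stats(dm, part)
#>   lineage n_members  intra_min  intra_max inter_nearest nearest_lineage
#> 1      L1         4 0.00501885 0.08709678     0.3203604              L2
#> 2      L2         3 0.00501885 0.02030653     0.3008593              L3
#> 3      L3         2 0.01007581 0.01007581     0.3008593              L2
#> 4      L4         1         NA         NA     0.3480367              L2

sublineage_scan(dm, part, 0.05)
#>   lineage n_sublineages max_between_divergence
#> 1      L1             2             0.08709678

abgd_partition(dm)
#> gap_partition_result: 5 groups (chosen at prior 0.001 )
#>   groups per prior: 5 5 5 5 5 5 5 5 5 4
```

Reading: the 10% cut finds the four planted lineages, each separated
from its nearest neighbour by ≥ 30% (`inter_nearest`); the singleton
lineage reports `NA` (printed `NC` in report files) rather than a fake
zero. The planted sublineage is invisible at 10% — L1's intra range
honestly reaches 8.7% — but the 5% scan reports exactly one split at
that divergence, and the gap partitioner, which needs no threshold,
resolves all five groups across the prior grid (collapsing to 4 only at
the largest prior, 0.1).

## The analysis workflow

Numbered drivers under `analysis/` run the survey-scale study on
synthetic data shaped like a regional oligochaete barcoding campaign
(185 fast-marker sequences, 41 lineages, 1–44 sequences per lineage,
cryptic complexes, immature morpho-groups, a clone-sequenced slow
marker):

```sh
Rscript analysis/01_simulate.R      # dataset + truth -> results/data/
Rscript analysis/02_delimit.R      # K2P, collapse, 10%/5% cuts, NJ tree
Rscript analysis/03_abgd.R         # barcode-gap validation per prior
Rscript analysis/04_network.R      # within-clade median-joining networks
Rscript analysis/05_concordance.R  # two-marker + morphology accounting
Rscript analysis/06_recovery.R     # truth-recovery benchmark over seeds
```

Each stage states what it found on stdout and writes TSVs under
`results/`.

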