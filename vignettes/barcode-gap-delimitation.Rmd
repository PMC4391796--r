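---
title: "Distance-based species delimitation from DNA barcodes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distance-based species delimitation from DNA barcodes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barcodegap)
```

# The problem

Benthic invertebrate groups such as aquatic oligochaetes are valuable
bioindicators, but most specimens in a sediment sample are immature and
morphologically unidentifiable, and common morphospecies hide cryptic
lineages. DNA barcoding replaces the morphological bottleneck with a
distance rule: sequence a short marker (typically the mitochondrial COI
fragment), compute pairwise genetic distances, and call two specimens
conspecific when their distance falls below a threshold. The rule works
when a *barcode gap* exists — when within-species divergences (a few
percent) and between-species divergences (tens of percent) occupy
disjoint ranges.

`barcodegap` implements the complete computational chain of such a
survey: K2P distances, haplotype collapsing, threshold partitioning into
MOTUs (molecular operational taxonomic units), automatic barcode-gap
detection, neighbor-joining trees with bootstrap support, median-joining
haplotype networks of a slower nuclear marker, and cross-marker /
morphology concordance accounting. A seeded simulator generates
two-marker datasets with known lineage truth so that every stage is
testable without field data.

# Distances

For two aligned sequences compared over the `n` columns where both carry
an unambiguous base, with transition proportion $P$ (A↔G, C↔T) and
transversion proportion $Q$, the Kimura two-parameter distance is

$$d = -\tfrac{1}{2}\ln\!\left(1 - 2P - Q\right)
      -\tfrac{1}{4}\ln\!\left(1 - 2Q\right).$$

Design points:

* **Gap policy.** The default is pairwise deletion — each pair drops only
  its own gap/ambiguous columns — because partial fragments are common
  and complete deletion would discard their information globally.
  `k2p_matrix(..., gap_mode = "complete_deletion")` is available for
  sensitivity analysis.
* **Saturation.** When $1-2P-Q \le 0$ or $1-2Q \le 0$ the correction is
  undefined. Such pairs carry an `NA` sentinel and are listed in
  `undefined_pairs`; they contribute no clustering edge and are never
  imputed. Tree building refuses them outright.
* Distances are proportions internally; reports render percentages with
  the `"NC"` (not calculated) sentinel for singleton lineages, which is
  how survey tables print intra-lineage variability.

# Threshold delimitation

`threshold_partition(dm, t)` returns the connected components of the
graph with an edge wherever `d < t` (single linkage). Single linkage is
the only linkage rule that guarantees the defining property of the
output — every two lineages are separated by at least `t` — and it
matches the logic of the barcode gap (components cannot straddle an
empty distance band). The price is chaining: a lineage's internal
maximum can exceed `t` through sub-threshold intermediates, so
per-lineage statistics report observed ranges honestly rather than
assuming `intra_max < t`.

Working thresholds follow the values standard in oligochaete barcoding:
10% for primary COI lineages, 5% for a secondary scan that exposes
cryptic sublineages sitting inside the gap, 1% for collapsing
near-identical haplotypes in tree displays, and 3% for the slower
nuclear marker. All are parameters, not constants.

`sublineage_scan` re-partitions each lineage at the lower threshold and
reports the maximum between-sublineage divergence of each split — the
quantity a reader needs to decide whether a 6–10% sublineage deserves
species rank.

The inter-lineage aggregator of `lineage_stats` is configurable
(`min_nearest` or `mean_nearest`) because published tables of this kind
do not always state which statistic they print; reports emit both.

# Automatic barcode-gap detection

`abgd_partition` re-implements recursive barcode-gap partitioning: for
each prior maximum intraspecific divergence $P$ on a log-spaced grid
(defaults 0.001–0.1, ten steps), detect the gap in the ranked pairwise
distances, split by connectivity at the gap's lower bound, and recurse
inside each group until no significant gap remains.

The gap detector is this package's own reconstruction, and its three
rules are worth stating precisely:

1. **Candidacy.** An interval $(d_i, d_{i+1})$ of the ranked distances
   is a candidate when $d_{i+1} > P$: a gap wholly inside the prior
   intraspecific range is meaningless, while one spanning the prior is
   acceptable.
2. **Significance.** The width must exceed $X$ times the local slope,
   estimated as the mean rank spacing over a sliding window of
   `max(10, 5%)` of the pairs — *floored at the prior itself*. The floor
   is what makes the prior bite: under a prior of, say, 4.6%, rank jumps
   smaller than 4.6% are within the spacing scale the prior tolerates.
   Without it, any long run of near-tied distances makes the local slope
   collapse and every minor jump "significant", and the group count
   stops depending on the prior at all. $X$ (the relative gap width)
   defaults to 1.0.
3. **Prominence.** Among significant candidates the detector returns the
   one with the largest width-to-slope ratio, not the first. The
   dominant scale is therefore split first, and finer real gaps are
   found by the recursion inside each group — which is exactly the
   nested behaviour the recursive design exists for. A first-hit rule
   would make the initial pass split at the finest significant scale and
   leave the recursion nothing to do.

Two further safeguards: a recursive refinement is accepted only when at
least two sequences stand on each side of the gap (one divergent
sequence is an outlier, not gap evidence — singleton groups are the
initial global pass's business), and the single reported partition is
the recursive partition at the modal group count across the prior grid,
ties resolved toward the count persisting at the largest prior. The
low-prior end of the grid legitimately over-splits (that is what a
prior of 0.1% means); the stable plateau, not the earliest prior, is
the method's answer.

# Trees

`nj_tree` wraps the standard Saitou–Nei implementation (`ape::nj`) with
the package's contracts: canonical input order for reproducible
tie-breaking, a hard error on undefined pairs, and negative branch
lengths clamped to zero with the clamped deficit recorded so additivity
tests can assert zero clamps. `bootstrap_support` resamples alignment
columns, recomputes K2P + NJ per replicate from a single seeded RNG
stream (bit-identical across runs), counts original bipartitions among
replicates, and skips (while counting) replicates whose resampled matrix
is saturated. Display conventions follow survey practice: support shown
only at or above 80%, and collapsed haplotype representatives suffixed
with their member count (`"_6ind"`).

# Haplotype networks

For the slow marker, distances in substitutions are the wrong currency:
ribosomal spacers evolve by multi-base indels and occasional inversions,
and a 5-bp deletion is one mutation, not five. `encode_characters`
therefore recodes the alignment with simple indel coding — each distinct
maximal gap run becomes one presence/absence character (sequences whose
own gap pattern partially overlaps a run get the inapplicable state),
annotated structural intervals become one multistate character each, and
remaining variable columns become multistate substitution characters.
Every character change weighs one step. Inversions cannot be detected
from an alignment, so they enter via explicit column-interval
annotations; unannotated data simply has no structural characters.

`median_joining` builds the network: start from the union of all minimum
spanning trees (an edge survives iff its weight does not exceed the
minimax path weight between its endpoints, plus the tolerance
`epsilon`); repeatedly add the majority-consensus (median) vector of a
connected triplet whenever it lowers the total minimum-spanning cost of
the node set; prune median vectors whose removal leaves that cost
unchanged. With `epsilon = 0` and fixed input order the result is
deterministic. Majority ties fall deterministically to the first node of
the triplet. Inapplicable states are treated as one extra state per
character for distance purposes — a visible, conservative choice that
keeps the step metric well-defined.

`lineage_separation` then answers the survey question "how many
mutations separate these two lineages?" as the minimum geodesic step
count between the lineages' node sets.

# Cross-marker concordance

Markers are compared through specimens, not sequences: a specimen
sequenced for both markers links its fast-marker lineage to its
slow-marker lineage. Three discordance types are distinguished: a
*merge* (one slow-marker lineage containing several fast-marker
lineages' specimens), a *split* (the inverse), and a *tangle* (a
specimen whose cloned slow-marker copies fall into several lineages —
intra-individual polymorphism, which undermines any clean merge/split
reading and is therefore reported as its own category rather than
double-counted).

`diversity_summary` tabulates morphotaxa against genetic lineages.
Counting rule: every distinct morphotaxon label counts once, including
explicit morpho-group labels carried by unidentifiable immatures (e.g.
"Tubificinae with hair setae"), and immatures with no label at all pool
into one indeterminate taxon per higher group. This is the rule under
which the per-family accounting of a mixed mature/immature survey
reproduces exactly; counting labeled groups but discarding unlabeled
immatures entirely would understate the morphological side by one taxon
per family that contains them. A morphotaxon spanning two or more
lineages is reported as a cryptic complex.

# The simulator

`simulate_dataset` generates the study conditions: a uniform random root
sequence; one ancestor per lineage evolved to a K2P target drawn from
`inter_divergence` (default 12–25%); members (one specimen each) evolved
from their ancestor to `intra_divergence` targets (default 0–2%);
substitutions placed by expected-count inversion of the K2P formula
(solve for the transition/transversion proportions at the target
distance with the realized P/Q ratio held at `kappa/2`, default
`kappa = 4`, then place that many changes at distinct random sites).
Expected-count inversion rather than a continuous-time simulation is a
deliberate trade: distance targets are what every downstream assertion
measures, and placement noise (homoplasy between independently evolved
branches) still enters realized distances.

The slow marker scales all divergences by `marker2_rate_scale` (default
0.25), adds lineage-level deletion blocks (Poisson per lineage, 2–8 bp,
realized as aligned gap columns shared by the lineage's members and
clones — insertions would only relabel columns and add nothing the
analyses exercise), and sequences 1–4 clones per specimen with
copy-level noise (default ≤0.5%), emulating intra-individual ribosomal
polymorphism.

Structured perturbations are explicit configuration, so every planted
signal has known truth:

* `degrade_gap` plants sublineages: a second sub-ancestor at a chosen
  divergence inside a lineage, members split between the two.
  Sublineage members carry clone-noise-level spread rather than the
  full member noise, mirroring the empirical pattern where sublineage
  members are near-identical haplotypes and the between-sublineage
  divergence dominates; with full member noise the realized divergence
  would overshoot the planted value by up to four points and cross the
  primary threshold.
* `marker2_merged_pairs` gives two lineages identical slow-marker
  sequences (a marker merge); `marker2_tangled_pairs` gives specimens of
  two lineages clones from both lineages' copy classes (a tangle).

Defaults the contract does not fix were chosen once as desk-scale
analogues of a regional survey: 8 lineages of 1–6 members at 600 nt
(fast marker) and 350 nt (slow marker). `survey_config` scales the same
machinery to the published-survey shape — 185 sequences, 41 lineages
with sizes 1–44 across four families, cryptic complexes of 4 + 5 + 2
lineages, two labeled immature morpho-groups and two unlabeled immature
lineages (28 morphotaxa in total), four mid-gap sublineages at
6.5–9.0%, one slow-marker merge and one tangle.

What the simulator does *not* emulate — and what passing tests therefore
do not show about real data: coalescent genealogy within lineages (the
intra-lineage distance structure is star-like, which is why a lone
divergent member is the typical false-gap shape), recombination,
selection, rate variation among sites, alignment error, and chimeric or
contaminated sequences. Recovery rates measured here are upper bounds
for field data.

# Numerical choices and degenerate inputs

* Thresholds are strict (`d < t`): ties at exactly `t` count as
  separated, implementing "separated by more than `t`".
* Lineage labels are deterministic ordinals assigned by the sorted first
  member id, so runs and permuted inputs agree.
* Haplotype collapse representatives are the lexicographically smallest
  member id.
* Empty alignments, single haplotypes, fewer than three sequences for
  trees or gap partitioning, and all-undefined matrices produce warnings
  or errors, never silent output.
* Problem sizes in the test-suite: brute-force oracles run at 30
  sequences (clustering), 9–10 sequences (exhaustive partition search,
  ≤ 115 975 partitions), ≤ 7 haplotypes (network properties), and 20
  seeded end-to-end recovery runs at the generator defaults; the suite
  completes in under a minute.

# Known limitations

* The gap detector's slope window and prominence rule are this package's
  design; on data without a real gap the per-prior staircase is the
  honest output and the single "chosen" partition should be read with
  the grid in view.
* Bootstrap support is computed for NJ topologies only; likelihood-based
  trees and model selection are out of scope.
* The median-joining implementation targets the within-clade scale
  (tens of haplotypes); full-survey networks of hundreds of clones are
  deliberately not built by default (`build_network = FALSE` in the
  comparison stage disables them).
* Cross-marker mapping requires shared specimens; sequence-level mapping
  across markers is undefined by design.
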