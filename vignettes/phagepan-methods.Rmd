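---
title: "Pan-genome and phylogenomic analysis of phage genomes: methods"
author: "phagepan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pan-genome and phylogenomic analysis of phage genomes: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phagepan)
```

## The problem

Marine cyanopodoviruses (T7-like phages of *Prochlorococcus* and
*Synechococcus*) have small (~42–48 kb), highly syntenic genomes of roughly
50–70 genes. Comparative questions about such a collection are naturally
phrased in terms of *clustered orthologous groups* (COGs): which gene
families are **core** (present in every genome), **accessory** (in some but
not all), or **unique** (one genome only); how the pan- and core-genome
sizes grow or shrink as genomes are sampled; whether whole-genome
phylogenies built from concatenated core genes agree with dendrograms built
from gene content alone; and whether individual core genes tell conflicting
phylogenetic stories (a signature of recombination or horizontal exchange).

`phagepan` implements that entire workflow — alignment, orthology,
rarefaction, tree building, and tree comparison — together with a synthetic
genome generator that plants a known answer for every stage, so the whole
pipeline is testable end to end without any downloads.

## Orthology model

Genes are compared by exact optimal local alignment (Smith–Waterman,
BLOSUM62, affine gaps with open 11 and extension 1, so a gap of length
$k$ costs $11 + k$). Raw scores $S$ are converted to bit scores with fixed
gapped Karlin–Altschul constants,

$$S' = \frac{\lambda S - \ln K}{\ln 2}, \qquad
  \lambda = 0.267,\; K = 0.041,$$

and e-values use the pairwise search space $E = mn\,2^{-S'}$, where $m$ and
$n$ are the two sequence lengths. Using the pairwise space rather than a
database-wide effective length makes the e-values exactly reproducible: no
database model is involved. They are therefore close to, but not identical
with, what a database search tool would print; all downstream thresholds
were verified robust to this choice on simulated data.

Two genes are called **orthologous** when hits exist in *both* directions
and both satisfy

* e-value ≤ 1e-5, and
* alignment length ≥ 50% of the shorter sequence;

for pairs whose shorter sequence is under 100 aa the e-value condition is
replaced by percent identity ≥ 35% (the coverage condition always stands —
the identity exception exists because short sequences cannot reach small
e-values, not because coverage stops mattering). We read "reciprocal hits"
literally — hits in both directions each meeting the cutoffs — rather than
as reciprocal *best* hits; the stricter best-hit mode is available via
`build_ortholog_graph(..., reciprocal_best = TRUE)` since the two readings
can differ on paralog-rich inputs.

COGs are the connected components of the resulting ortholog graph
(single-linkage closure). Components are the simplest clustering consistent
with transitive group membership and with the profile-merge step below;
within-genome paralogs may co-cluster, and are counted once per genome when
genome counts are formed. `merge_by_profile_hits()` merges COGs linked by
externally computed profile-search hits at e ≤ 1e-5, as connected components
of the merge relation, so the result is independent of hit order.

### Word-seeded pruning

`all_vs_all()` scores every candidate pair exactly, but by default restricts
candidates to pairs sharing exact 4-residue words (two shared words when
both sequences are ≥ 200 aa). Like any word-seeded search this trades a tiny
amount of sensitivity far beyond the twilight zone (~55%+ divergence, where
practical e-value cutoffs would rarely accept a pair anyway) for a several-
fold speed-up; `prefilter = FALSE` restores the exhaustive behaviour, and
the unit tests verify the two agree on hit sets in the divergence regime the
orthology rule operates in.

## Pan-genome quantities

* `classify_cogs()`: core ⇔ present in all $N$ genomes, unique ⇔ present in
  one, accessory otherwise.
* `accumulation_curves()`: for each random permutation of genome order, the
  running union (pan) and intersection (core) sizes at every prefix length;
  the band is the 2.5/97.5 percentile interval across permutations (default
  1000, seeded). Percentile bands are distribution-free and reproducible;
  nothing stronger is claimed for them. An `exhaustive = TRUE` mode
  enumerates all $n!$ orders for $n \le 8$ and is what the tests compare
  against brute-force subset enumeration.
* `genome_fractions()`: per-genome core/accessory/unique fractions by gene
  count, plus the fraction of the genome *length* covered by core genes.
* `pairwise_shared_fraction()`: shared gene families between two genomes
  divided by the mean of their family counts. The mean denominator is
  symmetric and bounded; a Jaccard (union) denominator is available as a
  switch because the choice is not canonical, and analyses of the
  identity–shared-fraction relationship should state which one they used.

## Phylogenomics

Per-COG protein alignments come from a progressive aligner: a UPGMA guide
tree on shared 3-mer distances, then profile–profile global alignment with
affine gaps (BLOSUM62, 11/1), where a column pair scores the average
substitution score over residue pairs and gap–residue pairs score zero.
This is deterministic, dependency-free Clustal-class behaviour — adequate
for the point-substitution divergences this package targets, and *not* a
replacement for a modern aligner on indel-rich data.

Alignments are trimmed before distance computation (`trim_blocks()`):
columns with more than 50% gaps or with modal-residue frequency below 50%
are dropped, then surviving runs shorter than 5 columns are dropped. The
retained column indices are recorded so trimming is auditable.

Distances are p-distances over columns where neither sequence is gapped,
optionally Poisson-corrected ($d = -\ln(1-p)$). Trees are built by
neighbor joining (`ape::nj`, negative estimates clamped to zero — the usual
convention, which keeps RF comparisons meaningful while admitting that a
clamped edge length is not an evolutionary estimate) or by UPGMA/WPGMA
(phangorn). Distance trees stand in for the likelihood machinery a
full-scale analysis would use; the quantities this package asserts —
cluster recovery, topological distances — are robust to that substitution,
and branch-length fidelity is deliberately not asserted anywhere.

`bootstrap_tree()` resamples alignment columns with replacement (default
1000 replicates for a concatenated-core tree, seeded), rebuilds the tree
per replicate, and labels each internal edge of the point tree with the
percentage of replicates containing the same bipartition.

## Tree comparison

Bipartitions are stored canonically (the side containing the lexically
smallest leaf, sorted). `robinson_foulds()` is the size of the symmetric
difference of the two nontrivial split sets — the plain unnormalised
symmetric difference, because that is the classical definition and because
every tree here shares one leaf set. `consensus_extended_majority()`
implements the extended majority rule: all splits above 50% frequency, then
remaining splits greedily by descending frequency (ties broken by the
canonical split key, so the result is deterministic rather than
input-order-dependent) when compatible with what is already accepted.

`nmds()` wraps `vegan::monoMDS` (Kruskal stress-1, global model) with a
classical-scaling start plus seeded random restarts (default 20, best
configuration kept, centred). `gene_content_distance()` offers Jaccard
distance on presence/absence rows and the two-state CFN maximum-likelihood
correction $d = -\tfrac12 \ln(1 - 2p)$; the source analysis named only an
"ML distance" on gene content, so both are provided and the cluster
topology — the assertion that matters — agrees between them on the planted
simulations. Saturated CFN pairs ($p \ge 0.5$) are capped at the largest
finite distance with a warning rather than silently dropped. Accessory-gene
presence/absence heat-map dendrograms cluster phages by WPGMA and genes by
UPGMA (`content_dendrograms()`).

## The synthetic genome generator

`simulate_genome_set()` plants, by construction, everything the pipeline is
later asked to recover. Defaults (all tunable via `sim_config()`):

* **20 genomes** in two clusters of 5 and 15; the large cluster contains
  four subclusters (5, 5, 3, 2), mirroring the cluster/subcluster
  architecture typical of marine cyanopodovirus collections.
* **15 core families** present in all genomes; core genes are drawn longer
  (log-normal, median ~450 codons) than accessory/unique genes (median ~150
  codons), so core genes occupy a disproportionate share of genome length
  — matching the field observation that core genes are the long structural
  and replication genes. With ~45 genes per genome the defaults put the
  core at roughly 28% of gene count and 45–50% of genome length.
* **Accessory blocks** shared by each cluster, each subcluster, and two
  subcluster pairs (61 accessory families), plus **12 unique genes** per
  genome — 316 families in total.
* An ultrametric genome tree with node heights 0.04 (within subcluster),
  0.10 (subcluster joins), 0.225 (root), in expected substitutions per
  site, i.e. maximum pairwise divergence ~0.45 before multiple-hit
  saturation. Proteins evolve by i.i.d. per-site substitution along each
  branch with replacement drawn from a fixed amino-acid background
  (`mutate_protein()`); there is no rate matrix and no indel process,
  because the acceptance surface is clustering and tree recovery, not
  substitution-model realism. The initiator residue is held fixed so every
  gene remains a valid ORF.
* **5 of the 15 core families evolve on an alternative guide tree** (the
  genome tree with leaf labels permuted), planting the phylogenetic
  incongruence that the tree-space NMDS analysis is meant to expose.
* **Two G+C regimes** (targets 0.39 and 0.50) split 11/9 across genomes and
  aligned with the cluster structure, emulating the low-G+C
  *Prochlorococcus*-phage vs high-G+C *Synechococcus*-phage contrast.
  Back-translation steers third-codon-position composition toward the
  target (solving the steering probability per gene in closed form), which
  lands realized genome G+C within ±2 percentage points of target. Genome
  lengths are drawn uniformly in 42.3–47.7 kb and padded with intergenic
  spacers at the genome's target composition.
* Shared families are laid out in a common order across genomes with
  unique genes inserted at random positions, emulating synteny. Output is
  byte-identical for a fixed seed.

What the simulator does **not** emulate: indels and alignment ambiguity,
rate heterogeneity across sites, gene gain/loss along the tree (the
presence/absence pattern is set combinatorially so that ground-truth
categories are exact), recombination breakpoints within genes, and
GenBank-grade annotation noise. Passing the planted-recovery tests
therefore demonstrates the pipeline's internal correctness and its
behaviour under clean divergence, not its robustness to every artefact of
real sequence data.

## Numerical and design choices

* E-value constants are fixed rather than estimated; exact agreement with
  any particular search tool's e-values is not promised (and not needed —
  thresholds are applied to our own e-values consistently).
* The ORF caller (`find_orfs()`) is a minimal six-frame stop-to-stop
  scanner (starts ATG/GTG/TTG, stops TAA/TAG/TGA, default minimum 30
  codons, longest ORF per stop-to-stop region, linear genomes). On real
  genomes it will not reproduce a trained gene finder's calls gene for
  gene; on this package's simulations the planted coordinates are used
  directly, and the caller is validated against its own contract.
* Welch's unequal-variance t-test is used for group comparisons (the safer
  default when group variances differ, as they do for the two host-group
  G+C samples); with those samples Student's variant reaches the same
  qualitative conclusion.
* NMDS uses 20 restarts, ≤ 500 iterations, and vegan's convergence
  criteria; the planar-recovery tests require final stress < 1e-3.
* Deterministic tie-breaks throughout: COG ids ordered by smallest member
  gene id, consensus ties by canonical split key, alignment traceback
  prefers diagonal over gaps.

## Problem sizes used by the tests

The test suite and acceptance script run entirely on synthetic data at the
default study conditions: 20 genomes, ~45 genes each (~900 proteins,
~400k candidate pairs per run). The planted-recovery property is evaluated
over 20 simulation seeds (clustering ARI and cluster-clade recovery) and 10
seeds for the tree-space NMDS outlier property; NJ exactness uses 100
random additive matrices; RF and consensus oracles use trees of up to 8
leaves, where exhaustive enumeration is comfortable. Tree-recovery
properties are evaluated on the planted per-family alignments (the
generator plants point substitutions only, so family members are
positionally aligned by construction); the progressive aligner has its own
oracle tests. These sizes are the package's own choices for a thorough
desk-scale validation.

## Known limitations

* The aligner and caller are deliberately minimal surrogates (see above).
* E-values are pairwise-space values, not database-corrected.
* Single-linkage clustering can chain families together through one chance
  significant pair; at the default study conditions this occurs in a
  minority of seeds and costs a small amount of partition agreement (the
  recovery tests bound it), but on real data with promiscuous domains a
  score-weighted clustering would be more robust.
* The published 20-genome census (349 COGs: 15 core, 99 accessory, 235
  unique) can only be recomputed after downloading the GenBank genomes;
  `published_cog_census()` runs that analysis, under both orthology
  readings, given a directory of genome FASTA files.
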