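---
title: "Modularity and node roles in host-microbiome bipartite networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modularity and node roles in host-microbiome bipartite networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spongenet)
```

## The scientific problem

Marine sponges filter enormous volumes of seawater and host dense microbial
communities, with some species (high-microbial-abundance, HMA) carrying far
richer microbiomes than others (low-microbial-abundance, LMA). When many
host species are surveyed with 16S rRNA amplicon sequencing, the data form a
bipartite occurrence network: host species on one side, microbial OTUs on
the other, with a link wherever an OTU was detected in at least one sample
of a species. The questions this package addresses are structural: does the
network decompose into modules of hosts that share microbes; are those
modules driven by environment (temperature), host type (HMA/LMA) or
microbial evolutionary history; which hosts and microbes act as hubs or
connectors; and do modules differ in the metabolic functions their
microbiomes are predicted to encode?

The package provides the full analysis chain as composable functions, plus
a synthetic-data generator with planted structure so every stage can be
validated without downloading a survey dataset.

## The model and its statistics

### Bipartite modularity

For an unweighted bipartite network with incidence indicator $A_{ij}$
(host $i$, OTU $j$), $m$ links, host degrees $k_i$ and OTU degrees $d_j$,
Barber's modularity of a partition $g$ is

$$Q = \frac{1}{m}\sum_{i,j}\left(A_{ij} - \frac{k_i d_j}{m}\right)
\delta(g_i, g_j).$$

Summing each host-OTU pair once with weight $1/m$ is algebraically
identical to summing both orientations of the symmetric adjacency matrix
with weight $1/(2m)$; `barber_Q()` implements the single-orientation form
and the equivalence is unit-tested against a brute-force double loop.
$Q = 0$ for any partition of a network indistinguishable from its degree
null model (e.g. a complete bipartite graph) and approaches $1 - 1/k$ for
$k$ equal disconnected blocks under the block partition.

`find_modules()` maximises $Q$ with a label-propagation strategy in the
spirit of LPAwb+: hosts start with unique labels, each node repeatedly
adopts the neighbouring-module label with the largest $Q$ gain (sweep order
shuffled each pass, equal-gain ties broken uniformly at random from the
seeded stream), the two node classes alternate until no single-node move
improves $Q$, and an agglomeration phase then tests module-pair merges.
Merges with zero gain are accepted so that among equal-$Q$ partitions the
one with fewer modules is preferred; merges across disconnected components
always have negative gain and can never occur. Propagation and
agglomeration alternate until neither improves $Q$. The best of
`n_restarts` (default 20) independent restarts wins; restart ties prefer
fewer modules, then the lexicographically smallest canonical labelling.
Everything is deterministic given `seed`.

Because a degree-one OTU is always optimally placed in its sole partner's
module, `prune_degree_one()` removes such OTUs before the search and
`reattach_pruned()` restores them afterwards; this changes the absolute
$Q$ but not how the remaining nodes partition.

### Node roles

Connectivity profiles follow the Guimerà-Amaral measures. The
within-module degree z-score is
$z_i = (k_i^{in} - \overline{k^{in}})/\sigma_{k^{in}}$
with mean and *population* standard deviation taken over the node's
normalisation group inside its module; the participation coefficient is
$P_i = 1 - \sum_s (k_{is}/k_i)^2$, i.e. one minus the Herfindahl
concentration of a node's links over modules. A provincial hub is a node
with $z > 2.5$ and $P < 0.3$, both strict.

Two normalisation groups for $z$ are exposed because the definition is
ambiguous for bipartite graphs, where degree scales differ by class:
`"same-class"` (default; hosts are compared with hosts of their module,
OTUs with OTUs) and `"all-nodes"` (the literal all-members reading).
Groups with $\sigma = 0$ map to $z = 0$ — the score is undefined there and
zero states "indistinguishable from the module mean". Single-member groups
degenerate to $z = 0$ the same way.

### Phylogenetic signal

Unweighted UniFrac between two tip communities is the fraction of branch
length (on the tree pruned to the union) leading exclusively to one
community. `unifrac_permutation_test()` scores every module pair and
obtains significance by shuffling tip-to-module labels with module sizes
held fixed; $p = (1 + \#\{\text{null} \ge \text{obs}\})/(1 + n_{perm})$,
so $p$ is never zero and the floor $1/(n_{perm}+1)$ is attainable. Modules
with fewer than two tips are skipped with a warning. The single-number
"overall" statistic is defined here as the mean of pairwise scores
weighted by each pair's pooled branch length; published single-number
UniFrac scores do not document their aggregation, so this is a package
choice, not a claim of equivalence.

Host-phylogeny comparisons use cophenetic (path-length) distances from the
supplied tree via `cophenetic_distances()` and a one-sided Mantel test.
Working from tree distances rather than sequence-based maximum-likelihood
distances preserves the structure of the test while keeping alignments out
of scope: trees are consumed, never inferred.

### Community statistics

`permanova()` implements the one-factor distance-based pseudo-F:
$SS_T = \frac{1}{n}\sum_{i<j} d_{ij}^2$, within-group sums weighted by
$1/n_g$, $F = (SS_A/(a-1))/(SS_W/(n-a))$, with free label permutation and
the same never-zero $p$ estimator. On Euclidean distances of 1-D points it
reproduces the classical ANOVA F exactly (unit-tested), and it agrees with
vegan's `adonis2` on random community matrices — vegan serves as an
independent cross-check there, never as the implementation. Pairwise
comparisons are corrected with Benjamini-Yekutieli by default (valid under
arbitrary dependence; Benjamini-Hochberg optional). Only the one-factor
design is implemented: every grouping used here (module, host type) is a
single factor.

Dispersion homogeneity (`beta_dispersion()`) wraps vegan's `betadisper`
with centroid-type distances; Bray-Curtis dissimilarity wraps `vegdist`;
rarefaction wraps `rrarefy`. The Nemenyi all-pairs rank test (studentized
range on mean ranks with tie-corrected variance; all-tie pairs give
$p = 1$) and the indicator analysis are implemented in the package. The
indicator statistic r.g is the point-biserial correlation between a
feature and a group indicator with samples weighted $1/n_{g(i)}$ so that
unequal groups contribute equally; permutation p-values are one-sided and
BH-adjusted across the feature-by-group family. Constant features are
flagged with r.g = 0, p = 1.

### Predicted functions

`predict_metagenome()` aggregates per-reference functional profiles in the
style of 16S-based metagenome prediction: each mapped OTU contributes
abundance times its reference profile divided by the reference's 16S copy
number; unit profiles are normalised to sum to one; the fraction of
taxonomic units unexplained (FTU) is the abundance mass of unmapped OTUs.
The OTU-to-reference mapping (in practice a 97%-identity alignment
product) is an input table — reference-database construction is out of
scope. The prediction is invariant to rescaling a unit's abundances, and
removing an unmapped OTU changes only FTU, never the profile. The log2
transform for function tables defaults to a pseudocount of $10^{-6}$,
appropriate for sum-to-1 profiles; the choice is configurable because no
convention exists for zero handling.

## Filtering rules and their edge conventions

* **Sample selection** keeps sponge samples from healthy adults with
  unequivocal taxonomy and strictly more than $10^4$ reads, from species
  retaining at least 3 qualifying samples. Strict inequalities are used
  everywhere a threshold is phrased as "larger than".
* **Seawater filter**: an OTU is removed from all sponge samples iff its
  relative abundance in the *pooled* seawater reads strictly exceeds
  0.01%. Pooling treats the threshold as a dataset-level property and is
  robust to uneven seawater depths; a per-sample-mean mode is available by
  flag. An OTU at exactly 0.01% is retained.
* **Core microbiome**: an OTU is core for a species iff present in at
  least $\lceil \tfrac{2}{3} n \rceil$ of its $n$ samples ("at least
  two-thirds" is a lower bound, so fractional counts round up) and its
  mean relative abundance strictly exceeds 0.01%. Two abundance scopes are
  implemented — per-species (default) and whole-dataset — because both
  phrasings appear in the literature this follows; neither is privileged.
  Presence for the prevalence count is any non-zero count.
* **Rarefaction** subsamples each sample without replacement to exactly
  $10^4$ reads (samples below depth are an error — selection is expected
  to have run first). `rarefaction_robustness()` repeats rarefaction with
  independent substreams and summarises pairwise PERMANOVA by module
  across replicates.

All filters are idempotent, and every `filter_report` reconciles
(`items_in - removed = items_out`) by construction.

## What the synthetic generator emulates

`synthetic_config()` plants: module-structured occurrence (`p_within` vs
`p_between`), lognormal(0, 1) OTU abundance weights with multinomial read
sampling (the fat-tailed profile of real 16S tables, in two parameters),
per-module Normal temperature distributions, per-module HMA probabilities,
an OTU tree in which modules are exact clades, an independent host tree
(reflecting the absence of host-phylogeny signal in the system this
models; coupling can be added for power studies), seawater samples with
designated contaminant OTUs pinned above the 0.01% pooled threshold, and
per-module enriched function blocks.

Defaults define the study conditions: 3 modules of 10 host species and 50
OTUs each, 3 samples per host, 20 000 reads per sample (above the strict
$10^4$ selection threshold, so rarefaction to $10^4$ is meaningful),
`p_within = 0.9`, `p_between = 0.01`, temperatures 27/19/11 degrees C with sd 3
(a warm-to-cold spread typical of shallow marine surveys), HMA fractions
(0.8, 0.2, 0.2) echoing one HMA-dominated module, 5 seawater samples with
5% contaminants, 60 functions with 4-fold block enrichment. One master
seed drives a fixed hierarchy of per-component substreams, so adding a
component never perturbs earlier draws and equal seeds give bit-identical
output.

Present OTUs are guaranteed at least one read before multinomial
allocation, so "present with probability p" is observable in counts; this
slightly deforms the multinomial but keeps the occurrence contract exact.
The generator does **not** emulate sequencing error, chimeras, sample
cross-contamination beyond the seawater rule, compositional artefacts,
overdispersed per-sample depths, or geography. Passing tests therefore
demonstrate correctness of the computations and recoverability of planted
structure — not robustness to every artefact of real amplicon data.

## Numerical choices

* Permutation p-values use $(1 + \text{exceedances})/(1 + n_{perm})$
  everywhere, so $p > 0$ always and "p < 0.001" is representable at 999
  permutations.
* Modularity ties (equal-gain moves, equal-Q restarts) are resolved by
  seeded uniform choice, then fewest modules, then lexicographic labels;
  results are exactly reproducible under a fixed seed.
* $\sigma = 0$ z-scores map to 0; all-zero distance matrices embed to zero
  eigenvalues; PCoA reports negative eigenvalues rather than hiding them.
* Module ids are dense integers starting at 1, relabelled canonically by
  first appearance.
* OTU tables must state their orientation explicitly on read; silent
  transposition is the classic microbiome-pipeline failure mode.
  Identifiers are opaque, case-sensitive, trimmed of surrounding
  whitespace only.

## Problem sizes used in the test-suite

The acceptance checks enumerate all set partitions of networks up to 10
nodes (exhaustive optimum), evaluate the brute-force double-loop Q on 200
random networks up to 12 nodes, run 20-seed planted-recovery experiments
at 3 modules by 10 hosts by 50 OTUs, and calibrate permutation tests with
200-300 replicates of 99 permutations. These sizes were chosen so the
whole suite completes in well under a minute per file while keeping
binomial tolerances tight enough to detect calibration errors.

## Known limitations

* Only the one-factor PERMANOVA design is implemented; nested or
  multi-factor designs need a different tool.
* The label-propagation optimiser is a heuristic; optimality is proven
  only where enumeration is feasible, and large networks inherit the
  usual local-optimum caveats (mitigated by restarts and agglomeration).
* The overall UniFrac aggregation is a documented package choice (see
  above); pairwise scores are the primitive quantity.
* Indicator analysis reports the full feature-by-group grid rather than
  assigning each feature its best group combination; site-combination
  indicators (IndVal over group unions) are not implemented.
* Weighted bipartite modularity, nestedness and NMDS/dbRDA ordinations
  are out of scope.
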