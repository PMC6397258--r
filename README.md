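# spongenet

Modularity, node roles and functional differentiation in host–microbiome
bipartite networks.

## What it is for

Large 16S rRNA surveys of marine sponges (and other hosts) yield OTU count
tables spanning many host species. Linking each host species to every OTU
detected in at least one of its samples gives a bipartite occurrence
network, and the interesting biology lives in its structure: modules of
hosts that share microbes, the environmental or evolutionary drivers of
those modules, the hub/connector roles of individual hosts and microbes,
and whether modules differ in the metabolic functions their microbiomes are
predicted to encode.

`spongenet` implements that analysis chain for microbial ecologists:

* **Filtering** — sample-selection rules (healthy adults, unequivocal
  taxonomy, > 10⁴ reads, ≥ 3 samples per species), removal of OTUs above
  0.01% pooled relative abundance in seawater controls, prevalence–abundance
  core-microbiome flags, and seeded rarefaction with a robustness summary.
* **Bipartite modularity** — Barber's Q,

  Q = (1/m) Σᵢⱼ (Aᵢⱼ − kᵢdⱼ/m) δ(gᵢ, gⱼ),

  maximised by an LPAwb+-style label-propagation search with restarts and
  an agglomeration phase; degree-one OTUs are pruned and reattached.
* **Node roles** — within-module degree z (population-SD convention),
  participation coefficient P = 1 − Σₛ(kᵢₛ/kᵢ)², and role classes with
  provincial hubs at z > 2.5, P < 0.3 (strict).
* **Phylogenetic signal** — unweighted UniFrac between module tip sets with
  label-permutation significance; cophenetic distances; Mantel tests.
* **Community statistics** — Bray–Curtis, one-factor PERMANOVA from the
  distance sums-of-squares partition, pairwise comparisons with
  Benjamini–Yekutieli/Hochberg correction, dispersion homogeneity, PCoA,
  two-sample KS, Nemenyi rank comparisons, and group-equalised indicator
  (r.g) analysis.
* **Predicted functions** — Tax4Fun2-style aggregation of per-reference KO
  profiles normalised by 16S copy number, sum-to-1 profiles and the
  fraction of taxonomic units unexplained (FTU).
* **Synthetic data** — a generator that plants modules in occurrence,
  temperature, host type, OTU phylogeny and function blocks, so the whole
  pipeline is testable end to end with no external data.

See the vignette in `vignettes/` for the models, conventions and design
choices in detail.

## Worked example

```r
library(spongenet)

cfg <- synthetic_config(seed = 42)      # 3 planted modules, 30 hosts, 150 OTUs
ds  <- generate_dataset(cfg)
sw  <- generate_seawater(cfg, ds$table, ds$meta)

cleaned <- remove_seawater_otus(sw$table, sw$meta)
cleaned$report
#> filter_report [remove_seawater_otus]: 150 -> 143 (7 removed)
sel <- select_samples(cleaned$table, sw$meta)

net <- build_network(sel$table, sw$meta)
net
#> bipartite_network: 30 hosts, 143 OTUs, 1510 links

pr   <- prune_degree_one(net)
part <- find_modules(pr$net, n_restarts = 20, seed = 1)
full <- reattach_pruned(part, pr$pruned, net = net)
full
#> module_partition: 3 modules over 173 nodes; Q = 0.613478
nmi(full$membership, ds$truth$membership)
#> [1] 1

module_summary(full, traits = ds$traits, meta = ds$meta)
#>   module_id n_hosts n_otus n_hma n_lma pct_hma temp_mean  temp_sd
#> 1         1      10     48     5     5      50  26.99772 3.106300
#> 2         2      10     46     0    10       0  18.22953 3.225286
#> 3         3      10     49     2     8      20  10.33871 2.605157

unifrac_permutation_test(ds$otu_tree, full, n_perm = 199, seed = 2)
#>   pair unifrac_score p_value n_permutations
#> 1  1-2             1   0.005            199
#> 2  1-3             1   0.005            199
#> 3  2-3             1   0.005            199
```

Reading the output: the seawater filter removed exactly the 7 designated
contaminant OTUs; the modularity search found the 3 planted modules
(normalised mutual information 1 with the ground truth) at Q ≈ 0.61; module
temperature means recover the configured 27/19/11 °C; and every module pair
sits at the UniFrac permutation floor p = 1/(199+1) = 0.005 because modules
are exact clades on the generated OTU tree.

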