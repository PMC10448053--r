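# oceanet

Downstream ecological inference for habitat-contrast microbiome surveys
— e.g. marine **sediment vs seawater** bacterial communities profiled by
16S rRNA amplicons. Starting from an OTU count table, sample metadata, a
taxonomy, an annotation flagging sulfate-reducing bacteria (SRB, or any
other keystone candidate set), and a phylogenetic tree, the package
answers three questions:

1. **How do the communities assemble?** Alpha diversity, Bray–Curtis
   PCoA and ANOSIM, SES.MNTD phylogenetic clustering, and a fit of the
   Sloan neutral community model — the occupancy curve
   `F(p) = 1 − I_d(Nmp, Nm(1−p))` with migration rate *m*, community
   size *N* and detection limit *d* — partitioned by a 95% Wilson band
   into neutrally vs deterministically assembled taxa and compared
   against a parameter-free binomial sampling model by bootstrap AIC.
2. **Who is in the core, and who holds the network together?**
   Abundance–occupancy core selection scored by cumulative contribution
   to Bray–Curtis beta diversity; per-habitat co-occurrence networks
   from Spearman correlations at |ρ| > 0.6 and BH-adjusted q < 0.01,
   with global (density, mean degree, clustering, path length, Louvain
   modularity, diameter) and node-level (degree, betweenness, closeness,
   eigenvector) topology, and Wilcoxon comparisons of SRB vs other
   nodes.
3. **What happens when the keystones go?** A seeded removal experiment
   deletes growing proportions of the SRB set vs size-matched random
   controls (50 repetitions per proportion) and scores each reduced
   network by **natural connectivity**
   `λ̄ = ln((1/N) Σ exp(λ_i))`, the fraction of nodes retaining an
   edge, and average degree, summarised by OLS decay slopes.

Seeded synthetic generators (neutral communities with known *m*,
block/hub-structured correlation tables with a known keystone set,
pure-birth phylogenies) make the whole pipeline testable without any
sequence data.

## Worked example

Simulate a community whose correlation structure contains known hub
(SRB-labelled) taxa, then run the main stages:

```r
library(oceanet)

sim <- simulate_structured_table(150, 60, 1500, rho_block = 0.9, seed = 42)
ot  <- rarefy(sim$table, seed = 1)
ot
#> <otu_table> 150 taxa x 60 samples; groups: sim

fit <- fit_neutral_model(to_relative(ot))
fit
#> <neutral_fit> m = 0.1681  R2 = 0.7921  N = 1500  d = 0.0006667
#>   partition: neutral 62, above 36, below 52  ratio = 0.7045
#>   AIC neutral = -630.85  binomial = -469.39
```

The fitted migration rate and R² describe how well pure
drift-plus-immigration explains the occupancy–abundance cloud; the
partition counts taxa inside/above/below the 95% band, and `ratio` is
the stochastic:deterministic balance (here < 1 — most taxa deviate from
neutrality, as expected for a strongly structured community). The
neutral model's lower AIC means it beats plain random sampling.

```r
net <- cooccurrence_network(ot, annotations = sim$annotations)
net
#> <cooccurrence_network> 141 nodes (103 connected), 317 edges; |rho| > 0.6, q < 0.01

compare_srb_topology(net)
#> # A tibble: 4 × 5
#>   metric      median_srb median_other statistic  p_value
#> 1 degree          12            4          514. 0.00257
#> 2 betweenness      9.88         0          524. 0.000691
#> 3 closeness        0.935        0.714      405  0.0992
#> 4 eigenvector      0            0          319  0.316

rob <- remove_nodes(net, repetitions = 50, seed = 7)
rob
#> <robustness_trajectory> 4 SRB of 141 nodes; slopes of natural connectivity:
#>  scheme      slope
#>   other -0.2133636
#>     srb -1.2244829
```

The planted hubs are recovered as high-degree, high-betweenness nodes,
and removing them degrades natural connectivity about six times faster
than removing random nodes — the keystone signature. `autoplot()` draws
each result type; `tidy()`/`glance()` return per-item and one-row
summaries; `run_pipeline(pipeline_config(...))` chains every stage per
habitat with full provenance and byte-identical reruns under one seed.

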