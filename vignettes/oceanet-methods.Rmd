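---
title: "Community assembly, co-occurrence networks and keystone robustness with oceanet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Community assembly, co-occurrence networks and keystone robustness with oceanet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oceanet)
```

oceanet implements the downstream inference layer of a habitat-contrast
amplicon survey — the kind of study that asks whether, say, marine
sediment and seawater bacterial communities differ in diversity, in how
they assemble, and in which taxa hold their co-occurrence networks
together. The package starts from an OTU count table and ends at a
keystone-taxon robustness verdict; everything upstream (read processing,
OTU clustering, taxonomy assignment, functional prediction) is out of
scope and enters only through plain input tables.

This vignette explains each model, its assumptions, the tunable
parameters and their defaults, the synthetic-data generators used for
validation, and the numerical choices made where conventions diverge.

## Input handling and rarefaction

The universal input is an `otu_table`: a non-negative integer count
matrix (taxa x samples) plus a sample-to-habitat map. Uneven sequencing
depth is removed by rarefaction — seeded subsampling without replacement
(multivariate hypergeometric, via `vegan::rrarefy`) down to a common
depth, by default the *median* of the per-sample totals. For an even
number of samples we take the lower of the two middle values, so the
depth is always an achievable integer read count. Samples below the
depth are dropped with a warning; taxa left with all-zero rows are
dropped everywhere downstream, because a taxon that is never observed
has no defined occupancy.

For network construction, taxa whose relative abundance across all
samples does not exceed 0.01% are removed first: low-abundance taxa
with very few non-zero observations produce spurious rank correlations.
"Relative abundance across all samples" admits two readings — the mean
per-sample fraction, or the raw sum of per-sample fractions — and both
appear in the literature. The default is the mean (`filter.mode =
"mean"`), which is invariant to the number of samples; the literal sum
is available as `mode = "sum"`. The filter is applied after
rarefaction, per habitat.

## Alpha and beta diversity

Richness is the count of detected taxa; Shannon diversity uses the
natural logarithm (the Shannon–Wiener convention of the ecology
packages this field uses; `log_base` is exposed); Pielou evenness is
H/ln(S), undefined for fewer than two taxa. Beta diversity uses
Bray–Curtis dissimilarity, ordinated by classical PCoA
(double-centring, eigendecomposition). Bray–Curtis matrices are
generally not Euclidean-embeddable, so some eigenvalues are negative;
they are reported as-is rather than corrected (no Cailliez/Lingoes
adjustment), since downstream use is visual ordination on the leading
axes.

Group separation is tested with ANOSIM: with all M = n(n-1)/2 pairwise
distances ranked, R = (mean between-group rank − mean within-group
rank)/(M/2), which lies in [−1, 1]. Significance comes from label
permutations (999 by default); when the number of *distinct* label
arrangements is at most 10,000 the test enumerates them all and the
p-value is exact. The permutation p-value uses the standard
add-one-to-both-counts estimator so it can never be zero.

Phylogenetic clustering is measured per sample by SES.MNTD: the
standardised effect size of the mean nearest-taxon distance against a
tip-label-shuffling null ("taxa.labels", 999 randomisations by
default), computed by `picante::ses.mntd`. Negative values mean the
taxa present in a sample sit closer together on the tree than chance
predicts. Abundance weighting is off by default. Saturated communities
(all tips present) and one-taxon samples are flagged undefined rather
than reported as zero, since the null distribution is degenerate there.

## The neutral assembly model

The Sloan neutral community model predicts how often a taxon should be
observed across local communities purely from drift and immigration.
For a taxon with metacommunity mean relative abundance $p$, its local
relative abundance at stationarity is Beta-distributed with shapes
$(N m p,\; N m (1-p))$, where $N$ is the local community size (reads
per sample) and $m$ the migration rate. The predicted occupancy is the
probability that this abundance exceeds the detection limit $d$:

$$\hat F(p) = 1 - I_d\big(N m p,\ N m (1-p)\big)$$

with $I_d$ the regularised incomplete Beta function. The package fits
$m$ by least squares of observed occupancies on this curve. Defaults,
all overridable: $N$ = mean post-rarefaction sample depth; $d$ = the
smallest observed non-zero relative abundance (≈ 1/depth), the standard
convention of the Sloan-fit lineage. The one-dimensional optimisation
runs a 61-point grid on $\log m \in [\log 10^{-6}, \log 10^{3}]$
followed by Brent refinement in the bracketing interval — effectively a
dense multi-start, immune to the local minima a single Newton start can
find.

Fit quality is the generalised $R^2 = 1 - SS_{res}/SS_{tot}$ about the
mean observed occupancy. A 95% Wilson score band with $n$ = number of
samples surrounds the fitted curve; taxa inside it are classed
`neutral`, those above `above` (more widespread than neutrality
predicts — positively selected or broadly dispersed), those below
`below`. The ratio of stochastically to deterministically assembled
taxa is defined here as (#inside)/(#outside the band). This definition
is a package decision: the ratio is often quoted in the literature
without a formula, and band membership is its most common reading.

The competitor is a binomial pure-sampling model with no free
parameter: occupancy if local communities were plain multinomial draws
of the source, $1 - \mathrm{BinomCDF}(\lceil Nd \rceil - 1;\, N, p)$.
Both models are scored with a Gaussian-residual AIC,
$n \ln(SS/n) + 2k$ ($k = 1$ for the neutral model's $m$, $k = 0$ for
the binomial), over 1,000 bootstrap resamples of taxa by default. The
likelihood behind this AIC is a package decision (the residual form is
the natural choice for a least-squares fit) and is reported alongside
both distributions. *Lower* AIC indicates the better-supported model
throughout.

### What the neutral generator emulates — and a known estimator bias

`simulate_neutral_table()` is the generative inverse of the fit: a
log-normal source community (log-sd 2, a typically long-tailed
amplicon metacommunity; normalised), per-sample Beta draws with the
stationary shapes above, renormalisation across taxa, and a multinomial
read draw at fixed depth. This is the stationary approximation the
Sloan fit assumes, not a forward Hubbell/Moran simulation — which makes
parameter recovery a fair test of the estimator rather than of the
approximation.

One consequence is worth stating precisely. The fitted curve treats
detection as a step: present iff abundance $> d$. The generator — like
real sequencing — detects through reads: present iff at least one read,
so $P(\text{detect}) = 1 - E[(1-f)^N]$, a smoothed step whose
half-height sits near $0.7/N$ rather than $1/N$. Rare taxa are
therefore observed slightly more often than the step-detection curve
predicts, and the least-squares fit compensates by inflating
$\hat m$ — by roughly 20% at $m = 0.05$ up to 40% at $m = 0.5$ at depth
2,000 (when $Nm$ approaches the depth, the read-sampling layer is no
longer negligible against the Beta variance). With detection replaced
by a step the estimator recovers $m$ to within ~2%, so the bias lives
in the detection-model mismatch, not the optimiser. We keep the
canonical $d$ = minimum non-zero fraction convention because it is what
the field's fits use; users comparing habitats should rely on the
*relative* ordering of $\hat m$ and on the band partition, both of
which are insensitive to this bias.

## Abundance–occupancy core microbiome

Taxa are ranked by occupancy (descending), ties broken by mean relative
abundance, remaining ties by taxon id so the ranking is deterministic.
Each rank r is scored by the share of the Bray–Curtis numerator carried
by the top-r taxa, averaged over sample pairs:

$$c_r = \mathrm{mean}_{(j,k)}\ \frac{\sum_{i \le r} |x_{ij} - x_{ik}|}{\sum_i |x_{ij} - x_{ik}|}.$$

Fixing the denominator at the full-community numerator makes $c_r$
monotone with $c_{\text{last}} = 1$, so it reads as "how much of
between-sample dissimilarity the candidate core already explains". The
core is cut at the last rank whose step adds at least 2% relative gain
(`threshold = 0.02`, configurable): $r^\ast = 1 + \max\{r : (c_{r+1} -
c_r)/c_r \ge 0.02\}$. Identical sample pairs (zero numerator) are
skipped with a warning. The summary reports the core's share of taxa,
its mean per-sample share of reads (the "on average across samples"
reading, since pooled-read shares would weight deep samples more), and
SRB representation inside versus outside the core.

## Co-occurrence networks

Per habitat, pairwise Spearman correlations (average-rank,
tie-corrected) are computed across that habitat's samples over the
abundance-filtered taxa; p-values use the t approximation. Correlations
are computed on rarefied counts, which at equal depth are
rank-equivalent to relative abundances. Benjamini–Hochberg correction
is applied over all tested pairs of that network, and an edge requires
|rho| > 0.6 **and** q < 0.01 — both thresholds strict and recorded in
the result's metadata. Zero-variance taxa are dropped with a warning;
filtered taxa that gain no edge stay in the node set flagged
`isolated`, and summaries report both node counts, since conventions
differ on whether isolates belong to "the network".

Global metrics: density 2E/(N(N−1)); mean degree 2E/N; clustering
coefficient as the mean of local clustering coefficients with
degree-<2 nodes contributing 0; average path length and diameter over
connected pairs only; modularity by Louvain with a fixed seed (the
algorithm is tie-broken randomly, so seeding makes runs reproducible
bit-for-bit). Node metrics: degree; unnormalised shortest-path
betweenness; closeness within each node's component as
$(n_c - 1)/\sum d$ with singletons at 0; eigenvector centrality as the
leading eigenvector of the largest component's adjacency (dense
symmetric eigensolver — deterministic, unlike ARPACK iteration),
max-normalised to 1. Edge signs are kept as attributes but all topology
is computed on the simple unweighted, unsigned graph. Keystone
candidates (SRB-annotated nodes) are compared to all other nodes on the
four node metrics with two-sided Wilcoxon rank-sum tests.

### The structured generator

`simulate_structured_table()` provides networks with known answers. A
latent Gaussian factor model places taxa in blocks sharing a factor
(pairwise latent correlation `rho_block`), plus hub taxa, each the
centre of its own star: the hub loads at 0.97 on a private factor and
its satellites (three blocks' worth each, by default) at 0.85. The
factor construction is positive semi-definite by construction, so no
eigenvalue clipping is ever needed (a non-PSD request is impossible by
design rather than silently repaired). Latent Gaussians map through
their CDF onto log-normal abundances and then to multinomial reads.

Two calibration facts shaped the defaults. First, rank correlations
attenuate under count sampling — zeros tie, and ties shrink Spearman's
rho — so the hub-satellite loading was set high enough (latent r ≈
0.82) that hub edges survive the |rho| > 0.6 threshold while
satellite–satellite correlations (latent ≈ 0.72, attenuated further)
mostly do not: hubs end up with several times the median degree of
other nodes, a genuine keystone position. Second, structured taxa
(blocks, hubs, satellites) receive a higher log-abundance than noise
taxa, emulating the empirical pattern that network-forming and keystone
taxa come from the abundant fraction of a community — rare taxa could
not carry detectable rank correlations at realistic depth anyway.
Hubs are labelled SRB in the generated annotations, giving robustness
experiments a known keystone set. The returned ground truth lists all
taxon pairs with latent correlation ≥ 0.6, tagged `within_block` or
hub-related.

What these simulations do *not* emulate: compositional coupling beyond
the multinomial constraint, environmental gradients driving
correlations without interaction, or phylogenetic signal in the
correlation structure. A pass on synthetic recovery therefore shows
the inference machinery is correct at its operating point, not that
real edges are ecological interactions — the usual caveat of
correlation networks.

## Robustness under keystone removal

Network stability is scored by natural connectivity,

$$\bar\lambda = \ln\!\Big(\tfrac{1}{N}\sum_i e^{\lambda_i}\Big),$$

the log-mean exponential of the adjacency eigenvalues — a spectral
measure of the redundancy of closed walks that decreases monotonically
as edges are lost. It is computed with an overflow-safe log-sum-exp
over all kept nodes *including isolated ones* (the alternative,
largest-component-only, changes discontinuously when components split;
the full-node form is monotone and matches the measure's definition).

The removal experiment deletes a proportion f ∈ {0.1, …, 1.0} of the
SRB set (count = round(f · |SRB|), half away from zero), or the *same
count* of randomly chosen non-SRB nodes as the size-matched control,
with 50 repetitions per cell by default. Each (scheme, proportion,
repetition) cell derives its own child seed from the master seed, so
any slice of the experiment reproduces independently. Reported per
cell: natural connectivity; the fraction of original nodes still
holding at least one edge (against the *original* node count — the
only reading under which the quantity moves when removal counts are
matched); and average degree over kept nodes. Trajectories are
summarised by per-scheme OLS slopes of natural connectivity on
proportion, pooled over repetitions. Deterministic degree-ordered
attack and edge-removal protocols are out of scope; the measure
captures resistance, not recovery (resilience).

## Pipeline, determinism and problem sizes

`run_pipeline()` chains all stages per habitat from one
`pipeline_config()` and writes TSVs (floats at 6 significant digits), a
JSON manifest (package version, seeds, parameters, input checksums) and
a log. All randomness flows from the master seed through fixed child
seeds, so a rerun with the same config is byte-identical — this is
asserted in the test suite.

Validation problem sizes, chosen to exercise every statistical property
at full strength while keeping the suite quick: neutral recovery at 500
taxa x 200 samples x depth 2,000 across m ∈ {0.05, 0.1, 0.5} with 20
seeds each; network FDR and recovery at 150 taxa x 100 samples over 10
null seeds; robustness at 50 repetitions; the natural-connectivity
implementation is checked against an independent matrix-exponential
oracle on ~12,000 small graphs (every labelled graph on up to 5 nodes,
the complete ≤7-node atlas, and seeded random 8-node graphs) at 1e-10.

## Known limitations

- The Sloan fit's $\hat m$ carries the detection-smoothing bias
  described above; between-habitat comparisons are safe, absolute
  values at high $m$ are upper estimates.
- Spearman networks are blind to compositional effects; no
  SparCC/SPIEC-EASI-style correction is attempted.
- ANOSIM's exact mode enumerates distinct arrangements and is
  infeasible past ~10,000; beyond that, seeded permutation p-values
  apply.
- The core stopping rule depends on the 2% relative-gain threshold;
  report it with results, as core sizes are threshold-sensitive.
- BIOM input requires the optional `biomformat` package; TSV is the
  first-class format.
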