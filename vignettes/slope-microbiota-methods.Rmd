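---
title: "Methods: cross-kingdom microbiota networks, assembly processes, and slope multifunctionality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-kingdom microbiota networks, assembly processes, and slope multifunctionality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

`rhizonet` implements the quantitative machinery needed to relate the
diversity and signed biotic associations of root-associated microbiota
(heterotrophic bacteria, rhizobia profiled by the *rpoB* marker, and
arbuscular mycorrhizal — AM — fungi) to ecosystem multifunctionality along
an ordered hillslope gradient, and to ask which community-assembly
processes shaped those communities.  Because the motivating field data are
sequencing deposits rather than tables, the package ships a synthetic-data
generator with planted ground truth; every method is validated against
that truth or against independent oracles.  This vignette documents the
models, the parameters that matter, and the design decisions taken where
the methodology left choices open.

## Multifunctionality

Twelve ecosystem functions in four services are measured per plot:
microbially driven C pools (DOC, MBC), nutrient cycling (TDN, Olsen-P,
MBN, MBP), organic matter decomposition (BG, NAG, LAP, AP), and plant
production (leaf C, litter C).  Three facets are computed:

1. **Single functions** — per-function z-scores, `(x - mean)/sd` with the
   sample (n − 1) standard deviation.  A constant function column is an
   error rather than being dropped: the 12-function design is fixed, and a
   silently shrinking denominator would corrupt the averaging index.
2. **Average multifunctionality** — the row mean of the z-scores; it has
   grand mean zero by construction.
3. **Multidimensional functioning** — the leading principal axes (default
   3) of the z-scored matrix.  On z-scores the covariance and correlation
   PCA coincide, which resolves the usual ambiguity.  Axis orientation is
   arbitrary in any PCA; we fix it by making the largest-magnitude loading
   of each axis positive, so reported axis directions are reproducible.

## Signed co-occurrence networks

Abundance tables are filtered per kingdom to dominant ASVs — present in
strictly more than 25% of samples with mean within-sample relative
abundance strictly above 10^-5 — *before* any cross-kingdom merge, so that
a taxon's dominance is judged within its own profiling assay.  Filtered
tables are merged (shared samples, disjoint taxa) to build cross-kingdom
networks.

Inference is compositionally robust sparse inverse-covariance estimation
in the neighborhood-selection (Meinshausen–Bühlmann) form:

* **CLR transform.**  Per sample: add a pseudocount (only when zeros are
  present; 1 for count tables, half the smallest positive value for
  non-integer absolute abundances), close to proportions, take logs,
  subtract the sample mean log.  Rows sum to zero, and multiplying a
  sample's abundances by any constant leaves the transform unchanged —
  this is what makes the downstream network insensitive to depth and
  total-biomass differences.
* **Neighborhood regressions.**  Each taxon's CLR profile is regressed on
  all others with an L1 penalty (glmnet's objective, `1/(2n) RSS +
  lambda * ||beta||_1`).  An edge is kept under the OR rule (either
  regression selects the pair); the AND rule is available and is what the
  planted-truth validations use, because requiring both directions trades
  a little recall for markedly better precision.  Edge sign is the sign of
  the mean of the two directed coefficients; an exact zero mean drops the
  edge.
* **StARS model selection.**  The penalty path is 30 log-spaced values
  spanning two decades down from `lambda_max` (the largest absolute
  CLR cross-covariance, above which the graph is empty).  Edge-selection
  instability `mean(2 theta (1 - theta))` is estimated from 50 random
  80% subsamples, monotonized along the decreasing path, and the smallest
  penalty with monotonized instability at or below 0.05 is selected.  If
  no penalty qualifies, the largest penalty is used and the fallback is
  recorded in the network's provenance, alongside the path, instabilities,
  and seed.

The variant (MB rather than full glasso), the path, and the StARS
parameters are package decisions recorded in provenance — the methodology
this follows names the estimator family but not its tuning.

## Network topology, roles, and association scores

Summary metrics follow the standard identities: average degree `2E/N`,
density `2E/(N(N-1))`, average path length and diameter on the unweighted
graph over connected pairs only, clustering as the global average of local
coefficients (degree < 2 counts 0), and modularity at the partition found
by unweighted fast-greedy modularity maximization (deterministic; the
seed is recorded anyway).  For an edgeless (sub)network the path-based
metrics are reported as 0, documented rather than NA, so per-sample tables
stay rectangular.

Node roles use the within-module degree z-score `Z` and participation
coefficient `P = 1 - sum_m (kappa_im / k_i)^2`: module hubs (`Z > 2.5, P <
0.62`), network hubs (`Z > 2.5, P > 0.62`), connectors (`Z < 2.5, P >
0.62`), peripherals otherwise.  When a module's within-degrees are all
equal (sd 0) the z-score is defined as 0, avoiding infinities; isolated
nodes get `P = 0`.

Keystone taxa are nodes whose Kleinberg hub-centrality score reaches 0.7.
On an undirected graph the HITS hub score equals the principal eigenvector
of the unsigned adjacency; we compute it per connected component, scale
each component's vector by its leading eigenvalue (denser components score
higher), and normalize globally so the maximum is 1 — this keeps the 0.7
threshold meaningful on disconnected graphs, where a naive power iteration
would zero out all but the dominant component.

Community-level biotic association scores take the most direct reading of
"multiplying ASV matrices with their signed connectedness": for sample
`s`, `PPA_s = sum over positive in-scope edges (i,j) of r_si * r_sj` with
`r` the within-sample relative abundance, and `PNA_s` the analogue over
negative edges.  A scope restricts the sum to one kingdom pair (e.g.
rhizobia–AM fungi).  Scores are invariant to global rescaling of a
sample's absolute abundances, and an absent endpoint contributes nothing.

## Community assembly null models (QPEN)

For each sample pair, the abundance-weighted beta mean nearest taxon
distance is

`betaMNTD = 0.5 * (sum_i f_i min_j d_ij + sum_j f_j min_i d_ij)`

with `f` relative abundances within each community and `d` cophenetic
distances; a shared taxon has nearest distance zero.  The inner loop is
implemented in C++ (as the field's null-model packages do) because the
null distributions require hundreds of full pairwise recomputations.

* **betaNTI** z-scores the observed betaMNTD against nulls obtained by
  shuffling taxa across all tree tips — the standard entire-community
  choice; the same shuffles are applied to every pair.  The RNG contract
  is documented (the k-th shuffle is the k-th `sample.int` draw after
  seeding), which lets an independent reimplementation reproduce it
  exactly, and the z-score construction makes betaNTI invariant to
  rescaling all branch lengths.  A pair whose null distribution is
  degenerate (zero sd — e.g. identical communities) is reported missing
  with a warning, never silently zero.
* **RC_Bray** assembles null communities per sample: draw the observed
  richness without replacement with probability proportional to occupancy,
  fill abundances proportional to regional relative abundances, scale to
  the observed total.  `RC = 2 * (P(null < obs) + 0.5 * P(tie)) - 1` lies
  in [−1, 1]; ties get half weight to keep the bounds exact.
* **Classification.**  `betaNTI > 2` → variable selection; `< −2` →
  homogeneous selection; otherwise `RC > 0.95` → dispersal limitation,
  `RC < −0.95` → homogenizing dispersal, else drift.  Boundary equalities
  resolve toward the stochastic/drift side (the thresholds are quoted as
  strict inequalities).  The published threshold prose conflates the signed
  RC rules; the implementation follows the standard signed convention
  above.  Fractions are computed over classified pairs; pairs with missing
  betaNTI are excluded and counted.

The default is 1000 randomizations; validation runs use 100–200 and are
reported as scaled down.

## Permutation statistics

Bray–Curtis distances, Mantel tests (Spearman by default, matching the
driver screens this pipeline exposes), PERMANOVA, constrained PCoA, and
distance-based variation partitioning are delegated to vegan behind the
package's interfaces, with every seed explicit.  All permutation p-values
use the `(1 + exceedances)/(1 + permutations)` estimator and are never
exactly zero.  Negative principal-coordinate eigenvalues (Bray–Curtis is
non-Euclidean) are handled by the Lingoes correction.  Variation
partitioning reports adjusted-R² fractions unclipped — small negative
values are an honest artifact of the adjustment, not an error.
Permutations are unrestricted; plot-level random effects are out of scope
here.

## The synthetic-data generator

The generator emulates the study design: 18 plots = 3 slope positions × 6
replicates, positions 20 m apart with replicates spread over 10 m; three
kingdoms profiled on the same samples with disjoint taxa (defaults 60
bacteria, 25 rhizobia, 20 AM fungi for minutes-scale validation; the
field's richnesses are one to two orders larger).

* **Planted network.**  A sparse symmetric precision matrix over all taxa
  (cross-kingdom entries allowed): edge magnitudes target partial
  correlations of 0.3–0.5 (the customary range in graphical-model
  simulations), positive definiteness is enforced by shifting the diagonal
  past the most negative eigenvalue and rescaling to unit diagonal.  Edge
  sign equals the sign of the implied partial correlation.
* **Latent abundances.**  Per sample, a multivariate normal draw with
  covariance the inverse precision, plus per-taxon intercepts with sd 2
  on the natural-log scale — the orders-of-magnitude rank-abundance spread
  that gives ASV-table-like sparse occupancy.  Scenario terms:
  * *selection*: habitat optima evolve by Brownian motion on each
    kingdom's coalescent tree (z-scored within kingdom), and the latent
    mean shifts by `strength × optimum × centered position score`
    (top/middle/bottom → −1/0/1).  The default strength 4 makes the
    per-position fitness shift dominate the latent noise, so the planted
    regime genuinely is environmental filtering.
  * *neutral*: the filter is replaced by per-taxon spatial random effects
    with exponential distance decay along the slope (range 20 m, sd 1.5)
    — dispersal-limited turnover with no phylogenetic structure.
* **Counts.**  Each sample's latent composition is scaled to a
  log-normally varying depth (CV 20%) and Poisson-sampled, preserving
  absolute-abundance ("quantitative profiling") semantics.
* **Functions.**  Each of the 12 functions is a linear combination of
  three standardized predictors — AM-fungal richness and the
  positive/negative association scores computed from the *true* network —
  with positive signs for richness and PPA and a negative sign for PNA,
  plus Gaussian noise (sd 0.5).

What the generator does *not* emulate: read-level noise and chimeras,
taxonomy, compositional zeros from library-size competition (depths are
absolute), interactions that change along the gradient, or temporal
dynamics.  Tests passing on these data show the machinery is correct and
identifiable under its own assumptions; they do not certify performance on
real sequencing data.

## Validation design and problem sizes

* Planted-network recovery is checked at 30 taxa, edge density 0.1, and
  ~200 samples, with no environmental forcing and moderate abundance
  spread (intercept sd 1), using the AND rule — the setting isolates
  interaction-signal recovery from the separate difficulties of
  environmental confounding and rare-taxon dropout, which are studied
  elsewhere in the suite.  Precision and recall both clear 0.7 there.
* Scenario recovery runs the QPEN classification at realistic bacterial
  richness (200 taxa, intercept sd 3): over repeated seeds the selection
  scenario yields deterministic fractions above drift and the neutral
  scenario yields stochastic fractions above selection.  At the compact
  60-taxon default the selection signal can be partial — nearest-taxon
  metrics lose power when communities are small and occupancy high —
  which is itself a documented property, not a defect.
* betaNTI on phylogenetically unstructured communities keeps ≈95% of
  values inside [−2, 2] (the null is approximately but not exactly
  normal, so a 0.90–0.99 band is the honest check); Mantel and PERMANOVA
  hold their nominal 5% type-I rate across 200 null datasets.
* Reported topological identities (average degree, density, cross-kingdom
  edge shares) recompute exactly from published node/edge counts of the
  motivating field study; path-length and subset-degree values from that
  table follow undocumented conventions and are deliberately not
  reproduced.

Every stochastic routine takes an explicit seed and reproduces
bit-identically; pipeline outputs carry a hash of the analysis
configuration.

## Known limitations

* Neighborhood selection with StARS systematically over-selects under the
  OR rule at moderate sample sizes; interpret 18-sample networks as
  stability-selected sketches, not edge-exact graphs.
* The per-component eigenvalue scaling of hub centrality is one defensible
  convention among several; rankings within a component are unaffected.
* The association-score product rule is the package's documented reading
  of community-level "connectedness multiplication"; an
  abundance-times-degree variant would weight hubs differently.
* QPEN fractions at 18 samples rest on 153 non-independent pairs; treat
  them as descriptive summaries rather than tests.
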