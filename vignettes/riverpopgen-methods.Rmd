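---
title: "Methods: network connectivity, dispersal and metapopulation genetic diversity"
author: "riverpopgen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network connectivity, dispersal and metapopulation genetic diversity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riverpopgen)
```

# The problem

River systems are dendritic: habitat patches (subcatchments) are connected
along a branching tree, flow is directional, and most movement of strictly
aquatic organisms is confined to the network. Theory predicts that this
connectivity leaves an imprint on neutral genetic diversity — in particular a
*downstream increase in intraspecific genetic diversity* (DIGD), because
central, downstream nodes receive migrants (and their alleles) from many
upstream branches, while headwaters are demographic dead ends when movement
is biased downstream.

`riverpopgen` packages the full analysis chain needed to test these
predictions for microsatellite surveys of river-dwelling metapopulations
(its motivating use case is freshwater amphipods sampled across a large
Rhine-basin network):

1. a **river-network data model** with the graph metrics used as regression
   predictors,
2. **population-genetic estimators** for diversity within and
   differentiation between nodes,
3. an **individual-based metapopulation simulator** that runs on the same
   graph as the data,
4. a **perpendicular-offset goodness-of-fit framework** scoring simulation
   scenarios against empirical node statistics, and
5. a **linear-model layer** for relating genetic responses to network
   metrics, including an isolation-by-distance power-term scan,
6. **synthetic generators** so that every step is testable without any
   external download.

# The network model

A `river_network` is a directed in-tree: each node drains to exactly one
downstream neighbour except a single outlet. Edges are stored
upstream→downstream and weighted by instream length (km); nodes carry their
local (unaccumulated) subcatchment area (km²). Validation enforces
acyclicity, connectedness, a unique outlet, at most one downstream edge per
node and strictly positive lengths, each with an error naming the offending
node or edge.

Node metrics (`node_metrics()`):

* **upstream distance** — instream distance to the outlet;
* **catchment area** — accumulated upstream area,
  `A(i) = a(i) + sum over upstream neighbours`;
* **betweenness** (directed and undirected) — raw counts of weighted
  shortest paths through a node, endpoints excluded. Directed mode follows
  flow orientation and counts ordered pairs, undirected mode counts each
  unordered pair once. Counts are left unnormalized: downstream analyses
  log-transform them, so only relative scale matters, and the convention is
  fixed and documented;
* **closeness** — reciprocal of the summed distances to all other nodes.
  *Directed closeness on an in-tree needs a convention*: most ordered pairs
  are mutually unreachable, and summing infinite distances would zero every
  value. Unreachable pairs are therefore excluded from the sum and the
  number of reachable pairs is reported alongside (attribute
  `n_reachable`); the outlet, which reaches no other node in flow
  orientation, is `NA`. This is a declared convention, not an inference
  about any particular graph library's behaviour;
* **standardized closeness** — `(c - min c)/(max c - min c)`, attaining 0
  and 1 over the node set; degenerate (all-equal) inputs raise an error
  rather than returning 0/0;
* **degree** — number of incident edges, orientation ignored.

All shortest-path computations treat edge lengths as weights (they are the
physical instream distances). Pairwise `instream_distance_matrix()` uses the
undirected tree metric.

# Genetic diversity statistics

Genotypes live in a flat table: one row per individual, two integer allele
columns per locus, plus node, species and individual identifiers. A locus
call is either fully observed or fully missing; missing data are handled by
per-locus pairwise deletion throughout.

* **Rarefied allelic richness.** The expected number of distinct alleles in
  a standardized sample of `g` gene copies,
  `AR_g = Σ_a [1 − C(N−N_a, g)/C(N, g)]`,
  computed with log-binomials for stability. The default `g` follows the
  rarefy-to-minimum convention per species: twice the smallest per-node
  number of fully typed individuals at the limiting locus. `g` is always
  reported next to AR. Rarefaction is performed per species, not on the
  pooled data set — the two species in a survey are distinct biological
  replicates, and pooling would let the worse-sampled species set the other
  one's rarefaction depth.
* **Observed heterozygosity** — fraction of heterozygous individuals.
* **Expected heterozygosity** — Nei's unbiased estimator
  `Hs = n/(n−1) · (1 − Σp² − Ho/(2n))` by default (matching standard
  microsatellite practice), with plain gene diversity `1 − Σp²` available by
  flag. Empirical means are only reproducible with a pinned estimator, so
  the choice is recorded in the output's attributes.
* **F_IS** — `1 − mean_l(Ho_l)/mean_l(Hs_l)`, a ratio of locus means.
* **Pairwise Nei F_ST** — `(Ht − Hs)/Ht` per node pair with the Nei–Chesser
  sample-size corrections (harmonic-mean `ñ` over the two samples,
  `Ht = 1 − Σp̄² + Hs/(2ñ) − Ho/(4ñ)`), and `Hs`, `Ht` averaged over loci
  *before* the ratio — the standard combination, which also matches the
  behaviour of the widely used estimators for this quantity. Small negative
  values are estimator artefacts and are reported as computed; zeroing
  happens only where the regression layer requires it (`power_scan()`),
  mirroring how such artefacts are usually handled just before modelling.
* **Garza–Williamson M-ratio** — `M = k/(r+1)` on the integer allele states
  as given, assuming a 1-unit repeat ladder (the package cannot know the
  repeat motif; users with dinucleotide sizes should divide sizes by the
  motif length first). Monomorphic loci return `M = 1` by convention.
* **Mantel test** — Pearson correlation of upper-triangle entries with a
  one-tailed permutation test (H1: positive association), joint row/column
  permutations, add-one smoothing `(1 + #{r* ≥ r})/(n_perm + 1)`, and an
  exact mode enumerating all `n!` permutations for small matrices.

# The simulator

`run_simulation()` is a discrete-time, stochastic, individual-based model of
a sexually reproducing, diploid metapopulation on the network graph, with
non-overlapping generations and the life cycle **reproduction → mutation →
natal dispersal**, censused after dispersal. The core loop is implemented in
C++ for speed and draws all randomness from R's RNG, so a fixed seed gives
bit-identical results; replicate `r` of master seed `s` uses the derived
seed `(1000·s + 7919·r) mod (2³¹ − 1)`.

* **Reproduction.** Each female with at least one male in her node picks a
  uniform-random local male (with replacement across females) and produces
  `Poisson(2λ₀ / (1 + (λ₀−1)·N/K))` offspring, where `N` counts all adults
  in the node before reproduction. This Beverton–Holt form is parameterized
  so that at `N = K` each female produces 2 offspring on average — exactly
  replacement at a 0.5 sex ratio — and per-capita growth approaches `λ₀`
  as `N → 0`. Defaults: `λ₀ = 2`, mean `K` of 1000 per node.
* **Mutation.** Each allele copy mutates independently with probability
  `μ` (default 10⁻⁴). Two models: *stepwise* (±1 with equal probability,
  reflecting at the ends of the state set) and *random* (uniform over all
  states, resampling the current state allowed, so the effective change
  rate is `μ(1 − 1/S)`). The allele state set is `1..100`: descriptions of
  such models sometimes mention reflecting bounds "at 0 and 100" while also
  speaking of 100 possible values, which is internally ambiguous (101
  labels vs 100 states); this package pins **100 states** with reflection
  from state 1 to 2 and from 100 to 99.
* **Dispersal.** Natal: each offspring emigrates with probability `d`; the
  target is drawn among adjacent nodes with weight 1 for the downstream
  neighbour and weight `W` for each upstream neighbour (`W = 0` pure
  downstream drift; `W = 1` symmetric; `W = 0.5` downstream twice as likely).
  If all weights are zero (the outlet at `W = 0`) the individual stays.
  Dispersal mortality `m` (default 0) removes emigrants.
* **Carrying capacities.** Either uniform (`K_base` everywhere) or scaled
  with the square root of accumulated catchment area,
  `K_i = round(c·√A_i)` with `c` chosen to conserve the metapopulation
  total `n·K_base`, floored at 2 so every node can host a breeding pair.
  The most downstream node automatically has the largest capacity.
* **Initialization.** Every node starts at `K_i` with uniform-random
  alleles and sexes. Long runs reach mutation–drift–migration
  quasi-equilibrium regardless of the start, and a maximally diverse start
  converges faster than a monomorphic one.

The exported result of each replicate is the final generation as a genotype
table (so the *same* estimator code computes empirical and simulated
statistics), plus a trajectory of total population size and mean
pooled-frequency expected heterozygosity.

# Model–data fit

Matched empirical/simulated node statistics are compared as points
`(emp, sim)` against the 1:1 line; the signed perpendicular offset is
`(sim − emp)/√2`, positive when the simulation overestimates. Per scenario,
response and species the package reports

* **SPO** — sum of absolute offsets (overall spread; larger = worse),
* **MPO** — median absolute offset (robust to outlier nodes),
* **DMPO** — median signed offset (direction of misfit).

Replicates are averaged per node before offsets are computed; averaging (as
opposed to pooling) keeps `n_points` equal to the number of empirical nodes
and treats replicates as estimates of the same scenario mean. For comparable
rarefied richness, simulated populations can be subsampled to the empirical
per-node sample sizes first (`subsample_genotypes()`), since AR is
sample-size sensitive even after rarefaction when `g` differs.

`parameter_win_fraction()` formalizes "which parameter value fits better":
for every *context* (combination of the other scenario parameters × response
× species × measure ∈ {SPO, MPO}) the focal value wins against an
alternative when its measure is strictly smaller. Exact ties count as
non-wins for both sides and are reported separately; missing grid cells are
skipped and counted. On a full 3×3×2 scenario grid with 3 responses and 2
species this yields 144 comparisons for the 3-valued parameters (2
alternatives × 36 contexts × 2 measures) and 108 for the 2-valued capacity
mode.

# Regression layer

* **Collinearity screen** (`kendall_screen()`): among predictor pairs with
  |Kendall τ| above the threshold (default 0.8), the member with the larger
  mean |τ| against all remaining predictors is dropped, iteratively. The
  tie-break rule had to be fixed somewhere: mean-|τ| removes the most
  globally redundant variable first.
* **Linear models** (`fit_lm()`): ordinary least squares via `lm()`, with
  named predictor transforms. Catchment area is conventionally
  log-transformed; betweenness uses `log1p` because leaves have betweenness
  exactly 0. AIC is reported in the full Gaussian-likelihood convention
  `n·ln(2π·RSS/n) + n + 2(k+1)`, which is identical to R's `AIC()` for
  `lm` objects, so values are comparable across all operations in the
  package; AICc adds `2(k+1)(k+2)/(n−k−2)`.
* **Backward stepwise** (`backward_stepwise()`) delegates to `step()`,
  which respects marginality for interaction models.
* **All-subsets search** (`all_subsets()`) enumerates every main-effects
  subset (≤ 15 predictors) and ranks by AICc.
* **VIF** (`vif()`): `1/(1 − R²_j)`; infinite under perfect collinearity.
* **IBD power scan** (`power_scan()`): fits `F_ST ~ dist^p × species` for
  `p = 0, 0.01, …, 1` and selects the minimum-AIC power; `p = 0` drops the
  then-constant distance term. Negative F_ST inputs are zeroed here. The
  power term captures saturating ("case-IV") isolation-by-distance shapes
  that a straight line misses.

# Synthetic data

Two generators make the package self-testing:

* `random_dendritic_network()` grows a random recursive in-tree; a
  `leaf_bias` parameter trades off elongation against confluence creation.
  Defaults (lognormal edge lengths around 1.5 km, gamma local areas with
  mean 2 km²) emulate a fine subcatchment partition of a mesoscale basin.
* `island_model_genotypes()` draws Balding–Nichols structured allele
  frequencies around Dirichlet-uniform ancestral frequencies and samples
  individuals in Hardy–Weinberg proportions. The Balding–Nichols parameter
  is set to `F = 2t/(1+t)` for a requested `target_fst = t`: the expected
  *pairwise* Nei F_ST between two populations drawn with parameter `F` is
  `(F/2)/(1 − F/2)`, because the pair's total diversity is computed from
  just those two populations. With this calibration the mean pairwise Nei
  F_ST of the generated data recovers `t`, which is what the package's
  recovery checks measure. Per-population sample sizes default to 15–40
  individuals, straddling the usual ≥ 15 inclusion filter.

What the synthetic data do **not** emulate: colonization history and
phylogeographic structure, null alleles and genotyping error, spatial
autocorrelation of allele frequencies along the network, and realistic
optimal-channel-network geomorphology. Passing tests on synthetic data
therefore validate the estimators and the machinery, not any biological
claim about a particular basin.

# Numerical choices and problem sizes

* Rarefaction uses `exp(lchoose(·))`; differences below 10⁻¹² are treated
  as ties in permutation p-values.
* `filter_nodes()` warns (rather than errors) on an empty result, so sweep
  code can continue past degenerate scenarios.
* The test suite and the acceptance script run the simulator at reduced
  scale — 20-node networks, `K` of 50–100, 400–2000 generations, 2–10
  replicates — chosen so that the qualitative claims they check
  (demographic equilibrium, fixation under pure drift, downstream diversity
  gradients, the dominance of `W = 0` scenarios against a downstream-drift
  reference) are already unambiguous at desk scale. The reduced-scale sweep
  uses an independently seeded `W = 0` simulation as its reference data
  set, standing in for an empirical survey; the expected outcome is that
  `W = 0` scenarios win the majority of fit comparisons, a
  direction-of-effect check rather than a quantitative reproduction.
* Tiny scaled-capacity demes (floored at `K = 2`) can drift to extinction
  when `W = 0` cuts them off from recolonization; sweep summaries therefore
  restrict to nodes observed in every scenario.

# Known limitations

* Pairwise Nei F_ST is computed per node pair from that pair only (no
  global `Hs`/`Ht` decomposition across all populations at once).
* The simulator has no selection, linkage, overlapping generations or
  temporal change in the landscape; mutation rate is shared across loci.
* The M-ratio uses the allele states as a 1-unit ladder and its common
  bottleneck threshold (≈ 0.68) is a published critical value, cited rather
  than rederived here.
* Directed closeness values depend on the declared unreachable-pair
  convention; comparisons with other software should standardize within one
  convention.

# A minimal end-to-end run

```{r example, eval = FALSE}
net <- random_dendritic_network(20, seed = 1)
metrics <- node_metrics(net)

sim <- run_simulation(net, sim_params(d = 0.01, W = 0, K_base = 100,
                                      generations = 2000, replicates = 5,
                                      seed = 1))
div <- sim_diversity(sim, min_n = 10)

# downstream increase in diversity: AR falls with upstream distance
fit <- fit_lm(div$AR, data.frame(
  upstream = metrics$upstream_distance[match(div$node_id, metrics$node_id)]))
fit$coefficients
```
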