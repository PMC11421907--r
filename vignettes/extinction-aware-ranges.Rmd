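---
title: "Extinction-aware ancestral range reconstruction with rangesse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extinction-aware ancestral range reconstruction with rangesse}
  %\VignetteEncoding{UTF-8}
---

## The model

`rangesse` models the joint evolution of a clade and the geographic ranges
of its lineages as a state-dependent speciation–extinction (SSE) process.
The state of a lineage is its *range*: a non-empty subset of a fixed list
of named areas, capped at `max_range_size` areas (the cap conventionally
used in empirical work is 3, because observed species ranges in the target
datasets are mostly of one or two areas). This generalizes the three-state
GeoSSE model to an arbitrary number of areas.

Four anagenetic/cladogenetic processes carry per-lineage rates, all in
events/lineage/Myr on a time-calibrated tree:

* **dispersal** `d` — range gain of one area; the total rate from range
  $S$ into $S \cup \{a\}$ is $d\,|S|$, each occupied area acting as an
  independent colonization source (the DEC convention);
* **extirpation** `e` — loss of one occupied area, per-area rate `e`,
  possible only for ranges of two or more areas. A single-area lineage
  cannot be removed anagenetically: range contraction and lineage death
  are deliberately separate processes;
* **in-situ speciation** `lambda_is` — speciation within one area;
* **vicariant speciation** `lambda_vic` — a split of a widespread range
  into two disjoint complementary daughter ranges.

The fifth rate, **lineage extinction** `mu`, kills a lineage instantly
across its entire range, whatever its size. `mu` is always a user-fixed
input: molecular phylogenies carry very little information about
extinction rates, so the package never estimates `mu`; it instead
reconstructs histories *conditional on* assumed extinction levels.

Two cladogenetic variants are provided, differing only in the arrangement
of allowed daughter pairs (their likelihoods are therefore directly
comparable):

* **DEC**: a widespread parent of $k$ areas has $k$ subset-sympatric
  in-situ events (one daughter a single area, the other the full parental
  range) and "narrow" vicariance (one daughter always a single area);
* **DIVA**: no subset sympatry (in-situ events exist only for single-area
  parents) and "widespread" vicariance — every bipartition of the parent
  into two non-empty complementary subsets (ABCD may split A|BCD or
  AB|CD).

`lambda_is` is applied **per in-situ event** (a DEC parent of size $k$
has total in-situ rate $k\,\lambda_{is}$) and `lambda_vic` **per
unordered bipartition**, with no per-state renormalization. This is the
simplest arrangement in which each variant has exactly one free rate per
speciation mode; the chosen convention is recorded in every result
object's metadata, because an alternative convention (dividing
`lambda_vic` among a parent's bipartitions) would fit the same number of
parameters.

## The likelihood

Two coupled vectors are integrated along every branch from the tips to
the root: $E_i(t)$, the probability that a lineage in state $i$ at time
$t$ before the present leaves no sampled descendants, and $D_i(t)$, the
partial likelihood of the observed subtree given state $i$:

$$\frac{dE_i}{dt} = \mu - (\Lambda_i + Q_i + \mu)E_i + \sum_j q_{ij}E_j
  + \sum_{(i\to j,k)} \lambda_e E_j E_k$$
$$\frac{dD_i}{dt} = -(\Lambda_i + Q_i + \mu)D_i + \sum_j q_{ij}D_j
  + \sum_{(i\to j,k)} \lambda_e (D_j E_k + D_k E_j)$$

where $q$ collects the dispersal/extirpation rates, $\Lambda_i$ and $Q_i$
are total cladogenetic and anagenetic out-rates, and $\mu$ enters every
state identically (whole-range extinction). It is the $E$ terms that let
extinct lineages — and the ranges they occupied — inform the
reconstruction. At internal nodes daughters combine through the event
table, $D_{i} = \sum_{(i\to j,k)} \lambda_e (D_{L,j}D_{R,k} +
D_{L,k}D_{R,j})$, the symmetric case $j=k$ counted once; this matches the
single $\lambda_e E_j E_k$ term of the $E$ equation, so the total flux per
event is exactly $\lambda_e$ (the BiSSE/MuSSE bookkeeping).

**Root protocol.** By default the root states are weighted
data-proportionally ($w_i = D_i/\sum_j D_j$, the FitzJohn weights) and the
likelihood is conditioned on survival of both root daughters by dividing
by $\sum_i w_i (1-E_i)^2$. Published analyses of this kind rarely state
their root protocol, so both the weighting (`"data"`/`"uniform"`/explicit
`root_weights`) and the conditioning are exposed in
`likelihood_options()` and recorded in outputs.

**Numerics.** Branches are integrated with an adaptive Cash–Karp
Runge–Kutta 4(5) core (compiled; relative/absolute tolerances 1e-8/1e-10
by default). The $D$ block is linear given $E$, so it is rescaled freely
during integration and traversal with accumulated log-scalers — a 63-state
space on a deep tree underflows raw partials long before the root. The
key validation quantities are also computed at loosened tolerances
(1e-6/1e-8) to demonstrate tolerance robustness, and heavier protocol
runs use those loosened tolerances; the two settings agree to ~1e-6 log
units on the packaged dataset. Trees deviating from ultrametricity by
more than 0.1% of tree height trigger a warning, not an error, since
empirical chronograms carry rounding noise. Degenerate inputs (zero-length
branches, all-zero daughter partials) propagate exactly rather than
erroring; a likelihood that underflows to zero returns `-Inf`, which the
optimizer treats as a rejected region.

## Inference and the scenario protocol

`fit_lemad()` maximizes the likelihood over
$(\lambda_{is}, \lambda_{vic}, d, e)$ on the log scale inside
$[10^{-6}, 10^{2}]$ events/Myr with `nlminb`, multi-start (5 by default,
seeded and recorded), with `mu` clamped. Two numerical details matter:

* when dispersal collapses to its bound, no widespread state is
  reachable and the likelihood is exactly flat in `lambda_vic`; on such
  ridges (and at active bounds) `nlminb` reports "false convergence", so
  the fit restarts from its optimum until the objective is stationary and
  reports stationarity-under-restart as convergence;
* if the fitted total speciation rate does not exceed the assumed `mu`,
  the fit carries a warning flag — in a surviving clade speciation should
  outpace extinction — but this is a diagnostic, never a constraint.

`run_scenarios()` implements the four-extinction-level protocol: a
standard birth–death model is fitted first (crown age given, conditioned
on survival; closed-form likelihood in `bd_loglik()`), and its
*speciation* rate estimate `bd_mu` — not its extinction estimate, which is
predictably near zero — calibrates the assumed extinction levels
$\{0,\ \mathrm{bd\_mu}/10,\ \mathrm{bd\_mu},\ 10\,\mathrm{bd\_mu}\}$,
bracketing the fossil-record expectation that extinction is nearly as
frequent as speciation. Both cladogenetic variants are fitted in every
level (8 cells); within a level the higher-likelihood variant is selected,
ties going to DEC by documented convention (equal parameter counts, so no
information criterion is needed; AIC is emitted for reference).

## Reconstruction

`node_marginals()` computes, for every node, the marginal posterior
probability of each range, *defined* as clamp-and-renormalise: restrict
the node to a state, recompute the likelihood, and normalise across
states. Root weights are held fixed at the unclamped run's values — with
data-proportional weights re-derived per clamp the clamped likelihoods
would not sum to the unclamped likelihood, and the definition would lose
its probabilistic meaning. The implementation does not actually re-clamp
node by node: a single up-pass caches subtree partials and a single
down-pass propagates the complement ("rest of tree") partials $G$ by the
adjoint of the linear $D$ system, so that the marginal at any point is
$\propto D(t) \odot G(t)$. The brute-force clamp implementation is kept
as `marginals_by_clamping()` and the two agree to 1e-8 on test problems;
the clamped likelihoods sum to the total within 1e-9 relative.

`richness_through_time()` evaluates $D(t)\odot G(t)$ at points *inside*
branches (equivalent to clamping an inserted degree-2 node — exact under
the model, not an interpolation between node marginals) on a uniform grid
of time slices, and accumulates per-area presence probabilities over the
branches crossing each slice. The present-day slice reproduces the
observed per-area tip counts exactly. Richness is an expectation over
reconstructed (sampled, surviving) lineages only; extinct lineages shape
the probabilities through the model but are not tallied. Whether a
per-branch modal range or an expectation is tallied is a reporting
convention; the expectation convention used here is this package's
choice.

`ancestral_origin()` thresholds the root's per-area presence
probabilities (default 0.5, configurable and recorded); if no area
passes, it falls back to the areas of the single most probable root state
and flags the fallback. The full root distribution is always retained —
any thresholding is presentation, not inference.

## The forward simulator

`simulate_forward()` is an exact competing-exponential-clocks (Gillespie)
simulation driven by *the same event tables* as the likelihood: per
lineage, one clock per in-situ event, vicariance event, dispersal move,
extirpation move, plus whole-lineage extinction at `mu`. This sharing is
what makes the simulator usable as a Monte-Carlo oracle: on conditioned
two-tip problems the empirical distribution of tip-range outcomes matches
the normalised likelihoods within Monte-Carlo error (the package's
keystone test, run at $10^5$ conditioned replicates).

Simulations start either from a stem lineage or (default in the packaged
datasets) from a crown split of a root state drawn uniformly among
single-area states — a widespread root should be a *finding*, not an
assumption baked into the generator. Stop rules are a fixed time horizon
(giving ultrametric trees) and/or a standing-diversity cap (the
simulation stops just before the speciation that would exceed the cap).
Conditioning on a minimum number of survivors is by rejection, with the
retry count reported, because silent conditioning would bias exactly the
calibration checks the simulator exists to serve. `prune_extinct()`
removes extinct leaves and suppresses unbranched nodes to produce the
reconstructed tree; extant pairwise divergence times are preserved
exactly.

### What the packaged synthetic data emulate — and what they do not

`make_fixture("iaa7_small")` emulates the empirical setting this kind of
analysis targets: 7 named areas (the major Indo-Australian Archipelago
landmasses), range cap 3, a clade of several dozen extant species over a
45-Myr horizon, simulated with non-zero lineage extinction
(`lambda_is = 0.12`, `lambda_vic = 0.03`, `d = 0.01`, `e = 0.03`,
`mu = 0.06` /Myr), under which tip ranges come out predominantly of size
1–2, as in the real datasets. The generator does **not** emulate several
features of real data: time-stratified palaeogeography (area
connectivity is constant), jump dispersal at cladogenesis, rate
heterogeneity across lineages, areas or time, incomplete and non-random
taxon sampling, and phylogenetic error in the input chronogram. Passing
tests on these data therefore demonstrate internal correctness of the
machinery (likelihood, optimizer, reconstruction, simulator agree with
each other and with independent oracles), not robustness of the model's
assumptions on empirical clades.

## Validation design and problem sizes

The validation suite computes every expected value it asserts:

* single-area trees (20–100 tips, 100 random rate draws): the pruning
  likelihood reduces to the closed-form constant-rate birth–death
  likelihood (same conditioning) within 1e-4 log units;
* zero extinction (fixed 4–6 tip trees, 2–3 areas, 50 draws): the $E$
  system vanishes and pruning matches a dense `Matrix::expm` propagator
  within 1e-6;
* 3-tip, 2-area problems: the up/down-pass marginals match
  clamp-and-renormalise within 1e-6 per entry, clamp sums within 1e-9
  relative;
* $10^5$ conditioned two-tip simulations: outcome frequencies within 3
  Monte-Carlo standard errors of the normalised likelihoods (unordered
  outcome pairs aggregate two labelled outcomes, hence the factor 2 for
  mixed pairs);
* 30 simulated 4-area clades of 150 tips at
  $(\lambda_{is},\lambda_{vic},d,e,\mu) = (0.25,0.05,0.05,0.02,0.1)$,
  fitted with `mu` fixed at truth: median relative error of
  $\lambda_{is}$ and $d$ below 30%;
* 50 replicates at informative rates $(0.3,0.05,0.03,0.01,\mu=0.05)$:
  the modal root marginal recovers the true crown state in well over 60%
  of replicates **when the reconstruction is given the generator's root
  prior** (uniform over single-area states) as fixed root weights. Under
  default data-proportional weights the mode lands almost always on a
  widespread superset of the true area — widespread states accumulate
  additional cladogenetic product terms — which is a real property of
  this model class (and the reason empirical reconstructions under
  extinction tend toward widespread origins), not an implementation
  artefact: the marginals still match the clamp oracle exactly. The
  recovery check pairs the estimator with the prior the data were
  actually generated under.

These problem sizes were chosen so the whole suite runs comfortably on a
single core while still exercising 63-state spaces, deep trees and
realistic clade sizes.

## Known limitations

* No time-stratified connectivity or dispersal matrices, no jump
  dispersal, no per-area speciation/extinction rates: rates are uniform
  in space and time by design.
* `mu` is assumed, never estimated; conclusions are conditional on the
  assumed extinction level, which is why the scenario grid brackets it by
  two orders of magnitude.
* Marginal (not joint) ancestral reconstruction: per-node marginals need
  not assemble into a coherent single history.
* The explicit Runge–Kutta core takes small steps when rates approach
  the optimizer's upper bound (100/Myr) on long branches; such corners
  are visited transiently during optimization but make pathological
  user-supplied rates slow rather than wrong.
* Confidence intervals on rates (profile likelihood) are not provided.
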