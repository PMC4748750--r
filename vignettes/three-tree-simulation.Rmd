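---
title: "Simulating gene families under the three-tree model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating gene families under the three-tree model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genefamsim)
```

## The model

`genefamsim` simulates multi-gene-family data sets under a hierarchical
model with three nested layers:

1. **Species tree.** An ultrametric time tree generated by a constant-rate
   birth–death process. Branch lengths are elapsed time; each branch
   carries an effective population size `Ne`, a generation time `g`
   (generations per time unit) and, at the tips, a number of sampled
   individuals. Extinct lineages are removed: the simulators return the
   reconstructed tree of extant species only.

2. **Locus trees.** Per gene family, locus lineages evolve *inside* the
   species tree under a linear birth–death process for gene duplication
   and loss, plus two independent pure-birth processes for replacing
   horizontal gene transfer (HGT) and gene conversion (GC). A transfer or
   conversion terminates the resident homolog at the receptor position
   (a replacement-loss node) and regrafts the receptor's continuation
   under the donor lineage — a subtree-prune-regraft at the event time.
   Receptors are drawn among contemporary lineages either uniformly or
   with probability proportional to `1/d`, `d` being the patristic
   distance between donor and candidate species at the event time.

3. **Gene trees.** Sampled gene copies coalesce inside the pruned locus
   tree. Ordinary branches follow the multispecies coalescent with rate
   `k(k-1)/(2 p Ne)` per generation for `k` lineages (`p` = ploidy).
   Branches founded by a duplication, transfer or conversion are
   *coalescent-bounded*: the event initially affects a single individual,
   so every sampled lineage of the new copy must coalesce to exactly one
   lineage before (looking backward, by) the founding time.

Under this ploidy convention the expected pairwise coalescence time is
`Ne` generations in a haploid population and `2 Ne` in a diploid one.

## Exact sampling of bounded subtrees

Rejection sampling of the bound (run the free coalescent, accept runs that
have fully coalesced at the event time) becomes arbitrarily slow when the
bound is tight. The package instead samples bounded subtrees exactly,
in three passes over the subtree:

* **Count dynamic program (bottom-up).** For every branch, the probability
  vector of the number of gene lineages entering (bottom) and leaving
  (top) the branch: a node's bottom distribution is the convolution of its
  children's top distributions, and the top distribution follows from the
  classical lineage-count transition probabilities `g_ij(t)` of the
  coalescent death chain. Fixed inputs sit at the leaves: the sampled
  copies at extant tips, and exactly one lineage at each nested bounding
  event (nested bounds are processed innermost-first).

* **Count sampling (top-down).** The count at the subtree root is pinned
  to one by the bound. Walking rootward-to-tipward, each branch's bottom
  count is drawn with probability proportional to
  `P_bottom(i) * g(i, top, t)` by inverse-transform sampling, and sibling
  top counts are drawn jointly conditional on summing to the parent's
  bottom count.

* **Conditional times.** Given bottom/top counts `i -> j` on a branch of
  length `t`, waiting times are drawn sequentially with density
  proportional to `r_k exp(-r_k u) g(k-1, j, t - u)`, inverted numerically
  (grid plus bisection to a relative tolerance of 1e-10). The coalescing
  pair is uniform over extant pairs (exchangeability).

`g_ij` is evaluated by the alternating-sum closed form in log space. That
series suffers catastrophic cancellation for many lineages over short
scaled times; when cancellation is detected (negative values, mass above
one, or a row that fails to normalise) the whole row is recomputed by
uniformization of the death chain — an all-positive series that is
unconditionally stable, at the cost of more terms. Rows are cached per
`(i, t/(p Ne))`.

The test suite holds the exact sampler to a rejection oracle (the
free-coalescent-plus-accept strategy) on three hand-built subtrees — a
single branch, a two-species cherry, and a subtree containing a nested
duplication — comparing both the lineage-count distributions (chi-square)
and the TMRCA distributions (Kolmogorov–Smirnov).

## Species tree samplers

Two conditioning modes are offered:

* `simulate_ssa()` runs the process forward from an origin time with two
  initial lineages, pruning extinct subtrees; fully extinct (or
  single-survivor) replicates are resampled. Two starting lineages make
  the expected extant count of a pure-birth tree `2 exp(lambda t)`, the
  calibration the tests check.
* `simulate_bdsa()` conditions on the number of extant tips. The tip
  split between the two origin lineages is drawn from the conditional
  birth–death count distribution, and each side's speciation times are
  i.i.d. draws from the reconstructed-process density (analytically
  inverted CDF), assembled by uniform ranked joins. When the height is not
  given it is first drawn from its conditional density under a uniform
  origin prior (numerically inverted, cached per parameter combination).
  The sampler is validated against the forward simulator conditioned by
  rejection, not trusted on faith.

Whether the forward sampler should also condition on survival of both
origin lineages is a genuinely open choice; we resample only complete
extinctions (and single survivors, which no downstream stage can use) and
document that as the package's convention.

## Rate heterogeneity and units

Species and locus trees live on one time axis (backwards, 0 at the
present). All locus-level rates are per generation; a branch of `T` time
units with generation time `g` contributes `T g` generations, so
generation-time variation acts upstream of every rate multiplier, on the
time-to-generations conversion itself. Gene trees are converted to
expected substitutions per site as

```
length = sum over segments (duration_gen * u * m_species * m_family * m_gene)
```

where `u` is the substitution rate per site per generation and the three
`m` layers are independent Gamma multipliers with mean forced to one
(shape `alpha`, scale `1/alpha`), the uncorrelated relaxed clock. A gene
branch crossing several species branches is split at the boundaries it
traverses (through the locus-tree embedding, so transfers reroute the
walk correctly); weighting by occupancy time is the only convention that
preserves the mean rate, since the model does not say how a multi-species
branch should otherwise be scaled. Gene lineages older than the species
root inherit the root branch's parameters. The species layer is drawn
once per replicate and shared by all families (a genome-wide effect);
family and gene layers are private to each family.

## Hierarchical priors

Every parameter can be a fixed value or a prior (`U`, `N`, `LN`, `E`,
`G`), with family-level specifications allowed to reference
replicate-level draws (`G:$dup_hyper,2e-7`): the replicate value acts as
a hyperparameter shaping the across-family distribution. Only outer-layer
(replicate to family) references are allowed; which parameters are made
interdependent is left open in the model, so the package permits any such
dependence and documents it as an extension point. Normal draws for
necessarily positive quantities are truncated at zero by resampling
(capped at 1e4 attempts). Each (replicate, family, purpose) unit draws
from an RNG substream keyed by integer hashing of its indices, so results
are bit-reproducible and insensitive to evaluation order.

## The duplication-time case study

`duplication_overestimation()` measures, for every duplication whose two
copies both left sampled descendants, the gap between the duplication
node and the first gene-tree coalescence joining lineages from the two
paralogs. Reconciliation methods unaware of locus trees date the
duplication at that coalescence, so the gap is their expected bias. In the
simplest scenario (one haploid individual, one duplication on a long
branch) the gap is exponential with mean `Ne` generations (`2 Ne`
diploid); the acceptance suite reproduces both values and then re-runs
the experiment across 10,000 replicates (25–50 species, `Ne` uniform on
[1000, 10000], 1–5 individuals, duplication rate uniform on
[0.05, 0.5]/1e6 generations, speciation rate fixed at 10 per 1e6
time units) and fits a Gamma GLM with inverse link. The model predicts
the bias to rise with `Ne` (longer coalescence), to fall with the number
of individuals (more lineages through the duplication point, earlier
first cross-coalescence) and with the duplication rate (duplications
nested in bounded subtrees face tighter bounds), and to show no
species-count effect. At this replicate count the `Ne` effect is
overwhelming and the individuals effect clear, but the duplication-rate
effect — about 2% of the mean by a direct fixed-parameter contrast — sits
below the sampling noise of 10,000 heterogeneous replicates, so its
fitted sign is unstable at desk scale and stabilises only at much larger
replicate counts. Duplications with survivors on one side only are
excluded from the mean but counted.

## Numerical and design choices

* **Tie-breaks.** Pending transfers/conversions are resolved strictly
  oldest-first, ties by creation index; this makes the candidate sets of
  later events consistent with earlier surgeries without recomputation.
* **Discarded events.** A transfer or conversion with no contemporary
  candidate is dropped and counted as attempted-but-unrealized;
  resampling would distort the pure-birth rate.
* **Which duplicate is new.** The second child (creation order) of a
  duplication node carries the bound; the model needs one bounded copy
  but does not name it, so the choice is recorded in the annotations.
* **Fully lost families** are kept as records without a gene tree by
  default (`keep-empty`), so family-size statistics remain unbiased; a
  `resample` policy is available.
* **Pruned bound chains.** When pruning suppresses a chain of unary
  nodes containing several bounds, the youngest bound is kept: a single
  lineage above the youngest bound satisfies all older ones.
* **Zero-length branches** produce identity count transitions.
* **Degenerate count support** escalates the inversion grid once
  (256 to 2048 points) before failing hard.

## What the generator does and does not emulate

The synthetic data reproduce the generative assumptions of the model:
perfect Wright–Fisher populations per branch, no migration, no
recombination within loci, free recombination between loci, no
duplication/loss/transfer polymorphism (every sampled individual of a
species carries the same copy number), no transfers from extinct donors,
and replacing (never additive) transfers. Real gene families violate
several of these (copy-number polymorphism, gradual fixation of
duplicates, autocorrelated rates), so green tests certify correctness of
the sampler with respect to this model, not realism of the model itself.

## Problem sizes used by the validation suite

The suite and the acceptance script run at desk scale, chosen so the
whole validation completes in minutes while keeping Monte-Carlo standard
errors a factor of ~3 below the effects being checked: 1e4 trees per
birth-rate level for the leaf-count calibration, 2000 accepted trees for
rejection-oracle comparisons, 1e4 families for event-count calibrations,
2000 draws per bounded-subtree case, and 1e4 replicates for the
duplication-time experiment (against 1e6 in a full-scale study; the
strong effects are unambiguous at this size, the weak duplication-rate
effect would need the larger run).
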