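---
title: "Methods: diagnosing and resolving phylogenomic incongruence at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diagnosing and resolving phylogenomic incongruence at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem this package addresses

Phylogenomic studies built on hundreds or thousands of loci routinely produce
*incongruent* results: concatenated maximum-likelihood analysis and
coalescent-aware summary species-tree methods, run on the same data, can
recover different, mutually incompatible resolutions of a focal node — each
with high nominal support. The two usual suspects are incomplete lineage
sorting (ILS), which makes true gene genealogies differ from the species
tree, and gene-tree estimation error (GTEE), which makes *estimated* gene
trees differ from the true genealogies. `phylotriage` implements, end to end
and at desk scale, a practical strategy for telling these apart and
resolving the conflict:

1. **Locus filtering** by five per-locus statistics (average bootstrap,
   clocklikeness, GC proportion, number of parsimony-informative sites,
   saturation slope), keeping the *k* best loci per criterion.
2. **Within-locus partitioning** of each ultraconserved-element (UCE) style
   locus into left flank / core / right flank by per-site entropy, so
   gene-tree estimation can give each region its own substitution model.
3. **Gene genealogy interrogation (GGI)**: per-locus topology tests that ask
   which of a small set of predefined hypotheses each locus supports, via
   constrained tree searches, per-site log-likelihoods, and the
   approximately unbiased (AU) test over a multiscale RELL bootstrap.
4. **Quartet-based summary species-tree estimation** from the gene trees
   that survive interrogation, with quartet-frequency branch support and
   coalescent-unit branch lengths.

Because the package must be testable without any external data or tools, a
first-class multispecies-coalescent (MSC) simulator generates UCE-like locus
collections with known truth: species tree, per-locus gene trees,
core/flank breakpoints, and missingness.

# The multispecies coalescent simulator

`species_tree_model()` wraps a rooted, binary, ultrametric species tree with
branch lengths in coalescent units (time divided by 2N generations) and a
single substitution scale (expected substitutions/site per coalescent unit).
`simulate_gene_trees()` samples one lineage per species and coalesces
lineages within each species-tree branch at rate k(k-1)/2, passing survivors
to the parent branch and completing above the root. For a 3-taxon species
tree with internal branch t, the probability that a gene tree is concordant
is 1 - (2/3)exp(-t); the simulator is validated against this closed form in
the test suite.

Assumptions: no migration, hybridization or gene duplication/loss; one
haploid sample per species; gaps arise only from taxon removal, never from
indels. Per-locus and per-gene seeds are derived from one master seed by a
single seed draw, so any locus can be regenerated independently.

## The locus profile

`locus_profile()` describes how one locus evolves along its gene tree:

* `length` (default 600 sites) — typical for trimmed UCE alignments;
* `core_fraction` (default 1/3), the centered conserved core;
* `core_mult` (default 0.05) and `flank_mult` (default 1.0) — the relative
  rate of core sites and of the outermost flank sites;
* `gradient` — `"linear"` (default), the rate rising linearly from the core
  boundary to the alignment edge, or `"step"` (flanks constant at
  `flank_mult`);
* `model` and optionally `core_model` — the substitution model of flank and
  core sites. When a model carries a gamma shape, each site additionally
  draws an iid Gamma(alpha, alpha) rate multiplier, giving within-segment
  rate variation.

The linear gradient is the package's reading of how variability increases
away from a conserved core. It has a consequence worth stating plainly:
a three-segment piecewise-constant entropy model fitted to a linear ramp
places its optimal boundaries tens of sites inside the ramp, so breakpoint
*recovery* benchmarks use the `"step"` profile, where "core at 0.05x, flanks
at 1.0x" is literally true and the entropy profile actually contains the
breakpoints being recovered. Tests that only need heterogeneity (not
breakpoint truth) use the linear default.

The generator emulates: conserved-core/variable-flank structure, ILS-driven
gene-tree discordance, per-locus missing taxa, compositional and
rate-process differences between core and flank. It does **not** emulate:
alignment error, indels, paralogy, base-composition differences *among
taxa* (non-stationarity), linkage between loci, or sequencing error.
Passing tests therefore demonstrate correctness of the machinery under the
MSC with clean alignments, not robustness to every artifact of real data.

# The likelihood engine

Gene trees are estimated with a compiled Felsenstein pruning engine
(`src/engine.cpp`) over compressed site patterns, supporting JC69, HKY85 and
GTR with empirical base frequencies and discrete-gamma rate variation
(4 categories, category means, mean-1 normalization; shape bounded to
[0.05, 50]).

* **Branch lengths** are optimized one at a time by Brent search on
  [1e-8, 10] substitutions/site, sweeping edges in pre-order with cached
  directional partials; passes repeat until the log-likelihood improves by
  less than 1e-6 or 20 passes. Accepted steps never decrease the
  log-likelihood. The Brent tolerance on branch lengths is 2e-4 — an order
  of magnitude below anything that matters to topology or support, chosen
  so a bootstrap replicate costs milliseconds rather than seconds.
* **Topology search** is first-improvement NNI hill climbing in a
  deterministic edge order. Candidate swaps are scored *locally*: with
  fresh upward/downward partials, a candidate's optimal central branch
  length and log-likelihood are computed from the four subtree partials
  alone, without mutating the tree; only candidates that beat the current
  tree are applied and verified with a full optimization pass.
* **Constrained searches** (the GGI work-horse) reject any NNI move whose
  bipartitions violate the hypothesis backbone, checked on 64-bit taxon
  masks; constrained starting trees are seeded random resolutions of the
  backbone. The seed is derived from the *content* of the pruned backbone,
  so two hypotheses with identical backbones produce bit-identical searches
  and site-likelihood rows — which is exactly the behavior wanted when GGI
  is deliberately run with indistinguishable hypotheses.
* **Model selection** (`select_model()`) scores {JC69, HKY85, GTR} x {+G,
  none} by BIC (`-2 lnL + k log(S)`) on the fixed NJ starting topology, a
  small-model stand-in for full model-finder searches; absolute
  log-likelihoods are therefore not comparable to tools searching larger
  model spaces.
* **Partitioned models** are edge-linked and proportional: all segments
  share the topology and branch lengths, each segment has its own
  substitution model and a rate multiplier, normalized to site-weighted
  mean 1. After the joint search, each segment's parameters are re-estimated
  on the joint tree and the fit is polished — the same
  parameter/branch-length alternation the single-model fit receives.
* **Bootstrap supports** are plain nonparametric bootstrap: sites resampled
  with replacement, each replicate re-estimated *de novo* from an NJ start
  built on the resampled data (starting replicates from the ML tree
  inflates support badly when the likelihood surface is flat), model
  parameters held fixed at their ML estimates. Site resampling is shared
  across analysis modes for a given locus and seed — a common-random-number
  design, so paired comparisons of partitioned vs. unpartitioned supports
  are not swamped by replicate noise. These supports are *a* bootstrap, not
  any particular accelerated approximation, and are not comparable in
  absolute value to ultrafast-bootstrap numbers.

# Entropy partitioning

`site_entropy()` is Shannon entropy (bits) of the A/C/G/T frequencies in a
column, ambiguity codes and gaps excluded, all-missing columns defined as 0.
`best_breakpoints()` minimizes the total within-segment sum of squared
deviations of per-site entropy about segment means over all admissible
(l, r) pairs using prefix sums (O(L^2)), with a minimum segment length of 50
sites (enough sites to fit a segment model; configurable). Ties resolve to
the smallest l, then the smallest r; numerical ties within 1e-9 are treated
as exact so a flat profile yields the canonical (min_len, 2 min_len) pair.
Loci shorter than 3 min_len are flagged unpartitionable and analyzed as a
single segment. Internally all coordinates are 0-based half-open; every
emitted charset is 1-based inclusive (the NEXUS convention).

# The five filtering statistics

* `mean_support()` — arithmetic mean of internal-branch bootstrap supports
  (0-100). * `clocklikeness()` — the tree is midpoint rooted (the rooting
  is not otherwise defined for unrooted gene trees) and the *population*
  variance of root-to-tip path lengths is returned; 0 iff ultrametric.
* `gc_proportion()` — (G+C)/(A+C+G+T) over all cells. * nPIS — sites with
  at least two states each in at least two sequences. * `saturation_slope()`
  — least squares *through the origin* of p-distance on patristic distance
  (both vanish together on identical sequences, so a free intercept is not
  meaningful).

`rank_and_select()` keeps the k best loci (default 600) per criterion with
fixed directions (high: bootstrap, nPIS, saturation; low: clocklikeness,
GC), ties broken by ascending locus id, missing statistics excluding a locus
from that criterion only. The support-improvement comparison uses the
"nonexact" paired Wilcoxon signed-rank test — normal approximation with
continuity and tie corrections, zeros dropped — one-sided (partitioned >
unpartitioned), Holm-corrected across the dataset family.

# Gene genealogy interrogation

For each locus, one constrained search per hypothesis (and optionally an
unconstrained search — the modified GGI), a shared per-locus model
(GTR+G by default), per-site log-likelihoods for every resulting tree, and:

* `rell_bootstrap()` — at each scale r in {0.5, ..., 1.4}, round(r S) sites
  are drawn with replacement and each tree's site log-likelihoods are
  summed; the winner takes the replicate, ties broken uniformly at random
  (seeded). 1,000 replicates per scale by default (500 in the heavier
  acceptance runs).
* `au_pvalue()` — the probit of 1-BP(r) is fitted as z(r) = d sqrt(r) +
  c / sqrt(r) by weighted least squares with binomial weights, and
  p_AU = 1 - Phi(d - c). BP values are clipped to
  [1/(10 R), 1 - 1/(10 R)]; trees with BP identically 1 (or 0) across
  scales are flagged degenerate with p 1 (or 0).

A locus *significantly supports* a hypothesis when that hypothesis's tree is
best by total log-likelihood **and** its AU p exceeds 0.95. The reported
convention matters: the best tree's AU p is high only when the resampled
evidence for it is nearly unanimous, so "significant" loci are those with
essentially unambiguous genealogical signal. When constrained fits tie
exactly (uninformative loci), the first hypothesis label wins the "best"
bookkeeping but can never reach significance, since tied rows give BP near
1/2.

`select_gene_trees()` implements the final-tree policy: keep each locus's
best tree when it is the unconstrained tree or the winning hypothesis's
constrained tree; discard loci favoring other hypotheses.

# Quartet summary species trees

`quartet_table()` tallies, for every 4-taxon subset, which of the three
unrooted quartet topologies each gene tree displays (via the four-point
condition on path-length distances; genes missing a taxon skip that
quartet). `search_species_tree()` maximizes total agreement: exhaustively
for up to 8 taxa, otherwise NNI hill climbing from a majority-rule consensus
start plus seeded random restarts (5 by default). Branch annotation samples
or enumerates quartets with one taxon from each of the four subtrees around
a branch (exact up to 100 quartets per branch, seeded sampling beyond);
q1 is the normalized frequency of the displayed arrangement, support is q1
itself by default (an optional `localpp` mode integrates the MSC posterior
of the displayed resolution under a uniform prior over the three resolutions
and an Exp(1) prior on the branch length — labelled, not silently
substituted for the published local-posterior-probability derivation), and
the coalescent branch length is d = -ln(1.5 (1 - q1)), zero and flagged when
q1 < 1/3, capped at 9 coalescent units as q1 approaches 1.

At 2,000 gene trees the Monte-Carlo standard deviation of d is about 0.07
at t = 2, so recovery bands of +/-0.1 are intentionally tight — roughly
1.4 sigma — and an occasional narrow miss at a fixed seed reflects sampling
noise, not estimator bias (the estimator is calibrated to within 0.02 at
20,000 trees in the unit suite).

# The canonical study system and test problem sizes

`example_system()` builds the design used across tests: four clades of three
taxa (X, Y, Z and outgroup O), competing hypotheses H1 (X,Y) vs. H2 (X,Z),
and a true species tree following H1 whose focal branch length t controls
ILS (concordance 1 - (2/3) e^(-t); t = 0.5, "moderate ILS", gives about
60%). Long clade stems (2 coalescent units) let within-clade lineages finish
sorting, mirroring empirical constraint sets whose clades are
uncontroversial.

Two signal regimes are used deliberately:

* a **strong-signal regime** (substitution scale 0.05/cu, 400-600 bp loci)
  for topology-testing machinery, where per-locus searches can actually
  discriminate hypotheses; and
* a **weak-signal regime** (scale 0.005/cu) with `example_het_profile()` —
  420 bp, core 1/3 at 0.05x, linear flank gradient, AT-rich
  transition-biased flanks with Gamma(0.3) site-rate variation, GC-balanced
  low-kappa cores — for the partitioning-benefit study. Mean per-locus
  bootstrap sits in the 60s-70s there, which is where empirical single-UCE
  gene trees live and the only regime where support *can* improve; a shared
  single model with purely scalar core/flank rate differences shows no
  partitioning benefit at all, because a discrete-gamma distribution
  absorbs scalar rate variation — the benefit comes from process
  differences between core and flank, which is also the field's stated
  rationale for partitioning these loci.

Problem sizes in the test and acceptance suites (chosen as desk-scale
defaults: minutes, one core): 3-taxon MSC calibration at 5,000 genes;
breakpoint recovery on 50 loci of 600 bp at 32 taxa; GGI power on 200 loci
of 12 taxa; partitioning benefit on 3 datasets of 100 loci with 100
bootstrap replicates; species-tree checks at 6-12 taxa with up to 2,000
gene trees.

# Known limitations

* NNI-only search; no SPR/TBR. Local optima are mitigated by NJ starts,
  local candidate scoring with full verification, and multiple starts for
  constrained searches.
* The reduced model set (JC69/HKY85/GTR, +G) changes absolute
  log-likelihoods relative to tools searching a large model space; all
  within-package comparisons are internally consistent.
* Branch supports are plain bootstrap percentages; quartet branch support
  defaults to a normalized frequency, not a calibrated posterior.
* Constrained searches require the backbone to cover the locus's taxa after
  pruning; partially covering backbones are rejected rather than guessed at.
* The simulator's clean-data assumptions mean empirical messiness
  (alignment error, non-stationary composition) is out of scope; effect
  sizes for the partitioning benefit in simulation are accordingly small,
  and the package measures them with a common-random-number paired design
  rather than claiming large absolute gains.
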