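---
title: "Quantifying what fossils add to ancestral-area reconstruction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying what fossils add to ancestral-area reconstruction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

Historical biogeography asks where clades originated and how they moved.
Most analyses infer ancestral areas from the phylogeny and ranges of living
species only, yet extinction and long-distance dispersal can erase the
signal those species carry. `fossilareas` provides the machinery to measure,
by simulation, how much precision and accuracy is gained by placing fossil
species in the tree — and how much is lost again when the known fossil
record is a biased subsample of what once existed.

This vignette documents the models, the tunable parameters, the numerical
choices, and the limits of what the simulations can show.

## The range-evolution model used for inference

Ranges are subsets of four continents — South America (SA), North America
(NA), Eurasia (EU), Africa (AF) — arranged on a chain: dispersal is possible
only between SA–NA, NA–EU and EU–AF. A species may occupy up to three (not
necessarily contiguous) continents, giving 14 observable states plus one
internal "null" state.

Along branches the range evolves anagenetically (the dispersal–extinction
part of DEC):

* expansion from range $R$ to $R \cup \{a\}$ at rate $d \cdot
  |\{b \in R : b \sim a\}|$, where $\sim$ is adjacency — expansion into a
  non-adjoining continent has rate zero;
* contraction $R \to R \setminus \{a\}$ at rate $e$ per occupied area;
* a singleton contracts into the absorbing null state at rate $e$
  (lineage-range extinction along a branch). The null state is excluded
  from tips, the root prior and cladogenesis; it is standard DEC
  bookkeeping for mass that leaves the observable process.

At each node (cladogenesis) the ancestral range splits:

* narrow sympatry, singleton $\to$ two copies (weight 1);
* subset sympatry, widespread $\to$ one singleton member + the full range,
  both orderings (weight 1 each);
* vicariance, widespread $\to$ two disjoint exhaustive parts with at least
  one part a singleton, both orderings (weight 1 each) — the classic DEC
  convention that keeps the event set finite;
* jump dispersal (DEC+J only), one daughter keeps the range, the other
  founds a singleton on an adjacent unoccupied continent, both orderings
  (weight $j$ each).

Weights are normalised per ancestral state. Note that widely used DEC+J
software normalises its event weights differently; numeric agreement with
that software is not a goal of this package. The anchors of correctness
here are (i) the DEC limit $j = 0$, which this weighting reproduces
exactly, and (ii) an exhaustive-enumeration oracle: on small trees the
pruning likelihood and the marginal ancestral probabilities are checked
against a brute-force sum over every joint assignment of states to
internal nodes.

The likelihood is Felsenstein pruning with $P(t) = e^{Qt}$ along branches
and cladogenetic mixing at nodes. Fossil tips need no special treatment:
a dated extinct tip contributes an indicator vector at its observed range,
entering the pruning exactly like an extant tip — the tree's branch
lengths do the rest. The root prior is uniform over observable states and
the likelihood is not conditioned on survival; both are deliberate,
conventional defaults, and the root prior is exposed as a `root_prior`
argument for anyone who prefers otherwise.

Maximum-likelihood fitting (`fit_ml()`) is bounded quasi-Newton on
$\log_{10} d$, $\log_{10} e$ (and $j$ on its natural scale), with
$d, e \in [10^{-8}, 5]$, $j \in [0, 3]$, from a fixed deterministic grid of
up to five starting points. Determinism matters more than squeezing the
last decimals: every experiment here refits hundreds of trees.

Two continent-level summaries of the marginal ancestral distributions are
reported per node: the *inclusion* probability (the probability that a
continent is part of the ancestral area — the quantity used by the
accuracy metric) and the *split-mode* probability, where widespread mass
is divided equally among member continents (a 20% chance of NA+EU
contributes 10% to each; a plotting convention, kept for comparability).

## The forward simulator (the synthetic-data generator)

`simulate_tree()` runs a Gillespie simulation of a four-area ClaSSE-type
model with five rates, identical across continents:

| rate | meaning | prior |
|------|---------|-------|
| $\mu$ | per-continent extinction /Ma | $U(0,1)$ |
| $\delta$ | range expansion per adjacent continent /Ma | $U(0,1)$ |
| $\lambda_1$ | sympatric speciation /Ma (per occupied continent for widespread species) | $U(0,1)$ |
| $\lambda_2$ | jump-dispersal speciation per adjacent continent /Ma | $U(0,0.25)$ |
| $\lambda_3$ | allopatric speciation of two-continent species /Ma | $U(0,3)$ |

Simulated ranges are capped at two adjacent continents (the reconstruction
model still allows three — the asymmetry is intentional: reconstruction
should not be told the simulator's cap). Where the event vocabulary leaves
sub-cases open, the GeoSSE conventions fill them: sympatric speciation of
a widespread species leaves one daughter endemic to the triggering
continent and the other with the full range, and jumps from widespread
ranges to adjacent unoccupied continents are allowed (both toggleable).
The root lineage starts endemic on a uniformly drawn continent, recorded
as simulation truth.

A run stops the first time the extant count reaches the target; runs that
go totally extinct (or stall) are rejected and redrawn, up to
`max_attempts`. This is a first-passage stopping rule, not a full
generalised-sampling scheme; it matches the "same number of extant
species" design while keeping the sampler simple. Extinct lineages are
retained as dated tips carrying their range at extinction and last
occupied continent; every internal node stores the ancestor's true range
at the split, and the full trajectory/event log is kept for the
preservation model and for rate-recovery checks. Those checks pool event
counts and exposures over *all* runs, including rejected ones — pooling
only surviving runs would condition on the outcome and bias realised
rates.

## ABC selection of plausible trees

Candidate trees simulated under prior-drawn rates are compared with a
target tree through five summaries: total tree length; root height;
fraction of species still extant; number of extant species on two
continents; and the fraction of cherries (mutually sister tips) that are
single-continent endemics on different continents, with extinct members
scored by their last occupied continent. Distance per summary is the
absolute log error $\mathrm{ALE} = |\log(r_{\mathrm{target}} /
r_{\mathrm{sim}})|$; candidates are ranked by the largest of the five
(ALE$_{\max}$), ties broken by candidate index.

Choices worth knowing:

* the denominator of the sister-species criterion is the number of
  cherries, of any extinct/extant composition — the strictest reading of
  "sister species";
* zero-valued count summaries get a continuity offset before the log
  (a zero two-continent count becomes 0.5; a zero split-sister fraction
  becomes $0.5/\max(1, \text{cherries})$), otherwise the ALE is undefined;
* failed candidate simulations (total extinction before reaching the
  target) get infinite distance and rank last.

The package's default problem sizes are desk-scale: a few hundred
candidates with tens kept, against a synthetic target simulated under
moderate rates ($\mu = 0.2$, $\delta = 0.1$, $\lambda_1 = 0.3$,
$\lambda_2 = 0.05$, $\lambda_3 = 0.5$ — a regime with appreciable but not
overwhelming extinction). Selection quality, not scale, is what the
package's checks pin down: the ranking is verified against an independent
sort oracle at $10^4$ candidates.

## Biased fossil knowledge and partial inclusion

Fossil detection is a Poisson process along each species' lifespan with a
per-(time-bin × continent) intensity; the probability a species is known
at all is $1 - \exp(-f \Lambda_i)$ with $\Lambda_i$ the intensity integral
over its trajectory (widespread instants contribute the mean of the
occupied continents' rates). The global multiplier $f$ is calibrated by
bisection so the *expected* fraction of extinct species detected equals
the scenario's fraction known (25/50/75%); calibration against the
realised fraction is available but expectation is the default. The
default bias surface enriches recent bins and northern continents — the
structure of the real mammalian record — and only relative rates matter,
since $f$ is recalibrated per tree.

A scenario is (fraction known, fraction included, mode). Both fractions
are fractions of *all* extinct species: the included set is a uniform
subsample of the known set of size `round(frac_included × n_extinct)`,
and when the fractions are equal the whole known set is included.
Random-mode sampling is the stratum-homogeneous special case. Pruning to
the chosen fossil subset keeps all extant tips, removes the rest, and
collapses unary nodes so path lengths and MRCA ages of retained tips are
exactly preserved.

## Accuracy, binning, and predictability

Every internal node of a reduced tree is matched to the *smallest* clade
of the reference tree containing the same species (the MRCA of its tip
set, which may subtend extra extinct reference tips). Matching keys on
the full retained tip set — extant plus any retained fossils — which
degenerates to the extant-only set when no fossils are kept. Per
continent, accuracy is $1 - |p_{\mathrm{ref}} - p_{\mathrm{est}}|$ on the
inclusion probabilities, and total accuracy is the product over the four
continents. The formula is symmetric; "reference" is a role, not a
property of the formula. Two reference modes exist: *empirical* (the full
tree's own fitted profile — accuracy means agreement with the full-tree
inference) and *truth* (the simulator's recorded node ranges as 0/1
inclusions). Crown-group style evaluation needs no extra machinery: it is
the full-tree profile read at the node matched to the extant-only clade.

Because simulated trees differ in root age, accuracy is binned by
within-tree age quantiles (absolute-age edges are available for
empirical-style use). Per tree and bin the mean accuracy is taken; across
trees the mean of means and a 95% HPD — the shortest interval containing
95% of the per-tree means — are reported. Empty bins are reported as
missing, never as zero.

Predictability of the accuracy loss uses two covariates: node age, and
*sampling similarity* — the Fisher's exact p-value comparing the
continental proportions of extant species against those of all species
(extant and extinct) in the matched reference clade. The two rows of that
2×4 table are nested rather than independent; the p-value is used as a
descriptive covariate of distributional change, exactly as constructed in
the study this package implements, not as a hypothesis test. Zero columns
are dropped; tables with total ≤ 200 are tested exactly, larger ones by
Monte Carlo over `r` × `c` tables with fixed margins (`r2dtable`,
$10^5$ tables, fixed seed). Correlations are Spearman by default (the
estimator is otherwise unspecified; Pearson by flag), per tree, with
undefined correlations (constant accuracy, < 3 nodes) recorded as
missing. Predictor strengths are compared by a paired t-test on absolute
correlations (age correlates negatively, similarity positively); signed
comparison by flag. Degenerate inputs follow documented conventions: all
differences zero ⇒ $t = 0, p = 1$; constant non-zero difference ⇒
$p \to 0$ with a degeneracy flag.

## The end-to-end study

`run_simulation_study()` chains everything: target tree → ABC acceptance →
study trees under accepted rates → per-tree extant-only and
biased-fossil reconstructions → truth-mode accuracy → binned summaries,
batch-level comparison of the oldest age quantile, and predictability
correlations. Its defaults — 20 study trees of 100 extant tips each, 300
ABC candidates keeping 20, DEC with 2 optimiser restarts, 4 age-quantile
bins, 10 batches — are the package's chosen problem sizes for a
reproducible desk-scale experiment; at these sizes the meaningful outputs
are directions and orderings (does adding fossils help at old nodes,
which predictor of accuracy loss is stronger), not precise effect
magnitudes. Every stochastic stage derives its seed from the master seed,
so a study is bit-reproducible.

```{r}
library(fossilareas)
study <- run_simulation_study(seed = 1, progress = TRUE)
print(study)
write_study(study, "results/study")
```

## Numerical choices

* $e^{Qt}$ is computed densely by eigendecomposition of the 15×15
  generator (factorised once per parameter set, ~2 matrix products per
  branch), falling back to `Matrix::expm` when the eigenbasis is
  ill-conditioned (condition number above $10^8$); tiny negative entries
  from round-off are clamped to zero.
* Pruning partials are rescaled per node (log-accumulated) to avoid
  underflow on large trees; outside (up-pass) vectors are renormalised per
  node, which is harmless because marginals are normalised anyway.
* ALE is computed as $|\log a - \log b|$ (equal to $|\log(a/b)|$, but
  exact when one argument is 1 and better conditioned).
* Newick branch lengths are written at 17 significant digits; round trips
  preserve path-length matrices to well below $10^{-9}$ Ma.
* Derived tip ages snap values below $10^{-12}$ Ma to zero so extant tips
  compare exactly to 0; the extinct-flag tolerance (default $10^{-6}$ Ma)
  is exposed, because deciding which Late Pleistocene/Holocene losses to
  code as "extant" is the caller's scientific call, not the parser's.

## What the simulations do and do not show

The generator reproduces the features the study design needs: fossil tips
with correct ages and last-occupied continents, true ancestral ranges,
biased preservation with realistic time-and-continent structure, and tree
shapes filtered by ABC to resemble a target. It deliberately omits
time-varying rates (e.g. the Pleistocene uptick in intercontinental
dispersal), continent-specific rates, diversity dependence, and
phylogenetic uncertainty (trees are known without error). Passing tests
therefore show that the *method* behaves as designed under its own model —
fossils improve truth-mode accuracy at old nodes; node age and sampling
similarity predict the loss — not that those effect sizes transfer to any
particular empirical clade.

Known limitations worth stating plainly:

* The anagenetic range-loss rate $e$ is effectively non-identifiable in
  DEC-type likelihoods: cladogenetic subset-sympatry and vicariance
  already produce singleton daughters from widespread ancestors, so the
  MLE of $e$ sits at or near zero even on data simulated with $e > 0$.
  The package's recovery tests pin the dispersal rate $d$ (factor-2
  recovery) and guard that $\hat e$ is not inflated; treat fitted $e$
  values as boundary estimates, as users of any DEC implementation
  should.
* DEC vs DEC+J model choice is reported, not adjudicated; both are fitted
  on request and the statistical controversy around founder-event
  weighting is out of scope.
* The oldest-fossil-record baseline implemented here is the simplified
  version (continent of the oldest occurrence, ties reported), without
  occurrence-database modelling of preservation when reading the record.
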