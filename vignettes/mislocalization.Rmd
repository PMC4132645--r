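---
title: "Measuring mislocalization in lesion-deficit inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring mislocalization in lesion-deficit inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lesionmapr)
```

## The problem

Voxel-based lesion-symptom mapping (VLSM) asks, one voxel at a time, whether
damage at that voxel is associated with a behavioural label, and reads the
thresholded map as a localization of function. The inference is sound only if
collateral damage is random: if the damage a lesion causes *elsewhere* is
uncorrelated with damage at the critical locus, localization errors have no
preferred direction and wash out across patients. Stroke lesions violate this
assumption profoundly. Damage follows the branching vascular architecture, so
some regions are damaged with far less spatial variability than others, and a
region that is merely a consistent travelling companion of the critical one
can carry a *stronger* voxel-wise association than the critical region
itself. The error this induces is systematic: replication reinforces rather
than removes it.

Because the true functional anatomy is exactly what lesion mapping is trying
to estimate, the bias cannot be measured on a real lesion-deficit
relationship. The approach implemented here instead posits *hypothetical*
ground-truth models on top of a lesion cohort: a critical locus is declared,
labels are generated from the lesions themselves, the standard analysis is
run, and the displacement between the true and the inferred locus is
measured. Iterating over loci yields an error vector field over the brain.

## Synthetic cohorts and what they emulate

The clinical cohorts this methodology was developed on are not publicly
available, so the package ships generators that reproduce the one property
the argument needs: stereotyped, tree-structured collateral damage.

* **Territory tree** (`make_territory_tree`): the canonical hemisphere (a
  declared first-axis slab of the grid; synthetic grids carry no anatomical
  template, so the midline is user-declared) is partitioned into contiguous
  territories by a seeded Voronoi construction and organised into a rooted
  tree by breadth-first traversal of the territory adjacency graph from a
  trunk placed at the medial face. This is a minimal model of a branching
  supply architecture, not a claim about vascular anatomy.
* **Stereotyped lesions** (`sample_stereotyped_lesion`): a territory `u` is
  drawn uniformly; the lesion is the union of territories on the root-to-`u`
  path, each intermediate territory at depth `d` kept with probability
  `incl_decay^d` (default 0.85; trunk and `u` always kept), followed by
  per-voxel Bernoulli erosion at `noise_rate` (default 0.1). Distal damage
  therefore co-occurs with a low-variance proximal core, which induces the
  positive off-diagonal voxel-damage covariance that drives mislocalization.
* **Independent lesions** (`sample_independent_lesion`): i.i.d. per-voxel
  Bernoulli damage — the explicit counterfactual with no hidden structure.
  On such cohorts the mean error vector is expected to be near zero, and the
  test suite asserts this.
* **Volume floor**: every generator enforces a minimum lesion volume by
  redrawing (default 27 voxels = 216 mm^3 at the default 2 mm isotropic
  spacing, matching the conventional minimum for acute stroke segmentation),
  and `read_mask_volume` applies the same exclusion at load time.

Defaults were fixed once, before any acceptance measurement, at values a
desk-scale simulation study would call realistic; there are no published
covariance statistics for real stroke cohorts to calibrate against, so the
generator is documented as a qualitative model. Real data differ in ways the
generator does not attempt: anatomically realistic vessel geometry, grey/
white tissue classes, registration error, lesion-volume distributions with
heavy tails, and bilateral damage (the package's `collapse_to_hemisphere`
handles the latter for real masks; synthetic cohorts are generated
unilaterally).

## Ground-truth models

`ground_truth_spec` declares a hypothetical lesion-deficit rule:

* **single-voxel**: subject is affected iff the lesion covers the critical
  voxel (deterministic).
* **area-set**: affected, with probability `deficit_probability` (default
  0.9), iff at least `damage_fraction` (default 0.2) of the voxels of *any*
  target area are damaged. The threshold is inclusive and compared on
  integer counts (`ceiling(fraction * n_area - 1e-9)` damaged voxels
  suffice) to avoid floating-point boundary artefacts. The deficit coin is
  flipped once per subject per model from the spec's seed; stochasticity is
  one-sided — a subject failing the damage criterion is never labelled
  affected. Evaluation can regenerate labels with the probability forced to
  1 (`noiseless = TRUE`), so that label noise does not contaminate estimates
  of classifier performance.

## The mass-univariate engine

At every voxel damaged in at least `min_hits` masks (default 4), the 2x2
table of damage against label is tested with Fisher's exact test. The
two-sided exact p-value follows the point-probability convention: the sum of
hypergeometric probabilities of all tables with the observed margins whose
point probability does not exceed the observed one (a relative tolerance of
1e-9 absorbs floating-point ties). A chi-square (1 df, no continuity
correction) asymptotic mode is provided for fidelity experiments; the
qualitative phenomenon is mode-independent. Degenerate margins return p = 1.
The implementation is validated in the test suite against an exhaustive
enumeration oracle over every table with N <= 12 and against
`stats::fisher.test` on random tables.

The p-map is thresholded at `alpha / n_tested` (Bonferroni over *tested*
voxels, not the full grid, since models are only fitted there; default
familywise alpha 0.01) with strict inequality. The inferred locus is the
centre of mass — the unweighted mean of world coordinates — of the entire
suprathreshold set (no connected-component step is applied, because the
procedure being modelled thresholds and then summarizes), or alternatively
the peak voxel, with ties at the minimal p resolved as the centre of mass of
the tied voxels: deterministic and orientation-unbiased. An empty
suprathreshold set is a flagged, recorded failure, never a silent drop, and
failed models are excluded from mean/SD summaries (the reported summaries
describe produced clusters; the failure count is carried alongside).

Displacements are reported in mm as `inferred - true`; summary SDs are
population-style (denominator n) by default and configurable. Voxel indices
are 1-based as everywhere in R, with world coordinate
`origin + (index - 1) * spacing`; all comparisons and exports are in mm, so
the indexing convention is invisible downstream.

`single_voxel_sweep` exploits a structural identity: for model voxel `v` and
tested voxel `w`, the contingency cell `a` counts subjects damaging both, so
a single cross-product of the damage matrix serves every model, and exact
p-values reduce to lookup-table reads keyed by hit counts. Results are
identical to model-by-model computation (asserted in the tests), which makes
exhaustive sweeps over thousands of models run in seconds.

## The canonical fixtures

`make_two_region_toy` realises the textbook mislocalization geometry: an
extended critical line A, a compact collateral block B contained in *every*
affected lesion (zero spatial variability), and remote lesions C for the
unaffected group. Under the rule "any damage to A causes the deficit", every
B voxel associates perfectly with the label while every A voxel associates
only partially, so B attains the minimal p and the inferred centre of mass
lands near B regardless of which A voxel is taken as the true locus. Note
the labels here follow the *area* rule; under single-voxel labels the
defining voxel's own column is the label and trivially attains the minimal
p, which is the containment property, not the mislocalization one.

`make_two_area_fixture` extends this to two disjoint critical areas A1 and
A2 with a shared collateral block M: affected lesions damage a random
segment of one critical area and include M with probability 0.9; unaffected
lesions include M with probability 0.3 (strokes elsewhere also reach the
collateral region, without the deficit). M is then the strongest
single-voxel correlate of the deficit — the univariate top-k set concentrates
there, off both true areas — while the damage pattern over A1 and A2
determines the label exactly, so a linear classifier can recover the true
areas. The 0.9/0.3 collateral rates and the 4-of-10-voxel segment were fixed
at construction as the fixture's defining geometry: the segment keeps
per-voxel associations in the critical areas well below M's, and the 0.3
leak is what prevents a classifier from leaning on M.

## High-dimensional multivariate inference

`build_design` turns the cohort into an N-by-V binary matrix over tested
voxels. A linear support vector machine (via e1071/libsvm; inputs are binary
so no feature scaling is applied, and no class weighting) is tuned by
`c_search` over costs `2^e` for integer exponents -20..20 (the grid's range
is standard; the integer step is this package's choice and configurable),
using a single fixed set of random train/test splits reused across all
costs (a paired comparison; default 17 splits with a held-out fraction of
25/581 of N, at least one case). The chosen cost maximizes mean held-out
accuracy, ties resolved toward the smaller cost (stronger regularization).
Splits whose training half is single-class are redrawn with a bounded retry
budget.

The full-data fit at the chosen cost yields the primal weight vector, with
the sign convention fixed empirically so that positive weights push toward
'affected' (libsvm's internal sign depends on class encounter order).
`threshold_weights_topk` retains the k largest signed weights (damage
causing deficit is the direction of interest; an absolute-weight mode
exists), with ties broken by canonical voxel order; retained-set sizes are
matched to the univariate set for comparison, and `compare_localization`
reports Dice overlap with the true critical set plus centre-of-mass offsets.
Two display-matching conventions exist in the literature (k equal to the
true union's size, or to a fraction of it); `k` is simply a parameter here,
defaulting to the true union's size. libsvm's termination tolerance is kept
at its field-standard default 1e-3 (exposed as an argument); on all problems
in the test suite, tightening it does not change any reported quantity.

## Numerical and design choices

* Seeds: every stochastic operation consumes its own seed, derived from a
  global seed and a stage name (`derive_seed`), and restores the RNG state
  afterwards; pipelines re-run bit-identically (asserted in the tests, down
  to file checksums).
* `significance` uses strict `p < threshold`, matching the thresholding
  convention of the procedure being modelled; since exact p-values can equal
  1, a threshold of exactly 1.0 does not retain uninformative voxels.
* Ties everywhere (peak, top-k) resolve by documented deterministic rules,
  never by RNG.
* Degenerate inputs are first-class: empty significant sets and single-class
  label vectors are flagged failures with their own bookkeeping; empty masks
  and out-of-range parameters are errors with typed conditions.

## Problem sizes

The test suite and the acceptance script run at desk scale, chosen so the
full pipeline (cohort simulation through exhaustive sweeps and the SVM
search) completes in minutes on one core while every property of interest is
comfortably powered: 16^3 grids at 2 mm spacing, cohorts of 120-300
subjects, exhaustive single-voxel sweeps over ~2000 models, 8-area
parcellations, 12-bin damage-fraction sweeps, and the full 41-cost SVM
search with 17 splits. All acceptance properties are scale-free; the MNI-like
91 x 109 x 91 grid is supported but not the default.

## Limitations

The generators demonstrate that the analysis machinery detects and
quantifies stereotypy-driven mislocalization when it is present and reports
none when it is absent; passing tests say nothing about the *magnitude* of
mislocalization in any real cohort, which depends on real vascular anatomy.
Deficits are binary; graded scores are out of scope. Multivariate recovery
is demonstrated for two critical areas and is not guaranteed for more
complex architectures. Lesion-volume covariate corrections are deliberately
not implemented: under multi-locus dependence the error field is not
invertible, so "correcting" published coordinates with it would not be
valid.
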