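---
title: "Reference-free deconvolution and cancer-intrinsic subtyping: model and methods"
author: "declust authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-free deconvolution and cancer-intrinsic subtyping: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(declust)
```

## The problem

Bulk tumor expression profiles mix signal from cancer cells, infiltrating
immune cells, and stromal cells (fibroblasts, endothelium). Molecular
subtypes called on the bulk profile therefore confound cancer-cell-intrinsic
biology with microenvironment composition, and reference-based deconvolution
methods need compartment expression profiles that are rarely available for
the tissue at hand. `declust` addresses both problems at once: from a single
genes × samples log-expression matrix it jointly estimates

1. per-sample compartment fractions (cancer, immune, stromal),
2. a cancer-intrinsic subtype label per sample, and
3. cohort-level reference expression profiles for each cancer subtype and
   for the immune and stromal compartments,

without any external reference profiles. Marker gene lists (immune and
stromal) are used only to initialize the fractions.

## The model

Let $o_{ij}$ be observed log expression of gene $i$ in sample $j$ (natural
log internally). With subtype assignment $s(j) \in \{1..K\}$, fractions
$(f_j^{can}, f_j^{imm}, f_j^{str})$ on the unit simplex, and log-scale
profiles $E_i^{(k)}, E_i^{imm}, E_i^{str}$, mixing is linear on the natural
scale:

$$
\exp(o_{ij}) \approx \exp\!\big(E_i^{(s(j))}\big) f_j^{can}
 + \exp\!\big(E_i^{imm}\big) f_j^{imm}
 + \exp\!\big(E_i^{str}\big) f_j^{str} .
$$

All parameters minimize the squared error on the log scale (a log-normal
noise assumption):

$$
\mathrm{SSE} = \sum_{i,j} \Big( o_{ij} - \log\big[\textstyle\sum_c
\exp(E_i^{c(j)}) f_j^c\big] \Big)^2 .
$$

The optimization objective is this sum; the mean variant
(÷ genes × samples) feeds the BIC used to choose $K$. The estimated profiles
are cohort-level references, not per-sample profiles, and each sample
carries exactly one cancer subtype; both are deliberate model restrictions.

### Identifiability remarks

With $n$ samples and $G$ genes there are $Gn$ observations against
$G(K{+}2) + 2n + n$ unknowns, so the problem is overdetermined at cohort
scale. Two soft degeneracies shape the optimization: (i) immune and stromal
profiles separate only to the extent that $f^{imm}$ and $f^{str}$ vary
non-proportionally across samples; (ii) rescaling a subtype's linear
profile trades off against its members' cancer fractions, with the simplex
constraint pinning the scale only weakly. Point (ii) drives the algorithmic
choices below.

## The fitting algorithm

A two-layer block-coordinate scheme:

* **Step 0 (initialization).** Per-sample immune/stromal marker scores
  (mean log expression of the matched markers) are mapped to fractions via
  $f_j^{imm} = \exp(\bar o_{imm,j}) \cdot C_{imm}$ (stromal analogous),
  cancer taking the remainder. The two constants are found by a 10 × 10
  grid search: each axis spans $(0, c_{max}]$ with
  $c_{max} = 1 / \max_j \exp(\bar o_j)$ (largest implied single-compartment
  fraction is 1), discretized at bin centers. Pairs implying
  $f^{imm} + f^{str} > 0.99$ for any sample are infeasible and skipped.
  Each feasible pair is scored by one non-iterated pass of the fit (step 1
  without inner iteration, then one fraction pass); the smallest objective
  wins. The grid runs once per candidate $K$.
* **Inner layer (given fractions).** First a single-subtype fit (per-gene
  L-BFGS-B on the three profile values); K-means over the columns of the
  residual matrix (25 restarts, fixed seed, labels renumbered by descending
  cluster size) initializes the labels. Then alternate: (1.1) per-gene
  profile optimization, (1.2) exhaustive per-sample reassignment (ties to
  the lowest subtype index), until the assignment stops changing or the
  relative objective change drops below `rel_tol_inner`.
* **Outer layer.** Alternate the inner layer with per-sample fraction
  optimization — 2 free parameters per sample in $[0,1]^2$, cancer fraction
  as the remainder with a soft feasibility penalty keeping it above 0.01,
  followed by simplex projection; a sample keeps its warm start if the
  optimized value is worse. Stop at `rel_tol_outer` or `max_outer_iter`.

Three implementation choices depart from the naive reading of this scheme;
all preserve the objective, constraints, and fixed points:

* **Warm-started inner loops.** Re-running the single-subtype fit and
  K-means re-initialization at every outer iteration would discard label
  information and cannot guarantee a monotone objective. Only the first
  outer iteration performs step 0 of the inner layer; later iterations warm
  start from the previous profiles and labels. Every accepted step is
  guarded to never increase the objective (within 1e-9), and the test suite
  asserts this on every run.
* **Stacked separable solves.** The per-gene profile problems are
  independent, so they are solved in one box-constrained L-BFGS-B call on
  the stacked parameter vector with analytic gradients — the same
  minimizers at a fraction of the interpreter overhead. Per-gene box
  constraints are the observed range ± `profile_bounds_pad` (2 log units);
  a compartment whose true expression sits far below the bulk mixture
  contributes no identifiable signal there, so the bound costs nothing
  statistically.
* **Joint refinement of the continuous blocks.** Pure alternation crawls
  along the profile-scale/fraction ridge (degeneracy (ii) above): on
  zero-noise test problems the objective still shrank ~10% per outer
  iteration after 60 iterations. Each outer iteration therefore ends with
  one L-BFGS-B pass over *all* profile values and fractions at fixed
  assignment (`refine_maxit` iterations, default 500), which collapses the
  ridge; with it, zero-noise problems reach fraction correlation ≈ 1.0
  within ~8 outer iterations.

### Choosing the number of subtypes

For each $K$ in the candidate range (default 1–10) the full fit yields the
mean-variant MSE and
$\mathrm{BIC}(K) = \log(\mathrm{MSE}) \cdot n + \log(n) \cdot K$.
Two readings are combined: the BIC minimum $K_{min}$ (ties toward smaller
$K$) and the elbow $K_{elbow}$, defined as the interior point maximizing the
discrete second forward difference
$\mathrm{BIC}(k{-}1) - 2\,\mathrm{BIC}(k) + \mathrm{BIC}(k{+}1)$ (ties
toward smaller $K$; a monotonically increasing curve returns its first
point). When they disagree the midpoint is taken, half-values rounded down
— parsimony. The elbow definition and the rounding direction are package
decisions; no standard operationalization exists for either.

On noise-free data the MSE at and beyond the true $K$ is the optimizer's
convergence floor rather than a statistical quantity, so $\log(\mathrm{MSE})$
can wobble the location of the minimum; the elbow is robust there, and the
midpoint rule usually lands on the true $K$ (8/10 seeds in the bundled
selection test; the misses pick $K{+}1$).

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `rel_tol_inner`, `rel_tol_outer` | 1e-6, 1e-5 | relative objective-change stops (unitless) |
| `max_inner_iter`, `max_outer_iter` | 20, 10 | iteration caps |
| `kmeans_restarts` | 25 | K-means restarts for label initialization |
| `profile_bounds_pad` | 2 | log-units of padding on per-gene profile boxes |
| `optim_maxit`, `optim_factr` | 100, 1e7 | L-BFGS-B budget for profile fits |
| `grid_optim_maxit` | 15 | looser budget inside the constant grid search |
| `refine_maxit` | 500 | budget for the joint profile+fraction refinement |
| `min_cancer_fraction` | 0.01 | feasibility floor on the cancer fraction |
| `seed` | 1 | drives K-means restarts; everything else is deterministic |

A note on the zero-noise regime: when the model can fit the data exactly,
the objective heads to 0 and its *relative* change never settles below the
tolerance, so the outer loop runs to `max_outer_iter` and warns. This is a
perfect-fit pathology, not a failure — the recovered parameters are at
numerical accuracy by then. Noisy data converge by the relative criterion.

## The synthetic-data generator

`simulation_config()` + `simulate_dataset()` emulate the benchmark design
of the simulation study:

* **Profiles.** A shared per-gene log-normal base (mean 4, sd 1, natural
  log) plus independent compartment-specific deviations (sd 1) makes the
  cancer, immune, and stromal profiles related but distinct
  (cross-compartment correlation ≈ 0.5, as in real tissue where
  housekeeping structure is shared). Subtype-specific cancer profiles add
  per-subtype perturbations whose scale is set by bisection so the realized
  mean pairwise Spearman correlation hits the target (default 0.87).
  Immune and stromal subtype *variants* are generated the same way at the
  (much higher) non-cancer target (default 0.98) and averaged into single
  ground-truth profiles — the fitted model assumes no such variants, so
  simulating them probes exactly that model violation. With
  `noncancer_subtype_specific = FALSE` the variants coincide and a
  zero-noise simulation is an exact realization of the fitted model
  (`observed == reconstruction`, used by the round-trip tests).
* **Markers.** Designated marker genes take the value
  max(other compartments) + `marker_logfc` (default 2 log units) in their
  own compartment, identically across subtype variants.
* **Fractions.** Subtype labels follow configurable proportions (default
  0.5/0.35/0.15, a bladder-cancer-like split); fractions are Dirichlet
  draws around per-subtype means (default purity rising 0.55→0.70 with the
  remainder split 60/40 immune/stromal) at concentration 25.
* **Noise.** Either additive Gaussian on the log mixture (log-normal
  model; sd is the `noise_level`) or negative-binomial counts with mean
  equal to the linear mixture (size 10 by default), observed as
  log(count + 1). A plausible log-scale sd range for bulk tumor cohorts is
  0.2–0.6.

What the generator does **not** emulate: heavy-tailed and zero-inflated
expression, gene-gene correlation beyond the compartment structure,
platform effects, and the specific collinearity of real cell-line/immune/
fibroblast reference panels. Gaussian-based synthetic profiles separate
more cleanly than real references, so recovery metrics here are optimistic
relative to real data — the bundled benchmark reproduces the qualitative
behavior (accuracy falling with noise, the method ordering below), and its
profile-recovery accuracy sits somewhat above the level reported for
reference panels derived from real data.

## Comparators and evaluation

Two baselines frame the fit: plain K-means on the bulk matrix, and a
two-step strategy — subtract reference immune/stromal signal in linear
scale, $(o^{lin} - \mathrm{ref}^{imm} f^{imm} - \mathrm{ref}^{str}
f^{str}) / f^{can}$, floor negative values, quantile-normalize, K-means.
When the references come from a different scale than the data, the
reference matrix is first rescaled so its median matches the data's
(`rescale = "median"`); with references on the data scale, `"none"` makes
the subtraction an exact algebraic inversion at zero noise.

Recovery metrics (`evaluate_recovery`): mean across-sample Pearson
correlation of fractions over the three compartments; best-permutation
label agreement via maximum-weight bipartite matching on the contingency
table (exact for integer counts; adjusted Rand index reported alongside);
mean across-gene Pearson correlation of profiles over compartments, cancer
columns matched by the same label permutation (Spearman reported for
diagnostics).

The method-ordering experiment (full model ≥ two-step ≥ bulk K-means at
high noise) is run with *shared* per-subtype fraction means (0.55/0.25/0.20)
and Dirichlet concentration 5 — purity sd ≈ 0.17, the wide spread typical
of real cohorts. That is the confounded regime the comparison is about:
with the generator's default distinct per-subtype purity means, purity
itself becomes a subtype label and bulk K-means wins trivially, which says
nothing about any method. The two-step comparator receives the true
references and true fractions, so only its intrinsic noise amplification
(division by $f^{can}$) limits it — an idealized, conservative comparison.

## Problem sizes used by the bundled checks

The test suite and the acceptance script regenerate everything from code:
profile-recovery accuracy on 5 seeds of 1500 genes × 100 samples across
noise sd 0.2–0.5; exact recovery on 300 × 60 at zero noise; method ordering
on 10 replicates of 240 × 48 at sd 0.5; subtype-number selection on 10
seeds of 160 × 36 over K = 1..5; and oracle equivalence checks on small
random instances. These sizes were chosen so each check isolates one claim
at cohort-like aspect ratios.

## Known limitations

* One subtype per sample; no mixtures of cancer states within a sample.
* No subtype structure for the immune or stromal compartments (the
  simulator can generate it; the model averages over it).
* Cohort-level profiles only — no per-sample purified profiles.
* Marker quality matters only through initialization, but a marker set
  that is badly wrong can leave the grid search without a feasible pair
  (reported as an explicit error).
* The BIC constant-selection interplay means the selected K should be read
  together with the emitted BIC curve, especially for flat curves.
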