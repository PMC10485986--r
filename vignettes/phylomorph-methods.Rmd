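---
title: "Models, assumptions and design choices in phylomorph"
author: "phylomorph maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, assumptions and design choices in phylomorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylomorph)
```

## The scientific problem

Across a clade, does ecology predict the shape of an anatomical structure?
The canonical workflow quantifies shape with 3-D landmarks, removes
non-shape variation (position, orientation, size) by Generalized Procrustes
Analysis, and asks whether ecological factors explain the residual shape
variation while accounting for the non-independence of related species.
`phylomorph` implements that workflow end to end for multi-module landmark
data — structures such as highly kinetic skulls, where mobile elements must
be aligned and analyzed in isolation because their relative positions in a
preserved specimen are arbitrary — together with the simulation machinery
needed to ask the harder follow-up question: *when can the resulting
p-values be believed?*

## Procrustes geometry

`generalized_procrustes()` centers every configuration, scales each to unit
centroid size, and then alternates (i) optimally rotating each
configuration onto the current consensus (proper rotations only — with
bilaterally landmarked structures a reflection is anatomical nonsense) and
(ii) recomputing the consensus as the unit-size mean, until the consensus
changes by less than `tol` (default `1e-10`, at most 200 iterations; both
configurable, and non-convergence returns results flagged
`converged = FALSE` rather than failing). The GPA objective — the summed
squared distance of all specimens to the consensus — is non-increasing
across iterations, and the test suite asserts this.

Numerical conventions, chosen so results are bit-reproducible across
platforms:

* the optimal rotation comes from the SVD of the cross-product matrix with
  the determinant-correction on the smallest singular value; degenerate
  (coplanar/collinear) optima fall back to the SVD's own deterministic
  tie-break, with a warning;
* after convergence the entire aligned set is rotated so the consensus lies
  along its principal axes, with each axis signed so its largest-magnitude
  loading is positive (if that sign pattern implies a reflection, the third
  axis is flipped);
* aligned shapes are finally projected orthogonally onto the tangent plane
  at the consensus, the linear space in which ordinary multivariate
  statistics are valid. Re-projection is the identity, and the consensus
  stored in the result is exactly the arithmetic mean of the projected
  shapes.

Scaling to unit centroid size follows the "full Procrustes" convention:
size is removed from shape and re-enters the models only as
`log_centroid_size`, computed per module from that module's landmarks.

## The three inference engines

All three engines reduce a phylogenetic problem to an ordinary one through
the same transform: if `C` is the Brownian-motion covariance of the tree
(shared root-to-tip branch length for each pair of taxa), the symmetric
inverse square root `P = C^(-1/2)` (eigendecomposition, not Cholesky, so the
transform is unique and order-invariant) turns GLS into OLS on `P Y` and
`P X`. With `C = I` every engine collapses exactly to its non-phylogenetic
counterpart — an invariant the acceptance tests check to `1e-8`.

**Multivariate PGLS with RRPP** (`fit_pgls_rrpp`). Sums of squares are
sequential (Type I) in the user's term order; the shipped pipelines use
habitat, then diet, then size, and the documentation warns that results are
order-dependent. For each term the reduced model contains all preceding
terms; its transformed residuals are row-permuted (`n_perm` random draws,
default 999, one schedule shared by all terms), the term's F is recomputed,
and `p` is the proportion of the `n_perm + 1` values — observed arrangement
included — at or above the observed, so `p >= 1/(n_perm+1) > 0` always.
The effect size `Z` standardizes `log F` within its permutation
distribution, the convention that makes effects comparable across terms.

**Univariate GLS with Wald tests** (`fit_gls_terms`). The GLS estimate
`(X'C⁻¹X)⁻¹X'C⁻¹y` with per-term Type II Wald chi-square tests: each term's
coefficients are tested given all other terms, which respects marginality
for the additive models used here (no interactions are constructed). The
test suite pins the coefficients against `nlme::gls` with a Brownian
correlation structure.

**Phylogenetic two-block PLS** (`ppls_integration`). Both blocks are
transformed by `P`, column-centered, and the cross-block covariance is
decomposed by SVD; `r_pls` is the correlation of the first singular-score
pair. Significance permutes the rows of the *second transformed* block
(transform once, permute after — the convention of the standard
implementation). Diet proportions enter raw and centered; no log-ratio
transform is applied, mirroring the direct use of proportion data in the
workflow this package supports.

### Rank-deficient designs

Ecological factors with many levels produce, in realistically sized
datasets, singleton levels that can alias each other (the one annelid
specialist is also the one cryptozoic species). By contract a singular
design is an error, and a factor collapsing to a single level is an error
naming the term. For pipeline use, `drop_aliased = TRUE` instead drops the
aliased columns with a warning and adjusts the term's degrees of freedom —
the `lm()` convention — and errors only if a term is absorbed entirely.
The robustness sweep never fits such designs: a subset draw whose design is
rank-deficient counts as failing the factor-level requirement and is
redrawn (with the redraw counted), exactly like a subset that loses a
factor level outright.

## The robustness experiment

`robustness_sweep()` measures how the PGLS p-values behave when the
shape–ecology association is destroyed by construction: for each replicate a
fresh uniform random subset of species is drawn and the ecological rows are
randomly permuted within it (habitat and diet move together by default,
preserving their empirical association; an independent-shuffle mode
exists because the choice is not forced). The size covariate is never
permuted. Label multisets are conserved by construction, and the sweep
records every term's p-value per (scenario, subset size, replicate) cell.

`bm_control()` is the negative control separating "property of the method"
from "property of the data": it estimates an evolutionary rate matrix from
reference shape data (via its principal component scores, one variable per
positive-variance component), simulates a genuinely Brownian response with
that covariance on the same tree, and reruns the permuted-label sweep. For
Brownian data the permuted-label p-values are uniform — median ≈ 0.5,
Type-I error ≈ 0.05 — and the acceptance suite verifies both at scale.

When shape evolution is *not* Brownian, the permuted-label test becomes
anticonservative, and the inflation grows with the number of species. The
intuition: the Brownian transform `P` whitens data that truly have
covariance `σ²C ⊗ R`; applied to anything else it manufactures structure,
and the residual-randomization null (row-exchangeable in transformed space)
no longer matches the randomization actually performed (label permutation
in raw space). The package's generator provides a controllable violation —
Brownian increments replaced by variance-matched Student-t draws (default
3 df) — and with it the acceptance suite reproduces the anomaly
directionally: pooled habitat+diet Type-I error at α = 0.05 rises well
above 0.05 and increases monotonically from 25 to 125 species. The
Student-t mechanism is a *chosen* violation, not a claim about what real
shape data do; the experiment establishes sensitivity of PGLS to the
violation, not the identity of the violation in any empirical dataset.

### Conditional versus unconditional calibration

One subtlety discovered while validating the suite, worth recording. If
*all* permutation replicates are run against a single simulated response
dataset, the median p-value is hostage to that draw: conditional on one
response realization the sequential RRPP label test is only approximately
exact (the transform does not commute with raw-space label permutation),
and measured pooled medians ranged roughly 0.3–0.7 across response draws at
30–100 variables and 100 taxa. The acceptance quantities are therefore
estimated *unconditionally* — a fresh Brownian response is simulated for
every replicate — which is the quantity the calibration claim is about; so
estimated, the pooled median is stable at 0.49–0.52 across seeds.

## The synthetic-data generator

`sim_config()` fixes the world the tests live in. Defaults, with rationale:

| parameter | default | meaning |
|---|---|---|
| `n_taxa` | 48 | taxa in the desk-scale fixture (full profile: 160) |
| `module_partition` | 8/6/6 landmarks in 3 modules | desk-scale stand-in for the 73-landmark, 8-module full profile (`paper_scale_config()`) |
| `habitat_jump_rate` | 1 | symmetric Markov jumps per unit tree depth; gives habitat realistic phylogenetic signal (`0` freezes the root state, `habitat_iid` removes signal) |
| `sigma_evo` | 0.05 | per-coordinate Brownian rate of shape deviations over the unit-depth tree, in Procrustes units — a few percent of configuration size, typical of interspecific shape variation |
| `habitat_effect` | 0.03 | habitat-specific mean-shape displacement, comparable to the evolutionary noise so it is detectable but not overwhelming |
| `diet_effect` | 0.02 | shape displacement along fixed directions weighted by centered diet proportions |
| `allometry_slope` | 0.02 | shape displacement per unit log size |
| `size_sd` | 0.5 | Brownian SD of log centroid size (around `log(30)`, a ~30 mm structure) |
| `evolution`, `heavy_df` | `"bm"`, 3 | `"heavy_tailed"` replaces Brownian increments with variance-matched Student-t draws — the controllable violation used by the robustness experiment |
| `tree_prune_to` | `NULL` | optionally write a tree covering only part of the taxon set (the full profile prunes 160 → 148, emulating incomplete phylogenetic coverage) |

Each taxon's preferred prey category is drawn from a habitat-specific
distribution over three categories rather than mapped 1:1 from habitat: a
deterministic map makes the diet factor *exactly* collinear with the
habitat factor and every model unidentifiable by construction. Raw
specimens are "digitized" with a random proper rotation, a translation, and
a scale equal to the taxon's simulated size, so GPA has real work to do and
`log_centroid_size` recovers the size covariate (plus the small
shape-dependent term `log CS` of the unit-size shape).

What the generator does **not** emulate: real skull geometry (landmarks are
abstract configurations), measurement error, missing landmarks, within-
species variation, and correlated module evolution. A green test therefore
establishes that the *statistical machinery* behaves as specified on data
with the assumed structure — not that any empirical dataset satisfies that
structure.

## Numerical choices

* Eigenvalues of a phylogenetic covariance below `1e-12 ×` the largest are
  a hard error (zero-length terminal branches), never silently
  regularized.
* Rate matrices use the maximum-likelihood divisor `n` (the convention of
  the tooling this replaces); `n − 1` is available.
* BM simulation uses symmetric PSD square roots of both `C` and `R`, so a
  seed fully determines the output and taxon order is respected.
* Permutation p-values compare with `>=` after subtracting `1e-12`, so
  exact ties (e.g. the observed arrangement re-drawn) count as extreme —
  the conservative direction.
* `log F` values are floored at `1e-300` before the effect-size Z
  computation to keep degenerate permutations finite.
* Fixture manifests are written with 17 significant digits so that
  regenerating a bundle from its manifest is byte-identical.

## Known limitations

* Brownian motion is the only evolutionary covariance (no
  Ornstein–Uhlenbeck or λ-rescaling); that restriction is the point of the
  robustness experiment, not an oversight.
* Sequential SS makes multivariate results order-dependent; the term order
  is a documented configuration knob.
* No sliding semilandmarks, missing-landmark estimation, or bilateral
  symmetry decomposition.
* The univariate robustness engine analyzes a single response column (a PC
  score) per sweep.
* PPLS applies no compositional transform to diet proportions; users with
  strongly zero-inflated compositions may prefer a log-ratio preprocessing
  of their own before calling `ppls_integration()`.
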