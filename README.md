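# phylomorph

Comparative analysis of multi-module 3-D landmark data in a phylogenetic
framework — for evolutionary morphologists asking whether ecology (habitat
use, diet) predicts the shape of an anatomical structure across a clade,
and for methodologists who want to know when that inference can be trusted.

The package implements the full analysis graph such studies use:

- **Generalized Procrustes Analysis (GPA)** per anatomical module:
  configurations are centered, scaled to unit centroid size
  (`CS = sqrt(sum_i ||x_i - x̄||²)`), iteratively rotated onto the evolving
  consensus, and projected onto the tangent space at the consensus. Modules
  (e.g. skull elements connected by kinetic joints) are aligned in
  isolation, because their relative positions are preservation artifacts.
- **Shape PCA** (covariance-based) of the aligned coordinates, with
  morphospace summaries (per-group centroids and dispersions).
- **Multivariate PGLS with RRPP**: the model `Y ~ habitat + diet + size` is
  estimated by transforming response and design with `C^(-1/2)`, where
  `C_ab` is the branch length shared by taxa `a` and `b` under Brownian
  motion; sequential (Type I) sums of squares are tested by residual
  randomization (permuting reduced-model residuals, `n_perm` draws plus the
  observed arrangement), with effect size
  `Z = (log F_obs − mean(log F*)) / sd(log F*)`.
- **Univariate GLS** on PC scores with Type II Wald chi-square term tests.
- **Phylogenetic two-block PLS** (r-PLS) of shape against diet proportions.
- **Brownian-motion machinery**: phylogenetic covariance, evolutionary rate
  matrix `R = (Y − 1â')' C⁻¹ (Y − 1â') / n`, and seeded multivariate BM
  simulation `Y = 1·root' + C^(1/2) Z R^(1/2)`.
- **The robustness experiment**: label-permutation sweeps over species
  subsets that measure the Type-I error of PGLS on shape data, plus a
  BM-simulated control. Under genuinely Brownian responses the permuted-label
  p-values are uniform (median ≈ 0.5); under heavy-tailed, non-Brownian
  shape evolution they skew toward zero, and the inflation *grows* with the
  number of species — an anomaly this package reproduces and quantifies.
- **A synthetic-data generator** (trees, ecology tables, raw landmark files
  with known effects and a controllable Brownian-motion violation) so every
  stage runs and is validated without any external data.

## Worked example

```r
library(phylomorph)

tree <- simulate_tree(48, seed = 1)                      # pure-birth, unit depth
eco  <- simulate_ecology(tree, sim_config(), seed = 2)   # habitat, diet, records
lms  <- simulate_landmark_dataset(tree, eco, sim_config(), seed = 3)

md  <- match_and_prune(lms, eco, tree)                   # shared taxon order
aln <- module_alignments(md$landmarks)$braincase         # per-module GPA
pca <- shape_pca(aln)
#> <shape_pca> 17 components; PC1 48.7%, PC2 14.5% of variance

C    <- bm_covariance(md$tree, md$taxa)
pred <- data.frame(habitat = md$ecology$habitat,
                   primary_diet = md$ecology$primary_diet,
                   size = aln$log_centroid_size)
fit_pgls_rrpp(flatten_shapes(aln), pred, C, n_perm = 999, seed = 10)
#>           term df     SS     MS     F      Z     p
#> 1      habitat  6 0.4303 0.0717 1.654  2.602 0.004
#> 2 primary_diet  9 0.5130 0.0570 1.314  1.561 0.061
#> 3         size  1 0.0297 0.0297 0.686 -0.598 0.733
#> 4    Residuals 31 1.3444 0.0434    NA     NA    NA
#> 5        Total 47 2.3175     NA    NA     NA    NA
```

The generator injected a habitat effect of 0.03 Procrustes units (its
default), and the fit recovers it: habitat is significant (permutation
p = 0.004, effect size Z = 2.6) while size, injected weakly, is not. The
diet block can also be tested as proportions via two-block PLS on the
quantitative-diet subset (taxa with > 10 diet records):

```r
eco_q <- filter_quantitative_diet(md$ecology)
idx   <- match(eco_q$taxon, md$taxa)
ppls_integration(flatten_shapes(aln)[idx, ], diet_proportion_matrix(eco_q),
                 C[idx, idx], n_perm = 999, seed = 10)
#> <pls_result> r-PLS = 0.596, P = 0.441 (999 permutations)
```

(High r-PLS with a non-significant permutation p is typical at n = 31 taxa
with 24 shape variables — the null distribution of the first singular-pair
correlation is itself high.)

## Command line

```sh
Rscript inst/cli/phylomorph simulate --out fixture --seed 1
Rscript inst/cli/phylomorph all --tree fixture/tree.nwk \
    --landmarks fixture/landmarks.csv --ecology fixture/ecology.csv \
    --modules fixture/modules.csv --out results --n_perm 999 --seed 1
Rscript inst/cli/phylomorph robustness --tree fixture/tree.nwk \
    --landmarks fixture/landmarks.csv --ecology fixture/ecology.csv \
    --modules fixture/modules.csv --out robust --subset_sizes 25,35,45
```

Subcommands: `simulate`, `gpa`, `pca`, `pgls`, `gls`, `ppls`, `robustness`,
`all`. Exit codes: 0 success, 2 validation error, 3 numerical failure.

## Vignette

`vignettes/phylomorph-methods.Rmd` documents the models and their
assumptions, every tunable parameter of the synthetic-data generator, the
numerical conventions (tie-breaks, tolerances, sign conventions), and what
the robustness experiment does and does not establish.
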