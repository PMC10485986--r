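# fixture builders shared across test files; everything is generated in code

fix_tree <- function(n = 48, seed = 1) simulate_tree(n, seed = seed)

fix_eco <- function(tree, seed = 2, cfg = sim_config(n_taxa = length(tree$tip.label)))
  simulate_ecology(tree, cfg, seed = seed)

# a small fully matched synthetic dataset (tree + ecology + raw landmarks)
fix_dataset <- function(n = 48, seed = 1, cfg = NULL) {
  cfg <- cfg %||% sim_config(n_taxa = n)
  cfg$n_taxa <- n
  tree <- simulate_tree(n, cfg$birth_rate, seed = seed)
  eco <- simulate_ecology(tree, cfg, seed = seed + 1)
  lm <- simulate_landmark_dataset(tree, eco, cfg, seed = seed + 2)
  match_and_prune(lm, eco, tree)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random landmark set with no structure, for I/O round trips
random_landmark_set <- function(n = 5, p = 7, seed = 99) {
  set.seed(seed)
  landmark_set(array(rnorm(n * p * 3), c(n, p, 3)),
               taxa = paste0("Genus_sp", seq_len(n)),
               module_of = rep(c("A", "B"), length.out = p))
}

# predictor frame for the standard three-term model
fix_predictors <- function(md, aln) {
  data.frame(habitat = md$ecology$habitat,
             primary_diet = md$ecology$primary_diet,
             size = aln$log_centroid_size)
}

# apply a common random rigid-motion + scale corruption to every specimen
corrupt_common <- function(lm, seed = 7) {
  set.seed(seed)
  R <- phylomorph:::random_rotation()
  s <- exp(rnorm(1)); tr <- runif(3, -5, 5)
  coords <- lm$coords
  for (i in seq_len(dim(coords)[1]))
    coords[i, , ] <- sweep(s * coords[i, , ] %*% R, 2, tr, `+`)
  landmark_set(coords, lm$taxa, module_of = lm$module_of,
               landmark_labels = lm$landmark_labels)
}
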