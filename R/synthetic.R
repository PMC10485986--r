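#' Configuration for the synthetic-data generator
#'
#' The generator produces trees, ecology tables and raw landmark datasets
#' with the statistical structure the analysis pipeline assumes: phylogenetic
#' signal in habitat, habitat-linked diet proportions, overdispersed diet
#' record counts, Brownian (or heavy-tailed, non-Brownian) shape evolution,
#' habitat-specific mean-shape displacement, allometry, and raw-specimen
#' corruption (rotation, translation, scale) so Procrustes alignment is
#' non-trivial.
#'
#' The default fixture (48 taxa, 20 landmarks, 3 modules) is deliberately
#' smaller than a full study so test suites run in minutes;
#' [paper_scale_config()] gives the full-scale profile (160 taxa, 73
#' landmarks, 8 skull modules, tree pruned to 148 tips).
#'
#' @param n_taxa number of species (default 48).
#' @param module_partition named integer vector of landmarks per module
#'   (default braincase 8, maxilla 6, mandible 6).
#' @param habitat_jump_rate Markov jump rate for habitat evolution on the
#'   unit-depth tree (default 1; 0 freezes the root state everywhere).
#' @param habitat_iid draw habitat iid instead of on the tree (default
#'   FALSE).
#' @param diet_categories_set prey categories (default [diet_categories()]).
#' @param evolution `"bm"` or `"heavy_tailed"` shape evolution.
#' @param heavy_df Student-t degrees of freedom for heavy-tailed increments
#'   (default 3).
#' @param sigma_evo per-coordinate Brownian rate scale of shape deviations
#'   (default 0.05 Procrustes units over the unit-depth tree).
#' @param habitat_effect magnitude of habitat-specific mean-shape
#'   displacement (default 0.03 Procrustes units).
#' @param diet_effect diet-proportion-to-shape covariance strength (default
#'   0.02).
#' @param allometry_slope shape displacement per unit log size (default
#'   0.02).
#' @param size_sd Brownian standard deviation of log centroid size across the
#'   tree (default 0.5 around `log_size_base`).
#' @param log_size_base mean log specimen size (default `log(30)`, a ~30 mm
#'   skull).
#' @param birth_rate pure-birth speciation rate (default 1).
#' @param tree_prune_to optionally prune the written tree to this many tips
#'   (emulates a dataset only partly covered by the phylogeny).
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_taxa = 48,
                       module_partition = c(braincase = 8, maxilla = 6,
                                            mandible = 6),
                       habitat_jump_rate = 1, habitat_iid = FALSE,
                       diet_categories_set = diet_categories(),
                       evolution = c("bm", "heavy_tailed"), heavy_df = 3,
                       sigma_evo = 0.05, habitat_effect = 0.03,
                       diet_effect = 0.02, allometry_slope = 0.02,
                       size_sd = 0.5, log_size_base = log(30),
                       birth_rate = 1, tree_prune_to = NULL) {
  evolution <- match.arg(evolution)
  if (is.null(names(module_partition)))
    names(module_partition) <- paste0("module", seq_along(module_partition))
  stopifnot(all(module_partition >= 3), heavy_df > 2,
            sigma_evo >= 0, habitat_effect >= 0, diet_effect >= 0,
            allometry_slope >= 0)
  structure(list(n_taxa = n_taxa, module_partition = module_partition,
                 habitat_jump_rate = habitat_jump_rate,
                 habitat_iid = habitat_iid,
                 diet_categories_set = diet_categories_set,
                 evolution = evolution, heavy_df = heavy_df,
                 sigma_evo = sigma_evo, habitat_effect = habitat_effect,
                 diet_effect = diet_effect,
                 allometry_slope = allometry_slope, size_sd = size_sd,
                 log_size_base = log_size_base, birth_rate = birth_rate,
                 tree_prune_to = tree_prune_to),
            class = "sim_config")
}

#' @rdname sim_config
#' @export
paper_scale_config <- function() {
  sim_config(n_taxa = 160,
             module_partition = c(non_trophic = 24, maxilla = 8,
                                  ectopterygoid = 6, supratemporal = 5,
                                  quadrate = 8, mandible = 12,
                                  pterygoid = 6, palatine = 4),
             tree_prune_to = 148)
}

#' Simulate a pure-birth phylogeny scaled to unit depth
#'
#' @param n_taxa number of tips (>= 4).
#' @param birth_rate speciation rate (default 1).
#' @param seed optional integer seed; the same seed gives an identical tree.
#' @return an ultrametric `ape::phylo` with root-to-tip depth 1 and tips
#'   `sp1..spN`.
#' @export
simulate_tree <- function(n_taxa, birth_rate = 1, seed = NULL) {
  if (n_taxa < 4) stop_validation("need at least 4 taxa")
  if (!is.null(seed)) set.seed(seed)
  tree <- ape::rphylo(n_taxa, birth = birth_rate, death = 0)
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / depth
  tree$tip.label <- paste0("sp", seq_len(n_taxa))
  tree
}

# symmetric Markov jump process for a categorical character on the tree;
# returns a state per tip (named). rate 0 inherits the root state everywhere.
simulate_discrete_character <- function(tree, states, rate) {
  n_node <- ape::Nnode(tree) + length(tree$tip.label)
  state <- integer(n_node)
  root <- length(tree$tip.label) + 1L
  state[root] <- sample.int(length(states), 1)
  tr <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(tr$edge))) {
    parent <- tr$edge[e, 1]; child <- tr$edge[e, 2]
    s <- state[parent]
    n_jump <- stats::rpois(1, rate * tr$edge.length[e])
    for (j in seq_len(n_jump)) {
      others <- setdiff(seq_along(states), s)
      s <- if (length(others) == 1) others else sample(others, 1)
    }
    state[child] <- s
  }
  stats::setNames(states[state[seq_along(tree$tip.label)]], tree$tip.label)
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha)
  g / sum(g)
}

#' Simulate an ecology table on a phylogeny
#'
#' Habitat evolves under a symmetric Markov jump process on the tree (so it
#' carries phylogenetic signal; `habitat_iid = TRUE` in the config removes
#' it). Diet proportions are Dirichlet draws whose concentration is boosted
#' on a habitat-linked preferred prey category, linking diet to habitat and
#' producing a realistic mix of specialists and generalists; the primary
#' diet label is derived from the proportions with the strict >50% rule.
#' Record counts are overdispersed (negative binomial, mean 14) so the
#' >10-record filter retains roughly half the taxa.
#'
#' @param tree an `ape::phylo`.
#' @param config a [sim_config()].
#' @param seed optional integer seed.
#' @return an [ecology_table()] in tree tip order.
#' @export
simulate_ecology <- function(tree, config = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  taxa <- tree$tip.label
  n <- length(taxa)
  habs <- habitat_levels()
  habitat <- if (config$habitat_iid)
    stats::setNames(sample(habs, n, replace = TRUE), taxa)
  else simulate_discrete_character(tree, habs, config$habitat_jump_rate)
  cats <- config$diet_categories_set
  nc <- length(cats)
  props <- matrix(NA_real_, n, nc, dimnames = list(taxa, cats))
  for (i in seq_len(n)) {
    # preferred prey depends on habitat but varies within it, so the diet
    # factor is linked to, yet never aliased with, the habitat factor
    h <- match(habitat[i], habs)
    pool <- ((h - 1 + 0:2) %% nc) + 1
    pref <- sample(pool, 1, prob = c(0.5, 0.25, 0.25))
    alpha <- rep(0.4, nc); alpha[pref] <- alpha[pref] + 6
    props[i, ] <- rdirichlet1(alpha)
  }
  primary <- apply(props, 1, assign_primary_diet)
  records <- stats::rnbinom(n, size = 3, mu = 14)
  ecology_table(taxa, habitat[taxa], primary, diet_proportions = props,
                n_diet_records = records, categories = cats)
}

# evolve m correlated traits along the tree; increments are Gaussian under
# "bm" or variance-matched scaled Student-t under "heavy_tailed"
evolve_traits <- function(tree, L_R, evolution, heavy_df) {
  m <- ncol(L_R)
  n_tip <- length(tree$tip.label)
  vals <- matrix(0, n_tip + ape::Nnode(tree), m)
  tr <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(tr$edge))) {
    z <- if (evolution == "heavy_tailed")
      stats::rt(m, df = heavy_df) * sqrt((heavy_df - 2) / heavy_df)
    else stats::rnorm(m)
    tr_inc <- sqrt(tr$edge.length[e]) * drop(L_R %*% z)
    vals[tr$edge[e, 2], ] <- vals[tr$edge[e, 1], ] + tr_inc
  }
  out <- vals[seq_len(n_tip), , drop = FALSE]
  rownames(out) <- tree$tip.label
  out
}

#' Simulate a raw (unaligned) landmark dataset with known generating process
#'
#' Per module: a base mean configuration (unit centroid size) plus per-taxon
#' shape deviations evolved along the tree (Brownian, or Student-t
#' increments in the `heavy_tailed` regime that violates the Brownian
#' assumption), plus a habitat-specific mean displacement, a diet-linked
#' component, and an allometric component proportional to simulated log
#' size. Each specimen is then "digitized": rotated by a random proper
#' rotation, translated, and scaled by its simulated size, so Procrustes
#' alignment has real work to do and log centroid size recovers the size
#' covariate.
#'
#' @param tree an `ape::phylo`.
#' @param eco matching [ecology_table()].
#' @param config a [sim_config()].
#' @param seed optional integer seed (end-to-end deterministic).
#' @return a [landmark_set()]; attribute `"log_size"` carries the true
#'   simulated log sizes.
#' @export
simulate_landmark_dataset <- function(tree, eco, config = sim_config(),
                                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  taxa <- tree$tip.label
  if (!setequal(taxa, eco$taxon))
    stop_validation("tree and ecology taxa differ")
  eco <- eco[match(taxa, eco$taxon), , drop = FALSE]
  n <- length(taxa)
  part <- config$module_partition
  habs <- habitat_levels()
  log_size <- config$log_size_base +
    drop(evolve_traits(tree, matrix(config$size_sd, 1, 1), "bm", 3))
  props <- diet_proportion_matrix(eco, drop_na = FALSE)
  shapes <- vector("list", length(part))
  for (k in seq_along(part)) {
    p <- part[k]; m <- 3L * p
    base <- center_config(matrix(stats::rnorm(p * 3), p, 3))
    base <- base / sqrt(sum(base^2))
    A <- matrix(stats::rnorm(m * m), m, m) / sqrt(m)
    L_R <- config$sigma_evo * psd_sqrt(tcrossprod(A))
    dev <- evolve_traits(tree, L_R, config$evolution, config$heavy_df)
    disp <- matrix(stats::rnorm(length(habs) * m), length(habs), m)
    disp <- config$habitat_effect * disp / sqrt(rowSums(disp^2))
    v_allo <- stats::rnorm(m); v_allo <- v_allo / sqrt(sum(v_allo^2))
    W <- matrix(stats::rnorm(ncol(props) * m), ncol(props), m)
    W <- config$diet_effect * W / sqrt(sum(W^2) / m)
    flat <- dev +
      disp[match(as.character(eco$habitat), habs), , drop = FALSE] +
      outer(log_size - mean(log_size), v_allo) * config$allometry_slope +
      scale(props, scale = FALSE) %*% W
    shapes[[k]] <- lapply(seq_len(n), function(i)
      base + matrix(flat[i, ], p, 3))
  }
  coords <- array(NA_real_, c(n, sum(part), 3))
  for (i in seq_len(n)) {
    cfg <- do.call(rbind, lapply(shapes, `[[`, i))
    rot <- random_rotation()
    cfg <- exp(log_size[i]) * cfg %*% rot
    cfg <- sweep(cfg, 2, stats::runif(3, -2, 2), `+`)
    coords[i, , ] <- cfg
  }
  lm <- landmark_set(coords, taxa,
                     module_of = rep(names(part), part),
                     units = "mm (synthetic)")
  attr(lm, "log_size") <- stats::setNames(log_size, taxa)
  lm
}

#' Write a complete synthetic fixture bundle to disk
#'
#' Emits `tree.nwk`, `landmarks.tps`, `landmarks.csv`, `ecology.csv`,
#' `modules.csv` and a `manifest.json` recording the generating parameters
#' and seed; re-running with the same config and seed reproduces the files
#' byte-identically, and [regenerate_fixture_bundle()] rebuilds a bundle
#' from its manifest alone.
#'
#' @param outdir output directory (created if needed).
#' @param config a [sim_config()].
#' @param seed integer master seed (default 1); tree, ecology and landmarks
#'   use `seed`, `seed + 1`, `seed + 2`.
#' @return named character vector of written paths, invisibly.
#' @export
write_fixture_bundle <- function(outdir, config = sim_config(), seed = 1) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  tree <- simulate_tree(config$n_taxa, config$birth_rate, seed = seed)
  eco <- simulate_ecology(tree, config, seed = seed + 1)
  lm <- simulate_landmark_dataset(tree, eco, config, seed = seed + 2)
  out_tree <- tree
  if (!is.null(config$tree_prune_to)) {
    set.seed(seed + 3)
    keep <- sort(sample(tree$tip.label, config$tree_prune_to))
    out_tree <- ape::keep.tip(tree, keep)
  }
  paths <- c(tree = file.path(outdir, "tree.nwk"),
             tps = file.path(outdir, "landmarks.tps"),
             csv = file.path(outdir, "landmarks.csv"),
             ecology = file.path(outdir, "ecology.csv"),
             modules = file.path(outdir, "modules.csv"),
             manifest = file.path(outdir, "manifest.json"))
  ape::write.tree(out_tree, paths["tree"])
  write_landmark_file(lm, paths["tps"], "tps")
  write_landmark_file(lm, paths["csv"], "csv")
  write_ecology_csv(eco, paths["ecology"])
  write_module_map(lm$module_of, paths["modules"])
  manifest <- c(unclass(config), list(seed = seed))
  manifest$module_partition <- as.list(config$module_partition)
  # 17 significant digits: doubles round-trip exactly through the manifest
  jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                       digits = I(17), null = "null", pretty = TRUE)
  invisible(paths)
}

#' @rdname write_fixture_bundle
#' @param manifest_path path to a `manifest.json` written by
#'   [write_fixture_bundle()].
#' @export
regenerate_fixture_bundle <- function(outdir, manifest_path) {
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  seed <- man$seed
  man$seed <- NULL
  man$module_partition <- unlist(man$module_partition)
  cfg <- do.call(sim_config, man[setdiff(names(man), "")])
  write_fixture_bundle(outdir, cfg, seed = seed)
}
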