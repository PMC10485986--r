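#' Randomly permute ecological codings across taxa
#'
#' Applies one random permutation to the taxon assignment of the ecological
#' columns (habitat, primary diet, diet proportions, record counts). By
#' default habitat and diet move together as one row shuffle, preserving
#' their empirical association; `joint = FALSE` shuffles habitat and the
#' diet columns with independent permutations. The size covariate is not an
#' ecology column and is never touched. The multiset of labels in every
#' column is preserved by construction.
#'
#' @param eco an [ecology_table()].
#' @param seed optional integer seed.
#' @param joint permute habitat and diet columns together (default TRUE).
#' @param perm optional explicit permutation (integer vector) overriding the
#'   random draw — useful for forcing the identity.
#' @return an `ecology_table` with permuted codings, same taxa.
#' @export
permute_ecology <- function(eco, seed = NULL, joint = TRUE, perm = NULL) {
  n <- nrow(eco)
  if (!is.null(seed)) set.seed(seed)
  eco_cols <- setdiff(names(eco), "taxon")
  out <- eco
  if (joint) {
    idx <- perm %||% sample.int(n)
    out[eco_cols] <- eco[idx, eco_cols]
  } else {
    idx1 <- perm %||% sample.int(n)
    idx2 <- perm %||% sample.int(n)
    out["habitat"] <- eco[idx1, "habitat"]
    diet_cols <- setdiff(eco_cols, "habitat")
    out[diet_cols] <- eco[idx2, diet_cols]
  }
  rownames(out) <- NULL
  out
}

# assemble the model predictor frame (habitat + primary_diet + size) for a
# taxon subset, in the conventional term order
model_predictors <- function(eco, size, idx = seq_len(nrow(eco))) {
  data.frame(habitat = droplevels(factor(eco$habitat[idx])),
             primary_diet = droplevels(factor(eco$primary_diet[idx])),
             size = as.numeric(size[idx]))
}

# is the model estimable on this predictor frame? (every factor >= 2 levels,
# enough residual df, and a full-rank design — singleton levels of two
# factors can alias each other in small subsets)
predictors_ok <- function(pred) {
  for (v in pred) if (is.factor(v) && nlevels(droplevels(v)) < 2) return(FALSE)
  X <- tryCatch(build_design(pred)$X, error = function(e) NULL)
  if (is.null(X) || nrow(X) < ncol(X) + 2) return(FALSE)
  qr(X)$rank == ncol(X)
}

#' Label-permutation robustness sweep over species subsets
#'
#' The core of the robustness experiment: for each subset size and
#' replicate, a fresh uniform random species subset is drawn (subsets whose
#' habitat or diet factor collapses below 2 levels are redrawn, counted);
#' under scenario `"permuted_labels"` the ecological codings are additionally
#' permuted within the subset, severing any shape-ecology association while
#' preserving the label multiset. The model `response ~ habitat +
#' primary_diet + size` is then fitted with the chosen engine and all term
#' p-values stored.
#'
#' @param Y numeric `n x m` response matrix with taxon rownames (flattened
#'   aligned shape, PC scores, or a simulated trait matrix). The univariate
#'   engine uses column 1.
#' @param eco an [ecology_table()] in the same taxon order.
#' @param tree an `ape::phylo` containing the taxa.
#' @param size numeric length-n size covariate (e.g. log centroid size).
#' @param subset_sizes integer vector of species-subset sizes.
#' @param n_reps replicates per subset size (default 200; the original
#'   experiment used 1000).
#' @param scenario `"true_labels"` or `"permuted_labels"`.
#' @param engine `"multivariate"` (PGLS + RRPP) or `"univariate"` (GLS +
#'   Wald).
#' @param n_perm RRPP permutations per fit (default 499).
#' @param seed optional integer seed for the whole sweep.
#' @param max_redraw redraw budget per cell before erroring (default 100).
#' @return A data frame of class `robustness_grid` with columns `scenario`,
#'   `subset_size`, `replicate`, `engine`, `term`, `p`, `redraws`.
#' @export
robustness_sweep <- function(Y, eco, tree, size,
                             subset_sizes = c(25, 50, 75, 100, 125),
                             n_reps = 200,
                             scenario = c("true_labels", "permuted_labels"),
                             engine = c("multivariate", "univariate"),
                             n_perm = 499, seed = NULL, max_redraw = 100) {
  scenario <- match.arg(scenario)
  engine <- match.arg(engine)
  Y <- as.matrix(Y)
  n <- nrow(Y)
  if (max(subset_sizes) > n)
    stop_validation("max subset size %d exceeds %d taxa", max(subset_sizes), n)
  taxa <- rownames(Y) %||% eco$taxon
  C_full <- bm_covariance(tree, taxa)
  if (!is.null(seed)) set.seed(seed)
  rows <- vector("list", length(subset_sizes) * n_reps)
  k <- 0L
  for (s in subset_sizes) {
    for (r in seq_len(n_reps)) {
      redraws <- 0L
      repeat {
        idx <- sort(sample.int(n, s))
        eco_sub <- eco[idx, , drop = FALSE]
        if (scenario == "permuted_labels")
          eco_sub <- permute_ecology(eco_sub)
        pred <- model_predictors(eco_sub, size[idx], seq_len(s))
        if (predictors_ok(pred)) break
        redraws <- redraws + 1L
        if (redraws > max_redraw)
          stop_validation("subset size %d cannot satisfy factor-level requirements after %d redraws",
                          s, max_redraw)
      }
      C_sub <- C_full[idx, idx]
      pv <- if (engine == "multivariate") {
        fit <- fit_pgls_rrpp(Y[idx, , drop = FALSE], pred, C_sub,
                             n_perm = n_perm)
        stats::setNames(fit$p[seq_len(3)], fit$term[seq_len(3)])
      } else {
        fit <- fit_gls_terms(Y[idx, 1], pred, C_sub)
        stats::setNames(fit$table$p, fit$table$term)
      }
      k <- k + 1L
      rows[[k]] <- data.frame(scenario = scenario, subset_size = s,
                              replicate = r, engine = engine,
                              term = names(pv), p = unname(pv),
                              redraws = redraws, row.names = NULL)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("robustness_grid", "data.frame")
  out
}

#' Brownian-motion control for the robustness experiment
#'
#' The negative control that separates "property of PGLS" from "property of
#' the data": a rate matrix is estimated from reference aligned shape data
#' (via its principal component scores, one variable per positive-variance
#' component), a multivariate Brownian response with that covariance is
#' simulated on the same tree, paired with the true ecology and size data,
#' and the permuted-label sweep is run on the simulated response. With the
#' response genuinely Brownian, p-values should be uniform (median ~ 0.5).
#'
#' @param alignment a `shape_alignment` for the reference module (taxa must
#'   match `eco`/`tree`), or an `n x m` trait matrix used directly.
#' @param eco,tree,size as in [robustness_sweep()].
#' @param n_vars number of simulated response variables; default the number
#'   of positive-variance principal components of the reference data.
#' @param subset_sizes,n_reps,n_perm,seed passed to [robustness_sweep()].
#' @return a `robustness_grid` with scenario `"bm_permuted"`.
#' @export
bm_control <- function(alignment, eco, tree, size, n_vars = NULL,
                       subset_sizes = c(25, 50, 75, 100, 125),
                       n_reps = 200, n_perm = 499, seed = NULL) {
  ref <- if (inherits(alignment, "shape_alignment")) {
    pca <- shape_pca(alignment)
    pca$scores
  } else as.matrix(alignment)
  if (!is.null(n_vars)) ref <- ref[, seq_len(min(n_vars, ncol(ref))),
                                   drop = FALSE]
  est <- estimate_rate_matrix(ref, tree)
  if (!is.null(seed)) set.seed(seed)
  Ysim <- simulate_multivariate_bm(tree, est$R, root = est$phylo_mean,
                                   taxa = rownames(ref))
  if (all(abs(est$R) < 1e-14))
    stop_validation("rate matrix is zero: simulated responses are constant")
  grid <- robustness_sweep(Ysim, eco, tree, size,
                           subset_sizes = subset_sizes, n_reps = n_reps,
                           scenario = "permuted_labels",
                           engine = "multivariate", n_perm = n_perm)
  grid$scenario <- "bm_permuted"
  grid
}

#' Summarize a robustness grid into medians, Type-I error and histograms
#'
#' @param grid a `robustness_grid`.
#' @param alpha rejection threshold (default 0.05).
#' @param n_bins histogram bins on \[0, 1\] (default 20).
#' @return list with `summary` (per scenario x subset size x term: `median_p`,
#'   `type1` = fraction of p at or below alpha, `n`) and `histogram` (long
#'   data frame of fixed-bin counts).
#' @export
summarize_pvalues <- function(grid, alpha = 0.05, n_bins = 20) {
  if (!nrow(grid)) stop_validation("empty robustness grid")
  key <- interaction(grid$scenario, grid$subset_size, grid$term, drop = TRUE)
  pieces <- split(grid, key)
  summ <- do.call(rbind, lapply(pieces, function(g)
    data.frame(scenario = g$scenario[1], subset_size = g$subset_size[1],
               term = g$term[1], n = nrow(g),
               median_p = stats::median(g$p),
               type1 = mean(g$p <= alpha), row.names = NULL)))
  breaks <- seq(0, 1, length.out = n_bins + 1)
  hist <- do.call(rbind, lapply(pieces, function(g) {
    cnt <- tabulate(findInterval(g$p, breaks, rightmost.closed = TRUE,
                                 all.inside = TRUE), n_bins)
    data.frame(scenario = g$scenario[1], subset_size = g$subset_size[1],
               term = g$term[1], bin = seq_len(n_bins),
               bin_upper = breaks[-1], count = cnt, row.names = NULL)
  }))
  rownames(summ) <- rownames(hist) <- NULL
  list(summary = summ, histogram = hist)
}
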