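#' Principal components analysis of aligned shapes
#'
#' Covariance-based PCA of Procrustes-aligned coordinates (the standard
#' choice in geometric morphometrics, so "variance explained" statements are
#' directly comparable across modules). The flattened `n x 3p` data are
#' column-centered and decomposed by singular values; components with
#' variance below `1e-12 x total` are dropped, and loading signs follow a
#' deterministic convention (largest-magnitude loading positive).
#'
#' @param x a `shape_alignment` or a numeric matrix (`n x q`).
#' @return An object of class `shape_pca`: `scores` (`n x k`), `loadings`
#'   (`q x k`), `variance_fraction` (length k, non-increasing, sums to 1),
#'   `sdev`, `center`, `n_components`.
#' @export
shape_pca <- function(x) {
  X <- if (inherits(x, "shape_alignment")) flatten_shapes(x) else as.matrix(x)
  n <- nrow(X)
  if (n < 3) stop_validation("PCA needs at least 3 specimens")
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  sv <- svd(Xc)
  total <- sum(sv$d^2)
  if (total <= 0) stop_validation("zero total shape variance")
  keep <- which(sv$d^2 > 1e-12 * total)
  d <- sv$d[keep]
  V <- fix_column_signs(sv$v[, keep, drop = FALSE])
  scores <- Xc %*% V
  rownames(scores) <- rownames(X)
  colnames(scores) <- colnames(V) <- paste0("PC", seq_along(keep))
  rownames(V) <- colnames(X)
  structure(list(scores = scores, loadings = V,
                 variance_fraction = d^2 / total,
                 sdev = d / sqrt(n - 1), center = ctr,
                 n_components = length(keep)),
            class = "shape_pca")
}

#' @export
print.shape_pca <- function(x, ...) {
  cat(sprintf("<shape_pca> %d components; PC1 %.1f%%, PC2 %.1f%% of variance\n",
              x$n_components, 100 * x$variance_fraction[1],
              if (x$n_components > 1) 100 * x$variance_fraction[2] else NA))
  invisible(x)
}

#' Morphospace table: PC scores joined with ecological codings
#'
#' Builds the per-taxon table behind a morphospace scatter plot, plus
#' per-group centroids and within-group dispersions in the chosen axes so
#' that "tight clustering" of an ecological group can be quantified rather
#' than eyeballed.
#'
#' @param pca a `shape_pca`.
#' @param eco an [ecology_table()] covering the same taxa.
#' @param axes integer pair of component indices (default `c(1, 2)`).
#' @param group ecology column used for group summaries (default
#'   `"habitat"`).
#' @return list with `table` (taxon, scores, habitat, primary_diet),
#'   `centroids` (per-group mean scores) and `dispersion` (per-group root
#'   mean squared distance to the group centroid).
#' @export
morphospace_table <- function(pca, eco, axes = c(1, 2), group = "habitat") {
  if (any(axes > pca$n_components))
    stop_validation("axis index beyond the %d positive-variance components",
                    pca$n_components)
  idx <- match(rownames(pca$scores), eco$taxon)
  if (anyNA(idx))
    stop_validation("ecology table missing taxa present in the PCA")
  sc <- pca$scores[, axes, drop = FALSE]
  tab <- data.frame(taxon = rownames(pca$scores), sc,
                    habitat = eco$habitat[idx],
                    primary_diet = eco$primary_diet[idx],
                    row.names = NULL)
  g <- droplevels(factor(tab[[group]]))
  centroids <- t(vapply(levels(g),
                        function(l) colMeans(sc[g == l, , drop = FALSE]),
                        numeric(ncol(sc))))
  dispersion <- vapply(levels(g), function(l) {
    m <- sc[g == l, , drop = FALSE]
    sqrt(mean(rowSums(sweep(m, 2, colMeans(m))^2)))
  }, numeric(1))
  list(table = tab, centroids = centroids, dispersion = dispersion)
}

#' Write PCA scores and variance fractions to CSV
#' @param pca a `shape_pca`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pca_csv <- function(pca, path) {
  df <- data.frame(taxon = rownames(pca$scores), pca$scores,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  vpath <- sub("(\\.csv)?$", "_variance.csv", path)
  utils::write.csv(data.frame(component = seq_along(pca$variance_fraction),
                              variance_fraction = pca$variance_fraction),
                   vpath, row.names = FALSE, quote = FALSE)
  invisible(path)
}
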