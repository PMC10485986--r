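#' Brownian-motion covariance matrix from a phylogeny
#'
#' Under Brownian motion the expected covariance between two tips is the
#' branch length shared by their root-to-tip paths; the diagonal holds
#' root-to-tip depths. Rows and columns follow the requested taxon order.
#'
#' @param tree an `ape::phylo` with branch lengths.
#' @param taxa taxon order for rows/columns (default: tree tip order).
#' @return symmetric positive-semidefinite `n x n` matrix with dimnames.
#' @export
bm_covariance <- function(tree, taxa = tree$tip.label) {
  if (!inherits(tree, "phylo")) stop_validation("tree must be an ape phylo")
  missing <- setdiff(taxa, tree$tip.label)
  if (length(missing))
    stop_validation("taxa not in tree: %s", paste(missing, collapse = ", "))
  C <- ape::vcv.phylo(tree)
  C[taxa, taxa, drop = FALSE]
}

#' Symmetric inverse square root of a covariance matrix
#'
#' Computed by symmetric eigendecomposition (not Cholesky) so the transform
#' is unique and invariant to taxon reordering up to conjugation. This is
#' the matrix `P` with `P %*% C %*% P = I` that turns a GLS problem into OLS
#' on transformed data.
#'
#' @param C symmetric positive-definite matrix.
#' @return symmetric matrix `P` of the same dimension.
#' @export
inverse_sqrt <- function(C) {
  C <- as.matrix(C)
  ev <- eigen(C, symmetric = TRUE)
  clamp <- 1e-12 * max(ev$values)
  if (min(ev$values) <= clamp)
    stop_numerical(
      "covariance matrix is numerically singular (min eigenvalue %.3g); the tree may have zero-length terminal branches",
      min(ev$values))
  P <- ev$vectors %*% (t(ev$vectors) / sqrt(ev$values))
  dimnames(P) <- dimnames(C)
  P
}

# symmetric PSD square root (eigenvalues clamped at zero)
psd_sqrt <- function(M) {
  M <- as.matrix(M)
  ev <- eigen(M, symmetric = TRUE)
  vals <- pmax(ev$values, 0)
  ev$vectors %*% (t(ev$vectors) * sqrt(vals))
}

#' Phylogenetic (GLS) mean of trait columns
#'
#' The generalized least squares intercept
#' `(1' C^-1 1)^-1 1' C^-1 Y`, i.e. the maximum-likelihood root-state
#' estimate under Brownian motion.
#'
#' @param Y numeric `n x m` matrix (or n-vector).
#' @param C `n x n` phylogenetic covariance (taxon order matching rows of Y).
#' @return numeric m-vector.
#' @export
phylo_mean <- function(Y, C) {
  Y <- as.matrix(Y)
  if (nrow(Y) != nrow(C)) stop_validation("Y and C disagree on taxon count")
  Cinv_1 <- solve(C, rep(1, nrow(C)))
  drop(crossprod(Y, Cinv_1)) / sum(Cinv_1)
}

#' Evolutionary rate matrix under multivariate Brownian motion
#'
#' Maximum-likelihood estimate of the per-unit-branch-length trait
#' covariance: `R = (Y - 1 a')' C^-1 (Y - 1 a') / n` with `a` the
#' phylogenetic mean. On a star tree with unit branches this reduces to the
#' ordinary ML covariance. The divisor is `n` (the cited tooling's
#' convention); `n - 1` is available via `divisor`.
#'
#' @param Y numeric `n x m` trait matrix, rows named by taxa.
#' @param tree an `ape::phylo` containing all row taxa.
#' @param divisor `"n"` (ML, default) or `"n-1"`.
#' @return list with `R` (`m x m` symmetric PSD) and `phylo_mean`
#'   (m-vector).
#' @export
estimate_rate_matrix <- function(Y, tree, divisor = c("n", "n-1")) {
  divisor <- match.arg(divisor)
  Y <- as.matrix(Y)
  taxa <- rownames(Y) %||% tree$tip.label
  C <- bm_covariance(tree, taxa)
  a <- phylo_mean(Y, C)
  D <- sweep(Y, 2, a)
  CiD <- solve(C, D)
  R <- crossprod(D, CiD) / (nrow(Y) - (divisor == "n-1"))
  R <- (R + t(R)) / 2
  list(R = R, phylo_mean = a)
}

#' Simulate correlated traits under multivariate Brownian motion
#'
#' Draws `Y = 1 root' + L_C Z L_R'` where `L_C`, `L_R` are symmetric PSD
#' square roots of the phylogenetic covariance and the rate matrix and `Z`
#' is an `n x m` standard-normal array, so
#' `cov(Y[a, i], Y[b, j]) = C[a, b] * R[i, j]`. The seed fully determines
#' the output.
#'
#' @param tree an `ape::phylo`.
#' @param R `m x m` positive-semidefinite rate matrix.
#' @param root length-m root state (default zeros).
#' @param seed optional integer seed.
#' @param taxa taxon order for rows (default tree tip order).
#' @return `n x m` matrix with taxon rownames.
#' @export
simulate_multivariate_bm <- function(tree, R, root = NULL, seed = NULL,
                                     taxa = tree$tip.label) {
  R <- as.matrix(R)
  m <- ncol(R)
  root <- root %||% numeric(m)
  if (length(root) != m) stop_validation("root length must match ncol(R)")
  if (!is.null(seed)) set.seed(seed)
  C <- bm_covariance(tree, taxa)
  n <- nrow(C)
  Z <- matrix(stats::rnorm(n * m), n, m)
  Y <- matrix(root, n, m, byrow = TRUE) + psd_sqrt(C) %*% Z %*% t(psd_sqrt(R))
  rownames(Y) <- taxa
  colnames(Y) <- colnames(R) %||% paste0("trait", seq_len(m))
  Y
}
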