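#' Centroid size of a landmark configuration
#'
#' The square root of the summed squared distances of the landmarks to their
#' centroid — the standard size measure in geometric morphometrics. It is
#' invariant to translation and rotation and scales linearly with the
#' configuration.
#'
#' @param config numeric `p x 3` (or `p x k`) coordinate matrix.
#' @return positive scalar (0, with a warning, for a fully degenerate
#'   configuration of identical points).
#' @export
centroid_size <- function(config) {
  config <- as.matrix(config)
  cs <- sqrt(sum(scale(config, scale = FALSE)^2))
  if (cs == 0) warning("degenerate configuration: all landmarks identical")
  cs
}

# center a p x k configuration at the origin
center_config <- function(config) scale(config, scale = FALSE)

#' Optimal superposition of one configuration onto another
#'
#' Finds the proper rotation (and optionally scale) minimizing
#' `sum(||A - s * B %*% R||^2)` for centered configurations, by singular value
#' decomposition of the cross-product matrix. Reflections are excluded
#' (determinant +1), the standard convention for bilaterally landmarked
#' structures; for a degenerate (coplanar/collinear) optimum the
#' singular-vector convention resolves ties deterministically and a warning
#' is issued.
#'
#' @param A,B `p x 3` coordinate matrices (centered; centering is enforced).
#' @param allow_scale also estimate a positive scale for B (default FALSE).
#' @return list with `rotation` (3 x 3, det +1), `scale`, and `residual`
#'   (root-sum-of-squares of the minimized criterion).
#' @export
optimal_superposition <- function(A, B, allow_scale = FALSE) {
  A <- center_config(as.matrix(A)); B <- center_config(as.matrix(B))
  if (nrow(A) != nrow(B)) stop_validation("configurations differ in landmarks")
  M <- crossprod(B, A)                     # 3 x 3
  sv <- svd(M)
  d <- c(1, 1, sign(det(sv$u %*% t(sv$v))))
  if (sv$d[2] < 1e-12 * max(sv$d[1], 1e-300))
    warning("degenerate configuration: rotation not unique, using SVD tie-break")
  R <- sv$u %*% diag(d) %*% t(sv$v)
  s <- if (allow_scale) sum(sv$d * d) / sum(B^2) else 1
  resid <- sqrt(max(0, sum(A^2) + s^2 * sum(B^2) - 2 * s * sum(sv$d * d)))
  list(rotation = R, scale = s, residual = resid)
}

#' Generalized Procrustes Analysis
#'
#' Iterative superimposition of all configurations: each is centered and
#' scaled to unit centroid size, then repeatedly rotated onto the current
#' consensus; the consensus (mean shape, rescaled to unit centroid size) is
#' updated until its change (root summed squared difference) falls below
#' `tol` or `max_iter` iterations are reached. The aligned shapes are finally
#' projected orthogonally onto the tangent space at the consensus, and the
#' whole set is rotated so the consensus lies along its principal axes with a
#' deterministic sign convention, making output reproducible across
#' platforms.
#'
#' @param x a [landmark_set()] or an `n x p x 3` array.
#' @param tol convergence tolerance on the consensus change (default 1e-10).
#' @param max_iter iteration cap (default 200); non-convergence returns
#'   results with `converged = FALSE` and a warning.
#' @param project project aligned shapes onto the tangent space (default
#'   TRUE).
#' @return An object of class `shape_alignment`: `aligned` (`n x p x 3`),
#'   `centroid_size` and `log_centroid_size` per taxon (pre-scaling),
#'   `consensus` (`p x 3`), `n_iterations`, `converged`, and the GPA
#'   objective trace `objective`.
#' @export
generalized_procrustes <- function(x, tol = 1e-10, max_iter = 200,
                                   project = TRUE) {
  coords <- if (inherits(x, "landmark_set")) x$coords else x
  n <- dim(coords)[1]; p <- dim(coords)[2]
  if (n < 2) stop_validation("GPA needs at least 2 specimens")
  taxa <- dimnames(coords)[[1]] %||% paste0("t", seq_len(n))
  cs <- numeric(n)
  aligned <- array(NA_real_, dim(coords), dimnames = dimnames(coords))
  for (i in seq_len(n)) {
    cfg <- center_config(coords[i, , ])
    cs[i] <- sqrt(sum(cfg^2))
    if (cs[i] <= 0) stop_validation("taxon '%s' has zero centroid size", taxa[i])
    aligned[i, , ] <- cfg / cs[i]
  }
  consensus <- aligned[1, , ]
  consensus <- consensus / sqrt(sum(consensus^2))
  objective <- numeric(0)
  converged <- FALSE; it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    for (i in seq_len(n)) {
      R <- optimal_superposition(consensus, aligned[i, , ])$rotation
      aligned[i, , ] <- aligned[i, , ] %*% R
    }
    new_con <- apply(aligned, c(2, 3), mean)
    new_con <- new_con / sqrt(sum(new_con^2))
    objective <- c(objective,
                   sum(sweep(aligned, c(2, 3), new_con)^2))
    delta <- sqrt(sum((new_con - consensus)^2))
    consensus <- new_con
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf("GPA did not converge in %d iterations", max_iter))
  # rotate the whole set to the consensus principal axes (deterministic signs)
  ev <- eigen(crossprod(consensus), symmetric = TRUE)
  V <- fix_column_signs(ev$vectors)
  if (det(V) < 0) V[, 3] <- -V[, 3]
  consensus <- consensus %*% V
  for (i in seq_len(n)) aligned[i, , ] <- aligned[i, , ] %*% V
  if (project) {
    cvec <- as.vector(consensus)             # unit norm
    flat <- matrix(aligned, nrow = n)        # n x 3p, column-major over (p,3)
    # affine projection onto the tangent plane {v : v . c = 1} at the consensus
    flat <- flat - (flat %*% cvec - 1) %*% t(cvec)
    aligned <- array(flat, dim(aligned), dimnames = dimnames(aligned))
  }
  consensus_out <- apply(aligned, c(2, 3), mean)
  names(cs) <- taxa
  structure(list(aligned = aligned, centroid_size = cs,
                 log_centroid_size = log(cs), consensus = consensus_out,
                 n_iterations = it, converged = converged,
                 objective = objective),
            class = "shape_alignment")
}

#' @export
print.shape_alignment <- function(x, ...) {
  d <- dim(x$aligned)
  cat(sprintf("<shape_alignment> %d taxa, %d landmarks; %d iterations (%s)\n",
              d[1], d[2], x$n_iterations,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Flatten aligned shapes to an n x 3p matrix
#'
#' Columns are ordered landmark-major (`lm1.x, lm1.y, lm1.z, lm2.x, ...`).
#'
#' @param alignment a `shape_alignment`.
#' @return numeric matrix with taxon rownames.
#' @export
flatten_shapes <- function(alignment) {
  a <- alignment$aligned
  n <- dim(a)[1]; p <- dim(a)[2]
  out <- do.call(cbind, lapply(seq_len(p), function(j) a[, j, , drop = TRUE]))
  colnames(out) <- as.vector(t(outer(
    dimnames(a)[[2]] %||% paste0("lm", seq_len(p)),
    c("x", "y", "z"), paste, sep = ".")))
  rownames(out) <- dimnames(a)[[1]]
  out
}

#' Per-module Generalized Procrustes alignments
#'
#' Runs [generalized_procrustes()] independently for each anatomical module;
#' per-module centroid sizes come from that module's landmarks only. Modules
#' are aligned in isolation because kinetic elements make their relative
#' positions arbitrary.
#'
#' @param lm a [landmark_set()] whose `module_of` covers all landmarks.
#' @param ... passed to [generalized_procrustes()].
#' @return named list of `shape_alignment` objects, one per module.
#' @export
module_alignments <- function(lm, ...) {
  mods <- unique(lm$module_of)
  out <- lapply(mods, function(m) {
    sub <- module_subset(lm, m)
    if (n_landmarks(sub) < 3)
      stop_validation("module '%s' has only %d landmarks (need >= 3)",
                      m, n_landmarks(sub))
    generalized_procrustes(sub, ...)
  })
  names(out) <- mods
  out
}

#' Procrustes distance matrix between aligned specimens
#' @param alignment a `shape_alignment`.
#' @return `dist` object of Euclidean distances in the tangent space.
#' @export
procrustes_distances <- function(alignment) {
  stats::dist(flatten_shapes(alignment))
}
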