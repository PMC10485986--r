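# internal helpers: condition classes and small numerics

stop_validation <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("phylomorph_validation_error", "error")))
}

stop_numerical <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("phylomorph_numerical_error", "error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Canonical habitat-use categories
#'
#' Seven microhabitat categories used to code habitat for each species,
#' spanning the subterranean-to-aquatic gradient.
#'
#' @return Character vector of the 7 habitat levels.
#' @export
habitat_levels <- function() {
  c("semi-fossorial", "cryptozoic", "terrestrial", "semi-arboreal",
    "arboreal", "semi-aquatic", "aquatic")
}

#' Canonical prey categories for diet coding
#'
#' Ten prey categories used for diet proportions; a species whose diet has no
#' single category above 50% is coded "generalist" (which is a derived primary
#' diet label, not a prey category).
#'
#' @return Character vector of 10 prey-category names.
#' @export
diet_categories <- function() {
  c("amphibians", "reptiles", "birds", "mammals", "fish",
    "reptile_eggs", "bird_eggs", "annelids", "mollusks",
    "other_invertebrates")
}

# normalize taxon names for matching: case-fold, spaces -> underscores
normalize_taxon <- function(x) tolower(gsub(" ", "_", x, fixed = TRUE))

# deterministic sign convention: flip columns so the largest-magnitude
# entry of each column is positive
fix_column_signs <- function(M) {
  for (j in seq_len(ncol(M))) {
    i <- which.max(abs(M[, j]))
    if (M[i, j] < 0) M[, j] <- -M[, j]
  }
  M
}

# random proper rotation matrix in 3-D (uniform via QR of Gaussian)
random_rotation <- function() {
  qrd <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qrd)
  Q <- Q %*% diag(sign(diag(qr.R(qrd))))
  if (det(Q) < 0) Q[, 3] <- -Q[, 3]
  Q
}
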