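# Build a sequential design matrix from an ordered predictor frame.
# Factors get treatment contrasts (k-1 columns); numerics one column.
# Returns the full matrix (with intercept), per-term column blocks, and df.
build_design <- function(predictors) {
  n <- nrow(predictors)
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  blocks <- list(); dfs <- integer(0)
  for (term in names(predictors)) {
    v <- predictors[[term]]
    if (is.character(v) || is.factor(v)) {
      f <- droplevels(factor(v))
      if (nlevels(f) < 2)
        stop_validation("term '%s' collapses to a single level", term)
      cols <- stats::model.matrix(~f)[, -1, drop = FALSE]
      colnames(cols) <- paste0(term, levels(f)[-1])
    } else {
      cols <- matrix(as.numeric(v), ncol = 1, dimnames = list(NULL, term))
    }
    blocks[[term]] <- ncol(X) + seq_len(ncol(cols))
    dfs[term] <- ncol(cols)
    X <- cbind(X, cols)
  }
  list(X = X, blocks = blocks, df = dfs)
}

# drop aliased (rank-deficient) columns, lm-style, keeping block structure;
# errors if a term loses all of its columns
drop_aliased_columns <- function(des) {
  qrx <- qr(des$X)
  if (qrx$rank == ncol(des$X)) return(des)
  keep <- sort(qrx$pivot[seq_len(qrx$rank)])
  if (!1 %in% keep) stop_validation("design lost its intercept")
  dropped <- colnames(des$X)[-keep]
  warning("dropping aliased design columns: ", paste(dropped, collapse = ", "))
  X <- des$X[, keep, drop = FALSE]
  blocks <- lapply(des$blocks, function(b) match(intersect(b, keep), keep))
  for (tm in names(blocks)) if (!length(blocks[[tm]]))
    stop_validation("term '%s' is entirely aliased", tm)
  list(X = X, blocks = blocks,
       df = vapply(blocks, length, 1L))
}

#' Multivariate phylogenetic GLS with residual-randomization permutation
#'
#' Fits the linear model `Y ~ term1 + term2 + ...` under a Brownian-motion
#' phylogenetic covariance by transforming response and design with the
#' symmetric inverse square root of `C` and running ordinary least squares on
#' the transformed data. Sums of squares are sequential (Type I) in the
#' given term order. Significance is assessed by residual randomization
#' (RRPP): for each term, residuals of its reduced model (all preceding
#' terms) are row-permuted, the statistic recomputed, and the p-value is the
#' proportion of the `n_perm + 1` values (observed arrangement included) at
#' or above the observed, so the minimum attainable p is
#' `1 / (n_perm + 1)`. The effect size `Z` is the standardized deviate of
#' `log(F)` within its permutation distribution, the convention that makes
#' effect sizes comparable across terms and models. One permutation schedule
#' is drawn and shared across terms; the seed fully determines it.
#'
#' Results are order-dependent (sequential SS): the default analysis order is
#' habitat, then diet, then size, and callers control it via the column order
#' of `predictors`.
#'
#' @param Y numeric `n x m` response (e.g. flattened Procrustes-aligned
#'   coordinates, or any trait matrix).
#' @param predictors data frame of factors/covariates, one column per model
#'   term, in the desired sequential order; rows in taxon order of `C`.
#' @param C `n x n` phylogenetic covariance; use `diag(n)` for a
#'   non-phylogenetic fit.
#' @param n_perm number of random permutations (default 999).
#' @param seed optional integer seed.
#' @param drop_aliased drop rank-deficient design columns with a warning
#'   (the `lm()` convention) instead of erroring (default FALSE: a singular
#'   design is an error).
#' @return An object of class `pgls_anova`: a data frame with one row per
#'   term (`df`, `SS`, `MS`, `F`, `Z`, `p`) plus `Residuals` and `Total`
#'   rows; attributes carry the permutation count and term order.
#' @export
fit_pgls_rrpp <- function(Y, predictors, C, n_perm = 999, seed = NULL,
                          drop_aliased = FALSE) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  if (nrow(predictors) != n || nrow(C) != n)
    stop_validation("Y, predictors and C disagree on taxon count")
  des <- build_design(predictors)
  if (drop_aliased) des <- drop_aliased_columns(des)
  p_tot <- ncol(des$X)
  if (n < p_tot + 2)
    stop_validation("n = %d too small for %d model df", n, p_tot)
  P <- inverse_sqrt(C)
  Yt <- P %*% Y
  Xt <- P %*% des$X
  qrx <- qr(Xt)
  if (qrx$rank < p_tot) stop_validation("singular design matrix")
  Q <- qr.Q(qrx)
  G0 <- crossprod(Q, Yt)
  rss_full <- sum(Yt^2) - sum(G0^2)
  df_res <- n - p_tot
  if (df_res <= 0) stop_validation("no residual degrees of freedom")
  terms <- names(des$blocks)
  ss <- vapply(terms, function(tm) sum(G0[des$blocks[[tm]], ]^2), 1)
  dfs <- des$df
  fstat <- (ss / dfs) / (rss_full / df_res)

  if (!is.null(seed)) set.seed(seed)
  perms <- replicate(n_perm, sample.int(n))      # n x n_perm
  pvals <- zvals <- numeric(length(terms)); names(pvals) <- names(zvals) <- terms
  for (j in seq_along(terms)) {
    blk <- des$blocks[[terms[j]]]
    red_cols <- seq_len(min(blk) - 1L)           # nested: all preceding columns
    E <- Yt - Q[, red_cols, drop = FALSE] %*% G0[red_cols, , drop = FALSE]
    normE2 <- sum(E^2)
    f_perm <- numeric(n_perm)
    for (i in seq_len(n_perm)) {
      G <- crossprod(Q, E[perms[, i], , drop = FALSE])
      ss_i <- sum(G[blk, ]^2)
      rss_i <- normE2 - sum(G^2)
      f_perm[i] <- (ss_i / dfs[j]) / (rss_i / df_res)
    }
    f_all <- c(fstat[j], f_perm)
    pvals[j] <- mean(f_all >= fstat[j] - 1e-12)
    lf <- log(pmax(f_all, 1e-300))
    zvals[j] <- (lf[1] - mean(lf)) / stats::sd(lf)
  }
  tab <- data.frame(term = c(terms, "Residuals", "Total"),
                    df = c(dfs, df_res, n - 1L),
                    SS = c(ss, rss_full, sum(ss) + rss_full),
                    MS = c(ss / dfs, rss_full / df_res, NA),
                    F = c(fstat, NA, NA),
                    Z = c(zvals, NA, NA),
                    p = c(pvals, NA, NA),
                    row.names = NULL)
  attr(tab, "n_perm") <- n_perm
  attr(tab, "term_order") <- terms
  class(tab) <- c("pgls_anova", "data.frame")
  tab
}

#' Univariate GLS with per-term Wald chi-square tests
#'
#' Generalized least squares fit of a single response (typically a principal
#' component score) on the model terms under a phylogenetic covariance:
#' `beta = (X' C^-1 X)^-1 X' C^-1 y`. Each term is tested with a Type II
#' Wald chi-square — the term's coefficients tested given all other terms,
#' which for an additive (no-interaction) model respects marginality — with
#' p-values from the chi-square reference distribution. With `C = diag(n)`
#' the fit reduces exactly to ordinary least squares.
#'
#' @param y numeric n-vector response.
#' @param predictors data frame of model terms (see [fit_pgls_rrpp()]).
#' @param C `n x n` phylogenetic covariance.
#' @param drop_aliased as in [fit_pgls_rrpp()].
#' @return An object of class `gls_fit`: `coefficients`, `sigma2` (fitted
#'   covariance scale, residual-based with denominator `n - p`), `vcov`, and
#'   `table` (term, df, chisq, p).
#' @export
fit_gls_terms <- function(y, predictors, C, drop_aliased = FALSE) {
  y <- as.numeric(y)
  n <- length(y)
  des <- build_design(predictors)
  if (drop_aliased) des <- drop_aliased_columns(des)
  X <- des$X
  if (n < ncol(X) + 1) stop_validation("n too small for the model")
  ch <- tryCatch(chol(C), error = function(e)
    stop_numerical("phylogenetic covariance not positive definite"))
  Ci <- chol2inv(ch)
  XtCiX <- crossprod(X, Ci %*% X)
  XtCiy <- crossprod(X, Ci %*% y)
  XtCiX_inv <- tryCatch(solve(XtCiX), error = function(e)
    stop_validation("singular design (X' C^-1 X not invertible)"))
  beta <- drop(XtCiX_inv %*% XtCiy)
  names(beta) <- colnames(X)
  r <- y - drop(X %*% beta)
  sigma2 <- drop(crossprod(r, Ci %*% r)) / (n - ncol(X))
  V <- sigma2 * XtCiX_inv
  terms <- names(des$blocks)
  chisq <- pv <- numeric(length(terms))
  for (j in seq_along(terms)) {
    blk <- des$blocks[[terms[j]]]
    bj <- beta[blk]
    chisq[j] <- drop(t(bj) %*% solve(V[blk, blk, drop = FALSE]) %*% bj)
    pv[j] <- stats::pchisq(chisq[j], df = length(blk), lower.tail = FALSE)
  }
  structure(list(coefficients = beta, sigma2 = sigma2, vcov = V,
                 table = data.frame(term = terms, df = des$df,
                                    chisq = chisq, p = pv,
                                    row.names = NULL)),
            class = "gls_fit")
}

#' @export
print.gls_fit <- function(x, ...) {
  cat("<gls_fit> Wald chi-square term tests:\n")
  print(x$table, digits = 4)
  invisible(x)
}

#' Phylogenetic two-block partial least squares
#'
#' Measures covariation between two trait blocks (e.g. module shape and diet
#' proportions) in a phylogenetic context: both blocks are transformed by the
#' inverse square root of `C`, column-centered, and the cross-block
#' covariance is decomposed by singular values. `r_pls` is the correlation
#' between the two blocks' projections onto their first singular vectors;
#' significance comes from permuting the rows of the second transformed
#' block (transform once, permute after — the convention of the standard
#' implementation), with the observed arrangement included in the null set.
#'
#' @param Y1,Y2 numeric `n x m1` / `n x m2` blocks in a shared taxon order.
#' @param C `n x n` phylogenetic covariance (identity for non-phylogenetic
#'   PLS).
#' @param n_perm number of permutations (default 999).
#' @param seed optional integer seed.
#' @return An object of class `pls_result`: `r_pls`, `p`, `left`/`right`
#'   first singular vectors, and `perm_r` (the null correlations).
#' @export
ppls_integration <- function(Y1, Y2, C, n_perm = 999, seed = NULL) {
  Y1 <- as.matrix(Y1); Y2 <- as.matrix(Y2)
  n <- nrow(Y1)
  if (nrow(Y2) != n || nrow(C) != n)
    stop_validation("blocks and C disagree on taxon count")
  P <- inverse_sqrt(C)
  T1 <- scale(P %*% Y1, scale = FALSE)
  T2 <- scale(P %*% Y2, scale = FALSE)
  if (all(abs(T1) < 1e-12) || all(abs(T2) < 1e-12))
    stop_validation("constant block: no variation to correlate")
  r_of <- function(B2) {
    sv <- svd(crossprod(T1, B2) / (n - 1), nu = 1, nv = 1)
    stats::cor(drop(T1 %*% sv$u), drop(B2 %*% sv$v))
  }
  r_obs <- r_of(T2)
  if (!is.null(seed)) set.seed(seed)
  perm_r <- vapply(seq_len(n_perm),
                   function(i) r_of(T2[sample.int(n), , drop = FALSE]),
                   numeric(1))
  p <- mean(c(r_obs, perm_r) >= r_obs - 1e-12)
  sv <- svd(crossprod(T1, T2) / (n - 1), nu = 1, nv = 1)
  flip <- if (sv$u[which.max(abs(sv$u)), 1] < 0) -1 else 1  # joint sign so the pair stays consistent
  structure(list(r_pls = r_obs, p = p,
                 left = sv$u * flip, right = sv$v * flip,
                 perm_r = perm_r, n_perm = n_perm),
            class = "pls_result")
}

#' @export
print.pls_result <- function(x, ...) {
  cat(sprintf("<pls_result> r-PLS = %.3f, P = %.4g (%d permutations)\n",
              x$r_pls, x$p, x$n_perm))
  invisible(x)
}

#' Serialize a fitted table to CSV or JSON
#' @param x a `pgls_anova`, `gls_fit`, or `pls_result`.
#' @param path output path ending in `.csv` or `.json`.
#' @return `path`, invisibly.
#' @export
write_fit <- function(x, path) {
  df <- if (inherits(x, "pgls_anova")) as.data.frame(x)
        else if (inherits(x, "gls_fit")) x$table
        else data.frame(r_pls = x$r_pls, p = x$p)
  if (grepl("\\.json$", path))
    jsonlite::write_json(df, path, digits = NA, auto_unbox = TRUE)
  else utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
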