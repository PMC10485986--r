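test_that("with identity covariance the PGLS F equals classical sequential ANOVA", {
  set.seed(31)
  n <- 30
  pred <- data.frame(habitat = factor(sample(c("aq", "te", "ar"), n, TRUE)),
                     diet = factor(sample(c("fish", "frog"), n, TRUE)),
                     size = rnorm(n))
  y <- rnorm(n)
  fit <- fit_pgls_rrpp(matrix(y), pred, diag(n), n_perm = 99, seed = 1)
  ref <- anova(lm(y ~ habitat + diet + size, data = pred))
  expect_equal(fit$F[1:3], ref$`F value`[1:3], tolerance = 1e-8)
  expect_equal(fit$SS[1:3], ref$`Sum Sq`[1:3], tolerance = 1e-8)
})

test_that("RRPP p matches exhaustive enumeration on n = 8", {
  set.seed(32)
  g <- factor(rep(c("a", "b"), each = 4))
  y <- c(0.2, 1.1, -0.4, 0.9, 1.8, 2.2, 0.7, 2.9)
  fstat_for <- function(members) {
    gg <- factor(ifelse(seq_len(8) %in% members, "a", "b"))
    anova(lm(y ~ gg))$`F value`[1]
  }
  f_obs <- fstat_for(1:4)
  # the permutation distribution over label shuffles is uniform over the
  # C(8,4) = 70 subsets assigned to group "a"
  subsets <- utils::combn(8, 4)
  f_all <- apply(subsets, 2, fstat_for)
  p_exact <- mean(f_all >= f_obs - 1e-12)
  fit <- fit_pgls_rrpp(matrix(y), data.frame(g = g), diag(8),
                       n_perm = 9999, seed = 2)
  expect_equal(fit$F[1], f_obs, tolerance = 1e-10)
  se <- sqrt(p_exact * (1 - p_exact) / 9999)
  expect_lt(abs(fit$p[1] - p_exact), 4 * se + 2 / 9999)
})

test_that("duplicated response columns double SS but keep F and p", {
  md <- fix_dataset(30, seed = 33)
  aln <- generalized_procrustes(module_subset(md$landmarks, "braincase"))
  Y <- flatten_shapes(aln)
  set.seed(133)
  pred <- data.frame(habitat = factor(sample(c("aq", "te", "ar"), 30, TRUE)),
                     diet = factor(sample(c("fish", "frog"), 30, TRUE)),
                     size = aln$log_centroid_size)
  C <- bm_covariance(md$tree, md$taxa)
  f1 <- fit_pgls_rrpp(Y, pred, C, n_perm = 99, seed = 3)
  f2 <- fit_pgls_rrpp(cbind(Y, Y), pred, C, n_perm = 99, seed = 3)
  expect_equal(f2$F, f1$F, tolerance = 1e-10)
  expect_equal(f2$p, f1$p)
  expect_equal(f2$SS, 2 * f1$SS, tolerance = 1e-10)
})

test_that("PGLS invariants: sequential SS identity, p > 0, determinism", {
  md <- fix_dataset(30, seed = 34)
  aln <- generalized_procrustes(module_subset(md$landmarks, "braincase"))
  Y <- flatten_shapes(aln)
  set.seed(134)
  pred <- data.frame(habitat = factor(sample(c("aq", "te", "ar"), 30, TRUE)),
                     primary_diet = factor(sample(c("fish", "frog"), 30, TRUE)),
                     size = aln$log_centroid_size)
  C <- bm_covariance(md$tree, md$taxa)
  f <- fit_pgls_rrpp(Y, pred, C, n_perm = 199, seed = 4)
  ss <- f$SS[f$term %in% c("habitat", "primary_diet", "size")]
  expect_equal(sum(ss) + f$SS[f$term == "Residuals"],
               f$SS[f$term == "Total"], tolerance = 1e-8)
  expect_true(all(f$p[1:3] >= 1 / 200))
  f2 <- fit_pgls_rrpp(Y, pred, C, n_perm = 199, seed = 4)
  expect_identical(as.data.frame(f), as.data.frame(f2))
  expect_error(fit_pgls_rrpp(Y, data.frame(g = factor(rep("a", 30))), C),
               "single level")
})

test_that("aliased designs error by default and drop columns on request", {
  set.seed(48)
  n <- 24
  g1 <- factor(rep(c("a", "b", "c"), each = 8))
  # one level of g4 coincides exactly with g1 == "b": that dummy is aliased,
  # but g4 keeps informative levels elsewhere
  g4 <- factor(c(sample(c("m", "n"), 8, TRUE), rep("o", 8),
                 sample(c("m", "n"), 8, TRUE)))
  pred <- data.frame(g1 = g1, g4 = g4)
  Y <- matrix(rnorm(n * 2), n)
  expect_error(fit_pgls_rrpp(Y, pred, diag(n), n_perm = 9), "singular")
  expect_warning(f <- fit_pgls_rrpp(Y, pred, diag(n), n_perm = 9,
                                    drop_aliased = TRUE, seed = 1), "aliased")
  expect_equal(f$df[f$term == "g4"], 1)
  expect_equal(f$df[f$term == "g1"], 2)
  # a fully duplicated term is still an error even when dropping
  g5 <- factor(ifelse(g1 == "a", "x", "y"))
  g6 <- factor(ifelse(g1 == "a", "p", "q"))
  expect_error(suppressWarnings(
    fit_pgls_rrpp(Y, data.frame(g5 = g5, g6 = g6), diag(n), n_perm = 9,
                  drop_aliased = TRUE)), "entirely aliased")
})

test_that("RRPP p-values are calibrated under an iid null", {
  set.seed(35)
  n <- 40
  ps <- replicate(300, {
    Y <- matrix(rnorm(n * 3), n)
    pred <- data.frame(g = factor(sample(c("a", "b", "c"), n, TRUE)),
                       x = rnorm(n))
    fit_pgls_rrpp(Y, pred, diag(n), n_perm = 199)$p[1]
  })
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("GLS matches OLS at identity covariance and nlme::gls on a tree", {
  set.seed(36)
  n <- 30
  pred <- data.frame(habitat = factor(sample(c("aq", "te", "ar"), n, TRUE)),
                     size = rnorm(n))
  y <- rnorm(n) + as.numeric(pred$habitat)
  fit <- fit_gls_terms(y, pred, diag(n))
  ref <- lm(y ~ habitat + size, data = pred)
  expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-8)
  # Wald chi-square oracle from the OLS fit, built independently
  V <- vcov(ref)
  bh <- coef(ref)[2:3]
  w <- drop(t(bh) %*% solve(V[2:3, 2:3]) %*% bh)
  expect_equal(fit$table$chisq[1], w, tolerance = 1e-6)
  expect_equal(fit$table$p[1], pchisq(w, 2, lower.tail = FALSE),
               tolerance = 1e-8)

  # phylogenetic case against nlme::gls with a Brownian correlation
  skip_if_not_installed("nlme")
  tree <- fix_tree(25, seed = 37)
  set.seed(38)
  dat <- data.frame(y = rnorm(25), x = rnorm(25), taxon = tree$tip.label)
  C <- bm_covariance(tree)
  fit2 <- fit_gls_terms(dat$y, dat["x"], C)
  ref2 <- nlme::gls(y ~ x, data = dat,
                    correlation = ape::corBrownian(1, tree, form = ~taxon))
  expect_equal(unname(fit2$coefficients), unname(coef(ref2)), tolerance = 1e-6)
})

test_that("GLS detects a pure size effect and ignores absent group effects", {
  tree <- fix_tree(60, seed = 39)
  C <- bm_covariance(tree)
  set.seed(40)
  size <- rnorm(60)
  y <- 2 * size + drop(simulate_multivariate_bm(tree, matrix(0.01)))
  pred <- data.frame(habitat = factor(sample(c("aq", "te", "ar"), 60, TRUE)),
                     size = size)
  fit <- fit_gls_terms(y, pred, C)
  expect_lt(fit$table$p[fit$table$term == "size"], 1e-6)
  expect_gt(fit$table$p[fit$table$term == "habitat"], 0.01)
})

test_that("GLS coefficients are invariant to coherent taxon permutation", {
  md <- fix_dataset(24, seed = 41)
  aln <- generalized_procrustes(module_subset(md$landmarks, "braincase"))
  pca <- shape_pca(aln)
  set.seed(141)
  pred <- data.frame(habitat = factor(sample(c("aq", "te", "ar"), 24, TRUE)),
                     size = aln$log_centroid_size)
  C <- bm_covariance(md$tree, md$taxa)
  fit1 <- fit_gls_terms(pca$scores[, 1], pred, C)
  set.seed(42)
  perm <- sample(24)
  fit2 <- fit_gls_terms(pca$scores[perm, 1], pred[perm, ], C[perm, perm])
  expect_equal(fit1$coefficients, fit2$coefficients, tolerance = 1e-10)
})

test_that("PPLS: self-integration, identity-covariance reduction, errors", {
  set.seed(43)
  n <- 20
  Y1 <- matrix(rnorm(n * 4), n)
  pls <- ppls_integration(Y1, Y1, diag(n), n_perm = 49, seed = 1)
  expect_equal(pls$r_pls, 1, tolerance = 1e-10)
  expect_error(ppls_integration(Y1, matrix(1, n, 2), diag(n)), "constant")

  # identity covariance equals an ordinary two-block PLS computed in-test
  Y2 <- matrix(rnorm(n * 3), n)
  pls2 <- ppls_integration(Y1, Y2, diag(n), n_perm = 49, seed = 2)
  A <- scale(Y1, scale = FALSE); B <- scale(Y2, scale = FALSE)
  sv <- svd(crossprod(A, B))
  r_ref <- cor(drop(A %*% sv$u[, 1]), drop(B %*% sv$v[, 1]))
  expect_equal(pls2$r_pls, r_ref, tolerance = 1e-8)
})

test_that("PPLS p-values are calibrated under independence", {
  tree <- fix_tree(30, seed = 44)
  C <- bm_covariance(tree)
  set.seed(45)
  ps <- replicate(200, {
    Y1 <- simulate_multivariate_bm(tree, diag(3))
    Y2 <- simulate_multivariate_bm(tree, diag(2))
    ppls_integration(Y1, Y2, C, n_perm = 199)$p
  })
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
  expect_true(all(ps >= 1 / 200))
})

test_that("r_pls rises monotonically with shared latent strength", {
  tree <- fix_tree(40, seed = 46)
  C <- bm_covariance(tree)
  set.seed(47)
  mean_r <- vapply(c(0, 0.5, 1, 2, 4), function(strength) {
    mean(replicate(15, {
      latent <- drop(simulate_multivariate_bm(tree, matrix(1)))
      Y1 <- matrix(rnorm(40 * 2), 40) + strength * latent
      Y2 <- matrix(rnorm(40 * 2), 40) + strength * latent
      ppls_integration(Y1, Y2, C, n_perm = 9)$r_pls
    }))
  }, numeric(1))
  expect_true(all(diff(mean_r) > 0))
})
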