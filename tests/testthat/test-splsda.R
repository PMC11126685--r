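sim_counts <- function(n = 8, p = 6, seed = 1) {
  set.seed(seed)
  m <- matrix(rpois(n * p, 4), n, p,
              dimnames = list(paste0("sp", 1:n), paste0("OG", 1:p)))
  m
}

two_groups <- function(m) {
  stats::setNames(rep(c("focal", "other"), length.out = nrow(m)), rownames(m))
}

test_that("a perfectly separating feature is forced into a keepX = 1 support", {
  m <- sim_counts(8, 5, seed = 2)
  g <- stats::setNames(rep(c("focal", "other"), each = 4), rownames(m))
  m[, 3] <- ifelse(g == "focal", 0L, 10L)
  fit <- fit_splsda(m, g, splsda_params(n_components = 1, keepX = 1))
  w <- fit$loadings[, 1]
  expect_equal(sum(w != 0), 1L)
  expect_equal(names(which(w != 0)), "OG3")
  expect_equal(abs(w[["OG3"]]), 1)
})

test_that("non-sparse component-1 weight matches the dense SVD of X'Y", {
  set.seed(13)
  m <- matrix(rnorm(30 * 40, 10, 3), 30, 40,
              dimnames = list(paste0("sp", 1:30), paste0("OG", 1:40)))
  g <- two_groups(m)
  m[g == "focal", 1:5] <- m[g == "focal", 1:5] + 4
  fit <- fit_splsda(round(pmax(m, 0)), g,
                    splsda_params(n_components = 1, keepX = 40))
  sc <- scale(round(pmax(m, 0)))
  Y0 <- cbind(g == "focal", g == "other") * 1
  Y <- scale(Y0)
  sv <- svd(crossprod(sc, Y))
  cosine <- abs(sum(fit$loadings[, 1] * sv$u[, 1]))
  expect_gte(cosine, 1 - 1e-8)
})

test_that("planted expanded families dominate the top-100 contributors", {
  ds <- simulate_dataset(sim_config(seed = 22))
  mf <- filter_families(ds$matrix)
  fit <- fit_splsda(mf, ds$groups)
  top <- top_contributors(fit, 1, 100)
  expect_gte(sum(ds$truth$families$expanded %in% top$family), 18L)
})

test_that("the two Y codings select the same component-1 support", {
  m <- sim_counts(12, 30, seed = 5)
  g <- two_groups(m)
  m[g == "focal", 1:4] <- m[g == "focal", 1:4] * 3L
  f1 <- fit_splsda(m, g, splsda_params(n_components = 1, keepX = 6))
  f2 <- fit_splsda(m, g, splsda_params(n_components = 1, keepX = 6),
                   y_coding = "pm1")
  expect_setequal(f1$selected[[1]], f2$selected[[1]])
})

test_that("support sizes, score orthogonality and permutation invariance hold", {
  set.seed(9)
  m <- sim_counts(20, 50, seed = 9)
  g <- two_groups(m)
  m[g == "focal", 1:6] <- m[g == "focal", 1:6] * 4L
  fit <- fit_splsda(m, g, splsda_params(n_components = 2, keepX = c(10, 15)))
  expect_equal(colSums(fit$loadings != 0), c(10L, 15L))
  expect_lt(abs(sum(fit$scores[, 1] * fit$scores[, 2])), 1e-8)
  # permuting species rows together with labels leaves loadings unchanged
  perm <- sample(nrow(m))
  fit_p <- fit_splsda(m[perm, ], g[perm],
                      splsda_params(n_components = 2, keepX = c(10, 15)))
  expect_equal(fit_p$loadings, fit$loadings, tolerance = 1e-8)
})

test_that("permuting labels alone destroys planted-family recovery", {
  ds <- simulate_dataset(sim_config(seed = 25, n_background = 500))
  mf <- filter_families(ds$matrix)
  set.seed(26)
  perm <- stats::setNames(sample(ds$groups), names(ds$groups))
  fit <- fit_splsda(mf, perm, splsda_params(n_components = 1, keepX = 100))
  top <- top_contributors(fit, 1, 100)
  n_planted <- sum(ds$truth$families$expanded %in% top$family)
  # chance level: 20 planted among ~520 families, 100 picks -> ~4 expected
  expect_lte(n_planted, 10L)
})

test_that("explained variance matches a Gram-Schmidt projection oracle", {
  set.seed(17)
  m <- sim_counts(15, 25, seed = 17)
  g <- two_groups(m)
  fit <- fit_splsda(m, g, splsda_params(n_components = 2, keepX = 25))
  X <- fit$X
  t1 <- fit$scores[, 1]; t2 <- fit$scores[, 2]
  u1 <- t1 / sqrt(sum(t1^2))
  t2o <- t2 - u1 * sum(u1 * t2)
  u2 <- t2o / sqrt(sum(t2o^2))
  frac <- c(sum((crossprod(X, u1))^2), sum((crossprod(X, u2))^2)) / sum(X^2)
  expect_equal(fit$explained_variance, frac, tolerance = 1e-10)
  expect_lte(sum(fit$explained_variance), 1)
  # rank-1 X captures everything on one component
  r1 <- outer(1:10, 1:4)
  dimnames(r1) <- list(paste0("sp", 1:10), paste0("OG", 1:4))
  g1 <- stats::setNames(rep(c("focal", "other"), 5), rownames(r1))
  # rank-1 after centering requires proportional columns; scale() keeps rank 1
  fit1 <- fit_splsda(r1, g1, splsda_params(n_components = 1, keepX = 4))
  expect_equal(fit1$explained_variance, 1, tolerance = 1e-10)
})

test_that("top_contributors ranks by absolute loading with stable ties", {
  m <- sim_counts(10, 5, seed = 3)
  g <- two_groups(m)
  fit <- fit_splsda(m, g, splsda_params(n_components = 1, keepX = 3))
  mock <- fit
  mock$loadings[, 1] <- c(-0.9, 0.3, 0, 0, 0.1)
  top <- top_contributors(mock, 1, 2)
  expect_equal(top$family, c("OG1", "OG2"))
  expect_error(top_contributors(fit, 1, 0), "positive")
  expect_error(top_contributors(fit, 1, 4), "exceeds keepX")
})

test_that("zero-variance features keep zero loadings and keepX is clipped", {
  m <- sim_counts(10, 6, seed = 8)
  m[, 2] <- 5L
  g <- two_groups(m)
  expect_warning(fit <- fit_splsda(m, g, splsda_params(n_components = 1, keepX = 6)),
                 "clipped")
  expect_equal(unname(fit$loadings["OG2", 1]), 0)
})

test_that("component-1 selection agrees with an independent sPLS-DA implementation", {
  skip_if_not_installed("mixOmics")
  ds <- simulate_dataset(sim_config(seed = 22, n_background = 500))
  mf <- filter_families(ds$matrix)
  fit <- fit_splsda(mf, ds$groups, splsda_params(n_components = 1, keepX = 50))
  ref <- mixOmics::splsda(mf, factor(ds$groups[rownames(mf)]),
                          ncomp = 1, keepX = 50)
  ref_sel <- mixOmics::selectVar(ref, comp = 1)$name
  expect_setequal(fit$selected[[1]], ref_sel)
  w_ref <- ref$loadings$X[, 1]
  cosine <- abs(sum(fit$loadings[, 1] * w_ref) / sqrt(sum(w_ref^2)))
  expect_gte(cosine, 1 - 1e-6)
})
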