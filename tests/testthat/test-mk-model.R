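test_that("cherry likelihood matches the closed form", {
  tree <- parse_newick("(A:1,B:1);")
  model <- mk_model(1, 1, kind = "ER", root_prior = "uniform")
  lik <- 0.5 * (((1 + exp(-2)) / 2)^2 + ((1 - exp(-2)) / 2)^2)
  expect_equal(mk_loglik(tree, c(A = 0, B = 0), model), log(lik),
               tolerance = 1e-12)
})

test_that("zero-length branch with matching state under a point prior gives logL 0", {
  tree <- parse_newick("(A:0,B:1);")
  # conditioning the root on state 0: the zero-length tip contributes 1
  model <- mk_model(1, 1, kind = "ER", root_prior = c(1, 0))
  ll_match <- mk_loglik(tree, c(A = 0, B = 0), model)
  ll_b1 <- mk_loglik(tree, c(A = 0, B = 1), model)
  # only the B branch contributes in either case
  expect_equal(ll_match, log(oracle_p(0, 0, 1, 1, 1)), tolerance = 1e-12)
  expect_equal(ll_b1, log(oracle_p(0, 1, 1, 1, 1)), tolerance = 1e-12)
  # and a fully-zero tree with a matching point prior has logL exactly 0
  tree0 <- parse_newick("(A:0,B:0);")
  expect_equal(mk_loglik(tree0, c(A = 0, B = 0), model), 0)
})

test_that("pruning equals exhaustive enumeration on random small trees", {
  set.seed(42)
  for (i in 1:25) {
    n <- sample(4:6, 1)
    tree <- rand_tree(n)
    trait <- rand_trait(tree)
    q01 <- runif(1, 0.1, 3); q10 <- runif(1, 0.1, 3)
    model <- mk_model(q01, q10)
    expect_equal(mk_loglik(tree, trait, model),
                 log(oracle_mk_lik(tree, trait, q01, q10)),
                 tolerance = 1e-10)
  }
})

test_that("likelihood handles polytomies and is invariant to zero-length subdivision", {
  set.seed(7)
  poly <- parse_newick("((A:1,B:1,C:1):0.5,(D:1,E:1):0.7);")
  trait <- c(A = 1, B = 1, C = 0, D = 0, E = 1)
  model <- mk_model(0.8, 1.2)
  expect_equal(mk_loglik(poly, trait, model),
               log(oracle_mk_lik(poly, trait, 0.8, 1.2)), tolerance = 1e-10)
  # split one branch into two by a zero-length edge: likelihood unchanged
  split <- parse_newick("((A:1,B:1,C:1):0.5,((D:1,E:1):0):0.7);")
  expect_equal(mk_loglik(split, trait, model), mk_loglik(poly, trait, model),
               tolerance = 1e-12)
})

test_that("missing tips are reported by name", {
  tree <- parse_newick("((A:1,B:1):1,C:1);")
  expect_error(mk_loglik(tree, c(A = 0, B = 1), mk_model(1, 1)),
               "missing from trait.*C")
})

test_that("ARD log-likelihood dominates ER and the cherry fit matches a rate grid", {
  set.seed(11)
  for (i in 1:5) {
    tree <- rand_tree(20)
    trait <- rand_trait(tree)
    er <- fit_mk(tree, trait, kind = "ER")
    ard <- fit_mk(tree, trait, kind = "ARD")
    expect_gte(ard$log_likelihood, er$log_likelihood - 1e-6)
  }
  # grid oracle on a (0,1) cherry: profile maximum at the fitted ER rate
  cherry <- parse_newick("(A:1,B:1);")
  trait <- c(A = 0, B = 1)
  fit <- fit_mk(cherry, trait, kind = "ER")
  grid <- exp(seq(log(1e-4), log(100), length.out = 4000))
  prof <- vapply(grid, function(q) {
    mk_loglik(cherry, trait, mk_model(q, q, kind = "ER"))
  }, numeric(1))
  # the fit attains (at least) the best grid value
  expect_gte(fit$log_likelihood, max(prof) - 1e-6)
})

test_that("a one-state trait pins the unobserved rate with a warning", {
  tree <- rand_tree(8)
  trait <- stats::setNames(rep(0L, 8), tree$tip.label)
  expect_warning(fit <- fit_mk(tree, trait, kind = "ARD"), "pinned")
  expect_true(fit$boundary)
})

test_that("rate recovery: median fitted ARD q01 within a factor of two", {
  set.seed(123)
  tree <- ape::rphylo(300, 1, 0)
  tree$edge.length <- tree$edge.length / max(ape::node.depth.edgelength(tree))
  tree$tip.label <- sprintf("sp%03d", 1:300)
  cfg <- sim_config(seed = 1, n_species = 300, trait_mode = "mk",
                    q01 = 0.5, q10 = 1.5)
  q01_hat <- replicate(50, {
    tra <- sim_trait(tree, cfg)
    if (length(unique(tra$trait)) < 2) return(NA_real_)
    fit_mk(tree, tra$trait, kind = "ARD")$model$q01
  })
  med <- stats::median(q01_hat, na.rm = TRUE)
  expect_gt(med, 0.25)
  expect_lt(med, 1.0)
})

test_that("compare_models reports LR arithmetic and the ER tie-break", {
  tree <- rand_tree(10)
  trait <- rand_trait(tree)
  er <- fit_mk(tree, trait, kind = "ER")
  ard <- fit_mk(tree, trait, kind = "ARD")
  # synthetic asr_result shells with controlled likelihoods
  er2 <- er; er2$log_likelihood <- -50
  ard2 <- ard; ard2$log_likelihood <- -48
  cm <- compare_models(er2, ard2)
  expect_equal(cm$lr_stat, 4)
  expect_equal(cm$retained, "ARD")
  expect_equal(cm$aic_er, 2 + 100)
  expect_equal(cm$aic_ard, 4 + 96)
  ard3 <- ard; ard3$log_likelihood <- -50
  expect_equal(compare_models(er2, ard3)$retained, "ER")
  # mismatched data rejected
  other <- fit_mk(tree, stats::setNames(1L - trait, names(trait)), kind = "ARD")
  expect_error(compare_models(er, other), "different data")
})

test_that("the ARD fit agrees with an independent Mk implementation", {
  skip_if_not_installed("phytools")
  set.seed(3)
  tree <- ape::rphylo(60, 1, 0)
  tree$edge.length <- tree$edge.length / max(ape::node.depth.edgelength(tree))
  tree$tip.label <- sprintf("t%02d", 1:60)
  cfg <- sim_config(seed = 3, n_species = 60, trait_mode = "mk",
                    q01 = 0.8, q10 = 1.4)
  trait <- sim_trait(tree, cfg)$trait
  fit <- fit_mk(tree, trait, kind = "ARD", root_prior = "uniform")
  x <- stats::setNames(as.character(trait), names(trait))
  ref <- phytools::fitMk(tree, x, model = "ARD", pi = "equal")
  expect_equal(fit$log_likelihood, as.numeric(stats::logLik(ref)),
               tolerance = 1e-4)
  # reference orders its rate vector as (1->0, 0->1)
  expect_equal(c(fit$model$q10, fit$model$q01), unname(ref$rates),
               tolerance = 1e-2)
})
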