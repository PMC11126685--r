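#' Define a two-state Mk model
#'
#' Continuous-time Markov model for a binary character on a phylogeny.
#' `ER` (equal rates) constrains the gain rate `q01` (0 to 1) and loss rate
#' `q10` (1 to 0) to be equal; `ARD` (all rates different) leaves them free.
#'
#' @param q01 Gain rate (state 0 to 1), per unit branch length, > 0.
#' @param q10 Loss rate (state 1 to 0), > 0. Must equal `q01` when `kind = "ER"`.
#' @param kind `"ER"` or `"ARD"`.
#' @param root_prior `"uniform"` (0.5, 0.5), `"stationary"`
#'   (q10, q01)/(q01+q10), or a numeric length-2 probability vector.
#' @return An object of class `mk_model`.
#' @export
mk_model <- function(q01, q10 = q01, kind = c("ARD", "ER"), root_prior = "uniform") {
  kind <- match.arg(kind)
  if (!is.finite(q01) || !is.finite(q10) || q01 <= 0 || q10 <= 0) {
    stop("rates must be finite and positive")
  }
  if (kind == "ER" && abs(q01 - q10) > 1e-12) stop("ER model requires q01 == q10")
  if (is.numeric(root_prior)) {
    if (length(root_prior) != 2L || any(root_prior < 0) ||
        abs(sum(root_prior) - 1) > 1e-9) {
      stop("custom root prior must be two non-negative numbers summing to 1")
    }
  } else if (!root_prior[1] %in% c("uniform", "stationary")) {
    stop("root_prior must be 'uniform', 'stationary', or a length-2 vector")
  }
  structure(list(q01 = q01, q10 = q10, kind = kind, root_prior = root_prior),
            class = "mk_model")
}

root_prior_vector <- function(model) {
  rp <- model$root_prior
  if (is.numeric(rp)) return(rp)
  if (rp == "stationary") {
    s <- model$q01 + model$q10
    return(c(model$q10, model$q01) / s)
  }
  c(0.5, 0.5)
}

## Closed-form 2-state transition probabilities for all edge lengths at once.
## Returns a list of vectors P00, P01, P10, P11 (rows of P(t) per edge).
mk_transition <- function(q01, q10, t) {
  s <- q01 + q10
  e <- exp(-s * t)
  P00 <- (q10 + q01 * e) / s
  P11 <- (q01 + q10 * e) / s
  list(P00 = P00, P01 = 1 - P00, P10 = 1 - P11, P11 = P11)
}

## Precompute pruning structures shared by likelihood evaluations.
## trait: named 0/1 vector covering all tips.
mk_prepare <- function(tree, trait) {
  ntip <- length(tree$tip.label)
  missing <- setdiff(tree$tip.label, names(trait))
  if (length(missing) > 0L) {
    stop("tip(s) missing from trait vector: ", paste(missing, collapse = ", "))
  }
  states <- as.integer(trait[tree$tip.label])
  if (any(!states %in% c(0L, 1L))) stop("trait states must be 0 or 1")
  tr <- stats::reorder(tree, "postorder")
  list(
    ntip = ntip,
    nnode = tree$Nnode,
    root = ntip + 1L,
    edge = tr$edge,
    len = tr$edge.length,
    states = states
  )
}

## Felsenstein pruning on the prepared structure; returns log-likelihood.
mk_prune <- function(prep, q01, q10, prior) {
  nn <- prep$ntip + prep$nnode
  L <- matrix(1, nn, 2)
  L[seq_len(prep$ntip), 1] <- as.numeric(prep$states == 0L)
  L[seq_len(prep$ntip), 2] <- as.numeric(prep$states == 1L)
  P <- mk_transition(q01, q10, prep$len)
  logscale <- 0
  edge <- prep$edge
  for (k in seq_len(nrow(edge))) {
    p <- edge[k, 1]; ch <- edge[k, 2]
    S0 <- P$P00[k] * L[ch, 1] + P$P01[k] * L[ch, 2]
    S1 <- P$P10[k] * L[ch, 1] + P$P11[k] * L[ch, 2]
    a <- L[p, 1] * S0
    b <- L[p, 2] * S1
    m <- max(a, b)
    if (m > 0 && m < 1e-140) {
      a <- a / m; b <- b / m
      logscale <- logscale + log(m)
    }
    L[p, 1] <- a; L[p, 2] <- b
  }
  lik <- prior[1] * L[prep$root, 1] + prior[2] * L[prep$root, 2]
  if (lik <= 0) return(-Inf)
  log(lik) + logscale
}

#' Mk-model log-likelihood of a binary trait on a tree
#'
#' Felsenstein pruning with the closed-form two-state transition matrix
#' \eqn{P_{00}(t) = (q_{10} + q_{01} e^{-(q_{01}+q_{10})t})/(q_{01}+q_{10})}.
#' Polytomies are handled natively (product over all children); zero-length
#' edges contribute an identity transition.
#'
#' @param tree A `phylo` object with branch lengths.
#' @param trait Named 0/1 vector covering every tip label.
#' @param model An [mk_model()].
#' @return Log-likelihood in nats.
#' @export
mk_loglik <- function(tree, trait, model) {
  stopifnot(inherits(model, "mk_model"))
  prep <- mk_prepare(tree, trait)
  mk_prune(prep, model$q01, model$q10, root_prior_vector(model))
}

#' Fit an Mk model by maximum likelihood
#'
#' Optimizes the rate(s) on the log scale with deterministic multi-start
#' local search (starting points 0.1, 1 and 10 times the inverse tree height),
#' rates bounded in `[1e-8, 1e3]`, convergence tolerance 1e-8.
#'
#' @inheritParams mk_loglik
#' @param kind `"ER"` or `"ARD"`.
#' @param root_prior See [mk_model()].
#' @return An object of class `asr_result` holding the fitted `mk_model`,
#'   `log_likelihood`, and bookkeeping (`boundary` flag when a state is
#'   unobserved at the tips). Posteriors are added by [asr_marginal()].
#' @export
fit_mk <- function(tree, trait, kind = c("ARD", "ER"), root_prior = "uniform") {
  kind <- match.arg(kind)
  prep <- mk_prepare(tree, trait)
  boundary <- length(unique(prep$states)) < 2L
  if (boundary) {
    warning("all tips share one state; rate for the unobserved transition ",
            "is pinned at the lower bound")
  }
  height <- max(node_depths(tree))
  if (height <= 0) height <- 1
  lb <- log(1e-8); ub <- log(1e3)
  starts <- log(c(0.1, 1, 10) / height)
  starts <- pmin(pmax(starts, lb), ub)

  prior_of <- function(q01, q10) {
    m <- list(q01 = q01, q10 = q10, root_prior = root_prior)
    root_prior_vector(m)
  }
  nll <- function(lq) {
    lq <- pmin(pmax(lq, lb), ub)
    q <- exp(lq)
    if (length(q) == 1L) q <- c(q, q)
    -mk_prune(prep, q[1], q[2], prior_of(q[1], q[2]))
  }

  best <- NULL
  for (s in starts) {
    if (kind == "ER") {
      fit <- stats::optim(s, nll, method = "Brent", lower = lb, upper = ub,
                          control = list(reltol = 1e-8))
    } else {
      fit <- stats::optim(c(s, s), nll,
                          control = list(reltol = 1e-8, maxit = 2000))
    }
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  lq <- pmin(pmax(best$par, lb), ub)
  q <- exp(lq)
  if (length(q) == 1L) q <- c(q, q)
  model <- mk_model(q[1], if (kind == "ER") q[1] else q[2], kind = kind,
                    root_prior = root_prior)
  structure(list(
    model = model,
    log_likelihood = -best$value,
    kind = kind,
    boundary = boundary,
    tree = tree,
    trait = trait,
    posterior = NULL,
    called_states = NULL,
    n_gains = NA_integer_,
    n_losses = NA_integer_
  ), class = "asr_result")
}

#' @export
print.asr_result <- function(x, ...) {
  cat("Mk", x$kind, "fit: q01 =", signif(x$model$q01, 4),
      " q10 =", signif(x$model$q10, 4),
      " logL =", round(x$log_likelihood, 4), "\n")
  if (!is.null(x$posterior)) {
    cat("marginal ASR available;",
        if (!is.na(x$n_gains)) paste0("gains = ", x$n_gains,
                                      ", losses = ", x$n_losses) else "", "\n")
  }
  invisible(x)
}

#' Compare fitted ER and ARD models
#'
#' Reports the log-likelihood difference, the likelihood-ratio statistic
#' `2 * (logL_ARD - logL_ER)` with its 1-df chi-squared p-value, AIC for both
#' models, and the retained model (the higher-likelihood one; ER on ties
#' within the optimizer tolerance, as the more parsimonious model).
#'
#' @param er,ard `asr_result` objects from [fit_mk()] on the same tree/trait.
#' @param tol Tie tolerance on the log-likelihood difference (default 1e-6).
#' @return A list with `delta_loglik`, `lr_stat`, `p_value`, `aic_er`,
#'   `aic_ard`, `retained`.
#' @export
compare_models <- function(er, ard, tol = 1e-6) {
  stopifnot(inherits(er, "asr_result"), inherits(ard, "asr_result"))
  if (er$kind != "ER" || ard$kind != "ARD") {
    stop("arguments must be an ER fit and an ARD fit, in that order")
  }
  same_tips <- identical(sort(er$tree$tip.label), sort(ard$tree$tip.label))
  same_trait <- isTRUE(all.equal(er$trait[sort(names(er$trait))],
                                 ard$trait[sort(names(ard$trait))]))
  if (!same_tips || !same_trait) stop("ER and ARD fits are on different data")
  delta <- ard$log_likelihood - er$log_likelihood
  lr <- max(2 * delta, 0)
  list(
    delta_loglik = delta,
    lr_stat = lr,
    p_value = stats::pchisq(lr, df = 1, lower.tail = FALSE),
    aic_er = 2 * 1 - 2 * er$log_likelihood,
    aic_ard = 2 * 2 - 2 * ard$log_likelihood,
    retained = if (delta < tol) "ER" else "ARD"
  )
}
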