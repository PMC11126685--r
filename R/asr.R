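#' Marginal ancestral state reconstruction under an Mk model
#'
#' Computes, for every node, the marginal posterior probability of each state
#' given the tip data and the (fitted or supplied) rates, by combining the
#' downward (pruning) conditional likelihoods with upward partial likelihoods
#' for the rest of the tree. Tip posteriors are point masses on the observed
#' states; internal posteriors sum to one.
#'
#' @param tree A `phylo` object. May be omitted when `fit` is given.
#' @param trait Named 0/1 vector over the tips.
#' @param model An [mk_model()] with finite positive rates.
#' @param fit Alternatively, an `asr_result` from [fit_mk()]; its tree, trait
#'   and fitted model are used.
#' @return An `asr_result` with a `posterior` matrix (rows = nodes in ape
#'   numbering, columns `P0`, `P1`).
#' @export
asr_marginal <- function(tree = NULL, trait = NULL, model = NULL, fit = NULL) {
  if (!is.null(fit)) {
    stopifnot(inherits(fit, "asr_result"))
    tree <- fit$tree; trait <- fit$trait; model <- fit$model
  }
  stopifnot(inherits(model, "mk_model"))
  if (!all(is.finite(c(model$q01, model$q10)))) stop("model rates must be finite")
  prep <- mk_prepare(tree, trait)
  prior <- root_prior_vector(model)
  nn <- prep$ntip + prep$nnode
  edge <- prep$edge
  ne <- nrow(edge)
  P <- mk_transition(model$q01, model$q10, prep$len)

  ## downward pass: conditional likelihood of the subtree below each node
  L <- matrix(1, nn, 2)
  L[seq_len(prep$ntip), 1] <- as.numeric(prep$states == 0L)
  L[seq_len(prep$ntip), 2] <- as.numeric(prep$states == 1L)
  S <- matrix(0, ne, 2) # S[k, i] = P(subtree below edge k | parent state i-1)
  logscale <- 0
  for (k in seq_len(ne)) {
    p <- edge[k, 1]; ch <- edge[k, 2]
    S[k, 1] <- P$P00[k] * L[ch, 1] + P$P01[k] * L[ch, 2]
    S[k, 2] <- P$P10[k] * L[ch, 1] + P$P11[k] * L[ch, 2]
    a <- L[p, 1] * S[k, 1]; b <- L[p, 2] * S[k, 2]
    m <- max(a, b)
    if (m > 0 && m < 1e-140) {
      a <- a / m; b <- b / m
      logscale <- logscale + log(m)
    }
    L[p, 1] <- a; L[p, 2] <- b
  }
  lik <- prior[1] * L[prep$root, 1] + prior[2] * L[prep$root, 2]
  logL <- if (lik > 0) log(lik) + logscale else -Inf

  ## product of sibling-edge contributions per parent and state
  prodS <- matrix(1, nn, 2)
  for (k in seq_len(ne)) {
    p <- edge[k, 1]
    prodS[p, 1] <- prodS[p, 1] * S[k, 1]
    prodS[p, 2] <- prodS[p, 2] * S[k, 2]
  }

  ## upward pass (preorder): G[v, i] = P(data outside subtree of v, v = i)
  ## up to a per-node constant; includes the root prior.
  G <- matrix(0, nn, 2)
  G[prep$root, ] <- prior
  edges_of_parent <- split(seq_len(ne), edge[, 1])
  for (k in rev(seq_len(ne))) {
    p <- edge[k, 1]; ch <- edge[k, 2]
    H <- numeric(2)
    for (i in 1:2) {
      if (S[k, i] > 0) {
        H[i] <- G[p, i] * prodS[p, i] / S[k, i]
      } else {
        sib <- setdiff(edges_of_parent[[as.character(p)]], k)
        H[i] <- G[p, i] * prod(S[sib, i])
      }
    }
    G[ch, 1] <- H[1] * P$P00[k] + H[2] * P$P10[k]
    G[ch, 2] <- H[1] * P$P01[k] + H[2] * P$P11[k]
    m <- max(G[ch, ])
    if (m > 0) G[ch, ] <- G[ch, ] / m
  }

  post <- L * G
  rs <- rowSums(post)
  if (any(rs <= 0)) stop("zero posterior mass at node(s); check model rates")
  post <- post / rs
  colnames(post) <- c("P0", "P1")

  structure(list(
    model = model,
    log_likelihood = logL,
    kind = model$kind,
    boundary = length(unique(prep$states)) < 2L,
    tree = tree,
    trait = trait,
    posterior = post,
    called_states = NULL,
    n_gains = NA_integer_,
    n_losses = NA_integer_
  ), class = "asr_result")
}

#' Count trait gains and losses from a marginal reconstruction
#'
#' Calls each node state 1 when its posterior P(1) exceeds `threshold`
#' (default 0.5). A node whose posterior equals the threshold exactly is
#' flagged ambiguous and inherits its parent's call (the root defaults to 0).
#' A gain is an edge whose parent is called 0 and child 1; a loss the reverse.
#'
#' @param asr An `asr_result` with posteriors (see [asr_marginal()]).
#' @param tree The tree; defaults to the one stored in `asr`.
#' @param threshold Posterior cutoff in (0, 1).
#' @return A list: `n_gains`, `n_losses`, `gain_edges`, `loss_edges` (matrices
#'   of parent/child node ids), `called_states` (per node), `ambiguous`
#'   (logical per node), and the updated `asr_result` as `$asr`.
#' @export
count_transitions <- function(asr, tree = asr$tree, threshold = 0.5) {
  stopifnot(inherits(asr, "asr_result"))
  if (is.null(asr$posterior)) stop("asr has no posteriors; run asr_marginal() first")
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1) {
    stop("threshold must lie strictly inside (0, 1)")
  }
  nn <- nrow(asr$posterior)
  p1 <- asr$posterior[, "P1"]
  called <- integer(nn)
  ambiguous <- logical(nn)
  tr <- stats::reorder(tree, "postorder")
  root <- length(tree$tip.label) + 1L
  call_node <- function(v, parent_call) {
    if (abs(p1[v] - threshold) < 1e-12) {
      ambiguous[v] <<- TRUE
      called[v] <<- parent_call
    } else {
      called[v] <<- as.integer(p1[v] > threshold)
    }
  }
  call_node(root, 0L)
  for (k in rev(seq_len(nrow(tr$edge)))) { # preorder: parents before children
    call_node(tr$edge[k, 2], called[tr$edge[k, 1]])
  }
  par_call <- called[tr$edge[, 1]]
  ch_call <- called[tr$edge[, 2]]
  gains <- tr$edge[par_call == 0L & ch_call == 1L, , drop = FALSE]
  losses <- tr$edge[par_call == 1L & ch_call == 0L, , drop = FALSE]
  asr$called_states <- called
  asr$n_gains <- nrow(gains)
  asr$n_losses <- nrow(losses)
  list(
    n_gains = nrow(gains),
    n_losses = nrow(losses),
    gain_edges = gains,
    loss_edges = losses,
    called_states = called,
    ambiguous = ambiguous,
    asr = asr
  )
}

#' Export an ancestral state reconstruction
#'
#' Writes a per-node TSV (node id, label, posterior P(1), called state) and an
#' annotated newick in which internal node labels carry the posterior P(1).
#'
#' @param asr An `asr_result` with posteriors and called states.
#' @param tsv,newick Output paths (either may be `NULL` to skip).
#' @return The per-node data frame, invisibly.
#' @export
write_asr_result <- function(asr, tsv = NULL, newick = NULL) {
  if (is.null(asr$posterior)) stop("asr has no posteriors")
  tree <- asr$tree
  ntip <- length(tree$tip.label)
  nn <- nrow(asr$posterior)
  labels <- c(tree$tip.label, paste0("node", (ntip + 1L):nn))
  df <- data.frame(
    node = seq_len(nn),
    label = labels,
    posterior_p1 = asr$posterior[, "P1"],
    called_state = if (is.null(asr$called_states)) NA_integer_ else asr$called_states
  )
  if (!is.null(tsv)) {
    utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(newick)) {
    annotated <- tree
    annotated$node.label <- sprintf("%.4f", asr$posterior[(ntip + 1L):nn, "P1"])
    writeLines(ape::write.tree(annotated), newick)
  }
  invisible(df)
}
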