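# Independent oracles used across the suite. Each recomputes a quantity by
# a route different from the implementation under test: exhaustive
# enumeration over ancestral states or group assignments, or direct linear
# algebra.

# 2-state transition probability, scalar version (independent of the
# vectorized implementation inside the package)
oracle_p <- function(i, j, t, q01, q10) {
  s <- q01 + q10
  e <- exp(-s * t)
  p00 <- (q10 + q01 * e) / s
  p11 <- (q01 + q10 * e) / s
  if (i == 0 && j == 0) p00 else if (i == 0 && j == 1) 1 - p00
  else if (i == 1 && j == 1) p11 else 1 - p11
}

# Likelihood by brute-force sum over all ancestral-state assignments
oracle_mk_lik <- function(tree, trait, q01, q10, prior = c(0.5, 0.5)) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  tr <- reorder(tree, "postorder")
  states_tip <- as.integer(trait[tree$tip.label])
  internal <- (ntip + 1L):nn
  grid <- expand.grid(rep(list(0:1), length(internal)))
  total <- 0
  for (r in seq_len(nrow(grid))) {
    st <- integer(nn)
    st[seq_len(ntip)] <- states_tip
    st[internal] <- as.integer(grid[r, ])
    lik <- prior[st[ntip + 1L] + 1L]
    for (k in seq_len(nrow(tr$edge))) {
      lik <- lik * oracle_p(st[tr$edge[k, 1]], st[tr$edge[k, 2]],
                            tr$edge.length[k], q01, q10)
    }
    total <- total + lik
  }
  total
}

# Marginal posteriors by the same enumeration (Bayes over assignments)
oracle_mk_posterior <- function(tree, trait, q01, q10, prior = c(0.5, 0.5)) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  tr <- reorder(tree, "postorder")
  states_tip <- as.integer(trait[tree$tip.label])
  internal <- (ntip + 1L):nn
  grid <- expand.grid(rep(list(0:1), length(internal)))
  post <- matrix(0, nn, 2)
  for (r in seq_len(nrow(grid))) {
    st <- integer(nn)
    st[seq_len(ntip)] <- states_tip
    st[internal] <- as.integer(grid[r, ])
    lik <- prior[st[ntip + 1L] + 1L]
    for (k in seq_len(nrow(tr$edge))) {
      lik <- lik * oracle_p(st[tr$edge[k, 1]], st[tr$edge[k, 2]],
                            tr$edge.length[k], q01, q10)
    }
    for (v in seq_len(nn)) post[v, st[v] + 1L] <- post[v, st[v] + 1L] + lik
  }
  post / rowSums(post)
}

# Exact two-sided Mann-Whitney p by enumeration, with U computed by direct
# pair counting (not rank sums)
oracle_wilcoxon_p <- function(x, y) {
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  cmp <- outer(pooled, pooled, function(a, b) (a > b) + 0.5 * (a == b))
  u_of <- function(idx) sum(cmp[idx, -idx, drop = FALSE])
  u_obs <- u_of(seq_len(n))
  mu <- n * m / 2
  idx_all <- utils::combn(n + m, n)
  us <- apply(idx_all, 2, u_of)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# Minimum total change cost over all ancestral labelings (Sankoff oracle)
oracle_min_changes <- function(tree, presence, gain_cost = 1, loss_cost = 1) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  tr <- reorder(tree, "postorder")
  tip_state <- as.integer(tree$tip.label %in% presence)
  internal <- (ntip + 1L):nn
  grid <- expand.grid(rep(list(0:1), length(internal)))
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    st <- integer(nn)
    st[seq_len(ntip)] <- tip_state
    st[internal] <- as.integer(grid[r, ])
    cost <- 0
    for (k in seq_len(nrow(tr$edge))) {
      a <- st[tr$edge[k, 1]]; b <- st[tr$edge[k, 2]]
      if (a == 0 && b == 1) cost <- cost + gain_cost
      if (a == 1 && b == 0) cost <- cost + loss_cost
    }
    best <- min(best, cost)
  }
  best
}

# Random tree with unit-scale branch lengths and a given tip count
rand_tree <- function(n) {
  tr <- ape::rtree(n)
  tr$tip.label <- paste0("t", seq_len(n))
  tr
}

rand_trait <- function(tree) {
  repeat {
    tr <- stats::setNames(sample(0:1, length(tree$tip.label), replace = TRUE),
                          tree$tip.label)
    if (length(unique(tr)) == 2L) return(tr)
  }
}

# The eight-lineage host tree of the worked transfer-versus-loss example:
# presence in bacteria, Mucoromycotina and the lichen algae; absence in
# Dikarya, animals, land plants, other chlorophytes and the non-symbiotic
# algae.
lineage_tree_fixture <- function() {
  nwk <- paste0("(bacteria:3,((Mucoromycotina:1,Dikarya:1):1,(animals:1.5,",
                "(land_plants:1,(other_chlorophytes:0.8,(NSA_algae:0.5,",
                "LAS_algae:0.5):0.3):0.2):0.5):0.5):1);")
  parse_newick(nwk)
}
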