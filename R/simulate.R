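#' Configuration for a synthetic comparative-phylogenomics dataset
#'
#' Defaults emulate the sampling structure of a chlorophyte-wide
#' lichenization study: a 141-species ultrametric tree; a binary symbiotic
#' trait gained in three independent clades and subsequently lost in eleven
#' species; a large background of orthogroup families plus a small set of
#' trait-linked "expanded" families (count multiplier in symbiotic species)
#' and "xenolog" families present almost only in symbiotic species (focal
#' retention 0.85 vs background retention 0.2, echoing an 11/13 vs 5/23
#' retention pattern).
#'
#' @param seed Integer seed; all downstream draws flow from one RNG stream
#'   in the order tree, trait, families, genes, fixtures.
#' @param n_species Number of tips (default 141).
#' @param trait_mode `"planted"` (default) or `"mk"`.
#' @param k_gains,n_losses Planted gains and losses (defaults 3 and 11).
#' @param loss_frac Maximum fraction of a planted clade's tips that may be
#'   flipped back to absent (default 0.4, so every gained clade keeps a
#'   clear majority of survivors, the way a symbiotic clade of two dozen
#'   species retains about half its members after eleven losses).
#' @param q01,q10 Mk-mode simulation rates (defaults 0.5, 1.5).
#' @param n_background,n_expanded,n_xenolog Family counts (2000, 20, 2).
#' @param expand_multiplier Poisson-mean multiplier in trait-positive species
#'   for expanded families (default 4).
#' @param xeno_focal_retention,xeno_other_retention Presence probabilities of
#'   a xenolog family in trait-positive / trait-negative species (0.85, 0.2).
#' @param deg_link_prob Probability that a gene of a trait-linked family is
#'   differentially expressed (default 0.8; direction a fair coin).
#' @param bg_de_prob Background differential-expression probability (0.05).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_species = 141L,
                       trait_mode = c("planted", "mk"),
                       k_gains = 3L, n_losses = 11L, loss_frac = 0.4,
                       q01 = 0.5, q10 = 1.5,
                       n_background = 2000L, n_expanded = 20L, n_xenolog = 2L,
                       expand_multiplier = 4,
                       xeno_focal_retention = 0.85, xeno_other_retention = 0.2,
                       deg_link_prob = 0.8, bg_de_prob = 0.05) {
  trait_mode <- match.arg(trait_mode)
  if (trait_mode == "planted" && k_gains < 1L) stop("k_gains must be >= 1")
  if (expand_multiplier <= 1) stop("expand_multiplier must exceed 1")
  probs <- c(xeno_focal_retention, xeno_other_retention, deg_link_prob, bg_de_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate an ultrametric Yule species tree
#'
#' Pure-birth tree (rate 1) conditioned on the number of tips, rescaled to
#' height 1, tips labeled `sp001`, `sp002`, ...
#'
#' @param cfg A [sim_config()]; only `n_species` is used. RNG state is taken
#'   from the current stream (see [simulate_dataset()] for the seeding
#'   discipline).
#' @return An ultrametric `phylo` object of height 1.
#' @export
sim_tree <- function(cfg) {
  n <- cfg$n_species
  if (n < 2L) stop("n_species must be >= 2")
  tree <- ape::rphylo(n, birth = 1, death = 0)
  h <- max(node_depths(tree))
  tree$edge.length <- tree$edge.length / h
  tree$tip.label <- sprintf("sp%03d", seq_len(n))
  tree
}

#' Simulate the binary symbiotic trait with known truth
#'
#' In `"planted"` mode the trait history mirrors the kind of history the
#' reconstruction targets: `k_gains` disjoint, strongly clustered and deeply
#' separated clades are set to state 1, then `n_losses` tips inside them are
#' flipped back to 0 as phylogenetically independent loss events (no two
#' flipped tips may form an all-absent subclade, each clade keeps at least
#' `1 - loss_frac` of its tips, and both basal lineages of each clade keep
#' survivors). Clades are screened by a fixed ladder of clustering criteria
#' (long stem relative to the parent's stem, a minimum number of intervening
#' lineages and a minimum path length between any two planted clades) that
#' relaxes only as far as the tree at hand requires, so each tree carries
#' the strongest clustering it affords. In `"mk"` mode the continuous-time
#' Markov chain is simulated edge by edge from a root state drawn from the
#' stationary distribution.
#'
#' @param tree Species tree.
#' @param cfg A [sim_config()].
#' @return A list: `trait` (named 0/1 vector) and `truth` (n_gains,
#'   n_losses, gain_nodes, loss_tips, clade_tips or node states).
#' @export
sim_trait <- function(tree, cfg) {
  if (cfg$trait_mode == "mk") return(sim_trait_mk(tree, cfg))
  ## clustering ladder: stem dominance, min intervening lineages, min path
  ## length, clade size range — strictest first
  ladder <- list(c(2, 5, 0.5, 10, 20), c(1.5, 5, 0.5, 10, 20),
                 c(1.5, 4, 0.4, 10, 22), c(1.2, 4, 0.3, 9, 22),
                 c(1, 3, 0.25, 9, 24), c(1, 2, 0.15, 8, 24),
                 c(0, 1, 0, 8, 28))
  res <- NULL
  for (L in ladder) {
    res <- plant_trait(tree, k = cfg$k_gains, n_loss = cfg$n_losses,
                       min_c = L[4], max_c = L[5], min_side = L[2],
                       min_path = L[3], stem_dom = L[1],
                       loss_frac = cfg$loss_frac)
    if (!is.null(res)) break
  }
  if (is.null(res)) {
    stop("could not place ", cfg$k_gains, " disjoint gain clades with ",
         cfg$n_losses, " independent losses on this tree")
  }
  ntip <- length(tree$tip.label)
  trait <- stats::setNames(rep(0L, ntip), tree$tip.label)
  for (s in res$sets) trait[tree$tip.label[s]] <- 1L
  trait[res$losses] <- 0L
  list(
    trait = trait,
    truth = list(
      n_gains = length(res$chosen), n_losses = length(res$losses),
      gain_nodes = res$chosen, loss_tips = res$losses,
      clade_tips = lapply(res$sets, function(s) tree$tip.label[s])
    )
  )
}

## Clade selection + loss placement under one set of clustering constraints.
## Returns NULL when the constraints cannot be met on this tree.
plant_trait <- function(tree, k, n_loss, min_c, max_c, min_side, min_path,
                        stem_dom, loss_frac) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  tr <- stats::reorder(tree, "postorder")
  parent <- integer(nn); plen <- numeric(nn)
  kids <- vector("list", nn)
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    parent[ch] <- p; plen[ch] <- tr$edge.length[e]
    kids[[p]] <- c(kids[[p]], ch)
  }
  sizes <- vapply(seq_len(nn), function(v) {
    if (v <= ntip) 1L else length(clade_tips(tree, v))
  }, integer(1))
  anc_path <- function(v, a) {
    out <- integer(0)
    while (v != a) { out <- c(out, v); v <- parent[v] }
    out
  }
  ## clustering statistics between two candidate clades: the number of
  ## lineages branching off the path joining them (each would be a separate
  ## loss under a merged single-gain scenario) and the path length itself
  sep_stat <- function(a, b) {
    m <- ape::getMRCA(tree, c(clade_tips(tree, a), clade_tips(tree, b)))
    pa <- anc_path(a, m); pb <- anc_path(b, m)
    onpath <- c(pa, pb, m)
    side <- 0L
    for (u in setdiff(onpath, c(a, b))) {
      for (ch in kids[[u]]) {
        if (!(ch %in% onpath) && ch != a && ch != b) side <- side + 1L
      }
    }
    c(side, sum(plen[c(pa, pb)]))
  }
  try_losses <- function(sets, chosen, quota) {
    for (att in 1:10) {
      losses_all <- character(0); ok <- TRUE
      for (i in seq_len(k)) {
        v <- chosen[i]
        pool <- sample(tree$tip.label[sets[[i]]])
        picked <- character(0)
        for (tp in pool) {
          if (length(picked) == quota[i]) break
          cand <- c(picked, tp)
          if (creates_absent_subclade(tree, v, cand)) next
          basal_ok <- all(vapply(kids[[v]], function(ch) {
            kt <- if (ch <= ntip) tree$tip.label[ch] else clade_tips(tree, ch)
            length(setdiff(kt, cand)) >= min(2L, length(kt))
          }, logical(1)))
          if (basal_ok) picked <- cand
        }
        if (length(picked) < quota[i]) { ok <- FALSE; break }
        losses_all <- c(losses_all, picked)
      }
      if (ok) return(losses_all)
    }
    NULL
  }
  elig <- which(sizes >= min_c & sizes <= max_c & seq_len(nn) > ntip)
  elig <- elig[order(-plen[elig])]
  res <- NULL
  dfs <- function(start, chosen, covered) {
    if (length(chosen) == k) {
      sets <- lapply(chosen, function(v) match(clade_tips(tree, v), tree$tip.label))
      caps <- vapply(sets, function(s) as.integer(floor(length(s) * loss_frac)),
                     integer(1))
      if (sum(caps) < n_loss) return(FALSE)
      quota <- integer(k); remaining <- n_loss
      while (remaining > 0L) {
        for (i in order(-caps)) {
          if (remaining == 0L) break
          if (quota[i] < caps[i]) {
            quota[i] <- quota[i] + 1L; remaining <- remaining - 1L
          }
        }
      }
      losses <- try_losses(sets, chosen, quota)
      if (is.null(losses)) return(FALSE)
      res <<- list(chosen = chosen, sets = sets, losses = losses)
      return(TRUE)
    }
    if (start > length(elig)) return(FALSE)
    for (i in start:length(elig)) {
      v <- elig[i]
      vt <- match(clade_tips(tree, v), tree$tip.label)
      if (any(covered[vt])) next
      if (stem_dom > 0 && plen[v] < stem_dom * plen[parent[v]]) next
      pt <- match(clade_tips(tree, parent[v]), tree$tip.label)
      if (length(setdiff(pt, c(vt, which(covered)))) < 1L) next
      ok <- all(vapply(chosen, function(c2) {
        st <- sep_stat(v, c2)
        st[1] >= min_side && st[2] >= min_path
      }, logical(1)))
      if (!ok) next
      cov2 <- covered; cov2[vt] <- TRUE
      if (dfs(i + 1L, c(chosen, v), cov2)) return(TRUE)
    }
    FALSE
  }
  if (!dfs(1L, integer(0), rep(FALSE, ntip))) return(NULL)
  res
}

## would flipping `flip_tips` (labels) inside clade rooted at v make any
## internal node of that clade an all-absent subtree of size >= 2?
creates_absent_subclade <- function(tree, v, flip_tips) {
  ntip <- length(tree$tip.label)
  tr <- stats::reorder(tree, "postorder")
  absent <- c(tree$tip.label %in% flip_tips, rep(TRUE, tree$Nnode))
  inside <- descendant_flags(tree, v)
  for (k in seq_len(nrow(tr$edge))) {
    p <- tr$edge[k, 1]; ch <- tr$edge[k, 2]
    absent[p] <- absent[p] && absent[ch]
  }
  internal <- which(inside & seq_len(ntip + tree$Nnode) > ntip)
  any(absent[internal])
}

sim_trait_mk <- function(tree, cfg) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  root <- ntip + 1L
  s <- cfg$q01 + cfg$q10
  states <- integer(nn)
  states[root] <- stats::rbinom(1, 1, if (s > 0) cfg$q01 / s else 0.5)
  tr <- stats::reorder(tree, "postorder")
  n_gain <- 0L; n_loss <- 0L
  for (k in rev(seq_len(nrow(tr$edge)))) {
    p <- tr$edge[k, 1]; ch <- tr$edge[k, 2]
    t <- tr$edge.length[k]
    P <- mk_transition(max(cfg$q01, 1e-12), max(cfg$q10, 1e-12), t)
    p1 <- if (states[p] == 0L) {
      if (cfg$q01 == 0) 0 else P$P01
    } else {
      if (cfg$q10 == 0) 1 else P$P11
    }
    states[ch] <- stats::rbinom(1, 1, p1)
    if (states[p] == 0L && states[ch] == 1L) n_gain <- n_gain + 1L
    if (states[p] == 1L && states[ch] == 0L) n_loss <- n_loss + 1L
  }
  trait <- stats::setNames(states[seq_len(ntip)], tree$tip.label)
  list(trait = trait,
       truth = list(n_gains = n_gain, n_losses = n_loss,
                    node_states = states))
}

#' Simulate a species-by-orthogroup count matrix with planted families
#'
#' Background families draw a per-family mean `lambda ~ Gamma(shape 2,
#' scale 1)` and iid Poisson counts per species. Expanded families multiply
#' the Poisson mean by `expand_multiplier` in trait-positive species.
#' Xenolog families are present in trait-positive species with probability
#' `xeno_focal_retention` (count `1 + Poisson(0.3)`) and in trait-negative
#' species with probability `xeno_other_retention`.
#'
#' @param tree Species tree (tip labels define the species set).
#' @param trait Named 0/1 trait vector.
#' @param cfg A [sim_config()].
#' @return A list: `matrix` (integer, species x families), `truth`
#'   (`expanded`, `xenolog`, `background` family-id vectors).
#' @export
sim_matrix <- function(tree, trait, cfg) {
  sp <- tree$tip.label
  if (!all(sp %in% names(trait))) stop("trait must cover all tips")
  ns <- length(sp)
  pos <- trait[sp] == 1L
  nfam <- cfg$n_background + cfg$n_expanded + cfg$n_xenolog
  fam_ids <- sprintf("OG%05d", seq_len(nfam))
  roles <- rep(c("background", "expanded", "xenolog"),
               c(cfg$n_background, cfg$n_expanded, cfg$n_xenolog))
  m <- matrix(0L, ns, nfam, dimnames = list(sp, fam_ids))
  lambda <- stats::rgamma(nfam, shape = 2, scale = 1)
  for (j in seq_len(nfam)) {
    if (roles[j] == "xenolog") {
      keep_pos <- stats::rbinom(sum(pos), 1, cfg$xeno_focal_retention) == 1
      keep_neg <- stats::rbinom(sum(!pos), 1, cfg$xeno_other_retention) == 1
      cnt <- integer(ns)
      cnt[which(pos)[keep_pos]] <- 1L + stats::rpois(sum(keep_pos), 0.3)
      cnt[which(!pos)[keep_neg]] <- 1L + stats::rpois(sum(keep_neg), 0.3)
      m[, j] <- cnt
    } else {
      mean_vec <- rep(lambda[j], ns)
      if (roles[j] == "expanded") mean_vec[pos] <- mean_vec[pos] * cfg$expand_multiplier
      m[, j] <- stats::rpois(ns, mean_vec)
    }
  }
  list(
    matrix = m,
    truth = list(
      background = fam_ids[roles == "background"],
      expanded = fam_ids[roles == "expanded"],
      xenolog = fam_ids[roles == "xenolog"]
    )
  )
}

#' Simulate per-gene differential-expression tables with known truth
#'
#' Instantiates genes for every family of one profiled trait-positive
#' species (as many genes as its count in the matrix). Genes of trait-linked
#' (expanded/xenolog) families are differentially expressed with probability
#' `deg_link_prob` (direction a fair coin unless a partition is supplied);
#' background genes with probability `bg_de_prob`. DE genes draw
#' `logFC = +/-(1.5 + Exp(mean 1))` and `fdr ~ U(0, 0.05)`; null genes draw
#' `logFC ~ N(0, 0.5)` and `fdr ~ U(0, 1)`, redrawn on the rare occasions
#' they would cross both DE thresholds, so the planted DE status is exactly
#' recoverable by thresholding.
#'
#' @param m Count matrix from [sim_matrix()].
#' @param truth Family-role truth from [sim_matrix()].
#' @param cfg A [sim_config()].
#' @param profiled_species Species whose genes are profiled; defaults to the
#'   first trait-positive species. Must have trait 1.
#' @param trait Named trait vector (needed for the default choice).
#' @param partition Optional named list `list(up = , both = , down = )` of
#'   counts; that many trait-linked families are forced to carry exactly
#'   up-only / up-and-down / down-only DE members (families are given extra
#'   genes when their profiled count is too small to support the class).
#' @return A list: `deg` (gene, logFC, pvalue, fdr, contrast), `gene2family`,
#'   `truth` (per-gene DE status, per-family planted class).
#' @export
sim_deg <- function(m, truth, cfg, trait, profiled_species = NULL,
                    partition = NULL) {
  if (is.null(profiled_species)) {
    pos <- names(trait)[trait == 1L]
    if (length(pos) == 0L) stop("no trait-positive species to profile")
    profiled_species <- pos[1]
  }
  if (!profiled_species %in% rownames(m)) stop("profiled species absent from matrix")
  linked <- c(truth$expanded, truth$xenolog)
  counts <- m[profiled_species, ]
  fam_class <- stats::setNames(rep(NA_character_, ncol(m)), colnames(m))
  if (!is.null(partition)) {
    need <- c(rep("up", partition$up), rep("both", partition$both),
              rep("down", partition$down))
    if (length(need) > length(linked)) {
      stop("partition asks for more families than there are trait-linked ones")
    }
    fam_class[linked[seq_along(need)]] <- need
  }
  genes <- list(); g2f <- character(0)
  rows <- list()
  draw_de <- function(direction) {
    lfc <- (1.5 + stats::rexp(1, 1)) * if (direction == "up") 1 else -1
    c(lfc, stats::runif(1, 0, 0.05))
  }
  draw_null <- function() {
    repeat {
      lfc <- stats::rnorm(1, 0, 0.5)
      fdr <- stats::runif(1)
      if (!(fdr < 0.05 && abs(lfc) > 1.5)) return(c(lfc, fdr))
    }
  }
  for (f in colnames(m)) {
    k <- counts[f]
    cls <- fam_class[f]
    if (!is.na(cls)) {
      k <- max(k, if (cls == "both") 2L else 1L)
      statuses <- switch(cls,
        up = c("up", sample(c("up", "none"), k - 1L, replace = TRUE)),
        down = c("down", sample(c("down", "none"), k - 1L, replace = TRUE)),
        both = c("up", "down", sample(c("up", "down", "none"), k - 2L, replace = TRUE))
      )
    } else if (k == 0L) {
      next
    } else if (f %in% linked) {
      de <- stats::rbinom(k, 1, cfg$deg_link_prob) == 1
      dirs <- sample(c("up", "down"), k, replace = TRUE)
      statuses <- ifelse(de, dirs, "none")
    } else {
      de <- stats::rbinom(k, 1, cfg$bg_de_prob) == 1
      dirs <- sample(c("up", "down"), k, replace = TRUE)
      statuses <- ifelse(de, dirs, "none")
    }
    ids <- sprintf("%s_g%02d", f, seq_along(statuses))
    for (i in seq_along(ids)) {
      vals <- if (statuses[i] == "none") draw_null() else draw_de(statuses[i])
      rows[[length(rows) + 1L]] <- data.frame(
        gene = ids[i], logFC = vals[1],
        pvalue = vals[2] * stats::runif(1), fdr = vals[2],
        contrast = "coculture_vs_alone",
        true_status = statuses[i], stringsAsFactors = FALSE
      )
    }
    g2f[ids] <- f
  }
  deg <- do.call(rbind, rows)
  list(
    deg = deg[, c("gene", "logFC", "pvalue", "fdr", "contrast")],
    gene2family = g2f,
    truth = list(
      gene_status = stats::setNames(deg$true_status, deg$gene),
      family_class = fam_class[!is.na(fam_class)],
      profiled_species = profiled_species
    )
  )
}

#' Simulate gene-tree and scaffold evidence for the HGT triage
#'
#' For a xenolog family the gene tree grafts the algal (chlorophyte) clade
#' inside a bacterial clade, with a fungal clade present elsewhere; for a
#' vertical family the algal clade sits with the other eukaryotic
#' chlorophyte sequences. The scaffold fixture either surrounds the
#' candidate gene with host-assigned neighbors (`"clean"`) or places it on a
#' short scaffold next to non-host genes (`"contaminated"`).
#'
#' @param cfg A [sim_config()] (used for RNG conventions only).
#' @param role `"xenolog"` or `"vertical"`.
#' @param fixture `"clean"` or `"contaminated"`.
#' @param n_algal,n_bacterial,n_fungal Tip counts per group (defaults 4, 8, 4).
#' @return A list: `gene_tree` (with `taxon_group`), `scaffolds` (data
#'   frame), `candidate` (gene id), `truth` (role and fixture).
#' @export
sim_hgt_evidence <- function(cfg, role = c("xenolog", "vertical"),
                             fixture = c("clean", "contaminated"),
                             n_algal = 4L, n_bacterial = 8L, n_fungal = 4L) {
  role <- match.arg(role)
  fixture <- match.arg(fixture)
  bl <- function(n) round(stats::runif(n, 0.05, 0.5), 3)
  tip <- function(pre, n, grp) paste0(pre, seq_len(n), "|", grp)
  algae <- tip("alga", n_algal, "trebouxiophyceae")
  bact <- tip("bact", n_bacterial, "bacteria")
  fung <- tip("fung", n_fungal, "fungi")
  chain <- function(tips) {
    # ladderized clade newick (string carries its own stem branch length)
    s <- paste0(tips[1], ":", bl(1))
    for (i in seq_along(tips)[-1]) {
      s <- paste0("(", s, ",", tips[i], ":", bl(1), "):", bl(1))
    }
    s
  }
  half <- n_bacterial %/% 2L
  if (role == "xenolog") {
    ## algal clade nested two levels inside the bacterial clade
    nested <- paste0("(", chain(algae), ",", chain(bact[seq_len(half)]), "):", bl(1))
    mid <- paste0("(", nested, ",", chain(bact[(half + 1L):n_bacterial]), "):", bl(1))
    nwk <- paste0("(", mid, ",", chain(fung), ");")
  } else {
    relatives <- tip("chloro", 3L, "chlorophyte")
    nwk <- paste0("((", chain(algae), ",", chain(relatives), "):", bl(1),
                  ",(", chain(bact), ",", chain(fung), "):", bl(1), ");")
  }
  gt <- read_gene_tree(nwk)
  candidate <- "cand_gene"
  if (fixture == "clean") {
    n_side <- 6L
    genes <- c(sprintf("left%02d", seq_len(n_side)), candidate,
               sprintf("right%02d", seq_len(n_side)))
    starts <- seq(1000L, by = 2000L, length.out = length(genes))
    scaffolds <- data.frame(
      gene = genes, scaffold = "scaf_big",
      start = starts, end = starts + 1500L,
      strand = sample(c("+", "-"), length(genes), replace = TRUE),
      assignment = c(rep("host", n_side), "unassigned", rep("host", n_side)),
      stringsAsFactors = FALSE
    )
  } else {
    genes <- c("ctg_a", candidate, "ctg_b")
    scaffolds <- data.frame(
      gene = genes, scaffold = "scaf_small",
      start = c(100L, 2100L, 4100L), end = c(1600L, 3600L, 5600L),
      strand = c("+", "+", "-"),
      assignment = c("non-host", "unassigned", "non-host"),
      stringsAsFactors = FALSE
    )
  }
  list(gene_tree = gt, scaffolds = scaffolds, candidate = candidate,
       truth = list(role = role, fixture = fixture))
}

#' Generate a complete synthetic dataset with ground truth
#'
#' Seeds a single RNG stream from `cfg$seed` and draws, in order: the
#' species tree, the trait history, the orthogroup matrix, the DEG tables,
#' and the gene-tree/scaffold fixtures (one xenolog and one vertical
#' control). When `dir` is given, all pipeline-consumable files are written
#' (`tree.nwk`, `traits.tsv`, `matrix.tsv`, `groups.tsv`, `deg.tsv`,
#' `gene2fam.tsv`, `gene_trees/*.nwk`, `genes.gff3`, `taxa.tsv`,
#' `truth.json`).
#'
#' @param cfg A [sim_config()].
#' @param dir Optional output directory.
#' @param partition Optional DE partition passed to [sim_deg()].
#' @return A list with all components and `truth`.
#' @export
simulate_dataset <- function(cfg = sim_config(), dir = NULL, partition = NULL) {
  set.seed(cfg$seed)
  tree <- sim_tree(cfg)
  tra <- sim_trait(tree, cfg)
  mat <- sim_matrix(tree, tra$trait, cfg)
  deg <- sim_deg(mat$matrix, mat$truth, cfg, tra$trait, partition = partition)
  xeno <- sim_hgt_evidence(cfg, role = "xenolog", fixture = "clean")
  vert <- sim_hgt_evidence(cfg, role = "vertical", fixture = "clean")
  contam <- sim_hgt_evidence(cfg, role = "xenolog", fixture = "contaminated")
  groups <- stats::setNames(ifelse(tra$trait == 1L, "focal", "other"),
                            names(tra$trait))
  out <- list(
    config = cfg, tree = tree, trait = tra$trait, groups = groups,
    matrix = mat$matrix, deg = deg$deg, gene2family = deg$gene2family,
    hgt = list(xenolog = xeno, vertical = vert, contaminated = contam),
    truth = list(trait = tra$truth, families = mat$truth, deg = deg$truth)
  )
  if (!is.null(dir)) write_dataset(out, dir)
  out
}

write_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(ape::write.tree(ds$tree), file.path(dir, "tree.nwk"))
  write_trait_table(ds$trait, file.path(dir, "traits.tsv"))
  write_ortho_matrix(ds$matrix, file.path(dir, "matrix.tsv"))
  utils::write.table(
    data.frame(species = names(ds$groups), group = unname(ds$groups)),
    file.path(dir, "groups.tsv"), sep = "\t", quote = FALSE, row.names = FALSE
  )
  utils::write.table(ds$deg, file.path(dir, "deg.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(gene = names(ds$gene2family), family = unname(ds$gene2family)),
    file.path(dir, "gene2fam.tsv"), sep = "\t", quote = FALSE, row.names = FALSE
  )
  gt_dir <- file.path(dir, "gene_trees")
  dir.create(gt_dir, showWarnings = FALSE)
  for (nm in names(ds$hgt)) {
    writeLines(ape::write.tree(ds$hgt[[nm]]$gene_tree),
               file.path(gt_dir, paste0(nm, ".nwk")))
  }
  write_scaffold_gff(do.call(rbind, lapply(names(ds$hgt), function(nm) {
    df <- ds$hgt[[nm]]$scaffolds
    df$gene <- paste0(nm, "_", df$gene)
    df
  })), file.path(dir, "genes.gff3"), file.path(dir, "taxa.tsv"))
  jsonlite::write_json(
    list(trait = ds$truth$trait[c("n_gains", "n_losses", "loss_tips")],
         families = ds$truth$families,
         deg = list(profiled_species = ds$truth$deg$profiled_species)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, pretty = TRUE
  )
  invisible(dir)
}

## GFF3 (gene features, 1-based inclusive) plus sidecar taxonomic TSV.
write_scaffold_gff <- function(scaffolds, gff_path, taxa_path) {
  lines <- c("##gff-version 3",
             sprintf("%s\tlichenscan\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     scaffolds$scaffold, scaffolds$start, scaffolds$end,
                     scaffolds$strand, scaffolds$gene))
  writeLines(lines, gff_path)
  utils::write.table(
    data.frame(gene = scaffolds$gene, assignment = scaffolds$assignment),
    taxa_path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(gff_path)
}

#' Read a scaffold table from GFF3 plus a taxonomic-assignment sidecar
#'
#' @param gff_path GFF3 file of gene features (1-based inclusive
#'   coordinates, gene id in the `ID` attribute).
#' @param taxa_path Two-column TSV `gene`, `assignment`
#'   (`host`/`non-host`/`unassigned`).
#' @return Data frame with columns gene, scaffold, start, end, strand,
#'   assignment, suitable for [check_anchoring()].
#' @export
read_scaffold_table <- function(gff_path, taxa_path) {
  raw <- readLines(gff_path)
  raw <- raw[!startsWith(raw, "#") & nzchar(raw)]
  f <- strsplit(raw, "\t", fixed = TRUE)
  if (any(lengths(f) != 9L)) stop("malformed GFF3: expected 9 columns")
  ids <- sub("^.*ID=([^;]+).*$", "\\1", vapply(f, `[[`, "", 9L))
  df <- data.frame(
    gene = ids,
    scaffold = vapply(f, `[[`, "", 1L),
    start = as.integer(vapply(f, `[[`, "", 4L)),
    end = as.integer(vapply(f, `[[`, "", 5L)),
    strand = vapply(f, `[[`, "", 7L),
    stringsAsFactors = FALSE
  )
  if (any(df$start > df$end)) stop("GFF3 feature with start > end")
  taxa <- utils::read.delim(taxa_path, stringsAsFactors = FALSE)
  df$assignment <- taxa$assignment[match(df$gene, taxa$gene)]
  df$assignment[is.na(df$assignment)] <- "unassigned"
  df
}
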