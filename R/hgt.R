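#' Presence fractions of a family in the focal and other groups
#'
#' @param m Count matrix (species rows, family columns).
#' @param groups Named character vector mapping species to `"focal"`/`"other"`.
#' @param family Family id (column of `m`).
#' @return A list with `focal_fraction`, `other_fraction`, and the underlying
#'   counts (`focal_present`, `focal_n`, `other_present`, `other_n`).
#'   Presence is count >= 1.
#' @export
specificity_profile <- function(m, groups, family) {
  if (!family %in% colnames(m)) stop("family ", dQuote(family), " not in matrix")
  groups <- groups[intersect(names(groups), rownames(m))]
  focal <- names(groups)[groups == "focal"]
  other <- names(groups)[groups == "other"]
  fp <- sum(m[focal, family] >= 1)
  op <- sum(m[other, family] >= 1)
  list(
    focal_fraction = if (length(focal)) fp / length(focal) else 0,
    other_fraction = if (length(other)) op / length(other) else 0,
    focal_present = fp, focal_n = length(focal),
    other_present = op, other_n = length(other)
  )
}

#' Transfer versus Dollo-loss event counts for a presence pattern
#'
#' Given a host/lineage tree and the set of tips possessing a gene family,
#' counts the events demanded by the two competing origins. Under the
#' transfer scenario the family is native to one present lineage and reaches
#' each further maximal present clade by one horizontal transfer, so
#' `transfers = (number of maximal present clades) - 1` (set
#' `count_origin = TRUE` to count the origin too). Under a single ancient
#' origin (Dollo), the family arose once in the most recent common ancestor
#' of the present tips and was lost along the way: `dollo_losses` is the
#' number of maximal absent clades strictly inside that ancestor's subtree.
#' A Sankoff minimum-change count with configurable gain/loss costs is
#' reported for sensitivity.
#'
#' @param host_tree A `phylo` object.
#' @param presence Character vector of tip labels possessing the family.
#' @param count_origin Count the initial acquisition as an event (default
#'   FALSE, matching the convention that the donor lineage is native).
#' @param gain_cost,loss_cost Costs for the Sankoff count (defaults 1, 1).
#' @return A list of class `event_scenario`: `transfers`, `dollo_losses`,
#'   `verdict` (`hgt_more_parsimonious` / `loss_more_parsimonious` / `tie`),
#'   `sankoff_min`, plus the maximal present/absent clade tip sets.
#' @export
event_scenarios <- function(host_tree, presence, count_origin = FALSE,
                            gain_cost = 1, loss_cost = 1) {
  tips <- host_tree$tip.label
  unknown <- setdiff(presence, tips)
  if (length(unknown) > 0L) {
    stop("presence tip(s) not in tree: ", paste(unknown, collapse = ", "))
  }
  if (length(presence) == 0L) stop("presence set is empty")
  ntip <- length(tips)
  root <- ntip + 1L
  tr <- stats::reorder(host_tree, "postorder")
  nn <- ntip + host_tree$Nnode
  present_tip <- tips %in% presence

  ## postorder: does each node's subtree consist entirely of present /
  ## absent tips?
  all_present <- c(present_tip, rep(TRUE, host_tree$Nnode))
  all_absent <- c(!present_tip, rep(TRUE, host_tree$Nnode))
  parent <- integer(nn)
  for (k in seq_len(nrow(tr$edge))) {
    p <- tr$edge[k, 1]; ch <- tr$edge[k, 2]
    parent[ch] <- p
    all_present[p] <- all_present[p] && all_present[ch]
    all_absent[p] <- all_absent[p] && all_absent[ch]
  }

  maximal_present <- which(all_present &
                             (seq_len(nn) == root | !all_present[pmax(parent, 1)]))
  if (all_present[root]) maximal_present <- root

  ## MRCA of the present tips
  mrca <- if (length(presence) == 1L) {
    match(presence, tips)
  } else {
    ape::getMRCA(host_tree, presence)
  }
  in_mrca <- descendant_flags(host_tree, mrca)
  maximal_absent <- which(all_absent & in_mrca & seq_len(nn) != mrca &
                            !all_absent[pmax(parent, 1)] &
                            in_mrca[pmax(parent, 1)])

  transfers <- length(maximal_present) - 1L + as.integer(count_origin)
  dollo_losses <- length(maximal_absent)
  if (all_present[root]) { transfers <- 0L + as.integer(count_origin); dollo_losses <- 0L }

  verdict <- if (transfers < dollo_losses) "hgt_more_parsimonious"
             else if (transfers > dollo_losses) "loss_more_parsimonious"
             else "tie"

  sankoff <- sankoff_count(host_tree, presence, gain_cost, loss_cost)

  structure(list(
    transfers = transfers,
    dollo_losses = dollo_losses,
    verdict = verdict,
    sankoff_min = sankoff,
    present_clades = lapply(maximal_present, function(v) clade_tips(host_tree, v)),
    absent_clades = lapply(maximal_absent, function(v) clade_tips(host_tree, v))
  ), class = "event_scenario")
}

## logical flags: is node v inside the subtree rooted at `node` (inclusive)?
descendant_flags <- function(tree, node) {
  nn <- length(tree$tip.label) + tree$Nnode
  flags <- logical(nn)
  flags[node] <- TRUE
  tr <- stats::reorder(tree, "postorder")
  for (k in rev(seq_len(nrow(tr$edge)))) {
    if (flags[tr$edge[k, 1]]) flags[tr$edge[k, 2]] <- TRUE
  }
  flags
}

clade_tips <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  tree$tip.label[intersect(which(descendant_flags(tree, node)), seq_len(ntip))]
}

#' Sankoff minimum-change cost for a binary presence pattern
#'
#' Dynamic program over the tree minimizing the total cost of state changes,
#' with `gain_cost` for a 0 to 1 change and `loss_cost` for 1 to 0; the root
#' state is free (minimum over both).
#'
#' @inheritParams event_scenarios
#' @return The minimum total cost (numeric).
#' @export
sankoff_count <- function(host_tree, presence, gain_cost = 1, loss_cost = 1) {
  tips <- host_tree$tip.label
  ntip <- length(tips)
  nn <- ntip + host_tree$Nnode
  tr <- stats::reorder(host_tree, "postorder")
  cost <- matrix(0, nn, 2)
  present_tip <- tips %in% presence
  cost[seq_len(ntip), 1] <- ifelse(present_tip, Inf, 0)
  cost[seq_len(ntip), 2] <- ifelse(present_tip, 0, Inf)
  for (k in seq_len(nrow(tr$edge))) {
    p <- tr$edge[k, 1]; ch <- tr$edge[k, 2]
    from0 <- min(cost[ch, 1], gain_cost + cost[ch, 2])
    from1 <- min(loss_cost + cost[ch, 1], cost[ch, 2])
    cost[p, 1] <- cost[p, 1] + from0
    cost[p, 2] <- cost[p, 2] + from1
  }
  min(cost[ntip + 1L, ])
}

#' Parse a gene tree with taxon-annotated tips
#'
#' Tip labels follow the `seqid|taxon_group` convention (e.g.
#' `alga1|chlorophyte`).
#'
#' @param text_or_path Newick string or file path.
#' @return A `phylo` object with extra vectors `seq_id` and `taxon_group`
#'   aligned with `tip.label`.
#' @export
read_gene_tree <- function(text_or_path) {
  tree <- if (file.exists(text_or_path)) ape::read.tree(text_or_path)
          else parse_newick(text_or_path)
  parts <- strsplit(tree$tip.label, "|", fixed = TRUE)
  if (any(lengths(parts) != 2L)) {
    stop("gene-tree tips must be labeled 'seqid|taxon_group'")
  }
  tree$seq_id <- vapply(parts, `[[`, "", 1L)
  tree$taxon_group <- vapply(parts, `[[`, "", 2L)
  tree
}

#' Gene-tree nesting analysis for HGT donor inference
#'
#' Roots the gene tree on the outgroup taxon (when present), finds the
#' maximal clades made entirely of focal-taxon tips, and summarizes the taxon
#' composition of each focal clade's sister lineages. The donor hypothesis is
#' the majority taxon across the pooled sister composition; when the majority
#' taxon is the focal group itself the signal is vertical and the donor
#' hypothesis is `"none"`.
#'
#' @param gt Gene tree from [read_gene_tree()] (with `taxon_group`).
#' @param focal_group Taxon label of the putative recipient (e.g.
#'   `"chlorophyte"`).
#' @param outgroup Taxon label used for rooting (e.g. `"fungi"`). When no
#'   outgroup tip exists the analysis proceeds unrooted with `caveat = TRUE`.
#' @param vertical_taxa Taxon labels that, as majority sister, indicate
#'   vertical inheritance rather than a donor (defaults to the focal group
#'   plus `"chlorophyte"`, the recipient's own lineage in this pipeline).
#' @return A list: `focal_monophyletic`, `n_focal_clades`,
#'   `sister_composition` (list of taxon count tables), `donor_hypothesis`,
#'   `rooted`, `caveat`.
#' @export
gene_tree_nesting <- function(gt, focal_group, outgroup = NULL,
                              vertical_taxa = c(focal_group, "chlorophyte")) {
  if (is.null(gt$taxon_group)) stop("gene tree lacks taxon_group annotations")
  focal_tips <- gt$tip.label[gt$taxon_group == focal_group]
  if (length(focal_tips) == 0L) stop("no focal tips with taxon ", dQuote(focal_group))
  caveat <- FALSE
  tree <- gt
  if (!is.null(outgroup)) {
    og_tips <- gt$tip.label[gt$taxon_group == outgroup]
    if (length(og_tips) == 0L) {
      caveat <- TRUE
    } else {
      tree <- ape::root(gt, outgroup = og_tips, resolve.root = TRUE)
      parts <- strsplit(tree$tip.label, "|", fixed = TRUE)
      tree$taxon_group <- vapply(parts, `[[`, "", 2L)
    }
  } else {
    caveat <- TRUE
  }
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  root <- ntip + 1L
  tr <- stats::reorder(tree, "postorder")
  is_focal_tip <- tree$taxon_group == focal_group
  all_focal <- c(is_focal_tip, rep(TRUE, tree$Nnode))
  parent <- integer(nn)
  for (k in seq_len(nrow(tr$edge))) {
    p <- tr$edge[k, 1]; ch <- tr$edge[k, 2]
    parent[ch] <- p
    all_focal[p] <- all_focal[p] && all_focal[ch]
  }
  maximal_focal <- which(all_focal &
                           (seq_len(nn) == root | !all_focal[pmax(parent, 1)]))
  if (all_focal[root]) maximal_focal <- root

  sisters <- lapply(maximal_focal, function(v) {
    if (v == root) return(table(character(0)))
    p <- parent[v]
    sibs <- tr$edge[tr$edge[, 1] == p & tr$edge[, 2] != v, 2]
    sib_tips <- unlist(lapply(sibs, function(s) clade_tips(tree, s)))
    idx <- match(sib_tips, tree$tip.label)
    table(tree$taxon_group[idx])
  })

  pooled <- table(unlist(lapply(sisters, function(tb) rep(names(tb), tb))))
  donor <- if (length(pooled) == 0L) "none" else names(pooled)[which.max(pooled)]
  if (donor %in% vertical_taxa) donor <- "none"

  list(
    focal_monophyletic = length(maximal_focal) == 1L,
    n_focal_clades = length(maximal_focal),
    sister_composition = sisters,
    donor_hypothesis = donor,
    rooted = !caveat,
    caveat = caveat
  )
}

#' Joint HGT triage verdict for a candidate family
#'
#' Combines the evidence streams into a single call: a family is
#' `"hgt_supported"` when its presence is strongly skewed toward the focal
#' group (`focal_fraction - other_fraction >= min_diff`), its gene tree
#' nests the focal sequences inside a foreign donor clade
#' (`donor_hypothesis != "none"`), its scaffold context (when available) is
#' not `suspect`, and the event comparison (when available) does not favor
#' vertical inheritance with losses. Otherwise `"not_supported"`.
#'
#' @param specificity Result of [specificity_profile()].
#' @param nesting Result of [gene_tree_nesting()].
#' @param anchoring Optional result of [check_anchoring()].
#' @param scenario Optional result of [event_scenarios()].
#' @param min_diff Minimum presence-fraction difference (default 0.4).
#' @return `"hgt_supported"` or `"not_supported"`, with the failing
#'   criteria as attribute `"reasons"`.
#' @export
triage_hgt <- function(specificity, nesting, anchoring = NULL,
                       scenario = NULL, min_diff = 0.4) {
  reasons <- character(0)
  if (specificity$focal_fraction - specificity$other_fraction < min_diff) {
    reasons <- c(reasons, "presence not focal-specific")
  }
  if (identical(nesting$donor_hypothesis, "none")) {
    reasons <- c(reasons, "gene tree shows vertical signal")
  }
  if (!is.null(anchoring) && anchoring$verdict == "suspect") {
    reasons <- c(reasons, "scaffold context suspect")
  }
  if (!is.null(scenario) && scenario$verdict == "loss_more_parsimonious") {
    reasons <- c(reasons, "losses more parsimonious than transfers")
  }
  structure(if (length(reasons) == 0L) "hgt_supported" else "not_supported",
            reasons = reasons)
}

#' Scaffold-anchoring check for a candidate gene
#'
#' Examines up to `window` genes on each side of the candidate (ordered by
#' start coordinate on its scaffold) and classifies the candidate as
#' `anchored` when at least 2 taxonomically assigned neighbors exist on each
#' available side and the fraction of host-assigned genes among assigned
#' neighbors reaches `host_fraction`; `suspect` when that fraction falls
#' below the threshold; `insufficient_context` when fewer than 2 assigned
#' neighbors exist in total (or a side lacks context).
#'
#' @param scaffolds Data frame with columns `gene`, `scaffold`, `start`,
#'   `end`, and `assignment` in `{"host", "non-host", "unassigned"}` (a
#'   `strand` column is carried but ignored for ordering).
#' @param candidate Gene id to check.
#' @param window Genes per side (default 5).
#' @param host_fraction Minimum host fraction among assigned neighbors
#'   (default 0.6).
#' @return A list of class `anchoring_verdict`: `verdict`, `n_host`,
#'   `n_nonhost`, `n_unassigned`, `host_fraction`, `scaffold`.
#' @export
check_anchoring <- function(scaffolds, candidate, window = 5L,
                            host_fraction = 0.6) {
  row <- scaffolds[scaffolds$gene == candidate, , drop = FALSE]
  if (nrow(row) == 0L) stop("candidate ", dQuote(candidate), " not on any scaffold")
  sc <- scaffolds[scaffolds$scaffold == row$scaffold[1], , drop = FALSE]
  sc <- sc[order(sc$start), , drop = FALSE]
  pos <- which(sc$gene == candidate)
  left <- sc[rev(seq_len(pos - 1L))[seq_len(min(window, pos - 1L))], , drop = FALSE]
  n_right <- nrow(sc) - pos
  right <- sc[pos + seq_len(min(window, n_right)), , drop = FALSE]
  neigh <- rbind(left, right)
  n_host <- sum(neigh$assignment == "host")
  n_nonhost <- sum(neigh$assignment == "non-host")
  n_unassigned <- sum(neigh$assignment == "unassigned")
  n_assigned <- n_host + n_nonhost
  frac <- if (n_assigned > 0) n_host / n_assigned else NA_real_
  assigned_left <- sum(left$assignment != "unassigned")
  assigned_right <- sum(right$assignment != "unassigned")
  sides_ok <- (nrow(left) == 0L || assigned_left >= 2L) &&
    (nrow(right) == 0L || assigned_right >= 2L) &&
    (nrow(left) > 0L || nrow(right) > 0L)
  verdict <- if (n_assigned < 2L) "insufficient_context"
             else if (frac < host_fraction) "suspect"
             else if (sides_ok) "anchored"
             else "insufficient_context"
  structure(list(
    verdict = verdict, n_host = n_host, n_nonhost = n_nonhost,
    n_unassigned = n_unassigned, host_fraction = frac,
    scaffold = row$scaffold[1]
  ), class = "anchoring_verdict")
}
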