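#' Parse a newick string into a phylogenetic tree
#'
#' Thin validating wrapper around [ape::read.tree()]. The returned tree is an
#' ape `phylo` object: node ids follow ape's convention (tips `1..n`, root
#' `n+1`, internal nodes `n+1..n+Nnode`). Trees may contain polytomies.
#'
#' @param text A newick string (single tree, terminated by `;`).
#' @return An object of class `phylo` with branch lengths. Trees written
#'   without branch lengths get every edge set to 1 with a warning.
#' @details Duplicate tip labels and unbalanced parentheses are rejected with
#'   an error naming the offending token, since downstream trait mapping is
#'   keyed on tip labels.
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  n_open <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  n_close <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (n_open != n_close) {
    stop("unbalanced parentheses in newick: ", n_open, " '(' vs ", n_close, " ')'")
  }
  tree <- ape::read.tree(text = text)
  if (is.null(tree)) stop("could not parse newick string")
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup) > 0L) {
    stop("duplicate tip label(s): ", paste(dQuote(dup), collapse = ", "))
  }
  if (is.null(tree$edge.length)) {
    warning("newick has no branch lengths; defaulting all to 1.0")
    tree$edge.length <- rep(1, nrow(tree$edge))
  }
  if (any(!is.finite(tree$edge.length))) stop("non-finite branch length in tree")
  if (any(tree$edge.length < 0)) stop("negative branch length in tree")
  tree
}

#' Write a tree to a newick string
#'
#' @param tree A `phylo` object.
#' @param file Optional path; if `NULL` the newick string is returned.
#' @return The newick string (invisibly when written to file).
#' @export
write_newick <- function(tree, file = NULL) {
  txt <- ape::write.tree(tree)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' Make a tree ultrametric
#'
#' Adjusts branch lengths so every root-to-tip path has equal length, leaving
#' the topology untouched.
#'
#' @param tree A `phylo` object with branch lengths.
#' @param method `"extend"` lengthens terminal branches so all tips reach the
#'   depth of the deepest tip; `"mean_path_length"` sets each node's height to
#'   the mean path length from that node to its descendant tips, so each edge
#'   becomes the difference of the two node heights (tip depths then all equal
#'   the root's mean path length by telescoping).
#' @return An ultrametric `phylo` object (tip depths equal within 1e-9).
#' @export
ultrametricize <- function(tree, method = c("extend", "mean_path_length")) {
  method <- match.arg(method)
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch length in input tree")
  depths <- node_depths(tree)
  ntip <- length(tree$tip.label)
  tipd <- depths[seq_len(ntip)]
  if (max(tipd) - min(tipd) < 1e-9) return(tree)
  if (method == "extend") {
    target <- max(tipd)
    term <- match(seq_len(ntip), tree$edge[, 2])
    tree$edge.length[term] <- tree$edge.length[term] + (target - tipd)
  } else {
    mpl <- mean_path_lengths(tree)
    tree$edge.length <- mpl[tree$edge[, 1]] - mpl[tree$edge[, 2]]
    if (any(tree$edge.length < 0)) {
      warning("mean_path_length produced negative branch length(s); ",
              "consider method = 'extend'")
    }
  }
  tree
}

## Depth of every node (distance from the root), preorder accumulation.
node_depths <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  root <- ntip + 1L
  tr <- stats::reorder(tree, "postorder")
  depths <- numeric(ntip + nnode)
  # preorder = reverse postorder edge order
  for (k in rev(seq_len(nrow(tr$edge)))) {
    depths[tr$edge[k, 2]] <- depths[tr$edge[k, 1]] + tr$edge.length[k]
  }
  depths
}

## Mean path length from each node down to its descendant tips (tips = 0).
mean_path_lengths <- function(tree) {
  ntip <- length(tree$tip.label)
  tr <- stats::reorder(tree, "postorder")
  n_below <- c(rep(1, ntip), rep(0, tree$Nnode))
  sum_below <- numeric(ntip + tree$Nnode)
  for (k in seq_len(nrow(tr$edge))) {
    p <- tr$edge[k, 1]; ch <- tr$edge[k, 2]
    n_below[p] <- n_below[p] + n_below[ch]
    sum_below[p] <- sum_below[p] + sum_below[ch] + n_below[ch] * tr$edge.length[k]
  }
  sum_below / pmax(n_below, 1)
}

#' Read a binary trait table
#'
#' Reads a two-column TSV (species, state). States `LAS`/`NSA` (case
#' insensitive) and `1`/`0` are accepted; LAS (lichen algal symbiont) codes
#' as 1, NSA (non-symbiotic alga) as 0.
#'
#' @param path Path to the TSV file. A header row `species<TAB>state` is
#'   accepted and detected automatically.
#' @return A named integer vector of 0/1 states, names = species.
#' @export
read_trait_table <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(tab) < 2L) stop("trait table must have two columns (species, state)")
  if (tolower(tab[1, 1]) %in% c("species", "taxon", "tip") ||
      tolower(tab[1, 2]) %in% c("state", "trait", "status")) {
    tab <- tab[-1, , drop = FALSE]
  }
  states <- trait_code(tab[[2]])
  stats::setNames(states, tab[[1]])
}

trait_code <- function(x) {
  x0 <- toupper(trimws(as.character(x)))
  out <- ifelse(x0 %in% c("1", "LAS"), 1L, ifelse(x0 %in% c("0", "NSA"), 0L, NA_integer_))
  if (anyNA(out)) {
    stop("unrecognized trait state(s): ",
         paste(unique(x0[is.na(out)]), collapse = ", "),
         " (accepted: LAS, NSA, 1, 0)")
  }
  out
}

#' Write a binary trait table
#'
#' @param trait Named 0/1 vector (names = species).
#' @param path Output TSV path.
#' @export
write_trait_table <- function(trait, path) {
  utils::write.table(
    data.frame(species = names(trait), state = as.integer(trait)),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
}
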