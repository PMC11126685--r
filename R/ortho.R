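#' Load a species-by-orthogroup count matrix
#'
#' Reads a rectangular TSV with a header row of family ids and a first column
#' of species ids. Orientation is declared, never guessed: set
#' `species_rows = FALSE` when rows are families and columns species.
#'
#' @param path TSV path.
#' @param species_rows Logical; `TRUE` (default) means rows are species.
#' @return An integer matrix, rows = species, columns = families.
#' @export
load_ortho_matrix <- function(path, species_rows = TRUE) {
  tab <- utils::read.delim(path, header = TRUE, row.names = 1,
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) stop("no data rows in ", path)
  m <- as.matrix(tab)
  bad <- which(!is.finite(suppressWarnings(as.numeric(m))) |
                 as.numeric(m) < 0 | as.numeric(m) != round(as.numeric(m)))
  if (length(bad) > 0L) {
    i <- ((bad[1] - 1L) %% nrow(m)) + 1L
    j <- ((bad[1] - 1L) %/% nrow(m)) + 1L
    stop("non-integer or negative count at row ", dQuote(rownames(m)[i]),
         ", column ", dQuote(colnames(m)[j]), ": ", m[i, j])
  }
  storage.mode(m) <- "integer"
  if (!species_rows) m <- t(m)
  if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m))) {
    stop("duplicate species or family labels in matrix")
  }
  m
}

#' Write an orthogroup count matrix to TSV
#'
#' @param m Count matrix (species rows, family columns).
#' @param path Output path.
#' @export
write_ortho_matrix <- function(m, path) {
  df <- data.frame(species = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Remove low-occupancy gene families
#'
#' Retains families present (count >= 1) in at least `min_species` species.
#' The default of 3 removes species-specific and two-species families, the
#' resolution filter applied before the discriminant and enrichment screens.
#'
#' @param m Count matrix (species rows, family columns).
#' @param min_species Minimum number of species with a non-zero count (>= 1).
#' @return The filtered matrix.
#' @export
filter_families <- function(m, min_species = 3L) {
  if (!is.numeric(min_species) || min_species < 1) stop("min_species must be >= 1")
  keep <- colSums(m >= 1) >= min_species
  m[, keep, drop = FALSE]
}

#' Two-sided Mann-Whitney-Wilcoxon test
#'
#' Mid-ranks for ties. Uses the exact null distribution, enumerated over all
#' `choose(n+m, n)` group assignments, whenever that count is at most
#' `max_enum` (default 200000); otherwise the normal approximation with tie
#' correction and continuity correction. The two-sided p-value is the null
#' probability of a U statistic at least as far from its mean `nm/2` as the
#' observed one (the distribution is symmetric about `nm/2` under exchange of
#' group labels), capped at 1.
#'
#' @param x,y Numeric vectors (focal and other group values), each non-empty.
#' @param max_enum Enumeration budget on `choose(n+m, n)`.
#' @return A list: `U` (for `x`), `p`, `method` (`"exact"` or `"normal"`).
#' @export
wilcoxon_two_sided <- function(x, y, max_enum = 2e5) {
  if (length(x) < 1L || length(y) < 1L) stop("both groups must be non-empty")
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  mu <- n * m / 2
  if (choose(n + m, n) <= max_enum) {
    idx <- utils::combn(n + m, n)
    usim <- colSums(matrix(r[idx], nrow = n)) - n * (n + 1) / 2
    p <- mean(abs(usim - mu) >= abs(U - mu) - 1e-9)
    method <- "exact"
  } else {
    N <- n + m
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- n * m / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (abs(U - mu) - 0.5) / sqrt(sigma2)
      z <- max(z, 0)
      p <- min(1, 2 * stats::pnorm(-z))
    }
    method <- "normal"
  }
  list(U = U, p = min(p, 1), method = method)
}

#' Per-family enrichment scan of an orthogroup matrix
#'
#' Runs a two-sided Mann-Whitney-Wilcoxon test per family comparing counts in
#' the focal group against the rest (zeros included: absence carries signal).
#' Families that are all-zero across the tested species are dropped with a
#' warning before testing. Significance is judged on the raw p-value when
#' `adjust = "none"` (default alpha 0.01) and on the BH-adjusted p-value when
#' `adjust = "BH"`. Direction comes from the mean-rank comparison, consistent
#' with the test statistic.
#'
#' @param m Count matrix (species rows, family columns), already filtered.
#' @param groups Named character vector mapping species to `"focal"`/`"other"`.
#' @param alpha Significance threshold (default 0.01).
#' @param adjust `"none"` or `"BH"`.
#' @return A data frame: family, U, p, p_adj (NA when `adjust = "none"`),
#'   direction (`focal_enriched`/`other_enriched`/`none`), significant.
#' @export
enrichment_scan <- function(m, groups, alpha = 0.01, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  groups <- groups[intersect(names(groups), rownames(m))]
  focal <- names(groups)[groups == "focal"]
  other <- names(groups)[groups == "other"]
  if (length(focal) == 0L || length(other) == 0L) {
    stop("both groups must be non-empty after intersecting with matrix rows")
  }
  sub <- m[c(focal, other), , drop = FALSE]
  allzero <- colSums(sub) == 0
  if (any(allzero)) {
    warning(sum(allzero), " all-zero famil(ies) dropped before testing")
    sub <- sub[, !allzero, drop = FALSE]
  }
  fams <- colnames(sub)
  nf <- length(focal)
  res <- lapply(seq_along(fams), function(j) {
    v <- sub[, j]
    w <- wilcoxon_two_sided(v[seq_len(nf)], v[-seq_len(nf)])
    mean_rank_focal <- mean(rank(v)[seq_len(nf)])
    mean_rank_other <- mean(rank(v)[-seq_len(nf)])
    dir <- if (mean_rank_focal > mean_rank_other) "focal_enriched"
           else if (mean_rank_focal < mean_rank_other) "other_enriched"
           else "none"
    data.frame(family = fams[j], U = w$U, p = w$p, direction = dir,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (adjust == "BH") {
    out$p_adj <- bh_adjust(out$p)
    out$significant <- out$p_adj < alpha
  } else {
    out$p_adj <- NA_real_
    out$significant <- out$p < alpha
  }
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate adjustment with monotonicity enforcement,
#' order-preserving with the input.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0) || any(pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Compare genomic features between groups
#'
#' Per-feature two-sided Mann-Whitney-Wilcoxon comparison (e.g. genome size,
#' protein-coding gene count, GC content, transposable-element fraction)
#' between the focal and other species groups. Missing values are excluded
#' per feature; group medians are reported so the direction of a difference
#' is explicit.
#'
#' @param features Data frame or matrix, rows = species (rownames), columns =
#'   numeric features.
#' @param groups Named character vector mapping species to `"focal"`/`"other"`.
#' @return Data frame: feature, U, p, median_focal, median_other, n_focal,
#'   n_other. Features with no data in a group are skipped with a warning.
#' @export
group_feature_compare <- function(features, groups) {
  features <- as.data.frame(features)
  groups <- groups[intersect(names(groups), rownames(features))]
  focal <- names(groups)[groups == "focal"]
  other <- names(groups)[groups == "other"]
  out <- list()
  for (feat in colnames(features)) {
    xf <- features[focal, feat]; xo <- features[other, feat]
    xf <- xf[is.finite(xf)]; xo <- xo[is.finite(xo)]
    if (length(xf) == 0L || length(xo) == 0L) {
      warning("feature ", dQuote(feat), " entirely missing in one group; skipped")
      next
    }
    if (length(xf) < 2L || length(xo) < 2L) {
      stop("feature ", dQuote(feat), ": need at least 2 species per group")
    }
    w <- wilcoxon_two_sided(xf, xo)
    out[[feat]] <- data.frame(
      feature = feat, U = w$U, p = w$p,
      median_focal = stats::median(xf), median_other = stats::median(xo),
      n_focal = length(xf), n_other = length(xo),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
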