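#' Filter consistently low-expressed genes
#'
#' Removes genes whose read counts stay below `min_reads` in every sample
#' class. Under the default `rule = "any_class"` a gene is retained as soon
#' as its summed reads reach `min_reads` in at least one class; the stricter
#' alternative `rule = "all_classes"` requires the threshold in every class.
#'
#' @param counts Integer matrix, rows = genes, columns = samples.
#' @param class_map Named character vector mapping every sample (column) to a
#'   class (e.g. algal culture / synthetic lichen / field lichen).
#' @param min_reads Threshold on the class sum (default 10).
#' @param rule `"any_class"` (default) or `"all_classes"`.
#' @return Character vector of retained gene ids.
#' @export
low_count_filter <- function(counts, class_map, min_reads = 10L,
                             rule = c("any_class", "all_classes")) {
  rule <- match.arg(rule)
  unmapped <- setdiff(colnames(counts), names(class_map))
  if (length(unmapped) > 0L) {
    stop("sample(s) without a class: ", paste(unmapped, collapse = ", "))
  }
  cls <- class_map[colnames(counts)]
  sums <- sapply(unique(cls), function(cl) {
    rowSums(counts[, cls == cl, drop = FALSE])
  })
  sums <- matrix(sums, nrow = nrow(counts))
  keep <- if (rule == "any_class") {
    apply(sums >= min_reads, 1, any)
  } else {
    apply(sums >= min_reads, 1, all)
  }
  rownames(counts)[keep]
}

#' Call differentially expressed genes
#'
#' Applies the standard thresholds to a per-gene differential-expression
#' table: a gene is `up` when `fdr < fdr_max` and `logFC > lfc_min`, `down`
#' when `fdr < fdr_max` and `logFC < -lfc_min`, otherwise `none`. Both
#' inequalities are strict. `logFC` is interpreted as log2 fold change (the
#' convention of the usual count-based DE tools), so the default
#' `lfc_min = 1.5` corresponds to roughly a 2.8-fold change.
#'
#' @param deg Data frame with columns `gene`, `logFC`, `fdr` (adjusted p).
#' @param fdr_max FDR threshold (default 0.05).
#' @param lfc_min Absolute log2-fold-change threshold (default 1.5).
#' @return The input with a `status` column in `{"up", "down", "none"}`.
#'   Genes with missing `fdr` are dropped with a warning.
#' @export
call_degs <- function(deg, fdr_max = 0.05, lfc_min = 1.5) {
  req <- c("gene", "logFC", "fdr")
  if (!all(req %in% colnames(deg))) {
    stop("deg table must have columns: ", paste(req, collapse = ", "))
  }
  bad <- !is.finite(deg$fdr)
  if (any(bad)) {
    warning(sum(bad), " gene(s) with missing fdr skipped")
    deg <- deg[!bad, , drop = FALSE]
  }
  deg$status <- ifelse(deg$fdr < fdr_max & deg$logFC > lfc_min, "up",
                ifelse(deg$fdr < fdr_max & deg$logFC < -lfc_min, "down", "none"))
  deg
}

#' Classify candidate families by member-gene regulation
#'
#' A family is `up` when it has at least one up-regulated member and no
#' down-regulated one, `down` in the mirror case, `both` when it has at least
#' one of each, and `none` when no member is differentially expressed (or no
#' member was profiled).
#'
#' @param calls Output of [call_degs()] (needs `gene` and `status`).
#' @param gene2family Named character vector mapping gene id to family id.
#' @param families Character vector of candidate family ids.
#' @return A list: `classes` (named vector family -> class), `counts` (table
#'   of classes over the candidate families), `genes` (list of supporting
#'   gene ids per family).
#' @export
classify_family_regulation <- function(calls, gene2family, families) {
  known <- calls$gene %in% names(gene2family)
  fam_of <- gene2family[calls$gene[known]]
  unknown_fam <- !(fam_of %in% families)
  if (any(unknown_fam)) {
    warning(sum(unknown_fam), " gene(s) mapped to famil(ies) outside the ",
            "candidate list; ignored")
  }
  status <- calls$status[known][!unknown_fam]
  fam_of <- fam_of[!unknown_fam]
  gene_id <- calls$gene[known][!unknown_fam]
  classes <- stats::setNames(rep("none", length(families)), families)
  genes <- stats::setNames(vector("list", length(families)), families)
  for (f in families) {
    st <- status[fam_of == f]
    has_up <- any(st == "up"); has_down <- any(st == "down")
    classes[f] <- if (has_up && has_down) "both"
                  else if (has_up) "up"
                  else if (has_down) "down"
                  else "none"
    sel <- fam_of == f
    genes[[f]] <- gene_id[sel][st != "none"]
  }
  counts <- table(factor(classes, levels = c("up", "both", "down", "none")))
  list(classes = classes, counts = counts, genes = genes)
}

#' Triage candidate families across all evidence streams
#'
#' Mirrors the pipeline order of the study: the top-k discriminant families
#' are intersected with the enrichment-significant set, families without any
#' differentially expressed member are dropped, and families whose
#' phylogenetic flag is `refuted` are removed (an `unresolved` flag is
#' retained but recorded). Output is ordered by discriminant rank.
#'
#' @param top Data frame from [top_contributors()] (family, loading, rank).
#' @param enrichment Data frame from [enrichment_scan()].
#' @param regulation Result of [classify_family_regulation()].
#' @param phylo_flags Named character vector family ->
#'   `{"supported", "refuted", "unresolved"}`; families absent from it
#'   default to `"supported"`.
#' @return A data frame (one row per top family): family, rank, loading,
#'   wilcoxon_p, direction, regulation, phylo_flag and final `status` in
#'   `{"retained", "dropped_not_enriched", "dropped_no_expression",
#'   "dropped_phylogeny", "unresolved"}`.
#' @export
triage_candidates <- function(top, enrichment, regulation,
                              phylo_flags = character()) {
  missing <- setdiff(top$family, enrichment$family)
  if (length(missing) > 0L) {
    stop("family universes disagree; missing from enrichment: ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) " ...")
  }
  enr <- enrichment[match(top$family, enrichment$family), ]
  reg <- regulation$classes[top$family]
  reg[is.na(reg)] <- "none"
  flags <- stats::setNames(rep("supported", nrow(top)), top$family)
  have <- intersect(names(phylo_flags), top$family)
  flags[have] <- phylo_flags[have]
  status <- ifelse(!enr$significant, "dropped_not_enriched",
            ifelse(reg == "none", "dropped_no_expression",
            ifelse(flags == "refuted", "dropped_phylogeny",
            ifelse(flags == "unresolved", "unresolved", "retained"))))
  data.frame(
    family = top$family, rank = top$rank, loading = top$loading,
    wilcoxon_p = enr$p, direction = enr$direction,
    regulation = unname(reg), phylo_flag = unname(flags),
    status = unname(status), stringsAsFactors = FALSE
  )
}
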