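#' Build a pipeline configuration
#'
#' Either point the pipeline at existing input files or let it simulate a
#' dataset first. A YAML file with the same keys can be supplied to
#' [run_pipeline()] directly.
#'
#' @param out_dir Output directory (required).
#' @param simulate Logical; when `TRUE` (default) a synthetic dataset is
#'   generated into `out_dir/data` using `sim` before the stages run.
#' @param sim A [sim_config()] used when `simulate = TRUE`.
#' @param tree,traits,matrix,groups,deg,gene2fam Input paths used when
#'   `simulate = FALSE`.
#' @param model `"ARD"`, `"ER"` or `"both"` (default: both, retain by
#'   log-likelihood).
#' @param root_prior `"nsa"` (the default: the root is constrained to the
#'   non-symbiotic state, reflecting a species tree rooted on a
#'   non-symbiotic outgroup), `"uniform"`, or `"stationary"`.
#' @param ultrametric `"extend"`, `"mpl"` or `"off"` preprocessing of the
#'   tree.
#' @param min_species Family occupancy filter (default 3).
#' @param alpha Enrichment significance threshold on the raw p (default 0.01).
#' @param adjust `"none"` or `"BH"`.
#' @param n_components,keepX,top_k sPLS-DA settings (defaults 2, 100, 100).
#' @param fdr_max,lfc_min DEG thresholds (defaults 0.05, 1.5).
#' @param asr_threshold Posterior call threshold (default 0.5).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, simulate = TRUE, sim = sim_config(),
                            tree = NULL, traits = NULL, matrix = NULL,
                            groups = NULL, deg = NULL, gene2fam = NULL,
                            model = c("both", "ARD", "ER"),
                            root_prior = "nsa",
                            ultrametric = c("off", "extend", "mpl"),
                            min_species = 3L, alpha = 0.01,
                            adjust = c("none", "BH"),
                            n_components = 2L, keepX = 100L, top_k = 100L,
                            fdr_max = 0.05, lfc_min = 1.5,
                            asr_threshold = 0.5) {
  model <- match.arg(model)
  ultrametric <- match.arg(ultrametric)
  adjust <- match.arg(adjust)
  cfg <- as.list(environment())
  if (!simulate) {
    paths <- list(tree = tree, traits = traits, matrix = matrix, groups = groups)
    ok <- vapply(paths, function(p) !is.null(p) && file.exists(p), logical(1))
    if (!all(ok)) {
      stop("missing input file(s): ", paste(names(paths)[!ok], collapse = ", "))
    }
  }
  structure(cfg, class = "pipeline_config")
}

#' Run the full comparative-phylogenomics pipeline
#'
#' Executes, in order: ancestral state reconstruction of the symbiotic trait
#' (ER and ARD Mk fits, model comparison, marginal reconstruction, gain/loss
#' counts), the orthogroup enrichment scan, the sparse PLS-DA screen, the
#' differential-expression cross-reference and candidate triage, and the HGT
#' evidence checks on any supplied gene-tree/scaffold fixtures. Every stage
#' writes its artifacts under `out_dir`, and a consolidated machine-readable
#' summary is written to `out_dir/report.json` (plus `report.tsv`).
#'
#' @param config A [pipeline_config()], a list with its fields, or a path to
#'   a YAML file holding them.
#' @return The report list, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    ycfg <- yaml::read_yaml(config)
    sim <- if (!is.null(ycfg$sim)) do.call(sim_config, ycfg$sim) else sim_config()
    ycfg$sim <- NULL
    config <- utils::modifyList(
      as.list(pipeline_config(out_dir = ycfg$out_dir %||% ".", sim = sim)),
      ycfg
    )
    config$sim <- sim
  }
  cfg <- config
  if (is.null(cfg$out_dir)) stop("config must name an out_dir")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_msg <- function(...) message("[lichenscan] ", ...)

  ## inputs -----------------------------------------------------------------
  if (isTRUE(cfg$simulate)) {
    log_msg("simulating dataset (seed ", cfg$sim$seed, ")")
    ds <- simulate_dataset(cfg$sim, dir = file.path(cfg$out_dir, "data"))
    tree <- ds$tree; trait <- ds$trait; m <- ds$matrix; groups <- ds$groups
    deg_tab <- ds$deg; g2f <- ds$gene2family; hgt_fixtures <- ds$hgt
  } else {
    for (key in c("tree", "traits", "matrix", "groups")) {
      if (is.null(cfg[[key]]) || !file.exists(cfg[[key]])) {
        stop("missing input file for ", dQuote(key))
      }
    }
    tree <- parse_newick(paste(readLines(cfg$tree), collapse = ""))
    trait <- read_trait_table(cfg$traits)
    m <- load_ortho_matrix(cfg$matrix)
    gtab <- utils::read.delim(cfg$groups, stringsAsFactors = FALSE)
    groups <- stats::setNames(gtab[[2]], gtab[[1]])
    deg_tab <- if (!is.null(cfg$deg)) utils::read.delim(cfg$deg) else NULL
    g2f <- if (!is.null(cfg$gene2fam)) {
      gf <- utils::read.delim(cfg$gene2fam, stringsAsFactors = FALSE)
      stats::setNames(gf[[2]], gf[[1]])
    } else NULL
    hgt_fixtures <- NULL
    ds <- NULL
  }
  if (cfg$ultrametric != "off") {
    tree <- ultrametricize(tree, method = if (cfg$ultrametric == "mpl")
      "mean_path_length" else "extend")
  }

  ## stage 1: ancestral state reconstruction --------------------------------
  log_msg("ASR: fitting Mk models")
  rp <- if (identical(cfg$root_prior, "nsa")) c(1, 0) else cfg$root_prior
  fits <- list()
  if (cfg$model %in% c("both", "ER")) {
    fits$ER <- fit_mk(tree, trait, kind = "ER", root_prior = rp)
  }
  if (cfg$model %in% c("both", "ARD")) {
    fits$ARD <- fit_mk(tree, trait, kind = "ARD", root_prior = rp)
  }
  selection <- if (cfg$model == "both") compare_models(fits$ER, fits$ARD) else NULL
  retained_kind <- if (is.null(selection)) cfg$model else selection$retained
  asr <- asr_marginal(fit = fits[[retained_kind]])
  trans <- count_transitions(asr, threshold = cfg$asr_threshold)
  write_asr_result(trans$asr, tsv = file.path(cfg$out_dir, "asr_nodes.tsv"),
                   newick = file.path(cfg$out_dir, "asr_annotated.nwk"))

  ## stage 2: enrichment screen ---------------------------------------------
  log_msg("screen: family filter + Mann-Whitney-Wilcoxon scan")
  mf <- filter_families(m, cfg$min_species)
  enr <- enrichment_scan(mf, groups, alpha = cfg$alpha, adjust = cfg$adjust)
  utils::write.table(enr, file.path(cfg$out_dir, "enrichment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ## stage 3: sparse PLS-DA --------------------------------------------------
  log_msg("splsda: fitting ", cfg$n_components, " component(s)")
  sp_par <- splsda_params(n_components = cfg$n_components, keepX = cfg$keepX)
  model <- fit_splsda(mf, groups, sp_par)
  top <- top_contributors(model, 1L, min(cfg$top_k, model$keepX[1]))
  utils::write.table(top, file.path(cfg$out_dir, "top_contributors.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  sig_set <- enr$family[enr$significant]
  overlap <- length(intersect(top$family, sig_set))

  ## stage 4: DEG cross-reference + triage ----------------------------------
  regulation <- NULL; triage <- NULL
  phylo_flags <- character(0)
  hgt_reports <- list()

  ## stage 5 runs first on fixtures so its flags can feed the triage
  if (!is.null(hgt_fixtures)) {
    log_msg("hgt: evaluating gene-tree and scaffold evidence")
    for (nm in names(hgt_fixtures)) {
      fx <- hgt_fixtures[[nm]]
      nest <- gene_tree_nesting(fx$gene_tree, focal_group = "trebouxiophyceae",
                                outgroup = "fungi")
      anch <- check_anchoring(fx$scaffolds, fx$candidate)
      hgt_reports[[nm]] <- list(
        donor_hypothesis = nest$donor_hypothesis,
        n_focal_clades = nest$n_focal_clades,
        anchoring = anch$verdict
      )
    }
  }

  if (!is.null(deg_tab) && !is.null(g2f)) {
    log_msg("crossref: DEG thresholds + family regulation + triage")
    calls <- call_degs(deg_tab, fdr_max = cfg$fdr_max, lfc_min = cfg$lfc_min)
    regulation <- classify_family_regulation(calls, g2f, top$family)
    triage <- triage_candidates(top, enr, regulation, phylo_flags)
    utils::write.table(triage, file.path(cfg$out_dir, "candidates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  report <- list(
    parameters = list(
      seed = if (isTRUE(cfg$simulate)) cfg$sim$seed else NA,
      model = cfg$model, root_prior = cfg$root_prior,
      min_species = cfg$min_species, alpha = cfg$alpha, adjust = cfg$adjust,
      keepX = cfg$keepX, top_k = cfg$top_k,
      fdr_max = cfg$fdr_max, lfc_min = cfg$lfc_min,
      asr_threshold = cfg$asr_threshold
    ),
    asr = list(
      model_selected = retained_kind,
      loglik_er = if (!is.null(fits$ER)) fits$ER$log_likelihood else NA,
      loglik_ard = if (!is.null(fits$ARD)) fits$ARD$log_likelihood else NA,
      q01 = asr$model$q01, q10 = asr$model$q10,
      n_gains = trans$n_gains, n_losses = trans$n_losses
    ),
    screen = list(
      n_families_tested = nrow(enr),
      n_significant = length(sig_set)
    ),
    splsda = list(
      explained_variance = round(model$explained_variance, 6),
      top_k = nrow(top),
      overlap_with_significant = overlap
    ),
    crossref = if (!is.null(triage)) list(
      regulation_counts = as.list(regulation$counts[c("up", "both", "down", "none")]),
      retained = sum(triage$status == "retained"),
      dropped_no_expression = sum(triage$status == "dropped_no_expression"),
      dropped_phylogeny = sum(triage$status == "dropped_phylogeny")
    ) else NULL,
    hgt = hgt_reports
  )
  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = 8)
  flat <- unlist(report)
  utils::write.table(
    data.frame(key = names(flat), value = as.character(flat)),
    file.path(cfg$out_dir, "report.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE
  )
  log_msg("done: report at ", file.path(cfg$out_dir, "report.json"))
  invisible(report)
}
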