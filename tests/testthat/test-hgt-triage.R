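test_that("specificity_profile reports the retention fractions", {
  sp <- c(sprintf("las%02d", 1:13), sprintf("nsa%02d", 1:23))
  g <- stats::setNames(rep(c("focal", "other"), c(13, 23)), sp)
  m <- matrix(0L, 36, 2, dimnames = list(sp, c("GH8", "ALL")))
  m[c(1:11, 14:18), "GH8"] <- 1L # 11 of 13 focal, 5 of 23 other
  m[, "ALL"] <- 1L
  prof <- specificity_profile(m, g, "GH8")
  expect_equal(prof$focal_fraction, 11 / 13)
  expect_equal(prof$other_fraction, 5 / 23)
  expect_equal(c(prof$focal_present, prof$other_present), c(11L, 5L))
  expect_equal(specificity_profile(m, g, "ALL")$focal_fraction, 1)
  m[, "ALL"] <- 0L
  none <- specificity_profile(m, g, "ALL")
  expect_equal(c(none$focal_fraction, none$other_fraction), c(0, 0))
  expect_error(specificity_profile(m, g, "nope"), "not in matrix")
})

test_that("the lineage worked example needs two transfers versus five losses", {
  tree <- lineage_tree_fixture()
  presence <- c("bacteria", "Mucoromycotina", "LAS_algae")
  sc <- event_scenarios(tree, presence)
  expect_equal(sc$transfers, 2L)
  expect_equal(sc$dollo_losses, 5L)
  expect_equal(sc$verdict, "hgt_more_parsimonious")
  # counting the origin as an event is available as an option
  expect_equal(event_scenarios(tree, presence, count_origin = TRUE)$transfers, 3L)
})

test_that("event_scenarios handles vertical and degenerate presence patterns", {
  tree <- lineage_tree_fixture()
  vertical <- c("NSA_algae", "LAS_algae")
  sc <- event_scenarios(tree, vertical)
  expect_equal(c(sc$transfers, sc$dollo_losses), c(0L, 0L))
  all_present <- event_scenarios(tree, tree$tip.label)
  expect_equal(c(all_present$transfers, all_present$dollo_losses), c(0L, 0L))
  expect_error(event_scenarios(tree, "martian"), "not in tree")
  # invariant bounds
  set.seed(71)
  for (i in 1:10) {
    tr <- rand_tree(8)
    pres <- sample(tr$tip.label, sample(1:7, 1))
    sc <- event_scenarios(tr, pres)
    expect_lte(sc$transfers + 1L, length(pres))
    expect_lte(sc$dollo_losses, 8L - length(pres))
  }
})

test_that("Sankoff counts equal brute-force enumeration on small trees", {
  set.seed(72)
  for (i in 1:25) {
    n <- sample(4:8, 1)
    tree <- rand_tree(n)
    pres <- sample(tree$tip.label, sample(seq_len(n - 1), 1))
    expect_equal(sankoff_count(tree, pres), oracle_min_changes(tree, pres))
    gc_ <- sample(c(1, 2, 5), 1); lc_ <- sample(c(1, 2), 1)
    expect_equal(sankoff_count(tree, pres, gc_, lc_),
                 oracle_min_changes(tree, pres, gc_, lc_))
  }
})

test_that("event counts are invariant to rotation and zero-length subdivision", {
  tree <- lineage_tree_fixture()
  presence <- c("bacteria", "Mucoromycotina", "LAS_algae")
  ref <- event_scenarios(tree, presence)
  rot <- ape::rotate(tree, node = length(tree$tip.label) + 1L)
  sc_rot <- event_scenarios(rot, presence)
  expect_equal(sc_rot$transfers, ref$transfers)
  expect_equal(sc_rot$dollo_losses, ref$dollo_losses)
  # subdividing a branch with a zero-length edge changes nothing
  sub <- parse_newick(sub("bacteria:3", "(bacteria:3):0", write_newick(tree)))
  sc_sub <- event_scenarios(sub, presence)
  expect_equal(sc_sub$transfers, ref$transfers)
  expect_equal(sc_sub$dollo_losses, ref$dollo_losses)
  expect_equal(sankoff_count(sub, presence), sankoff_count(tree, presence))
})

test_that("gene_tree_nesting identifies donors and vertical signals", {
  gt <- read_gene_tree(paste0("(((alga1|chlorophyte:1,alga2|chlorophyte:1):1,",
                              "bact1|bacteria:1):1,(bact2|bacteria:1,",
                              "(fung1|fungi:1,fung2|fungi:1):1):1);"))
  rep <- gene_tree_nesting(gt, "chlorophyte", outgroup = "fungi")
  expect_true(rep$focal_monophyletic)
  expect_equal(rep$n_focal_clades, 1L)
  expect_equal(rep$donor_hypothesis, "bacteria")
  expect_false(rep$caveat)

  # two scattered focal clades with bacterial sisters: double transfer
  gt2 <- read_gene_tree(paste0("(((alga1|treb:1,bact1|bacteria:1):1,",
                               "(alga2|treb:1,bact2|bacteria:1):1):1,",
                               "(fung1|fungi:1,fung2|fungi:1):1);"))
  rep2 <- gene_tree_nesting(gt2, "treb", outgroup = "fungi")
  expect_false(rep2$focal_monophyletic)
  expect_equal(rep2$n_focal_clades, 2L)
  expect_equal(rep2$donor_hypothesis, "bacteria")

  # chlorophyte sister = vertical signal
  gt3 <- read_gene_tree(paste0("(((alga1|treb:1,alga2|treb:1):1,",
                               "(chl1|chlorophyte:1,chl2|chlorophyte:1):1):1,",
                               "(bact1|bacteria:1,fung1|fungi:1):1);"))
  rep3 <- gene_tree_nesting(gt3, "treb", outgroup = "bacteria")
  expect_equal(rep3$donor_hypothesis, "none")

  expect_error(gene_tree_nesting(gt, "diatom"), "no focal tips")
  # missing outgroup flags a caveat instead of failing
  rep4 <- gene_tree_nesting(gt2, "treb", outgroup = "archaea")
  expect_true(rep4$caveat)
})

test_that("donor calls are invariant to the rooting tip within the outgroup", {
  gt <- sim_hgt_evidence(sim_config(seed = 73), role = "xenolog")$gene_tree
  full <- gene_tree_nesting(gt, "trebouxiophyceae", outgroup = "fungi")
  # re-root on a single fungal tip instead of the whole clade
  one_tip <- ape::root(gt, outgroup = grep("fungi", gt$tip.label, value = TRUE)[1],
                       resolve.root = TRUE)
  parts <- strsplit(one_tip$tip.label, "|", fixed = TRUE)
  one_tip$taxon_group <- vapply(parts, `[[`, "", 2L)
  rerooted <- gene_tree_nesting(one_tip, "trebouxiophyceae")
  expect_equal(rerooted$donor_hypothesis, full$donor_hypothesis)
})

test_that("check_anchoring classifies clean, contaminated and bare contexts", {
  clean <- sim_hgt_evidence(sim_config(seed = 74), role = "xenolog",
                            fixture = "clean")
  v <- check_anchoring(clean$scaffolds, clean$candidate)
  expect_equal(v$verdict, "anchored")
  expect_gte(v$host_fraction, 0.6)

  contam <- sim_hgt_evidence(sim_config(seed = 74), role = "xenolog",
                             fixture = "contaminated")
  v2 <- check_anchoring(contam$scaffolds, contam$candidate)
  expect_equal(v2$verdict, "suspect")

  lone <- data.frame(gene = "solo", scaffold = "s1", start = 1L, end = 10L,
                     strand = "+", assignment = "unassigned")
  expect_equal(check_anchoring(lone, "solo")$verdict, "insufficient_context")
  expect_error(check_anchoring(lone, "ghost"), "not on any scaffold")
})

test_that("joint triage separates xenolog from vertical families", {
  ds <- simulate_dataset(sim_config(seed = 31, n_background = 300,
                                    n_expanded = 0, n_xenolog = 40))
  set.seed(32)
  flag <- function(fam, role) {
    spec <- specificity_profile(ds$matrix, ds$groups, fam)
    ev <- sim_hgt_evidence(ds$config, role = role, fixture = "clean")
    nest <- gene_tree_nesting(ev$gene_tree, "trebouxiophyceae", outgroup = "fungi")
    pres <- rownames(ds$matrix)[ds$matrix[, fam] >= 1]
    sc <- event_scenarios(ds$tree, pres)
    triage_hgt(spec, nest, anchoring = check_anchoring(ev$scaffolds, ev$candidate),
               scenario = sc)
  }
  xeno <- ds$truth$families$xenolog
  sens <- mean(vapply(xeno, function(f) flag(f, "xenolog") == "hgt_supported",
                      logical(1)))
  bg <- sample(ds$truth$families$background, 40)
  fp <- mean(vapply(bg, function(f) flag(f, "vertical") == "hgt_supported",
                    logical(1)))
  expect_gte(sens, 0.9)
  expect_lte(fp, 0.05)
})

test_that("scaffold tables round-trip through GFF3 plus sidecar", {
  ev <- sim_hgt_evidence(sim_config(seed = 75), role = "xenolog", fixture = "clean")
  gff <- tempfile(fileext = ".gff3"); taxa <- tempfile(fileext = ".tsv")
  lichenscan:::write_scaffold_gff(ev$scaffolds, gff, taxa)
  back <- read_scaffold_table(gff, taxa)
  expect_equal(back[order(back$gene), c("gene", "scaffold", "start", "end", "assignment")],
               ev$scaffolds[order(ev$scaffolds$gene),
                            c("gene", "scaffold", "start", "end", "assignment")],
               ignore_attr = TRUE)
  v <- check_anchoring(back, ev$candidate)
  expect_equal(v$verdict, "anchored")
})
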