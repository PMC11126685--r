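Package: lichenscan
Title: Comparative Phylogenomics of Lichenization in Chlorophyte Algae
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing the evolutionary history of a binary
    symbiotic trait (lichen algal symbiont versus non-symbiotic alga) on a
    species phylogeny and for screening orthogroup gene-count matrices for
    symbiosis-associated gene families. Implements two-state Mk-model
    likelihoods via Felsenstein pruning, equal-rates versus all-rates-different
    model comparison, marginal ancestral state reconstruction and gain/loss
    counting; exact and tie-corrected Mann-Whitney-Wilcoxon enrichment scans;
    sparse partial least squares discriminant analysis with keepX
    soft-thresholding; differential-expression cross-referencing; and
    horizontal-gene-transfer triage (lineage specificity, gene-tree nesting,
    transfer-versus-Dollo event parsimony, scaffold anchoring). A synthetic
    data generator with planted ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    mixOmics,
    phytools,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
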