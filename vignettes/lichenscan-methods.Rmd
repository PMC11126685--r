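---
title: "Methods: screening chlorophyte genomes for symbiosis-associated gene families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening chlorophyte genomes for symbiosis-associated gene families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lichenscan)
```

# The problem

Lichens pair a fungus with a photosynthetic partner, most often a
chlorophyte alga. Whether the algal ability to live inside a lichen (the
lichen-algal-symbiont state, LAS, versus non-symbiotic, NSA) arose once and
was repeatedly lost, or arose several times independently, is a question
about the history of a binary character on a species phylogeny. Once the
history is resolved, a second question follows: which gene families track
the symbiotic habit — through family expansion, through lineage-restricted
presence, or through horizontal acquisition from outside the green lineage?

`lichenscan` implements that inference chain as reusable, tested
components: a two-state Markov (Mk) model of trait evolution with marginal
ancestral state reconstruction and gain/loss counting; a per-family
Mann–Whitney–Wilcoxon enrichment scan over a species-by-orthogroup
gene-count matrix; a sparse partial least squares discriminant analysis
(sPLS-DA) that ranks the families best separating symbiotic from
non-symbiotic species; a differential-expression cross-reference that
asks which candidate families respond transcriptionally to co-culture with
a fungal partner; and a horizontal-gene-transfer (HGT) triage combining
lineage-specificity, gene-tree nesting, event-count parsimony and
scaffold-anchoring checks. A synthetic-data generator with planted ground
truth ties the chain together so every stage can be validated end to end.

# Trait evolution: the Mk model

The trait follows a continuous-time Markov chain on the tree with gain
rate $q_{01}$ and loss rate $q_{10}$ per unit branch length. The
transition probabilities over a branch of length $t$ are closed-form:

$$P_{00}(t) = \frac{q_{10} + q_{01}e^{-(q_{01}+q_{10})t}}{q_{01}+q_{10}},
\qquad P_{01}(t) = 1 - P_{00}(t),$$

and symmetrically for $P_{11}, P_{10}$. `mk_loglik()` evaluates the
likelihood by Felsenstein pruning; polytomies are handled natively as
products over all children, and zero-length branches contribute an
identity transition. The *equal rates* (ER) model constrains
$q_{01} = q_{10}$; *all rates different* (ARD) leaves both free.
`fit_mk()` maximizes the likelihood over log-rates with three
deterministic starting points (0.1, 1 and 10 times the inverse tree
height), derivative-free local search, rate bounds $[10^{-8}, 10^3]$ and
convergence tolerance $10^{-8}$; the multi-start guards against the flat
ridges that Mk likelihood surfaces are known for. `compare_models()`
reports $\Delta\log L$, the 1-df likelihood-ratio test and AIC, and
retains the higher-likelihood model (ER on ties, as the more parsimonious
model).

`asr_marginal()` combines downward (pruning) and upward partial
likelihoods into per-node marginal posteriors; tip posteriors are point
masses on the observed states. `count_transitions()` calls a node derived
when its posterior exceeds 0.5 (an exact tie is flagged ambiguous and
inherits the parent's call), and counts an edge as a gain when the parent
is called 0 and the child 1, and as a loss in the reverse case.

## The root prior

The root state distribution is a genuine modeling choice. `mk_model()`
offers `uniform` (0.5, 0.5 — the default, and the common default of the
standard tooling), `stationary` ($\pi_1 = q_{01}/(q_{01}+q_{10})$), and a
custom vector. The choice matters more than it may appear: for a rare
derived trait, the ARD likelihood has a degenerate optimum at
$q_{01} \to 0$ in which the root is assigned the derived state and every
absence is explained as a loss. A flat prior gives that scenario half the
root mass and the maximum-likelihood fit can settle on it, after which the
reconstruction reports zero gains. The stationary prior shrinks the
derived root mass with $q_{01}$ and suppresses the ridge partially; a root
constrained to the ancestral state removes it entirely. Because the
pipeline's species tree is rooted on a known non-symbiotic outgroup — the
root of the chlorophyte radiation long predates any lichen — the pipeline
default is `root_prior = "nsa"`, i.e. the custom prior $(1, 0)$. The ER/ARD
comparison is unaffected by this choice of scope: both models are fit
under the same prior.

# The orthogroup screen

The screen's central object is a species-by-family matrix of non-negative
integer gene counts, as produced by orthology inference tools.
`filter_families()` first removes families present in fewer than three
species (species-specific and two-species families carry no comparative
signal). `enrichment_scan()` then applies a two-sided
Mann–Whitney–Wilcoxon test per family, comparing counts in the focal
group (symbiotic species) against all others, zeros included — absence is
part of the signal. Mid-ranks handle ties. The null distribution is exact,
enumerated over all $\binom{n+m}{n}$ group assignments whenever that
count is at most 200,000 (worst case well under a second); beyond that the
normal approximation with tie correction and continuity correction is
used, which at group sizes of 13 vs 23 is within 0.005 of the exact
p-value in our tests. Significance is judged on the raw p-value at
$\alpha = 0.01$ by default — matching the screen's role as a permissive
complement to the discriminant analysis — with Benjamini–Hochberg
adjustment available (`adjust = "BH"`). Direction is defined by mean
ranks, keeping it consistent with the statistic. The same test drives
`group_feature_compare()` for genome-level features (genome size, gene
count, GC content, repeat fraction), with group medians reported so the
direction of each difference is explicit.

# Sparse PLS-DA

`fit_splsda()` implements sPLS-DA from first principles. The count matrix
is column-centered and unit-variance scaled (zero-variance columns are
kept, pinned to zero loading, so feature indices remain stable); class
membership is coded as two indicator columns, also centered and scaled (a
one-column ±1 coding is equivalent for two classes and is verified to
select the same support). For each component the dominant singular pair of
$X_h^\top Y$ is obtained by power iteration (tolerance $10^{-9}$, at most
500 iterations); the X-weight is soft-thresholded with the order-statistic
rule — the threshold is the $(k{+}1)$-th largest absolute weight, ties
broken by ascending feature order — so that exactly `keepX` entries
survive, then re-normalized. Scores are $X_h w$; $X$ is deflated by its
least-squares regression on the score (regression-mode deflation; $Y$ is
not deflated). Explained variance is computed on the undeflated scaled
$X$ with scores orthogonalized in fit order, so per-component fractions
are additive and bounded by one. Counts enter untransformed by default; a
`log1p` option exists but is off, since the screen is defined on raw
counts. The implementation is cross-checked in the test suite against the
dense SVD of $X^\top Y$ (non-sparse limit) and against an independent
sPLS-DA implementation (identical component-1 support and loadings).

# Differential-expression cross-reference

The DE model fitting itself (normalization, dispersion estimation) is out
of scope: the module consumes per-gene tables of log fold change and FDR
from standard count-based DE tools. `low_count_filter()` removes genes
whose summed reads stay below 10 in every sample class; the stricter
"at least 10 in each class" reading is available behind a flag, since the
informal phrasing of such filters is ambiguous. `call_degs()` marks a gene
up-regulated when FDR < 0.05 and logFC > 1.5, down-regulated in the mirror
case — both inequalities strict, logFC interpreted as log2 (so 1.5 is
roughly a 2.8-fold change). `classify_family_regulation()` lifts gene
calls to families (`up`, `down`, `both`, `none`), and
`triage_candidates()` assembles the final report in pipeline order: the
discriminant top-k is intersected with the enrichment-significant set,
families without any regulated member are dropped, and families whose
gene-tree check refutes the association are removed (an `unresolved` flag
is carried but recorded). A family failing the enrichment intersection is
labeled `dropped_not_enriched` — a status the strong-effect regime makes
rare, since there the top-k nests completely inside the significant set.

# HGT triage

Four evidence streams feed the transfer assessment of a candidate family.
`specificity_profile()` reports presence fractions in the focal and other
groups with explicit numerators. `event_scenarios()` compares two origins
on the host/lineage tree: under transfer, the family is native to one
present lineage and each further maximal present clade costs one transfer
(`transfers = #maximal present clades - 1`; counting the origin is an
option); under a single ancient origin, every maximal absent clade
strictly inside the presence MRCA costs one Dollo loss. A Sankoff
minimum-change count with configurable gain/loss costs accompanies the two
tallies as a sensitivity check; it is verified against brute-force
enumeration in the tests. `gene_tree_nesting()` roots the gene tree on a
declared outgroup, finds the maximal all-focal clades and summarizes their
sister-group composition; the donor hypothesis is the majority sister
taxon, demoted to "none" when that majority is the recipient's own lineage
(vertical signal). The majority rule is a proxy for by-eye inspection of
nesting and is deliberately simple and auditable. `check_anchoring()`
orders genes along the candidate's scaffold and requires at least two
taxonomically assigned neighbors on each available side with a host
fraction of at least 0.6 among assigned neighbors; fewer neighbors give
`insufficient_context`, a lower host fraction gives `suspect`. The window
(5 genes per side) and the 0.6 threshold are package decisions — the
qualitative criterion they operationalize is "anchored among host genes".
`triage_hgt()` combines the streams: focal-skewed presence (difference of
fractions at least 0.4), a non-vertical donor, non-suspect anchoring, and
an event comparison not favoring losses.

# The synthetic-data generator

`simulate_dataset()` draws, from a single seeded RNG stream in documented
order (tree, trait, families, genes, fixtures): a pure-birth (Yule) tree
with 141 tips rescaled to height 1; a trait history; a count matrix of
2,000 background families, 20 "expanded" families whose Poisson mean is
multiplied by 4 in symbiotic species, and 2 "xenolog" families present
with probability 0.85 in symbiotic and 0.2 in non-symbiotic species
(echoing an 11/13 versus 5/23 retention contrast); per-gene DE tables for
one profiled symbiotic species in which trait-linked genes are regulated
with probability 0.8 and background genes with probability 0.05; and
gene-tree plus scaffold fixtures for the HGT checks. DE genes draw
$|{\rm logFC}| = 1.5 + {\rm Exp}(1)$ and ${\rm FDR} \sim U(0, 0.05)$;
null genes draw ${\rm logFC} \sim N(0, 0.5)$ and ${\rm FDR} \sim U(0,1)$,
re-drawn in the rare event both thresholds would be crossed, so the
planted DE status is recoverable exactly — a deliberate idealization that
makes threshold behavior testable in isolation.

## Planted trait histories

In planted mode the generator writes a history of three independent gains
followed by eleven losses — the history scale the reconstruction targets.
Early versions planted gains in arbitrary disjoint clades; maximum
likelihood reconstruction then frequently merged nearby clades into one
deep gain, absorbed basal losses into a shifted gain edge, or fell onto
the all-loss ridge described above. All three failure modes are properties
of real Mk inference, not bugs, so the generator now plants histories with
the strong phylogenetic clustering the real system exhibits (gains in
different algal classes are separated by long, lineage-rich backbones).
Concretely, clades are screened by a fixed ladder of criteria, strictest
first, relaxing only as far as the tree at hand requires: the clade's stem
should be long relative to its parent's stem (so the gain edge is
identifiable), any two planted clades should be separated by a minimum
number of intervening lineages and a minimum path length (so gains are not
mergeable), and clade sizes range from 8 to 28 tips. Losses are planted as
phylogenetically independent single-tip events — no two losses may form an
all-absent subclade, each basal lineage of a clade keeps survivors, and at
most 40% of a clade is lost. Under these conditions the ARD
reconstruction with the outgroup-constrained root recovers the exact
planted history in roughly nine out of ten replicate datasets, and the
modal recovered history equals the planted one; this is measured by the
test suite over twenty 141-species replicates.

## What the generator does not emulate

Counts are independent across species given the family law: there is no
phylogenetic autocorrelation beyond the trait linkage. This matches the
screen under test, which is itself phylogeny-blind, but it means passing
tests say nothing about robustness to phylogenetic pseudoreplication in
real data (a phylogenetically corrected test is a stated non-goal).
RNA-seq counts are not simulated at the read level — DE inputs are
(logFC, FDR) pairs, not negative-binomial counts. Gene trees are built
with the planted topology rather than inferred from simulated sequences,
so gene-tree estimation error is outside the validated envelope.

# Problem sizes and numerical choices

The validation suite runs the likelihood oracle on 200 random trees of up
to five internal nodes ($|\Delta| < 10^{-10}$ against full enumeration),
calibrates the likelihood-ratio test on 200 trait simulations on a
100-tip tree (type-I error at most 10% at $\alpha = 0.05$), measures
planted-history recovery on twenty 141-tip datasets, verifies exact
Wilcoxon p-values against enumeration for all group sizes up to 8 with and
without ties, and exercises the full pipeline at the default scale (141
species, about 2,000 families) twice to confirm byte-identical reports.
Those sizes keep each property statistically meaningful while the whole
suite completes in a few minutes on one CPU.

Ties in the sPLS-DA soft threshold are broken by ascending feature id;
exact |weight| ties across the keepX boundary would shrink the support by
the tied count (they do not arise in continuous-weight data). Exact
posterior ties at the 0.5 call threshold inherit the parent's call and are
flagged. Zero-length branches are legal everywhere and contribute identity
transitions; likelihoods and event counts are invariant to zero-length
subdivision, and the tests assert both.

# Limitations

The Mk machinery is strictly two-state: multi-state characters,
hidden-rate models and stochastic character mapping are out of scope. The
enrichment scan makes no phylogenetic correction. The transfer/loss event
counts are deterministic clade statistics, not a probabilistic
reconciliation; they are meant to make the parsimony argument auditable,
not to replace a DTL model. The triage's phylogenetic flags are inputs:
when gene-tree evidence is absent the pipeline treats a family as
unrefuted rather than guessing.
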