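---
title: "Methods behind phylopos: placing a fast-evolving clade with synteny, phylomes and topology tests"
author: "phylopos authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind phylopos}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylopos)
```

# The problem

Microsporidia are intracellular parasites whose genomes evolve so fast that
standard phylogenetics places them almost anywhere in (or outside) the
fungal tree, largely through long-branch attraction (LBA). Resolving where
such a clade attaches therefore requires several independent lines of
evidence, each guarded against its own artifacts. `phylopos` implements that
toolkit: gene-neighborhood (microsynteny) conservation corrected for
segmental duplications, a genome-wide census of gene-tree sister groups, a
duplication-minimizing supertree, signal stratification of concatenated
alignments, resampling-based topology tests, and two LBA diagnostics — all
validated against a synthetic-data generator with planted ground truth.

Throughout, a *focal group* (by default `"Microsporidia"`) is placed
relative to six predefined fungal groups — Chytridiomycotina (C),
Zygomycotina (Z), Basidiomycotina (B), Taphrinomycotina (T),
Saccharomycotina (S), Pezizomycotina (P) — plus an outgroup.

# Synthetic data: what the generator emulates

The simulators define the conditions under which the pipeline is tested.

* **Species trees** (`simSpeciesTree`) grow by a Yule tip-splitting process;
  branch lengths are i.i.d. exponential (mean 0.1 substitutions/site by
  default) — a one-parameter, strictly positive choice. With `groupSizes`,
  a backbone over groups receives per-group Yule subtrees so groups are
  monophyletic by construction. `referenceSpeciesTree()` is a deterministic
  22-species sampling (6 focal, 4 outgroups, 12 species over the six
  groups) with the focal clade basal to the other fungi.
* **Gene orders** (`simGeneOrders`) descend from one ancestral chromosome
  through inversions (reverse a block, flip strands), *tandem* segmental
  duplications (the copy lands next to the source, maximizing the
  confounding effect the synteny correction targets), and gene gain/loss.
  True orthology is descent without duplication; duplicated and gained
  copies carry no ortholog id. Loss never removes a genome's last member of
  a family, which keeps family bookkeeping well defined (and implies the
  family survives in the clade).
* **Gene trees** (`simGeneTrees`) arise by a birth–death process inside the
  species tree: per branch traversal a Poisson number of events, each a
  duplication (lineage forks) or loss (lineage dies); every surviving
  internal node records its true event label.
* **Alignments** (`simAlignment`) evolve under a 20-state equal-
  exchangeability CTMC with configurable stationary frequencies (an
  amino-acid analogue of F81) whose transition probabilities are available
  in closed form. Rate heterogeneity is discrete-gamma: equal-probability
  categories with *category-median* rates rescaled to mean 1; each column's
  true category is recorded. Empirical-matrix engines (LG, CAT) are
  deliberately out of scope — only a correct CTMC with planted rates is
  needed to validate rate stratification and tree building.
* **Phylome metadata** (`makePhylomeRecords`) attaches branch support,
  alignment length and consistency score to each gene tree, since the
  census filters consume these as given.

What the generator does *not* emulate: indels (alignments are gap-free
unless gaps are injected), codon structure, compositional heterogeneity
across lineages, heterotachy, and alignment error. Passing tests therefore
demonstrate the correctness of the algorithms under the stated model, not
robustness to every pathology of real data.

# Microsynteny with duplication correction

Two genes of a query genome separated by at most three intervening genes
form a **relaxed** syntenic pair when family homologs of both co-occur in
the target at most four genes apart; any intervening query gene with a
target homolog must have one within a 15-gene window of the target pair.
The window's anchor is not fully specified by the verbatim rule; `phylopos`
requires a homolog within 7 positions of the interval spanned by the two
target anchors (a 15-gene window centered on the pair).

The **strict** variant replaces homology by one-to-one orthology, requires
a shared orientation (the query genes share a strand and so do their
orthologs — whole-pair inversions are allowed), tightens the target
separation to three intervening genes, and discards a pair whenever an
intervening query gene has a target ortholog (`"literal"`). Because that
reading collapses perfectly colinear genomes to their adjacencies, an
`"interval_consistent"` mode is also provided that only discards the pair
when the intervening gene's ortholog falls outside the target interval —
both readings are implemented and neither is asserted as the original
intent.

A lineage-specific tandem duplication lets one query pair hit several
target loci of the same family pair, inflating counts;
`collapseParalogousPairs` groups hits by (query pair, unordered family
pair) and counts each group once. Counts are normalized per 1000 shared
homologs (relaxed) or shared 1:1 orthologs (strict); the shared-homolog
denominator counts query genes whose family has a member in the target —
the counting unit is a documented package choice, as is asymmetry: both
query→target and target→query directions are reported rather than assumed
equal. Group differences are assessed with the Kruskal–Wallis rank test
(midranks for ties, chi-square reference distribution).

# The phylome census

For every gene tree: root on the *most distant outgroup sequence* —
interpreted as the outgroup leaf with the greatest mean branch-length path
to the in-group leaves, ties broken lexicographically (the metric is not
dictated by the procedure's name; averaging resists single long in-group
branches). Outgroup monophyly is then assessed as an unrooted split, since
rooting *on* an outgroup leaf makes a rooted-clade reading of monophyly
vacuously false. Duplication/speciation labels come from species overlap:
a node is a duplication iff its child species sets intersect (score
|L∩R|/|L∪R| above a threshold of 0).

The sister partition of the (monophyletic) focal clade maps to a scenario
vocabulary: one group gives that group's letter; S+P, T+S+P, B+T+S+P and
B+T+S+P+Z give the corresponding ancestral placements; all six groups give
"A" (basal to all fungi) — unless C and Z form an exclusive clade inside
the sister partition, which distinguishes "A-C+Z"; everything else is
"other". Records with a non-monophyletic focal clade are tallied as their
own category rather than force-classified, and records missing a predefined
group are excluded, mirroring how artifact-laden trees are reported rather
than guessed at. Three quality filters use strict inequalities: branch
support of the focal clade's parental node > 0.8 (the support subtending
the parent; at the root the focal clade's own support is used), alignment
consistency > 0.75, alignment length > 500 columns.

# Duplication-minimizing supertree

`countDuplications` performs standard LCA reconciliation: each gene-tree
node maps to the species-tree LCA of its descendant species and is a
duplication iff it maps where one of its children maps. Species sets are
bit-encoded so a candidate species tree is scored against hundreds of gene
trees by a minimal-superset lookup; losses are not costed, matching the
objective of minimizing implied duplications only. `searchMinDupSupertree`
either enumerates all rooted topologies (up to 8 species; ties broken by
smallest canonical Newick) or hill-climbs with rooted nearest-neighbor
interchanges from random starts (default 50 seeded restarts — single runs
stall in local optima regularly, restarts recover the exhaustive optimum on
the large majority of instances). Gene trees are assumed rooted (by the
census rooting procedure); optimal-rooting search is out of scope.

# Alignment stratification

Families with at most one gene per species in enough species are
concatenated with per-column partition bookkeeping; absent species receive
gaps. Trimming removes columns without residue variation and columns that
are gaps in every focal row. Per-site, per-category log-likelihoods come
from Felsenstein pruning under the same equal-exchangeability model
(closed-form transitions, per-node rescaling against underflow; gaps are
missing data). Columns are assigned to 1 of 16 discrete-gamma categories by
posterior argmax under equal category priors, ties resolved toward the
slower category; the gamma shape is grid-maximized from the data unless
supplied. Only *relative* per-category likelihoods matter for assignment,
which is why a simple exchangeability model suffices; externally computed
site-likelihood matrices can be supplied wherever higher fidelity is
needed. Removing the k fastest categories (k = 2, 4, 6, 8) and
partitioning columns by the number of distinct focal-clade residues
(1–2 / 3 / 4 / ≥5, gap-only focal columns excluded, gaps never counted as
residues) stratify the signal. A four-letter recoding ships as a clearly
labeled stand-in grouping (small/polar, aromatic+C, charged/amide,
aliphatic), since the original reduced alphabet's groups are citation-only;
any total mapping can be supplied.

# Topology tests

Twelve constrained hypotheses are generated by pruning the focal clade
(internal structure intact) and regrafting it at the stem of each single
group, at the S+P, T+S+P, B+T+S+P and B+T+S+P+Z ancestors, basal to all
fungi, and basal with C and Z regrouped. The focal clade is kept intact
rather than re-resolved per hypothesis.

The eight tests consume a trees × sites log-likelihood matrix via RELL
resampling (sites resampled with replacement, no re-optimization): BP
(replicate win fraction, exact ties rotated across replicates), PP (BIC
weights, which reduce to likelihood weights for equal parameter counts),
KH/WKH against the maximum-likelihood tree using centered one-sided
replicate differences (the weighted variants standardize by the replicate
standard error and choose the standardized-worst opponent), SH/WSH with
worst-case centering over all trees, and AU/NP from a ten-scale
(0.5–1.4) multiscale bootstrap with a weighted-least-squares probit fit:
AU = 1 − Φ(d − c), NP = 1 − Φ(d + c). One-sided centering was chosen
because it yields the correct per-tree type-I error (~5% at α = 0.05)
under null simulations and preserves SH ≥ KH for non-best trees; a
two-sided variant does neither. Confidence sets keep trees with p ≥ α
(the operational reading of "could not be discarded") and always include
the best tree.

# LBA diagnostics

`buildNJTree` wraps classical neighbor joining on p-distances or
Poisson-corrected distances over pairwise comparable columns (rows sorted
first, so input order is irrelevant; negative branches are clamped to zero
with the deficit moved to the sibling). The **random replacement test**
substitutes the focal rows with i.i.d. residues (composition-matched by
default, preserving the compositional part of the LBA signal; uniform
available), rebuilds the tree per replica, and classifies the focal
attachment edge: the named focal-position edge is checked first, then
attachments inside the outgroup subtree or on its stem count as
`within_outgroups`, everything else (including non-monophyletic focal rows)
as `elsewhere`. The precedence matters because the basal-to-fungi position
*is* the outgroup stem edge. Random sequences attaching among the long
outgroup branches rather than at the focal position indicate that the
focal placement is not an attraction artifact. The **parametric test**
simulates gene families on a tree with the focal clade planted at a stated
position (for example, with the chytrids), rebuilds the tree from the
concatenate, and reports whether the planted placement is recovered —
if divergence alone sufficed to drag the clade basal, it would not be.

# Numerical choices and degenerate inputs

* All randomness flows through explicit `seed` arguments; every simulator
  and resampler is a pure function of (inputs, seed), and the caller's RNG
  state is restored.
* Likelihood pruning rescales partial likelihoods per node; the exhaustive
  state-sum oracle agrees to 10 significant digits on small trees.
* Bootstrap probabilities of exactly 0 or 1 short-circuit the AU fit (p = 0
  or 1); otherwise they are clipped to (1/(2B), 1 − 1/(2B)) before the
  probit transform.
* Zero event rates reproduce inputs exactly; zero branch lengths transmit
  sequences unchanged; empty confidence-set candidates cannot occur because
  the best tree is always retained.
* Polytomies in gene trees are resolved arbitrarily with zero-length
  branches and flagged, as species-overlap labeling requires binary nodes.

# Problem sizes used in the validation suite

The shipped tests and the acceptance script validate at desk scale chosen
to make the statistical checks decisive: 20 random genome pairs (80–200
genes) for detector–oracle equivalence, 500 random gene trees (≤ 12
leaves) for the reconciliation oracle, 100 replicates of the 6-species
supertree recovery (200 gene trees each), a census of 500 records on the
22-species reference sampling, 5,000 columns for rate-stratification
recovery, 1,000 null simulations for KH calibration, and 100 replicas for
the replacement test. Real-data headline numbers from genome-scale studies
(tens of thousands of positions, thousands of trees) depend on the
underlying genomes and are not reproduced by these simulations.

# Known limitations

* The substitution model is exchangeability-symmetric; site-likelihoods for
  publication-grade inference should come from external ML engines, which
  the site-lnl text format accommodates.
* The strict-synteny "literal" reading collapses colinear genomes to
  adjacencies; both readings are exposed because the source rule is
  ambiguous.
* Tree inference beyond neighbor joining (ML, Bayesian) is pluggable but
  not bundled.
* The supertree objective ignores losses and transfers; exhaustive search
  is capped at 8 species.
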