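## Long-branch-attraction diagnostics: a neighbor-joining builder on
## p/Poisson distances, the random-sequence replacement placement test, and
## the parametric simulation test.

#' Neighbor-joining tree from an alignment
#'
#' Pairwise distances are computed over columns where both sequences have
#' residues: \code{"p_distance"} is the mismatch proportion,
#' \code{"poisson_corrected"} is \code{-log(1 - p)} (saturated distances
#' capped). Agglomeration uses the classic NJ algorithm; rows are sorted by
#' label first so the result is independent of input order. Negative branch
#' lengths are clamped to zero with the deficit moved to the sibling branch.
#'
#' @param alignment an \code{\linkS4class{AlignmentMatrix}} with >= 3 rows.
#' @param distance \code{"p_distance"} or \code{"poisson_corrected"}.
#' @return an unrooted \code{phylo}.
#' @export
buildNJTree <- function(alignment, distance = c("p_distance", "poisson_corrected")) {
  distance <- match.arg(distance)
  m <- alnMatrix(alignment)
  stop_if(nrow(m) < 3L, "need at least 3 sequences")
  m <- m[order(rownames(m)), , drop = FALSE]
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    comp <- m[i, ] != GAP & m[j, ] != GAP
    stop_if(!any(comp), sprintf("no comparable columns between %s and %s",
                                rownames(m)[i], rownames(m)[j]))
    pd <- mean(m[i, comp] != m[j, comp])
    d <- if (distance == "p_distance") pd else -log(max(1 - pd, 0.05))
    D[i, j] <- D[j, i] <- d
  }
  tr <- ape::nj(as.dist(D))
  clamp_negative_branches(tr)
}

# Set negative branch lengths to 0 and move the deficit to the sibling
# branch (path lengths through the parent are preserved where possible).
clamp_negative_branches <- function(tree) {
  neg <- which(tree$edge.length < 0)
  for (e in neg) {
    parent <- tree$edge[e, 1]
    sibs <- setdiff(which(tree$edge[, 1] == parent), e)
    deficit <- tree$edge.length[e]
    tree$edge.length[e] <- 0
    if (length(sibs)) {
      s <- sibs[1]
      tree$edge.length[s] <- tree$edge.length[s] + deficit
    }
  }
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

# Attachment bipartition of the focal clade on an unrooted tree: returns the
# set of non-focal tips on the sibling side of the focal attachment edge, or
# NULL when the focal tips do not form a clean split.
focal_attachment_side <- function(tree, focalTips, refLeaf) {
  rooted <- ape::root(tree, outgroup = refLeaf, resolve.root = TRUE)
  sets <- node_tip_sets(rooted)
  node <- if (length(focalTips) == 1L) match(focalTips, rooted$tip.label)
    else ape::getMRCA(rooted, focalTips)
  if (is.null(node) || is.na(node)) return(NULL)
  if (!setequal(sets[[node]], focalTips)) return(NULL)
  parent_edge <- match(node, rooted$edge[, 2])
  if (is.na(parent_edge)) return(NULL)
  parent <- rooted$edge[parent_edge, 1]
  sibs <- setdiff(phylo_children(rooted)[[parent]], node)
  unlist(sets[sibs])
}

#' Random-sequence replacement test for long-branch attraction
#'
#' In each replica the focal clade's rows are replaced by random residues
#' (\code{\link{randomizeCladeSequences}}), the tree is rebuilt, and the
#' focal clade's attachment edge is classified: \code{at_focal_position}
#' when it matches the edge named by \code{focalPositionSpec} (the expected
#' sister set of the focal clade), \code{within_outgroups} when the
#' attachment is inside the outgroup subtree or on its stem, otherwise
#' \code{elsewhere} (including replicas where the randomized focal rows do
#' not form a single clade).
#'
#' @param alignment an \code{\linkS4class{AlignmentMatrix}}.
#' @param focalCladeSp focal species rows.
#' @param outgroupSpecies outgroup species rows (disjoint from the focal
#'   set).
#' @param focalPositionSpec character vector: the species expected as the
#'   focal clade's sister at its hypothesized position.
#' @param nReplicas number of replicas.
#' @param treeBuilder function(alignment) -> \code{phylo} (default
#'   \code{\link{buildNJTree}}).
#' @param mode randomization mode (see
#'   \code{\link{randomizeCladeSequences}}).
#' @param seed integer seed.
#' @return list with \code{counts} (within_outgroups, at_focal_position,
#'   elsewhere), \code{nReplicas} (successful replicas) and \code{failed}.
#' @export
randomReplacementTest <- function(alignment, focalCladeSp, outgroupSpecies,
                                  focalPositionSpec, nReplicas = 100L,
                                  treeBuilder = buildNJTree,
                                  mode = "composition_matched", seed = NULL) {
  stop_if(length(intersect(focalCladeSp, outgroupSpecies)) > 0,
          "focal and outgroup sets must be disjoint")
  m <- alnMatrix(alignment)
  stop_if(!all(c(focalCladeSp, outgroupSpecies) %in% rownames(m)),
          "focal/outgroup species missing from alignment")
  counts <- c(within_outgroups = 0L, at_focal_position = 0L, elsewhere = 0L)
  failed <- 0L
  if (nReplicas < 1)
    return(list(counts = counts, nReplicas = 0L, failed = 0L))
  nonfocal <- setdiff(rownames(m), focalCladeSp)
  ref <- sort(setdiff(nonfocal, outgroupSpecies))[1]
  stop_if(is.na(ref), "need a non-focal, non-outgroup reference species")
  seeds <- with_seed(seed, sample.int(.Machine$integer.max, nReplicas))
  for (r in seq_len(nReplicas)) {
    rep_aln <- randomizeCladeSequences(alignment, focalCladeSp, mode,
                                       seed = seeds[r])
    tr <- tryCatch(treeBuilder(rep_aln), error = function(e) NULL)
    if (is.null(tr)) { failed <- failed + 1L; next }
    side <- focal_attachment_side(tr, focalCladeSp, ref)
    lab <- classify_attachment(side, nonfocal, outgroupSpecies,
                               focalPositionSpec)
    counts[lab] <- counts[lab] + 1L
  }
  list(counts = counts, nReplicas = nReplicas - failed, failed = failed)
}

# Classify an attachment bipartition side against the outgroup subtree and
# the named focal-position edge. The focal-position edge takes precedence;
# within_outgroups covers attachments strictly inside the outgroup subtree
# and on its stem.
classify_attachment <- function(side, nonfocal, outgroupSpecies,
                                focalPositionSpec) {
  if (is.null(side)) return("elsewhere")
  other <- setdiff(nonfocal, side)
  spec <- intersect(focalPositionSpec, nonfocal)
  if (setequal(side, spec) || setequal(other, spec)) return("at_focal_position")
  og <- intersect(outgroupSpecies, nonfocal)
  inside_og <- function(s) length(s) > 0 && all(s %in% og)
  if (inside_og(side) || inside_og(other)) return("within_outgroups")
  "elsewhere"
}

#' Parametric simulation test for long-branch attraction
#'
#' Simulates \code{nFamilies} alignments on a known species tree in which
#' the focal clade is placed at a stated position, concatenates them,
#' rebuilds a tree, roots it on the most distant outgroup and classifies the
#' focal clade's placement. If the inference machinery were dominated by
#' long-branch attraction, the recovered placement would drift away from the
#' planted one.
#'
#' @param knownTree a \code{\linkS4class{SpeciesTree}} with the focal clade
#'   at the hypothesized position.
#' @param nFamilies number of simulated families (>= 1).
#' @param familyLength columns per family.
#' @param gammaShape,nCategories rate-heterogeneity parameters passed to
#'   \code{\link{simAlignment}}.
#' @param treeBuilder function(alignment) -> \code{phylo}.
#' @param focalGroup,outgroupLabel group labels.
#' @param seed integer seed.
#' @return list with \code{tree} (inferred, rooted), \code{label} (recovered
#'   placement), \code{plantedLabel} and \code{recovered}.
#' @export
parametricLBATest <- function(knownTree, nFamilies, familyLength = 300L,
                              gammaShape = 1, nCategories = 4L,
                              treeBuilder = buildNJTree,
                              focalGroup = "Microsporidia",
                              outgroupLabel = "Outgroup", seed = NULL) {
  stop_if(nFamilies < 1, "nFamilies must be >= 1")
  groups <- groupMap(knownTree)
  og_species <- names(groups)[groups == outgroupLabel]
  planted <- classifySisterGroup(asPhylo(knownTree), focalGroup, groups,
                                 speciesMap = setNames(names(groups), names(groups)),
                                 outgroupLabel = outgroupLabel)
  seeds <- with_seed(seed, sample.int(.Machine$integer.max, nFamilies))
  fams <- lapply(seq_len(nFamilies), function(i)
    simAlignment(knownTree, familyLength, gammaShape, nCategories,
                 seed = seeds[i])$alignment)
  names(fams) <- sprintf("fam%03d", seq_len(nFamilies))
  concat <- concatenateAlignments(fams, speciesNames(knownTree))
  inferred <- treeBuilder(concat)
  idmap <- setNames(inferred$tip.label, inferred$tip.label)
  rooted <- rootByMostDistantOutgroup(inferred, og_species, speciesMap = idmap)
  label <- classifySisterGroup(rooted, focalGroup, groups, speciesMap = idmap,
                               outgroupLabel = outgroupLabel)
  list(tree = rooted, label = label, plantedLabel = planted,
       recovered = identical(label, planted))
}
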