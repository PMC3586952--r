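## Gene-tree scanning: outgroup rooting, species-overlap event labeling,
## sister-group classification into the scenario vocabulary, record filters
## and the phylome-wide census.

# Scenario vocabulary: single-group letters plus the composite placements.
GROUP_LETTERS <- c(Chytridiomycotina = "C", Zygomycotina = "Z",
                   Basidiomycotina = "B", Taphrinomycotina = "T",
                   Saccharomycotina = "S", Pezizomycotina = "P")

#' All scenario labels used by the census
#' @return character vector of labels.
#' @export
scenarioLabels <- function() {
  c("A", "C", "Z", "B", "T", "S", "P", "S+P", "T+S+P", "B+T+S+P",
    "B+T+S+P+Z", "A-C+Z", "other", "non_monophyletic_outgroup",
    "non_monophyletic_focal")
}

# Resolve species for gene-tree tip labels: a named map wins, otherwise the
# "<species>__g<k>" convention.
resolve_species <- function(labels, speciesMap = NULL) {
  if (is.null(speciesMap)) return(leafSpecies(labels))
  sp <- unname(speciesMap[labels])
  if (anyNA(sp)) stop("unmapped leaves: ",
                      paste(labels[is.na(sp)], collapse = ","), call. = FALSE)
  sp
}

#' Root a gene tree on its most distant outgroup sequence
#'
#' Chooses the outgroup leaf with the greatest mean path length (sum of
#' branch lengths; unit lengths when absent) to the non-outgroup leaves and
#' places the root on that leaf's terminal branch. Ties break by
#' lexicographic leaf name. Support values in node labels are treated as
#' edge annotations and follow their edges through the re-rooting, so the
#' unrooted topology is unchanged.
#'
#' @param tree a \code{phylo}.
#' @param outgroupSpecies character vector of outgroup species names.
#' @param speciesMap optional named character vector tip label -> species.
#' @return a rooted \code{phylo}.
#' @export
rootByMostDistantOutgroup <- function(tree, outgroupSpecies, speciesMap = NULL) {
  sp <- resolve_species(tree$tip.label, speciesMap)
  og <- which(sp %in% outgroupSpecies)
  stop_if(length(og) == 0L, "no outgroup leaf present")
  tr <- tree
  if (is.null(tr$edge.length)) tr$edge.length <- rep(1, nrow(tr$edge))
  d <- ape::cophenetic.phylo(tr)
  ing <- setdiff(seq_along(sp), og)
  score <- if (length(ing)) rowMeans(d[tree$tip.label[og], tree$tip.label[ing],
                                       drop = FALSE])
           else setNames(rep(0, length(og)), tree$tip.label[og])
  best <- names(score)[order(-score, names(score))][1]
  has_lab <- !is.null(tree$node.label)
  rooted <- ape::root(tree, outgroup = best, resolve.root = TRUE,
                      edgelabel = has_lab)
  rooted
}

#' Is the outgroup monophyletic?
#'
#' Monophyly is assessed as an unrooted split, so a tree rooted on one of
#' the outgroup leaves still counts as outgroup-monophyletic when all
#' outgroup sequences fall on one side: the outgroup leaves, or equivalently
#' their complement, must form a clade.
#'
#' @param tree rooted \code{phylo}.
#' @param outgroupSpecies character vector of outgroup species.
#' @param speciesMap optional tip -> species map.
#' @return TRUE iff the outgroup leaves form one partition of the tree.
#' @export
isOutgroupMonophyletic <- function(tree, outgroupSpecies, speciesMap = NULL) {
  sp <- resolve_species(tree$tip.label, speciesMap)
  og <- tree$tip.label[sp %in% outgroupSpecies]
  ing <- setdiff(tree$tip.label, og)
  if (length(og) <= 1L || length(ing) <= 1L) return(TRUE)
  ape::is.monophyletic(tree, og) || ape::is.monophyletic(tree, ing)
}

#' Label duplication/speciation events by species overlap
#'
#' For every internal node of a rooted binary tree with child species sets
#' L and R, the overlap score is |L intersect R| / |L union R|; the node is
#' a duplication iff the score exceeds \code{threshold} (default 0), else a
#' speciation. Polytomies are resolved arbitrarily with zero-length branches
#' and flagged.
#'
#' @param tree rooted \code{phylo}.
#' @param speciesMap optional tip -> species map.
#' @param threshold species-overlap score above which a node is a
#'   duplication.
#' @return list: \code{tree} (binary version), \code{events} (data.frame
#'   node, score, event in {"S","D"}), \code{hadPolytomies} (logical).
#' @export
labelSpeciesOverlapEvents <- function(tree, speciesMap = NULL, threshold = 0) {
  had_poly <- !ape::is.binary.phylo(tree)
  if (had_poly) tree <- ape::multi2di(tree, random = FALSE)
  sp <- resolve_species(tree$tip.label, speciesMap)
  n_tip <- length(tree$tip.label)
  kids <- phylo_children(tree)
  sets <- vector("list", max(tree$edge))
  for (i in seq_len(n_tip)) sets[[i]] <- sp[i]
  ord <- ape::reorder.phylo(tree, "postorder")$edge
  internal <- unique(ord[, 1])
  for (i in seq_len(nrow(ord))) {
    p <- ord[i, 1]
    sets[[p]] <- unique(c(sets[[p]], sets[[ord[i, 2]]]))
  }
  score <- vapply(internal, function(nd) {
    ch <- kids[[nd]]
    L <- sets[[ch[1]]]; R <- sets[[ch[2]]]
    length(intersect(L, R)) / length(union(L, R))
  }, 1.0)
  list(tree = tree,
       events = data.frame(node = internal, score = score,
                           event = ifelse(score > threshold, "D", "S")),
       hadPolytomies = had_poly)
}

# Internal: focal clade node and sister tip labels for a rooted tree.
# Returns NULL if the focal leaves are not monophyletic.
focal_clade_info <- function(tree, focalGroup, groupMapVec, speciesMap = NULL) {
  sp <- resolve_species(tree$tip.label, speciesMap)
  grp <- unname(groupMapVec[sp])
  focal_tips <- which(grp == focalGroup)
  if (length(focal_tips) == 0L) return(NULL)
  n_tip <- length(tree$tip.label)
  node <- if (length(focal_tips) == 1L) focal_tips
    else ape::getMRCA(tree, focal_tips)
  sets <- node_tip_sets(tree)
  if (length(sets[[node]]) != length(focal_tips)) {
    return(list(monophyletic = FALSE))
  }
  root <- n_tip + 1L
  if (node == root) return(list(monophyletic = FALSE))
  parent <- tree$edge[match(node, tree$edge[, 2]), 1]
  sibs <- setdiff(phylo_children(tree)[[parent]], node)
  sister_tips <- unlist(sets[sibs])
  list(monophyletic = TRUE, node = node, parent = parent,
       sisterTips = sister_tips, species = sp, groups = grp)
}

#' Classify the sister group of a focal clade
#'
#' The rooted tree's focal-group leaves must be monophyletic (otherwise
#' \code{"non_monophyletic_focal"} is returned). The set of groups in the
#' sister partition maps to the scenario vocabulary: one group gives that
#' group's letter; the composite sets S+P, T+S+P, B+T+S+P and B+T+S+P+Z
#' give their labels; all six non-focal fungal groups give \code{"A"} -
#' unless Chytridiomycotina and Zygomycotina form an exclusive clade inside
#' the sister partition, which gives \code{"A-C+Z"} (as does a sister of
#' exactly those two groups); anything else, including sisters containing
#' outgroup sequences, is \code{"other"}.
#'
#' @param tree rooted \code{phylo} containing at least one leaf of every
#'   predefined (non-focal, non-outgroup) group.
#' @param focalGroup focal group label (e.g. \code{"Microsporidia"}).
#' @param groupMapVec named character vector species -> group.
#' @param speciesMap optional tip -> species map.
#' @param outgroupLabel group label of the outgroup (default
#'   \code{"Outgroup"}).
#' @return a single scenario label.
#' @export
classifySisterGroup <- function(tree, focalGroup, groupMapVec, speciesMap = NULL,
                                outgroupLabel = "Outgroup") {
  predefined <- setdiff(unique(unname(groupMapVec)), c(focalGroup, outgroupLabel))
  sp <- resolve_species(tree$tip.label, speciesMap)
  grp <- unname(groupMapVec[sp])
  missing <- setdiff(predefined, grp)
  stop_if(length(missing) > 0,
          paste("missing group representative:", paste(missing, collapse = ",")))
  info <- focal_clade_info(tree, focalGroup, groupMapVec, speciesMap)
  stop_if(is.null(info), "no focal leaves in tree")
  if (!info$monophyletic) return("non_monophyletic_focal")
  sister_groups <- sort(unique(info$groups[match(info$sisterTips,
                                                 tree$tip.label)]))
  if (outgroupLabel %in% sister_groups) return("other")
  letters <- sort(unname(GROUP_LETTERS[sister_groups]))
  if (anyNA(letters)) return("other")
  key <- paste(letters, collapse = "")
  if (length(letters) == 1L) return(letters)
  composite <- c(PS = "S+P", PST = "T+S+P", BPST = "B+T+S+P",
                 BPSTZ = "B+T+S+P+Z", CZ = "A-C+Z")
  if (key %in% names(composite)) return(unname(composite[key]))
  if (setequal(letters, c("C", "Z", "B", "T", "S", "P"))) {
    if (cz_exclusive_clade(tree, info, groupMapVec)) return("A-C+Z")
    return("A")
  }
  "other"
}

# TRUE iff the C and Z leaves of the sister partition form an exclusive
# clade somewhere in the tree.
cz_exclusive_clade <- function(tree, info, groupMapVec) {
  cz_groups <- names(GROUP_LETTERS)[GROUP_LETTERS %in% c("C", "Z")]
  idx <- match(info$sisterTips, tree$tip.label)
  cz_tips <- info$sisterTips[info$groups[idx] %in% cz_groups]
  if (length(cz_tips) < 2L) return(FALSE)
  sets <- node_tip_sets(tree)
  any(vapply(sets, function(s) setequal(s, cz_tips), TRUE))
}

#' Support value on the focal clade's parental node
#'
#' The branch support attached to the edge subtending the parent of the
#' focal clade, read from the rooted tree's node labels. When the parent is
#' the root (which has no subtending edge) the focal clade's own support is
#' used.
#'
#' @inheritParams classifySisterGroup
#' @return numeric support, or \code{NA} when no labels are present.
#' @export
focalParentSupport <- function(tree, focalGroup, groupMapVec, speciesMap = NULL) {
  if (is.null(tree$node.label)) return(NA_real_)
  info <- focal_clade_info(tree, focalGroup, groupMapVec, speciesMap)
  if (is.null(info) || !info$monophyletic) return(NA_real_)
  n_tip <- length(tree$tip.label)
  node <- if (info$parent == n_tip + 1L) info$node else info$parent
  if (node <= n_tip) return(NA_real_)
  suppressWarnings(as.numeric(tree$node.label[node - n_tip]))
}

#' Evaluate the census quality filters on one record
#'
#' Strict inequalities throughout: branch support of the focal clade's
#' parental node higher than \code{supportMin}, consistency score over
#' \code{consistencyMin}, alignment length larger than \code{lengthMin}.
#'
#' @param record a \code{\linkS4class{PhylomeRecord}} whose tree is rooted.
#' @inheritParams classifySisterGroup
#' @param supportMin,consistencyMin,lengthMin filter thresholds.
#' @return named logical vector: support, consistency, length, all.
#' @export
applyRecordFilters <- function(record, focalGroup, groupMapVec,
                               speciesMap = NULL, supportMin = 0.8,
                               consistencyMin = 0.75, lengthMin = 500) {
  supp <- focalParentSupport(record@tree, focalGroup, groupMapVec, speciesMap)
  f <- c(support = isTRUE(supp > supportMin),
         consistency = record@consistencyScore > consistencyMin,
         length = record@alignmentLength > lengthMin)
  c(f, all = all(f))
}

#' Phylome-wide scenario census
#'
#' For each record: roots the tree on the most distant outgroup, requires
#' every predefined group present (records failing this are dropped), labels
#' outgroup non-monophyly, classifies the focal sister group, and tallies
#' scenarios overall and under each quality filter plus their conjunction.
#'
#' @param records list of \code{\linkS4class{PhylomeRecord}}.
#' @param focalGroup focal group label.
#' @param groupMapVec named character vector species -> group.
#' @param speciesMap optional tip -> species map.
#' @param outgroupLabel outgroup group label.
#' @param supportMin,consistencyMin,lengthMin filter thresholds.
#' @return list with \code{table} (long data.frame: scenario, filter, count,
#'   fraction - fractions sum to 1 within each filter) and \code{nEligible}
#'   (records with all groups present).
#' @export
scenarioCensus <- function(records, focalGroup, groupMapVec, speciesMap = NULL,
                           outgroupLabel = "Outgroup", supportMin = 0.8,
                           consistencyMin = 0.75, lengthMin = 500) {
  stop_if(length(records) == 0L, "no records")
  outgroup_species <- names(groupMapVec)[groupMapVec == outgroupLabel]
  predefined <- setdiff(unique(unname(groupMapVec)), c(focalGroup, outgroupLabel))
  filters <- c("none", "support", "consistency", "length", "all")
  rows <- lapply(records, function(rec) {
    tr <- rec@tree
    sp <- tryCatch(resolve_species(tr$tip.label, speciesMap), error = function(e) NULL)
    if (is.null(sp)) return(NULL)
    grp <- unname(groupMapVec[sp])
    if (!all(predefined %in% grp) || !(focalGroup %in% grp) ||
        !any(sp %in% outgroup_species)) return(NULL)
    tr <- rootByMostDistantOutgroup(tr, outgroup_species, speciesMap)
    scen <- if (!isOutgroupMonophyletic(tr, outgroup_species, speciesMap))
      "non_monophyletic_outgroup"
    else classifySisterGroup(tr, focalGroup, groupMapVec, speciesMap, outgroupLabel)
    rec2 <- rec; rec2@tree <- tr
    f <- applyRecordFilters(rec2, focalGroup, groupMapVec, speciesMap,
                            supportMin, consistencyMin, lengthMin)
    data.frame(scenario = scen, none = TRUE, support = f[["support"]],
               consistency = f[["consistency"]], length = f[["length"]],
               all = f[["all"]], stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(rows) || nrow(rows) == 0L) {
    warning("no eligible record")
    return(list(table = data.frame(scenario = character(), filter = character(),
                                   count = integer(), fraction = numeric()),
                nEligible = 0L))
  }
  tab <- do.call(rbind, lapply(filters, function(f) {
    sub <- rows[rows[[f]], , drop = FALSE]
    counts <- table(factor(sub$scenario, levels = scenarioLabels()))
    data.frame(scenario = names(counts), filter = f,
               count = as.integer(counts),
               fraction = if (nrow(sub)) as.integer(counts) / nrow(sub) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(table = tab, nEligible = nrow(rows))
}

#' Write a census table
#' @param census result of \code{\link{scenarioCensus}}.
#' @param path file path.
#' @export
writeCensus <- function(census, path) {
  utils::write.table(census$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read phylome records from a metadata table plus Newick files
#'
#' Metadata TSV columns: tree_id, newick_file (relative to \code{dir}),
#' alignment_length, consistency_score, optional seed_gene.
#' @param metaPath metadata TSV path.
#' @param dir directory for tree files (default: metadata's directory).
#' @return list of \code{\linkS4class{PhylomeRecord}}.
#' @export
readPhylomeRecords <- function(metaPath, dir = dirname(metaPath)) {
  meta <- utils::read.delim(metaPath, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(meta)), function(i) {
    tr <- ape::read.tree(file.path(dir, meta$newick_file[i]))
    PhylomeRecord(tr, meta$alignment_length[i], meta$consistency_score[i],
                  seedGene = if ("seed_gene" %in% names(meta)) meta$seed_gene[i]
                             else NA_character_,
                  treeId = meta$tree_id[i])
  })
}
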