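## Gene-tree / species-tree reconciliation by LCA mapping and search for the
## species tree minimizing the total number of implied duplications.
##
## Species sets are encoded as bitmasks over the sorted species list (<= 30
## species), which makes the LCA mapping a minimal-superset lookup over the
## species tree's clades and lets one scoring pass handle hundreds of gene
## trees against hundreds of candidate topologies.

# Bitmask clade list of a rooted phylo: one mask per node (tips + internal),
# relative to `species` (sorted character vector).
phylo_clade_masks <- function(tree, species) {
  stop_if(length(species) > 30, "bitmask reconciliation supports <= 30 species")
  bit <- setNames(2^(seq_along(species) - 1), species)
  n_tip <- length(tree$tip.label)
  masks <- numeric(max(tree$edge))
  masks[seq_len(n_tip)] <- bit[tree$tip.label]
  ord <- ape::reorder.phylo(tree, "postorder")$edge
  for (i in seq_len(nrow(ord)))
    masks[ord[i, 1]] <- bitwOr(masks[ord[i, 1]], masks[ord[i, 2]])
  masks
}

# Internal-node mask triples (self, child1, child2) of a rooted binary gene
# tree, with species resolved via resolve_species().
gene_node_masks <- function(tree, species, speciesMap = NULL) {
  sp <- resolve_species(tree$tip.label, speciesMap)
  stop_if(!all(sp %in% species),
          paste("unknown species:", paste(setdiff(sp, species), collapse = ",")))
  bit <- setNames(2^(seq_along(species) - 1), species)
  n_tip <- length(tree$tip.label)
  masks <- numeric(max(tree$edge))
  masks[seq_len(n_tip)] <- bit[sp]
  ord <- ape::reorder.phylo(tree, "postorder")$edge
  for (i in seq_len(nrow(ord)))
    masks[ord[i, 1]] <- bitwOr(masks[ord[i, 1]], masks[ord[i, 2]])
  kids <- phylo_children(tree)
  internal <- (n_tip + 1L):max(tree$edge)
  cbind(node = internal,
        m = masks[internal],
        c1 = vapply(internal, function(nd) masks[kids[[nd]][1]], 1),
        c2 = vapply(internal, function(nd) masks[kids[[nd]][2]], 1))
}

# Minimal-superset lookup: for each query mask, the index (into `clades`) of
# the smallest clade containing it. `clades` must be sorted by popcount.
min_superset <- function(queries, clades) {
  vapply(queries, function(q) {
    for (i in seq_along(clades))
      if (bitwAnd(q, bitwNot(clades[i])) == 0) return(i)
    NA_integer_
  }, 1L)
}

popcount <- function(x) vapply(x, function(v) sum(bitwAnd(v, 2^(0:29)) > 0), 1.0)

#' LCA reconciliation of a gene tree against a species tree
#'
#' Maps every gene-tree node to the species-tree LCA of its descendant
#' species; an internal node is a duplication iff it maps to the same
#' species-tree node as at least one of its children.
#'
#' @param geneTree rooted binary \code{phylo}; tip species via
#'   \code{speciesMap} or the \code{"<species>__g<k>"} convention.
#' @param speciesTree a \code{\linkS4class{SpeciesTree}} or rooted
#'   \code{phylo} containing every gene-tree species.
#' @param speciesMap optional tip -> species map.
#' @return list with \code{nodeMap} (data.frame: gene node, species node,
#'   isDuplication) and \code{duplicationCount}.
#' @export
countDuplications <- function(geneTree, speciesTree, speciesMap = NULL) {
  sptr <- asPhylo(speciesTree)
  species <- sort(sptr$tip.label)
  sp_masks <- phylo_clade_masks(sptr, species)
  ord <- order(popcount(sp_masks))
  nodes <- gene_node_masks(geneTree, species, speciesMap)
  qmap <- min_superset(c(nodes[, "m"], nodes[, "c1"], nodes[, "c2"]),
                       sp_masks[ord])
  k <- nrow(nodes)
  map_m <- qmap[seq_len(k)]
  map_c1 <- qmap[k + seq_len(k)]
  map_c2 <- qmap[2L * k + seq_len(k)]
  is_dup <- map_m == map_c1 | map_m == map_c2
  list(nodeMap = data.frame(geneNode = nodes[, "node"],
                            speciesNode = ord[map_m],
                            isDuplication = is_dup),
       duplicationCount = sum(is_dup))
}

# Enumerate all rooted binary topologies on `labels` as nested lists
# (leaf = label index). (2n-3)!! trees.
enumerate_rooted <- function(n) {
  trees <- list(1L)
  for (taxon in 2:n) {
    nxt <- list()
    for (tr in trees) nxt <- c(nxt, attach_everywhere(tr, taxon))
    trees <- nxt
  }
  trees
}

# All ways to attach `leaf` onto tree `tr`: on every edge plus above the root.
attach_everywhere <- function(tr, leaf) {
  res <- list(list(tr, leaf)) # new root
  if (!is.list(tr)) return(res)
  for (side in 1:2) {
    for (sub in attach_everywhere(tr[[side]], leaf)) {
      t2 <- tr
      t2[[side]] <- sub
      res <- c(res, list(t2))
    }
  }
  res
}

# Clade masks of a nested-list tree (indices are species indices).
nested_clades <- function(tr) {
  rec <- function(node) {
    if (!is.list(node)) return(list(mask = 2^(node - 1), clades = 2^(node - 1)))
    l <- rec(node[[1]]); r <- rec(node[[2]])
    m <- l$mask + r$mask
    list(mask = m, clades = c(l$clades, r$clades, m))
  }
  rec(tr)$clades
}

# Canonical Newick of a nested-list tree: children ordered by smallest
# descendant label, matching canonical_newick() on phylo objects.
nested_newick <- function(tr, labels) {
  rec <- function(node) {
    if (!is.list(node)) return(list(str = labels[node], min = labels[node]))
    l <- rec(node[[1]]); r <- rec(node[[2]])
    if (r$min < l$min) { tmp <- l; l <- r; r <- tmp }
    list(str = paste0("(", l$str, ",", r$str, ")"), min = l$min)
  }
  paste0(rec(tr)$str, ";")
}

# Total duplications implied by `geneNodes` (rbind of gene_node_masks over
# all gene trees) on the topology whose clade masks are `clades`.
score_topology <- function(geneNodes, clades) {
  make_dup_scorer(geneNodes)(clades)
}

# Closure that scores candidate topologies against a fixed set of gene-tree
# node masks; the unique-mask bookkeeping is done once so repeated calls
# (hill-climbing, enumeration) stay cheap.
make_dup_scorer <- function(geneNodes) {
  U <- sort(unique(c(geneNodes[, "m"], geneNodes[, "c1"], geneNodes[, "c2"])))
  mi <- match(geneNodes[, "m"], U)
  c1i <- match(geneNodes[, "c1"], U)
  c2i <- match(geneNodes[, "c2"], U)
  nU <- length(U)
  function(clades) {
    ordc <- clades[order(popcount(clades))]
    nC <- length(ordc)
    contain <- outer(U, ordc, function(q, cl) bitwAnd(q, bitwNot(cl)) == 0)
    # first TRUE per row = minimal containing clade (columns sorted by size)
    mapU <- max.col(contain * rep(rev(seq_len(nC)), each = nU),
                    ties.method = "first")
    sum(mapU[mi] == mapU[c1i] | mapU[mi] == mapU[c2i])
  }
}

# Score every topology at once. `cladeMat` is nTopologies x nClades with
# each row's clade masks sorted by popcount. Returns a score vector.
score_topologies_batch <- function(geneNodes, cladeMat) {
  U <- sort(unique(c(geneNodes[, "m"], geneNodes[, "c1"], geneNodes[, "c2"])))
  mi <- match(geneNodes[, "m"], U)
  c1i <- match(geneNodes[, "c1"], U)
  c2i <- match(geneNodes[, "c2"], U)
  nU <- length(U); nT <- nrow(cladeMat); nC <- ncol(cladeMat)
  contain <- matrix(FALSE, nT * nU, nC)   # row (t-1)*nU + u
  qs <- rep(U, times = nT)
  for (j in seq_len(nC))
    contain[, j] <- bitwAnd(qs, bitwNot(rep(cladeMat[, j], each = nU))) == 0
  mapIdx <- max.col(contain * rep(rev(seq_len(nC)), each = nT * nU),
                    ties.method = "first")
  mapIdx <- matrix(mapIdx, nU, nT)
  A <- mapIdx[mi, , drop = FALSE]
  dup <- (A == mapIdx[c1i, , drop = FALSE]) | (A == mapIdx[c2i, , drop = FALSE])
  colSums(dup)
}

# Rooted-NNI neighbors of a nested-list tree: for every internal node with
# children (A, B) and internal child, the two swaps across that edge.
nni_neighbors <- function(tr) {
  res <- list()
  set_at <- function(node, p, newnode) {
    if (length(p) == 0L) return(newnode)
    node[[p[1]]] <- set_at(node[[p[1]]], p[-1], newnode)
    node
  }
  rec <- function(node, path) {
    if (!is.list(node)) return(invisible(NULL))
    A <- node[[1]]; B <- node[[2]]
    if (is.list(A)) {
      res[[length(res) + 1L]] <<- set_at(tr, path, list(list(A[[1]], B), A[[2]]))
      res[[length(res) + 1L]] <<- set_at(tr, path, list(list(A[[2]], B), A[[1]]))
    }
    if (is.list(B)) {
      res[[length(res) + 1L]] <<- set_at(tr, path, list(list(B[[1]], A), B[[2]]))
      res[[length(res) + 1L]] <<- set_at(tr, path, list(list(B[[2]], A), B[[1]]))
    }
    rec(A, c(path, 1L))
    rec(B, c(path, 2L))
  }
  rec(tr, integer())
  res
}

# Random rooted topology by sequential random attachment.
random_rooted <- function(n) {
  tr <- 1L
  for (taxon in 2:n) {
    opts <- attach_everywhere(tr, taxon)
    tr <- opts[[sample.int(length(opts), 1L)]]
  }
  tr
}

#' Search for the species tree minimizing total duplications
#'
#' Scores candidate rooted species topologies by the summed LCA-implied
#' duplication count over all gene trees. \code{"exhaustive"} enumerates all
#' rooted topologies (allowed up to 8 species) and returns the global
#' minimum, ties broken by lexicographically smallest canonical Newick;
#' \code{"nni_hillclimb"} starts from random topologies and applies rooted
#' nearest-neighbor interchanges until no neighbor improves, over
#' \code{restarts} restarts.
#'
#' @param geneTrees list of rooted binary \code{phylo} gene trees.
#' @param strategy \code{"exhaustive"} or \code{"nni_hillclimb"}.
#' @param restarts hill-climbing restarts.
#' @param speciesMap optional tip -> species map.
#' @param seed integer seed (hill-climbing starts).
#' @return list with \code{tree} (rooted \code{phylo}), \code{newick}
#'   (canonical form), \code{totalDuplications}, and for the exhaustive
#'   strategy \code{scores} (per-topology totals).
#' @export
searchMinDupSupertree <- function(geneTrees,
                                  strategy = c("exhaustive", "nni_hillclimb"),
                                  restarts = 50L, speciesMap = NULL,
                                  seed = NULL) {
  strategy <- match.arg(strategy)
  geneTrees <- geneTrees[!vapply(geneTrees, is.null, TRUE)]
  stop_if(length(geneTrees) == 0L, "need at least one gene tree")
  species <- sort(unique(unlist(lapply(geneTrees, function(tr)
    resolve_species(tr$tip.label, speciesMap)))))
  n <- length(species)
  geneNodes <- do.call(rbind, lapply(geneTrees, gene_node_masks,
                                     species = species, speciesMap = speciesMap))
  if (strategy == "exhaustive") {
    stop_if(n > 8, "exhaustive search supports at most 8 species")
    stop_if(n < 2, "need at least 2 species")
    topos <- enumerate_rooted(n)
    cladeMat <- do.call(rbind, lapply(topos, function(tr) {
      cl <- nested_clades(tr)
      cl[order(popcount(cl))]
    }))
    scores <- score_topologies_batch(geneNodes, cladeMat)
    best <- which(scores == min(scores))
    nwks <- vapply(topos[best], nested_newick, "", labels = species)
    pick <- best[order(nwks)[1]]
    out_tree <- ape::read.tree(text = nested_newick(topos[[pick]], species))
    list(tree = out_tree, newick = nested_newick(topos[[pick]], species),
         totalDuplications = scores[pick], scores = scores)
  } else {
    with_seed(seed, {
      scorer <- make_dup_scorer(geneNodes)
      best_tr <- NULL; best_score <- Inf
      for (r in seq_len(restarts)) {
        tr <- random_rooted(n)
        sc <- scorer(nested_clades(tr))
        repeat {
          nb <- nni_neighbors(tr)
          nb_sc <- vapply(nb, function(x) scorer(nested_clades(x)), 1)
          if (!length(nb_sc) || min(nb_sc) >= sc) break
          i <- which.min(nb_sc)
          tr <- nb[[i]]; sc <- nb_sc[i]
        }
        nwk <- nested_newick(tr, species)
        if (sc < best_score ||
            (sc == best_score && nwk < nested_newick(best_tr, species))) {
          best_tr <- tr; best_score <- sc
        }
      }
      list(tree = ape::read.tree(text = nested_newick(best_tr, species)),
           newick = nested_newick(best_tr, species),
           totalDuplications = best_score)
    })
  }
}
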