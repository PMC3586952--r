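#' @import methods
#' @importFrom stats setNames
NULL

setOldClass("phylo")

#' SpeciesTree: a rooted species tree with group annotations
#'
#' A rooted, binary, leaf-labeled species tree (an \code{ape} \code{phylo}
#' with branch lengths) together with a map from species to taxonomic group
#' (e.g. \code{"Microsporidia"}, \code{"Chytridiomycotina"}, ...,
#' \code{"Outgroup"}). The group map drives sister-group classification,
#' hypothesis generation and the census.
#'
#' @slot tree a rooted \code{phylo} object with unique tip labels.
#' @slot groups named character vector: names are species (tip labels),
#'   values are group labels. Every tip must be present exactly once.
#' @export
setClass("SpeciesTree", representation(tree = "phylo", groups = "character"))

setValidity("SpeciesTree", function(object) {
  tr <- object@tree
  if (is.null(tr$tip.label) || anyDuplicated(tr$tip.label))
    return("tip labels must be present and unique")
  if (!ape::is.rooted(tr)) return("species tree must be rooted")
  if (!is.null(tr$edge.length) && any(tr$edge.length < 0))
    return("branch lengths must be >= 0")
  miss <- setdiff(tr$tip.label, names(object@groups))
  if (length(miss)) return(paste("species without group:", paste(miss, collapse = ",")))
  TRUE
})

#' Construct a SpeciesTree
#'
#' @param tree rooted \code{phylo}.
#' @param groups named character vector mapping species to group labels; if
#'   missing, all species are assigned group \code{"Ingroup"}.
#' @return a \code{SpeciesTree} object.
#' @export
SpeciesTree <- function(tree, groups = NULL) {
  if (is.null(groups))
    groups <- setNames(rep("Ingroup", length(tree$tip.label)), tree$tip.label)
  new("SpeciesTree", tree = tree, groups = groups[tree$tip.label])
}

#' @describeIn SpeciesTree-class underlying \code{phylo} object
#' @param x a \code{SpeciesTree}
#' @export
asPhylo <- function(x) {
  if (is(x, "SpeciesTree")) x@tree else if (inherits(x, "phylo")) x
  else stop("cannot extract a phylo from class ", class(x))
}

#' Group map accessor
#' @param x a \code{SpeciesTree}
#' @return named character vector species -> group
#' @export
groupMap <- function(x) x@groups

#' Species names accessor
#' @param x a \code{SpeciesTree}
#' @export
speciesNames <- function(x) x@tree$tip.label

setMethod("show", "SpeciesTree", function(object) {
  cat("SpeciesTree with", length(object@tree$tip.label), "species in",
      length(unique(object@groups)), "groups\n")
  tab <- table(object@groups)
  cat(paste0("  ", names(tab), ": ", as.integer(tab), collapse = "\n"), "\n")
})

#' GeneOrderGenome: ordered, stranded genes on contigs
#'
#' Container for a genome's gene order. Each gene carries a contig, a 0-based
#' index along its contig, a strand, a family id (homology class) and an
#' optional ortholog id (lineage of descent without duplication; \code{NA}
#' for duplicated or gained copies).
#'
#' @slot genomeId single identifier string.
#' @slot genes \code{data.frame} with columns \code{gene_id}, \code{contig},
#'   \code{index}, \code{strand}, \code{family_id}, \code{ortholog_id}.
#' @export
setClass("GeneOrderGenome", representation(genomeId = "character", genes = "data.frame"))

setValidity("GeneOrderGenome", function(object) {
  g <- object@genes
  need <- c("gene_id", "contig", "index", "strand", "family_id", "ortholog_id")
  if (!all(need %in% names(g))) return("missing gene table columns")
  if (anyDuplicated(g$gene_id)) return("gene ids must be unique within a genome")
  if (!all(g$strand %in% c("+", "-"))) return("strand must be '+' or '-'")
  for (ct in unique(g$contig)) {
    idx <- sort(g$index[g$contig == ct])
    if (!identical(as.integer(idx), seq_along(idx) - 1L))
      return(sprintf("indices on contig %s must be consecutive from 0", ct))
  }
  TRUE
})

#' Construct a GeneOrderGenome
#' @param genomeId identifier string.
#' @param genes gene table (see \code{\linkS4class{GeneOrderGenome}}).
#' @export
GeneOrderGenome <- function(genomeId, genes) {
  genes <- genes[order(genes$contig, genes$index), , drop = FALSE]
  rownames(genes) <- NULL
  genes$index <- as.integer(genes$index)
  new("GeneOrderGenome", genomeId = as.character(genomeId), genes = genes)
}

#' Gene table accessor
#' @param x a \code{GeneOrderGenome}
#' @export
geneTable <- function(x) x@genes

#' Genome id accessor
#' @param x a \code{GeneOrderGenome}
#' @export
genomeId <- function(x) x@genomeId

setMethod("show", "GeneOrderGenome", function(object) {
  cat("GeneOrderGenome", object@genomeId, "-", nrow(object@genes), "genes on",
      length(unique(object@genes$contig)), "contig(s),",
      length(unique(object@genes$family_id)), "families\n")
})

#' PhylomeRecord: one gene tree plus its metadata
#'
#' Bundles a gene tree with the alignment metadata used by the census
#' filters: alignment length (columns), alignment consistency score and the
#' seed gene the tree was built for.
#'
#' @slot tree a \code{phylo}; node labels, when present, hold branch supports
#'   in [0,1].
#' @slot alignmentLength integer >= 1.
#' @slot consistencyScore numeric in [0,1].
#' @slot seedGene character.
#' @slot treeId character.
#' @export
setClass("PhylomeRecord", representation(
  tree = "phylo", alignmentLength = "numeric", consistencyScore = "numeric",
  seedGene = "character", treeId = "character"))

setValidity("PhylomeRecord", function(object) {
  if (object@alignmentLength < 1) return("alignmentLength must be >= 1")
  if (object@consistencyScore < 0 || object@consistencyScore > 1)
    return("consistencyScore must lie in [0,1]")
  TRUE
})

#' Construct a PhylomeRecord
#' @param tree gene tree (\code{phylo}).
#' @param alignmentLength alignment columns (>= 1).
#' @param consistencyScore alignment consistency in [0,1].
#' @param seedGene seed gene id.
#' @param treeId record id.
#' @export
PhylomeRecord <- function(tree, alignmentLength, consistencyScore,
                          seedGene = NA_character_, treeId = NA_character_) {
  new("PhylomeRecord", tree = tree, alignmentLength = as.numeric(alignmentLength),
      consistencyScore = as.numeric(consistencyScore),
      seedGene = as.character(seedGene), treeId = as.character(treeId))
}

setMethod("show", "PhylomeRecord", function(object) {
  cat("PhylomeRecord", object@treeId, "-", length(object@tree$tip.label),
      "leaves; alignment", object@alignmentLength, "cols, consistency",
      format(object@consistencyScore, digits = 3), "\n")
})

#' AlignmentMatrix: a species x columns residue matrix
#'
#' Aligned residues (20 amino acids plus \code{"-"}) as a character matrix
#' with species as rows. Column partitions track the source family after
#' concatenation; \code{focalClade} names the species subset used by
#' clade-variability partitioning and clade randomization.
#'
#' @slot seqs character matrix, rownames = species.
#' @slot partitions character vector, one entry per column (source family).
#' @slot focalClade character vector of species (possibly empty).
#' @export
setClass("AlignmentMatrix", representation(
  seqs = "matrix", partitions = "character", focalClade = "character"))

setValidity("AlignmentMatrix", function(object) {
  if (!is.character(object@seqs)) return("seqs must be a character matrix")
  if (is.null(rownames(object@seqs))) return("seqs must have species rownames")
  if (length(object@partitions) != ncol(object@seqs))
    return("partitions must annotate every column")
  if (length(bad <- setdiff(object@focalClade, rownames(object@seqs))))
    return(paste("focal species missing from alignment:", paste(bad, collapse = ",")))
  TRUE
})

#' Construct an AlignmentMatrix
#' @param seqs character matrix (rows species, cols positions) or named
#'   character vector of equal-length strings.
#' @param partitions per-column source family labels; defaults to a single
#'   partition \code{"aln"}.
#' @param focalClade species subset (default none).
#' @export
AlignmentMatrix <- function(seqs, partitions = NULL, focalClade = character()) {
  if (!is.matrix(seqs)) {
    stopifnot(!is.null(names(seqs)))
    nm <- names(seqs)
    seqs <- do.call(rbind, strsplit(unname(seqs), ""))
    rownames(seqs) <- nm
  }
  if (is.null(partitions)) partitions <- rep("aln", ncol(seqs))
  new("AlignmentMatrix", seqs = seqs, partitions = as.character(partitions),
      focalClade = as.character(focalClade))
}

#' Residue matrix accessor
#' @param x an \code{AlignmentMatrix}
#' @export
alnMatrix <- function(x) x@seqs

#' Partition annotation accessor
#' @param x an \code{AlignmentMatrix}
#' @export
alnPartitions <- function(x) x@partitions

#' Focal clade accessor
#' @param x an \code{AlignmentMatrix}
#' @export
focalClade <- function(x) x@focalClade

setMethod("show", "AlignmentMatrix", function(object) {
  cat("AlignmentMatrix:", nrow(object@seqs), "species x", ncol(object@seqs),
      "columns;", length(unique(object@partitions)), "partition(s)")
  if (length(object@focalClade))
    cat("; focal clade of", length(object@focalClade), "species")
  cat("\n")
})

setMethod("dim", "AlignmentMatrix", function(x) dim(x@seqs))

#' SiteLnLMatrix: per-site log-likelihoods for competing trees
#'
#' A trees x sites matrix of per-site log-likelihoods, the input to the
#' RELL-based topology tests. Row names are tree (hypothesis) ids.
#'
#' @slot lnl numeric matrix with finite entries; rownames = tree ids.
#' @export
setClass("SiteLnLMatrix", representation(lnl = "matrix"))

setValidity("SiteLnLMatrix", function(object) {
  if (!is.numeric(object@lnl)) return("lnl must be numeric")
  if (is.null(rownames(object@lnl))) return("lnl must have tree-id rownames")
  if (anyDuplicated(rownames(object@lnl))) return("tree ids must be unique")
  if (!all(is.finite(object@lnl))) return("lnl entries must be finite")
  TRUE
})

#' Construct a SiteLnLMatrix
#' @param lnl numeric matrix (rows trees, cols sites) with rownames.
#' @export
SiteLnLMatrix <- function(lnl) new("SiteLnLMatrix", lnl = as.matrix(lnl))

#' Site log-likelihood matrix accessor
#' @param x a \code{SiteLnLMatrix}
#' @export
siteLnL <- function(x) x@lnl

#' Tree id accessor
#' @param x a \code{SiteLnLMatrix}
#' @export
treeIds <- function(x) rownames(x@lnl)

setMethod("show", "SiteLnLMatrix", function(object) {
  cat("SiteLnLMatrix:", nrow(object@lnl), "trees x", ncol(object@lnl), "sites\n")
})

setMethod("dim", "SiteLnLMatrix", function(x) dim(x@lnl))
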