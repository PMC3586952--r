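## Concatenated-alignment construction and signal stratification: family
## selection, concatenation with partition bookkeeping, trimming,
## per-site per-rate-category log-likelihoods (Felsenstein pruning under the
## equal-exchangeability model), discrete-gamma rate-category assignment,
## fastest-site removal, clade-variability partitioning and reduced-alphabet
## recoding.

#' Select single-copy families present in enough species
#'
#' Keeps families with at most one gene per species and at least
#' \code{minSpecies} species represented.
#'
#' @param familyCounts integer matrix families x species of gene counts.
#' @param minSpecies minimum number of species with the family present.
#' @return character vector of family names (rownames) kept.
#' @export
selectSingleCopyFamilies <- function(familyCounts, minSpecies) {
  single <- apply(familyCounts, 1, function(r) all(r <= 1L))
  enough <- rowSums(familyCounts >= 1L) >= minSpecies
  rownames(familyCounts)[single & enough]
}

#' Concatenate per-family alignments
#'
#' Columns are appended in input order; a species absent from a family gets
#' gaps for that family's columns. Partition annotations record the source
#' family of every column.
#'
#' @param alignments named list of \code{\linkS4class{AlignmentMatrix}}
#'   (names = family ids).
#' @param speciesUniverse character vector of row labels for the result.
#' @return an \code{\linkS4class{AlignmentMatrix}}.
#' @export
concatenateAlignments <- function(alignments, speciesUniverse) {
  stop_if(is.null(names(alignments)), "alignments must be named by family")
  blocks <- lapply(names(alignments), function(fam) {
    m <- alnMatrix(alignments[[fam]])
    stop_if(anyDuplicated(rownames(m)) > 0,
            paste("duplicate species rows in family", fam))
    out <- matrix(GAP, nrow = length(speciesUniverse), ncol = ncol(m),
                  dimnames = list(speciesUniverse, NULL))
    common <- intersect(speciesUniverse, rownames(m))
    out[common, ] <- m[common, , drop = FALSE]
    out
  })
  parts <- rep(names(alignments), vapply(blocks, ncol, 1L))
  AlignmentMatrix(do.call(cbind, blocks), parts)
}

#' Extract one partition from a concatenated alignment
#' @param alignment an \code{\linkS4class{AlignmentMatrix}}.
#' @param family partition (family) name.
#' @return an \code{\linkS4class{AlignmentMatrix}} with that family's
#'   columns.
#' @export
extractPartition <- function(alignment, family) {
  keep <- alnPartitions(alignment) == family
  stop_if(!any(keep), paste("unknown partition:", family))
  AlignmentMatrix(alnMatrix(alignment)[, keep, drop = FALSE],
                  alnPartitions(alignment)[keep], focalClade(alignment))
}

#' Trim uninformative columns
#'
#' Drops columns with no residue variation across all sequences (all
#' non-gap residues identical, including all-gap columns) and columns that
#' are gaps in every focal-clade row. Survivor order is preserved.
#'
#' @param alignment an \code{\linkS4class{AlignmentMatrix}}.
#' @param focalCladeSp focal species (default: the alignment's focal clade).
#' @return the trimmed \code{\linkS4class{AlignmentMatrix}}.
#' @export
trimUninformative <- function(alignment, focalCladeSp = focalClade(alignment)) {
  m <- alnMatrix(alignment)
  stop_if(length(bad <- setdiff(focalCladeSp, rownames(m))),
          paste("focal species missing:", paste(bad, collapse = ",")))
  novar <- apply(m, 2, function(col) {
    r <- unique(col[col != GAP])
    length(r) <= 1L
  })
  focal_gap <- if (length(focalCladeSp))
    apply(m[focalCladeSp, , drop = FALSE], 2, function(col) all(col == GAP))
  else rep(FALSE, ncol(m))
  keep <- !(novar | focal_gap)
  if (!any(keep)) warning("no informative columns remain")
  AlignmentMatrix(m[, keep, drop = FALSE], alnPartitions(alignment)[keep],
                  focalCladeSp)
}

#' Per-site per-rate-category log-likelihoods by Felsenstein pruning
#'
#' Computes, for every alignment column and every discrete-gamma rate
#' category, the log-likelihood of the column on the given tree under the
#' equal-exchangeability amino-acid model with the supplied stationary
#' frequencies. Gaps are missing data (partial likelihood 1 over all
#' states). Partial likelihoods are rescaled per node to avoid underflow.
#'
#' @param alignment an \code{\linkS4class{AlignmentMatrix}} whose rows cover
#'   the tree's tips.
#' @param tree a \code{\linkS4class{SpeciesTree}} or rooted \code{phylo}
#'   with branch lengths.
#' @param gammaShape discrete-gamma shape (> 0); \code{Inf} means a single
#'   rate of 1.
#' @param nCategories number of rate categories.
#' @param freqs stationary frequencies over \code{AA20} (default uniform).
#' @return sites x categories matrix of log-likelihoods, with the category
#'   rates in attribute \code{"rates"}.
#' @export
computeSiteLoglik <- function(alignment, tree, gammaShape = 1,
                              nCategories = 16L, freqs = NULL) {
  m <- alnMatrix(alignment)
  stop_if(ncol(m) == 0L, "zero-length alignment")
  tr <- asPhylo(tree)
  stop_if(!all(tr$tip.label %in% rownames(m)), "tree tips missing from alignment")
  if (is.null(freqs)) freqs <- rep(1 / 20, 20)
  rates <- if (is.infinite(gammaShape)) rep(1, nCategories)
    else discreteGammaRates(gammaShape, nCategories)
  n_site <- ncol(m)
  n_tip <- length(tr$tip.label)
  edges <- ape::reorder.phylo(tr, "postorder")
  lens <- edges$edge.length
  if (is.null(lens)) lens <- rep(0, nrow(edges$edge))
  beta <- 1 / (1 - sum(freqs^2))
  # leaf partials: 20 x sites indicator (ones for gaps/unknown residues)
  leaf_part <- lapply(seq_len(n_tip), function(i) {
    res <- m[tr$tip.label[i], ]
    idx <- match(res, AA20)
    p <- matrix(0, 20L, n_site)
    known <- !is.na(idx)
    p[cbind(idx[known], which(known))] <- 1
    p[, !known] <- 1
    p
  })
  out <- matrix(NA_real_, n_site, nCategories)
  for (k in seq_len(nCategories)) {
    part <- vector("list", max(tr$edge))
    scale_log <- rep(0, n_site)
    for (i in seq_len(n_tip)) part[[i]] <- leaf_part[[i]]
    for (i in seq_len(nrow(edges$edge))) {
      p <- edges$edge[i, 1]; ch <- edges$edge[i, 2]
      e <- exp(-beta * rates[k] * lens[i])
      L <- part[[ch]]
      pooled <- colSums(L * freqs)           # sum_j pi_j L_j
      Mch <- e * L + rep(1 - e, each = 20L) * matrix(pooled, 20L, n_site, byrow = TRUE)
      part[[p]] <- if (is.null(part[[p]])) Mch else part[[p]] * Mch
      # rescale parent-in-progress occasionally via child contribution
      mx <- apply(part[[p]], 2, max)
      mx[mx == 0] <- 1
      part[[p]] <- sweep(part[[p]], 2, mx, "/")
      scale_log <- scale_log + log(mx)
    }
    root <- n_tip + 1L
    out[, k] <- log(colSums(part[[root]] * freqs)) + scale_log
  }
  attr(out, "rates") <- rates
  out
}

#' Assign alignment columns to discrete-gamma rate categories
#'
#' With equal category priors, the per-column posterior over categories is
#' proportional to the per-category likelihood; the assignment is the
#' posterior argmax, ties resolved to the slower category. Category 1 is
#' slowest.
#'
#' @param siteLogliks sites x categories matrix from
#'   \code{\link{computeSiteLoglik}}.
#' @return list with \code{category} (integer vector), \code{posterior}
#'   (sites x categories matrix, rows sum to 1) and \code{rates}.
#' @export
assignRateCategories <- function(siteLogliks) {
  post <- t(apply(siteLogliks, 1, function(x) {
    w <- exp(x - max(x)); w / sum(w)
  }))
  cat_idx <- apply(post, 1, function(p) which(p >= max(p) - 1e-12)[1])
  list(category = as.integer(cat_idx), posterior = post,
       rates = attr(siteLogliks, "rates"))
}

#' Estimate the discrete-gamma shape by grid maximization
#'
#' Maximizes the alignment log-likelihood (sites integrated over
#' equal-probability categories) over a shape grid.
#'
#' @inheritParams computeSiteLoglik
#' @param grid candidate shape values.
#' @return the maximizing shape.
#' @export
estimateGammaShape <- function(alignment, tree, nCategories = 16L,
                               freqs = NULL,
                               grid = c(0.2, 0.3, 0.5, 0.7, 1, 1.5, 2, 3, 5)) {
  ll <- vapply(grid, function(a) {
    s <- computeSiteLoglik(alignment, tree, a, nCategories, freqs)
    sum(apply(s, 1, logsumexp) - log(ncol(s)))
  }, 1.0)
  grid[which.max(ll)]
}

#' Remove sites in the fastest rate categories
#'
#' Drops all columns assigned to the top \code{k} (fastest) of the
#' \code{nCategories} categories.
#'
#' @param alignment an \code{\linkS4class{AlignmentMatrix}}.
#' @param assignment result of \code{\link{assignRateCategories}} for this
#'   alignment.
#' @param k number of fastest categories to remove (0 <= k < number of
#'   categories).
#' @return the reduced \code{\linkS4class{AlignmentMatrix}}.
#' @export
removeFastestSites <- function(alignment, assignment, k) {
  n_cat <- length(assignment$rates)
  stop_if(k >= n_cat, "k must be smaller than the number of categories")
  keep <- assignment$category <= n_cat - k
  AlignmentMatrix(alnMatrix(alignment)[, keep, drop = FALSE],
                  alnPartitions(alignment)[keep], focalClade(alignment))
}

#' Partition an alignment by focal-clade residue variability
#'
#' Routes each column by the number of distinct non-gap residues among the
#' focal-clade rows: partition 1 holds columns with 1-2 distinct residues,
#' partition 2 exactly 3, partition 3 exactly 4, partition 4 five or more.
#' Columns whose focal rows are all gaps are excluded.
#'
#' @param alignment an \code{\linkS4class{AlignmentMatrix}}.
#' @param focalCladeSp focal species (default: the alignment's focal clade).
#' @return list of four \code{\linkS4class{AlignmentMatrix}} objects.
#' @export
partitionByCladeVariability <- function(alignment,
                                        focalCladeSp = focalClade(alignment)) {
  m <- alnMatrix(alignment)
  stop_if(length(focalCladeSp) == 0L, "focal clade must be non-empty")
  stop_if(length(bad <- setdiff(focalCladeSp, rownames(m))),
          paste("focal species missing:", paste(bad, collapse = ",")))
  nres <- apply(m[focalCladeSp, , drop = FALSE], 2, function(col)
    length(unique(col[col != GAP])))
  bin <- ifelse(nres == 0L, NA_integer_,
         ifelse(nres <= 2L, 1L, ifelse(nres == 3L, 2L, ifelse(nres == 4L, 3L, 4L))))
  lapply(1:4, function(b) {
    keep <- !is.na(bin) & bin == b
    AlignmentMatrix(m[, keep, drop = FALSE], alnPartitions(alignment)[keep],
                    focalClade(alignment))
  })
}

#' Default four-letter amino-acid recoding
#'
#' A stand-in four-group recoding shipped with the package (small+polar,
#' aromatic+cysteine, charged+amide, aliphatic-hydrophobic). Any total
#' mapping over the 20 amino acids can be supplied instead.
#'
#' @return named character vector amino acid -> symbol in {a,b,c,d}.
#' @export
defaultRecodeMap <- function() {
  groups <- list(a = c("A", "G", "N", "P", "S", "T"),
                 b = c("C", "H", "W", "Y"),
                 c = c("D", "E", "K", "Q", "R"),
                 d = c("F", "I", "L", "M", "V"))
  unlist(lapply(names(groups), function(g) setNames(rep(g, length(groups[[g]])),
                                                    groups[[g]])))
}

#' Read a recoding map file
#'
#' Two-column TSV (residue, symbol). The shipped default
#' (\code{extdata/recode4_synthetic_default.tsv}) is the same stand-in
#' grouping as \code{\link{defaultRecodeMap}}; its filename marks it as a
#' package-constructed synthetic default rather than a published mapping.
#'
#' @param path file path; defaults to the shipped map.
#' @return named character vector residue -> symbol.
#' @export
readRecodeMap <- function(path = system.file("extdata",
                                             "recode4_synthetic_default.tsv",
                                             package = "phylopos")) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  setNames(d$symbol, d$residue)
}

#' Recode an alignment into a reduced alphabet
#'
#' Symbol-wise substitution of residues by their mapped group symbol; gaps
#' are preserved; dimensions and partitions unchanged.
#'
#' @param alignment an \code{\linkS4class{AlignmentMatrix}}.
#' @param mapping named character vector covering every residue present
#'   (default \code{\link{defaultRecodeMap}}).
#' @return the recoded \code{\linkS4class{AlignmentMatrix}}.
#' @export
recodeAlphabet <- function(alignment, mapping = defaultRecodeMap()) {
  m <- alnMatrix(alignment)
  mapping <- c(mapping, setNames(GAP, GAP))
  seen <- unique(as.vector(m))
  stop_if(length(bad <- setdiff(seen, names(mapping))),
          paste("unmapped residues:", paste(bad, collapse = ",")))
  out <- matrix(mapping[m], nrow(m), ncol(m), dimnames = dimnames(m))
  AlignmentMatrix(out, alnPartitions(alignment), focalClade(alignment))
}

#' Read an aligned FASTA file into an AlignmentMatrix
#' @param path FASTA path.
#' @param focalCladeSp optional focal species subset.
#' @return an \code{\linkS4class{AlignmentMatrix}}.
#' @export
readAlignment <- function(path, focalCladeSp = character()) {
  ss <- Biostrings::readAAStringSet(path)
  m <- do.call(rbind, strsplit(as.character(ss), ""))
  rownames(m) <- names(ss)
  AlignmentMatrix(m, focalClade = focalCladeSp)
}

#' Write an AlignmentMatrix as aligned FASTA
#' @param alignment an \code{\linkS4class{AlignmentMatrix}}.
#' @param path output path.
#' @export
writeAlignment <- function(alignment, path) {
  m <- alnMatrix(alignment)
  ss <- Biostrings::AAStringSet(apply(m, 1, paste0, collapse = ""))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Write partition annotations (family, start, end; 1-based inclusive)
#' @param alignment an \code{\linkS4class{AlignmentMatrix}}.
#' @param path output path.
#' @export
writePartitions <- function(alignment, path) {
  p <- alnPartitions(alignment)
  r <- rle(p)
  end <- cumsum(r$lengths)
  d <- data.frame(family = r$values, start = end - r$lengths + 1L, end = end)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
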