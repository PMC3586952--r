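## Conserved gene-neighborhood (microsynteny) detection between two genomes
## under two definitions:
##  - relaxed: query genes with <= 3 intervening genes whose family homologs
##    in the target co-occur with <= 4 intervening genes; intervening query
##    genes that have target homologs must have one within a 15-gene window
##    of the target pair.
##  - strict: query genes in the same orientation with <= 3 intervening
##    genes whose 1:1 orthologs lie <= 3 intervening genes apart; any
##    intervening query gene with a target ortholog voids the pair (literal
##    mode) or voids it only when that ortholog falls outside the interval
##    spanned by the pair's orthologs (interval_consistent mode).
## Plus the duplication correction (paralogous target loci counted once),
## per-1000 normalization, and Kruskal-Wallis group comparison.

MAX_QUERY_GAP <- 3L       # intervening genes allowed between query pair
MAX_RELAXED_TARGET_GAP <- 4L
MAX_STRICT_TARGET_GAP <- 3L
RELAXED_WINDOW_HALF <- 7L # 15-gene window around the target pair

#' Find relaxed syntenic pairs between two genomes
#'
#' A query gene pair on one contig with at most three intervening genes is
#' syntenic when homologs (same family) of both genes co-occur on a target
#' contig separated by at most four genes, and every intervening query gene
#' that has any homolog in the target has one within a 15-gene window of the
#' target pair (at most 7 positions outside the interval spanned by the two
#' target anchors). One row is reported per (query pair, target locus).
#'
#' @param query,target \code{\linkS4class{GeneOrderGenome}} objects sharing
#'   a family namespace.
#' @return data.frame with columns \code{query_g1}, \code{query_g2},
#'   \code{target_g1}, \code{target_g2}, \code{family_1}, \code{family_2},
#'   \code{mode}.
#' @export
findRelaxedPairs <- function(query, target) {
  qt <- geneTable(query); tt <- geneTable(target)
  fam_pos <- split(seq_len(nrow(tt)), tt$family_id)
  out <- vector("list", 256L); n_out <- 0L
  for (ct in unique(qt$contig)) {
    qc <- qt[qt$contig == ct, , drop = FALSE]
    qc <- qc[order(qc$index), , drop = FALSE]
    nq <- nrow(qc)
    for (i in seq_len(nq)) {
      for (j in seq_len(nq)) {
        if (j <= i) next
        gap <- qc$index[j] - qc$index[i] - 1L
        if (gap > MAX_QUERY_GAP) break
        hits_i <- fam_pos[[qc$family_id[i]]]
        hits_j <- fam_pos[[qc$family_id[j]]]
        if (is.null(hits_i) || is.null(hits_j)) next
        interv <- if (gap > 0L) qc[(i + 1L):(j - 1L), , drop = FALSE] else NULL
        for (a in hits_i) for (b in hits_j) {
          if (a == b) next
          if (tt$contig[a] != tt$contig[b]) next
          tgap <- abs(tt$index[b] - tt$index[a]) - 1L
          if (tgap > MAX_RELAXED_TARGET_GAP) next
          lo <- min(tt$index[a], tt$index[b]); hi <- max(tt$index[a], tt$index[b])
          ok <- TRUE
          if (!is.null(interv)) for (k in seq_len(nrow(interv))) {
            hk <- fam_pos[[interv$family_id[k]]]
            if (is.null(hk)) next  # no homolog in target: no constraint
            same_ct <- hk[tt$contig[hk] == tt$contig[a]]
            in_win <- length(same_ct) > 0L &&
              any(tt$index[same_ct] >= lo - RELAXED_WINDOW_HALF &
                  tt$index[same_ct] <= hi + RELAXED_WINDOW_HALF)
            if (!in_win) { ok <- FALSE; break }
          }
          if (!ok) next
          n_out <- n_out + 1L
          if (n_out > length(out)) out <- c(out, vector("list", length(out)))
          out[[n_out]] <- data.frame(
            query_g1 = qc$gene_id[i], query_g2 = qc$gene_id[j],
            target_g1 = tt$gene_id[a], target_g2 = tt$gene_id[b],
            family_1 = qc$family_id[i], family_2 = qc$family_id[j],
            mode = "relaxed", stringsAsFactors = FALSE)
        }
      }
    }
  }
  collect_pairs(out, n_out)
}

collect_pairs <- function(out, n_out) {
  if (n_out == 0L)
    return(data.frame(query_g1 = character(), query_g2 = character(),
                      target_g1 = character(), target_g2 = character(),
                      family_1 = character(), family_2 = character(),
                      mode = character(), stringsAsFactors = FALSE))
  do.call(rbind, out[seq_len(n_out)])
}

# 1:1 ortholog map between two genomes: ortholog ids present exactly once in
# each genome. Returns a named vector query gene_id -> target gene_id.
orthologMap1to1 <- function(query, target) {
  qt <- geneTable(query); tt <- geneTable(target)
  q1 <- qt[!is.na(qt$ortholog_id), ]
  t1 <- tt[!is.na(tt$ortholog_id), ]
  q1 <- q1[q1$ortholog_id %in% names(which(table(q1$ortholog_id) == 1L)), ]
  t1 <- t1[t1$ortholog_id %in% names(which(table(t1$ortholog_id) == 1L)), ]
  shared <- intersect(q1$ortholog_id, t1$ortholog_id)
  setNames(t1$gene_id[match(shared, t1$ortholog_id)],
           q1$gene_id[match(shared, q1$ortholog_id)])
}

#' Find strict syntenic pairs between two genomes
#'
#' A query gene pair in the same orientation (the two query genes share a
#' strand, and their orthologs share a strand with each other) with at most
#' three intervening genes is syntenic when the genes' one-to-one orthologs
#' lie on one target contig at most three intervening genes apart. In
#' \code{"literal"} mode the pair is discarded whenever any intervening
#' query gene has a target ortholog; in \code{"interval_consistent"} mode
#' only when that ortholog falls outside the target interval spanned by the
#' pair's orthologs.
#'
#' @inheritParams findRelaxedPairs
#' @param interveningMode \code{"literal"} (default) or
#'   \code{"interval_consistent"}.
#' @return data.frame as in \code{\link{findRelaxedPairs}} with
#'   \code{mode = "strict"}.
#' @export
findStrictPairs <- function(query, target,
                            interveningMode = c("literal", "interval_consistent")) {
  interveningMode <- match.arg(interveningMode)
  qt <- geneTable(query); tt <- geneTable(target)
  omap <- orthologMap1to1(query, target)
  t_row <- match(omap, tt$gene_id); names(t_row) <- names(omap)
  out <- vector("list", 256L); n_out <- 0L
  for (ct in unique(qt$contig)) {
    qc <- qt[qt$contig == ct, , drop = FALSE]
    qc <- qc[order(qc$index), , drop = FALSE]
    nq <- nrow(qc)
    for (i in seq_len(nq)) {
      a <- t_row[qc$gene_id[i]]
      if (is.na(a)) next
      for (j in seq_len(nq)) {
        if (j <= i) next
        gap <- qc$index[j] - qc$index[i] - 1L
        if (gap > MAX_QUERY_GAP) break
        b <- t_row[qc$gene_id[j]]
        if (is.na(b)) next
        if (qc$strand[i] != qc$strand[j]) next
        if (tt$strand[a] != tt$strand[b]) next
        if (tt$contig[a] != tt$contig[b]) next
        tgap <- abs(tt$index[b] - tt$index[a]) - 1L
        if (tgap > MAX_STRICT_TARGET_GAP) next
        lo <- min(tt$index[a], tt$index[b]); hi <- max(tt$index[a], tt$index[b])
        ok <- TRUE
        if (gap > 0L) for (k in (i + 1L):(j - 1L)) {
          o <- t_row[qc$gene_id[k]]
          if (is.na(o)) next
          if (interveningMode == "literal") { ok <- FALSE; break }
          inside <- tt$contig[o] == tt$contig[a] &&
            tt$index[o] > lo && tt$index[o] < hi
          if (!inside) { ok <- FALSE; break }
        }
        if (!ok) next
        n_out <- n_out + 1L
        if (n_out > length(out)) out <- c(out, vector("list", length(out)))
        out[[n_out]] <- data.frame(
          query_g1 = qc$gene_id[i], query_g2 = qc$gene_id[j],
          target_g1 = tt$gene_id[a], target_g2 = tt$gene_id[b],
          family_1 = qc$family_id[i], family_2 = qc$family_id[j],
          mode = "strict", stringsAsFactors = FALSE)
      }
    }
  }
  collect_pairs(out, n_out)
}

#' Collapse paralogous syntenic pairs
#'
#' Groups detected pairs by (query pair, unordered family pair) and keeps
#' one representative per group, so a single query pair matching several
#' target loci that arose by lineage-specific segmental duplication is
#' counted once.
#'
#' @param pairs data.frame from \code{\link{findRelaxedPairs}} or
#'   \code{\link{findStrictPairs}}.
#' @return the corrected data.frame (first representative per group).
#' @export
collapseParalogousPairs <- function(pairs) {
  if (nrow(pairs) == 0L) return(pairs)
  fam_lo <- pmin(pairs$family_1, pairs$family_2)
  fam_hi <- pmax(pairs$family_1, pairs$family_2)
  key <- paste(pairs$query_g1, pairs$query_g2, fam_lo, fam_hi, sep = "\r")
  pairs[!duplicated(key), , drop = FALSE]
}

#' Normalize a pair count per 1000 shared genes
#'
#' @param count number of syntenic pairs.
#' @param shared shared-homolog or shared-ortholog denominator (> 0).
#' @return \code{1000 * count / shared}.
#' @export
normalizePairCount <- function(count, shared) {
  stop_if(any(shared <= 0), "shared denominator must be > 0")
  1000 * count / shared
}

#' Number of shared homologs between two genomes
#'
#' Counted at the gene level: query genes whose family has at least one
#' member in the target genome.
#' @inheritParams findRelaxedPairs
#' @export
sharedHomologs <- function(query, target) {
  sum(geneTable(query)$family_id %in% geneTable(target)$family_id)
}

#' Number of shared one-to-one orthologs between two genomes
#' @inheritParams findRelaxedPairs
#' @export
sharedOrthologs <- function(query, target) {
  length(orthologMap1to1(query, target))
}

#' Full synteny comparison of two genomes
#'
#' Runs a detector, applies the paralogous-pair correction, and normalizes
#' raw and corrected counts by the appropriate shared-gene denominator
#' (shared homologs for relaxed mode, shared 1:1 orthologs for strict mode).
#' Counts are not symmetric in query/target; callers interested in both
#' directions should call twice.
#'
#' @inheritParams findStrictPairs
#' @param mode \code{"relaxed"} or \code{"strict"}.
#' @return one-row data.frame: query, target, mode, shared, raw_count,
#'   corrected_count, normalized_raw, normalized_corrected.
#' @export
syntenyCompare <- function(query, target, mode = c("relaxed", "strict"),
                           interveningMode = c("literal", "interval_consistent")) {
  mode <- match.arg(mode)
  pairs <- if (mode == "relaxed") findRelaxedPairs(query, target)
    else findStrictPairs(query, target, interveningMode)
  corrected <- collapseParalogousPairs(pairs)
  shared <- if (mode == "relaxed") sharedHomologs(query, target)
    else sharedOrthologs(query, target)
  data.frame(
    query = genomeId(query), target = genomeId(target), mode = mode,
    shared = shared, raw_count = nrow(pairs), corrected_count = nrow(corrected),
    normalized_raw = if (shared > 0) normalizePairCount(nrow(pairs), shared) else NA_real_,
    normalized_corrected = if (shared > 0)
      normalizePairCount(nrow(corrected), shared) else NA_real_,
    stringsAsFactors = FALSE)
}

#' Kruskal-Wallis comparison of normalized synteny scores across groups
#'
#' Rank-based Kruskal-Wallis H with midrank tie correction and a chi-square
#' p-value on (groups - 1) degrees of freedom.
#'
#' @param ratesByGroup named list: group label -> numeric vector of
#'   normalized scores (>= 2 non-empty groups).
#' @return list with \code{H}, \code{df} and \code{p.value}.
#' @export
compareGroupsKW <- function(ratesByGroup) {
  stop_if(length(ratesByGroup) < 2, "need at least 2 groups")
  stop_if(any(!vapply(ratesByGroup, length, 1L)), "groups must be non-empty")
  x <- unlist(ratesByGroup, use.names = FALSE)
  g <- factor(rep(names(ratesByGroup), vapply(ratesByGroup, length, 1L)))
  if (length(unique(x)) == 1L)  # all ranks tied: H = 0 by convention
    return(list(H = 0, df = length(levels(g)) - 1L, p.value = 1))
  kt <- kruskal.test(x, g)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p.value = kt$p.value)
}

#' Read a gene-order table
#'
#' TSV columns: genome_id, contig, index (0-based), gene_id, strand (+/-),
#' family_id, ortholog_id (empty/NA for none).
#' @param path file path.
#' @return named list of \code{\linkS4class{GeneOrderGenome}}.
#' @export
readGeneOrders <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = c(ortholog_id = "character"))
  d$ortholog_id[d$ortholog_id == ""] <- NA_character_
  lapply(split(d, d$genome_id), function(g)
    GeneOrderGenome(g$genome_id[1],
                    g[c("gene_id", "contig", "index", "strand", "family_id",
                        "ortholog_id")]))
}

#' Write gene-order tables
#' @param genomes list of \code{\linkS4class{GeneOrderGenome}}.
#' @param path file path.
#' @export
writeGeneOrders <- function(genomes, path) {
  if (is(genomes, "GeneOrderGenome")) genomes <- list(genomes)
  d <- do.call(rbind, lapply(genomes, function(g) {
    cbind(genome_id = genomeId(g), geneTable(g))
  }))
  d$ortholog_id[is.na(d$ortholog_id)] <- ""
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
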