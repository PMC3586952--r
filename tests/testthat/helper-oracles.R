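# Independent brute-force oracles. These re-implement the detection rules
# with different code paths (merge/filter style rather than the package's
# walk over contigs) so detector and oracle can disagree if either is wrong.

# All relaxed syntenic pairs by exhaustive filtering; returns a character
# vector of "q1|q2|t1|t2" keys.
oracle_relaxed_keys <- function(query, target) {
  qt <- geneTable(query); tt <- geneTable(target)
  keys <- character()
  qp <- merge(qt, qt, by = "contig", suffixes = c(".1", ".2"))
  qp <- qp[qp$index.1 < qp$index.2 & (qp$index.2 - qp$index.1 - 1) <= 3, ,
           drop = FALSE]
  for (r in seq_len(nrow(qp))) {
    t1 <- tt[tt$family_id == qp$family_id.1[r], , drop = FALSE]
    t2 <- tt[tt$family_id == qp$family_id.2[r], , drop = FALSE]
    if (!nrow(t1) || !nrow(t2)) next
    between <- qt[qt$contig == qp$contig[r] & qt$index > qp$index.1[r] &
                    qt$index < qp$index.2[r], , drop = FALSE]
    for (a in seq_len(nrow(t1))) for (b in seq_len(nrow(t2))) {
      if (t1$gene_id[a] == t2$gene_id[b]) next
      if (t1$contig[a] != t2$contig[b]) next
      if (abs(t2$index[b] - t1$index[a]) - 1 > 4) next
      lo <- min(t1$index[a], t2$index[b]); hi <- max(t1$index[a], t2$index[b])
      ok <- TRUE
      for (k in seq_len(nrow(between))) {
        hk <- tt[tt$family_id == between$family_id[k], , drop = FALSE]
        if (!nrow(hk)) next
        win <- hk[hk$contig == t1$contig[a] & hk$index >= lo - 7 &
                    hk$index <= hi + 7, , drop = FALSE]
        if (!nrow(win)) { ok <- FALSE; break }
      }
      if (ok) keys <- c(keys, paste(qp$gene_id.1[r], qp$gene_id.2[r],
                                    t1$gene_id[a], t2$gene_id[b], sep = "|"))
    }
  }
  sort(keys)
}

# Independent 1:1 ortholog map (ids present exactly once on each side).
oracle_ortho_map <- function(query, target) {
  qt <- geneTable(query); tt <- geneTable(target)
  q <- qt[!is.na(qt$ortholog_id), , drop = FALSE]
  t <- tt[!is.na(tt$ortholog_id), , drop = FALSE]
  q <- q[ave(seq_len(nrow(q)), q$ortholog_id, FUN = length) == 1, , drop = FALSE]
  t <- t[ave(seq_len(nrow(t)), t$ortholog_id, FUN = length) == 1, , drop = FALSE]
  mg <- merge(q, t, by = "ortholog_id", suffixes = c(".q", ".t"))
  setNames(mg$gene_id.t, mg$gene_id.q)
}

oracle_strict_keys <- function(query, target, literal = TRUE) {
  qt <- geneTable(query); tt <- geneTable(target)
  om <- oracle_ortho_map(query, target)
  keys <- character()
  qp <- merge(qt, qt, by = "contig", suffixes = c(".1", ".2"))
  qp <- qp[qp$index.1 < qp$index.2 & (qp$index.2 - qp$index.1 - 1) <= 3, ,
           drop = FALSE]
  for (r in seq_len(nrow(qp))) {
    o1 <- om[qp$gene_id.1[r]]; o2 <- om[qp$gene_id.2[r]]
    if (is.na(o1) || is.na(o2)) next
    if (qp$strand.1[r] != qp$strand.2[r]) next
    ta <- tt[tt$gene_id == o1, ]; tb <- tt[tt$gene_id == o2, ]
    if (ta$strand != tb$strand) next
    if (ta$contig != tb$contig) next
    if (abs(tb$index - ta$index) - 1 > 3) next
    lo <- min(ta$index, tb$index); hi <- max(ta$index, tb$index)
    between <- qt[qt$contig == qp$contig[r] & qt$index > qp$index.1[r] &
                    qt$index < qp$index.2[r], , drop = FALSE]
    ok <- TRUE
    for (k in seq_len(nrow(between))) {
      ok_id <- om[between$gene_id[k]]
      if (is.na(ok_id)) next
      if (literal) { ok <- FALSE; break }
      orow <- tt[tt$gene_id == ok_id, ]
      if (!(orow$contig == ta$contig && orow$index > lo && orow$index < hi)) {
        ok <- FALSE; break
      }
    }
    if (ok) keys <- c(keys, paste(qp$gene_id.1[r], qp$gene_id.2[r],
                                  ta$gene_id, tb$gene_id, sep = "|"))
  }
  sort(keys)
}

pair_keys <- function(pairs) {
  sort(paste(pairs$query_g1, pairs$query_g2, pairs$target_g1, pairs$target_g2,
             sep = "|"))
}

# Node-wise LCA reconciliation oracle built on ape primitives only.
oracle_dup_count <- function(geneTree, spTree) {
  n_tip <- length(geneTree$tip.label)
  parts <- ape::prop.part(geneTree)
  tipset <- function(node) {
    if (node <= n_tip) return(geneTree$tip.label[node])
    attr(parts, "labels")[parts[[node - n_tip]]]
  }
  map_node <- function(node) {
    spp <- unique(leafSpecies(tipset(node)))
    if (length(spp) == 1L) return(match(spp, spTree$tip.label))
    ape::getMRCA(spTree, spp)
  }
  dups <- 0L
  for (node in (n_tip + 1L):max(geneTree$edge)) {
    mm <- map_node(node)
    kids <- geneTree$edge[geneTree$edge[, 1] == node, 2]
    if (any(vapply(kids, map_node, 1L) == mm)) dups <- dups + 1L
  }
  dups
}

# Exhaustive-state log-likelihood for one alignment column on a small rooted
# binary tree under the equal-exchangeability model (sums over every
# internal-state assignment).
oracle_column_loglik <- function(tree, residues, freqs = rep(1 / 20, 20),
                                 rate = 1) {
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  beta <- 1 / (1 - sum(freqs^2))
  Pmat <- function(t) {
    e <- exp(-beta * t * rate)
    matrix(freqs * (1 - e), 20, 20, byrow = TRUE) + diag(20) * e
  }
  n_tip <- length(tree$tip.label)
  n_node <- max(tree$edge)
  internal <- (n_tip + 1L):n_node
  Plist <- vector("list", n_node)
  for (i in seq_len(nrow(tree$edge)))
    Plist[[tree$edge[i, 2]]] <- Pmat(tree$edge.length[i])
  grid <- as.matrix(expand.grid(rep(list(1:20), length(internal))))
  colnames(grid) <- as.character(internal)
  root <- n_tip + 1L
  total <- freqs[grid[, as.character(root)]]
  for (i in seq_len(nrow(tree$edge))) {
    par <- tree$edge[i, 1]; ch <- tree$edge[i, 2]
    ps <- grid[, as.character(par)]
    cs <- if (ch <= n_tip) {
      r <- match(residues[tree$tip.label[ch]], aa)
      rep(r, nrow(grid))
    } else grid[, as.character(ch)]
    total <- total * Plist[[ch]][cbind(ps, cs)]
  }
  log(sum(total))
}

# Random genome pair related by simulated rearrangements; used by the
# detector-oracle equivalence checks.
random_genome_pair <- function(nGenes, seed) {
  st <- simSpeciesTree(nSpecies = 2, brlenMean = 0.1, seed = seed)
  sim <- simGeneOrders(st, nGenes = nGenes, invRate = 2, segdupRate = 0.8,
                       gainlossRate = 1.5, seed = seed + 1000L)
  sim$genomes
}
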