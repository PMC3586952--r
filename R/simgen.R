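## Synthetic-data generators with planted ground truth. These define the
## study conditions for every downstream validation: species trees, gene
## orders evolved by inversion / tandem segmental duplication / gain-loss,
## duplication-loss gene trees, alignments under an equal-exchangeability
## amino-acid CTMC with discrete-gamma rate heterogeneity, phylome metadata,
## and clade randomization.

#' Group sizes of the reference taxon sampling
#'
#' A 22-species sampling: 6 focal (Microsporidia), 4 outgroups, and 12
#' species covering the six predefined fungal groups (2 Chytridiomycotina,
#' 3 Zygomycotina, 2 Basidiomycotina, 1 Taphrinomycotina,
#' 2 Saccharomycotina, 2 Pezizomycotina).
#'
#' @return named integer vector of species counts per group.
#' @export
defaultGroupSizes <- function() {
  c(Outgroup = 4L, Microsporidia = 6L, Chytridiomycotina = 2L,
    Zygomycotina = 3L, Basidiomycotina = 2L, Taphrinomycotina = 1L,
    Saccharomycotina = 2L, Pezizomycotina = 2L)
}

# Ladder (pectinate) newick over labels with constant branch lengths.
ladder_newick <- function(labels, brlen) {
  if (length(labels) == 1L) return(sprintf("%s:%g", labels, brlen))
  inner <- sprintf("%s:%g", labels[length(labels)], brlen)
  for (i in rev(seq_len(length(labels) - 1L)))
    inner <- sprintf("(%s:%g,%s):%g", labels[i], brlen, inner, brlen)
  inner
}

#' Reference species tree with the canonical group backbone
#'
#' Deterministic rooted species tree in which the focal group is sister to
#' all other fungal groups (the "basal" arrangement, scenario A) and the
#' remaining groups branch off in the order Chytridiomycotina,
#' Zygomycotina, Basidiomycotina, Taphrinomycotina, then
#' Saccharomycotina+Pezizomycotina; outgroups are the earliest split.
#' Within-group subtrees are ladders. Used as the base topology for
#' hypothesis generation and simulations.
#'
#' @param groupSizes named integer vector (see \code{\link{defaultGroupSizes}}).
#' @param brlen constant branch length (expected substitutions/site).
#' @param focalGroup name of the focal group.
#' @return a \code{\linkS4class{SpeciesTree}}.
#' @export
referenceSpeciesTree <- function(groupSizes = defaultGroupSizes(), brlen = 0.1,
                                 focalGroup = "Microsporidia") {
  backbone <- c("Chytridiomycotina", "Zygomycotina", "Basidiomycotina",
                "Taphrinomycotina", "Saccharomycotina", "Pezizomycotina")
  backbone <- backbone[backbone %in% names(groupSizes)]
  sp_of <- function(g) sprintf("%s_%02d", g, seq_len(groupSizes[[g]]))
  # ladder_newick already parenthesizes multi-species groups and carries the
  # subtree root branch length
  grp_nwk <- vapply(backbone, function(g) ladder_newick(sp_of(g), brlen), "")
  n <- length(grp_nwk)
  inner <- sprintf("(%s,%s):%g", grp_nwk[n - 1], grp_nwk[n], brlen)
  for (i in rev(seq_len(n - 2))) inner <- sprintf("(%s,%s):%g", grp_nwk[i], inner, brlen)
  focal_nwk <- ladder_newick(sp_of(focalGroup), brlen)
  out_nwk <- ladder_newick(sp_of("Outgroup"), brlen)
  nwk <- sprintf("(%s,(%s,%s):%g);", out_nwk, focal_nwk, inner, brlen)
  tr <- ape::read.tree(text = nwk)
  groups <- unlist(lapply(names(groupSizes), function(g) setNames(rep(g, groupSizes[[g]]), sp_of(g))))
  SpeciesTree(tr, groups)
}

#' Simulate a random rooted species tree (Yule process)
#'
#' Grows a rooted binary topology by repeatedly splitting a uniformly chosen
#' extant lineage until \code{nSpecies} tips exist, then draws every branch
#' length independently from an exponential distribution. When
#' \code{groupSizes} is supplied, a backbone tree over groups is generated
#' the same way and each group receives its own Yule subtree, so that groups
#' are monophyletic by construction.
#'
#' @param nSpecies number of species (>= 2); ignored when \code{groupSizes}
#'   is given.
#' @param groupSizes optional named integer vector of per-group species
#'   counts.
#' @param brlenMean mean of the exponential branch-length distribution.
#' @param seed integer seed; the result is a pure function of the arguments.
#' @return a \code{\linkS4class{SpeciesTree}}.
#' @export
simSpeciesTree <- function(nSpecies = NULL, groupSizes = NULL, brlenMean = 0.1,
                           seed = NULL) {
  with_seed(seed, {
    if (is.null(groupSizes)) {
      stop_if(is.null(nSpecies) || nSpecies < 2, "need at least 2 species")
      labels <- sample(sprintf("sp%03d", seq_len(nSpecies)))
      tr <- yule_topology(labels, brlenMean)
      SpeciesTree(tr)
    } else {
      stop_if(sum(groupSizes) < 2, "need at least 2 species")
      grp_labels <- names(groupSizes)
      backbone <- if (length(grp_labels) == 1L) NULL
        else yule_topology(sample(grp_labels), brlenMean)
      pieces <- lapply(grp_labels, function(g) {
        labs <- sprintf("%s_%02d", g, seq_len(groupSizes[[g]]))
        if (length(labs) == 1L) labs else yule_topology(sample(labs), brlenMean)
      })
      names(pieces) <- grp_labels
      nwk <- if (is.null(backbone)) {
        p <- pieces[[1L]]
        if (is.character(p)) sprintf("%s;", p) else ape::write.tree(p)
      } else {
        s <- ape::write.tree(backbone)
        for (g in grp_labels) {
          rep_nwk <- if (is.character(pieces[[g]])) pieces[[g]]
            else sub(";$", "", sub("^", "", ape::write.tree(pieces[[g]])))
          # replace the group placeholder tip, keeping its branch length
          s <- sub(paste0("(?<![A-Za-z0-9_])", g, ":"),
                   paste0(rep_nwk, ":"), s, perl = TRUE)
          s <- sub(paste0("(?<![A-Za-z0-9_])", g, "(?=[,);])"), rep_nwk, s, perl = TRUE)
        }
        s
      }
      tr <- ape::read.tree(text = nwk)
      groups <- unlist(lapply(grp_labels, function(g)
        setNames(rep(g, groupSizes[[g]]), sprintf("%s_%02d", g, seq_len(groupSizes[[g]])))))
      SpeciesTree(tr, groups)
    }
  })
}

# Yule tip-splitting topology with Exp(brlenMean) branch lengths; returns phylo.
yule_topology <- function(labels, brlenMean) {
  n <- length(labels)
  if (n == 1L) stop("yule_topology needs >= 2 labels")
  # nested-list tree: leaf = index into labels
  tree <- list(1L, 2L)
  leaves <- 2L
  # each leaf occupies a "slot"; track paths by growing a flat structure:
  # represent as parent vectors instead for efficiency
  # nodes: negative = internal; use lists (n small in practice)
  split_leaf <- function(node, target, new_leaf) {
    if (!is.list(node)) {
      if (node == target) return(list(node, new_leaf))
      return(node)
    }
    list(split_leaf(node[[1]], target, new_leaf), split_leaf(node[[2]], target, new_leaf))
  }
  while (leaves < n) {
    target <- sample.int(leaves, 1L)
    leaves <- leaves + 1L
    tree <- split_leaf(tree, target, leaves)
  }
  to_newick <- function(node) {
    if (!is.list(node)) return(sprintf("%s:%g", labels[node], rexp(1, 1 / brlenMean)))
    sprintf("(%s,%s):%g", to_newick(node[[1]]), to_newick(node[[2]]),
            rexp(1, 1 / brlenMean))
  }
  ape::read.tree(text = paste0(to_newick(tree), ";"))
}

#' Evolve gene orders along a species tree
#'
#' Starting from a common ancestral gene order (one contig, \code{nGenes}
#' genes with unique families), each branch of the species tree applies a
#' Poisson number of events per type: inversions (reverse a contiguous block
#' and flip strands), tandem segmental duplications (copy a contiguous block
#' and insert the copy immediately after the source; copies keep the family
#' id but lose ortholog status), and gene gain/loss (gains create novel
#' single-member families; losses never remove a genome's last family
#' member). True orthology is descent without duplication: a gene keeps its
#' ancestral ortholog id only along un-duplicated lines of descent.
#'
#' @param speciesTree a \code{\linkS4class{SpeciesTree}}.
#' @param nGenes ancestral gene count (>= 1).
#' @param invRate expected inversions per branch.
#' @param segdupRate expected segmental duplications per branch.
#' @param gainlossRate expected gain/loss events per branch (split evenly
#'   between gains and losses).
#' @param maxInvLen,maxDupLen maximal block lengths for inversions and
#'   duplications.
#' @param seed integer seed.
#' @return list with \code{genomes} (named list of
#'   \code{\linkS4class{GeneOrderGenome}}, one per species) and \code{truth}
#'   (list with \code{orthologSets}, a partition of gene ids by ancestral
#'   ortholog lineage).
#' @export
simGeneOrders <- function(speciesTree, nGenes, invRate = 0, segdupRate = 0,
                          gainlossRate = 0, maxInvLen = 5L, maxDupLen = 4L,
                          seed = NULL) {
  stop_if(nGenes < 1, "nGenes must be >= 1")
  stop_if(invRate < 0 || segdupRate < 0 || gainlossRate < 0, "rates must be >= 0")
  tr <- asPhylo(speciesTree)
  with_seed(seed, {
    anc <- data.frame(
      family_id = sprintf("f%04d", seq_len(nGenes)),
      ortholog_id = sprintf("og%04d", seq_len(nGenes)),
      strand = sample(c("+", "-"), nGenes, replace = TRUE),
      stringsAsFactors = FALSE)
    env <- new.env()
    env$gain_counter <- nGenes
    kids <- phylo_children(tr)
    n_tip <- length(tr$tip.label)
    genomes <- list()
    evolve <- function(node, genome) {
      if (node <= n_tip) {
        sp <- tr$tip.label[node]
        genome$gene_id <- sprintf("%s_g%04d", sp, seq_len(nrow(genome)))
        genomes[[sp]] <<- GeneOrderGenome(sp, data.frame(
          gene_id = genome$gene_id, contig = "c1",
          index = seq_len(nrow(genome)) - 1L, strand = genome$strand,
          family_id = genome$family_id, ortholog_id = genome$ortholog_id,
          stringsAsFactors = FALSE))
        return(invisible(NULL))
      }
      for (ch in kids[[node]]) {
        g <- mutate_order(genome, invRate, segdupRate, gainlossRate,
                          maxInvLen, maxDupLen, env)
        evolve(ch, g)
      }
    }
    evolve(n_tip + 1L, anc)
    all_genes <- do.call(rbind, lapply(genomes, geneTable))
    sets <- split(all_genes$gene_id, all_genes$ortholog_id)
    orphan <- all_genes$gene_id[is.na(all_genes$ortholog_id)]
    sets <- c(sets, as.list(orphan))
    list(genomes = genomes, truth = list(orthologSets = unname(sets)))
  })
}

# Apply one branch's worth of rearrangement events to an ordered gene table.
mutate_order <- function(genome, invRate, segdupRate, gainlossRate,
                         maxInvLen, maxDupLen, env) {
  n_inv <- rpois(1L, invRate)
  n_dup <- rpois(1L, segdupRate)
  n_gl <- rpois(1L, gainlossRate)
  ops <- sample(c(rep("inv", n_inv), rep("dup", n_dup), rep("gl", n_gl)))
  for (op in ops) {
    n <- nrow(genome)
    if (n == 0L) break
    if (op == "inv") {
      len <- sample.int(min(maxInvLen, n), 1L)
      start <- sample.int(n - len + 1L, 1L)
      block <- start:(start + len - 1L)
      seg <- genome[rev(block), , drop = FALSE]
      seg$strand <- ifelse(seg$strand == "+", "-", "+")
      genome[block, ] <- seg
    } else if (op == "dup") {
      len <- sample.int(min(maxDupLen, n), 1L)
      start <- sample.int(n - len + 1L, 1L)
      block <- start:(start + len - 1L)
      copy <- genome[block, , drop = FALSE]
      copy$ortholog_id <- NA_character_   # duplicated copies lose orthology
      genome <- rbind(genome[seq_len(start + len - 1L), , drop = FALSE], copy,
                      if (start + len <= n) genome[(start + len):n, , drop = FALSE])
    } else {
      if (runif(1) < 0.5) { # gain
        env$gain_counter <- env$gain_counter + 1L
        newg <- data.frame(family_id = sprintf("f%04d", env$gain_counter),
                           ortholog_id = NA_character_,
                           strand = sample(c("+", "-"), 1L),
                           stringsAsFactors = FALSE)
        pos <- sample.int(n + 1L, 1L)
        genome <- rbind(genome[seq_len(pos - 1L), , drop = FALSE], newg,
                        if (pos <= n) genome[pos:n, , drop = FALSE])
      } else { # loss; never the genome's last member of a family
        fam_n <- table(genome$family_id)
        eligible <- which(fam_n[genome$family_id] >= 2L)
        if (length(eligible)) {
          genome <- genome[-eligible[sample.int(length(eligible), 1L)], , drop = FALSE]
        }
      }
    }
    rownames(genome) <- NULL
  }
  genome
}

#' Plant one tandem segmental duplication in a genome
#'
#' Copies the contiguous block of \code{len} genes starting at 0-based index
#' \code{start} (first contig) and inserts the copy immediately after the
#' source block. Copies keep their family ids but lose ortholog status,
#' reproducing the signature by which lineage-specific duplications inflate
#' naive syntenic-pair counts.
#'
#' @param genome a \code{\linkS4class{GeneOrderGenome}}.
#' @param start 0-based index of the block's first gene.
#' @param len block length (>= 1).
#' @return the modified \code{\linkS4class{GeneOrderGenome}}.
#' @export
plantSegmentalDuplication <- function(genome, start, len) {
  g <- geneTable(genome)
  ct <- g$contig[1]
  gc <- g[g$contig == ct, , drop = FALSE]
  stop_if(start < 0 || start + len > nrow(gc), "block outside the contig")
  block <- (start + 1L):(start + len)
  copy <- gc[block, , drop = FALSE]
  copy$ortholog_id <- NA_character_
  copy$gene_id <- paste0(copy$gene_id, "_dup")
  out <- rbind(gc[seq_len(start + len), , drop = FALSE], copy,
               if (start + len < nrow(gc)) gc[(start + len + 1L):nrow(gc), , drop = FALSE])
  out$gene_id <- make.unique(out$gene_id, sep = "_")
  out$index <- seq_len(nrow(out)) - 1L
  rest <- g[g$contig != ct, , drop = FALSE]
  GeneOrderGenome(genomeId(genome), rbind(out, rest))
}

#' Simulate gene trees by duplication-loss inside a species tree
#'
#' A single gene lineage enters the species-tree root and descends through
#' the tree. On every species-tree branch each gene lineage experiences a
#' Poisson number of events (\code{dupRate} duplications, \code{lossRate}
#' losses per full branch traversal, positions uniform): a duplication forks
#' the lineage in two, a loss kills it. Speciation nodes mirror the species
#' tree. Lineages extinct before the tips are pruned; surviving internal
#' nodes are labeled with their true event (\code{"S"} or \code{"D"}).
#'
#' @param speciesTree a \code{\linkS4class{SpeciesTree}}.
#' @param nTrees number of independent gene families to simulate.
#' @param dupRate,lossRate expected events per lineage per branch.
#' @param seed integer seed.
#' @return list with \code{trees} (list of \code{phylo}; tip labels
#'   \code{"<species>__g<k>"}, node labels \code{"S<j>"}/\code{"D<j>"}),
#'   \code{events} (list of data.frames: node_label, event, species_node) and
#'   \code{dupCounts} (integer vector of planted duplications surviving in
#'   each returned tree). Trees in which fewer than two genes survive are
#'   returned as \code{NULL} entries.
#' @export
simGeneTrees <- function(speciesTree, nTrees, dupRate = 0, lossRate = 0,
                         seed = NULL) {
  stop_if(dupRate < 0 || lossRate < 0, "rates must be >= 0")
  tr <- asPhylo(speciesTree)
  kids <- phylo_children(tr)
  n_tip <- length(tr$tip.label)
  blen <- function(node) {
    e <- match(node, tr$edge[, 2])
    if (is.na(e)) 0 else tr$edge.length[e]
  }
  with_seed(seed, {
    res <- lapply(seq_len(nTrees), function(k) {
      env <- new.env(); env$leaf <- 0L; env$node <- 0L
      # simulate a lineage entering the branch above `node` at fraction `at`
      # returns list(newick=..., events=data.frame) or NULL if extinct
      sim_branch <- function(node, at) {
        remain <- 1 - at
        total <- dupRate + lossRate
        n_ev <- if (total > 0) rpois(1L, total * remain) else 0L
        if (n_ev > 0L) {
          pos <- sort(runif(n_ev, at, 1))
          is_dup <- runif(n_ev) < if (total > 0) dupRate / total else 0
          for (i in seq_len(n_ev)) {
            if (!is_dup[i]) return(NULL)  # loss kills the lineage
            left <- sim_branch(node, pos[i])
            right <- sim_branch(node, pos[i])
            seg <- (pos[i] - at) * blen(node)
            if (is.null(left) && is.null(right)) return(NULL)
            if (is.null(left)) return(add_len(right, seg))
            if (is.null(right)) return(add_len(left, seg))
            env$node <- env$node + 1L
            lab <- sprintf("D%d", env$node)
            return(list(
              newick = sprintf("(%s,%s)%s:%g", left$newick, right$newick, lab, seg),
              events = rbind(left$events, right$events,
                             data.frame(node_label = lab, event = "D",
                                        species_node = node)),
              root_len = seg))
          }
        }
        seg <- remain * blen(node)
        below <- sim_node(node)
        if (is.null(below)) return(NULL)
        add_len(below, seg)
      }
      add_len <- function(x, extra) {
        # add `extra` to the root branch length of a newick fragment
        x$newick <- sub(":([0-9.eE+-]+)$", "", x$newick)
        x$newick <- sprintf("%s:%g", x$newick, x$root_len + extra)
        x$root_len <- x$root_len + extra
        x
      }
      sim_node <- function(node) {
        if (node <= n_tip) {
          env$leaf <- env$leaf + 1L
          return(list(newick = sprintf("%s__g%d:0", tr$tip.label[node], env$leaf),
                      events = data.frame(node_label = character(), event = character(),
                                          species_node = integer()), root_len = 0))
        }
        parts <- lapply(kids[[node]], function(ch) sim_branch(ch, 0))
        parts <- parts[!vapply(parts, is.null, TRUE)]
        if (length(parts) == 0L) return(NULL)
        if (length(parts) == 1L) return(parts[[1L]])
        env$node <- env$node + 1L
        lab <- sprintf("S%d", env$node)
        list(newick = sprintf("(%s,%s)%s:0",
                              parts[[1]]$newick, parts[[2]]$newick, lab),
             events = rbind(parts[[1]]$events, parts[[2]]$events,
                            data.frame(node_label = lab, event = "S",
                                       species_node = node)),
             root_len = 0)
      }
      root <- sim_node(n_tip + 1L)
      if (is.null(root) || !grepl(",", root$newick)) return(NULL)
      tree <- ape::read.tree(text = paste0(root$newick, ";"))
      list(tree = tree, events = root$events)
    })
    trees <- lapply(res, function(x) if (is.null(x)) NULL else x$tree)
    events <- lapply(res, function(x) if (is.null(x)) NULL else x$events)
    dupCounts <- vapply(events, function(e)
      if (is.null(e)) NA_integer_ else sum(e$event == "D"), 1L)
    list(trees = trees, events = events, dupCounts = dupCounts)
  })
}

#' Species of a gene-tree leaf
#'
#' Gene-tree tip labels follow \code{"<species>__g<k>"}; this strips the
#' gene suffix. Labels without the separator are returned unchanged.
#' @param labels character vector of tip labels.
#' @return character vector of species names.
#' @export
leafSpecies <- function(labels) sub("__g.*$", "", labels)

#' Simulate an alignment under an equal-exchangeability CTMC with
#' discrete-gamma rate heterogeneity
#'
#' Residues evolve along the tree under a 20-state continuous-time Markov
#' model with equal exchangeabilities and configurable stationary
#' frequencies (an amino-acid analogue of F81), with branch lengths in
#' expected substitutions per site. Each column draws a rate multiplier
#' from a discretized gamma distribution (\code{nCategories}
#' equal-probability categories, category-median rates rescaled to mean 1);
#' the column's true category and rate are recorded. Alignments are gap-free.
#'
#' @param tree a \code{\linkS4class{SpeciesTree}} or \code{phylo}.
#' @param nColumns number of columns (>= 1).
#' @param gammaShape gamma shape (> 0); \code{Inf} gives rate 1 everywhere.
#' @param nCategories number of rate categories.
#' @param freqs stationary frequencies over \code{AA20} (default uniform).
#' @param seed integer seed.
#' @return list with \code{alignment} (\code{\linkS4class{AlignmentMatrix}})
#'   and \code{truth} (data.frame: column, category, rate).
#' @export
simAlignment <- function(tree, nColumns, gammaShape = 1, nCategories = 16L,
                         freqs = NULL, seed = NULL) {
  stop_if(nColumns < 1, "nColumns must be >= 1")
  stop_if(!is.infinite(gammaShape) && gammaShape <= 0, "gammaShape must be > 0")
  tr <- asPhylo(tree)
  if (is.null(freqs)) freqs <- rep(1 / 20, 20)
  rates <- if (is.infinite(gammaShape)) rep(1, nCategories)
    else discreteGammaRates(gammaShape, nCategories)
  with_seed(seed, {
    cat_idx <- sample.int(nCategories, nColumns, replace = TRUE)
    rate <- rates[cat_idx]
    n_tip <- length(tr$tip.label)
    n_node <- max(tr$edge)
    states <- vector("list", n_node)
    root <- n_tip + 1L
    states[[root]] <- sample_stationary(nColumns, freqs)
    edges <- ape::reorder.phylo(tr, "cladewise")$edge
    lens <- ape::reorder.phylo(tr, "cladewise")$edge.length
    if (is.null(lens)) lens <- rep(0, nrow(edges))
    for (i in seq_len(nrow(edges))) {
      p <- edges[i, 1]; ch <- edges[i, 2]
      states[[ch]] <- evolve_states(states[[p]], lens[i] * rate, freqs)
    }
    m <- do.call(rbind, lapply(seq_len(n_tip), function(i) AA20[states[[i]]]))
    rownames(m) <- tr$tip.label
    list(alignment = AlignmentMatrix(m),
         truth = data.frame(column = seq_len(nColumns), category = cat_idx,
                            rate = rate))
  })
}

#' Bundle gene trees with sampled phylome metadata
#'
#' Attaches branch support, alignment length and alignment consistency
#' metadata to gene trees, producing the records the census filters consume.
#' Each distribution argument is either a single number (used for every
#' record) or a function \code{f(n)} returning \code{n} draws. The sampled
#' support is written onto every internal node of the tree.
#'
#' @param geneTrees list of \code{phylo} gene trees.
#' @param supportDist support values in [0,1].
#' @param consistencyDist consistency scores in [0,1].
#' @param lengthDist alignment lengths (>= 1).
#' @param seed integer seed.
#' @return list of \code{\linkS4class{PhylomeRecord}}.
#' @export
makePhylomeRecords <- function(geneTrees, supportDist = 1, consistencyDist = 0.9,
                               lengthDist = 600, seed = NULL) {
  geneTrees <- geneTrees[!vapply(geneTrees, is.null, TRUE)]
  stop_if(length(geneTrees) == 0L, "empty gene tree list")
  draw <- function(d, n) if (is.function(d)) d(n) else rep(d, n)
  n <- length(geneTrees)
  with_seed(seed, {
    supp <- draw(supportDist, n)
    cons <- draw(consistencyDist, n)
    len <- draw(lengthDist, n)
    stop_if(any(supp < 0 | supp > 1), "support must lie in [0,1]")
    stop_if(any(cons < 0 | cons > 1), "consistency must lie in [0,1]")
    stop_if(any(len < 1), "length must be >= 1")
    lapply(seq_len(n), function(i) {
      tr <- geneTrees[[i]]
      tr$node.label <- rep(format(supp[i], digits = 6), tr$Nnode)
      PhylomeRecord(tr, len[i], cons[i],
                    seedGene = tr$tip.label[1], treeId = sprintf("t%04d", i))
    })
  })
}

#' Replace a clade's sequences by random residues
#'
#' Column-by-column i.i.d. replacement of each focal species row, preserving
#' the row's gap pattern. \code{"composition_matched"} draws from the row's
#' own non-gap residue frequencies; \code{"uniform"} draws uniformly over
#' the 20 amino acids. Non-focal rows are untouched.
#'
#' @param alignment an \code{\linkS4class{AlignmentMatrix}}.
#' @param focalSpecies non-empty character vector of row names.
#' @param mode \code{"composition_matched"} (default) or \code{"uniform"}.
#' @param seed integer seed.
#' @return an \code{\linkS4class{AlignmentMatrix}}.
#' @export
randomizeCladeSequences <- function(alignment, focalSpecies,
                                    mode = c("composition_matched", "uniform"),
                                    seed = NULL) {
  mode <- match.arg(mode)
  stop_if(length(focalSpecies) == 0L, "focal species set must be non-empty")
  m <- alnMatrix(alignment)
  stop_if(!all(focalSpecies %in% rownames(m)), "focal species missing from alignment")
  with_seed(seed, {
    for (sp in focalSpecies) {
      row <- m[sp, ]
      keep <- row == GAP
      n_rep <- sum(!keep)
      if (n_rep == 0L) next
      if (mode == "composition_matched") {
        tab <- table(factor(row[!keep], levels = AA20))
        prob <- as.numeric(tab) / sum(tab)
      } else prob <- rep(1 / 20, 20)
      row[!keep] <- AA20[sample.int(20L, n_rep, replace = TRUE, prob = prob)]
      m[sp, ] <- row
    }
    AlignmentMatrix(m, alnPartitions(alignment), focalClade(alignment))
  })
}
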