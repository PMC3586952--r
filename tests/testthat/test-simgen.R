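test_that("species tree simulation is seeded, binary and covers tree space", {
  expect_error(simSpeciesTree(nSpecies = 1), "at least 2")
  # two species: the single rooted cherry
  t2 <- asPhylo(simSpeciesTree(nSpecies = 2, seed = 1))
  expect_equal(length(t2$tip.label), 2L)
  expect_true(ape::is.rooted(t2) && ape::is.binary.phylo(t2))
  # seed determinism
  a <- ape::write.tree(asPhylo(simSpeciesTree(nSpecies = 6, seed = 7)))
  b <- ape::write.tree(asPhylo(simSpeciesTree(nSpecies = 6, seed = 7)))
  expect_identical(a, b)
  # many seeds explore the 945 rooted labeled topologies without exceeding them
  shapes <- vapply(1:400, function(s)
    phylopos:::canonical_newick(asPhylo(simSpeciesTree(nSpecies = 6, seed = s))), "")
  expect_lte(length(unique(shapes)), 945L)
  expect_gt(length(unique(shapes)), 150L)
  # grouped generation keeps groups monophyletic
  st <- simSpeciesTree(groupSizes = small_group_sizes(), seed = 11)
  tr <- asPhylo(st)
  expect_true(ape::is.binary.phylo(tr))
  for (g in unique(groupMap(st))) {
    tips <- names(groupMap(st))[groupMap(st) == g]
    if (length(tips) > 1) expect_true(ape::is.monophyletic(tr, tips))
  }
})

test_that("gene-order evolution honors zero-event conservation and records truth", {
  st <- referenceSpeciesTree(small_group_sizes())
  expect_error(simGeneOrders(st, nGenes = 0), "nGenes")
  sim <- simGeneOrders(st, nGenes = 25, seed = 5)
  ref <- geneTable(sim$genomes[[1]])
  for (g in sim$genomes) {
    tab <- geneTable(g)
    expect_identical(tab$family_id, ref$family_id)
    expect_identical(tab$ortholog_id, ref$ortholog_id)
    expect_false(anyNA(tab$ortholog_id))
  }
  # ortholog sets partition all genes
  all_ids <- unlist(lapply(sim$genomes, function(g) geneTable(g)$gene_id))
  expect_setequal(unlist(sim$truth$orthologSets), all_ids)
  expect_equal(sum(lengths(sim$truth$orthologSets)), length(all_ids))
})

test_that("a planted tandem duplication stays lineage specific", {
  st <- referenceSpeciesTree(small_group_sizes())
  sim <- simGeneOrders(st, nGenes = 20, seed = 8)
  target_sp <- names(sim$genomes)[1]
  sim$genomes[[target_sp]] <- plantSegmentalDuplication(sim$genomes[[target_sp]],
                                                        start = 4, len = 3)
  multi <- vapply(sim$genomes, function(g)
    any(table(geneTable(g)$family_id) > 1), TRUE)
  expect_true(multi[[target_sp]])
  expect_false(any(multi[names(multi) != target_sp]))
  # copies share families but carry no ortholog id
  tab <- geneTable(sim$genomes[[target_sp]])
  expect_equal(sum(is.na(tab$ortholog_id)), 3L)
})

test_that("strict synteny decays with increasing inversion rate", {
  rates <- c(0, 0.5, 2)
  mean_scores <- vapply(rates, function(rv) {
    scores <- vapply(1:8, function(rep) {
      st <- simSpeciesTree(nSpecies = 2, seed = 100 * rep)
      sim <- simGeneOrders(st, nGenes = 40, invRate = rv, seed = 100 * rep + 1)
      r <- syntenyCompare(sim$genomes[[1]], sim$genomes[[2]], "strict")
      r$normalized_corrected
    }, 1.0)
    mean(scores)
  }, 1.0)
  expect_true(all(diff(mean_scores) <= 0))
  expect_gt(mean_scores[1], mean_scores[3])
})

test_that("gene-tree simulation reproduces the species tree without events", {
  st <- referenceSpeciesTree(small_group_sizes())
  gt <- simGeneTrees(st, nTrees = 4, seed = 2)
  for (tr in gt$trees) {
    expect_equal(length(tr$tip.label), length(speciesNames(st)))
    ut <- ape::unroot(tr)
    ut$tip.label <- leafSpecies(ut$tip.label)
    expect_equal(phangorn::RF.dist(ut, ape::unroot(asPhylo(st))), 0)
  }
  expect_true(all(gt$dupCounts == 0))
  # duplication events appear and are recorded when the rate is positive
  gt2 <- simGeneTrees(st, nTrees = 30, dupRate = 0.1, seed = 3)
  expect_gt(sum(gt2$dupCounts, na.rm = TRUE), 0)
  for (i in seq_along(gt2$trees)) {
    tr <- gt2$trees[[i]]
    if (is.null(tr)) next
    expect_equal(sum(startsWith(tr$node.label, "D")), gt2$dupCounts[i])
  }
})

test_that("alignment simulation is a seeded CTMC with planted rate categories", {
  tr <- ape::read.tree(text = "((a:0,b:0):0,(c:0,d:0):0);")
  sim <- simAlignment(tr, nColumns = 50, gammaShape = 1, seed = 4)
  m <- alnMatrix(sim$alignment)
  # zero branch lengths: all sequences identical to the root sequence
  expect_true(all(apply(m, 2, function(col) length(unique(col)) == 1L)))
  # determinism: byte-identical FASTA
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  st <- referenceSpeciesTree(small_group_sizes())
  writeAlignment(simAlignment(st, 100, gammaShape = 0.7, seed = 9)$alignment, f1)
  writeAlignment(simAlignment(st, 100, gammaShape = 0.7, seed = 9)$alignment, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_error(simAlignment(st, 10, gammaShape = -1), "gammaShape")
  expect_error(simAlignment(st, 0), "nColumns")
})

test_that("slow categories change less often than fast ones", {
  # two-leaf tree of total length 0.1; compare per-column mismatch rates
  tr <- ape::read.tree(text = "(a:0.05,b:0.05);")
  sim <- simAlignment(tr, nColumns = 10000, gammaShape = 0.5,
                      nCategories = 16, seed = 12)
  m <- alnMatrix(sim$alignment)
  diffs <- m["a", ] != m["b", ]
  slow <- sim$truth$category <= 4
  fast <- sim$truth$category >= 13
  expect_lt(mean(diffs[slow]), mean(diffs[fast]))
})

test_that("phylome records bundle metadata and respect the filter thresholds", {
  st <- referenceSpeciesTree(small_group_sizes())
  gt <- simGeneTrees(st, nTrees = 5, seed = 1)
  expect_error(makePhylomeRecords(list()), "empty")
  recs <- makePhylomeRecords(gt$trees, supportDist = 1, consistencyDist = 0.9,
                             lengthDist = 600, seed = 2)
  gm <- groupMap(st)
  for (r in recs) {
    f <- applyRecordFilters(r, "Microsporidia", gm)
    expect_true(all(f))
  }
  # constant length 400 fails the length filter everywhere
  recs2 <- makePhylomeRecords(gt$trees, lengthDist = 400, seed = 2)
  for (r in recs2)
    expect_false(applyRecordFilters(r, "Microsporidia", gm)[["length"]])
  # metadata identical across runs with one seed
  draw <- function(n) runif(n, 0.5, 1)
  m1 <- makePhylomeRecords(gt$trees, supportDist = draw, seed = 33)
  m2 <- makePhylomeRecords(gt$trees, supportDist = draw, seed = 33)
  expect_identical(vapply(m1, function(r) r@tree$node.label[1], ""),
                   vapply(m2, function(r) r@tree$node.label[1], ""))
})

test_that("clade randomization preserves non-focal rows, gaps and composition", {
  st <- referenceSpeciesTree(small_group_sizes())
  sim <- simAlignment(st, 10000, gammaShape = Inf, seed = 21)
  m <- alnMatrix(sim$alignment)
  focal <- names(groupMap(st))[groupMap(st) == "Microsporidia"]
  # inject a gap pattern into one focal row
  gaps <- seq(5, 9000, by = 13)
  m[focal[1], gaps] <- "-"
  aln <- AlignmentMatrix(m, alnPartitions(sim$alignment))
  expect_error(randomizeCladeSequences(aln, character()), "non-empty")
  rnd <- randomizeCladeSequences(aln, focal, seed = 22)
  m2 <- alnMatrix(rnd)
  nonfocal <- setdiff(rownames(m), focal)
  expect_identical(m2[nonfocal, ], m[nonfocal, ])
  expect_identical(which(m2[focal[1], ] == "-"), which(m[focal[1], ] == "-"))
  # composition-matched frequencies within 2% of the original row's
  orig <- table(factor(m[focal[2], ], levels = phylopos:::AA20)) / ncol(m)
  new <- table(factor(m2[focal[2], ], levels = phylopos:::AA20)) / ncol(m)
  expect_lt(max(abs(orig - new)), 0.02)
})
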