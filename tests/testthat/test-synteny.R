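test_that("relaxed detection on identical colinear genomes finds every close pair", {
  q <- colinear_genome("Q", 10)
  t <- colinear_genome("T", 10)
  pairs <- findRelaxedPairs(q, t)
  # gaps 0..3 between 10 colinear genes: 9 + 8 + 7 + 6 = 30 pairs
  expect_equal(nrow(pairs), 30L)
  expect_identical(pair_keys(pairs), oracle_relaxed_keys(q, t))
})

test_that("relaxed detection enforces the query, target and window limits", {
  # query pair separated by 4 intervening genes is never reported
  q <- colinear_genome("Q", 12)
  t <- colinear_genome("T", 12)
  pairs <- findRelaxedPairs(q, t)
  gaps <- abs(match(pairs$query_g2, geneTable(q)$gene_id) -
                match(pairs$query_g1, geneTable(q)$gene_id)) - 1L
  expect_true(all(gaps <= 3))
  # target homologs separated by 5 genes are not reported: move f02's target
  # homolog far from f01's
  tt <- geneTable(t)
  perm <- c(1L, 8L, 3L, 4L, 5L, 6L, 7L, 2L, 9L:12L) # swap positions of f02,f08
  tt$family_id <- tt$family_id[perm]
  tt$ortholog_id <- tt$ortholog_id[perm]
  t2 <- GeneOrderGenome("T", tt)
  pairs2 <- findRelaxedPairs(q, t2)
  expect_false(any(pairs2$family_1 == "f01" & pairs2$family_2 == "f02"))
  expect_identical(pair_keys(pairs2), oracle_relaxed_keys(q, t2))
})

test_that("strict detection matches the rules in both intervening modes", {
  q <- colinear_genome("Q", 10)
  t <- colinear_genome("T", 10)
  lit <- findStrictPairs(q, t, "literal")
  # literal rule forces adjacency on colinear genomes: 9 adjacent pairs
  expect_equal(nrow(lit), 9L)
  expect_identical(pair_keys(lit), oracle_strict_keys(q, t, literal = TRUE))
  ic <- findStrictPairs(q, t, "interval_consistent")
  expect_equal(nrow(ic), 30L)
  expect_identical(pair_keys(ic), oracle_strict_keys(q, t, literal = FALSE))
})

test_that("strict detection requires a shared orientation", {
  q <- colinear_genome("Q", 6)
  qt <- geneTable(q)
  qt$strand[3] <- "-"   # g3 now opposite to its neighbors
  q2 <- GeneOrderGenome("Q", qt)
  t <- colinear_genome("T", 6)
  pairs <- findStrictPairs(q2, t)
  expect_false(any(pairs$query_g1 == qt$gene_id[3] |
                     pairs$query_g2 == qt$gene_id[3]))
  # whole-pair inversion in the target is still accepted
  tt <- geneTable(t)
  tt$strand <- rep("-", 6)
  t2 <- GeneOrderGenome("T", tt)
  expect_equal(nrow(findStrictPairs(q, t2, "literal")), 5L)
})

test_that("detectors agree with the brute-force oracle on random genome pairs", {
  for (s in 1:6) {
    gp <- random_genome_pair(60, seed = s)
    q <- gp[[1]]; t <- gp[[2]]
    expect_identical(pair_keys(findRelaxedPairs(q, t)), oracle_relaxed_keys(q, t))
    expect_identical(pair_keys(findStrictPairs(q, t, "literal")),
                     oracle_strict_keys(q, t, literal = TRUE))
    expect_identical(pair_keys(findStrictPairs(q, t, "interval_consistent")),
                     oracle_strict_keys(q, t, literal = FALSE))
  }
})

test_that("paralog collapsing counts each (query pair, family pair) once", {
  q <- colinear_genome("Q", 6)
  t <- colinear_genome("T", 6)
  # triplicate the f02-f03 block in the target, tandem
  t2 <- plantSegmentalDuplication(t, start = 1, len = 2)
  t3 <- plantSegmentalDuplication(t2, start = 1, len = 2)
  pairs <- findRelaxedPairs(q, t3)
  hit <- pairs[pairs$family_1 == "f02" & pairs$family_2 == "f03" &
                 pairs$query_g1 == geneTable(q)$gene_id[2] &
                 pairs$query_g2 == geneTable(q)$gene_id[3], ]
  expect_gte(nrow(hit), 3L)   # several target loci from the duplication
  collapsed <- collapseParalogousPairs(pairs)
  hit_c <- collapsed[collapsed$family_1 == "f02" & collapsed$family_2 == "f03" &
                       collapsed$query_g1 == geneTable(q)$gene_id[2] &
                       collapsed$query_g2 == geneTable(q)$gene_id[3], ]
  expect_equal(nrow(hit_c), 1L)
  # correction monotonicity, equality without duplicated families
  expect_lte(nrow(collapsed), nrow(pairs))
  clean <- findRelaxedPairs(q, t)
  expect_identical(collapseParalogousPairs(clean), clean)
})

test_that("planted duplications are fully corrected back to pre-duplication counts", {
  for (s in 1:5) {
    st <- simSpeciesTree(nSpecies = 2, seed = 300 + s)
    sim <- simGeneOrders(st, nGenes = 30, seed = 400 + s)
    q <- sim$genomes[[1]]; t0 <- sim$genomes[[2]]
    before <- nrow(collapseParalogousPairs(findRelaxedPairs(q, t0)))
    t1 <- plantSegmentalDuplication(t0, start = 10, len = 4)
    raw <- findRelaxedPairs(q, t1)
    after <- nrow(collapseParalogousPairs(raw))
    expect_gt(nrow(raw), before)  # duplication inflates the raw count
    expect_equal(after, before)
  }
})

test_that("normalization is pairs per 1000 shared genes", {
  expect_equal(normalizePairCount(5, 1000), 5.0)
  expect_equal(normalizePairCount(0, 123), 0.0)
  expect_equal(normalizePairCount(30, 10), 3000.0)
  expect_error(normalizePairCount(1, 0), "shared")
})

test_that("shared-gene denominators follow the gene-level definitions", {
  q <- colinear_genome("Q", 8)
  t <- colinear_genome("T", 8)
  tt <- geneTable(t)[1:5, ]; tt$index <- 0:4
  t2 <- GeneOrderGenome("T", tt)
  expect_equal(sharedHomologs(q, t2), 5L)
  expect_equal(sharedOrthologs(q, t2), 5L)
  # a duplicated family still counts each query gene once; a duplicated
  # ortholog id drops out of the 1:1 map
  t3 <- plantSegmentalDuplication(t2, start = 0, len = 1)
  expect_equal(sharedHomologs(q, t3), 5L)
  expect_equal(sharedOrthologs(q, t3), 5L) # copy has NA ortholog id
})

test_that("Kruskal-Wallis comparison matches the hand-computed rank formula", {
  expect_error(compareGroupsKW(list(a = 1:3)), "2 groups")
  allsame <- compareGroupsKW(list(a = c(2, 2), b = c(2, 2), c = c(2, 2)))
  expect_equal(allsame$H, 0)
  expect_equal(allsame$p.value, 1)
  # groups {1,2,3}, {4,5,6}, {7,8,9}: ranks are the values, no ties
  # H = 12/(N(N+1)) * sum Rj^2/nj - 3(N+1) = 12/90*(36+225+576)/3 - 30 = 7.2
  kw <- compareGroupsKW(list(g1 = 1:3, g2 = 4:6, g3 = 7:9))
  expect_equal(kw$H, 7.2)
  expect_equal(kw$df, 2)
  expect_equal(kw$p.value, stats::pchisq(7.2, 2, lower.tail = FALSE))
})

test_that("p-values are calibrated under permuted group labels", {
  set.seed(99)
  vals <- rnorm(24)
  ps <- replicate(400, {
    g <- sample(rep(c("a", "b", "c"), 8))
    compareGroupsKW(split(vals, g))$p.value
  })
  # uniformity checked through empirical rejection rates (the chi-square
  # p-values are mildly discrete, so pointwise binomial bands are used)
  expect_lt(abs(mean(ps <= 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / 400))
  expect_lt(abs(mean(ps <= 0.25) - 0.25), 3 * sqrt(0.25 * 0.75 / 400))
  expect_lt(abs(mean(ps <= 0.50) - 0.50), 3 * sqrt(0.50 * 0.50 / 400))
})

test_that("synteny comparison reports both raw and corrected normalized scores", {
  q <- colinear_genome("Q", 10)
  t <- colinear_genome("T", 10)
  res <- syntenyCompare(q, t, "relaxed")
  expect_equal(res$raw_count, 30L)
  expect_equal(res$shared, 10L)
  expect_equal(res$normalized_raw, 3000)
  expect_lte(res$corrected_count, res$raw_count)
  res2 <- syntenyCompare(q, t, "strict")
  expect_equal(res2$raw_count, 9L)
  expect_equal(res2$normalized_raw, 900)
})
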