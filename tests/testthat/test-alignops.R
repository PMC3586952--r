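aa <- phylopos:::AA20

test_that("single-copy family selection equals the direct predicate scan", {
  set.seed(3)
  counts <- matrix(rpois(40 * 22, 0.8), 40, 22,
                   dimnames = list(sprintf("fam%02d", 1:40),
                                   sprintf("sp%02d", 1:22)))
  kept <- selectSingleCopyFamilies(counts, minSpecies = 18)
  oracle <- rownames(counts)[apply(counts, 1, function(r)
    all(r <= 1) && sum(r >= 1) >= 18)]
  expect_identical(kept, oracle)
  # examples: present once in 20 of 22 -> kept; any two-copy species -> out
  m <- rbind(good = c(rep(1, 20), 0, 0), dupl = c(2, rep(1, 21)))
  colnames(m) <- sprintf("sp%02d", 1:22)
  expect_identical(selectSingleCopyFamilies(m, 18), "good")
})

test_that("concatenation appends columns, fills gaps and round-trips partitions", {
  sp <- c("s1", "s2", "s3")
  a1 <- AlignmentMatrix(matrix(sample(aa, 300, TRUE), 3, 100,
                               dimnames = list(sp, NULL)))
  a2 <- AlignmentMatrix(matrix(sample(aa, 100, TRUE), 2, 50,
                               dimnames = list(c("s1", "s3"), NULL)))
  cc <- concatenateAlignments(list(f1 = a1, f2 = a2), sp)
  expect_equal(dim(cc), c(3L, 150L))
  expect_equal(alnPartitions(cc), rep(c("f1", "f2"), c(100, 50)))
  # species missing from family 2 has 50 trailing gaps
  expect_true(all(alnMatrix(cc)["s2", 101:150] == "-"))
  # per-partition extraction recovers each input
  expect_identical(alnMatrix(extractPartition(cc, "f1")), alnMatrix(a1))
  expect_identical(alnMatrix(extractPartition(cc, "f2"))[c("s1", "s3"), ],
                   alnMatrix(a2))
  dup <- AlignmentMatrix(matrix("A", 2, 3, dimnames = list(c("s1", "s1"), NULL)))
  expect_error(concatenateAlignments(list(f = dup), sp), "duplicate")
})

test_that("trimming drops invariant and focal-gap columns, and is idempotent", {
  m <- rbind(s1 = c("A", "A", "C", "-", "A"),
             s2 = c("A", "C", "C", "D", "A"),
             f1 = c("A", "C", "-", "E", "-"),
             f2 = c("A", "D", "-", "F", "-"))
  aln <- AlignmentMatrix(m, focalClade = c("f1", "f2"))
  tr <- trimUninformative(aln)
  # col 1 invariant; col 3 focal all-gap; col 5 focal all-gap
  oracle <- which(!(apply(m, 2, function(col)
    length(unique(col[col != "-"])) <= 1) |
    apply(m[c("f1", "f2"), ], 2, function(col) all(col == "-"))))
  expect_equal(ncol(tr), length(oracle))
  expect_identical(alnMatrix(tr), m[, oracle])
  expect_identical(alnMatrix(trimUninformative(tr)), alnMatrix(tr))
  # random-matrix oracle scan
  set.seed(8)
  big <- matrix(sample(c(aa, "-"), 6 * 200, TRUE, prob = c(rep(1, 20), 6)),
                6, 200, dimnames = list(c(sprintf("s%d", 1:4), "f1", "f2"), NULL))
  baln <- AlignmentMatrix(big, focalClade = c("f1", "f2"))
  btr <- trimUninformative(baln)
  keep <- !(apply(big, 2, function(col) length(unique(col[col != "-"])) <= 1) |
              apply(big[c("f1", "f2"), ], 2, function(col) all(col == "-")))
  expect_identical(alnMatrix(btr), big[, keep])
})

test_that("pruning log-likelihoods match closed forms and the state-sum oracle", {
  # single leaf, equal frequencies
  a1 <- AlignmentMatrix(matrix("A", 1, 1, dimnames = list("a", NULL)))
  t1 <- ape::read.tree(text = "(a:0.3);")
  expect_equal(computeSiteLoglik(a1, t1, Inf, 1)[1, 1], log(1 / 20))
  # two identical residues at branch length zero
  a2 <- AlignmentMatrix(matrix("W", 2, 1, dimnames = list(c("a", "b"), NULL)))
  t2 <- ape::read.tree(text = "(a:0,b:0);")
  expect_equal(computeSiteLoglik(a2, t2, Inf, 1)[1, 1], log(1 / 20))
  # exhaustive internal-state oracle, four leaves
  set.seed(12)
  for (i in 1:5) {
    tr <- ape::rtree(4)
    tr$tip.label <- letters[1:4]
    col <- setNames(sample(aa, 4, TRUE), letters[1:4])
    aln <- AlignmentMatrix(matrix(col, 4, 1, dimnames = list(letters[1:4], NULL)))
    got <- computeSiteLoglik(aln, tr, Inf, 1)[1, 1]
    want <- oracle_column_loglik(tr, col)
    expect_equal(got, want, tolerance = 1e-10)
  }
  expect_error(computeSiteLoglik(
    AlignmentMatrix(matrix(character(), 1, 0, dimnames = list("a", NULL))),
    t1), "zero-length")
})

test_that("gaps are missing data in the likelihood", {
  t2 <- ape::read.tree(text = "(a:0.4,b:0.2);")
  full <- AlignmentMatrix(matrix(c("A", "-"), 2, 1,
                                 dimnames = list(c("a", "b"), NULL)))
  # one gapped leaf: the column reduces to the stationary probability of 'A'
  expect_equal(computeSiteLoglik(full, t2, Inf, 1)[1, 1], log(1 / 20))
})

test_that("rate-category assignment is a normalized posterior argmax", {
  st <- referenceSpeciesTree(small_group_sizes(), brlen = 0.2)
  sim <- simAlignment(st, 400, gammaShape = 0.6, nCategories = 16, seed = 31)
  sl <- computeSiteLoglik(sim$alignment, st, gammaShape = 0.6, nCategories = 16)
  asg <- assignRateCategories(sl)
  expect_true(all(abs(rowSums(asg$posterior) - 1) < 1e-9))
  expect_true(all(asg$category >= 1 & asg$category <= 16))
  # an invariant column on a tree with positive lengths goes to category 1
  inv <- AlignmentMatrix(matrix("L", length(speciesNames(st)), 1,
                                dimnames = list(speciesNames(st), NULL)))
  sli <- computeSiteLoglik(inv, st, gammaShape = 0.6, nCategories = 16)
  expect_equal(assignRateCategories(sli)$category, 1L)
  # recovery: assigned categories correlate with the planted ones
  expect_gt(cor(sim$truth$category, asg$category, method = "spearman"), 0.5)
})

test_that("fastest-site removal drops exactly the top categories", {
  st <- referenceSpeciesTree(small_group_sizes(), brlen = 0.2)
  sim <- simAlignment(st, 300, gammaShape = 0.6, nCategories = 16, seed = 41)
  sl <- computeSiteLoglik(sim$alignment, st, gammaShape = 0.6, nCategories = 16)
  asg <- assignRateCategories(sl)
  expect_identical(alnMatrix(removeFastestSites(sim$alignment, asg, 0)),
                   alnMatrix(sim$alignment))
  r2 <- removeFastestSites(sim$alignment, asg, 2)
  expect_false(any(asg$category[asg$category <= 14] > 14))
  expect_equal(ncol(r2), sum(asg$category <= 14))
  expect_error(removeFastestSites(sim$alignment, asg, 16), "smaller")
  # mean planted rate of survivors never increases with k
  mrate <- vapply(c(0, 2, 4, 6, 8), function(k)
    mean(sim$truth$rate[asg$category <= 16 - k]), 1.0)
  expect_true(all(diff(mrate) <= 0))
})

test_that("clade-variability partitioning routes columns by distinct focal residues", {
  m <- rbind(o1 = rep("A", 5),
             f1 = c("A", "A", "A", "A", "-"),
             f2 = c("A", "C", "C", "C", "-"),
             f3 = c("A", "C", "D", "D", "-"),
             f4 = c("A", "C", "D", "E", "-"),
             f5 = c("A", "A", "A", "F", "-"))
  aln <- AlignmentMatrix(m, focalClade = c("f1", "f2", "f3", "f4", "f5"))
  parts <- partitionByCladeVariability(aln)
  # focal residue counts per column: 1, 2, 3, 5, all-gap
  expect_equal(vapply(parts, ncol, 1L), c(2L, 1L, 0L, 1L))
  # all-gap focal column excluded entirely
  expect_equal(sum(vapply(parts, ncol, 1L)), 4L)
})

test_that("alphabet recoding preserves shape and never splits residue classes", {
  st <- referenceSpeciesTree(small_group_sizes())
  sim <- simAlignment(st, 120, gammaShape = Inf, seed = 51)
  ident <- setNames(aa, aa)
  expect_identical(alnMatrix(recodeAlphabet(sim$alignment, ident)),
                   alnMatrix(sim$alignment))
  rec <- recodeAlphabet(sim$alignment)
  expect_equal(dim(rec), dim(sim$alignment))
  expect_lte(length(setdiff(unique(as.vector(alnMatrix(rec))), "-")), 4L)
  # distinct symbols per column never exceed distinct residues before
  before <- apply(alnMatrix(sim$alignment), 2, function(c) length(unique(c)))
  after <- apply(alnMatrix(rec), 2, function(c) length(unique(c)))
  expect_true(all(after <= before))
  expect_error(recodeAlphabet(sim$alignment, c(A = "x")), "unmapped")
})

test_that("gamma-shape grid estimation lands near the generating shape", {
  st <- referenceSpeciesTree(small_group_sizes(), brlen = 0.25)
  sim <- simAlignment(st, 500, gammaShape = 0.5, nCategories = 8, seed = 61)
  est <- estimateGammaShape(sim$alignment, st, nCategories = 8,
                            grid = c(0.3, 0.5, 1, 2, 5))
  expect_lte(est, 1)
})
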