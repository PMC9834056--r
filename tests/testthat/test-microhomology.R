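test_that("match grids score base identity, with N matching nothing", {
  g <- junctionMatchGrid("AAAACCCC", "CCCCAAAA")
  expect_equal(sum(g), 32)
  expect_equal(mean(g), 0.5)
  expect_equal(g, oracleMatchGrid("AAAACCCC", "CCCCAAAA"),
               ignore_attr = TRUE)
  expect_true(all(junctionMatchGrid("AAAAAAAA", "AAAAAAAA") == 1))
  expect_true(all(junctionMatchGrid("AAAAAAAA", "GGGGGGGG") == 0))
  expect_true(all(junctionMatchGrid("NNNNNNNN", "NNNNNNNN") == 0))
})

test_that("match grids agree with the brute-force oracle on random flanks", {
  set.seed(51)
  for (i in 1:500) {
    l <- randomSeq(8, c("A", "C", "G", "T", "N"))
    r <- randomSeq(8, c("A", "C", "G", "T", "N"))
    expect_equal(junctionMatchGrid(l, r), oracleMatchGrid(l, r),
                 ignore_attr = TRUE)
  }
})

test_that("grid aggregation is the element-wise mean", {
  ones <- matrix(1, 8, 8); zeros <- matrix(0, 8, 8)
  hg <- aggregateGrids(list(ones, zeros))
  expect_true(all(gridMatrix(hg) == 0.5))
  expect_equal(hg@n, 2L)
  single <- aggregateGrids(list(ones))
  expect_true(all(gridMatrix(single) == 1))
  expect_error(aggregateGrids(list()), "zero grids")

  set.seed(52)
  gs <- lapply(1:100, function(i) matrix(rbinom(64, 1, 0.3), 8, 8))
  expect_equal(gridMatrix(aggregateGrids(gs)), Reduce(`+`, gs) / 100,
               ignore_attr = TRUE)
})

test_that("BH adjustment reproduces the hand-applied step-up", {
  expect_equal(bhAdjust(0.03), 0.03)
  expect_equal(bhAdjust(c(0.001, 0.02, 0.03, 0.05)),
               c(0.004, 0.04, 0.04, 0.05))
  expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
  set.seed(53)
  for (i in 1:500) {
    p <- runif(sample(2:64, 1))
    expect_equal(bhAdjust(p), oracleBH(p), tolerance = 1e-12)
  }
  # matrix shape preserved; q >= p bin-wise
  pm <- matrix(runif(64), 8, 8)
  qm <- bhAdjust(pm)
  expect_equal(dim(qm), c(8, 8))
  expect_true(all(qm >= pm))
})

test_that("microhomology length scans junction-spanning runs both ways", {
  # engineered: A:0 matches B:-1 but A:+1 differs from B:-2 -> length 1
  left <- "GGGGTACC"   # labels -4..-1 = GGGG, 0..+3 = TACC
  right <- "CCCTAAAA"  # labels -4..-1 = CCCT, 0..+3 = AAAA
  # direction 1: L0 (T) vs R-1 (T) match; L+1 (A) vs R-2 (C) mismatch
  expect_equal(microhomologyLength(left = left, right = right), 1L)
  # no matching first base either direction
  expect_equal(microhomologyLength(left = "GGGGTTTT", right = "CCCCAAAA"), 0L)
  # N breaks a run
  expect_equal(microhomologyLength(left = "GGGGNTTT", right = "CCCNAAAA"), 0L)
  set.seed(54)
  for (i in 1:500) {
    l <- randomSeq(8); r <- randomSeq(8)
    expect_identical(microhomologyLength(left = l, right = r),
                     as.integer(oracleMhLength(l, r)))
  }
})

test_that("planted microhomology lengths are recovered exactly", {
  for (m in 0:4) {
    cfg <- simConfig(seed = 60 + m, nTranslocations = 40, nDeletions = 0,
                     nInheritedTranslocations = 0, nInheritedDeletions = 0,
                     mhDist = stats::setNames(1, as.character(m)),
                     templatedInsertRate = 0, miscInsertRate = 0)
    sim <- simulateStudy(cfg)
    trl <- canonicalizeFusions(pairMates(sim$offspring$breakends))
    fl <- extractFlanks(trl, sim$genome)
    expect_true(all(microhomologyLength(fl) == m), info = paste("m =", m))
  }
})

test_that("permutation p-values hit the closed-form extremes", {
  # a planted always-match junction bin can never be reached by chance at
  # n = 50, so its p is exactly (0 + 1) / (nPerm + 1); the forced-mismatch
  # bin at frequency 0 is below every permuted value, so its p is 1
  cfg <- simConfig(seed = 71, nTranslocations = 50, nDeletions = 0,
                   nInheritedTranslocations = 0, nInheritedDeletions = 0,
                   mhDist = c(`1` = 1), templatedInsertRate = 0,
                   miscInsertRate = 0, typeMix = c(`1` = 1))
  sim <- simulateStudy(cfg)
  trl <- canonicalizeFusions(pairMates(sim$offspring$breakends))
  fl <- extractFlanks(trl, sim$genome)
  grid <- observedGrid(fl)
  expect_equal(gridMatrix(grid)["0", "-1"], 1)   # planted mh-1 bin
  p <- permutationNullGrid(grid, fl$ttype, sim$genome, nPerm = 999, seed = 3)
  expect_equal(p["0", "-1"], 1 / 1000)
  expect_equal(p["-1", "0"], 1)                  # forced mismatch, frequency 0
})

test_that("permutation nulls are seed-deterministic and calibrated", {
  cfg <- simConfig(seed = 72, nTranslocations = 40, nDeletions = 0,
                   nInheritedTranslocations = 0, nInheritedDeletions = 0,
                   mhDist = NULL, templatedInsertRate = 0, miscInsertRate = 0)
  sim <- simulateStudy(cfg)
  trl <- canonicalizeFusions(pairMates(sim$offspring$breakends))
  fl <- extractFlanks(trl, sim$genome)
  grid <- observedGrid(fl)
  p1 <- permutationNullGrid(grid, fl$ttype, sim$genome, nPerm = 499, seed = 9)
  p2 <- permutationNullGrid(grid, fl$ttype, sim$genome, nPerm = 499, seed = 9)
  expect_identical(p1, p2)
  # null data: roughly uniform p-values
  expect_lt(abs(mean(p1 < 0.05) - 0.05), 0.08)
})

test_that("base composition percentages and background behave", {
  # all flanks share an A at label 0 -> 100% A there
  L <- matrix(rep(utf8ToInt("GGGGACCC"), 5), 5, 8, byrow = TRUE)
  R <- matrix(rep(utf8ToInt("TTTTACGT"), 5), 5, 8, byrow = TRUE)
  g <- toyGenome(c1 = randomSeq(5000))
  bc <- baseComposition(list(left = L, right = R, ok = rep(TRUE, 5)), g,
                        nPerm = 200, seed = 2)
  expect_equal(bc@observed["A", "0"], 100)
  expect_true(all(abs(colSums(bc@observed) - 100) < 1e-9))
  expect_true(all(abs(colSums(bc@background) - 100) < 1e-9))

  # uniform genome background: each base ~25% (resampling bound)
  set.seed(55)
  gu <- toyGenome(c1 = randomSeq(100000))
  Lr <- matrix(sample(utf8ToInt("ACGT"), 50 * 8, replace = TRUE), 50, 8)
  bc2 <- baseComposition(list(left = Lr, right = Lr, ok = rep(TRUE, 50)), gu,
                         nPerm = 25000, seed = 5)
  expect_true(all(abs(bc2@background - 25) < 0.5))
})
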