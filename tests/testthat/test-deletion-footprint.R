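test_that("size filter keeps the inclusive 8-200 bp bounds and is idempotent", {
  d <- makeDels("c1", c(100, 300, 600, 1000), c(106, 307, 799, 1200))
  out <- sizeFilter(d)   # lengths 7, 8, 200, 201
  expect_equal(GenomicRanges::width(out), c(8, 200))
  expect_equal(length(sizeFilter(out)), 2)
  expect_equal(length(sizeFilter(makeDels("c1", integer(0), integer(0)))), 0)
})

test_that("deletion homology is the LCP of deleted and following sequence", {
  #            123456789012345678
  g <- toyGenome(c1 = "AGGCCTTAATTGGCCAAT")
  # delete TTAA (6..9); following retained is TTGG... -> LCP = 2
  d <- makeDels("c1", 6, 9)
  # guard: base before (C at 5) != last deleted (A at 9) -> no left shift
  jx <- deletionHomologyLength(d, g)
  expect_equal(jx$deletedSeq, "TTAA")
  expect_equal(jx$homologyLen, 2L)

  g2 <- toyGenome(c1 = "AGCCCCAAAAGG")
  jx2 <- deletionHomologyLength(makeDels("c1", 3, 6), g2)  # CCCC then AAAA
  expect_equal(jx2$homologyLen, 0L)
})

test_that("deletions are left-aligned before homology is measured", {
  # TACGACGT: deleting ACG at 5..7 is shiftable to 2..4 (identical allele)
  g <- toyGenome(c1 = "TACGACGTTTTT")
  jxA <- deletionHomologyLength(makeDels("c1", 5, 7), g)
  jxB <- deletionHomologyLength(makeDels("c1", 2, 4), g)
  expect_equal(jxA$start, jxB$start)
  expect_equal(jxA$homologyLen, jxB$homologyLen)
  # oracle on the aligned coordinates
  s <- as.character(g[["c1"]])
  expect_equal(jxB$homologyLen,
               oracleLcp(substr(s, jxB$start, jxB$end),
                         substr(s, jxB$end + 1, nchar(s))))
})

test_that("homology length matches the LCP oracle on random deletions", {
  set.seed(81)
  for (i in 1:500) {
    s <- randomSeq(400)
    st <- sample(50:200, 1); en <- st + sample(8:60, 1)
    g <- toyGenome(c1 = s)
    jx <- deletionHomologyLength(makeDels("c1", st, en), g)
    expect_equal(jx$homologyLen,
                 oracleLcp(substr(s, jx$start, jx$end),
                           substr(s, jx$end + 1, nchar(s))),
                 info = i)
  }
})

test_that("planted deletion homology is recovered exactly for h in 0..7", {
  for (h in 0:7) {
    cfg <- simConfig(seed = 90 + h, nTranslocations = 0, nDeletions = 100,
                     nInheritedTranslocations = 0, nInheritedDeletions = 0,
                     deletionHomologyDist = stats::setNames(1, as.character(h)))
    sim <- simulateStudy(cfg)
    jx <- deletionHomologyLength(sim$offspring$indels, sim$genome)
    expect_true(all(jx$homologyLen == h), info = paste("h =", h))
  }
})

test_that("categorization follows both naming schemes", {
  expect_equal(categorizeHomology(c(0, 1, 2, 5), "celegans_1bp"),
               c("non", "micro", "macro", "macro"))
  expect_equal(categorizeHomology(c(0, 1, 2, 4, 6, 7, 10), "human_2to6bp"),
               c("non", "non", "micro", "micro", "micro", "macro", "macro"))
  expect_error(categorizeHomology(1, "other"))
})

test_that("the binomial footprint test matches closed forms", {
  r0 <- footprintTest(c(non = 10, micro = 0, macro = 0), "celegans_1bp")
  expect_equal(binomP(r0), 1)
  r10 <- footprintTest(c(non = 0, micro = 10, macro = 0), "celegans_1bp")
  expect_equal(binomP(r10), 0.1666^10, tolerance = 1e-10)
  r5 <- footprintTest(c(non = 5, micro = 5, macro = 0), "celegans_1bp")
  expect_equal(binomP(r5), oracleBinomTail(5, 10, 0.1666), tolerance = 1e-12)
  # null constants as configured
  expect_equal(unname(footprintNullProbs("celegans_1bp")),
               c(0.75, 0.1666, 0.0833))
  expect_equal(unname(footprintNullProbs("human_2to6bp")),
               c(0.9166, 0.08325, 1 / 12288))
})

test_that("trio de novo filtering removes parent-overlapping deletions", {
  child <- makeDels("c1", c(100, 500, 900), c(150, 560, 950))
  father <- makeDels("c1", 140, 400)
  mother <- makeDels("c1", 520, 530)
  out <- trioDenovoFilter(child, father, mother)
  expect_equal(GenomicRanges::start(out), 900)
  # non-overlapping trio is identity
  out2 <- trioDenovoFilter(child, makeDels("c1", 2000, 2100),
                           makeDels("c1", 3000, 3100))
  expect_equal(length(out2), 3)
})

test_that("gamete-of-origin stratification drops unknowns", {
  d <- makeDels("c1", c(10, 60, 110), c(20, 70, 120), ids = c("a", "b", "c"))
  s <- stratifyByOrigin(d, c("father", "mother", "unknown"))
  expect_equal(length(s$father), 1)
  expect_equal(length(s$mother), 1)
  s2 <- stratifyByOrigin(d, data.frame(recordId = c("a", "b", "c"),
                                       origin = c("unknown", "unknown", "unknown")))
  expect_equal(length(s2$father), 0)
  expect_equal(length(s2$mother), 0)
  expect_error(stratifyByOrigin(d, c("dad", "mother", "unknown")), "origin label")
})

test_that("father-enriched microhomology yields the smaller binomial p", {
  set.seed(83)
  p0 <- footprintNullProbs("celegans_1bp")
  pf <- c(p0[["non"]] - p0[["micro"]], 2 * p0[["micro"]], p0[["macro"]])
  father <- rmultinom(1, 500, pf)[, 1]
  mother <- rmultinom(1, 500, unname(p0))[, 1]
  pF <- binomP(footprintTest(father))
  pM <- binomP(footprintTest(mother))
  expect_lt(pF, pM)
})

test_that("the single-comparison junction model gives the printed 75% chance", {
  expect_equal(chanceNonHomologyPct(), 75)
})
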