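test_that("PASS filtering keeps exactly the passing records and is idempotent", {
  b <- rbind(bndRow("a", "chr1", 10, "A[chr2:10[", pass = TRUE),
             bndRow("b", "chr1", 20, "A[chr2:20[", pass = FALSE),
             bndRow("c", "chr1", 30, "A[chr2:30[", pass = TRUE))
  out <- filterPassOnly(b)
  expect_equal(out$recordId, c("a", "c"))
  expect_equal(filterPassOnly(out), out)
  allPass <- b[b$filterPass, ]
  expect_equal(filterPassOnly(allPass), allPass)

  d <- makeDels("chr1", c(10, 50), c(20, 80), pass = c(TRUE, FALSE))
  expect_equal(length(filterPassOnly(d)), 1)
})

test_that("parental interval overlap removes offspring indels (>= 1 shared bp)", {
  child <- makeDels("chr1", 100, 150)
  parent <- makeDels("chr1", 140, 200)
  expect_equal(length(filterAgainstParents(child, parent)), 0)
  parentFar <- makeDels("chr1", 151, 200)
  expect_equal(length(filterAgainstParents(child, parentFar)), 1)
  # empty parental set is the identity
  expect_equal(length(filterAgainstParents(child, list())), 1)
})

test_that("parental breakend matching honours confidence intervals both ways", {
  # brute-force expectation: offspring pair at (1000, 5000), parents offset
  # by 5 bp with CI [-10,10] -> both sites within tolerance -> removed
  off <- canonicalizeFusions(pairMates(
    bndPairType1("o", "chr1", 1000, "chr2", 5000, ci = 10)))
  par <- canonicalizeFusions(pairMates(
    bndPairType1("p", "chr1", 1005, "chr2", 4995, ci = 0)))
  expect_equal(length(filterAgainstParents(off, par)), 0)
  # offset beyond the merged CI -> kept
  parFar <- canonicalizeFusions(pairMates(
    bndPairType1("p", "chr1", 1012, "chr2", 5000, ci = 0)))
  expect_equal(length(filterAgainstParents(off, parFar)), 1)
  # swapped partner order still matches
  parSwap <- canonicalizeFusions(pairMates(
    bndPairType1("p", "chr2", 5000, "chr1", 1000, ci = 0)))
  expect_equal(length(filterAgainstParents(off, parSwap)), 0)
})

test_that("repeat filter needs the same class at both break sites for fusions", {
  reps <- GenomicRanges::GRanges(c("chr1", "chr2", "chr2"),
                                 IRanges::IRanges(c(90, 490, 600), c(110, 510, 700)),
                                 repeatClass = c("LTR", "DNA", "LTR"))
  mixed <- canonicalizeFusions(pairMates(bndPairType1("m", "chr1", 100, "chr2", 500)))
  expect_equal(length(filterRepeats(mixed, reps)), 1)   # LTR vs DNA: kept
  same <- canonicalizeFusions(pairMates(bndPairType1("s", "chr1", 100, "chr2", 650)))
  expect_equal(length(filterRepeats(same, reps)), 0)    # LTR vs LTR: removed

  del <- makeDels("chr1", 95, 105)
  expect_equal(length(filterRepeats(del, reps)), 0)     # inside a repeat
  delOut <- makeDels("chr1", 300, 320)
  expect_equal(length(filterRepeats(delOut, reps)), 1)
})

test_that("deletion break-site repeat rule differs from the interval rule", {
  reps <- GenomicRanges::GRanges(c("chr1", "chr1"),
                                 IRanges::IRanges(c(95, 195), c(105, 230)),
                                 repeatClass = c("LTR", "LTR"))
  # spans two same-class repeats at its break sites -> removed
  d1 <- makeDels("chr1", 100, 200)
  expect_equal(length(filterRepeatsDeletions(d1, reps)), 0)
  # overlaps a repeat in the middle only -> kept by the break-site rule
  d2 <- makeDels("chr1", 90, 300)
  reps2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(150, 180),
                                  repeatClass = "LTR")
  expect_equal(length(filterRepeatsDeletions(d2, reps2)), 1)
  expect_equal(length(filterRepeats(d2, reps2)), 0)
})

test_that("duplicate fusions collapse within CI in any partner order", {
  # two annotations of one fusion, offset 3 bp, CI [-5,5]
  b <- rbind(bndPairType1("u", "chr1", 100, "chr2", 500, ci = 5),
             bndPairType1("v", "chr1", 103, "chr2", 497, ci = 5))
  trl <- canonicalizeFusions(pairMates(b))
  out <- dedupeBreakends(trl)
  expect_equal(length(out), 1)
  # lexicographically smallest representative retained
  expect_equal(fusions(out)$posA, 100L)

  # disjoint fusions stay distinct
  b2 <- rbind(bndPairType1("u", "chr1", 100, "chr1", 5000),
              bndPairType1("v", "chr2", 100, "chr2", 5000))
  expect_equal(length(dedupeBreakends(canonicalizeFusions(pairMates(b2)))), 2)
})

test_that("the cascade is idempotent and its report conserves counts", {
  cfg <- simConfig(seed = 17, nTranslocations = 15, nDeletions = 20,
                   nInheritedTranslocations = 4, nInheritedDeletions = 4)
  sim <- simulateStudy(cfg)
  parents <- lapply(cfg$parents, function(p) sim$parents[[p]])
  r1 <- denovoFilter(sim$offspring, parents, sim$repeats)
  s <- filterStages(r1$report)
  expect_true(all(s$nIn == s$nRemoved + s$nOut))
  # stage chaining: each stage's input equals the previous stage's output
  fus <- s[s$kind == "fusion", ]
  expect_equal(fus$nIn[-1], fus$nOut[-length(fus$nOut)])

  # idempotence: feeding the surviving records back changes nothing
  again <- filterAgainstParents(r1$translocations,
                                lapply(parents, function(p)
                                  canonicalizeFusions(pairMates(p$breakends))))
  expect_equal(length(again), length(r1$translocations))
  expect_equal(length(dedupeBreakends(r1$translocations)),
               length(r1$translocations))
})

test_that("de novo recall is exact on labelled simulations", {
  cfg <- simConfig(seed = 23, nTranslocations = 20, nDeletions = 25,
                   nInheritedTranslocations = 6, nInheritedDeletions = 6)
  sim <- simulateStudy(cfg)
  parents <- lapply(cfg$parents, function(p) sim$parents[[p]])
  res <- denovoFilter(sim$offspring, parents, sim$repeats)
  truthT <- sim$truth$translocations
  denovo <- truthT[!truthT$inherited, ]
  f <- fusions(res$translocations)
  key <- function(d) paste(d$contigA, d$posA, d$contigB, d$posB)
  expect_setequal(key(f), key(denovo))
  truthD <- sim$truth$deletions
  expect_setequal(paste(GenomicRanges::start(res$indels)),
                  paste(truthD$start[!truthD$inherited]))
})
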