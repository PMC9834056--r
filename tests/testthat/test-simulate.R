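test_that("simulated genomes are deterministic and follow base frequencies", {
  cfg <- simConfig(seed = 5, contigLengths = c(c1 = 100000L))
  g1 <- simulateGenome(cfg)
  g2 <- simulateGenome(cfg)
  expect_identical(as.character(g1), as.character(g2))
  tab <- table(strsplit(as.character(g1[["c1"]]), "")[[1]]) / 100000
  expect_true(all(abs(tab - 0.25) < 0.01))

  skew <- simConfig(seed = 5, contigLengths = c(c1 = 100000L),
                    baseFreqs = c(A = 0.2, C = 0.3, G = 0.3, T = 0.2))
  gs <- simulateGenome(skew)
  gc <- mean(strsplit(as.character(gs[["c1"]]), "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc - 0.6), 0.01)
})

test_that("all study outputs are byte-identical under a fixed seed", {
  cfg <- simConfig(seed = 13, nTranslocations = 10, nDeletions = 10)
  d1 <- file.path(tempdir(), "repA"); d2 <- file.path(tempdir(), "repB")
  simulateStudy(cfg, dir = d1)
  simulateStudy(cfg, dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("simulated type mix is recovered by classification", {
  cfg <- simConfig(seed = 29, contigLengths = c(c1 = 300000L, c2 = 300000L),
                   nTranslocations = 400L, nDeletions = 0,
                   nInheritedTranslocations = 0, nInheritedDeletions = 0)
  sim <- simulateStudy(cfg)
  trl <- canonicalizeFusions(pairMates(sim$offspring$breakends))
  frac <- table(factor(fusions(trl)$ttype, levels = c(1, 2, 4))) / 400
  expect_true(all(abs(frac - c(0.5, 0.25, 0.25)) < 0.07))
  expect_equal(fusions(trl)$ttype,
               sim$truth$translocations$ttype[
                 match(paste(fusions(trl)$contigA, fusions(trl)$posA),
                       paste(sim$truth$translocations$contigA,
                             sim$truth$translocations$posA))])
})

test_that("null configuration yields no insertions and zero microhomology", {
  cfg <- simConfig(seed = 37, nTranslocations = 40, nDeletions = 0,
                   nInheritedTranslocations = 0, nInheritedDeletions = 0,
                   mhDist = c(`0` = 1), templatedInsertRate = 0,
                   miscInsertRate = 0)
  sim <- simulateStudy(cfg)
  trl <- canonicalizeFusions(pairMates(sim$offspring$breakends))
  calls <- classifyInsertion(trl, sim$genome)
  expect_true(all(calls$category == "no_insertion"))
  fl <- extractFlanks(trl, sim$genome)
  expect_true(all(microhomologyLength(fl) == 0))
})

test_that("templated_insert_rate 1 makes every pipeline call templated", {
  cfg <- simConfig(seed = 38, nTranslocations = 50, nDeletions = 0,
                   nInheritedTranslocations = 0, nInheritedDeletions = 0,
                   templatedInsertRate = 1, miscInsertRate = 0)
  sim <- simulateStudy(cfg)
  trl <- canonicalizeFusions(pairMates(sim$offspring$breakends))
  calls <- classifyInsertion(trl, sim$genome)
  expect_true(all(calls$category == "templated"))
  # truth provenance: every planted template is found where it was planted
  truth <- sim$truth$translocations
  m <- match(fusions(trl)$insertSeq, truth$insertSeq)
  expect_false(anyNA(m))
})

test_that("deletion category fractions follow a configured distribution", {
  p0 <- footprintNullProbs("celegans_1bp")
  cfg <- simConfig(seed = 39, nTranslocations = 0, nDeletions = 500,
                   contigLengths = c(c1 = 300000L, c2 = 300000L),
                   nInheritedTranslocations = 0, nInheritedDeletions = 0,
                   deletionHomologyDist = c(`0` = p0[["non"]],
                                            `1` = p0[["micro"]],
                                            `2` = p0[["macro"]]))
  sim <- simulateStudy(cfg)
  jx <- deletionHomologyLength(sim$offspring$indels, sim$genome)
  cat3 <- categorizeHomology(jx$homologyLen, "celegans_1bp")
  fr <- table(factor(cat3, levels = c("non", "micro", "macro"))) / 500
  se <- sqrt(unname(p0) * (1 - unname(p0)) / 500)
  expect_true(all(abs(fr - unname(p0)) <= 3 * se))
  # sizes drawn in [8,200]: the size filter removes nothing
  expect_equal(length(sizeFilter(sim$offspring$indels)),
               length(sim$offspring$indels))
})

test_that("repeat tracks respect density 0 and drive closed-loop filtering", {
  cfg0 <- simConfig(seed = 40, repeatDensity = 0, nTranslocations = 5,
                    nDeletions = 5)
  expect_equal(length(simulateRepeats(simulateGenome(cfg0), cfg0)), 0)

  # a fusion with both breaks inside one repeat class is removed; breaks in
  # different classes are retained
  trl <- canonicalizeFusions(pairMates(
    rbind(bndPairType1("x", "c1", 100, "c1", 5000),
          bndPairType1("y", "c1", 200, "c1", 6000))))
  reps <- GenomicRanges::GRanges(
    "c1", IRanges::IRanges(c(90, 4990, 190, 5990), c(110, 5010, 210, 6010)),
    repeatClass = c("LTR", "LTR", "LTR", "DNA"))
  kept <- filterRepeats(trl, reps)
  expect_equal(length(kept), 1)
  expect_equal(fusions(kept)$posA, 200L)
})
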