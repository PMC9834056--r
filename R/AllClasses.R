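#' @import methods
NULL

# -------------------------------------------------------------------------
# TranslocationSet: canonicalized two-break-site fusions
# -------------------------------------------------------------------------

.FUSION_COLS <- c("fusionId", "contigA", "posA", "sideA", "rcA",
                  "contigB", "posB", "sideB", "rcB",
                  "ttype", "insertSeq", "ciALo", "ciAHi", "ciBLo", "ciBHi",
                  "sampleId", "sourceIds")

#' TranslocationSet: canonical two-break-site fusions
#'
#' Each row of the underlying table is one physical fusion of two break sites,
#' canonicalized so that (contigA, posA) <= (contigB, posB) lexicographically
#' and so that the breakend type is one of 1, 2, 4 (the VCF `]p]t` shape is the
#' same fusion as `t[p[` seen from the other partner and is re-expressed as
#' type 1). `sideA`/`sideB` record whether the retained segment ends at
#' (`"L"`) or starts at (`"R"`) the position; `rcA`/`rcB` whether that segment
#' enters the fusion product reverse-complemented.
#'
#' @slot fusions data.frame with one row per fusion.
#' @export
setClass("TranslocationSet", representation(fusions = "data.frame"))

setValidity("TranslocationSet", function(object) {
  f <- object@fusions
  miss <- setdiff(.FUSION_COLS, names(f))
  if (length(miss)) return(paste("missing columns:", paste(miss, collapse = ",")))
  if (!all(f$ttype %in% c(1L, 2L, 4L))) return("ttype must be 1, 2 or 4")
  bad <- f$contigA > f$contigB | (f$contigA == f$contigB & f$posA > f$posB)
  if (any(bad)) return("fusions not in canonical (contig, pos) order")
  sides <- paste0(f$sideA, f$sideB)
  okSides <- (f$ttype == 1L & sides %in% c("LR", "RL")) |
    (f$ttype == 2L & sides == "LL") |
    (f$ttype == 4L & sides == "RR")
  if (!all(okSides)) return("side labels inconsistent with ttype")
  TRUE
})

TranslocationSet <- function(fusions) {
  new("TranslocationSet", fusions = fusions)
}

#' Fusion table of a TranslocationSet
#' @param x A `TranslocationSet`.
#' @return data.frame, one row per canonical fusion.
#' @export
fusions <- function(x) x@fusions

#' @export
setMethod("length", "TranslocationSet", function(x) nrow(x@fusions))

setMethod("show", "TranslocationSet", function(object) {
  f <- object@fusions
  cat("TranslocationSet with", nrow(f), "fusions\n")
  if (nrow(f)) {
    tt <- table(factor(f$ttype, levels = c(1, 2, 4)))
    cat("  types: 1:", tt[["1"]], " 2:", tt[["2"]], " 4:", tt[["4"]], "\n")
    cat("  with insertion:", sum(nchar(f$insertSeq) > 0), "\n")
  }
})

#' @export
setMethod("as.data.frame", "TranslocationSet",
          function(x, row.names = NULL, optional = FALSE, ...) x@fusions)

# -------------------------------------------------------------------------
# HomologyGrid: 2w x 2w junction base-match frequencies (+ permutation stats)
# -------------------------------------------------------------------------

#' HomologyGrid: junction base-match frequency grid
#'
#' The `2w x 2w` matrix holds, for each (left-flank position i, right-flank
#' position j) pair of signed labels, the fraction of junctions at which the
#' two bases are identical (N never matches). Optional slots carry the
#' per-bin upper-tail permutation p-values against random genomic placement
#' and their Benjamini-Hochberg q-values.
#'
#' @slot w half-window (4 for translocations, 8 for deletion junctions).
#' @slot matrix match-frequency matrix, rows = left-flank labels.
#' @slot n number of junctions aggregated.
#' @slot pValues,qValues matrices (possibly 0x0 before testing).
#' @slot nPerm number of permutations used (0 before testing).
#' @slot seed RNG seed used for the permutation null.
#' @export
setClass("HomologyGrid", representation(
  w = "integer", matrix = "matrix", n = "integer",
  pValues = "matrix", qValues = "matrix", nPerm = "integer", seed = "integer"))

setValidity("HomologyGrid", function(object) {
  d <- 2L * object@w
  if (!all(dim(object@matrix) == c(d, d))) return("matrix must be 2w x 2w")
  v <- object@matrix
  if (any(v < 0 | v > 1)) return("frequencies must lie in [0,1]")
  if (length(object@pValues) && !all(dim(object@pValues) == c(d, d)))
    return("pValues must be 2w x 2w")
  if (length(object@qValues)) {
    if (!all(dim(object@qValues) == c(d, d))) return("qValues must be 2w x 2w")
    if (any(object@qValues + 1e-12 < object@pValues))
      return("q-values must be >= p-values bin-wise")
  }
  TRUE
})

.labelGrid <- function(m, w) {
  dimnames(m) <- list(left = as.character(flankLabels(w)),
                      right = as.character(flankLabels(w)))
  m
}

HomologyGrid <- function(matrix, w, n, pValues = NULL, qValues = NULL,
                         nPerm = 0L, seed = NA_integer_) {
  empty <- base::matrix(numeric(0), 0, 0)
  new("HomologyGrid", w = as.integer(w), matrix = .labelGrid(matrix, w),
      n = as.integer(n),
      pValues = if (is.null(pValues)) empty else .labelGrid(pValues, w),
      qValues = if (is.null(qValues)) empty else .labelGrid(qValues, w),
      nPerm = as.integer(nPerm), seed = as.integer(seed))
}

#' Match-frequency matrix of a HomologyGrid
#' @param x A `HomologyGrid`.
#' @export
gridMatrix <- function(x) x@matrix

#' Per-bin permutation p-values of a HomologyGrid
#' @param x A `HomologyGrid`.
#' @export
pValues <- function(x) x@pValues

#' Per-bin Benjamini-Hochberg q-values of a HomologyGrid
#' @param x A `HomologyGrid`.
#' @export
qValues <- function(x) x@qValues

setMethod("show", "HomologyGrid", function(object) {
  cat("HomologyGrid ", 2 * object@w, "x", 2 * object@w,
      " over ", object@n, " junctions\n", sep = "")
  cat("  mean match frequency:", round(mean(object@matrix), 4), "\n")
  if (length(object@qValues))
    cat("  bins with q < 0.05:", sum(object@qValues < 0.05),
        " (", object@nPerm, "permutations )\n")
})

# -------------------------------------------------------------------------
# BaseComposition
# -------------------------------------------------------------------------

#' BaseComposition: per-position base percentages around break sites
#'
#' Observed percentages of A, C, T, G at each signed flank position across a
#' set of junction flanks, together with the mean background percentages from
#' repeatedly sampling the same number of random genomic positions.
#'
#' @slot w half-window.
#' @slot observed,background 4 x 2w matrices (rows A, C, T, G; columns signed
#'   labels); columns sum to 100 (N-containing sites are dropped and counted
#'   in `nDropped`).
#' @slot nSites number of flank sequences observed.
#' @slot nPerm background resampling count.
#' @export
setClass("BaseComposition", representation(
  w = "integer", observed = "matrix", background = "matrix",
  nSites = "integer", nDropped = "integer", nPerm = "integer", seed = "integer"))

setValidity("BaseComposition", function(object) {
  d <- 2L * object@w
  if (!all(dim(object@observed) == c(4L, d))) return("observed must be 4 x 2w")
  sums <- colSums(object@observed)
  if (any(abs(sums - 100) > 1e-6)) return("observed percentages must sum to 100")
  TRUE
})

setMethod("show", "BaseComposition", function(object) {
  cat("BaseComposition over", object@nSites, "flanks (",
      object@nPerm, "background permutations )\n")
  print(round(object@observed, 1))
})

# -------------------------------------------------------------------------
# FootprintResult: deletion junction homology categories + binomial test
# -------------------------------------------------------------------------

#' FootprintResult: deletion microhomology footprint test
#'
#' Category counts of deletion junctions (non-, micro-, macro-homology) under a
#' named scheme, the chance expectation for each category, and the one-sided
#' binomial p-value for over-representation of the microhomology category.
#'
#' @slot scheme `"celegans_1bp"` or `"human_2to6bp"`.
#' @slot counts named integer vector (non, micro, macro).
#' @slot nullProbs chance probabilities for the three categories.
#' @slot binomP one-sided (greater) exact binomial p for the micro count.
#' @export
setClass("FootprintResult", representation(
  scheme = "character", counts = "integer", n = "integer",
  nullProbs = "numeric", binomP = "numeric"))

setValidity("FootprintResult", function(object) {
  if (!identical(names(object@counts), c("non", "micro", "macro")))
    return("counts must be named non/micro/macro")
  if (sum(object@counts) != object@n) return("counts must sum to n")
  if (abs(sum(object@nullProbs) - 1) > 0.01)
    return("null probabilities must sum to ~1")
  TRUE
})

setMethod("show", "FootprintResult", function(object) {
  cat("FootprintResult (", object@scheme, "), n = ", object@n, "\n", sep = "")
  pct <- if (object@n > 0) round(100 * object@counts / object@n, 1) else object@counts
  cat("  counts:", paste(names(object@counts), object@counts, collapse = "  "), "\n")
  cat("  observed %:", paste(names(pct), pct, collapse = "  "), "\n")
  cat("  chance %:", paste(names(object@counts),
                           round(100 * object@nullProbs, 2), collapse = "  "), "\n")
  cat("  binomial p (micro over-representation):",
      format(object@binomP, digits = 4), "\n")
})

#' Category counts of a FootprintResult
#' @param x A `FootprintResult`.
#' @export
footprintCounts <- function(x) x@counts

#' Binomial p-value of a FootprintResult
#' @param x A `FootprintResult`.
#' @export
binomP <- function(x) x@binomP

# -------------------------------------------------------------------------
# FilterReport
# -------------------------------------------------------------------------

#' FilterReport: per-stage accounting of the de novo filtering cascade
#'
#' One row per (stage, SV kind) with input, removed and output counts; counts
#' are conserved (`nIn == nRemoved + nOut`) at every stage, so the published
#' event totals can be audited.
#'
#' @slot stages data.frame with columns stage, kind, nIn, nRemoved, nOut.
#' @export
setClass("FilterReport", representation(stages = "data.frame"))

setValidity("FilterReport", function(object) {
  s <- object@stages
  need <- c("stage", "kind", "nIn", "nRemoved", "nOut")
  if (!all(need %in% names(s))) return("stages must have stage/kind/nIn/nRemoved/nOut")
  if (any(s$nIn != s$nRemoved + s$nOut)) return("counts not conserved at a stage")
  TRUE
})

FilterReport <- function(stages) new("FilterReport", stages = stages)

#' Stage table of a FilterReport
#' @param x A `FilterReport`.
#' @export
filterStages <- function(x) x@stages

setMethod("show", "FilterReport", function(object) {
  cat("FilterReport\n")
  print(object@stages, row.names = FALSE)
})
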