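#' Keep only records that passed all caller quality filters
#'
#' @param x Breakend data.frame (from [readSvVcf()]) or indel `GRanges`; both
#'   carry a `filterPass` field. Missing FILTER (`.`) was already mapped to
#'   `FALSE` on read.
#' @return Object of the same class, PASS records only.
#' @export
filterPassOnly <- function(x) {
  if (is.data.frame(x)) x[x$filterPass, , drop = FALSE]
  else x[S4Vectors::mcols(x)$filterPass]
}

# merged CI tolerance of a fusion: max absolute CI bound over both break sites
.fusionCiTol <- function(f) {
  pmax(abs(f$ciALo), abs(f$ciAHi), abs(f$ciBLo), abs(f$ciBHi))
}

# does offspring fusion i match parental fusion j in either partner order?
.fusionMatches <- function(fo, fp) {
  n <- nrow(fo); m <- nrow(fp)
  hit <- rep(FALSE, n)
  if (n == 0 || m == 0) return(hit)
  tolO <- .fusionCiTol(fo); tolP <- .fusionCiTol(fp)
  for (i in seq_len(n)) {
    tol <- pmax(tolO[i], tolP)
    straight <- fo$contigA[i] == fp$contigA & abs(fo$posA[i] - fp$posA) <= tol &
      fo$contigB[i] == fp$contigB & abs(fo$posB[i] - fp$posB) <= tol
    crossed <- fo$contigA[i] == fp$contigB & abs(fo$posA[i] - fp$posB) <= tol &
      fo$contigB[i] == fp$contigA & abs(fo$posB[i] - fp$posA) <= tol
    hit[i] <- any(straight | crossed)
  }
  hit
}

#' Remove offspring SVs present in any parental call set
#'
#' Interval SVs (deletions, insertions, duplications) are removed when their
#' interval shares at least one base with any parental SV interval. Fusions
#' are removed when some parental fusion has both break sites within the
#' merged confidence windows of the offspring fusion's break sites, in either
#' partner order.
#'
#' @param x Offspring calls: a [TranslocationSet-class] or an indel `GRanges`.
#' @param parents Parental calls of the matching class, or a list of them
#'   (one per parent sample).
#' @return `x` with inherited events removed.
#' @export
setGeneric("filterAgainstParents", function(x, parents)
  standardGeneric("filterAgainstParents"))

#' @rdname filterAgainstParents
#' @export
setMethod("filterAgainstParents", "TranslocationSet", function(x, parents) {
  if (methods::is(parents, "TranslocationSet")) parents <- list(parents)
  fp <- do.call(rbind, lapply(parents, fusions))
  fo <- fusions(x)
  if (is.null(fp) || nrow(fp) == 0 || nrow(fo) == 0) return(x)
  TranslocationSet(fo[!.fusionMatches(fo, fp), , drop = FALSE])
})

#' @rdname filterAgainstParents
#' @export
setMethod("filterAgainstParents", "GRanges", function(x, parents) {
  if (methods::is(parents, "GRanges")) parents <- list(parents)
  pgr <- suppressWarnings(do.call(c, lapply(parents, GenomicRanges::granges)))
  if (is.null(pgr) || length(pgr) == 0 || length(x) == 0) return(x)
  hits <- GenomicRanges::countOverlaps(x, pgr, minoverlap = 1L,
                                       ignore.strand = TRUE)
  x[hits == 0]
})

#' Remove SVs in repeat regions
#'
#' Interval SVs intersecting any repeat interval are removed. Fusions are
#' removed only when both break sites overlap repeat intervals *of the same
#' repeat class* (break sites in different repeat classes are kept).
#'
#' @param x A [TranslocationSet-class] or indel `GRanges`.
#' @param repeats `GRanges` with a `repeatClass` column ([readRepeats()]).
#' @return `x` with repeat-region events removed.
#' @export
setGeneric("filterRepeats", function(x, repeats) standardGeneric("filterRepeats"))

.classesAt <- function(contig, pos, repeats) {
  q <- GenomicRanges::GRanges(contig, IRanges::IRanges(pos, pos))
  h <- GenomicRanges::findOverlaps(q, repeats, ignore.strand = TRUE)
  split(S4Vectors::mcols(repeats)$repeatClass[S4Vectors::subjectHits(h)],
        factor(S4Vectors::queryHits(h), levels = seq_along(q)))
}

#' @rdname filterRepeats
#' @export
setMethod("filterRepeats", "TranslocationSet", function(x, repeats) {
  f <- fusions(x)
  if (nrow(f) == 0 || length(repeats) == 0) return(x)
  clsA <- .classesAt(f$contigA, f$posA, repeats)
  clsB <- .classesAt(f$contigB, f$posB, repeats)
  same <- mapply(function(a, b) length(intersect(a, b)) > 0, clsA, clsB)
  TranslocationSet(f[!same, , drop = FALSE])
})

#' @rdname filterRepeats
#' @export
setMethod("filterRepeats", "GRanges", function(x, repeats) {
  if (length(x) == 0 || length(repeats) == 0) return(x)
  hits <- GenomicRanges::countOverlaps(x, repeats, minoverlap = 1L,
                                       ignore.strand = TRUE)
  x[hits == 0]
})

#' Remove deletions whose two break sites share a repeat class
#'
#' The deletion-footprint analyses drop a deletion only when *both* junction
#' break sites (the first and last deleted base) are annotated within the same
#' repeat class, unlike the whole-interval rule used for de novo indels.
#'
#' @param dels Deletion `GRanges`.
#' @param repeats Repeat `GRanges` with `repeatClass`.
#' @return `dels` with same-class-flanked deletions removed.
#' @export
filterRepeatsDeletions <- function(dels, repeats) {
  if (length(dels) == 0 || length(repeats) == 0) return(dels)
  clsA <- .classesAt(as.character(GenomicRanges::seqnames(dels)),
                     GenomicRanges::start(dels), repeats)
  clsB <- .classesAt(as.character(GenomicRanges::seqnames(dels)),
                     GenomicRanges::end(dels), repeats)
  same <- mapply(function(a, b) length(intersect(a, b)) > 0, clsA, clsB)
  dels[!same]
}

#' Collapse duplicate annotations of the same physical fusion
#'
#' Callers annotate translocations in both directions; after mate pairing,
#' residual duplicates are fusions whose two break-site pairs agree within
#' their confidence intervals in any partner order. Matching fusions are
#' grouped transitively and the lexicographically smallest representative
#' (by contigA, posA, contigB, posB) of each group is retained.
#'
#' @param x A [TranslocationSet-class].
#' @return Deduplicated [TranslocationSet-class].
#' @export
dedupeBreakends <- function(x) {
  f <- fusions(x)
  n <- nrow(f)
  if (n <= 1) return(x)
  comp <- seq_len(n)
  findRoot <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  tol <- .fusionCiTol(f)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      t <- max(tol[i], tol[j])
      straight <- f$contigA[i] == f$contigA[j] && abs(f$posA[i] - f$posA[j]) <= t &&
        f$contigB[i] == f$contigB[j] && abs(f$posB[i] - f$posB[j]) <= t
      crossed <- f$contigA[i] == f$contigB[j] && abs(f$posA[i] - f$posB[j]) <= t &&
        f$contigB[i] == f$contigA[j] && abs(f$posB[i] - f$posA[j]) <= t
      if (straight || crossed) {
        ri <- findRoot(i); rj <- findRoot(j)
        if (ri != rj) comp[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(n), findRoot, integer(1))
  keyOrder <- order(f$contigA, f$posA, f$contigB, f$posB)
  keep <- vapply(split(seq_len(n), roots),
                 function(idx) idx[which.min(match(idx, keyOrder))], integer(1))
  TranslocationSet(f[sort(keep), , drop = FALSE])
}

#' Run the full de novo filtering cascade
#'
#' Stages, in order: caller PASS filter, mate pairing + canonicalization,
#' parental-overlap removal, repeat-region removal, duplicate-fusion
#' collapse. The [FilterReport-class] records input/removed/output counts at
#' every stage so published event totals can be audited.
#'
#' @param offspring List with `breakends` and `indels` from [readSvVcf()].
#' @param parents List of such lists, one per parent sample (may be empty).
#' @param repeats Optional repeat `GRanges` (NULL to skip the repeat stage).
#' @return List with `translocations` ([TranslocationSet-class]), `indels`
#'   (`GRanges`) and `report` ([FilterReport-class]).
#' @export
denovoFilter <- function(offspring, parents = list(), repeats = NULL) {
  rows <- list()
  note <- function(stage, kind, nIn, nOut)
    rows[[length(rows) + 1]] <<- data.frame(stage = stage, kind = kind,
                                            nIn = nIn, nRemoved = nIn - nOut,
                                            nOut = nOut)
  bnd <- offspring$breakends
  ind <- offspring$indels
  b1 <- filterPassOnly(bnd); i1 <- filterPassOnly(ind)
  note("pass", "breakend_record", nrow(bnd), nrow(b1))
  note("pass", "indel", length(ind), length(i1))

  pairs <- suppressWarnings(pairMates(b1))
  trl <- canonicalizeFusions(pairs)
  note("mate_pairing", "breakend_record", nrow(b1), 2L * length(trl))

  parentTrl <- lapply(parents, function(p)
    canonicalizeFusions(suppressWarnings(pairMates(filterPassOnly(p$breakends)))))
  parentInd <- lapply(parents, function(p) filterPassOnly(p$indels))
  t2 <- if (length(parentTrl)) filterAgainstParents(trl, parentTrl) else trl
  i2 <- if (length(parentInd)) filterAgainstParents(i1, parentInd) else i1
  note("parental", "fusion", length(trl), length(t2))
  note("parental", "indel", length(i1), length(i2))

  t3 <- if (!is.null(repeats)) filterRepeats(t2, repeats) else t2
  i3 <- if (!is.null(repeats)) filterRepeats(i2, repeats) else i2
  note("repeat", "fusion", length(t2), length(t3))
  note("repeat", "indel", length(i2), length(i3))

  t4 <- dedupeBreakends(t3)
  note("dedupe", "fusion", length(t3), length(t4))

  list(translocations = t4, indels = i3,
       report = FilterReport(do.call(rbind, rows)))
}
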