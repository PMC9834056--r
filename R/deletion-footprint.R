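#' Size-filter deletions
#'
#' Retains deletions whose length lies within the inclusive bounds used by
#' the footprint analyses (8-200 bp by default).
#'
#' @param dels Deletion `GRanges`.
#' @param lo,hi Inclusive length bounds in bp.
#' @return Filtered `GRanges`.
#' @export
sizeFilter <- function(dels, lo = 8L, hi = 200L) {
  len <- GenomicRanges::width(dels)
  dels[len >= lo & len <= hi]
}

# shift a deletion left while the base before it equals its last base
# (left-alignment normalization, so homology is measured at a canonical spot)
.leftAlign <- function(gint, s, e) {
  while (s > 1L && gint[s - 1L] == gint[e] && gint[e] != .BASE_N) {
    s <- s - 1L; e <- e - 1L
  }
  c(s, e)
}

.lcpLen <- function(a, b) {
  k <- min(length(a), length(b))
  if (k == 0) return(0L)
  eq <- a[seq_len(k)] == b[seq_len(k)] & a[seq_len(k)] != .BASE_N
  run <- cumprod(eq)
  as.integer(sum(run))
}

#' Junction homology length of deletions
#'
#' After left-alignment normalization, the homology length is the longest
#' common prefix of the deleted sequence and the retained sequence
#' immediately following the deletion (`N` breaks any run). With
#' `twoSided = TRUE` the breakpoint-ambiguity alternative is used: the
#' maximum of that and the longest common suffix of the deleted sequence and
#' the retained sequence immediately preceding it.
#'
#' @param dels Deletion `GRanges`.
#' @param genome Named `DNAStringSet`.
#' @param twoSided Use the two-sided convention (default FALSE).
#' @return data.frame with recordId, contig, start, end (post alignment),
#'   length, `homologyLen` (NA when the required flank runs off the contig,
#'   with a message), and `deletedSeq`.
#' @export
deletionHomologyLength <- function(dels, genome, twoSided = FALSE) {
  gints <- .genomeInts(genome)
  n <- length(dels)
  contig <- as.character(GenomicRanges::seqnames(dels))
  s <- GenomicRanges::start(dels)
  e <- GenomicRanges::end(dels)
  ids <- S4Vectors::mcols(dels)$recordId
  if (is.null(ids)) ids <- paste0("del", seq_len(n))
  hom <- integer(n)
  delSeq <- character(n)
  nExcluded <- 0L
  for (i in seq_len(n)) {
    g <- gints[[contig[i]]]
    al <- .leftAlign(g, s[i], e[i])
    s[i] <- al[1]; e[i] <- al[2]
    len <- e[i] - s[i] + 1L
    deleted <- g[s[i]:e[i]]
    delSeq[i] <- intToUtf8(deleted)
    after <- if (e[i] + 1L <= length(g)) g[(e[i] + 1L):min(length(g), e[i] + len)] else integer(0)
    if (length(after) == 0) { hom[i] <- NA_integer_; nExcluded <- nExcluded + 1L; next }
    h <- .lcpLen(deleted, after)
    if (twoSided) {
      before <- if (s[i] > 1L) g[max(1L, s[i] - len):(s[i] - 1L)] else integer(0)
      h2 <- .lcpLen(rev(deleted), rev(before))
      h <- max(h, h2)
    }
    hom[i] <- h
  }
  if (nExcluded > 0)
    message(nExcluded, " deletion(s) without a usable flank excluded (NA)")
  data.frame(recordId = ids, contig = contig, start = s, end = e,
             length = e - s + 1L, homologyLen = hom, deletedSeq = delSeq)
}

#' Categorize a homology length under a naming scheme
#'
#' `celegans_1bp`: 0 -> non, exactly 1 -> micro, >= 2 -> macro.
#' `human_2to6bp`: 0-1 -> non, 2-6 -> micro, >= 7 -> macro.
#'
#' @param homologyLen Integer vector (NA allowed, propagated).
#' @param scheme `"celegans_1bp"` or `"human_2to6bp"`.
#' @return Character vector in {"non", "micro", "macro"}.
#' @export
categorizeHomology <- function(homologyLen, scheme = c("celegans_1bp", "human_2to6bp")) {
  scheme <- match.arg(scheme)
  out <- rep(NA_character_, length(homologyLen))
  idx <- !is.na(homologyLen)
  h <- homologyLen[idx]
  out[idx] <- if (scheme == "celegans_1bp")
    ifelse(h == 0, "non", ifelse(h == 1, "micro", "macro"))
  else
    ifelse(h <= 1, "non", ifelse(h <= 6, "micro", "macro"))
  out
}

#' Chance category probabilities used as the binomial null
#'
#' Constants as printed in the source analyses: for the 1-bp scheme 75% /
#' 16.66% / 8.33% (non/micro/macro); for the 2-6 bp scheme 91.66% / 8.325% /
#' 1/12288.
#'
#' @param scheme `"celegans_1bp"` or `"human_2to6bp"`.
#' @return Named numeric vector (non, micro, macro).
#' @export
footprintNullProbs <- function(scheme = c("celegans_1bp", "human_2to6bp")) {
  scheme <- match.arg(scheme)
  if (scheme == "celegans_1bp")
    c(non = 0.75, micro = 0.1666, macro = 0.0833)
  else
    c(non = 0.9166, micro = 0.08325, macro = 1 / 12288)
}

#' Chance of a non-homologous junction under the single-comparison model
#'
#' One base comparison across the junction fails with probability
#' `1 - 1/alphabet`; with four equifrequent bases that is 75%.
#'
#' @param alphabetSize Number of equifrequent bases (default 4).
#' @return Percentage (0-100).
#' @export
chanceNonHomologyPct <- function(alphabetSize = 4L) {
  100 * (1 - 1 / alphabetSize)
}

#' Binomial test for microhomology over-representation
#'
#' One-sided (greater) exact binomial test of the microhomology category
#' count against the scheme's chance probability.
#'
#' @param x Either a character vector of categories ("non"/"micro"/"macro",
#'   NA dropped), a named count vector `c(non=, micro=, macro=)`, or a
#'   data.frame with a `category` column.
#' @param scheme `"celegans_1bp"` or `"human_2to6bp"`.
#' @return A [FootprintResult-class].
#' @export
footprintTest <- function(x, scheme = c("celegans_1bp", "human_2to6bp")) {
  scheme <- match.arg(scheme)
  if (is.data.frame(x)) x <- x$category
  if (is.numeric(x)) {
    if (!is.null(names(x)) && all(c("non", "micro", "macro") %in% names(x)))
      x <- x[c("non", "micro", "macro")]
    else if (length(x) != 3)
      stop("counts must be length 3 (non, micro, macro)")
    counts <- as.integer(x)
    names(counts) <- c("non", "micro", "macro")
  } else {
    x <- x[!is.na(x)]
    counts <- as.integer(table(factor(x, levels = c("non", "micro", "macro"))))
    names(counts) <- c("non", "micro", "macro")
  }
  n <- sum(counts)
  p0 <- footprintNullProbs(scheme)
  pval <- if (n == 0) NA_real_ else
    stats::pbinom(counts[["micro"]] - 1L, n, p0[["micro"]], lower.tail = FALSE)
  new("FootprintResult", scheme = scheme, counts = counts, n = as.integer(n),
      nullProbs = p0, binomP = pval)
}

#' Remove child deletions that overlap either parent's deletions
#'
#' @param child,father,mother Deletion `GRanges` on the same genome build.
#' @return Child deletions with any parent-overlapping (>= 1 bp) event
#'   removed.
#' @export
trioDenovoFilter <- function(child, father, mother) {
  filterAgainstParents(child, list(father, mother))
}

#' Split deletions by gamete of origin
#'
#' @param dels Deletion `GRanges` with a `recordId` column.
#' @param origins Either a character vector aligned with `dels` or a
#'   data.frame with `recordId` and `origin` columns; values in
#'   {"father", "mother", "unknown"}. Unknowns are dropped.
#' @return List with `father` and `mother` `GRanges` (disjoint).
#' @export
stratifyByOrigin <- function(dels, origins) {
  if (is.data.frame(origins)) {
    m <- match(S4Vectors::mcols(dels)$recordId, origins$recordId)
    lab <- origins$origin[m]
  } else lab <- origins
  lab[is.na(lab)] <- "unknown"
  bad <- !lab %in% c("father", "mother", "unknown")
  if (any(bad)) stop("unknown origin label(s): ", paste(unique(lab[bad]), collapse = ","))
  list(father = dels[lab == "father"], mother = dels[lab == "mother"])
}

#' Junction flanks of deletions for the 16 x 16 match grid
#'
#' A deletion junction fuses the base before the deletion (left, sense) to
#' the base after it (right, sense) - the type 1 orientation - so the same
#' grid, permutation-null and microhomology machinery applies with `w = 8`.
#'
#' @param dels Deletion `GRanges`.
#' @param genome Named `DNAStringSet`.
#' @param w Half-window (default 8).
#' @return Flank set as from [extractFlanks()] (all `ttype = 1`).
#' @export
deletionFlanks <- function(dels, genome, w = 8L) {
  gints <- .genomeInts(genome)
  contig <- as.character(GenomicRanges::seqnames(dels))
  sPos <- GenomicRanges::start(dels) - 1L   # last retained base on the left
  ePos <- GenomicRanges::end(dels) + 1L     # first retained base on the right
  left <- .flankMatrix(gints, contig, sPos, "L", FALSE, w)
  right <- .flankMatrix(gints, contig, ePos, "R", FALSE, w)
  ok <- !apply(is.na(left), 1, any) & !apply(is.na(right), 1, any)
  if (any(!ok))
    message(sum(!ok), " deletion junction(s) with out-of-bounds flank excluded")
  labs <- flankLabels(w)
  colnames(left) <- colnames(right) <- as.character(labs)
  ids <- S4Vectors::mcols(dels)$recordId
  if (is.null(ids)) ids <- paste0("del", seq_along(dels))
  list(left = left, right = right, ok = ok, labels = labs,
       ttype = rep(1L, length(dels)), fusionId = ids)
}
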