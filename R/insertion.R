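.ORIENTATIONS <- c("normal", "reverse", "complement", "reverse_complement")

.orientSeq <- function(seq, orientation) {
  switch(orientation,
         normal = seq,
         reverse = .reverseStr(seq),
         complement = .complementStr(seq),
         reverse_complement = revComp(seq))
}

# ±window bp of sequence centred on the junction-adjacent base of a break site
.breakWindow <- function(genome, contig, pos, window) {
  len <- length(genome[[contig]])
  lo <- max(1L, pos - window)
  hi <- min(len, pos + window)
  list(seq = as.character(Biostrings::subseq(genome[[contig]], lo, hi)), lo = lo)
}

#' Classify junction insertions as none / miscellaneous / templated
#'
#' A junction insertion is *templated* when it is at least `minlen` bp long
#' and its sequence has an exact match within ±`window` bp around either
#' break site, searched in all four literal orientations (normal, reversed,
#' complemented, reverse-complemented). Insertions below `minlen`, or with no
#' template hit, are *miscellaneous*; absent insertions are *no_insertion*.
#' All hits are recorded.
#'
#' @param x A [TranslocationSet-class].
#' @param genome Named `DNAStringSet`.
#' @param window Search half-window around each break site (default 25 bp).
#' @param minlen Minimum templated insert length (default 3 bp).
#' @return data.frame with one row per fusion: `fusionId`, `category`,
#'   `insertLen`, `nHits`, `bestHit` (site:offset:orientation of the first
#'   hit) and a `templateHits` list column of per-hit data.frames
#'   (site, offset of the hit start relative to the breakpoint base,
#'   orientation).
#' @export
classifyInsertion <- function(x, genome, window = 25L, minlen = 3L) {
  f <- fusions(x)
  n <- nrow(f)
  category <- character(n)
  insertLen <- integer(n)
  hitsList <- vector("list", n)
  roles <- .flankRoles(f)
  for (i in seq_len(n)) {
    ins <- f$insertSeq[i]
    insertLen[i] <- nchar(ins)
    hits <- data.frame(site = character(0), offset = integer(0),
                       orientation = character(0))
    if (nchar(ins) > 0) {
      sites <- list(A = list(contig = roles$left$contig[i], pos = roles$left$pos[i]),
                    B = list(contig = roles$right$contig[i], pos = roles$right$pos[i]))
      for (sname in names(sites)) {
        s <- sites[[sname]]
        wd <- .breakWindow(genome, s$contig, s$pos, window)
        for (ori in .ORIENTATIONS) {
          qry <- .orientSeq(ins, ori)
          m <- gregexpr(qry, wd$seq, fixed = TRUE)[[1]]
          if (m[1] != -1) {
            off <- as.integer(m) + wd$lo - 1L - s$pos
            hits <- rbind(hits, data.frame(site = sname, offset = off,
                                           orientation = ori))
          }
        }
      }
    }
    hitsList[[i]] <- hits
    category[i] <- if (insertLen[i] == 0) "no_insertion"
    else if (insertLen[i] >= minlen && nrow(hits) > 0) "templated"
    else "miscellaneous"
  }
  out <- data.frame(fusionId = f$fusionId, ttype = f$ttype,
                    category = category, insertLen = insertLen,
                    nHits = vapply(hitsList, nrow, integer(1)),
                    bestHit = vapply(hitsList, function(h)
                      if (nrow(h)) paste0(h$site[1], ":", h$offset[1], ":",
                                          h$orientation[1]) else "", character(1)))
  out$templateHits <- hitsList
  out
}

#' Fraction of junctions per insertion category
#'
#' @param calls data.frame from [classifyInsertion()] (or any data.frame with
#'   a `category` column).
#' @return List with `fractions` (named: no_insertion, miscellaneous,
#'   templated; sums to 1) and `n`. Empty input yields all-zero fractions
#'   with `n = 0`.
#' @export
insertionDistribution <- function(calls) {
  lv <- c("no_insertion", "miscellaneous", "templated")
  n <- nrow(calls)
  counts <- table(factor(calls$category, levels = lv))
  fr <- if (n > 0) as.numeric(counts) / n else rep(0, 3)
  list(fractions = stats::setNames(fr, lv), n = n)
}
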