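# Integer base codes (utf8) used by the flank/grid machinery. N is kept as its
# own code and never matches anything downstream.
.BASE_A <- 65L
.BASE_C <- 67L
.BASE_G <- 71L
.BASE_N <- 78L
.BASE_T <- 84L
.BASES <- c(.BASE_A, .BASE_C, .BASE_G, .BASE_T)

.COMP <- local({
  m <- integer(128)
  m[.BASE_A] <- .BASE_T
  m[.BASE_T] <- .BASE_A
  m[.BASE_C] <- .BASE_G
  m[.BASE_G] <- .BASE_C
  m[.BASE_N] <- .BASE_N
  m
})

.checkAlphabet <- function(seq, what = "sequence") {
  bad <- grepl("[^ACGTN]", seq)
  if (any(bad))
    stop(what, " contains characters outside {A,C,G,T,N}: ",
         paste(utils::head(gsub("[ACGTN]", "", seq[bad]), 3), collapse = " "))
  invisible(TRUE)
}

#' Reverse complement of nucleotide strings
#'
#' Vectorised over a character vector of A/C/G/T/N strings; `N` maps to `N`.
#' An involution: `revComp(revComp(x)) == x`.
#'
#' @param seq Character vector of nucleotide strings (uppercase A/C/G/T/N).
#' @return Character vector of the same length.
#' @examples
#' revComp(c("ACGT", "AAAC"))
#' @export
revComp <- function(seq) {
  if (length(seq) == 0) return(character(0))
  seq <- toupper(seq)
  .checkAlphabet(seq)
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
  names(out) <- names(seq)
  out
}

# complement without reversal (one of the four literal orientations of the
# templated-insert search)
.complementStr <- function(seq) {
  chartr("ACGTN", "TGCAN", seq)
}

.reverseStr <- function(seq) {
  vapply(strsplit(seq, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

# Signed flank position labels: -w..-1 are the w bases beyond the breakpoint
# (not part of the fusion product), 0 is the junction-adjacent retained base,
# +1..+(w-1) the retained bases proceeding away from the junction.
#' Signed position labels of a junction flank window
#'
#' @param w Half-window size in bp (the flank holds `2*w` bases).
#' @return Integer vector `-w .. w-1` in the storage order of flank matrices.
#' @export
flankLabels <- function(w) {
  seq.int(-w, w - 1L)
}

# genome (DNAStringSet) -> list of integer vectors for O(1) base lookup
.genomeInts <- function(genome) {
  lapply(as.character(genome), utf8ToInt)
}

# Extract flank base matrices for n sites on one orientation rule.
#
# side "L": the retained segment ends at pos  (genomic position = pos - label)
# side "R": the retained segment starts at pos (genomic position = pos + label)
# rc TRUE: the segment enters the fusion product reverse-complemented, so the
# base read at each label is complemented (the position mapping above already
# encodes the reversal of reading direction).
#
# Returns an n x 2w integer matrix; positions beyond the contig are NA.
.flankMatrix <- function(gints, contig, pos, side, rc, w) {
  n <- length(pos)
  labs <- flankLabels(w)
  out <- matrix(NA_integer_, nrow = n, ncol = 2L * w)
  if (n == 0) return(out)
  sgn <- rep_len(ifelse(side == "L", -1L, 1L), n)
  rc <- rep_len(rc, n)
  contig <- rep_len(contig, n)
  posm <- matrix(pos, nrow = n, ncol = 2L * w) + outer(sgn, labs, `*`)
  for (ct in unique(contig)) {
    rows <- which(contig == ct)
    g <- gints[[ct]]
    pm <- posm[rows, , drop = FALSE]
    ok <- pm >= 1L & pm <= length(g)
    vals <- matrix(NA_integer_, nrow = length(rows), ncol = 2L * w)
    vals[ok] <- g[pm[ok]]
    out[rows, ] <- vals
  }
  doRc <- which(rc)
  if (length(doRc)) {
    v <- out[doRc, , drop = FALSE]
    nz <- !is.na(v)
    v[nz] <- .COMP[v[nz]]
    out[doRc, ] <- v
  }
  out
}

.intsToStr <- function(m) {
  apply(m, 1L, function(r) intToUtf8(r[!is.na(r)]))
}
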