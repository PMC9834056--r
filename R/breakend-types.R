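# Role of each break site implied by the shape of the record annotating it.
# side "L": retained segment ends at pos; "R": retained segment starts at pos.
.localSide <- c(`1` = "L", `2` = "L", `3` = "R", `4` = "R")
.mateSide  <- c(`1` = "R", `2` = "L", `3` = "L", `4` = "R")

#' Pair mate breakend records into fusion precursors
#'
#' Breakend callers annotate each fusion twice, once from each partner, linked
#' by reciprocal `MATEID`s. Records lacking a `MATEID` are paired by
#' reciprocal coordinates (each record's mate pointer must hit the partner's
#' position within the merged confidence intervals). Unpaired singletons are
#' dropped with a warning.
#'
#' @param breakends data.frame as returned by [readSvVcf()].
#' @return data.frame of mate pairs, one row per fusion, with `A`/`B` suffixed
#'   columns in record-read order (not yet canonical; see
#'   [canonicalizeFusions()]).
#' @export
pairMates <- function(breakends) {
  b <- breakends
  emptyPair <- function() data.frame(
    idA = character(0), contigA = character(0), posA = integer(0),
    btypeA = integer(0), insertA = character(0), ciALo = integer(0), ciAHi = integer(0),
    idB = character(0), contigB = character(0), posB = integer(0),
    btypeB = integer(0), insertB = character(0), ciBLo = integer(0), ciBHi = integer(0),
    sampleId = character(0))
  if (is.null(b) || nrow(b) == 0) return(emptyPair())
  used <- rep(FALSE, nrow(b))
  rowsA <- integer(0); rowsB <- integer(0)
  idIndex <- match(b$mateId, b$recordId)
  for (i in seq_len(nrow(b))) {
    if (used[i]) next
    j <- NA_integer_
    if (!is.na(b$mateId[i])) {
      j <- idIndex[i]
      if (!is.na(j) && (used[j] || j == i)) j <- NA_integer_
    } else {
      # reciprocal-coordinate pairing within merged CIs
      tol <- function(k, l) max(abs(c(b$ciLo[k], b$ciHi[k], b$ciLo[l], b$ciHi[l])))
      cand <- which(!used & is.na(b$mateId) & seq_len(nrow(b)) != i &
                      b$contig == b$mateContig[i] & b$mateContig == b$contig[i])
      for (k in cand) {
        if (abs(b$pos[k] - b$matePos[i]) <= tol(i, k) &&
            abs(b$pos[i] - b$matePos[k]) <= tol(i, k)) { j <- k; break }
      }
    }
    if (is.na(j)) next
    used[i] <- TRUE; used[j] <- TRUE
    rowsA <- c(rowsA, i); rowsB <- c(rowsB, j)
  }
  nUnpaired <- sum(!used)
  if (nUnpaired > 0)
    warning(nUnpaired, " unpaired breakend record(s) dropped")
  if (!length(rowsA)) return(emptyPair())
  data.frame(idA = b$recordId[rowsA], contigA = b$contig[rowsA],
             posA = b$pos[rowsA], btypeA = b$btype[rowsA],
             insertA = b$insertSeq[rowsA],
             ciALo = b$ciLo[rowsA], ciAHi = b$ciHi[rowsA],
             idB = b$recordId[rowsB], contigB = b$contig[rowsB],
             posB = b$pos[rowsB], btypeB = b$btype[rowsB],
             insertB = b$insertSeq[rowsB],
             ciBLo = b$ciLo[rowsB], ciBHi = b$ciHi[rowsB],
             sampleId = b$sampleId[rowsA])
}

#' Canonicalize mate pairs into a TranslocationSet
#'
#' Re-expresses `]p]t` (type 3) fusions as type 1 viewed from the other
#' partner, orders the two break sites lexicographically by (contig, pos),
#' and selects the insert sequence in product orientation (for type 2 the
#' record at the lexicographically first site; for type 4 the record at the
#' second site, whose retained segment enters the product in sense
#' orientation). The result is independent of which mate record was read
#' first.
#'
#' @param pairs data.frame from [pairMates()].
#' @return A [TranslocationSet-class].
#' @export
canonicalizeFusions <- function(pairs) {
  p <- pairs
  n <- nrow(p)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    ba <- as.character(p$btypeA[i]); bb <- as.character(p$btypeB[i])
    okShapes <- (ba %in% c("1", "3") && bb %in% c("1", "3") && ba != bb) ||
      (ba == "2" && bb == "2") || (ba == "4" && bb == "4")
    if (!okShapes)
      stop("inconsistent mate shapes for pair ", p$idA[i], "/", p$idB[i],
           " (types ", ba, "/", bb, ")")
    ttype <- if (ba %in% c("1", "3")) 1L else as.integer(ba)
    sideA <- .localSide[[ba]]; sideB <- .localSide[[bb]]
    # order break sites lexicographically by (contig, pos)
    aFirst <- p$contigA[i] < p$contigB[i] ||
      (p$contigA[i] == p$contigB[i] && p$posA[i] <= p$posB[i])
    pick <- function(a, b) if (aFirst) c(a, b) else c(b, a)
    contig <- pick(p$contigA[i], p$contigB[i])
    pos <- as.integer(pick(p$posA[i], p$posB[i]))
    side <- pick(sideA, sideB)
    ciLo <- as.integer(pick(p$ciALo[i], p$ciBLo[i]))
    ciHi <- as.integer(pick(p$ciAHi[i], p$ciBHi[i]))
    ins <- pick(p$insertA[i], p$insertB[i])
    rc <- c(FALSE, FALSE)
    insertSeq <- ins[1]
    if (ttype == 2L) {
      rc <- c(FALSE, TRUE)
      insertSeq <- ins[1]           # record at canonical first site
    } else if (ttype == 4L) {
      rc <- c(TRUE, FALSE)
      insertSeq <- ins[2]           # record at canonical second site
    } else {
      # type 1: insert is sense in both records; take the t[p[ record's
      insertSeq <- if (side[1] == "L") ins[1] else ins[2]
    }
    out[[i]] <- data.frame(
      contigA = contig[1], posA = pos[1], sideA = side[1], rcA = rc[1],
      contigB = contig[2], posB = pos[2], sideB = side[2], rcB = rc[2],
      ttype = ttype, insertSeq = insertSeq,
      ciALo = ciLo[1], ciAHi = ciHi[1], ciBLo = ciLo[2], ciBHi = ciHi[2],
      sampleId = p$sampleId[i],
      sourceIds = paste(sort(c(p$idA[i], p$idB[i])), collapse = ","))
  }
  f <- if (n) do.call(rbind, out) else
    data.frame(contigA = character(0), posA = integer(0), sideA = character(0),
               rcA = logical(0), contigB = character(0), posB = integer(0),
               sideB = character(0), rcB = logical(0), ttype = integer(0),
               insertSeq = character(0), ciALo = integer(0), ciAHi = integer(0),
               ciBLo = integer(0), ciBHi = integer(0), sampleId = character(0),
               sourceIds = character(0))
  f <- f[order(f$contigA, f$posA, f$contigB, f$posB, f$ttype), , drop = FALSE]
  rownames(f) <- NULL
  f <- cbind(fusionId = if (nrow(f)) paste0("fus", seq_len(nrow(f))) else character(0),
             f, stringsAsFactors = FALSE)
  TranslocationSet(f)
}

# Which break site provides the left vs right flank of the junction product,
# and with which orientation (flank orientation rules, per type).
.flankRoles <- function(f) {
  n <- nrow(f)
  left <- data.frame(contig = character(n), pos = integer(n),
                     side = character(n), rc = logical(n))
  right <- left
  for (i in seq_len(n)) {
    if (f$ttype[i] == 1L) {
      if (f$sideA[i] == "L") {
        left[i, ] <- list(f$contigA[i], f$posA[i], "L", FALSE)
        right[i, ] <- list(f$contigB[i], f$posB[i], "R", FALSE)
      } else {
        left[i, ] <- list(f$contigB[i], f$posB[i], "L", FALSE)
        right[i, ] <- list(f$contigA[i], f$posA[i], "R", FALSE)
      }
    } else if (f$ttype[i] == 2L) {
      left[i, ] <- list(f$contigA[i], f$posA[i], "L", FALSE)
      right[i, ] <- list(f$contigB[i], f$posB[i], "L", TRUE)
    } else {
      left[i, ] <- list(f$contigA[i], f$posA[i], "R", TRUE)
      right[i, ] <- list(f$contigB[i], f$posB[i], "R", FALSE)
    }
  }
  list(left = left, right = right)
}

#' Extract oriented junction flank pairs
#'
#' For each fusion, extracts the `2w`-base windows around both break sites in
#' the orientation its type mandates: type 1 left and right flanks are both
#' 5'->3' sense; the type 2 right flank and the type 4 left flank are reverse
#' complemented. Bases are returned as integer matrices in signed-label order
#' ([flankLabels()]); fusions whose window exceeds a contig end are flagged
#' `ok = FALSE` and excluded from grid statistics by downstream code (a
#' message reports how many).
#'
#' @param x A [TranslocationSet-class].
#' @param genome Named `DNAStringSet`.
#' @param w Half-window in bp (default 4, the translocation grid).
#' @return List with integer matrices `left` and `right` (`n x 2w`, columns
#'   labelled by signed positions), logical `ok`, `labels`, and `ttype`.
#' @export
extractFlanks <- function(x, genome, w = 4L) {
  f <- fusions(x)
  gints <- .genomeInts(genome)
  bad <- !(f$contigA %in% names(gints)) | !(f$contigB %in% names(gints))
  if (any(bad)) stop("fusion contig absent from genome: ",
                     paste(unique(c(f$contigA, f$contigB)[bad]), collapse = ","))
  roles <- .flankRoles(f)
  left <- .flankMatrix(gints, roles$left$contig, roles$left$pos,
                       roles$left$side, roles$left$rc, w)
  right <- .flankMatrix(gints, roles$right$contig, roles$right$pos,
                        roles$right$side, roles$right$rc, w)
  ok <- !apply(is.na(left), 1, any) & !apply(is.na(right), 1, any)
  if (any(!ok))
    message(sum(!ok), " fusion(s) with flank window beyond contig bounds ",
            "excluded from grid statistics")
  labs <- flankLabels(w)
  colnames(left) <- colnames(right) <- as.character(labs)
  list(left = left, right = right, ok = ok, labels = labs,
       ttype = f$ttype, fusionId = f$fusionId)
}

#' Render flank matrices as strings (debugging/report aid)
#'
#' @param flanks Result of [extractFlanks()].
#' @return data.frame with fusionId, type and the two flanks in signed-label
#'   order (`-w .. +w-1`).
#' @export
flankStrings <- function(flanks) {
  asStr <- function(m) apply(m, 1, function(r) intToUtf8(ifelse(is.na(r), 46L, r)))
  data.frame(fusionId = flanks$fusionId, ttype = flanks$ttype,
             leftFlank = asStr(flanks$left), rightFlank = asStr(flanks$right),
             ok = flanks$ok)
}
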