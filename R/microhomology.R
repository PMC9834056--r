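.toIntsFlank <- function(x, what = "flank") {
  if (is.character(x)) {
    .checkAlphabet(x, what)
    utf8ToInt(x)
  } else as.integer(x)
}

#' Binary junction match grid for one flank pair
#'
#' Compares every base of the left flank with every base of the right flank:
#' `m[i, j] = 1` iff `left[i] == right[j]` and neither base is `N`.
#' Rows index left-flank signed labels, columns right-flank labels.
#'
#' @param left,right Flank sequences in signed-label order, as strings of
#'   length `2w` or integer base-code vectors.
#' @return `2w x 2w` binary matrix with label dimnames.
#' @export
junctionMatchGrid <- function(left, right) {
  l <- .toIntsFlank(left, "left flank")
  r <- .toIntsFlank(right, "right flank")
  if (length(l) != length(r)) stop("flanks must have equal length")
  if (length(l) %% 2L != 0L) stop("flank length must be 2w")
  w <- length(l) / 2L
  m <- outer(l, r, `==`) & outer(l != .BASE_N, r != .BASE_N, `&`)
  m[is.na(m)] <- FALSE
  .labelGrid(m + 0, w)
}

#' Aggregate binary match grids into a frequency HomologyGrid
#'
#' Element-wise mean over the per-junction binary grids; the result records
#' the junction count `n`.
#'
#' @param grids List of equally sized binary matrices ([junctionMatchGrid()]).
#' @return A [HomologyGrid-class] with frequencies only.
#' @export
aggregateGrids <- function(grids) {
  if (length(grids) == 0) stop("cannot aggregate zero grids")
  d <- dim(grids[[1]])
  if (!all(vapply(grids, function(g) all(dim(g) == d), logical(1))))
    stop("grids have mismatched dimensions")
  HomologyGrid(Reduce(`+`, grids) / length(grids), w = d[1] / 2L,
               n = length(grids))
}

# frequency grid straight from flank matrices (rows with NA/nonmissing
# handled by the ok mask); returns list(matrix, n)
.gridFromFlanks <- function(left, right, ok = NULL) {
  if (is.null(ok)) ok <- !apply(is.na(left), 1, any) & !apply(is.na(right), 1, any)
  L <- left[ok, , drop = FALSE]
  R <- right[ok, , drop = FALSE]
  d <- ncol(L)
  n <- nrow(L)
  m <- matrix(0, d, d)
  if (n > 0) {
    for (j in seq_len(d)) {
      rj <- R[, j]
      hit <- (L == rj) & (L != .BASE_N) & (rj != .BASE_N)
      m[, j] <- colSums(hit) / n
    }
  }
  list(matrix = m, n = n)
}

#' Observed junction match-frequency grid for a set of fusions
#'
#' @param flanks Result of [extractFlanks()] (or of [deletionFlanks()]).
#' @return A [HomologyGrid-class] (frequencies only; see
#'   [permutationNullGrid()] / [testGrid()] for the per-bin statistics).
#' @export
observedGrid <- function(flanks) {
  g <- .gridFromFlanks(flanks$left, flanks$right, flanks$ok)
  if (g$n == 0) stop("no junction with complete flanks")
  HomologyGrid(g$matrix, w = ncol(flanks$left) / 2L, n = g$n)
}

# orientation roles used when placing random junctions of each type
.typeRoles <- function(ttype) {
  list(left = data.frame(side = ifelse(ttype == 4L, "R", "L"),
                         rc = ttype == 4L),
       right = data.frame(side = ifelse(ttype == 2L, "L", "R"),
                          rc = ttype == 2L))
}

# draw n random break sites (contig, pos) uniformly over the mappable genome
# (length-weighted contigs, >= w from the ends)
.drawSites <- function(gints, w, n) {
  lens <- vapply(gints, length, integer(1))
  avail <- pmax(lens - 2L * w, 0L)
  if (all(avail == 0)) stop("genome shorter than 2w on all contigs")
  ci <- sample.int(length(gints), n, replace = TRUE, prob = avail)
  pos <- w + 1L + floor(stats::runif(n) * avail[ci])
  list(contig = names(gints)[ci], pos = as.integer(pos))
}

# flank matrix for random sites honouring per-event orientation roles,
# redrawing any event whose window touches an N or a contig end
.randomFlanks <- function(gints, w, roles) {
  n <- nrow(roles)
  out <- matrix(NA_integer_, n, 2L * w)
  todo <- seq_len(n)
  for (iter in 1:100) {
    s <- .drawSites(gints, w, length(todo))
    fm <- .flankMatrix(gints, s$contig, s$pos, roles$side[todo], roles$rc[todo], w)
    bad <- apply(is.na(fm) | fm == .BASE_N, 1, any)
    out[todo[!bad], ] <- fm[!bad, , drop = FALSE]
    todo <- todo[bad]
    if (!length(todo)) break
  }
  if (length(todo)) stop("could not place random break sites clear of N runs")
  out
}

#' Per-bin permutation p-values against random genomic placement
#'
#' For each of `nPerm` permutations, the same number of junctions (with the
#' same type mix, hence the same flank orientation rules) is placed uniformly
#' at random on the genome (contigs weighted by length, positions at least
#' `w` from contig ends, N-overlapping draws rejected), flanks are extracted
#' and the 64 (or 256) bin frequencies computed. The one-sided upper-tail
#' p-value per bin is `(r + 1) / (nPerm + 1)` where `r` counts permutations
#' with bin frequency at least the observed one. Deterministic given `seed`.
#'
#' @param grid Observed [HomologyGrid-class] (from [observedGrid()]).
#' @param ttype Integer vector of junction types (1/2/4) for the junctions
#'   aggregated in `grid`; deletion grids use all type 1.
#' @param genome Named `DNAStringSet`.
#' @param nPerm Number of permutations (100,000 for the full analysis;
#'   9,999 is the desk-scale test profile).
#' @param seed RNG seed.
#' @return Matrix of per-bin p-values.
#' @export
permutationNullGrid <- function(grid, ttype, genome, nPerm = 100000L, seed = 1L) {
  w <- grid@w
  n <- grid@n
  if (length(ttype) != n)
    stop("ttype must have one entry per junction in the grid (n = ", n, ")")
  gints <- .genomeInts(genome)
  obs <- grid@matrix
  d <- 2L * w
  set.seed(seed)
  exceed <- matrix(0L, d, d)
  chunk <- max(1L, min(nPerm, floor(1e6 / n)))
  done <- 0L
  roles <- .typeRoles(ttype)
  while (done < nPerm) {
    k <- min(chunk, nPerm - done)
    leftRoles <- roles$left[rep(seq_len(n), k), , drop = FALSE]
    rightRoles <- roles$right[rep(seq_len(n), k), , drop = FALSE]
    L <- .randomFlanks(gints, w, leftRoles)
    R <- .randomFlanks(gints, w, rightRoles)
    permId <- rep(seq_len(k), each = n)
    for (j in seq_len(d)) {
      rj <- R[, j]
      hit <- (L == rj) & (L != .BASE_N) & (rj != .BASE_N)
      counts <- rowsum(hit + 0L, permId)          # k x d match counts
      freq <- counts / n
      exceed[, j] <- exceed[, j] +
        colSums(freq >= matrix(obs[, j] - 1e-9, k, d, byrow = TRUE))
    }
    done <- done + k
  }
  p <- (exceed + 1) / (nPerm + 1)
  .labelGrid(p, w)
}

#' Benjamini-Hochberg adjustment over grid bins
#'
#' Standard step-up FDR control across all `m` bins (monotone, capped at 1).
#'
#' @param p Numeric vector or matrix of p-values in (0, 1].
#' @param m Number of tests (defaults to `length(p)`).
#' @return q-values with the shape of `p`.
#' @export
bhAdjust <- function(p, m = length(p)) {
  q <- stats::p.adjust(as.vector(p), method = "BH", n = m)
  if (is.matrix(p)) q <- matrix(q, nrow(p), ncol(p), dimnames = dimnames(p))
  q
}

#' Observed grid + permutation null + BH adjustment in one call
#'
#' @inheritParams permutationNullGrid
#' @param flanks Result of [extractFlanks()] / [deletionFlanks()].
#' @return A [HomologyGrid-class] with `pValues` and `qValues` filled in.
#' @export
testGrid <- function(flanks, genome, nPerm = 100000L, seed = 1L) {
  grid <- observedGrid(flanks)
  p <- permutationNullGrid(grid, flanks$ttype[flanks$ok], genome,
                           nPerm = nPerm, seed = seed)
  HomologyGrid(grid@matrix, w = grid@w, n = grid@n, pValues = p,
               qValues = bhAdjust(p), nPerm = nPerm, seed = seed)
}

#' Junction microhomology length from a flank pair
#'
#' The maximal number of consecutive junction-spanning matches in one
#' direction: either the retained bases of the left flank (labels 0, +1, ...)
#' matching the excluded bases of the right flank (labels -1, -2, ...), or
#' vice versa, compared base-by-base moving away from the junction. `N`
#' matches nothing; the result is 0 when the first comparison fails in both
#' directions, and is capped at `w`.
#'
#' @param flanks Result of [extractFlanks()], or a single flank pair given as
#'   two strings via `left`/`right`.
#' @param left,right Optional single flank strings (alternative interface).
#' @return Integer vector of microhomology lengths (NA where flanks were
#'   unavailable).
#' @export
microhomologyLength <- function(flanks = NULL, left = NULL, right = NULL) {
  if (!is.null(left)) {
    flanks <- list(left = matrix(.toIntsFlank(left), nrow = 1),
                   right = matrix(.toIntsFlank(right), nrow = 1),
                   ok = TRUE)
  }
  L <- flanks$left
  R <- flanks$right
  w <- ncol(L) / 2L
  runLen <- function(M1, M2) {
    # M1 retained cols (0..w-1), M2 excluded cols (-1..-w)
    eq <- matrix(FALSE, nrow(L), w)
    for (j in seq_len(w)) {
      a <- M1[, w + j]          # label j-1
      b <- M2[, w + 1L - j]     # label -j
      eq[, j] <- !is.na(a) & !is.na(b) & a == b & a != .BASE_N
    }
    rowSums(t(apply(eq, 1, cumprod)))
  }
  if (nrow(L) == 0) return(integer(0))
  res <- pmax(runLen(L, R), runLen(R, L))
  res[!flanks$ok] <- NA_integer_
  as.integer(res)
}

#' Base composition around break sites with a resampled genomic background
#'
#' Pools the oriented left and right flanks of the supplied junctions and
#' computes, at each signed label position, the percentage of A, C, T and G
#' (flanks containing `N` are dropped and counted). The background is the
#' mean percentage over `nPerm` draws of equally many uniformly random
#' genomic windows.
#'
#' @param flanks Result of [extractFlanks()] for the junction subset of
#'   interest (the analysis uses those with microhomology length 1).
#' @param genome Named `DNAStringSet`.
#' @param nPerm Background resampling count (default 25,000).
#' @param seed RNG seed.
#' @return A [BaseComposition-class].
#' @export
baseComposition <- function(flanks, genome, nPerm = 25000L, seed = 1L) {
  M <- rbind(flanks$left[flanks$ok, , drop = FALSE],
             flanks$right[flanks$ok, , drop = FALSE])
  if (nrow(M) == 0) stop("no junction flanks supplied")
  w <- ncol(M) / 2L
  clean <- !apply(M == .BASE_N | is.na(M), 1, any)
  nDropped <- sum(!clean)
  M <- M[clean, , drop = FALSE]
  if (nrow(M) == 0) stop("all flanks contain N")
  pct <- function(mat) {
    t(vapply(.BASES, function(b) 100 * colMeans(mat == b),
             numeric(ncol(mat))))
  }
  obs <- pct(M)
  dimnames(obs) <- list(c("A", "C", "G", "T"), as.character(flankLabels(w)))
  nSites <- nrow(M)
  gints <- .genomeInts(genome)
  set.seed(seed)
  total <- nPerm * nSites
  counts <- matrix(0, 4, 2L * w)
  done <- 0
  roles <- data.frame(side = "L", rc = FALSE)
  while (done < total) {
    k <- min(2e5, total - done)
    B <- .randomFlanks(gints, w, roles[rep(1, k), , drop = FALSE])
    for (bi in seq_along(.BASES))
      counts[bi, ] <- counts[bi, ] + colSums(B == .BASES[bi])
    done <- done + k
  }
  bg <- 100 * counts / total
  dimnames(bg) <- dimnames(obs)
  new("BaseComposition", w = as.integer(w), observed = obs, background = bg,
      nSites = as.integer(nSites), nDropped = as.integer(nDropped),
      nPerm = as.integer(nPerm), seed = as.integer(seed))
}
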