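#' Simulation configuration
#'
#' Defaults describe a desk-scale study: a two-contig 200 kb uniform-base
#' genome; 50 de novo translocations with the observed category mix of
#' junction insertions (77% none, 17% miscellaneous, 6% templated) and a
#' short-tailed junction-microhomology distribution; 200 deletions of 8-200
#' bp with a homology-length distribution concentrated at 0-1 bp; 10
#' inherited background events of each kind shared between a parent and the
#' offspring; and a sparse repeat track. All randomness derives
#' deterministically from `seed` (one sub-stream per component).
#'
#' @param seed Integer seed (mandatory).
#' @param ... Overrides for any default field.
#' @return Object of class `simConfig` (a validated list).
#' @export
simConfig <- function(seed, ...) {
  cfg <- list(
    seed = as.integer(seed),
    contigLengths = c(chrI = 100000L, chrII = 100000L),
    baseFreqs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
    nTranslocations = 50L,
    typeMix = c(`1` = 0.5, `2` = 0.25, `4` = 0.25),
    mhDist = c(`0` = 0.45, `1` = 0.30, `2` = 0.15, `3` = 0.07, `4` = 0.03),
    templatedInsertRate = 0.06,
    miscInsertRate = 0.17,
    insertLenRange = c(3L, 8L),
    nDeletions = 200L,
    deletionHomologyDist = c(`0` = 0.55, `1` = 0.25, `2` = 0.10, `3` = 0.05,
                             `4` = 0.03, `5` = 0.01, `6` = 0.005, `7` = 0.005),
    deletionSizeRange = c(8L, 200L),
    nInheritedTranslocations = 10L,
    nInheritedDeletions = 10L,
    repeatDensity = 0.05,
    repeatClasses = c("LTR", "LINE", "SINE", "DNA", "Satellite"),
    ciposJitter = 0L,
    parents = c("P0a", "P0b"),
    offspringId = "F1",
    w = 4L)
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown simConfig field(s): ", paste(bad, collapse = ","))
  cfg[names(dots)] <- dots
  if (is.na(cfg$seed)) stop("seed is mandatory")
  # mhDist / deletionHomologyDist may be NULL: junction context left random
  # (no planted homology), truth length recorded as NA
  for (f in c("typeMix", "mhDist", "deletionHomologyDist", "baseFreqs")) {
    if (is.null(cfg[[f]])) {
      if (f %in% c("typeMix", "baseFreqs")) stop(f, " is required")
      next
    }
    if (any(cfg[[f]] < 0)) stop(f, " must be non-negative")
    cfg[[f]] <- cfg[[f]] / sum(cfg[[f]])
  }
  for (r in c("templatedInsertRate", "miscInsertRate", "repeatDensity"))
    if (cfg[[r]] < 0 || cfg[[r]] > 1) stop(r, " must be in [0,1]")
  if (cfg$templatedInsertRate + cfg$miscInsertRate > 1)
    stop("insert rates sum to more than 1")
  if (min(cfg$contigLengths) < 2L * max(cfg$w, 8L))
    stop("contigs must be at least twice the flank window")
  structure(cfg, class = "simConfig")
}

# deterministic per-component sub-seed below 2^31
.subSeed <- function(seed, component) {
  h <- sum(utf8ToInt(component) * seq_along(utf8ToInt(component)))
  as.integer((as.numeric(seed) * 48271 + h * 9973) %% 2147483563)
}

#' Simulate an i.i.d. random genome
#'
#' @param config A [simConfig()].
#' @return Named `DNAStringSet` with bases drawn independently at the
#'   configured frequencies; deterministic per seed.
#' @export
simulateGenome <- function(config) {
  set.seed(.subSeed(config$seed, "genome"))
  g <- lapply(config$contigLengths, function(len)
    sample(.BASES, len, replace = TRUE, prob = config$baseFreqs))
  out <- Biostrings::DNAStringSet(vapply(g, intToUtf8, character(1)))
  names(out) <- names(config$contigLengths)
  out
}

# --- internal simulation state -------------------------------------------

.simState <- function(genome) {
  env <- new.env(parent = emptyenv())
  env$g <- .genomeInts(genome)
  env$reserved <- lapply(env$g, function(x) matrix(integer(0), ncol = 2))
  env
}

.finalizeGenome <- function(env) {
  out <- Biostrings::DNAStringSet(vapply(env$g, intToUtf8, character(1)))
  names(out) <- names(env$g)
  out
}

.reserve <- function(env, contig, lo, hi) {
  env$reserved[[contig]] <- rbind(env$reserved[[contig]], c(lo, hi))
}

.isFree <- function(env, contig, lo, hi) {
  r <- env$reserved[[contig]]
  nrow(r) == 0 || all(hi < r[, 1] | lo > r[, 2])
}

# draw a free genomic position with `margin` clear space either side
.drawFreeSite <- function(env, margin) {
  lens <- vapply(env$g, length, integer(1))
  for (i in 1:2000) {
    ci <- sample.int(length(lens), 1, prob = pmax(lens - 2 * margin, 0))
    pos <- sample.int(lens[ci] - 2L * margin, 1) + margin
    if (.isFree(env, names(lens)[ci], pos - margin, pos + margin)) {
      .reserve(env, names(lens)[ci], pos - margin, pos + margin)
      return(list(contig = names(lens)[ci], pos = as.integer(pos)))
    }
  }
  stop("could not place event: genome too crowded for the requested counts")
}

# flank-label addressing of genome bases for a break-site role
.flankPos <- function(site, label) {
  if (site$side == "L") site$pos - label else site$pos + label
}
.getFlankBase <- function(env, site, label) {
  v <- env$g[[site$contig]][.flankPos(site, label)]
  if (site$rc) .COMP[v] else v
}
.setFlankBase <- function(env, site, label, val) {
  env$g[[site$contig]][.flankPos(site, label)] <- if (site$rc) .COMP[val] else val
}
.differentBase <- function(avoid) {
  sample(setdiff(.BASES, avoid), 1)
}

# plant an exact junction microhomology of length m between a left-role and
# right-role break site: the last m retained bases of the left flank are
# copied into the excluded bases of the right flank adjacent to the
# junction, the next comparison is forced to mismatch, and the opposite
# direction is broken at its first comparison.
.plantMicrohomology <- function(env, leftSite, rightSite, m, w) {
  if (m > 0) for (j in seq_len(m) - 1L)
    .setFlankBase(env, rightSite, -(j + 1L), .getFlankBase(env, leftSite, j))
  if (m < w)
    .setFlankBase(env, rightSite, -(m + 1L),
                  .differentBase(.getFlankBase(env, leftSite, m)))
  .setFlankBase(env, leftSite, -1L,
                .differentBase(.getFlankBase(env, rightSite, 0L)))
}

# draw an insert for one junction; templated inserts are copied out of the
# final +/-25 bp window of one break site in one of the four orientations
.drawInsert <- function(env, leftSite, rightSite, config) {
  u <- stats::runif(1)
  if (u < config$templatedInsertRate) {
    len <- sample(seq(config$insertLenRange[1], config$insertLenRange[2]), 1)
    siteName <- sample(c("A", "B"), 1)
    site <- if (siteName == "A") leftSite else rightSite
    ori <- sample(.ORIENTATIONS, 1)
    srcStart <- site$pos - 25L + sample.int(51L - len, 1) - 1L
    src <- intToUtf8(env$g[[site$contig]][srcStart:(srcStart + len - 1L)])
    list(category = "templated", seq = .orientSeq(src, ori),
         site = siteName, offset = srcStart - site$pos, orientation = ori)
  } else if (u < config$templatedInsertRate + config$miscInsertRate) {
    len <- sample(1:2, 1)
    list(category = "miscellaneous",
         seq = intToUtf8(sample(.BASES, len, replace = TRUE)),
         site = NA, offset = NA, orientation = NA)
  } else list(category = "no_insertion", seq = "", site = NA, offset = NA,
              orientation = NA)
}

# mate-pair VCF records for one fusion (left role site + right role site,
# insert in product orientation)
.emitMatePair <- function(env, leftSite, rightSite, ttype, ins, ids, cipos,
                          sampleId) {
  refL <- intToUtf8(env$g[[leftSite$contig]][leftSite$pos])
  refR <- intToUtf8(env$g[[rightSite$contig]][rightSite$pos])
  loc <- function(s) paste0(s$contig, ":", s$pos)
  if (ttype == 1L) {
    altL <- paste0(refL, ins, "[", loc(rightSite), "[")
    altR <- paste0("]", loc(leftSite), "]", ins, refR)
  } else if (ttype == 2L) {
    altL <- paste0(refL, ins, "]", loc(rightSite), "]")
    altR <- paste0(refR, if (nchar(ins)) revComp(ins) else "", "]",
                   loc(leftSite), "]")
  } else {
    altL <- paste0("[", loc(rightSite), "[", if (nchar(ins)) revComp(ins) else "",
                   refL)
    altR <- paste0("[", loc(leftSite), "[", ins, refR)
  }
  data.frame(recordId = ids,
             contig = c(leftSite$contig, rightSite$contig),
             pos = c(leftSite$pos, rightSite$pos),
             refBase = c(refL, refR), alt = c(altL, altR),
             btype = classifyBreakend(c(altL, altR)),
             mateId = rev(ids),
             mateContig = c(rightSite$contig, leftSite$contig),
             matePos = c(rightSite$pos, leftSite$pos),
             ciLo = -cipos, ciHi = cipos,
             insertSeq = .parseBreakendAlt(c(altL, altR))$insertSeq,
             filterPass = TRUE, sampleId = sampleId)
}

#' Simulate translocations as mate-paired breakend call sets
#'
#' Plants, for each fusion, an exact junction microhomology drawn from the
#' configured length distribution (by editing the genome before
#' finalization, so truth is exact), optionally a miscellaneous (1-2 bp) or
#' templated (copied from within ±25 bp of a break site in one of the four
#' orientations) insertion, and emits both mate records with reciprocal
#' `MATEID`s. Inherited background fusions are written into one parent's
#' call set and the offspring's alike; de novo fusions only into the
#' offspring's.
#'
#' @param genome Named `DNAStringSet` (typically from [simulateGenome()]).
#' @param config A [simConfig()].
#' @param state Internal simulation state; when NULL a fresh one is built
#'   from `genome` and the edited genome is returned.
#' @return List: `genome` (edited), `offspring` (breakend data.frame),
#'   `parents` (named list of breakend data.frames), `truth` (one row per
#'   fusion: canonical coordinates, type, microhomology, insert category and
#'   template provenance, inherited flag).
#' @export
simulateTranslocations <- function(genome, config, state = NULL) {
  if (is.null(state)) state <- .simState(genome)
  env <- state
  set.seed(.subSeed(config$seed, "translocations"))
  w <- config$w
  nDen <- config$nTranslocations
  nInh <- config$nInheritedTranslocations
  n <- nDen + nInh
  inherited <- c(rep(FALSE, nDen), rep(TRUE, nInh))
  types <- as.integer(sample(names(config$typeMix), n, replace = TRUE,
                             prob = config$typeMix))
  mhs <- if (is.null(config$mhDist)) rep(NA_integer_, n) else
    as.integer(sample(names(config$mhDist), n, replace = TRUE,
                      prob = config$mhDist))
  margin <- 25L + max(w, config$insertLenRange[2]) + 8L
  offspring <- list(); parentRecs <- stats::setNames(
    rep(list(list()), length(config$parents)), config$parents)
  truth <- list()
  for (i in seq_len(n)) {
    tt <- types[i]
    s1 <- .drawFreeSite(env, margin)
    s2 <- .drawFreeSite(env, margin)
    if (tt == 1L) {
      leftSite <- c(s1, side = "L", rc = FALSE)
      rightSite <- c(s2, side = "R", rc = FALSE)
    } else if (tt == 2L) {
      # canonical first site carries the sense left flank
      first <- s1$contig < s2$contig || (s1$contig == s2$contig & s1$pos <= s2$pos)
      leftSite <- c(if (first) s1 else s2, side = "L", rc = FALSE)
      rightSite <- c(if (first) s2 else s1, side = "L", rc = TRUE)
    } else {
      first <- s1$contig < s2$contig || (s1$contig == s2$contig & s1$pos <= s2$pos)
      leftSite <- c(if (first) s1 else s2, side = "R", rc = TRUE)
      rightSite <- c(if (first) s2 else s1, side = "R", rc = FALSE)
    }
    if (!is.na(mhs[i])) .plantMicrohomology(env, leftSite, rightSite, mhs[i], w)
    ins <- .drawInsert(env, leftSite, rightSite, config)
    evId <- sprintf("tra%03d", i)
    ids <- paste0(config$offspringId, "_", evId, c("_a", "_b"))
    rec <- .emitMatePair(env, leftSite, rightSite, tt, ins$seq, ids,
                         config$ciposJitter, config$offspringId)
    offspring[[length(offspring) + 1]] <- rec
    parent <- NA_character_
    if (inherited[i]) {
      parent <- sample(config$parents, 1)
      pids <- paste0(parent, "_", evId, c("_a", "_b"))
      prec <- rec
      prec$recordId <- pids; prec$mateId <- rev(pids); prec$sampleId <- parent
      parentRecs[[parent]][[length(parentRecs[[parent]]) + 1]] <- prec
    }
    # canonical coordinate order for truth
    sites <- list(leftSite, rightSite)
    aFirst <- sites[[1]]$contig < sites[[2]]$contig ||
      (sites[[1]]$contig == sites[[2]]$contig && sites[[1]]$pos <= sites[[2]]$pos)
    A <- sites[[if (aFirst) 1 else 2]]; B <- sites[[if (aFirst) 2 else 1]]
    truth[[length(truth) + 1]] <- data.frame(
      eventId = evId, inherited = inherited[i], parent = parent,
      ttype = tt, contigA = A$contig, posA = A$pos,
      contigB = B$contig, posB = B$pos, mh = mhs[i],
      insertCategory = ins$category, insertLen = nchar(ins$seq),
      insertSeq = ins$seq, templateSite = ins$site,
      templateOffset = ins$offset, templateOrientation = ins$orientation)
  }
  list(genome = .finalizeGenome(env), state = env,
       offspring = if (length(offspring)) do.call(rbind, offspring) else
         .emptyBreakends(),
       parents = lapply(parentRecs, function(l)
         if (length(l)) do.call(rbind, l) else .emptyBreakends()),
       truth = do.call(rbind, truth))
}

#' Simulate deletions with planted junction homology
#'
#' Deletion sizes are uniform in the configured range; each junction's
#' homology length is drawn from the configured distribution and planted by
#' editing the bases following the deletion to copy the deleted prefix
#' (forcing a mismatch at the next base and preventing left-shift so that
#' the planted length is exact after left-alignment).
#'
#' @inheritParams simulateTranslocations
#' @return List: `genome`, `offspring` / `parents` (deletion `GRanges` in
#'   [readSvVcf()] layout), `truth` data.frame with planted sizes and
#'   homology lengths.
#' @export
simulateDeletions <- function(genome, config, state = NULL) {
  if (is.null(state)) state <- .simState(genome)
  env <- state
  set.seed(.subSeed(config$seed, "deletions"))
  nDen <- config$nDeletions
  nInh <- config$nInheritedDeletions
  n <- nDen + nInh
  inherited <- c(rep(FALSE, nDen), rep(TRUE, nInh))
  if (config$deletionSizeRange[1] < 1 ||
      config$deletionSizeRange[2] > min(vapply(env$g, length, integer(1))) / 10)
    stop("deletion size range outside [1, contig length/10]")
  sizes <- sample(seq(config$deletionSizeRange[1], config$deletionSizeRange[2]),
                  n, replace = TRUE)
  homs <- if (is.null(config$deletionHomologyDist)) rep(NA_integer_, n) else
    as.integer(sample(names(config$deletionHomologyDist), n, replace = TRUE,
                      prob = config$deletionHomologyDist))
  rows <- list(); truth <- list()
  for (i in seq_len(n)) {
    sz <- sizes[i]; h <- homs[i]
    site <- .drawFreeSite(env, as.integer(sz + 40L))
    s <- site$pos; e <- s + sz - 1L
    g <- env$g[[site$contig]]
    if (!is.na(h)) {
      for (j in seq_len(h) - 1L) g[e + 1L + j] <- g[s + j]
      g[e + 1L + h] <- sample(setdiff(.BASES, g[s + h]), 1)
      if (g[s - 1L] == g[e]) g[s - 1L] <- sample(setdiff(.BASES, g[e]), 1)
      env$g[[site$contig]] <- g
    }
    evId <- sprintf("del%03d", i)
    parent <- if (inherited[i]) sample(config$parents, 1) else NA_character_
    rows[[length(rows) + 1]] <- data.frame(
      contig = site$contig, start = s, end = e, inherited = inherited[i],
      parent = parent, recordId = paste0(config$offspringId, "_", evId))
    truth[[length(truth) + 1]] <- data.frame(
      eventId = evId, inherited = inherited[i], parent = parent,
      contig = site$contig, start = s, end = e, size = sz, homology = h)
  }
  rows <- if (length(rows)) do.call(rbind, rows) else
    data.frame(contig = character(0), start = integer(0), end = integer(0),
               inherited = logical(0), parent = character(0),
               recordId = character(0))
  mkGr <- function(df, sampleId, prefix) {
    if (nrow(df) == 0) return(.emptyIndels())
    gr <- GenomicRanges::GRanges(df$contig, IRanges::IRanges(df$start, df$end))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      kind = "deletion", svlen = df$end - df$start + 1L, filterPass = TRUE,
      sampleId = sampleId, recordId = sub(paste0("^", config$offspringId),
                                          prefix, df$recordId))
    gr
  }
  parents <- stats::setNames(lapply(config$parents, function(p)
    mkGr(rows[!is.na(rows$parent) & rows$parent == p, , drop = FALSE], p, p)),
    config$parents)
  list(genome = .finalizeGenome(env), state = env,
       offspring = mkGr(rows, config$offspringId, config$offspringId),
       parents = parents, truth = do.call(rbind, truth))
}

#' Simulate a repeat-class track
#'
#' Draws non-overlapping intervals (100-500 bp) with classes from the
#' configured vocabulary until roughly `repeatDensity` of the genome is
#' covered, avoiding the reserved windows of already placed SV events so
#' that planted de novo events are not repeat-filtered by default.
#'
#' @inheritParams simulateTranslocations
#' @return `GRanges` with `repeatClass`, deterministic per seed.
#' @export
simulateRepeats <- function(genome, config, state = NULL) {
  if (is.null(state)) state <- .simState(genome)
  env <- state
  set.seed(.subSeed(config$seed, "repeats"))
  lens <- vapply(env$g, length, integer(1))
  target <- config$repeatDensity * sum(lens)
  placed <- 0
  out <- list()
  attempts <- 0
  while (placed < target && attempts < 20000) {
    attempts <- attempts + 1
    len <- sample(100:500, 1)
    ci <- sample.int(length(lens), 1, prob = lens)
    if (lens[ci] <= len + 2) next
    lo <- sample.int(lens[ci] - len - 1L, 1)
    hi <- lo + len - 1L
    if (!.isFree(env, names(lens)[ci], lo, hi)) next
    .reserve(env, names(lens)[ci], lo, hi)
    out[[length(out) + 1]] <- data.frame(
      contig = names(lens)[ci], start = lo, end = hi,
      repeatClass = sample(config$repeatClasses, 1))
    placed <- placed + len
  }
  if (!length(out)) return(GenomicRanges::GRanges(repeatClass = character(0)))
  df <- do.call(rbind, out)
  gr <- GenomicRanges::GRanges(df$contig, IRanges::IRanges(df$start, df$end),
                               repeatClass = df$repeatClass)
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

#' Simulate a complete parent/offspring study
#'
#' Composes [simulateGenome()], [simulateTranslocations()],
#' [simulateDeletions()] and [simulateRepeats()] on one shared genome state
#' and (optionally) writes the FASTA, per-sample VCFs, repeat BED and truth
#' TSVs. All outputs are byte-identical under a fixed seed.
#'
#' @param config A [simConfig()].
#' @param dir Optional output directory (created if needed).
#' @return List with `genome`, `offspring` (breakends + indels),
#'   `parents` (per-parent breakends + indels), `repeats`, `truth`
#'   (translocations + deletions data.frames) and, when `dir` is given,
#'   `paths`.
#' @export
simulateStudy <- function(config, dir = NULL) {
  genome0 <- simulateGenome(config)
  state <- .simState(genome0)
  tra <- simulateTranslocations(genome0, config, state)
  del <- simulateDeletions(genome0, config, state)
  repeats <- simulateRepeats(genome0, config, state)
  genome <- .finalizeGenome(state)
  offspring <- list(breakends = tra$offspring, indels = del$offspring)
  parents <- stats::setNames(lapply(config$parents, function(p)
    list(breakends = tra$parents[[p]], indels = del$parents[[p]])),
    config$parents)
  out <- list(genome = genome, offspring = offspring, parents = parents,
              repeats = repeats,
              truth = list(translocations = tra$truth, deletions = del$truth),
              config = config)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(genome = file.path(dir, "genome.fa"),
                  offspring = file.path(dir, paste0(config$offspringId, ".vcf")),
                  repeats = file.path(dir, "repeats.bed"),
                  truthTranslocations = file.path(dir, "truth_translocations.tsv"),
                  truthDeletions = file.path(dir, "truth_deletions.tsv"))
    writeGenome(genome, paths$genome)
    writeSvVcf(offspring$breakends, offspring$indels, genome, paths$offspring)
    for (p in config$parents) {
      paths[[paste0("parent_", p)]] <- file.path(dir, paste0(p, ".vcf"))
      writeSvVcf(parents[[p]]$breakends, parents[[p]]$indels, genome,
                 paths[[paste0("parent_", p)]])
    }
    writeRepeats(repeats, paths$repeats)
    utils::write.table(tra$truth, paths$truthTranslocations, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(del$truth, paths$truthDeletions, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    out$paths <- paths
  }
  out
}
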