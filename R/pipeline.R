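#' Analysis run configuration
#'
#' Defaults are the parameters of the full analysis: 8x8 grid (`w = 4`),
#' ±25 bp templated-insert search with a 3 bp minimum, 100,000 grid
#' permutations, 25,000 base-composition permutations, 8-200 bp deletion
#' bounds. `profile = "test"` differs only in the permutation counts
#' (9,999 / 2,500), for desk-scale runs.
#'
#' @param seed Integer seed for all randomness in the run.
#' @param profile `"full"` or `"test"`.
#' @param ... Overrides for any field.
#' @return Classed list `runConfig`.
#' @export
runConfig <- function(seed = 1L, profile = c("full", "test"), ...) {
  profile <- match.arg(profile)
  cfg <- list(seed = as.integer(seed), profile = profile,
              w = 4L, insertWindow = 25L, insertMinLen = 3L,
              nPermGrid = if (profile == "full") 100000L else 9999L,
              nPermBasecomp = if (profile == "full") 25000L else 2500L,
              deletionSize = c(8L, 200L), scheme = "celegans_1bp")
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown runConfig field(s): ", paste(bad, collapse = ","))
  cfg[names(dots)] <- dots
  structure(cfg, class = "runConfig")
}

.loadGenome <- function(x) {
  if (methods::is(x, "DNAStringSet")) x else readGenome(x)
}
.loadCalls <- function(x) {
  if (is.character(x)) readSvVcf(x) else x
}
.loadRepeats <- function(x) {
  if (is.null(x) || methods::is(x, "GRanges")) x else readRepeats(x)
}

.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
.writeGridTsv <- function(m, path) {
  df <- data.frame(label = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full translocation junction-signature analysis
#'
#' Cascade: caller-PASS filter, mate pairing, parental de novo filter,
#' repeat filter, duplicate collapse; breakend-type classification and flank
#' extraction; insertion categorization (templated / miscellaneous / none);
#' per-type junction match grids with permutation nulls and BH-adjusted
#' per-bin q-values (translocations with a templated insertion are excluded
#' from the grids); microhomology-length spectrum; and base composition of
#' microhomology-length-1 junctions against a resampled genomic background.
#'
#' @param genome FASTA path or `DNAStringSet`.
#' @param offspring VCF path or a list as from [readSvVcf()].
#' @param parents List of VCF paths / call lists (may be empty).
#' @param repeats BED path, `GRanges`, or NULL.
#' @param config A [runConfig()].
#' @param outDir Optional output directory for the TSV/JSON report bundle.
#' @return List with `report` ([FilterReport-class]), `translocations`
#'   ([TranslocationSet-class]), `insertions`, `distribution`, `grids`
#'   (per-type [HomologyGrid-class]), `mhLengths`, `baseComposition`
#'   (NULL when no mh-1 junction exists) and `config`.
#' @export
runTranslocationAnalysis <- function(genome, offspring, parents = list(),
                                     repeats = NULL, config = runConfig(),
                                     outDir = NULL) {
  if (missing(genome) || missing(offspring))
    stop("config error: genome and offspring call set are required")
  genome <- .loadGenome(genome)
  offspring <- .loadCalls(offspring)
  parents <- lapply(parents, .loadCalls)
  repeats <- .loadRepeats(repeats)

  filt <- denovoFilter(offspring, parents, repeats)
  trl <- filt$translocations
  message("de novo translocations after filtering: ", length(trl))

  flanks <- extractFlanks(trl, genome, w = config$w)
  calls <- classifyInsertion(trl, genome, window = config$insertWindow,
                             minlen = config$insertMinLen)
  distr <- insertionDistribution(calls)
  mh <- microhomologyLength(flanks)

  # per-type grids; templated-insert junctions are excluded because their
  # junction context is the insert, not the fused flanks
  keep <- calls$category != "templated" & flanks$ok
  grids <- list()
  for (tt in c(1L, 2L, 4L)) {
    idx <- which(fusions(trl)$ttype == tt & keep)
    if (!length(idx)) next
    sub <- list(left = flanks$left[idx, , drop = FALSE],
                right = flanks$right[idx, , drop = FALSE],
                ok = rep(TRUE, length(idx)),
                ttype = flanks$ttype[idx], labels = flanks$labels)
    grids[[paste0("type", tt)]] <- testGrid(sub, genome,
                                            nPerm = config$nPermGrid,
                                            seed = config$seed + tt)
  }

  mh1 <- which(!is.na(mh) & mh == 1L)
  basecomp <- NULL
  if (length(mh1)) {
    sub <- list(left = flanks$left[mh1, , drop = FALSE],
                right = flanks$right[mh1, , drop = FALSE],
                ok = rep(TRUE, length(mh1)))
    basecomp <- baseComposition(sub, genome, nPerm = config$nPermBasecomp,
                                seed = config$seed)
  }

  out <- list(report = filt$report, translocations = trl, indels = filt$indels,
              flanks = flanks, insertions = calls, distribution = distr,
              grids = grids, mhLengths = mh, baseComposition = basecomp,
              config = config)
  if (!is.null(outDir)) .writeTranslocationBundle(out, outDir)
  out
}

.writeTranslocationBundle <- function(res, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  .writeTsv(filterStages(res$report), file.path(outDir, "filter_report.tsv"))
  .writeTsv(fusions(res$translocations), file.path(outDir, "translocations.tsv"))
  .writeTsv(cbind(flankStrings(res$flanks), mhLength = res$mhLengths),
            file.path(outDir, "junction_flanks.tsv"))
  ins <- res$insertions
  ins$templateHits <- NULL
  .writeTsv(ins, file.path(outDir, "insertions.tsv"))
  jsonlite::write_json(list(distribution = as.list(res$distribution$fractions),
                            n = res$distribution$n,
                            mhLengthCounts = as.list(table(res$mhLengths)),
                            seed = res$config$seed,
                            profile = res$config$profile),
                       file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (nm in names(res$grids)) {
    g <- res$grids[[nm]]
    .writeGridTsv(gridMatrix(g), file.path(outDir, paste0("grid_", nm, "_freq.tsv")))
    .writeGridTsv(pValues(g), file.path(outDir, paste0("grid_", nm, "_p.tsv")))
    .writeGridTsv(qValues(g), file.path(outDir, paste0("grid_", nm, "_q.tsv")))
  }
  if (!is.null(res$baseComposition)) {
    bc <- res$baseComposition
    .writeTsv(data.frame(base = rownames(bc@observed), bc@observed,
                         check.names = FALSE),
              file.path(outDir, "base_composition_observed.tsv"))
    .writeTsv(data.frame(base = rownames(bc@background), bc@background,
                         check.names = FALSE),
              file.path(outDir, "base_composition_background.tsv"))
  }
  jsonlite::write_json(unclass(res$config), file.path(outDir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(outDir)
}

#' Run the deletion microhomology-footprint analysis
#'
#' Cascade: caller-PASS filter, 8-200 bp size filter, same-repeat-class
#' break-site filter, optional trio de novo filter (drop deletions
#' overlapping either parent), optional gamete-of-origin stratification.
#' Each junction's homology length (longest common prefix of the deleted and
#' following sequence, after left alignment) is categorized under the chosen
#' scheme and the microhomology category is tested for over-representation
#' with a one-sided binomial test; microhomologous junctions feed a 16x16
#' match grid with a permutation null.
#'
#' @param genome FASTA path or `DNAStringSet`.
#' @param child VCF path or call list; deletions are used.
#' @param father,mother Optional parental VCFs / call lists for the trio
#'   de novo filter.
#' @param repeats BED path / `GRanges` / NULL.
#' @param origins Optional gamete-of-origin labels (data.frame recordId,
#'   origin) triggering stratified results.
#' @param config A [runConfig()] (fields `scheme`, `deletionSize`,
#'   `nPermGrid`, `seed`).
#' @param outDir Optional output directory.
#' @return List with `junctions` (per-junction data.frame), `result`
#'   ([FootprintResult-class], or per-stratum list), `grid`
#'   ([HomologyGrid-class] of microhomologous junctions, NULL when none) and
#'   `config`. With zero deletions after filtering an n=0 result is
#'   returned with a warning.
#' @export
runDeletionFootprint <- function(genome, child, father = NULL, mother = NULL,
                                 repeats = NULL, origins = NULL,
                                 config = runConfig(), outDir = NULL) {
  if (missing(genome) || missing(child))
    stop("config error: genome and child call set are required")
  genome <- .loadGenome(genome)
  childCalls <- .loadCalls(child)
  dels <- childCalls$indels
  dels <- dels[S4Vectors::mcols(dels)$kind == "deletion"]
  dels <- filterPassOnly(dels)
  dels <- sizeFilter(dels, config$deletionSize[1], config$deletionSize[2])
  if (!is.null(repeats)) dels <- filterRepeatsDeletions(dels, .loadRepeats(repeats))
  loadDels <- function(x) {
    if (is.null(x)) return(NULL)
    g <- .loadCalls(x)$indels
    filterPassOnly(g[S4Vectors::mcols(g)$kind == "deletion"])
  }
  fa <- loadDels(father); mo <- loadDels(mother)
  if (!is.null(fa) || !is.null(mo)) {
    parents <- Filter(Negate(is.null), list(fa, mo))
    dels <- filterAgainstParents(dels, parents)
  }

  analyse <- function(d) {
    if (length(d) == 0) {
      warning("no deletions after filtering; reporting n = 0")
      return(list(junctions = data.frame(), result = footprintTest(
        c(non = 0, micro = 0, macro = 0), config$scheme), grid = NULL))
    }
    jx <- deletionHomologyLength(d, genome)
    jx$category <- categorizeHomology(jx$homologyLen, config$scheme)
    res <- footprintTest(jx$category, config$scheme)
    grid <- NULL
    micro <- which(!is.na(jx$category) & jx$category == "micro")
    if (length(micro) >= 2) {
      fl <- deletionFlanks(d[micro], genome, w = 8L)
      grid <- testGrid(fl, genome, nPerm = config$nPermGrid, seed = config$seed)
    }
    list(junctions = jx, result = res, grid = grid)
  }

  if (!is.null(origins)) {
    strata <- stratifyByOrigin(dels, origins)
    res <- lapply(strata, analyse)
    out <- list(junctions = lapply(res, `[[`, "junctions"),
                result = lapply(res, `[[`, "result"),
                grid = lapply(res, `[[`, "grid"),
                stratified = TRUE, config = config)
  } else {
    r <- analyse(dels)
    out <- c(r, list(stratified = FALSE, config = config))
  }
  if (!is.null(outDir)) .writeDeletionBundle(out, outDir)
  out
}

.fpAsList <- function(r) list(scheme = r@scheme, n = r@n,
                              counts = as.list(r@counts),
                              nullProbs = as.list(r@nullProbs),
                              binomP = r@binomP)

.writeDeletionBundle <- function(res, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  if (res$stratified) {
    for (s in names(res$result)) {
      if (nrow(res$junctions[[s]]))
        .writeTsv(res$junctions[[s]], file.path(outDir, paste0("junctions_", s, ".tsv")))
      if (!is.null(res$grid[[s]]))
        .writeGridTsv(qValues(res$grid[[s]]),
                      file.path(outDir, paste0("grid16_q_", s, ".tsv")))
    }
    jsonlite::write_json(lapply(res$result, .fpAsList),
                         file.path(outDir, "footprint.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    if (nrow(res$junctions))
      .writeTsv(res$junctions, file.path(outDir, "junctions.tsv"))
    if (!is.null(res$grid)) {
      .writeGridTsv(gridMatrix(res$grid), file.path(outDir, "grid16_freq.tsv"))
      .writeGridTsv(qValues(res$grid), file.path(outDir, "grid16_q.tsv"))
    }
    jsonlite::write_json(.fpAsList(res$result),
                         file.path(outDir, "footprint.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  jsonlite::write_json(unclass(res$config), file.path(outDir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(outDir)
}
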