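#' Read a genome FASTA into a DNAStringSet
#'
#' Lowercase bases are normalised to uppercase; any character outside
#' A/C/G/T/N is rejected. Contig names are taken up to the first whitespace of
#' the FASTA header and must be unique and non-empty. Gzip-compressed files
#' are accepted.
#'
#' @param path Path to a FASTA (optionally `.gz`) file.
#' @return Named `DNAStringSet`; `sum(width(x))` is the genome length.
#' @export
readGenome <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  gen <- withCallingHandlers(
    tryCatch(Biostrings::readDNAStringSet(path),
             error = function(e) stop("malformed FASTA '", path, "': ",
                                      conditionMessage(e))),
    warning = function(w) {
      # the reader silently drops codes outside its alphabet; reject instead
      if (grepl("invalid one-letter sequence codes", conditionMessage(w)))
        stop("FASTA '", path, "' contains characters outside {A,C,G,T,N}")
      invokeRestart("muffleWarning")
    })
  if (length(gen) == 0) stop("FASTA '", path, "' contains no records")
  names(gen) <- sub("\\s.*$", "", names(gen))
  if (any(names(gen) == "")) stop("FASTA '", path, "' has an empty header name")
  if (anyDuplicated(names(gen)))
    stop("FASTA '", path, "' has duplicated contig names")
  if (any(Biostrings::width(gen) == 0))
    stop("FASTA '", path, "' contains an empty sequence for contig '",
         names(gen)[Biostrings::width(gen) == 0][1], "'")
  chars <- as.character(gen)
  chars <- toupper(chars)
  .checkAlphabet(chars, paste0("FASTA '", path, "'"))
  out <- Biostrings::DNAStringSet(chars)
  names(out) <- names(gen)
  out
}

#' Write a genome to FASTA
#'
#' @param genome Named `DNAStringSet` (or named character vector).
#' @param path Output path; `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
writeGenome <- function(genome, path) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  if (is.null(names(genome)) || any(names(genome) == ""))
    stop("genome contigs must be named")
  Biostrings::writeXStringSet(genome, path,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read a repeat-class track from BED4
#'
#' Expects 0-based half-open BED with the repeat class in column 4. The
#' result is returned 1-based as a `GRanges` with a `repeatClass` metadata
#' column, sorted within contig. Gzip input is accepted.
#'
#' @param path Path to a BED4 (optionally `.gz`) file.
#' @return `GRanges` with `repeatClass`.
#' @export
readRepeats <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  lines <- readLines(con)
  close(con)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0)
    return(GenomicRanges::GRanges(repeatClass = character(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(parts)
  if (any(ncols < 4))
    stop("BED '", path, "': repeat class required in column 4 (line ",
         which(ncols < 4)[1], ")")
  contig <- vapply(parts, `[`, character(1), 1L)
  start0 <- suppressWarnings(as.integer(vapply(parts, `[`, character(1), 2L)))
  end0 <- suppressWarnings(as.integer(vapply(parts, `[`, character(1), 3L)))
  cls <- vapply(parts, `[`, character(1), 4L)
  if (anyNA(start0) || anyNA(end0))
    stop("BED '", path, "': non-numeric coordinates")
  if (any(end0 <= start0))
    stop("BED '", path, "': end <= start at line ", which(end0 <= start0)[1])
  if (any(!nzchar(cls)))
    stop("BED '", path, "': empty repeat class at line ", which(!nzchar(cls))[1])
  gr <- GenomicRanges::GRanges(contig,
                               IRanges::IRanges(start = start0 + 1L, end = end0),
                               repeatClass = cls)
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

#' Write a repeat-class track as BED4
#'
#' @param repeats `GRanges` with a `repeatClass` metadata column (1-based).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeRepeats <- function(repeats, path) {
  df <- data.frame(contig = as.character(GenomicRanges::seqnames(repeats)),
                   start0 = GenomicRanges::start(repeats) - 1L,
                   end0 = GenomicRanges::end(repeats),
                   class = S4Vectors::mcols(repeats)$repeatClass)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
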