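# Breakend ALT grammar (VCF 4.1+). The four shapes encode which strands and
# directions are fused:
#   type 1  t[p[  : segment ending here  + segment starting at p (sense)
#   type 2  t]p]  : segment ending here  + revcomp of segment ending at p
#   type 3  ]p]t  : segment ending at p  + segment starting here (= type 1
#                   annotated from the other partner)
#   type 4  [p[t  : revcomp of segment starting at p + segment starting here
.BND_RE <- c(
  `1` = "^([ACGTN]+)\\[([^\\[\\]:]+):([0-9]+)\\[$",
  `2` = "^([ACGTN]+)\\]([^\\[\\]:]+):([0-9]+)\\]$",
  `3` = "^\\]([^\\[\\]:]+):([0-9]+)\\]([ACGTN]+)$",
  `4` = "^\\[([^\\[\\]:]+):([0-9]+)\\[([ACGTN]+)$")

#' Classify a breakend ALT string into its shape type
#'
#' Returns 1 for `t[p[`, 2 for `t]p]`, 3 for `]p]t` and 4 for `[p[t`.
#' Type 3 annotates the same fusion as type 1 seen from the other partner;
#' [canonicalizeFusions()] merges it into type 1.
#'
#' @param alt Character vector of breakend ALT strings.
#' @return Integer vector of types in 1..4.
#' @export
classifyBreakend <- function(alt) {
  out <- rep(NA_integer_, length(alt))
  for (k in 1:4) out[is.na(out) & grepl(.BND_RE[[k]], alt, perl = TRUE)] <- k
  if (anyNA(out))
    stop("not a breakend ALT: ", paste(alt[is.na(out)], collapse = ", "))
  out
}

# Parse breakend ALT strings -> data.frame(btype, mateContig, matePos,
# insertSeq). Unparseable entries get btype NA (caller decides what to do).
.parseBreakendAlt <- function(alt) {
  n <- length(alt)
  out <- data.frame(btype = rep(NA_integer_, n),
                    mateContig = NA_character_, matePos = NA_integer_,
                    insertSeq = NA_character_)
  for (k in 1:4) {
    idx <- which(is.na(out$btype) & grepl(.BND_RE[[k]], alt, perl = TRUE))
    if (!length(idx)) next
    m <- regmatches(alt[idx], regexec(.BND_RE[[k]], alt[idx], perl = TRUE))
    m <- do.call(rbind, m)
    if (k <= 2) {
      t <- m[, 2]; out$mateContig[idx] <- m[, 3]; out$matePos[idx] <- as.integer(m[, 4])
      out$insertSeq[idx] <- substring(t, 2L)        # REF padding base leads
    } else {
      t <- m[, 4]; out$mateContig[idx] <- m[, 2]; out$matePos[idx] <- as.integer(m[, 3])
      out$insertSeq[idx] <- substr(t, 1L, nchar(t) - 1L)  # REF padding base trails
    }
    out$btype[idx] <- k
  }
  out
}

.emptyBreakends <- function() {
  data.frame(recordId = character(0), contig = character(0), pos = integer(0),
             refBase = character(0), alt = character(0), btype = integer(0),
             mateId = character(0), mateContig = character(0),
             matePos = integer(0), ciLo = integer(0), ciHi = integer(0),
             insertSeq = character(0), filterPass = logical(0),
             sampleId = character(0))
}

.emptyIndels <- function() {
  gr <- GenomicRanges::GRanges()
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    kind = character(0), svlen = integer(0), filterPass = logical(0),
    sampleId = character(0), recordId = character(0))
  gr
}

#' Read structural variants from a VCF
#'
#' Splits records into breakends (BND bracket notation) and interval SVs
#' (deletions, insertions, tandem duplications; both symbolic `<DEL>`-style
#' records with `END` and explicit REF/ALT deletions are accepted and
#' normalised). `filterPass` is `TRUE` only for `FILTER == "PASS"`; missing
#' (`.`) filters are conservatively treated as non-PASS. `CIPOS` is parsed
#' when present, else `[0, 0]`. Breakend ALTs that match none of the four
#' bracket shapes are skipped and reported in the `skipped` element.
#'
#' @param path Path to a VCF (`.vcf`, `.vcf.gz`, `.vcf.bgz`).
#' @param sampleId Sample label attached to every record; defaults to the
#'   VCF's single sample name if present, else the file base name.
#' @return List with `breakends` (data.frame), `indels` (`GRanges` whose
#'   range covers the affected bases, with `kind`, `svlen`, `filterPass`,
#'   `sampleId`, `recordId`), and `skipped` (data.frame of record id/reason).
#' @export
readSvVcf <- function(path, sampleId = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.b?gz$", path)) {
    # decompress (plain gzip or bgzf) to a scratch copy for robust parsing
    tmp <- tempfile(fileext = ".vcf")
    on.exit(unlink(tmp), add = TRUE)
    con <- gzfile(path, "rt"); writeLines(readLines(con), tmp); close(con)
    path <- tmp
  }
  vcf <- suppressWarnings(VariantAnnotation::readVcf(path))
  if (is.null(sampleId)) {
    smp <- colnames(vcf)
    sampleId <- if (length(smp) == 1) smp else
      sub("\\.vcf(\\.b?gz)?$", "", basename(path))
  }
  n <- nrow(vcf)
  if (n == 0)
    return(list(breakends = .emptyBreakends(), indels = .emptyIndels(),
                skipped = data.frame(recordId = character(0), reason = character(0))))

  rr <- SummarizedExperiment::rowRanges(vcf)
  ids <- names(rr)
  if (is.null(ids)) ids <- paste0("rec", seq_len(n))
  ids[ids == "." | ids == ""] <- paste0("rec", which(ids == "." | ids == ""))
  contig <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  ref <- as.character(VariantAnnotation::ref(vcf))
  altL <- VariantAnnotation::alt(vcf)
  alt <- vapply(as.list(altL), function(a) as.character(a)[1], character(1))
  filt <- VariantAnnotation::filt(vcf)
  pass <- !is.na(filt) & filt == "PASS"

  inf <- VariantAnnotation::info(vcf)
  svtype <- if ("SVTYPE" %in% names(inf)) as.character(inf$SVTYPE) else
    rep(NA_character_, n)
  endInfo <- if ("END" %in% names(inf)) suppressWarnings(as.integer(inf$END)) else
    rep(NA_integer_, n)
  mateId <- if ("MATEID" %in% names(inf))
    vapply(as.list(inf$MATEID), function(x) if (length(x)) x[1] else NA_character_,
           character(1))
  else rep(NA_character_, n)
  cip <- if ("CIPOS" %in% names(inf)) as.list(inf$CIPOS) else
    rep(list(integer(0)), n)
  ciLo <- vapply(cip, function(x) if (length(x) >= 1 && !is.na(x[1])) x[1] else 0L,
                 integer(1))
  ciHi <- vapply(cip, function(x) if (length(x) >= 2 && !is.na(x[2])) x[2] else 0L,
                 integer(1))

  isBnd <- grepl("[][]", alt) | (!is.na(svtype) & svtype == "BND")
  skipped <- data.frame(recordId = character(0), reason = character(0))

  # --- breakends ---------------------------------------------------------
  bnd <- .emptyBreakends()
  if (any(isBnd)) {
    bi <- which(isBnd)
    parsed <- .parseBreakendAlt(alt[bi])
    bad <- is.na(parsed$btype)
    if (any(bad)) {
      skipped <- rbind(skipped, data.frame(
        recordId = ids[bi][bad],
        reason = paste0("unrecognised breakend ALT '", alt[bi][bad], "'")))
      warning(sum(bad), " breakend record(s) with unrecognised ALT skipped")
    }
    keep <- !bad
    bnd <- data.frame(recordId = ids[bi][keep], contig = contig[bi][keep],
                      pos = pos[bi][keep], refBase = ref[bi][keep],
                      alt = alt[bi][keep], btype = parsed$btype[keep],
                      mateId = mateId[bi][keep],
                      mateContig = parsed$mateContig[keep],
                      matePos = parsed$matePos[keep],
                      ciLo = ciLo[bi][keep], ciHi = ciHi[bi][keep],
                      insertSeq = parsed$insertSeq[keep],
                      filterPass = pass[bi][keep], sampleId = sampleId)
  }

  # --- interval SVs ------------------------------------------------------
  kind <- rep(NA_character_, n)
  start1 <- rep(NA_integer_, n)
  end1 <- rep(NA_integer_, n)
  svlen <- rep(NA_integer_, n)
  ii <- which(!isBnd)
  for (i in ii) {
    a <- alt[i]
    r <- ref[i]
    if (is.na(a)) { skipped <- rbind(skipped, data.frame(recordId = ids[i], reason = "missing ALT")); next }
    if (grepl("^<DEL", a) || (!is.na(svtype[i]) && svtype[i] == "DEL" && grepl("^<", a))) {
      if (is.na(endInfo[i])) { skipped <- rbind(skipped, data.frame(recordId = ids[i], reason = "symbolic DEL without END")); next }
      kind[i] <- "deletion"; start1[i] <- pos[i] + 1L; end1[i] <- endInfo[i]
      svlen[i] <- end1[i] - start1[i] + 1L
    } else if (grepl("^<DUP", a)) {
      if (is.na(endInfo[i])) { skipped <- rbind(skipped, data.frame(recordId = ids[i], reason = "symbolic DUP without END")); next }
      kind[i] <- "tandem_duplication"; start1[i] <- pos[i] + 1L; end1[i] <- endInfo[i]
      svlen[i] <- end1[i] - start1[i] + 1L
    } else if (grepl("^<INS", a)) {
      kind[i] <- "insertion"; start1[i] <- pos[i]; end1[i] <- pos[i]
      svlen[i] <- NA_integer_
    } else if (grepl("^[ACGTN]+$", a) && grepl("^[ACGTN]+$", r)) {
      if (nchar(r) > nchar(a) && substr(r, 1, nchar(a)) == a && nchar(a) == 1) {
        kind[i] <- "deletion"; start1[i] <- pos[i] + 1L
        end1[i] <- pos[i] + nchar(r) - 1L; svlen[i] <- nchar(r) - 1L
      } else if (nchar(a) > nchar(r) && nchar(r) == 1 && substr(a, 1, 1) == r) {
        kind[i] <- "insertion"; start1[i] <- pos[i]; end1[i] <- pos[i]
        svlen[i] <- nchar(a) - 1L
      } else {
        skipped <- rbind(skipped, data.frame(recordId = ids[i], reason = "unsupported REF/ALT shape"))
      }
    } else {
      skipped <- rbind(skipped, data.frame(recordId = ids[i], reason = paste0("unsupported ALT '", a, "'")))
    }
  }
  keep <- which(!is.na(kind))
  indels <- if (length(keep)) {
    gr <- GenomicRanges::GRanges(contig[keep],
                                 IRanges::IRanges(start1[keep], end1[keep]))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      kind = kind[keep], svlen = svlen[keep], filterPass = pass[keep],
      sampleId = sampleId, recordId = ids[keep])
    gr
  } else .emptyIndels()

  list(breakends = bnd, indels = indels, skipped = skipped)
}

#' Write structural variants to a VCF
#'
#' Emits a VCF 4.2 file with the contig, INFO and FILTER header lines needed
#' so that [readSvVcf()] round-trips every consumed field. Breakend ALT
#' strings are written verbatim; interval SVs are written as symbolic
#' `<DEL>`/`<INS>`/`<DUP:TANDEM>` records with `END`/`SVLEN`.
#'
#' @param breakends data.frame in the layout returned by [readSvVcf()] (may
#'   be empty or NULL).
#' @param indels `GRanges` in the layout returned by [readSvVcf()] (may be
#'   NULL).
#' @param contigLengths Named integer vector of contig lengths, or a
#'   `DNAStringSet` genome.
#' @param path Output path.
#' @param genome Optional `DNAStringSet` used to fill anchor REF bases for
#'   interval SVs (else `N`).
#' @return `path`, invisibly.
#' @export
writeSvVcf <- function(breakends, indels, contigLengths, path, genome = NULL) {
  if (methods::is(contigLengths, "DNAStringSet")) {
    genome <- contigLengths
    contigLengths <- stats::setNames(Biostrings::width(genome), names(genome))
  }
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##contig=<ID=", names(contigLengths),
                  ",length=", as.integer(contigLengths), ">"),
           "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
           "##INFO=<ID=MATEID,Number=.,Type=String,Description=\"ID of mate breakend\">",
           "##INFO=<ID=CIPOS,Number=2,Type=Integer,Description=\"Confidence interval around POS\">",
           "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position\">",
           "##INFO=<ID=SVLEN,Number=.,Type=Integer,Description=\"SV length\">",
           "##FILTER=<ID=LowQual,Description=\"Did not pass caller quality filters\">",
           "##ALT=<ID=DEL,Description=\"Deletion\">",
           "##ALT=<ID=INS,Description=\"Insertion\">",
           "##ALT=<ID=DUP:TANDEM,Description=\"Tandem duplication\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO"),
                 collapse = "\t"))
  rows <- character(0)
  anchorBase <- function(ct, p) {
    if (!is.null(genome) && p >= 1 && p <= length(genome[[ct]]))
      as.character(Biostrings::subseq(genome[[ct]], p, p)) else "N"
  }
  if (!is.null(breakends) && nrow(breakends)) {
    if (!all(breakends$contig %in% names(contigLengths)))
      stop("breakend contig absent from header info")
    inf <- paste0("SVTYPE=BND",
                  ifelse(is.na(breakends$mateId), "",
                         paste0(";MATEID=", breakends$mateId)),
                  ";CIPOS=", breakends$ciLo, ",", breakends$ciHi)
    rows <- c(rows, paste(breakends$contig, breakends$pos, breakends$recordId,
                          breakends$refBase, breakends$alt, ".",
                          ifelse(breakends$filterPass, "PASS", "LowQual"),
                          inf, sep = "\t"))
  }
  if (!is.null(indels) && length(indels)) {
    ct <- as.character(GenomicRanges::seqnames(indels))
    if (!all(ct %in% names(contigLengths)))
      stop("indel contig absent from header info")
    m <- S4Vectors::mcols(indels)
    st <- GenomicRanges::start(indels)
    en <- GenomicRanges::end(indels)
    kind <- m$kind
    posv <- ifelse(kind == "insertion", st, st - 1L)
    altv <- c(deletion = "<DEL>", insertion = "<INS>",
              tandem_duplication = "<DUP:TANDEM>")[kind]
    svt <- c(deletion = "DEL", insertion = "INS",
             tandem_duplication = "DUP")[kind]
    refv <- mapply(anchorBase, ct, posv)
    inf <- paste0("SVTYPE=", svt, ";END=", en,
                  ifelse(is.na(m$svlen), "",
                         paste0(";SVLEN=", ifelse(kind == "deletion", -1L, 1L) * m$svlen)))
    rows <- c(rows, paste(ct, posv, m$recordId, refv, altv, ".",
                          ifelse(m$filterPass, "PASS", "LowQual"),
                          inf, sep = "\t"))
  }
  # sort body by contig order then position
  if (length(rows)) {
    f <- strsplit(rows, "\t", fixed = TRUE)
    ctv <- vapply(f, `[`, character(1), 1L)
    pv <- as.integer(vapply(f, `[`, character(1), 2L))
    rows <- rows[order(match(ctv, names(contigLengths)), pv)]
  }
  writeLines(c(hdr, rows), path)
  invisible(path)
}
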