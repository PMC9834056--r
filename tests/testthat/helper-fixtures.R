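# In-code fixtures shared across the suite.

randomSeq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

toyGenome <- function(...) {
  Biostrings::DNAStringSet(c(...))
}

writeTempVcf <- function(lines) {
  path <- tempfile(fileext = ".vcf")
  writeLines(lines, path)
  path
}

# minimal single-record-set VCF around hand-written body rows
vcfWithBody <- function(body) {
  writeTempVcf(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=100000>",
    "##contig=<ID=chr2,length=100000>",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=MATEID,Number=.,Type=String,Description=\"Mate\">",
    "##INFO=<ID=CIPOS,Number=2,Type=Integer,Description=\"CI\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End\">",
    "##FILTER=<ID=MinQUAL,Description=\"low\">",
    "##ALT=<ID=DEL,Description=\"Deletion\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO"),
          collapse = "\t"),
    body))
}

# deletion GRanges in the readSvVcf indel layout
makeDels <- function(contig, start, end, sampleId = "S", pass = TRUE,
                     ids = NULL) {
  gr <- GenomicRanges::GRanges(rep_len(contig, length(start)),
                               IRanges::IRanges(start, end))
  if (is.null(ids)) ids <- paste0("d", seq_along(gr), recycle0 = TRUE)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    kind = rep_len("deletion", length(gr)), svlen = end - start + 1L,
    filterPass = rep_len(pass, length(gr)),
    sampleId = rep_len(sampleId, length(gr)), recordId = ids)
  gr
}

# hand-built breakend table row (layout of readSvVcf()$breakends)
bndRow <- function(recordId, contig, pos, alt, mateId = NA, ci = 0L,
                   pass = TRUE, sampleId = "S", refBase = "A") {
  p <- regmatches(alt, regexec("([^\\[\\]:]+):([0-9]+)", alt, perl = TRUE))[[1]]
  data.frame(recordId = recordId, contig = contig, pos = as.integer(pos),
             refBase = refBase, alt = alt,
             btype = classifyBreakend(alt), mateId = mateId,
             mateContig = p[2], matePos = as.integer(p[3]),
             ciLo = -abs(ci), ciHi = abs(ci),
             insertSeq = svfootprints:::.parseBreakendAlt(alt)$insertSeq,
             filterPass = pass, sampleId = sampleId)
}

# mate pair of breakend rows for a type-1 fusion chrA:posA -> chrB:posB
bndPairType1 <- function(id, contigA, posA, contigB, posB, ci = 0L,
                         sampleId = "S") {
  rbind(
    bndRow(paste0(id, "_a"), contigA, posA,
           paste0("A[", contigB, ":", posB, "["),
           mateId = paste0(id, "_b"), ci = ci, sampleId = sampleId),
    bndRow(paste0(id, "_b"), contigB, posB,
           paste0("]", contigA, ":", posA, "]A"),
           mateId = paste0(id, "_a"), ci = ci, sampleId = sampleId))
}
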