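Package: svfootprints
Title: Junction Signatures of Microhomology-Mediated Repair in Structural Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects the sequence footprints that error-prone double-strand-break
    repair (polymerase theta-mediated end joining in particular) leaves at
    structural-variant junctions. Reads genomes (FASTA), SV calls (VCF breakend
    and DEL/INS/DUP records) and repeat tracks (BED); filters offspring calls
    down to de novo, non-repeat, deduplicated events; classifies translocation
    breakend types and extracts correctly oriented junction flanks; detects
    templated insertions by exhaustive four-orientation search within +/-25 bp
    of the break sites; computes junction base-match grids with permutation
    nulls and Benjamini-Hochberg adjustment, junction microhomology lengths and
    base composition against resampled genomic backgrounds; and tests deletion
    microhomology footprints with binomial nulls under the C. elegans (1 bp)
    and human (2-6 bp) conventions, including trio de novo filtering and
    gamete-of-origin stratification. A synthetic-data generator with exact
    truth tables lets every stage run at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    SummarizedExperiment,
    VariantAnnotation,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
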