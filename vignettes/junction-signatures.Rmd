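---
title: "Detecting end-joining footprints at structural-variant junctions"
author: "svfootprints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting end-joining footprints at structural-variant junctions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(0)
```

## The scientific problem

When a DNA double-strand break is repaired by an error-prone end-joining
pathway — polymerase theta-mediated end joining (TMEJ) in particular — the
resulting junction carries characteristic sequence scars: short stretches of
*microhomology* shared by the two joined ends, and short *templated
insertions* copied from DNA within a few dozen base pairs of a breakpoint.
Given a genome, a set of structural-variant (SV) calls in VCF breakend
notation, and (optionally) parental call sets and a repeat annotation, this
package quantifies those scars: it reduces offspring calls to de novo
events, classifies each fusion's breakend type, orients and extracts the
junction flanks, and tests microhomology and insertion signals against
explicit null models.

```{r}
library(svfootprints)
```

## Breakend grammar and canonical fusions

A translocation (any inter- or intra-chromosomal fusion) is annotated twice
in a VCF, once from each partner, with one of four bracketed ALT shapes:
`t[p[` (type 1), `t]p]` (type 2), `]p]t` (type 3) and `[p[t` (type 4). The
shapes encode which strand and direction of each partner enter the fused
product. Types 1 and 3 describe the same physical fusion read from opposite
ends, so after mate pairing the package re-expresses type 3 as type 1 and
orders the two break sites lexicographically; `canonicalizeFusions()` is
therefore invariant to the order in which mate records appear in the file.

Each break site is stored with two orientation attributes: whether the
retained segment *ends at* (`L`) or *starts at* (`R`) the annotated
position, and whether it enters the product reverse-complemented. These two
attributes drive everything downstream — flank extraction, the simulator's
genome editing, and the permutation null all share the same mapping from
signed flank labels to genome positions, so they cannot drift apart.

## Junction flanks and signed labels

For each fusion, `extractFlanks()` returns two `2w`-base windows (default
`w = 4`). The junction-adjacent retained base is labelled 0, further
retained bases +1..+(w−1), and the `w` bases beyond the break (absent from
the fusion product) −1..−w. Flank orientation follows the breakend type:
both flanks of a type 1 fusion are sense-strand 5'→3'; the right flank of a
type 2 and the left flank of a type 4 fusion are reverse complements. One
residual ambiguity is purely presentational: mirroring the label direction
would relabel the grid axes without changing any statistic, so the package
fixes the convention above and uses it consistently.

## The match grid and its permutation null

`junctionMatchGrid()` compares every left-flank base with every right-flank
base (`N` matches nothing), and `observedGrid()` averages the binary grids
over junctions, giving a `2w × 2w` match-frequency matrix. A junction
microhomology of length *m* appears as *m* junction-spanning bins — (0, −1),
(+1, −2), … — with elevated frequency, because the retained end of one flank
re-occurs just beyond the break of the other.

Significance is assessed per bin by permutation (`permutationNullGrid()`):
each permutation places the same number of junctions, with the same type
mix and hence the same orientation rules, uniformly at random on the genome
(contigs weighted by length, positions at least `w` from contig ends, draws
overlapping `N` runs rejected and redrawn). The one-sided upper-tail
p-value is `(r + 1)/(nPerm + 1)`, never exactly zero; this finite-sample
estimator is standard and keeps the q-values honest at any permutation
count. The 64 (or 256) bins are then adjusted with Benjamini–Hochberg
step-up FDR control (`bhAdjust()`, delegating to `stats::p.adjust`).

Two permutation-design choices were genuinely open and are fixed as
follows. First, the two break sites of each permuted fusion are placed
independently (the observed inter-/intra-chromosomal pairing is not
preserved): the grid statistics depend only on local sequence context, and
independent placement is the plain reading of "randomly distributed on the
genome". Second, permutations preserve the *type mix* of the observed set
so that orientation-dependent composition biases (e.g. GC asymmetry between
strands) are represented in the null.

## Microhomology length and base composition

`microhomologyLength()` scans junction-spanning matches base-by-base moving
away from the junction, in both directions (left retained vs right excluded,
and vice versa), and reports the longer run; 0 means the first comparison
failed both ways. The run is capped at `w` by construction. Junctions with
microhomology length exactly 1 feed `baseComposition()`: per signed
position, the percentage of A, C, G and T across the pooled oriented
flanks, against the mean of `nPerm` draws of equally many random genomic
windows. Flanks containing `N` are dropped and counted. The pooling of both
flanks (two windows per junction) is a documented choice; the background is
sampled per *window* so the two sides of the comparison have equal weight.

## Templated insertions

An insertion at a junction is *templated* if it is at least 3 bp long and
occurs exactly — in normal, reversed, complemented or reverse-complemented
form — within ±25 bp of either break site. The four literal string
transforms are searched even though "reverse" and "complement" alone are
not biological strands, because the defining procedure enumerates all four;
the search is exact (no mismatches) and exhaustive over start offsets, and
all hits are recorded. Insertions shorter than 3 bp, or without a template
hit, are *miscellaneous*.

## De novo filtering

The filtering cascade runs in a fixed order: caller PASS filter → mate
pairing → parental overlap → repeat filter → duplicate collapse. Order is
observable only through the `FilterReport`, which conserves counts at every
stage. Decisions worth noting:

* a missing FILTER (`.`) is treated as non-PASS — conservative, since only
  calls that passed all caller filters should enter the analysis;
* an offspring interval SV is inherited if it shares ≥1 bp with *any*
  parental SV interval; breakend fusions are compared breakend-to-breakend,
  with a site matching when the positional offset is within the larger
  absolute confidence-interval bound of the two records, in either partner
  order;
* fusions are repeat-filtered only when both break sites overlap the *same*
  repeat class, indels when their interval touches any repeat;
* duplicate fusion annotations are grouped transitively under the CI-match
  relation and the lexicographically smallest representative survives.

## Deletion footprints

Deletions of 8–200 bp (inclusive bounds) are analysed junction-wise. After
left-alignment, the homology length is the longest common prefix of the
deleted sequence and the retained sequence that follows it. This
single-direction convention matches the chance model in which one base
comparison is non-matching with probability 3/4 (`chanceNonHomologyPct()`
returns 75); a two-sided breakpoint-ambiguity alternative is available via
`deletionHomologyLength(..., twoSided = TRUE)`. Two category schemes are
supported: `celegans_1bp` (0 / exactly 1 / ≥2 matching bases) and
`human_2to6bp` (0–1 / 2–6 / ≥7). The chance probabilities used as binomial
nulls (75% / 16.66% / 8.33%, and 91.66% / 8.325% / 1⁄12288) are
configuration constants taken as printed in the source analyses rather than
re-derived: they do not follow from a simple geometric match model (which
would give 75 / 18.75 / 6.25), and re-deriving them would silently change
every downstream p-value. The over-representation test is one-sided
(greater) on the microhomology count. Trio de novo filtering removes child
deletions overlapping either parent; gamete-of-origin labels split the set
into father/mother strata analysed independently. Microhomologous junctions
feed a 16×16 grid (`w = 8`) through exactly the same grid/permutation code
path as translocations.

## What the simulator emulates — and what it does not

`simulateStudy()` generates an i.i.d. random genome (uniform base
frequencies by default), translocations of the three canonical types with
*planted, exact* junction microhomology, miscellaneous and templated
insertions with the observed category mix (77% none, 17% miscellaneous, 6%
templated by default), deletions with planted homology lengths, inherited
background events shared between a parent and the offspring, and a repeat
track. Homology is planted by editing the genome before the FASTA is
finalized — copying retained bases of one flank into the excluded bases of
the other, forcing a mismatch at the next position, and breaking the
opposite direction at its first comparison — so the truth table is exact
rather than approximate, at any homology length, without rejection
sampling. Event windows are reserved and kept disjoint so edits never
interact. Setting `mhDist = NULL` skips planting entirely, leaving junction
context random: that is the correct null for calibration studies (a planted
length of 0 is *exactly zero*, which depresses the junction bins below
chance and is not a null).

The simulator does **not** emulate read-level noise, caller breakpoint
imprecision beyond a configurable CIPOS, mappability structure, non-uniform
base composition along chromosomes, or clustered/recurrent breakpoints.
Passing tests therefore demonstrate the correctness of the measurement
machinery under known truth, not the behaviour of any particular SV caller
on real data.

A single integer seed drives everything; each component derives its own
sub-stream deterministically, so outputs are byte-identical per seed and
partial re-runs reproduce.

## Numerical and scale choices

Full-profile permutation counts are 100,000 (grid) and 25,000 (base
composition); the `test` profile uses 9,999 and 2,500, which keeps the
whole suite at desk scale while leaving the smallest achievable per-bin
p-value (1⁄10,000) far below the 0.05/64 Benjamini–Hochberg threshold. The
calibration studies in the test suite use a 200 kb uniform genome with 100
random junctions, and truth-recovery runs use 1,000 events over 10 seeds —
sizes at which every binomial/multinomial tolerance in the tests is a
3-standard-error bound. Degenerate inputs are handled explicitly: empty
deletion sets yield an `n = 0` report with a warning; flank windows that
run off a contig end are excluded from grid statistics with a logged count;
unpaired breakend singletons are dropped with a warning.

Coordinates are 1-based inclusive internally (the Bioconductor convention;
BED input is converted on read), and all sequence containers are
`Biostrings::DNAStringSet` / `GenomicRanges::GRanges` objects.

## Known limitations

* The permutation null assumes the genome supplied is the mappable space;
  no mappability mask beyond `N`-rejection is applied.
* Template search is exact-match only; a single sequencing error in an
  insert hides a true template.
* The microhomology-length definition is run-based from the annotated
  breakpoint; callers that place breakpoints at the other end of the
  homology tract shift which grid bins light up (the spanning-bin pattern,
  and hence the tests, are unaffected).
* Genotype semantics beyond sample identity (heterozygous vs homozygous
  calls) are not modelled; the de novo logic is purely positional.
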