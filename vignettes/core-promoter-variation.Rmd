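---
title: "Methods: core-promoter variation analysis with CorePromVar"
author: "CorePromVar authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: core-promoter variation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CorePromVar)
```

# The analysis in one paragraph

`CorePromVar` analyses sequence variation in core promoters — the windows
of ±100 bp around transcription start sites (TSSs) where the RNA
polymerase II preinitiation complex assembles — across a cohort
structured into populations and continents. Variants from a multi-sample
VCF are restricted to these windows, normalised, typed, and subjected to
a presence rule (a variant counts in a population only when at least two
of its individuals carry an alternate allele). Downstream, each variant's
presence pattern is classified into one of four sharing classes, its
position is expressed in TSS-relative coordinates, its overlap with
canonical core-promoter motifs is computed, and it is annotated against
known-variant, eQTL and GWAS catalog snapshots. Per-population summary
tables and cross-population aggregates close the chain.

# Coordinate conventions

All internal coordinates are 1-based inclusive (the VCF convention); BED
input and output convert at the boundary (0-based half-open, TSS =
`start + 1` on `+`, `= end` on `-`).

TSS-relative offsets place the TSS at 0, so a window of 100 bp upstream
and 100 bp downstream spans offsets −100..+100 — 201 positions. Published
descriptions of such windows often leave unstated whether position 0
exists; we declare this symmetric convention once and use it everywhere
(window width = `windowUp + windowDown + 1`). Offsets increase in the
direction of transcription: on the minus strand, larger genomic
coordinates are more negative offsets. Promoter identity is the triple
(chromosome, TSS, strand); TSS records of several genes or transcript
isoforms that share the triple are merged into one promoter, so a
promoter can serve several genes and a gene can own several promoters.

## Indel offsets

A substitution's affected span is the replaced bases. A deletion's span
is the deleted bases, excluding the anchor base that VCF notation
retains. An insertion changes no reference base; it is assigned the
single inter-base point one offset downstream (in transcription
direction) of its anchor, on both strands. A variant is assigned to a
promoter when its affected span intersects the window; the recorded
offset is the transcriptionally first affected in-window position. The
generator's variants are placed so spans lie wholly inside the window,
and real cohorts only meet the clipped case for indels straddling a
window edge.

# Variant processing

**Normalisation.** The common suffix, then the common prefix, of
ref/alt are trimmed, always leaving one base on each side; the position
advances by the trimmed prefix length. This keeps VCF-style anchored
indels (`CAA→CA` becomes `CA→C`) and is idempotent. The distinct-variant
key is `chrom:pos:ref:alt` after normalisation; rsIDs are annotation
only, because catalogs differ in ID coverage.

**Typing.** Type is a function of allele lengths alone: longer alt =
insertion, shorter = deletion, equal = substitution (multi-base
equal-length changes are substitutions). Consequently substitutions +
insertions + deletions = total, an invariant the tests assert.

**Carriers and presence.** Carrier counting is per individual, not per
allele: heterozygous and homozygous-alternate genotypes each contribute
one carrier. The presence rule (default: ≥ 2 carriers per population)
reflects a common guard against singleton artefacts in cohort variant
calling; raising the floor can only shrink every population's variant
set (monotonicity is tested). Upstream depth or quality filtering is a
property of the input VCF and is not re-implemented here.

**Ts/Tv.** Transitions are A↔G and C↔T. The ratio is computed over
single-base substitutions only and is `NA` when there are no
transversions. Of the 12 ordered single-base changes, 4 are transitions
and 8 transversions, so a uniform mutation model gives 0.5; promoter
sequence context typically pushes observed cohort values well above 3.

# Motif scanning

The four canonical elements are encoded as degenerate IUPAC consensus
strings: BRE `SSRCGCC`, TATA `TATAWAAR`, Inr `YYANWYY`, DPE `RGWYV`. The
scanner uses the standard IUPAC table, in which W = {A, T}. Some printed
motif tables circulate with a nonstandard "W: A/C"; because that reading
contradicts the IUPAC standard the definitions cite, the package treats
it as a transcription error but keeps it selectable
(`iupacCodes(w = "AC")`) for exact replication of analyses that used it.

Scanning is performed on the transcription (sense) strand only, over the
entire −100..+100 window with no positional restriction — canonical
position ranges (e.g. TATA near −30) are deliberately not imposed, since
the analysis asks where variation falls within motif sequence space, not
whether a motif is positionally canonical. All overlapping occurrences
are reported; ambiguous bases (`N`) in a sequence never match. Where a
variant overlaps two instances of the same motif, both the pair count
and the distinct-variant count are reported, since either tally is a
defensible summary.

The implementation compiles each consensus to a character-class regular
expression scanned under a lookahead (so overlapping hits are found);
tests verify equivalence with two independent oracles — exhaustive
consensus expansion plus naive substring search, and
`Biostrings::matchPattern(fixed = FALSE)` — on randomized sequences.

# Sharing classes and spectra

With presence sets in hand, each variant falls into exactly one class:

1. *Private to population* — present in one population;
2. *Private to continent* — several populations, all one continent;
3. *Shared across continents* — at least two but not all continents;
4. *Shared across all continents* — every continent of the manifest.

"All continents" means all continents the manifest defines, so the
classifier works for synthetic manifests of any size; collapsing the
manifest to one continent degenerates every multi-population variant to
class 2, which the tests exercise. Per-population spectra count each
variant present in a population once, under its *global* class.
Genome-wide reference proportions for the χ² comparison are an input
table — they come from published whole-genome surveys and are never
derived from the promoter data themselves. The χ² statistic is the
textbook goodness-of-fit sum with 3 degrees of freedom (via
`stats::chisq.test`); zero expected cells raise an error instructing
category pooling rather than silently producing infinities.

# Catalog joins

Novelty is keyed on normalised coordinates, with rsID as a fallback.
eQTL associations are significant iff `p < alpha` with a strict
inequality (`p = 0.05` is not significant at `alpha = 0.05`); a variant
is expression-altering when significant in at least one tissue, and its
best (minimum-p) tissue is reported. Because published eQTL resources
can be matched by position or by rsID and the better choice depends on
the snapshot, both are supported; coordinate keys take precedence when
present. GWAS records match by rsID only — variants lacking rsIDs are
skipped and counted — and each matched trait is annotated with the
continents where the variant is present, yielding a trait-by-continent
matrix that separates cosmopolitan from continent-specific trait
associations.

# Summary tables and aggregation

Per-population summary rows tabulate totals, known/novel, type counts
and Ts/Tv, with percentages always computed from the row's own total.
Two cross-population aggregation schemes are first-class because
published per-population tables mix them: *mean-of-rows* averages each
column (including row percentages), while *pooled* sums counts and
derives percentages from the sums. They agree exactly only when all
rows have equal totals, so both are always reported. Rounding is
half-up to the printed precision and applied only at presentation
(`presentationRound`), never inside computations.

The package bundles a published 25-population core-promoter variant
summary (totals, known/novel, type counts, Ts/Tv) as a worked input for
these operations. Its printed rows carry minor internal inconsistencies
(e.g. a known + novel sum off by one, an average row cell that
duplicates a neighbouring row); the aggregation functions therefore
treat the table as data and assert consistency only on rows the package
itself computes.

# The synthetic cohort generator

`simulateCohort()` emits a complete, mutually consistent input set —
reference FASTA, TSS BED6, multi-sample VCF with GT genotypes, sample
manifest, and known/eQTL/GWAS catalog snapshots — plus ground truth for
every downstream statistic. Its defaults are a desk-scale image of a
worldwide exome panel: 5 continents × 2 populations × 20 samples (400
individuals), 500 promoters with ±100 windows on a single synthetic
chromosome, and a Poisson mean of 6 variants per promoter (~3,000
variants). Defaults for the distributional knobs are anchored on
published cohort-scale values: sharing-class proportions (0.48, 0.07,
0.22, 0.23) follow a published East-Asian core-promoter spectrum; the
SNV transition probability 0.78 gives an expected Ts/Tv of 3.55, near
the published per-population mean of 3.60; the indel fraction 0.135
with insertion share 0.45 mirrors the published ~6% insertion / ~7.5%
deletion split; known-catalog coverage 0.904 and eQTL-significant
fraction 0.12 match the published pooled known rate and
expression-altering rate.

Presence patterns are drawn *class-first*: the sharing class is sampled,
then a population set realising it, then carrier counts of at least
`minCarriers` in each present population and at most `minCarriers − 1`
elsewhere (a 20% chance of a single stray carrier exercises the filter).
This construction makes sharing classes, types, novelty flags, eQTL
flags and GWAS matches *deterministic functions of the emitted files*,
so the end-to-end test demands exact recovery, while rate-like outputs
(Ts/Tv, class proportions, downstream/upstream ratio) are checked within
three binomial standard errors of their configured values. A single
seeded RNG stream in a fixed order (layout → sequences and motifs →
variants → sharing and carriers → genotypes → catalogs) makes outputs
byte-identical across runs for a given seed.

What the generator does **not** emulate — and what passing tests
therefore do not establish about real data: linkage disequilibrium and
demographic history (presence patterns are drawn independently per
variant), allele-frequency spectra beyond carrier counts, repeat and
GC/CpG sequence structure (background is uniform i.i.d. ACGT, so the
elevated Ts/Tv of real promoters must be injected via
`transitionProb`), multi-nucleotide and overlapping complex variants,
and genotype-level error or missingness beyond all-missing records.

# Numerical and design choices

- Reported Ts/Tv values are exact rational counts; `NA` (not an error)
  encodes the undefined no-transversion case.
- Common-variant rankings break carrier-count ties deterministically by
  (chrom, pos, ref, alt).
- Empty inputs yield typed empty results (empty annotation warns; empty
  motif list or catalog returns zero rows) — errors are reserved for
  contract violations such as malformed coordinates, unknown
  populations, out-of-window offsets, or reference proportions that do
  not sum to 1.
- Problem sizes in the tests (40–60 promoters in unit tests, the full
  500-promoter default in the end-to-end check, 1,000-SNV Ts/Tv
  simulations, 40–60 randomized scanner trials) were chosen so every
  statistical check has enough resolution at three standard errors
  while the whole suite stays comfortably interactive.

# Known limitations

Promoter windows are assumed disjoint per (chrom, tss, strand) key but
may genuinely overlap on opposite strands or nearby TSSs; a variant in
two windows is one distinct variant with one offset per promoter, and
promoter-centric tallies count it once per promoter. Position-aware
motif priors, PWM scoring, repeat classification, pathway enrichment
and LD-aware sharing analysis are out of scope. The four-class sharing
partition depends on the manifest's continent definitions; results are
only comparable across analyses that use the same grouping.
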