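---
title: "Modelling NUMT interference in mitochondrial heteroplasmy calling"
author: "numtshadow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling NUMT interference in mitochondrial heteroplasmy calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Mitochondrial heteroplasmy — the fraction of mtDNA molecules carrying a
variant allele — is measured by deep sequencing of enriched mtDNA. The
nuclear genome, however, carries hundreds of old, diverged copies of
mitochondrial sequence (NUMTs: on the order of 750 per human individual,
roughly 100–6,000 bp long, with a mean similarity to modern mtDNA around 86%
and a standard deviation near 4%). When sequence data are aligned to a
mitochondrial reference alone, reads that actually originate from NUMTs can
be absorbed by the mtDNA contig and masquerade as low-level heteroplasmy;
when the nuclear genome is included in the reference, those reads map back
to their true origin and the spurious variants disappear. How much this
matters depends on how the mtDNA was enriched: an amplicon longer than any
NUMT cannot co-amplify one, whereas short-amplicon panels and untargeted
whole-genome amplification (MDA) carry nuclear material straight through to
the sequencer.

`numtshadow` turns this mechanism into a controlled, fully synthetic
experiment: it builds a ground-truth world (mtDNA circle, planted
heteroplasmies, NUMT-bearing nuclear contigs), simulates four enrichment
strategies and error-bearing reads, maps every read competitively under the
two reference modes, and classifies the per-site frequency differences.
Because every read carries provenance, every downstream claim can be checked
against the generator's truth.

## The synthetic world

`makeWorld()` assembles:

* a circular random mtDNA reference (default 16,569 bp, the rCRS length;
  a real reference FASTA can be substituted via `loadMitoReference()`);
* a heteroplasmy truth table (1-based position, ref, alt, true fraction;
  frequency 1 encodes a homoplasmic variant). By default 10 heteroplasmic
  sites with log-uniform frequencies between 1% and 50% plus 20 homoplasmic
  variants are planted — the homoplasmies emulate the private variants by
  which any real sample differs from the reference;
* NUMTs: each copies a uniform-random interval of the circle (length uniform
  over 100–6,000 bp; wrapping the origin is allowed and all interval
  arithmetic is modulo L), substitutes each base independently with
  probability `1 - s`, where `s ~ Normal(0.86, 0.041)` truncated to
  `[0.70, 0.995]`, optionally reverse-complements the copy, and embeds it in
  a fresh random contig with 2,000 bp flanks. One contig per NUMT stands in
  for the nuclear genome: it preserves the mapping competition while keeping
  the world desk-sized. The registry records the realized (not the drawn)
  similarity.

The NUMT length law is uniform because only the range is reported in the
literature this model follows; the similarity parameters are treated as free
parameters with the defaults above. Substitutions only — no indels — because
the mapper is ungapped and indel calling is out of scope.

Coordinates are 1-based closed internally (the R/Bioconductor convention);
BED output is 0-based half-open and VCF/TSV output 1-based, as those formats
require.

## Enrichment models

**Amplicon PCR** (`designAmpliconPanel()`, `amplify()`). Amplicons tile the
circle evenly with a minimum neighbour overlap; the presets are a 2-amplicon
long-range design (~8.4 kb amplicons, primers 25 bp), a 9-amplicon design
(~1.9 kb) and a 180-amplicon design (~122 bp, primers 20 bp). A NUMT is
co-amplified by an amplicon only if both primer footprints (the terminal
`primerLength` bases of the amplicon interval) lie inside the NUMT's mito
projection *and* the NUMT's realized divergence within each footprint is at
most `maxPrimerMismatches` (default 2). This is the minimal model of
primer binding consistent with the observation that long amplicons protect
against co-amplification: an interval cannot contain both footprints of a
longer one. Once primers bind, PCR efficiency is equal for mito and NUMT
templates; the only inefficiency modelled is a lognormal per-template
"jackpot" factor (`pcrJackpotSd`) standing in for low-template PCR
stochasticity.

Haplotype bookkeeping: within each amplicon one molecule is emitted per
haplotype class — the background (reference plus all homoplasmic variants)
and one class per covered sub-homoplasmic site — weighted by
`C × cells × frequency`; co-occurrence of two heteroplasmies on one molecule
is not modelled (sites are treated as independent single-alt classes).
Product termini are *primer* sequence: the footprints copy the reference,
not the template, so a NUMT product carries reference bases at its ends and
a template variant inside a footprint is masked.

**MDA** (`mdaFragments()`). Fragment sources are drawn with probability
proportional to copy-number-weighted source length (the mito circle at
`C × cells` copies; each NUMT contig, flanks included, at
`copy_number × cells`); starts are uniform on the source (fragments off a
linear contig are truncated at its end, which keeps per-base coverage
exactly proportional to copy-weighted length); lengths are
`Normal(500, 150)` truncated at 100 bp. No displacement branching or
chimeras — uniform copy-weighted fragmentation is sufficient to produce the
phenomenon of interest. At a site covered by k diploid NUMT copies the NUMT
template fraction converges to `2k / (C + 2k)`; with the pooled-cells
stoichiometry (C = 100) and one diploid NUMT this is 1.96%, which is also
where the simulated reference-exclusive variants land.

**Stoichiometry presets** (`stoichPreset()`): mtDNA copies per cell are not
quantified in the study setting this package models, so the presets are
declared configuration: `pooled_cells` (C = 100, jackpot sd 0.5),
`homogenate` (C = 500, jackpot sd 0) and `csf` (C = 100, jackpot sd 0.5).
They reproduce the qualitative ordering between starting materials (lower C
means a proportionally larger NUMT signal); they do not attempt to
reproduce any particular study's per-condition rates.

## Reads, primer artefacts and trimming

`sequenceReads()` samples molecules proportionally to weight, takes a
uniform start and strand, and substitutes each base independently
(`errorRate`, default 0.002; constant Q30 qualities — calling is
count-based). Bases that originate from a primer footprint are substituted
at a higher rate, `primerErrorRate` (default 0.02). This amplicon-end
artefact rate is the package's stand-in for oligo synthesis errors and
mispriming: it gives primer-derived bases a realistic excess of spurious
mismatches, which is what makes primer trimming matter. `trimPrimers()`
uses read provenance to remove every footprint-derived base from the read
ends; trimming therefore lowers the overall called-variant count (the
footprint artefacts go away) while leaving the NUMT-driven discrepancy
classes intact, since those live in amplicon interiors.

## Dual-reference mapping

`mapReads()` is an ungapped exact-k-mer seed-and-extend mapper (k = 15 by
default, all seed hits of the read and its reverse complement, candidate
loci capped at 200 in deterministic order, scoring +1/-1). The mito contig
is wrap-extended by one read length so origin-spanning reads map at their
true position modulo L. A read is `mapped` if its best locus is unique and
reaches `minIdentity`, `ambiguous` on a score tie across distinct loci
(ambiguous reads are dropped from pileups, mimicking MAPQ-0 filtering), and
`unmapped` otherwise.

`minIdentity = 0.88` is deliberately *below* typical NUMT similarity plus
sequencing error: the mito-only reference must be able to absorb
high-similarity NUMT reads, because that absorption is the phenomenon under
study, while the 86%-mean divergence keeps the most diverged NUMTs out.
Mapping the same reads against the combined reference can only remove or
re-home reads from the mito contig — the package checks this monotone
competition property over randomized worlds.

The mapper models the mechanism, not any specific production aligner; reads
shorter than k, or with indel structure (none is generated), go unmapped.

## Calling and comparison

`pileup()` tallies strand-normalized A/C/G/T counts per mito position from
uniquely mito-mapped reads; `callSites()` reports, at each position with
depth ≥ 100, the best non-reference allele whose frequency reaches the
calling floor (default 0.2%). The floor sits deliberately below the 0.5
percentage-point concordance threshold so that the comparison module, not
the caller, governs the discrepancy classes. Only the single best
non-reference allele is reported per site (one heteroplasmy level per site).

`compareRuns()` joins the two modes' calls on (position, alt) — a different
allele at the same position counts as two exclusives, the conservative
choice — and classifies: `concordant` (both modes, absolute difference
< 0.5 pp), `discrepant` (both modes, ≥ 0.5 pp), `exclusive_rcrs` /
`exclusive_combined` (one mode only). The threshold is an absolute
difference in percentage points, configurable. Downstream summaries:
scatter tables (exclusives plotted at 0 on the absent axis — a declared
convention), a NUMT-coverage track, positional histograms of
frequency-inflated and mito-only-exclusive variants, Fisher's exact test
for per-condition rate contrasts (exact rather than asymptotic because
exclusive counts can be tiny), and a circular-rotation permutation test for
positional clustering (the statistic is the mean track weight at the
variant positions; the null rotates the position set around the circle,
preserving spacing; add-one smoothing, so a constant track gives p = 1).
The rotation test is a declared stand-in for the unnamed correlation
analyses such studies report.

## Numerical and design notes

* **Determinism.** Every stochastic stage takes a seed; `runPipeline()`
  derives per-stage seeds from one master seed and records them. Identical
  seeds give byte-identical world files, pools, reads and reports.
* **Depth versus the calling floor.** With a 0.2% floor and a 0.002
  per-base error rate, per-site noise crosses the floor readily below
  ~2,000x depth, and presence/absence of borderline calls — not NUMT
  mechanics — then dominates the discrepancy classes. The shipped analyses
  therefore run at ~4,500–5,000x (500k–560k reads of 150 bp over 16.6 kb),
  where the floor sits well above the error quantile. These problem sizes
  are the package's own choice of realistic deep-coverage conditions.
* **The closed-form contamination check** (one diploid 5 kb NUMT at 95%
  similarity against C = 100; expected exclusive frequency 2/(C+2)) is run
  with `errorRate = 0`: the closed form assumes no sequencing error, and at
  the 0.2% floor error-level alt reads in the combined mode would
  stochastically re-classify the site from exclusive to discrepant — a
  classification artifact, not a stoichiometry failure.
* **Ties and degenerate inputs.** Allele argmax ties in the caller break
  deterministically (first of A<C<G<T); a single-NUMT registry reports
  similarity SD 0 by convention; empty truth tables, empty call sets and
  zero-NUMT worlds are all legal and round-trip through the writers.
* **Monotone strategy ordering** (discordant counts pcr180 ≥ pcr9 ≥ lrpcr2,
  with zero exclusives for the long-range design, and MDA worst of all) is
  checked end-to-end on a fixed 50-NUMT world at jackpot sd 0.

## What the synthetic world does and does not show

The generator reproduces the *mechanism*: stoichiometry-bounded NUMT read
fractions, amplicon-size-dependent co-amplification, competitive re-homing
under a combined reference, positional clustering of exclusives over NUMT
projections, and the primer-trimming effect. It does not reproduce
real-data magnitudes: real NUMT catalogues are non-uniform along the mtDNA
circle (real discrepancies cluster near the D-loop and mid-genome because
real NUMTs do), real samples differ from the reference in structured ways,
PCR chemistry and platform error are richer than i.i.d. substitutions, and
the observed difference between starting materials is only partially
captured by the copy-number/jackpot presets (its real cause is unresolved).
Passing the package's checks therefore validates the pipeline's mechanics
and bookkeeping, not any quantitative claim about a particular tissue or
kit. Re-analysis of user-supplied FASTQ + FASTA data is possible through
`readReadsFastq()`, `loadMitoReference()` and the mapper/caller modules,
but no external download is required by anything in the package.
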