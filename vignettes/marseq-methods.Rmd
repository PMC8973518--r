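---
title: "MARseq: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MARseq: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MARseq)
```

# The analysis model

Matrix attachment regions (MARs) are the DNA segments that stay bound to the
nuclear matrix — the fibro-granular scaffold left after nuclease digestion
and high-salt extraction of nuclei. Operationally, a MAR here is a sequencing
peak from matrix-associated DNA: the pipeline starts *after* read mapping and
peak calling, from one BED file of peaks per dataset (typically one per
developmental timepoint, e.g. day 1/5/7 silk-gland datasets). Everything
downstream rests on a few simple quantitative models:

* **Peak normalization.** Within a dataset, overlapping and bookended
  (end-touching) peaks describe one matrix contact, so they are merged into
  a single interval. Merging is idempotent and preserves covered bases.
* **Set comparison.** Biological dynamics across three timepoints are
  summarized by the seven-region Venn partition of the merged union of the
  three peak sets. A union interval belongs to an input set when it overlaps
  it by at least `minOverlap` bases; presence/absence semantics mean a union
  interval overlapping two peaks of one set still counts that set once,
  because the reported quantities are region counts, not pair counts.
* **Chromatin loop length.** Consecutive MARs on a chromosome anchor a
  chromatin loop between them, so the inter-MAR distance is used as a loop
  length proxy. For MAR midpoints $m_1 < \dots < m_n$ the loops are
  $d_i = m_{i+1} - m_i$; a chromosome needs at least two MARs to contribute.
* **Genomic context.** A MAR overlapping any exon by ≥1 bp is *exonic*,
  else overlapping any gene body is *intronic*, else *non-genic*. The three
  counts always sum to the number of classified MARs.
* **TSS distances.** Each MAR midpoint is assigned the signed distance to
  the nearest transcription start site (a gene's strand-aware 5' end);
  positive means downstream in gene orientation. Distances are binned over
  a symmetric window (±100 kb by default).
* **Sequence features.** MAR sequences are scanned for a catalog of
  MAR-associated motifs, the bipartite MAR recognition signature, and
  perfect simple sequence repeats; transposable-element alignment hits are
  filtered by identity and length thresholds.

# Parameters that matter

| parameter | default | unit | rationale |
|---|---|---|---|
| `minOverlap` (Venn membership) | 1 | bp | the `bedtools intersect` convention; the threshold is not dictated by the biology, so it is exposed |
| loop-length `method` | `midpoint` | — | midpoints are insensitive to peak width; `gap` (end to next start) is provided because either anchor is defensible |
| loop-length `aggregate` | `per_chromosome_mean` | — | chromosome-level loop estimates first, then averaged, so large chromosomes do not dominate; `global_mean` pools all distances |
| TSS `window` / `bin` | 100 000 / 10 000 | bp | the range over which MAR–TSS association is typically profiled; `bin` must divide `2*window` |
| gene flank | 800 000 | bp | the window used for fibroin-gene-style flank reports (800 kb up- and downstream) |
| motif `strands` | `forward` | — | single-strand counting is reproducible and sufficient for presence percentages; `both` is available since several catalog motifs are not strand-symmetric |
| MRS window | 200 | bp | definition of the bipartite signature: 8-mer `AATAAYAA` and 16-mer `AWWRTAANNWWGNNNC` within 200 bp |
| SSR `minReps` | 5 | copies | the standard microsatellite-discovery setting, applied uniformly to unit sizes 2–6 |
| SSR `maxInterruption` | 100 | bp | two simple SSRs closer than this form a compound SSR |
| TE `minIdentity` / `minLength` | 90 / 100 | % / bp | alignment-hit acceptance thresholds; boundary values pass |

Density reporting rounds half away from zero to two decimals, the precision
of published chromosome-wise MAR tables; unrounded values are kept
internally and rounding is applied only by `formatChromosomeSummary()`.

# Numerical and representational choices

**Coordinates.** Internally everything is a `GRanges` in the Bioconductor
1-based closed convention. BED input/output converts at the boundary
(0-based half-open), GFF3 maps directly. This differs from a raw 0-based
half-open internal representation only in bookkeeping, and it lets every
interval operation ride on `GenomicRanges`.

**Degenerate motif matching.** Patterns are literal IUPAC segments separated
by fixed-length unconstrained gaps, written compactly as e.g.
`TAn_3_TGn_3_CA` (an inline `n` inside a segment is the wildcard `N`).
Matching uses a bitwise IUPAC encoding; all overlapping hits are reported.
A base `N` in the *input* is matched only by pattern `N` — never by `W`,
`R`, etc. — so hard-masked stretches cannot inflate AT-rich counts. The
topoisomerase II consensus is shipped in its canonical 18-position form
(`RnYnnCnnGYnGKTnYnY`, `m_16`); a 15-position variant that circulates in the
literature is available as `TOPOII_SHORT_VARIANT` but is not part of the
default catalog.

**MRS pairing.** Either element may come first, elements may overlap, both
strands are searched by default (a forward-only mode exists), and pairs are
deduplicated on the two start positions. Separation is the number of bases
strictly between the elements, 0 when they overlap or abut.

**SSR detection.** The detector reports maximal perfect tandem runs,
scanning greedily left to right within each unit size so reported spans of
one size never overlap; only complete copies count, so a span is always
`unit_size * n_reps` long. A run whose unit is itself a tandem of a smaller
unit (`ATAT` = `(AT)2`) is reported once, at the smallest size.
Mononucleotide runs are excluded by default (unit sizes 2–6). Units are
reported exactly as found: no rotation or reverse-complement collapsing,
since e.g. `TTAGG` and `CCTAA` are conventionally listed as distinct repeat
classes. Members of a compound SSR are counted individually in class
summaries; the compound record itself is not double-counted.

**Ties and degenerate inputs.** Equidistant TSSs are broken toward the
lexicographically smaller gene id; chromosomes with fewer than two MARs have
an undefined (NA) loop length; zero-variance columns give NA correlations;
empty peak sets flow through merging, Venn partitioning and histograms as
empty results, not errors. In strict mode, MARs on chromosomes absent from
the size table (unplaced scaffolds) are an error; in lenient mode they are
dropped from per-chromosome tables and reported as a residual count, because
per-chromosome tables of published MAR counts typically sum to less than the
stated totals for exactly this reason.

# The synthetic-data generator

The generator emulates the study conditions the package is aimed at, at test
scale: an AT-rich genome (GC fraction 0.37, the silkworm genome-wide
composition), peaks of 200–400 bp (the enriched MAR size range), three
datasets with a configurable seven-region overlap design, gene models with
regular exon/intron structure, and sequences with motifs, MRS pairs and SSRs
planted at known positions.

Design choices worth knowing:

* Union regions are placed on a coarse grid whose cells are two bases wider
  than the longest peak, which guarantees ≥2 bp separation between distinct
  regions cheaply — merging can therefore never fuse two planted regions,
  and the Venn partition of the outputs recovers the design exactly. Shared
  regions are identical intervals across their member sets.
* Per-dataset peak counts are implied by the design; explicitly supplied
  counts are checked against it (too few is an error, not silently fixed).
* Planted motif instances resolve degenerate positions at random from the
  generator's seeded stream, and the concrete string is recorded in the
  truth so hits can be re-validated exactly.
* A planted SSR is flanked by guard bases chosen to break the periodicity,
  so the planted run is exactly the maximal run the detector must report;
  without this, a chance background base can extend and re-phase the run.
* All generators run on a private RNG stream seeded from the config and
  restore the caller's RNG state; bundles are byte-identical across runs of
  the same config.

What the generator does *not* emulate — and hence what passing tests do not
show about real data: read-level noise and coverage biases (the pipeline
starts from peaks), peak-width heterogeneity beyond a uniform length range,
sequence composition structure (isochores, real repeat landscapes, TE
sequence evolution), overlapping genes or alternative isoforms, and
partially overlapping shared peaks (shared planted regions are identical
across sets, whereas real replicate peaks jitter).

# Validation strategy and problem sizes

Each detector is checked against an independent oracle: merging and Venn
partitioning against per-base occupancy masks; motif scanning against a
PCRE lookahead regex built from the same notation; MRS pairing against a
direct cross-join of the two element hit lists; SSR detection against a
greedy backreference regex; the TE filter against a plain predicate; the
Pearson correlation against the closed-form sum formula. The oracle
equivalence suite runs 1000 random sequences (60–600 bp, with a tail up to
10 kb) across the full 18-motif catalog with planted SSRs and MRS pairs and
requires zero discrepancies. End-to-end, `simulateBundle()` plus
`runPipeline()` are exercised on a three-chromosome, 5 Mb genome with 120
genes and a 51-region design; these sizes keep the full suite at a few
minutes on one CPU while leaving every code path exercised.

Published chromosome-wise densities (the table shipped in
`inst/extdata/bmori_chromosome_mar_counts.tsv`) are reproduced to their
printed two decimals by the density arithmetic; rows whose printed values
are ambiguous in the source table are not included.

# Known limitations

* Loop lengths from peak sets answer "distance between adjacent matrix
  contacts"; they are not Hi-C-style loop calls, and published average loop
  lengths computed from full peak coordinates cannot be recomputed from
  per-chromosome summary tables alone (the anchor — midpoint, edge, or
  summit — and the averaging order both matter, which is why both are
  exposed as options).
* Motif hit totals depend on strand policy and overlap handling; published
  catalog counts produced by other scanners with unstated settings are
  treated as context, not as targets.
* Only perfect SSRs are detected (no mismatched/approximate repeats), and
  alignment itself (BLAST/RepeatMasker) is out of scope — the package
  consumes tabular hits.
* Pathway joins report gene counts per pathway; no enrichment statistics
  are computed.
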