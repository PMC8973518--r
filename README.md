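# MARseq

Downstream analysis of **nuclear matrix attachment region (MAR)** sequencing
peaks in R/Bioconductor style.

MARs (also called S/MARs) are the DNA segments that remain anchored to the
nuclear matrix after nuclease digestion and high-salt extraction; they tether
chromatin loops and are implicated in replication and transcriptional
regulation. MAR-Seq experiments recover them genome-wide as sequencing peaks
— for example across developmental timepoints of the *Bombyx mori* posterior
silk gland, the setting this package's defaults emulate. `MARseq` is for
genomicists who have called the peaks (BED), have a genome (FASTA) and gene
models (GFF3), and need the downstream biology:

* **Interval algebra** — merging of overlapping/bookended peaks and the
  seven-region Venn partition of three peak sets A, B, C (unique to each set,
  each pair, and common to all), with membership defined by an overlap of at
  least `minOverlap` bp.
* **Chromosome statistics** — per-chromosome MAR counts and densities
  (MARs/Mb), gene densities (genes/Mb), and the **chromatin loop-length
  proxy**: for consecutive MARs at midpoints m_1 < m_2 < ... on a chromosome,
  the loop lengths are d_i = m_(i+1) − m_i and the chromosome mean is
  mean(d_i) (an end-to-start "gap" variant is also provided). Pearson and
  Spearman correlations between any two chromosome-level statistics.
* **Annotation** — exonic / intronic / non-genic classification with
  precedence exon > intron > non-genic; signed, strand-aware MAR-to-TSS
  distance profiles over ±100 kb; MAR reports for the flanking window of a
  gene of interest; gene-to-pathway joins.
* **Motif scanning** — a built-in catalog of 18 MAR-associated motifs
  (ORI signals such as `ATTA`; TG-rich; curved DNA such as
  `AAAAn_7_AAAAn_7_AAAA`; kinked DNA such as `TAn_3_TGn_3_CA`; topoisomerase
  II consensus sites; the AT-rich hexamer `WWWWWW`), scanned with full IUPAC
  degeneracy and fixed-length gaps, plus the bipartite **MAR recognition
  signature** (an `AATAAYAA` 8-mer and an `AWWRTAANNWWGNNNC` 16-mer within
  200 bp of each other).
* **Repeats** — MISA-style perfect simple-sequence-repeat detection (units
  of 2–6 bp, ≥5 copies, compound SSRs at ≤100 bp interruption) and
  filtering of transposable-element alignment hits (≥90 % identity,
  ≥100 bp) with merged per-TE occupancy.
* **Synthetic data** — generators that plant peak overlap designs, uniform
  loop spacings, gene contexts, motifs, MRS pairs and SSRs at known
  positions, so every stage is validated against ground truth.

## Worked example

Simulate a three-dataset bundle with a planted overlap design, then run the
interval, loop and motif analyses:

```r
library(MARseq)
cfg <- syntheticConfig(seed = 7)          # 3 chromosomes, AT-rich, 51 regions
bundle <- simulateBundle(cfg, "demo")
peaks <- lapply(bundle$beds, readPeakBed)

vennPartition(peaks[[1]], peaks[[2]], peaks[[3]],
              labels = c("SG1", "SG5", "SG7"))
#> VennPartition of SG1/SG5/SG7 (min overlap 1 bp)
#>   onlyA         5  ( 9.80%)
#>   onlyB        10  (19.61%)
#>   onlyC        20  (39.22%)
#>   AB_only       3  ( 5.88%)
#>   AC_only       3  ( 5.88%)
#>   BC_only       3  ( 5.88%)
#>   ABC           7  (13.73%)
#>   union   51 intervals
```

The partition recovers the generator's design exactly: 7 regions common to
all three datasets, 5/10/20 unique ones, and 3 per pair; percentages are of
the 51-interval merged union.

```r
loopLengths(mergePeaks(peaks[[3]]))$overall_mean_kb
#> [1] 127.0228
```

The day-7-style set carries 33 MARs over three 1.7 Mb chromosomes, giving a
mean midpoint-to-midpoint loop length of about 127 kb.

```r
genome <- Biostrings::readDNAStringSet(bundle$fasta)
ab <- motifAbundance(extractSequences(genome, mergePeaks(peaks[[3]])))
head(ab$per_category)
#>     category n_seqs_with_hit presence_pct
#> 1    AT_rich              33    100.00000
#> 2 curved_DNA               8     24.24242
#> 3    dtopoII               0      0.00000
#> 4 kinked_DNA              10     30.30303
#> 5    mtopoII               0      0.00000
#> 6        ORI              33    100.00000
```

On an AT-rich background (GC 0.37) every 200–400 bp MAR sequence contains
AT-rich and ORI signals, while the long, gap-constrained topoisomerase II
consensus essentially never occurs by chance — the ordering reported for
real silk-gland MAR sequences.

`runPipeline(runConfig(...))` chains all stages (merge → Venn → chromosome
summary → loops → correlation → context/TSS → motifs/MRS → SSR → TE filter →
gene-flank → pathways), writing one TSV per stage and a JSON manifest;
`inst/scripts/marseq-cli.R` exposes the same operations as shell
subcommands.

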