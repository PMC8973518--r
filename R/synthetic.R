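# Run expr with a private RNG stream seeded by `seed`, restoring the caller's
# RNG state afterwards. All generators are fully deterministic given the seed.
.withSeed <- function(seed, expr) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
        on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
    }
    set.seed(seed)
    force(expr)
}

#' Configuration for the synthetic-data generators
#'
#' Default values emulate the study conditions of a silk-gland MAR-Seq
#' experiment at test scale: an AT-rich multi-chromosome genome (GC 0.37,
#' the silkworm genome-wide composition), peaks of 200-400 bp (the enriched
#' MAR size range), and a three-dataset design with a configurable
#' seven-region overlap structure.
#'
#' @param seed RNG seed.
#' @param nChroms number of chromosomes.
#' @param chromSizeBp chromosome length(s) in bp (recycled to `nChroms`).
#' @param gcFraction background GC fraction.
#' @param nGenesPerChrom genes per chromosome.
#' @param exonsPerGene exons per gene.
#' @param vennDesign named integer(7): target counts for `onlyA`, `onlyB`,
#'   `onlyC`, `AB_only`, `AC_only`, `BC_only`, `ABC`.
#' @param nPeaks optional integer(3) of per-dataset peak counts; must be
#'   consistent with `vennDesign` (it is checked, not inferred).
#' @param peakLength integer(2): min/max peak length in bp.
#' @param labels dataset labels.
#' @return a list of class `SyntheticConfig`.
#' @export
syntheticConfig <- function(seed = 1L, nChroms = 3L, chromSizeBp = 1700000L,
                            gcFraction = 0.37, nGenesPerChrom = 40L,
                            exonsPerGene = 3L,
                            vennDesign = c(onlyA = 5L, onlyB = 10L,
                                           onlyC = 20L, AB_only = 3L,
                                           AC_only = 3L, BC_only = 3L,
                                           ABC = 7L),
                            nPeaks = NULL,
                            peakLength = c(200L, 400L),
                            labels = c("SG1", "SG5", "SG7")) {
    stopifnot(nChroms >= 1L, gcFraction >= 0, gcFraction <= 1,
              length(peakLength) == 2L, peakLength[1L] > 0,
              peakLength[2L] >= peakLength[1L],
              peakLength[2L] < min(chromSizeBp))
    if (!all(.VENN_REGIONS %in% names(vennDesign)))
        stop("vennDesign must name all seven regions: ",
             paste(.VENN_REGIONS, collapse = ", "))
    vennDesign <- vennDesign[.VENN_REGIONS]
    if (any(vennDesign < 0L)) stop("vennDesign counts must be >= 0")
    need <- .designSetCounts(vennDesign)
    if (!is.null(nPeaks)) {
        if (any(nPeaks < need))
            stop("requested per-dataset peak counts (", paste(nPeaks,
                 collapse = ","), ") are below the counts implied by ",
                 "vennDesign (", paste(need, collapse = ","), ")")
        if (any(nPeaks != need))
            stop("per-dataset peak counts must equal the counts implied ",
                 "by vennDesign (", paste(need, collapse = ","), ")")
    }
    structure(list(seed = as.integer(seed), nChroms = as.integer(nChroms),
                   chromSizeBp = as.integer(rep_len(chromSizeBp, nChroms)),
                   gcFraction = gcFraction,
                   nGenesPerChrom = as.integer(nGenesPerChrom),
                   exonsPerGene = as.integer(exonsPerGene),
                   vennDesign = as.integer(vennDesign) |>
                       stats::setNames(.VENN_REGIONS),
                   peakLength = as.integer(peakLength),
                   labels = labels),
              class = "SyntheticConfig")
}

.designSetCounts <- function(design) {
    c(A = design[["onlyA"]] + design[["AB_only"]] + design[["AC_only"]] +
          design[["ABC"]],
      B = design[["onlyB"]] + design[["AB_only"]] + design[["BC_only"]] +
          design[["ABC"]],
      C = design[["onlyC"]] + design[["AC_only"]] + design[["BC_only"]] +
          design[["ABC"]])
}

#' Generate a synthetic genome
#'
#' Random i.i.d. nucleotide sequence per chromosome at the configured GC
#' fraction. Byte-identical across runs for a fixed seed.
#'
#' @param cfg a [syntheticConfig()].
#' @return list with `genome` ([Biostrings::DNAStringSet], names
#'   `chr1..chrN`) and `chromSizes` (data.frame `chrom`, `length_bp`).
#' @export
makeGenome <- function(cfg) {
    .withSeed(cfg$seed, {
        g <- cfg$gcFraction
        p <- c(A = (1 - g) / 2, C = g / 2, G = g / 2, T = (1 - g) / 2)
        seqs <- vapply(seq_len(cfg$nChroms), function(i)
            paste(sample(names(p), cfg$chromSizeBp[i], replace = TRUE,
                         prob = p), collapse = ""), character(1))
        names(seqs) <- paste0("chr", seq_len(cfg$nChroms))
        list(genome = Biostrings::DNAStringSet(seqs),
             chromSizes = data.frame(chrom = names(seqs),
                                     length_bp = cfg$chromSizeBp))
    })
}

#' Generate three peak sets with a planted seven-region overlap design
#'
#' Places `sum(vennDesign)` distinct union regions on a coarse grid (cells
#' two bases wider than the longest peak, so distinct regions are always
#' separated by at least 2 bp and merging never fuses them), then assigns
#' each region to one of the seven Venn regions. Shared regions are
#' *identical* intervals across their member sets, so [vennPartition()] on
#' the outputs recovers the design exactly.
#'
#' @param cfg a [syntheticConfig()].
#' @param chromSizes data.frame (`chrom`, `length_bp`); defaults to the
#'   genome implied by `cfg`.
#' @return list with `peaks` (named list of three `GRanges`), `truth`
#'   (data.frame: `region`, `chrom`, `start`, `end`, `membership`), and
#'   `design` (the planted counts).
#' @export
makePeakSets <- function(cfg, chromSizes = NULL) {
    if (is.null(chromSizes))
        chromSizes <- data.frame(chrom = paste0("chr",
                                                seq_len(cfg$nChroms)),
                                 length_bp = cfg$chromSizeBp)
    design <- cfg$vennDesign
    R <- sum(design)
    cell <- cfg$peakLength[2L] + 2L
    nCells <- pmax(0L, chromSizes$length_bp %/% cell)
    if (sum(nCells) < R)
        stop("infeasible design: ", R, " regions do not fit in ",
             sum(nCells), " grid cells; enlarge the genome or shrink the ",
             "design")
    .withSeed(cfg$seed + 1L, {
        cellChrom <- rep(chromSizes$chrom, nCells)
        cellOffset <- unlist(lapply(nCells, function(n)
            (seq_len(n) - 1L) * cell), use.names = FALSE)
        pick <- sample(length(cellChrom), R)
        len <- sample(seq(cfg$peakLength[1L], cfg$peakLength[2L]), R,
                      replace = TRUE)
        start <- cellOffset[pick] + 1L
        membership <- sample(rep(names(design), design))
        truth <- data.frame(region = paste0("r", seq_len(R)),
                            chrom = cellChrom[pick],
                            start = start, end = start + len - 1L,
                            membership = membership,
                            stringsAsFactors = FALSE)
        truth <- truth[order(truth$chrom, truth$start), , drop = FALSE]
        rownames(truth) <- NULL
        inSet <- list(
            A = truth$membership %in% c("onlyA", "AB_only", "AC_only", "ABC"),
            B = truth$membership %in% c("onlyB", "AB_only", "BC_only", "ABC"),
            C = truth$membership %in% c("onlyC", "AC_only", "BC_only", "ABC"))
        peaks <- lapply(inSet, function(sel) {
            gr <- GRanges(truth$chrom[sel],
                          IRanges(truth$start[sel], truth$end[sel]))
            gr
        })
        names(peaks) <- cfg$labels
        for (i in seq_along(peaks))
            metadata(peaks[[i]])$label <- cfg$labels[i]
        list(peaks = peaks, truth = truth, design = design)
    })
}

#' Uniformly spaced peaks with known loop length
#'
#' Plants peaks whose midpoints are exactly `spacing` bp apart on one
#' chromosome, so the midpoint inter-MAR distance — the chromatin loop-length
#' proxy — is `spacing` by construction.
#'
#' @param chrom chromosome name.
#' @param n number of peaks.
#' @param spacing midpoint-to-midpoint distance in bp.
#' @param width peak width (odd widths center exactly).
#' @param offset midpoint of the first peak.
#' @return list with `peaks` (`GRanges`) and `truth` (list: `spacing_bp`,
#'   `n`).
#' @export
makeUniformPeaks <- function(chrom = "chr1", n = 100L, spacing = 50000L,
                             width = 301L, offset = width) {
    mids <- offset + (seq_len(n) - 1L) * spacing
    half <- (width - 1L) %/% 2L
    gr <- GRanges(chrom, IRanges(mids - half, mids + half))
    list(peaks = gr, truth = list(spacing_bp = spacing, n = n))
}

#' Generate synthetic gene models
#'
#' Packs non-overlapping genes with a regular exon/intron structure onto
#' each chromosome; strands are assigned at random. Exons are 150-300 bp and
#' introns 300-600 bp, so every gene has interior room for planting
#' context-test peaks.
#'
#' @param cfg a [syntheticConfig()].
#' @param chromSizes as in [makePeakSets()].
#' @return list with `geneModels` ([GeneModelSet-class]) and `truth`
#'   (data.frame: `gene_id`, `chrom`, `strand`, `start`, `end`, `tss`).
#' @export
makeGeneModels <- function(cfg, chromSizes = NULL) {
    if (is.null(chromSizes))
        chromSizes <- data.frame(chrom = paste0("chr",
                                                seq_len(cfg$nChroms)),
                                 length_bp = cfg$chromSizeBp)
    k <- cfg$exonsPerGene
    maxGeneLen <- k * 300L + (k - 1L) * 600L
    cell <- maxGeneLen + 200L
    .withSeed(cfg$seed + 2L, {
        out <- list(); exlist <- list(); gi <- 0L
        for (ci in seq_len(nrow(chromSizes))) {
            nCells <- chromSizes$length_bp[ci] %/% cell
            if (nCells < cfg$nGenesPerChrom)
                stop("infeasible packing: ", cfg$nGenesPerChrom,
                     " genes need ", cfg$nGenesPerChrom, " cells of ", cell,
                     " bp on ", chromSizes$chrom[ci])
            cells <- sort(sample(nCells, cfg$nGenesPerChrom))
            for (cellIdx in cells) {
                gi <- gi + 1L
                exLen <- sample(150:300, k, replace = TRUE)
                inLen <- if (k > 1L) sample(300:600, k - 1L,
                                            replace = TRUE) else integer(0)
                gStart <- (cellIdx - 1L) * cell + sample(1:100, 1L)
                exStart <- gStart + cumsum(c(0L, exLen[-k] + inLen))
                exEnd <- exStart + exLen - 1L
                out[[gi]] <- data.frame(
                    gene_id = sprintf("g%04d", gi),
                    chrom = chromSizes$chrom[ci],
                    strand = sample(c("+", "-"), 1L),
                    start = gStart, end = exEnd[k])
                exlist[[gi]] <- data.frame(gene = sprintf("g%04d", gi),
                                           chrom = chromSizes$chrom[ci],
                                           start = exStart, end = exEnd)
            }
        }
        gdf <- do.call(rbind, out)
        edf <- do.call(rbind, exlist)
        gr <- GRanges(gdf$chrom, IRanges(gdf$start, gdf$end),
                      strand = gdf$strand, gene_id = gdf$gene_id)
        ex <- GRanges(edf$chrom, IRanges(edf$start, edf$end))
        gms <- GeneModelSet(gr, ex, exonGene = edf$gene)
        truth <- gdf
        truth$tss <- ifelse(gdf$strand == "+", gdf$start, gdf$end)
        list(geneModels = gms, truth = truth)
    })
}

#' Plant peaks with known genomic context
#'
#' Places peaks fully inside exons, fully inside introns, and fully outside
#' gene spans, in equal-opportunity random positions, so the true context
#' label of every peak is known by construction.
#'
#' @param geneModels a [GeneModelSet-class].
#' @param chromSizes data.frame (`chrom`, `length_bp`).
#' @param nExonic,nIntronic,nIntergenic planted counts per class.
#' @param width peak width (must fit inside the smallest exon/intron).
#' @param seed RNG seed.
#' @return list with `peaks` (`GRanges`) and `truth` (factor of labels).
#' @export
makeContextPeaks <- function(geneModels, chromSizes, nExonic = 100L,
                             nIntronic = 100L, nIntergenic = 100L,
                             width = 50L, seed = 1L) {
    ex <- unlist(exons(geneModels), use.names = FALSE)
    g <- genes(geneModels)
    introns <- GenomicRanges::setdiff(
        GenomicRanges::`strand<-`(g, value = "*"),
        GenomicRanges::`strand<-`(ex, value = "*"))
    genomeGr <- GRanges(chromSizes$chrom, IRanges(1L, chromSizes$length_bp))
    inter <- GenomicRanges::setdiff(genomeGr,
        GenomicRanges::`strand<-`(g, value = "*"))
    pickIn <- function(pool, n) {
        pool <- pool[GenomicRanges::width(pool) >= width + 2L]
        if (length(pool) < 1L) stop("no room to plant peaks of width ", width)
        sel <- sample(length(pool), n, replace = n > length(pool))
        s <- GenomicRanges::start(pool)[sel] +
            vapply(GenomicRanges::width(pool)[sel] - width - 1L,
                   function(m) sample.int(m, 1L), integer(1))
        GRanges(GenomicRanges::seqnames(pool)[sel], IRanges(s, width = width))
    }
    .withSeed(seed, {
        peaks <- c(pickIn(ex, nExonic), pickIn(introns, nIntronic),
                   pickIn(inter, nIntergenic))
        truth <- factor(rep(c("exonic", "intronic", "nongenic"),
                            c(nExonic, nIntronic, nIntergenic)),
                        levels = c("exonic", "intronic", "nongenic"))
        list(peaks = peaks, truth = truth)
    })
}

# draw one concrete expansion of a degenerate pattern (gaps filled at random)
.expandPattern <- function(pattern) {
    allowed <- list(A = "A", C = "C", G = "G", T = "T",
                    R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                    W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                    B = c("C", "G", "T"), D = c("A", "G", "T"),
                    H = c("A", "C", "T"), V = c("A", "C", "G"),
                    N = c("A", "C", "G", "T"))
    parts <- character(0)
    for (i in seq_along(pattern@segments)) {
        seg <- strsplit(pattern@segments[i], "", fixed = TRUE)[[1L]]
        parts <- c(parts, vapply(seg, function(ch) {
            ok <- allowed[[ch]]
            ok[sample.int(length(ok), 1L)]
        }, character(1)))
        if (i < length(pattern@segments))
            parts <- c(parts, sample(c("A", "C", "G", "T"),
                                     pattern@gaps[i], replace = TRUE))
    }
    paste(parts, collapse = "")
}

#' Plant sequence features at known positions
#'
#' Overwrites stretches of a sequence with concrete instances of motifs
#' (degenerate positions resolved at random), perfect tandem SSRs, or MRS
#' element pairs, and returns the truth records needed to re-validate every
#' detector. Planted spans must not overlap; an MRS pair with separation
#' above 200 bp is rejected.
#'
#' @param seq a single sequence (character or `DNAString`).
#' @param plan data.frame with columns `kind` (`motif`/`ssr`/`mrs`), `at`
#'   (1-based start), and per kind: `spec` (motif notation) for motifs,
#'   `unit` + `n_reps` for SSRs, `separation` for MRS pairs.
#' @param seed RNG seed for degenerate-position resolution.
#' @return list with `seq` (mutated character) and `truth` (data.frame:
#'   `kind`, `id`, `start`, `end`, `string`).
#' @export
plantFeatures <- function(seq, plan, seed = 1L) {
    x <- toupper(as.character(seq))
    .withSeed(seed, {
        pieces <- lapply(seq_len(nrow(plan)), function(i) {
            row <- plan[i, ]
            if (row$kind == "motif") {
                p <- compilePattern(row$spec)
                s <- .expandPattern(p)
                data.frame(kind = "motif", id = row$spec, start = row$at,
                           end = row$at + nchar(s) - 1L, string = s)
            } else if (row$kind == "ssr") {
                s <- strrep(row$unit, row$n_reps)
                data.frame(kind = "ssr",
                           id = sprintf("(%s)%d", row$unit, row$n_reps),
                           start = row$at, end = row$at + nchar(s) - 1L,
                           string = s)
            } else if (row$kind == "mrs") {
                if (row$separation > 200L)
                    stop("MRS pair with separation ", row$separation,
                         " exceeds the 200 bp window")
                s8 <- .expandPattern(compilePattern(MRS_8MER))
                s16 <- .expandPattern(compilePattern(MRS_16MER))
                spacer <- paste(sample(c("C", "G"), row$separation,
                                       replace = TRUE), collapse = "")
                s <- paste0(s8, spacer, s16)
                data.frame(kind = "mrs", id = "MRS", start = row$at,
                           end = row$at + nchar(s) - 1L, string = s)
            } else stop("unknown plan kind: ", row$kind)
        })
        truth <- do.call(rbind, pieces)
        if (any(truth$end > nchar(x)))
            stop("planted span extends beyond the sequence")
        o <- order(truth$start)
        if (any(truth$start[o][-1L] <= truth$end[o][-nrow(truth)]))
            stop("planted spans overlap")
        for (i in seq_len(nrow(truth)))
            substr(x, truth$start[i], truth$end[i]) <- truth$string[i]
        # guard bases around planted SSRs so the tandem run is exactly the
        # planted span: a chance background base continuing the periodicity
        # would otherwise extend (and re-phase) the maximal run
        for (i in which(truth$kind == "ssr")) {
            unit <- plan$unit[plan$at == truth$start[i]][1L]
            k <- nchar(unit)
            s <- truth$start[i]; e <- truth$end[i]
            other <- function(ch) setdiff(c("A", "C", "G", "T"), ch)[1L]
            if (s > 1L && substr(x, s - 1L, s - 1L) == substr(unit, k, k))
                substr(x, s - 1L, s - 1L) <- other(substr(unit, k, k))
            if (e < nchar(x) && substr(x, e + 1L, e + 1L) ==
                    substr(unit, 1L, 1L))
                substr(x, e + 1L, e + 1L) <- other(substr(unit, 1L, 1L))
        }
        list(seq = x, truth = truth)
    })
}

#' Simulate a complete analysis bundle on disk
#'
#' Generates a genome (FASTA), chromosome-size table (TSV), gene models
#' (GFF3), three peak BED files with a planted overlap design, and plants
#' motif/SSR/MRS features inside a subset of the common peaks; writes a JSON
#' truth file describing everything planted. Running twice with the same
#' config produces byte-identical bundles.
#'
#' @param cfg a [syntheticConfig()].
#' @param dir output directory (created).
#' @return invisibly, a list of the generated file paths plus the truth
#'   list.
#' @export
simulateBundle <- function(cfg, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    gen <- makeGenome(cfg)
    gm <- makeGeneModels(cfg, gen$chromSizes)
    pk <- makePeakSets(cfg, gen$chromSizes)
    # plant one motif, one SSR and one MRS inside the first few common peaks
    common <- pk$truth[pk$truth$membership == "ABC", , drop = FALSE]
    plantTruth <- NULL
    if (nrow(common) >= 3L) {
        rows <- common[1:3, ]
        genome <- as.character(gen$genome)
        plans <- list(
            data.frame(kind = "motif", at = 21L, spec = "TTTTGGGG"),
            data.frame(kind = "ssr", at = 21L, unit = "TTAGG", n_reps = 6L),
            data.frame(kind = "mrs", at = 21L, separation = 40L))
        plantTruth <- lapply(1:3, function(i) {
            chr <- rows$chrom[i]
            plan <- plans[[i]]
            plan$at <- rows$start[i] + plan$at - 1L
            pf <- plantFeatures(genome[[chr]], plan, seed = cfg$seed + 3L + i)
            genome[[chr]] <<- pf$seq
            cbind(chrom = chr, pf$truth)
        })
        plantTruth <- do.call(rbind, plantTruth)
        gen$genome <- Biostrings::DNAStringSet(genome)
    }
    paths <- list(
        fasta = file.path(dir, "genome.fa"),
        sizes = file.path(dir, "chrom_sizes.tsv"),
        gff = file.path(dir, "genes.gff3"),
        beds = file.path(dir, paste0("peaks_", cfg$labels, ".bed")),
        truthFile = file.path(dir, "truth.json"))
    Biostrings::writeXStringSet(gen$genome, paths$fasta)
    utils::write.table(gen$chromSizes, paths$sizes, sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    writeGeneModelsGff3(gm$geneModels, paths$gff)
    for (i in 1:3)
        writeBed(pk$peaks[[i]], paths$beds[i])
    truth <- list(seed = cfg$seed,
                  design = as.list(pk$design),
                  peak_counts = as.list(stats::setNames(
                      vapply(pk$peaks, length, integer(1)), cfg$labels)),
                  regions = pk$truth,
                  genes = gm$truth,
                  planted = plantTruth)
    jsonlite::write_json(truth, paths$truthFile, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
    invisible(c(paths, list(truth = truth)))
}
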