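#' Assemble a pipeline run configuration
#'
#' @param beds character(3): peak BED paths (one per dataset).
#' @param sizes chromosome-size TSV path.
#' @param fasta optional genome FASTA; sequence stages (motifs, MRS, SSRs)
#'   are skipped without it.
#' @param gff optional gene-model GFF3/GTF; annotation stages are skipped
#'   without it.
#' @param pathways optional gene-to-pathway TSV.
#' @param teHits optional alignment-hit TSV (blast outfmt 6).
#' @param outDir output directory.
#' @param labels dataset labels (default: BED file names).
#' @param minOverlap Venn membership threshold (bp).
#' @param loopMethod,loopAggregate passed to [loopLengths()].
#' @param tssWindow,tssBin passed to [tssProfile()].
#' @param strands motif-scan strand mode.
#' @param ssrMinReps,ssrMaxInterruption passed to [findSSRs()].
#' @param teMinIdentity,teMinLength passed to [teHitFilter()].
#' @param flankGene optional gene id for a gene-flank MAR report.
#' @param flank flank size (bp) for that report.
#' @return a list of class `RunConfig`.
#' @export
runConfig <- function(beds, sizes, fasta = NULL, gff = NULL,
                      pathways = NULL, teHits = NULL, outDir = "marseq_out",
                      labels = NULL, minOverlap = 1L,
                      loopMethod = "midpoint",
                      loopAggregate = "per_chromosome_mean",
                      tssWindow = 100000L, tssBin = 10000L,
                      strands = "forward", ssrMinReps = 5L,
                      ssrMaxInterruption = 100L, teMinIdentity = 90,
                      teMinLength = 100L, flankGene = NULL,
                      flank = 800000L) {
    if (length(beds) != 3L)
        stop("exactly three peak BED files are required")
    for (p in c(beds, sizes, fasta, gff, pathways, teHits))
        if (!file.exists(p))
            stop("input file not found: ", p)
    if (is.null(labels))
        labels <- sub("\\.[^.]*$", "", basename(beds))
    structure(mget(names(formals(runConfig)), envir = environment()),
              class = "RunConfig")
}

.writeTsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    path
}

#' Run the full MAR analysis pipeline
#'
#' Executes merge, Venn partition, length distribution, chromosome summary,
#' loop lengths, density correlation, context classification and TSS profile
#' (with gene models), motif/MRS/SSR scans (with a genome), TE-hit filtering,
#' gene-flank report and pathway join (with the respective optional inputs),
#' writing one TSV per stage plus a JSON run manifest echoing all parameters
#' and input checksums. Stages whose optional inputs are absent are skipped
#' with a message. Deterministic stages are bit-identical across re-runs.
#'
#' @param cfg a [runConfig()].
#' @return invisibly, a named list of the stage results.
#' @export
runPipeline <- function(cfg) {
    stopifnot(inherits(cfg, "RunConfig"))
    dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)
    notice <- function(...) message("[MARseq] ", ...)
    res <- list()

    raw <- Map(readPeakBed, cfg$beds, cfg$labels)
    merged <- lapply(raw, mergePeaks)
    names(merged) <- cfg$labels
    for (i in seq_along(merged))
        writeBed(merged[[i]],
                 file.path(cfg$outDir, paste0("merged_", cfg$labels[i],
                                              ".bed")))
    res$merged <- merged

    vp <- vennPartition(merged[[1L]], merged[[2L]], merged[[3L]],
                        minOverlap = cfg$minOverlap, labels = cfg$labels)
    writeVennPartition(vp, cfg$outDir)
    res$venn <- vp

    sizes <- readChromSizes(cfg$sizes)
    lens <- do.call(rbind, lapply(cfg$labels, function(l)
        cbind(dataset = l, lengthDistribution(merged[[l]]))))
    .writeTsv(lens, file.path(cfg$outDir, "length_distribution.tsv"))
    res$length_distribution <- lens

    gms <- NULL
    if (!is.null(cfg$gff))
        gms <- readGeneModels(cfg$gff)
    cs <- lapply(cfg$labels, function(l)
        chromosomeSummary(merged[[l]], sizes, gms,
                          loopMethod = cfg$loopMethod))
    names(cs) <- cfg$labels
    csTab <- do.call(rbind, lapply(cfg$labels, function(l)
        cbind(dataset = l, formatChromosomeSummary(cs[[l]]))))
    .writeTsv(csTab, file.path(cfg$outDir, "chromosome_summary.tsv"))
    res$chromosome_summary <- cs

    loops <- lapply(merged, loopLengths, method = cfg$loopMethod,
                    aggregate = cfg$loopAggregate)
    loopTab <- data.frame(dataset = cfg$labels,
                          overall_mean_loop_kb = vapply(loops,
                              `[[`, numeric(1), "overall_mean_kb"))
    .writeTsv(loopTab, file.path(cfg$outDir, "loop_lengths.tsv"))
    res$loops <- loops

    corr <- lapply(cs, function(s)
        tryCatch(densityCorrelation(s), error = function(e) NULL))
    corTab <- do.call(rbind, lapply(cfg$labels, function(l)
        if (!is.null(corr[[l]])) data.frame(dataset = l,
            pearson_r = corr[[l]]$pearson_r,
            spearman_rho = corr[[l]]$spearman_rho, n = corr[[l]]$n)))
    if (!is.null(corTab))
        .writeTsv(corTab, file.path(cfg$outDir, "density_correlation.tsv"))
    res$correlation <- corr

    if (!is.null(gms)) {
        ctx <- lapply(merged, classifyContext, geneModels = gms)
        ctxTab <- do.call(rbind, lapply(cfg$labels, function(l)
            data.frame(dataset = l, t(ctx[[l]]$counts))))
        .writeTsv(ctxTab, file.path(cfg$outDir, "context_counts.tsv"))
        res$context <- ctx

        tp <- lapply(merged, tssProfile, geneModels = gms,
                     window = cfg$tssWindow, bin = cfg$tssBin)
        tpTab <- do.call(rbind, lapply(cfg$labels, function(l)
            cbind(dataset = l, tp[[l]])))
        .writeTsv(tpTab, file.path(cfg$outDir, "tss_profile.tsv"))
        res$tss <- tp
    } else notice("no gene models: context and TSS stages skipped")

    if (!is.null(cfg$fasta)) {
        genome <- Biostrings::readDNAStringSet(cfg$fasta)
        names(genome) <- sub("\\s.*", "", names(genome))
        ab <- lapply(merged, function(m)
            motifAbundance(extractSequences(genome, m),
                           strands = cfg$strands))
        abTab <- do.call(rbind, lapply(cfg$labels, function(l)
            cbind(dataset = l, ab[[l]]$per_motif)))
        .writeTsv(abTab, file.path(cfg$outDir, "motif_abundance.tsv"))
        catTab <- do.call(rbind, lapply(cfg$labels, function(l)
            cbind(dataset = l, ab[[l]]$per_category)))
        .writeTsv(catTab, file.path(cfg$outDir, "motif_categories.tsv"))
        res$motifs <- ab

        ssr <- lapply(cfg$labels, function(l)
            findSSRs(extractSequences(genome, merged[[l]]),
                     minReps = cfg$ssrMinReps,
                     maxInterruption = cfg$ssrMaxInterruption))
        names(ssr) <- cfg$labels
        ssrTab <- do.call(rbind, lapply(cfg$labels, function(l)
            if (nrow(ssr[[l]])) cbind(dataset = l, ssr[[l]])))
        if (is.null(ssrTab))
            ssrTab <- data.frame(dataset = character())
        .writeTsv(ssrTab, file.path(cfg$outDir, "ssr_records.tsv"))
        res$ssr <- ssr
    } else notice("no genome FASTA: motif, MRS and SSR stages skipped")

    if (!is.null(cfg$teHits)) {
        te <- teHitFilter(readBlastHits(cfg$teHits),
                          minIdentity = cfg$teMinIdentity,
                          minLength = cfg$teMinLength)
        .writeTsv(te$occupancy, file.path(cfg$outDir, "te_occupancy.tsv"))
        res$te <- te
    } else notice("no TE hit table: TE stage skipped")

    if (!is.null(cfg$flankGene) && !is.null(gms)) {
        fr <- geneFlankReport(merged, gms, cfg$flankGene, flank = cfg$flank,
                              minOverlap = cfg$minOverlap)
        .writeTsv(cbind(fr$counts, n_common = fr$n_common),
                  file.path(cfg$outDir, "gene_flank.tsv"))
        res$flank <- fr
    }

    if (!is.null(cfg$pathways) && !is.null(gms)) {
        marGenes <- unique(unlist(lapply(merged, function(m) {
            hit <- IRanges::overlapsAny(genes(gms), m,
                                              ignore.strand = TRUE)
            mcols(genes(gms))$gene_id[hit]
        })))
        pj <- pathwayJoin(marGenes, readPathwayMap(cfg$pathways))
        .writeTsv(pj$counts, file.path(cfg$outDir, "pathway_counts.tsv"))
        res$pathways <- pj
    } else if (!is.null(cfg$pathways))
        notice("pathway map given but no gene models: pathway stage skipped")

    manifest <- list(
        package = "MARseq",
        version = as.character(utils::packageVersion("MARseq")),
        parameters = cfg[setdiff(names(cfg),
                                 c("beds", "sizes", "fasta", "gff",
                                   "pathways", "teHits"))],
        inputs = lapply(
            Filter(Negate(is.null),
                   cfg[c("beds", "sizes", "fasta", "gff", "pathways",
                         "teHits")]),
            function(p) as.list(tools::md5sum(p))))
    jsonlite::write_json(manifest, file.path(cfg$outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(res)
}

#' Plot a TSS distance profile
#'
#' Simple barplot of MAR counts per signed TSS-distance bin.
#'
#' @param profile output of [tssProfile()].
#' @param ... passed to [graphics::barplot()].
#' @return invisibly, the bar midpoints.
#' @export
plotTssProfile <- function(profile, ...) {
    mids <- (profile$bin_start + profile$bin_end) / 2000
    graphics::barplot(profile$count, names.arg = sprintf("%g", mids),
                      xlab = "distance from TSS (kb)", ylab = "MAR count",
                      ...)
}
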