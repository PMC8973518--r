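# round half away from zero, the convention of the published chromosome tables
roundHalfUp <- function(x, digits = 2L) {
    p <- 10^digits
    sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Density arithmetic for a chromosome table
#'
#' Core per-chromosome arithmetic: densities are counts per Mb, the mean
#' chromatin loop proxy is the chromosome span divided between consecutive
#' MARs (see [loopLengths()]). Exposed separately so the arithmetic can be run
#' directly on a published table of counts.
#'
#' @param chrom chromosome names.
#' @param sizeMb chromosome sizes in Mb.
#' @param nGenes gene counts (or `NA`).
#' @param marCount MAR counts.
#' @return data.frame with unrounded `gene_density` and `mar_density`
#'   (per Mb); use [formatChromosomeSummary()] for 2-decimal reporting.
#' @export
densityTable <- function(chrom, sizeMb, nGenes, marCount) {
    stopifnot(all(sizeMb > 0))
    data.frame(chrom = as.character(chrom),
               size_mb = sizeMb,
               n_genes = nGenes,
               gene_density = nGenes / sizeMb,
               mar_count = marCount,
               mar_density = marCount / sizeMb)
}

#' Chromosome-wise MAR statistics
#'
#' One row per chromosome: size, gene count and density (genes/Mb), MAR count
#' and density (MARs/Mb), and the mean inter-MAR distance (the chromatin
#' loop-length proxy, kb; `NA` when fewer than two MARs). Chromosomes present
#' in the size table but without MARs are reported with zero counts.
#' Chromosomes carrying MARs but absent from the size table (unplaced
#' scaffolds) are an error in strict mode; otherwise they are dropped from
#' the per-chromosome table and summarized in the `unplaced` attribute.
#'
#' @param mars a `GRanges` of (merged) MAR peaks.
#' @param chromSizes data.frame with `chrom` and `length_bp`
#'   (see [readChromSizes()]).
#' @param geneModels optional [GeneModelSet-class]; when `NULL`, gene columns
#'   are `NA`.
#' @param loopMethod passed to [loopLengths()].
#' @param strict error on MAR chromosomes missing from `chromSizes`
#'   (default) or warn and skip.
#' @return data.frame (unrounded); attributes `unplaced` (count of skipped
#'   MARs) and `total_mars`.
#' @export
chromosomeSummary <- function(mars, chromSizes, geneModels = NULL,
                              loopMethod = c("midpoint", "gap"),
                              strict = TRUE) {
    loopMethod <- match.arg(loopMethod)
    chr <- as.character(GenomicRanges::seqnames(mars))
    missing <- setdiff(unique(chr), chromSizes$chrom)
    if (length(missing)) {
        if (strict)
            stop("chromosomes present in MAR set but absent from size ",
                 "table: ", paste(missing, collapse = ", "))
        warning("skipping ", sum(chr %in% missing),
                " MARs on chromosomes absent from the size table: ",
                paste(missing, collapse = ", "))
    }
    keep <- !(chr %in% missing)
    marCount <- table(factor(chr[keep], levels = chromSizes$chrom))
    if (!is.null(geneModels)) {
        gchr <- as.character(GenomicRanges::seqnames(genes(geneModels)))
        nGenes <- as.integer(table(factor(gchr, levels = chromSizes$chrom)))
    } else {
        nGenes <- rep(NA_integer_, nrow(chromSizes))
    }
    df <- densityTable(chromSizes$chrom, chromSizes$length_bp / 1e6,
                       nGenes, as.integer(marCount))
    ll <- loopLengths(mars[keep], method = loopMethod)
    df$mean_loop_kb <- ll$per_chromosome$mean_loop_kb[
        match(df$chrom, ll$per_chromosome$chrom)]
    attr(df, "unplaced") <- sum(!keep)
    attr(df, "total_mars") <- length(mars)
    df
}

#' Round a chromosome summary for reporting
#'
#' Densities and loop lengths rounded to 2 decimals, half away from zero,
#' matching the reporting precision of published chromosome-wise MAR tables.
#'
#' @param df output of [chromosomeSummary()] or [densityTable()].
#' @return the data.frame with numeric columns rounded.
#' @export
formatChromosomeSummary <- function(df) {
    for (col in intersect(c("size_mb", "gene_density", "mar_density",
                            "mean_loop_kb"), names(df)))
        df[[col]] <- roundHalfUp(df[[col]], 2L)
    df
}

#' Chromatin loop lengths from inter-MAR distances
#'
#' The distance between consecutive MARs on a chromosome is used as a proxy
#' for the length of the chromatin loop anchored between them. Distances are
#' midpoint-to-midpoint by default, or the bare gap (end to next start).
#' Chromosomes with fewer than two MARs contribute nothing.
#'
#' @param mars a `GRanges`, normalized ([mergePeaks()]).
#' @param method `"midpoint"` (default) or `"gap"`.
#' @param aggregate `"per_chromosome_mean"` (default): the overall average is
#'   the mean of per-chromosome means; `"global_mean"`: the mean over all
#'   inter-MAR distances pooled.
#' @return list with `per_chromosome` (data.frame: `chrom`, `n_mars`,
#'   `n_loops`, `mean_loop_kb`) and `overall_mean_kb`.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
#'     c(1, 201, 401), width = 100))
#' loopLengths(gr)$overall_mean_kb  # 0.2
#' @export
loopLengths <- function(mars, method = c("midpoint", "gap"),
                        aggregate = c("per_chromosome_mean", "global_mean")) {
    method <- match.arg(method)
    aggregate <- match.arg(aggregate)
    mars <- GenomicRanges::sort(mars)
    chr <- as.character(GenomicRanges::seqnames(mars))
    chroms <- unique(chr)
    perChrom <- lapply(chroms, function(cc) {
        s <- GenomicRanges::start(mars)[chr == cc]
        e <- GenomicRanges::end(mars)[chr == cc]
        n <- length(s)
        if (n < 2L)
            return(data.frame(chrom = cc, n_mars = n, n_loops = 0L,
                              mean_loop_kb = NA_real_, sum_bp = 0))
        d <- switch(method,
            midpoint = diff((s + e) / 2),
            gap = s[-1L] - e[-n] - 1)
        data.frame(chrom = cc, n_mars = n, n_loops = n - 1L,
                   mean_loop_kb = mean(d) / 1000, sum_bp = sum(d))
    })
    perChrom <- do.call(rbind, perChrom)
    if (is.null(perChrom))
        perChrom <- data.frame(chrom = character(), n_mars = integer(),
                               n_loops = integer(), mean_loop_kb = numeric(),
                               sum_bp = numeric())
    overall <- switch(aggregate,
        per_chromosome_mean = mean(perChrom$mean_loop_kb, na.rm = TRUE),
        global_mean = sum(perChrom$sum_bp) / max(1L, sum(perChrom$n_loops)) /
            1000)
    if (!sum(perChrom$n_loops)) overall <- NA_real_
    list(per_chromosome = perChrom[, c("chrom", "n_mars", "n_loops",
                                       "mean_loop_kb")],
         overall_mean_kb = overall)
}

#' Correlation between chromosome-level statistics
#'
#' Pearson product-moment correlation between two columns of a chromosome
#' summary (e.g. MAR count vs gene density), with Spearman rank correlation
#' as a secondary statistic.
#'
#' @param stats data.frame from [chromosomeSummary()] or [densityTable()].
#' @param x,y column names.
#' @return list with `pearson_r`, `spearman_rho`, `n`. Both correlations are
#'   `NA` when either column has zero variance.
#' @export
densityCorrelation <- function(stats, x = "mar_count", y = "gene_density") {
    xv <- stats[[x]]; yv <- stats[[y]]
    ok <- stats::complete.cases(xv, yv)
    xv <- xv[ok]; yv <- yv[ok]
    if (length(xv) < 3L)
        stop("need at least 3 chromosomes with complete data")
    if (stats::sd(xv) == 0 || stats::sd(yv) == 0)
        return(list(pearson_r = NA_real_, spearman_rho = NA_real_,
                    n = length(xv)))
    list(pearson_r = stats::cor(xv, yv),
         spearman_rho = stats::cor(xv, yv, method = "spearman"),
         n = length(xv))
}

#' Classify MARs by genomic context
#'
#' Labels each MAR `exonic` if it overlaps any exon by at least 1 bp, else
#' `intronic` if it overlaps any gene body, else `nongenic`
#' (precedence exon > intron > non-genic). The three counts always sum to the
#' number of input MARs.
#'
#' @param mars a `GRanges`.
#' @param geneModels a [GeneModelSet-class].
#' @return list with `labels` (factor, one per MAR) and `counts` (named
#'   integer: `exonic`, `intronic`, `nongenic`).
#' @export
classifyContext <- function(mars, geneModels) {
    ex <- unlist(exons(geneModels), use.names = FALSE)
    exonic <- IRanges::overlapsAny(mars, ex, ignore.strand = TRUE)
    genic <- IRanges::overlapsAny(mars, genes(geneModels),
                                        ignore.strand = TRUE)
    labels <- factor(ifelse(exonic, "exonic",
                     ifelse(genic, "intronic", "nongenic")),
                     levels = c("exonic", "intronic", "nongenic"))
    list(labels = labels, counts = c(table(labels)))
}

#' MAR distance profile around transcription start sites
#'
#' For each MAR, the signed distance from its midpoint to the nearest TSS is
#' computed (strand-aware: positive distances are downstream of the TSS in
#' gene orientation, negative upstream) and binned over
#' `[-window, +window]`. Ties between equidistant TSSs are broken toward the
#' lexicographically smaller gene id for determinism. MARs on chromosomes
#' without any gene are excluded (their count is in the `dropped` attribute).
#'
#' @param mars a `GRanges`.
#' @param geneModels a [GeneModelSet-class]; must contain at least one gene.
#' @param window half-window in bp (default 100000).
#' @param bin bin width in bp; must divide `2 * window`.
#' @return data.frame with `bin_start`, `bin_end` (signed bp, half-open
#'   bins; the final bin includes `+window`) and `count`. Attributes:
#'   `distances` (the signed distances, one per retained MAR), `dropped`.
#' @export
tssProfile <- function(mars, geneModels, window = 100000L, bin = 10000L) {
    stopifnot(window > 0, bin > 0)
    if ((2L * window) %% bin != 0L)
        stop("bin width must divide 2 * window")
    if (!length(genes(geneModels)))
        stop("no genes in the gene-model set")
    t <- tss(geneModels)
    tchr <- as.character(GenomicRanges::seqnames(t))
    tpos <- GenomicRanges::start(t)
    tstr <- as.character(GenomicRanges::strand(t))
    tid <- mcols(t)$gene_id
    mchr <- as.character(GenomicRanges::seqnames(mars))
    mid <- floor((GenomicRanges::start(mars) + GenomicRanges::end(mars)) / 2)
    dist <- rep(NA_real_, length(mars))
    for (cc in unique(mchr)) {
        sel <- which(tchr == cc)
        if (!length(sel)) next
        ord <- order(tpos[sel], tid[sel])
        pos <- tpos[sel][ord]; str <- tstr[sel][ord]; ids <- tid[sel][ord]
        mi <- which(mchr == cc)
        idx <- findInterval(mid[mi], pos)
        lo <- pmax(idx, 1L); hi <- pmin(idx + 1L, length(pos))
        dlo <- abs(mid[mi] - pos[lo]); dhi <- abs(mid[mi] - pos[hi])
        pick <- ifelse(dhi < dlo, hi,
                ifelse(dlo < dhi, lo,
                       # equidistant: smaller gene id wins
                       ifelse(ids[lo] <= ids[hi], lo, hi)))
        signed <- mid[mi] - pos[pick]
        neg <- str[pick] == "-"
        signed[neg] <- -signed[neg]
        dist[mi] <- signed
    }
    dropped <- sum(is.na(dist))
    dist <- dist[!is.na(dist)]
    inWin <- abs(dist) <= window
    d <- dist[inWin]
    edges <- seq(-window, window, by = bin)
    idx <- pmin(findInterval(d, edges), length(edges) - 1L)
    tab <- tabulate(idx, nbins = length(edges) - 1L)
    out <- data.frame(bin_start = edges[-length(edges)],
                      bin_end = edges[-1L],
                      count = tab)
    attr(out, "distances") <- dist
    attr(out, "dropped") <- dropped
    out
}

#' MARs in the flanking window of a gene
#'
#' Restricts each dataset's MAR set to `[gene_start - flank, gene_end +
#' flank]` (clipped at 1) around a gene of interest and, for three datasets,
#' partitions the windowed MARs into common and unique groups.
#'
#' @param marsList named list of three `GRanges` (one per dataset).
#' @param geneModels a [GeneModelSet-class].
#' @param geneId the gene of interest.
#' @param flank flank size in bp (>= 0); `0` keeps only MARs overlapping the
#'   gene body.
#' @param minOverlap passed to [vennPartition()].
#' @return list with `window` (`GRanges`), `mars` (named list of windowed
#'   `GRanges`), `counts` (data.frame: dataset, n_in_window, n_unique),
#'   `n_common` (MARs shared by all three datasets in the window), and
#'   `venn` (the windowed [VennPartition-class]).
#' @export
geneFlankReport <- function(marsList, geneModels, geneId, flank = 800000L,
                            minOverlap = 1L) {
    stopifnot(flank >= 0, length(marsList) == 3L)
    if (is.null(names(marsList)))
        names(marsList) <- paste0("set", seq_along(marsList))
    g <- genes(geneModels)
    hit <- which(mcols(g)$gene_id == geneId)
    if (!length(hit))
        stop("gene not found: ", geneId)
    g <- g[hit[1L]]
    window <- GRanges(GenomicRanges::seqnames(g),
                      IRanges(max(1L, GenomicRanges::start(g) - flank),
                              GenomicRanges::end(g) + flank))
    windowed <- lapply(marsList, function(x)
        IRanges::subsetByOverlaps(mergePeaks(x), window))
    vp <- vennPartition(windowed[[1L]], windowed[[2L]], windowed[[3L]],
                        minOverlap = minOverlap, labels = names(marsList))
    n <- vennCounts(vp)
    counts <- data.frame(dataset = names(marsList),
                         n_in_window = vapply(windowed, length, integer(1)),
                         n_unique = as.integer(n[c("onlyA", "onlyB",
                                                   "onlyC")]))
    list(window = window, mars = windowed, counts = counts,
         n_common = as.integer(n[["ABC"]]), venn = vp)
}

#' Join MAR-associated genes to pathways
#'
#' Counts MAR-associated genes per pathway; a gene mapped to several pathways
#' counts once in each. Genes absent from the mapping are returned as
#' `unmapped`, never dropped silently.
#'
#' @param geneIds character vector of MAR-associated gene ids (duplicates
#'   are collapsed).
#' @param mapping data.frame with columns `gene_id`, `pathway`
#'   (see [readPathwayMap()]).
#' @return list with `counts` (data.frame `pathway`, `n_genes`, sorted
#'   descending) and `unmapped` (character vector).
#' @export
pathwayJoin <- function(geneIds, mapping) {
    if (!nrow(mapping))
        stop("empty pathway mapping")
    geneIds <- unique(as.character(geneIds))
    hit <- mapping[mapping$gene_id %in% geneIds, , drop = FALSE]
    hit <- unique(hit[, c("gene_id", "pathway")])
    tab <- sort(table(hit$pathway), decreasing = TRUE)
    counts <- data.frame(pathway = names(tab), n_genes = as.integer(tab))
    list(counts = counts,
         unmapped = setdiff(geneIds, mapping$gene_id))
}
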