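#' Merge overlapping and bookended peaks
#'
#' Normalizes a peak set: on each chromosome, every maximal run of intervals
#' in which each interval overlaps or directly abuts (bookends) the next is
#' replaced by a single interval spanning the run. The result is sorted and
#' pairwise non-overlapping. Merging is idempotent and preserves the total
#' number of covered bases.
#'
#' @param x a `GRanges` of peaks.
#' @return a merged, sorted `GRanges`; `metadata(x)$label` is carried over.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
#'     c(101, 201, 401), c(200, 300, 500)))
#' mergePeaks(gr)  # chr1:101-300, chr1:401-500
#' @export
mergePeaks <- function(x) {
    lab <- metadata(x)$label
    out <- GenomicRanges::reduce(
        GenomicRanges::sort(GenomicRanges::`strand<-`(x, value = "*")),
        min.gapwidth = 1L)
    metadata(out)$label <- lab
    out
}

#' Seven-region Venn partition of three peak sets
#'
#' Merges the union of three normalized peak sets and assigns each union
#' interval to exactly one of the seven Venn regions according to which input
#' sets it overlaps by at least `minOverlap` bp. A union interval overlapping
#' several intervals of the same input set still counts that set once
#' (presence/absence semantics).
#'
#' @param a,b,c `GRanges` peak sets; they are normalized with [mergePeaks()]
#'   first.
#' @param minOverlap minimum overlap in bp for set membership (default 1).
#' @param labels character(3) dataset labels; defaults to the `metadata`
#'   labels or `c("A","B","C")`.
#' @return a [VennPartition-class].
#' @examples
#' a <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100))
#' b <- GenomicRanges::GRanges("chr1", IRanges::IRanges(51, 150))
#' vennCounts(vennPartition(a, b, GenomicRanges::GRanges()))
#' @export
vennPartition <- function(a, b, c, minOverlap = 1L, labels = NULL) {
    stopifnot(minOverlap >= 1L)
    if (is.null(labels)) {
        labels <- vapply(list(a, b, c), function(x) {
            l <- metadata(x)$label
            if (is.null(l)) NA_character_ else l
        }, character(1))
        labels[is.na(labels)] <- c("A", "B", "C")[is.na(labels)]
    }
    a <- mergePeaks(a); b <- mergePeaks(b); c <- mergePeaks(c)
    un <- mergePeaks(base::c(a, b, c))
    ovbp <- function(un, s) {
        bp <- integer(length(un))
        if (!length(s) || !length(un)) return(bp)
        h <- GenomicRanges::findOverlaps(un, s)
        w <- GenomicRanges::width(IRanges::pintersect(
            un[S4Vectors::queryHits(h)], s[S4Vectors::subjectHits(h)]))
        agg <- tapply(w, S4Vectors::queryHits(h), max)
        bp[as.integer(names(agg))] <- as.integer(agg)
        bp
    }
    bpA <- ovbp(un, a); bpB <- ovbp(un, b); bpC <- ovbp(un, c)
    inA <- bpA >= minOverlap; inB <- bpB >= minOverlap; inC <- bpC >= minOverlap
    # a union interval below threshold everywhere (possible when minOverlap
    # exceeds the width of the inputs that formed it) falls back to the
    # set(s) with maximal overlap, so the seven regions always cover the union
    none <- !(inA | inB | inC)
    if (any(none)) {
        mx <- pmax(bpA, bpB, bpC)
        inA[none] <- bpA[none] == mx[none]
        inB[none] <- bpB[none] == mx[none]
        inC[none] <- bpC[none] == mx[none]
    }
    code <- inA + 2L * inB + 4L * inC
    region <- factor(code, levels = base::c(1L, 2L, 4L, 3L, 5L, 6L, 7L),
                     labels = .VENN_REGIONS)
    parts <- GenomicRanges::split(un, region)
    regions <- methods::as(parts[.VENN_REGIONS], "GRangesList")
    methods::new("VennPartition",
        regions = regions,
        labels = labels,
        minOverlap = as.integer(minOverlap),
        unionSize = length(un))
}

#' @rdname vennCounts
#' @export
setMethod("vennCounts", "VennPartition", function(x) lengths(x@regions))

#' @rdname vennPercentages
#' @export
setMethod("vennPercentages", "VennPartition", function(x) {
    n <- vennCounts(x)
    100 * n / max(1L, x@unionSize)
})

#' @rdname vennRegions
#' @export
setMethod("vennRegions", "VennPartition", function(x) x@regions)

#' @describeIn vennCounts display method
#' @param object a `VennPartition`.
#' @export
setMethod("show", "VennPartition", function(object) {
    cat("VennPartition of", paste(object@labels, collapse = "/"),
        "(min overlap", object@minOverlap, "bp)\n")
    n <- vennCounts(object)
    p <- vennPercentages(object)
    for (r in names(n))
        cat(sprintf("  %-8s %6d  (%5.2f%%)\n", r, n[[r]], p[[r]]))
    cat("  union  ", object@unionSize, "intervals\n")
})

#' Write a Venn partition as TSV and per-region BED files
#'
#' @param x a [VennPartition-class].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return the TSV path, invisibly.
#' @export
writeVennPartition <- function(x, dir, prefix = "venn") {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    df <- data.frame(region = names(vennCounts(x)),
                     count = as.integer(vennCounts(x)),
                     pct_of_union = round(vennPercentages(x), 2))
    tsv <- file.path(dir, paste0(prefix, ".tsv"))
    utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
    for (r in names(x@regions))
        writeBed(x@regions[[r]], file.path(dir, paste0(prefix, "_", r, ".bed")))
    invisible(tsv)
}

#' Histogram of interval lengths
#'
#' Bins interval widths into fixed-width bins `[0,w), [w,2w), ...`. The bin
#' counts always sum to the number of intervals.
#'
#' @param x a `GRanges`.
#' @param binWidth bin width in bp (> 0).
#' @return data.frame with `bin_start`, `bin_end`, `count`; empty for an
#'   empty input.
#' @export
lengthDistribution <- function(x, binWidth = 200L) {
    stopifnot(binWidth > 0)
    if (!length(x))
        return(data.frame(bin_start = integer(), bin_end = integer(),
                          count = integer()))
    w <- GenomicRanges::width(x)
    bin <- w %/% binWidth
    tab <- table(bin)
    idx <- as.integer(names(tab))
    data.frame(bin_start = idx * as.integer(binWidth),
               bin_end = (idx + 1L) * as.integer(binWidth),
               count = as.integer(tab))
}
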