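#' Read a BED file of MAR peaks
#'
#' Reads BED3/BED4/BED5 (tab-separated, no header) into a `GRanges`. BED
#' coordinates are 0-based half-open; they are converted to the 1-based closed
#' convention used throughout the package. Input order is preserved; use
#' [mergePeaks()] to normalize.
#'
#' @param path path to a BED file.
#' @param label dataset label stored in `metadata(x)$label` (default: file
#'   name without extension).
#' @return a [GenomicRanges::GRanges]; columns 4 and 5, when present, become
#'   mcols `name` and `score`.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t400\tpeak1", bed)
#' gr <- readPeakBed(bed)
#' width(gr)  # 300
#' @export
readPeakBed <- function(path, label = NULL) {
    if (!file.exists(path))
        stop("BED file not found: ", path)
    if (is.null(label))
        label <- sub("\\.[^.]*$", "", basename(path))
    lines <- readLines(path)
    keep <- !grepl("^\\s*$|^#|^track|^browser", lines)
    lineno <- which(keep)
    lines <- lines[keep]
    if (!length(lines)) {
        gr <- GRanges()
        metadata(gr)$label <- label
        return(gr)
    }
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 3L))
        stop("malformed BED line ", lineno[which(nf < 3L)[1L]],
             " in ", path, ": fewer than 3 tab-separated fields")
    chrom <- vapply(fields, `[[`, character(1), 1L)
    start0 <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 2L)))
    end0 <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 3L)))
    bad <- which(is.na(start0) | is.na(end0))
    if (length(bad))
        stop("malformed BED line ", lineno[bad[1L]], " in ", path,
             ": non-integer coordinates")
    bad <- which(start0 >= end0 | start0 < 0L)
    if (length(bad))
        stop("malformed BED line ", lineno[bad[1L]], " in ", path,
             ": requires 0 <= start < end")
    gr <- GRanges(chrom, IRanges(start0 + 1L, end0))
    if (all(nf >= 4L))
        mcols(gr)$name <- vapply(fields, `[[`, character(1), 4L)
    if (all(nf >= 5L))
        mcols(gr)$score <- suppressWarnings(
            as.numeric(vapply(fields, `[[`, character(1), 5L)))
    metadata(gr)$label <- label
    gr
}

#' Write intervals as BED
#'
#' Writes a `GRanges` as BED (0-based half-open), with the `name` mcols column
#' as field 4 when present.
#'
#' @param x a `GRanges`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeBed <- function(x, path) {
    df <- data.frame(
        chrom = as.character(GenomicRanges::seqnames(x)),
        start = GenomicRanges::start(x) - 1L,
        end = GenomicRanges::end(x)
    )
    if (!is.null(mcols(x)$name))
        df$name <- mcols(x)$name
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Read a chromosome-size table
#'
#' Two-column tab-separated file: chromosome name, length in bp. No header.
#'
#' @param path path to the TSV.
#' @return data.frame with columns `chrom` (character) and `length_bp`
#'   (integer).
#' @export
readChromSizes <- function(path) {
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            col.names = c("chrom", "length_bp"),
                            colClasses = c("character", "numeric"))
    if (any(is.na(df$length_bp)) || any(df$length_bp <= 0))
        stop("chromosome sizes must be positive integers: ", path)
    df$length_bp <- as.integer(df$length_bp)
    df
}

#' Read gene models from GFF3/GTF
#'
#' Imports `gene` and `exon` features. Exons are attached to genes through
#' their `Parent` attribute (GFF3) or shared `gene_id` (GTF). GFF 1-based
#' closed coordinates map directly onto the package's internal convention.
#'
#' @param path path to a GFF3 or GTF file.
#' @return a [GeneModelSet-class].
#' @export
readGeneModels <- function(path) {
    gff <- rtracklayer::import(path)
    type <- as.character(mcols(gff)$type)
    g <- gff[type == "gene"]
    ex <- gff[type == "exon"]
    gid <- mcols(g)$ID
    if (is.null(gid)) gid <- mcols(g)$gene_id
    if (is.null(gid))
        stop("gene features need an ID (GFF3) or gene_id (GTF) attribute")
    gid <- as.character(gid)
    parent <- mcols(ex)$Parent
    if (!is.null(parent)) {
        if (methods::is(parent, "List"))
            parent <- as.character(unlist(parent))
        else parent <- as.character(parent)
    } else {
        parent <- as.character(mcols(ex)$gene_id)
    }
    if (length(ex) && (is.null(parent) || anyNA(parent)))
        stop("exon features need a Parent (GFF3) or gene_id (GTF) attribute")
    GeneModelSet(
        genes = GRanges(GenomicRanges::seqnames(g), IRanges::ranges(g),
                        strand = GenomicRanges::strand(g), gene_id = gid),
        exons = ex,
        exonGene = parent
    )
}

#' Construct a GeneModelSet
#'
#' @param genes `GRanges` of gene spans with an mcols column `gene_id` (or
#'   pass ids via `geneId`).
#' @param exons `GRanges` of exon ranges (flat), or a `GRangesList` already
#'   named by gene id.
#' @param exonGene character vector assigning each flat exon to a gene id;
#'   ignored when `exons` is a `GRangesList`.
#' @param geneId optional gene ids if `genes` lacks a `gene_id` column.
#' @return a [GeneModelSet-class]; exon ranges are normalized (sorted,
#'   overlaps within a gene reduced).
#' @export
GeneModelSet <- function(genes, exons = GRanges(), exonGene = character(),
                         geneId = NULL) {
    if (!is.null(geneId))
        mcols(genes)$gene_id <- as.character(geneId)
    ids <- as.character(mcols(genes)$gene_id)
    if (methods::is(exons, "GRangesList")) {
        exl <- exons
    } else {
        exl <- GenomicRanges::split(exons, factor(exonGene, levels = ids))
    }
    exl <- exl[ids]
    names(exl) <- ids
    exl <- GenomicRanges::reduce(exl)
    methods::new("GeneModelSet", genes = genes, exons = exl)
}

#' Write a GeneModelSet as GFF3
#'
#' @param x a [GeneModelSet-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGeneModelsGff3 <- function(x, path) {
    g <- genes(x)
    ids <- mcols(g)$gene_id
    mcols(g) <- NULL
    mcols(g)$type <- "gene"
    mcols(g)$ID <- ids
    ex <- unlist(exons(x))
    exParent <- rep(names(exons(x)), lengths(exons(x)))
    mcols(ex) <- NULL
    mcols(ex)$type <- "exon"
    mcols(ex)$Parent <- exParent
    GenomicRanges::strand(ex) <-
        GenomicRanges::strand(g)[match(exParent, ids)]
    all <- c(g, ex)
    mcols(all)$source <- "MARseq"
    rtracklayer::export(all, path, format = "gff3")
    invisible(path)
}

#' Read a tabular alignment-hit file (BLAST outfmt 6 style)
#'
#' Twelve tab-separated columns: qseqid, sseqid, pident, length, mismatch,
#' gapopen, qstart, qend, sstart, send, evalue, bitscore. The query is the
#' transposable-element sequence, the subject the MAR sequence it aligns to.
#'
#' @param path path to the TSV (no header).
#' @return data.frame with the twelve standard columns.
#' @seealso [teHitFilter()]
#' @export
readBlastHits <- function(path) {
    cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
              "qstart", "qend", "sstart", "send", "evalue", "bitscore")
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE)
    if (ncol(df) < 10L)
        stop("expected >= 10 tab-separated columns (blast outfmt 6): ", path)
    names(df)[seq_len(min(ncol(df), 12L))] <- cols[seq_len(min(ncol(df), 12L))]
    df
}

#' Read a gene-to-pathway mapping table
#'
#' @param path TSV with columns `gene_id` and `pathway` (header required).
#' @return data.frame with those two columns.
#' @export
readPathwayMap <- function(path) {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    if (!all(c("gene_id", "pathway") %in% names(df)))
        stop("pathway map must have columns gene_id and pathway: ", path)
    df[, c("gene_id", "pathway")]
}

#' Extract interval sequences from a genome
#'
#' @param genome a [Biostrings::DNAStringSet] (named by chromosome) or a path
#'   to a FASTA file.
#' @param x a `GRanges` of intervals.
#' @return a [Biostrings::DNAStringSet], one sequence per interval, named
#'   `chrom:start-end`.
#' @export
extractSequences <- function(genome, x) {
    if (is.character(genome))
        genome <- Biostrings::readDNAStringSet(genome)
    chr <- as.character(GenomicRanges::seqnames(x))
    missing <- setdiff(unique(chr), names(genome))
    if (length(missing))
        stop("chromosomes absent from genome: ",
             paste(missing, collapse = ", "))
    out <- Biostrings::subseq(genome[chr],
                              start = GenomicRanges::start(x),
                              end = GenomicRanges::end(x))
    names(out) <- sprintf("%s:%d-%d", chr, GenomicRanges::start(x),
                          GenomicRanges::end(x))
    out
}
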