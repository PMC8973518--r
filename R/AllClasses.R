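#' @import methods
#' @importFrom S4Vectors mcols mcols<- DataFrame metadata metadata<-
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges GRangesList
NULL

#' MotifPattern: a degenerate, possibly gapped DNA motif
#'
#' A compiled MAR-associated motif: an ordered set of literal IUPAC segments
#' separated by fixed-length unconstrained gaps. `"TAn_3_TGn_3_CA"` compiles
#' to segments `TA`, `TG`, `CA` with gaps of 3 bp between them (span 12 bp);
#' an inline lower-case `n` inside a segment is the IUPAC wildcard `N`.
#'
#' @slot motifId character(1), e.g. `"m_10"`.
#' @slot category character(1); one of the MAR feature categories
#'   (`ORI`, `TG_rich`, `curved_DNA`, `kinked_DNA`, `mtopoII`, `dtopoII`,
#'   `AT_rich`, `MRS`, or a user label).
#' @slot segments character vector of literal IUPAC segments.
#' @slot gaps integer vector of gap widths (bp); `length(gaps) ==
#'   length(segments) - 1`.
#'
#' @seealso [compilePattern()], [scanMotif()], [marMotifCatalog()]
#' @export
setClass("MotifPattern",
    representation(
        motifId = "character",
        category = "character",
        segments = "character",
        gaps = "integer"
    )
)

setValidity("MotifPattern", function(object) {
    msg <- character()
    if (length(object@segments) < 1L)
        msg <- c(msg, "at least one segment is required")
    if (length(object@gaps) != length(object@segments) - 1L)
        msg <- c(msg, "length(gaps) must be length(segments) - 1")
    if (length(object@gaps) && any(object@gaps < 0L))
        msg <- c(msg, "gap widths must be >= 0")
    bad <- grepl("[^ACGTRYSWKMBDHVN]", object@segments)
    if (any(bad))
        msg <- c(msg, paste0("segment ", which(bad)[1L],
                             " contains a non-IUPAC character"))
    if (length(msg)) msg else TRUE
})

#' VennPartition: seven-way decomposition of three peak sets
#'
#' The merged union of three (normalized) peak sets partitioned into the seven
#' Venn regions: unique to each set, shared by exactly one pair, and common to
#' all three. Region counts always sum to the size of the merged union.
#'
#' @slot regions [GenomicRanges::GRangesList] of length 7, named
#'   `onlyA`, `onlyB`, `onlyC`, `AB_only`, `AC_only`, `BC_only`, `ABC`.
#' @slot labels character(3): the dataset labels behind A, B, C.
#' @slot minOverlap integer(1): minimum overlap (bp) used for membership.
#' @slot unionSize integer(1): number of intervals in the merged union.
#'
#' @seealso [vennPartition()], [vennCounts()], [vennPercentages()]
#' @export
setClass("VennPartition",
    representation(
        regions = "GRangesList",
        labels = "character",
        minOverlap = "integer",
        unionSize = "integer"
    )
)

.VENN_REGIONS <- c("onlyA", "onlyB", "onlyC",
                   "AB_only", "AC_only", "BC_only", "ABC")

setValidity("VennPartition", function(object) {
    msg <- character()
    if (!identical(names(object@regions), .VENN_REGIONS))
        msg <- c(msg, paste("regions must be named",
                            paste(.VENN_REGIONS, collapse = ", ")))
    if (length(object@labels) != 3L)
        msg <- c(msg, "exactly three dataset labels are required")
    if (sum(lengths(object@regions)) != object@unionSize)
        msg <- c(msg, "region counts must sum to the union size")
    if (length(msg)) msg else TRUE
})

#' GeneModelSet: gene spans with exon structure
#'
#' A minimal gene-model container: one range per gene (stranded) plus the exon
#' ranges of each gene. The transcription start site of a gene is its
#' strand-aware 5' end (`start` on `+`, `end` on `-`).
#'
#' @slot genes [GenomicRanges::GRanges] with an mcols column `gene_id`.
#' @slot exons [GenomicRanges::GRangesList] named by `gene_id`; exon ranges
#'   lie within their gene span and are non-overlapping after normalization.
#'
#' @seealso [readGeneModels()], [tss()], [classifyContext()]
#' @export
setClass("GeneModelSet",
    representation(
        genes = "GRanges",
        exons = "GRangesList"
    )
)

setValidity("GeneModelSet", function(object) {
    msg <- character()
    if (is.null(mcols(object@genes)$gene_id))
        msg <- c(msg, "genes must carry a gene_id mcols column")
    else {
        ids <- mcols(object@genes)$gene_id
        if (anyDuplicated(ids))
            msg <- c(msg, "gene_id values must be unique")
        if (!identical(names(object@exons), as.character(ids)))
            msg <- c(msg, "exons must be named by gene_id, in gene order")
        else if (length(object@genes)) {
            ok <- vapply(seq_along(object@genes), function(i) {
                ex <- object@exons[[i]]
                g <- object@genes[i]
                length(ex) == 0L ||
                    (all(GenomicRanges::start(ex) >= GenomicRanges::start(g)) &&
                     all(GenomicRanges::end(ex) <= GenomicRanges::end(g)))
            }, logical(1))
            if (!all(ok))
                msg <- c(msg, "exons must lie within their gene span")
        }
    }
    if (length(msg)) msg else TRUE
})
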