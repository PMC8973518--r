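#' Venn region counts
#'
#' @param x a [VennPartition-class].
#' @return named integer vector over the seven regions.
#' @export
setGeneric("vennCounts", function(x) standardGeneric("vennCounts"))

#' Venn region percentages of the merged union
#'
#' @param x a [VennPartition-class].
#' @return named numeric vector: each region as a percentage of the union.
#' @export
setGeneric("vennPercentages", function(x) standardGeneric("vennPercentages"))

#' Venn region interval lists
#'
#' @param x a [VennPartition-class].
#' @return the [GenomicRanges::GRangesList] of the seven regions.
#' @export
setGeneric("vennRegions", function(x) standardGeneric("vennRegions"))

#' Gene ranges of a gene-model set
#'
#' @param x a [GeneModelSet-class].
#' @return [GenomicRanges::GRanges] of gene spans (mcols column `gene_id`).
#' @export
setGeneric("genes", function(x) standardGeneric("genes"))

#' Exon ranges of a gene-model set
#'
#' @param x a [GeneModelSet-class].
#' @return [GenomicRanges::GRangesList] named by gene id.
#' @export
setGeneric("exons", function(x) standardGeneric("exons"))

#' Transcription start sites
#'
#' The strand-aware 5' end of each gene as a width-1 range.
#'
#' @param x a [GeneModelSet-class].
#' @return [GenomicRanges::GRanges] of width 1, one per gene.
#' @export
setGeneric("tss", function(x) standardGeneric("tss"))

#' Total span of a motif pattern
#'
#' Sum of segment lengths plus gap widths: the length of any match.
#'
#' @param x a [MotifPattern-class].
#' @return integer(1).
#' @export
setGeneric("motifSpan", function(x) standardGeneric("motifSpan"))

#' Render a motif pattern back to its compact notation
#'
#' Inverse of [compilePattern()]: segments joined by `n_<k>_` gap tokens.
#'
#' @param x a [MotifPattern-class].
#' @return character(1).
#' @export
setGeneric("renderPattern", function(x) standardGeneric("renderPattern"))
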