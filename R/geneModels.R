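#' @rdname genes
#' @export
setMethod("genes", "GeneModelSet", function(x) x@genes)

#' @rdname exons
#' @export
setMethod("exons", "GeneModelSet", function(x) x@exons)

#' @rdname tss
#' @export
setMethod("tss", "GeneModelSet", function(x) {
    out <- GenomicRanges::resize(x@genes, width = 1L, fix = "start")
    mcols(out) <- DataFrame(gene_id = mcols(x@genes)$gene_id)
    out
})

#' @describeIn genes display method
#' @param object a `GeneModelSet`.
#' @export
setMethod("show", "GeneModelSet", function(object) {
    cat("GeneModelSet with", length(object@genes), "genes and",
        sum(lengths(object@exons)), "exons on",
        length(unique(as.character(
            GenomicRanges::seqnames(object@genes)))), "sequences\n")
})

#' @describeIn genes number of genes
#' @param x a `GeneModelSet`.
#' @export
setMethod("length", "GeneModelSet", function(x) length(x@genes))
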