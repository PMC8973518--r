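# Bitwise IUPAC encoding. A/C/G/T are one bit each; degenerate pattern codes
# are unions. A base N in the *input* sequence gets its own bit (16) so that
# it is matched by pattern N (31 = 15 | 16) and by nothing else: masked
# positions never inflate counts for AT-rich or other degenerate motifs.
.IUPAC_PATTERN_BITS <- c(
    A = 1L, C = 2L, G = 4L, T = 8L,
    R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
    B = 14L, D = 13L, H = 11L, V = 7L, N = 31L)

.IUPAC_SEQ_BITS <- c(A = 1L, C = 2L, G = 4L, T = 8L, N = 16L)

.encodeSeq <- function(x) {
    chars <- strsplit(toupper(as.character(x)), "", fixed = TRUE)[[1L]]
    codes <- unname(.IUPAC_SEQ_BITS[chars])
    if (anyNA(codes))
        stop("sequence contains characters outside {A,C,G,T,N}: ",
             paste(unique(chars[is.na(codes)]), collapse = ", "))
    codes
}

# expand a pattern into per-position (offset, code) pairs; gaps unchecked
.patternOffsets <- function(p) {
    offs <- integer(0); codes <- integer(0); cursor <- 0L
    for (i in seq_along(p@segments)) {
        seg <- strsplit(p@segments[i], "", fixed = TRUE)[[1L]]
        offs <- c(offs, cursor + seq_along(seg) - 1L)
        codes <- c(codes, unname(.IUPAC_PATTERN_BITS[seg]))
        cursor <- cursor + length(seg)
        if (i < length(p@segments))
            cursor <- cursor + p@gaps[i]
    }
    list(offsets = offs, codes = codes)
}

#' Compile a motif from compact gapped-IUPAC notation
#'
#' Parses the compact notation used for MAR-associated motif catalogs:
#' literal IUPAC segments separated by `n_<k>_` tokens denoting fixed gaps of
#' `k` unconstrained bases. A lower-case `n` inside a segment is the IUPAC
#' wildcard `N`; case and spaces are otherwise ignored.
#'
#' @param spec pattern string, e.g. `"TAn_3_TGn_3_CA"` or `"WWWWWW"`.
#' @param motifId identifier stored in hits (default: the spec itself).
#' @param category motif category label.
#' @return a [MotifPattern-class].
#' @examples
#' p <- compilePattern("AAAAn_7_AAAAn_7_AAAA")
#' motifSpan(p)  # 26
#' renderPattern(p)
#' @export
compilePattern <- function(spec, motifId = spec, category = "user") {
    s <- gsub(" ", "", spec, fixed = TRUE)
    m <- gregexpr("n_([0-9]+)_", s)[[1L]]
    if (m[1L] == -1L) {
        segments <- s
        gaps <- integer(0)
    } else {
        starts <- as.integer(m)
        lens <- attr(m, "match.length")
        gaps <- as.integer(gsub("[n_]", "", regmatches(s, list(m))[[1L]]))
        segStart <- c(1L, starts + lens)
        segEnd <- c(starts - 1L, nchar(s))
        segments <- substring(s, segStart, segEnd)
        if (any(!nzchar(segments)))
            stop("malformed pattern '", spec,
                 "': empty segment next to a gap token")
    }
    segments <- toupper(segments)
    bad <- regmatches(segments, regexpr("[^ACGTRYSWKMBDHVN]", segments))
    bad <- unlist(bad)
    if (length(bad))
        stop("unknown character '", bad[1L], "' in pattern '", spec, "'")
    methods::new("MotifPattern", motifId = motifId, category = category,
                 segments = segments, gaps = gaps)
}

#' @rdname motifSpan
#' @export
setMethod("motifSpan", "MotifPattern", function(x)
    sum(nchar(x@segments)) + sum(x@gaps))

#' @rdname renderPattern
#' @export
setMethod("renderPattern", "MotifPattern", function(x) {
    if (!length(x@gaps)) return(x@segments)
    paste0(paste0(x@segments[-length(x@segments)],
                  sprintf("n_%d_", x@gaps), collapse = ""),
           x@segments[length(x@segments)])
})

#' @describeIn compilePattern display method
#' @param object a `MotifPattern`.
#' @export
setMethod("show", "MotifPattern", function(object) {
    cat("MotifPattern", object@motifId, sprintf("[%s]", object@category),
        renderPattern(object), sprintf("(span %d bp)\n", motifSpan(object)))
})

#' Accessor for motif metadata
#' @param x a `MotifPattern`.
#' @return character(1).
#' @export
motifId <- function(x) x@motifId

#' @rdname motifId
#' @export
motifCategory <- function(x) x@category

#' The built-in MAR-associated motif catalog
#'
#' Eighteen MAR-associated DNA motifs reported in the silkworm nuclear-matrix
#' literature: origin-of-replication (ORI) signals, TG-rich signals, curved-
#' and kinked-DNA signals, vertebrate and *Drosophila* topoisomerase II
#' consensus sites, and the AT-rich hexamer. The bipartite MAR recognition
#' signature is handled separately by [scanMRS()].
#'
#' @param file optional TSV overriding the catalog (columns `motif_id`,
#'   `category`, `spec`, header required).
#' @return a named list of [MotifPattern-class] objects.
#' @export
marMotifCatalog <- function(file = NULL) {
    if (!is.null(file)) {
        tab <- utils::read.table(file, sep = "\t", header = TRUE,
                                 stringsAsFactors = FALSE)
        stopifnot(all(c("motif_id", "category", "spec") %in% names(tab)))
    } else {
        tab <- .MAR_MOTIF_TABLE
    }
    pats <- mapply(compilePattern, tab$spec, tab$motif_id, tab$category,
                   SIMPLIFY = FALSE)
    names(pats) <- tab$motif_id
    pats
}

.MAR_MOTIF_TABLE <- data.frame(
    motif_id = paste0("m_", 1:18),
    category = c(rep("ORI", 3), rep("TG_rich", 3), rep("curved_DNA", 3),
                 rep("kinked_DNA", 6), "mtopoII", "dtopoII", "AT_rich"),
    spec = c("ATTA", "ATTTA", "ATTTTA",
             "TGTTTTG", "TGTTTTTTG", "TTTTGGGG",
             "AAAAn_7_AAAAn_7_AAAA", "TTTTn_7_TTTTn_7_TTTT", "TTTAAA",
             "TAn_3_TGn_3_CA", "TAn_3_CAn_3_TG", "TGn_3_TAn_3_CA",
             "TGn_3_CAn_3_TA", "CAn_3_TAn_3_TG", "CAn_3_TGn_3_TA",
             "RnYnnCnnGYnGKTnYnY", "GTnWAYATTnATnnR",
             "WWWWWW"),
    stringsAsFactors = FALSE)

#' Shorter topoisomerase II consensus variant
#'
#' A 15-position variant of the vertebrate topoisomerase II consensus that
#' circulates alongside the canonical 18-position form shipped as `m_16`;
#' compile it with [compilePattern()] if needed.
#' @format character(1).
#' @export
TOPOII_SHORT_VARIANT <- "RnYnnGYnGKTnYnY"

# match starts of a compiled pattern on one encoded sequence (forward only)
.scanEncoded <- function(enc, po, span) {
    L <- length(enc)
    n <- L - span + 1L
    if (n < 1L) return(integer(0))
    ok <- rep(TRUE, n)
    starts <- seq_len(n)
    for (j in seq_along(po$offsets)) {
        ok <- ok & bitwAnd(enc[starts + po$offsets[j]], po$codes[j]) > 0L
        if (!any(ok)) return(integer(0))
    }
    starts[ok]
}

.revcompChar <- function(x)
    chartr("ACGTN", "TGCAN", paste(rev(strsplit(toupper(x), "",
        fixed = TRUE)[[1L]]), collapse = ""))

#' Scan sequences for a degenerate gapped motif
#'
#' Reports every start position where all pattern segments match at their
#' offsets under IUPAC-degenerate equality; overlapping hits are all
#' reported. With `strands = "both"`, the reverse complement of each sequence
#' is also scanned and hits are mapped back to forward coordinates. A base
#' `N` in the sequence is matched only by pattern position `N`.
#'
#' @param seqs a [Biostrings::DNAStringSet], named character vector, or a
#'   single string.
#' @param pattern a [MotifPattern-class] (or a spec string, compiled on the
#'   fly).
#' @param strands `"forward"` (default) or `"both"`.
#' @return a `GRanges` (seqnames = sequence names, 1-based closed
#'   coordinates) with mcols `motif_id`; each hit has width equal to the
#'   pattern span.
#' @examples
#' scanMotif("GATTACA", "ATTA")  # one hit at 2..5
#' @export
scanMotif <- function(seqs, pattern, strands = c("forward", "both")) {
    strands <- match.arg(strands)
    if (is.character(pattern))
        pattern <- compilePattern(pattern)
    seqs <- .asCharSeqs(seqs)
    po <- .patternOffsets(pattern)
    span <- motifSpan(pattern)
    hits <- lapply(seq_along(seqs), function(i) {
        x <- seqs[[i]]
        enc <- .encodeSeq(x)
        L <- length(enc)
        sF <- .scanEncoded(enc, po, span)
        out <- data.frame(seq = rep(names(seqs)[i], length(sF)),
                          start = sF, strand = rep("+", length(sF)))
        if (strands == "both") {
            encR <- .encodeSeq(.revcompChar(x))
            sR <- .scanEncoded(encR, po, span)
            if (length(sR)) {
                fwd <- L - (sR + span - 1L) + 1L
                out <- rbind(out, data.frame(seq = names(seqs)[i],
                                             start = fwd,
                                             strand = "-"))
            }
        }
        out
    })
    hits <- do.call(rbind, hits)
    if (is.null(hits) || !nrow(hits)) {
        gr <- GRanges()
        mcols(gr)$motif_id <- character(0)
        return(gr)
    }
    gr <- GRanges(hits$seq, IRanges(hits$start, width = span),
                  strand = hits$strand)
    mcols(gr)$motif_id <- pattern@motifId
    GenomicRanges::sort(gr, ignore.strand = TRUE)
}

.asCharSeqs <- function(seqs) {
    if (methods::is(seqs, "XStringSet"))
        seqs <- as.character(seqs)
    if (methods::is(seqs, "XString"))
        seqs <- as.character(seqs)
    seqs <- as.character(seqs)
    if (is.null(names(seqs)) && length(seqs))
        names(seqs) <- if (length(seqs) == 1L) "seq" else
            paste0("seq", seq_along(seqs))
    seqs
}

#' The MAR recognition signature (MRS) element sequences
#'
#' The bipartite MRS consists of an 8-mer (`AATAAYAA`) and a 16-mer
#' (`AWWRTAANNWWGNNNC`) occurring within 200 bp of each other.
#' @format character vectors of length 1.
#' @export
MRS_8MER <- "AATAAYAA"

#' @rdname MRS_8MER
#' @export
MRS_16MER <- "AWWRTAANNWWGNNNC"

#' Scan for the bipartite MAR recognition signature
#'
#' Finds all pairs of an 8-mer (`AATAAYAA`) element and a 16-mer
#' (`AWWRTAANNWWGNNNC`) element whose separation (bases between the two
#' elements; 0 when they overlap or abut) is at most `window` bp. Either
#' element may come first, elements may overlap, and by default both strands
#' are searched for each element (pairs are deduplicated on the two start
#' positions).
#'
#' @param seqs sequences as in [scanMotif()].
#' @param window maximum separation in bp (default 200).
#' @param strands `"both"` (default) or `"forward"`.
#' @return data.frame with `seq`, `pos8`, `strand8`, `pos16`, `strand16`,
#'   `separation` (one row per deduplicated pair).
#' @export
scanMRS <- function(seqs, window = 200L, strands = c("both", "forward")) {
    strands <- match.arg(strands)
    stopifnot(window > 0)
    p8 <- compilePattern(MRS_8MER, "MRS_8", "MRS")
    p16 <- compilePattern(MRS_16MER, "MRS_16", "MRS")
    h8 <- scanMotif(seqs, p8, strands)
    h16 <- scanMotif(seqs, p16, strands)
    empty <- data.frame(seq = character(), pos8 = integer(),
                        strand8 = character(), pos16 = integer(),
                        strand16 = character(), separation = integer())
    if (!length(h8) || !length(h16)) return(empty)
    out <- lapply(intersect(unique(as.character(GenomicRanges::seqnames(h8))),
                            unique(as.character(GenomicRanges::seqnames(h16)))),
        function(sq) {
            a <- h8[GenomicRanges::seqnames(h8) == sq]
            b <- h16[GenomicRanges::seqnames(h16) == sq]
            g <- expand.grid(i = seq_along(a), j = seq_along(b))
            s8 <- GenomicRanges::start(a)[g$i]; e8 <- GenomicRanges::end(a)[g$i]
            s16 <- GenomicRanges::start(b)[g$j]; e16 <- GenomicRanges::end(b)[g$j]
            sep <- pmax(0L, pmax(s8, s16) - pmin(e8, e16) - 1L)
            keep <- sep <= window
            if (!any(keep)) return(NULL)
            df <- data.frame(seq = sq,
                             pos8 = s8[keep],
                             strand8 = as.character(
                                 GenomicRanges::strand(a))[g$i[keep]],
                             pos16 = s16[keep],
                             strand16 = as.character(
                                 GenomicRanges::strand(b))[g$j[keep]],
                             separation = sep[keep])
            df[!duplicated(df[, c("pos8", "pos16")]), , drop = FALSE]
        })
    out <- do.call(rbind, out)
    if (is.null(out)) empty else {
        rownames(out) <- NULL
        out[order(out$seq, out$pos8, out$pos16), , drop = FALSE]
    }
}

#' Motif hit counts and percentage abundance over MAR sequences
#'
#' For each motif of a catalog: the total hit count (distinct
#' (motif, start, strand) triples over all sequences) and the presence
#' percentage, i.e. the percentage of sequences containing at least one hit.
#' Category-level abundance is the percentage of sequences containing at
#' least one hit of *any* motif in the category. When `mrs = TRUE`, the
#' bipartite MRS is included as its own category (presence = at least one
#' qualifying pair; hits = number of deduplicated pairs).
#'
#' @param seqs sequences as in [scanMotif()]; must be non-empty.
#' @param catalog list of [MotifPattern-class] (default
#'   [marMotifCatalog()]).
#' @param strands passed to [scanMotif()].
#' @param mrs include the MRS scan (default TRUE).
#' @param mrsWindow passed to [scanMRS()].
#' @return list with `per_motif` (data.frame: `motif_id`, `category`,
#'   `n_hits`, `n_seqs_with_hit`, `presence_pct`) and `per_category`
#'   (data.frame: `category`, `n_seqs_with_hit`, `presence_pct`).
#' @export
motifAbundance <- function(seqs, catalog = marMotifCatalog(),
                           strands = c("forward", "both"), mrs = TRUE,
                           mrsWindow = 200L) {
    strands <- match.arg(strands)
    seqs <- .asCharSeqs(seqs)
    if (!length(seqs))
        stop("empty sequence collection")
    if (!length(catalog))
        stop("empty motif catalog")
    nseq <- length(seqs)
    hitsList <- lapply(catalog, function(p) scanMotif(seqs, p, strands))
    seqsWith <- lapply(hitsList, function(h)
        unique(as.character(GenomicRanges::seqnames(h))))
    perMotif <- Map(function(p, h, sw) {
        data.frame(motif_id = p@motifId, category = p@category,
                   n_hits = length(h), n_seqs_with_hit = length(sw),
                   presence_pct = 100 * length(sw) / nseq)
    }, catalog, hitsList, seqsWith)
    perMotif <- do.call(rbind, c(perMotif, list(make.row.names = FALSE)))
    cats <- split(seqsWith, vapply(catalog, motifCategory, character(1)))
    perCat <- data.frame(
        category = names(cats),
        n_seqs_with_hit = vapply(cats, function(x)
            length(unique(unlist(x))), integer(1)))
    if (mrs) {
        mh <- scanMRS(seqs, window = mrsWindow,
                      strands = if (strands == "both") "both" else "forward")
        withHit <- length(unique(mh$seq))
        perMotif <- rbind(perMotif, data.frame(
            motif_id = "MRS", category = "MRS", n_hits = nrow(mh),
            n_seqs_with_hit = withHit, presence_pct = 100 * withHit / nseq))
        perCat <- rbind(perCat, data.frame(category = "MRS",
                                           n_seqs_with_hit = withHit))
    }
    perCat$presence_pct <- 100 * perCat$n_seqs_with_hit / nseq
    rownames(perCat) <- NULL
    list(per_motif = perMotif, per_category = perCat)
}
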