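# smallest d < k dividing k such that unit is a tandem of its d-prefix;
# k itself when the unit is atomic
.minTandemPeriod <- function(unit) {
    k <- nchar(unit)
    for (d in seq_len(k - 1L)) {
        if (k %% d != 0L) next
        if (unit == strrep(substr(unit, 1L, d), k %/% d)) return(d)
    }
    k
}

.findSSRsOne <- function(x, seqid, minReps, unitSizes, maxInterruption) {
    chars <- strsplit(toupper(x), "", fixed = TRUE)[[1L]]
    L <- length(chars)
    simple <- list()
    for (k in sort(unitSizes)) {
        if (L < k * minReps) next
        eq <- chars[seq_len(L - k)] == chars[(k + 1L):L]
        r <- rle(eq)
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1L
        idx <- which(r$values & r$lengths >= k * (minReps - 1L))
        prevEnd <- 0L
        for (i in idx) {
            s <- starts[i]; m <- r$lengths[i]
            if (s <= prevEnd) {          # greedy left-to-right, no overlap
                shift <- prevEnd + 1L - s
                s <- s + shift; m <- m - shift
            }
            n <- (m + k) %/% k
            if (n < minReps) next
            e <- s + n * k - 1L
            unit <- paste(chars[s:(s + k - 1L)], collapse = "")
            prevEnd <- e
            if (.minTandemPeriod(unit) < k) next  # reported at smaller size
            simple[[length(simple) + 1L]] <- data.frame(
                seqid = seqid, unit = unit, unit_size = k, n_reps = n,
                start = s, end = e, kind = "simple", members = NA_character_,
                stringsAsFactors = FALSE)
        }
    }
    simple <- do.call(rbind, simple)
    if (is.null(simple)) return(NULL)
    simple <- simple[order(simple$start, simple$unit_size), , drop = FALSE]
    # group simple SSRs separated by <= maxInterruption into compound records
    if (nrow(simple) > 1L) {
        spacer <- simple$start[-1L] - simple$end[-nrow(simple)] - 1L
        grp <- cumsum(c(0L, as.integer(spacer > maxInterruption)))
        comp <- lapply(split(seq_len(nrow(simple)), grp), function(ii) {
            if (length(ii) < 2L) return(NULL)
            mem <- simple[ii, ]
            data.frame(seqid = seqid,
                       unit = paste(mem$unit, collapse = "-"),
                       unit_size = NA_integer_, n_reps = NA_integer_,
                       start = min(mem$start), end = max(mem$end),
                       kind = "compound",
                       members = paste(sprintf("(%s)%d", mem$unit,
                                               mem$n_reps), collapse = ";"),
                       stringsAsFactors = FALSE)
        })
        simple <- rbind(simple, do.call(rbind, comp))
    }
    rownames(simple) <- NULL
    simple
}

#' Detect simple sequence repeats (MISA-style)
#'
#' Finds all maximal perfect tandem runs of units of the allowed sizes with
#' at least `minReps` copies, scanning greedily left to right so that
#' reported spans of the same unit size never overlap. A run whose unit is
#' itself a tandem of a smaller unit (e.g. `ATAT` = `(AT)2`) is reported at
#' the smallest unit size only; mononucleotide runs are excluded unless `1`
#' is added to `unitSizes`. Simple SSRs separated by at most
#' `maxInterruption` bp are additionally grouped into compound records.
#'
#' @param seqs sequences as in [scanMotif()].
#' @param minReps minimum number of tandem copies (default 5, the standard
#'   microsatellite-discovery setting).
#' @param unitSizes allowed unit sizes (default 2:6).
#' @param maxInterruption maximum spacer between members of a compound SSR
#'   (default 100 bp).
#' @return data.frame with `seqid`, `unit` (as found, no rotation or
#'   reverse-complement collapsing), `unit_size`, `n_reps`, `start`, `end`
#'   (1-based closed, within the sequence), `kind` (`simple`/`compound`),
#'   `members` (compound only).
#' @examples
#' findSSRs(paste0("GG", strrep("TTAGG", 5), "CC"))
#' @export
findSSRs <- function(seqs, minReps = 5L, unitSizes = 2:6,
                     maxInterruption = 100L) {
    stopifnot(minReps >= 2L, all(unitSizes >= 1L))
    seqs <- .asCharSeqs(seqs)
    out <- do.call(rbind, lapply(seq_along(seqs), function(i)
        .findSSRsOne(seqs[[i]], names(seqs)[i], as.integer(minReps),
                     as.integer(unitSizes), as.integer(maxInterruption))))
    if (is.null(out))
        out <- data.frame(seqid = character(), unit = character(),
                          unit_size = integer(), n_reps = integer(),
                          start = integer(), end = integer(),
                          kind = character(), members = character())
    out
}

#' Summarize SSR occurrences per unit
#'
#' Occurrence count of each distinct repeat unit, partitioned by unit size
#' and sorted descending within each size. Members of compound SSRs are the
#' simple records themselves, so they are counted individually; compound
#' records are not double-counted.
#'
#' @param records output of [findSSRs()].
#' @return data.frame with `unit_size`, `unit`, `count`.
#' @export
ssrClassSummary <- function(records) {
    simple <- records[records$kind == "simple", , drop = FALSE]
    if (!nrow(simple))
        return(data.frame(unit_size = integer(), unit = character(),
                          count = integer()))
    tab <- stats::aggregate(list(count = simple$unit),
                            by = list(unit_size = simple$unit_size,
                                      unit = simple$unit), FUN = length)
    tab <- tab[order(tab$unit_size, -tab$count, tab$unit), , drop = FALSE]
    rownames(tab) <- NULL
    tab
}

#' Filter transposable-element alignment hits
#'
#' Retains hits meeting both thresholds (boundary values are retained:
#' exactly `minIdentity` percent and exactly `minLength` bp pass) and sums,
#' per TE, the bases occupied on the TE query after merging overlapping
#' query spans. Raising either threshold can only shrink the retained set.
#'
#' @param hits data.frame of alignment hits (see [readBlastHits()]); needs
#'   columns `qseqid` (TE name), `pident`, `length`, `qstart`, `qend`.
#' @param minIdentity minimum percent identity (default 90).
#' @param minLength minimum alignment length in bp (default 100).
#' @return list with `hits` (the retained rows) and `occupancy` (data.frame
#'   `te_name`, `n_hits`, `occupied_bp`).
#' @export
teHitFilter <- function(hits, minIdentity = 90, minLength = 100L) {
    need <- c("qseqid", "pident", "length", "qstart", "qend")
    if (!all(need %in% names(hits)))
        stop("hit table must have columns: ", paste(need, collapse = ", "))
    keep <- hits$pident >= minIdentity & hits$length >= minLength
    kept <- hits[keep, , drop = FALSE]
    if (nrow(kept)) {
        occ <- lapply(split(kept, kept$qseqid), function(h) {
            ir <- IRanges::reduce(IRanges(pmin(h$qstart, h$qend),
                                          pmax(h$qstart, h$qend)))
            data.frame(te_name = h$qseqid[1L], n_hits = nrow(h),
                       occupied_bp = sum(IRanges::width(ir)))
        })
        occ <- do.call(rbind, c(occ, list(make.row.names = FALSE)))
    } else {
        occ <- data.frame(te_name = character(), n_hits = integer(),
                          occupied_bp = integer())
    }
    list(hits = kept, occupancy = occ)
}

#' Write SSR records as GFF3
#'
#' @param records output of [findSSRs()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSSRGff3 <- function(records, path) {
    if (!nrow(records)) {
        writeLines("##gff-version 3", path)
        return(invisible(path))
    }
    gr <- GRanges(records$seqid, IRanges(records$start, records$end))
    mcols(gr)$type <- ifelse(records$kind == "compound",
                             "compound_microsatellite", "microsatellite")
    mcols(gr)$source <- "MARseq"
    mcols(gr)$Name <- ifelse(records$kind == "compound", records$members,
                             sprintf("(%s)%d", records$unit, records$n_reps))
    rtracklayer::export(gr, path, format = "gff3")
    invisible(path)
}
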