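# Independent oracles used across the suite. They share nothing with the
# package implementation beyond the input notation they must accept.

library(GenomicRanges)

randomSeq <- function(n, probs = c(A = .25, C = .25, G = .25, T = .25)) {
    paste(sample(names(probs), n, replace = TRUE, prob = probs),
          collapse = "")
}

revcomp <- function(x)
    chartr("ACGTN", "TGCAN",
           paste(rev(strsplit(x, "", fixed = TRUE)[[1]]), collapse = ""))

# ---- motif oracle: compact notation -> PCRE with overlap lookahead ----

.iupacClass <- c(A = "A", C = "C", G = "G", T = "T",
                 R = "[AG]", Y = "[CT]", S = "[CG]", W = "[AT]",
                 K = "[GT]", M = "[AC]", B = "[CGT]", D = "[AGT]",
                 H = "[ACT]", V = "[ACG]", N = "[ACGT]")

oracleMotifRegex <- function(spec) {
    s <- gsub(" ", "", spec)
    toks <- regmatches(s, gregexpr("n_[0-9]+_|.", s, perl = TRUE))[[1]]
    body <- vapply(toks, function(t) {
        if (grepl("^n_[0-9]+_$", t))
            sprintf(".{%s}", gsub("\\D", "", t))
        else .iupacClass[[toupper(t)]]
    }, character(1))
    paste(body, collapse = "")
}

# all (overlapping) forward match starts, 1-based
oracleMotifStarts <- function(seq, spec) {
    re <- paste0("(?=", oracleMotifRegex(spec), ")")
    m <- gregexpr(re, seq, perl = TRUE)[[1]]
    if (m[1] == -1L) integer(0) else as.integer(m)
}

oracleMotifSpan <- function(spec) {
    s <- gsub(" ", "", spec)
    gaps <- regmatches(s, gregexpr("n_[0-9]+_", s))[[1]]
    nchar(gsub("n_[0-9]+_", "", s)) +
        sum(as.integer(gsub("\\D", "", gaps)))
}

# both-strand starts in forward coordinates, as (start, strand) data.frame
oracleMotifStartsBoth <- function(seq, spec) {
    span <- oracleMotifSpan(spec)
    f <- oracleMotifStarts(seq, spec)
    r <- oracleMotifStarts(revcomp(seq), spec)
    rbind(data.frame(start = f, strand = rep("+", length(f))),
          data.frame(start = nchar(seq) - (r + span - 1L) + 1L,
                     strand = rep("-", length(r))))
}

# ---- MRS oracle: pair the two element hit lists directly ----

oracleMRSPairs <- function(seq, window = 200L) {
    h8 <- oracleMotifStartsBoth(seq, "AATAAYAA")
    h16 <- oracleMotifStartsBoth(seq, "AWWRTAANNWWGNNNC")
    if (!nrow(h8) || !nrow(h16))
        return(data.frame(pos8 = integer(), pos16 = integer()))
    g <- expand.grid(i = seq_len(nrow(h8)), j = seq_len(nrow(h16)))
    s8 <- h8$start[g$i]; e8 <- s8 + 7L
    s16 <- h16$start[g$j]; e16 <- s16 + 15L
    sep <- pmax(0L, pmax(s8, s16) - pmin(e8, e16) - 1L)
    keep <- sep <= window
    df <- unique(data.frame(pos8 = s8[keep], pos16 = s16[keep]))
    df[order(df$pos8, df$pos16), , drop = FALSE]
}

# ---- SSR oracle: greedy backreference regex per unit size ----

.oracleAtomic <- function(unit) {
    k <- nchar(unit)
    for (d in seq_len(k - 1L)) {
        if (k %% d) next
        if (unit == strrep(substr(unit, 1L, d), k %/% d)) return(FALSE)
    }
    TRUE
}

oracleSSRs <- function(seq, minReps = 5L, unitSizes = 2:6) {
    out <- list()
    for (k in sort(unitSizes)) {
        re <- sprintf("([ACGT]{%d})\\1{%d,}", k, minReps - 1L)
        m <- gregexpr(re, seq, perl = TRUE)[[1]]
        if (m[1] == -1L) next
        len <- attr(m, "match.length")
        for (i in seq_along(m)) {
            s <- as.integer(m[i])
            n <- len[i] %/% k
            unit <- substr(seq, s, s + k - 1L)
            if (!.oracleAtomic(unit)) next
            out[[length(out) + 1L]] <- data.frame(
                unit = unit, unit_size = k, n_reps = n,
                start = s, end = s + n * k - 1L)
        }
    }
    out <- do.call(rbind, out)
    if (is.null(out))
        data.frame(unit = character(), unit_size = integer(),
                   n_reps = integer(), start = integer(), end = integer())
    else out[order(out$unit_size, out$start), , drop = FALSE]
}

# ---- interval oracles: per-base occupancy masks ----

coverageMask <- function(gr, chromLen, chrom) {
    mask <- logical(chromLen)
    sel <- as.character(GenomicRanges::seqnames(gr)) == chrom
    for (i in which(sel))
        mask[GenomicRanges::start(gr)[i]:GenomicRanges::end(gr)[i]] <- TRUE
    mask
}

maskToIntervals <- function(mask) {
    r <- rle(mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    data.frame(start = starts[r$values], end = ends[r$values])
}

oracleMerge <- function(gr, chromLens) {
    out <- lapply(names(chromLens), function(cc) {
        iv <- maskToIntervals(coverageMask(gr, chromLens[[cc]], cc))
        if (nrow(iv)) cbind(chrom = cc, iv)
    })
    do.call(rbind, out)
}

# brute-force 7-region assignment of union components by per-base masks
oracleVennCounts <- function(a, b, c, chromLens, minOverlap = 1L) {
    counts <- setNames(integer(7),
                       c("onlyA", "onlyB", "onlyC", "AB_only", "AC_only",
                         "BC_only", "ABC"))
    for (cc in names(chromLens)) {
        L <- chromLens[[cc]]
        mA <- coverageMask(a, L, cc); mB <- coverageMask(b, L, cc)
        mC <- coverageMask(c, L, cc)
        comp <- maskToIntervals(mA | mB | mC)
        for (i in seq_len(nrow(comp))) {
            span <- comp$start[i]:comp$end[i]
            inA <- sum(mA[span]) >= minOverlap
            inB <- sum(mB[span]) >= minOverlap
            inC <- sum(mC[span]) >= minOverlap
            key <- paste0(ifelse(inA, "A", ""), ifelse(inB, "B", ""),
                          ifelse(inC, "C", ""))
            region <- switch(key, A = "onlyA", B = "onlyB", C = "onlyC",
                             AB = "AB_only", AC = "AC_only", BC = "BC_only",
                             ABC = "ABC")
            counts[region] <- counts[region] + 1L
        }
    }
    counts
}

randomIntervals <- function(n, chroms = c("chr1", "chr2"), maxPos = 5000L,
                            maxLen = 120L) {
    s <- sample(maxPos - maxLen, n, replace = TRUE)
    GenomicRanges::GRanges(
        sample(chroms, n, replace = TRUE),
        IRanges::IRanges(s, width = sample(maxLen, n, replace = TRUE)))
}

# hits re-validation: check one hit of a compiled pattern by per-position
# IUPAC set membership on the original string
validateHit <- function(seq, spec, start, strand = "+") {
    allowed <- list(A = "A", C = "C", G = "G", T = "T",
                    R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                    W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                    B = c("C", "G", "T"), D = c("A", "G", "T"),
                    H = c("A", "C", "T"), V = c("A", "C", "G"),
                    N = c("A", "C", "G", "T"))
    span <- oracleMotifSpan(spec)
    x <- substr(seq, start, start + span - 1L)
    if (strand == "-") x <- revcomp(x)
    s <- gsub(" ", "", spec)
    toks <- regmatches(s, gregexpr("n_[0-9]+_|.", s, perl = TRUE))[[1]]
    pos <- 1L
    for (t in toks) {
        if (grepl("^n_[0-9]+_$", t)) {
            pos <- pos + as.integer(gsub("\\D", "", t))
        } else {
            if (!substr(x, pos, pos) %in% allowed[[toupper(t)]])
                return(FALSE)
            pos <- pos + 1L
        }
    }
    TRUE
}
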