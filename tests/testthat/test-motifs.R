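test_that("compilePattern parses the compact gapped-IUPAC notation", {
    p <- compilePattern("ATTA")
    expect_equal(p@segments, "ATTA")
    expect_length(p@gaps, 0L)
    expect_equal(motifSpan(p), 4L)

    p <- compilePattern("TAn_3_TGn_3_CA")
    expect_equal(p@segments, c("TA", "TG", "CA"))
    expect_equal(p@gaps, c(3L, 3L))
    expect_equal(motifSpan(p), 12L)

    p <- compilePattern("AAAAn_7_AAAAn_7_AAAA")
    expect_equal(p@segments, rep("AAAA", 3))
    expect_equal(p@gaps, c(7L, 7L))
    expect_equal(motifSpan(p), 26L)

    # spaces and case are tolerated; inline n is IUPAC N
    p <- compilePattern("CA n_3_TAn_3_TG")
    expect_equal(p@segments, c("CA", "TA", "TG"))
    expect_equal(compilePattern("Tan_3_TGn_3_CA")@segments,
                 c("TA", "TG", "CA"))
    expect_equal(compilePattern("GTnWAYATTnATnnR")@segments,
                 "GTNWAYATTNATNNR")

    expect_error(compilePattern("ATXA"), "X")
})

test_that("renderPattern round-trips the canonical notation", {
    for (spec in c("ATTA", "WWWWWW", "TAn_3_TGn_3_CA",
                   "AAAAn_7_AAAAn_7_AAAA", "RnYnnCnnGYnGKTnYnY")) {
        p <- compilePattern(spec)
        # canonical form: segment wildcards as N, gap tokens as n_k_
        canonical <- gsub("n(?!_[0-9])", "N", spec, perl = TRUE)
        expect_equal(renderPattern(p), canonical)
        expect_equal(renderPattern(compilePattern(renderPattern(p))),
                     canonical)
        expect_equal(motifSpan(compilePattern(renderPattern(p))),
                     motifSpan(p))
    }
})

test_that("the built-in catalog has the 18 expected motifs", {
    cat18 <- marMotifCatalog()
    expect_length(cat18, 18L)
    expect_equal(motifId(cat18$m_1), "m_1")
    expect_equal(renderPattern(cat18$m_18), "WWWWWW")
    expect_equal(motifSpan(cat18$m_16), 18L)  # canonical topo-II consensus
    expect_equal(motifCategory(cat18$m_10), "kinked_DNA")
    spans <- vapply(cat18, motifSpan, integer(1))
    expect_true(all(spans >= 4L & spans <= 26L))
})

test_that("scanMotif finds direct, degenerate and gapped matches", {
    h <- scanMotif("GATTACA", "ATTA")
    expect_equal(start(h), 2L)
    expect_equal(width(h), 4L)

    h <- scanMotif("ATATATAT", "WWWWWW")
    expect_equal(start(h), 1:3)  # overlapping hits all reported

    h <- scanMotif("TAGGGTGAAACA", "TAn_3_TGn_3_CA")
    expect_equal(start(h), 1L)
    expect_equal(width(h), 12L)
})

test_that("sequence N is matched only by pattern N", {
    expect_length(scanMotif("ANTA", "ATTA"), 0L)
    expect_length(scanMotif("ANTA", "AWTA"), 0L)
    expect_length(scanMotif("ANTA", "ANTA"), 1L)
    expect_length(scanMotif("AATA", "ANTA"), 1L)
})

test_that("both-strand scanning maps hits back to forward coordinates", {
    # TGTTTTG at 3..9 on the minus strand of the forward sequence
    seq <- paste0("GG", revcomp("TGTTTTG"), "GG")
    h <- scanMotif(seq, "TGTTTTG", strands = "both")
    expect_equal(as.character(strand(h)), "-")
    expect_equal(start(h), 3L)
    expect_equal(end(h), 9L)

    # palindromic pattern: symmetric hit sets on both strands
    h <- scanMotif("GGATATGG", "ATAT", strands = "both")
    expect_equal(sort(start(h)), c(3L, 3L))
    expect_setequal(as.character(strand(h)), c("+", "-"))
})

test_that("hit counts are invariant under non-matching flanks", {
    set.seed(31)
    core <- randomSeq(300, c(A = .4, C = .1, G = .1, T = .4))
    for (spec in c("ATTA", "WWWWWW", "TAn_3_TGn_3_CA")) {
        n0 <- length(scanMotif(core, spec))
        flanked <- paste0(strrep("C", 50), core, strrep("G", 50))
        # C/G flanks cannot create or destroy hits of these AT-based motifs
        expect_equal(length(scanMotif(flanked, spec)), n0)
    }
})

test_that("scanMotif agrees with the regex oracle on random sequences", {
    set.seed(101)
    catalog <- marMotifCatalog()
    specs <- vapply(catalog, renderPattern, character(1))
    for (rep in 1:40) {
        seq <- randomSeq(sample(100:800, 1),
                         c(A = .3, C = .2, G = .2, T = .3))
        for (spec in specs) {
            got <- start(scanMotif(seq, spec))
            expect_identical(got, oracleMotifStarts(seq, spec))
        }
    }
})

test_that("every reported hit re-validates position by position", {
    set.seed(55)
    seq <- randomSeq(2000, c(A = .35, C = .15, G = .15, T = .35))
    for (spec in c("WWWWWW", "ATTTA", "TAn_3_CAn_3_TG",
                   "RnYnnCnnGYnGKTnYnY")) {
        h <- scanMotif(seq, spec, strands = "both")
        for (i in seq_along(h))
            expect_true(validateHit(seq, spec, start(h)[i],
                                    as.character(strand(h)[i])))
    }
})

test_that("scanMRS pairs the two elements within the window", {
    seq <- paste0("AATAATAA", strrep("C", 50), "AATGTAACCTAGGATC")
    got <- scanMRS(seq)
    expect_equal(nrow(got), 1L)
    expect_equal(got$pos8, 1L)
    expect_equal(got$pos16, 59L)
    expect_equal(got$separation, 50L)
    # the 8-mer matches AATAAYAA with Y=T; the 16-mer AWWRTAANNWWGNNNC
    expect_true(validateHit(seq, "AATAAYAA", 1L))
    expect_true(validateHit(seq, "AWWRTAANNWWGNNNC", 59L))

    far <- paste0("AATAATAA", strrep("C", 300), "AATGTAACCTAGGATC")
    expect_equal(nrow(scanMRS(far)), 0L)
    expect_equal(nrow(scanMRS(strrep("G", 400))), 0L)
})

test_that("scanMRS matches the oracle pairing on planted sequences", {
    set.seed(77)
    for (rep in 1:20) {
        sep <- sample(0:220, 1)
        pf <- plantFeatures(randomSeq(800, c(A = .2, C = .3, G = .3,
                                             T = .2)),
                            data.frame(kind = "mrs", at = 100,
                                       separation = min(sep, 200L)),
                            seed = rep)
        got <- scanMRS(pf$seq)
        oracle <- oracleMRSPairs(pf$seq)
        expect_equal(got[, c("pos8", "pos16")], oracle,
                     ignore_attr = TRUE)
        expect_gte(nrow(got), 1L)
    }
})

test_that("motifAbundance reports hit totals and presence percentages", {
    seqs <- c(rep("GGATTAGG", 9), "GGGGGGGG")
    ab <- motifAbundance(seqs, catalog = marMotifCatalog()["m_1"],
                         mrs = FALSE)
    expect_equal(ab$per_motif$presence_pct, 90)
    expect_equal(ab$per_motif$n_hits, 9L)

    allG <- rep(strrep("G", 60), 5)
    ab <- motifAbundance(allG)
    expect_true(all(ab$per_motif$presence_pct[
        ab$per_motif$motif_id != "m_6"] == 0))
    expect_error(motifAbundance(character(0)), "empty")
})

test_that("planted per-sequence motif rates are recovered as presence", {
    set.seed(92)
    n <- 400
    planted <- runif(n) < 0.92
    seqs <- vapply(seq_len(n), function(i) {
        s <- randomSeq(300, c(A = 0, C = .5, G = .5, T = 0))
        if (planted[i])
            s <- plantFeatures(s, data.frame(kind = "motif", at = 100,
                                             spec = "WWWWWW"),
                               seed = i)$seq
        s
    }, character(1))
    ab <- motifAbundance(seqs, catalog = marMotifCatalog()["m_18"],
                         mrs = FALSE)
    # GC-only background cannot contain W runs: presence equals the
    # planted fraction exactly
    expect_equal(ab$per_motif$n_seqs_with_hit, sum(planted))
    expect_equal(ab$per_motif$presence_pct, 100 * mean(planted))
    expect_gt(ab$per_motif$presence_pct, 85)
})
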