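refTable <- function() {
    read.table(system.file("extdata", "bmori_chromosome_mar_counts.tsv",
                           package = "MARseq"),
               sep = "\t", header = TRUE)
}

test_that("density arithmetic reproduces the published silkworm table", {
    ref <- refTable()
    # printed 2-decimal densities for the reference rows, frozen
    expected_gene <- c(34.37, 45.40, 41.87, 40.00, 31.79)
    expected_sg1 <- c(3.53, 5.38, 2.51, 4.93, 3.11)
    expected_sg5 <- c(12.34, 14.87, 12.21, 15.47, 15.94)
    expected_sg7 <- c(21.97, 25.20, 22.33, 24.39, 17.92)
    for (col in c("mar_sg1", "mar_sg5", "mar_sg7")) {
        dt <- densityTable(ref$chrom, ref$size_mb, ref$n_genes, ref[[col]])
        fm <- formatChromosomeSummary(dt)
        expect_equal(fm$gene_density, expected_gene)
        expect_equal(fm$mar_density,
                     switch(col, mar_sg1 = expected_sg1,
                            mar_sg5 = expected_sg5, mar_sg7 = expected_sg7))
    }
})

test_that("chromosomeSummary counts per chromosome and handles empties", {
    sizes <- data.frame(chrom = c("chr1", "chr2"),
                        length_bp = c(10000000L, 10000000L))
    mars <- GRanges("chr1", IRanges(seq(1, by = 1000, length.out = 10),
                                    width = 100))
    cs <- chromosomeSummary(mars, sizes)
    expect_equal(cs$mar_count, c(10L, 0L))
    expect_equal(cs$mar_density, c(1, 0))
    expect_true(is.na(cs$mean_loop_kb[2]))

    single <- GRanges("chr2", IRanges(1, 100))
    cs <- chromosomeSummary(single, sizes)
    expect_true(is.na(cs$mean_loop_kb[2]))  # < 2 MARs: loop undefined
})

test_that("chromosomeSummary strict mode errors on unknown chromosomes", {
    sizes <- data.frame(chrom = "chr1", length_bp = 1000000L)
    mars <- GRanges(c("chr1", "scaffold7"), IRanges(c(1, 1), width = 100))
    expect_error(chromosomeSummary(mars, sizes), "scaffold7")
    expect_warning(cs <- chromosomeSummary(mars, sizes, strict = FALSE),
                   "skipping")
    expect_equal(attr(cs, "unplaced"), 1L)
    expect_equal(attr(cs, "total_mars"), 2L)
    expect_equal(cs$mar_count, 1L)
})

test_that("loopLengths computes inter-MAR distances by both methods", {
    # 1-based equivalents of 0-based (0,100),(200,300),(400,500)
    gr <- GRanges("chr1", IRanges(c(1, 201, 401), c(100, 300, 500)))
    ll <- loopLengths(gr, method = "midpoint")
    expect_equal(ll$overall_mean_kb, 0.2)
    expect_equal(ll$per_chromosome$n_loops, 2L)
    ll <- loopLengths(gr, method = "gap")
    expect_equal(ll$overall_mean_kb, 0.1)

    # single MAR on a second chromosome contributes nothing
    gr2 <- suppressWarnings(c(gr, GRanges("chr2", IRanges(1, 100))))
    ll <- loopLengths(gr2)
    expect_equal(ll$overall_mean_kb, 0.2)
    expect_equal(ll$per_chromosome$n_loops[
        ll$per_chromosome$chrom == "chr2"], 0L)
})

test_that("uniformly planted peaks recover the planted spacing exactly", {
    up <- makeUniformPeaks(n = 100L, spacing = 50000L)
    ll <- loopLengths(up$peaks)
    expect_equal(ll$overall_mean_kb, 50)
    # uniform spacing equals span / (n - 1) segments
    span <- (max(start(up$peaks) + end(up$peaks)) -
             min(start(up$peaks) + end(up$peaks))) / 2
    expect_equal(ll$overall_mean_kb, span / 99 / 1000)
})

test_that("mar_density increases when MARs are added at fixed size", {
    sizes <- data.frame(chrom = "chr1", length_bp = 1000000L)
    d <- vapply(c(5L, 10L, 20L), function(n) {
        gr <- GRanges("chr1", IRanges(seq(1, by = 2000, length.out = n),
                                      width = 100))
        chromosomeSummary(gr, sizes)$mar_density
    }, numeric(1))
    expect_true(all(diff(d) > 0))
})

test_that("densityCorrelation matches the closed-form Pearson sums", {
    x <- 1:28
    expect_equal(densityCorrelation(
        data.frame(mar_count = x, gene_density = 2 * x))$pearson_r, 1)

    set.seed(9)
    y <- sample(x)
    got <- densityCorrelation(data.frame(mar_count = x, gene_density = y))
    n <- 28
    rOracle <- (n * sum(x * y) - sum(x) * sum(y)) /
        sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
    expect_equal(got$pearson_r, rOracle)
    expect_lt(abs(got$pearson_r), 0.5)

    expect_true(is.na(densityCorrelation(
        data.frame(mar_count = rep(3, 5), gene_density = 1:5))$pearson_r))
    expect_error(densityCorrelation(
        data.frame(mar_count = 1:2, gene_density = 1:2)), "3 chromosomes")
})

toyGenes <- function() {
    # one + gene (exons 101-200, 401-500) and one - gene (2001-2300)
    g <- GRanges("chr1", IRanges(c(101, 2001), c(500, 2300)),
                 strand = c("+", "-"), gene_id = c("gA", "gB"))
    ex <- GRanges("chr1", IRanges(c(101, 401, 2001), c(200, 500, 2300)))
    GeneModelSet(g, ex, exonGene = c("gA", "gA", "gB"))
}

test_that("classifyContext applies exon > intron > non-genic precedence", {
    gms <- toyGenes()
    mars <- GRanges("chr1", IRanges(c(120, 250, 150, 900),
                                    c(140, 300, 450, 950)))
    got <- classifyContext(mars, gms)
    # 150-450 touches exon1, intron and exon2: exon wins
    expect_equal(as.character(got$labels),
                 c("exonic", "intronic", "exonic", "nongenic"))
    expect_equal(sum(got$counts), length(mars))
})

test_that("classifyContext recovers planted context labels", {
    cfg <- syntheticConfig(seed = 5, nChroms = 2L, chromSizeBp = 800000L,
                           nGenesPerChrom = 30L)
    gm <- makeGeneModels(cfg)
    sizes <- data.frame(chrom = c("chr1", "chr2"),
                        length_bp = rep(800000L, 2))
    cp <- makeContextPeaks(gm$geneModels, sizes, 100L, 100L, 100L, seed = 6)
    got <- classifyContext(cp$peaks, gm$geneModels)
    expect_equal(unname(got$counts), c(100L, 100L, 100L))
    expect_equal(as.character(got$labels), as.character(cp$truth))
})

test_that("tss() uses the strand-aware 5' end", {
    gms <- toyGenes()
    t <- tss(gms)
    expect_equal(start(t), c(101L, 2300L))
})

test_that("tssProfile signs distances by gene orientation", {
    gms <- toyGenes()
    # MAR midpoint exactly at the + TSS
    atTss <- GRanges("chr1", IRanges(91, 111))  # midpoint 101
    p <- tssProfile(atTss, gms, window = 10000L, bin = 1000L)
    expect_equal(attr(p, "distances"), 0)

    # midpoint 5 kb 5' (genomically downstream) of the - strand TSS at 2300
    fivePrime <- GRanges("chr1", IRanges(7280, 7320))  # midpoint 7300
    p <- tssProfile(fivePrime, gms, window = 10000L, bin = 1000L)
    expect_equal(attr(p, "distances"), -5000)

    expect_error(tssProfile(atTss, gms, window = 10000L, bin = 3000L),
                 "divide")
})

test_that("tssProfile peaks at zero for MARs planted around TSSs", {
    cfg <- syntheticConfig(seed = 5, nChroms = 2L, chromSizeBp = 800000L,
                           nGenesPerChrom = 30L)
    gm <- makeGeneModels(cfg)
    t <- tss(gm$geneModels)
    set.seed(8)
    pick <- sample(length(t), 300, replace = TRUE)
    mids <- pmax(50L, start(t)[pick] + as.integer(rnorm(300, 0, 5000)))
    mars <- GRanges(seqnames(t)[pick], IRanges(mids - 20L, mids + 20L))
    p <- tssProfile(mars, gm$geneModels, window = 100000L, bin = 10000L)
    expect_equal(sum(p$count), 300L)
    modal <- which.max(p$count)
    expect_true(p$bin_start[modal] <= 0 && p$bin_end[modal] >= 0)
})

test_that("tssProfile is invariant under genome-wide translation", {
    gms <- toyGenes()
    mars <- GRanges("chr1", IRanges(c(50, 300, 1500), width = 41))
    p1 <- tssProfile(mars, gms, window = 10000L, bin = 1000L)
    shift <- 12345L
    gShift <- GenomicRanges::shift(genes(gms), shift)
    exShift <- GenomicRanges::shift(unlist(exons(gms)), shift)
    gms2 <- GeneModelSet(gShift, exShift,
                         exonGene = rep(names(exons(gms)),
                                        lengths(exons(gms))))
    p2 <- tssProfile(GenomicRanges::shift(mars, shift), gms2,
                     window = 10000L, bin = 1000L)
    expect_equal(p1$count, p2$count)
})

test_that("geneFlankReport windows the gene and recovers planted designs", {
    gms <- GeneModelSet(GRanges("chr25", IRanges(1000001, 1020000),
                                strand = "+", gene_id = "FIBH"))
    empty <- GRanges()
    fr <- geneFlankReport(list(a = empty, b = empty, c = empty), gms,
                          "FIBH", flank = 800000L)
    expect_equal(start(fr$window), 200001L)
    expect_equal(end(fr$window), 1820000L)
    expect_error(geneFlankReport(list(a = empty, b = empty, c = empty),
                                 gms, "nope"), "not found")

    # planted FIBH-flank-style design: 1/8/24 unique + 3 common
    design <- c(onlyA = 1L, onlyB = 8L, onlyC = 24L, AB_only = 0L,
                AC_only = 0L, BC_only = 0L, ABC = 3L)
    cfg <- syntheticConfig(seed = 21, nChroms = 1L, chromSizeBp = 2000000L,
                           vennDesign = design)
    pk <- makePeakSets(cfg, data.frame(chrom = "chr25",
                                       length_bp = 2000000L))
    fr <- geneFlankReport(pk$peaks, gms, "FIBH", flank = 2000000L)
    expect_equal(fr$counts$n_unique, c(1L, 8L, 24L))
    expect_equal(fr$n_common, 3L)

    # flank 0 keeps only gene-body overlaps
    inside <- GRanges("chr25", IRanges(1000101, 1000200))
    outside <- GRanges("chr25", IRanges(1, 100))
    fr <- geneFlankReport(list(a = c(inside, outside), b = inside,
                               c = inside), gms, "FIBH", flank = 0L)
    expect_equal(fr$counts$n_in_window, c(1L, 1L, 1L))
})

test_that("pathwayJoin counts genes per pathway and reports unmapped", {
    mapping <- data.frame(gene_id = c("g1", "g2", "g2"),
                          pathway = c("P1", "P1", "P2"))
    pj <- pathwayJoin(c("g1", "g2", "g3"), mapping)
    expect_equal(pj$counts$n_genes[pj$counts$pathway == "P1"], 2L)
    expect_equal(pj$unmapped, "g3")
    expect_error(pathwayJoin("g1", mapping[0, ]), "empty")

    # hash-join oracle on a synthetic mapping with known multiplicities
    set.seed(13)
    genes <- sprintf("g%03d", 1:60)
    mapping <- data.frame(
        gene_id = sample(genes, 200, replace = TRUE),
        pathway = sample(paste0("P", 1:8), 200, replace = TRUE))
    query <- sample(genes, 40)
    pj <- pathwayJoin(query, mapping)
    env <- new.env()
    for (i in seq_len(nrow(mapping))) {
        key <- mapping$gene_id[i]
        env[[key]] <- unique(c(env[[key]], mapping$pathway[i]))
    }
    expected <- table(unlist(mget(query, envir = env,
                                  ifnotfound = list(NULL))))
    got <- setNames(pj$counts$n_genes, pj$counts$pathway)
    expect_equal(got[order(names(got))],
                 c(expected)[order(names(expected))])
})
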