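mkTSS <- function(chrom, pos, strand, ids, sizes, expr = NULL) {
    si <- GenomeInfoDb::Seqinfo(names(sizes), seqlengths = as.integer(sizes))
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1),
                                 strand = strand, seqinfo = si)
    gr$gene_id <- ids
    if (!is.null(expr)) gr$expression <- expr
    gr
}

sizes <- c(chr1 = 100000L)

test_that("window counts place tags in strand-oriented 60-bp windows", {
    tss <- mkTSS("chr1", 5000, "+", "g1", sizes)
    lib <- TagLibrary(5030, "chr1", "+", sizes)
    m <- windowCounts(lib, tss, flank = 120)
    v <- metageneValues(m)
    expect_identical(dim(v), c(1L, 4L))
    expect_equal(as.numeric(v), c(0, 0, 1e6, 0))   # RPM of the only tag

    # empty library -> all-zero matrix
    empty <- TagLibrary(integer(0), character(0), character(0), sizes)
    m0 <- windowCounts(empty, tss, flank = 120)
    expect_true(all(metageneValues(m0) == 0))

    # window map tiles [-flank, flank)
    w <- metageneWindows(m)
    expect_equal(w$startOffset, c(-120, -60, 0, 60))
    expect_equal(w$endOffset - w$startOffset, rep(60, 4))
})

test_that("minus-strand genes are mirrored into the same row layout", {
    sizes2 <- c(chr1 = 100000L)
    # + gene at 5000 with a tag 30 bp downstream;
    # - gene at 8000 with a tag 30 bp downstream in gene orientation (7970)
    tssP <- mkTSS("chr1", 5000, "+", "gp", sizes2)
    tssM <- mkTSS("chr1", 8000, "-", "gm", sizes2)
    libP <- TagLibrary(5030, "chr1", "+", sizes2)
    libM <- TagLibrary(7970, "chr1", "+", sizes2)
    mp <- metageneValues(windowCounts(libP, tssP, flank = 120))
    mm <- metageneValues(windowCounts(libM, tssM, flank = 120))
    expect_equal(unname(mp), unname(mm))

    # enumerated offsets on both strands agree with direct binning
    set.seed(55)
    offs <- sample(-120:119, 30)
    libO <- TagLibrary(8000 - offs, "chr1",
                       sample(c("+", "-"), 30, TRUE), sizes2)
    mo <- metageneValues(windowCounts(libO, tssM, flank = 120))
    oracle <- tabulate((offs + 120) %/% 60 + 1, nbins = 4) * 1e6 / 30
    expect_equal(as.numeric(mo), oracle)
})

test_that("flanks beyond the chromosome end are NA and flagged", {
    tss <- mkTSS("chr1", 50, "+", "edge", sizes)
    lib <- TagLibrary(60, "chr1", "+", sizes)
    m <- windowCounts(lib, tss, flank = 120)
    expect_true("edge" %in% m@truncated)
    expect_true(anyNA(metageneValues(m)))
    # the in-bounds downstream windows are still counted
    expect_equal(unname(metageneValues(m)[1, 3]), 1e6)
})

test_that("RPM scales inversely with library size under duplication", {
    tss <- mkTSS("chr1", 5000, "+", "g1", sizes)
    lib1 <- TagLibrary(c(5030, 5090), "chr1", c("+", "+"), sizes)
    lib2 <- TagLibrary(rep(c(5030, 5090), 2), "chr1", rep("+", 4), sizes)
    m1 <- metageneValues(windowCounts(lib1, tss, flank = 120))
    m2 <- metageneValues(windowCounts(lib2, tss, flank = 120))
    expect_equal(m1, m2)   # counts double, N doubles
})

test_that("log2 enrichment is 0 for identical matrices and +1 for doubling", {
    tss <- mkTSS("chr1", c(5000, 9000), c("+", "-"), c("g1", "g2"), sizes)
    lib <- randomLibrary(2000, sizes, seed = 19)
    m <- windowCounts(lib, tss, flank = 300)
    p0 <- log2EnrichmentProfile(m, m)
    expect_true(all(p0$log2Ratio == 0))

    m2 <- m; m2@values <- m@values * 2
    p1 <- log2EnrichmentProfile(m2, m, pseudocount = 1e-12)
    nz <- p1$input > 1e-6
    expect_equal(p1$log2Ratio[nz], rep(1, sum(nz)), tolerance = 1e-6)

    # antisymmetry under swapping IP and input
    pa <- log2EnrichmentProfile(m2, m)
    pb <- log2EnrichmentProfile(m, m2)
    expect_equal(pa$log2Ratio, -pb$log2Ratio, tolerance = 1e-12)

    mBad <- windowCounts(lib, tss, flank = 360)
    expect_error(log2EnrichmentProfile(m, mBad), "shape error")
})

test_that("simulated TSS-proximal depletion dips at the TSS-adjacent windows", {
    tss <- simTSSAnnotation(sizes = c(chr1 = 1e6, chr2 = 1e6, chr3 = 1e6),
                            nGenes = 150, seed = 71)
    ip <- simTagLibrary(nTags = 200000, tss = tss, tssDepletionFold = 3,
                        tssDepletionHalfwidth = 150, seed = 72)$library
    input <- simTagLibrary(nTags = 200000, seed = 73)$library
    prof <- log2EnrichmentProfile(windowCounts(ip, tss, flank = 1980),
                                  windowCounts(input, tss, flank = 1980))
    dip <- which.min(prof$log2Ratio)
    adjacent <- which(prof$startOffset %in% c(-60, 0))
    expect_true(dip %in% adjacent)
})

test_that("expression strata are deterministic equal-count quantile bins", {
    tss <- mkTSS("chr1", c(1000, 2000, 3000, 4000), "+",
                 paste0("g", 1:4), sizes, expr = c(1, 2, 3, 4))
    g <- stratifyByExpression(tss, 2)
    expect_identical(as.character(g), c("q1", "q1", "q2", "q2"))

    const <- mkTSS("chr1", c(1000, 2000), "+", c("a", "b"), sizes,
                   expr = c(5, 5))
    expect_warning(gc_ <- stratifyByExpression(const, 2), "constant")
    expect_identical(as.character(gc_), c("q1", "q1"))

    noexpr <- mkTSS("chr1", 1000, "+", "a", sizes)
    expect_error(stratifyByExpression(noexpr, 2), "stratification error")

    # 1000 random values, 4 groups: sizes 250 each, matches a sort oracle
    set.seed(4)
    big <- mkTSS("chr1", seq(1000, by = 90, length.out = 1000), "+",
                 sprintf("g%04d", 1:1000), sizes, expr = rlnorm(1000))
    g4 <- stratifyByExpression(big, 4)
    expect_true(all(abs(table(g4) - 250) <= 1))
    o <- order(big$expression, big$gene_id)
    expect_identical(as.character(g4[o]),
                     paste0("q", rep(1:4, each = 250)))
})

test_that("TSS BED reading applies the 5'-end convention and joins expression", {
    f <- withr::local_tempfile(fileext = ".bed")
    writeLines(c("chr1\t999\t2000\tgA\t0\t+", "chr1\t2999\t4000\tgB\t0\t-"), f)
    fe <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("gene_id\tvalue", "gA\t3.5", "gB\t1.25"), fe)
    tss <- readTSS(f, sizes, expression = fe)
    expect_equal(GenomicRanges::start(tss), c(1000, 4000))
    expect_equal(tss$expression, c(3.5, 1.25))
})

test_that("metagene matrices export as TSV with offset-labelled columns", {
    tss <- mkTSS("chr1", 5000, "+", "g1", sizes)
    lib <- TagLibrary(5030, "chr1", "+", sizes)
    m <- windowCounts(lib, tss, flank = 120)
    f <- withr::local_tempfile(fileext = ".tsv")
    writeMetageneMatrix(m, f)
    d <- read.delim(f, check.names = FALSE)
    expect_identical(colnames(d), c("gene_id", "-120", "-60", "0", "60"))
    expect_equal(as.numeric(d[1, -1]), c(0, 0, 1e6, 0))
})
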