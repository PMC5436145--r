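sizes <- c(chr1 = 1000L, chr2 = 800L)

writeBed <- function(lines) {
    f <- withr::local_tempfile(fileext = ".bed", .local_envir = parent.frame())
    writeLines(lines, f)
    f
}

test_that("BED ingestion takes start+1 for + reads and end for - reads", {
    f <- writeBed(c("chr1\t9\t59\tr1\t0\t+", "chr1\t9\t59\tr2\t0\t-"))
    lib <- readTags(f, sizes)
    gr <- tags(lib)
    expect_equal(GenomicRanges::start(gr)[as.character(GenomicRanges::strand(gr)) == "+"], 10)
    expect_equal(GenomicRanges::start(gr)[as.character(GenomicRanges::strand(gr)) == "-"], 59)
    expect_identical(readLength(lib), 50L)
})

test_that("empty, unknown-chromosome and off-chromosome records are handled", {
    f <- writeBed(character(0))
    lib <- readTags(f, sizes)
    expect_identical(length(lib), 0L)

    f2 <- writeBed(c("chrX\t10\t60\tr\t0\t+", "chr1\t10\t60\tr\t0\t+"))
    expect_warning(lib2 <- readTags(f2, sizes), "unknown chromosome")
    expect_identical(length(lib2), 1L)

    f3 <- writeBed(c("chr2\t700\t900\tr\t0\t-", "chr1\t10\t60\tr\t0\t+"))
    expect_message(lib3 <- readTags(f3, sizes), "rejected")
    expect_identical(length(lib3), 1L)
})

test_that("write/read round-trips the 5' positions", {
    lib <- randomLibrary(300, sizes, seed = 4, readLength = 36L)
    f <- withr::local_tempfile(fileext = ".bed")
    writeTags(lib, f)
    back <- readTags(f, sizes, readLength = 36L)
    expect_setequal(tagKey(back), tagKey(lib))
    expect_identical(length(back), length(lib))
})

test_that("deduplication keeps one tag per chromosome/strand/position", {
    lib <- TagLibrary(c(100, 100, 100, 100), "chr1", c("+", "+", "+", "-"),
                      sizes)
    dd <- deduplicate(lib)
    expect_identical(length(dd), 2L)   # strand-aware
    expect_setequal(tagKey(dd), c("chr1 + 100", "chr1 - 100"))

    set.seed(12)
    base <- randomLibrary(400, sizes, seed = 12)
    dup <- TagLibrary(
        c(GenomicRanges::start(tags(base)),
          GenomicRanges::start(tags(base))[1:100]),
        c(as.character(GenomicRanges::seqnames(tags(base))),
          as.character(GenomicRanges::seqnames(tags(base)))[1:100]),
        c(as.character(GenomicRanges::strand(tags(base))),
          as.character(GenomicRanges::strand(tags(base)))[1:100]),
        sizes)
    expect_identical(length(deduplicate(dup)),
                     length(unique(tagKey(dup))))
})

test_that("blacklist removal matches a per-tag membership oracle", {
    f <- writeBed(c("chr1\t9\t10\tbl\t0\t."))
    bl <- readBlacklist(f)
    lib <- TagLibrary(c(9, 10, 11), "chr1", c("+", "+", "+"), sizes)
    kept <- blacklistFilter(lib, bl)
    # 0-based [9,10) covers only 1-based position 10
    expect_setequal(GenomicRanges::start(tags(kept)), c(9, 11))

    expect_identical(tagKey(blacklistFilter(lib, GenomicRanges::GRanges())),
                     tagKey(lib))

    set.seed(77)
    rlib <- randomLibrary(1000, sizes, seed = 77)
    ivs <- data.frame(chrom = sample(names(sizes), 30, replace = TRUE),
                      s = sample(0:700, 30, replace = TRUE))
    ivs$e <- ivs$s + sample(5:50, 30, replace = TRUE)
    f2 <- writeBed(sprintf("%s\t%d\t%d\tb\t0\t.", ivs$chrom, ivs$s, ivs$e))
    bl2 <- readBlacklist(f2)
    got <- blacklistFilter(rlib, bl2)
    # oracle: O(n*m) membership test on 1-based positions
    gr <- tags(rlib)
    inBl <- vapply(seq_along(gr), function(i) {
        p <- GenomicRanges::start(gr)[i]
        ch <- as.character(GenomicRanges::seqnames(gr))[i]
        any(ivs$chrom == ch & p > ivs$s & p <= pmin(ivs$e, sizes[ch]))
    }, logical(1))
    expect_setequal(tagKey(got), tagKey(rlib)[!inBl])
})

test_that("dedup and blacklist filters commute", {
    rlib <- randomLibrary(800, c(chr1 = 300L), seed = 9)  # dense -> duplicates
    f <- writeBed(c("chr1\t50\t100\tb\t0\t.", "chr1\t200\t220\tb\t0\t."))
    bl <- readBlacklist(f)
    a <- deduplicate(blacklistFilter(rlib, bl))
    b <- blacklistFilter(deduplicate(rlib), bl)
    expect_identical(tagKey(a), tagKey(b))
})

test_that("coverage smoothing matches a naive sliding mean and conserves mass", {
    one <- TagLibrary(500, "chr1", "+", sizes)
    t1 <- coverageTrack(one, bandwidth = 1)
    expect_equal(sum(t1$chr1 != 0), 1)
    expect_equal(t1$chr1[500], 1e6)

    t51 <- coverageTrack(one, bandwidth = 50)   # odd-rounded to 51
    expect_equal(sum(t51$chr1 != 0), 51)
    expect_equal(sum(t51$chr1), 1e6, tolerance = 1e-6)   # conservation
    expect_equal(max(abs(t51$chr1[475:525] - 1e6 / 51)), 0, tolerance = 1e-6)

    rlib <- randomLibrary(500, sizes, seed = 23)
    tr <- coverageTrack(rlib, bandwidth = 21)
    for (ch in names(sizes))
        expect_equal(tr[[ch]], oracleCoverage(rlib, ch, 21), tolerance = 1e-9)
})

test_that("bedGraph output encodes the track run-length compressed", {
    lib <- TagLibrary(c(10, 10, 400), "chr2", c("+", "-", "+"), sizes)
    tr <- coverageTrack(lib, bandwidth = 1)
    f <- withr::local_tempfile(fileext = ".bedgraph")
    writeBedGraph(tr, f)
    d <- read.delim(f, header = FALSE)
    expect_identical(nrow(d), 2L)       # two non-zero runs
    expect_equal(d$V2, c(9, 399))       # 0-based starts
})

test_that("chrom.sizes files parse with validation", {
    f <- withr::local_tempfile()
    writeLines(c("chr1\t1000", "chr2\t800"), f)
    expect_identical(readChromSizes(f), sizes)
    writeLines(c("chr1\t1000", "chr1\t800"), f)
    expect_error(readChromSizes(f), "duplicate")
})
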