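test_that("digest cleaves after Arg only, not before Pro, and tiles the input", {
    d <- propionylDigest(HistoneSequence("t", "GR"))
    expect_identical(d$sequence, "GR")
    expect_identical(d$lysPropionyl, 0L)
    expect_true(all(d$ntermPropionyl))

    d2 <- propionylDigest(HistoneSequence("t", "GKRAPRPGKR"))
    # K never cleaved; R6 before P7 retained
    expect_identical(d2$sequence, c("GKR", "APRPGKR"))

    d3 <- propionylDigest(HistoneSequence("t", "AKRGGRMM"))
    expect_identical(d3$sequence, c("AKR", "GGR", "MM"))
    expect_identical(d3$start, c(1L, 4L, 7L))
    expect_identical(d3$end, c(3L, 6L, 8L))
})

test_that("digest products tile random sequences and conserve mass", {
    set.seed(31)
    aa <- names(massTable()$mono)
    for (i in 1:15) {
        s <- paste(sample(aa, sample(20:80, 1), replace = TRUE), collapse = "")
        d <- propionylDigest(HistoneSequence("r", s))
        expect_identical(paste(d$sequence, collapse = ""), s)
        expect_identical(d$lysPropionyl,
                         vapply(strsplit(d$sequence, ""),
                                function(x) sum(x == "K"), integer(1)))
        # unmodified peptide masses: protein + (k-1) waters
        unmod <- d$mass - (d$lysPropionyl + 1L) * 56.026215
        expect_equal(sum(unmod), oracleMass(s) + (nrow(d) - 1) * 18.010565,
                     tolerance = 1e-6)
    }
})

test_that("missed cleavages emit merged species in addition to the full digest", {
    s <- HistoneSequence("t", "AKRGGRMM")
    d <- propionylDigest(s, missedCleavages = 1L)
    expect_setequal(d$sequence[d$missed == 1], c("AKRGGR", "GGRMM"))
    expect_identical(paste(d$sequence[d$missed == 0], collapse = ""),
                     residues(s))
    expect_error(propionylDigest(s, missedCleavages = 3L), "between 0 and 2")
})

test_that("H2A.J yields the Gly5-Arg12 peptide GKQGGKVR, canonical GKQGGKAR", {
    dj <- propionylDigest(h2ajSequence())
    g5 <- dj[dj$start == 5 & dj$end == 12, ]
    expect_identical(g5$sequence, "GKQGGKVR")
    expect_identical(g5$lysPropionyl, 2L)

    dc <- propionylDigest(canonicalH2APanel()[["H2A1C"]])
    c5 <- dc[dc$start == 5 & dc$end == 12, ]
    expect_identical(c5$sequence, "GKQGGKAR")
})

test_that("diagnostic peptide discovery finds the unique differing pair", {
    dp <- diagnosticPeptide(h2ajSequence(), canonicalH2APanel()[["H2A1C"]])
    expect_identical(c(dp$variant$start, dp$variant$end), c(5L, 12L))
    expect_identical(dp$variant$sequence, "GKQGGKVR")
    expect_identical(dp$canonical$sequence, "GKQGGKAR")
    # propionyl offsets cancel: difference is exactly Val - Ala
    expect_equal(dp$variant$mass - dp$canonical$mass, 28.0313,
                 tolerance = 1e-4)

    s <- h2ajSequence()
    expect_error(diagnosticPeptide(s, s), "no-diagnostic")
})

test_that("a single internal substitution is located by brute-force scan", {
    set.seed(17)
    aa <- setdiff(names(massTable()$mono), c("R", "P"))
    for (i in 1:10) {
        res <- sample(aa, 50, replace = TRUE)
        res[c(10, 20, 30, 40)] <- "R"    # guaranteed cleavage sites
        at <- sample(setdiff(2:49, c(10, 20, 30, 40)), 1)
        mut <- res
        mut[at] <- sample(setdiff(aa, res[at]), 1)
        v <- HistoneSequence("v", paste(mut, collapse = ""))
        c0 <- HistoneSequence("c", paste(res, collapse = ""))
        dp <- diagnosticPeptide(v, c0)
        expect_true(dp$variant$start <= at && at <= dp$variant$end)
        # brute-force: the differing peptide is the one whose span covers `at`
        d <- propionylDigest(c0)
        covering <- d[d$start <= at & d$end >= at, ]
        expect_identical(dp$canonical$sequence, covering$sequence)
    }
})

test_that("ambiguous diagnostics error unless a region is requested", {
    # two differing same-span pairs: positions 2 and 6
    v <- HistoneSequence("v", "AVARGVGRGGGR")
    c0 <- HistoneSequence("c", "AAARGAGRGGGR")
    expect_error(diagnosticPeptide(v, c0), "multiple differing")
    dp <- diagnosticPeptide(v, c0, region = c(1, 4))
    expect_identical(dp$variant$sequence, "AVAR")
})

test_that("variant fraction is the printed area-ratio formula", {
    expect_equal(variantFraction(1, 9), 10)
    expect_equal(variantFraction(5, 5), 50)
    expect_error(variantFraction(0, 0), "undefined-fraction")
    expect_error(variantFraction(-1, 2), ">= 0")
    # scale invariance and complementarity
    set.seed(3)
    for (i in 1:20) {
        a <- runif(1, 0.1, 100); b <- runif(1, 0.1, 100); k <- runif(1, 0.5, 50)
        expect_equal(variantFraction(a, b), variantFraction(k * a, k * b),
                     tolerance = 1e-12)
        expect_equal(variantFraction(a, b) + variantFraction(b, a), 100,
                     tolerance = 1e-12)
    }
})

test_that("area tables read back and feed the fraction", {
    f <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("peptide_label\tarea", "H2A.J\t100", "canonical\t900"), f)
    d <- readPeptideAreas(f)
    expect_equal(variantFraction(d$area[d$peptide_label == "H2A.J"],
                                 d$area[d$peptide_label == "canonical"]), 10)
    f2 <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("x\ty", "1\t2"), f2)
    expect_error(readPeptideAreas(f2), "format error")
})
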