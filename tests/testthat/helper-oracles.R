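# Independent brute-force oracles used across the suite. These deliberately
# take the slow, obvious path (dense vectors, per-element loops) so they are
# not entangled with the implementations they check.

# peptide/protein monoisotopic mass by per-character summation
oracleMass <- function(sequence, kind = "mono") {
    tab <- massTable()[[kind]]
    water <- if (kind == "mono") massTable()$water_mono else massTable()$water_avg
    m <- water
    for (ch in strsplit(sequence, "")[[1]]) m <- m + tab[[ch]]
    m
}

# chromosome-weighted strand cross-correlation on dense count vectors
oracleCC <- function(lib, shifts) {
    sz <- genomeSizes(lib)
    ct <- chromTagCounts(lib)
    use <- names(ct)[ct > 0]
    N <- sum(ct[use])
    out <- numeric(length(shifts))
    for (ch in use) {
        v <- tagCountVectors(lib, ch)
        L <- sz[[ch]]
        r <- vapply(shifts, function(d) {
            a <- v$plus[1:(L - d)]
            b <- v$minus[(1 + d):L]
            if (stats::sd(a) == 0 || stats::sd(b) == 0) 0 else stats::cor(a, b)
        }, numeric(1))
        out <- out + ct[[ch]] / N * r
    }
    out
}

# naive centred sliding mean in RPM
oracleCoverage <- function(lib, chrom, bandwidth) {
    b <- as.integer(bandwidth)
    if (b %% 2L == 0L) b <- b + 1L
    h <- (b - 1L) %/% 2L
    v <- tagCountVectors(lib, chrom)
    counts <- v$plus + v$minus
    L <- length(counts)
    out <- numeric(L)
    for (x in seq_len(L)) {
        lo <- max(1L, x - h); hi <- min(L, x + h)
        out[x] <- sum(counts[lo:hi]) / (hi - lo + 1L)
    }
    out * 1e6 / length(lib)
}

# random tag library on a small genome
randomLibrary <- function(n, sizes = c(c1 = 5000L, c2 = 7000L), seed = 1L,
                          readLength = 0L) {
    set.seed(seed)
    chrom <- sample(names(sizes), n, replace = TRUE)
    pos <- ceiling(runif(n) * sizes[chrom])
    TagLibrary(pos, chrom, sample(c("+", "-"), n, replace = TRUE),
               sizes, readLength = readLength)
}

# reverse-translate a protein with random synonymous codons
randomCodons <- function(protein, seed = 1L) {
    set.seed(seed)
    gc <- Biostrings::GENETIC_CODE
    by.aa <- split(names(gc), gc)
    paste(vapply(strsplit(protein, "")[[1]],
                 function(a) sample(by.aa[[a]], 1L), ""), collapse = "")
}

tagKey <- function(lib) {
    gr <- tags(lib)
    paste(GenomicRanges::seqnames(gr), GenomicRanges::strand(gr),
          GenomicRanges::start(gr))
}
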