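#' Seeded synthetic-data generators
#'
#' Each generator is a pure function of its arguments including the seed:
#' the RNG state is saved, seeded, and restored, so the same call always
#' returns the same object and generators never perturb the caller's RNG
#' stream. Defaults encode the regimes the analyses are designed for: a
#' senescent-cell-like top-down spectrum, a 10 percent variant fraction,
#' and ChIP libraries of 50,000 tags with N(150, 10) fragment lengths and
#' 50-bp reads on a 3 x 1 Mb genome.
#'
#' @name simulators
NULL

## run expr under a private RNG stream seeded with `seed`
.withSeed <- function(seed, expr) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
            else if (exists(".Random.seed", envir = globalenv()))
                rm(".Random.seed", envir = globalenv()))
    set.seed(seed)
    expr
}

## mean-1 multiplicative lognormal noise at coefficient of variation cv
.lognoise <- function(n, cv) {
    if (cv <= 0) return(rep(1, n))
    sdl <- sqrt(log(1 + cv^2))
    stats::rlnorm(n, meanlog = -sdl^2 / 2, sdlog = sdl)
}

#' Simulate a deconvoluted top-down spectrum
#'
#' One peak per registry label at the theoretical mass perturbed by
#' N(0, massSd), with intensity proportional to the generating share times
#' mean-1 lognormal noise. The generating shares are returned as the truth
#' record for round-trip tests.
#'
#' @param table named numeric vector label -> theoretical mass (Da).
#' @param shares generating shares in percent, summing to 100; default a
#'   senescent-like 90/10 split when the table has two entries, else uniform.
#' @param massSd mass error s.d. in Da (default 0.2).
#' @param intensityCV coefficient of variation of the multiplicative
#'   intensity noise (default 0.05).
#' @param totalIntensity summed expected intensity (arbitrary units).
#' @param seed integer seed.
#' @param fractionLabel label for the spectrum.
#' @return list(spectrum = \linkS4class{DeconvolutedSpectrum},
#'   truth = data.frame(label, share)).
#' @examples
#' tab <- theoreticalMasses(list(Proteoform(h2ajSequence())))
#' simDeconvolutedSpectrum(tab, shares = 100, seed = 1)
#' @export
simDeconvolutedSpectrum <- function(table, shares = NULL, massSd = 0.2,
                                    intensityCV = 0.05,
                                    totalIntensity = 1e6, seed = 1L,
                                    fractionLabel = "simulated") {
    if (is.null(shares))
        shares <- if (length(table) == 2L) c(90, 10)
                  else rep(100 / length(table), length(table))
    if (length(shares) != length(table))
        stop("shares and table lengths differ")
    if (abs(sum(shares) - 100) > 1e-9)
        stop("shares must sum to 100")
    if (massSd < 0 || intensityCV < 0) stop("noise levels must be >= 0")
    .withSeed(seed, {
        mass <- unname(table) + stats::rnorm(length(table), 0, massSd)
        intensity <- totalIntensity * (shares / 100) *
            .lognoise(length(table), intensityCV)
        list(spectrum = DeconvolutedSpectrum(mass, intensity, fractionLabel),
             truth = data.frame(label = names(table), share = shares))
    })
}

#' Simulate diagnostic-peptide area pairs
#'
#' Replicate (variant, canonical) chromatographic area pairs drawn around a
#' true variant fraction with mean-1 lognormal noise on each area.
#'
#' @param fraction true variant fraction in percent, in (0, 100); default 10,
#'   the senescent-fibroblast regime.
#' @param areaCV coefficient of variation of the area noise (default 0.05).
#' @param nReplicates number of pairs (default 4, as for the biological
#'   replicates behind the study's quantification).
#' @param totalArea expected summed area per replicate.
#' @param seed integer seed.
#' @return list(areas = data.frame(replicate, area_variant, area_canonical),
#'   truth = fraction).
#' @export
simPeptideAreas <- function(fraction = 10, areaCV = 0.05, nReplicates = 4L,
                            totalArea = 1e6, seed = 1L) {
    if (fraction <= 0 || fraction >= 100)
        stop("fraction must be in (0, 100)")
    if (areaCV < 0) stop("areaCV must be >= 0")
    .withSeed(seed, {
        av <- totalArea * fraction / 100 * .lognoise(nReplicates, areaCV)
        ac <- totalArea * (1 - fraction / 100) * .lognoise(nReplicates, areaCV)
        list(areas = data.frame(replicate = seq_len(nReplicates),
                                area_variant = av, area_canonical = ac),
             truth = fraction)
    })
}

#' Simulate a stranded ChIP tag library
#'
#' Sonication fragments are placed on the genome - uniformly for background,
#' at \code{enrichFold} times the background density inside enriched
#' intervals (on a nucleosome-periodic lattice of spacing \code{nucRepeat}
#' when set). Each fragment of length N(fragMean, fragSd) centred at c emits
#' a + tag at c - len/2 and a - tag at c + len/2 (clipped to the chromosome),
#' so the cross-correlation peak sits at the mean fragment length. With TSS
#' depletion enabled, tag 5' ends are then thinned with a triangular kernel
#' deepest at the TSS (the depletion the metagene profile measures); the
#' realised tag count is below \code{nTags} in that case.
#'
#' @param sizes named integer vector of chromosome lengths; default
#'   3 chromosomes of 1 Mb.
#' @param nTags total number of tags (two per fragment); default 50000.
#' @param fragMean,fragSd fragment length distribution in bp (150, 10).
#' @param readLength read length recorded on the library (50).
#' @param nucRepeat nucleosome repeat length in bp; NA (default) disables the
#'   lattice.
#' @param enriched optional data.frame(chrom, start, end) of enriched
#'   intervals (1-based closed).
#' @param enrichFold fold enrichment over background inside those intervals
#'   (default 1 = none).
#' @param tss optional TSS \code{GRanges} for depletion.
#' @param tssDepletionFold fold depletion at the TSS centre (default 1 =
#'   none).
#' @param tssDepletionHalfwidth half-width of the triangular depletion zone
#'   in bp (default 150).
#' @param seed integer seed.
#' @return list(library = \linkS4class{TagLibrary}, truth = list(...)) where
#'   truth records the generating parameters.
#' @examples
#' sim <- simTagLibrary(nTags = 2000, seed = 7)
#' length(sim$library)
#' @export
simTagLibrary <- function(sizes = c(chr1 = 1e6, chr2 = 1e6, chr3 = 1e6),
                          nTags = 50000L, fragMean = 150, fragSd = 10,
                          readLength = 50L, nucRepeat = NA,
                          enriched = NULL, enrichFold = 1,
                          tss = NULL, tssDepletionFold = 1,
                          tssDepletionHalfwidth = 150, seed = 1L) {
    if (nTags <= 0L) stop("nTags must be > 0")
    if (fragMean <= readLength)
        stop("fragment mean must exceed the read length")
    if (!is.null(enriched)) {
        bad <- !(enriched$chrom %in% names(sizes)) |
            enriched$start < 1 | enriched$end > sizes[enriched$chrom]
        if (any(bad)) stop("config error: enriched interval outside genome")
    }
    nFrag <- ceiling(nTags / 2)
    .withSeed(seed, {
        glen <- sum(sizes)
        wBg <- glen
        wEn <- if (!is.null(enriched) && enrichFold > 1)
            sum(enriched$end - enriched$start + 1) * (enrichFold - 1) else 0
        centers <- integer(0); chroms <- character(0)
        repeat {
            need <- nFrag - length(centers)
            if (need <= 0L) break
            draw <- ceiling(need * 1.4) + 10L
            fromEn <- stats::runif(draw) < wEn / (wBg + wEn)
            ch <- character(draw); ce <- numeric(draw)
            nBg <- sum(!fromEn)
            if (nBg) {
                ch[!fromEn] <- sample(names(sizes), nBg, replace = TRUE,
                                      prob = sizes / glen)
                ce[!fromEn] <- ceiling(stats::runif(nBg) * sizes[ch[!fromEn]])
            }
            nEn <- sum(fromEn)
            if (nEn) {
                lens <- enriched$end - enriched$start + 1
                iv <- sample(nrow(enriched), nEn, replace = TRUE,
                             prob = lens / sum(lens))
                ch[fromEn] <- enriched$chrom[iv]
                p <- enriched$start[iv] +
                    floor(stats::runif(nEn) * lens[iv])
                if (!is.na(nucRepeat))   # snap to the nucleosome lattice
                    p <- enriched$start[iv] + nucRepeat *
                        round((p - enriched$start[iv]) / nucRepeat)
                ce[fromEn] <- pmin(pmax(p, 1), sizes[ch[fromEn]])
            }
            centers <- c(centers, ce)
            chroms <- c(chroms, ch)
        }
        centers <- centers[seq_len(nFrag)]
        chroms <- chroms[seq_len(nFrag)]
        len <- stats::rnorm(nFrag, fragMean, fragSd)
        sl <- sizes[chroms]
        pos <- c(pmin(pmax(round(centers - len / 2), 1), sl),
                 pmin(pmax(round(centers + len / 2), 1), sl))
        tchrom <- c(chroms, chroms)
        tstrand <- rep(c("+", "-"), each = nFrag)
        ## TSS-proximal thinning operates on tag 5' ends (the density the
        ## metagene measures), with a triangular kernel deepest at the TSS;
        ## the realised tag count is then below nTags
        if (!is.null(tss) && tssDepletionFold > 1) {
            keepP <- rep(1, length(pos))
            tchr <- as.character(GenomicRanges::seqnames(tss))
            tpos <- GenomicRanges::start(tss)
            for (k in seq_along(tpos)) {
                sel <- tchrom == tchr[k]
                w <- pmax(0, 1 - abs(pos[sel] - tpos[k]) / tssDepletionHalfwidth)
                keepP[sel] <- keepP[sel] *
                    (1 - (1 - 1 / tssDepletionFold) * w)
            }
            ok <- stats::runif(length(pos)) < keepP
            pos <- pos[ok]; tchrom <- tchrom[ok]; tstrand <- tstrand[ok]
        }
        lib <- TagLibrary(pos, tchrom, tstrand, sizes, readLength)
        list(library = lib,
             truth = list(nTags = length(lib), fragMean = fragMean,
                          fragSd = fragSd, nucRepeat = nucRepeat,
                          enrichFold = enrichFold,
                          tssDepletionFold = tssDepletionFold,
                          tssDepletionHalfwidth = tssDepletionHalfwidth))
    })
}

#' Simulate a TSS annotation with graded expression
#'
#' Non-overlapping TSSs at least \code{spacing} bp apart (and \code{margin}
#' bp from chromosome ends) on random strands, with lognormal expression
#' values.
#'
#' @param sizes named integer vector of chromosome lengths.
#' @param nGenes number of genes (default 200).
#' @param spacing minimum distance between TSSs in bp (default 5000).
#' @param margin clearance from chromosome ends in bp (default 2100, just
#'   beyond the default metagene flank).
#' @param exprMeanlog,exprSdlog lognormal expression parameters (2, 1).
#' @param seed integer seed.
#' @return A width-1 \code{GRanges} with \code{gene_id} and
#'   \code{expression} metadata.
#' @export
simTSSAnnotation <- function(sizes = c(chr1 = 1e6, chr2 = 1e6, chr3 = 1e6),
                             nGenes = 200L, spacing = 5000L, margin = 2100L,
                             exprMeanlog = 2, exprSdlog = 1, seed = 1L) {
    if (nGenes < 1L) stop("nGenes must be >= 1")
    slots <- unlist(lapply(names(sizes), function(ch) {
        p <- seq(margin, sizes[[ch]] - margin, by = spacing)
        stats::setNames(p, rep(ch, length(p)))
    }))
    if (length(slots) < nGenes)
        stop("config error: genome too small for requested spacing")
    .withSeed(seed, {
        pick <- sort(sample(length(slots), nGenes))
        si <- Seqinfo(names(sizes), seqlengths = as.integer(sizes))
        gr <- GRanges(names(slots)[pick],
                      IRanges(as.integer(slots[pick]), width = 1L),
                      strand = sample(c("+", "-"), nGenes, replace = TRUE),
                      seqinfo = si)
        gr$gene_id <- sprintf("gene%04d", seq_len(nGenes))
        gr$expression <- stats::rlnorm(nGenes, exprMeanlog, exprSdlog)
        gr
    })
}
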