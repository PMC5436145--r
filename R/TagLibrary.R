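#' @importFrom GenomicRanges GRanges seqnames start end strand "strand<-" findOverlaps
#' @importFrom IRanges IRanges
#' @importFrom GenomeInfoDb seqlengths seqlevels Seqinfo keepSeqlevels
NULL

#' TagLibrary: stranded 5'-end positions of aligned ChIP-seq tags
#'
#' Per-chromosome, per-strand 1-based positions of tag 5' ends, stored as a
#' width-1 \code{GRanges} with a complete \code{Seqinfo}. This is the
#' container every downstream ChIP operation (filtering, coverage,
#' cross-correlation, metagenes) consumes.
#'
#' @slot tags width-1 \code{GRanges}, strand + or -, sorted.
#' @slot readLength sequencing read length in bp (used by the phantom-peak
#'   exclusion when calling the fragment-length peak).
#' @export
setClass("TagLibrary",
    representation(tags = "GRanges", readLength = "integer"))

setValidity("TagLibrary", function(object) {
    gr <- object@tags
    if (length(gr)) {
        if (any(GenomicRanges::width(gr) != 1L))
            return("tags must be width-1 positions")
        if (any(as.character(strand(gr)) == "*"))
            return("tags must be stranded (+/-)")
        sl <- seqlengths(gr)
        if (any(is.na(sl)))
            return("all chromosomes need lengths (Seqinfo)")
        if (any(start(gr) < 1L) ||
            any(start(gr) > sl[as.character(seqnames(gr))]))
            return("tag positions outside chromosome bounds")
    }
    if (length(object@readLength) != 1L || object@readLength < 0L)
        return("readLength must be a single non-negative integer")
    TRUE
})

#' Construct a TagLibrary
#'
#' @param positions integer vector of 1-based 5'-end positions.
#' @param chrom character vector of chromosome names (recycled if length 1).
#' @param strand character vector of "+"/"-".
#' @param sizes named integer vector of chromosome lengths (a genome-sizes
#'   table), or a \code{Seqinfo}.
#' @param readLength read length in bp, default 50.
#' @return A \linkS4class{TagLibrary}.
#' @examples
#' TagLibrary(c(10, 59), "chr1", c("+", "-"), c(chr1 = 1000))
#' @export
TagLibrary <- function(positions, chrom, strand, sizes, readLength = 50L) {
    si <- if (is(sizes, "Seqinfo")) sizes
          else Seqinfo(names(sizes), seqlengths = as.integer(sizes))
    gr <- GRanges(chrom, IRanges(as.integer(positions), width = 1L),
                  strand = strand, seqinfo = si)
    gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
    new("TagLibrary", tags = gr, readLength = as.integer(readLength))
}

#' @describeIn TagLibrary-class total tag count N
#' @param x a TagLibrary
#' @export
setMethod("length", "TagLibrary", function(x) length(x@tags))

#' Tags accessor
#' @param x a \linkS4class{TagLibrary}.
#' @return The underlying width-1 \code{GRanges}.
#' @export
tags <- function(x) x@tags

#' Genome sizes of a TagLibrary
#' @param x a \linkS4class{TagLibrary}.
#' @return Named integer vector chromosome -> length (bp).
#' @export
genomeSizes <- function(x) seqlengths(x@tags)

#' Per-chromosome tag counts N_c
#' @param x a \linkS4class{TagLibrary}.
#' @return Named integer vector over all chromosomes of the genome.
#' @export
chromTagCounts <- function(x) {
    tab <- table(factor(as.character(seqnames(x@tags)),
                        levels = seqlevels(x@tags)))
    stats::setNames(as.integer(tab), names(tab))
}

#' Read length accessor
#' @param x a \linkS4class{TagLibrary}.
#' @export
readLength <- function(x) x@readLength

setMethod("show", "TagLibrary", function(object) {
    n <- length(object)
    cat("TagLibrary: ", n, " tags on ",
        length(seqlevels(object@tags)), " chromosome(s), read length ",
        object@readLength, " bp\n", sep = "")
    if (n) {
        s <- table(as.character(strand(object@tags)))
        cat("  + strand: ", if ("+" %in% names(s)) s[["+"]] else 0L,
            "   - strand: ", if ("-" %in% names(s)) s[["-"]] else 0L, "\n",
            sep = "")
    }
})

#' Read a chromosome-sizes table
#'
#' Two-column TSV (name, length) as produced by \code{samtools faidx} /
#' UCSC \code{fetchChromSizes}.
#'
#' @param path chrom.sizes file.
#' @return Named integer vector.
#' @export
readChromSizes <- function(path) {
    d <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(d) < 2L) stop("format error: chrom.sizes needs two columns")
    if (anyDuplicated(d[[1L]])) stop("duplicate chromosome names")
    if (any(d[[2L]] <= 0)) stop("chromosome lengths must be > 0")
    stats::setNames(as.integer(d[[2L]]), d[[1L]])
}

#' Read stranded aligned tags from a BED6 file
#'
#' The 5' end of each record is \code{start + 1} (1-based) for + strand
#' reads and \code{end} for - strand reads. Records on chromosomes absent
#' from \code{sizes} are skipped with a warning; records whose 5' end falls
#' off the chromosome are rejected and counted in the message.
#'
#' @param path BED6 file (strand in column 6).
#' @param sizes named integer vector of chromosome lengths.
#' @param readLength read length recorded on the library; when NULL, the
#'   modal record width of the BED is used.
#' @return A \linkS4class{TagLibrary}.
#' @export
readTags <- function(path, sizes, readLength = NULL) {
    gr <- rtracklayer::import(path, format = "BED")
    if (length(gr) && any(as.character(strand(gr)) == "*"))
        stop("format error: BED records lack a strand field")
    keep <- as.character(seqnames(gr)) %in% names(sizes)
    if (!all(keep)) {
        warning(sum(!keep), " record(s) on unknown chromosome(s) skipped")
        gr <- gr[keep]
    }
    if (is.null(readLength))
        readLength <- if (length(gr)) {
            w <- GenomicRanges::width(gr)
            as.integer(names(sort(table(w), decreasing = TRUE))[1L])
        } else 50L
    pos <- ifelse(as.character(strand(gr)) == "+", start(gr), end(gr))
    chrom <- as.character(seqnames(gr))
    ok <- pos >= 1L & pos <= sizes[chrom]
    if (!all(ok)) {
        message(sum(!ok), " record(s) with off-chromosome 5' ends rejected")
        pos <- pos[ok]; chrom <- chrom[ok]
        gr <- gr[ok]
    }
    TagLibrary(pos, chrom, as.character(strand(gr)), sizes, readLength)
}

#' Write a TagLibrary as BED6
#'
#' Each tag becomes a read-length interval whose 5' end is the tag position:
#' \code{[pos-1, pos-1+L)} for + tags and \code{[pos-L, pos)} for - tags
#' (0-based half-open), truncated to chromosome bounds so that
#' \code{readTags(writeTags(x))} recovers the same 5' ends.
#'
#' @param lib a \linkS4class{TagLibrary}.
#' @param path output BED file.
#' @export
writeTags <- function(lib, path) {
    gr <- lib@tags
    L <- max(lib@readLength, 1L)
    pos <- start(gr)
    plus <- as.character(strand(gr)) == "+"
    sl <- seqlengths(gr)[as.character(seqnames(gr))]
    bs <- ifelse(plus, pos - 1L, pmax(pos - L, 0L))
    be <- ifelse(plus, pmin(pos - 1L + L, sl), pos)
    d <- data.frame(chrom = as.character(seqnames(gr)), start = bs, end = be,
                    name = paste0("tag", seq_along(gr)), score = 0L,
                    strand = as.character(strand(gr)))
    utils::write.table(d, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
}

#' Remove duplicate tags
#'
#' Keeps at most one tag per (chromosome, strand, 5' position) triple,
#' emulating optical/PCR duplicate removal on a tag library.
#'
#' @param lib a \linkS4class{TagLibrary}.
#' @return A deduplicated \linkS4class{TagLibrary}.
#' @export
deduplicate <- function(lib) {
    gr <- unique(lib@tags)
    new("TagLibrary", tags = gr, readLength = lib@readLength)
}

#' Remove tags falling in blacklisted intervals
#'
#' A tag is removed when its 5' position lies inside any blacklist interval
#' (5'-containment). Blacklists are half-open 0-based intervals as read from a
#' BED file.
#'
#' @param lib a \linkS4class{TagLibrary}.
#' @param blacklist a \code{GRanges} (1-based, as returned by
#'   \code{\link{readBlacklist}}), or a path to a BED file.
#' @return A filtered \linkS4class{TagLibrary}.
#' @export
blacklistFilter <- function(lib, blacklist) {
    if (is.character(blacklist)) blacklist <- readBlacklist(blacklist)
    if (length(blacklist) == 0L) return(lib)
    hits <- findOverlaps(lib@tags, blacklist, ignore.strand = TRUE)
    drop <- unique(S4Vectors::queryHits(hits))
    gr <- if (length(drop)) lib@tags[-drop] else lib@tags
    new("TagLibrary", tags = gr, readLength = lib@readLength)
}

#' Read a blacklist BED file
#'
#' @param path BED file of intervals to exclude (e.g. the ENCODE blacklist).
#' @return A \code{GRanges} (1-based closed, converted from BED's 0-based
#'   half-open convention by the importer).
#' @export
readBlacklist <- function(path) {
    gr <- rtracklayer::import(path, format = "BED")
    strand(gr) <- "*"
    gr
}

#' Smoothed tag-density track
#'
#' Combined-strand 5'-end counts convolved with a centred moving-average
#' (box) window, reported in RPM (reads per million). The stated bandwidth is
#' rounded up to the next odd integer so the window is centred (50 -> 51 bp).
#' At chromosome ends the window is truncated and renormalised to its
#' effective width. A Gaussian kernel (sd = bandwidth/4) is available as an
#' alternative shape.
#'
#' @param lib a \linkS4class{TagLibrary}.
#' @param bandwidth window width in bp, default 50 (realised as 51).
#' @param kernel \code{"box"} (default) or \code{"gaussian"}.
#' @return Named list of per-chromosome numeric vectors (RPM density).
#' @export
coverageTrack <- function(lib, bandwidth = 50, kernel = c("box", "gaussian")) {
    kernel <- match.arg(kernel)
    if (bandwidth <= 0) stop("bandwidth must be > 0")
    b <- as.integer(bandwidth)
    if (b %% 2L == 0L) b <- b + 1L
    h <- (b - 1L) %/% 2L
    N <- length(lib)
    scale <- if (N > 0L) 1e6 / N else 0
    sl <- genomeSizes(lib)
    out <- lapply(names(sl), function(ch) {
        L <- sl[[ch]]
        idx <- as.character(seqnames(lib@tags)) == ch
        counts <- tabulate(start(lib@tags)[idx], nbins = L)
        if (kernel == "box") {
            cs <- cumsum(counts)
            x <- seq_len(L)
            lo <- pmax(x - h, 1L)
            hi <- pmin(x + h, L)
            S <- cs[hi] - c(0, cs)[lo]
            S / (hi - lo + 1L) * scale
        } else {
            sd <- b / 4
            half <- 3L * ceiling(sd)
            k <- stats::dnorm(-half:half, sd = sd)
            k <- k / sum(k)
            full <- stats::filter(counts, k, sides = 2)
            full[is.na(full)] <- 0       # edge: renormalise below
            wt <- stats::filter(rep(1, L), k, sides = 2)
            wt[is.na(wt) | wt == 0] <- 1
            as.numeric(full / wt) * scale
        }
    })
    names(out) <- names(sl)
    out
}

#' Write a density track as bedGraph
#'
#' Runs of equal value are merged; zero runs are omitted.
#'
#' @param track named list of per-chromosome numeric vectors (from
#'   \code{\link{coverageTrack}}).
#' @param path output bedGraph file.
#' @export
writeBedGraph <- function(track, path) {
    con <- file(path, "w")
    on.exit(close(con))
    for (ch in names(track)) {
        r <- rle(track[[ch]])
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths   # 0-based
        keep <- r$values != 0
        if (any(keep))
            utils::write.table(
                data.frame(ch, starts[keep], ends[keep],
                           signif(r$values[keep], 6)),
                con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    }
    invisible(path)
}
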