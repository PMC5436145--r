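#' MetageneMatrix: per-gene window counts around TSSs
#'
#' Rows are genes, columns are non-overlapping 60-bp windows tiling
#' [-flank, +flank) around each TSS, ordered upstream to downstream along
#' the gene strand (minus-strand genes are mirrored). Values are RPM.
#'
#' @slot values numeric matrix (genes x windows), RPM; NA where a window
#'   fell off the chromosome.
#' @slot windows data.frame(column, startOffset, endOffset): the bp interval
#'   [startOffset, endOffset) of each column relative to the TSS (offset 0 =
#'   the TSS position itself; negative = upstream).
#' @slot flank flank extent in bp.
#' @slot windowSize window width in bp.
#' @slot totalTags library size N used for RPM scaling.
#' @slot truncated gene ids whose flank exceeded chromosome bounds.
#' @export
setClass("MetageneMatrix",
    representation(values = "matrix", windows = "data.frame",
                   flank = "integer", windowSize = "integer",
                   totalTags = "numeric", truncated = "character"))

setValidity("MetageneMatrix", function(object) {
    if (ncol(object@values) != nrow(object@windows))
        return("window map does not match matrix columns")
    w <- object@windows
    if (nrow(w) && any(diff(w$startOffset) != object@windowSize))
        return("windows must tile the flank without gaps")
    TRUE
})

setMethod("show", "MetageneMatrix", function(object) {
    cat("MetageneMatrix: ", nrow(object@values), " gene(s) x ",
        ncol(object@values), " windows of ", object@windowSize,
        " bp, flank +/-", object@flank, " bp\n", sep = "")
    if (length(object@truncated))
        cat("  truncated at chromosome bounds:",
            length(object@truncated), "gene(s)\n")
})

#' Matrix and window-map accessors
#' @param x a \linkS4class{MetageneMatrix}.
#' @return \code{metageneValues}: the RPM matrix; \code{metageneWindows}:
#'   the column -> bp-offset map.
#' @export
metageneValues <- function(x) x@values

#' @rdname metageneValues
#' @export
metageneWindows <- function(x) x@windows

#' Read TSS annotations from BED6 (plus optional expression TSV)
#'
#' The TSS of a + strand record is \code{start + 1} (1-based) and of a -
#' strand record \code{end}. Gene ids come from the BED name column and must
#' be unique. Expression values, when given, are joined by gene id.
#'
#' @param path BED6 file of gene spans or pre-made TSS records.
#' @param sizes named integer vector of chromosome lengths.
#' @param expression optional TSV with columns \code{gene_id}, \code{value}.
#' @return A width-1 \code{GRanges} at the TSS positions with metadata
#'   columns \code{gene_id} and (optionally) \code{expression}.
#' @export
readTSS <- function(path, sizes, expression = NULL) {
    gr <- rtracklayer::import(path, format = "BED")
    if (any(as.character(strand(gr)) == "*"))
        stop("format error: TSS BED needs a strand field")
    pos <- ifelse(as.character(strand(gr)) == "+", start(gr), end(gr))
    ids <- if (!is.null(gr$name)) gr$name else paste0("gene", seq_along(gr))
    if (anyDuplicated(ids)) stop("gene ids must be unique")
    si <- Seqinfo(names(sizes), seqlengths = as.integer(sizes))
    out <- GRanges(as.character(seqnames(gr)), IRanges(pos, width = 1L),
                   strand = strand(gr), seqinfo = si)
    out$gene_id <- ids
    if (!is.null(expression)) {
        ex <- utils::read.delim(expression, stringsAsFactors = FALSE)
        out$expression <- ex$value[match(ids, ex$gene_id)]
    }
    out
}

#' Tag counts in 60-bp windows around TSSs
#'
#' Counts tag 5' ends (both strands) in non-overlapping windows tiling
#' [-flank, +flank) around each TSS, oriented along the gene so column 1 is
#' the most upstream window for every gene, then scales to RPM with the
#' total library size. Genes whose flank extends beyond a chromosome end
#' keep their row, with out-of-bounds windows set to NA and the gene id
#' recorded as truncated.
#'
#' @param lib a \linkS4class{TagLibrary}.
#' @param tss a TSS \code{GRanges} from \code{\link{readTSS}} (or
#'   \code{\link{simTSSAnnotation}}).
#' @param flank half-width of the profiled region in bp; must be a positive
#'   multiple of the window size. Default 1980 (33 windows per side).
#' @param windowSize window width in bp, default 60.
#' @return A \linkS4class{MetageneMatrix}.
#' @export
windowCounts <- function(lib, tss, flank = 1980L, windowSize = 60L) {
    flank <- as.integer(flank)
    windowSize <- as.integer(windowSize)
    if (flank <= 0L || flank %% windowSize != 0L)
        stop("flank must be a positive multiple of the window size")
    m <- 2L * flank %/% windowSize
    sl <- genomeSizes(lib)
    ids <- tss$gene_id
    pos <- start(tss)
    tchr <- as.character(seqnames(tss))
    tneg <- as.character(strand(tss)) == "-"
    N <- length(lib)
    byChrom <- split(start(lib@tags),
                     factor(as.character(seqnames(lib@tags)),
                            levels = names(sl)))
    vals <- matrix(0, nrow = length(tss), ncol = m,
                   dimnames = list(ids, NULL))
    truncated <- character()
    for (g in seq_along(tss)) {
        L <- sl[[tchr[g]]]
        p <- byChrom[[tchr[g]]]
        off <- if (tneg[g]) pos[g] - p else p - pos[g]
        off <- off[off >= -flank & off < flank]
        cols <- (off + flank) %/% windowSize + 1L
        vals[g, ] <- tabulate(cols, nbins = m)
        ## windows (even partially) off the chromosome -> NA
        if (pos[g] - flank >= 1L && pos[g] + flank <= L) next
        for (j in seq_len(m)) {
            o1 <- -flank + (j - 1L) * windowSize
            o2 <- o1 + windowSize - 1L
            gwin <- if (tneg[g]) c(pos[g] - o2, pos[g] - o1)
                    else c(pos[g] + o1, pos[g] + o2)
            if (gwin[1L] < 1L || gwin[2L] > L) {
                vals[g, j] <- NA_real_
                truncated <- union(truncated, ids[g])
            }
        }
    }
    if (N > 0L) vals <- vals * 1e6 / N
    wins <- data.frame(column = seq_len(m),
                       startOffset = -flank + (seq_len(m) - 1L) * windowSize,
                       endOffset = -flank + seq_len(m) * windowSize)
    new("MetageneMatrix", values = vals, windows = wins, flank = flank,
        windowSize = windowSize, totalTags = as.numeric(N),
        truncated = truncated)
}

#' log2(IP/Input) metagene profile
#'
#' Collapses each matrix to a per-window mean (or median) RPM over genes,
#' then takes log2((ip + pseudocount) / (input + pseudocount)). IP and input
#' matrices must share gene sets and window maps.
#'
#' @param ip,input \linkS4class{MetageneMatrix} objects over the same genes
#'   and windows.
#' @param pseudocount epsilon added to both means before the ratio, in RPM
#'   (default 0.5) - keeps empty windows finite.
#' @param aggregate \code{"mean"} (default) or \code{"median"} across genes.
#' @return data.frame(startOffset, endOffset, ip, input, log2Ratio), one row
#'   per window.
#' @export
log2EnrichmentProfile <- function(ip, input, pseudocount = 0.5,
                                  aggregate = c("mean", "median")) {
    aggregate <- match.arg(aggregate)
    if (!identical(ip@windows, input@windows))
        stop("shape error: window maps differ")
    if (!identical(rownames(ip@values), rownames(input@values)))
        stop("shape error: gene sets differ")
    f <- if (aggregate == "mean") colMeans else
        function(x, na.rm) apply(x, 2, stats::median, na.rm = na.rm)
    mi <- f(ip@values, na.rm = TRUE)
    mn <- f(input@values, na.rm = TRUE)
    data.frame(startOffset = ip@windows$startOffset,
               endOffset = ip@windows$endOffset,
               ip = mi, input = mn,
               log2Ratio = log2((mi + pseudocount) / (mn + pseudocount)))
}

#' Stratify genes into expression quantile groups
#'
#' Equal-count quantile bins of the expression values, ties broken by gene
#' id order so the grouping is deterministic. Constant expression collapses
#' to a single bin with a warning.
#'
#' @param tss TSS \code{GRanges} with an \code{expression} metadata column.
#' @param nGroups number of strata, >= 2 (default 4).
#' @return Factor of group labels ("q1" lowest ... ) parallel to \code{tss}.
#' @export
stratifyByExpression <- function(tss, nGroups = 4L) {
    if (is.null(tss$expression) || anyNA(tss$expression))
        stop("stratification error: expression values missing")
    if (nGroups < 2L) stop("nGroups must be >= 2")
    x <- tss$expression
    if (length(unique(x)) == 1L) {
        warning("constant expression: all genes placed in one stratum")
        return(factor(rep("q1", length(x))))
    }
    o <- order(x, tss$gene_id)
    grp <- integer(length(x))
    grp[o] <- ceiling(seq_along(x) * nGroups / length(x))
    factor(paste0("q", grp), levels = paste0("q", seq_len(nGroups)))
}

#' Write a metagene matrix as TSV
#'
#' @param x a \linkS4class{MetageneMatrix}.
#' @param path output file; first column \code{gene_id}, then one column per
#'   window named by its start offset.
#' @export
writeMetageneMatrix <- function(x, path) {
    d <- data.frame(gene_id = rownames(x@values), x@values,
                    check.names = FALSE)
    colnames(d)[-1L] <- x@windows$startOffset
    utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
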