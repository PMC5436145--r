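#' DeconvolutedSpectrum: neutral-mass peaks from one LC fraction
#'
#' The output of charge-state deconvolution of a top-down run: a list of
#' (neutral mass, intensity) peaks. Deconvolution itself is upstream of this
#' package; this class consumes its peak lists.
#'
#' @slot peaks data.frame with columns \code{mass} (Da, > 0) and
#'   \code{intensity} (>= 0).
#' @slot fractionLabel which chromatographic fraction the spectrum came from
#'   (e.g. "H2A2").
#' @export
setClass("DeconvolutedSpectrum",
    representation(peaks = "data.frame", fractionLabel = "character"))

setValidity("DeconvolutedSpectrum", function(object) {
    p <- object@peaks
    if (!all(c("mass", "intensity") %in% colnames(p)))
        return("peaks needs columns mass, intensity")
    if (nrow(p) < 1L) return("at least one peak is required")
    if (any(p$mass <= 0)) return("masses must be strictly positive")
    if (any(p$intensity < 0)) return("intensities must be >= 0")
    TRUE
})

#' Construct a DeconvolutedSpectrum
#'
#' @param mass numeric vector of neutral masses (Da).
#' @param intensity numeric vector of intensities (arbitrary units).
#' @param fractionLabel fraction label, default "unspecified".
#' @return A \linkS4class{DeconvolutedSpectrum}.
#' @examples
#' DeconvolutedSpectrum(c(13900.1, 13928.2), c(90, 10), "H2A2")
#' @export
DeconvolutedSpectrum <- function(mass, intensity,
                                 fractionLabel = "unspecified") {
    new("DeconvolutedSpectrum",
        peaks = data.frame(mass = mass, intensity = intensity),
        fractionLabel = fractionLabel)
}

#' @describeIn DeconvolutedSpectrum-class number of peaks
#' @param x a DeconvolutedSpectrum
#' @export
setMethod("length", "DeconvolutedSpectrum", function(x) nrow(x@peaks))

#' Peak table accessor
#' @param x a \linkS4class{DeconvolutedSpectrum}.
#' @return data.frame(mass, intensity).
#' @export
peaks <- function(x) x@peaks

setMethod("show", "DeconvolutedSpectrum", function(object) {
    cat("DeconvolutedSpectrum [", object@fractionLabel, "]: ",
        nrow(object@peaks), " peak(s), mass range ",
        paste(format(range(object@peaks$mass), nsmall = 2), collapse = "-"),
        " Da\n", sep = "")
})

#' Read a deconvoluted peak list from TSV
#'
#' @param path TSV with columns \code{mass}, \code{intensity}.
#' @param fractionLabel fraction label for the spectrum.
#' @return A \linkS4class{DeconvolutedSpectrum}.
#' @export
readPeakList <- function(path, fractionLabel = "unspecified") {
    d <- utils::read.delim(path, stringsAsFactors = FALSE)
    DeconvolutedSpectrum(d$mass, d$intensity, fractionLabel)
}

#' Match deconvoluted peaks to theoretical proteoform masses
#'
#' Each peak is assigned to the theoretical mass minimising the absolute mass
#' error, provided that error is within tolerance; otherwise it is left
#' unassigned. Exact ties (two labels equidistant within tolerance) go to the
#' lexicographically first label and are flagged ambiguous, so matching is
#' deterministic. Several peaks may share one label (adducts, incomplete
#' deconvolution) and are summed downstream.
#'
#' @param spectrum a \linkS4class{DeconvolutedSpectrum}.
#' @param table named numeric vector label -> theoretical mass (Da).
#' @param tolerance matching tolerance, > 0. Interpreted in Da when
#'   \code{unit = "Da"} (default 1.0 Da, suited to intact-protein neutral
#'   masses), or in ppm of the theoretical mass when \code{unit = "ppm"}.
#' @param unit \code{"Da"} or \code{"ppm"}.
#' @return data.frame with one row per peak: \code{peak} (index),
#'   \code{mass}, \code{intensity}, \code{label} (NA when unassigned),
#'   \code{massError} (signed, observed - theoretical), \code{ambiguous}.
#' @examples
#' tab <- theoreticalMasses(list(Proteoform(h2ajSequence())))
#' sp <- DeconvolutedSpectrum(tab + 0.1, 100)
#' matchPeaks(sp, tab)
#' @export
matchPeaks <- function(spectrum, table, tolerance = 1.0,
                       unit = c("Da", "ppm")) {
    unit <- match.arg(unit)
    if (length(table) == 0L)
        stop("configuration error: empty theoretical mass table")
    if (!is.numeric(tolerance) || tolerance <= 0)
        stop("configuration error: tolerance must be > 0")
    labs <- names(table)
    o <- order(labs)
    table <- table[o]
    labs <- labs[o]
    p <- spectrum@peaks
    res <- lapply(seq_len(nrow(p)), function(i) {
        err <- p$mass[i] - table
        tol <- if (unit == "Da") rep(tolerance, length(table))
               else tolerance * 1e-6 * table
        ok <- abs(err) <= tol
        if (!any(ok))
            return(data.frame(peak = i, mass = p$mass[i],
                              intensity = p$intensity[i],
                              label = NA_character_, massError = NA_real_,
                              ambiguous = FALSE))
        aerr <- abs(err)
        aerr[!ok] <- Inf
        best <- which(aerr == min(aerr))   # lexicographic tie-break via sort
        data.frame(peak = i, mass = p$mass[i], intensity = p$intensity[i],
                   label = labs[best[1L]], massError = err[best[1L]],
                   ambiguous = length(best) > 1L)
    })
    do.call(rbind, res)
}

#' Relative abundance profile from peak assignments
#'
#' The intensity of each assigned species divided by the summed intensity of
#' all peaks in the spectrum, expressed in percent. Peaks sharing a label are
#' summed; unassigned intensity is reported under \code{unassigned}. Shares
#' sum to exactly 100.
#'
#' @param spectrum a \linkS4class{DeconvolutedSpectrum}.
#' @param assignments data.frame from \code{\link{matchPeaks}} on the same
#'   spectrum.
#' @return data.frame with columns \code{label} and \code{share} (percent),
#'   one row per assigned label (sorted) plus a final \code{unassigned} row.
#' @examples
#' tab <- c(a = 100, b = 200)
#' sp <- DeconvolutedSpectrum(c(100, 200), c(10, 90))
#' relativeAbundance(sp, matchPeaks(sp, tab))
#' @export
relativeAbundance <- function(spectrum, assignments) {
    p <- spectrum@peaks
    if (nrow(assignments) != nrow(p) ||
        !isTRUE(all.equal(assignments$mass, p$mass)))
        stop("assignments do not refer to this spectrum's peaks")
    total <- sum(p$intensity)
    if (total <= 0)
        stop("undefined-profile error: zero total intensity")
    lab <- assignments$label
    assigned <- !is.na(lab)
    shares <- if (any(assigned))
        100 * tapply(assignments$intensity[assigned], lab[assigned], sum) / total
    else stats::setNames(numeric(0), character(0))
    shares <- shares[order(names(shares))]
    out <- data.frame(label = c(names(shares), "unassigned"),
                      share = c(as.numeric(shares),
                                100 * sum(p$intensity[!assigned]) / total))
    rownames(out) <- NULL
    out
}

#' Write an abundance profile as TSV
#' @param profile data.frame from \code{\link{relativeAbundance}}.
#' @param path output file.
#' @export
writeAbundanceProfile <- function(profile, path) {
    utils::write.table(profile, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
}
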