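#' In-silico propionylation and tryptic digestion
#'
#' Histones are propionylated on lysines before digestion, so trypsin cleaves
#' only C-terminal to arginine (ArgC-like specificity); a second round of
#' propionylation derivatises the newly formed peptide N-termini. The digest
#' therefore cleaves after every Arg not followed by Pro, never after Lys,
#' and every product carries a propionyl group on each Lys plus one on its
#' N-terminus.
#'
#' @param s a \linkS4class{HistoneSequence}.
#' @param missedCleavages number of missed cleavages to allow (0-2); species
#'   with up to this many internal cleavage sites are emitted in addition to
#'   the fully cleaved set.
#' @param noCleaveBeforePro suppress cleavage when the next residue is Pro
#'   (standard rule, default TRUE).
#' @param kind mass kind for peptide masses.
#' @return data.frame with one row per peptide: \code{parent}, \code{start},
#'   \code{end} (Met1-based inclusive span), \code{sequence},
#'   \code{lysPropionyl} (count), \code{ntermPropionyl} (always TRUE),
#'   \code{missed}, \code{mass} (Da, includes propionyl offsets). Rows with
#'   \code{missed == 0} tile the input sequence exactly, in order.
#' @examples
#' propionylDigest(h2ajSequence())
#' @export
propionylDigest <- function(s, missedCleavages = 0L,
                            noCleaveBeforePro = TRUE,
                            kind = c("mono", "average")) {
    stopifnot(is(s, "HistoneSequence"))
    kind <- match.arg(kind)
    if (missedCleavages < 0L || missedCleavages > 2L)
        stop("missedCleavages must be between 0 and 2")
    res <- strsplit(residues(s), "")[[1]]
    n <- length(res)
    cut <- which(res == "R")
    if (noCleaveBeforePro)
        cut <- cut[cut == n | res[pmin(cut + 1L, n)] != "P"]
    bounds <- unique(c(0L, cut, n))          # peptide i spans (bounds[i], bounds[i+1]]
    k <- length(bounds) - 1L
    pep <- function(i, j) {                  # peptides i..j merged (j-i missed cleavages)
        from <- bounds[i] + 1L
        to <- bounds[j + 1L]
        sq <- paste(res[from:to], collapse = "")
        nK <- sum(res[from:to] == "K")
        prop <- .modOffset("propionyl", kind)
        data.frame(parent = names(s), start = from, end = to, sequence = sq,
                   lysPropionyl = nK, ntermPropionyl = TRUE, missed = j - i,
                   mass = peptideMass(sq, kind) + (nK + 1L) * prop)
    }
    out <- list()
    for (mc in 0:missedCleavages)
        for (i in seq_len(max(k - mc, 0L)))
            out[[length(out) + 1L]] <- pep(i, i + mc)
    out <- do.call(rbind, out)
    out[order(out$missed, out$start), , drop = FALSE]
}

#' Locate the diagnostic peptide pair distinguishing a variant from a
#' canonical histone
#'
#' Digests both sequences and returns the aligned peptide pair with identical
#' residue spans whose sequences differ - for H2A.J versus canonical H2A this
#' is the Gly5-Arg12 pair GKQGGKVR / GKQGGKAR (Val11 vs Ala11). Errors if no
#' differing pair exists (identical digests) or if several pairs differ
#' within the considered region; \code{region} restricts the search when the
#' two sequences differ in more than one same-span peptide.
#'
#' @param variant,canonical \linkS4class{HistoneSequence} objects.
#' @param region optional integer c(start, end): only peptide spans contained
#'   in this Met1-based interval are considered.
#' @param kind mass kind.
#' @return A list with components \code{variant} and \code{canonical}, each a
#'   one-row data.frame as returned by \code{\link{propionylDigest}}.
#' @examples
#' diagnosticPeptide(h2ajSequence(), canonicalH2APanel()[["H2A1C"]])
#' @export
diagnosticPeptide <- function(variant, canonical, region = NULL,
                              kind = c("mono", "average")) {
    kind <- match.arg(kind)
    dv <- propionylDigest(variant, kind = kind)
    dc <- propionylDigest(canonical, kind = kind)
    key <- function(d) paste(d$start, d$end)
    common <- intersect(key(dv), key(dc))
    dv <- dv[match(common, key(dv)), , drop = FALSE]
    dc <- dc[match(common, key(dc)), , drop = FALSE]
    if (!is.null(region)) {
        keep <- dv$start >= region[1L] & dv$end <= region[2L]
        dv <- dv[keep, , drop = FALSE]
        dc <- dc[keep, , drop = FALSE]
    }
    diff <- which(dv$sequence != dc$sequence)
    if (length(diff) == 0L)
        stop("no-diagnostic error: digests are identical",
             if (!is.null(region)) " within the requested region")
    if (length(diff) > 1L)
        stop("multiple differing peptide pairs: ",
             paste(sprintf("%d-%d (%s/%s)", dv$start[diff], dv$end[diff],
                           dv$sequence[diff], dc$sequence[diff]),
                   collapse = ", "),
             "; restrict with `region`")
    list(variant = dv[diff, , drop = FALSE],
         canonical = dc[diff, , drop = FALSE])
}

#' Variant fraction from chromatographic peak areas
#'
#' The relative abundance of the variant as
#' 100 * area_variant / (area_variant + area_canonical) - the percentage
#' of H2A.J among all H2A species when applied to the Gly5-Arg12 peptide
#' areas.
#'
#' @param areaVariant,areaCanonical integrated chromatographic areas, >= 0.
#' @return Percentage in [0, 100].
#' @examples
#' variantFraction(1, 9)  # 10
#' @export
variantFraction <- function(areaVariant, areaCanonical) {
    if (any(areaVariant < 0) || any(areaCanonical < 0))
        stop("areas must be >= 0")
    tot <- areaVariant + areaCanonical
    if (any(tot == 0))
        stop("undefined-fraction error: both areas are zero")
    100 * areaVariant / tot
}

#' Read a peptide area table from TSV
#'
#' @param path TSV with columns \code{peptide_label}, \code{area}.
#' @return data.frame(peptide_label, area).
#' @export
readPeptideAreas <- function(path) {
    d <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("peptide_label", "area") %in% colnames(d)))
        stop("format error: expected columns peptide_label, area")
    d
}

#' Write a digest table as TSV
#' @param digest data.frame from \code{\link{propionylDigest}}.
#' @param path output file.
#' @export
writeDigest <- function(digest, path) {
    utils::write.table(digest, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
}
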