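#' Amino-acid and modification mass table
#'
#' Residue (i.e. water-free) masses for the 20 standard amino acids together
#' with the water terminus mass and the modification offsets used throughout
#' the package. Monoisotopic values follow the IUPAC 2013 atomic masses;
#' average values use the standard atomic weights. Modification offsets are
#' elemental-composition sums: propionyl C3H4O, acetyl C2H2O, and the
#' performic-acid oxidation products of Met and Cys (sulfoxide +O,
#' sulfone +2O, cysteic acid +3O).
#'
#' @return A list with components \code{mono} and \code{average} (named
#'   numeric vectors over the one-letter residue codes), \code{water_mono},
#'   \code{water_avg}, and \code{mods}, itself a list of \code{mono}/
#'   \code{average} offset vectors named \code{propionyl}, \code{acetyl},
#'   \code{met_sulfoxide}, \code{met_sulfone}, \code{cys_cysteic_acid}.
#' @examples
#' tab <- massTable()
#' tab$mono[["G"]] + tab$water_mono  # glycine as a free amino acid
#' @export
massTable <- function() {
    mono <- c(
        G = 57.021464, A = 71.037114, S = 87.032028, P = 97.052764,
        V = 99.068414, T = 101.047678, C = 103.009185, L = 113.084064,
        I = 113.084064, N = 114.042927, D = 115.026943, Q = 128.058578,
        K = 128.094963, E = 129.042593, M = 131.040485, H = 137.058912,
        F = 147.068414, R = 156.101111, Y = 163.063329, W = 186.079313)
    average <- c(
        G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167,
        V = 99.1326, T = 101.1051, C = 103.1388, L = 113.1594,
        I = 113.1594, N = 114.1038, D = 115.0886, Q = 128.1307,
        K = 128.1741, E = 129.1155, M = 131.1926, H = 137.1411,
        F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132)
    list(
        mono = mono,
        average = average,
        water_mono = 18.010565,
        water_avg = 18.0153,
        mods = list(
            mono = c(propionyl = 56.026215, acetyl = 42.010565,
                     met_sulfoxide = 15.994915, met_sulfone = 31.989829,
                     cys_cysteic_acid = 47.984744),
            average = c(propionyl = 56.0633, acetyl = 42.0367,
                        met_sulfoxide = 15.9994, met_sulfone = 31.9988,
                        cys_cysteic_acid = 47.9982)))
}

## internal: residue mass vector for one mass kind
.residueMasses <- function(kind = c("mono", "average"), table = massTable()) {
    kind <- match.arg(kind)
    table[[kind]]
}

.waterMass <- function(kind = c("mono", "average"), table = massTable()) {
    kind <- match.arg(kind)
    if (kind == "mono") table$water_mono else table$water_avg
}

.modOffset <- function(name, kind = c("mono", "average"),
                       table = massTable()) {
    kind <- match.arg(kind)
    offs <- table$mods[[if (kind == "mono") "mono" else "average"]]
    bad <- setdiff(name, names(offs))
    if (length(bad))
        stop("unknown modification name(s): ", paste(bad, collapse = ", "))
    unname(offs[name])
}

#' Monoisotopic mass of a plain peptide string
#'
#' Residue-mass sum plus one water. Used internally by the digest and
#' proteoform machinery; exported because it is handy for sanity checks.
#'
#' @param sequence character string of one-letter residue codes.
#' @param kind \code{"mono"} or \code{"average"}.
#' @return Mass in Da.
#' @examples
#' peptideMass("GKQGGKVR")  # the H2A.J Gly5-Arg12 diagnostic peptide
#' @export
peptideMass <- function(sequence, kind = c("mono", "average")) {
    kind <- match.arg(kind)
    res <- strsplit(sequence, "")[[1]]
    tab <- .residueMasses(kind)
    bad <- setdiff(res, names(tab))
    if (length(bad))
        stop("non-standard residue(s): ", paste(unique(bad), collapse = ", "))
    sum(tab[res]) + .waterMass(kind)
}
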