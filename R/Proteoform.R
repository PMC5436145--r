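#' Proteoform: an intact histone species with a defined modification set
#'
#' A proteoform is a specific molecular form of a protein: a sequence, a flag
#' for initiator-Met cleavage, and a list of modification offsets (by residue
#' position or terminus). Its intact mass is computable and is what top-down
#' deconvoluted spectra are matched against.
#'
#' @slot sequence a \linkS4class{HistoneSequence}.
#' @slot met1Cleaved has the initiator Met been removed? Intact histones are
#'   Met1-cleaved by default.
#' @slot modifications data.frame with columns \code{position} (integer
#'   residue position on the *uncleaved* Met1 numbering, or \code{NA} for a
#'   terminal modification) and \code{name} (a modification known to
#'   \code{\link{massTable}}).
#' @slot label unique label within a registry.
#' @export
setClass("Proteoform",
    representation(sequence = "HistoneSequence", met1Cleaved = "logical",
                   modifications = "data.frame", label = "character"))

setValidity("Proteoform", function(object) {
    m <- object@modifications
    if (nrow(m)) {
        if (!all(c("position", "name") %in% colnames(m)))
            return("modifications needs columns position, name")
        len <- length(object@sequence)
        pos <- m$position[!is.na(m$position)]
        lo <- if (object@met1Cleaved) 2L else 1L
        if (any(pos < lo | pos > len))
            return("modification position outside the (possibly Met-cleaved) sequence")
        known <- names(massTable()$mods$mono)
        if (!all(m$name %in% known))
            return("unknown modification name")
    }
    if (length(object@label) != 1L || !nzchar(object@label))
        return("label must be a single non-empty string")
    TRUE
})

#' Construct a Proteoform
#'
#' @param sequence a \linkS4class{HistoneSequence}.
#' @param met1Cleaved logical; drop the initiator Met from the mass
#'   (default TRUE, the state of mature intact histones).
#' @param modifications data.frame(position, name); \code{NA} position means
#'   a terminal modification. Default: none (N-terminal acetylation off).
#' @param label registry label; defaults to the sequence name.
#' @return A \linkS4class{Proteoform}.
#' @examples
#' Proteoform(h2ajSequence())
#' @export
Proteoform <- function(sequence, met1Cleaved = TRUE,
                       modifications = data.frame(position = integer(),
                                                  name = character()),
                       label = names(sequence)) {
    new("Proteoform", sequence = sequence, met1Cleaved = met1Cleaved,
        modifications = modifications, label = label)
}

setMethod("show", "Proteoform", function(object) {
    cat("Proteoform ", object@label, ": ", length(object@sequence), " aa",
        if (object@met1Cleaved) " (Met1 cleaved)",
        ", ", nrow(object@modifications), " modification(s)\n", sep = "")
    cat("  mono mass: ", format(proteoformMass(object), nsmall = 4), " Da\n",
        sep = "")
})

#' Intact mass of a proteoform
#'
#' Sum of residue masses plus one water plus all modification offsets, minus
#' the Met residue mass when the initiator Met is cleaved.
#'
#' @param p a \linkS4class{Proteoform}.
#' @param kind \code{"mono"} (default; deconvoluted neutral masses from
#'   high-resolution instruments are monoisotopic) or \code{"average"}.
#' @return Mass in Da.
#' @examples
#' proteoformMass(Proteoform(HistoneSequence("g", "G"), met1Cleaved = FALSE))
#' @export
proteoformMass <- function(p, kind = c("mono", "average")) {
    kind <- match.arg(kind)
    m <- peptideMass(residues(p@sequence), kind)
    if (p@met1Cleaved) {
        if (substr(residues(p@sequence), 1L, 1L) != "M")
            stop("met1Cleaved set but sequence does not start with Met")
        m <- m - .residueMasses(kind)[["M"]]
    }
    if (nrow(p@modifications))
        m <- m + sum(.modOffset(p@modifications$name, kind))
    m
}

#' Build a theoretical mass table from a proteoform registry
#'
#' One mass per proteoform label. With \code{oxidationMode = "performic"},
#' the configured oxidation offsets are applied to every Met and Cys in the
#' (possibly Met-cleaved) sequence, emulating the mild performic oxidation
#' applied to histones extracted from mouse organs before profiling. Defaults
#' take Met to the sulfone (+31.990 Da) and Cys to cysteic acid (+47.985 Da).
#'
#' @param registry list of \linkS4class{Proteoform} with unique labels.
#' @param oxidationMode \code{"none"} or \code{"performic"}.
#' @param kind mass kind, \code{"mono"} or \code{"average"}.
#' @param metOxidation,cysOxidation modification names applied per Met/Cys in
#'   performic mode.
#' @return Named numeric vector: label -> Da.
#' @examples
#' theoreticalMasses(list(Proteoform(h2ajSequence())))
#' @export
theoreticalMasses <- function(registry, oxidationMode = c("none", "performic"),
                              kind = c("mono", "average"),
                              metOxidation = "met_sulfone",
                              cysOxidation = "cys_cysteic_acid") {
    oxidationMode <- match.arg(oxidationMode)
    kind <- match.arg(kind)
    labels <- vapply(registry, function(p) p@label, "")
    if (anyDuplicated(labels))
        stop("registry error: duplicate proteoform label(s): ",
             paste(unique(labels[duplicated(labels)]), collapse = ", "))
    masses <- vapply(registry, function(p) {
        m <- proteoformMass(p, kind)
        if (oxidationMode == "performic") {
            res <- strsplit(residues(p@sequence), "")[[1]]
            if (p@met1Cleaved) res <- res[-1L]
            nMet <- sum(res == "M")
            nCys <- sum(res == "C")
            if (nMet) m <- m + nMet * .modOffset(metOxidation, kind)
            if (nCys) m <- m + nCys * .modOffset(cysOxidation, kind)
        }
        m
    }, numeric(1))
    names(masses) <- labels
    masses
}

#' Write a theoretical mass table as TSV
#'
#' @param table named numeric vector from \code{\link{theoreticalMasses}}.
#' @param path output file; columns \code{label}, \code{mass}.
#' @export
writeMassTable <- function(table, path) {
    utils::write.table(
        data.frame(label = names(table), mass = unname(table)),
        path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a theoretical mass table from TSV
#'
#' @param path TSV with columns \code{label}, \code{mass}.
#' @return Named numeric vector.
#' @export
readMassTable <- function(path) {
    d <- utils::read.delim(path, stringsAsFactors = FALSE)
    stats::setNames(d$mass, d$label)
}
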