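#' @import methods
#' @importFrom S4Vectors metadata
NULL

setClassUnion("characterOrNULL", c("character", "NULL"))

#' HistoneSequence: a named histone protein sequence numbered from Met1
#'
#' Thin container for a histone (or any protein) sequence. All residue
#' numbering in this package is relative to the initiator methionine (Met1),
#' matching the convention used for H2A fraction classification (Leu52 vs
#' Met52) and the Gly5-Arg12 diagnostic peptide.
#'
#' @slot name sequence label, unique within a registry.
#' @slot residues one-letter amino-acid string.
#' @slot uniprotId optional UniProt accession.
#' @export
setClass("HistoneSequence",
    representation(name = "character", residues = "character",
                   uniprotId = "characterOrNULL"))

setValidity("HistoneSequence", function(object) {
    if (length(object@name) != 1L || !nzchar(object@name))
        return("name must be a single non-empty string")
    if (length(object@residues) != 1L || !nzchar(object@residues))
        return("residues must be a single non-empty string")
    res <- strsplit(object@residues, "")[[1]]
    bad <- setdiff(res, names(massTable()$mono))
    if (length(bad))
        return(paste0("non-standard residue(s): ",
                      paste(unique(bad), collapse = ", ")))
    TRUE
})

#' Construct a HistoneSequence
#'
#' @param name sequence label.
#' @param residues one-letter amino-acid string (standard alphabet).
#' @param uniprotId optional UniProt accession.
#' @return A \linkS4class{HistoneSequence}.
#' @examples
#' HistoneSequence("toy", "MSGRGKQGGKVR")
#' @export
HistoneSequence <- function(name, residues, uniprotId = NULL) {
    new("HistoneSequence", name = name, residues = toupper(residues),
        uniprotId = uniprotId)
}

#' @describeIn HistoneSequence-class sequence length in residues
#' @param x a HistoneSequence
#' @export
setMethod("length", "HistoneSequence", function(x) nchar(x@residues))

#' Residue string of a HistoneSequence
#' @param x a \linkS4class{HistoneSequence}.
#' @return Character string.
#' @export
residues <- function(x) x@residues

#' Name accessor for HistoneSequence
#' @param x a \linkS4class{HistoneSequence}.
#' @export
setMethod("names", "HistoneSequence", function(x) x@name)

setMethod("show", "HistoneSequence", function(object) {
    cat("HistoneSequence ", object@name,
        if (!is.null(object@uniprotId)) paste0(" (", object@uniprotId, ")"),
        ": ", length(object), " aa\n", sep = "")
    r <- object@residues
    cat(" ", if (nchar(r) > 60) paste0(substr(r, 1, 57), "...") else r, "\n")
})

#' Translate a coding sequence into a HistoneSequence
#'
#' Standard-genetic-code translation of a CDS, stopping at the first stop
#' codon. The input must consist of A/C/G/T only and have length divisible
#' by three. A stop codon before the final codon truncates the protein with
#' a warning giving the codon position.
#'
#' @param cds nucleotide string (A/C/G/T).
#' @param name label for the resulting sequence.
#' @return A \linkS4class{HistoneSequence} with the translated protein
#'   (stop excluded).
#' @examples
#' translateCDS("ATGTGA")  # -> "M"
#' @export
translateCDS <- function(cds, name = "translated") {
    cds <- toupper(gsub("[ \n\t]", "", cds))
    if (grepl("[^ACGT]", cds))
        stop("invalid sequence: non-ACGT character in CDS")
    if (nchar(cds) %% 3L != 0L)
        stop("invalid sequence: CDS length not divisible by 3")
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds),
        genetic.code = Biostrings::GENETIC_CODE))
    stop.at <- regexpr("*", aa, fixed = TRUE)
    if (stop.at == -1L) {
        prot <- aa
    } else {
        prot <- substr(aa, 1L, stop.at - 1L)
        if (stop.at < nchar(aa))
            warning("internal stop codon at codon ", stop.at,
                    "; translation truncated")
    }
    if (!nzchar(prot))
        stop("invalid sequence: translation is empty (stop at first codon)")
    HistoneSequence(name, prot)
}

#' Classify an H2A sequence into its chromatographic fraction
#'
#' H2A species separate on reverse-phase C18 into two fractions determined by
#' residue 52 (Met1 numbering): leucine at position 52 places a species in
#' fraction H2A2, methionine in fraction H2A1. Any other residue returns
#' \code{"other"}.
#'
#' @param s a \linkS4class{HistoneSequence} of length >= 52.
#' @return One of \code{"H2A2"}, \code{"H2A1"}, \code{"other"}.
#' @examples
#' classifyH2AFraction(h2ajSequence())  # "H2A2"
#' @export
classifyH2AFraction <- function(s) {
    stopifnot(is(s, "HistoneSequence"))
    if (length(s) < 52L)
        stop("classification error: sequence shorter than 52 residues")
    switch(substr(s@residues, 52L, 52L), L = "H2A2", M = "H2A1", "other")
}

#' Read histone sequences from a FASTA file
#'
#' @param path FASTA file of protein sequences.
#' @return A list of \linkS4class{HistoneSequence} objects named by FASTA
#'   header (first whitespace-delimited token).
#' @export
readHistoneFasta <- function(path) {
    aa <- Biostrings::readAAStringSet(path)
    nm <- vapply(strsplit(names(aa), "[ \t]"), `[`, "", 1L)
    out <- lapply(seq_along(aa), function(i)
        HistoneSequence(nm[i], as.character(aa[[i]])))
    names(out) <- nm
    out
}

#' Write histone sequences to FASTA
#'
#' @param seqs list of \linkS4class{HistoneSequence}.
#' @param path output file.
#' @export
writeHistoneFasta <- function(seqs, path) {
    aa <- Biostrings::AAStringSet(vapply(seqs, residues, ""))
    names(aa) <- vapply(seqs, names, "")
    Biostrings::writeXStringSet(aa, path)
}

#' Bundled H2A.J and canonical H2A sequences
#'
#' \code{h2ajCDS} returns the Flag-HA-tagged H2AFJ coding sequence;
#' \code{h2ajSequence} its mature H2A.J translation (the protein from the
#' internal ATG, 129 aa, Val11, Leu52); \code{canonicalH2APanel} the bundled
#' panel of canonical H2A sequences. The canonical panel
#' (inst/extdata/h2a_canonical_synthetic.fasta) contains best-effort
#' reconstructions of the named UniProt entries assembled for testing; they
#' carry the properties relied on here (Ala11, the Gly5-Arg12 peptide
#' GKQGGKAR, and Leu52 or Met52 as labelled) but are synthetic stand-ins, not
#' database downloads.
#'
#' @return \code{h2ajCDS}: a nucleotide string; \code{h2ajSequence}: a
#'   \linkS4class{HistoneSequence}; \code{canonicalH2APanel}: a named list of
#'   \linkS4class{HistoneSequence}.
#' @examples
#' substr(residues(h2ajSequence()), 5, 12)  # "GKQGGKVR"
#' @export
h2ajCDS <- function() {
    path <- system.file("extdata", "flag_ha_h2afj_cds.fasta",
                        package = "histvar", mustWork = TRUE)
    as.character(Biostrings::readDNAStringSet(path)[[1]])
}

#' @rdname h2ajCDS
#' @export
h2ajSequence <- function() {
    cds <- h2ajCDS()
    i <- regexpr("ATGTCCGGT", cds, fixed = TRUE)
    s <- translateCDS(substr(cds, i, nchar(cds)), name = "H2A.J")
    s@uniprotId <- "Q9BTM1"
    s
}

#' @rdname h2ajCDS
#' @export
canonicalH2APanel <- function() {
    path <- system.file("extdata", "h2a_canonical_synthetic.fasta",
                        package = "histvar", mustWork = TRUE)
    readHistoneFasta(path)
}
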