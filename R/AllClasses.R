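#' @import methods
#' @include AllGenerics.R
NULL

.AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' ProteinSet: a set of protein sequences with mature-chain coordinates
#'
#' Container for the proteins analysed by the pipeline. Each entry carries
#' an accession, optional gene names, an amino-acid sequence restricted to
#' the 20 standard residue letters, and 1-based inclusive coordinates of
#' the mature chain (the part of the sequence that is actually digested;
#' signal peptides and propeptides fall outside it).
#'
#' @slot sequences An [Biostrings::AAStringSet] named by accession.
#' @slot geneNames A list of character vectors, one per protein.
#' @slot matureStart,matureEnd Integer vectors of 1-based inclusive
#'   mature-chain coordinates.
#'
#' @export
setClass("ProteinSet",
    representation(
        sequences  = "AAStringSet",
        geneNames  = "list",
        matureStart = "integer",
        matureEnd   = "integer"
    )
)

setValidity("ProteinSet", function(object) {
    n <- length(object@sequences)
    msg <- character()
    if (length(object@geneNames) != n ||
        length(object@matureStart) != n || length(object@matureEnd) != n)
        msg <- c(msg, "slot lengths disagree")
    acc <- names(object@sequences)
    if (n > 0 && (is.null(acc) || anyNA(acc) || any(acc == "") ||
                  anyDuplicated(acc)))
        msg <- c(msg, "sequences must be uniquely named by accession")
    seqs <- as.character(object@sequences)
    if (any(nchar(seqs) == 0L))
        msg <- c(msg, "empty sequence")
    bad <- grepl(paste0("[^", paste(.AA20, collapse = ""), "]"), seqs)
    if (any(bad))
        msg <- c(msg, sprintf("non-standard residue letters in: %s",
                              paste(acc[bad], collapse = ", ")))
    if (n > 0) {
        ok <- !is.na(object@matureStart) & !is.na(object@matureEnd) &
            object@matureStart >= 1L &
            object@matureStart <= object@matureEnd &
            object@matureEnd <= nchar(seqs)
        if (!all(ok))
            msg <- c(msg, "mature coordinates out of range")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a ProteinSet
#'
#' @param sequences A named character vector or `AAStringSet` of protein
#'   sequences (names are accessions).
#' @param accessions Optional accessions overriding the names of
#'   `sequences`.
#' @param geneNames Optional list (or character vector) of gene names,
#'   one entry per protein.
#' @param matureStart,matureEnd Optional 1-based inclusive mature-chain
#'   coordinates; default to the whole sequence.
#'
#' @return A [ProteinSet-class] object.
#' @examples
#' ps <- ProteinSet(c(P1 = "MKGRAAAK"))
#' accessions(ps)
#' @export
ProteinSet <- function(sequences, accessions = NULL, geneNames = NULL,
                       matureStart = NULL, matureEnd = NULL) {
    if (is.character(sequences))
        sequences <- Biostrings::AAStringSet(sequences)
    if (!is.null(accessions))
        names(sequences) <- accessions
    n <- length(sequences)
    if (is.null(geneNames))
        geneNames <- rep(list(character()), n)
    if (is.character(geneNames))
        geneNames <- as.list(geneNames)
    if (is.null(matureStart)) matureStart <- rep(1L, n)
    if (is.null(matureEnd)) matureEnd <- Biostrings::width(sequences)
    new("ProteinSet",
        sequences = sequences,
        geneNames = geneNames,
        matureStart = as.integer(matureStart),
        matureEnd = as.integer(matureEnd))
}

#' @describeIn ProteinSet Number of proteins.
#' @param x A `ProteinSet`.
#' @export
setMethod("length", "ProteinSet", function(x) length(x@sequences))

#' @export
setMethod("accessions", "ProteinSet", function(x) names(x@sequences))

#' @export
setMethod("geneNames", "ProteinSet", function(x) x@geneNames)

#' @export
setMethod("sequences", "ProteinSet", function(x) {
    s <- as.character(x@sequences)
    names(s) <- names(x@sequences)
    s
})

#' @export
setMethod("matureStart", "ProteinSet", function(x) x@matureStart)

#' @export
setMethod("matureEnd", "ProteinSet", function(x) x@matureEnd)

#' @export
setMethod("matureSequence", "ProteinSet", function(x) {
    s <- sequences(x)
    out <- substr(s, x@matureStart, x@matureEnd)
    names(out) <- names(s)
    out
})

#' @export
setMethod("[", "ProteinSet", function(x, i, j, ..., drop = TRUE) {
    if (is.character(i))
        i <- match(i, accessions(x))
    new("ProteinSet",
        sequences = x@sequences[i],
        geneNames = x@geneNames[i],
        matureStart = x@matureStart[i],
        matureEnd = x@matureEnd[i])
})

setMethod("show", "ProteinSet", function(object) {
    cat("ProteinSet with", length(object), "proteins\n")
    if (length(object)) {
        w <- Biostrings::width(object@sequences)
        cat("  residues:", sum(w), " (length range ",
            min(w), "-", max(w), ")\n", sep = "")
        head_acc <- utils::head(accessions(object), 5)
        cat("  accessions:", paste(head_acc, collapse = ", "),
            if (length(object) > 5) "..." else "", "\n")
    }
})

#' SpectrumSet: replicate peak lists assigned to proteins
#'
#' One entry per replicate spectrum: a spectrum identifier, the accession
#' of the protein identified by peptide mass fingerprinting, and the list
#' of singly-protonated ([M+H]+) monoisotopic peptide masses observed.
#' Peaks are stored sorted in ascending order.
#'
#' @slot spectrumId Character vector of unique spectrum identifiers.
#' @slot accession Character vector: identified protein per spectrum.
#' @slot peaks List of numeric peak-mass vectors (Da).
#'
#' @export
setClass("SpectrumSet",
    representation(
        spectrumId = "character",
        accession  = "character",
        peaks      = "list"
    )
)

setValidity("SpectrumSet", function(object) {
    msg <- character()
    n <- length(object@spectrumId)
    if (length(object@accession) != n || length(object@peaks) != n)
        msg <- c(msg, "slot lengths disagree")
    if (anyDuplicated(object@spectrumId))
        msg <- c(msg, "duplicate spectrum ids")
    for (p in object@peaks) {
        if (!is.numeric(p)) { msg <- c(msg, "peaks must be numeric"); break }
        if (length(p) && (any(p <= 0) || is.unsorted(p))) {
            msg <- c(msg, "peaks must be positive and sorted ascending")
            break
        }
    }
    if (length(msg)) msg else TRUE
})

#' Construct a SpectrumSet
#'
#' @param spectrumId Character vector of spectrum identifiers.
#' @param accession Character vector of identified-protein accessions.
#' @param peaks List of numeric [M+H]+ peak masses (sorted on input).
#' @return A [SpectrumSet-class].
#' @export
SpectrumSet <- function(spectrumId, accession, peaks) {
    new("SpectrumSet",
        spectrumId = as.character(spectrumId),
        accession = as.character(accession),
        peaks = lapply(peaks, function(p) sort(as.numeric(p))))
}

#' @export
setMethod("length", "SpectrumSet", function(x) length(x@spectrumId))

#' @export
setMethod("spectrumIds", "SpectrumSet", function(x) x@spectrumId)

#' @export
setMethod("accessions", "SpectrumSet", function(x) x@accession)

#' @export
setMethod("peakList", "SpectrumSet", function(x) {
    p <- x@peaks
    names(p) <- x@spectrumId
    p
})

#' @export
setMethod("[", "SpectrumSet", function(x, i, j, ..., drop = TRUE) {
    if (is.logical(i)) i <- which(i)
    new("SpectrumSet",
        spectrumId = x@spectrumId[i],
        accession = x@accession[i],
        peaks = x@peaks[i])
})

setMethod("show", "SpectrumSet", function(object) {
    cat("SpectrumSet with", length(object), "spectra for",
        length(unique(object@accession)), "proteins\n")
    if (length(object)) {
        np <- lengths(object@peaks)
        cat("  peaks per spectrum: median", stats::median(np),
            "(range", min(np), "-", max(np), ")\n")
    }
})
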