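# Monoisotopic mass arithmetic. The residue mass table is generated at
# load time from elemental compositions and CODATA/IUPAC monoisotopic
# atomic masses, never hand-typed, so that downstream mass sums agree
# with composition-based oracles to floating-point precision.

.ATOMIC_MONO <- c(
    C = 12.0,
    H = 1.00782503207,
    N = 14.0030740048,
    O = 15.9949146196,
    S = 31.97207100
)

#' @rdname massConstants
#' @export
PROTON_MASS <- 1.00727646688

#' Monoisotopic mass constants
#'
#' `WATER_MASS` is the monoisotopic mass of H2O added on peptide-bond
#' hydrolysis; `PROTON_MASS` converts a neutral monoisotopic mass to the
#' singly-protonated [M+H]+ value; `OXYGEN_MASS` is the shift of one
#' methionine/tryptophan oxidation; `METHYL_DELTA` is the CH2 shift of a
#' single methylation.
#'
#' @name massConstants
#' @export
WATER_MASS <- 2 * .ATOMIC_MONO[["H"]] + .ATOMIC_MONO[["O"]]

#' @rdname massConstants
#' @export
OXYGEN_MASS <- .ATOMIC_MONO[["O"]]

#' @rdname massConstants
#' @export
METHYL_DELTA <- .ATOMIC_MONO[["C"]] + 2 * .ATOMIC_MONO[["H"]]

# In-chain residue elemental compositions (C, H, N, O, S).
.RESIDUE_FORMULA <- rbind(
    A = c(3, 5, 1, 1, 0),
    R = c(6, 12, 4, 1, 0),
    N = c(4, 6, 2, 2, 0),
    D = c(4, 5, 1, 3, 0),
    C = c(3, 5, 1, 1, 1),
    E = c(5, 7, 1, 3, 0),
    Q = c(5, 8, 2, 2, 0),
    G = c(2, 3, 1, 1, 0),
    H = c(6, 7, 3, 1, 0),
    I = c(6, 11, 1, 1, 0),
    L = c(6, 11, 1, 1, 0),
    K = c(6, 12, 2, 1, 0),
    M = c(5, 9, 1, 1, 1),
    F = c(9, 9, 1, 1, 0),
    P = c(5, 7, 1, 1, 0),
    S = c(3, 5, 1, 2, 0),
    T = c(4, 7, 1, 2, 0),
    W = c(11, 10, 2, 1, 0),
    Y = c(9, 9, 1, 2, 0),
    V = c(5, 9, 1, 1, 0)
)
colnames(.RESIDUE_FORMULA) <- c("C", "H", "N", "O", "S")

.RESIDUE_MONO <- drop(.RESIDUE_FORMULA %*%
                      .ATOMIC_MONO[colnames(.RESIDUE_FORMULA)])

#' Residue monoisotopic masses
#'
#' In-chain (residue) monoisotopic masses for the 20 standard amino
#' acids, derived from elemental compositions.
#'
#' @return Named numeric vector of 20 residue masses in Da.
#' @examples
#' residueMasses()[["G"]]
#' @export
residueMasses <- function() .RESIDUE_MONO

#' Monoisotopic [M+H]+ mass of a peptide
#'
#' Computes the singly-protonated monoisotopic mass of one or more
#' peptides: the sum of in-chain residue masses, plus one water (the
#' peptide termini), plus one proton, plus `oxidation` times the mass of
#' an oxygen atom for oxidised methionine/tryptophan variants.
#'
#' @param sequence Character vector of peptide sequences (standard
#'   one-letter residue codes).
#' @param oxidation Integer vector (recycled) of oxidation counts; each
#'   must not exceed the number of M plus W residues of its peptide.
#' @return Numeric vector of [M+H]+ masses in Da.
#' @examples
#' mhMass("GG")                 # 133.0608
#' mhMass("GLVK", oxidation = 0)
#' @export
mhMass <- function(sequence, oxidation = 0L) {
    stopifnot(is.character(sequence))
    oxidation <- rep_len(as.integer(oxidation), length(sequence))
    vapply(seq_along(sequence), function(i) {
        aa <- strsplit(sequence[i], "", fixed = TRUE)[[1]]
        if (length(aa) == 0L)
            stop("empty peptide sequence")
        m <- .RESIDUE_MONO[aa]
        if (anyNA(m))
            stop("invalid residue letter(s): ",
                 paste(unique(aa[is.na(m)]), collapse = ", "))
        nox <- sum(aa %in% c("M", "W"))
        if (oxidation[i] > nox)
            stop("oxidation count ", oxidation[i],
                 " exceeds number of M/W residues (", nox, ")")
        sum(m) + WATER_MASS + PROTON_MASS + oxidation[i] * OXYGEN_MASS
    }, numeric(1))
}

#' Count oxidisable residues (M and W) in peptides
#' @param sequence Character vector of peptide sequences.
#' @return Integer vector.
#' @export
countOxidisable <- function(sequence) {
    vapply(strsplit(sequence, "", fixed = TRUE),
           function(aa) sum(aa %in% c("M", "W")), integer(1))
}
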