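# In-silico tryptic digestion of mature protein chains.

.tcleavageAfter <- function(aa, suppressProline = TRUE) {
    # positions p (1-based, within the chain) after which trypsin cuts
    n <- length(aa)
    if (n == 0L) return(integer())
    p <- which(aa %in% c("K", "R"))
    p <- p[p < n]
    if (suppressProline && length(p))
        p <- p[aa[p + 1L] != "P"]
    p
}

#' In-silico tryptic digestion
#'
#' Digests the mature chains of a [ProteinSet-class] with trypsin
#' (cleavage C-terminal to K or R), enumerating fragments with 0 up to
#' `maxMissed` missed cleavages and, optionally, oxidised-methionine/
#' tryptophan variants. No mass filtering is applied here. Every
#' one-missed-cleavage peptide is the concatenation of two adjacent
#' fully-cleaved peptides.
#'
#' @param proteins A [ProteinSet-class].
#' @param maxMissed Maximum number of missed cleavages, 0 or 1.
#' @param suppressProline If `TRUE` (default, the conventional trypsin
#'   rule), K/R followed by proline is not cleaved.
#' @param oxidationCap Maximum number of oxidations enumerated per
#'   peptide (capped further by the number of M plus W residues). Set to
#'   0 to return only unoxidised peptides.
#' @return A data.frame with one row per (peptide, oxidation state):
#'   columns `parent`, `start`, `end` (1-based inclusive coordinates in
#'   the full parent sequence), `sequence`, `missedCleavages`,
#'   `oxidationCount`, `mhMass`.
#' @examples
#' digestProtein(ProteinSet(c(P1 = "MKGR")))
#' @export
digestProtein <- function(proteins, maxMissed = 1L, suppressProline = TRUE,
                          oxidationCap = 2L) {
    stopifnot(is(proteins, "ProteinSet"), maxMissed %in% c(0L, 1L))
    out <- vector("list", length(proteins))
    seqs <- sequences(proteins)
    for (i in seq_along(seqs)) {
        acc <- names(seqs)[i]
        ms <- matureStart(proteins)[i]
        me <- matureEnd(proteins)[i]
        chain <- substr(seqs[i], ms, me)
        if (nchar(chain) == 0L)
            stop("empty mature chain for ", acc)
        aa <- strsplit(chain, "", fixed = TRUE)[[1]]
        cuts <- .tcleavageAfter(aa, suppressProline)
        # fragment boundaries in chain coordinates
        starts <- c(1L, cuts + 1L)
        ends <- c(cuts, length(aa))
        frag <- data.frame(
            start = starts, end = ends, missedCleavages = 0L)
        if (maxMissed >= 1L && length(starts) > 1L) {
            frag <- rbind(frag, data.frame(
                start = starts[-length(starts)],
                end = ends[-1L],
                missedCleavages = 1L))
        }
        frag$parent <- acc
        frag$sequence <- substring(chain, frag$start, frag$end)
        # shift to full-sequence coordinates
        frag$start <- frag$start + ms - 1L
        frag$end <- frag$end + ms - 1L
        out[[i]] <- frag
    }
    pep <- do.call(rbind, out)
    pep <- pep[, c("parent", "start", "end", "sequence", "missedCleavages")]
    nox <- pmin(countOxidisable(pep$sequence), as.integer(oxidationCap))
    idx <- rep(seq_len(nrow(pep)), nox + 1L)
    oxc <- unlist(lapply(nox, function(k) 0:k), use.names = FALSE)
    pep <- pep[idx, , drop = FALSE]
    pep$oxidationCount <- as.integer(oxc)
    pep$mhMass <- mhMass(pep$sequence, pep$oxidationCount)
    rownames(pep) <- NULL
    pep
}

#' Default modification table
#'
#' A minimal modification screen: mono-, di- and tri-methylation of
#' lysine and arginine, lysine acetylation and methionine/tryptophan
#' oxidation. Deltas are monoisotopic and derived from elemental masses
#' (mono-methyl = CH2; di-methyl = exactly twice mono). Lysine
#' tri-methylation is retained in the table but discarded at match time
#' because it is near-isobaric to lysine acetylation. A fuller screen can
#' be supplied as a TSV via [readModificationTable()].
#'
#' @return A data.frame with columns `name`, `targets` (string of target
#'   residue letters), `delta` (Da), `degree` (1 = mono, 2 = di, 3 = tri,
#'   NA for non-methyl entries).
#' @examples
#' modificationTable()
#' @export
modificationTable <- function() {
    data.frame(
        name = c("monomethyl", "dimethyl", "trimethyl",
                 "acetyl", "oxidation"),
        targets = c("KR", "KR", "K", "K", "MW"),
        delta = c(METHYL_DELTA, 2 * METHYL_DELTA, 3 * METHYL_DELTA,
                  42.01056468, OXYGEN_MASS),
        degree = c(1L, 2L, 3L, NA_integer_, NA_integer_),
        stringsAsFactors = FALSE)
}

#' Methylation-only modification table
#'
#' Convenience subset of [modificationTable()] restricted to mono- and
#' di-methylation of K and R, the well-separated setting used for
#' noise-free validation runs.
#' @return A data.frame as in [modificationTable()].
#' @export
methylModificationTable <- function() {
    m <- modificationTable()
    m[m$name %in% c("monomethyl", "dimethyl"), , drop = FALSE]
}

#' Apply a single modification to theoretical peptides
#'
#' For each peptide that contains at least one residue the modification
#' can target, returns the shifted [M+H]+ mass and the set of parent
#' coordinates that could carry the modification. Exactly one
#' modification instance per peptide is considered; peptides with no
#' target residue are dropped (they are not candidates).
#'
#' @param peptides A digestion data.frame from [digestProtein()].
#' @param mod One row of a modification table (`name`, `targets`,
#'   `delta`, `degree`).
#' @return The candidate subset of `peptides` with added columns
#'   `modName`, `degree`, `modMass` and a list-column
#'   `candidatePositions` of 1-based parent coordinates.
#' @examples
#' pep <- digestProtein(ProteinSet(c(P1 = "GLVKAAAR")))
#' applyModification(pep, modificationTable()[1, ])
#' @export
applyModification <- function(peptides, mod) {
    stopifnot(nrow(mod) == 1L)
    targets <- strsplit(mod$targets, "", fixed = TRUE)[[1]]
    cand <- lapply(seq_len(nrow(peptides)), function(i) {
        aa <- strsplit(peptides$sequence[i], "", fixed = TRUE)[[1]]
        which(aa %in% targets) + peptides$start[i] - 1L
    })
    keep <- lengths(cand) > 0L
    out <- peptides[keep, , drop = FALSE]
    if (nrow(out) == 0L) {
        out$modName <- character(0)
        out$degree <- integer(0)
        out$modMass <- numeric(0)
        out$candidatePositions <- list()
        return(out)
    }
    out$modName <- mod$name
    out$degree <- mod$degree
    out$modMass <- out$mhMass + mod$delta
    out$candidatePositions <- cand[keep]
    rownames(out) <- NULL
    out
}
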