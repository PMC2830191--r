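# Sequence context around methylation sites: +/-10 residue windows,
# anchored motif matching, and position-specific amino-acid enrichment.

#' Extract the +/-10 residue window around a site
#'
#' Returns the up-to-21-residue context with the modified residue at
#' offset 0. Offsets beyond the protein termini are absent (windows are
#' clipped, not padded).
#'
#' @param sequence Protein sequence string.
#' @param position 1-based site coordinate.
#' @param flank Number of residues either side (default 10).
#' @param residue Optional expected residue letter; a mismatch at the
#'   centre signals a corrupt site table and is an error.
#' @return Named character vector of single letters; names are the
#'   signed offsets `-flank` to `flank` that exist.
#' @examples
#' w <- extractWindow("MVRVAINGFGRIGRLVMRIAL", 11)
#' w[["0"]]   # "R"
#' @export
extractWindow <- function(sequence, position, flank = 10L,
                          residue = NULL) {
    n <- nchar(sequence)
    stopifnot(position >= 1L, position <= n)
    centre <- substr(sequence, position, position)
    if (!is.null(residue) && centre != residue)
        stop("residue mismatch at position ", position, ": sequence has ",
             centre, ", site table says ", residue)
    off <- seq(-flank, flank)
    pos <- position + off
    keep <- pos >= 1L & pos <= n
    stats::setNames(
        strsplit(substr(sequence, min(pos[keep]), max(pos[keep])),
                 "", fixed = TRUE)[[1]],
        as.character(off[keep]))
}

#' Parse a 21-character window string into an offset-named window
#'
#' @param window A window string whose centre character is the modified
#'   residue (odd length).
#' @return Named character vector as from [extractWindow()].
#' @export
windowFromString <- function(window) {
    aa <- strsplit(window, "", fixed = TRUE)[[1]]
    n <- length(aa)
    if (n %% 2L == 0L)
        stop("window string must have odd length")
    flank <- (n - 1L) %/% 2L
    stats::setNames(aa, as.character(seq(-flank, flank)))
}

#' Match an anchored motif against a site window
#'
#' The motif is written over the alphabet of residue letters plus `X`
#' (any residue), anchored at the modified residue: `center` gives the
#' 1-based index of the modified residue within the pattern. For
#' example `GXXRXG` with `center = 4` requires G at offset -3 and G at
#' offset +2. The match is `TRUE` only when every specified offset
#' exists in the window and carries the specified letter.
#'
#' @param window Named window from [extractWindow()] /
#'   [windowFromString()].
#' @param pattern Motif string, e.g. `"WXXXR"`.
#' @param center 1-based index of the modified residue in `pattern`.
#' @return Logical.
#' @examples
#' w <- windowFromString("MVRVAINGFGRIGRLVMRIAL")
#' matchMotif(w, "GXXRXG", center = 4)  # TRUE
#' @export
matchMotif <- function(window, pattern, center) {
    pat <- strsplit(pattern, "", fixed = TRUE)[[1]]
    stopifnot(center >= 1L, center <= length(pat))
    off <- seq_along(pat) - center
    maxOff <- max(abs(as.integer(names(window))))
    if (any(abs(off) > max(10L, maxOff)))
        stop("pattern offsets extend beyond the window flank")
    for (k in seq_along(pat)) {
        if (pat[k] == "X") next
        key <- as.character(off[k])
        if (!key %in% names(window) || window[[key]] != pat[k])
            return(FALSE)
    }
    TRUE
}

#' Residue frequencies of a protein set
#'
#' @param proteins A [ProteinSet-class].
#' @return Named numeric vector over the 20 standard letters, summing
#'   to 1.
#' @export
residueFrequencies <- function(proteins) {
    aa <- unlist(strsplit(paste(sequences(proteins), collapse = ""),
                          "", fixed = TRUE))
    tab <- table(factor(aa, levels = .AA20))
    stats::setNames(as.numeric(tab) / length(aa), .AA20)
}

#' Position-specific amino-acid enrichment around sites
#'
#' For every (offset, residue letter) pair, tests whether the letter is
#' observed at that offset more often than expected from the background
#' frequency, over the windows that cover the offset (clipped windows
#' contribute only the offsets they have). Two one-sided tests are
#' available: an exact binomial tail (default; the observed counts are
#' small) or the chi-squared proportion test with continuity
#' correction ([stats::prop.test]). P-values are Bonferroni-corrected.
#'
#' @param windows List of named windows ([extractWindow()]).
#' @param background Named background residue frequencies; see
#'   [residueFrequencies()].
#' @param nTests Bonferroni factor; defaults to 20 letters times the
#'   number of offsets tested.
#' @param method `"binomial"` (exact tail) or `"prop"`.
#' @param flank Offsets tested run from `-flank` to `flank` (0, the
#'   site itself, is skipped).
#' @return data.frame: `offset`, `residue`, `observed`, `nCovering`,
#'   `background`, `p`, `pBonferroni`.
#' @export
positionalEnrichment <- function(windows, background,
                                 nTests = NULL,
                                 method = c("binomial", "prop"),
                                 flank = 10L) {
    method <- match.arg(method)
    offsets <- setdiff(seq(-flank, flank), 0L)
    if (is.null(nTests))
        nTests <- length(.AA20) * length(offsets)
    rows <- list()
    for (o in offsets) {
        key <- as.character(o)
        present <- vapply(windows, function(w) key %in% names(w),
                          logical(1))
        n <- sum(present)
        if (n == 0L) next
        letters <- vapply(windows[present], function(w) w[[key]],
                          character(1))
        for (a in .AA20) {
            obs <- sum(letters == a)
            p0 <- background[[a]]
            if (p0 == 0 && obs > 0) {
                p <- .Machine$double.xmin
            } else if (method == "binomial") {
                p <- stats::pbinom(obs - 1L, n, p0, lower.tail = FALSE)
            } else {
                p <- suppressWarnings(
                    stats::prop.test(obs, n, p = p0,
                                     alternative = "greater")$p.value)
            }
            rows[[length(rows) + 1L]] <- data.frame(
                offset = o, residue = a, observed = obs, nCovering = n,
                background = p0, p = p,
                pBonferroni = min(1, p * nTests),
                stringsAsFactors = FALSE)
        }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
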