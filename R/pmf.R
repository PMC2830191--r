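# Peak-list preprocessing, tailor-made per-spectrum tolerance
# estimation, and mass-delta matching of unmodified and modified
# theoretical peptides.

#' Commonly observed porcine trypsin autolysis masses
#'
#' Monoisotopic [M+H]+ masses of frequently seen autolysis products of
#' porcine trypsin, removed from peak lists during preprocessing.
#' @return Numeric vector of masses in Da.
#' @export
trypsinAutolysisMasses <- function() {
    c(842.5094, 1045.5637, 1469.7305, 1713.8084,
      2157.0990, 2211.1040, 2283.1802, 2299.1751)
}

#' Preprocess a raw peak list
#'
#' Removes peaks below `minMass` (small peptides carry little
#' information in MALDI-ToF fingerprints) and peaks matching trypsin
#' autolysis masses within `autolysisTol`. Peaks matching the protein's
#' own unmodified peptides are deliberately retained here: the first
#' confidence filter needs them to veto modified interpretations.
#'
#' @param peaks Numeric vector of [M+H]+ masses.
#' @param autolysisMasses Masses removed as trypsin autolysis products.
#' @param minMass Lower mass cutoff in Da (default 500).
#' @param autolysisTol Matching tolerance for autolysis removal, Da.
#' @return Sorted numeric vector; zero-length (with a warning) when all
#'   peaks are removed, in which case the spectrum should be dropped.
#' @export
preprocessPeaks <- function(peaks,
                            autolysisMasses = trypsinAutolysisMasses(),
                            minMass = 500, autolysisTol = 0.1) {
    stopifnot(all(peaks > 0))
    p <- peaks[peaks >= minMass]
    if (length(autolysisMasses) && length(p)) {
        hit <- vapply(p, function(m)
            any(abs(m - autolysisMasses) <= autolysisTol), logical(1))
        p <- p[!hit]
    }
    if (!length(p))
        warning("all peaks removed during preprocessing; spectrum dropped")
    sort(p)
}

#' Preprocess every spectrum of a SpectrumSet
#'
#' Applies [preprocessPeaks()] per spectrum and drops spectra left with
#' no peaks.
#'
#' @param spectra A [SpectrumSet-class].
#' @inheritParams preprocessPeaks
#' @return A filtered [SpectrumSet-class].
#' @export
preprocessSpectra <- function(spectra,
                              autolysisMasses = trypsinAutolysisMasses(),
                              minMass = 500, autolysisTol = 0.1) {
    pk <- lapply(peakList(spectra), preprocessPeaks,
                 autolysisMasses = autolysisMasses,
                 minMass = minMass, autolysisTol = autolysisTol)
    keep <- lengths(pk) > 0L
    SpectrumSet(spectrumIds(spectra)[keep], accessions(spectra)[keep],
                pk[keep])
}

#' Tailor-made mass tolerance for one spectrum
#'
#' Because the identity of the analysed protein is known, the absolute
#' mass differences between the observed peaks and the nearest
#' theoretical unmodified peptide masses (within a coarse search window)
#' estimate the calibration error of that particular spectrum. The
#' tolerance is the median absolute difference; spectra with fewer than
#' `minSupport` supporting matches fall back to the global default of
#' 0.04 Da. Spectra whose estimated tolerance exceeds `excludeAbove`
#' (0.1 Da) are flagged for exclusion from site discovery.
#'
#' @param peaks Numeric preprocessed peak masses of one spectrum.
#' @param theoreticalMasses [M+H]+ masses of the protein's unmodified
#'   peptides (including oxidation variants).
#' @param coarseWindow Search window used to pair peaks with theoretical
#'   peptides, Da.
#' @param fallback Global default tolerance used with sparse support.
#' @param minSupport Minimum number of matched unmodified peptides.
#' @param floor Lower bound applied to the estimate (a zero tolerance,
#'   possible on noise-free data, would match nothing).
#' @param excludeAbove Spectra above this tolerance are excluded from
#'   site discovery.
#' @return A list with `tolerance`, `nSupport`, `fallback` (logical) and
#'   `excluded` (logical).
#' @export
estimateTolerance <- function(peaks, theoreticalMasses,
                              coarseWindow = 0.15, fallback = 0.04,
                              minSupport = 3L, floor = 0.001,
                              excludeAbove = 0.1) {
    errs <- numeric()
    if (length(peaks) && length(theoreticalMasses)) {
        for (m in peaks) {
            d <- abs(m - theoreticalMasses)
            if (min(d) <= coarseWindow)
                errs <- c(errs, min(d))
        }
    }
    if (length(errs) < minSupport) {
        tol <- fallback
        fb <- TRUE
    } else {
        tol <- max(stats::median(errs), floor)
        fb <- FALSE
    }
    list(tolerance = tol, nSupport = length(errs), fallback = fb,
         excluded = tol > excludeAbove)
}

#' Per-spectrum tolerance report
#'
#' Runs [estimateTolerance()] for every spectrum against the digestion
#' of its identified protein.
#'
#' @param spectra A [SpectrumSet-class].
#' @param peptides Digestion table ([digestProtein()]) covering the
#'   identified proteins.
#' @param ... Passed to [estimateTolerance()].
#' @return data.frame: `spectrumId`, `accession`, `tolerance`,
#'   `nSupport`, `fallback`, `excluded`.
#' @export
toleranceReport <- function(spectra, peptides, ...) {
    pk <- peakList(spectra)
    acc <- accessions(spectra)
    rows <- lapply(seq_along(pk), function(i) {
        th <- peptides$mhMass[peptides$parent == acc[i]]
        est <- estimateTolerance(pk[[i]], th, ...)
        data.frame(spectrumId = spectrumIds(spectra)[i],
                   accession = acc[i],
                   tolerance = est$tolerance, nSupport = est$nSupport,
                   fallback = est$fallback, excluded = est$excluded)
    })
    do.call(rbind, rows)
}

#' Match peaks to unmodified theoretical peptides
#'
#' Enumerates every (peak, peptide) pair, across oxidation variants,
#' with absolute mass difference at most `tolerance`.
#'
#' @param peaks Numeric peak masses of one spectrum.
#' @param peptides Digestion table of the identified protein.
#' @param tolerance Mass tolerance in Da (> 0).
#' @param spectrumId Identifier recorded on the matches.
#' @return data.frame of matches: peptide columns plus `spectrumId`,
#'   `queryMass`, `massError`, `modName` (`NA`: unmodified).
#' @export
matchUnmodified <- function(peaks, peptides, tolerance,
                            spectrumId = NA_character_) {
    stopifnot(tolerance > 0)
    out <- list()
    for (m in peaks) {
        hit <- which(abs(peptides$mhMass - m) <= tolerance)
        if (length(hit)) {
            r <- peptides[hit, , drop = FALSE]
            r$spectrumId <- spectrumId
            r$queryMass <- m
            r$massError <- m - r$mhMass
            r$modName <- NA_character_
            out[[length(out) + 1L]] <- r
        }
    }
    if (!length(out)) {
        r <- peptides[0, , drop = FALSE]
        r$spectrumId <- character(0); r$queryMass <- numeric(0)
        r$massError <- numeric(0); r$modName <- character(0)
        return(r)
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

#' Match peaks to singly-modified theoretical peptides
#'
#' For every modification in the table and every theoretical peptide
#' carrying at least one target residue, tests whether a peak equals the
#' shifted mass within `tolerance`. One modification instance per
#' peptide is considered. Lysine tri-methylation matches are discarded
#' (near-isobaric to lysine acetylation), and modifications named in
#' `excludeMods` are skipped entirely.
#'
#' @param peaks Numeric peak masses of one spectrum.
#' @param peptides Digestion table of the identified protein.
#' @param modTable Modification table (see [modificationTable()]).
#' @param tolerance Mass tolerance in Da.
#' @param spectrumId Identifier recorded on the matches.
#' @param excludeMods Character vector of modification names to skip.
#' @param dropTrimethylK Discard tri-methyl matches targeting K.
#' @return data.frame of matches with peptide columns, `modName`,
#'   `degree`, `modMass`, list-column `candidatePositions`,
#'   `spectrumId`, `queryMass`, `massError` and `ambiguous` (`NA` until
#'   [classifyAmbiguity()]).
#' @export
matchModified <- function(peaks, peptides, modTable, tolerance,
                          spectrumId = NA_character_,
                          excludeMods = character(),
                          dropTrimethylK = TRUE) {
    if (is.null(modTable) || nrow(modTable) == 0L)
        stop("empty modification table")
    mt <- modTable[!(modTable$name %in% excludeMods), , drop = FALSE]
    if (dropTrimethylK)
        mt <- mt[!(!is.na(mt$degree) & mt$degree == 3L &
                   grepl("K", mt$targets)), , drop = FALSE]
    out <- list()
    for (k in seq_len(nrow(mt))) {
        cand <- applyModification(peptides, mt[k, , drop = FALSE])
        if (!nrow(cand)) next
        for (m in peaks) {
            hit <- which(abs(cand$modMass - m) <= tolerance)
            if (length(hit)) {
                r <- cand[hit, , drop = FALSE]
                r$spectrumId <- spectrumId
                r$queryMass <- m
                r$massError <- m - r$modMass
                out[[length(out) + 1L]] <- r
            }
        }
    }
    if (!length(out)) {
        r <- applyModification(peptides[0, , drop = FALSE],
                               modificationTable()[1, , drop = FALSE])
        r$spectrumId <- character(0); r$queryMass <- numeric(0)
        r$massError <- numeric(0); r$ambiguous <- logical(0)
        return(r)
    }
    res <- do.call(rbind, out)
    res$ambiguous <- NA
    rownames(res) <- NULL
    res
}

#' Classify match ambiguity per query mass
#'
#' A query mass is explained unambiguously when exactly one distinct
#' (peptide sequence, modification) identity matches it; oxidation
#' variants of the same peptide and modification collapse to a single
#' identity. When more than one identity matches, all matches for that
#' query mass are flagged ambiguous. Multiple candidate residues within
#' one peptide do not by themselves create ambiguity (site localisation
#' is resolved later by the consensus filter).
#'
#' @param matches Modified-match data.frame from [matchModified()].
#' @return `matches` with the `ambiguous` flag filled in.
#' @export
classifyAmbiguity <- function(matches) {
    if (!nrow(matches)) {
        matches$ambiguous <- logical(0)
        return(matches)
    }
    key <- paste(matches$spectrumId, format(matches$queryMass, digits = 12),
                 sep = "\r")
    ident <- paste(matches$sequence, matches$modName, sep = "\r")
    nid <- vapply(split(ident, key), function(x) length(unique(x)),
                  integer(1))
    matches$ambiguous <- nid[key] > 1L
    matches
}
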