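# The five sequential confidence filters that turn raw modified-peptide
# matches into high-confidence methylation sites, plus the end-to-end
# driver with its audit funnel.

.matchKey <- function(matches)
    paste(matches$spectrumId, format(matches$queryMass, digits = 12),
          sep = "\r")

#' Filter 1: veto query masses explained by unmodified peptides
#'
#' A modified match whose query mass also matched any unmodified
#' peptide (including oxidation variants) of the same spectrum is
#' removed: such masses are most simply explained as unmodified.
#'
#' @param modMatches Modified matches ([matchModified()]).
#' @param unmodMatches Unmodified matches ([matchUnmodified()]) of the
#'   same spectra.
#' @return The surviving subset of `modMatches`.
#' @export
filter1NotUnmodified <- function(modMatches, unmodMatches) {
    if (!nrow(modMatches)) return(modMatches)
    veto <- unique(.matchKey(unmodMatches))
    modMatches[!(.matchKey(modMatches) %in% veto), , drop = FALSE]
}

#' Filter 2: remove peptides containing Asp or Glu
#'
#' Partial methyl esterification of D/E side chains during sample
#' handling produces the same +CH2 mass shift as genuine methylation,
#' so any match on a D- or E-containing peptide is discarded.
#'
#' @param matches Modified-match data.frame.
#' @return The surviving subset.
#' @export
filter2NoDE <- function(matches) {
    if (!nrow(matches)) return(matches)
    matches[!grepl("[DE]", matches$sequence), , drop = FALSE]
}

#' Filter 3: require two or more overlapping peptides
#'
#' Methylation slows tryptic cleavage at the modified residue, so a
#' genuine site tends to be seen both in a fully cleaved peptide ending
#' at the site and in a missed-cleavage peptide reading through it.
#' Matches are grouped, per protein and modification, into connected
#' components whose peptide coordinates overlap *and* whose candidate
#' position sets intersect; only components with at least two members
#' (by default, two distinct peptide sequences) survive.
#'
#' @param matches Modified-match data.frame (any number of spectra).
#' @param distinctPeptides Require the two supporting members to be
#'   distinct peptide sequences (default) rather than just two match
#'   instances.
#' @return The surviving subset with an added `groupId` column.
#' @export
filter3Overlap <- function(matches, distinctPeptides = TRUE) {
    if (!nrow(matches)) {
        matches$groupId <- character(0)
        return(matches)
    }
    matches$groupId <- NA_character_
    kept <- logical(nrow(matches))
    for (grp in split(seq_len(nrow(matches)),
                      paste(matches$parent, matches$modName, sep = "\r"))) {
        n <- length(grp)
        comp <- seq_len(n)              # union-find over the group
        find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
        if (n > 1) {
            for (a in seq_len(n - 1)) for (b in seq((a + 1), n)) {
                i <- grp[a]; j <- grp[b]
                if (matches$start[i] <= matches$end[j] &&
                    matches$start[j] <= matches$end[i] &&
                    length(intersect(matches$candidatePositions[[i]],
                                     matches$candidatePositions[[j]])))
                    comp[find(b)] <- find(a)
            }
        }
        roots <- vapply(seq_len(n), find, integer(1))
        for (r in unique(roots)) {
            members <- grp[roots == r]
            size <- if (distinctPeptides)
                length(unique(matches$sequence[members]))
            else length(members)
            if (size >= 2L) {
                kept[members] <- TRUE
                matches$groupId[members] <-
                    paste(matches$parent[members[1]],
                          matches$modName[members[1]], r, sep = "|")
            }
        }
    }
    matches[kept, , drop = FALSE]
}

#' Filter 4: require an unambiguous anchor in each overlap group
#'
#' Groups in which every member is an ambiguous match (its query mass
#' has more than one peptide/modification explanation) are removed; at
#' least one member must be unambiguous.
#'
#' @param matches Grouped matches from [filter3Overlap()].
#' @return The surviving subset.
#' @export
filter4UnambiguousAnchor <- function(matches) {
    if (!nrow(matches)) return(matches)
    keep <- unlist(lapply(split(seq_len(nrow(matches)), matches$groupId),
        function(idx) if (any(!matches$ambiguous[idx])) idx else integer()))
    matches[sort(keep), , drop = FALSE]
}

#' Filter 5: site-level consensus across overlapping peptides
#'
#' Within each overlap group, a residue position becomes a
#' high-confidence site when it lies in the candidate sets of at least
#' two overlapping members carrying the same modification and degree,
#' at least one of which is unambiguous. Mono- and di-methyl evidence
#' never merge: they form separate sites at the same position.
#'
#' @param matches Grouped matches surviving filters 1-4.
#' @param proteins [ProteinSet-class] used to verify residue letters.
#' @param distinctPeptides Count support in distinct peptide sequences
#'   (default) rather than match instances.
#' @return A site table: `accession`, `position`, `residue`, `modName`,
#'   `degree`, `nSupport`, `nUnambiguous`, plus collapsed
#'   `spectrumIds`, `peptides` and the surviving supporting matches as
#'   attribute `"supportIndex"`.
#' @export
filter5SiteConsensus <- function(matches, proteins,
                                 distinctPeptides = TRUE) {
    empty <- data.frame(accession = character(), position = integer(),
                        residue = character(), modName = character(),
                        degree = integer(), nSupport = integer(),
                        nUnambiguous = integer(),
                        spectrumIds = character(), peptides = character(),
                        stringsAsFactors = FALSE)
    if (!nrow(matches)) {
        attr(empty, "supportIndex") <- integer(0)
        return(empty)
    }
    seqs <- sequences(proteins)
    sites <- list()
    supIdx <- integer()
    for (idx in split(seq_len(nrow(matches)), matches$groupId)) {
        pos <- sort(unique(unlist(matches$candidatePositions[idx])))
        for (p in pos) {
            sup <- idx[vapply(matches$candidatePositions[idx],
                              function(cp) p %in% cp, logical(1))]
            nPep <- if (distinctPeptides)
                length(unique(matches$sequence[sup])) else length(sup)
            nUnamb <- sum(!matches$ambiguous[sup])
            if (nPep >= 2L && nUnamb >= 1L) {
                acc <- matches$parent[sup[1]]
                sites[[length(sites) + 1L]] <- data.frame(
                    accession = acc,
                    position = p,
                    residue = substr(seqs[[acc]], p, p),
                    modName = matches$modName[sup[1]],
                    degree = matches$degree[sup[1]],
                    nSupport = nPep,
                    nUnambiguous = nUnamb,
                    spectrumIds = paste(
                        sort(unique(matches$spectrumId[sup])),
                        collapse = ";"),
                    peptides = paste(
                        sort(unique(matches$sequence[sup])),
                        collapse = ";"),
                    stringsAsFactors = FALSE)
                supIdx <- union(supIdx, sup)
            }
        }
    }
    if (!length(sites)) {
        attr(empty, "supportIndex") <- integer(0)
        return(empty)
    }
    out <- do.call(rbind, sites)
    out <- out[order(out$accession, out$position, out$modName), ,
               drop = FALSE]
    rownames(out) <- NULL
    attr(out, "supportIndex") <- sort(supIdx)
    out
}

#' Run the full methylation-discovery pipeline
#'
#' Preprocesses replicate peak lists, estimates a tailor-made tolerance
#' per spectrum (excluding spectra worse than `excludeAbove`), matches
#' unmodified and singly-modified theoretical peptides, and applies the
#' five confidence filters, recording an audit funnel of match counts
#' after every stage.
#'
#' @param spectra A [SpectrumSet-class] of replicate peak lists.
#' @param proteins A [ProteinSet-class] covering the identified
#'   accessions.
#' @param modTable Modification table; see [modificationTable()].
#' @param maxMissed Maximum missed cleavages (must be 1: the overlap
#'   filter is unreachable without missed-cleavage peptides).
#' @param suppressProline Trypsin proline rule for the digestion.
#' @param oxidationCap Maximum enumerated oxidations per peptide.
#' @param minMass Preprocessing lower mass cutoff, Da.
#' @param autolysisMasses Trypsin autolysis masses removed upfront.
#' @param coarseWindow,fallbackTol,toleranceFloor,excludeAbove Tolerance
#'   estimation parameters; see [estimateTolerance()].
#' @param excludeMods Modification names excluded from the screen.
#' @param dropTrimethylK Discard tri-methyl-lysine matches.
#' @param distinctPeptides Site support counted in distinct peptide
#'   sequences (default) or match instances.
#' @param applyFilter2 Set `FALSE` to skip the D/E filter (used for
#'   in-silico benchmarks where no esterification artifact exists).
#' @return A list: `sites` (high-confidence site table), `audit`
#'   (data.frame of stage names and surviving match counts), `tolerances`
#'   (per-spectrum report), and `matches` (supporting matches of the
#'   emitted sites).
#' @export
runPipeline <- function(spectra, proteins,
                        modTable = modificationTable(),
                        maxMissed = 1L, suppressProline = TRUE,
                        oxidationCap = 2L, minMass = 500,
                        autolysisMasses = trypsinAutolysisMasses(),
                        coarseWindow = 0.15, fallbackTol = 0.04,
                        toleranceFloor = 0.001, excludeAbove = 0.1,
                        excludeMods = character(),
                        dropTrimethylK = TRUE,
                        distinctPeptides = TRUE,
                        applyFilter2 = TRUE) {
    if (maxMissed < 1L)
        stop("maxMissed must be 1: the overlapping-peptide filter ",
             "requires missed-cleavage peptides")
    spectra <- preprocessSpectra(spectra, autolysisMasses = autolysisMasses,
                                 minMass = minMass)
    keepAcc <- accessions(spectra) %in% accessions(proteins)
    spectra <- spectra[keepAcc]
    accs <- unique(accessions(spectra))
    digests <- lapply(accs, function(a)
        digestProtein(proteins[a], maxMissed = maxMissed,
                      suppressProline = suppressProline,
                      oxidationCap = oxidationCap))
    names(digests) <- accs

    tolRows <- list(); unmodL <- list(); modL <- list()
    pk <- peakList(spectra)
    sacc <- accessions(spectra)
    sid <- spectrumIds(spectra)
    for (i in seq_along(pk)) {
        pep <- digests[[sacc[i]]]
        est <- estimateTolerance(pk[[i]], pep$mhMass,
                                 coarseWindow = coarseWindow,
                                 fallback = fallbackTol,
                                 floor = toleranceFloor,
                                 excludeAbove = excludeAbove)
        tolRows[[i]] <- data.frame(spectrumId = sid[i], accession = sacc[i],
                                   tolerance = est$tolerance,
                                   nSupport = est$nSupport,
                                   fallback = est$fallback,
                                   excluded = est$excluded)
        if (est$excluded) next
        unmodL[[length(unmodL) + 1L]] <-
            matchUnmodified(pk[[i]], pep, est$tolerance, sid[i])
        modL[[length(modL) + 1L]] <-
            matchModified(pk[[i]], pep, modTable, est$tolerance, sid[i],
                          excludeMods = excludeMods,
                          dropTrimethylK = dropTrimethylK)
    }
    tolerances <- do.call(rbind, tolRows)
    unmod <- if (length(unmodL)) do.call(rbind, unmodL) else NULL
    mod <- if (length(modL)) do.call(rbind, modL) else NULL
    if (is.null(mod) || !nrow(mod)) {
        emptySites <- data.frame(accession = character(),
                                 position = integer(),
                                 residue = character(),
                                 modName = character(), degree = integer(),
                                 nSupport = integer(),
                                 nUnambiguous = integer(),
                                 spectrumIds = character(),
                                 peptides = character(),
                                 stringsAsFactors = FALSE)
        audit <- data.frame(
            stage = c("modified_matches", "filter1_not_unmodified",
                      "filter2_no_DE", "filter3_overlap",
                      "filter4_unambiguous_anchor", "filter5_support"),
            nMatches = 0L)
        return(list(sites = emptySites, audit = audit,
                    tolerances = tolerances, matches = mod))
    }
    mod <- classifyAmbiguity(mod)

    audit <- data.frame(stage = "modified_matches", nMatches = nrow(mod))
    f1 <- if (is.null(unmod)) mod else filter1NotUnmodified(mod, unmod)
    audit <- rbind(audit, data.frame(stage = "filter1_not_unmodified",
                                     nMatches = nrow(f1)))
    f2 <- if (applyFilter2) filter2NoDE(f1) else f1
    audit <- rbind(audit, data.frame(stage = "filter2_no_DE",
                                     nMatches = nrow(f2)))
    f3 <- filter3Overlap(f2, distinctPeptides = distinctPeptides)
    audit <- rbind(audit, data.frame(stage = "filter3_overlap",
                                     nMatches = nrow(f3)))
    f4 <- filter4UnambiguousAnchor(f3)
    audit <- rbind(audit, data.frame(stage = "filter4_unambiguous_anchor",
                                     nMatches = nrow(f4)))
    sites <- filter5SiteConsensus(f4, proteins,
                                  distinctPeptides = distinctPeptides)
    sup <- attr(sites, "supportIndex")
    audit <- rbind(audit, data.frame(stage = "filter5_support",
                                     nMatches = length(sup)))
    list(sites = sites, audit = audit, tolerances = tolerances,
         matches = f4[sup, , drop = FALSE])
}
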