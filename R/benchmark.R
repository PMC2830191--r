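# In-silico benchmarking: artificial methylation test sets and the
# true-positive rate of the mass-delta matching strategy. The TP rate
# here is a precision over matches, TP / (TP + FP): a match is a true
# positive only when residue, sequence position and methylation type
# are all correct.

.METHYL_CLASSES <- data.frame(
    class = c("monomethyl-K", "dimethyl-K", "monomethyl-R", "dimethyl-R"),
    modName = c("monomethyl", "dimethyl", "monomethyl", "dimethyl"),
    residue = c("K", "K", "R", "R"),
    degree = c(1L, 2L, 1L, 2L),
    stringsAsFactors = FALSE)

#' Build an artificial methylation test set
#'
#' Randomly samples a fraction of the proteome's lysine (and,
#' independently, arginine) residues and emits the theoretical masses of
#' the methylated peptides that would be observed: all host peptides
#' with at most one missed cleavage, all oxidation variants, restricted
#' to modified masses between `massRange[1]` and `massRange[2]` Da. The
#' sampling is repeated independently per methylation class
#' (mono/di-methyl on K and R). Lysine tri-methylation is excluded
#' (near-isobaric to lysine acetylation).
#'
#' @param proteins A [ProteinSet-class].
#' @param fraction Fraction of eligible residues sampled per class
#'   (default 0.06).
#' @param seed Integer seed; sampling is bit-for-bit reproducible.
#' @param massRange Allowed modified [M+H]+ mass window, Da.
#' @param maxMissed,suppressProline,oxidationCap Digestion parameters.
#' @return List with `sites` (data.frame `accession`, `position`,
#'   `residue`, `degree`, `class`, `provenance = "artificial"`) and
#'   `queries` (one row per benchmark peptide mass: site fields plus
#'   `sequence`, `start`, `end`, `missedCleavages`, `oxidationCount`,
#'   `queryMass`).
#' @export
buildArtificialSet <- function(proteins, fraction = 0.06, seed = 1L,
                               massRange = c(500, 3000),
                               maxMissed = 1L, suppressProline = TRUE,
                               oxidationCap = 2L) {
    stopifnot(fraction > 0, fraction <= 1)
    seqs <- sequences(proteins)
    if (!any(grepl("[KR]", seqs)))
        stop("proteome contains no K or R residues")
    pep <- digestProtein(proteins, maxMissed = maxMissed,
                         suppressProline = suppressProline,
                         oxidationCap = oxidationCap)
    mt <- methylModificationTable()
    set.seed(as.integer(seed))
    sitesL <- list(); queriesL <- list()
    for (k in seq_len(nrow(.METHYL_CLASSES))) {
        cls <- .METHYL_CLASSES[k, ]
        delta <- mt$delta[mt$name == cls$modName]
        for (acc in names(seqs)) {
            aa <- strsplit(seqs[[acc]], "", fixed = TRUE)[[1]]
            pos <- which(aa == cls$residue)
            if (!length(pos)) next
            pick <- pos[stats::runif(length(pos)) < fraction]
            if (!length(pick)) next
            ppep <- pep[pep$parent == acc, , drop = FALSE]
            for (p in pick) {
                host <- ppep[ppep$start <= p & ppep$end >= p, ,
                             drop = FALSE]
                host$queryMass <- host$mhMass + delta
                host <- host[host$queryMass >= massRange[1] &
                             host$queryMass <= massRange[2], ,
                             drop = FALSE]
                if (!nrow(host)) next
                sitesL[[length(sitesL) + 1L]] <- data.frame(
                    accession = acc, position = p,
                    residue = cls$residue, degree = cls$degree,
                    class = cls$class, provenance = "artificial",
                    stringsAsFactors = FALSE)
                host$accession <- acc
                host$position <- p
                host$residue <- cls$residue
                host$degree <- cls$degree
                host$class <- cls$class
                queriesL[[length(queriesL) + 1L]] <- host[, c(
                    "accession", "position", "residue", "degree", "class",
                    "sequence", "start", "end", "missedCleavages",
                    "oxidationCount", "queryMass")]
            }
        }
    }
    list(sites = if (length(sitesL)) do.call(rbind, sitesL) else NULL,
         queries = if (length(queriesL)) do.call(rbind, queriesL) else NULL)
}

#' Read a known-methylation benchmark from TSV
#'
#' Columns: `accession`, `position`, `residue` (K/R), `degree` (1/2).
#' Emits the same query structure as [buildArtificialSet()].
#'
#' @param path TSV of annotated sites.
#' @param proteins A [ProteinSet-class] providing the sequences.
#' @param massRange,maxMissed,suppressProline,oxidationCap As in
#'   [buildArtificialSet()].
#' @return As [buildArtificialSet()], with `provenance = "known"`.
#' @export
readKnownSet <- function(path, proteins, massRange = c(500, 3000),
                         maxMissed = 1L, suppressProline = TRUE,
                         oxidationCap = 2L) {
    ann <- utils::read.delim(path, stringsAsFactors = FALSE)
    stopifnot(all(c("accession", "position", "residue", "degree") %in%
                  names(ann)))
    seqs <- sequences(proteins)
    mt <- methylModificationTable()
    pep <- digestProtein(proteins, maxMissed = maxMissed,
                         suppressProline = suppressProline,
                         oxidationCap = oxidationCap)
    sitesL <- list(); queriesL <- list()
    for (i in seq_len(nrow(ann))) {
        acc <- ann$accession[i]; p <- ann$position[i]
        if (!acc %in% names(seqs)) next
        if (substr(seqs[[acc]], p, p) != ann$residue[i])
            stop("residue mismatch at ", acc, " position ", p)
        cls <- .METHYL_CLASSES[.METHYL_CLASSES$residue == ann$residue[i] &
                               .METHYL_CLASSES$degree == ann$degree[i], ]
        if (!nrow(cls)) next
        delta <- mt$delta[mt$name == cls$modName]
        host <- pep[pep$parent == acc & pep$start <= p & pep$end >= p, ,
                    drop = FALSE]
        host$queryMass <- host$mhMass + delta
        host <- host[host$queryMass >= massRange[1] &
                     host$queryMass <= massRange[2], , drop = FALSE]
        if (!nrow(host)) next
        sitesL[[length(sitesL) + 1L]] <- data.frame(
            accession = acc, position = p, residue = ann$residue[i],
            degree = ann$degree[i], class = cls$class,
            provenance = "known", stringsAsFactors = FALSE)
        host$accession <- acc; host$position <- p
        host$residue <- ann$residue[i]; host$degree <- ann$degree[i]
        host$class <- cls$class
        queriesL[[length(queriesL) + 1L]] <- host[, c(
            "accession", "position", "residue", "degree", "class",
            "sequence", "start", "end", "missedCleavages",
            "oxidationCount", "queryMass")]
    }
    list(sites = if (length(sitesL)) do.call(rbind, sitesL) else NULL,
         queries = if (length(queriesL)) do.call(rbind, queriesL) else NULL)
}

#' Evaluate the true-positive rate of delta matching on a benchmark
#'
#' Each benchmark query mass is matched against all singly-modified
#' theoretical peptides of its protein at the given tolerance; the D/E
#' filter is not applied since no esterification artifact exists in
#' silico. A match is a true positive when its modification equals the
#' planted methylation type and the planted position lies in its
#' candidate set; every other match is a false positive. The rate per
#' class is `100 * TP / (TP + FP)`. Recall (fraction of planted sites
#' recovered by at least one true-positive match) is reported
#' separately; it is not part of the TP-rate definition.
#'
#' @param benchmark A list from [buildArtificialSet()] /
#'   [readKnownSet()].
#' @param proteins A [ProteinSet-class].
#' @param modTable Modification table used for the screen.
#' @param tolerance Match tolerance, Da (default 0.04).
#' @param minSites Classes with fewer tested sites are flagged `ND`.
#' @param maxMissed,suppressProline,oxidationCap Digestion parameters
#'   (must mirror those used to build the benchmark).
#' @return data.frame per class: `class`, `tpRate` (percent), `nTP`,
#'   `nFP`, `nSites`, `nPeptides`, `recall`, `ND`.
#' @export
evaluateTpRate <- function(benchmark, proteins,
                           modTable = modificationTable(),
                           tolerance = 0.04, minSites = 10L,
                           maxMissed = 1L, suppressProline = TRUE,
                           oxidationCap = 2L) {
    q <- benchmark$queries
    if (is.null(q) || !nrow(q)) {
        warning("no benchmark queries; TP rate undefined")
        return(data.frame(class = .METHYL_CLASSES$class, tpRate = NA_real_,
                          nTP = 0L, nFP = 0L, nSites = 0L, nPeptides = 0L,
                          recall = NA_real_, ND = TRUE))
    }
    accs <- unique(q$accession)
    digests <- lapply(accs, function(a)
        digestProtein(proteins[a], maxMissed = maxMissed,
                      suppressProline = suppressProline,
                      oxidationCap = oxidationCap))
    names(digests) <- accs
    q$nTP <- 0L; q$nFP <- 0L
    for (i in seq_len(nrow(q))) {
        m <- matchModified(q$queryMass[i], digests[[q$accession[i]]],
                           modTable, tolerance,
                           spectrumId = "benchmark")
        if (!nrow(m)) next
        # correct type AND the planted position assignable in the match
        mName <- .METHYL_CLASSES$modName[.METHYL_CLASSES$class == q$class[i]]
        tp <- m$modName == mName & vapply(
            m$candidatePositions, function(cp) q$position[i] %in% cp,
            logical(1))
        # collapse oxidation variants of one (peptide, modification)
        ident <- paste(m$sequence, m$modName, tp, sep = "\r")
        dup <- duplicated(ident)
        q$nTP[i] <- sum(tp[!dup])
        q$nFP[i] <- sum(!tp[!dup])
    }
    out <- lapply(split(q, q$class), function(d) {
        tp <- sum(d$nTP); fp <- sum(d$nFP)
        siteKey <- paste(d$accession, d$position)
        nS <- length(unique(siteKey))
        rec <- length(unique(siteKey[d$nTP > 0])) / nS
        data.frame(class = d$class[1],
                   tpRate = if (tp + fp > 0) 100 * tp / (tp + fp)
                            else NA_real_,
                   nTP = tp, nFP = fp, nSites = nS, nPeptides = nrow(d),
                   recall = rec, ND = nS < minSites,
                   stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

#' TP rate across a tolerance grid
#'
#' @param benchmark,proteins,modTable See [evaluateTpRate()].
#' @param tolerances Numeric grid of tolerances, Da.
#' @param ... Passed to [evaluateTpRate()].
#' @return data.frame with one row per (tolerance, class).
#' @export
tpRateOverTolerances <- function(benchmark, proteins,
                                 modTable = modificationTable(),
                                 tolerances = seq(0.01, 0.10, by = 0.01),
                                 ...) {
    out <- lapply(tolerances, function(tol) {
        r <- evaluateTpRate(benchmark, proteins, modTable,
                            tolerance = tol, ...)
        r$tolerance <- tol
        r
    })
    do.call(rbind, out)
}
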