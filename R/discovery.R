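# Peptide and residue discovery rates, and the comparative statistics
# over them. The identification unit is one replicate spectrum assigned
# to a protein group; paralogs with identical mature sequences are
# pooled because fingerprinting cannot tell them apart.

#' Group accessions with identical mature sequences
#'
#' @param proteins A [ProteinSet-class].
#' @return data.frame `accession`, `group` (the lexicographically first
#'   accession of each identical-sequence group).
#' @export
paralogGroups <- function(proteins) {
    seqs <- matureSequence(proteins)
    grp <- vapply(split(names(seqs), unname(seqs)), function(a)
        min(a), character(1))
    rep <- grp[unname(seqs)]
    data.frame(accession = names(seqs), group = unname(rep),
               stringsAsFactors = FALSE)
}

#' Discovery rate of a peptide mass within a protein group
#'
#' The fraction of the group's replicate identifications (spectra) in
#' which a peak matches the peptide mass within `wideTolerance`. A wide
#' tolerance (default 1.5 Da) is used so that every available spectrum
#' contributes, trading mass specificity for sample size.
#'
#' @param mass Theoretical [M+H]+ mass of the (possibly modified)
#'   peptide, Da.
#' @param spectra A [SpectrumSet-class] restricted to the group's
#'   spectra.
#' @param wideTolerance Matching tolerance in Da.
#' @return List with `rate` (fraction in `[0, 1]`), `nObserved` and
#'   `nIdentifications`. With zero identifications the record is
#'   undefined: `rate` is `NA` with a warning.
#' @export
peptideDiscoveryRate <- function(mass, spectra, wideTolerance = 1.5) {
    n <- length(spectra)
    if (n == 0L) {
        warning("no identifications for group; rate undefined")
        return(list(rate = NA_real_, nObserved = 0L, nIdentifications = 0L))
    }
    obs <- vapply(peakList(spectra), function(p)
        length(p) > 0 && min(abs(p - mass)) <= wideTolerance, logical(1))
    list(rate = sum(obs) / n, nObserved = sum(obs), nIdentifications = n)
}

#' Discovery rates for a table of peptides
#'
#' Computes [peptideDiscoveryRate()] for each row of a peptide table,
#' pooling spectra over paralog groups.
#'
#' @param peptides data.frame with columns `parent`, `sequence`,
#'   `start`, `end` and a mass column (`mhMass`, or `modMass` for
#'   modified peptides, selected via `massColumn`).
#' @param spectra A [SpectrumSet-class] (all spectra; grouping is
#'   internal).
#' @param proteins A [ProteinSet-class] used for paralog grouping.
#' @param wideTolerance Matching tolerance in Da (default 1.5).
#' @param massColumn Name of the mass column to match.
#' @return `peptides` with added `group`, `rate`, `nObserved`,
#'   `nIdentifications`; rows of groups without identifications are
#'   dropped with a warning.
#' @export
discoveryRates <- function(peptides, spectra, proteins,
                           wideTolerance = 1.5, massColumn = "mhMass") {
    pg <- paralogGroups(proteins)
    grp <- stats::setNames(pg$group, pg$accession)
    sgrp <- grp[accessions(spectra)]
    peptides$group <- unname(grp[peptides$parent])
    res <- lapply(seq_len(nrow(peptides)), function(i) {
        sub <- spectra[!is.na(sgrp) & sgrp == peptides$group[i]]
        if (length(sub) == 0L)
            return(c(NA_real_, NA_real_, 0))
        r <- peptideDiscoveryRate(peptides[[massColumn]][i], sub,
                                  wideTolerance)
        c(r$rate, r$nObserved, r$nIdentifications)
    })
    res <- do.call(rbind, res)
    peptides$rate <- res[, 1]
    peptides$nObserved <- as.integer(res[, 2])
    peptides$nIdentifications <- as.integer(res[, 3])
    drop <- peptides$nIdentifications == 0L
    if (any(drop)) {
        warning(sum(drop), " peptide(s) in groups with no identifications ",
                "skipped")
        peptides <- peptides[!drop, , drop = FALSE]
    }
    peptides
}

#' Discovery rate of a residue
#'
#' The sum of the discovery rates of all distinct peptides whose
#' coordinates cover the residue (the same definition applies to
#' methylated residues over methylated peptides).
#'
#' @param position 1-based residue coordinate.
#' @param peptideRates Rate table from [discoveryRates()] restricted to
#'   one protein group (columns `sequence`, `start`, `end`, `rate`).
#' @return Nonnegative numeric rate.
#' @export
residueDiscoveryRate <- function(position, peptideRates) {
    cov <- peptideRates[peptideRates$start <= position &
                        peptideRates$end >= position, , drop = FALSE]
    if (!nrow(cov)) return(0)
    # distinct peptides only: one rate per unique sequence
    cov <- cov[!duplicated(cov$sequence), , drop = FALSE]
    sum(cov$rate)
}

#' Compare methylated against unmodified discovery rates
#'
#' Two-sided Mann-Whitney (rank-sum) test between the two rate samples,
#' and a Kendall rank correlation over the paired residues (positions
#' observed both methylated and unmodified).
#'
#' @param methylRates Numeric vector of methylated-peptide (or residue)
#'   rates.
#' @param unmodRates Numeric vector of unmodified rates.
#' @param paired Optional data.frame with columns `methylated` and
#'   `unmodified` holding the paired residue rates.
#' @return List: `medianMethylated`, `medianUnmodified`, `wilcoxP`, and
#'   (when `paired` has at least 3 rows) `kendallTau`, `kendallP`.
#' @export
compareRates <- function(methylRates, unmodRates, paired = NULL) {
    stopifnot(length(methylRates) > 0, length(unmodRates) > 0)
    wt <- stats::wilcox.test(methylRates, unmodRates, exact = FALSE)
    out <- list(medianMethylated = stats::median(methylRates),
                medianUnmodified = stats::median(unmodRates),
                wilcoxP = wt$p.value,
                kendallTau = NA_real_, kendallP = NA_real_)
    if (!is.null(paired)) {
        if (nrow(paired) < 3L) {
            warning("fewer than 3 paired residues; correlation skipped")
        } else {
            ct <- suppressWarnings(
                stats::cor.test(paired$methylated, paired$unmodified,
                                method = "kendall"))
            out$kendallTau <- unname(ct$estimate)
            out$kendallP <- ct$p.value
        }
    }
    out
}
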