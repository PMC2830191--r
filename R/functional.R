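# Functional co-analysis of methylated proteins: GO slim enrichment,
# abundance / half-life group comparisons, and overlap with other
# modifications. All tests are nonparametric.

#' GO slim term enrichment of methylated proteins
#'
#' For each term, builds the 2x2 contingency table (methylated with /
#' without the term against non-methylated with / without) over the
#' annotated universe and computes a one-sided (enrichment) Fisher
#' exact p-value with Bonferroni correction. Each ontology branch
#' should be corrected independently: pass one branch at a time, or the
#' full table with the correction factor of your choice via `nTests`.
#'
#' @param methylated Character vector of methylated-protein accessions.
#' @param annotation data.frame with columns `accession`, `term` (one
#'   row per accession-term pair; proteins with no terms simply do not
#'   appear).
#' @param universe Character vector of all annotated accessions under
#'   consideration; every protein in it is assumed annotated (possibly
#'   with an empty term set).
#' @param nTests Bonferroni factor; defaults to the number of distinct
#'   terms tested.
#' @return data.frame per term: `term`, `n11`, `n12`, `n21`, `n22`,
#'   `p`, `pBonferroni`, sorted by `p`.
#' @export
goEnrichment <- function(methylated, annotation, universe,
                         nTests = NULL) {
    methylated <- intersect(unique(methylated), universe)
    terms <- unique(annotation$term)
    drop <- !annotation$accession %in% universe
    if (any(drop)) {
        warning(sum(drop), " annotation row(s) outside the universe ",
                "skipped")
        annotation <- annotation[!drop, , drop = FALSE]
    }
    terms <- terms[terms %in% annotation$term]
    if (is.null(nTests)) nTests <- length(terms)
    nMeth <- length(methylated)
    nOther <- length(universe) - nMeth
    rows <- lapply(terms, function(tm) {
        withTerm <- unique(annotation$accession[annotation$term == tm])
        n11 <- sum(methylated %in% withTerm)
        n12 <- nMeth - n11
        n21 <- length(setdiff(withTerm, methylated))
        n22 <- nOther - n21
        p <- stats::fisher.test(matrix(c(n11, n21, n12, n22), nrow = 2),
                                alternative = "greater")$p.value
        data.frame(term = tm, n11 = n11, n12 = n12, n21 = n21, n22 = n22,
                   p = p, pBonferroni = min(1, p * nTests),
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out[order(out$p), , drop = FALSE]
}

#' One-sided Fisher test on a printed contingency table
#'
#' Convenience for re-testing a published 2x2 table (methylated
#' with/without term, non-methylated with/without term).
#'
#' @param n11,n12,n21,n22 The four cells.
#' @return One-sided (enrichment) Fisher exact p-value.
#' @export
fisherEnrichment <- function(n11, n12, n21, n22) {
    stats::fisher.test(matrix(c(n11, n21, n12, n22), nrow = 2),
                       alternative = "greater")$p.value
}

#' Compare a numeric annotation between methylated and other proteins
#'
#' Mann-Whitney (two-sided rank-sum) comparison of e.g. abundance
#' (copies/cell) or half-life (minutes); missing values are dropped.
#'
#' @param methylValues Numeric values of the methylated proteins.
#' @param otherValues Numeric values of the comparison group.
#' @return List: `medianMethylated`, `medianOther`, `p`, `nMethylated`,
#'   `nOther`.
#' @export
groupCompare <- function(methylValues, otherValues) {
    x <- methylValues[!is.na(methylValues)]
    y <- otherValues[!is.na(otherValues)]
    if (!length(x) || !length(y))
        stop("a group is empty after dropping missing values")
    exact <- (length(x) * length(y) < 1e4) && !any(duplicated(c(x, y)))
    p <- stats::wilcox.test(x, y, exact = exact)$p.value
    list(medianMethylated = stats::median(x),
         medianOther = stats::median(y),
         p = p, nMethylated = length(x), nOther = length(y))
}

#' Overlap of methylation with a binary modification flag
#'
#' Reports what fraction of methylated proteins (or sites) carry
#' another annotation, e.g. known phosphorylation or predicted
#' ubiquitination. Percentages round half-up to integers, matching the
#' convention of reporting e.g. 30/32 as 94%.
#'
#' @param flags Logical vector, one per methylated protein/site.
#' @return List: `nFlagged`, `nTotal`, `percent`.
#' @export
interplayProportion <- function(flags) {
    flags <- as.logical(flags)
    if (!length(flags))
        stop("empty set")
    n <- sum(flags)
    list(nFlagged = n, nTotal = length(flags),
         percent = floor(100 * n / length(flags) + 0.5))
}
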