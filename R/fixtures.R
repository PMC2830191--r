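# Packaged reference fixtures -- transcriptions of the published
# high-confidence site list, motif windows and GO contingency tables --
# with parsing, self-consistency checks and tally helpers. Having them
# inside the package lets the fixture arithmetic and motif analyses run
# with no network access.

#' Parse site tokens like "mK121" or "dR35"
#'
#' The site notation is `(m|d)(K|R)<position>`: `m` = monomethyl
#' (degree 1), `d` = dimethyl (degree 2), on lysine or arginine.
#'
#' @param token Character vector of site tokens.
#' @return data.frame `token`, `degree`, `residue`, `position`.
#' @examples
#' parseSiteToken(c("mK121", "dR35"))
#' @export
parseSiteToken <- function(token) {
    m <- regmatches(token, regexec("^([md])([KR])([0-9]+)$", token))
    bad <- lengths(m) != 4L
    if (any(bad))
        stop("malformed site token(s): ",
             paste(token[bad], collapse = ", "))
    data.frame(
        token = token,
        degree = ifelse(vapply(m, `[`, character(1), 2) == "m", 1L, 2L),
        residue = vapply(m, `[`, character(1), 3),
        position = as.integer(vapply(m, `[`, character(1), 4)),
        stringsAsFactors = FALSE)
}

.fixturePath <- function(file)
    system.file("extdata", file, package = "MethylPMF", mustWork = TRUE)

#' Published high-confidence methylation site fixture
#'
#' The packaged transcription of the published site list (one row per
#' protein, comma-separated site tokens), expanded to one row per site
#' with parsed degree, residue and position. Tokens are validated at
#' load time.
#'
#' @return data.frame `gene`, `accession`, `description`, `token`,
#'   `degree`, `residue`, `position`.
#' @export
methylationSiteFixture <- function() {
    tab <- utils::read.delim(.fixturePath("table1_sites.tsv"),
                             stringsAsFactors = FALSE)
    toks <- strsplit(tab$sites, ",", fixed = TRUE)
    idx <- rep(seq_len(nrow(tab)), lengths(toks))
    parsed <- parseSiteToken(unlist(toks))
    cbind(tab[idx, c("gene", "accession", "description")], parsed,
          row.names = NULL)
}

#' Tallies over the site fixture
#'
#' @param sites The expanded fixture from [methylationSiteFixture()]
#'   (loaded automatically when omitted).
#' @return Named list of counts: lysine / arginine sites, mono/di
#'   breakdowns, total sites, protein rows, and proteins carrying both
#'   lysine and arginine methylation.
#' @export
siteTallies <- function(sites = methylationSiteFixture()) {
    byGene <- split(sites$residue, sites$gene)
    list(
        lysineSites = sum(sites$residue == "K"),
        arginineSites = sum(sites$residue == "R"),
        monomethylK = sum(sites$residue == "K" & sites$degree == 1L),
        dimethylK = sum(sites$residue == "K" & sites$degree == 2L),
        monomethylR = sum(sites$residue == "R" & sites$degree == 1L),
        dimethylR = sum(sites$residue == "R" & sites$degree == 2L),
        totalSites = nrow(sites),
        proteins = length(byGene),
        lysineProteins = sum(vapply(byGene, function(r) "K" %in% r,
                                    logical(1))),
        arginineProteins = sum(vapply(byGene, function(r) "R" %in% r,
                                      logical(1))),
        dualMethylated = sum(vapply(byGene, function(r)
            all(c("K", "R") %in% r), logical(1))))
}

#' Published methylation motif window fixture
#'
#' The packaged transcription of the published motif table: one row per
#' (site, motif-section) with the 21-residue window centred on the
#' modified residue. The centre letter of every window is checked
#' against the site residue at load time.
#'
#' @return data.frame `section`, `gene`, `accession`, `residue`,
#'   `position`, `degree`, `provenance` (`findmod` or `literature`),
#'   `window`.
#' @export
motifWindowFixture <- function() {
    tab <- utils::read.delim(.fixturePath("table5_motifs.tsv"),
                             stringsAsFactors = FALSE)
    centre <- substr(tab$window, 11, 11)
    if (any(centre != tab$residue))
        stop("motif fixture corrupt: window centre does not match residue",
             " for ", paste(tab$gene[centre != tab$residue],
                            collapse = ", "))
    tab
}

#' Motif-class counts over the window fixture
#'
#' Runs [matchMotif()] over the fixture windows and counts the distinct
#' methylated residues (unique accession + position) matching each
#' motif class: `RXG or RGX` (G at +1 or +2 of an R site), `GXXRXG`,
#' `WXXXR`, and the `MK` motif restricted to sites of the given
#' provenance.
#'
#' @param windows Fixture from [motifWindowFixture()].
#' @param mkProvenance Provenance filter for the MK count (default
#'   `"findmod"`: sites found by the mass-fingerprint screen itself).
#' @return Named list `rxg_rgx`, `gxxrxg`, `wxxxr`, `mk`.
#' @export
motifClassCounts <- function(windows = motifWindowFixture(),
                             mkProvenance = "findmod") {
    uniq <- windows[!duplicated(paste(windows$accession,
                                      windows$position)), , drop = FALSE]
    w <- lapply(uniq$window, windowFromString)
    isR <- uniq$residue == "R"
    isK <- uniq$residue == "K"
    rgx <- vapply(w, matchMotif, logical(1), pattern = "RG", center = 1)
    rxg <- vapply(w, matchMotif, logical(1), pattern = "RXG", center = 1)
    gxxrxg <- vapply(w, matchMotif, logical(1), pattern = "GXXRXG",
                     center = 4)
    wxxxr <- vapply(w, matchMotif, logical(1), pattern = "WXXXR",
                    center = 5)
    mk <- vapply(w, matchMotif, logical(1), pattern = "MK", center = 2)
    list(rxg_rgx = sum(isR & (rgx | rxg)),
         gxxrxg = sum(isR & gxxrxg),
         wxxxr = sum(isR & wxxxr),
         mk = sum(isK & mk & uniq$provenance == mkProvenance))
}

#' Published GO contingency-table fixture
#'
#' Per-branch contingency tables (methylated with/without term,
#' non-methylated with/without term) and the published
#' Bonferroni-corrected p-values.
#'
#' @return data.frame `branch`, `rank`, `term`, `go_id`, `n11`, `n12`,
#'   `n21`, `n22`, `corrected_p`.
#' @export
goContingencyFixture <- function() {
    tab <- utils::read.delim(.fixturePath("table4_go.tsv"),
                             stringsAsFactors = FALSE)
    if (any(tab$n11 < 0 | tab$n12 < 0 | tab$n21 < 0 | tab$n22 < 0))
        stop("GO fixture corrupt: negative counts")
    tab
}
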