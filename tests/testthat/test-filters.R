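# The five confidence filters and the end-to-end driver.

test_that("filter 1 vetoes query masses that also match unmodified
           peptides", {
    mod <- bindMatches(
        makeMatch(start = 10, end = 20, sequence = "GLVKAAAGGGR",
                  candidatePositions = list(13L), queryMass = 1000),
        makeMatch(start = 30, end = 40, sequence = "TTTKSSSSGGR",
                  candidatePositions = list(33L), queryMass = 1400))
    unmod <- makeMatch(start = 50, end = 60, sequence = "AAAAAGGGGGR",
                       modName = NA_character_, queryMass = 1000)
    out <- filter1NotUnmodified(mod, unmod)
    expect_equal(out$queryMass, 1400)
    expect_equal(nrow(filter1NotUnmodified(mod[0, ], unmod)), 0L)
})

test_that("filter 2 removes D/E-containing peptides", {
    m <- bindMatches(
        makeMatch(start = 1, end = 4, sequence = "GLDK",
                  candidatePositions = list(4L)),
        makeMatch(start = 1, end = 4, sequence = "GLVK",
                  candidatePositions = list(4L)),
        makeMatch(start = 1, end = 4, sequence = "EEEE",
                  candidatePositions = list(1L)))
    expect_identical(filter2NoDE(m)$sequence, "GLVK")
})

test_that("filter 3 groups overlapping peptides sharing a candidate", {
    # cleaved + read-through sharing K17: kept (scenario a)
    a <- bindMatches(
        makeMatch(start = 10, end = 20, sequence = "AAAAAAAKAAK",
                  missedCleavages = 0L, candidatePositions = list(17L),
                  spectrumId = "s1"),
        makeMatch(start = 10, end = 28, sequence = "AAAAAAAKAAKAAAAAAAR",
                  missedCleavages = 1L,
                  candidatePositions = list(c(17L, 20L)),
                  spectrumId = "s2", queryMass = 2000))
    out <- filter3Overlap(a)
    expect_equal(nrow(out), 2L)
    expect_length(unique(out$groupId), 1L)

    # disjoint coordinates: removed
    b <- bindMatches(
        makeMatch(start = 10, end = 20, sequence = "AAAAAAAKAAK",
                  candidatePositions = list(17L)),
        makeMatch(start = 30, end = 40, sequence = "CCCCCCCKCCC",
                  candidatePositions = list(37L), queryMass = 1800))
    expect_equal(nrow(filter3Overlap(b)), 0L)

    # two 1-MC peptides sharing the site: kept (scenario b)
    c2 <- bindMatches(
        makeMatch(start = 5, end = 20, sequence = "AAAAAAAAAAAAKAAK",
                  missedCleavages = 1L, candidatePositions = list(17L)),
        makeMatch(start = 10, end = 28, sequence = "AAAAAAAKAAKAAAAAAAR",
                  missedCleavages = 1L, candidatePositions = list(c(17L)),
                  queryMass = 2100))
    expect_equal(nrow(filter3Overlap(c2)), 2L)

    # overlap in coordinates but no shared candidate position: removed
    d <- bindMatches(
        makeMatch(start = 10, end = 20, sequence = "AAAAAAAKAAK",
                  candidatePositions = list(17L)),
        makeMatch(start = 15, end = 25, sequence = "AAKAAKAAAAR",
                  candidatePositions = list(20L), queryMass = 2200))
    expect_equal(nrow(filter3Overlap(d)), 0L)

    # mono and di never share a group
    e <- bindMatches(
        makeMatch(start = 10, end = 20, sequence = "AAAAAAAKAAK",
                  modName = "monomethyl", degree = 1L,
                  candidatePositions = list(17L)),
        makeMatch(start = 10, end = 28, sequence = "AAAAAAAKAAKAAAAAAAR",
                  modName = "dimethyl", degree = 2L,
                  candidatePositions = list(17L), queryMass = 2300))
    expect_equal(nrow(filter3Overlap(e)), 0L)
})

test_that("filter 3 can count match instances instead of distinct
           peptides", {
    same <- bindMatches(
        makeMatch(start = 10, end = 20, sequence = "AAAAAAAKAAK",
                  candidatePositions = list(17L), spectrumId = "s1"),
        makeMatch(start = 10, end = 20, sequence = "AAAAAAAKAAK",
                  candidatePositions = list(17L), spectrumId = "s2"))
    expect_equal(nrow(filter3Overlap(same)), 0L)
    expect_equal(nrow(filter3Overlap(same, distinctPeptides = FALSE)), 2L)
})

test_that("filter 4 keeps only groups with an unambiguous anchor", {
    g <- filter3Overlap(bindMatches(
        makeMatch(start = 10, end = 20, sequence = "AAAAAAAKAAK",
                  candidatePositions = list(17L), ambiguous = FALSE),
        makeMatch(start = 10, end = 28, sequence = "AAAAAAAKAAKAAAAAAAR",
                  candidatePositions = list(17L), ambiguous = TRUE,
                  queryMass = 2000)))
    expect_equal(nrow(filter4UnambiguousAnchor(g)), 2L)
    g$ambiguous <- TRUE
    expect_equal(nrow(filter4UnambiguousAnchor(g)), 0L)
    g$ambiguous <- FALSE
    expect_equal(nrow(filter4UnambiguousAnchor(g)), 2L)
})

test_that("filter 5 intersects candidate sets into consensus sites", {
    prot <- ProteinSet(c(P1 = paste0(strrep("A", 16), "K",
                                     strrep("A", 7), "K", strrep("A", 6))))
    base <- filter3Overlap(bindMatches(
        makeMatch(start = 10, end = 20, sequence = "AAAAAAAKAAA",
                  candidatePositions = list(17L)),
        makeMatch(start = 10, end = 28, sequence = "AAAAAAAKAAAAAAAKAAA",
                  candidatePositions = list(c(17L, 25L)),
                  queryMass = 2000)))
    sites <- filter5SiteConsensus(base, prot)
    expect_equal(nrow(sites), 1L)
    expect_equal(sites$position, 17L)
    expect_equal(sites$residue, "K")
    expect_equal(sites$nSupport, 2L)
    expect_gte(sites$nUnambiguous, 1L)

    # disjoint candidate sets cannot form a group, hence no site
    disj <- filter3Overlap(bindMatches(
        makeMatch(start = 10, end = 20, sequence = "AAAAAAAKAAA",
                  candidatePositions = list(17L)),
        makeMatch(start = 12, end = 28, sequence = "AAAAAAAAAAAAAKAAA",
                  candidatePositions = list(25L), queryMass = 2000)))
    expect_equal(nrow(filter5SiteConsensus(disj, prot)), 0L)
})

test_that("the pipeline recovers a hand-planted site end to end", {
    prot <- sitePlantProtein()
    res <- runPipeline(sitePlantSpectra(nRep = 3), prot,
                       modTable = methylModificationTable())
    expect_equal(nrow(res$sites), 1L)
    expect_equal(res$sites$accession, "TP1")
    expect_equal(res$sites$position, 6L)
    expect_equal(res$sites$residue, "K")
    expect_equal(res$sites$modName, "monomethyl")
    expect_gte(res$sites$nSupport, 2L)
    expect_gte(res$sites$nUnambiguous, 1L)
    # audit funnel is monotonically non-increasing
    expect_true(all(diff(res$audit$nMatches) <= 0))
})

test_that("dimethyl evidence yields a separate site of its own degree", {
    prot <- sitePlantProtein()
    res <- runPipeline(sitePlantSpectra(nRep = 3, degree = 2), prot,
                       modTable = methylModificationTable())
    expect_equal(res$sites$modName, "dimethyl")
    expect_equal(res$sites$degree, 2L)
})

test_that("single-peptide evidence is rejected by the overlap filter", {
    prot <- sitePlantProtein()
    pep <- digestProtein(prot, oxidationCap = 0L)
    unmod <- pep$mhMass[pep$missedCleavages == 0L]
    onlyCleaved <- mhMass("MAGLVK") + METHYL_DELTA
    spec <- SpectrumSet(sprintf("TP1_r%d", 1:3), rep("TP1", 3),
                        rep(list(sort(c(unmod, onlyCleaved))), 3))
    res <- runPipeline(spec, prot, modTable = methylModificationTable())
    expect_equal(nrow(res$sites), 0L)
    expect_gte(res$audit$nMatches[1], 1L)
})

test_that("pipeline rejects configurations without missed cleavages", {
    expect_error(runPipeline(sitePlantSpectra(), sitePlantProtein(),
                             maxMissed = 0L), "maxMissed")
})

test_that("empty spectra give an empty site table", {
    spec <- SpectrumSet(character(), character(), list())
    res <- runPipeline(spec, sitePlantProtein())
    expect_equal(nrow(res$sites), 0L)
    expect_true(all(res$audit$nMatches == 0L))
})
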