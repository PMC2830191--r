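# The synthetic-data generator and its statistical guarantees.

test_that("configuration validation catches bad inputs", {
    expect_error(simulationConfig(), "seed")
    badComp <- yeastResidueFrequencies()
    badComp["A"] <- badComp["A"] + 0.01
    expect_error(simulationConfig(seed = 1, residueFrequencies = badComp),
                 "sum to 1")
    expect_error(simulationConfig(seed = 1, detectionProb = 1.3),
                 "probabilities")
    expect_error(simulationConfig(seed = 1, minReplicates = 2L),
                 "3 replicate")
    expect_error(simulationConfig(seed = 1,
                                  degreeMix = c(mono = 0.7, di = 0.2)),
                 "degreeMix")
})

test_that("the generator is deterministic under its seed", {
    cfg <- simulationConfig(seed = 123L, nProteins = 6L)
    p1 <- generateProteome(cfg); p2 <- generateProteome(cfg)
    expect_identical(sequences(p1), sequences(p2))
    f1 <- tempfile(fileext = ".fasta"); f2 <- tempfile(fileext = ".fasta")
    writeProteinFasta(p1, f1); writeProteinFasta(p2, f2)
    expect_identical(readLines(f1), readLines(f2))
    t1 <- plantSites(p1, cfg); t2 <- plantSites(p2, cfg)
    expect_identical(t1, t2)
    s1 <- simulateSpectra(p1, t1, cfg); s2 <- simulateSpectra(p2, t2, cfg)
    expect_identical(peakList(s1), peakList(s2))
})

test_that("degenerate configurations behave as specified", {
    cfg0 <- simulationConfig(seed = 9L, nProteins = 0L)
    expect_equal(length(generateProteome(cfg0)), 0L)
    cfgNone <- simulationConfig(seed = 9L, nProteins = 5L,
                                fractionK = 0, fractionR = 0)
    prot <- generateProteome(cfgNone)
    expect_equal(nrow(plantSites(prot, cfgNone)), 0L)
})

test_that("planted truth is consistent with the proteome and the
           filter-compatibility contract", {
    cfg <- simulationConfig(seed = 77L, nProteins = 25L,
                            fractionK = 0.1, fractionR = 0.1)
    prot <- generateProteome(cfg)
    truth <- plantSites(prot, cfg)
    expect_gt(nrow(truth), 0L)
    seqs <- sequences(prot)
    for (i in seq_len(nrow(truth)))
        expect_identical(substr(seqs[[truth$accession[i]]],
                                truth$position[i], truth$position[i]),
                         truth$residue[i])
    # filter-compatible sites never sit on a D/E-containing host peptide
    pep <- digestProtein(prot, oxidationCap = 0L)
    for (i in seq_len(nrow(truth))) {
        host <- pep[pep$parent == truth$accession[i] &
                    pep$start <= truth$position[i] &
                    pep$end >= truth$position[i] &
                    pep$missedCleavages == 0L, ]
        expect_false(any(grepl("[DE]", host$sequence)))
    }
})

test_that("the noise-free limit emits exactly the theoretical masses", {
    cfg <- simulationConfig(seed = 13L, nProteins = 5L,
                            massErrorSd = 0, contaminantRate = 0,
                            siteStoichiometry = 1, detectionProb = 1,
                            missedCleavageDetectionProb = 0,
                            partialCleavageProb = 0.5)
    prot <- generateProteome(cfg)
    truth <- plantSites(prot, cfg)
    spec <- simulateSpectra(prot, truth, cfg)
    pep <- digestProtein(prot, oxidationCap = 0L)
    delta <- c(monomethyl = METHYL_DELTA, dimethyl = 2 * METHYL_DELTA)
    theo <- c(pep$mhMass,
              unlist(lapply(seq_len(nrow(truth)), function(i) {
                  host <- pep[pep$parent == truth$accession[i] &
                              pep$start <= truth$position[i] &
                              pep$end >= truth$position[i], ]
                  host$mhMass + delta[[truth$modName[i]]]
              })))
    for (p in peakList(spec))
        for (m in p)
            expect_lt(min(abs(m - theo)), 1e-9)
})

test_that("stoichiometry zero never emits methylated peaks", {
    cfg <- simulationConfig(seed = 19L, nProteins = 5L,
                            massErrorSd = 0, contaminantRate = 0,
                            siteStoichiometry = 0, detectionProb = 1)
    prot <- generateProteome(cfg)
    truth <- plantSites(prot, cfg)
    spec <- simulateSpectra(prot, truth, cfg)
    pep <- digestProtein(prot, oxidationCap = 0L)
    for (p in peakList(spec))
        for (m in p)
            expect_lt(min(abs(m - pep$mhMass)), 1e-9)
})

test_that("raising the mass error never increases recovery at fixed
           tolerance", {
    recovered <- vapply(c(0.005, 0.03, 0.08, 0.3), function(sig) {
        cfg <- simulationConfig(seed = 55L, nProteins = 10L,
                                fractionK = 0.2, fractionR = 0.2,
                                massErrorSd = sig)
        prot <- generateProteome(cfg)
        truth <- plantSites(prot, cfg)
        spec <- simulateSpectra(prot, truth, cfg)
        pep <- digestProtein(prot, oxidationCap = 0L)
        delta <- c(monomethyl = METHYL_DELTA, dimethyl = 2 * METHYL_DELTA)
        hits <- 0L
        for (i in seq_len(nrow(truth))) {
            host <- pep[pep$parent == truth$accession[i] &
                        pep$end == truth$position[i] &
                        pep$missedCleavages == 0L, ]
            if (!nrow(host)) next
            target <- host$mhMass[1] + delta[[truth$modName[i]]]
            for (p in peakList(spec[accessions(spec) ==
                                    truth$accession[i]]))
                if (length(p) && min(abs(p - target)) <= 0.04)
                    hits <- hits + 1L
        }
        hits
    }, integer(1))
    expect_true(all(diff(recovered) <= 0))
})

test_that("a written simulation round-trips through the readers", {
    cfg <- simulationConfig(seed = 29L, nProteins = 6L,
                            fractionK = 0.3, fractionR = 0.3)
    prot <- generateProteome(cfg)
    truth <- plantSites(prot, cfg)
    expect_gt(nrow(truth), 0L)
    spec <- simulateSpectra(prot, truth, cfg)
    dir <- tempfile("sim")
    writeSimulation(dir, prot, truth, spec, cfg)
    protBack <- readProteinFasta(file.path(dir, "proteome.fasta"))
    expect_identical(unname(sequences(protBack)),
                     unname(sequences(prot)))
    expect_identical(accessions(protBack), accessions(prot))
    specBack <- readSpectrumDir(file.path(dir, "spectra"))
    expect_equal(length(specBack), length(spec))
    # masses survive the 5-decimal text format
    orig <- peakList(spec)[[1]]
    back <- peakList(specBack)[[spectrumIds(spec)[1]]]
    expect_equal(back, orig, tolerance = 1e-4)
    truthBack <- readTSV(file.path(dir, "ground_truth.tsv"))
    expect_equal(truthBack$position, truth$position)
    manifest <- readLines(file.path(dir, "config_manifest.txt"))
    expect_true(any(grepl("^seed=29$", manifest)))
})
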