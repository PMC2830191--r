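# Builders for hand-constructed match tables and tiny spectra used in
# the filter tests.

makeMatch <- function(parent = "P1", start, end, sequence,
                      missedCleavages = 0L, modName = "monomethyl",
                      degree = 1L, candidatePositions = list(integer()),
                      spectrumId = "s1", queryMass = 1000,
                      ambiguous = FALSE, oxidationCount = 0L) {
    data.frame(parent = parent, start = start, end = end,
               sequence = sequence, missedCleavages = missedCleavages,
               oxidationCount = oxidationCount,
               mhMass = 1000, modName = modName, degree = degree,
               modMass = queryMass, spectrumId = spectrumId,
               queryMass = queryMass, massError = 0,
               ambiguous = ambiguous,
               stringsAsFactors = FALSE) -> d
    d$candidatePositions <- candidatePositions
    d
}

bindMatches <- function(...) do.call(rbind, list(...))

# A protein engineered so that one methylation site (the K of GLVK) has
# both a cleaved and a read-through tryptic host peptide, neither
# containing D or E.
sitePlantProtein <- function() {
    ProteinSet(c(TP1 = "MAGLVKSSLGGRTTTTTKAAAAWAAR"))
}

# Replicate noise-free spectra carrying both methylated host forms of
# K6 (mono), plus the unmodified fingerprint.
sitePlantSpectra <- function(nRep = 3, degree = 1) {
    pep <- digestProtein(sitePlantProtein(), oxidationCap = 0L)
    unmod <- pep$mhMass[pep$missedCleavages == 0L]
    d <- degree * METHYL_DELTA
    cleaved <- mhMass("MAGLVK") + d
    readthrough <- mhMass("MAGLVKSSLGGR") + d
    pk <- rep(list(sort(c(unmod, cleaved, readthrough))), nRep)
    SpectrumSet(sprintf("TP1_r%d", seq_len(nRep)),
                rep("TP1", nRep), pk)
}
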