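# Independent [M+H]+ mass oracle: parses elemental formula strings and
# sums atom counts across the peptide before multiplying by atomic
# masses -- a different computational route from the package's
# per-residue mass table, used to cross-check mass arithmetic.

.oracleAtomic <- c(C = 12.0, H = 1.00782503207, N = 14.0030740048,
                   O = 15.9949146196, S = 31.97207100)

.oracleFormulas <- c(
    A = "C3H5NO",  R = "C6H12N4O", N = "C4H6N2O2", D = "C4H5NO3",
    C = "C3H5NOS", E = "C5H7NO3",  Q = "C5H8N2O2", G = "C2H3NO",
    H = "C6H7N3O", I = "C6H11NO",  L = "C6H11NO",  K = "C6H12N2O",
    M = "C5H9NOS", F = "C9H9NO",   P = "C5H7NO",   S = "C3H5NO2",
    T = "C4H7NO2", W = "C11H10N2O", Y = "C9H9NO2", V = "C5H9NO")

.oracleParseFormula <- function(f) {
    parts <- regmatches(f, gregexpr("([CHNOS])([0-9]*)", f))[[1]]
    counts <- c(C = 0, H = 0, N = 0, O = 0, S = 0)
    for (p in parts) {
        el <- substr(p, 1, 1)
        k <- substr(p, 2, nchar(p))
        counts[el] <- counts[el] + if (nchar(k)) as.integer(k) else 1L
    }
    counts
}

oracleMhMass <- function(sequence, oxidation = 0L) {
    aa <- strsplit(sequence, "", fixed = TRUE)[[1]]
    atoms <- Reduce(`+`, lapply(.oracleFormulas[aa], .oracleParseFormula))
    atoms["H"] <- atoms["H"] + 2 + 1          # water + proton hydrogens
    atoms["O"] <- atoms["O"] + 1 + oxidation  # water + oxidations
    # proton: the extra H above over-counts the electron-less proton;
    # correct by subtracting one H atom and adding the bare proton mass
    sum(atoms * .oracleAtomic[names(atoms)]) -
        .oracleAtomic[["H"]] + 1.00727646688
}

randomPeptide <- function(len) {
    paste(sample(names(.oracleFormulas), len, replace = TRUE),
          collapse = "")
}
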