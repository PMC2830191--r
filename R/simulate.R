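# Synthetic data generator: random proteomes, planted methylation
# ground truth, and replicate MALDI-style peak lists with the
# statistical structure the discovery pipeline relies on --
# sub-stoichiometric methylated peaks, partial tryptic cleavage at
# methylated residues yielding overlapping missed-cleavage peptides,
# Gaussian mass error and uniform contaminant peaks.

#' Average yeast residue frequencies
#'
#' Literature-typical amino-acid composition of the S. cerevisiae
#' proteome, used as the default sequence composition of the generator.
#' @return Named numeric vector over the 20 letters, summing to 1.
#' @export
yeastResidueFrequencies <- function() {
    c(A = 0.055, R = 0.044, N = 0.061, D = 0.058, C = 0.013,
      Q = 0.039, E = 0.065, G = 0.050, H = 0.022, I = 0.066,
      L = 0.096, K = 0.073, M = 0.021, F = 0.045, P = 0.044,
      S = 0.090, T = 0.059, W = 0.010, Y = 0.034, V = 0.055)
}

#' Simulation configuration
#'
#' Bundles and validates all generator parameters. Defaults emulate the
#' conditions of a replicate MALDI-ToF fingerprinting screen: an
#' average of 11 replicate spectra per protein with a minimum of 3, a
#' Gaussian mass error of 0.02 Da, sub-stoichiometric methylation, and
#' partial tryptic cleavage at methylated residues so that both the
#' cleaved and the read-through (missed-cleavage) peptide forms occur
#' across replicates.
#'
#' @param nProteins Number of proteins generated.
#' @param lengthMeanLog,lengthSdLog Log-normal protein-length
#'   parameters (default: median ~400 residues).
#' @param minLength Lower bound on protein length.
#' @param residueFrequencies Named composition over the 20 letters
#'   (must sum to 1 within 1e-6).
#' @param siteStoichiometry Fraction of protein molecules methylated at
#'   a planted site (default 0.3; methylation is sub-stoichiometric).
#' @param fractionK,fractionR Fraction of eligible K / R residues that
#'   receive a planted site.
#' @param degreeMix Named probabilities `mono`/`di` for the degree of a
#'   planted site.
#' @param meanReplicates,minReplicates Replicate spectra per protein
#'   (Poisson mean, hard minimum).
#' @param detectionProb Probability that a detectable peptide of a
#'   molecule pool yields a peak in a given replicate.
#' @param missedCleavageDetectionProb Detection probability of
#'   unmodified one-missed-cleavage peptides (they are seen, but less
#'   often than fully cleaved ones).
#' @param massErrorSd Gaussian mass error sigma in Da (default 0.02,
#'   a typical average MALDI-ToF calibration error).
#' @param contaminantRate Poisson mean of contaminant peaks per
#'   spectrum, drawn uniformly over `contaminantRange`.
#' @param contaminantRange Mass range of contaminant peaks, Da.
#' @param partialCleavageProb Probability that trypsin cleaves at a
#'   methylated residue (the remainder reads through, producing the
#'   missed-cleavage form).
#' @param filterCompatible Plant only sites whose host peptides can
#'   pass the confidence filters (cleavable position, D/E-free host
#'   peptides, mass window); `FALSE` plants adversarial sites instead.
#' @param seed Mandatory integer seed; all generator stages are
#'   bit-for-bit reproducible under it.
#' @return A validated list of class `SimulationConfig`.
#' @export
simulationConfig <- function(nProteins = 30L,
                             lengthMeanLog = log(400), lengthSdLog = 0.35,
                             minLength = 60L,
                             residueFrequencies = yeastResidueFrequencies(),
                             siteStoichiometry = 0.3,
                             fractionK = 0.05, fractionR = 0.05,
                             degreeMix = c(mono = 0.5, di = 0.5),
                             meanReplicates = 11, minReplicates = 3L,
                             detectionProb = 0.7,
                             missedCleavageDetectionProb = 0.1,
                             massErrorSd = 0.02,
                             contaminantRate = 2,
                             contaminantRange = c(500, 3000),
                             partialCleavageProb = 0.5,
                             filterCompatible = TRUE,
                             seed) {
    if (missing(seed))
        stop("seed is mandatory")
    cfg <- list(nProteins = as.integer(nProteins),
                lengthMeanLog = lengthMeanLog, lengthSdLog = lengthSdLog,
                minLength = as.integer(minLength),
                residueFrequencies = residueFrequencies,
                siteStoichiometry = siteStoichiometry,
                fractionK = fractionK, fractionR = fractionR,
                degreeMix = degreeMix,
                meanReplicates = meanReplicates,
                minReplicates = as.integer(minReplicates),
                detectionProb = detectionProb,
                missedCleavageDetectionProb = missedCleavageDetectionProb,
                massErrorSd = massErrorSd,
                contaminantRate = contaminantRate,
                contaminantRange = contaminantRange,
                partialCleavageProb = partialCleavageProb,
                filterCompatible = isTRUE(filterCompatible),
                seed = as.integer(seed))
    probs <- c(cfg$siteStoichiometry, cfg$fractionK, cfg$fractionR,
               cfg$detectionProb, cfg$missedCleavageDetectionProb,
               cfg$partialCleavageProb, cfg$degreeMix)
    if (any(probs < 0 | probs > 1))
        stop("all probabilities must be in [0, 1]")
    if (abs(sum(cfg$residueFrequencies) - 1) > 1e-6)
        stop("residue composition must sum to 1 (tolerance 1e-6)")
    if (!setequal(names(cfg$residueFrequencies), .AA20))
        stop("residue composition must cover the 20 standard letters")
    if (abs(sum(cfg$degreeMix) - 1) > 1e-6 ||
        !setequal(names(cfg$degreeMix), c("mono", "di")))
        stop("degreeMix must be named probabilities mono/di summing to 1")
    if (cfg$minReplicates < 3L)
        stop("at least 3 replicate spectra per protein are required")
    if (cfg$massErrorSd < 0 || cfg$contaminantRate < 0)
        stop("massErrorSd and contaminantRate must be nonnegative")
    structure(cfg, class = "SimulationConfig")
}

#' Generate a random proteome
#'
#' Sequences are i.i.d. draws from the configured residue composition
#' with log-normal lengths; deterministic under the config seed.
#'
#' @param config A [simulationConfig()].
#' @return A [ProteinSet-class] with accessions `SYNP0001`, ...
#' @export
generateProteome <- function(config) {
    stopifnot(inherits(config, "SimulationConfig"))
    set.seed(config$seed)
    n <- config$nProteins
    if (n == 0L)
        return(ProteinSet(Biostrings::AAStringSet(character(0))))
    len <- pmax(config$minLength,
                round(stats::rlnorm(n, config$lengthMeanLog,
                                    config$lengthSdLog)))
    comp <- config$residueFrequencies[.AA20]
    seqs <- vapply(len, function(L)
        paste(sample(.AA20, L, replace = TRUE, prob = comp),
              collapse = ""), character(1))
    acc <- sprintf("SYNP%04d", seq_len(n))
    ProteinSet(stats::setNames(seqs, acc),
               geneNames = as.list(sprintf("GSYN%04d", seq_len(n))))
}

#' Filter-compatible candidate site positions
#'
#' A planted site can survive the confidence filters only if (i) it is
#' a cleavable K/R (trypsin actually cuts there, so both a fully
#' cleaved peptide ending at the site and a read-through
#' missed-cleavage peptide exist), (ii) neither host peptide contains D
#' or E, and (iii) the methylated masses of both host forms fall in the
#' detectable 500-3000 Da window.
#'
#' @param proteins A [ProteinSet-class].
#' @param suppressProline Trypsin proline rule.
#' @param massRange Detectable modified-mass window, Da.
#' @return data.frame `accession`, `position`, `residue`.
#' @export
eligibleSites <- function(proteins, suppressProline = TRUE,
                          massRange = c(500, 3000)) {
    rows <- list()
    for (acc in accessions(proteins)) {
        s <- sequences(proteins)[[acc]]
        aa <- strsplit(s, "", fixed = TRUE)[[1]]
        cuts <- .tcleavageAfter(aa, suppressProline)
        if (length(cuts) < 2L) next
        bounds <- c(0L, cuts, length(aa))
        for (k in seq_along(cuts)) {
            p <- cuts[k]
            from <- bounds[k] + 1L
            toNext <- bounds[k + 2L]
            pep0 <- substr(s, from, p)
            pep1 <- substr(s, from, toNext)
            if (grepl("[DE]", pep1)) next
            m0 <- mhMass(pep0) + METHYL_DELTA
            m1 <- mhMass(pep1) + METHYL_DELTA
            # both degrees must stay inside the window
            if (m0 < massRange[1] || m1 + METHYL_DELTA > massRange[2])
                next
            rows[[length(rows) + 1L]] <- data.frame(
                accession = acc, position = p, residue = aa[p],
                stringsAsFactors = FALSE)
        }
    }
    if (!length(rows))
        return(data.frame(accession = character(), position = integer(),
                          residue = character(), stringsAsFactors = FALSE))
    do.call(rbind, rows)
}

#' Plant methylation ground truth
#'
#' Samples planted sites per residue class at the configured fractions
#' and degrees. In filter-compatible mode only positions from
#' [eligibleSites()] are used; in adversarial mode sites are planted at
#' K/R positions that fail at least one compatibility condition, to
#' exercise the pipeline's rejection paths.
#'
#' @param proteins A [ProteinSet-class] from [generateProteome()].
#' @param config The same [simulationConfig()].
#' @return data.frame `accession`, `position`, `residue`, `degree`,
#'   `modName`, `stoichiometry`.
#' @export
plantSites <- function(proteins, config) {
    stopifnot(inherits(config, "SimulationConfig"))
    set.seed(config$seed + 1L)
    seqs <- sequences(proteins)
    allKR <- do.call(rbind, lapply(names(seqs), function(acc) {
        aa <- strsplit(seqs[[acc]], "", fixed = TRUE)[[1]]
        pos <- which(aa %in% c("K", "R"))
        if (!length(pos)) return(NULL)
        data.frame(accession = acc, position = pos, residue = aa[pos],
                   stringsAsFactors = FALSE)
    }))
    if (is.null(allKR) || !nrow(allKR))
        stop("proteome has no K or R residues")
    elig <- eligibleSites(proteins)
    pool <- if (config$filterCompatible) {
        elig
    } else {
        key <- function(d) paste(d$accession, d$position)
        allKR[!(key(allKR) %in% key(elig)), , drop = FALSE]
    }
    rows <- list()
    for (res in c("K", "R")) {
        frac <- if (res == "K") config$fractionK else config$fractionR
        if (frac == 0) next
        cand <- pool[pool$residue == res, , drop = FALSE]
        if (!nrow(cand)) {
            if (frac > 0)
                stop("no eligible ", res, " residues to plant sites on")
            next
        }
        pick <- cand[stats::runif(nrow(cand)) < frac, , drop = FALSE]
        if (!nrow(pick)) next
        deg <- 1L + (stats::runif(nrow(pick)) < config$degreeMix[["di"]])
        pick$degree <- as.integer(deg)
        pick$modName <- ifelse(deg == 1L, "monomethyl", "dimethyl")
        pick$stoichiometry <- config$siteStoichiometry
        rows[[length(rows) + 1L]] <- pick
    }
    truth <- if (length(rows)) do.call(rbind, rows) else
        data.frame(accession = character(), position = integer(),
                   residue = character(), degree = integer(),
                   modName = character(), stoichiometry = numeric(),
                   stringsAsFactors = FALSE)
    rownames(truth) <- NULL
    truth[order(truth$accession, truth$position), , drop = FALSE]
}

#' Simulate replicate peak lists
#'
#' For each protein and replicate, emits detected unmodified fully
#' cleaved peptide masses (and, less often, unmodified missed-cleavage
#' peptides), plus methylated peptide masses governed by stoichiometry
#' times detection probability. At each planted cleavage-site, trypsin
#' cleaves the methylated molecules with `partialCleavageProb`, so the
#' fully cleaved peptide ending at the site and the read-through
#' missed-cleavage peptide both occur across replicates -- the
#' overlapping evidence the confidence filters require. Gaussian mass
#' error and Poisson contaminants are then added and peaks below 500 Da
#' are dropped.
#'
#' @param proteins A [ProteinSet-class].
#' @param truth Ground truth from [plantSites()].
#' @param config The same [simulationConfig()].
#' @return A [SpectrumSet-class]; spectrum ids are `<accession>_r<k>`.
#' @export
simulateSpectra <- function(proteins, truth, config) {
    stopifnot(inherits(config, "SimulationConfig"))
    set.seed(config$seed + 2L)
    ids <- character(); accs <- character(); pks <- list()
    delta <- c(monomethyl = METHYL_DELTA, dimethyl = 2 * METHYL_DELTA)
    for (acc in accessions(proteins)) {
        pep <- digestProtein(proteins[acc], maxMissed = 1L,
                             oxidationCap = 0L)
        pep0 <- pep[pep$missedCleavages == 0L, , drop = FALSE]
        pep1 <- pep[pep$missedCleavages == 1L, , drop = FALSE]
        tr <- truth[truth$accession == acc, , drop = FALSE]
        siteForms <- lapply(seq_len(nrow(tr)), function(i) {
            p <- tr$position[i]
            d <- delta[[tr$modName[i]]]
            cleaved <- pep0[pep0$end == p, , drop = FALSE]
            host0 <- pep0[pep0$start <= p & pep0$end >= p, , drop = FALSE]
            readthrough <- pep1[pep1$start <= p & pep1$end > p, ,
                                drop = FALSE]
            list(atCleavage = nrow(cleaved) > 0,
                 cleavedMass = if (nrow(cleaved)) cleaved$mhMass[1] + d
                               else NA_real_,
                 readthroughMass = if (nrow(readthrough))
                     readthrough$mhMass[1] + d else NA_real_,
                 hostMass = if (nrow(host0)) host0$mhMass[1] + d
                            else NA_real_,
                 stoich = tr$stoichiometry[i])
        })
        nRep <- max(config$minReplicates,
                    stats::rpois(1, config$meanReplicates))
        for (r in seq_len(nRep)) {
            masses <- numeric()
            det0 <- stats::runif(nrow(pep0)) < config$detectionProb
            masses <- c(masses, pep0$mhMass[det0])
            det1 <- stats::runif(nrow(pep1)) <
                config$missedCleavageDetectionProb
            masses <- c(masses, pep1$mhMass[det1])
            for (sf in siteForms) {
                pDet <- sf$stoich * config$detectionProb
                if (sf$atCleavage) {
                    if (!is.na(sf$cleavedMass) &&
                        stats::runif(1) < pDet * config$partialCleavageProb)
                        masses <- c(masses, sf$cleavedMass)
                    if (!is.na(sf$readthroughMass) &&
                        stats::runif(1) <
                            pDet * (1 - config$partialCleavageProb))
                        masses <- c(masses, sf$readthroughMass)
                } else if (!is.na(sf$hostMass) &&
                           stats::runif(1) < pDet) {
                    masses <- c(masses, sf$hostMass)
                }
            }
            if (length(masses) && config$massErrorSd > 0)
                masses <- masses + stats::rnorm(length(masses), 0,
                                                config$massErrorSd)
            nCont <- stats::rpois(1, config$contaminantRate)
            if (nCont > 0)
                masses <- c(masses,
                            stats::runif(nCont, config$contaminantRange[1],
                                         config$contaminantRange[2]))
            masses <- masses[masses >= 500]
            ids <- c(ids, sprintf("%s_r%d", acc, r))
            accs <- c(accs, acc)
            pks <- c(pks, list(sort(masses)))
        }
    }
    SpectrumSet(ids, accs, pks)
}

#' Write a complete simulation to disk
#'
#' Writes the proteome FASTA, one peak-list directory per protein (one
#' file per replicate), the ground-truth TSV and a reproducibility
#' manifest echoing every configuration parameter including the seed.
#'
#' @param dir Output directory (created if needed).
#' @param proteins,truth,spectra,config Simulation components.
#' @return `dir`, invisibly.
#' @export
writeSimulation <- function(dir, proteins, truth, spectra, config) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    writeProteinFasta(proteins, file.path(dir, "proteome.fasta"))
    writeTSV(truth, file.path(dir, "ground_truth.tsv"))
    pk <- peakList(spectra)
    acc <- accessions(spectra)
    for (i in seq_along(pk)) {
        d <- file.path(dir, "spectra", acc[i])
        dir.create(d, recursive = TRUE, showWarnings = FALSE)
        stem <- sub(paste0("^", acc[i], "_"), "",
                    spectrumIds(spectra)[i])
        writePeakList(pk[[i]], file.path(d, paste0(stem, ".txt")))
    }
    scal <- vapply(config, function(v)
        paste(format(v, digits = 12), collapse = ","), character(1))
    writeLines(paste(names(scal), scal, sep = "="),
               file.path(dir, "config_manifest.txt"))
    invisible(dir)
}
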