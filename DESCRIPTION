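Package: MethylPMF
Title: Discovery of Protein Methylation Sites from Peptide Mass Fingerprints
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for discovering arginine and lysine methylation sites in
    proteins from replicate MALDI-ToF peptide mass fingerprinting data.
    Implements in-silico tryptic digestion with monoisotopic mass
    calculation, per-spectrum (tailor-made) mass tolerance estimation,
    mass-delta matching of post-translational modifications, a five-stage
    confidence filter exploiting overlapping missed-cleavage peptides,
    peptide and residue discovery rates, in-silico benchmarking of the
    matching strategy, position-specific sequence-motif enrichment around
    modification sites, and functional co-analysis statistics (GO term
    enrichment, abundance and half-life comparisons, modification
    interplay). A synthetic spectrum generator produces replicate peak
    lists with planted methylation ground truth so every stage of the
    pipeline can be exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
biocViews: Proteomics, MassSpectrometry, Software
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'MethylPMF-package.R'
    'benchmark.R'
    'digest.R'
    'discovery.R'
    'filters.R'
    'fixtures.R'
    'functional.R'
    'io.R'
    'masses.R'
    'motif.R'
    'pmf.R'
    'simulate.R'
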