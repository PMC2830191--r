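# Readers and writers for the plain-text formats used around the
# pipeline: FASTA proteomes, one-mass-per-line peak lists, a minimal MGF
# subset, modification tables and generic TSV reports.

#' Read a protein FASTA file into a ProteinSet
#'
#' The accession is taken from the description line: for UniProt-style
#' headers (`>sp|ACC|NAME ...` or `>tr|ACC|NAME ...`) the second
#' pipe-delimited field, otherwise the first whitespace-delimited token.
#' A `GN=...` token, when present, is parsed into the gene names.
#'
#' @param path Path to a FASTA file.
#' @return A [ProteinSet-class] spanning the whole sequences (mature
#'   coordinates can be narrowed afterwards).
#' @export
readProteinFasta <- function(path) {
    ss <- Biostrings::readAAStringSet(path)
    desc <- names(ss)
    acc <- vapply(desc, function(d) {
        tok <- strsplit(d, "\\s+")[[1]][1]
        if (grepl("^(sp|tr)\\|", tok))
            strsplit(tok, "|", fixed = TRUE)[[1]][2]
        else tok
    }, character(1), USE.NAMES = FALSE)
    gn <- lapply(desc, function(d) {
        m <- regmatches(d, regexpr("GN=[^ ]+", d))
        if (length(m)) sub("^GN=", "", m) else character()
    })
    names(ss) <- acc
    ProteinSet(ss, geneNames = gn)
}

#' Write a ProteinSet as FASTA
#' @param proteins A [ProteinSet-class].
#' @param path Output path.
#' @export
writeProteinFasta <- function(proteins, path) {
    ss <- Biostrings::AAStringSet(sequences(proteins))
    gn <- vapply(geneNames(proteins), function(g)
        if (length(g)) paste0(" GN=", g[1]) else "", character(1))
    names(ss) <- paste0(accessions(proteins), gn)
    Biostrings::writeXStringSet(ss, path)
    invisible(path)
}

#' Read a plain-text peak list (one [M+H]+ mass per line)
#'
#' Blank lines and lines starting with `#` are skipped.
#'
#' @param path Path to a peak-list file.
#' @return Sorted numeric vector of masses in Da.
#' @export
readPeakList <- function(path) {
    ln <- trimws(readLines(path))
    ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
    x <- suppressWarnings(as.numeric(ln))
    if (anyNA(x))
        stop("malformed peak list: ", path)
    sort(x)
}

#' Write a peak list, one mass per line
#' @param peaks Numeric masses.
#' @param path Output path.
#' @param digits Number of decimal places written.
#' @export
writePeakList <- function(peaks, path, digits = 5) {
    writeLines(formatC(sort(peaks), format = "f", digits = digits), path)
    invisible(path)
}

#' Read peptide masses from a minimal MGF file
#'
#' Only the `PEPMASS=` line of each `BEGIN IONS`/`END IONS` block is
#' used (the first numeric field, taken as an [M+H]+ mass); fragment ion
#' lines are ignored.
#'
#' @param path Path to an MGF file.
#' @return Sorted numeric vector of precursor masses in Da.
#' @export
readMGF <- function(path) {
    ln <- readLines(path)
    pm <- grep("^PEPMASS=", ln, value = TRUE)
    if (!length(pm))
        stop("no PEPMASS entries in ", path)
    x <- as.numeric(vapply(strsplit(sub("^PEPMASS=", "", pm), "\\s+"),
                           `[`, character(1), 1))
    if (anyNA(x))
        stop("malformed PEPMASS line in ", path)
    sort(x)
}

#' Read a directory tree of replicate peak lists
#'
#' Expects one sub-directory per protein (named by accession), holding
#' one peak-list file per replicate spectrum (`.txt` one-mass-per-line,
#' or `.mgf`).
#'
#' @param dir Root directory.
#' @return A [SpectrumSet-class]; spectrum ids are
#'   `<accession>_<filename-stem>`.
#' @export
readSpectrumDir <- function(dir) {
    accs <- list.dirs(dir, recursive = FALSE, full.names = FALSE)
    ids <- character(); acc <- character(); pk <- list()
    for (a in accs) {
        files <- list.files(file.path(dir, a), full.names = TRUE)
        for (f in files) {
            masses <- if (grepl("\\.mgf$", f, ignore.case = TRUE))
                readMGF(f) else readPeakList(f)
            ids <- c(ids, paste0(a, "_", sub("\\.[^.]*$", "", basename(f))))
            acc <- c(acc, a)
            pk <- c(pk, list(masses))
        }
    }
    SpectrumSet(ids, acc, pk)
}

#' Read a modification table from TSV
#'
#' Expected columns: `name`, `targets` (string of residue letters),
#' `delta` (monoisotopic Da), `degree` (integer or empty).
#'
#' @param path Path to a TSV file.
#' @return A modification data.frame as from [modificationTable()].
#' @export
readModificationTable <- function(path) {
    m <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("name", "targets", "delta", "degree")
    if (!all(need %in% names(m)))
        stop("modification table must have columns: ",
             paste(need, collapse = ", "))
    if (nrow(m) == 0L)
        stop("empty modification table: ", path)
    m$delta <- as.numeric(m$delta)
    m$degree <- as.integer(m$degree)
    m
}

#' Write / read TSV reports
#'
#' Thin wrappers used for all tabular outputs (site tables, audit
#' funnels, rate tables, enrichment reports) so that they round-trip.
#'
#' @param x A data.frame (list-columns are collapsed with `;`).
#' @param path File path.
#' @return `readTSV` returns a data.frame.
#' @export
writeTSV <- function(x, path) {
    x <- as.data.frame(x)
    for (j in seq_along(x))
        if (is.list(x[[j]]))
            x[[j]] <- vapply(x[[j]], paste, character(1), collapse = ";")
    utils::write.table(x, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname writeTSV
#' @export
readTSV <- function(path) {
    utils::read.delim(path, stringsAsFactors = FALSE)
}
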