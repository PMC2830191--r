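#' @export
setGeneric("accessions", function(x, ...) standardGeneric("accessions"))

#' @export
setGeneric("geneNames", function(x, ...) standardGeneric("geneNames"))

#' @export
setGeneric("sequences", function(x, ...) standardGeneric("sequences"))

#' @export
setGeneric("matureStart", function(x, ...) standardGeneric("matureStart"))

#' @export
setGeneric("matureEnd", function(x, ...) standardGeneric("matureEnd"))

#' @export
setGeneric("matureSequence", function(x, ...) standardGeneric("matureSequence"))

#' @export
setGeneric("spectrumIds", function(x, ...) standardGeneric("spectrumIds"))

#' @export
setGeneric("peakList", function(x, ...) standardGeneric("peakList"))
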