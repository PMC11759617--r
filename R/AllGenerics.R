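#' @export
setGeneric("dosages", function(x, ...) standardGeneric("dosages"))

#' @export
setGeneric("variantInfo", function(x, ...) standardGeneric("variantInfo"))

#' @export
setGeneric("sampleInfo", function(x, ...) standardGeneric("sampleInfo"))

#' @export
setGeneric("alleleFreq", function(x, ...) standardGeneric("alleleFreq"))

#' @export
setGeneric("minorAlleleCount", function(x, ...) standardGeneric("minorAlleleCount"))

#' @export
setGeneric("scores", function(x, ...) standardGeneric("scores"))

#' @export
setGeneric("provenance", function(x, ...) standardGeneric("provenance"))

#' @export
setGeneric("propensity", function(x, ...) standardGeneric("propensity"))

#' @export
setGeneric("matchedSamples", function(x, ...) standardGeneric("matchedSamples"))

#' @export
setGeneric("matchWeights", function(x, ...) standardGeneric("matchWeights"))

#' @export
setGeneric("removedSamples", function(x, ...) standardGeneric("removedSamples"))

#' @export
setGeneric("removedVariants", function(x, ...) standardGeneric("removedVariants"))
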