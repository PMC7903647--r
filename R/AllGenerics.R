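#' @export
setGeneric("taxonLevel", function(x) standardGeneric("taxonLevel"))

#' @export
setGeneric("strainToSpecies", function(x) standardGeneric("strainToSpecies"))

#' @export
setGeneric("sampleData", function(x) standardGeneric("sampleData"))

#' @export
setGeneric("filterLowDepth",
    function(x, minReads = 5000) standardGeneric("filterLowDepth"))

#' @export
setGeneric("filterSingletonTaxa",
    function(x, minSamples = 2) standardGeneric("filterSingletonTaxa"))

#' @export
setGeneric("rarefyCounts",
    function(x, depth = "row_min", seed = 1L) standardGeneric("rarefyCounts"))

#' @export
setGeneric("toPresenceAbsence",
    function(x) standardGeneric("toPresenceAbsence"))

#' @export
setGeneric("toRelativeAbundance",
    function(x) standardGeneric("toRelativeAbundance"))

#' @export
setGeneric("collapseToSpecies",
    function(x) standardGeneric("collapseToSpecies"))

#' @export
setGeneric("distanceMatrix",
    function(x, metric = c("bray_curtis", "jaccard"),
             basis = c("membership", "relative_abundance"))
        standardGeneric("distanceMatrix"))

#' @export
setGeneric("pairedPairs", function(design) standardGeneric("pairedPairs"))

#' @export
setGeneric("unrelatedPairs",
    function(design) standardGeneric("unrelatedPairs"))

#' @export
setGeneric("nPairs", function(design) standardGeneric("nPairs"))
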