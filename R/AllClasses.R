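#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData
#'   colData rowData<- colData<-
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' CommunityTable: a taxa-by-sample count matrix with a resolution tag
#'
#' `CommunityTable` extends [SummarizedExperiment::SummarizedExperiment] and
#' holds one `counts` assay (taxa as rows, samples as columns), a `level` tag
#' declaring the taxonomic resolution (`"species"` or `"strain"`), an optional
#' strain-to-species map in `rowData(x)$species`, and per-sample metadata in
#' `colData`.
#'
#' @slot level character(1), `"species"` or `"strain"`.
#'
#' @seealso [CommunityTable()] for construction, [filterLowDepth()],
#'   [rarefyCounts()], [collapseToSpecies()], [distanceMatrix()].
#' @export
setClass("CommunityTable",
    contains = "SummarizedExperiment",
    representation(level = "character"))

setValidity("CommunityTable", function(object) {
    msg <- character()
    if (length(object@level) != 1L ||
        !object@level %in% c("species", "strain"))
        msg <- c(msg, "'level' must be \"species\" or \"strain\"")
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'counts' is required")
    else {
        m <- SummarizedExperiment::assay(object, "counts")
        if (anyNA(m))
            msg <- c(msg, "counts must not contain NA")
        else if (any(m < 0))
            msg <- c(msg, "counts must be nonnegative")
        if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
            msg <- c(msg, "taxon IDs (rownames) must be present and unique")
        if (is.null(colnames(m)) || anyDuplicated(colnames(m)))
            msg <- c(msg, "sample IDs (colnames) must be present and unique")
    }
    sp <- SummarizedExperiment::rowData(object)$species
    if (!is.null(sp) && anyNA(sp))
        msg <- c(msg, "rowData(x)$species must not contain NA when present")
    if (length(msg)) msg else TRUE
})

#' DistanceMatrix: pairwise sample dissimilarities with provenance
#'
#' Dense symmetric matrix of pairwise dissimilarities in `[0, 1]` with zero
#' diagonal, tagged with the metric (`bray_curtis` or `jaccard`) and the basis
#' it was computed on (`membership` or `relative_abundance`).
#'
#' @slot values symmetric numeric matrix with sample IDs as dimnames.
#' @slot metric character(1).
#' @slot basis character(1).
#' @export
setClass("DistanceMatrix",
    representation(values = "matrix", metric = "character",
                   basis = "character"))

setValidity("DistanceMatrix", function(object) {
    v <- object@values
    msg <- character()
    if (nrow(v) != ncol(v))
        msg <- c(msg, "'values' must be square")
    if (is.null(rownames(v)) || !identical(rownames(v), colnames(v)))
        msg <- c(msg, "row and column sample IDs must be present and equal")
    if (any(abs(v - t(v)) > 1e-12))
        msg <- c(msg, "'values' must be symmetric")
    if (any(diag(v) != 0))
        msg <- c(msg, "diagonal must be zero")
    if (any(v < -1e-12 | v > 1 + 1e-12))
        msg <- c(msg, "values must lie in [0, 1]")
    if (!object@metric %in% c("bray_curtis", "jaccard"))
        msg <- c(msg, "metric must be 'bray_curtis' or 'jaccard'")
    if (!object@basis %in% c("membership", "relative_abundance"))
        msg <- c(msg, "basis must be 'membership' or 'relative_abundance'")
    if (length(msg)) msg else TRUE
})

#' PairDesign: dyad pairing structure for paired-vs-unrelated comparisons
#'
#' Holds, for one relation/group/niche, the two sides of each true dyad (one
#' sample per family on each side, e.g. mothers on side A and children on
#' side B) together with family IDs and per-family group labels. The true
#' pairings are the within-family matches; the unrelated universe is every
#' cross-family role-matched pairing.
#'
#' @slot relation character(1): `mother_child`, `father_child`, `couple` or
#'   `sibling`.
#' @slot group character(1): `biological`, `adoptive` or `combined`.
#' @slot niche character(1).
#' @slot sideA,sideB character vectors of sample IDs; `(sideA[i], sideB[i])`
#'   is the i-th true dyad.
#' @slot familyA,familyB family ID of each sample on the two sides (equal in
#'   designs built from metadata; they diverge after [shufflePairs()]).
#' @slot familyGroup character vector: group label per dyad (aligned with
#'   side A).
#' @export
setClass("PairDesign",
    representation(relation = "character", group = "character",
                   niche = "character", sideA = "character",
                   sideB = "character", familyA = "character",
                   familyB = "character", familyGroup = "character"))

setValidity("PairDesign", function(object) {
    n <- length(object@familyA)
    msg <- character()
    if (length(object@sideA) != n || length(object@sideB) != n ||
        length(object@familyB) != n || length(object@familyGroup) != n)
        msg <- c(msg, "side and family slots must have equal length")
    if (anyDuplicated(object@familyA) || anyDuplicated(object@familyB))
        msg <- c(msg, "one dyad per family: family IDs must be unique")
    if (any(object@sideA == object@sideB))
        msg <- c(msg, "a pair must not join a sample with itself")
    if (length(msg)) msg else TRUE
})

#' PermutationResult: outcome of the dependency-aware permutation test
#'
#' @slot observed numeric(1), the observed statistic (median dissimilarity of
#'   a random unrelated subset minus median dissimilarity of the true pairs).
#' @slot null numeric vector of permutation statistics.
#' @slot p numeric(1), two-sided p value.
#' @slot B integer(1), number of permutations.
#' @slot seed integer(1), RNG seed used.
#' @slot nPairs integer(1), number of dyads.
#' @slot estimator character(1), `"proportion"` or `"plus_one"`.
#' @slot exhaustive logical(1), whether all assignments were enumerated.
#' @export
setClass("PermutationResult",
    representation(observed = "numeric", null = "numeric", p = "numeric",
                   B = "integer", seed = "integer", nPairs = "integer",
                   estimator = "character", exhaustive = "logical"))

setValidity("PermutationResult", function(object) {
    if (object@p < 0 || object@p > 1) "p must lie in [0, 1]" else TRUE
})

#' SimConfig: parameters of the family-structured community generator
#'
#' See [simConfig()] for field documentation and defaults.
#' @export
setClass("SimConfig",
    representation(nFamilies = "integer", groupSplit = "numeric",
                   nSpeciesPool = "integer", strainsPerSpecies = "integer",
                   coreOccupancy = "numeric", strainOccupancy = "numeric",
                   tau = "numeric", householdRho = "numeric",
                   geneticEffect = "numeric", envRate = "numeric",
                   childAgeYears = "numeric", ageHalf = "numeric",
                   richnessMax = "numeric", readDepth = "numeric",
                   depthDispersion = "numeric", dirichletAlpha = "numeric",
                   abundanceCoupling = "numeric", fatherProb = "numeric",
                   siblingProb = "numeric",
                   niche = "character", seed = "integer"))

#' SimTruth: generative ground truth recorded by the simulator
#'
#' @slot config the [SimConfig-class] used.
#' @slot repertoires named list of character vectors: true strain repertoire
#'   per subject.
#' @slot dyadShared data.frame with one row per mother-child dyad: family,
#'   group, nShared (true shared strains) and sharedFraction (union-based).
#' @export
setClass("SimTruth",
    representation(config = "SimConfig", repertoires = "list",
                   dyadShared = "data.frame"))
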