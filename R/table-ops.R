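#' Remove low-depth samples
#'
#' Drops every sample whose total read count falls below `minReads`. The
#' default of 5000 reads reflects common amplicon practice of excluding
#' low-throughput libraries before analysis. Removed sample IDs are reported
#' via [message()].
#'
#' @param x a [CommunityTable-class].
#' @param minReads nonnegative count; samples with column sum strictly below
#'   this are removed.
#' @return the filtered `CommunityTable` (taxa unchanged).
#' @export
setMethod("filterLowDepth", "CommunityTable", function(x, minReads = 5000) {
    if (minReads < 0)
        stop("'minReads' must be nonnegative", call. = FALSE)
    depths <- colSums(counts(x))
    keep <- depths >= minReads
    if (!any(keep))
        stop("all samples fall below ", minReads,
             " reads; empty table", call. = FALSE)
    if (any(!keep))
        message("filterLowDepth: removed ", sum(!keep), " sample(s): ",
                paste(colnames(x)[!keep], collapse = ", "))
    x[, keep]
})

#' Remove taxa detected in too few samples
#'
#' Drops every taxon with a nonzero count in fewer than `minSamples` samples.
#' The default of 2 removes taxa seen in only a single sample, the usual
#' guard against PCR artifacts in amplicon sequence variant tables.
#'
#' @param x a [CommunityTable-class].
#' @param minSamples minimum number of samples (>= 1) a taxon must be
#'   detected in to be retained.
#' @return the filtered `CommunityTable` (samples unchanged).
#' @export
setMethod("filterSingletonTaxa", "CommunityTable",
    function(x, minSamples = 2) {
    if (minSamples < 1)
        stop("'minSamples' must be >= 1", call. = FALSE)
    prevalence <- rowSums(counts(x) > 0)
    keep <- prevalence >= minSamples
    if (!any(keep))
        warning("all taxa removed; returning a zero-taxon table",
                call. = FALSE)
    if (any(!keep))
        message("filterSingletonTaxa: removed ", sum(!keep), " taxon/taxa")
    x[keep, ]
})

#' Rarefy samples to a common depth
#'
#' Subsamples each sample's reads without replacement to a fixed depth using
#' [vegan::rrarefy()], the standard community-ecology subsampler. With
#' `depth = "row_min"` the depth is the minimum column sum of the table, so
#' every sample is drawn down to the shallowest library.
#'
#' @param x a [CommunityTable-class].
#' @param depth a positive count, or `"row_min"` for the minimum column sum.
#' @param seed integer RNG seed; identical seeds give identical output.
#' @return a `CommunityTable` whose column sums all equal `depth`.
#' @export
setMethod("rarefyCounts", "CommunityTable",
    function(x, depth = "row_min", seed = 1L) {
    m <- counts(x)
    depths <- colSums(m)
    if (identical(depth, "row_min")) depth <- min(depths)
    depth <- as.numeric(depth)
    if (length(depth) != 1L || is.na(depth) || depth < 1)
        stop("'depth' must be a positive count or \"row_min\"", call. = FALSE)
    short <- depths < depth
    if (any(short))
        stop("rarefaction depth ", depth, " exceeds the read count of ",
             "sample(s): ", paste(colnames(m)[short], collapse = ", "),
             call. = FALSE)
    rar <- withCallingHandlers(
        runSeeded(asSeed(seed), vegan::rrarefy(t(m), depth)),
        warning = function(w) {
            # vegan warns when the smallest nonzero count exceeds 1, which is
            # routine for simulated tables; depth violations are caught above
            if (grepl("observed counts", conditionMessage(w)))
                invokeRestart("muffleWarning")
        })
    out <- x
    SummarizedExperiment::assay(out, "counts") <- t(rar)
    out
})

#' Convert counts to presence/absence
#'
#' Maps every positive count to 1 and keeps zeros, giving the community
#' membership representation used for membership-based dissimilarities.
#' Idempotent.
#'
#' @param x a [CommunityTable-class].
#' @return a `CommunityTable` of 0/1 values.
#' @export
setMethod("toPresenceAbsence", "CommunityTable", function(x) {
    out <- x
    m <- counts(x)
    SummarizedExperiment::assay(out, "counts") <- (m > 0) + 0
    out
})

#' Convert counts to relative abundances
#'
#' Divides each sample (column) by its total, so columns sum to one.
#'
#' @param x a [CommunityTable-class].
#' @return a numeric matrix of relative abundances (not a `CommunityTable`;
#'   the result is no longer a count table).
#' @export
setMethod("toRelativeAbundance", "CommunityTable", function(x) {
    m <- counts(x)
    tot <- colSums(m)
    if (any(tot == 0))
        stop("zero-sum sample(s): ",
             paste(colnames(m)[tot == 0], collapse = ", "), call. = FALSE)
    sweep(m, 2L, tot, "/")
})

#' Collapse a strain table to species level
#'
#' Sums the counts of all strains mapped to the same species, using the
#' strain-to-species map stored in `rowData(x)$species`. Column sums are
#' preserved exactly.
#'
#' @param x a strain-level [CommunityTable-class] with a strain-to-species
#'   map.
#' @return a species-level `CommunityTable`.
#' @export
setMethod("collapseToSpecies", "CommunityTable", function(x) {
    if (x@level != "strain")
        stop("collapseToSpecies expects a strain-level table", call. = FALSE)
    map <- strainToSpecies(x)
    if (is.null(map))
        stop("no strain-to-species map present; missing for all taxa: ",
             paste(utils::head(rownames(x), 5), collapse = ", "),
             if (nrow(x) > 5) ", ..." else "", call. = FALSE)
    m <- rowsum(counts(x), group = map, reorder = TRUE)
    CommunityTable(m, level = "species",
                   metadata = if (ncol(SummarizedExperiment::colData(x)))
                       sampleData(x) else NULL)
})

#' Depth-then-singleton filtering pipeline
#'
#' Applies the two standard quality filters in the fixed order used
#' throughout this package: first remove low-depth samples
#' ([filterLowDepth()]), then remove taxa detected in fewer than
#' `minSamples` samples ([filterSingletonTaxa()]). Fixing the order keeps
#' runs reproducible.
#'
#' @param x a [CommunityTable-class].
#' @param minReads passed to [filterLowDepth()].
#' @param minSamples passed to [filterSingletonTaxa()].
#' @return the filtered `CommunityTable`.
#' @export
filterPipeline <- function(x, minReads = 5000, minSamples = 2) {
    filterSingletonTaxa(filterLowDepth(x, minReads), minSamples)
}
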