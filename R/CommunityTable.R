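#' Construct a CommunityTable
#'
#' Wraps a taxa-by-sample count matrix (taxa as rows) into a
#' [CommunityTable-class], optionally attaching a strain-to-species map and
#' per-sample metadata.
#'
#' @param counts nonnegative numeric matrix, taxa as rows, samples as columns,
#'   with unique row and column names.
#' @param level `"strain"` or `"species"`.
#' @param species optional character vector mapping each taxon (strain) to a
#'   species label; either named by taxon ID or aligned with `rownames(counts)`.
#' @param metadata optional `data.frame` of per-sample metadata containing at
#'   least a `sample_id` column; every column of `counts` must have a row.
#'
#' @return a [CommunityTable-class].
#' @examples
#' m <- matrix(c(5L, 0L, 3L, 2L), 2, 2,
#'             dimnames = list(c("t1", "t2"), c("s1", "s2")))
#' CommunityTable(m, level = "species")
#' @export
CommunityTable <- function(counts, level = c("strain", "species"),
                           species = NULL, metadata = NULL) {
    level <- match.arg(level)
    counts <- as.matrix(counts)
    storage.mode(counts) <- "double"
    rd <- S4Vectors::DataFrame(row.names = rownames(counts))
    if (!is.null(species)) {
        if (!is.null(names(species))) {
            missing <- setdiff(rownames(counts), names(species))
            if (length(missing))
                stop("taxa missing from the strain-to-species map: ",
                     paste(missing, collapse = ", "), call. = FALSE)
            species <- species[rownames(counts)]
        } else if (length(species) != nrow(counts)) {
            stop("'species' must be named or match nrow(counts)",
                 call. = FALSE)
        }
        rd$species <- unname(species)
    }
    cd <- S4Vectors::DataFrame(row.names = colnames(counts))
    if (!is.null(metadata)) {
        metadata <- validateSampleMetadata(metadata, require = colnames(counts))
        cd <- S4Vectors::DataFrame(
            metadata[match(colnames(counts), metadata$sample_id), ,
                     drop = FALSE],
            row.names = colnames(counts))
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts), rowData = rd, colData = cd)
    methods::new("CommunityTable", se, level = level)
}

#' Validate a sample metadata table
#'
#' Checks the contract of per-sample metadata: unique `sample_id`, recognised
#' `role`/`group`/`niche` codes when present, nonnegative ages, and (when
#' `require` is given) coverage of a set of sample IDs. Ordinal clinical
#' covariates are expected to already be coded none/mild/moderate/severe as
#' 1/2/3/4; see [codeOrdinal()].
#'
#' @param meta a `data.frame` with at least `sample_id`.
#' @param require optional character vector of sample IDs that must be present.
#' @return the validated `data.frame`, invisibly usable downstream.
#' @export
validateSampleMetadata <- function(meta, require = NULL) {
    meta <- as.data.frame(meta)
    if (!"sample_id" %in% names(meta))
        stop("metadata must contain a 'sample_id' column", call. = FALSE)
    if (anyDuplicated(meta$sample_id))
        stop("metadata sample_id values must be unique", call. = FALSE)
    if (!is.null(require)) {
        missing <- setdiff(require, meta$sample_id)
        if (length(missing))
            stop("samples missing from metadata: ",
                 paste(missing, collapse = ", "), call. = FALSE)
    }
    if ("role" %in% names(meta)) {
        bad <- setdiff(unique(meta$role),
                       c("mother", "father", "child", "sibling"))
        if (length(bad))
            stop("unknown role(s): ", paste(bad, collapse = ", "),
                 call. = FALSE)
    }
    if ("group" %in% names(meta)) {
        bad <- setdiff(unique(meta$group), c("biological", "adoptive"))
        if (length(bad))
            stop("unknown group(s): ", paste(bad, collapse = ", "),
                 call. = FALSE)
    }
    if ("niche" %in% names(meta)) {
        bad <- setdiff(unique(meta$niche),
                       c("saliva_soft_tissue", "supragingival", "subgingival"))
        if (length(bad))
            stop("unknown niche(s): ", paste(bad, collapse = ", "),
                 call. = FALSE)
    }
    if ("age_years" %in% names(meta) &&
        any(!is.na(meta$age_years) & meta$age_years < 0))
        stop("age_years must be nonnegative", call. = FALSE)
    meta
}

#' Code an ordinal clinical covariate as 1/2/3/4
#'
#' Converts none/mild/moderate/severe ratings to the numeric scale 1/2/3/4
#' used for regression.
#'
#' @param x character or factor vector of ratings.
#' @return integer vector.
#' @examples
#' codeOrdinal(c("none", "severe", "mild"))
#' @export
codeOrdinal <- function(x) {
    levels <- c("none", "mild", "moderate", "severe")
    x <- as.character(x)
    bad <- setdiff(unique(x[!is.na(x)]), levels)
    if (length(bad))
        stop("unknown ordinal level(s): ", paste(bad, collapse = ", "),
             call. = FALSE)
    match(x, levels)
}

#' @describeIn CommunityTable-class taxonomic resolution tag.
#' @param x a `CommunityTable`.
#' @export
setMethod("taxonLevel", "CommunityTable", function(x) x@level)

#' @describeIn CommunityTable-class named character vector mapping strain IDs
#'   to species labels (or `NULL`).
#' @export
setMethod("strainToSpecies", "CommunityTable", function(x) {
    sp <- SummarizedExperiment::rowData(x)$species
    if (is.null(sp)) return(NULL)
    stats::setNames(as.character(sp), rownames(x))
})

#' @describeIn CommunityTable-class per-sample metadata as a base
#'   `data.frame`.
#' @export
setMethod("sampleData", "CommunityTable", function(x) {
    df <- as.data.frame(SummarizedExperiment::colData(x))
    if (!"sample_id" %in% names(df) && nrow(df))
        df$sample_id <- rownames(df)
    df
})

#' @importFrom BiocGenerics counts
#' @export
setMethod("counts", "CommunityTable", function(object, ...) {
    SummarizedExperiment::assay(object, "counts")
})

setMethod("show", "CommunityTable", function(object) {
    cat(sprintf("CommunityTable (%s level): %d taxa x %d samples\n",
                object@level, nrow(object), ncol(object)))
    depths <- colSums(counts(object))
    if (length(depths))
        cat(sprintf("  column sums: min %s / median %s / max %s\n",
                    format(min(depths)), format(stats::median(depths)),
                    format(max(depths))))
    if (!is.null(strainToSpecies(object)))
        cat(sprintf("  strain-to-species map: %d species\n",
                    length(unique(strainToSpecies(object)))))
    invisible(object)
})
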