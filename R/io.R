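#' Read a taxa-by-sample count table from TSV
#'
#' Expects tab-separated text with taxa as rows: first column taxon IDs,
#' header row sample IDs. Gzipped files are read transparently. Use
#' `transposed = TRUE` for tables stored samples-as-rows.
#'
#' @param path file path (optionally `.gz`).
#' @param level `"strain"` or `"species"`.
#' @param speciesMap optional path to a two-column TSV (`taxon_id`,
#'   `species`) mapping strains to species.
#' @param metadata optional `data.frame` of sample metadata, or a path to a
#'   metadata TSV.
#' @param transposed logical; set `TRUE` if samples are rows on disk.
#' @return a [CommunityTable-class].
#' @export
readCommunityTable <- function(path, level = c("strain", "species"),
                               speciesMap = NULL, metadata = NULL,
                               transposed = FALSE) {
    level <- match.arg(level)
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- as.character(df[[1]])
    if (transposed) m <- t(m)
    species <- NULL
    if (!is.null(speciesMap)) {
        sm <- utils::read.delim(speciesMap, check.names = FALSE,
                                stringsAsFactors = FALSE)
        species <- stats::setNames(as.character(sm[[2]]),
                                   as.character(sm[[1]]))
    }
    if (is.character(metadata)) metadata <- readSampleMetadata(metadata)
    CommunityTable(m, level = level, species = species, metadata = metadata)
}

#' Write a CommunityTable (and its strain map) to TSV
#'
#' Writes taxa as rows with a leading `taxon_id` column. When the table has a
#' strain-to-species map it is written alongside as `<path>.map.tsv` unless
#' `mapPath` is given.
#'
#' @param x a [CommunityTable-class].
#' @param path output path; a `.gz` suffix triggers gzip compression.
#' @param mapPath optional path for the strain-to-species map.
#' @return `path`, invisibly.
#' @export
writeCommunityTable <- function(x, path, mapPath = NULL) {
    m <- counts(x)
    df <- data.frame(taxon_id = rownames(m), m, check.names = FALSE)
    writeTsv(df, path)
    map <- strainToSpecies(x)
    if (!is.null(map)) {
        if (is.null(mapPath)) mapPath <- paste0(path, ".map.tsv")
        writeTsv(data.frame(taxon_id = names(map), species = unname(map)),
                 mapPath)
    }
    invisible(path)
}

#' Read sample metadata from TSV
#'
#' @param path tab-separated metadata file with a `sample_id` column.
#' @return a validated `data.frame` (see [validateSampleMetadata()]).
#' @export
readSampleMetadata <- function(path) {
    validateSampleMetadata(utils::read.delim(path, check.names = FALSE,
                                             stringsAsFactors = FALSE))
}

#' Write sample metadata to TSV
#' @param meta a metadata `data.frame`.
#' @param path output path; `.gz` supported.
#' @return `path`, invisibly.
#' @export
writeSampleMetadata <- function(meta, path) {
    writeTsv(validateSampleMetadata(meta), path)
    invisible(path)
}

#' Write a DistanceMatrix to square TSV
#'
#' @param d a [DistanceMatrix-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeDistanceMatrix <- function(d, path) {
    m <- as.matrix(d)
    writeTsv(data.frame(sample_id = rownames(m), m, check.names = FALSE),
             path)
    invisible(path)
}

writeTsv <- function(df, path) {
    con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
    on.exit(close(con))
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}
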