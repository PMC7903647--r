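#' Top species by total abundance
#'
#' Ranks species by total read count across all samples, using the
#' strain-to-species map of a strain-level table (or the row names of a
#' species-level table).
#'
#' @param x a [CommunityTable-class].
#' @param k number of species to return.
#' @return character vector of species labels, most abundant first.
#' @export
topSpecies <- function(x, k = 10) {
    totals <- if (taxonLevel(x) == "strain") {
        map <- strainToSpecies(x)
        if (is.null(map))
            stop("a strain-to-species map is required", call. = FALSE)
        rowsum(rowSums(counts(x)), group = map)[, 1]
    } else rowSums(counts(x))
    names(sort(totals, decreasing = TRUE))[seq_len(min(k, length(totals)))]
}

#' Per-dyad strain dissimilarity within one species
#'
#' Restricts a strain-level table to the strains of one species and
#' recomputes the membership Bray-Curtis dissimilarity for every dyad of the
#' design. Dyads where either member carries no detected strain of the
#' species are dropped (and counted in the `dropped` attribute). Results are
#' split by the dyad's group label, the layout used for per-species
#' biological-vs-adoptive comparisons.
#'
#' @param x a strain-level [CommunityTable-class] with a strain-to-species
#'   map.
#' @param design a [PairDesign-class].
#' @param species a species label present in the map.
#' @return named list of numeric distance vectors, one per group, with an
#'   attribute `dropped` (number of dyads without the species).
#' @export
perSpeciesDissimilarity <- function(x, design, species) {
    map <- strainToSpecies(x)
    if (is.null(map))
        stop("a strain-to-species map is required", call. = FALSE)
    if (!species %in% map)
        stop("species '", species, "' absent from the strain-to-species map",
             call. = FALSE)
    sub <- counts(x)[map == species, , drop = FALSE]
    pairs <- pairedPairs(design)
    a <- sub[, pairs$sample_a, drop = FALSE]
    b <- sub[, pairs$sample_b, drop = FALSE]
    ok <- colSums(a) > 0 & colSums(b) > 0
    if (any(!ok))
        message("perSpeciesDissimilarity(", species, "): dropped ",
                sum(!ok), " dyad(s) lacking the species")
    d <- vapply(which(ok), function(i)
        brayCurtis((a[, i] > 0) + 0, (b[, i] > 0) + 0), 0)
    out <- split(unname(d), pairs$group[ok])
    attr(out, "dropped") <- sum(!ok)
    out
}

#' Per-species biological-vs-adoptive strain comparisons
#'
#' For the `k` most abundant species, compares the distribution of per-dyad
#' strain-membership Bray-Curtis dissimilarities between biological and
#' adoptive dyads with a Wilcoxon rank-sum test, then adjusts the p values
#' across species by Benjamini-Hochberg.
#'
#' @param x a strain-level [CommunityTable-class] with a strain-to-species
#'   map.
#' @param design a [PairDesign-class] built on the combined cohort (its
#'   `familyGroup` labels split the dyads).
#' @param k number of top-abundance species to test (default 10).
#' @param species optional explicit species vector overriding `k`.
#' @return `data.frame` with one row per species: `species`,
#'   `n_biological`, `n_adoptive`, `statistic`, `p`, `q`, `stars`.
#' @export
perSpeciesTests <- function(x, design, k = 10, species = NULL) {
    if (is.null(species)) species <- topSpecies(x, k)
    rows <- lapply(species, function(sp) {
        d <- perSpeciesDissimilarity(x, design, sp)
        bio <- d[["biological"]]; ado <- d[["adoptive"]]
        if (is.null(bio) || is.null(ado) || !length(bio) || !length(ado))
            return(data.frame(species = sp, n_biological = length(bio),
                              n_adoptive = length(ado), statistic = NA_real_,
                              p = NA_real_, stringsAsFactors = FALSE))
        rs <- rankSumTest(bio, ado)
        data.frame(species = sp, n_biological = length(bio),
                   n_adoptive = length(ado), statistic = rs$statistic,
                   p = rs$p, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$q <- NA_real_
    tested <- !is.na(out$p)
    out$q[tested] <- bhAdjust(out$p[tested])
    out$stars <- NA_character_
    out$stars[tested] <- pToStars(out$q[tested])
    out
}
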