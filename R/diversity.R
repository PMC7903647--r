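#' Bray-Curtis dissimilarity between two samples
#'
#' Computes `1 - 2 * sum(pmin(x, y)) / (sum(x) + sum(y))`. On 0/1 vectors
#' this is the Sorensen dissimilarity `1 - 2|A n B| / (|A| + |B|)`: identical
#' communities score 0 and communities with no taxa in common score 1.
#'
#' @param x,y nonnegative numeric vectors of equal length (counts, relative
#'   abundances, or 0/1 membership).
#' @return dissimilarity in `[0, 1]`.
#' @examples
#' brayCurtis(c(1, 1, 1, 0), c(0, 1, 1, 1))  # 1/3
#' @export
brayCurtis <- function(x, y) {
    checkPair(x, y)
    1 - 2 * sum(pmin(x, y)) / (sum(x) + sum(y))
}

#' Jaccard dissimilarity between two membership vectors
#'
#' Computes `1 - |A n B| / |A u B|` on presence/absence vectors. Defined on
#' membership only; convert counts with [toPresenceAbsence()] first.
#'
#' @param x,y 0/1 vectors of equal length, not both all-zero.
#' @return dissimilarity in `[0, 1]`.
#' @examples
#' jaccard(c(1, 1, 1, 0), c(0, 1, 1, 1))  # 0.5
#' @export
jaccard <- function(x, y) {
    checkPair(x, y)
    if (!all(x %in% c(0, 1)) || !all(y %in% c(0, 1)))
        stop("jaccard is defined on 0/1 membership vectors; ",
             "use toPresenceAbsence() first", call. = FALSE)
    inter <- sum(x == 1 & y == 1)
    union <- sum(x == 1 | y == 1)
    1 - inter / union
}

checkPair <- function(x, y) {
    if (length(x) != length(y))
        stop("vectors must have equal length", call. = FALSE)
    if (any(x < 0) || any(y < 0))
        stop("vectors must be nonnegative", call. = FALSE)
    if (sum(x) == 0 && sum(y) == 0)
        stop("dissimilarity is undefined for two all-zero samples",
             call. = FALSE)
    invisible(NULL)
}

#' Shannon diversity of one sample
#'
#' `H = -sum(p_i * log(p_i))` over `p_i = x_i / sum(x)`, with `0 * log(0)`
#' taken as 0. Natural log by default (`base` is exposed for other
#' conventions). Thin wrapper over [vegan::diversity()].
#'
#' @param x nonnegative count or abundance vector with positive sum.
#' @param base logarithm base; default `exp(1)`.
#' @return Shannon index (>= 0, at most `log(richness, base)`).
#' @examples
#' shannon(rep(1, 4))  # log(4)
#' @export
shannon <- function(x, base = exp(1)) {
    if (any(x < 0) || sum(x) <= 0)
        stop("shannon requires a nonnegative vector with positive sum",
             call. = FALSE)
    as.numeric(vegan::diversity(x, index = "shannon", base = base))
}

#' Pairwise dissimilarity matrix for a community table
#'
#' Computes all pairwise sample dissimilarities via [vegan::vegdist()].
#' `basis = "membership"` converts to presence/absence first (binary
#' Bray-Curtis equals Sorensen); `basis = "relative_abundance"` normalises
#' each sample to proportions first. Jaccard is only defined on membership
#' here.
#'
#' @param x a [CommunityTable-class] with at least two samples.
#' @param metric `"bray_curtis"` or `"jaccard"`.
#' @param basis `"membership"` or `"relative_abundance"`.
#' @return a [DistanceMatrix-class].
#' @export
setMethod("distanceMatrix", "CommunityTable",
    function(x, metric = c("bray_curtis", "jaccard"),
             basis = c("membership", "relative_abundance")) {
    metric <- match.arg(metric)
    basis <- match.arg(basis)
    if (ncol(x) < 2)
        stop("at least two samples are required", call. = FALSE)
    if (metric == "jaccard" && basis == "relative_abundance")
        stop("jaccard is defined on membership only", call. = FALSE)
    m <- counts(x)
    empty <- colSums(m) == 0
    if (any(empty))
        stop("all-zero sample(s): ",
             paste(colnames(m)[empty], collapse = ", "), call. = FALSE)
    d <- if (basis == "membership") {
        vegan::vegdist(t(m), method = if (metric == "bray_curtis") "bray"
                                      else "jaccard", binary = TRUE)
    } else {
        vegan::vegdist(t(toRelativeAbundance(x)), method = "bray")
    }
    v <- as.matrix(d)
    diag(v) <- 0
    methods::new("DistanceMatrix", values = v, metric = metric,
                 basis = basis)
})

#' @describeIn DistanceMatrix-class dense symmetric matrix of values.
#' @param x a `DistanceMatrix`.
#' @param ... ignored.
#' @export
setMethod("as.matrix", "DistanceMatrix", function(x, ...) x@values)

#' Look up dissimilarities for sample pairs
#'
#' @param d a [DistanceMatrix-class].
#' @param a,b character vectors of sample IDs (recycled pairwise).
#' @return numeric vector of dissimilarities.
#' @export
pairDistances <- function(d, a, b) {
    v <- as.matrix(d)
    missing <- setdiff(c(a, b), rownames(v))
    if (length(missing))
        stop("samples absent from the distance matrix: ",
             paste(missing, collapse = ", "), call. = FALSE)
    v[cbind(a, b)]
}

setMethod("show", "DistanceMatrix", function(object) {
    v <- object@values
    off <- v[lower.tri(v)]
    cat(sprintf("DistanceMatrix: %d samples, metric = %s, basis = %s\n",
                nrow(v), object@metric, object@basis))
    if (length(off))
        cat(sprintf("  dissimilarity range: %.3f - %.3f (median %.3f)\n",
                    min(off), max(off), stats::median(off)))
    invisible(object)
})
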