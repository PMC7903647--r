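#' Two-sided Wilcoxon rank-sum test
#'
#' Wrapper around [stats::wilcox.test()] with a fixed policy: exact
#' enumeration when both groups have at most 10 observations and there are no
#' ties, otherwise the normal approximation with tie correction and
#' continuity correction.
#'
#' @param a,b numeric vectors (both nonempty).
#' @param exact override the automatic exact/approximate choice.
#' @return list with `statistic` (W) and `p` (two-sided).
#' @examples
#' rankSumTest(c(0.1, 0.2, 0.3), c(0.7, 0.8, 0.9))$p  # 0.1
#' @export
rankSumTest <- function(a, b, exact = NULL) {
    if (!length(a) || !length(b))
        stop("both groups must be nonempty", call. = FALSE)
    ties <- anyDuplicated(c(a, b)) > 0
    if (is.null(exact))
        exact <- length(a) <= 10 && length(b) <= 10 && !ties
    if (exact && ties)
        stop("exact enumeration is not defined with ties", call. = FALSE)
    res <- suppressWarnings(
        stats::wilcox.test(a, b, alternative = "two.sided", exact = exact,
                           correct = TRUE))
    list(statistic = unname(res$statistic), p = res$p.value)
}

#' Shared-taxon fraction between two samples
#'
#' Quantifies how much of two communities is shared: `nShared` is the number
#' of taxa detected in both; `fracByCount` is the union-based fraction
#' `|A n B| / |A u B|`; `fracByAbundance` is the mean, over the two samples,
#' of the summed relative abundance of the shared taxa. Per-member count
#' fractions (`|A n B| / |A|`, `|A n B| / |B|`) are reported alongside.
#'
#' @param x,y nonnegative count or abundance vectors of equal length, each
#'   with at least one detected taxon.
#' @return list with `nShared`, `fracByCount`, `fracByAbundance`,
#'   `fracByMember` (length-2 vector).
#' @examples
#' shared <- sharedFraction(c(4, 3, 2, 1, 0), c(0, 5, 3, 0, 2))
#' shared$fracByCount  # 2 shared of 5 in the union
#' @export
sharedFraction <- function(x, y) {
    if (length(x) != length(y))
        stop("vectors must have equal length", call. = FALSE)
    if (any(x < 0) || any(y < 0))
        stop("vectors must be nonnegative", call. = FALSE)
    inX <- x > 0; inY <- y > 0
    if (!any(inX) || !any(inY))
        stop("each sample must have at least one detected taxon",
             call. = FALSE)
    both <- inX & inY
    relX <- x / sum(x); relY <- y / sum(y)
    list(nShared = sum(both),
         fracByCount = sum(both) / sum(inX | inY),
         fracByAbundance = mean(c(sum(relX[both]), sum(relY[both]))),
         fracByMember = c(a = sum(both) / sum(inX),
                          b = sum(both) / sum(inY)))
}

#' Shared fractions for every dyad of a design
#'
#' Applies [sharedFraction()] to each pair of a [PairDesign-class] against a
#' community table, returning one row per dyad.
#'
#' @param x a [CommunityTable-class].
#' @param design a [PairDesign-class]; may also be a `data.frame` with
#'   columns `sample_a`/`sample_b` (e.g. from [unrelatedPairs()]).
#' @return `data.frame` with columns `sample_a`, `sample_b`, `n_shared`,
#'   `frac_by_count`, `frac_by_abundance`.
#' @export
dyadSharedFractions <- function(x, design) {
    pairs <- if (methods::is(design, "PairDesign")) pairedPairs(design)
             else as.data.frame(design)
    m <- counts(x)
    missing <- setdiff(c(pairs$sample_a, pairs$sample_b), colnames(m))
    if (length(missing))
        stop("samples absent from the table: ",
             paste(missing, collapse = ", "), call. = FALSE)
    res <- mapply(function(a, b) {
        s <- sharedFraction(m[, a], m[, b])
        c(s$nShared, s$fracByCount, s$fracByAbundance)
    }, pairs$sample_a, pairs$sample_b)
    data.frame(sample_a = pairs$sample_a, sample_b = pairs$sample_b,
               n_shared = res[1, ], frac_by_count = res[2, ],
               frac_by_abundance = res[3, ], row.names = NULL,
               stringsAsFactors = FALSE)
}

#' Spearman rank correlation
#'
#' [stats::cor.test()] with `method = "spearman"`, midranks for ties and the
#' asymptotic t approximation for the p value.
#'
#' @param x,y numeric vectors of equal length >= 3, neither constant.
#' @return list with `rho` and `p`.
#' @export
correlate <- function(x, y) {
    if (length(x) != length(y) || length(x) < 3)
        stop("'x' and 'y' must have equal length >= 3", call. = FALSE)
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
        stop("correlation is undefined for a constant vector",
             call. = FALSE)
    res <- suppressWarnings(
        stats::cor.test(x, y, method = "spearman", exact = FALSE))
    list(rho = unname(res$estimate), p = res$p.value)
}

#' Ordinary least squares for dyad distances on covariates
#'
#' Fits `distance ~ predictors` with an intercept via [stats::lm()], the
#' usual confounder-adjustment model for dyad dissimilarities (ordinal
#' clinical covariates are expected 1/2/3/4-coded; see [codeOrdinal()]).
#'
#' @param dist numeric response vector.
#' @param predictors `data.frame` of numeric predictors.
#' @return `data.frame` with one row per coefficient: `term`, `estimate`,
#'   `std_error`, `p_value`.
#' @export
regressDistance <- function(dist, predictors) {
    predictors <- as.data.frame(predictors)
    if (length(dist) != nrow(predictors))
        stop("'dist' and 'predictors' must have matching rows", call. = FALSE)
    if (length(dist) <= ncol(predictors) + 1)
        stop("need n > number of predictors + 1", call. = FALSE)
    dat <- cbind(.distance = dist, predictors)
    fit <- stats::lm(.distance ~ ., data = dat)
    X <- stats::model.matrix(fit)
    if (qr(X)$rank < ncol(X)) {
        dropped <- names(which(is.na(stats::coef(fit))))
        stop("rank-deficient design; collinear column(s): ",
             paste(dropped, collapse = ", "), call. = FALSE)
    }
    cf <- summary(fit)$coefficients
    data.frame(term = rownames(cf), estimate = cf[, 1],
               std_error = cf[, 2], p_value = cf[, 4],
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate control via [stats::p.adjust()].
#'
#' @param p numeric vector of p values in `[0, 1]`.
#' @return q values, same order as `p`.
#' @export
bhAdjust <- function(p) {
    if (anyNA(p) || any(p < 0 | p > 1))
        stop("p values must lie in [0, 1]", call. = FALSE)
    stats::p.adjust(p, method = "BH")
}

#' Star notation for p values
#'
#' `p < 0.001` = `"***"`, `p < 0.01` = `"**"`, `p < 0.05` = `"*"`, otherwise
#' `"ns"`.
#'
#' @param p numeric vector of p values in `[0, 1]`.
#' @return character vector.
#' @examples
#' pToStars(c(0.0005, 0.03, 0.5))
#' @export
pToStars <- function(p) {
    if (anyNA(p) || any(p < 0 | p > 1))
        stop("p values must lie in [0, 1]", call. = FALSE)
    ifelse(p < 0.001, "***",
        ifelse(p < 0.01, "**",
            ifelse(p < 0.05, "*", "ns")))
}
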