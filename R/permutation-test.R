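#' Dependency-aware permutation test for paired vs unrelated dissimilarity
#'
#' Tests whether true dyads (e.g. mother-child pairs) are more similar than
#' unrelated cross-family pairings, while accounting for the dependency
#' created by re-using each sample in many unrelated pairings. The observed
#' statistic is the median dissimilarity of a random subset of the unrelated
#' universe (subset size = number of dyads, giving power comparable to a
#' rank-sum test on independent groups) minus the median dissimilarity of the
#' true pairs. For each of `B` permutations the side-B assignment is randomly
#' permuted, the permuted pairings become the "paired" set, a fresh random
#' unrelated subset is drawn from the universe excluding the permuted
#' pairings, and the statistic is recomputed identically. The two-sided p
#' value is the proportion of permutations whose absolute statistic is at
#' least the absolute observed statistic.
#'
#' With `exhaustive = TRUE` (small designs only) all `n!` assignments are
#' enumerated instead, and each statistic uses the median over the full
#' remaining universe rather than a random subset, making the result
#' deterministic.
#'
#' @param design a [PairDesign-class].
#' @param dmat a [DistanceMatrix-class] containing every design sample.
#' @param B number of permutations (default 1000).
#' @param seed integer RNG seed; identical seeds give identical results.
#' @param fixedSubset logical; if `TRUE` the unrelated subset is drawn once
#'   and its median reused across permutations (only the paired median is
#'   recomputed). Default `FALSE` (fresh subset per permutation).
#' @param estimator `"proportion"` for `#\{|null| >= |obs|\} / B`, or
#'   `"plus_one"` for the `(b + 1) / (B + 1)` variant.
#' @param exhaustive logical; enumerate all assignments (requires <= 8
#'   dyads).
#' @return a [PermutationResult-class].
#' @examples
#' sim <- simulatePopulation(simConfig(nFamilies = 10, seed = 3))
#' d <- distanceMatrix(sim$strainTable)
#' design <- buildPairDesign(sim$metadata, "mother_child", "combined")
#' permutationTest(design, d, B = 200, seed = 42)
#' @export
permutationTest <- function(design, dmat, B = 1000, seed = 1L,
                            fixedSubset = FALSE,
                            estimator = c("proportion", "plus_one"),
                            exhaustive = FALSE) {
    estimator <- match.arg(estimator)
    stopifnot(methods::is(design, "PairDesign"),
              methods::is(dmat, "DistanceMatrix"))
    if (B < 1) stop("'B' must be >= 1", call. = FALSE)
    n <- nPairs(design)
    if (n < 2) stop("at least 2 dyads are required", call. = FALSE)
    v <- as.matrix(dmat)
    missing <- setdiff(c(design@sideA, design@sideB), rownames(v))
    if (length(missing))
        stop("design samples absent from the distance matrix: ",
             paste(missing, collapse = ", "), call. = FALSE)

    # n x n lookup: D[i, j] = dissimilarity(sideA[i], sideB[j])
    D <- v[design@sideA, design@sideB, drop = FALSE]
    cross <- outer(design@familyA, design@familyB, "!=")
    universeIdx <- which(cross)  # column-major linear indices
    if (length(universeIdx) < n)
        stop("unrelated universe (", length(universeIdx),
             " pairings) is smaller than the number of dyads (", n, ")",
             call. = FALSE)
    pairedIdx <- seq_len(n) + (seq_len(n) - 1L) * n

    if (exhaustive) {
        if (n > 8)
            stop("exhaustive enumeration supported for <= 8 dyads",
                 call. = FALSE)
        perms <- enumeratePermutations(n)
        stats <- apply(perms, 1L, function(perm) {
            assigned <- seq_len(n) + (perm - 1L) * n
            avail <- setdiff(universeIdx, assigned)
            fastMedian(D[avail]) - fastMedian(D[assigned])
        })
        observed <- fastMedian(D[universeIdx]) - fastMedian(D[pairedIdx])
        p <- mean(abs(stats) >= abs(observed))
        return(methods::new("PermutationResult", observed = observed,
                            null = as.numeric(stats), p = p,
                            B = nrow(perms), seed = asSeed(seed),
                            nPairs = as.integer(n), estimator = estimator,
                            exhaustive = TRUE))
    }

    inUniverse <- logical(n * n)
    inUniverse[universeIdx] <- TRUE
    res <- runSeeded(asSeed(seed), {
        # the observed subset excludes the true pairings, exactly as each
        # permutation's subset excludes the permuted pairings (the exclusion
        # only bites when the paired set lies inside the universe, e.g. in
        # shuffled null designs)
        obsSubset <- sample(setdiff(universeIdx, pairedIdx), n)
        observed <- fastMedian(D[obsSubset]) - fastMedian(D[pairedIdx])
        fixedMedian <- fastMedian(D[obsSubset])
        null <- numeric(B)
        for (b in seq_len(B)) {
            perm <- sample.int(n)
            assigned <- seq_len(n) + (perm - 1L) * n
            pairedMed <- fastMedian(D[assigned])
            if (fixedSubset) {
                null[b] <- fixedMedian - pairedMed
            } else {
                ok <- inUniverse
                ok[assigned] <- FALSE
                avail <- which(ok)
                if (length(avail) < n)
                    stop("unrelated universe too small after excluding ",
                         "the permuted pairings", call. = FALSE)
                null[b] <- fastMedian(D[sample(avail, n)]) - pairedMed
            }
        }
        list(observed = observed, null = null)
    })
    count <- sum(abs(res$null) >= abs(res$observed))
    p <- if (estimator == "proportion") count / B else (count + 1) / (B + 1)
    methods::new("PermutationResult", observed = res$observed,
                 null = res$null, p = p, B = as.integer(B),
                 seed = asSeed(seed), nPairs = as.integer(n),
                 estimator = estimator, exhaustive = FALSE)
}

# all n! permutations of 1..n, one per row (small n only)
enumeratePermutations <- function(n) {
    if (n == 1L) return(matrix(1L, 1, 1))
    sub <- enumeratePermutations(n - 1L)
    out <- matrix(0L, n * nrow(sub), n)
    row <- 1L
    for (k in seq_len(n)) {
        rest <- setdiff(seq_len(n), k)
        for (r in seq_len(nrow(sub))) {
            out[row, ] <- c(k, rest[sub[r, ]])
            row <- row + 1L
        }
    }
    out
}

setMethod("show", "PermutationResult", function(object) {
    cat(sprintf(paste0("PermutationResult: observed = %.4f, p = %.4g %s ",
                       "(%s, B = %d, %d dyads%s)\n"),
                object@observed, object@p, pToStars(object@p),
                object@estimator, object@B, object@nPairs,
                if (object@exhaustive) ", exhaustive" else ""))
    invisible(object)
})
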