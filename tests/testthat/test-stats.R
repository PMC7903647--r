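test_that("rank-sum exact p matches enumeration over C(6,3) labelings", {
    a <- c(0.1, 0.2, 0.3); b <- c(0.7, 0.8, 0.9)
    # independent oracle: enumerate all 20 ways to label 3 of 6 values "a",
    # compute the rank-sum of group a, two-sided p by symmetry
    vals <- c(a, b)
    combos <- utils::combn(6, 3)
    W <- apply(combos, 2, function(idx) sum(rank(vals)[idx]) - 6)
    obs <- sum(rank(vals)[1:3]) - 6
    pOracle <- mean(abs(W - 4.5) >= abs(obs - 4.5))
    expect_equal(pOracle, 0.1)
    expect_equal(rankSumTest(a, b)$p, pOracle)
    # identical multisets -> p = 1 by symmetry (tie-corrected path)
    expect_equal(rankSumTest(c(1, 2, 5), c(5, 1, 2))$p, 1)
    expect_error(rankSumTest(c(1, 1, 2), c(1, 3, 4), exact = TRUE), "ties")
})

test_that("normal approximation tracks exact enumeration for n = 8 vs 8", {
    set.seed(14)
    for (i in 1:5) {
        a <- round(runif(8), 3); b <- round(runif(8, 0.2, 1.2), 3)
        if (anyDuplicated(c(a, b))) next
        pExact <- rankSumTest(a, b, exact = TRUE)$p
        pApprox <- rankSumTest(a, b, exact = FALSE)$p
        expect_lt(abs(pExact - pApprox), 0.02)
    }
    expect_error(rankSumTest(numeric(), 1:3), "nonempty")
})

test_that("shared fractions match their closed-form examples", {
    # mother {a,b,c,d}, child {b,c,e}
    m <- c(a = 1, b = 1, c = 1, d = 1, e = 0)
    c1 <- c(a = 0, b = 1, c = 1, d = 0, e = 1)
    s <- sharedFraction(m, c1)
    expect_identical(s$nShared, 2L)
    expect_equal(s$fracByCount, 0.4)
    # abundance example: shared taxa carry 0.5 of mother, 0.8 of child
    m2 <- c(0.4, 0.3, 0.2, 0.1, 0)
    c2 <- c(0, 0.5, 0.3, 0, 0.2)
    expect_equal(sharedFraction(m2, c2)$fracByAbundance, 0.65)
    # identical samples -> both fractions 1
    s3 <- sharedFraction(c(3, 2, 1), c(3, 2, 1))
    expect_equal(s3$fracByCount, 1)
    expect_equal(s3$fracByAbundance, 1)
    expect_error(sharedFraction(c(0, 0), c(1, 0)), "detected")
})

test_that("shared fraction is symmetric in its arguments", {
    set.seed(8)
    for (i in 1:50) {
        x <- rpois(20, 1); y <- rpois(20, 1)
        if (sum(x) == 0 || sum(y) == 0) next
        sxy <- sharedFraction(x, y); syx <- sharedFraction(y, x)
        expect_identical(sxy$nShared, syx$nShared)
        expect_equal(sxy$fracByCount, syx$fracByCount)
        expect_equal(sxy$fracByAbundance, syx$fracByAbundance)
        expect_equal(unname(sxy$fracByMember), rev(unname(syx$fracByMember)))
    }
})

test_that("Spearman correlation has its textbook values", {
    expect_equal(correlate(1:10, (1:10)^2)$rho, 1)
    expect_equal(correlate(1:10, -(1:10)^3)$rho, -1)
    expect_equal(correlate(c(1, 2, 3, 4, 5), c(1, 3, 2, 5, 4))$rho, 0.8)
    expect_error(correlate(rep(1, 5), 1:5), "constant")
    expect_error(correlate(1:2, 1:2), "length")
})

test_that("regression recovers exact and noisy coefficients", {
    x <- 1:20
    fit <- suppressWarnings(regressDistance(2 + 3 * x, data.frame(x = x)))
    expect_equal(fit$estimate[fit$term == "(Intercept)"], 2)
    expect_equal(fit$estimate[fit$term == "x"], 3)
    # balanced group indicator with equal group means -> coefficient 0
    g <- rep(0:1, each = 10)
    y <- c(rep(1, 10), rep(1, 10))
    fit2 <- regressDistance(y + rep(c(-.1, .1), 10),
                            data.frame(group = g))
    expect_equal(fit2$estimate[fit2$term == "group"], 0, tolerance = 1e-12)
    # simulation with known truth: beta_group = -0.05
    set.seed(5)
    g3 <- rep(0:1, 50)
    y3 <- 0.4 - 0.05 * g3 + rnorm(100, 0, 0.01)
    fit3 <- regressDistance(y3, data.frame(group = g3))
    row <- fit3[fit3$term == "group", ]
    expect_lt(abs(row$estimate - (-0.05)), 3 * row$std_error)
    # collinearity is reported by column name
    expect_error(regressDistance(rnorm(20),
                                 data.frame(a = 1:20, b = 2 * (1:20))),
                 "collinear")
})

test_that("BH adjustment matches the step-up closed form and is monotone", {
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
    expect_equal(bhAdjust(0.2), 0.2)
    set.seed(31)
    for (i in 1:100) {
        p <- runif(12)
        q <- bhAdjust(p)
        # reference step-up computed independently
        o <- order(p); n <- length(p)
        ref <- rev(cummin(rev(p[o] * n / seq_len(n))))[order(o)]
        expect_equal(q, pmin(ref, 1))
        expect_true(all(q >= p - 1e-15))
        expect_identical(order(q[o]), seq_len(n))  # no inversions
    }
    expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("star notation follows the <0.05/<0.01/<0.001 convention", {
    expect_identical(pToStars(c(0.0005, 0.005, 0.03, 0.5)),
                     c("***", "**", "*", "ns"))
    expect_identical(pToStars(0.05), "ns")  # strictly less than
    expect_error(pToStars(1.5), "\\[0, 1\\]")
})
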