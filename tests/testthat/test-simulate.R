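test_that("simConfig validates fields by name", {
    expect_error(simConfig(tau = 1.2), "tau")
    expect_error(simConfig(groupSplit = -0.1), "groupSplit")
    expect_error(simConfig(nFamilies = 1), "nFamilies")
    expect_error(simConfig(readDepth = 0), "readDepth")
    expect_error(simConfig(tau = 0.8, geneticEffect = 0.3), "geneticEffect")
    expect_error(simConfig(childAgeYears = 0.1), "childAgeYears")
    expect_s4_class(simConfig(), "SimConfig")
})

test_that("simulation is deterministic under a fixed seed", {
    cfg <- simConfig(nFamilies = 6, readDepth = 2000, seed = 33)
    a <- simulatePopulation(cfg)
    b <- simulatePopulation(cfg)
    expect_identical(counts(a$strainTable), counts(b$strainTable))
    expect_identical(counts(a$speciesTable), counts(b$speciesTable))
    expect_identical(a$metadata, b$metadata)
    expect_identical(a$truth@repertoires, b$truth@repertoires)
    c <- simulatePopulation(simConfig(nFamilies = 6, readDepth = 2000,
                                      seed = 34))
    expect_false(identical(counts(a$strainTable), counts(c$strainTable)))
})

test_that("species table is the exact collapse of the strain table", {
    sim <- simulatePopulation(simConfig(nFamilies = 5, readDepth = 3000,
                                        seed = 2))
    expect_identical(colSums(counts(sim$strainTable)),
                     colSums(counts(sim$speciesTable)))
    expect_identical(counts(collapseToSpecies(sim$strainTable)),
                     counts(sim$speciesTable))
})

test_that("perfect transmission with no environment makes children subsets", {
    cfg <- simConfig(nFamilies = 8, tau = 1, envRate = 0,
                     childAgeYears = 1000, ageHalf = 0.01,
                     readDepth = 1000, seed = 5)
    sim <- simulatePopulation(cfg)
    reps <- sim$truth@repertoires
    for (f in sprintf("F%03d", 1:8)) {
        child <- reps[[paste0(f, "_C")]]
        mother <- reps[[paste0(f, "_M")]]
        expect_true(all(child %in% mother))
    }
    # shared fraction by child repertoire is 1
    shared <- vapply(sprintf("F%03d", 1:8), function(f)
        mean(reps[[paste0(f, "_C")]] %in% reps[[paste0(f, "_M")]]), 0)
    expect_true(all(shared == 1))
})

test_that("tau = 0 dyad overlap matches a Monte-Carlo independence oracle", {
    # with tau = 0, full environmental acquisition and no age thinning, a
    # child is an independent adult-like draw; the mean union-based overlap
    # must match that of independent repertoire pairs drawn by a separate
    # sampler
    cfg <- simConfig(nFamilies = 150, tau = 0, envRate = 1,
                     childAgeYears = 1e6, readDepth = 100, seed = 17)
    sim <- simulatePopulation(cfg)
    observed <- mean(sim$truth@dyadShared$sharedFraction)

    # independent oracle: direct two-tier occupancy sampling, 10,000 pairs
    set.seed(99)
    occ <- rep(cfg@coreOccupancy, each = cfg@strainsPerSpecies)
    q <- cfg@strainOccupancy
    K <- cfg@strainsPerSpecies
    nS <- cfg@nSpeciesPool
    drawOne <- function() {
        sp <- runif(nS) < cfg@coreOccupancy
        st <- rep(sp, each = K) & (runif(nS * K) < q)
        # enforce >= 1 strain per carried species, as the generator does
        for (s in which(sp)) {
            idx <- ((s - 1) * K + 1):(s * K)
            if (!any(st[idx])) st[sample(idx, 1)] <- TRUE
        }
        st
    }
    oracle <- mean(replicate(10000, {
        a <- drawOne(); b <- drawOne()
        u <- sum(a | b)
        if (u == 0) 0 else sum(a & b) / u
    }))
    expect_equal(observed, oracle, tolerance = 0.02)
})

test_that("dyad shared-strain fraction is monotone in tau", {
    taus <- c(0, 0.25, 0.5, 0.75, 1)
    means <- vapply(seq_along(taus), function(i) {
        sim <- simulatePopulation(simConfig(nFamilies = 50, tau = taus[i],
                                            readDepth = 100,
                                            seed = 300 + i))
        mean(sim$truth@dyadShared$sharedFraction)
    }, 0)
    expect_identical(order(means), seq_along(taus))
    expect_equal(cor(means, taus, method = "spearman"), 1)
})

test_that("child Shannon diversity rises with age toward maternal levels", {
    ages <- c(0.25, 1, 3, 6, 20)
    cfg <- function(a, s) simConfig(nFamilies = 40, childAgeYears = a,
                                    readDepth = 5000, seed = s)
    H <- vapply(seq_along(ages), function(i) {
        sim <- simulatePopulation(cfg(ages[i], 400 + i))
        m <- counts(sim$strainTable)
        children <- grep("_C$", colnames(m), value = TRUE)
        mean(apply(m[, children], 2, shannon))
    }, 0)
    expect_identical(order(H), seq_along(ages))
    # oldest children reach adult diversity
    sim <- simulatePopulation(cfg(20, 444))
    m <- counts(sim$strainTable)
    Hm <- mean(apply(m[, grep("_M$", colnames(m))], 2, shannon))
    Hc <- mean(apply(m[, grep("_C$", colnames(m))], 2, shannon))
    expect_lt(abs(Hm - Hc) / Hm, 0.1)
})

test_that("fathers and siblings are generated with expected structure", {
    cfg <- simConfig(nFamilies = 10, groupSplit = 0, fatherProb = 1,
                     siblingProb = 1, readDepth = 500, seed = 12)
    sim <- simulatePopulation(cfg)
    meta <- sim$metadata
    expect_identical(sum(meta$role == "father"), 10L)
    expect_identical(sum(meta$role == "sibling"), 10L)
    # couples share more than unrelated adults on average (householdRho)
    reps <- sim$truth@repertoires
    couple <- vapply(sprintf("F%03d", 1:10), function(f) {
        a <- reps[[paste0(f, "_M")]]; b <- reps[[paste0(f, "_F")]]
        sum(b %in% a) / length(union(a, b))
    }, 0)
    cross <- vapply(1:10, function(i) {
        a <- reps[[sprintf("F%03d_M", i)]]
        b <- reps[[sprintf("F%03d_F", i %% 10 + 1)]]
        sum(b %in% a) / length(union(a, b))
    }, 0)
    expect_gt(mean(couple), mean(cross))
})
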