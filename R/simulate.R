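#' Configure the family-structured community simulator
#'
#' Builds a validated [SimConfig-class] for [simulatePopulation()]. The
#' generative model: every adult carries a personal strain repertoire (species
#' drawn by per-species occupancy, strains within carried species drawn by
#' `strainOccupancy`); a child's repertoire is its mother's strains each kept
#' with probability `tau` (plus `geneticEffect` in biological dyads), unioned
#' with an independent environmental draw scaled by `envRate`, then thinned by
#' an age-dependent retention `richnessMax * age / (age + ageHalf)` so that
#' young children are species-poor and converge to adult richness with age.
#' Relative abundances are symmetric-Dirichlet over the repertoire and read
#' counts multinomial at a log-normally perturbed depth.
#'
#' Defaults emulate an adoption-cohort design: ~50 biological plus ~50
#' adoptive mother-child families, ~25,000 reads per sample, child ages
#' between 3 months and 6 years, a species pool with a widely shared core,
#' and strain-level personalisation such that unrelated adults share roughly
#' 40% of species but only ~10% of strains while true dyads share more.
#'
#' @param nFamilies number of families (>= 2).
#' @param groupSplit fraction of families labelled `adoptive` in `[0, 1]`.
#' @param nSpeciesPool size of the species pool.
#' @param strainsPerSpecies strains available per species.
#' @param coreOccupancy per-species colonisation probability; a scalar, a
#'   vector of length `nSpeciesPool`, or the default two-tier core/rare
#'   profile (40 core species at 0.95, the rest at 0.20 for the default
#'   pool).
#' @param strainOccupancy probability an adult carries each strain of a
#'   carried species (at least one strain is always carried).
#' @param tau transmission fidelity in `[0, 1]`: probability a mother-carried
#'   strain is transmitted to her child.
#' @param householdRho adult-adult strain-sharing probability for cohabiting
#'   couples, in `[0, 1]`.
#' @param geneticEffect additive increment to `tau` applied only to
#'   biological dyads; must satisfy `tau + geneticEffect <= 1`.
#' @param envRate scale in `[0, 1]` of the child's independent environmental
#'   strain acquisition (1 = a full adult-like draw, 0 = none).
#' @param childAgeYears per-child age(s) in years (>= 0.25), recycled across
#'   children; `NULL` draws ages uniformly on `[0.25, 6]`.
#' @param ageHalf age (years) at which child richness reaches half its
#'   asymptote.
#' @param richnessMax asymptotic child retention fraction (<= 1).
#' @param readDepth mean reads per sample (>= 1).
#' @param depthDispersion nonnegative log-normal sigma of per-sample depth.
#' @param dirichletAlpha symmetric Dirichlet concentration for relative
#'   abundances over the repertoire.
#' @param abundanceCoupling exponent linking a species' occupancy to its
#'   expected abundance (core species dominate communities); 0 decouples
#'   them.
#' @param fatherProb probability a biological family also contributes a
#'   father sample (couple mechanism via `householdRho`).
#' @param siblingProb probability a biological family contributes a second
#'   child (sibling), drawn by the same mother-child mechanism.
#' @param niche niche label stamped on all samples.
#' @param seed integer RNG seed.
#' @return a [SimConfig-class].
#' @export
simConfig <- function(nFamilies = 100, groupSplit = 0.5,
                      nSpeciesPool = 120, strainsPerSpecies = 8,
                      coreOccupancy = NULL, strainOccupancy = 0.3,
                      tau = 0.25, householdRho = 0.5, geneticEffect = 0,
                      envRate = 0.65, childAgeYears = NULL, ageHalf = 1.5,
                      richnessMax = 1, readDepth = 25000,
                      depthDispersion = 0.3, dirichletAlpha = 0.5,
                      abundanceCoupling = 2, fatherProb = 0,
                      siblingProb = 0,
                      niche = "saliva_soft_tissue", seed = 1L) {
    if (nFamilies < 2)
        stop("'nFamilies' must be >= 2", call. = FALSE)
    if (is.null(coreOccupancy)) {
        nCore <- min(40L, as.integer(nSpeciesPool))
        coreOccupancy <- c(rep(0.95, nCore),
                           rep(0.20, nSpeciesPool - nCore))
    }
    if (length(coreOccupancy) == 1L)
        coreOccupancy <- rep(coreOccupancy, nSpeciesPool)
    if (length(coreOccupancy) != nSpeciesPool)
        stop("'coreOccupancy' must be scalar or length nSpeciesPool",
             call. = FALSE)
    checkFraction(groupSplit, "groupSplit")
    checkFraction(coreOccupancy, "coreOccupancy")
    checkFraction(strainOccupancy, "strainOccupancy")
    checkFraction(tau, "tau")
    checkFraction(householdRho, "householdRho")
    checkFraction(envRate, "envRate")
    checkFraction(fatherProb, "fatherProb")
    checkFraction(siblingProb, "siblingProb")
    checkFraction(richnessMax, "richnessMax")
    if (geneticEffect < 0 || tau + geneticEffect > 1)
        stop("'geneticEffect' must lie in [0, 1 - tau]", call. = FALSE)
    if (!is.null(childAgeYears) && any(childAgeYears < 0.25))
        stop("'childAgeYears' must be >= 0.25", call. = FALSE)
    if (ageHalf <= 0)
        stop("'ageHalf' must be positive", call. = FALSE)
    if (readDepth < 1)
        stop("'readDepth' must be >= 1", call. = FALSE)
    if (depthDispersion < 0)
        stop("'depthDispersion' must be nonnegative", call. = FALSE)
    if (dirichletAlpha <= 0)
        stop("'dirichletAlpha' must be positive", call. = FALSE)
    if (abundanceCoupling < 0)
        stop("'abundanceCoupling' must be nonnegative", call. = FALSE)
    methods::new("SimConfig",
        nFamilies = as.integer(nFamilies), groupSplit = groupSplit,
        nSpeciesPool = as.integer(nSpeciesPool),
        strainsPerSpecies = as.integer(strainsPerSpecies),
        coreOccupancy = coreOccupancy, strainOccupancy = strainOccupancy,
        tau = tau, householdRho = householdRho,
        geneticEffect = geneticEffect, envRate = envRate,
        childAgeYears = if (is.null(childAgeYears)) numeric()
                        else as.numeric(childAgeYears),
        ageHalf = ageHalf, richnessMax = richnessMax,
        readDepth = as.numeric(readDepth),
        depthDispersion = depthDispersion,
        dirichletAlpha = dirichletAlpha,
        abundanceCoupling = abundanceCoupling, fatherProb = fatherProb,
        siblingProb = siblingProb, niche = niche, seed = asSeed(seed))
}

setMethod("show", "SimConfig", function(object) {
    cat(sprintf(paste0("SimConfig: %d families (%.0f%% adoptive), pool %d ",
                       "species x %d strains\n"),
                object@nFamilies, 100 * object@groupSplit,
                object@nSpeciesPool, object@strainsPerSpecies))
    cat(sprintf("  tau = %.2f (+%.2f genetic), envRate = %.2f, rho = %.2f\n",
                object@tau, object@geneticEffect, object@envRate,
                object@householdRho))
    cat(sprintf("  depth ~ %s reads (sigma %.2f), seed %d\n",
                format(object@readDepth), object@depthDispersion,
                object@seed))
    invisible(object)
})

# draw one adult-like repertoire: logical vector over the strain pool,
# occProb is the per-strain species occupancy, scale thins the species draw
drawAdultRepertoire <- function(cfg, scale = 1) {
    K <- cfg@strainsPerSpecies
    carried <- stats::runif(cfg@nSpeciesPool) < cfg@coreOccupancy * scale
    rep <- logical(cfg@nSpeciesPool * K)
    if (!any(carried)) return(rep)
    idx <- which(carried)
    for (s in idx) {
        strains <- stats::runif(K) < cfg@strainOccupancy
        if (!any(strains)) strains[sample.int(K, 1L)] <- TRUE
        rep[((s - 1L) * K + 1L):(s * K)] <- strains
    }
    rep
}

# child repertoire: tau-retained maternal strains + scaled environmental
# draw, thinned by the age retention curve
drawChildRepertoire <- function(cfg, motherRep, tau, age) {
    keep <- motherRep & (stats::runif(length(motherRep)) < tau)
    env <- drawAdultRepertoire(cfg, scale = cfg@envRate)
    candidate <- keep | env
    retain <- cfg@richnessMax * age / (age + cfg@ageHalf)
    candidate & (stats::runif(length(candidate)) < retain)
}

# Dirichlet abundances over the repertoire, tilted so that widely shared
# (core) species carry more abundance, -> multinomial counts
sampleCounts <- function(cfg, repertoire) {
    n <- length(repertoire)
    counts <- numeric(n)
    k <- sum(repertoire)
    if (k == 0L) return(counts)
    occ <- rep(cfg@coreOccupancy, each = cfg@strainsPerSpecies)[repertoire]
    w <- stats::rgamma(k, shape = cfg@dirichletAlpha) *
        occ^cfg@abundanceCoupling
    if (sum(w) == 0) w <- rep(1, k)
    depth <- max(1, round(cfg@readDepth *
                          stats::rlnorm(1, 0, cfg@depthDispersion)))
    counts[repertoire] <- stats::rmultinom(1, depth, w / sum(w))[, 1]
    counts
}

#' Simulate a family-structured cohort
#'
#' Generates strain- and species-level count tables, sample metadata and the
#' generative ground truth for a cohort of mother-child families (optionally
#' with fathers and siblings in the biological group). See [simConfig()] for
#' the model. One sample per subject; the species table is the strain table
#' collapsed through the strain-to-species map, so its column sums match
#' exactly. Identical configs (including seed) give identical output.
#'
#' @param config a [SimConfig-class].
#' @return a list with elements `strainTable` and `speciesTable`
#'   ([CommunityTable-class]), `metadata` (`data.frame`) and `truth`
#'   ([SimTruth-class]).
#' @examples
#' sim <- simulatePopulation(simConfig(nFamilies = 4, seed = 7))
#' sim$strainTable
#' @export
simulatePopulation <- function(config) {
    stopifnot(methods::is(config, "SimConfig"))
    runSeeded(config@seed, simulateImpl(config))
}

simulateImpl <- function(cfg) {
    K <- cfg@strainsPerSpecies
    speciesIds <- sprintf("sp%03d", seq_len(cfg@nSpeciesPool))
    strainIds <- as.vector(t(outer(speciesIds, seq_len(K),
                                   function(s, k) sprintf("%s_str%d", s, k))))
    strainSpecies <- rep(speciesIds, each = K)

    nAdoptive <- round(cfg@nFamilies * cfg@groupSplit)
    groups <- rep(c("adoptive", "biological"),
                  c(nAdoptive, cfg@nFamilies - nAdoptive))

    nChildren <- cfg@nFamilies  # one index child per family (pre-sibling)
    ages <- if (length(cfg@childAgeYears))
        rep_len(cfg@childAgeYears, nChildren)
    else stats::runif(nChildren, 0.25, 6)

    reps <- list(); meta <- list(); dyad <- list()
    addSample <- function(subject, family, role, group, age, repertoire) {
        reps[[subject]] <<- strainIds[repertoire]
        meta[[subject]] <<- data.frame(
            sample_id = subject, subject_id = subject, family_id = family,
            role = role, group = group, niche = cfg@niche,
            age_years = age, stringsAsFactors = FALSE)
        repertoire
    }

    repMatrix <- list()
    for (f in seq_len(cfg@nFamilies)) {
        fam <- sprintf("F%03d", f)
        group <- groups[f]
        tauEff <- cfg@tau +
            if (group == "biological") cfg@geneticEffect else 0
        motherRep <- drawAdultRepertoire(cfg)
        repMatrix[[paste0(fam, "_M")]] <-
            addSample(paste0(fam, "_M"), fam, "mother", group, 30, motherRep)
        childRep <- drawChildRepertoire(cfg, motherRep, tauEff, ages[f])
        repMatrix[[paste0(fam, "_C")]] <-
            addSample(paste0(fam, "_C"), fam, "child", group, ages[f],
                      childRep)
        shared <- sum(motherRep & childRep)
        union <- sum(motherRep | childRep)
        dyad[[fam]] <- data.frame(
            family = fam, group = group, nShared = shared,
            sharedFraction = if (union) shared / union else 0,
            stringsAsFactors = FALSE)
        if (group == "biological" && stats::runif(1) < cfg@fatherProb) {
            own <- drawAdultRepertoire(cfg)
            fromMother <- motherRep &
                (stats::runif(length(motherRep)) < cfg@householdRho)
            repMatrix[[paste0(fam, "_F")]] <-
                addSample(paste0(fam, "_F"), fam, "father", group, 32,
                          own | fromMother)
        }
        if (group == "biological" && stats::runif(1) < cfg@siblingProb) {
            sibAge <- stats::runif(1, 0.25, 6)
            sibRep <- drawChildRepertoire(cfg, motherRep, tauEff, sibAge)
            repMatrix[[paste0(fam, "_S")]] <-
                addSample(paste0(fam, "_S"), fam, "sibling", group, sibAge,
                          sibRep)
        }
    }

    countMat <- vapply(repMatrix, function(r) sampleCounts(cfg, r),
                       numeric(length(strainIds)))
    rownames(countMat) <- strainIds
    metadata <- do.call(rbind, meta[colnames(countMat)])
    rownames(metadata) <- NULL

    strainTable <- CommunityTable(countMat, level = "strain",
        species = stats::setNames(strainSpecies, strainIds),
        metadata = metadata)
    speciesTable <- collapseToSpecies(strainTable)
    truth <- methods::new("SimTruth", config = cfg, repertoires = reps,
                          dyadShared = do.call(rbind, dyad))
    list(strainTable = strainTable, speciesTable = speciesTable,
         metadata = metadata, truth = truth)
}

setMethod("show", "SimTruth", function(object) {
    ds <- object@dyadShared
    cat(sprintf("SimTruth: %d subjects, %d mother-child dyads\n",
                length(object@repertoires), nrow(ds)))
    cat(sprintf("  true shared-strain fraction: mean %.3f (range %.3f-%.3f)\n",
                mean(ds$sharedFraction), min(ds$sharedFraction),
                max(ds$sharedFraction)))
    invisible(object)
})
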