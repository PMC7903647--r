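#' Configure an end-to-end analysis run
#'
#' Collects everything [runPipeline()] needs: either a [SimConfig-class] to
#' simulate input from, or paths to a strain table, strain-to-species map and
#' metadata on disk; the filtering, rarefaction and testing parameters; and a
#' global seed from which per-stage seeds are derived deterministically.
#'
#' @param sim a [SimConfig-class], or `NULL` when reading tables from disk.
#' @param strainTablePath,speciesMapPath,metadataPath input paths (TSV) used
#'   when `sim` is `NULL`.
#' @param minReads depth filter threshold (default 5000 reads).
#' @param minSamples singleton-taxon filter threshold (default 2 samples).
#' @param rarefy logical; rarefy to the minimum column sum before distances.
#' @param metric,basis dissimilarity metric and basis for the comparisons.
#' @param relations relations to test (see [buildPairDesign()]).
#' @param groups groups to test within each relation.
#' @param niche niche to analyse.
#' @param B permutations for each related-vs-unrelated test.
#' @param outDir output directory (created if needed); `NULL` for none.
#' @param seed global integer seed.
#' @return a list of class `pipelineConfig`.
#' @export
pipelineConfig <- function(sim = simConfig(), strainTablePath = NULL,
                           speciesMapPath = NULL, metadataPath = NULL,
                           minReads = 5000, minSamples = 2, rarefy = TRUE,
                           metric = "bray_curtis", basis = "membership",
                           relations = "mother_child",
                           groups = c("biological", "adoptive", "combined"),
                           niche = "saliva_soft_tissue", B = 1000,
                           outDir = NULL, seed = 1L) {
    if (B < 1) stop("'B' must be >= 1", call. = FALSE)
    for (p in c(strainTablePath, speciesMapPath, metadataPath))
        if (!is.null(p) && !file.exists(p))
            stop("input file does not exist: ", p, call. = FALSE)
    structure(list(sim = sim, strainTablePath = strainTablePath,
                   speciesMapPath = speciesMapPath,
                   metadataPath = metadataPath, minReads = minReads,
                   minSamples = minSamples, rarefy = rarefy, metric = metric,
                   basis = basis, relations = relations, groups = groups,
                   niche = niche, B = B, outDir = outDir,
                   seed = asSeed(seed)),
              class = "pipelineConfig")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipelineConfig()]; a `sim:` block holds
#' [simConfig()] arguments.
#'
#' @param path YAML file.
#' @return a `pipelineConfig`.
#' @export
readPipelineConfig <- function(path) {
    y <- yaml::read_yaml(path)
    sim <- if (!is.null(y$sim)) do.call(simConfig, y$sim)
           else if (is.null(y$strainTablePath)) simConfig() else NULL
    args <- y[setdiff(names(y), "sim")]
    do.call(pipelineConfig, c(list(sim = sim), args))
}

#' Run the full dyad-transmission analysis
#'
#' Executes the fixed stage order: simulate (or load) tables; depth filter;
#' singleton filter; optional rarefaction; species collapse; distance
#' matrices at strain and species level; per-relation/group dyad statistics
#' (permutation test against the unrelated universe, biological-vs-adoptive
#' rank-sum where both groups exist, shared fractions); and a run summary.
#' Per-stage seeds are spawned deterministically from the global seed, so a
#' rerun with the same config is identical. When `outDir` is set, each stage
#' writes its TSV artifact plus a JSON summary recording seeds, parameters
#' and attrition counts.
#'
#' @param config a `pipelineConfig` (see [pipelineConfig()]), or a path to a
#'   YAML config.
#' @return (invisibly) a list with `tables` (filtered strain and species
#'   [CommunityTable-class]s), `comparisons` (`data.frame`: one row per
#'   test), `sharedFractions` (`data.frame`), and `summary` (list).
#' @export
runPipeline <- function(config) {
    if (is.character(config)) config <- readPipelineConfig(config)
    stopifnot(inherits(config, "pipelineConfig"))
    seeds <- spawnSeeds(config$seed, 4L)
    log <- list()
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
                 call. = FALSE))
    }

    strain <- stage("input", {
        if (!is.null(config$sim)) {
            cfg <- config$sim
            cfg@seed <- seeds[1]
            simulatePopulation(cfg)$strainTable
        } else {
            readCommunityTable(config$strainTablePath, level = "strain",
                               speciesMap = config$speciesMapPath,
                               metadata = config$metadataPath)
        }
    })
    log$input <- c(taxa = nrow(strain), samples = ncol(strain))

    filtered <- stage("filter", {
        x <- filterLowDepth(strain, config$minReads)
        filterSingletonTaxa(x, config$minSamples)
    })
    log$filter <- c(taxa = nrow(filtered), samples = ncol(filtered),
                    samples_removed = ncol(strain) - ncol(filtered),
                    taxa_removed = nrow(strain) - nrow(filtered))

    if (config$rarefy)
        filtered <- stage("rarefy", rarefyCounts(filtered, "row_min",
                                                 seed = seeds[2]))
    species <- stage("collapse", collapseToSpecies(filtered))

    dists <- stage("distance", list(
        strain = distanceMatrix(filtered, config$metric, config$basis),
        species = distanceMatrix(species, config$metric, config$basis)))

    meta <- sampleData(filtered)
    testSeeds <- spawnSeeds(seeds[3],
                            2L * length(config$relations) *
                                length(config$groups))
    comparisons <- list(); sharedRows <- list(); si <- 1L
    for (rel in config$relations) {
        for (grp in config$groups) {
            design <- tryCatch(
                buildPairDesign(meta, rel, grp, config$niche),
                error = function(e) NULL)
            if (is.null(design)) next
            for (lev in c("strain", "species")) {
                tab <- if (lev == "strain") filtered else species
                pt <- permutationTest(design, dists[[lev]], B = config$B,
                                      seed = testSeeds[si])
                si <- si + 1L
                row <- data.frame(
                    relation = rel, group = grp, niche = config$niche,
                    level = lev, metric = config$metric,
                    basis = config$basis, test = "permutation",
                    n_pairs = nPairs(design), statistic = pt@observed,
                    p = pt@p, stringsAsFactors = FALSE)
                if (grp == "combined" &&
                    length(unique(design@familyGroup)) == 2) {
                    pd <- pairDistances(dists[[lev]], design@sideA,
                                        design@sideB)
                    rs <- rankSumTest(pd[design@familyGroup == "biological"],
                                      pd[design@familyGroup == "adoptive"])
                    row <- rbind(row, data.frame(
                        relation = rel, group = "biological_vs_adoptive",
                        niche = config$niche, level = lev,
                        metric = config$metric, basis = config$basis,
                        test = "wilcoxon", n_pairs = nPairs(design),
                        statistic = rs$statistic, p = rs$p,
                        stringsAsFactors = FALSE))
                }
                comparisons[[length(comparisons) + 1L]] <- row
                sf <- dyadSharedFractions(tab, design)
                sharedRows[[length(sharedRows) + 1L]] <- data.frame(
                    relation = rel, group = grp, level = lev,
                    mean_n_shared = mean(sf$n_shared),
                    mean_frac_by_count = mean(sf$frac_by_count),
                    mean_frac_by_abundance = mean(sf$frac_by_abundance),
                    stringsAsFactors = FALSE)
            }
        }
    }
    comparisons <- do.call(rbind, comparisons)
    if (!is.null(comparisons)) {
        comparisons$stars <- pToStars(comparisons$p)
        rownames(comparisons) <- NULL
    }
    shared <- if (length(sharedRows)) do.call(rbind, sharedRows) else NULL

    summary <- list(
        package_version = as.character(utils::packageVersion("dyadtrans")),
        global_seed = config$seed,
        stage_seeds = as.list(stats::setNames(
            seeds, c("input", "rarefy", "tests", "reserved"))),
        B = config$B, metric = config$metric, basis = config$basis,
        niche = config$niche, log = log)

    if (!is.null(config$outDir)) {
        dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
        out <- function(f) file.path(config$outDir, f)
        writeCommunityTable(filtered, out("strain_table.tsv"))
        writeCommunityTable(species, out("species_table.tsv"))
        writeSampleMetadata(meta, out("metadata.tsv"))
        writeDistanceMatrix(dists$strain, out("distance_strain.tsv"))
        writeDistanceMatrix(dists$species, out("distance_species.tsv"))
        if (!is.null(comparisons))
            writeTsv(comparisons, out("comparisons.tsv"))
        if (!is.null(shared))
            writeTsv(shared, out("shared_fractions.tsv"))
        jsonlite::write_json(summary, out("run_summary.json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    invisible(list(tables = list(strain = filtered, species = species),
                   distances = dists, comparisons = comparisons,
                   sharedFractions = shared, summary = summary))
}
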