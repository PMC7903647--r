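relationRoles <- list(
    mother_child = c("mother", "child"),
    father_child = c("father", "child"),
    couple       = c("mother", "father"),
    sibling      = c("child",  "sibling"))

#' Build a dyad pairing design from sample metadata
#'
#' Selects, for every family with both required roles sampled in the
#' requested niche and group, one sample per role side. True dyads are the
#' within-family matches; the unrelated universe is every cross-family
#' role-matched pairing (any same-family combination is excluded from the
#' universe). Families missing either role are excluded with a message;
#' if a family has several samples for a role, the first by sample ID is used.
#'
#' @param meta sample metadata `data.frame` (see [validateSampleMetadata()]).
#' @param relation `"mother_child"`, `"father_child"`, `"couple"` or
#'   `"sibling"`.
#' @param group `"biological"`, `"adoptive"` or `"combined"`.
#' @param niche niche to restrict to (default `"saliva_soft_tissue"`).
#' @return a [PairDesign-class].
#' @examples
#' sim <- simulatePopulation(simConfig(nFamilies = 6, seed = 1))
#' buildPairDesign(sim$metadata, "mother_child", "combined")
#' @export
buildPairDesign <- function(meta,
                            relation = c("mother_child", "father_child",
                                         "couple", "sibling"),
                            group = c("combined", "biological", "adoptive"),
                            niche = "saliva_soft_tissue") {
    relation <- match.arg(relation)
    group <- match.arg(group)
    meta <- validateSampleMetadata(meta)
    roles <- relationRoles[[relation]]
    sub <- meta[meta$niche == niche, , drop = FALSE]
    if (group != "combined")
        sub <- sub[sub$group == group, , drop = FALSE]
    pickRole <- function(fam, role) {
        s <- sort(sub$sample_id[sub$family_id == fam & sub$role == role])
        if (length(s)) s[1] else NA_character_
    }
    families <- sort(unique(sub$family_id))
    sideA <- vapply(families, pickRole, "", role = roles[1])
    sideB <- vapply(families, pickRole, "", role = roles[2])
    ok <- !is.na(sideA) & !is.na(sideB)
    if (any(!ok))
        message("buildPairDesign: excluded ", sum(!ok),
                " family/families lacking a ", roles[1], " or ", roles[2],
                " sample in niche ", niche, ": ",
                paste(families[!ok], collapse = ", "))
    if (sum(ok) < 2)
        stop("fewer than 2 families with both '", roles[1], "' and '",
             roles[2], "' samples in niche '", niche, "'", call. = FALSE)
    famGroup <- vapply(families[ok], function(f) {
        unique(sub$group[sub$family_id == f])[1]
    }, "")
    methods::new("PairDesign", relation = relation, group = group,
                 niche = niche, sideA = unname(sideA[ok]),
                 sideB = unname(sideB[ok]), familyA = families[ok],
                 familyB = families[ok], familyGroup = unname(famGroup))
}

#' @describeIn PairDesign-class number of true dyads.
#' @param design a `PairDesign`.
#' @export
setMethod("nPairs", "PairDesign", function(design) length(design@familyA))

#' @describeIn PairDesign-class `data.frame` of the true within-family pairs
#'   (`sample_a`, `sample_b`, `family`, `group`).
#' @export
setMethod("pairedPairs", "PairDesign", function(design) {
    data.frame(sample_a = design@sideA, sample_b = design@sideB,
               family = design@familyA, group = design@familyGroup,
               stringsAsFactors = FALSE)
})

#' @describeIn PairDesign-class `data.frame` of all cross-family role-matched
#'   pairings (the unrelated universe).
#' @export
setMethod("unrelatedPairs", "PairDesign", function(design) {
    n <- nPairs(design)
    grid <- expand.grid(i = seq_len(n), j = seq_len(n))
    grid <- grid[design@familyA[grid$i] != design@familyB[grid$j], ,
                 drop = FALSE]
    data.frame(sample_a = design@sideA[grid$i],
               sample_b = design@sideB[grid$j],
               stringsAsFactors = FALSE)
})

#' Shuffle the dyad assignment of a design
#'
#' Randomly permutes side B (e.g. children) against side A, breaking the true
#' pairing while keeping the marginal structure. Used to construct exact null
#' datasets for calibration studies.
#'
#' @param design a [PairDesign-class].
#' @param seed integer RNG seed.
#' @return a `PairDesign` with permuted side B.
#' @export
shufflePairs <- function(design, seed) {
    n <- nPairs(design)
    perm <- runSeeded(asSeed(seed), sample.int(n))
    methods::initialize(design, sideB = design@sideB[perm],
                        familyB = design@familyB[perm])
}

setMethod("show", "PairDesign", function(object) {
    cat(sprintf(paste0("PairDesign: %s (%s, %s): %d dyads, ",
                       "%d unrelated pairings\n"),
                object@relation, object@group, object@niche, nPairs(object),
                nrow(unrelatedPairs(object))))
    invisible(object)
})
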