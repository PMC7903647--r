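# Small in-code fixtures shared across tests.

# deterministic tiny count table: 4 taxa x 3 samples
tinyTable <- function(level = "species") {
    m <- matrix(c(5, 0, 3, 2,
                  0, 4, 3, 0,
                  1, 1, 1, 1), nrow = 4,
                dimnames = list(paste0("t", 1:4), paste0("s", 1:3)))
    CommunityTable(m, level = level)
}

# strain table with a two-species map
tinyStrainTable <- function() {
    m <- matrix(c(3, 4, 2, 0,
                  1, 0, 5, 2,
                  0, 2, 0, 6), nrow = 4,
                dimnames = list(c("spA_str1", "spA_str2",
                                  "spB_str1", "spB_str2"),
                                paste0("s", 1:3)))
    CommunityTable(m, level = "strain",
                   species = c(spA_str1 = "spA", spA_str2 = "spA",
                               spB_str1 = "spB", spB_str2 = "spB"))
}

# metadata for n mother-child families in one niche
dyadMetadata <- function(n, group = rep("biological", n),
                         niche = "saliva_soft_tissue",
                         ages = rep(3, n)) {
    fam <- sprintf("F%02d", seq_len(n))
    do.call(rbind, lapply(seq_len(n), function(i) data.frame(
        sample_id = c(paste0(fam[i], "_M"), paste0(fam[i], "_C")),
        subject_id = c(paste0(fam[i], "_M"), paste0(fam[i], "_C")),
        family_id = fam[i], role = c("mother", "child"),
        group = group[i], niche = niche, age_years = c(30, ages[i]),
        stringsAsFactors = FALSE)))
}

# hand-built distance objects for permutation-test fixtures:
# paired distance `within`, every cross-family distance `between`
blockDistance <- function(n, within = 0.1, between = 0.9) {
    ids <- c(sprintf("F%02d_M", seq_len(n)), sprintf("F%02d_C", seq_len(n)))
    v <- matrix(between, 2 * n, 2 * n, dimnames = list(ids, ids))
    diag(v) <- 0
    for (i in seq_len(n)) {
        v[i, n + i] <- within
        v[n + i, i] <- within
    }
    methods::new("DistanceMatrix", values = v, metric = "bray_curtis",
                 basis = "membership")
}

blockDesign <- function(n, group = rep("biological", n)) {
    fam <- sprintf("F%02d", seq_len(n))
    methods::new("PairDesign", relation = "mother_child",
                 group = "combined", niche = "saliva_soft_tissue",
                 sideA = paste0(fam, "_M"), sideB = paste0(fam, "_C"),
                 familyA = fam, familyB = fam, familyGroup = group)
}
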