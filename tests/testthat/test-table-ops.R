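test_that("low-depth filtering removes samples strictly below the cutoff", {
    m <- matrix(0, nrow = 2, ncol = 3,
                dimnames = list(c("t1", "t2"), c("s1", "s2", "s3")))
    m[1, ] <- c(6000, 4500, 7000)
    x <- CommunityTable(m, level = "species")
    expect_message(out <- filterLowDepth(x, 5000), "s2")
    expect_identical(colnames(out), c("s1", "s3"))
    expect_identical(nrow(out), 2L)
    # a sample at exactly the cutoff is retained
    m[1, 2] <- 5000
    x <- CommunityTable(m, level = "species")
    expect_identical(ncol(filterLowDepth(x, 5000)), 3L)
    # minReads = 0 is the identity
    expect_identical(counts(filterLowDepth(x, 0)), counts(x))
    expect_error(filterLowDepth(x, 1e9), "empty")
})

test_that("singleton-taxon filtering drops taxa seen in < minSamples samples", {
    m <- matrix(c(1, 1, 1, 1, 1, 1,   # everywhere
                  0, 5, 0, 0, 0, 0,   # singleton
                  0, 2, 3, 0, 0, 0),  # two samples
                nrow = 3, byrow = TRUE,
                dimnames = list(c("t1", "t2", "t3"), paste0("s", 1:6)))
    x <- CommunityTable(m, level = "strain")
    expect_message(out <- filterSingletonTaxa(x, 2), "removed 1")
    expect_identical(rownames(out), c("t1", "t3"))
    # boundary: present in exactly minSamples samples -> retained
    expect_true("t3" %in% rownames(filterSingletonTaxa(x, 2)))
    # minSamples = 1 is the identity
    expect_identical(counts(filterSingletonTaxa(x, 1)), counts(x))
    expect_warning(filterSingletonTaxa(x, 10), "all taxa")
})

test_that("the packaged filter pipeline applies depth first, then singletons", {
    path <- system.file("extdata", "toy_counts.tsv", package = "dyadtrans")
    x <- readCommunityTable(path, level = "strain")
    expect_identical(unname(colSums(counts(x))),
                     c(6000, 4500, 7000, 5000, 5100, 12000))
    out <- suppressMessages(filterPipeline(x))
    expect_identical(ncol(out), 5L)          # strict < 5000 removes S2 only
    expect_false("S2" %in% colnames(out))
    expect_identical(nrow(out), 4L)          # both singleton ASVs removed
    expect_false(any(c("s1", "s2") %in% rownames(out)))
})

test_that("rarefaction hits the requested depth, keeps zeros, and is seeded", {
    set.seed(42)
    m <- matrix(rpois(60, 50), nrow = 6,
                dimnames = list(paste0("t", 1:6), paste0("s", 1:10)))
    m[3, ] <- 0
    x <- CommunityTable(m, level = "species")
    dmin <- min(colSums(m))
    out <- rarefyCounts(x, "row_min", seed = 9)
    expect_true(all(colSums(counts(out)) == dmin))
    expect_true(all(counts(out)[3, ] == 0))
    expect_true(all(counts(out) <= counts(x)))
    # determinism / seed sensitivity
    expect_identical(counts(rarefyCounts(x, 100, seed = 1)),
                     counts(rarefyCounts(x, 100, seed = 1)))
    expect_false(identical(counts(rarefyCounts(x, 100, seed = 1)),
                           counts(rarefyCounts(x, 100, seed = 2))))
    expect_error(rarefyCounts(x, max(colSums(m)) + 1), "s[0-9]+")
})

test_that("presence/absence conversion is binary and idempotent", {
    x <- tinyTable()
    pa <- toPresenceAbsence(x)
    expect_true(all(counts(pa) %in% c(0, 1)))
    expect_identical(counts(pa), (counts(x) > 0) + 0)
    expect_identical(counts(toPresenceAbsence(pa)), counts(pa))
})

test_that("relative abundance columns sum to one and reject empty samples", {
    x <- tinyTable()
    ra <- toRelativeAbundance(x)
    expect_true(all(abs(colSums(ra) - 1) < 1e-12))
    expect_equal(unname(ra[, 3]), c(0.25, 0.25, 0.25, 0.25))
    m <- counts(x); m[, 2] <- 0
    expect_error(toRelativeAbundance(CommunityTable(m, level = "species")),
                 "zero-sum")
})

test_that("species collapse sums member strains and conserves column sums", {
    x <- tinyStrainTable()
    sp <- collapseToSpecies(x)
    expect_identical(taxonLevel(sp), "species")
    expect_identical(unname(counts(sp)["spA", ]),
                     unname(counts(x)[1, ] + counts(x)[2, ]))
    expect_identical(colSums(counts(sp)), colSums(counts(x)))
    # identity map -> unchanged up to relabelling
    m <- counts(tinyTable())
    x1 <- CommunityTable(m, level = "strain",
                         species = stats::setNames(rownames(m), rownames(m)))
    sp1 <- collapseToSpecies(x1)
    expect_identical(counts(sp1)[rownames(m), ], m)
    # missing map is an error naming taxa
    expect_error(collapseToSpecies(CommunityTable(m, level = "strain")),
                 "t1")
})

test_that("tables and metadata round-trip through TSV", {
    x <- tinyStrainTable()
    meta <- dyadMetadata(2)[1:3, ]
    meta$sample_id <- colnames(x)
    tf <- tempfile(fileext = ".tsv")
    mf <- tempfile(fileext = ".tsv")
    writeCommunityTable(x, tf, mapPath = mf)
    writeSampleMetadata(meta, mt <- tempfile(fileext = ".tsv"))
    y <- readCommunityTable(tf, level = "strain", speciesMap = mf,
                            metadata = mt)
    expect_identical(counts(y), counts(x))
    expect_identical(strainToSpecies(y), strainToSpecies(x))
    expect_identical(sampleData(y)$family_id, meta$family_id)
    # transposed reader
    tr <- tempfile(fileext = ".tsv")
    df <- data.frame(sample_id = colnames(x), t(counts(x)),
                     check.names = FALSE)
    write.table(df, tr, sep = "\t", quote = FALSE, row.names = FALSE)
    z <- readCommunityTable(tr, level = "strain", transposed = TRUE)
    expect_identical(counts(z), counts(x))
})

test_that("metadata validation enforces the contract", {
    meta <- dyadMetadata(2)
    expect_silent(validateSampleMetadata(meta))
    bad <- meta; bad$sample_id[2] <- bad$sample_id[1]
    expect_error(validateSampleMetadata(bad), "unique")
    bad <- meta; bad$role[1] <- "uncle"
    expect_error(validateSampleMetadata(bad), "role")
    expect_error(validateSampleMetadata(meta, require = "nope"), "nope")
    expect_identical(codeOrdinal(c("none", "mild", "moderate", "severe")),
                     1:4)
    expect_error(codeOrdinal("huge"), "huge")
})
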