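# Correlation-based feature ranking and cross-target counting.

test_that("self- and affine-anticorrelated features hit r = +/-1", {
    set.seed(1)
    y <- rnorm(30)
    X <- cbind(same = y, anti = -2 * y + 7, noise = rnorm(30))
    r <- featureTargetCorrelations(X, y)
    expect_equal(r[["same"]], 1.0, tolerance = 1e-12)
    expect_equal(r[["anti"]], -1.0, tolerance = 1e-12)
})

test_that("independent features have small correlations at n = 1000", {
    hits <- 0L
    for (s in 1:100) {
        set.seed(200 + s)
        X <- matrix(rnorm(1000), 1000, 1,
                    dimnames = list(NULL, "noise"))
        r <- featureTargetCorrelations(X, rnorm(1000))
        if (abs(r) < 0.1) hits <- hits + 1L
    }
    expect_gte(hits, 99L)
})

test_that("zero-variance features warn and get r = 0; flat target errors", {
    set.seed(2)
    X <- cbind(const = rep(1, 20), ok = rnorm(20))
    y <- rnorm(20)
    expect_warning(r <- featureTargetCorrelations(X, y), "zero-variance")
    expect_identical(r[["const"]], 0)
    expect_error(featureTargetCorrelations(X, rep(2, 20)),
                 "zero-variance target")
    expect_error(featureTargetCorrelations(X[1:2, ], y[1:2]),
                 "at least 3")
})

test_that("top-5 ranking follows |r| with index tie-breaks", {
    r <- c(0.9, 0.8, 0.7, 0.6, 0.5, 0.1, 0.05)
    expect_identical(topFeatures(r), 1:5)
    expect_identical(topFeatures(rep(0.3, 10)), 1:5)
    r2 <- c(-0.95, 0.9, 0.5, 0.2, 0.8, 0.1)
    expect_identical(topFeatures(r2)[1], 1L)        # magnitude ranking
    expect_identical(topFeatures(r2, absolute = FALSE)[1], 2L)
})

test_that("top-k matches an exhaustive sort oracle on random vectors", {
    set.seed(3)
    for (i in 1:20) {
        r <- round(runif(45, -1, 1), 2)             # induces ties
        got <- topFeatures(r)
        key <- abs(r)
        oracle <- integer(0)
        remaining <- seq_along(r)
        for (k in 1:5) {
            best <- remaining[key[remaining] == max(key[remaining])]
            pick <- min(best)                       # lowest index on ties
            oracle <- c(oracle, pick)
            remaining <- setdiff(remaining, pick)
        }
        expect_identical(got, oracle)
    }
})

test_that("ranking by |r| equals ranking by r^2", {
    set.seed(4)
    for (i in 1:10) {
        r <- runif(45, -1, 1)
        expect_identical(order(-abs(r), seq_along(r)),
                         order(-r^2, seq_along(r)))
    }
})

test_that("cross-target counts sum to k x n_targets", {
    top <- list(1:5, c(2L, 3L, 9L, 11L, 20L), c(1L, 2L, 3L, 4L, 45L))
    counts <- maxIndexCounts(top)
    expect_identical(sum(counts), 15L)
    expect_identical(unname(counts[2]), 3L)
    # identical top-5 across 8 targets
    counts8 <- maxIndexCounts(rep(list(c(3L, 7L, 12L, 30L, 41L)), 8))
    expect_identical(unname(counts8[c(3, 7, 12, 30, 41)]), rep(8L, 5))
    expect_identical(sum(counts8), 40L)
    # one target: indicator summing to 5
    one <- maxIndexCounts(list(c(5L, 6L, 7L, 8L, 9L)))
    expect_identical(sum(one), 5L)
    expect_true(all(one %in% c(0L, 1L)))
})

test_that("top-k is permutation-equivariant", {
    set.seed(5)
    r <- rnorm(45)                                   # continuous: no ties
    perm <- sample.int(45)
    topP <- topFeatures(r[perm])
    expect_identical(perm[topP], topFeatures(r))
})

test_that("monotone-transform features enter every target's top-5", {
    set.seed(6)
    n <- 120
    driver <- runif(n, 0.15, 0.55)
    X <- matrix(rnorm(n * 45), n, 45,
                dimnames = list(NULL, paste0("f", 1:45)))
    X[, 10] <- driver                                # monotone transforms
    X[, 15] <- driver^3
    targets <- lapply(1:8, function(i) 0.2 + i * driver +
                                       rnorm(n, 0, 0.02 * i))
    names(targets) <- paste0("target_", 1:8, "_bmc")
    te <- makeTE(X, targets)
    sel <- selectFeatures(te, targets = names(targets))
    expect_true(all(apply(selectionTop(sel), 2,
                          function(v) all(c(10L, 15L) %in% v))))
    expect_identical(sum(selectionCounts(sel)), 40L)
})

test_that("selection CSV export is deterministic across reruns", {
    spec <- cohortSpec(nCases = 30, regions = "L1", seed = 71L,
                       phantom = phantomParams(gridSize = c(16L, 16L)))
    te <- extractFeatures(generateCohort(spec))
    sel <- selectFeatures(te)
    d1 <- tempfile(); d2 <- tempfile()
    dir.create(d1); dir.create(d2)
    writeSelection(sel, file.path(d1, "sel"))
    writeSelection(selectFeatures(te), file.path(d2, "sel"))
    for (f in c("sel_correlations.csv", "sel_counts.csv"))
        expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                         readBin(file.path(d2, f), "raw", 1e6))
})
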