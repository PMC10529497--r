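# Discretization, GLCM construction and Haralick statistics.

test_that("equal-width discretization matches the worked 4-level example", {
    g <- matrix(c(0, 200, 100, 300), 2)    # rows: (0, 100), (200, 300)
    expect_identical(discretize(g, 4), matrix(c(1L, 3L, 2L, 4L), 2))
})

test_that("constant grids map to level 1 and the maximum maps to level n", {
    expect_identical(discretize(matrix(5, 3, 3), 8), matrix(1L, 3, 3))
    g <- matrix(c(0, 1, 2, 3), 2)
    d <- discretize(g, 4)
    expect_identical(d[g == 3], 4L)
})

test_that("two-level discretization splits at the range midpoint", {
    set.seed(1)
    g <- matrix(runif(64, 0, 100), 8)
    g[1] <- 0; g[64] <- 100            # pin the range
    d <- discretize(g, 2)
    mid <- 50
    expect_true(all(d[g < mid] == 1L))
    expect_true(all(d[g > mid] == 2L))
    expect_identical(d[g == 100], 2L)
})

test_that("GLCM of the worked 2x2 grid matches the symmetrized counts", {
    g <- matrix(c(1L, 1L, 1L, 2L), 2)  # rows: (1, 1), (1, 2)
    p <- glcmMatrix(computeGLCM(g, levels = 2))
    expect_equal(p, matrix(c(0.5, 0.25, 0.25, 0), 2), tolerance = 0)
})

test_that("a constant grid concentrates all mass at (1, 1)", {
    p <- glcmMatrix(computeGLCM(matrix(1L, 4, 4), levels = 2))
    expect_identical(p[1, 1], 1)
    expect_identical(sum(p), 1)
})

test_that("transposing the grid swaps horizontal and vertical GLCMs", {
    set.seed(7)
    for (i in 1:10) {
        g <- matrix(sample.int(4L, 64, replace = TRUE), 8)
        for (sym in c(TRUE, FALSE)) {
            h <- glcmMatrix(computeGLCM(g, 4, "horizontal",
                                        symmetric = sym))
            vT <- glcmMatrix(computeGLCM(t(g), 4, "vertical",
                                         symmetric = sym))
            expect_equal(h, vT, tolerance = 0)
        }
    }
})

test_that("GLCM matches the naive pair-counting oracle on random grids", {
    set.seed(11)
    for (i in 1:25) {
        nr <- sample(2:8, 1); nc <- sample(2:8, 1)
        lv <- sample(2:6, 1)
        g <- matrix(sample.int(lv, nr * nc, replace = TRUE), nr)
        for (o in c("horizontal", "vertical")) {
            if (o == "horizontal" && nc < 2) next
            if (o == "vertical" && nr < 2) next
            for (sym in c(TRUE, FALSE)) {
                got <- glcmMatrix(computeGLCM(g, lv, o, symmetric = sym))
                expect_equal(got, naiveGLCM(g, lv, o, symmetric = sym),
                             tolerance = 0)
            }
        }
    }
})

test_that("uniform 2x2 GLCM reproduces the closed-form statistics", {
    g <- new("GLCM", p = matrix(0.25, 2, 2), levels = 2L,
             orientation = "horizontal", distance = 1L, symmetric = TRUE)
    s <- glcmStatistics(g)
    expect_equal(unname(s), c(2.0, 0.5, 0.0, 0.75, 0.25),
                 tolerance = 1e-12)
})

test_that("degenerate single-cell GLCM uses the sigma = 0 convention", {
    p <- matrix(0, 2, 2); p[1, 1] <- 1
    g <- new("GLCM", p = p, levels = 2L, orientation = "horizontal",
             distance = 1L, symmetric = TRUE)
    s <- glcmStatistics(g)
    expect_equal(unname(s), c(0, 0, 0, 1, 0), tolerance = 1e-12)
})

test_that("identity-diagonal GLCM has correlation exactly 1", {
    n <- 16L
    g <- new("GLCM", p = diag(n) / n, levels = n,
             orientation = "horizontal", distance = 1L, symmetric = TRUE)
    expect_equal(glcmStatistics(g)[["correlation"]], 1.0,
                 tolerance = 1e-12)
})

test_that("statistic ranges hold on random grids", {
    set.seed(23)
    for (i in 1:15) {
        lv <- sample(c(4L, 8L, 16L), 1)
        g <- matrix(sample.int(lv, 144, replace = TRUE), 12)
        glcm <- computeGLCM(g, lv)
        s <- glcmStatistics(glcm)
        expect_gte(s[["entropy"]], 0)
        expect_lte(s[["entropy"]], 2 * log2(lv) + 1e-12)
        expect_gt(s[["homogeneity"]], 0)
        expect_lte(s[["homogeneity"]], 1)
        expect_gte(s[["correlation"]], -1 - 1e-12)
        expect_lte(s[["correlation"]], 1 + 1e-12)
        expect_gte(s[["contrast"]], 0)
        p <- glcmMatrix(glcm)
        expect_equal(sum(p), 1, tolerance = 1e-12)
        expect_equal(p, t(p), tolerance = 0)
    }
})

test_that("grids without pairs at the offset are rejected", {
    g <- matrix(1L, 8, 1)
    expect_error(computeGLCM(g, 2, "horizontal"), "no pixel pairs")
    expect_error(computeGLCM(t(g), 2, "vertical"), "no pixel pairs")
})
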