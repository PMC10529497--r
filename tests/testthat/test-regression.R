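# Exclusion rule, z-scoring, least-squares fit, prediction and
# evaluation.

test_that("exclusion removes missing-feature rows and sub-cutoff BMD", {
    set.seed(2)
    X <- matrix(rnorm(5 * 10), 5, 10)
    X[2, 4] <- NA                                  # one missing feature
    te <- makeTE(X, list(neck_bmd = c(0.9, 0.8, 0.10, 0.7, 0.15)))
    ex <- excludeCases(te, "neck_bmd")
    expect_identical(ncol(ex$experiment), 3L)       # rows 1, 4, 5 kept
    expect_identical(nrow(ex$log), 2L)
    expect_match(ex$log$reason[1], "missing")
    expect_match(ex$log$reason[2], "below")
    # boundary: exactly 0.15 is retained (strict 'below')
    expect_true("case_005" %in% cohortData(ex$experiment)$caseId)
})

test_that("BMC targets use only the missingness rule", {
    set.seed(3)
    X <- matrix(rnorm(4 * 6), 4, 6)
    te <- makeTE(X, list(lumbar_bmc = c(40, 0.1, 0.05, 55)))
    ex <- excludeCases(te, "lumbar_bmc")
    expect_identical(ncol(ex$experiment), 4L)       # no floor for BMC
})

test_that("excluding every row raises an empty-cohort error", {
    X <- matrix(rnorm(3 * 4), 3, 4)
    te <- makeTE(X, list(neck_bmd = c(0.1, 0.12, 0.14)))
    expect_error(excludeCases(te, "neck_bmd"), "empty cohort")
})

test_that("generated floor cohorts filter to the designed count", {
    spec <- cohortSpec(nCases = 100, regions = "L1", bmdFloorRate = 0.1,
                       seed = 44L)
    te <- extractFeatures(generateCohort(spec))
    ex <- excludeCases(te, "total_lumbar_bmd")
    expect_identical(ncol(ex$experiment), 90L)
    expect_identical(nrow(ex$log), 10L)
})

test_that("z-scoring gives mean 0, sd 1 and inverts exactly", {
    set.seed(5)
    X <- matrix(rnorm(40 * 6, 100, 25), 40, 6,
                dimnames = list(NULL, paste0("f", 1:6)))
    y <- rnorm(40, 1, 0.2)
    nm <- normalizeFeatures(X, y)
    expect_lt(max(abs(colMeans(nm$X))), 1e-10)
    expect_lt(max(abs(apply(nm$X, 2, sd) - 1)), 1e-10)
    expect_lt(abs(mean(nm$y)), 1e-10)
    expect_lt(abs(sd(nm$y) - 1), 1e-10)
    back <- sweep(sweep(nm$X, 2, nm$featureSds, "*"), 2, nm$featureMeans,
                  "+")
    expect_equal(back, X, tolerance = 1e-10)
})

test_that("degenerate variance paths: dropped features and target error", {
    set.seed(6)
    X <- cbind(const = rep(3, 20), ok = rnorm(20))
    y <- rnorm(20)
    expect_warning(nm <- normalizeFeatures(X, y), "zero-variance")
    expect_identical(nm$dropped, "const")
    expect_identical(colnames(nm$X), "ok")
    expect_error(normalizeFeatures(X[, 2, drop = FALSE], rep(1, 20)),
                 "zero-variance target")
})

test_that("identity fit: single normalized feature recovers w0 = 0, w1 = 1",
{
    X <- matrix(c(-1, 0, 1), 3, 1, dimnames = list(NULL, "x"))
    fit <- fitLinearModel(X, c(-1, 0, 1))
    expect_equal(fit$bias, 0, tolerance = 1e-12)
    expect_equal(unname(fit$weights), 1, tolerance = 1e-12)
})

test_that("noiseless linear targets are recovered exactly", {
    set.seed(7)
    X <- matrix(rnorm(60 * 45), 60, 45,
                dimnames = list(NULL, paste0("f", 1:45)))
    w <- rnorm(45)
    y <- drop(X %*% w) + 0.3
    fit <- fitLinearModel(X, y)
    expect_equal(unname(fit$weights), w, tolerance = 1e-8)
    expect_equal(fit$bias, 0.3, tolerance = 1e-8)
    rss <- sum((y - fit$bias - drop(X %*% fit$weights))^2)
    expect_lt(rss, 1e-16 * 60)
})

test_that("fitted weights match the normal-equations oracle under noise", {
    set.seed(8)
    X <- matrix(rnorm(60 * 45), 60, 45,
                dimnames = list(NULL, paste0("f", 1:45)))
    y <- drop(X %*% rnorm(45)) + rnorm(60, 0, 0.1)
    fit <- fitLinearModel(X, y)
    A <- cbind(1, X)
    oracle <- solve(t(A) %*% A, t(A) %*% y)
    expect_equal(c(fit$bias, unname(fit$weights)), unname(drop(oracle)),
                 tolerance = 1e-8)
})

test_that("duplicating a feature column leaves predictions unchanged", {
    set.seed(9)
    X <- matrix(rnorm(30 * 5), 30, 5,
                dimnames = list(NULL, paste0("f", 1:5)))
    y <- rnorm(30)
    fit1 <- fitLinearModel(X, y)
    X2 <- cbind(X, f1dup = X[, 1])
    fit2 <- fitLinearModel(X2, y)
    pred1 <- fit1$bias + drop(X %*% fit1$weights)
    pred2 <- fit2$bias + drop(X2 %*% fit2$weights)
    expect_equal(pred1, pred2, tolerance = 1e-8)
})

test_that("evaluation recovers perfect and anti-monotone limits", {
    spec <- cohortSpec(nCases = 20, regions = "L1",
                       targetModel = defaultTargetModel(r = 1), seed = 13L)
    te <- extractFeatures(generateCohort(spec))
    # mean HU is monotone in the driver; with r = 1 and p > n the fit
    # interpolates: perfect in-sample correlation
    fit <- fitBMDModel(te, "total_lumbar_bmd")
    ev <- evaluateModel(fit$model, fit$experiment)
    expect_equal(ev$cc, 1.0, tolerance = 1e-8)
    expect_lt(ev$mse, 1e-12)
    # anti-monotone linear predictions give cc = -1
    y <- rnorm(10)
    pred <- 2 - 3 * y
    expect_equal(cor(pred, y), -1, tolerance = 1e-12)
})

test_that("cc is affine-invariant and mse scales quadratically", {
    spec <- cohortSpec(nCases = 60, regions = "L1", seed = 22L,
                       phantom = phantomParams(gridSize = c(16L, 16L)))
    te <- extractFeatures(generateCohort(spec))
    fit <- fitBMDModel(te, "total_lumbar_bmd")
    X <- featureMatrix(fit$experiment)
    y <- cohortData(fit$experiment)$total_lumbar_bmd
    pred <- predict(fit$model, X)
    cc <- cor(pred, y)
    mse <- mean((pred - y)^2)
    expect_equal(cor(3 * pred + 1, 3 * y + 1), cc, tolerance = 1e-12)
    expect_equal(mean(((3 * pred + 1) - (3 * y + 1))^2), 9 * mse,
                 tolerance = 1e-9)
})

test_that("fewer than 3 evaluation cases is an error", {
    set.seed(10)
    X <- matrix(rnorm(10 * 4), 10, 4,
                dimnames = list(NULL, paste0("f", 1:4)))
    y <- rnorm(10)
    te <- makeTE(X, list(t_bmc = y))
    fit <- fitBMDModel(te, "t_bmc")
    expect_error(evaluateModel(fit$model, X[1:2, , drop = FALSE],
                               y[1:2]), "fewer than 3")
})

test_that("in-sample MSE never exceeds the target variance", {
    for (s in 1:3) {
        spec <- cohortSpec(nCases = 70, regions = "L1", seed = 50L + s,
                           phantom = phantomParams(gridSize = c(16L, 16L)))
        te <- extractFeatures(generateCohort(spec))
        fit <- fitBMDModel(te, "femur_neck_bmc")
        ev <- evaluateModel(fit$model, fit$experiment)
        y <- cohortData(fit$experiment)$femur_neck_bmc
        expect_lte(ev$mse, mean((y - mean(y))^2) + 1e-12)
    }
})

test_that("weight error shrinks as the cohort grows", {
    set.seed(12)
    w <- rnorm(20)
    rmse <- vapply(c(100, 400, 1600), function(n) {
        X <- matrix(rnorm(n * 20), n, 20,
                    dimnames = list(NULL, paste0("f", 1:20)))
        y <- drop(X %*% w) + rnorm(n, 0, 1)
        fit <- fitLinearModel(X, y)
        sqrt(mean((fit$weights - w)^2))
    }, numeric(1))
    expect_lt(rmse[3], rmse[1])
    expect_lt(rmse[2], rmse[1])
})

test_that("models round-trip through JSON with identical predictions", {
    spec <- cohortSpec(nCases = 25, regions = "L1", seed = 33L,
                       phantom = phantomParams(gridSize = c(16L, 16L)))
    te <- extractFeatures(generateCohort(spec))
    fit <- fitBMDModel(te, "total_femur_bmd")
    path <- tempfile(fileext = ".json")
    writeBMDModel(fit$model, path)
    back <- readBMDModel(path)
    X <- featureMatrix(fit$experiment)
    expect_equal(predict(back, X), predict(fit$model, X),
                 tolerance = 1e-12)
    expect_identical(back@targetName, "total_femur_bmd")
})
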