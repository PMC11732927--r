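test_that("separable training data is fit to a training AUROC of 1", {
    set.seed(3)
    x <- cbind(sig = sample(0:1, 120, TRUE), noise = rnorm(120))
    y <- x[, "sig"]
    m <- fitCrowdingModel(x, y, defaultHyperparameters(20, max_depth = 2), seed = 1)
    expect_identical(aurocScore(predict(m, x), y), 1)
})

test_that("fits are reproducible given the seed", {
    set.seed(4)
    x <- matrix(rnorm(600), 100, 6, dimnames = list(NULL, paste0("f", 1:6)))
    y <- rbinom(100, 1, plogis(x[, 1]))
    m1 <- fitCrowdingModel(x, y, defaultHyperparameters(30), seed = 5)
    m2 <- fitCrowdingModel(x, y, defaultHyperparameters(30), seed = 5)
    expect_identical(predict(m1, x), predict(m2, x))
})

test_that("single-class training sets fall back to a constant model", {
    x <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
    expect_warning(m <- fitCrowdingModel(x, rep(0L, 20)), "single-class")
    expect_true(all(predict(m, x) == 0))
    expect_warning(m1 <- fitCrowdingModel(x, rep(1L, 20)), "single-class")
    expect_true(all(predict(m1, x) == 1))
})

test_that("stride bookkeeping: one refit when stride spans the test set", {
    fx <- cachedDesign(40, 11)
    start <- min(designDates(fx$dm))
    hyper <- defaultHyperparameters(10, max_depth = 3)
    runStatic <- expandingWindowForecast(
        fx$dm, splitConfig(start + 24, start + 39, strideDays = 30),
        hyper, seed = 1)
    expect_identical(runMeta(runStatic)$nRefits, 1L)
    expect_identical(nrow(predictions(runStatic)), 15L * 4L * 6L)

    runDaily <- expandingWindowForecast(
        fx$dm, splitConfig(start + 29, start + 39, strideDays = 1),
        hyper, seed = 1)
    meta <- runMeta(runDaily)
    expect_identical(meta$nRefits, 10L)
    pr <- predictions(runDaily)
    expect_true(all(pr$probability >= 0 & pr$probability <= 1))
    expect_true(all(pr$train_window_end < pr$date))
    ends <- sort(unique(pr$train_window_end))
    expect_identical(length(ends), 10L)
    expect_true(all(diff(ends) > 0))
    expect_true(all(diff(meta$trainSizes) > 0))
})

test_that("an empty test range is a structural error", {
    fx <- cachedDesign(40, 11)
    start <- min(designDates(fx$dm))
    expect_error(
        expandingWindowForecast(fx$dm,
                                splitConfig(start + 100, start + 120),
                                defaultHyperparameters(5), seed = 1),
        "test range")
})

test_that("full features outperform a calendar-only baseline", {
    hyper <- defaultHyperparameters(40, max_depth = 4)
    calRoles <- c("calendar", "subgroup", "origin")
    deltas <- vapply(c(21L, 22L, 23L), function(seed) {
        fx <- cachedDesign(160, seed)
        f <- designFeatures(fx$dm)
        y <- designLabel(fx$dm)
        dts <- designDates(fx$dm)
        trainIdx <- dts <= min(dts) + 119
        testIdx <- !trainIdx
        roles <- featureRoles(fx$dm)
        evalAuc <- function(cols) {
            m <- fitCrowdingModel(f[trainIdx, cols, drop = FALSE], y[trainIdx],
                                  hyper, seed = 1)
            aurocScore(predict(m, f[testIdx, cols, drop = FALSE]), y[testIdx])
        }
        evalAuc(colnames(f)) - evalAuc(colnames(f)[roles %in% calRoles])
    }, numeric(1))
    expect_gt(mean(deltas), 0)
    expect_gt(sum(deltas > 0), 1)   # majority of seeds
})
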