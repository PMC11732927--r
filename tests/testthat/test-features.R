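test_that("design-matrix geometry follows days x subgroups x origins", {
    fx <- cachedDesign(40, 11)
    dm <- fx$dm
    expect_identical(dim(dm), c(40L * 4L * 6L, 1366L))
    roles <- featureRoles(dm)
    expect_identical(sum(roles == "lookback"), 1344L)
    expect_identical(length(roles), 1365L)          # + label = 1366 columns
    expect_identical(sum(roles == "lag"), 8L)
    expect_identical(sum(roles %in% c("calendar", "beds", "weather",
                                      "subgroup", "origin")), 13L)
    f <- designFeatures(dm)
    expect_setequal(unique(f[, "subgroup"]), 0:3)
    expect_setequal(unique(f[, "origin"]), 8:13)
    expect_true(all(f[, "weekday"] %in% 0:6))
    expect_true(all(f[, "month"] %in% 1:12))
})

test_that("lag columns are missing for exactly the first 7 and 14 days", {
    fx <- cachedDesign(40, 11)
    f <- designFeatures(fx$dm)
    dts <- designDates(fx$dm)
    firstDate <- min(dts)
    for (col in c("q90_bedoccupying_7", "q90_medical_7")) {
        miss <- is.na(f[, col])
        expect_identical(sum(miss), 7L * 4L * 6L)
        expect_true(all(dts[miss] < firstDate + 7))
    }
    for (col in c("q90_surgical_14", "q90_critical_14")) {
        miss <- is.na(f[, col])
        expect_identical(sum(miss), 14L * 4L * 6L)
        expect_true(all(dts[miss] < firstDate + 14))
    }
    ## populated lag cells carry the daily label of the named subgroup
    daily <- dailyCrowding(fx$labels)
    d20 <- which(dts == firstDate + 19)
    expect_true(all(f[d20, "q90_medical_7"] ==
                    as.numeric(daily["medical", 20 - 7])))
})

test_that("a one-day single-subgroup panel yields one all-missing-history row", {
    panel <- toyPanel(rep(0.95, 24))
    labels <- crowdingLabels(panel)
    dm <- buildDesignMatrix(panel, toyCovariates(as.Date("2018-01-01")),
                            labels, origins = 8L)
    expect_identical(nrow(designFeatures(dm)), 1L)
    roles <- featureRoles(dm)
    f <- designFeatures(dm)
    ## only the same day's hours 0..7 precede origin 8; everything that would
    ## reach before the panel start is missing
    lb <- f[, roles == "lookback", drop = FALSE]
    ks <- as.integer(sub(".*_t", "", colnames(lb)))
    expect_true(all(is.na(lb[, ks > 8])))
    expect_true(all(!is.na(lb[, ks <= 8])))
    expect_identical(ncol(f), 13L + 2L + 336L)
    expect_true(all(is.na(f[, roles == "lag"])))
    expect_identical(designLabel(dm), 1L)
})

test_that("lookback cells equal the panel strictly before the origin", {
    fx <- cachedDesign(40, 11)
    f <- designFeatures(fx$dm)
    dts <- designDates(fx$dm)
    occ <- occupancy(fx$sim$panel)
    ind <- hourlyIndicators(fx$labels)
    firstDate <- min(dts)
    set.seed(42)
    for (r in sample(nrow(f), 50)) {
        d <- as.integer(dts[r] - firstDate) + 1L
        og <- f[r, "origin"]
        for (k in c(1L, 24L, 168L)) {
            h <- (d - 1L) * 24L + og + 1L - k
            for (s in c("medical", "bedoccupying")) {
                expv <- if (h >= 1) unname(occ[s, h]) else NA_real_
                expi <- if (h >= 1) as.numeric(ind[s, h]) else NA_real_
                expect_equal(unname(f[r, sprintf("occ_%s_t%03d", s, k)]), expv)
                expect_equal(unname(f[r, sprintf("q90h_%s_t%03d", s, k)]), expi)
            }
        }
    }
})

test_that("leakage audit passes a faithful build and flags injected faults", {
    fx <- cachedDesign(40, 11)
    aud <- leakageAudit(fx$dm, fx$sim$panel, fx$labels)
    expect_true(aud$pass)
    expect_identical(aud$nViolations, 0L)

    ## shift one lookback cell to the origin hour -> exactly one violation
    dm2 <- fx$dm
    occ <- occupancy(fx$sim$panel)
    r <- 500L
    d <- as.integer(designDates(dm2)[r] - min(designDates(dm2))) + 1L
    og <- designFeatures(dm2)[r, "origin"]
    dm2@features[r, "occ_medical_t001"] <- occ["medical", (d - 1L) * 24L + og + 1L]
    aud2 <- leakageAudit(dm2, fx$sim$panel, fx$labels)
    expect_false(aud2$pass)
    expect_identical(aud2$nViolations, 1L)
    expect_identical(aud2$violations$column, "occ_medical_t001")
    expect_identical(aud2$violations$row, r)

    ## copy the label into a base feature column -> same-day-dependence flag
    dm3 <- fx$dm
    dm3@features[, "precipitation_mm"] <- as.numeric(designLabel(dm3))
    aud3 <- leakageAudit(dm3, fx$sim$panel, fx$labels)
    expect_false(aud3$pass)
    expect_true("precipitation_mm" %in% aud3$sameDayFlags)
})

test_that("rebuilds are bit-identical and row order is canonical", {
    fx <- cachedDesign(40, 11)
    dm2 <- buildDesignMatrix(fx$sim$panel, fx$sim$covariates, fx$labels)
    expect_identical(designFeatures(fx$dm), designFeatures(dm2))
    expect_identical(designLabel(fx$dm), designLabel(dm2))

    ## shuffle rows, then restore canonical (date, subgroup, origin) order
    f <- designFeatures(fx$dm)
    set.seed(1)
    perm <- sample(nrow(f))
    o <- order(designDates(fx$dm)[perm], f[perm, "subgroup"], f[perm, "origin"])
    expect_identical(f[perm, ][o, ], f)
})

test_that("mismatched inputs and unknown subgroups are rejected", {
    fx <- cachedDesign(40, 11)
    shortCov <- EDCovariates(covariateData(fx$sim$covariates)[1:20, ])
    expect_error(buildDesignMatrix(fx$sim$panel, shortCov, fx$labels),
                 "same date range")
    expect_error(buildDesignMatrix(fx$sim$panel, fx$sim$covariates, fx$labels,
                                   subgroups = "walkin"), "unknown subgroup")
    expect_error(buildDesignMatrix(fx$sim$panel, fx$sim$covariates, fx$labels,
                                   origins = c(8, 25)), "origins")
})
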