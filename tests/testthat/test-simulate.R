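test_that("identical configs are bit-identical and different seeds differ", {
    a <- simulatePanel(edSimConfig(nDays = 20, seed = 7))
    b <- simulatePanel(edSimConfig(nDays = 20, seed = 7))
    expect_identical(occupancy(a$panel), occupancy(b$panel))
    expect_identical(covariateData(a$covariates), covariateData(b$covariates))
    c <- simulatePanel(edSimConfig(nDays = 20, seed = 8))
    expect_false(identical(occupancy(a$panel), occupancy(c$panel)))
})

test_that("zero arrival rate gives identically zero occupancy and EDOR", {
    sim <- simulatePanel(edSimConfig(
        nDays = 5, seed = 1,
        baseRate = c(critical = 0, medical = 0, surgical = 0)))
    expect_true(all(occupancy(sim$panel) == 0))
    expect_true(all(edor(sim$panel) == 0))
})

test_that("panel covers exactly nDays x 24 contiguous hours", {
    sim <- cachedSim(35, 3)
    p <- sim$panel
    expect_identical(ncol(p), 35L * 24L)
    ts <- panelTimestamps(p)
    expect_true(all(diff(as.numeric(ts)) == 3600))
    expect_identical(length(panelDates(p)), 35L)
    cd <- SummarizedExperiment::colData(p)
    expect_identical(as.integer(cd$hour), rep(0:23, 35))
})

test_that("EDOR times capacity equals occupancy and sections sum to bedoccupying", {
    sim <- cachedSim(35, 3)
    occ <- occupancy(sim$panel)
    ed <- edor(sim$panel)
    caps <- capacities(sim$panel)
    expect_equal(ed * caps[rownames(ed)], occ, ignore_attr = FALSE)
    expect_identical(
        occ["bedoccupying", ],
        occ["critical", ] + occ["medical", ] + occ["surgical", ])
})

test_that("constant-rate occupancy converges to the M/G/infinity mean", {
    lambda <- 3; losMean <- 5
    cfg <- edSimConfig(
        nDays = 420, seed = 11,
        baseRate = c(critical = 0, medical = lambda, surgical = 0),
        hourMult = rep(1, 24), weekdayMult = rep(1, 7), holidayMult = 1,
        seasonAmplitude = 0, dailyEffectSd = 0, hourlyEffectSd = 0,
        losMeanHours = c(critical = 1, medical = losMean, surgical = 1))
    sim <- simulatePanel(cfg)
    m <- mean(occupancy(sim$panel)["medical", ])
    nH <- 420 * 24
    ## stationary mean lambda * losMean; time-average SE inflated by the
    ## occupancy autocorrelation time (~ losMean hours)
    se <- sqrt(lambda * losMean * 2 * losMean / nH)
    expect_lt(abs(m - lambda * losMean), 3 * se)
})

test_that("every arrival contributes exactly its stay in patient-hours", {
    res <- withr::with_seed(4, edcast:::.simulateSectionQueue(rep(2, 500), 4))
    expect_identical(sum(res$occupancyFull), sum(res$los))
    expect_identical(sum(res$arrivals), length(res$los))
})

test_that("covariates respect temperature order, sentinels and holiday adjacency", {
    sim <- cachedSim(400, 5)
    d <- covariateData(sim$covariates)
    expect_true(all(d$air_temp_min_c <= d$air_temp_mean_c))
    expect_true(all(d$air_temp_mean_c <= d$air_temp_max_c))
    expect_true(any(d$precipitation_mm == -1))
    expect_true(any(d$snow_depth_cm == -1))
    expect_true(any(d$snow_depth_cm > 0))
    expect_type(d$beds_available, "integer")
    n <- nrow(d)
    expect_identical(d$after_holiday[-1], d$holiday[-n])
    expect_identical(d$before_holiday[-n], d$holiday[-1])
    expect_gt(sum(d$holiday), 8)   # a Nordic calendar has ~13-14 holidays/year
})

test_that("invalid configurations fail naming the offending field", {
    expect_error(edSimConfig(nDays = 0), "nDays")
    expect_error(edSimConfig(capacities = c(bedoccupying = 65L, critical = -1L,
                                            medical = 36L, surgical = 23L)),
                 "capacities")
    expect_error(edSimConfig(losMeanHours = c(critical = 0.5, medical = 5,
                                              surgical = 4.5)),
                 "losMeanHours")
    expect_error(edSimConfig(hourMult = rep(1, 23)), "hourMult")
    expect_error(edSimConfig(baseRate = c(critical = -1, medical = 3,
                                          surgical = 2)), "baseRate")
})
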