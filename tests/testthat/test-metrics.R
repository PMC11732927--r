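test_that("confusion identities hold and zero denominators yield NA markers", {
    set.seed(9)
    p <- runif(200)
    y <- rbinom(200, 1, p)
    rec <- binaryMetrics(p, y)
    expect_equal(rec$tpr + rec$fnr, 1)
    expect_equal(rec$tnr + rec$fpr, 1)
    expect_equal(rec$acc, (rec$tp + rec$tn) / 200)
    expect_equal(rec$f1, 2 * rec$ppv * rec$tpr / (rec$ppv + rec$tpr))

    ## all predictions negative with true positives present
    rec2 <- binaryMetrics(rep(0.1, 10), c(rep(1, 3), rep(0, 7)))
    expect_true(is.na(rec2$ppv))
    expect_identical(rec2$tpr, 0)

    ## perfect predictions
    rec3 <- binaryMetrics(c(0.9, 0.9, 0.1), c(1, 1, 0))
    expect_identical(rec3$f1, 1)
    expect_identical(rec3$acc, 1)
    expect_identical(rec3$fpr, 0)
    expect_identical(rec3$fnr, 0)

    expect_error(binaryMetrics(numeric(), integer()), "empty")
})

test_that("AUROC matches exhaustive pair counting, including ties", {
    expect_equal(aurocScore(rep(0.4, 20), rep(c(0, 1), 10)), 0.5)
    expect_equal(aurocScore(c(0, 1, 1, 0), c(0, 1, 1, 0)), 1)
    expect_warning(expect_true(is.na(aurocScore(runif(5), rep(1, 5)))),
                   "one class")
    for (seed in 1:20) {
        set.seed(seed)
        n <- sample(10:40, 1)
        p <- round(runif(n), 1)          # coarse grid forces ties
        y <- rbinom(n, 1, 0.4)
        if (length(unique(y)) < 2) next
        expect_equal(aurocScore(p, y), aurocOracle(p, y), tolerance = 1e-12)
    }
})

test_that("AUPRC matches an exhaustive threshold sweep and the guess level", {
    expect_equal(auprcScore(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
    ## constant predictor scores exactly the positive prevalence
    expect_equal(auprcScore(rep(0.3, 10), c(rep(1, 3), rep(0, 7))), 0.3)
    expect_warning(expect_true(is.na(auprcScore(runif(4), rep(0, 4)))),
                   "no positive")
    for (seed in 1:20) {
        set.seed(seed + 100)
        n <- sample(10:40, 1)
        p <- round(runif(n), 1)
        y <- rbinom(n, 1, 0.4)
        if (sum(y) == 0) next
        expect_equal(auprcScore(p, y), auprcOracle(p, y), tolerance = 1e-12)
    }
})

test_that("bootstrap intervals are deterministic, order-invariant and converge", {
    set.seed(30)
    p <- runif(500)
    y <- rbinom(500, 1, plogis(3 * (p - 0.5)))
    cfg <- bootstrapConfig(200, seed = 17)
    ci1 <- bootstrapCI("auroc", p, y, cfg)
    ci2 <- bootstrapCI("auroc", p, y, cfg)
    expect_identical(ci1, ci2)

    perm <- sample(500)
    ci3 <- bootstrapCI("auroc", p[perm], y[perm], cfg)
    expect_identical(as.numeric(ci1), as.numeric(ci3))

    ## perfect predictor: metric constant under resampling
    ciP <- bootstrapCI("f1", c(rep(0.9, 5), rep(0.1, 5)),
                       c(rep(1, 5), rep(0, 5)), bootstrapConfig(50, seed = 1))
    expect_equal(as.numeric(ciP), c(1, 1))

    ## n = 200 vs n = 10000 resamples agree within 0.03 at both endpoints
    ciBig <- bootstrapCI("auroc", p, y, bootstrapConfig(10000, seed = 17))
    expect_lt(max(abs(as.numeric(ci1) - as.numeric(ciBig))), 0.03)
})

## A synthetic forecast run: 3 evaluated subgroups + critical, 6 origins,
## nDays test days, probabilities correlated with labels.
makeToyRun <- function(nDays = 30, seed = 5) {
    set.seed(seed)
    grid <- expand.grid(date = as.Date("2019-01-01") + seq_len(nDays) - 1,
                        subgroup = c("bedoccupying", "critical", "medical",
                                     "surgical"),
                        origin = 8:13)
    grid$label <- rbinom(nrow(grid), 1, 0.3)
    grid$probability <- plogis(2 * grid$label - 1 + rnorm(nrow(grid)))
    grid$train_window_end <- grid$date - 1
    new("ForecastRun", predictions = grid, params = defaultHyperparameters(1),
        seed = 1L, nRefits = 1L, trainSizes = 1L)
}

test_that("metrics table covers evaluated cells and excludes critical", {
    run <- makeToyRun()
    cfg <- bootstrapConfig(50, seed = 3)
    tab <- metricsTable(run, cfg)
    expect_identical(nrow(tab), 18L)
    expect_false("critical" %in% tab$target)
    expect_true(all(tab$auroc_lo <= tab$auroc & tab$auroc <= tab$auroc_hi))

    tab12 <- metricsTable(run, cfg, targets = c("medical", "surgical"))
    expect_identical(nrow(tab12), 12L)

    ## row order of the run does not matter
    run2 <- run
    set.seed(1)
    run2@predictions <- run@predictions[sample(nrow(run@predictions)), ]
    expect_equal(metricsTable(run2, cfg), tab)
})

test_that("single-class cells yield undefined markers, not zeros", {
    run <- makeToyRun()
    pr <- run@predictions
    pick <- pr$subgroup == "medical" & pr$origin == 8
    pr$label[pick] <- 0L
    pr$probability[pick] <- pmin(pr$probability[pick], 0.49)
    run@predictions <- pr
    tab <- metricsTable(run, bootstrapConfig(20, seed = 2))
    row <- tab[tab$target == "medical" & tab$origin == 8, ]
    expect_true(is.na(row$auroc))
    expect_true(is.na(row$auroc_lo))
    expect_true(is.na(row$f1))
})

test_that("calendar outcomes reconcile with confusion counts and flip symmetrically", {
    run <- makeToyRun()
    cal <- calendarOutcomes(run, origin = 11)
    pr <- predictions(run)
    cell <- pr[pr$origin == 11, ]
    rec <- binaryMetrics(cell$probability, cell$label)
    counts <- table(factor(cal$outcome, levels = c("TP", "FP", "TN", "FN")))
    expect_identical(as.integer(counts),
                     c(rec$tp, rec$fp, rec$tn, rec$fn))
    expect_identical(nrow(cal), length(unique(cell$date)) * 4L)

    ## inverting predictions swaps TP<->FP and TN<->FN
    run2 <- run
    run2@predictions$probability <- 1 - run2@predictions$probability
    run2@predictions$label <- run2@predictions$label   # labels unchanged
    cal2 <- calendarOutcomes(run2, origin = 11)
    c2 <- table(factor(cal2$outcome, levels = c("TP", "FP", "TN", "FN")))
    expect_identical(as.integer(c2["TP"] + c2["FN"]),
                     as.integer(counts["TP"] + counts["FN"]))
    expect_identical(as.integer(c2["FP"]), rec$tn)
    expect_identical(as.integer(c2["TP"]), rec$fn)

    expect_error(calendarOutcomes(run, origin = 20), "not present")
})
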