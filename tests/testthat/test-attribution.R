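test_that("features the model never splits on get exactly zero attribution", {
    set.seed(2)
    x <- cbind(sig = sample(0:1, 150, TRUE), dead1 = rnorm(150),
               dead2 = rnorm(150))
    y <- x[, "sig"]
    m <- fitCrowdingModel(x, y, defaultHyperparameters(10, max_depth = 2), seed = 1)
    used <- unique(xgboost::xgb.model.dt.tree(model = m$booster)$Feature)
    expect_identical(setdiff(used, "Leaf"), "sig")
    attr <- shapleyImportance(m, x)
    phi <- rowAttributions(attr)
    expect_true(all(phi[, c("dead1", "dead2")] == 0))
    expect_identical(globalImportance(attr)$feature[1], "sig")
})

test_that("tree-exact Shapley equals brute-force subset enumeration", {
    ## single split, three features
    set.seed(5)
    x1 <- cbind(a = rnorm(80), b = sample(0:1, 80, TRUE), c = rnorm(80))
    m1 <- fitCrowdingModel(x1, x1[, "b"],
                           defaultHyperparameters(1, max_depth = 1), seed = 1)
    phi1 <- rowAttributions(shapleyImportance(m1, x1[1:4, , drop = FALSE]))
    for (i in 1:4) {
        bf <- bruteForceShapley(m1$booster, as.list(x1[i, ]))
        expect_equal(unname(phi1[i, names(bf)]), unname(bf), tolerance = 1e-5)
    }

    ## multi-tree model with interactions, five features
    set.seed(6)
    x2 <- matrix(rnorm(120 * 5), 120, 5,
                 dimnames = list(NULL, paste0("f", 1:5)))
    y2 <- as.integer(x2[, 1] > 0 & x2[, 2] < 0.5)
    m2 <- fitCrowdingModel(x2, y2, defaultHyperparameters(6, max_depth = 3),
                           seed = 2)
    phi2 <- rowAttributions(shapleyImportance(m2, x2[1:5, , drop = FALSE]))
    for (i in 1:5) {
        bf <- bruteForceShapley(m2$booster, as.list(x2[i, ]))
        expect_equal(unname(phi2[i, names(bf)]), unname(bf), tolerance = 1e-5)
    }
})

test_that("local accuracy: base value plus attributions equals the raw output", {
    set.seed(7)
    x <- matrix(rnorm(200 * 4), 200, 4, dimnames = list(NULL, paste0("v", 1:4)))
    y <- rbinom(200, 1, plogis(x[, 1] - x[, 3]))
    m <- fitCrowdingModel(x, y, defaultHyperparameters(25, max_depth = 4), seed = 3)
    attr <- shapleyImportance(m, x)
    marg <- predict(m, x, outputmargin = TRUE)
    expect_equal(rowSums(rowAttributions(attr)) + attr@baseValue,
                 unname(marg), tolerance = 1e-5)
    ## ranking is a permutation sorted non-increasing
    g <- globalImportance(attr)
    expect_setequal(g$feature, colnames(x))
    expect_true(all(diff(g$importance) <= 0))
})

test_that("planted signals are recovered by both attribution methods", {
    set.seed(8)
    x <- cbind(planted = sample(0:2, 200, TRUE), n1 = rnorm(200),
               n2 = rnorm(200), n3 = rnorm(200))
    y <- as.integer(x[, "planted"] >= 1)
    m <- fitCrowdingModel(x, y, defaultHyperparameters(15, max_depth = 2), seed = 1)

    expect_identical(globalImportance(shapleyImportance(m, x))$feature[1],
                     "planted")

    hits <- vapply(1:5, function(seed) {
        li <- surrogateImportance(m, x[1:20, ], reference = x,
                                  nSamples = 150, seed = seed)
        phi <- rowAttributions(li)
        mean(colnames(phi)[max.col(phi)] == "planted")
    }, numeric(1))
    expect_true(all(hits >= 0.95))
})

test_that("surrogate attributions are deterministic and handle degenerate input", {
    set.seed(9)
    x <- matrix(rnorm(50 * 3), 50, 3, dimnames = list(NULL, c("a", "b", "c")))
    y <- rbinom(50, 1, 0.5)
    m <- fitCrowdingModel(x, y, defaultHyperparameters(5, max_depth = 2), seed = 1)
    l1 <- surrogateImportance(m, x[1:3, ], reference = x, nSamples = 100, seed = 4)
    l2 <- surrogateImportance(m, x[1:3, ], reference = x, nSamples = 100, seed = 4)
    expect_identical(globalImportance(l1), globalImportance(l2))

    ## constant model -> all importances (essentially) zero
    expect_warning(mc <- fitCrowdingModel(x, rep(1L, 50)), "single-class")
    lc <- surrogateImportance(mc, x[1:3, ], reference = x, nSamples = 100, seed = 1)
    expect_true(all(globalImportance(lc)$importance == 0))

    ## zero perturbation variance is an error
    xconst <- matrix(1, 10, 3, dimnames = list(NULL, c("a", "b", "c")))
    expect_error(surrogateImportance(m, xconst, reference = xconst,
                                     nSamples = 50, seed = 1),
                 "zero perturbation variance")
})

test_that("schema mismatches are structural errors", {
    set.seed(10)
    x <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
    y <- rbinom(20, 1, 0.5)
    m <- fitCrowdingModel(x, y, defaultHyperparameters(3), seed = 1)
    bad <- x; colnames(bad) <- c("a", "b", "z")
    expect_error(shapleyImportance(m, bad), "schema mismatch")
    expect_error(surrogateImportance(m, bad), "schema mismatch")
    expect_error(predict(m, bad), "schema mismatch")
})
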