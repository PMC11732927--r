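#' @importFrom xgboost xgb.DMatrix xgb.train xgb.save xgb.load
NULL

#' Expanding-window split configuration
#'
#' @param initialTrainEnd Last date of the initial training window (the
#'   default protocol trains on the first 365 days).
#' @param testEnd Last test date (inclusive).
#' @param strideDays Retraining stride: 1 refits at the start of every test
#'   day (the reference protocol); larger values refit every `strideDays`
#'   days, predicting each block with the model fitted on all data strictly
#'   before the block.
#' @return A list of class `edcastSplit`.
#' @export
#' @examples
#' splitConfig(as.Date("2018-12-31"), as.Date("2019-06-30"), strideDays = 7)
splitConfig <- function(initialTrainEnd, testEnd, strideDays = 1L) {
    initialTrainEnd <- as.Date(initialTrainEnd); testEnd <- as.Date(testEnd)
    if (initialTrainEnd >= testEnd)
        stop("initialTrainEnd must precede testEnd")
    if (strideDays < 1L) stop("strideDays must be >= 1")
    structure(list(initialTrainEnd = initialTrainEnd, testEnd = testEnd,
                   strideDays = as.integer(strideDays)),
              class = "edcastSplit")
}

#' Default gradient-boosting hyperparameters
#'
#' Library-default-style settings with single-threaded histogram training so
#' that fits are bit-reproducible given a seed.  All values can be overridden
#' by passing a modified list wherever hyperparameters are accepted.
#'
#' @param nrounds Number of boosting rounds.
#' @param ... Overrides for the parameter list entries.
#' @return A list: `params` (passed to the learner) and `nrounds`.
#' @export
defaultHyperparameters <- function(nrounds = 100L, ...) {
    params <- list(objective = "binary:logistic", eval_metric = "logloss",
                   tree_method = "hist", max_depth = 6L, eta = 0.1,
                   min_child_weight = 1, subsample = 1, colsample_bytree = 1,
                   lambda = 1, nthread = 1L)
    dots <- list(...)
    params[names(dots)] <- dots
    list(params = params, nrounds = as.integer(nrounds))
}

#' Fit the crowding classifier
#'
#' Fits a gradient-boosted tree binary classifier (histogram method, native
#' missing-value handling, integer-coded categoricals split ordinally) on a
#' feature matrix.  If the training labels contain a single class, a
#' constant-probability fallback model is returned with a warning.
#'
#' @param x Numeric feature matrix (NAs allowed).
#' @param y 0/1 labels.
#' @param hyper Hyperparameters from [defaultHyperparameters()].
#' @param seed Integer seed for the fit.
#' @return An object of class `crowdingModel` with a `predict()` method
#'   returning probabilities.
#' @export
#' @examples
#' x <- cbind(a = rnorm(80), b = rep(0:1, 40))
#' y <- as.integer(x[, "b"] == 1)
#' m <- fitCrowdingModel(x, y, defaultHyperparameters(20), seed = 1)
#' range(predict(m, x))
fitCrowdingModel <- function(x, y, hyper = defaultHyperparameters(), seed = 1L) {
    stopifnot(is.matrix(x), nrow(x) == length(y))
    if (nrow(x) == 0L) stop("training set is empty")
    y <- as.integer(y)
    if (length(unique(y)) < 2L) {
        warning("single-class training set; falling back to a constant-probability model")
        return(structure(list(booster = NULL, constant = mean(y),
                              features = colnames(x)),
                         class = "crowdingModel"))
    }
    booster <- withr::with_seed(as.integer(seed), {
        dtrain <- xgboost::xgb.DMatrix(x, label = y)
        xgboost::xgb.train(params = hyper$params, data = dtrain,
                           nrounds = hyper$nrounds, verbose = 0)
    })
    structure(list(booster = booster, constant = NULL, features = colnames(x)),
              class = "crowdingModel")
}

#' @export
predict.crowdingModel <- function(object, newdata, outputmargin = FALSE, ...) {
    stopifnot(is.matrix(newdata))
    if (!is.null(object$features) &&
        !identical(colnames(newdata), object$features))
        stop("feature schema mismatch between model and data")
    if (is.null(object$booster)) {
        p <- rep(object$constant, nrow(newdata))
        return(if (outputmargin) log(p / (1 - p)) else p)
    }
    stats::predict(object$booster, xgboost::xgb.DMatrix(newdata),
                   outputmargin = outputmargin)
}

#' @export
print.crowdingModel <- function(x, ...) {
    if (is.null(x$booster))
        cat(sprintf("crowdingModel: constant fallback, p = %.3f\n", x$constant))
    else
        cat(sprintf("crowdingModel: boosted trees on %d features\n",
                    length(x$features)))
    invisible(x)
}

#' Expanding-window daily-retraining forecast
#'
#' Walks through the test period in blocks of `strideDays` days.  For each
#' block the classifier is refit on every design-matrix row dated strictly
#' before the block start ("all of the preceding data") and then predicts all
#' rows -- every subgroup and every forecast origin -- of the block's days.
#' With stride 1 this refits at the start of each test day, the reference
#' protocol; the training window therefore expands monotonically and no row
#' is ever predicted by a model that saw its date.
#'
#' @param dm An [EDDesignMatrix-class].
#' @param split An `edcastSplit` from [splitConfig()].
#' @param hyper Hyperparameters from [defaultHyperparameters()].
#' @param seed Integer seed (shared by every refit).
#' @return A [ForecastRun-class].
#' @export
expandingWindowForecast <- function(dm, split, hyper = defaultHyperparameters(),
                                    seed = 1L) {
    stopifnot(is(dm, "EDDesignMatrix"), inherits(split, "edcastSplit"))
    feats <- designFeatures(dm)
    label <- designLabel(dm)
    rowDates <- designDates(dm)
    testDays <- sort(unique(rowDates[rowDates > split$initialTrainEnd &
                                     rowDates <= split$testEnd]))
    if (!length(testDays))
        stop("no design-matrix rows fall inside the test range")
    blocks <- base::split(testDays,
                          (as.integer(testDays - testDays[1L])) %/% split$strideDays)
    preds <- vector("list", length(blocks))
    trainSizes <- integer(length(blocks))
    for (b in seq_along(blocks)) {
        blockDays <- blocks[[b]]
        trainIdx <- which(rowDates < blockDays[1L])
        testIdx <- which(rowDates %in% blockDays)
        if (!length(trainIdx)) stop("empty training window before ", blockDays[1L])
        model <- fitCrowdingModel(feats[trainIdx, , drop = FALSE],
                                  label[trainIdx], hyper, seed)
        p <- predict(model, feats[testIdx, , drop = FALSE])
        subNames <- names(dm@panelSubgroups)[
            match(feats[testIdx, "subgroup"], dm@panelSubgroups)]
        preds[[b]] <- data.frame(
            date = rowDates[testIdx],
            subgroup = subNames,
            origin = as.integer(feats[testIdx, "origin"]),
            probability = as.numeric(p),
            label = label[testIdx],
            train_window_end = max(rowDates[trainIdx]))
        trainSizes[b] <- length(trainIdx)
    }
    new("ForecastRun",
        predictions = do.call(rbind, preds),
        params = hyper, seed = as.integer(seed),
        nRefits = length(blocks), trainSizes = trainSizes)
}
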