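#' F1 score from precision and recall
#'
#' Harmonic mean `2 * ppv * tpr / (ppv + tpr)`; `NA` when the denominator is
#' zero or either input is undefined.  Useful for internal-consistency checks
#' of reported metric tables.
#'
#' @param ppv Precision (positive predictive value).
#' @param tpr Recall (true positive rate / sensitivity).
#' @return Numeric F1 in `[0, 1]` or `NA`.
#' @export
#' @examples
#' f1FromPrecisionRecall(0.56, 0.72)
f1FromPrecisionRecall <- function(ppv, tpr) {
    ifelse(is.na(ppv) | is.na(tpr) | (ppv + tpr) == 0,
           NA_real_, 2 * ppv * tpr / (ppv + tpr))
}

#' Area under the ROC curve
#'
#' Rank (Mann-Whitney) formulation: the probability that a uniformly random
#' positive outranks a uniformly random negative, with ties counted half.
#' Equivalent to trapezoidal integration of the ROC curve.
#'
#' @param probabilities Numeric scores.
#' @param labels 0/1 labels.
#' @return AUROC in `[0, 1]`, or `NA` with a warning if only one class is
#'   present.
#' @export
#' @examples
#' aurocScore(c(0.9, 0.8, 0.3, 0.2), c(1, 0, 1, 0))
aurocScore <- function(probabilities, labels) {
    stopifnot(length(probabilities) == length(labels))
    labels <- as.integer(labels)
    nPos <- sum(labels == 1L); nNeg <- sum(labels == 0L)
    if (nPos == 0L || nNeg == 0L) {
        warning("AUROC undefined: only one class present")
        return(NA_real_)
    }
    r <- rank(probabilities, ties.method = "average")
    (sum(r[labels == 1L]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Area under the precision-recall curve
#'
#' Step-wise average-precision convention (no interpolation): descending
#' sweep over distinct score values, summing `deltaRecall * precision` at
#' each step.  Ties are grouped, so a constant predictor scores exactly the
#' positive prevalence (the "guess level").
#'
#' @inheritParams aurocScore
#' @return AUPRC in `[0, 1]`, or `NA` with a warning if there are no
#'   positives.
#' @export
#' @examples
#' auprcScore(c(0.9, 0.8, 0.3, 0.2), c(1, 0, 1, 0))
auprcScore <- function(probabilities, labels) {
    stopifnot(length(probabilities) == length(labels))
    labels <- as.integer(labels)
    nPos <- sum(labels == 1L)
    if (nPos == 0L) {
        warning("AUPRC undefined: no positive labels")
        return(NA_real_)
    }
    o <- order(probabilities, decreasing = TRUE)
    p <- probabilities[o]; y <- labels[o]
    grp <- cumsum(!duplicated(p))              # tie groups, descending
    tpCum <- cumsum(y); nCum <- seq_along(y)
    last <- which(!duplicated(grp, fromLast = TRUE))   # last index per group
    tp <- tpCum[last]; nn <- nCum[last]
    prec <- tp / nn
    rec <- tp / nPos
    sum(diff(c(0, rec)) * prec)
}

#' Full binary-metric record at a probability threshold
#'
#' Thresholds the probabilities at `threshold` (prediction positive when
#' `probability >= threshold`), tabulates the confusion counts and computes
#' the full metric panel: F1, TPR, TNR, PPV, NPV, FPR, FNR, accuracy, AUROC
#' and AUPRC.  Ratios with zero denominators are returned as `NA`
#' (an explicit undefined marker), never silently as 0.
#'
#' @inheritParams aurocScore
#' @param threshold Probability cutoff (default 0.5).
#' @return A one-row `data.frame` with the metrics, the confusion counts
#'   `tp, fp, tn, fn` and the threshold.
#' @export
#' @examples
#' binaryMetrics(c(0.9, 0.8, 0.3, 0.2), c(1, 0, 1, 0))
binaryMetrics <- function(probabilities, labels, threshold = 0.5) {
    if (length(probabilities) == 0L) stop("empty input")
    stopifnot(length(probabilities) == length(labels))
    labels <- as.integer(labels)
    if (!all(labels %in% c(0L, 1L))) stop("labels must be binary 0/1")
    pred <- as.integer(probabilities >= threshold)
    tp <- sum(pred == 1L & labels == 1L); fp <- sum(pred == 1L & labels == 0L)
    tn <- sum(pred == 0L & labels == 0L); fn <- sum(pred == 0L & labels == 1L)
    sdiv <- function(num, den) if (den == 0) NA_real_ else num / den
    tpr <- sdiv(tp, tp + fn); tnr <- sdiv(tn, tn + fp)
    ppv <- sdiv(tp, tp + fp); npv <- sdiv(tn, tn + fn)
    fpr <- if (is.na(tnr)) NA_real_ else 1 - tnr
    fnr <- if (is.na(tpr)) NA_real_ else 1 - tpr
    auroc <- if (tp + fn == 0L || tn + fp == 0L) NA_real_ else
        aurocScore(probabilities, labels)
    auprc <- if (tp + fn == 0L) NA_real_ else auprcScore(probabilities, labels)
    data.frame(
        f1 = f1FromPrecisionRecall(ppv, tpr),
        tpr = tpr, tnr = tnr, ppv = ppv, npv = npv, fpr = fpr, fnr = fnr,
        acc = (tp + tn) / (tp + tn + fp + fn),
        auroc = auroc, auprc = auprc,
        tp = tp, fp = fp, tn = tn, fn = fn, threshold = threshold)
}

#' Bootstrap configuration
#'
#' @param nResamples Number of bootstrap resamples (the reference protocol
#'   uses 200).
#' @param alpha Two-sided miscoverage; 0.05 gives 95% percentile intervals.
#' @param seed Integer seed.
#' @param maxRedraws Cap on redraws of resamples that lose a class.
#' @return A list of class `edcastBootstrap`.
#' @export
bootstrapConfig <- function(nResamples = 200L, alpha = 0.05, seed = 1L,
                            maxRedraws = 1000L) {
    if (nResamples < 1L) stop("nResamples must be >= 1")
    if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
    structure(list(nResamples = as.integer(nResamples), alpha = alpha,
                   seed = as.integer(seed), maxRedraws = as.integer(maxRedraws)),
              class = "edcastBootstrap")
}

## Draw resample index sets; redraw (counted, capped) when a resample loses a
## class so rank metrics stay defined.  Inputs are sorted canonically first
## so intervals are invariant to row order.
.bootstrapStats <- function(probabilities, labels, config, metricFuns) {
    o <- order(probabilities, labels)
    p <- probabilities[o]; y <- as.integer(labels[o])
    n <- length(p)
    stats <- matrix(NA_real_, config$nResamples, length(metricFuns),
                    dimnames = list(NULL, names(metricFuns)))
    withr::with_seed(config$seed, {
        redraws <- 0L
        for (b in seq_len(config$nResamples)) {
            repeat {
                idx <- sample.int(n, n, replace = TRUE)
                if (length(unique(y[idx])) == 2L) break
                redraws <- redraws + 1L
                if (redraws > config$maxRedraws)
                    stop("degenerate resampling: class lost in more than ",
                         config$maxRedraws, " resamples")
            }
            for (m in seq_along(metricFuns))
                stats[b, m] <- metricFuns[[m]](p[idx], y[idx])
        }
    })
    attr(stats, "redraws") <- redraws
    stats
}

#' Percentile-bootstrap confidence interval for a metric
#'
#' Resamples (probability, label) pairs with replacement `nResamples` times,
#' recomputes the metric on each resample and returns the percentile
#' interval.  Resamples that lose a class are redrawn (counted and capped).
#' Inputs are canonically sorted before resampling, so the interval does not
#' depend on row order.
#'
#' @param metric One of `"auroc"`, `"auprc"`, `"f1"`, `"acc"`, or a function
#'   `f(probabilities, labels)`.
#' @inheritParams aurocScore
#' @param config An `edcastBootstrap` from [bootstrapConfig()].
#' @param threshold Cutoff used by threshold-based metrics.
#' @return Numeric `c(low, high)` with attribute `redraws`.
#' @export
#' @examples
#' set.seed(1)
#' p <- runif(100); y <- rbinom(100, 1, p)
#' bootstrapCI("auroc", p, y, bootstrapConfig(seed = 7))
bootstrapCI <- function(metric, probabilities, labels,
                        config = bootstrapConfig(), threshold = 0.5) {
    fun <- if (is.function(metric)) metric else switch(
        metric,
        auroc = aurocScore,
        auprc = auprcScore,
        f1 = function(p, y) binaryMetrics(p, y, threshold)$f1,
        acc = function(p, y) binaryMetrics(p, y, threshold)$acc,
        stop("unknown metric: ", metric))
    full <- fun(probabilities, labels)
    if (is.na(full)) stop("metric undefined on the full sample")
    stats <- .bootstrapStats(probabilities, labels, config,
                             stats::setNames(list(fun), "m"))
    ci <- stats::quantile(stats[, 1L], c(config$alpha / 2, 1 - config$alpha / 2),
                          na.rm = TRUE, names = FALSE)
    attr(ci, "redraws") <- attr(stats, "redraws")
    ci
}

#' Per-(subgroup, origin) metrics table with confidence intervals
#'
#' Computes the full binary-metric record for every evaluated (subgroup,
#' origin) cell of a forecast run, with percentile-bootstrap confidence
#' intervals for F1, AUROC and AUPRC (one shared resampling engine; the F1
#' interval method is recorded in the output).  The critical section is
#' excluded from evaluation by default: it serves as an explanatory variable
#' only.
#'
#' @param run A [ForecastRun-class].
#' @param config An `edcastBootstrap` from [bootstrapConfig()].
#' @param threshold Probability cutoff (default 0.5).
#' @param targets Subgroups to evaluate (default bedoccupying, medical,
#'   surgical).
#' @return A `data.frame`, one row per (target, origin) cell, sorted by
#'   target then origin, with metric columns, `*_lo`/`*_hi` interval bounds,
#'   confusion counts and `ci_method`.
#' @export
metricsTable <- function(run, config = bootstrapConfig(), threshold = 0.5,
                         targets = c("bedoccupying", "medical", "surgical")) {
    stopifnot(is(run, "ForecastRun"))
    pr <- predictions(run)
    if (!nrow(pr)) stop("empty forecast run")
    targets <- intersect(targets, unique(pr$subgroup))
    rows <- list()
    for (tg in sort(targets)) {
        for (og in sort(unique(pr$origin))) {
            cell <- pr[pr$subgroup == tg & pr$origin == og, ]
            if (!nrow(cell)) next
            rec <- binaryMetrics(cell$probability, cell$label, threshold)
            oneClass <- length(unique(cell$label)) < 2L
            cis <- list(f1 = c(NA_real_, NA_real_),
                        auroc = c(NA_real_, NA_real_),
                        auprc = c(NA_real_, NA_real_))
            if (!oneClass) {
                funs <- list(
                    f1 = function(p, y) binaryMetrics(p, y, threshold)$f1,
                    auroc = aurocScore, auprc = auprcScore)
                stats <- .bootstrapStats(cell$probability, cell$label, config, funs)
                qs <- c(config$alpha / 2, 1 - config$alpha / 2)
                for (m in names(funs))
                    cis[[m]] <- stats::quantile(stats[, m], qs, na.rm = TRUE,
                                                names = FALSE)
            }
            rows[[length(rows) + 1L]] <- cbind(
                data.frame(target = tg, origin = og),
                rec,
                data.frame(f1_lo = cis$f1[1], f1_hi = cis$f1[2],
                           auroc_lo = cis$auroc[1], auroc_hi = cis$auroc[2],
                           auprc_lo = cis$auprc[1], auprc_hi = cis$auprc[2],
                           prevalence = mean(cell$label), n = nrow(cell),
                           ci_method = "percentile-bootstrap"))
        }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Per-day confusion outcome classes at one forecast origin
#'
#' Maps every (test date, subgroup) pair at the given origin to exactly one
#' outcome class -- TP, FP, TN or FN -- at the given threshold, the
#' classification used for calendar-map reporting.  Counts reconcile with
#' [binaryMetrics()] confusion counts on the same rows.
#'
#' @param run A [ForecastRun-class].
#' @param origin Forecast origin hour to extract.
#' @param threshold Probability cutoff.
#' @return `data.frame(date, subgroup, probability, label, outcome)`.
#' @export
calendarOutcomes <- function(run, origin, threshold = 0.5) {
    pr <- predictions(run)
    pr <- pr[pr$origin == origin, ]
    if (!nrow(pr)) stop("origin ", origin, " not present in run")
    pred <- as.integer(pr$probability >= threshold)
    outcome <- ifelse(pred == 1L & pr$label == 1L, "TP",
               ifelse(pred == 1L & pr$label == 0L, "FP",
               ifelse(pred == 0L & pr$label == 0L, "TN", "FN")))
    data.frame(date = pr$date, subgroup = pr$subgroup,
               probability = pr$probability, label = pr$label,
               outcome = outcome)
}
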