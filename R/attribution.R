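#' @importFrom glmnet glmnet
NULL

.rankGlobal <- function(phi) {
    imp <- colMeans(abs(phi))
    o <- order(imp, decreasing = TRUE)
    data.frame(feature = colnames(phi)[o], importance = unname(imp[o]),
               rank = seq_along(o))
}

#' Tree-exact Shapley feature attribution
#'
#' Computes per-row Shapley values with the tree-exact algorithm of the
#' gradient-boosting library (no subset enumeration) and aggregates them into
#' a global ranking by mean absolute attribution.  Attributions are on the
#' model's raw (log-odds) output scale and satisfy local accuracy: for every
#' row, `baseValue + sum(phi)` equals the model's raw prediction.  Features
#' the model never splits on receive exactly zero attribution.
#'
#' @param model A `crowdingModel` from [fitCrowdingModel()].
#' @param x Numeric feature matrix with the model's feature schema.
#' @param nRows Optional subsample size of rows to attribute (with `seed`);
#'   default all rows.
#' @param seed Seed for the row subsample.
#' @return An [AttributionResult-class] with `method = "shapley"`.
#' @export
#' @examples
#' x <- cbind(a = rnorm(120), b = rep(0:1, 60), c = rnorm(120))
#' y <- as.integer(x[, "b"] == 1)
#' m <- fitCrowdingModel(x, y, defaultHyperparameters(15), seed = 1)
#' globalImportance(shapleyImportance(m, x))
shapleyImportance <- function(model, x, nRows = NULL, seed = 1L) {
    stopifnot(inherits(model, "crowdingModel"), is.matrix(x))
    if (!is.null(model$features) && !identical(colnames(x), model$features))
        stop("feature schema mismatch between model and data")
    if (!is.null(nRows) && nRows < nrow(x))
        x <- withr::with_seed(as.integer(seed),
                              x[sample.int(nrow(x), nRows), , drop = FALSE])
    if (is.null(model$booster)) {               # constant fallback: null game
        phi <- matrix(0, nrow(x), ncol(x), dimnames = list(NULL, colnames(x)))
        base <- log(model$constant / (1 - model$constant))
    } else {
        contrib <- stats::predict(model$booster, xgboost::xgb.DMatrix(x),
                                  predcontrib = TRUE)
        biasCol <- intersect(c("BIAS", "(Intercept)"), colnames(contrib))[1L]
        phi <- contrib[, setdiff(colnames(contrib), biasCol), drop = FALSE]
        base <- unname(contrib[1L, biasCol])
    }
    new("AttributionResult", method = "shapley", global = .rankGlobal(phi),
        rowAttributions = phi, baseValue = base)
}

## Weighted sparse linear fit for one locality; returns |coefficients| on the
## standardized perturbation scale.
.sparseSurrogateFit <- function(zs, fhat, w, nSelect) {
    p <- ncol(zs)
    if (stats::var(fhat) == 0) return(rep(0, p))
    if (p < 2L) {
        fit <- stats::lm.wfit(cbind(1, zs), fhat, w)
        return(abs(fit$coefficients[2L]))
    }
    fit <- glmnet::glmnet(zs, fhat, weights = w, standardize = FALSE,
                          nlambda = 50)
    ok <- which(fit$df <= nSelect)
    idx <- if (length(ok)) max(ok) else 1L
    abs(as.numeric(fit$beta[, idx]))
}

#' Locality-weighted linear surrogate attribution
#'
#' For each evaluated row, perturbs the features (Gaussian noise scaled by
#' the reference-data spread for continuous features; resampling from the
#' reference empirical distribution for integer-coded categoricals and for
#' missing entries), queries the model, weights the perturbed samples by an
#' exponential proximity kernel on standardized distance, and fits a sparse
#' weighted linear surrogate.  Absolute surrogate coefficients are the
#' per-row attributions; the global ranking uses their mean over rows.
#'
#' @param model A `crowdingModel`.
#' @param x Rows to explain (numeric matrix, model schema).
#' @param reference Matrix defining the perturbation scales and categorical
#'   value pools (default `x`).
#' @param categorical Nominal categorical column names: perturbed by
#'   resampling from the reference pool and entered into the surrogate as a
#'   matches-the-instance indicator (a linear term in an arbitrary code
#'   would be meaningless).
#' @param ordinal Ordered integer-coded column names (e.g. weekday, month,
#'   origin hour): perturbed by resampling from the reference pool so codes
#'   stay valid, but entered into the surrogate as values, so level shifts
#'   and thresholds along the order are visible to the linear fit.
#' @param nSamples Perturbed samples per explained row.
#' @param nSelect Sparsity budget: maximum surrogate features per row.
#' @param kernelWidth Proximity kernel width (default `0.75 * sqrt(p)`).
#' @param seed Integer seed; results are reproducible.
#' @return An [AttributionResult-class] with `method = "local-surrogate"`.
#' @export
surrogateImportance <- function(model, x, reference = x,
                                categorical = character(),
                                ordinal = character(), nSamples = 200L,
                                nSelect = 10L, kernelWidth = NULL, seed = 1L) {
    stopifnot(inherits(model, "crowdingModel"), is.matrix(x))
    if (!is.null(model$features) && !identical(colnames(x), model$features))
        stop("feature schema mismatch between model and data")
    p <- ncol(x)
    sds <- apply(reference, 2L, stats::sd, na.rm = TRUE)
    sds[is.na(sds)] <- 0
    if (all(sds == 0))
        stop("zero perturbation variance: reference data is constant in every feature")
    if (is.null(kernelWidth)) kernelWidth <- 0.75 * sqrt(p)
    mus <- colMeans(reference, na.rm = TRUE)
    sdsSafe <- ifelse(sds > 0, sds, 1)
    catIdx <- which(colnames(x) %in% categorical)
    ordIdx <- which(colnames(x) %in% setdiff(ordinal, categorical))
    poolIdx <- union(catIdx, ordIdx)
    sdsSafe[catIdx] <- 1      # nominals enter distance as 0/1 mismatch
    pools <- lapply(seq_len(p), function(j) {
        v <- reference[, j]; v <- v[!is.na(v)]
        if (length(v)) v else 0
    })

    phi <- matrix(0, nrow(x), p, dimnames = list(NULL, colnames(x)))
    withr::with_seed(as.integer(seed), {
        for (i in seq_len(nrow(x))) {
            xi <- x[i, ]
            Z <- matrix(rep(xi, each = nSamples), nrow = nSamples,
                        dimnames = list(NULL, colnames(x)))
            for (j in seq_len(p)) {
                if (j %in% poolIdx || is.na(xi[j])) {
                    Z[, j] <- sample(pools[[j]], nSamples, replace = TRUE)
                } else {
                    Z[, j] <- xi[j] + stats::rnorm(nSamples, 0, sds[j])
                }
            }
            Z[1L, ] <- xi                       # keep the instance itself
            fhat <- predict(model, Z)
            ## surrogate design: standardized values for continuous features,
            ## match-with-instance indicators for categoricals (the linear
            ## surrogate must capture arbitrary category structure)
            S <- Z
            for (j in catIdx)
                S[, j] <- as.numeric(!is.na(Z[, j]) & !is.na(xi[j]) &
                                     Z[, j] == xi[j])
            for (j in seq_len(p)) S[is.na(S[, j]), j] <- mus[j]
            ctr <- ifelse(is.na(xi), mus, xi)
            ctr[catIdx] <- 1                    # the instance matches itself
            d2 <- rowSums(sweep(sweep(S, 2L, ctr, "-"), 2L, sdsSafe, "/")^2)
            w <- exp(-d2 / kernelWidth^2)
            zs <- sweep(sweep(S, 2L, colMeans(S), "-"), 2L,
                        pmax(apply(S, 2L, stats::sd), 1e-12), "/")
            phi[i, ] <- .sparseSurrogateFit(zs, fhat, w, nSelect)
        }
    })
    new("AttributionResult", method = "local-surrogate",
        global = .rankGlobal(phi), rowAttributions = phi,
        baseValue = NA_real_)
}
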