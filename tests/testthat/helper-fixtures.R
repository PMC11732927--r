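# Shared fixtures and independent oracles.  Simulations are cached per
# process so several test files can reuse the same panel.

.fixtureCache <- new.env(parent = emptyenv())

cachedSim <- function(nDays, seed) {
    key <- sprintf("sim_%d_%d", nDays, seed)
    if (is.null(.fixtureCache[[key]]))
        .fixtureCache[[key]] <- simulatePanel(edSimConfig(nDays = nDays, seed = seed))
    .fixtureCache[[key]]
}

cachedDesign <- function(nDays, seed) {
    key <- sprintf("dm_%d_%d", nDays, seed)
    if (is.null(.fixtureCache[[key]])) {
        sim <- cachedSim(nDays, seed)
        labels <- crowdingLabels(sim$panel)
        .fixtureCache[[key]] <- list(
            sim = sim, labels = labels,
            dm = buildDesignMatrix(sim$panel, sim$covariates, labels))
    }
    .fixtureCache[[key]]
}

# Single-subgroup panel with exact EDOR values (capacity 100 so two-decimal
# ratios map to integer occupancy without rounding).
toyPanel <- function(edorByHour, subgroup = "medical", capacity = 100L,
                     startDate = "2018-01-01") {
    stopifnot(length(edorByHour) %% 24 == 0)
    occ <- matrix(as.integer(round(edorByHour * capacity)), nrow = 1,
                  dimnames = list(subgroup, NULL))
    EDPanel(occ, stats::setNames(capacity, subgroup), as.Date(startDate))
}

# One-day covariate table consistent with an empty holiday calendar.
toyCovariates <- function(dates) {
    n <- length(dates)
    EDCovariates(data.frame(
        date = as.Date(dates),
        precipitation_mm = rep(-1, n), snow_depth_cm = rep(-1, n),
        air_temp_mean_c = rep(5, n), air_temp_max_c = rep(9, n),
        air_temp_min_c = rep(1, n), beds_available = rep(20L, n),
        holiday = rep(FALSE, n), after_holiday = rep(FALSE, n),
        before_holiday = rep(FALSE, n)))
}

# --- independent metric oracles -------------------------------------------

# AUROC by exhaustive pair counting (ties half credit).
aurocOracle <- function(p, y) {
    pos <- p[y == 1]; neg <- p[y == 0]
    tot <- 0
    for (a in pos) tot <- tot + sum(a > neg) + 0.5 * sum(a == neg)
    tot / (length(pos) * length(neg))
}

# AUPRC by an exhaustive sweep over every distinct threshold, summing
# deltaRecall * precision down the sorted score list.
auprcOracle <- function(p, y) {
    th <- sort(unique(p), decreasing = TRUE)
    nPos <- sum(y == 1)
    area <- 0; prevRec <- 0
    for (t in th) {
        pred <- p >= t
        tp <- sum(pred & y == 1)
        prec <- tp / sum(pred)
        rec <- tp / nPos
        area <- area + (rec - prevRec) * prec
        prevRec <- rec
    }
    area
}

# --- brute-force Shapley oracle -------------------------------------------

# v(S): expected tree output when only features in S are fixed to x; at a
# split on an excluded feature, average the children weighted by cover.
.treeValue <- function(nodes, valcol, x, S) {
    rec <- function(id) {
        nd <- nodes[id, ]
        if (nd$Feature == "Leaf") return(nd[[valcol]])
        if (nd$Feature %in% S) {
            xv <- x[[nd$Feature]]
            if (is.na(xv)) return(rec(nd$Missing))
            return(if (xv < nd$Split) rec(nd$Yes) else rec(nd$No))
        }
        cy <- nodes[nd$Yes, "Cover"]; cn <- nodes[nd$No, "Cover"]
        (cy * rec(nd$Yes) + cn * rec(nd$No)) / (cy + cn)
    }
    rec(nodes$ID[nodes$Node == 0])
}

# Shapley values by full subset enumeration with weights
# |S|! (n - |S| - 1)! / n!, feasible for <= 8 features.
bruteForceShapley <- function(booster, x) {
    tr <- as.data.frame(xgboost::xgb.model.dt.tree(model = booster))
    valcol <- if ("Gain" %in% names(tr)) "Gain" else "Quality"
    trees <- lapply(split(tr, tr$Tree), function(nodes) {
        rownames(nodes) <- nodes$ID
        nodes
    })
    v <- function(S) sum(vapply(trees, .treeValue, 0, valcol = valcol,
                                x = x, S = S))
    feats <- names(x)
    n <- length(feats)
    phi <- stats::setNames(numeric(n), feats)
    for (i in feats) {
        others <- setdiff(feats, i)
        for (k in 0:length(others)) {
            combs <- if (k == 0) list(character()) else
                asplit(utils::combn(others, k), 2)
            wt <- factorial(k) * factorial(n - k - 1) / factorial(n)
            for (S in combs) phi[i] <- phi[i] + wt * (v(c(S, i)) - v(S))
        }
    }
    phi
}
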