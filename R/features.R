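#' @importFrom stats complete.cases
NULL

.BASE_FIXED_PRE <- c("holiday", "after_holiday", "before_holiday", "weekday",
                     "month", "beds_all")
.WEATHER_COLS <- c("precipitation_mm", "snow_depth_cm", "air_temp_mean_c",
                   "air_temp_max_c", "air_temp_min_c")
.CATEGORICAL_FEATURES <- c("weekday", "month", "subgroup", "origin")

## Canonical feature column names for a panel with the given subgroups.
.designColumnNames <- function(panelSubs) {
    lagCols <- c(paste0("q90_", panelSubs, "_7"), paste0("q90_", panelSubs, "_14"))
    lookback <- unlist(lapply(panelSubs, function(s)
        c(sprintf("q90h_%s_t%03d", s, 1:168), sprintf("occ_%s_t%03d", s, 1:168))),
        use.names = FALSE)
    list(base = c(.BASE_FIXED_PRE, lagCols, .WEATHER_COLS, "subgroup", "origin"),
         lookback = lookback)
}

#' Build the multi-origin design matrix
#'
#' Assembles one row per (date, subgroup, forecast origin) from the hourly
#' panel, the daily covariates and the crowding labels.  Each row carries the
#' base features (holiday triple, weekday 0-6 Monday-first, month, bed
#' availability, the daily crowding labels of every panel subgroup lagged 7
#' and 14 days, five weather values, the subgroup integer code and the origin
#' hour) plus, for every panel subgroup, 168 hourly crowding indicators and
#' 168 hourly occupancy counts covering the hours `origin-168 .. origin-1` of
#' the row's date -- strictly before the origin, so no same-hour information
#' can leak.  Cells whose history reaches before the panel start (or before
#' day 8 / day 15 for the 7- and 14-day lags) are `NA`; rows are retained.
#'
#' @param panel An [EDPanel-class].
#' @param covariates An [EDCovariates-class] over the same dates.
#' @param labels A [CrowdingLabels-class] built from `panel`.
#' @param origins Integer forecast-origin hours (default 8..13, i.e. 8 a.m.
#'   to 1 p.m.).
#' @param subgroups Subgroup names to emit rows for (default: all panel
#'   subgroups).  Lookback and lag columns always cover all panel subgroups.
#' @return An [EDDesignMatrix-class] with `nDays * |subgroups| * |origins|`
#'   rows.
#' @export
#' @examples
#' sim <- simulatePanel(edSimConfig(nDays = 20, seed = 2))
#' lab <- crowdingLabels(sim$panel)
#' dm <- buildDesignMatrix(sim$panel, sim$covariates, lab)
#' dim(dm)
buildDesignMatrix <- function(panel, covariates, labels, origins = 8:13,
                              subgroups = NULL) {
    stopifnot(is(panel, "EDPanel"), is(covariates, "EDCovariates"),
              is(labels, "CrowdingLabels"))
    origins <- as.integer(origins)
    if (any(origins < 0L | origins > 23L)) stop("origins must lie in 0..23")
    dates <- panelDates(panel)
    cov <- covariateData(covariates)
    if (!identical(as.Date(cov$date), dates) ||
        !identical(panelDates(labels), dates))
        stop("panel, covariates and labels must share the same date range")
    panelSubs <- subgroupNames(panel)
    if (is.null(subgroups)) subgroups <- panelSubs
    unknown <- setdiff(subgroups, panelSubs)
    if (length(unknown))
        stop("unknown subgroup(s): ", paste(unknown, collapse = ", "))
    codes <- .SUBGROUP_CODES
    if (!all(panelSubs %in% names(codes)))
        codes <- setNames(seq_along(panelSubs) - 1L, panelSubs)

    D <- length(dates); O <- length(origins)
    nSubRows <- length(subgroups); nSubPanel <- length(panelSubs)
    n <- D * nSubRows * O

    occ <- occupancy(panel)
    crowdHourly <- hourlyIndicators(labels)
    daily <- dailyCrowding(labels)
    H <- ncol(occ)
    stopifnot(ncol(crowdHourly) == H, ncol(daily) == D)

    ## (date, origin) lookback block, shared by all subgroup rows of a day
    dIdxDO <- rep(seq_len(D), each = O)
    oIdxDO <- rep(seq_len(O), times = D)
    originHourIdx <- (dIdxDO - 1L) * 24L + origins[oIdxDO] + 1L
    refIdx <- outer(originHourIdx, 1:168, "-")     # hour index of origin - k
    refIdx[refIdx < 1L] <- NA_integer_
    cols <- .designColumnNames(panelSubs)
    LB <- matrix(NA_real_, D * O, 336L * nSubPanel,
                 dimnames = list(NULL, cols$lookback))
    for (si in seq_len(nSubPanel)) {
        off <- (si - 1L) * 336L
        LB[, off + 1:168] <- as.numeric(crowdHourly[si, ])[refIdx]
        LB[, off + 169:336] <- as.numeric(occ[si, ])[refIdx]
    }

    ## row bookkeeping: date-major, subgroup, origin innermost
    dVec <- rep(seq_len(D), each = nSubRows * O)
    sVec <- rep(rep(seq_along(subgroups), each = O), times = D)
    oVec <- rep(seq_len(O), times = nSubRows * D)
    lookIdx <- (dVec - 1L) * O + oVec

    wday <- (as.POSIXlt(dates)$wday + 6L) %% 7L
    month <- as.integer(format(dates, "%m"))
    lag7 <- cbind(matrix(NA_real_, nSubPanel, min(7L, D)),
                  daily[, seq_len(max(0L, D - 7L)), drop = FALSE] + 0)
    lag14 <- cbind(matrix(NA_real_, nSubPanel, min(14L, D)),
                   daily[, seq_len(max(0L, D - 14L)), drop = FALSE] + 0)

    features <- matrix(NA_real_, n, length(cols$base) + length(cols$lookback),
                       dimnames = list(NULL, c(cols$base, cols$lookback)))
    features[, "holiday"] <- as.numeric(cov$holiday[dVec])
    features[, "after_holiday"] <- as.numeric(cov$after_holiday[dVec])
    features[, "before_holiday"] <- as.numeric(cov$before_holiday[dVec])
    features[, "weekday"] <- wday[dVec]
    features[, "month"] <- month[dVec]
    features[, "beds_all"] <- cov$beds_available[dVec]
    for (si in seq_len(nSubPanel)) {
        features[, paste0("q90_", panelSubs[si], "_7")] <- lag7[si, dVec]
        features[, paste0("q90_", panelSubs[si], "_14")] <- lag14[si, dVec]
    }
    for (w in .WEATHER_COLS) features[, w] <- cov[[w]][dVec]
    features[, "subgroup"] <- as.numeric(codes[subgroups[sVec]])
    features[, "origin"] <- origins[oVec]
    features[, cols$lookback] <- LB[lookIdx, , drop = FALSE]

    label <- as.integer(daily[cbind(match(subgroups[sVec], panelSubs), dVec)])
    roles <- c(rep("calendar", 5L), "beds", rep("lag", 2L * nSubPanel),
               rep("weather", 5L), "subgroup", "origin",
               rep("lookback", length(cols$lookback)))

    new("EDDesignMatrix",
        date = dates[dVec], features = features, label = label,
        roles = roles, origins = origins,
        panelSubgroups = setNames(as.integer(codes[panelSubs]), panelSubs),
        categorical = .CATEGORICAL_FEATURES)
}

#' Audit a design matrix for temporal leakage
#'
#' Recomputes, for every lookback cell, the panel value at its claimed
#' historical hour (`origin - k` on the row's date) and compares it with the
#' stored value; the latest hour any column may reference is `origin - 1`.
#' Additionally flags same-day dependence: any base feature column that is
#' identical to the label column over the populated rows.
#'
#' @param dm An [EDDesignMatrix-class] built from `panel`.
#' @param panel The source [EDPanel-class].
#' @param labels The [CrowdingLabels-class] used to build `dm`.
#' @param maxViolations Stop collecting per-cell detail after this many
#'   violations (counting continues).
#' @return A list with `pass` (logical), `nChecked`, `nViolations`,
#'   `violations` (data.frame row/column detail, truncated), and
#'   `sameDayFlags` (names of suspicious base columns).
#' @export
leakageAudit <- function(dm, panel, labels, maxViolations = 100L) {
    stopifnot(is(dm, "EDDesignMatrix"), is(panel, "EDPanel"),
              is(labels, "CrowdingLabels"))
    feats <- designFeatures(dm)
    panelSubs <- subgroupNames(panel)
    occ <- occupancy(panel)
    crowdHourly <- hourlyIndicators(labels)
    dates <- panelDates(panel)
    dIdx <- match(designDates(dm), dates)
    originHour <- feats[, "origin"]
    originHourIdx <- (dIdx - 1L) * 24L + as.integer(originHour) + 1L

    lookCols <- colnames(feats)[featureRoles(dm) == "lookback"]
    parsed <- regmatches(lookCols, regexec("^(q90h|occ)_(.+)_t([0-9]+)$", lookCols))
    nChecked <- 0L; nViol <- 0L
    viol <- list()
    for (j in seq_along(lookCols)) {
        p <- parsed[[j]]
        type <- p[2]; sub <- p[3]; k <- as.integer(p[4])
        if (k < 1L) {                      # column at or after the origin hour
            nViol <- nViol + nrow(feats)
            next
        }
        ref <- originHourIdx - k
        ref[ref < 1L] <- NA_integer_
        src <- if (type == "q90h") as.numeric(crowdHourly[sub, ]) else
            as.numeric(occ[sub, ])
        expected <- src[ref]
        actual <- feats[, lookCols[j]]
        bad <- which(xor(is.na(expected), is.na(actual)) |
                     (!is.na(expected) & !is.na(actual) & expected != actual))
        nChecked <- nChecked + nrow(feats)
        if (length(bad)) {
            nViol <- nViol + length(bad)
            take <- utils::head(bad, max(0L, maxViolations - length(viol)))
            for (b in take)
                viol[[length(viol) + 1L]] <- data.frame(
                    row = b, column = lookCols[j],
                    expected = expected[b], actual = actual[b])
        }
    }

    label <- designLabel(dm)
    baseCols <- colnames(feats)[featureRoles(dm) != "lookback"]
    sameDay <- character()
    for (cn in baseCols) {
        v <- feats[, cn]
        ok <- !is.na(v)
        if (any(ok) && all(v[ok] == label[ok]) && length(unique(label[ok])) > 1L)
            sameDay <- c(sameDay, cn)
    }

    list(pass = nViol == 0L && length(sameDay) == 0L,
         nChecked = nChecked, nViolations = nViol,
         violations = if (length(viol)) do.call(rbind, viol) else
             data.frame(row = integer(), column = character(),
                        expected = numeric(), actual = numeric()),
         sameDayFlags = sameDay)
}
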