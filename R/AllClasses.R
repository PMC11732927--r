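#' @include AllGenerics.R
#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
NULL

## Canonical subgroup integer coding (fixed; alphabetical, 0-based so the
## "subgroup" design-matrix column summarises to min 0 / max 3 / mean 1.5).
.SUBGROUP_CODES <- c(bedoccupying = 0L, critical = 1L, medical = 2L, surgical = 3L)

## Operational sections simulated independently; bedoccupying is their sum.
.SECTIONS <- c("critical", "medical", "surgical")

#' Subgroup integer coding
#'
#' The fixed code-to-name mapping used throughout: bedoccupying = 0,
#' critical = 1, medical = 2, surgical = 3.
#'
#' @return A named integer vector.
#' @export
#' @examples
#' subgroupCodes()
subgroupCodes <- function() .SUBGROUP_CODES

# ---------------------------------------------------------------------------
# EDPanel: hourly sectioned occupancy as a SummarizedExperiment
# ---------------------------------------------------------------------------

#' Hourly ED occupancy panel
#'
#' `EDPanel` stores hourly occupancy counts and occupancy ratios (EDOR:
#' occupancy divided by bed capacity) for a set of ED subgroups over a
#' contiguous range of calendar days.  It extends
#' [SummarizedExperiment::SummarizedExperiment] with subgroups as rows
#' (`rowData` carries the bed capacity) and hours as columns (`colData`
#' carries the timestamp, calendar date and hour of day).  The hourly grid
#' must be complete (no gaps, no duplicates, whole days starting at 00:00).
#'
#' @slot .. see `SummarizedExperiment`; assays are `occupancy` (nonnegative
#'   counts) and `edor` (occupancy / capacity, may exceed 1).
#' @export
setClass("EDPanel", contains = "SummarizedExperiment")

.validEDPanel <- function(object) {
    msg <- character()
    if (!all(c("occupancy", "edor") %in% SummarizedExperiment::assayNames(object)))
        return("assays 'occupancy' and 'edor' are required")
    occ <- SummarizedExperiment::assay(object, "occupancy")
    ed <- SummarizedExperiment::assay(object, "edor")
    cd <- SummarizedExperiment::colData(object)
    rd <- SummarizedExperiment::rowData(object)
    if (!all(c("timestamp", "date", "hour") %in% colnames(cd)))
        msg <- c(msg, "colData must contain timestamp, date, hour")
    if (!"capacity" %in% colnames(rd))
        msg <- c(msg, "rowData must contain capacity")
    if (length(msg)) return(msg)
    if (any(occ < 0)) msg <- c(msg, "occupancy must be nonnegative")
    if (any(rd$capacity <= 0)) msg <- c(msg, "capacities must be positive")
    n <- ncol(object)
    if (n %% 24L != 0L)
        msg <- c(msg, "panel must cover whole calendar days (24 hours each)")
    hrs <- cd$hour
    if (n > 0L && !identical(as.integer(hrs), rep(0:23, length.out = n)))
        msg <- c(msg, "hour grid must be complete hourly 0..23 per day, in order")
    ts <- cd$timestamp
    if (n > 1L && !all(diff(as.numeric(ts)) == 3600))
        msg <- c(msg, "timestamps must be strictly increasing by one hour with no gaps")
    if (max(abs(ed * rd$capacity - occ)) > 1e-6)
        msg <- c(msg, "edor * capacity must equal occupancy")
    if (length(msg)) msg else TRUE
}
setValidity("EDPanel", .validEDPanel)

#' Construct an hourly occupancy panel
#'
#' @param occupancy Integer matrix of patients present, one row per subgroup
#'   (rownames required), one column per hour.
#' @param capacities Named positive integer vector of bed capacities, one
#'   entry per subgroup row.
#' @param startDate `Date` of the first day; the panel starts at 00:00 on
#'   this day and must cover whole days (`ncol(occupancy)` divisible by 24).
#' @return An [EDPanel-class].
#' @export
#' @examples
#' occ <- matrix(rpois(48, 3), nrow = 2, dimnames = list(c("medical", "surgical"), NULL))
#' p <- EDPanel(occ, c(medical = 36, surgical = 23), as.Date("2018-01-01"))
#' dim(occupancy(p))
EDPanel <- function(occupancy, capacities, startDate) {
    stopifnot(is.matrix(occupancy), !is.null(rownames(occupancy)))
    startDate <- as.Date(startDate)
    caps <- as.integer(capacities[rownames(occupancy)])
    if (anyNA(caps))
        stop("capacities must be named and cover every occupancy row")
    H <- ncol(occupancy)
    ts <- as.POSIXct(startDate, tz = "UTC") + 3600 * (seq_len(H) - 1L)
    cd <- S4Vectors::DataFrame(
        timestamp = ts,
        date = startDate + (seq_len(H) - 1L) %/% 24L,
        hour = as.integer((seq_len(H) - 1L) %% 24L)
    )
    ed <- sweep(occupancy, 1L, caps, "/")
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(occupancy = occupancy, edor = ed),
        rowData = S4Vectors::DataFrame(subgroup = rownames(occupancy), capacity = caps),
        colData = cd
    )
    new("EDPanel", se)
}

#' @rdname occupancy
#' @export
setMethod("occupancy", "EDPanel", function(object)
    SummarizedExperiment::assay(object, "occupancy"))

#' @rdname occupancy
#' @export
setMethod("edor", "EDPanel", function(object)
    SummarizedExperiment::assay(object, "edor"))

#' @rdname occupancy
#' @export
setMethod("capacities", "EDPanel", function(object) {
    rd <- SummarizedExperiment::rowData(object)
    stats::setNames(as.integer(rd$capacity), rd$subgroup)
})

#' @rdname occupancy
#' @export
setMethod("subgroupNames", "EDPanel", function(object)
    as.character(SummarizedExperiment::rowData(object)$subgroup))

#' @rdname panelDates
#' @export
setMethod("panelDates", "EDPanel", function(object)
    unique(as.Date(SummarizedExperiment::colData(object)$date)))

#' Hourly timestamps of a panel
#' @param object An `EDPanel`.
#' @return `POSIXct` vector, one element per panel hour.
#' @export
panelTimestamps <- function(object) SummarizedExperiment::colData(object)$timestamp

setMethod("show", "EDPanel", function(object) {
    d <- panelDates(object)
    cat(sprintf("EDPanel: %d subgroups x %d hours (%d days, %s .. %s)\n",
                nrow(object), ncol(object), length(d), min(d), max(d)))
    caps <- capacities(object)
    cat("  capacities:", paste(sprintf("%s=%d", names(caps), caps), collapse = ", "), "\n")
})

# ---------------------------------------------------------------------------
# EDCovariates: daily weather / beds / holiday covariates
# ---------------------------------------------------------------------------

.COVARIATE_COLS <- c("date", "precipitation_mm", "snow_depth_cm",
                     "air_temp_mean_c", "air_temp_max_c", "air_temp_min_c",
                     "beds_available", "holiday", "after_holiday", "before_holiday")

#' Daily covariate panel
#'
#' Daily weather (precipitation and snow depth use the sentinel value -1 on
#' days with none), air temperatures, region-wide hospital bed availability
#' (integer, may be negative as reported by the source system) and holiday
#' indicator triples.  `after_holiday[d]` is true iff day `d - 1` is a
#' holiday and `before_holiday[d]` iff day `d + 1` is (resolved against the
#' holiday calendar, which may extend beyond the panel range).
#'
#' @slot data A `data.frame` with columns `date`, `precipitation_mm`,
#'   `snow_depth_cm`, `air_temp_mean_c`, `air_temp_max_c`, `air_temp_min_c`,
#'   `beds_available`, `holiday`, `after_holiday`, `before_holiday`.
#' @export
setClass("EDCovariates", representation(data = "data.frame"))

.validEDCovariates <- function(object) {
    d <- object@data
    msg <- character()
    if (!all(.COVARIATE_COLS %in% names(d)))
        return(paste("missing covariate columns:",
                     paste(setdiff(.COVARIATE_COLS, names(d)), collapse = ", ")))
    if (is.unsorted(d$date, strictly = TRUE))
        msg <- c(msg, "dates must be strictly increasing")
    if (nrow(d) > 1L && any(diff(as.integer(d$date)) != 1L))
        msg <- c(msg, "dates must be a complete daily grid")
    bad <- d$air_temp_min_c > d$air_temp_mean_c | d$air_temp_mean_c > d$air_temp_max_c
    if (any(bad))
        msg <- c(msg, "air temperature ordering min <= mean <= max violated")
    n <- nrow(d)
    if (n > 1L) {
        if (!identical(as.logical(d$after_holiday[-1L]), as.logical(d$holiday[-n])))
            msg <- c(msg, "after_holiday[d] must equal holiday[d-1] on interior days")
        if (!identical(as.logical(d$before_holiday[-n]), as.logical(d$holiday[-1L])))
            msg <- c(msg, "before_holiday[d] must equal holiday[d+1] on interior days")
    }
    if (length(msg)) msg else TRUE
}
setValidity("EDCovariates", .validEDCovariates)

#' @rdname covariateData
#' @export
EDCovariates <- function(data) new("EDCovariates", data = as.data.frame(data))

#' Covariate table accessor
#'
#' @param object An [EDCovariates-class].
#' @param data For the constructor `EDCovariates()`: a `data.frame` with the
#'   ten canonical covariate columns.
#' @return The daily covariate `data.frame`.
#' @export
covariateData <- function(object) object@data

#' @rdname panelDates
#' @export
setMethod("panelDates", "EDCovariates", function(object) object@data$date)

setMethod("show", "EDCovariates", function(object) {
    d <- object@data
    cat(sprintf("EDCovariates: %d days (%s .. %s), %d holidays\n",
                nrow(d), min(d$date), max(d$date), sum(d$holiday)))
})

# ---------------------------------------------------------------------------
# CrowdingLabels
# ---------------------------------------------------------------------------

#' Hourly crowding indicators and daily crisis labels
#'
#' A calendar day is a mortality-associated crisis day for a subgroup when
#' its occupancy ratio is at or above `threshold` (default 0.90) during at
#' least `minHours` (default 3) hours of that day.
#'
#' @slot hourly Logical subgroup-by-hour indicator matrix (EDOR >= threshold).
#' @slot daily Logical subgroup-by-date daily crisis label matrix.
#' @slot counts Integer subgroup-by-date crowded-hour counts.
#' @slot dates Date vector (one per daily column).
#' @slot timestamps POSIXct vector (one per hourly column).
#' @slot threshold,minHours The crisis definition used.
#' @export
setClass("CrowdingLabels", representation(
    hourly = "matrix", daily = "matrix", counts = "matrix",
    dates = "Date", timestamps = "POSIXct",
    threshold = "numeric", minHours = "integer"))

.validCrowdingLabels <- function(object) {
    msg <- character()
    if (!identical(dim(object@daily), dim(object@counts)))
        msg <- c(msg, "daily and counts must have identical shape")
    if (ncol(object@hourly) != 24L * ncol(object@daily))
        msg <- c(msg, "hourly columns must equal 24 x daily columns")
    if (!identical(object@daily, object@counts >= object@minHours))
        msg <- c(msg, "daily label must equal (crowded hour count >= minHours)")
    day <- rep(seq_len(ncol(object@daily)), each = 24L)
    recount <- t(apply(object@hourly, 1L, function(h) tapply(h, day, sum)))
    dim(recount) <- dim(object@counts)
    if (!all(recount == object@counts))
        msg <- c(msg, "counts must equal the per-day sum of hourly indicators")
    if (length(msg)) msg else TRUE
}
setValidity("CrowdingLabels", .validCrowdingLabels)

#' @rdname hourlyIndicators
#' @export
setMethod("hourlyIndicators", "CrowdingLabels", function(object) object@hourly)

#' @rdname hourlyIndicators
#' @export
setMethod("dailyCrowding", "CrowdingLabels", function(object) object@daily)

#' @rdname hourlyIndicators
#' @export
setMethod("crowdedHourCounts", "CrowdingLabels", function(object) object@counts)

#' @rdname panelDates
#' @export
setMethod("panelDates", "CrowdingLabels", function(object) object@dates)

setMethod("show", "CrowdingLabels", function(object) {
    prev <- rowMeans(object@daily)
    cat(sprintf("CrowdingLabels: %d subgroups x %d days (EDOR >= %.2f for >= %d h)\n",
                nrow(object@daily), ncol(object@daily), object@threshold, object@minHours))
    cat("  daily crisis prevalence:",
        paste(sprintf("%s=%.2f", rownames(object@daily), prev), collapse = ", "), "\n")
})

# ---------------------------------------------------------------------------
# EDDesignMatrix
# ---------------------------------------------------------------------------

#' Multi-origin design matrix
#'
#' One row per (date, subgroup, forecast origin).  Features comprise the
#' base block (holiday triple, weekday, month, bed availability, daily
#' crowding labels lagged 7 and 14 days for every subgroup, five weather
#' variables, subgroup code, origin hour) and, for every panel subgroup, a
#' 168-hour lookback block of hourly crowding indicators and absolute
#' occupancy covering hours origin-168 .. origin-1.  Values that would
#' reach before the first panel hour are `NA`; rows are retained.
#'
#' @slot date Row dates.
#' @slot features Numeric feature matrix (rows align with `date`).
#' @slot label Integer 0/1 daily crowding label of the row's subgroup.
#' @slot roles Character vector, one per feature column: calendar, beds,
#'   lag, weather, subgroup, origin or lookback.
#' @slot origins Integer forecast origin hours used.
#' @slot panelSubgroups Named integer subgroup codes of the source panel.
#' @slot categorical Names of integer-coded categorical feature columns.
#' @export
setClass("EDDesignMatrix", representation(
    date = "Date", features = "matrix", label = "integer",
    roles = "character", origins = "integer",
    panelSubgroups = "integer", categorical = "character"))

.validEDDesignMatrix <- function(object) {
    msg <- character()
    if (length(object@date) != nrow(object@features))
        msg <- c(msg, "date vector must align with feature rows")
    if (length(object@label) != nrow(object@features))
        msg <- c(msg, "label must align with feature rows")
    if (length(object@roles) != ncol(object@features))
        msg <- c(msg, "roles must align with feature columns")
    nSub <- length(object@panelSubgroups)
    expCols <- 13L + 2L * nSub + 336L * nSub
    if (ncol(object@features) != expCols)
        msg <- c(msg, sprintf("expected %d feature columns for %d subgroups, got %d",
                              expCols, nSub, ncol(object@features)))
    if (!all(object@label %in% c(0L, 1L)))
        msg <- c(msg, "label must be 0/1")
    if (length(msg)) msg else TRUE
}
setValidity("EDDesignMatrix", .validEDDesignMatrix)

#' @rdname designFeatures
#' @export
setMethod("designFeatures", "EDDesignMatrix", function(object) object@features)

#' @rdname designFeatures
#' @export
setMethod("designLabel", "EDDesignMatrix", function(object) object@label)

#' @rdname designFeatures
#' @export
setMethod("designDates", "EDDesignMatrix", function(object) object@date)

#' @rdname designFeatures
#' @export
setMethod("featureRoles", "EDDesignMatrix", function(object)
    stats::setNames(object@roles, colnames(object@features)))

#' @rdname panelDates
#' @export
setMethod("panelDates", "EDDesignMatrix", function(object) unique(object@date))

setMethod("show", "EDDesignMatrix", function(object) {
    cat(sprintf("EDDesignMatrix: %d rows x %d feature columns (+ label)\n",
                nrow(object@features), ncol(object@features)))
    cat(sprintf("  %d days x %d subgroups x %d origins; %d lookback columns\n",
                length(unique(object@date)), length(object@panelSubgroups),
                length(object@origins), sum(object@roles == "lookback")))
})

#' Dimensions of a design matrix
#' @param x An `EDDesignMatrix`.
#' @return `c(rows, feature columns + 1)`; the label counts as one column so
#'   the shape matches the conventional rows-by-columns description of the
#'   full analysis matrix.
#' @export
setMethod("dim", "EDDesignMatrix", function(x) c(nrow(x@features), ncol(x@features) + 1L))

# ---------------------------------------------------------------------------
# ForecastRun
# ---------------------------------------------------------------------------

#' Expanding-window forecast results
#'
#' Per-test-row predicted crowding probabilities together with the training
#' window boundary that produced each prediction, plus run metadata.
#'
#' @slot predictions `data.frame` with columns `date`, `subgroup`, `origin`,
#'   `probability`, `label`, `train_window_end`.
#' @slot params Hyperparameter list used for every refit.
#' @slot seed Integer seed.
#' @slot nRefits Number of model refits performed.
#' @slot trainSizes Integer vector of training-set row counts per refit.
#' @export
setClass("ForecastRun", representation(
    predictions = "data.frame", params = "list", seed = "integer",
    nRefits = "integer", trainSizes = "integer"))

.validForecastRun <- function(object) {
    p <- object@predictions
    msg <- character()
    need <- c("date", "subgroup", "origin", "probability", "label", "train_window_end")
    if (!all(need %in% names(p)))
        return(paste("predictions must contain:", paste(need, collapse = ", ")))
    if (any(p$probability < 0 | p$probability > 1))
        msg <- c(msg, "probabilities must lie in [0, 1]")
    if (any(p$train_window_end >= p$date))
        msg <- c(msg, "train_window_end must precede every predicted date")
    if (object@nRefits < 1L)
        msg <- c(msg, "at least one refit is required")
    if (is.unsorted(object@trainSizes))
        msg <- c(msg, "training sizes must be non-decreasing (expanding window)")
    if (length(msg)) msg else TRUE
}
setValidity("ForecastRun", .validForecastRun)

#' @rdname predictions
#' @export
setMethod("predictions", "ForecastRun", function(object) object@predictions)

#' @rdname predictions
#' @export
setMethod("runMeta", "ForecastRun", function(object)
    list(params = object@params, seed = object@seed,
         nRefits = object@nRefits, trainSizes = object@trainSizes))

setMethod("show", "ForecastRun", function(object) {
    p <- object@predictions
    cat(sprintf("ForecastRun: %d predictions over %d test days, %d refits\n",
                nrow(p), length(unique(p$date)), object@nRefits))
})

# ---------------------------------------------------------------------------
# AttributionResult
# ---------------------------------------------------------------------------

#' Feature-attribution results
#'
#' Global feature importance (mean absolute attribution over the evaluated
#' rows) with per-row attributions, for either the tree-exact Shapley method
#' or the locality-weighted linear surrogate method.
#'
#' @slot method `"shapley"` or `"local-surrogate"`.
#' @slot global `data.frame(feature, importance, rank)`, sorted
#'   non-increasing by importance.
#' @slot rowAttributions Numeric rows-by-features attribution matrix
#'   (Shapley phi values, or absolute surrogate coefficients).
#' @slot baseValue Expected model output (Shapley only; `NA` otherwise).
#' @export
setClass("AttributionResult", representation(
    method = "character", global = "data.frame",
    rowAttributions = "matrix", baseValue = "numeric"))

.validAttributionResult <- function(object) {
    g <- object@global
    msg <- character()
    if (!all(c("feature", "importance", "rank") %in% names(g)))
        return("global must have feature, importance, rank columns")
    if (is.unsorted(rev(g$importance)))
        msg <- c(msg, "global importance must be sorted non-increasing")
    if (!setequal(g$feature, colnames(object@rowAttributions)))
        msg <- c(msg, "ranking must be a permutation of the feature set")
    if (!identical(sort(as.integer(g$rank)), seq_len(nrow(g))))
        msg <- c(msg, "ranks must be a permutation of 1..nFeatures")
    if (length(msg)) msg else TRUE
}
setValidity("AttributionResult", .validAttributionResult)

#' @rdname globalImportance
#' @export
setMethod("globalImportance", "AttributionResult", function(object) object@global)

#' @rdname globalImportance
#' @export
setMethod("rowAttributions", "AttributionResult", function(object) object@rowAttributions)

setMethod("show", "AttributionResult", function(object) {
    cat(sprintf("AttributionResult (%s): %d rows x %d features; top features:\n",
                object@method, nrow(object@rowAttributions), nrow(object@global)))
    print(utils::head(object@global, 5L), row.names = FALSE)
})
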