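NULL

#' Hourly occupancy counts
#'
#' Accessors for the occupancy assay of an [EDPanel-class]: `occupancy()`
#' returns the subgroup-by-hour matrix of patients present, `edor()` the
#' corresponding occupancy ratio (occupancy divided by bed capacity;
#' dimensionless and allowed to exceed 1), and `capacities()` the named bed
#' capacity vector.
#'
#' @param object An `EDPanel`.
#' @return `occupancy()` and `edor()` return a numeric matrix with one row
#'   per subgroup and one column per hour; `capacities()` a named integer
#'   vector.
#' @export
setGeneric("occupancy", function(object) standardGeneric("occupancy"))

#' @rdname occupancy
#' @export
setGeneric("edor", function(object) standardGeneric("edor"))

#' @rdname occupancy
#' @export
setGeneric("capacities", function(object) standardGeneric("capacities"))

#' @rdname occupancy
#' @export
setGeneric("subgroupNames", function(object) standardGeneric("subgroupNames"))

#' Calendar dates covered by an object
#'
#' @param object An `EDPanel`, `EDCovariates`, `CrowdingLabels` or
#'   `EDDesignMatrix`.
#' @return A `Date` vector of the distinct calendar days covered, in order.
#' @export
setGeneric("panelDates", function(object) standardGeneric("panelDates"))

#' Crowding label accessors
#'
#' `hourlyIndicators()` returns the subgroup-by-hour logical crowding
#' indicator matrix, `dailyCrowding()` the subgroup-by-date daily crisis
#' label matrix, and `crowdedHourCounts()` the subgroup-by-date count of
#' crowded hours within each calendar day.
#'
#' @param object A [CrowdingLabels-class] object.
#' @return Logical (or integer, for counts) matrices with subgroups as rows.
#' @export
setGeneric("hourlyIndicators", function(object) standardGeneric("hourlyIndicators"))

#' @rdname hourlyIndicators
#' @export
setGeneric("dailyCrowding", function(object) standardGeneric("dailyCrowding"))

#' @rdname hourlyIndicators
#' @export
setGeneric("crowdedHourCounts", function(object) standardGeneric("crowdedHourCounts"))

#' Design-matrix accessors
#'
#' `designFeatures()` returns the numeric feature matrix (one row per
#' (date, subgroup, origin) combination), `designLabel()` the 0/1 daily
#' crowding label aligned to its rows, and `designDates()` the row dates.
#' `featureRoles()` maps each feature column to its role (calendar, beds,
#' lag, weather, subgroup, origin or lookback).
#'
#' @param object An [EDDesignMatrix-class].
#' @return See the individual descriptions.
#' @export
setGeneric("designFeatures", function(object) standardGeneric("designFeatures"))

#' @rdname designFeatures
#' @export
setGeneric("designLabel", function(object) standardGeneric("designLabel"))

#' @rdname designFeatures
#' @export
setGeneric("designDates", function(object) standardGeneric("designDates"))

#' @rdname designFeatures
#' @export
setGeneric("featureRoles", function(object) standardGeneric("featureRoles"))

#' Forecast-run accessors
#'
#' `predictions()` returns the per-row test-set predictions of a
#' [ForecastRun-class] (date, subgroup, origin, predicted probability, true
#' label and the training-window end date that produced it); `runMeta()`
#' the metadata list (hyperparameters, seed, refit count, training sizes).
#'
#' @param object A `ForecastRun`.
#' @return A `data.frame` (`predictions`) or a list (`runMeta`).
#' @export
setGeneric("predictions", function(object) standardGeneric("predictions"))

#' @rdname predictions
#' @export
setGeneric("runMeta", function(object) standardGeneric("runMeta"))

#' Attribution accessors
#'
#' `globalImportance()` returns the per-feature global importance table
#' (mean absolute attribution, sorted non-increasing with ranks);
#' `rowAttributions()` the per-row attribution matrix.
#'
#' @param object An [AttributionResult-class].
#' @return A `data.frame` or a numeric matrix respectively.
#' @export
setGeneric("globalImportance", function(object) standardGeneric("globalImportance"))

#' @rdname globalImportance
#' @export
setGeneric("rowAttributions", function(object) standardGeneric("rowAttributions"))
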