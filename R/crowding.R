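#' Hourly crowding indicators
#'
#' Flags every (subgroup, hour) cell whose occupancy ratio is at or above the
#' crisis threshold.  The comparison is `>=` so an EDOR of exactly the
#' threshold counts as crowded.
#'
#' @param panel An [EDPanel-class].
#' @param threshold EDOR crisis threshold (default 0.90, the level associated
#'   with increased 10-day mortality).
#' @return Logical matrix, subgroups by hours, with the panel's dimnames.
#' @export
#' @examples
#' sim <- simulatePanel(edSimConfig(nDays = 7, seed = 2))
#' ind <- hourlyCrowding(sim$panel)
#' mean(ind["medical", ])
hourlyCrowding <- function(panel, threshold = 0.90) {
    stopifnot(is(panel, "EDPanel"))
    if (threshold <= 0) stop("threshold must be positive")
    cd <- SummarizedExperiment::colData(panel)
    secs <- as.numeric(cd$timestamp)
    gaps <- which(diff(secs) != 3600)
    if (length(gaps))
        stop("panel has gaps in its hourly grid after: ",
             paste(format(cd$timestamp[gaps]), collapse = ", "))
    ind <- edor(panel) >= threshold
    dimnames(ind) <- list(subgroupNames(panel), format(cd$timestamp))
    ind
}

#' Daily crisis labels from hourly indicators
#'
#' Aggregates hourly crowding indicators into per-(subgroup, date) crisis
#' labels: a calendar day is labelled crowded when at least `minHours` of its
#' 24 hours are crowded.  The label covers the whole calendar day and is
#' shared by all forecast origins of that day.
#'
#' @param hourly Logical subgroup-by-hour indicator matrix covering whole
#'   calendar days (from [hourlyCrowding()]).
#' @param dates `Date` vector, one per day covered (defaults to parsing the
#'   indicator column names).
#' @param threshold,minHours Crisis definition recorded in the result.
#' @return A [CrowdingLabels-class].
#' @export
dailyLabels <- function(hourly, dates = NULL, threshold = 0.90, minHours = 3L) {
    if (minHours < 1L) stop("minHours must be >= 1")
    if (ncol(hourly) %% 24L != 0L)
        stop("indicators must cover whole calendar days; got ", ncol(hourly),
             " hours (not a multiple of 24); partial days are not truncated silently")
    nD <- ncol(hourly) %/% 24L
    if (is.null(dates)) {
        ts <- as.POSIXct(colnames(hourly), tz = "UTC")
        if (anyNA(ts)) stop("cannot recover dates from column names; pass `dates`")
        if (any(as.POSIXlt(ts[seq(1L, ncol(hourly), by = 24L)])$hour != 0L))
            stop("days must start at hour 00")
        dates <- as.Date(ts[seq(1L, ncol(hourly), by = 24L)])
    }
    stopifnot(length(dates) == nD)
    day <- rep(seq_len(nD), each = 24L)
    counts <- t(apply(hourly, 1L, function(h) as.integer(tapply(h, day, sum))))
    dim(counts) <- c(nrow(hourly), nD)
    storage.mode(counts) <- "integer"
    dimnames(counts) <- list(rownames(hourly), format(dates))
    daily <- counts >= as.integer(minHours)
    new("CrowdingLabels", hourly = hourly, daily = daily, counts = counts,
        dates = as.Date(dates), timestamps = as.POSIXct(colnames(hourly), tz = "UTC"),
        threshold = threshold, minHours = as.integer(minHours))
}

#' Crowding labels straight from a panel
#'
#' Convenience wrapper chaining [hourlyCrowding()] and [dailyLabels()].
#'
#' @inheritParams hourlyCrowding
#' @inheritParams dailyLabels
#' @return A [CrowdingLabels-class].
#' @export
#' @examples
#' sim <- simulatePanel(edSimConfig(nDays = 30, seed = 2))
#' lab <- crowdingLabels(sim$panel)
#' rowMeans(dailyCrowding(lab))
crowdingLabels <- function(panel, threshold = 0.90, minHours = 3L) {
    cd <- SummarizedExperiment::colData(panel)
    dailyLabels(hourlyCrowding(panel, threshold),
                dates = unique(as.Date(cd$date)),
                threshold = threshold, minHours = minHours)
}
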