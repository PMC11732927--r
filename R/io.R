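#' @importFrom data.table fwrite fread
#' @importFrom jsonlite write_json read_json
NULL

#' Read and write pipeline stage files
#'
#' Every pipeline stage serializes its output to plain-text files so each
#' intermediate is inspectable and any stage can be re-run from its
#' predecessor's files.  Panels are one row per hour (`timestamp`,
#' `occ_<subgroup>`, `edor_<subgroup>`), covariates one row per day, labels
#' one row per (subgroup, date), and the design matrix a wide CSV plus a JSON
#' schema recording column order, roles and categorical declarations
#' (bit-exact column ordering is part of the contract).
#'
#' @param panel,covariates,labels,dm,run Objects to serialize.
#' @param path,dir File or directory path.
#' @param capacities Optional named capacities when reading a panel whose
#'   occupancy never leaves zero (otherwise recovered from occupancy/EDOR).
#' @name stage-io
NULL

#' @rdname stage-io
#' @export
writePanelCsv <- function(panel, path) {
    subs <- subgroupNames(panel)
    occ <- t(occupancy(panel)); ed <- t(edor(panel))
    colnames(occ) <- paste0("occ_", subs)
    colnames(ed) <- paste0("edor_", subs)
    dt <- data.table::data.table(
        timestamp = format(panelTimestamps(panel), "%Y-%m-%d %H:%M:%S"))
    data.table::fwrite(cbind(dt, occ, ed), path)
    invisible(path)
}

#' @rdname stage-io
#' @export
readPanelCsv <- function(path, capacities = NULL) {
    dt <- data.table::fread(path)
    subs <- sub("^occ_", "", grep("^occ_", names(dt), value = TRUE))
    occ <- t(as.matrix(dt[, paste0("occ_", subs), with = FALSE]))
    rownames(occ) <- subs
    storage.mode(occ) <- "integer"
    if (is.null(capacities)) {
        caps <- vapply(subs, function(s) {
            o <- dt[[paste0("occ_", s)]]; e <- dt[[paste0("edor_", s)]]
            i <- which(o > 0)
            if (!length(i)) stop("cannot recover capacity for subgroup '", s,
                                 "' from an all-zero series; pass `capacities`")
            round(stats::median(o[i] / e[i]))
        }, numeric(1))
        capacities <- stats::setNames(as.integer(caps), subs)
    }
    ts <- as.POSIXct(dt$timestamp, tz = "UTC")
    EDPanel(occ, capacities, as.Date(ts[1L]))
}

#' @rdname stage-io
#' @export
writeCovariatesCsv <- function(covariates, path) {
    data.table::fwrite(covariateData(covariates), path)
    invisible(path)
}

#' @rdname stage-io
#' @export
readCovariatesCsv <- function(path) {
    d <- as.data.frame(data.table::fread(path))
    d$date <- as.Date(d$date)
    for (cn in c("holiday", "after_holiday", "before_holiday"))
        d[[cn]] <- as.logical(d[[cn]])
    EDCovariates(d)
}

#' @rdname stage-io
#' @export
writeLabelsCsv <- function(labels, path) {
    counts <- crowdedHourCounts(labels)
    daily <- dailyCrowding(labels)
    dates <- panelDates(labels)
    dt <- data.table::data.table(
        subgroup = rep(rownames(counts), times = ncol(counts)),
        date = rep(format(dates), each = nrow(counts)),
        crowded_hour_count = as.integer(counts),
        label = as.integer(daily),
        threshold = labels@threshold,
        min_hours = labels@minHours)
    data.table::fwrite(dt, path)
    invisible(path)
}

#' Re-derive crowding labels from a panel and verify them against a labels CSV
#'
#' @param path Labels CSV written by [writeLabelsCsv()].
#' @param panel The source [EDPanel-class] (labels are hourly-resolved, so
#'   the panel is required to reconstruct the hourly indicators).
#' @return A [CrowdingLabels-class]; errors if the recomputed labels disagree
#'   with the file.
#' @export
readLabelsCsv <- function(path, panel) {
    dt <- data.table::fread(path)
    labels <- crowdingLabels(panel, threshold = dt$threshold[1L],
                             minHours = dt$min_hours[1L])
    key <- cbind(match(dt$subgroup, rownames(crowdedHourCounts(labels))),
                 match(as.Date(dt$date), panelDates(labels)))
    if (!all(crowdedHourCounts(labels)[key] == dt$crowded_hour_count) ||
        !all(as.integer(dailyCrowding(labels))[ (key[, 2] - 1) * nrow(dailyCrowding(labels)) + key[, 1] ] == dt$label))
        stop("labels file disagrees with labels recomputed from the panel")
    labels
}

#' @rdname stage-io
#' @export
writeDesignMatrixCsv <- function(dm, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    feats <- designFeatures(dm)
    dt <- data.table::data.table(date = format(designDates(dm)))
    dt <- cbind(dt, data.table::as.data.table(feats),
                data.table::data.table(crowding = designLabel(dm)))
    data.table::fwrite(dt, file.path(dir, "design_matrix.csv"))
    schema <- list(
        columns = colnames(feats), roles = unname(dm@roles),
        label = "crowding", categorical = dm@categorical,
        origins = dm@origins,
        subgroup_codes = as.list(dm@panelSubgroups))
    jsonlite::write_json(schema, file.path(dir, "schema.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(dir)
}

#' @rdname stage-io
#' @export
readDesignMatrixCsv <- function(dir) {
    schema <- jsonlite::read_json(file.path(dir, "schema.json"),
                                  simplifyVector = TRUE)
    dt <- data.table::fread(file.path(dir, "design_matrix.csv"))
    feats <- as.matrix(dt[, schema$columns, with = FALSE])
    new("EDDesignMatrix",
        date = as.Date(dt$date), features = feats,
        label = as.integer(dt$crowding), roles = schema$roles,
        origins = as.integer(schema$origins),
        panelSubgroups = stats::setNames(as.integer(unlist(schema$subgroup_codes)),
                                         names(schema$subgroup_codes)),
        categorical = schema$categorical)
}

#' @rdname stage-io
#' @export
writeForecastCsv <- function(run, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    pr <- predictions(run)
    pr$date <- format(pr$date); pr$train_window_end <- format(pr$train_window_end)
    data.table::fwrite(pr, file.path(dir, "forecast.csv"))
    meta <- runMeta(run)
    jsonlite::write_json(
        list(params = meta$params$params, nrounds = meta$params$nrounds,
             seed = meta$seed, n_refits = meta$nRefits,
             train_sizes = meta$trainSizes),
        file.path(dir, "run_manifest.json"), auto_unbox = TRUE, digits = NA,
        pretty = TRUE)
    invisible(dir)
}

#' @rdname stage-io
#' @export
readForecastCsv <- function(dir) {
    pr <- as.data.frame(data.table::fread(file.path(dir, "forecast.csv")))
    pr$date <- as.Date(pr$date)
    pr$train_window_end <- as.Date(pr$train_window_end)
    meta <- jsonlite::read_json(file.path(dir, "run_manifest.json"),
                                simplifyVector = TRUE)
    new("ForecastRun", predictions = pr,
        params = list(params = as.list(meta$params),
                      nrounds = as.integer(meta$nrounds)),
        seed = as.integer(meta$seed), nRefits = as.integer(meta$n_refits),
        trainSizes = as.integer(meta$train_sizes))
}
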