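#' Pipeline configuration
#'
#' Bundles every stage's parameters plus a single global seed.  The global
#' seed fans out deterministically to per-stage seeds (simulation uses
#' `seed`, model fitting `seed + 1000`, bootstrap `seed + 2000`, surrogate
#' attribution `seed + 3000`, attribution row subsampling `seed + 4000`) so
#' each stage is independently reproducible.
#'
#' @param outDir Output directory; every stage writes its files there.
#' @param sim An [EDSimConfig-class] (its seed is overridden by `seed`).
#' @param edorThreshold,minCrowdedHours Crisis definition (defaults 0.90, 3).
#' @param origins Forecast-origin hours (default 8..13).
#' @param initialTrainDays Length of the initial training window in days
#'   (default 365); the test period is the remainder of the panel.
#' @param strideDays Retraining stride (1 = refit at the start of each test
#'   day).
#' @param hyper Hyperparameters ([defaultHyperparameters()]).
#' @param nBootstrap Bootstrap resamples (default 200).
#' @param predThreshold Classification cutoff (default 0.5).
#' @param shapRows,limeRows,limeSamples Attribution workload: rows attributed
#'   by the Shapley method, rows explained by the surrogate method, and
#'   perturbed samples per explained row.
#' @param seed Global integer seed.
#' @return A list of class `edcastPipeline` (validated fail-fast).
#' @export
pipelineConfig <- function(outDir,
                           sim = edSimConfig(),
                           edorThreshold = 0.90,
                           minCrowdedHours = 3L,
                           origins = 8:13,
                           initialTrainDays = 365L,
                           strideDays = 1L,
                           hyper = defaultHyperparameters(),
                           nBootstrap = 200L,
                           predThreshold = 0.5,
                           shapRows = 200L,
                           limeRows = 10L,
                           limeSamples = 150L,
                           seed = 1L) {
    if (initialTrainDays < 1L || initialTrainDays >= sim@nDays)
        stop("initialTrainDays must leave at least one test day inside the panel")
    lastDate <- sim@startDate + sim@nDays - 1L
    split <- splitConfig(sim@startDate + initialTrainDays - 1L, lastDate,
                         strideDays)
    sim@seed <- as.integer(seed)
    structure(list(outDir = outDir, sim = sim, edorThreshold = edorThreshold,
                   minCrowdedHours = as.integer(minCrowdedHours),
                   origins = as.integer(origins), split = split,
                   hyper = hyper, nBootstrap = as.integer(nBootstrap),
                   predThreshold = predThreshold,
                   shapRows = as.integer(shapRows),
                   limeRows = as.integer(limeRows),
                   limeSamples = as.integer(limeSamples),
                   seed = as.integer(seed)),
              class = "edcastPipeline")
}

.STAGES <- c("simulate", "targets", "features", "train", "evaluate", "attribute")

#' Run the end-to-end pipeline
#'
#' Executes simulate, targets, features, train, evaluate and attribute in
#' order.  Every stage reads only the previous stage's serialized files from
#' `outDir` (no in-memory shortcuts), so each intermediate is inspectable and
#' any suffix of stages can be re-run after deleting downstream outputs.  A
#' manifest with the configuration seeds and an MD5 checksum per output file
#' is written at the end; identical configurations yield identical
#' checksums.
#'
#' @param config An `edcastPipeline` from [pipelineConfig()].
#' @param stages Subset of stages to run (default all, in order).
#' @return The manifest list, invisibly.
#' @export
#' @examples
#' \donttest{
#' cfg <- pipelineConfig(tempfile("edrun"), sim = edSimConfig(nDays = 60),
#'                       initialTrainDays = 40, strideDays = 7,
#'                       hyper = defaultHyperparameters(20, max_depth = 3),
#'                       nBootstrap = 50, shapRows = 40, limeRows = 2,
#'                       limeSamples = 60)
#' manifest <- runPipeline(cfg)
#' }
runPipeline <- function(config, stages = .STAGES) {
    stopifnot(inherits(config, "edcastPipeline"))
    stages <- match.arg(stages, .STAGES, several.ok = TRUE)
    out <- config$outDir
    if (!dir.exists(out)) dir.create(out, recursive = TRUE)
    pth <- function(...) file.path(out, ...)
    runStage <- function(name, fun) {
        tryCatch(fun(), error = function(e)
            stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
                 call. = FALSE))
    }

    if ("simulate" %in% stages) runStage("simulate", function() {
        simOut <- simulatePanel(config$sim)
        writePanelCsv(simOut$panel, pth("panel.csv"))
        writeCovariatesCsv(simOut$covariates, pth("covariates.csv"))
    })
    if ("targets" %in% stages) runStage("targets", function() {
        panel <- readPanelCsv(pth("panel.csv"), config$sim@capacities)
        labels <- crowdingLabels(panel, config$edorThreshold,
                                 config$minCrowdedHours)
        writeLabelsCsv(labels, pth("labels.csv"))
    })
    if ("features" %in% stages) runStage("features", function() {
        panel <- readPanelCsv(pth("panel.csv"), config$sim@capacities)
        covariates <- readCovariatesCsv(pth("covariates.csv"))
        labels <- readLabelsCsv(pth("labels.csv"), panel)
        dm <- buildDesignMatrix(panel, covariates, labels, config$origins)
        writeDesignMatrixCsv(dm, out)
    })
    if ("train" %in% stages) runStage("train", function() {
        dm <- readDesignMatrixCsv(out)
        run <- expandingWindowForecast(dm, config$split, config$hyper,
                                       seed = config$seed + 1000L)
        writeForecastCsv(run, out)
        feats <- designFeatures(dm)
        trainIdx <- designDates(dm) <= config$split$initialTrainEnd
        model <- fitCrowdingModel(feats[trainIdx, , drop = FALSE],
                                  designLabel(dm)[trainIdx], config$hyper,
                                  seed = config$seed + 1000L)
        if (!is.null(model$booster))
            xgboost::xgb.save(model$booster, pth("model.ubj"))
    })
    if ("evaluate" %in% stages) runStage("evaluate", function() {
        run <- readForecastCsv(out)
        bc <- bootstrapConfig(config$nBootstrap, seed = config$seed + 2000L)
        tab <- metricsTable(run, bc, config$predThreshold)
        data.table::fwrite(tab, pth("metrics.csv"))
        cal <- do.call(rbind, lapply(sort(unique(predictions(run)$origin)),
            function(og) cbind(origin = og,
                               calendarOutcomes(run, og, config$predThreshold))))
        data.table::fwrite(cal, pth("calendar_outcomes.csv"))
    })
    if ("attribute" %in% stages) runStage("attribute", function() {
        dm <- readDesignMatrixCsv(out)
        if (!file.exists(pth("model.ubj")))
            stop("no fitted model file; run the train stage first")
        model <- structure(list(booster = xgboost::xgb.load(pth("model.ubj")),
                                constant = NULL,
                                features = colnames(designFeatures(dm))),
                           class = "crowdingModel")
        feats <- designFeatures(dm)
        testIdx <- which(designDates(dm) > config$split$initialTrainEnd)
        xTest <- feats[testIdx, , drop = FALSE]
        shap <- shapleyImportance(model, xTest,
                                  nRows = min(config$shapRows, nrow(xTest)),
                                  seed = config$seed + 4000L)
        limeRowIdx <- withr::with_seed(config$seed + 4000L,
            sample.int(nrow(xTest), min(config$limeRows, nrow(xTest))))
        lime <- surrogateImportance(model, xTest[limeRowIdx, , drop = FALSE],
                                    reference = xTest,
                                    categorical = intersect(dm@categorical,
                                                            "subgroup"),
                                    ordinal = setdiff(dm@categorical,
                                                      "subgroup"),
                                    nSamples = config$limeSamples,
                                    seed = config$seed + 3000L)
        imp <- rbind(cbind(method = "shapley", globalImportance(shap)),
                     cbind(method = "local-surrogate", globalImportance(lime)))
        data.table::fwrite(imp, pth("importance.csv"))
    })

    files <- c("panel.csv", "covariates.csv", "labels.csv",
               "design_matrix.csv", "schema.json", "forecast.csv",
               "run_manifest.json", "metrics.csv", "calendar_outcomes.csv",
               "importance.csv")
    present <- files[file.exists(pth(files))]
    manifest <- list(
        package = as.character(utils::packageVersion("edcast")),
        seed = config$seed,
        stage_seeds = list(simulate = config$seed, train = config$seed + 1000L,
                           bootstrap = config$seed + 2000L,
                           surrogate = config$seed + 3000L,
                           subsample = config$seed + 4000L),
        checksums = as.list(tools::md5sum(pth(present))))
    names(manifest$checksums) <- present
    jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    invisible(manifest)
}
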