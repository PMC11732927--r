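#' @importFrom stats rpois rgeom rnorm rgamma rbinom runif setNames quantile
#' @importFrom withr with_seed
NULL

# ---------------------------------------------------------------------------
# Simulation configuration
# ---------------------------------------------------------------------------

#' Simulation configuration for synthetic ED panels
#'
#' Parameterises the arrival/departure queue that generates hourly sectioned
#' occupancy: each operational section (critical, medical, surgical) receives
#' Poisson arrivals with a nonhomogeneous hourly intensity
#' `base * hourMult(hour) * weekdayMult(weekday) * holiday factor * seasonal
#' sinusoid * shared daily load effect`, every arrival stays a geometric
#' (whole-hour) length of stay, and occupancy counts patients present.  The
#' bedoccupying series is the sum of the three sections (a simulator
#' convention).  Daily weather, regional bed availability (AR(1), may go
#' negative) and a Nordic-style holiday calendar are generated alongside.
#'
#' @slot startDate First panel day.
#' @slot nDays Number of simulated days (>= 1).
#' @slot capacities Named positive integer bed capacities.
#' @slot baseRate Named mean hourly arrival rate per section.
#' @slot hourMult 24 nonnegative hour-of-day intensity multipliers
#'   (internally normalised to mean 1).
#' @slot weekdayMult 7 multipliers, Monday first.
#' @slot holidayMult Single multiplier applied on public holidays.
#' @slot seasonAmplitude,seasonPeakDay Sinusoidal annual intensity component.
#' @slot dailyEffectSd,dailyEffectRho Log-normal AR(1) day-level load effect
#'   shared by all sections (mean 1).
#' @slot hourlyEffectSd,hourlyEffectRho Log-normal AR(1) hour-level load
#'   shock shared by all sections (mean 1); makes section loads co-move
#'   within a day the way hospital-wide surges do.
#' @slot losMeanHours Named mean length of stay (hours, >= 1) per section;
#'   stays are geometric on whole hours.
#' @slot weatherModel,bedsModel Parameter lists, see `edSimConfig()`.
#' @slot holidays Resolved holiday calendar (extends beyond the panel range
#'   so boundary before/after-holiday flags are well defined).
#' @slot warmupDays Burn-in days simulated before `startDate` so occupancy
#'   starts at its stationary level.
#' @slot seed Integer seed; identical configs yield bit-identical output.
#' @export
setClass("EDSimConfig", representation(
    startDate = "Date", nDays = "integer", capacities = "integer",
    baseRate = "numeric", hourMult = "numeric", weekdayMult = "numeric",
    holidayMult = "numeric", seasonAmplitude = "numeric", seasonPeakDay = "numeric",
    dailyEffectSd = "numeric", dailyEffectRho = "numeric",
    hourlyEffectSd = "numeric", hourlyEffectRho = "numeric",
    losMeanHours = "numeric", weatherModel = "list", bedsModel = "list",
    holidays = "Date", warmupDays = "integer", seed = "integer"))

.validEDSimConfig <- function(object) {
    msg <- character()
    if (object@nDays < 1L) msg <- c(msg, "nDays: must be >= 1")
    if (!all(names(.SUBGROUP_CODES) %in% names(object@capacities)))
        msg <- c(msg, "capacities: must name bedoccupying, critical, medical, surgical")
    else if (any(object@capacities <= 0L)) msg <- c(msg, "capacities: must be positive")
    if (!all(.SECTIONS %in% names(object@baseRate)))
        msg <- c(msg, "baseRate: must name critical, medical, surgical")
    else if (any(object@baseRate < 0)) msg <- c(msg, "baseRate: must be nonnegative")
    if (length(object@hourMult) != 24L || any(object@hourMult < 0))
        msg <- c(msg, "hourMult: 24 nonnegative values required")
    if (length(object@weekdayMult) != 7L || any(object@weekdayMult < 0))
        msg <- c(msg, "weekdayMult: 7 nonnegative values required")
    if (object@holidayMult < 0) msg <- c(msg, "holidayMult: must be nonnegative")
    if (object@seasonAmplitude < 0 || object@seasonAmplitude >= 1)
        msg <- c(msg, "seasonAmplitude: must lie in [0, 1)")
    if (object@dailyEffectSd < 0) msg <- c(msg, "dailyEffectSd: must be nonnegative")
    if (abs(object@dailyEffectRho) >= 1) msg <- c(msg, "dailyEffectRho: must lie in (-1, 1)")
    if (object@hourlyEffectSd < 0) msg <- c(msg, "hourlyEffectSd: must be nonnegative")
    if (abs(object@hourlyEffectRho) >= 1) msg <- c(msg, "hourlyEffectRho: must lie in (-1, 1)")
    if (!all(.SECTIONS %in% names(object@losMeanHours)))
        msg <- c(msg, "losMeanHours: must name critical, medical, surgical")
    else if (any(object@losMeanHours < 1)) msg <- c(msg, "losMeanHours: must be >= 1 hour")
    if (object@warmupDays < 0L) msg <- c(msg, "warmupDays: must be nonnegative")
    if (length(msg)) msg else TRUE
}
setValidity("EDSimConfig", .validEDSimConfig)

## Calibrated default arrival/queue parameters.  The shape gives a late-night
## trough, a steep late-morning rise and an early-afternoon plateau so that
## occupancy (which lags arrivals by the mean stay) troughs at 8-10 a.m. and
## peaks mid-afternoon, matching the observed diurnal crowding pattern.
.DEFAULT_HOUR_MULT <- c(0.28, 0.20, 0.16, 0.14, 0.13, 0.15, 0.24, 0.48,
                        0.85, 1.30, 1.65, 1.90, 1.98, 1.95, 1.85, 1.75,
                        1.62, 1.50, 1.35, 1.18, 1.00, 0.80, 0.58, 0.42)
.DEFAULT_WEEKDAY_MULT <- c(1.06, 1.04, 1.03, 1.03, 1.02, 0.89, 0.93)

#' Construct a simulation configuration
#'
#' `edSimConfig()` builds an [EDSimConfig-class]; called with no arguments it
#' returns the calibrated default parameterisation shipped with the package
#' (also available as `defaultSimConfig()`), for which the daily crisis-day
#' prevalence over long horizons is close to 28% (bedoccupying), 36%
#' (medical) and 25% (surgical) while morning (8-10 a.m.) hourly crowding is
#' essentially absent.
#'
#' @param startDate First simulated day.
#' @param nDays Number of days to simulate.
#' @param seed Integer seed.
#' @param capacities Named bed capacities (defaults: bedoccupying 65,
#'   critical 6, medical 36, surgical 23).
#' @param baseRate Mean hourly arrivals per section.
#' @param hourMult,weekdayMult,holidayMult Intensity multipliers.
#' @param seasonAmplitude,seasonPeakDay Annual sinusoid (peak day of year).
#' @param dailyEffectSd,dailyEffectRho Shared day-level log-normal AR(1)
#'   load effect (captures epidemics/weather surges; gives the morning hours
#'   genuine predictive value for the same afternoon).
#' @param hourlyEffectSd,hourlyEffectRho Shared hour-level log-normal AR(1)
#'   load shock (hospital-wide surges within a day).
#' @param losMeanHours Mean length of stay per section (geometric, hours).
#' @param weatherModel,bedsModel Covariate model parameter lists; see the
#'   defaults in the function signature.
#' @param holidays Optional explicit holiday `Date` vector; by default a
#'   Nordic-style public-holiday calendar covering the simulated years (plus
#'   a margin) is generated.
#' @param warmupDays Queue burn-in days before `startDate`.
#' @return An [EDSimConfig-class].
#' @export
#' @examples
#' cfg <- edSimConfig(nDays = 30, seed = 7)
#' cfg
edSimConfig <- function(startDate = as.Date("2018-01-01"),
                        nDays = 730L,
                        seed = 1L,
                        capacities = c(bedoccupying = 65L, critical = 6L,
                                       medical = 36L, surgical = 23L),
                        baseRate = c(critical = 0.65, medical = 3.75, surgical = 2.35),
                        hourMult = .DEFAULT_HOUR_MULT,
                        weekdayMult = .DEFAULT_WEEKDAY_MULT,
                        holidayMult = 0.90,
                        seasonAmplitude = 0.06,
                        seasonPeakDay = 45,
                        dailyEffectSd = 0.22,
                        dailyEffectRho = 0.5,
                        hourlyEffectSd = 0.15,
                        hourlyEffectRho = 0.92,
                        losMeanHours = c(critical = 2.2, medical = 5.0, surgical = 4.5),
                        weatherModel = list(tempMeanAnnualC = 5.0, tempAmplitudeC = 12.5,
                                            tempPeakDoy = 197, tempNoiseSd = 3.5,
                                            diurnalHalfRangeC = 3.5, wetProb = 0.45,
                                            rainShape = 0.7, rainScale = 4.8),
                        bedsModel = list(mean = 29, rho = 0.85, sd = 8),
                        holidays = NULL,
                        warmupDays = 10L) {
    startDate <- as.Date(startDate)
    if (is.null(holidays)) {
        yrs <- seq(as.integer(format(startDate - 366, "%Y")),
                   as.integer(format(startDate + nDays + 366, "%Y")))
        holidays <- nordicHolidays(yrs)
    }
    new("EDSimConfig",
        startDate = startDate, nDays = as.integer(nDays),
        capacities = setNames(as.integer(capacities), names(capacities)),
        baseRate = baseRate, hourMult = hourMult, weekdayMult = weekdayMult,
        holidayMult = holidayMult, seasonAmplitude = seasonAmplitude,
        seasonPeakDay = seasonPeakDay, dailyEffectSd = dailyEffectSd,
        dailyEffectRho = dailyEffectRho, hourlyEffectSd = hourlyEffectSd,
        hourlyEffectRho = hourlyEffectRho, losMeanHours = losMeanHours,
        weatherModel = weatherModel, bedsModel = bedsModel,
        holidays = as.Date(holidays), warmupDays = as.integer(warmupDays),
        seed = as.integer(seed))
}

#' @rdname edSimConfig
#' @param ... Passed to `edSimConfig()` (typically `nDays`, `seed`).
#' @export
defaultSimConfig <- function(...) edSimConfig(...)

setMethod("show", "EDSimConfig", function(object) {
    cat(sprintf("EDSimConfig: %d days from %s, seed %d\n",
                object@nDays, object@startDate, object@seed))
    cat("  base arrival rates/h:",
        paste(sprintf("%s=%.2f", names(object@baseRate), object@baseRate),
              collapse = ", "), "\n")
})

# ---------------------------------------------------------------------------
# Holiday calendar
# ---------------------------------------------------------------------------

## Gregorian Easter Sunday (anonymous computus).
.easterSunday <- function(year) {
    a <- year %% 19; b <- year %/% 100; c <- year %% 100
    d <- b %/% 4; e <- b %% 4; f <- (b + 8) %/% 25
    g <- (b - f + 1) %/% 3
    h <- (19 * a + b - d - g + 15) %% 30
    i <- c %/% 4; k <- c %% 4
    l <- (32 + 2 * e + 2 * i - h - k) %% 7
    m <- (a + 11 * h + 22 * l) %/% 451
    month <- (h + l - 7 * m + 114) %/% 31
    day <- ((h + l - 7 * m + 114) %% 31) + 1
    as.Date(sprintf("%d-%02d-%02d", year, month, day))
}

## First date with the given weekday (1 = Monday .. 7 = Sunday) in [from, to].
.weekdayIn <- function(year, month, fromDay, weekday) {
    d <- as.Date(sprintf("%d-%02d-%02d", year, month, fromDay))
    d + (weekday - ((as.POSIXlt(d)$wday + 6L) %% 7L + 1L)) %% 7L
}

#' Nordic-style public-holiday calendar
#'
#' Fixed-date holidays (Jan 1, Epiphany, May 1, Independence Day Dec 6,
#' Christmas Eve/Day/Boxing Day), Easter-anchored holidays (Good Friday,
#' Easter Sunday and Monday, Ascension) and the Saturday-anchored Midsummer
#' and All Saints days, per year.
#'
#' @param years Integer vector of calendar years.
#' @return Sorted `Date` vector of holidays.
#' @export
#' @examples
#' length(nordicHolidays(2018))
nordicHolidays <- function(years) {
    out <- lapply(years, function(y) {
        easter <- .easterSunday(y)
        c(as.Date(sprintf("%d-01-01", y)), as.Date(sprintf("%d-01-06", y)),
          easter - 2, easter, easter + 1, easter + 39,
          as.Date(sprintf("%d-05-01", y)),
          .weekdayIn(y, 6, 19, 5), .weekdayIn(y, 6, 20, 6),   # Midsummer Eve/Day
          .weekdayIn(y, 10, 31, 6),                           # All Saints
          as.Date(sprintf("%d-12-06", y)),
          as.Date(sprintf("%d-12-24", y)), as.Date(sprintf("%d-12-25", y)),
          as.Date(sprintf("%d-12-26", y)))
    })
    sort(unique(do.call(c, out)))
}

# ---------------------------------------------------------------------------
# Queue simulation internals
# ---------------------------------------------------------------------------

## Hourly arrival intensity grid over (warmup + nDays) x 24 hours for one
## section; dayEffect is the shared log-normal AR(1) load multiplier.
.lambdaGrid <- function(config, section, dayEffect, hourEffect) {
    nTot <- config@warmupDays + config@nDays
    dates <- config@startDate - config@warmupDays + seq_len(nTot) - 1L
    wday <- (as.POSIXlt(dates)$wday + 6L) %% 7L + 1L   # 1 = Monday
    doy <- as.integer(format(dates, "%j"))
    season <- 1 + config@seasonAmplitude *
        cos(2 * pi * (doy - config@seasonPeakDay) / 365.25)
    dayMult <- config@weekdayMult[wday]
    dayMult[dates %in% config@holidays] <- config@holidayMult
    hm <- config@hourMult / mean(config@hourMult)
    base <- config@baseRate[[section]]
    as.vector(outer(hm, base * dayMult * season * dayEffect)) * hourEffect
}

## Simulate one section's queue on an extended hourly grid.  Returns the
## occupancy over the full grid plus arrival bookkeeping so that patient-hour
## conservation can be verified: every arrival contributes exactly `los`
## hours to `occupancyFull`.
.simulateSectionQueue <- function(lambda, losMean) {
    nH <- length(lambda)
    arrivals <- rpois(nH, lambda)
    tot <- sum(arrivals)
    los <- if (tot > 0) 1L + rgeom(tot, prob = 1 / losMean) else integer()
    starts <- rep.int(seq_len(nH), arrivals)
    ends <- starts + los - 1L
    nBins <- if (tot > 0) max(nH, max(ends)) + 1L else nH + 1L
    delta <- tabulate(starts, nBins) - tabulate(ends + 1L, nBins)
    occFull <- cumsum(delta)
    list(occupancyFull = occFull, arrivals = arrivals, los = los, nHours = nH)
}

## Daily covariates; day effect reused nowhere here (weather independent).
.simulateCovariates <- function(config) {
    n <- config@nDays
    dates <- config@startDate + seq_len(n) - 1L
    doy <- as.integer(format(dates, "%j"))
    wm <- config@weatherModel
    seasonal <- wm$tempMeanAnnualC + wm$tempAmplitudeC *
        cos(2 * pi * (doy - wm$tempPeakDoy) / 365.25)
    tmean <- round(seasonal + rnorm(n, 0, wm$tempNoiseSd), 1)
    tmax <- round(tmean + wm$diurnalHalfRangeC + abs(rnorm(n, 0, 1.5)), 1)
    tmin <- round(tmean - wm$diurnalHalfRangeC - abs(rnorm(n, 0, 1.5)), 1)

    wet <- runif(n) < wm$wetProb
    precip <- ifelse(wet, round(rgamma(n, wm$rainShape, scale = wm$rainScale), 1), -1)
    ## Snow pack: accumulate precipitation on freezing days, melt above 0 C.
    snow <- numeric(n)
    pack <- 0
    for (d in seq_len(n)) {
        if (tmean[d] <= 0 && wet[d]) pack <- pack + max(precip[d], 0)
        if (tmean[d] > 0) pack <- max(0, pack - 1.5 * tmean[d])
        snow[d] <- if (pack > 0) round(pack, 1) else -1
    }

    bm <- config@bedsModel
    beds <- integer(n)
    statSd <- bm$sd / sqrt(1 - bm$rho^2)
    prev <- bm$mean + rnorm(1, 0, statSd)
    for (d in seq_len(n)) {
        prev <- bm$mean + bm$rho * (prev - bm$mean) + rnorm(1, 0, bm$sd)
        beds[d] <- as.integer(round(prev))
    }

    hol <- dates %in% config@holidays
    EDCovariates(data.frame(
        date = dates,
        precipitation_mm = precip, snow_depth_cm = snow,
        air_temp_mean_c = tmean, air_temp_max_c = tmax, air_temp_min_c = tmin,
        beds_available = beds,
        holiday = hol,
        after_holiday = (dates - 1L) %in% config@holidays,
        before_holiday = (dates + 1L) %in% config@holidays))
}

## Full simulation with arrival bookkeeping (deterministic given config).
.simulatePanelInternal <- function(config) {
    validObject(config)
    with_seed(config@seed, {
        nTot <- config@warmupDays + config@nDays
        eps <- rnorm(nTot)
        logEff <- numeric(nTot)
        sInn <- config@dailyEffectSd * sqrt(1 - config@dailyEffectRho^2)
        logEff[1] <- config@dailyEffectSd * eps[1]
        for (d in seq_len(nTot - 1L))
            logEff[d + 1L] <- config@dailyEffectRho * logEff[d] + sInn * eps[d + 1L]
        dayEffect <- exp(logEff - config@dailyEffectSd^2 / 2)

        nHTot <- nTot * 24L
        epsH <- rnorm(nHTot)
        logH <- numeric(nHTot)
        sInnH <- config@hourlyEffectSd * sqrt(1 - config@hourlyEffectRho^2)
        logH[1] <- config@hourlyEffectSd * epsH[1]
        for (h in seq_len(nHTot - 1L))
            logH[h + 1L] <- config@hourlyEffectRho * logH[h] + sInnH * epsH[h + 1L]
        hourEffect <- exp(logH - config@hourlyEffectSd^2 / 2)

        queues <- lapply(.SECTIONS, function(sec)
            .simulateSectionQueue(.lambdaGrid(config, sec, dayEffect, hourEffect),
                                  config@losMeanHours[[sec]]))
        names(queues) <- .SECTIONS
        covariates <- .simulateCovariates(config)
    })
    keep <- config@warmupDays * 24L + seq_len(config@nDays * 24L)
    secOcc <- vapply(queues, function(q) q$occupancyFull[keep], numeric(length(keep)))
    occ <- rbind(bedoccupying = rowSums(secOcc),
                 critical = secOcc[, "critical"],
                 medical = secOcc[, "medical"],
                 surgical = secOcc[, "surgical"])
    storage.mode(occ) <- "integer"
    panel <- EDPanel(occ, config@capacities, config@startDate)
    list(panel = panel, covariates = covariates, queues = queues)
}

#' Simulate a synthetic hourly ED panel with daily covariates
#'
#' Generates the hourly occupancy/EDOR panel and the daily covariate panel
#' from an arrival/departure queue: Poisson arrivals with nonhomogeneous
#' intensity, geometric whole-hour lengths of stay, occupancy counting
#' patients present.  A warm-up period before `startDate` is simulated and
#' discarded so the panel starts at stationary occupancy.  Identical
#' configurations (including seed) give bit-identical output.
#'
#' @param config An [EDSimConfig-class], e.g. from [edSimConfig()].
#' @return A list with elements `panel` ([EDPanel-class]) and `covariates`
#'   ([EDCovariates-class]).
#' @export
#' @examples
#' sim <- simulatePanel(edSimConfig(nDays = 14, seed = 3))
#' sim$panel
simulatePanel <- function(config) {
    res <- .simulatePanelInternal(config)
    res[c("panel", "covariates")]
}
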