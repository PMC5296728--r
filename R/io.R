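# --- configuration files, result serialization, run manifest ---

.CONFIG_SCHEMA <- list(
    signal = list(
        upper_mean = NULL, lower_mean = NULL,
        on_time_mean = 100, off_time_mean = 100,
        amplitude_var = 0, frequency_noise = 0, duration = 3,
        regulation = "transcription", modulation = "AM",
        noise_family = "lognormal"),
    model = list(
        target_mean = 15, fixed_rate = NULL, m0 = 0,
        burn_in_cycles = 5, sample_dt = 1, measure_periods = 4),
    experiment = list(
        type = "mi-sweep", period = 200,
        on_times = seq(20, 180, by = 20),
        noise_levels = c(0, 0.001, 0.01),
        durations = c(1, 3, 10),
        periods = c(25, 50, 100, 200, 400),
        on_off_ratio = NULL,
        n_replicates = 1000, n_batches = 10, n_signals = 200,
        n_bins = 8, seed = 1))

.EXPERIMENT_TYPES <- c("simulate", "mi-sweep", "ec-sweep", "duration-sweep",
                       "sf-curve")

#' Load and validate an experiment configuration
#'
#' Reads a YAML configuration with sections \code{signal}, \code{model} and
#' \code{experiment}, validates every field against the schema (unknown keys
#' are rejected; every violation is reported at once), and fills documented
#' defaults.  Shipped example configurations live under
#' \code{system.file("extdata", package = "PulseDecode")}.
#'
#' @param path path to a YAML file.
#' @return a validated configuration (a nested list of class
#'   \code{"PulseDecodeConfig"}).
#' @export
loadConfig <- function(path) {
    if (!file.exists(path)) stop("config file not found: ", path)
    raw <- yaml::read_yaml(path)
    errs <- character()
    out <- .CONFIG_SCHEMA
    for (sec in names(raw)) {
        if (!sec %in% names(.CONFIG_SCHEMA)) {
            errs <- c(errs, sprintf("unknown section '%s'", sec))
            next
        }
        for (key in names(raw[[sec]])) {
            if (!key %in% names(.CONFIG_SCHEMA[[sec]]))
                errs <- c(errs, sprintf("unknown key '%s.%s'", sec, key))
            else out[[sec]][key] <- raw[[sec]][key]
        }
    }
    # yaml returns mixed int/double sequences as lists; flatten numeric fields
    for (key in c("on_times", "noise_levels", "durations", "periods"))
        if (!is.null(out$experiment[[key]]))
            out$experiment[[key]] <- as.numeric(unlist(out$experiment[[key]]))
    sig <- out$signal
    if (is.null(sig$upper_mean) || is.null(sig$lower_mean)) {
        lev <- .defaultLevels(if (identical(sig$regulation, "degradation"))
                              "degradation" else "transcription")
        if (is.null(sig$upper_mean)) out$signal$upper_mean <- lev[["upper"]]
        if (is.null(sig$lower_mean)) out$signal$lower_mean <- lev[["lower"]]
    }
    sig <- out$signal
    if (!is.numeric(sig$upper_mean) || !is.numeric(sig$lower_mean) ||
        sig$upper_mean <= sig$lower_mean)
        errs <- c(errs, "signal: need numeric upper_mean > lower_mean")
    for (k in c("on_time_mean", "off_time_mean", "duration"))
        if (!is.numeric(sig[[k]]) || sig[[k]] <= 0)
            errs <- c(errs, sprintf("signal.%s must be a positive number", k))
    for (k in c("amplitude_var", "frequency_noise"))
        if (!is.numeric(sig[[k]]) || sig[[k]] < 0)
            errs <- c(errs, sprintf("signal.%s must be non-negative", k))
    if (!sig$regulation %in% .REGULATIONS)
        errs <- c(errs, "signal.regulation must be transcription|degradation")
    if (!sig$modulation %in% .MODULATIONS)
        errs <- c(errs, "signal.modulation must be AM|FM")
    if (!sig$noise_family %in% .NOISE_FAMILY)
        errs <- c(errs, "signal.noise_family must be lognormal|gamma")
    if (!out$experiment$type %in% .EXPERIMENT_TYPES)
        errs <- c(errs, sprintf("experiment.type must be one of: %s",
                                paste(.EXPERIMENT_TYPES, collapse = ", ")))
    if (!is.null(out$model$target_mean) && !is.null(out$model$fixed_rate))
        errs <- c(errs, "model: give target_mean or fixed_rate, not both")
    if (length(errs))
        stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "))
    structure(out, class = "PulseDecodeConfig")
}

#' @rdname loadConfig
#' @param config a \code{PulseDecodeConfig}.
#' @export
writeConfig <- function(config, path) {
    yaml::write_yaml(unclass(config), path)
    invisible(path)
}

#' Run the experiment described by a configuration
#'
#' Dispatches on \code{config$experiment$type}: \code{"mi-sweep"} and
#' \code{"ec-sweep"} run [sweepOnOff()] (both quantities are always
#' computed), \code{"duration-sweep"} runs [sweepDuration()],
#' \code{"sf-curve"} runs [sfCurve()], and \code{"simulate"} returns one
#' replicate ensemble under a fresh signal realization.
#'
#' @param config a configuration from [loadConfig()].
#' @param seed optional override of \code{config$experiment$seed}.
#' @param nReplicates optional override of \code{config$experiment$n_replicates}.
#' @return the result object of the dispatched pipeline.
#' @export
runExperiment <- function(config, seed = NULL, nReplicates = NULL) {
    stopifnot(inherits(config, "PulseDecodeConfig"))
    sig <- config$signal; mod <- config$model; exp <- config$experiment
    if (is.null(seed)) seed <- exp$seed
    if (is.null(nReplicates)) nReplicates <- exp$n_replicates
    common <- list(regulation = sig$regulation, period = exp$period,
                   nReplicates = nReplicates, nBatches = exp$n_batches,
                   seed = seed, targetMean = mod$target_mean,
                   fixedRate = mod$fixed_rate, upperMean = sig$upper_mean,
                   lowerMean = sig$lower_mean,
                   burnInCycles = mod$burn_in_cycles,
                   measurePeriods = mod$measure_periods,
                   sampleDt = mod$sample_dt, nBins = exp$n_bins,
                   noiseFamily = sig$noise_family)
    switch(exp$type,
        "mi-sweep" = ,
        "ec-sweep" = do.call(sweepOnOff, c(list(onTimes = exp$on_times,
            noiseLevels = exp$noise_levels, modulation = sig$modulation),
            common)),
        "duration-sweep" = do.call(sweepDuration, c(list(
            durations = exp$durations, onTimes = exp$on_times,
            amplitudeVar = sig$amplitude_var), common)),
        "sf-curve" = sfCurve(periods = exp$periods,
            noiseLevels = exp$noise_levels, modulation = sig$modulation,
            regulation = sig$regulation,
            onOffRatio = if (is.null(exp$on_off_ratio)) {
                if (sig$modulation == "AM") 0.25 else 1
            } else exp$on_off_ratio,
            nSignals = exp$n_signals, seed = seed,
            fixedRate = mod$fixed_rate, upperMean = sig$upper_mean,
            lowerMean = sig$lower_mean, duration = sig$duration,
            burnInCycles = mod$burn_in_cycles,
            noiseFamily = sig$noise_family),
        "simulate" = {
            Tper <- sig$on_time_mean + sig$off_time_mean
            tot <- (mod$burn_in_cycles + mod$measure_periods) * Tper
            params <- signalParams(upperMean = sig$upper_mean,
                lowerMean = sig$lower_mean, onTimeMean = sig$on_time_mean,
                offTimeMean = sig$off_time_mean,
                amplitudeVar = sig$amplitude_var,
                frequencyNoise = sig$frequency_noise,
                duration = sig$duration, totalTime = tot,
                regulation = sig$regulation, modulation = sig$modulation,
                noiseFamily = sig$noise_family)
            kFree <- if (!is.null(mod$target_mean))
                calibrateMeanOutput(params, mod$target_mean)
            else if (!is.null(mod$fixed_rate)) mod$fixed_rate
            else .defaultFixedRate(sig$regulation)
            s <- makeSignal(params, .childSeed(seed, 1L))
            rs <- .rates(s, kFree)
            cfg <- modelConfig(rs$birth, rs$death, m0 = mod$m0, tMax = tot,
                               burnIn = mod$burn_in_cycles * Tper,
                               sampleDt = mod$sample_dt)
            simulateEnsemble(cfg, nReplicates, .childSeed(seed, 2L))
        })
}

# ---- result writers -------------------------------------------------------

.updateManifest <- function(outDir, files, seed = NULL) {
    mf <- file.path(outDir, "manifest.json")
    man <- if (file.exists(mf)) jsonlite::read_json(mf) else
        list(package = "PulseDecode",
             version = as.character(packageVersion("PulseDecode")),
             files = list())
    for (f in files)
        man$files[[basename(f)]] <- list(
            md5 = unname(tools::md5sum(f)),
            bytes = unname(file.size(f)))
    if (!is.null(seed)) man$seed <- seed
    jsonlite::write_json(man, mf, auto_unbox = TRUE, pretty = TRUE)
    invisible(mf)
}

#' Write a result object to disk
#'
#' Serializes sweep tables ([sweepOnOff()] and friends), [ECSeries-class]
#' and [EnsembleDistribution-class] objects as CSV files with a stable
#' column order, and records each file (with its MD5 checksum) plus the
#' generating seed in \code{manifest.json} inside \code{outDir}.  Re-running
#' with identical inputs reproduces byte-identical files.
#'
#' @param result the object to write.
#' @param outDir output directory (created if needed).
#' @param name base file name without extension (default chosen by type).
#' @return invisibly, the path(s) written.
#' @export
writeResults <- function(result, outDir, name = NULL) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    if (is.data.frame(result)) {
        if (is.null(name)) name <- "sweep"
        path <- file.path(outDir, paste0(name, ".csv"))
        write.csv(result, path, row.names = FALSE, quote = FALSE)
    } else if (is(result, "ECSeries")) {
        if (is.null(name)) name <- "ec_series"
        path <- file.path(outDir, paste0(name, ".csv"))
        df <- data.frame(time = result@times, sigma = result@sigma)
        write.csv(df, path, row.names = FALSE, quote = FALSE)
    } else if (is(result, "EnsembleDistribution")) {
        if (is.null(name)) name <- "ensemble_pmf"
        path <- file.path(outDir, paste0(name, ".csv"))
        pm <- pmfMatrix(result)
        df <- data.frame(
            time = rep(result@times, each = nrow(pm)),
            m = rep.int(as.integer(rownames(pm)), ncol(pm)),
            probability = as.vector(pm))
        df <- df[df$probability > 0, ]
        write.csv(df, path, row.names = FALSE, quote = FALSE)
    } else stop("unsupported result type: ", class(result)[1L])
    .updateManifest(outDir, path, seed = attr(result, "seed"))
    invisible(path)
}
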