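# --- sweep pipelines: ON/OFF grids, duration effects, stochastic focusing ---

.defaultLevels <- function(regulation) {
    if (regulation == "transcription") c(upper = 0.8, lower = 0.1)
    else c(upper = 0.1, lower = 0.025)
}

.defaultFixedRate <- function(regulation) {
    if (regulation == "transcription") 0.05 else 0.5
}

#' Calibrate the free constant rate to a target mean output
#'
#' The figures' "mean output fixed at 15" normalization: with the pulsatile
#' rate given by \code{params}, sets the free constant rate (the death rate
#' under transcription regulation, the birth rate under degradation
#' regulation) so that the periodic steady-state cycle mean of the noiseless
#' skeleton equals \code{targetMean}.  Under transcription regulation this is
#' the closed form \eqn{k_d = \langle k_b \rangle / target}; under
#' degradation regulation the cycle mean is proportional to \eqn{k_b}, so
#' the constant rescales exactly.  The result is verified by re-evaluating
#' [cycleMean()] to relative tolerance 1e-6.
#'
#' @param params a [SignalParams-class] describing the pulsatile rate.
#' @param targetMean desired cycle-averaged mean copy number (> 0).
#' @return the calibrated free constant rate.
#' @examples
#' calibrateMeanOutput(signalParams(), 15)   # 0.45 / 15 = 0.03
#' @export
calibrateMeanOutput <- function(params, targetMean) {
    stopifnot(is(params, "SignalParams"))
    if (!is.finite(targetMean) || targetMean <= 0)
        stop("targetMean must be positive")
    bw <- .branchWidths(params)
    if (params@regulation == "transcription") {
        meanKb <- (params@upperMean * bw[["upper"]] +
                   params@lowerMean * bw[["lower"]]) / sum(bw)
        rate <- meanKb / targetMean
        achieved <- cycleMean(params, rate)
    } else {
        rate <- targetMean / cycleMean(1, params)
        achieved <- cycleMean(rate, params)
    }
    if (abs(achieved - targetMean) > 1e-6 * targetMean)
        stop(sprintf("calibration failed: achieved %.8g, target %.8g",
                     achieved, targetMean))
    unname(rate)
}

# Build birth/death schedules for a realized signal under the regulation
# mode of its parameters.
.rates <- function(signal, kFree) {
    if (signal@params@regulation == "transcription")
        list(birth = signal, death = kFree)
    else
        list(birth = kFree, death = signal)
}

# One sweep grid point: nBatches independent signal realizations, each with
# its own replicate ensemble.  MI pairs the binned instantaneous input level
# with the output count at the same sample instant, pooled over the batch's
# replicates and post-burn-in times; EC uses the exact conditional Poisson
# law along the realized signal.  Standard errors are across batches.
.sweepPoint <- function(params, kFree, nBatches, repsPerBatch, seed,
                        burnInCycles, measurePeriods, sampleDt, nBins,
                        miCorrection = "none") {
    Tper <- signalPeriod(params)
    tMax <- (burnInCycles + measurePeriods) * Tper
    params@totalTime <- tMax
    burnIn <- burnInCycles * Tper
    mi <- ec <- mo <- numeric(nBatches)
    for (b in seq_len(nBatches)) {
        sig <- makeSignal(params, .childSeed(seed, b))
        rs <- .rates(sig, kFree)
        cfg <- modelConfig(rs$birth, rs$death, tMax = tMax, burnIn = burnIn,
                           sampleDt = sampleDt)
        ens <- simulateEnsemble(cfg, repsPerBatch, .childSeed(seed, 10000L + b))
        times <- sampleTimes(ens)
        ec[b] <- ecTimeAverage(ecFromRates(rs$birth, rs$death, times))
        xs <- .autoBin(signalValueAt(sig, times), nBins)
        counts <- countsMatrix(ens)
        mi[b] <- estimateMI(rep(xs, each = nrow(counts)), as.vector(counts),
                            correction = miCorrection)
        mo[b] <- mean(counts)
    }
    se <- function(x) sd(x) / sqrt(length(x))
    c(mi = mean(mi), mi_se = se(mi), ec = mean(ec), ec_se = se(ec),
      mean_output = mean(mo), mean_output_se = se(mo))
}

.sweepParams <- function(onTime, period, noise, modulation, regulation,
                         levels, duration, noiseFamily) {
    signalParams(upperMean = levels[["upper"]], lowerMean = levels[["lower"]],
                 onTimeMean = onTime, offTimeMean = period - onTime,
                 amplitudeVar = if (modulation == "AM") noise else 0,
                 frequencyNoise = if (modulation == "FM") noise else 0,
                 duration = duration, totalTime = period,
                 regulation = regulation, modulation = modulation,
                 noiseFamily = noiseFamily)
}

#' ON/OFF-time sweep of mutual information and energetic cost
#'
#' For every combination of ON-time (OFF-time is \code{period - onTime}) and
#' input-noise level, realizes the signal, simulates replicate ensembles,
#' and reports the plug-in mutual information between the instantaneous
#' input level and the output count (bits), the time-averaged entropy
#' production rate, and the mean output, each with standard errors over
#' \code{nBatches} independent signal realizations.
#'
#' @param onTimes grid of ON-times (seconds), strictly inside
#'   \code{(0, period)}.
#' @param noiseLevels AM variances ("Var") or FM width CV-squared values
#'   ("Noise"), depending on \code{modulation}.
#' @param modulation \code{"AM"} or \code{"FM"}.
#' @param regulation \code{"transcription"} or \code{"degradation"}.
#' @param period the fixed signal period T (default 200 s).
#' @param nReplicates total replicate trajectories per grid point (split
#'   over batches).
#' @param nBatches independent signal realizations per grid point used for
#'   error bars (default 10).
#' @param seed root integer seed; every signal and ensemble stream is
#'   derived from it.
#' @param targetMean calibrate the free constant rate so the noiseless cycle
#'   mean equals this value (default 15); set \code{NULL} to use
#'   \code{fixedRate} instead.
#' @param fixedRate free constant rate used when \code{targetMean} is NULL
#'   (defaults: death 0.05 under transcription regulation, birth 0.5 under
#'   degradation regulation).
#' @param upperMean,lowerMean branch means; defaults 0.8/0.1 under
#'   transcription regulation and 0.1/0.025 under degradation regulation.
#' @param duration AM noise refresh interval D (default 3 s).
#' @param burnInCycles discarded periods before statistics (default 5).
#' @param measurePeriods measured periods per realization (default 4).
#' @param sampleDt sampling interval (default 1 s).
#' @param nBins input bins for AM mutual information (default 8; inputs
#'   with few distinct levels, e.g. FM or noiseless signals, are treated as
#'   discrete symbols).
#' @param noiseFamily noise distribution family.
#' @return a data.frame with one row per (onTime, noise) and columns
#'   \code{on_time}, \code{off_time}, \code{noise}, \code{mi}, \code{mi_se},
#'   \code{ec}, \code{ec_se}, \code{mean_output}, \code{mean_output_se},
#'   \code{free_rate}; the call's seed and settings are kept in attributes
#'   \code{seed} and \code{settings}.
#' @examples
#' \donttest{
#' sw <- sweepOnOff(c(60, 100, 140), 0, nReplicates = 60, seed = 1)
#' }
#' @export
sweepOnOff <- function(onTimes, noiseLevels,
                       modulation = c("AM", "FM"),
                       regulation = c("transcription", "degradation"),
                       period = 200, nReplicates = 1000, nBatches = 10,
                       seed = 1, targetMean = 15, fixedRate = NULL,
                       upperMean = NULL, lowerMean = NULL, duration = 3,
                       burnInCycles = 5, measurePeriods = 4, sampleDt = 1,
                       nBins = 8,
                       noiseFamily = c("lognormal", "gamma")) {
    modulation <- match.arg(modulation)
    regulation <- match.arg(regulation)
    noiseFamily <- match.arg(noiseFamily)
    stopifnot(all(onTimes > 0 & onTimes < period))
    levels <- .defaultLevels(regulation)
    if (!is.null(upperMean)) levels[["upper"]] <- upperMean
    if (!is.null(lowerMean)) levels[["lower"]] <- lowerMean
    repsPerBatch <- max(2L, as.integer(round(nReplicates / nBatches)))
    grid <- expand.grid(on_time = onTimes, noise = noiseLevels,
                        KEEP.OUT.ATTRS = FALSE)
    rows <- lapply(seq_len(nrow(grid)), function(i) {
        params <- .sweepParams(grid$on_time[i], period, grid$noise[i],
                               modulation, regulation, levels, duration,
                               noiseFamily)
        kFree <- if (!is.null(targetMean)) calibrateMeanOutput(params, targetMean)
                 else if (!is.null(fixedRate)) fixedRate
                 else .defaultFixedRate(regulation)
        stats <- .sweepPoint(params, kFree, nBatches, repsPerBatch,
                             .childSeed(seed, 1000L * i), burnInCycles,
                             measurePeriods, sampleDt, nBins)
        data.frame(on_time = grid$on_time[i],
                   off_time = period - grid$on_time[i],
                   noise = grid$noise[i], t(stats), free_rate = kFree)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "seed") <- seed
    attr(out, "settings") <- list(modulation = modulation,
        regulation = regulation, period = period, nReplicates = nReplicates,
        nBatches = nBatches, targetMean = targetMean, duration = duration,
        levels = levels, burnInCycles = burnInCycles,
        measurePeriods = measurePeriods, sampleDt = sampleDt, nBins = nBins,
        noiseFamily = noiseFamily)
    out
}

#' Signal-duration sweep
#'
#' MI and EC per (ON-time, duration D) point for an AM signal with fixed
#' amplitude variance: larger D means the amplitude noise refreshes less
#' often, i.e. a more slowly fluctuating input.
#'
#' @param durations grid of noise refresh intervals D (seconds, > 0).
#' @param onTimes ON-time grid (seconds).
#' @param amplitudeVar fixed AM variance (default 0.01).
#' @inheritParams sweepOnOff
#' @return a data.frame as in [sweepOnOff()] plus a \code{duration} column.
#' @export
sweepDuration <- function(durations, onTimes, amplitudeVar = 0.01,
                          regulation = c("transcription", "degradation"),
                          period = 200, nReplicates = 1000, nBatches = 10,
                          seed = 1, targetMean = 15, fixedRate = NULL,
                          upperMean = NULL, lowerMean = NULL,
                          burnInCycles = 5, measurePeriods = 4, sampleDt = 1,
                          nBins = 8,
                          noiseFamily = c("lognormal", "gamma")) {
    stopifnot(all(durations > 0))
    regulation <- match.arg(regulation)
    rows <- lapply(seq_along(durations), function(k) {
        sw <- sweepOnOff(onTimes, amplitudeVar, modulation = "AM",
                         regulation = regulation, period = period,
                         nReplicates = nReplicates, nBatches = nBatches,
                         seed = .childSeed(seed, 77L * k),
                         targetMean = targetMean, fixedRate = fixedRate,
                         upperMean = upperMean, lowerMean = lowerMean,
                         duration = durations[k], burnInCycles = burnInCycles,
                         measurePeriods = measurePeriods, sampleDt = sampleDt,
                         nBins = nBins, noiseFamily = noiseFamily)
        cbind(duration = durations[k], sw)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "seed") <- seed
    out
}

# Per-cycle means of mu over the cycles (pulse onset to next pulse onset)
# inside [from, to).  Cycle onsets are the starts of upper-branch runs.
.cycleMeansOfMu <- function(signal, kFree, from, to) {
    rs <- .rates(signal, kFree)
    runs <- .branchRuns(signal)
    onsets <- runs$start[runs$branch == "upper"]
    onsets <- onsets[onsets >= from & onsets < to]
    if (length(onsets) < 2L) return(numeric(0))
    sch <- .mergedSchedule(rs$birth, rs$death, to)
    muB <- .muAtBreaks(sch)
    intOver <- function(a, b) {
        tot <- 0
        for (i in seq_along(sch$breaks)) {
            lo <- max(a, sch$breaks[i]); hi <- min(b, sch$ends[i])
            if (hi <= lo) next
            mu_lo <- .propagateMu(muB[i], sch$kb[i], sch$kd[i],
                                  lo - sch$breaks[i])
            tot <- tot + .muSegIntegral(mu_lo, sch$kb[i], sch$kd[i], hi - lo)
        }
        tot
    }
    vapply(seq_len(length(onsets) - 1L), function(j)
        intOver(onsets[j], onsets[j + 1L]) / (onsets[j + 1L] - onsets[j]),
        numeric(1))
}

#' Stochastic-focusing curves
#'
#' Cycle-averaged mean output versus the signal period T, for several noise
#' levels, at a fixed ON/OFF-time ratio.  The mean output is computed from
#' the exact conditional mean \eqn{\mu(t)} of each realized signal: the
#' time average of \eqn{\mu} over each signal cycle (pulse onset to next
#' pulse onset) after burn-in, averaged unweighted across cycles and signal
#' realizations.  The SF index is the ratio of this mean to its zero-noise
#' value at the same T; noise-induced stochastic focusing shows as an index
#' above 1.
#'
#' @param periods grid of signal periods T (seconds).
#' @param noiseLevels noise levels (Var for AM, Noise for FM), including 0
#'   implicitly as the reference.
#' @param onOffRatio fixed ON-time/OFF-time ratio (0.25 for the AM setting,
#'   1 for the FM setting).
#' @param nSignals signal realizations averaged per point (default 200).
#' @inheritParams sweepOnOff
#' @return a data.frame with columns \code{period}, \code{noise},
#'   \code{mean_output}, \code{mean_output_se}, \code{window_mean},
#'   \code{sf_index}.
#' @export
sfCurve <- function(periods, noiseLevels,
                    modulation = c("AM", "FM"),
                    regulation = c("transcription", "degradation"),
                    onOffRatio = if (match.arg(modulation) == "AM") 0.25 else 1,
                    nSignals = 200, seed = 1, fixedRate = NULL,
                    upperMean = NULL, lowerMean = NULL, duration = 3,
                    burnInCycles = 5, measurePeriods = 8,
                    noiseFamily = c("lognormal", "gamma")) {
    modulation <- match.arg(modulation)
    regulation <- match.arg(regulation)
    noiseFamily <- match.arg(noiseFamily)
    stopifnot(onOffRatio > 0, all(periods > 0))
    levels <- .defaultLevels(regulation)
    if (!is.null(upperMean)) levels[["upper"]] <- upperMean
    if (!is.null(lowerMean)) levels[["lower"]] <- lowerMean
    kFree <- if (is.null(fixedRate)) .defaultFixedRate(regulation) else fixedRate
    noiseLevels <- sort(unique(c(0, noiseLevels)))
    rows <- list()
    ref <- setNames(rep(NA_real_, length(periods)), periods)
    for (Tper in periods) {
        onT <- Tper * onOffRatio / (1 + onOffRatio)
        for (v in noiseLevels) {
            params <- .sweepParams(onT, Tper, v, modulation, regulation,
                                   levels, duration, noiseFamily)
            tMax <- (burnInCycles + measurePeriods) * Tper
            params@totalTime <- tMax
            from <- burnInCycles * Tper
            nDraw <- if (v == 0) 1L else nSignals
            perDraw <- winDraw <- numeric(nDraw)
            for (s in seq_len(nDraw)) {
                sig <- makeSignal(params,
                                  .childSeed(seed, 131L * match(Tper, periods) +
                                                   7919L * match(v, noiseLevels) + s))
                cm <- .cycleMeansOfMu(sig, kFree, from, tMax)
                rs <- .rates(sig, kFree)
                winDraw[s] <- .muIntegral(rs$birth, rs$death, from, tMax) /
                              (tMax - from)
                perDraw[s] <- if (length(cm)) mean(cm) else winDraw[s]
            }
            mo <- mean(perDraw)
            if (v == 0) ref[as.character(Tper)] <- mo
            rows[[length(rows) + 1L]] <- data.frame(
                period = Tper, noise = v, mean_output = mo,
                mean_output_se = if (nDraw > 1L) sd(perDraw) / sqrt(nDraw) else 0,
                window_mean = mean(winDraw),
                sf_index = mo / ref[as.character(Tper)])
        }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "seed") <- seed
    attr(out, "settings") <- list(modulation = modulation,
        regulation = regulation, onOffRatio = onOffRatio, levels = levels,
        fixedRate = kFree, duration = duration, nSignals = nSignals)
    out
}

#' Correlation between mutual information and energetic cost
#'
#' Pearson correlation of the (MI, EC) pairs across the grid points of a
#' sweep result, the quantity behind the information-energy trade-off plots.
#'
#' @param sweep a data.frame from [sweepOnOff()] (or any data.frame with
#'   \code{mi} and \code{ec} columns), with at least 3 rows.
#' @return the Pearson correlation coefficient.
#' @export
miEcCorrelation <- function(sweep) {
    stopifnot(is.data.frame(sweep), all(c("mi", "ec") %in% names(sweep)))
    if (nrow(sweep) < 3L) stop("need at least 3 grid points")
    if (sd(sweep$mi) == 0 || sd(sweep$ec) == 0)
        stop("correlation undefined: constant MI or EC column")
    cor(sweep$mi, sweep$ec)
}
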