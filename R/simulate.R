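# Decompose a rate schedule into (breaks, levels) covering [0, tMax].
.schedule <- function(x, tMax) {
    if (is.numeric(x)) return(list(breaks = 0, levels = unname(x)))
    if (x@totalTime < tMax) stop("signal shorter than requested horizon")
    list(breaks = x@start, levels = x@level)
}

#' Construct a simulation configuration
#'
#' @param birth transcription-rate schedule: positive constant or
#'   [PulseSignal-class].
#' @param death per-molecule degradation-rate schedule.
#' @param m0 initial copy number (default 0).
#' @param tMax time horizon; defaults to the realized length of the pulsatile
#'   rate (or 1000 s when both rates are constant).
#' @param burnIn seconds discarded before statistics; default
#'   \code{burnInCycles} signal periods, or \eqn{10/k_d} for constant rates.
#' @param burnInCycles periods of burn-in used when \code{burnIn} is not
#'   given (default 5).
#' @param sampleDt sampling grid spacing (default 1 s).
#' @return a validated [ModelConfig-class].
#' @examples
#' sig <- makeSignal(signalParams(totalTime = 1400))
#' cfg <- modelConfig(birth = sig, death = 0.05)
#' @export
modelConfig <- function(birth, death, m0 = 0L, tMax = NULL, burnIn = NULL,
                        burnInCycles = 5, sampleDt = 1) {
    pulse <- if (is(birth, "PulseSignal")) birth
             else if (is(death, "PulseSignal")) death
    if (is.null(tMax))
        tMax <- if (is.null(pulse)) 1000 else totalTime(pulse)
    if (is.null(burnIn)) {
        burnIn <- if (!is.null(pulse)) {
            burnInCycles * signalPeriod(pulse)
        } else 10 / death
        burnIn <- min(burnIn, tMax / 2)
    }
    new("ModelConfig", birth = birth, death = death, m0 = as.integer(m0),
        tMax = tMax, burnIn = burnIn, sampleDt = sampleDt)
}

setMethod("show", "ModelConfig", function(object) {
    fmt <- function(x)
        if (is.numeric(x)) sprintf("constant %.4g", x)
        else sprintf("%s pulse signal (%d segments)",
                     x@params@modulation, length(x@start))
    cat("ModelConfig\n")
    cat("  birth:", fmt(object@birth), "\n")
    cat("  death:", fmt(object@death), "\n")
    cat(sprintf("  m0 = %d, tMax = %.4g s, burnIn = %.4g s, sampleDt = %.4g s\n",
                object@m0, object@tMax, object@burnIn, object@sampleDt))
})

#' Simulate one exact trajectory of the birth-death process
#'
#' Draws a statistically exact sample path of the non-homogeneous process
#' \eqn{\emptyset \to mRNA} at rate \eqn{k_b(t)}, \eqn{mRNA \to \emptyset} at
#' rate \eqn{k_d(t) m}, for piecewise-constant rate schedules.  Waiting times
#' are exponential at the current total propensity; draws that overshoot the
#' next rate breakpoint advance the clock to the breakpoint and are re-drawn,
#' which is exact by memorylessness within each constant-rate window.
#'
#' @param config a [ModelConfig-class].
#' @param seed optional integer seed (caller RNG state preserved).
#' @param sampleAt sampling grid; default
#'   \code{seq(0, tMax, by = sampleDt)}.
#' @param keepEvents keep the full event list (default TRUE).
#' @return a [Trajectory-class].
#' @examples
#' cfg <- modelConfig(birth = 0.5, death = 0.05, tMax = 500)
#' tr <- simulateTrajectory(cfg, seed = 1)
#' mean(sampledCounts(tr)[sampleTimes(tr) > 200])   # near 10 = kb/kd
#' @export
simulateTrajectory <- function(config, seed = NULL, sampleAt = NULL,
                               keepEvents = TRUE) {
    validObject(config)
    if (is.null(sampleAt))
        sampleAt <- seq(0, config@tMax, by = config@sampleDt)
    if (any(sampleAt < 0 | sampleAt > config@tMax))
        stop("sampling times outside [0, tMax]")
    b <- .schedule(config@birth, config@tMax)
    d <- .schedule(config@death, config@tMax)
    res <- .withSeed(seed,
        simulate_bd_cpp(b$breaks, b$levels, d$breaks, d$levels,
                        config@m0, config@tMax, sampleAt, keepEvents))
    new("Trajectory", eventTimes = res$event_times,
        eventDeltas = as.integer(res$event_deltas), m0 = config@m0,
        tMax = config@tMax, sampledTimes = sampleAt,
        sampledCounts = as.integer(res$sampled_counts))
}

#' @rdname Trajectory-class
#' @export
setMethod("eventTimes", "Trajectory", function(x) x@eventTimes)
#' @rdname Trajectory-class
#' @export
setMethod("eventDeltas", "Trajectory", function(x) x@eventDeltas)
#' @rdname Trajectory-class
#' @export
setMethod("sampledCounts", "Trajectory", function(x) x@sampledCounts)
#' @rdname Trajectory-class
#' @export
setMethod("sampleTimes", "Trajectory", function(x) x@sampledTimes)

setMethod("show", "Trajectory", function(object) {
    cat(sprintf("Trajectory: %d events over [0, %.4g] s, m0 = %d\n",
                length(object@eventTimes), object@tMax, object@m0))
})

#' Re-sample a trajectory at arbitrary times
#'
#' Right-continuous piecewise-constant interpolation of the event path: a
#' query at an event time sees the post-event copy number.
#'
#' @param trajectory a [Trajectory-class].
#' @param times numeric vector within \eqn{[0, tMax]}.
#' @return integer copy numbers.
#' @export
sampleStates <- function(trajectory, times) {
    stopifnot(is(trajectory, "Trajectory"))
    if (any(times < 0 | times > trajectory@tMax))
        stop("times outside [0, tMax]")
    counts <- trajectory@m0 + cumsum(trajectory@eventDeltas)
    idx <- findInterval(times, trajectory@eventTimes)
    as.integer(ifelse(idx == 0L, trajectory@m0, counts[pmax(idx, 1L)]))
}

#' Simulate an ensemble of replicate trajectories
#'
#' Runs \code{nReplicates} independent trajectories that all share the rate
#' schedules in \code{config} (one realization of the input signal), and
#' collects the copy numbers on the post-burn-in sampling grid.  The per-time
#' empirical pmf (see [pmfMatrix()]) estimates the conditional law
#' \eqn{P(m, t)} given the signal realization.
#'
#' @param config a [ModelConfig-class].
#' @param nReplicates number of replicates (>= 2).
#' @param seed optional integer seed.
#' @return an [EnsembleDistribution-class].
#' @examples
#' sig <- makeSignal(signalParams(totalTime = 1400))
#' ens <- simulateEnsemble(modelConfig(sig, 0.05), 50, seed = 1)
#' @export
simulateEnsemble <- function(config, nReplicates, seed = NULL) {
    validObject(config)
    if (nReplicates < 2L) stop("nReplicates must be >= 2")
    times <- seq(config@burnIn, config@tMax - config@sampleDt,
                 by = config@sampleDt)
    b <- .schedule(config@birth, config@tMax)
    d <- .schedule(config@death, config@tMax)
    counts <- .withSeed(seed, {
        out <- matrix(0L, nrow = nReplicates, ncol = length(times))
        for (r in seq_len(nReplicates)) {
            res <- simulate_bd_cpp(b$breaks, b$levels, d$breaks, d$levels,
                                   config@m0, config@tMax, times, FALSE)
            out[r, ] <- res$sampled_counts
        }
        out
    })
    new("EnsembleDistribution", times = times, counts = counts,
        config = config)
}

#' @rdname EnsembleDistribution-class
#' @export
setMethod("sampleTimes", "EnsembleDistribution", function(x) x@times)
#' @rdname EnsembleDistribution-class
#' @export
setMethod("countsMatrix", "EnsembleDistribution", function(x) x@counts)
#' @rdname EnsembleDistribution-class
#' @export
setMethod("nReplicates", "EnsembleDistribution", function(x) nrow(x@counts))

#' @rdname pmfMatrix
#' @export
setMethod("pmfMatrix", "EnsembleDistribution", function(x, mMax = NULL) {
    if (is.null(mMax)) mMax <- max(x@counts)
    n <- nrow(x@counts)
    pm <- vapply(seq_along(x@times), function(j)
        tabulate(x@counts[, j] + 1L, nbins = mMax + 1L) / n,
        numeric(mMax + 1L))
    dimnames(pm) <- list(m = 0:mMax, NULL)
    pm
})

setMethod("show", "EnsembleDistribution", function(object) {
    cat(sprintf(
        "EnsembleDistribution: %d replicates x %d times on [%.4g, %.4g] s\n",
        nrow(object@counts), length(object@times), min(object@times),
        max(object@times)))
})
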