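#' @useDynLib PulseDecode, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
#' @importFrom stats dpois qpois quantile rlnorm rgamma cor sd var setNames
#' @importFrom tools md5sum
#' @importFrom utils packageVersion read.table write.csv head tail
NULL

.REGULATIONS  <- c("transcription", "degradation")
.MODULATIONS  <- c("AM", "FM")
.NOISE_FAMILY <- c("lognormal", "gamma")

#' Parameters of a pulsatile input signal
#'
#' Describes a two-level (square-wave) transcription-factor signal that drives
#' either the transcription rate \eqn{k_b(t)} or the per-molecule degradation
#' rate \eqn{k_d(t)} of a downstream gene.  The signal alternates between an
#' upper and a lower branch; noise enters either through the amplitude
#' (AM: branch levels re-sampled every \code{duration} seconds from a
#' moment-matched log-normal or gamma distribution with variance
#' \code{amplitudeVar}) or through the timing (FM: branch widths sampled with
#' squared coefficient of variation \code{frequencyNoise}).
#'
#' The "ON" branch is the one producing high mRNA: the upper branch under
#' transcription regulation, the lower branch under degradation regulation
#' (a small degradation rate means slow decay, hence high mRNA).
#' \code{onTimeMean}/\code{offTimeMean} are therefore mapped to branch widths
#' according to \code{regulation}.
#'
#' @slot upperMean,lowerMean mean rate levels of the two branches
#'   (dimensionless rate units per second); \code{upperMean > lowerMean > 0}.
#' @slot onTimeMean,offTimeMean mean widths (seconds) of the ON and OFF
#'   phases; the period is their sum.
#' @slot amplitudeVar variance of the AM amplitude noise (squared rate units).
#' @slot frequencyNoise squared coefficient of variation of FM branch widths.
#' @slot duration refresh interval D (seconds) of the AM amplitude noise:
#'   within a branch the level is re-drawn every \code{duration} seconds, so a
#'   larger D means a more slowly fluctuating input.
#' @slot totalTime length (seconds) of signal to realize.
#' @slot regulation \code{"transcription"} or \code{"degradation"}.
#' @slot modulation \code{"AM"} or \code{"FM"}.
#' @slot noiseFamily \code{"lognormal"} (default) or \code{"gamma"}; both are
#'   parameterized by matching the requested mean and variance exactly.
#' @seealso [signalParams()], [makeSignal()]
#' @export
setClass("SignalParams",
    representation(upperMean = "numeric", lowerMean = "numeric",
                   onTimeMean = "numeric", offTimeMean = "numeric",
                   amplitudeVar = "numeric", frequencyNoise = "numeric",
                   duration = "numeric", totalTime = "numeric",
                   regulation = "character", modulation = "character",
                   noiseFamily = "character"),
    prototype(upperMean = 0.8, lowerMean = 0.1, onTimeMean = 100,
              offTimeMean = 100, amplitudeVar = 0, frequencyNoise = 0,
              duration = 3, totalTime = 2000, regulation = "transcription",
              modulation = "AM", noiseFamily = "lognormal"))

setValidity("SignalParams", function(object) {
    msg <- character()
    num1 <- function(x) length(x) == 1L && is.finite(x)
    for (s in c("upperMean", "lowerMean", "onTimeMean", "offTimeMean",
                "amplitudeVar", "frequencyNoise", "duration", "totalTime"))
        if (!num1(slot(object, s)))
            msg <- c(msg, sprintf("'%s' must be a finite scalar", s))
    if (length(msg)) return(msg)
    if (!(object@upperMean > object@lowerMean && object@lowerMean > 0))
        msg <- c(msg, "need upperMean > lowerMean > 0")
    if (object@onTimeMean <= 0 || object@offTimeMean <= 0)
        msg <- c(msg, "onTimeMean and offTimeMean must be > 0")
    if (object@duration <= 0) msg <- c(msg, "duration must be > 0")
    if (object@totalTime <= 0) msg <- c(msg, "totalTime must be > 0")
    if (object@amplitudeVar < 0) msg <- c(msg, "amplitudeVar must be >= 0")
    if (object@frequencyNoise < 0) msg <- c(msg, "frequencyNoise must be >= 0")
    if (!object@regulation %in% .REGULATIONS)
        msg <- c(msg, "regulation must be 'transcription' or 'degradation'")
    if (!object@modulation %in% .MODULATIONS)
        msg <- c(msg, "modulation must be 'AM' or 'FM'")
    if (!object@noiseFamily %in% .NOISE_FAMILY)
        msg <- c(msg, "noiseFamily must be 'lognormal' or 'gamma'")
    if (length(msg)) msg else TRUE
})

#' A realized piecewise-constant rate schedule
#'
#' One realization of a pulsatile input signal: an ordered set of half-open
#' segments \eqn{[start_i, start_{i+1})} covering \eqn{[0, totalTime)}, each
#' with a constant positive rate level and a branch label
#' (\code{"upper"}/\code{"lower"}).
#'
#' @slot start segment start times; strictly increasing, first is 0.
#' @slot level rate level of each segment (all positive).
#' @slot branch branch label per segment.
#' @slot totalTime right end of the covered time domain.
#' @slot params the [SignalParams-class] the realization was drawn from.
#' @export
setClass("PulseSignal",
    representation(start = "numeric", level = "numeric", branch = "character",
                   totalTime = "numeric", params = "SignalParams"))

setValidity("PulseSignal", function(object) {
    msg <- character()
    n <- length(object@start)
    if (n == 0L) msg <- c(msg, "signal needs at least one segment")
    if (length(object@level) != n || length(object@branch) != n)
        msg <- c(msg, "start, level and branch must have equal length")
    if (length(msg)) return(msg)
    if (object@start[1L] != 0) msg <- c(msg, "first segment must start at 0")
    if (n > 1L && any(diff(object@start) <= 0))
        msg <- c(msg, "segment start times must be strictly increasing")
    if (any(object@level <= 0)) msg <- c(msg, "all levels must be positive")
    if (object@totalTime <= object@start[n])
        msg <- c(msg, "totalTime must exceed the last segment start")
    if (!all(object@branch %in% c("upper", "lower")))
        msg <- c(msg, "branch labels must be 'upper' or 'lower'")
    if (length(msg)) msg else TRUE
})

# Either a constant rate (numeric scalar) or a realized schedule.
#' @export
setClassUnion("RateSchedule", c("numeric", "PulseSignal"))

#' Configuration of one birth-death simulation
#'
#' @slot birth transcription-rate schedule: a constant rate or a
#'   [PulseSignal-class].
#' @slot death per-molecule degradation-rate schedule.
#' @slot m0 initial mRNA copy number.
#' @slot tMax simulated time horizon (seconds).
#' @slot burnIn time (seconds) discarded before any statistic; defaults to
#'   five signal periods (or ten relaxation times \eqn{10/k_d} when both
#'   rates are constant).
#' @slot sampleDt spacing (seconds) of the regular sampling grid.
#' @export
setClass("ModelConfig",
    representation(birth = "RateSchedule", death = "RateSchedule",
                   m0 = "integer", tMax = "numeric", burnIn = "numeric",
                   sampleDt = "numeric"))

setValidity("ModelConfig", function(object) {
    msg <- character()
    # a zero constant birth rate is allowed (pure-death validation runs);
    # the death rate must be strictly positive
    chk <- function(x, nm, lowest) {
        if (is.numeric(x)) {
            if (length(x) != 1L || !is.finite(x) || x < lowest ||
                (nm == "death" && x <= 0))
                return(sprintf("constant %s rate out of range", nm))
        } else if (x@totalTime < object@tMax)
            return(sprintf("%s signal is shorter than tMax", nm))
        NULL
    }
    msg <- c(msg, chk(object@birth, "birth", 0), chk(object@death, "death", 0))
    if (is(object@birth, "PulseSignal") && is(object@death, "PulseSignal"))
        msg <- c(msg, "at most one of birth/death may be a PulseSignal")
    if (object@m0 < 0L) msg <- c(msg, "m0 must be >= 0")
    if (object@tMax <= 0) msg <- c(msg, "tMax must be > 0")
    if (object@burnIn < 0 || object@burnIn >= object@tMax)
        msg <- c(msg, "burnIn must lie in [0, tMax)")
    if (object@sampleDt <= 0) msg <- c(msg, "sampleDt must be > 0")
    if (length(msg)) msg else TRUE
})

#' One stochastic mRNA trajectory
#'
#' @slot eventTimes times of birth/death events.
#' @slot eventDeltas +1 (birth) or -1 (death) per event.
#' @slot m0 initial copy number.
#' @slot tMax time horizon.
#' @slot sampledTimes regular sampling grid.
#' @slot sampledCounts copy number at each sampled time (right-continuous).
#' @export
setClass("Trajectory",
    representation(eventTimes = "numeric", eventDeltas = "integer",
                   m0 = "integer", tMax = "numeric",
                   sampledTimes = "numeric", sampledCounts = "integer"))

setValidity("Trajectory", function(object) {
    msg <- character()
    if (length(object@eventTimes) != length(object@eventDeltas))
        msg <- c(msg, "eventTimes and eventDeltas must have equal length")
    if (length(object@eventDeltas) && !all(abs(object@eventDeltas) == 1L))
        msg <- c(msg, "event deltas must be +1 or -1")
    if (length(object@eventTimes) > 1L && any(diff(object@eventTimes) < 0))
        msg <- c(msg, "event times must be non-decreasing")
    if (length(object@eventDeltas) &&
        min(object@m0 + cumsum(object@eventDeltas)) < 0L)
        msg <- c(msg, "copy number must never be negative")
    if (length(object@sampledCounts) && any(object@sampledCounts < 0L))
        msg <- c(msg, "sampled counts must be non-negative")
    if (length(msg)) msg else TRUE
})

#' Time-indexed empirical distribution over an ensemble of replicates
#'
#' Replicate trajectories share one realization of the input signal, so the
#' per-time empirical pmf estimates the conditional law \eqn{P(m, t)} given
#' the signal.
#'
#' @slot times sampling grid (after burn-in).
#' @slot counts integer matrix, replicates in rows, times in columns.
#' @slot config the [ModelConfig-class] used.
#' @export
setClass("EnsembleDistribution",
    representation(times = "numeric", counts = "matrix",
                   config = "ModelConfig"))

setValidity("EnsembleDistribution", function(object) {
    msg <- character()
    if (ncol(object@counts) != length(object@times))
        msg <- c(msg, "counts must have one column per time point")
    if (nrow(object@counts) < 2L)
        msg <- c(msg, "an ensemble needs at least 2 replicates")
    if (any(object@counts < 0))
        msg <- c(msg, "counts must be non-negative")
    if (length(msg)) msg else TRUE
})

#' Entropy-production-rate series
#'
#' Instantaneous entropy production rate \eqn{\sigma(t)} of the mRNA
#' birth-death chain (natural-log units, per second) along a sampling grid,
#' with its time average.
#'
#' @slot times sampling grid.
#' @slot sigma instantaneous entropy production rate at each time.
#' @slot timeAverage average of \code{sigma} over the grid.
#' @slot nReplicates replicates behind the pmf estimates (NA when the exact
#'   conditional Poisson law was used).
#' @export
setClass("ECSeries",
    representation(times = "numeric", sigma = "numeric",
                   timeAverage = "numeric", nReplicates = "numeric"))
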