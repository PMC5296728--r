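# Derive a reproducible child stream seed from a root seed.  Keeps results
# below 2^31 so the value is a valid R integer seed.
.childSeed <- function(seed, stream) {
    if (is.null(seed)) return(NULL)
    as.integer((as.double(seed) %% 2147483647 * 48271 + stream * 69621 + 1) %%
               2147483647)
}

.withSeed <- function(seed, expr) {
    if (is.null(seed)) return(eval.parent(substitute(expr)))
    has <- exists(".Random.seed", globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", globalenv())
    set.seed(seed)
    on.exit(if (has) assign(".Random.seed", old, globalenv())
            else rm(".Random.seed", envir = globalenv()))
    eval.parent(substitute(expr))
}

#' Construct signal parameters
#'
#' Convenience constructor for [SignalParams-class] with the package defaults:
#' a transcription-regulated amplitude-modulated signal with branch means
#' 0.8/0.1, period 200 s (equal ON/OFF times), noise refresh interval
#' D = 3 s and no noise.  For degradation regulation the conventional branch
#' means are 0.1/0.025.
#'
#' @param upperMean,lowerMean branch mean levels.
#' @param onTimeMean,offTimeMean mean ON/OFF phase widths (seconds).  ON is
#'   the phase producing high mRNA: upper branch for transcription
#'   regulation, lower branch for degradation regulation.
#' @param amplitudeVar AM amplitude variance ("Var").
#' @param frequencyNoise FM width CV-squared ("Noise").
#' @param duration AM noise refresh interval D (seconds).
#' @param totalTime realized signal length (seconds).
#' @param regulation \code{"transcription"} or \code{"degradation"}.
#' @param modulation \code{"AM"} or \code{"FM"}.
#' @param noiseFamily \code{"lognormal"} or \code{"gamma"}.
#' @return a validated [SignalParams-class].
#' @examples
#' signalParams(amplitudeVar = 0.01, totalTime = 1000)
#' @export
signalParams <- function(upperMean = 0.8, lowerMean = 0.1,
                         onTimeMean = 100, offTimeMean = 100,
                         amplitudeVar = 0, frequencyNoise = 0,
                         duration = 3, totalTime = 2000,
                         regulation = c("transcription", "degradation"),
                         modulation = c("AM", "FM"),
                         noiseFamily = c("lognormal", "gamma")) {
    new("SignalParams", upperMean = upperMean, lowerMean = lowerMean,
        onTimeMean = onTimeMean, offTimeMean = offTimeMean,
        amplitudeVar = amplitudeVar, frequencyNoise = frequencyNoise,
        duration = duration, totalTime = totalTime,
        regulation = match.arg(regulation),
        modulation = match.arg(modulation),
        noiseFamily = match.arg(noiseFamily))
}

#' Moment-matched positive samplers
#'
#' Returns a sampler \code{function(n)} over positive rates whose first
#' moment is exactly \code{mean} and whose variance is exactly
#' \code{variance}.  For the log-normal family the log-scale parameters are
#' \eqn{\sigma^2 = \log(1 + variance/mean^2)} and
#' \eqn{\mu = \log(mean) - \sigma^2/2}; for the gamma family shape
#' \eqn{= mean^2/variance} and rate \eqn{= mean/variance}.  Zero variance
#' returns a constant sampler.
#'
#' @param mean target mean (> 0).
#' @param variance target variance (>= 0).
#' @param family \code{"lognormal"} or \code{"gamma"}.
#' @return a function of \code{n} returning \code{n} positive draws.
#' @examples
#' s <- lognormalFromMoments(0.8, 0.01)
#' mean(s(1e4))
#' @export
momentSampler <- function(mean, variance,
                          family = c("lognormal", "gamma")) {
    if (!is.finite(mean) || mean <= 0)
        stop("'mean' must be a positive number")
    if (!is.finite(variance) || variance < 0)
        stop("'variance' must be non-negative")
    family <- match.arg(family)
    if (variance == 0) {
        force(mean)
        return(function(n) rep(mean, n))
    }
    if (family == "lognormal") {
        sdlog2 <- log(1 + variance / mean^2)
        meanlog <- log(mean) - sdlog2 / 2
        sdlog <- sqrt(sdlog2)
        function(n) rlnorm(n, meanlog = meanlog, sdlog = sdlog)
    } else {
        shape <- mean^2 / variance
        rate <- mean / variance
        function(n) rgamma(n, shape = shape, rate = rate)
    }
}

#' @rdname momentSampler
#' @export
lognormalFromMoments <- function(mean, variance)
    momentSampler(mean, variance, family = "lognormal")

#' @rdname momentSampler
#' @export
gammaFromMoments <- function(mean, variance)
    momentSampler(mean, variance, family = "gamma")

# Branch widths in construction order (upper first), honoring the ON/OFF
# mapping of the regulation mode.
.branchWidths <- function(params) {
    if (params@regulation == "transcription")
        c(upper = params@onTimeMean, lower = params@offTimeMean)
    else
        c(upper = params@offTimeMean, lower = params@onTimeMean)
}

#' Realize a pulsatile input signal
#'
#' Draws one realization of the signal described by \code{params}.  AM
#' signals have a fixed square-wave timing skeleton (widths
#' \code{onTimeMean}/\code{offTimeMean}); within each branch the level is
#' re-sampled every \code{duration} seconds from the branch's moment-matched
#' noise family with variance \code{amplitudeVar}.  FM signals keep the two
#' exact levels but draw every branch width from the moment-matched family
#' with mean equal to the branch's nominal width and CV-squared
#' \code{frequencyNoise}.  Zero noise yields the deterministic square wave
#' for any seed.  The realization starts on the upper branch at time 0.
#'
#' @param params a [SignalParams-class].
#' @param seed optional integer seed for this realization; the caller's RNG
#'   state is left untouched when a seed is given.
#' @return a [PulseSignal-class].
#' @examples
#' s <- makeSignal(signalParams(amplitudeVar = 0.01, totalTime = 600), seed = 1)
#' summarizeSignal(s)
#' @export
makeSignal <- function(params, seed = NULL) {
    stopifnot(is(params, "SignalParams"))
    validObject(params)
    if (params@modulation == "AM") makeAMSignal(params, seed)
    else makeFMSignal(params, seed)
}

#' @rdname makeSignal
#' @export
makeAMSignal <- function(params, seed = NULL) {
    stopifnot(is(params, "SignalParams"), params@modulation == "AM")
    bw <- .branchWidths(params)
    means <- c(upper = params@upperMean, lower = params@lowerMean)
    D <- params@duration
    tot <- params@totalTime
    noiseless <- params@amplitudeVar == 0
    samplers <- if (!noiseless)
        lapply(means, momentSampler, variance = params@amplitudeVar,
               family = params@noiseFamily)
    build <- function() {
        start <- numeric(0); level <- numeric(0); branch <- character(0)
        t <- 0; b <- "upper"
        while (t < tot) {
            w <- unname(bw[b])
            if (noiseless) {
                start <- c(start, t); level <- c(level, means[[b]])
                branch <- c(branch, b)
            } else {
                nseg <- max(1L, ceiling(w / D - 1e-9))
                offs <- (seq_len(nseg) - 1) * D
                start <- c(start, t + offs)
                level <- c(level, samplers[[b]](nseg))
                branch <- c(branch, rep(b, nseg))
            }
            t <- t + w
            b <- if (b == "upper") "lower" else "upper"
        }
        keep <- start < tot
        new("PulseSignal", start = start[keep], level = level[keep],
            branch = branch[keep], totalTime = tot, params = params)
    }
    if (noiseless) build() else .withSeed(seed, build())
}

#' @rdname makeSignal
#' @export
makeFMSignal <- function(params, seed = NULL) {
    stopifnot(is(params, "SignalParams"), params@modulation == "FM")
    bw <- .branchWidths(params)
    means <- c(upper = params@upperMean, lower = params@lowerMean)
    tot <- params@totalTime
    noiseless <- params@frequencyNoise == 0
    samplers <- if (!noiseless)
        lapply(bw, function(w)
            momentSampler(w, params@frequencyNoise * w^2,
                          family = params@noiseFamily))
    build <- function() {
        # draw whole cycles in blocks until [0, totalTime) is covered
        nCyc <- max(4L, ceiling(tot / sum(bw) * 1.5) + 3L)
        repeat {
            up <- if (noiseless) rep(bw[["upper"]], nCyc) else samplers$upper(nCyc)
            lo <- if (noiseless) rep(bw[["lower"]], nCyc) else samplers$lower(nCyc)
            widths <- as.vector(rbind(up, lo))
            if (sum(widths) >= tot) break
            nCyc <- nCyc * 2L
        }
        branch <- rep(c("upper", "lower"), nCyc)
        start <- cumsum(c(0, widths[-length(widths)]))
        keep <- start < tot
        new("PulseSignal", start = start[keep],
            level = unname(means[branch[keep]]), branch = branch[keep],
            totalTime = tot, params = params)
    }
    if (noiseless) build() else .withSeed(seed, build())
}

#' @rdname PulseSignal-class
#' @export
setMethod("segmentStarts", "PulseSignal", function(x) x@start)
#' @rdname PulseSignal-class
#' @export
setMethod("segmentLevels", "PulseSignal", function(x) x@level)
#' @rdname PulseSignal-class
#' @export
setMethod("segmentWidths", "PulseSignal",
    function(x) diff(c(x@start, x@totalTime)))
#' @rdname PulseSignal-class
#' @export
setMethod("branchLabels", "PulseSignal", function(x) x@branch)
#' @rdname PulseSignal-class
#' @export
setMethod("totalTime", "PulseSignal", function(x) x@totalTime)
#' @rdname SignalParams-class
#' @export
setMethod("signalPeriod", "SignalParams",
    function(x) x@onTimeMean + x@offTimeMean)
#' @rdname SignalParams-class
#' @export
setMethod("signalPeriod", "PulseSignal", function(x) signalPeriod(x@params))

#' @rdname signalValueAt
#' @export
setMethod("signalValueAt", "PulseSignal", function(signal, t) {
    if (any(t < 0 | t >= signal@totalTime))
        stop("time outside [0, totalTime)")
    signal@level[findInterval(t, signal@start)]
})
#' @rdname signalValueAt
#' @export
setMethod("signalValueAt", "numeric", function(signal, t) rep(signal, length(t)))

setMethod("show", "SignalParams", function(object) {
    cat(sprintf("SignalParams: %s, %s-regulated (%s noise)\n",
                object@modulation, object@regulation, object@noiseFamily))
    cat(sprintf("  levels %.4g/%.4g  ON/OFF %.4g/%.4g s  T = %.4g s\n",
                object@upperMean, object@lowerMean, object@onTimeMean,
                object@offTimeMean, signalPeriod(object)))
    cat(sprintf("  Var = %.4g  Noise = %.4g  D = %.4g s  totalTime = %.4g s\n",
                object@amplitudeVar, object@frequencyNoise, object@duration,
                object@totalTime))
})

setMethod("show", "PulseSignal", function(object) {
    cat(sprintf("PulseSignal: %d segments over [0, %.4g) s\n",
                length(object@start), object@totalTime))
    show(object@params)
})

# Merge consecutive same-branch segments into branch runs.
.branchRuns <- function(signal) {
    r <- rle(signal@branch)
    ends <- cumsum(r$lengths)
    starts_idx <- c(1L, head(ends, -1L) + 1L)
    runStart <- signal@start[starts_idx]
    runEnd <- c(signal@start[starts_idx[-1L]], signal@totalTime)
    data.frame(branch = r$values, start = runStart, width = runEnd - runStart)
}

#' Summarize a realized signal
#'
#' Computes observed ON/OFF-time means (branch runs, with the final
#' truncated run excluded), the time-weighted level mean and variance, and
#' the observed width CV-squared ("Noise", averaged over the two branches).
#' ON/OFF labelling follows the regulation mode of the signal's parameters.
#'
#' @param signal a [PulseSignal-class] spanning at least one full cycle.
#' @return a list with elements \code{onTimeMean}, \code{offTimeMean},
#'   \code{levelMean}, \code{levelVar}, \code{noise}.
#' @export
summarizeSignal <- function(signal) {
    stopifnot(is(signal, "PulseSignal"))
    runs <- .branchRuns(signal)
    if (nrow(runs) > 1L) runs <- runs[-nrow(runs), , drop = FALSE]  # truncated
    onBranch <- if (signal@params@regulation == "transcription") "upper"
                else "lower"
    w <- segmentWidths(signal)
    lvl <- segmentLevels(signal)
    m1 <- sum(w * lvl) / sum(w)
    v <- sum(w * (lvl - m1)^2) / sum(w)
    cv2 <- vapply(c("upper", "lower"), function(b) {
        x <- runs$width[runs$branch == b]
        if (length(x) < 2L) return(NA_real_)
        var(x) * (length(x) - 1) / length(x) / mean(x)^2
    }, numeric(1))
    list(onTimeMean = mean(runs$width[runs$branch == onBranch]),
         offTimeMean = mean(runs$width[runs$branch != onBranch]),
         levelMean = m1, levelVar = v,
         noise = mean(cv2, na.rm = TRUE))
}

#' Write / read a realized signal as a plain-text table
#'
#' Serializes a [PulseSignal-class] to a two-column whitespace table
#' (\code{start_time}, \code{level}) preceded by \code{#}-comment header
#' lines carrying the generating parameters and branch labels, so the object
#' round-trips losslessly.
#'
#' @param signal a [PulseSignal-class].
#' @param path file path.
#' @return \code{writeSignal} returns \code{path} invisibly;
#'   \code{readSignal} returns the reconstructed [PulseSignal-class].
#' @export
writeSignal <- function(signal, path) {
    p <- signal@params
    hdr <- c(sprintf("# upperMean: %.17g", p@upperMean),
             sprintf("# lowerMean: %.17g", p@lowerMean),
             sprintf("# onTimeMean: %.17g", p@onTimeMean),
             sprintf("# offTimeMean: %.17g", p@offTimeMean),
             sprintf("# amplitudeVar: %.17g", p@amplitudeVar),
             sprintf("# frequencyNoise: %.17g", p@frequencyNoise),
             sprintf("# duration: %.17g", p@duration),
             sprintf("# totalTime: %.17g", p@totalTime),
             sprintf("# regulation: %s", p@regulation),
             sprintf("# modulation: %s", p@modulation),
             sprintf("# noiseFamily: %s", p@noiseFamily),
             sprintf("# branch: %s", paste(signal@branch, collapse = ",")),
             "start_time level")
    body <- sprintf("%.17g %.17g", signal@start, signal@level)
    writeLines(c(hdr, body), path)
    invisible(path)
}

#' @rdname writeSignal
#' @export
readSignal <- function(path) {
    lines <- readLines(path)
    hdr <- grep("^#", lines, value = TRUE)
    kv <- sub("^# ([^:]+): (.*)$", "\\1\1\\2", hdr)
    kv <- strsplit(kv, "\1", fixed = TRUE)
    vals <- setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
    num <- function(k) as.numeric(vals[[k]])
    params <- signalParams(upperMean = num("upperMean"),
        lowerMean = num("lowerMean"), onTimeMean = num("onTimeMean"),
        offTimeMean = num("offTimeMean"), amplitudeVar = num("amplitudeVar"),
        frequencyNoise = num("frequencyNoise"), duration = num("duration"),
        totalTime = num("totalTime"), regulation = vals[["regulation"]],
        modulation = vals[["modulation"]], noiseFamily = vals[["noiseFamily"]])
    tab <- read.table(path, comment.char = "#", header = TRUE)
    new("PulseSignal", start = tab$start_time, level = tab$level,
        branch = strsplit(vals[["branch"]], ",", fixed = TRUE)[[1L]],
        totalTime = num("totalTime"), params = params)
}
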