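# --- entropy production rate (energetic cost) of the birth-death chain ---
#
# The only transitions of the chain are m -> m+1 (rate k_b) and m+1 -> m
# (rate k_d (m+1)), so the Schnakenberg entropy production rate reduces to a
# sum over nearest-neighbour edges:
#   sigma = sum_m [k_b P(m) - k_d (m+1) P(m+1)]
#                 * ln[ k_b P(m) / (k_d (m+1) P(m+1)) ]
# Each term has the form (a-b) ln(a/b) >= 0.  At the constant-rate
# stationary law (Poisson(k_b/k_d)) every edge flux vanishes (detailed
# balance) and sigma = 0.

#' Instantaneous entropy production rate
#'
#' @param pmf numeric pmf over copy numbers \code{0:(length(pmf)-1)};
#'   must sum to 1 within 1e-6.
#' @param kb birth (transcription) rate in force.
#' @param kd per-molecule death (degradation) rate in force.
#' @param pseudo optional pseudo-count probability added to every state
#'   before normalization (default 0: edges with an empty endpoint are
#'   skipped, which avoids artificial divergences from finite sampling).
#' @return entropy production rate (natural-log units, per second).
#' @examples
#' instantaneousEC(analyticPmf(10), kb = 0.5, kd = 0.05)   # 0: detailed balance
#' @export
instantaneousEC <- function(pmf, kb, kd, pseudo = 0) {
    if (abs(sum(pmf) - 1) > 1e-6) stop("pmf must sum to 1 (within 1e-6)")
    if (kb <= 0 || kd <= 0) stop("rates must be positive")
    if (pseudo > 0) pmf <- (pmf + pseudo) / sum(pmf + pseudo)
    n <- length(pmf)
    if (n < 2L) return(0)
    m <- 0:(n - 2L)
    a <- kb * pmf[m + 1L]
    b <- kd * (m + 1) * pmf[m + 2L]
    ok <- a > 0 & b > 0
    sum((a[ok] - b[ok]) * log(a[ok] / b[ok]))
}

.ecSeries <- function(times, sigma, nRep) {
    new("ECSeries", times = times, sigma = sigma,
        timeAverage = mean(sigma), nReplicates = nRep)
}

setMethod("show", "ECSeries", function(object) {
    cat(sprintf(
        "ECSeries: %d times on [%.4g, %.4g] s, time average %.5g\n",
        length(object@times), min(object@times), max(object@times),
        object@timeAverage))
})

#' @rdname ECSeries-class
#' @param x an \code{ECSeries}
#' @export
setMethod("sampleTimes", "ECSeries", function(x) x@times)

#' @rdname ECSeries-class
#' @export
ecSigma <- function(x) x@sigma

#' @rdname ECSeries-class
#' @export
ecTimeAverage <- function(x) x@timeAverage

#' Time-averaged entropy production from an ensemble
#'
#' Evaluates [instantaneousEC()] at each post-burn-in grid time using the
#' ensemble's empirical pmf and the rates in force at that time, then time
#' averages over the largest whole number of signal periods that fits the
#' grid.
#'
#' @param ensemble an [EnsembleDistribution-class] whose grid covers at
#'   least one full signal period.
#' @param pseudo passed to [instantaneousEC()].
#' @return an [ECSeries-class].
#' @export
timeAveragedEC <- function(ensemble, pseudo = 0) {
    stopifnot(is(ensemble, "EnsembleDistribution"))
    cfg <- ensemble@config
    times <- ensemble@times
    pulse <- if (is(cfg@birth, "PulseSignal")) cfg@birth
             else if (is(cfg@death, "PulseSignal")) cfg@death
    Tper <- if (is.null(pulse)) diff(range(times)) + cfg@sampleDt
            else signalPeriod(pulse)
    span <- diff(range(times)) + cfg@sampleDt
    nPer <- floor(span / Tper + 1e-9)
    if (nPer < 1L) stop("sampling grid must cover at least one full period")
    keep <- times < times[1L] + nPer * Tper
    times <- times[keep]
    pm <- pmfMatrix(ensemble)[, keep, drop = FALSE]
    kb <- signalValueAt(cfg@birth, times)
    kd <- signalValueAt(cfg@death, times)
    sigma <- vapply(seq_along(times), function(j)
        instantaneousEC(pm[, j], kb[j], kd[j], pseudo = pseudo),
        numeric(1))
    .ecSeries(times, sigma, nrow(ensemble@counts))
}

#' Entropy production conditional on a realized signal
#'
#' For a given realized rate path the conditional copy-number law is exactly
#' Poisson(\eqn{\mu(t)}) (see [muPath()]), so the entropy production rate
#' can be evaluated without Monte-Carlo pmf estimation.  This exact route is
#' what the sweep pipelines use; [timeAveragedEC()] provides the empirical
#' counterpart.
#'
#' @param birth,death rate schedules (constant or [PulseSignal-class]).
#' @param times evaluation grid (should span whole periods after burn-in).
#' @return an [ECSeries-class] (with \code{nReplicates = NA}).
#' @export
ecFromRates <- function(birth, death, times) {
    mu <- muPath(birth, death, times)
    kb <- signalValueAt(birth, times)
    kd <- signalValueAt(death, times)
    mMax <- max(10, qpois(1e-12, max(mu), lower.tail = FALSE))
    sigma <- vapply(seq_along(times), function(j)
        instantaneousEC(dpois(0:mMax, mu[j]), kb[j], kd[j]), numeric(1))
    .ecSeries(times, sigma, NA_real_)
}
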