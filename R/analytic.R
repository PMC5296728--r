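# --- closed-form solution of the master equation with deterministic rates ---
#
# For known piecewise-constant rates the generating-function solution of the
# chemical master equation is a Poisson law with time-dependent parameter
# mu(t) solving  dmu/dt = k_b(t) - k_d(t) mu,  mu(0) = 0.  Within a
# constant-rate segment the ODE has the exact propagator used below, so mu is
# computed exactly in O(#segments).

.propagateMu <- function(mu0, kb, kd, dt) {
    if (kd > 0) kb / kd + (mu0 - kb / kd) * exp(-kd * dt)
    else mu0 + kb * dt
}

# Exact integral of mu over a constant-rate segment of length dt.
.muSegIntegral <- function(mu0, kb, kd, dt) {
    if (kd > 0) (kb / kd) * dt + (mu0 - kb / kd) * (1 - exp(-kd * dt)) / kd
    else mu0 * dt + kb * dt^2 / 2
}

# Merge two schedules into common segments covering [0, tEnd].
.mergedSchedule <- function(birth, death, tEnd) {
    b <- .schedule(birth, tEnd)
    d <- .schedule(death, tEnd)
    breaks <- sort(unique(c(b$breaks, d$breaks)))
    breaks <- breaks[breaks < tEnd]
    kb <- b$levels[findInterval(breaks, b$breaks)]
    kd <- d$levels[findInterval(breaks, d$breaks)]
    list(breaks = breaks, kb = kb, kd = kd,
         ends = c(breaks[-1L], tEnd))
}

# mu at every merged-segment start, from mu(0) = mu0.
.muAtBreaks <- function(sch, mu0 = 0) {
    n <- length(sch$breaks)
    mu <- numeric(n)
    mu[1L] <- mu0
    if (n > 1L)
        for (i in seq_len(n - 1L))
            mu[i + 1L] <- .propagateMu(mu[i], sch$kb[i], sch$kd[i],
                                       sch$breaks[i + 1L] - sch$breaks[i])
    mu
}

#' Mean copy number under deterministic rates
#'
#' Solves \eqn{d\mu/dt = k_b(t) - k_d(t)\,\mu} with \eqn{\mu(0) = 0} exactly
#' per constant-rate segment and evaluates \eqn{\mu} at the requested times.
#' Under deterministic (realized) rate schedules the copy-number law at time
#' t is exactly Poisson(\eqn{\mu(t)}) when the initial copy number is zero.
#'
#' @param birth,death rate schedules (constant or [PulseSignal-class]).
#' @param times numeric vector of evaluation times (>= 0); pulsatile
#'   schedules must cover \code{max(times)}.
#' @return numeric vector \eqn{\mu(times)}.
#' @examples
#' muPath(0.5, 0.05, c(0, 20))     # 0 and 10 * (1 - exp(-1))
#' @export
muPath <- function(birth, death, times) {
    if (any(times < 0)) stop("times must be >= 0")
    tEnd <- max(times, 0)
    for (x in list(birth, death))
        if (is(x, "PulseSignal") && x@totalTime < tEnd)
            stop("schedule not defined up to max(times)")
    if (tEnd == 0) return(numeric(length(times)))
    sch <- .mergedSchedule(birth, death, tEnd)
    muB <- .muAtBreaks(sch)
    idx <- findInterval(times, sch$breaks)
    vapply(seq_along(times), function(j) {
        i <- max(idx[j], 1L)
        .propagateMu(muB[i], sch$kb[i], sch$kd[i], times[j] - sch$breaks[i])
    }, numeric(1))
}

# Exact integral of mu(t) over [from, to], mu(0) = 0 (or muStart at t=0).
.muIntegral <- function(birth, death, from, to, muStart = 0) {
    stopifnot(from >= 0, to >= from)
    sch <- .mergedSchedule(birth, death, max(to, from, 1e-12))
    muB <- .muAtBreaks(sch, muStart)
    total <- 0
    for (i in seq_along(sch$breaks)) {
        a <- max(from, sch$breaks[i]); bnd <- min(to, sch$ends[i])
        if (bnd <= a) next
        mu_a <- .propagateMu(muB[i], sch$kb[i], sch$kd[i], a - sch$breaks[i])
        total <- total + .muSegIntegral(mu_a, sch$kb[i], sch$kd[i], bnd - a)
    }
    total
}

#' Time-dependent copy-number pmf
#'
#' The master-equation solution for deterministic rates and zero initial
#' copy number: \eqn{P(m, t) = e^{-\mu(t)} \mu(t)^m / m!}.
#'
#' @param mu non-negative Poisson parameter \eqn{\mu(t)}.
#' @param mMax largest copy number of the support; default is the smallest
#'   integer leaving Poisson tail mass below 1e-12.
#' @return numeric pmf over \code{0:mMax} (named by copy number).
#' @examples
#' p <- analyticPmf(10)
#' sum(p * as.numeric(names(p)))   # mean 10
#' @export
analyticPmf <- function(mu, mMax = NULL) {
    if (!is.finite(mu) || mu < 0) stop("'mu' must be non-negative")
    if (is.null(mMax))
        mMax <- max(10, qpois(1e-12, mu, lower.tail = FALSE))
    setNames(dpois(0:mMax, mu), 0:mMax)
}

#' Marginal copy-number pmf under a random input
#'
#' When the input signal (hence \eqn{\mu(t)}) is random, the marginal law of
#' the output is the mixture of the conditional Poisson laws over the
#' distribution of \eqn{\mu(t)}: the average of
#' \code{analyticPmf(mu)} over draws of \eqn{\mu(t)}.
#'
#' @param muDraws numeric vector of \eqn{\mu(t)} values, one per realized
#'   rate path (>= 1 draw).
#' @param mMax support bound; default covers the largest draw.
#' @return numeric pmf over \code{0:mMax}.
#' @export
mixturePmf <- function(muDraws, mMax = NULL) {
    if (length(muDraws) < 1L) stop("need at least one rate-path draw")
    if (any(!is.finite(muDraws) | muDraws < 0))
        stop("mu draws must be non-negative")
    if (is.null(mMax))
        mMax <- max(10, qpois(1e-12, max(muDraws), lower.tail = FALSE))
    pm <- vapply(muDraws, function(mu) dpois(0:mMax, mu),
                 numeric(mMax + 1L))
    setNames(rowMeans(pm), 0:mMax)
}

# One-period deterministic skeleton (upper then lower branch) of a pulsatile
# rate, as a schedule list.
.skeletonPeriod <- function(x) {
    p <- if (is(x, "PulseSignal")) x@params else x
    stopifnot(is(p, "SignalParams"))
    bw <- .branchWidths(p)
    list(breaks = c(0, bw[["upper"]]),
         levels = c(p@upperMean, p@lowerMean),
         period = sum(bw))
}

#' Periodic steady-state cycle mean of the output
#'
#' Time average of \eqn{\mu(t)} over one period at the periodic steady state
#' of the deterministic square-wave skeleton.  For a periodic birth rate with
#' constant death rate this equals \eqn{\langle k_b \rangle / k_d} exactly;
#' the general case solves the periodic fixed point of the per-segment
#' propagator and integrates in closed form.
#'
#' @param birth,death a constant rate, a [SignalParams-class] or a
#'   [PulseSignal-class] (pulsatile inputs contribute their noiseless
#'   square-wave skeleton); at least for constant/constant the mean is
#'   \eqn{k_b/k_d}.  At most one argument may be pulsatile.
#' @return the cycle-averaged mean copy number.
#' @examples
#' cycleMean(signalParams(), 0.03)        # 0.45 / 0.03 = 15
#' cycleMean(0.5, 0.05)                   # 10
#' @export
cycleMean <- function(birth, death) {
    bNum <- is.numeric(birth); dNum <- is.numeric(death)
    if (bNum && dNum) return(birth / death)
    if (!bNum && !dNum) stop("at most one rate may be pulsatile")
    sk <- .skeletonPeriod(if (bNum) death else birth)
    Tper <- sk$period
    bs <- if (bNum) list(breaks = 0, levels = birth) else sk
    ds <- if (dNum) list(breaks = 0, levels = death) else sk
    breaks <- sort(unique(c(bs$breaks, ds$breaks)))
    kb <- bs$levels[findInterval(breaks, bs$breaks)]
    kd <- ds$levels[findInterval(breaks, ds$breaks)]
    ends <- c(breaks[-1L], Tper)
    dt <- ends - breaks
    # one-period affine map mu -> A + B mu, then the fixed point
    A <- 0
    for (i in seq_along(breaks)) A <- .propagateMu(A, kb[i], kd[i], dt[i])
    B <- exp(-sum(kd * dt))
    if (B >= 1) stop("death rate must be positive over the period")
    muStar <- A / (1 - B)
    total <- 0; mu <- muStar
    for (i in seq_along(breaks)) {
        total <- total + .muSegIntegral(mu, kb[i], kd[i], dt[i])
        mu <- .propagateMu(mu, kb[i], kd[i], dt[i])
    }
    total / Tper
}

#' Direct numerical integration of the master equation
#'
#' Integrates the truncated chemical master equation of the birth-death
#' process on states \code{0:mMax} (reflecting truncation: no birth out of
#' \code{mMax}) by matrix exponentiation over each constant-rate segment.
#' This is an independent oracle for the stochastic simulator; it makes no
#' use of the Poisson-form solution.
#'
#' @param birth,death rate schedules (constant or [PulseSignal-class]).
#' @param times evaluation times (sorted, >= 0).
#' @param mMax state-space truncation bound.
#' @param m0 initial copy number (default 0).
#' @return matrix of pmfs, rows \code{0:mMax}, one column per time.
#' @export
masterEquationPmf <- function(birth, death, times, mMax, m0 = 0L) {
    stopifnot(all(diff(times) >= 0), all(times >= 0), mMax >= 1, m0 <= mMax)
    tEnd <- max(times)
    sch <- .mergedSchedule(birth, death, max(tEnd, 1e-12))
    m <- 0:mMax
    gen <- function(kb, kd) {
        Q <- matrix(0, mMax + 1L, mMax + 1L)
        Q[cbind(m[-1L] + 1L, m[-1L])] <- kb            # m-1 -> m birth
        Q[cbind(m[-length(m)] + 1L, m[-1L] + 1L)] <- kd * m[-1L]  # m -> m-1
        diag(Q) <- -(kb * (m < mMax) + kd * m)
        Q
    }
    p <- numeric(mMax + 1L); p[m0 + 1L] <- 1
    out <- matrix(NA_real_, mMax + 1L, length(times),
                  dimnames = list(m = m, NULL))
    tNow <- 0
    ti <- 1L
    while (ti <= length(times) && times[ti] <= 0) {
        out[, ti] <- p; ti <- ti + 1L
    }
    for (i in seq_along(sch$breaks)) {
        segEnd <- sch$ends[i]
        Q <- gen(sch$kb[i], sch$kd[i])
        # propagate to each requested time inside this segment, then its end
        while (ti <= length(times) && times[ti] <= segEnd + 1e-12) {
            dt <- times[ti] - tNow
            if (dt > 0)
                p <- as.numeric(Matrix::expm(Q * dt) %*% p)
            out[, ti] <- p
            tNow <- times[ti]
            ti <- ti + 1L
        }
        if (segEnd > tNow && segEnd < tEnd) {
            p <- as.numeric(Matrix::expm(Q * (segEnd - tNow)) %*% p)
            tNow <- segEnd
        }
        if (ti > length(times)) break
    }
    out
}
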