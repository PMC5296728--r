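test_that("mu solves the linear ODE exactly for constant rates", {
    expect_equal(muPath(0.5, 0.05, c(0, 20, 1e6)),
                 c(0, 10 * (1 - exp(-1)), 10))
    # mu(0) = 0 for any schedule
    sig <- makeSignal(signalParams(amplitudeVar = 0.01, totalTime = 600),
                      seed = 1)
    expect_identical(muPath(sig, 0.05, 0), 0)
})

test_that("segment-wise mu agrees with independent quadrature", {
    # mu(t) = integral of kb(s) exp(-kd (t - s)) ds, evaluated piecewise with
    # adaptive quadrature as an independent oracle
    sig <- makeSignal(signalParams(totalTime = 600))
    kd <- 0.05
    quadMu <- function(t) {
        br <- c(segmentStarts(sig), totalTime(sig))
        lv <- segmentLevels(sig)
        tot <- 0
        for (i in seq_along(lv)) {
            lo <- br[i]; hi <- min(br[i + 1], t)
            if (hi <= lo) next
            tot <- tot + integrate(function(s) lv[i] * exp(-kd * (t - s)),
                                   lo, hi, rel.tol = 1e-13)$value
        }
        tot
    }
    for (t in c(50, 100, 150, 350, 599))
        expect_equal(muPath(sig, kd, t), quadMu(t), tolerance = 1e-10)
})

test_that("mu is invariant under refinement of the segment partition", {
    sig <- makeSignal(signalParams(totalTime = 400))
    split <- new("PulseSignal",
                 start = c(0, 50, 100, 200, 300),
                 level = c(0.8, 0.8, 0.1, 0.8, 0.1),
                 branch = c("upper", "upper", "lower", "upper", "lower"),
                 totalTime = 400, params = sig@params)
    tt <- seq(0, 399, by = 7)
    expect_equal(muPath(split, 0.05, tt), muPath(sig, 0.05, tt))
})

test_that("the analytic pmf is the time-dependent Poisson law", {
    expect_identical(unname(analyticPmf(0)[1]), 1)
    p10 <- analyticPmf(10)
    expect_equal(unname(p10[1]), exp(-10))
    expect_equal(sum(p10 * as.numeric(names(p10))), 10)
    expect_lt(1 - sum(p10), 1e-12)
    expect_error(analyticPmf(-1), "non-negative")
})

test_that("ensemble pmf at cycle end matches the analytic law", {
    sig <- makeSignal(signalParams(totalTime = 1400))
    cfg <- modelConfig(sig, 0.05, burnIn = 1000)
    ens <- simulateEnsemble(cfg, 5000, seed = 2)
    j <- which(sampleTimes(ens) == 1200)    # end of a full cycle
    mu <- muPath(sig, 0.05, 1200)
    emp <- tabulate(countsMatrix(ens)[, j] + 1L, nbins = 61) / 5000
    expect_lt(tvDist(emp, analyticPmf(mu, 60)),
              max(0.02, 2 * expectedTV(analyticPmf(mu, 60), 5000)))
})

test_that("the mixture law averages the conditional Poisson laws", {
    expect_equal(mixturePmf(7), analyticPmf(7))
    m2 <- mixturePmf(c(5, 15))
    # truncation at Poisson tail mass 1e-12 leaves an O(mMax * 1e-12) residue
    expect_equal(sum(m2 * as.numeric(names(m2))), 10, tolerance = 1e-9)
    expect_error(mixturePmf(numeric(0)), "draw")

    # marginal over signal draws: mixture vs simulation with re-drawn signals
    p <- signalParams(amplitudeVar = 0.01, totalTime = 1250)
    tStar <- 1250 - 50            # upper branch, past burn-in
    set.seed(77)
    mus <- counts <- NULL
    for (k in 1:40) {
        sig <- makeSignal(p, seed = 100 + k)
        mus <- c(mus, muPath(sig, 0.05, tStar))
        cfg <- modelConfig(sig, 0.05, burnIn = 1000)
        tr <- replicate(50, {
            r <- simulateTrajectory(cfg, sampleAt = tStar, keepEvents = FALSE)
            sampledCounts(r)
        })
        counts <- c(counts, tr)
    }
    mix <- mixturePmf(mus, mMax = 80)
    emp <- tabulate(counts + 1L, nbins = 81) / length(counts)
    expect_lt(tvDist(emp, mix), 0.03)
})

test_that("cycle means have their closed forms", {
    expect_equal(cycleMean(signalParams(), 0.03), 15)
    expect_equal(cycleMean(0.5, 0.05), 10)
    # degradation-regulated: cross-check against long-horizon mu integration
    dp <- signalParams(upperMean = 0.1, lowerMean = 0.025,
                       regulation = "degradation", totalTime = 4200)
    cm <- cycleMean(0.5, dp)
    sig <- makeSignal(dp)
    longAvg <- PulseDecode:::.muIntegral(0.5, sig, 4000, 4200) / 200
    expect_equal(cm, longAvg, tolerance = 1e-6)
    expect_error(cycleMean(makeSignal(signalParams(totalTime = 400)),
                           makeSignal(dp)), "pulsatile")
})
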