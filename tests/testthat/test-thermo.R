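test_that("entropy production vanishes at detailed balance", {
    expect_lt(abs(instantaneousEC(analyticPmf(10), 0.5, 0.05)), 1e-12)
    expect_lt(abs(instantaneousEC(analyticPmf(2), 0.1, 0.05)), 1e-12)
})

test_that("instantaneous EC matches a brute-force edge sum and is >= 0", {
    # independent term-by-term summation over the chain's edges
    bruteEC <- function(p, kb, kd) {
        total <- 0
        for (m in 0:(length(p) - 2)) {
            a <- kb * p[m + 1]
            b <- kd * (m + 1) * p[m + 2]
            if (a > 0 && b > 0) total <- total + (a - b) * log(a / b)
        }
        total
    }
    p4 <- c(0.4, 0.3, 0.2, 0.1)
    expect_equal(instantaneousEC(p4, 0.5, 0.05), bruteEC(p4, 0.5, 0.05))
    expect_equal(instantaneousEC(p4, 0.5, 0.05), 0.9024, tolerance = 1e-4)

    set.seed(1)
    for (i in 1:15) {
        p <- rgamma(sample(3:30, 1), 1); p <- p / sum(p)
        kb <- runif(1, 0.01, 2); kd <- runif(1, 0.01, 0.5)
        ec <- instantaneousEC(p, kb, kd)
        expect_gte(ec, 0)
        expect_equal(ec, bruteEC(p, kb, kd))
        # invariant under support extension by zero-probability states
        expect_equal(instantaneousEC(c(p, 0, 0), kb, kd), ec)
    }
    expect_error(instantaneousEC(c(0.5, 0.4), 0.5, 0.05), "sum to 1")
})

test_that("empirical EC is near zero at equilibrium and positive under drive", {
    # stationary constant-rate pmf from 1e5 pooled samples
    cfg <- modelConfig(birth = 0.5, death = 0.05, tMax = 101000,
                       burnIn = 1000, sampleDt = 1)
    tr <- simulateTrajectory(cfg, seed = 2,
                             sampleAt = seq(1000, 101000, by = 1),
                             keepEvents = FALSE)
    emp <- tabulate(sampledCounts(tr) + 1L, nbins = 60) /
           length(sampledCounts(tr))
    expect_lt(abs(instantaneousEC(emp, 0.5, 0.05)), 1e-3)

    # periodic drive breaks detailed balance
    sig <- makeSignal(signalParams(totalTime = 1400))
    times <- seq(1000, 1399, by = 1)
    ecx <- ecFromRates(sig, 0.05, times)
    expect_gt(ecTimeAverage(ecx), 0.05)
    expect_true(all(ecSigma(ecx) >= 0))
})

test_that("ensemble EC agrees with the master-equation-exact EC", {
    sig <- makeSignal(signalParams(totalTime = 1400))
    cfg <- modelConfig(sig, 0.05, burnIn = 1000, sampleDt = 5)
    ens <- simulateEnsemble(cfg, 3000, seed = 3)
    empirical <- timeAveragedEC(ens)

    tt <- sampleTimes(ens)[sampleTimes(ens) < 1000 + 200]  # one period
    exact <- masterEquationPmf(sig, 0.05, tt, mMax = 60)
    kb <- signalValueAt(sig, tt)
    sigExact <- vapply(seq_along(tt), function(j)
        instantaneousEC(exact[, j], kb[j], 0.05), numeric(1))
    expect_lt(abs(ecTimeAverage(empirical) - mean(sigExact)) / mean(sigExact),
              0.1)
    # the analytic conditional-Poisson route agrees with the exact one too
    analytic <- ecFromRates(sig, 0.05, tt)
    expect_lt(abs(ecTimeAverage(analytic) - mean(sigExact)) / mean(sigExact),
              0.02)
})

test_that("time-averaged EC keeps whole periods and validates its grid", {
    sig <- makeSignal(signalParams(totalTime = 1400))
    cfg <- modelConfig(sig, 0.05, burnIn = 1000, sampleDt = 150)
    ens <- simulateEnsemble(cfg, 50, seed = 4)
    # grid spans 400 s = 2 periods; only whole periods enter the average
    ecs <- timeAveragedEC(ens)
    expect_lte(max(sampleTimes(ecs)), 1000 + 2 * 200)
    short <- new("EnsembleDistribution", times = ens@times[1:1],
                 counts = ens@counts[, 1:1, drop = FALSE], config = cfg)
    expect_error(timeAveragedEC(short), "period")
})
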