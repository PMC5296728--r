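test_that("constant-rate simulation reaches the known stationary law", {
    cfg <- modelConfig(birth = 0.5, death = 0.05, tMax = 2.1e6, burnIn = 2000,
                       sampleDt = 20)
    tr <- simulateTrajectory(cfg, seed = 1,
                             sampleAt = seq(2000, 2.1e6, by = 20),
                             keepEvents = FALSE)
    x <- sampledCounts(tr)
    expect_lt(abs(mean(x) - 10), 0.15)
    # pooled samples against the Poisson(10) stationary pmf
    emp <- tabulate(x + 1L, nbins = 40) / length(x)
    expect_lt(tvDist(emp, dpois(0:39, 10)), 0.02)
})

test_that("a pure-death process is monotone and absorbs at zero", {
    cfg <- modelConfig(birth = 0, death = 0.1, m0 = 5L, tMax = 400)
    tr <- simulateTrajectory(cfg, seed = 2)
    expect_true(all(eventDeltas(tr) == -1L))
    expect_length(eventTimes(tr), 5L)
    expect_identical(sampledCounts(tr)[length(sampledCounts(tr))], 0L)
})

test_that("trajectories have the +/-1 jump structure and stay non-negative", {
    sig <- makeSignal(signalParams(amplitudeVar = 0.01, totalTime = 1400),
                      seed = 3)
    cfg <- modelConfig(sig, 0.05)
    for (s in 1:5) {
        tr <- simulateTrajectory(cfg, seed = s)
        path <- tr@m0 + cumsum(eventDeltas(tr))
        expect_true(all(path >= 0L))
        expect_true(all(abs(eventDeltas(tr)) == 1L))
        expect_true(all(diff(eventTimes(tr)) >= 0))
    }
})

test_that("state sampling is right-continuous and matches an event replay", {
    cfg <- modelConfig(birth = 0.5, death = 0.05, m0 = 2L, tMax = 500)
    tr <- simulateTrajectory(cfg, seed = 4)
    # replay oracle: step through events one by one
    replay <- function(t) {
        m <- tr@m0
        for (i in seq_along(eventTimes(tr))) {
            if (eventTimes(tr)[i] > t) break
            m <- m + eventDeltas(tr)[i]
        }
        m
    }
    set.seed(5)
    ts <- c(runif(50, 0, 500), eventTimes(tr)[1:5], 0, 500)
    expect_identical(sampleStates(tr, ts),
                     vapply(ts, replay, integer(1)))
    # a query at an event time sees the post-event state
    e1 <- eventTimes(tr)[1]
    expect_identical(sampleStates(tr, e1),
                     tr@m0 + eventDeltas(tr)[1])
    expect_error(sampleStates(tr, 501), "tMax")
    # the C++ grid sampler agrees with the replay-based sampler
    expect_identical(sampledCounts(tr), sampleStates(tr, sampleTimes(tr)))
})

test_that("the breakpoint-horizon scheme is exact for the first event time", {
    # two-segment birth rate, no deaths possible from m0 = 0 until the first
    # birth, so the first event time has the inhomogeneous-exponential law
    # with hazard kb(t): kb = 0.05 for t < 30, then 0.4
    sch <- list(b = c(0, 30), lb = c(0.05, 0.4))
    set.seed(6)
    first <- replicate(2e4, {
        r <- PulseDecode:::simulate_bd_cpp(sch$b, sch$lb, 0, 1, 0L, 1e4,
                                           numeric(0), TRUE)
        r$event_times[1]
    })
    cdf <- function(t) 1 - exp(-(0.05 * pmin(t, 30) + 0.4 * pmax(t - 30, 0)))
    ks <- suppressWarnings(stats::ks.test(first, cdf))
    expect_gt(ks$p.value, 0.001)
})

test_that("ensemble distributions normalize and respect preconditions", {
    sig <- makeSignal(signalParams(totalTime = 1400))
    cfg <- modelConfig(sig, 0.05)
    expect_error(simulateEnsemble(cfg, 1), ">= 2")
    ens <- simulateEnsemble(cfg, 100, seed = 7)
    pm <- pmfMatrix(ens)
    expect_equal(unname(colSums(pm)), rep(1, ncol(pm)))
    expect_identical(dim(countsMatrix(ens)), c(100L, length(sampleTimes(ens))))
    expect_identical(nReplicates(ens), 100L)
    # identical seeds reproduce the ensemble bit for bit
    expect_identical(countsMatrix(simulateEnsemble(cfg, 100, seed = 7)),
                     countsMatrix(ens))
})

test_that("ensemble pmfs match direct master-equation integration", {
    # six-segment drive, state space well inside m <= 60
    sig <- makeSignal(signalParams(totalTime = 600))
    cfg <- modelConfig(sig, 0.05, tMax = 600, burnIn = 0, sampleDt = 60)
    ens <- simulateEnsemble(cfg, 3000, seed = 8)
    tt <- sampleTimes(ens)
    exact <- masterEquationPmf(sig, 0.05, tt, mMax = 60)
    emp <- pmfMatrix(ens, mMax = 60)
    for (j in seq_along(tt)) {
        tol <- max(0.02, 2 * expectedTV(exact[, j], 3000))
        expect_lt(tvDist(emp[, j], exact[, j]), tol)
    }
})
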