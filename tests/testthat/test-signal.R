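test_that("moment-matched samplers reproduce the requested moments", {
    # zero variance degenerates to a constant
    s0 <- lognormalFromMoments(0.8, 0)
    expect_identical(s0(5), rep(0.8, 5))

    # (1,1): log-scale variance must be exactly ln 2; check empirically
    cases <- list(c(0.8, 0.01), c(1, 1), c(0.1, 0.001), c(100, 1e4))
    for (family in c("lognormal", "gamma")) {
        for (cs in cases) {
            smp <- momentSampler(cs[1], cs[2], family)
            set.seed(101)
            x <- smp(1e6)
            seMean <- sqrt(cs[2] / 1e6)
            expect_lt(abs(mean(x) - cs[1]), 4 * seMean)
            # SE of the sample variance from the empirical fourth moment
            seVar <- sqrt((mean((x - mean(x))^4) - var(x)^2) / 1e6)
            expect_lt(abs(var(x) - cs[2]), 4 * seVar)
            expect_true(all(x > 0))
        }
    }
    expect_error(momentSampler(-1, 0.1), "positive")
    expect_error(momentSampler(1, -0.1), "non-negative")
})

test_that("zero-noise signals are the exact square wave, independent of seed", {
    p <- signalParams(totalTime = 400)
    s <- makeSignal(p, seed = 1)
    expect_identical(segmentLevels(s), c(0.8, 0.1, 0.8, 0.1))
    expect_identical(segmentStarts(s), c(0, 100, 200, 300))
    expect_identical(s, makeSignal(p, seed = 999))

    pf <- signalParams(modulation = "FM", totalTime = 400)
    sf <- makeSignal(pf, seed = 1)
    expect_identical(segmentStarts(sf), segmentStarts(s))
    expect_identical(segmentLevels(sf), segmentLevels(s))
})

test_that("AM amplitude noise refreshes every D seconds within a branch", {
    p <- signalParams(amplitudeVar = 0.01, duration = 3, totalTime = 400)
    s <- makeSignal(p, seed = 7)
    runs <- rle(branchLabels(s))
    expect_equal(runs$lengths, rep(34L, 4))      # ceiling(100 / 3)
    expect_true(all(segmentLevels(s) > 0))
    # refresh segments are D long except the last of each branch
    w <- segmentWidths(s)
    expect_true(all(abs(w[-cumsum(runs$lengths)] - 3) < 1e-9))

    # D larger than the branch width: one draw per branch
    pD <- signalParams(amplitudeVar = 0.01, duration = 150, totalTime = 400)
    expect_equal(length(segmentStarts(makeSignal(pD, seed = 1))), 4L)

    # branch means are preserved over many cycles
    pL <- signalParams(amplitudeVar = 0.01, totalTime = 20000)
    sL <- makeSignal(pL, seed = 8)
    up <- segmentLevels(sL)[branchLabels(sL) == "upper"]
    expect_lt(abs(mean(up) - 0.8), 4 * sqrt(0.01 / length(up)))
})

test_that("FM signals keep exact levels and moment-matched widths", {
    p <- signalParams(modulation = "FM", frequencyNoise = 1, totalTime = 2e5)
    s <- makeSignal(p, seed = 3)
    expect_setequal(unique(segmentLevels(s)), c(0.8, 0.1))
    # width CV^2 of the underlying sampler at Monte-Carlo precision
    set.seed(11)
    w <- momentSampler(100, 1 * 100^2)(1e5)
    cv2 <- var(w) / mean(w)^2
    expect_lt(abs(cv2 - 1), 0.1)
    # observed on the realized signal (smaller n, looser bound)
    expect_lt(abs(summarizeSignal(s)$noise - 1), 0.3)
})

test_that("segments cover [0, totalTime) without gaps for any parameters", {
    set.seed(42)
    for (i in 1:20) {
        p <- signalParams(
            upperMean = runif(1, 0.5, 2), lowerMean = runif(1, 0.01, 0.4),
            onTimeMean = runif(1, 20, 150), offTimeMean = runif(1, 20, 150),
            amplitudeVar = sample(c(0, 0.01), 1),
            frequencyNoise = sample(c(0, 1), 1),
            modulation = sample(c("AM", "FM"), 1),
            noiseFamily = sample(c("lognormal", "gamma"), 1),
            totalTime = runif(1, 300, 2000))
        s <- makeSignal(p, seed = i)
        expect_equal(sum(segmentWidths(s)), totalTime(s))
        expect_identical(segmentStarts(s)[1], 0)
        expect_true(all(diff(segmentStarts(s)) > 0))
    }
})

test_that("signal evaluation uses half-open segments and checks the domain", {
    s <- makeSignal(signalParams(totalTime = 400))
    expect_identical(signalValueAt(s, 50), 0.8)
    expect_identical(signalValueAt(s, 100), 0.1)   # boundary -> next segment
    expect_identical(signalValueAt(s, 0), 0.8)
    expect_error(signalValueAt(s, 400), "totalTime")
    expect_error(signalValueAt(s, -1), "totalTime")
})

test_that("ON/OFF labels follow the regulation mode", {
    s <- makeSignal(signalParams(onTimeMean = 120, offTimeMean = 80,
                                 totalTime = 1000))
    sm <- summarizeSignal(s)
    expect_equal(sm$onTimeMean, 120)
    expect_equal(sm$offTimeMean, 80)

    # under degradation regulation ON is the lower branch (high mRNA)
    sd <- makeSignal(signalParams(upperMean = 0.1, lowerMean = 0.025,
                                  onTimeMean = 120, offTimeMean = 80,
                                  regulation = "degradation",
                                  totalTime = 1000))
    smd <- summarizeSignal(sd)
    expect_equal(smd$onTimeMean, 120)   # lower-branch runs are 120 s
    runs <- rle(branchLabels(sd))
    expect_equal(unique(runs$lengths[runs$values == "lower"]), 1L)
    expect_equal(segmentWidths(sd)[branchLabels(sd) == "lower"][1], 120)
})

test_that("parameter invariants are enforced", {
    expect_error(signalParams(upperMean = 0.1, lowerMean = 0.8), "upperMean")
    expect_error(signalParams(onTimeMean = -1), "onTimeMean")
    expect_error(signalParams(amplitudeVar = -0.1), "amplitudeVar")
})

test_that("signals round-trip through the text serialization", {
    p <- signalParams(amplitudeVar = 0.01, totalTime = 600)
    s <- makeSignal(p, seed = 5)
    path <- withr::local_tempfile(fileext = ".txt")
    writeSignal(s, path)
    s2 <- readSignal(path)
    expect_equal(segmentStarts(s2), segmentStarts(s))
    expect_equal(segmentLevels(s2), segmentLevels(s))
    expect_identical(branchLabels(s2), branchLabels(s))
    expect_equal(totalTime(s2), totalTime(s))
})
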