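test_that("input binning covers the three schemes", {
    b <- binInput(c(0.8, 0.1, 0.8, 0.8), scheme = "discrete")
    expect_identical(b$symbols, c(2L, 1L, 2L, 2L))
    expect_null(b$edges)
    expect_identical(unique(binInput(rep(0.5, 10), "discrete")$symbols), 1L)

    set.seed(1)
    x <- lognormalFromMoments(1, 1)(1e4)
    q <- binInput(x, "quantile", nBins = 8)
    occ <- tabulate(q$symbols, 8)
    expect_lt(max(occ) / min(occ), 1.2)
    expect_true(all(diff(q$edges) > 0))
    expect_error(binInput(x, "quantile", nBins = 1), "nBins")
    expect_error(binInput(c(1, 1, 2), "quantile", nBins = 3), "distinct")
})

test_that("plug-in MI reproduces exact values on known joints", {
    # independent inputs: MI within a few times the plug-in bias bound
    set.seed(2)
    n <- 1e5
    x <- sample(4, n, replace = TRUE)
    y <- sample(4, n, replace = TRUE)
    bias <- (4 - 1) * (4 - 1) / (2 * n * log(2))
    expect_lt(estimateMI(x, y), 5 * bias)

    # noiseless 4-symbol channel transmits exactly 2 bits
    z <- rep(1:4, times = 250)
    expect_equal(estimateMI(z, z), 2)

    # hand-built joint [[0.4, 0.1], [0.1, 0.4]] via exact sample proportions
    x2 <- rep(1:2, each = 1000)
    y2 <- c(rep(1, 800), rep(2, 200), rep(1, 200), rep(2, 800))
    expected <- miBrute(matrix(c(0.4, 0.1, 0.1, 0.4), 2, byrow = TRUE))
    expect_equal(estimateMI(x2, y2), expected, tolerance = 1e-6)
    expect_equal(expected, 0.278072, tolerance = 1e-6)
    expect_error(estimateMI(integer(0), integer(0)), "non-empty")
})

test_that("MI is bounded, label-invariant and consistent", {
    entropy <- function(v) {
        p <- table(v) / length(v)
        -sum(p * log2(p))
    }
    set.seed(3)
    for (i in 1:10) {
        # random joint law on a small alphabet
        k <- sample(2:5, 2, replace = TRUE)
        J <- matrix(rgamma(prod(k), 0.6), k[1], k[2])
        J <- J / sum(J)
        idx <- sample(length(J), 4000, replace = TRUE, prob = J)
        x <- (idx - 1) %% k[1] + 1
        y <- (idx - 1) %/% k[1] + 1
        mi <- estimateMI(x, y)
        expect_gte(mi, 0)
        expect_lte(mi, min(entropy(x), entropy(y)) + 1e-12)
        # invariance under relabeling x and any bijection of y
        expect_equal(estimateMI(max(x) + 1 - x, letters[y]), mi)
    }
    # convergence to the exact MI of a fixed joint law
    J <- matrix(c(0.35, 0.05, 0.1, 0.5), 2, byrow = TRUE)
    exact <- miBrute(J)
    err <- sapply(c(2e3, 2e5), function(n) {
        set.seed(4)
        idx <- sample(4, n, replace = TRUE, prob = as.vector(J))
        abs(estimateMI((idx - 1) %% 2, (idx - 1) %/% 2) - exact)
    })
    expect_lt(err[2], err[1])
    expect_lt(err[2], 0.005)
})

test_that("Miller-Madow correction shrinks the independence bias", {
    set.seed(5)
    x <- sample(6, 3000, replace = TRUE)
    y <- sample(6, 3000, replace = TRUE)
    expect_lt(abs(estimateMI(x, y, correction = "miller-madow")),
              estimateMI(x, y))
})

test_that("joint histograms tally every pair exactly once", {
    x <- c(1, 1, 2, 2, 2)
    y <- c(0, 0, 5, 5, 7)
    h <- jointHistogram(x, y)
    expect_identical(sum(h$count), 5L)
    expect_identical(nrow(h), 3L)
    expect_identical(h$count[h$input_bin == "1" & h$output_count == "0"], 2L)
})
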