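# Shared fixtures and independent mini-oracles used across the suite.

# total-variation distance between two pmfs on a common support
tvDist <- function(p, q) {
    n <- max(length(p), length(q))
    sum(abs(c(p, numeric(n - length(p))) - c(q, numeric(n - length(q))))) / 2
}

# expected Monte-Carlo TV of an n-sample empirical pmf around truth p
# (half-normal mean of the per-cell deviations)
expectedTV <- function(p, n) 0.5 * sqrt(2 / (pi * n)) * sum(sqrt(p * (1 - p)))

# direct summation of MI (bits) over the cells of a joint probability matrix;
# deliberately naive (loops), independent of the package implementation
miBrute <- function(p) {
    p <- p / sum(p)
    px <- rowSums(p); py <- colSums(p)
    total <- 0
    for (i in seq_len(nrow(p)))
        for (j in seq_len(ncol(p)))
            if (p[i, j] > 0)
                total <- total + p[i, j] * log2(p[i, j] / (px[i] * py[j]))
    total
}

# the standard transcription-regulated square-wave setting
txParams <- function(..., totalTime = 1400) {
    signalParams(totalTime = totalTime, ...)
}

degParams <- function(..., totalTime = 1400) {
    signalParams(upperMean = 0.1, lowerMean = 0.025,
                 regulation = "degradation", totalTime = totalTime, ...)
}
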