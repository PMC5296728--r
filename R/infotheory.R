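# --- plug-in mutual information between input level and output count ---

#' Discretize input levels into symbols
#'
#' @param values numeric input levels (e.g. the instantaneous rate at each
#'   sample time).
#' @param scheme \code{"quantile"} (near-equal occupancy), \code{"width"}
#'   (equal-width bins) or \code{"discrete"} (one symbol per distinct value;
#'   appropriate for FM inputs, which take only two levels).
#' @param nBins number of bins for the continuous schemes (>= 2); the
#'   quantile scheme requires at least \code{nBins} distinct values.
#' @return a list with \code{symbols} (integer symbol per value) and
#'   \code{edges} (bin edges, \code{NULL} for the discrete scheme).
#' @examples
#' binInput(c(0.8, 0.1, 0.8), scheme = "discrete")$symbols
#' @export
binInput <- function(values, scheme = c("quantile", "width", "discrete"),
                     nBins = 8) {
    scheme <- match.arg(scheme)
    if (!length(values)) stop("'values' is empty")
    if (scheme == "discrete") {
        lev <- sort(unique(values))
        return(list(symbols = match(values, lev), edges = NULL))
    }
    if (nBins < 2) stop("nBins must be >= 2")
    if (scheme == "quantile") {
        if (length(unique(values)) < nBins)
            stop("need at least nBins distinct values for quantile binning")
        edges <- unique(quantile(values, probs = seq(0, 1, length.out = nBins + 1),
                                 names = FALSE, type = 7))
    } else {
        edges <- seq(min(values), max(values), length.out = nBins + 1)
    }
    edges[1L] <- -Inf; edges[length(edges)] <- Inf
    list(symbols = findInterval(values, edges, left.open = FALSE,
                                rightmost.closed = TRUE),
         edges = edges)
}

# Discrete when few distinct levels (deterministic or FM inputs), quantile
# bins otherwise.
.autoBin <- function(values, nBins = 8) {
    if (length(unique(values)) <= nBins)
        binInput(values, "discrete")$symbols
    else
        binInput(values, "quantile", nBins)$symbols
}

#' Joint histogram of (input symbol, output count) pairs
#'
#' @param x input symbols.
#' @param y output copy numbers.
#' @return a data.frame with columns \code{input_bin}, \code{output_count},
#'   \code{count} (occupied cells only).
#' @export
jointHistogram <- function(x, y) {
    stopifnot(length(x) == length(y), length(x) > 0)
    tab <- table(input_bin = x, output_count = y)
    df <- as.data.frame(tab, stringsAsFactors = FALSE)
    names(df) <- c("input_bin", "output_count", "count")
    df[df$count > 0, , drop = FALSE]
}

# Plug-in MI (bits) from a joint probability or count matrix.
.miFromJoint <- function(p) {
    p <- p / sum(p)
    px <- rowSums(p); py <- colSums(p)
    idx <- which(p > 0, arr.ind = TRUE)
    sum(p[idx] * log2(p[idx] / (px[idx[, 1L]] * py[idx[, 2L]])))
}

#' Plug-in mutual information estimate
#'
#' Estimates \eqn{MI(X;Y) = \sum P(x,y) \log_2 [P(x,y)/(P(x)P(y))]} (bits)
#' from paired samples of the binned input \code{x} and output count
#' \code{y}, using the empirical joint law.  Zero-probability cells
#' contribute nothing.  The optional Miller-Madow correction subtracts the
#' leading \eqn{O(1/n)} plug-in bias.
#'
#' @param x input symbols (any discrete labels).
#' @param y output copy numbers (or any discrete labels).
#' @param correction \code{"none"} (default) or \code{"miller-madow"}.
#' @return mutual information in bits (>= 0 for the plain plug-in).
#' @examples
#' x <- rep(1:2, each = 500); y <- c(rep(1, 400), rep(2, 100),
#'                                   rep(1, 100), rep(2, 400))
#' estimateMI(x, y)   # 0.2781 bits
#' @export
estimateMI <- function(x, y, correction = c("none", "miller-madow")) {
    correction <- match.arg(correction)
    if (!length(x) || length(x) != length(y))
        stop("x and y must be non-empty and of equal length")
    tab <- table(x, y)
    mi <- .miFromJoint(tab)
    if (correction == "miller-madow") {
        n <- length(x)
        kx <- sum(rowSums(tab) > 0); ky <- sum(colSums(tab) > 0)
        kxy <- sum(tab > 0)
        mi <- mi + ((kx - 1) + (ky - 1) - (kxy - 1)) / (2 * n * log(2))
    }
    mi
}
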