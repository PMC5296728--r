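#' @rdname PulseSignal-class
#' @param object,x a package object
#' @export
setGeneric("segmentStarts", function(x) standardGeneric("segmentStarts"))

#' @rdname PulseSignal-class
#' @export
setGeneric("segmentLevels", function(x) standardGeneric("segmentLevels"))

#' @rdname PulseSignal-class
#' @export
setGeneric("segmentWidths", function(x) standardGeneric("segmentWidths"))

#' @rdname PulseSignal-class
#' @export
setGeneric("branchLabels", function(x) standardGeneric("branchLabels"))

#' @rdname PulseSignal-class
#' @export
setGeneric("totalTime", function(x) standardGeneric("totalTime"))

#' @rdname SignalParams-class
#' @param x a package object
#' @export
setGeneric("signalPeriod", function(x) standardGeneric("signalPeriod"))

#' Rate level of a signal at given times
#'
#' Evaluates a realized [PulseSignal-class] at time points \code{t} using the
#' left-closed/right-open segment convention: a breakpoint belongs to the
#' segment it starts.
#'
#' @param signal a [PulseSignal-class] (or a constant rate, returned as-is).
#' @param t numeric vector of times in \eqn{[0, totalTime)}.
#' @return numeric vector of rate levels.
#' @examples
#' p <- signalParams(totalTime = 400)
#' s <- makeSignal(p)
#' signalValueAt(s, c(50, 100))   # 0.8 then 0.1
#' @export
setGeneric("signalValueAt", function(signal, t) standardGeneric("signalValueAt"))

#' @rdname EnsembleDistribution-class
#' @param x a package object
#' @export
setGeneric("sampleTimes", function(x) standardGeneric("sampleTimes"))

#' @rdname EnsembleDistribution-class
#' @export
setGeneric("countsMatrix", function(x) standardGeneric("countsMatrix"))

#' @rdname EnsembleDistribution-class
#' @export
setGeneric("nReplicates", function(x) standardGeneric("nReplicates"))

#' Per-time empirical pmf of an ensemble
#'
#' @param x an [EnsembleDistribution-class].
#' @param mMax largest copy number of the returned support (default: the
#'   largest count observed).
#' @return numeric matrix with rows \code{0:mMax} (copy number) and one
#'   column per time point; every column sums to 1.
#' @export
setGeneric("pmfMatrix", function(x, mMax = NULL) standardGeneric("pmfMatrix"))

#' @rdname Trajectory-class
#' @param x a package object
#' @export
setGeneric("eventTimes", function(x) standardGeneric("eventTimes"))

#' @rdname Trajectory-class
#' @export
setGeneric("eventDeltas", function(x) standardGeneric("eventDeltas"))

#' @rdname Trajectory-class
#' @export
setGeneric("sampledCounts", function(x) standardGeneric("sampledCounts"))
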