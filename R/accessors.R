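#' @rdname TimeGrid-class
#' @param grid a [TimeGrid-class].
#' @export
binCount <- function(grid) as.integer(round(grid@period / grid@delta))

#' @rdname TimeGrid-class
#' @export
timeStep <- function(grid) grid@delta

#' @rdname TimeGrid-class
#' @export
gridPeriod <- function(grid) grid@period

#' @rdname TimeGrid-class
#' @export
gridTimes <- function(grid) (seq_len(binCount(grid)) - 1) * grid@delta

#' Snap times onto the grid
#'
#' Rounds each time to the nearest bin, breaking exact half-bin ties toward
#' the earlier bin.
#'
#' @param time numeric vector of times in ms.
#' @param grid a [TimeGrid-class].
#' @return Times as exact grid multiples.
#' @export
snapToGrid <- function(time, grid) {
  q <- time / grid@delta
  lo <- floor(q)
  # nearest bin, half-way cases to the earlier bin
  bin <- ifelse(q - lo > 0.5, lo + 1, lo)
  bin * grid@delta
}

#' @rdname DelaySNN-class
#' @param object,model a [DelaySNN-class].
#' @export
synapticWeights <- function(model) model@weights

#' @rdname DelaySNN-class
#' @export
conductionDelays <- function(model) model@delays

#' @rdname DelaySNN-class
#' @export
intrinsicExcitability <- function(model) model@bTilde

#' Number of pre-synaptic neurons
#' @param x a [SpikePattern-class], [SpikeDataset-class] or [DelaySNN-class].
#' @export
setGeneric("nNeurons", function(x) standardGeneric("nNeurons"))

#' @rdname nNeurons
#' @export
setMethod("nNeurons", "SpikePattern", function(x) x@nNeurons)

#' @rdname nNeurons
#' @export
setMethod("nNeurons", "DelaySNN", function(x) length(x@weights))

#' @rdname nNeurons
#' @export
setMethod("nNeurons", "SpikeDataset", function(x) {
  if (!length(x@patterns)) 0L else x@patterns[[1]]@nNeurons
})

#' Number of events in a pattern
#' @param pattern a [SpikePattern-class].
#' @export
nEvents <- function(pattern) length(pattern@time)

#' Events of a pattern as a data frame
#' @param pattern a [SpikePattern-class].
#' @return `data.frame(neuron, time)` sorted by neuron then time.
#' @export
patternEvents <- function(pattern) {
  ord <- order(pattern@neuron, pattern@time)
  data.frame(neuron = pattern@neuron[ord], time = pattern@time[ord])
}

#' Spike times of a post-synaptic train
#' @param train a [SpikeTrain-class].
#' @export
spikeTimes <- function(train) train@times

#' @rdname SpikeDataset-class
#' @param x a [SpikeDataset-class].
#' @export
setMethod("length", "SpikeDataset", function(x) length(x@patterns))

#' @rdname SpikeDataset-class
#' @param i index.
#' @export
setMethod("[[", "SpikeDataset", function(x, i) x@patterns[[i]])

#' @rdname SpikeDataset-class
#' @param j,drop,... ignored.
#' @export
setMethod("[", "SpikeDataset", function(x, i, j, ..., drop = TRUE) {
  new("SpikeDataset", patterns = x@patterns[i],
      labels = if (length(x@labels)) x@labels[i] else character(),
      ids = x@ids[i])
})

#' Class labels of a dataset
#' @param ds a [SpikeDataset-class].
#' @return Character vector of labels (length 0 if unlabelled).
#' @export
patternLabels <- function(ds) ds@labels

#' Pattern identifiers of a dataset
#' @param ds a [SpikeDataset-class].
#' @export
patternIds <- function(ds) ds@ids

#' @rdname SNNFit-class
#' @param fit an [SNNFit-class].
#' @export
fittedModel <- function(fit) fit@model

#' @rdname SNNFit-class
#' @export
trainingHistory <- function(fit) fit@history

#' @rdname ExperimentReport-class
#' @param report an [ExperimentReport-class].
#' @param which `"train"` or `"test"`.
#' @export
trialAccuracies <- function(report, which = c("train", "test")) {
  which <- match.arg(which)
  if (which == "train") report@trainAcc else report@testAcc
}

#' @rdname ExperimentReport-class
#' @export
accuracySummary <- function(report) {
  s <- function(x) if (length(x)) c(mean = mean(x), sd = stats::sd(x)) else c(mean = NA_real_, sd = NA_real_)
  rbind(train = s(report@trainAcc), test = s(report@testAcc))
}

setMethod("show", "TimeGrid", function(object) {
  cat(sprintf("TimeGrid: %g ms period, %g ms step (%d bins)\n",
              object@period, object@delta, binCount(object)))
})

setMethod("show", "KernelConfig", function(object) {
  cat(sprintf("KernelConfig: Gaussian EPSP, mu = %g ms, sigma = %g ms, clamp = %s\n",
              object@mu, object@sigma, object@clampRule))
})

setMethod("show", "SpikePattern", function(object) {
  cat(sprintf("SpikePattern: %d neurons, %d events\n",
              object@nNeurons, length(object@time)))
  if (length(object@time)) {
    ev <- patternEvents(object)
    n <- min(nrow(ev), 8L)
    cat(paste(sprintf("  neuron %d @ %.3f ms", ev$neuron[1:n], ev$time[1:n]),
              collapse = "\n"), "\n")
    if (nrow(ev) > n) cat("  ...\n")
  }
})

setMethod("show", "SpikeTrain", function(object) {
  cat(sprintf("SpikeTrain (%s): %d spike(s)%s\n", object@kind,
              length(object@times),
              if (length(object@times))
                paste0(" at ", paste(sprintf("%.3f", object@times), collapse = ", "), " ms")
              else ""))
})

setMethod("show", "SpikeDataset", function(object) {
  cat(sprintf("SpikeDataset: %d pattern(s), %d neurons%s\n",
              length(object@patterns), nNeurons(object),
              if (length(object@labels))
                paste0(", labels: ",
                       paste(names(table(object@labels)), table(object@labels),
                             sep = "=", collapse = ", "))
              else ", unlabelled"))
})

setMethod("show", "DelaySNN", function(object) {
  cat(sprintf("DelaySNN (%s readout): %d synapses\n",
              object@kind, length(object@weights)))
  cat("  W  :", paste(sprintf("%.3f", utils::head(object@weights, 6)), collapse = " "),
      if (length(object@weights) > 6) "...", "\n")
  cat("  tau:", paste(sprintf("%.3f", utils::head(object@delays, 6)), collapse = " "),
      if (length(object@delays) > 6) "...", "ms\n")
  if (object@kind == "bb")
    cat(sprintf("  bTilde: %.4f (b+ = %g, b- = %g)\n",
                object@bTilde, object@bPlus, object@bMinus))
  show(object@kernel)
  show(object@grid)
})

setMethod("show", "DecisionBoundaries", function(object) {
  cat(sprintf("DecisionBoundaries: %d groups, thresholds at %s ms\n",
              object@nGroups,
              paste(sprintf("%.3f", object@thresholds), collapse = ", ")))
})

setMethod("show", "SNNFit", function(object) {
  cat(sprintf("SNNFit: %d snapshots up to presentation %d%s\n",
              length(object@history@presentation),
              max(object@history@presentation, 0L),
              if (is.na(object@seed)) "" else sprintf(" (seed %d)", object@seed)))
  show(object@model)
})

setMethod("show", "ExperimentReport", function(object) {
  s <- accuracySummary(object)
  cat(sprintf("ExperimentReport: %d trial(s)\n", length(object@trainAcc)))
  cat(sprintf("  train accuracy: %.1f +/- %.1f %%\n", s["train", "mean"], s["train", "sd"]))
  if (length(object@testAcc))
    cat(sprintf("  test accuracy : %.1f +/- %.1f %%\n", s["test", "mean"], s["test", "sd"]))
})
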