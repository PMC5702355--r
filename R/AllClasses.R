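#' @import methods
NULL

#' Discrete simulation time grid
#'
#' The network is simulated on a discrete time grid: an experimental period of
#' `period` milliseconds divided into bins of width `delta` milliseconds. All
#' spike times (pre- and post-synaptic) lie on the grid, i.e. they are integer
#' multiples of `delta` in `[0, period)`. A spike occupies exactly one bin.
#'
#' @slot delta numeric(1), time step in ms.
#' @slot period numeric(1), experimental time period in ms.
#'
#' @seealso [timeGrid()], [binCount()], [gridTimes()]
#' @export
setClass("TimeGrid",
  representation(delta = "numeric", period = "numeric"),
  prototype(delta = 0.05, period = 50),
  validity = function(object) {
    msg <- character()
    if (length(object@delta) != 1L || !is.finite(object@delta) || object@delta <= 0)
      msg <- c(msg, "'delta' must be a single positive number")
    if (length(object@period) != 1L || !is.finite(object@period) || object@period <= 0)
      msg <- c(msg, "'period' must be a single positive number")
    if (length(msg) == 0L) {
      bins <- object@period / object@delta
      if (abs(bins - round(bins)) > 1e-8)
        msg <- c(msg, "'period' must be an integer multiple of 'delta'")
    }
    if (length(msg)) msg else TRUE
  })

#' Temporal-relation (EPSP) kernel configuration
#'
#' The excitatory post-synaptic potential evoked by a pre-synaptic spike is
#' modelled as a Gaussian bump `g(dt) = exp(-(dt - mu)^2 / (2 sigma^2)) /
#' (sqrt(2 pi) sigma)` of the temporal difference `dt = s + tau - t` between
#' the delayed arrival time of the pre-synaptic spike and the post-synaptic
#' time `t`. The kernel peaks `mu` ms after arrival.
#'
#' Because a Gaussian is two-sided, the raw kernel responds on both sides of
#' its peak, unlike biophysical EPSP models (e.g. double-exponential
#' kernels), which are one-sided. The `clampRule` controls how the acausal
#' side is suppressed:
#' \describe{
#'   \item{"negative-dt"}{(default) `g(dt)` is clamped to exactly 0 for all
#'     `dt < 0`, wherever the kernel appears (potential, gradients,
#'     depression window). This makes the plasticity windows one-sided --
#'     in particular the synaptic window is depressing for every negative
#'     temporal difference -- and lets an output spike attract only the
#'     delayed arrivals that trail it.}
#'   \item{"future-presyn"}{clamp the contribution of an event at time `s`
#'     to the potential at time `t` whenever `s > t`: a spike not yet fired
#'     cannot contribute.}
#'   \item{"literal"}{clamp whenever `s - t < 0`, i.e. suppress
#'     contributions from spikes fired *before* `t` (the mirror image of
#'     "future-presyn"); selectable for comparison only.}
#'   \item{"none"}{no clamping.}
#' }
#'
#' @slot mu numeric(1), kernel peak offset in ms.
#' @slot sigma numeric(1), kernel width in ms.
#' @slot clampRule character(1), one of "negative-dt", "future-presyn",
#'   "literal", "none".
#'
#' @seealso [kernelConfig()], [kernelValue()]
#' @export
setClass("KernelConfig",
  representation(mu = "numeric", sigma = "numeric", clampRule = "character"),
  prototype(mu = 1.5, sigma = 1.0, clampRule = "negative-dt"),
  validity = function(object) {
    msg <- character()
    if (length(object@sigma) != 1L || !is.finite(object@sigma) || object@sigma <= 0)
      msg <- c(msg, "'sigma' must be a single positive number")
    if (length(object@mu) != 1L || !is.finite(object@mu))
      msg <- c(msg, "'mu' must be a single finite number")
    if (length(object@clampRule) != 1L ||
        !object@clampRule %in% c("negative-dt", "future-presyn", "literal", "none"))
      msg <- c(msg, paste("'clampRule' must be one of \"negative-dt\",",
                          "\"future-presyn\", \"literal\", \"none\""))
    if (length(msg)) msg else TRUE
  })

#' Spatio-temporal spike pattern
#'
#' One input sample: a set of binary events (neuron index, spike time) on the
#' discrete time grid. A neuron may carry zero, one or many spikes, but at
#' most one per (neuron, time) pair. Neuron indices are 1-based.
#'
#' @slot nNeurons integer(1), number of pre-synaptic neurons.
#' @slot neuron integer vector of event neuron indices in `[1, nNeurons]`.
#' @slot time numeric vector of event times in ms (same length as `neuron`).
#'
#' @seealso [spikePattern()], [generateToyDataset()], [encodeFeatureVector()]
#' @export
setClass("SpikePattern",
  representation(nNeurons = "integer", neuron = "integer", time = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@nNeurons) != 1L || is.na(object@nNeurons) || object@nNeurons < 1L)
      msg <- c(msg, "'nNeurons' must be a single positive integer")
    if (length(object@neuron) != length(object@time))
      msg <- c(msg, "'neuron' and 'time' must have the same length")
    if (length(object@neuron) &&
        (any(object@neuron < 1L) || any(object@neuron > object@nNeurons)))
      msg <- c(msg, "event neuron indices must lie in [1, nNeurons]")
    if (length(object@time) && any(!is.finite(object@time) | object@time < 0))
      msg <- c(msg, "event times must be finite and non-negative")
    if (anyDuplicated(paste(object@neuron, object@time)))
      msg <- c(msg, "duplicated (neuron, time) events: the pattern is binary")
    if (length(msg)) msg else TRUE
  })

#' Post-synaptic spike train
#'
#' The output of the post-synaptic neuron for one presented pattern. Under the
#' Multinoulli ("mb") readout exactly one spike is generated per pattern;
#' under the Bernoulli ("bb") readout each time bin spikes independently, so
#' the train holds zero or more times.
#'
#' @slot times numeric vector of spike times in ms, on the grid.
#' @slot kind character(1), `"mb"` or `"bb"`.
#'
#' @seealso [mbSampleSpike()], [bbSampleSpikes()], [timingSummary()]
#' @export
setClass("SpikeTrain",
  representation(times = "numeric", kind = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@kind) != 1L || !object@kind %in% c("mb", "bb"))
      msg <- c(msg, "'kind' must be \"mb\" or \"bb\"")
    else if (object@kind == "mb" && length(object@times) != 1L)
      msg <- c(msg, "an \"mb\" train carries exactly one spike")
    if (length(object@times) && any(!is.finite(object@times) | object@times < 0))
      msg <- c(msg, "spike times must be finite and non-negative")
    if (length(msg)) msg else TRUE
  })

#' Labelled collection of spike patterns
#'
#' A thin container for a list of [SpikePattern-class] objects with optional
#' per-pattern class labels and identifiers; the unit read from and written to
#' spike files and consumed by [trainModel()].
#'
#' @slot patterns list of [SpikePattern-class] objects.
#' @slot labels character vector of class labels (length 0 if unlabelled).
#' @slot ids character vector of pattern identifiers.
#'
#' @seealso [spikeDataset()], [readPatterns()], [writePatterns()]
#' @export
setClass("SpikeDataset",
  representation(patterns = "list", labels = "character", ids = "character"),
  validity = function(object) {
    msg <- character()
    n <- length(object@patterns)
    if (n && !all(vapply(object@patterns, is, logical(1), "SpikePattern")))
      msg <- c(msg, "'patterns' must contain SpikePattern objects")
    if (length(object@labels) && length(object@labels) != n)
      msg <- c(msg, "'labels' must be empty or one per pattern")
    if (length(object@ids) != n)
      msg <- c(msg, "'ids' must have one entry per pattern")
    if (n > 1L) {
      nn <- vapply(object@patterns, function(p) p@nNeurons, integer(1))
      if (length(unique(nn)) > 1L)
        msg <- c(msg, "all patterns must share the same number of neurons")
    }
    if (length(msg)) msg else TRUE
  })

#' Single-post-synaptic-neuron spiking network model
#'
#' Holds the learnable parameters of the network -- one synaptic weight
#' `W_i >= 0` and one axonal conduction delay `tau_i` (ms) per pre-synaptic
#' neuron -- together with the EPSP kernel, the time grid and the generative
#' readout kind. The Bernoulli readout ("bb") additionally carries an
#' intrinsic excitability `bTilde` adjusted by homeostatic plasticity with
#' increment `bPlus` (applied after a silent pattern) and decrement `bMinus`
#' (applied after at least one output spike). The sigmoid bias `vBias` enters
#' the learning rule only.
#'
#' @slot weights numeric vector of synaptic weights, one per neuron.
#' @slot delays numeric vector of conduction delays in ms.
#' @slot tauBounds numeric(2), clamp range for the delays in ms.
#' @slot vBias numeric(1), sigmoid bias of the generative model.
#' @slot bTilde numeric(1), intrinsic excitability (Bernoulli readout).
#' @slot bPlus,bMinus numeric(1), homeostatic step sizes.
#' @slot kind character(1), `"mb"` or `"bb"`.
#' @slot kernel a [KernelConfig-class].
#' @slot grid a [TimeGrid-class].
#'
#' @seealso [delaySNN()], [trainModel()], [potentialTrace()]
#' @export
setClass("DelaySNN",
  representation(weights = "numeric", delays = "numeric", tauBounds = "numeric",
                 vBias = "numeric", bTilde = "numeric", bPlus = "numeric",
                 bMinus = "numeric", kind = "character",
                 kernel = "KernelConfig", grid = "TimeGrid"),
  validity = function(object) {
    msg <- character()
    n <- length(object@weights)
    if (length(object@delays) != n)
      msg <- c(msg, "'weights' and 'delays' must have the same length")
    if (n && any(!is.finite(object@weights) | object@weights < 0))
      msg <- c(msg, "synaptic weights must be finite and >= 0")
    if (length(object@tauBounds) != 2L || object@tauBounds[1] > object@tauBounds[2])
      msg <- c(msg, "'tauBounds' must be (low, high) with low <= high")
    else if (n && (any(object@delays < object@tauBounds[1]) ||
                   any(object@delays > object@tauBounds[2])))
      msg <- c(msg, "delays must lie within 'tauBounds'")
    if (length(object@kind) != 1L || !object@kind %in% c("mb", "bb"))
      msg <- c(msg, "'kind' must be \"mb\" or \"bb\"")
    if (length(object@bPlus) != 1L || object@bPlus <= 0 ||
        length(object@bMinus) != 1L || object@bMinus <= 0)
      msg <- c(msg, "'bPlus' and 'bMinus' must be positive")
    if (length(msg)) msg else TRUE
  })

#' Quantile decision boundaries over post-synaptic spike timing
#'
#' `nGroups - 1` sorted timing thresholds (ms) placed at the n/nGroups
#' weighted quantiles of the pooled post-synaptic spike timings; a timing
#' exactly equal to a threshold falls in the lower group.
#'
#' @slot nGroups integer(1), number of groups.
#' @slot thresholds numeric vector of length `nGroups - 1`, non-decreasing.
#'
#' @seealso [fitBoundaries()], [assignGroup()]
#' @export
setClass("DecisionBoundaries",
  representation(nGroups = "integer", thresholds = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@nGroups) != 1L || object@nGroups < 2L)
      msg <- c(msg, "'nGroups' must be >= 2")
    if (length(object@thresholds) != object@nGroups - 1L)
      msg <- c(msg, "'thresholds' must have length nGroups - 1")
    if (is.unsorted(object@thresholds))
      msg <- c(msg, "'thresholds' must be non-decreasing")
    if (length(msg)) msg else TRUE
  })

#' Parameter trajectory of a training run
#'
#' Snapshots of the learnable parameters recorded every `historyStride`
#' presentations during [trainModel()] (plus the initial state).
#'
#' @slot presentation integer vector of presentation counters.
#' @slot weights numeric matrix, one row per snapshot, one column per neuron.
#' @slot delays numeric matrix, same shape as `weights`.
#' @slot bTilde numeric vector of intrinsic excitability snapshots.
#'
#' @export
setClass("TrainingHistory",
  representation(presentation = "integer", weights = "matrix",
                 delays = "matrix", bTilde = "numeric"),
  validity = function(object) {
    k <- length(object@presentation)
    if (nrow(object@weights) != k || nrow(object@delays) != k ||
        length(object@bTilde) != k)
      return("snapshot slots must agree in length")
    if (is.unsorted(object@presentation))
      return("'presentation' must be increasing")
    TRUE
  })

#' Result of a training run
#'
#' @slot model the trained [DelaySNN-class].
#' @slot history a [TrainingHistory-class] of parameter snapshots.
#' @slot seed numeric(1), the seed the run was started from (NA if none given).
#'
#' @seealso [trainModel()], [fittedModel()], [trainingHistory()]
#' @export
setClass("SNNFit",
  representation(model = "DelaySNN", history = "TrainingHistory",
                 seed = "numeric"))

#' Aggregated results of repeated classification trials
#'
#' Per-trial train/test accuracies (percent) from [runTrials()] together with
#' the resolved configuration and the per-trial seeds.
#'
#' @slot trainAcc,testAcc numeric vectors of per-trial accuracies in percent.
#' @slot seeds numeric vector of per-trial seeds.
#' @slot config list, the resolved experiment configuration.
#'
#' @seealso [runTrials()], [experimentConfig()]
#' @export
setClass("ExperimentReport",
  representation(trainAcc = "numeric", testAcc = "numeric",
                 seeds = "numeric", config = "list"),
  validity = function(object) {
    msg <- character()
    if (length(object@testAcc) && length(object@testAcc) != length(object@trainAcc))
      msg <- c(msg, "'testAcc' must be empty or one per trial")
    if (length(object@trainAcc) &&
        (any(object@trainAcc < 0) || any(object@trainAcc > 100)))
      msg <- c(msg, "accuracies are percentages in [0, 100]")
    if (length(msg)) msg else TRUE
  })
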