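#' Create a simulation time grid
#'
#' @param delta time step in ms.
#' @param period experimental time period in ms.
#' @return A [TimeGrid-class] object.
#' @examples
#' g <- timeGrid()          # 50 ms at 0.05 ms resolution, 1000 bins
#' binCount(g)
#' @export
timeGrid <- function(delta = 0.05, period = 50) {
  new("TimeGrid", delta = as.numeric(delta), period = as.numeric(period))
}

#' Create an EPSP kernel configuration
#'
#' @param mu kernel peak offset in ms.
#' @param sigma kernel width in ms.
#' @param clampRule causality clamp rule, see [KernelConfig-class].
#' @return A [KernelConfig-class] object.
#' @export
kernelConfig <- function(mu = 1.5, sigma = 1.0,
                         clampRule = c("negative-dt", "future-presyn",
                                       "literal", "none")) {
  new("KernelConfig", mu = as.numeric(mu), sigma = as.numeric(sigma),
      clampRule = match.arg(clampRule))
}

#' Create a spike pattern
#'
#' Events are given as parallel vectors of 1-based neuron indices and spike
#' times in ms. Times are snapped to the nearest grid bin (ties toward the
#' earlier bin) when `snap = TRUE`; off-grid times are an error otherwise.
#' An empty pattern (no events) is legal.
#'
#' @param neuron integer vector of event neuron indices.
#' @param time numeric vector of event times in ms.
#' @param nNeurons number of pre-synaptic neurons.
#' @param grid a [TimeGrid-class].
#' @param snap snap times to the grid instead of requiring exact grid times.
#' @return A [SpikePattern-class] object.
#' @examples
#' p <- spikePattern(neuron = 1:3, time = c(1, 5, 13), nNeurons = 3)
#' nEvents(p)
#' @export
spikePattern <- function(neuron, time, nNeurons, grid = timeGrid(), snap = TRUE) {
  neuron <- as.integer(neuron)
  time <- as.numeric(time)
  if (snap) {
    time <- snapToGrid(time, grid)
  } else {
    off <- abs(time / grid@delta - round(time / grid@delta)) > 1e-6
    if (any(off))
      stop("event times not on the grid: ", paste(time[off], collapse = ", "))
  }
  if (length(time) && any(time >= grid@period))
    stop("event times must be < period (", grid@period, " ms)")
  new("SpikePattern", nNeurons = as.integer(nNeurons),
      neuron = neuron, time = time)
}

#' Create a post-synaptic spike train
#'
#' @param times numeric vector of spike times in ms (exactly one for `"mb"`).
#' @param kind `"mb"` (single-spike Multinoulli readout) or `"bb"`
#'   (independent-bin Bernoulli readout).
#' @return A [SpikeTrain-class] object.
#' @export
spikeTrain <- function(times, kind = c("mb", "bb")) {
  new("SpikeTrain", times = as.numeric(times), kind = match.arg(kind))
}

#' Bundle spike patterns into a dataset
#'
#' @param patterns list of [SpikePattern-class] objects.
#' @param labels optional character vector of class labels, one per pattern.
#' @param ids optional character vector of pattern identifiers.
#' @return A [SpikeDataset-class] object.
#' @export
spikeDataset <- function(patterns, labels = character(), ids = NULL) {
  if (is(patterns, "SpikePattern")) patterns <- list(patterns)
  if (is.null(ids))
    ids <- if (length(patterns)) paste0("p", seq_along(patterns)) else character()
  if (is.factor(labels)) labels <- as.character(labels)
  if (length(labels) && anyNA(labels)) stop("labels must not contain NA")
  new("SpikeDataset", patterns = patterns,
      labels = as.character(labels), ids = as.character(ids))
}

#' Create a network model
#'
#' Constructs the model with the standard initialization unless overridden:
#' all synaptic weights at 1 and conduction delays drawn uniformly from
#' `delayInit` (clamped to `tauBounds`). The Bernoulli readout's intrinsic
#' excitability defaults to `-log(bins - 1)`, i.e. one expected spontaneous
#' output spike per pattern when the membrane potential is flat at zero.
#'
#' @param nNeurons number of pre-synaptic neurons.
#' @param kind generative readout, `"mb"` or `"bb"`.
#' @param weights initial synaptic weights (recycled to `nNeurons`).
#' @param delays initial conduction delays in ms; if `NULL`, drawn from
#'   `runif(nNeurons, delayInit[1], delayInit[2])`.
#' @param delayInit range of the uniform delay initialization in ms.
#' @param tauBounds clamp range for the delays in ms.
#' @param vBias sigmoid bias of the generative model.
#' @param bTilde initial intrinsic excitability (`"bb"` only); `NULL` for the
#'   default described above.
#' @param bPlus,bMinus homeostatic increment / decrement.
#' @param kernel a [KernelConfig-class].
#' @param grid a [TimeGrid-class].
#' @return A [DelaySNN-class] object.
#' @examples
#' set.seed(1)
#' m <- delaySNN(3)
#' conductionDelays(m)
#' @export
delaySNN <- function(nNeurons, kind = c("mb", "bb"), weights = 1, delays = NULL,
                     delayInit = c(5, 15), tauBounds = c(0, 20), vBias = 10,
                     bTilde = NULL, bPlus = 0.01, bMinus = 1e-04,
                     kernel = kernelConfig(), grid = timeGrid()) {
  kind <- match.arg(kind)
  nNeurons <- as.integer(nNeurons)
  if (is.null(delays))
    delays <- stats::runif(nNeurons, delayInit[1], delayInit[2])
  if (is.null(bTilde))
    bTilde <- -log(binCount(grid) - 1)
  new("DelaySNN",
      weights = rep_len(as.numeric(weights), nNeurons),
      delays = pmin(pmax(as.numeric(delays), tauBounds[1]), tauBounds[2]),
      tauBounds = as.numeric(tauBounds), vBias = as.numeric(vBias),
      bTilde = as.numeric(bTilde), bPlus = as.numeric(bPlus),
      bMinus = as.numeric(bMinus), kind = kind, kernel = kernel, grid = grid)
}
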