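# Core generative model: EPSP kernel, membrane potential, spike generation.

# scalar/vector Gaussian density, the unclamped EPSP shape
.gauss <- function(dt, mu, sigma) {
  exp(-((dt - mu)^2) / (2 * sigma^2)) / (sqrt(2 * pi) * sigma)
}

.sigmoid <- function(u) 1 / (1 + exp(-u))

# TRUE where the clamp suppresses a kernel contribution
.clamped <- function(dt, s, t, clampRule) {
  switch(clampRule,
         "negative-dt" = dt < 0,
         "future-presyn" = s > t,
         "literal" = s < t,
         "none" = rep(FALSE, length.out = max(length(dt), length(s), length(t))))
}

#' EPSP kernel value
#'
#' Evaluates the Gaussian temporal-relation kernel
#' `g(dt) = exp(-(dt - mu)^2 / (2 sigma^2)) / (sqrt(2 pi) sigma)` at the
#' temporal difference `dt = s + tau - t`, applying the causality clamp of
#' `kernel`: under the default `"negative-dt"` rule the value is exactly 0
#' for `dt < 0`, in analogy to double-exponential EPSP models which vanish
#' for negative temporal differences. The kernel peaks at `dt = mu`, where
#' it equals `1 / (sqrt(2 pi) sigma)`. See [KernelConfig-class] for the
#' alternative clamp rules.
#'
#' @param dt temporal difference `s + tau - t` in ms (vectorized).
#' @param s pre-synaptic spike time in ms (vectorized, recycled; used by the
#'   `"future-presyn"` and `"literal"` rules only).
#' @param t post-synaptic time in ms (vectorized, recycled).
#' @param kernel a [KernelConfig-class].
#' @return Kernel values, same length as the longest argument.
#' @examples
#' kernelValue(1.5, s = 0, t = 10)   # peak: 1 / sqrt(2 * pi)
#' kernelValue(-0.5, s = 0, t = 10)  # clamped: 0
#' @export
kernelValue <- function(dt, s, t, kernel = kernelConfig()) {
  g <- .gauss(dt, kernel@mu, kernel@sigma)
  cl <- .clamped(dt, s, t, kernel@clampRule)
  g * as.numeric(!cl)
}

# Membrane potential over the whole grid from raw event vectors.
# Kept free of S4 dispatch: this is the inner-loop workhorse.
.traceRaw <- function(evNeuron, evTime, W, tau, mu, sigma, clampRule, tGrid) {
  v <- numeric(length(tGrid))
  for (e in seq_along(evTime)) {
    dt <- evTime[e] + tau[evNeuron[e]] - tGrid
    g <- exp(-((dt - mu)^2) / (2 * sigma^2))
    if (clampRule == "negative-dt") {
      g[dt < 0] <- 0
    } else if (clampRule == "future-presyn") {
      g[tGrid < evTime[e]] <- 0
    } else if (clampRule == "literal") {
      g[tGrid > evTime[e]] <- 0
    }
    v <- v + (W[evNeuron[e]] / (sqrt(2 * pi) * sigma)) * g
  }
  v
}

#' Membrane potential trace
#'
#' The post-synaptic membrane potential `v_t` at every grid time, i.e. the
#' linear superposition of the per-event EPSPs: each event (neuron `i`, time
#' `s`) contributes `W_i * g(s + tau_i - t)`.
#'
#' @param pattern a [SpikePattern-class].
#' @param model a [DelaySNN-class] sized to the pattern.
#' @return Numeric vector of length `binCount(grid)`.
#' @examples
#' m <- delaySNN(1, delays = 10)
#' p <- spikePattern(1, 0, nNeurons = 1)
#' max(potentialTrace(p, m))   # ~ g(mu) = 1/sqrt(2*pi) for W = 1
#' @export
potentialTrace <- function(pattern, model) {
  .checkDims(pattern, model)
  .traceRaw(pattern@neuron, pattern@time, model@weights, model@delays,
            model@kernel@mu, model@kernel@sigma, model@kernel@clampRule,
            gridTimes(model@grid))
}

.checkDims <- function(pattern, model) {
  if (pattern@nNeurons != length(model@weights))
    stop("pattern has ", pattern@nNeurons, " neurons but the model has ",
         length(model@weights), " synapses")
  invisible(TRUE)
}

#' Multinoulli single-spike timing distribution
#'
#' Under the Multinoulli readout the post-synaptic neuron emits exactly one
#' spike per pattern, at a time drawn from the softmax of the membrane
#' potential over the grid: `p(z_t = 1 | x) = exp(v_t) / sum_t' exp(v_t')`.
#' The distribution is strictly positive everywhere (a spike can occur even
#' before the first pre-synaptic spike arrives) and invariant to adding a
#' constant to the whole trace.
#'
#' @inheritParams potentialTrace
#' @return Probability vector over the grid bins (sums to 1).
#' @export
mbSpikeDistribution <- function(pattern, model) {
  v <- potentialTrace(pattern, model)
  w <- exp(v - max(v))
  w / sum(w)
}

#' Sample the Multinoulli post-synaptic spike
#'
#' Draws one spike time from [mbSpikeDistribution()] using the current RNG
#' state.
#'
#' @inheritParams potentialTrace
#' @return A [SpikeTrain-class] with exactly one spike.
#' @export
mbSampleSpike <- function(pattern, model) {
  v <- potentialTrace(pattern, model)
  w <- exp(v - max(v))
  bin <- sample.int(length(w), 1L, prob = w)
  spikeTrain((bin - 1L) * model@grid@delta, kind = "mb")
}

#' Bernoulli per-bin spike probabilities
#'
#' Under the Bernoulli readout every grid bin spikes independently with
#' probability `sigm(v_t + bTilde)`, where `bTilde` is the intrinsic
#' excitability. Unlike the Multinoulli readout this requires no anti-causal
#' normalization over future potentials.
#'
#' @inheritParams potentialTrace
#' @return Probability vector over the grid bins (each in (0, 1)).
#' @export
bbSpikeProbabilities <- function(pattern, model) {
  v <- potentialTrace(pattern, model)
  .sigmoid(v + model@bTilde)
}

#' Sample the Bernoulli post-synaptic spike train
#'
#' Independent Bernoulli draw per bin from [bbSpikeProbabilities()]; the
#' train may be empty or carry many spikes.
#'
#' @inheritParams potentialTrace
#' @return A [SpikeTrain-class] of kind `"bb"`.
#' @export
bbSampleSpikes <- function(pattern, model) {
  p <- bbSpikeProbabilities(pattern, model)
  bins <- which(stats::runif(length(p)) < p)
  spikeTrain((bins - 1L) * model@grid@delta, kind = "bb")
}
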