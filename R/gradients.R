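# Stochastic-EM gradients of the evidence lower bound w.r.t. the conduction
# delays and synaptic weights, plus the parameter / homeostatic updates.

# g(dt') over the depression window, restricted to its numerical support.
# Terms with g(dt') this small contribute < 1e-15 to the depression sum, far
# below the 1e-10 agreement guaranteed against brute-force summation. Under
# the "negative-dt" clamp the kernel vanishes for dt' < 0, so that half of
# the window drops out exactly.
.depressionSupport <- function(mu, sigma, delta, span,
                               clampRule = "negative-dt") {
  dtp <- seq(-span, span, by = delta)
  if (clampRule == "negative-dt") dtp <- dtp[dtp >= 0]
  g <- .gauss(dtp, mu, sigma)
  g[g >= 1e-12]
}

# depression term per synapse: delta * sum_dt' sigm(W_i g(dt') - v) g(dt')
.depRaw <- function(W, vBias, gsup, delta) {
  S <- .sigmoid(outer(gsup, W) - vBias)   # |support| x N
  delta * colSums(S * gsup)
}

# per-presentation gradients from raw vectors (inner-loop workhorse)
.gradsRaw <- function(evNeuron, evTime, postTimes, W, tau, mu, sigma,
                      clampRule, dep) {
  N <- length(W)
  dgrad <- numeric(N)
  wpot <- numeric(N)
  K <- length(postTimes)
  if (K && length(evTime)) {
    ar <- evTime + tau[evNeuron]
    dtM <- outer(ar, postTimes, "-")          # events x post spikes
    gM <- .gauss(dtM, mu, sigma)
    if (clampRule == "negative-dt") {
      gM[dtM < 0] <- 0
    } else if (clampRule == "future-presyn") {
      gM[outer(evTime, postTimes, ">")] <- 0
    } else if (clampRule == "literal") {
      gM[outer(evTime, postTimes, "<")] <- 0
    }
    dcomp <- -W[evNeuron] * rowSums(gM * (dtM - mu)) / sigma^2
    pcomp <- rowSums(gM)
    for (e in seq_along(evNeuron)) {
      i <- evNeuron[e]
      dgrad[i] <- dgrad[i] + dcomp[e]
      wpot[i] <- wpot[i] + pcomp[e]
    }
  }
  list(delay = dgrad, potentiation = wpot, nPost = K)
}

#' Conduction-delay gradient
#'
#' Gradient of the evidence lower bound with respect to each conduction delay
#' for one presented pattern and one post-synaptic spike train, in the
#' simplified form used for training:
#' `grad_i = -sum_(t, s) x_is g(dt) W_i (dt - mu) / sigma^2` with
#' `dt = s + tau_i - t`, summed over the post-synaptic spikes `t` and the
#' events `(i, s)` of synapse `i`. The sign realises the delay-learning
#' window: the delay grows when the delayed arrival precedes the kernel peak
#' (`dt < mu`) and shrinks when it trails it, so post-synaptic spikes attract
#' nearby pre-synaptic arrivals.
#'
#' The same per-spike form serves both readouts; under the Bernoulli readout
#' it is summed over all spikes of the train and an empty train yields a zero
#' gradient.
#'
#' @param pattern a [SpikePattern-class].
#' @param post a [SpikeTrain-class].
#' @param model a [DelaySNN-class].
#' @return Numeric vector of gradient components, one per synapse.
#' @seealso [weightGradient()], [applyUpdate()], [plasticityWindows()]
#' @export
delayGradient <- function(pattern, post, model) {
  .checkDims(pattern, model)
  k <- model@kernel
  .gradsRaw(pattern@neuron, pattern@time, post@times, model@weights,
            model@delays, k@mu, k@sigma, k@clampRule, dep = NULL)$delay
}

#' Synaptic-weight gradient
#'
#' Gradient of the evidence lower bound with respect to each synaptic weight
#' for one presented pattern and post-synaptic train. Per post-synaptic spike
#' `t` the component of synapse `i` is a potentiation term
#' `sum_s x_is g(dt)` minus a depression term
#' `delta * sum_dt' sigm(W_i g(dt') - v) g(dt')`, where `dt'` steps by the
#' grid resolution `delta` over `[-dtPrimeSpan, +dtPrimeSpan]`. The `delta`
#' factor makes the depression term (a Riemann sum) robust to the grid
#' resolution. Together the two terms form an STDP-like window: potentiation
#' when the delayed pre-synaptic arrival slightly precedes the post-synaptic
#' spike, depression otherwise, and weaker net potentiation at larger
#' weights.
#'
#' Summed over the spikes of the train, so the depression term is applied
#' once per post-synaptic spike and an empty (Bernoulli) train yields a zero
#' gradient.
#'
#' @inheritParams delayGradient
#' @param dtPrimeSpan half-width in ms of the depression window; defaults to
#'   the full experimental period (the kernel decays to numerical zero far
#'   sooner, so the choice is immaterial).
#' @return Numeric vector of gradient components, one per synapse.
#' @seealso [weightDepression()], [delayGradient()]
#' @export
weightGradient <- function(pattern, post, model, dtPrimeSpan = NULL) {
  .checkDims(pattern, model)
  k <- model@kernel
  g <- .gradsRaw(pattern@neuron, pattern@time, post@times, model@weights,
                 model@delays, k@mu, k@sigma, k@clampRule, dep = NULL)
  if (g$nPost == 0L) return(numeric(length(model@weights)))
  dep <- weightDepression(model, dtPrimeSpan)
  g$potentiation - g$nPost * dep
}

#' Depression term of the weight gradient
#'
#' `delta * sum_dt' sigm(W_i g(dt') - v) g(dt')` per synapse, evaluated over
#' the symmetric window `[-dtPrimeSpan, +dtPrimeSpan]` stepped by the grid
#' resolution. Non-negative and strictly increasing in the synaptic weight.
#'
#' @inheritParams weightGradient
#' @param model a [DelaySNN-class].
#' @return Numeric vector, one value per synapse.
#' @export
weightDepression <- function(model, dtPrimeSpan = NULL) {
  if (is.null(dtPrimeSpan)) dtPrimeSpan <- model@grid@period
  gsup <- .depressionSupport(model@kernel@mu, model@kernel@sigma,
                             model@grid@delta, dtPrimeSpan,
                             model@kernel@clampRule)
  .depRaw(model@weights, model@vBias, gsup, model@grid@delta)
}

#' Unsimplified conduction-delay gradient
#'
#' The delay gradient before dropping the sigmoid term: per post-synaptic
#' spike `t` and *every* grid time `s`,
#' `(x_is - sigm(W_i g(dt) - v)) g(dt) W_i (-(dt - mu) / sigma^2)`.
#' The dropped sigmoid part is an approximately odd-symmetric sum about
#' `dt = mu` and nearly cancels, which is why the simplified
#' [delayGradient()] is used for training; this form exists to verify that
#' claim numerically.
#'
#' @inheritParams delayGradient
#' @return Numeric vector of gradient components, one per synapse.
#' @export
delayGradientFull <- function(pattern, post, model) {
  .checkDims(pattern, model)
  k <- model@kernel
  tGrid <- gridTimes(model@grid)
  N <- length(model@weights)
  grad <- numeric(N)
  for (i in seq_len(N)) {
    x <- numeric(length(tGrid))
    sEv <- pattern@time[pattern@neuron == i]
    x[round(sEv / model@grid@delta) + 1L] <- 1
    for (t in post@times) {
      dt <- tGrid + model@delays[i] - t
      gv <- kernelValue(dt, s = tGrid, t = t, kernel = k)
      grad[i] <- grad[i] + sum(
        (x - .sigmoid(model@weights[i] * gv - model@vBias)) *
          gv * model@weights[i] * (-(dt - k@mu) / k@sigma^2))
    }
  }
  grad
}

#' Apply one gradient-ascent update
#'
#' `theta <- theta + eta * grad`, followed by the hard constraints: weights
#' are clamped at zero from below and delays into `tauBounds`. When
#' `delayLearning` is `FALSE` the delays are left untouched (the fixed-delay
#' ablation), regardless of the supplied delay gradient.
#'
#' @param model a [DelaySNN-class].
#' @param delayGrad,weightGrad gradient vectors, one component per synapse.
#' @param eta learning rate.
#' @param delayLearning update the conduction delays?
#' @return The updated [DelaySNN-class].
#' @export
applyUpdate <- function(model, delayGrad, weightGrad, eta = 0.001,
                        delayLearning = TRUE) {
  if (length(delayGrad) != length(model@weights) ||
      length(weightGrad) != length(model@weights))
    stop("gradient length must match the number of synapses")
  model@weights <- pmax(model@weights + eta * weightGrad, 0)
  if (delayLearning)
    model@delays <- pmin(pmax(model@delays + eta * delayGrad,
                              model@tauBounds[1]), model@tauBounds[2])
  validObject(model)
  model
}

#' Homeostatic excitability update
#'
#' After each presented pattern the Bernoulli readout's intrinsic
#' excitability is nudged toward a regular firing regime: decreased by
#' `bMinus` if the neuron spiked at least once, increased by `bPlus` if it
#' stayed silent. With the defaults (`bPlus = 0.01`, `bMinus = 1e-4`) the
#' equilibrium leaves about one pattern in a hundred silent.
#'
#' @param model a [DelaySNN-class] of kind `"bb"`.
#' @param post the sampled [SpikeTrain-class] for the presented pattern.
#' @return The updated model.
#' @export
homeostaticUpdate <- function(model, post) {
  if (model@kind != "bb")
    stop("homeostatic plasticity applies to the \"bb\" readout only")
  model@bTilde <- if (length(post@times) > 0)
    model@bTilde - model@bMinus else model@bTilde + model@bPlus
  model
}

#' Teacher spike train for weakly supervised learning
#'
#' Supervision never dictates absolute spike timings: the sampled
#' post-synaptic spikes are merely nudged in the direction their class should
#' move. Classes are ranked by the ascending mean timing the current model
#' assigns them; every sampled spike of a class in the earliest half of the
#' ranking is shifted `d` ms earlier, in the latest half `d` ms later, and an
#' exact middle rank (odd group counts) is left in place. Shifted times are
#' clipped to `[0, period - delta]`. An empty sampled train is returned
#' unchanged -- no teacher spike is fabricated.
#'
#' @param sampled the sampled [SpikeTrain-class].
#' @param groupRank 1-based rank of the pattern's class (1 = earliest mean
#'   timing).
#' @param nGroups number of classes.
#' @param d teacher offset in ms (typically the grid step).
#' @param grid a [TimeGrid-class].
#' @return A [SpikeTrain-class] with shifted times.
#' @export
teacherSpikeTrain <- function(sampled, groupRank, nGroups, d, grid = timeGrid()) {
  if (length(sampled@times) == 0L) return(sampled)
  if (groupRank < 1 || groupRank > nGroups)
    stop("'groupRank' must lie in [1, nGroups]")
  shift <- if (groupRank <= nGroups / 2) -d
           else if (groupRank > (nGroups + 1) / 2) d
           else 0
  tt <- snapToGrid(sampled@times + shift, grid)
  tt <- pmin(pmax(tt, 0), grid@period - grid@delta)
  spikeTrain(tt, kind = sampled@kind)
}
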