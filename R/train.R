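# Stochastic-EM training loop: sample a pattern, sample the latent
# post-synaptic spike(s) (E-step), take one gradient-ascent step on the
# delays and weights (M-step); optionally replace the sampled train by a
# teacher-shifted one (supervised mode) and adjust the intrinsic
# excitability (Bernoulli readout). The per-presentation arithmetic lives in
# src/train.cpp; the exported R functions (potentialTrace, delayGradient,
# weightGradient, ...) are the reference implementation the compiled loop is
# tested against.

# assemble the .cppTrain argument list (shared by trainModel and the tests)
.trainArgs <- function(model, dataset, eta, nPresentations, delayLearning,
                       supervised, dShift, dtPrimeSpan, historyStride,
                       rankStride) {
  grid <- model@grid
  kern <- model@kernel
  if (is.null(dShift)) dShift <- grid@delta
  if (is.null(dtPrimeSpan)) dtPrimeSpan <- grid@period
  cls <- integer(length(dataset))
  nClasses <- 0L
  if (supervised) {
    labels <- patternLabels(dataset)
    if (length(labels) != length(dataset))
      stop("supervised training requires one label per pattern")
    lev <- sort(unique(labels))
    cls <- match(labels, lev)
    nClasses <- length(lev)
  }
  list(evNeuron = lapply(dataset@patterns, function(p) p@neuron),
       evTime = lapply(dataset@patterns, function(p) p@time),
       cls = cls, nClasses = nClasses,
       W0 = model@weights, tau0 = model@delays, bTilde0 = model@bTilde,
       isBB = model@kind == "bb", vBias = model@vBias,
       bPlus = model@bPlus, bMinus = model@bMinus,
       mu = kern@mu, sigma = kern@sigma,
       clampRule = match(kern@clampRule,
                         c("future-presyn", "literal", "none", "negative-dt")) - 1L,
       delta = grid@delta, bins = binCount(grid),
       gsup = .depressionSupport(kern@mu, kern@sigma, grid@delta, dtPrimeSpan,
                                 kern@clampRule),
       eta = eta, nPres = as.integer(nPresentations),
       delayLearning = delayLearning, supervised = supervised,
       dShift = dShift, tauLow = model@tauBounds[1],
       tauHigh = model@tauBounds[2],
       historyStride = as.integer(historyStride),
       rankStride = as.integer(rankStride))
}

#' Train the network by stochastic EM
#'
#' Presents `nPresentations` patterns drawn uniformly at random (with
#' replacement) from the dataset. For each presentation the post-synaptic
#' spike train is sampled from the current generative model (the E-step),
#' then the conduction delays and synaptic weights take one gradient-ascent
#' step of size `eta` on the evidence lower bound (the M-step), with delays
#' clamped into the model's `tauBounds` and weights at zero from below.
#'
#' In supervised mode the sampled train is replaced, before the gradient
#' step, by a teacher train shifted `dShift` ms earlier or later according to
#' the pattern's class (see [teacherSpikeTrain()]); the class ranking by mean
#' model timing is recomputed every `rankStride` presentations. Under the
#' Bernoulli readout the homeostatic excitability update always uses the
#' *sampled* (pre-shift) train. With `delayLearning = FALSE` the delays stay
#' at their initial values and only the weights learn (the fixed-delay
#' ablation).
#'
#' Training runs until the parameters reach their converged regime; for the
#' three-neuron toy task with the default learning rate this takes on the
#' order of 1e5 presentations (the delays move first and align the delayed
#' arrivals, then the weights grow and the output timing distribution
#' sharpens).
#'
#' @param model a [DelaySNN-class] with initial parameters.
#' @param dataset a [SpikeDataset-class]; must be labelled in supervised mode.
#' @param eta learning rate.
#' @param nPresentations number of single-pattern presentations.
#' @param delayLearning update the conduction delays?
#' @param supervised use teacher-shifted spike trains?
#' @param dShift teacher offset in ms; default = the grid step.
#' @param dtPrimeSpan half-width of the depression window in ms; default =
#'   the experimental period.
#' @param historyStride record a parameter snapshot every this many
#'   presentations.
#' @param rankStride recompute the supervised class ranking every this many
#'   presentations.
#' @param seed optional integer seed (`set.seed` is called if given).
#' @return An [SNNFit-class] holding the trained model and the parameter
#'   trajectory.
#' @examples
#' toy <- generateToyDataset(5, seed = 1)
#' m <- delaySNN(3, delays = c(10, 10, 10))
#' fit <- trainModel(m, toy, nPresentations = 50, seed = 1)
#' fittedModel(fit)
#' @export
trainModel <- function(model, dataset, eta = 0.001, nPresentations = 250000,
                       delayLearning = TRUE, supervised = FALSE,
                       dShift = NULL, dtPrimeSpan = NULL,
                       historyStride = 500, rankStride = 1000, seed = NULL) {
  if (!is(dataset, "SpikeDataset")) dataset <- spikeDataset(dataset)
  if (length(dataset) == 0L) stop("the dataset is empty")
  if (nNeurons(dataset) != nNeurons(model))
    stop("dataset and model disagree on the number of neurons")
  if (nPresentations < 1L) stop("'nPresentations' must be >= 1")
  if (eta < 0) stop("'eta' must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  args <- .trainArgs(model, dataset, eta, nPresentations, delayLearning,
                     supervised, dShift, dtPrimeSpan, historyStride,
                     rankStride)
  out <- do.call(.cppTrain, c(args, traceFirst = 0L))
  model@weights <- out$W
  model@delays <- out$tau
  model@bTilde <- out$bTilde
  history <- new("TrainingHistory", presentation = out$histP,
                 weights = out$histW, delays = out$histTau,
                 bTilde = out$histB)
  new("SNNFit", model = model, history = history,
      seed = if (is.null(seed)) NA_real_ else as.numeric(seed))
}
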