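# Experiment drivers: plasticity-window curves, repeated seeded
# classification trials, and checkpoint accuracy along a training run.

#' Plasticity windows of the learning rule
#'
#' Evaluates the learning-rate-scaled parameter changes for a single
#' pre-synaptic spike (at `s = 0`, delay `tauRef`) paired with a single
#' post-synaptic spike placed so that the temporal difference
#' `dt = s + tau - t` sweeps `dtGrid`:
#' the delay-learning window `dTau(dt)`, the STDP-like synaptic window
#' `dW(dt)`, and the weight dependence `dW(W)` at fixed temporal differences
#' `dtFixed`. The delay window crosses zero at `dt = mu` (the kernel peak)
#' and is positive below it; the weight window is positive near `dt = mu`,
#' negative for negative `dt`, and shrinks with growing weight.
#'
#' @param dtGrid temporal differences to sweep, in ms (must keep the implied
#'   post time `tauRef - dt` inside the grid).
#' @param weight synaptic weight used for the two `dt` sweeps.
#' @param wGrid weights for the `dW(W)` curve.
#' @param dtFixed temporal differences (ms) at which `dW(W)` is traced.
#' @param tauRef reference conduction delay in ms.
#' @param eta learning rate scaling the reported changes.
#' @param vBias sigmoid bias.
#' @param kernel a [KernelConfig-class].
#' @param grid a [TimeGrid-class].
#' @return List of data frames: `delay` (dt, dTau), `weight` (dt, dW) and
#'   `weightVsW` (dt, W, dW).
#' @export
plasticityWindows <- function(dtGrid = seq(-5, 8, by = 0.05), weight = 1,
                              wGrid = c(0.5, 1, 2, 5, 10),
                              dtFixed = c(1.5, -5), tauRef = 10, eta = 0.001,
                              vBias = 10, kernel = kernelConfig(),
                              grid = timeGrid()) {
  pat <- spikePattern(1L, 0, nNeurons = 1L, grid = grid)
  pairChange <- function(w, dt) {
    m <- delaySNN(1L, weights = w, delays = tauRef, vBias = vBias,
                  kernel = kernel, grid = grid)
    tPost <- snapToGrid(tauRef - dt, grid)
    if (tPost < 0 || tPost >= grid@period)
      stop("dt = ", dt, " puts the post-synaptic spike outside the grid")
    post <- spikeTrain(tPost, "mb")
    c(dTau = eta * delayGradient(pat, post, m)[1],
      dW = eta * weightGradient(pat, post, m)[1])
  }
  sweep <- vapply(dtGrid, function(dt) pairChange(weight, dt), numeric(2))
  byW <- expand.grid(W = wGrid, dt = dtFixed)
  byW$dW <- mapply(function(w, dt) pairChange(w, dt)["dW"], byW$W, byW$dt)
  list(delay = data.frame(dt = dtGrid, dTau = sweep["dTau", ]),
       weight = data.frame(dt = dtGrid, dW = sweep["dW", ]),
       weightVsW = byW[c("dt", "W", "dW")])
}

#' Experiment configuration
#'
#' Resolves an experiment configuration with explicit defaults for every
#' hyperparameter of the toy-pattern study conditions. Unknown keys are an
#' error.
#'
#' @param ... overrides of the default keys, either as named arguments or a
#'   single named list.
#' @return Named list with the resolved configuration.
#' @export
experimentConfig <- function(...) {
  defaults <- list(
    model = "mb", supervised = FALSE, delayLearning = TRUE,
    nPresentations = 250000, nPerClass = 50, nGroups = 2,
    eta = 0.001, delta = 0.05, period = 50, mu = 1.5, sigma = 1,
    clampRule = "negative-dt", vBias = 10, bPlus = 0.01, bMinus = 1e-04,
    bTilde = NULL, dShift = NULL, tauBounds = c(0, 20), delayInit = c(5, 15),
    weightInit = 1, historyStride = 500, rankStride = 1000,
    baseA = c(1, 5, 13), baseB = c(13, 9, 1), jitter = 1)
  over <- list(...)
  if (length(over) == 1L && is.null(names(over)) && is.list(over[[1]]))
    over <- over[[1]]
  bad <- setdiff(names(over), names(defaults))
  if (length(bad)) stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  defaults[names(over)] <- over
  if (!defaults$model %in% c("mb", "bb")) stop("'model' must be \"mb\" or \"bb\"")
  defaults
}

#' Read an experiment configuration from JSON
#'
#' @param path JSON file with a flat object of configuration keys (see
#'   [experimentConfig()]). Bundled examples live in
#'   `system.file("configs", package = "delaysnn")`.
#' @return Resolved configuration list.
#' @export
readConfig <- function(path) {
  experimentConfig(jsonlite::fromJSON(path))
}

.configGrid <- function(config) timeGrid(config$delta, config$period)

.configModel <- function(config, grid) {
  delaySNN(length(config$baseA), kind = config$model,
           weights = config$weightInit, delayInit = config$delayInit,
           tauBounds = config$tauBounds, vBias = config$vBias,
           bTilde = config$bTilde, bPlus = config$bPlus, bMinus = config$bMinus,
           kernel = kernelConfig(config$mu, config$sigma, config$clampRule),
           grid = grid)
}

#' Run repeated seeded classification trials
#'
#' For each trial: draw a fresh seed, generate (or obtain) a labelled
#' train/test split, initialize the model with the standard initialization
#' (weights at `weightInit`, delays uniform over `delayInit`), train with
#' [trainModel()] under the configuration, then classify both splits with
#' [evaluateModel()] (boundaries and group-to-class mapping fitted on the
#' training split and frozen for test). Reports per-trial accuracies in
#' percent.
#'
#' @param config configuration from [experimentConfig()].
#' @param nTrials number of trials.
#' @param seed integer master seed; per-trial seeds are drawn from it, so the
#'   whole report is reproducible.
#' @param makeData optional `function(trial)` returning
#'   `list(train = , test = )` of labelled [SpikeDataset-class] objects (it
#'   runs under the trial's seed); the default generates the toy dataset
#'   with `nPerClass` train and `nPerClass` test patterns per class.
#' @param verbose print one line per trial.
#' @return An [ExperimentReport-class].
#' @examples
#' \donttest{
#' cfg <- experimentConfig(nPresentations = 2000, nPerClass = 10)
#' runTrials(cfg, nTrials = 2, seed = 1)
#' }
#' @export
runTrials <- function(config = experimentConfig(), nTrials = 20, seed = 1,
                      makeData = NULL, verbose = FALSE) {
  if (nTrials < 1L) stop("'nTrials' must be >= 1")
  grid <- .configGrid(config)
  if (is.null(makeData))
    makeData <- function(trial) {
      gen <- function() generateToyDataset(config$nPerClass, config$baseA,
                                           config$baseB, config$jitter, grid)
      list(train = gen(), test = gen())
    }
  set.seed(seed)
  trialSeeds <- sample.int(.Machine$integer.max - 1L, nTrials)
  trainAcc <- numeric(nTrials)
  testAcc <- numeric(nTrials)
  for (k in seq_len(nTrials)) {
    set.seed(trialSeeds[k])
    data <- makeData(k)
    model <- .configModel(config, grid)
    fit <- trainModel(model, data$train, eta = config$eta,
                      nPresentations = config$nPresentations,
                      delayLearning = config$delayLearning,
                      supervised = config$supervised, dShift = config$dShift,
                      historyStride = config$historyStride,
                      rankStride = config$rankStride)
    res <- evaluateModel(fittedModel(fit), data$train, data$test,
                         nGroups = config$nGroups)
    trainAcc[k] <- 100 * res$trainAccuracy
    testAcc[k] <- 100 * res$testAccuracy
    if (verbose)
      message(sprintf("trial %d/%d (seed %d): train %.1f %%, test %.1f %%",
                      k, nTrials, trialSeeds[k], trainAcc[k], testAcc[k]))
  }
  new("ExperimentReport", trainAcc = trainAcc,
      testAcc = testAcc[!is.na(testAcc)], seeds = as.numeric(trialSeeds),
      config = config)
}

#' Accuracy along a training trajectory
#'
#' Replays the parameter snapshots of a fit and evaluates the classification
#' accuracy at each checkpoint, refitting the decision boundaries and the
#' group-to-class mapping at every checkpoint (each is an independent
#' read-out of the then-current model).
#'
#' @param fit an [SNNFit-class].
#' @param train labelled training [SpikeDataset-class].
#' @param test optional held-out [SpikeDataset-class].
#' @param nGroups number of groups; default = number of training classes.
#' @return Data frame with columns `presentation`, `train` and (if a test
#'   set was given) `test`, accuracies in percent.
#' @export
checkpointAccuracies <- function(fit, train, test = NULL, nGroups = NULL) {
  h <- trainingHistory(fit)
  model <- fittedModel(fit)
  out <- lapply(seq_along(h@presentation), function(k) {
    model@weights <- h@weights[k, ]
    model@delays <- h@delays[k, ]
    model@bTilde <- h@bTilde[k]
    res <- evaluateModel(model, train, test, nGroups)
    c(train = 100 * res$trainAccuracy, test = 100 * res$testAccuracy)
  })
  out <- do.call(rbind, out)
  df <- data.frame(presentation = h@presentation, train = out[, "train"])
  if (!is.null(test)) df$test <- out[, "test"]
  df
}
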