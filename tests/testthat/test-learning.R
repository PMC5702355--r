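# Gradients, parameter updates, homeostasis, teacher spikes, training loop.

test_that("delay gradient sign follows the delay-learning window", {
  m <- delaySNN(1, weights = 1, delays = 10)
  p <- spikePattern(1, 0, nNeurons = 1)
  gradAt <- function(dt) delayGradient(p, spikeTrain(10 - dt, "mb"), m)[1]
  expect_equal(gradAt(1.5), 0)            # zero crossing exactly at dt = mu
  expect_gt(gradAt(0.5), 0)               # arrival early in dt: delay grows
  expect_lt(gradAt(3.0), 0)
  # no events on a synapse -> zero component
  m2 <- delaySNN(2, delays = c(10, 10))
  g <- delayGradient(p2 <- spikePattern(1, 0, nNeurons = 2), spikeTrain(8.5, "mb"), m2)
  expect_identical(g[2], 0)
})

test_that("gradients equal brute-force summation on random small instances", {
  set.seed(71)
  for (rep in 1:100) {
    inst <- randomInstance(kind = sample(c("mb", "bb"), 1))
    expect_equal(delayGradient(inst$pattern, inst$post, inst$model),
                 oDelayGrad(inst$pattern, inst$post, inst$model),
                 tolerance = 1e-10)
    expect_equal(weightGradient(inst$pattern, inst$post, inst$model),
                 oWeightGrad(inst$pattern, inst$post, inst$model),
                 tolerance = 1e-10)
  }
})

test_that("weight gradient is potentiation minus a per-spike depression term", {
  m <- delaySNN(1, weights = 1, delays = 10)
  p <- spikePattern(1, 0, nNeurons = 1)
  # single pair at dt = mu: potentiation dominates (sigm(g(mu) - 10) is tiny)
  expect_gt(weightGradient(p, spikeTrain(8.5, "mb"), m)[1], 0)
  # an empty Bernoulli train contributes no update at all
  mbb <- delaySNN(1, kind = "bb", weights = 1, delays = 10)
  expect_identical(weightGradient(p, spikeTrain(numeric(), "bb"), mbb), 0)
  expect_identical(delayGradient(p, spikeTrain(numeric(), "bb"), mbb), 0)
})

test_that("depression term matches fine-grid quadrature and increases in W", {
  quad <- function(w, v = 10, step = 0.0025) {
    dtp <- seq(0, 50, by = step)   # the clamped kernel vanishes for dt' < 0
    g <- oGauss(dtp)
    step * sum(g / (1 + exp(-(w * g - v))))
  }
  for (w in c(0.5, 1, 5, 20)) {
    m <- delaySNN(1, weights = w, delays = 10)
    # Riemann sum at delta = 0.05 vs a 20x finer quadrature: within 1%
    expect_equal(weightDepression(m)[1], quad(w), tolerance = 0.01)
  }
  depAt <- vapply(c(0.5, 1, 2, 5, 10, 20), function(w)
    weightDepression(delaySNN(1, weights = w, delays = 10))[1], numeric(1))
  expect_true(all(diff(depAt) > 0))
  expect_true(all(depAt >= 0))
})

test_that("depression term is robust to halving the time step", {
  for (w in c(1, 5, 20)) {
    d1 <- weightDepression(delaySNN(1, weights = w, delays = 10,
                                    grid = timeGrid(0.05, 50)))[1]
    d2 <- weightDepression(delaySNN(1, weights = w, delays = 10,
                                    grid = timeGrid(0.025, 50)))[1]
    expect_lt(abs(d2 - d1) / d1, 0.02)
  }
})

test_that("simplified delay gradient agrees with the unsimplified form", {
  # the dropped sigmoid term sums odd-symmetrically about dt = mu for the
  # unclamped kernel (mu lies on the grid, so grid points pair up exactly)
  set.seed(81)
  for (rep in 1:20) {
    N <- sample(1:3, 1)
    m <- delaySNN(N, weights = runif(N, 0.5, 5), delays = runif(N, 10, 15),
                  kernel = kernelConfig(clampRule = "none"))
    p <- spikePattern(seq_len(N), sample(seq(5, 20, by = 0.05), N), nNeurons = N)
    # post spike placed so dt is off the zero crossing and clamps stay inactive
    t <- sample(seq(22, 38, by = 0.05), 1)
    simp <- delayGradient(p, spikeTrain(t, "mb"), m)
    full <- delayGradientFull(p, spikeTrain(t, "mb"), m)
    keep <- abs(simp) > 1e-3
    if (any(keep))
      expect_equal(full[keep], simp[keep], tolerance = 1e-3)
  }
})

test_that("applyUpdate respects the hard parameter constraints", {
  m <- delaySNN(2, weights = c(1, 0.0001), delays = c(19.9, 5))
  # zero gradients leave the model untouched
  m0 <- applyUpdate(m, c(0, 0), c(0, 0))
  expect_identical(synapticWeights(m0), synapticWeights(m))
  expect_identical(conductionDelays(m0), conductionDelays(m))
  # delay clamp saturates at the upper bound, weight clamp at zero
  m1 <- applyUpdate(m, delayGrad = c(0.5 / 0.001, 0), weightGrad = c(0, -1),
                    eta = 0.001)
  expect_identical(conductionDelays(m1)[1], 20)
  expect_identical(synapticWeights(m1)[2], 0)
  # ablation: delays frozen, weights still learn
  m2 <- applyUpdate(m, delayGrad = c(100, 100), weightGrad = c(1, 1),
                    eta = 0.001, delayLearning = FALSE)
  expect_identical(conductionDelays(m2), conductionDelays(m))
  expect_equal(synapticWeights(m2), synapticWeights(m) + 0.001)
})

test_that("homeostatic update follows the spike/no-spike rule", {
  m <- delaySNN(1, kind = "bb", delays = 10, bTilde = 0)
  expect_equal(intrinsicExcitability(homeostaticUpdate(m, spikeTrain(c(1, 2), "bb"))),
               -1e-4)
  expect_equal(intrinsicExcitability(homeostaticUpdate(m, spikeTrain(numeric(), "bb"))),
               0.01)
  # alternating silent/active presentations accumulate the difference
  for (k in 1:100) {
    m <- homeostaticUpdate(m, spikeTrain(numeric(), "bb"))
    m <- homeostaticUpdate(m, spikeTrain(5, "bb"))
  }
  expect_equal(intrinsicExcitability(m), 100 * (0.01 - 1e-4))
  mmb <- delaySNN(1, kind = "mb", delays = 10)
  expect_error(homeostaticUpdate(mmb, spikeTrain(5, "mb")), "bb")
})

test_that("teacher spikes shift by the class rank direction", {
  g <- timeGrid()
  tr <- spikeTrain(25, "mb")
  expect_equal(spikeTimes(teacherSpikeTrain(tr, 2, 2, d = 0.05, g)), 25.05)
  expect_equal(spikeTimes(teacherSpikeTrain(tr, 1, 2, d = 0.05, g)), 24.95)
  # exact middle rank of three groups: unchanged
  expect_equal(spikeTimes(teacherSpikeTrain(tr, 2, 3, d = 0.05, g)), 25)
  expect_equal(spikeTimes(teacherSpikeTrain(tr, 1, 3, d = 0.05, g)), 24.95)
  expect_equal(spikeTimes(teacherSpikeTrain(tr, 3, 3, d = 0.05, g)), 25.05)
  # empty sampled train: no teacher spike is fabricated
  e <- spikeTrain(numeric(), "bb")
  expect_length(spikeTimes(teacherSpikeTrain(e, 2, 2, d = 0.05, g)), 0)
  # clipping at the window edge
  late <- spikeTrain(49.95, "bb")
  expect_equal(spikeTimes(teacherSpikeTrain(late, 2, 2, d = 0.05, g)), 49.95)
})

test_that("training with eta = 0 is a null update and runs are seed-reproducible", {
  toy <- generateToyDataset(5, seed = 3)
  m <- delaySNN(3, delays = c(9, 10, 11))
  fit0 <- trainModel(m, toy, eta = 0, nPresentations = 200, seed = 5)
  expect_identical(synapticWeights(fittedModel(fit0)), synapticWeights(m))
  expect_identical(conductionDelays(fittedModel(fit0)), conductionDelays(m))
  fitA <- trainModel(m, toy, nPresentations = 500, seed = 9)
  fitB <- trainModel(m, toy, nPresentations = 500, seed = 9)
  expect_identical(fittedModel(fitA)@weights, fittedModel(fitB)@weights)
  expect_identical(fittedModel(fitA)@delays, fittedModel(fitB)@delays)
  expect_error(trainModel(m, spikeDataset(list()), nPresentations = 1), "empty")
})

test_that("parameter clamps hold at every checkpoint of a training run", {
  toy <- generateToyDataset(20, seed = 13)
  m <- delaySNN(3)
  fit <- trainModel(m, toy, nPresentations = 20000, historyStride = 200, seed = 13)
  h <- trainingHistory(fit)
  expect_true(all(h@weights >= 0))
  expect_true(all(h@delays >= 0 & h@delays <= 20))
  expect_true(!is.unsorted(h@presentation))
})

test_that("the compiled training loop reproduces the R reference step for step", {
  # replay the loop's own sampled spikes through the exported R functions
  set.seed(17)
  for (kind in c("mb", "bb")) {
    toy <- generateToyDataset(4, seed = 23)
    m <- delaySNN(3, kind = kind, delays = c(9, 10, 11),
                  bTilde = if (kind == "bb") -2 else NULL)
    K <- 40L
    args <- delaysnn:::.trainArgs(m, toy, eta = 0.01, nPresentations = K,
                                  delayLearning = TRUE, supervised = FALSE,
                                  dShift = NULL, dtPrimeSpan = NULL,
                                  historyStride = K, rankStride = 1000L)
    set.seed(29)
    out <- do.call(delaysnn:::.cppTrain, c(args, traceFirst = K))
    mm <- m
    for (p in seq_len(K)) {
      pat <- toy[[out$dbgPick[p]]]
      post <- spikeTrain(out$dbgSpikes[[p]], kind)
      if (kind == "bb") mm <- homeostaticUpdate(mm, post)
      dg <- delayGradient(pat, post, mm)
      wg <- weightGradient(pat, post, mm)
      mm <- applyUpdate(mm, dg, wg, eta = 0.01)
    }
    expect_equal(out$W, synapticWeights(mm), tolerance = 1e-10)
    expect_equal(out$tau, conductionDelays(mm), tolerance = 1e-10)
    if (kind == "bb")
      expect_equal(out$bTilde, intrinsicExcitability(mm), tolerance = 1e-12)
  }
})
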