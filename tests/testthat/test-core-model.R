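# EPSP kernel, membrane potential, and spike generation for both readouts.

test_that("kernel peaks at mu with the Gaussian closed-form value and is symmetric", {
  expect_equal(kernelValue(1.5, s = 0, t = 10), 1 / sqrt(2 * pi))
  k <- kernelConfig(mu = 1.5, sigma = 2)
  expect_equal(kernelValue(1.5, 0, 10, k), 1 / (sqrt(2 * pi) * 2))
  # symmetric pairs about mu (where unclamped; and for the raw Gaussian)
  for (off in c(0.3, 1, 1.4))
    expect_equal(kernelValue(1.5 + off, 0, 10), kernelValue(1.5 - off, 0, 10))
  raw <- kernelConfig(clampRule = "none")
  for (off in c(2.5, 4))
    expect_equal(kernelValue(1.5 + off, 0, 10, raw),
                 kernelValue(1.5 - off, 0, 10, raw))
  # maximum over a dt sweep is attained at dt = mu
  dt <- seq(-5, 8, by = 0.05)
  g <- kernelValue(dt, s = 0, t = 10)
  expect_equal(dt[which.max(g)], 1.5)
})

test_that("kernel matches the clamp-masked Gaussian oracle on random triples", {
  set.seed(11)
  for (rule in c("negative-dt", "future-presyn", "literal", "none")) {
    k <- kernelConfig(clampRule = rule)
    s <- runif(1000, 0, 50)
    t <- runif(1000, 0, 50)
    tau <- runif(1000, 0, 20)
    dt <- s + tau - t
    expected <- ifelse(oClamped(dt, s, t, rule), 0, oGauss(dt))
    expect_equal(kernelValue(dt, s, t, k), expected, tolerance = 1e-12)
  }
})

test_that("the default clamp suppresses the kernel for negative temporal differences", {
  # one-sided kernel: exactly zero left of dt = 0, untouched at and above it
  expect_identical(kernelValue(-0.5, s = 0, t = 12), 0)
  expect_identical(kernelValue(-4, s = 0, t = 12), 0)
  expect_equal(kernelValue(0, s = 0, t = 10), oGauss(0))
  expect_gt(kernelValue(0.2, s = 0, t = 10), 0)
  # alternative rules condition on the raw spike times instead
  fut <- kernelConfig(clampRule = "future-presyn")
  expect_identical(kernelValue(1.5, 20, 10, fut), 0)   # s > t: not yet fired
  expect_gt(kernelValue(1.5, 10, 10, fut), 0)          # boundary s == t kept
  lit <- kernelConfig(clampRule = "literal")
  expect_gt(kernelValue(1.5, 20, 10, lit), 0)
  expect_identical(kernelValue(1.5, 5, 10, lit), 0)
  none <- kernelConfig(clampRule = "none")
  expect_equal(kernelValue(-0.5, 0, 12, none), oGauss(-0.5))
})

test_that("empty pattern gives a zero trace, uniform MB distribution, sigm(bTilde) BB probabilities", {
  m <- delaySNN(3, delays = c(10, 10, 10))
  empty <- spikePattern(integer(), numeric(), nNeurons = 3)
  expect_identical(potentialTrace(empty, m), rep(0, 1000))
  expect_equal(mbSpikeDistribution(empty, m), rep(1 / 1000, 1000))
  mb0 <- delaySNN(3, kind = "bb", delays = c(10, 10, 10), bTilde = 0)
  expect_equal(bbSpikeProbabilities(empty, mb0), rep(0.5, 1000))
  mneg <- delaySNN(3, kind = "bb", delays = c(10, 10, 10), bTilde = -60)
  expect_true(all(bbSpikeProbabilities(empty, mneg) < 1e-20))
})

test_that("a single event puts the kernel peak g(mu) at the mu-aligned bin", {
  m <- delaySNN(1, weights = 1, delays = 10)
  p <- spikePattern(1, 0, nNeurons = 1)
  v <- potentialTrace(p, m)
  tg <- gridTimes(timeGrid())
  expect_equal(max(v), 1 / sqrt(2 * pi))
  # dt = s + tau - t peaks at dt = mu, i.e. at t = s + tau - mu = 8.5 ms
  expect_equal(tg[which.max(v)], 8.5)
})

test_that("the trace is linear in weights and event multiplicity", {
  # two neurons, same event time and delay, W = (1, 2): 3x the unit trace
  m1 <- delaySNN(1, weights = 1, delays = 8)
  m12 <- delaySNN(2, weights = c(1, 2), delays = c(8, 8))
  p1 <- spikePattern(1, 5, nNeurons = 1)
  p12 <- spikePattern(c(1, 2), c(5, 5), nNeurons = 2)
  expect_equal(potentialTrace(p12, m12), 3 * potentialTrace(p1, m1),
               tolerance = 1e-12)
  # superposition on random patterns
  set.seed(21)
  for (rep in 1:20) {
    inst <- randomInstance()
    expect_equal(potentialTrace(inst$pattern, inst$model), oTrace(inst$pattern, inst$model),
                 tolerance = 1e-12)
  }
})

test_that("dimension mismatch between pattern and model is an error", {
  m <- delaySNN(2, delays = c(10, 10))
  p <- spikePattern(1:3, c(1, 5, 13), nNeurons = 3)
  expect_error(potentialTrace(p, m), "neurons")
  expect_error(delayGradient(p, spikeTrain(10, "mb"), m), "neurons")
})

test_that("MB distribution is a proper softmax: normalized, positive, shift-invariant", {
  set.seed(31)
  for (rep in 1:10) {
    inst <- randomInstance(kind = "mb")
    p <- mbSpikeDistribution(inst$pattern, inst$model)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(p > 0))
    # direct exp/sum oracle, including shift invariance of the softmax
    v <- oTrace(inst$pattern, inst$model)
    expect_equal(p, exp(v) / sum(exp(v)), tolerance = 1e-12)
    expect_equal(p, exp(v + 10) / sum(exp(v + 10)), tolerance = 1e-12)
  }
})

test_that("MB sampling frequencies follow the softmax distribution", {
  set.seed(41)
  # structured pattern: frequencies within 4 binomial SEs of the distribution
  m <- delaySNN(2, weights = c(4, 6), delays = c(8, 10))
  p <- spikePattern(c(1, 2), c(2, 4), nNeurons = 2)
  prob <- mbSpikeDistribution(p, m)
  nDraw <- 1e5
  bins <- vapply(seq_len(nDraw), function(i)
    as.integer(round(spikeTimes(mbSampleSpike(p, m)) / 0.05)) + 1L, integer(1))
  freq <- tabulate(bins, nbins = length(prob)) / nDraw
  se <- sqrt(prob * (1 - prob) / nDraw)
  expect_lt(mean(abs(freq - prob) > 4 * se + 1e-12), 0.005)
  # the dominant bin is hit at about its probability
  top <- which.max(prob)
  expect_lt(abs(freq[top] - prob[top]), 4 * se[top])
})

test_that("sampling is reproducible under a fixed seed", {
  m <- delaySNN(3, delays = c(10, 11, 12))
  p <- spikePattern(1:3, c(1, 5, 13), nNeurons = 3)
  set.seed(7); a <- mbSampleSpike(p, m)
  set.seed(7); b <- mbSampleSpike(p, m)
  expect_identical(spikeTimes(a), spikeTimes(b))
  mbb <- delaySNN(3, kind = "bb", delays = c(10, 11, 12), bTilde = -3)
  set.seed(7); a <- bbSampleSpikes(p, mbb)
  set.seed(7); b <- bbSampleSpikes(p, mbb)
  expect_identical(spikeTimes(a), spikeTimes(b))
})

test_that("BB probabilities match the elementwise sigmoid oracle and grow with bTilde", {
  set.seed(51)
  inst <- randomInstance(kind = "bb")
  v <- oTrace(inst$pattern, inst$model)
  q <- bbSpikeProbabilities(inst$pattern, inst$model)
  expect_equal(q, 1 / (1 + exp(-(v + inst$model@bTilde))), tolerance = 1e-12)
  # expected spike count is monotone non-decreasing in bTilde
  counts <- vapply(seq(-10, 2, by = 1), function(b) {
    inst$model@bTilde <- b
    sum(bbSpikeProbabilities(inst$pattern, inst$model))
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("BB sampling: empty at vanishing probability, binomial mean otherwise", {
  m <- delaySNN(1, kind = "bb", delays = 10, bTilde = -800)
  empty <- spikePattern(integer(), numeric(), nNeurons = 1)
  expect_length(spikeTimes(bbSampleSpikes(empty, m)), 0)
  # constant probability p per bin: mean count ~ p * bins
  pConst <- 0.02
  m@bTilde <- log(pConst / (1 - pConst))
  set.seed(61)
  counts <- vapply(1:2000, function(i)
    length(spikeTimes(bbSampleSpikes(empty, m))), numeric(1))
  expected <- pConst * 1000
  se <- sqrt(1000 * pConst * (1 - pConst) / 2000)
  expect_lt(abs(mean(counts) - expected), 4 * se)
})

test_that("class constructors validate their invariants", {
  expect_error(timeGrid(delta = -1), "positive")
  expect_error(timeGrid(delta = 0.3, period = 50), "multiple")
  expect_error(kernelConfig(sigma = 0), "sigma")
  expect_error(spikePattern(1, 55, nNeurons = 1), "period")
  expect_error(spikePattern(c(1, 1), c(5, 5), nNeurons = 1), "binary")
  expect_error(spikePattern(2, 5, nNeurons = 1), "nNeurons")
  expect_error(spikeTrain(c(1, 2), "mb"), "exactly one")
  expect_silent(spikeTrain(numeric(), "bb"))
  expect_error(delaySNN(2, weights = c(-1, 1), delays = c(5, 5)), ">= 0")
})
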