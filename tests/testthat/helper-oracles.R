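# Independent brute-force oracles: plain-loop evaluations of the model
# formulas, kept free of the package's computational code paths.

oGauss <- function(dt, mu = 1.5, sigma = 1) {
  exp(-(dt - mu)^2 / (2 * sigma^2)) / (sqrt(2 * pi) * sigma)
}

oClamped <- function(dt, s, t, rule = "negative-dt") {
  switch(rule,
         "negative-dt" = dt < 0,
         "future-presyn" = s > t,
         "literal" = s < t,
         "none" = rep(FALSE, max(length(dt), length(s), length(t))))
}

# membrane potential by direct double loop over events and bins
oTrace <- function(pattern, model) {
  ev <- patternEvents(pattern)
  k <- model@kernel
  tg <- gridTimes(model@grid)
  v <- numeric(length(tg))
  for (j in seq_along(tg)) {
    for (r in seq_len(nrow(ev))) {
      i <- ev$neuron[r]
      s <- ev$time[r]
      dt <- s + model@delays[i] - tg[j]
      if (!oClamped(dt, s, tg[j], k@clampRule)) {
        v[j] <- v[j] + model@weights[i] * oGauss(dt, k@mu, k@sigma)
      }
    }
  }
  v
}

# simplified delay gradient by direct double loop (post spikes x events)
oDelayGrad <- function(pattern, post, model) {
  ev <- patternEvents(pattern)
  k <- model@kernel
  grad <- numeric(length(model@weights))
  for (t in post@times) {
    for (r in seq_len(nrow(ev))) {
      i <- ev$neuron[r]
      s <- ev$time[r]
      dt <- s + model@delays[i] - t
      if (oClamped(dt, s, t, k@clampRule)) next
      grad[i] <- grad[i] -
        oGauss(dt, k@mu, k@sigma) * model@weights[i] * (dt - k@mu) / k@sigma^2
    }
  }
  grad
}

# weight gradient: potentiation per (post, event) pair minus the depression
# sum over the full dt' window, the latter applied once per post spike
oWeightGrad <- function(pattern, post, model, span = NULL) {
  ev <- patternEvents(pattern)
  k <- model@kernel
  delta <- model@grid@delta
  if (is.null(span)) span <- model@grid@period
  grad <- numeric(length(model@weights))
  for (t in post@times) {
    for (r in seq_len(nrow(ev))) {
      i <- ev$neuron[r]
      s <- ev$time[r]
      dt <- s + model@delays[i] - t
      if (oClamped(dt, s, t, k@clampRule)) next
      grad[i] <- grad[i] + oGauss(dt, k@mu, k@sigma)
    }
  }
  dtp <- seq(-span, span, by = delta)
  for (i in seq_along(grad)) {
    g <- oGauss(dtp, k@mu, k@sigma)
    if (k@clampRule == "negative-dt") g[dtp < 0] <- 0
    dep <- delta * sum(g / (1 + exp(-(model@weights[i] * g - model@vBias))))
    grad[i] <- grad[i] - length(post@times) * dep
  }
  grad
}

# random small test instance on the default grid
randomInstance <- function(N = sample(2:4, 1), nEvents = sample(1:5, 1),
                           nPost = sample(1:3, 1), kind = "bb",
                           grid = timeGrid()) {
  ev <- unique(data.frame(neuron = sample.int(N, nEvents, replace = TRUE),
                          time = sample(0:399, nEvents) * grid@delta))
  pattern <- spikePattern(ev$neuron, ev$time, nNeurons = N, grid = grid)
  if (kind == "mb") nPost <- 1L
  post <- spikeTrain(sort(sample(0:999, nPost)) * grid@delta, kind = kind)
  model <- delaySNN(N, kind = kind, weights = runif(N, 0.2, 5),
                    delays = runif(N, 5, 15), grid = grid)
  list(pattern = pattern, post = post, model = model)
}
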