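---
title: "Conduction-delay learning for spike-timing classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conduction-delay learning for spike-timing classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(delaysnn)
```

## The model

A single post-synaptic neuron receives input from $N$ pre-synaptic neurons.
An input sample is a *spatio-temporal spike pattern*: a set of binary events
$x_{is} \in \{0, 1\}$ on a discrete time grid $t = 0, \delta, 2\delta, \dots
< T$ (defaults $\delta = 0.05$ ms, $T = 50$ ms). Each synapse $i$ carries two
learnable parameters: a synaptic weight $W_i \ge 0$ and an axonal conduction
delay $\tau_i$ (ms, clamped to $[0, 20]$). A pre-synaptic spike at time $s$
arrives at the soma at $s + \tau_i$ and evokes an EPSP-like contribution
described by a Gaussian temporal-relation kernel of the temporal difference
$\Delta t = s + \tau_i - t$,

$$g(\Delta t) = \frac{1}{\sqrt{2\pi}\,\sigma}
  \exp\!\Big(-\frac{(\Delta t - \mu)^2}{2\sigma^2}\Big),$$

with peak offset $\mu = 1.5$ ms and width $\sigma = 1$ ms by default. The
membrane potential is the linear superposition
$v_t = \sum_{is} x_{is} W_i\, g(s + \tau_i - t)$.

Two generative readouts turn the potential into output spikes:

* **Multinoulli ("mb")** — exactly one output spike per pattern, at a time
  drawn from the softmax $p(z_t = 1 \mid x) = e^{v_t} / \sum_{t'} e^{v_{t'}}$.
  The normalizer runs over the whole window, so sampling is anti-causal; this
  is accepted as part of the formulation, and the Bernoulli readout below is
  the causal alternative.
* **Bernoulli ("bb")** — every grid bin spikes independently with probability
  $\mathrm{sigm}(v_t + \tilde b)$, where $\tilde b$ is an intrinsic
  excitability kept in a regular firing regime by homeostatic plasticity:
  after a pattern with at least one output spike $\tilde b \leftarrow \tilde b
  - b_-$, after a silent pattern $\tilde b \leftarrow \tilde b + b_+$
  (defaults $b_+ = 0.01$, $b_- = 10^{-4}$, so about one pattern in a hundred
  stays silent at equilibrium).

Information is carried purely by output-spike *timing*: a dataset is
classified by sorting patterns by their output timings and cutting at the
$n/N_{\text{groups}}$ weighted quantiles (`fitBoundaries()`). Under the
Bernoulli readout each spike of a burst votes with weight $1/\text{count}$,
and a silent pattern counts as a maximally late spike at $T - \delta$.
Because unsupervised groups carry no class identity, accuracy is measured
under the best injective group-to-class mapping, fitted on the training
split and frozen for test data.

## The learning rule

Training is a stochastic EM scheme: present one pattern, sample the latent
output train from the current model (E-step), then take one gradient-ascent
step of size $\eta$ on the evidence lower bound (M-step). Per output spike
$t$ the gradients implemented are

$$\Delta\tau_i \propto -\sum_{s} x_{is}\, g(\Delta t)\, W_i\,
  \frac{\Delta t - \mu}{\sigma^2}, \qquad
  \Delta W_i \propto \sum_{s} x_{is}\, g(\Delta t) \;-\;
  \delta \sum_{\Delta t'} \mathrm{sigm}(W_i\, g(\Delta t') - v)\,
  g(\Delta t'),$$

with bias $v = 10$ and $\eta = 0.001$ by default. The delay window crosses
zero at $\Delta t = \mu$: output spikes attract the delayed arrivals of the
events that caused them, which is the delay-learning mechanism. The weight
window resembles STDP — potentiation when the arrival slightly precedes the
kernel peak, depression for arrivals far on either side — and the
depression term grows with $W_i$, damping runaway potentiation. The $\delta$
factor makes the depression term a Riemann sum, hence robust to the grid
resolution (halving $\delta$ changes it by well under 2 %; this is a tested
invariant). The delay gradient is the simplified form with the
near-odd-symmetric sigmoid term dropped; `delayGradientFull()` retains the
full expression and the test suite verifies the two agree to about
$10^{-3}$ relative for moderate weights.

Design choices where the formulation leaves room:

* **Causality clamp.** The Gaussian kernel is two-sided, unlike biophysical
  EPSP models (double-exponential kernels vanish for negative temporal
  differences). The default `clampRule = "negative-dt"` therefore clamps
  $g(\Delta t)$ to exactly zero for $\Delta t < 0$, wherever the kernel
  appears — potential, gradients and the depression window. This makes both
  plasticity windows one-sided: the delay window is zero for $\Delta t < 0$
  and the synaptic window is purely depressing there, so an output spike
  attracts only the delayed arrivals that trail it. That forward-capture
  asymmetry matters dynamically: without it the learning frequently stalls
  in a stalemate where one class aligns all its arrivals and the other
  stays dispersed. Two alternative readings that condition on the raw spike
  times instead — `"future-presyn"` (drop events with $s > t$, i.e. spikes
  not yet fired) and its mirror image `"literal"` (drop $s < t$) — remain
  selectable for comparison, as does `"none"`.
* **Depression window.** The $\Delta t'$ sum runs over the full symmetric
  window $[-T, T]$ stepped by $\delta$ (the clamp removes the negative
  half); since $g$ decays to numerical zero beyond $\mu \pm 6\sigma$ the
  span is immaterial, and a full window avoids an arbitrary cutoff
  (`dtPrimeSpan` exposes it).
* **Multiple output spikes (Bernoulli).** The per-spike gradient form is
  summed over the spikes of the sampled train, so the depression term is
  applied once per output spike; a silent train yields no weight or delay
  update (only the homeostatic step), which is what the Bernoulli
  log-likelihood prescribes.
* **Weight floor.** The model declares $W_i \ge 0$ but the update can cross
  zero, so weights are clamped at zero from below; delays are clamped into
  `tauBounds` after every step.
* **Initial excitability.** $\tilde b_0 = -\ln(\text{bins} - 1)$, i.e. one
  expected spontaneous spike per pattern on a flat potential; configurable.

## Weak supervision

In supervised mode no absolute target timings are imposed. After sampling,
every spike of a pattern whose class ranks early (by the mean output timing
the current model assigns each class) is shifted $d$ ms earlier, and late
classes $d$ ms later, before the gradient step; $d$ defaults to one grid
step (0.05 ms). With more than two classes the earliest half of the ranking
shifts $-d$, the latest half $+d$, and an exact middle rank stays in place.
The ranking is recomputed every `rankStride` (1000) presentations, and the
homeostatic update always uses the unshifted sampled train. Whether to
re-sample the output spike before constructing the teacher at every
presentation is an open choice; this implementation re-samples each time.

## Input encodings

* `generateToyDataset()` — the built-in benchmark: three neurons firing once
  each at base times $(1, 5, 13)$ ms (class A) or $(13, 9, 1)$ ms (class B),
  each jittered by $U(-1, 1)$ ms and snapped to the grid (nearest bin, ties
  to the earlier bin). The classes are the same times in different spatial
  order, so only the temporal structure separates them.
* `encodeFeatureVector()` — latency encoding: feature $k_i$ with range
  $(\min_i, \max_i)$ becomes one spike at $t_{\max} (k_i - \min_i) /
  (\max_i - \min_i)$ ms ($t_{\max} = 10$ ms). Ranges are computed from the
  training split and reused for held-out data (out-of-range values are
  clipped with a warning).
* `encodeImage()` — rows become neurons, columns become times (1 ms per
  column by default, so a 28-column image fits the 50 ms window with room
  for delays up to 20 ms); every pixel above 0.5 produces a spike.

The toy generator emulates the essential difficulty — spatial permutations
of identical spike times under timing jitter — but not features of real
recordings such as background spikes, missing events, rate variability or
correlated noise. Results on it demonstrate that the learning rule works as
specified, not that it is robust to such nuisances.

## Study conditions and problem sizes

The repeated-trial studies (`runTrials()`, and the reproduction script in
`scripts/acceptance.R`) use: 50 training and 50 test patterns per class,
weights initialized to 1, delays drawn from $U(5, 15)$ ms, 20 trials per
condition, and training runs of 250{,}000 presentations.

The presentation count deserves a note, because it is the one study
condition chosen by this package rather than copied from a stated value.
With $\eta = 0.001$ a single potentiation step is at most $\eta\, g(\mu)
\approx 4 \times 10^{-4}$, so the converged weight scale ($W \sim 10$–$30$
per synapse, needed before the softmax over 1000 bins concentrates) is
unreachable in a few tens of thousands of presentations; measured
trajectories show the characteristic two-phase course — delays align the
arrivals first, then weights grow and accuracy rises — with the median
trial reaching its accuracy plateau by roughly 200{,}000–250{,}000
presentations in every condition (unsupervised, supervised, fixed-delay,
Bernoulli), while training well beyond that occasionally *degrades* an
unsupervised trial, as the delay steps (whose size scales with the grown
weights) let timing clusters drift and merge. The default of 250{,}000 is
the smallest 50{,}000-multiple on the plateau for all four conditions and
is deliberately not varied per condition.

At this size one 20-trial study takes a couple of minutes on one core (the
per-presentation arithmetic is compiled); the test suite runs the four
studies once and reuses them across its checks.

## Numerical notes

* All grid arithmetic is done on bin indices; times are snapped to the
  nearest bin with half-way ties toward the earlier bin, so float equality
  never decides anything.
* The compiled loop accumulates kernel contributions only within $9\sigma$
  of the peak, where the Gaussian has decayed to below $5 \times 10^{-18}$
  of its maximum — invisible in double precision next to potentials of
  order 1. The depression support is likewise truncated where
  $g < 10^{-12}$; the tests verify the loop against the plain R reference
  to $10^{-10}$.
* Quantile boundaries use the inverted-CDF convention (lowest time whose
  cumulative weight reaches $n/N$), ties in stable input order; a timing
  exactly on a threshold falls in the lower group. Degenerate all-equal
  timings give equal thresholds and assign everything to group 1.
* Group-to-vote ties in majority voting go to the earlier group.

## Known limitations

One post-synaptic neuron, hence at most as many groups as the timing axis
supports cleanly (the studies use two or three); no refractory dynamics, so
the Bernoulli readout can burst within a single kernel width; discrete time
only; no minibatching or adaptive step sizes. Image inputs are tested on
synthetic matrices — no image dataset is bundled or downloaded.

## A worked run

```{r, eval = FALSE}
set.seed(1)
toy <- generateToyDataset(50)
test <- generateToyDataset(50)
model <- delaySNN(3)                  # W = 1, tau ~ U(5, 15)
fit <- trainModel(model, toy)         # 250,000 presentations
res <- evaluateModel(fittedModel(fit), toy, test)
res$trainAccuracy; res$testAccuracy
```

The trained delays align two of the three arrivals per class, the aligned
weights grow largest, and the two classes' output timings separate cleanly
around the median boundary. `checkpointAccuracies(fit, toy)` replays the
recorded parameter snapshots to show the accuracy trajectory, and
`plasticityWindows()` reproduces the delay-learning and STDP-like windows
described above.
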