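// Inner training loop of the stochastic-EM rule.
//
// One presentation = sample a pattern, sample the latent post-synaptic
// spike(s) from the current generative model, take one gradient-ascent step
// on the delays and weights. The loop runs millions of presentations per
// study, hence compiled. The R-level gradient/trace functions are the
// reference implementation; the test suite checks this loop reproduces them
// step for step.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double INV_SQRT_2PI = 0.3989422804014327;

// membrane potential v over the grid for one pattern; contributions are
// accumulated only inside the kernel's 9-sigma support (beyond it the
// Gaussian is < 5e-18 of its peak, invisible in double precision next to
// the O(1) potentials)
static void trace(const IntegerVector& evN, const NumericVector& evT,
                  const std::vector<double>& W, const std::vector<double>& tau,
                  double mu, double sigma, int clampRule,
                  double delta, int bins, std::vector<double>& v) {
  std::fill(v.begin(), v.end(), 0.0);
  const double halfw = 9.0 * sigma;
  const double norm = INV_SQRT_2PI / sigma;
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  for (int e = 0; e < evN.size(); ++e) {
    const int i = evN[e] - 1;
    const double s = evT[e];
    const double ar = s + tau[i];
    int lo = (int)std::ceil((ar - mu - halfw) / delta);
    int hi = (int)std::floor((ar - mu + halfw) / delta);
    if (clampRule == 3) {                    // negative-dt: need t <= ar
      int tmax = (int)std::floor(ar / delta + 1e-9);
      if (hi > tmax) hi = tmax;
    } else if (clampRule == 0) {             // future-presyn: need t >= s
      int smin = (int)std::ceil(s / delta - 1e-9);
      if (lo < smin) lo = smin;
    } else if (clampRule == 1) {             // literal: need t <= s
      int smax = (int)std::floor(s / delta + 1e-9);
      if (hi > smax) hi = smax;
    }
    if (lo < 0) lo = 0;
    if (hi > bins - 1) hi = bins - 1;
    const double wsc = W[i] * norm;
    for (int j = lo; j <= hi; ++j) {
      const double dtv = ar - j * delta;
      if (clampRule == 3 && dtv < 0) continue;   // exact sign agreement with R
      const double dt = dtv - mu;
      v[j] += wsc * std::exp(-dt * dt * inv2s2);
    }
  }
}

// [[Rcpp::export(name = ".cppTrain")]]
List cppTrain(List evNeuron, List evTime, IntegerVector cls, int nClasses,
              NumericVector W0, NumericVector tau0, double bTilde0,
              bool isBB, double vBias, double bPlus, double bMinus,
              double mu, double sigma, int clampRule,
              double delta, int bins, NumericVector gsup,
              double eta, int nPres, bool delayLearning, bool supervised,
              double dShift, double tauLow, double tauHigh,
              int historyStride, int rankStride, int traceFirst) {
  const int nPat = evNeuron.size();
  const int N = W0.size();
  const double period = bins * delta;
  std::vector<double> W(W0.begin(), W0.end());
  std::vector<double> tau(tau0.begin(), tau0.end());
  double bTilde = bTilde0;

  std::vector<double> v(bins), w(bins);
  std::vector<double> dgrad(N), wpot(N), dep(N);
  std::vector<double> shiftByClass(nClasses > 0 ? nClasses : 1, 0.0);
  std::vector<int> postBins;
  postBins.reserve(64);

  const int m = gsup.size();

  // history storage
  int nSnap = nPres / historyStride + 1 + (nPres % historyStride != 0 ? 1 : 0);
  IntegerVector histP(nSnap);
  NumericMatrix histW(nSnap, N), histTau(nSnap, N);
  NumericVector histB(nSnap);
  int snap = 0;
  auto record = [&](int p) {
    histP[snap] = p;
    for (int i = 0; i < N; ++i) { histW(snap, i) = W[i]; histTau(snap, i) = tau[i]; }
    histB[snap] = bTilde;
    ++snap;
  };

  // optional per-presentation diagnostics (for R-vs-C++ equivalence tests)
  IntegerVector dbgPick(traceFirst);
  List dbgSpikes(traceFirst);

  // class ranking -> teacher shifts, from the mean expected output timing
  auto refreshShifts = [&]() {
    std::vector<double> sum(nClasses, 0.0);
    std::vector<int> cnt(nClasses, 0);
    for (int k = 0; k < nPat; ++k) {
      trace(evNeuron[k], evTime[k], W, tau, mu, sigma, clampRule, delta, bins, v);
      double et;
      if (!isBB) {
        double vmax = *std::max_element(v.begin(), v.end());
        double tot = 0.0, wt = 0.0;
        for (int j = 0; j < bins; ++j) {
          double e = std::exp(v[j] - vmax);
          tot += e; wt += e * (j * delta);
        }
        et = wt / tot;
      } else {
        double tot = 0.0, wt = 0.0;
        for (int j = 0; j < bins; ++j) {
          double q = 1.0 / (1.0 + std::exp(-(v[j] + bTilde)));
          tot += q; wt += q * (j * delta);
        }
        et = (tot < 1e-12) ? period - delta : wt / tot;
      }
      sum[cls[k] - 1] += et;
      cnt[cls[k] - 1] += 1;
    }
    // ascending rank of the class means, ties kept in class order
    std::vector<int> ord(nClasses);
    for (int c = 0; c < nClasses; ++c) ord[c] = c;
    std::stable_sort(ord.begin(), ord.end(), [&](int a, int b) {
      return sum[a] / std::max(cnt[a], 1) < sum[b] / std::max(cnt[b], 1);
    });
    for (int r = 0; r < nClasses; ++r) {
      int c = ord[r];
      double rk = r + 1;
      if (rk <= nClasses / 2.0) shiftByClass[c] = -dShift;
      else if (rk > (nClasses + 1) / 2.0) shiftByClass[c] = dShift;
      else shiftByClass[c] = 0.0;
    }
  };
  if (supervised) refreshShifts();
  record(0);

  for (int p = 1; p <= nPres; ++p) {
    if (supervised && p % rankStride == 0) refreshShifts();
    int pick = (int)(unif_rand() * nPat);
    if (pick >= nPat) pick = nPat - 1;
    const IntegerVector evN = evNeuron[pick];
    const NumericVector evT = evTime[pick];
    trace(evN, evT, W, tau, mu, sigma, clampRule, delta, bins, v);

    // E-step: sample the post-synaptic spike train
    postBins.clear();
    if (!isBB) {
      double vmax = *std::max_element(v.begin(), v.end());
      double tot = 0.0;
      for (int j = 0; j < bins; ++j) { w[j] = std::exp(v[j] - vmax); tot += w[j]; }
      double u = unif_rand() * tot, acc = 0.0;
      int b = bins - 1;
      for (int j = 0; j < bins; ++j) { acc += w[j]; if (acc >= u) { b = j; break; } }
      postBins.push_back(b);
    } else {
      for (int j = 0; j < bins; ++j) {
        double q = 1.0 / (1.0 + std::exp(-(v[j] + bTilde)));
        if (unif_rand() < q) postBins.push_back(j);
      }
      // homeostatic intrinsic plasticity, driven by the sampled train
      bTilde += postBins.empty() ? bPlus : -bMinus;
    }

    if (p <= traceFirst) {
      dbgPick[p - 1] = pick + 1;
      NumericVector st(postBins.size());
      for (size_t r = 0; r < postBins.size(); ++r) st[r] = postBins[r] * delta;
      dbgSpikes[p - 1] = st;
    }

    const int K = (int)postBins.size();
    if (K > 0) {
      // teacher shift (supervised): nudge every sampled spike by the class shift
      double shift = 0.0;
      if (supervised) shift = shiftByClass[cls[pick] - 1];

      // M-step gradients
      std::fill(dgrad.begin(), dgrad.end(), 0.0);
      std::fill(wpot.begin(), wpot.end(), 0.0);
      const double inv_s2 = 1.0 / (sigma * sigma);
      const double norm = INV_SQRT_2PI / sigma;
      for (int r = 0; r < K; ++r) {
        double t = postBins[r] * delta + shift;
        double q = t / delta;                 // snap, half-way ties earlier
        double lo = std::floor(q);
        t = ((q - lo > 0.5) ? lo + 1 : lo) * delta;
        if (t < 0) t = 0;
        if (t > period - delta) t = period - delta;
        for (int e = 0; e < evN.size(); ++e) {
          const int i = evN[e] - 1;
          const double s = evT[e];
          if (clampRule == 0 && s > t) continue;
          if (clampRule == 1 && s < t) continue;
          const double dt = s + tau[i] - t;
          if (clampRule == 3 && dt < 0) continue;
          const double g = norm * std::exp(-(dt - mu) * (dt - mu) /
                                           (2.0 * sigma * sigma));
          dgrad[i] -= g * W[i] * (dt - mu) * inv_s2;
          wpot[i] += g;
        }
      }
      for (int i = 0; i < N; ++i) {
        double d = 0.0;
        for (int j = 0; j < m; ++j)
          d += gsup[j] / (1.0 + std::exp(-(W[i] * gsup[j] - vBias)));
        dep[i] = delta * d;
      }
      for (int i = 0; i < N; ++i) {
        W[i] += eta * (wpot[i] - K * dep[i]);
        if (W[i] < 0) W[i] = 0;
        if (delayLearning) {
          tau[i] += eta * dgrad[i];
          if (tau[i] < tauLow) tau[i] = tauLow;
          if (tau[i] > tauHigh) tau[i] = tauHigh;
        }
      }
    }
    if (p % historyStride == 0 || p == nPres) record(p);
  }

  return List::create(
    _["W"] = NumericVector(W.begin(), W.end()),
    _["tau"] = NumericVector(tau.begin(), tau.end()),
    _["bTilde"] = bTilde,
    _["histP"] = histP[Range(0, snap - 1)],
    _["histW"] = histW(Range(0, snap - 1), _),
    _["histTau"] = histTau(Range(0, snap - 1), _),
    _["histB"] = histB[Range(0, snap - 1)],
    _["dbgPick"] = dbgPick,
    _["dbgSpikes"] = dbgSpikes);
}
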