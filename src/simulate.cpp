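#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Column-compressed view of the dense coupling matrix: the inner loop only
// touches columns of currently active presynaptic neurons.
struct CscJ {
  std::vector<int> ptr, row;
  std::vector<double> val;
  int n;
  explicit CscJ(const NumericMatrix &J) {
    n = J.ncol();
    ptr.assign(n + 1, 0);
    for (int i = 0; i < n; ++i) {
      int cnt = 0;
      for (int j = 0; j < n; ++j) if (J(j, i) != 0.0) ++cnt;
      ptr[i + 1] = ptr[i] + cnt;
    }
    row.resize(ptr[n]);
    val.resize(ptr[n]);
    for (int i = 0, k = 0; i < n; ++i)
      for (int j = 0; j < n; ++j)
        if (J(j, i) != 0.0) { row[k] = j; val[k] = J(j, i); ++k; }
  }
  void accumulate(const std::vector<int> &active, std::vector<double> &I) const {
    std::fill(I.begin(), I.end(), 0.0);
    for (int a : active)
      for (int k = ptr[a]; k < ptr[a + 1]; ++k)
        I[row[k]] += val[k];
  }
};

static inline double clamp01(double x) {
  return x <= 0.0 ? 0.0 : (x >= 1.0 ? 1.0 : x);
}

// Iterate the probabilistic binary dynamics. Each step the recurrent firing
// probability is the clamped synaptic input; the external drive is then
// applied as an independent Bernoulli (probabilistic OR). Uses R's RNG, so
// runs are reproducible under set.seed(). Events and per-step active counts
// are recorded only after the burn-in window.
// [[Rcpp::export]]
List sim_core(NumericMatrix J, int steps, int burn_in,
              IntegerVector init_active, double p_ext) {
  const int N = J.ncol();
  if (J.nrow() != N) stop("J must be square");
  if (steps <= burn_in) stop("steps must exceed burn_in");
  CscJ csc(J);

  std::vector<int> state(N, 0);
  std::vector<int> active;
  for (int k = 0; k < init_active.size(); ++k) {
    int i = init_active[k] - 1;
    if (i < 0 || i >= N) stop("initial active index out of range");
    if (!state[i]) { state[i] = 1; active.push_back(i); }
  }

  const int keep = steps - burn_in;
  std::vector<double> I(N);
  std::vector<double> state_sum(N, 0.0);
  IntegerVector counts(keep);
  std::vector<int> ev_neuron, ev_time, idx(N);
  ev_neuron.reserve(1 << 20);
  ev_time.reserve(1 << 20);

  for (int t = 1; t <= steps; ++t) {
    csc.accumulate(active, I);
    active.clear();
    // recurrent pass: one Bernoulli draw per neuron with positive input
    for (int i = 0; i < N; ++i) {
      double pi = clamp01(I[i]);
      bool fired = pi > 0.0 && unif_rand() < pi;
      state[i] = fired;
      if (fired) active.push_back(i);
    }
    // external pass: binomial count of externally driven neurons, then a
    // uniform choice of that many distinct targets (exactly equivalent to
    // independent per-neuron Bernoulli(p_ext) draws)
    if (p_ext > 0.0) {
      int k = (int)R::rbinom((double)N, p_ext);
      if (k > 0) {
        for (int i = 0; i < N; ++i) idx[i] = i;
        for (int i = 0; i < k; ++i) {
          int j = i + (int)(unif_rand() * (N - i));
          if (j >= N) j = N - 1;
          std::swap(idx[i], idx[j]);
          int tgt = idx[i];
          if (!state[tgt]) { state[tgt] = 1; active.push_back(tgt); }
        }
      }
    }
    if (t > burn_in) {
      counts[t - burn_in - 1] = (int)active.size();
      for (int a : active) {
        ev_neuron.push_back(a + 1);
        ev_time.push_back(t - burn_in);
        state_sum[a] += 1.0;
      }
    }
  }

  NumericVector mean_state(N);
  for (int i = 0; i < N; ++i) mean_state[i] = state_sum[i] / keep;
  return List::create(_["neuron"] = wrap(ev_neuron),
                      _["time"] = wrap(ev_time),
                      _["counts"] = counts,
                      _["mean_state"] = mean_state);
}

// One-step branching trials: for each imposed active count k, activate k
// uniformly chosen neurons, sample one forward step of the recurrent
// dynamics (no external drive), and return the ratio of next to imposed
// active fraction, averaged over trials, with its standard error.
// [[Rcpp::export]]
NumericMatrix branching_trials(NumericMatrix J, IntegerVector ks, int n_trials) {
  const int N = J.ncol();
  if (J.nrow() != N) stop("J must be square");
  if (n_trials < 1) stop("n_trials must be >= 1");
  CscJ csc(J);
  std::vector<double> I(N);
  std::vector<int> idx(N);
  NumericMatrix out(ks.size(), 2);

  for (int q = 0; q < ks.size(); ++q) {
    int k = ks[q];
    if (k < 1 || k > N) stop("imposed active count out of range");
    double sum = 0.0, sumsq = 0.0;
    for (int tr = 0; tr < n_trials; ++tr) {
      for (int i = 0; i < N; ++i) idx[i] = i;
      std::vector<int> active(k);
      for (int i = 0; i < k; ++i) {   // partial Fisher-Yates
        int j = i + (int)(unif_rand() * (N - i));
        if (j >= N) j = N - 1;
        std::swap(idx[i], idx[j]);
        active[i] = idx[i];
      }
      csc.accumulate(active, I);
      int m = 0;
      for (int i = 0; i < N; ++i) {
        double pi = clamp01(I[i]);
        if (pi > 0.0 && unif_rand() < pi) ++m;
      }
      double r = (double)m / (double)k;
      sum += r;
      sumsq += r * r;
    }
    double mean = sum / n_trials;
    double var = n_trials > 1 ? (sumsq - n_trials * mean * mean) / (n_trials - 1)
                              : 0.0;
    if (var < 0) var = 0;
    out(q, 0) = mean;
    out(q, 1) = std::sqrt(var / n_trials);
  }
  return out;
}
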