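#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Fenwick (binary-indexed) tree holding per-node total event rates,
// supporting O(log N) update, prefix-sum and inverse-CDF search.
struct Fenwick {
  int n;
  std::vector<double> t;
  explicit Fenwick(int n_) : n(n_), t(n_ + 1, 0.0) {}
  void add(int i, double d) {
    for (++i; i <= n; i += i & -i) t[i] += d;
  }
  double total() const {
    double s = 0.0;
    for (int i = n; i > 0; i -= i & -i) s += t[i];
    return s;
  }
  // largest index with prefix(idx) <= u; returns 0-based node index
  int find(double u) const {
    int pos = 0;
    int pw = 1;
    while ((pw << 1) <= n) pw <<= 1;
    for (; pw; pw >>= 1) {
      int np = pos + pw;
      if (np <= n && t[np] <= u) {
        u -= t[np];
        pos = np;
      }
    }
    return pos < n ? pos : n - 1;
  }
};

struct SISState {
  int N;
  const int *indptr;
  const int *indices;
  const double *delta;
  std::vector<double> beta;   // per-edge rate of node i towards a neighbour
  std::vector<char> inf;      // infection indicator
  std::vector<int> nsusc;     // susceptible-neighbour counts
  std::vector<double> rate;   // cached per-node total rate
  Fenwick fen;
  int nI;

  SISState(int N_, const int *ip, const int *ix, const double *d,
           const std::vector<double> &b)
      : N(N_), indptr(ip), indices(ix), delta(d), beta(b), inf(N_, 0),
        nsusc(N_, 0), rate(N_, 0.0), fen(N_), nI(0) {
    for (int i = 0; i < N; ++i) nsusc[i] = indptr[i + 1] - indptr[i];
  }

  void setRate(int i, double r) {
    fen.add(i, r - rate[i]);
    rate[i] = r;
  }

  void infect(int i) {
    inf[i] = 1;
    ++nI;
    for (int e = indptr[i]; e < indptr[i + 1]; ++e) {
      int j = indices[e];
      --nsusc[j];
      if (inf[j]) setRate(j, rate[j] - beta[j]);
    }
    setRate(i, delta[i] + beta[i] * nsusc[i]);
  }

  void recover(int i) {
    inf[i] = 0;
    --nI;
    setRate(i, 0.0);
    for (int e = indptr[i]; e < indptr[i + 1]; ++e) {
      int j = indices[e];
      ++nsusc[j];
      if (inf[j]) setRate(j, rate[j] + beta[j]);
    }
  }

  // valid only when all nodes are susceptible
  void restore(const std::vector<int> &config) {
    for (int i : config) infect(i);
  }

  std::vector<int> snapshot() const {
    std::vector<int> out;
    out.reserve(nI);
    for (int i = 0; i < N; ++i)
      if (inf[i]) out.push_back(i);
    return out;
  }
};

// Quasistationary Gillespie run. Continuous-time SIS with per-node recovery
// rates delta and per-edge transmission rate lambda (uniform) or lambda/k_i
// (contact process, cp = true). On absorption the state is replaced by a
// uniformly drawn member of a store of previously visited active
// configurations; the store is refreshed with probability
// p_store * dt per event. After relax_time, the infected count is sampled on
// a fixed time grid to build the quasistationary histogram.
// [[Rcpp::export(name = ".qs_run_cpp")]]
List qs_run_cpp(IntegerVector indptr, IntegerVector indices,
                NumericVector delta, double lambda, bool cp,
                IntegerVector init_infected, double relax_time,
                double avg_time, int n_store, double p_store,
                double sample_interval) {
  const int N = delta.size();
  std::vector<double> beta(N);
  for (int i = 0; i < N; ++i) {
    int k = indptr[i + 1] - indptr[i];
    beta[i] = cp ? (k > 0 ? lambda / k : 0.0) : lambda;
  }
  SISState st(N, &indptr[0], &indices[0], &delta[0], beta);
  std::vector<int> init(init_infected.begin(), init_infected.end());
  st.restore(init);
  if (st.nI == 0) stop("initial configuration has no infected nodes");

  std::vector<std::vector<int>> store;
  store.reserve(n_store);
  store.push_back(init);

  const double t_end = relax_time + avg_time;
  double t = 0.0;
  double next_sample = relax_time;
  std::vector<double> hist(N + 1, 0.0);
  double n_samples = 0.0;
  long n_absorptions = 0;

  RNGScope scope;
  while (t < t_end) {
    double R = st.fen.total();
    if (R <= 0.0) stop("internal error: zero total rate in active state");
    double dt = ::exp_rand() / R;
    double t_new = t + dt;

    while (next_sample < t_new && next_sample <= t_end) {
      hist[st.nI] += 1.0;
      n_samples += 1.0;
      next_sample += sample_interval;
    }

    // refresh the configuration store on the p_store * dt schedule: grow it
    // until full, then replace a uniformly chosen slot. Filling on the same
    // clock keeps the initial transient from dominating the store.
    if (::unif_rand() < p_store * dt) {
      if ((int)store.size() < n_store) {
        store.push_back(st.snapshot());
      } else {
        int slot = (int)(::unif_rand() * store.size());
        if (slot >= (int)store.size()) slot = store.size() - 1;
        store[slot] = st.snapshot();
      }
    }

    t = t_new;
    if (t >= t_end) break;

    double u = ::unif_rand() * R;
    int i = st.fen.find(u);
    double ri = st.rate[i];
    if (::unif_rand() * ri < delta[i]) {
      st.recover(i);
      if (st.nI == 0) {
        ++n_absorptions;
        int slot = (int)(::unif_rand() * store.size());
        if (slot >= (int)store.size()) slot = store.size() - 1;
        st.restore(store[slot]);
      }
    } else {
      // infection: pick the m-th susceptible neighbour of i
      int m = (int)(::unif_rand() * st.nsusc[i]);
      if (m >= st.nsusc[i]) m = st.nsusc[i] - 1;
      int target = -1;
      for (int e = indptr[i]; e < indptr[i + 1]; ++e) {
        int j = indices[e];
        if (!st.inf[j] && m-- == 0) {
          target = j;
          break;
        }
      }
      if (target >= 0) st.infect(target);
    }
  }

  return List::create(
      _["hist_counts"] = NumericVector(hist.begin() + 1, hist.end()),
      _["n_samples"] = n_samples,
      _["n_absorptions"] = (double)n_absorptions,
      _["final_n_infected"] = st.nI);
}
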