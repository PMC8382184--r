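// Core integrators for the stochastic theta model on a weighted network.
//
// Noise streams are keyed per node (splitmix64 seeded from the run seed and
// a node key derived from the ROI label), so removing or permuting nodes
// leaves the remaining nodes' noise realizations untouched.  That makes
// node-removal BNI differences paired ("common random numbers") and gives
// exact permutation equivariance of seizure times.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

// splitmix64: small, fast, statistically solid for simulation noise
struct SplitMix64 {
  uint64_t s;
  explicit SplitMix64(uint64_t seed) : s(seed) {}
  uint64_t next() {
    uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  // uniform on (0,1)
  double unif() {
    return (static_cast<double>(next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
};

// Box-Muller with cached spare deviate
struct GaussStream {
  SplitMix64 rng;
  bool has_spare;
  double spare;
  explicit GaussStream(uint64_t seed) : rng(seed), has_spare(false), spare(0.0) {}
  double next() {
    if (has_spare) { has_spare = false; return spare; }
    double u1 = rng.unif(), u2 = rng.unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    double a = 2.0 * M_PI * u2;
    spare = r * std::sin(a);
    has_spare = true;
    return r * std::cos(a);
  }
};

inline uint64_t node_stream_seed(double seed, double key) {
  uint64_t s = static_cast<uint64_t>(seed);
  uint64_t k = static_cast<uint64_t>(key);
  return (s * 0x9E3779B97F4A7C15ULL) ^ (k + 0xD1B54A32D192ED03ULL);
}

struct StepperState {
  int N;
  arma::mat A;              // symmetric adjacency, a(j,i) weights j -> i
  double I0, K, sigma, dt, theta_s;
  double k_over_n;          // K / n_norm
  bool em;                  // true: Euler-Maruyama sqrt(dt) noise; false: dt convention
  bool has_noise_mat;
  arma::mat noise;          // N x (T-1) externally supplied deviates (optional)
  std::vector<GaussStream> streams;

  void advance(arma::vec& theta, int step) {
    arma::vec s(N);
    for (int j = 0; j < N; ++j) s[j] = 1.0 - std::cos(theta[j] - theta_s);
    arma::vec coup;
    if (K != 0.0) coup = k_over_n * (A.t() * s); else coup = arma::zeros(N);
    for (int i = 0; i < N; ++i) {
      double z = 0.0;
      if (sigma > 0.0 || has_noise_mat) {
        z = has_noise_mat ? noise(i, step) : streams[i].next();
      }
      double c = std::cos(theta[i]);
      double det_I = I0 + coup[i];
      double drift = (1.0 - c) + (1.0 + c) * det_I;
      if (em) {
        theta[i] += dt * drift + (1.0 + c) * sigma * std::sqrt(dt) * z;
      } else {
        theta[i] += dt * (drift + (1.0 + c) * sigma * z);
      }
    }
  }
};

StepperState make_stepper(const arma::mat& A, double I0, double K, double sigma,
                          double dt, double theta_s, double n_norm,
                          const NumericVector& node_keys, double seed,
                          bool em, SEXP noise_mat) {
  StepperState st;
  st.N = A.n_rows;
  st.A = A;
  st.I0 = I0; st.K = K; st.sigma = sigma; st.dt = dt; st.theta_s = theta_s;
  st.k_over_n = (n_norm > 0) ? K / n_norm : 0.0;
  st.em = em;
  st.has_noise_mat = !Rf_isNull(noise_mat);
  if (st.has_noise_mat) {
    st.noise = as<arma::mat>(noise_mat);
  } else {
    st.streams.reserve(st.N);
    for (int i = 0; i < st.N; ++i)
      st.streams.emplace_back(node_stream_seed(seed, node_keys[i]));
  }
  return st;
}

} // namespace

// Full phase trajectories: N x T matrix, column 1 the initial condition,
// T-1 Euler steps.
// [[Rcpp::export(name = ".cpp_theta_phases")]]
arma::mat cpp_theta_phases(const arma::mat& A, double I0, double K, double sigma,
                           double dt, int T, double theta_s, const arma::vec& theta0,
                           double n_norm, NumericVector node_keys, double seed,
                           bool em, SEXP noise_mat) {
  StepperState st = make_stepper(A, I0, K, sigma, dt, theta_s, n_norm,
                                 node_keys, seed, em, noise_mat);
  int N = st.N;
  arma::mat out(N, T);
  arma::vec theta = theta0;
  out.col(0) = theta;
  for (int t = 1; t < T; ++t) {
    st.advance(theta, t - 1);
    out.col(t) = theta;
  }
  return out;
}

// Streaming simulate + classify: returns per-node counts of scored seizure
// samples (samples with index >= burn_in, 0-based) without storing phases.
// Classifier: raw indicator 1 - cos(theta - theta_ref) > 1, centered moving
// average over `window` samples (truncated at the edges), smoothed value
// strictly above 0.5 (integer comparison 2*sum > len).
// [[Rcpp::export(name = ".cpp_theta_tsz")]]
IntegerVector cpp_theta_tsz(const arma::mat& A, double I0, double K, double sigma,
                            double dt, int T, double theta_s, const arma::vec& theta0,
                            double n_norm, NumericVector node_keys, double seed,
                            bool em, SEXP noise_mat, double theta_ref,
                            int window, int burn_in) {
  StepperState st = make_stepper(A, I0, K, sigma, dt, theta_s, n_norm,
                                 node_keys, seed, em, noise_mat);
  int N = st.N;
  std::vector<unsigned char> r(static_cast<size_t>(N) * T);
  arma::vec theta = theta0;
  for (int i = 0; i < N; ++i)
    r[static_cast<size_t>(i) * T] =
      (1.0 - std::cos(theta[i] - theta_ref)) > 1.0 ? 1 : 0;
  for (int t = 1; t < T; ++t) {
    st.advance(theta, t - 1);
    for (int i = 0; i < N; ++i)
      r[static_cast<size_t>(i) * T + t] =
        (1.0 - std::cos(theta[i] - theta_ref)) > 1.0 ? 1 : 0;
  }
  int h = window / 2;
  IntegerVector counts(N);
  for (int i = 0; i < N; ++i) {
    const unsigned char* ri = &r[static_cast<size_t>(i) * T];
    // prefix sums for truncated centered windows
    std::vector<int> cs(T + 1, 0);
    for (int t = 0; t < T; ++t) cs[t + 1] = cs[t] + ri[t];
    int cnt = 0;
    for (int t = burn_in; t < T; ++t) {
      int lo = t - h; if (lo < 0) lo = 0;
      int hi = t + h; if (hi > T - 1) hi = T - 1;
      int len = hi - lo + 1;
      int s = cs[hi + 1] - cs[lo];
      if (2 * s > len) ++cnt;
    }
    counts[i] = cnt;
  }
  return counts;
}

// Column medians (bootstrap-surrogate helper; avoids an R apply() over
// hundreds of thousands of columns).
// [[Rcpp::export(name = ".cpp_col_medians")]]
arma::rowvec cpp_col_medians(const arma::mat& x) {
  return arma::median(x, 0);
}

// Iterative amplitude adjusted Fourier transform surrogate of one channel.
// Keeps the exact amplitude distribution of x; matches the amplitude
// spectrum iteratively.  Returns the surrogate with attributes
// `iterations` and `spec_error` (relative L2 error of the magnitude
// spectrum at exit).
// [[Rcpp::export(name = ".cpp_iaaft")]]
NumericVector cpp_iaaft(const arma::vec& x, int n_iter, double tol, double seed) {
  int n = x.n_elem;
  arma::vec amp_sorted = arma::sort(x);
  arma::cx_vec X = arma::fft(x);
  arma::vec target_mag = arma::abs(X);
  double target_norm = arma::norm(target_mag);

  // random initial permutation of the amplitude values
  SplitMix64 rng(node_stream_seed(seed, 0x5DEECE66D));
  arma::vec y = x;
  for (int i = n - 1; i > 0; --i) {
    int j = static_cast<int>(rng.next() % static_cast<uint64_t>(i + 1));
    std::swap(y[i], y[j]);
  }

  double err = arma::datum::inf;
  double prev_err = arma::datum::inf;
  int it = 0;
  for (it = 0; it < n_iter; ++it) {
    arma::cx_vec Y = arma::fft(y);
    arma::vec mag = arma::abs(Y);
    arma::cx_vec Y2(n);
    for (int k = 0; k < n; ++k) {
      if (mag[k] > 0)
        Y2[k] = target_mag[k] * Y[k] / mag[k];
      else
        Y2[k] = arma::cx_double(target_mag[k], 0.0);
    }
    arma::vec y2 = arma::real(arma::ifft(Y2));
    // rank remap onto the original amplitude distribution
    arma::uvec idx = arma::sort_index(y2);
    for (int k = 0; k < n; ++k) y[idx[k]] = amp_sorted[k];
    err = arma::norm(arma::abs(arma::fft(y)) - target_mag) / target_norm;
    if (err < tol) { ++it; break; }
    // plateau: further iterations trade the same spectral error around
    if (prev_err - err < 0.05 * err) { ++it; break; }
    prev_err = err;
  }
  NumericVector out(y.begin(), y.end());
  out.attr("iterations") = it;
  out.attr("spec_error") = err;
  return out;
}
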