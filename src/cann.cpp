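// Three-layer ring-attractor (CANN) batch integrator.
//
// Layers: MT (visual), PIVC (vestibular), multisensory subnetwork.
// All trials in a batch share the dynamics parameters and noise SD but may
// differ in input centers, input amplitudes and forward weights, so a whole
// sweep cell (or a mixed 1000-trial group experiment) runs as one batch and
// the lateral term becomes a single L x 3N dgemm per Euler step.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline double circ_deg(double a, double b) {
  double x = std::fabs(a - b);
  while (x >= 360.0) x -= 360.0;
  if (x > 180.0) x = 360.0 - x;
  return x;
}

// Deterministic Gaussian stream: splitmix64-seeded mt19937_64 + Box-Muller.
// std::normal_distribution is implementation-defined, so we roll the
// transform by hand for cross-platform reproducibility.
struct GaussStream {
  std::mt19937_64 eng;
  bool has_spare = false;
  double spare = 0.0;
  explicit GaussStream(uint64_t seed) {
    uint64_t z = seed + 0x9E3779B97F4A7C15ULL;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    eng.seed(z ^ (z >> 31));
  }
  double unif() { // in (0,1)
    return (static_cast<double>(eng() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double norm() {
    if (has_spare) { has_spare = false; return spare; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    double a = 6.283185307179586 * u2;
    spare = r * std::sin(a);
    has_spare = true;
    return r * std::cos(a);
  }
};

// [[Rcpp::export]]
Rcpp::List cann_run_batch_cpp(const arma::vec& theta_vis,
                              const arma::vec& theta_ves,
                              const arma::vec& w_mt,
                              const arma::vec& w_pivc,
                              const arma::vec& amp_vis,
                              const arma::vec& amp_ves,
                              const Rcpp::List& par,
                              double sigma_noise,
                              double beta_scale,
                              double duration,
                              double seed,
                              double record_every,
                              Rcpp::Nullable<Rcpp::NumericMatrix> y0_ = R_NilValue) {
  const int L = Rcpp::as<int>(par["L"]);
  const double tau   = Rcpp::as<double>(par["tau"]);
  const double dt    = Rcpp::as<double>(par["dt"]);
  const double gain  = Rcpp::as<double>(par["gain"]);
  const double offs  = Rcpp::as<double>(par["offset"]);
  const double w_ex  = Rcpp::as<double>(par["w_ex"]);
  const double s_ex  = Rcpp::as<double>(par["sigma_ex"]);
  const double w_in  = Rcpp::as<double>(par["w_in"]);
  const double s_in  = Rcpp::as<double>(par["sigma_in"]);
  const double w_ext = Rcpp::as<double>(par["w_external"]);
  const double s_ext = Rcpp::as<double>(par["sigma_external"]);
  const double s_fwd = Rcpp::as<double>(par["sigma_forward"]);
  const double final_window = Rcpp::as<double>(par["final_window"]);

  const int N = theta_vis.n_elem;
  const int n_steps = (int) std::lround(duration / dt);
  const double deg_per = 360.0 / L;

  // lateral kernel (Mexican hat, zero self-weight) and forward kernel
  mat Wlat(L, L), Kf(L, L);
  for (int j = 0; j < L; ++j) {
    for (int k = 0; k < L; ++k) {
      double idx = std::abs(j - k);
      double d = deg_per * std::min(idx, L - idx);
      Kf(j, k) = std::exp(-d * d / (2.0 * s_fwd * s_fwd));
      Wlat(j, k) = (j == k) ? 0.0
        : beta_scale * (w_ex * std::exp(-d * d / (2.0 * s_ex * s_ex))
                      - w_in * std::exp(-d * d / (2.0 * s_in * s_in)));
    }
  }

  // external inputs to the unisensory layers (fixed over the trial)
  mat Iext_mt(L, N), Iext_pivc(L, N);
  for (int n = 0; n < N; ++n) {
    for (int k = 0; k < L; ++k) {
      double pos = deg_per * k;
      double dv = circ_deg(theta_vis(n), pos);
      double de = circ_deg(theta_ves(n), pos);
      Iext_mt(k, n)   = amp_vis(n) * w_ext * std::exp(-dv * dv / (2.0 * s_ext * s_ext));
      Iext_pivc(k, n) = amp_ves(n) * w_ext * std::exp(-de * de / (2.0 * s_ext * s_ext));
    }
  }

  mat Y(L, 3 * N, fill::zeros);
  if (y0_.isNotNull()) {
    Rcpp::NumericMatrix y0(y0_);
    if (y0.nrow() != L || y0.ncol() != 3 * N)
      Rcpp::stop("y0 must be L x 3N");
    Y = mat(y0.begin(), L, 3 * N);
  }

  const int rec_stride = record_every > 0 ? (int) std::lround(record_every / dt) : 0;
  const int n_rec = rec_stride > 0 ? n_steps / rec_stride : 0;
  cube traj;
  mat sum_mt, sum_pivc, sum_sub;
  vec rec_t;
  if (n_rec > 0) {
    traj.set_size(L, n_rec, N);
    sum_mt.set_size(n_rec, N);
    sum_pivc.set_size(n_rec, N);
    sum_sub.set_size(n_rec, N);
    rec_t.set_size(n_rec);
  }

  GaussStream rng((uint64_t) seed);
  const int final_from = n_steps - (int) std::lround(final_window / dt);
  mat Yfinal(L, 3 * N, fill::zeros);
  int n_final = 0;

  mat Iall(L, 3 * N), U(L, N), Ifwd(L, N);
  const rowvec wm = w_mt.t(), wp = w_pivc.t();
  int rec_i = 0;

  for (int s = 0; s < n_steps; ++s) {
    Iall = Wlat * Y;
    U = Y.cols(0, N - 1).each_row() % wm
      + Y.cols(N, 2 * N - 1).each_row() % wp;
    Ifwd = Kf * U;
    Iall.cols(0, N - 1) += Iext_mt;
    Iall.cols(N, 2 * N - 1) += Iext_pivc;
    Iall.cols(2 * N, 3 * N - 1) += Ifwd;
    if (sigma_noise > 0) {
      double* p = Iall.memptr();
      const uword ne = Iall.n_elem;
      for (uword i = 0; i < ne; ++i) p[i] += sigma_noise * rng.norm();
    }
    // S(I) = 1 / (1 + exp(-gain (I - offset))), increasing in I
    Iall = 1.0 / (1.0 + exp(-gain * (Iall - offs)));
    Y += (dt / tau) * (Iall - Y);

    if (s >= final_from) { Yfinal += Y; ++n_final; }
    if (rec_stride > 0 && (s + 1) % rec_stride == 0 && rec_i < n_rec) {
      for (int n = 0; n < N; ++n) traj.slice(n).col(rec_i) = Y.col(2 * N + n);
      sum_mt.row(rec_i)   = sum(Y.cols(0, N - 1), 0);
      sum_pivc.row(rec_i) = sum(Y.cols(N, 2 * N - 1), 0);
      sum_sub.row(rec_i)  = sum(Y.cols(2 * N, 3 * N - 1), 0);
      rec_t(rec_i) = (s + 1) * dt;
      ++rec_i;
    }
  }
  Yfinal /= std::max(n_final, 1);

  Rcpp::LogicalVector finite(N);
  for (int n = 0; n < N; ++n)
    finite[n] = Y.col(n).is_finite() && Y.col(N + n).is_finite() &&
                Y.col(2 * N + n).is_finite();

  Rcpp::List out = Rcpp::List::create(
    Rcpp::Named("mt")    = Rcpp::wrap(Yfinal.cols(0, N - 1)),
    Rcpp::Named("pivc")  = Rcpp::wrap(Yfinal.cols(N, 2 * N - 1)),
    Rcpp::Named("sub")   = Rcpp::wrap(Yfinal.cols(2 * N, 3 * N - 1)),
    Rcpp::Named("y_end") = Rcpp::wrap(Y),
    Rcpp::Named("finite") = finite);
  if (n_rec > 0) {
    out["traj"] = Rcpp::wrap(traj);
    out["sum_mt"] = Rcpp::wrap(sum_mt);
    out["sum_pivc"] = Rcpp::wrap(sum_pivc);
    out["sum_sub"] = Rcpp::wrap(sum_sub);
    out["times"] = Rcpp::wrap(rec_t);
  }
  return out;
}
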