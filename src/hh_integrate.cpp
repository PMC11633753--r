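// Fixed-step implicit integrator for an unbranched chain of Hodgkin-Huxley
// compartments. Voltage uses backward Euler with a tridiagonal (Thomas)
// solve; gating variables use exponential Euler evaluated at the previous
// voltage (staggered update). Units: mV, ms, nF, uS, nA.
#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

// Deterministic RNG: splitmix64 stream with an explicit Box-Muller so the
// noise sequence is bit-identical across platforms and standard libraries.
struct Rng {
  uint64_t s;
  bool have_spare = false;
  double spare = 0.0;
  explicit Rng(uint64_t seed) : s(seed ? seed : 0x9e3779b97f4a7c15ULL) {}
  uint64_t next_u64() {
    uint64_t z = (s += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  double next_unif() {  // (0, 1)
    return ((next_u64() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double next_norm() {
    if (have_spare) { have_spare = false; return spare; }
    double u1 = next_unif(), u2 = next_unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    double th = 6.283185307179586476925286766559 * u2;
    spare = r * std::sin(th);
    have_spare = true;
    return r * std::cos(th);
  }
};

inline double vtrap(double x, double y) {
  // x / (exp(x/y) - 1) with the removable singularity at x = 0 patched.
  return (std::fabs(x / y) < 1e-6) ? y * (1.0 - x / y / 2.0) : x / (std::exp(x / y) - 1.0);
}

// Canonical squid-axon rate functions (6.3 degC), mV and 1/ms.
inline double alpha_m(double v) { return 0.1 * vtrap(-(v + 40.0), 10.0); }
inline double beta_m(double v)  { return 4.0 * std::exp(-(v + 65.0) / 18.0); }
inline double alpha_h(double v) { return 0.07 * std::exp(-(v + 65.0) / 20.0); }
inline double beta_h(double v)  { return 1.0 / (1.0 + std::exp(-(v + 35.0) / 10.0)); }
inline double alpha_n(double v) { return 0.01 * vtrap(-(v + 55.0), 10.0); }
inline double beta_n(double v)  { return 0.125 * std::exp(-(v + 65.0) / 80.0); }

constexpr double TAB_VMIN = -120.0;
constexpr double TAB_DV = 0.05;
constexpr int TAB_N = 4401;  // covers [-120, 100] mV

// Interleaved rate table: per grid point {m_inf, exp(-dt*(am+bm)), h_inf,
// exp(-dt*(ah+bh)), n_inf, exp(-dt*(an+bn))}. dt-dependent, rebuilt per
// call; construction cost is negligible next to the stepping loop.
std::vector<double> build_tables(double dt) {
  std::vector<double> tab(6 * TAB_N);
  for (int i = 0; i < TAB_N; ++i) {
    double v = TAB_VMIN + i * TAB_DV;
    double am = alpha_m(v), bm = beta_m(v);
    double ah = alpha_h(v), bh = beta_h(v);
    double an = alpha_n(v), bn = beta_n(v);
    tab[6 * i + 0] = am / (am + bm);
    tab[6 * i + 1] = std::exp(-dt * (am + bm));
    tab[6 * i + 2] = ah / (ah + bh);
    tab[6 * i + 3] = std::exp(-dt * (ah + bh));
    tab[6 * i + 4] = an / (an + bn);
    tab[6 * i + 5] = std::exp(-dt * (an + bn));
  }
  return tab;
}

}  // namespace

//' @noRd
// [[Rcpp::export(name = ".hh_integrate_cpp")]]
List hh_integrate_cpp(NumericVector v_init,
                      NumericVector cap_nF,
                      NumericVector gna_uS,
                      NumericVector gk_uS,
                      NumericVector gpas_uS,
                      double ena, double ek, double epas,
                      NumericVector g_axial_uS,
                      double dt, double n_steps_d,
                      NumericVector syn_g_uS,   // length n_steps or 0
                      int syn_node, double e_syn,
                      int noise_node, double noise_mean_nA, double noise_sd_nA,
                      int inj_node, NumericVector inj_nA,  // length n_steps, 1 or 0
                      int spike_node, double spike_thresh, double refractory_ms,
                      IntegerVector record_nodes, int record_every,
                      double seed,
                      NumericVector gating_init) {
  const int N = v_init.size();
  const R_xlen_t n_steps = (R_xlen_t)n_steps_d;
  if (cap_nF.size() != N || gna_uS.size() != N || gk_uS.size() != N ||
      gpas_uS.size() != N || g_axial_uS.size() != N - 1)
    stop("inconsistent compartment vector lengths");
  if (dt <= 0) stop("dt must be positive");
  if (syn_g_uS.size() > 0 && syn_g_uS.size() < n_steps)
    stop("synaptic conductance vector shorter than n_steps");

  std::vector<double> V_(v_init.begin(), v_init.end());
  std::vector<double> m_(N), h_(N), n_(N);
  if (gating_init.size() == 3 * N) {
    for (int i = 0; i < N; ++i) {
      m_[i] = gating_init[i];
      h_[i] = gating_init[N + i];
      n_[i] = gating_init[2 * N + i];
    }
  } else {
    for (int i = 0; i < N; ++i) {
      double v = V_[i];
      m_[i] = alpha_m(v) / (alpha_m(v) + beta_m(v));
      h_[i] = alpha_h(v) / (alpha_h(v) + beta_h(v));
      n_[i] = alpha_n(v) / (alpha_n(v) + beta_n(v));
    }
  }

  const std::vector<double> tab_ = build_tables(dt);
  Rng rng((uint64_t)seed);

  const bool have_syn = syn_g_uS.size() > 0;
  const bool have_noise = noise_sd_nA > 0.0 || noise_mean_nA != 0.0;
  const bool inj_const = inj_nA.size() == 1;
  const bool have_inj = inj_nA.size() > 0;

  const int n_rec_nodes = record_nodes.size();
  R_xlen_t n_rec_steps = (record_every > 0 && n_rec_nodes > 0)
                             ? (n_steps / record_every + 1) : 0;
  NumericMatrix vrec(n_rec_steps, n_rec_nodes);
  R_xlen_t rec_i = 0;
  if (n_rec_steps > 0) {
    for (int j = 0; j < n_rec_nodes; ++j) vrec(0, j) = V_[record_nodes[j]];
    rec_i = 1;
  }
  R_xlen_t rec_countdown = (n_rec_steps > 0) ? record_every : -1;

  std::vector<double> spikes;
  double last_spike = -1e30;
  double v_spike_prev = (spike_node >= 0) ? V_[spike_node] : 0.0;

  std::vector<double> diag_(N), rhs_(N), cp_(N), dp_(N), cinv_(N);
  std::vector<double> gax_(g_axial_uS.begin(), g_axial_uS.end());
  std::vector<double> gna2_(gna_uS.begin(), gna_uS.end());
  std::vector<double> gk2_(gk_uS.begin(), gk_uS.end());
  std::vector<double> gpas2_(gpas_uS.begin(), gpas_uS.end());
  for (int i = 0; i < N; ++i) cinv_[i] = cap_nF[i] / dt;
  std::vector<double> syn2_(syn_g_uS.begin(), syn_g_uS.end());
  std::vector<double> inj2_(inj_nA.begin(), inj_nA.end());

  // Raw restrict pointers: keeps the hot loop free of aliasing assumptions.
  double *__restrict V = V_.data();
  double *__restrict m = m_.data();
  double *__restrict h = h_.data();
  double *__restrict nv = n_.data();
  double *__restrict diag = diag_.data();
  double *__restrict rhs = rhs_.data();
  double *__restrict cp = cp_.data();
  double *__restrict dp = dp_.data();
  const double *__restrict cinv = cinv_.data();
  const double *__restrict gax = gax_.data();
  const double *__restrict gna = gna2_.data();
  const double *__restrict gk = gk2_.data();
  const double *__restrict gpas = gpas2_.data();
  const double *__restrict tab = tab_.data();
  const double *__restrict syn = syn2_.data();
  const double *__restrict inj = inj2_.data();

  bool diverged = false;
  double diverge_t = 0.0;

  for (R_xlen_t step = 0; step < n_steps; ++step) {
    // gating update (exponential Euler at V_t) + membrane terms
    for (int i = 0; i < N; ++i) {
      double v = V[i];
      if (!(v > -200.0 && v < 200.0)) { diverged = true; diverge_t = step * dt; break; }
      double x = (v - TAB_VMIN) * (1.0 / TAB_DV);
      int k = (int)x;
      double f = x - k;
      const double *T = tab + 6 * k;
      double mi  = T[0] + f * (T[6]  - T[0]);
      double efm = T[1] + f * (T[7]  - T[1]);
      double hi  = T[2] + f * (T[8]  - T[2]);
      double efh = T[3] + f * (T[9]  - T[3]);
      double ni  = T[4] + f * (T[10] - T[4]);
      double efn = T[5] + f * (T[11] - T[5]);
      double mm = mi + (m[i] - mi) * efm;
      double hh = hi + (h[i] - hi) * efh;
      double nn = ni + (nv[i] - ni) * efn;
      m[i] = mm; h[i] = hh; nv[i] = nn;
      double gna_i = gna[i] * mm * mm * mm * hh;
      double n2 = nn * nn;
      double gk_i = gk[i] * n2 * n2;
      diag[i] = cinv[i] + gna_i + gk_i + gpas[i];
      rhs[i]  = cinv[i] * v + gna_i * ena + gk_i * ek + gpas[i] * epas;
    }
    if (diverged) break;
    for (int i = 0; i < N - 1; ++i) {
      diag[i] += gax[i];
      diag[i + 1] += gax[i];
    }
    if (have_syn) {  // receptor conductance, handled implicitly
      double gs = syn[step];
      diag[syn_node] += gs;
      rhs[syn_node] += gs * e_syn;
    }
    if (have_noise)
      rhs[noise_node] += noise_mean_nA + noise_sd_nA * rng.next_norm();
    if (have_inj)
      rhs[inj_node] += inj_const ? inj[0] : inj[step];

    // Thomas solve: sub/super diagonals are -gax
    cp[0] = (N > 1) ? -gax[0] / diag[0] : 0.0;
    dp[0] = rhs[0] / diag[0];
    for (int i = 1; i < N; ++i) {
      double mlt = 1.0 / (diag[i] + gax[i - 1] * cp[i - 1]);
      cp[i] = (i < N - 1) ? -gax[i] * mlt : 0.0;
      dp[i] = (rhs[i] + gax[i - 1] * dp[i - 1]) * mlt;
    }
    V[N - 1] = dp[N - 1];
    for (int i = N - 2; i >= 0; --i) V[i] = dp[i] - cp[i] * V[i + 1];

    if (spike_node >= 0) {
      double v_now = V[spike_node];
      if (v_spike_prev < spike_thresh && v_now >= spike_thresh) {
        double t_now = (step + 1) * dt;
        if (t_now - last_spike >= refractory_ms) {
          spikes.push_back(t_now);
          last_spike = t_now;
        }
      }
      v_spike_prev = v_now;
    }
    if (rec_countdown > 0 && --rec_countdown == 0) {
      if (rec_i < n_rec_steps) {
        for (int j = 0; j < n_rec_nodes; ++j) vrec(rec_i, j) = V[record_nodes[j]];
        ++rec_i;
      }
      rec_countdown = record_every;
    }
  }

  if (diverged)
    stop("membrane potential diverged (|V| > 200 mV) at t = %.3f ms; reduce dt (currently %g ms)",
         diverge_t, dt);

  NumericVector gating_out(3 * N);
  for (int i = 0; i < N; ++i) {
    gating_out[i] = m_[i];
    gating_out[N + i] = h_[i];
    gating_out[2 * N + i] = n_[i];
  }
  return List::create(_["spikes"] = NumericVector(spikes.begin(), spikes.end()),
                      _["v"] = vrec,
                      _["v_final"] = NumericVector(V_.begin(), V_.end()),
                      _["gating_final"] = gating_out);
}
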