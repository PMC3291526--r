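#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Fast in-loop RNG: xoshiro256++ seeded once per call from R's uniform
// stream (so set.seed() fully determines every simulation), with
// Box-Muller normals and a cached spare.  The per-time-step draw pattern
// is fixed regardless of spiking outcomes.
struct FastRng {
  uint64_t s[4];
  explicit FastRng() {
    // splitmix64 expansion of a 64-bit seed taken from R's RNG
    uint64_t x = (uint64_t)(unif_rand() * 4294967296.0) << 32 |
                 (uint64_t)(unif_rand() * 4294967296.0);
    for (int i = 0; i < 4; ++i) {
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double uniform() {  // in (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  bool has_spare = false;
  double spare = 0.0;
  inline double normal() {
    if (has_spare) { has_spare = false; return spare; }
    const double u1 = uniform();
    const double u2 = uniform();
    const double r = std::sqrt(-2.0 * std::log(u1));
    const double a = 6.283185307179586 * u2;
    spare = r * std::sin(a);
    has_spare = true;
    return r * std::cos(a);
  }
};

// Conductance-based leaky integrate-and-fire dynamics for one stimulus
// presentation of the two-layer network, forward-Euler with dt = 1 ms.
//
// Lower-layer neurons receive three conductance inputs: rate-coded external
// stimulus spikes (mean Jbar[i] * envelope[t], Gaussian per time-step,
// rectified at zero), excitatory Gaussian noise, and delayed top-down spikes
// weighted by W (weights may be negative, so the total conductance can be
// negative and hyperpolarizing).  Higher-layer neurons receive delayed
// bottom-up spikes weighted by Q, the same noise process, and optionally
// their own external drive (Jbar_higher).  The conductance decays with time
// constant tau_syn and is reset to zero when the post-synaptic neuron fires,
// so it tracks the input accumulated since the neuron's last action
// potential.  All random draws use R's RNG, so results are reproducible via
// set.seed().
//
// g_clamp >= 0 freezes every conductance at that value (no increments, no
// decay, no reset); this diagnostic mode exposes the bare membrane equation
// for closed-form checks and is not used during training.
// [[Rcpp::export]]
List cpp_run_presentation(NumericMatrix Q, NumericMatrix W,
                          double tau_m, double V_rest, double E_exc,
                          double V_thresh, double V_reset,
                          double g_gain, double tau_syn, double dt,
                          NumericVector Jbar, NumericVector envelope,
                          double sigma_input, double noise_S,
                          double sigma_noise, int delay,
                          Nullable<NumericVector> Jbar_higher = R_NilValue,
                          double g_clamp = -1.0, bool record_V = false,
                          double coupling_gain = 1.0) {
  const int n_lower = W.nrow();
  const int n_higher = Q.nrow();
  const int T = envelope.size();
  if (Q.ncol() != n_lower || W.ncol() != n_higher)
    stop("cpp_run_presentation: Q/W shapes are not conjugate");
  if (delay < 1) stop("cpp_run_presentation: delay must be >= 1 ms");

  const bool clamped = g_clamp >= 0.0;
  const double decay = std::exp(-dt / tau_syn);
  const double dt_s = dt / 1000.0;  // ms -> s for rate-to-count conversion
  NumericVector JbarH;
  const bool has_higher_input = Jbar_higher.isNotNull();
  if (has_higher_input) {
    JbarH = Jbar_higher.get();
    if (JbarH.size() != n_higher)
      stop("cpp_run_presentation: Jbar_higher has wrong length");
  }

  FastRng rnorm_fast;
  IntegerMatrix L_spk(n_lower, T), H_spk(n_higher, T);
  std::vector<double> V_L(n_lower, V_rest), V_H(n_higher, V_rest);
  std::vector<double> g_L(n_lower, clamped ? g_clamp : 0.0);
  std::vector<double> g_H(n_higher, clamped ? g_clamp : 0.0);
  NumericMatrix V_L_trace;
  if (record_V) V_L_trace = NumericMatrix(n_lower, T);
  bool pathological = false;

  for (int t = 0; t < T && !pathological; ++t) {
    if (!clamped) {
      // synaptic decay
      for (int i = 0; i < n_lower; ++i) g_L[i] *= decay;
      for (int j = 0; j < n_higher; ++j) g_H[j] *= decay;
      // external stimulus + noise counts for the lower layer
      const double env = envelope[t];
      for (int i = 0; i < n_lower; ++i) {
        double inc = 0.0;
        if (env > 0.0) {
          const double mean_rate = Jbar[i] * env;
          double r = mean_rate * (1.0 + sigma_input * rnorm_fast.normal());
          if (r > 0.0) inc += r * dt_s;
        }
        double s = noise_S * (1.0 + sigma_noise * rnorm_fast.normal());
        if (s > 0.0) inc += s * dt_s;
        g_L[i] += g_gain * inc;
      }
      // noise (and optional external drive) for the higher layer
      for (int j = 0; j < n_higher; ++j) {
        double inc = 0.0;
        if (has_higher_input && env > 0.0) {
          const double mean_rate = JbarH[j] * env;
          double r = mean_rate * (1.0 + sigma_input * rnorm_fast.normal());
          if (r > 0.0) inc += r * dt_s;
        }
        double s = noise_S * (1.0 + sigma_noise * rnorm_fast.normal());
        if (s > 0.0) inc += s * dt_s;
        g_H[j] += g_gain * inc;
      }
      // delayed inter-layer spikes
      const int td = t - delay;
      if (td >= 0) {
        const double gc = g_gain * coupling_gain;
        for (int j = 0; j < n_higher; ++j) {
          if (H_spk(j, td)) {
            for (int i = 0; i < n_lower; ++i)
              g_L[i] += gc * W(i, j);
          }
        }
        for (int i = 0; i < n_lower; ++i) {
          if (L_spk(i, td)) {
            for (int j = 0; j < n_higher; ++j)
              g_H[j] += gc * Q(j, i);
          }
        }
      }
    }
    // membrane update and threshold crossing
    for (int i = 0; i < n_lower; ++i) {
      V_L[i] += (dt / tau_m) * ((V_rest - V_L[i]) + g_L[i] * (E_exc - V_L[i]));
      if (!std::isfinite(V_L[i])) { pathological = true; break; }
      if (V_L[i] >= V_thresh) {
        L_spk(i, t) = 1;
        V_L[i] = V_reset;
        if (!clamped) g_L[i] = 0.0;
      }
      if (record_V) V_L_trace(i, t) = V_L[i];
    }
    for (int j = 0; j < n_higher && !pathological; ++j) {
      V_H[j] += (dt / tau_m) * ((V_rest - V_H[j]) + g_H[j] * (E_exc - V_H[j]));
      if (!std::isfinite(V_H[j])) { pathological = true; break; }
      if (V_H[j] >= V_thresh) {
        H_spk(j, t) = 1;
        V_H[j] = V_reset;
        if (!clamped) g_H[j] = 0.0;
      }
    }
  }

  double nL = 0.0, nH = 0.0;
  for (int t = 0; t < T; ++t) {
    for (int i = 0; i < n_lower; ++i) nL += L_spk(i, t);
    for (int j = 0; j < n_higher; ++j) nH += H_spk(j, t);
  }
  const double dur_s = T * dt_s;
  List out = List::create(
    _["lower_spikes"] = L_spk,
    _["higher_spikes"] = H_spk,
    _["rate_lower"] = nL / n_lower / dur_s,
    _["rate_higher"] = nH / n_higher / dur_s,
    _["pathological"] = pathological);
  if (record_V) out["V_lower"] = V_L_trace;
  return out;
}

// Exact all-pairs exponential-window pair sums between higher-layer
// (pre-synaptic) and lower-layer (post-synaptic) spike trains, computed with
// per-neuron exponential traces.  pre_post(i, j) accumulates
// exp(-(tL - tH)/tau) over all pairs with the higher spike strictly earlier;
// post_pre(i, j) accumulates exp(-(tH - tL)/tau) over all pairs with the
// lower spike strictly earlier.  Simultaneous spikes (same 1-ms bin) have no
// defined temporal order and contribute to neither sum.
// [[Rcpp::export]]
List cpp_stdp_pair_sums(IntegerMatrix L_spk, IntegerMatrix H_spk,
                        double tau_stdp, double dt = 1.0) {
  const int n_lower = L_spk.nrow();
  const int n_higher = H_spk.nrow();
  const int T = L_spk.ncol();
  if (H_spk.ncol() != T) stop("cpp_stdp_pair_sums: spike rasters differ in length");
  const double decay = std::exp(-dt / tau_stdp);

  // pre_post is accumulated transposed (n_higher x n_lower) so that both
  // accumulation loops write contiguous columns
  NumericMatrix pre_post_t(n_higher, n_lower), post_pre(n_lower, n_higher);
  std::vector<double> traceL(n_lower, 0.0), traceH(n_higher, 0.0);
  const int* Lp = INTEGER(L_spk);
  const int* Hp = INTEGER(H_spk);
  double* ppt = REAL(pre_post_t);
  double* pp = REAL(post_pre);

  for (int t = 0; t < T; ++t) {
    const int* Lt = Lp + (size_t)t * n_lower;
    const int* Ht = Hp + (size_t)t * n_higher;
    for (int i = 0; i < n_lower; ++i) traceL[i] *= decay;
    for (int j = 0; j < n_higher; ++j) traceH[j] *= decay;
    for (int i = 0; i < n_lower; ++i) {
      if (Lt[i]) {
        double* col = ppt + (size_t)i * n_higher;
        for (int j = 0; j < n_higher; ++j) col[j] += traceH[j];
      }
    }
    for (int j = 0; j < n_higher; ++j) {
      if (Ht[j]) {
        double* col = pp + (size_t)j * n_lower;
        for (int i = 0; i < n_lower; ++i) col[i] += traceL[i];
      }
    }
    for (int i = 0; i < n_lower; ++i) if (Lt[i]) traceL[i] += 1.0;
    for (int j = 0; j < n_higher; ++j) if (Ht[j]) traceH[j] += 1.0;
  }
  NumericMatrix pre_post(n_lower, n_higher);
  for (int j = 0; j < n_higher; ++j)
    for (int i = 0; i < n_lower; ++i)
      pre_post(i, j) = pre_post_t(j, i);
  return List::create(_["pre_post"] = pre_post, _["post_pre"] = post_pre);
}
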