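// Fast survival engine for threshold-hazard (GUTS) models.
//
// Damage follows first-order kinetics dD/dt = ke * (C(t) - D) with C(t)
// piecewise linear between measured concentrations; the solution is evaluated
// in closed form per exposure segment, so the only discretisation error in
// the survival probabilities comes from the time grid used for the hazard
// integral and from the threshold grid.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

// 1 - exp(-x), accurate for small x
inline double one_m_exp(double x) { return -std::expm1(-x); }

// Damage at time (s_k + dt) inside segment [s_k, s_{k+1}] given D(s_k) = D0,
// segment start concentration Ck and linear slope of C(t).
inline double damage_step(double D0, double Ck, double slope, double ke,
                          double dt) {
  const double x = ke * dt;
  const double em = one_m_exp(x);  // 1 - e^{-ke dt}
  double ramp;                     // dt - (1 - e^{-ke dt})/ke
  if (x < 1e-8) {
    // series branch: avoids 0/0 at ke == 0 and cancellation for tiny ke
    ramp = ke * dt * dt * (0.5 - x / 6.0);
  } else {
    ramp = dt - em / ke;
  }
  return D0 * (1.0 - em) + Ck * em + slope * ramp;
}

// Evaluate damage at sorted query times `t` (all >= 0), with D(0) = 0.
// Exposure is held constant at the last measured concentration beyond the
// last exposure time point.
std::vector<double> damage_at_times(const NumericVector& C,
                                    const NumericVector& Ct,
                                    double ke,
                                    const std::vector<double>& t) {
  const int K = C.size();
  std::vector<double> D(t.size());
  int k = 0;             // current exposure segment index
  double Dstart = 0.0;   // damage at segment start
  for (size_t q = 0; q < t.size(); ++q) {
    // advance segments until t[q] lies in [Ct[k], Ct[k+1]] (or beyond last)
    while (k < K - 1 && t[q] > Ct[k + 1]) {
      const double len = Ct[k + 1] - Ct[k];
      const double slope = (C[k + 1] - C[k]) / len;
      Dstart = damage_step(Dstart, C[k], slope, ke, len);
      ++k;
    }
    if (k < K - 1) {
      const double slope = (C[k + 1] - C[k]) / (Ct[k + 1] - Ct[k]);
      D[q] = damage_step(Dstart, C[k], slope, ke, t[q] - Ct[k]);
    } else {
      // constant extrapolation at the last measured concentration
      D[q] = damage_step(Dstart, C[K - 1], 0.0, ke, t[q] - Ct[K - 1]);
    }
  }
  return D;
}

// index of first fine-grid point tau_l = l * dtau with tau_l >= t (i.e. the
// number of grid points strictly before t); capped at M
inline int cut_index(double t, double dtau, int M) {
  int cut = (int)std::ceil(t / dtau - 1e-9);
  if (cut < 0) cut = 0;
  if (cut > M) cut = M;
  return cut;
}

}  // namespace

// Damage on the equidistant grid tau_l = l * tn/M, l = 0..M-1 (exported for
// the naive-summation oracle and the forward simulator).
// [[Rcpp::export(name = ".guts_damage_grid")]]
NumericVector guts_damage_grid(NumericVector C, NumericVector Ct, double ke,
                               double tn, int M) {
  const double dtau = tn / M;
  std::vector<double> tau(M);
  for (int l = 0; l < M; ++l) tau[l] = l * dtau;
  std::vector<double> D = damage_at_times(C, Ct, ke, tau);
  return NumericVector(D.begin(), D.end());
}

// Exact damage at arbitrary sorted times.
// [[Rcpp::export(name = ".guts_damage_at")]]
NumericVector guts_damage_at(NumericVector C, NumericVector Ct, double ke,
                             NumericVector t) {
  std::vector<double> tt(t.begin(), t.end());
  std::vector<double> D = damage_at_times(C, Ct, ke, tt);
  return NumericVector(D.begin(), D.end());
}

// Survival probabilities at the observation times `yt` for the proper model
// (lognormal threshold grid with importance weights, or a delta threshold).
//
// thresholds z and log-weights logw are passed in from R so that R and C++
// agree bit-for-bit on the grid; logw must be 0 for plain (unweighted)
// samples and for the delta distribution.
// [[Rcpp::export(name = ".guts_survival_proper")]]
NumericVector guts_survival_proper(NumericVector C, NumericVector Ct,
                                   NumericVector yt, double hb, double kk,
                                   double ke, NumericVector z,
                                   NumericVector logw, int M) {
  const int n1 = yt.size();           // number of observation times (incl. 0)
  const int N = z.size();
  const double tn = yt[n1 - 1];
  const double dtau = tn / M;

  NumericVector S(n1);
  if (tn <= 0.0) {  // degenerate: single time point 0
    for (int i = 0; i < n1; ++i) S[i] = 1.0;
    return S;
  }

  std::vector<double> tau(M);
  for (int l = 0; l < M; ++l) tau[l] = l * dtau;
  std::vector<double> D = damage_at_times(C, Ct, ke, tau);

  // per-bin damage sums e_j and counts f_j; bin j (0-based) collects grid
  // values with z_j < D_l <= z_{j+1} (z_{N+1} = infinity); values <= z_1
  // exceed no threshold and are dropped
  std::vector<double> e(N, 0.0);
  std::vector<int> f(N, 0);
  std::vector<double> a(N);

  double logS0 = 0.0;  // log of the unnormalised first element
  int l = 0;
  for (int i = 0; i < n1; ++i) {
    const int cut = cut_index(yt[i], dtau, M);
    for (; l < cut; ++l) {
      const double Dl = D[l];
      // number of thresholds strictly below Dl; ties go to the lower bin
      const int b = (int)(std::lower_bound(z.begin(), z.end(), Dl) - z.begin());
      if (b > 0) {
        f[b - 1] += 1;
        e[b - 1] += Dl;
      }
    }
    // suffix sums F_j, E_j and log-sum-exp over exponents
    double Fs = 0.0, Es = 0.0, amax = -INFINITY;
    for (int j = N - 1; j >= 0; --j) {
      Fs += f[j];
      Es += e[j];
      a[j] = -kk * dtau * (Es - Fs * z[j]) + logw[j];
      if (a[j] > amax) amax = a[j];
    }
    double s = 0.0;
    for (int j = 0; j < N; ++j) s += std::exp(a[j] - amax);
    const double logSi = amax + std::log(s);
    if (i == 0) logS0 = logSi;
    S[i] = std::exp(-hb * yt[i] + logSi - logS0);
  }
  return S;
}

// Survival probabilities for the individual-tolerance model: an individual
// dies as soon as damage first exceeds its threshold, so population survival
// is e^{-hb t} * (1 - F(max damage up to t)) with F the lognormal threshold
// CDF.  The running maximum uses the fine grid plus the exact damage at each
// observation time.
// [[Rcpp::export(name = ".guts_survival_it")]]
NumericVector guts_survival_it(NumericVector C, NumericVector Ct,
                               NumericVector yt, double hb, double ke,
                               double mulog, double sdlog, int M) {
  const int n1 = yt.size();
  const double tn = yt[n1 - 1];
  NumericVector S(n1);
  if (tn <= 0.0) {
    for (int i = 0; i < n1; ++i) S[i] = 1.0;
    return S;
  }
  const double dtau = tn / M;
  std::vector<double> tau(M);
  for (int l = 0; l < M; ++l) tau[l] = l * dtau;
  std::vector<double> D = damage_at_times(C, Ct, ke, tau);
  std::vector<double> tobs(yt.begin(), yt.end());
  std::vector<double> Dobs = damage_at_times(C, Ct, ke, tobs);

  double runmax = 0.0;
  int l = 0;
  for (int i = 0; i < n1; ++i) {
    const int cut = cut_index(yt[i], dtau, M);
    for (; l < cut; ++l)
      if (D[l] > runmax) runmax = D[l];
    const double mx = std::max(runmax, Dobs[i]);
    const double F = (mx > 0.0) ? R::plnorm(mx, mulog, sdlog, 1, 0) : 0.0;
    S[i] = std::exp(-hb * yt[i]) * (1.0 - F);
  }
  return S;
}
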