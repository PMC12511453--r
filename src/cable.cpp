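#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Hodgkin-Huxley style rate functions for nodal membrane, u = Vm - Vrest (mV).
// Singularities at u = 25 and u = 10 handled with the standard x/expm1 guard.
static inline double vtrap(double x, double y) {
  // x / (exp(x/y) - 1), stable near x = 0
  if (std::fabs(x / y) < 1e-6) return y * (1.0 - x / y / 2.0);
  return x / std::expm1(x / y);
}

static inline void hh_rates(double u, double *am, double *bm, double *ah,
                            double *bh, double *an, double *bn) {
  *am = 0.1 * vtrap(25.0 - u, 10.0);
  *bm = 4.0 * std::exp(-u / 18.0);
  *ah = 0.07 * std::exp(-u / 20.0);
  *bh = 1.0 / (std::exp((30.0 - u) / 10.0) + 1.0);
  *an = 0.01 * vtrap(10.0 - u, 10.0);
  *bn = 0.125 * std::exp(-u / 80.0);
}

// Backward-Euler cable update with Rush-Larsen gating; tridiagonal Thomas solve.
//
// Cable equation per node (all densities per cm^2 of nodal membrane):
//   cm dV/dt = -Iion(V) + ga * D2[V] + ga * D2[Ve]
// where D2 is the second difference along the fiber (sealed ends) and
// Ve_i(t) = ve_basis_i * drive(t) is the extracellular potential at node i.
//
// [[Rcpp::export(name = ".cable_integrate")]]
List cable_integrate(NumericVector ve_basis, NumericVector drive, double dt,
                     double cm, double g_na, double g_k, double g_leak,
                     double e_na, double e_k, double e_leak, double v_rest,
                     double phi, double g_axial, bool passive,
                     int store_every, bool store_vm, double spike_level = 0.0,
                     Nullable<IntegerVector> stop_nodes = R_NilValue,
                     double stop_grace_ms = 1.0) {
  const int n = ve_basis.size();
  const int nsteps = drive.size();

  std::vector<double> V(n, v_rest), m(n), h(n), ng(n);
  // gate steady states at rest (u = 0)
  {
    double am, bm, ah, bh, an, bn;
    hh_rates(0.0, &am, &bm, &ah, &bh, &an, &bn);
    for (int i = 0; i < n; ++i) {
      m[i] = am / (am + bm);
      h[i] = ah / (ah + bh);
      ng[i] = an / (an + bn);
    }
  }
  const double m0 = m[0], h0 = h[0], n0 = ng[0];

  // storage
  int nstore = store_vm ? (nsteps / store_every + 1) : 1;
  NumericMatrix vm_store(store_vm ? nstore : 1, store_vm ? n : 1);
  NumericVector t_store(store_vm ? nstore : 1);
  int istore = 0;
  if (store_vm) {
    for (int i = 0; i < n; ++i) vm_store(0, i) = v_rest;
    t_store[0] = 0.0;
    istore = 1;
  }

  std::vector<std::vector<double> > crossings(n);
  std::vector<double> vmax(n, v_rest);
  std::vector<double> vprev(n, v_rest);

  // Thomas solve workspaces
  std::vector<double> diag(n), rhs(n), cp(n), dp(n);
  const double cmdt = cm / dt;
  bool blowup = false;
  double blow_t = -1.0;

  // optional early termination once a spike reaches a designated node set
  std::vector<bool> is_stop(n, false);
  bool use_stop = false;
  if (stop_nodes.isNotNull()) {
    IntegerVector sn(stop_nodes);
    for (int k = 0; k < sn.size(); ++k)
      if (sn[k] >= 1 && sn[k] <= n) { is_stop[sn[k] - 1] = true; use_stop = true; }
  }
  double stop_at = -1.0;

  for (int s = 0; s < nsteps && !blowup; ++s) {
    const double t_new = (s + 1) * dt;
    const double I_new = drive[s];

    // gating update (Rush-Larsen, rates at current V), skipped in passive mode
    if (!passive) {
      for (int i = 0; i < n; ++i) {
        double am, bm, ah, bh, an, bn;
        hh_rates(V[i] - v_rest, &am, &bm, &ah, &bh, &an, &bn);
        double sm = am + bm, sh = ah + bh, sn = an + bn;
        double em = std::exp(-dt * phi * sm);
        double eh = std::exp(-dt * phi * sh);
        double en = std::exp(-dt * phi * sn);
        m[i] = am / sm + (m[i] - am / sm) * em;
        h[i] = ah / sh + (h[i] - ah / sh) * eh;
        ng[i] = an / sn + (ng[i] - an / sn) * en;
      }
    }

    // assemble tridiagonal system: (cmdt + Gion + c_i*ga) V_i - ga (V_{i-1}+V_{i+1})
    //   = cmdt V_i^old + Gion*Erev_eff + ga * D2[Ve](t_new)
    for (int i = 0; i < n; ++i) {
      double gna_i, gk_i;
      if (passive) {
        gna_i = g_na * m0 * m0 * m0 * h0;
        gk_i = g_k * n0 * n0 * n0 * n0;
      } else {
        gna_i = g_na * m[i] * m[i] * m[i] * h[i];
        gk_i = g_k * ng[i] * ng[i] * ng[i] * ng[i];
      }
      double gtot = gna_i + gk_i + g_leak;
      double isrc = gna_i * e_na + gk_i * e_k + g_leak * e_leak;
      double cnb = (i == 0 || i == n - 1) ? 1.0 : 2.0;
      double d2ve;
      if (i == 0)
        d2ve = ve_basis[1] - ve_basis[0];
      else if (i == n - 1)
        d2ve = ve_basis[n - 2] - ve_basis[n - 1];
      else
        d2ve = ve_basis[i - 1] - 2.0 * ve_basis[i] + ve_basis[i + 1];
      diag[i] = cmdt + gtot + cnb * g_axial;
      rhs[i] = cmdt * V[i] + isrc + g_axial * d2ve * I_new;
    }

    // Thomas algorithm, off-diagonals are -g_axial
    cp[0] = -g_axial / diag[0];
    dp[0] = rhs[0] / diag[0];
    for (int i = 1; i < n; ++i) {
      double denom = diag[i] + g_axial * cp[i - 1];
      cp[i] = -g_axial / denom;
      dp[i] = (rhs[i] + g_axial * dp[i - 1]) / denom;
    }
    V[n - 1] = dp[n - 1];
    for (int i = n - 2; i >= 0; --i) V[i] = dp[i] - cp[i] * V[i + 1];

    // spike crossings (upward through spike_level) and extrema
    for (int i = 0; i < n; ++i) {
      if (vprev[i] < spike_level && V[i] >= spike_level) {
        crossings[i].push_back(t_new);
        if (use_stop && is_stop[i] && stop_at < 0.0) stop_at = t_new + stop_grace_ms;
      }
      if (V[i] > vmax[i]) vmax[i] = V[i];
      if (std::fabs(V[i]) > 200.0) { blowup = true; blow_t = t_new; }
      vprev[i] = V[i];
    }

    if (store_vm && ((s + 1) % store_every == 0) && istore < nstore) {
      for (int i = 0; i < n; ++i) vm_store(istore, i) = V[i];
      t_store[istore] = t_new;
      ++istore;
    }

    if (stop_at > 0.0 && t_new >= stop_at) break;
  }

  List cross(n);
  for (int i = 0; i < n; ++i) cross[i] = NumericVector(crossings[i].begin(), crossings[i].end());

  if (store_vm && istore < nstore) {
    vm_store = vm_store(Range(0, istore - 1), _);
    t_store = t_store[Range(0, istore - 1)];
  }

  return List::create(_["t_ms"] = t_store, _["vm"] = vm_store,
                      _["crossings"] = cross,
                      _["vmax"] = NumericVector(vmax.begin(), vmax.end()),
                      _["blowup"] = blowup, _["blowup_t_ms"] = blow_t);
}
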