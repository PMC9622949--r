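#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Centred firing sigmoid: S(v) = 2 e0 / (1 + exp(r (v0 - v))) - s0,
// with s0 = 2 e0 / (1 + exp(r v0)) so that S(0) = 0.
static inline double sigm(double v, double e0, double r, double v0, double s0) {
  return 2.0 * e0 / (1.0 + std::exp(r * (v0 - v))) - s0;
}

// Jansen-Rit network right-hand side. State layout per source i:
// y0, y1, y2 (synaptic outputs, mV) and their derivatives. Pyramidal
// potential vP = y1 - y2. Forward+lateral afferents drive the excitatory
// (y1) equation; backward afferents enter the inhibitory sigmoid argument.
static void jr_rhs_c(int n, const double *s, double *ds, double u,
                     const double *He, const double *Hi,
                     const double *te, const double *ti,
                     const double *gam, double e0, double r, double v0,
                     double s0, double rs, const double *CfL, const double *Cb,
                     const double *uw, double *sp /* scratch, length n */) {
  // state layout: columns y0 (0..n-1), y1 (n..2n-1), y2 (2n..3n-1),
  // dy0 (3n..), dy1 (4n..), dy2 (5n..)
  for (int j = 0; j < n; ++j)
    sp[j] = sigm(s[n + j] - s[2 * n + j], e0, r, v0, s0);
  for (int i = 0; i < n; ++i) {
    double aff_f = 0.0, aff_b = 0.0;
    for (int j = 0; j < n; ++j) {
      aff_f += CfL[i + n * j] * sp[j];
      aff_b += Cb[i + n * j] * sp[j];
    }
    double y0 = s[i], y1 = s[n + i], y2 = s[2 * n + i];
    double d0 = s[3 * n + i], d1 = s[4 * n + i], d2 = s[5 * n + i];
    double ke = He[i] / te[i], ki = Hi[i] / ti[i];
    ds[i] = d0;
    ds[n + i] = d1;
    ds[2 * n + i] = d2;
    ds[3 * n + i] = ke * rs * sigm(y1 - y2, e0, r, v0, s0)
      - 2.0 / te[i] * d0 - y0 / (te[i] * te[i]);
    ds[4 * n + i] = ke * rs * (uw[i] * u + gam[1] * sigm(gam[0] * y0, e0, r, v0, s0) + aff_f)
      - 2.0 / te[i] * d1 - y1 / (te[i] * te[i]);
    ds[5 * n + i] = ki * rs * gam[3] * sigm(gam[2] * y0 + aff_b, e0, r, v0, s0)
      - 2.0 / ti[i] * d2 - y2 / (ti[i] * ti[i]);
  }
}

// Fixed-step RK4 over nt steps of size dt. u is sampled on the half grid
// (length 2*nt+1: t = 0, dt/2, dt, ...). Returns pyramidal potentials
// (n x nt+1) and, optionally, the full final-state trajectory.
// [[Rcpp::export]]
List jr_integrate_cpp(NumericMatrix state0, NumericVector He, NumericVector Hi,
                      NumericVector te, NumericVector ti, NumericVector gamma,
                      double e0, double r, double v0, double rate_scale,
                      NumericMatrix CfL, NumericMatrix Cb,
                      NumericVector u, NumericVector uw,
                      double dt, bool keep_states) {
  const int n = state0.nrow();
  const int nt = (u.size() - 1) / 2;
  if (state0.ncol() != 6) stop("state0 must be n x 6");
  std::vector<double> s(state0.begin(), state0.end());
  std::vector<double> k1(6 * n), k2(6 * n), k3(6 * n), k4(6 * n), tmp(6 * n), sp(n);
  NumericMatrix vp(n, nt + 1);
  NumericMatrix states;
  if (keep_states) states = NumericMatrix(6 * n, nt + 1);
  double s0 = 2.0 * e0 / (1.0 + std::exp(r * v0));

  auto record = [&](int step) {
    for (int i = 0; i < n; ++i) vp(i, step) = s[n + i] - s[2 * n + i];
    if (keep_states) for (int i = 0; i < 6 * n; ++i) states(i, step) = s[i];
  };
  record(0);
  for (int stp = 0; stp < nt; ++stp) {
    double u0 = u[2 * stp], uh = u[2 * stp + 1], u1 = u[2 * stp + 2];
    jr_rhs_c(n, s.data(), k1.data(), u0, He.begin(), Hi.begin(), te.begin(), ti.begin(),
             gamma.begin(), e0, r, v0, s0, rate_scale, CfL.begin(), Cb.begin(), uw.begin(), sp.data());
    for (int i = 0; i < 6 * n; ++i) tmp[i] = s[i] + 0.5 * dt * k1[i];
    jr_rhs_c(n, tmp.data(), k2.data(), uh, He.begin(), Hi.begin(), te.begin(), ti.begin(),
             gamma.begin(), e0, r, v0, s0, rate_scale, CfL.begin(), Cb.begin(), uw.begin(), sp.data());
    for (int i = 0; i < 6 * n; ++i) tmp[i] = s[i] + 0.5 * dt * k2[i];
    jr_rhs_c(n, tmp.data(), k3.data(), uh, He.begin(), Hi.begin(), te.begin(), ti.begin(),
             gamma.begin(), e0, r, v0, s0, rate_scale, CfL.begin(), Cb.begin(), uw.begin(), sp.data());
    for (int i = 0; i < 6 * n; ++i) tmp[i] = s[i] + dt * k3[i];
    jr_rhs_c(n, tmp.data(), k4.data(), u1, He.begin(), Hi.begin(), te.begin(), ti.begin(),
             gamma.begin(), e0, r, v0, s0, rate_scale, CfL.begin(), Cb.begin(), uw.begin(), sp.data());
    for (int i = 0; i < 6 * n; ++i)
      s[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
    for (int i = 0; i < 6 * n; ++i)
      if (!std::isfinite(s[i]))
        stop("integration diverged (non-finite state) at t = %f ms", (stp + 1) * dt);
    record(stp + 1);
  }
  if (keep_states) return List::create(_["vp"] = vp, _["states"] = states);
  return List::create(_["vp"] = vp);
}
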