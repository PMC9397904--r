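// 18-state kinetic model of the Neurospora circadian clock with light input.
// The derivative is hand-coded per species; an independent stoichiometry-matrix
// oracle lives on the R side and the two are cross-checked in the test suite.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// State layout (must match clockSpecies() in R/registry.R)
enum {
  iM_WCC = 0, iM_FRQ, iM_VVD, iM_CSP1, iM_FAM3,
  iWCC, iP_WCC, iWCCS, iWCC2S, iWCCVVDS, iVVD, iVVDS,
  iF1, iF2, iF3, iF4, iF5, iFFC,
  NSTATE
};

// Parameter layout (must match clockParameterNames() in R/registry.R)
enum {
  pBAS_WCC = 0, pVMAX_L_WCC, pK_L_WCC,
  pBAS_FRQ, pVMAX_D_FRQ, pK_D_FRQ, pVMAX_L_FRQ, pK_L_FRQ,
  pBAS_VVD, pVMAX_D_VVD, pK_D_VVD, pVMAX_L_VVD, pK_L_VVD,
  pBAS_CSP1, pVMAX_D_CSP1, pK_D_CSP1, pVMAX_L_CSP1, pK_L_CSP1, pK_REP_CSP1,
  pBAS_FAM3, pK_REP_FAM3,
  pKDM_WCC, pKDM_FRQ, pKDM_VVD, pKDM_CSP1, pKDM_FAM3,
  pKTL_WCC, pKTL_FRQ, pKTL_VVD,
  pKMAT_1, pKMAT_2, pKMAT_3, pKMAT_4, pKMAT_5,
  pKDF_1, pKDF_2, pKDF_3, pKDF_4, pKDF_5,
  pKDEG_FFC,
  pKCAT_WCC, pKMP_WCC, pKCAT_WCCS, pKMP_WCCS,
  pKCAT_WCC2S, pKMP_WCC2S, pKCAT_WCCVVDS, pKMP_WCCVVDS,
  pKD2,
  pKLIGHT_WCC, pKLIGHT_VVD,
  pKREV_WCCS, pKREV_VVDS, pKREV_WCC2S, pKREV_WCCVVDS,
  pKON_WW, pKOFF_WW, pKON_WV, pKOFF_WV,
  pKDEG_WCC, pKDEG_PWCC, pKDEG_WCCS, pKDEG_WCC2S, pKDEG_WCCVVDS,
  pKDEG_VVD, pKDEG_VVDS,
  NPAR
};

static inline void clock_deriv(const double* x, const double* p, double u,
                               double* dx) {
  // transcription-activator occupancies: dark-equivalent activity pools the
  // dark WCC with the light monomer and the WCC*VVD* heterodimer; the potent
  // light activator is the WCC* homodimer alone
  const double Ad = x[iWCC] + x[iWCCS] + x[iWCCVVDS];
  const double Al = x[iWCC2S];

  const double tx_wcc = p[pBAS_WCC] + p[pVMAX_L_WCC] * Al / (p[pK_L_WCC] + Al);
  const double tx_frq = p[pBAS_FRQ] +
    p[pVMAX_D_FRQ] * Ad / (p[pK_D_FRQ] + Ad) +
    p[pVMAX_L_FRQ] * Al / (p[pK_L_FRQ] + Al);
  const double tx_vvd = p[pBAS_VVD] +
    p[pVMAX_D_VVD] * Ad / (p[pK_D_VVD] + Ad) +
    p[pVMAX_L_VVD] * Al / (p[pK_L_VVD] + Al);
  const double tx_csp1 = (p[pBAS_CSP1] +
    p[pVMAX_D_CSP1] * Ad / (p[pK_D_CSP1] + Ad) +
    p[pVMAX_L_CSP1] * Al / (p[pK_L_CSP1] + Al)) /
    (1.0 + x[iM_CSP1] / p[pK_REP_CSP1]);
  const double tx_fam3 = p[pBAS_FAM3] / (1.0 + x[iM_CSP1] / p[pK_REP_FAM3]);

  // FFC-catalysed phosphorylation of every WCC species into the common P-WCC
  // pool (Michaelis-Menten in the substrate, first order in the FFC enzyme)
  const double ph_wcc =
    p[pKCAT_WCC] * x[iFFC] * x[iWCC] / (p[pKMP_WCC] + x[iWCC]);
  const double ph_wccs =
    p[pKCAT_WCCS] * x[iFFC] * x[iWCCS] / (p[pKMP_WCCS] + x[iWCCS]);
  const double ph_wcc2s =
    p[pKCAT_WCC2S] * x[iFFC] * x[iWCC2S] / (p[pKMP_WCC2S] + x[iWCC2S]);
  const double ph_wccvvds =
    p[pKCAT_WCCVVDS] * x[iFFC] * x[iWCCVVDS] / (p[pKMP_WCCVVDS] + x[iWCCVVDS]);

  const double lact_wcc = p[pKLIGHT_WCC] * u * x[iWCC];
  const double lact_vvd = p[pKLIGHT_VVD] * u * x[iVVD];
  const double dim_ww_on = p[pKON_WW] * x[iWCCS] * x[iWCCS];
  const double dim_ww_off = p[pKOFF_WW] * x[iWCC2S];
  const double dim_wv_on = p[pKON_WV] * x[iWCCS] * x[iVVDS];
  const double dim_wv_off = p[pKOFF_WV] * x[iWCCVVDS];
  const double rev_wccs = p[pKREV_WCCS] * x[iWCCS];
  const double rev_vvds = p[pKREV_VVDS] * x[iVVDS];
  const double rev_wcc2s = p[pKREV_WCC2S] * x[iWCC2S];
  const double rev_wccvvds = p[pKREV_WCCVVDS] * x[iWCCVVDS];
  const double dephos = p[pKD2] * x[iP_WCC];

  dx[iM_WCC]  = tx_wcc  - p[pKDM_WCC]  * x[iM_WCC];
  dx[iM_FRQ]  = tx_frq  - p[pKDM_FRQ]  * x[iM_FRQ];
  dx[iM_VVD]  = tx_vvd  - p[pKDM_VVD]  * x[iM_VVD];
  dx[iM_CSP1] = tx_csp1 - p[pKDM_CSP1] * x[iM_CSP1];
  dx[iM_FAM3] = tx_fam3 - p[pKDM_FAM3] * x[iM_FAM3];

  dx[iWCC] = p[pKTL_WCC] * x[iM_WCC] - ph_wcc + dephos
    - lact_wcc + rev_wccs + rev_wcc2s
    - p[pKDEG_WCC] * x[iWCC];
  dx[iP_WCC] = ph_wcc + ph_wccs + 2.0 * ph_wcc2s + ph_wccvvds
    - dephos - p[pKDEG_PWCC] * x[iP_WCC];
  dx[iWCCS] = lact_wcc - rev_wccs - ph_wccs
    - 2.0 * dim_ww_on + 2.0 * dim_ww_off + rev_wcc2s
    - dim_wv_on + dim_wv_off + rev_wccvvds
    - p[pKDEG_WCCS] * x[iWCCS];
  dx[iWCC2S] = dim_ww_on - dim_ww_off - rev_wcc2s - ph_wcc2s
    - p[pKDEG_WCC2S] * x[iWCC2S];
  dx[iWCCVVDS] = dim_wv_on - dim_wv_off - rev_wccvvds - ph_wccvvds
    - p[pKDEG_WCCVVDS] * x[iWCCVVDS];
  dx[iVVD] = p[pKTL_VVD] * x[iM_VVD] - lact_vvd + rev_vvds + rev_wccvvds
    - p[pKDEG_VVD] * x[iVVD];
  dx[iVVDS] = lact_vvd - rev_vvds - dim_wv_on + dim_wv_off + ph_wccvvds
    - p[pKDEG_VVDS] * x[iVVDS];

  dx[iF1] = p[pKTL_FRQ] * x[iM_FRQ] - p[pKMAT_1] * x[iF1] - p[pKDF_1] * x[iF1];
  dx[iF2] = p[pKMAT_1] * x[iF1] - p[pKMAT_2] * x[iF2] - p[pKDF_2] * x[iF2];
  dx[iF3] = p[pKMAT_2] * x[iF2] - p[pKMAT_3] * x[iF3] - p[pKDF_3] * x[iF3];
  dx[iF4] = p[pKMAT_3] * x[iF3] - p[pKMAT_4] * x[iF4] - p[pKDF_4] * x[iF4];
  dx[iF5] = p[pKMAT_4] * x[iF4] - p[pKMAT_5] * x[iF5] - p[pKDF_5] * x[iF5];
  dx[iFFC] = p[pKMAT_5] * x[iF5] - p[pKDEG_FFC] * x[iFFC];
}

// [[Rcpp::export(name = ".clockDerivCpp")]]
NumericVector clock_deriv_cpp(NumericVector x, NumericVector p, double u) {
  if (x.size() != NSTATE) stop("state must have length %d", NSTATE);
  if (p.size() != NPAR) stop("parameter vector must have length %d", NPAR);
  NumericVector dx(NSTATE);
  clock_deriv(x.begin(), p.begin(), u, dx.begin());
  return dx;
}

// ---- Dormand-Prince 5(4) adaptive integrator --------------------------------

struct DPWork {
  double k1[NSTATE], k2[NSTATE], k3[NSTATE], k4[NSTATE],
         k5[NSTATE], k6[NSTATE], k7[NSTATE], xt[NSTATE];
};

// one attempted step from (t, x) with size h under constant light u;
// writes the 5th-order solution into xout and returns the scaled error norm
static double dp_step(const double* x, const double* p, double u, double h,
                      double* xout, double rtol, double atol, DPWork& w) {
  static const double
    a21 = 1.0 / 5.0,
    a31 = 3.0 / 40.0, a32 = 9.0 / 40.0,
    a41 = 44.0 / 45.0, a42 = -56.0 / 15.0, a43 = 32.0 / 9.0,
    a51 = 19372.0 / 6561.0, a52 = -25360.0 / 2187.0,
    a53 = 64448.0 / 6561.0, a54 = -212.0 / 729.0,
    a61 = 9017.0 / 3168.0, a62 = -355.0 / 33.0, a63 = 46732.0 / 5247.0,
    a64 = 49.0 / 176.0, a65 = -5103.0 / 18656.0,
    b1 = 35.0 / 384.0, b3 = 500.0 / 1113.0, b4 = 125.0 / 192.0,
    b5 = -2187.0 / 6784.0, b6 = 11.0 / 84.0,
    e1 = 71.0 / 57600.0, e3 = -71.0 / 16695.0, e4 = 71.0 / 1920.0,
    e5 = -17253.0 / 339200.0, e6 = 22.0 / 525.0, e7 = -1.0 / 40.0;

  clock_deriv(x, p, u, w.k1);
  for (int i = 0; i < NSTATE; ++i) w.xt[i] = x[i] + h * a21 * w.k1[i];
  clock_deriv(w.xt, p, u, w.k2);
  for (int i = 0; i < NSTATE; ++i)
    w.xt[i] = x[i] + h * (a31 * w.k1[i] + a32 * w.k2[i]);
  clock_deriv(w.xt, p, u, w.k3);
  for (int i = 0; i < NSTATE; ++i)
    w.xt[i] = x[i] + h * (a41 * w.k1[i] + a42 * w.k2[i] + a43 * w.k3[i]);
  clock_deriv(w.xt, p, u, w.k4);
  for (int i = 0; i < NSTATE; ++i)
    w.xt[i] = x[i] + h * (a51 * w.k1[i] + a52 * w.k2[i] + a53 * w.k3[i] +
                          a54 * w.k4[i]);
  clock_deriv(w.xt, p, u, w.k5);
  for (int i = 0; i < NSTATE; ++i)
    w.xt[i] = x[i] + h * (a61 * w.k1[i] + a62 * w.k2[i] + a63 * w.k3[i] +
                          a64 * w.k4[i] + a65 * w.k5[i]);
  clock_deriv(w.xt, p, u, w.k6);
  for (int i = 0; i < NSTATE; ++i)
    xout[i] = x[i] + h * (b1 * w.k1[i] + b3 * w.k3[i] + b4 * w.k4[i] +
                          b5 * w.k5[i] + b6 * w.k6[i]);
  clock_deriv(xout, p, u, w.k7);

  double err = 0.0;
  for (int i = 0; i < NSTATE; ++i) {
    double e = h * (e1 * w.k1[i] + e3 * w.k3[i] + e4 * w.k4[i] +
                    e5 * w.k5[i] + e6 * w.k6[i] + e7 * w.k7[i]);
    double sc = atol + rtol * std::max(std::fabs(x[i]), std::fabs(xout[i]));
    double r = e / sc;
    err += r * r;
  }
  return std::sqrt(err / NSTATE);
}

// Integrate over piecewise-constant light segments, recording the state at
// each requested output time. The integrator restarts at every segment
// boundary so light discontinuities are handled exactly.
// [[Rcpp::export(name = ".clockIntegrateCpp")]]
NumericMatrix clock_integrate_cpp(NumericVector x0, NumericVector p,
                                  NumericVector seg_start,
                                  NumericVector seg_end,
                                  NumericVector seg_u,
                                  NumericVector times,
                                  double rtol, double atol,
                                  double max_steps) {
  if (x0.size() != NSTATE) stop("state must have length %d", NSTATE);
  if (p.size() != NPAR) stop("parameter vector must have length %d", NPAR);
  const int nseg = seg_start.size(), nout = times.size();
  NumericMatrix out(nout, NSTATE);
  double x[NSTATE], xnew[NSTATE];
  for (int i = 0; i < NSTATE; ++i) x[i] = x0[i];
  DPWork w;

  int iout = 0;
  double steps = 0.0;
  // output times exactly at t = 0 (or segment starts) are recorded in passing
  for (int s = 0; s < nseg; ++s) {
    double t = seg_start[s];
    const double tend = seg_end[s];
    const double u = seg_u[s];
    while (iout < nout && times[iout] <= t + 1e-12) {
      for (int i = 0; i < NSTATE; ++i) out(iout, i) = x[i];
      ++iout;
    }
    double h = std::min(0.1, tend - t);
    while (t < tend - 1e-12) {
      double tlim = tend;
      if (iout < nout && times[iout] < tlim) tlim = times[iout];
      if (t + h > tlim) h = tlim - t;
      double err = dp_step(x, p.begin(), u, h, xnew, rtol, atol, w);
      bool finite = true;
      for (int i = 0; i < NSTATE; ++i)
        if (!std::isfinite(xnew[i])) { finite = false; break; }
      if (finite && err <= 1.0) {
        t += h;
        for (int i = 0; i < NSTATE; ++i) x[i] = xnew[i];
        while (iout < nout && times[iout] <= t + 1e-12) {
          for (int i = 0; i < NSTATE; ++i) out(iout, i) = x[i];
          ++iout;
        }
      } else if (!finite) {
        err = 10.0; // force a strong step reduction
      }
      double fac = finite ? 0.9 * std::pow(std::max(err, 1e-10), -0.2) : 0.1;
      if (fac < 0.2) fac = 0.2;
      if (fac > 5.0) fac = 5.0;
      h *= fac;
      if (h < 1e-12) {
        stop("integration step size underflow at t = %g (light = %g)", t, u);
      }
      if (++steps > max_steps) {
        stop("integration exceeded %g steps at t = %g", max_steps, t);
      }
    }
  }
  while (iout < nout) { // trailing outputs at the final horizon
    for (int i = 0; i < NSTATE; ++i) out(iout, i) = x[i];
    ++iout;
  }
  return out;
}

// classical fixed-step RK4 under constant light; independent accuracy oracle
// [[Rcpp::export(name = ".clockRk4Cpp")]]
NumericVector clock_rk4_cpp(NumericVector x0, NumericVector p, double u,
                            double t0, double t1, double dt) {
  if (x0.size() != NSTATE) stop("state must have length %d", NSTATE);
  double x[NSTATE], k1[NSTATE], k2[NSTATE], k3[NSTATE], k4[NSTATE],
         xt[NSTATE];
  for (int i = 0; i < NSTATE; ++i) x[i] = x0[i];
  double t = t0;
  const long n = (long)std::ceil((t1 - t0) / dt - 1e-9);
  for (long s = 0; s < n; ++s) {
    double h = std::min(dt, t1 - t);
    clock_deriv(x, p.begin(), u, k1);
    for (int i = 0; i < NSTATE; ++i) xt[i] = x[i] + 0.5 * h * k1[i];
    clock_deriv(xt, p.begin(), u, k2);
    for (int i = 0; i < NSTATE; ++i) xt[i] = x[i] + 0.5 * h * k2[i];
    clock_deriv(xt, p.begin(), u, k3);
    for (int i = 0; i < NSTATE; ++i) xt[i] = x[i] + h * k3[i];
    clock_deriv(xt, p.begin(), u, k4);
    for (int i = 0; i < NSTATE; ++i)
      x[i] += h / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
    t += h;
  }
  NumericVector out(NSTATE);
  for (int i = 0; i < NSTATE; ++i) out[i] = x[i];
  return out;
}
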