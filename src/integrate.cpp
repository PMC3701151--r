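#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Packed circuit parameter layout (kept in step with pack_params() on the R
// side; any change here must be mirrored there).
enum {
  P_TMAX_RET = 0, P_TH_RET, P_SG_RET,
  P_TMAX_TCR,     P_TH_TCR, P_SG_TCR,
  P_TMAX_TRN,     P_TH_TRN, P_SG_TRN,
  P_A_AR, P_B_AR, P_G_AR, P_VR_AR,   // AMPA retina -> TCR
  P_A_AT, P_B_AT, P_G_AT, P_VR_AT,   // AMPA TCR -> TRN
  P_A_GT, P_B_GT, P_G_GT, P_VR_GT,   // GABA_A TRN -> TCR
  P_A_GN, P_B_GN, P_G_GN, P_VR_GN,   // GABA_A TRN -> TRN
  P_A1, P_B1, P_A2, P_B2, P_KD, P_NH, P_G_B, P_VR_B, // GABA_B TRN -> TCR
  P_KAP_T, P_GL_T, P_VL_T,
  P_KAP_N, P_GL_N, P_VL_N,
  P_CTRE, P_CTNIA, P_CTNIB, P_CNTE, P_CNSI,
  P_LEN
};

// State layout: V_tcr, V_trn, r_ampa_ret, r_gabaa_n2t, R_gabab, X_gabab,
//               r_ampa_t2n, r_gabaa_n2n
#define NSTATE 8

static inline double sigT(double V, double Tmax, double th, double sg) {
  return Tmax / (1.0 + std::exp(-(V - th) / sg));
}

static void rhs(const double *y, double Vret, const double *p, double *dy) {
  const double Tret = sigT(Vret, p[P_TMAX_RET], p[P_TH_RET], p[P_SG_RET]);
  const double Ttcr = sigT(y[0], p[P_TMAX_TCR], p[P_TH_TCR], p[P_SG_TCR]);
  const double Ttrn = sigT(y[1], p[P_TMAX_TRN], p[P_TH_TRN], p[P_SG_TRN]);

  // two-state ligand-gated channels
  dy[2] = p[P_A_AR] * Tret * (1.0 - y[2]) - p[P_B_AR] * y[2];
  dy[3] = p[P_A_GT] * Ttrn * (1.0 - y[3]) - p[P_B_GT] * y[3];
  dy[6] = p[P_A_AT] * Ttcr * (1.0 - y[6]) - p[P_B_AT] * y[6];
  dy[7] = p[P_A_GN] * Ttrn * (1.0 - y[7]) - p[P_B_GN] * y[7];

  // GABA_B G-protein cascade; channel opening is algebraic in X
  dy[4] = p[P_A1] * Ttrn * (1.0 - y[4]) - p[P_B1] * y[4];
  dy[5] = p[P_A2] * y[4] - p[P_B2] * y[5];
  const double Xn = std::pow(std::max(y[5], 0.0), p[P_NH]);
  const double rB = Xn / (Xn + p[P_KD]);

  const double I_tcr =
      p[P_CTRE]  * p[P_G_AR] * y[2] * (y[0] - p[P_VR_AR]) +
      p[P_CTNIA] * p[P_G_GT] * y[3] * (y[0] - p[P_VR_GT]) +
      p[P_CTNIB] * p[P_G_B]  * rB   * (y[0] - p[P_VR_B]);
  dy[0] = (-I_tcr - p[P_GL_T] * (y[0] - p[P_VL_T])) / p[P_KAP_T];

  const double I_trn =
      p[P_CNTE] * p[P_G_AT] * y[6] * (y[1] - p[P_VR_AT]) +
      p[P_CNSI] * p[P_G_GN] * y[7] * (y[1] - p[P_VR_GN]);
  dy[1] = (-I_trn - p[P_GL_N] * (y[1] - p[P_VL_N])) / p[P_KAP_N];
}

// [[Rcpp::export]]
NumericVector cpp_circuit_rhs(NumericVector state, double V_ret,
                              NumericVector pack) {
  if (state.size() != NSTATE) stop("state must have length 8");
  if (pack.size() != P_LEN) stop("parameter pack has wrong length");
  NumericVector out(NSTATE);
  rhs(REAL(state), V_ret, REAL(pack), REAL(out));
  return out;
}

// Fehlberg 4(5) embedded pair. One adaptive step attempt; returns the error
// ratio (<= 1 means accept) and writes the 5th-order solution into ynew.
static double rkf45_step(const double *y, double Vret, const double *p,
                         double h, double rel_tol, double abs_tol,
                         double *ynew) {
  double k1[NSTATE], k2[NSTATE], k3[NSTATE], k4[NSTATE], k5[NSTATE],
      k6[NSTATE], tmp[NSTATE];
  rhs(y, Vret, p, k1);
  for (int i = 0; i < NSTATE; ++i) tmp[i] = y[i] + h * k1[i] / 4.0;
  rhs(tmp, Vret, p, k2);
  for (int i = 0; i < NSTATE; ++i)
    tmp[i] = y[i] + h * (3.0 * k1[i] + 9.0 * k2[i]) / 32.0;
  rhs(tmp, Vret, p, k3);
  for (int i = 0; i < NSTATE; ++i)
    tmp[i] = y[i] + h * (1932.0 * k1[i] - 7200.0 * k2[i] + 7296.0 * k3[i]) /
                        2197.0;
  rhs(tmp, Vret, p, k4);
  for (int i = 0; i < NSTATE; ++i)
    tmp[i] = y[i] + h * (439.0 / 216.0 * k1[i] - 8.0 * k2[i] +
                         3680.0 / 513.0 * k3[i] - 845.0 / 4104.0 * k4[i]);
  rhs(tmp, Vret, p, k5);
  for (int i = 0; i < NSTATE; ++i)
    tmp[i] = y[i] + h * (-8.0 / 27.0 * k1[i] + 2.0 * k2[i] -
                         3544.0 / 2565.0 * k3[i] + 1859.0 / 4104.0 * k4[i] -
                         11.0 / 40.0 * k5[i]);
  rhs(tmp, Vret, p, k6);

  double maxratio = 0.0;
  for (int i = 0; i < NSTATE; ++i) {
    const double y4 = y[i] + h * (25.0 / 216.0 * k1[i] +
                                  1408.0 / 2565.0 * k3[i] +
                                  2197.0 / 4104.0 * k4[i] - 0.2 * k5[i]);
    const double y5 = y[i] + h * (16.0 / 135.0 * k1[i] +
                                  6656.0 / 12825.0 * k3[i] +
                                  28561.0 / 56430.0 * k4[i] -
                                  9.0 / 50.0 * k5[i] + 2.0 / 55.0 * k6[i]);
    ynew[i] = y5;
    const double sc =
        abs_tol + rel_tol * std::max(std::fabs(y[i]), std::fabs(y5));
    const double ratio = std::fabs(y5 - y4) / sc;
    if (ratio > maxratio) maxratio = ratio;
  }
  return maxratio;
}

// Integrate one segment [0, len] with the drive held constant, adaptively.
static void advance_segment(double *y, double Vret, const double *p,
                            double len, double rel_tol, double abs_tol,
                            double *h_io, double t_abs) {
  double t = 0.0;
  double h = *h_io;
  const double hmin = 1e-10;
  double ynew[NSTATE];
  while (t < len) {
    if (h > len - t) h = len - t;
    if (h < hmin) h = hmin;
    const double ratio = rkf45_step(y, Vret, p, h, rel_tol, abs_tol, ynew);
    if (ratio <= 1.0 || h <= hmin * 1.0000001) {
      t += h;
      for (int i = 0; i < NSTATE; ++i) y[i] = ynew[i];
      if (!R_FINITE(y[0]) || !R_FINITE(y[1]))
        stop("non-finite state near t = %.3f ms", t_abs + t);
      double fac = (ratio > 0.0) ? 0.9 * std::pow(ratio, -0.2) : 5.0;
      if (fac > 5.0) fac = 5.0;
      h *= fac;
    } else {
      double fac = 0.9 * std::pow(ratio, -0.2);
      if (fac < 0.2) fac = 0.2;
      h *= fac;
      if (h < hmin)
        stop("step size underflow in interval starting at t = %.3f ms",
             t_abs);
    }
  }
  *h_io = (h > 0.0) ? h : 0.25;
}

// [[Rcpp::export]]
NumericMatrix cpp_integrate_rkf45(NumericVector y0, NumericVector drive,
                                  double dt_hold, double report_dt,
                                  double duration, NumericVector pack,
                                  double rel_tol, double abs_tol) {
  if (y0.size() != NSTATE) stop("y0 must have length 8");
  if (pack.size() != P_LEN) stop("parameter pack has wrong length");
  const int nrep = (int)std::lround(duration / report_dt);
  const int nhold = drive.size();
  if ((nhold - 1) * dt_hold >= duration + 1e-9 || nhold * dt_hold < duration - 1e-9)
    if (nhold * dt_hold < duration - 1e-9)
      stop("drive does not cover the requested duration");
  NumericMatrix out(nrep + 1, NSTATE);
  double y[NSTATE];
  for (int i = 0; i < NSTATE; ++i) { y[i] = y0[i]; out(0, i) = y0[i]; }
  const double *p = REAL(pack);
  const double *dr = REAL(drive);
  double h = std::min(0.25, dt_hold);
  double t = 0.0;
  for (int r = 1; r <= nrep; ++r) {
    const double t_end = r * report_dt;
    while (t < t_end - 1e-9) {
      int ih = (int)std::floor(t / dt_hold + 1e-9);
      if (ih >= nhold) ih = nhold - 1;
      const double hold_end = std::min((ih + 1) * dt_hold, t_end);
      const double len = hold_end - t;
      advance_segment(y, dr[ih], p, len, rel_tol, abs_tol, &h, t);
      t = hold_end;
    }
    for (int i = 0; i < NSTATE; ++i) out(r, i) = y[i];
  }
  return out;
}

// Fixed-step classic RK4 oracle; dt_step must subdivide the hold interval.
// [[Rcpp::export]]
NumericMatrix cpp_integrate_rk4(NumericVector y0, NumericVector drive,
                                double dt_hold, double report_dt,
                                double duration, NumericVector pack,
                                double dt_step) {
  if (y0.size() != NSTATE) stop("y0 must have length 8");
  if (pack.size() != P_LEN) stop("parameter pack has wrong length");
  const int nrep = (int)std::lround(duration / report_dt);
  const int nsub_hold = (int)std::lround(dt_hold / dt_step);
  if (std::fabs(nsub_hold * dt_step - dt_hold) > 1e-9)
    stop("dt_step must divide dt_hold");
  const int nhold = drive.size();
  if (nhold * dt_hold < duration - 1e-9)
    stop("drive does not cover the requested duration");
  NumericMatrix out(nrep + 1, NSTATE);
  double y[NSTATE], k1[NSTATE], k2[NSTATE], k3[NSTATE], k4[NSTATE],
      tmp[NSTATE];
  for (int i = 0; i < NSTATE; ++i) { y[i] = y0[i]; out(0, i) = y0[i]; }
  const double *p = REAL(pack);
  const double *dr = REAL(drive);
  const long nsteps_total = std::lround(duration / dt_step);
  const long steps_per_rep = std::lround(report_dt / dt_step);
  int r = 1;
  for (long s = 0; s < nsteps_total; ++s) {
    const double t = s * dt_step;
    int ih = (int)std::floor(t / dt_hold + 1e-9);
    if (ih >= nhold) ih = nhold - 1;
    const double V = dr[ih];
    rhs(y, V, p, k1);
    for (int i = 0; i < NSTATE; ++i) tmp[i] = y[i] + 0.5 * dt_step * k1[i];
    rhs(tmp, V, p, k2);
    for (int i = 0; i < NSTATE; ++i) tmp[i] = y[i] + 0.5 * dt_step * k2[i];
    rhs(tmp, V, p, k3);
    for (int i = 0; i < NSTATE; ++i) tmp[i] = y[i] + dt_step * k3[i];
    rhs(tmp, V, p, k4);
    for (int i = 0; i < NSTATE; ++i)
      y[i] += dt_step / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
    if ((s + 1) % steps_per_rep == 0) {
      if (!R_FINITE(y[0]) || !R_FINITE(y[1]))
        stop("non-finite state near t = %.3f ms", (s + 1) * dt_step);
      for (int i = 0; i < NSTATE; ++i) out(r, i) = y[i];
      ++r;
    }
  }
  return out;
}
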