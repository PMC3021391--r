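#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Bilinear neural + balloon haemodynamic forward model, integrated with a
// fixed-step classical Runge-Kutta (RK4) scheme on the microtime grid.
//
// Per-region state: z (neural), s (vasodilatory signal), and log f (flow),
// log v (venous volume), log q (deoxyhaemoglobin).  Flow, volume and dHb are
// integrated in log space so they remain positive by construction.
//
// Neural dynamics:  dz/dt = (A + u2 * B) z + C u
// Haemodynamics (per region):
//   ds/dt = z - kappa * s - gamma * (f - 1)
//   df/dt = s
//   tau dv/dt = f - v^(1/alpha)
//   tau dq/dt = f * (1 - (1 - E0)^(1/f)) / E0 - v^(1/alpha) * q / v
// BOLD observation (percent signal change):
//   y = 100 * V0 * (k1 (1 - q) + k2 (1 - q/v) + k3 (1 - v)),
//   k1 = 7 E0, k2 = 2, k3 = 2 E0 - 0.2.

static const int NR = 4;       // regions
static const int NS = 5 * NR;  // states

struct HemoPar {
  double kappa, gamma, tau, alpha, E0, V0;
};

static inline void deriv(const double *x, const double *u,
                         const NumericMatrix &A, const NumericMatrix &B,
                         const NumericMatrix &C, const HemoPar &h,
                         double *dx) {
  const double u1 = u[0], u2 = u[1];
  // neural
  for (int i = 0; i < NR; ++i) {
    double acc = C(i, 0) * u1 + C(i, 1) * u2;
    for (int j = 0; j < NR; ++j)
      acc += (A(i, j) + u2 * B(i, j)) * x[j];
    dx[i] = acc;
  }
  // haemodynamic
  const double ia = 1.0 / h.alpha;
  for (int i = 0; i < NR; ++i) {
    const double z = x[i];
    const double s = x[NR + i];
    const double f = std::exp(x[2 * NR + i]);
    const double v = std::exp(x[3 * NR + i]);
    const double q = std::exp(x[4 * NR + i]);
    const double fv = std::pow(v, ia);
    dx[NR + i] = z - h.kappa * s - h.gamma * (f - 1.0);
    dx[2 * NR + i] = s / f;
    dx[3 * NR + i] = (f - fv) / (h.tau * v);
    const double ef = 1.0 - std::pow(1.0 - h.E0, 1.0 / f);
    dx[4 * NR + i] = (f * ef / h.E0 - fv * q / v) / (h.tau * q);
  }
}

// [[Rcpp::export(name = ".dcm_integrate")]]
List dcm_integrate(NumericMatrix A, NumericMatrix B, NumericMatrix C,
                   NumericMatrix U, double dt, int sampleEvery, int nVol,
                   NumericVector hemo) {
  if (A.nrow() != NR || A.ncol() != NR || B.nrow() != NR || B.ncol() != NR)
    stop("A and B must be 4 x 4");
  if (C.nrow() != NR || C.ncol() != 2) stop("C must be 4 x 2");
  if (U.ncol() != 2) stop("U must have 2 columns");
  const int nSteps = U.nrow();
  if (nSteps < nVol * sampleEvery) stop("input grid shorter than sampled span");
  HemoPar h;
  h.kappa = hemo[0]; h.gamma = hemo[1]; h.tau = hemo[2];
  h.alpha = hemo[3]; h.E0 = hemo[4]; h.V0 = hemo[5];

  double x[NS], k1[NS], k2[NS], k3[NS], k4[NS], xt[NS];
  for (int i = 0; i < NS; ++i) x[i] = 0.0;  // log f = log v = log q = 0

  NumericMatrix y(nVol, NR);
  const double kk1 = 7.0 * h.E0, kk2 = 2.0, kk3 = 2.0 * h.E0 - 0.2;
  bool ok = true;
  int vol = 0;
  double uu[2];

  for (int step = 0; step < nSteps && vol < nVol; ++step) {
    uu[0] = U(step, 0); uu[1] = U(step, 1);
    deriv(x, uu, A, B, C, h, k1);
    for (int i = 0; i < NS; ++i) xt[i] = x[i] + 0.5 * dt * k1[i];
    deriv(xt, uu, A, B, C, h, k2);
    for (int i = 0; i < NS; ++i) xt[i] = x[i] + 0.5 * dt * k2[i];
    deriv(xt, uu, A, B, C, h, k3);
    for (int i = 0; i < NS; ++i) xt[i] = x[i] + dt * k3[i];
    deriv(xt, uu, A, B, C, h, k4);
    for (int i = 0; i < NS; ++i)
      x[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);

    for (int i = 0; i < NS; ++i) {
      if (!std::isfinite(x[i]) || std::fabs(x[i]) > 1e4) { ok = false; break; }
    }
    if (!ok) break;

    if ((step + 1) % sampleEvery == 0) {
      for (int i = 0; i < NR; ++i) {
        const double v = std::exp(x[3 * NR + i]);
        const double q = std::exp(x[4 * NR + i]);
        y(vol, i) = 100.0 * h.V0 *
          (kk1 * (1.0 - q) + kk2 * (1.0 - q / v) + kk3 * (1.0 - v));
      }
      ++vol;
    }
  }
  return List::create(_["y"] = y, _["ok"] = ok, _["nVol"] = vol);
}
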