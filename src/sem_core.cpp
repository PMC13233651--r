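// Compiled core of the spatial Epileptor field integrator.
//
// Deterministic Heun stepping with (i) delayed global difference coupling
// on x1 read from a ring-buffer history and (ii) Heaviside-gated local
// coupling over a sparse geodesic kernel (CSC arrays). Coupling inputs are
// evaluated once per step from the state at the start of the step, the
// convention of reference delayed neural-field integrators, so the
// predictor and corrector stages see identical inputs.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct Pars {
  double Iext, Iext2, m, k, g11, g12, g22, gglob,
      th11, th12, th22, tau0, tau1, tau2, tt, a, b, c, d, aa, bb;
};

inline void derivs(const Pars& p, const std::vector<double>& x0, int n,
                   const double* x1, const double* y1, const double* z,
                   const double* x2, const double* y2, const double* g,
                   const double* glob, const double* lc11,
                   const double* lc12, const double* lc22,
                   double* dx1, double* dy1, double* dz,
                   double* dx2, double* dy2, double* dg) {
  for (int i = 0; i < n; ++i) {
    double f1 = (x1[i] < 0.0)
        ? (p.a * x1[i] - p.b) * x1[i] * x1[i]
        : (x2[i] - 0.6 * (z[i] - 4.0) * (z[i] - 4.0) - p.m) * x1[i];
    double f2 = (x2[i] < -0.25) ? 0.0 : p.aa * (x2[i] + 0.25);
    dx1[i] = p.tt * (y1[i] - f1 - z[i] + p.Iext + glob[i] + lc11[i]);
    dy1[i] = p.tt * ((p.c - p.d * x1[i] * x1[i] - y1[i]) / p.tau1);
    dz[i]  = p.tt * ((4.0 * (x1[i] - x0[i]) - z[i]) / p.tau0);
    dx2[i] = p.tt * (-y2[i] + x2[i] - x2[i] * x2[i] * x2[i] + p.Iext2 +
                     p.bb * g[i] - 0.3 * (z[i] - 3.5) + lc22[i]);
    dy2[i] = p.tt * ((-y2[i] + f2) / p.tau2);
    dg[i]  = p.tt * (-0.01 * (g[i] - 0.1 * x1[i]) + lc12[i]);
  }
}

} // namespace

// [[Rcpp::export]]
List sem_run_cpp(NumericMatrix init, NumericVector x0_, NumericVector pars,
                 IntegerVector ei, IntegerVector ej, NumericVector ew,
                 IntegerVector ed, IntegerVector kp, IntegerVector ki,
                 NumericVector kx, double dt, int n_steps, int stride) {
  const int n = init.ncol();
  if (init.nrow() != 6) stop("init must be a 6 x n matrix");
  Pars p;
  p.Iext = pars[0];  p.Iext2 = pars[1]; p.m = pars[2];   p.k = pars[3];
  p.g11 = pars[4];   p.g12 = pars[5];   p.g22 = pars[6]; p.gglob = pars[7];
  p.th11 = pars[8];  p.th12 = pars[9];  p.th22 = pars[10];
  p.tau0 = pars[11]; p.tau1 = pars[12]; p.tau2 = pars[13]; p.tt = pars[14];
  p.a = pars[15]; p.b = pars[16]; p.c = pars[17]; p.d = pars[18];
  p.aa = pars[19]; p.bb = pars[20];

  std::vector<double> x0(x0_.begin(), x0_.end());
  std::vector<double> x1(n), y1(n), z(n), x2(n), y2(n), g(n);
  for (int i = 0; i < n; ++i) {
    x1[i] = init(0, i); y1[i] = init(1, i); z[i] = init(2, i);
    x2[i] = init(3, i); y2[i] = init(4, i); g[i] = init(5, i);
  }

  const int n_edges = ei.size();
  int depth = 1;
  for (int e = 0; e < n_edges; ++e)
    if (ed[e] + 1 > depth) depth = ed[e] + 1;

  // ring buffer of past x1, pre-filled with the initial state
  std::vector<double> hist((size_t)n * depth);
  for (int c = 0; c < depth; ++c)
    for (int i = 0; i < n; ++i) hist[(size_t)c * n + i] = x1[i];
  int pos = 0;  // column holding the newest write

  const bool has_kernel = kp.size() == n + 1;

  const int n_samples = n_steps / stride + 1;
  NumericMatrix R1(n, n_samples), R2(n, n_samples), R3(n, n_samples),
      R4(n, n_samples), R5(n, n_samples), R6(n, n_samples);
  IntegerVector sample_steps(n_samples);
  NumericVector x1max(n), x2max(n);
  for (int i = 0; i < n; ++i) { x1max[i] = x1[i]; x2max[i] = x2[i]; }

  std::vector<double> glob(n), lc11(n), lc12(n), lc22(n);
  std::vector<double> d1(6 * n), d2(6 * n), px1(n), py1(n), pz(n), px2(n),
      py2(n), pg(n);

  int samp = 0;
  auto record = [&](int step) {
    for (int i = 0; i < n; ++i) {
      R1(i, samp) = x1[i]; R2(i, samp) = y1[i]; R3(i, samp) = z[i];
      R4(i, samp) = x2[i]; R5(i, samp) = y2[i]; R6(i, samp) = g[i];
    }
    sample_steps[samp] = step;
    ++samp;
  };
  record(0);

  const double kg = p.k * p.gglob;
  for (int step = 1; step <= n_steps; ++step) {
    // global delayed difference coupling (frozen for this step)
    std::fill(glob.begin(), glob.end(), 0.0);
    for (int e = 0; e < n_edges; ++e) {
      int col = pos - ed[e];
      if (col < 0) col += depth;
      double xd = hist[(size_t)col * n + ej[e]];
      glob[ei[e]] += ew[e] * (xd - x1[ei[e]]);
    }
    for (int i = 0; i < n; ++i) glob[i] *= kg;

    // Heaviside local coupling (frozen for this step)
    std::fill(lc11.begin(), lc11.end(), 0.0);
    std::fill(lc12.begin(), lc12.end(), 0.0);
    std::fill(lc22.begin(), lc22.end(), 0.0);
    if (has_kernel) {
      for (int j = 0; j < n; ++j) {
        bool h11 = x1[j] >= p.th11, h12 = x1[j] >= p.th12,
             h22 = x2[j] >= p.th22;
        if (!(h11 || h12 || h22)) continue;
        for (int q = kp[j]; q < kp[j + 1]; ++q) {
          int i = ki[q];
          double kv = kx[q];
          if (h11) lc11[i] += kv;
          if (h12) lc12[i] += kv;
          if (h22) lc22[i] += kv;
        }
      }
      for (int i = 0; i < n; ++i) {
        lc11[i] *= p.g11; lc12[i] *= p.g12; lc22[i] *= p.g22;
      }
    }

    derivs(p, x0, n, x1.data(), y1.data(), z.data(), x2.data(), y2.data(),
           g.data(), glob.data(), lc11.data(), lc12.data(), lc22.data(),
           &d1[0], &d1[n], &d1[2 * n], &d1[3 * n], &d1[4 * n], &d1[5 * n]);
    for (int i = 0; i < n; ++i) {
      px1[i] = x1[i] + dt * d1[i];
      py1[i] = y1[i] + dt * d1[n + i];
      pz[i]  = z[i]  + dt * d1[2 * n + i];
      px2[i] = x2[i] + dt * d1[3 * n + i];
      py2[i] = y2[i] + dt * d1[4 * n + i];
      pg[i]  = g[i]  + dt * d1[5 * n + i];
    }
    derivs(p, x0, n, px1.data(), py1.data(), pz.data(), px2.data(),
           py2.data(), pg.data(), glob.data(), lc11.data(), lc12.data(),
           lc22.data(),
           &d2[0], &d2[n], &d2[2 * n], &d2[3 * n], &d2[4 * n], &d2[5 * n]);
    const double hdt = 0.5 * dt;
    for (int i = 0; i < n; ++i) {
      x1[i] += hdt * (d1[i] + d2[i]);
      y1[i] += hdt * (d1[n + i] + d2[n + i]);
      z[i]  += hdt * (d1[2 * n + i] + d2[2 * n + i]);
      x2[i] += hdt * (d1[3 * n + i] + d2[3 * n + i]);
      y2[i] += hdt * (d1[4 * n + i] + d2[4 * n + i]);
      g[i]  += hdt * (d1[5 * n + i] + d2[5 * n + i]);
      if (x1[i] > x1max[i]) x1max[i] = x1[i];
      if (x2[i] > x2max[i]) x2max[i] = x2[i];
      if (!std::isfinite(x1[i]))
        stop("integration diverged (non-finite state) at step %d", step);
    }

    // advance the history ring buffer
    pos = (pos + 1) % depth;
    for (int i = 0; i < n; ++i) hist[(size_t)pos * n + i] = x1[i];

    if (step % stride == 0) record(step);
  }

  NumericMatrix fin(6, n);
  for (int i = 0; i < n; ++i) {
    fin(0, i) = x1[i]; fin(1, i) = y1[i]; fin(2, i) = z[i];
    fin(3, i) = x2[i]; fin(4, i) = y2[i]; fin(5, i) = g[i];
  }

  return List::create(
      _["sample_steps"] = sample_steps, _["x1"] = R1, _["y1"] = R2,
      _["z"] = R3, _["x2"] = R4, _["y2"] = R5, _["g"] = R6,
      _["x1_max"] = x1max, _["x2_max"] = x2max, _["final"] = fin);
}
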