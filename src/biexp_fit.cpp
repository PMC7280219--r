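#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Bi-exponential decay fitting by variable projection: for a candidate pair of
// lifetimes the two amplitudes have a closed-form weighted least-squares
// solution, so the nonlinear search runs over (log tau1, log tau2) only.
// Weights are 1/max(count, 1), the usual Gaussian approximation to Poisson
// counting noise. Exponential bases are built by repeated multiplication
// (rho = exp(-dt/tau)) so no per-bin exp() calls are needed.

static const double TAU_MIN = 0.01;
static const double TAU_MAX = 10.0;

struct AmpSolve {
  double a1, a2, sse;
};

// Weighted LS amplitudes for fixed (tau1, tau2); negative amplitudes are
// handled by falling back to the better single-component solution.
static AmpSolve solve_amplitudes(const double* y, const double* w, int K,
                                 double dt, double tau1, double tau2,
                                 double sumwy2) {
  double rho1 = std::exp(-dt / tau1);
  double rho2 = std::exp(-dt / tau2);
  double b1 = 1.0, b2 = 1.0;
  double S11 = 0.0, S12 = 0.0, S22 = 0.0, r1 = 0.0, r2 = 0.0;
  for (int k = 0; k < K; ++k) {
    double wb1 = w[k] * b1;
    double wb2 = w[k] * b2;
    S11 += wb1 * b1;
    S12 += wb1 * b2;
    S22 += wb2 * b2;
    r1 += wb1 * y[k];
    r2 += wb2 * y[k];
    b1 *= rho1;
    b2 *= rho2;
  }
  AmpSolve out;
  double det = S11 * S22 - S12 * S12;
  double a1 = 0.0, a2 = 0.0;
  if (det > 1e-14 * S11 * S22) {
    a1 = (S22 * r1 - S12 * r2) / det;
    a2 = (S11 * r2 - S12 * r1) / det;
  } else {
    a1 = -1.0;  // force single-component fallback for collinear bases
  }
  if (a1 >= 0.0 && a2 >= 0.0) {
    out.a1 = a1;
    out.a2 = a2;
    out.sse = sumwy2 - (a1 * r1 + a2 * r2);
  } else {
    // best non-negative solution lies on an axis
    double c1 = (S11 > 0) ? std::max(r1, 0.0) / S11 : 0.0;
    double c2 = (S22 > 0) ? std::max(r2, 0.0) / S22 : 0.0;
    double sse1 = sumwy2 - c1 * r1 * (c1 > 0);
    double sse2 = sumwy2 - c2 * r2 * (c2 > 0);
    if (sse1 <= sse2) {
      out.a1 = c1;
      out.a2 = 0.0;
      out.sse = sse1;
    } else {
      out.a1 = 0.0;
      out.a2 = c2;
      out.sse = sse2;
    }
  }
  if (out.sse < 0.0) out.sse = 0.0;  // guard rounding
  return out;
}

static inline double clamp_log_tau(double l) {
  double lo = std::log(TAU_MIN), hi = std::log(TAU_MAX);
  return std::min(std::max(l, lo), hi);
}

struct FitResult {
  double a1, a2, tau1, tau2, sse;
  bool converged;
};

// deterministic initial tau2 guess: log-linear fit to the tail of the trace
static double tail_tau_guess(const double* y, int K, double dt) {
  int start = K / 3;
  double sx = 0, sy = 0, sxx = 0, sxy = 0;
  int n = 0;
  for (int k = start; k < K; ++k) {
    if (y[k] > 0.0) {
      double t = k * dt;
      double ly = std::log(y[k]);
      sx += t; sy += ly; sxx += t * t; sxy += t * ly;
      ++n;
    }
  }
  if (n < 3) return 1.0;
  double denom = n * sxx - sx * sx;
  if (denom <= 0) return 1.0;
  double slope = (n * sxy - sx * sy) / denom;
  if (slope >= -1e-9) return 1.0;
  double tau = -1.0 / slope;
  return std::min(std::max(tau, TAU_MIN * 2), TAU_MAX * 0.9);
}

// Nelder-Mead on (log tau1, log tau2)
static FitResult fit_varpro(const double* y, const double* w, int K, double dt,
                            int max_iter, double ftol,
                            bool warm, double warm_l1, double warm_l2) {
  double sumwy2 = 0.0;
  for (int k = 0; k < K; ++k) sumwy2 += w[k] * y[k] * y[k];

  double l1_0, l2_0;
  if (warm) {
    l1_0 = clamp_log_tau(warm_l1);
    l2_0 = clamp_log_tau(warm_l2);
  } else {
    double tau2_init = tail_tau_guess(y, K, dt);
    l2_0 = clamp_log_tau(std::log(tau2_init));
    l1_0 = clamp_log_tau(std::log(tau2_init / 5.0));
  }

  // simplex vertices
  double px[3] = {l1_0, l1_0 + 0.35, l1_0};
  double py[3] = {l2_0, l2_0, l2_0 + 0.35};
  double fv[3];
  AmpSolve amp;
  for (int i = 0; i < 3; ++i) {
    amp = solve_amplitudes(y, w, K, dt, std::exp(clamp_log_tau(px[i])),
                           std::exp(clamp_log_tau(py[i])), sumwy2);
    fv[i] = amp.sse;
  }

  bool converged = false;
  for (int it = 0; it < max_iter; ++it) {
    // order vertices: lo, mid, hi
    int lo = 0, hi = 0;
    for (int i = 1; i < 3; ++i) {
      if (fv[i] < fv[lo]) lo = i;
      if (fv[i] > fv[hi]) hi = i;
    }
    if (std::fabs(fv[hi] - fv[lo]) <= ftol * (std::fabs(fv[lo]) + 1e-12)) {
      converged = true;
      break;
    }
    int mid = 3 - lo - hi;
    if (mid == lo || mid == hi) mid = (lo + 1) % 3;  // degenerate equal values
    double cx = (px[lo] + px[mid]) / 2.0;
    double cy = (py[lo] + py[mid]) / 2.0;
    // reflect
    double rx = cx + (cx - px[hi]);
    double ry = cy + (cy - py[hi]);
    amp = solve_amplitudes(y, w, K, dt, std::exp(clamp_log_tau(rx)),
                           std::exp(clamp_log_tau(ry)), sumwy2);
    double fr = amp.sse;
    if (fr < fv[lo]) {
      // expand
      double ex = cx + 2.0 * (cx - px[hi]);
      double ey = cy + 2.0 * (cy - py[hi]);
      amp = solve_amplitudes(y, w, K, dt, std::exp(clamp_log_tau(ex)),
                             std::exp(clamp_log_tau(ey)), sumwy2);
      if (amp.sse < fr) {
        px[hi] = ex; py[hi] = ey; fv[hi] = amp.sse;
      } else {
        px[hi] = rx; py[hi] = ry; fv[hi] = fr;
      }
    } else if (fr < fv[mid]) {
      px[hi] = rx; py[hi] = ry; fv[hi] = fr;
    } else {
      // contract
      double kx = cx + 0.5 * (px[hi] - cx);
      double ky = cy + 0.5 * (py[hi] - cy);
      amp = solve_amplitudes(y, w, K, dt, std::exp(clamp_log_tau(kx)),
                             std::exp(clamp_log_tau(ky)), sumwy2);
      if (amp.sse < fv[hi]) {
        px[hi] = kx; py[hi] = ky; fv[hi] = amp.sse;
      } else {
        // shrink toward lo
        for (int i = 0; i < 3; ++i) {
          if (i == lo) continue;
          px[i] = px[lo] + 0.5 * (px[i] - px[lo]);
          py[i] = py[lo] + 0.5 * (py[i] - py[lo]);
          amp = solve_amplitudes(y, w, K, dt, std::exp(clamp_log_tau(px[i])),
                                 std::exp(clamp_log_tau(py[i])), sumwy2);
          fv[i] = amp.sse;
        }
      }
    }
  }

  int lo = 0;
  for (int i = 1; i < 3; ++i)
    if (fv[i] < fv[lo]) lo = i;
  double tau_a = std::exp(clamp_log_tau(px[lo]));
  double tau_b = std::exp(clamp_log_tau(py[lo]));
  amp = solve_amplitudes(y, w, K, dt, tau_a, tau_b, sumwy2);

  FitResult res;
  res.converged = converged;
  res.sse = amp.sse;
  // report components sorted ascending by lifetime
  if (tau_a <= tau_b) {
    res.a1 = amp.a1; res.tau1 = tau_a; res.a2 = amp.a2; res.tau2 = tau_b;
  } else {
    res.a1 = amp.a2; res.tau1 = tau_b; res.a2 = amp.a1; res.tau2 = tau_a;
  }

  // near-equal lifetimes are unidentifiable: collapse to one component;
  // likewise when either amplitude is negligible
  bool tie = (res.tau2 / res.tau1 < 1.1);
  bool negligible =
      (res.a1 + res.a2 > 0) &&
      (std::min(res.a1, res.a2) / (res.a1 + res.a2) < 1e-4);
  bool collapse = tie || negligible || res.a1 == 0.0 || res.a2 == 0.0;
  if (collapse) {
    // 1-D golden-section refit over log tau
    double gl = std::log(TAU_MIN), gh = std::log(TAU_MAX);
    const double gr = 0.6180339887498949;
    double x1 = gh - gr * (gh - gl), x2 = gl + gr * (gh - gl);
    auto f1 = [&](double l) {
      double rho = std::exp(-dt / std::exp(l));
      double b = 1.0, S = 0.0, r = 0.0;
      for (int k = 0; k < K; ++k) {
        S += w[k] * b * b;
        r += w[k] * b * y[k];
        b *= rho;
      }
      double a = (S > 0) ? std::max(r, 0.0) / S : 0.0;
      double sse = sumwy2 - a * r * (a > 0);
      return std::make_pair(std::max(sse, 0.0), a);
    };
    auto p1 = f1(x1), p2 = f1(x2);
    for (int it = 0; it < 80; ++it) {
      if (p1.first < p2.first) {
        gh = x2; x2 = x1; p2 = p1;
        x1 = gh - gr * (gh - gl);
        p1 = f1(x1);
      } else {
        gl = x1; x1 = x2; p1 = p2;
        x2 = gl + gr * (gh - gl);
        p2 = f1(x2);
      }
    }
    double lbest = (p1.first < p2.first) ? x1 : x2;
    auto pb = f1(lbest);
    double tau = std::exp(lbest);
    // only accept if it does not degrade the fit materially (tie collapse
    // is lossless; a genuine second component keeps the 2-component fit)
    if (pb.first <= res.sse * 1.02 + 1e-9) {
      res.a1 = pb.second;
      res.tau1 = tau;
      res.a2 = 0.0;
      res.tau2 = tau;
      res.sse = pb.first;
      res.converged = true;
    }
  }
  return res;
}

// [[Rcpp::export]]
List cpp_fit_biexp(NumericVector trace, double time_bin_ns, int max_iter,
                   double ftol) {
  int K = trace.size();
  std::vector<double> y(K), w(K);
  for (int k = 0; k < K; ++k) {
    y[k] = trace[k];
    w[k] = 1.0 / std::max(y[k], 1.0);
  }
  FitResult r = fit_varpro(y.data(), w.data(), K, time_bin_ns, max_iter, ftol,
                           false, 0, 0);
  int dof = std::max(K - 4, 1);
  return List::create(_["a1"] = r.a1, _["a2"] = r.a2, _["tau1_ns"] = r.tau1,
                      _["tau2_ns"] = r.tau2,
                      _["chi2_reduced"] = r.sse / dof,
                      _["converged"] = r.converged);
}

// Moving-window (2n+1)x(2n+1) sum of decays, clipped at frame edges.
// cube is (ny, nx, K) in R array order; returns same shape.
// [[Rcpp::export]]
NumericVector cpp_bin_cube(NumericVector cube, int ny, int nx, int K, int n) {
  NumericVector out(cube.size());
  std::vector<double> sat((ny + 1) * (nx + 1));
  int satw = ny + 1;
  for (int k = 0; k < K; ++k) {
    const double* slice = &cube[(R_xlen_t)k * ny * nx];
    // summed-area table, column-major like R
    for (int j = 0; j <= nx; ++j)
      for (int i = 0; i <= ny; ++i) {
        if (i == 0 || j == 0) {
          sat[j * satw + i] = 0.0;
          continue;
        }
        sat[j * satw + i] = slice[(j - 1) * ny + (i - 1)] +
                            sat[(j - 1) * satw + i] + sat[j * satw + i - 1] -
                            sat[(j - 1) * satw + i - 1];
      }
    double* oslice = &out[(R_xlen_t)k * ny * nx];
    for (int j = 0; j < nx; ++j) {
      int j0 = std::max(j - n, 0), j1 = std::min(j + n, nx - 1);
      for (int i = 0; i < ny; ++i) {
        int i0 = std::max(i - n, 0), i1 = std::min(i + n, ny - 1);
        oslice[j * ny + i] = sat[(j1 + 1) * satw + i1 + 1] -
                             sat[j0 * satw + i1 + 1] -
                             sat[(j1 + 1) * satw + i0] + sat[j0 * satw + i0];
      }
    }
  }
  return out;
}

// Bin + fit every `stride`-th pixel of a decay cube. Returns per-pixel
// parameter matrices (NA where skipped/below threshold) in R array order.
// [[Rcpp::export]]
List cpp_fit_frame(NumericVector cube, int ny, int nx, int K,
                   double time_bin_ns, int n_bin, double min_photons,
                   int stride, int max_iter, double ftol) {
  NumericVector binned = cpp_bin_cube(cube, ny, nx, K, n_bin);
  NumericMatrix tau1(ny, nx), tau2(ny, nx), a1(ny, nx), a2(ny, nx),
      chi2(ny, nx), nph(ny, nx);
  std::fill(tau1.begin(), tau1.end(), NA_REAL);
  std::fill(tau2.begin(), tau2.end(), NA_REAL);
  std::fill(a1.begin(), a1.end(), NA_REAL);
  std::fill(a2.begin(), a2.end(), NA_REAL);
  std::fill(chi2.begin(), chi2.end(), NA_REAL);
  std::fill(nph.begin(), nph.end(), NA_REAL);

  std::vector<double> y(K), w(K);
  int dof = std::max(K - 4, 1);
  bool have_warm = false;
  double warm_l1 = 0, warm_l2 = 0;
  for (int j = 0; j < nx; j += stride) {
    for (int i = 0; i < ny; i += stride) {
      double tot = 0.0;
      for (int k = 0; k < K; ++k) {
        y[k] = binned[(R_xlen_t)k * ny * nx + (R_xlen_t)j * ny + i];
        w[k] = 1.0 / std::max(y[k], 1.0);
        tot += y[k];
      }
      nph(i, j) = tot;
      if (tot < min_photons) continue;
      FitResult r = fit_varpro(y.data(), w.data(), K, time_bin_ns, max_iter,
                               ftol, have_warm, warm_l1, warm_l2);
      if (!r.converged) continue;  // caller masks the pixel
      tau1(i, j) = r.tau1;
      tau2(i, j) = r.tau2;
      a1(i, j) = r.a1;
      a2(i, j) = r.a2;
      chi2(i, j) = r.sse / dof;
      warm_l1 = std::log(r.tau1);
      warm_l2 = std::log(std::max(r.tau2, r.tau1 * 1.2));
      have_warm = true;
    }
  }
  return List::create(_["tau1"] = tau1, _["tau2"] = tau2, _["a1"] = a1,
                      _["a2"] = a2, _["chi2"] = chi2, _["n_photons"] = nph);
}
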