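#include <Rcpp.h>
using namespace Rcpp;

// L1-area agreement evaluated over a (scale, shift) grid.
//
// ref, det: normalized curves on uniform grids (ref_t0 + j*ref_dt, etc.).
// tau_steps: shifts expressed as integer multiples of det_dt, so that a
// shift is an index offset and the reference only needs interpolating once
// per scale value. Agreement(s, tau) =
//   1 - sum_t |ref((t - tau)/s) - det(t)| * det_dt / (sum_t det(t) * det_dt)
// with ref taken as 0 outside its domain, clipped to [0, 1].
// [[Rcpp::export]]
NumericMatrix agreement_grid_cpp(NumericVector ref, double ref_t0, double ref_dt,
                                 NumericVector det, double det_t0, double det_dt,
                                 NumericVector s_grid, IntegerVector tau_steps) {
  const int n = det.size(), m = ref.size();
  const int ns = s_grid.size(), nk = tau_steps.size();
  NumericMatrix out(ns, nk);
  const double* rp = ref.begin();
  const double* dp = det.begin();

  double det_area = 0.0;
  for (int i = 0; i < n; ++i) det_area += dp[i];
  det_area *= det_dt;
  if (det_area <= 0) stop("unquantifiable determinative curve (zero area)");

  int kmin = tau_steps[0], kmax = tau_steps[0];
  for (int k = 0; k < nk; ++k) {
    if (tau_steps[k] < kmin) kmin = tau_steps[k];
    if (tau_steps[k] > kmax) kmax = tau_steps[k];
  }
  const int g_lo = -kmax;            // lowest det-grid index needed
  const int g_hi = n - 1 - kmin;     // highest
  const int glen = g_hi - g_lo + 1;
  std::vector<double> g(glen);

  for (int si = 0; si < ns; ++si) {
    const double s = s_grid[si];
    for (int j = 0; j < glen; ++j) {
      const double t = det_t0 + (g_lo + j) * det_dt;
      const double x = (t / s - ref_t0) / ref_dt;
      if (x < 0.0 || x > m - 1) { g[j] = 0.0; continue; }
      const int i0 = (int)std::floor(x);
      if (i0 >= m - 1) { g[j] = rp[m - 1]; continue; }
      const double f = x - i0;
      g[j] = rp[i0] * (1.0 - f) + rp[i0 + 1] * f;
    }
    for (int ki = 0; ki < nk; ++ki) {
      const int k = tau_steps[ki];
      const double* __restrict gp = g.data() + (-k - g_lo);
      double acc = 0.0;
      for (int i = 0; i < n; ++i) acc += std::fabs(gp[i] - dp[i]);
      double a = 1.0 - acc * det_dt / det_area;
      if (a < 0.0) a = 0.0;
      if (a > 1.0) a = 1.0;
      out(si, ki) = a;
    }
  }
  return out;
}

// Scalar L1-area agreement at one (s, tau); same interpolation rules as
// the grid kernel, for the refinement stage.
// [[Rcpp::export]]
double agreement_point_cpp(NumericVector ref, double ref_t0, double ref_dt,
                           NumericVector det, double det_t0, double det_dt,
                           double s, double tau) {
  const int n = det.size(), m = ref.size();
  double det_area = 0.0;
  for (int i = 0; i < n; ++i) det_area += det[i];
  det_area *= det_dt;
  if (det_area <= 0) stop("unquantifiable determinative curve (zero area)");
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    const double t = det_t0 + i * det_dt;
    const double x = ((t - tau) / s - ref_t0) / ref_dt;
    double g = 0.0;
    if (x >= 0.0 && x <= m - 1) {
      const int i0 = (int)std::floor(x);
      if (i0 >= m - 1) g = ref[m - 1];
      else {
        const double f = x - i0;
        g = ref[i0] * (1.0 - f) + ref[i0 + 1] * f;
      }
    }
    acc += std::fabs(g - det[i]);
  }
  double a = 1.0 - acc * det_dt / det_area;
  if (a < 0.0) a = 0.0;
  if (a > 1.0) a = 1.0;
  return a;
}
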