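#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// median via nth_element (O(n)); v is taken by value and may be reordered
static double median_of(std::vector<double> v) {
  const size_t n = v.size();
  if (n == 0) return NA_REAL;
  const size_t h = n / 2;
  std::nth_element(v.begin(), v.begin() + h, v.end());
  double m = v[h];
  if (n % 2 == 0) {
    double lo = *std::max_element(v.begin(), v.begin() + h);
    m = 0.5 * (lo + m);
  }
  return m;
}

// One-eye dilation-speed MAD filter. Per pass: speeds over the valid
// subsequence (max of backward/forward absolute speed, or backward only),
// threshold median + k*MAD (mad_constant-scaled) or plain k*MAD, flag and
// repeat on survivors. Returns updated validity flags.
// [[Rcpp::export]]
LogicalVector dilation_valid_cpp(NumericVector t, NumericVector x,
                                 LogicalVector valid, double k, int passes,
                                 bool median_plus, double mad_constant,
                                 bool forward_only) {
  const int n = x.size();
  LogicalVector out = clone(valid);
  std::vector<int> idx;
  idx.reserve(n);
  for (int pass = 0; pass < passes; ++pass) {
    idx.clear();
    for (int i = 0; i < n; ++i) if (out[i]) idx.push_back(i);
    const int m = idx.size();
    if (m < 3) break; // caller warns
    std::vector<double> step(m - 1), d(m);
    for (int j = 0; j + 1 < m; ++j)
      step[j] = std::fabs(x[idx[j + 1]] - x[idx[j]]) /
                (t[idx[j + 1]] - t[idx[j]]);
    if (forward_only) {
      d[0] = step[0];
      for (int j = 1; j < m; ++j) d[j] = step[j - 1];
    } else {
      d[0] = step[0];
      d[m - 1] = step[m - 2];
      for (int j = 1; j + 1 < m; ++j) d[j] = std::max(step[j - 1], step[j]);
    }
    const double med = median_of(d);
    std::vector<double> absdev(m);
    for (int j = 0; j < m; ++j) absdev[j] = std::fabs(d[j] - med);
    const double mad = mad_constant * median_of(absdev);
    const double thr = median_plus ? med + k * mad : k * mad;
    bool any = false;
    for (int j = 0; j < m; ++j)
      if (d[j] > thr) { out[idx[j]] = false; any = true; }
    if (!any) break;
  }
  return out;
}

// Blink detection on one eye: invalid runs spanning [lo, hi] ms (run span =
// t[last] - t[first] + nominal dt) are blinks; valid samples within pad_ms
// before/after the run are invalidated. Returns (valid, blink).
// [[Rcpp::export]]
List blink_valid_cpp(NumericVector t, LogicalVector valid,
                     double lo, double hi, double pad_ms, double dt) {
  const int n = valid.size();
  LogicalVector out = clone(valid);
  LogicalVector blink(n, false);
  int i = 0;
  while (i < n) {
    if (valid[i]) { ++i; continue; }
    int j = i;
    while (j + 1 < n && !valid[j + 1]) ++j;
    const double span = t[j] - t[i] + dt;
    if (span >= lo && span <= hi) {
      for (int q = i; q <= j; ++q) blink[q] = true;
      for (int q = i - 1; q >= 0 && t[i] - t[q] <= pad_ms; --q)
        out[q] = false;
      for (int q = j + 1; q < n && t[q] - t[j] <= pad_ms; ++q)
        out[q] = false;
    }
    i = j + 1;
  }
  return List::create(_["valid"] = out, _["blink"] = blink);
}

// Linear interpolation of one eye's interior invalid runs up to max_gap ms
// (run span as above); imputed samples become valid. Returns (x, valid,
// imputed).
// [[Rcpp::export]]
List interp_gaps_cpp(NumericVector t, NumericVector x, LogicalVector valid,
                     double max_gap, double dt) {
  const int n = valid.size();
  NumericVector xo = clone(x);
  LogicalVector vo = clone(valid);
  LogicalVector imputed(n, false);
  int i = 0;
  while (i < n) {
    if (valid[i]) { ++i; continue; }
    int j = i;
    while (j + 1 < n && !valid[j + 1]) ++j;
    const double span = t[j] - t[i] + dt;
    if (i > 0 && j + 1 < n && valid[i - 1] && valid[j + 1] &&
        span <= max_gap) {
      const double t0 = t[i - 1], t1 = t[j + 1];
      const double x0 = x[i - 1], x1 = x[j + 1];
      for (int q = i; q <= j; ++q) {
        xo[q] = x0 + (x1 - x0) * (t[q] - t0) / (t1 - t0);
        vo[q] = true;
        imputed[q] = true;
      }
    }
    i = j + 1;
  }
  return List::create(_["x"] = xo, _["valid"] = vo, _["imputed"] = imputed);
}

// Full per-trial preprocessing chain on one trial's two-eye vectors:
// range filter [2, 8] mm -> dilation-speed MAD filter (k, passes, median +
// k*MAD, unscaled MAD, bidirectional speeds) -> blink detection (75-250 ms
// gaps, 27 ms padding) -> interpolation (<= 300 ms interior gaps) -> eye
// average -> BPS [0, 250) ms, SEPR [500, 1500) ms, 50% validity rule.
// Mirrors the exported R operations (asserted in the test suite).
// Returns c(bps, sepr, valid_fraction, included).
// [[Rcpp::export]]
NumericVector preprocess_values_cpp(NumericVector t, NumericVector l,
                                    NumericVector r, double k, int passes) {
  const int n = t.size();
  double dtv;
  { // median sample spacing
    std::vector<double> d(n - 1);
    for (int i = 0; i + 1 < n; ++i) d[i] = t[i + 1] - t[i];
    dtv = median_of(d);
  }
  NumericMatrix eyes(n, 2);
  LogicalMatrix vm(n, 2);
  for (int e = 0; e < 2; ++e) {
    NumericVector x = (e == 0) ? l : r;
    LogicalVector v(n);
    int nv = 0;
    for (int i = 0; i < n; ++i) {
      v[i] = R_finite(x[i]) && x[i] >= 2.0 && x[i] <= 8.0;
      if (v[i]) ++nv;
    }
    if (nv >= 3)
      v = dilation_valid_cpp(t, x, v, k, passes, true, 1.0, false);
    v = as<LogicalVector>(blink_valid_cpp(t, v, 75, 250, 27, dtv)["valid"]);
    List ip = interp_gaps_cpp(t, x, v, 300, dtv);
    NumericVector xo = ip["x"];
    LogicalVector vo = ip["valid"];
    for (int i = 0; i < n; ++i) { eyes(i, e) = xo[i]; vm(i, e) = vo[i]; }
  }
  int nvalid = 0, nbase = 0, nsepr = 0;
  double sbase = 0, ssepr = 0;
  for (int i = 0; i < n; ++i) {
    double mm;
    if (vm(i, 0) && vm(i, 1)) mm = 0.5 * (eyes(i, 0) + eyes(i, 1));
    else if (vm(i, 0)) mm = eyes(i, 0);
    else if (vm(i, 1)) mm = eyes(i, 1);
    else continue;
    ++nvalid;
    if (t[i] >= 0 && t[i] < 250) { sbase += mm; ++nbase; }
    else if (t[i] >= 500 && t[i] < 1500) { ssepr += mm; ++nsepr; }
  }
  const double frac = double(nvalid) / n;
  NumericVector out =
      NumericVector::create(NA_REAL, NA_REAL, frac, 0.0);
  if (frac < 0.5 || nbase == 0) return out;
  const double bps = sbase / nbase;
  out[0] = bps;
  out[1] = (nsepr > 0) ? ssepr / nsepr - bps : NA_REAL;
  out[3] = 1.0;
  return out;
}

// Zero-phase forward-backward filtering of each matrix row with
// odd-reflection padding and steady-state initial conditions (zi for a unit
// step, scaled by the first padded sample).
// [[Rcpp::export]]
NumericMatrix filtfilt_rows_cpp(NumericVector b, NumericVector a,
                                NumericMatrix x, NumericVector zi) {
  const int nr = x.nrow(), nc = x.ncol();
  const int nb = b.size(), na = a.size(), nz = zi.size();
  const int pad = 3 * std::max(na, nb);
  if (nc <= pad) stop("series too short for filtfilt padding");
  const int ne = nc + 2 * pad;
  NumericMatrix out(nr, nc);
  std::vector<double> ext(ne), y(ne), z(nz);

  for (int r = 0; r < nr; ++r) {
    for (int q = 0; q < pad; ++q)
      ext[q] = 2.0 * x(r, 0) - x(r, pad - q);
    for (int q = 0; q < nc; ++q) ext[pad + q] = x(r, q);
    for (int q = 0; q < pad; ++q)
      ext[pad + nc + q] = 2.0 * x(r, nc - 1) - x(r, nc - 2 - q);

    // forward
    for (int q = 0; q < nz; ++q) z[q] = zi[q] * ext[0];
    for (int q = 0; q < ne; ++q) {
      const double xi = ext[q];
      const double yi = b[0] * xi + (nz > 0 ? z[0] : 0.0);
      for (int kk = 0; kk < nz; ++kk) {
        double acc = (kk + 1 < nz) ? z[kk + 1] : 0.0;
        if (kk + 1 < nb) acc += b[kk + 1] * xi;
        if (kk + 1 < na) acc -= a[kk + 1] * yi;
        z[kk] = acc;
      }
      y[q] = yi;
    }
    // backward
    for (int q = 0; q < nz; ++q) z[q] = zi[q] * y[ne - 1];
    for (int q = ne - 1; q >= 0; --q) {
      const double xi = y[q];
      const double yi = b[0] * xi + (nz > 0 ? z[0] : 0.0);
      for (int kk = 0; kk < nz; ++kk) {
        double acc = (kk + 1 < nz) ? z[kk + 1] : 0.0;
        if (kk + 1 < nb) acc += b[kk + 1] * xi;
        if (kk + 1 < na) acc -= a[kk + 1] * yi;
        z[kk] = acc;
      }
      ext[q] = yi; // reuse ext as backward output
    }
    for (int q = 0; q < nc; ++q) out(r, q) = ext[pad + q];
  }
  return out;
}
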