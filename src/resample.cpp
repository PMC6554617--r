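// Periodic (bi/tri)linear interpolation and the inner loops of geodesic
// shooting.  The R wrappers keep all bookkeeping and NaN semantics identical
// to the reference pure-R path: 0 * NaN propagates through pull (IEEE), and
// push skips NaN source values.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline int wrap(int i, int n) {
  i %= n;
  return i < 0 ? i + n : i;
}

// Corner offsets and weights at one coordinate along one axis.
static inline void axis_parts(double c, int n, int& lo, int& hi, double& t) {
  double fl = std::floor(c);
  t = c - fl;
  lo = wrap((int)fl, n);
  hi = lo + 1 == n ? 0 : lo + 1;
}

// Corner indices (1-based linear) and weights for sampling at the given
// coordinates (0-based voxel units, arbitrary reals; wrapped periodically).
// [[Rcpp::export]]
List cpp_interp_plan(const NumericMatrix& map, const IntegerVector& dims) {
  const int d = dims.size();
  const int M = map.nrow();
  const int nc = 1 << d;
  IntegerMatrix idx(M, nc);
  NumericMatrix w(M, nc);
  int* pi = INTEGER(idx);
  double* pw = REAL(w);
  const double* pm = REAL(map);
  if (d == 2) {
    const int n0 = dims[0], n1 = dims[1];
    for (int i = 0; i < M; ++i) {
      int l0, h0, l1, h1;
      double t0, t1;
      axis_parts(pm[i], n0, l0, h0, t0);
      axis_parts(pm[i + M], n1, l1, h1, t1);
      const int b0 = l1 * n0, b1 = h1 * n0;
      pi[i] = 1 + l0 + b0;
      pi[i + M] = 1 + h0 + b0;
      pi[i + 2 * M] = 1 + l0 + b1;
      pi[i + 3 * M] = 1 + h0 + b1;
      const double s0 = 1 - t0, s1 = 1 - t1;
      pw[i] = s0 * s1;
      pw[i + M] = t0 * s1;
      pw[i + 2 * M] = s0 * t1;
      pw[i + 3 * M] = t0 * t1;
    }
  } else {
    const int n0 = dims[0], n1 = dims[1], n2 = dims[2];
    const int n01 = n0 * n1;
    for (int i = 0; i < M; ++i) {
      int l0, h0, l1, h1, l2, h2;
      double t0, t1, t2;
      axis_parts(pm[i], n0, l0, h0, t0);
      axis_parts(pm[i + M], n1, l1, h1, t1);
      axis_parts(pm[i + 2 * M], n2, l2, h2, t2);
      const int b00 = l1 * n0 + l2 * n01, b10 = h1 * n0 + l2 * n01;
      const int b01 = l1 * n0 + h2 * n01, b11 = h1 * n0 + h2 * n01;
      pi[i] = 1 + l0 + b00;
      pi[i + M] = 1 + h0 + b00;
      pi[i + 2 * M] = 1 + l0 + b10;
      pi[i + 3 * M] = 1 + h0 + b10;
      pi[i + 4 * M] = 1 + l0 + b01;
      pi[i + 5 * M] = 1 + h0 + b01;
      pi[i + 6 * M] = 1 + l0 + b11;
      pi[i + 7 * M] = 1 + h0 + b11;
      const double s0 = 1 - t0, s1 = 1 - t1, s2 = 1 - t2;
      pw[i] = s0 * s1 * s2;
      pw[i + M] = t0 * s1 * s2;
      pw[i + 2 * M] = s0 * t1 * s2;
      pw[i + 3 * M] = t0 * t1 * s2;
      pw[i + 4 * M] = s0 * s1 * t2;
      pw[i + 5 * M] = t0 * s1 * t2;
      pw[i + 6 * M] = s0 * t1 * t2;
      pw[i + 7 * M] = t0 * t1 * t2;
    }
  }
  return List::create(Named("idx") = idx, Named("w") = w, Named("M") = M);
}

// Sample values at the plan's locations: out[i] = sum_c w[i,c] * v[idx[i,c]].
// NaN in v propagates whenever a corner is touched (0 * NaN = NaN).
// [[Rcpp::export]]
NumericVector cpp_pull_channel(const NumericVector& values,
                               const IntegerMatrix& idx,
                               const NumericMatrix& w) {
  const int M = idx.nrow();
  const int nc = idx.ncol();
  NumericVector out(M);
  const double* pv = REAL(values);
  const int* pi = INTEGER(idx);
  const double* pw = REAL(w);
  double* po = REAL(out);
  for (int i = 0; i < M; ++i) {
    double acc = 0.0;
    for (int c = 0; c < nc; ++c)
      acc += pw[i + c * M] * pv[pi[i + c * M] - 1];
    po[i] = acc;
  }
  return out;
}

// Exact adjoint: splat values back with the same weights; NaN sources are
// skipped (contribute nothing).
// [[Rcpp::export]]
NumericVector cpp_push_channel(const NumericVector& values,
                               const IntegerMatrix& idx,
                               const NumericMatrix& w) {
  const int M = idx.nrow();
  const int nc = idx.ncol();
  NumericVector out(M);   // zero-initialised
  const double* pv = REAL(values);
  const int* pi = INTEGER(idx);
  const double* pw = REAL(w);
  double* po = REAL(out);
  for (int i = 0; i < M; ++i) {
    double v = pv[i];
    if (ISNAN(v)) continue;
    for (int c = 0; c < nc; ++c)
      po[pi[i + c * M] - 1] += pw[i + c * M] * v;
  }
  return out;
}

// Interpolate the columns of `fields` (M x K, periodic-smooth values) at the
// points x - dt * vt, where x is the identity lattice.  Used for the map
// composition inside Euler shooting (fields = displacement components).
static void sample_at_offset(const double* fields, int K, const double* vt,
                             double dt, const IntegerVector& dims, int M,
                             double* out) {
  const int d = dims.size();
  if (d == 2) {
    const int n0 = dims[0], n1 = dims[1];
    for (int i = 0; i < M; ++i) {
      const int x0 = i % n0, x1 = i / n0;
      int l0, h0, l1, h1;
      double t0, t1;
      axis_parts(x0 - dt * vt[i], n0, l0, h0, t0);
      axis_parts(x1 - dt * vt[i + M], n1, l1, h1, t1);
      const int i00 = l0 + l1 * n0, i10 = h0 + l1 * n0;
      const int i01 = l0 + h1 * n0, i11 = h0 + h1 * n0;
      const double w00 = (1 - t0) * (1 - t1), w10 = t0 * (1 - t1);
      const double w01 = (1 - t0) * t1, w11 = t0 * t1;
      for (int k = 0; k < K; ++k) {
        const double* f = fields + k * M;
        out[i + k * M] = w00 * f[i00] + w10 * f[i10] +
          w01 * f[i01] + w11 * f[i11];
      }
    }
  } else {
    const int n0 = dims[0], n1 = dims[1], n2 = dims[2];
    const int n01 = n0 * n1;
    for (int i = 0; i < M; ++i) {
      const int x0 = i % n0, x1 = (i / n0) % n1, x2 = i / n01;
      int l0, h0, l1, h1, l2, h2;
      double t0, t1, t2;
      axis_parts(x0 - dt * vt[i], n0, l0, h0, t0);
      axis_parts(x1 - dt * vt[i + M], n1, l1, h1, t1);
      axis_parts(x2 - dt * vt[i + 2 * M], n2, l2, h2, t2);
      const double s0 = 1 - t0, s1 = 1 - t1, s2 = 1 - t2;
      const int c[8] = {l0 + l1 * n0 + l2 * n01, h0 + l1 * n0 + l2 * n01,
                        l0 + h1 * n0 + l2 * n01, h0 + h1 * n0 + l2 * n01,
                        l0 + l1 * n0 + h2 * n01, h0 + l1 * n0 + h2 * n01,
                        l0 + h1 * n0 + h2 * n01, h0 + h1 * n0 + h2 * n01};
      const double wt[8] = {s0 * s1 * s2, t0 * s1 * s2, s0 * t1 * s2,
                            t0 * t1 * s2, s0 * s1 * t2, t0 * s1 * t2,
                            s0 * t1 * t2, t0 * t1 * t2};
      for (int k = 0; k < K; ++k) {
        const double* f = fields + k * M;
        double acc = 0.0;
        for (int q = 0; q < 8; ++q) acc += wt[q] * f[c[q]];
        out[i + k * M] = acc;
      }
    }
  }
}

// One Euler composition step of the inverse flow:
//   disp_new(x) = -dt * vt(x) + disp(x - dt * vt(x))
// disp and vt are M x d matrices (column-major, displacement in voxel units).
// [[Rcpp::export]]
NumericMatrix cpp_compose_disp(const NumericMatrix& disp,
                               const NumericMatrix& vt,
                               const IntegerVector& dims, double dt) {
  const int M = disp.nrow();
  const int d = dims.size();
  NumericMatrix out(M, d);
  sample_at_offset(REAL(disp), d, REAL(vt), dt, dims, M, REAL(out));
  double* po = REAL(out);
  const double* pv = REAL(vt);
  for (int j = 0; j < d * M; ++j) po[j] -= dt * pv[j];
  return out;
}

// Momentum transport by the current map psi = id + disp:
//   u(x) = |Dpsi|(x) * (Dpsi)^T(x) * u0(psi(x))
// with the Jacobian from central differences of disp (periodic).
// [[Rcpp::export]]
NumericMatrix cpp_transport_momentum(const NumericMatrix& disp,
                                     const NumericMatrix& u0,
                                     const IntegerVector& dims) {
  const int M = disp.nrow();
  const int d = dims.size();
  NumericMatrix out(M, d);
  // u0 sampled at psi(x) = x + disp(x): reuse the offset sampler with dt=-1
  std::vector<double> u0p(M * d);
  sample_at_offset(REAL(u0), d, REAL(disp), -1.0, dims, M, u0p.data());
  const double* pd = REAL(disp);
  double* po = REAL(out);
  if (d == 2) {
    const int n0 = dims[0], n1 = dims[1];
    for (int i = 0; i < M; ++i) {
      const int x0 = i % n0, x1 = i / n0;
      const int xp0 = (x0 + 1 == n0 ? 0 : x0 + 1) + x1 * n0;
      const int xm0 = (x0 == 0 ? n0 - 1 : x0 - 1) + x1 * n0;
      const int xp1 = x0 + (x1 + 1 == n1 ? 0 : x1 + 1) * n0;
      const int xm1 = x0 + (x1 == 0 ? n1 - 1 : x1 - 1) * n0;
      const double J00 = 1 + 0.5 * (pd[xp0] - pd[xm0]);
      const double J01 = 0.5 * (pd[xp1] - pd[xm1]);
      const double J10 = 0.5 * (pd[M + xp0] - pd[M + xm0]);
      const double J11 = 1 + 0.5 * (pd[M + xp1] - pd[M + xm1]);
      const double det = J00 * J11 - J01 * J10;
      const double a = u0p[i], b = u0p[i + M];
      po[i] = det * (J00 * a + J10 * b);
      po[i + M] = det * (J01 * a + J11 * b);
    }
  } else {
    const int n0 = dims[0], n1 = dims[1], n2 = dims[2];
    const int n01 = n0 * n1;
    for (int i = 0; i < M; ++i) {
      const int x0 = i % n0, x1 = (i / n0) % n1, x2 = i / n01;
      const int p0 = (x0 + 1 == n0 ? 0 : x0 + 1) - x0;
      const int m0 = (x0 == 0 ? n0 - 1 : x0 - 1) - x0;
      const int p1 = ((x1 + 1 == n1 ? 0 : x1 + 1) - x1) * n0;
      const int m1 = ((x1 == 0 ? n1 - 1 : x1 - 1) - x1) * n0;
      const int p2 = ((x2 + 1 == n2 ? 0 : x2 + 1) - x2) * n01;
      const int m2 = ((x2 == 0 ? n2 - 1 : x2 - 1) - x2) * n01;
      double J[3][3];
      for (int r = 0; r < 3; ++r) {      // J[r][c] = d psi_r / d x_c
        const double* dr = pd + r * M;
        J[r][0] = 0.5 * (dr[i + p0] - dr[i + m0]);
        J[r][1] = 0.5 * (dr[i + p1] - dr[i + m1]);
        J[r][2] = 0.5 * (dr[i + p2] - dr[i + m2]);
        J[r][r] += 1.0;
      }
      const double det =
        J[0][0] * (J[1][1] * J[2][2] - J[1][2] * J[2][1]) -
        J[0][1] * (J[1][0] * J[2][2] - J[1][2] * J[2][0]) +
        J[0][2] * (J[1][0] * J[2][1] - J[1][1] * J[2][0]);
      const double a = u0p[i], b = u0p[i + M], c = u0p[i + 2 * M];
      for (int r = 0; r < 3; ++r)
        po[i + r * M] = det * (J[0][r] * a + J[1][r] * b + J[2][r] * c);
    }
  }
  return out;
}
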