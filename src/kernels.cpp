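#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Trilinear interpolation of a column-major 3D array at a physical point.
// Returns false when the point lies outside the voxel-centre bounding box.
static inline bool trilin(const double* a, const int* d, const double* sp,
                          const double* orig, double px, double py, double pz,
                          double& out) {
  double cx = (px - orig[0]) / sp[0];
  double cy = (py - orig[1]) / sp[1];
  double cz = (pz - orig[2]) / sp[2];
  if (cx < 0 || cy < 0 || cz < 0 || cx > d[0] - 1 || cy > d[1] - 1 ||
      cz > d[2] - 1)
    return false;
  int i0 = std::min((int)std::floor(cx), d[0] - 2); if (i0 < 0) i0 = 0;
  int j0 = std::min((int)std::floor(cy), d[1] - 2); if (j0 < 0) j0 = 0;
  int k0 = std::min((int)std::floor(cz), d[2] - 2); if (k0 < 0) k0 = 0;
  double fx = cx - i0, fy = cy - j0, fz = cz - k0;
  int dx = d[0] > 1 ? 1 : 0;
  int dy = d[1] > 1 ? d[0] : 0;
  int dz = d[2] > 1 ? d[0] * d[1] : 0;
  if (d[0] == 1) fx = 0;
  if (d[1] == 1) fy = 0;
  if (d[2] == 1) fz = 0;
  long base = i0 + (long)j0 * d[0] + (long)k0 * d[0] * d[1];
  out = a[base] * (1 - fx) * (1 - fy) * (1 - fz) +
        a[base + dx] * fx * (1 - fy) * (1 - fz) +
        a[base + dy] * (1 - fx) * fy * (1 - fz) +
        a[base + dx + dy] * fx * fy * (1 - fz) +
        a[base + dz] * (1 - fx) * (1 - fy) * fz +
        a[base + dx + dz] * fx * (1 - fy) * fz +
        a[base + dy + dz] * (1 - fx) * fy * fz +
        a[base + dx + dy + dz] * fx * fy * fz;
  return true;
}

struct Offset { double x, y, z, d2; };

static std::vector<Offset> buildOffsets(double radius, double step) {
  int m = (int)std::floor(radius / step + 1e-12);
  std::vector<Offset> offs;
  offs.reserve((2 * m + 1) * (2 * m + 1) * (2 * m + 1));
  double r2 = radius * radius * (1 + 1e-12);
  for (int k = -m; k <= m; ++k)
    for (int j = -m; j <= m; ++j)
      for (int i = -m; i <= m; ++i) {
        Offset o;
        o.x = i * step; o.y = j * step; o.z = k * step;
        o.d2 = o.x * o.x + o.y * o.y + o.z * o.z;
        if (o.d2 <= r2) offs.push_back(o);
      }
  return offs;
}

// Gamma index by sorted dense search with per-voxel early termination.
// refPos: N x 3 physical positions (mm) of evaluated reference voxels;
// refVal: their reference doses; doseTol: absolute dose tolerance (Gy);
// dta, radius, step in mm. Returns gamma per evaluated voxel (NA when the
// search sphere contains no test-grid data).
// [[Rcpp::export(name = ".cppGamma")]]
NumericVector cppGamma(NumericMatrix refPos, NumericVector refVal,
                       NumericVector testDose, IntegerVector testDim,
                       NumericVector testSpacing, NumericVector testOrigin,
                       double doseTol, double dta, double radius, double step) {
  std::vector<Offset> offs = buildOffsets(radius, step);
  std::sort(offs.begin(), offs.end(),
            [](const Offset& a, const Offset& b) { return a.d2 < b.d2; });
  int n = refPos.nrow();
  NumericVector gamma(n);
  const double* td = testDose.begin();
  const int* d = testDim.begin();
  const double* sp = testSpacing.begin();
  const double* orig = testOrigin.begin();
  double dta2 = dta * dta, tol2 = doseTol * doseTol;
  for (int v = 0; v < n; ++v) {
    double px = refPos(v, 0), py = refPos(v, 1), pz = refPos(v, 2);
    double rv = refVal[v];
    double g2min = R_PosInf;
    for (size_t o = 0; o < offs.size(); ++o) {
      double spatial2 = offs[o].d2 / dta2;
      if (spatial2 >= g2min) break;  // offsets sorted: no later one can win
      double tv;
      if (!trilin(td, d, sp, orig, px + offs[o].x, py + offs[o].y,
                  pz + offs[o].z, tv))
        continue;
      double dd = tv - rv;
      double g2 = dd * dd / tol2 + spatial2;
      if (g2 < g2min) g2min = g2;
    }
    gamma[v] = R_FINITE(g2min) ? std::sqrt(g2min) : NA_REAL;
  }
  return gamma;
}

// Exhaustive oracle: full lexicographic sweep of the dense offset grid with
// a per-voxel running minimum and the sound skip "spatial term alone already
// exceeds the current minimum". A coarse internal pre-search (its offsets
// are a subset of the dense grid, so priming cannot change the result)
// tightens the running minima first so the sweep prunes well. Identical in
// value to the naive full dense search at the given step.
// [[Rcpp::export(name = ".cppGammaOracle")]]
NumericVector cppGammaOracle(NumericMatrix refPos, NumericVector refVal,
                             NumericVector testDose, IntegerVector testDim,
                             NumericVector testSpacing,
                             NumericVector testOrigin, double doseTol,
                             double dta, double radius, double step) {
  int n = refPos.nrow();
  std::vector<double> g2min(n, R_PosInf);
  const double* td = testDose.begin();
  const int* d = testDim.begin();
  const double* sp = testSpacing.begin();
  const double* orig = testOrigin.begin();
  double dta2 = dta * dta, tol2 = doseTol * doseTol;

  // coarse prime: multiples of the fine step so the set stays a subset
  int coarseMult = std::max(1, (int)std::floor(dta / (4.0 * step)));
  std::vector<Offset> coarse = buildOffsets(radius, step * coarseMult);
  std::sort(coarse.begin(), coarse.end(),
            [](const Offset& a, const Offset& b) { return a.d2 < b.d2; });
  for (int v = 0; v < n; ++v) {
    double px = refPos(v, 0), py = refPos(v, 1), pz = refPos(v, 2);
    double rv = refVal[v], g2 = R_PosInf;
    for (size_t o = 0; o < coarse.size(); ++o) {
      double spatial2 = coarse[o].d2 / dta2;
      if (spatial2 >= g2) break;
      double tv;
      if (!trilin(td, d, sp, orig, px + coarse[o].x, py + coarse[o].y,
                  pz + coarse[o].z, tv))
        continue;
      double dd = tv - rv;
      double cand = dd * dd / tol2 + spatial2;
      if (cand < g2) g2 = cand;
    }
    g2min[v] = g2;
  }

  // exhaustive sweep at the fine step
  std::vector<Offset> offs = buildOffsets(radius, step);
  int m = (int)offs.size();
  std::vector<double> spatial2v(m);
  for (int o = 0; o < m; ++o) spatial2v[o] = offs[o].d2 / dta2;
  for (int v = 0; v < n; ++v) {
    double px = refPos(v, 0), py = refPos(v, 1), pz = refPos(v, 2);
    double rv = refVal[v], g2 = g2min[v];
    for (int o = 0; o < m; ++o) {
      if (spatial2v[o] >= g2) continue;
      double tv;
      if (!trilin(td, d, sp, orig, px + offs[o].x, py + offs[o].y,
                  pz + offs[o].z, tv))
        continue;
      double dd = tv - rv;
      double cand = dd * dd / tol2 + spatial2v[o];
      if (cand < g2) g2 = cand;
    }
    g2min[v] = g2;
  }
  NumericVector gamma(n);
  for (int v = 0; v < n; ++v)
    gamma[v] = R_FINITE(g2min[v]) ? std::sqrt(g2min[v]) : NA_REAL;
  return gamma;
}

// For each point in A (N x 3, mm), the Euclidean distance to the nearest
// point in B (M x 3, mm). Plain O(N*M) scan.
// [[Rcpp::export(name = ".cppNearestDist")]]
NumericVector cppNearestDist(NumericMatrix A, NumericMatrix B) {
  int n = A.nrow(), m = B.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double ax = A(i, 0), ay = A(i, 1), az = A(i, 2);
    double best = R_PosInf;
    for (int j = 0; j < m; ++j) {
      double dx = ax - B(j, 0), dy = ay - B(j, 1), dz = az - B(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
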