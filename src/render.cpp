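// Ray-traced attenuation path lengths through a closed triangle mesh.
//
// The fiducial is projected with the locally parallel-beam model implied by
// the landmark forward map: every ray through the object runs along the
// projection normal, and the in-plane scale is 1/(c_d2p * d) px/mm. A pixel's
// fiducial path length is obtained by intersecting its vertical ray with all
// mesh triangles (2D barycentric test on the projected triangle, depth by
// interpolation) and summing consecutive entry/exit interval lengths.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// crossing depths of the vertical ray at (wx, wy) [mm, object frame]
static inline void ray_hits(const double* X, const double* Y, const double* Z,
                            const int* f0, const int* f1, const int* f2,
                            int ntri, double wx, double wy,
                            std::vector<double>& zs) {
  zs.clear();
  for (int t = 0; t < ntri; ++t) {
    const double x1 = X[f0[t]], y1 = Y[f0[t]];
    const double x2 = X[f1[t]], y2 = Y[f1[t]];
    const double x3 = X[f2[t]], y3 = Y[f2[t]];
    const double det = (y2 - y3) * (x1 - x3) + (x3 - x2) * (y1 - y3);
    if (std::abs(det) < 1e-14) continue;  // edge-on triangle, measure zero
    const double l1 = ((y2 - y3) * (wx - x3) + (x3 - x2) * (wy - y3)) / det;
    if (l1 < 0.0 || l1 > 1.0) continue;
    const double l2 = ((y3 - y1) * (wx - x3) + (x1 - x3) * (wy - y3)) / det;
    if (l2 < 0.0 || l1 + l2 > 1.0) continue;
    const double l3 = 1.0 - l1 - l2;
    zs.push_back(l1 * Z[f0[t]] + l2 * Z[f1[t]] + l3 * Z[f2[t]]);
  }
}

// [[Rcpp::export]]
NumericMatrix fp_path_map(NumericMatrix Vw, IntegerMatrix F,
                          double px, double py, double s,
                          int u0, int u1, int v0, int v1) {
  const int nv = Vw.nrow(), ntri = F.nrow();
  std::vector<double> X(nv), Y(nv), Z(nv);
  for (int i = 0; i < nv; ++i) { X[i] = Vw(i, 0); Y[i] = Vw(i, 1); Z[i] = Vw(i, 2); }
  std::vector<int> f0(ntri), f1(ntri), f2(ntri);
  for (int t = 0; t < ntri; ++t) { f0[t] = F(t, 0) - 1; f1[t] = F(t, 1) - 1; f2[t] = F(t, 2) - 1; }

  const int nu = u1 - u0 + 1, nvp = v1 - v0 + 1;
  NumericMatrix out(nvp, nu);  // rows = y, cols = x
  std::vector<double> zs;
  zs.reserve(16);
  for (int u = u0; u <= u1; ++u) {
    const double wx = (u - px) / s;
    for (int v = v0; v <= v1; ++v) {
      const double wy = (v - py) / s;
      ray_hits(X.data(), Y.data(), Z.data(), f0.data(), f1.data(), f2.data(),
               ntri, wx, wy, zs);
      if (zs.size() < 2) continue;
      std::sort(zs.begin(), zs.end());
      double len = 0.0;
      const size_t npair = zs.size() / 2;
      for (size_t k = 0; k < npair; ++k) len += zs[2 * k + 1] - zs[2 * k];
      out(v - v0, u - u0) = len;
    }
  }
  return out;
}

// crossing counts of vertical rays at arbitrary (wx, wy) points — used by the
// watertightness (ray parity) audit
// [[Rcpp::export]]
IntegerVector fp_vertical_hits(NumericMatrix Vw, IntegerMatrix F,
                               NumericMatrix pts) {
  const int nv = Vw.nrow(), ntri = F.nrow(), np = pts.nrow();
  std::vector<double> X(nv), Y(nv), Z(nv);
  for (int i = 0; i < nv; ++i) { X[i] = Vw(i, 0); Y[i] = Vw(i, 1); Z[i] = Vw(i, 2); }
  std::vector<int> f0(ntri), f1(ntri), f2(ntri);
  for (int t = 0; t < ntri; ++t) { f0[t] = F(t, 0) - 1; f1[t] = F(t, 1) - 1; f2[t] = F(t, 2) - 1; }
  IntegerVector out(np);
  std::vector<double> zs;
  for (int i = 0; i < np; ++i) {
    ray_hits(X.data(), Y.data(), Z.data(), f0.data(), f1.data(), f2.data(),
             ntri, pts(i, 0), pts(i, 1), zs);
    out[i] = (int)zs.size();
  }
  return out;
}
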