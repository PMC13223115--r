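// Ray-parity containment kernel (Moller-Trumbore) for watertight triangle
// meshes. Faces are 1-based index triples; parity of crossings along a fixed
// direction decides interior/exterior. Hits grazing a triangle edge are
// flagged ambiguous so the caller can retry with another direction.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
List cpp_crossing_parity(NumericMatrix vertices, IntegerMatrix faces,
                         NumericMatrix points, NumericVector dir,
                         double eps = 1e-9) {
  const int nf = faces.nrow(), np = points.nrow();
  std::vector<double> v0x(nf), v0y(nf), v0z(nf),
      e1x(nf), e1y(nf), e1z(nf), e2x(nf), e2y(nf), e2z(nf),
      hx(nf), hy(nf), hz(nf), inva(nf);
  std::vector<bool> ok(nf);
  const double dx = dir[0], dy = dir[1], dz = dir[2];
  for (int j = 0; j < nf; ++j) {
    const int a = faces(j, 0) - 1, b = faces(j, 1) - 1, c = faces(j, 2) - 1;
    v0x[j] = vertices(a, 0); v0y[j] = vertices(a, 1); v0z[j] = vertices(a, 2);
    e1x[j] = vertices(b, 0) - v0x[j];
    e1y[j] = vertices(b, 1) - v0y[j];
    e1z[j] = vertices(b, 2) - v0z[j];
    e2x[j] = vertices(c, 0) - v0x[j];
    e2y[j] = vertices(c, 1) - v0y[j];
    e2z[j] = vertices(c, 2) - v0z[j];
    hx[j] = dy * e2z[j] - dz * e2y[j];
    hy[j] = dz * e2x[j] - dx * e2z[j];
    hz[j] = dx * e2y[j] - dy * e2x[j];
    const double a0 = e1x[j] * hx[j] + e1y[j] * hy[j] + e1z[j] * hz[j];
    ok[j] = std::abs(a0) > eps;
    inva[j] = ok[j] ? 1.0 / a0 : 0.0;
  }
  LogicalVector odd(np), ambiguous(np);
  for (int i = 0; i < np; ++i) {
    const double px = points(i, 0), py = points(i, 1), pz = points(i, 2);
    int cnt = 0; bool amb = false;
    for (int j = 0; j < nf; ++j) {
      if (!ok[j]) continue;
      const double sx = px - v0x[j], sy = py - v0y[j], sz = pz - v0z[j];
      const double u = (sx * hx[j] + sy * hy[j] + sz * hz[j]) * inva[j];
      if (u < -eps) continue;
      const double qx = sy * e1z[j] - sz * e1y[j];
      const double qy = sz * e1x[j] - sx * e1z[j];
      const double qz = sx * e1y[j] - sy * e1x[j];
      const double v = (dx * qx + dy * qy + dz * qz) * inva[j];
      if (v < -eps || u + v > 1 + eps) continue;
      const double t = (e2x[j] * qx + e2y[j] * qy + e2z[j] * qz) * inva[j];
      if (t <= eps) continue;
      ++cnt;
      if (u < eps || v < eps || u + v > 1 - eps) amb = true;
    }
    odd[i] = (cnt % 2) == 1;
    ambiguous[i] = amb;
  }
  return List::create(_["odd"] = odd, _["ambiguous"] = ambiguous);
}
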