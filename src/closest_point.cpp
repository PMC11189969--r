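#include <Rcpp.h>
using namespace Rcpp;

// Closest point on a triangle (Ericson, Real-Time Collision Detection).
// Also reports the closest feature so the caller can pick the right
// pseudo-normal for the distance sign:
//   0 face interior; 1,2,3 vertex a,b,c; 4 edge ab, 5 edge bc, 6 edge ca.
static inline void closest_on_tri(const double *p, const double *a,
                                  const double *b, const double *c,
                                  double *out, int *feature) {
  double ab[3], ac[3], ap[3];
  for (int k = 0; k < 3; ++k) {
    ab[k] = b[k] - a[k];
    ac[k] = c[k] - a[k];
    ap[k] = p[k] - a[k];
  }
  double d1 = ab[0]*ap[0] + ab[1]*ap[1] + ab[2]*ap[2];
  double d2 = ac[0]*ap[0] + ac[1]*ap[1] + ac[2]*ap[2];
  if (d1 <= 0.0 && d2 <= 0.0) {
    for (int k = 0; k < 3; ++k) out[k] = a[k];
    *feature = 1; return;
  }
  double bp[3];
  for (int k = 0; k < 3; ++k) bp[k] = p[k] - b[k];
  double d3 = ab[0]*bp[0] + ab[1]*bp[1] + ab[2]*bp[2];
  double d4 = ac[0]*bp[0] + ac[1]*bp[1] + ac[2]*bp[2];
  if (d3 >= 0.0 && d4 <= d3) {
    for (int k = 0; k < 3; ++k) out[k] = b[k];
    *feature = 2; return;
  }
  double vc = d1*d4 - d3*d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    for (int k = 0; k < 3; ++k) out[k] = a[k] + v * ab[k];
    *feature = 4; return;
  }
  double cp[3];
  for (int k = 0; k < 3; ++k) cp[k] = p[k] - c[k];
  double d5 = ab[0]*cp[0] + ab[1]*cp[1] + ab[2]*cp[2];
  double d6 = ac[0]*cp[0] + ac[1]*cp[1] + ac[2]*cp[2];
  if (d6 >= 0.0 && d5 <= d6) {
    for (int k = 0; k < 3; ++k) out[k] = c[k];
    *feature = 3; return;
  }
  double vb = d5*d2 - d1*d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    for (int k = 0; k < 3; ++k) out[k] = a[k] + w * ac[k];
    *feature = 6; return;
  }
  double va = d3*d6 - d5*d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int k = 0; k < 3; ++k) out[k] = b[k] + w * (c[k] - b[k]);
    *feature = 5; return;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int k = 0; k < 3; ++k) out[k] = a[k] + ab[k]*v + ac[k]*w;
  *feature = 0;
}

// Brute-force closest point on a triangle mesh for each query point.
// Ties (exactly equal squared distances) keep the lowest triangle index.
// [[Rcpp::export]]
List cpp_closest_point(NumericMatrix pts, NumericMatrix V, IntegerMatrix F) {
  const int np = pts.nrow(), nf = F.nrow();
  NumericVector dist(np);
  IntegerVector tri(np), feature(np);
  NumericMatrix closest(np, 3);
  std::vector<double> vx(V.nrow()), vy(V.nrow()), vz(V.nrow());
  for (int i = 0; i < V.nrow(); ++i) {
    vx[i] = V(i, 0); vy[i] = V(i, 1); vz[i] = V(i, 2);
  }
  for (int ip = 0; ip < np; ++ip) {
    double p[3] = { pts(ip, 0), pts(ip, 1), pts(ip, 2) };
    double best = R_PosInf, bestpt[3] = {0, 0, 0};
    int bestf = -1, bestfeat = 0;
    for (int f = 0; f < nf; ++f) {
      int ia = F(f, 0) - 1, ib = F(f, 1) - 1, ic = F(f, 2) - 1;
      double a[3] = { vx[ia], vy[ia], vz[ia] };
      double b[3] = { vx[ib], vy[ib], vz[ib] };
      double c[3] = { vx[ic], vy[ic], vz[ic] };
      double q[3]; int feat;
      closest_on_tri(p, a, b, c, q, &feat);
      double dx = p[0]-q[0], dy = p[1]-q[1], dz = p[2]-q[2];
      double d2 = dx*dx + dy*dy + dz*dz;
      if (d2 < best) {
        best = d2;
        bestf = f; bestfeat = feat;
        bestpt[0] = q[0]; bestpt[1] = q[1]; bestpt[2] = q[2];
      }
    }
    dist[ip] = std::sqrt(best);
    tri[ip] = bestf + 1;
    feature[ip] = bestfeat;
    closest(ip, 0) = bestpt[0];
    closest(ip, 1) = bestpt[1];
    closest(ip, 2) = bestpt[2];
  }
  return List::create(_["dist"] = dist, _["tri"] = tri,
                      _["feature"] = feature, _["closest"] = closest);
}
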