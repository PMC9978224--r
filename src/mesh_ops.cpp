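#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double dot3(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}

// Closest point on a triangle (a,b,c) to p; Ericson, Real-Time Collision
// Detection, ch. 5. Writes the closest point into q.
static void closest_on_tri(const double* p, const double* a, const double* b,
                           const double* c, double* q) {
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; ++i) {
    ab[i] = b[i] - a[i];
    ac[i] = c[i] - a[i];
    ap[i] = p[i] - a[i];
  }
  double d1 = dot3(ab, ap), d2 = dot3(ac, ap);
  if (d1 <= 0.0 && d2 <= 0.0) { for (int i = 0; i < 3; ++i) q[i] = a[i]; return; }

  double bp[3];
  for (int i = 0; i < 3; ++i) bp[i] = p[i] - b[i];
  double d3 = dot3(ab, bp), d4 = dot3(ac, bp);
  if (d3 >= 0.0 && d4 <= d3) { for (int i = 0; i < 3; ++i) q[i] = b[i]; return; }

  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    for (int i = 0; i < 3; ++i) q[i] = a[i] + v * ab[i];
    return;
  }

  double cp[3];
  for (int i = 0; i < 3; ++i) cp[i] = p[i] - c[i];
  double d5 = dot3(ab, cp), d6 = dot3(ac, cp);
  if (d6 >= 0.0 && d5 <= d6) { for (int i = 0; i < 3; ++i) q[i] = c[i]; return; }

  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    for (int i = 0; i < 3; ++i) q[i] = a[i] + w * ac[i];
    return;
  }

  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int i = 0; i < 3; ++i) q[i] = b[i] + w * (c[i] - b[i]);
    return;
  }

  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int i = 0; i < 3; ++i) q[i] = a[i] + ab[i] * v + ac[i] * w;
}

// For each query point, the closest surface point over all triangles.
// Ties (equal distance) resolve to the lowest face index: faces are scanned
// in order and only a strictly smaller distance replaces the incumbent.
// [[Rcpp::export]]
List closest_points_cpp(NumericMatrix P, NumericMatrix V, IntegerMatrix F) {
  const int np = P.nrow(), nv = V.nrow(), nf = F.nrow();
  std::vector<double> vv(3 * nv);
  for (int i = 0; i < nv; ++i)
    for (int j = 0; j < 3; ++j) vv[3 * i + j] = V(i, j);
  std::vector<int> ff(3 * nf);
  for (int i = 0; i < nf; ++i)
    for (int j = 0; j < 3; ++j) ff[3 * i + j] = F(i, j) - 1;

  NumericMatrix Q(np, 3);
  IntegerVector face(np);
  NumericVector dist(np);
  double p[3], q[3], best_q[3];

  for (int ip = 0; ip < np; ++ip) {
    for (int j = 0; j < 3; ++j) p[j] = P(ip, j);
    double best = R_PosInf;
    int best_f = -1;
    for (int f = 0; f < nf; ++f) {
      const double* a = &vv[3 * ff[3 * f]];
      const double* b = &vv[3 * ff[3 * f + 1]];
      const double* c = &vv[3 * ff[3 * f + 2]];
      closest_on_tri(p, a, b, c, q);
      double d2 = 0.0;
      for (int j = 0; j < 3; ++j) {
        double e = p[j] - q[j];
        d2 += e * e;
      }
      if (d2 < best) {
        best = d2;
        best_f = f;
        for (int j = 0; j < 3; ++j) best_q[j] = q[j];
      }
    }
    for (int j = 0; j < 3; ++j) Q(ip, j) = best_q[j];
    face[ip] = best_f + 1;
    dist[ip] = std::sqrt(best);
  }
  return List::create(_["point"] = Q, _["face"] = face, _["distance"] = dist);
}

// Variant with face-bounding-sphere pruning and warm-start hints: the
// distance to the hinted face bounds the search, and any face whose
// centroid is farther than best + circumradius cannot contain a closer
// point. With coherent hints (particles move little between calls) most
// faces are rejected by one comparison.
// [[Rcpp::export]]
List closest_points_hint_cpp(NumericMatrix P, NumericMatrix V,
                             IntegerMatrix F, IntegerVector hint) {
  const int np = P.nrow(), nv = V.nrow(), nf = F.nrow();
  std::vector<double> vv(3 * nv);
  for (int i = 0; i < nv; ++i)
    for (int j = 0; j < 3; ++j) vv[3 * i + j] = V(i, j);
  std::vector<int> ff(3 * nf);
  for (int i = 0; i < nf; ++i)
    for (int j = 0; j < 3; ++j) ff[3 * i + j] = F(i, j) - 1;

  // face centroids and circumscribing radii
  std::vector<double> fc(3 * nf), fr(nf);
  for (int f = 0; f < nf; ++f) {
    const double* a = &vv[3 * ff[3 * f]];
    const double* b = &vv[3 * ff[3 * f + 1]];
    const double* c = &vv[3 * ff[3 * f + 2]];
    double r2 = 0.0;
    for (int j = 0; j < 3; ++j) fc[3 * f + j] = (a[j] + b[j] + c[j]) / 3.0;
    const double* vs[3] = {a, b, c};
    for (int t = 0; t < 3; ++t) {
      double d2 = 0.0;
      for (int j = 0; j < 3; ++j) {
        double e = vs[t][j] - fc[3 * f + j];
        d2 += e * e;
      }
      if (d2 > r2) r2 = d2;
    }
    fr[f] = std::sqrt(r2);
  }

  NumericMatrix Q(np, 3);
  IntegerVector face(np);
  NumericVector dist(np);
  double p[3], q[3], best_q[3];

  for (int ip = 0; ip < np; ++ip) {
    for (int j = 0; j < 3; ++j) p[j] = P(ip, j);
    double best = R_PosInf;
    int best_f = -1;
    int h = hint[ip] - 1;
    if (h >= 0 && h < nf) {
      closest_on_tri(p, &vv[3 * ff[3 * h]], &vv[3 * ff[3 * h + 1]],
                     &vv[3 * ff[3 * h + 2]], q);
      best = 0.0;
      for (int j = 0; j < 3; ++j) {
        double e = p[j] - q[j];
        best += e * e;
      }
      best_f = h;
      for (int j = 0; j < 3; ++j) best_q[j] = q[j];
    }
    double best_d = std::sqrt(best);
    for (int f = 0; f < nf; ++f) {
      double dc2 = 0.0;
      for (int j = 0; j < 3; ++j) {
        double e = p[j] - fc[3 * f + j];
        dc2 += e * e;
      }
      double lb = std::sqrt(dc2) - fr[f];
      if (lb >= best_d) continue;      // incumbent kept on ties
      closest_on_tri(p, &vv[3 * ff[3 * f]], &vv[3 * ff[3 * f + 1]],
                     &vv[3 * ff[3 * f + 2]], q);
      double d2 = 0.0;
      for (int j = 0; j < 3; ++j) {
        double e = p[j] - q[j];
        d2 += e * e;
      }
      if (d2 < best) {
        best = d2;
        best_d = std::sqrt(best);
        best_f = f;
        for (int j = 0; j < 3; ++j) best_q[j] = q[j];
      }
    }
    for (int j = 0; j < 3; ++j) Q(ip, j) = best_q[j];
    face[ip] = best_f + 1;
    dist[ip] = std::sqrt(best);
  }
  return List::create(_["point"] = Q, _["face"] = face, _["distance"] = dist);
}

// Forward ray-mesh intersections (Moller-Trumbore). For each ray i
// (origin O[i,], direction D[i,]) returns hit count, smallest and largest
// ray parameter t among hits with t > eps.
// [[Rcpp::export]]
NumericMatrix ray_hits_cpp(NumericMatrix O, NumericMatrix D, NumericMatrix V,
                           IntegerMatrix F, double eps) {
  const int nr = O.nrow(), nv = V.nrow(), nf = F.nrow();
  std::vector<double> vv(3 * nv);
  for (int i = 0; i < nv; ++i)
    for (int j = 0; j < 3; ++j) vv[3 * i + j] = V(i, j);
  std::vector<int> ff(3 * nf);
  for (int i = 0; i < nf; ++i)
    for (int j = 0; j < 3; ++j) ff[3 * i + j] = F(i, j) - 1;

  NumericMatrix out(nr, 3);
  for (int ir = 0; ir < nr; ++ir) {
    double o[3], d[3];
    for (int j = 0; j < 3; ++j) { o[j] = O(ir, j); d[j] = D(ir, j); }
    int count = 0;
    double tmin = R_PosInf, tmax = R_NegInf;
    for (int f = 0; f < nf; ++f) {
      const double* a = &vv[3 * ff[3 * f]];
      const double* b = &vv[3 * ff[3 * f + 1]];
      const double* c = &vv[3 * ff[3 * f + 2]];
      double e1[3], e2[3];
      for (int j = 0; j < 3; ++j) { e1[j] = b[j] - a[j]; e2[j] = c[j] - a[j]; }
      double pv[3] = {d[1] * e2[2] - d[2] * e2[1],
                      d[2] * e2[0] - d[0] * e2[2],
                      d[0] * e2[1] - d[1] * e2[0]};
      double det = dot3(e1, pv);
      if (std::fabs(det) < 1e-14) continue;
      double inv = 1.0 / det;
      double tv[3];
      for (int j = 0; j < 3; ++j) tv[j] = o[j] - a[j];
      double u = dot3(tv, pv) * inv;
      if (u < -1e-12 || u > 1.0 + 1e-12) continue;
      double qv[3] = {tv[1] * e1[2] - tv[2] * e1[1],
                      tv[2] * e1[0] - tv[0] * e1[2],
                      tv[0] * e1[1] - tv[1] * e1[0]};
      double v = dot3(d, qv) * inv;
      if (v < -1e-12 || u + v > 1.0 + 1e-12) continue;
      double t = dot3(e2, qv) * inv;
      if (t > eps) {
        ++count;
        if (t < tmin) tmin = t;
        if (t > tmax) tmax = t;
      }
    }
    out(ir, 0) = count;
    out(ir, 1) = count ? tmin : NA_REAL;
    out(ir, 2) = count ? tmax : NA_REAL;
  }
  return out;
}
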