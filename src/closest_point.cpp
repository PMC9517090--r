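#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Closest point on a closed triangle (a,b,c) to p. Ericson, Real-Time
// Collision Detection, ch. 5.1.5; handles interior, edge and vertex regions.
static inline void closest_pt_tri(const double *p, const double *a,
                                  const double *b, const double *c,
                                  double *out) {
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; ++i) {
    ab[i] = b[i] - a[i];
    ac[i] = c[i] - a[i];
    ap[i] = p[i] - a[i];
  }
  double d1 = ab[0] * ap[0] + ab[1] * ap[1] + ab[2] * ap[2];
  double d2 = ac[0] * ap[0] + ac[1] * ap[1] + ac[2] * ap[2];
  if (d1 <= 0.0 && d2 <= 0.0) {
    out[0] = a[0]; out[1] = a[1]; out[2] = a[2];
    return;
  }
  double bp[3];
  for (int i = 0; i < 3; ++i) bp[i] = p[i] - b[i];
  double d3 = ab[0] * bp[0] + ab[1] * bp[1] + ab[2] * bp[2];
  double d4 = ac[0] * bp[0] + ac[1] * bp[1] + ac[2] * bp[2];
  if (d3 >= 0.0 && d4 <= d3) {
    out[0] = b[0]; out[1] = b[1]; out[2] = b[2];
    return;
  }
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + v * ab[i];
    return;
  }
  double cp[3];
  for (int i = 0; i < 3; ++i) cp[i] = p[i] - c[i];
  double d5 = ab[0] * cp[0] + ab[1] * cp[1] + ab[2] * cp[2];
  double d6 = ac[0] * cp[0] + ac[1] * cp[1] + ac[2] * cp[2];
  if (d6 >= 0.0 && d5 <= d6) {
    out[0] = c[0]; out[1] = c[1]; out[2] = c[2];
    return;
  }
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + w * ac[i];
    return;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int i = 0; i < 3; ++i) out[i] = b[i] + w * (c[i] - b[i]);
    return;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int i = 0; i < 3; ++i) out[i] = a[i] + ab[i] * v + ac[i] * w;
}

static inline double sqdist3(const double *x, const double *y) {
  double dx = x[0] - y[0], dy = x[1] - y[1], dz = x[2] - y[2];
  return dx * dx + dy * dy + dz * dz;
}

// squared distance from point to axis-aligned box [lo, hi]
static inline double sqdist_aabb(const double *p, const double *lo,
                                 const double *hi) {
  double s = 0.0;
  for (int i = 0; i < 3; ++i) {
    double d = 0.0;
    if (p[i] < lo[i]) d = lo[i] - p[i];
    else if (p[i] > hi[i]) d = p[i] - hi[i];
    s += d * d;
  }
  return s;
}

// [[Rcpp::export]]
List cpp_closest_point_mesh(NumericMatrix queries, NumericMatrix vertices,
                            IntegerMatrix faces, bool exhaustive = false) {
  const int nq = queries.nrow();
  const int nf = faces.nrow();
  if (nf == 0) stop("mesh has no faces");

  // face vertex coordinates, row-major triplets, plus per-face AABBs
  std::vector<double> fa(3 * nf), fb(3 * nf), fc(3 * nf);
  std::vector<double> lo(3 * nf), hi(3 * nf), cen(3 * nf);
  for (int f = 0; f < nf; ++f) {
    int ia = faces(f, 0) - 1, ib = faces(f, 1) - 1, ic = faces(f, 2) - 1;
    for (int k = 0; k < 3; ++k) {
      double va = vertices(ia, k), vb = vertices(ib, k), vc = vertices(ic, k);
      fa[3 * f + k] = va; fb[3 * f + k] = vb; fc[3 * f + k] = vc;
      double mn = va < vb ? va : vb; if (vc < mn) mn = vc;
      double mx = va > vb ? va : vb; if (vc > mx) mx = vc;
      lo[3 * f + k] = mn; hi[3 * f + k] = mx;
      cen[3 * f + k] = (va + vb + vc) / 3.0;
    }
  }

  NumericVector dist(nq);
  NumericMatrix points(nq, 3);
  IntegerVector face_id(nq);
  double q[3], cand[3], best_pt[3];

  for (int i = 0; i < nq; ++i) {
    q[0] = queries(i, 0); q[1] = queries(i, 1); q[2] = queries(i, 2);
    double best = std::numeric_limits<double>::infinity();
    int bestf = -1;
    if (!exhaustive) {
      // seed the bound with the face whose centroid is nearest
      int seed = 0;
      double bestc = std::numeric_limits<double>::infinity();
      for (int f = 0; f < nf; ++f) {
        double d = sqdist3(q, &cen[3 * f]);
        if (d < bestc) { bestc = d; seed = f; }
      }
      closest_pt_tri(q, &fa[3 * seed], &fb[3 * seed], &fc[3 * seed], cand);
      best = sqdist3(q, cand);
      bestf = seed;
      best_pt[0] = cand[0]; best_pt[1] = cand[1]; best_pt[2] = cand[2];
    }
    for (int f = 0; f < nf; ++f) {
      if (!exhaustive) {
        if (f == bestf) continue;
        // strict inequality: an equal-distance face must still be examined
        // so that ties resolve to the lowest face id
        if (sqdist_aabb(q, &lo[3 * f], &hi[3 * f]) > best) continue;
      }
      closest_pt_tri(q, &fa[3 * f], &fb[3 * f], &fc[3 * f], cand);
      double d = sqdist3(q, cand);
      if (d < best || (d == best && f < bestf)) {
        best = d; bestf = f;
        best_pt[0] = cand[0]; best_pt[1] = cand[1]; best_pt[2] = cand[2];
      }
    }
    dist[i] = std::sqrt(best);
    points(i, 0) = best_pt[0]; points(i, 1) = best_pt[1];
    points(i, 2) = best_pt[2];
    face_id[i] = bestf + 1;
  }
  return List::create(_["distance"] = dist, _["point"] = points,
                      _["face"] = face_id);
}

// [[Rcpp::export]]
List cpp_closest_point_triangle(NumericVector p, NumericVector a,
                                NumericVector b, NumericVector c) {
  double out[3];
  closest_pt_tri(REAL(p), REAL(a), REAL(b), REAL(c), out);
  NumericVector pt = NumericVector::create(out[0], out[1], out[2]);
  double d = std::sqrt(sqdist3(REAL(p), out));
  return List::create(_["point"] = pt, _["distance"] = d);
}

// brute-force nearest neighbour among target points; returns 1-based index
// and distance (ties -> lowest index)
// [[Rcpp::export]]
List cpp_nearest_neighbour(NumericMatrix queries, NumericMatrix target) {
  const int nq = queries.nrow(), nt = target.nrow();
  if (nt == 0) stop("empty target point set");
  IntegerVector idx(nq);
  NumericVector dist(nq);
  for (int i = 0; i < nq; ++i) {
    double q0 = queries(i, 0), q1 = queries(i, 1), q2 = queries(i, 2);
    double best = std::numeric_limits<double>::infinity();
    int bestj = 0;
    for (int j = 0; j < nt; ++j) {
      double dx = target(j, 0) - q0, dy = target(j, 1) - q1,
             dz = target(j, 2) - q2;
      double d = dx * dx + dy * dy + dz * dz;
      if (d < best) { best = d; bestj = j; }
    }
    idx[i] = bestj + 1;
    dist[i] = std::sqrt(best);
  }
  return List::create(_["index"] = idx, _["distance"] = dist);
}
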