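// Geometry kernels: triangle-triangle intersection (Moller 1997 interval
// test with coplanar fallback) and ray-casting point-in-mesh, plus the
// mesh-pair overlap driver with AABB prefiltering.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static const double COPL_EPS = 1e-12;

static inline void sub3(const double* a, const double* b, double* out) {
  out[0] = a[0] - b[0]; out[1] = a[1] - b[1]; out[2] = a[2] - b[2];
}
static inline void cross3(const double* a, const double* b, double* out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}
static inline double dot3(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}

// 2D edge-edge intersection used by the coplanar branch.
static bool edge_edge_test(const double* v0, const double* v1,
                           const double* u0, const double* u1,
                           int i0, int i1) {
  double Ax = v1[i0] - v0[i0];
  double Ay = v1[i1] - v0[i1];
  double Bx = u0[i0] - u1[i0];
  double By = u0[i1] - u1[i1];
  double Cx = v0[i0] - u0[i0];
  double Cy = v0[i1] - u0[i1];
  double f = Ay * Bx - Ax * By;
  double d = By * Cx - Bx * Cy;
  if ((f > 0 && d >= 0 && d <= f) || (f < 0 && d <= 0 && d >= f)) {
    double e = Ax * Cy - Ay * Cx;
    if (f > 0) {
      if (e >= 0 && e <= f) return true;
    } else {
      if (e <= 0 && e >= f) return true;
    }
  }
  return false;
}

static bool edge_against_tri_edges(const double* v0, const double* v1,
                                   const double* u0, const double* u1,
                                   const double* u2, int i0, int i1) {
  return edge_edge_test(v0, v1, u0, u1, i0, i1) ||
         edge_edge_test(v0, v1, u1, u2, i0, i1) ||
         edge_edge_test(v0, v1, u2, u0, i0, i1);
}

static bool point_in_tri_2d(const double* v0, const double* u0,
                            const double* u1, const double* u2,
                            int i0, int i1) {
  double a = u1[i1] - u0[i1];
  double b = -(u1[i0] - u0[i0]);
  double c = -a * u0[i0] - b * u0[i1];
  double d0 = a * v0[i0] + b * v0[i1] + c;

  a = u2[i1] - u1[i1];
  b = -(u2[i0] - u1[i0]);
  c = -a * u1[i0] - b * u1[i1];
  double d1 = a * v0[i0] + b * v0[i1] + c;

  a = u0[i1] - u2[i1];
  b = -(u0[i0] - u2[i0]);
  c = -a * u2[i0] - b * u2[i1];
  double d2 = a * v0[i0] + b * v0[i1] + c;

  return (d0 * d1 > 0 && d0 * d2 > 0);
}

static bool coplanar_tri_tri(const double* N,
                             const double* v0, const double* v1, const double* v2,
                             const double* u0, const double* u1, const double* u2) {
  double A[3] = {std::fabs(N[0]), std::fabs(N[1]), std::fabs(N[2])};
  int i0, i1;
  if (A[0] > A[1]) {
    if (A[0] > A[2]) { i0 = 1; i1 = 2; } else { i0 = 0; i1 = 1; }
  } else {
    if (A[2] > A[1]) { i0 = 0; i1 = 1; } else { i0 = 0; i1 = 2; }
  }
  if (edge_against_tri_edges(v0, v1, u0, u1, u2, i0, i1)) return true;
  if (edge_against_tri_edges(v1, v2, u0, u1, u2, i0, i1)) return true;
  if (edge_against_tri_edges(v2, v0, u0, u1, u2, i0, i1)) return true;
  if (point_in_tri_2d(v0, u0, u1, u2, i0, i1)) return true;
  if (point_in_tri_2d(u0, v0, v1, v2, i0, i1)) return true;
  return false;
}

// Interval of the projected intersection line covered by a triangle.
static inline void isect_interval(double VV0, double VV1, double VV2,
                                  double D0, double D1, double D2,
                                  double* a, double* b) {
  *a = VV0 + (VV1 - VV0) * D0 / (D0 - D1);
  *b = VV0 + (VV2 - VV0) * D0 / (D0 - D2);
}

// Returns 0 = disjoint, 1 = intersecting, 2 = coplanar case handled.
static bool compute_intervals(double VV0, double VV1, double VV2,
                              double D0, double D1, double D2,
                              double D0D1, double D0D2,
                              double* a, double* b, bool* coplanar) {
  *coplanar = false;
  if (D0D1 > 0) {
    // D0 and D1 same side, D2 on the other
    isect_interval(VV2, VV0, VV1, D2, D0, D1, a, b);
  } else if (D0D2 > 0) {
    isect_interval(VV1, VV0, VV2, D1, D0, D2, a, b);
  } else if (D1 * D2 > 0 || D0 != 0) {
    isect_interval(VV0, VV1, VV2, D0, D1, D2, a, b);
  } else if (D1 != 0) {
    isect_interval(VV1, VV0, VV2, D1, D0, D2, a, b);
  } else if (D2 != 0) {
    isect_interval(VV2, VV0, VV1, D2, D0, D1, a, b);
  } else {
    *coplanar = true;
  }
  return true;
}

static bool tri_tri_intersect(const double* V0, const double* V1, const double* V2,
                              const double* U0, const double* U1, const double* U2) {
  double E1[3], E2[3], N1[3], N2[3], D[3];

  sub3(V1, V0, E1);
  sub3(V2, V0, E2);
  cross3(E1, E2, N1);
  double d1 = -dot3(N1, V0);

  double du0 = dot3(N1, U0) + d1;
  double du1 = dot3(N1, U1) + d1;
  double du2 = dot3(N1, U2) + d1;
  double scale1 = std::sqrt(dot3(N1, N1));
  if (std::fabs(du0) < COPL_EPS * scale1) du0 = 0.0;
  if (std::fabs(du1) < COPL_EPS * scale1) du1 = 0.0;
  if (std::fabs(du2) < COPL_EPS * scale1) du2 = 0.0;
  double du0du1 = du0 * du1;
  double du0du2 = du0 * du2;
  if (du0du1 > 0 && du0du2 > 0) return false;

  sub3(U1, U0, E1);
  sub3(U2, U0, E2);
  cross3(E1, E2, N2);
  double d2 = -dot3(N2, U0);

  double dv0 = dot3(N2, V0) + d2;
  double dv1 = dot3(N2, V1) + d2;
  double dv2 = dot3(N2, V2) + d2;
  double scale2 = std::sqrt(dot3(N2, N2));
  if (std::fabs(dv0) < COPL_EPS * scale2) dv0 = 0.0;
  if (std::fabs(dv1) < COPL_EPS * scale2) dv1 = 0.0;
  if (std::fabs(dv2) < COPL_EPS * scale2) dv2 = 0.0;
  double dv0dv1 = dv0 * dv1;
  double dv0dv2 = dv0 * dv2;
  if (dv0dv1 > 0 && dv0dv2 > 0) return false;

  cross3(N1, N2, D);

  int index = 0;
  double maxc = std::fabs(D[0]);
  if (std::fabs(D[1]) > maxc) { maxc = std::fabs(D[1]); index = 1; }
  if (std::fabs(D[2]) > maxc) { index = 2; }

  double vp0 = V0[index], vp1 = V1[index], vp2 = V2[index];
  double up0 = U0[index], up1 = U1[index], up2 = U2[index];

  double isect1a, isect1b, isect2a, isect2b;
  bool copl = false;
  compute_intervals(vp0, vp1, vp2, dv0, dv1, dv2, dv0dv1, dv0dv2,
                    &isect1a, &isect1b, &copl);
  if (copl) return coplanar_tri_tri(N1, V0, V1, V2, U0, U1, U2);
  compute_intervals(up0, up1, up2, du0, du1, du2, du0du1, du0du2,
                    &isect2a, &isect2b, &copl);
  if (copl) return coplanar_tri_tri(N1, V0, V1, V2, U0, U1, U2);

  if (isect1a > isect1b) std::swap(isect1a, isect1b);
  if (isect2a > isect2b) std::swap(isect2a, isect2b);
  return !(isect1b < isect2a || isect2b < isect1a);
}

// Moller-Trumbore ray-triangle intersection; counts only t > eps hits.
static bool ray_hits_tri(const double* orig, const double* dir,
                         const double* v0, const double* v1, const double* v2) {
  double e1[3], e2[3], pvec[3], tvec[3], qvec[3];
  sub3(v1, v0, e1);
  sub3(v2, v0, e2);
  cross3(dir, e1, pvec);
  double det = dot3(e2, pvec);
  if (std::fabs(det) < 1e-14) return false;
  double inv = 1.0 / det;
  sub3(orig, v0, tvec);
  double u = dot3(tvec, pvec) * inv;
  if (u < 0.0 || u > 1.0) return false;
  cross3(tvec, e2, qvec);
  double v = dot3(dir, qvec) * inv;
  if (v < 0.0 || u + v > 1.0) return false;
  double t = dot3(e1, qvec) * inv;
  return t > 1e-12;
}

static bool point_in_mesh_impl(const double* p, const NumericMatrix& V,
                               const IntegerMatrix& F) {
  // deliberately irrational-ish direction to dodge edge/vertex grazing
  double dir[3] = {0.5370861, 0.6628462, 0.5215469};
  int nf = F.nrow(), nv = V.nrow();
  int hits = 0;
  for (int i = 0; i < nf; ++i) {
    int a = F(i, 0), b = F(i, 1), c = F(i, 2);
    double v0[3] = {V(a, 0), V(a, 1), V(a, 2)};
    double v1[3] = {V(b, 0), V(b, 1), V(b, 2)};
    double v2[3] = {V(c, 0), V(c, 1), V(c, 2)};
    if (ray_hits_tri(p, dir, v0, v1, v2)) ++hits;
  }
  (void)nv;
  return (hits % 2) == 1;
}

// [[Rcpp::export]]
bool cpp_point_in_mesh(NumericVector point, NumericMatrix V, IntegerMatrix F) {
  double p[3] = {point[0], point[1], point[2]};
  return point_in_mesh_impl(p, V, F);
}

// [[Rcpp::export]]
bool cpp_tri_tri(NumericMatrix T1, NumericMatrix T2) {
  double a0[3] = {T1(0, 0), T1(0, 1), T1(0, 2)};
  double a1[3] = {T1(1, 0), T1(1, 1), T1(1, 2)};
  double a2[3] = {T1(2, 0), T1(2, 1), T1(2, 2)};
  double b0[3] = {T2(0, 0), T2(0, 1), T2(0, 2)};
  double b1[3] = {T2(1, 0), T2(1, 1), T2(1, 2)};
  double b2[3] = {T2(2, 0), T2(2, 1), T2(2, 2)};
  return tri_tri_intersect(a0, a1, a2, b0, b1, b2);
}

struct TriBoxes {
  std::vector<double> lo0, lo1, lo2, hi0, hi1, hi2;
};

static void tri_boxes(const NumericMatrix& V, const IntegerMatrix& F, TriBoxes& B) {
  int nf = F.nrow();
  B.lo0.resize(nf); B.lo1.resize(nf); B.lo2.resize(nf);
  B.hi0.resize(nf); B.hi1.resize(nf); B.hi2.resize(nf);
  for (int i = 0; i < nf; ++i) {
    int a = F(i, 0), b = F(i, 1), c = F(i, 2);
    for (int k = 0; k < 3; ++k) {
      double x = V(a, k), y = V(b, k), z = V(c, k);
      double lo = x < y ? x : y; if (z < lo) lo = z;
      double hi = x > y ? x : y; if (z > hi) hi = z;
      if (k == 0) { B.lo0[i] = lo; B.hi0[i] = hi; }
      else if (k == 1) { B.lo1[i] = lo; B.hi1[i] = hi; }
      else { B.lo2[i] = lo; B.hi2[i] = hi; }
    }
  }
}

// Surface-surface intersection OR mutual centroid containment. Centroids
// (volume centroids) are computed on the R side.
// [[Rcpp::export]]
bool cpp_meshes_overlap(NumericMatrix V1, IntegerMatrix F1,
                        NumericMatrix V2, IntegerMatrix F2,
                        NumericVector c1, NumericVector c2) {
  // global AABB reject
  double lo1[3], hi1[3], lo2[3], hi2[3];
  for (int k = 0; k < 3; ++k) {
    lo1[k] = R_PosInf; hi1[k] = R_NegInf;
    lo2[k] = R_PosInf; hi2[k] = R_NegInf;
  }
  for (int i = 0; i < V1.nrow(); ++i)
    for (int k = 0; k < 3; ++k) {
      if (V1(i, k) < lo1[k]) lo1[k] = V1(i, k);
      if (V1(i, k) > hi1[k]) hi1[k] = V1(i, k);
    }
  for (int i = 0; i < V2.nrow(); ++i)
    for (int k = 0; k < 3; ++k) {
      if (V2(i, k) < lo2[k]) lo2[k] = V2(i, k);
      if (V2(i, k) > hi2[k]) hi2[k] = V2(i, k);
    }
  for (int k = 0; k < 3; ++k)
    if (hi1[k] < lo2[k] || hi2[k] < lo1[k]) return false;

  TriBoxes B1, B2;
  tri_boxes(V1, F1, B1);
  tri_boxes(V2, F2, B2);

  int n1 = F1.nrow(), n2 = F2.nrow();
  for (int i = 0; i < n1; ++i) {
    // skip triangles of mesh 1 outside mesh 2's global box
    if (B1.hi0[i] < lo2[0] || B1.lo0[i] > hi2[0] ||
        B1.hi1[i] < lo2[1] || B1.lo1[i] > hi2[1] ||
        B1.hi2[i] < lo2[2] || B1.lo2[i] > hi2[2]) continue;
    int a = F1(i, 0), b = F1(i, 1), c = F1(i, 2);
    double t0[3] = {V1(a, 0), V1(a, 1), V1(a, 2)};
    double t1[3] = {V1(b, 0), V1(b, 1), V1(b, 2)};
    double t2[3] = {V1(c, 0), V1(c, 1), V1(c, 2)};
    for (int j = 0; j < n2; ++j) {
      if (B1.hi0[i] < B2.lo0[j] || B2.hi0[j] < B1.lo0[i] ||
          B1.hi1[i] < B2.lo1[j] || B2.hi1[j] < B1.lo1[i] ||
          B1.hi2[i] < B2.lo2[j] || B2.hi2[j] < B1.lo2[i]) continue;
      int d = F2(j, 0), e = F2(j, 1), f = F2(j, 2);
      double u0[3] = {V2(d, 0), V2(d, 1), V2(d, 2)};
      double u1[3] = {V2(e, 0), V2(e, 1), V2(e, 2)};
      double u2[3] = {V2(f, 0), V2(f, 1), V2(f, 2)};
      if (tri_tri_intersect(t0, t1, t2, u0, u1, u2)) return true;
    }
  }

  // full engulfment: no surface crossing but one centroid inside the other
  double p1[3] = {c1[0], c1[1], c1[2]};
  double p2[3] = {c2[0], c2[1], c2[2]};
  if (point_in_mesh_impl(p1, V2, F2)) return true;
  if (point_in_mesh_impl(p2, V1, F1)) return true;
  return false;
}
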