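// Triangle-mesh contact kernels: exact triangle-triangle intersection
// (Moller 1997), closest-point distances, point-in-mesh parity test and
// ray casting. These back detect_collision() and compute_entry_point().

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>

using namespace Rcpp;

typedef double Vec3[3];

static inline void sub(const double* a, const double* b, double* r) {
  r[0] = a[0] - b[0]; r[1] = a[1] - b[1]; r[2] = a[2] - b[2];
}
static inline void cross(const double* a, const double* b, double* r) {
  r[0] = a[1] * b[2] - a[2] * b[1];
  r[1] = a[2] * b[0] - a[0] * b[2];
  r[2] = a[0] * b[1] - a[1] * b[0];
}
static inline double dot(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
static inline double norm2(const double* a) { return dot(a, a); }

// ---------------- Moller triangle-triangle intersection -----------------

static inline void isect2(const double* VTX0, const double* VTX1,
                          const double* VTX2, double VV0, double VV1,
                          double VV2, double D0, double D1, double D2,
                          double* isect0, double* isect1) {
  double tmp = D0 / (D0 - D1);
  *isect0 = VV0 + (VV1 - VV0) * tmp;
  tmp = D0 / (D0 - D2);
  *isect1 = VV0 + (VV2 - VV0) * tmp;
}

static bool compute_intervals(const double* VERT0, const double* VERT1,
                              const double* VERT2, double VV0, double VV1,
                              double VV2, double D0, double D1, double D2,
                              double D0D1, double D0D2,
                              double* isect0, double* isect1,
                              bool* coplanar) {
  *coplanar = false;
  if (D0D1 > 0.0) {
    isect2(VERT2, VERT0, VERT1, VV2, VV0, VV1, D2, D0, D1, isect0, isect1);
  } else if (D0D2 > 0.0) {
    isect2(VERT1, VERT0, VERT2, VV1, VV0, VV2, D1, D0, D2, isect0, isect1);
  } else if (D1 * D2 > 0.0 || D0 != 0.0) {
    isect2(VERT0, VERT1, VERT2, VV0, VV1, VV2, D0, D1, D2, isect0, isect1);
  } else if (D1 != 0.0) {
    isect2(VERT1, VERT0, VERT2, VV1, VV0, VV2, D1, D0, D2, isect0, isect1);
  } else if (D2 != 0.0) {
    isect2(VERT2, VERT0, VERT1, VV2, VV0, VV1, D2, D0, D1, isect0, isect1);
  } else {
    *coplanar = true;
    return false;
  }
  return true;
}

static bool edge_edge_test(const double* V0, const double* U0,
                           const double* U1, int i0, int i1,
                           double Ax, double Ay) {
  double Bx = U0[i0] - U1[i0];
  double By = U0[i1] - U1[i1];
  double Cx = V0[i0] - U0[i0];
  double Cy = V0[i1] - U0[i1];
  double f = Ay * Bx - Ax * By;
  double d = By * Cx - Bx * Cy;
  if ((f > 0 && d >= 0 && d <= f) || (f < 0 && d <= 0 && d >= f)) {
    double e = Ax * Cy - Ay * Cx;
    if (f > 0) { if (e >= 0 && e <= f) return true; }
    else       { if (e <= 0 && e >= f) return true; }
  }
  return false;
}

static bool edge_against_tri_edges(const double* V0, const double* V1,
                                   const double* U0, const double* U1,
                                   const double* U2, int i0, int i1) {
  double Ax = V1[i0] - V0[i0];
  double Ay = V1[i1] - V0[i1];
  if (edge_edge_test(V0, U0, U1, i0, i1, Ax, Ay)) return true;
  if (edge_edge_test(V0, U1, U2, i0, i1, Ax, Ay)) return true;
  if (edge_edge_test(V0, U2, U0, i0, i1, Ax, Ay)) return true;
  return false;
}

static bool point_in_tri(const double* V0, const double* U0,
                         const double* U1, const double* U2,
                         int i0, int i1) {
  double a, b, c, d0, d1, d2;
  a = U1[i1] - U0[i1];
  b = -(U1[i0] - U0[i0]);
  c = -a * U0[i0] - b * U0[i1];
  d0 = a * V0[i0] + b * V0[i1] + c;

  a = U2[i1] - U1[i1];
  b = -(U2[i0] - U1[i0]);
  c = -a * U1[i0] - b * U1[i1];
  d1 = a * V0[i0] + b * V0[i1] + c;

  a = U0[i1] - U2[i1];
  b = -(U0[i0] - U2[i0]);
  c = -a * U2[i0] - b * U2[i1];
  d2 = a * V0[i0] + b * V0[i1] + c;

  return (d0 * d1 > 0.0 && d0 * d2 > 0.0);
}

static bool coplanar_tri_tri(const double* N, const double* V0,
                             const double* V1, const double* V2,
                             const double* U0, const double* U1,
                             const double* U2) {
  double A[3];
  int i0, i1;
  A[0] = std::fabs(N[0]); A[1] = std::fabs(N[1]); A[2] = std::fabs(N[2]);
  if (A[0] > A[1]) {
    if (A[0] > A[2]) { i0 = 1; i1 = 2; }
    else             { i0 = 0; i1 = 1; }
  } else {
    if (A[2] > A[1]) { i0 = 0; i1 = 1; }
    else             { i0 = 0; i1 = 2; }
  }
  if (edge_against_tri_edges(V0, V1, U0, U1, U2, i0, i1)) return true;
  if (edge_against_tri_edges(V1, V2, U0, U1, U2, i0, i1)) return true;
  if (edge_against_tri_edges(V2, V0, U0, U1, U2, i0, i1)) return true;
  if (point_in_tri(V0, U0, U1, U2, i0, i1)) return true;
  if (point_in_tri(U0, V0, V1, V2, i0, i1)) return true;
  return false;
}

static bool tri_tri_intersect(const double* V0, const double* V1,
                              const double* V2, const double* U0,
                              const double* U1, const double* U2) {
  double E1[3], E2[3], N1[3], N2[3], D[3];
  double d1, d2, du0, du1, du2, dv0, dv1, dv2;
  double isect1[2], isect2v[2];
  double du0du1, du0du2, dv0dv1, dv0dv2;
  bool coplanar = false;

  sub(V1, V0, E1); sub(V2, V0, E2);
  cross(E1, E2, N1);
  d1 = -dot(N1, V0);
  du0 = dot(N1, U0) + d1;
  du1 = dot(N1, U1) + d1;
  du2 = dot(N1, U2) + d1;
  du0du1 = du0 * du1; du0du2 = du0 * du2;
  if (du0du1 > 0.0 && du0du2 > 0.0) return false;

  sub(U1, U0, E1); sub(U2, U0, E2);
  cross(E1, E2, N2);
  d2 = -dot(N2, U0);
  dv0 = dot(N2, V0) + d2;
  dv1 = dot(N2, V1) + d2;
  dv2 = dot(N2, V2) + d2;
  dv0dv1 = dv0 * dv1; dv0dv2 = dv0 * dv2;
  if (dv0dv1 > 0.0 && dv0dv2 > 0.0) return false;

  cross(N1, N2, D);
  double max = std::fabs(D[0]);
  int index = 0;
  double bb = std::fabs(D[1]), cc = std::fabs(D[2]);
  if (bb > max) { max = bb; index = 1; }
  if (cc > max) { max = cc; index = 2; }
  double vp0 = V0[index], vp1 = V1[index], vp2 = V2[index];
  double up0 = U0[index], up1 = U1[index], up2 = U2[index];

  if (!compute_intervals(V0, V1, V2, vp0, vp1, vp2, dv0, dv1, dv2,
                         dv0dv1, dv0dv2, &isect1[0], &isect1[1], &coplanar))
    return coplanar_tri_tri(N1, V0, V1, V2, U0, U1, U2);
  if (!compute_intervals(U0, U1, U2, up0, up1, up2, du0, du1, du2,
                         du0du1, du0du2, &isect2v[0], &isect2v[1], &coplanar))
    return coplanar_tri_tri(N1, V0, V1, V2, U0, U1, U2);

  if (isect1[0] > isect1[1]) std::swap(isect1[0], isect1[1]);
  if (isect2v[0] > isect2v[1]) std::swap(isect2v[0], isect2v[1]);
  if (isect1[1] < isect2v[0] || isect2v[1] < isect1[0]) return false;
  return true;
}

// ---------------- closest-point distances --------------------------------

// closest point on triangle ABC to P (Ericson, Real-Time Collision Detection)
static void closest_pt_triangle(const double* p, const double* a,
                                const double* b, const double* c,
                                double* out) {
  double ab[3], ac[3], ap[3];
  sub(b, a, ab); sub(c, a, ac); sub(p, a, ap);
  double d1 = dot(ab, ap), d2 = dot(ac, ap);
  if (d1 <= 0.0 && d2 <= 0.0) { out[0]=a[0]; out[1]=a[1]; out[2]=a[2]; return; }
  double bp[3];
  sub(p, b, bp);
  double d3 = dot(ab, bp), d4 = dot(ac, bp);
  if (d3 >= 0.0 && d4 <= d3) { out[0]=b[0]; out[1]=b[1]; out[2]=b[2]; return; }
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    out[0] = a[0] + v * ab[0]; out[1] = a[1] + v * ab[1];
    out[2] = a[2] + v * ab[2];
    return;
  }
  double cp[3];
  sub(p, c, cp);
  double d5 = dot(ab, cp), d6 = dot(ac, cp);
  if (d6 >= 0.0 && d5 <= d6) { out[0]=c[0]; out[1]=c[1]; out[2]=c[2]; return; }
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    out[0] = a[0] + w * ac[0]; out[1] = a[1] + w * ac[1];
    out[2] = a[2] + w * ac[2];
    return;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    out[0] = b[0] + w * (c[0] - b[0]);
    out[1] = b[1] + w * (c[1] - b[1]);
    out[2] = b[2] + w * (c[2] - b[2]);
    return;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  out[0] = a[0] + ab[0] * v + ac[0] * w;
  out[1] = a[1] + ab[1] * v + ac[1] * w;
  out[2] = a[2] + ab[2] * v + ac[2] * w;
}

static double pt_tri_dist2(const double* p, const double* a,
                           const double* b, const double* c) {
  double q[3], d[3];
  closest_pt_triangle(p, a, b, c, q);
  sub(p, q, d);
  return norm2(d);
}

// segment-segment squared distance (Ericson)
static double seg_seg_dist2(const double* p1, const double* q1,
                            const double* p2, const double* q2) {
  double d1[3], d2[3], r[3];
  sub(q1, p1, d1); sub(q2, p2, d2); sub(p1, p2, r);
  double a = norm2(d1), e = norm2(d2), f = dot(d2, r);
  double s = 0.0, t = 0.0;
  const double EPS = 1e-14;
  if (a <= EPS && e <= EPS) {
    return norm2(r);
  }
  if (a <= EPS) {
    t = f / e; t = std::min(std::max(t, 0.0), 1.0);
  } else {
    double c = dot(d1, r);
    if (e <= EPS) {
      s = std::min(std::max(-c / a, 0.0), 1.0);
    } else {
      double b = dot(d1, d2);
      double denom = a * e - b * b;
      if (denom > EPS) s = std::min(std::max((b * f - c * e) / denom, 0.0), 1.0);
      t = (b * s + f) / e;
      if (t < 0.0) { t = 0.0; s = std::min(std::max(-c / a, 0.0), 1.0); }
      else if (t > 1.0) { t = 1.0; s = std::min(std::max((b - c) / a, 0.0), 1.0); }
    }
  }
  double c1[3], c2[3], d[3];
  for (int i = 0; i < 3; ++i) {
    c1[i] = p1[i] + d1[i] * s;
    c2[i] = p2[i] + d2[i] * t;
  }
  sub(c1, c2, d);
  return norm2(d);
}

static double tri_tri_dist2(const double* V0, const double* V1,
                            const double* V2, const double* U0,
                            const double* U1, const double* U2) {
  double best = std::numeric_limits<double>::infinity();
  best = std::min(best, pt_tri_dist2(V0, U0, U1, U2));
  best = std::min(best, pt_tri_dist2(V1, U0, U1, U2));
  best = std::min(best, pt_tri_dist2(V2, U0, U1, U2));
  best = std::min(best, pt_tri_dist2(U0, V0, V1, V2));
  best = std::min(best, pt_tri_dist2(U1, V0, V1, V2));
  best = std::min(best, pt_tri_dist2(U2, V0, V1, V2));
  const double* ea[3][2] = {{V0, V1}, {V1, V2}, {V2, V0}};
  const double* eb[3][2] = {{U0, U1}, {U1, U2}, {U2, U0}};
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j)
      best = std::min(best, seg_seg_dist2(ea[i][0], ea[i][1],
                                          eb[j][0], eb[j][1]));
  return best;
}

// ---------------- mesh helpers -------------------------------------------

struct TriSet {
  const double* V;   // nv x 3, column-major from R
  int nv;
  const int* F;      // nf x 3 (1-based), column-major
  int nf;
  std::vector<double> lo, hi; // per-tri AABB, 3 * nf
  void build(const NumericMatrix& Vm, const IntegerMatrix& Fm) {
    V = Vm.begin(); nv = Vm.nrow();
    F = Fm.begin(); nf = Fm.nrow();
    lo.assign(3 * nf, 0.0); hi.assign(3 * nf, 0.0);
    for (int i = 0; i < nf; ++i) {
      for (int d = 0; d < 3; ++d) {
        double a = vtx(F[i] - 1)[d];
        double b = vtx(F[i + nf] - 1)[d];
        double c = vtx(F[i + 2 * nf] - 1)[d];
        lo[3 * i + d] = std::min(a, std::min(b, c));
        hi[3 * i + d] = std::max(a, std::max(b, c));
      }
    }
  }
  // gather vertex into contiguous storage
  std::vector<double> buf;
  const double* vtx(int i) {
    // column-major: V[i], V[i+nv], V[i+2nv]; need contiguous triple
    thread_local double tmp[3];
    tmp[0] = V[i]; tmp[1] = V[i + nv]; tmp[2] = V[i + 2 * nv];
    return tmp;
  }
  void tri(int i, double* a, double* b, double* c) {
    int i0 = F[i] - 1, i1 = F[i + nf] - 1, i2 = F[i + 2 * nf] - 1;
    a[0] = V[i0]; a[1] = V[i0 + nv]; a[2] = V[i0 + 2 * nv];
    b[0] = V[i1]; b[1] = V[i1 + nv]; b[2] = V[i1 + 2 * nv];
    c[0] = V[i2]; c[1] = V[i2 + nv]; c[2] = V[i2 + 2 * nv];
  }
};

static double bbox_dist2(const TriSet& A, int i, const TriSet& B, int j,
                         double pad) {
  double d2 = 0.0;
  for (int d = 0; d < 3; ++d) {
    double gap = std::max(A.lo[3 * i + d] - B.hi[3 * j + d],
                          B.lo[3 * j + d] - A.hi[3 * i + d]);
    gap -= pad;
    if (gap > 0) d2 += gap * gap;
  }
  return d2;
}

// parity-based point-in-mesh (closed mesh); fixed irrational-ish direction
static bool point_in_mesh(const double* p, TriSet& M) {
  const double dir[3] = {0.5358979321, 0.2817693241, 0.7972356812};
  int crossings = 0;
  double a[3], b[3], c[3];
  for (int i = 0; i < M.nf; ++i) {
    M.tri(i, a, b, c);
    // Moller-Trumbore
    double e1[3], e2[3], pv[3], tv[3], qv[3];
    sub(b, a, e1); sub(c, a, e2);
    cross(dir, e2, pv);
    double det = dot(e1, pv);
    if (std::fabs(det) < 1e-14) continue;
    double inv = 1.0 / det;
    sub(p, a, tv);
    double u = dot(tv, pv) * inv;
    if (u < 0.0 || u > 1.0) continue;
    cross(tv, e1, qv);
    double v = dot(dir, qv) * inv;
    if (v < 0.0 || u + v > 1.0) continue;
    double t = dot(e2, qv) * inv;
    if (t > 1e-12) ++crossings;
  }
  return (crossings % 2) == 1;
}

// distance from point to whole mesh
static double point_mesh_dist(const double* p, TriSet& M) {
  double best = std::numeric_limits<double>::infinity();
  double a[3], b[3], c[3];
  for (int i = 0; i < M.nf; ++i) {
    // bbox lower bound
    double d2 = 0.0;
    for (int d = 0; d < 3; ++d) {
      double gap = std::max(M.lo[3 * i + d] - p[d], p[d] - M.hi[3 * i + d]);
      if (gap > 0) d2 += gap * gap;
    }
    if (d2 >= best) continue;
    M.tri(i, a, b, c);
    best = std::min(best, pt_tri_dist2(p, a, b, c));
  }
  return std::sqrt(best);
}

// [[Rcpp::export]]
List mesh_contact_cpp(NumericMatrix VA, IntegerMatrix FA,
                      NumericMatrix VB, IntegerMatrix FB,
                      double tolerance, bool closed_test) {
  TriSet A, B;
  A.build(VA, FA);
  B.build(VB, FB);
  double a0[3], a1[3], a2[3], b0[3], b1[3], b2[3];

  // 1. intersecting triangle pairs (AABB broad phase, exact narrow phase)
  std::vector<int> hitA, hitB;
  for (int i = 0; i < A.nf; ++i) {
    for (int j = 0; j < B.nf; ++j) {
      if (bbox_dist2(A, i, B, j, 0.0) > 0.0) continue;
      A.tri(i, a0, a1, a2);
      B.tri(j, b0, b1, b2);
      if (tri_tri_intersect(a0, a1, a2, b0, b1, b2)) {
        hitA.push_back(i + 1);
        hitB.push_back(j + 1);
      }
    }
  }

  bool intersects = !hitA.empty();
  bool contained = false;
  double clearance;

  if (intersects || !closed_test) {
    // skip containment when surfaces cross (or caller says meshes open)
  } else {
    double p[3];
    p[0] = VA(0, 0); p[1] = VA(0, 1); p[2] = VA(0, 2);
    if (point_in_mesh(p, B)) contained = true;
    if (!contained) {
      p[0] = VB(0, 0); p[1] = VB(0, 1); p[2] = VB(0, 2);
      if (point_in_mesh(p, A)) contained = true;
    }
  }

  if (intersects || contained) {
    // penetration depth: deepest vertex of one mesh inside the other
    double depth = 0.0;
    if (closed_test) {
      double p[3];
      for (int i = 0; i < A.nv; ++i) {
        p[0] = VA(i, 0); p[1] = VA(i, 1); p[2] = VA(i, 2);
        if (point_in_mesh(p, B))
          depth = std::max(depth, point_mesh_dist(p, B));
      }
      for (int i = 0; i < B.nv; ++i) {
        p[0] = VB(i, 0); p[1] = VB(i, 1); p[2] = VB(i, 2);
        if (point_in_mesh(p, A))
          depth = std::max(depth, point_mesh_dist(p, A));
      }
    }
    clearance = -depth;
    if (contained && hitA.empty()) {
      // full containment: report every face of the contained mesh
      for (int i = 0; i < A.nf; ++i) hitA.push_back(i + 1);
      for (int j = 0; j < B.nf; ++j) hitB.push_back(j + 1);
    }
    return List::create(_["collides"] = true,
                        _["clearance"] = clearance,
                        _["faces_a"] = wrap(hitA),
                        _["faces_b"] = wrap(hitB));
  }

  // 2. separated: minimal surface-surface distance with bbox pruning
  double best2 = std::numeric_limits<double>::infinity();
  for (int i = 0; i < A.nf; ++i) {
    for (int j = 0; j < B.nf; ++j) {
      if (bbox_dist2(A, i, B, j, 0.0) >= best2) continue;
      A.tri(i, a0, a1, a2);
      B.tri(j, b0, b1, b2);
      best2 = std::min(best2, tri_tri_dist2(a0, a1, a2, b0, b1, b2));
    }
  }
  clearance = std::sqrt(best2);
  bool collides = clearance <= tolerance;
  if (collides) {
    // contact faces = pairs within tolerance
    double tol2 = tolerance * tolerance * (1.0 + 1e-9) + 1e-18;
    for (int i = 0; i < A.nf; ++i) {
      for (int j = 0; j < B.nf; ++j) {
        if (bbox_dist2(A, i, B, j, tolerance) > 0.0) continue;
        A.tri(i, a0, a1, a2);
        B.tri(j, b0, b1, b2);
        if (tri_tri_dist2(a0, a1, a2, b0, b1, b2) <= tol2) {
          hitA.push_back(i + 1);
          hitB.push_back(j + 1);
        }
      }
    }
  }
  return List::create(_["collides"] = collides,
                      _["clearance"] = clearance,
                      _["faces_a"] = wrap(hitA),
                      _["faces_b"] = wrap(hitB));
}

// [[Rcpp::export]]
List ray_mesh_cpp(NumericMatrix V, IntegerMatrix F,
                  NumericVector origin, NumericVector direction) {
  TriSet M;
  M.build(V, F);
  double o[3] = {origin[0], origin[1], origin[2]};
  double dir[3] = {direction[0], direction[1], direction[2]};
  std::vector<double> ts;
  std::vector<int> faces;
  double a[3], b[3], c[3];
  for (int i = 0; i < M.nf; ++i) {
    M.tri(i, a, b, c);
    double e1[3], e2[3], pv[3], tv[3], qv[3];
    sub(b, a, e1); sub(c, a, e2);
    cross(dir, e2, pv);
    double det = dot(e1, pv);
    if (std::fabs(det) < 1e-14) continue;
    double inv = 1.0 / det;
    sub(o, a, tv);
    double u = dot(tv, pv) * inv;
    if (u < -1e-9 || u > 1.0 + 1e-9) continue;
    cross(tv, e1, qv);
    double v = dot(dir, qv) * inv;
    if (v < -1e-9 || u + v > 1.0 + 1e-9) continue;
    ts.push_back(dot(e2, qv) * inv);
    faces.push_back(i + 1);
  }
  return List::create(_["t"] = wrap(ts), _["face"] = wrap(faces));
}

// [[Rcpp::export]]
NumericVector points_mesh_distance_cpp(NumericMatrix P, NumericMatrix V,
                                       IntegerMatrix F) {
  TriSet M;
  M.build(V, F);
  int n = P.nrow();
  NumericVector out(n);
  double p[3];
  for (int i = 0; i < n; ++i) {
    p[0] = P(i, 0); p[1] = P(i, 1); p[2] = P(i, 2);
    out[i] = point_mesh_dist(p, M);
  }
  return out;
}
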