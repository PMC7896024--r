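// Compiled kernels: rigid base-pair step compounding, discrete Gauss
// integrals (writhe, linking number), ribbon twist, fragment-length
// distributions, fused fiber energies and the Metropolis sampler.
//
// Conventions: 3x3 rotations are column-major double[9] (column c, row r at
// [3*c + r]); frames are right-handed with columns (short axis, long axis,
// normal/tangent).  Angles cross the R boundary in degrees, lengths in nm.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static const double D2R = M_PI / 180.0;

// ---------------------------------------------------------------- 3x3 algebra

static inline void matmul(const double* A, const double* B, double* C) {
  for (int c = 0; c < 3; ++c)
    for (int r = 0; r < 3; ++r)
      C[3 * c + r] = A[r] * B[3 * c] + A[3 + r] * B[3 * c + 1] + A[6 + r] * B[3 * c + 2];
}
static inline void matvec(const double* A, const double* v, double* w) {
  for (int r = 0; r < 3; ++r) w[r] = A[r] * v[0] + A[3 + r] * v[1] + A[6 + r] * v[2];
}
// w = A^T v
static inline void mattvec(const double* A, const double* v, double* w) {
  for (int c = 0; c < 3; ++c) w[c] = A[3 * c] * v[0] + A[3 * c + 1] * v[1] + A[3 * c + 2] * v[2];
}
static inline void rotz(double a, double* R) {
  double c = std::cos(a), s = std::sin(a);
  R[0] = c; R[1] = s; R[2] = 0; R[3] = -s; R[4] = c; R[5] = 0; R[6] = 0; R[7] = 0; R[8] = 1;
}
static inline void roty(double a, double* R) {
  double c = std::cos(a), s = std::sin(a);
  R[0] = c; R[1] = 0; R[2] = -s; R[3] = 0; R[4] = 1; R[5] = 0; R[6] = s; R[7] = 0; R[8] = c;
}
static inline void cross3(const double* a, const double* b, double* c) {
  c[0] = a[1] * b[2] - a[2] * b[1];
  c[1] = a[2] * b[0] - a[0] * b[2];
  c[2] = a[0] * b[1] - a[1] * b[0];
}
static inline double dot3(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
static inline double norm3(const double* a) { return std::sqrt(dot3(a, a)); }

// Gram-Schmidt re-orthogonalization, preserving the z (tangent) column.
static inline void reorthogonalize(double* R) {
  double z[3] = {R[6], R[7], R[8]};
  double nz = norm3(z);
  for (int k = 0; k < 3; ++k) z[k] /= nz;
  double x[3] = {R[0], R[1], R[2]};
  double d = dot3(x, z);
  for (int k = 0; k < 3; ++k) x[k] -= d * z[k];
  double nx = norm3(x);
  for (int k = 0; k < 3; ++k) x[k] /= nx;
  double y[3];
  cross3(z, x, y);
  R[0] = x[0]; R[1] = x[1]; R[2] = x[2];
  R[3] = y[0]; R[4] = y[1]; R[5] = y[2];
  R[6] = z[0]; R[7] = z[1]; R[8] = z[2];
}

// ------------------------------------------------- base-pair step compounding
//
// Mid-step convention: with bend magnitude Gamma = sqrt(tilt^2 + roll^2) and
// bend phase phi = atan2(tilt, roll),
//   A   = Rz(Tw/2 - phi) Ry(Gamma)   Rz(Tw/2 + phi)      (frame i -> i+1)
//   Rm  = Rz(Tw/2 - phi) Ry(Gamma/2) Rz(phi)             (mid-step frame)
//   o'  = o + R_i Rm (shift, slide, rise)

static void step_transform_raw(const double* s, double* A, double* u) {
  double tilt = s[0] * D2R, roll = s[1] * D2R, tw = s[2] * D2R;
  double G = std::sqrt(tilt * tilt + roll * roll);
  double phi = (G > 1e-14) ? std::atan2(tilt, roll) : 0.0;
  double R1[9], R2[9], R3[9], T[9];
  rotz(tw / 2 - phi, R1);
  roty(G, R2);
  rotz(tw / 2 + phi, R3);
  matmul(R1, R2, T);
  matmul(T, R3, A);
  double Rm[9];
  roty(G / 2, R2);
  rotz(phi, R3);
  matmul(R1, R2, T);
  matmul(T, R3, Rm);
  matvec(Rm, s + 3, u);
}

static void extract_step_raw(const double* R0, const double* o0,
                             const double* R1, const double* o1, double* s) {
  double A[9];
  for (int c = 0; c < 3; ++c) {
    double col[3] = {R1[3 * c], R1[3 * c + 1], R1[3 * c + 2]};
    double w[3];
    mattvec(R0, col, w);
    A[3 * c] = w[0]; A[3 * c + 1] = w[1]; A[3 * c + 2] = w[2];
  }
  double cG = A[8];
  if (cG > 1) cG = 1;
  if (cG < -1) cG = -1;
  double G = std::acos(cG), tw, phi;
  if (G < 1e-9) {
    tw = std::atan2(A[1], A[0]);
    phi = 0;
    G = 0;
  } else {
    double a = std::atan2(A[7], A[6]);
    double b = std::atan2(A[5], -A[2]);
    tw = a + b;
    phi = 0.5 * (b - a);
    // keep twist in (-pi, pi]; the gauge shift flips the bend phase by pi
    if (tw > M_PI)  { tw -= 2 * M_PI; phi += M_PI; }
    if (tw <= -M_PI){ tw += 2 * M_PI; phi += M_PI; }
  }
  s[0] = G * std::sin(phi) / D2R;
  s[1] = G * std::cos(phi) / D2R;
  s[2] = tw / D2R;
  double R1z[9], R2y[9], R3z[9], T[9], Rm[9], Rmg[9];
  rotz(tw / 2 - phi, R1z);
  roty(G / 2, R2y);
  rotz(phi, R3z);
  matmul(R1z, R2y, T);
  matmul(T, R3z, Rm);
  matmul(R0, Rm, Rmg);
  double d[3] = {o1[0] - o0[0], o1[1] - o0[1], o1[2] - o0[2]}, dl[3];
  mattvec(Rmg, d, dl);
  s[3] = dl[0]; s[4] = dl[1]; s[5] = dl[2];
}

// [[Rcpp::export]]
List cpp_step_transform(NumericVector step) {
  double A[9], u[3];
  step_transform_raw(REAL(step), A, u);
  NumericMatrix R(3, 3);
  for (int c = 0; c < 3; ++c)
    for (int r = 0; r < 3; ++r) R(r, c) = A[3 * c + r];
  NumericVector t(3);
  t[0] = u[0]; t[1] = u[1]; t[2] = u[2];
  return List::create(_["rotation"] = R, _["translation"] = t);
}

// [[Rcpp::export]]
List cpp_build_chain(NumericVector origin0, NumericMatrix axes0, NumericMatrix steps) {
  int n = steps.nrow();
  NumericMatrix origins(n + 1, 3), axes(n + 1, 9);
  double R[9], o[3];
  for (int c = 0; c < 3; ++c)
    for (int r = 0; r < 3; ++r) R[3 * c + r] = axes0(r, c);
  for (int k = 0; k < 3; ++k) o[k] = origin0[k];
  for (int k = 0; k < 3; ++k) origins(0, k) = o[k];
  for (int k = 0; k < 9; ++k) axes(0, k) = R[k];
  double s[6], A[9], u[3], Rn[9], w[3];
  for (int i = 0; i < n; ++i) {
    for (int k = 0; k < 6; ++k) s[k] = steps(i, k);
    step_transform_raw(s, A, u);
    matvec(R, u, w);
    for (int k = 0; k < 3; ++k) o[k] += w[k];
    matmul(R, A, Rn);
    reorthogonalize(Rn);
    for (int k = 0; k < 9; ++k) R[k] = Rn[k];
    for (int k = 0; k < 3; ++k) origins(i + 1, k) = o[k];
    for (int k = 0; k < 9; ++k) axes(i + 1, k) = R[k];
  }
  return List::create(_["origins"] = origins, _["axes"] = axes);
}

// [[Rcpp::export]]
NumericMatrix cpp_extract_steps(NumericMatrix origins, NumericMatrix axes) {
  int n = origins.nrow();
  NumericMatrix steps(n - 1, 6);
  double s[6];
  for (int i = 0; i + 1 < n; ++i) {
    double R0[9], R1[9], o0[3], o1[3];
    for (int k = 0; k < 9; ++k) { R0[k] = axes(i, k); R1[k] = axes(i + 1, k); }
    for (int k = 0; k < 3; ++k) { o0[k] = origins(i, k); o1[k] = origins(i + 1, k); }
    extract_step_raw(R0, o0, R1, o1, s);
    for (int k = 0; k < 6; ++k) steps(i, k) = s[k];
  }
  return steps;
}

// ------------------------------------------------------------- ribbon twist
//
// Exact twist of the material frame about the tangent: parallel-transport the
// x axis between successive tangents and measure the residual rotation.

// [[Rcpp::export]]
double cpp_ribbon_twist(NumericMatrix axes, bool closed) {
  int n = axes.nrow();
  int nsteps = closed ? n : (n - 1);
  double total = 0.0;
  for (int i = 0; i < nsteps; ++i) {
    int j = (i + 1) % n;
    double z0[3] = {axes(i, 6), axes(i, 7), axes(i, 8)};
    double z1[3] = {axes(j, 6), axes(j, 7), axes(j, 8)};
    double x0[3] = {axes(i, 0), axes(i, 1), axes(i, 2)};
    double x1[3] = {axes(j, 0), axes(j, 1), axes(j, 2)};
    double k[3];
    cross3(z0, z1, k);
    double sk = norm3(k), ck = dot3(z0, z1);
    double xpt[3];
    if (sk < 1e-13) {
      if (ck < 0) stop("antiparallel consecutive tangents: twist undefined");
      for (int t = 0; t < 3; ++t) xpt[t] = x0[t];
    } else {
      double ang = std::atan2(sk, ck);
      double ax[3] = {k[0] / sk, k[1] / sk, k[2] / sk};
      // Rodrigues rotation of x0 about ax by ang
      double c = std::cos(ang), s = std::sin(ang);
      double axx[3];
      cross3(ax, x0, axx);
      double ad = dot3(ax, x0);
      for (int t = 0; t < 3; ++t)
        xpt[t] = x0[t] * c + axx[t] * s + ax[t] * ad * (1 - c);
    }
    double cr[3];
    cross3(xpt, x1, cr);
    total += std::atan2(dot3(cr, z1), dot3(xpt, x1));
  }
  return total / (2 * M_PI);
}

// --------------------------------------------------------- Gauss integrals

// Minimum distance between segments [p1,p2] and [p3,p4].
static double seg_seg_dist(const double* p1, const double* p2,
                           const double* p3, const double* p4) {
  double d1[3], d2[3], r[3];
  for (int k = 0; k < 3; ++k) {
    d1[k] = p2[k] - p1[k];
    d2[k] = p4[k] - p3[k];
    r[k] = p1[k] - p3[k];
  }
  double a = dot3(d1, d1), e = dot3(d2, d2), f = dot3(d2, r);
  double s = 0, t = 0;
  if (a <= 1e-18 && e <= 1e-18) {
    // both degenerate points
  } else if (a <= 1e-18) {
    t = f / e;
    t = std::max(0.0, std::min(1.0, t));
  } else {
    double c = dot3(d1, r);
    if (e <= 1e-18) {
      s = std::max(0.0, std::min(1.0, -c / a));
    } else {
      double b = dot3(d1, d2);
      double denom = a * e - b * b;
      if (denom > 1e-18) s = std::max(0.0, std::min(1.0, (b * f - c * e) / denom));
      t = (b * s + f) / e;
      if (t < 0) { t = 0; s = std::max(0.0, std::min(1.0, -c / a)); }
      else if (t > 1) { t = 1; s = std::max(0.0, std::min(1.0, (b - c) / a)); }
    }
  }
  double diff[3];
  for (int k = 0; k < 3; ++k) diff[k] = (p1[k] + s * d1[k]) - (p3[k] + t * d2[k]);
  return norm3(diff);
}

// Exact solid angle of a segment pair (Klenin & Langowski, method 1a).
static inline double pair_solid_angle(const double* p1, const double* p2,
                                      const double* p3, const double* p4,
                                      bool* degenerate) {
  double r12[3], r13[3], r14[3], r23[3], r24[3], r34[3];
  for (int k = 0; k < 3; ++k) {
    r12[k] = p2[k] - p1[k];
    r13[k] = p3[k] - p1[k];
    r14[k] = p4[k] - p1[k];
    r23[k] = p3[k] - p2[k];
    r24[k] = p4[k] - p2[k];
    r34[k] = p4[k] - p3[k];
  }
  double n1[3], n2[3], n3[3], n4[3];
  cross3(r13, r14, n1);
  cross3(r14, r24, n2);
  cross3(r24, r23, n3);
  cross3(r23, r13, n4);
  double l1 = norm3(n1), l2 = norm3(n2), l3 = norm3(n3), l4 = norm3(n4);
  if (l1 < 1e-12 || l2 < 1e-12 || l3 < 1e-12 || l4 < 1e-12) {
    // coplanar/collinear pair: contributes 0 unless the segments actually
    // touch, which makes the Gauss integrand singular
    if (seg_seg_dist(p1, p2, p3, p4) < 1e-9) *degenerate = true;
    return 0.0;
  }
  for (int k = 0; k < 3; ++k) {
    n1[k] /= l1; n2[k] /= l2; n3[k] /= l3; n4[k] /= l4;
  }
  double a1 = dot3(n1, n2), a2 = dot3(n2, n3), a3 = dot3(n3, n4), a4 = dot3(n4, n1);
  if (a1 > 1) a1 = 1; if (a1 < -1) a1 = -1;
  if (a2 > 1) a2 = 1; if (a2 < -1) a2 = -1;
  if (a3 > 1) a3 = 1; if (a3 < -1) a3 = -1;
  if (a4 > 1) a4 = 1; if (a4 < -1) a4 = -1;
  double S = std::asin(a1) + std::asin(a2) + std::asin(a3) + std::asin(a4);
  double cr[3];
  cross3(r34, r12, cr);
  return (dot3(cr, r13) > 0) ? S : -S;
}

// Signed solid angle of a spherical triangle (van Oosterom & Strackee).
static inline double tri_solid_angle(const double* a, const double* b, const double* c) {
  double cx[3];
  cross3(b, c, cx);
  double num = dot3(a, cx);
  double la = norm3(a), lb = norm3(b), lc = norm3(c);
  double den = la * lb * lc + dot3(a, b) * lc + dot3(a, c) * lb + dot3(b, c) * la;
  return 2.0 * std::atan2(num, den);
}

// Same pair contribution via two spherical triangles (independent formula).
static inline double pair_solid_angle_vos(const double* p1, const double* p2,
                                          const double* p3, const double* p4) {
  double e13[3], e14[3], e24[3], e23[3];
  for (int k = 0; k < 3; ++k) {
    e13[k] = p3[k] - p1[k];
    e14[k] = p4[k] - p1[k];
    e24[k] = p4[k] - p2[k];
    e23[k] = p3[k] - p2[k];
  }
  // spherical quadrilateral e13 -> e23 -> e24 -> e14 (orientation matching
  // the arcsine formulation's sign convention)
  return -(tri_solid_angle(e13, e14, e24) + tri_solid_angle(e13, e24, e23));
}

// [[Rcpp::export]]
List cpp_writhe(NumericMatrix v, bool closed, int method) {
  int n = v.nrow();
  int nseg = closed ? n : (n - 1);
  std::vector<double> P(3 * n);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) P[3 * i + k] = v(i, k);
  bool degen = false;
  double acc = 0.0;
  for (int i = 0; i < nseg; ++i) {
    int i2 = (i + 1) % n;
    for (int j = i + 2; j < nseg; ++j) {
      if (closed && i == 0 && j == nseg - 1) continue;  // shares vertex 0
      int j2 = (j + 1) % n;
      double om;
      if (method == 2)
        om = pair_solid_angle_vos(&P[3 * i], &P[3 * i2], &P[3 * j], &P[3 * j2]);
      else
        om = pair_solid_angle(&P[3 * i], &P[3 * i2], &P[3 * j], &P[3 * j2], &degen);
      acc += om;
    }
  }
  return List::create(_["wr"] = acc / (2 * M_PI), _["degenerate"] = degen);
}

// [[Rcpp::export]]
double cpp_linking(NumericMatrix a, NumericMatrix b) {
  int na = a.nrow(), nb = b.nrow();
  bool degen = false;
  double acc = 0.0;
  for (int i = 0; i < na; ++i) {
    int i2 = (i + 1) % na;
    double p1[3] = {a(i, 0), a(i, 1), a(i, 2)};
    double p2[3] = {a(i2, 0), a(i2, 1), a(i2, 2)};
    for (int j = 0; j < nb; ++j) {
      int j2 = (j + 1) % nb;
      double p3[3] = {b(j, 0), b(j, 1), b(j, 2)};
      double p4[3] = {b(j2, 0), b(j2, 1), b(j2, 2)};
      acc += pair_solid_angle(p1, p2, p3, p4, &degen);
    }
  }
  return acc / (4 * M_PI);
}

// ------------------------------------------------------------------- FLD

// [[Rcpp::export]]
NumericVector cpp_fld(NumericMatrix origins, double lambda, int nmin, int nmax) {
  int N = origins.nrow();
  NumericVector out(nmax - nmin + 1, NA_REAL);
  for (int n = nmin; n <= nmax; ++n) {
    if (n >= N) continue;  // undefined beyond chain length
    double acc = 0.0;
    int cnt = N - n;
    for (int i = 0; i < cnt; ++i) {
      double dx = origins(i + n, 0) - origins(i, 0);
      double dy = origins(i + n, 1) - origins(i, 1);
      double dz = origins(i + n, 2) - origins(i, 2);
      acc += std::exp(-std::sqrt(dx * dx + dy * dy + dz * dz) / lambda);
    }
    out[n - nmin] = acc / cnt;
  }
  return out;
}

// ------------------------------------------------- fiber geometry + energy

struct CoreTpl {
  double exitR[9], exitT[3], center[3], axis[3];
  std::vector<double> spheres;  // k x 3, row-major triplets (local coords)
  double sphere_r;
  std::vector<double> bp_o, bp_R;  // optional full local frames
  int lncp;
};

struct EPar {
  double eq[6];
  double K[36];      // col-major 6x6
  double depth, d0, w;
  bool stack_on;
  double rcore, hh, rdna;
  bool ev_on;
  int stack_min_sep;   // smallest |i-j| entering the stacking sum
  double adj_floor;    // minimum center distance of sequence-neighbor cores
};

static CoreTpl core_from_list(List core) {
  CoreTpl c;
  NumericMatrix eR = core["exit_R"];
  NumericVector eT = core["exit_t"], ce = core["center"], ax = core["axis"];
  for (int cc = 0; cc < 3; ++cc)
    for (int r = 0; r < 3; ++r) c.exitR[3 * cc + r] = eR(r, cc);
  for (int k = 0; k < 3; ++k) {
    c.exitT[k] = eT[k];
    c.center[k] = ce[k];
    c.axis[k] = ax[k];
  }
  NumericMatrix sp = core["spheres"];
  c.spheres.resize(3 * sp.nrow());
  for (int i = 0; i < sp.nrow(); ++i)
    for (int k = 0; k < 3; ++k) c.spheres[3 * i + k] = sp(i, k);
  c.sphere_r = as<double>(core["sphere_r"]);
  c.lncp = as<int>(core["l_ncp"]);
  if (core.containsElementNamed("bp_origins")) {
    NumericMatrix bo = core["bp_origins"], ba = core["bp_axes"];
    c.bp_o.resize(3 * bo.nrow());
    c.bp_R.resize(9 * ba.nrow());
    for (int i = 0; i < bo.nrow(); ++i) {
      for (int k = 0; k < 3; ++k) c.bp_o[3 * i + k] = bo(i, k);
      for (int k = 0; k < 9; ++k) c.bp_R[9 * i + k] = ba(i, k);
    }
  }
  return c;
}

static EPar epar_from_list(List ep) {
  EPar e;
  NumericVector eq = ep["step_equilibrium"];
  NumericMatrix K = ep["step_stiffness"];
  for (int k = 0; k < 6; ++k) e.eq[k] = eq[k];
  for (int c = 0; c < 6; ++c)
    for (int r = 0; r < 6; ++r) e.K[6 * c + r] = K(r, c);
  e.depth = as<double>(ep["stacking_depth"]);
  e.d0 = as<double>(ep["stacking_distance"]);
  e.w = as<double>(ep["stacking_width"]);
  e.stack_on = as<bool>(ep["stacking"]);
  e.rcore = as<double>(ep["core_radius"]);
  e.hh = as<double>(ep["core_half_height"]);
  e.rdna = as<double>(ep["dna_radius"]);
  e.ev_on = as<bool>(ep["excluded_volume"]);
  e.stack_min_sep = ep.containsElementNamed("stack_min_sep")
    ? as<int>(ep["stack_min_sep"]) : 1;
  e.adj_floor = ep.containsElementNamed("adjacent_center_floor")
    ? as<double>(ep["adjacent_center_floor"]) : 0.0;
  return e;
}

static inline double step_energy_raw(const double* s, const EPar& e) {
  double d[6];
  for (int k = 0; k < 6; ++k) d[k] = s[k] - e.eq[k];
  double acc = 0.0;
  for (int c = 0; c < 6; ++c) {
    double kd = 0.0;
    for (int r = 0; r < 6; ++r) kd += e.K[6 * c + r] * d[r];
    acc += d[c] * kd;
  }
  return 0.5 * acc;
}

static inline double stack_pair(const double* ci, const double* ai,
                                const double* cj, const double* aj, const EPar& e) {
  double d[3] = {cj[0] - ci[0], cj[1] - ci[1], cj[2] - ci[2]};
  double dist = norm3(d);
  if (dist > e.d0 + 3 * e.w) return 0.0;
  double g = std::fabs(dot3(ai, aj));
  double x = (dist - e.d0) / e.w;
  return -e.depth * std::exp(-0.5 * x * x) * g;
}

// Geometry of one fiber realization: per-core entry frames, centers, axes,
// global EV spheres, and global linker bp positions.
struct FiberGeom {
  int n;
  std::vector<double> entR, entT;       // n x 9, n x 3
  std::vector<double> cen, ax;          // n x 3
  std::vector<double> sph;              // n * ns * 3
  std::vector<double> lpt;              // per linker: nl * npt * 3
  std::vector<double> lcen, lrad;       // linker bounding spheres
  int npt;                              // points stored per linker (= L)
};

// Build geometry from per-linker step sets. linkers: nl matrices (L+1) x 6.
static void build_geom(const std::vector<const double*>& linkers, int nsteps_per,
                       int n, const CoreTpl& core, FiberGeom& g) {
  int ns = (int)core.spheres.size() / 3;
  int nl = (int)linkers.size();
  g.n = n;
  g.npt = nsteps_per - 1;  // L free bp per linker
  g.entR.assign(9 * n, 0.0);
  g.entT.assign(3 * n, 0.0);
  g.cen.assign(3 * n, 0.0);
  g.ax.assign(3 * n, 0.0);
  g.sph.assign((size_t)3 * ns * n, 0.0);
  g.lpt.assign((size_t)3 * g.npt * nl, 0.0);
  g.lcen.assign(3 * nl, 0.0);
  g.lrad.assign(nl, 0.0);
  double R[9] = {1, 0, 0, 0, 1, 0, 0, 0, 1};
  double o[3] = {0, 0, 0};
  double A[9], u[3], w[3], Rn[9];
  for (int i = 0; i < n; ++i) {
    for (int k = 0; k < 9; ++k) g.entR[9 * i + k] = R[k];
    for (int k = 0; k < 3; ++k) g.entT[3 * i + k] = o[k];
    matvec(R, core.center, w);
    for (int k = 0; k < 3; ++k) g.cen[3 * i + k] = o[k] + w[k];
    matvec(R, core.axis, w);
    for (int k = 0; k < 3; ++k) g.ax[3 * i + k] = w[k];
    for (int s = 0; s < ns; ++s) {
      matvec(R, &core.spheres[3 * s], w);
      for (int k = 0; k < 3; ++k) g.sph[3 * (ns * i + s) + k] = o[k] + w[k];
    }
    if (i < nl) {
      // move to exit frame, then walk the linker
      double Rx[9], ox[3];
      matmul(R, core.exitR, Rx);
      matvec(R, core.exitT, w);
      for (int k = 0; k < 3; ++k) ox[k] = o[k] + w[k];
      double cmin[3] = {1e30, 1e30, 1e30}, cmax[3] = {-1e30, -1e30, -1e30};
      const double* st = linkers[i];
      for (int ksp = 0; ksp < nsteps_per; ++ksp) {
        double s6[6];
        for (int k = 0; k < 6; ++k) s6[k] = st[ksp + nsteps_per * k];  // column-major L+1 x 6
        step_transform_raw(s6, A, u);
        matvec(Rx, u, w);
        for (int k = 0; k < 3; ++k) ox[k] += w[k];
        matmul(Rx, A, Rn);
        reorthogonalize(Rn);
        for (int k = 0; k < 9; ++k) Rx[k] = Rn[k];
        if (ksp < g.npt) {
          for (int k = 0; k < 3; ++k) {
            g.lpt[3 * (g.npt * i + ksp) + k] = ox[k];
            if (ox[k] < cmin[k]) cmin[k] = ox[k];
            if (ox[k] > cmax[k]) cmax[k] = ox[k];
          }
        }
      }
      if (g.npt > 0) {
        for (int k = 0; k < 3; ++k) g.lcen[3 * i + k] = 0.5 * (cmin[k] + cmax[k]);
        double r2 = 0;
        for (int k = 0; k < 3; ++k) {
          double h = 0.5 * (cmax[k] - cmin[k]);
          r2 += h * h;
        }
        g.lrad[i] = std::sqrt(r2);
      }
      for (int k = 0; k < 9; ++k) R[k] = Rx[k];
      for (int k = 0; k < 3; ++k) o[k] = ox[k];
    }
  }
}

// Excluded-volume scan; returns soft penalty, sets violated flag.
static double ev_penalty(const FiberGeom& g, const CoreTpl& core, const EPar& e,
                         bool* violated) {
  *violated = false;
  if (!e.ev_on) return 0.0;
  double pen = 0.0;
  int ns = (int)core.spheres.size() / 3;
  int n = g.n;
  // sequence-neighbor cores: the cylinder check is waived for them (the
  // connecting linker legitimately keeps them close), but their centers may
  // not approach below the stereochemical floor
  if (e.adj_floor > 0) {
    for (int i = 0; i + 1 < n; ++i) {
      double dc[3] = {g.cen[3 * (i + 1)] - g.cen[3 * i],
                      g.cen[3 * (i + 1) + 1] - g.cen[3 * i + 1],
                      g.cen[3 * (i + 1) + 2] - g.cen[3 * i + 2]};
      double dd = norm3(dc);
      if (dd < e.adj_floor) {
        *violated = true;
        pen += (e.adj_floor - dd) * (e.adj_floor - dd);
      }
    }
  }
  // non-adjacent core pairs, sphere sets
  for (int i = 0; i + 2 < n; ++i) {
    for (int j = i + 2; j < n; ++j) {
      double dc[3] = {g.cen[3 * j] - g.cen[3 * i], g.cen[3 * j + 1] - g.cen[3 * i + 1],
                      g.cen[3 * j + 2] - g.cen[3 * i + 2]};
      double dcent = norm3(dc);
      if (dcent > 2 * (e.rcore + core.sphere_r)) continue;
      for (int a = 0; a < ns; ++a)
        for (int b = 0; b < ns; ++b) {
          const double* pa = &g.sph[3 * (ns * i + a)];
          const double* pb = &g.sph[3 * (ns * j + b)];
          double d[3] = {pb[0] - pa[0], pb[1] - pa[1], pb[2] - pa[2]};
          double dd = norm3(d);
          double lim = 2 * core.sphere_r;
          if (dd < lim) {
            *violated = true;
            pen += (lim - dd) * (lim - dd);
          }
        }
    }
  }
  // linker bp inside non-own core cylinders
  int nl = (n > 1) ? ((int)g.lrad.size()) : 0;
  for (int l = 0; l < nl; ++l) {
    for (int c = 0; c < n; ++c) {
      if (c == l || c == l + 1) continue;  // own cores
      double dc[3] = {g.lcen[3 * l] - g.cen[3 * c], g.lcen[3 * l + 1] - g.cen[3 * c + 1],
                      g.lcen[3 * l + 2] - g.cen[3 * c + 2]};
      if (norm3(dc) > g.lrad[l] + e.rcore + e.hh) continue;
      const double* axc = &g.ax[3 * c];
      for (int p = 0; p < g.npt; ++p) {
        const double* pt = &g.lpt[3 * (g.npt * l + p)];
        double d[3] = {pt[0] - g.cen[3 * c], pt[1] - g.cen[3 * c + 1], pt[2] - g.cen[3 * c + 2]};
        double axial = dot3(d, axc);
        if (std::fabs(axial) >= e.hh) continue;
        double rad2 = dot3(d, d) - axial * axial;
        if (rad2 < e.rcore * e.rcore) {
          *violated = true;
          double pendep = e.rcore - std::sqrt(rad2 > 0 ? rad2 : 0);
          double pendax = e.hh - std::fabs(axial);
          double dep = (pendep < pendax) ? pendep : pendax;
          pen += dep * dep;
        }
      }
    }
  }
  // linker-linker close approach (distinct linkers)
  double lim = 2 * e.rdna;
  for (int a = 0; a < nl; ++a)
    for (int b = a + 1; b < nl; ++b) {
      double dc[3] = {g.lcen[3 * b] - g.lcen[3 * a], g.lcen[3 * b + 1] - g.lcen[3 * a + 1],
                      g.lcen[3 * b + 2] - g.lcen[3 * a + 2]};
      if (norm3(dc) > g.lrad[a] + g.lrad[b] + lim) continue;
      for (int p = 0; p < g.npt; ++p)
        for (int q = 0; q < g.npt; ++q) {
          const double* pa = &g.lpt[3 * (g.npt * a + p)];
          const double* pb = &g.lpt[3 * (g.npt * b + q)];
          double d[3] = {pb[0] - pa[0], pb[1] - pa[1], pb[2] - pa[2]};
          double dd = norm3(d);
          if (dd < lim) {
            *violated = true;
            pen += (lim - dd) * (lim - dd);
          }
        }
    }
  return pen;
}

static double stacking_total(const FiberGeom& g, const EPar& e) {
  if (!e.stack_on) return 0.0;
  double acc = 0.0;
  for (int i = 0; i < g.n; ++i)
    for (int j = i + e.stack_min_sep; j < g.n; ++j)
      acc += stack_pair(&g.cen[3 * i], &g.ax[3 * i], &g.cen[3 * j], &g.ax[3 * j], e);
  return acc;
}

// [[Rcpp::export]]
List cpp_regular_energy(NumericVector theta, int L, int n_nuc, List core_tpl,
                        List epar, bool want_geometry) {
  CoreTpl core = core_from_list(core_tpl);
  EPar e = epar_from_list(epar);
  int nsteps = L + 1;
  // replicate theta into a column-major (L+1) x 6 block
  std::vector<double> block((size_t)nsteps * 6);
  for (int k = 0; k < 6; ++k)
    for (int s = 0; s < nsteps; ++s) block[s + nsteps * k] = theta[k];
  std::vector<const double*> linkers(n_nuc - 1, block.data());
  FiberGeom g;
  build_geom(linkers, nsteps, n_nuc, core, g);
  double s6[6];
  for (int k = 0; k < 6; ++k) s6[k] = theta[k];
  double elastic = (n_nuc - 1) * nsteps * step_energy_raw(s6, e);
  double stack = stacking_total(g, e);
  bool viol = false;
  double pen = ev_penalty(g, core, e, &viol);
  List out = List::create(_["elastic"] = elastic, _["stacking"] = stack,
                          _["violated"] = viol, _["penalty"] = pen);
  if (want_geometry) {
    NumericMatrix cen(n_nuc, 3), ax(n_nuc, 3);
    for (int i = 0; i < n_nuc; ++i)
      for (int k = 0; k < 3; ++k) {
        cen(i, k) = g.cen[3 * i + k];
        ax(i, k) = g.ax[3 * i + k];
      }
    out["centers"] = cen;
    out["axes"] = ax;
  }
  return out;
}

// Full base-pair resolution fiber build from per-linker step matrices.
// [[Rcpp::export]]
List cpp_build_fiber(List linker_list, int n_nuc, List core_tpl, bool circular) {
  CoreTpl core = core_from_list(core_tpl);
  if ((int)core.bp_o.size() / 3 != core.lncp)
    stop("core template lacks full bp frames");
  int nl = linker_list.size();
  int L = 0;
  std::vector<NumericMatrix> lm(nl);
  std::vector<const double*> ptrs(nl);
  for (int i = 0; i < nl; ++i) {
    lm[i] = as<NumericMatrix>(linker_list[i]);
    ptrs[i] = REAL(lm[i]);
    L = lm[i].nrow() - 1;
  }
  int nsteps = L + 1;
  FiberGeom g;
  build_geom(ptrs, nsteps, n_nuc, core, g);
  int N = n_nuc * core.lncp + nl * L;
  NumericMatrix origins(N, 3), axes(N, 9);
  IntegerVector region(N), is_core(N);
  int idx = 0;
  for (int i = 0; i < n_nuc; ++i) {
    const double* R = &g.entR[9 * i];
    const double* t = &g.entT[3 * i];
    for (int b = 0; b < core.lncp; ++b) {
      double w[3];
      matvec(R, &core.bp_o[3 * b], w);
      for (int k = 0; k < 3; ++k) origins(idx, k) = t[k] + w[k];
      double Rb[9];
      matmul(R, &core.bp_R[9 * b], Rb);
      for (int k = 0; k < 9; ++k) axes(idx, k) = Rb[k];
      region[idx] = i;
      is_core[idx] = 1;
      ++idx;
    }
    if (i < nl) {
      // linker bp frames: rebuild with axes (build_geom stored origins only)
      double Rx[9], ox[3], w[3];
      matmul(R, core.exitR, Rx);
      matvec(R, core.exitT, w);
      for (int k = 0; k < 3; ++k) ox[k] = t[k] + w[k];
      for (int ksp = 0; ksp < nsteps; ++ksp) {
        double s6[6];
        for (int k = 0; k < 6; ++k) s6[k] = lm[i](ksp, k);
        double A[9], u[3], Rn[9];
        step_transform_raw(s6, A, u);
        matvec(Rx, u, w);
        for (int k = 0; k < 3; ++k) ox[k] += w[k];
        matmul(Rx, A, Rn);
        reorthogonalize(Rn);
        for (int k = 0; k < 9; ++k) Rx[k] = Rn[k];
        if (ksp < L) {
          for (int k = 0; k < 3; ++k) origins(idx, k) = ox[k];
          for (int k = 0; k < 9; ++k) axes(idx, k) = Rx[k];
          region[idx] = i;
          is_core[idx] = 0;
          ++idx;
        }
      }
    }
  }
  NumericMatrix cen(n_nuc, 3), ax(n_nuc, 3);
  for (int i = 0; i < n_nuc; ++i)
    for (int k = 0; k < 3; ++k) {
      cen(i, k) = g.cen[3 * i + k];
      ax(i, k) = g.ax[3 * i + k];
    }
  return List::create(_["origins"] = origins, _["axes"] = axes,
                      _["region"] = region, _["is_core"] = is_core,
                      _["centers"] = cen, _["core_axes"] = ax);
}

// Cached optimizer context: converting the template and parameter lists on
// every objective evaluation dominates the search cost, so the regular-fiber
// optimizer builds this once and passes an external pointer.
struct RegCtx {
  CoreTpl core;
  EPar e;
};

// [[Rcpp::export]]
SEXP cpp_make_regctx(List core_tpl, List epar) {
  RegCtx* ctx = new RegCtx;
  ctx->core = core_from_list(core_tpl);
  ctx->e = epar_from_list(epar);
  XPtr<RegCtx> p(ctx, true);
  return p;
}

static void regular_geom(const double* theta, int L, int n_nuc,
                         const CoreTpl& core, FiberGeom& g,
                         std::vector<double>& block) {
  int nsteps = L + 1;
  block.resize((size_t)nsteps * 6);
  for (int k = 0; k < 6; ++k)
    for (int s = 0; s < nsteps; ++s) block[s + nsteps * k] = theta[k];
  std::vector<const double*> linkers(n_nuc - 1, block.data());
  build_geom(linkers, nsteps, n_nuc, core, g);
}

// [[Rcpp::export]]
List cpp_regular_energy_ctx(NumericVector theta, int L, int n_nuc, SEXP ctx_,
                            bool want_geometry) {
  XPtr<RegCtx> ctx(ctx_);
  FiberGeom g;
  std::vector<double> block;
  regular_geom(REAL(theta), L, n_nuc, ctx->core, g, block);
  double s6[6];
  for (int k = 0; k < 6; ++k) s6[k] = theta[k];
  double elastic = (n_nuc - 1) * (L + 1) * step_energy_raw(s6, ctx->e);
  double stack = stacking_total(g, ctx->e);
  bool viol = false;
  double pen = ev_penalty(g, ctx->core, ctx->e, &viol);
  List out = List::create(_["elastic"] = elastic, _["stacking"] = stack,
                          _["violated"] = viol, _["penalty"] = pen);
  if (want_geometry) {
    NumericMatrix cen(n_nuc, 3), ax(n_nuc, 3);
    for (int i = 0; i < n_nuc; ++i)
      for (int k = 0; k < 3; ++k) {
        cen(i, k) = g.cen[3 * i + k];
        ax(i, k) = g.ax[3 * i + k];
      }
    out["centers"] = cen;
    out["axes"] = ax;
  }
  return out;
}

// Guided-compaction objective, evaluated wholly in compiled code:
// elastic + pw * penalty + kg * sum (d_{i,i+2} - tau)^2 + aw * sum (1 - g).
// [[Rcpp::export]]
double cpp_guide_energy_ctx(NumericVector theta, int L, int n_nuc, SEXP ctx_,
                            double tau, double kg, double aw, double pw) {
  XPtr<RegCtx> ctx(ctx_);
  FiberGeom g;
  std::vector<double> block;
  regular_geom(REAL(theta), L, n_nuc, ctx->core, g, block);
  double s6[6];
  for (int k = 0; k < 6; ++k) s6[k] = theta[k];
  double acc = (n_nuc - 1) * (L + 1) * step_energy_raw(s6, ctx->e);
  bool viol = false;
  acc += pw * ev_penalty(g, ctx->core, ctx->e, &viol);
  for (int i = 0; i + 2 < n_nuc; ++i) {
    double d[3] = {g.cen[3 * (i + 2)] - g.cen[3 * i],
                   g.cen[3 * (i + 2) + 1] - g.cen[3 * i + 1],
                   g.cen[3 * (i + 2) + 2] - g.cen[3 * i + 2]};
    double dd = norm3(d);
    acc += kg * (dd - tau) * (dd - tau);
    double ga = std::fabs(dot3(&g.ax[3 * i], &g.ax[3 * (i + 2)]));
    acc += aw * (1 - ga);
  }
  return acc;
}

// Hard/soft polish objectives in compiled code; mode 0 = hard wall
// (violated -> +Inf), mode 1 = soft quadratic penalty with weight pw.
// [[Rcpp::export]]
double cpp_true_energy_ctx(NumericVector theta, int L, int n_nuc, SEXP ctx_,
                           int mode, double pw) {
  XPtr<RegCtx> ctx(ctx_);
  FiberGeom g;
  std::vector<double> block;
  regular_geom(REAL(theta), L, n_nuc, ctx->core, g, block);
  double s6[6];
  for (int k = 0; k < 6; ++k) s6[k] = theta[k];
  double elastic = (n_nuc - 1) * (L + 1) * step_energy_raw(s6, ctx->e);
  bool viol = false;
  double pen = ev_penalty(g, ctx->core, ctx->e, &viol);
  if (mode == 0 && viol) return R_PosInf;
  double stack = stacking_total(g, ctx->e);
  return elastic + stack + (mode == 0 ? 0.0 : pw * pen);
}

// Energy of an arbitrary (possibly irregular) fiber from its linker steps.
// [[Rcpp::export]]
List cpp_fiber_energy(List linker_list, int n_nuc, List core_tpl, List epar) {
  CoreTpl core = core_from_list(core_tpl);
  EPar e = epar_from_list(epar);
  int nl = linker_list.size();
  std::vector<NumericMatrix> lm(nl);
  std::vector<const double*> ptrs(nl);
  int nsteps = 1;
  for (int i = 0; i < nl; ++i) {
    lm[i] = as<NumericMatrix>(linker_list[i]);
    ptrs[i] = REAL(lm[i]);
    nsteps = lm[i].nrow();
  }
  FiberGeom g;
  build_geom(ptrs, nsteps, n_nuc, core, g);
  double elastic = 0.0, s6[6];
  for (int i = 0; i < nl; ++i)
    for (int s = 0; s < nsteps; ++s) {
      for (int k = 0; k < 6; ++k) s6[k] = lm[i](s, k);
      elastic += step_energy_raw(s6, e);
    }
  double stack = stacking_total(g, e);
  bool viol = false;
  double pen = ev_penalty(g, core, e, &viol);
  return List::create(_["elastic"] = elastic, _["stacking"] = stack,
                      _["violated"] = viol, _["penalty"] = pen);
}

// ------------------------------------------------------------- Metropolis MC

// [[Rcpp::export]]
List cpp_mc(List linker_list, int n_nuc, List core_tpl, List epar,
            double temperature, int n_steps, double move_ang, double move_disp,
            int record_every) {
  CoreTpl core = core_from_list(core_tpl);
  EPar e = epar_from_list(epar);
  int nl = linker_list.size();
  NumericMatrix l0 = as<NumericMatrix>(linker_list[0]);
  int nsteps_per = l0.nrow();
  // state, column-major (L+1) x 6 per linker
  std::vector<std::vector<double>> state(nl);
  for (int i = 0; i < nl; ++i) {
    NumericMatrix m = as<NumericMatrix>(linker_list[i]);
    state[i].resize((size_t)nsteps_per * 6);
    for (int k = 0; k < 6; ++k)
      for (int s = 0; s < nsteps_per; ++s) state[i][s + nsteps_per * k] = m(s, k);
  }
  std::vector<const double*> ptrs(nl);
  for (int i = 0; i < nl; ++i) ptrs[i] = state[i].data();

  // per-step elastic energies
  std::vector<double> stepE((size_t)nl * nsteps_per);
  double s6[6];
  for (int i = 0; i < nl; ++i)
    for (int s = 0; s < nsteps_per; ++s) {
      for (int k = 0; k < 6; ++k) s6[k] = state[i][s + nsteps_per * k];
      stepE[i * nsteps_per + s] = step_energy_raw(s6, e);
    }
  double elastic = 0.0;
  for (double v : stepE) elastic += v;

  FiberGeom g;
  build_geom(ptrs, nsteps_per, n_nuc, core, g);
  bool viol = false;
  ev_penalty(g, core, e, &viol);
  if (viol) stop("starting conformation violates excluded volume");
  double stack = stacking_total(g, e);
  double E = elastic + stack;

  int n_snap = n_steps / record_every;
  NumericVector energies(n_snap);
  NumericVector snap_linkers((R_xlen_t)n_snap * nl * nsteps_per * 6);
  snap_linkers.attr("dim") = IntegerVector::create(nsteps_per, 6, nl, n_snap);
  NumericVector snap_cen((R_xlen_t)n_snap * n_nuc * 3), snap_ax((R_xlen_t)n_snap * n_nuc * 3);
  snap_cen.attr("dim") = IntegerVector::create(3, n_nuc, n_snap);
  snap_ax.attr("dim") = IntegerVector::create(3, n_nuc, n_snap);

  long accepted = 0;
  int isnap = 0;
  FiberGeom gnew;
  for (int it = 1; it <= n_steps; ++it) {
    int l = (int)std::floor(R::unif_rand() * nl);
    if (l >= nl) l = nl - 1;
    int s = (int)std::floor(R::unif_rand() * nsteps_per);
    if (s >= nsteps_per) s = nsteps_per - 1;
    int p = (int)std::floor(R::unif_rand() * 6);
    if (p >= 6) p = 5;
    double delta = (p < 3 ? move_ang : move_disp) * (2.0 * R::unif_rand() - 1.0);
    double old = state[l][s + nsteps_per * p];
    state[l][s + nsteps_per * p] = old + delta;
    for (int k = 0; k < 6; ++k) s6[k] = state[l][s + nsteps_per * k];
    double newStepE = step_energy_raw(s6, e);
    double dElastic = newStepE - stepE[l * nsteps_per + s];

    build_geom(ptrs, nsteps_per, n_nuc, core, gnew);
    bool v2 = false;
    ev_penalty(gnew, core, e, &v2);
    bool accept = false;
    if (!v2) {
      double stack2 = stacking_total(gnew, e);
      double dE = dElastic + (stack2 - stack);
      if (dE <= 0 || R::unif_rand() < std::exp(-dE / temperature)) {
        accept = true;
        stack = stack2;
        elastic += dElastic;
        stepE[l * nsteps_per + s] = newStepE;
        E = elastic + stack;
        std::swap(g, gnew);
      }
    }
    if (!accept) {
      state[l][s + nsteps_per * p] = old;
    } else {
      ++accepted;
    }
    if (it % record_every == 0 && isnap < n_snap) {
      energies[isnap] = E;
      for (int i = 0; i < nl; ++i)
        for (int k6 = 0; k6 < 6; ++k6)
          for (int ss = 0; ss < nsteps_per; ++ss)
            snap_linkers[ss + nsteps_per * (k6 + 6 * (i + (R_xlen_t)nl * isnap))] =
              state[i][ss + nsteps_per * k6];
      for (int i = 0; i < n_nuc; ++i)
        for (int k = 0; k < 3; ++k) {
          snap_cen[k + 3 * (i + (R_xlen_t)n_nuc * isnap)] = g.cen[3 * i + k];
          snap_ax[k + 3 * (i + (R_xlen_t)n_nuc * isnap)] = g.ax[3 * i + k];
        }
      ++isnap;
    }
  }
  return List::create(_["energies"] = energies,
                      _["snap_linkers"] = snap_linkers,
                      _["snap_centers"] = snap_cen,
                      _["snap_axes"] = snap_ax,
                      _["acceptance_rate"] = (double)accepted / n_steps);
}
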