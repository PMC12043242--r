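#include <Rcpp.h>
#include "core.h"
using namespace Rcpp;

// 3x3 helpers on flat double[9], row-major.
static inline void mat_id(double *A) {
  A[0] = 1; A[1] = 0; A[2] = 0;
  A[3] = 0; A[4] = 1; A[5] = 0;
  A[6] = 0; A[7] = 0; A[8] = 1;
}

static inline void mat_mul(const double *A, const double *B, double *C) {
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j)
      C[3 * i + j] = A[3 * i] * B[j] + A[3 * i + 1] * B[3 + j] +
                     A[3 * i + 2] * B[6 + j];
}

static inline void mat_vec(const double *A, const double *v, double *w) {
  for (int i = 0; i < 3; ++i)
    w[i] = A[3 * i] * v[0] + A[3 * i + 1] * v[1] + A[3 * i + 2] * v[2];
}

// xy-plane (about z) rotation by pi - theta.
static inline void bend_matrix(double theta, double *A) {
  double a = M_PI - theta, c = std::cos(a), s = std::sin(a);
  A[0] = c; A[1] = -s; A[2] = 0;
  A[3] = s; A[4] = c;  A[5] = 0;
  A[6] = 0; A[7] = 0;  A[8] = 1;
}

// yz-plane (about x) rotation by phi.
static inline void twist_matrix(double phi, double *A) {
  double c = std::cos(phi), s = std::sin(phi);
  A[0] = 1; A[1] = 0; A[2] = 0;
  A[3] = 0; A[4] = c; A[5] = -s;
  A[6] = 0; A[7] = s; A[8] = c;
}

// geom: dN, dCa, dCp, thetaN, thetaCa, thetaCp, omega (radians).
static void step_q(const double *g, double *q) {
  double TN[9], TCp[9], Rom[9], tmp[9], chain[9];
  bend_matrix(g[3], TN);
  bend_matrix(g[5], TCp);
  twist_matrix(g[6], Rom);
  mat_mul(TCp, Rom, tmp);
  mat_mul(tmp, TN, chain); // T_C' R_omega T_N
  double pN[3] = {g[0], 0, 0}, pCp[3] = {g[2], 0, 0};
  double a[3], b[3];
  mat_vec(chain, pN, a);
  mat_vec(TCp, pCp, b);
  q[0] = a[0] + b[0] + g[1];
  q[1] = a[1] + b[1];
  q[2] = a[2] + b[2];
}

// M_i = T_C' R_omega T_N R_phi T_Ca R_psi
static void residue_rot(const double *g, double phi, double psi, double *M) {
  double TN[9], TCa[9], TCp[9], Rom[9], Rphi[9], Rpsi[9];
  double t1[9], t2[9], t3[9], t4[9];
  bend_matrix(g[3], TN);
  bend_matrix(g[4], TCa);
  bend_matrix(g[5], TCp);
  twist_matrix(g[6], Rom);
  twist_matrix(phi, Rphi);
  twist_matrix(psi, Rpsi);
  mat_mul(TCp, Rom, t1);
  mat_mul(t1, TN, t2);
  mat_mul(t2, Rphi, t3);
  mat_mul(t3, TCa, t4);
  mat_mul(t4, Rpsi, M);
}

// Closure error: squared norm of the accumulated ring displacement plus the
// squared mismatch of the terminal frame's x and y axes.
double cyclic_error_core(const double *phi, const double *psi, int n,
                         const double *g) {
  double q[3];
  step_q(g, q);
  double P[9], M[9], Pn[9], Pq[3];
  mat_id(P);
  double r[3] = {q[0], q[1], q[2]};
  for (int i = 0; i < n - 1; ++i) {
    residue_rot(g, phi[i], psi[i], M);
    mat_mul(P, M, Pn);
    std::copy(Pn, Pn + 9, P);
    mat_vec(P, q, Pq);
    r[0] += Pq[0]; r[1] += Pq[1]; r[2] += Pq[2];
  }
  residue_rot(g, phi[n - 1], psi[n - 1], M);
  mat_mul(P, M, Pn);
  double e = r[0] * r[0] + r[1] * r[1] + r[2] * r[2];
  double x0 = Pn[0] - 1, x1 = Pn[3], x2 = Pn[6];
  double y0 = Pn[1], y1 = Pn[4] - 1, y2 = Pn[7];
  e += x0 * x0 + x1 * x1 + x2 * x2;
  e += y0 * y0 + y1 * y1 + y2 * y2;
  return e;
}

// Forward kinematics along the frame chain anchored at CA of residue n.
// Fills bb (3 x 3n col-major: N_1, CA_1, C_1, ...), N_1 at the origin.
// The frame chain's yz-rotation sense is the mirror of the standard
// dihedral convention, so torsions are negated when composing frames; the
// closure error is exactly invariant under this mirror.
void forward_core(const double *phi, const double *psi, int n,
                  const double *g, double *bb) {
  double A[9], An[9], T[9], R[9], TR[9];
  mat_id(A);
  double x[3] = {0, 0, 0};
  std::vector<double> pos(3 * (3 * n + 1), 0.0);
  for (int m = 1; m <= 3 * n; ++m) {
    int mm = m % 3; // donor atom type: 1 CA->C', 2 C'->N, 0 N->CA
    double d = (mm == 1) ? g[1] : (mm == 2) ? g[2] : g[0];
    double p[3] = {d, 0, 0}, Ap[3];
    mat_vec(A, p, Ap);
    x[0] += Ap[0]; x[1] += Ap[1]; x[2] += Ap[2];
    pos[3 * m] = x[0]; pos[3 * m + 1] = x[1]; pos[3 * m + 2] = x[2];
    double theta, tor;
    if (mm == 1) { theta = g[5]; tor = -g[6]; }                  // at C'
    else if (mm == 2) { theta = g[3]; tor = -phi[(m - 2) / 3]; } // at N
    else { theta = g[4]; tor = -psi[m / 3 - 1]; }                // at CA
    bend_matrix(theta, T);
    twist_matrix(tor, R);
    mat_mul(T, R, TR);
    mat_mul(A, TR, An);
    std::copy(An, An + 9, A);
  }
  double pCa[3] = {g[1], 0, 0}, Ap[3];
  mat_vec(A, pCa, Ap);
  double cpn[3] = {x[0] + Ap[0], x[1] + Ap[1], x[2] + Ap[2]};
  // chain atom j (1-based) at pos[3*(j-1)]; origin shift to N_1 (atom 3)
  double org[3] = {pos[6], pos[7], pos[8]};
  for (int k = 1; k <= n; ++k) {
    for (int d = 0; d < 3; ++d) {
      bb[3 * (3 * (k - 1)) + d] = pos[3 * (3 * k - 1) + d] - org[d];
      if (k < n) {
        bb[3 * (3 * (k - 1) + 1) + d] = pos[3 * (3 * k) + d] - org[d];
        bb[3 * (3 * (k - 1) + 2) + d] = pos[3 * (3 * k + 1) + d] - org[d];
      }
    }
  }
  for (int d = 0; d < 3; ++d) {
    bb[3 * (3 * (n - 1) + 1) + d] = pos[3 * (3 * n) + d] - org[d];
    bb[3 * (3 * (n - 1) + 2) + d] = cpn[d] - org[d];
  }
}

// [[Rcpp::export(name = ".cpp_step_vector")]]
NumericVector cpp_step_vector(NumericVector geom) {
  double q[3];
  step_q(geom.begin(), q);
  return NumericVector::create(q[0], q[1], q[2]);
}

// [[Rcpp::export(name = ".cpp_residue_matrix")]]
NumericMatrix cpp_residue_matrix(double phi, double psi, NumericVector geom) {
  double M[9];
  residue_rot(geom.begin(), phi, psi, M);
  NumericMatrix out(3, 3);
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j)
      out(i, j) = M[3 * i + j];
  return out;
}

// [[Rcpp::export(name = ".cpp_cyclic_error")]]
double cpp_cyclic_error(NumericVector phi, NumericVector psi,
                        NumericVector geom) {
  return cyclic_error_core(phi.begin(), psi.begin(), phi.size(),
                           geom.begin());
}

// [[Rcpp::export(name = ".cpp_forward_kin")]]
NumericMatrix cpp_forward_kin(NumericVector phi, NumericVector psi,
                              NumericVector geom) {
  int n = phi.size();
  NumericMatrix out(3, 3 * n);
  forward_core(phi.begin(), psi.begin(), n, geom.begin(), out.begin());
  return out;
}
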