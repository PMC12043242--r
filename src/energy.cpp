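#include <Rcpp.h>
#include "core.h"
using namespace Rcpp;

static inline double dist3(const double *a, const double *b) {
  double dx = a[0] - b[0], dy = a[1] - b[1], dz = a[2] - b[2];
  return std::sqrt(dx * dx + dy * dy + dz * dz);
}

static inline void unit_diff(const double *a, const double *b, double *u) {
  double dx = a[0] - b[0], dy = a[1] - b[1], dz = a[2] - b[2];
  double n = std::sqrt(dx * dx + dy * dy + dz * dz);
  u[0] = dx / n; u[1] = dy / n; u[2] = dz / n;
}

// Carbonyl O in the CA-C'-N(next) plane opposite N(next); amide H in the
// peptide plane bisecting C'(prev)-N-CA, pointing away from the chain.
void place_oh_core(const double *bb, int n, double d_o, double ang_o,
                   double d_h, double *oh) {
  for (int k = 0; k < n; ++k) {
    const double *N = bb + 3 * (3 * k);
    const double *CA = bb + 3 * (3 * k + 1);
    const double *C = bb + 3 * (3 * k + 2);
    const double *Nnext = bb + 3 * (3 * ((k + 1) % n));
    const double *Cprev = bb + 3 * (3 * ((k + n - 1) % n) + 2);
    double a[3], b[3], eb[3];
    unit_diff(CA, C, a);
    unit_diff(Nnext, C, b);
    double dot = a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
    double nb = 0;
    for (int d = 0; d < 3; ++d) { eb[d] = b[d] - dot * a[d]; nb += eb[d] * eb[d]; }
    nb = std::sqrt(nb);
    double ca = std::cos(ang_o), sa = std::sin(ang_o);
    for (int d = 0; d < 3; ++d)
      oh[3 * k + d] = C[d] + d_o * (ca * a[d] - sa * eb[d] / (nb > 1e-12 ? nb : 1));
    double u[3], v[3], h[3];
    unit_diff(Cprev, N, u);
    unit_diff(CA, N, v);
    double nh = 0;
    for (int d = 0; d < 3; ++d) { h[d] = -(u[d] + v[d]); nh += h[d] * h[d]; }
    nh = std::sqrt(nh);
    for (int d = 0; d < 3; ++d)
      oh[3 * (n + k) + d] = N[d] + d_h * h[d] / (nh > 1e-12 ? nh : 1);
  }
}

void pair_core(const double *xyz, const int *bbpos, const int *branch,
               const int *type, int m, int nres, const PairParams &pp,
               double *out) {
  int L = 3 * nres;
  double rep = 0, att = 0, elec = 0, solv = 0;
  const double lk_pre = 2.0 * std::sqrt(M_PI) * M_PI; // 2 pi^{3/2}
  for (int i = 0; i < m; ++i) {
    for (int j = i + 1; j < m; ++j) {
      int db = std::abs(bbpos[i] - bbpos[j]);
      int d = std::min(db, L - db) + branch[i] + branch[j];
      if (d < 4) continue;
      double r = dist3(xyz + 3 * i, xyz + 3 * j);
      if (r > pp.cutoff || r < 1e-6) continue;
      int ti = type[i], tj = type[j];
      // electrostatics, distance-dependent dielectric
      elec += pp.coulomb * pp.charges[ti] * pp.charges[tj] / (r * r);
      if (ti == 4 || tj == 4) continue; // H: electrostatics only
      double rm = pp.radii[ti] + pp.radii[tj];
      double x = rm / r;
      double x6 = x * x * x; x6 *= x6;
      double lj = pp.lj_eps * (x6 * x6 - 2.0 * x6);
      if (r < rm) { rep += lj + pp.lj_eps; att += -pp.lj_eps; }
      else att += lj;
      double gi = std::exp(-std::pow((r - pp.radii[ti]) / pp.lambda, 2));
      double gj = std::exp(-std::pow((r - pp.radii[tj]) / pp.lambda, 2));
      solv += -(pp.dg_free[ti] * gi * pp.volume[tj] +
                pp.dg_free[tj] * gj * pp.volume[ti]) /
              (lk_pre * pp.lambda * r * r);
    }
  }
  out[0] = rep; out[1] = att; out[2] = elec; out[3] = solv;
}

double hbond_core(const double *bb, const double *oh, const int *has_h,
                  int n, const HBParams &hp, int *nbonds, int *nstrong,
                  std::vector<double> *rows) {
  double total = 0;
  int nb = 0, ns = 0;
  for (int i = 0; i < n; ++i) {
    if (!has_h[i]) continue;
    const double *N = bb + 3 * (3 * i);
    const double *H = oh + 3 * (n + i);
    for (int j = 0; j < n; ++j) {
      if (j == i || j == (i + n - 1) % n) continue;
      const double *O = oh + 3 * j;
      double r = dist3(H, O);
      if (r >= hp.dmax) continue;
      double u[3], v[3];
      unit_diff(N, H, u);
      unit_diff(O, H, v);
      double ca = u[0] * v[0] + u[1] * v[1] + u[2] * v[2];
      if (ca > 1) ca = 1; if (ca < -1) ca = -1;
      double ang = std::acos(ca);
      if (ang <= hp.angmin) continue;
      double fa = (ca + 0.5) / (-0.5);
      if (fa < 0) fa = 0;
      double e = hp.depth * std::exp(-std::pow((r - hp.r0) / hp.sigma, 2)) *
                 fa * fa;
      total += e;
      nb += 1;
      if (e < hp.strong) ns += 1;
      if (rows) {
        rows->push_back(i + 1); rows->push_back(j + 1);
        rows->push_back(r); rows->push_back(ang * 180.0 / M_PI);
        rows->push_back(e);
      }
    }
  }
  if (nbonds) *nbonds = nb;
  if (nstrong) *nstrong = ns;
  return total;
}

// [[Rcpp::export(name = ".cpp_place_oh")]]
NumericMatrix cpp_place_oh(NumericMatrix bb, double d_o, double ang_o,
                           double d_h) {
  int n = bb.ncol() / 3;
  NumericMatrix out(3, 2 * n);
  place_oh_core(bb.begin(), n, d_o, ang_o, d_h, out.begin());
  return out;
}

// [[Rcpp::export(name = ".cpp_pair_energies")]]
NumericVector cpp_pair_energies(NumericMatrix xyz, IntegerVector bbpos,
                                IntegerVector branch, IntegerVector type,
                                int nres, NumericVector radii,
                                NumericVector charges, double lj_eps,
                                double cutoff, double coulomb,
                                NumericVector dg_free, NumericVector volume,
                                double lambda, bool elec_only) {
  PairParams pp = {radii.begin(), charges.begin(), lj_eps, cutoff, coulomb,
                   dg_free.begin(), volume.begin(), lambda};
  double out[4];
  pair_core(xyz.begin(), bbpos.begin(), branch.begin(), type.begin(),
            xyz.ncol(), nres, pp, out);
  return NumericVector::create(out[0], out[1], out[2], out[3]);
}

// [[Rcpp::export(name = ".cpp_hbonds")]]
NumericMatrix cpp_hbonds(NumericMatrix bb, NumericMatrix oh,
                         LogicalVector has_h, double dmax, double angmin,
                         double depth, double r0, double sigma) {
  int n = bb.ncol() / 3;
  std::vector<int> hh(n);
  for (int i = 0; i < n; ++i) hh[i] = has_h[i] ? 1 : 0;
  HBParams hp = {dmax, angmin, depth, r0, sigma, 0.0};
  std::vector<double> rows;
  hbond_core(bb.begin(), oh.begin(), hh.data(), n, hp, nullptr, nullptr,
             &rows);
  int k = rows.size() / 5;
  NumericMatrix out(k, 5);
  for (int i = 0; i < k; ++i)
    for (int c = 0; c < 5; ++c) out(i, c) = rows[5 * i + c];
  return out;
}
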