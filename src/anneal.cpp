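#include <Rcpp.h>
#include "core.h"
using namespace Rcpp;

// Layered simulated annealing inner loop over the default layer stack
// (rama, rep, cyclic, hbond [, misc]) with an analytic basin Ramachandran
// map. Mirrors the R-level propose_move / layer_accept semantics; the R
// wrapper dispatches here for the default configuration and falls back to
// the R loop for custom layer stacks or grid maps.

static const double DEG = M_PI / 180.0;

static inline double wrapd(double x) {
  // degrees -> (-180, 180]
  return x - 360.0 * std::ceil((x - 180.0) / 360.0);
}

static inline double tordist2(double p1, double s1, double p2, double s2) {
  double dp = wrapd(p1 - p2), ds = wrapd(s1 - s2);
  return dp * dp + ds * ds;
}

struct BasinMap {
  const double *cphi, *cpsi, *rad;
  int k;
  double scale;
  double energy(double phi, double psi) const {
    double best = R_PosInf;
    for (int i = 0; i < k; ++i) {
      double v = scale * tordist2(phi, psi, cphi[i], cpsi[i]) /
                 (rad[i] * rad[i]);
      if (v < best) best = v;
    }
    return best;
  }
  bool allowed(double phi, double psi) const {
    return energy(phi, psi) <= scale;
  }
};

static inline bool metropolis(double ecur, double enew, double thr,
                              double T) {
  if (enew < ecur || enew < thr) return true;
  return R::runif(0, 1) < std::exp((ecur - enew) / T);
}

// [[Rcpp::export(name = ".cpp_run_annealing")]]
List cpp_run_annealing(NumericVector phi0, NumericVector psi0,
                       NumericVector geom, int steps, double k0, double k1,
                       bool k_geometric,
                       NumericVector thr0s, NumericVector thr1s,
                       NumericVector T0s,
                       NumericVector Tfs, bool has_misc,
                       NumericMatrix centers, NumericVector cradii,
                       double cscale, NumericVector radii,
                       NumericVector charges, double lj_eps, double cutoff,
                       double coulomb, NumericVector dg_free,
                       NumericVector volume, double solv_lambda,
                       double hb_dmax, double hb_angmin, double hb_depth,
                       double hb_r0, double hb_sigma, double hb_strong,
                       double crit_cyc, double crit_rep, int crit_strong) {
  int n = phi0.size();
  int nlay = has_misc ? 5 : 4;
  std::vector<double> cphi(centers.nrow()), cpsi(centers.nrow());
  for (int i = 0; i < centers.nrow(); ++i) {
    cphi[i] = centers(i, 0);
    cpsi[i] = centers(i, 1);
  }
  BasinMap map = {cphi.data(), cpsi.data(), cradii.begin(),
                  (int)centers.nrow(), cscale};
  PairParams pp = {radii.begin(), charges.begin(), lj_eps, cutoff, coulomb,
                   dg_free.begin(), volume.begin(), solv_lambda};
  HBParams hp = {hb_dmax, hb_angmin, hb_depth, hb_r0, hb_sigma, hb_strong};
  // static atom-table layout: 3n backbone atoms, then n O, then n H
  int m = 5 * n;
  std::vector<double> xyz(3 * m);
  std::vector<int> bbpos(m), branch(m), type(m), has_h(n, 1);
  for (int k = 0; k < n; ++k) {
    bbpos[3 * k] = 3 * k;     branch[3 * k] = 0;     type[3 * k] = 0;
    bbpos[3 * k + 1] = 3 * k + 1; branch[3 * k + 1] = 0; type[3 * k + 1] = 1;
    bbpos[3 * k + 2] = 3 * k + 2; branch[3 * k + 2] = 0; type[3 * k + 2] = 2;
    bbpos[3 * n + k] = 3 * k + 2; branch[3 * n + k] = 1; type[3 * n + k] = 3;
    bbpos[4 * n + k] = 3 * k;     branch[4 * n + k] = 1; type[4 * n + k] = 4;
  }
  std::vector<double> bb(9 * n), oh(6 * n), prad(n), srad(n);
  // evaluate all layer energies of a configuration; returns per-layer e
  struct State {
    double e[5];      // rama, rep, cyclic, hbond, misc
    double pair[4];   // rep, att, elec, solv
    int nbonds, nstrong;
  };
  std::vector<double> phi(phi0.begin(), phi0.end()),
      psi(psi0.begin(), psi0.end()), nphi(n), npsi(n);
  std::vector<double> evals(5, 0.0);
  const double d_o = 1.231, ang_o = 120.1 * DEG, d_h = 1.010;
  auto eval_layer = [&](int li, const std::vector<double> &p,
                        const std::vector<double> &s, State &st) {
    switch (li) {
    case 0: { // rama
      double e = 0;
      for (int i = 0; i < n; ++i) e += map.energy(p[i], s[i]);
      st.e[0] = e;
      break;
    }
    case 1: { // rep (builds coordinates and all pair terms)
      for (int i = 0; i < n; ++i) { prad[i] = p[i] * DEG; srad[i] = s[i] * DEG; }
      forward_core(prad.data(), srad.data(), n, geom.begin(), bb.data());
      place_oh_core(bb.data(), n, d_o, ang_o, d_h, oh.data());
      std::copy(bb.begin(), bb.end(), xyz.begin());
      std::copy(oh.begin(), oh.end(), xyz.begin() + 9 * n);
      pair_core(xyz.data(), bbpos.data(), branch.data(), type.data(), m, n,
                pp, st.pair);
      st.e[1] = st.pair[0];
      break;
    }
    case 2: { // cyclic
      for (int i = 0; i < n; ++i) { prad[i] = p[i] * DEG; srad[i] = s[i] * DEG; }
      st.e[2] = cyclic_error_core(prad.data(), srad.data(), n, geom.begin());
      break;
    }
    case 3: { // hbond (reuses bb/oh from the rep layer of this proposal)
      st.e[3] = hbond_core(bb.data(), oh.data(), has_h.data(), n, hp,
                           &st.nbonds, &st.nstrong, nullptr);
      break;
    }
    case 4: // misc
      st.e[4] = st.pair[1] + st.pair[2] + st.pair[3];
      break;
    }
  };
  State cur, prop;
  for (int li = 0; li < nlay; ++li) eval_layer(li, phi, psi, cur);
  std::vector<double> cand;
  int ncand = 0, accepted = 0;
  int ncol = 2 * n + 10;
  for (int t = 1; t <= steps; ++t) {
    double f = steps == 1 ? 0.0 : (double)(t - 1) / (steps - 1);
    double k = k_geometric ? k0 * std::pow(k1 / k0, f) : k0 + f * (k1 - k0);
    // propose: uniform disk move per residue, prohibited points keep old
    for (int i = 0; i < n; ++i) {
      double r = k * std::sqrt(R::runif(0, 1));
      double a = R::runif(0, 2 * M_PI);
      double np = wrapd(phi[i] + r * std::cos(a));
      double ns = wrapd(psi[i] + r * std::sin(a));
      if (map.allowed(np, ns)) { nphi[i] = np; npsi[i] = ns; }
      else { nphi[i] = phi[i]; npsi[i] = psi[i]; }
    }
    bool pass = true;
    prop = cur;
    for (int li = 0; li < nlay; ++li) {
      eval_layer(li, nphi, npsi, prop);
      evals[li] += 1;
      double T = T0s[li] * std::pow(Tfs[li] / T0s[li], f);
      // annealed threshold: geometric when both ends positive, else linear
      double thr = (thr0s[li] > 0 && thr1s[li] > 0)
                       ? thr0s[li] * std::pow(thr1s[li] / thr0s[li], f)
                       : thr0s[li] + f * (thr1s[li] - thr0s[li]);
      if (!metropolis(cur.e[li], prop.e[li], thr, T)) {
        pass = false;
        break;
      }
    }
    if (!pass) continue;
    phi = nphi; psi = npsi; cur = prop;
    accepted += 1;
    if (cur.e[2] <= crit_cyc && cur.e[1] <= crit_rep &&
        cur.nstrong >= crit_strong) {
      for (int i = 0; i < n; ++i) cand.push_back(phi[i]);
      for (int i = 0; i < n; ++i) cand.push_back(psi[i]);
      cand.push_back(cur.e[0]); cand.push_back(cur.pair[0]);
      cand.push_back(cur.pair[1]); cand.push_back(cur.pair[2]);
      cand.push_back(cur.pair[3]); cand.push_back(cur.e[3]);
      cand.push_back(cur.e[2]); cand.push_back(cur.nbonds);
      cand.push_back(cur.nstrong); cand.push_back(t);
      ncand += 1;
    }
  }
  NumericMatrix cm(ncol, ncand);
  std::copy(cand.begin(), cand.end(), cm.begin());
  NumericVector ev(evals.begin(), evals.begin() + nlay);
  return List::create(Named("candidates") = cm, Named("evals") = ev,
                      Named("accepted") = accepted);
}
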