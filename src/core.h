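#ifndef MACROCYCLER_CORE_H
#define MACROCYCLER_CORE_H

// shared internal kernels: frame-chain geometry, O/H placement, pair
// energies and H-bond scanning. Angles in radians, lengths in Angstrom.
// geom vector layout: dN, dCa, dCp, thetaN, thetaCa, thetaCp, omega.

double cyclic_error_core(const double *phi, const double *psi, int n,
                         const double *g);

// bb: 3 x 3n column-major (N_1, CA_1, C_1, ...), N_1 at origin
void forward_core(const double *phi, const double *psi, int n,
                  const double *g, double *bb);

// oh: 3 x 2n column-major (O_1..O_n, H_1..H_n)
void place_oh_core(const double *bb, int n, double d_o, double ang_o,
                   double d_h, double *oh);

struct PairParams {
  const double *radii;    // by type: N, CA, C, O, H
  const double *charges;
  double lj_eps, cutoff, coulomb;
  const double *dg_free;
  const double *volume;
  double lambda;
};

// out: rep, att, elec, solv. Atom table arrays of length m.
void pair_core(const double *xyz, const int *bbpos, const int *branch,
               const int *type, int m, int nres, const PairParams &pp,
               double *out);

struct HBParams {
  double dmax, angmin, depth, r0, sigma, strong;
};

// returns total H-bond energy; counts written to *nbonds / *nstrong.
// rows (donor, acceptor, dist, angle_deg, energy) appended to `rows` when
// non-null.
double hbond_core(const double *bb, const double *oh, const int *has_h,
                  int n, const HBParams &hp, int *nbonds, int *nstrong,
                  std::vector<double> *rows);

#endif
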