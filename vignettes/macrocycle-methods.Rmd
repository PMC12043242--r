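---
title: "Methods: torsion-space design and stability analysis of cyclic peptides"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: torsion-space design and stability analysis of cyclic peptides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(macrocycler)
```

## The closure problem

A head-to-tail cyclic peptide's backbone is a ring of `n` residues whose
geometry, at fixed ideal bond lengths, bond angles and a trans peptide bond
(`omega = 180` degrees), is fully determined by the `2n` torsions
`(phi_i, psi_i)`. Closing the ring is a hard constraint: six scalar
conditions (the terminal atom must coincide with the first, and the
terminal local frame must match the initial one) that a random torsion
assignment essentially never satisfies.

`macrocycler` encodes this constraint as a smooth error function. A local
right-handed frame is attached to every backbone atom (x toward the next
atom, y in the plane of the atom after that); moving from one frame to the
next composes an in-plane bend by `180 - theta` with a twist by the bond
torsion, plus a translation along the bond. Accumulated over one residue,
the translation is the constant displacement vector

```{r}
step_vector(ideal_geometry())
```

(Angstrom, in the local frame; the third component vanishes because a
trans peptide unit is planar) and the rotation is the residue matrix
`residue_matrix(phi, psi)`. The *cyclic error* sums the squared norm of
the accumulated ring displacement with the squared mismatches of the
terminal frame's x and y axes:

```{r}
conf <- torsion_conformation(runif(7, -180, 180), runif(7, -180, 180))
cyclic_error(conf)
```

It is non-negative, zero exactly on closed rings, smooth in the torsions,
and cheap (a chain of 3x3 matrix products), which is what makes annealing
and genetic search over the closure manifold practical. The origin term
carries squared Angstroms while the two axis terms are dimensionless; they
are combined without re-weighting, keeping the function exactly as
defined.

One numerical convention is worth stating: the frame-chain twist matrices
rotate in the mirror sense of the standard (IUPAC) dihedral convention.
All user-facing torsions follow the standard convention;
`forward_kinematics()` negates torsions when composing frames. Because the
error function is exactly invariant under mirroring (negating every
torsion reflects the backbone through a plane), its values are unchanged —
the test suite verifies the matrix form against an independently built
NeRF atom chain to 1e-9.

## Backbone energy model

The sampler scores only backbone atoms (N, CA, C', O, amide H). The
Ramachandran term is a per-residue map lookup; the pair terms use every
atom pair separated by at least four covalent bonds on the *cyclic* bond
graph. Totals use the weighting

    E_total = 0.45 * E_rama + E_rep + E_hbond + E_other

with `E_other = E_attractive + E_elec + E_solv`.

The pairwise functional forms are deliberately simple, documented
surrogates for a full-atom force field, with every constant exposed in
`energy_params()`:

* repulsive / attractive: the positive and negative branches of a 12-6
  Lennard-Jones potential split at the contact radius (radii N 1.55,
  C 1.70, O 1.52, H 1.10 Angstrom; well depth 0.15 kcal/mol; 6 Angstrom
  cutoff);
* electrostatics: Coulomb with partial charges (N -0.47, H +0.31,
  C' +0.51, O -0.51, CA +0.16) and a distance-dependent dielectric
  `eps = 4r` — the scale factor 4 keeps backbone electrostatics at the few
  kcal/mol magnitude expected for solvated peptides;
* solvation: a Lazaridis–Karplus-style Gaussian exclusion term;
* hydrogen bonds: geometric detection (H...O < 2.5 Angstrom, N-H...O
  angle > 120 degrees, the acceptor one residue upstream excluded as
  covalently adjacent) with energy
  `-1.5 * exp(-((r - 2.0)/0.6)^2) * f(angle)^2` kcal/mol. The 0.6 Angstrom
  radial width reflects the breadth of real backbone H-bond wells and, in
  sampling, provides a capture gradient that lets the H-bond acceptance
  layer pull marginal contacts into place. Bonds below -0.5 kcal/mol are
  counted as "strong".

These are not a fit to any published force field; they preserve the
*algorithmic* behavior (clash rejection, H-bond seeking, finite-range pair
terms) and can be swapped wholesale through `energy_params()`.

## Ramachandran maps and torsion bins

Sampling runs on a permissive, point-symmetric glycine map so that any
amino acid (L or D) can later be threaded onto a backbone. The packaged
default is an analytic approximation: the union of six circular basins of
radius 85 degrees centred on the torsion-bin centres
`(-61,-41), (61,41), (-135,135), (135,-135), (-61,141), (61,-141)`, with a
shallow quadratic bowl in each basin (0 at the centre, 2 at the rim) and
infinite energy outside. The construction is symmetric under
`(phi, psi) -> (-phi, -psi)` by design, matching the mirror relation of
L- and D-amino acids; generic residues get the three `phi < 0` basins
(radius 70), proline a two-basin map of radius 40, and D forms the point
reflection. The exact statistical maps used in structure-prediction
pipelines are not redistributed here; any map in the plain-text grid
format of `read_rama_grid()` can be dropped in.

The six basin centres double as the torsion-bin scheme: every residue is
assigned the nearest centre under the toroidal metric, giving each
conformation a length-`n` bin string over the alphabet 1..6. Strings that
differ by a cyclic rotation describe the same ring, so classes are keyed
by the lexicographically smallest rotation. The number of rotation-unique
assignments is the classic necklace count `(1/n) * sum_i 6^gcd(i, n)` —
39,996 for `n = 7` — and `enumerate_initial_configurations()` generates
exactly one representative per class (or a seeded sample when the count
exceeds the requested limit).

## Layered simulated annealing

Each step proposes, for every residue independently, a uniform
displacement in a disk of radius `k_t` in `(phi, psi)`; proposals landing
in a prohibited map region keep that residue's old torsions. The new
configuration then faces an ordered stack of Metropolis tests — cheap
first: Ramachandran, repulsion, cyclic error, H-bond energy, and (for
small rings) the miscellaneous pair terms. A test passes if the layer
energy decreased, is below the layer threshold, or with probability
`exp((E_cur - E_new)/T_t)`; any failure rejects the move without
evaluating later layers. Configurations that are closed
(cyclic error <= 0.01), clash-free (repulsion <= 0.5 per residue) and
hold at least `max(2, ceiling(n/5))` strong H-bonds are recorded as good
backbone candidates.

The default schedule was chosen from desk-scale pilot runs and is the
point where genuinely open design decisions live:

* 50,000 steps; move radius decaying geometrically from 30 to 0.5
  degrees, so most of the run is spent at the small radii where the
  closure manifold can actually be explored;
* per-layer geometric cooling (rama 5 -> 0.5, rep 10 -> 0.5,
  cyclic 0.5 -> 1e-5, hbond 2 -> 0.05, misc 2 -> 0.3);
* an *annealed* cyclic-error threshold, 20 -> 2e-4 geometrically. This is
  the load-bearing choice: with a fixed tight threshold the chain freezes
  into whatever (usually H-bond-free) closed shape it first finds, while a
  narrowing "closure tube" lets hydrogen bonds nucleate among loosely
  closed states early and then squeezes the ring shut around them.

Runs from one initial configuration that record nothing are repeated (at
most three runs in total). All schedules, thresholds and criteria are
plain lists the user can override; the compiled inner loop and the
reference R loop implement identical semantics, and the reference engine
remains available via `run_annealing(..., engine = "reference")`.

The sampler is explicitly not a thermodynamic-ensemble method: the layer
stack is a rejection cascade designed to find low-energy closed states
quickly, not to sample a Boltzmann distribution.

## Stability analysis

For a designed sequence, stability is judged from an energy landscape: a
set of alternative conformations with energies and RMSDs to the design.
Backbone-heavy-atom RMSD (N, CA, C', O) uses the Kabsch superposition;
because a ring has no distinguished first residue, `cyclic_min_rmsd()`
minimizes over all `n` cyclic relabelings. The funnel statistic

    PNear = sum_i exp(-rmsd_i^2/lambda^2) exp(-E_i/kT) / sum_j exp(-E_j/kT)

uses `kT = 0.62` kcal/mol and a size-classed funnel width `lambda` (0.5
Angstrom up to 7 residues, 1.5 up to 15, 2.0 beyond), computed in log
space so energy scales spanning tens of kcal/mol cannot overflow; values
above 0.9 are read as stable.

Small rings are screened by *Ramachandran-stability filtering*: the
designed sequence is threaded onto every pooled poly-glycine backbone at
all `n` cyclic offsets, and an offset survives only if every residue's
torsions are allowed for the amino acid (with its chirality) at that
position. Pools built this way mix distinct backbones, so their RMSDs use
the cyclic-minimized form; landscapes of a single labeled sequence (the
genetic algorithm's) use fixed-labeling RMSD when a native reference is
supplied.

`reshape_landscape()` re-centres a landscape on its lowest-energy
conformation and recomputes all RMSDs — the device used to find stable
*alternative* states when the deepest sampled funnel is off-design.
Compactness analytics (`backbone_radius()`, `hbond_intersections()`)
quantify the observation that rings whose H-bond chords cross tend to be
more compact.

## ClusterGen

For larger rings the landscape is generated by a genetic algorithm over
closed conformations:

1. **Seeding.** Backbones from the layered annealer (plus, when a native
   structure is given, a two-layer low-RMSD annealer that tests only the
   cyclic error and a Metropolis criterion on RMSD-to-reference) are
   relaxed and greedily clustered; the `2 * N_GA(0)` lowest-energy cluster
   centres form the population. In prediction mode the low-RMSD seeding is
   dropped so sequence is the only input.
2. **Variation.** Crossover swaps the torsions of a random cyclic window
   (2 to n/2 residues) between parents; mutation perturbs a window's
   torsions within the allowed map (up to ten redraws per residue). Both
   operators break closure at the window edges, so every offspring is
   re-closed by local minimization of the cyclic error and discarded if
   that fails — the closure gate.
3. **Selection.** Children are relaxed by the internal surrogate for a
   full-atom Cartesian relax — bounded L-BFGS-B over all torsions of
   `E_total + 1000 * E_cyc` (the weight keeps closure violations at the
   1e-3 scale of the energies) — then parents and children are sorted by
   energy and greedily clustered: walking upward in energy, a structure
   becomes a new centre only if it is at least the RMSD cutoff from every
   existing centre. The `N_GA(i)` lowest-energy centres form the next
   generation, so the best energy never increases.
4. **Recording.** Every selected centre with energy below the recording
   ceiling (0 by default) joins the landscape.

Published-scale profiles run 50 generations with `N_GA` constant at 500
(15 residues) or shrinking as `750 - 5i` (20) and `1000 - 10i` (24); the
`toy` profile (15 generations, `N_GA = 50`, direct closure seeding) is the
desk-scale configuration exercised by the test suite. Structure prediction
clusters the 50 lowest-energy records at 1.5 Angstrom and returns the
(at most) five lowest-energy centres.

## Free-energy surfaces

`free_energy_surface()` histogramms (RMSD, radius-of-gyration) samples on
a 50 x 50 grid and reports `F = -RT ln P` on occupied cells, empty cells
masked. `P` is probability mass per cell, so `sum(exp(-F/RT)) = 1` and the
global minimum sits in the modal cell. Changing length units rescales the
bin edges but only shifts `F` by an additive constant; the grid metadata
records this caveat. The radius of gyration is unweighted by default
(backbone atoms treated as equal masses), with mass weights available.

## Synthetic data and what passing tests show

Everything the tests consume is generated in code by
`fixture_generator()`: closed toy backbones (local closure from bin-centre
starts), an open helical segment whose i,i+3/i,i+4 hydrogen bonds exist by
construction, a two-funnel landscape built from two genuinely distant
closed rings with the deeper funnel off-native, a planted-minimum toy
system (per-residue quadratic torsion wells of width 60 degrees and depth
20 kcal/mol centred on a known closed 6-residue ring; its unique global
minimum is the planted state and basin energies are negative, so the
recording ceiling behaves as in production), and seeded bivariate clouds
for the FES. Problem sizes throughout are desk-scale choices: rings of
4-10 residues, 200 annealing starts, 10 genetic-algorithm seeds at 15
generations with populations of 50.

These fixtures emulate the *mechanics* of the method — closure, H-bond
topology, funnel shapes, recovery of a known minimum — not the physics of
real peptides: the energy surrogate is not a published force field, the
analytic Ramachandran maps are approximations, and no solvent or
side-chain chemistry exists anywhere in the package. A passing suite
therefore certifies the algorithms and their contracts, not the
thermodynamic accuracy of any particular designed molecule. Interfaces for
full-atom refinement exist (`write_pdb()` exports, landscape tables
re-import) so external relaxation and scoring tools can replace the
surrogates where real designs are at stake.

## Known limitations

* Bond lengths, angles and `omega` are frozen at ideal values; the
  sampler cannot express the small deviations real backbones use to
  relieve strain (5-residue rings, for instance, close only rarely).
* The analytic maps have hard circular boundaries; statistical maps have
  softer, irregular ones. Soft continuation outside the allowed region is
  quadratic, chosen for optimizer friendliness, not physics.
* The annealed-threshold schedule was tuned at n = 7; larger rings may
  want longer runs or different tube schedules (all exposed in
  `anneal_schedule()`).
* Necklace counts above n = 20 exceed exact double-precision integers and
  are returned as the nearest double with a warning.
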