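# Rigid-geometry backbone kinematics: local frames, the per-residue
# transformation, forward coordinate generation, and the cyclic error
# function. All user-facing angles are degrees; radians are used at the
# compiled boundary.

#' Ideal backbone bond geometry
#'
#' Fixed bond lengths, bond angles and the peptide-bond torsion used by the
#' torsion-space kinematics. Defaults are the standard ideal values for
#' protein backbones: d(N-CA) = 1.458, d(CA-C') = 1.524, d(C'-N) = 1.329
#' Angstrom; bond angles 121.7 (at N), 111.2 (at CA), 116.2 (at C') degrees;
#' omega fixed at 180 degrees (trans peptide bond).
#'
#' @param d_n,d_ca,d_cp bond lengths N-CA, CA-C', C'-N in Angstrom.
#' @param theta_n,theta_ca,theta_cp bond angles at N, CA, C' in degrees.
#' @param omega peptide-bond torsion in degrees.
#' @return an object of class `ideal_geometry`.
#' @export
ideal_geometry <- function(d_n = 1.458, d_ca = 1.524, d_cp = 1.329,
                           theta_n = 121.7, theta_ca = 111.2,
                           theta_cp = 116.2, omega = 180) {
  lens <- c(d_n, d_ca, d_cp)
  angs <- c(theta_n, theta_ca, theta_cp)
  if (any(!is.finite(lens)) || any(lens <= 0))
    stop("bond lengths must be positive")
  if (any(!is.finite(angs)) || any(angs <= 0) || any(angs > 180))
    stop("bond angles must lie in (0, 180] degrees")
  structure(list(d_n = d_n, d_ca = d_ca, d_cp = d_cp,
                 theta_n = theta_n, theta_ca = theta_ca,
                 theta_cp = theta_cp, omega = omega),
            class = "ideal_geometry")
}

# pack geometry for the compiled layer (lengths in Angstrom, angles radians)
geom_vec <- function(geom) {
  c(geom$d_n, geom$d_ca, geom$d_cp,
    deg2rad(geom$theta_n), deg2rad(geom$theta_ca), deg2rad(geom$theta_cp),
    deg2rad(geom$omega))
}

#' Torsion-space conformation of a cyclic peptide backbone
#'
#' The sampler's state: per-residue (phi, psi) torsions in degrees plus the
#' fixed ideal bond geometry. Angles are wrapped to (-180, 180].
#'
#' @param phi,psi numeric vectors of equal length (>= 3), degrees.
#' @param geometry an [ideal_geometry()] object.
#' @return an object of class `torsion_conformation`.
#' @export
torsion_conformation <- function(phi, psi, geometry = ideal_geometry()) {
  if (length(phi) != length(psi)) stop("phi and psi must have equal length")
  if (length(phi) < 3) stop("need at least 3 residues")
  if (!inherits(geometry, "ideal_geometry")) stop("invalid geometry")
  structure(list(n = length(phi), phi = wrap_angle(phi),
                 psi = wrap_angle(psi), geometry = geometry),
            class = "torsion_conformation")
}

#' @export
print.torsion_conformation <- function(x, ...) {
  cat("Cyclic backbone torsions:", x$n, "residues\n")
  print(round(rbind(phi = x$phi, psi = x$psi), 2))
  invisible(x)
}

#' In-plane bend rotation used by the frame chain
#'
#' The counterclockwise xy-plane rotation by `180 - theta` degrees that
#' realigns the local x-axis along the next bond after bending at an atom
#' with bond angle `theta`.
#'
#' @param theta bond angle in degrees, in (0, 180].
#' @return a 3x3 rotation matrix.
#' @export
plane_rotation <- function(theta) {
  if (!is.finite(theta) || theta <= 0 || theta > 180)
    stop("theta must lie in (0, 180] degrees")
  a <- deg2rad(180 - theta)
  ca <- cos(a); sa <- sin(a)
  matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3, 3)
}

#' Torsion rotation about the local bond axis
#'
#' Counterclockwise yz-plane rotation by `phi` degrees; leaves the x-axis
#' (the bond direction) fixed.
#'
#' @param phi torsion angle in degrees.
#' @return a 3x3 rotation matrix.
#' @export
torsion_rotation <- function(phi) {
  a <- deg2rad(phi)
  ca <- cos(a); sa <- sin(a)
  matrix(c(1, 0, 0, 0, ca, sa, 0, -sa, ca), 3, 3)
}

#' Per-residue displacement vector q
#'
#' The displacement of one residue's alpha carbon relative to the previous
#' one, expressed in the local frame: q = T(thetaC') R(omega) T(thetaN)
#' [dN,0,0]' + T(thetaC') [dC',0,0]' + [dCA,0,0]'. For the default ideal
#' geometry q = (3.5620, 1.3322, 0).
#'
#' @param geom an [ideal_geometry()] object.
#' @return numeric length-3 vector in Angstrom.
#' @export
step_vector <- function(geom = ideal_geometry()) {
  as.numeric(.cpp_step_vector(geom_vec(geom)))
}

#' Per-residue frame rotation matrix
#'
#' M(phi, psi) = T(thetaC') R(omega) T(thetaN) R(phi) T(thetaCA) R(psi),
#' the net rotation carried by one residue of the cyclic frame chain.
#'
#' @param phi,psi torsions in degrees.
#' @param geom an [ideal_geometry()] object.
#' @return a 3x3 rotation matrix (orthonormal, det +1).
#' @export
residue_matrix <- function(phi, psi, geom = ideal_geometry()) {
  .cpp_residue_matrix(deg2rad(phi), deg2rad(psi), geom_vec(geom))
}

#' Cyclic closure error
#'
#' Non-negative scalar that is zero exactly when the torsion assignment
#' yields a closed backbone whose terminal local frame matches the initial
#' one: the squared norm of the accumulated ring displacement (Angstrom^2)
#' plus the squared mismatches of the terminal frame's x and y axes
#' (dimensionless), combined without re-weighting.
#'
#' @param conf a [torsion_conformation()] (n >= 3).
#' @return non-negative numeric scalar.
#' @export
cyclic_error <- function(conf) {
  stopifnot(inherits(conf, "torsion_conformation"))
  .cpp_cyclic_error(deg2rad(conf$phi), deg2rad(conf$psi),
                    geom_vec(conf$geometry))
}

# raw torsions in degrees -> cyclic error (no object overhead; SA hot path)
cyclic_error_raw <- function(phi, psi, gv) {
  .cpp_cyclic_error(deg2rad(phi), deg2rad(psi), gv)
}

#' Backbone structure container
#'
#' Cartesian coordinates (Angstrom) for backbone atoms N, CA, C', O and
#' amide H of an n-residue ring. O/H rows may be NA when not placed
#' (H is NA at proline positions when the sequence is known).
#'
#' @param N,CA,C,O,H n x 3 coordinate matrices (O, H optional).
#' @param provenance optional [torsion_conformation()] the coordinates were
#'   built from.
#' @return an object of class `backbone_structure`.
#' @export
backbone_structure <- function(N, CA, C, O = NULL, H = NULL,
                               provenance = NULL) {
  n <- nrow(N)
  stopifnot(nrow(CA) == n, nrow(C) == n)
  structure(list(n = n, N = N, CA = CA, C = C, O = O, H = H,
                 provenance = provenance),
            class = "backbone_structure")
}

#' @export
print.backbone_structure <- function(x, ...) {
  cat("Backbone structure:", x$n, "residues;",
    if (is.null(x$O)) "O not placed;" else "O placed;",
    if (is.null(x$H)) "H not placed\n" else "H placed\n")
  invisible(x)
}

# stack selected atoms residue-by-residue into an (n*k) x 3 matrix
heavy_coords <- function(struct, atoms = c("N", "CA", "C", "O")) {
  mats <- lapply(atoms, function(a) struct[[a]])
  if (any(vapply(mats, is.null, logical(1))))
    stop("requested atoms not present in structure")
  n <- struct$n
  out <- matrix(NA_real_, n * length(atoms), 3)
  for (k in seq_len(n))
    for (j in seq_along(atoms))
      out[(k - 1) * length(atoms) + j, ] <- mats[[j]][k, ]
  out
}

#' Generate Cartesian backbone coordinates from torsions
#'
#' Composes the per-atom local frame transforms of the cyclic frame chain
#' (anchored at the alpha carbon of residue n, as the closure error is) and
#' places carbonyl O and amide H by the planar ideal-geometry rule:
#' O in the CA-C'-N(next) plane opposite N with d(C'=O) = 1.231 Angstrom and
#' angle CA-C'-O = 120.1 degrees; H in the peptide plane bisecting
#' C'(prev)-N-CA with d(N-H) = 1.010 Angstrom. The first atom (N of residue
#' 1) is translated to the origin.
#'
#' @param conf a [torsion_conformation()].
#' @param place_oh logical; also place O and H atoms (default TRUE).
#' @return a [backbone_structure()].
#' @export
forward_kinematics <- function(conf, place_oh = TRUE) {
  stopifnot(inherits(conf, "torsion_conformation"))
  bb <- .cpp_forward_kin(deg2rad(conf$phi), deg2rad(conf$psi),
                         geom_vec(conf$geometry))
  n <- conf$n
  idx <- function(k) 3 * (seq_len(n) - 1) + k
  N <- t(bb[, idx(1), drop = FALSE])
  CA <- t(bb[, idx(2), drop = FALSE])
  C <- t(bb[, idx(3), drop = FALSE])
  O <- H <- NULL
  if (place_oh) {
    oh <- .cpp_place_oh(bb, 1.231, deg2rad(120.1), 1.010)
    O <- t(oh[, seq_len(n), drop = FALSE])
    H <- t(oh[, n + seq_len(n), drop = FALSE])
  }
  backbone_structure(N, CA, C, O, H, provenance = conf)
}

#' Dihedral angle of four points
#'
#' Standard signed dihedral (degrees) about the b-c axis using the atan2
#' convention. Errors on degenerate (collinear) geometry instead of
#' returning NaN.
#'
#' @param a,b,c,d numeric length-3 coordinate vectors.
#' @return angle in degrees in (-180, 180].
#' @export
dihedral_angle <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  if (sqrt(sum(n1^2)) < 1e-9 || sqrt(sum(n2^2)) < 1e-9)
    stop("degenerate (collinear) geometry in dihedral computation")
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1])
  nb2 <- sqrt(sum(b2^2))
  wrap_angle(rad2deg(atan2(sum(m1 / nb2 * n2), sum(n1 * n2))))
}

#' Measure backbone torsions from Cartesian coordinates
#'
#' Inverse of [forward_kinematics()] on ideal-geometry structures. Dihedrals
#' use the cyclic neighbour convention: phi_1 is measured against C' of
#' residue n and psi_n against N of residue 1, so the identity holds exactly
#' for closed rings (and for all non-seam torsions of open chains).
#'
#' @param struct a [backbone_structure()] with all N/CA/C atoms present.
#' @param geometry geometry to attach to the result.
#' @return a [torsion_conformation()].
#' @export
measure_torsions <- function(struct, geometry = ideal_geometry()) {
  stopifnot(inherits(struct, "backbone_structure"))
  n <- struct$n
  if (anyNA(struct$N) || anyNA(struct$CA) || anyNA(struct$C))
    stop("missing backbone atoms: cannot measure torsions")
  phi <- psi <- numeric(n)
  for (k in seq_len(n)) {
    prev <- if (k == 1) n else k - 1
    nxt <- if (k == n) 1 else k + 1
    phi[k] <- dihedral_angle(struct$C[prev, ], struct$N[k, ],
                             struct$CA[k, ], struct$C[k, ])
    psi[k] <- dihedral_angle(struct$N[k, ], struct$CA[k, ],
                             struct$C[k, ], struct$N[nxt, ])
  }
  torsion_conformation(phi, psi, geometry)
}

#' Close a backbone by local minimization of the cyclic error
#'
#' Finds an exactly closed conformation near a starting point by
#' derivative-based local minimization of the cyclic error over all 2n
#' torsions (BFGS with a Nelder-Mead fallback). Deterministic for a fixed
#' RNG state; restarts jitter the start using the current RNG stream.
#'
#' @param initial a [torsion_conformation()] (n >= 4).
#' @param tolerance accept when cyclic error <= tolerance.
#' @param max_restarts jittered restarts before giving up.
#' @param maxit iteration budget per optimizer call.
#' @return a closed [torsion_conformation()] with attribute `cyclic_error`.
#' @export
close_backbone <- function(initial, tolerance = 1e-8, max_restarts = 5,
                           maxit = 500) {
  stopifnot(inherits(initial, "torsion_conformation"))
  if (initial$n < 4) stop("need at least 4 residues to close")
  gv <- geom_vec(initial$geometry)
  n <- initial$n
  fn <- function(x) .cpp_cyclic_error(x[seq_len(n)], x[n + seq_len(n)], gv)
  start <- deg2rad(c(initial$phi, initial$psi))
  if (fn(start) <= tolerance) {
    attr(initial, "cyclic_error") <- fn(start)
    return(initial)
  }
  best <- NULL; bestval <- Inf
  x0 <- start
  for (r in seq_len(max_restarts + 1)) {
    o1 <- stats::optim(x0, fn, method = "BFGS",
                       control = list(maxit = maxit, reltol = 1e-14))
    o2 <- stats::optim(o1$par, fn, method = "Nelder-Mead",
                       control = list(maxit = maxit, reltol = 1e-14))
    o3 <- stats::optim(o2$par, fn, method = "BFGS",
                       control = list(maxit = maxit, reltol = 1e-14))
    if (o3$value < bestval) { bestval <- o3$value; best <- o3$par }
    if (bestval <= tolerance) break
    x0 <- start + stats::rnorm(2 * n, sd = 0.3)
  }
  if (bestval > tolerance)
    stop(sprintf(
      "close_backbone did not converge: cyclic error %.3g > tolerance %.3g",
      bestval, tolerance))
  out <- torsion_conformation(rad2deg(best[seq_len(n)]),
                              rad2deg(best[n + seq_len(n)]),
                              initial$geometry)
  attr(out, "cyclic_error") <- bestval
  out
}
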