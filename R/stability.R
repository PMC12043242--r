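# Stability machinery: Kabsch RMSD with cyclic residue relabeling, the
# PNear folding-funnel statistic, Ramachandran-stability filtering for
# small macrocycles, landscape reshaping, compactness and H-bond topology
# analytics, and free-energy-surface histogramming.

#' Kabsch backbone RMSD
#'
#' Minimal RMSD over rigid superposition (rotation + translation, no
#' reflection) of backbone heavy atoms N, CA, C', O.
#'
#' @param a,b [backbone_structure()]s with equal residue counts.
#' @param atoms atoms to superpose.
#' @return RMSD in Angstrom.
#' @export
kabsch_rmsd <- function(a, b, atoms = c("N", "CA", "C", "O")) {
  if (a$n != b$n) stop("residue count mismatch")
  .cpp_kabsch_rmsd(heavy_coords(a, atoms), heavy_coords(b, atoms))
}

#' Minimum RMSD over cyclic residue relabelings
#'
#' Because the backbone is a ring, structure identity is defined modulo a
#' cyclic renumbering of residues; all n relabelings of `b` are
#' superposed against `a` and the best is returned.
#'
#' @param a,b [backbone_structure()]s with equal residue counts.
#' @param atoms atoms to superpose.
#' @return list with `rmsd` (Angstrom) and `offset` (0-based: residue i of
#'   `a` matches residue i + offset of `b`).
#' @export
cyclic_min_rmsd <- function(a, b, atoms = c("N", "CA", "C", "O")) {
  if (a$n != b$n) stop("residue count mismatch")
  .cpp_cyclic_min_rmsd(heavy_coords(a, atoms), heavy_coords(b, atoms),
                       a$n, length(atoms))
}

#' Energy landscape container
#'
#' Records of (id, energy, RMSD-to-native) describing the sampled
#' conformational ensemble of one sequence, plus the Boltzmann parameters
#' of the PNear statistic. lambda defaults follow the macrocycle size
#' class: 0.5 Angstrom for small (n <= 7), 1.5 for medium (n <= 15), 2.0
#' for large rings; kT = 0.62 kcal/mol (37 C).
#'
#' @param energy,rmsd numeric vectors (kcal/mol, Angstrom).
#' @param id optional record ids.
#' @param native optional reference [backbone_structure()].
#' @param conformations optional list of structures or conformations
#'   behind the records (needed for reshaping).
#' @param lambda funnel width, Angstrom.
#' @param kT Boltzmann factor, kcal/mol.
#' @return an object of class `energy_landscape`.
#' @export
energy_landscape <- function(energy, rmsd, id = NULL, native = NULL,
                             conformations = NULL, lambda = NULL,
                             kT = 0.62) {
  stopifnot(length(energy) == length(rmsd))
  if (any(rmsd < 0, na.rm = TRUE)) stop("rmsd must be non-negative")
  if (is.null(lambda)) {
    n <- if (!is.null(native)) native$n else NA
    lambda <- if (is.na(n)) 1.5 else default_lambda(n)
  }
  structure(list(records = data.frame(
    id = id %||% seq_along(energy), energy = energy, rmsd = rmsd),
    native = native, conformations = conformations,
    lambda = lambda, kT = kT),
    class = "energy_landscape")
}

#' Default PNear funnel width by ring size
#'
#' @param n residue count.
#' @return lambda in Angstrom: 0.5 (n <= 7), 1.5 (n <= 15), 2.0 otherwise.
#' @export
default_lambda <- function(n) if (n <= 7) 0.5 else if (n <= 15) 1.5 else 2.0

#' @export
print.energy_landscape <- function(x, ...) {
  cat(sprintf("Energy landscape: %d records, lambda = %.2f A, kT = %.2f\n",
              nrow(x$records), x$lambda, x$kT))
  invisible(x)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' PNear folding-funnel statistic
#'
#' Boltzmann-weighted measure of how much of the ensemble's thermodynamic
#' weight lies near the native structure:
#' PNear = sum_i exp(-RMSD_i^2/lambda^2) exp(-E_i/kT) / sum_j exp(-E_j/kT),
#' computed in log space so that energies spanning tens of kcal/mol do not
#' overflow. Invariant to adding a constant to all energies; in (0, 1];
#' values above 0.9 indicate a stable design.
#'
#' @param landscape an [energy_landscape()], or a numeric energy vector.
#' @param rmsd,lambda,kT used when `landscape` is a plain vector.
#' @return numeric scalar in (0, 1].
#' @export
pnear <- function(landscape, rmsd = NULL, lambda = NULL, kT = 0.62) {
  if (inherits(landscape, "energy_landscape")) {
    e <- landscape$records$energy
    r <- landscape$records$rmsd
    lambda <- lambda %||% landscape$lambda
    kT <- landscape$kT
  } else {
    e <- landscape
    r <- rmsd
  }
  if (length(e) == 0) stop("empty landscape")
  if (is.null(lambda) || lambda <= 0) stop("lambda must be positive")
  if (kT <= 0) stop("kT must be positive")
  exp(logsumexp(-r^2 / lambda^2 - e / kT) - logsumexp(-e / kT))
}

#' Ramachandran-stability filter for threading a sequence onto backbones
#'
#' For each pooled backbone candidate and each of its n cyclic threading
#' offsets, the candidate is kept iff every residue's (phi, psi) lies in
#' the allowed Ramachandran region of the amino acid threaded at that
#' position (L/D mirroring applied). The output is the landscape-ready set
#' of compatible (candidate, offset) pairs.
#'
#' @param sequence chirality-coded string (uppercase L, lowercase D),
#'   length = n of the pool members.
#' @param pool list of candidates (each with a `conformation`) or of
#'   [torsion_conformation()]s.
#' @return data.frame with columns `candidate` (index into pool) and
#'   `offset` (0-based: sequence position 1 sits at backbone residue
#'   1 + offset); attribute `tests` counts offset tests performed.
#' @export
rama_stability_filter <- function(sequence, pool) {
  aas <- strsplit(sequence, "")[[1]]
  n <- length(aas)
  maps <- lapply(aas, map_for_residue)
  tests <- 0L
  rows <- list()
  for (ci in seq_along(pool)) {
    conf <- pool[[ci]]$conformation %||% pool[[ci]]
    if (conf$n != n) stop("sequence length does not match pool member ", ci)
    for (off in 0:(n - 1)) {
      tests <- tests + 1L
      ok <- TRUE
      for (r in seq_len(n)) {
        # backbone residue r carries sequence position (r - off) mod n
        sp <- ((r - 1 - off) %% n) + 1
        if (!rama_allowed(maps[[sp]], conf$phi[r], conf$psi[r])) {
          ok <- FALSE
          break
        }
      }
      if (ok) rows[[length(rows) + 1]] <- c(ci, off)
    }
  }
  out <- if (length(rows)) {
    m <- do.call(rbind, rows)
    data.frame(candidate = m[, 1], offset = m[, 2])
  } else data.frame(candidate = integer(0), offset = integer(0))
  attr(out, "tests") <- tests
  out
}

#' Reshape a landscape around its lowest-energy structure
#'
#' Re-designates the lowest-energy sampled conformation as the native
#' state and recomputes every record's RMSD against it; energies are
#' unchanged. Used to find stable alternative states when the deepest
#' funnel is off-native.
#'
#' @param landscape an [energy_landscape()] whose `conformations` are
#'   retrievable.
#' @param method `"cyclic"` (minimum over cyclic relabelings, default) or
#'   `"fixed"` (fixed residue labeling).
#' @return a new [energy_landscape()].
#' @export
reshape_landscape <- function(landscape, method = c("cyclic", "fixed")) {
  method <- match.arg(method)
  confs <- landscape$conformations
  if (is.null(confs)) stop("landscape lacks stored conformations")
  as_struct <- function(x)
    if (inherits(x, "backbone_structure")) x else forward_kinematics(x)
  best <- which.min(landscape$records$energy)
  native <- as_struct(confs[[best]])
  rmsd <- vapply(confs, function(x) {
    s <- as_struct(x)
    if (method == "cyclic") cyclic_min_rmsd(native, s)$rmsd
    else kabsch_rmsd(native, s)
  }, numeric(1))
  energy_landscape(landscape$records$energy, rmsd,
                   id = landscape$records$id, native = native,
                   conformations = confs, lambda = landscape$lambda,
                   kT = landscape$kT)
}

#' Backbone root-mean-square radius
#'
#' RMS distance of the backbone heavy atoms (N, CA, C', O) from their
#' centroid; a compactness measure, invariant under rigid motion.
#'
#' @param struct a [backbone_structure()].
#' @param atoms atoms included.
#' @return radius in Angstrom.
#' @export
backbone_radius <- function(struct, atoms = c("N", "CA", "C", "O")) {
  atoms <- atoms[!vapply(atoms, function(a) is.null(struct[[a]]),
                         logical(1))]
  xyz <- heavy_coords(struct, atoms)
  ctr <- colMeans(xyz)
  sqrt(mean(rowSums((xyz - matrix(ctr, nrow(xyz), 3, byrow = TRUE))^2)))
}

#' Count crossing H-bond chords on the backbone ring
#'
#' Drawing each H-bond as a chord of the residue cycle, two bonds (i, j)
#' and (k, l) cross iff exactly one of k, l lies strictly between i and j
#' in cyclic order; bonds sharing an endpoint do not cross.
#'
#' @param bonds data.frame with `donor`, `acceptor` residue indices.
#' @param n residue count.
#' @return integer crossing count.
#' @export
hbond_intersections <- function(bonds, n) {
  if (nrow(bonds) == 0) return(0L)
  if (any(bonds$donor < 1 | bonds$donor > n |
          bonds$acceptor < 1 | bonds$acceptor > n))
    stop("residue index out of range")
  between <- function(x, i, j) {
    # strictly between i and j walking forward i -> j on the cycle
    if (i == j) return(FALSE)
    d_ij <- (j - i) %% n
    d_ix <- (x - i) %% n
    d_ix > 0 && d_ix < d_ij
  }
  cnt <- 0L
  m <- nrow(bonds)
  if (m < 2) return(0L)
  for (a in 1:(m - 1)) for (b in (a + 1):m) {
    i <- bonds$donor[a]; j <- bonds$acceptor[a]
    k <- bonds$donor[b]; l <- bonds$acceptor[b]
    if (length(intersect(c(i, j), c(k, l))) > 0) next
    if (xor(between(k, i, j), between(l, i, j))) cnt <- cnt + 1L
  }
  cnt
}

#' Radius of gyration of a coordinate set
#'
#' Unweighted by default (all atoms equal mass); optional masses.
#'
#' @param coords m x 3 matrix, Angstrom.
#' @param masses optional length-m weights.
#' @return Rg in Angstrom.
#' @export
radius_of_gyration <- function(coords, masses = NULL) {
  coords <- rbind(coords)
  w <- masses %||% rep(1, nrow(coords))
  w <- w / sum(w)
  ctr <- colSums(coords * w)
  sqrt(sum(w * rowSums((coords - matrix(ctr, nrow(coords), 3,
                                        byrow = TRUE))^2)))
}

#' Free-energy surface over (RMSD, Rg)
#'
#' 2D probability histogram of the samples with 50 bins per dimension;
#' F = -RT ln P on occupied cells, with empty cells masked (NA). The
#' global minimum of F sits at the most-populated cell and
#' sum(exp(-F/RT)) = 1 over occupied cells.
#'
#' @param rmsd,rg equal-length sample vectors.
#' @param temperature Kelvin.
#' @param bins bins per dimension.
#' @return object of class `fes_grid`: list with `rmsd_edges`, `rg_edges`,
#'   `free_energy` (bins x bins, kcal/mol), `prob`, `temperature`, `RT`.
#'   Metadata note: bin shape is unit-invariant; histogramming in other
#'   length units shifts F by a constant only.
#' @export
free_energy_surface <- function(rmsd, rg, temperature = 300, bins = 50) {
  if (length(rmsd) == 0 || length(rmsd) != length(rg))
    stop("rmsd and rg must be equal-length, nonempty")
  R <- 0.00198720425864083 # kcal / (mol K)
  RT <- R * temperature
  pad <- function(x) {
    rng <- range(x)
    if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
    rng
  }
  re <- seq(pad(rmsd)[1], pad(rmsd)[2], length.out = bins + 1)
  ge <- seq(pad(rg)[1], pad(rg)[2], length.out = bins + 1)
  bi <- pmin(pmax(findInterval(rmsd, re, rightmost.closed = TRUE), 1), bins)
  bj <- pmin(pmax(findInterval(rg, ge, rightmost.closed = TRUE), 1), bins)
  cnt <- matrix(0, bins, bins)
  for (s in seq_along(bi)) cnt[bi[s], bj[s]] <- cnt[bi[s], bj[s]] + 1
  P <- cnt / sum(cnt)
  FE <- -RT * log(P)
  FE[cnt == 0] <- NA
  structure(list(rmsd_edges = re, rg_edges = ge, free_energy = FE,
                 prob = P, temperature = temperature, RT = RT,
                 note = paste("F computed from probability mass per cell;",
                              "unit changes shift F by a constant")),
            class = "fes_grid")
}
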