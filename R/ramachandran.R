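# Symmetrized glycine Ramachandran map, per-amino-acid maps with L/D
# mirroring, the 6-bin partition, and initial-configuration enumeration.
#
# The exact published map grids are not reproduced here; the packaged
# defaults are a documented analytic approximation (union of circular
# basins around the six torsion-bin centers, point-symmetric by
# construction) at 10-degree resolution. Users may substitute any grid in
# the plain-text format read by read_rama_grid().

AA_CODES <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# default bin centers (degrees), labels 1..6; mirror partners are
# (1,2), (3,4), (5,6)
DEFAULT_BIN_CENTERS <- matrix(c(
  -61,  -41,   # 1: right-handed alpha
   61,   41,   # 2: left-handed alpha (mirror of 1)
 -135,  135,   # 3: beta / extended
  135, -135,   # 4: mirror beta
  -61,  141,   # 5: polyproline-II-like
   61, -141    # 6: mirror PPII
), ncol = 2, byrow = TRUE)

#' Six-bin partition of the Ramachandran map
#'
#' Bin centers (degrees) with membership by nearest center under the
#' toroidal metric. Labels are "1".."6"; mirror-image bins are paired
#' (1,2), (3,4), (5,6) so that D-residue torsions land in the partner of
#' their L mirror image.
#'
#' @param centers 6 x 2 matrix of (phi, psi) centers in degrees.
#' @return an object of class `torsion_bins`.
#' @export
torsion_bins <- function(centers = DEFAULT_BIN_CENTERS) {
  stopifnot(is.matrix(centers), ncol(centers) == 2)
  structure(list(centers = centers, k = nrow(centers),
                 mirror = c(2, 1, 4, 3, 6, 5)[seq_len(nrow(centers))]),
            class = "torsion_bins")
}

# analytic basin map: allowed iff min_c (d_c / r_c) <= 1; energy =
# scale * min_c (d_c / r_c)^2 (0 at centers, `scale` at the boundary)
make_basin_map <- function(centers, radii, scale = 2, step = 10,
                           label = "map") {
  nodes <- seq(-180, 180 - step, by = step)
  grid <- expand.grid(phi = nodes, psi = nodes)
  e <- basin_energy(grid$phi, grid$psi, centers, radii, scale)
  energy <- matrix(e, nrow = length(nodes))
  allowed <- energy <= scale
  energy[!allowed] <- Inf
  structure(list(step = step, phi = nodes, psi = nodes,
                 energy = energy, allowed = allowed,
                 centers = centers, radii = radii, scale = scale,
                 symmetrized = is_symmetric_centerset(centers, radii),
                 label = label),
            class = "rama_map")
}

basin_energy <- function(phi, psi, centers, radii, scale) {
  vals <- rep(Inf, length(phi))
  for (i in seq_len(nrow(centers))) {
    d <- toroidal_dist(phi, psi, centers[i, 1], centers[i, 2])
    vals <- pmin(vals, scale * (d / radii[i])^2)
  }
  vals
}

is_symmetric_centerset <- function(centers, radii) {
  m <- cbind(wrap_angle(-centers[, 1]), wrap_angle(-centers[, 2]))
  for (i in seq_len(nrow(centers))) {
    hit <- which(abs(angle_diff(m[, 1], centers[i, 1])) < 1e-9 &
                 abs(angle_diff(m[, 2], centers[i, 2])) < 1e-9 &
                 abs(radii - radii[i]) < 1e-9)
    if (length(hit) == 0) return(FALSE)
  }
  TRUE
}

#' Default symmetrized glycine Ramachandran map
#'
#' A permissive, point-symmetric map on a 10-degree grid: the union of
#' circular basins of radius 85 degrees around the six torsion-bin centers,
#' with a shallow quadratic energy bowl in each basin (0 at the center, 2
#' at the boundary) and infinite energy outside. Symmetry
#' energy(phi, psi) = energy(-phi, -psi) holds exactly by construction.
#'
#' @return an object of class `rama_map`.
#' @export
default_glycine_map <- function() {
  make_basin_map(DEFAULT_BIN_CENTERS, radii = rep(85, 6), label = "G")
}

#' Ramachandran map for a chirality-coded residue
#'
#' Uppercase letters are L-amino acids, lowercase are D; glycine ('G') is
#' achiral and returns the symmetric map. D maps are the point reflection
#' (phi, psi) -> (-phi, -psi) of the corresponding L map. Non-glycine,
#' non-proline residues share a generic three-basin L map; proline's map is
#' the smallest, glycine's the largest.
#'
#' @param aa single one-letter code; case encodes chirality.
#' @return an object of class `rama_map`.
#' @export
map_for_residue <- function(aa) {
  if (!is.character(aa) || length(aa) != 1 || nchar(aa) != 1)
    stop("aa must be a single one-letter code")
  up <- toupper(aa)
  if (!up %in% AA_CODES) stop("unknown amino acid code: ", aa)
  if (aa == "g") stop("glycine is achiral: no D form 'g'")
  if (up == "G") return(default_glycine_map())
  if (up == "P") {
    centers <- DEFAULT_BIN_CENTERS[c(1, 5), , drop = FALSE]
    radii <- c(40, 40)
  } else {
    centers <- DEFAULT_BIN_CENTERS[c(1, 3, 5), , drop = FALSE]
    radii <- c(70, 70, 70)
  }
  if (aa %in% letters) {  # D form: point reflection
    centers <- cbind(wrap_angle(-centers[, 1]), wrap_angle(-centers[, 2]))
  }
  make_basin_map(centers, radii, label = aa)
}

#' @export
print.rama_map <- function(x, ...) {
  cat(sprintf("Ramachandran map '%s': %d-degree grid, %.1f%% allowed%s\n",
              x$label, x$step, 100 * mean(x$allowed),
              if (isTRUE(x$symmetrized)) ", symmetrized" else ""))
  invisible(x)
}

#' Allowed-region membership of torsion points
#'
#' @param map a `rama_map`.
#' @param phi,psi numeric vectors, degrees.
#' @return logical vector.
#' @export
rama_allowed <- function(map, phi, psi) {
  if (!is.null(map$centers)) {
    vals <- basin_energy(wrap_angle(phi), wrap_angle(psi),
                         map$centers, map$radii, map$scale)
    return(vals <= map$scale)
  }
  i <- grid_index(map, phi)
  j <- grid_index(map, psi)
  map$allowed[cbind(i, j)]
}

grid_index <- function(map, x) {
  ((round((wrap_angle(x) + 180) / map$step)) %% length(map$phi)) + 1L
}

#' Ramachandran energy lookup
#'
#' Per-point energy in kcal/mol-scale units. Disallowed points return `Inf`
#' unless `soft = TRUE`, in which case the continuous quadratic
#' continuation outside the allowed region is returned (used by the local
#' relax surrogate, which cannot digest infinities).
#'
#' @param map a `rama_map`.
#' @param phi,psi numeric vectors, degrees.
#' @param soft logical; continue smoothly outside the allowed region.
#' @return numeric vector of energies.
#' @export
rama_energy <- function(map, phi, psi, soft = FALSE) {
  phi <- wrap_angle(phi); psi <- wrap_angle(psi)
  if (!is.null(map$centers)) {
    vals <- basin_energy(phi, psi, map$centers, map$radii, map$scale)
    if (!soft) vals[vals > map$scale] <- Inf
    return(vals)
  }
  # grid map: bilinear interpolation with periodic wrap
  np <- length(map$phi)
  fi <- (phi + 180) / map$step
  fj <- (psi + 180) / map$step
  i0 <- floor(fi); j0 <- floor(fj)
  wi <- fi - i0; wj <- fj - j0
  i0 <- (i0 %% np) + 1L; j0 <- (j0 %% np) + 1L
  i1 <- (i0 %% np) + 1L; j1 <- (j0 %% np) + 1L
  E <- if (soft) map$soft %||% fill_grid(map) else map$energy
  # zero-weight corners must not contribute (0 * Inf would poison the sum)
  term <- function(w, e) ifelse(w == 0, 0, w * e)
  term((1 - wi) * (1 - wj), E[cbind(i0, j0)]) +
    term(wi * (1 - wj), E[cbind(i1, j0)]) +
    term((1 - wi) * wj, E[cbind(i0, j1)]) +
    term(wi * wj, E[cbind(i1, j1)])
}

# replace Inf cells by increasing finite values via grid dilation so that
# soft lookups have a downhill path back into the allowed region
fill_grid <- function(map, bump = 1) {
  E <- map$energy
  E[!is.finite(E)] <- NA
  np <- nrow(E)
  while (anyNA(E)) {
    En <- E
    sh <- function(M, di, dj) M[((seq_len(np) - 1 + di) %% np) + 1,
                                ((seq_len(np) - 1 + dj) %% np) + 1]
    nb <- pmin(sh(E, 1, 0), sh(E, -1, 0), sh(E, 0, 1), sh(E, 0, -1),
               na.rm = TRUE)
    fillable <- is.na(E) & is.finite(nb)
    En[fillable] <- nb[fillable] + bump
    E <- En
  }
  E
}

#' Assign a torsion point to its bin
#'
#' Nearest bin center under the toroidal metric; ties break to the lowest
#' label. Points outside the allowed region of `map` (when given) still
#' receive the nearest-center label, with attribute `fallback` flagging
#' them.
#'
#' @param phi,psi numeric vectors, degrees.
#' @param scheme a [torsion_bins()] scheme.
#' @param map optional `rama_map` for the fallback flag.
#' @return integer labels in 1..6 (attribute `fallback`: logical vector).
#' @export
assign_bin <- function(phi, psi, scheme = torsion_bins(), map = NULL) {
  phi <- wrap_angle(phi); psi <- wrap_angle(psi)
  d <- sapply(seq_len(scheme$k), function(i)
    toroidal_dist(phi, psi, scheme$centers[i, 1], scheme$centers[i, 2]))
  d <- matrix(d, nrow = length(phi))
  lab <- apply(d, 1, which.min)
  out <- as.integer(lab)
  if (!is.null(map)) attr(out, "fallback") <- !rama_allowed(map, phi, psi)
  out
}

# --- initial-configuration combinatorics --------------------------------

gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)

#' Count rotation-unique initial bin assignments
#'
#' Number of equivalence classes of length-n strings over k torsion bins
#' under cyclic rotation (necklace counting):
#' (1/n) * sum_{i=1..n} k^gcd(i, n). For n = 7 and k = 6 this is 39,996.
#' Exact in double precision for k^n < 2^53 (n <= 20 at k = 6); larger n
#' return the nearest representable double with a warning.
#'
#' @param n residue count (>= 1).
#' @param k number of bins (default 6).
#' @return numeric count (integer-valued).
#' @export
count_unique_initial_configurations <- function(n, k = 6) {
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != round(n))
    stop("n must be a positive integer")
  if (k^n > 2^53)
    warning("k^n exceeds exact double-precision range; count is approximate")
  s <- sum(vapply(seq_len(n), function(i) k^gcd2(i, n), numeric(1)))
  s / n
}

# integer codes 0..k^n-1 <-> digit strings; rotation by one digit
rotate_code <- function(v, n, k = 6) {
  top <- k^(n - 1)
  (v %% top) * k + v %/% top
}

canonical_code <- function(v, n, k = 6) {
  best <- v
  w <- v
  for (r in seq_len(n - 1)) {
    w <- rotate_code(w, n, k)
    best <- pmin(best, w)
  }
  best
}

code_to_digits <- function(v, n, k = 6) {
  out <- matrix(0L, length(v), n)
  for (j in n:1) {
    out[, j] <- as.integer(v %% k)
    v <- v %/% k
  }
  out + 1L
}

#' Enumerate rotation-unique initial configurations
#'
#' Yields one representative conformation per rotation-equivalence class of
#' bin-center assignments. If the total class count is at most `limit`, all
#' classes are returned (canonical representatives in increasing order);
#' otherwise `limit` distinct classes are sampled with the given seed.
#' Each conformation's torsions are the chosen bin centers.
#'
#' @param n residue count (>= 3).
#' @param limit maximum number of configurations to return.
#' @param seed RNG seed used when sampling.
#' @param scheme a [torsion_bins()] scheme.
#' @param geometry geometry attached to the conformations.
#' @return list of [torsion_conformation()]s; attribute `strings` holds the
#'   canonical bin strings.
#' @export
enumerate_initial_configurations <- function(n, limit = Inf, seed = NULL,
                                             scheme = torsion_bins(),
                                             geometry = ideal_geometry()) {
  if (n < 3) stop("n must be >= 3")
  k <- scheme$k
  total <- count_unique_initial_configurations(n, k)
  if (total <= limit) {
    codes <- canonical_code(0:(k^n - 1), n, k)
    codes <- sort(unique(codes))
  } else {
    if (!is.null(seed)) set.seed(seed)
    codes <- numeric(0)
    while (length(codes) < limit) {
      draw <- floor(runif(limit, 0, k^n))
      codes <- unique(c(codes, canonical_code(draw, n, k)))
    }
    codes <- codes[seq_len(limit)]
  }
  digs <- code_to_digits(codes, n, k)
  confs <- lapply(seq_len(nrow(digs)), function(r) {
    torsion_conformation(scheme$centers[digs[r, ], 1],
                         scheme$centers[digs[r, ], 2], geometry)
  })
  attr(confs, "strings") <-
    apply(digs, 1, function(d) paste(d, collapse = ""))
  confs
}
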