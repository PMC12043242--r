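# Backbone energy terms: Ramachandran, repulsive, attractive, electrostatic,
# solvation and H-bond, under the >= 4-covalent-bond pair rule on the cyclic
# bond graph, with the Etotal weighting
# Etotal = 0.45 * Erama + Erep + Ehbond + Eother.
#
# The pairwise functional forms are documented package surrogates for a
# full-atom force field: a 12-6 Lennard-Jones split into its positive
# (repulsive) and negative (attractive) branches, Coulomb electrostatics
# with a distance-dependent dielectric, and a Lazaridis-Karplus style
# Gaussian-exclusion solvation term. All constants live in energy_params()
# and are swappable.

#' Energy model parameters
#'
#' One configuration block holding every constant of the backbone energy
#' surrogate: van der Waals radii and partial charges per atom type,
#' Lennard-Jones well depth, interaction cutoff, Coulomb constant
#' (dielectric = r), solvation parameters, and the H-bond detection and
#' scoring thresholds (detection: H..O < 2.5 Angstrom and N-H..O angle >
#' 120 degrees; depth -1.5 kcal/mol; "strong" below -0.5 kcal/mol).
#'
#' @param ... named overrides of the defaults.
#' @return a named list of class `energy_params`.
#' @export
energy_params <- function(...) {
  p <- list(
    radii = c(N = 1.55, CA = 1.70, C = 1.70, O = 1.52, H = 1.10),
    charges = c(N = -0.47, CA = 0.16, C = 0.51, O = -0.51, H = 0.31),
    lj_eps = 0.15,
    cutoff = 6,
    coulomb = 332.0637,
    dielectric = 4,  # scale of the distance-dependent dielectric (eps = D r)
    dg_free = c(N = -5.0, CA = 0.4, C = 1.0, O = -5.0, H = 0),
    volume = c(N = 4.4, CA = 23.7, C = 14.7, O = 10.8, H = 0),
    solv_lambda = 3.5,
    hb_dmax = 2.5, hb_angmin = 120, hb_depth = -1.5,
    hb_r0 = 2.0, hb_sigma = 0.6, hb_strong = -0.5,
    rama_weight = 0.45
  )
  dots <- list(...)
  for (nm in names(dots)) p[[nm]] <- dots[[nm]]
  structure(p, class = "energy_params")
}

# atom table of a structure for the pair machinery: coordinates, cyclic
# backbone chain position (0-based), branch offset and type code
atom_table <- function(struct, include_h = FALSE) {
  n <- struct$n
  xyz <- list(); bbpos <- c(); branch <- c(); type <- c()
  add <- function(M, pos, br, ty) {
    keep <- !is.na(M[, 1])
    xyz[[length(xyz) + 1]] <<- M[keep, , drop = FALSE]
    bbpos <<- c(bbpos, pos[keep]); branch <<- c(branch, rep(br, sum(keep)))
    type <<- c(type, rep(ty, sum(keep)))
  }
  add(struct$N, 3 * (seq_len(n) - 1), 0L, 0L)
  add(struct$CA, 3 * (seq_len(n) - 1) + 1L, 0L, 1L)
  add(struct$C, 3 * (seq_len(n) - 1) + 2L, 0L, 2L)
  if (!is.null(struct$O)) add(struct$O, 3 * (seq_len(n) - 1) + 2L, 1L, 3L)
  if (include_h && !is.null(struct$H))
    add(struct$H, 3 * (seq_len(n) - 1), 1L, 4L)
  list(xyz = t(do.call(rbind, xyz)), bbpos = as.integer(bbpos),
       branch = as.integer(branch), type = as.integer(type))
}

#' Nonbonded atom pairs of a cyclic backbone
#'
#' All and only heavy-atom pairs separated by at least 4 covalent bonds on
#' the cyclic bond graph (C' of residue n is bonded to N of residue 1).
#' Separations are computed from cyclic chain positions; O atoms hang one
#' bond off their C'.
#'
#' @param struct a [backbone_structure()].
#' @param atoms atom names to include.
#' @return data.frame with columns `i`, `j` (row indices into the stacked
#'   atom list), `atom_i`, `atom_j`, `res_i`, `res_j`, `bond_sep`.
#' @export
pair_list <- function(struct, atoms = c("N", "CA", "C", "O")) {
  n <- struct$n
  present <- atoms[!vapply(atoms, function(a) is.null(struct[[a]]),
                           logical(1))]
  pos <- c(N = 0L, CA = 1L, C = 2L, O = 2L)
  br <- c(N = 0L, CA = 0L, C = 0L, O = 1L)
  tab <- do.call(rbind, lapply(present, function(a)
    data.frame(atom = a, res = seq_len(n),
               bbpos = 3L * (seq_len(n) - 1L) + pos[[a]],
               branch = br[[a]])))
  m <- nrow(tab)
  L <- 3L * n
  idx <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)
  db <- abs(tab$bbpos[idx[, 1]] - tab$bbpos[idx[, 2]])
  sep <- pmin(db, L - db) + tab$branch[idx[, 1]] + tab$branch[idx[, 2]]
  keep <- sep >= 4
  data.frame(i = idx[keep, 1], j = idx[keep, 2],
             atom_i = tab$atom[idx[keep, 1]], atom_j = tab$atom[idx[keep, 2]],
             res_i = tab$res[idx[keep, 1]], res_j = tab$res[idx[keep, 2]],
             bond_sep = sep[keep])
}

#' Detect backbone hydrogen bonds
#'
#' Geometric detection from placed amide H and carbonyl O atoms: H..O
#' distance below the threshold and N-H..O angle above it. Proline
#' positions (NA rows in the H matrix) cannot donate.
#'
#' @param struct a [backbone_structure()] with O and H placed.
#' @param params an [energy_params()] block.
#' @return data.frame with columns donor, acceptor, distance, angle, energy.
#' @export
detect_hbonds <- function(struct, params = energy_params()) {
  if (is.null(struct$O) || is.null(struct$H))
    stop("O and H atoms must be placed before H-bond detection")
  n <- struct$n
  bb <- matrix(NA_real_, 3, 3 * n)
  for (k in seq_len(n)) {
    bb[, 3 * k - 2] <- struct$N[k, ]
    bb[, 3 * k - 1] <- struct$CA[k, ]
    bb[, 3 * k] <- struct$C[k, ]
  }
  oh <- cbind(t(struct$O), t(struct$H))  # 3 x 2n: O_1..O_n, H_1..H_n
  oh[is.na(oh)] <- 1e9  # masked H positions can never satisfy the cutoff
  m <- .cpp_hbonds(bb, oh, !is.na(struct$H[, 1]),
                   params$hb_dmax, deg2rad(params$hb_angmin),
                   params$hb_depth, params$hb_r0, params$hb_sigma)
  data.frame(donor = as.integer(m[, 1]), acceptor = as.integer(m[, 2]),
             distance = m[, 3], angle = m[, 4], energy = m[, 5])
}

#' Aggregate H-bond count and energy
#'
#' @param bonds a data.frame from [detect_hbonds()].
#' @return list with `count` and `energy` (kcal/mol, <= 0).
#' @export
hbond_count_and_energy <- function(bonds) {
  list(count = nrow(bonds), energy = if (nrow(bonds)) sum(bonds$energy) else 0)
}

#' Count strong hydrogen bonds
#'
#' @param bonds a data.frame from [detect_hbonds()].
#' @param cutoff energy below which a bond counts as strong.
#' @return integer count.
#' @export
count_strong_hbonds <- function(bonds, cutoff = -0.5) {
  sum(bonds$energy < cutoff)
}

#' Score the backbone energy terms of a structure
#'
#' Computes the per-term backbone energies: `rama` (sum of per-residue map
#' lookups), `rep`/`attractive`/`elec`/`solv` (pair terms under the
#' >= 4-bond rule), `hbond`, plus `other = attractive + elec + solv`,
#' `total = 0.45 * rama + rep + hbond + other` and the cyclic error.
#' Torsions in a disallowed map region make `rama` (and `total`) infinite;
#' the `prohibited` flag is set. Terms whose atoms are absent (O/H not
#' placed) are returned as NA and excluded from the total.
#'
#' @param struct a [backbone_structure()].
#' @param maps a single `rama_map` or a list of n per-residue maps.
#' @param params an [energy_params()] block.
#' @param conf optional [torsion_conformation()]; measured from coordinates
#'   when absent.
#' @return an object of class `energy_breakdown`.
#' @export
score_terms <- function(struct, maps = default_glycine_map(),
                        params = energy_params(), conf = NULL) {
  n <- struct$n
  conf <- conf %||% struct$provenance %||% measure_torsions(struct)
  if (inherits(maps, "rama_map")) maps <- rep(list(maps), n)
  rama <- sum(vapply(seq_len(n), function(i)
    rama_energy(maps[[i]], conf$phi[i], conf$psi[i]), numeric(1)))
  at <- atom_table(struct, include_h = TRUE)
  pe <- .cpp_pair_energies(at$xyz, at$bbpos, at$branch, at$type, n,
                           params$radii, params$charges, params$lj_eps,
                           params$cutoff, params$coulomb / params$dielectric, params$dg_free,
                           params$volume, params$solv_lambda, FALSE)
  hb <- if (!is.null(struct$O) && !is.null(struct$H)) {
    hbond_count_and_energy(detect_hbonds(struct, params))
  } else list(count = NA_integer_, energy = NA_real_)
  other <- pe[2] + pe[3] + pe[4]
  hbe <- if (is.na(hb$energy)) 0 else hb$energy
  structure(list(rama = rama, rep = pe[1], attractive = pe[2],
                 elec = pe[3], solv = pe[4], hbond = hb$energy,
                 other = other,
                 total = params$rama_weight * rama + pe[1] + hbe + other,
                 cyclic_err = cyclic_error(conf),
                 hbond_count = hb$count,
                 prohibited = !is.finite(rama)),
            class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat(sprintf(paste0("Backbone energies (kcal/mol): rama %.3f  rep %.3f  ",
                     "hbond %s  other %.3f  total %s\n"),
              x$rama, x$rep, format(x$hbond), x$other, format(x$total)))
  cat(sprintf("  cyclic error %.3g, %s H-bonds\n", x$cyclic_err,
              format(x$hbond_count)))
  invisible(x)
}
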