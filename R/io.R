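# PDB and table I/O, chirality-coded sequences, Ramachandran grid files and
# YAML configuration. Residue indexing is 1-based in all user-facing
# output (PDB convention). Tables are tab-delimited with a '#'-prefixed
# header naming columns and units.

# standard PDB residue names for D-amino acids (glycine is achiral)
D_RESNAMES <- c(A = "DAL", R = "DAR", N = "DSG", D = "DAS", C = "DCY",
                Q = "DGN", E = "DGL", H = "DHI", I = "DIL", L = "DLE",
                K = "DLY", M = "MED", F = "DPN", P = "DPR", S = "DSN",
                T = "DTH", W = "DTR", Y = "DTY", V = "DVA")
L_RESNAMES <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
                Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
                L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
                S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

#' Parse a chirality-coded sequence
#'
#' Uppercase letters are L-amino acids, lowercase are D-amino acids;
#' glycine has no D form.
#'
#' @param sequence one-letter string.
#' @return list with `residues` (uppercase letters) and `d_form` (logical).
#' @export
chiral_sequence <- function(sequence) {
  aas <- strsplit(sequence, "")[[1]]
  up <- toupper(aas)
  if (!all(up %in% AA_CODES)) stop("unknown amino acid code in sequence")
  if (any(aas == "g")) stop("glycine is achiral: no D form 'g'")
  list(residues = up, d_form = aas %in% letters)
}

resname_for <- function(aa) {
  if (aa %in% letters) unname(D_RESNAMES[toupper(aa)])
  else unname(L_RESNAMES[aa])
}

#' Write a backbone structure to a PDB file
#'
#' Standard PDB v3 ATOM records for N, CA, C, O (and H where present),
#' followed by TER and a CONECT record joining C' of the last residue to N
#' of the first (the cyclic amide bond). D-residues are written with their
#' standard D names (DAL, DPR, ...).
#'
#' @param struct a [backbone_structure()].
#' @param path output file.
#' @param sequence optional chirality-coded sequence (default poly-glycine).
#' @return invisibly, the path.
#' @export
write_pdb <- function(struct, path, sequence = NULL) {
  n <- struct$n
  aas <- if (is.null(sequence)) rep("G", n) else strsplit(sequence, "")[[1]]
  if (length(aas) != n) stop("sequence length must match residue count")
  lines <- character(0)
  serial <- 0L
  first_n_serial <- NA_integer_
  last_c_serial <- NA_integer_
  for (k in seq_len(n)) {
    res <- resname_for(aas[k])
    for (at in c("N", "CA", "C", "O", "H")) {
      M <- struct[[at]]
      if (is.null(M) || anyNA(M[k, ])) next
      serial <- serial + 1L
      if (at == "N" && k == 1) first_n_serial <- serial
      if (at == "C" && k == n) last_c_serial <- serial
      name4 <- sprintf(" %-3s", at)
      lines <- c(lines, sprintf(
        "ATOM  %5d %4s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
        serial, name4, res, k, M[k, 1], M[k, 2], M[k, 3],
        substr(at, 1, 1)))
    }
  }
  lines <- c(lines, "TER")
  if (!is.na(first_n_serial) && !is.na(last_c_serial))
    lines <- c(lines, sprintf("CONECT%5d%5d", last_c_serial, first_n_serial))
  lines <- c(lines, "END")
  writeLines(lines, path)
  invisible(path)
}

#' Read a backbone structure from a PDB file
#'
#' Parses ATOM records for N/CA/C/O (and amide H) of one chain. D-residues
#' are recognized by their standard names; missing O atoms are rebuilt by
#' the planar placement rule and flagged in the `rebuilt_o` attribute.
#'
#' @param path PDB file.
#' @return a [backbone_structure()] with attributes `sequence`
#'   (chirality-coded string) and `rebuilt_o` (logical vector).
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom[pdb$atom$type == "ATOM", ]
  if (nrow(at) == 0) stop("no ATOM records in ", path)
  resnos <- unique(at$resno)
  n <- length(resnos)
  get <- function(name) {
    M <- matrix(NA_real_, n, 3)
    for (k in seq_len(n)) {
      row <- at[at$resno == resnos[k] & at$elety == name, , drop = FALSE]
      if (nrow(row) >= 1)
        M[k, ] <- as.numeric(row[1, c("x", "y", "z")])
    }
    M
  }
  N <- get("N"); CA <- get("CA"); C <- get("C")
  O <- get("O"); H <- get("H")
  if (anyNA(N) || anyNA(CA) || anyNA(C)) {
    bad <- which(apply(is.na(N) | is.na(CA) | is.na(C), 1, any))
    stop("missing backbone atoms at residue(s) ",
         paste(resnos[bad], collapse = ", "), " in ", path)
  }
  rebuilt <- is.na(O[, 1])
  if (any(rebuilt)) {
    for (k in which(rebuilt)) {
      nxt <- if (k == n) 1 else k + 1
      O[k, ] <- place_o_atom(CA[k, ], C[k, ], N[nxt, ])
    }
  }
  if (all(is.na(H[, 1]))) H <- NULL
  seq_codes <- vapply(seq_len(n), function(k) {
    res <- at$resid[at$resno == resnos[k]][1]
    if (res %in% D_RESNAMES) tolower(names(D_RESNAMES)[D_RESNAMES == res])
    else if (res %in% L_RESNAMES) names(L_RESNAMES)[L_RESNAMES == res]
    else "G"
  }, character(1))
  out <- backbone_structure(N, CA, C, O, H)
  attr(out, "sequence") <- paste(seq_codes, collapse = "")
  attr(out, "rebuilt_o") <- rebuilt
  out
}

# carbonyl O from the planar ideal-geometry rule
place_o_atom <- function(ca, c, n_next, d = 1.231, ang = 120.1) {
  a <- (ca - c); a <- a / sqrt(sum(a^2))
  b <- (n_next - c); b <- b / sqrt(sum(b^2))
  eb <- b - sum(a * b) * a
  eb <- eb / sqrt(sum(eb^2))
  c + d * (cos(deg2rad(ang)) * a - sin(deg2rad(ang)) * eb)
}

# --- delimited tables ---------------------------------------------------

write_table_with_header <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", header), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

read_commented_table <- function(path) {
  read.table(path, header = TRUE, sep = "\t", comment.char = "#",
             stringsAsFactors = FALSE)
}

#' Write an energy landscape table
#'
#' Tab-delimited text with columns id, energy (kcal/mol), rmsd (Angstrom)
#' and, when available, bin_string.
#'
#' @param landscape an [energy_landscape()].
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_landscape <- function(landscape, path) {
  df <- landscape$records
  write_table_with_header(df, path,
    sprintf("energy landscape: energy kcal/mol, rmsd Angstrom, lambda=%g, kT=%g",
            landscape$lambda, landscape$kT))
}

#' Read an energy landscape table
#'
#' @param path file written by [write_landscape()] (or any tab-delimited
#'   table with `energy` and `rmsd` columns).
#' @param lambda,kT PNear parameters to attach.
#' @return an [energy_landscape()].
#' @export
read_landscape <- function(path, lambda = NULL, kT = 0.62) {
  df <- read_commented_table(path)
  if (!all(c("energy", "rmsd") %in% names(df)))
    stop("landscape table needs 'energy' and 'rmsd' columns")
  energy_landscape(df$energy, df$rmsd, id = df$id %||% seq_len(nrow(df)),
                   lambda = lambda %||% 1.5, kT = kT)
}

#' Write a candidate dump
#'
#' One row per recorded backbone candidate: torsions (degrees), term
#' energies, cyclic error, H-bond count and bin string.
#'
#' @param candidates list from [run_annealing()] / [sample_backbones()].
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_candidates <- function(candidates, path) {
  if (length(candidates) == 0) {
    writeLines("# empty candidate dump", path)
    return(invisible(path))
  }
  n <- candidates[[1]]$conformation$n
  rows <- lapply(candidates, function(cd) {
    bd <- cd$breakdown
    c(stats::setNames(cd$conformation$phi, paste0("phi", seq_len(n))),
      stats::setNames(cd$conformation$psi, paste0("psi", seq_len(n))),
      rama = bd$rama, rep = bd$rep, hbond = bd$hbond, other = bd$other,
      total = bd$total, cyclic_err = bd$cyclic_err,
      hbond_count = cd$hbond_count, strong_hbonds = cd$strong_hbonds,
      step_found = cd$step_found)
  })
  df <- as.data.frame(do.call(rbind, rows))
  df$bin_string <- vapply(candidates, `[[`, character(1), "bin_string")
  write_table_with_header(df, path,
    "backbone candidates: torsions degrees, energies kcal/mol")
}

#' Read a candidate dump
#'
#' @param path file written by [write_candidates()].
#' @param geometry geometry to attach.
#' @return list of candidates (conformation, breakdown, bin_string, ...).
#' @export
read_candidates <- function(path, geometry = ideal_geometry()) {
  first <- readLines(path, n = 1)
  if (grepl("empty candidate dump", first)) return(list())
  df <- read_commented_table(path)
  phic <- grep("^phi[0-9]+$", names(df))
  psic <- grep("^psi[0-9]+$", names(df))
  lapply(seq_len(nrow(df)), function(r) {
    conf <- torsion_conformation(as.numeric(df[r, phic]),
                                 as.numeric(df[r, psic]), geometry)
    list(conformation = conf,
         breakdown = structure(list(rama = df$rama[r], rep = df$rep[r],
                                    hbond = df$hbond[r], other = df$other[r],
                                    total = df$total[r],
                                    cyclic_err = df$cyclic_err[r]),
                               class = "energy_breakdown"),
         hbond_count = df$hbond_count[r],
         strong_hbonds = df$strong_hbonds[r],
         bin_string = as.character(df$bin_string[r]),
         step_found = df$step_found[r])
  })
}

# --- Ramachandran grid files -------------------------------------------

#' Write a Ramachandran map grid file
#'
#' Plain-text format: a header line `# phi_min phi_max step`, then
#' row-major psi x phi energies (one row per psi value, ascending),
#' sentinel `INF` for disallowed cells.
#'
#' @param map a `rama_map`.
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_rama_grid <- function(map, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %g %g %g", min(map$phi), max(map$phi), map$step), con)
  # recompute on the grid so analytic maps export faithfully
  for (j in seq_along(map$psi)) {
    vals <- rama_energy(map, map$phi, rep(map$psi[j], length(map$phi)))
    writeLines(paste(ifelse(is.finite(vals), sprintf("%.6g", vals), "INF"),
                     collapse = " "), con)
  }
  invisible(path)
}

#' Read a Ramachandran map grid file
#'
#' @param path grid file in the format of [write_rama_grid()].
#' @param label map label.
#' @return a `rama_map` (grid-backed).
#' @export
read_rama_grid <- function(path, label = basename(path)) {
  lines <- readLines(path)
  hdr <- as.numeric(strsplit(sub("^#\\s*", "", lines[1]), "\\s+")[[1]])
  step <- hdr[3]
  nodes <- seq(hdr[1], hdr[2], by = step)
  rows <- lapply(lines[-1], function(l) {
    v <- strsplit(trimws(l), "\\s+")[[1]]
    out <- suppressWarnings(as.numeric(v))
    out[toupper(v) == "INF"] <- Inf
    out
  })
  E <- do.call(rbind, rows) # psi rows x phi cols
  if (nrow(E) != length(nodes) || ncol(E) != length(nodes))
    stop("grid dimensions do not match header")
  energy <- t(E) # energy[iphi, ipsi]
  # mirror index of node x is the node of -x (wrapped)
  mi <- ((length(nodes) + 1 - seq_along(nodes)) %% length(nodes)) + 1
  m <- structure(list(step = step, phi = nodes, psi = nodes,
                      energy = energy, allowed = is.finite(energy),
                      centers = NULL, radii = NULL, scale = NULL,
                      symmetrized = isTRUE(all(energy == energy[mi, mi])),
                      label = label),
                 class = "rama_map")
  m$soft <- fill_grid(m)
  m
}

#' Write a free-energy surface grid
#'
#' @param fes a `fes_grid` from [free_energy_surface()].
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_fes <- function(fes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# FES kcal/mol, T=%g K; %s", fes$temperature,
                     fes$note), con)
  writeLines(paste("# rmsd_edges:",
                   paste(sprintf("%.6g", fes$rmsd_edges), collapse = " ")),
             con)
  writeLines(paste("# rg_edges:",
                   paste(sprintf("%.6g", fes$rg_edges), collapse = " ")),
             con)
  for (i in seq_len(nrow(fes$free_energy)))
    writeLines(paste(ifelse(is.na(fes$free_energy[i, ]), "NA",
                            sprintf("%.6g", fes$free_energy[i, ])),
                     collapse = " "), con)
  invisible(path)
}

#' Load a YAML configuration file
#'
#' @param path YAML file.
#' @return named list.
#' @export
load_config <- function(path) yaml::read_yaml(path)
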