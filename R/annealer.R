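# Layered simulated annealing over torsion space. A proposed move must pass
# an ordered sequence of increasingly expensive Metropolis tests (rama ->
# rep -> cyclic -> hbond [-> misc]); a failure at any layer rejects the move
# without evaluating later layers. Configurations satisfying the good-
# backbone criteria at acceptance time are recorded as candidates.

#' Annealing schedule
#'
#' Move radius decays (geometrically by default) from `k0` to `k1` degrees
#' over `steps` steps; each layer cools geometrically from `T0` to `Tf`,
#' and a layer threshold may itself anneal between a start and end value
#' (length-2 `threshold`). The `misc` layer (attractive + electrostatic +
#' solvation) is part of the small-macrocycle profile only. Thresholds for
#' the extensive layers (rama, rep) are per-residue and scaled by n.
#'
#' @param n residue count the schedule is built for.
#' @param steps number of annealing steps.
#' @param k0,k1 initial and final move-disk radius, degrees.
#' @param k_shape decay shape of the move radius over the run.
#' @param include_misc include the final miscellaneous-energy layer
#'   (default: TRUE for n <= 7).
#' @param layers optional full override: list of lists with fields
#'   `name`, `threshold`, `T0`, `Tf`.
#' @param max_repeats re-runs allowed when a run records no candidate.
#' @return an object of class `anneal_schedule`.
#' @export
anneal_schedule <- function(n, steps = 50000, k0 = 30, k1 = 0.5,
                            k_shape = c("geometric", "linear"),
                            include_misc = n <= 7, layers = NULL,
                            max_repeats = 3) {
  k_shape <- match.arg(k_shape)
  if (steps < 1) stop("schedule must have at least one step")
  if (is.null(layers)) {
    # thresholds may be length-2 (start, end): the cyclic tube narrows
    # geometrically over the run so hydrogen bonds can form among loosely
    # closed states before the closure constraint freezes the backbone
    layers <- list(
      list(name = "rama", threshold = 2.0 * n, T0 = 5, Tf = 0.5),
      list(name = "rep", threshold = 1.0 * n, T0 = 10, Tf = 0.5),
      list(name = "cyclic", threshold = c(20, 2e-4), T0 = 0.5, Tf = 1e-5),
      list(name = "hbond", threshold = -1.0, T0 = 2, Tf = 0.05))
    if (include_misc)
      layers <- c(layers,
                  list(list(name = "misc", threshold = 0, T0 = 2, Tf = 0.3)))
  }
  structure(list(n = n, steps = steps, k0 = k0, k1 = k1,
                 k_shape = k_shape, layers = layers,
                 max_repeats = max_repeats),
            class = "anneal_schedule")
}

#' Move radius at a step
#'
#' @param schedule an [anneal_schedule()].
#' @param t step index in 1..steps.
#' @return radius in degrees (non-increasing in t).
#' @export
move_radius <- function(schedule, t) {
  f <- if (schedule$steps == 1) 0 else (t - 1) / (schedule$steps - 1)
  if (identical(schedule$k_shape, "linear"))
    schedule$k0 + f * (schedule$k1 - schedule$k0)
  else schedule$k0 * (schedule$k1 / schedule$k0)^f
}

layer_temperature <- function(layer, t, steps) {
  f <- if (steps == 1) 1 else (t - 1) / (steps - 1)
  layer$T0 * (layer$Tf / layer$T0)^f
}

# annealed threshold: geometric when both ends positive, else linear
layer_threshold <- function(layer, t, steps) {
  th <- layer$threshold
  if (length(th) == 1) return(th)
  f <- if (steps == 1) 1 else (t - 1) / (steps - 1)
  if (th[1] > 0 && th[2] > 0) th[1] * (th[2] / th[1])^f
  else th[1] + f * (th[2] - th[1])
}

#' Good-backbone recording criteria
#'
#' Defaults: cyclic error <= 0.01, repulsive energy <= 0.5 per residue,
#' strong H-bonds >= max(2, ceiling(n/5)).
#'
#' @param n residue count.
#' @param max_cyclic_error,max_rep_energy,min_strong_hbonds overrides.
#' @return a named list of class `good_backbone_criteria`.
#' @export
good_backbone_criteria <- function(n, max_cyclic_error = 0.01,
                                   max_rep_energy = 0.5 * n,
                                   min_strong_hbonds = max(2, ceiling(n / 5))) {
  structure(list(max_cyclic_error = max_cyclic_error,
                 max_rep_energy = max_rep_energy,
                 min_strong_hbonds = min_strong_hbonds),
            class = "good_backbone_criteria")
}

#' Propose a torsion move
#'
#' Each residue is independently displaced by a uniform point in the disk
#' of radius `k` degrees in (phi, psi) space (with toroidal wrap); residues
#' whose displaced point falls in a prohibited region of the map keep their
#' old torsions.
#'
#' @param conf a [torsion_conformation()].
#' @param k disk radius, degrees (> 0).
#' @param map `rama_map` defining the prohibited region.
#' @return a new [torsion_conformation()].
#' @export
propose_move <- function(conf, k, map = default_glycine_map()) {
  if (k < 0) stop("k must be non-negative")
  n <- conf$n
  r <- k * sqrt(runif(n))
  a <- runif(n, 0, 2 * pi)
  phi <- wrap_angle(conf$phi + r * cos(a))
  psi <- wrap_angle(conf$psi + r * sin(a))
  ok <- rama_allowed(map, phi, psi)
  phi[!ok] <- conf$phi[!ok]
  psi[!ok] <- conf$psi[!ok]
  out <- conf
  out$phi <- phi
  out$psi <- psi
  out
}

#' Layered Metropolis acceptance test
#'
#' Passes if the new energy is below the current energy or below the layer
#' threshold; otherwise passes with probability
#' exp((E_current - E_new) / T).
#'
#' @param e_current,e_new layer energies.
#' @param threshold layer pass-through threshold.
#' @param temperature layer temperature (> 0).
#' @return logical.
#' @export
layer_accept <- function(e_current, e_new, threshold, temperature) {
  if (temperature <= 0) stop("temperature must be positive")
  if (e_new < e_current || e_new < threshold) return(TRUE)
  runif(1) < exp((e_current - e_new) / temperature)
}

# evaluate the energy of one named layer for a conformation; `cache` carries
# coordinates between layers of the same proposal
layer_energy <- function(name, conf, cache, map, params, gv) {
  if (is.null(cache$struct) && name %in% c("rep", "hbond", "misc")) {
    cache$struct <- forward_kinematics(conf, place_oh = TRUE)
    cache$at <- atom_table(cache$struct, include_h = TRUE)
  }
  e <- switch(name,
    rama = sum(rama_energy(map, conf$phi, conf$psi)),
    cyclic = cyclic_error_raw(conf$phi, conf$psi, gv),
    rep = {
      pe <- .cpp_pair_energies(cache$at$xyz, cache$at$bbpos, cache$at$branch,
                               cache$at$type, conf$n, params$radii,
                               params$charges, params$lj_eps, params$cutoff,
                               params$coulomb / params$dielectric, params$dg_free, params$volume,
                               params$solv_lambda, FALSE)
      cache$pair <- pe
      pe[1]
    },
    hbond = {
      cache$bonds <- detect_hbonds(cache$struct, params)
      hbond_count_and_energy(cache$bonds)$energy
    },
    misc = {
      pe <- cache$pair
      pe[2] + pe[3] + pe[4]
    },
    stop("unknown layer: ", name))
  list(e = e, cache = cache)
}

#' Run layered simulated annealing
#'
#' The full sampling loop: at each step a disk move is proposed for every
#' residue, then the layers are evaluated cheapest-first, each with its own
#' Metropolis test; any failure rejects the move immediately. After each
#' acceptance, the current configuration is recorded as a candidate when it
#' meets the good-backbone criteria.
#'
#' @param initial a [torsion_conformation()] with allowed torsions.
#' @param schedule an [anneal_schedule()].
#' @param criteria a [good_backbone_criteria()] list.
#' @param map `rama_map` used for moves and the rama layer.
#' @param params an [energy_params()] block.
#' @param seed optional RNG seed (reproducible runs).
#' @param scheme [torsion_bins()] used for candidate bin strings.
#' @return list of candidates (each with `conformation`, `breakdown`,
#'   `hbond_count`, `strong_hbonds`, `bin_string`, `step_found`); attribute
#'   `layer_evals` counts energy evaluations per layer.
#' @export
run_annealing <- function(initial, schedule,
                          criteria = good_backbone_criteria(initial$n),
                          map = default_glycine_map(),
                          params = energy_params(), seed = NULL,
                          scheme = torsion_bins(),
                          engine = c("auto", "compiled", "reference")) {
  stopifnot(inherits(initial, "torsion_conformation"))
  engine <- match.arg(engine)
  lnames0 <- vapply(schedule$layers, `[[`, character(1), "name")
  default_stack <- identical(lnames0, c("rama", "rep", "cyclic", "hbond")) ||
    identical(lnames0, c("rama", "rep", "cyclic", "hbond", "misc"))
  if (engine == "auto")
    engine <- if (!is.null(map$centers) && default_stack) "compiled"
              else "reference"
  if (engine == "compiled") {
    if (is.null(map$centers) || !default_stack)
      stop("compiled engine needs an analytic map and the default layers")
    if (!is.null(seed)) set.seed(seed)
    return(run_annealing_compiled(initial, schedule, criteria, map, params,
                                  scheme))
  }
  if (!is.null(seed)) set.seed(seed)
  gv <- geom_vec(initial$geometry)
  layers <- schedule$layers
  lnames <- vapply(layers, `[[`, character(1), "name")
  evals <- stats::setNames(numeric(length(layers)), lnames)
  # energies of the current configuration at every layer
  cur <- initial
  cache <- list()
  e_cur <- numeric(length(layers))
  for (li in seq_along(layers)) {
    r <- layer_energy(lnames[li], cur, cache, map, params, gv)
    e_cur[li] <- r$e; cache <- r$cache
  }
  cur_cache <- cache
  candidates <- vector("list", 256)
  ncand <- 0
  for (t in seq_len(schedule$steps)) {
    prop <- propose_move(cur, move_radius(schedule, t), map)
    cache <- list()
    e_new <- e_cur
    pass <- TRUE
    for (li in seq_along(layers)) {
      r <- layer_energy(lnames[li], prop, cache, map, params, gv)
      evals[li] <- evals[li] + 1
      e_new[li] <- r$e; cache <- r$cache
      if (!layer_accept(e_cur[li], e_new[li],
                        layer_threshold(layers[[li]], t, schedule$steps),
                        layer_temperature(layers[[li]], t, schedule$steps))) {
        pass <- FALSE
        break
      }
    }
    if (!pass) next
    cur <- prop
    e_cur <- e_new
    cur_cache <- cache
    # good-backbone recording
    cyc <- e_cur[match("cyclic", lnames)]
    rep_e <- e_cur[match("rep", lnames)]
    if (cyc <= criteria$max_cyclic_error && rep_e <= criteria$max_rep_energy) {
      bonds <- cur_cache$bonds %||%
        detect_hbonds(cur_cache$struct, params)
      strong <- count_strong_hbonds(bonds, params$hb_strong)
      if (strong >= criteria$min_strong_hbonds) {
        bd <- score_terms(cur_cache$struct, map, params, conf = cur)
        ncand <- ncand + 1
        if (ncand > length(candidates))
          candidates <- c(candidates, vector("list", length(candidates)))
        candidates[[ncand]] <- list(
          conformation = cur, breakdown = bd,
          hbond_count = nrow(bonds), strong_hbonds = strong,
          bin_string = paste(assign_bin(cur$phi, cur$psi, scheme),
                             collapse = ""),
          step_found = t)
      }
    }
  }
  out <- candidates[seq_len(ncand)]
  attr(out, "layer_evals") <- evals
  out
}

# compiled fast path for the default layer stack + analytic basin map
run_annealing_compiled <- function(initial, schedule, criteria, map, params,
                                   scheme) {
  n <- initial$n
  layers <- schedule$layers
  lnames <- vapply(layers, `[[`, character(1), "name")
  res <- .cpp_run_annealing(
    initial$phi, initial$psi, geom_vec(initial$geometry),
    as.integer(schedule$steps), schedule$k0, schedule$k1,
    !identical(schedule$k_shape, "linear"),
    vapply(layers, function(l) l$threshold[1], numeric(1)),
    vapply(layers, function(l) l$threshold[length(l$threshold)], numeric(1)),
    vapply(layers, `[[`, numeric(1), "T0"),
    vapply(layers, `[[`, numeric(1), "Tf"),
    "misc" %in% lnames,
    map$centers, map$radii, map$scale,
    params$radii, params$charges, params$lj_eps, params$cutoff,
    params$coulomb / params$dielectric, params$dg_free, params$volume,
    params$solv_lambda,
    params$hb_dmax, deg2rad(params$hb_angmin), params$hb_depth,
    params$hb_r0, params$hb_sigma, params$hb_strong,
    criteria$max_cyclic_error, criteria$max_rep_energy,
    as.integer(criteria$min_strong_hbonds))
  cm <- res$candidates
  out <- lapply(seq_len(ncol(cm)), function(ci) {
    v <- cm[, ci]
    conf <- torsion_conformation(v[seq_len(n)], v[n + seq_len(n)],
                                 initial$geometry)
    e <- v[2 * n + 1:10]
    other <- e[3] + e[4] + e[5]
    bd <- structure(list(rama = e[1], rep = e[2], attractive = e[3],
                         elec = e[4], solv = e[5], hbond = e[6],
                         other = other,
                         total = params$rama_weight * e[1] + e[2] + e[6] +
                           other,
                         cyclic_err = e[7],
                         hbond_count = as.integer(e[8]),
                         prohibited = FALSE),
                    class = "energy_breakdown")
    list(conformation = conf, breakdown = bd,
         hbond_count = as.integer(e[8]), strong_hbonds = as.integer(e[9]),
         bin_string = paste(assign_bin(conf$phi, conf$psi, scheme),
                            collapse = ""),
         step_found = as.integer(e[10]))
  })
  attr(out, "layer_evals") <- stats::setNames(as.numeric(res$evals), lnames)
  attr(out, "accepted") <- res$accepted
  out
}

#' Sample good backbones from many initial configurations
#'
#' Runs the layered annealing from each initial configuration; runs that
#' record no candidate are repeated (fresh RNG substream) up to
#' `schedule$max_repeats` times in total.
#'
#' @param initials list of [torsion_conformation()]s.
#' @param schedule an [anneal_schedule()].
#' @param seed base seed; run r uses substream seed + r.
#' @param ... passed to [run_annealing()].
#' @return flat list of candidates; attribute `runs` maps candidates to
#'   initial-configuration indices.
#' @export
sample_backbones <- function(initials, schedule, seed = 1, ...) {
  all <- list()
  runs <- integer(0)
  for (r in seq_along(initials)) {
    cand <- list()
    for (rep in seq_len(max(1, schedule$max_repeats))) {
      cand <- run_annealing(initials[[r]], schedule,
                            seed = seed + 7919L * (r - 1L) + rep - 1L, ...)
      if (length(cand) > 0) break
    }
    runs <- c(runs, rep(r, length(cand)))
    all <- c(all, cand)
  }
  attr(all, "runs") <- runs
  all
}

#' Low-RMSD simulated annealing toward a reference structure
#'
#' The two-layer variant used to seed the genetic algorithm with
#' conformations near a designed structure: only the cyclic-error test and
#' a Metropolis test on the backbone-heavy-atom Kabsch RMSD to the
#' reference are applied. No other energy term is evaluated.
#'
#' @param initial a [torsion_conformation()] with the reference's residue
#'   count.
#' @param reference a [backbone_structure()].
#' @param schedule an [anneal_schedule()]; its `cyclic` layer settings are
#'   used, plus an `rmsd` layer cooling from `rmsd_T0` to `rmsd_Tf`.
#' @param max_cyclic_error recording threshold on the cyclic error.
#' @param rmsd_threshold,rmsd_T0,rmsd_Tf RMSD layer parameters (Angstrom).
#' @param cyclic_layer optional override of the cyclic layer
#'   (list with `threshold`, `T0`, `Tf`).
#' @param map,seed as in [run_annealing()].
#' @return list of candidates (conformation, cyclic_err, rmsd, step_found);
#'   attribute `layer_evals` has counts for the two layers only.
#' @export
low_rmsd_annealing <- function(initial, reference, schedule,
                               max_cyclic_error = 0.01,
                               rmsd_threshold = 0.5, rmsd_T0 = 1,
                               rmsd_Tf = 0.05, cyclic_layer = NULL,
                               map = default_glycine_map(), seed = NULL) {
  stopifnot(inherits(reference, "backbone_structure"))
  if (initial$n != reference$n) stop("residue count mismatch with reference")
  if (!is.null(seed)) set.seed(seed)
  gv <- geom_vec(initial$geometry)
  # own cyclic-layer defaults: a loose tube early (the RMSD layer is doing
  # the steering) that anneals shut so late states are recordable closures
  cyc_layer <- cyclic_layer %||% list(threshold = c(1, 1e-4), T0 = 0.5,
                                      Tf = 1e-5)
  ref_xyz <- heavy_coords(reference, c("N", "CA", "C", "O"))
  rmsd_of <- function(conf) {
    s <- forward_kinematics(conf, place_oh = TRUE)
    .cpp_kabsch_rmsd(heavy_coords(s, c("N", "CA", "C", "O")), ref_xyz)
  }
  evals <- c(cyclic = 0, rmsd = 0)
  cur <- initial
  cyc_cur <- cyclic_error_raw(cur$phi, cur$psi, gv)
  rmsd_cur <- rmsd_of(cur)
  candidates <- list()
  if (cyc_cur <= max_cyclic_error)
    candidates[[1]] <- list(conformation = cur, cyclic_err = cyc_cur,
                            rmsd = rmsd_cur, step_found = 0L)
  for (t in seq_len(schedule$steps)) {
    prop <- propose_move(cur, move_radius(schedule, t), map)
    cyc_new <- cyclic_error_raw(prop$phi, prop$psi, gv)
    evals["cyclic"] <- evals["cyclic"] + 1
    if (!layer_accept(cyc_cur, cyc_new,
                      layer_threshold(cyc_layer, t, schedule$steps),
                      layer_temperature(cyc_layer, t, schedule$steps))) next
    rmsd_new <- rmsd_of(prop)
    evals["rmsd"] <- evals["rmsd"] + 1
    Tt <- rmsd_T0 * (rmsd_Tf / rmsd_T0)^((t - 1) / max(1, schedule$steps - 1))
    if (!layer_accept(rmsd_cur, rmsd_new, rmsd_threshold, Tt)) next
    cur <- prop; cyc_cur <- cyc_new; rmsd_cur <- rmsd_new
    if (cyc_cur <= max_cyclic_error) {
      candidates[[length(candidates) + 1]] <- list(
        conformation = cur, cyclic_err = cyc_cur, rmsd = rmsd_cur,
        step_found = t)
    }
  }
  attr(candidates, "layer_evals") <- evals
  candidates
}
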