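# ClusterGen: the genetic-algorithm energy-landscape sampler. Populations
# are seeded from simulated annealing, refined by window crossover and
# mutation with closure restoration, locally relaxed by a bounded
# torsion-space minimizer (the internal stand-in for a full Cartesian
# relax), and compressed each generation by greedy energy-sorted RMSD
# clustering. Cluster centers with energy below the recording ceiling
# accumulate into the energy landscape.

#' Population schedule by size-class profile
#'
#' The published generation schedules: constant 500 for 15-residue rings,
#' 750 - 5 i for 20, 1000 - 10 i for 24 (generation i = 0..49); the toy
#' profile uses a constant 50.
#'
#' @param profile one of "toy", "15", "20", "24".
#' @return function of the generation index i (0-based).
#' @export
ga_population_schedule <- function(profile) {
  switch(profile,
         "toy" = function(i) 50,
         "15" = function(i) 500,
         "20" = function(i) 750 - 5 * i,
         "24" = function(i) 1000 - 10 * i,
         stop("unknown profile: ", profile))
}

#' Genetic-algorithm configuration
#'
#' @param n residue count.
#' @param profile size-class profile; sets the population schedule and
#'   desk-scale defaults ("toy") or the published schedules ("15", "20",
#'   "24").
#' @param generations number of generations (default 50; 15 for "toy").
#' @param population_schedule function i -> N_GA(i), i 0-based.
#' @param cluster_rmsd_cutoff greedy clustering cutoff, Angstrom.
#' @param crossover_rate,mutation_rate per-child operator probabilities
#'   (crossover attempted first with its rate; otherwise mutation).
#' @param mutation_radius torsion perturbation disk radius, degrees.
#' @param record_energy_ceiling record centers with energy below this.
#' @param closure_tol cyclic-error tolerance for offspring closure.
#' @param relax_maxit iteration budget of the internal relax.
#' @param closure_weight weight of the cyclic error in the relax objective.
#' @param init list: `mode` ("direct" or "sa"), `n_starts`, `sa_steps`.
#' @param seed RNG seed for the whole run.
#' @return list of class `ga_config`.
#' @export
ga_config <- function(n, profile = "toy",
                      generations = if (profile == "toy") 15 else 50,
                      population_schedule = ga_population_schedule(profile),
                      cluster_rmsd_cutoff = 1.5,
                      crossover_rate = 0.5, mutation_rate = 0.5,
                      mutation_radius = 20,
                      record_energy_ceiling = 0,
                      closure_tol = 1e-6,
                      relax_maxit = if (profile == "toy") 60 else 200,
                      closure_weight = 1000,
                      init = list(mode = if (profile == "toy") "direct"
                                  else "sa",
                                  n_starts = if (profile == "toy") 60 else 200,
                                  sa_steps = 1500),
                      seed = 1) {
  for (i in 0:(generations - 1))
    if (population_schedule(i) <= 0)
      stop("population schedule must stay positive over all generations")
  if (cluster_rmsd_cutoff <= 0) stop("cluster cutoff must be positive")
  structure(list(n = n, profile = profile, generations = generations,
                 population_schedule = population_schedule,
                 cluster_rmsd_cutoff = cluster_rmsd_cutoff,
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 mutation_radius = mutation_radius,
                 record_energy_ceiling = record_energy_ceiling,
                 closure_tol = closure_tol, relax_maxit = relax_maxit,
                 closure_weight = closure_weight, init = init, seed = seed),
            class = "ga_config")
}

#' Backbone energy function for a chirality-coded sequence
#'
#' Builds the default GA objective: weighted Ramachandran energy with the
#' per-residue (L/D-mirrored) maps in soft mode, plus the repulsive,
#' H-bond and miscellaneous pair terms.
#'
#' @param sequence chirality-coded string.
#' @param params an [energy_params()] block.
#' @return function(conf) -> kcal/mol.
#' @export
make_energy_function <- function(sequence, params = energy_params()) {
  maps <- lapply(strsplit(sequence, "")[[1]], map_for_residue)
  function(conf) {
    s <- forward_kinematics(conf, place_oh = TRUE)
    rama <- sum(vapply(seq_len(conf$n), function(i)
      rama_energy(maps[[i]], conf$phi[i], conf$psi[i], soft = TRUE),
      numeric(1)))
    at <- atom_table(s, include_h = TRUE)
    pe <- .cpp_pair_energies(at$xyz, at$bbpos, at$branch, at$type, conf$n,
                             params$radii, params$charges, params$lj_eps,
                             params$cutoff, params$coulomb / params$dielectric, params$dg_free,
                             params$volume, params$solv_lambda, FALSE)
    hb <- hbond_count_and_energy(detect_hbonds(s, params))$energy
    params$rama_weight * rama + pe[1] + hb + pe[2] + pe[3] + pe[4]
  }
}

#' Relax a conformation in torsion space
#'
#' Bounded local minimization of energy + w * cyclic_error over all 2n
#' torsions (L-BFGS-B with numerical gradients); the internal surrogate
#' for a full-atom Cartesian relax. Returns a closed, locally refined
#' individual.
#'
#' @param conf a [torsion_conformation()].
#' @param energy_fn function(conf) -> kcal/mol.
#' @param closure_weight weight of the cyclic error term.
#' @param maxit iteration budget.
#' @return list (`Individual`): `conformation`, `structure`, `energy`,
#'   `cyclic_err`.
#' @export
relax_conformation <- function(conf, energy_fn, closure_weight = 1000,
                               maxit = 200) {
  n <- conf$n
  gv <- geom_vec(conf$geometry)
  proto <- conf
  obj <- function(x) {
    proto$phi <- x[seq_len(n)]
    proto$psi <- x[n + seq_len(n)]
    energy_fn(proto) +
      closure_weight * cyclic_error_raw(proto$phi, proto$psi, gv)
  }
  o <- stats::optim(c(conf$phi, conf$psi), obj, method = "L-BFGS-B",
                    control = list(maxit = maxit, factr = 1e10))
  out <- torsion_conformation(o$par[seq_len(n)], o$par[n + seq_len(n)],
                              conf$geometry)
  list(conformation = out, structure = forward_kinematics(out),
       energy = energy_fn(out),
       cyclic_err = cyclic_error_raw(out$phi, out$psi, gv))
}

ind_coords <- function(ind) {
  ind$coords %||% heavy_coords(ind$structure, c("N", "CA", "C", "O"))
}

#' Greedy energy-sorted RMSD clustering
#'
#' Walks the individuals in ascending order of energy and keeps one as a
#' new cluster center iff its cyclic-minimum RMSD to every existing center
#' is at least the cutoff. Deterministic.
#'
#' @param individuals list of individuals (with `structure` and `energy`).
#' @param cutoff Angstrom.
#' @return indices (into `individuals`) of the centers, ascending energy.
#' @export
energy_cluster <- function(individuals, cutoff) {
  if (length(individuals) == 0) return(integer(0))
  e <- vapply(individuals, `[[`, numeric(1), "energy")
  ord <- order(e)
  n <- individuals[[ord[1]]]$structure$n
  coords <- lapply(individuals, ind_coords)
  centers <- integer(0)
  for (i in ord) {
    ok <- TRUE
    for (c in centers) {
      r <- .cpp_cyclic_min_rmsd(coords[[c]], coords[[i]], n, 4L)$rmsd
      if (r < cutoff) { ok <- FALSE; break }
    }
    if (ok) centers <- c(centers, i)
  }
  centers
}

# pick a cyclic window: start uniform in 1..n, length uniform in 2..n/2
sample_window <- function(n) {
  w <- if (n >= 4) sample(2:max(2, floor(n / 2)), 1) else 2
  s <- sample(n, 1)
  ((s - 1 + 0:(w - 1)) %% n) + 1
}

try_close <- function(conf, tol) {
  tryCatch(close_backbone(conf, tolerance = tol, max_restarts = 1,
                          maxit = 300),
           error = function(e) NULL)
}

#' Crossover of two parent conformations
#'
#' Swaps the (phi, psi) torsions of a random cyclic window from parent a
#' into parent b, then checks whether the ring can be re-closed by local
#' minimization of the cyclic error. Returns NULL when the closure gate
#' fails.
#'
#' @param parent_a,parent_b individuals or [torsion_conformation()]s of
#'   equal n.
#' @param tol closure tolerance for the gate.
#' @return a closed [torsion_conformation()] or NULL.
#' @export
crossover <- function(parent_a, parent_b, tol = 1e-6) {
  a <- parent_a$conformation %||% parent_a
  b <- parent_b$conformation %||% parent_b
  if (a$n != b$n) stop("parents must have the same residue count")
  win <- sample_window(a$n)
  child <- b
  child$phi[win] <- a$phi[win]
  child$psi[win] <- a$psi[win]
  try_close(child, tol)
}

#' Mutation of a conformation
#'
#' Perturbs the torsions of a random cyclic window, each residue by a
#' uniform point in the disk of the given radius; proposals landing in a
#' prohibited Ramachandran region are re-drawn (up to 10 attempts) and
#' otherwise skipped. The ring is re-closed afterwards.
#'
#' @param ind individual or [torsion_conformation()].
#' @param radius disk radius, degrees (> 0).
#' @param map `rama_map` defining prohibited regions.
#' @param tol closure tolerance.
#' @return a closed [torsion_conformation()] or NULL.
#' @export
mutate <- function(ind, radius = 20, map = default_glycine_map(),
                   tol = 1e-6) {
  if (radius <= 0) stop("radius must be positive")
  conf <- ind$conformation %||% ind
  win <- sample_window(conf$n)
  child <- conf
  for (r in win) {
    for (a in seq_len(10)) {
      rr <- radius * sqrt(runif(1))
      th <- runif(1, 0, 2 * pi)
      np <- wrap_angle(conf$phi[r] + rr * cos(th))
      ns <- wrap_angle(conf$psi[r] + rr * sin(th))
      if (rama_allowed(map, np, ns)) {
        child$phi[r] <- np
        child$psi[r] <- ns
        break
      }
    }
  }
  try_close(child, tol)
}

# initial population: SA-seeded (sequence mode) or direct closures of
# random bin-center starts (toy mode); relaxed, sorted, clustered, and cut
# to 2 * N_GA(0)
#' Initial GA population
#'
#' Samples backbones (by layered simulated annealing, plus low-RMSD
#' annealing when a native reference is available; or by direct closure of
#' random bin-center starts in "direct" mode), relaxes them, sorts by
#' energy, clusters, and returns the 2 N_GA(0) lowest-energy cluster
#' centers. Without a native reference only the low-energy sampling feeds
#' the pool (prediction mode).
#'
#' @param energy_fn GA objective, function(conf) -> kcal/mol.
#' @param config a [ga_config()].
#' @param native optional [backbone_structure()].
#' @param map `rama_map` for sampling moves.
#' @return list of individuals sorted ascending by energy.
#' @export
init_population <- function(energy_fn, config, native = NULL,
                            map = default_glycine_map()) {
  n <- config$n
  starts <- enumerate_initial_configurations(n, limit = config$init$n_starts,
                                             seed = config$seed)
  confs <- list()
  if (identical(config$init$mode, "sa")) {
    sched <- anneal_schedule(n, steps = config$init$sa_steps)
    cand <- sample_backbones(starts, sched, seed = config$seed, map = map)
    confs <- lapply(cand, `[[`, "conformation")
    if (!is.null(native)) {
      nt <- measure_torsions(native)
      lr <- low_rmsd_annealing(nt, native, sched, map = map,
                               seed = config$seed + 1L)
      confs <- c(confs, lapply(lr, `[[`, "conformation"))
    }
  } else {
    for (s in starts) {
      cc <- try_close(s, config$closure_tol)
      if (!is.null(cc)) confs[[length(confs) + 1]] <- cc
    }
  }
  if (length(confs) == 0) stop("initial sampling produced no candidates")
  inds <- lapply(confs, relax_conformation, energy_fn = energy_fn,
                 closure_weight = config$closure_weight,
                 maxit = config$relax_maxit)
  e <- vapply(inds, `[[`, numeric(1), "energy")
  inds <- inds[order(e)]
  centers <- energy_cluster(inds, config$cluster_rmsd_cutoff)
  inds[centers][seq_len(min(length(centers),
                            2 * config$population_schedule(0)))]
}

#' Advance the genetic algorithm by one generation
#'
#' Generates crossover and mutation children (2 x population), re-closes
#' and relaxes them, merges with the parents, clusters by energy-sorted
#' greedy RMSD, and keeps the N_GA(i) lowest-energy centers. Centers with
#' energy below the recording ceiling are appended to the landscape
#' accumulator.
#'
#' @param population list of individuals.
#' @param config a [ga_config()].
#' @param i generation index (0-based).
#' @param energy_fn GA objective.
#' @param native optional reference for record RMSDs.
#' @param recorder environment with a `records` list, or NULL.
#' @param map `rama_map` for mutation.
#' @return next population (ascending energy).
#' @export
next_generation <- function(population, config, i, energy_fn, native = NULL,
                            recorder = NULL, map = default_glycine_map()) {
  if (length(population) == 0) stop("population is extinct")
  nch <- 2 * length(population)
  children <- list()
  for (k in seq_len(nch)) {
    child <- NULL
    if (runif(1) < config$crossover_rate && length(population) >= 2) {
      ps <- sample(length(population), 2)
      child <- crossover(population[[ps[1]]], population[[ps[2]]],
                         tol = config$closure_tol)
    } else {
      child <- mutate(population[[sample(length(population), 1)]],
                      radius = config$mutation_radius, map = map,
                      tol = config$closure_tol)
    }
    if (!is.null(child))
      children[[length(children) + 1]] <-
        relax_conformation(child, energy_fn,
                           closure_weight = config$closure_weight,
                           maxit = config$relax_maxit)
  }
  merged <- c(population, children)
  if (length(merged) == 0) stop("population is extinct")
  centers <- energy_cluster(merged, config$cluster_rmsd_cutoff)
  keep <- merged[centers][seq_len(min(length(centers),
                                      config$population_schedule(i)))]
  if (!is.null(recorder)) {
    for (ind in keep) {
      if (ind$energy < config$record_energy_ceiling) {
        rec <- list(conformation = ind$conformation,
                    structure = ind$structure, energy = ind$energy,
                    rmsd = if (!is.null(native))
                      kabsch_rmsd(native, ind$structure) else NA_real_,
                    generation = i)
        recorder$records[[length(recorder$records) + 1]] <- rec
      }
    }
  }
  keep
}

#' Run the ClusterGen landscape sampler
#'
#' Full pipeline: initial population (dual SA seeding, or direct closures
#' in toy mode), then `generations` rounds of crossover / mutation /
#' relax / clustering / selection, recording all cluster centers with
#' energy below the ceiling. When no native reference is given the RMSDs
#' are computed at the end against the lowest-energy recorded structure.
#'
#' @param config a [ga_config()].
#' @param sequence chirality-coded sequence (builds the default energy
#'   function) - optional if `energy_fn` is given.
#' @param native optional reference [backbone_structure()].
#' @param energy_fn optional custom objective, function(conf) -> kcal/mol.
#' @param map `rama_map` for sampling and mutation moves.
#' @param verbose print per-generation progress.
#' @return an [energy_landscape()] with stored conformations.
#' @export
run_clustergen <- function(config, sequence = NULL, native = NULL,
                           energy_fn = NULL,
                           map = default_glycine_map(), verbose = FALSE) {
  if (is.null(energy_fn)) {
    if (is.null(sequence)) stop("need a sequence or an energy function")
    energy_fn <- make_energy_function(sequence)
  }
  set.seed(config$seed)
  pop <- init_population(energy_fn, config, native = native, map = map)
  recorder <- new.env()
  recorder$records <- list()
  # the initial population's qualifying members are part of the landscape
  for (ind in pop) {
    if (ind$energy < config$record_energy_ceiling) {
      recorder$records[[length(recorder$records) + 1]] <-
        list(conformation = ind$conformation, structure = ind$structure,
             energy = ind$energy,
             rmsd = if (!is.null(native)) kabsch_rmsd(native, ind$structure)
                    else NA_real_,
             generation = -1)
    }
  }
  if (config$generations > 0) {
    for (i in 0:(config$generations - 1)) {
      pop <- next_generation(pop, config, i, energy_fn, native = native,
                             recorder = recorder, map = map)
      if (verbose)
        message(sprintf("generation %d: pop %d, best %.3f", i, length(pop),
                        pop[[1]]$energy))
    }
  }
  recs <- recorder$records
  if (length(recs) == 0)
    return(energy_landscape(numeric(0), numeric(0), native = native,
                            lambda = default_lambda(config$n)))
  e <- vapply(recs, `[[`, numeric(1), "energy")
  r <- vapply(recs, `[[`, numeric(1), "rmsd")
  structs <- lapply(recs, `[[`, "structure")
  if (is.null(native)) {
    best <- which.min(e)
    native <- structs[[best]]
    r <- vapply(structs, function(s) kabsch_rmsd(native, s), numeric(1))
  }
  energy_landscape(e, r, native = native, conformations = structs,
                   lambda = default_lambda(config$n))
}

#' Predict macrocycle structures from sequence alone
#'
#' Runs ClusterGen without a native reference, clusters the 50
#' lowest-energy recorded structures at a 1.5 Angstrom RMSD cutoff, and
#' returns the (at most) five lowest-energy cluster centers as the
#' predictions.
#'
#' @param config a [ga_config()].
#' @param sequence,energy_fn,map as in [run_clustergen()].
#' @param pool_size records entering the final clustering.
#' @param cutoff final clustering cutoff, Angstrom.
#' @param top predictions returned.
#' @return list of individuals, ascending energy; attribute `flagged` is
#'   TRUE when the landscape held fewer than `top` records.
#' @export
predict_structure <- function(config, sequence = NULL, energy_fn = NULL,
                              map = default_glycine_map(), pool_size = 50,
                              cutoff = 1.5, top = 5) {
  ls <- run_clustergen(config, sequence = sequence, native = NULL,
                       energy_fn = energy_fn, map = map)
  e <- ls$records$energy
  ord <- order(e)[seq_len(min(pool_size, length(e)))]
  inds <- lapply(ord, function(i)
    list(conformation = attr(ls$conformations[[i]], "provenance") %||%
           ls$conformations[[i]]$provenance,
         structure = ls$conformations[[i]], energy = e[i]))
  centers <- energy_cluster(inds, cutoff)
  out <- inds[centers][seq_len(min(top, length(centers)))]
  attr(out, "flagged") <- length(e) < top
  out
}
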