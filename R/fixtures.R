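# Deterministic synthetic fixtures: closed toy backbones, a helical-turn
# structure with i,i+3/i,i+4 hydrogen bonds, a two-funnel landscape built
# from real conformations, a planted-minimum toy energy system for the
# genetic algorithm, and sample clouds for FES tests. Everything is
# generated in code; no external data.

#' Generate synthetic test fixtures
#'
#' @param kind one of `"closed_backbone"`, `"helical_turn"`,
#'   `"two_funnel_landscape"`, `"planted_minimum_system"`,
#'   `"bivariate_samples"`.
#' @param n residue count (where meaningful).
#' @param seed RNG seed; identical seeds give identical fixtures.
#' @param ... kind-specific overrides (see details of each branch).
#' @return kind-specific object, see below.
#' @export
fixture_generator <- function(kind, n = 7, seed = 1, ...) {
  set.seed(seed)
  switch(kind,
         closed_backbone = fixture_closed_backbones(n, ...),
         helical_turn = fixture_helical_turn(n, ...),
         two_funnel_landscape = fixture_two_funnel(n, ...),
         planted_minimum_system = fixture_planted(n, ...),
         bivariate_samples = fixture_bivariate(...),
         stop("unknown fixture kind: ", kind))
}

# closed conformations found by local closure from sampled bin-center
# starts; all have cyclic error <= tol
fixture_closed_backbones <- function(n, count = 5, tol = 1e-8) {
  starts <- enumerate_initial_configurations(
    n, limit = 12 * count, seed = sample.int(1e6, 1))
  out <- list()
  for (s in starts) {
    cc <- tryCatch(close_backbone(s, tolerance = tol, max_restarts = 3),
                   error = function(e) NULL)
    if (!is.null(cc)) out[[length(out) + 1]] <- cc
    if (length(out) >= count) break
  }
  out
}

# open alpha-helical segment: canonical helix torsions produce i,i+3 and
# i,i+4 CO...HN hydrogen bonds by construction
fixture_helical_turn <- function(n = 8, phi = -61, psi = -41) {
  forward_kinematics(torsion_conformation(rep(phi, n), rep(psi, n)))
}

# landscape with a shallow funnel at the native and a deeper funnel at a
# distant alternative conformation; reshaping should raise PNear
fixture_two_funnel <- function(n = 7, members = 25, jitter = 4,
                               depth_native = -2, depth_alt = -6) {
  closed <- fixture_closed_backbones(n, count = 6)
  if (length(closed) < 2) stop("could not build two distinct closed rings")
  # pick the pair with the largest mutual RMSD
  structs <- lapply(closed, forward_kinematics)
  best <- c(1, 2); bestd <- -1
  for (i in 1:(length(structs) - 1)) for (j in (i + 1):length(structs)) {
    d <- cyclic_min_rmsd(structs[[i]], structs[[j]])$rmsd
    if (d > bestd) { bestd <- d; best <- c(i, j) }
  }
  base <- list(closed[[best[1]]], closed[[best[2]]])
  native <- structs[[best[1]]]
  confs <- list(); energy <- c()
  for (f in 1:2) {
    for (m in seq_len(members)) {
      cf <- base[[f]]
      cf$phi <- wrap_angle(cf$phi + rnorm(n, sd = jitter))
      cf$psi <- wrap_angle(cf$psi + rnorm(n, sd = jitter))
      confs[[length(confs) + 1]] <- forward_kinematics(cf)
      energy <- c(energy,
                  (if (f == 1) depth_native else depth_alt) +
                    abs(rnorm(1, sd = 0.5)))
    }
  }
  rmsd <- vapply(confs, function(s) kabsch_rmsd(native, s), numeric(1))
  energy_landscape(energy, rmsd, native = native, conformations = confs,
                   lambda = default_lambda(n))
}

# toy system: per-residue quadratic torsion wells centered on a planted
# closed conformation; unique global minimum at the planted state
fixture_planted <- function(n = 6, sigma = 60, depth = 20) {
  start <- enumerate_initial_configurations(n, limit = 1,
                                            seed = sample.int(1e6, 1))[[1]]
  planted <- close_backbone(start, tolerance = 1e-10, max_restarts = 5)
  energy_fn <- function(conf) {
    sum((angle_diff(conf$phi, planted$phi)^2 +
         angle_diff(conf$psi, planted$psi)^2) / sigma^2) - depth
  }
  list(n = n, planted = planted, structure = forward_kinematics(planted),
       energy_fn = energy_fn, sigma = sigma, depth = depth)
}

fixture_bivariate <- function(ns = 10000, rmsd_mean = 2, rmsd_sd = 0.5,
                              rg_mean = 6, rg_sd = 0.8) {
  list(rmsd = abs(rnorm(ns, rmsd_mean, rmsd_sd)),
       rg = abs(rnorm(ns, rg_mean, rg_sd)))
}
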