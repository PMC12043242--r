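# Genetic-algorithm landscape sampler: clustering, operators, generation
# turnover, and planted-minimum recovery.

toy_system <- fixture_generator("planted_minimum_system", n = 6, seed = 201)

mk_individual <- function(conf, energy_fn) {
  list(conformation = conf, structure = forward_kinematics(conf),
       energy = energy_fn(conf))
}

test_that("population schedules follow the published profiles", {
  expect_equal(ga_population_schedule("15")(0), 500)
  expect_equal(ga_population_schedule("15")(49), 500)
  expect_equal(ga_population_schedule("20")(10), 700)
  expect_equal(ga_population_schedule("20")(49), 505)
  expect_equal(ga_population_schedule("24")(0), 1000)
  expect_equal(ga_population_schedule("24")(49), 510)
  expect_error(ga_config(6, profile = "toy",
                         population_schedule = function(i) 50 - 5 * i),
               "positive")
})

test_that("greedy energy clustering matches a brute-force oracle", {
  set.seed(22)
  fx <- toy_system
  inds <- list()
  base <- fx$planted
  for (i in 1:30) {
    cf <- base
    cf$phi <- wrap_angle(cf$phi + rnorm(6, sd = sample(c(2, 40), 1)))
    cf$psi <- wrap_angle(cf$psi + rnorm(6, sd = sample(c(2, 40), 1)))
    inds[[i]] <- mk_individual(cf, fx$energy_fn)
  }
  cutoff <- 1.0
  centers <- energy_cluster(inds, cutoff)
  # oracle: replay the greedy definition directly
  e <- vapply(inds, `[[`, numeric(1), "energy")
  ord <- order(e)
  expected <- integer(0)
  for (i in ord) {
    ok <- TRUE
    for (c in expected) {
      if (cyclic_min_rmsd(inds[[c]]$structure,
                          inds[[i]]$structure)$rmsd < cutoff) {
        ok <- FALSE
        break
      }
    }
    if (ok) expected <- c(expected, i)
  }
  expect_identical(centers, expected)
  # every center is >= cutoff from every other center
  for (a in seq_along(centers)) for (b in seq_along(centers)) {
    if (a >= b) next
    expect_gte(cyclic_min_rmsd(inds[[centers[a]]]$structure,
                               inds[[centers[b]]]$structure)$rmsd, cutoff)
  }
  # two near-identical structures collapse onto the lower-energy one
  twin <- inds[[1]]
  twin$energy <- inds[[1]]$energy + 1
  got <- energy_cluster(list(inds[[1]], twin), cutoff)
  expect_identical(got, 1L)
})

test_that("crossover swaps a window and only returns closed offspring", {
  fx <- toy_system
  set.seed(23)
  parents <- fixture_generator("closed_backbone", n = 6, seed = 31,
                               count = 2)
  expect_length(parents, 2)
  a <- parents[[1]]; b <- parents[[2]]
  # identical parents reproduce themselves (the gate trivially passes)
  same <- crossover(a, a, tol = 1e-6)
  expect_false(is.null(same))
  expect_equal(same$phi, a$phi, tolerance = 1e-3)
  got_one <- FALSE
  for (i in 1:10) {
    child <- crossover(a, b, tol = 1e-6)
    if (!is.null(child)) {
      got_one <- TRUE
      expect_lte(cyclic_error(child), 1e-6)
    }
  }
  expect_true(got_one)
})

test_that("mutation perturbs a window within the map and restores closure", {
  set.seed(24)
  base <- fixture_generator("closed_backbone", n = 6, seed = 31,
                            count = 1)[[1]]
  child <- NULL
  for (i in 1:10) {
    child <- mutate(base, radius = 15, tol = 1e-6)
    if (!is.null(child)) break
  }
  expect_false(is.null(child))
  expect_lte(cyclic_error(child), 1e-6)
  expect_error(mutate(base, radius = 0), "positive")
})

test_that("generations keep elitism and the scheduled population size", {
  fx <- toy_system
  set.seed(25)
  cfg <- ga_config(6, profile = "toy", generations = 3, seed = 7)
  pop <- init_population(fx$energy_fn, cfg)
  expect_lte(length(pop), 2 * cfg$population_schedule(0))
  e <- vapply(pop, `[[`, numeric(1), "energy")
  expect_identical(order(e), seq_along(e))  # sorted ascending
  rec <- new.env(); rec$records <- list()
  best <- min(e)
  for (i in 0:2) {
    pop <- next_generation(pop, cfg, i, fx$energy_fn, recorder = rec)
    expect_lte(length(pop), cfg$population_schedule(i))
    nb <- min(vapply(pop, `[[`, numeric(1), "energy"))
    expect_lte(nb, best + 1e-9)  # parents compete with children
    best <- nb
  }
  # recorded centers all satisfy the energy ceiling
  if (length(rec$records))
    expect_true(all(vapply(rec$records, `[[`, numeric(1), "energy") <
                    cfg$record_energy_ceiling))
})

test_that("run_clustergen is seed-reproducible and bounded by the schedule", {
  fx <- toy_system
  cfg <- ga_config(6, profile = "toy", generations = 2, seed = 11,
                   init = list(mode = "direct", n_starts = 20))
  ls1 <- run_clustergen(cfg, energy_fn = fx$energy_fn)
  ls2 <- run_clustergen(cfg, energy_fn = fx$energy_fn)
  expect_equal(ls1$records, ls2$records)
  expect_lte(nrow(ls1$records),
             2 * cfg$population_schedule(0) +
               sum(vapply(0:1, cfg$population_schedule, numeric(1))))
  # every recorded structure is a verified closure
  for (s in ls1$conformations[seq_len(min(5, length(ls1$conformations)))]) {
    conf <- s$provenance
    expect_lte(cyclic_error(conf), 1e-4)
  }
  # with generations = 0 the landscape is the recorded initial population
  cfg0 <- ga_config(6, profile = "toy", generations = 0, seed = 11,
                    init = list(mode = "direct", n_starts = 20))
  ls0 <- run_clustergen(cfg0, energy_fn = fx$energy_fn)
  expect_lte(nrow(ls0$records), 2 * cfg0$population_schedule(0))
})

test_that("prediction recovers the planted minimum and respects the cutoff", {
  fx <- fixture_generator("planted_minimum_system", n = 6, seed = 301)
  cfg <- ga_config(6, profile = "toy", generations = 5, seed = 13)
  preds <- predict_structure(cfg, energy_fn = fx$energy_fn)
  expect_lte(length(preds), 5)
  e <- vapply(preds, `[[`, numeric(1), "energy")
  expect_identical(order(e), seq_along(e))
  # pairwise separation respects the 1.5 A prediction cutoff
  if (length(preds) >= 2) {
    for (a in 1:(length(preds) - 1)) for (b in (a + 1):length(preds))
      expect_gte(cyclic_min_rmsd(preds[[a]]$structure,
                                 preds[[b]]$structure)$rmsd, 1.5)
  }
  expect_lt(cyclic_min_rmsd(fx$structure, preds[[1]]$structure)$rmsd, 0.5)
})

test_that("sequence-based objective drives the full pipeline end to end", {
  cfg <- ga_config(6, profile = "toy", generations = 1, seed = 17,
                   init = list(mode = "direct", n_starts = 10),
                   record_energy_ceiling = Inf)
  ls <- run_clustergen(cfg, sequence = "GAGGaG")
  expect_s3_class(ls, "energy_landscape")
  expect_gt(nrow(ls$records), 0)
  expect_true(all(is.finite(ls$records$energy)))
  expect_gte(min(ls$records$rmsd), 0)
  p <- pnear(ls)
  expect_true(p > 0 && p <= 1)
})
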