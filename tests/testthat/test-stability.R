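# RMSD machinery, PNear, stability filtering, reshaping, compactness and
# H-bond topology analytics, and FES histogramming.

test_that("Kabsch RMSD is zero on rigid copies and matches the grid oracle", {
  a <- forward_kinematics(closed_ring(7))
  expect_equal(kabsch_rmsd(a, a), 0)
  b <- transform_structure(a, seed = 5)
  expect_lt(kabsch_rmsd(a, b), 1e-9)
  # brute-force SO(3) grid oracle on perturbed coordinate sets
  set.seed(6)
  for (i in 1:3) {
    pa <- heavy_coords(a)[1:12, ]
    pb <- pa + matrix(rnorm(length(pa), sd = 0.2), ncol = 3)
    exact <- .cpp_kabsch_rmsd(pa, pb)
    grid <- oracle_grid_rmsd(pa, pb, steps = 16, refine = TRUE)
    expect_gte(grid, exact - 1e-9)  # grid can never beat the optimum
    expect_lt(grid - exact, 1e-3)
  }
  # cross-check against an established superposition implementation
  pa <- heavy_coords(a)
  pb <- rigid_motion(pa + matrix(rnorm(length(pa), sd = 0.3), ncol = 3),
                     seed = 9)
  fit <- suppressWarnings(bio3d::fit.xyz(as.numeric(t(pa)), as.numeric(t(pb))))
  ref_rmsd <- sqrt(mean(rowSums((matrix(fit, ncol = 3, byrow = TRUE) -
                                   pa)^2)))
  expect_equal(.cpp_kabsch_rmsd(pa, pb), ref_rmsd, tolerance = 1e-6)
})

test_that("cyclic relabeling RMSD finds the rotation and bounds plain RMSD", {
  a <- forward_kinematics(closed_ring(7))
  # relabel residues of a by 2: residue i of b is residue i+2 of a
  b <- a
  idx <- ((seq_len(7) - 1 + 2) %% 7) + 1
  for (at in c("N", "CA", "C", "O", "H")) b[[at]] <- a[[at]][idx, ]
  r <- cyclic_min_rmsd(a, b)
  expect_lt(r$rmsd, 1e-9)
  expect_identical(r$offset, 5L)  # residue i of a sits at i+5 of b (mod 7)
  set.seed(7)
  for (i in 1:5) {
    c2 <- forward_kinematics(torsion_conformation(runif(7, -180, 180),
                                                  runif(7, -180, 180)))
    both <- cyclic_min_rmsd(a, c2)
    expect_lte(both$rmsd, kabsch_rmsd(a, c2) + 1e-12)
    # brute-force over all relabelings
    best <- Inf
    for (o in 0:6) {
      bo <- c2
      idx <- ((seq_len(7) - 1 + o) %% 7) + 1
      for (at in c("N", "CA", "C", "O")) bo[[at]] <- c2[[at]][idx, ]
      best <- min(best, kabsch_rmsd(a, bo))
    }
    expect_equal(both$rmsd, best, tolerance = 1e-9)
    # pseudo-metric symmetry
    expect_equal(cyclic_min_rmsd(c2, a)$rmsd, both$rmsd, tolerance = 1e-9)
  }
})

test_that("PNear has its analytic limits and invariances", {
  expect_equal(pnear(c(0, -1, 2), rep(0, 3), lambda = 0.5), 1)
  expect_equal(pnear(0, 0.5, lambda = 0.5), exp(-1))
  # half split between a perfect and an infinitely distant record
  expect_equal(pnear(c(0, 0), c(0, 1e9), lambda = 0.5), 0.5)
  # naive unstabilized evaluation agrees on benign energies
  set.seed(8)
  e <- runif(40, -2, 2); r <- runif(40, 0, 4)
  naive <- sum(exp(-r^2 / 1.5^2) * exp(-e / 0.62)) / sum(exp(-e / 0.62))
  expect_equal(pnear(e, r, lambda = 1.5), naive, tolerance = 1e-12)
  # energy-shift invariance at extreme offsets (log-sum-exp stabilization)
  expect_equal(pnear(e + 5000, r, lambda = 1.5),
               pnear(e, r, lambda = 1.5), tolerance = 1e-12)
  # monotone: decreasing any record's RMSD cannot decrease PNear
  r2 <- r; r2[7] <- r2[7] / 2
  expect_gte(pnear(e, r2, lambda = 1.5), pnear(e, r, lambda = 1.5))
  expect_true(pnear(e, r, lambda = 1.5) > 0 &&
              pnear(e, r, lambda = 1.5) <= 1)
  expect_error(pnear(numeric(0), numeric(0), lambda = 1), "empty")
})

test_that("threading filter keeps glycine everywhere and applies residue maps", {
  pool <- fixture_generator("closed_backbone", n = 5, seed = 3, count = 3)
  out <- rama_stability_filter("GGGGG", pool)
  # glycine is the most permissive map and offset-invariant: members whose
  # torsions all lie in the allowed region pass at every offset, members
  # with any disallowed residue pass at none
  gly_ok <- vapply(pool, function(cf)
    all(rama_allowed(default_glycine_map(), cf$phi, cf$psi)), logical(1))
  expect_identical(nrow(out), sum(gly_ok) * 5L)
  expect_gt(nrow(out), 0)
  expect_identical(attr(out, "tests"), length(pool) * 5L)
  # independent re-verification of every kept pair by direct map lookup
  seqs <- "GAPav"
  out2 <- rama_stability_filter(seqs, pool)
  aas <- strsplit(seqs, "")[[1]]
  for (r in seq_len(nrow(out2))) {
    conf <- pool[[out2$candidate[r]]]
    for (res in 1:5) {
      sp <- ((res - 1 - out2$offset[r]) %% 5) + 1
      expect_true(rama_allowed(map_for_residue(aas[sp]),
                               conf$phi[res], conf$psi[res]))
    }
  }
  # a proline-containing sequence can only shrink the compatible set
  expect_lte(nrow(out2), nrow(out))
  expect_error(rama_stability_filter("GG", pool), "match")
})

test_that("reshaping recenters the landscape on the energy minimum", {
  ls <- fixture_generator("two_funnel_landscape", n = 7, seed = 10)
  p0 <- pnear(ls)
  rs <- reshape_landscape(ls)
  expect_equal(rs$records$energy, ls$records$energy)
  best <- which.min(ls$records$energy)
  expect_equal(rs$records$rmsd[best], 0, tolerance = 1e-6)
  # the deeper funnel is off-native by construction, so reshaping helps
  expect_gt(pnear(rs), p0)
  # if the old native already is the minimum, reshaping changes nothing
  ls2 <- ls
  ls2$records$energy[ls$records$rmsd < 0.5][1] <- min(ls$records$energy) - 5
  rs2 <- reshape_landscape(ls2)
  expect_lt(rs2$records$rmsd[which.min(ls2$records$energy)], 1e-6)
})

test_that("backbone radius and radius of gyration have known small cases", {
  sq <- matrix(c(0, 0, 0, 1, 0, 0, 1, 1, 0, 0, 1, 0), 4, 3, byrow = TRUE)
  expect_equal(radius_of_gyration(sq), sqrt(2) / 2, tolerance = 1e-12)
  expect_equal(radius_of_gyration(matrix(c(5, 5, 5), 1)), 0)
  expect_equal(radius_of_gyration(matrix(c(0, 0, 0, 1, 0, 0), 2,
                                         byrow = TRUE)), 0.5)
  s <- forward_kinematics(closed_ring(7))
  r1 <- backbone_radius(s)
  expect_equal(backbone_radius(transform_structure(s, seed = 2)), r1,
               tolerance = 1e-9)
  expect_equal(r1, radius_of_gyration(heavy_coords(s)), tolerance = 1e-12)
})

test_that("H-bond chord crossings match the planar drawing rule", {
  b <- function(...) {
    m <- matrix(c(...), ncol = 2, byrow = TRUE)
    data.frame(donor = m[, 1], acceptor = m[, 2])
  }
  expect_identical(hbond_intersections(b(1, 4), 7), 0L)
  expect_identical(hbond_intersections(b(1, 4, 2, 6), 7), 1L)
  expect_identical(hbond_intersections(b(1, 4, 5, 7), 7), 0L)
  expect_identical(hbond_intersections(b(1, 4, 4, 6), 7), 0L) # shared endpoint
  expect_error(hbond_intersections(b(1, 9), 7), "range")
  # brute force over all pairs on random bond sets
  set.seed(11)
  for (i in 1:20) {
    n <- sample(6:10, 1)
    m <- 5
    bonds <- data.frame(donor = sample(n, m, replace = TRUE),
                        acceptor = sample(n, m, replace = TRUE))
    bonds <- bonds[bonds$donor != bonds$acceptor, ]
    # oracle: walk the cycle and test separation patterns pairwise
    crossings <- 0L
    if (nrow(bonds) >= 2) {
      for (a in 1:(nrow(bonds) - 1)) for (bb in (a + 1):nrow(bonds)) {
        ij <- c(bonds$donor[a], bonds$acceptor[a])
        kl <- c(bonds$donor[bb], bonds$acceptor[bb])
        if (length(intersect(ij, kl))) next
        inside <- function(x) ((x - ij[1]) %% n) > 0 &&
          ((x - ij[1]) %% n) < ((ij[2] - ij[1]) %% n)
        if (xor(inside(kl[1]), inside(kl[2]))) crossings <- crossings + 1L
      }
    }
    expect_identical(hbond_intersections(bonds, n), crossings)
  }
})

test_that("FES has the stated closed forms and normalization", {
  # all samples in one cell
  f1 <- free_energy_surface(rep(1, 10), rep(2, 10), temperature = 300)
  occ <- which(!is.na(f1$free_energy))
  expect_identical(length(occ), 1L)
  expect_equal(f1$free_energy[occ], 0)
  # two equally occupied cells
  f2 <- free_energy_surface(c(rep(0, 5), rep(5, 5)), rep(1, 10),
                            temperature = 300)
  vals <- f2$free_energy[!is.na(f2$free_energy)]
  expect_length(vals, 2)
  expect_equal(vals, rep(-f2$RT * log(0.5), 2))
  # normalization and modal-cell minimum on a seeded bivariate cloud
  cl <- fixture_generator("bivariate_samples", seed = 12)
  fes <- free_energy_surface(cl$rmsd, cl$rg, temperature = 300)
  expect_equal(sum(exp(-fes$free_energy / fes$RT), na.rm = TRUE), 1,
               tolerance = 1e-9)
  mode_cell <- which(fes$prob == max(fes$prob), arr.ind = TRUE)[1, ]
  min_cell <- which(fes$free_energy == min(fes$free_energy, na.rm = TRUE),
                    arr.ind = TRUE)[1, ]
  expect_identical(mode_cell, min_cell)
  expect_error(free_energy_surface(numeric(0), numeric(0)), "nonempty")
})
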