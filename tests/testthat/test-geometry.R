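# Frame-chain kinematics, the cyclic error function and backbone closure.

test_that("bend and twist rotations have the stated closed forms", {
  expect_equal(plane_rotation(180), diag(3))
  R90 <- plane_rotation(90)
  expect_equal(R90[3, ], c(0, 0, 1))
  expect_equal(R90[, 3], c(0, 0, 1))
  expect_equal(R90[1:2, 1:2],
               matrix(c(cos(pi / 2), sin(pi / 2),
                        -sin(pi / 2), cos(pi / 2)), 2))
  # independent 2D evaluation of the bend by 180 - 111.2 = 68.8 degrees
  a <- (180 - 111.2) * pi / 180
  expect_equal(plane_rotation(111.2)[1:2, 1:2],
               matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2),
               tolerance = 1e-12)
  expect_error(plane_rotation(0), "0, 180")
  expect_error(plane_rotation(200), "0, 180")

  expect_equal(torsion_rotation(0), diag(3))
  for (phi in c(-170, -45, 10, 111))
    expect_equal(as.numeric(torsion_rotation(phi) %*% c(1, 0, 0)),
                 c(1, 0, 0))
  expect_equal(torsion_rotation(180), torsion_rotation(-180))
})

test_that("step vector matches the ideal-geometry value and degenerate limits", {
  q <- step_vector(ideal_geometry())
  expect_equal(q[1], 3.5620, tolerance = 5e-4)
  expect_equal(q[2], 1.3322, tolerance = 5e-4)
  expect_equal(q[3], 0, tolerance = 5e-4)
  # collinear chain: straight bonds add up
  g <- ideal_geometry(theta_n = 180, theta_cp = 180)
  expect_equal(step_vector(g)[1], 1.458 + 1.329 + 1.524, tolerance = 1e-12)
  expect_equal(step_vector(g)[2:3], c(0, 0), tolerance = 1e-12)
  # trans peptide keeps the construction planar for any bond angles
  set.seed(1)
  for (i in 1:10) {
    g <- ideal_geometry(theta_n = runif(1, 60, 179),
                        theta_ca = runif(1, 60, 179),
                        theta_cp = runif(1, 60, 179))
    expect_equal(step_vector(g)[3], 0, tolerance = 1e-12)
  }
})

test_that("residue matrix is a proper rotation equal to its factor chain", {
  set.seed(2)
  g <- ideal_geometry()
  for (i in 1:20) {
    phi <- runif(1, -180, 180); psi <- runif(1, -180, 180)
    M <- residue_matrix(phi, psi, g)
    expect_equal(t(M) %*% M, diag(3), tolerance = 1e-12)
    expect_equal(det(M), 1, tolerance = 1e-12)
    # naive independent composition of the five stated factors
    Mref <- plane_rotation(g$theta_cp) %*% torsion_rotation(g$omega) %*%
      plane_rotation(g$theta_n) %*% torsion_rotation(phi) %*%
      plane_rotation(g$theta_ca) %*% torsion_rotation(psi)
    expect_equal(M, Mref, tolerance = 1e-12)
  }
})

test_that("cyclic error equals the Cartesian frame-chain mismatch", {
  set.seed(3)
  for (rep in 1:40) {
    n <- sample(4:10, 1)
    phi <- runif(n, -180, 180); psi <- runif(n, -180, 180)
    e_mat <- cyclic_error(torsion_conformation(phi, psi))
    e_cart <- oracle_cartesian_ecyc(phi, psi)
    expect_gte(e_mat, 0)
    expect_equal(e_mat, e_cart, tolerance = 1e-9)
  }
})

test_that("cyclic error is invariant under backbone mirroring", {
  set.seed(4)
  for (rep in 1:20) {
    n <- sample(4:9, 1)
    phi <- runif(n, -180, 180); psi <- runif(n, -180, 180)
    expect_equal(cyclic_error(torsion_conformation(phi, psi)),
                 cyclic_error(torsion_conformation(-phi, -psi)),
                 tolerance = 1e-12)
  }
})

test_that("forward kinematics reproduces ideal bonds and fixed omega", {
  conf <- closed_ring(7)
  s <- forward_kinematics(conf)
  for (k in 1:7) {
    expect_equal(sqrt(sum((s$N[k, ] - s$CA[k, ])^2)), 1.458,
                 tolerance = 1e-9)
    expect_equal(sqrt(sum((s$CA[k, ] - s$C[k, ])^2)), 1.524,
                 tolerance = 1e-9)
    nxt <- if (k == 7) 1 else k + 1
    expect_equal(sqrt(sum((s$C[k, ] - s$N[nxt, ])^2)), 1.329,
                 tolerance = 1e-6)
    om <- dihedral_angle(s$CA[k, ], s$C[k, ], s$N[nxt, ], s$CA[nxt, ])
    expect_equal(abs(om), 180, tolerance = 1e-5)
  }
  expect_equal(s$N[1, ], c(0, 0, 0))
})

test_that("measured torsions invert forward kinematics", {
  conf <- closed_ring(6, seed = 9)
  mt <- measure_torsions(forward_kinematics(conf))
  expect_equal(wrap_angle(mt$phi - conf$phi), rep(0, 6), tolerance = 1e-6)
  expect_equal(wrap_angle(mt$psi - conf$psi), rep(0, 6), tolerance = 1e-6)
  # open chains: all non-seam torsions round-trip
  set.seed(5)
  n <- 8
  phi <- runif(n, -180, 180); psi <- runif(n, -180, 180)
  open_conf <- torsion_conformation(phi, psi)
  mt <- measure_torsions(forward_kinematics(open_conf))
  expect_equal(wrap_angle(mt$phi[-1] - phi[-1]), rep(0, n - 1),
               tolerance = 1e-6)
  expect_equal(wrap_angle(mt$psi[-n] - psi[-n]), rep(0, n - 1),
               tolerance = 1e-6)
})

test_that("mirrored coordinates negate every torsion", {
  conf <- closed_ring(7)
  s <- forward_kinematics(conf)
  m <- s
  for (at in c("N", "CA", "C", "O", "H"))
    m[[at]][, 3] <- -m[[at]][, 3]
  m$provenance <- NULL
  mt <- measure_torsions(m)
  ref <- measure_torsions(s)
  expect_equal(wrap_angle(mt$phi + ref$phi), rep(0, 7), tolerance = 1e-6)
  expect_equal(wrap_angle(mt$psi + ref$psi), rep(0, 7), tolerance = 1e-6)
})

test_that("degenerate collinear geometry raises a structured error", {
  expect_error(dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0),
                              c(3, 1, 0)),
               "degenerate")
})

test_that("closure soundness: tiny cyclic error means the ring closes in space", {
  conf <- closed_ring(7)
  expect_lte(cyclic_error(conf), 1e-10)
  s <- forward_kinematics(conf)
  # the seam bond C'(n) -> N(1) must have the ideal peptide-bond length
  expect_equal(sqrt(sum((s$C[7, ] - s$N[1, ])^2)), 1.329, tolerance = 1e-4)
  # and the Cartesian mismatch oracle agrees the terminal frame matches
  expect_lte(oracle_cartesian_ecyc(conf$phi, conf$psi), 1e-8)
})

test_that("close_backbone finds closures and is a fixed point on closed input", {
  conf <- closed_ring(7)
  again <- close_backbone(conf, tolerance = 1e-8)
  expect_equal(again$phi, conf$phi)
  expect_equal(again$psi, conf$psi)
  # random starts: closures found with verified Cartesian seam
  set.seed(11)
  found <- 0
  for (i in 1:10) {
    start <- torsion_conformation(runif(7, -180, 180), runif(7, -180, 180))
    cl <- tryCatch(close_backbone(start, tolerance = 1e-6),
                   error = function(e) NULL)
    if (!is.null(cl)) {
      found <- found + 1
      expect_lte(cyclic_error(cl), 1e-6)
      s <- forward_kinematics(cl)
      expect_lte(abs(sqrt(sum((s$C[7, ] - s$N[1, ])^2)) - 1.329),
                 sqrt(1e-6))
    }
  }
  expect_gte(found, 1)
})

test_that("geometry constructors validate their inputs", {
  expect_error(ideal_geometry(d_n = -1), "positive")
  expect_error(ideal_geometry(theta_n = 190), "180")
  expect_error(torsion_conformation(1:3, 1:2), "equal length")
  expect_error(torsion_conformation(1:2, 1:2), "at least 3")
})
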