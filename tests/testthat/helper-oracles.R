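# Independent oracles used across the suite. These deliberately avoid the
# package's frame-matrix machinery: chains are built atom-by-atom from
# internal coordinates (NeRF construction), bond graphs are walked by BFS,
# and combinatorial counts come from explicit enumeration.

# place atom D given A-B-C, bond |C-D| = d, angle B-C-D = theta (rad),
# dihedral A-B-C-D = tau (rad), standard right-handed convention
nerf_place <- function(a, b, c, d, theta, tau) {
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  nrm <- c(ab[2] * bc[3] - ab[3] * bc[2],
           ab[3] * bc[1] - ab[1] * bc[3],
           ab[1] * bc[2] - ab[2] * bc[1])
  nrm <- nrm / sqrt(sum(nrm^2))
  m <- c(nrm[2] * bc[3] - nrm[3] * bc[2],
         nrm[3] * bc[1] - nrm[1] * bc[3],
         nrm[1] * bc[2] - nrm[2] * bc[1])
  d2 <- c(-d * cos(theta), d * sin(theta) * cos(tau),
          d * sin(theta) * sin(tau))
  c + d2[1] * bc + d2[2] * m + d2[3] * nrm
}

# build the 3n+3 atom ring chain (CA_n, C'_n, N_1, CA_1, ...) from torsions
# (degrees) and measure the closure mismatch: squared distance between the
# terminal image of atom 1 and atom 1, plus squared mismatches of the local
# frame x and y axes. This is the Cartesian counterpart of the cyclic error.
oracle_cartesian_ecyc <- function(phi, psi, geom = ideal_geometry()) {
  n <- length(phi)
  d <- c(geom$d_ca, geom$d_cp, geom$d_n)       # CA->C', C'->N, N->CA
  th <- deg2rad(c(geom$theta_ca, geom$theta_cp, geom$theta_n)) # at CA, C', N
  tors <- deg2rad(as.vector(rbind(rep(geom$omega, n), phi, psi)))
  atoms <- matrix(NA_real_, 3 * n + 3, 3)
  atoms[1, ] <- c(0, 0, 0)
  atoms[2, ] <- c(d[1], 0, 0)
  atoms[3, ] <- atoms[2, ] + d[2] * c(-cos(th[2]), sin(th[2]), 0)
  for (j in 3:(3 * n + 2)) {
    ty <- j %% 3 # atom j: 1 -> CA, 2 -> C', 0 -> N
    dd <- if (ty == 1) d[1] else if (ty == 2) d[2] else d[3]
    tt <- if (ty == 1) th[1] else if (ty == 2) th[2] else th[3]
    atoms[j + 1, ] <- nerf_place(atoms[j - 2, ], atoms[j - 1, ], atoms[j, ],
                                 dd, tt, tors[j - 2])
  }
  frame_axes <- function(i) {
    x <- atoms[i + 1, ] - atoms[i, ]
    x <- x / sqrt(sum(x^2))
    v <- atoms[i + 2, ] - atoms[i, ]
    y <- v - sum(v * x) * x
    y <- y / sqrt(sum(y^2))
    list(x = x, y = y)
  }
  f1 <- frame_axes(1)
  fe <- frame_axes(3 * n + 1)
  sum((atoms[3 * n + 1, ] - atoms[1, ])^2) +
    sum((fe$x - f1$x)^2) + sum((fe$y - f1$y)^2)
}

# breadth-first covalent-bond distance on the explicit cyclic bond graph
oracle_bond_graph <- function(n, atoms = c("N", "CA", "C", "O")) {
  ids <- unlist(lapply(seq_len(n), function(k) paste0(atoms, k)))
  adj <- list()
  link <- function(a, b) {
    adj[[a]] <<- c(adj[[a]], b)
    adj[[b]] <<- c(adj[[b]], a)
  }
  for (id in ids) adj[[id]] <- character(0)
  for (k in seq_len(n)) {
    nxt <- if (k == n) 1 else k + 1
    link(paste0("N", k), paste0("CA", k))
    link(paste0("CA", k), paste0("C", k))
    link(paste0("C", k), paste0("N", nxt))
    if ("O" %in% atoms) link(paste0("C", k), paste0("O", k))
  }
  list(ids = ids, adj = adj)
}

oracle_bond_sep <- function(graph, a, b) {
  dist <- stats::setNames(rep(Inf, length(graph$ids)), graph$ids)
  dist[a] <- 0
  queue <- a
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    for (nb in graph$adj[[cur]]) {
      if (dist[nb] > dist[cur] + 1) {
        dist[nb] <- dist[cur] + 1
        queue <- c(queue, nb)
      }
    }
  }
  unname(dist[b])
}

# brute-force count of rotation-equivalence classes of length-n strings
# over k symbols (explicit enumeration; n small)
oracle_necklace_count <- function(n, k = 6) {
  v <- 0:(k^n - 1)
  best <- v
  w <- v
  top <- k^(n - 1)
  for (r in seq_len(n - 1)) {
    w <- (w %% top) * k + w %/% top
    best <- pmin(best, w)
  }
  length(unique(best))
}

# brute-force rigid-superposition RMSD over an SO(3) rotation grid
oracle_grid_rmsd <- function(a, b, steps = 24, refine = FALSE) {
  if (refine) return(oracle_grid_rmsd_refined(a, b, steps))
  ac <- sweep(a, 2, colMeans(a))
  bc <- sweep(b, 2, colMeans(b))
  angs <- seq(0, 2 * pi, length.out = steps + 1)[-(steps + 1)]
  half <- seq(0, pi, length.out = steps / 2 + 1)
  best <- Inf
  for (al in angs) for (be in half) for (ga in angs) {
    cz <- cos(al); sz <- sin(al)
    cy <- cos(be); sy <- sin(be)
    cx <- cos(ga); sx <- sin(ga)
    Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3)
    Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3)
    Rz2 <- matrix(c(cx, sx, 0, -sx, cx, 0, 0, 0, 1), 3)
    R <- Rz %*% Ry %*% Rz2
    v <- mean(rowSums((ac %*% R - bc)^2))
    if (v < best) best <- v
  }
  sqrt(best)
}

# small closed ring cached per session for structure-level tests
closed_ring <- local({
  cache <- list()
  function(n = 7, seed = 42, which = 1) {
    key <- paste(n, seed, which)
    if (is.null(cache[[key]])) {
      confs <- fixture_generator("closed_backbone", n = n, seed = seed,
                                 count = which)
      cache[[key]] <<- confs[[which]]
    }
    cache[[key]]
  }
})

rigid_motion <- function(coords, seed = 1) {
  set.seed(seed)
  ang <- runif(3, 0, 2 * pi)
  Rz <- matrix(c(cos(ang[1]), sin(ang[1]), 0,
                 -sin(ang[1]), cos(ang[1]), 0, 0, 0, 1), 3)
  Rx <- matrix(c(1, 0, 0, 0, cos(ang[2]), sin(ang[2]),
                 0, -sin(ang[2]), cos(ang[2])), 3)
  R <- Rz %*% Rx
  sweep(coords %*% R, 2, runif(3, -5, 5), "+")
}

transform_structure <- function(struct, seed = 1) {
  out <- struct
  set.seed(seed)
  ang <- runif(3, 0, 2 * pi)
  Rz <- matrix(c(cos(ang[1]), sin(ang[1]), 0,
                 -sin(ang[1]), cos(ang[1]), 0, 0, 0, 1), 3)
  Rx <- matrix(c(1, 0, 0, 0, cos(ang[2]), sin(ang[2]),
                 0, -sin(ang[2]), cos(ang[2])), 3)
  R <- Rz %*% Rx
  shift <- runif(3, -5, 5)
  for (at in c("N", "CA", "C", "O", "H"))
    if (!is.null(out[[at]]))
      out[[at]] <- sweep(out[[at]] %*% R, 2, shift, "+")
  out
}

# optional local refinement of the grid oracle: polish the best Euler
# triple with a derivative-free simplex search (still SVD-free)
oracle_grid_rmsd_refined <- function(a, b, steps = 16) {
  ac <- sweep(a, 2, colMeans(a))
  bc <- sweep(b, 2, colMeans(b))
  rot <- function(p) {
    cz <- cos(p[1]); sz <- sin(p[1])
    cy <- cos(p[2]); sy <- sin(p[2])
    cx <- cos(p[3]); sx <- sin(p[3])
    Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3)
    Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3)
    Rz2 <- matrix(c(cx, sx, 0, -sx, cx, 0, 0, 0, 1), 3)
    Rz %*% Ry %*% Rz2
  }
  obj <- function(p) mean(rowSums((ac %*% rot(p) - bc)^2))
  angs <- seq(0, 2 * pi, length.out = steps + 1)[-(steps + 1)]
  half <- seq(0, pi, length.out = steps / 2 + 1)
  best <- Inf; bp <- c(0, 0, 0)
  for (al in angs) for (be in half) for (ga in angs) {
    v <- obj(c(al, be, ga))
    if (v < best) { best <- v; bp <- c(al, be, ga) }
  }
  o <- stats::optim(bp, obj, method = "Nelder-Mead",
                    control = list(maxit = 500, reltol = 1e-14))
  sqrt(o$value)
}
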