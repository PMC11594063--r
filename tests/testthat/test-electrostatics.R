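# independent recomputation of the Coulomb prefactor from CODATA constants,
# kept deliberately separate from the package's own constant handling
indep_prefactor <- function(temperature) {
  e <- 1.602176634e-19
  eps0 <- 8.8541878128e-12
  kB <- 1.380649e-23
  (e^2 / (4 * pi * eps0)) / (kB * temperature) * 1e10
}

test_that("a unit point charge gives the closed-form Coulomb potential", {
  m <- single_atom_model(charge = 1)
  cfg <- electrostatics_config(ionic_strength = 0, temperature = 300)
  phi <- screened_coulomb_potential(m, matrix(c(3, 0, 0), 1), cfg)
  expect_equal(phi, indep_prefactor(300) / (78.5 * 3.0), tolerance = 1e-12)
  # the prefactor itself is ~557.0 Angstrom kBT/ec per e at 300 K
  expect_equal(coulomb_prefactor(300), 557.0, tolerance = 1e-4 * 557)
})

test_that("potential is zero for uncharged systems and linear in charges", {
  pts <- matrix(rnorm(30, sd = 8), ncol = 3)
  pts <- pts[sqrt(rowSums(pts^2)) > 3, , drop = FALSE]
  m0 <- mk_model(c(0, 2), c(0, 0), c(0, 0), charge = 0, resno = c(1, 2))
  cfg <- electrostatics_config()
  expect_equal(screened_coulomb_potential(m0, pts, cfg), rep(0, nrow(pts)))

  m1 <- m0; m1$atoms$charge <- c(0.7, 0)
  m2 <- m0; m2$atoms$charge <- c(0, -1.2)
  m12 <- m0; m12$atoms$charge <- c(0.7, -1.2)
  expect_equal(
    screened_coulomb_potential(m12, pts, cfg),
    screened_coulomb_potential(m1, pts, cfg) +
      screened_coulomb_potential(m2, pts, cfg),
    tolerance = 1e-12
  )
})

test_that("screened Coulomb matches an independent double-loop to 1e-12 relative", {
  set.seed(31)
  n <- 20
  m <- mk_model(rnorm(n, sd = 4), rnorm(n, sd = 4), rnorm(n, sd = 4),
                charge = round(runif(n, -1, 1), 2), resno = 1:n)
  pts <- matrix(rnorm(45, sd = 12), ncol = 3)
  cfg <- electrostatics_config(ionic_strength = 0.15, temperature = 300)
  got <- screened_coulomb_potential(m, pts, cfg)

  kappa <- debye_kappa(0.15, 78.5, 300)
  C <- indep_prefactor(300) / 78.5
  brute <- numeric(nrow(pts))
  for (p in seq_len(nrow(pts))) {
    acc <- 0
    for (a in seq_len(n)) {
      d <- sqrt(sum((pts[p, ] - c(m$atoms$x[a], m$atoms$y[a], m$atoms$z[a]))^2))
      acc <- acc + m$atoms$charge[a] * exp(-kappa * d) / d
    }
    brute[p] <- C * acc
  }
  expect_equal(got, brute, tolerance = 1e-12)
})

test_that("screening attenuates monotonically with ionic strength", {
  m <- single_atom_model(charge = 1)
  pt <- matrix(c(5, 0, 0), 1)
  phis <- vapply(c(0, 0.05, 0.15, 0.5, 1.0), function(I) {
    screened_coulomb_potential(m, pt, electrostatics_config(ionic_strength = I))
  }, 0)
  expect_true(all(diff(phis) < 0))
})

test_that("evaluation on an atom centre is rejected, naming the point", {
  m <- single_atom_model(charge = 1)
  expect_error(
    screened_coulomb_potential(m, rbind(c(5, 0, 0), c(0, 0, 0))),
    "point 2"
  )
})

test_that("trilinear grid mapping is exact on constant and affine fields", {
  mesh <- compute_ses(single_atom_model(), 0.4, 1.4)
  # constant field
  gconst <- potential_grid(c(-6, -6, -6), c(0.5, 0.5, 0.5), c(25, 25, 25),
                           rep(3.25, 25^3))
  expect_equal(map_grid_to_mesh(gconst, mesh)$vertex_potential,
               rep(3.25, nrow(mesh$vertices)))

  # affine field 2x - y + 0.5z: trilinear interpolation is exact
  counts <- c(25L, 27L, 29L)
  org <- c(-6, -6.5, -6.2)
  sp <- c(0.5, 0.5, 0.45)
  ii <- rep(0:(counts[1] - 1), each = counts[2] * counts[3])
  jj <- rep(rep(0:(counts[2] - 1), each = counts[3]), times = counts[1])
  kk <- rep(0:(counts[3] - 1), times = counts[1] * counts[2])
  f <- function(x, y, z) 2 * x - y + 0.5 * z
  gaff <- potential_grid(org, sp, counts,
                         f(org[1] + ii * sp[1], org[2] + jj * sp[2],
                           org[3] + kk * sp[3]))
  got <- map_grid_to_mesh(gaff, mesh)$vertex_potential
  want <- f(mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3])
  expect_equal(got, want, tolerance = 1e-10)

  # a vertex placed exactly on a grid node returns the stored value
  node_mesh <- triangle_mesh()
  node_mesh$vertices <- matrix(c(-6 + 3 * 0.5, -6.5 + 2 * 0.5, -6.2 + 4 * 0.45),
                               1, byrow = TRUE)
  node_mesh$faces <- node_mesh$faces[0, , drop = FALSE]
  got1 <- map_grid_to_mesh(gaff, node_mesh)$vertex_potential
  expect_equal(got1, grid_value_at(gaff, 3, 2, 4), tolerance = 1e-12)
})

test_that("vertices outside the grid error with a count, or clamp with a warning", {
  mesh <- compute_ses(single_atom_model(), 0.4, 1.4)
  small <- potential_grid(c(-1, -1, -1), c(0.5, 0.5, 0.5), c(5, 5, 5),
                          rep(1, 125))
  expect_error(map_grid_to_mesh(small, mesh), "vertices lie outside")
  expect_warning(out <- map_grid_to_mesh(small, mesh, clamp = TRUE), "clamped")
  expect_equal(out$vertex_potential, rep(1, nrow(mesh$vertices)))
})

test_that("grid self-consistency: DX-mapped potential matches the direct model", {
  toy <- make_toy_protein(3, seed = 8, charge_pattern = c(1, -1, 1))
  mesh <- compute_ses(toy$model, 0.4, 1.4)
  direct <- screened_coulomb_potential(toy$model, mesh$vertices)
  lo <- apply(mesh$vertices, 2, min) - 1
  hi <- apply(mesh$vertices, 2, max) + 1
  counts <- ceiling((hi - lo) / 0.25) + 1
  grid <- fill_grid_from_model(toy$model, lo, rep(0.25, 3), counts)
  mapped <- map_grid_to_mesh(grid, mesh)$vertex_potential
  rel <- abs(mapped - direct) / pmax(abs(direct), 1e-6)
  expect_lt(median(rel), 0.02)
})

test_that("potential_distribution respects subsets and validates indices", {
  mesh <- tetra_mesh()
  mesh$vertex_potential <- c(0.5, -1, 2, 4)
  expect_equal(potential_distribution(mesh), c(0.5, -1, 2, 4))
  expect_equal(potential_distribution(mesh, c(1, 3)), c(0.5, 2))
  expect_error(potential_distribution(mesh, integer(0)), "empty")
  expect_error(potential_distribution(mesh, c(1, 9)), "out-of-range")
  mesh$vertex_potential <- NULL
  expect_error(potential_distribution(mesh), "no vertex potentials")
})
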