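# in-code fixtures shared across test files

# a bare structure model from coordinate/charge/radius vectors
mk_model <- function(x, y, z, charge = 0, radius = 1.7, chain = "A",
                     resno = seq_along(x), name = "CA", resname = "ALA") {
  n <- length(x)
  atoms <- surfdelta:::atom_df(
    seq_len(n), rep_len(name, n), rep_len(resname, n), rep_len(chain, n),
    rep_len(resno, n), rep_len("", n), x, y, z,
    rep_len(charge, n), rep_len(radius, n)
  )
  surfdelta:::new_structure_model(atoms)
}

single_atom_model <- function(radius = 1.6, charge = 1) {
  mk_model(0, 0, 0, charge = charge, radius = radius)
}

# a tiny hand-made mesh (unit right triangle) for area/IO tests
triangle_mesh <- function() {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  surfdelta:::new_surface_mesh(v, matrix(c(1L, 2L, 3L), 1), 0.5, 1.4)
}

tetra_mesh <- function() {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  f <- rbind(c(1L, 2L, 3L), c(1L, 2L, 4L), c(1L, 3L, 4L), c(2L, 3L, 4L))
  surfdelta:::new_surface_mesh(v, f, 0.5, 1.4)
}

# whitespace-dialect PQR text for two atoms
pqr_two_atoms <- function(eol = "\n") {
  paste0(paste(
    c("REMARK toy",
      "ATOM 1 CA ALA A 1 0.000 0.000 0.000 -0.500 1.700",
      "ATOM 2 CB ALA A 1 1.500 0.000 0.000 0.500 1.500",
      "END"),
    collapse = eol), eol)
}
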