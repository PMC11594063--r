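test_that("PQR parsing populates charges and radii and preserves order", {
  path <- withr::local_tempfile(fileext = ".pqr")
  writeLines(strsplit(pqr_two_atoms(), "\n")[[1]], path)
  m <- read_pqr(path)
  expect_s3_class(m, "structure_model")
  expect_equal(nrow(m$atoms), 2)
  expect_equal(m$atoms$charge, c(-0.5, 0.5))
  expect_equal(sum(m$atoms$charge), 0)
  expect_equal(m$atoms$name, c("CA", "CB"))
  expect_equal(m$atoms$radius, c(1.7, 1.5))
  expect_equal(m$atoms$serial, c(1L, 2L))
})

test_that("PQR dialects: Windows line endings and fixed columns parse identically", {
  p1 <- withr::local_tempfile(fileext = ".pqr")
  p2 <- withr::local_tempfile(fileext = ".pqr")
  writeLines(strsplit(pqr_two_atoms(), "\n")[[1]], p1)
  con <- file(p2, "wb")
  writeBin(charToRaw(pqr_two_atoms(eol = "\r\n")), con)
  close(con)
  m1 <- read_pqr(p1)
  m2 <- read_pqr(p2)
  expect_equal(m1$atoms, m2$atoms)

  # fixed-column dialect (PDB-style columns, charge/radius in occ/B slots)
  p3 <- withr::local_tempfile(fileext = ".pqr")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  -0.5000 1.7000",
    "ATOM      2  CB  ALA A   1       1.500   0.000   0.000   0.5000 1.5000"
  ), p3)
  m3 <- read_pqr(p3)
  expect_equal(m3$atoms$charge, m1$atoms$charge)
  expect_equal(m3$atoms$radius, m1$atoms$radius)
  expect_equal(m3$atoms[, c("x", "y", "z")], m1$atoms[, c("x", "y", "z")])

  # independent reader cross-check (bio3d reads the fixed-column dialect,
  # placing charge in its "o" slot and radius in "b")
  b3d <- bio3d::read.pqr(p3)
  expect_equal(b3d$atom$o, m3$atoms$charge)
  expect_equal(b3d$atom$b, m3$atoms$radius)
  expect_equal(b3d$atom$x, m3$atoms$x)
})

test_that("PQR errors cite the offending line and reject empty files", {
  p <- withr::local_tempfile(fileext = ".pqr")
  writeLines(c(
    "ATOM 1 CA ALA A 1 0.0 0.0 0.0 -0.5 1.7",
    "ATOM 2 CB ALA A 1 1.5 0.0 0.0 0.5 1.5",
    "ATOM 3 CG ALA A 1 3.0 0.0 0.0 oops 1.5"
  ), p)
  expect_error(read_pqr(p), "line 3")
  p2 <- withr::local_tempfile(fileext = ".pqr")
  writeLines("REMARK nothing here", p2)
  expect_error(read_pqr(p2), "no ATOM")
})

test_that("PQR round-trips through write_pqr", {
  toy <- make_toy_protein(5, seed = 3, charge_pattern = c(1, -1))
  p <- withr::local_tempfile(fileext = ".pqr")
  write_pqr(toy$model, p)
  back <- read_pqr(p)
  expect_equal(back$atoms$charge, toy$model$atoms$charge, tolerance = 1e-5)
  expect_equal(back$atoms$radius, toy$model$atoms$radius, tolerance = 1e-5)
  expect_equal(back$atoms$x, toy$model$atoms$x, tolerance = 1e-6)
  expect_equal(back$atoms$residue_number, toy$model$atoms$residue_number)
  # a second round trip is exact (serialisation is a fixed point)
  p2 <- withr::local_tempfile(fileext = ".pqr")
  write_pqr(back, p2)
  expect_identical(read_pqr(p2)$atoms, back$atoms)
})

test_that("multi-model PDB files become topology-checked ensembles", {
  block <- c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00",
    "ATOM      2  CB  ALA A   1       1.500   0.000   0.000  1.00  0.00"
  )
  p <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "MODEL     1", block, "ENDMDL",
    "MODEL     2", block, "ENDMDL",
    "MODEL     3", block, "ENDMDL", "END"
  ), p)
  ens <- read_pdb_models(p)
  expect_s3_class(ens, "ensemble")
  expect_length(ens$models, 3)
  expect_false(ens$aligned)
  expect_equal(ens$models[[2]]$atoms$charge, c(0, 0))

  # no MODEL records -> single-frame ensemble
  p1 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(block, "END"), p1)
  expect_length(read_pdb_models(p1)$models, 1)

  # second model missing an atom -> topology error naming the mismatch
  p2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("MODEL     1", block, "ENDMDL",
               "MODEL     2", block[1], "ENDMDL"), p2)
  expect_error(read_pdb_models(p2), "topology")
})

test_that("PQR template join fills ensemble charges, warning on unmatched atoms", {
  toy <- make_toy_protein(4, seed = 2, charge_pattern = c(1, -1))
  ens <- make_wobble_ensemble(toy$model, 3, 0.1, seed = 9)
  stripped <- ens
  for (i in seq_along(stripped$models)) {
    stripped$models[[i]]$atoms$charge <- 0
    stripped$models[[i]]$atoms$radius <- 1.0
  }
  joined <- apply_pqr_topology(stripped, toy$model)
  expect_equal(joined$models[[2]]$atoms$charge, toy$model$atoms$charge)
  expect_equal(joined$models[[3]]$atoms$radius, toy$model$atoms$radius)

  # unmatched atom keeps charge 0, takes element radius, warns
  odd <- stripped
  odd$models[[1]]$atoms$name[1] <- "OXT"
  for (i in 2:3) odd$models[[i]]$atoms$name[1] <- "OXT"
  expect_warning(j2 <- apply_pqr_topology(odd, toy$model), "not found")
  expect_equal(j2$models[[1]]$atoms$charge[1], 0)
  expect_equal(j2$models[[1]]$atoms$radius[1], 1.52)  # oxygen
})

test_that("OpenDX grids honour z-fastest ordering and validate counts", {
  # 2x2x2 grid with values 0..7 in file (z-fastest) order
  p <- withr::local_tempfile(fileext = ".dx")
  writeLines(c(
    "object 1 class gridpositions counts 2 2 2",
    "origin 0.0 0.0 0.0",
    "delta 0.5 0.0 0.0",
    "delta 0.0 0.5 0.0",
    "delta 0.0 0.0 0.5",
    "object 2 class gridconnections counts 2 2 2",
    "object 3 class array type double rank 0 items 8 data follows",
    "0 1 2", "3 4 5", "6 7",
    'attribute "dep" string "positions"'
  ), p)
  g <- read_dx_grid(p)
  expect_equal(g$counts, c(2L, 2L, 2L))
  expect_equal(g$spacing, c(0.5, 0.5, 0.5))
  expect_equal(grid_value_at(g, 0, 0, 1), 1.0)
  expect_equal(grid_value_at(g, 1, 0, 0), 4.0)
  # ordering invariant: value at (i,j,k) sits at i*ny*nz + j*nz + k
  for (idx in list(c(0, 1, 0), c(1, 1, 1), c(0, 1, 1))) {
    pos <- idx[1] * 4 + idx[2] * 2 + idx[3] + 1
    expect_equal(grid_value_at(g, idx[1], idx[2], idx[3]), g$values[pos])
  }

  # count mismatch
  p2 <- withr::local_tempfile(fileext = ".dx")
  writeLines(c(
    "object 1 class gridpositions counts 3 3 3",
    "origin 0 0 0", "delta 1 0 0", "delta 0 1 0", "delta 0 0 1",
    "object 3 class array type double rank 0 items 26 data follows",
    paste(1:26, collapse = " ")
  ), p2)
  expect_error(read_dx_grid(p2), "27 values but file has 26")

  # non-orthogonal deltas unsupported
  p3 <- withr::local_tempfile(fileext = ".dx")
  writeLines(c(
    "object 1 class gridpositions counts 2 2 2",
    "origin 0 0 0", "delta 1 0.2 0", "delta 0 1 0", "delta 0 0 1",
    "object 3 class array type double rank 0 items 8 data follows",
    paste(0:7, collapse = " ")
  ), p3)
  expect_error(read_dx_grid(p3), "non-orthogonal")

  # writer round-trip
  p4 <- withr::local_tempfile(fileext = ".dx")
  write_dx_grid(g, p4)
  g2 <- read_dx_grid(p4)
  expect_equal(g2$values, g$values)
  expect_equal(g2$origin, g$origin)
})

test_that("PLY export round-trips vertices, faces, and the potential field", {
  mesh <- tetra_mesh()
  mesh$vertex_potential <- c(0.1, -2.5, 3.25, 0)
  p <- withr::local_tempfile(fileext = ".ply")
  write_mesh(mesh, p, scalar = "potential")
  back <- read_ply(p)
  expect_equal(nrow(back$vertices), 4)
  expect_equal(nrow(back$faces), 4)
  expect_equal(back$vertices, mesh$vertices, ignore_attr = TRUE)
  expect_equal(back$faces, mesh$faces, ignore_attr = TRUE)
  expect_equal(back$vertex_potential, mesh$vertex_potential)
  expect_error(write_mesh(mesh, p, scalar = "shape_index"), "unknown")
  mesh$vertex_potential <- NULL
  expect_error(write_mesh(mesh, p, scalar = "potential"), "no per-vertex")
})
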