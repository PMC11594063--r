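# Per-vertex electrostatic potential, in kBT/ec.
#
# Two sources: a built-in screened-Coulomb (Debye-Hueckel) model
#   phi(r) = C(T) / eps_r * sum_i q_i exp(-kappa |r - r_i|) / |r - r_i|
# with C(T) = e^2 / (4 pi eps0 kB T) expressed in Angstrom * kBT/ec per
# elementary charge, or trilinear interpolation of an imported OpenDX grid
# (e.g. an APBS Poisson-Boltzmann map). The screened-Coulomb model has no
# low-dielectric solute cavity; users wanting full Poisson-Boltzmann physics
# import a DX grid.

# CODATA 2018 constants (SI)
.phys <- list(
  e = 1.602176634e-19,      # C
  eps0 = 8.8541878128e-12,  # F/m
  kB = 1.380649e-23,        # J/K
  Nav = 6.02214076e23       # 1/mol
)

#' Electrostatics configuration
#'
#' @param mode `"screened_coulomb"` (built-in Debye-Hueckel model) or
#'   `"dx_grid"` (interpolate an imported OpenDX potential map).
#' @param solvent_dielectric Relative solvent dielectric (default 78.5,
#'   water at room temperature).
#' @param ionic_strength Ionic strength in mol/L (default 0.150,
#'   physiological saline). 0 disables Debye screening.
#' @param temperature Temperature in Kelvin (default 300); sets both the
#'   Debye parameter and the kBT/ec unit scale.
#' @return A list of class `electrostatics_config`.
#' @export
electrostatics_config <- function(mode = c("screened_coulomb", "dx_grid"),
                                  solvent_dielectric = 78.5,
                                  ionic_strength = 0.150,
                                  temperature = 300) {
  mode <- match.arg(mode)
  stopifnot(solvent_dielectric >= 1, ionic_strength >= 0, temperature > 0)
  structure(list(mode = mode, solvent_dielectric = solvent_dielectric,
                 ionic_strength = ionic_strength, temperature = temperature),
            class = "electrostatics_config")
}

#' Coulomb prefactor in Angstrom * kBT/ec per elementary charge
#'
#' `e^2 / (4 pi eps0 kB T)` converted to Angstrom; about 557.0 at 300 K.
#'
#' @param temperature Kelvin.
#' @return Prefactor (Angstrom).
#' @export
coulomb_prefactor <- function(temperature = 300) {
  with(.phys, e^2 / (4 * pi * eps0 * kB * temperature)) * 1e10
}

#' Debye screening parameter
#'
#' `kappa = sqrt(2 e^2 NA * 1000 * I / (eps0 eps_r kB T))`, with the ionic
#' strength I in mol/L converted to mol/m^3. Returned in 1/Angstrom; the
#' Debye length is `1/kappa` (about 7.9 Angstrom at 150 mM, 78.5, 300 K).
#'
#' @param ionic_strength mol/L.
#' @param dielectric Relative solvent dielectric.
#' @param temperature Kelvin.
#' @return kappa in 1/Angstrom (0 when `ionic_strength` is 0).
#' @export
debye_kappa <- function(ionic_strength, dielectric = 78.5, temperature = 300) {
  if (ionic_strength == 0) return(0)
  kappa_m <- with(.phys, sqrt(
    2 * e^2 * Nav * 1000 * ionic_strength /
      (eps0 * dielectric * kB * temperature)
  ))
  kappa_m * 1e-10
}

#' Screened-Coulomb potential at arbitrary points
#'
#' Sums Debye-screened Coulomb contributions of all atom partial charges at
#' each evaluation point. Linear in the charges; reduces to plain Coulomb
#' when the ionic strength is 0.
#'
#' @param model A `structure_model` with charges.
#' @param points n x 3 matrix of evaluation points (Angstrom).
#' @param cfg An [electrostatics_config()].
#' @param min_dist Guard distance: evaluation points closer than this to an
#'   atom centre are an error (default 1e-6 Angstrom).
#' @return Numeric vector of potentials (kBT/ec), one per point.
#' @export
screened_coulomb_potential <- function(model, points,
                                       cfg = electrostatics_config(),
                                       min_dist = 1e-6) {
  stopifnot(inherits(model, "structure_model"))
  points <- matrix(as.numeric(points), ncol = 3)
  kappa <- debye_kappa(cfg$ionic_strength, cfg$solvent_dielectric,
                       cfg$temperature)
  C <- coulomb_prefactor(cfg$temperature) / cfg$solvent_dielectric
  out <- cpp_screened_coulomb(points, model_coords(model),
                              model$atoms$charge, kappa, C, min_dist)
  if (anyNA(out)) {
    bad <- which(is.na(out))[1]
    stop(sprintf(
      "evaluation point %d (%.3f, %.3f, %.3f) coincides with an atom centre",
      bad, points[bad, 1], points[bad, 2], points[bad, 3]))
  }
  out
}

#' Attach screened-Coulomb potential to every mesh vertex
#'
#' @param mesh A `surface_mesh`.
#' @param model The generating `structure_model` (with charges).
#' @param cfg An [electrostatics_config()].
#' @return The mesh with `vertex_potential` set (kBT/ec).
#' @export
map_potential_to_mesh <- function(mesh, model, cfg = electrostatics_config()) {
  mesh$vertex_potential <- screened_coulomb_potential(model, mesh$vertices, cfg)
  mesh
}

#' Interpolate an OpenDX potential grid onto a surface mesh
#'
#' Trilinear interpolation of the 8 surrounding grid nodes at each vertex
#' (exact for affine fields). Vertices outside the grid are an error by
#' default, reporting how many fell outside and the worst overshoot;
#' `clamp = TRUE` clamps them to the grid edge with a warning instead.
#'
#' @param grid A `potential_grid`.
#' @param mesh A `surface_mesh`.
#' @param clamp Clamp out-of-grid vertices to the boundary instead of
#'   erroring.
#' @return The mesh with `vertex_potential` set (kBT/ec).
#' @export
map_grid_to_mesh <- function(grid, mesh, clamp = FALSE) {
  v <- mesh$vertices
  n <- grid$counts
  # fractional grid coordinates
  g <- sweep(sweep(v, 2, grid$origin), 2, grid$spacing, "/")
  hi <- n - 1
  over <- pmax(
    pmax(-g[, 1], g[, 1] - hi[1]),
    pmax(-g[, 2], g[, 2] - hi[2]),
    pmax(-g[, 3], g[, 3] - hi[3])
  )
  out_of_grid <- over > 1e-9
  if (any(out_of_grid)) {
    worst <- max(over) * min(grid$spacing)
    if (!clamp) {
      stop(sprintf(
        "%d of %d vertices lie outside the potential grid (worst overshoot %.3f Angstrom); enlarge the grid or use clamp = TRUE",
        sum(out_of_grid), nrow(v), worst))
    }
    warning(sprintf(
      "%d vertices outside the grid clamped to its edge (worst overshoot %.3f Angstrom)",
      sum(out_of_grid), worst))
  }
  g[, 1] <- pmin(pmax(g[, 1], 0), hi[1])
  g[, 2] <- pmin(pmax(g[, 2], 0), hi[2])
  g[, 3] <- pmin(pmax(g[, 3], 0), hi[3])
  i0 <- pmin(floor(g[, 1]), hi[1] - 1)
  j0 <- pmin(floor(g[, 2]), hi[2] - 1)
  k0 <- pmin(floor(g[, 3]), hi[3] - 1)
  fx <- g[, 1] - i0
  fy <- g[, 2] - j0
  fz <- g[, 3] - k0
  val <- function(i, j, k) grid_value_at(grid, i, j, k)
  p <- val(i0, j0, k0) * (1 - fx) * (1 - fy) * (1 - fz) +
    val(i0 + 1, j0, k0) * fx * (1 - fy) * (1 - fz) +
    val(i0, j0 + 1, k0) * (1 - fx) * fy * (1 - fz) +
    val(i0, j0, k0 + 1) * (1 - fx) * (1 - fy) * fz +
    val(i0 + 1, j0 + 1, k0) * fx * fy * (1 - fz) +
    val(i0 + 1, j0, k0 + 1) * fx * (1 - fy) * fz +
    val(i0, j0 + 1, k0 + 1) * (1 - fx) * fy * fz +
    val(i0 + 1, j0 + 1, k0 + 1) * fx * fy * fz
  mesh$vertex_potential <- p
  mesh
}

#' Fill a potential grid from the screened-Coulomb model
#'
#' Evaluates the built-in model at every grid node; useful for
#' self-consistency checks of grid interpolation and for exporting maps.
#'
#' @param model A `structure_model` with charges.
#' @param origin,spacing,counts Grid geometry (see [potential_grid()]).
#' @param cfg An [electrostatics_config()].
#' @return A `potential_grid`.
#' @export
fill_grid_from_model <- function(model, origin, spacing, counts,
                                 cfg = electrostatics_config()) {
  counts <- as.integer(counts)
  # z-fastest node ordering to match OpenDX layout
  ii <- rep(0:(counts[1] - 1), each = counts[2] * counts[3])
  jj <- rep(rep(0:(counts[2] - 1), each = counts[3]), times = counts[1])
  kk <- rep(0:(counts[3] - 1), times = counts[1] * counts[2])
  pts <- cbind(origin[1] + ii * spacing[1],
               origin[2] + jj * spacing[2],
               origin[3] + kk * spacing[3])
  vals <- screened_coulomb_potential(model, pts, cfg)
  new_potential_grid(origin, spacing, counts, vals)
}

#' The distribution of surface potentials over a vertex subset
#'
#' Returns the multiset of per-vertex potentials, in vertex order, over the
#' given subset (the whole surface when `vertex_subset` is `NULL`).
#'
#' @param mesh A `surface_mesh` with `vertex_potential` populated.
#' @param vertex_subset Optional integer vector of 1-based vertex indices.
#' @return Numeric vector of potentials (kBT/ec).
#' @export
potential_distribution <- function(mesh, vertex_subset = NULL) {
  if (is.null(mesh$vertex_potential)) {
    stop("mesh has no vertex potentials; map a potential first")
  }
  if (is.null(vertex_subset)) {
    return(mesh$vertex_potential)
  }
  if (length(vertex_subset) == 0) stop("empty vertex subset")
  if (any(vertex_subset < 1 | vertex_subset > nrow(mesh$vertices))) {
    stop("vertex subset contains out-of-range indices")
  }
  mesh$vertex_potential[vertex_subset]
}
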