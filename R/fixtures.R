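# Synthetic inputs for tests, examples, and calibration studies: toy charged
# "proteins", point mutants, wobble ensembles standing in for trajectory
# frames, and potential-value sample pairs with controlled distributional
# differences. Everything is deterministic given its seed; nothing here
# aims for physically realistic protein geometry.

#' Generate a toy charged protein
#'
#' Residues are laid along a helical curve (or packed on a sphere) with a
#' small fixed cluster of atoms per residue plus a light seeded jitter, so
#' the full surface/electrostatics/statistics pipeline runs in seconds.
#' Residue numbering starts at 1 on chain "A"; each residue's pattern charge
#' sits on its first atom.
#'
#' @param n_residues Number of residues (>= 1).
#' @param atoms_per_residue Atoms per residue (default 3).
#' @param backbone `"helix_curve"` or `"sphere_packing"`.
#' @param charge_pattern Per-residue charges in e, recycled (default
#'   alternating +1/-1/0).
#' @param radius Atom radius in Angstrom (default 1.7).
#' @param seed RNG seed.
#' @param pqr_path If non-NULL, also write the model as a PQR file there.
#' @return A list with `model` (a `structure_model`) and `pqr` (the path or
#'   NULL).
#' @export
make_toy_protein <- function(n_residues, atoms_per_residue = 3,
                             backbone = c("helix_curve", "sphere_packing"),
                             charge_pattern = c(1, -1, 0),
                             radius = 1.7, seed = 1, pqr_path = NULL) {
  backbone <- match.arg(backbone)
  stopifnot(n_residues >= 1, atoms_per_residue >= 1, radius > 0)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  centers <- switch(backbone,
    helix_curve = {
      # generous helix so neighbouring residues never collide
      i <- seq_len(n_residues) - 1
      theta <- i * 0.6
      cbind(8 * cos(theta), 8 * sin(theta), 1.8 * i)
    },
    sphere_packing = {
      # Fibonacci lattice on a sphere sized for ~5.5 A spacing
      i <- seq_len(n_residues) - 0.5
      phi <- acos(1 - 2 * i / n_residues)
      theta <- pi * (1 + sqrt(5)) * i
      Rs <- max(6, 5.5 * sqrt(n_residues / 4) / 2 + 4)
      cbind(Rs * sin(phi) * cos(theta), Rs * sin(phi) * sin(theta),
            Rs * cos(phi))
    }
  )
  # fixed intra-residue offsets (~1.5 A) plus small jitter
  base_off <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(0, 1.5, 0), c(0, 0, 1.5),
                    c(-1.5, 0, 0), c(0, -1.5, 0), c(0, 0, -1.5))
  charges <- rep_len(charge_pattern, n_residues)
  rows <- list()
  serial <- 0L
  atom_names <- c("CA", "CB", "CG", "CD", "CE", "CZ", "CH")
  for (r in seq_len(n_residues)) {
    for (a in seq_len(atoms_per_residue)) {
      serial <- serial + 1L
      off <- base_off[((a - 1) %% nrow(base_off)) + 1, ] +
        runif(3, -0.15, 0.15)
      rows[[serial]] <- atom_df(
        serial, atom_names[((a - 1) %% length(atom_names)) + 1],
        "ALA", "A", r, "",
        centers[r, 1] + off[1], centers[r, 2] + off[2], centers[r, 3] + off[3],
        if (a == 1) charges[r] else 0, radius)
    }
  }
  atoms <- do.call(rbind, rows)
  model <- new_structure_model(atoms, 1L, "synthetic")
  # invariant: atoms must not overlap beyond half a radius
  if (nrow(atoms) > 1) {
    xyz <- as.matrix(atoms[, c("x", "y", "z")])
    dmin <- min(dist(xyz))
    if (dmin < 0.5 * radius) {
      stop(sprintf(
        "generated atoms overlap (min distance %.2f < %.2f); increase spacing",
        dmin, 0.5 * radius))
    }
  }
  pqr <- NULL
  if (!is.null(pqr_path)) {
    write_pqr(model, pqr_path)
    pqr <- pqr_path
  }
  list(model = model, pqr = pqr)
}

#' Derive a point mutant from a toy model
#'
#' Perturbs only the site residue: its atoms share `delta_charge` equally,
#' grow by `delta_radius`, and are jittered by at most `displacement`
#' Angstrom. Every other residue is untouched (bit-identical), emulating a
#' side-chain substitution such as a charge-loss mutation.
#'
#' @param model A `structure_model`.
#' @param site A [site_spec()].
#' @param delta_charge Total charge change at the site (e).
#' @param delta_radius Radius change per site atom (Angstrom).
#' @param displacement Maximum positional jitter per coordinate (Angstrom).
#' @param seed RNG seed for the jitter.
#' @return The mutated `structure_model`.
#' @export
make_mutant <- function(model, site, delta_charge = 0, delta_radius = 0,
                        displacement = 0, seed = 1) {
  idx <- site_atoms(model, site)
  if (length(idx) == 0) {
    stop(sprintf("site %s:%d not present in model", site$chain_id,
                 site$residue_number))
  }
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  out <- model
  out$atoms$charge[idx] <- out$atoms$charge[idx] +
    delta_charge / length(idx)
  out$atoms$radius[idx] <- out$atoms$radius[idx] + delta_radius
  if (displacement > 0) {
    jit <- matrix(runif(3 * length(idx), -displacement, displacement),
                  ncol = 3)
    out$atoms$x[idx] <- out$atoms$x[idx] + jit[, 1]
    out$atoms$y[idx] <- out$atoms$y[idx] + jit[, 2]
    out$atoms$z[idx] <- out$atoms$z[idx] + jit[, 3]
  }
  out
}

#' Build a wobble ensemble around a model
#'
#' Stands in for trajectory frames: frame 1 is the unperturbed model, later
#' frames add independent Gaussian displacements of the given amplitude to
#' every atom. Topology is identical across frames.
#'
#' @param model A `structure_model`.
#' @param n_frames Number of frames (>= 1).
#' @param amplitude Per-coordinate Gaussian displacement sd (Angstrom).
#' @param seed RNG seed.
#' @return An `ensemble` (not aligned).
#' @export
make_wobble_ensemble <- function(model, n_frames, amplitude = 0.3, seed = 1) {
  stopifnot(n_frames >= 1, amplitude >= 0)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  n <- nrow(model$atoms)
  models <- vector("list", n_frames)
  models[[1]] <- model
  models[[1]]$model_index <- 1L
  if (n_frames > 1) {
    for (f in 2:n_frames) {
      m <- model
      m$model_index <- as.integer(f)
      m$atoms$x <- m$atoms$x + rnorm(n, 0, amplitude)
      m$atoms$y <- m$atoms$y + rnorm(n, 0, amplitude)
      m$atoms$z <- m$atoms$z + rnorm(n, 0, amplitude)
      models[[f]] <- m
    }
  }
  new_ensemble(models, aligned = FALSE)
}

#' Sample pairs of potential-like values with controlled differences
#'
#' Draws two samples from the same distributional family; the second is
#' location-shifted by `shift`, and for the bimodal family `shape_delta`
#' additionally widens the mode separation of the second sample while
#' preserving its mean and median -- the kind of distribution-shape change
#' that tail-sensitive tests detect and mean-based tests miss.
#'
#' @param n Sample size (>= 10).
#' @param shift Location shift of the second sample (kBT/ec).
#' @param shape `"normal"` (unit variance), `"heavy_tail"` (Student t with
#'   3 df), or `"bimodal"` (symmetric two-component normal mixture).
#' @param seed RNG seed.
#' @param shape_delta Bimodal mode-separation increase for the second
#'   sample (ignored for other shapes).
#' @return List with numeric `x` (reference) and `y` (shifted/reshaped).
#' @export
sample_potential_pair <- function(n, shift = 0,
                                  shape = c("normal", "heavy_tail", "bimodal"),
                                  seed = 1, shape_delta = 0) {
  shape <- match.arg(shape)
  stopifnot(n >= 10)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  draw <- function(n, sep = 1) {
    switch(shape,
      normal = rnorm(n),
      heavy_tail = stats::rt(n, df = 3),
      bimodal = {
        comp <- sample(c(-1, 1), n, replace = TRUE)
        rnorm(n, mean = comp * sep, sd = 0.35)
      }
    )
  }
  x <- draw(n)
  y <- draw(n, sep = 1 + shape_delta) + shift
  list(x = x, y = y)
}
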