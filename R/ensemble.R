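# Conformational-ensemble support: rigid-body superposition onto a
# reference, production-frame selection, per-frame surface/potential
# computation, and pooling of local-region potentials across conformers.

match_selection <- function(mobile, reference, selection = "CA") {
  key <- function(m, sel) {
    a <- m$atoms
    use <- if (is.null(sel)) rep(TRUE, nrow(a)) else a$name %in% sel
    list(idx = which(use),
         key = paste(a$chain_id, a$residue_number, a$insertion_code,
                     a$name, sep = "|")[use])
  }
  mb <- key(mobile, selection)
  rf <- key(reference, selection)
  m <- match(mb$key, rf$key)
  ok <- !is.na(m)
  list(mobile_idx = mb$idx[ok], reference_idx = rf$idx[m[ok]])
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Superposes `mobile` onto `reference` using the optimal proper rotation
#' and translation over a named atom selection (C-alpha atoms by default),
#' matched by (chain, residue number, atom name). The rotation is always a
#' proper rotation (determinant +1); the degenerate reflection case is
#' handled by sign correction of the smallest singular vector.
#'
#' @param mobile,reference `structure_model`s.
#' @param selection Atom name(s) to align on (default `"CA"`); `NULL` for
#'   all atoms.
#' @return List with `model` (all atoms of `mobile`, transformed), `rmsd`
#'   (over the selection, after superposition, Angstrom), `rotation` (the
#'   3 x 3 proper rotation applied), and `translation`.
#' @export
kabsch_superpose <- function(mobile, reference, selection = "CA") {
  sel <- match_selection(mobile, reference, selection)
  if (length(sel$mobile_idx) < 3) {
    stop(sprintf("only %d matched atoms in selection; need at least 3",
                 length(sel$mobile_idx)))
  }
  P <- model_coords(mobile)[sel$mobile_idx, , drop = FALSE]
  Q <- model_coords(reference)[sel$reference_idx, , drop = FALSE]
  pc <- colMeans(P)
  qc <- colMeans(Q)
  P0 <- sweep(P, 2, pc)
  Q0 <- sweep(Q, 2, qc)
  H <- t(P0) %*% Q0
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  out <- mobile
  X <- sweep(model_coords(mobile), 2, pc) %*% t(R)
  X <- sweep(X, 2, qc, "+")
  out$atoms$x <- X[, 1]
  out$atoms$y <- X[, 2]
  out$atoms$z <- X[, 3]
  aligned_sel <- X[sel$mobile_idx, , drop = FALSE]
  rmsd <- sqrt(mean(rowSums((aligned_sel - Q)^2)))
  list(model = out, rmsd = rmsd, rotation = R,
       translation = as.numeric(qc - R %*% pc))
}

#' Align every frame of an ensemble to a reference
#'
#' @param ensemble An `ensemble`.
#' @param reference A `structure_model`; defaults to frame 1 (align
#'   trajectories to the initial wild-type conformation by passing that
#'   model explicitly).
#' @param selection Atom selection for [kabsch_superpose()].
#' @return The ensemble with `aligned = TRUE` and an `rmsd` attribute (one
#'   value per frame).
#' @export
align_ensemble <- function(ensemble, reference = NULL, selection = "CA") {
  stopifnot(inherits(ensemble, "ensemble"))
  if (is.null(reference)) reference <- ensemble$models[[1]]
  rmsd <- numeric(length(ensemble$models))
  for (i in seq_along(ensemble$models)) {
    fit <- kabsch_superpose(ensemble$models[[i]], reference, selection)
    ensemble$models[[i]] <- fit$model
    rmsd[i] <- fit$rmsd
  }
  ensemble$aligned <- TRUE
  attr(ensemble, "rmsd") <- rmsd
  ensemble
}

#' Keep the production tail of a trajectory
#'
#' Keeps the last `ceiling(fraction * N)` frames in order -- the
#' equilibrated portion of a simulation (final quarter by default).
#'
#' @param ensemble An `ensemble`.
#' @param fraction Fraction of frames to keep, in (0, 1].
#' @return The truncated `ensemble`; kept original frame numbers in
#'   attribute `frame_indices`.
#' @export
select_production_frames <- function(ensemble, fraction = 0.25) {
  stopifnot(inherits(ensemble, "ensemble"), fraction > 0, fraction <= 1)
  n <- length(ensemble$models)
  if (n == 0) stop("empty ensemble")
  keep <- ceiling(fraction * n)
  idx <- seq.int(n - keep + 1L, n)
  out <- ensemble
  out$models <- ensemble$models[idx]
  attr(out, "frame_indices") <- idx
  out
}

#' Pooled local-surface potentials across an ensemble
#'
#' For each conformer: build the solvent-excluded surface, label vertices by
#' residue, attach the screened-Coulomb potential, and collect the
#' potentials of the local region around the site. The region residue set is
#' derived once from frame 1 and held fixed across conformers so the region
#' keeps its identity over the dynamics (set `recompute_region = TRUE` to
#' re-derive it per frame). Values are pooled across frames, tagged by
#' source frame. Frames whose region is entirely buried contribute no
#' vertices (with a message); a region buried in every frame is an error.
#'
#' If the ensemble is not flagged as aligned it is auto-aligned to frame 1.
#'
#' @param ensemble An `ensemble` with charges/radii populated.
#' @param site A [site_spec()], or `NULL` to pool the whole surface.
#' @param e_cfg An [electrostatics_config()].
#' @param s_params A [surface_params()].
#' @param cutoff Region cutoff in Angstrom.
#' @param region_residues Optional residue-key vector overriding the
#'   frame-1-derived region (used for WT/mutant consensus regions).
#' @param recompute_region Re-derive the residue set for every frame.
#' @return An `ensemble_surface_set`: `conformer_meshes`, `frame_indices`,
#'   `region` (a `region_mask` or NULL), `pooled_values`, `frame_tags`.
#' @export
ensemble_region_values <- function(ensemble, site = NULL,
                                   e_cfg = electrostatics_config(),
                                   s_params = surface_params(),
                                   cutoff = 4.0,
                                   region_residues = NULL,
                                   recompute_region = FALSE) {
  stopifnot(inherits(ensemble, "ensemble"))
  if (!ensemble$aligned && length(ensemble$models) > 1) {
    ensemble <- align_ensemble(ensemble)
  }
  frame_indices <- attr(ensemble, "frame_indices")
  if (is.null(frame_indices)) frame_indices <- seq_along(ensemble$models)

  residues <- region_residues
  if (is.null(residues) && !is.null(site) && !recompute_region) {
    residues <- local_residues(ensemble$models[[1]], site, cutoff)
  }

  meshes <- vector("list", length(ensemble$models))
  values <- vector("list", length(ensemble$models))
  tags <- vector("list", length(ensemble$models))
  n_buried <- 0L
  for (i in seq_along(ensemble$models)) {
    model <- ensemble$models[[i]]
    mesh <- compute_ses(model, s_params$grid_spacing, s_params$probe_radius,
                        s_params$voxel_budget)
    mesh <- assign_vertices_to_residues(mesh, model)
    mesh <- map_potential_to_mesh(mesh, model, e_cfg)
    meshes[[i]] <- mesh
    res_i <- residues
    if (recompute_region && !is.null(site)) {
      res_i <- local_residues(model, site, cutoff)
    }
    if (is.null(res_i)) {
      vi <- seq_len(nrow(mesh$vertices))
    } else {
      vi <- tryCatch(region_vertices(mesh, res_i), error = function(e) {
        integer(0)
      })
      if (length(vi) == 0) {
        n_buried <- n_buried + 1L
        message(sprintf("frame %d: region buried, contributing 0 vertices",
                        frame_indices[i]))
      }
    }
    values[[i]] <- if (length(vi)) potential_distribution(mesh, vi) else numeric(0)
    tags[[i]] <- rep(frame_indices[i], length(vi))
  }
  if (n_buried == length(ensemble$models) && !is.null(site)) {
    stop("region is buried in every frame: no surface vertices to pool")
  }
  region <- if (!is.null(residues)) {
    new_region_mask(residues, lapply(meshes, function(m) NULL), cutoff)
  } else NULL
  structure(
    list(conformer_meshes = meshes, frame_indices = frame_indices,
         region = region,
         pooled_values = unlist(values, use.names = FALSE),
         frame_tags = unlist(tags, use.names = FALSE)),
    class = "ensemble_surface_set"
  )
}

#' @export
print.ensemble_surface_set <- function(x, ...) {
  cat(sprintf("<ensemble_surface_set> %d conformers, %d pooled values\n",
              length(x$conformer_meshes), length(x$pooled_values)))
  invisible(x)
}
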