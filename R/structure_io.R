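# Readers and writers for the structural and grid formats the pipeline
# touches: PQR (atoms with charge/radius), multi-model PDB (conformer
# ensembles), OpenDX scalar grids (APBS potential maps), and ascii PLY
# meshes. Parsing only -- no science here.

# van der Waals radii (Angstrom) by element, used when a PDB atom cannot be
# matched to a PQR template atom
.element_radii <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
  F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, FE = 1.80, ZN = 1.39,
  MG = 1.73, CA = 2.31, "NA" = 2.27, K = 2.75
)

element_from_name <- function(name) {
  # strip leading digits (e.g. "1HB"), element is the leading letters
  core <- sub("^[0-9]+", "", name)
  first <- toupper(substr(core, 1, 1))
  ifelse(first == "", "C", first)
}

default_radius <- function(name) {
  el <- element_from_name(name)
  r <- .element_radii[el]
  ifelse(is.na(r), 1.70, r)
}

new_structure_model <- function(atoms, model_index = 1L, source_path = "") {
  stopifnot(is.data.frame(atoms))
  if (anyDuplicated(atoms$serial)) {
    stop("duplicate atom serials within a model")
  }
  structure(
    list(atoms = atoms, model_index = as.integer(model_index),
         source_path = source_path),
    class = "structure_model"
  )
}

#' @export
print.structure_model <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("<structure_model> %d atoms, %d residues, net charge %+.3f e\n",
              nrow(a), length(unique(residue_key(a$chain_id, a$residue_number,
                                                 a$insertion_code))),
              sum(a$charge)))
  invisible(x)
}

atom_df <- function(serial, name, resname, chain, resno, ins, x, y, z,
                    charge, radius) {
  data.frame(
    serial = as.integer(serial), name = name, residue_name = resname,
    chain_id = chain, residue_number = as.integer(resno),
    insertion_code = ins, x = x, y = y, z = z,
    charge = charge, radius = radius,
    is_hydrogen = element_from_name(name) == "H",
    stringsAsFactors = FALSE
  )
}

model_coords <- function(model) {
  as.matrix(model$atoms[, c("x", "y", "z")])
}

# split a residue-number token that may carry an insertion code ("52A")
split_resno <- function(tok) {
  m <- regmatches(tok, regexec("^(-?[0-9]+)([A-Za-z]?)$", tok))[[1]]
  if (length(m) == 0) return(NULL)
  list(resno = as.integer(m[2]), ins = m[3])
}

#' Read a PQR file
#'
#' Parses ATOM/HETATM records of a PQR file (PDB-like coordinates with
#' per-atom charge in elementary charges and radius in Angstrom). Both the
#' whitespace-delimited dialect written by PDB2PQR/APBS and fixed-column
#' variants are accepted; the dialect is detected per line. Chain identifiers
#' are optional (some PQR writers omit them). Non-atom records are ignored.
#'
#' @param path Path to the PQR file.
#' @return A `structure_model`: a list with an `atoms` data frame (serial,
#'   name, residue_name, chain_id, residue_number, insertion_code, x, y, z,
#'   charge, radius, is_hydrogen), `model_index`, and `source_path`.
#' @export
read_pqr <- function(path) {
  if (!file.exists(path)) stop("PQR file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  rows <- vector("list", length(lines))
  n <- 0L
  for (ln in seq_along(lines)) {
    line <- lines[ln]
    rec <- substr(line, 1, 6)
    if (!grepl("^(ATOM|HETATM)", rec)) next
    row <- parse_pqr_line(line, ln)
    n <- n + 1L
    rows[[n]] <- row
  }
  if (n == 0L) stop("no ATOM/HETATM records in ", path)
  atoms <- do.call(rbind, rows[seq_len(n)])
  new_structure_model(atoms, 1L, path)
}

parse_pqr_line <- function(line, ln) {
  toks <- strsplit(trimws(line), "[[:space:]]+")[[1]]
  # whitespace dialect: REC serial name resName [chain] resSeq x y z q r
  parsed <- NULL
  if (length(toks) %in% c(10L, 11L)) {
    has_chain <- length(toks) == 11L
    chain <- if (has_chain) toks[5] else ""
    resno_tok <- if (has_chain) toks[6] else toks[5]
    rest <- suppressWarnings(as.numeric(toks[(length(toks) - 4):length(toks)]))
    rr <- split_resno(resno_tok)
    serial <- suppressWarnings(as.integer(toks[2]))
    if (!is.null(rr) && !anyNA(rest) && !is.na(serial)) {
      parsed <- atom_df(serial, toks[3], toks[4], chain, rr$resno, rr$ins,
                        rest[1], rest[2], rest[3], rest[4], rest[5])
    }
  }
  if (is.null(parsed)) {
    # fixed-column dialect (PDB columns; charge/radius replace occ/B)
    serial <- suppressWarnings(as.integer(substr(line, 7, 11)))
    name <- trimws(substr(line, 13, 16))
    resname <- trimws(substr(line, 18, 20))
    chain <- trimws(substr(line, 22, 22))
    resno <- suppressWarnings(as.integer(substr(line, 23, 26)))
    ins <- trimws(substr(line, 27, 27))
    xyz <- suppressWarnings(as.numeric(c(
      substr(line, 31, 38), substr(line, 39, 46), substr(line, 47, 54)
    )))
    qr <- suppressWarnings(as.numeric(
      strsplit(trimws(substr(line, 55, nchar(line))), "[[:space:]]+")[[1]]
    ))
    if (is.na(serial) || anyNA(xyz) || length(qr) < 2 || anyNA(qr[1:2])) {
      stop(sprintf("malformed PQR record at line %d: %s", ln, line))
    }
    parsed <- atom_df(serial, name, resname, chain, resno, ins,
                      xyz[1], xyz[2], xyz[3], qr[1], qr[2])
  }
  if (!all(is.finite(c(parsed$x, parsed$y, parsed$z)))) {
    stop(sprintf("non-finite coordinates at line %d", ln))
  }
  if (parsed$radius < 0) {
    stop(sprintf("negative radius at line %d", ln))
  }
  parsed
}

#' Write a structure model as a PQR file
#'
#' Emits the whitespace-delimited PQR dialect (APBS convention). Round-trips
#' through [read_pqr()].
#'
#' @param model A `structure_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pqr <- function(model, path) {
  a <- model$atoms
  lines <- sprintf(
    "ATOM  %5d %-4s %-3s %s%4d%s %11.6f %11.6f %11.6f %9.5f %8.5f",
    a$serial, a$name, a$residue_name,
    ifelse(a$chain_id == "", " ", a$chain_id),
    a$residue_number, ifelse(a$insertion_code == "", "", a$insertion_code),
    a$x, a$y, a$z, a$charge, a$radius
  )
  # whitespace dialect: collapse runs so token count is stable
  lines <- gsub("[[:space:]]+", " ", lines)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

new_ensemble <- function(models, aligned = FALSE) {
  structure(list(models = models, aligned = isTRUE(aligned)),
            class = "ensemble")
}

#' @export
print.ensemble <- function(x, ...) {
  cat(sprintf("<ensemble> %d conformers x %d atoms%s\n", length(x$models),
              nrow(x$models[[1]]$atoms),
              if (x$aligned) ", aligned" else ""))
  invisible(x)
}

topology_keys <- function(model) {
  a <- model$atoms
  paste(a$chain_id, a$residue_number, a$insertion_code, a$name, sep = "|")
}

check_ensemble_topology <- function(models) {
  ref <- topology_keys(models[[1]])
  for (i in seq_along(models)[-1]) {
    cur <- topology_keys(models[[i]])
    if (length(cur) != length(ref)) {
      stop(sprintf(
        "model %d has %d atoms but model 1 has %d: mismatched atom topology",
        i, length(cur), length(ref)))
    }
    bad <- which(cur != ref)
    if (length(bad) > 0) {
      stop(sprintf(
        "model %d atom %d is '%s' but model 1 has '%s': mismatched atom topology",
        i, bad[1], cur[bad[1]], ref[bad[1]]))
    }
  }
  invisible(TRUE)
}

#' Read a (multi-model) PDB file as a conformer ensemble
#'
#' One `structure_model` per MODEL/ENDMDL block; a file without MODEL records
#' yields a single-model ensemble. All models must share an identical
#' (chain, residue number, atom name) sequence. Charges are set to 0 and radii
#' from a per-element table; join force-field charges and radii from a
#' companion PQR with [apply_pqr_topology()].
#'
#' @param path Path to the PDB file.
#' @return An `ensemble`: list of `structure_model`s plus an `aligned` flag.
#' @export
read_pdb_models <- function(path) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  lines <- sub("\r$", "", readLines(path, warn = FALSE))
  models <- list()
  cur <- list()
  ncur <- 0L
  model_idx <- 1L
  flush <- function() {
    if (ncur == 0L) return(invisible())
    atoms <- do.call(rbind, cur[seq_len(ncur)])
    models[[length(models) + 1L]] <<- new_structure_model(atoms, model_idx, path)
    cur <<- list()
    ncur <<- 0L
  }
  for (ln in seq_along(lines)) {
    line <- lines[ln]
    rec <- substr(line, 1, 6)
    if (grepl("^MODEL", rec)) {
      flush()
      model_idx <- suppressWarnings(as.integer(trimws(substr(line, 7, 20))))
      if (is.na(model_idx)) model_idx <- length(models) + 1L
    } else if (grepl("^ENDMDL", rec)) {
      flush()
    } else if (grepl("^(ATOM|HETATM)", rec)) {
      serial <- suppressWarnings(as.integer(substr(line, 7, 11)))
      name <- trimws(substr(line, 13, 16))
      resname <- trimws(substr(line, 18, 20))
      chain <- trimws(substr(line, 22, 22))
      resno <- suppressWarnings(as.integer(substr(line, 23, 26)))
      ins <- trimws(substr(line, 27, 27))
      xyz <- suppressWarnings(as.numeric(c(
        substr(line, 31, 38), substr(line, 39, 46), substr(line, 47, 54)
      )))
      if (is.na(serial) || anyNA(xyz) || is.na(resno)) {
        stop(sprintf("malformed PDB ATOM record at line %d", ln))
      }
      ncur <- ncur + 1L
      cur[[ncur]] <- atom_df(serial, name, resname, chain, resno, ins,
                             xyz[1], xyz[2], xyz[3], 0,
                             default_radius(name))
    }
  }
  flush()
  if (length(models) == 0L) stop("no atoms found in ", path)
  check_ensemble_topology(models)
  new_ensemble(models, aligned = FALSE)
}

#' Join charges and radii from a PQR template onto a PDB-derived ensemble
#'
#' MD trajectories are exported as PDB without charges; this joins per-atom
#' charge and radius from a companion PQR by (chain, residue number, atom
#' name). Atoms with no PQR match keep charge 0 and an element-table radius,
#' with a warning. Conformations change geometry, not charge, so the same
#' template applies to every frame.
#'
#' @param ensemble An `ensemble` (or a single `structure_model`).
#' @param pqr A `structure_model` read from a PQR file.
#' @return The input with charges/radii populated.
#' @export
apply_pqr_topology <- function(ensemble, pqr) {
  single <- inherits(ensemble, "structure_model")
  models <- if (single) list(ensemble) else ensemble$models
  key <- function(a) paste(a$chain_id, a$residue_number, a$name, sep = "|")
  tpl <- pqr$atoms
  tkey <- key(tpl)
  for (i in seq_along(models)) {
    a <- models[[i]]$atoms
    idx <- match(key(a), tkey)
    miss <- is.na(idx)
    if (any(miss) && i == 1L) {
      warning(sprintf(
        "%d atom(s) not found in PQR template; using element radii and charge 0 (first: %s)",
        sum(miss), key(a)[which(miss)[1]]))
    }
    a$charge[!miss] <- tpl$charge[idx[!miss]]
    a$radius[!miss] <- tpl$radius[idx[!miss]]
    a$charge[miss] <- 0
    a$radius[miss] <- default_radius(a$name[miss])
    models[[i]]$atoms <- a
  }
  if (single) models[[1]] else {
    ensemble$models <- models
    ensemble
  }
}

new_potential_grid <- function(origin, spacing, counts, values) {
  counts <- as.integer(counts)
  stopifnot(length(origin) == 3, length(spacing) == 3, length(counts) == 3)
  if (any(spacing <= 0)) stop("grid spacing components must be > 0")
  if (length(values) != prod(counts)) {
    stop(sprintf("grid declares %d values but %d supplied",
                 prod(counts), length(values)))
  }
  structure(
    list(origin = as.numeric(origin), spacing = as.numeric(spacing),
         counts = counts, values = as.numeric(values)),
    class = "potential_grid"
  )
}

#' Construct a potential grid in memory
#'
#' Regular 3-D scalar grid of electrostatic potential with OpenDX semantics:
#' `values` laid out z-fastest, i.e. the value at 0-based grid index
#' (i, j, k) is `values[i*ny*nz + j*nz + k + 1]`.
#'
#' @param origin Grid origin (Angstrom), length 3.
#' @param spacing Grid spacing (Angstrom), length 3, all > 0.
#' @param counts Node counts, length 3.
#' @param values Scalar values (kBT/ec), length `prod(counts)`, z-fastest.
#' @return A `potential_grid`.
#' @export
potential_grid <- function(origin, spacing, counts, values) {
  new_potential_grid(origin, spacing, counts, values)
}

#' Value at integer grid index
#'
#' @param grid A `potential_grid`.
#' @param i,j,k 0-based grid indices.
#' @return The stored scalar at that node.
#' @export
grid_value_at <- function(grid, i, j, k) {
  n <- grid$counts
  stopifnot(all(i >= 0 & i < n[1]), all(j >= 0 & j < n[2]),
            all(k >= 0 & k < n[3]))
  grid$values[i * n[2] * n[3] + j * n[3] + k + 1]
}

#' Read an OpenDX scalar grid (APBS potential map)
#'
#' Supports the "gridpositions" ascii format APBS writes: counts, origin,
#' three axis-aligned delta rows, then the scalar data in z-fastest order.
#' Values are taken to be in kBT/ec (the APBS default output unit).
#'
#' @param path Path to the .dx file.
#' @return A `potential_grid`.
#' @export
read_dx_grid <- function(path) {
  if (!file.exists(path)) stop("DX file not found: ", path)
  lines <- sub("\r$", "", readLines(path, warn = FALSE))
  lines <- lines[!grepl("^[[:space:]]*#", lines)]
  cnt_ln <- grep("class gridpositions counts", lines, fixed = TRUE)
  if (length(cnt_ln) == 0) stop("not an OpenDX gridpositions file: ", path)
  toks <- strsplit(trimws(lines[cnt_ln[1]]), "[[:space:]]+")[[1]]
  counts <- as.integer(tail(toks, 3))
  org_ln <- grep("^[[:space:]]*origin", lines)[1]
  origin <- as.numeric(strsplit(trimws(lines[org_ln]), "[[:space:]]+")[[1]][2:4])
  del_ln <- grep("^[[:space:]]*delta", lines)
  if (length(del_ln) < 3) stop("expected 3 delta rows in ", path)
  deltas <- t(vapply(lines[del_ln[1:3]], function(l) {
    as.numeric(strsplit(trimws(l), "[[:space:]]+")[[1]][2:4])
  }, numeric(3)))
  off_diag <- deltas
  diag(off_diag) <- 0
  if (any(abs(off_diag) > 1e-12)) {
    stop("unsupported format: non-orthogonal delta vectors in ", path)
  }
  spacing <- diag(deltas)
  data_ln <- grep("data follows", lines, fixed = TRUE)
  if (length(data_ln) == 0) stop("no 'data follows' object in ", path)
  first <- data_ln[1] + 1L
  # data ends at the next non-numeric line (trailing attribute/object rows)
  vals <- numeric(0)
  for (ln in seq(first, length(lines))) {
    toks <- strsplit(trimws(lines[ln]), "[[:space:]]+")[[1]]
    toks <- toks[nzchar(toks)]
    if (length(toks) == 0) next
    v <- suppressWarnings(as.numeric(toks))
    if (anyNA(v)) break
    vals <- c(vals, v)
  }
  if (length(vals) != prod(counts)) {
    stop(sprintf("DX grid declares %d x %d x %d = %d values but file has %d",
                 counts[1], counts[2], counts[3], prod(counts), length(vals)))
  }
  new_potential_grid(origin, spacing, counts, vals)
}

#' Write a potential grid as an OpenDX file
#'
#' @param grid A `potential_grid`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dx_grid <- function(grid, path) {
  n <- grid$counts
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# OpenDX scalar grid (potential, kBT/ec)",
    sprintf("object 1 class gridpositions counts %d %d %d", n[1], n[2], n[3]),
    sprintf("origin %g %g %g", grid$origin[1], grid$origin[2], grid$origin[3]),
    sprintf("delta %g 0.0 0.0", grid$spacing[1]),
    sprintf("delta 0.0 %g 0.0", grid$spacing[2]),
    sprintf("delta 0.0 0.0 %g", grid$spacing[3]),
    sprintf("object 2 class gridconnections counts %d %d %d", n[1], n[2], n[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(n))
  ), con)
  v <- grid$values
  pad <- (3 - length(v) %% 3) %% 3
  vm <- matrix(c(v, rep(NA_real_, pad)), nrow = 3)
  rows <- apply(vm, 2, function(r) paste(format(r[!is.na(r)], digits = 12),
                                         collapse = " "))
  writeLines(rows, con)
  writeLines('attribute "dep" string "positions"', con)
  invisible(path)
}

#' Write a surface mesh as ascii PLY
#'
#' Vertex positions, one optional per-vertex scalar, and triangular faces.
#'
#' @param mesh A `surface_mesh`.
#' @param path Output path.
#' @param scalar Name of the per-vertex field to attach as a vertex property:
#'   `"potential"` (requires `vertex_potential`) or `NULL` for none.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, scalar = "potential") {
  v <- mesh$vertices
  f <- mesh$faces
  sc <- NULL
  if (!is.null(scalar)) {
    if (identical(scalar, "potential")) {
      if (is.null(mesh$vertex_potential)) {
        stop("mesh has no per-vertex field 'potential'")
      }
      sc <- mesh$vertex_potential
    } else {
      stop("unknown per-vertex scalar: ", scalar)
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- c(
    "ply", "format ascii 1.0",
    sprintf("element vertex %d", nrow(v)),
    "property double x", "property double y", "property double z"
  )
  if (!is.null(sc)) hdr <- c(hdr, sprintf("property double %s", scalar))
  hdr <- c(hdr,
           sprintf("element face %d", nrow(f)),
           "property list uchar int vertex_indices", "end_header")
  writeLines(hdr, con)
  vm <- if (is.null(sc)) v else cbind(v, sc)
  writeLines(apply(vm, 1, function(r) paste(format(r, digits = 12),
                                            collapse = " ")), con)
  writeLines(paste(3, f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  invisible(path)
}

#' Read an ascii PLY mesh
#'
#' Counterpart of [write_mesh()]; used for round-tripping surfaces.
#'
#' @param path Path to the .ply file.
#' @return A `surface_mesh` (per-vertex scalars restored if present).
#' @export
read_ply <- function(path) {
  lines <- sub("\r$", "", readLines(path, warn = FALSE))
  if (lines[1] != "ply") stop("not a PLY file: ", path)
  endh <- which(lines == "end_header")[1]
  hdr <- lines[seq_len(endh)]
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", hdr,
                                                   value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face", hdr,
                                                 value = TRUE)))
  props <- sub("^property double ", "", grep("^property double", hdr,
                                             value = TRUE))
  vl <- lines[(endh + 1):(endh + nv)]
  vm <- do.call(rbind, lapply(strsplit(trimws(vl), "[[:space:]]+"), as.numeric))
  colnames(vm) <- props
  fl <- lines[(endh + nv + 1):(endh + nv + nf)]
  fm <- do.call(rbind, lapply(strsplit(trimws(fl), "[[:space:]]+"), as.integer))
  mesh <- new_surface_mesh(vm[, c("x", "y", "z"), drop = FALSE],
                           fm[, 2:4, drop = FALSE] + 1L,
                           grid_spacing = NA_real_, probe_radius = NA_real_)
  if ("potential" %in% props) mesh$vertex_potential <- vm[, "potential"]
  mesh
}
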