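# Local-surface selection around a mutated site: the residues within a
# minimum pairwise atomic distance of the site (default 4 Angstrom), and the
# surface vertices those residues own.

.aa3to1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)

#' Specify a variant site
#'
#' Sites are named by author-assigned residue numbers (the numbering used in
#' variant names like D306Y), never sequential indices. The mutant amino
#' acid `"-"` marks a deletion.
#'
#' @param chain_id Chain identifier.
#' @param residue_number Author residue number.
#' @param wt_aa Wild-type amino acid, 1-letter code.
#' @param mut_aa Mutant amino acid, 1-letter code, or `"-"` for a deletion.
#' @param insertion_code Optional insertion code.
#' @return A list of class `site_spec`.
#' @export
site_spec <- function(chain_id, residue_number, wt_aa, mut_aa,
                      insertion_code = "") {
  structure(
    list(chain_id = chain_id, residue_number = as.integer(residue_number),
         insertion_code = insertion_code,
         wt_aa = toupper(wt_aa), mut_aa = toupper(mut_aa)),
    class = "site_spec"
  )
}

#' @export
print.site_spec <- function(x, ...) {
  cat(sprintf("<site_spec> %s:%d%s %s>%s\n", x$chain_id, x$residue_number,
              x$insertion_code, x$wt_aa, x$mut_aa))
  invisible(x)
}

site_key <- function(site) {
  residue_key(site$chain_id, site$residue_number, site$insertion_code)
}

variant_label <- function(site) {
  sprintf("%s%d%s", site$wt_aa, site$residue_number,
          if (site$mut_aa == "-") "del" else site$mut_aa)
}

site_atoms <- function(model, site) {
  a <- model$atoms
  keys <- residue_key(a$chain_id, a$residue_number, a$insertion_code)
  which(keys == site_key(site))
}

# check that the model's residue type at the site matches the declared amino
# acid; error for the WT structure, warning for the mutant
check_site <- function(model, site, role = c("wt", "mut")) {
  role <- match.arg(role)
  idx <- site_atoms(model, site)
  if (length(idx) == 0) {
    chain_res <- model$atoms[model$atoms$chain_id == site$chain_id, ]
    avail <- unique(chain_res$residue_number)
    stop(sprintf(
      "site %s:%d not found; chain %s has residues: %s",
      site$chain_id, site$residue_number, site$chain_id,
      if (length(avail)) paste(sort(avail), collapse = ", ") else "(none)"))
  }
  resname <- model$atoms$residue_name[idx[1]]
  expect <- if (role == "wt") site$wt_aa else site$mut_aa
  one <- .aa3to1[toupper(resname)]
  if (!is.na(one) && expect != "-" && one != expect) {
    msg <- sprintf("site %s:%d is %s (%s) in the %s structure, not %s",
                   site$chain_id, site$residue_number, resname, one, role,
                   expect)
    if (role == "wt") stop(msg) else warning(msg)
  }
  invisible(TRUE)
}

#' Residues within a cutoff of a variant site
#'
#' Returns the site residue plus every residue whose minimum pairwise
#' atom-centre distance to any site atom is less than or equal to `cutoff`
#' (default 4 Angstrom). Distances are between atom centres; hydrogens count
#' when present unless excluded. Residues of all chains are considered by
#' default (surfaces are physical, not per-chain).
#'
#' @param model A `structure_model`.
#' @param site A [site_spec()].
#' @param cutoff Distance cutoff in Angstrom (inclusive).
#' @param include_hydrogens Count hydrogen atoms in the distances.
#' @param same_chain_only Restrict neighbours to the site's chain.
#' @return Sorted character vector of residue keys ("chain|resno|ins").
#' @export
local_residues <- function(model, site, cutoff = 4.0,
                           include_hydrogens = TRUE,
                           same_chain_only = FALSE) {
  stopifnot(inherits(model, "structure_model"), inherits(site, "site_spec"))
  a <- model$atoms
  keys <- residue_key(a$chain_id, a$residue_number, a$insertion_code)
  s_idx <- which(keys == site_key(site))
  if (length(s_idx) == 0) {
    chain_res <- unique(a$residue_number[a$chain_id == site$chain_id])
    stop(sprintf("site %s:%d not found; chain %s has residues: %s",
                 site$chain_id, site$residue_number, site$chain_id,
                 if (length(chain_res)) paste(sort(chain_res), collapse = ", ")
                 else "(none)"))
  }
  keep <- rep(TRUE, nrow(a))
  if (!include_hydrogens) keep <- !a$is_hydrogen
  if (same_chain_only) keep <- keep & a$chain_id == site$chain_id
  s_use <- intersect(s_idx, which(keep))
  if (length(s_use) == 0) s_use <- s_idx
  o_idx <- setdiff(which(keep), s_idx)
  res <- site_key(site)
  if (length(o_idx) > 0 && length(s_use) > 0) {
    sc <- as.matrix(a[s_use, c("x", "y", "z")])
    oc <- as.matrix(a[o_idx, c("x", "y", "z")])
    # min distance from each non-site atom to any site atom
    d2 <- outer(rowSums(oc^2), rowSums(sc^2), "+") - 2 * oc %*% t(sc)
    mind <- sqrt(pmax(apply(d2, 1, min), 0))
    near <- keys[o_idx][mind <= cutoff]
    res <- union(res, near)
  }
  sort(unique(res))
}

#' Surface vertices owned by a residue set
#'
#' @param mesh A `surface_mesh` labeled by [assign_vertices_to_residues()].
#' @param residues Character vector of residue keys.
#' @return Ascending integer vector of 1-based vertex indices. A fully
#'   buried region (no surface vertices) is an error, since it is a real,
#'   reportable outcome the caller must handle.
#' @export
region_vertices <- function(mesh, residues) {
  if (is.null(mesh$vertex_residue)) {
    stop("mesh vertices are not residue-labeled; run assign_vertices_to_residues first")
  }
  if (length(residues) == 0) stop("empty residue set")
  idx <- which(mesh$vertex_residue %in% residues)
  if (length(idx) == 0) {
    stop("region is buried: no surface vertices belong to the selected residues")
  }
  sort(idx)
}

new_region_mask <- function(residues, vertex_indices, cutoff) {
  structure(list(residues = residues, vertex_indices = vertex_indices,
                 cutoff = cutoff),
            class = "region_mask")
}

#' Consensus local region for a WT/mutant pair
#'
#' The region residue set is the union of the WT-derived and mutant-derived
#' neighbourhoods, so both potential samples describe the same nominal
#' surface patch even when the mutant side chain reaches farther (or the
#' site is deleted in the mutant). Vertex lists are computed per structure
#' from that shared set.
#'
#' @param wt,mut `structure_model`s sharing residue numbering around the
#'   site.
#' @param site A [site_spec()].
#' @param cutoff Distance cutoff in Angstrom.
#' @param wt_mesh,mut_mesh Optional labeled meshes; when given, per-structure
#'   vertex indices are filled in.
#' @param ... Passed to [local_residues()].
#' @return List with `region_mask` elements `wt` and `mut` (shared
#'   `residues`, per-structure `vertex_indices`).
#' @export
consensus_region <- function(wt, mut, site, cutoff = 4.0,
                             wt_mesh = NULL, mut_mesh = NULL, ...) {
  r_wt <- local_residues(wt, site, cutoff, ...)
  r_mut <- if (length(site_atoms(mut, site)) > 0) {
    local_residues(mut, site, cutoff, ...)
  } else {
    character(0)  # site deleted in the mutant; WT side defines it
  }
  shared <- sort(union(r_wt, r_mut))
  check_union_numbering(wt, mut, shared, site)
  vi_wt <- if (!is.null(wt_mesh)) region_vertices(wt_mesh, shared) else NULL
  vi_mut <- if (!is.null(mut_mesh)) region_vertices(mut_mesh, shared) else NULL
  list(wt = new_region_mask(shared, vi_wt, cutoff),
       mut = new_region_mask(shared, vi_mut, cutoff))
}

# residues of the union set present in both models must agree on residue
# type (except the mutated site itself)
check_union_numbering <- function(wt, mut, residues, site) {
  skey <- site_key(site)
  wt_names <- resname_by_key(wt)
  mut_names <- resname_by_key(mut)
  common <- setdiff(intersect(names(wt_names), names(mut_names)), skey)
  common <- intersect(common, residues)
  bad <- common[wt_names[common] != mut_names[common]]
  if (length(bad) > 0) {
    stop(sprintf(
      "residue numbering mismatch between WT and mutant in the region: %s is %s in WT but %s in mutant",
      bad[1], wt_names[bad[1]], mut_names[bad[1]]))
  }
  invisible(TRUE)
}

resname_by_key <- function(model) {
  a <- model$atoms
  keys <- residue_key(a$chain_id, a$residue_number, a$insertion_code)
  first <- !duplicated(keys)
  setNames(a$residue_name[first], keys[first])
}
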