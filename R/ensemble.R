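#' Configuration ensemble container
#'
#' A `sc_ensemble` holds an ordered set of frames (snapshots) of one
#' molecular system: a static atom table plus per-frame coordinates and box
#' vectors.  Atom ordering is identical in every frame; coordinates are nm.
#'
#' @param atoms data.frame with columns `element`, `mass` (u), `vdw_radius`
#'   (nm), `molecule_id` (integer), `molecule_type` (character), `role`
#'   (one of `"lipid"`, `"water"`, `"solute"`) and `atom_name`.
#' @param coords list of numeric matrices, one per frame, each
#'   `nrow(atoms)` x 3, in nm.
#' @param boxes numeric matrix, one row per frame, columns the x/y/z box
#'   edge lengths in nm (may contain `NA` when the source format carried no
#'   box; operations that need a box raise an error at the point of use).
#' @param catalog molecule-type catalog as returned by
#'   [molecule_catalog()]; built from `atoms` when `NULL`.
#'
#' @return An object of class `sc_ensemble`.
#' @export
sc_ensemble <- function(atoms, coords, boxes, catalog = NULL) {
  stopifnot(is.data.frame(atoms), is.list(coords), length(coords) >= 1L)
  needed <- c("element", "mass", "vdw_radius", "molecule_id",
              "molecule_type", "role")
  missing_cols <- setdiff(needed, names(atoms))
  if (length(missing_cols)) {
    .stopf("atom table lacks column(s): %s", paste(missing_cols, collapse = ", "))
  }
  if (!all(atoms$mass > 0)) .stopf("all atom masses must be > 0")
  if (!all(atoms$vdw_radius > 0)) .stopf("all vdW radii must be > 0")
  n_atoms <- nrow(atoms)
  for (k in seq_along(coords)) {
    xyz <- coords[[k]]
    if (!is.matrix(xyz) || nrow(xyz) != n_atoms || ncol(xyz) != 3L) {
      .stopf("frame %d: expected a %d x 3 coordinate matrix", k, n_atoms)
    }
    if (!all(is.finite(xyz))) .stopf("frame %d: non-finite coordinates", k)
  }
  boxes <- matrix(as.numeric(boxes), ncol = 3L)
  if (nrow(boxes) != length(coords)) {
    .stopf("need one box row per frame (%d frames, %d boxes)",
           length(coords), nrow(boxes))
  }
  if (any(!is.na(boxes) & boxes <= 0)) .stopf("box edge lengths must be > 0")
  if (is.null(catalog)) catalog <- molecule_catalog(atoms)
  structure(
    list(atoms = atoms, coords = coords, boxes = boxes, catalog = catalog),
    class = "sc_ensemble"
  )
}

#' Number of frames / atoms in an ensemble
#' @param ensemble an [sc_ensemble()]
#' @return integer count.
#' @export
n_frames <- function(ensemble) length(ensemble$coords)

#' @rdname n_frames
#' @export
n_atoms <- function(ensemble) nrow(ensemble$atoms)

#' Build the molecule-type catalog of an atom table
#'
#' One row per molecule type: name, molecular weight (sum of one molecule's
#' atomic masses, g/mol), role, atoms per molecule and molecule count.
#' All molecules of one type must have the same atom count.
#'
#' @param atoms atom table (see [sc_ensemble()]).
#' @return data.frame of class `sc_catalog` with columns `name`,
#'   `molecular_weight`, `role`, `n_atoms`, `count`.
#' @export
molecule_catalog <- function(atoms) {
  split_idx <- split(seq_len(nrow(atoms)), atoms$molecule_id)
  first_of_mol <- vapply(split_idx, `[`, integer(1), 1L)
  mol_type <- atoms$molecule_type[first_of_mol]
  mol_natoms <- lengths(split_idx)
  mol_mass <- vapply(split_idx, function(i) sum(atoms$mass[i]), numeric(1))
  types <- unique(mol_type)
  cat_df <- data.frame(
    name = types,
    molecular_weight = vapply(types, function(t) mol_mass[mol_type == t][1], numeric(1)),
    role = vapply(types, function(t) {
      atoms$role[atoms$molecule_type == t][1]
    }, character(1)),
    n_atoms = vapply(types, function(t) mol_natoms[mol_type == t][1], numeric(1)),
    count = vapply(types, function(t) sum(mol_type == t), numeric(1)),
    stringsAsFactors = FALSE
  )
  for (t in types) {
    na_t <- mol_natoms[mol_type == t]
    if (length(unique(na_t)) != 1L) {
      .stopf("molecule type '%s' has inconsistent atom counts per molecule", t)
    }
  }
  rownames(cat_df) <- NULL
  class(cat_df) <- c("sc_catalog", "data.frame")
  cat_df
}

#' @export
print.sc_ensemble <- function(x, ...) {
  cat(sprintf("<sc_ensemble> %d frame(s), %d atoms, %d molecule type(s)\n",
              n_frames(x), n_atoms(x), nrow(x$catalog)))
  b <- x$boxes[1L, ]
  cat(sprintf("  box (frame 1): %.4g x %.4g x %.4g nm\n", b[1], b[2], b[3]))
  cat(sprintf("  types: %s\n",
              paste(sprintf("%s(%d)", x$catalog$name, x$catalog$count),
                    collapse = ", ")))
  invisible(x)
}

## Within-molecule atom slot index (1..k per molecule), used to aggregate
## per-atom densities over all molecules of one type.
.atom_slot <- function(atoms) {
  stats::ave(seq_len(nrow(atoms)), atoms$molecule_id, FUN = seq_along)
}

## Roles from residue names: water dialects, everything else defaults to
## lipid unless the caller's catalog says otherwise.
.infer_role <- function(molecule_type) {
  ifelse(toupper(molecule_type) %in% .WATER_RESNAMES, "water", "lipid")
}

## Apply a user catalog (masses/radii per molecule type + atom slot) to a
## freshly parsed atom table.  The catalog may be an sc_catalog (roles and
## weights only) or an ensemble whose atoms carry per-slot masses.
.apply_reference_atoms <- function(atoms, reference) {
  ref_atoms <- if (inherits(reference, "sc_ensemble")) reference$atoms else reference
  stopifnot(is.data.frame(ref_atoms))
  slot <- .atom_slot(atoms)
  ref_slot <- .atom_slot(ref_atoms)
  key <- paste(atoms$molecule_type, slot)
  ref_key <- paste(ref_atoms$molecule_type, ref_slot)
  idx <- match(key, ref_key)
  hit <- !is.na(idx)
  atoms$mass[hit] <- ref_atoms$mass[idx[hit]]
  atoms$vdw_radius[hit] <- ref_atoms$vdw_radius[idx[hit]]
  atoms$element[hit] <- ref_atoms$element[idx[hit]]
  atoms$role[hit] <- ref_atoms$role[idx[hit]]
  atoms
}
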