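#' Shrake-Rupley solvent-accessible surface area
#'
#' Each atom's van der Waals sphere is inflated by the probe radius and
#' covered with a deterministic Fibonacci-spiral lattice of `n_points`
#' points; a point is buried when it lies strictly inside any other atom's
#' inflated sphere.  The atom's accessible area is
#' `4 * pi * (r_i + probe)^2 * accessible_points / n_points`.
#' The point set is deterministic, so results are exactly reproducible
#' without a seed.  Periodic images are not considered.
#'
#' @param coords numeric `m x 3` matrix of atom centres, nm.
#' @param radii van der Waals radii, nm (length `m`, all > 0).
#' @param probe_radius probe sphere radius, nm; the default 0.14 nm is the
#'   conventional water-probe radius used by `gmx sasa`.
#' @param n_points lattice points per sphere (>= 32).
#' @return list with `total` (nm^2) and `per_atom` (length-`m` vector, nm^2).
#' @export
shrake_rupley <- function(coords, radii, probe_radius = 0.14, n_points = 960L) {
  if (is.null(dim(coords))) coords <- matrix(coords, ncol = 3L)
  m <- nrow(coords)
  if (m == 0L) return(list(total = 0, per_atom = numeric(0)))
  stopifnot(length(radii) == m)
  if (any(radii <= 0)) .stopf("all vdW radii must be > 0")
  if (n_points < 32L) .stopf("n_points must be >= 32")
  pts <- .fibonacci_sphere(n_points)
  inflated <- radii + probe_radius
  per_atom <- numeric(m)
  ## Neighbour search: atom j can only occlude i when centres are closer
  ## than (r_i + probe) + (r_j + probe).
  d2 <- as.matrix(stats::dist(coords))^2
  for (i in seq_len(m)) {
    Ri <- inflated[i]
    cut2 <- (Ri + inflated)^2
    nb <- which(d2[i, ] < cut2 & seq_len(m) != i)
    if (!length(nb)) {
      per_atom[i] <- 4 * pi * Ri^2
      next
    }
    P <- pts * Ri
    P[, 1L] <- P[, 1L] + coords[i, 1L]
    P[, 2L] <- P[, 2L] + coords[i, 2L]
    P[, 3L] <- P[, 3L] + coords[i, 3L]
    accessible <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(accessible)) break
      idx <- which(accessible)
      dx <- P[idx, 1L] - coords[j, 1L]
      dy <- P[idx, 2L] - coords[j, 2L]
      dz <- P[idx, 3L] - coords[j, 3L]
      accessible[idx] <- (dx * dx + dy * dy + dz * dz) >= inflated[j]^2
    }
    per_atom[i] <- 4 * pi * Ri^2 * sum(accessible) / n_points
  }
  list(total = sum(per_atom), per_atom = per_atom)
}

## Deterministic Fibonacci spiral on the unit sphere.
.fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 1L
  z <- 1 - 2 * (i + 0.5) / n
  r <- sqrt(pmax(0, 1 - z * z))
  phi <- i * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' SASA distribution of one molecule type over an ensemble
#'
#' Computes every instance's SASA in the context of the full frame with
#' water excluded (water is the solvent the probe represents, so it never
#' occludes): lipid/solute neighbours shield each other, exactly as a
#' whole-system `gmx sasa` run with the solvent group removed.  The mean
#' over all (frame, instance) pairs defines the type's average SASA, and
#' the record marks the conformer nearest to that average.
#'
#' @param ensemble an [sc_ensemble()].
#' @param molecule_type molecule type name present in the ensemble.
#' @param probe_radius,n_points passed to [shrake_rupley()].
#' @return object of class `sc_sasa`: `molecule_type`, `values`
#'   (data.frame `frame`, `molecule_id`, `sasa` in nm^2), `mean_sasa`,
#'   `selected` (row of `values` minimizing `|sasa - mean_sasa|`, earliest
#'   (frame, molecule) on ties).
#' @export
sasa_distribution <- function(ensemble, molecule_type, probe_radius = 0.14,
                              n_points = 960L) {
  stopifnot(inherits(ensemble, "sc_ensemble"))
  at <- ensemble$atoms
  if (!molecule_type %in% at$molecule_type) {
    .stopf("unknown molecule type '%s'", molecule_type)
  }
  context <- which(at$role != "water")
  mol_ids <- unique(at$molecule_id[at$molecule_type == molecule_type])
  if (!length(mol_ids)) .stopf("no molecules of type '%s'", molecule_type)
  ## water itself: its SASA must be computed against the non-water context
  ## plus its own atoms
  rows <- list()
  for (f in seq_len(n_frames(ensemble))) {
    xyz <- ensemble$coords[[f]]
    res <- shrake_rupley(xyz[context, , drop = FALSE],
                         at$vdw_radius[context],
                         probe_radius = probe_radius, n_points = n_points)
    for (mid in mol_ids) {
      mine <- which(at$molecule_id[context] == mid)
      if (!length(mine)) {
        ## molecule not in context (a water type): isolated-molecule SASA
        own <- which(at$molecule_id == mid)
        s <- shrake_rupley(xyz[own, , drop = FALSE], at$vdw_radius[own],
                           probe_radius = probe_radius,
                           n_points = n_points)$total
      } else {
        s <- sum(res$per_atom[mine])
      }
      rows[[length(rows) + 1L]] <- data.frame(frame = f, molecule_id = mid,
                                              sasa = s)
    }
  }
  values <- do.call(rbind, rows)
  mean_sasa <- mean(values$sasa)
  sel <- which.min(abs(values$sasa - mean_sasa))  # ties -> earliest row
  structure(list(molecule_type = molecule_type, values = values,
                 mean_sasa = mean_sasa,
                 selected = values[sel, , drop = FALSE]),
            class = "sc_sasa")
}

#' @export
print.sc_sasa <- function(x, ...) {
  cat(sprintf("<sc_sasa> %s: %d observations, mean %.4f nm^2, selected frame %d molecule %d (%.4f nm^2)\n",
              x$molecule_type, nrow(x$values), x$mean_sasa,
              x$selected$frame, x$selected$molecule_id, x$selected$sasa))
  invisible(x)
}

#' Extract the representative (nearest-to-average-SASA) conformer
#'
#' Returns the conformer whose SASA is closest to the type's mean SASA
#' (earliest (frame, molecule) on ties), with coordinates translated to
#' its centroid, ready for export to a single-molecule structure file.
#'
#' @param ensemble the ensemble the record was computed from.
#' @param record an `sc_sasa` record from [sasa_distribution()].
#' @return list: `frame`, `molecule_id`, `sasa`, `atoms` (atom table
#'   subset), `coords` (centred coordinates, nm), and `ensemble` (a
#'   single-frame single-molecule [sc_ensemble()] for writing).
#' @export
select_representative_conformer <- function(ensemble, record) {
  stopifnot(inherits(record, "sc_sasa"))
  if (!nrow(record$values)) .stopf("empty SASA record")
  sel <- record$selected
  at <- ensemble$atoms
  own <- which(at$molecule_id == sel$molecule_id)
  xyz <- ensemble$coords[[sel$frame]][own, , drop = FALSE]
  xyz <- sweep(xyz, 2L, colMeans(xyz))
  atoms <- at[own, , drop = FALSE]
  atoms$molecule_id <- 1L
  rownames(atoms) <- NULL
  out_box <- ensemble$boxes[sel$frame, , drop = TRUE]
  list(frame = sel$frame, molecule_id = sel$molecule_id, sasa = sel$sasa,
       atoms = atoms, coords = xyz,
       ensemble = sc_ensemble(atoms, list(xyz), matrix(out_box, ncol = 3L)))
}
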