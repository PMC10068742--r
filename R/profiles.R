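#' Build the z-axis slice grid
#'
#' The membrane normal (z) is divided into `n` equal slices, with `n`
#' chosen so the slices are as close as possible to `target_thickness`
#' (default 0.1 nm, i.e. ca. 1 Angstrom — thin enough to treat each slice
#' as homogeneous): `n = max(1, round(box_z / target_thickness))` and
#' `thickness = box_z / n`.  Slice volumes are `thickness * box_x * box_y`.
#'
#' @param box 3-vector of box edge lengths (nm), or a single z length (in
#'   which case `box_area` must be supplied).
#' @param target_thickness desired slice thickness, nm.
#' @param box_area cross-sectional area x*y (nm^2) when `box` is scalar.
#' @return object of class `sc_grid`: `n`, `thickness`, `z_centers`,
#'   `slice_volume` (nm^3), `box_area` (nm^2), `box_z` (nm).
#' @export
build_slice_grid <- function(box, target_thickness = 0.1, box_area = NULL) {
  if (length(box) == 3L) {
    if (any(!is.finite(box)) || any(box <= 0)) .stopf("box edge lengths must be > 0")
    box_area <- box[1L] * box[2L]
    box_z <- box[3L]
  } else if (length(box) == 1L) {
    if (is.null(box_area)) .stopf("box_area required when box is a scalar z length")
    box_z <- box
  } else {
    .stopf("box must be a 3-vector or scalar z length")
  }
  if (!is.finite(box_z) || box_z <= 0) .stopf("box z length must be > 0")
  if (target_thickness <= 0) .stopf("target_thickness must be > 0")
  n <- max(1L, as.integer(round(box_z / target_thickness)))
  thickness <- box_z / n
  .slice_grid_raw(n, thickness, box_area,
                  z_centers = (seq_len(n) - 0.5) * thickness)
}

## Internal constructor used by readers; trusts its arguments.
.slice_grid_raw <- function(n, thickness, box_area, z_centers) {
  structure(
    list(n = as.integer(n), thickness = thickness, z_centers = z_centers,
         slice_volume = thickness * box_area, box_area = box_area,
         box_z = n * thickness),
    class = "sc_grid"
  )
}

#' @export
print.sc_grid <- function(x, ...) {
  cat(sprintf("<sc_grid> %d slices x %s nm over box_z = %s nm, dV = %s nm^3\n",
              x$n, format(x$thickness, digits = 6),
              format(x$box_z, digits = 6),
              format(x$slice_volume, digits = 6)))
  invisible(x)
}

## Half-open binning [z_lo, z_hi) after periodic wrap into [0, box_z);
## z == box_z wraps to slice 1.  Binning is done in fractional coordinates
## so fluctuating NPT boxes can be rescaled per frame onto a fixed grid.
.slice_of <- function(z, box_z, n) {
  frac <- z / box_z
  frac <- frac - floor(frac)
  idx <- floor(frac * n) + 1L
  pmin(as.integer(idx), n)  # guard the frac == 1 - eps rounding edge
}

.check_grid_box <- function(ensemble, grid) {
  mean_bz <- mean(ensemble$boxes[, 3L])
  if (!is.finite(mean_bz)) .stopf("ensemble has no box: density profiles need one")
  if (abs(mean_bz - grid$box_z) > 0.01 * grid$box_z) {
    .stopf("grid box_z (%.4g nm) and ensemble mean box_z (%.4g nm) differ by > 1%%",
           grid$box_z, mean_bz)
  }
  invisible(mean_bz)
}

## Per-atom slice occupancy counts over all frames: n_slices x n_atoms.
.slice_counts <- function(ensemble, grid) {
  n <- grid$n
  counts <- matrix(0, nrow = n, ncol = n_atoms(ensemble))
  for (f in seq_len(n_frames(ensemble))) {
    idx <- .slice_of(ensemble$coords[[f]][, 3L], ensemble$boxes[f, 3L], n)
    counts[cbind(idx, seq_len(ncol(counts)))] <-
      counts[cbind(idx, seq_len(ncol(counts)))] + 1
  }
  counts
}

#' Time-averaged normalized number-density profiles
#'
#' For every molecule type and every atom slot within a molecule of that
#' type, the fraction of (frame, molecule instance) observations falling
#' in each z slice — i.e. a normalized number density summing to 1 over
#' slices.  Atoms are binned per frame in fractional z so that fluctuating
#' NPT boxes rescale onto the fixed grid; the grid's (time-averaged) box
#' must agree with the ensemble's mean box_z within 1%.
#'
#' Also compiles the lipid and water mass-density profiles and the
#' water-fraction profile (when the ensemble contains water) into a
#' [DensityProfileSet][number_density_profiles] of class `sc_profiles`.
#'
#' @param ensemble an [sc_ensemble()].
#' @param grid an [build_slice_grid()] grid.
#' @return object of class `sc_profiles`: `grid`, `density` (named list of
#'   `n x atoms-per-molecule` matrices), `mass_density` (list with
#'   `lipid`, `water`, `all`; kg/m^3), `water` ([water_fraction_profile()]
#'   or `NULL`), `n_frames`.
#' @export
number_density_profiles <- function(ensemble, grid) {
  stopifnot(inherits(ensemble, "sc_ensemble"), inherits(grid, "sc_grid"))
  if (n_frames(ensemble) < 1L) .stopf("empty ensemble")
  .check_grid_box(ensemble, grid)
  counts <- .slice_counts(ensemble, grid)
  at <- ensemble$atoms
  slot <- .atom_slot(at)
  density <- list()
  for (t in ensemble$catalog$name) {
    sel <- which(at$molecule_type == t)
    k <- max(slot[sel])
    m <- matrix(0, nrow = grid$n, ncol = k)
    for (s in seq_len(k)) {
      cols <- sel[slot[sel] == s]
      m[, s] <- rowSums(counts[, cols, drop = FALSE])
      m[, s] <- m[, s] / sum(m[, s])
    }
    density[[t]] <- m
  }
  water <- if (any(at$role == "water")) water_fraction_profile(ensemble, grid) else NULL
  quiet_rho <- function(sel) {  # absent roles are simply flat zero here
    if (sel != "all" && !any(at$role == sel)) return(numeric(grid$n))
    mass_density_profile(ensemble, grid, sel)
  }
  structure(
    list(grid = grid, density = density,
         mass_density = list(lipid = quiet_rho("lipid"),
                             water = quiet_rho("water"),
                             all = quiet_rho("all")),
         water = water, n_frames = n_frames(ensemble)),
    class = "sc_profiles"
  )
}

#' @export
print.sc_profiles <- function(x, ...) {
  cat(sprintf("<sc_profiles> %d slices, types: %s; water %s\n",
              x$grid$n, paste(names(x$density), collapse = ", "),
              if (is.null(x$water)) "absent" else "present"))
  invisible(x)
}

#' Water-fraction profile x_w(z)
#'
#' Each water molecule is located by its oxygen atom (first O in the
#' molecule, else its first atom).  `n_w` is the time-averaged number of
#' water molecules per slice (fractional), `n_w_tot` the total water
#' count, and `x_w(z_i) = n_w(z_i) / n_w_tot`, which sums to 1.
#'
#' @inheritParams number_density_profiles
#' @return object of class `sc_water_profile`: `n_w`, `n_w_tot`, `x_w`, `n`.
#' @export
water_fraction_profile <- function(ensemble, grid) {
  stopifnot(inherits(ensemble, "sc_ensemble"), inherits(grid, "sc_grid"))
  at <- ensemble$atoms
  wat <- which(at$role == "water")
  if (!length(wat)) .stopf("water phase required: ensemble contains no water molecules")
  .check_grid_box(ensemble, grid)
  ## oxygen (or first atom) of each water molecule
  ref <- vapply(split(wat, at$molecule_id[wat]), function(i) {
    o <- i[at$element[i] == "O"]
    if (length(o)) o[1L] else i[1L]
  }, integer(1))
  n_w_tot <- length(ref)
  n_w <- numeric(grid$n)
  for (f in seq_len(n_frames(ensemble))) {
    idx <- .slice_of(ensemble$coords[[f]][ref, 3L], ensemble$boxes[f, 3L], grid$n)
    n_w <- n_w + tabulate(idx, nbins = grid$n)
  }
  n_w <- n_w / n_frames(ensemble)
  structure(list(n_w = n_w, n_w_tot = n_w_tot, x_w = n_w / n_w_tot,
                 n = grid$n),
            class = "sc_water_profile")
}

#' Mass-density profile
#'
#' Time-averaged mass per slice divided by the slice volume, in SI kg/m^3,
#' for the selected molecule role.  An empty selection yields an all-zero
#' profile with a warning (not an error).
#'
#' @inheritParams number_density_profiles
#' @param selection `"lipid"`, `"water"`, `"solute"` or `"all"`.
#' @return numeric vector of length `grid$n`, kg/m^3.
#' @export
mass_density_profile <- function(ensemble, grid,
                                 selection = c("lipid", "water", "solute", "all")) {
  selection <- match.arg(selection)
  stopifnot(inherits(ensemble, "sc_ensemble"), inherits(grid, "sc_grid"))
  .check_grid_box(ensemble, grid)
  at <- ensemble$atoms
  sel <- if (selection == "all") seq_len(nrow(at)) else which(at$role == selection)
  if (!length(sel)) {
    warning(sprintf("no atoms with role '%s': returning zero profile", selection),
            call. = FALSE)
    return(numeric(grid$n))
  }
  acc <- numeric(grid$n)
  for (f in seq_len(n_frames(ensemble))) {
    idx <- .slice_of(ensemble$coords[[f]][sel, 3L], ensemble$boxes[f, 3L], grid$n)
    per_slice <- rowsum(at$mass[sel], idx)
    acc[as.integer(rownames(per_slice))] <-
      acc[as.integer(rownames(per_slice))] + per_slice[, 1L]
  }
  mass_u <- acc / n_frames(ensemble)            # mean mass (u) per slice
  mass_u * .AMU_KG / (grid$slice_volume * 1e-27)  # kg / m^3
}

#' Locate the bilayer centre
#'
#' Mass-density-weighted circular mean of z under periodic boundary
#' conditions: slice centres are mapped to angles on a circle of
#' circumference `box_z`, averaged with the profile as weights, and mapped
#' back into `[0, box_z)`.
#'
#' @param rho per-slice mass-density (or any non-negative weight) profile.
#' @param grid the slice grid the profile lives on.
#' @return z position of the centre, nm.
#' @export
locate_bilayer_center <- function(rho, grid) {
  stopifnot(inherits(grid, "sc_grid"), length(rho) == grid$n)
  if (any(rho < 0)) .stopf("weights must be non-negative")
  if (all(rho == 0)) .stopf("all-zero profile: cannot locate a centre")
  theta <- 2 * pi * grid$z_centers / grid$box_z
  ang <- atan2(sum(rho * sin(theta)), sum(rho * cos(theta)))
  z <- ang / (2 * pi) * grid$box_z
  z - floor(z / grid$box_z) * grid$box_z
}

#' Symmetrize a profile about the bilayer centre
#'
#' The profile is first shifted by a whole number of slices (periodically)
#' so the given centre lands on the grid's reflection point `box_z / 2`,
#' then averaged with its mirror image (`slice i` with `slice n + 1 - i`;
#' for odd `n` the middle slice is its own mirror).  Whole-slice shifting
#' preserves the total sum exactly; no sub-slice interpolation is done.
#'
#' @param profile numeric vector of length `grid$n`.
#' @param grid the slice grid.
#' @param center z position (nm) of the bilayer centre; defaults to the
#'   grid midpoint (no shift).
#' @return symmetrized profile, same length, same total sum.
#' @export
symmetrize <- function(profile, grid, center = grid$box_z / 2) {
  stopifnot(inherits(grid, "sc_grid"), length(profile) == grid$n)
  if (!is.finite(center) || center < 0 || center > grid$box_z) {
    .stopf("center must lie within [0, box_z]")
  }
  n <- grid$n
  k <- as.integer(round((grid$box_z / 2 - center) / grid$thickness)) %% n
  shifted <- if (k == 0L) profile else c(profile[(n - k + 1L):n], profile[1L:(n - k)])
  (shifted + rev(shifted)) / 2
}
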