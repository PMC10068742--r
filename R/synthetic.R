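## Coarse bead architectures for the stratum-corneum lipid classes.
## One polar head bead plus an apolar tail chain; bead masses are chosen
## so the per-type molecular weights match the real lipids (making the
## L/kg conversion's M_lip realistic) while the geometry only needs to
## produce leaflet-structured densities, not chemistry.
.BEAD_SPECS <- list(
  CER2 = list(head_mass = 110.0, tail_mass = 60, n_tail = 9L),  # MW 650.0
  CER3 = list(head_mass = 112.0, tail_mass = 60, n_tail = 9L),  # MW 652.0
  CERO = list(head_mass = 105.0, tail_mass = 60, n_tail = 14L), # MW 945.0
  LIGN = list(head_mass = 68.6,  tail_mass = 60, n_tail = 5L),  # MW 368.6
  CHOL = list(head_mass = 86.7,  tail_mass = 60, n_tail = 5L)   # MW 386.7
)
.BEAD_STEP <- 0.22       # nm between consecutive tail beads
.HEAD_RADIUS <- 0.22     # nm, head bead vdW radius
.TAIL_RADIUS <- 0.20     # nm, tail bead vdW radius
.WATER_MASS <- 18.015    # u, single-bead water
.LEAFLET_OFFSET <- 2.2   # nm, head planes sit at centre +/- this

#' Bilayer fixture specification
#'
#' Describes a synthetic, bead-level stand-in for an equilibrated
#' stratum-corneum lipid system: which geometry, how many lipids of each
#' type, how much water, the box, the number of frames and the positional
#' noise that stands in for thermal motion.  The named presets reproduce
#' the component counts of the reference systems (mixed 1:1:1
#' FFA/CHOL/CER compositions; fully hydrated single bilayers carry 30
#' waters per lipid):
#'
#' | preset  | geometry         | lipids                                    | waters |
#' |---------|------------------|-------------------------------------------|--------|
#' | HPm2    | single_bilayer   | CER2 50, LIGN 50, CHOL 50                  | 4500   |
#' | HPm3    | single_bilayer   | CER3 50, LIGN 50, CHOL 50                  | 4500   |
#' | HPm2t   | stacked_trilayer | CER2 150, LIGN 150, CHOL 150               | 4500   |
#' | Amor    | amorphous        | CER2 50, CER3 50, LIGN 100, CHOL 100       | 9346   |
#'
#' The LPP (long-periodicity phase) geometry is not generated; the
#' stacked-trilayer fixture covers the multi-leaflet, anhydrous-core code
#' path.
#'
#' @param system preset name (`"HPm2"`, `"HPm3"`, `"HPm2t"`, `"Amor"`) or
#'   `"custom"`.
#' @param geometry `"single_bilayer"`, `"stacked_trilayer"` or
#'   `"amorphous"` (overrides the preset when given).
#' @param counts named lipid counts (overrides the preset when given).
#' @param n_waters total water count; when `NULL`, presets use their table
#'   value and custom specs use `waters_per_lipid * n_lip`.
#' @param waters_per_lipid hydration ratio used when `n_waters` is `NULL`
#'   (30 = fully hydrated).
#' @param box 3-vector, nm; a geometry-appropriate default when `NULL`.
#' @param n_frames frames in the generated ensemble.
#' @param noise_sd per-frame Gaussian positional noise, nm.
#' @param seed integer RNG seed; generation is a pure function of the spec.
#' @return list of class `sc_fixture_spec`.
#' @export
fixture_spec <- function(system = c("HPm2", "HPm3", "HPm2t", "Amor", "custom"),
                         geometry = NULL, counts = NULL, n_waters = NULL,
                         waters_per_lipid = 30, box = NULL, n_frames = 5L,
                         noise_sd = 0.03, seed = 1L) {
  system <- match.arg(system)
  presets <- list(
    HPm2 = list(geometry = "single_bilayer",
                counts = c(CER2 = 50L, LIGN = 50L, CHOL = 50L), n_waters = 4500L),
    HPm3 = list(geometry = "single_bilayer",
                counts = c(CER3 = 50L, LIGN = 50L, CHOL = 50L), n_waters = 4500L),
    HPm2t = list(geometry = "stacked_trilayer",
                 counts = c(CER2 = 150L, LIGN = 150L, CHOL = 150L), n_waters = 4500L),
    Amor = list(geometry = "amorphous",
                counts = c(CER2 = 50L, CER3 = 50L, LIGN = 100L, CHOL = 100L),
                n_waters = 9346L)
  )
  p <- presets[[system]]
  if (is.null(geometry)) geometry <- if (is.null(p)) "single_bilayer" else p$geometry
  geometry <- match.arg(geometry, c("single_bilayer", "stacked_trilayer", "amorphous"))
  if (is.null(counts)) {
    if (is.null(p)) .stopf("custom spec needs explicit lipid counts")
    counts <- p$counts
  }
  if (any(counts < 0)) .stopf("lipid counts must be >= 0")
  unknown <- setdiff(names(counts), names(.BEAD_SPECS))
  if (length(unknown)) {
    .stopf("no bead architecture for lipid type(s): %s",
           paste(unknown, collapse = ", "))
  }
  if (is.null(n_waters)) {
    n_waters <- if (!is.null(p)) p$n_waters else as.integer(round(waters_per_lipid * sum(counts)))
  }
  if (n_waters < 1L) .stopf("at least one water molecule required")
  if (is.null(box)) {
    box <- switch(geometry,
                  single_bilayer = c(7.2, 7.2, 10.0),
                  stacked_trilayer = c(7.2, 7.2, 19.0),
                  amorphous = c(8.0, 8.0, 14.0))
  }
  if (n_frames < 1L) .stopf("n_frames must be >= 1")
  if (noise_sd < 0) .stopf("noise_sd must be >= 0")
  structure(list(system = system, geometry = geometry, counts = counts,
                 n_waters = as.integer(n_waters), box = box,
                 n_frames = as.integer(n_frames), noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "sc_fixture_spec")
}

#' Generate a bilayer-like configuration ensemble
#'
#' Lipids are laid out as head + tail bead chains.  Single bilayers place
#' head beads (Gaussian laterally jittered) on the two leaflet planes at
#' `centre +/- 2.2 nm` with tails pointing to the core, and fill the two
#' water slabs outside the heads uniformly.  Stacked trilayers repeat the
#' bilayer three times along z with water only outside the stack (the
#' inner leaflets are anhydrous).  The amorphous geometry scatters
#' randomly oriented lipid chains uniformly in a slab and joins a water
#' slab above it, forming a biphasic lipid/water system.  Frames differ by
#' iid Gaussian positional noise of sd `noise_sd`; with the same spec
#' (seed included) the output is bitwise identical.
#'
#' @param spec an [fixture_spec()].
#' @return an [sc_ensemble()] whose catalog counts match the spec exactly.
#' @export
generate_bilayer_fixture <- function(spec) {
  stopifnot(inherits(spec, "sc_fixture_spec"))
  .with_seed(spec$seed, {
    base <- switch(spec$geometry,
                   single_bilayer = .layout_bilayer(spec, centers = spec$box[3] / 2),
                   stacked_trilayer = .layout_stack(spec),
                   amorphous = .layout_amorphous(spec))
    atoms <- base$atoms
    coords <- lapply(seq_len(spec$n_frames), function(f) {
      xyz <- base$xyz
      if (spec$noise_sd > 0) {
        xyz <- xyz + matrix(stats::rnorm(length(xyz), sd = spec$noise_sd),
                            ncol = 3L)
      }
      ## keep everything inside the periodic box
      xyz - floor(sweep(xyz, 2L, spec$box, "/")) * rep(spec$box, each = nrow(xyz))
    })
    boxes <- matrix(rep(spec$box, spec$n_frames), ncol = 3L, byrow = TRUE)
    sc_ensemble(atoms, coords, boxes)
  })
}

## -- geometry layouts ------------------------------------------------------

## Atom rows for one lipid molecule type.
.lipid_atoms <- function(type, mol_id) {
  b <- .BEAD_SPECS[[type]]
  k <- 1L + b$n_tail
  data.frame(
    element = c("O", rep("C", b$n_tail)),
    mass = c(b$head_mass, rep(b$tail_mass, b$n_tail)),
    vdw_radius = c(.HEAD_RADIUS, rep(.TAIL_RADIUS, b$n_tail)),
    molecule_id = rep(mol_id, k),
    molecule_type = rep(type, k),
    role = rep("lipid", k),
    atom_name = c("HD", sprintf("T%d", seq_len(b$n_tail))),
    stringsAsFactors = FALSE
  )
}

.water_atoms <- function(n, first_id) {
  data.frame(
    element = "O", mass = .WATER_MASS, vdw_radius = .element_radius("O"),
    molecule_id = seq.int(first_id, length.out = n),
    molecule_type = "H2O", role = "water", atom_name = "OW",
    stringsAsFactors = FALSE
  )
}

## Lateral site grid for per-leaflet placement; errors when the box cannot
## hold the requested lipids at the minimum spacing.
.lateral_sites <- function(n_needed, box, min_spacing = 0.55) {
  side <- ceiling(sqrt(n_needed))
  if (side < 1L) return(cbind(numeric(0), numeric(0)))
  spacing <- box[1] / side
  if (spacing < min_spacing) {
    .stopf("box too small: %d lipids per leaflet need spacing %.2f nm, box allows %.2f nm",
           n_needed, min_spacing, spacing)
  }
  gx <- (seq_len(side) - 0.5) * box[1] / side
  gy <- (seq_len(side) - 0.5) * box[2] / side
  sites <- as.matrix(expand.grid(x = gx, y = gy))
  sites[seq_len(n_needed), , drop = FALSE]
}

## Interleave lipid types so each leaflet is well mixed.
.type_sequence <- function(counts) {
  types <- rep(names(counts), counts)
  types[order(stats::ave(seq_along(types), types, FUN = seq_along),
              seq_along(types))]
}

## One or more bilayers: `centers` gives the bilayer midplanes; water
## fills z regions outside all head planes when `water_range` rows are
## supplied.
.layout_bilayer <- function(spec, centers, water_gap = 0.3) {
  box <- spec$box
  seq_types <- .type_sequence(spec$counts)
  n_lip <- length(seq_types)
  n_bilayers <- length(centers)
  per_leaflet <- ceiling(n_lip / (2L * n_bilayers))
  sites <- .lateral_sites(per_leaflet, box)
  atoms_list <- list()
  xyz_list <- list()
  mol_id <- 0L
  li <- 0L
  for (bc in centers) {
    for (leaf in c(+1, -1)) {
      for (s in seq_len(per_leaflet)) {
        if (li >= n_lip) break
        li <- li + 1L
        mol_id <- mol_id + 1L
        type <- seq_types[li]
        b <- .BEAD_SPECS[[type]]
        head_z <- bc + leaf * .LEAFLET_OFFSET
        zs <- head_z - leaf * .BEAD_STEP * (0:b$n_tail)
        xy <- sites[s, ] + stats::rnorm(2L, sd = 0.05)
        atoms_list[[mol_id]] <- .lipid_atoms(type, mol_id)
        xyz_list[[mol_id]] <- cbind(rep(xy[1L], length(zs)),
                                    rep(xy[2L], length(zs)), zs)
      }
    }
  }
  ## water slabs: everything outside [min head - gap, max head + gap]
  z_lo <- min(centers) - .LEAFLET_OFFSET - water_gap
  z_hi <- max(centers) + .LEAFLET_OFFSET + water_gap
  if (z_lo <= 0.05 && z_hi >= box[3] - 0.05) {
    .stopf("box too small: no room for water slabs outside the lipid phase")
  }
  nw <- spec$n_waters
  lower_len <- max(0, z_lo)
  upper_len <- max(0, box[3] - z_hi)
  n_lower <- round(nw * lower_len / (lower_len + upper_len))
  wz <- c(stats::runif(n_lower, 0, z_lo),
          stats::runif(nw - n_lower, z_hi, box[3]))
  wxy <- cbind(stats::runif(nw, 0, box[1]), stats::runif(nw, 0, box[2]))
  atoms_list[[length(atoms_list) + 1L]] <- .water_atoms(nw, mol_id + 1L)
  xyz_list[[length(xyz_list) + 1L]] <- cbind(wxy, wz)
  list(atoms = do.call(rbind, atoms_list), xyz = do.call(rbind, xyz_list))
}

.layout_stack <- function(spec, repeat_distance = 5.2) {
  mid <- spec$box[3] / 2
  centers <- mid + repeat_distance * c(-1, 0, 1)
  .layout_bilayer(spec, centers = centers)
}

.layout_amorphous <- function(spec, margin = 0.25) {
  box <- spec$box
  z_split <- 0.45 * box[3]  # lipid slab below, water slab above
  seq_types <- .type_sequence(spec$counts)
  atoms_list <- list()
  xyz_list <- list()
  mol_id <- 0L
  for (type in seq_types) {
    mol_id <- mol_id + 1L
    b <- .BEAD_SPECS[[type]]
    k <- 1L + b$n_tail
    origin <- c(stats::runif(1, 0, box[1]), stats::runif(1, 0, box[2]),
                stats::runif(1, margin, z_split - margin))
    dir <- stats::rnorm(3L)
    dir[3L] <- dir[3L] * 0.3   # keep chains mostly in-plane so they stay in the slab
    dir <- dir / sqrt(sum(dir^2))
    steps <- outer(0:b$n_tail, dir) * .BEAD_STEP
    xyz <- sweep(steps, 2L, origin, "+")
    xyz[, 3L] <- pmin(pmax(xyz[, 3L], 0.05), z_split - 0.05)
    atoms_list[[mol_id]] <- .lipid_atoms(type, mol_id)
    xyz_list[[mol_id]] <- xyz
  }
  nw <- spec$n_waters
  wxyz <- cbind(stats::runif(nw, 0, box[1]), stats::runif(nw, 0, box[2]),
                stats::runif(nw, z_split + margin, box[3] - margin))
  atoms_list[[length(atoms_list) + 1L]] <- .water_atoms(nw, mol_id + 1L)
  xyz_list[[length(xyz_list) + 1L]] <- wxyz
  list(atoms = do.call(rbind, atoms_list), xyz = do.call(rbind, xyz_list))
}

#' Parametric free-energy profile specification / generator
#'
#' A stand-in for an exported per-slice free-energy profile: twin Gaussian
#' wells of depth `well_depth` at `centre +/- well_center` (the lipid
#' interior), optional Gaussian head-group barriers at
#' `centre +/- barrier_center`, Gaussian noise of sd `noise_sd`, and zero
#' (the bulk-water reference) elsewhere.
#'
#' @param well_depth well depth, kJ/mol (>= 0; subtracted).
#' @param well_center offset of each well from the bilayer centre, nm.
#' @param well_width Gaussian sd of the wells, nm (> 0).
#' @param barrier_height head-group barrier height, kJ/mol.
#' @param barrier_center offset of the barriers from the centre, nm.
#' @param barrier_width Gaussian sd of the barriers, nm.
#' @param noise_sd Gaussian noise on every slice, kJ/mol.
#' @param temperature K.
#' @param seed integer seed.
#' @return list of class `sc_dg_spec`.
#' @export
dg_profile_spec <- function(well_depth = 15, well_center = 1.1,
                            well_width = 0.5, barrier_height = 0,
                            barrier_center = .LEAFLET_OFFSET,
                            barrier_width = 0.25, noise_sd = 0,
                            temperature = .T_DEFAULT, seed = 1L) {
  if (well_width <= 0 || barrier_width <= 0) .stopf("widths must be > 0")
  structure(list(well_depth = well_depth, well_center = well_center,
                 well_width = well_width, barrier_height = barrier_height,
                 barrier_center = barrier_center, barrier_width = barrier_width,
                 noise_sd = noise_sd, temperature = temperature,
                 seed = as.integer(seed)),
            class = "sc_dg_spec")
}

#' @rdname dg_profile_spec
#' @param spec an `sc_dg_spec`.
#' @param grid the slice grid the profile lives on (>= 3 slices).
#' @return `generate_dg_profile`: an [free_energy_profile()].
#' @export
generate_dg_profile <- function(spec, grid) {
  stopifnot(inherits(spec, "sc_dg_spec"), inherits(grid, "sc_grid"))
  if (grid$n < 3L) .stopf("free-energy profile needs at least 3 slices")
  .with_seed(spec$seed, {
    d <- grid$z_centers - grid$box_z / 2
    gauss <- function(x, w) exp(-x^2 / (2 * w^2))
    dg <- -spec$well_depth * (gauss(d - spec$well_center, spec$well_width) +
                              gauss(d + spec$well_center, spec$well_width)) +
      spec$barrier_height * (gauss(d - spec$barrier_center, spec$barrier_width) +
                             gauss(d + spec$barrier_center, spec$barrier_width))
    if (spec$noise_sd > 0) dg <- dg + stats::rnorm(grid$n, sd = spec$noise_sd)
    free_energy_profile(grid$z_centers, dg, temperature = spec$temperature)
  })
}

#' Synthetic solute benchmark table
#'
#' Emulates a compiled experimental solute database with known statistical
#' structure: `log_kow` drawn uniformly with planted strata
#' (`n_extreme` values above 5 and `n_hydrophilic` values below 1, the
#' counts the dataset filters must recover), and
#' `log_klip_exp = beta_true * log_kow + Normal(0, sigma^2)`.  For each
#' name in `systems` a predicted column
#' `log_klip_pred_<system> = log_klip_exp + bias + noise` is added, with
#' `bias = -underprediction * max(0, 1 - log_kow)` emulating the
#' systematic underprediction of hydrophilic solutes; a noisy
#' `log_kow_pred` column emulates an in-silico octanol/water prediction.
#'
#' @param n_solutes total rows.
#' @param beta_true true through-origin slope (default 0.74, the slope of
#'   the compiled experimental database).
#' @param sigma sd of the experimental noise, log units (default 0.46,
#'   the scatter of that database around the QSPR line).
#' @param kow_range range the non-planted `log_kow` values are drawn from.
#' @param n_extreme planted count with `log_kow > 5`.
#' @param n_hydrophilic planted count with `log_kow < 1`.
#' @param systems character vector of system names to fabricate
#'   predictions for.
#' @param underprediction strength of the hydrophilic bias, log units.
#' @param pred_sd sd of the prediction noise, log units.
#' @param seed integer seed.
#' @return `solute_set_spec`: list of class `sc_solute_spec`;
#'   `generate_solute_table`: an `sc_solutes` data.frame.
#' @export
solute_set_spec <- function(n_solutes = 64L, beta_true = 0.74, sigma = 0.46,
                            kow_range = c(1, 5), n_extreme = 2L,
                            n_hydrophilic = 16L, systems = character(),
                            underprediction = 0.5, pred_sd = 0.3, seed = 1L) {
  if (n_solutes < n_extreme + n_hydrophilic) {
    .stopf("n_solutes must be >= n_extreme + n_hydrophilic")
  }
  if (sigma < 0 || pred_sd < 0) .stopf("noise sds must be >= 0")
  structure(list(n_solutes = as.integer(n_solutes), beta_true = beta_true,
                 sigma = sigma, kow_range = kow_range,
                 n_extreme = as.integer(n_extreme),
                 n_hydrophilic = as.integer(n_hydrophilic), systems = systems,
                 underprediction = underprediction, pred_sd = pred_sd,
                 seed = as.integer(seed)),
            class = "sc_solute_spec")
}

#' @rdname solute_set_spec
#' @param spec an `sc_solute_spec`.
#' @export
generate_solute_table <- function(spec) {
  stopifnot(inherits(spec, "sc_solute_spec"))
  .with_seed(spec$seed, {
    n <- spec$n_solutes
    n_mid <- n - spec$n_extreme - spec$n_hydrophilic
    log_kow <- c(
      stats::runif(spec$n_hydrophilic, -1.5, 0.95),
      stats::runif(n_mid, max(1, spec$kow_range[1]), min(5, spec$kow_range[2])),
      stats::runif(spec$n_extreme, 5.05, 7.0)
    )
    ord <- sample.int(n)
    log_kow <- log_kow[ord]
    tab <- data.frame(
      name = sprintf("solute_%03d", seq_len(n)),
      log_klip_exp = spec$beta_true * log_kow + stats::rnorm(n, sd = spec$sigma),
      log_kow = log_kow,
      stringsAsFactors = FALSE
    )
    if (length(spec$systems)) {
      tab$log_kow_pred <- log_kow + stats::rnorm(n, sd = spec$pred_sd)
      bias <- -spec$underprediction * pmax(0, 1 - log_kow)
      for (sys in spec$systems) {
        tab[[paste0("log_klip_pred_", sys)]] <-
          tab$log_klip_exp + bias + stats::rnorm(n, sd = spec$pred_sd)
      }
    }
    class(tab) <- c("sc_solutes", "data.frame")
    tab
  })
}
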