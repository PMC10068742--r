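#' Bilayer composition
#'
#' Per-type lipid counts with a count-weighted mean molecular weight
#' `M_lip = sum(count_t * MW_t) / n_lip`, so that `n_lip * M_lip` is the
#' exact total lipid mass, plus the total water count.
#'
#' @param counts named integer vector of lipid counts per molecule type.
#' @param molecular_weights named numeric vector, g/mol, covering every
#'   name in `counts`.
#' @param n_waters total number of water molecules in the system.
#' @return object of class `sc_composition`: `counts`, `n_lip`, `M_lip`,
#'   `n_w_tot`.
#' @export
bilayer_composition <- function(counts, molecular_weights, n_waters = 0L) {
  if (!length(counts)) .stopf("no lipid counts given")
  if (is.null(names(counts))) .stopf("counts must be named by molecule type")
  if (any(counts < 0)) .stopf("counts must be >= 0")
  mw <- molecular_weights[names(counts)]
  if (any(is.na(mw))) {
    .stopf("molecular weight missing for: %s",
           paste(names(counts)[is.na(mw)], collapse = ", "))
  }
  n_lip <- sum(counts)
  if (n_lip == 0) .stopf("n_lip = 0: at least one lipid required")
  structure(list(counts = counts, n_lip = n_lip,
                 M_lip = sum(counts * mw) / n_lip,
                 n_w_tot = n_waters),
            class = "sc_composition")
}

#' Composition from a layer-table catalog
#'
#' Lipid counts and molecular weights are taken from catalog rows with
#' role `"lipid"`, the water count from rows with role `"water"`.
#'
#' @param table an `sc_layer_table`.
#' @return an [bilayer_composition()] object.
#' @export
composition_from_layer_table <- function(table) {
  stopifnot(inherits(table, "sc_layer_table"))
  cat_df <- table$catalog
  lip <- cat_df[cat_df$role == "lipid", , drop = FALSE]
  if (!nrow(lip)) .stopf("layer table catalog contains no lipids")
  bilayer_composition(
    stats::setNames(lip$count, lip$name),
    stats::setNames(lip$molecular_weight, lip$name),
    n_waters = sum(cat_df$count[cat_df$role == "water"])
  )
}

#' Extensive mol/mol partition coefficient from a free-energy profile
#'
#' Boltzmann integration of the full free-energy profile over the slice
#' grid:
#' \deqn{K = \frac{\sum_i V(z_i)\, e^{-\Delta G(z_i)/RT}}
#'            {\sum_i V(z_i)\, x_w(z_i)\, e^{-\Delta G(z_i)/RT}}}
#' with uniform slice volumes \eqn{V(z_i) = \delta V} (which cancel).
#' The exponentials are computed with the maximum Boltzmann exponent
#' factored out, so profiles anywhere in [-500, 500] kJ/mol neither
#' overflow nor collapse to 0/Inf — the property that keeps the estimator
#' stable even for strongly hydrophilic solutes, whose favourable region
#' is the water phase itself.  Because every slice contributes, K > 0
#' always.
#'
#' @param profile an [free_energy_profile()] (kJ/mol, referenced to bulk
#'   water) whose length matches the water profile.
#' @param water an [water_fraction_profile()] (or any list with an `x_w`
#'   vector summing to 1).
#' @return the mol/mol partition coefficient (scalar, > 0).
#' @export
k_mol_per_mol <- function(profile, water) {
  stopifnot(inherits(profile, "sc_dg_profile"))
  x_w <- water$x_w
  if (length(x_w) != profile$n) {
    .stopf("grid mismatch: profile has %d slices, water profile %d",
           profile$n, length(x_w))
  }
  if (any(x_w < 0)) .stopf("x_w must be non-negative")
  if (abs(sum(x_w) - 1) > 1e-6) {
    .stopf("water fractions must sum to 1 (got %.8g)", sum(x_w))
  }
  rt <- .R_KJ * profile$temperature
  expo <- -profile$dG / rt
  w <- exp(expo - max(expo))  # overflow-safe shift; max weight is 1
  denom <- sum(w * x_w)
  if (denom == 0) .stopf("all water weight falls on zero Boltzmann weight slices")
  sum(w) / denom
}

#' Convert mol/mol to the intensive L/kg partition coefficient
#'
#' \deqn{K_{lip} [L/kg] = K_{mol/mol} \cdot
#'   \frac{\delta V \, N_A}{n_{lip} M_{lip} / 1000}}
#' i.e. `K_molmol * deltaV[L] / m_lip[kg]` with the slice volume in litres
#' (1 nm^3 = 1e-24 L) and the total lipid mass
#' `m_lip = n_lip * M_lip / N_A` in kg.  Requires uniform slice volumes
#' (guaranteed by the grid construction).
#'
#' @param K_molmol extensive mol/mol coefficient from [k_mol_per_mol()].
#' @param grid the slice grid (supplies `slice_volume` in nm^3).
#' @param composition an [bilayer_composition()].
#' @return the L/kg partition coefficient (moles of solute per kg lipid
#'   over moles of solute per litre water).
#' @export
k_L_per_kg <- function(K_molmol, grid, composition) {
  stopifnot(inherits(grid, "sc_grid"), inherits(composition, "sc_composition"))
  if (composition$n_lip == 0) .stopf("n_lip = 0")
  dV_L <- grid$slice_volume * 1e-24           # nm^3 -> L
  m_lip_kg <- composition$n_lip * composition$M_lip / .N_AVOGADRO / 1000
  K_molmol * dV_L / m_lip_kg
}

#' Assemble a partition-coefficient result
#'
#' @param profile free-energy profile.
#' @param water water-fraction profile.
#' @param grid slice grid.
#' @param composition bilayer composition.
#' @return object of class `sc_partition`: `K_molmol`, `K_Lkg`,
#'   `log10_K_molmol`, `log10_K_Lkg`, `temperature`, `composition`.
#' @export
partition_coefficient <- function(profile, water, grid, composition) {
  K <- k_mol_per_mol(profile, water)
  KL <- k_L_per_kg(K, grid, composition)
  structure(list(K_molmol = K, K_Lkg = KL,
                 log10_K_molmol = log10(K), log10_K_Lkg = log10(KL),
                 temperature = profile$temperature,
                 composition = composition),
            class = "sc_partition")
}

#' @export
print.sc_partition <- function(x, ...) {
  cat(sprintf(
    "<sc_partition> K = %.6g mol/mol (log10 %.4f);  K_lip = %.6g L/kg (log10 %.4f) at %g K\n",
    x$K_molmol, x$log10_K_molmol, x$K_Lkg, x$log10_K_Lkg, x$temperature))
  invisible(x)
}

#' Predict a partition coefficient from on-disk inputs
#'
#' Reads a free-energy profile and a layer table, checks that the two live
#' on the same slice grid, takes the water-fraction profile from the layer
#' table's water-type oxygen densities, and chains
#' [k_mol_per_mol()] and [k_L_per_kg()].
#'
#' @param dg_path path to a free-energy profile TSV ([read_dg_profile()]).
#' @param layer_table_path path to a layer table ([read_layer_table()]).
#' @param composition an [bilayer_composition()]; derived from the layer
#'   table's catalog when `NULL`.
#' @param temperature K; attached to the profile.
#' @return an `sc_partition` (see [partition_coefficient()]).
#' @export
predict_from_files <- function(dg_path, layer_table_path, composition = NULL,
                               temperature = .T_DEFAULT) {
  profile <- read_dg_profile(dg_path, temperature = temperature)
  table <- read_layer_table(layer_table_path)
  if (profile$n != table$grid$n) {
    .stopf("grid mismatch: free-energy profile has %d slices, layer table %d",
           profile$n, table$grid$n)
  }
  if (is.null(composition)) composition <- composition_from_layer_table(table)
  water <- water_profile_from_layer_table(table)
  partition_coefficient(profile, water, table$grid, composition)
}

#' Water-fraction profile stored in a layer table
#'
#' The water type's first atom slot (the oxygen for the bead/atomistic
#' waters written by this package) carries a normalized per-atom density,
#' which is exactly `x_w`; `n_w` is recovered through the catalog's water
#' count.
#'
#' @param table an `sc_layer_table`.
#' @return an `sc_water_profile`.
#' @export
water_profile_from_layer_table <- function(table) {
  stopifnot(inherits(table, "sc_layer_table"))
  wt <- table$catalog$name[table$catalog$role == "water"]
  if (!length(wt)) .stopf("layer table contains no water type")
  x_w <- table$density[[wt[1L]]][, 1L]
  n_w_tot <- table$catalog$count[table$catalog$name == wt[1L]]
  structure(list(n_w = x_w * n_w_tot, n_w_tot = n_w_tot, x_w = x_w,
                 n = table$grid$n),
            class = "sc_water_profile")
}
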