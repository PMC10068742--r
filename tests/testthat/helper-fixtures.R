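# Shared in-code fixtures: tiny ensembles built directly from coordinates.

# Single-bead molecules at given positions. `z` may be a vector (one frame)
# or a list of vectors (frames); x/y default to box centre.
point_ensemble <- function(z, box = c(1, 1, 1), mass = 18.015, role = "water",
                           type = if (role == "water") "H2O" else "LIP",
                           element = "O", radius = 0.152) {
  if (!is.list(z)) z <- list(z)
  n <- length(z[[1L]])
  atoms <- data.frame(
    element = element, mass = mass, vdw_radius = radius,
    molecule_id = seq_len(n), molecule_type = type, role = role,
    atom_name = element, stringsAsFactors = FALSE
  )
  coords <- lapply(z, function(zz) {
    stopifnot(length(zz) == n)
    cbind(rep(box[1] / 2, n), rep(box[2] / 2, n), zz)
  })
  sc_ensemble(atoms, coords,
              matrix(rep(box, length(z)), ncol = 3, byrow = TRUE))
}

# Two molecule types (one lipid bead + waters), handy for mass/water tests.
mixed_ensemble <- function(z_lipid, z_water, box = c(1, 1, 1),
                           lipid_mass = 600) {
  nl <- length(z_lipid)
  nw <- length(z_water)
  atoms <- rbind(
    data.frame(element = "C", mass = lipid_mass, vdw_radius = 0.17,
               molecule_id = seq_len(nl), molecule_type = "LIP",
               role = "lipid", atom_name = "C", stringsAsFactors = FALSE),
    data.frame(element = "O", mass = 18.015, vdw_radius = 0.152,
               molecule_id = nl + seq_len(nw), molecule_type = "H2O",
               role = "water", atom_name = "OW", stringsAsFactors = FALSE)
  )
  z <- c(z_lipid, z_water)
  coords <- list(cbind(rep(box[1] / 2, nl + nw), rep(box[2] / 2, nl + nw), z))
  sc_ensemble(atoms, coords, matrix(box, ncol = 3))
}

# Uniform water profile over a grid (for partition tests).
uniform_water <- function(n, slices = seq_len(n)) {
  x_w <- numeric(n)
  x_w[slices] <- 1 / length(slices)
  list(x_w = x_w, n_w = x_w * 100, n_w_tot = 100)
}

RT_303 <- 8.314462618e-3 * 303.15  # kJ/mol at the default temperature
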