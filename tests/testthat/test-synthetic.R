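test_that("HPm2 preset carries the reference component counts", {
  spec <- fixture_spec("HPm2")
  ens <- generate_bilayer_fixture(spec)
  cat_df <- ens$catalog
  expect_equal(sum(cat_df$count[cat_df$role == "lipid"]), 150)
  expect_equal(cat_df$count[cat_df$name == "H2O"], 4500)
  expect_setequal(cat_df$name[cat_df$role == "lipid"],
                  c("CER2", "LIGN", "CHOL"))
  expect_equal(cat_df$count[cat_df$name == "CER2"], 50)
  # fully hydrated: 30 waters per lipid
  expect_equal(4500 / 150, 30)
  # bead molecular weights match the targeted lipid weights
  expect_equal(cat_df$molecular_weight[cat_df$name == "CER2"], 650.0,
               tolerance = 0.5 / 650)
  expect_equal(cat_df$molecular_weight[cat_df$name == "LIGN"], 368.6,
               tolerance = 0.5 / 368)
  expect_equal(cat_df$molecular_weight[cat_df$name == "CHOL"], 386.7,
               tolerance = 0.5 / 386)
})

test_that("catalog molecular weights equal summed atomic masses", {
  spec <- fixture_spec("Amor", counts = c(CER2 = 3L, CER3 = 3L, LIGN = 5L,
                                          CHOL = 5L),
                       n_waters = 200L, n_frames = 1L, seed = 9L)
  ens <- generate_bilayer_fixture(spec)
  at <- ens$atoms
  for (t in ens$catalog$name) {
    mw <- ens$catalog$molecular_weight[ens$catalog$name == t]
    first_mol <- min(at$molecule_id[at$molecule_type == t])
    expect_equal(sum(at$mass[at$molecule_id == first_mol]), mw,
                 tolerance = 0.5 / mw)
  }
})

test_that("generation is a pure function of the spec", {
  spec <- fixture_spec("HPm3", counts = c(CER3 = 5L, LIGN = 5L, CHOL = 5L),
                       n_waters = 100L, n_frames = 3L, seed = 123L)
  e1 <- generate_bilayer_fixture(spec)
  e2 <- generate_bilayer_fixture(spec)
  expect_identical(e1$coords, e2$coords)
  expect_identical(e1$atoms, e2$atoms)

  g <- build_slice_grid(c(7.2, 7.2, 10))
  d1 <- generate_dg_profile(dg_profile_spec(noise_sd = 1, seed = 77L), g)
  d2 <- generate_dg_profile(dg_profile_spec(noise_sd = 1, seed = 77L), g)
  expect_identical(d1$dG, d2$dG)

  s1 <- generate_solute_table(solute_set_spec(seed = 99L, systems = "X"))
  s2 <- generate_solute_table(solute_set_spec(seed = 99L, systems = "X"))
  expect_identical(s1, s2)

  # the generators do not disturb the caller's RNG stream
  set.seed(1); r1 <- runif(1)
  set.seed(1); invisible(generate_bilayer_fixture(spec)); r2 <- runif(1)
  expect_identical(r1, r2)
})

test_that("single-bilayer fixtures have symmetric leaflet density peaks", {
  spec <- fixture_spec("HPm2", n_frames = 3L, seed = 6L)
  ens <- generate_bilayer_fixture(spec)
  grid <- build_slice_grid(spec$box)
  rho <- mass_density_profile(ens, grid, "lipid")
  ctr <- locate_bilayer_center(rho, grid)
  expect_equal(ctr, spec$box[3] / 2, tolerance = grid$thickness / 2)
  upper <- which(grid$z_centers > ctr)
  lower <- which(grid$z_centers <= ctr)
  z_up <- grid$z_centers[upper[which.max(rho[upper])]]
  z_lo <- grid$z_centers[lower[which.max(rho[lower])]]
  # peaks mirror about the centre within one slice
  expect_lt(abs((z_up - ctr) + (z_lo - ctr)), grid$thickness + 1e-9)
  # water is confined to the outer slabs
  w <- water_fraction_profile(ens, grid)
  core <- abs(grid$z_centers - ctr) < 2.0
  expect_lt(sum(w$x_w[core]), 1e-9)
  expect_equal(sum(w$x_w), 1, tolerance = 1e-9)
})

test_that("stacked and amorphous geometries keep their stated structure", {
  spec <- fixture_spec("HPm2t", counts = c(CER2 = 18L, LIGN = 18L, CHOL = 18L),
                       n_waters = 540L, n_frames = 2L, seed = 14L)
  ens <- generate_bilayer_fixture(spec)
  grid <- build_slice_grid(spec$box)
  w <- water_fraction_profile(ens, grid)
  mid <- spec$box[3] / 2
  # anhydrous core: no water within the stacked region
  inner <- abs(grid$z_centers - mid) < 7.0
  expect_lt(sum(w$x_w[inner]), 1e-9)
  rho <- mass_density_profile(ens, grid, "lipid")
  # lipid mass present around all three bilayer midplanes
  for (off in c(-5.2, 0, 5.2)) {
    expect_gt(sum(rho[abs(grid$z_centers - (mid + off)) < 2.3]), 0)
  }

  amor <- fixture_spec("Amor", counts = c(CER2 = 10L, CER3 = 10L,
                                          LIGN = 20L, CHOL = 20L),
                       n_waters = 600L, n_frames = 2L, seed = 15L)
  ae <- generate_bilayer_fixture(amor)
  agrid <- build_slice_grid(amor$box)
  aw <- water_fraction_profile(ae, agrid)
  arho <- mass_density_profile(ae, agrid, "lipid")
  # biphasic: the lipid slab and the water slab occupy disjoint z regions
  lipid_z <- agrid$z_centers[arho > max(arho) * 0.05]
  water_z <- agrid$z_centers[aw$x_w > 1e-6]
  expect_lt(max(lipid_z), min(water_z) + 0.5)
})

test_that("boxes too small for the requested lipids are rejected", {
  spec <- fixture_spec("HPm2", counts = c(CER2 = 200L, LIGN = 200L,
                                          CHOL = 200L),
                       n_waters = 100L, box = c(3, 3, 10), seed = 1L)
  expect_error(generate_bilayer_fixture(spec), "box too small")
})

test_that("parametric free-energy profiles behave as specified", {
  grid <- build_slice_grid(c(7.2, 7.2, 10))
  flat <- generate_dg_profile(dg_profile_spec(well_depth = 0,
                                              barrier_height = 0,
                                              noise_sd = 0), grid)
  expect_equal(flat$dG, numeric(grid$n))
  expect_equal(k_mol_per_mol(flat, uniform_water(grid$n, 1:20)), grid$n,
               tolerance = 1e-12)

  # depth RT ln 10 concentrated in known slices -> direct-summation oracle
  dg <- numeric(grid$n)
  well_slices <- 48:53
  dg[well_slices] <- -RT_303 * log(10)
  prof <- free_energy_profile(grid$z_centers, dg, temperature = 303.15)
  w_slices <- c(1:20, 81:100)
  w <- uniform_water(grid$n, w_slices)
  direct <- sum(exp(-dg / RT_303)) /
    sum((1 / length(w_slices)) * exp(-dg[w_slices] / RT_303))
  expect_equal(k_mol_per_mol(prof, w), direct, tolerance = 1e-12)

  # wells sit where asked; water region stays near the bulk reference
  shaped <- generate_dg_profile(dg_profile_spec(well_depth = 20,
                                                well_center = 1.1,
                                                well_width = 0.3,
                                                barrier_height = 5),
                                grid)
  expect_lt(min(shaped$dG), -18)
  d <- abs(grid$z_centers - 5)
  expect_true(all(abs(shaped$dG[d > 3.5]) < 1.0))
})

test_that("solute tables plant the stated strata and slope", {
  tab <- generate_solute_table(solute_set_spec(seed = 3L))
  expect_equal(nrow(tab), 64L)
  kept <- exclude_extreme_lipophilic(tab)
  expect_equal(nrow(kept), 62L)
  red <- reduced_dataset(kept)
  expect_equal(nrow(kept) - nrow(red), 16L)

  # sigma = 0 recovers beta exactly
  exact <- generate_solute_table(solute_set_spec(sigma = 0, seed = 10L))
  fit <- qspr_fit(exact$log_klip_exp, exact$log_kow)
  expect_equal(fit$beta, 0.74, tolerance = 1e-12)
  expect_equal(fit$rmse_fit, 0, tolerance = 1e-12)

  # hydrophilic underprediction bias shows up in the planted predictions
  biased <- generate_solute_table(solute_set_spec(systems = "S", seed = 12L,
                                                  pred_sd = 0.05))
  res <- prediction_residuals(biased$log_klip_pred_S, biased$log_klip_exp)
  hyd <- biased$log_kow < 1
  expect_lt(mean(res[hyd]), mean(res[!hyd]))
  expect_lt(mean(res[hyd]), 0)
})

test_that("generated ensembles satisfy the container invariants", {
  spec <- fixture_spec("HPm2", counts = c(CER2 = 4L, LIGN = 4L, CHOL = 4L),
                       n_waters = 80L, n_frames = 4L, seed = 20L)
  ens <- generate_bilayer_fixture(spec)
  expect_s3_class(ens, "sc_ensemble")
  expect_true(all(ens$atoms$mass > 0))
  expect_true(all(ens$atoms$vdw_radius > 0))
  for (f in seq_len(n_frames(ens))) {
    expect_true(all(is.finite(ens$coords[[f]])))
    expect_true(all(ens$coords[[f]] >= 0))
    expect_true(all(ens$coords[[f]] <= rep(spec$box, each = n_atoms(ens))))
  }
  # bookkeeping: counts match the spec exactly
  expect_equal(sum(ens$catalog$count[ens$catalog$role == "lipid"]),
               sum(spec$counts))
  expect_equal(ens$catalog$count[ens$catalog$role == "water"], spec$n_waters)
})
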