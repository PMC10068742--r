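test_that("GRO reader echoes handcrafted frames and duplicates", {
  gro <- c(
    "two atoms",
    "    2",
    "    1LIG     C1    1   1.000   2.000   3.000",
    "    1LIG     C2    2   1.500   2.500   3.500",
    "   5.00000   5.00000  10.00000"
  )
  path <- withr::local_tempfile(fileext = ".gro")
  writeLines(gro, path)
  ens <- read_gro_ensemble(path)
  expect_equal(n_frames(ens), 1L)
  expect_equal(n_atoms(ens), 2L)
  expect_equal(ens$boxes[1, ], c(5, 5, 10))
  expect_equal(ens$coords[[1]][1, ], c(1, 2, 3))
  expect_equal(ens$atoms$molecule_type, c("LIG", "LIG"))
  expect_equal(ens$atoms$molecule_id, c(1L, 1L))

  writeLines(c(gro, gro), path)
  ens2 <- read_gro_ensemble(path)
  expect_equal(n_frames(ens2), 2L)
  expect_identical(ens2$coords[[1]], ens2$coords[[2]])
})

test_that("GRO reader rejects malformed input with line numbers", {
  path <- withr::local_tempfile(fileext = ".gro")
  writeLines(c("t", "    1", "    1LIG     C1    1   1.0",
               "   5.0 5.0 5.0"), path)
  expect_error(read_gro_ensemble(path), "line 3")
  writeLines(c("t", "    1", "    1LIG     C1    1   1.0"), path)
  expect_error(read_gro_ensemble(path), "runs past end of file")
  writeLines(c("t", "    1",
               "    1LIG     C1    1   1.000   2.000   x.000",
               "   5.0 5.0 5.0"), path)
  expect_error(read_gro_ensemble(path), "line 3")
  # inconsistent atom counts across frames
  writeLines(c("t", "    2",
               "    1LIG     C1    1   1.000   2.000   3.000",
               "    1LIG     C2    2   1.000   2.000   3.000",
               "   5.0 5.0 5.0",
               "t", "    1",
               "    1LIG     C1    1   1.000   2.000   3.000",
               "   5.0 5.0 5.0"), path)
  expect_error(read_gro_ensemble(path), "frame 2 has 1 atoms")
})

test_that("generated fixture round-trips through GRO within format precision", {
  spec <- fixture_spec("HPm2", counts = c(CER2 = 4L, LIGN = 4L, CHOL = 4L),
                       n_waters = 60L, n_frames = 3L, seed = 7L)
  ens <- generate_bilayer_fixture(spec)
  path <- withr::local_tempfile(fileext = ".gro")
  write_gro_ensemble(ens, path)
  back <- read_gro_ensemble(path, reference = ens)
  expect_equal(n_frames(back), 3L)
  for (f in 1:3) {
    expect_lt(max(abs(back$coords[[f]] - ens$coords[[f]])), 1e-3 + 1e-12)
  }
  expect_equal(back$atoms$molecule_type, ens$atoms$molecule_type)
  expect_equal(back$atoms$mass, ens$atoms$mass)
  expect_equal(back$atoms$role, ens$atoms$role)
})

test_that("PDB reader converts Angstrom to nm and splits MODEL blocks", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  O   HOH     1      10.000   0.000   0.000  1.00  0.00           O",
    "END"), path)
  ens <- read_pdb_ensemble(path)
  expect_equal(ens$coords[[1]][1, ], c(1, 0, 0))
  expect_equal(ens$atoms$role, "water")

  writeLines(c(
    "MODEL        1",
    "ATOM      1  C1  LIG     1       1.000   2.000   3.000  1.00  0.00           C",
    "ENDMDL",
    "MODEL        2",
    "ATOM      1  C1  LIG     1       1.100   2.000   3.000  1.00  0.00           C",
    "ENDMDL", "END"), path)
  ens2 <- read_pdb_ensemble(path)
  expect_equal(n_frames(ens2), 2L)
  expect_equal(ens2$coords[[2]][1, 1], 0.11)
})

test_that("GRO -> PDB -> read round-trips coordinates within 1e-4 nm", {
  spec <- fixture_spec("HPm2", counts = c(CER2 = 3L, CHOL = 3L, LIGN = 2L),
                       n_waters = 40L, n_frames = 2L, seed = 3L)
  ens <- generate_bilayer_fixture(spec)
  pdb <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_ensemble(ens, pdb)
  back <- read_pdb_ensemble(pdb, reference = ens)
  expect_equal(n_frames(back), 2L)
  for (f in 1:2) {
    expect_lt(max(abs(back$coords[[f]] - ens$coords[[f]])), 1e-4 + 1e-12)
  }
  expect_equal(back$boxes[1, ], ens$boxes[1, ], tolerance = 1e-3)
})

test_that("layer table round-trips exactly and rejects degenerate input", {
  grid <- build_slice_grid(c(2, 2, 0.3), target_thickness = 0.1)
  cat_df <- data.frame(name = "X", molecular_weight = 10, role = "lipid",
                       n_atoms = 1L, count = 1L, stringsAsFactors = FALSE)
  tab <- layer_table(grid, list(X = matrix(c(0, 1, 0), ncol = 1)), cat_df,
                     system = "tiny", n_frames_averaged = 1L)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_layer_table(tab, path)
  back <- read_layer_table(path)
  expect_identical(back$density$X, tab$density$X)
  expect_equal(back$grid$slice_volume, grid$slice_volume)
  expect_equal(back$metadata$system, "tiny")

  expect_error(layer_table(grid, list(), cat_df), "no molecule types")
  # header/body slice-count mismatch
  lines <- readLines(path)
  writeLines(lines[-length(lines)], path)
  expect_error(read_layer_table(path), "3 slices, body has 2")
})

test_that("randomized layer tables survive write/read within 1e-9", {
  set.seed(42)
  for (rep in 1:5) {
    n <- sample(3:30, 1)
    grid <- build_slice_grid(c(runif(1, 1, 8), runif(1, 1, 8), n * 0.1))
    types <- paste0("T", seq_len(sample(1:3, 1)))
    dens <- lapply(types, function(t) {
      k <- sample(1:4, 1)
      m <- matrix(stats::rexp(n * k), nrow = n)
      sweep(m, 2, colSums(m), "/")
    })
    names(dens) <- types
    cat_df <- data.frame(name = types, molecular_weight = runif(length(types), 18, 900),
                         role = "lipid", n_atoms = vapply(dens, ncol, 0L),
                         count = sample(1:50, length(types)),
                         stringsAsFactors = FALSE)
    cat_df$role[1] <- "water"
    tab <- layer_table(grid, dens, cat_df, system = sprintf("rand%d", rep))
    path <- withr::local_tempfile(fileext = ".tsv")
    write_layer_table(tab, path)
    back <- read_layer_table(path)
    for (t in types) {
      expect_lt(max(abs(back$density[[t]] - dens[[t]])), 1e-9)
    }
    expect_equal(back$catalog$molecular_weight, cat_df$molecular_weight)
  }
})

test_that("free-energy profile reader enforces uniform spacing and units", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("z_nm\tdG_kJ_per_mol",
               paste(seq(0.05, by = 0.1, length.out = 5), 0, sep = "\t")), path)
  p <- read_dg_profile(path)
  expect_equal(p$n, 5L)
  expect_equal(p$dG, rep(0, 5))

  writeLines(paste(c(0, 1, 2, 4), c(0, -1, -2, -1), sep = "\t"), path)
  expect_error(read_dg_profile(path), "non-uniform")

  # Angstrom flag converts at the boundary
  writeLines(c("# z_units angstrom",
               paste(c(0.5, 1.5, 2.5), c(0, -5, 0), sep = "\t")), path)
  pa <- read_dg_profile(path)
  expect_equal(pa$z, c(0.05, 0.15, 0.25))

  # round trip at full precision
  prof <- free_energy_profile(seq(0.05, by = 0.0997, length.out = 11),
                              rnorm(11))
  write_dg_profile(prof, path)
  back <- read_dg_profile(path)
  expect_lt(max(abs(back$dG - prof$dG)), 1e-9)
  expect_lt(max(abs(back$z - prof$z)), 1e-9)
})

test_that("solute table reader parses, flags missing values, rejects duplicates", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("name,log_klip_exp,log_kow",
               "a,1.0,1.5", "b,2.0,3.0", "c,0.5,0.2"), path)
  tab <- read_solute_table(path)
  expect_s3_class(tab, "sc_solutes")
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$log_kow, c(1.5, 3.0, 0.2))

  writeLines(c("name,log_klip_exp,log_kow", "a,1.0,1.5", "a,2.0,3.0"), path)
  expect_error(read_solute_table(path), "duplicate.*a")

  # missing optional predictions are kept as NA, not dropped
  writeLines(c("name,log_klip_exp,log_kow,log_klip_pred_S1",
               "a,1.0,1.5,0.9", "b,2.0,3.0,"), path)
  tab2 <- read_solute_table(path)
  expect_equal(nrow(tab2), 2L)
  expect_true(is.na(tab2$log_klip_pred_S1[2]))

  # generator output round-trips
  gen <- generate_solute_table(solute_set_spec(n_solutes = 64L, seed = 11L))
  write_solute_table(gen, path)
  back <- read_solute_table(path)
  expect_equal(nrow(back), 64L)
  expect_equal(back$log_kow, gen$log_kow, tolerance = 1e-12)
})

test_that("coordinates never leak Angstrom scale into memory", {
  path <- withr::local_tempfile(fileext = ".gro")
  writeLines(c("t", "    1",
               sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f", 1L, "LIG", "C1", 1L,
                       5000, 2, 3),
               "  1.0 1.0 1.0"), path)
  expect_error(read_gro_ensemble(path), "Angstrom leak")
})
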