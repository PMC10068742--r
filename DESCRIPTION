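Package: scpart
Title: Stratum Corneum Lipid/Water Partition Coefficients from Bilayer
    Ensembles and Free-Energy Profiles
Version: 0.1.0
Authors@R:
    person("scpart", "developers", email = "scpart@example.org",
           role = c("aut", "cre"))
Description: Post-processing toolkit for predicting stratum-corneum
    lipid/water partition coefficients from molecular-dynamics bilayer
    configuration ensembles and per-slice free-energy profiles.  Provides
    readers and writers for multi-frame GRO and PDB coordinate files, an
    open plain-text layer-table (density) format, free-energy profile
    tables and solute benchmark tables; slice-wise time-averaged number,
    mass and water-fraction density profiles with symmetrization about the
    bilayer centre; Shrake-Rupley solvent-accessible surface area with
    nearest-to-average representative conformer selection; Boltzmann
    integration of free-energy profiles into mol/mol and L/kg partition
    coefficients; QSPR benchmarking (through-origin fits, RMSE, residuals,
    dataset filters, quadrant analysis); and synthetic generators for
    bilayer-like ensembles, parametric free-energy profiles and solute
    datasets with known statistical structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
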