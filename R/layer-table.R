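#' Layer table: slice-wise normalized per-atom number densities
#'
#' The layer table is the density payload handed to the continuum-solvation
#' step: for every molecule type and every atom slot within a molecule of
#' that type, the normalized (sums to 1 over slices) time-averaged number
#' density on the z-slice grid, together with the grid geometry, the
#' molecule catalog and run metadata.  The on-disk dialect written by
#' [write_layer_table()] is an open, self-describing plain-text format
#' (documented below); byte compatibility with any proprietary `.mic`
#' layout is explicitly not claimed.
#'
#' @section File dialect:
#' ```
#' # scpart layer table v1
#' # system <name>
#' # temperature_K <T>
#' # n_frames <count>
#' # n_slices <n>
#' # thickness_nm <h>
#' # box_area_nm2 <A>
#' # slice_volume_nm3 <dV>
#' # molecule <name> <MW g/mol> <role> <atoms/molecule> <count>   (1+ lines)
#' z_nm <type>.<slot> ...                                  (TSV header row)
#' <z_1> <d_11> ...                                        (n body rows)
#' ```
#' Numbers are written at full double precision.
#'
#' @param grid an [build_slice_grid()] grid.
#' @param density named list (per molecule type) of `n x k` matrices of
#'   normalized per-atom-slot densities.
#' @param catalog molecule catalog ([molecule_catalog()]-shaped data.frame
#'   with columns `name`, `molecular_weight`, `role`, `n_atoms`, `count`).
#' @param system system name string.
#' @param temperature simulation temperature, K.
#' @param n_frames_averaged number of frames the densities average over.
#' @return object of class `sc_layer_table`.
#' @export
layer_table <- function(grid, density, catalog, system = "system",
                        temperature = .T_DEFAULT, n_frames_averaged = 1L) {
  stopifnot(inherits(grid, "sc_grid"))
  if (!length(density)) .stopf("no molecule types in layer table")
  if (is.null(names(density)) || any(!nzchar(names(density)))) {
    .stopf("density list must be named by molecule type")
  }
  for (t in names(density)) {
    m <- density[[t]]
    if (!is.matrix(m) || nrow(m) != grid$n) {
      .stopf("density block '%s' must have %d rows (one per slice)", t, grid$n)
    }
    if (any(m < 0)) .stopf("negative density entries for '%s'", t)
    s <- colSums(m)
    if (any(abs(s - 1) > 1e-9)) {
      .stopf("per-atom density for '%s' does not sum to 1 (max dev %.3g)",
             t, max(abs(s - 1)))
    }
  }
  missing_types <- setdiff(names(density), catalog$name)
  if (length(missing_types)) {
    .stopf("catalog lacks molecule type(s): %s",
           paste(missing_types, collapse = ", "))
  }
  structure(
    list(grid = grid, density = density,
         catalog = catalog[match(names(density), catalog$name), , drop = FALSE],
         metadata = list(system = system, temperature = temperature,
                         n_frames = as.integer(n_frames_averaged))),
    class = "sc_layer_table"
  )
}

#' @export
print.sc_layer_table <- function(x, ...) {
  cat(sprintf("<sc_layer_table> system %s, %d slices x %s nm, T = %g K, %d frame(s)\n",
              x$metadata$system, x$grid$n, format(x$grid$thickness, digits = 6),
              x$metadata$temperature, x$metadata$n_frames))
  cat(sprintf("  types: %s\n",
              paste(sprintf("%s[%d atoms x %d]", x$catalog$name,
                            x$catalog$n_atoms, x$catalog$count), collapse = ", ")))
  invisible(x)
}

#' Write / read the layer-table dialect
#'
#' `read_layer_table(write_layer_table(x, path))` reproduces `x` within
#' 1e-9 per entry (full-precision numeric text).
#'
#' @param table an `sc_layer_table`.
#' @param path file path.
#' @return `write_layer_table` returns `path` invisibly;
#'   `read_layer_table` returns an `sc_layer_table`.
#' @export
write_layer_table <- function(table, path) {
  stopifnot(inherits(table, "sc_layer_table"))
  g <- table$grid
  hdr <- c(
    "# scpart layer table v1",
    paste("# system", table$metadata$system),
    paste("# temperature_K", .fmt_num(table$metadata$temperature)),
    paste("# n_frames", table$metadata$n_frames),
    paste("# n_slices", g$n),
    paste("# thickness_nm", .fmt_num(g$thickness)),
    paste("# box_area_nm2", .fmt_num(g$box_area)),
    paste("# slice_volume_nm3", .fmt_num(g$slice_volume)),
    sprintf("# molecule %s %s %s %d %d",
            table$catalog$name, .fmt_num(table$catalog$molecular_weight),
            table$catalog$role, table$catalog$n_atoms, table$catalog$count)
  )
  cols <- unlist(lapply(names(table$density), function(t) {
    sprintf("%s.%d", t, seq_len(ncol(table$density[[t]])))
  }))
  body <- do.call(cbind, table$density)
  rows <- vapply(seq_len(g$n), function(i) {
    paste(c(.fmt_num(g$z_centers[i]), .fmt_num(body[i, ])), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, paste(c("z_nm", cols), collapse = "\t"), rows), path)
  invisible(path)
}

#' @rdname write_layer_table
#' @export
read_layer_table <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  is_comment <- startsWith(lines, "#")
  hdr <- lines[is_comment]
  meta <- list()
  mol_lines <- character()
  for (h in hdr) {
    tok <- strsplit(trimws(sub("^#\\s*", "", h)), "\\s+")[[1L]]
    if (!length(tok)) next
    if (tok[1L] == "molecule") mol_lines <- c(mol_lines, h)
    else if (length(tok) >= 2L) meta[[tok[1L]]] <- tok[-1L]
  }
  if (!length(mol_lines)) .stopf("layer-table format error: no molecule types in %s", path)
  cat_df <- do.call(rbind, lapply(mol_lines, function(h) {
    tok <- strsplit(trimws(sub("^#\\s*molecule\\s*", "", h)), "\\s+")[[1L]]
    if (length(tok) != 5L) .stopf("layer-table format error: bad molecule line '%s'", h)
    data.frame(name = tok[1L], molecular_weight = as.numeric(tok[2L]),
               role = tok[3L], n_atoms = as.integer(tok[4L]),
               count = as.integer(tok[5L]), stringsAsFactors = FALSE)
  }))
  class(cat_df) <- c("sc_catalog", "data.frame")

  body_lines <- lines[!is_comment & nzchar(trimws(lines))]
  if (length(body_lines) < 2L) .stopf("layer-table format error: missing body in %s", path)
  col_names <- strsplit(body_lines[1L], "\t", fixed = TRUE)[[1L]]
  n_slices <- as.integer(meta$n_slices[1L])
  rows <- body_lines[-1L]
  if (length(rows) != n_slices) {
    .stopf("layer-table format error: header says %d slices, body has %d rows",
           n_slices, length(rows))
  }
  num <- do.call(rbind, lapply(rows, function(r) {
    as.numeric(strsplit(r, "\t", fixed = TRUE)[[1L]])
  }))
  if (ncol(num) != length(col_names)) {
    .stopf("layer-table format error: ragged body in %s", path)
  }
  z <- num[, 1L]
  thickness <- as.numeric(meta$thickness_nm[1L])
  area <- as.numeric(meta$box_area_nm2[1L])
  grid <- .slice_grid_raw(n = n_slices, thickness = thickness,
                          box_area = area, z_centers = z)
  dens_cols <- col_names[-1L]
  type_of <- sub("\\.[0-9]+$", "", dens_cols)
  density <- lapply(unique(type_of), function(t) {
    m <- num[, -1L, drop = FALSE][, type_of == t, drop = FALSE]
    colnames(m) <- NULL
    m
  })
  names(density) <- unique(type_of)
  layer_table(grid, density, cat_df,
              system = paste(meta$system, collapse = " "),
              temperature = as.numeric(meta$temperature_K[1L]),
              n_frames_averaged = as.integer(meta$n_frames[1L]))
}

#' Read / write a per-slice free-energy profile table
#'
#' Two-column TSV: slice-centre z and free energy referenced to bulk water
#' (kJ/mol).  z may be nm (default, column `z_nm`) or Angstrom (column
#' `z_A` or a `# z_units angstrom` comment); values are converted to nm at
#' this boundary.  The z spacing must be uniform to within 1% of the mean
#' spacing — the downstream L/kg conversion requires equal slice volumes —
#' and strictly monotone increasing.
#'
#' @param path file path.
#' @param temperature temperature context attached to the profile, K.
#' @return an object of class `sc_dg_profile`: list with `z` (nm), `dG`
#'   (kJ/mol), `n`, `dz` and `temperature`.
#' @export
read_dg_profile <- function(path, temperature = .T_DEFAULT) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  comments <- lines[startsWith(lines, "#")]
  units <- "nm"
  for (h in comments) {
    tok <- strsplit(trimws(sub("^#\\s*", "", h)), "\\s+")[[1L]]
    if (length(tok) >= 2L && tok[1L] %in% c("z_units", "units")) units <- tolower(tok[2L])
  }
  body <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (!length(body)) .stopf("empty free-energy profile: %s", path)
  header <- strsplit(body[1L], "\\s+")[[1L]]
  has_header <- suppressWarnings(any(is.na(as.numeric(header))))
  if (has_header) {
    if (any(tolower(header) %in% c("z_a", "z_angstrom"))) units <- "angstrom"
    body <- body[-1L]
  }
  num <- do.call(rbind, lapply(body, function(r) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(r), "\\s+")[[1L]]))
    if (length(v) < 2L || any(!is.finite(v[1:2]))) {
      .stopf("malformed free-energy profile row: '%s'", r)
    }
    v[1:2]
  }))
  z <- num[, 1L]
  if (units %in% c("angstrom", "a", "ang")) z <- z / 10
  dg <- num[, 2L]
  free_energy_profile(z, dg, temperature = temperature)
}

#' Construct a free-energy profile
#'
#' @param z slice-centre positions, nm, strictly increasing, uniformly
#'   spaced (max deviation of successive spacings < 1% of the mean).
#' @param dG free energies, kJ/mol, referenced to bulk water.
#' @param temperature K.
#' @return object of class `sc_dg_profile`.
#' @export
free_energy_profile <- function(z, dG, temperature = .T_DEFAULT) {
  stopifnot(length(z) == length(dG), length(z) >= 1L)
  if (any(!is.finite(z)) || any(!is.finite(dG))) .stopf("non-finite profile values")
  if (temperature <= 0) .stopf("temperature must be > 0 K")
  dz <- NA_real_
  if (length(z) >= 2L) {
    dzs <- diff(z)
    if (any(dzs <= 0)) .stopf("profile z values must be strictly increasing")
    dz <- mean(dzs)
    if (max(abs(dzs - dz)) >= 0.01 * dz) {
      .stopf("non-uniform slice spacing (max deviation %.3g of mean %.3g): equal slice volumes required",
             max(abs(dzs - dz)), dz)
    }
  }
  structure(list(z = z, dG = dG, n = length(z), dz = dz,
                 temperature = temperature),
            class = "sc_dg_profile")
}

#' @rdname read_dg_profile
#' @param profile an `sc_dg_profile`.
#' @param units `"nm"` or `"angstrom"` for the written z column.
#' @export
write_dg_profile <- function(profile, path, units = c("nm", "angstrom")) {
  units <- match.arg(units)
  z <- if (units == "angstrom") profile$z * 10 else profile$z
  writeLines(c(sprintf("# z_units %s", units),
               paste(if (units == "angstrom") "z_A" else "z_nm",
                     "dG_kJ_per_mol", sep = "\t"),
               paste(.fmt_num(z), .fmt_num(profile$dG), sep = "\t")),
             path)
  invisible(path)
}

#' @export
print.sc_dg_profile <- function(x, ...) {
  cat(sprintf("<sc_dg_profile> %d slices, dz = %s nm, T = %g K, dG range [%.3g, %.3g] kJ/mol\n",
              x$n, format(x$dz, digits = 6), x$temperature,
              min(x$dG), max(x$dG)))
  invisible(x)
}

#' Read / write a solute benchmark table
#'
#' CSV with mandatory columns `name`, `log_klip_exp`, `log_kow`, and
#' optional columns `log_kow_pred` plus any number of per-system predicted
#' columns `log_klip_pred_<system>`.  Missing optional values are kept as
#' `NA`, never dropped.  Duplicate solute names are an error.
#'
#' @param path file path.
#' @return data.frame of class `sc_solutes`.
#' @export
read_solute_table <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  needed <- c("name", "log_klip_exp", "log_kow")
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols)) {
    .stopf("solute table lacks column(s): %s", paste(missing_cols, collapse = ", "))
  }
  dup <- unique(tab$name[duplicated(tab$name)])
  if (length(dup)) {
    .stopf("duplicate solute name(s): %s", paste(dup, collapse = ", "))
  }
  num_cols <- setdiff(names(tab), "name")
  for (cc in num_cols) tab[[cc]] <- as.numeric(tab[[cc]])
  class(tab) <- c("sc_solutes", "data.frame")
  tab
}

#' @rdname read_solute_table
#' @param records an `sc_solutes` data.frame.
#' @export
write_solute_table <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
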