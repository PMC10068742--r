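#' Read a (multi-frame) GRO coordinate file
#'
#' Parses one or more concatenated fixed-column GRO blocks into an
#' [sc_ensemble()].  Coordinates are kept in nm (the GRO native unit).
#' Molecule ids are assigned from the residue number column (a new molecule
#' starts whenever the residue number or name changes between consecutive
#' lines); molecule types are residue names.  Elements are inferred from
#' atom names and give each atom a mass and a Bondi van der Waals radius;
#' pass `reference` (an ensemble or atom table, typically the generator
#' output or a radii table read with [read_radii_table()]) to override
#' masses/radii/roles per molecule type and atom slot.
#'
#' @param path file path.
#' @param reference optional ensemble/atom table supplying per-atom masses,
#'   radii, elements and roles for matching molecule types.
#' @param radii optional named numeric vector (element -> nm) overriding
#'   the built-in Bondi table.
#' @return an [sc_ensemble()].
#' @export
read_gro_ensemble <- function(path, reference = NULL, radii = NULL) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[seq_len(max(which(nzchar(trimws(lines))), 0L))]
  if (!length(lines)) .stopf("empty GRO file: %s", path)

  frames <- list()
  boxes <- list()
  atom_tabs <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (i + 1L > length(lines)) .stopf("GRO parse error at line %d: truncated frame header", i)
    nat <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(nat) || nat < 1L) {
      .stopf("GRO parse error at line %d: expected atom count, got '%s'",
             i + 1L, trimws(lines[i + 1L]))
    }
    last <- i + 1L + nat
    if (last + 1L > length(lines)) {
      .stopf("GRO parse error: frame starting at line %d runs past end of file", i)
    }
    body <- lines[(i + 2L):last]
    widths_ok <- nchar(body) >= 44L
    if (!all(widths_ok)) {
      bad <- i + 1L + which(!widths_ok)[1L]
      .stopf("GRO parse error at line %d: record shorter than 44 columns", bad)
    }
    resid <- trimws(substr(body, 1L, 5L))
    resname <- trimws(substr(body, 6L, 10L))
    atomname <- trimws(substr(body, 11L, 15L))
    x <- suppressWarnings(as.numeric(substr(body, 21L, 28L)))
    y <- suppressWarnings(as.numeric(substr(body, 29L, 36L)))
    z <- suppressWarnings(as.numeric(substr(body, 37L, 44L)))
    bad <- which(!is.finite(x) | !is.finite(y) | !is.finite(z))
    if (length(bad)) {
      .stopf("GRO parse error at line %d: malformed coordinate fields", i + 1L + bad[1L])
    }
    boxvec <- suppressWarnings(as.numeric(strsplit(trimws(lines[last + 1L]), "\\s+")[[1L]]))
    if (length(boxvec) < 3L || any(!is.finite(boxvec[1:3]))) {
      .stopf("GRO parse error at line %d: malformed box line", last + 1L)
    }
    frames[[length(frames) + 1L]] <- cbind(x, y, z, deparse.level = 0)
    boxes[[length(boxes) + 1L]] <- boxvec[1:3]
    atom_tabs[[length(atom_tabs) + 1L]] <-
      data.frame(resid = resid, resname = resname, atomname = atomname,
                 stringsAsFactors = FALSE)
    i <- last + 2L
  }

  nat0 <- nrow(atom_tabs[[1L]])
  for (k in seq_along(atom_tabs)) {
    if (nrow(atom_tabs[[k]]) != nat0) {
      .stopf("ensemble error: frame %d has %d atoms, frame 1 has %d",
             k, nrow(atom_tabs[[k]]), nat0)
    }
  }
  atoms <- .atoms_from_records(atom_tabs[[1L]], radii)
  ens <- sc_ensemble(atoms, frames, do.call(rbind, boxes))
  if (!is.null(reference)) {
    ens$atoms <- .apply_reference_atoms(ens$atoms, reference)
    ens$catalog <- molecule_catalog(ens$atoms)
  }
  .assert_nm_scale(ens, path)
  ens
}

#' Write an ensemble as a (multi-frame) GRO file
#'
#' @param ensemble an [sc_ensemble()].
#' @param path output file path.
#' @param title title string written on each frame's first line.
#' @return `path`, invisibly.
#' @export
write_gro_ensemble <- function(ensemble, path, title = "scpart ensemble") {
  at <- ensemble$atoms
  resid <- ((at$molecule_id - 1L) %% 99999L) + 1L
  name <- if ("atom_name" %in% names(at)) at$atom_name else at$element
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames(ensemble))) {
    xyz <- ensemble$coords[[f]]
    writeLines(c(sprintf("%s, frame %d", title, f),
                 sprintf("%5d", nrow(at))), con)
    writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       resid, substr(at$molecule_type, 1L, 5L),
                       substr(name, 1L, 5L),
                       ((seq_len(nrow(at)) - 1L) %% 99999L) + 1L,
                       xyz[, 1L], xyz[, 2L], xyz[, 3L]), con)
    writeLines(sprintf("%10.5f%10.5f%10.5f",
                       ensemble$boxes[f, 1L], ensemble$boxes[f, 2L],
                       ensemble$boxes[f, 3L]), con)
  }
  invisible(path)
}

#' Read a (multi-model) PDB coordinate file
#'
#' ATOM/HETATM records, with optional MODEL/ENDMDL frame markers and an
#' optional CRYST1 box.  Coordinates are converted from Angstrom to nm at
#' this boundary.  A missing CRYST1 leaves the box `NA`; operations that
#' need a box raise their own error at the point of use.
#'
#' @inheritParams read_gro_ensemble
#' @return an [sc_ensemble()].
#' @export
read_pdb_ensemble <- function(path, reference = NULL, radii = NULL) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1L, 6L)
  box <- c(NA_real_, NA_real_, NA_real_)
  cr <- which(trimws(rec) == "CRYST1")
  if (length(cr)) {
    v <- suppressWarnings(as.numeric(c(substr(lines[cr[1L]], 7L, 15L),
                                       substr(lines[cr[1L]], 16L, 24L),
                                       substr(lines[cr[1L]], 25L, 33L))))
    if (all(is.finite(v))) box <- v / 10
  }
  is_atom <- trimws(rec) %in% c("ATOM", "HETATM")
  is_model <- trimws(rec) == "MODEL"
  if (!any(is_atom)) .stopf("no ATOM/HETATM records in %s", path)

  frame_of <- cumsum(is_model)
  frame_of[frame_of == 0L] <- 1L
  frame_ids <- unique(frame_of[is_atom])
  frames <- list()
  atom_tabs <- list()
  for (fi in seq_along(frame_ids)) {
    sel <- which(is_atom & frame_of == frame_ids[fi])
    body <- lines[sel]
    x <- suppressWarnings(as.numeric(substr(body, 31L, 38L)))
    y <- suppressWarnings(as.numeric(substr(body, 39L, 46L)))
    z <- suppressWarnings(as.numeric(substr(body, 47L, 54L)))
    bad <- which(!is.finite(x) | !is.finite(y) | !is.finite(z))
    if (length(bad)) {
      .stopf("PDB parse error at line %d: malformed coordinates", sel[bad[1L]])
    }
    frames[[fi]] <- cbind(x, y, z, deparse.level = 0) / 10  # Angstrom -> nm
    elem <- trimws(substr(body, 77L, 78L))
    atom_tabs[[fi]] <- data.frame(
      resid = trimws(substr(body, 23L, 26L)),
      resname = trimws(substr(body, 18L, 20L)),
      atomname = trimws(substr(body, 13L, 16L)),
      element = elem,
      stringsAsFactors = FALSE
    )
  }
  nat0 <- nrow(atom_tabs[[1L]])
  for (k in seq_along(atom_tabs)) {
    if (nrow(atom_tabs[[k]]) != nat0) {
      .stopf("ensemble error: model %d has %d atoms, model 1 has %d",
             k, nrow(atom_tabs[[k]]), nat0)
    }
  }
  atoms <- .atoms_from_records(atom_tabs[[1L]], radii,
                               element = atom_tabs[[1L]]$element)
  ens <- sc_ensemble(atoms, frames,
                     matrix(rep(box, length(frames)), ncol = 3L, byrow = TRUE))
  if (!is.null(reference)) {
    ens$atoms <- .apply_reference_atoms(ens$atoms, reference)
    ens$catalog <- molecule_catalog(ens$atoms)
  }
  .assert_nm_scale(ens, path)
  ens
}

#' Write an ensemble as a (multi-model) PDB file
#'
#' Coordinates are written in Angstrom; multiple frames become MODEL
#' blocks.  Frames with a known box get a CRYST1 record.
#'
#' @inheritParams write_gro_ensemble
#' @export
write_pdb_ensemble <- function(ensemble, path) {
  at <- ensemble$atoms
  name <- if ("atom_name" %in% names(at)) at$atom_name else at$element
  con <- file(path, "w")
  on.exit(close(con))
  b <- ensemble$boxes[1L, ]
  if (all(is.finite(b))) {
    writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                       b[1] * 10, b[2] * 10, b[3] * 10, 90, 90, 90), con)
  }
  multi <- n_frames(ensemble) > 1L
  for (f in seq_len(n_frames(ensemble))) {
    if (multi) writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- ensemble$coords[[f]] * 10
    writeLines(sprintf(
      "ATOM  %5d %-4s%-4s%5d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      ((seq_len(nrow(at)) - 1L) %% 99999L) + 1L,
      substr(name, 1L, 4L), substr(at$molecule_type, 1L, 4L),
      ((at$molecule_id - 1L) %% 9999L) + 1L,
      xyz[, 1L], xyz[, 2L], xyz[, 3L],
      substr(at$element, 1L, 2L)), con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

## Shared GRO/PDB post-parse: molecule assignment, element inference,
## masses, radii, roles.
.atoms_from_records <- function(tab, radii = NULL, element = NULL) {
  n <- nrow(tab)
  key <- paste(tab$resid, tab$resname)
  new_mol <- c(TRUE, key[-1L] != key[-n])
  molecule_id <- cumsum(new_mol)
  if (is.null(element) || !any(nzchar(element))) {
    element <- .element_from_name(tab$atomname)
  } else {
    element <- ifelse(nzchar(element), element, .element_from_name(tab$atomname))
  }
  vdw <- .element_radius(element)
  if (!is.null(radii)) {
    ov <- radii[.element_key(element)]
    vdw <- ifelse(is.na(ov), vdw, unname(ov))
  }
  data.frame(
    element = element,
    mass = .element_mass(element),
    vdw_radius = vdw,
    molecule_id = molecule_id,
    molecule_type = tab$resname,
    role = .infer_role(tab$resname),
    atom_name = tab$atomname,
    stringsAsFactors = FALSE
  )
}

## Element from an atom name: strip digits, try a two-letter symbol first
## (Cl, Br, Na, ...), else the first letter.
.element_from_name <- function(atomname) {
  core <- toupper(gsub("[^A-Za-z]", "", atomname))
  two <- substr(core, 1L, 2L)
  one <- substr(core, 1L, 1L)
  known2 <- c("CL", "BR", "NA", "MG", "CA", "FE", "ZN")
  ifelse(two %in% known2, two, one)
}

## Angstrom-leak tripwire: all in-memory coordinates are nm.
.assert_nm_scale <- function(ensemble, path) {
  mx <- max(vapply(ensemble$coords, function(m) max(abs(m)), numeric(1)))
  if (mx > 1e3) {
    .stopf("suspiciously large coordinates (%.3g nm) after reading %s: Angstrom leak?",
           mx, path)
  }
  invisible(TRUE)
}

#' Read a radii override table
#'
#' Two-column whitespace/TSV text: element symbol, van der Waals radius in
#' nm.  Lines starting with `#` are comments.
#'
#' @param path file path.
#' @return named numeric vector keyed like the built-in Bondi table.
#' @export
read_radii_table <- function(path) {
  tab <- utils::read.table(path, comment.char = "#", header = FALSE,
                           col.names = c("element", "radius"),
                           stringsAsFactors = FALSE)
  if (any(tab$radius <= 0)) .stopf("radii must be > 0 in %s", path)
  stats::setNames(tab$radius, .element_key(tab$element))
}
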