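#' Build a molecular topology
#'
#' A topology is the static description of a system: one row per atom plus a
#' derived residue table. It underlies every selection, metric and network in
#' the package. Coordinates live separately in frames / trajectories.
#'
#' @param atoms A data frame with columns `id` (unique integer), `name`
#'   (atom name, e.g. `"CA"`), `element` (element symbol), `resid` (1-based
#'   residue sequence number), and optionally `resname`, `chain`, `mass`
#'   (amu, > 0) and `radius` (Angstrom). Missing masses are filled from the
#'   element; missing radii default to `NA`.
#' @return An object of class `topology` with tibbles `atoms` and `residues`.
#' @export
#' @examples
#' top <- topology(data.frame(
#'   id = 1:3, name = c("CA", "CA", "CA"), element = "C", resid = 1:3
#' ))
#' top
topology <- function(atoms) {
  atoms <- as_tibble(atoms)
  required <- c("id", "name", "element", "resid")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0) {
    stop_usage(paste0("`atoms` is missing column(s): ",
                      paste(missing_cols, collapse = ", ")))
  }
  if (nrow(atoms) == 0) stop_usage("`atoms` must contain at least one atom.")
  if (anyDuplicated(atoms$id)) stop_topology("atom ids must be unique.")
  if (!"resname" %in% names(atoms)) atoms$resname <- "RES"
  if (!"chain" %in% names(atoms)) atoms$chain <- "A"
  atoms$chain[is.na(atoms$chain)] <- "A"
  if (!"mass" %in% names(atoms)) atoms$mass <- element_mass(atoms$element)
  atoms$mass[is.na(atoms$mass)] <- element_mass(atoms$element[is.na(atoms$mass)])
  if (any(atoms$mass <= 0)) stop_topology("atom masses must be > 0.")
  if (!"radius" %in% names(atoms)) atoms$radius <- NA_real_
  atoms <- atoms[, c("id", "name", "element", "resid", "resname", "chain",
                     "mass", "radius")]
  residues <- distinct(atoms[, c("resid", "resname", "chain")])
  if (anyDuplicated(residues$resid)) {
    stop_topology("a residue index maps to more than one residue name/chain.")
  }
  structure(list(atoms = atoms, residues = arrange(residues, .data$resid)),
            class = "topology")
}

#' @export
print.topology <- function(x, ...) {
  cat(sprintf("<topology> %d atoms, %d residues, %d chain(s)\n",
              nrow(x$atoms), nrow(x$residues), length(unique(x$atoms$chain))))
  invisible(x)
}

#' Number of atoms in a topology or trajectory
#' @param x A `topology` or `trajectory`.
#' @return Integer atom count.
#' @export
n_atoms <- function(x) {
  if (inherits(x, "trajectory")) x <- x$topology
  nrow(x$atoms)
}

#' Assemble a trajectory from a topology and coordinate frames
#'
#' @param topology A [topology()].
#' @param coords Either a single n_atoms x 3 matrix, a list of such matrices,
#'   or an array with dim `c(n_atoms, 3, n_frames)`. Units: Angstrom.
#' @param time_step_ps Time between saved frames in picoseconds (metadata).
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(topology, coords, time_step_ps = 20) {
  stopifnot(inherits(topology, "topology"))
  na <- nrow(topology$atoms)
  if (is.list(coords) && !is.array(coords)) {
    coords <- array(unlist(coords), dim = c(nrow(coords[[1]]), 3, length(coords)))
  } else if (is.matrix(coords)) {
    coords <- array(coords, dim = c(nrow(coords), 3, 1))
  }
  if (!is.array(coords) || length(dim(coords)) != 3 || dim(coords)[2] != 3) {
    stop_usage("`coords` must be an n_atoms x 3 x n_frames array (or matrix/list).")
  }
  if (dim(coords)[1] != na) {
    stop_topology(sprintf("coordinate atom count (%d) does not match topology (%d).",
                          dim(coords)[1], na))
  }
  if (dim(coords)[3] < 1) stop_usage("a trajectory needs at least one frame.")
  if (!all(is.finite(coords))) stop_data("all coordinates must be finite.")
  structure(list(topology = topology, coords = coords,
                 time_step_ps = time_step_ps),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d atoms x %d frames (%g ps/frame)\n",
              dim(x$coords)[1], dim(x$coords)[3], x$time_step_ps))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param trj A `trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(trj) {
  stopifnot(inherits(trj, "trajectory"))
  dim(trj$coords)[3]
}

#' Extract one frame as an n_atoms x 3 coordinate matrix
#' @param trj A `trajectory`.
#' @param i Frame index (1-based).
#' @return Numeric matrix with columns x, y, z (Angstrom).
#' @export
get_frame <- function(trj, i) {
  stopifnot(inherits(trj, "trajectory"))
  if (i < 1 || i > n_frames(trj)) stop_usage("frame index out of range.")
  m <- trj$coords[, , i, drop = TRUE]
  if (is.null(dim(m))) m <- matrix(m, ncol = 3)  # single-atom systems
  m
}

# PDB I/O ---------------------------------------------------------------------

#' Read a PDB file into a topology plus coordinate frames
#'
#' Multi-model files (MODEL/ENDMDL records) become one frame per model; all
#' models must contain the same atoms. Residue indices are taken verbatim from
#' the PDB residue sequence numbers. The first alternate location is kept;
#' insertion codes are rejected.
#'
#' @param path Path to a PDB file.
#' @param time_step_ps Frame spacing metadata for the returned trajectory.
#' @return A `trajectory` (with a one-frame trajectory for single-model files).
#' @export
read_pdb <- function(path, time_step_ps = 20) {
  if (!file.exists(path)) stop_usage(sprintf("file not found: %s", path))
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
    error = function(e) stop_format(sprintf("PDB parse failure in '%s': %s",
                                            path, conditionMessage(e)))
  )
  at <- pdb$atom
  if (nrow(at) == 0) stop_usage(sprintf("no atoms in PDB file '%s'.", path))
  xyz_cols <- if (is.null(dim(pdb$xyz))) length(pdb$xyz) else ncol(pdb$xyz)
  if (xyz_cols != 3 * nrow(at)) {
    stop_format("MODEL records disagree on the atom count.")
  }
  if (any(!is.na(at$insert) & at$insert != "")) {
    bad <- which(!is.na(at$insert) & at$insert != "")[1]
    stop_format(sprintf("insertion codes are not supported (atom record %d).", bad))
  }
  keep <- rep(TRUE, nrow(at))
  if (any(!is.na(at$alt) & at$alt != "")) {
    first_alt <- at$alt[!is.na(at$alt) & at$alt != ""][1]
    keep <- is.na(at$alt) | at$alt == "" | at$alt == first_alt
  }
  at <- at[keep, , drop = FALSE]
  el <- at$elesy
  if (is.null(el) || all(is.na(el)) || all(el == "")) {
    el <- substr(trimws(at$elety), 1, 1)
  }
  el[is.na(el) | el == ""] <- substr(trimws(at$elety[is.na(el) | el == ""]), 1, 1)
  top <- topology(tibble(
    id = at$eleno, name = trimws(at$elety), element = trimws(el),
    resid = at$resno, resname = trimws(at$resid),
    chain = ifelse(is.na(at$chain) | at$chain == "", "A", at$chain)
  ))
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  xyz <- xyz[, as.vector(rbind(keep, keep, keep)), drop = FALSE]
  if (ncol(xyz) != 3 * nrow(at)) {
    stop_format("MODEL records disagree on the atom count.")
  }
  coords <- xyz_to_array(xyz)
  trajectory(top, coords, time_step_ps = time_step_ps)
}

# bio3d xyz row (x1,y1,z1,x2,...) -> n_atoms x 3 x n_frames array
xyz_to_array <- function(xyz) {
  nf <- nrow(xyz)
  na <- ncol(xyz) / 3L
  out <- array(NA_real_, dim = c(na, 3, nf))
  for (f in seq_len(nf)) {
    out[, , f] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  }
  out
}

array_to_xyz <- function(coords) {
  nf <- dim(coords)[3]
  na <- dim(coords)[1]
  xyz <- matrix(NA_real_, nrow = nf, ncol = 3 * na)
  for (f in seq_len(nf)) {
    xyz[f, ] <- as.vector(t(coords[, , f]))
  }
  xyz
}

#' Read a binary DCD trajectory against a known topology
#'
#' @param path Path to a CHARMM-style binary DCD file.
#' @param topology The [topology()] the coordinates belong to; the atom count
#'   must match the file.
#' @param time_step_ps Frame spacing metadata.
#' @return A `trajectory`.
#' @export
read_dcd <- function(path, topology, time_step_ps = 20) {
  stopifnot(inherits(topology, "topology"))
  if (!file.exists(path)) stop_usage(sprintf("file not found: %s", path))
  if (file.size(path) < 100) stop_format(sprintf("'%s' is empty or truncated.", path))
  xyz <- tryCatch(
    suppressWarnings(bio3d::read.dcd(path, verbose = FALSE)),
    error = function(e) stop_format(sprintf("DCD parse failure in '%s': %s",
                                            path, conditionMessage(e)))
  )
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  if (ncol(xyz) != 3 * nrow(topology$atoms)) {
    stop_topology(sprintf(
      "DCD atom count (%d) does not match topology (%d).",
      ncol(xyz) / 3, nrow(topology$atoms)))
  }
  trajectory(topology, xyz_to_array(xyz), time_step_ps = time_step_ps)
}

#' Write a trajectory to disk
#'
#' Supported formats are CHARMM-style binary DCD and (multi-model) PDB; both
#' round-trip through [read_dcd()] / [read_pdb()].
#'
#' @param trj A `trajectory`.
#' @param path Output path.
#' @param format `"dcd"` or `"pdb"`.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trj, path, format = c("dcd", "pdb")) {
  stopifnot(inherits(trj, "trajectory"))
  if (length(format) == 1 && !tolower(format) %in% c("dcd", "pdb")) {
    stop_usage(sprintf("unsupported trajectory format '%s' (use dcd or pdb).",
                       format))
  }
  format <- match.arg(tolower(format), c("dcd", "pdb"))
  if (format == "dcd") write_dcd_file(trj, path) else write_pdb_file(trj, path)
  invisible(path)
}

# CHARMM DCD layout: [84]["CORD" + 20 ints][84] [title][natom] [x][y][z] blocks,
# each Fortran record bracketed by its byte length.
write_dcd_file <- function(trj, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  nf <- n_frames(trj)
  na <- n_atoms(trj)
  icntrl <- integer(20)
  icntrl[1] <- nf      # NSET
  icntrl[2] <- 1       # ISTART
  icntrl[3] <- 1       # NSAVC
  icntrl[4] <- nf      # NSTEP
  icntrl[8] <- 3 * na  # NDEGF
  icntrl[10] <- readBin(writeBin(as.numeric(1), raw(), size = 4), "integer", 1)
  icntrl[20] <- 24     # CHARMM version flag
  writeBin(84L, con, size = 4)
  writeChar("CORD", con, nchars = 4, eos = NULL)
  writeBin(as.integer(icntrl), con, size = 4)
  writeBin(84L, con, size = 4)
  title <- formatC("generated by allostera", width = 80, flag = "-")
  writeBin(as.integer(4 + 80), con, size = 4)
  writeBin(1L, con, size = 4)
  writeChar(title, con, nchars = 80, eos = NULL)
  writeBin(as.integer(4 + 80), con, size = 4)
  writeBin(4L, con, size = 4)
  writeBin(as.integer(na), con, size = 4)
  writeBin(4L, con, size = 4)
  nb <- as.integer(4 * na)
  for (f in seq_len(nf)) {
    fr <- get_frame(trj, f)
    for (d in 1:3) {
      writeBin(nb, con, size = 4)
      writeBin(as.numeric(fr[, d]), con, size = 4)
      writeBin(nb, con, size = 4)
    }
  }
  invisible(path)
}

write_pdb_file <- function(trj, path) {
  at <- trj$topology$atoms
  nf <- n_frames(trj)
  lines <- character(0)
  fmt_atom <- function(fr) {
    nm <- at$name
    # standard PDB alignment: 1-3 char names start in column 14
    nm <- ifelse(nchar(nm) < 4, paste0(" ", nm), nm)
    sprintf("ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            at$id, nm, substr(at$resname, 1, 3), at$chain, at$resid,
            fr[, 1], fr[, 2], fr[, 3], 1.00, 0.00, at$element)
  }
  for (f in seq_len(nf)) {
    if (nf > 1) lines <- c(lines, sprintf("MODEL     %4d", f))
    lines <- c(lines, fmt_atom(get_frame(trj, f)))
    if (nf > 1) lines <- c(lines, "ENDMDL")
  }
  lines <- c(lines, "END")
  writeLines(lines, path)
  invisible(path)
}
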