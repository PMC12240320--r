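#' @keywords internal
"_PACKAGE"

## Atom bookkeeping -----------------------------------------------------------

# Canonical atom key used to match atoms across models and to address atoms in
# distance-series groups: "chain:resseq[icode]:name".
atom_keys <- function(top) {
  paste0(top$chain, ":", top$resseq, trimws(top$icode), ":", top$name)
}

# Residue key "chain:resseq[icode]"
residue_keys <- function(top) {
  paste0(top$chain, ":", top$resseq, trimws(top$icode))
}

BACKBONE_ATOMS <- c("N", "CA", "C", "O")

#' Construct a trajectory object
#'
#' A trajectory is a fixed atom topology shared by an ordered series of
#' coordinate snapshots. Coordinates are stored as an `n_frames x 3N` matrix
#' (columns grouped x,y,z per atom, in topology order), in Angstrom.
#'
#' @param topology data frame with columns `serial`, `name`, `resname`,
#'   `chain`, `resseq`, `icode`, `element` describing the atoms of one model.
#' @param xyz numeric matrix, one row per snapshot, `3 * nrow(topology)`
#'   columns.
#' @param dt_ns time between consecutive snapshots, nanoseconds.
#' @param t0_ns time of the first snapshot, nanoseconds.
#' @param label free-text description.
#' @return An object of class `"trajectory"`.
#' @export
trajectory <- function(topology, xyz, dt_ns = 1, t0_ns = 0, label = "") {
  xyz <- as.matrix(xyz)
  if (!is.numeric(dt_ns) || length(dt_ns) != 1L || dt_ns <= 0)
    stop("dt_ns must be a single positive number", call. = FALSE)
  if (nrow(topology) == 0L)
    stop("topology has no atoms", call. = FALSE)
  if (ncol(xyz) != 3L * nrow(topology))
    stop(sprintf("xyz has %d columns; expected %d (3 per topology atom)",
                 ncol(xyz), 3L * nrow(topology)), call. = FALSE)
  if (nrow(xyz) < 1L)
    stop("trajectory needs at least one snapshot", call. = FALSE)
  if (any(!is.finite(xyz)))
    stop("non-finite coordinates in trajectory", call. = FALSE)
  keys <- atom_keys(topology)
  if (anyDuplicated(keys))
    stop("duplicate atom keys in topology: ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "), call. = FALSE)
  structure(list(topology = topology, xyz = xyz,
                 dt_ns = dt_ns, t0_ns = t0_ns, label = label),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d snapshots x %d atoms, dt = %g ns (t = %g..%g ns)\n",
              nrow(x$xyz), nrow(x$topology), x$dt_ns,
              x$t0_ns, x$t0_ns + (nrow(x$xyz) - 1L) * x$dt_ns))
  ch <- table(x$topology$chain[!duplicated(residue_keys(x$topology))])
  cat("  chains:", paste(sprintf("%s (%d res)", names(ch), ch), collapse = ", "), "\n")
  if (nzchar(x$label)) cat(" ", x$label, "\n")
  invisible(x)
}

#' Number of snapshots in a trajectory
#' @param traj a [trajectory()] object.
#' @return Integer snapshot count.
#' @export
n_frames <- function(traj) nrow(traj$xyz)

#' Snapshot times of a trajectory
#' @param traj a [trajectory()] object.
#' @return Numeric vector of snapshot times in ns.
#' @export
frame_times <- function(traj) traj$t0_ns + (seq_len(nrow(traj$xyz)) - 1L) * traj$dt_ns

#' Extract one snapshot as a structure
#'
#' @param traj a [trajectory()] object.
#' @param i snapshot index (1-based).
#' @return An object of class `"structure"`: the topology data frame with
#'   `x`, `y`, `z` coordinate columns filled in.
#' @export
get_frame <- function(traj, i) {
  if (i < 1L || i > nrow(traj$xyz))
    stop(sprintf("frame index %d out of range 1..%d", i, nrow(traj$xyz)),
         call. = FALSE)
  as_structure(traj$topology, frame_coords(traj$xyz, i),
               label = sprintf("%s frame %d", traj$label, i))
}

# xyz row i as an natoms x 3 matrix
frame_coords <- function(xyz, i) matrix(xyz[i, ], ncol = 3L, byrow = TRUE)

# natoms x 3 matrix back to a flat xyz row
flat_coords <- function(m) as.numeric(t(m))

#' Build a structure from an atom table and coordinates
#'
#' @param atoms data frame with at least `name`, `resname`, `chain`, `resseq`
#'   columns; `serial`, `icode`, `element` are filled with defaults when
#'   absent.
#' @param coord optional `natoms x 3` coordinate matrix; alternatively `atoms`
#'   may carry `x`, `y`, `z` columns.
#' @param label free text.
#' @return Object of class `"structure"`.
#' @export
as_structure <- function(atoms, coord = NULL, label = "") {
  atoms <- as.data.frame(atoms)
  if (nrow(atoms) == 0L) stop("structure has no atoms", call. = FALSE)
  if (is.null(atoms$serial)) atoms$serial <- seq_len(nrow(atoms))
  if (is.null(atoms$icode)) atoms$icode <- ""
  if (is.null(atoms$element)) atoms$element <- guess_element(atoms$name)
  if (!is.null(coord)) {
    coord <- as.matrix(coord)
    stopifnot(nrow(coord) == nrow(atoms), ncol(coord) == 3L)
    atoms$x <- coord[, 1]; atoms$y <- coord[, 2]; atoms$z <- coord[, 3]
  }
  if (is.null(atoms$x) || is.null(atoms$y) || is.null(atoms$z))
    stop("no coordinates supplied", call. = FALSE)
  if (any(!is.finite(c(atoms$x, atoms$y, atoms$z))))
    stop("non-finite coordinates", call. = FALSE)
  attr(atoms, "label") <- label
  class(atoms) <- c("structure", "data.frame")
  atoms
}

#' @export
print.structure <- function(x, ...) {
  cat(sprintf("<structure> %d atoms, %d residues, chains: %s\n",
              nrow(x), length(unique(residue_keys(x))),
              paste(unique(x$chain), collapse = ", ")))
  invisible(x)
}

# coordinates of a structure as natoms x 3 matrix
struct_coords <- function(s) cbind(s$x, s$y, s$z)

# crude element guess from PDB atom name (first alphabetic character after
# stripping digits; good enough for protein heavy atoms and hydrogens)
guess_element <- function(name) {
  nm <- gsub("[0-9']", "", trimws(name))
  ifelse(substr(nm, 1, 1) %in% c("H", "D"), "H", substr(nm, 1, 1))
}

## PDB reading ----------------------------------------------------------------

parse_pdb_num <- function(field, lineno, what) {
  v <- suppressWarnings(as.numeric(field))
  bad <- is.na(v) & nzchar(trimws(field))
  bad <- bad | is.na(v)
  if (any(bad))
    stop(sprintf("malformed %s field at line %d: '%s'",
                 what, lineno[which(bad)[1]], field[which(bad)[1]]),
         call. = FALSE)
  v
}

#' Read a multi-model PDB file as a trajectory
#'
#' Each `MODEL`/`ENDMDL` block becomes one snapshot; a file without `MODEL`
#' records is read as a single-snapshot trajectory. The first model defines
#' the topology; atoms of later models are matched to it by
#' (chain, resseq, icode, name), so atom order may differ between models but
#' the atom set may not. Alternate locations other than blank or "A" are
#' dropped. `HETATM` records and waters are skipped unless requested.
#'
#' @param file path to a PDB file, or a character vector of PDB lines.
#' @param dt_ns time between models, ns. PDB files carry no time information,
#'   so this must be supplied; defaults to 1.
#' @param t0_ns time of the first model, ns.
#' @param include_hetatm also keep `HETATM` records (waters are still
#'   skipped).
#' @return A [trajectory()].
#' @export
read_pdb <- function(file, dt_ns = 1, t0_ns = 0, include_hetatm = FALSE) {
  lines <- if (length(file) == 1L && !grepl("\n", file) && file.exists(file))
    readLines(file) else unlist(strsplit(file, "\n", fixed = TRUE))
  rec <- substr(lines, 1, 6)
  is_atom <- rec == "ATOM  " | (include_hetatm & rec == "HETATM")
  model_id <- cumsum(rec == "MODEL ")
  if (max(model_id) == 0L) model_id <- model_id + 1L  # implicit single model
  keep <- which(is_atom & model_id >= 1L)
  if (length(keep) == 0L) stop("no ATOM records found", call. = FALSE)

  ln <- lines[keep]
  lineno <- keep
  altloc <- substr(ln, 17, 17)
  ok_alt <- altloc %in% c(" ", "A")
  resname <- trimws(substr(ln, 18, 20))
  not_water <- !(resname %in% c("HOH", "WAT", "TIP3", "SOL"))
  sel <- ok_alt & not_water
  ln <- ln[sel]; lineno <- lineno[sel]
  atoms <- data.frame(
    serial  = suppressWarnings(as.integer(substr(ln, 7, 11))),
    name    = trimws(substr(ln, 13, 16)),
    resname = trimws(substr(ln, 18, 20)),
    chain   = substr(ln, 22, 22),
    resseq  = as.integer(parse_pdb_num(substr(ln, 23, 26), lineno, "residue number")),
    icode   = trimws(substr(ln, 27, 27)),
    x = parse_pdb_num(substr(ln, 31, 38), lineno, "coordinate"),
    y = parse_pdb_num(substr(ln, 39, 46), lineno, "coordinate"),
    z = parse_pdb_num(substr(ln, 47, 54), lineno, "coordinate"),
    element = trimws(substr(ln, 77, 78)),
    stringsAsFactors = FALSE)
  atoms$element[!nzchar(atoms$element)] <- guess_element(atoms$name[!nzchar(atoms$element)])
  model <- model_id[lineno]
  model <- match(model, sort(unique(model)))  # densify to 1..n

  first <- atoms[model == 1L, ]
  top <- first[c("serial", "name", "resname", "chain", "resseq", "icode", "element")]
  ref_keys <- atom_keys(top)
  if (anyDuplicated(ref_keys))
    stop("duplicate atoms in model 1: ",
         paste(unique(ref_keys[duplicated(ref_keys)]), collapse = ", "),
         call. = FALSE)

  n_models <- max(model)
  xyz <- matrix(NA_real_, n_models, 3L * nrow(top))
  for (m in seq_len(n_models)) {
    am <- atoms[model == m, ]
    km <- atom_keys(am)
    missing <- setdiff(ref_keys, km)
    extra <- setdiff(km, ref_keys)
    if (length(missing) || length(extra))
      stop(sprintf("topology mismatch in model %d:%s%s", m,
                   if (length(missing)) paste0(" missing [", paste(missing, collapse = ", "), "]") else "",
                   if (length(extra)) paste0(" extra [", paste(extra, collapse = ", "), "]") else ""),
           call. = FALSE)
    ord <- match(ref_keys, km)
    xyz[m, ] <- flat_coords(cbind(am$x, am$y, am$z)[ord, , drop = FALSE])
  }
  trajectory(top, xyz, dt_ns = dt_ns, t0_ns = t0_ns,
             label = if (file.exists(file[1])) basename(file[1]) else "")
}

## PDB writing ----------------------------------------------------------------

#' Write a trajectory as a multi-model PDB file
#'
#' One `MODEL`/`ENDMDL` block per snapshot, fixed columns per PDB v3.3,
#' coordinates to three decimals.
#'
#' @param traj a [trajectory()] or a single [as_structure()] snapshot.
#' @param file output path or connection.
#' @return Invisibly, the path written.
#' @export
write_pdb <- function(traj, file) {
  if (inherits(traj, "structure"))
    traj <- trajectory(traj[setdiff(names(traj), c("x", "y", "z"))],
                       matrix(flat_coords(struct_coords(traj)), 1))
  if (max(abs(traj$xyz)) >= 10000)
    stop("coordinate magnitude >= 10000 A cannot be formatted in PDB fixed columns",
         call. = FALSE)
  top <- traj$topology
  # PDB v3.3 atom-name justification: names shorter than 4 chars start in
  # column 14 for 1-letter elements
  nm <- ifelse(nchar(top$name) >= 4L, top$name,
               ifelse(nchar(top$element) == 1L,
                      sprintf(" %-3s", top$name), sprintf("%-4s", top$name)))
  out <- character(0)
  nfr <- nrow(traj$xyz)
  for (m in seq_len(nfr)) {
    co <- frame_coords(traj$xyz, m)
    recs <- sprintf("ATOM  %5d %-4s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                    top$serial %% 100000L, nm, top$resname, top$chain,
                    top$resseq, ifelse(nzchar(top$icode), top$icode, " "),
                    co[, 1], co[, 2], co[, 3], 1, 0, top$element)
    if (nfr > 1L) out <- c(out, sprintf("MODEL %8d", m), recs, "ENDMDL")
    else out <- c(out, "MODEL        1", recs, "ENDMDL")
  }
  writeLines(c(out, "END"), file)
  invisible(file)
}

## Selections -----------------------------------------------------------------

#' Define an atom selection
#'
#' A selection restricts analyses to chains, residue ranges, and an atom
#' class. Resolving it against a structure or topology yields a deterministic
#' ordered index vector.
#'
#' @param chains optional character vector of chain ids.
#' @param resseq_range optional inclusive `c(start, end)` residue-number
#'   range (applied within the selected chains).
#' @param atom_class one of `"all"`, `"heavy"`, `"backbone"` (N, CA, C, O) or
#'   `"calpha"`.
#' @return Object of class `"atom_select"`.
#' @export
atom_select <- function(chains = NULL, resseq_range = NULL,
                        atom_class = c("all", "heavy", "backbone", "calpha")) {
  atom_class <- match.arg(atom_class)
  if (!is.null(resseq_range) && (length(resseq_range) != 2L ||
                                 resseq_range[1] > resseq_range[2]))
    stop("resseq_range must be c(start, end) with start <= end", call. = FALSE)
  structure(list(chains = chains, resseq_range = resseq_range,
                 atom_class = atom_class), class = "atom_select")
}

#' Resolve a selection to atom indices
#'
#' @param x a topology data frame, [as_structure()] or [trajectory()].
#' @param sel an [atom_select()]; a bare atom-class string is also accepted.
#' @return Ordered integer indices into the topology. An empty result is an
#'   error: silently analysing nothing is never acceptable.
#' @export
resolve_selection <- function(x, sel = atom_select()) {
  top <- if (inherits(x, "trajectory")) x$topology else x
  if (is.character(sel)) sel <- atom_select(atom_class = sel)
  keep <- rep(TRUE, nrow(top))
  if (!is.null(sel$chains)) {
    unknown <- setdiff(sel$chains, unique(top$chain))
    if (length(unknown))
      stop("unknown chain id(s): ", paste(unknown, collapse = ", "), call. = FALSE)
    keep <- keep & top$chain %in% sel$chains
  }
  if (!is.null(sel$resseq_range))
    keep <- keep & top$resseq >= sel$resseq_range[1] & top$resseq <= sel$resseq_range[2]
  keep <- keep & switch(sel$atom_class,
    all      = TRUE,
    heavy    = top$element != "H",
    backbone = trimws(top$name) %in% BACKBONE_ATOMS,
    calpha   = trimws(top$name) == "CA")
  idx <- which(keep)
  if (length(idx) == 0L)
    stop("selection resolves to zero atoms", call. = FALSE)
  idx
}

# column indices into the flat xyz matrix for a set of atom indices
xyz_cols <- function(atom_idx) {
  as.vector(rbind(3L * atom_idx - 2L, 3L * atom_idx - 1L, 3L * atom_idx))
}
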