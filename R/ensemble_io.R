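#' Read a conformational ensemble from standard structure formats
#'
#' Reads a multi-model PDB file (NMR ensemble or concatenated models), a set
#' of single-model PDB files of the same molecule (e.g. related x-ray
#' structures), a DCD trajectory plus a PDB topology, or a multi-frame XYZ
#' file, and returns the selected atoms as a [conf_ensemble()].
#'
#' Coordinates are converted to nanometres (PDB/DCD/XYZ files carry
#' angstroms). No superposition or fitting is performed at any point: the
#' downstream analysis uses internal coordinates (pairwise distances) only
#' and is independent of a reference structure.
#'
#' When several PDB files are given, atoms are matched across structures by
#' the key (chain, residue number, atom name). Structures whose atom sets
#' differ are rejected with a report listing the unmatched atoms, so that
#' the user can clean up heterogeneous crystal structures explicitly rather
#' than having atoms dropped silently.
#'
#' @param path path to a multi-model PDB, DCD or XYZ file, or a character
#'   vector of several single-model PDB paths.
#' @param topology path to a PDB file providing atom naming for a DCD
#'   trajectory; required for DCD, ignored otherwise.
#' @param selection atom selection: one of the bio3d selection strings
#'   (`"calpha"`, `"backbone"`, `"protein"`, `"noh"`, `"all"`, ...). The
#'   default `"calpha"` is the usual reduced representation for large
#'   systems; use `"all"` for small peptides where every solute atom is of
#'   interest. XYZ input carries no atom metadata and supports `"all"` only.
#' @return a [conf_ensemble()]
#' @seealso [deviation_matrix()], [write_domain_pdb()]
#' @export
read_ensemble <- function(path, topology = NULL, selection = "calpha") {
  if (length(path) > 1L)
    return(read_pdb_set(path, selection))
  if (!file.exists(path)) stop("input file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    pdb = , ent = , pdbqt = read_pdb_ensemble(path, selection),
    dcd = read_dcd_ensemble(path, topology, selection),
    xyz = read_xyz_ensemble(path, selection),
    xtc = stop("XTC trajectories are not supported; convert to DCD ",
               "(e.g. with 'mdconvert') or provide a multi-model PDB"),
    stop("unrecognized ensemble format: .", ext,
         " (supported: multi-model PDB, DCD + PDB topology, multi-frame XYZ)")
  )
}

normalize_selection <- function(selection) {
  sel <- tolower(selection)
  if (sel %in% c("ca", "c-alpha", "c.alpha")) sel <- "calpha"
  if (sel == "back") sel <- "backbone"
  sel
}

select_atoms <- function(pdb, selection) {
  sel <- normalize_selection(selection)
  idx <- bio3d::atom.select(pdb, string = sel, verbose = FALSE)
  if (length(idx$atom) == 0L)
    stop("atom selection '", selection, "' matches zero atoms")
  idx
}

atoms_table <- function(pdb, atom_idx) {
  at <- pdb$atom[atom_idx, c("chain", "resno", "resid", "elety")]
  at$chain[is.na(at$chain)] <- "A"
  rownames(at) <- NULL
  at
}

read_pdb_ensemble <- function(path, selection) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1L)
  if (nrow(xyz) < 2L)
    stop("ensemble must contain >= 2 conformations, found ", nrow(xyz),
         " model(s) in ", path)
  idx <- select_atoms(pdb, selection)
  conf_ensemble(xyz[, idx$xyz, drop = FALSE] / 10, atoms_table(pdb, idx$atom))
}

read_dcd_ensemble <- function(path, topology, selection) {
  if (is.null(topology))
    stop("a DCD trajectory requires a PDB topology file (topology = ...)")
  if (!file.exists(topology)) stop("topology file not found: ", topology)
  pdb <- bio3d::read.pdb(topology, verbose = FALSE)
  traj <- bio3d::read.dcd(path, verbose = FALSE)
  if (ncol(traj) != length(pdb$xyz))
    stop("trajectory has ", ncol(traj) / 3, " atoms but topology has ",
         length(pdb$xyz) / 3)
  if (nrow(traj) < 2L)
    stop("ensemble must contain >= 2 conformations, found ", nrow(traj),
         " frame(s) in ", path)
  idx <- select_atoms(pdb, selection)
  conf_ensemble(traj[, idx$xyz, drop = FALSE] / 10, atoms_table(pdb, idx$atom))
}

# several single-model PDBs of the same molecule (e.g. x-ray structures);
# atoms matched by (chain, resno, elety), mismatches rejected with a report
read_pdb_set <- function(paths, selection) {
  missing <- paths[!file.exists(paths)]
  if (length(missing)) stop("input file not found: ", missing[1])
  frames <- lapply(paths, function(p) {
    pdb <- bio3d::read.pdb(p, multi = FALSE, verbose = FALSE)
    idx <- select_atoms(pdb, selection)
    at <- atoms_table(pdb, idx$atom)
    key <- paste(at$chain, at$resno, at$elety, sep = "/")
    if (anyDuplicated(key))
      stop("duplicate atoms (altloc?) in ", p, ": ",
           paste(utils::head(key[duplicated(key)], 5L), collapse = ", "))
    list(at = at, key = key,
         xyz = matrix(pdb$xyz[idx$xyz], ncol = 3L, byrow = TRUE))
  })
  ref <- frames[[1]]
  for (i in seq_along(frames)[-1]) {
    extra <- setdiff(frames[[i]]$key, ref$key)
    absent <- setdiff(ref$key, frames[[i]]$key)
    if (length(extra) || length(absent))
      stop("atom sets differ between ", paths[1], " and ", paths[i],
           if (length(extra)) paste0("; only in ", paths[i], ": ",
                                     paste(extra, collapse = ", ")) else "",
           if (length(absent)) paste0("; only in ", paths[1], ": ",
                                      paste(absent, collapse = ", ")) else "",
           ". Clean up the structure files so all share one atom set.")
  }
  n <- length(ref$key)
  coords <- array(NA_real_, dim = c(length(frames), n, 3L))
  for (i in seq_along(frames)) {
    ord <- match(ref$key, frames[[i]]$key)
    coords[i, , ] <- frames[[i]]$xyz[ord, , drop = FALSE]
  }
  conf_ensemble(coords / 10, ref$at)
}

# multi-frame XYZ: repeated blocks of "natoms \n comment \n  name x y z ..."
read_xyz_ensemble <- function(path, selection = "all") {
  if (normalize_selection(selection) != "all")
    stop("XYZ files carry no atom metadata; only selection = \"all\" is supported")
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty XYZ file: ", path)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 1L) stop("malformed XYZ header in ", path)
  block <- n + 2L
  if (length(lines) %% block != 0L)
    stop("XYZ file length is not a multiple of the frame block size; ",
         "atom counts may differ across frames")
  n_frames <- length(lines) %/% block
  if (n_frames < 2L)
    stop("ensemble must contain >= 2 conformations, found ", n_frames,
         " frame(s) in ", path)
  coords <- array(NA_real_, dim = c(n_frames, n, 3L))
  names1 <- NULL
  for (f in seq_len(n_frames)) {
    off <- (f - 1L) * block
    nf <- as.integer(trimws(lines[off + 1L]))
    if (is.na(nf) || nf != n)
      stop("atom counts differ across frames in ", path)
    toks <- strsplit(trimws(lines[off + 2L + seq_len(n)]), "[[:space:]]+")
    nm <- vapply(toks, `[`, "", 1L)
    if (f == 1L) names1 <- nm
    else if (!identical(nm, names1))
      stop("atom names differ across frames in ", path)
    xyz <- vapply(toks, function(tk) as.numeric(tk[2:4]), numeric(3L))
    if (!all(is.finite(xyz))) stop("non-numeric coordinates in ", path)
    coords[f, , ] <- t(xyz)
  }
  atoms <- data.frame(chain = "A", resno = seq_len(n), resid = "UNK",
                      elety = names1, stringsAsFactors = FALSE)
  conf_ensemble(coords / 10, atoms)
}

#' Write a domain-annotated PDB file
#'
#' Writes a single-model PDB in which the B-factor column carries the hard
#' domain label of each atom and the occupancy column carries the per-atom
#' flexibility rescaled to \[0, 1\], so that molecular viewers can color the
#' structure by domain or by flexibility directly.
#'
#' @param ensemble a [conf_ensemble()] providing coordinates and atom names
#' @param assignment integer vector of hard domain labels in `1..M`, one per
#'   atom
#' @param flexibility optional numeric vector of per-atom flexibility values
#'   (see [atom_flexibility()]); rescaled to \[0, 1\] for the occupancy
#'   column. Zeros are written when omitted.
#' @param file output path
#' @param frame which frame's coordinates to write (default first)
#' @return invisibly, the output path
#' @export
write_domain_pdb <- function(ensemble, assignment, flexibility = NULL,
                             file, frame = 1L) {
  stopifnot(inherits(ensemble, "conf_ensemble"))
  n <- ensemble$n_atoms
  if (length(assignment) == 0L) stop("empty domain assignment")
  if (length(assignment) != n)
    stop("assignment has length ", length(assignment),
         " but the ensemble has ", n, " atoms")
  assignment <- as.integer(assignment)
  if (anyNA(assignment) || any(assignment < 1L))
    stop("domain labels must be positive integers")
  if (is.null(flexibility)) flexibility <- rep(0, n)
  if (length(flexibility) != n)
    stop("flexibility has length ", length(flexibility), ", expected ", n)
  rng <- range(flexibility)
  occ <- if (diff(rng) > 0) (flexibility - rng[1]) / diff(rng) else rep(0, n)
  xyz <- as.vector(t(ensemble_frame(ensemble, frame))) * 10  # nm -> angstrom
  at <- ensemble$atoms
  bio3d::write.pdb(file = file, xyz = xyz, resno = at$resno, chain = at$chain,
                   resid = at$resid, elety = at$elety, eleno = seq_len(n),
                   o = round(occ, 2), b = assignment)
  invisible(file)
}

#' Write an ensemble as a multi-model PDB file
#'
#' @param ensemble a [conf_ensemble()]
#' @param file output path
#' @return invisibly, the output path
#' @export
write_ensemble_pdb <- function(ensemble, file) {
  stopifnot(inherits(ensemble, "conf_ensemble"))
  at <- ensemble$atoms
  bio3d::write.pdb(file = file, xyz = flatten_coords(ensemble) * 10,
                   resno = at$resno, chain = at$chain, resid = at$resid,
                   elety = at$elety, eleno = seq_len(ensemble$n_atoms))
  invisible(file)
}

#' Write an ensemble as a multi-frame XYZ file
#'
#' Coordinates are written in angstroms, the customary unit of the XYZ
#' format; atom names are taken from the ensemble's atom table.
#'
#' @param ensemble a [conf_ensemble()]
#' @param file output path
#' @return invisibly, the output path
#' @export
write_ensemble_xyz <- function(ensemble, file) {
  stopifnot(inherits(ensemble, "conf_ensemble"))
  n <- ensemble$n_atoms
  nm <- gsub("[[:space:]]+", "", ensemble$atoms$elety)
  nm[!nzchar(nm)] <- "X"
  con <- file(file, "w")
  on.exit(close(con))
  for (f in seq_len(ensemble$n_frames)) {
    writeLines(c(as.character(n), paste("frame", f)), con)
    xyz <- ensemble$coords[f, , , drop = TRUE] * 10
    if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
    writeLines(sprintf("%s %.6f %.6f %.6f", nm, xyz[, 1], xyz[, 2], xyz[, 3]),
               con)
  }
  invisible(file)
}
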