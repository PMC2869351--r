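#' Conformational ensemble container
#'
#' An ordered set of conformations (frames) of the same molecule over a fixed
#' atom list. Coordinates are stored as an `n_frames x n_atoms x 3` numeric
#' array in nanometres; every frame must list the same atoms in the same
#' order. Two or more frames are required before a distance-deviation matrix
#' can be computed, because deviations of a single frame from its own mean
#' are identically zero.
#'
#' @param coords numeric array of dimension `n_frames x n_atoms x 3`
#'   (nanometres), or a matrix of dimension `n_frames x (3 * n_atoms)` with
#'   columns ordered x1,y1,z1,x2,...
#' @param atoms optional `data.frame` with one row per atom and (at least)
#'   columns `chain`, `resno`, `resid`, `elety` (atom name). Generated
#'   placeholders are used when omitted.
#' @return an object of class `conf_ensemble` with elements `coords` (the
#'   3-d array), `atoms`, `n_frames` and `n_atoms`.
#' @examples
#' coords <- array(rnorm(2 * 4 * 3), dim = c(2, 4, 3))
#' ens <- conf_ensemble(coords)
#' ens$n_atoms
#' @export
conf_ensemble <- function(coords, atoms = NULL) {
  if (is.matrix(coords)) {
    if (ncol(coords) %% 3L != 0L)
      stop("flat coordinate matrix must have 3 * n_atoms columns")
    n <- ncol(coords) / 3L
    coords <- aperm(array(t(coords), dim = c(3L, n, nrow(coords))), c(3L, 2L, 1L))
  }
  if (!is.array(coords) || length(dim(coords)) != 3L || dim(coords)[3] != 3L)
    stop("coords must be an n_frames x n_atoms x 3 array")
  if (!all(is.finite(coords)))
    stop("coordinates must be finite")
  n_frames <- dim(coords)[1]
  n_atoms <- dim(coords)[2]
  if (n_atoms < 1L) stop("ensemble has no atoms")
  if (is.null(atoms)) {
    atoms <- data.frame(
      chain = "A", resno = seq_len(n_atoms), resid = "GLY", elety = "CA",
      stringsAsFactors = FALSE
    )
  }
  if (nrow(atoms) != n_atoms)
    stop("atoms table has ", nrow(atoms), " rows but coords describe ",
         n_atoms, " atoms")
  structure(
    list(coords = coords, atoms = atoms, n_frames = n_frames, n_atoms = n_atoms),
    class = "conf_ensemble"
  )
}

#' @export
print.conf_ensemble <- function(x, ...) {
  cat("Conformational ensemble:", x$n_frames, "frames x", x$n_atoms,
      "atoms (coordinates in nm)\n")
  invisible(x)
}

# frames x 3N flat view (x1,y1,z1,x2,...) used by the bio3d writers
flatten_coords <- function(ensemble) {
  co <- ensemble$coords
  matrix(aperm(co, c(3L, 2L, 1L)), nrow = ensemble$n_frames, byrow = TRUE)
}

#' Extract a single frame
#'
#' @param ensemble a [conf_ensemble()]
#' @param frame frame index
#' @return `n_atoms x 3` coordinate matrix (nm)
#' @export
ensemble_frame <- function(ensemble, frame = 1L) {
  stopifnot(inherits(ensemble, "conf_ensemble"))
  if (frame < 1L || frame > ensemble$n_frames)
    stop("frame index out of range")
  ensemble$coords[frame, , , drop = TRUE]
}
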