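#' Distance-deviation matrix of a conformational ensemble
#'
#' Computes the symmetric `N x N` matrix whose entry (i, j) measures how
#' much the Euclidean distance between atoms i and j fluctuates across the
#' ensemble. Within a rigid unit pairwise distances are constant, so the
#' matrix is zero on rigid blocks; atom pairs that belong to units moving
#' relative to each other show large entries. Because only internal
#' distances enter, the matrix is invariant under any per-frame rigid
#' transformation and no superposition of frames is needed.
#'
#' Two conventions are offered for the deviation of the instantaneous
#' distance d_ij(t) from its ensemble mean:
#' \describe{
#'   \item{`absolute`}{mean |d_ij(t) - <d_ij>| over frames, in nm (default);}
#'   \item{`squared`}{mean (d_ij(t) - <d_ij>)^2 over frames, in nm^2 — the
#'     variance of the distance.}
#' }
#' The choice is recorded in the result and propagated to all error
#' measures; in squared mode the normalized clustering error is reported as
#' a root mean square so it stays a length.
#'
#' The computation is two-pass (first pass mean distances, second pass
#' deviations) and streams over frames, so only one frame's pairwise
#' distances are in memory at a time.
#'
#' @param ensemble a [conf_ensemble()] with at least 2 frames
#' @param mode `"absolute"` or `"squared"`
#' @return an `N x N` matrix of class `deviation_matrix` with attributes
#'   `mode` and `units`
#' @examples
#' # two atoms at distance 1 nm then 3 nm: mean 2, deviations both 1
#' co <- array(0, dim = c(2, 2, 3))
#' co[1, 2, 1] <- 1; co[2, 2, 1] <- 3
#' D <- deviation_matrix(conf_ensemble(co))
#' D[1, 2]  # 1 nm
#' @export
deviation_matrix <- function(ensemble, mode = c("absolute", "squared")) {
  mode <- match.arg(mode)
  stopifnot(inherits(ensemble, "conf_ensemble"))
  if (ensemble$n_frames < 2L)
    stop("ensemble must contain >= 2 conformations to measure deviations")
  n <- ensemble$n_atoms
  co <- ensemble$coords
  mean_d <- matrix(0, n, n)
  for (f in seq_len(ensemble$n_frames)) {
    frame <- co[f, , , drop = TRUE]
    if (is.null(dim(frame))) frame <- matrix(frame, nrow = 1L)
    mean_d <- mean_d + as.matrix(stats::dist(frame))
  }
  mean_d <- mean_d / ensemble$n_frames
  dev <- matrix(0, n, n)
  for (f in seq_len(ensemble$n_frames)) {
    frame <- co[f, , , drop = TRUE]
    if (is.null(dim(frame))) frame <- matrix(frame, nrow = 1L)
    delta <- as.matrix(stats::dist(frame)) - mean_d
    dev <- dev + if (mode == "absolute") abs(delta) else delta^2
  }
  dev <- dev / ensemble$n_frames
  dev <- (dev + t(dev)) / 2  # enforce exact symmetry against rounding
  diag(dev) <- 0
  dimnames(dev) <- NULL
  new_deviation_matrix(dev, mode)
}

new_deviation_matrix <- function(values, mode) {
  structure(values,
            deviation_mode = mode,
            units = if (mode == "absolute") "nm" else "nm^2",
            class = c("deviation_matrix", "matrix", "array"))
}

#' Construct a deviation matrix from raw values
#'
#' Wraps an existing symmetric non-negative matrix (e.g. read from a file or
#' built analytically) as a `deviation_matrix`, validating its invariants.
#'
#' @param values symmetric non-negative square matrix with zero diagonal
#' @param mode `"absolute"` (nm) or `"squared"` (nm^2)
#' @return a `deviation_matrix`
#' @export
as_deviation_matrix <- function(values, mode = c("absolute", "squared")) {
  mode <- match.arg(mode)
  values <- unclass(as.matrix(values))
  if (nrow(values) != ncol(values)) stop("deviation matrix must be square")
  if (!all(is.finite(values))) stop("deviation matrix entries must be finite")
  if (max(abs(values - t(values))) > 1e-8)
    stop("deviation matrix must be symmetric")
  if (any(values < -1e-12)) stop("deviation matrix entries must be >= 0")
  if (any(abs(diag(values)) > 1e-12))
    stop("deviation matrix must have a zero diagonal")
  values <- (values + t(values)) / 2
  values[values < 0] <- 0
  diag(values) <- 0
  dimnames(values) <- NULL
  new_deviation_matrix(values, mode)
}

dev_mode <- function(D) {
  m <- attr(D, "deviation_mode")
  if (is.null(m)) "absolute" else m
}

#' @export
print.deviation_matrix <- function(x, ...) {
  cat("Distance-deviation matrix:", nrow(x), "x", ncol(x),
      sprintf("(%s mode, %s)\n", dev_mode(x), attr(x, "units")))
  print(unclass(x)[seq_len(min(6L, nrow(x))), seq_len(min(6L, ncol(x))),
                   drop = FALSE], ...)
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

#' Per-atom flexibility profile
#'
#' The mean row value of the distance-deviation matrix: for atom i, the
#' average deviation of its distances to all other atoms. Peaks mark mobile
#' or destabilized regions; rigid cores score low.
#'
#' @param D a `deviation_matrix`
#' @return numeric vector of length N (row means over the N - 1
#'   off-diagonal entries)
#' @export
atom_flexibility <- function(D) {
  n <- nrow(D)
  if (n < 2L) stop("flexibility profile needs at least 2 atoms")
  rowSums(D) / (n - 1)
}

#' Average the deviation matrix over symmetric copies
#'
#' For a complex built from structurally identical subunits, averaging the
#' intra-subunit blocks of the deviation matrix over the copies improves
#' the statistics of the estimate. Each copy is given as a vector of atom
#' indices listing its m atoms in structurally equivalent order; the result
#' is the m x m element-wise mean of the intra-copy sub-blocks.
#'
#' @param D a `deviation_matrix`
#' @param copies list of equal-length integer index vectors, one per copy,
#'   non-overlapping, each in structurally equivalent atom order
#' @return an m x m `deviation_matrix` in the same mode
#' @export
average_symmetric_copies <- function(D, copies) {
  if (!length(copies)) stop("no copies given")
  copies <- lapply(copies, as.integer)
  m <- length(copies[[1]])
  if (m < 1L) stop("empty copy index list")
  lens <- vapply(copies, length, 0L)
  if (any(lens != m))
    stop("all copies must list the same number of atoms (got ",
         paste(lens, collapse = ", "), ")")
  all_idx <- unlist(copies)
  if (any(all_idx < 1L) || any(all_idx > nrow(D)))
    stop("copy index out of range 1..", nrow(D))
  if (anyDuplicated(all_idx)) stop("copies must not overlap")
  acc <- matrix(0, m, m)
  for (idx in copies) acc <- acc + unclass(D)[idx, idx, drop = FALSE]
  acc <- acc / length(copies)
  as_deviation_matrix(acc, dev_mode(D))
}

#' Write / read a deviation matrix as CSV
#'
#' Plain CSV dialect: no header, comma separated, the full symmetric matrix
#' row by row. Recomputing the matrix dominates the cost of an analysis of
#' a long trajectory, so persisting it for reuse is worthwhile.
#'
#' @param D a `deviation_matrix`
#' @param file path
#' @return `write_deviation_csv` invisibly returns the path;
#'   `read_deviation_csv` returns the `deviation_matrix`.
#' @export
write_deviation_csv <- function(D, file) {
  utils::write.table(unclass(D), file, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(file)
}

#' @rdname write_deviation_csv
#' @param mode deviation mode the stored matrix was computed in
#' @export
read_deviation_csv <- function(file, mode = c("absolute", "squared")) {
  vals <- as.matrix(utils::read.table(file, sep = ",", header = FALSE))
  as_deviation_matrix(vals, match.arg(mode))
}
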