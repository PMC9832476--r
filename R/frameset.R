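#' Construct a frame set
#'
#' A `frame_set` bundles an atom table with an ordered series of coordinate
#' frames and the time interval between stored frames. It is the common
#' container consumed by every analysis in the package.
#'
#' @param atoms data.frame with one row per atom and columns `eleno`
#'   (integer atom id), `elety` (atom name, e.g. "CA", "O"), `resid`
#'   (3-letter residue name), `resno` (author residue numbering), `chain`
#'   (chain identifier), `subunit` (integer 0-3 for the four pore subunits;
#'   `NA` for solvent/ion atoms), `element` (element symbol).
#' @param coords numeric array of dimension `c(n_atoms, 3, n_frames)`
#'   (Angstrom), or an `n_atoms x 3` matrix for a single frame.
#' @param frame_interval time between stored frames in ns; default 0.01 ns
#'   (coordinates saved every 10 ps).
#' @return object of class `frame_set`.
#' @export
frame_set <- function(atoms, coords, frame_interval = 0.01) {
  req <- c("eleno", "elety", "resid", "resno", "chain", "subunit", "element")
  miss <- setdiff(req, names(atoms))
  if (length(miss))
    stop("`atoms` is missing columns: ", paste(miss, collapse = ", "))
  if (is.matrix(coords)) coords <- array(coords, dim = c(dim(coords), 1L))
  if (!is.array(coords) || length(dim(coords)) != 3L || dim(coords)[2] != 3L)
    stop("`coords` must be an n_atoms x 3 x n_frames array")
  if (dim(coords)[1] != nrow(atoms))
    stop(sprintf("atom count mismatch: atom table has %d atoms, coordinates have %d",
                 nrow(atoms), dim(coords)[1]))
  if (any(!is.finite(coords))) stop("coordinates must be finite")
  if (!is.numeric(frame_interval) || length(frame_interval) != 1L ||
      frame_interval <= 0)
    stop("`frame_interval` must be a single positive number (ns)")
  structure(list(atoms = atoms, coords = coords,
                 frame_interval = frame_interval),
            class = "frame_set")
}

#' Number of frames / atoms in a frame set
#' @param fs a `frame_set`.
#' @return integer.
#' @export
n_frames <- function(fs) {
  stopifnot(inherits(fs, "frame_set"))
  dim(fs$coords)[3]
}

#' @rdname n_frames
#' @export
n_atoms <- function(fs) {
  stopifnot(inherits(fs, "frame_set"))
  dim(fs$coords)[1]
}

#' Extract one frame as an n x 3 coordinate matrix
#' @param fs a `frame_set`.
#' @param i frame index (1-based).
#' @return `n_atoms x 3` matrix.
#' @export
frame_coords <- function(fs, i = 1L) {
  stopifnot(inherits(fs, "frame_set"))
  if (i < 1L || i > n_frames(fs))
    stop(sprintf("frame index %d out of range [1, %d]", i, n_frames(fs)))
  fs$coords[, , i, drop = TRUE]
}

#' Subset frames of a frame set
#'
#' `stride_frames()` keeps every `stride`-th frame (starting at the first)
#' and scales `frame_interval` accordingly, mirroring how trajectories are
#' read with a stride. `subset_frames()` keeps an arbitrary ordered frame
#' index vector without touching `frame_interval`.
#'
#' @param fs a `frame_set`.
#' @param stride positive integer.
#' @return a `frame_set`.
#' @export
stride_frames <- function(fs, stride) {
  stopifnot(inherits(fs, "frame_set"))
  stride <- as.integer(stride)
  if (is.na(stride) || stride < 1L) stop("`stride` must be a positive integer")
  keep <- seq(1L, n_frames(fs), by = stride)
  frame_set(fs$atoms, fs$coords[, , keep, drop = FALSE],
            frame_interval = fs$frame_interval * stride)
}

#' @rdname stride_frames
#' @param idx ordered frame indices to keep.
#' @export
subset_frames <- function(fs, idx) {
  stopifnot(inherits(fs, "frame_set"))
  idx <- as.integer(idx)
  if (any(is.na(idx)) || any(idx < 1L) || any(idx > n_frames(fs)))
    stop("frame indices out of range")
  frame_set(fs$atoms, fs$coords[, , idx, drop = FALSE],
            frame_interval = fs$frame_interval)
}

#' @export
print.frame_set <- function(x, ...) {
  ns <- sort(unique(x$atoms$subunit[!is.na(x$atoms$subunit)]))
  cat(sprintf("frame_set: %d atoms, %d frame(s), %.4g ns/frame\n",
              n_atoms(x), n_frames(x), x$frame_interval))
  cat(sprintf("  subunits: %s; %d solvent/ion atoms\n",
              if (length(ns)) paste(ns, collapse = " ") else "none",
              sum(is.na(x$atoms$subunit))))
  invisible(x)
}

# 3 x n_frames trajectory of one atom
.atom_track <- function(fs, i) {
  m <- fs$coords[i, , , drop = FALSE]
  dim(m) <- dim(m)[2:3]
  m
}

# 3 x n_frames trajectory of the centroid of an atom index set
.center_track <- function(fs, idx) {
  if (length(idx) == 1L) return(.atom_track(fs, idx))
  sub <- fs$coords[idx, , , drop = FALSE]
  apply(sub, c(2L, 3L), mean)
}
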