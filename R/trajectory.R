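#' Build a Trajectory
#'
#' A Trajectory binds per-frame coordinates (nm) to a Topology, with
#' timestamps (ps) and per-frame orthorhombic box lengths (nm). Coordinate
#' rows follow the flat convention `(x1, y1, z1, x2, y2, z2, ...)`.
#'
#' @param topology a `Topology`
#' @param xyz numeric matrix, `n_frames x 3*n_atoms`, nm
#' @param times numeric vector of frame times in ps (strictly increasing);
#'   defaults to `0:(n_frames-1)`
#' @param boxes `NULL`, a length-3 vector, or an `n_frames x 3` matrix of
#'   box edge lengths in nm
#' @return An object of class `Trajectory`.
#' @export
new_trajectory <- function(topology, xyz, times = NULL, boxes = NULL) {
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  if (ncol(xyz) != 3L * nrow(topology$atoms))
    stop("xyz has ", ncol(xyz), " columns; topology expects ",
         3L * nrow(topology$atoms))
  n <- nrow(xyz)
  if (is.null(times)) times <- as.numeric(seq_len(n) - 1L)
  if (length(times) != n) stop("times length must equal number of frames")
  if (n > 1 && any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (!is.null(boxes)) {
    if (is.null(dim(boxes))) boxes <- matrix(boxes, nrow = n, ncol = 3, byrow = TRUE)
    if (nrow(boxes) != n || ncol(boxes) != 3)
      stop("boxes must be n_frames x 3")
    if (any(boxes <= 0)) stop("box lengths must be > 0 for all frames")
  }
  structure(list(topology = topology, xyz = xyz, times = times, boxes = boxes),
            class = "Trajectory")
}

#' @export
print.Trajectory <- function(x, ...) {
  cat("Trajectory:", nrow(x$xyz), "frames x", n_atoms(x), "atoms",
      if (!is.null(x$boxes)) sprintf("(box %.3g x %.3g x %.3g nm)",
                                     x$boxes[1, 1], x$boxes[1, 2], x$boxes[1, 3])
      else "(no box)", "\n")
  cat("  time:", x$times[1], "..", x$times[length(x$times)], "ps\n")
  invisible(x)
}

#' Number of frames
#' @param trajectory a `Trajectory`
#' @return integer
#' @export
n_frames <- function(trajectory) nrow(trajectory$xyz)

#' Extract one frame as an n_atoms x 3 coordinate matrix
#' @param trajectory a `Trajectory`
#' @param frame frame index (1-based)
#' @param selection optional integer atom indices
#' @return numeric matrix, nm
#' @export
frame_coords <- function(trajectory, frame = 1L, selection = NULL) {
  x <- matrix(trajectory$xyz[frame, ], ncol = 3, byrow = TRUE)
  if (!is.null(selection)) x <- x[selection, , drop = FALSE]
  x
}

#' Subset a trajectory by frames and/or atoms
#' @param trajectory a `Trajectory`
#' @param frames frame indices to keep (default all)
#' @param selection atom indices to keep (default all); the topology is
#'   subset accordingly
#' @return a `Trajectory`
#' @export
subset_trajectory <- function(trajectory, frames = NULL, selection = NULL) {
  if (is.null(frames)) frames <- seq_len(n_frames(trajectory))
  xyz <- trajectory$xyz[frames, , drop = FALSE]
  times <- trajectory$times[frames]
  boxes <- if (is.null(trajectory$boxes)) NULL else
    trajectory$boxes[frames, , drop = FALSE]
  top <- trajectory$topology
  if (!is.null(selection)) {
    cols <- as.vector(rbind(3 * selection - 2, 3 * selection - 1, 3 * selection))
    xyz <- xyz[, cols, drop = FALSE]
    atoms <- top$atoms[selection, , drop = FALSE]
    rownames(atoms) <- NULL
    top <- new_topology(atoms)
  }
  new_trajectory(top, xyz, times, boxes)
}

# flat coordinate row -> selection columns
.sel_cols <- function(selection) {
  as.vector(rbind(3 * selection - 2, 3 * selection - 1, 3 * selection))
}

# n x 3 matrix -> flat row
.flatten_coords <- function(x) as.vector(t(x))
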