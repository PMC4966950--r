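#' Kabsch superposition
#'
#' Optimal (weighted) rigid-body superposition of a mobile point set onto a
#' reference. The returned rotation is always proper (det = +1, reflections
#' excluded) and the RMSD is the global minimum of the weighted RMSD over
#' rigid transforms.
#'
#' The transform acts on row-vector coordinates: `fitted = mobile %*% rotation
#' + translation` (see [apply_transform()]).
#'
#' @param mobile,reference n x 3 coordinate matrices (nm), n >= 3
#' @param weights optional non-negative weights (e.g. masses), length n
#' @return list with `rotation` (3 x 3), `translation` (length 3), `rmsd`
#'   (nm) and `fitted` (the transformed mobile coordinates)
#' @export
kabsch_superpose <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)))
    stop("mobile and reference must have identical dimensions")
  n <- nrow(mobile)
  if (n < 3) stop("at least 3 points are required")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights < 0) || sum(weights) == 0)
    stop("weights must be non-negative with positive sum")
  w <- weights / sum(weights)
  com_m <- colSums(mobile * w)
  com_r <- colSums(reference * w)
  A <- sweep(mobile, 2, com_m)
  B <- sweep(reference, 2, com_r)
  # collinearity check on the reference
  sv_ref <- svd(B * sqrt(w))$d
  if (sv_ref[2] < 1e-10 * max(sv_ref[1], 1e-30))
    stop("reference points are collinear; superposition is degenerate")
  H <- t(A * w) %*% B
  s <- svd(H)
  d <- sign(det(s$u %*% t(s$v)))
  if (d == 0) d <- 1
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  fittedA <- A %*% R
  rmsd <- sqrt(sum(w * rowSums((fittedA - B)^2)))
  translation <- as.numeric(com_r - com_m %*% R)
  list(rotation = R, translation = translation, rmsd = rmsd,
       fitted = sweep(fittedA, 2, com_r, "+"))
}

#' Apply a rigid transform to coordinates
#' @param x n x 3 matrix
#' @param rotation 3 x 3 rotation matrix
#' @param translation length-3 vector
#' @return transformed n x 3 matrix (`x %*% rotation + translation`)
#' @export
apply_transform <- function(x, rotation, translation = c(0, 0, 0)) {
  sweep(as.matrix(x) %*% rotation, 2, translation, "+")
}

#' Per-frame RMSD from a reference structure
#'
#' Each frame is superposed independently onto the reference (Kabsch) before
#' the deviation is measured.
#'
#' @param trajectory a `Trajectory`
#' @param reference n x 3 matrix, a single-frame `Trajectory`, or a frame
#'   index into `trajectory` (default: frame 1, the starting conformation)
#' @param selection optional atom indices (applied to both)
#' @param weights optional per-atom weights over the selection
#' @return numeric vector of per-frame RMSD values (nm)
#' @export
rmsd_series <- function(trajectory, reference = 1L, selection = NULL,
                        weights = NULL) {
  if (is.null(selection)) selection <- seq_len(n_atoms(trajectory))
  ref <- .as_ref_coords(reference, trajectory, selection)
  vapply(seq_len(n_frames(trajectory)), function(f) {
    kabsch_superpose(frame_coords(trajectory, f, selection), ref, weights)$rmsd
  }, numeric(1))
}

.as_ref_coords <- function(reference, trajectory, selection) {
  if (inherits(reference, "Trajectory"))
    return(frame_coords(reference, 1L, selection))
  if (is.numeric(reference) && length(reference) == 1)
    return(frame_coords(trajectory, as.integer(reference), selection))
  ref <- as.matrix(reference)
  if (ncol(ref) != 3) stop("reference must be an n x 3 matrix")
  if (nrow(ref) == length(selection)) ref else ref[selection, , drop = FALSE]
}

# iteratively superpose all frames onto their mean structure; returns the
# superposed coordinate matrix (n_frames x 3N) and the converged mean
.superpose_to_mean <- function(xyz, weights = NULL, tol = 1e-7, max_iter = 25) {
  n <- nrow(xyz)
  natoms <- ncol(xyz) / 3
  as_mat <- function(v) matrix(v, ncol = 3, byrow = TRUE)
  ref <- as_mat(xyz[1, ])
  out <- xyz
  for (it in seq_len(max_iter)) {
    for (f in seq_len(n)) {
      fit <- kabsch_superpose(as_mat(out[f, ]), ref, weights)
      out[f, ] <- .flatten_coords(fit$fitted)
    }
    m <- as_mat(colMeans(out))
    shift <- kabsch_superpose(m, ref, weights)$rmsd
    ref <- m
    if (shift < tol) break
  }
  list(xyz = out, mean = ref)
}

#' Root mean square fluctuation per atom
#'
#' Frames are first iteratively superposed onto their mean structure (so
#' rigid-body motion does not inflate the fluctuations), then the per-atom
#' fluctuation `sqrt(<|r_i - <r_i>|^2>)` is computed.
#'
#' @param trajectory a `Trajectory` with >= 2 frames
#' @param selection optional atom indices
#' @param weights optional superposition weights (defaults to atom masses)
#' @return numeric vector, one fluctuation (nm) per selected atom
#' @export
rmsf <- function(trajectory, selection = NULL, weights = NULL) {
  if (n_frames(trajectory) < 2) stop("rmsf needs at least 2 frames")
  if (is.null(selection)) selection <- seq_len(n_atoms(trajectory))
  if (is.null(weights)) weights <- trajectory$topology$atoms$mass[selection]
  xyz <- trajectory$xyz[, .sel_cols(selection), drop = FALSE]
  sup <- .superpose_to_mean(xyz, weights)
  dev <- sweep(sup$xyz, 2, colMeans(sup$xyz))
  msf <- colMeans(dev^2)
  sqrt(msf[c(TRUE, FALSE, FALSE)] + msf[c(FALSE, TRUE, FALSE)] +
         msf[c(FALSE, FALSE, TRUE)])
}
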