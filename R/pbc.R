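#' Minimum-image distance under an orthorhombic box
#'
#' @param p1,p2 numeric length-3 vectors or n x 3 matrices (nm)
#' @param box length-3 box edge lengths (nm)
#' @return distance(s) in nm, the minimum over all periodic images
#' @export
minimum_image_distance <- function(p1, p2, box) {
  box <- as.numeric(box)
  if (length(box) != 3 || any(!is.finite(box)) || any(box <= 0))
    stop("box must be three positive edge lengths")
  if (is.null(dim(p1))) p1 <- matrix(p1, ncol = 3)
  if (is.null(dim(p2))) p2 <- matrix(p2, ncol = 3)
  d <- p2 - p1
  d <- d - sweep(round(sweep(d, 2, box, "/")), 2, box, "*")
  out <- sqrt(rowSums(d^2))
  if (length(out) == 1) out[[1]] else out
}

#' Wrap coordinates into the primary box [0, L)
#' @param x n x 3 coordinate matrix (nm)
#' @param box length-3 box (nm)
#' @return wrapped n x 3 matrix
#' @export
wrap_coords <- function(x, box) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 3)
  x - sweep(floor(sweep(x, 2, box, "/")), 2, box, "*")
}

#' Unwrap a wrapped coordinate series into a continuous one
#'
#' Removes periodic jumps from a per-frame position series (one particle or
#' center of mass) by accumulating minimum-image displacements, so that mean
#' square displacements grow without wrap artifacts. Requires that true
#' consecutive-frame displacements stay below half a box edge per axis.
#'
#' @param x n_frames x 3 wrapped positions (nm)
#' @param boxes length-3 vector or n_frames x 3 matrix of box edges (nm)
#' @return n_frames x 3 continuous positions; re-wrapping recovers the input
#'   modulo the box
#' @export
unwrap_series <- function(x, boxes) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 3)
  n <- nrow(x)
  if (is.null(dim(boxes))) boxes <- matrix(boxes, nrow = n, ncol = 3, byrow = TRUE)
  if (n == 1) return(x)
  d <- diff(x)
  b <- boxes[-1, , drop = FALSE]
  d_img <- d - round(d / b) * b
  big <- abs(d_img) >= b / 2 * (1 - 1e-9)
  if (any(big)) {
    fr <- which(rowSums(big) > 0)[1] + 1L
    warning("displacement of at least half a box edge at frame ", fr,
            "; unwrap is ambiguous (increase sampling resolution)")
  }
  inc <- apply(d_img, 2, cumsum)
  if (is.null(dim(inc))) inc <- matrix(inc, nrow = 1)
  rbind(x[1, , drop = FALSE], sweep(inc, 2, x[1, ], "+"))
}

#' Center-of-mass series per molecule
#'
#' Computes the mass-weighted center of mass of each requested molecule in
#' every frame. When a box is present each molecule is first made whole by
#' minimum-image reconstruction relative to its first atom, then the COM is
#' wrapped back into the primary box; pass the result to [unwrap_series()]
#' before computing MSDs.
#'
#' @param trajectory a `Trajectory`
#' @param mols molecule ids (default: all molecules)
#' @param wrap wrap the COM into the primary box (default `TRUE` when a box
#'   is present)
#' @return list of n_frames x 3 matrices, one per molecule, named by id
#' @export
com_series <- function(trajectory, mols = NULL, wrap = !is.null(trajectory$boxes)) {
  top <- trajectory$topology
  if (is.null(mols)) mols <- unique(top$atoms$mol)
  nfr <- n_frames(trajectory)
  out <- lapply(mols, function(m) {
    idx <- which(top$atoms$mol == m)
    mass <- top$atoms$mass[idx]
    cols <- .sel_cols(idx)
    res <- matrix(0, nfr, 3)
    for (f in seq_len(nfr)) {
      x <- matrix(trajectory$xyz[f, cols], ncol = 3, byrow = TRUE)
      if (!is.null(trajectory$boxes)) {
        box <- trajectory$boxes[f, ]
        d <- sweep(x, 2, x[1, ])
        d <- d - sweep(round(sweep(d, 2, box, "/")), 2, box, "*")
        x <- sweep(d, 2, x[1, ], "+")
      }
      com <- colSums(x * mass) / sum(mass)
      if (wrap && !is.null(trajectory$boxes))
        com <- as.numeric(wrap_coords(com, trajectory$boxes[f, ]))
      res[f, ] <- com
    }
    res
  })
  names(out) <- as.character(mols)
  out
}
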