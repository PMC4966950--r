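#' Helix axis vector
#'
#' The first principal axis of a helix's Calpha positions (eigenvector of
#' the positional covariance with the largest eigenvalue), with its sign
#' fixed to point from the N- to the C-terminal end (positive projection on
#' the last-minus-first Calpha).
#'
#' @param x n x 3 Calpha coordinates of the helical segment (n >= 4), in
#'   residue order
#' @return unit length-3 vector
#' @export
helix_vector <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 4) stop("a helix needs at least 4 Calpha atoms")
  xc <- sweep(x, 2, colMeans(x))
  ev <- eigen(crossprod(xc) / nrow(xc), symmetric = TRUE)
  if (ev$values[1] < 1e-12 ||
      ev$values[1] < 1.5 * ev$values[2])
    stop("degenerate (near-spherical) point set; no well-defined axis")
  v <- ev$vectors[, 1]
  if (sum(v * (x[nrow(x), ] - x[1, ])) < 0) v <- -v
  v / sqrt(sum(v^2))
}

#' Elevation and azimuth of a target vector in a molecular frame
#'
#' The frame is built from two non-parallel vectors: `z = v_axis`,
#' `x = component of v_plane perpendicular to z`, `y = z cross x`.
#' Elevation is `90 - angle(v_target, z)` degrees, signed into
#' \[-90, 90\]; azimuth is `atan2(y component, x component)` in
#' (-180, 180\]. At the poles (target parallel to z) the azimuth is
#' undefined and reported as 0 with `degenerate = TRUE`.
#'
#' @param v_axis frame z-axis (helix 1 vector)
#' @param v_plane vector whose perpendicular component defines the x-axis
#' @param v_target vector whose orientation is measured
#' @return list with `elevation`, `azimuth` (degrees) and `degenerate`
#' @export
elevation_azimuth <- function(v_axis, v_plane, v_target) {
  z <- v_axis / sqrt(sum(v_axis^2))
  xp <- v_plane - sum(v_plane * z) * z
  if (sqrt(sum(xp^2)) < 1e-10)
    stop("frame vectors are parallel; the molecular frame is undefined")
  xhat <- xp / sqrt(sum(xp^2))
  yhat <- c(z[2] * xhat[3] - z[3] * xhat[2],
            z[3] * xhat[1] - z[1] * xhat[3],
            z[1] * xhat[2] - z[2] * xhat[1])
  t <- v_target / sqrt(sum(v_target^2))
  cz <- max(-1, min(1, sum(t * z)))
  elevation <- 90 - acos(cz) * 180 / pi
  tx <- sum(t * xhat); ty <- sum(t * yhat)
  degenerate <- sqrt(tx^2 + ty^2) < 1e-10
  azimuth <- if (degenerate) 0 else atan2(ty, tx) * 180 / pi
  if (azimuth <= -180) azimuth <- azimuth + 360
  list(elevation = elevation, azimuth = azimuth, degenerate = degenerate)
}

#' Per-frame helix orientation series
#'
#' For every frame, helix axis vectors are computed from frozen residue
#' ranges (taken from the reference assignment, even if a helix partially
#' unfolds) and the orientation of each target helix is expressed in the
#' molecular frame z = first helix axis, x = perpendicular component of the
#' second helix axis in the same frame. The frame convention id
#' `"z-h1/x-h2perp"` is recorded in the output.
#'
#' @param trajectory a `Trajectory`
#' @param helix_defs named list of 0-based residue-index vectors (in
#'   trajectory numbering), e.g. `list(h1 = 0:9, h2 = 12:21, h3 = 24:33)`;
#'   at least two entries, each of length >= 4
#' @param mol molecule id holding the helices (default: first molecule)
#' @return data.frame with columns `frame`, `time`, `helix`, `elevation`,
#'   `azimuth`, `degenerate`; attribute `convention`
#' @export
orientation_series <- function(trajectory, helix_defs, mol = NULL) {
  if (length(helix_defs) < 2) stop("at least two helix definitions required")
  if (any(vapply(helix_defs, length, integer(1)) < 4))
    stop("each helix range must contain at least 4 residues")
  top <- trajectory$topology
  if (is.null(mol)) mol <- top$atoms$mol[1]
  ca <- .ca_table(top, mol)
  idx <- lapply(helix_defs, function(rng) {
    j <- ca$atom[match(rng, ca$resid)]
    if (anyNA(j)) stop("helix range includes residues without Calpha atoms")
    j
  })
  nfr <- n_frames(trajectory)
  targets <- names(helix_defs)[-1]
  rows <- vector("list", nfr * length(targets))
  k <- 0
  for (f in seq_len(nfr)) {
    x <- frame_coords(trajectory, f)
    vecs <- lapply(idx, function(j) helix_vector(x[j, , drop = FALSE]))
    v1 <- vecs[[1]]
    v2 <- vecs[[2]]
    for (h in targets) {
      ea <- elevation_azimuth(v1, v2, vecs[[h]])
      k <- k + 1
      rows[[k]] <- data.frame(frame = f, time = trajectory$times[f],
                              helix = h, elevation = ea$elevation,
                              azimuth = ea$azimuth,
                              degenerate = ea$degenerate)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "convention") <- "z-h1/x-h2perp"
  out
}

#' Orientation frequency map
#'
#' 2-D frequency histogram over (azimuth, elevation) for one helix of an
#' [orientation_series()]; frequencies sum to 1.
#'
#' @param series result of [orientation_series()]
#' @param helix which helix label to map (default: first target present)
#' @param bins bins per axis (default 36); or a list of explicit breaks
#' @return a `SamplingMap` (frequency-normalized)
#' @export
orientation_frequency_map <- function(series, helix = NULL, bins = 36) {
  if (is.null(helix)) helix <- series$helix[1]
  s <- series[series$helix == helix, ]
  sampling_map(s$azimuth, s$elevation, bins = bins, normalize = "frequency",
               labels = c("azimuth (deg)", "elevation (deg)"))
}
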