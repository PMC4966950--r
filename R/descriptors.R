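#' Radius of gyration
#'
#' `sqrt(sum(m_i |r_i - r_com|^2) / sum(m_i))`, the standard global
#' compactness measure.
#'
#' @param x n x 3 coordinate matrix (nm)
#' @param masses optional atom masses; ignored when `mass_weighted = FALSE`
#' @param mass_weighted logical (default `TRUE` when masses are given)
#' @return radius of gyration in nm
#' @export
radius_of_gyration <- function(x, masses = NULL, mass_weighted = !is.null(masses)) {
  x <- as.matrix(x)
  if (is.null(dim(x))) x <- matrix(x, ncol = 3)
  n <- nrow(x)
  if (n < 1) stop("at least one atom is required")
  w <- if (mass_weighted && !is.null(masses)) masses else rep(1, n)
  w <- w / sum(w)
  com <- colSums(x * w)
  sqrt(sum(w * rowSums(sweep(x, 2, com)^2)))
}

#' Per-frame radius of gyration
#' @param trajectory a `Trajectory`
#' @param selection optional atom indices
#' @param mass_weighted use atom masses (default `TRUE`)
#' @return numeric vector, nm
#' @export
rg_series <- function(trajectory, selection = NULL, mass_weighted = TRUE) {
  if (is.null(selection)) selection <- seq_len(n_atoms(trajectory))
  masses <- trajectory$topology$atoms$mass[selection]
  vapply(seq_len(n_frames(trajectory)), function(f) {
    radius_of_gyration(frame_coords(trajectory, f, selection),
                       masses = if (mass_weighted) masses else NULL,
                       mass_weighted = mass_weighted)
  }, numeric(1))
}

#' Two-dimensional sampling map
#'
#' Histogram of two per-frame series (e.g. RMSD from the start vs radius of
#' gyration, or % polar SASA vs total SASA) used to visualize which regions
#' of a 2-D descriptor space a trajectory samples.
#'
#' @param x,y numeric series of equal length
#' @param bins number of bins per axis, or a list `list(x=, y=)` of explicit
#'   break vectors
#' @param normalize `"counts"` or `"frequency"`
#' @param labels length-2 character vector of axis labels
#' @return object of class `SamplingMap`: list with `x_edges`, `y_edges`,
#'   `counts`, `labels`, `n`
#' @export
sampling_map <- function(x, y, bins = 30, normalize = c("counts", "frequency"),
                         labels = c("x", "y")) {
  normalize <- match.arg(normalize)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) == 0) stop("empty input")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  edges <- function(v, nb) {
    r <- range(v)
    if (r[1] == r[2]) r <- r + c(-0.5, 0.5) * max(abs(r[1]), 1) * 1e-3
    seq(r[1], r[2], length.out = nb + 1)
  }
  if (is.list(bins)) {
    xe <- bins$x; ye <- bins$y
  } else {
    xe <- edges(x, bins); ye <- edges(y, bins)
  }
  xi <- pmin(pmax(findInterval(x, xe, rightmost.closed = TRUE), 1), length(xe) - 1)
  yi <- pmin(pmax(findInterval(y, ye, rightmost.closed = TRUE), 1), length(ye) - 1)
  counts <- matrix(0, length(xe) - 1, length(ye) - 1)
  for (k in seq_along(xi)) counts[xi[k], yi[k]] <- counts[xi[k], yi[k]] + 1
  if (normalize == "frequency") counts <- counts / length(xi)
  structure(list(x_edges = xe, y_edges = ye, counts = counts,
                 labels = labels, n = length(xi), normalize = normalize),
            class = "SamplingMap")
}

#' @export
print.SamplingMap <- function(x, ...) {
  cat("SamplingMap:", nrow(x$counts), "x", ncol(x$counts), "bins,",
      x$n, "observations (", x$labels[1], "vs", x$labels[2], ")\n")
  invisible(x)
}

#' Long-format data frame from a SamplingMap
#' @param x a `SamplingMap`
#' @param ... unused
#' @return data.frame with bin centers and counts
#' @export
as.data.frame.SamplingMap <- function(x, ...) {
  xc <- (x$x_edges[-1] + x$x_edges[-length(x$x_edges)]) / 2
  yc <- (x$y_edges[-1] + x$y_edges[-length(x$y_edges)]) / 2
  data.frame(x = rep(xc, times = length(yc)),
             y = rep(yc, each = length(xc)),
             count = as.vector(x$counts))
}

# dihedral angle (degrees) for four points, rows of a matrix
.dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

#' Assign helical secondary structure
#'
#' A deliberately simple two-state (helix/coil) assignment. With a full
#' backbone (N, CA, C present) a residue qualifies when its dihedrals fall in
#' the alpha-helical window (phi in \[-100, -30\] and psi in \[-80, -5\]
#' degrees); with only Calpha atoms it qualifies when the i to i+3 Calpha
#' distance lies in \[0.49, 0.56\] nm. Qualifying residues are labelled `H`
#' only inside runs of at least `min_run` consecutive qualifying residues.
#' This is not a STRIDE reimplementation; it tracks helicity trends, which is
#' what the crowding analysis consumes.
#'
#' @param trajectory a `Trajectory`
#' @param mol molecule id to analyse (default: first molecule)
#' @param min_run minimum run length of qualifying residues (default 4)
#' @return list with `labels` (n_frames x n_res character matrix, `"H"` or
#'   `"C"`), `helicity` (per-residue % of frames helical) and `method`
#'   (`"backbone"` or `"calpha"`)
#' @export
assign_secondary_structure <- function(trajectory, mol = NULL, min_run = 4) {
  top <- trajectory$topology
  if (is.null(mol)) mol <- top$atoms$mol[1]
  aidx <- which(top$atoms$mol == mol)
  a <- top$atoms[aidx, ]
  resids <- sort(unique(a$resid))
  n_res <- length(resids)
  nfr <- n_frames(trajectory)

  find_atom <- function(resid, nm) {
    j <- aidx[a$resid == resid & a$name == nm]
    if (length(j)) j[1] else NA_integer_
  }
  Nn <- vapply(resids, find_atom, integer(1), nm = "N")
  CA <- vapply(resids, find_atom, integer(1), nm = "CA")
  Cc <- vapply(resids, find_atom, integer(1), nm = "C")
  full_bb <- !anyNA(Nn) && !anyNA(CA) && !anyNA(Cc) && n_res >= 2
  if (!full_bb && anyNA(CA))
    stop("molecule ", mol, " lacks Calpha atoms; cannot assign secondary structure")
  if (!full_bb && !anyNA(Nn))
    warning("incomplete backbone for molecule ", mol,
            "; falling back to the Calpha-distance rule")

  labels <- matrix("C", nfr, n_res)
  for (f in seq_len(nfr)) {
    x <- frame_coords(trajectory, f)
    qual <- rep(FALSE, n_res)
    if (full_bb) {
      for (i in seq_len(n_res)) {
        if (i == 1 || i == n_res) next
        phi <- .dihedral(x[Cc[i - 1], ], x[Nn[i], ], x[CA[i], ], x[Cc[i], ])
        psi <- .dihedral(x[Nn[i], ], x[CA[i], ], x[Cc[i], ], x[Nn[i + 1], ])
        qual[i] <- phi >= -100 && phi <= -30 && psi >= -80 && psi <= -5
      }
    } else {
      for (i in seq_len(n_res)) {
        if (i + 3 > n_res) next
        d <- sqrt(sum((x[CA[i + 3], ] - x[CA[i], ])^2))
        qual[i] <- d >= 0.49 && d <= 0.56
      }
    }
    # keep only runs of >= min_run qualifying residues
    r <- rle(qual)
    r$values <- r$values & r$lengths >= min_run
    labels[f, inverse.rle(r)] <- "H"
  }
  list(labels = labels,
       helicity = 100 * colMeans(labels == "H"),
       resid = resids,
       method = if (full_bb) "backbone" else "calpha")
}
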