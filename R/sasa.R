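# deterministic Fibonacci-lattice quadrature on the unit sphere
.fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Rolls a probe sphere over atomic van der Waals spheres using a
#' deterministic Fibonacci lattice of test points. Per-atom accessible area
#' is `(accessible points / total points) * 4 pi (r_i + probe)^2`. Areas are
#' aggregated per residue into the classes `ALL` (all atoms), `BB`
#' (backbone), `SIDE` (side chain), `POL` (side-chain oxygens and
#' nitrogens) and `APOL` (all other side-chain atoms), so that
#' `ALL = BB + SIDE` and `SIDE = POL + APOL` hold exactly.
#'
#' @param trajectory a `Trajectory` (or a single-frame one)
#' @param frame frame index (default 1)
#' @param selection optional atom indices (default: all atoms)
#' @param probe probe radius in nm (default 0.14, a water-sized probe)
#' @param n_points quadrature points per atom (default 960, about 1%
#'   accuracy)
#' @param radii optional named vector of per-element radii (nm); defaults to
#'   the Bondi set, with 0.17 nm and a warning for unknown elements
#' @return object of class `SASAProfile`: list with `residues` (data.frame
#'   of per-residue areas in nm^2 by class, 1-based residue numbers),
#'   `atom_area` (per-atom areas), `totals` (named vector) and parameters
#' @export
sasa <- function(trajectory, frame = 1L, selection = NULL, probe = 0.14,
                 n_points = 960, radii = NULL) {
  top <- trajectory$topology
  if (is.null(selection)) selection <- seq_len(n_atoms(trajectory))
  a <- top$atoms[selection, , drop = FALSE]
  x <- frame_coords(trajectory, frame, selection)
  if (is.null(radii)) radii <- .bondi_radii
  r <- unname(radii[a$element])
  if (anyNA(r)) {
    unknown <- unique(a$element[is.na(r)])
    warning("no radius for element(s) ", paste(unknown, collapse = ", "),
            "; using 0.17 nm")
    r[is.na(r)] <- 0.17
  }
  R <- r + probe
  n <- nrow(x)
  sphere <- .fibonacci_sphere(n_points)
  atom_area <- numeric(n)
  # neighbor cutoff: spheres can only intersect within R_i + max(R_j)
  maxR <- max(R)
  for (i in seq_len(n)) {
    d2 <- rowSums(sweep(x, 2, x[i, ])^2)
    nb <- which(d2 < (R[i] + maxR)^2 & seq_len(n) != i)
    nb <- nb[d2[nb] < (R[i] + R[nb])^2]
    pts <- sweep(sphere * R[i], 2, x[i, ], "+")
    if (length(nb)) {
      acc <- rep(TRUE, n_points)
      for (j in nb) {
        dj2 <- rowSums(sweep(pts, 2, x[j, ])^2)
        # a point exactly on a neighbor's surface is buried only when the
        # neighbor has the lower index, so coincident identical spheres
        # contribute the union surface once
        tol <- 1e-12
        buried <- dj2 < R[j]^2 - tol | (abs(dj2 - R[j]^2) <= tol & j < i)
        acc <- acc & !buried
        if (!any(acc)) break
      }
      frac <- mean(acc)
    } else frac <- 1
    atom_area[i] <- frac * 4 * pi * R[i]^2
  }
  side <- !a$backbone
  pol <- side & a$element %in% c("O", "N")
  key <- paste(a$mol, a$resid, sep = "|")
  agg <- function(mask) {
    v <- tapply(atom_area * mask, key, sum)
    v[match(unique(key), names(v))]
  }
  ukey <- unique(key)
  first <- match(ukey, key)
  residues <- data.frame(
    mol = a$mol[first],
    residue = a$resid[first] + 1L,  # 1-based in reports
    resname = a$resname[first],
    ALL = as.numeric(agg(rep(TRUE, n))),
    BB = as.numeric(agg(a$backbone)),
    SIDE = as.numeric(agg(side)),
    POL = as.numeric(agg(pol)),
    APOL = as.numeric(agg(side & !pol))
  )
  structure(list(residues = residues, atom_area = atom_area,
                 totals = c(ALL = sum(residues$ALL), BB = sum(residues$BB),
                            SIDE = sum(residues$SIDE), POL = sum(residues$POL),
                            APOL = sum(residues$APOL)),
                 probe = probe, n_points = n_points),
            class = "SASAProfile")
}

#' @export
print.SASAProfile <- function(x, ...) {
  cat("SASAProfile:", nrow(x$residues), "residues, probe", x$probe, "nm,",
      x$n_points, "points\n")
  print(round(x$totals, 3))
  invisible(x)
}

#' Per-frame SASA series
#'
#' @param trajectory a `Trajectory`
#' @param frames frame indices (default: all)
#' @param ... passed to [sasa()]
#' @return data.frame with one row per frame: total SASA per class plus the
#'   percentage of polar side-chain SASA (`pct_polar`)
#' @export
sasa_series <- function(trajectory, frames = NULL, ...) {
  if (is.null(frames)) frames <- seq_len(n_frames(trajectory))
  rows <- lapply(frames, function(f) {
    tot <- sasa(trajectory, frame = f, ...)$totals
    data.frame(frame = f, time = trajectory$times[f],
               ALL = tot[["ALL"]], BB = tot[["BB"]], SIDE = tot[["SIDE"]],
               POL = tot[["POL"]], APOL = tot[["APOL"]],
               pct_polar = if (tot[["SIDE"]] > 0)
                 100 * tot[["POL"]] / tot[["SIDE"]] else NA_real_)
  })
  do.call(rbind, rows)
}
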