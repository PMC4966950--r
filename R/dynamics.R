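#' Mean square displacement of unwrapped center-of-mass series
#'
#' `msd(tau) = <|r(t+tau) - r(t)|^2>`, averaged over all valid time origins
#' and over molecules. Input series must be unwrapped (see
#' [unwrap_series()]); when a box is supplied, wrapped input (any
#' consecutive jump above half a box edge) is rejected with an error.
#'
#' @param series an n_frames x 3 matrix, or a list of them (one per
#'   molecule, as returned by [com_series()] after unwrapping)
#' @param times frame times in ps (default unit spacing)
#' @param window largest lag to evaluate, in ps (default: half the series)
#' @param n_lags maximum number of lag points (evenly spaced; default 200)
#' @param box optional length-3 box (nm) used only to detect wrapped input
#' @return object of class `MSDCurve`: data.frame with `lag` (ps), `msd`
#'   (nm^2), `n_origins`
#' @export
msd <- function(series, times = NULL, window = NULL, n_lags = 200, box = NULL) {
  if (!is.list(series)) series <- list(series)
  series <- lapply(series, function(s) {
    s <- as.matrix(s)
    if (ncol(s) != 3) stop("each series must be n_frames x 3")
    s
  })
  n <- nrow(series[[1]])
  if (any(vapply(series, nrow, integer(1)) != n))
    stop("all molecule series must have the same frame count")
  if (is.null(times)) times <- as.numeric(seq_len(n) - 1)
  dt <- diff(times)
  if (any(dt <= 0)) stop("times must be strictly increasing")
  if (!is.null(box)) {
    for (s in series) {
      if (n > 1 && any(abs(diff(s)) > rep(box / 2, each = n - 1)))
        stop("input looks wrapped (jump above half a box edge); ",
             "unwrap the series first (see unwrap_series)")
    }
  }
  if (is.null(window)) window <- (times[n] - times[1]) / 2
  if (window > times[n] - times[1]) stop("window exceeds trajectory length")
  max_lag_frames <- max(1L, sum(times - times[1] <= window) - 1L)
  lags <- unique(round(seq(1, max_lag_frames, length.out = min(n_lags,
                                                               max_lag_frames))))
  out <- data.frame(lag = 0, msd = 0, n_origins = n * length(series))
  for (L in lags) {
    acc <- 0
    for (s in series) {
      d <- s[(1 + L):n, , drop = FALSE] - s[1:(n - L), , drop = FALSE]
      acc <- acc + sum(d^2)
    }
    out <- rbind(out, data.frame(lag = times[1 + L] - times[1],
                                 msd = acc / ((n - L) * length(series)),
                                 n_origins = (n - L) * length(series)))
  }
  structure(out, class = c("MSDCurve", "data.frame"), window = window)
}

#' Self-diffusion coefficient from the Einstein relation
#'
#' Least-squares line through the MSD curve inside a fit window given as
#' fractions of the largest lag; `D = slope / 6` for 3-D diffusion. A
#' log-log slope far from 1 raises a poor-linearity diagnostic (e.g. for
#' ballistic motion, slope 2).
#'
#' @param curve an `MSDCurve`
#' @param fit_fraction two fractions of the largest lag bounding the fit
#'   window (default `c(0.1, 0.9)`)
#' @return list with `D` (nm^2/ps), `D_um2_s` (micrometers^2/s; 1 nm^2/ps =
#'   1e6 um^2/s), `slope_se`, `r_squared`, `loglog_slope`,
#'   `poor_linearity` flag, `negative_slope` flag, `fit_range` (ps)
#' @export
einstein_diffusion <- function(curve, fit_fraction = c(0.1, 0.9)) {
  lag_max <- max(curve$lag)
  lo <- fit_fraction[1] * lag_max
  hi <- fit_fraction[2] * lag_max
  use <- curve$lag >= lo & curve$lag <= hi & curve$lag > 0
  if (sum(use) < 10)
    stop("fewer than 10 lags in the fit range; widen the window")
  fit <- stats::lm(msd ~ lag, data = curve[use, ])
  slope <- stats::coef(fit)[["lag"]]
  sm <- suppressWarnings(summary(fit))  # exact lines trip lm's perfect-fit note
  se <- sm$coefficients["lag", "Std. Error"]
  r2 <- sm$r.squared
  pos <- use & curve$msd > 0
  alpha <- if (sum(pos) >= 3)
    stats::coef(stats::lm(log(msd) ~ log(lag), data = curve[pos, ]))[[2]]
  else NA_real_
  poor <- is.na(alpha) || abs(alpha - 1) > 0.15
  negative <- slope < 0
  D <- if (negative) 0 else slope / 6
  if (negative)
    warning("negative fitted MSD slope; D reported as 0")
  if (poor)
    warning("MSD is not linear in the fit window (log-log slope ",
            sprintf("%.2f", alpha), "); Einstein estimate unreliable")
  list(D = D, D_um2_s = D * 1e6, slope_se = se, r_squared = r2,
       loglog_slope = alpha, poor_linearity = poor,
       negative_slope = negative, fit_range = c(lo, hi))
}

#' Finite-size (periodic-box) correction to a diffusion coefficient
#'
#' The Yeh-Hummer additive correction for self-diffusion under cubic
#' periodic boundary conditions: `D0 = D_pbc + kB T xi / (6 pi eta L)` with
#' `xi = 2.837297`, the cubic-lattice self-interaction constant. The
#' correction is always positive, scales as 1/L and vanishes as the solvent
#' viscosity grows.
#'
#' @param D_pbc diffusion coefficient under PBC, micrometers^2/s
#' @param temperature kelvin
#' @param viscosity solvent shear viscosity in Pa s (default 0.89e-3, water
#'   at 300 K)
#' @param box_edge cubic box edge L in nm
#' @param xi lattice constant (default 2.837297)
#' @return list with `D_corrected` and `correction` (micrometers^2/s)
#' @export
finite_size_correction <- function(D_pbc, temperature, viscosity = 0.89e-3,
                                   box_edge, xi = 2.837297) {
  if (box_edge <= 0) stop("box edge must be > 0")
  if (viscosity <= 0) stop("viscosity must be > 0")
  corr_m2_s <- md_constants$kB_J * temperature * xi /
    (6 * pi * viscosity * box_edge * 1e-9)
  corr <- corr_m2_s * 1e12  # m^2/s -> um^2/s
  list(D_corrected = D_pbc + corr, correction = corr)
}

#' Per-group diffusion table
#'
#' Computes, for each molecule group, the per-molecule center-of-mass MSD
#' and Einstein diffusion coefficient, then the group mean and standard
#' deviation, with and without the finite-size correction (both are always
#' reported because the correction depends on an externally supplied
#' viscosity).
#'
#' @param trajectory a `Trajectory` with boxes
#' @param groups named list of molecule-id vectors (e.g.
#'   `list(water = ..., proteins = ...)`)
#' @param windows MSD window in ps, recycled per group
#' @param temperature kelvin (default 300)
#' @param viscosity Pa s (default water at 300 K, 0.89e-3)
#' @param fit_fraction passed to [einstein_diffusion()]
#' @return data.frame, one row per group: `group`, `n_molecules`,
#'   `D_mean_um2_s`, `D_sd_um2_s` (NA for single-molecule groups),
#'   `D_corrected_um2_s`, `correction_um2_s`, `window_ps`
#' @export
diffusion_table <- function(trajectory, groups, windows = NULL,
                            temperature = 300, viscosity = 0.89e-3,
                            fit_fraction = c(0.1, 0.9)) {
  if (is.null(names(groups))) stop("groups must be named")
  duration <- diff(range(trajectory$times))
  if (is.null(windows)) windows <- duration / 2
  windows <- rep(windows, length.out = length(groups))
  L <- if (!is.null(trajectory$boxes)) mean(trajectory$boxes[, 1]) else NA
  rows <- lapply(seq_along(groups), function(g) {
    mols <- groups[[g]]
    coms <- com_series(trajectory, mols = mols)
    Ds <- vapply(coms, function(cs) {
      un <- if (!is.null(trajectory$boxes))
        unwrap_series(cs, trajectory$boxes) else cs
      curve <- msd(un, times = trajectory$times, window = windows[g])
      einstein_diffusion(curve, fit_fraction)$D_um2_s
    }, numeric(1))
    corr <- if (!is.na(L))
      finite_size_correction(mean(Ds), temperature, viscosity, L)$correction
    else NA_real_
    data.frame(group = names(groups)[g], n_molecules = length(mols),
               D_mean_um2_s = mean(Ds),
               D_sd_um2_s = if (length(Ds) > 1) stats::sd(Ds) else NA_real_,
               D_corrected_um2_s = mean(Ds) + corr,
               correction_um2_s = corr,
               window_ps = windows[g])
  })
  do.call(rbind, rows)
}
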