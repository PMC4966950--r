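#' Mass-weighted covariance of conformational fluctuations
#'
#' Builds `C = < M^{1/2} dx dx' M^{1/2} >` over a trailing window of
#' frames, where `dx` are deviations from the mean structure after
#' (optional) iterative superposition that removes rigid-body motion. When
#' superposition is on, the six near-zero rigid-body eigenvalues are
#' discarded (the 6 smallest, plus anything below `eig_floor`).
#'
#' @param trajectory a `Trajectory`
#' @param selection atom indices (default: backbone atoms - N, CA, C, O)
#' @param window two fractions of the trajectory giving the analysis window
#'   (default `c(0.5, 1)`, the trailing half, mirroring tail-window
#'   entropy estimates on production runs)
#' @param superpose remove rigid-body motion first (default `TRUE`; turn off
#'   for abstract ensembles that carry none)
#' @param drop_rigid drop the 6 smallest eigenvalues (default = `superpose`)
#' @param eig_floor discard eigenvalues below this value (amu nm^2;
#'   default 1e-8)
#' @param keep_deviations retain the mass-weighted deviation matrix for
#'   bootstrap use (default `FALSE`)
#' @return list with `eigenvalues` (amu nm^2, decreasing, filtered),
#'   `covariance`, `n_frames`, `selection_label`, `window`, and optionally
#'   `deviations`
#' @export
mass_weighted_covariance <- function(trajectory, selection = NULL,
                                     window = c(0.5, 1), superpose = TRUE,
                                     drop_rigid = superpose,
                                     eig_floor = 1e-8,
                                     keep_deviations = FALSE) {
  top <- trajectory$topology
  if (is.null(selection)) {
    selection <- which(top$atoms$name %in% c("N", "CA", "C", "O"))
    if (length(selection) == 0) selection <- seq_len(n_atoms(trajectory))
  }
  nfr <- n_frames(trajectory)
  f0 <- max(1L, floor(window[1] * nfr) + 1L)
  f1 <- min(nfr, ceiling(window[2] * nfr))
  frames <- f0:f1
  xyz <- trajectory$xyz[frames, .sel_cols(selection), drop = FALSE]
  masses <- top$atoms$mass[selection]
  if (superpose) {
    xyz <- .superpose_to_mean(xyz, weights = masses)$xyz
  }
  ndof <- ncol(xyz)
  if (nrow(xyz) < ndof)
    warning("fewer frames (", nrow(xyz), ") than degrees of freedom (",
            ndof, "); covariance is rank-deficient and eigenvalues are ",
            "truncated accordingly")
  sqm <- rep(sqrt(masses), each = 3)
  dev <- sweep(xyz, 2, colMeans(xyz))
  dev <- sweep(dev, 2, sqm, "*")
  C <- crossprod(dev) / nrow(dev)
  ev <- eigen(C, symmetric = TRUE, only.values = !keep_deviations)
  lam <- ev$values
  if (drop_rigid && length(lam) > 6) lam <- lam[seq_len(length(lam) - 6)]
  lam <- lam[lam > eig_floor]
  out <- list(eigenvalues = lam, covariance = C,
              n_frames = nrow(dev),
              selection_label = attr(selection, "label") %||% "selection",
              window = c(f0, f1))
  if (keep_deviations) out$deviations <- dev
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Quasi-harmonic conformational entropy
#'
#' Treats the mass-weighted covariance eigenvalues as independent harmonic
#' modes with frequencies `omega_i = sqrt(kB T / lambda_i)` and sums the
#' quantum harmonic-oscillator entropy
#' `S/kB = sum_i [ x_i/(exp(x_i)-1) - ln(1-exp(-x_i)) ]`, `x_i = hbar
#' omega_i / kB T`. Stiff modes (lambda -> 0) contribute nothing; soft
#' modes dominate.
#'
#' @param eigenvalues positive eigenvalues in amu nm^2 (already filtered of
#'   rigid-body zeros)
#' @param temperature kelvin (default 300)
#' @return object of class `EntropyResult`: `S_J_mol_K` (J/(mol K)),
#'   `S_kB` (same entropy in units of kB, i.e. per molecule),
#'   `per_mode_kB`, `eigenvalues`, `temperature`
#' @export
quasiharmonic_entropy <- function(eigenvalues, temperature = 300) {
  if (length(eigenvalues) == 0) stop("no eigenvalues supplied")
  if (any(eigenvalues <= 0))
    stop("non-positive eigenvalue after filtering; check eig_floor")
  kB <- md_constants$kB
  hbar <- md_constants$hbar
  omega <- sqrt(kB * temperature / eigenvalues)  # 1/ps
  x <- hbar * omega / (kB * temperature)
  per_mode <- x / expm1(x) - log1p(-exp(-x))
  S_kB <- sum(per_mode)
  structure(list(S_J_mol_K = S_kB * md_constants$R_gas,
                 S_kB = S_kB, per_mode_kB = per_mode,
                 eigenvalues = eigenvalues, temperature = temperature),
            class = "EntropyResult")
}

#' @export
print.EntropyResult <- function(x, ...) {
  cat(sprintf("Quasi-harmonic entropy: %.4f kB (%.3f J/(mol K)) over %d modes at %g K\n",
              x$S_kB, x$S_J_mol_K, length(x$eigenvalues), x$temperature))
  invisible(x)
}

#' Entropy difference between two environments
#'
#' `dS = S_env - S_water` from two mass-weighted covariance results on the
#' same selection and temperature, with an uncertainty from a block
#' bootstrap over frames (blocks preserve the short-time correlation of the
#' fluctuations). Both covariance results must have been built with
#' `keep_deviations = TRUE`.
#'
#' @param cov_env,cov_water results of [mass_weighted_covariance()] with
#'   deviations retained
#' @param temperature kelvin (default 300)
#' @param n_boot bootstrap replicates (default 50)
#' @param block_frac block length as a fraction of the frame count
#'   (default 0.05)
#' @param drop_rigid,eig_floor eigenvalue filtering applied to each
#'   bootstrap covariance, matching the original estimates
#' @param seed optional RNG seed for reproducible uncertainty
#' @return list with `dS_J_mol_K`, `dS_kB`, `se_J_mol_K` (bootstrap
#'   standard error), `S_env`, `S_water`
#' @export
entropy_difference <- function(cov_env, cov_water, temperature = 300,
                               n_boot = 50, block_frac = 0.05,
                               drop_rigid = TRUE, eig_floor = 1e-8,
                               seed = NULL) {
  if (is.null(cov_env$deviations) || is.null(cov_water$deviations))
    stop("run mass_weighted_covariance with keep_deviations = TRUE")
  if (ncol(cov_env$deviations) != ncol(cov_water$deviations))
    stop("mismatched selections: ", ncol(cov_env$deviations), " vs ",
         ncol(cov_water$deviations), " coordinates")
  ent <- function(dev) {
    lam <- eigen(crossprod(dev) / nrow(dev), symmetric = TRUE,
                 only.values = TRUE)$values
    if (drop_rigid && length(lam) > 6) lam <- lam[seq_len(length(lam) - 6)]
    lam <- lam[lam > eig_floor]
    quasiharmonic_entropy(lam, temperature)$S_J_mol_K
  }
  S_env <- ent(cov_env$deviations)
  S_wat <- ent(cov_water$deviations)
  if (!is.null(seed)) {
    old <- .Random.seed %||% NULL
    set.seed(seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  }
  boot_one <- function(dev) {
    n <- nrow(dev)
    bl <- max(1L, round(block_frac * n))
    starts <- sample.int(n - bl + 1L, ceiling(n / bl), replace = TRUE)
    idx <- unlist(lapply(starts, function(s) s:(s + bl - 1L)))[1:n]
    ent(dev[idx, , drop = FALSE])
  }
  d_boot <- replicate(n_boot, boot_one(cov_env$deviations) -
                        boot_one(cov_water$deviations))
  list(dS_J_mol_K = S_env - S_wat,
       dS_kB = (S_env - S_wat) / md_constants$R_gas,
       se_J_mol_K = stats::sd(d_boot),
       S_env = S_env, S_water = S_wat)
}
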