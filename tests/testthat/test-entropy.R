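test_that("covariance of a static trajectory is zero", {
  h <- build_helix(6)
  tr <- beads_traj(replicate(8, h, simplify = FALSE))
  # 8 frames < 18 degrees of freedom: the rank warning is expected here
  cv <- suppressWarnings(
    mass_weighted_covariance(tr, selection = 1:6, window = c(0, 1)))
  expect_lt(max(abs(cv$covariance)), 1e-12)
  expect_equal(length(cv$eigenvalues), 0)
  expect_error(quasiharmonic_entropy(cv$eigenvalues), "no eigenvalues")
})

test_that("planted spectra are recovered and scale with mass as M^{1/2} C M^{1/2}", {
  lam <- rep(c(0.03, 0.012, 0.006, 0.002), 3)
  tr <- gen_gaussian_ensemble(lam, masses = rep(12, 4), n_frames = 2e4,
                              seed = 19)
  cv <- mass_weighted_covariance(tr, selection = 1:4, superpose = FALSE,
                                 drop_rigid = FALSE)
  expect_equal(cv$eigenvalues, sort(lam, decreasing = TRUE), tolerance = 0.05)
  # quadrupling every mass multiplies the mass-weighted eigenvalues by 4
  tr4 <- tr
  tr4$topology$atoms$mass <- tr$topology$atoms$mass * 4
  cv4 <- mass_weighted_covariance(tr4, selection = 1:4, superpose = FALSE,
                                  drop_rigid = FALSE)
  expect_equal(cv4$eigenvalues, 4 * cv$eigenvalues, tolerance = 1e-9)
})

test_that("the quasi-harmonic closed form is evaluated exactly", {
  # x = hbar omega / kB T = 1 when lambda = hbar^2 / (kB T)
  lam1 <- md_constants$hbar^2 / (md_constants$kB * 300)
  s <- quasiharmonic_entropy(lam1, 300)
  expect_equal(s$S_kB, 1 / (exp(1) - 1) - log(1 - exp(-1)), tolerance = 1e-12)
  expect_equal(s$S_kB, 1.04065185226, tolerance = 1e-8)
  expect_equal(s$S_J_mol_K, s$S_kB * md_constants$R_gas, tolerance = 1e-12)
  # stiff limit: S -> 0
  expect_lt(quasiharmonic_entropy(lam1 * 1e-6, 300)$S_kB, 1e-3)
  expect_error(quasiharmonic_entropy(c(0.1, -0.1)), "non-positive")
})

test_that("entropy is monotone in the eigenvalues with the classical doubling law", {
  lam <- c(0.05, 0.02, 0.01)
  s1 <- quasiharmonic_entropy(lam, 300)$S_kB
  s2 <- quasiharmonic_entropy(2 * lam, 300)$S_kB
  expect_gt(s2, s1)
  # classical (large-lambda) limit: doubling all lambda adds n kB ln sqrt(2)
  big <- c(5, 2, 1) * 1e3
  ds <- quasiharmonic_entropy(2 * big, 300)$S_kB -
    quasiharmonic_entropy(big, 300)$S_kB
  expect_equal(ds, 3 * log(sqrt(2)), tolerance = 1e-3)
})

test_that("entropy is invariant to rigid motion once frames are superposed", {
  lam <- rep(c(0.02, 0.008, 0.004), 4)
  tr <- gen_gaussian_ensemble(lam, masses = rep(12, 4), n_frames = 6000,
                              seed = 23)
  # the raw ensemble carries no rigid-body motion; compare against frames
  # that are arbitrarily rotated and translated, then superposed
  set.seed(24)
  xyz2 <- t(vapply(seq_len(n_frames(tr)), function(f) {
    x <- frame_coords(tr, f)
    as.vector(t(sweep(x %*% rand_rotation(), 2, rnorm(3, sd = 3), "+")))
  }, numeric(12)))
  tr2 <- new_trajectory(tr$topology, xyz2)
  cv1 <- mass_weighted_covariance(tr, selection = 1:4, superpose = TRUE,
                                  window = c(0, 1))
  cv2 <- mass_weighted_covariance(tr2, selection = 1:4, superpose = TRUE,
                                  window = c(0, 1))
  s1 <- quasiharmonic_entropy(cv1$eigenvalues, 300)$S_kB
  s2 <- quasiharmonic_entropy(cv2$eigenvalues, 300)$S_kB
  expect_equal(s2, s1, tolerance = 0.02)
})

test_that("entropy differences come with bootstrap uncertainty", {
  lam <- rep(c(0.02, 0.008, 0.004), 4)
  trw <- gen_gaussian_ensemble(lam, masses = rep(12, 4), n_frames = 5000,
                               seed = 31)
  tre <- gen_gaussian_ensemble(2 * lam, masses = rep(12, 4), n_frames = 5000,
                               seed = 32)
  cw <- mass_weighted_covariance(trw, selection = 1:4, superpose = FALSE,
                                 drop_rigid = FALSE, keep_deviations = TRUE)
  ce <- mass_weighted_covariance(tre, selection = 1:4, superpose = FALSE,
                                 drop_rigid = FALSE, keep_deviations = TRUE)
  # identical inputs: exactly zero difference
  d0 <- entropy_difference(cw, cw, 300, n_boot = 5, drop_rigid = FALSE,
                           seed = 1)
  expect_equal(d0$dS_J_mol_K, 0)
  # doubled spectrum: positive difference, close to the closed-form gap
  d <- entropy_difference(ce, cw, 300, n_boot = 20, drop_rigid = FALSE,
                          seed = 2)
  expect_gt(d$dS_J_mol_K, 0)
  truth <- (quasiharmonic_entropy(2 * lam, 300)$S_J_mol_K -
              quasiharmonic_entropy(lam, 300)$S_J_mol_K)
  expect_equal(d$dS_J_mol_K, truth, tolerance = 0.05)
  expect_gt(d$se_J_mol_K, 0)
  expect_lt(abs(d$dS_J_mol_K - truth), 5 * d$se_J_mol_K + 1)
})

test_that("rank deficiency triggers a warning with truncated spectra", {
  lam <- rep(c(0.02, 0.008), 6)  # 12 coordinates
  tr <- gen_gaussian_ensemble(lam, masses = rep(12, 4), n_frames = 8,
                              seed = 41)
  expect_warning(
    cv <- mass_weighted_covariance(tr, selection = 1:4, superpose = FALSE,
                                   drop_rigid = FALSE),
    "rank")
  expect_lte(length(cv$eigenvalues), 8)
})
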