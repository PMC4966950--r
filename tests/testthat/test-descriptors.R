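test_that("Kabsch superposition recovers rigid motions exactly", {
  set.seed(21)
  A <- matrix(rnorm(30), 10, 3)
  fit <- kabsch_superpose(A, A)
  expect_equal(fit$rmsd, 0, tolerance = 1e-10)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-8)
  # 90 degrees about z plus translation
  R90 <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)
  B <- sweep(A %*% R90, 2, c(1, -2, 3), "+")
  fit <- kabsch_superpose(A, B)
  expect_equal(fit$rmsd, 0, tolerance = 1e-10)
  expect_equal(fit$rotation, R90, tolerance = 1e-8)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-10)
  expect_equal(apply_transform(A, fit$rotation, fit$translation), B,
               tolerance = 1e-8)
  expect_error(kabsch_superpose(A[1:2, ], A[1:2, ]), "3 points")
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(kabsch_superpose(line + rnorm(15, sd = 1e-14), line),
               "collinear")
})

test_that("minimal RMSD agrees with a rotation-grid brute force", {
  set.seed(22)
  for (k in 1:2) {
    A <- matrix(rnorm(30), 10, 3)
    B <- matrix(rnorm(30), 10, 3)
    expect_equal(kabsch_superpose(A, B)$rmsd, grid_min_rmsd(A, B),
                 tolerance = 1e-3)
  }
})

test_that("rmsd_series is zero on copies and invariant to rigid motion", {
  h <- build_helix(10)
  frames <- replicate(6, h, simplify = FALSE)
  tr <- beads_traj(frames)
  expect_equal(rmsd_series(tr), rep(0, 6), tolerance = 1e-10)
  set.seed(23)
  rot <- lapply(frames, function(x)
    sweep(x %*% rand_rotation(), 2, rnorm(3), "+"))
  tr2 <- beads_traj(rot)
  expect_equal(rmsd_series(tr2), rep(0, 6), tolerance = 1e-8)
  # adding the same rigid motion to every frame leaves a series unchanged
  ts <- gen_two_state(build_helix(9), zigzag_chain(9), 5, 40, seed = 3)
  R <- rand_rotation()
  moved <- lapply(seq_len(40), function(f)
    sweep(frame_coords(ts, f) %*% R, 2, c(5, 5, 5), "+"))
  expect_equal(rmsd_series(beads_traj(moved)), rmsd_series(ts),
               tolerance = 1e-8)
})

test_that("two-state fixture gives a bimodal RMSD distribution", {
  A <- build_helix(12); B <- zigzag_chain(12)
  sep <- kabsch_superpose(A, B)$rmsd
  tr <- gen_two_state(A, B, dwell = 10, n_frames = 400, noise_sigma = 0.01,
                      seed = 13)
  r <- rmsd_series(tr, reference = A)
  states <- ground_truth(tr)$states
  expect_lt(max(r[states == 1]), 0.1)
  expect_equal(mean(r[states == 2]), sep, tolerance = 0.1)
})

test_that("radius of gyration matches closed forms", {
  expect_equal(radius_of_gyration(matrix(c(1, 2, 3), 1)), 0)
  two <- rbind(c(0, 0, 0), c(2, 0, 0))
  expect_equal(radius_of_gyration(two, masses = c(1, 1)), 1)
  # compactness ordering: compacted coil < random coil < fully extended chain
  coil <- gen_random_coil(51, 100, seed = 9)
  mean_coil <- mean(rg_series(coil, mass_weighted = FALSE))
  extended <- radius_of_gyration(zigzag_chain(51))
  compacted <- radius_of_gyration(frame_coords(coil, 1) * 0.3)
  expect_lt(mean_coil, extended)
  expect_lt(compacted, mean_coil)
  # ideal-chain closed form: <Rg^2> = b^2 (n^2 - 1) / (6 n)
  expect_equal(mean(rg_series(coil, mass_weighted = FALSE)^2),
               0.38^2 * (51^2 - 1) / (6 * 51), tolerance = 0.1)
})

test_that("rmsf recovers planted isotropic fluctuations", {
  h <- build_helix(30)
  static <- beads_traj(replicate(5, h, simplify = FALSE))
  expect_equal(rmsf(static), rep(0, 30), tolerance = 1e-9)
  sigma <- 0.03
  set.seed(31)
  noisy <- beads_traj(lapply(1:800, function(f)
    h + matrix(rnorm(90, sd = sigma), 30, 3)))
  fl <- rmsf(noisy)
  expect_equal(mean(fl), sqrt(3) * sigma, tolerance = 0.05)
  # rigid tumbling of a static structure is removed by superposition
  set.seed(32)
  tumb <- beads_traj(lapply(1:30, function(f)
    sweep(h %*% rand_rotation(), 2, rnorm(3, sd = 2), "+")))
  expect_lt(max(rmsf(tumb)), 1e-8)
})

test_that("Shrake-Rupley SASA matches analytic sphere results", {
  one <- new_trajectory(
    new_topology(data.frame(name = "O", element = "O", mass = 16, resid = 0L,
                            resname = "HOH", mol = 1L, backbone = FALSE)),
    matrix(c(0, 0, 0), 1))
  s <- sasa(one, radii = c(O = 0.16), probe = 0.14, n_points = 960)
  expect_equal(s$totals[["ALL"]], 4 * pi * 0.3^2, tolerance = 0.01)
  # two coincident identical atoms: the union surface is one sphere
  two_top <- new_topology(data.frame(name = c("O", "O"), element = "O",
                                     mass = 16, resid = 0:1, resname = "HOH",
                                     mol = 1L, backbone = FALSE))
  two <- new_trajectory(two_top, matrix(c(0, 0, 0, 0, 0, 0), 1))
  s2 <- sasa(two, radii = c(O = 0.16))
  expect_equal(s2$totals[["ALL"]], 4 * pi * 0.3^2, tolerance = 0.01)
  # partial overlap vs spherical-cap closed form (1% quadrature tolerance)
  for (d in c(0.2, 0.35, 0.5)) {
    tw <- new_trajectory(two_top, matrix(c(0, 0, 0, d, 0, 0), 1))
    st <- sasa(tw, radii = c(O = 0.16), n_points = 960)
    expect_equal(st$totals[["ALL"]], two_sphere_sasa(0.3, 0.3, d),
                 tolerance = 0.01)
  }
})

test_that("SASA classes decompose consistently and respond to burial", {
  atoms <- data.frame(
    name = c("N", "CA", "C", "O", "CB", "OG"),
    element = c("N", "C", "C", "O", "C", "O"),
    mass = c(14, 12, 12, 16, 12, 16),
    resid = 0L, resname = "SER", mol = 1L,
    backbone = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE))
  x <- matrix(rnorm(18, sd = 0.12), 6, 3)
  tr <- new_trajectory(new_topology(atoms), matrix(as.vector(t(x)), 1))
  s <- sasa(tr)
  r <- s$residues
  expect_equal(r$ALL, r$BB + r$SIDE, tolerance = 1e-9)
  expect_equal(r$SIDE, r$POL + r$APOL, tolerance = 1e-9)
  expect_true(all(unlist(r[, c("ALL", "BB", "SIDE", "POL", "APOL")]) >= 0))
  # side-chain OG is polar, CB apolar
  expect_gt(r$POL, 0); expect_gt(r$APOL, 0)
  # total SASA decreases monotonically as two chains approach
  h <- build_helix(10)
  seps <- c(5, 2, 1, 0.5)
  tot <- vapply(seps, function(sep) {
    both <- rbind(h, sweep(h, 2, c(sep, 0, 0), "+"))
    top <- mdcrowd:::.bead_topology(c(10L, 10L))
    sasa(new_trajectory(top, matrix(as.vector(t(both)), 1)),
         n_points = 480)$totals[["ALL"]]
  }, numeric(1))
  expect_true(all(diff(tot) <= 1e-9))
})

test_that("helicity assignment distinguishes helix from coil", {
  # Calpha-only rule on an ideal helical trace
  h <- beads_traj(list(build_helix(12)))
  ss <- assign_secondary_structure(h)
  expect_equal(ss$method, "calpha")
  expect_equal(unname(ss$helicity[3:8]), rep(100, 6))
  # a 3-residue fragment can never satisfy the run-length rule
  tiny <- beads_traj(list(build_helix(4)[1:3, ] + 0))
  expect_true(all(assign_secondary_structure(tiny)$helicity == 0))
  # full-backbone dihedral rule on an ideal phi/psi helix
  bb <- build_backbone_helix(10)
  ssb <- assign_secondary_structure(bb)
  expect_equal(ssb$method, "backbone")
  expect_equal(unname(ssb$helicity[3:8]), rep(100, 6))
  # random coils are essentially helix-free
  coil <- gen_random_coil(30, 300, seed = 12)
  hel <- assign_secondary_structure(coil)$helicity
  expect_true(all(hel <= 5))
})

test_that("sampling maps conserve counts and resolve two states", {
  m <- sampling_map(rep(1, 50), rep(2, 50), bins = 10)
  expect_equal(sum(m$counts), 50)
  expect_equal(sum(m$counts > 0), 1)
  set.seed(41)
  m2 <- sampling_map(runif(1000), runif(1000), bins = 8)
  expect_equal(sum(m2$counts), 1000)
  expect_error(sampling_map(numeric(0), numeric(0)), "empty")
  # two-state fixture occupies two islands in (RMSD, Rg) space
  A <- build_helix(12); B <- zigzag_chain(12)
  tr <- gen_two_state(A, B, dwell = 10, n_frames = 200, noise_sigma = 0.005,
                      seed = 2)
  r <- rmsd_series(tr, reference = A)
  g <- rg_series(tr, mass_weighted = FALSE)
  m3 <- sampling_map(r, g, bins = 12)
  expect_gte(sum(m3$counts > 0), 2)
  expect_equal(sum(m3$counts), 200)
})
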