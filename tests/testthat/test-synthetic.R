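test_that("generators are reproducible given the same seed", {
  expect_equal(gen_brownian(5, 1e-3, 1, 50, seed = 8)$xyz,
               gen_brownian(5, 1e-3, 1, 50, seed = 8)$xyz)
  expect_equal(gen_random_coil(12, 5, seed = 8)$xyz,
               gen_random_coil(12, 5, seed = 8)$xyz)
  A <- build_helix(8); B <- zigzag_chain(8)
  expect_equal(gen_two_state(A, B, 10, 50, seed = 8)$xyz,
               gen_two_state(A, B, 10, 50, seed = 8)$xyz)
  # generators do not disturb the global RNG stream
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(gen_brownian(3, 1e-3, 1, 10, seed = 99))
  expect_equal(rnorm(1), before)
})

test_that("zero-diffusion Brownian particles are static", {
  tr <- gen_brownian(4, 0, 1, 100, seed = 2)
  expect_equal(max(abs(sweep(tr$xyz, 2, tr$xyz[1, ]))), 0)
})

test_that("ideal helix geometry matches alpha-helical distances", {
  h <- build_helix(10)
  d1 <- sqrt(rowSums(diff(h)^2))
  expect_true(all(abs(d1 - 0.38) < 0.01))
  d3 <- sqrt(rowSums((h[4:10, ] - h[1:7, ])^2))
  expect_true(all(d3 > 0.49 & d3 < 0.56))
  # the principal axis of a finite helix carries an O(1/n^2) tilt off the
  # geometric axis; by 72 residues it is within 1 degree of +z
  v <- helix_vector(build_helix(72))
  expect_gt(sum(v * c(0, 0, 1)), cos(1 * pi / 180))
})

test_that("freely jointed coil has exact bonds and ideal-chain Rg scaling", {
  tr <- gen_random_coil(2, 3, seed = 5)
  expect_equal(rg_series(tr, mass_weighted = FALSE),
               rep(0.19, 3), tolerance = 1e-10)
  tr20 <- gen_random_coil(21, 150, seed = 6)
  tr80 <- gen_random_coil(81, 150, seed = 7)
  # bonds exact in every frame
  x <- frame_coords(tr20, 7)
  expect_equal(sqrt(rowSums(diff(x)^2)), rep(0.38, 20), tolerance = 1e-10)
  # <Rg^2> ~ b^2 n / 6: quadrupling n doubles Rg
  ratio <- mean(rg_series(tr80, mass_weighted = FALSE)) /
    mean(rg_series(tr20, mass_weighted = FALSE))
  expect_equal(ratio, 2, tolerance = 0.15)
})

test_that("planted contact pairs stay within the cutoff", {
  tr <- gen_random_coil(50, 150, planted_pairs = rbind(c(5, 40)), seed = 3)
  x <- lapply(seq_len(n_frames(tr)), function(f) frame_coords(tr, f))
  d <- vapply(x, function(m) sqrt(sum((m[5, ] - m[40, ])^2)), numeric(1))
  expect_gte(mean(d <= 0.8), 0.95)
  # bonds still exact under the restrained sampler
  expect_equal(sqrt(rowSums(diff(x[[10]])^2)), rep(0.38, 49), tolerance = 1e-9)
  expect_error(gen_random_coil(20, 5, planted_pairs = rbind(c(5, 7))),
               "separated")
})

test_that("two-state generator plants a recoverable hidden state sequence", {
  A <- build_helix(12); B <- zigzag_chain(12)
  tr <- gen_two_state(A, B, dwell = 15, n_frames = 300, noise_sigma = 0,
                      seed = 4)
  gt <- ground_truth(tr)
  cl <- gromos_cluster(tr, cutoff = 0.15)
  # noiseless: cluster labels are a relabeling of the hidden states
  expect_equal(length(unique(paste(cl$labels, gt$states))),
               length(unique(gt$states)))
  # no-switch limit: single cluster, zero transitions
  tr1 <- gen_two_state(A, B, dwell = 1e9, n_frames = 50, seed = 4)
  cc <- conformational_change_times(tr1, cutoff = 0.15)
  expect_equal(cc$n_transitions, 0)
  expect_true(cc$no_transitions)
  expect_equal(length(gromos_cluster(tr1, 0.15)$centers), 1)
  # conformers closer than 2x cutoff are rejected
  expect_error(gen_two_state(A, A + 0.01, dwell = 5, n_frames = 10),
               "exceed")
})

test_that("crowded box hits the target concentration by unit arithmetic", {
  # 6022 amu at 100 g/L: volume = 1e-22 L = 100 nm^3, edge 4.642 nm
  cb <- build_crowded_box(data.frame(length = 2, kind = "coil", copies = 1),
                          concentration = 100, residue_mass = 3011, seed = 2)
  gt <- ground_truth(cb)
  expect_equal(gt$total_mass_amu, 6022)
  expect_equal(gt$box_edge, (6022 * 1.66053906660e-24 / 100 * 1e24)^(1 / 3),
               tolerance = 1e-10)
  expect_equal(gt$box_edge, 4.6416, tolerance = 1e-3)
  expect_error(build_crowded_box(data.frame(length = 2, kind = "coil",
                                            copies = 1), 0), "> 0")
  # the paper-scale composition: 8 chains at 192 g/L, within 2%
  cb8 <- build_crowded_box(data.frame(length = c(30, 20, 30),
                                      kind = c("helix", "helix", "coil"),
                                      copies = c(1, 6, 1)),
                           concentration = 192, seed = 1)
  ach <- ground_truth(cb8)$achieved_concentration
  expect_lt(abs(ach - 192) / 192, 0.02)
  # placement respects the minimum inter-chain separation
  x <- frame_coords(cb8, 1)
  mols <- cb8$topology$atoms$mol
  box <- cb8$boxes[1, ]
  for (m in 1:2) {
    a <- x[mols == m, ]; b <- x[mols > m, ]
    dmin <- min(vapply(seq_len(nrow(a)), function(i)
      min(minimum_image_distance(matrix(a[i, ], nrow(b), 3, byrow = TRUE),
                                 b, box)), numeric(1)))
    expect_gte(dmin, 0.3)
  }
})

test_that("gaussian ensemble reproduces its planted spectrum", {
  lam <- c(0.02, 0.01, 0.004, 0.02, 0.01, 0.004)
  tr <- gen_gaussian_ensemble(lam, masses = c(12, 40), n_frames = 3e4,
                              seed = 11)
  cv <- mass_weighted_covariance(tr, selection = 1:2, superpose = FALSE,
                                 drop_rigid = FALSE)
  expect_equal(cv$eigenvalues, sort(lam, decreasing = TRUE),
               tolerance = 0.05)
  expect_error(gen_gaussian_ensemble(c(0.1, -1, 0.1), 12, n_frames = 10),
               "singular")
})

test_that("manifest sidecar stores the generator ground truth", {
  tr <- gen_brownian(3, 1e-3, 1, 10, seed = 5)
  path <- withr::local_tempfile(fileext = ".json")
  write_manifest(tr, path)
  m <- jsonlite::read_json(path)
  expect_equal(m$generator, "brownian")
  expect_equal(m$D_true, 1e-3)
  expect_equal(m$seed, 5)
})
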