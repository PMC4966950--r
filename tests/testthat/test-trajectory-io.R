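test_that("PDB coordinates are converted from Angstrom to nm on ingest", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1       1.000   2.000   3.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.000   2.000   3.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.500  -1.000   0.000  1.00  0.00           C",
    "END"), path)
  res <- read_structure(path)
  expect_equal(frame_coords(res$trajectory, 1)[2, ], c(0.10, 0.20, 0.30),
               tolerance = 1e-8)
  expect_equal(res$topology$atoms$element, c("N", "C", "C"))
})

test_that("GRO files parse box line and keep nm units", {
  path <- withr::local_tempfile(fileext = ".gro")
  writeLines(c("test", "    2",
               "    1ALA     CA    1   0.100   0.200   0.300",
               "    2ALA     CA    2   1.000   1.000   1.000",
               "   5.0   5.0   5.0"), path)
  res <- suppressWarnings(read_structure(path))
  expect_equal(res$trajectory$boxes[1, ], c(5, 5, 5))
  expect_equal(frame_coords(res$trajectory, 1)[1, ], c(0.1, 0.2, 0.3))
  # triclinic box entries are rejected
  path2 <- withr::local_tempfile(fileext = ".gro")
  writeLines(c("test", "    1",
               "    1ALA     CA    1   0.100   0.200   0.300",
               "   5.0   5.0   5.0   0.0   0.0   1.2"), path2)
  expect_error(suppressWarnings(read_structure(path2)), "triclinic")
})

test_that("chain identifiers split a PDB into molecules like a reference parser", {
  hp <- build_helix_pair(6, 20, 40)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure(hp, path)
  res <- suppressMessages(read_structure(path))
  expect_equal(nrow(res$topology$molecules), 2)
  # independent route: bio3d's chain field on the same file
  ref <- bio3d::read.pdb(path, verbose = FALSE)
  expect_equal(length(unique(ref$atom$chain)), 2)
  expect_equal(as.integer(factor(ref$atom$chain, unique(ref$atom$chain))),
               res$topology$atoms$mol)
})

test_that("multi-model PDB yields one frame per MODEL and round-trips", {
  A <- build_helix(8)
  B <- zigzag_chain(8)
  tr <- gen_two_state(A, B, dwell = 2, n_frames = 3, seed = 1)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory(tr, path)
  res <- suppressMessages(read_structure(path))
  expect_equal(n_frames(res$trajectory), 3)
  # PDB stores 3 decimals in Angstrom -> 1e-4 nm round-trip precision
  expect_lt(max(abs(res$trajectory$xyz - tr$xyz)), 1e-4)
})

test_that("DCD round trip preserves positions and boxes within format precision", {
  tr <- gen_brownian(8, 1e-3, 1, 15, seed = 3)
  path <- withr::local_tempfile(fileext = ".dcd")
  write_dcd(tr, path)
  rt <- read_dcd(path)
  expect_lt(max(abs(rt$xyz - tr$xyz)), 1e-5)  # 32-bit float precision
  expect_equal(rt$boxes, tr$boxes, tolerance = 1e-6)
  # independent reader on the same bytes
  ref <- bio3d::read.dcd(path, verbose = FALSE)
  expect_lt(max(abs(ref / 10 - tr$xyz)), 1e-5)
  # per-frame Rg identical before/after serialization
  full <- read_trajectory(path, tr$topology, dt = 1)
  expect_equal(rg_series(full), rg_series(tr), tolerance = 1e-4)
})

test_that("read_trajectory rejects an atom-count mismatch", {
  tr <- gen_brownian(8, 1e-3, 1, 5, seed = 3)
  path <- withr::local_tempfile(fileext = ".dcd")
  write_dcd(tr, path)
  wrong <- gen_brownian(9, 1e-3, 1, 2, seed = 1)$topology
  expect_error(read_trajectory(path, wrong), "mismatch")
})

test_that("minimum image distance equals the exhaustive 27-image minimum", {
  expect_equal(minimum_image_distance(c(0.1, 0, 0), c(4.9, 0, 0), c(5, 5, 5)),
               0.2, tolerance = 1e-12)
  expect_equal(minimum_image_distance(c(1, 2, 3), c(1, 2, 3), c(5, 5, 5)), 0)
  expect_error(minimum_image_distance(c(0, 0, 0), c(1, 1, 1), c(5, 0, 5)),
               "positive")
  set.seed(11)
  box <- c(4, 6, 9)
  # points in the primary box, where the 27-image enumeration is exhaustive
  for (k in 1:200) {
    p1 <- runif(3) * box; p2 <- runif(3) * box
    expect_equal(minimum_image_distance(p1, p2, box),
                 min_image_27(p1, p2, box), tolerance = 1e-10)
  }
  # shifting either point by whole boxes never changes the distance
  for (k in 1:20) {
    p1 <- runif(3) * box; p2 <- runif(3) * box
    expect_equal(minimum_image_distance(p1, p2 + c(2, -1, 3) * box, box),
                 minimum_image_distance(p1, p2, box), tolerance = 1e-10)
  }
})

test_that("unwrap removes periodic jumps and is inverted by wrapping", {
  x <- rbind(c(4.9, 1, 1), c(0.1, 1, 1))
  un <- unwrap_series(x, c(5, 5, 5))
  expect_equal(un[2, 1], 5.1, tolerance = 1e-12)
  # stationary particle untouched
  xs <- matrix(rep(c(2, 2, 2), 10), ncol = 3, byrow = TRUE)
  expect_equal(unwrap_series(xs, c(5, 5, 5)), xs)
  # unwrap then wrap reproduces the original wrapped series
  set.seed(4)
  tr <- gen_brownian(1, 5e-3, 1, 500, box = c(3, 3, 3), seed = 4)
  wrapped <- matrix(tr$xyz[, 1:3], ncol = 3)
  un <- unwrap_series(wrapped, tr$boxes)
  expect_lt(max(abs(wrap_coords(un, c(3, 3, 3)) - wrapped)), 1e-9)
})

test_that("wrapped MSD plateaus while unwrapped MSD keeps growing", {
  tr <- gen_brownian(20, 2e-3, 1, 4000, box = c(3, 3, 3), seed = 9)
  coms <- lapply(seq_len(n_atoms(tr)), function(i) tr$xyz[, (3 * i - 2):(3 * i)])
  un <- lapply(coms, unwrap_series, boxes = tr$boxes)
  m_un <- msd(un, times = tr$times, window = 1500)
  m_wr <- msd(coms, times = tr$times, window = 1500)
  tail_un <- tail(m_un$msd, 3)
  tail_wr <- tail(m_wr$msd, 3)
  expect_gt(mean(tail_un), 6 * 2e-3 * 1200)     # linear growth ~ 6 D t
  expect_lt(mean(tail_wr), 3 * 3^2 / 4)         # bounded by the box
  expect_error(msd(coms, times = tr$times, box = c(3, 3, 3)), "wrapped")
})
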