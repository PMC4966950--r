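test_that("contact occupancy finds planted pairs and respects symmetry", {
  tr <- gen_random_coil(50, 120, planted_pairs = rbind(c(5, 40)), seed = 3)
  cm <- contact_map(tr, 1)
  i <- which(cm$groupA$resid == 4); j <- which(cm$groupA$resid == 39)
  expect_gte(cm$occupancy[i, j], 0.95)
  occ <- cm$occupancy
  expect_equal(occ, t(occ))
  expect_true(all(is.na(diag(occ))))
  expect_true(all(occ[!is.na(occ)] >= 0 & occ[!is.na(occ)] <= 1))
})

test_that("chains beyond the cutoff give an all-zero inter map", {
  h <- build_helix(8)
  far <- rbind(h, sweep(h, 2, c(10, 0, 0), "+"))
  top <- mdcrowd:::.bead_topology(c(8L, 8L))
  tr <- new_trajectory(top, matrix(as.vector(t(far)), 1))
  cm <- contact_map(tr, 1, 2)
  expect_equal(sum(cm$occupancy), 0)
})

test_that("contact maps are invariant to periodic re-wrapping", {
  tr <- gen_random_coil(30, 40, seed = 6)
  box <- c(4, 4, 4)
  shifted <- sweep(tr$xyz, 2, rep(c(3.8, 0, 0), 30), "+")  # straddle +x face
  un <- new_trajectory(tr$topology, shifted, boxes = box)
  wrapped_xyz <- t(apply(shifted, 1, function(row) {
    as.vector(t(wrap_coords(matrix(row, ncol = 3, byrow = TRUE), box)))
  }))
  wr <- new_trajectory(tr$topology, wrapped_xyz, boxes = box)
  expect_equal(contact_map(wr, 1)$occupancy, contact_map(un, 1)$occupancy)
})

test_that("the explored rule is strict at five frames", {
  # residues 1 and 5 of a 6-bead chain touch in exactly k frames
  make_traj <- function(k, n_frames = 12) {
    base <- cbind(2.0 * (0:5), 0, 0)            # well separated: no contacts
    touch <- base; touch[5, ] <- base[1, ] + c(0.5, 0, 0)
    frames <- c(replicate(k, touch, simplify = FALSE),
                replicate(n_frames - k, base, simplify = FALSE))
    beads_traj(frames)
  }
  ex5 <- explored_contacts(make_traj(5))
  ex6 <- explored_contacts(make_traj(6))
  expect_equal(ex5$count, 0)
  expect_equal(ex6$count, 1)
  # possible pairs exclude |i-j| <= 2: choose(6,2)=15 minus 9 near-diagonal
  expect_equal(ex6$possible, 6)
})

test_that("explored contacts grow with trajectory length and beat any frame", {
  tr <- gen_random_coil(25, 150, seed = 8)
  ex_short <- explored_contacts(subset_trajectory(tr, frames = 1:50),
                                min_frames = 2)
  ex_long <- explored_contacts(tr, min_frames = 2)
  expect_gte(ex_long$count, ex_short$count)
  cm <- contact_map(tr, 1)
  per_frame_frac <- cm$frame_events / ex_long$possible
  expect_gt(explored_contacts(tr, min_frames = 0)$fraction,
            max(per_frame_frac[-which.max(per_frame_frac)]) * 0.999)
})

test_that("interprotein fraction spans the isolated and interdigitated limits", {
  # isolated chain: 0 percent
  tr <- gen_random_coil(20, 30, seed = 4)
  top2 <- mdcrowd:::.bead_topology(c(20L, 20L))
  far <- new_trajectory(top2, cbind(tr$xyz, tr$xyz + 50))
  intra <- contact_map(far, 1)
  inter <- contact_map(far, 1, 2)
  expect_equal(interprotein_fraction(intra, inter)$percent, 0)
  # two interleaved extended chains, no intra contacts: 100 percent
  a <- cbind(0.9 * (0:9), 0, 0)
  b <- sweep(a, 2, c(0.45, 0.3, 0), "+")
  tr2 <- beads_traj(list(rbind(a, b)))
  tr2 <- new_trajectory(mdcrowd:::.bead_topology(c(10L, 10L)), tr2$xyz)
  intra2 <- contact_map(tr2, 1)
  inter2 <- contact_map(tr2, 1, 2)
  expect_equal(sum(intra2$frame_events), 0)
  expect_equal(interprotein_fraction(intra2, inter2)$percent, 100)
})

test_that("interprotein fraction matches a brute-force event recount", {
  cb <- build_crowded_box(data.frame(length = c(12, 10), kind = c("helix", "coil"),
                                     copies = c(2, 2)), 150, seed = 5)
  jig <- function(tr, k) {
    set.seed(k)
    xyz <- do.call(rbind, lapply(1:15, function(f)
      tr$xyz[1, ] + rnorm(ncol(tr$xyz), sd = 0.05)))
    new_trajectory(tr$topology, xyz, boxes = matrix(tr$boxes[1, ], 15, 3,
                                                    byrow = TRUE))
  }
  tr <- jig(cb, 77)
  intra <- contact_map(tr, 1)
  inter <- contact_map(tr, 1, 2:4)
  got <- interprotein_fraction(intra, inter)
  # independent recount from raw minimum-image distances
  mols <- tr$topology$atoms$mol
  resid <- tr$topology$atoms$resid
  box <- tr$boxes[1, ]
  fracs <- c()
  for (f in seq_len(n_frames(tr))) {
    x <- frame_coords(tr, f)
    n_inter <- 0; n_intra <- 0
    for (i in which(mols == 1)) for (j in seq_len(nrow(x))) {
      if (j <= i && mols[j] == 1) next
      d <- min_image_27(x[i, ], x[j, ], box)
      if (d <= 0.8) {
        if (mols[j] == 1) {
          if (abs(resid[i] - resid[j]) > 2) n_intra <- n_intra + 1
        } else n_inter <- n_inter + 1
      }
    }
    if (n_inter + n_intra > 0)
      fracs <- c(fracs, 100 * n_inter / (n_inter + n_intra))
  }
  expect_equal(got$percent, mean(fracs), tolerance = 1e-9)
})

test_that("class composition is occupancy-weighted with a sequence background", {
  # all-ALA chain: everything hydrophobic
  a <- cbind(0.9 * (0:9), 0, 0)
  b <- sweep(a, 2, c(0.45, 0.3, 0), "+")
  tr <- new_trajectory(mdcrowd:::.bead_topology(c(10L, 10L)),
                       matrix(as.vector(t(rbind(a, b))), 1))
  comp <- class_composition(contact_map(tr, 1, 2))
  expect_equal(unname(comp$composition[["H"]]), 100)
  expect_equal(unname(comp$background[["H"]]), 100)
  # zero contacts: explicit empty flag
  far <- new_trajectory(mdcrowd:::.bead_topology(c(10L, 10L)),
                        matrix(as.vector(t(rbind(a, a + 100))), 1))
  comp0 <- class_composition(contact_map(far, 1, 2))
  expect_true(comp0$empty)
  expect_true(all(is.na(comp0$composition)))
  # a single dominant LYS-GLU contact drives the charged share to 100
  resn1 <- rep("ALA", 5); resn1[3] <- "LYS"
  resn2 <- rep("ALA", 5); resn2[3] <- "GLU"
  c1 <- cbind(0.9 * (0:4), 0, 0)
  c2 <- sweep(c1, 2, c(0, 4, 0), "+"); c2[3, ] <- c1[3, ] + c(0, 0.5, 0)
  top <- mdcrowd:::.bead_topology(c(5L, 5L), resnames = list(resn1, resn2))
  trk <- new_trajectory(top, matrix(as.vector(t(rbind(c1, c2))), 1))
  compk <- class_composition(contact_map(trk, 1, 2))
  expect_equal(unname(compk$composition[["C"]]), 100)
  # nonstandard residues fall into class U
  sch <- residue_class_scheme()
  expect_true(all(sch %in% c("H", "P", "C")))
  expect_equal(length(sch), 20)
})

test_that("contact differences are antisymmetric and localize planted changes", {
  trA <- gen_random_coil(30, 80, planted_pairs = rbind(c(4, 25)), seed = 10)
  trB <- gen_random_coil(30, 80, seed = 10)
  mA <- contact_map(trA, 1); mB <- contact_map(trB, 1)
  d0 <- contact_difference(mA, mA)
  expect_true(all(d0[!is.na(d0)] == 0))
  d <- contact_difference(mA, mB)
  expect_equal(d, -contact_difference(mB, mA))
  i <- which(mA$groupA$resid == 3); j <- which(mA$groupA$resid == 24)
  expect_gt(d[i, j], 0.8)
  expect_true(all(abs(d[!is.na(d)]) <= 1))
  expect_error(contact_difference(mA, contact_map(gen_random_coil(10, 5, seed = 1), 1)),
               "shape")
})

test_that("native overlap reads reference contacts at matched thresholds", {
  # trajectory frozen at the reference: overlap 1 at any threshold < 1
  ref <- gen_random_coil(20, 1, planted_pairs = rbind(c(3, 15)), seed = 2)
  frozen <- new_trajectory(ref$topology,
                           ref$xyz[rep(1, 10), , drop = FALSE])
  m <- contact_map(frozen, 1)
  expect_equal(native_overlap(m, ref, threshold = 0.9)$overlap, 1)
  # chains never in contact: overlap 0
  a <- cbind(0.9 * (0:9), 0, 0)
  top2 <- mdcrowd:::.bead_topology(c(10L, 10L))
  ref2 <- new_trajectory(top2, matrix(as.vector(t(rbind(a, sweep(a, 2, c(0.45, 0.3, 0), "+")))), 1))
  far2 <- new_trajectory(top2, matrix(as.vector(t(rbind(a, a + 100))), nrow = 1)[rep(1, 8), ])
  m2 <- contact_map(far2, 1, 2)
  expect_equal(native_overlap(m2, ref2)$overlap, 0)
  # 50% occupancy: present above threshold 0.25, absent above 0.75
  touch <- ref$xyz[1, ]
  apart <- as.vector(t(frame_coords(ref, 1) + outer(0:19 >= 10, c(5, 0, 0))))
  half <- new_trajectory(ref$topology,
                         rbind(matrix(touch, 5, length(touch), byrow = TRUE),
                               matrix(apart, 5, length(touch), byrow = TRUE)))
  mh <- contact_map(half, 1)
  i <- which(mh$groupA$resid == 2); j <- which(mh$groupA$resid == 14)
  expect_equal(mh$occupancy[i, j], 0.5)
  ov25 <- native_overlap(mh, ref, threshold = 0.25)
  ov75 <- native_overlap(mh, ref, threshold = 0.75)
  expect_equal(contact_map(ref, 1)$occupancy[i, j], 1)
  expect_equal(ov25$overlap, 1)
  expect_gt(ov25$overlap, ov75$overlap)
})

test_that("occupancy is monotone in the cutoff", {
  tr <- gen_random_coil(25, 60, seed = 14)
  occ6 <- contact_map(tr, 1, cutoff = 0.6)$occupancy
  occ8 <- contact_map(tr, 1, cutoff = 0.8)$occupancy
  keep <- !is.na(occ6)
  expect_true(all(occ8[keep] >= occ6[keep]))
})
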