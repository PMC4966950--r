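# All generators route randomness through one local RNG seeded per call
# (no global state leaks), and attach their ground truth as a manifest
# attribute so tests never re-derive it.

.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Ground-truth manifest of a synthetic trajectory
#' @param trajectory a generator-produced `Trajectory`
#' @return list of generator parameters and planted truth
#' @export
ground_truth <- function(trajectory) attr(trajectory, "ground_truth")

#' Write the ground-truth manifest as JSON
#' @param trajectory a generator-produced `Trajectory`
#' @param path output JSON path
#' @return `path`, invisibly
#' @export
write_manifest <- function(trajectory, path) {
  gt <- ground_truth(trajectory)
  if (is.null(gt)) stop("trajectory carries no ground-truth manifest")
  jsonlite::write_json(gt, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

# uniform random rotation matrix (QR of a Gaussian matrix, det +1)
.random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# random unit vectors, n x 3
.random_units <- function(n) {
  v <- matrix(stats::rnorm(3 * n), n, 3)
  v / sqrt(rowSums(v^2))
}

#' Brownian point-particle trajectory
#'
#' Independent random walkers with per-step displacement Normal(0, 2 D dt)
#' per axis, wrapped into an orthorhombic box: the ground truth for the
#' Einstein-relation diffusion estimator.
#'
#' @param n_particles number of particles
#' @param D true self-diffusion coefficient, nm^2/ps
#' @param dt time step, ps
#' @param n_steps number of steps (frames = n_steps + 1)
#' @param box length-3 box edges, nm
#' @param seed RNG seed
#' @return a `Trajectory` (one molecule per particle) with ground truth
#'   `list(D_true, dt, ...)`
#' @export
gen_brownian <- function(n_particles, D, dt, n_steps, box = c(10, 10, 10),
                         seed = 1) {
  if (D < 0 || dt <= 0) stop("require D >= 0 and dt > 0")
  if (sqrt(2 * D * dt) >= min(box) / 2)
    stop("per-step displacement scale exceeds half a box edge")
  .with_seed(seed, {
    x0 <- cbind(stats::runif(n_particles, 0, box[1]),
                stats::runif(n_particles, 0, box[2]),
                stats::runif(n_particles, 0, box[3]))
    nfr <- n_steps + 1L
    xyz <- matrix(0, nfr, 3L * n_particles)
    cur <- x0
    xyz[1, ] <- .flatten_coords(cur)
    sd_step <- sqrt(2 * D * dt)
    for (f in 2:nfr) {
      cur <- cur + matrix(stats::rnorm(3 * n_particles, sd = sd_step),
                          n_particles, 3)
      cur <- wrap_coords(cur, box)
      xyz[f, ] <- .flatten_coords(cur)
    }
    top <- .bead_topology(rep(1L, n_particles), atom_name = "COM")
    top$atoms$backbone <- FALSE
    tr <- new_trajectory(top, xyz, times = (seq_len(nfr) - 1) * dt,
                         boxes = box)
    attr(tr, "ground_truth") <- list(generator = "brownian", D_true = D,
                                     dt = dt, n_steps = n_steps,
                                     n_particles = n_particles,
                                     box = box, seed = seed)
    tr
  })
}

#' Gaussian ensemble with a planted covariance spectrum
#'
#' Frames drawn from a zero-mean Gaussian whose mass-weighted covariance has
#' exactly the requested eigenvalues (in a random orthogonal eigenbasis):
#' the ground truth for the quasi-harmonic entropy estimator.
#'
#' @param eigenvalues planted mass-weighted covariance eigenvalues, amu
#'   nm^2; length must be a multiple of 3 (3 coordinates per atom)
#' @param masses per-atom masses, amu (length `length(eigenvalues)/3`), or
#'   per-coordinate masses (length `length(eigenvalues)`, constant within
#'   each atom triplet)
#' @param temperature kelvin, recorded in the manifest
#' @param n_frames number of frames (>= 10 x dimension recommended)
#' @param seed RNG seed
#' @return a `Trajectory` with ground truth `list(eigenvalues, ...)`
#' @export
gen_gaussian_ensemble <- function(eigenvalues, masses, temperature = 300,
                                  n_frames, seed = 1) {
  dim <- length(eigenvalues)
  if (dim %% 3 != 0) stop("eigenvalue count must be a multiple of 3")
  if (any(eigenvalues <= 0)) stop("eigenvalues must be > 0 (singular covariance)")
  if (length(masses) == dim) {
    m3 <- matrix(masses, nrow = 3)
    if (any(abs(sweep(m3, 2, m3[1, ])) > 1e-12))
      stop("per-coordinate masses must be constant within each atom")
    masses <- m3[1, ]
  }
  if (length(masses) != dim / 3)
    stop("need one mass per atom (eigenvalue count / 3)")
  .with_seed(seed, {
    Q <- qr.Q(qr(matrix(stats::rnorm(dim * dim), dim, dim)))
    y <- matrix(stats::rnorm(n_frames * dim), n_frames, dim)
    y <- sweep(y, 2, sqrt(eigenvalues), "*")
    u <- y %*% t(Q)                       # mass-weighted coordinates
    sqm <- rep(sqrt(masses), each = 3)
    xyz <- sweep(u, 2, sqm, "/")
    top <- .bead_topology(rep(1L, dim / 3), mass = masses[1], atom_name = "X")
    top$atoms$mass <- rep(masses, each = 1)
    tr <- new_trajectory(top, xyz)
    attr(tr, "ground_truth") <- list(generator = "gaussian_ensemble",
                                     eigenvalues = eigenvalues,
                                     masses = masses,
                                     temperature = temperature,
                                     n_frames = n_frames, seed = seed)
    tr
  })
}

#' Ideal alpha-helical Calpha trace
#'
#' Calpha positions on a helix of radius 0.23 nm with the given rise and
#' twist per residue, axis along +z. With the defaults the consecutive
#' Calpha-Calpha distance is about 0.38 nm and the i to i+3 distance about
#' 0.505 nm, as in real alpha helices.
#'
#' @param n_res number of residues (>= 4)
#' @param rise rise per residue, nm (default 0.15)
#' @param twist twist per residue, degrees (default 100)
#' @param radius helix radius, nm (default 0.23)
#' @return n_res x 3 coordinate matrix (nm)
#' @export
build_helix <- function(n_res, rise = 0.15, twist = 100, radius = 0.23) {
  if (n_res < 4) stop("a helix needs at least 4 residues")
  i <- seq_len(n_res) - 1
  th <- i * twist * pi / 180
  cbind(radius * cos(th), radius * sin(th), i * rise)
}

#' Two-helix fixture with planted relative orientation
#'
#' Helix 1 lies on the +z axis; helix 2 is an identical helix rotated so
#' its axis points along the planted (elevation, azimuth) in the frame
#' z = helix-1 axis, x = lab x. Optional isotropic Gaussian noise is added
#' per atom. The planted angles are the ground truth for
#' [elevation_azimuth()] recovery.
#'
#' @param n_res residues per helix
#' @param elevation,azimuth planted angles in degrees (elevation in
#'   \[-90, 90\], azimuth in (-180, 180\])
#' @param noise_sigma per-atom isotropic noise, nm (default 0)
#' @param separation center-to-center offset of helix 2 along x, nm
#' @param seed RNG seed (used only when noise_sigma > 0)
#' @return single-frame `Trajectory` with two molecules and ground truth
#'   `list(elevation, azimuth, ...)`
#' @export
build_helix_pair <- function(n_res = 18, elevation = 0, azimuth = 0,
                             noise_sigma = 0, separation = 1.5, seed = 1) {
  if (elevation < -90 || elevation > 90) stop("elevation outside [-90, 90]")
  if (azimuth <= -180 || azimuth > 180) stop("azimuth outside (-180, 180]")
  h <- build_helix(n_res)
  h1 <- sweep(h, 2, colMeans(h))
  # the measured (principal-axis) vector of a finite helix is tilted slightly
  # off the geometric axis, so the planted angles are defined in the frame of
  # the *measured* helix-1 axis: z = helix_vector(h1), x = lab x perp to z.
  # Helix 2 is helix 1 rotated so its measured axis lands exactly on the
  # planted direction, making the angles recoverable at any helix length.
  z1 <- helix_vector(h1)
  xp <- c(1, 0, 0) - z1[1] * z1
  xp <- xp / sqrt(sum(xp^2))
  yp <- c(z1[2] * xp[3] - z1[3] * xp[2],
          z1[3] * xp[1] - z1[1] * xp[3],
          z1[1] * xp[2] - z1[2] * xp[1])
  e <- elevation * pi / 180; a <- azimuth * pi / 180
  target <- cos(e) * cos(a) * xp + cos(e) * sin(a) * yp + sin(e) * z1
  # rotation taking z1 to the target direction (about z1 x target)
  v <- c(z1[2] * target[3] - z1[3] * target[2],
         z1[3] * target[1] - z1[1] * target[3],
         z1[1] * target[2] - z1[2] * target[1])
  s <- sqrt(sum(v^2)); cth <- sum(z1 * target)
  R <- if (s < 1e-12) {
    if (cth > 0) diag(3) else {
      # antipodal: rotate 180 degrees about xp
      2 * outer(xp, xp) - diag(3)
    }
  } else {
    K <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
    diag(3) + K + K %*% K * ((1 - cth) / s^2)
  }
  h2 <- h1 %*% t(R)
  h2 <- sweep(h2, 2, c(separation, 0, 0), "+")
  x <- rbind(h1, h2)
  if (noise_sigma > 0)
    x <- .with_seed(seed,
                    x + matrix(stats::rnorm(length(x), sd = noise_sigma),
                               nrow(x), 3))
  top <- .bead_topology(c(n_res, n_res))
  tr <- new_trajectory(top, matrix(.flatten_coords(x), nrow = 1))
  attr(tr, "ground_truth") <- list(generator = "helix_pair",
                                   elevation = elevation, azimuth = azimuth,
                                   noise_sigma = noise_sigma,
                                   frame_plane = c(1, 0, 0),
                                   n_res = n_res, seed = seed)
  tr
}

# one freely jointed chain conformation, bond length exact
.fjc_frame <- function(n_res, bond) {
  steps <- .random_units(n_res - 1) * bond
  rbind(c(0, 0, 0), apply(steps, 2, cumsum))
}

# feasible initial chain for planted contacts: random walk forced towards
# the restraint anchor whenever the remaining steps could not close it
.restrained_initial <- function(n_res, bond, pairs, d_target) {
  x <- matrix(0, n_res, 3)
  for (k in 2:n_res) {
    # nearest open restraint ending at or after k
    cand <- pairs[pairs[, 1] < k & pairs[, 2] >= k, , drop = FALSE]
    step <- .random_units(1) * bond
    if (nrow(cand)) {
      j <- cand[which.min(cand[, 2]), ]
      anchor <- x[j[1], ]
      steps_left <- j[2] - k
      trial <- x[k - 1, ] + step
      if (sqrt(sum((trial - anchor)^2)) > steps_left * bond + d_target) {
        dir <- anchor - x[k - 1, ]
        dir <- dir / max(sqrt(sum(dir^2)), 1e-12)
        step <- dir * bond
      }
    }
    x[k, ] <- x[k - 1, ] + step
  }
  x
}

# harmonic flat-bottom restraint energy (kT units)
.restraint_energy <- function(x, pairs, d0, k_spring) {
  if (nrow(pairs) == 0) return(0)
  d <- sqrt(rowSums((x[pairs[, 1], , drop = FALSE] -
                       x[pairs[, 2], , drop = FALSE])^2))
  sum(0.5 * k_spring * pmax(0, d - d0)^2)
}

#' Freely jointed Calpha coil, optionally with planted contacts
#'
#' Without planted pairs, every frame is an independent freely jointed
#' chain (consecutive Calpha distance exactly `bond`). With planted pairs,
#' frames are sampled by a pivot Monte Carlo walk under flat-bottom
#' harmonic restraints that hold each planted pair within the contact
#' cutoff in at least ~95% of frames; bond lengths stay exact because pivot
#' moves are rigid rotations.
#'
#' @param n_res chain length
#' @param n_frames number of frames
#' @param bond Calpha-Calpha bond length, nm (default 0.38)
#' @param planted_pairs optional 2-column matrix of 1-based residue pairs
#'   to hold in contact; pairs must be separated by >= 3 residues
#' @param seed RNG seed
#' @param d0 flat-bottom restraint onset, nm (default 0.5)
#' @param k_spring restraint stiffness, kT/nm^2 (default 200)
#' @param moves_per_frame pivot moves between stored frames (default n_res)
#' @return a `Trajectory` (single molecule of `CA` beads) with ground truth
#'   `list(planted_pairs, ...)`
#' @export
gen_random_coil <- function(n_res, n_frames, bond = 0.38,
                            planted_pairs = NULL, seed = 1, d0 = 0.5,
                            k_spring = 200, moves_per_frame = n_res) {
  pairs <- if (is.null(planted_pairs)) matrix(0L, 0, 2) else {
    p <- matrix(as.integer(planted_pairs), ncol = 2)
    p <- t(apply(p, 1, sort))
    if (any(p[, 2] - p[, 1] < 3))
      stop("planted pairs must be separated by at least 3 residues")
    if (any(p < 1) || any(p > n_res)) stop("planted pair out of range")
    p
  }
  .with_seed(seed, {
    xyz <- matrix(0, n_frames, 3L * n_res)
    if (nrow(pairs) == 0) {
      for (f in seq_len(n_frames))
        xyz[f, ] <- .flatten_coords(.fjc_frame(n_res, bond))
    } else {
      x <- .restrained_initial(n_res, bond, pairs, d0)
      E <- .restraint_energy(x, pairs, d0, k_spring)
      if (!all(sqrt(rowSums((x[pairs[, 1], , drop = FALSE] -
                               x[pairs[, 2], , drop = FALSE])^2)) <
               (pairs[, 2] - pairs[, 1]) * bond))
        stop("infeasible restraint set")
      pivot <- function(x, E) {
        p <- sample(2:(n_res - 1), 1)
        ang <- stats::rnorm(1, sd = 0.5)
        ax <- as.numeric(.random_units(1))
        K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0),
                    3, 3)
        R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * K %*% K
        xn <- x
        tail_idx <- (p + 1):n_res
        xn[tail_idx, ] <- sweep(sweep(x[tail_idx, , drop = FALSE], 2, x[p, ]) %*%
                                  t(R), 2, x[p, ], "+")
        En <- .restraint_energy(xn, pairs, d0, k_spring)
        if (En <= E || stats::runif(1) < exp(E - En)) list(x = xn, E = En)
        else list(x = x, E = E)
      }
      for (b in seq_len(5 * n_res)) {
        st <- pivot(x, E); x <- st$x; E <- st$E
      }
      for (f in seq_len(n_frames)) {
        for (mv in seq_len(moves_per_frame)) {
          st <- pivot(x, E); x <- st$x; E <- st$E
        }
        xyz[f, ] <- .flatten_coords(x)
      }
    }
    tr <- new_trajectory(.bead_topology(n_res), xyz)
    attr(tr, "ground_truth") <- list(generator = "random_coil",
                                     n_res = n_res, bond = bond,
                                     planted_pairs = pairs, d0 = d0,
                                     seed = seed)
    tr
  })
}

#' Two-state switching trajectory
#'
#' A hidden two-state Markov chain (switch probability 1/dwell per frame)
#' selects one of two conformers; the emitted frame is the conformer plus
#' isotropic Gaussian noise. Ground truth carries the hidden state
#' sequence, so cluster assignments and conformational-change times can be
#' checked exactly.
#'
#' @param conformer_a,conformer_b n x 3 coordinate matrices; their RMSD
#'   must exceed `2 * cluster_cutoff`
#' @param dwell mean dwell time in frames
#' @param n_frames number of frames
#' @param noise_sigma per-atom noise, nm (must stay below
#'   `cluster_cutoff / 4`)
#' @param cluster_cutoff the clustering cutoff the fixture is designed for
#'   (default 0.15 nm; used only for validation)
#' @param dt frame spacing, ps (default 1)
#' @param seed RNG seed
#' @return a `Trajectory` with ground truth `list(states, dwell, ...)`
#' @export
gen_two_state <- function(conformer_a, conformer_b, dwell, n_frames,
                          noise_sigma = 0, cluster_cutoff = 0.15, dt = 1,
                          seed = 1) {
  A <- as.matrix(conformer_a); B <- as.matrix(conformer_b)
  if (!all(dim(A) == dim(B))) stop("conformers must have equal dimensions")
  sep <- .cpp_pairwise_rmsd(rbind(.flatten_coords(A), .flatten_coords(B)))[1, 2]
  if (sep <= 2 * cluster_cutoff)
    stop(sprintf("conformer RMSD %.3f nm must exceed 2 x cutoff = %.3f nm",
                 sep, 2 * cluster_cutoff))
  if (noise_sigma >= cluster_cutoff / 4)
    stop("noise_sigma must stay below cutoff / 4")
  .with_seed(seed, {
    switches <- stats::runif(n_frames - 1) < 1 / dwell
    states <- cumsum(c(1L, as.integer(switches))) %% 2L  # 0 = A, 1 = B
    states <- states + 1L  # 1 = A, 2 = B ... keep 1/2 labels
    n_at <- nrow(A)
    xyz <- matrix(0, n_frames, 3L * n_at)
    for (f in seq_len(n_frames)) {
      x <- if (states[f] == 1L) A else B
      if (noise_sigma > 0)
        x <- x + matrix(stats::rnorm(3 * n_at, sd = noise_sigma), n_at, 3)
      xyz[f, ] <- .flatten_coords(x)
    }
    tr <- new_trajectory(.bead_topology(n_at), xyz,
                         times = (seq_len(n_frames) - 1) * dt)
    attr(tr, "ground_truth") <- list(generator = "two_state",
                                     states = states, dwell = dwell,
                                     n_transitions = sum(diff(states) != 0),
                                     conformer_rmsd = sep,
                                     noise_sigma = noise_sigma, dt = dt,
                                     seed = seed)
    tr
  })
}

#' Crowded box of bead chains at a target mass concentration
#'
#' Builds helical and/or coil Calpha chains, picks the cubic box edge so
#' that total chain mass over box volume equals the target concentration
#' (amu -> g and nm^3 -> L), and places the chains with random positions
#' and orientations subject to a minimum-image overlap threshold between
#' Calpha atoms of different chains.
#'
#' @param chains data.frame with columns `length` (residues), `kind`
#'   (`"helix"` or `"coil"`) and `copies`
#' @param concentration target concentration in g/L (> 0)
#' @param residue_mass mass per residue in amu (default 110, an average
#'   residue)
#' @param min_sep minimum allowed inter-chain Calpha distance, nm
#'   (default 0.3)
#' @param seed RNG seed
#' @param max_tries placement attempts per chain before giving up
#'   (default 500)
#' @return single-frame `Trajectory` (one molecule per chain, with box)
#'   with ground truth `list(achieved_concentration, box_edge, ...)`
#' @export
build_crowded_box <- function(chains, concentration, residue_mass = 110,
                              min_sep = 0.3, seed = 1, max_tries = 500) {
  if (concentration <= 0) stop("target concentration must be > 0 g/L")
  lengths <- rep(chains$length, chains$copies)
  kinds <- rep(as.character(chains$kind), chains$copies)
  total_mass_g <- sum(lengths) * residue_mass * md_constants$amu_g
  volume_L <- total_mass_g / concentration
  L <- (volume_L / md_constants$nm3_L)^(1 / 3)  # nm
  .with_seed(seed, {
    placed <- list()
    for (ci in seq_along(lengths)) {
      n <- lengths[ci]
      base <- if (kinds[ci] == "helix") build_helix(n) else .fjc_frame(n, 0.38)
      base <- sweep(base, 2, colMeans(base))
      ok <- FALSE
      for (t in seq_len(max_tries)) {
        x <- base %*% t(.random_rotation())
        x <- sweep(x, 2, stats::runif(3, 0, L), "+")
        x <- wrap_coords(x, c(L, L, L))
        clash <- FALSE
        for (p in placed) {
          dmin <- min(vapply(seq_len(nrow(x)), function(i)
            min(minimum_image_distance(
              matrix(x[i, ], nrow(p), 3, byrow = TRUE), p, c(L, L, L))),
            numeric(1)))
          if (dmin < min_sep) { clash <- TRUE; break }
        }
        if (!clash) { ok <- TRUE; break }
      }
      if (!ok) stop("chain placement failed after ", max_tries,
                    " attempts (box too dense)")
      placed[[ci]] <- x
    }
    resnames <- lapply(lengths, function(n)
      sample(names(residue_class_scheme()), n, replace = TRUE))
    top <- .bead_topology(lengths, resnames = resnames, mass = residue_mass)
    xyz <- matrix(.flatten_coords(do.call(rbind, placed)), nrow = 1)
    tr <- new_trajectory(top, xyz, boxes = c(L, L, L))
    achieved <- total_mass_g / (L^3 * md_constants$nm3_L)
    if (abs(achieved - concentration) > 0.02 * concentration)
      stop("achieved concentration misses the target by more than 2%")
    attr(tr, "ground_truth") <- list(generator = "crowded_box",
                                     target_concentration = concentration,
                                     achieved_concentration = achieved,
                                     box_edge = L,
                                     total_mass_amu = sum(lengths) * residue_mass,
                                     chain_lengths = lengths,
                                     chain_kinds = kinds, seed = seed)
    tr
  })
}
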