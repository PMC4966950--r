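# Independent oracles and fixture builders. Everything here is deliberately
# written without reusing the package's computational paths, so tests compare
# two independent routes to the same quantity.

# --- minimum image: exhaustive 27-translation minimum -----------------------
min_image_27 <- function(p1, p2, box) {
  best <- Inf
  for (ix in -1:1) for (iy in -1:1) for (iz in -1:1) {
    d <- p2 + c(ix, iy, iz) * box - p1
    best <- min(best, sqrt(sum(d^2)))
  }
  best
}

# --- reference Kabsch RMSD via base svd (used by the GROMOS oracle) ---------
ref_kabsch_rmsd <- function(A, B) {
  A <- sweep(A, 2, colMeans(A)); B <- sweep(B, 2, colMeans(B))
  s <- svd(t(A) %*% B)
  d <- sign(det(s$u %*% t(s$v))); if (d == 0) d <- 1
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  sqrt(mean(rowSums((A %*% R - B)^2)))
}

# --- brute-force greedy GROMOS reference ------------------------------------
ref_gromos <- function(xyz, cutoff) {
  n <- nrow(xyz)
  as_mat <- function(v) matrix(v, ncol = 3, byrow = TRUE)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    D[i, j] <- D[j, i] <- ref_kabsch_rmsd(as_mat(xyz[i, ]), as_mat(xyz[j, ]))
  }
  nb <- D <= cutoff
  labels <- integer(n); active <- rep(TRUE, n); cl <- 0L
  centers <- integer(0)
  while (any(active)) {
    counts <- vapply(seq_len(n), function(i)
      if (active[i]) sum(nb[i, ] & active) else -1L, integer(1))
    center <- which.max(counts)           # first max = lowest index tie-break
    cl <- cl + 1L
    centers[cl] <- center
    member <- active & nb[center, ]
    labels[member] <- cl
    active[member] <- FALSE
  }
  list(labels = labels, centers = centers)
}

# --- brute-force rotation-grid RMSD minimum ---------------------------------
grid_min_rmsd <- function(A, B) {
  A <- sweep(A, 2, colMeans(A)); B <- sweep(B, 2, colMeans(B))
  eval_R <- function(R) sqrt(mean(rowSums((A %*% R - B)^2)))
  euler <- function(a, b, c) {
    Rz1 <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
    Ry <- matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3, 3)
    Rz2 <- matrix(c(cos(c), sin(c), 0, -sin(c), cos(c), 0, 0, 0, 1), 3, 3)
    Rz1 %*% Ry %*% Rz2
  }
  best <- Inf; best_abc <- c(0, 0, 0)
  scan <- function(centers, widths, steps) {
    for (a in seq(centers[1] - widths[1], centers[1] + widths[1], by = steps)) {
      for (b in seq(max(0, centers[2] - widths[2]),
                    min(pi, centers[2] + widths[2]), by = steps)) {
        for (c in seq(centers[3] - widths[3], centers[3] + widths[3],
                      by = steps)) {
          r <- eval_R(euler(a, b, c))
          if (r < best) { best <<- r; best_abc <<- c(a, b, c) }
        }
      }
    }
  }
  scan(c(0, pi / 2, 0), c(pi, pi / 2, pi), 10 * pi / 180)
  scan(best_abc, rep(6 * pi / 180, 3), 1 * pi / 180)
  scan(best_abc, rep(1 * pi / 180, 3), 0.15 * pi / 180)
  best
}

# --- analytic two-sphere SASA (spherical caps) ------------------------------
two_sphere_sasa <- function(R1, R2, d) {
  if (d >= R1 + R2) return(4 * pi * (R1^2 + R2^2))
  x1 <- (d^2 + R1^2 - R2^2) / (2 * d)
  h1 <- R1 - x1
  h2 <- R2 - (d - x1)
  (4 * pi * R1^2 - 2 * pi * R1 * h1) + (4 * pi * R2^2 - 2 * pi * R2 * h2)
}

# --- ideal backbone helix built by internal-coordinate (NeRF) placement -----
# bond lengths/angles from standard peptide geometry; phi/psi set explicitly
place_nerf <- function(a, b, c, bond, angle_deg, dih_deg) {
  ang <- angle_deg * pi / 180; dih <- -dih_deg * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  n <- c((b - a)[2] * bc[3] - (b - a)[3] * bc[2],
         (b - a)[3] * bc[1] - (b - a)[1] * bc[3],
         (b - a)[1] * bc[2] - (b - a)[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(dih), bond * sin(ang) * sin(dih))
  c + cbind(bc, m, n) %*% d2
}

build_backbone_helix <- function(n_res, phi = -60, psi = -45) {
  bNC <- 0.1458; bCAC <- 0.1525; bCN <- 0.1329
  aNCAC <- 111.0; aCACN <- 116.2; aCNCA <- 121.7
  coords <- matrix(0, 3 * n_res, 3)
  coords[1, ] <- c(0, 0, 0)                      # N1
  coords[2, ] <- c(bNC, 0, 0)                    # CA1
  coords[3, ] <- place_nerf(c(-0.1, 0.1, 0), coords[1, ], coords[2, ],
                            bCAC, aNCAC, phi)    # C1 (phi sets its dihedral)
  k <- 3
  for (r in 2:n_res) {
    Np <- place_nerf(coords[k - 2, ], coords[k - 1, ], coords[k, ],
                     bCN, aCACN, psi)
    CAp <- place_nerf(coords[k - 1, ], coords[k, ], Np, bNC, aCNCA, 180)
    Cp <- place_nerf(coords[k, ], Np, CAp, bCAC, aNCAC, phi)
    coords[k + 1, ] <- Np; coords[k + 2, ] <- CAp; coords[k + 3, ] <- Cp
    k <- k + 3
  }
  atoms <- data.frame(
    name = rep(c("N", "CA", "C"), n_res),
    element = rep(c("N", "C", "C"), n_res),
    mass = rep(c(14.007, 12.011, 12.011), n_res),
    resid = rep(seq_len(n_res) - 1L, each = 3L),
    resname = "ALA", mol = 1L,
    backbone = TRUE)
  top <- new_topology(atoms)
  new_trajectory(top, matrix(as.vector(t(coords)), nrow = 1))
}

# --- misc fixtures ----------------------------------------------------------
# extended but non-collinear chain conformation
zigzag_chain <- function(n, spacing = 0.35) {
  cbind(spacing * (seq_len(n) - 1), 0.12 * (seq_len(n) %% 2), 0)
}

# random rotation for invariance tests
rand_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# trajectory from an explicit list of n x 3 frames over a bead topology
beads_traj <- function(frames, times = NULL, boxes = NULL, resnames = NULL) {
  n <- nrow(frames[[1]])
  top <- mdcrowd:::.bead_topology(n, resnames = if (is.null(resnames)) NULL
                                  else list(resnames))
  xyz <- do.call(rbind, lapply(frames, function(x) as.vector(t(x))))
  new_trajectory(top, xyz, times = times, boxes = boxes)
}
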