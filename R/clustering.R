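#' GROMOS conformational clustering
#'
#' Greedy neighbor-count clustering of trajectory frames by pairwise
#' minimal RMSD (each pair optimally superposed before the distance is
#' taken). Iteratively, the frame with the most neighbors within `cutoff`
#' becomes a cluster center; it and its neighbors are removed and the
#' procedure repeats until every frame is assigned. Ties in neighbor count
#' are broken towards the lowest frame index, making the partition
#' deterministic.
#'
#' @param x a `Trajectory`, or an `n_frames x 3N` coordinate matrix
#' @param cutoff RMSD cutoff in nm
#' @param selection atom indices used for the RMSD (default: backbone atoms
#'   when `x` is a Trajectory, else all columns)
#' @return object of class `ClusterAssignment`: `labels` (per frame, 1-based
#'   in formation order), `centers` (frame indices), `populations`
#'   (fractions summing to 1), `cutoff`, `metric`
#' @export
gromos_cluster <- function(x, cutoff, selection = NULL) {
  xyz <- .cluster_xyz(x, selection)
  if (nrow(xyz) < 1) stop("empty input")
  res <- .cpp_gromos(xyz, cutoff)
  labels <- res$labels
  pops <- as.numeric(table(factor(labels, levels = seq_along(res$centers))))
  structure(list(labels = labels, centers = res$centers,
                 populations = pops / length(labels),
                 cutoff = cutoff, metric = "minimal pairwise RMSD (nm)"),
            class = "ClusterAssignment")
}

.cluster_xyz <- function(x, selection) {
  if (inherits(x, "Trajectory")) {
    if (is.null(selection)) {
      selection <- which(x$topology$atoms$backbone)
      if (length(selection) == 0) selection <- seq_len(n_atoms(x))
    }
    x$xyz[, .sel_cols(selection), drop = FALSE]
  } else {
    x <- as.matrix(x)
    if (!is.null(selection)) x[, .sel_cols(selection), drop = FALSE] else x
  }
}

#' @export
print.ClusterAssignment <- function(x, ...) {
  cat("ClusterAssignment:", length(x$centers), "clusters over",
      length(x$labels), "frames (cutoff", x$cutoff, "nm)\n")
  k <- min(5, length(x$centers))
  cat("  top populations:",
      paste(sprintf("%.3f", sort(x$populations, decreasing = TRUE)[1:k]),
            collapse = ", "), "\n")
  invisible(x)
}

#' Two-step GROMOS clustering across environments
#'
#' Step 1 clusters each environment's trajectory separately at `cutoff1`,
#' reducing it to cluster centers carrying their population weights. Step 2
#' pools all centers and clusters them at `cutoff2`; each joint cluster
#' reports its per-environment occupancy (each environment's weights are
#' normalized to 1, so total weight is conserved per environment).
#'
#' @param trajectories named list of `Trajectory` objects (names are
#'   environment labels, e.g. WATER / PEG / CROW-192); the same selection
#'   must be valid in all
#' @param cutoff1 step-1 cutoff in nm (default 0.15)
#' @param cutoff2 step-2 cutoff in nm (default 0.35)
#' @param selection atom indices for the RMSD (default: backbone)
#' @return list with `occupancy` (clusters x environments matrix),
#'   `centers` (data.frame: environment, frame), `step1` (list of
#'   `ClusterAssignment`), `labels` (joint label per pooled center)
#' @export
two_step_cluster <- function(trajectories, cutoff1 = 0.15, cutoff2 = 0.35,
                             selection = NULL) {
  if (is.null(names(trajectories)) || any(names(trajectories) == ""))
    stop("trajectories must be a named list (environment labels)")
  dims <- vapply(trajectories, function(t) ncol(.cluster_xyz(t, selection)),
                 numeric(1))
  if (length(unique(dims)) != 1)
    stop("selections are inconsistent across trajectories")
  envs <- names(trajectories)
  step1 <- lapply(trajectories, gromos_cluster, cutoff = cutoff1,
                  selection = selection)
  pooled <- do.call(rbind, lapply(envs, function(e) {
    .cluster_xyz(trajectories[[e]], selection)[step1[[e]]$centers, ,
                                               drop = FALSE]
  }))
  env_of <- rep(envs, vapply(step1, function(s) length(s$centers), integer(1)))
  weights <- unlist(lapply(step1, function(s) s$populations), use.names = FALSE)
  # weighted greedy GROMOS over pooled centers
  D <- .cpp_pairwise_rmsd(pooled)
  nb <- D <= cutoff2
  n <- nrow(pooled)
  labels <- integer(n)
  active <- rep(TRUE, n)
  cl <- 0L
  while (any(active)) {
    score <- vapply(seq_len(n), function(i)
      if (active[i]) sum(weights[active & nb[i, ]]) else -Inf, numeric(1))
    center <- which.max(score)  # which.max takes the first (lowest index) tie
    cl <- cl + 1L
    member <- active & nb[center, ]
    labels[member] <- cl
    active[member] <- FALSE
  }
  occ <- matrix(0, cl, length(envs), dimnames = list(NULL, envs))
  for (k in seq_len(cl)) {
    for (e in envs) {
      occ[k, e] <- sum(weights[labels == k & env_of == e])
    }
  }
  # each environment's step-1 populations already sum to 1
  list(occupancy = occ,
       centers = data.frame(environment = env_of,
                            frame = unlist(lapply(step1, function(s) s$centers),
                                           use.names = FALSE)),
       step1 = step1, labels = labels,
       cutoff1 = cutoff1, cutoff2 = cutoff2)
}

#' Conformational overlap between environments
#'
#' For each environment pair, the overlap is the sum over joint clusters of
#' the minimum of the two environments' occupancies: 1 for identical
#' occupancy vectors, 0 for disjoint cluster usage. The number of shared
#' clusters (both occupancies positive) is also reported as an alternative
#' reading.
#'
#' @param joint result of [two_step_cluster()] (or any list with an
#'   `occupancy` clusters x environments matrix)
#' @return list with `overlap` (symmetric environments x environments
#'   matrix) and `shared_clusters` (counts)
#' @export
environment_overlap <- function(joint) {
  occ <- joint$occupancy
  if (ncol(occ) < 2) stop("at least 2 environments are required")
  envs <- colnames(occ)
  ov <- matrix(1, ncol(occ), ncol(occ), dimnames = list(envs, envs))
  sh <- matrix(NA_integer_, ncol(occ), ncol(occ), dimnames = list(envs, envs))
  for (i in seq_along(envs)) for (j in seq_along(envs)) {
    ov[i, j] <- sum(pmin(occ[, i], occ[, j]))
    sh[i, j] <- sum(occ[, i] > 0 & occ[, j] > 0)
  }
  list(overlap = ov, shared_clusters = sh)
}

#' Conformational-change timing
#'
#' Clusters the trajectory with the GROMOS algorithm and labels any change
#' of cluster between consecutive frames as a large conformational change.
#' The mean inter-change time is total duration / number of transitions.
#'
#' @param trajectory a `Trajectory` with >= 2 frames
#' @param cutoff RMSD cutoff in nm (default 0.15; use 0.1 for rigid,
#'   well-folded proteins)
#' @param selection atom indices (default: all atoms)
#' @return list with `n_transitions`, `mean_time` (ps, `NA` with
#'   `no_transitions = TRUE` when the label never changes), `labels`
#' @export
conformational_change_times <- function(trajectory, cutoff = 0.15,
                                        selection = NULL) {
  if (n_frames(trajectory) < 2)
    stop("conformational_change_times needs at least 2 frames")
  if (is.null(selection)) selection <- seq_len(n_atoms(trajectory))
  cl <- gromos_cluster(trajectory, cutoff, selection)
  lab <- cl$labels
  n_tr <- sum(diff(lab) != 0)
  duration <- trajectory$times[length(trajectory$times)] - trajectory$times[1]
  list(n_transitions = n_tr,
       mean_time = if (n_tr > 0) duration / n_tr else NA_real_,
       no_transitions = n_tr == 0,
       labels = lab, cutoff = cutoff)
}
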