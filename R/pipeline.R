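#' Bundled synthetic crowding demo
#'
#' Builds a small two-environment study with known construction: the same
#' set of bead chains (one 30-residue helix, six 20-residue helices, one
#' 30-residue coil) simulated as a crowded box at the target concentration
#' and as a dilute "water" reference box. Dynamics are emulated as per-chain
#' center-of-mass random walks plus per-atom Gaussian jitter whose
#' amplitude is larger in water than under crowding (restricted dynamics),
#' with the coil chain switching between two conformers. This exercises
#' every pipeline stage; it is a statistical stand-in, not physics.
#'
#' @param seed RNG seed
#' @param n_frames frames per environment (default 120, 20-ps stride)
#' @param concentration crowded-box target, g/L (default 192)
#' @return list with `environments` (named list of `Trajectory`),
#'   `proteins` (named list of molecule ids), `disorder` (named %),
#'   `helix_defs`, `reference_env`
#' @export
make_synthetic_demo <- function(seed = 1, n_frames = 120,
                                concentration = 192) {
  chains <- data.frame(length = c(30L, 20L, 30L),
                       kind = c("helix", "helix", "coil"),
                       copies = c(1L, 6L, 1L))
  crowd_box <- build_crowded_box(chains, concentration, seed = seed)
  top <- crowd_box$topology
  n_mol <- nrow(top$molecules)
  gt_box <- ground_truth(crowd_box)
  # dilute reference: same chains re-placed in a 10x-volume box
  water_box <- build_crowded_box(chains, concentration / 10, seed = seed + 1)

  # alternative conformer per chain: bend the tail of helical chains, compact
  # the coil; structural amplitude and switching rate grow with disorder
  bend_tail <- function(x, n_tail, angle_deg) {
    p <- nrow(x) - n_tail
    ax <- c(1, 0, 0)
    a <- angle_deg * pi / 180
    K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
    R <- diag(3) + sin(a) * K + (1 - cos(a)) * K %*% K
    ti <- (p + 1):nrow(x)
    x[ti, ] <- sweep(sweep(x[ti, , drop = FALSE], 2, x[p, ]) %*% t(R), 2,
                     x[p, ], "+")
    x
  }
  jiggle <- function(base_traj, sigma_scale, D_com, dwell_scale, sub_seed) {
    .with_seed(sub_seed, {
      base <- frame_coords(base_traj, 1)
      L <- base_traj$boxes[1, ]
      mols <- base_traj$topology$atoms$mol
      # per-molecule kind: 1 = ordered, 2 = molten-globule-like, 3 = coil
      kind <- ifelse(seq_len(n_mol) == 1L, 1L,
                     ifelse(seq_len(n_mol) == n_mol, 3L, 2L))
      alt <- lapply(seq_len(n_mol), function(m) {
        xm <- base[mols == m, , drop = FALSE]
        switch(kind[m],
               bend_tail(xm, 10, 30),
               bend_tail(xm, 7, 55),
               sweep(sweep(xm, 2, colMeans(xm)) * 0.6, 2, colMeans(xm), "+"))
      })
      dwell <- c(40, 20, 10)[kind] * dwell_scale  # frames between switches
      sig_kind <- c(0.02, 0.035, 0.05)[kind] * sigma_scale
      sig <- sig_kind[mols]
      state <- rep(1L, n_mol)
      xyz <- matrix(0, n_frames, 3 * nrow(base))
      com_disp <- matrix(0, n_mol, 3)
      dt <- 20
      for (f in seq_len(n_frames)) {
        if (f > 1) {
          flip <- stats::runif(n_mol) < 1 / dwell
          state[flip] <- 3L - state[flip]
        }
        cur <- base
        for (m in which(state == 2L)) cur[mols == m, ] <- alt[[m]]
        com_disp <- com_disp + matrix(stats::rnorm(3 * n_mol,
                                                   sd = sqrt(2 * D_com * dt)),
                                      n_mol, 3)
        cur <- cur + com_disp[mols, ]
        cur <- cur + matrix(stats::rnorm(length(cur), sd = sig), nrow(base), 3)
        xyz[f, ] <- .flatten_coords(cur)
      }
      new_trajectory(base_traj$topology, xyz,
                     times = (seq_len(n_frames) - 1) * dt,
                     boxes = matrix(L, n_frames, 3, byrow = TRUE))
    })
  }
  envs <- list(
    WATER = jiggle(water_box, sigma_scale = 1.6, D_com = 1e-4,
                   dwell_scale = 0.5, sub_seed = seed + 11),
    CROW = jiggle(crowd_box, sigma_scale = 1.0, D_com = 2e-5,
                  dwell_scale = 1, sub_seed = seed + 12)
  )
  list(environments = envs,
       proteins = list(ORD = 1L, MGP = 2:7, IDP = n_mol),
       disorder = c(ORD = 8, MGP = 45, IDP = 90),
       helix_defs = list(h1 = 0:8, h2 = 10:18, h3 = 20:28),
       reference_env = "WATER",
       box_truth = gt_box)
}

.stage <- function(results, name, expr) {
  results$status[[name]] <- tryCatch({
    results$out[[name]] <- expr
    "ok"
  }, error = function(e) {
    message("stage '", name, "' failed: ", conditionMessage(e))
    paste("failed:", conditionMessage(e))
  })
  results
}

#' Run the full crowding-analysis pipeline
#'
#' Orchestrates descriptors, SASA, contacts, clustering, helix geometry,
#' diffusion, entropy and the disorder-vs-effect trend over a set of
#' environments, writing self-describing CSV/JSON reports plus a manifest.
#' Stages fail independently: an error in one is logged and the remaining
#' stages still run (the manifest records per-stage status). Outputs are
#' deterministic given the same inputs and seed and carry no timestamps, so
#' reruns are byte-identical.
#'
#' @param config a list as returned by [make_synthetic_demo()]:
#'   `environments` (named list of `Trajectory`), `proteins` (named list of
#'   molecule-id vectors), `disorder` (named %, one per protein),
#'   `reference_env`, optional `helix_defs`
#' @param out_dir output directory (created if needed)
#' @param seed RNG seed for the stochastic pieces (bootstrap, permutation)
#' @param contact_cutoff nm (default 0.8)
#' @param cluster_cutoffs two-step cutoffs, nm (default `c(0.15, 0.35)`)
#' @param change_cutoff conformational-change cutoff, nm (default 0.15)
#' @param temperature kelvin (default 300)
#' @param viscosity Pa s (default 0.89e-3)
#' @param sasa_frames number of evenly spaced frames for SASA (default 5)
#' @return invisible list with per-stage results, `status`, and
#'   `trend_table`; attribute `exit_code` is 0 when every stage succeeded
#' @export
run_pipeline <- function(config, out_dir, seed = 1,
                         contact_cutoff = 0.8,
                         cluster_cutoffs = c(0.15, 0.35),
                         change_cutoff = 0.15,
                         temperature = 300, viscosity = 0.89e-3,
                         sasa_frames = 5) {
  envs <- config$environments
  if (is.null(names(envs)) || anyDuplicated(names(envs)))
    stop("environment labels must be unique and named")
  if (any(c(contact_cutoff, cluster_cutoffs, change_cutoff) <= 0))
    stop("cutoffs must be > 0")
  proteins <- config$proteins
  ref_env <- config$reference_env %||% names(envs)[1]
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- list(out = list(), status = list())
  wcsv <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    path
  }

  # -- descriptors ----------------------------------------------------------
  res <- .stage(res, "descriptors", {
    rows <- list(); maps <- list()
    for (e in names(envs)) {
      tr <- envs[[e]]
      for (p in names(proteins)) {
        sel <- select_atoms(tr$topology, mol = proteins[[p]])
        r <- rmsd_series(tr, 1L, sel)
        g <- rg_series(tr, sel)
        fl <- rmsf(tr, sel)
        hel <- mean(vapply(proteins[[p]], function(m)
          mean(assign_secondary_structure(tr, mol = m)$helicity),
          numeric(1)))
        rows[[paste(e, p)]] <- data.frame(
          environment = e, protein = p,
          mean_rmsd_nm = mean(r), mean_rg_nm = mean(g),
          mean_rmsf_nm = mean(fl), helicity_pct = hel)
        if (p == names(proteins)[1])
          maps[[e]] <- cbind(environment = e,
                             as.data.frame(sampling_map(r, g, bins = 20,
                                                        labels = c("rmsd_nm", "rg_nm"))))
      }
    }
    list(summary_csv = wcsv(do.call(rbind, rows), "descriptors.csv"),
         map_csv = wcsv(do.call(rbind, maps), "sampling_map_rmsd_rg.csv"),
         table = do.call(rbind, rows))
  })

  # -- sasa -----------------------------------------------------------------
  res <- .stage(res, "sasa", {
    rows <- list()
    for (e in names(envs)) {
      tr <- envs[[e]]
      fr <- unique(round(seq(1, n_frames(tr), length.out = sasa_frames)))
      for (p in names(proteins)) {
        sel <- select_atoms(tr$topology, mol = proteins[[p]])
        s <- sasa_series(tr, frames = fr, selection = sel, n_points = 240)
        rows[[paste(e, p)]] <- cbind(environment = e, protein = p, s)
      }
    }
    df <- do.call(rbind, rows)
    list(csv = wcsv(df, "sasa.csv"), table = df)
  })

  # -- contacts -------------------------------------------------------------
  res <- .stage(res, "contacts", {
    all_mols <- unique(envs[[1]]$topology$atoms$mol)
    per <- list(); longs <- list()
    for (e in names(envs)) {
      tr <- envs[[e]]
      for (p in names(proteins)) {
        mols <- proteins[[p]]
        intra <- contact_map(tr, mols, mols, contact_cutoff)
        others <- setdiff(all_mols, mols)
        inter <- contact_map(tr, mols, others, contact_cutoff)
        ipf <- interprotein_fraction(intra, inter)
        exp_c <- explored_contacts(intra)
        comp <- class_composition(inter)
        per[[paste(e, p)]] <- data.frame(
          environment = e, protein = p,
          interprotein_pct = ipf$percent,
          explored_count = exp_c$count,
          explored_fraction = exp_c$fraction,
          comp_H = comp$composition[["H"]],
          comp_P = comp$composition[["P"]],
          comp_C = comp$composition[["C"]])
        if (e != ref_env)
          longs[[paste(e, p)]] <- cbind(environment = e, protein = p,
                                        as.data.frame(intra))
      }
    }
    df <- do.call(rbind, per)
    list(csv = wcsv(df, "contacts.csv"),
         maps_csv = wcsv(do.call(rbind, longs), "contact_maps.csv"),
         table = df)
  })

  # -- clustering -----------------------------------------------------------
  res <- .stage(res, "clustering", {
    rows <- list(); overlaps <- list()
    for (p in names(proteins)) {
      sel_list <- lapply(envs, function(tr)
        subset_trajectory(tr, selection = select_atoms(tr$topology,
                                                       mol = proteins[[p]])))
      joint <- two_step_cluster(sel_list, cluster_cutoffs[1],
                                cluster_cutoffs[2])
      if (length(envs) >= 2) {
        ov <- environment_overlap(joint)
        overlaps[[p]] <- cbind(protein = p, as.data.frame(as.table(ov$overlap)))
      } else {
        message("single environment: conformational overlap skipped")
      }
      for (e in names(envs)) {
        cc <- conformational_change_times(sel_list[[e]], change_cutoff)
        rows[[paste(e, p)]] <- data.frame(
          environment = e, protein = p,
          n_clusters_step1 = length(joint$step1[[e]]$centers),
          n_transitions = cc$n_transitions,
          mean_change_time_ps = cc$mean_time)
      }
    }
    df <- do.call(rbind, rows)
    out <- list(csv = wcsv(df, "clustering.csv"), table = df)
    if (length(overlaps))
      out$overlap_csv <- wcsv(do.call(rbind, overlaps),
                              "environment_overlap.csv")
    out
  })

  # -- helix geometry -------------------------------------------------------
  if (!is.null(config$helix_defs)) {
    res <- .stage(res, "helix", {
      rows <- list()
      for (e in names(envs)) {
        s <- orientation_series(envs[[e]], config$helix_defs,
                                mol = proteins[[1]][1])
        rows[[e]] <- cbind(environment = e, s)
      }
      df <- do.call(rbind, rows)
      list(csv = wcsv(df, "helix_orientation.csv"), table = df)
    })
  }

  # -- diffusion ------------------------------------------------------------
  res <- .stage(res, "diffusion", {
    rows <- list()
    for (e in names(envs)) {
      tr <- envs[[e]]
      dur <- diff(range(tr$times))
      tab <- diffusion_table(tr, groups = list(proteins = unique(tr$topology$atoms$mol)),
                             windows = dur / 2, temperature = temperature,
                             viscosity = viscosity)
      rows[[e]] <- cbind(environment = e, tab)
    }
    df <- do.call(rbind, rows)
    list(csv = wcsv(df, "diffusion.csv"), table = df)
  })

  # -- entropy --------------------------------------------------------------
  res <- .stage(res, "entropy", {
    rows <- list()
    for (p in names(proteins)) {
      covs <- lapply(envs, function(tr) {
        sel <- select_atoms(tr$topology, mol = proteins[[p]])
        mass_weighted_covariance(tr, sel, keep_deviations = TRUE)
      })
      S_ref <- quasiharmonic_entropy(covs[[ref_env]]$eigenvalues,
                                     temperature)$S_J_mol_K
      for (e in names(envs)) {
        if (e == ref_env) {
          rows[[paste(e, p)]] <- data.frame(environment = e, protein = p,
                                            S_J_mol_K = S_ref,
                                            dS_vs_ref_J_mol_K = 0,
                                            dS_se = NA_real_)
        } else {
          d <- entropy_difference(covs[[e]], covs[[ref_env]], temperature,
                                  n_boot = 20, seed = seed)
          rows[[paste(e, p)]] <- data.frame(environment = e, protein = p,
                                            S_J_mol_K = d$S_env,
                                            dS_vs_ref_J_mol_K = d$dS_J_mol_K,
                                            dS_se = d$se_J_mol_K)
        }
      }
    }
    df <- do.call(rbind, rows)
    list(csv = wcsv(df, "entropy.csv"), table = df)
  })

  # -- trend ----------------------------------------------------------------
  res <- .stage(res, "trend", {
    if (length(proteins) < 3)
      stop("disorder trend needs at least 3 proteins")
    crowd_envs <- setdiff(names(envs), ref_env)
    if (length(crowd_envs) == 0) stop("no non-reference environment present")
    get_row <- function(tab, e, p, col)
      tab[tab$environment == e & tab$protein == p, col]
    rows <- lapply(names(proteins), function(p) {
      vals <- function(col, tab) mean(vapply(crowd_envs, function(e)
        get_row(tab, e, p, col), numeric(1)))
      ref_expl <- get_row(res$out$contacts$table, ref_env, p, "explored_fraction")
      data.frame(
        protein = p,
        disorder_pct = unname(config$disorder[p]),
        interprotein_pct = vals("interprotein_pct", res$out$contacts$table),
        dS_vs_water_J_mol_K = vals("dS_vs_ref_J_mol_K", res$out$entropy$table),
        d_explored_pct = 100 * (vals("explored_fraction",
                                     res$out$contacts$table) - ref_expl),
        mean_rmsf_nm = vals("mean_rmsf_nm", res$out$descriptors$table),
        mean_change_time_ps = vals("mean_change_time_ps",
                                   res$out$clustering$table))
    })
    trend <- do.call(rbind, rows)
    stats <- disorder_trend(trend, seed = seed)
    list(csv = wcsv(trend, "trend_table.csv"),
         stats_csv = wcsv(stats, "trend_stats.csv"),
         table = trend, stats = stats)
  })

  manifest <- list(
    package = "mdcrowd",
    version = as.character(utils::packageVersion("mdcrowd")),
    seed = seed,
    parameters = list(contact_cutoff = contact_cutoff,
                      cluster_cutoffs = cluster_cutoffs,
                      change_cutoff = change_cutoff,
                      temperature = temperature, viscosity = viscosity,
                      reference_env = ref_env,
                      units = list(length = "nm", time = "ps",
                                   entropy = "J/(mol K)",
                                   diffusion = "um^2/s"),
                      residue_numbering = "1-based in all reports"),
    environments = names(envs),
    proteins = lapply(proteins, as.integer),
    stages = res$status)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  failed <- any(vapply(res$status, function(s) s != "ok", logical(1)))
  out <- list(results = res$out, status = res$status,
              trend_table = res$out$trend$table,
              manifest = file.path(out_dir, "manifest.json"))
  attr(out, "exit_code") <- if (failed) 1L else 0L
  invisible(out)
}

# all permutations of 1..n (n small)
.all_perms <- function(n) {
  if (n == 1) return(list(1L))
  sub <- .all_perms(n - 1L)
  out <- list()
  for (p in sub) for (k in seq_len(n)) {
    out[[length(out) + 1L]] <- append(p, n, after = k - 1L)
  }
  out
}

#' Disorder-vs-effect rank correlation with permutation test
#'
#' Spearman rank correlation of each effect column against the intrinsic
#' disorder column, with a permutation p-value: exhaustive over all
#' orderings when the protein count is <= 6, otherwise `n_perm` seeded
#' shuffles. The p-value is one-sided in the direction of the observed
#' correlation (so a perfect trend over 3 proteins gives p = 1/6).
#'
#' @param trend data.frame with a disorder column and numeric effect columns
#' @param disorder_col column name holding disorder % (default
#'   `"disorder_pct"`)
#' @param effect_cols effect columns (default: every other numeric column)
#' @param n_perm random permutations when exhaustive is infeasible
#'   (default 10000)
#' @param seed RNG seed for the sampled case
#' @return data.frame with `effect`, `rho`, `p_value`, `method`; constant
#'   columns yield `NA` with method `"undefined (constant column)"`
#' @export
disorder_trend <- function(trend, disorder_col = "disorder_pct",
                           effect_cols = NULL, n_perm = 10000, seed = 1) {
  if (nrow(trend) < 3) stop("at least 3 proteins are required")
  d <- trend[[disorder_col]]
  if (is.null(effect_cols)) {
    num <- vapply(trend, is.numeric, logical(1))
    effect_cols <- setdiff(names(trend)[num], disorder_col)
  }
  rows <- lapply(effect_cols, function(cn) {
    y_all <- trend[[cn]]
    ok <- is.finite(y_all) & is.finite(d)
    y <- y_all[ok]; dd <- d[ok]
    if (sum(ok) < 3)
      return(data.frame(effect = cn, rho = NA_real_, p_value = NA_real_,
                        method = "undefined (fewer than 3 finite values)"))
    if (length(unique(y)) == 1 || length(unique(dd)) == 1)
      return(data.frame(effect = cn, rho = NA_real_, p_value = NA_real_,
                        method = "undefined (constant column)"))
    rho <- stats::cor(dd, y, method = "spearman")
    nn <- length(dd)
    if (factorial(nn) <= 720) {
      perms <- .all_perms(nn)
      rhos <- vapply(perms, function(p)
        stats::cor(dd, y[p], method = "spearman"), numeric(1))
      p <- if (rho >= 0) mean(rhos >= rho - 1e-12)
           else mean(rhos <= rho + 1e-12)
      meth <- sprintf("exhaustive (%d orderings)", length(perms))
    } else {
      rhos <- .with_seed(seed, replicate(n_perm,
        stats::cor(dd, sample(y), method = "spearman")))
      p <- if (rho >= 0) (1 + sum(rhos >= rho - 1e-12)) / (1 + n_perm)
           else (1 + sum(rhos <= rho + 1e-12)) / (1 + n_perm)
      meth <- sprintf("sampled (%d shuffles)", n_perm)
    }
    data.frame(effect = cn, rho = rho, p_value = p, method = meth)
  })
  do.call(rbind, rows)
}
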