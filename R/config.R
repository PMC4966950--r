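#' Load an analysis configuration from YAML
#'
#' The configuration mirrors the pipeline's inputs: per-environment
#' structure (+ optional trajectory) files, a molecule-to-protein map,
#' per-protein disorder percentages (an external predictor's output,
#' supplied as numbers, never computed here), and optional helix
#' definitions. Example:
#'
#' ```yaml
#' reference_env: WATER
#' environments:
#'   WATER: {structure: water.pdb, trajectory: water.dcd, dt: 20}
#'   CROW-192: {structure: crow.gro, trajectory: crow.dcd, dt: 20}
#' proteins:
#'   IRF3: [1]
#'   NCBD: [2, 3, 4, 5, 6, 7]
#'   ACTR: [8]
#' disorder: {IRF3: 8, NCBD: 45, ACTR: 90}
#' helix_defs: {h1: [0, 8], h2: [10, 18], h3: [20, 28]}
#' ```
#'
#' Helix definitions are `[start, end]` 0-based residue ranges, inclusive.
#'
#' @param path YAML file
#' @return a config list suitable for [run_pipeline()]
#' @export
load_analysis_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$environments) || length(cfg$environments) == 0)
    stop("config must define at least one environment")
  base <- dirname(normalizePath(path))
  resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
  envs <- lapply(names(cfg$environments), function(e) {
    spec <- cfg$environments[[e]]
    spath <- resolve(spec$structure)
    if (!file.exists(spath)) stop("missing structure file for ", e, ": ",
                                  spec$structure)
    st <- read_structure(spath)
    if (!is.null(spec$trajectory)) {
      tpath <- resolve(spec$trajectory)
      if (!file.exists(tpath)) stop("missing trajectory file for ", e, ": ",
                                    spec$trajectory)
      read_trajectory(tpath, st$topology, dt = spec$dt %||% 1)
    } else st$trajectory
  })
  names(envs) <- names(cfg$environments)
  helix_defs <- NULL
  if (!is.null(cfg$helix_defs))
    helix_defs <- lapply(cfg$helix_defs, function(rng) rng[1]:rng[2])
  list(environments = envs,
       proteins = lapply(cfg$proteins, as.integer),
       disorder = unlist(cfg$disorder),
       reference_env = cfg$reference_env %||% names(envs)[1],
       helix_defs = helix_defs)
}
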