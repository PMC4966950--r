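#' Build a Topology
#'
#' A Topology is the static half of a system: a table of atoms (names,
#' elements, masses, residue and molecule identity, backbone flag) plus a
#' molecule table. Residue indices are 0-based internally; all textual
#' reports use 1-based numbering.
#'
#' @param atoms data.frame with columns `name`, `element`, `mass`,
#'   `resid` (0-based integer residue index), `resname` (3-letter code),
#'   `mol` (integer molecule id) and logical `backbone`.
#' @param molecules optional data.frame with columns `mol`, `res_start`,
#'   `res_end`, `label`; derived from `atoms` when omitted.
#' @return An object of class `Topology`.
#' @export
new_topology <- function(atoms, molecules = NULL) {
  req <- c("name", "element", "mass", "resid", "resname", "mol", "backbone")
  miss <- setdiff(req, names(atoms))
  if (length(miss)) stop("atoms is missing columns: ", paste(miss, collapse = ", "))
  atoms$resid <- as.integer(atoms$resid)
  atoms$mol <- as.integer(atoms$mol)
  if (any(!is.finite(atoms$mass)) || any(atoms$mass <= 0))
    stop("all atom masses must be > 0")
  if (anyNA(atoms$mol)) stop("every atom must belong to exactly one molecule")
  for (m in unique(atoms$mol)) {
    r <- atoms$resid[atoms$mol == m]
    if (is.unsorted(r)) stop("residue_index must be non-decreasing within molecule ", m)
  }
  if (is.null(molecules)) {
    molecules <- do.call(rbind, lapply(split(atoms, atoms$mol), function(a) {
      data.frame(mol = a$mol[1], res_start = min(a$resid), res_end = max(a$resid),
                 label = paste0("mol", a$mol[1]))
    }))
    rownames(molecules) <- NULL
  }
  structure(list(atoms = atoms, molecules = molecules), class = "Topology")
}

#' @export
print.Topology <- function(x, ...) {
  cat("Topology:", nrow(x$atoms), "atoms,",
      length(unique(paste(x$atoms$mol, x$atoms$resid))), "residues,",
      nrow(x$molecules), "molecules\n")
  invisible(x)
}

#' Number of atoms in a Topology or Trajectory
#' @param x a `Topology` or `Trajectory`
#' @return integer
#' @export
n_atoms <- function(x) {
  if (inherits(x, "Trajectory")) x <- x$topology
  nrow(x$atoms)
}

#' Select atom indices from a Topology
#'
#' @param topology a `Topology`
#' @param mol optional molecule id(s)
#' @param resid optional 0-based residue indices
#' @param name optional atom-name filter (e.g. `"CA"`)
#' @param element optional element filter
#' @param backbone optional logical; `TRUE` keeps backbone atoms only
#' @param label selection label stored as an attribute
#' @return integer vector of atom indices (1-based into the atom table)
#' @export
select_atoms <- function(topology, mol = NULL, resid = NULL, name = NULL,
                         element = NULL, backbone = NULL, label = "selection") {
  a <- topology$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(mol)) keep <- keep & a$mol %in% mol
  if (!is.null(resid)) keep <- keep & a$resid %in% resid
  if (!is.null(name)) keep <- keep & a$name %in% name
  if (!is.null(element)) keep <- keep & a$element %in% element
  if (!is.null(backbone)) keep <- keep & (a$backbone == backbone)
  idx <- which(keep)
  if (anyDuplicated(idx)) stop("selection indices must be unique")
  attr(idx, "label") <- label
  idx
}

# atom names treated as backbone for proteins
.backbone_names <- c("N", "CA", "C", "O", "OXT", "H", "HN", "HA", "H1", "H2", "H3")

# quick topology for bead (Calpha-only) models: one atom per residue
.bead_topology <- function(n_res_per_mol, resnames = NULL, mass = 110,
                           atom_name = "CA", labels = NULL) {
  n_mol <- length(n_res_per_mol)
  rows <- lapply(seq_len(n_mol), function(m) {
    n <- n_res_per_mol[m]
    rn <- if (is.null(resnames)) rep("ALA", n) else resnames[[m]]
    data.frame(name = atom_name, element = "C",
               mass = rep(mass, n), resid = seq_len(n) - 1L,
               resname = rn, mol = m, backbone = TRUE)
  })
  atoms <- do.call(rbind, rows)
  top <- new_topology(atoms)
  if (!is.null(labels)) top$molecules$label <- labels
  top
}
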