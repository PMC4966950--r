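#' Read a structure file (PDB or GRO)
#'
#' Parses a structure into a [new_topology()] plus a single-frame (or, for
#' multi-model PDB, multi-frame) [new_trajectory()]. All coordinates are
#' converted to nm on ingest (PDB Angstrom -> nm); GRO files are already in
#' nm. Molecules are assigned from chain identifiers when present, else from
#' TER records, else from an explicit `molecule_map`.
#'
#' @param path file path
#' @param format `"auto"` (from extension), `"pdb"` or `"gro"`
#' @param molecule_map optional list of 1-based sequential residue ranges
#'   (`c(start, end)`), one per molecule, overriding chain/TER assignment
#' @param times optional frame times in ps (multi-model PDB); defaults to a
#'   1-ps stride
#' @return list with elements `topology` and `trajectory`
#' @export
read_structure <- function(path, format = c("auto", "pdb", "gro"),
                           molecule_map = NULL, times = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("gro")) "gro" else "pdb"
  }
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
         pdb = .read_pdb(path, molecule_map, times),
         gro = .read_gro(path, molecule_map))
}

# infer the element from a PDB/GRO atom name
.infer_element <- function(name) {
  s <- gsub("[^A-Za-z]", "", name)
  if (nchar(s) == 0) return("X")
  two <- toupper(substr(s, 1, 2))
  if (two %in% c("CL", "BR", "FE", "ZN", "SE", "MG", "NA", "MN"))
    return(two)
  toupper(substr(s, 1, 1))
}

.atoms_from_fields <- function(name, resno_key, resname, chain, ter_group,
                               molecule_map, elesy = NULL, path = "") {
  n <- length(name)
  # sequential residue index over the file (0-based)
  res_seq <- cumsum(c(TRUE, resno_key[-1] != resno_key[-n])) - 1L
  # molecule assignment: chain ids, else TER groups, else config map
  if (!is.null(molecule_map)) {
    mol <- rep(NA_integer_, n)
    for (k in seq_along(molecule_map)) {
      rng <- molecule_map[[k]]
      mol[res_seq + 1L >= rng[1] & res_seq + 1L <= rng[2]] <- k
    }
    if (anyNA(mol)) stop("molecule_map does not cover every residue in ", path)
  } else if (!is.null(chain) && length(unique(chain[!is.na(chain) & chain != ""])) > 1) {
    mol <- as.integer(factor(chain, levels = unique(chain)))
  } else if (!is.null(ter_group) && length(unique(ter_group)) > 1) {
    mol <- as.integer(factor(ter_group, levels = unique(ter_group)))
  } else {
    mol <- rep(1L, n)
  }
  element <- if (!is.null(elesy)) toupper(trimws(elesy)) else rep("", n)
  blank <- is.na(element) | element == ""
  if (any(blank)) {
    element[blank] <- vapply(name[blank], .infer_element, character(1))
    warning(sum(blank), " atoms without an element field; inferred from atom names")
  }
  mass <- unname(.element_masses[element])
  mass[is.na(mass)] <- .element_masses[["X"]]
  data.frame(name = name, element = element, mass = mass,
             resid = res_seq, resname = resname, mol = mol,
             backbone = name %in% .backbone_names,
             stringsAsFactors = FALSE)
}

.read_pdb <- function(path, molecule_map = NULL, times = NULL) {
  pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
                  error = function(e) stop("malformed PDB file ", path, ": ",
                                           conditionMessage(e)))
  a <- pdb$atom
  # TER grouping: count TER records preceding each ATOM/HETATM line
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  ter_cum <- cumsum(trimws(rec) == "TER")
  ter_group <- ter_cum[is_atom][seq_len(nrow(a))]
  if (is.null(ter_group) || length(ter_group) != nrow(a)) ter_group <- NULL

  key <- paste(a$chain, a$resno, a$insert, sep = "|")
  atoms <- .atoms_from_fields(a$elety, key, a$resid, a$chain, ter_group,
                              molecule_map, elesy = a$elesy, path = path)
  top <- new_topology(atoms)
  xyz <- matrix(pdb$xyz, ncol = length(pdb$xyz) / max(1, nrow(pdb$xyz)),
                nrow = max(1, nrow(pdb$xyz)))
  if (is.null(dim(pdb$xyz))) xyz <- matrix(pdb$xyz, nrow = 1)
  xyz <- xyz / 10  # Angstrom -> nm
  if (is.null(times)) times <- as.numeric(seq_len(nrow(xyz)) - 1L)
  list(topology = top,
       trajectory = new_trajectory(top, xyz, times = times, boxes = NULL))
}

.read_gro <- function(path, molecule_map = NULL) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3) stop("malformed GRO file ", path, ": too short")
  natoms <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(natoms)) stop("malformed GRO file ", path, ": bad atom count at line 2")
  if (length(lines) < 3 + natoms)
    stop("malformed GRO file ", path, ": expected ", natoms, " atom lines")
  al <- lines[3:(2 + natoms)]
  resno <- suppressWarnings(as.integer(substr(al, 1, 5)))
  resname <- trimws(substr(al, 6, 10))
  name <- trimws(substr(al, 11, 15))
  x <- suppressWarnings(as.numeric(substr(al, 21, 28)))
  y <- suppressWarnings(as.numeric(substr(al, 29, 36)))
  z <- suppressWarnings(as.numeric(substr(al, 37, 44)))
  bad <- which(is.na(x) | is.na(y) | is.na(z) | is.na(resno))
  if (length(bad))
    stop("malformed GRO record at line ", 2 + bad[1], " of ", path)
  box <- suppressWarnings(as.numeric(strsplit(trimws(lines[3 + natoms]), "\\s+")[[1]]))
  if (length(box) < 3 || anyNA(box[1:3]))
    stop("malformed GRO box line in ", path)
  if (length(box) > 3 && any(abs(box[4:length(box)]) > 1e-9))
    stop("triclinic boxes are not supported (orthorhombic only)")
  atoms <- .atoms_from_fields(name, as.character(resno), resname,
                              chain = NULL, ter_group = NULL,
                              molecule_map = molecule_map, path = path)
  top <- new_topology(atoms)
  xyz <- as.vector(rbind(x, y, z))
  boxes <- if (all(box[1:3] <= 0)) NULL else box[1:3]  # zero box = none
  list(topology = top,
       trajectory = new_trajectory(top, matrix(xyz, nrow = 1),
                                   times = 0, boxes = boxes))
}

#' Write a structure or trajectory to PDB or GRO
#'
#' PDB output uses one MODEL record per frame (multi-model for multi-frame
#' trajectories) with coordinates in Angstrom; GRO output is one file per
#' frame set (frames concatenated, nm).
#'
#' @param trajectory a `Trajectory`
#' @param path output file path
#' @param format `"pdb"` or `"gro"` (default from extension)
#' @return `path`, invisibly
#' @export
write_structure <- function(trajectory, path, format = c("auto", "pdb", "gro")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "gro") "gro" else "pdb"
  }
  a <- trajectory$topology$atoms
  nfr <- n_frames(trajectory)
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "pdb") {
    chains <- LETTERS[((a$mol - 1L) %% 26L) + 1L]
    for (f in seq_len(nfr)) {
      if (nfr > 1) writeLines(sprintf("MODEL     %4d", f), con)
      x <- frame_coords(trajectory, f) * 10  # nm -> Angstrom
      ln <- sprintf("ATOM  %5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
                    seq_len(nrow(a)) %% 100000,
                    ifelse(nchar(a$name) < 4, paste0(" ", a$name), a$name),
                    substr(a$resname, 1, 3), chains, (a$resid %% 9999L) + 1L,
                    x[, 1], x[, 2], x[, 3], substr(a$element, 1, 2))
      # TER between molecules
      last_of_mol <- which(diff(c(a$mol, -1L)) != 0)
      out <- character(0)
      prev <- 1L
      for (e in last_of_mol) {
        out <- c(out, ln[prev:e], "TER")
        prev <- e + 1L
      }
      writeLines(out, con)
      if (nfr > 1) writeLines("ENDMDL", con)
    }
    writeLines("END", con)
  } else {
    box <- if (!is.null(trajectory$boxes)) trajectory$boxes else
      matrix(0, nfr, 3)
    for (f in seq_len(nfr)) {
      x <- frame_coords(trajectory, f)
      writeLines(sprintf("frame %d, t= %.3f", f, trajectory$times[f]), con)
      writeLines(sprintf("%5d", nrow(a)), con)
      writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                         (a$resid %% 99999L) + 1L, substr(a$resname, 1, 5),
                         substr(a$name, 1, 5), seq_len(nrow(a)) %% 100000L,
                         x[, 1], x[, 2], x[, 3]), con)
      writeLines(sprintf("%10.5f%10.5f%10.5f", box[f, 1], box[f, 2], box[f, 3]), con)
    }
  }
  invisible(path)
}
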