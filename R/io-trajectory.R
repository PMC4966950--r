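#' Read a trajectory file
#'
#' Supported formats: multi-model PDB (text) and CHARMM/X-PLOR DCD (binary).
#' Coordinates are converted to nm; DCD box lengths (Angstrom) become
#' per-frame orthorhombic boxes.
#'
#' @param path file path
#' @param topology a `Topology` whose atom count must match the file
#' @param format `"auto"`, `"pdb"` or `"dcd"`
#' @param dt frame spacing in ps used when the file carries no times
#'   (default 1 ps)
#' @return a `Trajectory`
#' @export
read_trajectory <- function(path, topology, format = c("auto", "pdb", "dcd"),
                            dt = 1) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "dcd") "dcd" else "pdb"
  }
  if (format == "pdb") {
    res <- .read_pdb(path)
    if (n_atoms(res$topology) != n_atoms(list(atoms = topology$atoms)))
      stop("atom count mismatch: file has ", n_atoms(res$topology),
           ", topology expects ", nrow(topology$atoms))
    tr <- res$trajectory
    return(new_trajectory(topology, tr$xyz,
                          times = (seq_len(nrow(tr$xyz)) - 1) * dt,
                          boxes = tr$boxes))
  }
  dcd <- read_dcd(path)
  if (ncol(dcd$xyz) != 3L * nrow(topology$atoms))
    stop("atom count mismatch: DCD has ", ncol(dcd$xyz) / 3,
         " atoms, topology expects ", nrow(topology$atoms))
  new_trajectory(topology, dcd$xyz,
                 times = (seq_len(nrow(dcd$xyz)) - 1) * dt,
                 boxes = dcd$boxes)
}

#' Write a trajectory file
#'
#' @param trajectory a `Trajectory`
#' @param path output path
#' @param format `"auto"` (from extension), `"pdb"` (multi-model) or `"dcd"`
#' @return `path`, invisibly
#' @export
write_trajectory <- function(trajectory, path, format = c("auto", "pdb", "dcd")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "dcd") "dcd" else "pdb"
  }
  if (format == "pdb") return(write_structure(trajectory, path, "pdb"))
  write_dcd(trajectory, path)
}

#' Low-level DCD reader
#'
#' Reads a CHARMM-style DCD file (little- or big-endian, optional unit-cell
#' records). Coordinates are returned in nm.
#'
#' @param path DCD file
#' @return list with `xyz` (n_frames x 3N, nm) and `boxes` (n_frames x 3 nm,
#'   or `NULL` when the file has no cell records)
#' @export
read_dcd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  endian <- "little"
  len <- readBin(con, "integer", 1, size = 4, endian = endian)
  if (len != 84) {
    endian <- "big"
    seek(con, 0)
    len <- readBin(con, "integer", 1, size = 4, endian = endian)
    if (len != 84) stop("not a DCD file (bad header record length): ", path)
  }
  magic <- rawToChar(readBin(con, "raw", 4))
  if (magic != "CORD") stop("not a DCD file (missing CORD magic): ", path)
  icntrl <- readBin(con, "integer", 20, size = 4, endian = endian)
  readBin(con, "integer", 1, size = 4, endian = endian)  # trailing length
  nframes <- icntrl[1]
  has_cell <- icntrl[11] == 1
  # title record
  len <- readBin(con, "integer", 1, size = 4, endian = endian)
  readBin(con, "raw", len)
  readBin(con, "integer", 1, size = 4, endian = endian)
  # natom record
  readBin(con, "integer", 1, size = 4, endian = endian)
  natom <- readBin(con, "integer", 1, size = 4, endian = endian)
  readBin(con, "integer", 1, size = 4, endian = endian)

  xyz <- matrix(NA_real_, nframes, 3L * natom)
  boxes <- if (has_cell) matrix(NA_real_, nframes, 3) else NULL
  idx <- seq_len(natom)
  got <- 0L
  for (f in seq_len(nframes)) {
    ok <- tryCatch({
      if (has_cell) {
        readBin(con, "integer", 1, size = 4, endian = endian)
        cell <- readBin(con, "double", 6, size = 8, endian = endian)
        readBin(con, "integer", 1, size = 4, endian = endian)
        boxes[f, ] <- cell[c(1, 3, 6)] / 10  # A, B, C in Angstrom -> nm
      }
      co <- matrix(NA_real_, natom, 3)
      for (ax in 1:3) {
        readBin(con, "integer", 1, size = 4, endian = endian)
        co[, ax] <- readBin(con, "numeric", natom, size = 4, endian = endian)
        readBin(con, "integer", 1, size = 4, endian = endian)
      }
      xyz[f, ] <- as.vector(t(co)) / 10  # Angstrom -> nm
      TRUE
    }, error = function(e) FALSE)
    if (!ok || anyNA(xyz[f, ])) break
    got <- f
  }
  if (got < nframes) {
    warning("truncated final frame dropped: read ", got, " of ", nframes,
            " frames from ", path)
    xyz <- xyz[seq_len(got), , drop = FALSE]
    if (!is.null(boxes)) boxes <- boxes[seq_len(got), , drop = FALSE]
  }
  list(xyz = xyz, boxes = boxes)
}

#' Low-level DCD writer
#'
#' Writes a CHARMM-format DCD (32-bit float coordinates in Angstrom,
#' orthorhombic unit-cell records when the trajectory has boxes).
#'
#' @param trajectory a `Trajectory`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_dcd <- function(trajectory, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  nfr <- n_frames(trajectory)
  natom <- n_atoms(trajectory)
  has_cell <- !is.null(trajectory$boxes)
  w_int <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  # header record
  w_int(84)
  writeBin(charToRaw("CORD"), con)
  icntrl <- integer(20)
  icntrl[1] <- nfr      # frames
  icntrl[2] <- 0        # first step
  icntrl[3] <- 1        # save frequency
  icntrl[4] <- nfr      # steps
  icntrl[11] <- if (has_cell) 1L else 0L
  icntrl[20] <- 24L     # CHARMM version flag
  # timestep goes in slot 10 as a 32-bit float
  dt <- if (nfr > 1) diff(trajectory$times)[1] else 1
  w_int(icntrl[1:9])
  writeBin(as.numeric(dt), con, size = 4, endian = "little")
  w_int(icntrl[11:20])
  w_int(84)
  # title record
  title <- sprintf("%-80s", "written by mdcrowd")
  w_int(4 + 80)
  w_int(1)
  writeBin(charToRaw(title), con)
  w_int(4 + 80)
  # natom record
  w_int(4); w_int(natom); w_int(4)
  for (f in seq_len(nfr)) {
    if (has_cell) {
      b <- trajectory$boxes[f, ] * 10  # nm -> Angstrom
      w_int(48)
      writeBin(as.numeric(c(b[1], 90, b[2], 90, 90, b[3])), con,
               size = 8, endian = "little")
      w_int(48)
    }
    x <- frame_coords(trajectory, f) * 10
    for (ax in 1:3) {
      w_int(4 * natom)
      writeBin(as.numeric(x[, ax]), con, size = 4, endian = "little")
      w_int(4 * natom)
    }
  }
  invisible(path)
}
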