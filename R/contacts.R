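#' Residue class scheme (hydrophobic / polar / charged)
#'
#' Three-class residue typing used for quinary-contact composition. The
#' default mapping: charged C = Asp, Glu, Lys, Arg, His; polar P = Ser, Thr,
#' Asn, Gln, Cys, Tyr, Trp; hydrophobic H = Ala, Val, Leu, Ile, Met, Phe,
#' Pro, Gly. Override any entry via `...`; nonstandard residues fall into
#' class `U` at use time.
#'
#' @param ... named overrides, e.g. `HIS = "P"`
#' @return named character vector (class `ResidueClassScheme`)
#' @export
residue_class_scheme <- function(...) {
  s <- c(ASP = "C", GLU = "C", LYS = "C", ARG = "C", HIS = "C",
         SER = "P", THR = "P", ASN = "P", GLN = "P", CYS = "P",
         TYR = "P", TRP = "P",
         ALA = "H", VAL = "H", LEU = "H", ILE = "H", MET = "H",
         PHE = "H", PRO = "H", GLY = "H")
  ov <- list(...)
  for (nm in names(ov)) s[nm] <- ov[[nm]]
  if (!all(s %in% c("H", "P", "C"))) stop("classes must be H, P or C")
  structure(s, class = "ResidueClassScheme")
}

# Calpha atom index and metadata per residue of the given molecules;
# residues lacking a CA atom are dropped with a warning
.ca_table <- function(topology, mols) {
  a <- topology$atoms
  keep <- a$mol %in% mols & a$name == "CA"
  tab <- a[keep, c("mol", "resid", "resname")]
  tab$atom <- which(keep)
  # detect residues without CA
  all_res <- unique(a[a$mol %in% mols, c("mol", "resid")])
  if (nrow(all_res) > nrow(tab)) {
    warning(nrow(all_res) - nrow(tab),
            " residue(s) without a Calpha atom dropped from contact analysis")
  }
  tab[order(tab$mol, tab$resid), ]
}

#' Calpha contact map
#'
#' Contact occupancy between two residue groups: a pair is in contact in a
#' frame when its Calpha-Calpha distance is at or below `cutoff`. Distances
#' use the minimum-image convention whenever the trajectory carries a box,
#' so maps are invariant to periodic re-wrapping. For intra maps
#' (`groupA == groupB`) the diagonal band `|i-j| <= neighbor_excl` is
#' excluded from all statistics (stored as `NA`).
#'
#' @param trajectory a `Trajectory`
#' @param groupA,groupB molecule id(s) defining the two residue groups;
#'   identical ids give an intra map
#' @param cutoff contact cutoff in nm (default 0.8)
#' @param neighbor_excl sequence-neighbor exclusion for intra maps
#'   (default 2: pairs with `|i-j| <= 2` are excluded)
#' @return object of class `ContactMap`: occupancy and frame-count matrices,
#'   residue metadata, per-frame contact event counts, and parameters
#' @export
contact_map <- function(trajectory, groupA, groupB = groupA, cutoff = 0.8,
                        neighbor_excl = 2) {
  top <- trajectory$topology
  intra <- identical(sort(unique(groupA)), sort(unique(groupB)))
  if (!intra && length(intersect(groupA, groupB)))
    stop("inter-group contact maps require disjoint molecule groups")
  ta <- .ca_table(top, groupA)
  tb <- if (intra) ta else .ca_table(top, groupB)
  na <- nrow(ta); nb <- nrow(tb)
  if (na == 0 || nb == 0) stop("no Calpha atoms in the requested groups")
  nfr <- n_frames(trajectory)
  counts <- matrix(0L, na, nb)
  frame_events <- integer(nfr)
  excl <- NULL
  if (intra && na > 1) {
    ij <- expand.grid(i = seq_len(na), j = seq_len(nb))
    same_mol <- ta$mol[ij$i] == tb$mol[ij$j]
    excl <- matrix(same_mol & abs(ta$resid[ij$i] - tb$resid[ij$j]) <= neighbor_excl,
                   na, nb)
  }
  ca_cols_a <- .sel_cols(ta$atom)
  ca_cols_b <- .sel_cols(tb$atom)
  for (f in seq_len(nfr)) {
    xa <- matrix(trajectory$xyz[f, ca_cols_a], ncol = 3, byrow = TRUE)
    xb <- if (intra) xa else
      matrix(trajectory$xyz[f, ca_cols_b], ncol = 3, byrow = TRUE)
    d2 <- matrix(0, na, nb)
    for (ax in 1:3) {
      dd <- outer(xa[, ax], xb[, ax], "-")
      if (!is.null(trajectory$boxes)) {
        L <- trajectory$boxes[f, ax]
        dd <- dd - round(dd / L) * L
      }
      d2 <- d2 + dd^2
    }
    inc <- d2 <= cutoff^2
    if (!is.null(excl)) inc[excl] <- FALSE
    counts <- counts + inc
    frame_events[f] <- if (intra) sum(inc) / 2L else sum(inc)
  }
  occupancy <- counts / nfr
  if (!is.null(excl)) {
    occupancy[excl] <- NA_real_
    counts[excl] <- NA_integer_
  }
  structure(list(occupancy = occupancy, counts = counts,
                 groupA = ta, groupB = tb, cutoff = cutoff,
                 n_frames = nfr, intra = intra,
                 neighbor_excl = neighbor_excl,
                 frame_events = frame_events,
                 pbc = !is.null(trajectory$boxes)),
            class = "ContactMap")
}

#' @export
print.ContactMap <- function(x, ...) {
  cat("ContactMap (", if (x$intra) "intra" else "inter", "): ",
      nrow(x$occupancy), " x ", ncol(x$occupancy), " residues, cutoff ",
      x$cutoff, " nm, ", x$n_frames, " frames\n", sep = "")
  invisible(x)
}

#' Long-format data frame from a ContactMap
#' @param x a `ContactMap`
#' @param ... unused
#' @return data.frame `(i, j, occupancy)` with 1-based residue numbers
#' @export
as.data.frame.ContactMap <- function(x, ...) {
  df <- expand.grid(i = x$groupA$resid + 1L, j = x$groupB$resid + 1L)
  df$occupancy <- as.vector(x$occupancy)
  df[!is.na(df$occupancy), ]
}

#' Explored intra-protein contacts
#'
#' A residue pair is "explored" when it is found in contact in strictly more
#' than `min_frames` frames. Possible pairs exclude the sequence-neighbor
#' band of the map.
#'
#' @param x an intra `ContactMap`, or a `Trajectory` (then `group`,
#'   `cutoff`, `neighbor_excl` are forwarded to [contact_map()])
#' @param min_frames strict threshold in frames (default 5: a pair seen in
#'   exactly 5 frames is not explored, 6 is)
#' @param group,cutoff,neighbor_excl see [contact_map()]
#' @return list with `count`, `possible` and `fraction`
#' @export
explored_contacts <- function(x, min_frames = 5, group = NULL, cutoff = 0.8,
                              neighbor_excl = 2) {
  if (inherits(x, "Trajectory")) {
    if (is.null(group)) group <- unique(x$topology$atoms$mol)
    x <- contact_map(x, group, group, cutoff, neighbor_excl)
  }
  if (!x$intra) stop("explored_contacts applies to intra maps")
  cnt <- x$counts
  ut <- upper.tri(cnt)
  valid <- ut & !is.na(cnt)
  count <- sum(cnt[valid] > min_frames)
  possible <- sum(valid)
  list(count = count, possible = possible,
       fraction = if (possible) count / possible else NA_real_)
}

#' Fraction of instantaneous contacts that are inter-protein
#'
#' Per frame, the inter-protein contact events of one chain are divided by
#' its total (inter + intra) events; the percentage is averaged over frames.
#' Frames with zero total contacts are skipped (and counted in the output).
#'
#' @param intra_map intra `ContactMap` of the chain
#' @param inter_maps a single inter `ContactMap` or a list of them (the
#'   chain against each other group), computed on the same frames
#' @return list with `percent`, `n_frames_used`, `n_frames_skipped`
#' @export
interprotein_fraction <- function(intra_map, inter_maps) {
  if (inherits(inter_maps, "ContactMap")) inter_maps <- list(inter_maps)
  nfr <- intra_map$n_frames
  for (m in inter_maps)
    if (m$n_frames != nfr)
      stop("intra and inter maps must be computed on the same frames")
  inter_ev <- Reduce(`+`, lapply(inter_maps, function(m) m$frame_events))
  intra_ev <- intra_map$frame_events
  tot <- inter_ev + intra_ev
  use <- tot > 0
  pct <- if (any(use)) mean(100 * inter_ev[use] / tot[use]) else NA_real_
  if (any(!use))
    message(sum(!use), " frame(s) with zero total contacts skipped")
  list(percent = pct, n_frames_used = sum(use), n_frames_skipped = sum(!use))
}

#' Residue-class composition of inter-protein contacts
#'
#' Each contacting residue of the chain (map rows) contributes its class,
#' weighted by its total contact occupancy, reproducing a contact-time
#' weighted composition. The chain's sequence composition is returned as the
#' background reference.
#'
#' @param inter_map an inter `ContactMap` (rows = the chain of interest)
#' @param scheme a [residue_class_scheme()]
#' @return list with `composition` (% over H/P/C/U of occupancy-weighted
#'   contacts), `background` (% over the chain sequence), `total_weight`
#'   and `empty` flag
#' @export
class_composition <- function(inter_map, scheme = residue_class_scheme()) {
  cls <- unname(scheme[inter_map$groupA$resname])
  cls[is.na(cls)] <- "U"
  w <- rowSums(inter_map$occupancy, na.rm = TRUE)
  lv <- c("H", "P", "C", "U")
  comp <- vapply(lv, function(k) sum(w[cls == k]), numeric(1))
  tot <- sum(comp)
  empty <- tot == 0
  composition <- if (empty) setNames(rep(NA_real_, 4), lv) else 100 * comp / tot
  bg <- vapply(lv, function(k) mean(cls == k), numeric(1)) * 100
  list(composition = composition, background = bg,
       total_weight = tot, empty = empty)
}

#' Signed difference of two contact maps
#'
#' Elementwise `occupancy(a) - occupancy(b)`, e.g. water minus crowded
#' contact time.
#'
#' @param a,b `ContactMap`s with identical residue indexing
#' @return numeric matrix in \[-1, 1\] (NA on excluded bands)
#' @export
contact_difference <- function(a, b) {
  if (!all(dim(a$occupancy) == dim(b$occupancy)))
    stop("contact maps have mismatched shapes: ",
         paste(dim(a$occupancy), collapse = "x"), " vs ",
         paste(dim(b$occupancy), collapse = "x"))
  if (!identical(a$groupA$resid, b$groupA$resid) ||
      !identical(a$groupB$resid, b$groupB$resid))
    stop("contact maps have mismatched residue indexing")
  a$occupancy - b$occupancy
}

#' Overlap with native (reference-structure) contacts
#'
#' The reference contact set is computed from a single reference frame at
#' the same cutoff and exclusion rules; the overlap is the fraction of
#' reference contacts whose trajectory occupancy exceeds `threshold`.
#'
#' @param map a `ContactMap`
#' @param reference a single-frame `Trajectory` sharing the map's residue
#'   numbering (same molecules)
#' @param threshold occupancy threshold (strictly above; default 0.5)
#' @return list with `overlap` in \[0, 1\], `n_reference_contacts`
#' @export
native_overlap <- function(map, reference, threshold = 0.5) {
  ref_map <- contact_map(reference,
                         groupA = unique(map$groupA$mol),
                         groupB = unique(map$groupB$mol),
                         cutoff = map$cutoff,
                         neighbor_excl = map$neighbor_excl)
  if (!identical(ref_map$groupA$resid, map$groupA$resid) ||
      !identical(ref_map$groupB$resid, map$groupB$resid))
    stop("residue numbering mismatch between map and reference; residues: ",
         paste(setdiff(ref_map$groupA$resid, map$groupA$resid), collapse = ", "))
  ref_contacts <- ref_map$occupancy > 0
  sel <- which(ref_contacts & !is.na(ref_contacts))
  if (map$intra) {
    # count each unsorted pair once
    ij <- arrayInd(sel, dim(ref_contacts))
    sel <- sel[ij[, 1] < ij[, 2]]
  }
  n_ref <- length(sel)
  if (n_ref == 0) return(list(overlap = NA_real_, n_reference_contacts = 0))
  list(overlap = mean(map$occupancy[sel] > threshold),
       n_reference_contacts = n_ref)
}
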