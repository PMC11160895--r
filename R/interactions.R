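pair_dists <- function(xyz, ia, ib) {
  a <- xyz[ia, , drop = FALSE]; b <- xyz[ib, , drop = FALSE]
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

heavy_only <- function(structure, idx) {
  idx[toupper(structure$atom$element[idx]) != "H"]
}

#' Per-frame interatomic contact counts between two selections
#'
#' A contact is an atom pair at distance strictly below `cutoff` (default
#' 4 Angstrom; a pair at exactly 4.0 does not count). Heavy atoms only by
#' default, so crystal structures (no hydrogens) and MD frames are counted
#' on the same footing.
#'
#' @param traj a [Trajectory].
#' @param selA,selB disjoint [Selection]s.
#' @param cutoff distance cutoff in Angstrom.
#' @param all_atom include hydrogens if `TRUE`.
#' @return An `InteractionSeries`: list with per-frame `counts`, `cutoff`,
#'   and the resolved index sets.
#' @export
contact_series <- function(traj, selA, selB, cutoff = 4.0, all_atom = FALSE) {
  stopifnot(inherits(traj, "Trajectory"))
  ia <- select_atoms(traj$topology, selA)
  ib <- select_atoms(traj$topology, selB)
  if (!all_atom) {
    ia <- heavy_only(traj$topology, ia)
    ib <- heavy_only(traj$topology, ib)
  }
  if (length(intersect(ia, ib)))
    stop("selections overlap; contact counting requires disjoint sets")
  if (!length(ia) || !length(ib)) stop("empty selection")
  counts <- vapply(seq_len(n_frames(traj)), function(f)
    sum(pair_dists(frame_coords(traj, f), ia, ib) < cutoff), numeric(1))
  structure(list(counts = as.integer(counts), cutoff = cutoff,
                 indices_a = ia, indices_b = ib, kind = "contacts"),
            class = "InteractionSeries")
}

HBOND_DONORS <- list(
  backbone = "N",
  SER = "OG", THR = "OG1", TYR = "OH", CYS = "SG", TRP = "NE1",
  HIS = c("ND1", "NE2"), LYS = "NZ", ARG = c("NE", "NH1", "NH2"),
  ASN = "ND2", GLN = "NE2")
HBOND_ACCEPTORS <- list(
  backbone = c("O", "OXT"),
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1", GLN = "OE1",
  SER = "OG", THR = "OG1", TYR = "OH", HIS = c("ND1", "NE2"))

check_polar_role <- function(structure, idx, role) {
  a <- structure$atom[idx, ]
  tmpl <- if (role == "donor") HBOND_DONORS else HBOND_ACCEPTORS
  el_ok <- toupper(a$element) %in%
    (if (role == "donor") c("N", "O", "S") else c("N", "O"))
  if (!all(el_ok))
    stop(role, " atoms must be N/O", if (role == "donor") "/S",
         " heavy atoms; offending: ",
         paste(head(a$name[!el_ok], 5), collapse = ", "))
  std <- a$res_name %in% names(CHI1_GAMMA) | a$res_name %in% c("GLY", "ALA")
  ok <- !std |
    a$name %in% tmpl$backbone |
    mapply(function(rn, nm) nm %in% (tmpl[[rn]] %||% character(0)),
           a$res_name, a$name)
  if (role == "donor") ok <- ok & !(a$res_name == "PRO" & a$name == "N")
  if (!all(ok))
    warning("atoms outside the standard polar ", role, " templates: ",
            paste(head(paste(a$res_name[!ok], a$name[!ok]), 5),
                  collapse = ", "))
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-frame hydrogen-bond presence and persistence
#'
#' Distance-only criterion: a donor-acceptor heavy-atom pair is bonded in a
#' frame when its distance is at most `cutoff` (default 3.5 Angstrom). No
#' angle term is applied, so crystal structures without hydrogens and MD
#' frames are treated identically. Donors and acceptors are validated
#' against standard residue polar-atom templates (by element only for
#' non-standard residue names, as in synthetic fixtures).
#'
#' @param traj a [Trajectory].
#' @param donors,acceptors [Selection]s of donor and acceptor heavy atoms.
#' @param cutoff donor-acceptor distance cutoff, Angstrom.
#' @return An `InteractionSeries` with `presence` (n_frames x n_pairs
#'   logical matrix), `persistence` (per-pair fraction of frames), `pairs`
#'   (data.frame), and `counts` (bonds per frame).
#' @export
hbond_series <- function(traj, donors, acceptors, cutoff = 3.5) {
  stopifnot(inherits(traj, "Trajectory"))
  id <- heavy_only(traj$topology, select_atoms(traj$topology, donors))
  ia <- heavy_only(traj$topology, select_atoms(traj$topology, acceptors))
  if (!length(id) || !length(ia))
    stop("empty donor or acceptor selection")
  check_polar_role(traj$topology, id, "donor")
  check_polar_role(traj$topology, ia, "acceptor")
  pairs <- expand.grid(donor = id, acceptor = ia)
  pairs <- pairs[pairs$donor != pairs$acceptor, , drop = FALSE]
  nf <- n_frames(traj)
  presence <- matrix(FALSE, nf, nrow(pairs))
  for (f in seq_len(nf)) {
    d <- pair_dists(frame_coords(traj, f), id, ia)
    keep <- as.matrix(expand.grid(seq_along(id), seq_along(ia)))
    keep <- keep[id[keep[, 1]] != ia[keep[, 2]], , drop = FALSE]
    presence[f, ] <- d[keep] <= cutoff
  }
  at <- traj$topology$atom
  lab <- function(i) paste0(at$chain[i], at$res_seq[i], ":", at$name[i])
  structure(list(presence = presence,
                 persistence = colMeans(presence),
                 counts = as.integer(rowSums(presence)),
                 pairs = data.frame(donor = lab(pairs$donor),
                                    acceptor = lab(pairs$acceptor)),
                 cutoff = cutoff, kind = "hbonds"),
            class = "InteractionSeries")
}

#' Per-frame distance between side-chain (or any) centers of mass
#'
#' @param traj a [Trajectory] with masses assigned.
#' @param selA,selB non-empty [Selection]s.
#' @return numeric vector of Euclidean distances (Angstrom) between the
#'   mass-weighted centroids, one per frame.
#' @export
com_distance_series <- function(traj, selA, selB) {
  stopifnot(inherits(traj, "Trajectory"))
  ia <- select_atoms(traj$topology, selA)
  ib <- select_atoms(traj$topology, selB)
  if (!length(ia) || !length(ib)) stop("empty selection")
  ma <- traj$topology$atom$mass[ia]; mb <- traj$topology$atom$mass[ib]
  if (anyNA(c(ma, mb))) stop("masses unassigned; run assign_parameters()")
  vapply(seq_len(n_frames(traj)), function(f) {
    xyz <- frame_coords(traj, f)
    ca <- colSums(xyz[ia, , drop = FALSE] * ma) / sum(ma)
    cb <- colSums(xyz[ib, , drop = FALSE] * mb) / sum(mb)
    sqrt(sum((ca - cb)^2))
  }, numeric(1))
}

#' Van der Waals overlap between two atom sets
#'
#' For each cross pair, overlap = max(0, r_a + r_b - d): the positive part
#' of the radius-sum excess over the interatomic distance, a steric-clash
#' measure. Returns all per-pair values and the mean over pairs with
#' positive overlap.
#'
#' @param structure a [Structure] with vdW radii assigned.
#' @param selA,selB [Selection]s.
#' @return list with `pairs` (data.frame: indices, distance, overlap) and
#'   `mean_overlap` (Angstrom; `NA` when no pair overlaps).
#' @export
vdw_overlap <- function(structure, selA, selB) {
  stopifnot(inherits(structure, "Structure"))
  ia <- select_atoms(structure, selA)
  ib <- select_atoms(structure, selB)
  if (!length(ia) || !length(ib)) stop("empty selection")
  ra <- structure$atom$vdw_radius[ia]; rb <- structure$atom$vdw_radius[ib]
  if (anyNA(c(ra, rb))) stop("vdW radii unassigned; run assign_parameters()")
  d <- pair_dists(coords(structure), ia, ib)
  ov <- pmax(0, outer(ra, rb, "+") - d)
  grid <- expand.grid(a = ia, b = ib)
  pairs <- data.frame(a = grid$a, b = grid$b,
                      distance = as.numeric(d), overlap = as.numeric(ov))
  contacting <- pairs$overlap > 0
  list(pairs = pairs,
       mean_overlap = if (any(contacting)) mean(pairs$overlap[contacting])
                      else NA_real_)
}
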