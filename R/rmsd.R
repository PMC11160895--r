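resolve_pair <- function(topology, target, sel) {
  ia <- select_atoms(topology, sel)
  ib <- select_atoms(target, sel)
  if (length(ia) != length(ib) ||
      any(topology$atom$name[ia] != target$atom$name[ib])) {
    bad <- union(setdiff(paste(topology$atom$res_seq[ia],
                               topology$atom$name[ia]),
                         paste(target$atom$res_seq[ib],
                               target$atom$name[ib])),
                 setdiff(paste(target$atom$res_seq[ib],
                               target$atom$name[ib]),
                         paste(topology$atom$res_seq[ia],
                               topology$atom$name[ia])))
    stop("atom correspondence mismatch between trajectory and target: ",
         paste(head(bad, 5), collapse = "; "))
  }
  list(traj = ia, target = ib)
}

#' Per-frame RMSD of a trajectory against a target structure
#'
#' Each frame is superposed on the target over `fit_sel` (e.g. groove
#' Calpha atoms, residues 1-180) and the RMSD is then measured over
#' `measure_sel` (e.g. all pTrp6 atoms) without re-fitting. With
#' `fit_sel = NULL` frames are assumed pre-aligned and measured directly.
#'
#' @param traj a [Trajectory].
#' @param target a [Structure] to compare against.
#' @param fit_sel [Selection] (or index vector) for the superposition, or
#'   `NULL` for no fitting.
#' @param measure_sel [Selection] for the reported RMSD; defaults to
#'   `fit_sel`.
#' @param fit_weights `"none"` (default) or `"mass"` weighting for the fit.
#' @return numeric vector, one RMSD (Angstrom) per frame.
#' @export
rmsd_series <- function(traj, target, fit_sel, measure_sel = fit_sel,
                        fit_weights = c("none", "mass")) {
  stopifnot(inherits(traj, "Trajectory"), inherits(target, "Structure"))
  fit_weights <- match.arg(fit_weights)
  if (is.null(measure_sel)) stop("measure_sel must be given")
  m <- resolve_pair(traj$topology, target, measure_sel)
  tgt_m <- coords(target)[m$target, , drop = FALSE]
  if (!is.null(fit_sel)) {
    f <- resolve_pair(traj$topology, target, fit_sel)
    tgt_f <- coords(target)[f$target, , drop = FALSE]
    w <- if (fit_weights == "mass") {
      ms <- traj$topology$atom$mass[f$traj]
      if (anyNA(ms)) stop("mass weighting requested but masses unassigned; ",
                          "run assign_parameters() first")
      ms
    } else NULL
  }
  vapply(seq_len(n_frames(traj)), function(i) {
    xyz <- frame_coords(traj, i)
    if (!is.null(fit_sel)) {
      fit <- superpose(xyz[f$traj, , drop = FALSE], tgt_f, weights = w)
      xyz_m <- apply_transform(xyz[m$traj, , drop = FALSE], fit)
    } else {
      xyz_m <- xyz[m$traj, , drop = FALSE]
    }
    rmsd_raw(xyz_m, tgt_m)
  }, numeric(1))
}

#' Pairwise (2D) RMSD matrix over frames and optional reference structures
#'
#' Entry (i, j) is the RMSD of item i against item j over `measure_sel`,
#' after superposing on `fit_sel` (fit-then-measure per pair). Reference
#' structures (e.g. crystallographic coordinates) are appended after the
#' trajectory frames. With `fit_sel = NULL` (pre-aligned frames) a fast
#' vectorized path is used.
#'
#' @param traj a [Trajectory].
#' @param refs optional list of [Structure] objects appended as extra items.
#' @param fit_sel [Selection] for the per-pair fit, or `NULL`.
#' @param measure_sel [Selection] for the measured RMSD; default `fit_sel`.
#' @return symmetric matrix (Angstrom) with zero diagonal.
#' @export
pairwise_rmsd <- function(traj, refs = NULL, fit_sel = NULL,
                          measure_sel = fit_sel) {
  stopifnot(inherits(traj, "Trajectory"))
  if (is.null(measure_sel)) stop("measure_sel must be given")
  im <- select_atoms(traj$topology, measure_sel)
  items_m <- lapply(seq_len(n_frames(traj)), function(i)
    frame_coords(traj, i)[im, , drop = FALSE])
  if (!is.null(fit_sel)) {
    iff <- select_atoms(traj$topology, fit_sel)
    items_f <- lapply(seq_len(n_frames(traj)), function(i)
      frame_coords(traj, i)[iff, , drop = FALSE])
  }
  for (r in refs) {
    mr <- resolve_pair(traj$topology, r, measure_sel)
    items_m <- c(items_m, list(coords(r)[mr$target, , drop = FALSE]))
    if (!is.null(fit_sel)) {
      fr <- resolve_pair(traj$topology, r, fit_sel)
      items_f <- c(items_f, list(coords(r)[fr$target, , drop = FALSE]))
    }
  }
  n <- length(items_m)
  if (n < 2) stop("pairwise RMSD needs at least 2 items")
  if (is.null(fit_sel)) {
    flat <- t(vapply(items_m, as.numeric, numeric(3 * length(im))))
    m <- as.matrix(dist(flat)) / sqrt(length(im))
    dimnames(m) <- NULL
    return(m)
  }
  m <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      fit <- superpose(items_f[[i]], items_f[[j]])
      m[i, j] <- m[j, i] <- rmsd_raw(apply_transform(items_m[[i]], fit),
                                     items_m[[j]])
    }
  }
  m
}

#' Mass-weighted per-residue RMSF profile
#'
#' Root-mean-square fluctuation of atoms about their trajectory-average
#' positions, aggregated per residue with mass weighting:
#' sqrt( sum_i m_i <|x_i - <x_i>|^2> / sum_i m_i ) over the atoms i of each
#' residue. Frames must be pre-aligned (superpose on a fit selection first);
#' fluctuations about the mean are otherwise inflated by rigid-body motion.
#'
#' @param traj a [Trajectory] with masses assigned on its topology.
#' @param sel [Selection] of atoms to include (default: all heavy atoms).
#' @return data.frame with columns `chain`, `res_seq`, `res_name`, `rmsf`
#'   (Angstrom).
#' @export
mass_weighted_rmsf <- function(traj, sel = atom_selection(heavy = TRUE)) {
  stopifnot(inherits(traj, "Trajectory"))
  if (n_frames(traj) < 2)
    stop("RMSF undefined for a single frame")
  idx <- select_atoms(traj$topology, sel)
  if (!length(idx)) stop("empty selection")
  ms <- traj$topology$atom$mass[idx]
  if (anyNA(ms)) stop("masses unassigned; run assign_parameters() first")
  xyz <- traj$coords[idx, , , drop = FALSE]
  mean_xyz <- apply(xyz, c(1, 2), mean)
  msf <- rowMeans(matrix(
    apply(xyz, 3, function(fr) rowSums((fr - mean_xyz)^2)),
    nrow = length(idx)))
  a <- traj$topology$atom[idx, ]
  key <- paste(a$chain, a$res_seq)
  agg <- lapply(split(seq_along(idx), key), function(k)
    data.frame(chain = a$chain[k[1]], res_seq = a$res_seq[k[1]],
               res_name = a$res_name[k[1]],
               rmsf = sqrt(sum(ms[k] * msf[k]) / sum(ms[k]))))
  out <- do.call(rbind, agg)
  out <- out[order(out$chain, out$res_seq), ]
  rownames(out) <- NULL
  out
}
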