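#' Voxel occupancy grid of tracked atoms over a trajectory
#'
#' Lays a regular lattice (default spacing 0.1 Angstrom) over the region
#' sampled by the selected atoms and tallies, for every voxel, (i) the
#' number of atom-frame events whose atom center falls in it and (ii) the
#' fraction of frames in which at least one tracked atom lies in it (the
#' fractional occupancy). Frames must be pre-aligned. Atoms falling outside
#' explicit bounds expand them; nothing is silently dropped.
#'
#' @param traj a [Trajectory].
#' @param sel [Selection] of tracked atoms (e.g. the pTrp6 side chain).
#' @param spacing voxel edge length, Angstrom.
#' @param bounds optional list with `origin` (length 3) and `shape`
#'   (length-3 integer); default auto-fitted to the data extent.
#' @return An `OccupancyGrid`: list with `origin`, `spacing`, `shape`,
#'   `counts` and `frame_frac` 3D arrays, `n_frames`, `n_atoms`.
#' @export
occupancy_grid <- function(traj, sel, spacing = 0.1, bounds = NULL) {
  stopifnot(inherits(traj, "Trajectory"), spacing > 0)
  idx <- select_atoms(traj$topology, sel)
  if (!length(idx)) stop("empty selection")
  nf <- n_frames(traj); na <- length(idx)
  pts <- matrix(aperm(traj$coords[idx, , , drop = FALSE], c(1, 3, 2)),
                ncol = 3)                      # (atom, frame) rows
  if (is.null(bounds)) {
    origin <- apply(pts, 2, min) - spacing / 2
    shape <- pmax(ceiling((apply(pts, 2, max) - origin) / spacing + 1e-9), 1)
  } else {
    origin <- bounds$origin; shape <- bounds$shape
    lo <- pmin(origin, apply(pts, 2, min) - spacing / 2)
    hi <- pmax(origin + shape * spacing, apply(pts, 2, max) + spacing / 2)
    if (any(lo < origin) || any(hi > origin + shape * spacing)) {
      origin <- lo
      shape <- ceiling((hi - lo) / spacing)
    }
  }
  shape <- as.integer(shape)
  vox <- floor(sweep(pts, 2, origin) / spacing)
  vox <- pmin(pmax(vox, 0), matrix(shape - 1L, nrow(vox), 3, byrow = TRUE))
  lin <- vox[, 1] + shape[1] * (vox[, 2] + shape[2] * vox[, 3]) + 1
  counts <- array(tabulate(lin, nbins = prod(shape)), dim = shape)
  frame_id <- rep(seq_len(nf), each = na)
  uniq <- !duplicated(paste(frame_id, lin))
  frame_frac <- array(tabulate(lin[uniq], nbins = prod(shape)) / nf,
                      dim = shape)
  structure(list(origin = origin, spacing = spacing, shape = shape,
                 counts = counts, frame_frac = frame_frac,
                 n_frames = nf, n_atoms = na),
            class = "OccupancyGrid")
}

gaussian_smooth_3d <- function(arr, sigma) {
  half <- max(1, ceiling(3 * sigma))
  k <- exp(-(-half:half)^2 / (2 * sigma^2)); k <- k / sum(k)
  pad_conv <- function(v) {
    n <- length(v)
    vp <- c(rep(0, half), v, rep(0, half))
    vapply(seq_len(n), function(i) sum(vp[i:(i + 2 * half)] * k), numeric(1))
  }
  for (pass in 1:3) {
    d <- dim(arr)
    arr <- array(apply(arr, c(2, 3), pad_conv), dim = d)  # smooths dim 1
    arr <- aperm(arr, c(2, 3, 1))
  }
  arr  # three cyclic permutations restore the original orientation
}

#' Threshold an occupancy grid into a binary mask and volume
#'
#' Marks voxels whose (optionally Gaussian-smoothed) fractional occupancy
#' is at least `min_fraction` (default 0.10: occupied for at least 10% of
#' simulation time; the boundary is inclusive). Smoothing defaults off so
#' the reported volume is quantitative; enable it (sigma in voxels) for
#' visualization-style contouring.
#'
#' @param grid an `OccupancyGrid`.
#' @param min_fraction occupancy threshold in (0, 1].
#' @param smooth_sigma optional Gaussian sigma in voxels, or `NULL`.
#' @return list with `mask` (logical 3D array), `volume` (Angstrom^3),
#'   `n_voxels`.
#' @export
threshold_grid <- function(grid, min_fraction = 0.10, smooth_sigma = NULL) {
  stopifnot(inherits(grid, "OccupancyGrid"),
            min_fraction > 0, min_fraction <= 1)
  frac <- grid$frame_frac
  if (!is.null(smooth_sigma)) frac <- gaussian_smooth_3d(frac, smooth_sigma)
  mask <- frac >= min_fraction
  list(mask = mask, volume = sum(mask) * grid$spacing^3,
       n_voxels = sum(mask))
}

#' Export an occupancy grid as OpenDX scalar-field text
#'
#' @param grid an `OccupancyGrid`.
#' @param path output path.
#' @param what `"frame_frac"` (default) or `"counts"`.
#' @return `path`, invisibly.
#' @export
write_grid_dx <- function(grid, path, what = c("frame_frac", "counts")) {
  what <- match.arg(what)
  v <- grid[[what]]
  sh <- grid$shape
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("object 1 class gridpositions counts %d %d %d", sh[1], sh[2], sh[3]),
    sprintf("origin %.4f %.4f %.4f", grid$origin[1], grid$origin[2], grid$origin[3]),
    sprintf("delta %.4f 0 0", grid$spacing),
    sprintf("delta 0 %.4f 0", grid$spacing),
    sprintf("delta 0 0 %.4f", grid$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d", sh[1], sh[2], sh[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(sh))), con)
  # DX fastest-varying is z
  vals <- as.numeric(aperm(v, c(3, 2, 1)))
  pad <- c(vals, rep(0, (3 - length(vals) %% 3) %% 3))
  m <- matrix(pad, ncol = 3, byrow = TRUE)
  writeLines(sprintf("%g %g %g", m[, 1], m[, 2], m[, 3])[
    seq_len(ceiling(length(vals) / 3))], con)
  writeLines('attribute "dep" string "positions"', con)
  invisible(path)
}

#' Export an occupancy grid as a flat (i, j, k, fraction) table
#'
#' @param grid an `OccupancyGrid`.
#' @param path output path.
#' @param nonzero_only drop zero voxels (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_grid_table <- function(grid, path, nonzero_only = TRUE) {
  sh <- grid$shape
  ijk <- as.matrix(expand.grid(i = seq_len(sh[1]), j = seq_len(sh[2]),
                               k = seq_len(sh[3])))
  tab <- data.frame(ijk, fraction = as.numeric(grid$frame_frac))
  if (nonzero_only) tab <- tab[tab$fraction > 0, , drop = FALSE]
  write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
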