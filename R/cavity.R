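# mark grid voxel centers lying inside any sphere (centers xyz, radii r);
# grid defined by origin/spacing/shape; returns logical vector (linear index)
mark_inside <- function(origin, spacing, shape, xyz, r) {
  inside <- logical(prod(shape))
  ax <- lapply(1:3, function(d) origin[d] + (seq_len(shape[d]) - 0.5) * spacing)
  for (i in seq_len(nrow(xyz))) {
    ri <- r[i]
    rng <- lapply(1:3, function(d) {
      w <- which(abs(ax[[d]] - xyz[i, d]) <= ri)
      w
    })
    if (any(vapply(rng, length, integer(1)) == 0)) next
    dx2 <- (ax[[1]][rng[[1]]] - xyz[i, 1])^2
    dy2 <- (ax[[2]][rng[[2]]] - xyz[i, 2])^2
    dz2 <- (ax[[3]][rng[[3]]] - xyz[i, 3])^2
    sub <- outer(outer(dx2, dy2, "+"), dz2, "+") < ri^2
    lin <- as.vector(outer(outer(rng[[1]], (rng[[2]] - 1) * shape[1], "+"),
                           (rng[[3]] - 1) * shape[1] * shape[2], "+"))
    inside[lin[as.vector(sub)]] <- TRUE
  }
  inside
}

# 6-connected flood fill over free voxels from seed linear indices
flood_fill6 <- function(free, shape, seeds) {
  visited <- logical(length(free))
  frontier <- seeds[free[seeds] & !visited[seeds]]
  visited[frontier] <- TRUE
  nxy <- shape[1] * shape[2]
  while (length(frontier)) {
    i0 <- frontier - 1L
    x <- i0 %% shape[1]; y <- (i0 %/% shape[1]) %% shape[2]; z <- i0 %/% nxy
    nb <- c(frontier[x > 0] - 1L, frontier[x < shape[1] - 1] + 1L,
            frontier[y > 0] - shape[1], frontier[y < shape[2] - 1] + shape[1],
            frontier[z > 0] - nxy, frontier[z < shape[3] - 1] + nxy)
    nb <- unique(nb[free[nb] & !visited[nb]])
    visited[nb] <- TRUE
    frontier <- nb
  }
  visited
}

boundary_voxels <- function(shape) {
  idx <- array(seq_len(prod(shape)), dim = shape)
  unique(c(idx[1, , ], idx[shape[1], , ], idx[, 1, ], idx[, shape[2], ],
           idx[, , 1], idx[, , shape[3]]))
}

#' Union-of-spheres van der Waals volume of an atom set
#'
#' Volume of the union of atomic vdW spheres (overlaps counted once), by
#' grid integration (deterministic, default) or seeded Monte Carlo.
#'
#' @param structure a [Structure] with radii assigned.
#' @param sel optional [Selection]; default all atoms.
#' @param method `"grid"` or `"mc"`.
#' @param spacing grid spacing in Angstrom (grid method).
#' @param n_samples Monte Carlo samples.
#' @param seed RNG seed for the Monte Carlo method.
#' @return volume in Angstrom^3 (0 with a warning for an empty selection).
#' @export
residue_vdw_volume <- function(structure, sel = NULL,
                               method = c("grid", "mc"),
                               spacing = 0.2, n_samples = 2e5, seed = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(structure, "Structure"))
  idx <- if (is.null(sel)) seq_len(n_atoms(structure))
         else select_atoms(structure, sel)
  if (!length(idx)) {
    warning("empty selection; volume 0")
    return(0)
  }
  r <- structure$atom$vdw_radius[idx]
  if (anyNA(r)) stop("vdW radii unassigned; run assign_parameters() first")
  xyz <- coords(structure)[idx, , drop = FALSE]
  lo <- apply(xyz - r, 2, min); hi <- apply(xyz + r, 2, max)
  if (method == "grid") {
    shape <- pmax(as.integer(ceiling((hi - lo) / spacing)), 1L)
    inside <- mark_inside(lo, spacing, shape, xyz, r)
    return(sum(inside) * spacing^3)
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    set.seed(seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  }
  pts <- cbind(runif(n_samples, lo[1], hi[1]), runif(n_samples, lo[2], hi[2]),
               runif(n_samples, lo[3], hi[3]))
  hit <- rep(FALSE, n_samples)
  for (i in seq_along(r))
    hit <- hit | rowSums(sweep(pts, 2, xyz[i, ])^2) < r[i]^2
  mean(hit) * prod(hi - lo)
}

#' Detect enclosed cavities between a peptide and the groove floor
#'
#' Grid-based cavity detection: a voxel is "free" when its center lies
#' outside every probe-expanded sphere (r + probe); free voxels reachable
#' from the box faces by 6-connected flood fill are bulk solvent; the
#' remainder are cavity voxels. Cavities are reported as connected
#' components, restricted to voxels lying between the two region
#' selections along the groove axis: the voxel's nearest peptide atom must
#' sit above it and its nearest floor atom below it along the axis from the
#' floor centroid to the peptide centroid.
#'
#' @param structure a [Structure] with radii assigned.
#' @param peptide_sel [Selection] for the peptide (roof of the cavity).
#' @param floor_sel [Selection] for the groove floor.
#' @param probe probe radius, Angstrom (default 1.4, solvent-sized).
#' @param spacing grid spacing, Angstrom (default 0.5; must not exceed the
#'   probe radius).
#' @param restrict apply the between-peptide-and-floor restriction
#'   (default `TRUE`; set `FALSE` to report all enclosed voids).
#' @return A `CavityReport`: list with `total_volume`, `largest_volume`
#'   (Angstrom^3), `cavities` (list of voxel-center coordinate matrices,
#'   largest first), `probe`, `spacing`.
#' @export
find_cavities <- function(structure, peptide_sel, floor_sel,
                          probe = 1.4, spacing = 0.5, restrict = TRUE) {
  stopifnot(inherits(structure, "Structure"))
  if (spacing > probe)
    stop("spacing exceeds probe radius: cavity grid would be undersampled")
  ip <- select_atoms(structure, peptide_sel)
  ifl <- select_atoms(structure, floor_sel)
  if (!length(ip) || !length(ifl)) stop("empty region selection")
  r <- structure$atom$vdw_radius
  if (anyNA(r)) stop("vdW radii unassigned; run assign_parameters() first")
  xyz <- coords(structure)
  margin <- max(r) + probe + 2 * spacing
  lo <- apply(xyz, 2, min) - margin; hi <- apply(xyz, 2, max) + margin
  shape <- as.integer(ceiling((hi - lo) / spacing))
  occupied <- mark_inside(lo, spacing, shape, xyz, r + probe)
  free <- !occupied
  solvent <- flood_fill6(free, shape, boundary_voxels(shape))
  cav <- free & !solvent
  cav_idx <- which(cav)
  centers <- function(lin) {
    i0 <- lin - 1L
    cbind(lo[1] + (i0 %% shape[1] + 0.5) * spacing,
          lo[2] + ((i0 %/% shape[1]) %% shape[2] + 0.5) * spacing,
          lo[3] + (i0 %/% (shape[1] * shape[2]) + 0.5) * spacing)
  }
  if (restrict && length(cav_idx)) {
    vc <- centers(cav_idx)
    axis_z <- colMeans(xyz[ip, , drop = FALSE]) -
      colMeans(xyz[ifl, , drop = FALSE])
    axis_z <- axis_z / sqrt(sum(axis_z^2))
    nearest_proj <- function(sel_idx) {
      proj <- numeric(length(cav_idx))
      sxyz <- xyz[sel_idx, , drop = FALSE]
      sz <- as.numeric(sxyz %*% axis_z)
      chunk <- 2000L
      for (s in seq(1, length(cav_idx), by = chunk)) {
        e <- min(s + chunk - 1L, length(cav_idx))
        d2 <- outer(rowSums(vc[s:e, , drop = FALSE]^2), rowSums(sxyz^2), "+") -
          2 * tcrossprod(vc[s:e, , drop = FALSE], sxyz)
        proj[s:e] <- sz[max.col(-d2)]
      }
      proj
    }
    vz <- as.numeric(vc %*% axis_z)
    keep <- nearest_proj(ip) > vz & nearest_proj(ifl) < vz
    drop_idx <- cav_idx[!keep]
    cav[drop_idx] <- FALSE
    cav_idx <- cav_idx[keep]
  }
  comps <- list()
  remaining <- cav
  while (any(remaining)) {
    seed <- which(remaining)[1]
    comp <- flood_fill6(remaining, shape, seed)
    comps <- c(comps, list(which(comp)))
    remaining[comp] <- FALSE
  }
  comps <- comps[order(vapply(comps, length, integer(1)), decreasing = TRUE)]
  vols <- vapply(comps, length, integer(1)) * spacing^3
  structure(list(total_volume = sum(vols),
                 largest_volume = if (length(vols)) vols[1] else 0,
                 volumes = vols,
                 cavities = lapply(comps, centers),
                 probe = probe, spacing = spacing),
            class = "CavityReport")
}

#' @export
print.CavityReport <- function(x, ...) {
  cat(sprintf(
    "CavityReport: %d cavit%s, total %.1f A^3, largest %.1f A^3 (probe %.2f, spacing %.2f)\n",
    length(x$cavities), if (length(x$cavities) == 1) "y" else "ies",
    x$total_volume, x$largest_volume, x$probe, x$spacing))
  invisible(x)
}

#' Export cavity voxels as pseudo-PDB HETATM points
#'
#' @param report a `CavityReport`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cavity_pdb <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- 0L
  for (ci in seq_along(report$cavities)) {
    vc <- report$cavities[[ci]]
    for (i in seq_len(nrow(vc))) {
      n <- n + 1L
      writeLines(sprintf(
        "HETATM%5d  O   CAV %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           O",
        n %% 100000, LETTERS[(ci - 1) %% 26 + 1], ci,
        vc[i, 1], vc[i, 2], vc[i, 3]), con)
    }
  }
  writeLines("END", con)
  invisible(path)
}
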