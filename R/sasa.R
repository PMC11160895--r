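# Deterministic quasi-uniform sphere points (Fibonacci spiral); no RNG, so
# SASA values are exactly reproducible across runs and platforms.
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent accessible surface area (Shrake-Rupley)
#'
#' Rolls a probe sphere (default 1.4 Angstrom, water-sized) over the vdW
#' surface: for each atom, test points on the expanded sphere
#' (r_i + probe) are kept if not strictly inside any other atom's expanded
#' sphere; the accessible fraction times the expanded-sphere area gives the
#' per-atom SASA. Points are a deterministic Fibonacci spiral set.
#'
#' @param structure a [Structure] with vdW radii assigned.
#' @param sel [Selection] of atoms whose area is reported (all atoms still
#'   occlude); default all heavy atoms.
#' @param probe probe radius, Angstrom.
#' @param n_points test points per sphere (>= 100; default 960).
#' @return list with `per_atom` (data.frame: index, area) and `total`
#'   (Angstrom^2).
#' @export
sasa <- function(structure, sel = atom_selection(heavy = TRUE),
                 probe = 1.4, n_points = 960) {
  stopifnot(inherits(structure, "Structure"), n_points >= 100)
  idx <- select_atoms(structure, sel)
  if (!length(idx)) stop("empty selection")
  all_idx <- heavy_only(structure, seq_len(n_atoms(structure)))
  r <- structure$atom$vdw_radius
  if (anyNA(r[all_idx])) stop("vdW radii unassigned; run assign_parameters()")
  if (any(r[all_idx] <= 0)) stop("zero-radius atom in structure")
  xyz <- coords(structure)
  pts <- fibonacci_sphere(n_points)
  area <- vapply(idx, function(i) {
    Ri <- r[i] + probe
    test <- sweep(pts * Ri, 2, xyz[i, ], "+")
    nb <- all_idx[all_idx != i]
    d2 <- rowSums(sweep(xyz[nb, , drop = FALSE], 2, xyz[i, ])^2)
    nb <- nb[d2 < (Ri + r[nb] + probe)^2]
    free <- rep(TRUE, n_points)
    for (j in nb) {
      Rj2 <- (r[j] + probe)^2
      free <- free & (rowSums(sweep(test, 2, xyz[j, ])^2) >= Rj2)
      if (!any(free)) break
    }
    4 * pi * Ri^2 * mean(free)
  }, numeric(1))
  list(per_atom = data.frame(index = idx, area = area), total = sum(area))
}
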