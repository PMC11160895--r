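#' D-score backbone torsion divergence
#'
#' Per-residue divergence between two sets of backbone torsions:
#' D = 2(1 - cos dphi) + 2(1 - cos dpsi), dimensionless in [0, 8]. D is 0
#' only when both angle differences vanish (mod 360 degrees) and reaches 8
#' when both angles differ by 180 degrees. Following the convention of
#' comparing simulation ensembles, the inputs are typically circular-mean
#' angles (see [dscore_profile()]).
#'
#' @param anglesA,anglesB data.frames (or matrices) with columns `phi` and
#'   `psi`, degrees, same residue positions in the same order.
#' @return numeric vector of D values; `NA` where either side has a missing
#'   angle.
#' @export
dscore <- function(anglesA, anglesB) {
  anglesA <- as.data.frame(anglesA); anglesB <- as.data.frame(anglesB)
  stopifnot(all(c("phi", "psi") %in% names(anglesA)),
            all(c("phi", "psi") %in% names(anglesB)),
            nrow(anglesA) == nrow(anglesB))
  dphi <- (anglesA$phi - anglesB$phi) * pi / 180
  dpsi <- (anglesA$psi - anglesB$psi) * pi / 180
  2 * (1 - cos(dphi)) + 2 * (1 - cos(dpsi))
}

#' D-score profile between two trajectories
#'
#' Convenience wrapper composing [torsion_series()], [circular_mean_torsions()]
#' and [dscore()]: compares the average phi/psi angles of the same residues
#' in two simulations, residue by residue.
#'
#' @param trajA,trajB [Trajectory] objects sharing residue numbering on
#'   `chain`.
#' @param chain chain id of the compared residues.
#' @param res_seq residue numbers to compare.
#' @return data.frame with `res_seq` and `d` columns.
#' @export
dscore_profile <- function(trajA, trajB, chain, res_seq) {
  mean_angles <- function(traj) {
    data.frame(
      phi = circular_mean_torsions(torsion_series(traj, chain, res_seq, "phi")),
      psi = circular_mean_torsions(torsion_series(traj, chain, res_seq, "psi")))
  }
  data.frame(res_seq = res_seq,
             d = dscore(mean_angles(trajA), mean_angles(trajB)))
}
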