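#' Weighted rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the weighted RMSD
#' between two point sets, e.g. fitting each trajectory frame on the
#' Calpha atoms of the MHC binding groove before measuring peptide RMSDs.
#'
#' @param mobile n x 3 coordinate matrix to be moved.
#' @param reference n x 3 coordinate matrix held fixed.
#' @param weights per-point weights (e.g. masses); default equal weights.
#' @return A `SuperpositionResult`: list with `rotation` (3 x 3, det +1),
#'   `translation` (length-3), `rmsd` (Angstrom, over the fit points), and
#'   `fit_indices`. The aligned mobile set is
#'   `mobile %*% rotation + translation` (rows).
#' @export
superpose <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (nrow(mobile) != nrow(reference) || ncol(mobile) != 3 ||
      ncol(reference) != 3)
    stop("mobile and reference must be n x 3 with equal n")
  n <- nrow(mobile)
  if (n < 3) stop("superposition requires at least 3 points")
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(weights) == n, all(weights >= 0), sum(weights) > 0)
  w <- weights / sum(weights)
  mu_m <- colSums(mobile * w); mu_r <- colSums(reference * w)
  Pm <- sweep(mobile, 2, mu_m); Pr <- sweep(reference, 2, mu_r)
  # collinearity check on the reference spread
  ev <- eigen(crossprod(Pr * sqrt(w)), symmetric = TRUE,
              only.values = TRUE)$values
  if (ev[2] < 1e-10 * max(ev[1], 1e-12))
    stop("degenerate (collinear) point set; use a larger selection")
  A <- crossprod(Pm * w, Pr)          # 3x3 weighted covariance
  sv <- svd(A)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  aligned <- Pm %*% R
  rmsd <- sqrt(sum(w * rowSums((aligned - Pr)^2)))
  structure(list(rotation = R,
                 translation = as.numeric(mu_r - mu_m %*% R),
                 rmsd = rmsd,
                 fit_indices = seq_len(n),
                 weights = weights),
            class = "SuperpositionResult")
}

#' Apply a superposition transform to coordinates
#' @param xyz n x 3 matrix.
#' @param fit a `SuperpositionResult` from [superpose()].
#' @return transformed n x 3 matrix.
#' @export
apply_transform <- function(xyz, fit) {
  stopifnot(inherits(fit, "SuperpositionResult"))
  sweep(as.matrix(xyz) %*% fit$rotation, 2, -fit$translation)
}

#' RMSD between two coordinate sets (no fitting)
#' @param a,b n x 3 matrices.
#' @param weights optional per-point weights.
#' @return RMSD in Angstrom.
#' @export
rmsd_raw <- function(a, b, weights = NULL) {
  a <- as.matrix(a); b <- as.matrix(b)
  stopifnot(nrow(a) == nrow(b))
  if (is.null(weights)) weights <- rep(1, nrow(a))
  w <- weights / sum(weights)
  sqrt(sum(w * rowSums((a - b)^2)))
}
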