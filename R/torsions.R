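#' Signed dihedral angle from four points
#'
#' IUPAC sign convention via the standard atan2 construction; degrees in
#' (-180, 180].
#'
#' @param p1,p2,p3,p4 length-3 coordinate vectors.
#' @return angle in degrees.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  m1 <- cross3(n1, b2 / sqrt(sum(b2^2)))
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

CHI1_GAMMA <- c(ARG = "CG", ASN = "CG", ASP = "CG", CYS = "SG", GLN = "CG",
                GLU = "CG", HIS = "CG", ILE = "CG1", LEU = "CG", LYS = "CG",
                MET = "CG", PHE = "CG", PRO = "CG", SER = "OG", THR = "OG1",
                TRP = "CG", TYR = "CG", VAL = "CG1")

# per-residue atom-index quadruples for one torsion kind; NA row = undefined
torsion_quads <- function(structure, chain, res_seq, kind) {
  a <- structure$atom
  find <- function(rs, nm) {
    i <- which(a$chain == chain & a$res_seq == rs & a$name == nm)
    if (length(i)) i[1] else NA_integer_
  }
  t(vapply(res_seq, function(r) {
    switch(kind,
      phi = c(find(r - 1, "C"), find(r, "N"), find(r, "CA"), find(r, "C")),
      psi = c(find(r, "N"), find(r, "CA"), find(r, "C"), find(r + 1, "N")),
      chi1 = {
        rn <- a$res_name[a$chain == chain & a$res_seq == r][1]
        g <- if (!is.na(rn) && rn %in% names(CHI1_GAMMA))
          CHI1_GAMMA[[rn]] else NA_character_
        if (is.na(g)) rep(NA_integer_, 4)
        else c(find(r, "N"), find(r, "CA"), find(r, "CB"), find(r, g))
      })
  }, integer(4)))
}

#' Per-frame backbone or side-chain torsion series
#'
#' Computes phi, psi, or chi1 angles for the requested residues in every
#' frame. Undefined torsions (chain termini, glycine chi1, missing atoms)
#' are marked `NA`, never silently zero.
#'
#' @param traj a [Trajectory] (or a [Structure] for a single frame).
#' @param chain chain id of the residues.
#' @param res_seq integer vector of residue numbers.
#' @param kind `"phi"`, `"psi"`, or `"chi1"`.
#' @return A `TorsionSeries`: list with `residues` (data.frame), `kind`, and
#'   `angles` (n_frames x n_residues matrix, degrees in (-180, 180]).
#' @export
torsion_series <- function(traj, chain, res_seq, kind = c("phi", "psi", "chi1")) {
  kind <- match.arg(kind)
  if (inherits(traj, "Structure")) traj <- new_trajectory(traj, list(coords(traj)))
  stopifnot(inherits(traj, "Trajectory"))
  quads <- torsion_quads(traj$topology, chain, res_seq, kind)
  nf <- n_frames(traj)
  ang <- matrix(NA_real_, nf, length(res_seq))
  defined <- !apply(is.na(quads), 1, any)
  for (f in seq_len(nf)) {
    xyz <- frame_coords(traj, f)
    for (r in which(defined)) {
      q <- quads[r, ]
      ang[f, r] <- dihedral_angle(xyz[q[1], ], xyz[q[2], ],
                                  xyz[q[3], ], xyz[q[4], ])
    }
  }
  a <- traj$topology$atom
  rn <- vapply(res_seq, function(r) {
    v <- a$res_name[a$chain == chain & a$res_seq == r]
    if (length(v)) v[1] else NA_character_
  }, character(1))
  structure(list(residues = data.frame(chain = chain, res_seq = res_seq,
                                       res_name = rn),
                 kind = kind, angles = ang),
            class = "TorsionSeries")
}

#' Circular mean of a torsion series
#'
#' Resultant-vector (atan2 of mean sine and cosine) average per residue, as
#' appropriate for angles: the mean of \{175, -175\} degrees is 180, not 0.
#'
#' @param series a `TorsionSeries` (or a numeric matrix of angles in
#'   degrees, frames x residues).
#' @return numeric vector of mean angles in degrees, (-180, 180]; `NA`
#'   where no frame had a defined angle.
#' @export
circular_mean_torsions <- function(series) {
  ang <- if (inherits(series, "TorsionSeries")) series$angles else as.matrix(series)
  out <- apply(ang, 2, function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) return(NA_real_)
    r <- atan2(mean(sin(v * pi / 180)), mean(cos(v * pi / 180))) * 180 / pi
    if (r <= -180) r + 360 else r
  })
  as.numeric(out)
}

# ---- Ramachandran reference -------------------------------------------------

# Rasterized 2-degree torus mask of general-residue phi/psi space, built
# from a smooth synthetic density over the canonical basins (beta, PPII,
# alpha-R, bridge, alpha-L). Levels: 2 = allowed (90% of density mass),
# 1 = generously allowed (99%), 0 = outside. The mask is a reproducible
# stand-in for published survey-based contours; it is built in code, not
# shipped as data.
build_rama_mask <- function(spacing = 2) {
  centers <- seq(-180 + spacing / 2, 180 - spacing / 2, by = spacing)
  comp <- rbind(
    c(-120, 130, 30, 25, 0.30),   # beta sheet
    c(-70, 145, 20, 20, 0.15),    # polyproline II
    c(-63, -43, 14, 12, 0.35),    # alpha-R
    c(-100, 10, 20, 25, 0.10),    # bridge
    c(60, 45, 13, 13, 0.10))      # alpha-L
  wrap_d <- function(x, c0) {
    d <- abs(x - c0) %% 360
    pmin(d, 360 - d)
  }
  dens <- matrix(0, length(centers), length(centers))
  for (k in seq_len(nrow(comp))) {
    dphi <- wrap_d(centers, comp[k, 1]) / comp[k, 3]
    dpsi <- wrap_d(centers, comp[k, 2]) / comp[k, 4]
    dens <- dens + comp[k, 5] * outer(exp(-dphi^2 / 2), exp(-dpsi^2 / 2))
  }
  dens <- dens / sum(dens)
  o <- order(dens, decreasing = TRUE)
  cum <- cumsum(dens[o])
  lev <- matrix(0L, nrow(dens), ncol(dens))
  lev[o[cum <= 0.99]] <- 1L
  lev[o[cum <= 0.90]] <- 2L
  list(centers = centers, spacing = spacing, level = lev)
}

#' Ramachandran reference map
#'
#' Torus mask with two nested region classes: "allowed" (90% of reference
#' density mass) and "generously allowed" (99%). Built procedurally from a
#' smooth density over the canonical backbone basins; cached per session.
#'
#' @return A `RamachandranReference`: list with `centers` (bin centers,
#'   degrees), `spacing`, and `level` matrix (2 allowed, 1 generously
#'   allowed, 0 outside).
#' @export
ramachandran_reference <- function() {
  if (is.null(.pmhcdyn_env$rama))
    .pmhcdyn_env$rama <- structure(build_rama_mask(),
                                   class = "RamachandranReference")
  .pmhcdyn_env$rama
}

rama_level <- function(phi, psi, reference) {
  sp <- reference$spacing
  ix <- pmin(pmax(floor((phi + 180) / sp) + 1, 1), length(reference$centers))
  iy <- pmin(pmax(floor((psi + 180) / sp) + 1, 1), length(reference$centers))
  reference$level[cbind(ix, iy)]
}

#' Per-frame Ramachandran torsional-strain counts
#'
#' Counts, in each frame, the residues whose (phi, psi) pair falls outside
#' the generously-allowed region of the reference map. Glycines are
#' excluded (their accessible region is far larger), as are residues with
#' undefined phi or psi (chain termini).
#'
#' @param phi,psi `TorsionSeries` of kind phi and psi over the same
#'   residues.
#' @param reference a `RamachandranReference`; default
#'   [ramachandran_reference()].
#' @return integer vector of violation counts, one per frame.
#' @export
ramachandran_strain <- function(phi, psi, reference = ramachandran_reference()) {
  stopifnot(inherits(phi, "TorsionSeries"), inherits(psi, "TorsionSeries"),
            phi$kind == "phi", psi$kind == "psi",
            nrow(phi$angles) == nrow(psi$angles),
            ncol(phi$angles) == ncol(psi$angles))
  if (is.null(reference)) stop("missing Ramachandran reference map")
  gly <- !is.na(phi$residues$res_name) & phi$residues$res_name == "GLY"
  nf <- nrow(phi$angles)
  counts <- integer(nf)
  for (f in seq_len(nf)) {
    ph <- phi$angles[f, ]; ps <- psi$angles[f, ]
    ok <- !is.na(ph) & !is.na(ps) & !gly
    if (!any(ok)) next
    counts[f] <- sum(rama_level(ph[ok], ps[ok], reference) == 0L)
  }
  counts
}
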