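# run expr with a local, restored RNG state so generators are pure
# functions of (parameters, seed)
with_seed <- function(seed, expr) {
  if (is.null(seed)) stop("a seed is required for reproducible generation")
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
    else if (exists(".Random.seed", .GlobalEnv))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  force(expr)
}

# NeRF atom placement: position d with |cd| = bond, angle(b,c,d) = angle,
# dihedral(a,b,c,d) = dihedral (degrees)
place_atom <- function(a, b, c, bond, angle, dihedral) {
  ang <- angle * pi / 180; dih <- dihedral * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  n <- cross3(b - a, bc); n <- n / sqrt(sum(n^2))
  m <- cross3(n, bc)
  d2 <- bond * c(-cos(ang), sin(ang) * cos(dih), -sin(ang) * sin(dih))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Idealized tryptophan structure
#'
#' Loads the packaged idealized free-tryptophan geometry (force-field
#' optimized) with parameters assigned; the standard fixture for
#' union-of-spheres volume and side-chain topology checks.
#'
#' @return a [Structure] of one TRP residue (15 heavy atoms incl. OXT).
#' @export
ideal_tryptophan <- function() {
  path <- system.file("extdata", "trp_ideal.pdb", package = "pmhcdyn")
  assign_parameters(read_structure(path))
}

# idealized side-chain templates (force-field optimized free amino acids);
# each matrix holds N/CA/CB for grafting plus the side-chain heavy atoms
SIDECHAIN_TEMPLATES <- list(
  TRP = NULL,  # loaded lazily from extdata
  HIS = rbind(
    N = c(-2.518, 0.984, 0.848), CA = c(-1.343, 0.451, 0.103),
    CB = c(-0.124, 0.349, 1.026), CG = c(1.150, 0.176, 0.269),
    ND1 = c(1.596, 1.158, -0.586), CD2 = c(2.030, -0.884, 0.276),
    CE1 = c(2.721, 0.702, -1.088), NE2 = c(3.022, -0.535, -0.595)),
  LEU = rbind(
    N = c(-1.306, -1.654, 0.342), CA = c(-1.254, -0.174, 0.356),
    CB = c(-0.086, 0.351, -0.494), CG = c(1.296, 0.309, 0.194),
    CD1 = c(1.779, -1.105, 0.515), CD2 = c(2.330, 1.010, -0.693)))

get_template <- function(res_name) {
  if (res_name == "TRP") {
    trp <- ideal_tryptophan()
    keep <- c("N", "CA", "CB", "CG", "CD1", "CD2", "NE1", "CE2", "CE3",
              "CZ2", "CZ3", "CH2")
    m <- coords(trp)[match(keep, trp$atom$name), ]
    rownames(m) <- keep
    return(m)
  }
  SIDECHAIN_TEMPLATES[[res_name]]
}

AA3 <- c(A = "ALA", L = "LEU", H = "HIS", G = "GLY", W = "TRP", T = "THR",
         K = "LYS", S = "SER", V = "VAL", F = "PHE", Y = "TYR", I = "ILE",
         E = "GLU", D = "ASP", N = "ASN", Q = "GLN", R = "ARG", M = "MET",
         C = "CYS", P = "PRO")

#' Build a peptide from backbone torsions
#'
#' Constructs an ideal-geometry polypeptide backbone (N, CA, C, O) from
#' per-residue phi/psi angles (NeRF chain extension, omega fixed trans),
#' adds CB to non-glycine residues, and grafts full idealized side chains
#' for TRP, HIS and LEU (other residue types are represented to CB only --
#' sufficient for backbone-torsion, anchor-rotamer and bulky-side-chain
#' analyses on synthetic fixtures).
#'
#' @param sequence one-letter amino acid string (e.g. `"ALHGGWTTK"`).
#' @param phi,psi backbone torsions in degrees, recycled to the sequence
#'   length. phi of residue 1 and psi of the last residue are undefined and
#'   ignored.
#' @param chain chain id (default "P").
#' @return a [Structure].
#' @export
build_peptide <- function(sequence, phi = -139, psi = 135, chain = "P") {
  seq1 <- strsplit(sequence, "")[[1]]
  nres <- length(seq1)
  stopifnot(nres >= 2, all(seq1 %in% names(AA3)))
  phi <- rep_len(phi, nres); psi <- rep_len(psi, nres)
  b_n <- 1.458; b_ca <- 1.525; b_c <- 1.329   # N-CA, CA-C, C-N bond lengths
  a_ncac <- 111.2; a_cacn <- 116.2; a_cnca <- 121.7
  pos <- list()
  pos[[1]] <- list(N = c(0, 0, 0), CA = c(b_n, 0, 0))
  pos[[1]]$C <- place_atom(c(0, 1, 0), pos[[1]]$N, pos[[1]]$CA,
                           b_ca, a_ncac, psi[1] + 60)  # arbitrary branch
  for (i in 2:nres) {
    prev <- pos[[i - 1]]
    N <- place_atom(prev$N, prev$CA, prev$C, b_c, a_cacn, psi[i - 1])
    CA <- place_atom(prev$CA, prev$C, N, b_n, a_cnca, 180)   # omega trans
    C <- place_atom(prev$C, N, CA, b_ca, a_ncac, phi[i])
    pos[[i]] <- list(N = N, CA = CA, C = C)
  }
  rows <- list()
  add <- function(res_i, name, xyz) {
    rows[[length(rows) + 1]] <<- data.frame(
      name = name, res_name = AA3[[seq1[res_i]]], chain = chain,
      res_seq = res_i, x = xyz[1], y = xyz[2], z = xyz[3],
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(nres)) {
    p <- pos[[i]]
    add(i, "N", p$N); add(i, "CA", p$CA); add(i, "C", p$C)
    o_dih <- if (i < nres) psi[i] + 180 else psi[i]
    add(i, "O", place_atom(p$N, p$CA, p$C, 1.231, 120.5, o_dih))
    rn <- AA3[[seq1[i]]]
    if (rn != "GLY") {
      cb <- place_atom(p$C, p$N, p$CA, 1.53, 110.5, 122.5)
      add(i, "CB", cb)
      tmpl <- get_template(rn)
      if (!is.null(tmpl)) {
        fit <- superpose(tmpl[c("N", "CA", "CB"), ],
                         rbind(p$N, p$CA, cb))
        sc <- apply_transform(tmpl[setdiff(rownames(tmpl),
                                           c("N", "CA", "CB")), ,
                                   drop = FALSE], fit)
        for (k in seq_len(nrow(sc)))
          add(i, setdiff(rownames(tmpl), c("N", "CA", "CB"))[k], sc[k, ])
      }
    }
  }
  atom <- do.call(rbind, rows)
  assign_parameters(new_structure(atom, title = sequence))
}

rot_about_x_axis <- function(xyz, origin, theta_deg) {
  th <- theta_deg * pi / 180
  rel <- sweep(xyz, 2, origin)
  y <- rel[, 2] * cos(th) - rel[, 3] * sin(th)
  z <- rel[, 2] * sin(th) + rel[, 3] * cos(th)
  sweep(cbind(rel[, 1], y, z), 2, origin, "+")
}

plate_atoms <- function(xs, ys, zs, chain, res_name) {
  g <- expand.grid(x = xs, y = ys, z = zs)
  data.frame(name = "C", res_name = res_name, chain = chain,
             res_seq = seq_len(nrow(g)), x = g$x, y = g$y, z = g$z,
             element = "C", stringsAsFactors = FALSE)
}

#' Build an idealized toy binding groove with a peptide
#'
#' Deterministic stand-in for a class I MHC binding groove: a sealed
#' rectangular chamber (continuum walls of carbon atoms at 0.6 Angstrom
#' spacing) whose roof plate represents the floor-facing surface of the
#' peptide bulge, enclosing an under-peptide void of designed volume
#' 400 Angstrom^3 (clear span 10 x 8 x 5); open wall rows above the roof
#' stand in for the alpha1 (+y) and alpha2 (-y) helices; and a 9-residue
#' peptide along the groove axis (x) with a full tryptophan side chain at
#' position 6 and the preset-dependent anchor at position 2
#' (`"neoantigen"`: leucine, rigid; `"wt"`: histidine, mobile).
#'
#' The returned structure carries attributes used by
#' [simulate_flip_trajectory()]: `conformers` (absolute coordinates of the
#' position-6 side chain in the alpha1-aligned, under-backbone and
#' alpha2-flipped poses), `anchor_rotamers`, `void_volume` (the designed
#' 400), and `preset`.
#'
#' Chains: `F` floor, `S` bulge shelf (peptide-proxy roof), `A`/`B` walls
#' and helix rows, `E` end caps, `P` peptide.
#'
#' @param preset `"neoantigen"` (rigid anchor) or `"wt"` (mobile anchor).
#' @return a [Structure] with parameters assigned.
#' @export
build_toy_groove <- function(preset = c("neoantigen", "wt")) {
  preset <- match.arg(preset)
  sp <- 0.6
  # sealed chamber: clear void x [7,17], y [-4,4], z [3.1,8.1] = 400 A^3
  # (plate planes sit vdW+probe = 1.7+1.4 = 3.1 A outside each void face)
  x0 <- 3.9; x1 <- 20.1; y0 <- -7.1; y1 <- 7.1; z0 <- 0; z1 <- 11.2
  xs <- seq(x0, x1, by = sp); ys <- seq(y0, y1, by = sp)
  zs <- seq(z0, z1, by = sp)
  plates <- rbind(
    plate_atoms(xs, ys, z0, "F", "FLR"),          # groove floor
    plate_atoms(xs, ys, z1, "S", "SHF"),          # peptide-bulge shelf
    plate_atoms(xs, y0, zs, "B", "WAL"),
    plate_atoms(xs, y1, zs, "A", "WAL"),
    plate_atoms(x0, ys, zs, "E", "CAP"),
    plate_atoms(x1, ys, zs, "E", "CAP"))
  # open helix rows above the shelf (alpha1 at +y, alpha2 at -y)
  helix <- rbind(
    plate_atoms(seq(x0, x1, by = 1.5), 6.5, seq(12.5, 17, by = 1.5),
                "A", "HLX"),
    plate_atoms(seq(x0, x1, by = 1.5), -6.5, seq(12.5, 17, by = 1.5),
                "B", "HLX"))
  seqs <- c(neoantigen = "ALHGGWTTK", wt = "AHHGGWTTK")
  # anchor is position 2: neoantigen L (rigid), wt H (mobile)
  pep <- build_peptide(seqs[[preset]], phi = -139, psi = 135, chain = "P")
  # orient the peptide along +x, centered over the chamber at z ~ 13.4
  xyz <- coords(pep)
  ca <- xyz[pep$atom$name == "CA", ]
  axis <- ca[nrow(ca), ] - ca[1, ]; axis <- axis / sqrt(sum(axis^2))
  # rotation taking the CA axis to +x (Rodrigues)
  v <- cross3(axis, c(1, 0, 0)); s <- sqrt(sum(v^2)); cth <- axis[1]
  R <- if (s < 1e-12) diag(3) else {
    K <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
    diag(3) + K + K %*% K * (1 - cth) / s^2
  }
  xyz <- xyz %*% t(R)
  ca_now <- xyz[pep$atom$name == "CA", ]
  xyz <- sweep(xyz, 2, colMeans(ca_now))
  xyz[, 1] <- xyz[, 1] + 12; xyz[, 3] <- xyz[, 3] + 13.4
  pep <- set_coords(pep, xyz)
  atom <- rbind(plates, helix)
  atom$res_seq <- seq_len(nrow(atom))
  atom <- rbind(atom,
                cbind(pep$atom[, c("name", "res_name", "chain", "res_seq",
                                   "x", "y", "z")],
                      element = pep$atom$element))
  atom$serial <- seq_len(nrow(atom))
  groove <- assign_parameters(
    new_structure(atom, title = sprintf("toy groove (%s-like)", preset)))
  # conformer library for the position-6 side chain: poses rotated about
  # the groove axis through CA6, from a base pose pointing up (+z)
  p6 <- which(groove$atom$chain == "P" & groove$atom$res_seq == 6 &
                !(groove$atom$name %in% BACKBONE_NAMES))
  ca6 <- unlist(groove$atom[groove$atom$chain == "P" &
                              groove$atom$res_seq == 6 &
                              groove$atom$name == "CA",
                            c("x", "y", "z")])
  sc <- coords(groove)[p6, , drop = FALSE]
  cen <- colMeans(sc) - ca6
  base <- rot_about_x_axis(sc, ca6, -atan2(cen[2], cen[3]) * 180 / pi)
  conformers <- list(alpha1 = rot_about_x_axis(base, ca6, 57),
                     under = rot_about_x_axis(base, ca6, 180),
                     alpha2 = rot_about_x_axis(base, ca6, -57))
  # anchor rotamers: position-2 side chain swung about the groove axis
  p2 <- which(groove$atom$chain == "P" & groove$atom$res_seq == 2 &
                !(groove$atom$name %in% BACKBONE_NAMES))
  ca2 <- unlist(groove$atom[groove$atom$chain == "P" &
                              groove$atom$res_seq == 2 &
                              groove$atom$name == "CA",
                            c("x", "y", "z")])
  sc2 <- coords(groove)[p2, , drop = FALSE]
  rotamers <- list(rot_about_x_axis(sc2, ca2, 0),
                   rot_about_x_axis(sc2, ca2, 80))
  attr(groove, "p6_sidechain") <- p6
  attr(groove, "p2_sidechain") <- p2
  attr(groove, "conformers") <- conformers
  attr(groove, "anchor_rotamers") <- rotamers
  attr(groove, "void_volume") <- 400
  attr(groove, "preset") <- preset
  attr(groove, "axes") <- list(groove = c(1, 0, 0), up = c(0, 0, 1))
  groove
}

#' Specification for a synthetic side-chain flip trajectory
#'
#' @param n_frames number of frames.
#' @param conformers names of the conformer-library poses to use (subset of
#'   `"alpha1"`, `"under"`, `"alpha2"`).
#' @param trans per-frame Markov transition-probability matrix (rows sum to
#'   1), one row/column per conformer. The default two-state chain has
#'   stationary populations (0.6, 0.4).
#' @param sigma isotropic Gaussian positional noise per coordinate,
#'   Angstrom.
#' @param anchor `"rigid"` or `"mobile"`; default follows the groove
#'   preset (`"neoantigen"` is rigid, `"wt"` mobile).
#' @param anchor_switch_prob per-frame switch probability of the mobile
#'   anchor's two-rotamer process.
#' @param seed RNG seed (required; generation is a pure function of
#'   parameters and seed).
#' @return an object of class `FlipSimSpec`.
#' @export
flip_sim_spec <- function(n_frames = 2000,
                          conformers = c("alpha1", "under"),
                          trans = rbind(c(0.96, 0.04), c(0.06, 0.94)),
                          sigma = 0.08, anchor = NULL,
                          anchor_switch_prob = 0.04, seed = NULL) {
  trans <- as.matrix(trans)
  if (nrow(trans) != length(conformers) || ncol(trans) != length(conformers))
    stop("transition matrix must be square with one row per conformer")
  if (any(trans < 0) || any(abs(rowSums(trans) - 1) > 1e-9))
    stop("transition matrix rows must be non-negative and sum to 1")
  stopifnot(sigma >= 0, n_frames >= 1)
  structure(list(n_frames = as.integer(n_frames), conformers = conformers,
                 trans = trans, sigma = sigma, anchor = anchor,
                 anchor_switch_prob = anchor_switch_prob, seed = seed),
            class = "FlipSimSpec")
}

markov_stationary <- function(trans) {
  e <- eigen(t(trans))
  v <- Re(e$vectors[, which.min(abs(e$values - 1))])
  v / sum(v)
}

sample_markov <- function(n, trans) {
  k <- nrow(trans)
  states <- integer(n)
  states[1] <- sample.int(k, 1, prob = markov_stationary(trans))
  for (i in seq_len(n - 1))
    states[i + 1] <- sample.int(k, 1, prob = trans[states[i], ])
  states
}

#' Simulate a synthetic side-chain flip trajectory
#'
#' Draws a Markov state sequence over the chosen conformer poses and emits,
#' per frame, the peptide coordinates with the position-6 side chain set to
#' the current pose plus isotropic Gaussian noise. With a mobile anchor, a
#' second, independent two-rotamer Markov process jitters the position-2
#' side chain (the WT-like histidine anchor); a rigid anchor only carries
#' the background noise. The trajectory covers the peptide chain only
#' (the groove walls are static scaffolding).
#'
#' @param groove a [build_toy_groove()] structure.
#' @param spec a [flip_sim_spec()] (must carry a seed).
#' @return a [Trajectory] over the peptide atoms with attributes `states`
#'   (ground-truth conformer sequence), `anchor_states`, and
#'   `stationary` (the chain's stationary distribution).
#' @export
simulate_flip_trajectory <- function(groove, spec) {
  stopifnot(inherits(spec, "FlipSimSpec"))
  conf_lib <- attr(groove, "conformers")
  stopifnot(!is.null(conf_lib), all(spec$conformers %in% names(conf_lib)))
  anchor <- spec$anchor %||%
    if (identical(attr(groove, "preset"), "wt")) "mobile" else "rigid"
  pep_idx <- which(groove$atom$chain == "P")
  p6 <- match(attr(groove, "p6_sidechain"), pep_idx)
  p2 <- match(attr(groove, "p2_sidechain"), pep_idx)
  rotamers <- lapply(attr(groove, "anchor_rotamers"), identity)
  base <- coords(groove)[pep_idx, , drop = FALSE]
  top <- groove
  top$atom <- top$atom[pep_idx, , drop = FALSE]
  rownames(top$atom) <- NULL
  top <- new_structure(top$atom, title = "peptide (flip simulation)")
  top <- assign_parameters(top)
  nf <- spec$n_frames
  with_seed(spec$seed, {
    states <- sample_markov(nf, spec$trans)
    anchor_states <- if (anchor == "mobile") {
      tr <- rbind(c(1 - spec$anchor_switch_prob, spec$anchor_switch_prob),
                  c(spec$anchor_switch_prob, 1 - spec$anchor_switch_prob))
      sample_markov(nf, tr)
    } else rep(1L, nf)
    frames <- array(0, dim = c(nrow(base), 3, nf))
    for (f in seq_len(nf)) {
      xyz <- base
      xyz[p6, ] <- conf_lib[[spec$conformers[states[f]]]]
      xyz[p2, ] <- rotamers[[anchor_states[f]]]
      if (spec$sigma > 0)
        xyz <- xyz + matrix(rnorm(length(xyz), sd = spec$sigma),
                            ncol = 3)
      frames[, , f] <- xyz
    }
    traj <- new_trajectory(top, frames)
    attr(traj, "states") <- states
    attr(traj, "anchor_states") <- anchor_states
    attr(traj, "stationary") <- markov_stationary(spec$trans)
    traj
  })
}

#' Simulate a 1:1 binding isotherm
#'
#' R = R_max C / (K_D + C) with multiplicative Gaussian noise of relative
#' standard deviation `sigma`.
#'
#' @param K_D dissociation constant, M.
#' @param R_max saturating response.
#' @param concentrations analyte concentrations, M (strictly increasing).
#' @param sigma relative noise (e.g. 0.02 for 2%).
#' @param seed RNG seed (required when sigma > 0).
#' @return a [binding_isotherm()] data.frame.
#' @export
simulate_isotherm <- function(K_D, R_max, concentrations, sigma = 0,
                              seed = NULL) {
  stopifnot(K_D > 0, R_max > 0, all(concentrations > 0))
  r <- R_max * concentrations / (K_D + concentrations)
  if (sigma > 0)
    r <- with_seed(seed, r * (1 + rnorm(length(r), sd = sigma)))
  binding_isotherm(concentrations, r)
}

#' Simulate an exponential dissociation trace
#'
#' Single- or multi-phase decay: R(t) = sum_i A_i exp(-k_i t) + offset,
#' plus Gaussian noise of standard deviation `sigma` (absolute units).
#'
#' @param rates decay rate(s), s^-1.
#' @param amplitudes amplitude(s), recycled to the rates.
#' @param offset constant baseline.
#' @param duration trace length, s.
#' @param n_points number of samples (default 200).
#' @param sigma absolute noise SD.
#' @param seed RNG seed (required when sigma > 0).
#' @return a [kinetic_trace()] data.frame.
#' @export
simulate_decay <- function(rates, amplitudes = 1, offset = 0, duration,
                           n_points = 200, sigma = 0, seed = NULL) {
  stopifnot(all(rates > 0), duration > 0, n_points >= 10)
  amplitudes <- rep_len(amplitudes, length(rates))
  t <- seq(0, duration, length.out = n_points)
  r <- offset + rowSums(vapply(seq_along(rates), function(i)
    amplitudes[i] * exp(-rates[i] * t), numeric(n_points)))
  if (sigma > 0) r <- with_seed(seed, r + rnorm(n_points, sd = sigma))
  kinetic_trace(t, r)
}

#' Simulate a 1D spectrum of Lorentzian peaks
#'
#' @param peaks data.frame with columns `center` (ppm), `fwhm` (ppm),
#'   `area`.
#' @param baseline constant baseline.
#' @param sigma noise SD relative to the maximum peak height.
#' @param ppm_range length-2 axis range.
#' @param n_points axis points (default 2048).
#' @param seed RNG seed (required when sigma > 0).
#' @return a [spectrum1d()] data.frame (axis descending).
#' @export
simulate_spectrum <- function(peaks, baseline = 0, sigma = 0,
                              ppm_range, n_points = 2048, seed = NULL) {
  stopifnot(all(c("center", "fwhm", "area") %in% names(peaks)))
  if (any(peaks$center < min(ppm_range) | peaks$center > max(ppm_range)))
    stop("peak center outside the ppm axis range")
  x <- seq(max(ppm_range), min(ppm_range), length.out = n_points)
  heights <- 2 * peaks$area / (pi * peaks$fwhm)
  y <- rep(baseline, n_points)
  for (i in seq_len(nrow(peaks)))
    y <- y + lorentzian(x, peaks$center[i], peaks$fwhm[i], heights[i])
  if (sigma > 0)
    y <- with_seed(seed, y + rnorm(n_points, sd = sigma * max(heights)))
  spectrum1d(x, y)
}

#' Simulate a DSF melt-derivative curve
#'
#' Sum of Gaussians (peak height parameterization) plus Gaussian noise.
#'
#' @param centers melt temperatures, degrees C.
#' @param widths Gaussian sigmas, degrees C.
#' @param amplitudes peak heights.
#' @param sigma noise SD relative to the maximum amplitude.
#' @param t_range length-2 temperature range, degrees C.
#' @param n_points samples (default 150).
#' @param seed RNG seed (required when sigma > 0).
#' @return a [melt_curve()] data.frame.
#' @export
simulate_melt <- function(centers, widths, amplitudes, sigma = 0,
                          t_range = c(20, 95), n_points = 150, seed = NULL) {
  stopifnot(all(centers > min(t_range)), all(centers < max(t_range)),
            length(widths) == length(centers),
            length(amplitudes) == length(centers))
  t <- seq(t_range[1], t_range[2], length.out = n_points)
  y <- rowSums(vapply(seq_along(centers), function(i)
    amplitudes[i] * exp(-(t - centers[i])^2 / (2 * widths[i]^2)),
    numeric(n_points)))
  if (sigma > 0)
    y <- with_seed(seed, y + rnorm(n_points, sd = sigma * max(amplitudes)))
  melt_curve(t, y)
}
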