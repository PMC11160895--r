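test_that("superposition recovers rigid motions and matches a grid-search oracle", {
  set.seed(3)
  pts <- matrix(rnorm(15, sd = 3), ncol = 3)
  fit <- superpose(pts, pts)
  expect_lt(fit$rmsd, 1e-9)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-9)
  expect_lt(abs(det(fit$rotation) - 1), 1e-9)
  # 90 degrees about z plus translation: rmsd 0 after superposition
  Rz <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)
  moved <- sweep(pts %*% t(Rz), 2, c(5, 0, 0), "+")
  fit2 <- superpose(pts, moved)
  expect_lt(fit2$rmsd, 1e-9)
  expect_lt(abs(det(fit2$rotation) - 1), 1e-9)
  # 4-point toy with one displaced point: agree with brute-force search
  ref <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0), c(0, 0, 2))
  mob <- ref; mob[4, ] <- mob[4, ] + c(1, 0, 0)
  fit3 <- superpose(mob, ref)
  expect_equal(fit3$rmsd, brute_force_rmsd(mob, ref), tolerance = 1e-3)
  expect_error(superpose(ref[1:2, ], ref[1:2, ]), "3 points")
  line <- cbind(0:4, 0, 0)
  expect_error(superpose(line, line), "collinear")
})

test_that("RMSD is invariant under a common rigid transform", {
  set.seed(11)
  for (rep in 1:5) {
    a <- matrix(rnorm(30), ncol = 3); b <- matrix(rnorm(30), ncol = 3)
    th <- runif(3, -pi, pi)
    R1 <- matrix(c(cos(th[1]), sin(th[1]), 0, -sin(th[1]), cos(th[1]), 0,
                   0, 0, 1), 3, 3)
    shift <- rnorm(3, sd = 10)
    r0 <- superpose(a, b)$rmsd
    r1 <- superpose(sweep(a %*% R1, 2, shift, "+"), b)$rmsd
    expect_equal(r0, r1, tolerance = 1e-9)
  }
})

test_that("rmsd_series applies fit-then-measure", {
  set.seed(7)
  target <- point_structure(matrix(rnorm(60, sd = 4), ncol = 3))
  traj <- new_trajectory(target, list(coords(target), coords(target)))
  allsel <- atom_selection(chain = "A")
  expect_equal(rmsd_series(traj, target, allsel), c(0, 0), tolerance = 1e-9)
  # fit region held fixed, measured atoms uniformly offset by d after fit
  fit_sel <- atom_selection(res_seq = 1:15)
  meas_sel <- atom_selection(res_seq = 16:20)
  d <- 2.5
  xyz <- coords(target)
  xyz[16:20, 1] <- xyz[16:20, 1] + d
  traj2 <- new_trajectory(target, list(xyz))
  expect_equal(rmsd_series(traj2, target, fit_sel, meas_sel), d,
               tolerance = 1e-9)
})

test_that("pairwise RMSD is symmetric, zero-diagonal, and consistent", {
  s <- point_structure(matrix(rnorm(30, sd = 3), ncol = 3))
  traj <- new_trajectory(s, list(coords(s), coords(s), coords(s)))
  sel <- atom_selection(chain = "A")
  m <- pairwise_rmsd(traj, measure_sel = sel)
  expect_equal(m, matrix(0, 3, 3), tolerance = 1e-9)
  set.seed(21)
  frames <- lapply(1:4, function(i) coords(s) + matrix(rnorm(30), ncol = 3))
  t2 <- new_trajectory(s, frames)
  m2 <- pairwise_rmsd(t2, fit_sel = sel, measure_sel = sel)
  expect_symmetric_zero_diag(m2)
  # 2-frame off-diagonal equals rmsd_series against the other frame
  t3 <- new_trajectory(s, frames[1:2])
  direct <- rmsd_series(t3, set_coords(s, frames[[2]]), sel)[1]
  expect_equal(pairwise_rmsd(t3, fit_sel = sel, measure_sel = sel)[1, 2],
               direct, tolerance = 1e-9)
  # pre-aligned fast path agrees with raw per-pair computation
  m4 <- pairwise_rmsd(t2, measure_sel = sel)
  expect_equal(m4[1, 3], rmsd_raw(frames[[1]], frames[[3]]),
               tolerance = 1e-9)
})

test_that("mass-weighted RMSF matches closed forms and direct summation", {
  static <- point_structure(matrix(rnorm(30), ncol = 3))
  trj <- new_trajectory(static, list(coords(static), coords(static)))
  expect_equal(mass_weighted_rmsf(trj)$rmsf, rep(0, 10), tolerance = 1e-9)
  expect_error(mass_weighted_rmsf(new_trajectory(static,
                                                 list(coords(static)))),
               "single frame")
  # one-atom residue alternating between two points 2d apart -> RMSF d
  d <- 0.7
  one <- point_structure(c(0, 0, 0))
  t1 <- new_trajectory(one, list(matrix(c(-d, 0, 0), 1),
                                 matrix(c(d, 0, 0), 1)))
  expect_equal(mass_weighted_rmsf(t1)$rmsf, d, tolerance = 1e-9)
  # two-atom residue, masses 12 and 1: sqrt((12 v1 + v2) / 13)
  atom <- data.frame(name = c("CA", "HA"), res_name = "GLY", chain = "A",
                     res_seq = 1, x = c(0, 2), y = 0, z = 0,
                     element = c("C", "H"), stringsAsFactors = FALSE)
  two <- assign_parameters(new_structure(atom))
  a1 <- c(0.3, 0.9); a2 <- c(-0.3, -0.9)   # x-displacements per frame
  frames <- list(cbind(c(0, 2) + a1, 0, 0), cbind(c(0, 2) + a2, 0, 0))
  t2 <- new_trajectory(two, frames)
  v1 <- mean(a1[1]^2 + a2[1]^2) / 1  # variance about mean (mean is 0)
  v1 <- (a1[1]^2 + a2[1]^2) / 2; v2 <- (a1[2]^2 + a2[2]^2) / 2
  m <- c(12.011, 1.008)
  expected <- sqrt((m[1] * v1 + m[2] * v2) / sum(m))
  got <- mass_weighted_rmsf(t2, atom_selection(chain = "A"))
  expect_equal(got$rmsf, expected, tolerance = 1e-6)
})

test_that("torsion angles follow the IUPAC convention", {
  # trans (antiperiplanar) coplanar points -> 180; eclipsed -> 0
  expect_equal(dihedral_angle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0),
                              c(1, -1, 0)), 180)
  expect_equal(dihedral_angle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0),
                              c(1, 1, 0)), 0)
  # ideal alpha-helix built from phi = -57, psi = -47
  p <- build_peptide("AAAAAA", phi = -57, psi = -47)
  phi <- torsion_series(p, "P", 1:6, "phi")$angles[1, ]
  psi <- torsion_series(p, "P", 1:6, "psi")$angles[1, ]
  expect_true(is.na(phi[1]) && is.na(psi[6]))
  expect_equal(unname(phi[2:6]), rep(-57, 5), tolerance = 1)
  expect_equal(unname(psi[1:5]), rep(-47, 5), tolerance = 1)
  # glycine chi1 is absent, not zero
  g <- build_peptide("AGA")
  chi <- torsion_series(g, "P", 1:3, "chi1")
  expect_true(is.na(chi$angles[1, 2]))
})

test_that("contacts use a strict < cutoff and match a brute-force oracle", {
  mk <- function(d) {
    s <- point_structure(rbind(c(0, 0, 0), c(d, 0, 0)),
                         chain = c("A", "B"))
    new_trajectory(s, list(coords(s)))
  }
  a <- atom_selection(chain = "A"); b <- atom_selection(chain = "B")
  expect_equal(contact_series(mk(3.9), a, b)$counts, 1L)
  expect_equal(contact_series(mk(4.0), a, b)$counts, 0L)  # strict <
  set.seed(17)
  xyz <- matrix(runif(60, 0, 8), ncol = 3)
  s <- point_structure(xyz, chain = rep(c("A", "B"), each = 10))
  traj <- new_trajectory(s, list(xyz))
  got <- contact_series(traj, a, b)$counts
  oracle <- sum(as.matrix(dist(xyz))[1:10, 11:20] < 4)
  expect_equal(got, oracle)
  expect_error(contact_series(traj, a, a), "overlap")
})

test_that("hydrogen bonds use an inclusive 3.5 A donor-acceptor cutoff", {
  mk_traj <- function(ds) {
    atom <- data.frame(name = c("NE1", "O"), res_name = c("TRP", "TYR"),
                       chain = c("P", "H"), res_seq = c(6, 99),
                       x = 0, y = 0, z = 0, element = c("N", "O"),
                       stringsAsFactors = FALSE)
    top <- assign_parameters(new_structure(atom))
    new_trajectory(top, lapply(ds, function(d)
      rbind(c(0, 0, 0), c(d, 0, 0))))
  }
  don <- atom_selection(name = "NE1"); acc <- atom_selection(name = "O")
  hb <- hbond_series(mk_traj(3.4), don, acc)
  expect_true(hb$presence[1, 1])
  expect_equal(hbond_series(mk_traj(3.5), don, acc)$persistence, 1)
  expect_equal(hbond_series(mk_traj(3.6), don, acc)$persistence, 0)
  # 23 of 100 frames within cutoff -> persistence 23%
  ds <- c(rep(3.0, 23), rep(6.0, 77))
  expect_equal(hbond_series(mk_traj(ds), don, acc)$persistence, 0.23)
  expect_error(hbond_series(mk_traj(3), atom_selection(name = "XX"), acc),
               "empty")
})

test_that("center-of-mass distances use mass weighting", {
  s <- point_structure(rbind(c(0, 0, 0), c(5, 0, 0)), chain = c("A", "B"))
  traj <- new_trajectory(s, list(coords(s)))
  expect_equal(com_distance_series(traj, atom_selection(chain = "A"),
                                   atom_selection(chain = "B")), 5)
  expect_equal(com_distance_series(traj, atom_selection(chain = "A"),
                                   atom_selection(chain = "A")), 0)
  # unequal masses: hand-computed weighted centroids
  atom <- data.frame(name = c("C1", "N1", "O1", "C2", "S2", "C3"),
                     res_name = "LIG", chain = c(rep("A", 3), rep("B", 3)),
                     res_seq = c(1, 1, 1, 2, 2, 2),
                     x = c(0, 1, 2, 10, 11, 12), y = 0, z = 0,
                     element = c("C", "N", "O", "C", "S", "C"),
                     stringsAsFactors = FALSE)
  st <- assign_parameters(new_structure(atom))
  tr <- new_trajectory(st, list(coords(st)))
  mA <- c(12.011, 14.007, 15.999); mB <- c(12.011, 32.06, 12.011)
  comA <- sum(c(0, 1, 2) * mA) / sum(mA)
  comB <- sum(c(10, 11, 12) * mB) / sum(mB)
  expect_equal(com_distance_series(tr, atom_selection(chain = "A"),
                                   atom_selection(chain = "B")),
               comB - comA, tolerance = 1e-9)
})

test_that("vdW overlap is the clamped radius-sum excess", {
  mk <- function(d) point_structure(rbind(c(0, 0, 0), c(d, 0, 0)),
                                    chain = c("A", "B"))
  ov <- function(d) vdw_overlap(mk(d), atom_selection(chain = "A"),
                                atom_selection(chain = "B"))
  expect_equal(ov(3.0)$pairs$overlap, 0.40, tolerance = 1e-9)
  expect_equal(ov(3.0)$mean_overlap, 0.40, tolerance = 1e-9)
  expect_equal(ov(3.4)$pairs$overlap, 0)
  expect_equal(ov(4.0)$pairs$overlap, 0)   # clamped, never negative
})

test_that("SASA matches closed forms and is monotone under burial", {
  one <- point_structure(c(0, 0, 0))
  a1 <- sasa(one)$total
  expect_equal(a1, 4 * pi * (1.7 + 1.4)^2, tolerance = 0.01 * a1)
  far <- point_structure(rbind(c(0, 0, 0), c(50, 0, 0)))
  expect_equal(sasa(far)$total, 2 * a1, tolerance = 1e-6)
  # two carbons at 3.4 A: analytic two-sphere (spherical cap) oracle
  d <- 3.4; R <- 1.7 + 1.4
  cos_a <- d / (2 * R)  # equal radii
  buried_per_sphere <- 2 * pi * R^2 * (1 - cos_a)
  oracle <- 2 * (4 * pi * R^2 - buried_per_sphere)
  near <- point_structure(rbind(c(0, 0, 0), c(d, 0, 0)))
  expect_equal(sasa(near)$total, oracle, tolerance = 0.02 * oracle)
  expect_lt(sasa(near)$total, 2 * a1)
})

test_that("Ramachandran strain counts residues outside generous regions", {
  p <- build_peptide("AAAAAA", phi = -60, psi = -45)
  phi <- torsion_series(p, "P", 1:6, "phi")
  psi <- torsion_series(p, "P", 1:6, "psi")
  expect_equal(ramachandran_strain(phi, psi), 0L)
  ref <- ramachandran_reference()
  expect_equal(pmhcdyn:::rama_level(-60, -45, ref), 2L)   # allowed
  expect_equal(pmhcdyn:::rama_level(75, -60, ref), 0L)    # disallowed
  # allowed region is nested inside generously allowed
  expect_true(all(ref$level[ref$level == 2L] >= 1L))
  expect_gt(sum(ref$level >= 1), sum(ref$level == 2))
  # a strained non-glycine residue counts once; glycine never counts
  strained <- build_peptide("AAAAAA", phi = 75, psi = -60)
  sphi <- torsion_series(strained, "P", 1:6, "phi")
  spsi <- torsion_series(strained, "P", 1:6, "psi")
  expect_equal(ramachandran_strain(sphi, spsi), 4L)  # non-terminal residues
  gly <- build_peptide("GGGGGG", phi = 75, psi = -60)
  gphi <- torsion_series(gly, "P", 1:6, "phi")
  gpsi <- torsion_series(gly, "P", 1:6, "psi")
  expect_equal(ramachandran_strain(gphi, gpsi), 0L)
})
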