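test_that("circular means handle wraparound and match the vector-sum oracle", {
  expect_equal(circular_mean_torsions(matrix(rep(170, 5))), 170,
               tolerance = 1e-9)
  expect_equal(circular_mean_torsions(matrix(c(175, -175))), 180,
               tolerance = 1e-9)
  set.seed(5)
  v <- runif(200, -180, 180)
  oracle <- atan2(mean(sin(v * pi / 180)), mean(cos(v * pi / 180))) * 180 / pi
  expect_equal(circular_mean_torsions(matrix(v)), oracle, tolerance = 1e-9)
})

test_that("D-score spans [0, 8] with the defining values", {
  mk <- function(phi, psi) data.frame(phi = phi, psi = psi)
  expect_equal(dscore(mk(-60, -45), mk(-60, -45)), 0)
  expect_equal(dscore(mk(0, 0), mk(180, 180)), 8)
  expect_equal(dscore(mk(90, 10), mk(0, 10)), 2)
  # symmetry and 360-degree invariance
  set.seed(9)
  a <- mk(runif(20, -180, 180), runif(20, -180, 180))
  b <- mk(runif(20, -180, 180), runif(20, -180, 180))
  expect_equal(dscore(a, b), dscore(b, a), tolerance = 1e-12)
  a360 <- mk(a$phi + 360, a$psi - 360)
  expect_equal(dscore(a, b), dscore(a360, b), tolerance = 1e-9)
  expect_true(all(dscore(a, b) >= 0 & dscore(a, b) <= 8))
})

test_that("D-score profile between ensembles compares circular-mean angles", {
  g <- build_toy_groove("neoantigen")
  t1 <- simulate_flip_trajectory(g, flip_sim_spec(n_frames = 30, seed = 1))
  prof <- dscore_profile(t1, t1, "P", 2:8)
  expect_equal(prof$d, rep(0, 7), tolerance = 1e-12)
})

test_that("occupancy grids tally atom centers and conserve counts", {
  one <- point_structure(c(0.51, 0.52, 0.53))
  static <- new_trajectory(one, rep(list(coords(one)), 100))
  g <- occupancy_grid(static, atom_selection(chain = "A"))
  expect_equal(sum(g$frame_frac == 1), 1)
  expect_equal(sum(g$frame_frac > 0), 1)
  # alternating two sites >= spacing apart: two voxels at 0.5
  alt <- new_trajectory(one, rep(list(matrix(c(0, 0, 0), 1),
                                      matrix(c(1, 0, 0), 1)), 25))
  g2 <- occupancy_grid(alt, atom_selection(chain = "A"), spacing = 0.1)
  expect_equal(sort(g2$frame_frac[g2$frame_frac > 0]), c(0.5, 0.5))
  # conservation: total tallies = n_frames x n_tracked_atoms
  groove <- build_toy_groove("neoantigen")
  tr <- simulate_flip_trajectory(groove, flip_sim_spec(n_frames = 50, seed = 2))
  sel <- atom_selection(res_seq = 6, sidechain = TRUE)
  g3 <- occupancy_grid(tr, sel, spacing = 0.5)
  expect_equal(sum(g3$counts), 50 * g3$n_atoms)
  expect_true(all(g3$frame_frac >= 0 & g3$frame_frac <= 1))
})

test_that("grid thresholding is inclusive at the boundary and monotone", {
  one <- point_structure(c(0, 0, 0))
  frames <- c(rep(list(matrix(c(0, 0, 0), 1)), 10),
              rep(list(matrix(c(2, 0, 0), 1)), 90))
  tr <- new_trajectory(one, frames)
  g <- occupancy_grid(tr, atom_selection(chain = "A"), spacing = 0.5)
  # the 10%-occupied voxel is included at threshold 0.10 ...
  expect_equal(threshold_grid(g, 0.10)$n_voxels, 2)
  # ... and excluded just above it
  expect_equal(threshold_grid(g, 0.101)$n_voxels, 1)
  # volume is monotone non-increasing in the threshold
  vols <- vapply(c(0.05, 0.1, 0.5, 0.95), function(f)
    threshold_grid(g, f)$volume, numeric(1))
  expect_true(all(diff(vols) <= 0))
  # uniformly occupied voxels survive any threshold up to their fraction:
  # a single static atom gives one voxel at fraction 1 at every threshold
  static <- new_trajectory(one, rep(list(matrix(c(0, 0, 0), 1)), 10))
  gs <- occupancy_grid(static, atom_selection(chain = "A"), spacing = 0.5)
  expect_equal(threshold_grid(gs, 1)$volume, gs$spacing^3)
})

test_that("clustering recovers planted conformer partitions and selects k", {
  set.seed(31)
  mk_planted <- function(k, per, sep = 10, noise = 0.3) {
    centers <- matrix(rnorm(k * 3, sd = sep), k, 3)
    xyz <- do.call(rbind, lapply(1:k, function(i)
      sweep(matrix(rnorm(per * 3, sd = noise), per, 3), 2,
            centers[i, ], "+")))
    list(m = as.matrix(dist(xyz)), truth = rep(1:k, each = per))
  }
  two <- mk_planted(2, 20)
  mod <- cluster_conformations(two$m, k_range = 2:6)
  expect_equal(mod$k, 2)
  expect_equal(length(unique(paste(mod$labels, two$truth))), 2)
  expect_equal(sum(mod$populations), 1, tolerance = 1e-9)
  # eight well-separated conformers
  eight <- mk_planted(8, 12, sep = 25)
  mod8 <- cluster_conformations(eight$m, k_range = 2:12)
  expect_equal(mod8$k, 8)
  expect_equal(length(unique(paste(mod8$labels, eight$truth))), 8)
  # duplication invariance: appending a copy of every frame keeps k and
  # pairs labels identically
  n <- nrow(two$m)
  dup <- rbind(cbind(two$m, two$m), cbind(two$m, two$m))
  mod_dup <- cluster_conformations(dup, k_range = 2:6)
  expect_equal(mod_dup$k, 2)
  expect_equal(mod_dup$labels[1:n], mod_dup$labels[(n + 1):(2 * n)])
  # permutation equivariance
  perm <- sample(n)
  mod_p <- cluster_conformations(two$m[perm, perm], k_range = 2:6)
  relabel <- function(l) as.integer(factor(l, levels = unique(l)))
  expect_equal(relabel(mod_p$labels), relabel(mod$labels[perm]))
  # degenerate all-zero matrix
  expect_warning(z <- cluster_conformations(matrix(0, 5, 5)), "k = 1")
  expect_equal(z$k, 1)
})

test_that("cluster averages equal the direct coordinate mean", {
  s <- point_structure(matrix(rnorm(30), ncol = 3))
  frames <- lapply(1:6, function(i) coords(s) + i)
  tr <- new_trajectory(s, frames)
  labels <- c(1, 1, 1, 2, 2, 2)
  avg <- cluster_average(tr, labels)
  expect_equal(coords(avg[["1"]]), coords(s) + 2, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(coords(avg[["2"]]), coords(s) + 5, tolerance = 1e-9,
               ignore_attr = TRUE)
  # identical frames -> that frame; random labels match direct means
  same <- new_trajectory(s, frames[c(1, 1)])
  expect_equal(coords(cluster_average(same, c(1, 1))[["1"]]),
               frames[[1]], tolerance = 1e-12, ignore_attr = TRUE)
  set.seed(4)
  lab <- sample(1:2, 6, replace = TRUE)
  if (length(unique(lab)) == 2) {
    got <- cluster_average(tr, lab)
    direct <- Reduce(`+`, frames[lab == 1]) / sum(lab == 1)
    expect_equal(coords(got[["1"]]), direct, tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("LOWESS smoothing preserves lines and denoises a sine", {
  x <- 1:50
  expect_equal(lowess_smooth(x, rep(3, 50)), rep(3, 50), tolerance = 1e-9)
  y_lin <- 2 * x + 1
  expect_equal(lowess_smooth(x, y_lin), y_lin, tolerance = 1e-9)
  set.seed(12)
  xs <- seq(0, 2 * pi, length.out = 500)
  truth <- sin(xs)
  noisy <- truth + rnorm(500, sd = 0.1)
  sm <- lowess_smooth(xs, noisy, fraction = 0.1)
  expect_lt(sqrt(mean((sm - truth)^2)), 0.05)
  expect_error(lowess_smooth(x[1:5], y_lin[1:5], fraction = 0.05),
               "fraction")
})
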