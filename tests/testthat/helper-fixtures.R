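# Small in-code fixtures shared across the suite.

pdb_line <- function(serial, name, res_name, chain, res_seq, x, y, z,
                     occ = 1, altloc = " ", element = substr(name, 1, 1)) {
  sprintf("ATOM  %5d  %-3s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name, altloc, res_name, chain, res_seq, x, y, z, occ, 0,
          element)
}

tiny_pdb_text <- function() {
  paste(c(
    pdb_line(1, "N", "ALA", "A", 1, 1.234, 2.345, 3.456),
    pdb_line(2, "CA", "ALA", "A", 1, 2.468, 2.345, 3.456),
    pdb_line(3, "C", "ALA", "A", 1, 3.100, 3.500, 4.200),
    "END"), collapse = "\n")
}

# structure with n one-atom "residues" at given coordinates, carbon atoms
point_structure <- function(xyz, element = "C", chain = "A") {
  xyz <- matrix(xyz, ncol = 3)
  assign_parameters(new_structure(data.frame(
    name = "CA", res_name = "GLY", chain = chain,
    res_seq = seq_len(nrow(xyz)),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    element = element, stringsAsFactors = FALSE)))
}

# trajectory from a list of coordinate matrices over a point structure
point_trajectory <- function(frames, element = "C") {
  top <- point_structure(frames[[1]], element = element)
  new_trajectory(top, frames)
}

random_point_structure <- function(n, scale = 10, seed = 1) {
  set.seed(seed)
  point_structure(matrix(runif(3 * n, 0, scale), ncol = 3))
}

# brute-force rigid-fit oracle, independent of the Kabsch closed form:
# a global grid over ZYZ Euler angles with centroid-matched translation,
# polished by Nelder-Mead from the best grid candidates
brute_force_rmsd <- function(mobile, reference) {
  rot <- function(ang) {
    Rz <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0,
                               0, 0, 1), 3, 3)
    Ry <- function(t) matrix(c(cos(t), 0, -sin(t), 0, 1, 0,
                               sin(t), 0, cos(t)), 3, 3)
    Rz(ang[1]) %*% Ry(ang[2]) %*% Rz(ang[3])
  }
  pm <- sweep(mobile, 2, colMeans(mobile))
  pr <- sweep(reference, 2, colMeans(reference))
  score <- function(ang) {
    sqrt(mean(rowSums((pm %*% t(rot(ang)) - pr)^2)))
  }
  grid <- as.matrix(expand.grid(a = seq(-pi, pi, by = pi / 8),
                                b = seq(0, pi, by = pi / 8),
                                c = seq(-pi, pi, by = pi / 8)))
  vals <- apply(grid, 1, score)
  starts <- grid[order(vals)[1:5], , drop = FALSE]
  min(apply(starts, 1, function(s)
    optim(s, score, method = "Nelder-Mead",
          control = list(reltol = 1e-14, maxit = 2000))$value))
}

expect_symmetric_zero_diag <- function(m, tol = 1e-9) {
  expect_lt(max(abs(m - t(m))), tol)
  expect_lt(max(abs(diag(m))), tol)
}
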