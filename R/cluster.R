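calinski_harabasz <- function(X, labels) {
  n <- nrow(X); k <- length(unique(labels))
  if (k < 2 || k >= n) return(NA_real_)
  gmean <- colMeans(X)
  W <- 0; B <- 0
  for (g in unique(labels)) {
    Xi <- X[labels == g, , drop = FALSE]
    ci <- colMeans(Xi)
    W <- W + sum(sweep(Xi, 2, ci)^2)
    B <- B + nrow(Xi) * sum((ci - gmean)^2)
  }
  (B / (k - 1)) / (W / (n - k))
}

# classical MDS embedding of a distance matrix keeping components that
# capture >= var_goal of the positive-eigenvalue variance
cmds_embed <- function(m, var_goal = 0.95) {
  n <- nrow(m)
  # RMSD matrices are not exactly Euclidean, so some trailing eigenvalues
  # are negative; they are clamped below, and cmdscale's warning about
  # returning fewer axes than asked is expected
  mds <- suppressWarnings(cmdscale(as.dist(m), k = n - 1, eig = TRUE))
  ev <- pmax(mds$eig, 0)
  keep <- which(cumsum(ev) / sum(ev) >= var_goal)[1]
  keep <- max(keep, 2)
  mds$points[, seq_len(min(keep, ncol(mds$points))), drop = FALSE]
}

#' Conformational clustering of a pairwise RMSD matrix
#'
#' Agglomerative clustering on the precomputed distance matrix, with the
#' number of clusters chosen by maximizing the Calinski-Harabasz index.
#' CH is defined on coordinates, so frames are first embedded by classical
#' multidimensional scaling of the RMSD matrix (components capturing at
#' least 95% of variance).
#'
#' @param m symmetric pairwise RMSD matrix with zero diagonal.
#' @param k_range candidate cluster counts (subset of 2..n-1);
#'   default 2:15.
#' @param linkage `"average"` (default), `"complete"`, `"single"`, or
#'   `"ward.D2"` (Ward on the MDS embedding distances).
#' @return A `ClusterModel`: list with `labels` (1..k, relabeled by
#'   decreasing population), `k`, `ch_curve` (named by candidate k),
#'   `tree` (hclust object), `populations` (fractions summing to 1), and
#'   `method`.
#' @export
cluster_conformations <- function(m, k_range = 2:15, linkage = "average") {
  m <- as.matrix(m)
  n <- nrow(m)
  stopifnot(n == ncol(m), max(abs(m - t(m))) < 1e-8,
            all(abs(diag(m)) < 1e-8))
  if (all(m < 1e-12)) {
    warning("all-zero distance matrix; Calinski-Harabasz undefined, k = 1")
    return(structure(list(labels = rep(1L, n), k = 1L,
                          ch_curve = setNames(numeric(0), character(0)),
                          tree = NULL, populations = 1, method = linkage),
                     class = "ClusterModel"))
  }
  k_range <- k_range[k_range >= 2 & k_range <= n - 1]
  if (!length(k_range)) stop("k_range must contain values in [2, n-1]")
  tree <- hclust(as.dist(m), method = linkage)
  X <- cmds_embed(m)
  ch <- vapply(k_range, function(k)
    calinski_harabasz(X, cutree(tree, k = k)), numeric(1))
  names(ch) <- k_range
  k_best <- k_range[which.max(ch)]
  labels <- cutree(tree, k = k_best)
  # relabel clusters by decreasing population for stable reporting
  pop <- sort(table(labels), decreasing = TRUE)
  map <- setNames(seq_along(pop), names(pop))
  labels <- as.integer(map[as.character(labels)])
  structure(list(labels = labels, k = k_best, ch_curve = ch, tree = tree,
                 populations = as.numeric(table(labels) / n),
                 method = linkage),
            class = "ClusterModel")
}

#' @export
print.ClusterModel <- function(x, ...) {
  cat(sprintf("ClusterModel: k = %d (%s linkage), populations: %s\n",
              x$k, x$method,
              paste(sprintf("%.1f%%", 100 * x$populations), collapse = " ")))
  invisible(x)
}

#' Per-cluster average structures
#'
#' Arithmetic mean of coordinates over the member frames of each cluster
#' (frames must be pre-aligned).
#'
#' @param traj a [Trajectory].
#' @param labels integer cluster label per frame.
#' @param sel optional [Selection]; default all atoms.
#' @return named list of [Structure] objects, one per cluster label.
#' @export
cluster_average <- function(traj, labels, sel = NULL) {
  stopifnot(inherits(traj, "Trajectory"), length(labels) == n_frames(traj))
  idx <- if (is.null(sel)) seq_len(n_atoms(traj))
         else select_atoms(traj$topology, sel)
  out <- list()
  for (g in sort(unique(labels))) {
    members <- which(labels == g)
    if (!length(members)) stop("empty cluster: ", g)
    avg <- apply(traj$coords[idx, , members, drop = FALSE], c(1, 2), mean)
    top <- traj$topology
    top$atom <- top$atom[idx, , drop = FALSE]
    rownames(top$atom) <- NULL
    s <- set_coords(top, avg)
    s$title <- sprintf("cluster %d average (%d frames)", g, length(members))
    out[[as.character(g)]] <- s
  }
  out
}

#' Write a cluster dendrogram as Newick text
#'
#' @param model a `ClusterModel` with a tree.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(model, path) {
  stopifnot(inherits(model, "ClusterModel"))
  if (is.null(model$tree)) stop("cluster model has no tree (k = 1 case)")
  phy <- ape::as.phylo(model$tree)
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Write cluster assignments as delimited text
#'
#' @param model a `ClusterModel`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cluster_table <- function(model, path) {
  write.table(data.frame(frame = seq_along(model$labels),
                         label = model$labels),
              path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' LOWESS smoothing of a series
#'
#' Locally weighted scatterplot smoothing: a tricube-weighted local linear
#' fit at each x. Robustness iterations default off (plain LOWESS), so an
#' exactly linear series is reproduced to machine precision.
#'
#' @param x,y numeric vectors (>= 5 points).
#' @param fraction smoother span in (0, 1]; the window must cover at least
#'   2 points.
#' @param iter robustness iterations (default 0).
#' @return numeric vector of smoothed y at the input x, input order.
#' @export
lowess_smooth <- function(x, y, fraction = 2 / 3, iter = 0) {
  stopifnot(length(x) == length(y), length(x) >= 5,
            fraction > 0, fraction <= 1)
  if (floor(fraction * length(x)) < 2)
    stop("fraction too small: window covers fewer than 2 points")
  o <- order(x)
  sm <- lowess(x[o], y[o], f = fraction, iter = iter)
  out <- numeric(length(x))
  out[o] <- sm$y
  out
}
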