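#' Molecular structure container
#'
#' A `Structure` holds an ordered atom table plus a title and model id. The
#' atom table has one row per atom with columns `serial`, `name`, `altloc`,
#' `res_name`, `chain`, `res_seq`, `x`, `y`, `z` (Angstrom), `occupancy`,
#' `element`, `mass` (Da, `NA` until [assign_parameters()]), and
#' `vdw_radius` (Angstrom, likewise).
#'
#' @param atom data.frame of atoms (see above; missing optional columns are
#'   filled with defaults).
#' @param title free-text title.
#' @param model_id integer model number.
#' @return An object of class `Structure`.
#' @export
new_structure <- function(atom, title = "", model_id = 1L) {
  stopifnot(is.data.frame(atom), nrow(atom) >= 1)
  need <- c("name", "res_name", "chain", "res_seq", "x", "y", "z")
  if (!all(need %in% names(atom)))
    stop("atom table missing columns: ",
         paste(setdiff(need, names(atom)), collapse = ", "))
  n <- nrow(atom)
  if (is.null(atom$serial)) atom$serial <- seq_len(n)
  if (is.null(atom$altloc)) atom$altloc <- ""
  if (is.null(atom$occupancy)) atom$occupancy <- 1
  if (is.null(atom$element)) atom$element <- guess_element(atom$name)
  if (is.null(atom$mass)) atom$mass <- NA_real_
  if (is.null(atom$vdw_radius)) atom$vdw_radius <- NA_real_
  atom$res_seq <- as.integer(atom$res_seq)
  xyz <- as.matrix(atom[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("non-finite coordinates in atom table")
  key <- paste(atom$chain, atom$res_seq, atom$name, atom$altloc)
  if (anyDuplicated(key))
    stop("duplicate atoms (chain, res_seq, name, altloc): ",
         paste(head(key[duplicated(key)], 3), collapse = "; "))
  rownames(atom) <- NULL
  structure(list(atom = atom, title = title, model_id = as.integer(model_id)),
            class = "Structure")
}

# element symbol from a PDB atom name: leading digits stripped, two-letter
# symbols only for recognised cases (CL, BR, NA, MG, ZN, SE, FE, ...)
guess_element <- function(name) {
  nm <- toupper(gsub("[0-9' ]", "", name))
  two <- c("CL", "BR", "NA", "MG", "ZN", "SE", "FE", "MN", "CU")
  vapply(nm, function(x) {
    if (nchar(x) >= 2 && substr(x, 1, 2) %in% two) substr(x, 1, 2)
    else substr(x, 1, 1)
  }, character(1), USE.NAMES = FALSE)
}

#' Number of atoms in a structure or trajectory topology
#' @param x a `Structure` or `Trajectory`.
#' @return integer atom count.
#' @export
n_atoms <- function(x) {
  if (inherits(x, "Trajectory")) return(nrow(x$topology$atom))
  stopifnot(inherits(x, "Structure"))
  nrow(x$atom)
}

#' Atom coordinates as an n x 3 matrix
#' @param x a `Structure`.
#' @return numeric matrix with columns x, y, z (Angstrom).
#' @export
coords <- function(x) {
  stopifnot(inherits(x, "Structure"))
  m <- as.matrix(x$atom[, c("x", "y", "z")])
  dimnames(m) <- NULL
  m
}

#' Replace coordinates of a structure
#' @param x a `Structure`.
#' @param xyz n x 3 matrix.
#' @return the modified `Structure`.
#' @export
set_coords <- function(x, xyz) {
  stopifnot(inherits(x, "Structure"), nrow(xyz) == n_atoms(x), ncol(xyz) == 3)
  x$atom$x <- xyz[, 1]; x$atom$y <- xyz[, 2]; x$atom$z <- xyz[, 3]
  x
}

#' @export
print.Structure <- function(x, ...) {
  cat(sprintf("Structure: %d atoms, %d residues, chains [%s]%s\n",
              n_atoms(x),
              length(unique(paste(x$atom$chain, x$atom$res_seq))),
              paste(unique(x$atom$chain), collapse = " "),
              if (nzchar(x$title)) paste0(" - ", x$title) else ""))
  invisible(x)
}

#' Trajectory container
#'
#' A `Trajectory` is a fixed atom roster (`topology`, a [Structure]) plus an
#' ordered stack of coordinate frames stored as an `n_atoms x 3 x n_frames`
#' array in Angstrom, with optional `frame_interval` metadata (time per
#' frame in arbitrary units, e.g. ns).
#'
#' @param topology a `Structure` giving the atom roster.
#' @param frames list of n_atoms x 3 matrices, or an n_atoms x 3 x n_frames
#'   array.
#' @param frame_interval optional numeric time per frame.
#' @return An object of class `Trajectory`.
#' @export
new_trajectory <- function(topology, frames, frame_interval = NA_real_) {
  stopifnot(inherits(topology, "Structure"))
  na <- n_atoms(topology)
  if (is.list(frames)) {
    for (i in seq_along(frames)) {
      if (nrow(frames[[i]]) != na || ncol(frames[[i]]) != 3)
        stop("frame ", i, " has ", nrow(frames[[i]]),
             " atoms; topology has ", na)
    }
    arr <- array(unlist(frames), dim = c(na, 3, length(frames)))
  } else {
    stopifnot(length(dim(frames)) == 3)
    if (dim(frames)[1] != na)
      stop("frame array has ", dim(frames)[1], " atoms; topology has ", na)
    arr <- frames
  }
  if (dim(arr)[3] < 1) stop("trajectory needs at least one frame")
  structure(list(topology = topology, coords = arr,
                 frame_interval = frame_interval),
            class = "Trajectory")
}

#' Number of frames in a trajectory
#' @param traj a `Trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) {
  stopifnot(inherits(traj, "Trajectory"))
  dim(traj$coords)[3]
}

#' Coordinates of one frame
#' @param traj a `Trajectory`.
#' @param i frame index (1-based).
#' @return n_atoms x 3 matrix.
#' @export
frame_coords <- function(traj, i) {
  stopifnot(inherits(traj, "Trajectory"), i >= 1, i <= n_frames(traj))
  traj$coords[, , i, drop = TRUE]
}

#' Extract one frame as a Structure
#' @param traj a `Trajectory`.
#' @param i frame index.
#' @return a `Structure` with the topology's atom table and frame i's
#'   coordinates.
#' @export
frame_structure <- function(traj, i) {
  s <- set_coords(traj$topology, frame_coords(traj, i))
  s$model_id <- as.integer(i)
  s
}

#' Subset a trajectory to an atom index set
#' @param traj a `Trajectory`.
#' @param indices increasing atom indices (as from [select_atoms()]).
#' @return a `Trajectory` over the selected atoms only.
#' @export
subset_trajectory <- function(traj, indices) {
  stopifnot(inherits(traj, "Trajectory"))
  top <- traj$topology
  top$atom <- top$atom[indices, , drop = FALSE]
  rownames(top$atom) <- NULL
  new_trajectory(top, traj$coords[indices, , , drop = FALSE],
                 traj$frame_interval)
}

#' @export
print.Trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d frames x %d atoms%s\n", n_frames(x), n_atoms(x),
              if (is.finite(x$frame_interval))
                sprintf(", %g time units/frame", x$frame_interval) else ""))
  invisible(x)
}
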