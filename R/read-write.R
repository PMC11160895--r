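#' Read a structure from PDB text or file
#'
#' Parses ATOM/HETATM/MODEL records. By default the first model is returned
#' and, where alternate locations are present, only the highest-occupancy
#' altloc of each atom is kept (ties broken alphabetically), matching the
#' single-conformer convention of crystal-structure analyses.
#'
#' @param source a file path, or PDB-format text (single string with
#'   newlines, or a character vector of lines).
#' @param model integer model to return (default 1).
#' @param keep_altlocs if `TRUE`, keep all altlocs instead of applying the
#'   highest-occupancy policy.
#' @return A [Structure].
#' @export
read_structure <- function(source, model = 1L, keep_altlocs = FALSE) {
  path <- as_pdb_path(source)
  validate_pdb_lines(path)
  multi <- length(grep("^MODEL", readLines(path, warn = FALSE))) > 1
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = multi))
  atom <- bio3d_atom_table(pdb)
  if (nrow(atom) == 0) stop("empty structure: no ATOM/HETATM records")
  if (multi) {
    nm <- nrow(pdb$xyz)
    if (model > nm) stop("model ", model, " requested; file has ", nm)
    xyz <- matrix(pdb$xyz[model, ], ncol = 3, byrow = TRUE)
    atom$x <- xyz[, 1]; atom$y <- xyz[, 2]; atom$z <- xyz[, 3]
  } else if (model != 1L) {
    stop("model ", model, " requested; file has 1")
  }
  if (!keep_altlocs) atom <- apply_altloc_policy(atom)
  new_structure(atom, title = basename(path), model_id = model)
}

as_pdb_path <- function(source) {
  if (length(source) == 1 && !grepl("\n", source) && file.exists(source))
    return(source)
  path <- tempfile(fileext = ".pdb")
  writeLines(if (length(source) == 1) strsplit(source, "\n")[[1]] else source,
             path)
  path
}

validate_pdb_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  for (i in which(rec)) {
    fields <- c(substr(lines[i], 31, 38), substr(lines[i], 39, 46),
                substr(lines[i], 47, 54))
    vals <- suppressWarnings(as.numeric(fields))
    if (any(is.na(vals)))
      stop("malformed coordinate field at line ", i, ": ", lines[i])
  }
  invisible(TRUE)
}

bio3d_atom_table <- function(pdb) {
  a <- pdb$atom
  data.frame(serial = a$eleno,
             name = a$elety,
             altloc = ifelse(is.na(a$alt), "", a$alt),
             res_name = a$resid,
             chain = ifelse(is.na(a$chain), "", a$chain),
             res_seq = a$resno,
             x = a$x, y = a$y, z = a$z,
             occupancy = ifelse(is.na(a$o), 1, a$o),
             element = ifelse(is.na(a$elesy) | a$elesy == "",
                              guess_element(a$elety), a$elesy),
             stringsAsFactors = FALSE)
}

# keep the highest-occupancy altloc per (chain, res_seq, name); ties go to
# the alphabetically first altloc code
apply_altloc_policy <- function(atom) {
  key <- paste(atom$chain, atom$res_seq, atom$name)
  keep <- unlist(lapply(split(seq_len(nrow(atom)), key), function(idx) {
    if (length(idx) == 1) return(idx)
    occ <- atom$occupancy[idx]
    best <- idx[occ == max(occ)]
    best[order(atom$altloc[best])][1]
  }), use.names = FALSE)
  out <- atom[sort(keep), , drop = FALSE]
  out$altloc <- ""
  rownames(out) <- NULL
  out
}

#' Write a structure to a PDB file
#'
#' @param structure a [Structure].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (nzchar(structure$title))
    writeLines(sprintf("TITLE     %s", structure$title), con)
  writeLines(pdb_atom_lines(structure$atom), con)
  writeLines("END", con)
  invisible(path)
}

pdb_atom_lines <- function(atom) {
  nm <- ifelse(nchar(atom$name) >= 4, atom$name,
               paste0(" ", formatC(atom$name, width = -3)))
  sprintf("ATOM  %5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          atom$serial %% 100000, nm,
          ifelse(atom$altloc == "", " ", atom$altloc),
          atom$res_name, ifelse(atom$chain == "", " ", atom$chain),
          atom$res_seq, atom$x, atom$y, atom$z, atom$occupancy, 0,
          toupper(atom$element))
}

#' Write a trajectory as a multi-model PDB file
#'
#' @param traj a [Trajectory].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  atom <- traj$topology$atom
  for (i in seq_len(n_frames(traj))) {
    xyz <- frame_coords(traj, i)
    atom$x <- xyz[, 1]; atom$y <- xyz[, 2]; atom$z <- xyz[, 3]
    writeLines(sprintf("MODEL     %4d", i), con)
    writeLines(pdb_atom_lines(atom), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a trajectory
#'
#' Accepts a multi-model PDB file (canonical interchange format), a single
#' XYZ file containing concatenated frames, or an ordered vector of
#' per-frame files (PDB or XYZ). A topology is required for XYZ input
#' (XYZ frames carry elements only); for PDB input it defaults to the first
#' model.
#'
#' @param sources path or ordered vector of paths.
#' @param topology optional [Structure] giving the atom roster.
#' @param frame_interval optional time per frame.
#' @return A [Trajectory].
#' @export
read_trajectory <- function(sources, topology = NULL,
                            frame_interval = NA_real_) {
  frames <- list()
  if (length(sources) == 1 && is_xyz_file(sources)) {
    frames <- read_xyz_frames(sources)
  } else if (length(sources) == 1) {
    validate_pdb_lines(sources)
    pdb <- suppressWarnings(bio3d::read.pdb(sources, multi = TRUE))
    atom <- bio3d_atom_table(pdb)
    if (is.null(topology)) topology <- new_structure(atom)
    if (is.matrix(pdb$xyz) && nrow(pdb$xyz) > 1) {
      frames <- lapply(seq_len(nrow(pdb$xyz)), function(i)
        matrix(pdb$xyz[i, ], ncol = 3, byrow = TRUE))
    } else {
      frames <- list(as.matrix(atom[, c("x", "y", "z")]))
    }
  } else {
    for (f in sources) {
      if (is_xyz_file(f)) {
        frames <- c(frames, read_xyz_frames(f))
      } else {
        s <- read_structure(f)
        if (is.null(topology)) topology <- s
        frames <- c(frames, list(coords(s)))
      }
    }
  }
  if (is.null(topology))
    stop("a topology Structure is required for XYZ frame input")
  na <- n_atoms(topology)
  for (i in seq_along(frames)) {
    if (nrow(frames[[i]]) != na)
      stop("frame ", i, " has ", nrow(frames[[i]]),
           " atoms; topology has ", na)
  }
  new_trajectory(topology, frames, frame_interval)
}

is_xyz_file <- function(path) {
  if (grepl("\\.xyz$", path, ignore.case = TRUE)) return(TRUE)
  first <- readLines(path, n = 1, warn = FALSE)
  grepl("^\\s*[0-9]+\\s*$", first)
}

#' Read concatenated XYZ frames
#'
#' Plain XYZ dialect: each frame is an atom-count line, a comment line, then
#' `element x y z` records.
#'
#' @param path XYZ file path.
#' @return list of n x 3 coordinate matrices, with the element column of the
#'   first frame attached as attribute `elements`.
#' @export
read_xyz_frames <- function(path) {
  lines <- readLines(path, warn = FALSE)
  frames <- list()
  i <- 1
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop("malformed XYZ atom-count line ", i, ": ", lines[i])
    block <- lines[(i + 2):(i + 1 + n)]
    parts <- strsplit(trimws(block), "\\s+")
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (any(is.na(xyz)))
      stop("malformed XYZ coordinate in frame ", length(frames) + 1)
    if (length(frames) == 0)
      attr(xyz, "elements") <- vapply(parts, `[`, character(1), 1)
    frames <- c(frames, list(xyz))
    i <- i + 2 + n
  }
  if (!length(frames)) stop("no frames in XYZ file")
  el <- attr(frames[[1]], "elements")
  attr(frames[[1]], "elements") <- NULL
  attr(frames, "elements") <- el
  frames
}

#' Write a trajectory as concatenated XYZ frames
#'
#' @param traj a [Trajectory].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_xyz_frames <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  el <- traj$topology$atom$element
  for (i in seq_len(n_frames(traj))) {
    xyz <- frame_coords(traj, i)
    writeLines(c(sprintf("%d", length(el)), sprintf("frame %d", i),
                 sprintf("%-2s %12.6f %12.6f %12.6f", el,
                         xyz[, 1], xyz[, 2], xyz[, 3])), con)
  }
  invisible(path)
}
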