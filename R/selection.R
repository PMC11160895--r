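BACKBONE_NAMES <- c("N", "CA", "C", "O", "OXT")

#' Build an atom selection
#'
#' A `Selection` is a conjunctive predicate over atom attributes. Resolving
#' it against a [Structure] with [select_atoms()] yields a deterministic,
#' strictly increasing atom-index list in file order.
#'
#' @param chain character vector of chain ids, or `NULL` for any.
#' @param res_seq integer vector of residue numbers (e.g. `1:180`), or `NULL`.
#' @param res_name character vector of 3-letter residue codes, or `NULL`.
#' @param name character vector of atom names, or `NULL`.
#' @param element character vector of element symbols, or `NULL`.
#' @param heavy drop hydrogens if `TRUE`.
#' @param backbone keep only backbone atoms (N, CA, C, O, OXT) if `TRUE`.
#' @param sidechain keep only side-chain atoms if `TRUE`.
#' @return An object of class `Selection`.
#' @examples
#' groove_ca <- atom_selection(chain = "A", res_seq = 1:180, name = "CA")
#' @export
atom_selection <- function(chain = NULL, res_seq = NULL, res_name = NULL,
                           name = NULL, element = NULL, heavy = FALSE,
                           backbone = FALSE, sidechain = FALSE) {
  if (backbone && sidechain)
    stop("backbone and sidechain flags are mutually exclusive")
  structure(list(chain = chain, res_seq = res_seq, res_name = res_name,
                 name = name, element = element, heavy = heavy,
                 backbone = backbone, sidechain = sidechain),
            class = "Selection")
}

#' Resolve a selection against a structure
#'
#' @param structure a [Structure].
#' @param selection a [Selection] (or an integer index vector, passed
#'   through after validation).
#' @return strictly increasing integer atom indices; empty (with a warning
#'   for a nonexistent chain) when nothing matches.
#' @export
select_atoms <- function(structure, selection) {
  stopifnot(inherits(structure, "Structure"))
  a <- structure$atom
  if (is.numeric(selection)) {
    idx <- as.integer(selection)
    stopifnot(all(idx >= 1), all(idx <= nrow(a)))
    return(sort(unique(idx)))
  }
  stopifnot(inherits(selection, "Selection"))
  keep <- rep(TRUE, nrow(a))
  if (!is.null(selection$chain)) {
    if (!any(selection$chain %in% a$chain))
      warning("chain(s) not present in structure: ",
              paste(setdiff(selection$chain, a$chain), collapse = ", "))
    keep <- keep & a$chain %in% selection$chain
  }
  if (!is.null(selection$res_seq)) keep <- keep & a$res_seq %in% selection$res_seq
  if (!is.null(selection$res_name))
    keep <- keep & a$res_name %in% toupper(selection$res_name)
  if (!is.null(selection$name)) keep <- keep & a$name %in% selection$name
  if (!is.null(selection$element))
    keep <- keep & toupper(a$element) %in% toupper(selection$element)
  if (selection$heavy) keep <- keep & toupper(a$element) != "H"
  if (selection$backbone) keep <- keep & a$name %in% BACKBONE_NAMES
  if (selection$sidechain)
    keep <- keep & !(a$name %in% BACKBONE_NAMES)
  which(keep)
}

#' @export
print.Selection <- function(x, ...) {
  parts <- character(0)
  for (f in c("chain", "res_seq", "res_name", "name", "element")) {
    if (!is.null(x[[f]]))
      parts <- c(parts, sprintf("%s in {%s}", f,
                                paste(range_label(x[[f]]), collapse = ",")))
  }
  for (f in c("heavy", "backbone", "sidechain"))
    if (isTRUE(x[[f]])) parts <- c(parts, f)
  cat("Selection:", if (length(parts)) paste(parts, collapse = " & ")
      else "all atoms", "\n")
  invisible(x)
}

range_label <- function(v) {
  if (is.numeric(v) && length(v) > 4 && all(diff(v) == 1))
    return(sprintf("%d..%d", min(v), max(v)))
  if (length(v) > 6) v <- c(head(v, 5), "...")
  v
}
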