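#' Default atomic parameter table
#'
#' Standard atomic weights (Da) and Bondi van der Waals radii (Angstrom) for
#' the elements that occur in proteins and common ligands. The table is the
#' default used by [assign_parameters()]; a custom table can be loaded from
#' two-column delimited text with [read_parameter_table()].
#'
#' Selenium and other non-standard elements are deliberately absent from the
#' default set: structures containing them must supply an extended table, so
#' that a silently wrong mass or radius can never enter a mass-weighted or
#' volumetric calculation.
#'
#' @return An object of class `ParameterTable`: a list with named numeric
#'   vectors `mass` (Da) and `vdw` (Angstrom), keyed by element symbol.
#' @examples
#' tab <- default_parameter_table()
#' tab$mass[["C"]]   # 12.011
#' tab$vdw[["C"]]    # 1.70
#' @export
default_parameter_table <- function() {
  mass <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
            F = 18.998, P = 30.974, CL = 35.45, BR = 79.904, I = 126.904,
            NA. = 22.990, MG = 24.305, K = 39.098, CA = 40.078, ZN = 65.38)
  vdw <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
           F = 1.47, P = 1.80, CL = 1.75, BR = 1.85, I = 1.98,
           NA. = 2.27, MG = 1.73, K = 2.75, CA = 2.31, ZN = 1.39)
  names(mass) <- sub("\\.$", "", names(mass))
  names(vdw) <- sub("\\.$", "", names(vdw))
  parameter_table(mass, vdw)
}

#' Construct a parameter table
#'
#' @param mass named numeric vector, element symbol -> mass (Da).
#' @param vdw named numeric vector, element symbol -> vdW radius (Angstrom).
#' @return A `ParameterTable` object.
#' @export
parameter_table <- function(mass, vdw) {
  stopifnot(is.numeric(mass), is.numeric(vdw),
            !is.null(names(mass)), !is.null(names(vdw)))
  if (any(mass <= 0) || any(vdw <= 0))
    stop("parameter table entries must be positive")
  names(mass) <- toupper(names(mass))
  names(vdw) <- toupper(names(vdw))
  structure(list(mass = mass, vdw = vdw), class = "ParameterTable")
}

#' Read a parameter table from delimited text
#'
#' Expects two files or one file with three columns: element, mass, radius.
#' Lines starting with `#` are ignored.
#'
#' @param path path to a whitespace/comma delimited file with columns
#'   `element`, `mass`, `vdw`.
#' @return A `ParameterTable`.
#' @export
read_parameter_table <- function(path) {
  tab <- read.table(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("element", "mass", "vdw")
  if (!all(need %in% names(tab)))
    stop("parameter table file must have columns: ",
         paste(need, collapse = ", "))
  parameter_table(setNames(tab$mass, tab$element),
                  setNames(tab$vdw, tab$element))
}

#' Attach masses and van der Waals radii to a structure
#'
#' Every atom's element symbol is looked up in the parameter table and the
#' `mass` and `vdw_radius` columns are (re)filled. The operation is
#' idempotent. Elements missing from the table cause an error naming them,
#' rather than propagating `NA` into downstream mass-weighted quantities.
#'
#' @param structure a [Structure] object.
#' @param table a `ParameterTable`; defaults to [default_parameter_table()].
#' @return The structure with `mass` and `vdw_radius` populated.
#' @export
assign_parameters <- function(structure, table = default_parameter_table()) {
  stopifnot(inherits(structure, "Structure"),
            inherits(table, "ParameterTable"))
  el <- toupper(structure$atom$element)
  missing_el <- sort(unique(el[!(el %in% names(table$mass)) |
                               !(el %in% names(table$vdw))]))
  if (length(missing_el))
    stop("elements missing from parameter table: ",
         paste(missing_el, collapse = ", "))
  structure$atom$mass <- unname(table$mass[el])
  structure$atom$vdw_radius <- unname(table$vdw[el])
  structure
}
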