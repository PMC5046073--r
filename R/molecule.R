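#' Construct a molecule
#'
#' A molecule is an ordered atom table plus a bond list. Atoms carry 3D
#' coordinates (possibly `NA` before embedding), Gasteiger partial charges
#' (`NA` before preparation), van der Waals parameters and the five CoMSIA
#' property weights (columns `w_steric`, `w_electrostatic`, `w_hydrophobic`,
#' `w_hbd`, `w_hba`).
#'
#' @param id Short identifier, unique within a collection.
#' @param name Human-readable name.
#' @param atoms `data.frame` with at least `element`, `x`, `y`, `z`; optional
#'   `charge`, `vdw_r`, `vdw_eps` and `w_*` columns are filled with `NA`/0
#'   when absent.
#' @param bonds `data.frame` with columns `a1`, `a2` (1-based atom indices)
#'   and `order` (character: `"1"`, `"2"`, `"3"`, `"ar"`, `"am"`).
#' @param provenance Free-text note on the structure's source.
#' @return An object of class `mif_molecule`.
#' @export
molecule <- function(id, name = id, atoms, bonds = empty_bonds(),
                     provenance = "") {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  stopifnot(is.character(atoms$element), all(c("x", "y", "z") %in% names(atoms)))
  for (col in c("charge", "vdw_r", "vdw_eps"))
    if (is.null(atoms[[col]])) atoms[[col]] <- NA_real_
  for (p in COMSIA_PROPERTIES) {
    col <- paste0("w_", p)
    if (is.null(atoms[[col]])) atoms[[col]] <- NA_real_
  }
  bonds <- as.data.frame(bonds, stringsAsFactors = FALSE)
  bonds$a1 <- as.integer(bonds$a1); bonds$a2 <- as.integer(bonds$a2)
  bonds$order <- as.character(bonds$order)
  m <- structure(
    list(id = as.character(id), name = as.character(name),
         atoms = atoms, bonds = bonds,
         provenance = as.character(provenance), flags = list()),
    class = "mif_molecule")
  validate_molecule(m)
  m
}

empty_bonds <- function() {
  data.frame(a1 = integer(), a2 = integer(), order = character(),
             stringsAsFactors = FALSE)
}

validate_molecule <- function(m) {
  a <- m$atoms; b <- m$bonds
  xyz <- as.matrix(a[, c("x", "y", "z")])
  if (any(is.infinite(xyz) | is.nan(xyz)))
    stop("molecule '", m$id, "': non-finite atom coordinates")
  if (nrow(b)) {
    if (any(b$a1 < 1 | b$a1 > nrow(a) | b$a2 < 1 | b$a2 > nrow(a)))
      stop("molecule '", m$id, "': bond references an invalid atom index")
    if (any(b$a1 == b$a2))
      stop("molecule '", m$id, "': self-bond")
  }
  ok <- is.na(a$vdw_r) | a$vdw_r > 0
  if (!all(ok)) stop("molecule '", m$id, "': vdw_radius must be > 0")
  ok <- is.na(a$vdw_eps) | a$vdw_eps >= 0
  if (!all(ok)) stop("molecule '", m$id, "': vdw_epsilon must be >= 0")
  invisible(m)
}

#' @export
print.mif_molecule <- function(x, ...) {
  cat(sprintf("<mif_molecule %s> '%s': %d atoms, %d bonds\n",
              x$id, x$name, nrow(x$atoms), nrow(x$bonds)))
  cat(sprintf("  coordinates: %s; charges: %s; parameterized: %s\n",
              if (has_coords(x)) "3D" else "none",
              if (all(is.na(x$atoms$charge))) "none" else "assigned",
              if (all(is.na(x$atoms$vdw_r))) "no" else "yes"))
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' Does the molecule carry 3D coordinates?
#' @param m A `mif_molecule`.
#' @return Logical scalar.
#' @export
has_coords <- function(m) {
  xyz <- as.matrix(m$atoms[, c("x", "y", "z")])
  if (anyNA(xyz)) return(FALSE)
  # an all-zero block for a polyatomic molecule means "not embedded yet"
  !(nrow(xyz) > 1 && all(xyz == 0))
}

#' Atom coordinates as a matrix
#' @param m A `mif_molecule`.
#' @return Numeric n x 3 matrix (columns x, y, z).
#' @export
coords <- function(m) {
  as.matrix(m$atoms[, c("x", "y", "z")])
}

set_coords <- function(m, xyz) {
  m$atoms$x <- xyz[, 1]; m$atoms$y <- xyz[, 2]; m$atoms$z <- xyz[, 3]
  m
}

#' Net charge consistency check
#'
#' Verifies that the partial charges sum to an integer net formal charge
#' within `tol` elementary charge units.
#' @param m A prepared `mif_molecule`.
#' @param tol Tolerance in e.
#' @return Invisibly the net formal charge (integer).
#' @export
check_net_charge <- function(m, tol = 1e-3) {
  q <- sum(m$atoms$charge)
  if (is.na(q)) stop("molecule '", m$id, "': charges not assigned")
  net <- round(q)
  if (abs(q - net) > tol)
    stop(sprintf("molecule '%s': charges sum to %.5f, not an integer within %g e",
                 m$id, q, tol))
  invisible(as.integer(net))
}

#' CoMSIA property weights of every atom
#' @param m A prepared `mif_molecule`.
#' @param property One of `"steric"`, `"electrostatic"`, `"hydrophobic"`,
#'   `"hbd"`, `"hba"`.
#' @return Numeric vector, one weight per atom.
#' @export
comsia_weights <- function(m, property) {
  property <- match.arg(property, COMSIA_PROPERTIES)
  w <- m$atoms[[paste0("w_", property)]]
  if (all(is.na(w)))
    stop("molecule '", m$id, "': CoMSIA weights not assigned; run prepare()")
  w
}

heavy_atom_count <- function(m) sum(m$atoms$element != "H")

## element symbol from a MOL2/SYBYL atom type ("C.ar" -> "C")
element_of <- function(atom_type) sub("\\..*$", "", atom_type)
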