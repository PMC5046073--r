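#' Read molecular structures
#'
#' Reads SDF (V2000), MOL2 or SMILES files into [molecule()] objects. SDF
#' records are normalized to explicit hydrogens on input (hydrogen-bond
#' donor fields require them); SMILES records carry no coordinates until
#' [prepare()] embeds them. Atom order is preserved from the file (added
#' hydrogens are appended).
#'
#' @param path File to read.
#' @param format `"sdf"`, `"mol2"` or `"smiles"` (one SMILES per line, with
#'   an optional tab-separated id).
#' @return List of `mif_molecule`. An empty file yields an empty list with a
#'   warning.
#' @export
read_structures <- function(path, format = c("sdf", "mol2", "smiles")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  lines <- readLines(path, warn = FALSE)
  if (!any(nzchar(trimws(lines)))) {
    warning("'", path, "' is empty; returning no molecules")
    return(list())
  }
  switch(format,
    smiles = read_smiles_lines(lines),
    sdf = read_sdf_lines(lines),
    mol2 = read_mol2_lines(lines))
}

read_smiles_lines <- function(lines) {
  lines <- lines[nzchar(trimws(lines))]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[[i]], "[\t ]+")[[1]]
    smi <- parts[[1]]
    id <- if (length(parts) > 1) parts[[2]] else paste0("mol", i)
    out[[i]] <- tryCatch(
      molecule_from_smiles(smi, id = id),
      error = function(e) stop("record ", i, " ('", smi, "'): ",
                               conditionMessage(e)))
  }
  out
}

#' Molecule from a SMILES string
#'
#' Connectivity-only molecule (explicit hydrogens, no coordinates until
#' [prepare()] embeds a conformation).
#'
#' @param smiles SMILES string.
#' @param id,name Identifier and display name.
#' @return A `mif_molecule`.
#' @export
molecule_from_smiles <- function(smiles, id = "mol1", name = id) {
  mol2 <- babel_convert(smiles, "smi", "mol2")
  m <- parse_mol2(mol2, id = id, name = name)
  m$atoms$x <- NA_real_; m$atoms$y <- NA_real_; m$atoms$z <- NA_real_
  m$atoms$charge <- NA_real_  # charges are assigned by prepare(), not here
  m$provenance <- paste0("from SMILES ", smiles)
  m$smiles <- smiles
  m
}

read_sdf_lines <- function(lines) {
  recs <- split_records(lines, "^\\${4}")
  out <- list()
  for (i in seq_along(recs)) {
    rec <- recs[[i]]
    if (!any(nzchar(trimws(rec)))) next
    m <- tryCatch({
      mol2 <- babel_convert(c(rec, "$$$$"), "sdf", "mol2", "-h")
      title <- trimws(rec[[1]])
      id <- if (nzchar(title)) title else paste0("mol", i)
      mm <- parse_mol2(mol2, id = id, name = id)
      mm$atoms$charge <- sdf_charges(rec, nrow(mm$atoms))
      mm$provenance <- "from SDF"
      mm
    }, error = function(e) stop("record ", i, ": ", conditionMessage(e)))
    out[[length(out) + 1]] <- m
  }
  out
}

## Partial charges from the MIF_PARTIAL_CHARGES data item written by
## write_structures(); NA when absent or when H-normalization changed counts.
sdf_charges <- function(rec, natoms) {
  tag <- grep("^>.*<MIF_PARTIAL_CHARGES>", rec)
  if (!length(tag)) return(NA_real_)
  vals <- character()
  for (j in seq(tag[[1]] + 1L, length(rec))) {
    if (!nzchar(trimws(rec[[j]]))) break
    vals <- c(vals, strsplit(trimws(rec[[j]]), "[ \t]+")[[1]])
  }
  q <- suppressWarnings(as.numeric(vals))
  if (length(q) != natoms || anyNA(q)) return(NA_real_)
  q
}

read_mol2_lines <- function(lines) {
  starts <- grep("^@<TRIPOS>MOLECULE", lines)
  if (!length(starts)) stop("record 1: no @<TRIPOS>MOLECULE section found")
  ends <- c(starts[-1] - 1L, length(lines))
  out <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    rec <- lines[starts[[i]]:ends[[i]]]
    out[[i]] <- tryCatch(parse_mol2(rec, id = paste0("mol", i)),
                         error = function(e) stop("record ", i, ": ",
                                                  conditionMessage(e)))
  }
  out
}

split_records <- function(lines, delim_regex) {
  idx <- grep(delim_regex, lines)
  bounds <- c(0L, idx, if (length(idx) && idx[length(idx)] == length(lines))
    integer() else length(lines) + 1L)
  recs <- list()
  for (k in seq_len(length(bounds) - 1L)) {
    lo <- bounds[[k]] + 1L
    hi <- min(bounds[[k + 1L]] - 1L, length(lines))
    if (lo <= hi) recs[[length(recs) + 1L]] <- lines[lo:hi]
  }
  recs
}

## --- MOL2 parsing/writing (no installed R package reads MOL2) -----------

parse_mol2 <- function(lines, id = "mol1", name = NULL) {
  sec <- function(tag) {
    i <- grep(paste0("^@<TRIPOS>", tag, "\\s*$"), lines)
    if (!length(i)) return(character())
    i <- i[[1]] + 1L
    if (i > length(lines)) return(character())
    j <- i
    while (j <= length(lines) && !grepl("^@<TRIPOS>", lines[[j]])) j <- j + 1L
    if (j == i) character() else lines[i:(j - 1L)]
  }
  molsec <- sec("MOLECULE")
  if (length(molsec) && nzchar(trimws(molsec[[1]])) &&
      !grepl("^\\*+$", trimws(molsec[[1]])))
    name <- trimws(molsec[[1]])
  if (is.null(name)) name <- id
  atom_lines <- sec("ATOM"); atom_lines <- atom_lines[nzchar(trimws(atom_lines))]
  if (!length(atom_lines))
    stop("MOL2 record for '", id, "' has no atoms (conversion or ",
         "force-field setup may have failed)")
  f <- strsplit(trimws(atom_lines), "[ \t]+")
  natom <- length(f)
  atoms <- data.frame(
    element = vapply(f, function(v) element_of(v[[6]]), character(1)),
    x = vapply(f, function(v) as.numeric(v[[3]]), numeric(1)),
    y = vapply(f, function(v) as.numeric(v[[4]]), numeric(1)),
    z = vapply(f, function(v) as.numeric(v[[5]]), numeric(1)),
    charge = vapply(f, function(v)
      if (length(v) >= 9) as.numeric(v[[9]]) else NA_real_, numeric(1)),
    sybyl_type = vapply(f, function(v) v[[6]], character(1)),
    stringsAsFactors = FALSE)
  bond_lines <- sec("BOND"); bond_lines <- bond_lines[nzchar(trimws(bond_lines))]
  bonds <- if (length(bond_lines)) {
    g <- strsplit(trimws(bond_lines), "[ \t]+")
    data.frame(
      a1 = vapply(g, function(v) as.integer(v[[2]]), integer(1)),
      a2 = vapply(g, function(v) as.integer(v[[3]]), integer(1)),
      order = vapply(g, function(v) v[[4]], character(1)),
      stringsAsFactors = FALSE)
  } else empty_bonds()
  molecule(id = id, name = name, atoms = atoms, bonds = bonds)
}

format_mol2 <- function(m) {
  a <- m$atoms; b <- m$bonds
  type <- if (!is.null(a$sybyl_type)) a$sybyl_type else a$element
  q <- ifelse(is.na(a$charge), 0, a$charge)
  xyz <- coords(m); xyz[is.na(xyz)] <- 0
  c(
    "@<TRIPOS>MOLECULE",
    m$name,
    sprintf(" %d %d 0 0 0", nrow(a), nrow(b)),
    "SMALL",
    "USER_CHARGES",
    "",
    "@<TRIPOS>ATOM",
    sprintf("%7d %-4s %10.4f %10.4f %10.4f %-7s %3d UNL1 %10.6f",
            seq_len(nrow(a)), paste0(a$element, seq_len(nrow(a))),
            xyz[, 1], xyz[, 2], xyz[, 3], type, 1L, q),
    "@<TRIPOS>BOND",
    if (nrow(b)) sprintf("%6d %5d %5d %4s", seq_len(nrow(b)), b$a1, b$a2,
                         b$order) else character())
}

## --- SDF (V2000) writing -------------------------------------------------

format_sdf <- function(m) {
  a <- m$atoms; b <- m$bonds
  xyz <- coords(m); xyz[is.na(xyz)] <- 0
  order_num <- vapply(b$order, function(o)
    switch(o, "1" = 1L, "2" = 2L, "3" = 3L, "ar" = 4L, "am" = 1L, 1L),
    integer(1), USE.NAMES = FALSE)
  lines <- c(
    m$name,
    "  mifqsar",
    m$provenance,
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", nrow(a), nrow(b)),
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            xyz[, 1], xyz[, 2], xyz[, 3], a$element),
    if (nrow(b)) sprintf("%3d%3d%3d  0", b$a1, b$a2, order_num)
      else character(),
    "M  END")
  if (!all(is.na(a$charge))) {
    qs <- sprintf("%.6f", a$charge)
    lines <- c(lines, "> <MIF_PARTIAL_CHARGES>",
               vapply(split(qs, ceiling(seq_along(qs) / 8)),
                      paste, character(1), collapse = " "), "")
  }
  c(lines, "$$$$")
}

#' Write molecular structures
#'
#' Writes molecules as SDF (V2000, coordinates to 1e-4 Angstrom; partial
#' charges stored in a `MIF_PARTIAL_CHARGES` data item) or MOL2 (charges in
#' the atom block).
#'
#' @param molecules List of `mif_molecule`.
#' @param path Output file.
#' @param format `"sdf"` or `"mol2"`.
#' @return `path`, invisibly.
#' @export
write_structures <- function(molecules, path, format = c("sdf", "mol2")) {
  format <- match.arg(format)
  if (inherits(molecules, "mif_molecule")) molecules <- list(molecules)
  fmt <- if (format == "sdf") format_sdf else format_mol2
  writeLines(unlist(lapply(molecules, fmt)), path)
  invisible(path)
}
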