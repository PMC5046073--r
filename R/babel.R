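## Thin wrappers around the Open Babel command line (obabel / obenergy).
## All structure plumbing that is not this package's contribution --
## SMILES parsing, 3D embedding, explicit-H addition, MMFF94 minimization,
## Gasteiger charge assignment, molecular formulas -- is delegated here.

obabel_path <- function() {
  p <- Sys.which("obabel")
  if (!nzchar(p))
    stop("Open Babel ('obabel') not found on PATH; it is required for ",
         "structure preparation")
  p
}

run_obabel <- function(args, input = NULL) {
  out <- suppressWarnings(system2(obabel_path(), args = args,
                                  stdout = TRUE, stderr = TRUE,
                                  input = input))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0)
    stop("obabel failed (status ", status, "): ",
         paste(utils::tail(out, 3), collapse = " / "))
  out
}

## Convert between formats; `source` is a character vector of file lines (or
## a SMILES string with in_format "smi"). Returns output lines.
babel_convert <- function(source, in_format, out_format, options = character()) {
  fin <- tempfile(fileext = paste0(".", in_format))
  fout <- tempfile(fileext = paste0(".", out_format))
  on.exit(unlink(c(fin, fout)), add = TRUE)
  writeLines(source, fin)
  run_obabel(c(fin, "-O", fout, options))
  if (!file.exists(fout)) stop("obabel produced no output")
  readLines(fout, warn = FALSE)
}

## Molecular formula (Hill order) of a SMILES string.
babel_formula <- function(smiles) {
  out <- babel_convert(smiles, "smi", "smi", c("--append", "formula"))
  out <- out[nzchar(out)]
  if (!length(out)) stop("obabel returned no formula for SMILES: ", smiles)
  parts <- strsplit(out[[1]], "\t")[[1]]
  parts[length(parts)]
}

## MMFF94 total energy (kcal/mol) of a molecule with 3D coordinates.
#' Force-field energy of a molecule
#'
#' Evaluates the MMFF94 total energy of the current conformation; used to
#' verify that minimization lowers the energy.
#' @param m A `mif_molecule` with 3D coordinates.
#' @return Energy in kcal/mol.
#' @export
ff_energy <- function(m) {
  if (!has_coords(m)) stop("molecule '", m$id, "' has no 3D coordinates")
  fin <- tempfile(fileext = ".mol2")
  on.exit(unlink(fin), add = TRUE)
  writeLines(format_mol2(m), fin)
  exe <- Sys.which("obenergy")
  if (!nzchar(exe)) stop("'obenergy' not found on PATH")
  out <- suppressWarnings(system2(exe, c("-ff", "MMFF94", fin),
                                  stdout = TRUE, stderr = FALSE))
  line <- grep("^TOTAL ENERGY", out, value = TRUE)
  if (!length(line)) stop("obenergy reported no total energy for '", m$id, "'")
  as.numeric(sub(".*=\\s*([-+0-9.eE]+).*", "\\1", line[[1]]))
}
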