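#' Preparation settings
#'
#' Controls how [prepare()] turns a raw structure into a charged, minimized,
#' parameterized 3D molecule.
#'
#' @param charge_scheme Partial-charge model. Only `"gasteiger"` (iterative
#'   partial equalization of orbital electronegativity) is supported: it is
#'   the closest open, deterministic relative of the proprietary
#'   Gasteiger-Huckel hybrid used by commercial modelling suites, and the
#'   substitution is recorded in each molecule's provenance.
#' @param minimize_gradient_tol Convergence tolerance for energy
#'   minimization, kcal/(Angstrom mol). Default 0.05.
#' @param minimize_max_steps Step budget for the conjugate-gradient
#'   minimizer. Default 20000.
#' @param embed_seed Integer seed for the ETKDG distance-geometry embedding
#'   of structures that arrive without coordinates; the same seed always
#'   reproduces the same conformation.
#' @return A `mif_prep_config` list.
#' @export
preparation_config <- function(charge_scheme = "gasteiger",
                               minimize_gradient_tol = 0.05,
                               minimize_max_steps = 20000L,
                               embed_seed = 0L) {
  charge_scheme <- match.arg(charge_scheme, "gasteiger")
  stopifnot(minimize_gradient_tol > 0, minimize_max_steps >= 1)
  structure(list(charge_scheme = charge_scheme,
                 minimize_gradient_tol = minimize_gradient_tol,
                 minimize_max_steps = as.integer(minimize_max_steps),
                 embed_seed = as.integer(embed_seed)),
            class = "mif_prep_config")
}

#' Prepare a molecule for field calculation
#'
#' Adds explicit hydrogens, embeds a 3D conformation when the input has
#' none, minimizes the structure with the MMFF94 force field (conjugate
#' gradients), assigns Gasteiger partial charges, and populates van der
#' Waals parameters and the five CoMSIA atomic property weights from the
#' packaged parameter tables.
#'
#' @param m A `mif_molecule`.
#' @param config A [preparation_config()].
#' @param check_convergence Probe whether further minimization still lowers
#'   the energy by more than the tolerance (one extra minimizer call); the
#'   outcome is stored in `flags$converged`.
#' @return The prepared `mif_molecule`, with `flags$minimized`,
#'   `flags$converged` and `flags$charge_scheme` set.
#' @export
prepare <- function(m, config = preparation_config(), check_convergence = TRUE) {
  stopifnot(inherits(m, "mif_molecule"), inherits(config, "mif_prep_config"))
  missing <- setdiff(unique(m$atoms$element), vdw_parameters()$element)
  if (length(missing))
    stop("molecule '", m$id, "': no parameters for element(s) ",
         paste(missing, collapse = ", "))
  embedded <- FALSE
  if (!has_coords(m)) {
    m2 <- tryCatch(embed_molecule(m, seed = config$embed_seed),
                   error = function(e)
      stop("3D embedding failed for molecule '", m$id, "': ",
           conditionMessage(e)))
    if (!has_coords(m2))
      stop("3D embedding failed for molecule '", m$id, "'")
    m <- m2
    embedded <- TRUE
  }
  m <- minimize_structure(m, steps = config$minimize_max_steps,
                          charges = TRUE)
  converged <- NA
  if (check_convergence) {
    probe <- minimize_structure(m, steps = 100L, charges = FALSE)
    converged <- (ff_energy(m) - ff_energy(probe)) <= config$minimize_gradient_tol
    if (!converged)
      m$flags$convergence_note <- "step budget exhausted before convergence"
  }
  m <- assign_parameters(m)
  check_net_charge(m)
  m$flags$minimized <- TRUE
  m$flags$converged <- converged
  m$flags$charge_scheme <- config$charge_scheme
  m$flags$embed_seed <- config$embed_seed
  note <- paste0("prepared: gasteiger charges (open substitute for ",
                 "Gasteiger-Huckel), MMFF94 minimization",
                 if (embedded) paste0(", ETKDG embedding (seed ",
                                      config$embed_seed, ")"))
  m$provenance <- paste(c(m$provenance[nzchar(m$provenance)], note),
                        collapse = "; ")
  m
}

## Deterministic 3D embedding: ETKDG distance geometry (seeded) through the
## shipped Python helper; prepare()'s full minimization then relaxes the
## geometry. Prefers the stored SMILES so stereochemistry survives
## untouched. Batched so a whole series costs one interpreter start.
embed_molecules <- function(molecules, seed = 0L) {
  smi <- vapply(molecules, function(m) {
    if (!is.null(m$smiles)) return(m$smiles)
    out <- babel_convert(format_mol2(m), "mol2", "smi")
    strsplit(trimws(out[[1]]), "[ \t]+")[[1]][[1]]
  }, character(1))
  ids <- vapply(molecules, `[[`, character(1), "id")
  script <- system.file("python", "embed3d.py", package = "mifqsar")
  if (!nzchar(script)) stop("embed3d.py helper not found in the package")
  py <- Sys.which("python")
  if (!nzchar(py)) py <- Sys.which("python3")
  if (!nzchar(py)) stop("no 'python' interpreter on PATH for 3D embedding")
  fin <- tempfile(fileext = ".smi"); fout <- tempfile(fileext = ".sdf")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  writeLines(paste(smi, ids, sep = "\t"), fin)
  msg <- suppressWarnings(system2(py, c(script, fin, fout, seed),
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(msg, "status")
  if (!is.null(status) && status != 0)
    stop("3D embedding failed: ", paste(msg, collapse = " / "))
  out <- read_sdf_lines(readLines(fout, warn = FALSE))
  if (length(out) != length(molecules))
    stop("3D embedding returned ", length(out), " of ", length(molecules),
         " molecules")
  for (k in seq_along(out)) {
    out[[k]]$id <- ids[[k]]
    out[[k]]$name <- molecules[[k]]$name
    out[[k]]$atoms$charge <- NA_real_
    out[[k]]$provenance <- molecules[[k]]$provenance
    out[[k]]$smiles <- smi[[k]]
  }
  out
}

embed_molecule <- function(m, seed = 0L) embed_molecules(list(m), seed)[[1]]

#' Minimize a structure with MMFF94
#'
#' Runs up to `steps` conjugate-gradient steps. Exposed separately from
#' [prepare()] so the energy trace of chunked minimization can be inspected
#' (each accepted step lowers the MMFF94 energy).
#'
#' @param m A `mif_molecule` with 3D coordinates.
#' @param steps Maximum minimizer steps.
#' @param crit Energy-change convergence criterion (kcal/mol).
#' @param charges Also (re)assign Gasteiger partial charges.
#' @return The minimized `mif_molecule`.
#' @export
minimize_structure <- function(m, steps = 20000L, crit = 1e-6,
                               charges = FALSE) {
  if (!has_coords(m)) stop("molecule '", m$id, "' has no 3D coordinates")
  opts <- c("-h", "--minimize", "--ff", "MMFF94",
            "--steps", format(as.integer(steps)),
            "--crit", format(crit, scientific = FALSE))
  if (charges) opts <- c(opts, "--partialcharge", "gasteiger")
  mol2 <- babel_convert(format_mol2(m), "mol2", "mol2", opts)
  out <- parse_mol2(mol2, id = m$id, name = m$name)
  if (!charges) out$atoms$charge <- m$atoms$charge[seq_len(min(nrow(m$atoms),
                                                               nrow(out$atoms)))]
  out$provenance <- m$provenance
  out$smiles <- m$smiles
  out$flags <- m$flags
  out
}

## --- parameter tables ----------------------------------------------------

mif_extdata <- function(file) {
  p <- system.file("extdata", file, package = "mifqsar")
  if (!nzchar(p)) stop("packaged table '", file, "' not found")
  p
}

#' Packaged van der Waals parameter table
#'
#' Element-keyed radii (Angstrom) and well depths (kcal/mol) patterned on
#' the Tripos force field, shipped as a versioned plain-text table so CoMFA
#' energies do not depend on any third-party library's internal values.
#' @return `data.frame` with `element`, `vdw_r`, `vdw_eps`.
#' @export
vdw_parameters <- function() {
  read.delim(mif_extdata("vdw_params.tsv"), comment.char = "#",
             stringsAsFactors = FALSE)
}

#' Packaged CoMSIA hydrophobic weight table
#'
#' Coarse atom-class hydrophobicity weights (dimensionless) used for the
#' CoMSIA hydrophobic property; editable plain text.
#' @return `data.frame` with `atom_class`, `weight`.
#' @export
hydrophobic_parameters <- function() {
  read.delim(mif_extdata("comsia_hydrophobic.tsv"), comment.char = "#",
             stringsAsFactors = FALSE)
}

## vdW parameters and CoMSIA weights are pure functions of the charged
## structure, so molecules read back from interchange formats (which keep
## coordinates and charges but not the derived tables) can be
## re-parameterized losslessly.
ensure_parameters <- function(m) {
  if (!anyNA(m$atoms$vdw_r) && !anyNA(m$atoms$w_hbd)) return(m)
  if (anyNA(m$atoms$charge))
    stop("molecule '", m$id, "' lacks partial charges; run prepare()")
  assign_parameters(m)
}

## Assign vdW parameters and CoMSIA property weights.
## CoMSIA parameterization: steric weight = r_vdw^3; electrostatic = partial
## charge; hydrophobic from the atom-class table; hbd/hba as rule-based
## indicator weights on donor/acceptor heavy atoms.
assign_parameters <- function(m) {
  vdw <- vdw_parameters()
  a <- m$atoms
  idx <- match(a$element, vdw$element)
  if (anyNA(idx)) {
    missing <- unique(a$element[is.na(idx)])
    stop("molecule '", m$id, "': no van der Waals parameters for element(s) ",
         paste(missing, collapse = ", "))
  }
  a$vdw_r <- vdw$vdw_r[idx]
  a$vdw_eps <- vdw$vdw_eps[idx]

  n <- nrow(a)
  nbr <- vector("list", n)
  for (k in seq_len(nrow(m$bonds))) {
    i <- m$bonds$a1[[k]]; j <- m$bonds$a2[[k]]
    nbr[[i]] <- c(nbr[[i]], j); nbr[[j]] <- c(nbr[[j]], i)
  }
  elem_of <- a$element
  h_neighbors <- vapply(seq_len(n), function(i)
    sum(elem_of[nbr[[i]]] == "H"), integer(1))
  degree <- lengths(nbr)

  hyd <- hydrophobic_parameters()
  hyd_w <- setNames(hyd$weight, hyd$atom_class)
  hclass <- vapply(seq_len(n), function(i) {
    e <- elem_of[[i]]
    if (e != "H") return(e)
    heavy <- nbr[[i]][elem_of[nbr[[i]]] != "H"]
    if (length(heavy) && elem_of[heavy[[1]]] %in% c("O", "N", "S"))
      "H_polar" else "H_on_C"
  }, character(1))
  w_h <- unname(hyd_w[hclass])
  w_h[is.na(w_h)] <- unname(hyd_w[["default"]])

  a$w_steric <- a$vdw_r^3
  a$w_electrostatic <- a$charge
  a$w_hydrophobic <- w_h
  a$w_hbd <- as.numeric(elem_of %in% c("N", "O") & h_neighbors >= 1)
  a$w_hba <- as.numeric(elem_of == "O" | (elem_of == "N" & degree < 4))
  m$atoms <- a
  m
}
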