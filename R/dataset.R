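## Packaged compound data: 37 tea-polyphenol activity records with their
## 30/7 train/test split, published reference predictions (regression
## fixtures), and a curated SMILES registry. Plain-text tables guarded by
## checksums against accidental edits.

.dataset_md5 <- c(
  activities.tsv = "ca7b78e11dc3f17e9a28c3e71fccd54f",
  reference_predictions.tsv = "389ef9cdaaa34411cb68d0837f634d1d",
  smiles_registry.tsv = "8c7cf1616d5d42b7e0c9d6967feee0c3")

check_dataset_file <- function(file) {
  p <- mif_extdata(file)
  want <- .dataset_md5[[file]]
  got <- unname(md5sum(p))
  if (!identical(got, want))
    stop("packaged data file '", file, "' has been modified (checksum ",
         got, ", expected ", want, ")")
  p
}

#' Convert an IC50 to pIC50
#'
#' `pIC50 = -log10(IC50 in mol/L) = 6 - log10(IC50 in uM)`.
#'
#' @param ic50 IC50 in micromolar; must be positive.
#' @return pIC50 (dimensionless).
#' @export
pic50_from_ic50 <- function(ic50) {
  if (any(!is.finite(ic50)) || any(ic50 <= 0))
    stop("ic50 must be positive and finite (micromolar)")
  6 - log10(ic50)
}

#' Load the 37-compound activity table
#'
#' One row per compound: id, name, IC50 (micromolar; censored rows were
#' reported as "> 30" and keep the printed pIC50 4.5229 plus a censoring
#' flag), pIC50, and train/test assignment (30 training, 7 test compounds:
#' 6, 11, 14, 15, 21, 31, 37).
#'
#' @return `data.frame` ordered by `compound_no`.
#' @export
load_activities <- function() {
  df <- read.delim(check_dataset_file("activities.tsv"), comment.char = "#",
                   stringsAsFactors = FALSE)
  df <- df[order(df$compound_no), ]
  rownames(df) <- NULL
  stopifnot(nrow(df) == 37, identical(sort(df$compound_no), 1:37))
  ok <- df$censored | abs(df$pic50 - pic50_from_ic50(df$ic50)) < 5e-5
  if (!all(ok))
    stop("activity table internal inconsistency at compound(s) ",
         paste(df$compound_no[!ok], collapse = ", "))
  df
}

#' Load the published reference predictions
#'
#' Verbatim actual and model-predicted pIC50 values for all 37 compounds.
#' Regression fixtures only; never used as training input. Only the
#' CoMFA residual column is arithmetically consistent
#' (`res = pred - actual`); the CoMSIA residual column is kept verbatim for
#' the record.
#'
#' @return `data.frame` ordered by `compound_no`.
#' @export
load_reference_predictions <- function() {
  df <- read.delim(check_dataset_file("reference_predictions.tsv"),
                   comment.char = "#", stringsAsFactors = FALSE)
  df <- df[order(df$compound_no), ]
  rownames(df) <- NULL
  stopifnot(nrow(df) == 37)
  df
}

#' Load curated compound structures
#'
#' Builds molecules from the packaged SMILES registry. Compounds whose
#' polymeric structure could not be confidently encoded are returned as an
#' explicit `mif_unavailable` marker (with the reason), never silently
#' skipped. The returned list carries a `coverage` attribute summarizing
#' how many compounds have structures.
#'
#' @param compounds Integer vector of compound numbers (default: all 37).
#' @return Named list (by compound number) of `mif_molecule` or
#'   `mif_unavailable` entries.
#' @export
load_structures <- function(compounds = 1:37) {
  reg <- read.delim(check_dataset_file("smiles_registry.tsv"),
                    comment.char = "#", stringsAsFactors = FALSE)
  act <- load_activities()
  stopifnot(all(compounds %in% reg$compound_no))
  out <- vector("list", length(compounds))
  names(out) <- as.character(compounds)
  for (k in seq_along(compounds)) {
    no <- compounds[[k]]
    row <- reg[reg$compound_no == no, ]
    nm <- act$name[act$compound_no == no]
    out[[k]] <- if (is.na(row$smiles) || !nzchar(row$smiles)) {
      structure(list(compound_no = no, name = nm, reason = row$provenance),
                class = "mif_unavailable")
    } else {
      m <- molecule_from_smiles(row$smiles, id = as.character(no), name = nm)
      m$provenance <- row$provenance
      m
    }
  }
  n_av <- sum(vapply(out, inherits, logical(1), "mif_molecule"))
  attr(out, "coverage") <- sprintf(
    "%d of %d requested compounds have curated structures (monomers plus available dimers)",
    n_av, length(out))
  out
}

#' @export
print.mif_unavailable <- function(x, ...) {
  cat(sprintf("<structure unavailable> compound %s (%s): %s\n",
              x$compound_no, x$name, x$reason))
  invisible(x)
}

#' Export the packaged dataset
#'
#' Copies the packaged plain-text tables (activities, reference
#' predictions, SMILES registry) into a directory.
#'
#' @param dir Output directory (created if needed).
#' @return Paths of the written files, invisibly.
#' @export
export_dataset <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- names(.dataset_md5)
  out <- file.path(dir, files)
  for (k in seq_along(files))
    file.copy(check_dataset_file(files[[k]]), out[[k]], overwrite = TRUE)
  invisible(out)
}
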