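#' Run the full 3D-QSAR pipeline
#'
#' Alignment onto a template through the shared core, field calculation on
#' one grid, descriptor assembly with variance filtering, component
#' selection by leave-one-out q2, final PLS fit, and (optionally) external
#' validation on held-out compounds.
#'
#' @param molecules List of prepared `mif_molecule`s.
#' @param y Named activity vector (pIC50) covering every molecule id.
#' @param fields Field types to compute (see `FIELD_TYPES`).
#' @param template_id Alignment template id (default: first molecule).
#' @param test_ids Molecule ids held out for external validation (`NULL`
#'   for none).
#' @param max_components Upper bound for component selection.
#' @param spacing,margin Grid construction, Angstrom.
#' @param cutoff CoMFA truncation, kcal/mol.
#' @param attenuation CoMSIA attenuation factor.
#' @param core Alignment core query.
#' @param block_scale Equalize field-block variance before PLS.
#' @return List with `model` (`mif_pls`, including LOO `q2` in its stats),
#'   `selection` (q2 trace), `alignment` (per-molecule report),
#'   `descriptors`, `grid`, and `validation` (a `mif_validation` or
#'   `NULL`).
#' @export
qsar_pipeline <- function(molecules, y, fields = c("comsia_steric",
                                                   "comsia_electrostatic"),
                          template_id = NULL, test_ids = NULL,
                          max_components = 5, spacing = 2, margin = 4,
                          cutoff = 30, attenuation = 0.3,
                          core = core_query(), block_scale = TRUE) {
  ids <- vapply(molecules, `[[`, character(1), "id")
  stopifnot(all(ids %in% names(y)))
  molecules <- lapply(molecules, ensure_parameters)
  if (is.null(template_id)) template_id <- ids[[1]]
  ali <- align_set(molecules, template_id, core)
  grid <- make_grid(ali$molecules, spacing, margin)
  blocks <- compute_fields(ali$molecules, fields, grid = grid,
                           cutoff = cutoff, attenuation = attenuation)
  desc <- build_descriptor_matrix(blocks)
  train_ids <- setdiff(ids, test_ids)
  dtrain <- descriptor_rows(desc, train_ids)
  ytrain <- y[train_ids]
  sel <- select_components(dtrain, ytrain, max_components,
                           block_scale = block_scale)
  model <- fit_pls(dtrain, ytrain, sel$n_components,
                   block_scale = block_scale)
  model$stats$q2 <- sel$q2_trace[[sel$n_components]]
  validation <- NULL
  if (length(test_ids)) {
    dtest <- descriptor_rows(desc, test_ids)
    validation <- external_validate(model, dtest, y[test_ids], ytrain)
  }
  list(model = model, selection = sel, alignment = ali$report,
       descriptors = desc, grid = grid, validation = validation)
}
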