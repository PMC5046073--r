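## Dose-response arithmetic for the fluorogenic 4-MU oleate lipase assay.

#' Lipase inhibition rate from fluorescence readings
#'
#' `inhibition (%) = [1 - (F_test - F_test_blank) /
#' (F_control - F_control_blank)] x 100`, where the blanks are the readings
#' without substrate.
#'
#' @param f_test,f_test_blank Test-sample fluorescence with / without
#'   substrate (arbitrary units).
#' @param f_control,f_control_blank Control fluorescence with / without
#'   substrate.
#' @return Inhibition in percent (vectorized).
#' @export
inhibition_rate <- function(f_test, f_test_blank, f_control, f_control_blank) {
  window <- f_control - f_control_blank
  if (any(window <= 0))
    stop("assay window (f_control - f_control_blank) must be positive")
  (1 - (f_test - f_test_blank) / window) * 100
}

#' IC50 from a log-linear dose-response series
#'
#' Ordinary least squares of inhibition (%) on log10(concentration); the
#' IC50 is the concentration where the fitted line crosses 50%. When the
#' observed inhibition values do not straddle 50%, the result is an
#' extrapolation and is flagged.
#'
#' @param concentrations Strictly positive concentrations (any single
#'   unit); at least 2 distinct values.
#' @param inhibition Inhibition (%) per concentration.
#' @return List with `ic50` (in the input unit), `slope`, `intercept`
#'   (regression on log10 concentration) and `extrapolated` (logical).
#' @export
fit_ic50 <- function(concentrations, inhibition) {
  stopifnot(length(concentrations) == length(inhibition))
  if (any(concentrations <= 0)) stop("concentrations must be positive")
  if (length(unique(concentrations)) < 2)
    stop("at least 2 distinct concentrations are required")
  lc <- log10(concentrations)
  fit <- lm(inhibition ~ lc)
  slope <- unname(coef(fit)[[2]]); icept <- unname(coef(fit)[[1]])
  if (abs(slope) < 1e-12)
    stop("dose-response slope is zero; IC50 is undefined")
  extrapolated <- !(min(inhibition) <= 50 && max(inhibition) >= 50)
  if (extrapolated)
    warning("inhibition values do not straddle 50%; IC50 is extrapolated")
  list(ic50 = 10^((50 - icept) / slope), slope = slope, intercept = icept,
       extrapolated = extrapolated)
}

#' Batch IC50 from a plate table
#'
#' @param plate `data.frame` with columns `concentration`, `f_test`,
#'   `f_test_blank`, `f_control`, `f_control_blank` and optionally `sample`
#'   (grouping).
#' @return `data.frame` with one row per sample: `sample`, `ic50`,
#'   `extrapolated`.
#' @export
assay_ic50_table <- function(plate) {
  need <- c("concentration", "f_test", "f_test_blank", "f_control",
            "f_control_blank")
  stopifnot(all(need %in% names(plate)))
  if (is.null(plate$sample)) plate$sample <- "sample1"
  res <- lapply(split(plate, plate$sample), function(g) {
    inh <- inhibition_rate(g$f_test, g$f_test_blank, g$f_control,
                           g$f_control_blank)
    fit <- fit_ic50(g$concentration, inh)
    data.frame(sample = g$sample[[1]], ic50 = fit$ic50,
               extrapolated = fit$extrapolated, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
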