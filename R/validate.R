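#' External test-set validation
#'
#' Predictive coefficient `r2_pred = 1 - PRESS / SD`, where PRESS is the sum
#' of squared test-set prediction errors and SD is the sum of squared
#' deviations of the test activities from the *training-set mean* activity
#' (the standard external-validation convention). Residuals follow the
#' predicted-minus-actual sign convention.
#'
#' @param model A `mif_pls` model.
#' @param test_desc Descriptor rows for the test compounds (a
#'   `mif_descriptors` or active-column matrix).
#' @param test_y Observed test activities.
#' @param train_y Training activities (for the reference mean).
#' @return A `mif_validation`: list with `press`, `sd`, `r2_pred` and
#'   `table` (id, actual, predicted, residual).
#' @export
external_validate <- function(model, test_desc, test_y, train_y) {
  if (!length(test_y)) stop("test set is empty")
  if (sd(train_y) == 0) stop("training activities are degenerate")
  pred <- predict(model, test_desc)
  if (length(pred) != length(test_y))
    stop("test_y length does not match the number of test rows")
  press <- sum((pred - test_y)^2)
  sdsum <- sum((test_y - mean(train_y))^2)
  if (sdsum <= 0)
    stop("test activities show no deviation from the training mean; ",
         "r2_pred is undefined")
  ids <- if (!is.null(names(pred))) names(pred) else seq_along(pred)
  structure(list(
    press = press, sd = sdsum, r2_pred = 1 - press / sdsum,
    table = data.frame(id = ids, actual = test_y, predicted = unname(pred),
                       residual = unname(pred) - test_y,
                       stringsAsFactors = FALSE)),
    class = "mif_validation")
}

#' @export
print.mif_validation <- function(x, ...) {
  cat(sprintf("<mif_validation> %d test compounds: r2_pred = %.3f (PRESS %.4f, SD %.4f)\n",
              nrow(x$table), x$r2_pred, x$press, x$sd))
  print(x$table, row.names = FALSE)
  invisible(x)
}
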