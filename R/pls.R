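## PLS1 (NIPALS) regression of activity on field descriptors, with the
## CoMFA-standard preprocessing: active columns centered, optional block
## scaling to equal total variance per field type, response centered only.

## block scale factors: per field type, 1/sqrt(total variance of its active
## columns), so every block contributes total variance 1 after scaling
block_scale_factors <- function(X, field_type) {
  vapply(split(seq_len(ncol(X)), field_type), function(j) {
    tv <- sum(apply(X[, j, drop = FALSE], 2, var))
    if (tv <= 0) 1 else 1 / sqrt(tv)
  }, numeric(1))
}

#' Fit a PLS regression on field descriptors
#'
#' NIPALS PLS1 with `n_components` latent variables. Columns masked by the
#' variance filter never enter the fit. Reports the non-cross-validated
#' r-squared, the standard error of estimate
#' `SEE = sqrt(RSS / (n - c - 1))`, the F ratio
#' `(r2/c) / ((1-r2)/(n-c-1))`, and the per-field-type contribution
#' fractions.
#'
#' @param desc A `mif_descriptors` (training rows).
#' @param y Numeric activity vector (pIC50), one value per row of `desc`.
#' @param n_components Number of latent components; at most
#'   `min(rows - 1, active columns)`.
#' @param block_scale Scale each field block to equal total variance before
#'   fitting (essential for multi-field CoMSIA models); recorded in the
#'   model.
#' @return A `mif_pls` model.
#' @export
fit_pls <- function(desc, y, n_components, block_scale = TRUE) {
  stopifnot(inherits(desc, "mif_descriptors"))
  X <- desc$X[, desc$mask, drop = FALSE]
  cols <- desc$columns[desc$mask, , drop = FALSE]
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("length(y) != number of descriptor rows")
  if (anyNA(X) || anyNA(y)) stop("missing values are not allowed")
  if (sd(y) == 0) stop("y has zero variance")
  if (n_components > min(n - 1, p))
    stop("n_components = ", n_components, " exceeds min(rows - 1, ",
         "active columns) = ", min(n - 1, p))

  center <- colMeans(X)
  scale_f <- rep(1, p)
  if (block_scale) {
    bf <- block_scale_factors(X, cols$field_type)
    scale_f <- unname(bf[cols$field_type])
  }
  Xs <- sweep(sweep(X, 2, center), 2, scale_f, `*`)
  ym <- mean(y)
  u <- y - ym

  W <- matrix(0, p, n_components)   # x weights
  P <- matrix(0, p, n_components)   # x loadings
  qv <- numeric(n_components)       # y loadings
  E <- Xs; f <- u
  for (a in seq_len(n_components)) {
    w <- crossprod(E, f)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-14) { # residual y orthogonal to X; stop early
      W <- W[, seq_len(a - 1), drop = FALSE]
      P <- P[, seq_len(a - 1), drop = FALSE]
      qv <- qv[seq_len(a - 1)]
      n_components <- a - 1L
      break
    }
    w <- w / nw
    t <- as.vector(E %*% w)
    tt <- sum(t^2)
    pvec <- crossprod(E, t) / tt
    qa <- sum(f * t) / tt
    E <- E - tcrossprod(t, pvec)
    f <- f - qa * t
    W[, a] <- w; P[, a] <- pvec; qv[a] <- qa
  }
  ## regression vector in the scaled, centered space
  R <- W %*% solve(crossprod(P, W))
  b <- as.vector(R %*% qv)

  fitted <- as.vector(Xs %*% b) + ym
  resid <- y - fitted
  rss <- sum(resid^2); tss <- sum((y - ym)^2)
  r2 <- 1 - rss / tss
  cc <- n_components
  see <- sqrt(rss / (n - cc - 1))
  fstat <- (r2 / cc) / ((1 - r2) / (n - cc - 1))
  col_sd <- apply(Xs, 2, sd)

  model <- structure(list(
    n_components = cc,
    x_weights = W, x_loadings = P, y_loadings = qv,
    coefficients = b, y_mean = ym,
    col_center = center, col_scale = scale_f, col_sd = col_sd,
    columns = cols, block_scale = block_scale,
    training_ids = rownames(X), fitted = fitted, residuals = resid,
    stats = list(r2 = r2, see = see, f = fstat, n = n)),
    class = "mif_pls")
  model$stats$contributions <- field_contributions(model)
  model
}

#' @export
print.mif_pls <- function(x, ...) {
  s <- x$stats
  cat(sprintf("<mif_pls> %d components, %d training compounds, %d columns\n",
              x$n_components, s$n, length(x$coefficients)))
  cat(sprintf("  r2 = %.3f, SEE = %.3f, F = %.3f\n", s$r2, s$see, s$f))
  if (!is.null(s$q2)) cat(sprintf("  LOO q2 = %.3f\n", s$q2))
  cat("  field contributions:",
      paste(sprintf("%s %.3f", names(s$contributions), s$contributions),
            collapse = ", "), "\n")
  invisible(x)
}

#' Predict activities for new descriptor rows
#'
#' Deterministic linear map on the model's centered/scaled columns; rows
#' must carry the model's column layout (same field types and grid).
#'
#' @param object A `mif_pls` model.
#' @param newdata A `mif_descriptors` (or matrix with the model's full or
#'   active column count).
#' @param ... Unused.
#' @return Numeric vector of predicted pIC50, named by molecule id when
#'   available.
#' @export
predict.mif_pls <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "mif_descriptors"))
    newdata$X[, newdata$mask, drop = FALSE]
  else
    as.matrix(newdata)
  if (ncol(X) != nrow(object$columns))
    stop("newdata has ", ncol(X), " active columns; the model expects ",
         nrow(object$columns))
  Xs <- sweep(sweep(X, 2, object$col_center), 2, object$col_scale, `*`)
  pred <- as.vector(Xs %*% object$coefficients) + object$y_mean
  names(pred) <- rownames(X)
  pred
}

#' Leave-one-out cross-validation
#'
#' Refits the model with each training row held out and predicts it; the
#' variance filter and block-scale factors are frozen from the full
#' training set (set `refilter = TRUE` to redo the column filter inside
#' each fold). `q2 = 1 - PRESS / sum((y - mean(y))^2)`.
#'
#' @param desc A `mif_descriptors` (training rows).
#' @param y Activity vector.
#' @param n_components Components per fold fit.
#' @param block_scale Passed to [fit_pls()].
#' @param refilter Redo column variance filtering inside each fold.
#' @return List with `q2` and `predictions` (per-row LOO predictions).
#' @export
loo_q2 <- function(desc, y, n_components, block_scale = TRUE,
                   refilter = FALSE) {
  n <- nrow(desc$X)
  if (n < 3) stop("leave-one-out needs at least 3 rows")
  preds <- numeric(n)
  for (i in seq_len(n)) {
    di <- desc
    di$X <- desc$X[-i, , drop = FALSE]
    if (refilter) {
      sds <- apply(di$X, 2, sd)
      sig <- desc$filter_sigma[di$columns$field_type]
      di$mask <- !(sds < sig)
    }
    fit <- fit_pls(di, y[-i], n_components, block_scale = block_scale)
    preds[[i]] <- predict(fit, desc$X[i, desc$mask, drop = FALSE])
  }
  press <- sum((y - preds)^2)
  q2 <- 1 - press / sum((y - mean(y))^2)
  list(q2 = q2, predictions = setNames(preds, rownames(desc$X)),
       press = press)
}

#' Choose the number of PLS components
#'
#' Evaluates LOO q2 for every component count up to `max_components`
#' (capped at `rows - 2` so each fold remains fittable) and returns the
#' count maximizing q2, breaking ties toward fewer components.
#'
#' @param desc,y,block_scale As in [loo_q2()].
#' @param max_components Largest count to consider.
#' @return List with `n_components` (the optimum) and `q2_trace` (named
#'   numeric vector over all evaluated counts).
#' @export
select_components <- function(desc, y, max_components = 10,
                              block_scale = TRUE) {
  stopifnot(max_components >= 1)
  amax <- min(max_components, nrow(desc$X) - 2, sum(desc$mask))
  trace <- vapply(seq_len(amax), function(a)
    loo_q2(desc, y, a, block_scale = block_scale)$q2, numeric(1))
  names(trace) <- seq_len(amax)
  list(n_components = unname(which.max(trace)), q2_trace = trace)
}

#' Per-field contribution fractions
#'
#' For each field type, the fraction
#' `sum_j |coefficient_j * sd_j| / total` over that field's active columns;
#' nonnegative and summing to 1.
#'
#' @param model A `mif_pls` model.
#' @param columns Column metadata; defaults to the model's own.
#' @return Named numeric vector over field types.
#' @export
field_contributions <- function(model, columns = model$columns) {
  w <- abs(model$coefficients * model$col_sd)
  agg <- vapply(split(w, columns$field_type), sum, numeric(1))
  agg <- agg[order(match(names(agg), FIELD_TYPES))]   # canonical order first
  total <- sum(agg)
  if (total == 0) return(setNames(rep(0, length(agg)), names(agg)))
  agg / total
}

## --- model (de)serialization --------------------------------------------

#' Save / load a PLS model as JSON
#'
#' The whole model (coefficients, preprocessing record, column metadata,
#' statistics) as a single JSON document.
#'
#' @param model A `mif_pls`.
#' @param path Output / input file.
#' @return `write_model()`: `path` invisibly; `read_model()`: a `mif_pls`.
#' @export
write_model <- function(model, path) {
  obj <- model
  obj$x_weights <- unclass(obj$x_weights)
  obj$x_loadings <- unclass(obj$x_loadings)
  jsonlite::write_json(unclass(obj), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$columns <- as.data.frame(obj$columns, stringsAsFactors = FALSE)
  obj$x_weights <- as.matrix(obj$x_weights)
  obj$x_loadings <- as.matrix(obj$x_loadings)
  obj$stats$contributions <- unlist(obj$stats$contributions)
  structure(obj, class = "mif_pls")
}
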