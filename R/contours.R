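#' StDev*Coeff contour map
#'
#' For one field type, maps each active column's `coefficient x column
#' standard deviation` back to its grid position (masked columns are exactly
#' zero). The product is computed on the preprocessed columns and is
#' invariant to the block scaling. "Favored" and "disfavored" iso-levels are
#' set at the configured upper/lower percentiles of the value distribution
#' over the field's active columns (the conventional reading of 80%/20%
#' contribution contours).
#'
#' @param model A `mif_pls` model.
#' @param field_type One of the model's field types.
#' @param grid The shared `mif_grid` the descriptors were computed on.
#' @param levels Lower/upper percentile pair, default `c(0.2, 0.8)`.
#' @return A `mif_contour`: list with `field_type`, `grid`, `values` (one
#'   per grid point), `favored_level`, `disfavored_level`.
#' @export
stdev_coeff_map <- function(model, field_type, grid, levels = c(0.2, 0.8)) {
  stopifnot(inherits(model, "mif_pls"), length(levels) == 2,
            levels[1] <= levels[2])
  sel <- model$columns$field_type == field_type
  if (!any(sel))
    stop("field type '", field_type, "' is not part of the model")
  vals <- numeric(n_grid_points(grid))
  active_vals <- model$coefficients[sel] * model$col_sd[sel]
  vals[model$columns$grid_index[sel]] <- active_vals
  fav <- unname(quantile(active_vals, levels[2]))
  dis <- unname(quantile(active_vals, levels[1]))
  structure(list(field_type = field_type, grid = grid, values = vals,
                 favored_level = fav, disfavored_level = dis),
            class = "mif_contour")
}

#' @export
print.mif_contour <- function(x, ...) {
  cat(sprintf("<mif_contour %s> %d grid points; favored >= %.4g, disfavored <= %.4g\n",
              x$field_type, length(x$values), x$favored_level,
              x$disfavored_level))
  invisible(x)
}

#' Write a volumetric grid as OpenDX
#'
#' Plain-text OpenDX scalar field, loadable next to the aligned structures
#' in standard molecular viewers. Values are written in the package's grid
#' order (z fastest), which is also the OpenDX convention.
#'
#' @param x A `mif_contour` or `mif_field`.
#' @param path Output `.dx` file.
#' @return `path`, invisibly.
#' @export
write_opendx <- function(x, path) {
  grid <- x$grid; v <- x$values
  n <- grid$counts
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(
    sprintf("# OpenDX scalar field (%s) written by mifqsar",
            if (!is.null(x$field_type)) x$field_type else "field"),
    sprintf("object 1 class gridpositions counts %d %d %d", n[1], n[2], n[3]),
    sprintf("origin %.10g %.10g %.10g", grid$origin[1], grid$origin[2],
            grid$origin[3]),
    sprintf("delta %.10g 0 0", grid$spacing),
    sprintf("delta 0 %.10g 0", grid$spacing),
    sprintf("delta 0 0 %.10g", grid$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d",
            n[1], n[2], n[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            length(v))), con)
  full <- length(v) %/% 3
  if (full > 0) {
    m <- matrix(v[seq_len(3 * full)], ncol = 3, byrow = TRUE)
    writeLines(sprintf("%.10e %.10e %.10e", m[, 1], m[, 2], m[, 3]), con)
  }
  rest <- v[seq_len(length(v)) > 3 * full]
  if (length(rest))
    writeLines(paste(sprintf("%.10e", rest), collapse = " "), con)
  writeLines(c('attribute "dep" string "positions"',
               'object "regular positions regular connections" class field',
               'component "positions" value 1',
               'component "connections" value 2',
               'component "data" value 3'), con)
  invisible(path)
}

#' Read an OpenDX scalar field written by [write_opendx()]
#'
#' @param path A `.dx` file.
#' @return List with `grid` (a `mif_grid`) and `values`.
#' @export
read_opendx <- function(path) {
  lines <- readLines(path, warn = FALSE)
  gp <- grep("class gridpositions counts", lines, value = TRUE)[[1]]
  counts <- as.integer(utils::tail(strsplit(gp, "\\s+")[[1]], 3))
  og <- grep("^origin", lines, value = TRUE)[[1]]
  origin <- as.numeric(strsplit(og, "\\s+")[[1]][2:4])
  deltas <- grep("^delta", lines, value = TRUE)
  dvals <- lapply(deltas, function(l) as.numeric(strsplit(l, "\\s+")[[1]][2:4]))
  spacing <- dvals[[1]][1]
  stopifnot(abs(dvals[[2]][2] - spacing) < 1e-9,
            abs(dvals[[3]][3] - spacing) < 1e-9)
  start <- grep("data follows", lines)
  n_items <- as.integer(sub(".*items (\\d+) data follows.*", "\\1",
                            lines[[start]]))
  vals <- numeric(0); i <- start + 1L
  while (length(vals) < n_items) {
    vals <- c(vals, as.numeric(strsplit(trimws(lines[[i]]), "\\s+")[[1]]))
    i <- i + 1L
  }
  list(grid = grid_spec(origin = origin, spacing = spacing, counts = counts),
       values = vals[seq_len(n_items)])
}
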