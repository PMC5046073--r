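#' Rectilinear probe grid
#'
#' @param origin Numeric 3-vector, Angstrom (grid corner).
#' @param spacing Grid spacing in Angstrom (default 2, the conventional
#'   CoMFA setting).
#' @param counts Integer 3-vector of points per axis (each >= 2).
#' @return A `mif_grid`.
#' @export
grid_spec <- function(origin, spacing = 2, counts) {
  counts <- as.integer(counts)
  stopifnot(length(origin) == 3, length(counts) == 3, spacing > 0,
            all(counts >= 2))
  structure(list(origin = as.numeric(origin), spacing = as.numeric(spacing),
                 counts = counts),
            class = "mif_grid")
}

#' @export
print.mif_grid <- function(x, ...) {
  cat(sprintf("<mif_grid> %dx%dx%d points, spacing %g A, origin (%g, %g, %g)\n",
              x$counts[1], x$counts[2], x$counts[3], x$spacing,
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

n_grid_points <- function(grid) prod(grid$counts)

#' Grid point coordinates
#'
#' Points are ordered x-major with z varying fastest (the OpenDX
#' convention); the linear index of point (ix, iy, iz) is
#' `((ix-1)*ny + (iy-1))*nz + iz`.
#'
#' @param grid A `mif_grid`.
#' @return Numeric (nx*ny*nz) x 3 matrix.
#' @export
grid_points <- function(grid) {
  ax <- lapply(1:3, function(k)
    grid$origin[[k]] + grid$spacing * (seq_len(grid$counts[[k]]) - 1))
  g <- expand.grid(z = ax[[3]], y = ax[[2]], x = ax[[1]],
                   KEEP.OUT.ATTRS = FALSE)
  unname(as.matrix(g[, c("x", "y", "z")]))
}

#' Build a grid around aligned molecules
#'
#' Axis-aligned grid covering the union bounding box of all atoms, extended
#' by `margin` on every side; the point counts are the smallest that cover
#' the extended box at the given spacing (at least 2 per axis).
#'
#' @param molecules List of `mif_molecule`s with coordinates (or a single
#'   molecule).
#' @param spacing Grid spacing, Angstrom.
#' @param margin Margin added on every side, Angstrom (default 4 = two grid
#'   cells at the default spacing).
#' @return A `mif_grid`.
#' @export
make_grid <- function(molecules, spacing = 2, margin = 4) {
  if (inherits(molecules, "mif_molecule")) molecules <- list(molecules)
  if (!length(molecules) || !all(vapply(molecules, has_coords, logical(1))))
    stop("make_grid() needs at least one molecule with 3D coordinates")
  xyz <- do.call(rbind, lapply(molecules, coords))
  lo <- apply(xyz, 2, min) - margin
  hi <- apply(xyz, 2, max) + margin
  counts <- pmax(2L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
  grid_spec(origin = lo, spacing = spacing, counts = counts)
}

same_grid <- function(a, b, tol = 1e-9) {
  all(abs(a$origin - b$origin) < tol) && abs(a$spacing - b$spacing) < tol &&
    all(a$counts == b$counts)
}

#' Probe atom specification
#'
#' Default: an sp3-carbon probe (Tripos-patterned van der Waals parameters
#' from the packaged table) with charge +1 e and unit CoMSIA weight for
#' every property.
#'
#' @param vdw_radius,vdw_epsilon Probe Lennard-Jones parameters.
#' @param charge Probe charge, e.
#' @param comsia_weights Named numeric vector over the five CoMSIA
#'   properties.
#' @return A `mif_probe`.
#' @export
probe_spec <- function(vdw_radius = 1.70, vdw_epsilon = 0.107, charge = 1,
                       comsia_weights = setNames(rep(1, 5), COMSIA_PROPERTIES)) {
  stopifnot(vdw_radius > 0, vdw_epsilon >= 0,
            all(names(comsia_weights) %in% COMSIA_PROPERTIES))
  structure(list(vdw_radius = vdw_radius, vdw_epsilon = vdw_epsilon,
                 charge = charge, comsia_weights = comsia_weights),
            class = "mif_probe")
}

## distances (n_points x n_atoms) from grid points to atoms
point_atom_distances <- function(grid, m) {
  pts <- grid_points(grid)
  xyz <- coords(m)
  d2 <- outer(rowSums(pts^2), rowSums(xyz^2), `+`) - 2 * pts %*% t(xyz)
  sqrt(pmax(d2, 0))
}

field_block <- function(molecule_id, field_type, values, grid,
                        metadata = list()) {
  structure(list(molecule_id = molecule_id, field_type = field_type,
                 values = as.numeric(values), grid = grid,
                 metadata = metadata),
            class = "mif_field")
}

## Coulomb constant: kcal/mol per (e^2/Angstrom)
COULOMB_KCAL <- 332.0636

#' CoMFA probe-interaction fields
#'
#' Steric field: Lennard-Jones 6-12 energy of the probe summed over atoms,
#' with arithmetic radius combination (`R_ij = r_i + r_probe`) and geometric
#' well depths. Electrostatic field: Coulomb energy
#' `332.0636 q_probe q_i / (eps(r) r)` with the distance-dependent
#' dielectric `eps(r) = r`. Both fields are clamped to `[-cutoff, +cutoff]`;
#' at points where the steric energy hits the cutoff (inside the van der
#' Waals envelope) the electrostatic value is replaced by the mean of the
#' molecule's non-clamped electrostatic values, the conventional CoMFA
#' treatment, and the affected point indices are recorded in the block
#' metadata.
#'
#' @param m Prepared, aligned `mif_molecule` (charges and vdW parameters
#'   assigned).
#' @param grid A `mif_grid`.
#' @param probe A [probe_spec()].
#' @param cutoff Truncation value, kcal/mol (default 30).
#' @return List with elements `steric` and `electrostatic`, each a
#'   `mif_field`.
#' @export
comfa_fields <- function(m, grid, probe = probe_spec(), cutoff = 30) {
  if (anyNA(m$atoms$vdw_r) || anyNA(m$atoms$charge))
    stop("molecule '", m$id, "' lacks charges or vdW parameters; run prepare()")
  if (!all(atoms_inside(grid, m)))
    warning("molecule '", m$id, "' has atoms outside the grid box")
  d <- point_atom_distances(grid, m)
  d <- pmax(d, 1e-6)
  rij <- matrix(m$atoms$vdw_r + probe$vdw_radius, nrow(d), ncol(d),
                byrow = TRUE)
  eij <- matrix(sqrt(m$atoms$vdw_eps * probe$vdw_epsilon), nrow(d), ncol(d),
                byrow = TRUE)
  sr6 <- (rij / d)^6
  steric <- rowSums(eij * (sr6^2 - 2 * sr6))
  steric <- pmin(pmax(steric, -cutoff), cutoff)
  elec <- COULOMB_KCAL * probe$charge * as.vector(d^-2 %*% m$atoms$charge)
  elec <- pmin(pmax(elec, -cutoff), cutoff)
  clamped <- which(steric >= cutoff)
  if (length(clamped)) {
    keep <- if (length(clamped) < length(elec)) elec[-clamped] else numeric()
    elec[clamped] <- if (length(keep)) mean(keep) else 0
  }
  list(
    steric = field_block(m$id, "comfa_steric", steric, grid),
    electrostatic = field_block(m$id, "comfa_electrostatic", elec, grid,
                                metadata = list(mean_substituted = clamped)))
}

atoms_inside <- function(grid, m) {
  xyz <- coords(m)
  hi <- grid$origin + grid$spacing * (grid$counts - 1)
  apply(xyz >= matrix(grid$origin, nrow(xyz), 3, byrow = TRUE) &
        xyz <= matrix(hi, nrow(xyz), 3, byrow = TRUE), 1, all)
}

#' CoMSIA similarity-index field
#'
#' Gaussian similarity index at grid point q:
#' `A(q) = -sum_i w_probe w_i exp(-alpha r_iq^2)`, with the attenuation
#' factor `alpha` defaulting to 0.3 and atomic property weights `w_i` taken
#' from the preparation step. Finite everywhere; no cutoff is needed, which
#' is the point of replacing potentials with similarity indices.
#'
#' @param m Prepared, aligned `mif_molecule`.
#' @param grid A `mif_grid`.
#' @param property One of `"steric"`, `"electrostatic"`, `"hydrophobic"`,
#'   `"hbd"`, `"hba"`.
#' @param probe A [probe_spec()].
#' @param attenuation Gaussian attenuation factor (1/Angstrom^2).
#' @return A `mif_field` with field_type `comsia_<property>`.
#' @export
comsia_field <- function(m, grid, property, probe = probe_spec(),
                         attenuation = 0.3) {
  property <- match.arg(property, COMSIA_PROPERTIES)
  w <- comsia_weights(m, property)
  wp <- probe$comsia_weights[[property]]
  d <- point_atom_distances(grid, m)
  vals <- -wp * as.vector(exp(-attenuation * d^2) %*% w)
  field_block(m$id, paste0("comsia_", property), vals, grid,
              metadata = list(attenuation = attenuation))
}

#' Compute a set of fields for aligned molecules
#'
#' Convenience wrapper producing one `mif_field` per molecule and field
#' type, all on one shared grid.
#'
#' @param molecules List of prepared, aligned `mif_molecule`s.
#' @param fields Character vector of field types (see `FIELD_TYPES`).
#' @param grid Shared grid; built with [make_grid()] when `NULL`.
#' @param probe A [probe_spec()].
#' @param cutoff CoMFA truncation, kcal/mol.
#' @param attenuation CoMSIA attenuation factor.
#' @param spacing,margin Grid construction parameters when `grid` is `NULL`.
#' @return Flat list of `mif_field` blocks.
#' @export
compute_fields <- function(molecules, fields, grid = NULL,
                           probe = probe_spec(), cutoff = 30,
                           attenuation = 0.3, spacing = 2, margin = 4) {
  stopifnot(all(fields %in% FIELD_TYPES))
  if (is.null(grid)) grid <- make_grid(molecules, spacing, margin)
  blocks <- list()
  for (m in molecules) {
    if (any(c("comfa_steric", "comfa_electrostatic") %in% fields)) {
      cf <- comfa_fields(m, grid, probe, cutoff)
      if ("comfa_steric" %in% fields)
        blocks[[length(blocks) + 1]] <- cf$steric
      if ("comfa_electrostatic" %in% fields)
        blocks[[length(blocks) + 1]] <- cf$electrostatic
    }
    for (p in COMSIA_PROPERTIES) {
      ft <- paste0("comsia_", p)
      if (ft %in% fields)
        blocks[[length(blocks) + 1]] <- comsia_field(m, grid, p, probe,
                                                     attenuation)
    }
  }
  blocks
}

#' Assemble the descriptor matrix
#'
#' One row per molecule, one column per (field type, grid point), columns
#' ordered by field type (canonical order) then linear grid index. Columns
#' whose standard deviation across molecules falls below the per-field
#' minimum-sigma threshold are masked out of all downstream fitting.
#'
#' @param blocks Flat list of `mif_field` objects sharing one grid, with
#'   every molecule present for every field type.
#' @param column_filter_sigma Minimum column standard deviation; either a
#'   single number or a named vector per field type. Default: 2.0 kcal/mol
#'   for CoMFA fields, 0 for CoMSIA fields (the classic settings).
#' @return A `mif_descriptors`: list with `X` (full matrix, molecule ids as
#'   rownames), `columns` (metadata: field_type, grid_index), `mask`
#'   (logical, TRUE = active), `grid`, `filter_sigma`.
#' @export
build_descriptor_matrix <- function(blocks,
                                    column_filter_sigma = c(
                                      comfa_steric = 2, comfa_electrostatic = 2,
                                      comsia_steric = 0, comsia_electrostatic = 0,
                                      comsia_hydrophobic = 0, comsia_hbd = 0,
                                      comsia_hba = 0)) {
  stopifnot(length(blocks) > 0)
  grid <- blocks[[1]]$grid
  if (!all(vapply(blocks, function(b) same_grid(b$grid, grid), logical(1))))
    stop("field blocks do not share a single grid")
  types <- intersect(FIELD_TYPES,
                     unique(vapply(blocks, `[[`, character(1), "field_type")))
  ids <- unique(vapply(blocks, `[[`, character(1), "molecule_id"))
  np <- n_grid_points(grid)
  Xs <- list(); meta <- list()
  for (ft in types) {
    sub <- blocks[vapply(blocks, function(b) b$field_type == ft, logical(1))]
    bid <- vapply(sub, `[[`, character(1), "molecule_id")
    if (!setequal(bid, ids) || anyDuplicated(bid))
      stop("field type '", ft, "': molecules do not match across field types")
    M <- do.call(rbind, lapply(ids, function(i)
      sub[[match(i, bid)]]$values))
    Xs[[ft]] <- M
    meta[[ft]] <- data.frame(field_type = ft, grid_index = seq_len(np),
                             stringsAsFactors = FALSE)
  }
  X <- do.call(cbind, Xs)
  rownames(X) <- ids
  columns <- do.call(rbind, meta)
  rownames(columns) <- NULL
  if (length(column_filter_sigma) == 1 && is.null(names(column_filter_sigma)))
    column_filter_sigma <- setNames(rep(column_filter_sigma, length(types)),
                                    types)
  sig <- column_filter_sigma[columns$field_type]
  if (anyNA(sig)) stop("column_filter_sigma missing for some field type")
  sds <- apply(X, 2, sd)
  sds[is.na(sds)] <- 0   # single-molecule matrix
  mask <- !(sds < sig)
  structure(list(X = X, columns = columns, mask = mask, grid = grid,
                 filter_sigma = column_filter_sigma),
            class = "mif_descriptors")
}

#' @export
print.mif_descriptors <- function(x, ...) {
  cat(sprintf("<mif_descriptors> %d molecules x %d columns (%d active)\n",
              nrow(x$X), ncol(x$X), sum(x$mask)))
  for (ft in unique(x$columns$field_type))
    cat(sprintf("  %s: %d active / %d\n", ft,
                sum(x$mask[x$columns$field_type == ft]),
                sum(x$columns$field_type == ft)))
  invisible(x)
}

#' Export a descriptor matrix as tab-separated text
#'
#' Writes the full molecules x columns matrix as TSV (row names = molecule
#' ids) plus a JSON sidecar (`<path>.json`) with the column metadata, the
#' active-column mask, the grid, and the filter thresholds.
#'
#' @param desc A `mif_descriptors`.
#' @param path Output TSV file.
#' @return Paths of the two written files, invisibly.
#' @export
write_descriptors <- function(desc, path) {
  df <- data.frame(molecule_id = rownames(desc$X), desc$X,
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("molecule_id",
                    paste0(desc$columns$field_type, ".",
                           desc$columns$grid_index))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  sidecar <- paste0(path, ".json")
  jsonlite::write_json(
    list(columns = desc$columns, mask = desc$mask,
         grid = unclass(desc$grid), filter_sigma = as.list(desc$filter_sigma)),
    sidecar, digits = NA, auto_unbox = TRUE)
  invisible(c(path, sidecar))
}

#' Subset descriptor rows by molecule id
#' @param desc A `mif_descriptors`.
#' @param ids Molecule ids to keep, in order.
#' @return A `mif_descriptors` with the selected rows (mask unchanged).
#' @export
descriptor_rows <- function(desc, ids) {
  miss <- setdiff(ids, rownames(desc$X))
  if (length(miss)) stop("unknown molecule id(s): ", paste(miss, collapse = ", "))
  out <- desc
  out$X <- desc$X[ids, , drop = FALSE]
  out
}
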