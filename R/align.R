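## Common-substructure alignment: every molecule is rigidly superposed onto
## a template through the shared benzopyran core, the open replacement for
## a docking-derived alignment.

#' Default benzopyran core query
#'
#' The chromane (2H-1-benzopyran) skeleton shared by all flavan-3-ols:
#' a benzene ring fused to an oxygen-containing six-membered ring. Matching
#' is by element and connectivity only (bond orders and aromaticity are
#' ignored), so the same query hits catechins, gallocatechins and the
#' benzopyranone scaffold of the synthetic series.
#'
#' @param smiles Core pattern as SMILES; override to change the query.
#' @return A connectivity-only `mif_molecule` usable as `core` in
#'   [find_core_mapping()].
#' @export
core_query <- function(smiles = "C1Cc2ccccc2OC1") {
  key <- paste0("core:", smiles)
  if (is.null(.mif_cache[[key]]))
    .mif_cache[[key]] <- molecule_from_smiles(smiles, id = "core_query")
  .mif_cache[[key]]
}

.mif_cache <- new.env(parent = emptyenv())

## molecule -> undirected igraph over all atoms (H included)
molecule_graph <- function(m) {
  g <- igraph::make_empty_graph(n = nrow(m$atoms), directed = FALSE)
  if (nrow(m$bonds))
    g <- igraph::add_edges(g, rbind(m$bonds$a1, m$bonds$a2))
  g
}

## all element-consistent embeddings of `pattern` in `target`, each an
## integer vector of target atom indices ordered by pattern atom
core_matches <- function(pattern, target) {
  elems <- unique(c(pattern$atoms$element, target$atoms$element))
  col_p <- as.integer(factor(pattern$atoms$element, levels = elems))
  col_t <- as.integer(factor(target$atoms$element, levels = elems))
  maps <- igraph::subgraph_isomorphisms(
    pattern = molecule_graph(pattern), target = molecule_graph(target),
    method = "vf2", vertex.color1 = col_t, vertex.color2 = col_p)
  ms <- lapply(maps, as.integer)
  ms[order(vapply(ms, paste, character(1), collapse = ","))]
}

#' Map the common core of two molecules
#'
#' Finds the benzopyran-core atoms of the template and of the mobile
#' molecule and pairs them. When a molecule contains several core
#' embeddings, the combination minimizing the post-superposition RMSD is
#' chosen; exact ties break deterministically toward the lowest atom-index
#' sequence.
#'
#' @param template,mobile Prepared `mif_molecule`s with coordinates.
#' @param core Core substructure query (a connectivity-only molecule), by
#'   default [core_query()].
#' @return `data.frame` with columns `template`, `mobile` (1-based atom
#'   indices, one row per core atom).
#' @export
find_core_mapping <- function(template, mobile, core = core_query()) {
  mt <- core_matches(core, template)
  if (!length(mt)) stop("core not found in template '", template$id, "'")
  mm <- core_matches(core, mobile)
  if (!length(mm)) stop("core not found in molecule '", mobile$id, "'")
  tmatch <- mt[[1]]
  if (length(mm) > 1 && has_coords(template) && has_coords(mobile)) {
    rmsds <- vapply(mm, function(sel)
      kabsch(coords(template)[tmatch, , drop = FALSE],
             coords(mobile)[sel, , drop = FALSE])$rmsd, numeric(1))
    best <- rmsds <= min(rmsds) + 1e-9   # tie band; order is lexicographic
    mm <- mm[best]
  }
  data.frame(template = tmatch, mobile = mm[[1]])
}

## Kabsch: least-squares rigid superposition of Q (mobile) onto P (fixed).
## Returns proper rotation R, translation t (x' = R x + t) and rmsd.
kabsch <- function(P, Q) {
  stopifnot(nrow(P) == nrow(Q), ncol(P) == 3)
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  H <- t(Qc) %*% Pc
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tvec <- cp - as.vector(R %*% cq)
  moved <- Qc %*% t(R)
  rmsd <- sqrt(mean(rowSums((moved - Pc)^2)))
  list(rotation = R, translation = tvec, rmsd = rmsd)
}

#' Superpose a molecule onto a template
#'
#' Solves the rigid least-squares (Kabsch) problem over the mapped core
#' atoms and applies the optimal proper rotation and translation to every
#' atom of the mobile molecule.
#'
#' @param template Fixed `mif_molecule` with coordinates.
#' @param mobile Moving `mif_molecule` with coordinates.
#' @param atom_map `data.frame` from [find_core_mapping()] (columns
#'   `template`, `mobile`); needs at least 3 non-collinear pairs.
#' @return List with `result` (class `mif_alignment`: rotation, translation,
#'   rmsd over mapped atoms, atom_map) and `molecule` (the transformed
#'   mobile molecule).
#' @export
superpose <- function(template, mobile, atom_map) {
  stopifnot(has_coords(template), has_coords(mobile))
  if (nrow(atom_map) < 3)
    stop("atom_map has ", nrow(atom_map), " pairs; at least 3 are required")
  P <- coords(template)[atom_map$template, , drop = FALSE]
  Q <- coords(mobile)[atom_map$mobile, , drop = FALSE]
  for (M in list(P, Q)) {
    sv <- svd(sweep(M, 2, colMeans(M)))$d
    if (sv[[2]] < 1e-8)
      stop("mapped core atoms are collinear; superposition is degenerate")
  }
  k <- kabsch(P, Q)
  if (abs(det(k$rotation) - 1) > 1e-8)
    stop("superposition produced an improper rotation")  # should not happen
  xyz <- coords(mobile) %*% t(k$rotation)
  xyz <- sweep(xyz, 2, k$translation, `+`)
  out <- set_coords(mobile, xyz)
  res <- structure(
    list(molecule_id = mobile$id, rotation = k$rotation,
         translation = k$translation, rmsd = k$rmsd, atom_map = atom_map),
    class = "mif_alignment")
  list(result = res, molecule = out)
}

#' @export
print.mif_alignment <- function(x, ...) {
  cat(sprintf("<mif_alignment %s> rmsd %.4f A over %d core atoms\n",
              x$molecule_id, x$rmsd, nrow(x$atom_map)))
  invisible(x)
}

#' Align a set of molecules onto one template
#'
#' Applies [find_core_mapping()] and [superpose()] to every molecule; the
#' template itself passes through with an identity transform.
#'
#' @param molecules List of prepared `mif_molecule`s.
#' @param template_id Id of the template molecule (must be in `molecules`).
#' @param core Core query, see [core_query()].
#' @return List with `molecules` (aligned, template first retained in input
#'   order) and `report` (`data.frame`: molecule_id, rmsd, n_matched).
#' @export
align_set <- function(molecules, template_id, core = core_query()) {
  ids <- vapply(molecules, `[[`, character(1), "id")
  ti <- match(template_id, ids)
  if (is.na(ti)) stop("template '", template_id, "' not among the molecules")
  template <- molecules[[ti]]
  aligned <- vector("list", length(molecules))
  report <- data.frame(molecule_id = ids, rmsd = NA_real_,
                       n_matched = NA_integer_)
  for (i in seq_along(molecules)) {
    map <- find_core_mapping(template, molecules[[i]], core)
    sup <- superpose(template, molecules[[i]], map)
    aligned[[i]] <- sup$molecule
    report$rmsd[[i]] <- sup$result$rmsd
    report$n_matched[[i]] <- nrow(map)
  }
  list(molecules = aligned, report = report)
}
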