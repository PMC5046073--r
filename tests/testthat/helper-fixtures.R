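# Shared fixtures, memoized so expensive structure preparation and the
# synthetic end-to-end pipeline run once per test session.

.fix <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fix[[key]])) .fix[[key]] <- force(expr)
  .fix[[key]]
}

EC_SMILES <- "C1[C@@H]([C@H](OC2=CC(=CC(=C21)O)O)C3=CC(=C(C=C3)O)O)O"
CATECHIN_SMILES <- "C1[C@@H]([C@@H](OC2=CC(=CC(=C21)O)O)C3=CC(=C(C=C3)O)O)O"

prepared_ec <- function() memo("ec", {
  prepare(molecule_from_smiles(EC_SMILES, id = "EC"),
          check_convergence = FALSE)
})

prepared_catechin <- function() memo("catechin", {
  prepare(molecule_from_smiles(CATECHIN_SMILES, id = "catechin"),
          check_convergence = FALSE)
})

prepared_benzene <- function() memo("benzene", {
  prepare(molecule_from_smiles("c1ccccc1", id = "benzene"),
          check_convergence = FALSE)
})

# 20-molecule synthetic series under the study conditions (noise 0.1),
# plus the full pipeline fit used by the recovery checks.
sim_series <- function() memo("sim_series", {
  spec <- simulation_spec(n_molecules = 20, noise_sd = 0.1, seed = 42)
  series <- make_series(spec)
  list(spec = spec, series = series,
       y = simulate_activities(series, spec))
})

sim_pipeline <- function() memo("sim_pipeline", {
  s <- sim_series()
  qsar_pipeline(s$series$molecules, s$y,
                fields = c("comsia_steric", "comsia_electrostatic"),
                max_components = 8)
})

# A bare molecule with manually set parameters (no preparation round-trip),
# for analytic field fixtures.
bare_atom_molecule <- function(elements, xyz, charge = 0, vdw_r = 1.70,
                               vdw_eps = 0.107, w = list()) {
  atoms <- data.frame(element = elements, x = xyz[, 1], y = xyz[, 2],
                      z = xyz[, 3], charge = charge, vdw_r = vdw_r,
                      vdw_eps = vdw_eps, stringsAsFactors = FALSE)
  for (p in c("steric", "electrostatic", "hydrophobic", "hbd", "hba"))
    atoms[[paste0("w_", p)]] <- if (!is.null(w[[p]])) w[[p]] else 0
  molecule("bare", atoms = atoms)
}

# Toy descriptor container for PLS tests: any numeric matrix with per-column
# field types, bypassing the geometry pipeline.
toy_desc <- function(X, field_type = "comsia_steric", mask = NULL,
                     filter_sigma = NULL) {
  X <- as.matrix(X)
  if (is.null(rownames(X))) rownames(X) <- paste0("m", seq_len(nrow(X)))
  if (length(field_type) == 1) field_type <- rep(field_type, ncol(X))
  idx <- stats::ave(seq_len(ncol(X)), field_type, FUN = seq_along)
  npts <- max(idx)
  counts <- c(2L, 2L, max(2L, as.integer(ceiling(npts / 4))))
  if (prod(counts) < npts) counts[3] <- counts[3] + npts  # ensure coverage
  if (is.null(mask)) mask <- rep(TRUE, ncol(X))
  if (is.null(filter_sigma))
    filter_sigma <- setNames(rep(0, length(unique(field_type))),
                             unique(field_type))
  structure(list(X = X,
                 columns = data.frame(field_type = field_type,
                                      grid_index = idx,
                                      stringsAsFactors = FALSE),
                 mask = mask,
                 grid = grid_spec(c(0, 0, 0), 2, counts),
                 filter_sigma = filter_sigma),
            class = "mif_descriptors")
}

# ---- independent oracles -------------------------------------------------

# Exhaustive subgraph monomorphism matcher (elements + bond existence),
# independent of the igraph-based implementation.
brute_subgraph_matches <- function(pattern, target) {
  pn <- nrow(pattern$atoms); tn <- nrow(target$atoms)
  padj <- matrix(FALSE, pn, pn); tadj <- matrix(FALSE, tn, tn)
  for (k in seq_len(nrow(pattern$bonds))) {
    i <- pattern$bonds$a1[[k]]; j <- pattern$bonds$a2[[k]]
    padj[i, j] <- padj[j, i] <- TRUE
  }
  for (k in seq_len(nrow(target$bonds))) {
    i <- target$bonds$a1[[k]]; j <- target$bonds$a2[[k]]
    tadj[i, j] <- tadj[j, i] <- TRUE
  }
  pe <- pattern$atoms$element; te <- target$atoms$element
  out <- list()
  assign_next <- function(map) {
    d <- length(map) + 1L
    if (d > pn) { out[[length(out) + 1L]] <<- map; return(invisible()) }
    for (cand in seq_len(tn)) {
      if (cand %in% map) next
      if (te[[cand]] != pe[[d]]) next
      ok <- TRUE
      for (prev in seq_len(d - 1L))
        if (padj[prev, d] && !tadj[map[[prev]], cand]) { ok <- FALSE; break }
      if (ok) assign_next(c(map, cand))
    }
  }
  assign_next(integer())
  out
}

# Hierarchically refined rotation grid search for the minimal RMSD of two
# centered point sets (oracle for the least-squares superposition).
grid_search_rmsd <- function(P, Q) {
  Pc <- sweep(P, 2, colMeans(P)); Qc <- sweep(Q, 2, colMeans(Q))
  rotmat <- function(a, b, g) {
    ca <- cos(a); sa <- sin(a); cb <- cos(b); sb <- sin(b)
    cg <- cos(g); sg <- sin(g)
    Rz1 <- matrix(c(ca, -sa, 0, sa, ca, 0, 0, 0, 1), 3, byrow = TRUE)
    Ry <- matrix(c(cb, 0, sb, 0, 1, 0, -sb, 0, cb), 3, byrow = TRUE)
    Rz2 <- matrix(c(cg, -sg, 0, sg, cg, 0, 0, 0, 1), 3, byrow = TRUE)
    Rz1 %*% Ry %*% Rz2
  }
  eval_rmsd <- function(a, b, g)
    sqrt(mean(rowSums((Qc %*% t(rotmat(a, b, g)) - Pc)^2)))
  best <- c(0, 0, 0); best_val <- Inf
  step <- pi / 12
  grid1 <- expand.grid(a = seq(0, 2 * pi - step, step),
                       b = seq(0, pi, step),
                       g = seq(0, 2 * pi - step, step))
  for (r in seq_len(nrow(grid1))) {
    v <- eval_rmsd(grid1$a[[r]], grid1$b[[r]], grid1$g[[r]])
    if (v < best_val) { best_val <- v; best <- as.numeric(grid1[r, ]) }
  }
  for (step in c(pi / 60, pi / 360, pi / 2160, pi / 12960)) {
    grid2 <- expand.grid(a = best[1] + seq(-5, 5) * step,
                         b = best[2] + seq(-5, 5) * step,
                         g = best[3] + seq(-5, 5) * step)
    for (r in seq_len(nrow(grid2))) {
      v <- eval_rmsd(grid2$a[[r]], grid2$b[[r]], grid2$g[[r]])
      if (v < best_val) { best_val <- v; best <- as.numeric(grid2[r, ]) }
    }
  }
  best_val
}

# Ordinary least squares through the QR decomposition (oracle for the
# full-rank PLS limit).
ols_predictions <- function(X, y, Xnew = X) {
  Xc <- cbind(1, X)
  beta <- qr.solve(Xc, y)
  as.vector(cbind(1, Xnew) %*% beta)
}

rigid_motion <- function(xyz, angle, axis, shift) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, byrow = TRUE)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
  sweep(xyz %*% t(R), 2, shift, `+`)
}
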