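## Synthetic congeneric series with known ground truth: benzopyranone
## scaffold plus sampled substituents, activities generated from
## interpretable substituent summaries (not from the computed fields, so
## end-to-end recovery is a genuine test rather than a circular one).

#' Default substituent menu for the synthetic series
#'
#' Compact alkyl and cycloalkyl fragments spanning steric bulk (H to
#' cyclohexyl; the larger substituents are rings so their grid occupancy is
#' conformationally stable) plus two polar substituents (hydroxyl,
#' methoxy), attached to the scaffold by SMILES substitution. `volume` is
#' the substituent's van der Waals volume proxy, the sum of r_vdw^3 over
#' its atoms (hydrogens included) from the packaged parameter table -- the
#' same per-atom measure the CoMSIA steric weights use, so a volume-linear
#' activity is a physically well-posed steric signal. Within this menu,
#' volume is monotone in fragment heavy-atom count.
#'
#' @return `data.frame` with `name`, `fragment` (SMILES), `heavy_atoms`,
#'   `polar_atoms`, `volume`.
#' @export
substituent_menu <- function() {
  # ring-closure digit 9 so cyclic fragments cannot collide with the
  # scaffold template's open ring bonds
  m <- data.frame(
    name = c("H", "methyl", "ethyl", "propyl", "isopropyl", "tert-butyl",
             "cyclopentyl", "cyclohexyl", "hydroxyl", "methoxy"),
    fragment = c("[H]", "C", "CC", "CCC", "C(C)C", "C(C)(C)C",
                 "C9CCCC9", "C9CCCCC9", "O", "OC"),
    heavy_atoms = c(0L, 1L, 2L, 3L, 3L, 4L, 5L, 6L, 1L, 2L),
    polar_atoms = c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 1L, 1L),
    n_carbon = c(0L, 1L, 2L, 3L, 3L, 4L, 5L, 6L, 0L, 1L),
    n_hydrogen = c(1L, 3L, 5L, 7L, 7L, 9L, 9L, 11L, 1L, 3L),
    n_oxygen = c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 1L, 1L),
    stringsAsFactors = FALSE)
  vdw <- vdw_parameters()
  r3 <- function(e) vdw$vdw_r[vdw$element == e]^3
  m$volume <- m$n_carbon * r3("C") + m$n_hydrogen * r3("H") +
    m$n_oxygen * r3("O")
  m[, c("name", "fragment", "heavy_atoms", "polar_atoms", "volume")]
}

#' Simulation settings for the synthetic congeneric series
#'
#' The scaffold is a benzopyranone (chroman-4-one) with two substitution
#' slots (C2 and C7), so the default benzopyran alignment core query works
#' unmodified. True activity is a linear function of substituent summaries:
#' `pIC50 = base + w_bulk * bulk + w_polar * polar + noise`, where `bulk`
#' is the total substituent van der Waals volume proxy (Angstrom^3, a
#' steric signal; see [substituent_menu()]) and `polar` the substituent O+N
#' count (an electrostatic/H-bond signal, weight 0 by default so the
#' generating signal is purely steric).
#'
#' @param n_molecules Series size (at least 8).
#' @param scaffold Scaffold SMILES template with two `%s` substituent
#'   slots.
#' @param menu Substituent menu, see [substituent_menu()].
#' @param effect_weights Named vector `c(bulk = ..., polar = ...)`, pIC50
#'   units per summary unit.
#' @param base_pic50 Intercept of the generating model.
#' @param noise_sd Gaussian noise, pIC50 units.
#' @param seed Integer; the same seed gives byte-identical series.
#' @return A `mif_sim_spec`.
#' @export
simulation_spec <- function(n_molecules = 20,
                            scaffold = "O=C1CC(%s)Oc2cc(%s)ccc12",
                            menu = substituent_menu(),
                            effect_weights = c(bulk = 0.02, polar = 0),
                            base_pic50 = 5,
                            noise_sd = 0.1,
                            seed = 1L) {
  stopifnot(n_molecules >= 8, noise_sd >= 0,
            all(c("bulk", "polar") %in% names(effect_weights)),
            lengths(regmatches(scaffold, gregexpr("%s", scaffold))) == 2)
  structure(list(n_molecules = as.integer(n_molecules), scaffold = scaffold,
                 menu = menu, effect_weights = effect_weights,
                 base_pic50 = base_pic50, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "mif_sim_spec")
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Generate the synthetic molecule series
#'
#' Samples distinct substituent pairs, builds each molecule's SMILES from
#' the scaffold, and prepares it (embedding, minimization, charges,
#' parameters). Chemically unbuildable combinations are resampled a bounded
#' number of times.
#'
#' @param spec A [simulation_spec()].
#' @param prepare_config Preparation settings.
#' @return List with `molecules` (prepared `mif_molecule`s) and `truth`
#'   (`data.frame`: id, substituent names, `bulk`, `polar`).
#' @export
make_series <- function(spec, prepare_config = preparation_config()) {
  stopifnot(inherits(spec, "mif_sim_spec"))
  menu <- spec$menu
  combos <- with_seed(spec$seed, {
    picked <- list(); tries <- 0
    while (length(picked) < spec$n_molecules) {
      tries <- tries + 1
      if (tries > 100 * spec$n_molecules)
        stop("could not sample ", spec$n_molecules,
             " distinct substituent pairs from the menu")
      pair <- sample.int(nrow(menu), 2, replace = TRUE)
      key <- paste(pair, collapse = "-")
      if (!key %in% names(picked)) picked[[key]] <- pair
    }
    picked
  })
  raw <- vector("list", spec$n_molecules)
  for (i in seq_len(spec$n_molecules)) {
    pair <- combos[[i]]
    smi <- sprintf(spec$scaffold, menu$fragment[[pair[[1]]]],
                   menu$fragment[[pair[[2]]]])
    id <- sprintf("sim%02d", i)
    raw[[i]] <- tryCatch(molecule_from_smiles(smi, id = id),
                         error = function(e)
      stop("synthetic molecule ", id, " ('", smi, "') could not be built: ",
           conditionMessage(e)))
  }
  embedded <- embed_molecules(raw, seed = spec$seed)  # one batched call
  molecules <- vector("list", spec$n_molecules)
  truth <- data.frame(id = character(), r1 = character(), r2 = character(),
                      heavy = integer(), bulk = numeric(), polar = integer(),
                      stringsAsFactors = FALSE)
  for (i in seq_len(spec$n_molecules)) {
    pair <- combos[[i]]
    id <- embedded[[i]]$id
    m <- tryCatch(
      prepare(embedded[[i]], prepare_config, check_convergence = FALSE),
      error = function(e) stop("synthetic molecule ", id,
                               " could not be prepared: ",
                               conditionMessage(e)))
    molecules[[i]] <- m
    truth <- rbind(truth, data.frame(
      id = id, r1 = menu$name[[pair[[1]]]], r2 = menu$name[[pair[[2]]]],
      heavy = menu$heavy_atoms[[pair[[1]]]] + menu$heavy_atoms[[pair[[2]]]],
      bulk = menu$volume[[pair[[1]]]] + menu$volume[[pair[[2]]]],
      polar = menu$polar_atoms[[pair[[1]]]] + menu$polar_atoms[[pair[[2]]]],
      stringsAsFactors = FALSE))
  }
  list(molecules = molecules, truth = truth)
}

#' Simulate activities for a synthetic series
#'
#' `pIC50_i = base + w_bulk bulk_i + w_polar polar_i + eps_i`,
#' `eps ~ N(0, noise_sd^2)`, seeded from the spec.
#'
#' @param series Output of [make_series()].
#' @param spec The same [simulation_spec()].
#' @return Named numeric vector of pIC50 values (by molecule id).
#' @export
simulate_activities <- function(series, spec) {
  stopifnot(inherits(spec, "mif_sim_spec"))
  tr <- series$truth
  mu <- spec$base_pic50 + spec$effect_weights[["bulk"]] * tr$bulk +
    spec$effect_weights[["polar"]] * tr$polar
  eps <- with_seed(spec$seed + 1000L, rnorm(nrow(tr), 0, spec$noise_sd))
  setNames(mu + eps, tr$id)
}
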