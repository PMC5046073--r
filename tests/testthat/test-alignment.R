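test_that("a molecule maps onto itself by the identity", {
  ec <- prepared_ec()
  map <- find_core_mapping(ec, ec)
  expect_equal(map$template, map$mobile)
  sup <- superpose(ec, ec, map)
  expect_lt(sup$result$rmsd, 1e-10)
  expect_equal(sup$result$rotation, diag(3), tolerance = 1e-8)
  expect_equal(det(sup$result$rotation), 1, tolerance = 1e-8)
})

test_that("core mapping of catechin vs epicatechin matches the exhaustive oracle", {
  ec <- prepared_ec(); cat <- prepared_catechin()
  core <- core_query()
  map <- find_core_mapping(ec, cat, core)
  expect_equal(nrow(map), sum(core$atoms$element != "H"))

  # oracle: brute-force subgraph monomorphism on the small graphs
  oracle <- brute_subgraph_matches(core, cat)
  expect_gte(length(oracle), 1)
  oracle_sets <- unique(lapply(oracle, function(m) sort(m)))
  expect_true(list(sort(map$mobile)) %in% oracle_sets)
  # the implementation's match list agrees with the oracle's match sets
  impl <- mifqsar:::core_matches(core, cat)
  expect_setequal(vapply(impl, function(m) paste(sort(m), collapse = ","),
                         character(1)),
                  vapply(oracle_sets, paste, character(1), collapse = ","))
})

test_that("an applied rigid motion is recovered exactly", {
  ec <- prepared_ec()
  moved <- ec
  moved$id <- "moved"
  moved <- mifqsar:::set_coords(moved, rigid_motion(coords(ec), pi / 2,
                                                    c(0, 0, 1), c(1, 2, 3)))
  map <- find_core_mapping(ec, moved)
  sup <- superpose(ec, moved, map)
  expect_lt(sup$result$rmsd, 1e-6)
  expect_lt(max(abs(coords(sup$molecule) - coords(ec))), 1e-6)
})

test_that("noisy superposition attains the grid-search optimum", {
  ec <- prepared_ec()
  core_idx <- find_core_mapping(ec, ec)$template
  P <- coords(ec)[core_idx, ]
  set.seed(11)
  Q <- P + matrix(rnorm(length(P), sd = 0.1), ncol = 3)
  Q <- rigid_motion(Q, 0.8, c(1, 1, 0), c(-2, 0.5, 4))
  fit <- mifqsar:::kabsch(P, Q)
  oracle <- grid_search_rmsd(P, Q)
  expect_lt(abs(fit$rmsd - oracle), 1e-3)
  expect_lte(fit$rmsd, oracle + 1e-9)  # never worse than the search
})

test_that("superposition rejects degenerate input", {
  ec <- prepared_ec()
  expect_error(superpose(ec, ec, data.frame(template = 1:2, mobile = 1:2)),
               "at least 3")
  lin <- bare_atom_molecule(rep("C", 4),
                            cbind(0:3, 0, 0))
  expect_error(superpose(lin, lin,
                         data.frame(template = 1:4, mobile = 1:4)),
               "collinear")
  bz <- prepared_benzene()
  expect_error(find_core_mapping(ec, bz), "core not found")
})

test_that("alignment RMSD is invariant to prior rigid motions of the mobile", {
  ec <- prepared_ec(); cat <- prepared_catechin()
  map <- find_core_mapping(ec, cat)
  base <- superpose(ec, cat, map)$result$rmsd
  for (s in 1:5) {
    set.seed(s)
    moved <- mifqsar:::set_coords(cat, rigid_motion(
      coords(cat), runif(1, 0, pi), rnorm(3), rnorm(3, sd = 5)))
    expect_equal(superpose(ec, moved, map)$result$rmsd, base,
                 tolerance = 1e-6)
  }
})

test_that("align_set aligns a whole series onto the template", {
  ec <- prepared_ec(); cat <- prepared_catechin()
  res <- align_set(list(ec, cat), template_id = "EC")
  expect_equal(res$report$molecule_id, c("EC", "catechin"))
  expect_lt(res$report$rmsd[[1]], 1e-10)
  expect_equal(res$report$n_matched, c(10L, 10L))
  expect_error(align_set(list(ec), template_id = "nope"), "not among")
})
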