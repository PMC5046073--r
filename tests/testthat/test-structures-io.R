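test_that("benzene SDF reads to explicit-hydrogen form and round-trips", {
  bz <- prepared_benzene()
  path <- withr::local_tempfile(fileext = ".sdf")
  write_structures(bz, path, format = "sdf")
  back <- read_structures(path, format = "sdf")
  expect_length(back, 1)
  m <- back[[1]]
  expect_equal(sum(m$atoms$element == "C"), 6)
  expect_equal(sum(m$atoms$element == "H"), 6)
  # round-trip preserves element sequence, bond list and coordinates
  expect_equal(m$atoms$element, bz$atoms$element)
  expect_equal(m$bonds[, c("a1", "a2")], bz$bonds[, c("a1", "a2")])
  expect_lt(max(abs(coords(m) - coords(bz))), 1e-4)
  # partial charges survive through the SDF data item
  expect_equal(m$atoms$charge, bz$atoms$charge, tolerance = 1e-6)
})

test_that("MOL2 round-trip preserves charges in the atom block", {
  ec <- prepared_ec()
  path <- withr::local_tempfile(fileext = ".mol2")
  write_structures(ec, path, format = "mol2")
  back <- read_structures(path, format = "mol2")[[1]]
  expect_equal(back$atoms$element, ec$atoms$element)
  expect_equal(back$atoms$charge, ec$atoms$charge, tolerance = 1e-6)
  expect_lt(max(abs(coords(back) - coords(ec))), 1e-4)
})

test_that("empty and malformed inputs are reported, not swallowed", {
  empty <- withr::local_tempfile(fileext = ".smi")
  writeLines(character(), empty)
  expect_warning(out <- read_structures(empty, "smiles"), "empty")
  expect_length(out, 0)
  expect_error(read_structures(file.path(tempdir(), "nope.sdf"), "sdf"),
               "no such file")
  bad <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("CCO ok", "C1CC not_closed"), bad)
  expect_error(read_structures(bad, "smiles"), "record 2")
})

test_that("SMILES records carry connectivity but no coordinates", {
  path <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("OC1=CC=CC=C1\tphenol", "CCO\tethanol"), path)
  mols <- read_structures(path, "smiles")
  expect_length(mols, 2)
  expect_equal(mols[[1]]$id, "phenol")
  expect_equal(sum(mols[[1]]$atoms$element != "H"), 7)
  expect_false(has_coords(mols[[1]]))
})

test_that("preparation assigns deterministic, symmetric Gasteiger charges", {
  me <- prepare(molecule_from_smiles("C", id = "methane",
                                     name = "methane"),
                preparation_config(embed_seed = 7),
                check_convergence = FALSE)
  expect_equal(nrow(me$atoms), 5)
  qc <- me$atoms$charge[me$atoms$element == "C"]
  qh <- me$atoms$charge[me$atoms$element == "H"]
  expect_lt(qc, 0)
  expect_lt(max(qh) - min(qh), 1e-6)        # symmetry
  expect_lt(abs(sum(me$atoms$charge)), 1e-3) # neutral molecule

  me2 <- prepare(molecule_from_smiles("C", id = "methane"),
                 preparation_config(embed_seed = 7),
                 check_convergence = FALSE)
  expect_identical(me$atoms$charge, me2$atoms$charge)  # determinism
})

test_that("preparation populates vdW parameters and CoMSIA weights", {
  ph <- prepare(molecule_from_smiles("OC1=CC=CC=C1", id = "phenol"),
                check_convergence = FALSE)
  o <- ph$atoms$element == "O"
  expect_gt(ph$atoms$w_hbd[o], 0)   # phenolic OH donates
  expect_gt(ph$atoms$w_hba[o], 0)   # and accepts
  expect_equal(ph$atoms$vdw_r[o], 1.52)
  expect_equal(ph$atoms$w_steric, ph$atoms$vdw_r^3)
  expect_equal(ph$atoms$w_electrostatic, ph$atoms$charge)
  # polar H vs apolar H hydrophobic classes
  hw <- ph$atoms$w_hydrophobic[ph$atoms$element == "H"]
  expect_true(any(hw < 0) && any(hw > 0))
  expect_true(isTRUE(ph$flags$minimized))
})

test_that("unparameterizable elements are reported by name", {
  expect_error(prepare(molecule_from_smiles("OB(O)c1ccccc1", id = "pba"),
                       check_convergence = FALSE),
               "element\\(s\\) B")
})

test_that("chunked minimization lowers the MMFF94 energy monotonically", {
  m0 <- mifqsar:::embed_molecule(molecule_from_smiles("CCCCO", id = "butanol"))
  trace <- numeric()
  m <- m0
  for (k in 1:4) {
    m <- minimize_structure(m, steps = 15, crit = 1e-12)
    trace <- c(trace, ff_energy(m))
  }
  expect_lt(trace[[1]], ff_energy(m0) + 1e-9)
  expect_true(all(diff(trace) <= 1e-6))  # non-increasing energy trace
})

test_that("preparing an already-minimized structure is a near fixed point", {
  ec <- prepared_ec()
  again <- minimize_structure(ec, steps = 20000, crit = 1e-6)
  disp <- sqrt(mean(rowSums((coords(again) - coords(ec))^2)))
  expect_lt(disp, 0.2)  # only numerical-noise-scale relaxation remains
})
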