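single_c_atom <- function(at = c(0, 0, 0), charge = 0)
  bare_atom_molecule("C", matrix(at, 1), charge = charge,
                     w = list(steric = 1))

test_that("grid construction covers the bounding box plus margin", {
  m <- single_c_atom()
  g <- make_grid(m, spacing = 2, margin = 4)
  expect_equal(g$origin, c(-4, -4, -4))
  expect_equal(g$counts, c(5L, 5L, 5L))
  pts <- grid_points(g)
  expect_equal(range(pts), c(-4, 4))

  # degenerate margin still yields >= 2 points per axis
  g0 <- make_grid(m, spacing = 2, margin = 0)
  expect_equal(g0$counts, c(2L, 2L, 2L))

  # a union grid contains each individual grid
  m2 <- single_c_atom(c(6, 1, -3))
  gu <- make_grid(list(m, m2), spacing = 2, margin = 4)
  g2 <- make_grid(m2, spacing = 2, margin = 4)
  hi <- function(g) g$origin + g$spacing * (g$counts - 1)
  expect_true(all(gu$origin <= g$origin) && all(gu$origin <= g2$origin))
  expect_true(all(hi(gu) >= hi(g)) && all(hi(gu) >= hi(g2)))

  expect_error(make_grid(list()), "at least one molecule")
})

test_that("CoMFA steric values clamp at the cutoff and match the 6-12 form", {
  m <- single_c_atom()
  g <- grid_spec(c(0, 0, 0), spacing = 10, counts = c(2, 2, 2))
  f <- comfa_fields(m, g, cutoff = 30)
  # point coincident with the atom center is clamped to +30
  pts <- grid_points(g)
  at_center <- which(rowSums(abs(pts)) == 0)
  expect_equal(f$steric$values[[at_center]], 30)
  # point at 10 A: direct evaluation of the Lennard-Jones 6-12 formula
  d <- 10; rij <- 1.70 + 1.70; eij <- sqrt(0.107 * 0.107)
  lj <- eij * ((rij / d)^12 - 2 * (rij / d)^6)
  on_axis <- which(pts[, 1] == 10 & pts[, 2] == 0 & pts[, 3] == 0)
  expect_equal(f$steric$values[[on_axis]], lj, tolerance = 1e-12)
  # neutral molecule: electrostatic field identically zero
  expect_true(all(f$electrostatic$values == 0))
})

test_that("CoMFA electrostatics use eps(r) = r and mean-fill clamped points", {
  m <- single_c_atom(charge = 0.5)
  g <- grid_spec(c(0, 0, 0), spacing = 5, counts = c(3, 2, 2))
  f <- comfa_fields(m, g, cutoff = 30)
  pts <- grid_points(g)
  on_axis <- which(pts[, 1] == 5 & pts[, 2] == 0 & pts[, 3] == 0)
  expect_equal(f$electrostatic$values[[on_axis]],
               332.0636 * 1 * 0.5 / 5^2, tolerance = 1e-12)
  # the sterically clamped point got the mean of the non-clamped values
  clamped <- f$electrostatic$metadata$mean_substituted
  expect_gte(length(clamped), 1)
  expect_equal(f$electrostatic$values[clamped[[1]]],
               mean(f$electrostatic$values[-clamped]))
})

test_that("CoMSIA kernel matches its closed form and stays finite", {
  m <- single_c_atom()
  g <- grid_spec(c(0, 0, 0), spacing = 2, counts = c(3, 2, 2))
  f <- comsia_field(m, g, "steric", attenuation = 0.3)
  pts <- grid_points(g)
  at0 <- which(rowSums(abs(pts)) == 0)
  r2 <- which(pts[, 1] == 2 & pts[, 2] == 0 & pts[, 3] == 0)
  expect_equal(f$values[[at0]], -1)                       # -e^0
  expect_equal(f$values[[r2]], -exp(-0.3 * 4), tolerance = 1e-12)
  expect_true(all(is.finite(f$values)))
  # zero property weight: identically zero field
  m0 <- bare_atom_molecule("C", matrix(0, 1, 3), w = list(steric = 0))
  expect_true(all(comsia_field(m0, g, "steric")$values == 0))
  expect_error(comsia_field(m, g, "banana"), "arg")
})

test_that("fields are invariant under a common translation", {
  ec <- prepared_ec()
  g <- make_grid(ec, spacing = 2, margin = 4)
  shift <- c(3.1, -2.2, 0.7)
  ec2 <- mifqsar:::set_coords(ec, sweep(coords(ec), 2, shift, `+`))
  g2 <- grid_spec(g$origin + shift, g$spacing, g$counts)
  f1 <- comfa_fields(ec, g); f2 <- comfa_fields(ec2, g2)
  expect_lt(max(abs(f1$steric$values - f2$steric$values)), 1e-10)
  expect_lt(max(abs(f1$electrostatic$values - f2$electrostatic$values)),
            1e-10)
  c1 <- comsia_field(ec, g, "hydrophobic")
  c2 <- comsia_field(ec2, g2, "hydrophobic")
  expect_lt(max(abs(c1$values - c2$values)), 1e-10)
})

test_that("steric decay and attenuation behave monotonically", {
  m <- single_c_atom()
  # steric magnitude decays monotonically beyond the LJ minimum (r = rij)
  d <- seq(3.4, 12, by = 0.25)
  lj <- vapply(d, function(x) {
    gx <- grid_spec(c(x, 0, 0), 1, c(2, 2, 2))
    suppressWarnings(comfa_fields(m, gx)$steric$values[[1]])
  }, numeric(1))
  expect_true(all(lj <= 0))                    # attractive branch
  expect_true(all(diff(abs(lj)) <= 1e-12))     # decaying magnitude
  # doubling the attenuation never increases |value| anywhere
  gg <- grid_spec(c(-3, -3, -3), 1.5, c(5, 5, 5))
  a1 <- abs(comsia_field(m, gg, "steric", attenuation = 0.3)$values)
  a2 <- abs(comsia_field(m, gg, "steric", attenuation = 0.6)$values)
  expect_true(all(a2 <= a1 + 1e-15))
})

test_that("CoMSIA fields vary smoothly on grid refinement", {
  ec <- prepared_ec()
  # max difference between adjacent grid values shrinks with the spacing
  jumps <- vapply(c(2, 1, 0.5), function(sp) {
    g <- make_grid(ec, spacing = sp, margin = 2)
    v <- comsia_field(ec, g, "steric")$values
    arr <- array(v, dim = rev(g$counts))  # z fastest
    max(abs(diff(arr)))
  }, numeric(1))
  expect_true(all(diff(jumps) < 0))
})

test_that("descriptor assembly filters columns exactly like a direct std sweep", {
  mols <- list(single_c_atom(c(0, 0, 0)), single_c_atom(c(1, 0, 0)),
               single_c_atom(c(0, 1.5, 0)))
  for (k in seq_along(mols)) mols[[k]]$id <- paste0("t", k)
  g <- grid_spec(c(-4, -4, -4), 2, c(5, 5, 5))
  blocks <- compute_fields(mols, c("comfa_steric", "comsia_steric"),
                           grid = g)
  desc <- build_descriptor_matrix(blocks, column_filter_sigma = c(
    comfa_steric = 2, comsia_steric = 0))
  expect_equal(rownames(desc$X), c("t1", "t2", "t3"))
  # oracle: direct column-wise standard deviations against the thresholds
  sds <- apply(desc$X, 2, sd)
  sig <- c(comfa_steric = 2, comsia_steric = 0)[desc$columns$field_type]
  expect_identical(unname(desc$mask), unname(!(sds < sig)))
  expect_true(any(desc$mask))

  # identical molecules: every CoMFA column masked at sigma 2
  twin <- mols[c(1, 1)]; twin[[2]]$id <- "t1b"
  b2 <- compute_fields(twin, "comfa_steric", grid = g)
  d2 <- build_descriptor_matrix(b2, c(comfa_steric = 2))
  expect_false(any(d2$mask))
  # sigma 0 masks nothing
  d0 <- build_descriptor_matrix(b2, c(comfa_steric = 0))
  expect_true(all(d0$mask))

  # inconsistent grids are rejected
  b3 <- compute_fields(mols[1:2], "comfa_steric",
                       grid = grid_spec(c(-4, -4, -4), 2, c(4, 4, 4)))
  expect_error(build_descriptor_matrix(c(b2, b3[1])), "share")

  # TSV + JSON sidecar export round-trips the matrix and mask
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_descriptors(desc, tsv)
  back <- read.delim(tsv, check.names = FALSE)
  expect_equal(back$molecule_id, rownames(desc$X))
  expect_equal(unname(as.matrix(back[, -1])), unname(desc$X),
               tolerance = 1e-9)
  side <- jsonlite::read_json(paste0(tsv, ".json"), simplifyVector = TRUE)
  expect_equal(side$mask, unname(desc$mask))
})
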