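toy_xy <- function(n = 12, p = 4, seed = 3, noise = 0.3) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  y <- as.vector(X %*% seq_len(p)) + rnorm(n, sd = noise)
  list(X = X, y = y)
}

test_that("a noiseless single-column response is recovered exactly", {
  set.seed(1)
  X <- matrix(rnorm(40), 10, 4)
  y <- 2 * X[, 3] + 1
  # column 3 is the only active column; one component suffices exactly
  desc <- toy_desc(X, mask = c(FALSE, FALSE, TRUE, FALSE))
  fit <- fit_pls(desc, y, n_components = 1)
  expect_equal(fit$stats$r2, 1, tolerance = 1e-10)
  expect_lt(fit$stats$see, 1e-8)
  expect_equal(unname(predict(fit, desc)), fit$fitted, tolerance = 1e-12)
})

test_that("full-rank PLS coincides with the least-squares oracle", {
  t <- toy_xy()
  fit <- fit_pls(toy_desc(t$X), t$y, n_components = ncol(t$X))
  expect_equal(fit$fitted, ols_predictions(t$X, t$y), tolerance = 1e-8)
})

test_that("ill-posed fits are rejected", {
  t <- toy_xy(n = 5, p = 3)
  expect_error(fit_pls(toy_desc(t$X), t$y, n_components = 10), "exceeds")
  expect_error(fit_pls(toy_desc(t$X), rep(1, 5), 1), "zero variance")
  expect_error(fit_pls(toy_desc(t$X), t$y[1:3], 1), "length")
})

test_that("leave-one-out equals the brute-force loop exactly", {
  t <- toy_xy(n = 10, p = 5, seed = 9)
  desc <- toy_desc(t$X)
  res <- loo_q2(desc, t$y, n_components = 2)
  # oracle: ten independent fit/predict calls assembled by hand
  preds <- vapply(1:10, function(i) {
    di <- desc; di$X <- desc$X[-i, , drop = FALSE]
    fit <- fit_pls(di, t$y[-i], 2)
    unname(predict(fit, desc$X[i, , drop = FALSE]))
  }, numeric(1))
  q2_oracle <- 1 - sum((t$y - preds)^2) / sum((t$y - mean(t$y))^2)
  expect_equal(res$q2, q2_oracle, tolerance = 1e-10)
  expect_equal(unname(res$predictions), preds, tolerance = 1e-10)
  expect_error(loo_q2(toy_desc(t$X[1:2, , drop = FALSE]), t$y[1:2], 1),
               "at least 3")
})

test_that("a noiseless linear response yields q2 near 1", {
  set.seed(5)
  X <- matrix(rnorm(200), 20, 10)
  y <- as.vector(X %*% c(3, -1, rep(0, 8)))
  expect_gt(loo_q2(toy_desc(X), y, ncol(X))$q2, 0.99)
})

test_that("scrambled activities destroy q2 (permutation null)", {
  t <- toy_xy(n = 14, p = 6, seed = 21, noise = 0.2)
  desc <- toy_desc(t$X)
  set.seed(77)
  q2s <- vapply(1:20, function(k)
    loo_q2(desc, sample(t$y), 2)$q2, numeric(1))
  expect_lte(mean(q2s), 0.2)
})

test_that("component selection is an exhaustive argmax with ties to fewer", {
  t <- toy_xy(n = 12, p = 5, seed = 4)
  desc <- toy_desc(t$X)
  sel <- select_components(desc, t$y, max_components = 6)
  # trace covers every admissible count and the optimum is its argmax
  expect_equal(as.integer(names(sel$q2_trace)),
               seq_len(min(6, nrow(t$X) - 2, 5)))
  brute <- vapply(seq_along(sel$q2_trace), function(a)
    loo_q2(desc, t$y, a)$q2, numeric(1))
  expect_equal(unname(sel$q2_trace), brute, tolerance = 1e-12)
  expect_equal(sel$n_components, min(which(brute == max(brute))))
})

test_that("field contributions normalize, symmetrize and recompute by hand", {
  t <- toy_xy(n = 12, p = 6, seed = 8)
  # one field type only
  fit1 <- fit_pls(toy_desc(t$X), t$y, 2)
  expect_equal(unname(fit1$stats$contributions), 1)
  expect_named(fit1$stats$contributions, "comsia_steric")
  # duplicated blocks share the signal evenly
  Xd <- cbind(t$X, t$X)
  ft <- rep(c("comsia_steric", "comsia_hbd"), each = ncol(t$X))
  fit2 <- fit_pls(toy_desc(Xd, field_type = ft), t$y, 2)
  expect_equal(unname(fit2$stats$contributions), c(0.5, 0.5),
               tolerance = 1e-10)
  # hand recomputation of |coef * sd| per block
  w <- abs(fit2$coefficients * fit2$col_sd)
  hand <- c(sum(w[1:6]), sum(w[7:12])) / sum(w)
  expect_equal(unname(fit2$stats$contributions),
               unname(hand[order(match(c("comsia_steric", "comsia_hbd"),
                                       mifqsar:::FIELD_TYPES))]),
               tolerance = 1e-12)
  expect_true(all(fit2$stats$contributions >= 0))
  expect_equal(sum(fit2$stats$contributions), 1, tolerance = 1e-6)
})

test_that("prediction is the documented linear map", {
  t <- toy_xy()
  desc <- toy_desc(t$X)
  fit <- fit_pls(desc, t$y, 2)
  # training rows reproduce stored fitted values
  expect_equal(unname(predict(fit, desc)), fit$fitted, tolerance = 1e-10)
  # a row at the column means predicts the training mean
  expect_equal(unname(predict(fit, matrix(fit$col_center, 1))),
               mean(t$y), tolerance = 1e-10)
  # independent matrix arithmetic
  Xs <- sweep(sweep(t$X, 2, fit$col_center), 2, fit$col_scale, `*`)
  expect_equal(unname(predict(fit, t$X)),
               as.vector(Xs %*% fit$coefficients) + fit$y_mean,
               tolerance = 1e-12)
  expect_error(predict(fit, t$X[, 1:2]), "columns")
})

test_that("stored SEE and F agree with recomputation from residuals", {
  t <- toy_xy()
  fit <- fit_pls(toy_desc(t$X), t$y, 3)
  n <- length(t$y); cc <- fit$n_components
  rss <- sum(fit$residuals^2)
  r2 <- 1 - rss / sum((t$y - mean(t$y))^2)
  expect_equal(fit$stats$see, sqrt(rss / (n - cc - 1)), tolerance = 1e-12)
  expect_equal(fit$stats$f, (r2 / cc) / ((1 - r2) / (n - cc - 1)),
               tolerance = 1e-12)
})

test_that("models survive a JSON round-trip", {
  t <- toy_xy()
  fit <- fit_pls(toy_desc(t$X), t$y, 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_model(fit, path)
  back <- read_model(path)
  expect_equal(back$coefficients, fit$coefficients, tolerance = 1e-12)
  expect_equal(unname(predict(back, t$X)), unname(predict(fit, t$X)),
               tolerance = 1e-12)
  expect_equal(back$stats$r2, fit$stats$r2, tolerance = 1e-12)
})

test_that("synthetic-series recovery finds the generating steric signal", {
  pipe <- sim_pipeline()
  expect_gte(pipe$model$stats$q2, 0.8)
  contrib <- pipe$model$stats$contributions
  expect_equal(names(which.max(contrib)), "comsia_steric")
})
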