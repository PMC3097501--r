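test_that("descriptor table CSV round trip is bit-identical", {
  m <- rand_table(7, 3, seed = 11)
  tab <- descriptor_table(m)
  path <- withr::local_tempfile(fileext = ".csv")
  write_descriptor_table(tab, path)
  back <- load_descriptor_table(path)
  expect_identical(dim(descriptor_values(back)), dim(m))
  expect_identical(descriptor_values(back), descriptor_values(tab))
  expect_identical(compound_ids(back), compound_ids(tab))
})

test_that("loading rejects malformed input", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("compound,A,A", "1,0.5,0.2", "2,0.1,0.3"), path)
  expect_error(load_descriptor_table(path), "duplicate descriptor")

  writeLines(c("compound,A,B", "1,0.5,x", "2,0.1,0.3"), path)
  expect_error(load_descriptor_table(path), "non-numeric.*B.*row 1")

  writeLines(c("compound,A,B", "1,0.5,0.2", "1,0.1,0.3"), path)
  expect_error(load_descriptor_table(path), "duplicate compound")

  writeLines(c("compound,A,B", "1,0.5,", "2,0.1,0.3"), path)
  expect_error(load_descriptor_table(path), "missing value")
})

test_that("variance filter keeps exactly the descriptors at or above threshold", {
  m <- rand_table(100, 20, seed = 3)
  # three near-constant columns with population variance below 1e-4
  for (j in c(4L, 9L, 17L)) m[, j] <- mean(m[, j]) + 1e-3 * scale(m[, j])[, 1]
  filtered <- variance_filter(m, threshold = 1e-4)
  pv <- colSums((t(t(m) - colMeans(m)))^2) / nrow(m)   # independent oracle
  expect_identical(descriptor_names(filtered), names(pv)[pv >= 1e-4])
  expect_identical(ncol(descriptor_values(filtered)), 17L)
  expect_setequal(attr(filtered, "dropped"), paste0("D", c(4, 9, 17)))

  # threshold 0 keeps everything, constant column always removed
  expect_identical(ncol(descriptor_values(variance_filter(m, 0))), 20L)
  m[, 1] <- 5
  expect_false("D1" %in% descriptor_names(variance_filter(m)))
  expect_error(variance_filter(matrix(1, 5, 2)), "no informative")
})

test_that("standardization is exact and invertible", {
  tab <- descriptor_table(cbind(A = c(1, 2, 3), B = c(10, 30, 20)))
  sc <- standardize(tab)
  z <- descriptor_values(sc$table)
  expect_equal(unname(colMeans(z)), c(0, 0), tolerance = 1e-14)
  expect_equal(unname(apply(z, 2, sd)), c(1, 1), tolerance = 1e-14)
  # stored parameters reproduce the standardized table and invert it
  expect_equal(descriptor_values(apply_standardization(sc, tab)), z)
  expect_equal(descriptor_values(unstandardize(sc, sc$table)),
               descriptor_values(tab), tolerance = 1e-12)
  expect_error(standardize(cbind(A = c(1, 1, 1), B = c(1, 2, 3))),
               "zero-variance")
})

test_that("intercorrelation matrix matches a two-pass Pearson oracle", {
  m <- rand_table(50, 4, seed = 21)
  r <- intercorrelation_matrix(m)
  # independent two-pass formula
  oracle <- matrix(1, 4, 4)
  for (i in 1:4) for (j in 1:4) {
    xi <- m[, i] - mean(m[, i]); xj <- m[, j] - mean(m[, j])
    oracle[i, j] <- sum(xi * xj) / sqrt(sum(xi^2) * sum(xj^2))
  }
  expect_equal(unname(r), oracle, tolerance = 1e-12)
  expect_identical(r, t(r))
  expect_true(all(diag(r) == 1))
  expect_true(min(eigen(r, symmetric = TRUE, only.values = TRUE)$values) > -1e-10)

  # duplicated / negated columns; constant column flagged not NaN-propagated
  dup <- cbind(A = m[, 1], B = m[, 1], C = -m[, 1], K = rep(2, 50))
  rd <- intercorrelation_matrix(dup)
  expect_equal(rd["A", "B"], 1)
  expect_equal(rd["A", "C"], -1)
  expect_true(all(is.na(rd["K", c("A", "B", "C")])))
  expect_identical(attr(rd, "undefined"), "K")
  expect_equal(rd["A", "B"], 1)  # unaffected by the constant column
})

test_that("packaged phenol fixtures satisfy their structural invariants", {
  ps <- phenol_sets()
  expect_identical(nrow(ps$act), 33L)
  expect_identical(sum(ps$act$test_set), 8L)
  expect_identical(ps$act$compound[ps$act$test_set],
                   as.character(c(4, 5, 11, 13, 20, 21, 23, 24)))

  des <- designed_predictions()
  expect_identical(dim(des), c(15L, 13L))
  model_cols <- setdiff(names(des), c("compound", "APA"))
  expect_length(model_cols, 11L)
  # printed consensus column equals the mean of the 11 model predictions
  expect_equal(rowMeans(des[model_cols]), des$APA, tolerance = 6e-4)

  pm <- published_models()
  expect_named(pm, c("eq7", "eq8", "eq9", "eq10"))
  expect_length(pm$eq7$terms, 6L)
  knots <- vapply(pm$eq10$terms, function(t)
    if (is.null(t$knot)) NA_real_ else t$knot, numeric(1))
  expect_true(all(c(6.68154, 1.98556) %in% knots))
})

test_that("model JSON serialization round-trips a fitted equation", {
  m <- rand_table(30, 4, seed = 5)
  y <- 1 + 2 * m[, 1] + rnorm(30, sd = 0.1)
  fit <- ols_fit(list(model_term("D1"),
                      model_term("D2", "spline_below", knot = 0.25)), m, y)
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(fit, path)
  back <- read_model_json(path)
  expect_equal(back$intercept, fit$intercept)
  expect_equal(predict(back, m), predict(fit, m), tolerance = 1e-12)
  expect_equal(back$terms[[2]]$knot, 0.25)
})
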