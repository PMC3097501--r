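test_that("basis terms evaluate the truncated-power-spline algebra", {
  below <- model_term("S_sCH3", "spline_below", knot = 1.79401)
  expect_equal(eval_term(below, 0), 1.79401)     # <a - x> with x below the knot
  expect_equal(eval_term(below, 2.5), 0)         # negative argument clamps to 0
  expect_equal(eval_term(model_term("x", "square"), -3), 9)
  expect_equal(eval_term(model_term("x", "linear"), -3), -3)
  above <- model_term("x", "spline_above", knot = 2)
  expect_equal(eval_term(above, c(1, 2, 5)), c(0, 0, 3))
  expect_true(all(eval_term(below, rnorm(100, 1.8, 2)) >= 0))
  expect_error(model_term("x", "spline_below"), "knot")
  expect_error(model_term("x", "linear", knot = 1), "knot")
})

test_that("published G/PLS equation predicts by hand-checkable arithmetic", {
  eq10 <- published_models()$eq10
  row <- matrix(c(7, 10, 2.5, 5), 1,
                dimnames = list("probe", c("Chi1", "Chi3_p", "S_sCH3", "S_aasC")))
  # both spline terms clamp to zero: 1.158 + 1.08 + 1.44
  expect_equal(unname(predict(eq10, row)), 3.678, tolerance = 1e-12)
  expect_error(predict(eq10, row[, 1:2, drop = FALSE]), "S_sCH3")
})

test_that("prediction reproduces a noise-free generating model exactly", {
  dat <- generate_qsar_data(40, synthetic_truth(sigma = 0), seed = 6)
  pred <- predict(truth_model(dat$truth), dat$table)
  expect_equal(pred, as_vec <- stats::setNames(as.numeric(dat$activity),
                                               names(dat$activity)),
               tolerance = 1e-12)
  # a model with zero coefficients predicts its intercept everywhere
  flat <- spline_model(2.5, list(model_term("ES1", coefficient = 0)))
  expect_equal(unname(predict(flat, dat$table)), rep(2.5, 40))
})

test_that("OLS fit matches the normal-equations oracle and its stated statistics", {
  m <- rand_table(25, 4, seed = 17)
  set.seed(18)
  y <- 0.5 + m %*% c(1, -2, 0.5, 0) + rnorm(25, sd = 0.4)
  fit <- ols_fit(colnames(m), m, drop(y))
  # independent normal-equations solution
  X <- cbind(1, m)
  beta_oracle <- solve(crossprod(X), crossprod(X, y))
  beta_fit <- c(fit$intercept, vapply(fit$terms, `[[`, numeric(1), "coefficient"))
  expect_equal(beta_fit, drop(beta_oracle), tolerance = 1e-10,
               ignore_attr = TRUE)
  # statistics agree with their definitions
  n <- 25; p <- 4
  expect_equal(fit$stats$Ra2, adj_r2(fit$stats$R2, n, p), tolerance = 1e-12)
  expect_lte(fit$stats$Ra2, fit$stats$R2)
  expect_equal(fit$stats$F,
               (fit$stats$R2 / p) / ((1 - fit$stats$R2) / (n - p - 1)),
               tolerance = 1e-12)
  # exact fit: R2 = 1, s = 0
  ex <- ols_fit("D1", m, 3 + 2 * m[, 1])
  expect_equal(ex$stats$R2, 1, tolerance = 1e-12)
  expect_lt(ex$stats$s, 1e-10)
  # rank deficiency is reported with the offending term
  expect_error(ols_fit(c("D1", "D2", "D5"), cbind(m, D5 = m[, 1]), drop(y)),
               "collinear")
})

test_that("adjusted R2 closed form reproduces the printed training statistics", {
  # the four-descriptor 25-compound equation rounds R2 to 0.889 and prints 0.867
  expect_equal(adj_r2(0.889, 25, 4), 0.867, tolerance = 0.001)
  expect_error(adj_r2(0.9, 5, 4), "n > p")
})

test_that("RSS is non-increasing for nested OLS fits", {
  m <- rand_table(40, 5, seed = 23)
  set.seed(24)
  y <- m[, 1] - m[, 2] + rnorm(40, sd = 0.5)
  rss <- vapply(1:5, function(p) ols_fit(colnames(m)[1:p], m, y)$stats$RSS,
                numeric(1))
  expect_true(all(diff(rss) <= 1e-10))
})

test_that("stepwise regression selects the generating descriptor in a 20-seed majority", {
  exact <- logical(20)
  truth <- synthetic_truth(n_count = 0, n_estate = 11, n_pairs = 0, sigma = 0.1,
                           terms = list(model_term("ES1", coefficient = 2)))
  for (s in 1:20) {
    d <- generate_qsar_data(50, truth, seed = s)
    f <- stepwise_mlr(d$table, d$activity)
    exact[s] <- setequal(model_support(f), "ES1")
  }
  expect_gt(sum(exact), 10)
})

test_that("stepwise honours the F-to-enter threshold", {
  # independent noise: every candidate's partial F sits below 4 (verified
  # below), so nothing may enter and the intercept-only model is returned
  set.seed(31)
  X <- matrix(rnorm(120), 40, 3, dimnames = list(NULL, c("A", "B", "C")))
  y <- rnorm(40)
  single_f <- vapply(colnames(X), function(d)
    (summary(lm(y ~ X[, d]))$coefficients[2, "t value"])^2, numeric(1))
  expect_lt(max(single_f), 4)
  expect_warning(fit <- stepwise_mlr(X, y), "intercept-only")
  expect_length(fit$terms, 0)
  expect_equal(unname(predict(fit, X)), rep(mean(y), 40))
})

test_that("an entered variable is removed once later entries make it redundant", {
  # collinear triple: x1 = x2 + x3 + noise predicts best alone, but becomes
  # redundant after x2 and x3 both enter
  set.seed(42)
  n <- 50
  x2 <- rnorm(n); x3 <- rnorm(n)
  x1 <- x2 + x3 + rnorm(n, sd = 0.5)
  y <- x2 + x3 + rnorm(n, sd = 0.05)
  X <- cbind(x1 = x1, x2 = x2, x3 = x3)
  # confirm x1 really is the first entry (largest single-descriptor F)
  single_f <- vapply(colnames(X), function(d)
    (summary(lm(y ~ X[, d]))$coefficients[2, "t value"])^2, numeric(1))
  expect_identical(names(which.max(single_f)), "x1")
  fit <- stepwise_mlr(X, y)
  expect_setequal(model_support(fit), c("x2", "x3"))
})

test_that("stepwise selection is invariant to descriptor column order", {
  truth <- synthetic_truth(sigma = 0.2)
  d <- generate_qsar_data(50, truth, seed = 77)
  m <- descriptor_values(d$table)
  f1 <- stepwise_mlr(m, d$activity)
  f2 <- stepwise_mlr(m[, rev(colnames(m))], d$activity)
  expect_setequal(model_support(f1), model_support(f2))
})

test_that("consensus prediction is the arithmetic mean and order-invariant", {
  des <- designed_predictions()
  model_cols <- setdiff(names(des), c("compound", "APA"))
  n1 <- unlist(des[des$compound == "N1", model_cols])
  expect_equal(unname(consensus_predict(t(n1))), 5.113, tolerance = 0.001)
  # single model: identity; permutation invariance in model order
  expect_equal(unname(consensus_predict(matrix(n1[1:3], 3, 1))),
               unname(n1[1:3]))
  perm <- sample(length(n1))
  expect_equal(consensus_predict(t(n1)), consensus_predict(t(n1[perm])))
  expect_error(consensus_predict(matrix(numeric(0), 3, 0)), "at least one")
})

test_that("consensus over spline models equals the mean of their predictions", {
  m <- rand_table(10, 3, seed = 41)
  mods <- list(spline_model(1, list(model_term("D1", coefficient = 2))),
               spline_model(-1, list(model_term("D2", coefficient = 1))))
  cp <- consensus_predict(mods, m)
  expect_equal(cp, (predict(mods[[1]], m) + predict(mods[[2]], m)) / 2,
               tolerance = 1e-12)
})
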