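test_that("PRESS over the phenol training compounds matches the printed values", {
  ps <- phenol_sets()
  expect_equal(press(ps$act$pIC50, ps$act$pIC50), 0)
  expect_equal(press(ps$act$pIC50[ps$train], ps$act$pred_gfa[ps$train]),
               4.557, tolerance = 0.01)
  expect_equal(press(ps$act$pIC50[ps$train], ps$act$pred_gpls[ps$train]),
               3.022, tolerance = 0.01)
  expect_error(press(1:3, 1:2), "mismatch")
})

test_that("Q2 matches its definition and the printed LOO statistics", {
  ps <- phenol_sets()
  obs <- ps$act$pIC50[ps$train]
  expect_equal(q2(obs, obs), 1)
  expect_equal(q2(obs, rep(mean(obs), length(obs))), 0)
  expect_equal(q2(obs, ps$act$pred_gpls[ps$train], ps$ym), 0.877,
               tolerance = 0.005)
  expect_equal(q2(obs, ps$act$pred_gfa[ps$train], ps$ym), 0.814,
               tolerance = 0.005)
  expect_error(q2(rep(1, 5), rnorm(5)), "constant")
})

test_that("Q2 identity: 1 - PRESS/SSY to 1e-12", {
  for (s in 1:20) {
    set.seed(s)
    obs <- rnorm(20); prd <- obs + rnorm(20, sd = 0.5)
    expect_equal(q2(obs, prd),
                 1 - press(obs, prd) / sum((obs - mean(obs))^2),
                 tolerance = 1e-12)
  }
})

test_that("predictive R2 on the external test compounds matches the printed values", {
  ps <- phenol_sets()
  obs_te <- ps$act$pIC50[ps$test]
  expect_equal(r2_pred(obs_te, ps$act$pred_gpls[ps$test], ps$ym), 0.884,
               tolerance = 0.005)
  expect_equal(r2_pred(obs_te, ps$act$pred_gfa[ps$test], ps$ym), 0.917,
               tolerance = 0.005)
  expect_equal(r2_pred(obs_te, rep(ps$ym, length(obs_te)), ps$ym), 0)
})

test_that("rm2 through-origin computation reproduces the printed metrics", {
  ps <- phenol_sets()
  obs_te <- ps$act$pIC50[ps$test]
  prd_te <- ps$act$pred_gpls[ps$test]
  out <- rm2(obs_te, prd_te)
  expect_equal(out$r2, 0.889, tolerance = 0.005)
  expect_equal(out$r0_2, 0.881, tolerance = 0.005)
  expect_equal(out$rm2, 0.812, tolerance = 0.01)
  expect_equal(rm2_overall(ps$act$pIC50, ps$act$pred_gpls), 0.872,
               tolerance = 0.01)
  expect_equal(rm2(ps$act$pIC50[ps$train], ps$act$pred_gpls[ps$train])$rm2,
               0.870, tolerance = 0.01)
  # perfect prediction: all three equal one
  out1 <- rm2(obs_te, obs_te)
  expect_equal(unlist(out1), c(r2 = 1, r0_2 = 1, rm2 = 1))
  # a constant shift keeps r2 = 1 but is penalized through r0_2
  sh <- rm2(obs_te, obs_te + 0.8)
  expect_equal(sh$r2, 1, tolerance = 1e-12)
  expect_lt(sh$rm2, 1)
  # pooling order does not matter
  perm <- c(5:8, 1:4)
  expect_equal(rm2_overall(obs_te[perm], prd_te[perm]),
               rm2_overall(obs_te, prd_te), tolerance = 1e-14)
  # the sqrt-free legacy variant is exposed but differs
  expect_gt(rm2(obs_te, prd_te, legacy_no_sqrt = TRUE)$rm2, out$rm2)
})

test_that("r0_2 never exceeds r2 and rm2 never exceeds r2 on random instances", {
  set.seed(99)
  for (i in 1:1000) {
    n <- sample(5:30, 1)
    obs <- rnorm(n, mean = runif(1, -2, 4))
    prd <- obs * runif(1, 0.3, 1.5) + rnorm(n, sd = runif(1, 0.05, 1))
    out <- rm2(obs, prd)
    expect_lte(out$r0_2, out$r2 + 1e-12)
    expect_lte(out$rm2, out$r2 + 1e-12)
  }
})

test_that("hat-matrix LOO equals naive refit LOO", {
  m <- rand_table(25, 4, seed = 55)
  set.seed(56)
  y <- 0.5 + m %*% c(1, -1, 0, 0.3) + rnorm(25, sd = 0.4)
  terms <- c("D1", "D2", "D4")
  expect_equal(loo_predict(terms, m, drop(y), method = "hat"),
               loo_predict(terms, m, drop(y), method = "refit"),
               tolerance = 1e-10)
})

test_that("validation_report bundles the metric suite consistently", {
  ps <- phenol_sets()
  rep <- validation_report(ps$act$pIC50[ps$train], ps$act$pred_gpls[ps$train],
                           ps$act$pIC50[ps$test], ps$act$pred_gpls[ps$test])
  expect_equal(rep$q2, 0.877, tolerance = 0.005)
  expect_equal(rep$r2_pred, 0.884, tolerance = 0.005)
  expect_equal(rep$rm2_overall, 0.872, tolerance = 0.01)
  expect_identical(rep$n_train, 25L)
  expect_identical(rep$n_test, 8L)
  expect_gte(rep$press, 0)
  expect_lte(rep$r0_2_test, rep$r2_test)
})

test_that("rigorous LOO rm2 is exact in the noise-free limit", {
  truth <- synthetic_truth(n_count = 2, n_estate = 6, n_pairs = 0, sigma = 0,
                           terms = list(model_term("ES1", coefficient = 2),
                                        model_term("ES2", coefficient = -1)))
  d <- generate_qsar_data(30, truth, seed = 2)
  val <- true_rm2_loo(d$table, d$activity, stepwise_mlr)
  expect_equal(as.numeric(val), 1, tolerance = 1e-6)
})

test_that("rigorous LOO rm2 reduces to plain LOO for a constant selection strategy", {
  d <- generate_qsar_data(30, synthetic_truth(sigma = 0.4), seed = 3)
  fixed <- function(tab, act) ols_fit(c("ES1", "ES2"), tab, act)
  val <- true_rm2_loo(d$table, d$activity, fixed)
  plain <- loo_predict(c("ES1", "ES2"), d$table, d$activity)
  expect_equal(as.numeric(val),
               rm2(as.numeric(d$activity), plain)$rm2, tolerance = 1e-10)
})

test_that("rigorous LOO rm2 stays low for pure-noise activity", {
  low <- logical(20)
  for (s in 1:20) {
    d <- generate_qsar_data(30, synthetic_truth(n_count = 10, n_estate = 10,
                                                n_pairs = 0, sigma = 1),
                            seed = s)
    set.seed(1000 + s)
    ynull <- rnorm(30)
    val <- suppressWarnings(true_rm2_loo(
      d$table, ynull, function(tb, yy) suppressWarnings(stepwise_mlr(tb, yy))))
    low[s] <- val < 0.5
  }
  expect_gte(sum(low), 18)
})

test_that("randomization statistics reproduce the published closed-form values", {
  expect_equal(crp2(R = 0.943, Rr2 = 0.282, R2 = 0.889), 0.735,
               tolerance = 0.002)
  expect_equal(crp2(R = 0.952, Rr2 = 0.014, R2 = 0.906), 0.899,
               tolerance = 0.002)
  # every published randomization row is reproduced at once
  rnd <- randomization_summary()
  expect_equal(mapply(crp2, R = rnd$R, Rr2 = rnd$Rr2, R2 = rnd$R2),
               rnd$cRp2, tolerance = 0.002, ignore_attr = TRUE)
  # no-information limit
  expect_equal(crp2(R = 0.9, Rr2 = 0.81, R2 = 0.81), 0)
})

test_that("Y-scrambling of a fixed model matches its null expectation", {
  m <- rand_table(30, 8, seed = 77)
  set.seed(78)
  y <- m %*% c(1, 1, 0, 0, 0, 0, 0, 0) + rnorm(30, sd = 2)
  fitter <- function(tab, act) ols_fit(c("D1", "D2", "D3"), tab, act)
  rep <- randomize(m, drop(y), fitter, mode = "model", n_permutations = 500,
                   seed = 42)
  # mean scrambled R2 of a p-descriptor model is p/(n-1) under the null;
  # 0.02 is five Monte-Carlo standard errors at 500 permutations
  expect_lt(abs(rep$Rr2 - 3 / 29), 0.02)
  expect_identical(rep$n_permutations, 500L)
  expect_equal(rep$cRp2, crp2(rep$R, rep$Rr2, rep$R2), tolerance = 1e-12)
  # determinism and defaults
  rep2 <- randomize(m, drop(y), fitter, mode = "model", n_permutations = 500,
                    seed = 42)
  expect_identical(rep$r2_perm, rep2$r2_perm)
  expect_identical(randomize(m, drop(y), fitter, "process")$n_permutations, 9L)
  expect_identical(randomize(m, drop(y), fitter, "model")$n_permutations, 99L)
})

test_that("process randomization reruns selection and reports a robust model", {
  truth <- synthetic_truth(n_count = 4, n_estate = 6, n_pairs = 0, sigma = 0.3,
                           terms = list(model_term("ES1", coefficient = 2)))
  d <- generate_qsar_data(40, truth, seed = 5)
  rep <- randomize(d$table, d$activity,
                   function(tb, act) suppressWarnings(stepwise_mlr(tb, act)),
                   mode = "process", seed = 7)
  expect_lt(rep$Rr2, rep$R2)
  expect_gt(rep$cRp2, 0.5)
})

test_that("critical F values match the published table and the median identity", {
  expect_equal(f_critical(0.01, 4, 20), 4.431, tolerance = 0.005)
  expect_equal(f_critical(0.01, 2, 22), 5.719, tolerance = 0.005)
  expect_equal(f_critical(0.5, 7, 7), 1, tolerance = 1e-12)
  expect_error(f_critical(1.2, 3, 3), "upper_tail_prob")
  expect_error(f_critical(0.01, 0, 3), "degrees of freedom")
})
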