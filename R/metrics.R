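#' Predicted residual sum of squares
#'
#' `PRESS = sum((obs - pred)^2)`; with leave-one-out predictions this is the
#' standard internal-validation error sum.
#'
#' @param obs,pred Equal-length numeric vectors.
#' @return The sum of squared prediction residuals.
#' @export
press <- function(obs, pred) {
  if (length(obs) != length(pred)) stop_("length mismatch: %d vs %d",
                                         length(obs), length(pred))
  if (length(obs) < 1L) stop_("need at least one observation")
  sum((as.numeric(obs) - as.numeric(pred))^2)
}

#' Leave-one-out cross-validated Q2
#'
#' `Q2 = 1 - sum((Y_obs - Y_pred)^2) / sum((Y_obs - Ybar_training)^2)` over
#' the training compounds, with `Y_pred` the leave-one-out predictions and
#' `Ybar_training` the fixed mean of the training observations (not
#' per-fold means).  Values above 0.5 are conventionally considered
#' satisfactory.
#'
#' @param obs_train Observed training activities.
#' @param pred_loo Leave-one-out predicted activities.
#' @param training_mean Mean of the training observations (default computed
#'   from `obs_train`).
#' @return The Q2 value.
#' @export
q2 <- function(obs_train, pred_loo, training_mean = mean(obs_train)) {
  obs_train <- as.numeric(obs_train); pred_loo <- as.numeric(pred_loo)
  if (length(obs_train) != length(pred_loo)) stop_("length mismatch")
  denom <- sum((obs_train - training_mean)^2)
  if (denom == 0) stop_("constant activity: Q2 undefined")
  1 - sum((obs_train - pred_loo)^2) / denom
}

#' External predictive R2
#'
#' `R2_pred = 1 - sum((Y_obs(test) - Y_pred(test))^2) /
#' sum((Y_obs(test) - Ybar_training)^2)`, referencing the test-set errors to
#' the training-set mean.  Values above 0.5 indicate efficient prediction
#' for the external compounds.
#'
#' @param obs_test,pred_test Observed and predicted test-set activities.
#' @param training_mean Mean observed activity of the training set (must be
#'   supplied; it is not computable from the test data).
#' @return The predictive R2.
#' @export
r2_pred <- function(obs_test, pred_test, training_mean) {
  obs_test <- as.numeric(obs_test); pred_test <- as.numeric(pred_test)
  if (length(obs_test) != length(pred_test)) stop_("length mismatch")
  denom <- sum((obs_test - training_mean)^2)
  if (denom == 0) stop_("zero denominator in R2_pred")
  1 - sum((obs_test - pred_test)^2) / denom
}

#' The rm2 metric
#'
#' `rm2 = r2 * (1 - sqrt(r2 - r0_2))`, where `r2` is the squared Pearson
#' correlation between observed and predicted activities and `r0_2` is the
#' determination coefficient of the through-origin regression of observed
#' on predicted (`slope k = sum(obs*pred)/sum(pred^2)`,
#' `r0_2 = 1 - sum((obs - k*pred)^2)/sum((obs - mean(obs))^2)`).  The metric
#' penalizes a good correlation whose predictions are systematically offset
#' from the observations; `rm2 = r2` only when the through-origin fit is as
#' good as the free fit.  A variant without the square root appears in some
#' typeset sources but does not reproduce the reference values; it is
#' available behind `legacy_no_sqrt`.
#'
#' @param obs,pred Observed and predicted activities (length >= 3, both
#'   non-constant).
#' @param legacy_no_sqrt If `TRUE`, use `r2 * (1 - (r2 - r0_2))`.
#' @param transpose If `TRUE`, regress predicted on observed through the
#'   origin instead (the non-default orientation convention).
#' @return List with `r2`, `r0_2` and `rm2`.
#' @export
rm2 <- function(obs, pred, legacy_no_sqrt = FALSE, transpose = FALSE) {
  obs <- as.numeric(obs); pred <- as.numeric(pred)
  if (length(obs) != length(pred)) stop_("length mismatch")
  if (length(obs) < 3L) stop_("need at least 3 compounds")
  if (stats::sd(obs) == 0 || stats::sd(pred) == 0) {
    stop_("constant observed or predicted vector")
  }
  if (transpose) { tmp <- obs; obs <- pred; pred <- tmp }
  r2v <- stats::cor(obs, pred)^2
  k <- sum(obs * pred) / sum(pred^2)
  r0 <- 1 - sum((obs - k * pred)^2) / sum((obs - mean(obs))^2)
  if (r2v < r0 - 1e-12) {
    stop_("internal inconsistency: r2 (%.6f) < r0_2 (%.6f)", r2v, r0)
  }
  gap <- max(0, r2v - r0)
  val <- if (legacy_no_sqrt) r2v * (1 - gap) else r2v * (1 - sqrt(gap))
  list(r2 = r2v, r0_2 = r0, rm2 = val)
}

#' Overall rm2 on pooled training and test predictions
#'
#' Applies [rm2()] to the pooled vectors of LOO-predicted training
#' activities and predicted test activities, so a single metric summarizes
#' proximity of prediction to observation across the whole dataset.
#'
#' @param obs_all,pred_all Pooled observed and predicted activities.
#' @inheritParams rm2
#' @return The pooled `rm2` value.
#' @export
rm2_overall <- function(obs_all, pred_all, legacy_no_sqrt = FALSE) {
  rm2(obs_all, pred_all, legacy_no_sqrt = legacy_no_sqrt)$rm2
}

#' Full internal/external validation report
#'
#' @param obs_train,pred_loo Training observations and their LOO predictions.
#' @param obs_test,pred_test Optional external test observations/predictions.
#' @return A list of class `validation_report`: `press`, `q2`, `rm2_loo`
#'   (with its `r2`/`r0_2`), and when test data are given `press_test`,
#'   `r2_pred`, `rm2_test`, `rm2_overall`, plus `training_mean`, `n_train`,
#'   `n_test`.
#' @export
validation_report <- function(obs_train, pred_loo,
                              obs_test = NULL, pred_test = NULL) {
  ym <- mean(as.numeric(obs_train))
  tr <- rm2(obs_train, pred_loo)
  out <- list(training_mean = ym, n_train = length(obs_train),
              press = press(obs_train, pred_loo),
              q2 = q2(obs_train, pred_loo, ym),
              r2_loo = tr$r2, r0_2_loo = tr$r0_2, rm2_loo = tr$rm2)
  if (!is.null(obs_test)) {
    te <- rm2(obs_test, pred_test)
    out$n_test <- length(obs_test)
    out$press_test <- press(obs_test, pred_test)
    out$r2_pred <- r2_pred(obs_test, pred_test, ym)
    out$r2_test <- te$r2; out$r0_2_test <- te$r0_2; out$rm2_test <- te$rm2
    out$rm2_overall <- rm2_overall(c(obs_train, obs_test),
                                   c(pred_loo, pred_test))
  }
  structure(out, class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report: n_train=%d%s>\n", x$n_train,
              if (!is.null(x$n_test)) sprintf(", n_test=%d", x$n_test) else ""))
  cat(sprintf("  Q2 = %.3f, PRESS = %.3f, rm2(LOO) = %.3f\n",
              x$q2, x$press, x$rm2_loo))
  if (!is.null(x$r2_pred)) {
    cat(sprintf("  R2_pred = %.3f, rm2(test) = %.3f, rm2(overall) = %.3f\n",
                x$r2_pred, x$rm2_test, x$rm2_overall))
  }
  invisible(x)
}

#' Model R2 accessor
#'
#' @param model A fitted model (`spline_model`, `pls_model`, `gpls_model`)
#'   or a bare numeric R2 value.
#' @return The determination coefficient of the fit.
#' @export
model_r2 <- function(model) UseMethod("model_r2")

#' @export
model_r2.spline_model <- function(model) model$stats$R2

#' @export
model_r2.pls_model <- function(model) model$stats$R2

#' @export
model_r2.gpls_model <- function(model) model$pls$stats$R2

#' @export
model_r2.numeric <- function(model) as.numeric(model)

#' Rigorous leave-one-out rm2 with repeated variable selection
#'
#' Each compound is deleted once, the full variable-selection strategy is
#' re-run on the remaining compounds, the refitted model predicts the
#' deleted compound, and [rm2()] is evaluated on the pooled out-of-sample
#' predictions.  Because selection is repeated inside every fold, this
#' measures the predictive ability of the whole model-building process, not
#' of one fixed equation — the honest variant of the LOO rm2 for small
#' datasets where a train/test split would discard too much information.
#'
#' @param table Descriptor data.
#' @param activity Observed activity.
#' @param selection_strategy Function `(table, activity) -> model` running
#'   variable selection plus fitting (e.g. [stepwise_mlr()], or a wrapper
#'   around [gfa_search()]); the returned model must have a `predict` method.
#' @return The pooled `rm2` value, with the per-compound predictions in
#'   attribute `"predictions"`.
#' @export
true_rm2_loo <- function(table, activity, selection_strategy) {
  m <- as_descriptor_matrix(table)
  y <- as_activity_vector(activity, table)
  n <- nrow(m)
  pred <- numeric(n)
  for (i in seq_len(n)) {
    fit <- selection_strategy(m[-i, , drop = FALSE], y[-i])
    if (length(fit$terms) == 0L) {
      warn_("fold %d produced an intercept-only model; fold retained", i)
    }
    pred[i] <- predict(fit, m[i, , drop = FALSE])
  }
  out <- rm2(y, pred)$rm2
  attr(out, "predictions") <- stats::setNames(pred, rownames(m))
  out
}

#' Y-randomization (Y-scrambling) robustness test
#'
#' The activity column is permuted while the descriptor matrix is left
#' unchanged, a model is rebuilt on each scrambled dataset, and the mean
#' scrambled determination coefficient `Rr2` is compared with the true
#' model's `R2` through the penalized statistics
#' `Rp2 = R2 * sqrt(R2 - Rr2)` and the Todeschini-corrected
#' `cRp2 = R * sqrt(R2 - Rr2)` (values above 0.5 indicate the model is not
#' a chance correlation; both are clamped to 0 and flagged if `Rr2 > R2`).
#' In process randomization the fitter re-runs variable selection on the
#' full descriptor pool each time (conventionally 9 permutations, the 90%
#' confidence level); in model randomization the fixed term set of the
#' final model is refitted (99 permutations, 99%).
#'
#' @param table Descriptor data.
#' @param activity Observed activity.
#' @param fitter Function `(table, activity) -> model` (or numeric R2).  For
#'   `mode = "process"` pass the full selection+fit procedure; for
#'   `mode = "model"` pass a fixed-term refit.
#' @param mode `"process"` or `"model"`.
#' @param n_permutations Number of permutations; defaults to 9 (process) or
#'   99 (model), the `1/(n+1)` convention for the two confidence levels.
#' @param seed Integer RNG seed for the permutations.
#' @return A list of class `randomization_report`: `mode`,
#'   `n_permutations`, `r2_perm` (per-permutation R2), `Rr2` (their mean),
#'   `R2` and `R` of the unscrambled model, `Rp2`, `cRp2`, `flagged`, `seed`.
#' @export
randomize <- function(table, activity, fitter,
                      mode = c("process", "model"),
                      n_permutations = NULL, seed = 1L) {
  mode <- match.arg(mode)
  if (is.null(n_permutations)) {
    n_permutations <- if (mode == "process") 9L else 99L
  }
  n_permutations <- as.integer(n_permutations)
  if (n_permutations < 1L) stop_("n_permutations must be >= 1")
  m <- as_descriptor_matrix(table)
  y <- as_activity_vector(activity, table)
  r2_true <- model_r2(fitter(m, y))
  yu <- unname(y)  # names must not travel: compound-id alignment would undo the scramble
  r2_perm <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(i) {
      model_r2(fitter(m, sample(yu)))
    }, numeric(1L))
  })
  rr2 <- mean(r2_perm)
  gap <- r2_true - rr2
  flagged <- gap < 0
  rp2 <- if (flagged) 0 else r2_true * sqrt(gap)
  crp2 <- if (flagged) 0 else sqrt(r2_true) * sqrt(gap)
  structure(list(mode = mode, n_permutations = n_permutations,
                 r2_perm = r2_perm, Rr2 = rr2, R2 = r2_true,
                 R = sqrt(r2_true), Rp2 = rp2, cRp2 = crp2,
                 flagged = flagged, seed = seed),
            class = "randomization_report")
}

#' @export
print.randomization_report <- function(x, ...) {
  cat(sprintf("<randomization_report: %s mode, %d permutations>\n",
              x$mode, x$n_permutations))
  cat(sprintf("  R2 = %.3f, Rr2 = %.3f, Rp2 = %.3f, cRp2 = %.3f%s\n",
              x$R2, x$Rr2, x$Rp2, x$cRp2,
              if (x$flagged) "  [Rr2 > R2: clamped]" else ""))
  invisible(x)
}

#' Corrected randomization statistic from summary inputs
#'
#' Closed-form `cRp2 = R * sqrt(R2 - Rr2)` for recomputing published
#' randomization tables from their printed `R` and mean scrambled `Rr2`.
#'
#' @param R Correlation coefficient of the unscrambled model.
#' @param Rr2 Mean squared correlation of the scrambled models.
#' @param R2 Squared correlation of the unscrambled model (default `R^2`).
#' @param legacy_no_sqrt If `TRUE`, use the sqrt-free variant
#'   `R * (R2 - Rr2)`.
#' @return The `cRp2` value (0 when `Rr2 > R2`).
#' @export
crp2 <- function(R, Rr2, R2 = R^2, legacy_no_sqrt = FALSE) {
  gap <- R2 - Rr2
  if (gap < 0) return(0)
  if (legacy_no_sqrt) R * gap else R * sqrt(gap)
}

#' Adjusted determination coefficient
#'
#' `Ra2 = 1 - (1 - R2) * (n - 1) / (n - p - 1)`: penalizes `R2` for the
#' number of fitted descriptors, so adding uninformative terms can lower it.
#'
#' @param r2 Determination coefficient.
#' @param n Number of observations.
#' @param p Number of descriptors (model terms).
#' @return The adjusted R2 (always `<= r2` for `p >= 1`).
#' @export
adj_r2 <- function(r2, n, p) {
  if (n - p - 1 <= 0) stop_("need n > p + 1")
  1 - (1 - r2) * (n - 1) / (n - p - 1)
}

#' Critical value of the F distribution
#'
#' Upper-tail inverse CDF; the tabulated "two-tailed 98% significance"
#' convention corresponds to an upper-tail probability of 0.01.
#'
#' @param upper_tail_prob Upper-tail probability in (0, 1).
#' @param df1,df2 Degrees of freedom.
#' @return The F quantile.
#' @export
f_critical <- function(upper_tail_prob, df1, df2) {
  if (upper_tail_prob <= 0 || upper_tail_prob >= 1) {
    stop_("upper_tail_prob must be in (0, 1)")
  }
  if (df1 < 1 || df2 < 1) stop_("degrees of freedom must be >= 1")
  stats::qf(upper_tail_prob, df1, df2, lower.tail = FALSE)
}
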