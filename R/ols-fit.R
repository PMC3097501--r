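#' Ordinary least squares fit of a term set
#'
#' Fits `pIC50 ~ intercept + basis terms` by least squares and populates the
#' standard QSAR fit statistics: standard error of the estimate `s`,
#' determination coefficient `R2`, adjusted `Ra2 = 1 - (1-R2)(n-1)/(n-p-1)`,
#' the overall `F = (R2/p) / ((1-R2)/(n-p-1))` on `(p, n-p-1)` degrees of
#' freedom, and the leave-one-out `PRESS` and `Q2` (via the hat-matrix
#' shortcut, exactly equal to refitting with each compound deleted).
#'
#' @param terms List of [model_term()] (coefficients are overwritten) or a
#'   character vector of descriptor names (taken as linear terms).
#' @param table Descriptor data.
#' @param activity Observed activity, aligned by compound id where named.
#' @param provenance Optional label stored on the model.
#' @return A `spline_model` whose `stats` also carry `RSS`, `df`, residuals,
#'   fitted and LOO-predicted values, and coefficient t-values.
#' @export
ols_fit <- function(terms, table, activity, provenance = NULL) {
  if (is.character(terms)) terms <- lapply(terms, model_term)
  y <- as_activity_vector(activity, table)
  z <- design_matrix(terms, table)
  n <- nrow(z); p <- ncol(z)
  if (n <= p + 1L) stop_("need n > p + 1 (n=%d, p=%d)", n, p)
  X <- cbind(`(Intercept)` = 1, z)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    drop_idx <- qx$pivot[seq.int(qx$rank + 1L, ncol(X))]
    stop_("rank-deficient design; collinear term(s): %s",
          paste(colnames(X)[drop_idx], collapse = ", "))
  }
  beta <- qr.coef(qx, y)
  fitted <- drop(X %*% beta)
  resid <- y - fitted
  rss <- sum(resid^2)
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - rss / tss
  ra2 <- 1 - (1 - r2) * (n - 1) / (n - p - 1)
  s <- sqrt(rss / (n - p - 1))
  fstat <- (r2 / p) / ((1 - r2) / (n - p - 1))
  # hat-matrix LOO: e_i / (1 - h_ii)
  h <- rowSums(qr.Q(qx)[, seq_len(qx$rank), drop = FALSE]^2)
  loo <- y - resid / (1 - h)
  press <- sum((y - loo)^2)
  q2 <- 1 - press / tss
  XtXinv <- chol2inv(qr.R(qx))
  se <- sqrt(diag(XtXinv)) * s
  tval <- beta / se
  for (j in seq_along(terms)) {
    terms[[j]]$coefficient <- unname(beta[j + 1L])
    terms[[j]]$se <- unname(se[j + 1L])
  }
  spline_model(
    intercept = unname(beta[1L]), terms = terms, n = n,
    stats = list(s = s, R2 = r2, Ra2 = ra2, F = fstat, df = c(p, n - p - 1L),
                 RSS = rss, PRESS = press, Q2 = q2,
                 fitted = fitted, residuals = resid, loo = loo,
                 hat = h, t_values = unname(tval[-1L]),
                 y = y),
    provenance = provenance)
}

#' Leave-one-out predictions for a term set
#'
#' @param terms Term list or descriptor names (see [ols_fit()]).
#' @param table,activity Training data.
#' @param method `"hat"` uses the closed-form hat-matrix shortcut; `"refit"`
#'   re-estimates the model with each compound deleted (identical for OLS,
#'   kept as an independent cross-check path).
#' @return Named numeric vector of LOO-predicted activities.
#' @export
loo_predict <- function(terms, table, activity, method = c("hat", "refit")) {
  method <- match.arg(method)
  if (is.character(terms)) terms <- lapply(terms, model_term)
  if (method == "hat") {
    fit <- ols_fit(terms, table, activity)
    return(stats::setNames(fit$stats$loo, rownames(as_descriptor_matrix(table))))
  }
  m <- as_descriptor_matrix(table)
  y <- as_activity_vector(activity, table)
  out <- numeric(nrow(m))
  for (i in seq_len(nrow(m))) {
    fit <- ols_fit(terms, m[-i, , drop = FALSE], y[-i])
    out[i] <- predict(fit, m[i, , drop = FALSE])
  }
  stats::setNames(out, rownames(m))
}

#' Stepwise multiple linear regression
#'
#' Forward-selection / backward-elimination over linear descriptor terms
#' using the partial-F stepping criterion: the F statistic for entering or
#' removing a variable is the square of its coefficient's t-value in the
#' enlarged (or current) equation.  A candidate enters when its partial F
#' reaches `f_enter`; an included variable is removed when its partial F
#' falls below `f_remove`.  Ties are broken by descriptor column order, so
#' the procedure is deterministic.
#'
#' @param table Descriptor data.
#' @param activity Observed activity.
#' @param f_enter F-to-enter threshold (default 4.0).
#' @param f_remove F-to-remove threshold (default 3.9; must be < `f_enter`).
#' @param max_terms Maximum number of descriptors in the model (default 6).
#' @return A `spline_model` (intercept-only with a warning when no
#'   descriptor passes `f_enter` at the first step).
#' @export
stepwise_mlr <- function(table, activity, f_enter = 4.0, f_remove = 3.9,
                         max_terms = 6L) {
  if (f_remove >= f_enter) stop_("f_remove must be below f_enter")
  m <- as_descriptor_matrix(table)
  y <- as_activity_vector(activity, table)
  if (ncol(m) < 2L) stop_("need at least 2 candidate descriptors")
  selected <- character(0L)
  seen <- character(0L)
  partial_f <- function(vars) {
    fit <- ols_fit(vars, m, y)
    stats::setNames(fit$stats$t_values^2, vars)
  }
  tss <- sum((y - mean(y))^2)
  repeat {
    changed <- FALSE
    # partial F is ill-defined once the fit is numerically exact: stop entering
    if (length(selected)) {
      rss <- ols_fit(selected, m, y)$stats$RSS
      if (rss < 1e-12 * tss) break
    }
    # forward step: best candidate by partial F in the enlarged model
    if (length(selected) < max_terms) {
      cand <- setdiff(colnames(m), selected)
      fvals <- vapply(cand, function(d) {
        ok <- try(partial_f(c(selected, d)), silent = TRUE)
        if (inherits(ok, "try-error")) -Inf else unname(ok[d])
      }, numeric(1L))
      if (length(fvals) && max(fvals) >= f_enter) {
        best <- cand[which.max(fvals)]  # which.max: first max -> column order
        selected <- c(selected, best)
        changed <- TRUE
      }
    }
    # backward steps: drop weakest included variable while below f_remove
    while (length(selected) > 1L) {
      fvals <- partial_f(selected)
      if (min(fvals) < f_remove) {
        selected <- setdiff(selected, names(fvals)[which.min(fvals)])
        changed <- TRUE
      } else break
    }
    key <- paste(sort(selected), collapse = ";")
    if (!changed || key %in% seen) break
    seen <- c(seen, key)
  }
  if (length(selected) == 0L) {
    warn_("no descriptor passed F-to-enter = %g; returning intercept-only model",
          f_enter)
    return(spline_model(mean(y), list(), n = length(y),
                        stats = list(R2 = 0, y = y),
                        provenance = "stepwise_mlr (intercept only)"))
  }
  ols_fit(selected, m, y, provenance = "stepwise_mlr")
}
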