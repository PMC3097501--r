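#' Partial least squares regression (NIPALS, single response)
#'
#' Fits a PLS1 model on autoscaled predictors (mean 0, unit sample SD) and a
#' centered response.  Components are extracted by NIPALS with deflation of
#' X only (for a single response this is equivalent to the y-deflating
#' variant); the inner loop is run to a 1e-10 tolerance with a 500-iteration
#' cap, though for one response it converges in a single pass.  The X
#' residual matrix after all components is retained, together with its
#' pooled residual standard deviation, for distance-to-model
#' ([dmodx()]) diagnostics.
#'
#' @param table Training descriptor data (no zero-variance columns).
#' @param activity Observed activity.
#' @param n_lv Number of latent variables `A <= min(N-1, K)`.
#' @return An object of class `pls_model` with weights `W`, X-loadings `P`,
#'   y-loadings `q`, scores `T` (columns mutually orthogonal), regression
#'   coefficients on the standardized scale, the residual matrix `E`, pooled
#'   residual SD `s0`, centering/scaling parameters and fit statistics.
#' @export
pls_fit <- function(table, activity, n_lv) {
  m <- as_descriptor_matrix(table)
  y <- as_activity_vector(activity, table)
  n <- nrow(m); K <- ncol(m)
  n_lv <- as.integer(n_lv)
  if (n_lv < 1L || n_lv > min(n - 1L, K)) {
    stop_("n_lv must be in [1, min(N-1, K)] = [1, %d], got %d",
          min(n - 1L, K), n_lv)
  }
  sc <- standardize(m)          # errors on zero-variance columns
  X <- descriptor_values(sc$table)
  y_center <- mean(y)
  yc <- y - y_center
  core <- pls_core(X, yc, n_lv)
  W <- core$W; P <- core$P; q <- core$q; Tm <- core$Tm; B <- core$B
  rownames(W) <- rownames(P) <- colnames(m)
  rownames(Tm) <- rownames(m)
  fitted <- drop(X %*% B) + y_center
  resid <- y - fitted
  rss <- sum(resid^2)
  tss_y <- sum(yc^2)
  E <- core$E
  dimnames(E) <- dimnames(X)
  dof <- (n - n_lv - 1) * (K - n_lv)
  s0 <- if (dof > 0) sqrt(sum(E^2) / dof) else NA_real_
  structure(list(W = W, P = P, q = q, scores = Tm, coef_scaled = B,
                 center = sc$center, scale = sc$scale, y_center = y_center,
                 E = E, s0 = s0, n = n, K = K, n_lv = n_lv,
                 stats = list(R2 = 1 - rss / tss_y, RSS = rss, s =
                                sqrt(rss / max(1, n - n_lv - 1)),
                              fitted = fitted, residuals = resid, y = y)),
            class = "pls_model")
}

# Bare NIPALS PLS1 on a pre-scaled X and centered y (no containers, no
# scaling): the shared numerical core of pls_fit and the G/PLS inner LOO.
# For a single response the weight update has its fixed point in one pass,
# but the loop is kept with a 1e-10 tolerance / 500-iteration cap for form.
pls_core <- function(X, yc, n_lv) {
  n <- nrow(X); K <- ncol(X)
  W <- P <- matrix(0, K, n_lv)
  Tm <- matrix(0, n, n_lv)
  q <- numeric(n_lv)
  Xa <- X
  ya <- yc
  tol <- 1e-10
  for (a in seq_len(n_lv)) {
    w <- drop(crossprod(Xa, ya))
    for (iter in seq_len(500L)) {
      nw <- sqrt(sum(w^2))
      if (nw == 0 || !is.finite(nw)) {
        stop("NIPALS breakdown: no remaining X variance", call. = FALSE)
      }
      w_new <- w / nw
      if (sum((w_new - w)^2) < tol^2) { w <- w_new; break }
      w <- w_new
    }
    tt <- drop(Xa %*% w)
    tss <- sum(tt^2)
    if (tss < .Machine$double.eps) {
      stop("degenerate component: zero score variance", call. = FALSE)
    }
    p <- drop(crossprod(Xa, tt)) / tss
    qa <- sum(ya * tt) / tss
    Xa <- Xa - tcrossprod(tt, p)
    ya <- ya - tt * qa
    W[, a] <- w; P[, a] <- p; Tm[, a] <- tt; q[a] <- qa
  }
  B <- drop(W %*% solve(crossprod(P, W), q))
  list(W = W, P = P, q = q, Tm = Tm, B = B, E = Xa)
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model: %d compounds x %d descriptors, %d latent variable(s), R2 = %.4f>\n",
              x$n, x$K, x$n_lv, x$stats$R2))
  invisible(x)
}

# Project new rows: standardized X, scores, X-residuals, predictions.
pls_project <- function(object, newdata) {
  m <- as_descriptor_matrix(newdata)
  nm <- names(object$center)
  missing <- setdiff(nm, colnames(m))
  if (length(missing)) stop_("missing descriptor(s): %s",
                             paste(missing, collapse = ", "))
  X <- sweep(sweep(m[, nm, drop = FALSE], 2L, object$center), 2L,
             object$scale, "/")
  R <- object$W %*% solve(crossprod(object$P, object$W))  # T = X R
  Tn <- X %*% R
  E <- X - Tn %*% t(object$P)
  pred <- drop(X %*% object$coef_scaled) + object$y_center
  list(X = X, scores = Tn, E = E, pred = stats::setNames(pred, rownames(m)))
}

#' Predict activity from a PLS model
#'
#' @param object A `pls_model`.
#' @param newdata Descriptor data sharing the training descriptors.
#' @param ... Unused.
#' @return Named numeric vector of predicted activities.
#' @export
predict.pls_model <- function(object, newdata, ...) {
  pls_project(object, newdata)$pred
}

#' Distance to the model in X-space (DModX) applicability domain
#'
#' For each compound the standard deviation of its X-residuals after the
#' model's `A` latent variables, `s_i = sqrt(sum_k e_ik^2 / (K - A))`, is
#' proportional to its distance from the PLS model plane.  The normalized
#' DModX divides by the pooled training residual SD
#' `s0 = sqrt(SS_E / ((N - A - 1)(K - A)))`; compounds are flagged outside
#' the applicability domain when DModX exceeds the critical value
#' `sqrt(F_crit)`, the upper-`alpha` quantile of the F distribution on
#' `(K - A, (N - A - 1)(K - A))` degrees of freedom.  A ratio of residual
#' variances is F-distributed under the model, hence DModX around 2.5 (an
#' F-value of 6.25) marks the conventional 99% cutoff on typical dimensions.
#'
#' @param model A fitted `pls_model`.
#' @param newdata Optional descriptor data to assess; defaults to the
#'   training compounds (using their stored residuals).
#' @param alpha Upper-tail significance level (default 0.01, i.e. 99%).
#' @return A data.frame of class `ad_report` with columns `compound`,
#'   `dmodx`, `inside`, and attributes `critical`, `alpha`.
#' @export
dmodx <- function(model, newdata = NULL, alpha = 0.01) {
  A <- model$n_lv; K <- model$K; N <- model$n
  if (K <= A) stop_("K must exceed the number of latent variables")
  E <- if (is.null(newdata)) model$E else pls_project(model, newdata)$E
  s_i <- sqrt(rowSums(E^2) / (K - A))
  dm <- s_i / model$s0
  crit <- sqrt(stats::qf(alpha, K - A, (N - A - 1) * (K - A),
                         lower.tail = FALSE))
  ids <- rownames(E)
  if (is.null(ids)) ids <- as.character(seq_along(dm))
  out <- data.frame(compound = ids, dmodx = unname(dm),
                    inside = unname(dm <= crit), stringsAsFactors = FALSE)
  class(out) <- c("ad_report", "data.frame")
  attr(out, "critical") <- crit
  attr(out, "alpha") <- alpha
  out
}

#' @export
print.ad_report <- function(x, ...) {
  cat(sprintf("<ad_report: %d compounds, DModX critical %.3f at alpha=%g; %d outside>\n",
              nrow(x), attr(x, "critical"), attr(x, "alpha"), sum(!x$inside)))
  print.data.frame(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat("  ...\n")
  invisible(x)
}
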