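#' Genetic partial least squares (G/PLS)
#'
#' Combines the genetic term search of [gfa_search()] with PLS regression:
#' the genetic algorithm proposes sets of basis terms (the same
#' linear/spline term algebra, so the spline option is available), each
#' candidate's evaluated basis matrix is fitted by [pls_fit()], the number
#' of latent variables is chosen in `1..max_lv` by minimizing the
#' leave-one-out PRESS, and the candidate is scored by the lack-of-fit of
#' that PLS fit (`LSE = RSS/m`).  PLS weighs the relative contributions of
#' the selected variables while tolerating collinear terms, which is what
#' lets G/PLS carry longer equations without overfitting.
#'
#' @param table Descriptor data.
#' @param activity Observed activity.
#' @param iterations Number of genetic operations (default 1000).
#' @param max_lv Maximum number of latent variables (default 3).
#' @param seed Integer RNG seed.
#' @param config Optional [gfa_config()] overriding the genetic defaults;
#'   its `iterations`/`seed` are superseded by the arguments above.
#' @return A list of class `gpls_result`: `best` (a `gpls_model`: terms plus
#'   the PLS fit on their basis), `models`, `lof`, `trajectory`, `config`.
#' @export
gpls_search <- function(table, activity, iterations = 1000L, max_lv = 3L,
                        seed = 1L, config = NULL) {
  m <- as_descriptor_matrix(table)
  y <- as_activity_vector(activity, table)
  if (ncol(m) < 2L) stop_("need at least 2 descriptors")
  if (is.null(config)) config <- gfa_config(population = 50L)
  config$iterations <- as.integer(iterations)
  config$seed <- as.integer(seed)
  if (nrow(m) <= config$max_terms + 1L) {
    stop_("too few observations (n=%d) for max_terms=%d",
          nrow(m), config$max_terms)
  }
  score_fn <- function(terms) {
    fit <- try(fit_term_pls(terms, m, y, max_lv), silent = TRUE)
    if (inherits(fit, "try-error")) return(list(lof = Inf, model = NULL))
    p_desc <- length(unique(vapply(terms, `[[`, character(1L), "descriptor")))
    val <- lof(fit$pls$stats$RSS / nrow(m), c = length(terms), d = config$d,
               p = p_desc, m = nrow(m))
    # tie-break numerically equal LOF toward the smaller equation
    list(lof = val + 1e-12 * length(terms), model = fit)
  }
  res <- with_seed(config$seed, run_ga(m, config, score_fn))
  # deterministic backward pruning of the champion (no knot polish: each
  # candidate evaluation carries a full LOO pass)
  ref <- refine_terms(res$population[[1L]], res$lof[1L], m, config, score_fn,
                      polish_knots = FALSE)
  models <- lapply(res$scored, `[[`, "model")
  models[[1L]] <- ref$model
  lofs <- res$lof
  lofs[1L] <- ref$lof
  structure(list(best = models[[1L]], models = models, lof = lofs,
                 trajectory = res$trajectory, config = config,
                 max_lv = as.integer(max_lv)),
            class = "gpls_result")
}

# PLS on the evaluated basis of a term set, LV count by inner LOO-PRESS.
fit_term_pls <- function(terms, m, y, max_lv) {
  z <- design_matrix(terms, m)
  if (any(apply(z, 2L, stats::sd) == 0)) {
    stop_("degenerate basis column (constant over training compounds)")
  }
  a_max <- min(max_lv, ncol(z), nrow(z) - 2L)
  press_a <- pls_loo_press(z, y, a_max)
  a_best <- which.min(press_a)
  pls <- pls_fit(z, y, a_best)
  structure(list(terms = terms, pls = pls, n_lv = a_best,
                 loo_press = press_a),
            class = "gpls_model")
}

# Lean LOO loop on the bare NIPALS core (scaling recomputed per fold).
# Components are extracted once per fold up to a_max and the deleted
# compound is predicted at every latent-variable count, so the PRESS curve
# over 1..a_max costs a single pass.
pls_loo_press <- function(z, y, a_max) {
  n <- nrow(z)
  press <- numeric(a_max)
  for (i in seq_len(n)) {
    Xi <- z[-i, , drop = FALSE]
    yi <- y[-i]
    ctr <- colMeans(Xi)
    scl <- sqrt((colSums(Xi^2) - (n - 1) * ctr^2) / (n - 2))
    if (any(scl == 0) || any(!is.finite(scl))) return(rep(Inf, a_max))
    Xs <- sweep(sweep(Xi, 2L, ctr), 2L, scl, "/")
    core <- try(pls_core(Xs, yi - mean(yi), a_max), silent = TRUE)
    if (inherits(core, "try-error")) return(rep(Inf, a_max))
    xnew <- (z[i, ] - ctr) / scl
    for (a in seq_len(a_max)) {
      Wa <- core$W[, seq_len(a), drop = FALSE]
      Ba <- drop(Wa %*% solve(crossprod(core$P[, seq_len(a), drop = FALSE],
                                        Wa), core$q[seq_len(a)]))
      press[a] <- press[a] + (y[i] - sum(xnew * Ba) - mean(yi))^2
    }
  }
  unname(press)
}

#' Fit a fixed term set by PLS
#'
#' Evaluates the given basis terms and fits them by [pls_fit()], choosing
#' the latent-variable count by leave-one-out PRESS up to `max_lv`.  This is
#' the refit path used when a G/PLS term set is already known.
#'
#' @param terms List of [model_term()].
#' @param table,activity Training data.
#' @param max_lv Maximum latent variables (default 3).
#' @return A `gpls_model`.
#' @export
gpls_fit <- function(terms, table, activity, max_lv = 3L) {
  m <- as_descriptor_matrix(table)
  y <- as_activity_vector(activity, table)
  fit_term_pls(terms, m, y, max_lv)
}

#' @export
print.gpls_model <- function(x, ...) {
  cat(sprintf("<gpls_model: %d term(s), %d latent variable(s), R2 = %.4f>\n",
              length(x$terms), x$n_lv, x$pls$stats$R2))
  for (t in x$terms) cat("  ", term_label(t), "\n")
  invisible(x)
}

#' @export
predict.gpls_model <- function(object, newdata, ...) {
  z <- design_matrix(object$terms, newdata)
  predict(object$pls, z)
}

#' @export
print.gpls_result <- function(x, ...) {
  cat(sprintf("<gpls_result: population %d, best LOF %.6g>\n",
              length(x$models), x$lof[1L]))
  print(x$best)
  invisible(x)
}
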