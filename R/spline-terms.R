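#' Basis terms for linear/spline QSAR equations
#'
#' A model term maps one descriptor through one of four basis transforms:
#' * `linear`: x
#' * `spline_below`: `max(0, knot - x)` — a truncated power spline written
#'   `<a - x>` in the field's angular-bracket notation
#' * `spline_above`: `max(0, x - knot)` — written `<x - a>`
#' * `square`: x^2
#'
#' The constant `a` is the knot of the spline; a spline term evaluates to
#' zero whenever its argument is negative, so its contribution is always
#' non-negative before weighting by the coefficient.
#'
#' @param descriptor Descriptor name the term reads.
#' @param transform One of `"linear"`, `"spline_below"`, `"spline_above"`,
#'   `"square"`.
#' @param knot Spline knot; required for (and only for) spline transforms.
#' @param coefficient Regression coefficient (may be `NA` before fitting).
#' @param se Optional standard error of the coefficient.
#' @return An object of class `model_term`.
#' @export
model_term <- function(descriptor,
                       transform = c("linear", "spline_below",
                                     "spline_above", "square"),
                       knot = NULL, coefficient = NA_real_, se = NA_real_) {
  transform <- match.arg(transform)
  is_spline <- transform %in% c("spline_below", "spline_above")
  if (is_spline && is.null(knot)) stop_("spline term needs a knot")
  if (!is_spline && !is.null(knot)) stop_("knot only allowed for spline terms")
  structure(list(descriptor = as.character(descriptor), transform = transform,
                 knot = if (is_spline) as.numeric(knot) else NULL,
                 coefficient = as.numeric(coefficient), se = as.numeric(se)),
            class = "model_term")
}

#' Evaluate a basis term
#'
#' @param term A [model_term()].
#' @param x Numeric vector of descriptor values.
#' @return Numeric vector: `x`, `pmax(0, knot - x)`, `pmax(0, x - knot)` or
#'   `x^2` according to the term's transform.
#' @export
eval_term <- function(term, x) {
  switch(term$transform,
         linear       = x,
         spline_below = pmax(0, term$knot - x),
         spline_above = pmax(0, x - term$knot),
         square       = x^2)
}

term_label <- function(term) {
  switch(term$transform,
         linear       = term$descriptor,
         spline_below = sprintf("<%g-%s>", term$knot, term$descriptor),
         spline_above = sprintf("<%s-%g>", term$descriptor, term$knot),
         square       = sprintf("(%s)^2", term$descriptor))
}

#' @export
print.model_term <- function(x, ...) {
  coef <- if (is.na(x$coefficient)) "" else sprintf("%+.4g x ", x$coefficient)
  cat(sprintf("model_term: %s%s\n", coef, term_label(x)))
  invisible(x)
}

# Canonical signature of a term set; used for GA dedup and set comparison.
term_signature <- function(terms) {
  paste(sort(vapply(terms, function(t) {
    paste(t$descriptor, t$transform,
          if (is.null(t$knot)) "" else format(t$knot, digits = 12), sep = "|")
  }, character(1L))), collapse = ";")
}

# Evaluate a list of terms into an N x p basis matrix.
design_matrix <- function(terms, table) {
  m <- as_descriptor_matrix(table)
  need <- unique(vapply(terms, `[[`, character(1L), "descriptor"))
  missing <- setdiff(need, colnames(m))
  if (length(missing)) stop_("missing descriptor(s): %s",
                             paste(missing, collapse = ", "))
  z <- vapply(terms, function(t) eval_term(t, m[, t$descriptor]),
              numeric(nrow(m)))
  z <- matrix(z, nrow = nrow(m))
  colnames(z) <- vapply(terms, term_label, character(1L))
  rownames(z) <- rownames(m)
  z
}

#' Construct a fitted linear/spline equation
#'
#' Usually produced by [ols_fit()], [stepwise_mlr()] or [gfa_search()];
#' direct construction is used for serialized literature equations whose
#' training descriptors are not available for refitting.
#'
#' @param intercept Model intercept.
#' @param terms List of [model_term()] with coefficients set.
#' @param n Number of training compounds (NA for prediction-only fixtures).
#' @param stats Named list of fit statistics (`s`, `R2`, `Ra2`, `F`, `df`,
#'   `PRESS`, `Q2`, ... whichever were computed).
#' @param provenance Free-form label recording where the model came from.
#' @return An object of class `spline_model`.
#' @export
spline_model <- function(intercept, terms, n = NA_integer_, stats = list(),
                         provenance = NULL) {
  stopifnot(is.numeric(intercept), length(intercept) == 1L)
  if (!all(vapply(terms, inherits, logical(1L), "model_term"))) {
    stop_("terms must be a list of model_term objects")
  }
  structure(list(intercept = as.numeric(intercept), terms = terms,
                 n = n, stats = stats, provenance = provenance),
            class = "spline_model")
}

#' @export
print.spline_model <- function(x, digits = 4L, ...) {
  rhs <- vapply(x$terms, function(t)
    sprintf("%+.*g*%s", digits, t$coefficient, term_label(t)), character(1L))
  cat("spline_model: pIC50 =", format(x$intercept, digits = digits),
      paste(rhs, collapse = " "), "\n")
  if (!is.null(x$provenance)) cat("  provenance:", x$provenance, "\n")
  st <- x$stats
  if (length(st)) {
    keys <- intersect(c("n", "s", "R2", "Ra2", "F", "PRESS", "Q2"), names(st))
    cat(" ", paste(sprintf("%s=%.4g", keys, unlist(st[keys])),
                   collapse = ", "), "\n")
  }
  invisible(x)
}

#' Predict activity from a fitted equation
#'
#' @param object A `spline_model`.
#' @param newdata A `descriptor_table`, matrix or data frame containing every
#'   descriptor the model's terms reference.
#' @param ... Unused.
#' @return Named numeric vector of predicted activities,
#'   `intercept + sum(coefficient * basis)` per compound.
#' @export
predict.spline_model <- function(object, newdata, ...) {
  if (length(object$terms) == 0L) {
    m <- as_descriptor_matrix(newdata)
    return(stats::setNames(rep(object$intercept, nrow(m)), rownames(m)))
  }
  z <- design_matrix(object$terms, newdata)
  beta <- vapply(object$terms, `[[`, numeric(1L), "coefficient")
  if (anyNA(beta)) stop_("model has unset coefficients")
  stats::setNames(drop(object$intercept + z %*% beta), rownames(z))
}

#' Arithmetic-mean consensus prediction
#'
#' Averages per-compound predictions across an ensemble of QSAR models, the
#' standard way a panel of equations is combined into a single predicted
#' activity for a designed compound.
#'
#' @param predictions Either a numeric matrix/data frame (compounds x models)
#'   of precomputed predictions, or a list of `spline_model`s, in which case
#'   `table` must supply the descriptors.
#' @param table Descriptor data; only needed when `predictions` is a model list.
#' @return Named numeric vector of consensus (mean) predictions.
#' @export
consensus_predict <- function(predictions, table = NULL) {
  if (is.list(predictions) && !is.data.frame(predictions) &&
      all(vapply(predictions, inherits, logical(1L), "spline_model"))) {
    if (is.null(table)) stop_("table required when passing models")
    predictions <- vapply(predictions, predict,
                          numeric(nrow(as_descriptor_matrix(table))),
                          newdata = table)
    predictions <- matrix(predictions, nrow = nrow(as_descriptor_matrix(table)),
                          dimnames = list(rownames(as_descriptor_matrix(table)),
                                          NULL))
  }
  m <- as.matrix(predictions)
  if (!is.numeric(m)) stop_("predictions must be numeric")
  if (ncol(m) < 1L) stop_("need at least one model prediction")
  rowMeans(m)
}
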