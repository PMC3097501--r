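#' Packaged reference data: the NO-donor phenol series
#'
#' Observed and predicted activity for the 33 phenolic antioxidant
#' derivatives the package's validation surface is checked against:
#' observed pIC50 (negative log10 of IC50 in mM, TBARS assay), the
#' LOO/test predictions of the published GFA-spline equation
#' (`pred_gfa`) and of the G/PLS-spline equation (`pred_gpls`), and the
#' cluster-selected external test-set membership (compounds 4, 5, 11, 13,
#' 20, 21, 23, 24 — 8 of 33, one quarter).
#'
#' For the training compounds the prediction columns hold leave-one-out
#' predictions; for the test compounds they hold external predictions from
#' the training-set model.  Note the attribution subtlety recorded in
#' [published_models()]: the statistics recomputed from `pred_gfa` match the
#' quadratic-reformulation equation (model A2a), not the spline equation its
#' table footnote cites.
#'
#' @return A data.frame with columns `compound` (character), `pIC50`,
#'   `pred_gfa`, `pred_gpls` (numeric) and `test_set` (logical).
#' @export
phenols_activity <- function() {
  df <- utils::read.csv(pkg_extdata("phenols_activity.csv"),
                        stringsAsFactors = FALSE)
  df$compound <- as.character(df$compound)
  df$test_set <- as.logical(df$test_set)
  df
}

#' Predicted activities of the 15 designed compounds
#'
#' In-silico predictions of the antioxidant activity of 15 newly designed
#' phenolic compounds under each of the 11 published QSAR models, together
#' with the printed consensus column `APA` (average predicted activity, the
#' arithmetic mean over the 11 models).
#'
#' @return A data.frame: `compound` plus 11 model columns and `APA`.
#' @export
designed_predictions <- function() {
  df <- utils::read.csv(pkg_extdata("designed_predictions.csv"),
                        stringsAsFactors = FALSE)
  df$compound <- as.character(df$compound)
  df
}

#' Published Y-randomization summaries
#'
#' Per-model randomization results: `R2` and `R` of the unscrambled model,
#' mean scrambled correlation `Rr`/`Rr2`, and the printed corrected
#' statistic `cRp2`, for both process (whole descriptor pool, 90%
#' confidence) and model (fixed descriptors, 99%) randomization.
#'
#' @return A data.frame with columns `model`, `tool`, `mode`, `R2`, `R`,
#'   `Rr`, `Rr2`, `cRp2`.
#' @export
randomization_summary <- function() {
  utils::read.csv(pkg_extdata("randomization_summary.csv"),
                  stringsAsFactors = FALSE)
}

#' Published QSAR equations as prediction-only models
#'
#' The four printed equations for the phenol series — the whole-dataset
#' stepwise model, the two GFA spline equations and the G/PLS spline
#' equation — reconstructed from their printed intercepts, coefficients and
#' spline knots.  The raw descriptor matrix behind them is unpublished
#' supplementary material, so these are prediction-only: they can be
#' evaluated on new descriptor values via [predict.spline_model()] but not
#' refitted.  Printed fit statistics travel in each model's `stats`.
#'
#' @return Named list of `spline_model`s (`eq7`, `eq8`, `eq9`, `eq10`) with
#'   attribute `"column_labels"` documenting which activity-table prediction
#'   column corresponds to which equation.
#' @export
published_models <- function() {
  js <- jsonlite::fromJSON(pkg_extdata("published_models.json"),
                           simplifyVector = FALSE)
  models <- lapply(js$models, function(mj) {
    terms <- lapply(mj$terms, function(tj) {
      model_term(tj$descriptor, tj$transform,
                 knot = tj$knot, coefficient = tj$coefficient,
                 se = if (is.null(tj$se)) NA_real_ else tj$se)
    })
    spline_model(mj$intercept, terms, n = mj$stats$n, stats = mj$stats,
                 provenance = sprintf("%s (%s; %s)", mj$label, mj$model_id,
                                      mj$fitted_on))
  })
  names(models) <- vapply(js$models, `[[`, character(1L), "label")
  attr(models, "column_labels") <- js$table1_prediction_columns
  models
}

pkg_extdata <- function(file) {
  path <- system.file("extdata", file, package = "genqsar")
  if (path == "") stop_("packaged fixture not found: %s", file)
  path
}

#' Serialize a fitted equation to JSON
#'
#' Writes intercept, terms (descriptor, transform, knot, coefficient,
#' standard error) and fit statistics in the same schema used by the
#' packaged published models, so fitted equations round-trip through
#' [read_model_json()].
#'
#' @param model A `spline_model`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_model_json <- function(model, path) {
  terms <- lapply(model$terms, function(t) {
    out <- list(descriptor = t$descriptor, transform = t$transform,
                coefficient = t$coefficient)
    if (!is.null(t$knot)) out$knot <- t$knot
    if (!is.na(t$se)) out$se <- t$se
    out
  })
  stats_keep <- model$stats[vapply(model$stats, function(v)
    is.numeric(v) && length(v) <= 2L, logical(1L))]
  obj <- list(intercept = model$intercept, terms = terms, n = model$n,
              stats = stats_keep, provenance = model$provenance)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  js <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  terms <- lapply(js$terms, function(tj) {
    model_term(tj$descriptor, tj$transform, knot = tj$knot,
               coefficient = tj$coefficient,
               se = if (is.null(tj$se)) NA_real_ else tj$se)
  })
  spline_model(js$intercept, terms,
               n = if (is.null(js$n)) NA_integer_ else js$n,
               stats = lapply(js$stats, function(v)
                 if (is.list(v)) unlist(v) else v),
               provenance = js$provenance)
}
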