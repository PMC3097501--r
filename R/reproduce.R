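#' Recompute every fixture-derivable published statistic
#'
#' Runs the package's validation machinery over the packaged reference data
#' and compares each recomputed quantity with its printed value at the
#' stated tolerance: Q2, PRESS, R2_pred and the rm2 metrics for both
#' prediction columns of the phenol activity table; the adjusted-R2 and
#' overall-F closed forms on the printed whole-dataset fit; the tabulated
#' critical F values; the consensus (mean) predictions of the 15 designed
#' compounds against the printed APA column; and the corrected
#' randomization statistic cRp2 for every published randomization row.
#' Tolerances reflect that the printed inputs are rounded to three decimals.
#'
#' @param verbose Print the pass/fail table (default `TRUE`).
#' @return Invisibly, a data.frame of class `published_check` with columns
#'   `quantity`, `computed`, `reference`, `tolerance`, `pass`.
#' @export
reproduce_published <- function(verbose = TRUE) {
  act <- phenols_activity()
  tr <- !act$test_set
  te <- act$test_set
  ym <- mean(act$pIC50[tr])
  rows <- list()
  add <- function(quantity, computed, reference, tolerance) {
    rows[[length(rows) + 1L]] <<- data.frame(
      quantity = quantity, computed = computed, reference = reference,
      tolerance = tolerance, stringsAsFactors = FALSE)
  }

  for (col in c("pred_gfa", "pred_gpls")) {
    p <- act[[col]]
    ref <- if (col == "pred_gfa") {
      list(q2 = 0.814, press = 4.557, r2p = 0.917, rm2t = 0.818,
           rm2o = 0.711, rm2l = 0.677)
    } else {
      list(q2 = 0.877, press = 3.022, r2p = 0.884, rm2t = 0.812,
           rm2o = 0.872, rm2l = 0.870)
    }
    add(paste0(col, ": Q2"), q2(act$pIC50[tr], p[tr], ym), ref$q2, 0.005)
    add(paste0(col, ": PRESS"), press(act$pIC50[tr], p[tr]), ref$press, 0.01)
    add(paste0(col, ": R2_pred"), r2_pred(act$pIC50[te], p[te], ym),
        ref$r2p, 0.005)
    add(paste0(col, ": rm2(LOO)"), rm2(act$pIC50[tr], p[tr])$rm2, ref$rm2l, 0.01)
    add(paste0(col, ": rm2(test)"), rm2(act$pIC50[te], p[te])$rm2, ref$rm2t, 0.01)
    add(paste0(col, ": rm2(overall)"), rm2_overall(act$pIC50, p), ref$rm2o, 0.01)
  }

  # closed-form fit statistics of the printed whole-dataset equation
  add("Ra2(R2=0.914, n=33, p=6)", 1 - (1 - 0.914) * 32 / 26, 0.894, 0.001)
  add("F(R2=0.914, n=33, p=6)", (0.914 / 6) / ((1 - 0.914) / 26), 46.10, 0.5)

  add("critical F(4,20) at upper 1%", f_critical(0.01, 4, 20), 4.431, 0.005)
  add("critical F(2,22) at upper 1%", f_critical(0.01, 2, 22), 5.719, 0.005)

  des <- designed_predictions()
  model_cols <- setdiff(names(des), c("compound", "APA"))
  apa <- consensus_predict(des[model_cols])
  for (i in seq_len(nrow(des))) {
    add(paste0("consensus APA ", des$compound[i]), unname(apa[i]),
        des$APA[i], 0.001)
  }

  rnd <- randomization_summary()
  for (i in seq_len(nrow(rnd))) {
    add(sprintf("cRp2 %s (%s)", rnd$model[i], rnd$mode[i]),
        crp2(R = rnd$R[i], Rr2 = rnd$Rr2[i], R2 = rnd$R2[i]),
        rnd$cRp2[i], 0.002)
  }

  out <- do.call(rbind, rows)
  out$pass <- abs(out$computed - out$reference) <= out$tolerance
  class(out) <- c("published_check", "data.frame")
  if (verbose) print(out)
  invisible(out)
}

#' @export
print.published_check <- function(x, ...) {
  df <- as.data.frame(x)
  df$computed <- sprintf("%.4f", df$computed)
  df$status <- ifelse(x$pass, "ok", "FAIL")
  print.data.frame(df[, c("quantity", "computed", "reference",
                          "tolerance", "status")], row.names = FALSE)
  cat(sprintf("%d/%d checks within tolerance\n", sum(x$pass), nrow(x)))
  invisible(x)
}
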