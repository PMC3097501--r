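{
  "comment": "Published QSAR equations for the 33 NO-donor phenols, stored as prediction-only fixtures: the raw descriptor matrix behind them is unpublished supplementary material, so these models can be evaluated on new descriptor values but not re-fitted here. Spline terms are truncated power splines: spline_below = max(0, knot - x), spline_above = max(0, x - knot).",
  "models": [
    {
      "label": "eq7",
      "model_id": "whole-dataset stepwise MLR",
      "fitted_on": "all 33 compounds",
      "intercept": -0.373,
      "terms": [
        {"descriptor": "S_aasC",    "transform": "linear", "coefficient":  0.302, "se": 0.069},
        {"descriptor": "Jurs_TASA", "transform": "linear", "coefficient":  0.009, "se": 0.001},
        {"descriptor": "MR",        "transform": "linear", "coefficient": -0.017, "se": 0.006},
        {"descriptor": "Chi3v_c",   "transform": "linear", "coefficient": -0.360, "se": 0.088},
        {"descriptor": "S_ddsN",    "transform": "linear", "coefficient": -2.11,  "se": 0.608},
        {"descriptor": "Jurs_RPCG", "transform": "linear", "coefficient": -1.80,  "se": 0.821}
      ],
      "stats": {"n": 33, "s": 0.317, "R2": 0.914, "Ra2": 0.894, "F": 46.10,
                "df1": 6, "df2": 26, "PRESS": 4.091, "Q2": 0.866,
                "true_rm2_loo": 0.578}
    },
    {
      "label": "eq8",
      "model_id": "A2",
      "fitted_on": "25 training compounds (GFA, spline option)",
      "intercept": -1.68,
      "terms": [
        {"descriptor": "SC3_P",  "transform": "spline_above", "knot": 20.0,     "coefficient": -0.113, "se": 0.029},
        {"descriptor": "Chi3_p", "transform": "linear",                          "coefficient":  0.786, "se": 0.164},
        {"descriptor": "S_sCH3", "transform": "spline_below", "knot": 1.79401,  "coefficient": -0.637, "se": 0.099},
        {"descriptor": "S_aasC", "transform": "linear",                          "coefficient":  0.329, "se": 0.049}
      ],
      "stats": {"n": 25, "s": 0.315, "R2": 0.919, "Ra2": 0.903, "F": 56.95,
                "df1": 4, "df2": 20, "PRESS": 3.022, "Q2": 0.877,
                "rm2_loo": 0.757, "n_test": 8, "R2_pred": 0.924,
                "rm2_test": 0.899, "rm2_overall": 0.777}
    },
    {
      "label": "eq9",
      "model_id": "A2a",
      "fitted_on": "25 training compounds (GFA, quadratic reformulation of A2)",
      "intercept": -0.448,
      "terms": [
        {"descriptor": "Chi3_p", "transform": "linear",                          "coefficient":  0.497,  "se": 0.147},
        {"descriptor": "Chi3_p", "transform": "square",                          "coefficient": -0.0225, "se": 0.009},
        {"descriptor": "S_aasC", "transform": "linear",                          "coefficient":  0.300,  "se": 0.110},
        {"descriptor": "S_sCH3", "transform": "spline_below", "knot": 1.79401,  "coefficient": -0.539,  "se": 0.057}
      ],
      "stats": {"n": 25, "s": 0.369, "R2": 0.889, "Ra2": 0.867, "F": 40.17,
                "df1": 4, "df2": 20, "PRESS": 4.557, "Q2": 0.814,
                "rm2_loo": 0.677, "n_test": 8, "R2_pred": 0.917,
                "rm2_test": 0.818, "rm2_overall": 0.711}
    },
    {
      "label": "eq10",
      "model_id": "A4",
      "fitted_on": "25 training compounds (G/PLS, spline option, 2 latent variables)",
      "intercept": 1.158,
      "terms": [
        {"descriptor": "Chi1",   "transform": "spline_below", "knot": 6.68154,  "coefficient": -0.429},
        {"descriptor": "Chi3_p", "transform": "linear",                          "coefficient":  0.108},
        {"descriptor": "S_sCH3", "transform": "spline_below", "knot": 1.98556,  "coefficient": -0.525},
        {"descriptor": "S_aasC", "transform": "linear",                          "coefficient":  0.288}
      ],
      "stats": {"n": 25, "LVs": 2, "s": 0.323, "R2": 0.905, "Ra2": 0.897,
                "F": 106.44, "df1": 2, "df2": 22, "PRESS": 3.023, "Q2": 0.877,
                "rm2_loo": 0.870, "n_test": 8, "R2_pred": 0.884,
                "rm2_test": 0.812, "rm2_overall": 0.872}
    }
  ],
  "table1_prediction_columns": {
    "pred_gfa": {
      "footnote_label": "eq8",
      "statistics_match": "eq9 / model A2a",
      "note": "The printed footnote attributes this column to the first GFA spline equation, but its recomputed PRESS (4.557), Q2 (0.814) and R2_pred (0.917) match the quadratic reformulation's statistics block; both labels are recorded."
    },
    "pred_gpls": {
      "footnote_label": "eq10",
      "statistics_match": "eq10 / model A4"
    }
  }
}
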