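#' Construct a descriptor table
#'
#' A descriptor table holds the numeric molecular-descriptor matrix for a set
#' of compounds: one row per compound, one column per descriptor.  It is the
#' common input container for train/test splitting, model fitting and the
#' applicability-domain machinery.
#'
#' @param values Numeric matrix (or object coercible to one), compounds in
#'   rows and descriptors in columns.  Missing values are not supported.
#' @param compound_ids Character vector of unique compound identifiers;
#'   defaults to the row names of `values` (or `"1"`, `"2"`, ... if absent).
#' @param descriptor_names Character vector of unique descriptor names;
#'   defaults to the column names of `values`.
#' @param meta Optional free-form provenance list.
#'
#' @return An object of class `descriptor_table`.
#' @seealso [load_descriptor_table()], [variance_filter()], [standardize()]
#' @export
descriptor_table <- function(values, compound_ids = NULL,
                             descriptor_names = NULL, meta = list()) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop_("descriptor values must be numeric")
  if (nrow(values) < 2L) stop_("need at least 2 compounds, got %d", nrow(values))
  if (ncol(values) < 1L) stop_("need at least 1 descriptor")
  if (is.null(compound_ids)) {
    compound_ids <- rownames(values)
    if (is.null(compound_ids)) compound_ids <- as.character(seq_len(nrow(values)))
  }
  if (is.null(descriptor_names)) {
    descriptor_names <- colnames(values)
    if (is.null(descriptor_names)) {
      descriptor_names <- paste0("D", seq_len(ncol(values)))
    }
  }
  compound_ids <- as.character(compound_ids)
  descriptor_names <- as.character(descriptor_names)
  if (length(compound_ids) != nrow(values)) {
    stop_("compound_ids length (%d) != number of rows (%d)",
          length(compound_ids), nrow(values))
  }
  if (length(descriptor_names) != ncol(values)) {
    stop_("descriptor_names length (%d) != number of columns (%d)",
          length(descriptor_names), ncol(values))
  }
  if (anyDuplicated(compound_ids)) {
    stop_("duplicate compound ids: %s",
          paste(unique(compound_ids[duplicated(compound_ids)]), collapse = ", "))
  }
  if (anyDuplicated(descriptor_names)) {
    stop_("duplicate descriptor names: %s",
          paste(unique(descriptor_names[duplicated(descriptor_names)]),
                collapse = ", "))
  }
  if (anyNA(values) || any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop_("non-finite value at compound '%s', descriptor '%s'",
          compound_ids[bad[1L]], descriptor_names[bad[2L]])
  }
  dimnames(values) <- list(compound_ids, descriptor_names)
  structure(list(values = values, meta = meta), class = "descriptor_table")
}

#' @export
print.descriptor_table <- function(x, ...) {
  cat(sprintf("<descriptor_table: %d compounds x %d descriptors>\n",
              nrow(x$values), ncol(x$values)))
  show <- utils::head(descriptor_names(x), 6L)
  cat("  descriptors:", paste(show, collapse = ", "),
      if (ncol(x$values) > 6L) "..." else "", "\n")
  invisible(x)
}

#' Accessors for descriptor tables
#'
#' @param x A `descriptor_table`.
#' @return `compound_ids()` and `descriptor_names()` return character vectors;
#'   `descriptor_values()` returns the underlying numeric matrix with
#'   compound ids as row names.
#' @export
compound_ids <- function(x) UseMethod("compound_ids")

#' @export
compound_ids.descriptor_table <- function(x) rownames(x$values)

#' @rdname compound_ids
#' @export
descriptor_names <- function(x) UseMethod("descriptor_names")

#' @export
descriptor_names.descriptor_table <- function(x) colnames(x$values)

#' @rdname compound_ids
#' @export
descriptor_values <- function(x) UseMethod("descriptor_values")

#' @export
descriptor_values.descriptor_table <- function(x) x$values

# Coerce matrices / data frames / descriptor_tables to a plain numeric matrix.
as_descriptor_matrix <- function(x) {
  if (inherits(x, "descriptor_table")) return(x$values)
  m <- as.matrix(x)
  storage.mode(m) <- "double"
  if (is.null(colnames(m))) colnames(m) <- paste0("D", seq_len(ncol(m)))
  m
}

#' Construct an activity series
#'
#' Observed activity on the pIC50 scale (negative decadic logarithm of the
#' 50% inhibitory concentration in millimolar), aligned with a descriptor
#' table by compound id.
#'
#' @param pIC50 Numeric vector of observed activities.
#' @param compound_ids Character identifiers, one per activity value.
#' @return A named numeric vector of class `activity_series`.
#' @export
activity_series <- function(pIC50, compound_ids = names(pIC50)) {
  force(compound_ids)
  pIC50 <- as.numeric(pIC50)
  if (is.null(compound_ids)) compound_ids <- as.character(seq_along(pIC50))
  if (length(compound_ids) != length(pIC50)) {
    stop_("compound_ids and pIC50 lengths differ")
  }
  if (anyNA(pIC50) || any(!is.finite(pIC50))) stop_("activity values must be finite")
  if (anyDuplicated(compound_ids)) stop_("duplicate compound ids in activity")
  structure(stats::setNames(pIC50, as.character(compound_ids)),
            class = "activity_series")
}

#' @export
print.activity_series <- function(x, ...) {
  cat(sprintf("<activity_series: %d compounds, pIC50 range [%.3f, %.3f]>\n",
              length(x), min(x), max(x)))
  invisible(x)
}

# Strip class; optionally align to a descriptor table's compound order.
as_activity_vector <- function(y, table = NULL) {
  v <- as.numeric(y)
  names(v) <- names(y)
  if (!is.null(table) && !is.null(names(v))) {
    ids <- rownames(as_descriptor_matrix(table))
    if (!is.null(ids)) {
      if (!all(ids %in% names(v))) {
        stop_("activity is missing compounds: %s",
              paste(setdiff(ids, names(v)), collapse = ", "))
      }
      v <- v[ids]
    }
  }
  v
}

#' Read a descriptor table from CSV
#'
#' Expects a header row; one column (by default the first) carries compound
#' identifiers and every other column must parse as numeric.
#'
#' @param path Path to a CSV file.
#' @param id_column Name or index of the compound-id column (default first).
#' @return A [descriptor_table()].
#' @export
load_descriptor_table <- function(path, id_column = 1L) {
  if (!file.exists(path)) stop_("file not found: %s", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (is.character(id_column)) {
    if (!id_column %in% names(df)) stop_("id column '%s' not in file", id_column)
    idc <- match(id_column, names(df))
  } else idc <- as.integer(id_column)
  ids <- as.character(df[[idc]])
  desc_names <- names(df)[-idc]  # before subsetting: `[.data.frame` deduplicates
  vals <- df[-idc]
  names(vals) <- desc_names
  for (j in seq_along(vals)) {
    col <- vals[[j]]
    if (!is.numeric(col)) {
      num <- suppressWarnings(as.numeric(col))
      bad <- which(is.na(num) & !is.na(col))
      if (length(bad)) {
        stop_("non-numeric value '%s' in column '%s', row %d (compound '%s')",
              col[bad[1L]], names(vals)[j], bad[1L], ids[bad[1L]])
      }
      vals[[j]] <- num
    }
  }
  if (anyNA(as.matrix(vals))) {
    bad <- which(is.na(as.matrix(vals)), arr.ind = TRUE)[1L, ]
    stop_("missing value at row %d (compound '%s'), column '%s'",
          bad[1L], ids[bad[1L]], names(vals)[bad[2L]])
  }
  descriptor_table(as.matrix(vals), compound_ids = ids,
                   descriptor_names = names(vals),
                   meta = list(source = path))
}

#' Write a descriptor table to CSV
#'
#' Inverse of [load_descriptor_table()]: a write-then-read round trip
#' reproduces the table values.
#'
#' @param x A `descriptor_table`.
#' @param path Output CSV path.
#' @param id_column Header for the compound-id column.
#' @return Invisibly, `path`.
#' @export
write_descriptor_table <- function(x, path, id_column = "compound") {
  m <- as_descriptor_matrix(x)
  # 17 significant digits: doubles survive the round trip bit-identically
  fm <- apply(m, 2L, function(col) sprintf("%.17g", col))
  df <- data.frame(id = rownames(m), fm, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c(id_column, colnames(m))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an activity series from CSV
#'
#' @param path CSV with a compound-id column and a numeric activity column.
#' @param id_column Name/index of the id column (default first).
#' @param activity_column Name/index of the activity column (default second).
#' @return An [activity_series()].
#' @export
load_activity <- function(path, id_column = 1L, activity_column = 2L) {
  if (!file.exists(path)) stop_("file not found: %s", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  pick <- function(col) if (is.character(col)) df[[col]] else df[[as.integer(col)]]
  activity_series(as.numeric(pick(activity_column)),
                  compound_ids = as.character(pick(id_column)))
}

#' Drop near-constant descriptors
#'
#' Removes descriptors whose population variance (divide by N) falls below
#' `threshold`; descriptors with variance exactly at the threshold are kept.
#' The conventional pre-filter before standardization and model search.
#'
#' @param table A `descriptor_table` (or numeric matrix).
#' @param threshold Non-negative variance cutoff; default `1e-4`.
#' @return A filtered `descriptor_table`; the names of removed descriptors
#'   are available in attribute `"dropped"`.
#' @export
variance_filter <- function(table, threshold = 1e-4) {
  if (threshold < 0) stop_("threshold must be non-negative")
  m <- as_descriptor_matrix(table)
  v <- pop_var(m)
  keep <- v >= threshold
  if (!any(keep)) stop_("no informative descriptors: all %d fall below variance %g",
                        ncol(m), threshold)
  out <- descriptor_table(m[, keep, drop = FALSE],
                          meta = if (inherits(table, "descriptor_table"))
                            table$meta else list())
  attr(out, "dropped") <- colnames(m)[!keep]
  out
}

#' Standardize a descriptor table
#'
#' Centers every descriptor to mean zero and scales to unit sample standard
#' deviation (denominator N-1), returning the transform parameters so new
#' compounds can be projected into the same space.
#'
#' @param table A `descriptor_table` (or numeric matrix) with no
#'   zero-variance columns (apply [variance_filter()] first).
#' @return A list of class `standardized_table` with elements `table` (the
#'   z-scored `descriptor_table`), `center` and `scale` (named numeric).
#' @export
standardize <- function(table) {
  m <- as_descriptor_matrix(table)
  ctr <- colMeans(m)
  scl <- apply(m, 2L, stats::sd)
  zero <- scl == 0 | !is.finite(scl)
  if (any(zero)) {
    stop_("zero-variance descriptor(s): %s (variance-filter first)",
          paste(colnames(m)[zero], collapse = ", "))
  }
  z <- sweep(sweep(m, 2L, ctr), 2L, scl, "/")
  structure(list(table = descriptor_table(z), center = ctr, scale = scl),
            class = "standardized_table")
}

#' Apply or invert stored standardization parameters
#'
#' @param params A `standardized_table` (as returned by [standardize()]) or a
#'   list with `center` and `scale`.
#' @param table New descriptor data sharing the training descriptors.
#' @return A `descriptor_table` in standardized (or, for
#'   `unstandardize()`, original) units.
#' @export
apply_standardization <- function(params, table) {
  m <- as_descriptor_matrix(table)
  nm <- names(params$center)
  if (!all(nm %in% colnames(m))) {
    stop_("table lacks descriptors: %s",
          paste(setdiff(nm, colnames(m)), collapse = ", "))
  }
  m <- m[, nm, drop = FALSE]
  descriptor_table(sweep(sweep(m, 2L, params$center), 2L, params$scale, "/"))
}

#' @rdname apply_standardization
#' @export
unstandardize <- function(params, table) {
  m <- as_descriptor_matrix(table)
  nm <- names(params$center)
  m <- m[, nm, drop = FALSE]
  descriptor_table(sweep(sweep(m, 2L, params$scale, "*"), 2L,
                         params$center, "+"))
}

#' Pairwise Pearson intercorrelation of descriptors
#'
#' Symmetric unit-diagonal matrix of Pearson correlations, used to inspect
#' collinearity among the descriptors of a fitted equation (highly
#' intercorrelated index pairs are common among topological descriptors).
#' Constant descriptors yield `NA` entries (flagged, not propagated as NaN).
#'
#' @param table A `descriptor_table` or numeric matrix.
#' @param subset Optional character vector of descriptor names to restrict to.
#' @return Correlation matrix with attribute `"undefined"` naming constant
#'   descriptors, if any.
#' @export
intercorrelation_matrix <- function(table, subset = NULL) {
  m <- as_descriptor_matrix(table)
  if (!is.null(subset)) {
    missing <- setdiff(subset, colnames(m))
    if (length(missing)) stop_("unknown descriptors: %s",
                               paste(missing, collapse = ", "))
    m <- m[, subset, drop = FALSE]
  }
  if (nrow(m) < 3L) stop_("need at least 3 compounds for correlations")
  sds <- apply(m, 2L, stats::sd)
  const <- sds == 0
  r <- suppressWarnings(stats::cor(m))
  r[const, ] <- NA_real_
  r[, const] <- NA_real_
  diag(r) <- 1
  r <- (r + t(r)) / 2  # enforce exact symmetry
  if (any(const)) attr(r, "undefined") <- colnames(m)[const]
  r
}
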