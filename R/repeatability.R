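# Inter-reader repeatability feature selection.
#
# A feature enters the model only if its values, computed from the two
# readers' segmentations across all subjects, have product-moment correlation
# strictly greater than the threshold (default 0.95). Selection is performed
# once on the full cohort, before cross-validation, as the original analysis
# did; see the methods vignette for the leakage discussion and the strict
# within-fold alternative.

#' Select features repeatable between two readers
#'
#' @param table1,table2 per-reader feature matrices with identical row names
#'   (subjects, >= 3) and column names (feature keys).
#' @param threshold correlation threshold; selection requires `r > threshold`
#'   (strict). Default 0.95.
#' @return list of class `repeatability_report`: `report` (data.frame with
#'   key, r, selected), `selected` (character keys), `threshold`.
#' @export
repeatability_filter <- function(table1, table2, threshold = 0.95) {
  if (!identical(rownames(table1), rownames(table2)) ||
      !identical(colnames(table1), colnames(table2)))
    stop("reader tables must have identical subjects and feature keys")
  if (nrow(table1) < 3) stop("need at least 3 subjects to assess repeatability")
  n <- nrow(table1)
  x <- sweep(table1, 2, colMeans(table1)); y <- sweep(table2, 2, colMeans(table2))
  sx <- sqrt(colSums(x^2)); sy <- sqrt(colSums(y^2))
  r <- colSums(x * y) / (sx * sy)          # NaN where either column is constant
  selected <- !is.na(r) & r > threshold
  list(
    report = data.frame(key = colnames(table1), r = as.numeric(r),
                        selected = selected, row.names = NULL,
                        stringsAsFactors = FALSE),
    selected = colnames(table1)[selected],
    threshold = threshold
  ) |> structure(class = "repeatability_report")
}

#' @export
print.repeatability_report <- function(x, ...) {
  cat("<repeatability_report>", sum(x$report$selected), "of",
      nrow(x$report), "features selected at r >", x$threshold, "\n")
  invisible(x)
}

#' Average the two readers' tables over the selected features
#'
#' The modeling table is the arithmetic mean of the reader values per subject
#' and key (the source analysis does not state which reader feeds the model;
#' averaging is the package default, `reader = 1` or `2` for sensitivity).
#'
#' @param table1,table2 per-reader matrices (identical dimnames).
#' @param selected_keys character vector of keys to retain (nonempty).
#' @param reader `"mean"` (default), `1`, or `2`.
#' @return numeric matrix, columns restricted to `selected_keys`.
#' @export
consensus_table <- function(table1, table2, selected_keys, reader = "mean") {
  if (length(selected_keys) == 0)
    stop("no features selected; relax the repeatability threshold")
  missing1 <- setdiff(selected_keys, colnames(table1))
  if (length(missing1)) stop("keys absent from tables: ", missing1[1], " ...")
  out <- switch(as.character(reader),
    mean = (table1[, selected_keys, drop = FALSE] +
            table2[, selected_keys, drop = FALSE]) / 2,
    "1" = table1[, selected_keys, drop = FALSE],
    "2" = table2[, selected_keys, drop = FALSE],
    stop("`reader` must be \"mean\", 1 or 2"))
  out
}

#' Mean absolute pairwise correlation among features
#'
#' Mean over all unordered feature pairs of |r|; the exploratory collinearity
#' summary that motivates a latent-component model.
#'
#' @param table numeric matrix with >= 2 non-constant columns and >= 3 rows.
#' @return scalar in [0, 1].
#' @export
mean_abs_correlation <- function(table) {
  if (nrow(table) < 3) stop("need >= 3 subjects")
  sds <- apply(table, 2, stats::sd)
  keep <- is.finite(sds) & sds > 0
  if (any(!keep)) warning(sum(!keep), " constant column(s) excluded")
  table <- table[, keep, drop = FALSE]
  if (ncol(table) < 2) stop("need >= 2 non-constant features")
  cm <- stats::cor(table)
  mean(abs(cm[upper.tri(cm)]))
}
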