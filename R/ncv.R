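# Leave-one-out nested cross-validation.
#
# Outer loop: hold out one subject; all preprocessing (z-scoring) and the PLS
# fit derive only from the remaining n-1. Inner loop: leave-one-out over those
# n-1 to pick the component count maximizing inner AUC (ties -> smallest k).
# The whole procedure is deterministic given the feature table and labels.

#' Select the PLS component count by inner leave-one-out AUC
#'
#' @param X_train numeric matrix (training subjects x features), already
#'   standardized.
#' @param y_train binary 0/1 outcome, both classes present.
#' @param k_grid candidate component counts (positive integers within bounds).
#' @return list: `k` (selected), `inner_auc` (named by k_grid).
#' @export
inner_select_k <- function(X_train, y_train, k_grid) {
  if (length(k_grid) == 0) stop("`k_grid` is empty")
  k_grid <- sort(unique(as.integer(k_grid)))
  n <- nrow(X_train)
  kmax_ok <- min(n - 2L, ncol(X_train))    # inner folds train on n-1 rows
  if (any(k_grid < 1) || any(k_grid > kmax_ok))
    stop("`k_grid` out of bounds for inner training size (max ", kmax_ok, ")")
  kmax <- max(k_grid)
  preds <- matrix(NA_real_, n, kmax)
  for (j in seq_len(n)) {
    pth <- .pls_path(X_train[-j, , drop = FALSE], as.numeric(y_train[-j]), kmax)
    preds[j, ] <- X_train[j, ] %*% pth$beta_path + pth$intercepts
  }
  inner_auc <- vapply(k_grid, function(k) roc_auc(preds[, k], y_train), 0)
  names(inner_auc) <- k_grid
  if (length(k_grid) > 1 && max(inner_auc) - min(inner_auc) < 1e-12)
    warning("inner AUC identical across k_grid; returning smallest k")
  list(k = k_grid[which.max(inner_auc)], inner_auc = inner_auc)
}

#' Leave-one-out nested cross-validation of the PLS classifier
#'
#' @param table numeric matrix (subjects x features), unstandardized; rows
#'   named by subject id.
#' @param labels binary 0/1 outcome per subject.
#' @param k_grid candidate component counts; default `1:min(30, n - 2, p)`.
#' @param global_zscore if TRUE, z-score once on the full cohort before
#'   splitting (the source analysis' convention); default FALSE refits the
#'   standardization inside every outer training fold (stricter, no leakage).
#' @param held_out_overrides optional named list mapping subject id to a
#'   replacement feature row, applied only when that subject is the held-out
#'   test case. Training folds always use the original table, so this is the
#'   lever for the no-leakage audit: overriding one subject may change only
#'   that subject's out-of-sample score.
#' @return object of class `ncv_result`: `scores` (one out-of-sample score per
#'   subject), `fold_k` (selected components per outer fold), `inner_auc`
#'   (folds x k_grid matrix), `labels`, `k_grid`.
#' @export
loo_ncv <- function(table, labels, k_grid = NULL, global_zscore = FALSE,
                    held_out_overrides = NULL) {
  table <- as.matrix(table)
  n <- nrow(table)
  if (n < 4) stop("need at least 4 subjects")
  if (length(labels) != n) stop("labels length must match rows")
  if (!all(labels %in% c(0, 1)) || length(unique(labels)) < 2)
    stop("labels must be binary 0/1 with both classes present")
  if (is.null(k_grid)) k_grid <- seq_len(min(30L, n - 2L, ncol(table)))
  k_grid <- sort(unique(as.integer(k_grid)))
  if (length(k_grid) == 0) stop("`k_grid` is empty")
  if (global_zscore) table <- zscore_columns(table)
  scores <- stats::setNames(numeric(n), rownames(table))
  fold_k <- stats::setNames(integer(n), rownames(table))
  inner_mat <- matrix(NA_real_, n, length(k_grid),
                      dimnames = list(rownames(table), k_grid))
  for (i in seq_len(n)) {
    ytr <- labels[-i]
    if (length(unique(ytr)) < 2)
      stop("outer training fold ", i, " contains a single class")
    raw_te <- table[i, , drop = FALSE]
    ov <- held_out_overrides[[rownames(table)[i] %||% i]]
    if (!is.null(ov)) raw_te[1, ] <- ov
    if (global_zscore) {
      Xtr <- table[-i, , drop = FALSE]
      Xte <- raw_te
    } else {
      z <- suppressWarnings(zscore_columns(table[-i, , drop = FALSE]))
      Xtr <- z
      Xte <- sweep(sweep(raw_te[, colnames(z), drop = FALSE], 2,
                         attr(z, "center")), 2, attr(z, "scale"), "/")
    }
    sel <- inner_select_k(Xtr, ytr, k_grid)
    fit <- fit_pls(Xtr, ytr, sel$k)
    scores[i] <- predict(fit, Xte)
    fold_k[i] <- sel$k
    inner_mat[i, ] <- sel$inner_auc
  }
  structure(list(scores = scores, fold_k = fold_k, inner_auc = inner_mat,
                 labels = labels, k_grid = k_grid),
            class = "ncv_result")
}

#' @export
print.ncv_result <- function(x, ...) {
  cat("<ncv_result>", length(x$scores), "outer folds; selected k:",
      paste(range(x$fold_k), collapse = ".."), "; out-of-sample AUC",
      round(roc_auc(x$scores, x$labels), 3), "\n")
  invisible(x)
}

#' Write nested-CV results as CSV (subject, score, fold k)
#' @param result an `ncv_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ncv_result <- function(result, path) {
  utils::write.csv(data.frame(subject = names(result$scores),
                              score = as.numeric(result$scores),
                              label = result$labels,
                              fold_k = as.integer(result$fold_k)),
                   path, row.names = FALSE)
  invisible(path)
}
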