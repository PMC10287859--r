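# Partial least squares (PLS1) regression of a binary outcome on a
# high-dimensional standardized feature table.
#
# NIPALS with the usual beta-path recursion: because P'W is unit upper
# triangular, the coefficient vector for every component count 1..k comes out
# of a single pass. With k = rank(X) and n > p the coefficients coincide with
# ordinary least squares (tested). Outcome coding is {0,1} with 1 = high risk,
# so a positive beta means higher predicted risk as the feature increases.

# single NIPALS pass; returns coefficient path and intercepts for 1..kmax
.pls_path <- function(X, y, kmax) {
  n <- nrow(X); p <- ncol(X)
  xm <- colMeans(X); ym <- mean(y)
  Xc <- X - rep(xm, each = n)
  yc <- y - ym
  # NIPALS scores are mutually orthogonal, so deflating y is unnecessary:
  # Xc' yc and yc' t are unchanged by previous components once X is deflated.
  beta_path <- matrix(0, p, kmax)
  intercepts <- numeric(kmax)
  Rmat <- matrix(0, p, kmax)
  Pmat <- matrix(0, p, kmax)
  beta <- numeric(p)
  a_done <- 0L
  for (a in seq_len(kmax)) {
    w <- crossprod(Xc, yc)[, 1]
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break                  # residual orthogonal to X: done
    w <- w / nw
    tt_vec <- Xc %*% w
    tt <- sum(tt_vec^2)
    if (tt < 1e-12) break
    pvec <- crossprod(Xc, tt_vec)[, 1] / tt
    qa <- sum(yc * tt_vec) / tt
    Xc <- Xc - tt_vec %*% t(pvec)
    r <- w
    if (a > 1) {
      prev <- seq_len(a - 1L)
      r <- w - Rmat[, prev, drop = FALSE] %*% crossprod(Pmat[, prev, drop = FALSE], w)[, 1]
    }
    Rmat[, a] <- r
    Pmat[, a] <- pvec
    beta <- beta + qa * r
    beta_path[, a] <- beta
    intercepts[a] <- ym - sum(xm * beta)
    a_done <- a
  }
  if (a_done < kmax) {                     # X exhausted: later ks equal last
    for (a in seq(a_done + 1L, kmax)) {
      beta_path[, a] <- beta_path[, max(a_done, 1L)]
      intercepts[a] <- if (a_done > 0) intercepts[a_done] else mean(y)
    }
  }
  list(beta_path = beta_path, intercepts = intercepts, n_effective = a_done)
}

#' Fit a PLS1 regression
#'
#' @param X numeric matrix (subjects x standardized features).
#' @param y binary outcome vector coded 0/1 (1 = high risk), both classes
#'   present.
#' @param k number of latent components, `1 <= k <= min(n - 1, p)`.
#' @return object of class `pls_fit` with `beta` (per-feature coefficients),
#'   `intercept`, `n_components`, `feature_keys`, and the full `beta_path`.
#' @export
fit_pls <- function(X, y, k) {
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop("rows(X) must equal length(y)")
  if (!all(y %in% c(0, 1))) stop("y must be coded 0/1")
  if (length(unique(y)) < 2) stop("y contains a single class; cannot fit")
  kmax_ok <- min(nrow(X) - 1L, ncol(X))
  if (!is.numeric(k) || k < 1 || k > kmax_ok)
    stop("`k` out of bounds: must be in 1..", kmax_ok)
  path <- .pls_path(X, as.numeric(y), as.integer(k))
  structure(list(beta = stats::setNames(path$beta_path[, k], colnames(X)),
                 intercept = path$intercepts[k],
                 n_components = as.integer(k),
                 feature_keys = colnames(X),
                 beta_path = path$beta_path,
                 intercepts = path$intercepts),
            class = "pls_fit")
}

#' Predict continuous risk scores from a PLS fit
#'
#' Scores are `intercept + X %*% beta`, unthresholded: they feed ROC analysis
#' directly.
#'
#' @param object a [fit_pls()] result.
#' @param newdata numeric matrix whose columns match the fit's feature keys.
#' @param ... unused.
#' @return numeric score vector.
#' @export
predict.pls_fit <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (!is.null(colnames(newdata)) && !is.null(object$feature_keys)) {
    if (!identical(colnames(newdata), object$feature_keys))
      stop("feature columns do not match the fitted model")
  } else if (ncol(newdata) != length(object$beta)) {
    stop("feature count mismatch: ", ncol(newdata), " vs ", length(object$beta))
  }
  as.numeric(object$intercept + newdata %*% object$beta)
}

#' @export
print.pls_fit <- function(x, ...) {
  cat("<pls_fit>", x$n_components, "components,", length(x$beta), "features\n")
  invisible(x)
}

#' Top fraction of features by |beta|
#'
#' Returns the `floor(fraction * n_features)` keys with the largest absolute
#' coefficients, sorted by decreasing |beta|; boundary ties are broken by
#' lexicographic key order so the list is deterministic.
#'
#' @param fit a `pls_fit`.
#' @param fraction fraction in (0, 1]; default 0.05 (the "top 5%").
#' @return character vector of ranked feature keys.
#' @export
top_beta_fraction <- function(fit, fraction = 0.05) {
  stopifnot(inherits(fit, "pls_fit"))
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1)
    stop("`fraction` must be in (0, 1]")
  keys <- fit$feature_keys
  if (is.null(keys)) keys <- as.character(seq_along(fit$beta))
  m <- floor(fraction * length(fit$beta))
  ord <- order(-abs(fit$beta), keys)
  keys[ord][seq_len(m)]
}

#' Profile a ranked feature list by provenance
#'
#' Tabulates counts by compartment (T vs TST), resolution, DCE phase, and
#' class group (first-order vs texture vs shape). Texture = the second-order
#' families glcm, glrlm, glszm, gldm, ngtdm.
#'
#' @param keys character feature keys with full provenance (see
#'   [feature_key()]).
#' @return list of named count vectors: `compartment`, `resolution_mm`,
#'   `phase`, `class_group`, plus `n` (list length).
#' @export
profile_top_features <- function(keys) {
  info <- parse_feature_keys(keys)
  grp <- ifelse(info$feature_class %in% c("glcm", "glrlm", "glszm", "gldm", "ngtdm"),
                "texture",
                ifelse(info$feature_class == "shape", "shape", "firstorder"))
  count <- function(v) { t <- table(v); stats::setNames(as.integer(t), names(t)) }
  list(n = length(keys),
       compartment = count(info$compartment),
       resolution_mm = count(info$resolution_mm),
       phase = count(info$phase),
       class_group = count(grp))
}
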