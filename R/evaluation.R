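# ROC/AUC and permutation-null significance.
#
# AUC is the Mann-Whitney concordance probability (ties count 1/2). The null
# is built by shuffling outcome labels against the *fixed* out-of-fold scores
# and recomputing AUC; the observed AUC is then expressed as a z-score against
# the null mean and standard deviation (n-1 denominator) with a one-sided
# upper-tail test, and as an empirical permutation p-value.

#' Area under the ROC curve
#'
#' @param scores numeric, finite; higher = more positive.
#' @param labels binary 0/1, both classes present.
#' @return AUC in [0, 1], equal to the tie-corrected Mann-Whitney
#'   concordance probability.
#' @export
roc_auc <- function(scores, labels) {
  if (length(scores) != length(labels)) stop("length mismatch")
  if (any(!is.finite(scores))) stop("scores must be finite")
  if (!all(labels %in% c(0, 1)) || length(unique(labels)) < 2)
    stop("labels must be binary 0/1 with both classes present")
  npos <- sum(labels == 1); nneg <- sum(labels == 0)
  rk <- rank(scores)                       # midranks handle ties as 1/2
  (sum(rk[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Permutation null distribution of the AUC
#'
#' Each replicate permutes the label vector uniformly at random against the
#' fixed scores and records the AUC. Equivalent to re-drawing which subjects
#' are "positive"; reproducible given `seed`.
#'
#' @param scores,labels as in [roc_auc()].
#' @param n_perm number of permutations (>= 1; use >= 1000 for p-values).
#' @param seed integer seed (local RNG).
#' @return object of class `permutation_null`: `null_auc`, `null_mean`,
#'   `null_sd` (n-1 denominator), `n_perm`, `seed`.
#' @export
permutation_null <- function(scores, labels, n_perm = 1e5, seed = 1) {
  roc_auc(scores, labels)                  # validates inputs
  if (n_perm < 1) stop("`n_perm` must be >= 1")
  rs <- .with_local_seed(seed)
  on.exit(rs())
  n <- length(scores)
  npos <- sum(labels == 1); nneg <- n - npos
  rk <- rank(scores)
  offset <- npos * (npos + 1) / 2
  denom <- npos * nneg
  null_auc <- vapply(seq_len(n_perm), function(b) {
    (sum(rk[sample.int(n, npos)]) - offset) / denom
  }, 0)
  structure(list(null_auc = null_auc, null_mean = mean(null_auc),
                 null_sd = stats::sd(null_auc), n_perm = as.integer(n_perm),
                 seed = as.integer(seed)),
            class = "permutation_null")
}

#' @export
print.permutation_null <- function(x, ...) {
  cat("<permutation_null>", x$n_perm, "permutations; mean",
      round(x$null_mean, 4), "sd", round(x$null_sd, 4), "\n")
  invisible(x)
}

#' Significance of an observed AUC against a permutation null
#'
#' @param observed_auc observed AUC.
#' @param null a [permutation_null()].
#' @param alpha decision threshold (default 0.05).
#' @return list: `z = (AUC - null mean)/null sd`, `p_normal` (upper-tail
#'   standard normal), `p_empirical = (1 + #\{null >= AUC\})/(1 + n_perm)`,
#'   `significant` (p_empirical < alpha), plus the inputs echoed.
#' @export
auc_significance <- function(observed_auc, null, alpha = 0.05) {
  stopifnot(inherits(null, "permutation_null"))
  if (length(unique(null$null_auc)) < 2 || null$null_sd == 0)
    stop("degenerate null distribution (zero spread)")
  z <- (observed_auc - null$null_mean) / null$null_sd
  p_normal <- stats::pnorm(z, lower.tail = FALSE)
  p_empirical <- (1 + sum(null$null_auc >= observed_auc)) / (1 + null$n_perm)
  list(auc = observed_auc, z = z, p_normal = p_normal,
       p_empirical = p_empirical, alpha = alpha,
       significant = p_empirical < alpha,
       null_mean = null$null_mean, null_sd = null$null_sd,
       n_perm = null$n_perm)
}
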