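# PLS1 regression, beta ranking, provenance profiling.

sim_xy <- function(n, p, seed = 1) {
  set.seed(seed)
  X <- matrix(stats::rnorm(n * p), n, p,
              dimnames = list(NULL, sprintf("f%02d", 1:p)))
  y <- as.integer(X[, 1] + 0.5 * X[, 2] + stats::rnorm(n, 0, 0.3) > 0)
  list(X = X, y = y)
}

test_that("PLS at full rank equals the normal-equations OLS solution", {
  for (seed in 1:3) {
    d <- sim_xy(20, 5, seed)
    fit <- fit_pls(d$X, d$y, k = 5)
    # independent oracle: solve X'X beta = X'y on centred data
    Xc <- scale(d$X, scale = FALSE)
    yc <- d$y - mean(d$y)
    beta_ols <- solve(crossprod(Xc), crossprod(Xc, yc))[, 1]
    expect_equal(unname(fit$beta), unname(beta_ols), tolerance = 1e-8)
    expect_equal(fit$intercept, mean(d$y) - sum(colMeans(d$X) * beta_ols),
                 tolerance = 1e-8)
  }
})

test_that("an outcome equal to a single standardized column is recovered", {
  set.seed(2)
  y <- rep(c(0L, 1L), 15)
  # p = 1: the k = 1 training predictions correlate exactly with y
  X1 <- matrix(scale(y + 0), 30, 1, dimnames = list(NULL, "f01"))
  fit1 <- fit_pls(X1, y, k = 1)
  expect_equal(stats::cor(predict(fit1, X1), y), 1.0)

  # two orthonormal columns, y = first column: first weight vector aligns
  # with that column (up to sign)
  Q <- qr.Q(qr(matrix(stats::rnorm(30 * 2), 30, 2)))
  yq <- Q[, 1]
  w <- crossprod(scale(Q, scale = FALSE), yq - mean(yq))[, 1]
  w <- w / sqrt(sum(w^2))
  expect_gt(abs(w[1]), 0.999)

  # with extra noise columns the correlation is high but not exact
  Xn <- cbind(X1, matrix(stats::rnorm(30 * 3), 30, 3))
  colnames(Xn) <- sprintf("f%02d", 1:4)
  fitn <- fit_pls(scale(Xn), y, k = 1)
  expect_gt(stats::cor(predict(fitn, scale(Xn)), y), 0.95)
})

test_that("prediction is the linear score intercept + X beta", {
  fit <- structure(list(beta = c(a = 2, b = -1), intercept = 0.5,
                        n_components = 1L, feature_keys = c("a", "b")),
                   class = "pls_fit")
  X <- matrix(c(1, 3, 2, -1), 2, 2, dimnames = list(NULL, c("a", "b")))
  expect_equal(predict(fit, X), c(0.5 + 2 * 1 - 2, 0.5 + 6 + 1))  # by hand
  X0 <- matrix(0, 2, 2, dimnames = list(NULL, c("a", "b")))
  expect_equal(predict(fit, X0), c(0.5, 0.5))
  bad <- matrix(0, 2, 2, dimnames = list(NULL, c("a", "c")))
  expect_error(predict(fit, bad), "match")
})

test_that("training RSS is non-increasing in the component count", {
  d <- sim_xy(25, 10, seed = 4)
  rss <- vapply(1:8, function(k) {
    fit <- fit_pls(d$X, d$y, k)
    sum((d$y - predict(fit, d$X))^2)
  }, 0)
  expect_true(all(diff(rss) <= 1e-10))
})

test_that("negating a feature column negates its beta, predictions unchanged", {
  d <- sim_xy(20, 6, seed = 5)
  f1 <- fit_pls(d$X, d$y, 3)
  X2 <- d$X; X2[, 2] <- -X2[, 2]
  f2 <- fit_pls(X2, d$y, 3)
  expect_equal(f2$beta[2], -f1$beta[2], tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(f2$beta[-2], f1$beta[-2], tolerance = 1e-10)
  expect_equal(predict(f2, X2), predict(f1, d$X), tolerance = 1e-10)
})

test_that("fit_pls validates its inputs", {
  d <- sim_xy(10, 3)
  expect_error(fit_pls(d$X, rep(1, 10), 1), "single class")
  expect_error(fit_pls(d$X, d$y, 0), "out of bounds")
  expect_error(fit_pls(d$X, d$y, 10), "out of bounds")
  expect_error(fit_pls(d$X, c(d$y[-1], 2), 1), "0/1")
})

test_that("top_beta_fraction counts, ordering and tie-breaking are exact", {
  # 940 features -> floor(0.05 * 940) = 47
  set.seed(6)
  X <- matrix(stats::rnorm(50 * 940), 50, 940,
              dimnames = list(NULL, sprintf("k%04d", 1:940)))
  y <- as.integer(stats::rnorm(50) + X[, 1] > 0)
  fit <- fit_pls(X, y, 3)
  top <- top_beta_fraction(fit, 0.05)
  expect_length(top, 47)
  expect_true(all(abs(fit$beta[top]) >= max(abs(fit$beta[setdiff(names(fit$beta), top)]))))

  fit100 <- structure(list(beta = stats::setNames(stats::rnorm(100), sprintf("f%03d", 1:100)),
                           feature_keys = sprintf("f%03d", 1:100)), class = "pls_fit")
  expect_length(top_beta_fraction(fit100, 0.05), 5)

  # all-equal magnitudes: lexicographically first floor(0.5*6)=3 keys, stable
  keys <- c("delta", "alpha", "echo", "bravo", "charlie", "foxtrot")
  ftie <- structure(list(beta = stats::setNames(c(1, -1, 1, -1, 1, 1), keys),
                         feature_keys = keys), class = "pls_fit")
  expect_equal(top_beta_fraction(ftie, 0.5), c("alpha", "bravo", "charlie"))
  expect_error(top_beta_fraction(ftie, 0), "fraction")
  expect_error(top_beta_fraction(ftie, 1.2), "fraction")
})

test_that("provenance profile counts are conserved and correct", {
  keys <- c(
    feature_key("peak", "TST", 1, "original", "glcm", "Contrast"),
    feature_key("early", "T", 2, "wavelet-LLH", "firstorder", "Mean"),
    feature_key("peak", "T", 1, "original", "shape", "Sphericity"),
    feature_key("peak", "TST", 3, "gradient", "gldm", "GrayLevelVariance")
  )
  pr <- profile_top_features(keys)
  expect_equal(pr$n, 4)
  expect_equal(sum(pr$compartment), 4)
  expect_equal(sum(pr$phase), 4)
  expect_equal(sum(pr$resolution_mm), 4)
  expect_equal(sum(pr$class_group), 4)
  expect_equal(pr$compartment[["TST"]], 2L)
  expect_equal(pr$class_group[["texture"]], 2L)
  expect_equal(pr$class_group[["shape"]], 1L)

  one <- profile_top_features(feature_key("peak", "TST", 1, "original", "glcm", "X"))
  expect_equal(unname(one$compartment), 1L)
  expect_equal(names(one$phase), "peak")

  # tabulation oracle on a generated list
  set.seed(7)
  many <- replicate(40, feature_key(sample(c("early", "peak"), 1),
                                    sample(c("T", "TST"), 1),
                                    sample(1:3, 1), "original",
                                    sample(c("glcm", "firstorder"), 1), "F"))
  pr2 <- profile_top_features(many)
  oracle <- table(vapply(strsplit(many, "|", fixed = TRUE), `[`, "", 2))
  expect_equal(pr2$compartment, stats::setNames(as.integer(oracle), names(oracle)))
})
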