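# Texture (second-order) feature families: GLCM, GLRLM, GLSZM, GLDM, NGTDM.
#
# All operate on a gray-level array discretized with a fixed bin width whose
# first bin edge sits at the in-mask minimum (hence intensity-shift invariant).
# Voxels outside the mask are NA and break co-occurrences, runs and zones.
# Degenerate inputs (single gray level, no valid pairs) follow the conventions
# noted at each feature; values may be NaN, which the cohort layer drops
# column-wise before modeling.

# 13 unique direction offsets covering the 26-neighbourhood up to sign
.directions13 <- function() {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  g <- g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ]
  keep <- g$dz > 0 | (g$dz == 0 & g$dy > 0) | (g$dz == 0 & g$dy == 0 & g$dx > 0)
  as.matrix(g[keep, ])
}

#' Discretize in-mask intensities into gray levels
#'
#' Bin index = `floor((x - min) / bin_width) + 1`, with the first edge anchored
#' at the in-mask minimum, so adding a constant to the image leaves all
#' discretized texture features unchanged.
#'
#' @param values numeric 3D array.
#' @param inmask logical 3D array, same dim.
#' @param bin_width positive bin width in intensity units.
#' @return integer array of gray levels (NA outside mask).
#' @export
discretize_gray_levels <- function(values, inmask, bin_width) {
  if (bin_width <= 0) stop("`bin_width` must be > 0")
  lv <- array(NA_integer_, dim = dim(values))
  x <- values[inmask]
  lv[inmask] <- as.integer(floor((x - min(x)) / bin_width + 1e-9)) + 1L
  lv
}

# paired gray levels for one direction offset: rows (from, to)
.offset_pairs <- function(lv, o) {
  dm <- dim(lv)
  sx <- max(1L, 1L - o[1]):min(dm[1], dm[1] - o[1])
  sy <- max(1L, 1L - o[2]):min(dm[2], dm[2] - o[2])
  sz <- max(1L, 1L - o[3]):min(dm[3], dm[3] - o[3])
  a <- lv[sx, sy, sz, drop = FALSE]
  b <- lv[sx + o[1], sy + o[2], sz + o[3], drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  cbind(a[ok], b[ok])
}

# --- GLCM --------------------------------------------------------------------

.glcm_features_one <- function(P) {
  # P: symmetric co-occurrence count matrix with integer gray values as names
  tot <- sum(P)
  out <- rep(NaN, 24)
  names(out) <- .glcm_names
  if (tot == 0) return(out)
  p <- P / tot
  iv <- as.numeric(rownames(P))
  Ng <- length(iv)
  px <- rowSums(p); py <- colSums(p)
  mux <- sum(iv * px); muy <- sum(iv * py)
  sx <- sqrt(sum((iv - mux)^2 * px)); sy <- sqrt(sum((iv - muy)^2 * py))
  I <- matrix(iv, Ng, Ng); J <- t(I)
  ipj <- I + J; imj <- abs(I - J)
  # p_{x+y} and p_{x-y}
  kd <- sort(unique(as.vector(imj)))
  pd <- vapply(kd, function(k) sum(p[imj == k]), 0)
  ks <- sort(unique(as.vector(ipj)))
  ps <- vapply(ks, function(k) sum(p[ipj == k]), 0)
  l2 <- function(q) { q <- q[q > 0]; -sum(q * log2(q)) }
  out["Autocorrelation"] <- sum(I * J * p)
  out["JointAverage"] <- sum(I * p)
  mu2 <- mux + muy
  out["ClusterProminence"] <- sum((ipj - mu2)^4 * p)
  out["ClusterShade"] <- sum((ipj - mu2)^3 * p)
  out["ClusterTendency"] <- sum((ipj - mu2)^2 * p)
  out["Contrast"] <- sum((I - J)^2 * p)
  out["Correlation"] <- if (sx * sy > 0) (sum(I * J * p) - mux * muy) / (sx * sy) else 1
  da <- sum(kd * pd)
  out["DifferenceAverage"] <- da
  out["DifferenceEntropy"] <- l2(pd)
  out["DifferenceVariance"] <- sum((kd - da)^2 * pd)
  out["Id"] <- sum(pd / (1 + kd))
  out["Idm"] <- sum(pd / (1 + kd^2))
  out["Idmn"] <- sum(pd / (1 + (kd / Ng)^2))
  out["Idn"] <- sum(pd / (1 + kd / Ng))
  hxy <- l2(p)
  pxy_prod <- outer(px, py)
  hxy1 <- -sum(p[pxy_prod > 0] * log2(pxy_prod[pxy_prod > 0]))
  hxy2 <- l2(pxy_prod)
  hx <- l2(px); hy <- l2(py)
  out["Imc1"] <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
  out["Imc2"] <- sqrt(pmax(0, 1 - exp(-2 * (hxy2 - hxy))))
  iv_pos <- kd > 0
  out["InverseVariance"] <- if (any(iv_pos)) sum(pd[iv_pos] / kd[iv_pos]^2) else 0
  out["JointEnergy"] <- sum(p^2)
  out["JointEntropy"] <- hxy
  out["MaximumProbability"] <- max(p)
  out["MCC"] <- .glcm_mcc(p, px, py)
  out["SumAverage"] <- sum(ks * ps)
  out["SumEntropy"] <- l2(ps)
  out["SumSquares"] <- sum((I - mux)^2 * p)
  out
}

.glcm_mcc <- function(p, px, py) {
  # Q(i,j) = sum_k p(i,k) p(j,k) / (px(i) py(k)); MCC = sqrt(2nd eigenvalue)
  Ng <- length(px)
  if (Ng == 1) return(1)
  B <- sweep(p, 2, ifelse(py > 0, py, 1), "/")
  Q <- (B %*% t(p)) / ifelse(px > 0, px, 1)
  ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
  sqrt(max(0, ev[2]))
}

.glcm_names <- c("Autocorrelation", "ClusterProminence", "ClusterShade",
  "ClusterTendency", "Contrast", "Correlation", "DifferenceAverage",
  "DifferenceEntropy", "DifferenceVariance", "Id", "Idm", "Idmn", "Idn",
  "Imc1", "Imc2", "InverseVariance", "JointAverage", "JointEnergy",
  "JointEntropy", "MCC", "MaximumProbability", "SumAverage", "SumEntropy",
  "SumSquares")

glcm_features <- function(lv) {
  dirs <- .directions13()
  maxlev <- max(lv, na.rm = TRUE)
  acc <- NULL
  n_dir <- 0L
  for (r in seq_len(nrow(dirs))) {
    pr <- .offset_pairs(lv, dirs[r, ])
    if (nrow(pr) == 0) next
    cnt <- matrix(tabulate(pr[, 1] + (pr[, 2] - 1L) * maxlev, nbins = maxlev^2),
                  maxlev, maxlev)
    cnt <- cnt + t(cnt)  # symmetric GLCM
    obs <- which(rowSums(cnt) + colSums(cnt) > 0)
    P <- cnt[obs, obs, drop = FALSE]
    dimnames(P) <- list(obs, obs)
    f <- .glcm_features_one(P)
    acc <- if (is.null(acc)) f else acc + f
    n_dir <- n_dir + 1L
  }
  if (n_dir == 0L) { f <- rep(NaN, 24); names(f) <- .glcm_names; return(f) }
  acc / n_dir
}

# --- generalized gray-level x size matrix features ---------------------------

# P: counts over (gray level value i, size s); used by GLRLM / GLSZM / GLDM.
# Returns the 16 canonical components named small/large/gln/glnn/szn/sznn/
# pct/glv/szv/ent/lgl/hgl/sl/sh/ll/lh; each family maps a subset to its names.
.gls_components <- c("small", "large", "gln", "glnn", "szn", "sznn", "pct",
                     "glv", "szv", "ent", "lgl", "hgl", "sl", "sh", "ll", "lh")
.gls_features <- function(P, iv, sv, Np) {
  Nz <- sum(P)
  if (Nz == 0) {
    out <- rep(NaN, length(.gls_components)); names(out) <- .gls_components
    return(out)
  }
  p <- P / Nz
  gl_marg <- rowSums(P); sz_marg <- colSums(P)
  I <- matrix(iv, length(iv), length(sv)); S <- matrix(sv, length(iv), length(sv), byrow = TRUE)
  mu_i <- sum(p * I); mu_s <- sum(p * S)
  l2 <- function(q) { q <- q[q > 0]; -sum(q * log2(q)) }
  vals <- c(
    small = sum(P / S^2) / Nz,
    large = sum(P * S^2) / Nz,
    gln = sum(gl_marg^2) / Nz,
    glnn = sum(gl_marg^2) / Nz^2,
    szn = sum(sz_marg^2) / Nz,
    sznn = sum(sz_marg^2) / Nz^2,
    pct = Nz / Np,
    glv = sum(p * (I - mu_i)^2),
    szv = sum(p * (S - mu_s)^2),
    ent = l2(p),
    lgl = sum(P / I^2) / Nz,
    hgl = sum(P * I^2) / Nz,
    sl = sum(P / (I^2 * S^2)) / Nz,
    sh = sum(P * I^2 / S^2) / Nz,
    ll = sum(P * S^2 / I^2) / Nz,
    lh = sum(P * I^2 * S^2) / Nz
  )
  vals
}

.size_matrix_from_pairs <- function(levels, sizes) {
  iv <- sort(unique(levels)); sv <- sort(unique(sizes))
  tab <- table(factor(levels, levels = iv), factor(sizes, levels = sv))
  list(P = matrix(as.numeric(tab), length(iv), length(sv)), iv = iv, sv = sv)
}

glrlm_names <- c("ShortRunEmphasis", "LongRunEmphasis", "GrayLevelNonUniformity",
  "GrayLevelNonUniformityNormalized", "RunLengthNonUniformity",
  "RunLengthNonUniformityNormalized", "RunPercentage", "GrayLevelVariance",
  "RunVariance", "RunEntropy", "LowGrayLevelRunEmphasis",
  "HighGrayLevelRunEmphasis", "ShortRunLowGrayLevelEmphasis",
  "ShortRunHighGrayLevelEmphasis", "LongRunLowGrayLevelEmphasis",
  "LongRunHighGrayLevelEmphasis")

.map_gls <- function(vals, which_names,
                     sel = c("small", "large", "gln", "glnn", "szn", "sznn",
                             "pct", "glv", "szv", "ent", "lgl", "hgl",
                             "sl", "sh", "ll", "lh")) {
  out <- as.numeric(vals[sel]); names(out) <- which_names; out
}

glrlm_features <- function(lv) {
  dirs <- .directions13()
  Np <- sum(!is.na(lv))
  vox <- which(!is.na(lv), arr.ind = TRUE)
  lev <- lv[!is.na(lv)]
  acc <- NULL; n_dir <- 0L
  for (r in seq_len(nrow(dirs))) {
    d <- dirs[r, ]
    t_along <- vox %*% d
    k1 <- vox[, 1] * d[2] - vox[, 2] * d[1]
    k2 <- vox[, 2] * d[3] - vox[, 3] * d[2]
    k3 <- vox[, 1] * d[3] - vox[, 3] * d[1]
    ord <- order(k1, k2, k3, t_along)
    tl <- t_along[ord]; lo <- lev[ord]
    step <- sum(d^2)
    newrun <- c(TRUE, k1[ord][-1] != k1[ord][-Np] |
                  k2[ord][-1] != k2[ord][-Np] |
                  k3[ord][-1] != k3[ord][-Np] |
                  lo[-1] != lo[-Np] |
                  (tl[-1] - tl[-Np]) != step)
    starts <- which(newrun)
    lens <- diff(c(starts, Np + 1L))
    rl_lev <- lo[starts]
    sm <- .size_matrix_from_pairs(rl_lev, lens)
    vals <- .gls_features(sm$P, sm$iv, sm$sv, Np)
    acc <- if (is.null(acc)) vals else acc + vals
    n_dir <- n_dir + 1L
  }
  .map_gls(acc / n_dir, glrlm_names)
}

glszm_names <- c("SmallAreaEmphasis", "LargeAreaEmphasis", "GrayLevelNonUniformity",
  "GrayLevelNonUniformityNormalized", "SizeZoneNonUniformity",
  "SizeZoneNonUniformityNormalized", "ZonePercentage", "GrayLevelVariance",
  "ZoneVariance", "ZoneEntropy", "LowGrayLevelZoneEmphasis",
  "HighGrayLevelZoneEmphasis", "SmallAreaLowGrayLevelEmphasis",
  "SmallAreaHighGrayLevelEmphasis", "LargeAreaLowGrayLevelEmphasis",
  "LargeAreaHighGrayLevelEmphasis")

# 26-connected same-gray-level zones via union-find on adjacency edges
.zone_partition <- function(lv) {
  dm <- dim(lv)
  inm <- !is.na(lv)
  nv <- sum(inm)
  idx <- array(NA_integer_, dim = dm)
  idx[inm] <- seq_len(nv)
  dirs <- .directions13()
  ea <- integer(0); eb <- integer(0)
  for (r in seq_len(nrow(dirs))) {
    o <- dirs[r, ]
    sx <- max(1L, 1L - o[1]):min(dm[1], dm[1] - o[1])
    sy <- max(1L, 1L - o[2]):min(dm[2], dm[2] - o[2])
    sz <- max(1L, 1L - o[3]):min(dm[3], dm[3] - o[3])
    a <- lv[sx, sy, sz, drop = FALSE]
    b <- lv[sx + o[1], sy + o[2], sz + o[3], drop = FALSE]
    ok <- !is.na(a) & !is.na(b) & a == b
    if (!any(ok)) next
    ia <- idx[sx, sy, sz, drop = FALSE][ok]
    ib <- idx[sx + o[1], sy + o[2], sz + o[3], drop = FALSE][ok]
    ea <- c(ea, ia); eb <- c(eb, ib)
  }
  parent <- seq_len(nv)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (e in seq_along(ea)) {
    ra <- find(ea[e]); rb <- find(eb[e])
    if (ra != rb) parent[if (ra < rb) rb else ra] <- min(ra, rb)
  }
  root <- vapply(seq_len(nv), find, 0L)
  list(zone = root, level = lv[inm])
}

glszm_features <- function(lv) {
  Np <- sum(!is.na(lv))
  zp <- .zone_partition(lv)
  spl <- split(zp$level, zp$zone)          # one entry per zone
  sizes <- lengths(spl)
  zone_lev <- vapply(spl, function(z) z[1], 0L)
  sm <- .size_matrix_from_pairs(as.integer(zone_lev), as.integer(sizes))
  vals <- .gls_features(sm$P, sm$iv, sm$sv, Np)
  .map_gls(vals, glszm_names)
}

gldm_names <- c("SmallDependenceEmphasis", "LargeDependenceEmphasis",
  "GrayLevelNonUniformity", "DependenceNonUniformity",
  "DependenceNonUniformityNormalized", "GrayLevelVariance",
  "DependenceVariance", "DependenceEntropy", "LowGrayLevelEmphasis",
  "HighGrayLevelEmphasis", "SmallDependenceLowGrayLevelEmphasis",
  "SmallDependenceHighGrayLevelEmphasis",
  "LargeDependenceLowGrayLevelEmphasis",
  "LargeDependenceHighGrayLevelEmphasis")

gldm_features <- function(lv, alpha = 0) {
  dm <- dim(lv)
  dirs <- .directions13()
  offsets <- rbind(dirs, -dirs)
  dep <- array(0L, dim = dm)
  for (r in seq_len(nrow(offsets))) {
    o <- offsets[r, ]
    sx <- max(1L, 1L - o[1]):min(dm[1], dm[1] - o[1])
    sy <- max(1L, 1L - o[2]):min(dm[2], dm[2] - o[2])
    sz <- max(1L, 1L - o[3]):min(dm[3], dm[3] - o[3])
    a <- lv[sx, sy, sz, drop = FALSE]
    b <- lv[sx + o[1], sy + o[2], sz + o[3], drop = FALSE]
    inc <- array(0L, dim = dim(a))
    ok <- !is.na(a) & !is.na(b) & abs(a - b) <= alpha
    inc[ok] <- 1L
    dep[sx, sy, sz] <- dep[sx, sy, sz] + inc
  }
  ok <- !is.na(lv)
  Np <- sum(ok)
  # dependence size = number of dependent neighbours + 1 (so sizes start at 1)
  sm <- .size_matrix_from_pairs(lv[ok], dep[ok] + 1L)
  vals <- .gls_features(sm$P, sm$iv, sm$sv, Np)
  .map_gls(vals, gldm_names,
           sel = c("small", "large", "gln", "szn", "sznn", "glv", "szv",
                   "ent", "lgl", "hgl", "sl", "sh", "ll", "lh"))
}

ngtdm_names <- c("Coarseness", "Contrast", "Busyness", "Complexity", "Strength")

ngtdm_features <- function(lv) {
  dm <- dim(lv)
  dirs <- .directions13()
  offsets <- rbind(dirs, -dirs)
  nsum <- array(0, dim = dm); ncnt <- array(0L, dim = dm)
  for (r in seq_len(nrow(offsets))) {
    o <- offsets[r, ]
    sx <- max(1L, 1L - o[1]):min(dm[1], dm[1] - o[1])
    sy <- max(1L, 1L - o[2]):min(dm[2], dm[2] - o[2])
    sz <- max(1L, 1L - o[3]):min(dm[3], dm[3] - o[3])
    b <- lv[sx + o[1], sy + o[2], sz + o[3], drop = FALSE]
    okb <- !is.na(b)
    add <- array(0, dim = dim(b)); add[okb] <- b[okb]
    nsum[sx, sy, sz] <- nsum[sx, sy, sz] + add
    ncnt[sx, sy, sz] <- ncnt[sx, sy, sz] + okb
  }
  ok <- !is.na(lv) & ncnt > 0
  N <- sum(ok)
  out <- rep(NaN, 5); names(out) <- ngtdm_names
  if (N == 0) return(out)
  lev <- lv[ok]
  abar <- nsum[ok] / ncnt[ok]
  iv <- sort(unique(lev))
  n_i <- vapply(iv, function(i) sum(lev == i), 0)
  s_i <- vapply(iv, function(i) sum(abs(i - abar[lev == i])), 0)
  p_i <- n_i / N
  Ngp <- length(iv)
  den_coarse <- sum(p_i * s_i)
  out["Coarseness"] <- if (den_coarse > 0) 1 / den_coarse else 1e6
  out["Contrast"] <- if (Ngp > 1) {
    sum(outer(p_i, p_i) * outer(iv, iv, "-")^2) / (Ngp * (Ngp - 1)) * sum(s_i) / N
  } else 0
  bus_den <- sum(abs(outer(iv * p_i, iv * p_i, "-")))
  out["Busyness"] <- if (bus_den > 0) sum(p_i * s_i) / bus_den else 0
  PI <- outer(p_i, p_i, "+")
  psps <- outer(p_i * s_i, p_i * s_i, "+")
  DIJ <- abs(outer(iv, iv, "-"))
  out["Complexity"] <- sum(DIJ * psps / PI) / N
  str_num <- sum(PI * outer(iv, iv, "-")^2)
  out["Strength"] <- if (sum(s_i) > 0) str_num / sum(s_i) else 0
  out
}
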