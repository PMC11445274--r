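# Independent brute-force oracles for radiomics and majority voting.
# These deliberately share nothing with the package implementation beyond
# the documented conventions (type-7 percentiles, fixed-bin-count
# discretization, population moments, log2 entropies, Ng = bin count).

oracle_discretize <- function(vals, bins = 32L) {
  rng <- range(vals)
  if (rng[1] == rng[2]) return(list(lev = rep(1L, length(vals)), ng = 1L))
  w <- (rng[2] - rng[1]) / bins
  list(lev = pmin(as.integer(floor((vals - rng[1]) / w)) + 1L, bins),
       ng = bins)
}

oracle_first_order <- function(vals, bins = 32L, voxvol = 1) {
  n <- length(vals)
  mu <- sum(vals) / n
  q <- stats::quantile(vals, c(.1, .25, .5, .75, .9), names = FALSE, type = 7)
  d <- oracle_discretize(vals, bins)
  p <- as.numeric(table(factor(d$lev, levels = seq_len(d$ng)))) / n
  p <- p[p > 0]
  rob <- vals[vals >= q[1] & vals <= q[5]]
  m2 <- sum((vals - mu)^2) / n
  c(energy = sum(vals^2),
    total_energy = voxvol * sum(vals^2),
    entropy = -sum(p * log2(p)),
    minimum = min(vals), p10 = q[1], p90 = q[5], maximum = max(vals),
    mean = mu, median = q[3], iqr = q[4] - q[2],
    range = diff(range(vals)),
    mad = sum(abs(vals - mu)) / n,
    rmad = if (length(rob)) sum(abs(rob - mean(rob))) / length(rob) else 0,
    rms = sqrt(sum(vals^2) / n),
    skewness = if (m2 > 0) e1071::skewness(vals, type = 1) else 0,
    kurtosis = if (m2 > 0) e1071::kurtosis(vals, type = 1) + 3 else 0,
    variance = m2,
    uniformity = sum(p^2))
}

oracle_glcm_directions <- function() {
  out <- NULL
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    o <- c(dx, dy, dz)
    nz <- which(o != 0)
    if (length(nz) && o[nz[1]] > 0) out <- rbind(out, o)
  }
  out
}

# all-ordered-pairs co-occurrence counting over the voxel set: enumerate
# every (a, b) pair whose coordinate difference equals the offset
oracle_glcm_matrix <- function(coords, lev, ng, offset) {
  d <- function(k) outer(coords[, k], coords[, k],
                         function(a, b) b - a)   # [a, b] = coord(b) - coord(a)
  hit <- d(1) == offset[1] & d(2) == offset[2] & d(3) == offset[3]
  pairs <- which(hit, arr.ind = TRUE)
  P <- matrix(0, ng, ng)
  for (r in seq_len(nrow(pairs))) {
    a <- pairs[r, 1]; b <- pairs[r, 2]
    P[lev[a], lev[b]] <- P[lev[a], lev[b]] + 1
    P[lev[b], lev[a]] <- P[lev[b], lev[a]] + 1    # symmetric accumulation
  }
  P
}

oracle_glcm_features_one <- function(P) {
  ng <- nrow(P)
  P <- P / sum(P)
  px <- rowSums(P); py <- colSums(P)
  lv <- seq_len(ng)
  mux <- sum(lv * px); muy <- sum(lv * py)
  sx <- sqrt(sum((lv - mux)^2 * px)); sy <- sqrt(sum((lv - muy)^2 * py))
  l2 <- function(v) ifelse(v > 0, log2(v), 0)
  ac <- 0; cp <- 0; cs <- 0; ct <- 0; con <- 0; idv <- 0; idnv <- 0
  idm <- 0; idmn <- 0; invv <- 0; ss <- 0; je <- 0; jent <- 0
  for (i in lv) for (j in lv) {
    pij <- P[i, j]
    ac <- ac + i * j * pij
    cp <- cp + (i + j - mux - muy)^4 * pij
    cs <- cs + (i + j - mux - muy)^3 * pij
    ct <- ct + (i + j - mux - muy)^2 * pij
    con <- con + (i - j)^2 * pij
    idv <- idv + pij / (1 + abs(i - j))
    idnv <- idnv + pij / (1 + abs(i - j) / ng)
    idm <- idm + pij / (1 + (i - j)^2)
    idmn <- idmn + pij / (1 + (i - j)^2 / ng^2)
    if (i != j) invv <- invv + pij / (i - j)^2
    ss <- ss + (i - mux)^2 * pij
    je <- je + pij^2
    jent <- jent - pij * l2(pij)
  }
  psum <- sapply(2:(2 * ng), function(k) sum(P[outer(lv, lv, `+`) == k]))
  pdif <- sapply(0:(ng - 1), function(k) sum(P[abs(outer(lv, lv, `-`)) == k]))
  da <- sum((0:(ng - 1)) * pdif)
  HX <- -sum(px * l2(px)); HY <- -sum(py * l2(py))
  HXY1 <- 0; HXY2 <- 0
  for (i in lv) for (j in lv) {
    HXY1 <- HXY1 - P[i, j] * l2(px[i] * py[j])
    HXY2 <- HXY2 - px[i] * py[j] * l2(px[i] * py[j])
  }
  keep <- which(px > 0)
  mcc <- if (length(keep) < 2) 1 else {
    Q <- matrix(0, length(keep), length(keep))
    for (ii in seq_along(keep)) for (jj in seq_along(keep))
      Q[ii, jj] <- sum(P[keep[ii], keep] * P[keep[jj], keep] /
                         (px[keep[ii]] * py[keep]))
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    sqrt(max(0, min(1, ev[2])))
  }
  c(autocorrelation = ac, joint_average = mux, cluster_prominence = cp,
    cluster_shade = cs, cluster_tendency = ct, contrast = con,
    correlation = if (sx > 0 && sy > 0) (ac - mux * muy) / (sx * sy) else 1,
    difference_average = da,
    difference_entropy = -sum(pdif * l2(pdif)),
    difference_variance = sum(((0:(ng - 1)) - da)^2 * pdif),
    joint_energy = je, joint_entropy = jent,
    imc1 = if (max(HX, HY) > 0) (jent - HXY1) / max(HX, HY) else 0,
    imc2 = sqrt(max(0, 1 - exp(-2 * (HXY2 - jent)))),
    inverse_difference = idv, idn = idnv,
    inverse_difference_moment = idm, idmn = idmn,
    inverse_variance = invv, maximum_probability = max(P),
    sum_average = sum((2:(2 * ng)) * psum),
    sum_entropy = -sum(psum * l2(psum)),
    sum_of_squares = ss, mcc = mcc)
}

oracle_glcm_features <- function(vol, idx, bins = 32L) {
  vals <- as.numeric(vol[idx])
  d <- oracle_discretize(vals, bins)
  coords <- arrayInd(idx, dim(vol))
  dirs <- oracle_glcm_directions()
  acc <- NULL
  for (r in seq_len(nrow(dirs))) {
    P <- oracle_glcm_matrix(coords, d$lev, d$ng, dirs[r, ])
    if (sum(P) == 0) next
    acc <- rbind(acc, oracle_glcm_features_one(P))
  }
  colMeans(acc)
}

# per-id label histogram by explicit looping
oracle_majority <- function(ids_vol, labels_vol) {
  out <- NULL
  for (id in sort(unique(ids_vol[ids_vol > 0]))) {
    labs <- labels_vol[ids_vol == id]
    n_tp <- 0; n_psp <- 0
    for (l in labs) {
      if (l == 1) n_tp <- n_tp + 1
      if (l == 2) n_psp <- n_psp + 1
    }
    out <- rbind(out, data.frame(
      svx_id = id, n_tp = n_tp, n_psp = n_psp,
      label = if (n_tp >= n_psp) "TP" else "PsP",
      majority_fraction = max(n_tp, n_psp) / (n_tp + n_psp)))
  }
  out
}
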