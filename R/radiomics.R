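#' Gray-level discretization specification
#'
#' Intensities are discretized per supervoxel and per channel before
#' histogram-based first-order features (entropy, uniformity) and all GLCM
#' features. Fixed bin count (default 32) is used because supervoxels are
#' small (~200 voxels) and each channel spans a different range.
#'
#' @param mode `"fixed-bin-count"` or `"fixed-bin-width"`.
#' @param bins bin count (mode `"fixed-bin-count"`; >= 2).
#' @param width bin width (mode `"fixed-bin-width"`; > 0).
#' @return An object of class `discretization_spec`.
#' @export
discretization_spec <- function(mode = c("fixed-bin-count", "fixed-bin-width"),
                                bins = 32L, width = NULL) {
  mode <- match.arg(mode)
  if (mode == "fixed-bin-count") {
    if (is.null(bins) || bins < 2L) stop("bins must be >= 2", call. = FALSE)
  } else {
    if (is.null(width) || width <= 0) stop("width must be > 0", call. = FALSE)
  }
  structure(list(mode = mode, bins = as.integer(bins), width = width),
            class = "discretization_spec")
}

#' Discretize a value vector to integer gray levels
#'
#' Fixed-bin-count: equal-width bins spanning \[min, max\], the maximum
#' mapped into the top bin. Fixed-bin-width: levels
#' `floor(x / width) - floor(min / width) + 1`. A constant region maps to a
#' single level.
#'
#' @param values numeric vector.
#' @param spec a [discretization_spec()].
#' @return Integer levels in `1..n_levels`, with attribute `n_levels`.
#' @export
discretize_values <- function(values, spec = discretization_spec()) {
  if (!length(values)) stop("no values to discretize", call. = FALSE)
  if (spec$mode == "fixed-bin-count") {
    rng <- range(values)
    if (rng[2] == rng[1]) {
      lev <- rep(1L, length(values))
      attr(lev, "n_levels") <- 1L
      return(lev)
    }
    w <- (rng[2] - rng[1]) / spec$bins
    lev <- pmin(as.integer(floor((values - rng[1]) / w)) + 1L, spec$bins)
    attr(lev, "n_levels") <- spec$bins
  } else {
    base <- floor(min(values) / spec$width)
    lev <- as.integer(floor(values / spec$width) - base) + 1L
    attr(lev, "n_levels") <- max(lev)
  }
  lev
}

first_order_names <- c(
  "energy", "total_energy", "entropy", "minimum", "p10", "p90", "maximum",
  "mean", "median", "iqr", "range", "mad", "rmad", "rms", "skewness",
  "kurtosis", "variance", "uniformity")

glcm_names <- c(
  "autocorrelation", "joint_average", "cluster_prominence", "cluster_shade",
  "cluster_tendency", "contrast", "correlation", "difference_average",
  "difference_entropy", "difference_variance", "joint_energy",
  "joint_entropy", "imc1", "imc2", "inverse_difference", "idn",
  "inverse_difference_moment", "idmn", "inverse_variance",
  "maximum_probability", "sum_average", "sum_entropy", "sum_of_squares",
  "mcc")

#' The 18 first-order intensity features
#'
#' IBSI-style first-order statistics of the raw values in one supervoxel
#' and one channel. Percentiles use linear interpolation (quantile type 7);
#' variance, skewness and kurtosis use the population convention; kurtosis
#' is not excess-corrected (a Gaussian scores 3). Entropy (log2) and
#' uniformity are computed on the discretized histogram.
#'
#' @param values numeric vector (>= 1 value) of raw intensities.
#' @param spec a [discretization_spec()] for entropy/uniformity.
#' @param voxel_volume_mm3 physical voxel volume; total energy is
#'   `voxel_volume_mm3 * energy`.
#' @return Named numeric vector of length 18.
#' @export
first_order_features <- function(values, spec = discretization_spec(),
                                 voxel_volume_mm3 = 1) {
  if (!length(values)) stop("empty value set", call. = FALSE)
  n <- length(values)
  mu <- mean(values)
  m2 <- mean((values - mu)^2)
  q <- stats::quantile(values, c(0.10, 0.25, 0.50, 0.75, 0.90),
                       names = FALSE, type = 7)
  in_rob <- values[values >= q[1] & values <= q[5]]
  lev <- discretize_values(values, spec)
  p <- tabulate(lev, attr(lev, "n_levels")) / n
  p <- p[p > 0]
  skew <- if (m2 > 0) mean((values - mu)^3) / m2^1.5 else 0
  kurt <- if (m2 > 0) mean((values - mu)^4) / m2^2 else 0
  c(energy = sum(values^2),
    total_energy = voxel_volume_mm3 * sum(values^2),
    entropy = -sum(p * log2(p)),
    minimum = min(values),
    p10 = q[1], p90 = q[5],
    maximum = max(values),
    mean = mu,
    median = q[3],
    iqr = q[4] - q[2],
    range = max(values) - min(values),
    mad = mean(abs(values - mu)),
    rmad = if (length(in_rob)) mean(abs(in_rob - mean(in_rob))) else 0,
    rms = sqrt(mean(values^2)),
    skewness = skew,
    kurtosis = kurt,
    variance = m2,
    uniformity = sum(p^2))
}

#' The 13 unique 3D GLCM directions
#'
#' All offsets `(dx, dy, dz)` in `{-1,0,1}^3` that are unique under
#' inversion (the symmetric matrix makes an offset and its negation
#' equivalent).
#'
#' @return 13 x 3 integer matrix.
#' @export
glcm_directions_3d <- function() {
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  keep <- apply(offs, 1L, function(o) {
    nz <- which(o != 0)
    length(nz) > 0 && o[nz[1]] > 0
  })
  unname(offs[keep, , drop = FALSE])
}

#' GLCM specification
#'
#' @param distance voxel offset magnitude (default 1).
#' @param symmetric accumulate each pair in both orders (default `TRUE`).
#' @return An object of class `glcm_spec`.
#' @export
glcm_spec <- function(distance = 1L, symmetric = TRUE) {
  structure(list(distance = as.integer(distance),
                 symmetric = isTRUE(symmetric),
                 directions = glcm_directions_3d() * as.integer(distance)),
            class = "glcm_spec")
}

#' The 24 gray-level co-occurrence matrix texture features
#'
#' Builds one co-occurrence matrix per 3D direction, counting only voxel
#' pairs that both lie inside the supervoxel, normalizes each matrix to sum
#' 1, computes the 24 IBSI GLCM features per direction, and returns their
#' average over directions. Degenerate regions (a single gray level, or no
#' valid pair in any direction) yield the documented limiting values or
#' `NA` with a `degenerate` attribute, so callers can exclude them.
#'
#' @param volume 3D channel volume.
#' @param voxel_idx linear indices of the supervoxel's voxels.
#' @param disc a [discretization_spec()].
#' @param spec a [glcm_spec()].
#' @return Named numeric vector of length 24 (attribute `degenerate` set
#'   when no direction had a valid pair).
#' @export
glcm_features <- function(volume, voxel_idx, disc = discretization_spec(),
                          spec = glcm_spec()) {
  if (length(voxel_idx) < 2L)
    stop("supervoxel needs >= 2 voxels for co-occurrences", call. = FALSE)
  sh <- dim(volume)
  lev <- discretize_values(as.numeric(volume[voxel_idx]), disc)
  ng <- attr(lev, "n_levels")
  # bounding-box subarray holding levels (NA outside the supervoxel)
  idx0 <- voxel_idx - 1L
  ci <- idx0 %% sh[1] + 1L
  cj <- (idx0 %/% sh[1]) %% sh[2] + 1L
  ck <- idx0 %/% (sh[1] * sh[2]) + 1L
  lo <- c(min(ci), min(cj), min(ck))
  d <- c(max(ci), max(cj), max(ck)) - lo + 1L
  LV <- array(NA_integer_, dim = d)
  LV[cbind(ci - lo[1] + 1L, cj - lo[2] + 1L, ck - lo[3] + 1L)] <- lev
  per_dir <- matrix(NA_real_, nrow = nrow(spec$directions),
                    ncol = length(glcm_names))
  any_valid <- FALSE
  for (r in seq_len(nrow(spec$directions))) {
    o <- spec$directions[r, ]
    lo <- pmax(1, 1 - o)
    hi <- pmin(d, d - o)
    if (any(hi < lo)) next
    xs1 <- lo[1]:hi[1]; ys1 <- lo[2]:hi[2]; zs1 <- lo[3]:hi[3]
    v1 <- LV[xs1, ys1, zs1, drop = FALSE]
    v2 <- LV[xs1 + o[1], ys1 + o[2], zs1 + o[3], drop = FALSE]
    ok <- !is.na(v1) & !is.na(v2)
    if (!any(ok)) next
    counts <- tabulate((v1[ok] - 1L) * ng + v2[ok], nbins = ng * ng)
    P <- matrix(counts, nrow = ng, ncol = ng, byrow = TRUE)
    if (spec$symmetric) P <- P + t(P)
    P <- P / sum(P)
    per_dir[r, ] <- glcm_features_from_matrix(P)
    any_valid <- TRUE
  }
  if (!any_valid) {
    out <- stats::setNames(rep(NA_real_, length(glcm_names)), glcm_names)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  out <- colMeans(per_dir, na.rm = TRUE)
  names(out) <- glcm_names
  out
}

# the 24 features of one normalized (sum = 1) co-occurrence matrix
glcm_features_from_matrix <- function(P) {
  ng <- nrow(P)
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  px <- rowSums(P)
  py <- colSums(P)
  mu_x <- sum(seq_len(ng) * px)
  mu_y <- sum(seq_len(ng) * py)
  sd_x <- sqrt(sum((seq_len(ng) - mu_x)^2 * px))
  sd_y <- sqrt(sum((seq_len(ng) - mu_y)^2 * py))
  # diagonal / cross-diagonal marginals
  k_sum <- 2:(2 * ng)
  p_sum <- vapply(k_sum, function(k) sum(P[i + j == k]), numeric(1))
  k_diff <- 0:(ng - 1)
  p_diff <- vapply(k_diff, function(k) sum(P[abs(i - j) == k]), numeric(1))
  eps_log <- function(v) ifelse(v > 0, log2(v), 0)
  HX <- -sum(px * eps_log(px))
  HY <- -sum(py * eps_log(py))
  HXY <- -sum(P * eps_log(P))
  pxy <- outer(px, py)
  HXY1 <- -sum(P * eps_log(pxy))
  HXY2 <- -sum(pxy * eps_log(pxy))
  da <- sum(k_diff * p_diff)
  corr <- if (sd_x > 0 && sd_y > 0)
    (sum(i * j * P) - mu_x * mu_y) / (sd_x * sd_y) else 1
  imc1 <- if (max(HX, HY) > 0) (HXY - HXY1) / max(HX, HY) else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (HXY2 - HXY))))
  off <- i != j
  inv_var <- if (any(off)) sum(P[off] / (i[off] - j[off])^2) else 0
  c(autocorrelation = sum(i * j * P),
    joint_average = mu_x,
    cluster_prominence = sum((i + j - mu_x - mu_y)^4 * P),
    cluster_shade = sum((i + j - mu_x - mu_y)^3 * P),
    cluster_tendency = sum((i + j - mu_x - mu_y)^2 * P),
    contrast = sum((i - j)^2 * P),
    correlation = corr,
    difference_average = da,
    difference_entropy = -sum(p_diff * eps_log(p_diff)),
    difference_variance = sum((k_diff - da)^2 * p_diff),
    joint_energy = sum(P^2),
    joint_entropy = HXY,
    imc1 = imc1,
    imc2 = imc2,
    inverse_difference = sum(P / (1 + abs(i - j))),
    idn = sum(P / (1 + abs(i - j) / ng)),
    inverse_difference_moment = sum(P / (1 + (i - j)^2)),
    idmn = sum(P / (1 + (i - j)^2 / ng^2)),
    inverse_variance = inv_var,
    maximum_probability = max(P),
    sum_average = sum(k_sum * p_sum),
    sum_entropy = -sum(p_sum * eps_log(p_sum)),
    sum_of_squares = sum((i - mu_x)^2 * P),
    mcc = glcm_mcc(P, px, py))
}

# maximal correlation coefficient: sqrt of the second-largest eigenvalue of
# Q(i, j) = sum_k p(i,k) p(j,k) / (px(i) py(k)), over levels with support
glcm_mcc <- function(P, px, py) {
  keep <- px > 0
  if (sum(keep) < 2L) return(1)
  Psub <- P[keep, keep, drop = FALSE]
  pxs <- px[keep]
  pys <- py[keep]
  Q <- (Psub / pxs) %*% t(Psub / matrix(pys, nrow(Psub), ncol(Psub),
                                        byrow = TRUE))
  ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
  if (length(ev) < 2L) return(1)
  sqrt(max(0, min(1, ev[2])))
}
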