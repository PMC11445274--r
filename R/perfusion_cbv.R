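#' A 4D dynamic susceptibility contrast (DSC) acquisition
#'
#' @param signal 4D array S(x, y, z, t) of raw DSC signal (arbitrary units).
#' @param TE echo time in ms.
#' @param TR repetition time in ms (time step between dynamics).
#' @param baseline_window integer index range of pre-bolus time points used
#'   to estimate the baseline signal S0.
#' @param geometry a [vox_geometry()] for the spatial grid.
#' @return An object of class `dsc_series`.
#' @export
dsc_series <- function(signal, TE, TR, baseline_window,
                       geometry = vox_geometry(dim(signal)[1:3])) {
  if (length(dim(signal)) != 4L)
    stop("signal must be a 4D array (x, y, z, t)", call. = FALSE)
  nt <- dim(signal)[4]
  if (nt < 10L) stop("DSC series needs >= 10 time points", call. = FALSE)
  baseline_window <- as.integer(baseline_window)
  if (length(baseline_window) == 0L || any(baseline_window < 1L) ||
      any(baseline_window > nt))
    stop("baseline_window must be a nonempty index range within the series",
         call. = FALSE)
  if (max(baseline_window) >= nt)
    stop("baseline_window must precede the bolus (cannot span the full series)",
         call. = FALSE)
  if (TE <= 0 || TR <= 0) stop("TE and TR must be positive", call. = FALSE)
  structure(list(signal = signal, TE = TE, TR = TR,
                 baseline_window = baseline_window, geometry = geometry),
            class = "dsc_series")
}

#' @export
print.dsc_series <- function(x, ...) {
  d <- dim(x$signal)
  cat(sprintf("<dsc_series> %dx%dx%d voxels, %d dynamics, TE %.1f ms, TR %.0f ms\n",
              d[1], d[2], d[3], d[4], x$TE, x$TR))
  invisible(x)
}

#' Convert DSC signal to a relaxivity-change (concentration proxy) series
#'
#' Applies the standard single-echo gradient-echo model
#' \eqn{\Delta R_2^*(t) = -\frac{1}{TE}\,\ln\!\big(S(t)/S_0\big)}
#' with \eqn{S_0} the per-voxel mean over the pre-bolus baseline window.
#' Voxels with non-positive \eqn{S_0} or any non-positive \eqn{S(t)} inside
#' the mask are not an error: they are reported in the `flagged` attribute
#' and their series set to `NA` so downstream fits can exclude them.
#'
#' @param series a [dsc_series()].
#' @param brain_mask logical 3D mask of voxels to convert.
#' @return 4D array of \eqn{\Delta R_2^*} (1/ms) with attribute `flagged`
#'   (linear spatial indices of excluded voxels); zero outside the mask.
#' @export
signal_to_delta_r2 <- function(series, brain_mask) {
  stopifnot(inherits(series, "dsc_series"))
  d <- dim(series$signal)
  if (!all(dim(brain_mask) == d[1:3]))
    stop("brain_mask does not match the DSC spatial grid", call. = FALSE)
  nt <- d[4]
  nvox <- prod(d[1:3])
  S <- matrix(series$signal, nrow = nvox, ncol = nt)
  midx <- which(brain_mask)
  Sm <- S[midx, , drop = FALSE]
  S0 <- rowMeans(Sm[, series$baseline_window, drop = FALSE])
  bad <- S0 <= 0 | apply(Sm <= 0, 1L, any)
  out <- matrix(0, nrow = nvox, ncol = nt)
  good <- midx[!bad]
  if (length(good))
    out[good, ] <- -log(S[good, , drop = FALSE] / S0[!bad]) / series$TE
  flagged <- midx[bad]
  out[flagged, ] <- NA_real_
  res <- array(out, dim = d)
  attr(res, "flagged") <- flagged
  attr(res, "TR") <- series$TR
  res
}

#' Leakage-corrected cerebral blood volume from a relaxivity series
#'
#' Implements the Boxerman–Weisskoff linear leakage model: each voxel's
#' curve is regressed on the whole-brain nonenhancing reference curve
#' \eqn{\bar{\Delta R_2^*}(t)} and its running integral,
#' \deqn{\Delta R_2^*(t) \approx K_1\,\bar{\Delta R_2^*}(t) -
#'       K_2 \int_0^t \bar{\Delta R_2^*}(\tau)\,d\tau,}
#' and the corrected CBV is the trapezoidal integral of the voxel curve plus
#' the leakage term, \eqn{\int \Delta R_2^* + K_2 \iint \bar{\Delta R_2^*}}.
#' Where \eqn{K_2 = 0} the corrected value equals the plain integral.
#'
#' @param delta_r2 4D relaxivity-change array from [signal_to_delta_r2()]
#'   (or simulated); `NA` series are skipped and stay `NA` in the maps.
#' @param reference_mask logical mask of nonenhancing brain (>= 100 voxels)
#'   defining the reference curve.
#' @param integration_window integer time indices over which to integrate
#'   (default: the whole series). Must cover the bolus passage.
#' @param TR time step in ms (defaults to the `TR` attribute of `delta_r2`).
#' @param brain_mask voxels for which maps are computed (default: all
#'   voxels with a finite series).
#' @return An object of class `cbv_result` with 3D `cbv`, `cbv_uncorrected`,
#'   `K1_map` and `K2_map` volumes.
#' @export
leakage_corrected_cbv <- function(delta_r2, reference_mask,
                                  integration_window = NULL, TR = NULL,
                                  brain_mask = NULL) {
  d <- dim(delta_r2)
  stopifnot(length(d) == 4L)
  nt <- d[4]
  nvox <- prod(d[1:3])
  if (is.null(TR)) TR <- attr(delta_r2, "TR")
  if (is.null(TR)) TR <- 1
  if (sum(reference_mask) < 100L)
    stop("reference_mask must contain >= 100 voxels", call. = FALSE)
  if (is.null(integration_window)) integration_window <- seq_len(nt)
  X <- matrix(delta_r2, nrow = nvox, ncol = nt)
  ref_rows <- X[which(reference_mask), , drop = FALSE]
  ref_rows <- ref_rows[stats::complete.cases(ref_rows), , drop = FALSE]
  if (nrow(ref_rows) == 0L)
    stop("no valid voxels in reference_mask", call. = FALSE)
  refc <- colMeans(ref_rows)
  if (all(abs(refc) < .Machine$double.eps))
    stop("degenerate reference curve (identically zero)", call. = FALSE)
  t_s <- (seq_len(nt) - 1) * TR
  ref_int <- pracma::cumtrapz(t_s, refc)[, 1]    # running integral of ref
  iw <- integration_window
  ref_auc <- pracma::trapz(t_s[iw], refc[iw])
  ref_iint <- pracma::trapz(t_s[iw], ref_int[iw])  # double integral
  if (is.null(brain_mask)) {
    vidx <- which(stats::complete.cases(X) &
                    rowSums(abs(X)) > 0)
  } else {
    vidx <- which(brain_mask)
    vidx <- vidx[stats::complete.cases(X[vidx, , drop = FALSE])]
  }
  # closed-form two-parameter least squares, vectorized over voxels:
  # y ~ K1 * refc - K2 * ref_int
  A11 <- sum(refc * refc); A12 <- -sum(refc * ref_int)
  A22 <- sum(ref_int * ref_int)
  det <- A11 * A22 - A12 * A12
  Y <- X[vidx, , drop = FALSE]
  b1 <- as.vector(Y %*% refc)
  b2 <- -as.vector(Y %*% ref_int)
  if (abs(det) < .Machine$double.eps * max(A11, A22, 1)) {
    k1 <- b1 / A11
    k2 <- rep(0, length(vidx))
  } else {
    k1 <- (A22 * b1 - A12 * b2) / det
    k2 <- (A11 * b2 - A12 * b1) / det
  }
  # trapezoidal integral of each voxel curve over the window
  w <- rep(0, nt)
  w[iw] <- trapezoid_weights(t_s[iw])
  auc <- as.vector(Y %*% w)
  cbv_cor <- auc + k2 * ref_iint
  mk <- function(vals) {
    m <- rep(NA_real_, nvox)
    m[vidx] <- vals
    array(m, dim = d[1:3])
  }
  structure(list(cbv = mk(cbv_cor), cbv_uncorrected = mk(auc),
                 K1_map = mk(k1), K2_map = mk(k2),
                 reference_curve = refc, reference_auc = ref_auc,
                 n_reference = nrow(ref_rows), TR = TR),
            class = "cbv_result")
}

trapezoid_weights <- function(t) {
  n <- length(t)
  if (n == 1L) return(0)
  w <- numeric(n)
  dt <- diff(t)
  w[1] <- dt[1] / 2
  w[n] <- dt[n - 1] / 2
  if (n > 2L) w[2:(n - 1)] <- (dt[-(n - 1)] + dt[-1]) / 2
  w
}

#' @export
print.cbv_result <- function(x, ...) {
  cat(sprintf("<cbv_result> %s grid, %d reference voxels, median K2 %.4g\n",
              paste(dim(x$cbv), collapse = "x"), x$n_reference,
              stats::median(x$K2_map, na.rm = TRUE)))
  invisible(x)
}

#' Normalize a CBV map to contralateral / nonenhancing white matter
#'
#' @param cbv_result a [leakage_corrected_cbv()] result or a plain 3D map.
#' @param wm_mask logical white-matter reference mask (>= 100 voxels).
#' @return The CBV volume divided by the mean over `wm_mask`.
#' @export
normalize_cbv_to_wm <- function(cbv_result, wm_mask) {
  cbv <- if (inherits(cbv_result, "cbv_result")) cbv_result$cbv else cbv_result
  if (sum(wm_mask) < 100L)
    stop("wm_mask must contain >= 100 voxels", call. = FALSE)
  ref <- mean(cbv[wm_mask], na.rm = TRUE)
  if (!is.finite(ref) || ref <= 0)
    stop("non-positive white-matter reference CBV", call. = FALSE)
  cbv / ref
}

#' Gamma-variate bolus curve
#'
#' Canonical shape for simulated first-pass contrast boluses:
#' \eqn{c(t) = A\,(t - t_0)^\alpha e^{-(t - t_0)/\beta}} for \eqn{t > t_0},
#' zero before arrival.
#'
#' @param t time vector (ms).
#' @param t0 bolus arrival time (ms).
#' @param alpha,beta shape and scale parameters.
#' @param amplitude peak scaling `A`.
#' @return Numeric vector of concentration-proxy values.
#' @export
gamma_variate <- function(t, t0 = 0, alpha = 3, beta = 1500, amplitude = 1) {
  out <- numeric(length(t))
  tt <- t - t0
  pos <- tt > 0
  out[pos] <- amplitude * (tt[pos]^alpha) * exp(-tt[pos] / beta)
  peak <- max(out)
  if (peak > 0) out <- out / peak * amplitude
  out
}

#' Forward-simulate a DSC series on a voxel grid from a CBV-like map
#'
#' Builds per-voxel relaxivity curves proportional to a shared gamma-variate
#' bolus scaled so each voxel's curve integral equals its map value, then
#' converts to signal via \eqn{S(t) = S_0 e^{-TE\,\Delta R_2^*(t)}}. Used by
#' the phantom generator (`with_dsc = TRUE`) and by the parameter-recovery
#' test-benches.
#'
#' @param cbv_map 3D volume of target integrals (arbitrary units).
#' @param brain_mask logical mask; signal is constant S0 outside.
#' @param nt number of dynamics.
#' @param TE,TR echo / repetition time in ms.
#' @param S0 baseline signal level.
#' @param n_baseline pre-bolus time points.
#' @param noise_sd Gaussian signal noise SD (absolute units).
#' @return A [dsc_series()].
#' @export
simulate_dsc_from_cbv <- function(cbv_map, brain_mask, nt = 40L, TE = 30,
                                  TR = 1500, S0 = 1000, n_baseline = 8L,
                                  noise_sd = 0) {
  sh <- dim(cbv_map)
  t_s <- (seq_len(nt) - 1) * TR
  bolus <- gamma_variate(t_s, t0 = t_s[n_baseline], alpha = 3, beta = 2 * TR,
                         amplitude = 1)
  bolus_auc <- pracma::trapz(t_s, bolus)
  sig <- array(S0, dim = c(sh, nt))
  idx <- which(brain_mask)
  scale <- cbv_map[idx] / bolus_auc
  scale[!is.finite(scale) | scale < 0] <- 0
  # keep TE * peak dR2* modest so signal stays positive
  curves <- outer(scale, bolus)           # n_vox x nt of dR2*
  Svox <- S0 * exp(-TE * curves)
  for (ti in seq_len(nt)) {
    tmp <- sig[, , , ti]
    tmp[idx] <- Svox[, ti]
    sig[, , , ti] <- tmp
  }
  if (noise_sd > 0) sig <- sig + stats::rnorm(length(sig), sd = noise_sd)
  dsc_series(sig, TE = TE, TR = TR, baseline_window = seq_len(n_baseline),
             geometry = geometry_of(cbv_map, vox_geometry(sh)))
}
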