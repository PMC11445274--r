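# helpers shared by the DSC tests: a 1-slice grid whose first rows hold
# constructed voxel curves and whose remainder holds reference tissue
make_dsc_grid <- function(curves, refc, noise_sd = 0, n_ref = 150,
                          TE = 30, TR = 1500) {
  nt <- length(refc)
  n_tissue <- nrow(curves)
  side <- ceiling(sqrt(n_tissue + n_ref))
  nvox <- side * side
  arr <- matrix(rep(refc, each = nvox), nrow = nvox)
  arr[seq_len(n_tissue), ] <- curves
  if (noise_sd > 0) arr <- arr + stats::rnorm(length(arr), sd = noise_sd)
  dr2 <- array(arr, dim = c(side, side, 1, nt))
  attr(dr2, "TR") <- TR
  refmask <- array(FALSE, c(side, side, 1))
  refmask[(n_tissue + 1):(n_tissue + n_ref)] <- TRUE
  list(dr2 = dr2, refmask = refmask, side = side)
}

test_that("signal-to-relaxivity conversion inverts the forward model", {
  nt <- 30; TE <- 30; TR <- 1500
  t_s <- (0:(nt - 1)) * TR
  ctrue <- gamma_variate(t_s, t0 = t_s[8], alpha = 3, beta = 2 * TR,
                         amplitude = 0.012)
  sig <- array(0, dim = c(4, 4, 1, nt))
  for (ti in seq_len(nt)) sig[, , 1, ti] <- 1000 * exp(-TE * ctrue[ti])
  ser <- dsc_series(sig, TE = TE, TR = TR, baseline_window = 1:7)
  mask <- array(TRUE, c(4, 4, 1))
  dr2 <- signal_to_delta_r2(ser, mask)
  expect_equal(as.numeric(dr2[1, 1, 1, ]), ctrue, tolerance = 1e-12)
  # constant signal -> zero relaxivity change
  ser0 <- dsc_series(array(500, dim = c(4, 4, 1, nt)), TE, TR, 1:7)
  dr0 <- signal_to_delta_r2(ser0, mask)
  expect_true(all(abs(dr0) < 1e-14))
  expect_length(attr(dr0, "flagged"), 0)
})

test_that("non-positive signal flags the voxel instead of erroring", {
  nt <- 12
  sig <- array(100, dim = c(3, 3, 1, nt))
  sig[2, 2, 1, 6] <- 0
  ser <- dsc_series(sig, TE = 30, TR = 1500, baseline_window = 1:4)
  mask <- array(TRUE, c(3, 3, 1))
  dr2 <- signal_to_delta_r2(ser, mask)
  flagged <- attr(dr2, "flagged")
  expect_length(flagged, 1L)
  expect_equal(arrayInd(flagged, c(3, 3, 1))[1, ], c(2L, 2L, 1L),
               ignore_attr = TRUE)
  expect_true(all(is.na(dr2[2, 2, 1, ])))
})

test_that("leakage fit recovers planted K1/K2 and the model identities", {
  nt <- 40; TR <- 1500
  t_s <- (0:(nt - 1)) * TR
  refc <- gamma_variate(t_s, t0 = t_s[8], alpha = 3, beta = 2 * TR,
                        amplitude = 0.01)
  ref_int <- pracma::cumtrapz(t_s, refc)[, 1]
  k2u <- 0.05 / 1000   # per-ms units on this time axis
  curves <- rbind(1.2 * refc - k2u * ref_int,   # leaky voxel
                  0.8 * refc,                   # K2 = 0 voxel
                  refc)                         # the reference itself
  gr <- make_dsc_grid(curves, refc)
  res <- leakage_corrected_cbv(gr$dr2, gr$refmask, TR = TR)
  expect_equal(res$K1_map[1], 1.2, tolerance = 0.05)
  expect_equal(res$K2_map[1], k2u, tolerance = 0.05)
  # corrected CBV restores the leakage-free integral K1 * int(ref)
  expect_equal(res$cbv[1], 1.2 * pracma::trapz(t_s, refc), tolerance = 1e-6)
  # K2 = 0: corrected equals uncorrected
  expect_equal(res$K2_map[2], 0, tolerance = 1e-10)
  expect_lt(abs(res$cbv[2] - res$cbv_uncorrected[2]) /
              abs(res$cbv_uncorrected[2]), 1e-6)
  # self-fit of the reference curve
  expect_equal(res$K1_map[3], 1, tolerance = 1e-9)
  expect_equal(res$K2_map[3], 0, tolerance = 1e-12)
  expect_equal(res$cbv[3], pracma::trapz(t_s, refc), tolerance = 1e-9)
})

test_that("relaxivity scaling scales CBV linearly", {
  nt <- 40; TR <- 1500
  t_s <- (0:(nt - 1)) * TR
  refc <- gamma_variate(t_s, t0 = t_s[8], amplitude = 0.01)
  ref_int <- pracma::cumtrapz(t_s, refc)[, 1]
  curves <- rbind(1.3 * refc - 4e-5 * ref_int, 0.7 * refc - 2e-5 * ref_int)
  gr <- make_dsc_grid(curves, refc)
  res1 <- leakage_corrected_cbv(gr$dr2, gr$refmask, TR = TR)
  res3 <- leakage_corrected_cbv(gr$dr2 * 3, gr$refmask, TR = TR)
  expect_equal(res3$cbv[1:2], 3 * res1$cbv[1:2], tolerance = 1e-9)
})

test_that("degenerate reference curves and small masks are rejected", {
  dr2 <- array(0, dim = c(10, 10, 2, 15))
  mask <- array(TRUE, c(10, 10, 2))
  expect_error(leakage_corrected_cbv(dr2, mask, TR = 1000),
               "degenerate reference")
  small <- array(FALSE, c(10, 10, 2)); small[1:50] <- TRUE
  expect_error(leakage_corrected_cbv(dr2, small, TR = 1000), ">= 100")
})
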