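homogeneous_channels <- function(mask, value = 1) {
  g <- geometry_of(mask)
  v <- as_volume(array(value, g$shape), g)
  list(CBV = v, PET = v, T1c = v)
}

test_that("a homogeneous 1000-voxel cube yields 4-6 compact supervoxels", {
  mask <- cuboid_mask(c(10, 10, 10))
  svx <- slic_supervoxels(homogeneous_channels(mask), mask, slic_config())
  expect_gte(svx$n_supervoxels, 4L)
  expect_lte(svx$n_supervoxels, 6L)
  # compactness: voxels stay near their supervoxel centroid (S ~ 5.8 mm)
  S <- (1000 / svx$n_supervoxels)^(1 / 3)
  for (id in seq_len(svx$n_supervoxels)) {
    co <- arrayInd(which(svx$ids == id), dim(svx$ids))
    cent <- colMeans(co)
    mean_dist <- mean(sqrt(rowSums((co - matrix(cent, nrow(co), 3,
                                                byrow = TRUE))^2)))
    expect_lte(mean_dist, 1.2 * S)
  }
})

test_that("supervoxels partition the CET mask exactly", {
  co <- generate_cohort(small_cohort_config(n_patients = 2, seed = 23))
  for (b in co) {
    svx <- slic_supervoxels(
      list(CBV = b$channels$CBV, PET = b$channels$PET_raw,
           T1c = b$channels$T1c_baseline), b$masks$cet, slic_config())
    expect_identical(which(svx$ids > 0L), which(b$masks$cet))
    expect_equal(sum(svx$voxel_counts), sum(b$masks$cet))
    expect_equal(length(svx$voxel_counts), svx$n_supervoxels)
    expect_true(all(svx$voxel_counts > 0L))
    # each id 26-connected
    for (id in seq_len(svx$n_supervoxels)) {
      m <- svx$ids == id
      comp <- svxresp:::connected_components_26(m)
      expect_equal(max(comp), 1L)
    }
  }
})

test_that("identical inputs give an identical canonical id volume", {
  b <- generate_cohort(small_cohort_config(n_patients = 1, seed = 29))[[1]]
  chans <- list(CBV = b$channels$CBV, PET = b$channels$PET_raw,
                T1c = b$channels$T1c_baseline)
  s1 <- slic_supervoxels(chans, b$masks$cet, slic_config(seed = 5))
  s2 <- slic_supervoxels(chans, b$masks$cet, slic_config(seed = 5))
  expect_identical(s1$ids, s2$ids)
})

test_that("an intensity boundary is respected by the clustering", {
  mask <- cuboid_mask(c(20, 10, 5))
  g <- geometry_of(mask)
  tbr <- array(1, g$shape)
  left <- array(FALSE, g$shape); left[1:(g$shape[1] / 2), , ] <- TRUE
  tbr[!left] <- 3
  chans <- list(CBV = as_volume(array(1, g$shape), g),
                PET = as_volume(tbr, g),
                T1c = as_volume(array(1, g$shape), g))
  svx <- slic_supervoxels(chans, mask, slic_config())
  for (id in seq_len(svx$n_supervoxels)) {
    sel <- svx$ids == id
    n_left <- sum(sel & left)
    straddle <- min(n_left, sum(sel) - n_left) / sum(sel)
    expect_lte(straddle, 0.05)
  }
})

test_that("a mask smaller than the target size becomes one supervoxel", {
  mask <- cuboid_mask(c(5, 5, 5))
  expect_warning(
    svx <- slic_supervoxels(homogeneous_channels(mask), mask, slic_config()),
    "single supervoxel")
  expect_equal(svx$n_supervoxels, 1L)
  expect_identical(which(svx$ids == 1L), which(mask))
})

test_that("majority voting follows the documented rule including ties", {
  mask <- cuboid_mask(c(10, 10, 2))
  g <- geometry_of(mask)
  ids <- array(0L, g$shape)
  idx <- which(mask)
  ids[idx[1:100]] <- 1L
  ids[idx[101:200]] <- 2L
  svx <- structure(list(ids = as_volume(ids, g), n_supervoxels = 2L,
                        voxel_counts = c(100L, 100L)),
                   class = "supervoxel_map")
  lab <- array(0L, g$shape)
  lab[idx[1:75]] <- 1L; lab[idx[76:100]] <- 2L     # 75/25 split
  lab[idx[101:150]] <- 1L; lab[idx[151:200]] <- 2L # 50/50 tie
  cet <- array(FALSE, g$shape); cet[idx[1:200]] <- TRUE
  labs <- response_labels(as_volume(lab, g), as_volume(cet, g),
                          provenance = "synthetic-truth")
  ml <- majority_label(svx, labs)
  expect_equal(ml$label, c("TP", "TP"))            # tie goes to TP
  expect_equal(ml$majority_fraction, c(0.75, 0.5))
  expect_equal(ml$n_voxels, c(100L, 100L))
})

test_that("a fully unanimous supervoxel reports fraction one", {
  b <- generate_cohort(small_cohort_config(
    n_patients = 1, tp_fraction = 0, seed = 3))[[1]]
  svx <- slic_supervoxels(
    list(CBV = b$channels$CBV, PET = b$channels$PET_raw,
         T1c = b$channels$T1c_baseline), b$masks$cet, slic_config())
  ml <- majority_label(svx, b$truth_labels)
  expect_true(all(ml$label == "PsP"))
  expect_true(all(ml$majority_fraction == 1))
})
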