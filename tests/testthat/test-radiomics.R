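test_that("the feature schema is 126 stable names, 42 per channel", {
  sch <- feature_schema()
  expect_length(sch, 126L)
  expect_false(anyDuplicated(sch) > 0)
  for (ch in c("CBV", "PET", "T1c"))
    expect_equal(sum(startsWith(sch, paste0(ch, "__"))), 42L)
  expect_identical(sch, feature_schema())
})

test_that("first-order features match hand computations", {
  f <- first_order_features(c(1, 2, 3, 4))
  expect_equal(unname(f["mean"]), 2.5)
  expect_equal(unname(f["median"]), 2.5)
  expect_equal(unname(f["range"]), 3)
  expect_equal(unname(f["variance"]), 1.25)   # population convention
  expect_equal(unname(f["energy"]), 30)
  expect_equal(unname(f["rms"]), sqrt(7.5))

  const <- first_order_features(rep(3.7, 50))
  expect_equal(unname(const["variance"]), 0)
  expect_equal(unname(const["range"]), 0)
  expect_equal(unname(const["entropy"]), 0)
  expect_equal(unname(const["uniformity"]), 1)
  expect_equal(unname(const["mean"]), 3.7)

  expect_error(first_order_features(numeric(0)), "empty")
})

test_that("order statistics are ordered for arbitrary inputs", {
  set.seed(5)
  for (i in 1:20) {
    f <- first_order_features(rnorm(sample(5:200, 1)))
    expect_true(f["minimum"] <= f["p10"])
    expect_true(f["p10"] <= f["median"])
    expect_true(f["median"] <= f["p90"])
    expect_true(f["p90"] <= f["maximum"])
  }
})

test_that("GLCM features on a hand-enumerated 2x2 patch are exact", {
  vol <- array(c(1, 2, 1, 2), dim = c(2, 2, 1))
  disc <- discretization_spec(bins = 2L)
  f <- glcm_features(vol, which(!is.na(vol)), disc)
  # four in-plane directions have pairs; per-direction values averaged:
  # contrast (1, 0, 1, 1) -> 0.75; max prob 0.5 each; entropy 1 each;
  # correlation (-1, +1, -1, -1) -> -0.5
  expect_equal(unname(f["contrast"]), 0.75)
  expect_equal(unname(f["maximum_probability"]), 0.5)
  expect_equal(unname(f["joint_entropy"]), 1)
  expect_equal(unname(f["correlation"]), -0.5)
})

test_that("a single gray level gives the degenerate limiting values", {
  vol <- array(2, dim = c(3, 3, 3))
  f <- glcm_features(vol, 1:27)
  expect_equal(unname(f["maximum_probability"]), 1)
  expect_equal(unname(f["joint_entropy"]), 0)
  expect_equal(unname(f["contrast"]), 0)
  expect_equal(unname(f["joint_energy"]), 1)
})

test_that("every per-direction co-occurrence matrix is normalized", {
  set.seed(11)
  vol <- array(runif(125), dim = c(5, 5, 5))
  lev <- discretize_values(vol[1:125], discretization_spec())
  ng <- attr(lev, "n_levels")
  LV <- array(lev, dim = c(5, 5, 5))
  dirs <- glcm_directions_3d()
  for (r in seq_len(nrow(dirs))) {
    o <- dirs[r, ]
    xs <- max(1, 1 - o[1]):min(5, 5 - o[1])
    ys <- max(1, 1 - o[2]):min(5, 5 - o[2])
    zs <- max(1, 1 - o[3]):min(5, 5 - o[3])
    v1 <- LV[xs, ys, zs]; v2 <- LV[xs + o[1], ys + o[2], zs + o[3]]
    counts <- tabulate((v1 - 1L) * ng + v2, nbins = ng * ng)
    P <- matrix(counts, ng, ng, byrow = TRUE)
    P <- (P + t(P)) / sum(P + t(P))
    expect_lt(abs(sum(P) - 1), 1e-12)
  }
})

test_that("intensity shifts leave texture invariant under fixed bin counts", {
  set.seed(13)
  vol <- array(rnorm(216), dim = c(6, 6, 6))
  idx <- 1:216
  f1 <- glcm_features(vol, idx)
  f2 <- glcm_features(vol + 100, idx)
  for (feat in c("contrast", "joint_entropy", "difference_entropy",
                 "sum_entropy", "joint_energy", "maximum_probability"))
    expect_equal(unname(f1[feat]), unname(f2[feat]), tolerance = 1e-12)
  fo1 <- first_order_features(as.numeric(vol))
  fo2 <- first_order_features(as.numeric(vol) + 100)
  expect_equal(unname(fo1["entropy"]), unname(fo2["entropy"]),
               tolerance = 1e-12)
  expect_equal(unname(fo1["variance"]), unname(fo2["variance"]),
               tolerance = 1e-9)
})

test_that("the feature table has 126 features per supervoxel and is stable", {
  co <- generate_cohort(small_cohort_config(n_patients = 2, seed = 41))
  mk <- function(b) {
    svx <- slic_supervoxels(
      list(CBV = b$channels$CBV, PET = b$channels$PET_raw,
           T1c = b$channels$T1c_baseline), b$masks$cet, slic_config())
    list(ch = list(CBV = b$channels$CBV, PET = b$channels$PET_raw,
                   T1c = b$channels$T1c_baseline),
         svx = svx, ml = majority_label(svx, b$truth_labels))
  }
  parts <- lapply(co, mk)
  names(parts) <- vapply(co, `[[`, "", "case_id")
  tab <- extract_feature_table(
    co, lapply(parts, `[[`, "ch"), lapply(parts, `[[`, "svx"),
    lapply(parts, `[[`, "ml"))
  expect_length(feature_columns(tab), 126L)
  expect_true(all(is.finite(as.matrix(tab[, feature_columns(tab)]))))
  expect_true(all(tab$label %in% c("TP", "PsP")))
  tab2 <- extract_feature_table(
    co, lapply(parts, `[[`, "ch"), lapply(parts, `[[`, "svx"),
    lapply(parts, `[[`, "ml"))
  expect_identical(tab, tab2)

  # record count tracks |CET| / target size
  expected <- sum(vapply(co, function(b) sum(b$masks$cet), numeric(1))) / 200
  expect_lt(abs(nrow(tab) - expected) / expected, 0.5)

  # a missing channel errors by name
  broken <- lapply(parts, `[[`, "ch")
  broken[[1]]$PET <- NULL
  expect_error(extract_feature_table(co, broken,
                                     lapply(parts, `[[`, "svx"),
                                     lapply(parts, `[[`, "ml")),
               "missing channel PET")
})
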