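test_that("cohort size, patient identity and determinism follow the config", {
  cfg <- small_cohort_config(n_patients = 10, seed = 3)
  co <- generate_cohort(cfg)
  expect_length(co, 10L)
  expect_length(unique(vapply(co, `[[`, "", "patient_id")), 10L)

  co2 <- generate_cohort(cfg)
  expect_identical(co[[4]]$channels$T1c_baseline, co2[[4]]$channels$T1c_baseline)
  expect_identical(co[[4]]$truth_labels$labels, co2[[4]]$truth_labels$labels)
  expect_identical(co[[7]]$followup_T1c, co2[[7]]$followup_T1c)
})

test_that("repeat inclusion creates second cases sharing a patient id", {
  cfg <- small_cohort_config(n_patients = 6, n_repeat_patients = 2, seed = 5)
  co <- generate_cohort(cfg)
  expect_length(co, 8L)
  pats <- vapply(co, `[[`, "", "patient_id")
  expect_equal(sum(table(pats) == 2L), 2L)
  expect_length(unique(vapply(co, `[[`, "", "case_id")), 8L)
})

test_that("planted TP fraction tracks the configured proportion", {
  cfg <- cohort_config(n_patients = 1, tp_fraction = 0.5, seed = 2)
  b <- generate_cohort(cfg)[[1]]
  n_cet <- sum(b$masks$cet)
  expect_gt(n_cet, 3000)  # default lesion size regime
  frac <- b$truth_labels$n_tp / n_cet
  expect_true(abs(frac - 0.5) < 0.05)
})

test_that("plant_response_regions honours boundaries and builds blobs", {
  mask <- cuboid_mask(c(22, 22, 22))
  expect_error(plant_response_regions(mask, -0.1), "tp_fraction")
  expect_equal(sum(plant_response_regions(mask, 0, seed = 1)$labels == 1L), 0)
  lab1 <- plant_response_regions(mask, 1, seed = 1)
  expect_equal(sum(lab1$labels == 1L), sum(mask))

  lab <- plant_response_regions(mask, 0.3, blob_scale_mm = 8, seed = 4)
  n_tp <- sum(lab$labels == 1L)
  expect_true(abs(n_tp - 0.3 * sum(mask)) < 0.05 * sum(mask) + 1)
  # TP voxels form coherent blobs, not salt-and-pepper
  tp_mask <- lab$labels == 1L
  comp <- svxresp:::connected_components_26(tp_mask)
  expect_gte(mean(tabulate(comp)), 27)
})

test_that("truth label support equals the CET mask exactly", {
  co <- generate_cohort(small_cohort_config(n_patients = 3, seed = 9))
  for (b in co) {
    expect_identical(which(b$truth_labels$labels != 0L), which(b$masks$cet))
    expect_equal(sum(b$masks$cet & b$masks$necrosis), 0)
    expect_equal(sum(b$masks$cet & b$masks$edema), 0)
  }
})

test_that("follow-up enhances TP and fades PsP relative to baseline", {
  b <- generate_cohort(small_cohort_config(n_patients = 1, seed = 11))[[1]]
  tp <- b$truth_labels$labels == 1L
  psp <- b$truth_labels$labels == 2L
  d <- b$followup_T1c - b$channels$T1c_baseline
  expect_gt(mean(d[tp]), 0)
  expect_lt(mean(d[psp]), 0)
})

test_that("per-class TBR means match the configured effect sizes", {
  cfg <- small_cohort_config(n_patients = 10, seed = 21)
  co <- generate_cohort(cfg)
  case_means <- function(cls) vapply(co, function(b) {
    tbr <- b$channels$PET_raw / mean(b$channels$PET_raw[
      b$masks$wm & !b$masks$cet & !b$masks$necrosis & !b$masks$edema])
    mean(tbr[b$truth_labels$labels == cls])
  }, numeric(1))
  for (cls in 1:2) {
    m <- case_means(cls)
    target <- cfg$class_means$TBR[if (cls == 1) "TP" else "PsP"]
    se <- stats::sd(m) / sqrt(length(m))
    expect_lt(abs(mean(m) - target), 3 * se + 0.02)
  }
})

test_that("raising the TP-PsP TBR gap strictly raises the rank effect", {
  effects <- vapply(c(2.0, 2.4, 3.0), function(tp_mean) {
    cfg <- small_cohort_config(
      n_patients = 3, seed = 31,
      class_means = list(TBR = c(TP = tp_mean, PsP = 1.9),
                         CBV = c(TP = 2.1, PsP = 1.3),
                         T1c = c(TP = 3.4, PsP = 3.0)))
    co <- generate_cohort(cfg)
    x <- unlist(lapply(co, function(b)
      b$channels$PET_raw[b$truth_labels$labels == 1L]))
    y <- unlist(lapply(co, function(b)
      b$channels$PET_raw[b$truth_labels$labels == 2L]))
    r <- mann_whitney_u(x, y)
    r$U / (as.numeric(r$n1) * r$n2)
  }, numeric(1))
  expect_true(all(diff(effects) > 0))
})

test_that("a tumor larger than the brain is rejected", {
  expect_error(
    generate_cohort(cohort_config(
      n_patients = 1, geometry = vox_geometry(c(32, 32, 32), c(2, 2, 2)),
      tumor_radius_mm = 40, rim_thickness_mm = 8)),
    "does not fit")
})
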