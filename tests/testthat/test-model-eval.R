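# small synthetic feature tables built directly, for classifier unit tests
toy_table <- function(n_patients = 12, svx_per_patient = 6, sep = 3,
                      seed = 1, all_features = FALSE) {
  set.seed(seed)
  rows <- do.call(rbind, lapply(seq_len(n_patients), function(p) {
    lab <- sample(c("TP", "PsP"), svx_per_patient, replace = TRUE)
    data.frame(patient_id = sprintf("P%02d", p),
               case_id = sprintf("P%02d_C1", p),
               svx_id = seq_len(svx_per_patient),
               n_voxels = 200L, label = lab, majority_fraction = 1,
               stringsAsFactors = FALSE)
  }))
  sch <- feature_schema()
  X <- matrix(rnorm(nrow(rows) * length(sch)), nrow(rows),
              dimnames = list(NULL, sch))
  if (all_features) {
    X <- X + sep * (rows$label == "TP")   # disjoint supports everywhere
  } else {
    X[, "PET__firstorder__median"] <-
      X[, "PET__firstorder__median"] + sep * (rows$label == "TP")
  }
  out <- cbind(rows, as.data.frame(X))
  class(out) <- c("feature_table", "data.frame")
  out
}

test_that("grouped folds keep each patient in exactly one fold", {
  tab <- toy_table(n_patients = 61)
  folds <- grouped_folds(tab, 10L, seed = 2)
  expect_equal(sort(unique(folds$fold)), 1:10)
  expect_equal(nrow(folds), 61L)
  expect_false(anyDuplicated(folds$patient_id) > 0)
  # deterministic given seed
  expect_identical(folds, grouped_folds(tab, 10L, seed = 2))
  # too few patients
  expect_error(grouped_folds(toy_table(n_patients = 5), 10L), "5 patients")
})

test_that("both cases of a repeat-inclusion patient share one fold", {
  tab <- toy_table(n_patients = 12)
  tab2 <- tab[tab$patient_id == "P03", ]
  tab2$case_id <- "P03_C2"
  tab <- rbind(tab, tab2)
  folds <- grouped_folds(tab, 4L, seed = 7)
  f <- folds$fold[folds$patient_id == "P03"]
  expect_length(f, 1L)
  fold_of <- folds$fold[match(tab$patient_id, folds$patient_id)]
  expect_length(unique(fold_of[tab$patient_id == "P03"]), 1L)
})

test_that("a separable table cross-validates perfectly without leakage", {
  tab <- toy_table(sep = 20, seed = 3, all_features = TRUE)
  cv <- cross_validate(tab, grouped_folds(tab, 4L, seed = 3),
                       rf_config(n_trees = 50L, seed = 3), n_folds = 4L)
  expect_equal(cv$macro_auc, 1.0)
  expect_equal(cv$pooled$accuracy, 1.0)
  expect_true(assert_no_leakage(cv))
  expect_equal(sum(is.na(cv$predictions$prob_tp)), 0L)
  expect_equal(sum(cv$importances), 1, tolerance = 1e-9)
  expect_true(all(cv$importances >= 0))
})

test_that("pooled accuracy equals the fold-size-weighted mean accuracy", {
  tab <- toy_table(sep = 1.5, seed = 9)
  cv <- cross_validate(tab, grouped_folds(tab, 4L, seed = 9),
                       rf_config(n_trees = 30L, seed = 9), n_folds = 4L)
  weighted <- sum(cv$per_fold$accuracy * cv$per_fold$n) / sum(cv$per_fold$n)
  expect_equal(cv$pooled$accuracy, weighted, tolerance = 1e-12)
})

test_that("classification metrics match hand-evaluated confusion tables", {
  r <- classification_report(c("TP", "TP", "PsP", "PsP"),
                             c(0.9, 0.8, 0.2, 0.1))
  expect_equal(r$accuracy, 1)
  expect_equal(unname(r$per_class["TP", "f1"]), 1)
  expect_equal(unname(r$per_class["PsP", "f1"]), 1)
  expect_equal(r$auc, 1)

  r2 <- classification_report(c("TP", "PsP", "TP", "PsP"),
                              c(0.6, 0.6, 0.4, 0.4))
  expect_equal(r2$accuracy, 0.5)
  expect_equal(unname(r2$per_class["TP", "precision"]), 0.5)

  # F1 is the harmonic mean of the reported precision and recall
  set.seed(4)
  for (i in 1:10) {
    y <- sample(c("TP", "PsP"), 40, replace = TRUE)
    p <- runif(40)
    rep_i <- suppressWarnings(classification_report(y, p))
    for (cl in c("TP", "PsP")) {
      pr <- rep_i$per_class[cl, "precision"]; rc <- rep_i$per_class[cl, "recall"]
      if (is.finite(pr) && is.finite(rc) && pr + rc > 0)
        expect_equal(unname(rep_i$per_class[cl, "f1"]),
                     2 * pr * rc / (pr + rc), tolerance = 1e-12)
    }
  }

  expect_warning(classification_report(rep("TP", 4), c(.9, .8, .7, .6)),
                 "single-class")
})

test_that("Mann-Whitney U matches pair enumeration and its identities", {
  r <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(unname(r$U), 0)          # no x beats any y
  expect_equal(r$direction, -1)

  x <- c(5, 6, 7, 8)
  r2 <- mann_whitney_u(x, x)
  expect_equal(unname(r2$U), length(x)^2 / 2)
  expect_gt(r2$p_value, 0.9)
  expect_equal(r2$direction, 0)

  set.seed(6)
  for (i in 1:10) {
    a <- rnorm(sample(3:30, 1)); b <- rnorm(sample(3:30, 1))
    expect_equal(unname(mann_whitney_u(a, b)$U + mann_whitney_u(b, a)$U),
                 length(a) * length(b))
  }
  expect_error(mann_whitney_u(numeric(0), 1:3), "empty")
})

test_that("significance stars follow the 0.05 / 0.01 / 0.001 thresholds", {
  expect_equal(significance_stars(c(0.04, 0.004, 0.0004, 0.2)),
               c("*", "**", "***", "ns"))
})

test_that("percentile contrasts report the seven headline features", {
  tab <- toy_table(sep = 2, seed = 10)
  res <- compare_percentile_features(tab)
  expect_equal(nrow(res), 7L)
  med <- res[res$feature == "PET__firstorder__median", ]
  expect_lt(med$p_value, 0.001)
  expect_equal(med$direction, 1)
  expect_equal(med$stars, "***")
  tab$PET__firstorder__p10 <- NULL
  expect_error(compare_percentile_features(tab), "PET__firstorder__p10")
})

test_that("null labels give chance-level performance", {
  tab <- toy_table(sep = 3, seed = 12, n_patients = 14)
  null_tab <- permute_labels_within_patients(tab, seed = 99)
  expect_equal(sort(null_tab$label), sort(tab$label))
  # permutation preserves each patient's class mix
  for (p in unique(tab$patient_id))
    expect_equal(sort(null_tab$label[null_tab$patient_id == p]),
                 sort(tab$label[tab$patient_id == p]))
})

test_that("only-PET class signal concentrates importance on PET features", {
  cfg <- cohort_config(
    n_patients = 12,
    geometry = vox_geometry(c(48, 48, 48), c(2, 2, 2)),
    tumor_radius_mm = 14, rim_thickness_mm = 7, edema_margin_mm = 5,
    class_means = list(TBR = c(TP = 2.8, PsP = 1.8),
                       CBV = c(TP = 1.7, PsP = 1.7),
                       T1c = c(TP = 3.2, PsP = 3.2)),
    seed = 55)
  co <- generate_cohort(cfg)
  parts <- lapply(co, function(b) {
    svx <- slic_supervoxels(
      list(CBV = b$channels$CBV, PET = b$channels$PET_raw,
           T1c = b$channels$T1c_baseline), b$masks$cet, slic_config())
    list(ch = list(CBV = b$channels$CBV, PET = b$channels$PET_raw,
                   T1c = b$channels$T1c_baseline),
         svx = svx, ml = majority_label(svx, b$truth_labels))
  })
  names(parts) <- vapply(co, `[[`, "", "case_id")
  tab <- extract_feature_table(
    co, lapply(parts, `[[`, "ch"), lapply(parts, `[[`, "svx"),
    lapply(parts, `[[`, "ml"))
  cv <- cross_validate(tab, grouped_folds(tab, 4L, seed = 55),
                       rf_config(seed = 55), n_folds = 4L)
  ch_imp <- channel_importance(cv)
  expect_gt(ch_imp["PET"], ch_imp["CBV"])
  expect_gt(ch_imp["PET"], ch_imp["T1c"])
  expect_equal(sum(ch_imp), 1, tolerance = 1e-9)
})
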