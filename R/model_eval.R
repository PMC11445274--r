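#' Patient-grouped fold assignment
#'
#' Assigns whole patients to folds so that every supervoxel of a patient
#' (across repeat inclusions) lands in the same fold — the guard against
#' information leakage in cross-validation. Folds are balanced by a greedy
#' largest-first heuristic on per-patient supervoxel counts; ties are broken
#' by a seeded shuffle, so the assignment is deterministic given the seed.
#'
#' @param table a `feature_table` (needs `patient_id`).
#' @param n_folds number of folds (default 10).
#' @param seed integer seed.
#' @return A data frame `patient_id`, `fold` of class `fold_assignment`.
#' @export
grouped_folds <- function(table, n_folds = 10L, seed = 1L) {
  counts <- table(table$patient_id)
  patients <- names(counts)
  if (length(patients) < n_folds)
    stop(sprintf("only %d patients for %d folds", length(patients), n_folds),
         call. = FALSE)
  set.seed(seed)
  ord <- order(-as.integer(counts), sample.int(length(patients)))
  loads <- numeric(n_folds)
  fold <- integer(length(patients))
  for (i in ord) {
    f <- which.min(loads)
    fold[i] <- f
    loads[f] <- loads[f] + counts[i]
  }
  out <- data.frame(patient_id = patients, fold = fold,
                    stringsAsFactors = FALSE)
  class(out) <- c("fold_assignment", "data.frame")
  out
}

#' Mann-Whitney U test (normal approximation, tie-corrected)
#'
#' Thin, typed wrapper around the rank-sum machinery of
#' [stats::wilcox.test()]: U by midranks, two-sided p-value via the normal
#' approximation with continuity and tie correction.
#'
#' @param x,y numeric samples (each nonempty).
#' @return An object of class `mwu_result`: `U` (number of (x, y) pairs
#'   with x > y, ties counted half), `n1`, `n2`, `p_value`, and the
#'   `direction` of the median difference (+1, 0, -1).
#' @export
mann_whitney_u <- function(x, y) {
  if (!length(x) || !length(y)) stop("empty sample", call. = FALSE)
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                            correct = TRUE))
  structure(list(U = unname(wt$statistic), n1 = length(x), n2 = length(y),
                 p_value = wt$p.value,
                 direction = sign(stats::median(x) - stats::median(y))),
            class = "mwu_result")
}

#' @export
print.mwu_result <- function(x, ...) {
  cat(sprintf("<mwu_result> U = %.1f (n1 = %d, n2 = %d), p = %.3g, %s\n",
              x$U, x$n1, x$n2, x$p_value,
              c("x < y", "x ~ y", "x > y")[x$direction + 2]))
  invisible(x)
}

#' Classification metrics at a probability cutoff
#'
#' Binarizes TP probabilities at the pre-defined cutoff (default 0.5;
#' probabilities >= cutoff predict TP) and reports accuracy, balanced
#' accuracy, sensitivity (TP recall), specificity (PsP recall) and
#' per-class precision/recall/F1, plus the AUC when both classes are
#' present (with TP as the positive class).
#'
#' @param y_true factor/character truth with levels `"TP"`, `"PsP"`.
#' @param prob numeric TP probabilities in \[0, 1\].
#' @param cutoff probability cutoff (default 0.5).
#' @return A list of class `classification_report`.
#' @export
classification_report <- function(y_true, prob, cutoff = 0.5) {
  y <- as.character(y_true)
  stopifnot(all(y %in% c("TP", "PsP")))
  if (any(prob < 0 | prob > 1)) stop("prob must lie in [0, 1]", call. = FALSE)
  pred <- ifelse(prob >= cutoff, "TP", "PsP")
  tp <- sum(pred == "TP" & y == "TP")
  fp <- sum(pred == "TP" & y == "PsP")
  fn <- sum(pred == "PsP" & y == "TP")
  tn <- sum(pred == "PsP" & y == "PsP")
  prf <- function(tp, fp, fn) {
    prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    f1 <- if (isTRUE(prec + rec > 0)) 2 * prec * rec / (prec + rec) else NA_real_
    c(precision = prec, recall = rec, f1 = f1)
  }
  auc <- NA_real_
  macro_auc <- NA_real_
  if (length(unique(y)) == 2L) {
    roc <- pROC::roc(response = y, predictor = prob,
                     levels = c("PsP", "TP"), direction = "<", quiet = TRUE)
    auc <- as.numeric(pROC::auc(roc))
    roc2 <- pROC::roc(response = y, predictor = 1 - prob,
                      levels = c("TP", "PsP"), direction = "<", quiet = TRUE)
    macro_auc <- mean(c(auc, as.numeric(pROC::auc(roc2))))
  } else {
    warning("single-class truth: AUC undefined, reported as NA")
  }
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  structure(list(
    confusion = matrix(c(tp, fn, fp, tn), 2, 2,
                       dimnames = list(truth = c("TP", "PsP"),
                                       predicted = c("TP", "PsP"))),
    accuracy = (tp + tn) / length(y),
    balanced_accuracy = mean(c(sens, spec)),
    sensitivity = sens,
    specificity = spec,
    per_class = rbind(TP = prf(tp, fp, fn), PsP = prf(tn, fn, fp)),
    auc = auc,
    macro_auc = macro_auc,
    cutoff = cutoff,
    n = length(y)), class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("<classification_report> n = %d @ cutoff %.2f\n", x$n, x$cutoff))
  cat(sprintf("  accuracy %.3f | balanced %.3f | macro AUC %s\n",
              x$accuracy, x$balanced_accuracy,
              ifelse(is.na(x$macro_auc), "NA", sprintf("%.3f", x$macro_auc))))
  for (cl in rownames(x$per_class))
    cat(sprintf("  %-3s precision %.2f recall %.2f F1 %.2f\n", cl,
                x$per_class[cl, "precision"], x$per_class[cl, "recall"],
                x$per_class[cl, "f1"]))
  invisible(x)
}

#' Patient-grouped cross-validated training and evaluation
#'
#' Per fold: fit the forest on the other folds' supervoxels, predict TP
#' probabilities on the held-out fold; pool the out-of-fold probabilities
#' and compute metrics at the 0.5 cutoff. The macro AUC is the unweighted
#' mean of the per-class one-vs-rest AUCs (identical to the single AUC for
#' a binary problem with complementary scores, but both are reported).
#' Records per-row fold/patient provenance so the no-leakage property can
#' be asserted programmatically.
#'
#' @param table a `feature_table` with `patient_id` and `label`.
#' @param folds a [grouped_folds()] assignment (built from `rf$seed` when
#'   `NULL`).
#' @param rf an [rf_config()].
#' @param n_folds folds used when `folds` is `NULL`.
#' @return An object of class `cv_result`.
#' @export
cross_validate <- function(table, folds = NULL, rf = rf_config(),
                           n_folds = 10L) {
  if (is.null(folds)) folds <- grouped_folds(table, n_folds, seed = rf$seed)
  fcols <- feature_columns(table)
  if (!length(fcols)) stop("table carries no feature columns", call. = FALSE)
  fold_of <- folds$fold[match(table$patient_id, folds$patient_id)]
  if (anyNA(fold_of)) stop("patients missing from fold assignment",
                           call. = FALSE)
  y <- factor(table$label, levels = c("PsP", "TP"))
  prob <- rep(NA_real_, nrow(table))
  fold_ids <- sort(unique(folds$fold))
  per_fold <- data.frame(fold = fold_ids, n = NA_integer_,
                         auc = NA_real_, macro_auc = NA_real_,
                         accuracy = NA_real_)
  importances <- NULL
  train_patients <- list()
  for (f in fold_ids) {
    tr <- fold_of != f
    te <- !tr
    if (!any(te)) next
    ytr <- droplevels(y[tr])
    if (nlevels(ytr) < 2L)
      stop(sprintf("training split for fold %d contains a single class", f),
           call. = FALSE)
    fit <- fit_response_forest(table[tr, fcols], y[tr],
                               rf_config(rf$n_trees, rf$split_criterion,
                                         rf$mtry, seed = rf$seed + f))
    prob[te] <- predict(fit, table[te, fcols])
    importances <- if (is.null(importances)) fit$importances
    else importances + fit$importances
    train_patients[[as.character(f)]] <- unique(table$patient_id[tr])
    rep_f <- suppressWarnings(
      classification_report(y[te], prob[te], cutoff = 0.5))
    per_fold[per_fold$fold == f, c("n", "auc", "macro_auc", "accuracy")] <-
      list(sum(te), rep_f$auc, rep_f$macro_auc, rep_f$accuracy)
  }
  importances <- importances / sum(importances)
  pooled <- classification_report(y, prob, cutoff = 0.5)
  structure(list(
    predictions = data.frame(patient_id = table$patient_id,
                             case_id = table$case_id,
                             svx_id = table$svx_id,
                             label = as.character(y),
                             fold = fold_of,
                             prob_tp = prob,
                             stringsAsFactors = FALSE),
    per_fold = per_fold,
    pooled = pooled,
    macro_auc = pooled$macro_auc,
    importances = importances,
    folds = folds,
    train_patients = train_patients,
    rf = rf), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d folds, %d supervoxels\n",
              nrow(x$per_fold), nrow(x$predictions)))
  cat(sprintf("  pooled macro AUC %.3f | accuracy %.1f%%\n",
              x$macro_auc, 100 * x$pooled$accuracy))
  invisible(x)
}

#' Assert the no-leakage property of a cross-validation result
#'
#' Every supervoxel's out-of-fold probability must come from a model whose
#' training set contained no supervoxel sharing its `patient_id`.
#'
#' @param cv a [cross_validate()] result.
#' @return `TRUE` invisibly; errors when leakage is detected.
#' @export
assert_no_leakage <- function(cv) {
  stopifnot(inherits(cv, "cv_result"))
  for (f in names(cv$train_patients)) {
    test_pat <- unique(cv$predictions$patient_id[cv$predictions$fold ==
                                                   as.integer(f)])
    bad <- intersect(test_pat, cv$train_patients[[f]])
    if (length(bad))
      stop("leakage: patient(s) ", paste(bad, collapse = ", "),
           " appear in both training and test of fold ", f, call. = FALSE)
  }
  invisible(TRUE)
}

#' Channel-summed feature importances
#'
#' @param cv a [cross_validate()] result.
#' @return Named numeric vector: total importance per channel.
#' @export
channel_importance <- function(cv) {
  imp <- cv$importances
  ch <- sub("__.*$", "", names(imp))
  tapply(imp, ch, sum)
}

#' Top-ranked features by importance
#'
#' @param cv a [cross_validate()] result.
#' @param n number of features (default 20, the usual reporting depth).
#' @return Data frame `feature`, `importance`, sorted descending.
#' @export
top_features <- function(cv, n = 20L) {
  imp <- sort(cv$importances, decreasing = TRUE)
  data.frame(feature = names(imp)[seq_len(min(n, length(imp)))],
             importance = unname(imp[seq_len(min(n, length(imp)))]),
             stringsAsFactors = FALSE)
}

#' Permute labels within patients (null cohort)
#'
#' Destroys the feature-label association while preserving each patient's
#' class mix, for permutation-null calibration of the classifier.
#'
#' @param table a `feature_table`.
#' @param seed integer seed.
#' @return The table with `label` permuted within each `patient_id`.
#' @export
permute_labels_within_patients <- function(table, seed = 1L) {
  set.seed(seed)
  for (p in unique(table$patient_id)) {
    sel <- which(table$patient_id == p)
    table$label[sel] <- sample(table$label[sel])
  }
  table
}

#' Significance stars
#'
#' @param p p-value.
#' @return `"***"` for p < 0.001, `"**"` for p < 0.01, `"*"` for p < 0.05,
#'   `"ns"` otherwise.
#' @export
significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns")))
}

#' TP-vs-PsP contrasts of the tangible percentile features
#'
#' Mann-Whitney comparisons of the seven headline supervoxel features
#' between TP- and PsP-labeled supervoxels: PET P10/median/P90, CBV
#' P10/P90, and T1c P10/P90, with direction and significance stars.
#'
#' @param table a `feature_table` with both classes.
#' @return Data frame of class `percentile_contrasts`: `feature`, `U`,
#'   `p_value`, `direction` (+1 when TP > PsP in median), `stars`.
#' @export
compare_percentile_features <- function(table) {
  feats <- c("PET__firstorder__p10", "PET__firstorder__median",
             "PET__firstorder__p90",
             "CBV__firstorder__p10", "CBV__firstorder__p90",
             "T1c__firstorder__p10", "T1c__firstorder__p90")
  missing <- setdiff(feats, names(table))
  if (length(missing))
    stop("missing feature column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  tp <- table$label == "TP"
  if (!any(tp) || all(tp))
    stop("table must contain both TP and PsP supervoxels", call. = FALSE)
  rows <- lapply(feats, function(fc) {
    r <- mann_whitney_u(table[[fc]][tp], table[[fc]][!tp])
    data.frame(feature = fc, U = r$U, n_tp = r$n1, n_psp = r$n2,
               p_value = r$p_value, direction = r$direction,
               stars = significance_stars(r$p_value),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("percentile_contrasts", "data.frame")
  out
}

#' Proportions of a printed contingency row
#'
#' Worked-example helper for recomputing published contingency tables:
#' turns a vector of counts into proportions and rounded percentages.
#'
#' @param counts named integer vector of category counts.
#' @return Data frame `category`, `count`, `proportion`, `pct` (percent
#'   rounded to integer, as such tables print them).
#' @export
contingency_proportions <- function(counts) {
  total <- sum(counts)
  if (total <= 0) stop("counts must sum to a positive total", call. = FALSE)
  data.frame(category = names(counts),
             count = as.integer(counts),
             proportion = as.numeric(counts) / total,
             pct = round(100 * as.numeric(counts) / total),
             stringsAsFactors = FALSE)
}
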