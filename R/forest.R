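#' Random forest configuration
#'
#' The classifier is an in-package random forest: bagged CART trees grown
#' with an entropy (information) split criterion, each tree seeing a
#' bootstrap resample of the supervoxels and a random subset of
#' `floor(sqrt(p))` features. Class probability is the fraction of trees
#' voting for the class; impurity-based importances are accumulated over
#' trees and normalized to sum 1.
#'
#' @param n_trees number of trees (default 100).
#' @param split_criterion `"entropy"` (information gain) or `"gini"`.
#' @param mtry features drawn per tree; default `floor(sqrt(p))` at fit
#'   time when `NULL`.
#' @param seed integer seed for bootstrap and feature subsampling.
#' @return An object of class `rf_config`.
#' @export
rf_config <- function(n_trees = 100L, split_criterion = c("entropy", "gini"),
                      mtry = NULL, seed = 1L) {
  split_criterion <- match.arg(split_criterion)
  if (n_trees < 1L) stop("n_trees must be >= 1", call. = FALSE)
  structure(list(n_trees = as.integer(n_trees),
                 split_criterion = split_criterion,
                 mtry = if (!is.null(mtry)) as.integer(mtry),
                 seed = as.integer(seed)),
            class = "rf_config")
}

#' Fit the entropy-split random forest
#'
#' @param x data frame or matrix of features.
#' @param y factor of class labels (two levels, `"PsP"` < `"TP"` by
#'   convention).
#' @param config an [rf_config()].
#' @return An object of class `response_forest` with the tree list,
#'   per-tree feature subsets and normalized impurity importances.
#' @export
fit_response_forest <- function(x, y, config = rf_config()) {
  x <- as.data.frame(x)
  y <- factor(y)
  if (nlevels(y) < 2L)
    stop("training data must contain both classes", call. = FALSE)
  n <- nrow(x); p <- ncol(x)
  mtry <- if (!is.null(config$mtry)) min(config$mtry, p)
  else max(1L, floor(sqrt(p)))
  split <- if (config$split_criterion == "entropy") "information" else "gini"
  ctrl <- rpart::rpart.control(minsplit = 2L, minbucket = 1L, cp = 0,
                               xval = 0L, maxdepth = 30L,
                               maxcompete = 0L, maxsurrogate = 0L)
  set.seed(config$seed)
  imp <- stats::setNames(numeric(p), colnames(x))
  trees <- vector("list", config$n_trees)
  feat_sets <- vector("list", config$n_trees)
  for (t in seq_len(config$n_trees)) {
    rows <- sample.int(n, n, replace = TRUE)
    feats <- sort(sample.int(p, mtry))
    if (length(unique(y[rows])) < 2L) {
      # single-class bootstrap resample: the tree degenerates to a
      # constant vote for that class
      trees[[t]] <- as.character(y[rows[1]])
      feat_sets[[t]] <- character(0)
      next
    }
    d <- x[rows, feats, drop = FALSE]
    d$.y <- droplevels(y[rows])
    fit <- rpart::rpart(.y ~ ., data = d, method = "class",
                        parms = list(split = split), control = ctrl)
    trees[[t]] <- fit
    feat_sets[[t]] <- colnames(x)[feats]
    vi <- fit$variable.importance
    if (!is.null(vi)) imp[names(vi)] <- imp[names(vi)] + vi
  }
  if (sum(imp) > 0) imp <- imp / sum(imp)
  structure(list(trees = trees, feature_sets = feat_sets,
                 levels = levels(y), importances = imp, config = config),
            class = "response_forest")
}

#' Predict TP probability (vote fraction) from a fitted forest
#'
#' @param object a `response_forest`.
#' @param newdata feature data frame.
#' @param ... unused.
#' @return Numeric vector of probabilities of the `"TP"` class (last
#'   factor level when labels are not TP/PsP).
#' @export
predict.response_forest <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  pos <- if ("TP" %in% object$levels) "TP" else object$levels[length(object$levels)]
  votes <- numeric(nrow(newdata))
  for (t in seq_along(object$trees)) {
    tree <- object$trees[[t]]
    if (is.character(tree)) {            # constant-vote degenerate tree
      votes <- votes + (tree == pos)
      next
    }
    cls <- predict(tree, newdata = newdata, type = "class")
    votes <- votes + (as.character(cls) == pos)
  }
  votes / length(object$trees)
}

#' @export
print.response_forest <- function(x, ...) {
  cat(sprintf("<response_forest> %d %s-split trees, %d features in play\n",
              length(x$trees), x$config$split_criterion,
              sum(x$importances > 0)))
  invisible(x)
}
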