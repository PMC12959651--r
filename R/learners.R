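#' Learner specifications
#'
#' A learner specification bundles fit/predict/importance closures behind a
#' common interface so the same cross-validation, feature-elimination and
#' ensemble code can drive different algorithms. The primary learner is the
#' gradient-boosted decision tree (\code{learner_gbdt}, leaf-wise growth on
#' xgboost's histogram method); logistic regression, random forest and
#' linear-kernel SVM are available as framework-comparison baselines.
#' Non-tree learners are min-max scaled internally (ranges fitted on the
#' training rows of each fit).
#'
#' The boosted-tree defaults deliberately favour ensemble-member diversity
#' over single-model polish: strong per-tree feature subsampling and row
#' bagging decorrelate the 25 fold models, and the bootstrap abstention test
#' (\code{\link{bootstrap_pvalue}}) is only informative when members can
#' disagree. A single maximally accurate model is better obtained by
#' hyperparameter search (\code{\link{tune_hyperparams}}).
#'
#' @param nrounds Boosting rounds.
#' @param eta Learning rate.
#' @param max_leaves Maximum leaves per tree (leaf-wise growth).
#' @param booster \code{"gbtree"} or \code{"dart"}.
#' @param subsample Row-bagging fraction.
#' @param colsample_bytree Feature fraction per tree.
#' @param reg_alpha,reg_lambda L1/L2 regularisation.
#' @param min_child_weight Minimum hessian sum per child.
#' @param min_split_gain Minimum loss reduction to split (gamma).
#' @return A \code{del_learner} object.
#' @export
learner_gbdt <- function(nrounds = 60, eta = 0.3, max_leaves = 31,
                         booster = "gbtree", subsample = 0.25,
                         colsample_bytree = 0.08, reg_alpha = 0, reg_lambda = 1,
                         min_child_weight = 3, min_split_gain = 0) {
  params <- list(objective = "binary:logistic", booster = booster, eta = eta,
                 tree_method = "hist", grow_policy = "lossguide",
                 max_leaves = max_leaves, max_depth = 0,
                 subsample = subsample, colsample_bytree = colsample_bytree,
                 alpha = reg_alpha, lambda = reg_lambda,
                 min_child_weight = min_child_weight, gamma = min_split_gain,
                 nthread = 1)
  structure(list(
    name = "gbdt",
    scale = FALSE,
    params = c(params, nrounds = nrounds),
    fit = function(x, y) {
      p <- c(params, list(seed = sample.int(.Machine$integer.max, 1)))
      xgboost::xgb.train(p, xgboost::xgb.DMatrix(x, label = y),
                         nrounds = nrounds, verbose = 0)
    },
    predict = function(model, x) predict(model, xgboost::xgb.DMatrix(x)),
    importance = function(model, feature_names) {
      imp <- xgboost::xgb.importance(model = model)
      out <- setNames(rep(0, length(feature_names)), feature_names)
      out[imp$Feature] <- imp$Gain
      out
    }
  ), class = "del_learner")
}

#' @rdname learner_gbdt
#' @export
learner_logistic <- function() {
  structure(list(
    name = "logistic",
    scale = TRUE,
    params = list(),
    fit = function(x, y) {
      # balanced class weights: each class contributes half the total weight
      w <- ifelse(y == 1, length(y) / (2 * sum(y == 1)),
                  length(y) / (2 * sum(y == 0)))
      df <- as.data.frame(x)
      df$.y <- y
      suppressWarnings(glm(.y ~ ., data = df, family = binomial(),
                           weights = w))
    },
    predict = function(model, x)
      as.numeric(predict(model, newdata = as.data.frame(x), type = "response")),
    importance = function(model, feature_names) {
      co <- coef(model)[-1]
      out <- setNames(rep(0, length(feature_names)), feature_names)
      nm <- intersect(names(co), feature_names)
      out[nm] <- abs(co[nm])
      out[is.na(out)] <- 0
      out
    }
  ), class = "del_learner")
}

#' @rdname learner_gbdt
#' @param num_trees Trees in the random forest (default 100).
#' @export
learner_rf <- function(num_trees = 100) {
  if (!requireNamespace("ranger", quietly = TRUE))
    stop("learner_rf requires the 'ranger' package")
  structure(list(
    name = "rf",
    scale = FALSE,
    params = list(num_trees = num_trees),
    fit = function(x, y)
      ranger::ranger(x = as.data.frame(x), y = factor(y, levels = c(0, 1)),
                     num.trees = num_trees, probability = TRUE,
                     importance = "impurity", num.threads = 1,
                     seed = sample.int(.Machine$integer.max, 1)),
    predict = function(model, x)
      predict(model, data = as.data.frame(x),
              num.threads = 1)$predictions[, "1"],
    importance = function(model, feature_names) {
      imp <- ranger::importance(model)
      out <- setNames(rep(0, length(feature_names)), feature_names)
      out[names(imp)] <- imp
      out
    }
  ), class = "del_learner")
}

#' @rdname learner_gbdt
#' @export
learner_svm <- function() {
  if (!requireNamespace("e1071", quietly = TRUE))
    stop("learner_svm requires the 'e1071' package")
  structure(list(
    name = "svm",
    scale = TRUE,
    params = list(kernel = "linear"),
    fit = function(x, y)
      e1071::svm(x, factor(y, levels = c(0, 1)), kernel = "linear",
                 probability = TRUE, scale = FALSE),
    predict = function(model, x) {
      pr <- predict(model, x, probability = TRUE)
      attr(pr, "probabilities")[, "1"]
    },
    importance = function(model, feature_names) {
      w <- drop(t(model$coefs) %*% model$SV)
      out <- setNames(rep(0, length(feature_names)), feature_names)
      out[names(w)] <- abs(w)
      out
    }
  ), class = "del_learner")
}

#' @export
print.del_learner <- function(x, ...) {
  cat("Learner:", x$name,
      if (x$scale) "(min-max scaled input)" else "", "\n")
  invisible(x)
}

# Fit a learner on a numeric matrix, handling internal min-max scaling.
fit_learner <- function(learner, x, y) {
  ranges <- NULL
  if (isTRUE(learner$scale)) {
    ranges <- minmax_fit(x)
    x <- minmax_apply(x, ranges)
  }
  list(model = learner$fit(x, y), ranges = ranges, learner_name = learner$name)
}

predict_learner <- function(learner, fit, x) {
  if (!is.null(fit$ranges)) x <- minmax_apply(x, fit$ranges)
  p <- learner$predict(fit$model, x)
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("learner returned probabilities outside [0, 1]")
  as.numeric(p)
}

# Feature matrix for model input; errors name any missing feature.
feature_matrix <- function(table, features) {
  missing <- setdiff(features, names(table))
  if (length(missing))
    stop("missing feature(s): ", paste(missing, collapse = ", "))
  as.matrix(as.data.frame(lapply(table[features], as.numeric),
                          check.names = FALSE))
}

label01 <- function(label) {
  if (any(!label %in% c("pathogenic", "benign")))
    stop("labels must be 'pathogenic' or 'benign'")
  as.integer(label == "pathogenic")
}
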