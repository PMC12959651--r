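#' Full training pipeline: filter, select, tune, fit
#'
#' Convenience wrapper chaining the training-side stages on one feature
#' table: the filtering cascade (\code{\link{filter_features}}), recursive
#' feature elimination (\code{\link{rfe_select}}), the random
#' hyperparameter search (\code{\link{tune_hyperparams}}, skipped when
#' \code{tune_trials = 0}) and the split/fold ensemble fit
#' (\code{\link{del_train}}). Everything here consumes training data only;
#' hold out a blind test set first with \code{\link{make_split}} and replay
#' the fitted filter on it with \code{\link{apply_filter}}.
#'
#' @param table Training feature table.
#' @param learner Base learner (default \code{learner_gbdt()}).
#' @param filter Run the filtering cascade (default TRUE).
#' @param rfe_sizes Candidate sizes for RFE, or NULL to skip RFE.
#' @param rfe_tol AUC tolerance for the RFE size choice.
#' @param tune_trials Hyperparameter-search trials (0 skips tuning).
#' @param n_splits,n_folds Ensemble layout.
#' @param min_minority,cor_threshold Filter parameters.
#' @param seed Seed.
#' @return A \code{del_pipeline}: list with \code{ensemble},
#'   \code{filter_report}, \code{rfe}, \code{tune}, \code{features}.
#' @export
del_pipeline <- function(table, learner = learner_gbdt(), filter = TRUE,
                         rfe_sizes = seq(10, 190, by = 10), rfe_tol = 0.005,
                         tune_trials = 0, n_splits = 5, n_folds = 5,
                         min_minority = 6, cor_threshold = 0.8, seed = 1) {
  flt <- if (filter) filter_features(table, min_minority = min_minority,
                                     threshold = cor_threshold)
         else list(table = table, report = NULL)
  tab <- flt$table
  plan <- make_split(tab, test_frac = 0, n_folds = n_folds, seed = seed)
  rfe <- if (!is.null(rfe_sizes))
    rfe_select(learner, tab, plan, sizes = rfe_sizes, tol = rfe_tol, seed = seed)
  feats <- if (!is.null(rfe)) rfe$features else model_feature_names(tab)
  tune <- if (tune_trials > 0)
    tune_hyperparams(tab, plan, n_trials = tune_trials, features = feats,
                     seed = seed)
  learner_final <- if (!is.null(tune)) do.call(learner_gbdt, tune$best_params)
                   else learner
  fit <- del_train(tab, features = feats, learner = learner_final,
                   n_splits = n_splits, n_folds = n_folds, seed = seed)
  structure(list(ensemble = fit, filter_report = flt$report, rfe = rfe,
                 tune = tune, features = feats),
            class = "del_pipeline")
}

#' @export
print.del_pipeline <- function(x, ...) {
  if (!is.null(x$filter_report)) print(x$filter_report)
  if (!is.null(x$rfe)) cat("RFE: kept", x$rfe$size, "features\n")
  if (!is.null(x$tune)) cat("Tuning: best CV AUC", round(x$tune$best_auc, 4), "\n")
  print(x$ensemble)
  invisible(x)
}

#' Read/write feature tables as CSV
#'
#' Plain-CSV persistence for feature tables (registry metadata is inferred
#' on re-read: 0/1 columns as binary, character columns as sequence).
#'
#' @param table A feature table.
#' @param path File path.
#' @return \code{path} / the table.
#' @export
write_feature_table <- function(table, path) {
  write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE)
  structure(out, class = c("feature_table", "data.frame"))
}
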