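#' Protein-disjoint stratified train/test split with cross-validation folds
#'
#' Assigns whole proteins -- never individual variants -- to the training or
#' test side, so no protein contributes variants to both. Proteins are first
#' given a protein-level class (majority label of their variants; ties count
#' as pathogenic), then shuffled within class and assigned to the test side
#' until each class's test variant count reaches \code{test_frac} of that
#' class. The training proteins are further partitioned into
#' \code{n_folds} protein-disjoint cross-validation groups, balancing variant
#' counts per class greedily. The resulting variant-level pathogenic
#' fraction of the test side stays within a few percentage points of the
#' overall fraction; a deviation above 5 points triggers a warning.
#'
#' @param variants Data frame with at least \code{protein_id} and
#'   \code{label} columns (labels \code{pathogenic}/\code{benign}).
#' @param test_frac Fraction of variants (per class) held out; 0 gives an
#'   empty test side with all proteins folded.
#' @param n_folds Number of cross-validation folds.
#' @param seed Random seed; identical seeds reproduce the plan exactly.
#' @param split_id Identifier stored in the plan.
#' @return A \code{split_plan}: list with \code{train_proteins},
#'   \code{test_proteins}, \code{fold} (named integer vector over train
#'   proteins), \code{protein_class}, \code{seed}, \code{split_id}.
#' @export
make_split <- function(variants, test_frac = 0.2, n_folds = 5, seed = 1,
                       split_id = 1L) {
  v <- as.data.frame(variants)
  if (any(!v$label %in% c("pathogenic", "benign")))
    stop("all variants must be labeled pathogenic or benign for splitting")
  counts <- table(v$protein_id, v$label)
  prots <- rownames(counts)
  n_path <- if ("pathogenic" %in% colnames(counts)) counts[, "pathogenic"] else rep(0, length(prots))
  n_tot <- rowSums(counts)
  pclass <- ifelse(n_path * 2 >= n_tot, "pathogenic", "benign")
  names(pclass) <- prots

  assignment <- with_seed(seed, {
    test <- character(0)
    for (cl in c("pathogenic", "benign")) {
      in_cl <- prots[pclass == cl]
      if (length(in_cl) < 2)
        stop("too few proteins of class '", cl, "' to stratify")
      if (test_frac > 0) {
        sh <- sample(in_cl)
        target <- test_frac * sum(n_tot[in_cl])
        k <- which(cumsum(n_tot[sh]) >= target)[1]
        if (is.na(k)) k <- length(sh) - 1
        k <- min(k, length(sh) - 1)  # keep at least one train protein
        test <- c(test, sh[seq_len(k)])
      }
    }
    train <- setdiff(prots, test)
    # greedy fold balancing: within class, largest proteins first into the
    # currently lightest fold
    fold <- setNames(integer(length(train)), train)
    load <- numeric(n_folds)
    for (cl in c("pathogenic", "benign")) {
      in_cl <- intersect(train, prots[pclass == cl])
      in_cl <- sample(in_cl)
      in_cl <- in_cl[order(-n_tot[in_cl])]
      for (p in in_cl) {
        f <- which.min(load)
        fold[p] <- f
        load[f] <- load[f] + n_tot[p]
      }
    }
    list(test = test, fold = fold)
  })
  test <- assignment$test
  fold <- assignment$fold
  train <- names(fold)

  if (test_frac > 0) {
    overall <- mean(v$label == "pathogenic")
    test_frac_path <- mean(v$label[v$protein_id %in% test] == "pathogenic")
    if (abs(test_frac_path - overall) > 0.05)
      warning(sprintf("test pathogenic fraction %.3f deviates from overall %.3f by > 0.05",
                      test_frac_path, overall))
  }
  structure(list(split_id = split_id, seed = seed, test_frac = test_frac,
                 n_folds = n_folds, protein_class = pclass,
                 train_proteins = train, test_proteins = test, fold = fold),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat("Split plan", x$split_id, "(seed", paste0(x$seed, "):"),
      length(x$train_proteins), "train /", length(x$test_proteins),
      "test proteins,", x$n_folds, "folds\n")
  invisible(x)
}

#' Protein-disjoint cross-validation of a learner
#'
#' Runs one round of k-fold cross-validation over a split plan's fold groups
#' (training rows only). Each fold is held out in turn, the learner is fitted
#' on the remaining folds, and held-out probabilities are scored against the
#' 0.5 threshold. Confusion counts are fold-averaged (so they are fractional)
#' and the summary metrics are computed on those averaged counts; AUC is
#' averaged over folds.
#'
#' @param learner A \code{del_learner}.
#' @param table A feature table restricted to (or containing) the plan's
#'   training proteins.
#' @param plan A \code{split_plan}.
#' @param features Feature names to use (default: all numeric/binary
#'   registry features).
#' @param seed Seed for per-fold learner randomness.
#' @return A \code{del_cv}: list with \code{folds} (per-fold metrics
#'   reports and AUCs), \code{mean_counts}, \code{mean_metrics},
#'   \code{mean_auc}.
#' @export
cross_validate <- function(learner, table, plan, features = NULL, seed = 1) {
  features <- features %||% model_feature_names(table)
  tab <- table[table$protein_id %in% plan$train_proteins, , drop = FALSE]
  fold <- plan$fold[tab$protein_id]
  x <- feature_matrix(tab, features)
  y <- label01(tab$label)
  folds <- list()
  aucs <- numeric(plan$n_folds)
  count_sum <- c(TP = 0, TN = 0, FP = 0, FN = 0)
  for (f in seq_len(plan$n_folds)) {
    tr <- fold != f
    va <- fold == f
    if (length(unique(y[tr])) < 2 || length(unique(y[va])) < 2)
      stop("fold ", f, " has a single class; refit the split plan")
    fit <- with_seed(seed + f, fit_learner(learner, x[tr, , drop = FALSE], y[tr]))
    p <- predict_learner(learner, fit, x[va, , drop = FALSE])
    calls <- ifelse(p > 0.5, "pathogenic", "benign")
    cc <- confusion(tab$label[va], calls)
    aucs[f] <- auc_rank(tab$label[va], p)
    count_sum <- count_sum + unlist(cc[c("TP", "TN", "FP", "FN")])
    folds[[f]] <- list(counts = cc, metrics = del_metrics(cc), auc = aucs[f])
  }
  mean_counts <- confusion_counts(TP = count_sum["TP"] / plan$n_folds,
                                  TN = count_sum["TN"] / plan$n_folds,
                                  FP = count_sum["FP"] / plan$n_folds,
                                  FN = count_sum["FN"] / plan$n_folds)
  structure(list(folds = folds, mean_counts = mean_counts,
                 mean_metrics = del_metrics(mean_counts),
                 mean_auc = mean(aucs), learner = learner$name),
            class = "del_cv")
}

#' @export
print.del_cv <- function(x, ...) {
  cat("Cross-validation (", length(x$folds), " folds, learner ", x$learner,
      ")\n", sep = "")
  cat("mean AUC:", round(x$mean_auc, 3), "\n")
  print(x$mean_metrics)
  invisible(x)
}

#' Recursive feature elimination with cross-validated size choice
#'
#' Ranks features by recursive elimination -- the learner is fitted on the
#' current set, the least important features are removed down to the next
#' grid size, and so on -- then measures mean cross-validated AUC for each
#' candidate size. The chosen size is the smallest whose mean AUC is within
#' \code{tol} of the best, trading a marginal score for a compact model
#' (\code{tol = 0} gives the argmax size).
#'
#' @param learner A \code{del_learner} with an importance function.
#' @param table Feature table (training proteins).
#' @param plan A \code{split_plan}.
#' @param sizes Candidate feature-set sizes (default 10 to 190 by 10; sizes
#'   beyond the available features are truncated with a warning).
#' @param tol AUC tolerance for preferring smaller sets (default 0.005).
#' @param seed Seed.
#' @return An \code{rfe_result}: list with \code{ranking} (all features,
#'   most important first), \code{sizes}, \code{cv_auc}, chosen \code{size}
#'   and \code{features}.
#' @export
rfe_select <- function(learner, table, plan, sizes = seq(10, 190, by = 10),
                       tol = 0.005, seed = 1) {
  features <- model_feature_names(table)
  p <- length(features)
  if (any(sizes > p)) {
    warning("feature-set sizes above ", p, " truncated")
    sizes <- sizes[sizes <= p]
  }
  if (length(sizes) == 0) sizes <- p
  sizes <- sort(unique(as.integer(sizes)))

  tab <- table[table$protein_id %in% plan$train_proteins, , drop = FALSE]
  y <- label01(tab$label)
  grid <- sort(unique(c(sizes, p)), decreasing = TRUE)
  current <- features
  elim <- character(0)
  for (g in seq_along(grid)[-1]) {
    x <- feature_matrix(tab, current)
    fit <- with_seed(seed + g, fit_learner(learner, x, y))
    imp <- learner$importance(fit$model, current)
    ord <- order(imp, decreasing = TRUE)
    drop_n <- length(current) - grid[g]
    dropped <- current[rev(ord)][seq_len(drop_n)]
    elim <- c(dropped, elim)  # earlier-eliminated features rank last
    current <- current[ord][seq_len(grid[g])]
  }
  # remaining (smallest-set) features ranked by final importance
  x <- feature_matrix(tab, current)
  fit <- with_seed(seed, fit_learner(learner, x, y))
  imp <- learner$importance(fit$model, current)
  ranking <- c(current[order(imp, decreasing = TRUE)], elim)

  cv_auc <- vapply(sizes, function(s)
    cross_validate(learner, tab, plan, features = ranking[seq_len(s)],
                   seed = seed)$mean_auc, numeric(1))
  best <- max(cv_auc)
  size <- sizes[which(cv_auc >= best - tol)[1]]
  structure(list(ranking = ranking, sizes = sizes, cv_auc = cv_auc,
                 size = size, features = ranking[seq_len(size)], tol = tol),
            class = "rfe_result")
}

#' @export
print.rfe_result <- function(x, ...) {
  cat("RFE: chose", x$size, "features (tolerance", x$tol, ")\n")
  print(data.frame(size = x$sizes, cv_auc = round(x$cv_auc, 4)))
  invisible(x)
}

#' Seeded random hyperparameter search for the boosted-tree learner
#'
#' Samples \code{n_trials} configurations from the boosted-tree search space
#' (learning rate, boosting type, number of leaves, L1/L2 regularisation,
#' bagging fraction, minimum child weight, minimum split gain, feature
#' fraction) and scores each by mean cross-validated AUC on the plan's
#' folds. The incumbent best is tracked over the trial log.
#'
#' @param table Feature table (training proteins).
#' @param plan A \code{split_plan}.
#' @param n_trials Number of sampled configurations (default 100).
#' @param features Feature subset (default all numeric registry features).
#' @param seed Seed making the whole search reproducible.
#' @param nrounds Boosting rounds per trial.
#' @return A \code{del_tune}: list with \code{best_params},
#'   \code{best_auc}, \code{trials} (data frame with per-trial AUC and
#'   incumbent), \code{params} (list of sampled configurations).
#' @export
tune_hyperparams <- function(table, plan, n_trials = 100, features = NULL,
                             seed = 1, nrounds = 200) {
  stopifnot(n_trials >= 1)
  sample_params <- function() list(
    eta = exp(runif(1, log(0.01), log(0.3))),
    booster = sample(c("gbtree", "dart"), 1, prob = c(0.8, 0.2)),
    max_leaves = sample(c(7, 15, 31, 63, 127), 1),
    reg_alpha = exp(runif(1, log(1e-8), log(10))),
    reg_lambda = exp(runif(1, log(1e-8), log(10))),
    subsample = runif(1, 0.5, 1),
    min_child_weight = exp(runif(1, log(1e-3), log(10))),
    min_split_gain = exp(runif(1, log(1e-8), log(1))),
    colsample_bytree = runif(1, 0.5, 1)
  )
  params_log <- vector("list", n_trials)
  auc <- numeric(n_trials)
  with_seed(seed, {
    for (t in seq_len(n_trials)) {
      params_log[[t]] <- sample_params()
      learner <- do.call(learner_gbdt, c(params_log[[t]], nrounds = nrounds))
      auc[t] <- cross_validate(learner, table, plan, features = features,
                               seed = seed + t)$mean_auc
    }
  })
  incumbent <- cummax(auc)
  best <- which.max(auc)
  structure(list(best_params = params_log[[best]], best_auc = auc[best],
                 trials = data.frame(trial = seq_len(n_trials), auc = auc,
                                     best_so_far = incumbent),
                 params = params_log, n_trials = n_trials, seed = seed),
            class = "del_tune")
}

#' @export
print.del_tune <- function(x, ...) {
  cat("Hyperparameter search:", x$n_trials, "trials, best CV AUC",
      round(x$best_auc, 4), "\n")
  str(x$best_params, give.attr = FALSE)
  invisible(x)
}

#' Fit the split/fold ensemble of deletion-pathogenicity models
#'
#' The core fitting function. The training data are partitioned
#' \code{n_splits} times into \code{n_folds} protein-disjoint fold groups
#' (each partition independently re-randomised from a seed derived from
#' \code{seed}); for every (split, fold) pair one model is fitted on the
#' out-of-fold rows, giving \code{n_splits * n_folds} (by default 25)
#' independently trained binary classifiers sharing one feature list. Their
#' per-variant probability spread is what the three-state predictor's
#' bootstrap test consumes (see \code{\link{predict.del_ensemble}}).
#'
#' Everything passed here is training material: hold out a blind,
#' protein-disjoint test set beforehand (\code{\link{make_split}}) if you
#' intend to report unbiased performance. Alternatively supply your own
#' \code{plans} (whose train portions are then used), or a list of
#' \code{n_splits} per-split tables when split-specific features (e.g.
#' logo bit scores refitted per split) are needed.
#'
#' @param data A feature table, or a list of \code{n_splits} feature tables
#'   with identical columns.
#' @param features Feature names (default: all numeric/binary registry
#'   features of the first table).
#' @param learner A \code{del_learner} (default \code{learner_gbdt()}).
#' @param n_splits,n_folds Ensemble layout (default 5 x 5).
#' @param plans Optional list of \code{n_splits} \code{split_plan}s.
#' @param seed Seed; refitting with the same data and seed reproduces every
#'   model exactly.
#' @return A \code{del_ensemble} with \code{print}, \code{summary} and
#'   \code{predict} methods.
#' @examples
#' tab <- simulate_feature_table(n_rows = 300, n_features = 8,
#'                               n_informative = 3, effect = 2, seed = 1)
#' fit <- del_train(tab, n_splits = 2, n_folds = 3,
#'                  learner = learner_gbdt(nrounds = 30), seed = 1)
#' fit
#' @export
del_train <- function(data, features = NULL, learner = learner_gbdt(),
                      n_splits = 5, n_folds = 5, plans = NULL, seed = 1) {
  tables <- if (is.data.frame(data)) rep(list(data), n_splits) else data
  if (length(tables) != n_splits)
    stop("need one table, or one per split (", n_splits, ")")
  features <- features %||% model_feature_names(tables[[1]])
  for (tb in tables) feature_matrix(tb[0, , drop = FALSE], features)  # validate
  if (is.null(plans)) {
    plans <- lapply(seq_len(n_splits), function(s)
      make_split(tables[[s]], test_frac = 0, n_folds = n_folds,
                 seed = (as.numeric(seed) * 131 + s * 7919) %% 2147480009,
                 split_id = s))
  }
  stopifnot(length(plans) == n_splits)
  models <- list()
  for (s in seq_len(n_splits)) {
    tab <- tables[[s]]
    tab <- tab[tab$protein_id %in% plans[[s]]$train_proteins, , drop = FALSE]
    fold <- plans[[s]]$fold[tab$protein_id]
    x <- feature_matrix(tab, features)
    y <- label01(tab$label)
    for (f in seq_len(n_folds)) {
      tr <- fold != f
      fit <- with_seed((as.numeric(seed) * 977 + s * 101 + f) %% 2147480009,
                       fit_learner(learner, x[tr, , drop = FALSE], y[tr]))
      models[[length(models) + 1]] <-
        c(fit, list(split = s, fold = f, n_train = sum(tr)))
    }
  }
  structure(list(models = models, features = features, learner = learner,
                 n_splits = n_splits, n_folds = n_folds, plans = plans,
                 seed = seed, n_obs = nrow(tables[[1]]),
                 label_balance = table(tables[[1]]$label),
                 call = match.call()),
            class = "del_ensemble")
}

#' @export
print.del_ensemble <- function(x, ...) {
  cat("Deletion-pathogenicity ensemble:", length(x$models), "models (",
      x$n_splits, "splits x", x$n_folds, "folds ),", length(x$features),
      "features, learner", x$learner$name, "\n")
  invisible(x)
}

#' @export
summary.del_ensemble <- function(object, ...) {
  cat("Deletion-pathogenicity ensemble\n")
  cat("  models:       ", length(object$models), " (", object$n_splits, " splits x ",
      object$n_folds, " folds)\n", sep = "")
  cat("  learner:      ", object$learner$name, "\n")
  cat("  features (", length(object$features), "): ",
      paste(head(object$features, 8), collapse = ", "),
      if (length(object$features) > 8) ", ..." else "", "\n", sep = "")
  cat("  training rows:", object$n_obs, "\n")
  if (!is.null(object$label_balance)) {
    cat("  label balance:")
    print(object$label_balance)
  }
  cat("  seed:         ", object$seed, "\n")
  invisible(object)
}

#' Persist / restore a fitted ensemble
#'
#' Writes the ensemble to a directory: one model file per (split, fold) plus
#' a \code{manifest.json} recording the feature list, learner name and
#' parameters, layout and seed.
#'
#' @param object A \code{del_ensemble}.
#' @param dir Directory (created if needed).
#' @return \code{dir} (write) or the restored ensemble (read).
#' @export
write_del_ensemble <- function(object, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "delpath",
                   features = object$features,
                   learner = object$learner$name,
                   learner_params = object$learner$params,
                   n_splits = object$n_splits, n_folds = object$n_folds,
                   seed = object$seed,
                   models = vapply(object$models, function(m)
                     sprintf("model_s%d_f%d.rds", m$split, m$fold), character(1)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  for (m in object$models)
    saveRDS(m, file.path(dir, sprintf("model_s%d_f%d.rds", m$split, m$fold)))
  saveRDS(object["plans"], file.path(dir, "plans.rds"))
  invisible(dir)
}

#' @rdname write_del_ensemble
#' @export
read_del_ensemble <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  models <- lapply(manifest$models, function(f) readRDS(file.path(dir, f)))
  learner <- switch(manifest$learner,
                    gbdt = learner_gbdt(), logistic = learner_logistic(),
                    rf = learner_rf(), svm = learner_svm(),
                    stop("unknown learner in manifest: ", manifest$learner))
  plans <- readRDS(file.path(dir, "plans.rds"))$plans
  structure(list(models = models, features = manifest$features,
                 learner = learner, n_splits = manifest$n_splits,
                 n_folds = manifest$n_folds, plans = plans,
                 seed = manifest$seed, n_obs = NA_integer_,
                 label_balance = NULL, call = NULL),
            class = "del_ensemble")
}
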