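quick_gbdt <- function() learner_gbdt(nrounds = 40)

test_that("splits are protein-disjoint, stratified and reproducible", {
  tab <- simulate_feature_table(n_rows = 800, n_features = 5,
                                n_informative = 2, effect = 1, seed = 3)
  plan <- make_split(tab, test_frac = 0.2, n_folds = 5, seed = 17)
  expect_length(intersect(plan$train_proteins, plan$test_proteins), 0)
  expect_setequal(c(plan$train_proteins, plan$test_proteins),
                  unique(tab$protein_id))
  # folds partition the training proteins
  expect_setequal(names(plan$fold), plan$train_proteins)
  expect_setequal(unique(plan$fold), 1:5)
  # stratification: variant-level pathogenic share close to overall
  overall <- mean(tab$label == "pathogenic")
  in_test <- mean(tab$label[tab$protein_id %in% plan$test_proteins] == "pathogenic")
  expect_lt(abs(in_test - overall), 0.05)
  # test size approximately test_frac of variants (protein granularity slack)
  n_test <- sum(tab$protein_id %in% plan$test_proteins)
  expect_gt(n_test, 0.15 * nrow(tab))
  expect_lt(n_test, 0.3 * nrow(tab))
  # identical seed, identical plan
  plan2 <- make_split(tab, test_frac = 0.2, n_folds = 5, seed = 17)
  expect_identical(plan[c("train_proteins", "test_proteins", "fold")],
                   plan2[c("train_proteins", "test_proteins", "fold")])
})

test_that("splitting requires at least two proteins per class", {
  tab <- data.frame(protein_id = c("A", "A", "B"), label = c("pathogenic", "pathogenic", "benign"))
  expect_error(make_split(tab, seed = 1), "too few proteins")
})

test_that("cross-validation separates a separable table and conserves fold-averaged counts", {
  tab <- simulate_feature_table(n_rows = 600, n_features = 10,
                                n_informative = 4, effect = 6, seed = 5)
  plan <- make_split(tab, test_frac = 0, n_folds = 5, seed = 2)
  cv <- cross_validate(quick_gbdt(), tab, plan, seed = 1)
  expect_gte(cv$mean_metrics$metrics[["accuracy"]], 0.99)
  # fold-averaged counts total the average fold size
  cc <- cv$mean_counts
  expect_equal(cc$TP + cc$TN + cc$FP + cc$FN, nrow(tab) / 5)
})

test_that("label-permuted data gives chance-level cross-validated MCC", {
  tab <- simulate_feature_table(n_rows = 800, n_features = 10,
                                n_informative = 4, effect = 0,
                                pathogenic_fraction = 0.5, seed = 6)
  plan <- make_split(tab, test_frac = 0, n_folds = 5, seed = 2)
  cv <- cross_validate(quick_gbdt(), tab, plan, seed = 1)
  expect_lt(abs(cv$mean_metrics$metrics[["MCC"]]), 0.12)
  expect_lt(abs(cv$mean_auc - 0.5), 0.06)
})

test_that("recursive elimination recovers planted informative features", {
  tab <- simulate_feature_table(n_rows = 700, n_features = 30,
                                n_informative = 5, effect = 1.5, seed = 8)
  plan <- make_split(tab, test_frac = 0, n_folds = 5, seed = 4)
  rfe <- rfe_select(quick_gbdt(), tab, plan, sizes = seq(5, 25, 5), seed = 9)
  inf <- attr(tab, "informative")
  expect_gte(mean(inf %in% rfe$features), 0.8)
  expect_lte(rfe$size, 20)
  # deterministic given the seed
  rfe2 <- rfe_select(quick_gbdt(), tab, plan, sizes = seq(5, 25, 5), seed = 9)
  expect_identical(rfe$ranking, rfe2$ranking)
  expect_identical(rfe$cv_auc, rfe2$cv_auc)
  # zero tolerance picks the argmax size
  rfe0 <- rfe_select(quick_gbdt(), tab, plan, sizes = seq(5, 25, 5), tol = 0,
                     seed = 9)
  expect_equal(rfe0$size, rfe0$sizes[which.max(rfe0$cv_auc)])
  # sizes beyond the feature count are truncated with a warning
  expect_warning(rfe_select(quick_gbdt(), tab, plan, sizes = c(10, 100), seed = 9),
                 "truncated")
})

test_that("hyperparameter search logs a non-decreasing incumbent and is seeded", {
  tab <- simulate_feature_table(n_rows = 400, n_features = 8,
                                n_informative = 3, effect = 2, seed = 10)
  plan <- make_split(tab, test_frac = 0, n_folds = 3, seed = 4)
  tune1 <- tune_hyperparams(tab, plan, n_trials = 1, seed = 12, nrounds = 30)
  expect_equal(tune1$best_params, tune1$params[[1]])
  tune <- tune_hyperparams(tab, plan, n_trials = 5, seed = 12, nrounds = 30)
  expect_true(all(diff(tune$trials$best_so_far) >= 0))
  expect_equal(tune$best_auc, max(tune$trials$auc))
  tune_b <- tune_hyperparams(tab, plan, n_trials = 5, seed = 12, nrounds = 30)
  expect_equal(tune$trials$auc, tune_b$trials$auc)
})

test_that("tuning is marginal on easy synthetic data", {
  tab <- simulate_feature_table(n_rows = 500, n_features = 8,
                                n_informative = 4, effect = 2.5, seed = 13)
  plan <- make_split(tab, test_frac = 0, n_folds = 3, seed = 4)
  default_auc <- cross_validate(learner_gbdt(), tab, plan, seed = 1)$mean_auc
  tune <- tune_hyperparams(tab, plan, n_trials = 8, seed = 14, nrounds = 80)
  expect_lt(abs(tune$best_auc - default_auc), 0.01)
})

test_that("the ensemble has 25 models sharing one feature list and is reproducible", {
  tab <- simulate_feature_table(n_rows = 500, n_features = 8,
                                n_informative = 3, effect = 2, seed = 15)
  fit <- del_train(tab, learner = quick_gbdt(), seed = 7)
  expect_s3_class(fit, "del_ensemble")
  expect_length(fit$models, 25)
  expect_equal(sort(unique(vapply(fit$models, `[[`, 1, "split"))), 1:5)
  expect_equal(sort(unique(vapply(fit$models, `[[`, 1, "fold"))), 1:5)
  probe <- simulate_feature_table(n_rows = 40, n_features = 8,
                                  n_informative = 3, effect = 2, seed = 16)
  p1 <- predict(fit, probe, type = "prob")
  fit2 <- del_train(tab, learner = quick_gbdt(), seed = 7)
  expect_identical(p1, predict(fit2, probe, type = "prob"))
  # missing feature errors by name
  expect_error(predict(fit, probe[, -4]), "missing feature.*f001")
})

test_that("an ensemble survives a round trip through its persisted directory", {
  tab <- simulate_feature_table(n_rows = 300, n_features = 6,
                                n_informative = 2, effect = 2, seed = 18)
  fit <- del_train(tab, learner = quick_gbdt(), n_splits = 2, n_folds = 3,
                   seed = 2)
  dir <- withr::local_tempdir()
  write_del_ensemble(fit, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- read_del_ensemble(dir)
  probe <- tab[1:20, ]
  expect_equal(predict(back, probe, type = "prob"),
               predict(fit, probe, type = "prob"))
  expect_identical(back$features, fit$features)
})

test_that("baseline learners fit and rank features through the same interface", {
  skip_if_not_installed("ranger")
  skip_if_not_installed("e1071")
  tab <- simulate_feature_table(n_rows = 300, n_features = 6,
                                n_informative = 3, effect = 2, seed = 20)
  plan <- make_split(tab, test_frac = 0, n_folds = 3, seed = 4)
  for (lrn in list(learner_logistic(), learner_rf(), learner_svm())) {
    cv <- cross_validate(lrn, tab, plan, seed = 1)
    expect_gt(cv$mean_auc, 0.8, label = lrn$name)
  }
})
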