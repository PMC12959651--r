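test_that("the proteome generator is deterministic and scales to empty", {
  cf <- sim_config(n_proteins = 12, length_range = c(60, 150),
                   n_variants = 40, seed = 5)
  p1 <- simulate_proteome(cf)
  p2 <- simulate_proteome(cf)
  expect_identical(p1$proteins, p2$proteins)
  expect_identical(p1$tracks, p2$tracks)
  expect_identical(p1$edges, p2$edges)
  empty <- simulate_proteome(sim_config(n_proteins = 0, n_variants = 0))
  expect_length(empty$proteins, 0)
})

test_that("domain coverage tracks the configured fraction", {
  cf <- sim_config(n_proteins = 150, length_range = c(150, 400),
                   domain_coverage = 0.4, n_variants = 10, seed = 8)
  pr <- simulate_proteome(cf)
  tr <- as.data.frame(pr$tracks)
  dom <- tr[tr$category == "domain", ]
  cov <- vapply(names(pr$proteins), function(p) {
    L <- nchar(pr$proteins[[p]])
    m <- logical(L)
    d <- dom[dom$protein_id == p, ]
    for (r in seq_len(nrow(d))) m[d$start[r]:d$end[r]] <- TRUE
    mean(m)
  }, numeric(1))
  expect_lt(abs(mean(cov) - 0.4), 0.05)
})

test_that("simulated variants respect coordinate constraints and length targets", {
  cf <- sim_config(n_proteins = 250, length_range = c(120, 400),
                   n_variants = 3000, seed = 9)
  pr <- simulate_proteome(cf)
  v <- simulate_variants(pr, cf)
  expect_gt(nrow(v), 2900)
  expect_true(all(v$start >= 2))                       # never the first residue
  len <- v$end - v$start + 1
  expect_true(all(len >= 1 & len <= 10))
  expect_true(all(v$end <= nchar(pr$proteins[v$protein_id])))
  expect_false(any(duplicated(v[c("protein_id", "start", "end")])))
  # class-conditional means near their targets; both classes mode at one
  mp <- mean(len[v$label == "pathogenic"])
  mb <- mean(len[v$label == "benign"])
  expect_lt(abs(mp - 2.71), 0.2)
  expect_lt(abs(mb - 4.11), 0.2)
  expect_equal(as.integer(names(which.max(table(len[v$label == "pathogenic"])))), 1L)
  expect_equal(as.integer(names(which.max(table(len[v$label == "benign"])))), 1L)
  expect_lt(abs(mean(v$label == "pathogenic") - 0.577), 0.03)
})

test_that("zero effect removes the class-placement signal", {
  cf <- sim_config(n_proteins = 150, length_range = c(120, 300),
                   n_variants = 1500, effect = 0, seed = 10)
  pr <- simulate_proteome(cf)
  v <- simulate_variants(pr, cf)
  ov <- overlap_flags(v, pr$tracks, categories = "domain")[, 1]
  d <- abs(mean(ov[v$label == "pathogenic"]) - mean(ov[v$label == "benign"]))
  expect_lt(d, 0.06)
})

test_that("positive effect places pathogenic deletions in domains preferentially", {
  cf <- sim_config(n_proteins = 150, length_range = c(120, 300),
                   n_variants = 1500, effect = 2, seed = 10)
  pr <- simulate_proteome(cf)
  v <- simulate_variants(pr, cf)
  ov <- overlap_flags(v, pr$tracks, categories = "domain")[, 1]
  expect_gt(mean(ov[v$label == "pathogenic"]) - mean(ov[v$label == "benign"]), 0.15)
})

test_that("written simulation artifacts round-trip through the package readers", {
  cf <- sim_config(n_proteins = 10, length_range = c(60, 120), n_variants = 30,
                   seed = 12)
  pr <- simulate_proteome(cf)
  v <- simulate_variants(pr, cf)
  dir <- withr::local_tempdir()
  write_proteome(pr, dir)
  write_variants(v, file.path(dir, "variants.csv"))
  prot_back <- read_fasta(file.path(dir, "proteins.fasta"))
  expect_identical(prot_back, pr$proteins)
  tracks_back <- read_annotation_tracks(file.path(dir, "tracks.tsv"), prot_back)
  expect_equal(nrow(tracks_back), nrow(pr$tracks))
  v_back <- read_variants(file.path(dir, "variants.csv"), proteins = prot_back)
  expect_equal(as.data.frame(v_back), as.data.frame(v))
  ann_back <- read_numeric_annotations(file.path(dir, "numeric.tsv"))
  expect_equal(nrow(ann_back), nrow(pr$numeric_annotations))
  edges_back <- read_edges(file.path(dir, "edges.tsv"))
  expect_equal(nrow(edges_back), nrow(pr$edges))
})

test_that("direct feature tables separate classes exactly as configured", {
  null_tab <- simulate_feature_table(n_rows = 600, n_features = 10,
                                     n_informative = 3, effect = 0,
                                     pathogenic_fraction = 0.5, seed = 14)
  plan <- make_split(null_tab, test_frac = 0.3, seed = 1)
  tr <- null_tab$protein_id %in% plan$train_proteins
  x <- as.matrix(null_tab[tr, delpath:::model_feature_names(null_tab)])
  fit <- delpath:::fit_learner(learner_gbdt(nrounds = 40), x,
                               as.integer(null_tab$label[tr] == "pathogenic"))
  p <- delpath:::predict_learner(learner_gbdt(nrounds = 40), fit,
                                 as.matrix(null_tab[!tr, colnames(x)]))
  expect_lt(abs(auc_rank(null_tab$label[!tr], p) - 0.5), 0.08)

  sep_tab <- simulate_feature_table(n_rows = 600, n_features = 10,
                                    n_informative = 5, effect = 2, seed = 15)
  plan2 <- make_split(sep_tab, test_frac = 0.3, seed = 1)
  tr2 <- sep_tab$protein_id %in% plan2$train_proteins
  x2 <- as.matrix(sep_tab[tr2, delpath:::model_feature_names(sep_tab)])
  fit2 <- delpath:::fit_learner(learner_gbdt(nrounds = 40), x2,
                                as.integer(sep_tab$label[tr2] == "pathogenic"))
  p2 <- delpath:::predict_learner(learner_gbdt(nrounds = 40), fit2,
                                  as.matrix(sep_tab[!tr2, colnames(x2)]))
  expect_gte(auc_rank(sep_tab$label[!tr2], p2), 0.9)

  # planted duplicate columns are caught by the correlation stage
  dup_tab <- simulate_feature_table(n_rows = 200, n_features = 6,
                                    n_informative = 2, effect = 1,
                                    n_redundant = 3, seed = 16)
  out <- drop_correlated(dup_tab)
  expect_true(all(sprintf("dup%03d", 1:3) %in% out$dropped$dropped))
})

test_that("the full sequence-level path runs end to end", {
  cf <- sim_config(n_proteins = 60, length_range = c(100, 250),
                   n_variants = 400, effect = 2, seed = 20)
  pr <- simulate_proteome(cf)
  v <- simulate_variants(pr, cf)
  plan0 <- make_split(v, test_frac = 0.25, seed = 3)
  train_v <- v[v$protein_id %in% plan0$train_proteins, ]
  test_v <- v[v$protein_id %in% plan0$test_proteins, ]
  logos <- list(benign = build_position_logo(train_v, pr$proteins, "benign"),
                pathogenic = build_position_logo(train_v, pr$proteins, "pathogenic"))
  scales <- list(hyd = setNames(rnorm(20), delpath:::AA_STANDARD))
  ft <- function(vv) featurize(vv, pr$proteins, logos = logos, scales = scales,
                               tracks = pr$tracks,
                               numeric_annotations = pr$numeric_annotations,
                               edges = pr$edges)
  tab_train <- ft(train_v)
  tab_test <- ft(test_v)
  flt <- filter_features(tab_train)
  fit <- del_train(flt$table, learner = learner_gbdt(nrounds = 40),
                   n_splits = 3, n_folds = 3, seed = 4)
  pred <- predict(fit, apply_filter(tab_test, flt$report), type = "tristate",
                  B = 300, seed = 5)
  rep <- evaluate_tristate(tab_test$label, pred$call)
  # planted placement signal is learnable well above chance
  expect_gt(rep$metrics[["MCC"]], 0.25)
  expect_gt(auc_rank(tab_test$label, pred$mean_prob), 0.7)
})
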