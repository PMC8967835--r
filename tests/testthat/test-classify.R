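# synthetic feature table: two Gaussian classes over the named columns
toy_table <- function(n_per_class = 40, n_patients = 10, sep = 3,
                      feature_set = "base8+extended", seed = 1) {
  cols <- feature_columns(feature_set)
  withr_seed(seed, {
    n <- 2 * n_per_class
    lab <- rep(c("AF", "SR"), each = n_per_class)
    X <- matrix(rnorm(n * length(cols)), n)
    X[lab == "AF", 1:3] <- X[lab == "AF", 1:3] + sep
    df <- as.data.frame(X)
    names(df) <- cols
    df$label <- lab
    df$patient_id <- sample(sprintf("P%02d", seq_len(n_patients)), n,
                            replace = TRUE)
    df$start_time <- seq_len(n) * 20
    df
  })
}

test_that("separable features are fit perfectly and deterministically", {
  tab <- toy_table(sep = 6)
  for (m in c("LINEAR_SVM", "RBF_SVM", "RANDOM_FOREST")) {
    cfg <- model_config(m, feature_set = "base8+extended", seed = 5)
    fit <- fit_af_model(cfg, tab)
    sc <- predict_scores(fit, tab)
    expect_equal(roc_auc(sc, tab$label == "AF")$auc, 1)
    fit2 <- fit_af_model(cfg, tab)
    expect_identical(predict_scores(fit2, tab), sc)
    expect_length(sc, nrow(tab))
  }
})

test_that("label-free features score at chance out of fold", {
  tab <- toy_table(n_per_class = 250, n_patients = 20, sep = 0, seed = 3)
  cv <- crossvalidate(tab, split_plan(k = 5, seed = 3),
                      model_config("LINEAR_SVM",
                                   feature_set = "base8+extended"))
  auc <- roc_auc(cv$scores, cv$labels == "AF")$auc
  expect_gt(auc, 0.4)
  expect_lt(auc, 0.6)
})

test_that("training rejects degenerate inputs and schema mismatches", {
  tab <- toy_table()
  one_class <- tab[tab$label == "AF", ]
  cfg <- model_config("LINEAR_SVM", feature_set = "base8+extended")
  expect_error(fit_af_model(cfg, one_class), "single-class")
  fit <- fit_af_model(cfg, tab)
  expect_error(predict_scores(fit, tab[, 1:4]), "schema|missing")
  expect_error(model_config("LINEAR_SVM", cost = 5), "cost")
})

test_that("patient folds are disjoint and score every segment once", {
  tab <- toy_table(n_per_class = 60, n_patients = 10, seed = 7)
  plan <- split_plan(k = 5, seed = 7)
  cv <- crossvalidate(tab, plan, model_config("LINEAR_SVM",
                                              feature_set = "base8+extended"))
  expect_equal(as.integer(table(cv$fold_of)), rep(2L, 5))
  expect_length(cv$scores, nrow(tab))
  # each patient's segments all fall in that patient's fold
  for (p in names(cv$fold_of))
    expect_true(all(cv$fold[cv$patient_id == p] == cv$fold_of[[p]]))
})

test_that("chronological split never trains on the future", {
  tab <- toy_table(n_per_class = 60, n_patients = 6, seed = 9)
  plan <- split_plan("WITHIN_SUBJECT_CHRONO", train_fraction = 0.5)
  cv <- crossvalidate(tab, plan, model_config("LINEAR_SVM",
                                              feature_set = "base8+extended"))
  train_idx <- cv$unscored
  for (p in unique(tab$patient_id)) for (cl in c("AF", "SR")) {
    tr_t <- tab$start_time[intersect(train_idx,
                                     which(tab$patient_id == p &
                                             tab$label == cl))]
    te_t <- cv$patient_id == p & cv$labels == cl
    if (length(tr_t) > 0 && any(te_t))
      expect_lt(max(tr_t), min(tab$start_time[tab$patient_id == p &
                                                tab$label == cl &
                                                !(seq_len(nrow(tab)) %in%
                                                    train_idx)]) + 1e-9)
  }
})

test_that("standardization statistics come from the training fold only", {
  tab <- toy_table(seed = 11)
  cfg <- model_config("LINEAR_SVM", feature_set = "base8+extended")
  fit <- fit_af_model(cfg, tab)
  # scoring a permuted table permutes the scores and nothing else
  perm <- withr_seed(1, sample(nrow(tab)))
  expect_equal(predict_scores(fit, tab[perm, ]), predict_scores(fit, tab)[perm])
  # model statistics equal train-set statistics exactly
  expect_equal(unname(fit$mu),
               unname(colMeans(as.matrix(tab[, fit$cols]))))
})

test_that("the cost grid search evaluates candidates and picks by AUC", {
  tab <- toy_table(n_per_class = 40, n_patients = 10, sep = 2, seed = 17)
  tuned <- tune_cost(tab, split_plan(k = 5, seed = 17),
                     model_config("LINEAR_SVM",
                                  feature_set = "base8+extended"),
                     costs = c(0, 0.1, 0.5))
  expect_length(tuned$auc, 2)          # cost 0 is inadmissible and skipped
  expect_true(tuned$best_cost %in% c(0.1, 0.5))
  expect_equal(unname(tuned$auc[as.character(tuned$best_cost)]),
               max(tuned$auc))
})

test_that("the model ladder runs four comparable configurations", {
  tab <- toy_table(n_per_class = 80, n_patients = 10, sep = 2, seed = 13)
  lad <- model_ladder(tab, split_plan(k = 5, seed = 13), seed = 13)
  expect_named(lad, c("A", "B", "C", "D"))
  cvs <- attr(lad, "cv")
  expect_identical(cvs$A$fold_of, cvs$D$fold_of)
  for (r in lad) expect_true(r$auc > 0.5 && r$auc <= 1)
  expect_error(model_ladder(tab[, c(feature_columns("base8"), "label",
                                    "patient_id", "start_time")]),
               "extended")
})
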