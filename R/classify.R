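#' Classifier configuration
#'
#' @param model \code{"LINEAR_SVM"}, \code{"RBF_SVM"} or
#'   \code{"RANDOM_FOREST"}.
#' @param cost SVM soft-margin penalty C (default 0.1, the value selected
#'   by a 0-1.5 grid search in the development data; see
#'   \code{\link{tune_cost}}).
#' @param cost_grid admissible range of \code{cost}.
#' @param rbf_gamma RBF kernel width, or NULL for the 1/(p * var)
#'   heuristic of the backend.
#' @param n_trees number of random-forest trees.
#' @param feature_set \code{"base8"} or \code{"base8+extended"}.
#' @param seed integer seed (random forest bootstrap).
#' @return An object of class \code{"model_config"}.
#' @export
model_config <- function(model = c("LINEAR_SVM", "RBF_SVM", "RANDOM_FOREST"),
                         cost = 0.1, cost_grid = c(0, 1.5),
                         rbf_gamma = NULL, n_trees = 500,
                         feature_set = c("base8", "base8+extended"),
                         seed = 1L) {
  model <- match.arg(model)
  feature_set <- match.arg(feature_set)
  if (cost < cost_grid[1] || cost > cost_grid[2])
    stop("cost outside cost_grid", call. = FALSE)
  stopifnot(n_trees >= 1)
  structure(list(model = model, cost = cost, cost_grid = cost_grid,
                 rbf_gamma = rbf_gamma, n_trees = as.integer(n_trees),
                 feature_set = feature_set, seed = as.integer(seed)),
            class = "model_config")
}

#' Cross-validation split plan
#'
#' \code{PATIENT_KFOLD} partitions patients (never segments) into k
#' disjoint folds, so no patient contributes to both training and test.
#' \code{WITHIN_SUBJECT_CHRONO} trains on each patient's earliest
#' \code{train_fraction} of segments per class and tests on the later
#' remainder (patient-specific models evaluated forward in time).
#'
#' @param scheme split scheme.
#' @param k number of folds (patient k-fold).
#' @param train_fraction fraction of earliest segments used for training
#'   (chronological split).
#' @param seed integer seed (fold assignment).
#' @return An object of class \code{"split_plan"}.
#' @export
split_plan <- function(scheme = c("PATIENT_KFOLD", "WITHIN_SUBJECT_CHRONO"),
                       k = 5, train_fraction = 0.5, seed = 1L) {
  scheme <- match.arg(scheme)
  stopifnot(k >= 2, train_fraction > 0, train_fraction < 1)
  structure(list(scheme = scheme, k = as.integer(k),
                 train_fraction = train_fraction, seed = as.integer(seed)),
            class = "split_plan")
}

# label vector -> 0/1 with AF = 1 (everything else is the non-AF class)
af_binary <- function(labels) as.integer(labels == "AF")

#' Fit an AF-vs-non-AF classifier
#'
#' Features are z-score standardized with training-set statistics (stored
#' in the model and reapplied at prediction time — test data never touch
#' the standardization). SVM decision scores are oriented so that higher
#' means more AF-like; the random forest scores with its AF class vote
#' fraction.
#'
#' @param config a \code{\link{model_config}}.
#' @param train feature table (rows = segments) with a \code{label}
#'   column; feature columns per \code{config$feature_set}.
#' @return An object of class \code{"af_model"}.
#' @export
fit_af_model <- function(config, train) {
  stopifnot(inherits(config, "model_config"))
  cols <- feature_columns(config$feature_set)
  miss <- setdiff(cols, names(train))
  if (length(miss) > 0)
    stop("missing feature columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  y <- af_binary(train$label)
  if (length(unique(y)) < 2) stop("single-class training set", call. = FALSE)
  X <- as.matrix(train[, cols, drop = FALSE])
  if (anyNA(X)) stop("missing feature values in training data", call. = FALSE)
  mu <- colMeans(X)
  sig <- apply(X, 2, sd)
  sig[sig == 0] <- 1
  Xs <- scale(X, center = mu, scale = sig)

  fit <- with_seed(config$seed, {
    if (config$model == "RANDOM_FOREST") {
      randomForest::randomForest(x = Xs, y = factor(y, levels = c(0, 1)),
                                 ntree = config$n_trees)
    } else {
      kern <- if (config$model == "LINEAR_SVM") "linear" else "radial"
      args <- list(x = Xs, y = factor(y, levels = c(0, 1)),
                   kernel = kern, cost = config$cost, scale = FALSE)
      if (!is.null(config$rbf_gamma)) args$gamma <- config$rbf_gamma
      do.call(e1071::svm, args)
    }
  })

  model <- structure(list(config = config, fit = fit, mu = mu, sig = sig,
                          cols = cols, flip = FALSE),
                     class = "af_model")
  # orient SVM decision values: higher = AF
  if (config$model != "RANDOM_FOREST") {
    sc <- raw_scores(model, Xs)
    if (mean(sc[y == 1]) < mean(sc[y == 0])) model$flip <- TRUE
  }
  model
}

raw_scores <- function(model, Xs) {
  if (model$config$model == "RANDOM_FOREST") {
    predict(model$fit, Xs, type = "prob")[, "1"]
  } else {
    as.numeric(attr(predict(model$fit, Xs, decision.values = TRUE),
                    "decision.values"))
  }
}

#' @export
print.af_model <- function(x, ...) {
  cat(sprintf("<af_model %s (%s, %d features)>\n", x$config$model,
              x$config$feature_set, length(x$cols)))
  invisible(x)
}

#' Continuous AF scores for a feature table
#'
#' @param model an \code{\link{fit_af_model}} result.
#' @param table feature table with the model's feature columns.
#' @return numeric vector, one score per row; higher = more AF-like.
#' @export
predict_scores <- function(model, table) {
  stopifnot(inherits(model, "af_model"))
  miss <- setdiff(model$cols, names(table))
  if (length(miss) > 0)
    stop("schema mismatch, missing: ", paste(miss, collapse = ", "),
         call. = FALSE)
  X <- as.matrix(table[, model$cols, drop = FALSE])
  Xs <- scale(X, center = model$mu, scale = model$sig)
  sc <- raw_scores(model, Xs)
  if (model$flip) sc <- -sc
  unname(sc)
}

#' Linear-SVM cost grid search
#'
#' Evaluates candidate soft-margin costs over a patient-wise
#' cross-validation and returns the cost with the best pooled AUC. The
#' production default (0.1) was selected this way; the search is
#' provided for recalibration on new data.
#'
#' @param table feature table.
#' @param plan a \code{\link{split_plan}}.
#' @param config template \code{\link{model_config}} (its cost is
#'   ignored).
#' @param costs candidate costs (default 0.1 to 1.5 in steps of 0.1; a
#'   cost of exactly 0 is not admissible for a soft-margin SVM and is
#'   skipped if supplied).
#' @return list with \code{best_cost} and \code{auc} per candidate.
#' @export
tune_cost <- function(table, plan = split_plan(),
                      config = model_config("LINEAR_SVM"),
                      costs = seq(0.1, 1.5, by = 0.1)) {
  costs <- costs[costs > 0]
  aucs <- vapply(costs, function(co) {
    cfg <- config; cfg$cost <- co
    cv <- crossvalidate(table, plan, cfg)
    roc_auc(cv$scores, af_binary(cv$labels))$auc
  }, numeric(1))
  list(best_cost = costs[which.max(aucs)],
       auc = stats::setNames(aucs, costs))
}

#' Cross-validated out-of-fold scores
#'
#' PATIENT_KFOLD: patients are shuffled (seeded) and partitioned into k
#' disjoint folds; each fold's segments are scored by a model trained on
#' the other folds, so every segment is scored exactly once out-of-fold.
#' WITHIN_SUBJECT_CHRONO: per patient and class, the earliest
#' \code{train_fraction} of segments train a single pooled model and the
#' later remainder is scored.
#'
#' Folds whose training part contains a single class are skipped with a
#' warning and their segments are unscored (NA).
#'
#' @param table feature table with \code{patient_id}, \code{start_time},
#'   \code{label} and the feature columns.
#' @param plan a \code{\link{split_plan}}.
#' @param config a \code{\link{model_config}}.
#' @return list with \code{scores}, \code{labels}, \code{patient_id},
#'   \code{fold} (vectors aligned to the scored rows of \code{table}),
#'   \code{models} (per-fold), and \code{fold_of} (patient -> fold map,
#'   patient k-fold only).
#' @export
crossvalidate <- function(table, plan = split_plan(),
                          config = model_config()) {
  stopifnot(inherits(plan, "split_plan"), inherits(config, "model_config"))
  n <- nrow(table)
  scores <- rep(NA_real_, n)
  fold_id <- rep(NA_integer_, n)
  models <- list()

  if (plan$scheme == "PATIENT_KFOLD") {
    patients <- unique(table$patient_id)
    if (length(patients) < plan$k)
      stop("fewer patients than folds", call. = FALSE)
    shuffled <- with_seed(plan$seed, sample(patients))
    fold_of <- stats::setNames(rep(seq_len(plan$k),
                                   length.out = length(shuffled)),
                               shuffled)
    for (f in seq_len(plan$k)) {
      test_p <- names(fold_of)[fold_of == f]
      tr <- table[!(table$patient_id %in% test_p), , drop = FALSE]
      te_idx <- which(table$patient_id %in% test_p)
      if (length(te_idx) == 0) next
      if (length(unique(af_binary(tr$label))) < 2) {
        warning(sprintf("fold %d skipped: single-class training set", f))
        next
      }
      m <- fit_af_model(config, tr)
      models[[length(models) + 1L]] <- m
      scores[te_idx] <- predict_scores(m, table[te_idx, , drop = FALSE])
      fold_id[te_idx] <- f
    }
    scored <- which(!is.na(scores))
    return(list(scores = scores[scored], labels = table$label[scored],
                patient_id = table$patient_id[scored],
                fold = fold_id[scored], models = models,
                fold_of = fold_of, unscored = setdiff(seq_len(n), scored)))
  }

  # WITHIN_SUBJECT_CHRONO: pooled model on each patient-class's earliest
  # fraction; later segments are the test set.
  in_train <- rep(FALSE, n)
  for (pid in unique(table$patient_id)) {
    for (cl in unique(table$label[table$patient_id == pid])) {
      idx <- which(table$patient_id == pid & table$label == cl)
      idx <- idx[order(table$start_time[idx])]
      n_tr <- floor(length(idx) * plan$train_fraction)
      if (n_tr >= 1) in_train[idx[seq_len(n_tr)]] <- TRUE
    }
  }
  tr <- table[in_train, , drop = FALSE]
  if (length(unique(af_binary(tr$label))) < 2)
    stop("chronological training set has a single class", call. = FALSE)
  m <- fit_af_model(config, tr)
  te_idx <- which(!in_train)
  scores[te_idx] <- predict_scores(m, table[te_idx, , drop = FALSE])
  fold_id[te_idx] <- 1L
  list(scores = scores[te_idx], labels = table$label[te_idx],
       patient_id = table$patient_id[te_idx], fold = fold_id[te_idx],
       models = list(m), fold_of = NULL, unscored = which(in_train))
}

#' Evaluate the four-model ectopy ladder
#'
#' Runs the four classifier configurations — A: linear SVM on the 8 base
#' features; B: RBF SVM on the base features; C: RBF SVM with the 5
#' ectopy features added; D: random forest on the same columns as C —
#' under one shared split plan on a table whose non-AF class may contain
#' premature-complex segments. Reported AUCs are comparable because the
#' fold assignments are identical.
#'
#' @param table feature table containing AF and non-AF rows (non-AF =
#'   SR, PVC and PAC relabeled), with the extended feature columns
#'   present for models C and D.
#' @param plan a \code{\link{split_plan}} shared by the four runs.
#' @param seed integer seed forwarded to the model configs.
#' @return named list of four \code{\link{roc_auc}} results (A-D), with
#'   per-model cross-validation outputs in attribute \code{"cv"}.
#' @export
model_ladder <- function(table, plan = split_plan(), seed = 1L) {
  miss <- setdiff(ext_features(), names(table))
  if (length(miss) > 0)
    stop("extended feature columns required for models C/D: ",
         paste(miss, collapse = ", "), call. = FALSE)
  configs <- list(
    A = model_config("LINEAR_SVM", feature_set = "base8", seed = seed),
    B = model_config("RBF_SVM", feature_set = "base8", seed = seed),
    C = model_config("RBF_SVM", feature_set = "base8+extended", seed = seed),
    D = model_config("RANDOM_FOREST", feature_set = "base8+extended",
                     seed = seed))
  cvs <- lapply(configs, function(cfg) crossvalidate(table, plan, cfg))
  out <- lapply(cvs, function(cv) roc_auc(cv$scores, af_binary(cv$labels)))
  attr(out, "cv") <- cvs
  out
}
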