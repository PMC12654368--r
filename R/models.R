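# Model harness: hyperparameter search spaces, seeded randomized search with
# 5-fold cross-validation, class-imbalance handling (majority downsampling +
# inverse-frequency sample weights), final refit, ranked model selection, and
# artifact persistence. Random forests are fitted with ranger, gradient
# boosted trees with xgboost; the MLP and GCN families are the package's own
# implementations (see nn.R, gcn.R).

#' Hyperparameter search space for a model family
#'
#' Returns the named hyperparameter domains searched for each family:
#' \describe{
#'   \item{rf}{`n_estimators` \{200,300,400,600\}, `max_depth` \{10,20,30\},
#'     `min_samples_split` \{2,5,10\}, `min_samples_leaf` \{1,2,4\},
#'     `max_features` \{"sqrt","log2"\}}
#'   \item{gbdt}{`n_estimators` \{300,600,900\}, `max_depth` \{4,6,8\},
#'     `learning_rate` \{0.03,0.05,0.1\}, `subsample` \{0.7,0.9,1.0\},
#'     `colsample_bytree` \{0.6,0.8,1.0\}, `reg_lambda` \{0.0,1.0,3.0\}}
#'   \item{mlp}{`hidden_layer_sizes` \{(512,128),(256,128),(256,64)\},
#'     `alpha` 5 log-spaced values in \[1e-5, 1e-3\], `learning_rate_init`
#'     5 log-spaced values in \[1e-4, 1e-3\], `batch_size` \{128,256,512\}}
#'   \item{gcn}{`hidden` \{64,128,256\}, `dropout` \{0.1,0.3,0.5\},
#'     `learning_rate` \{1e-3,3e-3,5e-4\}, `weight_decay` \{0,1e-4,5e-4\},
#'     `batch_size` \{64,128,256\}}
#' }
#'
#' @param family `"rf"`, `"gbdt"`, `"mlp"` or `"gcn"`.
#' @return Named list of domains (each a vector or list of candidate values).
#' @export
search_space <- function(family = c("rf", "gbdt", "mlp", "gcn")) {
  family <- match.arg(family)
  switch(family,
    rf = list(
      n_estimators = c(200L, 300L, 400L, 600L),
      max_depth = c(10L, 20L, 30L),
      min_samples_split = c(2L, 5L, 10L),
      min_samples_leaf = c(1L, 2L, 4L),
      max_features = c("sqrt", "log2")),
    gbdt = list(
      n_estimators = c(300L, 600L, 900L),
      max_depth = c(4L, 6L, 8L),
      learning_rate = c(0.03, 0.05, 0.1),
      subsample = c(0.7, 0.9, 1.0),
      colsample_bytree = c(0.6, 0.8, 1.0),
      reg_lambda = c(0.0, 1.0, 3.0)),
    mlp = list(
      hidden_layer_sizes = list(c(512L, 128L), c(256L, 128L), c(256L, 64L)),
      alpha = 10^seq(log10(1e-5), log10(1e-3), length.out = 5),
      learning_rate_init = 10^seq(log10(1e-4), log10(1e-3), length.out = 5),
      batch_size = c(128L, 256L, 512L)),
    gcn = list(
      hidden = c(64L, 128L, 256L),
      dropout = c(0.1, 0.3, 0.5),
      learning_rate = c(1e-3, 3e-3, 5e-4),
      weight_decay = c(0, 1e-4, 5e-4),
      batch_size = c(64L, 128L, 256L)))
}

#' Draw seeded configurations from a search space
#'
#' Uniform independent draws from each hyperparameter domain.
#'
#' @param space A [search_space()] list.
#' @param n_draws Number of configurations.
#' @param seed RNG seed.
#' @return List of named configuration lists.
#' @export
draw_configs <- function(space, n_draws = 30, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n_draws), function(i)
    lapply(space, function(domain) {
      k <- sample.int(length(domain), 1L)
      if (is.list(domain)) domain[[k]] else domain[k]
    }))
}

#' Downsample the majority class
#'
#' Caps the most frequent class at `cap` instances, sampled without
#' replacement with a seeded RNG; all other classes are untouched. Applied to
#' the training set only, never to validation data.
#'
#' @param labels Vector of class labels.
#' @param cap Maximum size of the majority class (default 5000).
#' @param seed RNG seed.
#' @return Integer vector of retained row indices (ascending).
#' @export
downsample_majority <- function(labels, cap = 5000L, seed = 1) {
  tab <- table(labels)
  major <- names(tab)[which.max(tab)]
  idx_major <- which(labels == major)
  if (length(idx_major) <= cap) return(seq_along(labels))
  set.seed(seed)
  keep_major <- sample(idx_major, cap)
  sort(c(which(labels != major), keep_major))
}

#' Inverse-frequency class weights
#'
#' `w_c = N / (K * N_c)`: the mean weight over samples is 1 and
#' `sum_c w_c * N_c = N`.
#'
#' @param labels Vector of class labels with at least two classes present.
#' @return Named numeric vector of per-class weights.
#' @export
class_weights <- function(labels) {
  tab <- table(labels)
  if (length(tab) < 2L) stop("class_weights: need at least 2 classes")
  n <- length(labels); k <- length(tab)
  w <- n / (k * as.numeric(tab))
  stats::setNames(w, names(tab))
}

# -- family dispatch ----------------------------------------------------------

fit_family <- function(family, task, X, y, config, weights = NULL, seed = 1) {
  cls <- task == "classification"
  if (family == "rf") {
    mtry_p <- if (is.matrix(X)) ncol(X) else stop("rf needs a feature matrix")
    mtry <- if (config$max_features == "sqrt") max(1L, floor(sqrt(mtry_p)))
            else max(1L, floor(log2(mtry_p)))
    fit <- ranger::ranger(
      x = X, y = if (cls) factor(y) else as.numeric(y),
      num.trees = config$n_estimators, mtry = mtry,
      max.depth = config$max_depth,
      min.node.size = config$min_samples_split,
      min.bucket = config$min_samples_leaf,
      probability = cls, case.weights = weights,
      seed = seed, num.threads = 1)
    list(kind = "rf", fit = fit, classes = if (cls) levels(factor(y)))
  } else if (family == "gbdt") {
    classes <- if (cls) levels(factor(y))
    ylab <- if (cls) as.integer(factor(y)) - 1L else as.numeric(y)
    nclass <- length(classes)
    params <- list(
      max_depth = config$max_depth, eta = config$learning_rate,
      subsample = config$subsample, colsample_bytree = config$colsample_bytree,
      lambda = config$reg_lambda, nthread = 1, seed = seed,
      objective = if (!cls) "reg:squarederror"
                  else if (nclass == 2L) "binary:logistic" else "multi:softprob")
    if (cls && nclass > 2L) params$num_class <- nclass
    dtrain <- xgboost::xgb.DMatrix(X, label = ylab,
                                   weight = if (is.null(weights)) rep(1, length(ylab)) else weights)
    fit <- xgboost::xgb.train(params, dtrain, nrounds = config$n_estimators,
                              verbose = 0)
    list(kind = "gbdt", fit = fit, classes = classes)
  } else if (family == "mlp") {
    fit <- mlp_fit(X, y, task,
                   hidden = config$hidden_layer_sizes, alpha = config$alpha,
                   lr = config$learning_rate_init,
                   batch_size = config$batch_size, weights = weights,
                   seed = seed)
    list(kind = "mlp", fit = fit, classes = fit$classes)
  } else if (family == "gcn") {
    fit <- gcn_fit(X, y, task, hidden = config$hidden,
                   dropout = config$dropout, lr = config$learning_rate,
                   weight_decay = config$weight_decay,
                   batch_size = config$batch_size, weights = weights,
                   seed = seed)
    list(kind = "gcn", fit = fit, classes = fit$classes)
  } else stop("unknown family: ", family)
}

predict_family <- function(obj, X) {
  if (obj$kind == "rf") {
    pr <- stats::predict(obj$fit, data = X, num.threads = 1)$predictions
    if (!is.null(obj$classes)) pr[, obj$classes, drop = FALSE] else pr
  } else if (obj$kind == "gbdt") {
    pr <- stats::predict(obj$fit, xgboost::xgb.DMatrix(X))
    if (is.null(obj$classes)) return(pr)
    if (length(obj$classes) == 2L) {
      cbind(1 - pr, pr, deparse.level = 0) -> m
      colnames(m) <- obj$classes
      m
    } else {
      m <- matrix(pr, ncol = length(obj$classes), byrow = TRUE)
      colnames(m) <- obj$classes
      m
    }
  } else if (obj$kind == "mlp") {
    mlp_predict(obj$fit, X)
  } else if (obj$kind == "gcn") {
    gcn_predict(obj$fit, X)
  } else stop("unknown fit kind")
}

# stratified (classification) or plain (regression) k-fold assignment
make_folds <- function(y, k, stratify, seed) {
  set.seed(seed)
  n <- length(y)
  fold <- integer(n)
  if (stratify) {
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    if (any(vapply(seq_len(k), function(f)
      length(unique(y[fold != f])) < 2L, TRUE)))
      stop("stratified folds impossible: a class has fewer members than folds")
  } else {
    fold[sample(n)] <- rep_len(seq_len(k), n)
  }
  fold
}

#' Randomized hyperparameter search with k-fold cross-validation
#'
#' Draws `n_draws` seeded configurations and scores each by k-fold CV on the
#' training data only. Classification folds are stratified by label and
#' scored by fold-mean macro-F1 (inverse-frequency sample weights are
#' computed on each fold's training labels); regression folds are plain
#' k-fold, scored by fold-mean R-squared with RMSE as tie-breaker. Ties after
#' both criteria fall back to draw order.
#'
#' @param task `"classification"` or `"regression"`.
#' @param X Feature matrix, or list of graphs for `family = "gcn"`.
#' @param y Labels or numeric targets.
#' @param family Model family, see [search_space()].
#' @param n_draws Number of random configurations (default 30).
#' @param folds Number of CV folds (default 5).
#' @param seed RNG seed for draws and fold assignment.
#' @return A list of class `cv_result`: `best_config`, `best_mean`,
#'   `best_sd`, `fold_metrics`, and `table` (per-draw summary).
#' @export
random_search <- function(task, X, y, family, n_draws = 30, folds = 5,
                          seed = 1) {
  cls <- task == "classification"
  configs <- draw_configs(search_space(family), n_draws, seed)
  fold <- make_folds(if (cls) as.character(y) else as.numeric(y),
                     folds, stratify = cls, seed = seed + 1L)
  subset_X <- function(idx)
    if (is.list(X) && !is.data.frame(X)) X[idx] else X[idx, , drop = FALSE]
  score_config <- function(config) {
    prim <- numeric(folds); tie <- numeric(folds)
    for (f in seq_len(folds)) {
      tr <- which(fold != f); te <- which(fold == f)
      w <- NULL
      if (cls) {
        cw <- class_weights(y[tr])
        w <- unname(cw[as.character(y[tr])])
      }
      fitobj <- fit_family(family, task, subset_X(tr), y[tr], config,
                           weights = w, seed = seed)
      pred <- predict_family(fitobj, subset_X(te))
      if (cls) {
        rep_ <- classification_report(y[te], pred)
        prim[f] <- rep_$macro_f1; tie[f] <- rep_$accuracy
      } else {
        rep_ <- regression_report(y[te], pred)
        prim[f] <- rep_$r2; tie[f] <- -rep_$rmse
      }
    }
    list(prim = prim, tie = tie)
  }
  res <- lapply(configs, score_config)
  means <- vapply(res, function(r) mean(r$prim), 0)
  ties <- vapply(res, function(r) mean(r$tie), 0)
  best <- order(-means, -ties)[1]
  tab <- data.frame(
    draw = seq_len(n_draws),
    mean_primary = means,
    sd_primary = vapply(res, function(r) stats::sd(r$prim), 0),
    mean_tiebreak = ties)
  out <- list(task = task, family = family, metric = if (cls) "macro_f1" else "r2",
              best_config = configs[[best]], best_draw = best,
              best_mean = means[best],
              best_sd = stats::sd(res[[best]]$prim),
              fold_metrics = res[[best]]$prim, table = tab,
              configs = configs)
  class(out) <- "cv_result"
  out
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result [%s/%s]: best draw %d, %s = %.3f (sd %.3f)\n",
              x$family, x$task, x$best_draw, x$metric, x$best_mean, x$best_sd))
  invisible(x)
}

#' Rank fingerprint-model combinations
#'
#' Lexicographic descending sort on validation macro-F1, with ties broken by
#' accuracy, then macro-precision, then macro-recall; fully tied entries keep
#' their input order (stable).
#'
#' @param reports List of classification `eval_report`s (optionally named) or
#'   a data.frame carrying the four metric columns.
#' @return data.frame ordered best-first with the four metrics and the
#'   original position (`input_rank`).
#' @export
rank_combinations <- function(reports) {
  if (is.data.frame(reports)) {
    df <- reports
  } else {
    df <- do.call(rbind, lapply(seq_along(reports), function(i) {
      r <- reports[[i]]
      data.frame(combination = if (!is.null(names(reports))) names(reports)[i]
                               else paste0("model_", i),
                 macro_f1 = r$macro_f1, accuracy = r$accuracy,
                 macro_precision = r$macro_precision,
                 macro_recall = r$macro_recall, stringsAsFactors = FALSE)
    }))
  }
  df$input_rank <- seq_len(nrow(df))
  ord <- order(-df$macro_f1, -df$accuracy, -df$macro_precision,
               -df$macro_recall, df$input_rank)
  out <- df[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# -- final fit and prediction -------------------------------------------------

#' Fit the final model on the full training set
#'
#' Featurizes the training SMILES for the requested scheme, standardizes the
#' physicochemical block with training statistics only (fingerprint bits are
#' left unscaled), applies majority-class downsampling and inverse-frequency
#' sample weights for classification, fits the chosen family/configuration,
#' and returns a self-contained artifact that can be persisted and reloaded
#' to reproduce predictions exactly.
#'
#' @param task `"contribution"`, `"category"` or `"threshold"`.
#' @param scheme `"ecfp4"`, `"ecfp6"`, `"maccs"` or `"graph"`.
#' @param family Model family, see [search_space()].
#' @param config Hyperparameter configuration (e.g. from [random_search()]).
#' @param smiles Canonical training SMILES.
#' @param y Labels (contribution/category) or `-log10(mg/L)` targets.
#' @param downsample_cap Majority-class cap (classification only; default
#'   5000). `Inf` disables.
#' @param seed RNG seed.
#' @return An object of class `aroma_model`.
#' @export
fit_final <- function(task = c("contribution", "category", "threshold"),
                      scheme = c("ecfp4", "ecfp6", "maccs", "graph"),
                      family, config, smiles, y,
                      downsample_cap = 5000L, seed = 1) {
  task <- match.arg(task)
  scheme <- match.arg(scheme)
  mltask <- if (task == "threshold") "regression" else "classification"
  keep <- seq_along(smiles)
  if (mltask == "classification" && is.finite(downsample_cap))
    keep <- downsample_majority(y, downsample_cap, seed)
  smiles <- smiles[keep]; y <- y[keep]

  if (scheme == "graph") {
    X <- lapply(smiles, to_graph)
    pc_mean <- pc_sd <- NULL
  } else {
    X <- featurize(smiles, scheme)
    pc_cols <- c("MW", "logP", "TPSA", "MR")
    pc_mean <- colMeans(X[, pc_cols, drop = FALSE])
    pc_sd <- pmax(apply(X[, pc_cols, drop = FALSE], 2, stats::sd), 1e-8)
    X[, pc_cols] <- sweep(sweep(X[, pc_cols, drop = FALSE], 2, pc_mean),
                          2, pc_sd, "/")
  }
  w <- NULL
  if (mltask == "classification") {
    cw <- class_weights(y)
    w <- unname(cw[as.character(y)])
  }
  fitobj <- fit_family(family, mltask, X, y, config, weights = w, seed = seed)
  out <- list(task = task, scheme = scheme, family = family, config = config,
              fit = fitobj, pc_mean = pc_mean, pc_sd = pc_sd,
              classes = fitobj$classes, seed = seed,
              train_smiles = unique(smiles),
              version = as.character(utils::packageVersion("odortools")))
  class(out) <- "aroma_model"
  out
}

#' @export
print.aroma_model <- function(x, ...) {
  cat(sprintf("aroma_model: task=%s scheme=%s family=%s (trained on %d compounds)\n",
              x$task, x$scheme, x$family, length(x$train_smiles)))
  invisible(x)
}

#' Predict from a fitted aroma model
#'
#' For contribution models returns the probability of the positive class in
#' `[0, 1]`; for category models a probability matrix; for threshold models
#' the predicted `-log10(mg/L)`. Unparseable SMILES yield `NA` for that row
#' (with the failures listed in `attr(, "errors")`); the batch continues.
#'
#' @param object An `aroma_model`.
#' @param smiles Character vector of SMILES.
#' @param ... Unused.
#' @return Numeric vector (or matrix for category task) aligned with input.
#' @export
predict.aroma_model <- function(object, smiles, ...) {
  can <- canonicalize_smiles(smiles, strict = FALSE)
  ok <- which(!is.na(can))
  k_out <- if (object$task == "category") length(object$classes) else 1L
  out <- if (k_out > 1L)
    matrix(NA_real_, length(smiles), k_out,
           dimnames = list(NULL, object$classes))
  else rep(NA_real_, length(smiles))
  if (length(ok)) {
    if (object$scheme == "graph") {
      X <- lapply(can[ok], to_graph)
    } else {
      X <- featurize(can[ok], object$scheme)
      pc_cols <- c("MW", "logP", "TPSA", "MR")
      X[, pc_cols] <- sweep(sweep(X[, pc_cols, drop = FALSE], 2,
                                  object$pc_mean), 2, object$pc_sd, "/")
    }
    pred <- predict_family(object$fit, X)
    if (object$task == "category") {
      out[ok, ] <- pred
    } else if (object$task == "contribution") {
      out[ok] <- pred[, "positive"]
    } else {
      out[ok] <- pred
    }
  }
  if (length(ok) < length(smiles))
    attr(out, "errors") <- smiles[is.na(can)]
  out
}

#' Persist / reload a fitted model artifact
#'
#' The artifact directory holds the fitted parameters (`params.rds`; xgboost
#' boosters are stored as raw serialized bytes for version-stable reload) and
#' a JSON manifest recording task, scheme, family, configuration, seed and
#' package version. A reloaded artifact reproduces predictions exactly.
#'
#' @param model An `aroma_model`.
#' @param dir Artifact directory (created if needed).
#' @return `save_model`: invisibly, `dir`. `load_model`: the `aroma_model`.
#' @export
save_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ser <- model
  if (ser$fit$kind == "gbdt")
    ser$fit$fit <- xgboost::xgb.save.raw(ser$fit$fit)
  saveRDS(ser, file.path(dir, "params.rds"))
  jsonlite::write_json(
    list(task = model$task, scheme = model$scheme, family = model$family,
         config = model$config, seed = model$seed, version = model$version,
         n_train = length(model$train_smiles)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  model <- readRDS(file.path(dir, "params.rds"))
  if (model$fit$kind == "gbdt")
    model$fit$fit <- xgboost::xgb.load.raw(model$fit$fit)
  model
}
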