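# Classical ML backend over the aggregated features, evaluated with
# leave-one-out (LOO) cross-validation. Six model families are wrapped
# behind one fit/predict surface; regression families (SVR) are mapped back
# to ordinal grades by rounding.

ML_FAMILIES <- c("decision_tree", "random_forest", "adaboost",
                 "gradient_boosting", "knn", "svr")
ML_FEATURES <- c("spine_value", "head_min", "head_drop", "legs_value")

#' Specify an ML model
#'
#' @param family one of `"decision_tree"`, `"random_forest"`, `"adaboost"`,
#'   `"gradient_boosting"` (xgboost), `"knn"`, `"svr"`.
#' @param task `"grade7"` (ordinal 1..7) or `"binary"` (healthy/lame).
#' @param seed RNG seed fixed for the run.
#' @param hyperparameters named list of family-specific overrides
#'   (`k` for knn, `ntree` for random_forest, `nrounds` for boosting
#'   families, `maxdepth` for trees/adaboost, `cost`/`epsilon` for svr).
#' @return A list of class `ml_spec`.
#' @export
ml_spec <- function(family = "random_forest", task = c("grade7", "binary"),
                    seed = 42L, hyperparameters = list()) {
  task <- match.arg(task)
  if (!family %in% ML_FAMILIES)
    stop("family must be one of: ", paste(ML_FAMILIES, collapse = ", "))
  structure(list(family = family, task = task, seed = as.integer(seed),
                 hyperparameters = hyperparameters),
            class = "ml_spec")
}

hp <- function(spec, name, default) {
  v <- spec$hyperparameters[[name]]
  if (is.null(v)) default else v
}

# Feature matrix with sentinel-aware imputation: NA entries (zero-step
# passages) are replaced by the training-set column median.
feature_matrix <- function(features_table, medians = NULL) {
  X <- as.matrix(features_table[, ML_FEATURES, drop = FALSE])
  if (is.null(medians))
    medians <- apply(X, 2, stats::median, na.rm = TRUE)
  medians[is.na(medians)] <- 0
  for (j in seq_len(ncol(X))) X[is.na(X[, j]), j] <- medians[j]
  list(X = X, medians = medians)
}

round_grade <- function(v) pmin(7, pmax(1, floor(v + 0.5)))

# SAMME multi-class AdaBoost over shallow rpart trees. Implemented here
# because no boosting-for-classification package is available; the base
# learner and the reweighting follow the standard SAMME recipe.
fit_adaboost <- function(X, y, M = 30L, maxdepth = 2L) {
  y <- factor(y)
  K <- nlevels(y)
  n <- nrow(X)
  w <- rep(1 / n, n)
  stumps <- list(); alphas <- numeric()
  df <- data.frame(X, y = y)
  for (m in seq_len(M)) {
    fit <- rpart::rpart(y ~ ., data = df, weights = w,
                        control = rpart::rpart.control(
                          maxdepth = maxdepth, cp = 0, minsplit = 2,
                          xval = 0))
    pred <- stats::predict(fit, df, type = "class")
    err <- sum(w * (pred != y)) / sum(w)
    if (err >= 1 - 1 / K) break
    err <- max(err, 1e-10)
    alpha <- log((1 - err) / err) + log(K - 1)
    w <- w * exp(alpha * (pred != y))
    w <- w / sum(w)
    stumps[[m]] <- fit; alphas[m] <- alpha
    if (err < 1e-10) break
  }
  list(stumps = stumps, alphas = alphas, levels = levels(y))
}

predict_adaboost <- function(model, X) {
  df <- as.data.frame(X)
  votes <- matrix(0, nrow(df), length(model$levels),
                  dimnames = list(NULL, model$levels))
  for (m in seq_along(model$stumps)) {
    p <- as.character(stats::predict(model$stumps[[m]], df, type = "class"))
    votes[cbind(seq_len(nrow(df)), match(p, model$levels))] <-
      votes[cbind(seq_len(nrow(df)), match(p, model$levels))] + model$alphas[m]
  }
  model$levels[max.col(votes, ties.method = "first")]
}

#' Train a final model on a full feature table
#'
#' Deployment-mode counterpart of the LOO protocol: fits the specified
#' family on all rows. The returned artifact is self-contained (it carries
#' the imputation medians and the label encoding) and serializable with
#' `saveRDS()`; a reloaded model predicts identically.
#'
#' @param features_table data frame with the feature columns
#'   `spine_value`, `head_min`, `head_drop`, `legs_value`.
#' @param labels grade vector (1..7) for `task = "grade7"`, or
#'   healthy/lame labels (or grades, mapped per protocol) for binary.
#' @param spec an [ml_spec()].
#' @return An object of class `bovigait_ml_model`.
#' @export
train_final <- function(features_table, labels, spec) {
  stopifnot(inherits(spec, "ml_spec"))
  fm <- feature_matrix(features_table)
  X <- fm$X
  y <- if (spec$task == "grade7") as.numeric(labels) else as.character(labels)
  if (length(y) != nrow(X)) stop("labels length mismatch")
  set.seed(spec$seed)
  yf <- factor(y)
  single_class <- nlevels(yf) == 1L
  # a zero-variance feature table carries no signal for any family (and
  # stalls some library split searches); the only fit is the majority class
  if (!single_class && all(apply(X, 2L, function(c) max(c) == min(c)))) {
    tab <- table(yf)
    maj <- names(tab)[which.max(tab)]   # ties: first level
    return(structure(list(spec = spec, fit = NULL, medians = fm$medians,
                          levels = maj, single_class = TRUE),
                     class = "bovigait_ml_model"))
  }
  fit <- NULL
  if (!single_class) fit <- switch(
    spec$family,
    decision_tree = rpart::rpart(
      y ~ ., data = data.frame(X, y = yf), method = "class",
      control = rpart::rpart.control(maxdepth = hp(spec, "maxdepth", 8L),
                                     cp = 0, minsplit = 4, xval = 0)),
    random_forest = randomForest::randomForest(
      X, yf, ntree = hp(spec, "ntree", 300L)),
    adaboost = fit_adaboost(X, y, M = hp(spec, "nrounds", 30L),
                            maxdepth = hp(spec, "maxdepth", 2L)),
    gradient_boosting = {
      yi <- as.integer(yf) - 1L
      nc <- nlevels(yf)
      dm <- xgboost::xgb.DMatrix(X, label = yi, nthread = 1)
      prm <- list(
        objective = if (nc > 2) "multi:softmax" else "binary:logistic",
        max_depth = hp(spec, "maxdepth", 4L), eta = 0.3, nthread = 1,
        seed = spec$seed)
      if (nc > 2) prm$num_class <- nc
      xgboost::xgb.train(params = prm, data = dm,
                         nrounds = hp(spec, "nrounds", 50L), verbose = 0)
    },
    knn = list(X = X, y = yf, k = hp(spec, "k", 5L)),
    svr = {
      if (spec$task == "grade7")
        e1071::svm(X, as.numeric(y), type = "eps-regression",
                   cost = hp(spec, "cost", 1), epsilon = hp(spec, "epsilon", 0.1))
      else e1071::svm(X, yf, type = "C-classification",
                      cost = hp(spec, "cost", 1))
    }
  )
  structure(list(spec = spec, fit = fit, medians = fm$medians,
                 levels = levels(yf), single_class = single_class),
            class = "bovigait_ml_model")
}

#' Predict grades or binary labels from a trained ML model
#'
#' @param object a [train_final()] model.
#' @param newdata feature table (same columns as at training).
#' @param ... unused.
#' @return Numeric grades (grade7 task) or character healthy/lame labels.
#' @export
predict.bovigait_ml_model <- function(object, newdata, ...) {
  if (is.null(object$fit) && !object$single_class)
    stop("model has not been fitted")
  X <- feature_matrix(newdata, object$medians)$X
  spec <- object$spec
  lv <- object$levels
  if (object$single_class) {
    out <- rep(lv, nrow(X))
    return(if (spec$task == "grade7") as.numeric(out) else out)
  }
  raw <- switch(
    spec$family,
    decision_tree = as.character(stats::predict(object$fit,
                                                data.frame(X), type = "class")),
    random_forest = as.character(stats::predict(object$fit, X)),
    adaboost = predict_adaboost(object$fit, X),
    gradient_boosting = {
      p <- stats::predict(object$fit, X)
      if (length(lv) > 2) lv[p + 1L]
      else lv[as.integer(p > 0.5) + 1L]
    },
    knn = as.character(class::knn(object$fit$X, X, object$fit$y,
                                  k = min(object$fit$k, nrow(object$fit$X)))),
    svr = {
      p <- stats::predict(object$fit, X)
      if (spec$task == "grade7") return(round_grade(as.numeric(p)))
      as.character(p)
    }
  )
  if (spec$task == "grade7") as.numeric(raw) else raw
}

#' Leave-one-out predictions over a feature table
#'
#' For each row i, a model of the given family is trained on all other rows
#' and predicts row i; row i's own label is never seen by the model that
#' predicts it. Deterministic given the spec's seed. A class present in a
#' single row cannot be predicted for that row (it is absent from the
#' training fold); a warning is raised and predictions are still produced.
#'
#' @inheritParams train_final
#' @return Vector of per-row predictions (numeric grades or binary labels).
#' @export
fit_predict_loo <- function(features_table, labels, spec) {
  n <- nrow(features_table)
  if (n < 2L) stop("need at least 2 rows for LOO")
  tab <- table(labels)
  if (any(tab == 1L))
    warning("class(es) with a single row cannot be predicted under LOO: ",
            paste(names(tab)[tab == 1L], collapse = ", "))
  preds <- vector(if (spec$task == "grade7") "numeric" else "character", n)
  for (i in seq_len(n)) {
    m <- train_final(features_table[-i, , drop = FALSE], labels[-i], spec)
    preds[i] <- predict(m, features_table[i, , drop = FALSE])
  }
  preds
}
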