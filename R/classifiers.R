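# Classifier adapters. Each kind gets a uniform fit/predict surface so the
# grid harness can treat configurations interchangeably. Scale-sensitive kinds
# (logistic regression, knn, svm) receive standardized features from the
# harness; tree ensembles receive raw features.

scale_sensitive <- function(kind)
  kind %in% c("logistic_regression", "knn", "svm")

#' Fit one classifier
#'
#' Supported kinds and hyperparameters: `logistic_regression` (ridge-penalised,
#' inverse regularisation `C`), `knn` (`nn` neighbours), `random_forest`
#' (100 trees, `depth`: integer or `"none"` for unlimited), `svm` (RBF kernel,
#' cost `C`), `gradient_boosted_trees` (100 rounds, learning rate `lr`,
#' depth-3 trees).
#'
#' @param kind Classifier kind string.
#' @param params Named list of hyperparameters for the kind.
#' @param X Numeric training matrix.
#' @param y Binary training labels.
#' @param seed Integer seed for stochastic learners.
#' @return Opaque model object for [predict_classifier()].
#' @export
fit_classifier <- function(kind, params, X, y, seed = 1L) {
  X <- as.matrix(X)
  model <- switch(
    kind,
    logistic_regression = {
      Xg <- if (ncol(X) < 2L) cbind(X, `..pad` = 0) else X
      # glmnet warns on small class counts; expected in small CV folds
      suppressWarnings(
        glmnet::glmnet(Xg, factor(y, levels = c(0, 1)), family = "binomial",
                       alpha = 0, lambda = 1 / (params$C * nrow(Xg)),
                       standardize = FALSE))
    },
    knn = list(train = X, cl = y, nn = params$nn),
    random_forest = {
      depth <- if (identical(params$depth, "none")) 0L else as.integer(params$depth)
      ranger::ranger(x = as.data.frame(X), y = factor(y, levels = c(0, 1)),
                     num.trees = 100L, max.depth = depth, seed = seed,
                     num.threads = 1L)
    },
    svm = e1071::svm(X, factor(y, levels = c(0, 1)), kernel = "radial",
                     cost = params$C, scale = FALSE),
    gradient_boosted_trees = xgboost::xgb.train(
      params = list(objective = "binary:logistic", eta = params$lr,
                    max_depth = 3L, nthread = 1L, seed = seed),
      data = xgboost::xgb.DMatrix(X, label = as.numeric(y), nthread = 1L),
      nrounds = 100L, verbose = 0
    ),
    stop("unknown classifier kind: ", kind)
  )
  structure(list(kind = kind, fit = model, seed = seed,
                 cols = colnames(X)), class = "dyskrep_model")
}

#' Predict binary labels from a fitted classifier
#' @param model Object from [fit_classifier()].
#' @param X Feature matrix with the training columns.
#' @return Integer vector of 0/1 predictions.
#' @export
predict_classifier <- function(model, X) {
  X <- as.matrix(X)
  out <- switch(
    model$kind,
    logistic_regression = {
      Xg <- if (ncol(X) < 2L) cbind(X, `..pad` = 0) else X
      as.integer(as.character(
        stats::predict(model$fit, newx = Xg, type = "class")[, 1L]))
    },
    knn = {
      # class::knn breaks distance/vote ties randomly; pin the RNG state so
      # predictions are reproducible, then restore the caller's state
      old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
        get(".Random.seed", globalenv()) else NULL
      set.seed(model$seed)
      pred <- class::knn(model$fit$train, X, factor(model$fit$cl, levels = c(0, 1)),
                         k = model$fit$nn)
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
      as.integer(as.character(pred))
    },
    random_forest = as.integer(as.character(
      stats::predict(model$fit, data = as.data.frame(X))$predictions)),
    svm = as.integer(as.character(stats::predict(model$fit, X))),
    gradient_boosted_trees = as.integer(
      stats::predict(model$fit, xgboost::xgb.DMatrix(X, nthread = 1L)) > 0.5)
  )
  out
}
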