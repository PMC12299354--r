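#' Model-configuration grids
#'
#' `default_grid()` expands five classifier kinds over their documented
#' hyperparameter sets -- logistic regression C in \{0.1, 1, 10\}; knn
#' neighbours in \{5, 11\}; random forest (100 trees) depth in \{5, none\};
#' RBF svm C in \{0.1, 1, 10\}; gradient-boosted trees (100 rounds) learning
#' rate in \{0.1, 1.0\} -- crossed with selector k in \{none, 5, 10\} and
#' sampler in \{none, smote\} (72 configurations). `base_grid()` keeps one
#' base hyperparameter setting per kind (30 configurations), for fast
#' simulation studies.
#'
#' @return A list of configurations; each has `config_id`, `classifier_kind`,
#'   `params`, `selector_k`, `sampler`.
#' @export
default_grid <- function() {
  make_grid(list(
    logistic_regression = lapply(c(0.1, 1, 10), function(C) list(C = C)),
    knn = lapply(c(5L, 11L), function(nn) list(nn = nn)),
    random_forest = lapply(list(5L, "none"), function(d) list(depth = d)),
    svm = lapply(c(0.1, 1, 10), function(C) list(C = C)),
    gradient_boosted_trees = lapply(c(0.1, 1.0), function(lr) list(lr = lr))
  ))
}

#' @rdname default_grid
#' @export
base_grid <- function() {
  make_grid(list(
    logistic_regression = list(list(C = 1)),
    knn = list(list(nn = 5L)),
    random_forest = list(list(depth = "none")),
    svm = list(list(C = 1)),
    gradient_boosted_trees = list(list(lr = 1.0))
  ))
}

make_grid <- function(classifiers, selectors = list("none", 5L, 10L),
                      samplers = c("none", "smote")) {
  grid <- list()
  for (kind in names(classifiers)) for (params in classifiers[[kind]])
    for (sel in selectors) for (smp in samplers) {
      pstr <- paste(names(params), unlist(params), sep = "=", collapse = ",")
      grid[[length(grid) + 1L]] <- list(
        config_id = paste0(kind, "(", pstr, ")|sel=", sel, "|", smp),
        classifier_kind = kind, params = params,
        selector_k = sel, sampler = smp
      )
    }
  grid
}

config_seed <- function(seed, config_idx, fold) {
  as.integer((as.numeric(seed) * 97 + config_idx * 131 + fold * 7919) %%
               (.Machine$integer.max - 1)) + 1L
}

# Fit the full pipeline (impute -> optional SMOTE -> optional top-k selector ->
# optional z-scoring -> classifier) on training data only, returning a
# predictor closure. This single code path serves both cross-validation and
# the cross-cohort transfer evaluation, so leakage guards live in one place.
fit_pipeline <- function(config, X_train, y_train, seed, smote_k = 5L) {
  med <- fit_imputer(X_train)
  X_train <- apply_imputer(X_train, med)
  if (config$sampler == "smote") {
    bal <- smote_oversample(X_train, y_train, k_neighbors = smote_k, seed = seed)
    X_train <- bal$X; y_train <- bal$y
  }
  cols <- select_k_best(X_train, y_train, config$selector_k)
  X_train <- X_train[, cols, drop = FALSE]
  scaler <- NULL
  if (scale_sensitive(config$classifier_kind)) {
    scaler <- fit_scaler(X_train)
    X_train <- apply_scaler(X_train, scaler)
  }
  model <- fit_classifier(config$classifier_kind, config$params,
                          X_train, y_train, seed = seed)
  function(X_new) {
    X_new <- apply_imputer(X_new[, names(med), drop = FALSE], med)
    X_new <- X_new[, cols, drop = FALSE]
    if (!is.null(scaler)) X_new <- apply_scaler(X_new, scaler)
    predict_classifier(model, X_new)
  }
}

#' Grid search with stratified cross-validation
#'
#' Evaluates every configuration of the grid with stratified k-fold
#' cross-validation. Within each fold the pipeline order is: median imputation
#' (medians learned on the training fold), optional relevance filter
#' ([fresh_relevance_filter()], fit on the training fold), optional SMOTE on
#' the training fold, ANOVA-F top-k selection fit on the (possibly resampled)
#' training fold, z-scoring fit on the training fold for scale-sensitive
#' classifiers, classifier fit, prediction of the held-out fold. Nothing is
#' ever fit on test-fold rows. Configurations are ranked by mean fold macro F1
#' (ties: higher mean accuracy, then lexicographic config id); a configuration
#' failing on any fold scores 0 with a warning rather than being dropped.
#'
#' @param X Feature matrix (rows = sessions, named columns).
#' @param labels Binary label vector.
#' @param grid List of configurations ([default_grid()], [base_grid()]).
#' @param k Number of CV folds (default 10).
#' @param seed Master seed; fans out to folds, SMOTE and stochastic learners.
#' @param fresh_fdr If non-NULL, FDR level for the per-fold relevance filter.
#' @param smote_k SMOTE neighbourhood size.
#' @return Object of class `ranked_grid`: list with `leaderboard` (data.frame:
#'   rank, config_id, classifier, hyperparams, selector, sampler,
#'   macro_f1_mean, macro_f1_sd, accuracy_mean, accuracy_sd), `details`
#'   (per-config fold scores and pooled confusion matrices), `folds`, `seed`.
#' @export
run_grid <- function(X, labels, grid = default_grid(), k = 10L, seed = 1L,
                     fresh_fdr = NULL, smote_k = 5L) {
  stopifnot(nrow(X) == length(labels))
  folds <- stratified_folds(labels, k = k, seed = seed)
  k <- attr(folds, "k")

  # fold-scoped, configuration-independent preprocessing, computed once
  fold_data <- lapply(seq_len(k), function(f) {
    tr <- folds != f
    Xtr <- X[tr, , drop = FALSE]
    if (!is.null(fresh_fdr)) {
      filt <- fresh_relevance_filter(apply_imputer(Xtr, fit_imputer(Xtr)),
                                     labels[tr], fdr_level = fresh_fdr)
      keep <- attr(filt, "retained")
      if (length(keep) == 0L) keep <- colnames(X)  # filter vetoed everything
    } else keep <- colnames(X)
    list(X_train = Xtr[, keep, drop = FALSE],
         y_train = labels[tr],
         X_test = X[!tr, keep, drop = FALSE],
         y_test = labels[!tr])
  })

  details <- vector("list", length(grid))
  rows <- vector("list", length(grid))
  for (ci in seq_along(grid)) {
    config <- grid[[ci]]
    f1 <- acc <- numeric(k)
    conf <- matrix(0L, 2L, 2L, dimnames = list(true = c("0", "1"),
                                               predicted = c("0", "1")))
    for (f in seq_len(k)) {
      fd <- fold_data[[f]]
      pred <- tryCatch({
        predictor <- fit_pipeline(config, fd$X_train, fd$y_train,
                                  seed = config_seed(seed, ci, f),
                                  smote_k = smote_k)
        predictor(fd$X_test)
      }, error = function(e) {
        warning("config ", config$config_id, " failed on fold ", f, ": ",
                conditionMessage(e))
        NULL
      })
      if (is.null(pred)) { f1[f] <- 0; acc[f] <- 0; next }
      f1[f] <- macro_f1(fd$y_test, pred)
      acc[f] <- accuracy(fd$y_test, pred)
      conf <- conf + confusion_matrix(fd$y_test, pred)
    }
    details[[ci]] <- list(config = config, fold_macro_f1 = f1,
                          fold_accuracy = acc, confusion = conf)
    rows[[ci]] <- data.frame(
      config_id = config$config_id,
      classifier = config$classifier_kind,
      hyperparams = paste(names(config$params), unlist(config$params),
                          sep = "=", collapse = ","),
      selector = as.character(config$selector_k),
      sampler = config$sampler,
      macro_f1_mean = mean(f1), macro_f1_sd = stats::sd(f1),
      accuracy_mean = mean(acc), accuracy_sd = stats::sd(acc)
    )
  }
  lb <- do.call(rbind, rows)
  ord <- order(-lb$macro_f1_mean, -lb$accuracy_mean, lb$config_id)
  lb <- lb[ord, ]
  lb$rank <- seq_len(nrow(lb))
  rownames(lb) <- NULL
  structure(list(leaderboard = lb[, c("rank", setdiff(names(lb), "rank"))],
                 details = details[ord], folds = folds, seed = seed,
                 fresh_fdr = fresh_fdr, smote_k = smote_k,
                 tie_break = "macro_f1_mean desc, accuracy_mean desc, config_id"),
            class = "ranked_grid")
}

#' @export
print.ranked_grid <- function(x, n = 10L, ...) {
  cat("<ranked_grid> ", nrow(x$leaderboard), " configs, ",
      attr(x$folds, "k"), "-fold CV, seed ", x$seed, "\n", sep = "")
  print(utils::head(x$leaderboard[, c("rank", "classifier", "hyperparams",
                                      "selector", "sampler", "macro_f1_mean",
                                      "accuracy_mean")], n))
  invisible(x)
}

#' Write a leaderboard as TSV
#' @param ranked A `ranked_grid`.
#' @param path Output file.
#' @export
write_leaderboard <- function(ranked, path) {
  utils::write.table(ranked$leaderboard, path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
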