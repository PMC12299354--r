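#' Cross-cohort transfer evaluation
#'
#' Refits each of the `top_k` best cross-validated configurations on the full
#' source cohort (imputation, optional relevance filter, SMOTE, selector and
#' scaler all fit on source data only) and scores each once, unchanged, on the
#' target cohort. No target information influences fitting; target labels are
#' touched only inside metric computation.
#'
#' @param X_source,y_source Source feature matrix and labels.
#' @param X_target,y_target Target feature matrix and labels; the target must
#'   provide (at least) the source's columns and contain both classes.
#' @param ranked A `ranked_grid` from [run_grid()] on the source cohort.
#' @param top_k Number of leading configurations to transfer (default 10).
#' @param seed Integer seed for stochastic refits.
#' @return Object of class `transfer_report`: list with `per_model`
#'   (data.frame: rank, config_id, cv_macro_f1, target_macro_f1,
#'   target_accuracy), `confusions` (list of 2x2 matrices), `mean_macro_f1`,
#'   `sd_macro_f1`, `representation`.
#' @export
transfer_evaluate <- function(X_source, y_source, X_target, y_target,
                              ranked, top_k = 10L, seed = 1L) {
  missing_cols <- setdiff(colnames(X_source), colnames(X_target))
  if (length(missing_cols))
    stop("target schema lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (length(unique(y_target)) < 2L)
    stop("target cohort must contain both classes")
  X_target <- X_target[, colnames(X_source), drop = FALSE]

  keep <- colnames(X_source)
  if (!is.null(ranked$fresh_fdr)) {
    filt <- fresh_relevance_filter(
      apply_imputer(X_source, fit_imputer(X_source)), y_source,
      fdr_level = ranked$fresh_fdr)
    keep <- attr(filt, "retained")
    if (length(keep) == 0L) keep <- colnames(X_source)
  }
  top <- utils::head(ranked$leaderboard, top_k)
  by_id <- stats::setNames(lapply(ranked$details, `[[`, "config"),
                           vapply(ranked$details, function(d) d$config$config_id, ""))
  confusions <- list()
  rows <- lapply(seq_len(nrow(top)), function(i) {
    config <- by_id[[top$config_id[i]]]
    predictor <- fit_pipeline(config,
                              X_source[, keep, drop = FALSE], y_source,
                              seed = config_seed(seed, i, 0L),
                              smote_k = ranked$smote_k)
    pred <- predictor(X_target[, keep, drop = FALSE])
    confusions[[config$config_id]] <<- confusion_matrix(y_target, pred)
    data.frame(rank = top$rank[i], config_id = top$config_id[i],
               cv_macro_f1 = top$macro_f1_mean[i],
               target_macro_f1 = macro_f1(y_target, pred),
               target_accuracy = accuracy(y_target, pred))
  })
  per_model <- do.call(rbind, rows)
  structure(list(per_model = per_model, confusions = confusions,
                 mean_macro_f1 = mean(per_model$target_macro_f1),
                 sd_macro_f1 = stats::sd(per_model$target_macro_f1),
                 representation = attr(X_source, "representation")),
            class = "transfer_report")
}

#' @export
print.transfer_report <- function(x, ...) {
  cat(sprintf("<transfer_report%s> top %d models: target macro F1 %.3f +/- %.3f\n",
              if (is.null(x$representation)) "" else paste0(" ", x$representation),
              nrow(x$per_model), x$mean_macro_f1, x$sd_macro_f1))
  invisible(x)
}

#' Pairwise Welch comparison of representation score sets
#'
#' Compares the transfer (or CV) macro-F1 score sets of representations with
#' Welch's t-test, flagging significance at the stated threshold
#' (default p < 0.001).
#'
#' @param scores Named list of numeric score vectors, one per representation.
#' @param p_threshold Significance threshold.
#' @return data.frame with one row per pair: the two representation names,
#'   their mean +/- sd, `t`, `p_value`, `significant`. Pairs with fewer than 2
#'   scores on either side are skipped with a reason column entry.
#' @export
compare_representations <- function(scores, p_threshold = 0.001) {
  stopifnot(length(scores) >= 2L, !is.null(names(scores)))
  pairs <- utils::combn(names(scores), 2L, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    a <- scores[[pr[1L]]]; b <- scores[[pr[2L]]]
    out <- data.frame(
      rep_a = pr[1L], rep_b = pr[2L],
      mean_a = mean(a), sd_a = stats::sd(a),
      mean_b = mean(b), sd_b = stats::sd(b),
      t = NA_real_, p_value = NA_real_, significant = NA,
      note = ""
    )
    if (length(a) < 2L || length(b) < 2L) {
      out$note <- "skipped: fewer than 2 scores in a set"
      return(out)
    }
    wt <- welch_t_test(a, b)
    out$t <- wt$statistic
    out$p_value <- wt$p_value
    out$significant <- wt$p_value < p_threshold
    out
  })
  do.call(rbind, rows)
}
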