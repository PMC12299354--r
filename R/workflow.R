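#' Generate, align and label a synthetic cohort in one call
#'
#' Convenience wrapper used by the simulation studies: generates a cohort,
#' applies the gravity alignment ([global_rotation_align()]) to every session
#' and returns the retained sessions with their label vector.
#'
#' @param params A [synth_params()] object.
#' @param min_duration Minimum retained session duration, seconds.
#' @return List with `sessions` (rotated), `labels` (aligned integer vector)
#'   and `manifest` (rows of retained sessions).
#' @export
simulate_prepared_cohort <- function(params, min_duration = 5) {
  cohort <- generate_cohort(params)
  sessions <- prepare_sessions(cohort$sessions, min_duration = min_duration)
  manifest <- cohort$manifest[cohort$manifest$session_id %in% names(sessions), ]
  list(sessions = sessions[manifest$session_id],
       labels = manifest$label,
       manifest = manifest)
}

#' Feature matrix of a cohort under one representation
#'
#' Dispatches to [semantic_feature_matrix()] (`SEMANTIC`) or
#' [extract_auto_features()] (`PCA_AUTO`, `AUTO3D`).
#'
#' @param sessions List of rotated, validated sessions.
#' @param representation One of `"SEMANTIC"`, `"PCA_AUTO"`, `"AUTO3D"`.
#' @return Numeric feature matrix with `representation` attribute.
#' @export
cohort_features <- function(sessions,
                            representation = c("SEMANTIC", "PCA_AUTO", "AUTO3D")) {
  representation <- match.arg(representation)
  if (representation == "SEMANTIC") semantic_feature_matrix(sessions)
  else extract_auto_features(sessions, mode = representation)
}

#' Write a feature matrix as TSV
#'
#' Rows = sessions; feature columns plus `session_id`, `label`, `dataset_tag`.
#'
#' @param X Feature matrix with session-id rownames.
#' @param manifest Manifest rows matching the matrix rows.
#' @param path Output file.
#' @export
write_feature_matrix <- function(X, manifest, path) {
  idx <- match(rownames(X), manifest$session_id)
  d <- data.frame(session_id = rownames(X), label = manifest$label[idx],
                  dataset_tag = manifest$dataset_tag[idx], X,
                  check.names = FALSE)
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
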