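#' Construct an accelerometer session
#'
#' An `accel_session` is one labelled, variable-length tri-axial recording of
#' the alternating pronation-supination task. No truncation or padding is ever
#' applied: downstream representations accept arbitrary durations.
#'
#' @param session_id Unique session identifier.
#' @param subject_id Subject identifier.
#' @param dataset_tag Source-cohort label (e.g. which site or simulator preset).
#' @param task_tag Task label, `"UPDRS_3_6"` for the pronation-supination item.
#' @param timestamps Numeric vector of seconds, strictly increasing.
#' @param acc Numeric n x 3 matrix of accelerations in g-units (columns x, y, z).
#' @param label Binary dyskinesia label (1 = present, 0 = absent).
#' @param rotated Logical; whether [global_rotation_align()] has been applied.
#' @param sim Optional list of simulator ground-truth parameters.
#'
#' @return An object of class `accel_session`.
#' @export
accel_session <- function(session_id, subject_id, dataset_tag, task_tag,
                          timestamps, acc, label, rotated = FALSE, sim = NULL) {
  acc <- as.matrix(acc)
  storage.mode(acc) <- "double"
  timestamps <- as.numeric(timestamps)
  n <- length(timestamps)
  if (ncol(acc) != 3L)
    stop("acc must have exactly 3 columns (x, y, z)")
  if (nrow(acc) != n)
    stop("timestamps and acc must have the same length")
  if (n < 2L)
    stop("session '", session_id, "': fewer than 2 samples")
  if (any(diff(timestamps) <= 0))
    stop("session '", session_id, "': timestamps not strictly increasing")
  if (any(!is.finite(timestamps)) || any(!is.finite(acc)))
    stop("session '", session_id, "': non-finite values after validation")
  if (!label %in% c(0, 1))
    stop("session '", session_id, "': label must be 0 or 1")
  duration <- timestamps[n] - timestamps[1L]
  structure(
    list(
      session_id  = as.character(session_id),
      subject_id  = as.character(subject_id),
      dataset_tag = as.character(dataset_tag),
      task_tag    = as.character(task_tag),
      sample_rate = (n - 1L) / duration,
      timestamps  = timestamps,
      acc         = acc,
      label       = as.integer(label),
      rotated     = isTRUE(rotated),
      sim         = sim
    ),
    class = "accel_session"
  )
}

#' @export
print.accel_session <- function(x, ...) {
  cat(sprintf(
    "<accel_session %s> subject %s [%s] %s\n  %d samples, %.1f s @ %.1f Hz, label = %d, rotated = %s\n",
    x$session_id, x$subject_id, x$dataset_tag, x$task_tag,
    length(x$timestamps), session_duration(x), x$sample_rate, x$label,
    x$rotated
  ))
  invisible(x)
}

#' Session duration in seconds
#' @param session An `accel_session`.
#' @return Duration (last minus first timestamp), seconds.
#' @export
session_duration <- function(session) {
  ts <- session$timestamps
  ts[length(ts)] - ts[1L]
}
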