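#' Read a cohort manifest
#'
#' The manifest is a tab-separated table with header
#' `file  session_id  subject_id  dataset_tag  label  task_tag`, one row per
#' session file. Row order is preserved.
#'
#' @param path Path to the manifest TSV.
#' @return A data.frame with the six manifest columns.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path))
    stop("manifest not found: ", path)
  m <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  required <- c("file", "session_id", "subject_id", "dataset_tag",
                "label", "task_tag")
  missing <- setdiff(required, names(m))
  if (length(missing))
    stop("manifest missing column(s): ", paste(missing, collapse = ", "))
  m <- m[, required]
  dup <- m$session_id[duplicated(m$session_id)]
  if (length(dup))
    stop("duplicate session_id in manifest: ", paste(unique(dup), collapse = ", "))
  m$label <- as.integer(m$label)
  if (any(is.na(m$label)) || !all(m$label %in% c(0L, 1L)))
    stop("manifest labels must be 0 or 1")
  base <- dirname(path)
  resolved <- ifelse(file.exists(m$file), m$file, file.path(base, m$file))
  gone <- !file.exists(resolved)
  if (any(gone))
    stop("manifest row(s) reference missing file(s): ",
         paste(m$session_id[gone], collapse = ", "))
  m$file <- resolved
  m
}

#' Read one session CSV
#'
#' Session files are CSV with header `t,x,y,z`: `t` in seconds (strictly
#' increasing), axes in g. Rows containing NaN are dropped with a message; the
#' sample rate is estimated as the average rate `(n - 1) / (t_last - t_first)`.
#' No resampling is performed.
#'
#' @param path Path to the session CSV.
#' @param meta One manifest row (list or single-row data.frame) supplying
#'   `session_id`, `subject_id`, `dataset_tag`, `label`, `task_tag`.
#' @return An [accel_session()].
#' @export
read_session <- function(path, meta) {
  d <- utils::read.csv(path)
  need <- c("t", "x", "y", "z")
  if (!all(need %in% names(d)))
    stop("session file ", path, " must have columns t,x,y,z")
  d <- d[, need]
  for (ax in c("x", "y", "z"))
    if (all(is.na(d[[ax]]))) stop("session file ", path, ": axis ", ax, " is all-NaN")
  keep <- stats::complete.cases(d)
  if (any(!keep))
    message(sum(!keep), " row(s) with NaN dropped from ", basename(path))
  d <- d[keep, ]
  if (nrow(d) < 2L)
    stop("session file ", path, ": fewer than 2 usable samples")
  if (any(diff(d$t) <= 0))
    stop("session file ", path, ": time not strictly increasing")
  accel_session(
    session_id  = meta$session_id,
    subject_id  = meta$subject_id,
    dataset_tag = meta$dataset_tag,
    task_tag    = meta$task_tag,
    timestamps  = d$t,
    acc         = cbind(x = d$x, y = d$y, z = d$z),
    label       = meta$label
  )
}

#' Load every session referenced by a manifest
#'
#' @param manifest A manifest data.frame from [read_manifest()].
#' @return Named list of [accel_session()] objects (names = session ids).
#' @export
read_cohort <- function(manifest) {
  sessions <- lapply(seq_len(nrow(manifest)), function(i)
    read_session(manifest$file[i], manifest[i, ]))
  names(sessions) <- manifest$session_id
  sessions
}

# Minimal rotation taking unit vector a onto unit vector b (Rodrigues).
rotation_between <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2],
         a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  s <- sqrt(sum(v^2))
  c_ <- sum(a * b)
  if (s < 1e-12) {
    if (c_ > 0) return(diag(3))
    # antipodal: rotate pi about any axis orthogonal to a
    ax <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- ax - sum(ax * a) * a
    ax <- ax / sqrt(sum(ax^2))
    K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
                3, 3, byrow = TRUE)
    return(diag(3) + 2 * K %*% K)
  }
  K <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + K + K %*% K * ((1 - c_) / s^2)
}

#' Align a session's gravity estimate with the +z axis
#'
#' Different wearables use different device coordinate frames. To harmonise
#' them, the session's mean acceleration vector (the gravity estimate for this
#' quasi-stationary task) is mapped onto +z by the minimal (geodesic) rotation
#' in the plane spanned by the mean vector and +z. The residual yaw freedom
#' about gravity is left undetermined; the per-session PCA downstream is
#' invariant to it. Per-sample norms are preserved (rotations are isometries).
#'
#' @param session An unrotated, validated [accel_session()].
#' @return The session with rotated acceleration and `rotated = TRUE`.
#' @export
global_rotation_align <- function(session) {
  if (isTRUE(session$rotated))
    stop("session '", session$session_id, "' already rotated")
  m <- colMeans(session$acc)
  if (sqrt(sum(m^2)) < 0.1)
    stop("session '", session$session_id,
         "': no stable gravity estimate (mean-vector norm < 0.1 g)")
  R <- rotation_between(m, c(0, 0, 1))
  session$acc <- session$acc %*% t(R)
  colnames(session$acc) <- c("x", "y", "z")
  session$rotated <- TRUE
  session
}

#' Rotate and retain valid sessions of a cohort
#'
#' Convenience wrapper: applies [global_rotation_align()] to each session and
#' drops sessions failing validation (too short, unstable gravity), consistent
#' with [validate_cohort()].
#'
#' @param sessions List of sessions.
#' @param min_duration Minimum retained duration, seconds.
#' @return Named list of rotated sessions.
#' @export
prepare_sessions <- function(sessions, min_duration = 5) {
  out <- list()
  for (s in sessions) {
    if (session_duration(s) < min_duration) next
    r <- tryCatch(global_rotation_align(s), error = function(e) NULL)
    if (!is.null(r)) out[[r$session_id]] <- r
  }
  out
}

#' Validate a loaded cohort
#'
#' Report-only quality check: flags sessions shorter than the minimum
#' duration, with non-finite samples, or with an unstable gravity estimate,
#' and tabulates retained sessions per dataset tag and label.
#'
#' @param manifest Manifest data.frame.
#' @param sessions List of sessions matching the manifest.
#' @param min_duration Minimum session duration in seconds (default 5).
#' @return A list with elements `per_session` (data.frame: session_id, pass,
#'   reason) and `counts` (data.frame: dataset_tag, label, n over passing
#'   sessions).
#' @export
validate_cohort <- function(manifest, sessions, min_duration = 5) {
  rows <- lapply(manifest$session_id, function(id) {
    s <- sessions[[id]]
    if (is.null(s))
      return(data.frame(session_id = id, pass = FALSE, reason = "not loaded"))
    reason <- ""
    if (any(!is.finite(s$acc)) || any(!is.finite(s$timestamps)))
      reason <- "non-finite values"
    else if (session_duration(s) < min_duration)
      reason <- sprintf("too short (%.2f s < %g s)", session_duration(s), min_duration)
    else if (sqrt(sum(colMeans(s$acc)^2)) < 0.1 && !isTRUE(s$rotated))
      reason <- "no stable gravity estimate"
    data.frame(session_id = id, pass = reason == "", reason = reason)
  })
  per_session <- do.call(rbind, rows)
  ok <- manifest[manifest$session_id %in% per_session$session_id[per_session$pass], ]
  counts <- as.data.frame(table(dataset_tag = ok$dataset_tag, label = ok$label),
                          responseName = "n")
  list(per_session = per_session, counts = counts)
}
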