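#' Project a session onto its first principal component
#'
#' Per-session PCA of the centred tri-axial accelerations. Projecting onto the
#' top eigenvector of the session's own 3x3 covariance collapses the
#' alternating pronation-supination motion to a one-dimensional trace while
#' remaining invariant to how the device was worn (any fixed rotation of the
#' raw vectors). The loading sign is fixed by flipping it so its
#' largest-magnitude entry is positive.
#'
#' @param session A rotated, validated [accel_session()].
#' @return An object of class `projected_signal`: list with `values` (centred
#'   PC scores), `loading` (unit 3-vector), `explained_variance_ratio`,
#'   `sample_rate`.
#' @export
project_pc1 <- function(session) {
  X <- session$acc
  Xc <- sweep(X, 2L, colMeans(X))
  C <- stats::cov(Xc)
  ev <- eigen(C, symmetric = TRUE)
  if (sum(ev$values) <= 0)
    stop("session '", session$session_id, "': constant signal")
  v <- ev$vectors[, 1L]
  i <- which.max(abs(v))
  if (v[i] < 0) v <- -v
  structure(
    list(
      values = as.numeric(Xc %*% v),
      loading = v,
      explained_variance_ratio = ev$values[1L] / sum(ev$values),
      sample_rate = session$sample_rate
    ),
    class = "projected_signal"
  )
}

#' Split a trace into beginning / middle / end parts
#'
#' Each session trace is divided into three contiguous parts featurised
#' separately; the middle and end parts get `floor(n/3)` samples each and any
#' remainder goes to the beginning (deterministic).
#'
#' @param n Number of samples (>= 3).
#' @return List of three integer vectors `c(start, end)` with half-open
#'   `[start, end)` 1-based sample ranges (i.e. samples `start .. end - 1`).
#' @export
split_parts <- function(n) {
  if (n < 3L) stop("signal too short to split into three parts (n < 3)")
  third <- n %/% 3L
  first <- n - 2L * third
  list(
    c(1L, first + 1L),
    c(first + 1L, first + third + 1L),
    c(first + third + 1L, n + 1L)
  )
}

#' Segment one part of a trace by extremum sign
#'
#' The centred trace is cut at zero crossings (a crossing sits between
#' consecutive samples of strictly opposite sign; the boundary index is the
#' first sample of the new sign). Each maximal constant-sign run of at least 2
#' samples becomes a segment characterised by its extremum (the
#' largest-magnitude sample within it); shorter runs are merged into the
#' preceding segment (the first run, lacking a predecessor, merges forward).
#' After merging, adjacent spans whose extrema share a sign are coalesced, so
#' consecutive segments always alternate sign. A part with no sign change
#' yields a single segment.
#'
#' @param signal A `projected_signal` from [project_pc1()].
#' @param part A `c(start, end)` half-open range from [split_parts()].
#' @return Object of class `part_segmentation`: list with `part_range` and
#'   `segments`, a data.frame with columns `start_idx`, `end_idx` (half-open,
#'   relative to the whole signal), `duration` (s), `extremum_value`, `sign`.
#' @export
segment_by_extrema <- function(signal, part) {
  lo <- part[1L]; hi <- part[2L] - 1L
  v <- signal$values[lo:hi]
  n <- length(v)
  sgn <- sign(v)
  # zero-valued samples carry the previous sign (no crossing at a touch)
  for (i in seq_len(n)) if (sgn[i] == 0) sgn[i] <- if (i > 1L) sgn[i - 1L] else 0
  if (sgn[1L] == 0) {
    nz <- which(sgn != 0)[1L]
    if (is.na(nz)) sgn[] <- 1 else sgn[1:(nz - 1L)] <- sgn[nz]
  }
  r <- rle(sgn)
  starts <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
  ends <- cumsum(r$lengths)            # inclusive, local indices
  spans <- cbind(starts, ends)
  # merge runs shorter than 2 samples into the preceding span
  while (nrow(spans) > 1L && any(spans[, 2] - spans[, 1] + 1L < 2L)) {
    k <- which(spans[, 2] - spans[, 1] + 1L < 2L)[1L]
    if (k == 1L) {
      spans[2L, 1L] <- spans[1L, 1L]
      spans <- spans[-1L, , drop = FALSE]
    } else {
      spans[k - 1L, 2L] <- spans[k, 2L]
      spans <- spans[-k, , drop = FALSE]
    }
  }
  extremum_of <- function(a, b) {
    seg <- v[a:b]
    seg[which.max(abs(seg))]
  }
  ext <- mapply(extremum_of, spans[, 1], spans[, 2])
  # coalesce adjacent spans whose extrema share a sign
  i <- 1L
  while (i < nrow(spans)) {
    if (sign(ext[i]) == sign(ext[i + 1L])) {
      spans[i, 2L] <- spans[i + 1L, 2L]
      spans <- spans[-(i + 1L), , drop = FALSE]
      ext[i] <- extremum_of(spans[i, 1L], spans[i, 2L])
      ext <- ext[-(i + 1L)]
    } else i <- i + 1L
  }
  fs <- signal$sample_rate
  segments <- data.frame(
    start_idx = lo + spans[, 1L] - 1L,
    end_idx   = lo + spans[, 2L],      # half-open
    duration  = (spans[, 2L] - spans[, 1L] + 1L) / fs,
    extremum_value = ext,
    sign = ifelse(ext > 0, "positive", "negative")
  )
  structure(list(part_range = part, segments = segments),
            class = "part_segmentation")
}

# IQR with the linear-interpolation quantile definition (R type 7);
# degenerate inputs (< 2 values) take the sentinel 0.
iqr_or_sentinel <- function(x) {
  if (length(x) < 2L) return(0)
  unname(diff(stats::quantile(x, c(0.25, 0.75), names = FALSE, type = 7)))
}

mean_or_sentinel <- function(x) if (length(x) < 1L) 0 else mean(x)

#' Names of the 25 semantic features, in canonical order
#' @return Character vector of length 25.
#' @export
semantic_feature_names <- function() {
  kinds <- c("n_segments", "duration_ratio", "mean_duration", "iqr_duration",
             "relmax_mean", "relmax_iqr", "relmin_mean", "relmin_iqr")
  c("abs_mean_extremum",
    as.vector(t(outer(kinds, 0:2, function(k, p) paste0(k, "__part", p)))))
}

#' Extract the semantic biomechanical feature vector of a session
#'
#' The session is projected onto its first principal component
#' ([project_pc1()]), split into beginning/middle/end parts ([split_parts()]),
#' and each part segmented by extremum sign ([segment_by_extrema()]). Nine
#' feature kinds are then computed: one whole-measurement feature, the absolute
#' mean of segment extrema, and eight per-part features -- segment count,
#' positive-to-negative total-duration ratio (pronation/supination asymmetry),
#' mean and interquartile range of segment durations, and mean/IQR of the
#' relative maxima (positive-segment extrema) and relative minima
#' (negative-segment extrema). 1 + 8 x 3 = 25 named values.
#'
#' Degenerate statistics (a part lacking segments of one sign, or fewer than 2
#' values for an IQR) take sentinels -- 1 for the duration ratio, 0 for IQRs
#' and means of empty sets -- so the matrix stays finite; affected features are
#' reported in the `degenerate` attribute.
#'
#' @param session A validated [accel_session()].
#' @return Named numeric vector of length 25 with attribute `degenerate`
#'   (character vector of sentinel-valued feature names).
#' @export
extract_semantic_features <- function(session) {
  sig <- project_pc1(session)
  parts <- split_parts(length(sig$values))
  segs <- lapply(parts, function(p) segment_by_extrema(sig, p)$segments)

  degenerate <- character()
  out <- numeric(0)
  all_ext <- unlist(lapply(segs, function(s) s$extremum_value))
  out["abs_mean_extremum"] <- mean(abs(all_ext))
  for (p in 0:2) {
    s <- segs[[p + 1L]]
    pos <- s$extremum_value[s$extremum_value > 0]
    neg <- s$extremum_value[s$extremum_value < 0]
    dpos <- sum(s$duration[s$extremum_value > 0])
    dneg <- sum(s$duration[s$extremum_value < 0])
    nm <- function(k) paste0(k, "__part", p)

    out[nm("n_segments")] <- nrow(s)
    if (length(pos) == 0L || length(neg) == 0L || dneg == 0) {
      out[nm("duration_ratio")] <- 1
      degenerate <- c(degenerate, nm("duration_ratio"))
    } else out[nm("duration_ratio")] <- dpos / dneg
    out[nm("mean_duration")] <- mean(s$duration)
    out[nm("iqr_duration")] <- iqr_or_sentinel(s$duration)
    if (nrow(s) < 2L) degenerate <- c(degenerate, nm("iqr_duration"))
    out[nm("relmax_mean")] <- mean_or_sentinel(pos)
    out[nm("relmax_iqr")] <- iqr_or_sentinel(pos)
    out[nm("relmin_mean")] <- mean_or_sentinel(neg)
    out[nm("relmin_iqr")] <- iqr_or_sentinel(neg)
    if (length(pos) == 0L)
      degenerate <- c(degenerate, nm("relmax_mean"), nm("relmax_iqr"))
    else if (length(pos) < 2L) degenerate <- c(degenerate, nm("relmax_iqr"))
    if (length(neg) == 0L)
      degenerate <- c(degenerate, nm("relmin_mean"), nm("relmin_iqr"))
    else if (length(neg) < 2L) degenerate <- c(degenerate, nm("relmin_iqr"))
  }
  out <- out[semantic_feature_names()]
  attr(out, "degenerate") <- degenerate
  out
}

#' Semantic feature matrix of a cohort
#'
#' @param sessions List of validated sessions.
#' @return Numeric matrix (rows = sessions, 25 columns) with rownames set to
#'   session ids and attribute `representation = "SEMANTIC"`.
#' @export
semantic_feature_matrix <- function(sessions) {
  M <- t(vapply(sessions, function(s) {
    f <- extract_semantic_features(s)
    attributes(f)$degenerate <- NULL
    as.numeric(f)
  }, numeric(25L)))
  colnames(M) <- semantic_feature_names()
  rownames(M) <- vapply(sessions, `[[`, "", "session_id")
  attr(M, "representation") <- "SEMANTIC"
  M
}
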