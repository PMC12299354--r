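#' Generic time-series feature catalogue for one series
#'
#' A fixed, documented catalogue of distributional, temporal-structure and
#' spectral descriptors (60+ named features per series), in the spirit of
#' large-scale automatic time-series featurisation. Spectral features use the
#' series' average sample rate after linear detrending; features undefined on a
#' degenerate series (constant, or shorter than the longest lag) are set to 0.
#' Output is deterministic with stable column names.
#'
#' @param x Numeric series.
#' @param fs Average sample rate in Hz.
#' @return Named numeric vector.
#' @export
ts_feature_catalogue <- function(x, fs) {
  n <- length(x)
  mu <- mean(x)
  s2 <- stats::var(x)
  sdx <- sqrt(s2)
  const <- !is.finite(sdx) || sdx == 0
  xc <- x - mu
  f <- c(
    mean = mu,
    median = stats::median(x),
    variance = s2,
    sd = sdx,
    skewness = if (const) 0 else e1071::skewness(x, type = 2),
    kurtosis = if (const) 0 else e1071::kurtosis(x, type = 2),
    iqr = iqr_or_sentinel(x),
    rms = sqrt(mean(x^2)),
    min = min(x),
    max = max(x),
    range = max(x) - min(x),
    mad = stats::mad(x)
  )
  q <- stats::quantile(x, c(0.05, 0.1, 0.25, 0.75, 0.9, 0.95), names = FALSE)
  f <- c(f, stats::setNames(q, paste0("q", c("05", "10", "25", "75", "90", "95"))))

  sgn <- sign(xc); sgn <- sgn[sgn != 0]
  f["zero_crossings"] <- if (length(sgn) > 1L) sum(diff(sgn) != 0) else 0
  dx <- diff(x)
  f["mean_abs_change"] <- if (n > 1L) mean(abs(dx)) else 0
  f["mean_change"] <- if (n > 1L) mean(dx) else 0
  f["abs_energy"] <- sum(x^2)
  f["cid"] <- if (n > 1L) sqrt(sum(dx^2)) else 0
  f["count_above_mean"] <- sum(x > mu)
  f["count_below_mean"] <- sum(x < mu)
  runs <- rle(x > mu)
  f["longest_run_above_mean"] <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0
  f["longest_run_below_mean"] <- if (any(!runs$values)) max(runs$lengths[!runs$values]) else 0
  f["first_max_loc"] <- (which.max(x) - 1L) / n
  f["first_min_loc"] <- (which.min(x) - 1L) / n
  f["last_max_loc"] <- (n - which.max(rev(x)) ) / n
  f["last_min_loc"] <- (n - which.min(rev(x)) ) / n
  f["ratio_beyond_1sd"] <- if (const) 0 else mean(abs(xc) > sdx)
  f["ratio_beyond_2sd"] <- if (const) 0 else mean(abs(xc) > 2 * sdx)

  for (m in c(1L, 3L, 5L))
    f[paste0("n_peaks_support", m)] <- count_peaks(x, m)
  amax <- max(abs(xc))
  for (frac in c(0.5, 0.75))
    f[paste0("peaks_above_", frac, "max")] <-
      if (amax == 0) 0 else sum(local_maxima(xc) & xc > frac * amax)

  for (k in 1:10)
    f[paste0("autocorr_lag", k)] <- autocorr_at(xc, k, s2)

  tr <- linear_trend(x)
  f["trend_slope"] <- tr[1L]
  f["trend_intercept"] <- tr[2L]
  f["trend_r2"] <- tr[3L]

  f <- c(f, spectral_features(x, fs))
  f["sample_entropy"] <- sample_entropy(x, max_n = 512L)
  f["binned_entropy"] <- binned_entropy(x, 10L)
  f["c3_lag1"] <- if (n > 2L) mean(x[1:(n - 2)] * x[2:(n - 1)] * x[3:n]) else 0
  f["time_rev_asym_lag1"] <-
    if (n > 2L) mean(x[3:n]^2 * x[2:(n - 1)] - x[2:(n - 1)] * x[1:(n - 2)]^2) else 0
  f[!is.finite(f)] <- 0
  f
}

local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(rep(FALSE, n))
  c(FALSE, x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] > x[3:n], FALSE)
}

count_peaks <- function(x, support) {
  n <- length(x)
  if (n < 2L * support + 1L) return(0)
  idx <- (support + 1L):(n - support)
  ok <- rep(TRUE, length(idx))
  for (d in seq_len(support))
    ok <- ok & x[idx] > x[idx - d] & x[idx] > x[idx + d]
  sum(ok)
}

autocorr_at <- function(xc, k, s2) {
  n <- length(xc)
  if (n <= k || !is.finite(s2) || s2 == 0) return(0)
  sum(xc[1:(n - k)] * xc[(k + 1):n]) / ((n - 1) * s2)
}

linear_trend <- function(x) {
  n <- length(x)
  if (n < 2L) return(c(0, x[1L], 0))
  t <- seq_len(n)
  fit <- stats::lm.fit(cbind(1, t), x)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((x - mean(x))^2)
  c(fit$coefficients[2L], fit$coefficients[1L],
    if (ss_tot == 0) 0 else 1 - ss_res / ss_tot)
}

# Spectral descriptors of the linearly detrended series: relative band powers
# over 0.5-3, 3-7 and 7-12 Hz, dominant frequency and its power fraction,
# normalized spectral entropy and centroid. Constant series take the floor 0.
spectral_features <- function(x, fs) {
  out <- c(band_power_0.5_3 = 0, band_power_3_7 = 0, band_power_7_12 = 0,
           dominant_freq = 0, dominant_power_frac = 0,
           spectral_entropy = 0, spectral_centroid = 0)
  n <- length(x)
  if (n < 4L || max(x) == min(x)) return(out)
  t <- seq_len(n)
  xd <- stats::lm.fit(cbind(1, t), x)$residuals
  m <- n %/% 2L
  p <- Mod(stats::fft(xd))[2:(m + 1L)]^2     # exclude DC
  freqs <- (1:m) * fs / n
  tot <- sum(p)
  if (tot <= 0) return(out)
  bp <- function(a, b) sum(p[freqs >= a & freqs < b]) / tot
  out["band_power_0.5_3"] <- bp(0.5, 3)
  out["band_power_3_7"] <- bp(3, 7)
  out["band_power_7_12"] <- bp(7, 12)
  imax <- which.max(p)
  out["dominant_freq"] <- freqs[imax]
  out["dominant_power_frac"] <- p[imax] / tot
  pr <- p / tot
  pr <- pr[pr > 0]
  out["spectral_entropy"] <- if (length(pr) > 1L) -sum(pr * log(pr)) / log(m) else 0
  out["spectral_centroid"] <- sum(freqs * p) / tot
  out
}

# Sample entropy (m = 2, r = 0.2 sd) on at most the first max_n samples
# (quadratic pair comparisons; truncation keeps long sessions tractable).
sample_entropy <- function(x, m = 2L, r_frac = 0.2, max_n = 512L) {
  if (length(x) > max_n) x <- x[seq_len(max_n)]
  n <- length(x)
  sdx <- stats::sd(x)
  if (n < m + 2L || !is.finite(sdx) || sdx == 0) return(0)
  r <- r_frac * sdx
  count_matches <- function(mm) {
    nv <- n - mm + 1L
    cnt <- 0L
    for (i in 1:(nv - 1L)) {
      # Chebyshev distance between template i and all j > i, vectorised per lag
      ok <- rep(TRUE, nv - i)
      for (k in 0:(mm - 1L)) {
        ok <- ok & abs(x[(i + k)] - x[(i + k + 1):(i + k + nv - i)]) <= r
        if (!any(ok)) break
      }
      cnt <- cnt + sum(ok)
    }
    cnt
  }
  B <- count_matches(m)
  A <- count_matches(m + 1L)
  if (A == 0L || B == 0L) return(0)
  -log(A / B)
}

binned_entropy <- function(x, bins = 10L) {
  if (length(x) < 2L || max(x) == min(x)) return(0)
  h <- tabulate(cut(x, breaks = bins, labels = FALSE), nbins = bins)
  p <- h / sum(h)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Automatic feature matrix of a cohort
#'
#' Applies [ts_feature_catalogue()] in one of two modes: `PCA_AUTO` featurises
#' the first-principal-component trace of each session (columns prefixed
#' `pc1__`); `AUTO3D` featurises each raw axis separately (columns prefixed
#' `x__`, `y__`, `z__`, giving three times as many columns).
#'
#' @param sessions List of validated sessions.
#' @param mode `"PCA_AUTO"` or `"AUTO3D"`.
#' @return Numeric matrix, rows = sessions (rownames = session ids), with
#'   attribute `representation` set to the mode.
#' @export
extract_auto_features <- function(sessions, mode = c("PCA_AUTO", "AUTO3D")) {
  mode <- match.arg(mode)
  feat_one <- function(s) {
    if (mode == "PCA_AUTO") {
      sig <- project_pc1(s)
      f <- ts_feature_catalogue(sig$values, sig$sample_rate)
      names(f) <- paste0("pc1__", names(f))
      f
    } else {
      unlist(lapply(c("x", "y", "z"), function(ax) {
        f <- ts_feature_catalogue(s$acc[, match(ax, c("x", "y", "z"))], s$sample_rate)
        names(f) <- paste0(ax, "__", names(f))
        f
      }))
    }
  }
  rows <- lapply(sessions, feat_one)
  M <- do.call(rbind, rows)
  rownames(M) <- vapply(sessions, `[[`, "", "session_id")
  attr(M, "representation") <- mode
  M
}

#' Statistical relevance filter for a feature matrix
#'
#' Per-feature two-sample test of association with the binary label:
#' Mann-Whitney U (normal approximation) for real-valued features, Fisher's
#' exact test for binary features. Constant columns are removed before
#' testing. P-values are adjusted by Benjamini-Hochberg and columns with
#' adjusted p <= `fdr_level` are retained. Applied inside each training fold
#' (never on pooled data) by the model-selection harness to avoid selection
#' leakage.
#'
#' @param X Feature matrix (rows = sessions).
#' @param labels Binary label vector matching the rows.
#' @param fdr_level False-discovery-rate level (default 0.05).
#' @return The filtered matrix, with attributes `retained` (column names) and
#'   `p_adjusted` (named adjusted p-values of all tested columns).
#' @export
fresh_relevance_filter <- function(X, labels, fdr_level = 0.05) {
  if (length(unique(labels)) < 2L)
    stop("single-class labels: relevance filtering undefined")
  if (nrow(X) != length(labels))
    stop("matrix rows must match label vector")
  keep <- apply(X, 2L, function(col) length(unique(col)) > 1L)
  Xt <- X[, keep, drop = FALSE]
  g1 <- labels == sort(unique(labels))[2L]
  pvals <- vapply(seq_len(ncol(Xt)), function(j) {
    col <- Xt[, j]
    if (length(unique(col)) == 2L) {
      stats::fisher.test(table(col, g1))$p.value
    } else {
      stats::wilcox.test(col[g1], col[!g1], exact = FALSE)$p.value
    }
  }, numeric(1L))
  names(pvals) <- colnames(Xt)
  padj <- stats::p.adjust(pvals, method = "BH")
  sel <- names(padj)[padj <= fdr_level]
  out <- X[, sel, drop = FALSE]
  attr(out, "representation") <- attr(X, "representation")
  attr(out, "retained") <- sel
  attr(out, "p_adjusted") <- padj
  out
}
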