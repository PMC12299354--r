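# Fixture builders and independent oracles shared across tests.

# Sine session oscillating along a 3-D direction `dir`; with freq 2.5 Hz at
# 50 Hz sampling and a half-sample phase offset the samples are exactly
# symmetric under sign flip (half-period = 10 samples), which pins down the
# PC-sign-convention-sensitive features.
sine_session <- function(n = 600, fs = 50, freq = 2.5, amp = 1,
                         dir = c(1, 0, 0), phase = pi * freq / fs,
                         id = "sine", label = 0) {
  t <- (seq_len(n) - 1) / fs
  s <- amp * sin(2 * pi * freq * t + phase)
  acc <- outer(s, dir / sqrt(sum(dir^2)))
  colnames(acc) <- c("x", "y", "z")
  accel_session(id, "subj", "fixture", "UPDRS_3_6", t, acc, label)
}

# uniformly random rotation matrix (QR of a Gaussian matrix, det +1)
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

rotate_session <- function(session, Q) {
  session$acc <- session$acc %*% t(Q)
  colnames(session$acc) <- c("x", "y", "z")
  session
}

# --- independent metric oracles (brute force / closed form) -----------------

oracle_macro_f1 <- function(y_true, y_pred) {
  per_class <- function(cl) {
    tp <- 0; fp <- 0; fn <- 0
    for (i in seq_along(y_true)) {
      if (y_pred[i] == cl && y_true[i] == cl) tp <- tp + 1
      if (y_pred[i] == cl && y_true[i] != cl) fp <- fp + 1
      if (y_pred[i] != cl && y_true[i] == cl) fn <- fn + 1
    }
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
    if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  }
  (per_class(0) + per_class(1)) / 2
}

oracle_confusion <- function(y_true, y_pred) {
  m <- matrix(0L, 2, 2)
  for (i in seq_along(y_true))
    m[y_true[i] + 1, y_pred[i] + 1] <- m[y_true[i] + 1, y_pred[i] + 1] + 1L
  m
}

# textbook Welch t with Welch-Satterthwaite df
oracle_welch <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- sum((a - mean(a))^2) / (na - 1)
  vb <- sum((b - mean(b))^2) / (nb - 1)
  se2 <- va / na + vb / nb
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(statistic = t, df = df, p_value = 2 * stats::pt(-abs(t), df))
}

# small synthetic feature problem with a known separating structure
separable_features <- function(n = 80, p = 6, shift = 4, seed = 1) {
  set.seed(seed)
  y <- rep(c(0L, 1L), length.out = n)
  X <- matrix(stats::rnorm(n * p), n, p)
  X[, 1] <- X[, 1] + shift * y
  colnames(X) <- paste0("f", seq_len(p))
  rownames(X) <- paste0("s", seq_len(n))
  list(X = X, y = y)
}
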