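#' Stratified k-fold assignment
#'
#' Shuffles each class independently (seeded) and deals its members to folds
#' round-robin, so per-fold class proportions stay within one sample of the
#' global proportions. If the minority class has fewer than `k` members, `k`
#' is reduced to the minority count with a warning.
#'
#' @param labels Binary label vector.
#' @param k Number of folds (default 10).
#' @param seed Integer seed; the assignment is deterministic given it.
#' @return Integer vector of fold ids (1..k) per observation, with attribute
#'   `k` (the fold count actually used).
#' @export
stratified_folds <- function(labels, k = 10L, seed = 1L) {
  classes <- unique(labels)
  if (length(classes) < 2L)
    stop("single-class labels: stratified folds undefined")
  min_count <- min(table(labels))
  if (min_count < k) {
    warning("minority class has ", min_count, " members; reducing k from ",
            k, " to ", min_count)
    k <- as.integer(min_count)
  }
  folds <- integer(length(labels))
  rng <- local_rng(seed)
  for (cl in sort(classes)) {
    idx <- which(labels == cl)
    idx <- idx[rng$sample_perm(length(idx))]
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  attr(folds, "k") <- k
  folds
}

# Self-contained RNG scope: evaluates seeded draws without disturbing the
# caller's global RNG state.
local_rng <- function(seed) {
  env <- new.env()
  run <- function(expr_fun) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    if (!is.null(env$state)) assign(".Random.seed", env$state, envir = globalenv())
    else set.seed(seed)
    res <- expr_fun()
    env$state <- get(".Random.seed", globalenv())
    res
  }
  list(
    sample_perm = function(n) run(function() sample.int(n)),
    runif = function(n, min = 0, max = 1) run(function() stats::runif(n, min, max)),
    rnorm = function(n, mean = 0, sd = 1) run(function() stats::rnorm(n, mean, sd)),
    sample_int = function(n, size, replace = FALSE)
      run(function() sample.int(n, size, replace = replace))
  )
}

#' SMOTE oversampling of the minority class
#'
#' Synthetic minority rows are convex combinations `m + u * (nb - m)` of a
#' minority row `m`, one of its `k_neighbors` nearest minority neighbours `nb`
#' (Euclidean), and `u` uniform on [0, 1]. Originals are preserved and classes
#' are exactly balanced on output. Applied to training folds only by the
#' harness.
#'
#' @param X Numeric feature matrix.
#' @param y Binary label vector.
#' @param k_neighbors Neighbourhood size (clipped to minority size - 1).
#' @param seed Integer seed; synthetic rows are deterministic given it.
#' @return List `(X, y)` with balanced classes.
#' @export
smote_oversample <- function(X, y, k_neighbors = 5L, seed = 1L) {
  tab <- table(y)
  if (length(tab) < 2L) stop("single-class labels: nothing to balance")
  min_class <- as.numeric(names(tab)[which.min(tab)])
  n_min <- min(tab); n_maj <- max(tab)
  if (n_min < 2L) stop("cannot interpolate: minority class has a single member")
  n_new <- n_maj - n_min
  if (n_new == 0L) return(list(X = X, y = y))
  k_neighbors <- min(k_neighbors, n_min - 1L)
  Xm <- X[y == min_class, , drop = FALSE]
  D <- as.matrix(stats::dist(Xm))
  diag(D) <- Inf
  nn_idx <- apply(D, 1L, function(d) order(d)[seq_len(k_neighbors)])
  nn_idx <- matrix(nn_idx, nrow = k_neighbors)  # k x n_min

  rng <- local_rng(seed)
  base <- rng$sample_int(n_min, n_new, replace = TRUE)
  pick <- rng$sample_int(k_neighbors, n_new, replace = TRUE)
  u <- rng$runif(n_new)
  synth <- Xm[base, , drop = FALSE] +
    u * (Xm[nn_idx[cbind(pick, base)], , drop = FALSE] - Xm[base, , drop = FALSE])
  list(X = rbind(X, synth), y = c(y, rep(min_class, n_new)))
}

#' ANOVA-F top-k feature selection
#'
#' Ranks columns by the one-way ANOVA F statistic of the binary grouping
#' (computed on the training fold only) and keeps the top `k`. Zero-variance
#' columns score 0; ties break deterministically by column name.
#'
#' @param X Feature matrix with column names.
#' @param y Binary labels.
#' @param k Number of columns to keep, or `"none"`/`NULL` to keep all.
#' @return Character vector of selected column names, in name order.
#' @export
select_k_best <- function(X, y, k) {
  if (is.null(k) || identical(k, "none")) return(colnames(X))
  k <- min(as.integer(k), ncol(X))
  scores <- anova_f_scores(X, y)
  ord <- order(-scores, colnames(X))
  sort(colnames(X)[ord[seq_len(k)]])
}

anova_f_scores <- function(X, y) {
  classes <- sort(unique(y))
  n <- nrow(X)
  gm <- colMeans(X)
  ss_between <- 0; ss_within <- 0
  for (cl in classes) {
    Xi <- X[y == cl, , drop = FALSE]
    ni <- nrow(Xi)
    mi <- colMeans(Xi)
    ss_between <- ss_between + ni * (mi - gm)^2
    ss_within <- ss_within + colSums(sweep(Xi, 2L, mi)^2)
  }
  df1 <- length(classes) - 1L
  df2 <- n - length(classes)
  f <- (ss_between / df1) / (ss_within / df2)
  # zero within-class variance with real between-class spread is perfect
  # separation (F = Inf, ranked first); an all-constant column is 0/0 -> 0
  f[is.nan(f)] <- 0
  f
}

# Median imputation: medians learned on the training rows only.
fit_imputer <- function(X) apply(X, 2L, stats::median, na.rm = TRUE)

apply_imputer <- function(X, med) {
  for (j in seq_len(ncol(X))) {
    nas <- is.na(X[, j])
    if (any(nas)) X[nas, j] <- med[j]
  }
  X
}

# Z-score standardisation fit on the training rows (sd 0 -> 1).
fit_scaler <- function(X) {
  s <- apply(X, 2L, stats::sd)
  s[s == 0 | !is.finite(s)] <- 1
  list(center = colMeans(X), scale = s)
}

apply_scaler <- function(X, sc)
  sweep(sweep(X, 2L, sc$center), 2L, sc$scale, "/")
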