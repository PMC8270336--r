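# Independent oracles used by the unit tests. These deliberately avoid the
# package's own linear-algebra paths (no quad_model_matrix etc.) so that a
# bug there cannot hide in both routes.

# Term-by-term evaluation of the 15-coefficient quadratic at a coded point,
# written out longhand.
poly_eval_oracle <- function(beta, x) {
  stopifnot(length(beta) == 15L, length(x) == 4L)
  beta[1] +
    beta[2] * x[1] + beta[3] * x[2] + beta[4] * x[3] + beta[5] * x[4] +
    beta[6] * x[1] * x[2] + beta[7] * x[1] * x[3] + beta[8] * x[1] * x[4] +
    beta[9] * x[2] * x[3] + beta[10] * x[2] * x[4] + beta[11] * x[3] * x[4] +
    beta[12] * x[1]^2 + beta[13] * x[2]^2 + beta[14] * x[3]^2 + beta[15] * x[4]^2
}

# Exhaustive enumeration of every (feature, midpoint-cut) split, returning
# the best achievable SSE decrease. Brute force; use on <= 10 rows.
best_split_oracle <- function(X, y, min_leaf = 1L) {
  n <- length(y)
  parent <- sum((y - mean(y))^2)
  best <- 0
  for (j in seq_len(ncol(X))) {
    ux <- sort(unique(X[, j]))
    if (length(ux) < 2L) next
    for (cut in (ux[-1] + ux[-length(ux)]) / 2) {
      left <- X[, j] <= cut
      if (sum(left) < min_leaf || sum(!left) < min_leaf) next
      sse <- sum((y[left] - mean(y[left]))^2) +
        sum((y[!left] - mean(y[!left]))^2)
      best <- max(best, parent - sse)
    }
  }
  best
}

# Dense grid search over the coded cube: the oracle for every optimizer.
# Evaluates in chunks to bound memory.
grid_max_oracle <- function(predict_fn, n_per_dim = 21L) {
  g <- seq(-1, 1, length.out = n_per_dim)
  best <- -Inf
  # chunk over the first two dimensions
  for (a in g) for (b in g) {
    pts <- as.matrix(expand.grid(a, b, g, g))
    best <- max(best, max(predict_fn(pts)))
  }
  best
}

# OLS slope/intercept via the textbook closed form (no lm()).
ols_line_oracle <- function(x, y) {
  sx <- sum(x); sy <- sum(y); n <- length(x)
  slope <- (n * sum(x * y) - sx * sy) / (n * sum(x^2) - sx^2)
  c(slope = slope, intercept = (sy - slope * sx) / n)
}

fixture_design <- function() rosa_design()
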