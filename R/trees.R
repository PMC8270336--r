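# CART regression-tree primitive shared by the random-forest and
# gradient-boosting rankers. Deliberately small: axis-aligned binary splits
# minimizing residual sum of squares, depth/leaf-size limits, optional
# per-node feature subsampling. Deterministic given data, config and the
# caller's RNG state.

best_split <- function(X, y, features, min_leaf) {
  n <- length(y)
  parent_sse <- sum((y - mean(y))^2)
  best <- NULL
  for (j in features) {
    xv <- X[, j]
    ux <- sort(unique(xv))
    if (length(ux) < 2L) next
    cuts <- (ux[-1] + ux[-length(ux)]) / 2
    for (cut in cuts) {
      left <- xv <= cut
      nl <- sum(left)
      if (nl < min_leaf || n - nl < min_leaf) next
      yl <- y[left]; yr <- y[!left]
      sse <- sum((yl - mean(yl))^2) + sum((yr - mean(yr))^2)
      dec <- parent_sse - sse
      if (is.null(best) || dec > best$decrease + 1e-12) {
        best <- list(feature = j, cut = cut, decrease = dec)
      }
    }
  }
  if (!is.null(best) && best$decrease <= 1e-12) best <- NULL
  best
}

grow_tree <- function(X, y, depth, max_depth, min_leaf, mtry, importance_env) {
  n <- length(y)
  if (depth >= max_depth || n < 2L * min_leaf || var(y) == 0 || is.na(var(y)))
    return(list(leaf = TRUE, value = mean(y)))
  features <- if (mtry < ncol(X)) sort(sample.int(ncol(X), mtry)) else seq_len(ncol(X))
  sp <- best_split(X, y, features, min_leaf)
  if (is.null(sp)) return(list(leaf = TRUE, value = mean(y)))
  importance_env$imp[sp$feature] <- importance_env$imp[sp$feature] + sp$decrease
  left <- X[, sp$feature] <= sp$cut
  list(leaf = FALSE, feature = sp$feature, cut = sp$cut,
       left = grow_tree(X[left, , drop = FALSE], y[left], depth + 1L,
                        max_depth, min_leaf, mtry, importance_env),
       right = grow_tree(X[!left, , drop = FALSE], y[!left], depth + 1L,
                         max_depth, min_leaf, mtry, importance_env))
}

#' Fit a CART regression tree
#'
#' Axis-aligned binary splits chosen to maximize the decrease in residual
#' sum of squares, with candidate cuts at midpoints between consecutive
#' observed values. A split is only accepted if it strictly decreases the
#' SSE and respects the minimum leaf size; ties favour the lowest feature
#' index and smallest cut (first encountered).
#'
#' @param X Numeric feature matrix.
#' @param y Numeric response.
#' @param max_depth Maximum tree depth (0 = a single leaf predicting the
#'   mean).
#' @param min_leaf Minimum observations per leaf.
#' @param mtry Number of features sampled per node (uses the current RNG
#'   stream when smaller than `ncol(X)`).
#' @return A `cart_tree`: nested split/leaf nodes plus a per-feature
#'   `importance` vector of accumulated SSE decreases.
#' @export
fit_cart <- function(X, y, max_depth = 3L, min_leaf = 2L, mtry = ncol(X)) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), max_depth >= 0L, min_leaf >= 1L)
  env <- new.env()
  env$imp <- numeric(ncol(X))
  root <- grow_tree(X, y, 0L, max_depth, min_leaf, mtry, env)
  structure(list(root = root, importance = env$imp,
                 n_features = ncol(X)), class = "cart_tree")
}

predict_node <- function(node, x) {
  while (!node$leaf) {
    node <- if (x[node$feature] <= node$cut) node$left else node$right
  }
  node$value
}

#' @export
predict.cart_tree <- function(object, X, ...) {
  X <- as.matrix(X)
  apply(X, 1L, function(x) predict_node(object$root, x))
}
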