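# Four routes to ranking the extraction factors: Garson weight
# decomposition of the neural surrogate, the ANOVA linear-term F test, and
# impurity-based importances from in-package random-forest and
# gradient-boosted-tree ensembles.

new_importance_result <- function(method, scores, factor_names) {
  ranks <- rank(-scores, ties.method = "first")  # ties broken by factor order
  structure(list(method = method,
                 scores = stats::setNames(as.numeric(scores), factor_names),
                 ranks = stats::setNames(as.integer(ranks), factor_names)),
            class = "importance_result")
}

#' @export
print.importance_result <- function(x, ...) {
  cat(sprintf("factor importance (%s):\n", x$method))
  print(data.frame(score = round(x$scores, 3), rank = x$ranks))
  invisible(x)
}

#' Garson weight-decomposition importance of a neural surrogate
#'
#' Each hidden unit's output weight magnitude is apportioned to the inputs
#' in proportion to their absolute input-weight shares at that unit; the
#' per-input totals are normalized to percentage contributions summing to
#' 100. A hidden unit whose input weights are all zero contributes nothing
#' (no division by zero).
#'
#' @param model An `ann_model` with a single hidden layer.
#' @return An `importance_result` with `method = "garson"`; scores are
#'   percentage shares.
#' @examples
#' garson(rosa_ann())$ranks  # material-liquid ratio ranks first
#' @export
garson <- function(model) {
  stopifnot(inherits(model, "ann_model"))
  W <- abs(model$input_weights)            # hidden x 4
  v <- abs(model$layer_weights)            # hidden
  rs <- rowSums(W)
  ok <- rs > 0
  Q <- W[ok, , drop = FALSE] / rs[ok]      # share of each input at the unit
  contrib <- drop(crossprod(Q, v[ok]))
  total <- sum(contrib)
  shares <- if (total > 0) contrib / total * 100 else rep(25, 4)
  nb <- model$norm_bounds
  new_importance_result("garson", shares, nb$var[nb$var != "response"])
}

#' Rank factors by their ANOVA linear-term F statistics
#'
#' @param anova An `anova_table` from [rsm_anova()].
#' @return An `importance_result` with `method = "f_test"`; scores are the
#'   linear-term F values. Ties are broken by factor order.
#' @export
f_test_rank <- function(anova) {
  stopifnot(inherits(anova, "anova_table"))
  lin <- anova[anova$term %in% LETTERS[1:4], ]
  lin <- lin[match(LETTERS[1:4], lin$term), ]
  nm <- sub("^[A-D]-", "", lin$source)
  new_importance_result("f_test", lin$F, nm)
}

#' Tree-ensemble configurations for factor ranking
#'
#' Defaults: the forest uses 500 bootstrapped depth-3 trees with 2 of the
#' 4 features sampled per node; the boosted ensemble uses 200 depth-2
#' rounds at learning rate 0.1 on all features, no bootstrap.
#'
#' @param n_trees Number of trees / boosting rounds.
#' @param max_depth,min_leaf Tree shape limits.
#' @param mtry Features sampled per node.
#' @param bootstrap Bootstrap-resample rows per tree.
#' @param learning_rate Shrinkage (boosting only), in (0, 1].
#' @param seed RNG seed for resampling/feature subsampling.
#' @return A config list.
#' @export
rf_config <- function(n_trees = 500L, max_depth = 3L, min_leaf = 2L,
                      mtry = 2L, bootstrap = TRUE, seed = 1L) {
  stopifnot(n_trees >= 1L)
  list(n_trees = as.integer(n_trees), max_depth = as.integer(max_depth),
       min_leaf = as.integer(min_leaf), mtry = as.integer(mtry),
       bootstrap = isTRUE(bootstrap), seed = seed)
}

#' @rdname rf_config
#' @export
gbrt_config <- function(n_trees = 200L, max_depth = 2L, min_leaf = 2L,
                        learning_rate = 0.1, seed = 1L) {
  stopifnot(n_trees >= 0L)
  if (!(learning_rate > 0 && learning_rate <= 1))
    flav_stop("learning_rate must lie in (0, 1]", "flav_config_error")
  list(n_trees = as.integer(n_trees), max_depth = as.integer(max_depth),
       min_leaf = as.integer(min_leaf), learning_rate = learning_rate,
       seed = seed)
}

design_xy <- function(design) {
  keep <- !is.na(design$response)
  list(X = design$coded[keep, , drop = FALSE], y = design$response[keep],
       names = colnames(design$coded))
}

#' Random-forest factor importance
#'
#' Bootstrap-aggregated CART regression trees with per-node feature
#' subsampling; importance is each feature's mean impurity (SSE) decrease
#' across trees, normalized to sum to 100.
#'
#' @param design A `design_table` with responses.
#' @param config An [rf_config()].
#' @return An `importance_result` with `method = "rf"`.
#' @export
rf_importance <- function(design, config = rf_config()) {
  d <- design_xy(design)
  n <- length(d$y)
  imp <- with_seed(config$seed, {
    acc <- numeric(ncol(d$X))
    for (b in seq_len(config$n_trees)) {
      rows <- if (config$bootstrap) sample.int(n, n, replace = TRUE) else seq_len(n)
      tree <- fit_cart(d$X[rows, , drop = FALSE], d$y[rows],
                       max_depth = config$max_depth,
                       min_leaf = config$min_leaf, mtry = config$mtry)
      acc <- acc + tree$importance
    }
    acc / config$n_trees
  })
  total <- sum(imp)
  scores <- if (total > 0) imp / total * 100 else rep(25, 4)
  new_importance_result("rf", scores, d$names)
}

#' Gradient-boosted-tree factor importance
#'
#' Forward-stagewise boosting on squared loss: each round fits a shallow
#' CART tree to the current residuals and adds `learning_rate` times its
#' prediction. Importance is the per-feature impurity decrease summed over
#' rounds, normalized to 100. With squared loss and shrinkage in (0, 1]
#' the training loss is non-increasing in rounds.
#'
#' @param design A `design_table` with responses.
#' @param config A [gbrt_config()].
#' @return An `importance_result` with `method = "gbrt"`; also carries the
#'   per-round training loss as attribute `loss`.
#' @export
gbrt_importance <- function(design, config = gbrt_config()) {
  d <- design_xy(design)
  res <- with_seed(config$seed, {
    pred <- rep(mean(d$y), length(d$y))
    acc <- numeric(ncol(d$X))
    loss <- numeric(config$n_trees)
    for (m in seq_len(config$n_trees)) {
      r <- d$y - pred
      tree <- fit_cart(d$X, r, max_depth = config$max_depth,
                       min_leaf = config$min_leaf)
      pred <- pred + config$learning_rate * predict(tree, d$X)
      acc <- acc + tree$importance
      loss[m] <- mean((d$y - pred)^2)
    }
    list(acc = acc, loss = loss)
  })
  total <- sum(res$acc)
  scores <- if (total > 0) res$acc / total * 100 else rep(25, 4)
  out <- new_importance_result("gbrt", scores, d$names)
  attr(out, "loss") <- res$loss
  out
}

#' Assemble importance results into a methods-by-factors rank matrix
#'
#' @param results List of `importance_result`s (any subset of methods).
#' @return Integer matrix, one row per method (named by its tag), one
#'   column per factor; entry 1 marks the most important factor.
#' @export
rank_table <- function(results) {
  stopifnot(length(results) >= 1L,
            all(vapply(results, inherits, TRUE, "importance_result")))
  nm <- names(results[[1]]$ranks)
  mat <- do.call(rbind, lapply(results, function(r) {
    if (!identical(names(r$ranks), nm))
      flav_stop("importance results rank different factor sets",
                "flav_config_error")
    r$ranks
  }))
  rownames(mat) <- unname(vapply(results, function(r) r$method, ""))
  mat
}
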