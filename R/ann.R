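# Single-hidden-layer feed-forward surrogate: 4 inputs -> n tansig hidden
# units -> 1 linear output, with min-max normalization of every variable
# (inputs and response) onto [-1, 1].

#' Min-max normalization onto a symmetric target range
#'
#' `2*(x - xmin)/(xmax - xmin) - 1` for the default range; an optional
#' `range` argument supports other affine targets (e.g. `c(0.1, 0.9)`).
#' `ann_denormalize()` is the exact inverse.
#'
#' @param x Numeric vector.
#' @param xmin,xmax Variable bounds; `xmax` must exceed `xmin`.
#' @param range Length-2 target interval, default `c(-1, 1)`.
#' @return Normalized (resp. de-normalized) values.
#' @export
ann_normalize <- function(x, xmin, xmax, range = c(-1, 1)) {
  if (!(xmax > xmin))
    flav_stop("degenerate normalization range: xmax must exceed xmin",
              "flav_config_error")
  range[1] + (x - xmin) / (xmax - xmin) * (range[2] - range[1])
}

#' @rdname ann_normalize
#' @export
ann_denormalize <- function(x, xmin, xmax, range = c(-1, 1)) {
  if (!(xmax > xmin))
    flav_stop("degenerate normalization range: xmax must exceed xmin",
              "flav_config_error")
  xmin + (x - range[1]) / (range[2] - range[1]) * (xmax - xmin)
}

#' Hyperbolic-tangent sigmoid transfer function
#'
#' `2/(1 + exp(-2x)) - 1`, identical to `tanh(x)`; the hidden-layer
#' transfer function of the surrogate. The output layer is linear.
#'
#' @param x Numeric.
#' @return Values in (-1, 1).
#' @export
tansig <- function(x) 2 / (1 + exp(-2 * x)) - 1

#' Construct a feed-forward surrogate from explicit weights
#'
#' @param input_weights hidden x 4 matrix of input-to-hidden weights.
#' @param input_bias Hidden-layer bias vector.
#' @param layer_weights Hidden-to-output weight vector.
#' @param layer_bias Output bias (scalar).
#' @param norm_bounds data.frame with columns `var`, `min`, `max` covering
#'   the four inputs (in design order) and the response (`var = "response"`).
#' @return An `ann_model`.
#' @export
ann_model <- function(input_weights, input_bias, layer_weights, layer_bias,
                      norm_bounds) {
  input_weights <- as.matrix(input_weights)
  h <- nrow(input_weights)
  if (ncol(input_weights) != 4L)
    flav_stop("input_weights must have 4 columns", "flav_shape_error")
  if (length(input_bias) != h || length(layer_weights) != h ||
      length(layer_bias) != 1L)
    flav_stop("inconsistent layer dimensions", "flav_shape_error")
  stopifnot(is.data.frame(norm_bounds),
            all(c("var", "min", "max") %in% names(norm_bounds)))
  if (nrow(norm_bounds) != 5L || !"response" %in% norm_bounds$var)
    flav_stop("norm_bounds must cover 4 inputs plus the response",
              "flav_shape_error")
  if (any(norm_bounds$max <= norm_bounds$min))
    flav_stop("norm_bounds need max > min for every variable",
              "flav_config_error")
  structure(list(
    input_weights = unname(input_weights),
    input_bias = as.numeric(input_bias),
    layer_weights = as.numeric(layer_weights),
    layer_bias = as.numeric(layer_bias),
    hidden_size = h,
    norm_bounds = norm_bounds
  ), class = "ann_model")
}

#' @export
print.ann_model <- function(x, ...) {
  cat(sprintf("feed-forward surrogate: 4 -> %d (tansig) -> 1 (linear)\n",
              x$hidden_size))
  invisible(x)
}

norm_bounds_from <- function(factors, response_range) {
  data.frame(
    var = c(vapply(factors, function(f) f$name, ""), "response"),
    min = c(vapply(factors, function(f) f$low, 0), response_range[1]),
    max = c(vapply(factors, function(f) f$high, 0), response_range[2]),
    stringsAsFactors = FALSE
  )
}

#' Evaluate the surrogate at natural-unit operating points
#'
#' Inputs are min-max normalized to [-1,1], passed through the tansig
#' hidden layer and linear output, and the output is de-normalized back to
#' response units. Points outside the normalization bounds are evaluated
#' anyway and flagged via an `extrapolated` attribute.
#'
#' @param model An `ann_model`.
#' @param natural Length-4 vector or matrix (rows = points) of natural
#'   factor settings, in design order.
#' @return Predicted response(s) (%).
#' @export
ann_forward <- function(model, natural) {
  stopifnot(inherits(model, "ann_model"))
  if (!is.matrix(natural)) natural <- matrix(natural, nrow = 1L)
  if (ncol(natural) != 4L)
    flav_stop("expected 4 input columns", "flav_shape_error")
  nb <- model$norm_bounds
  xb <- nb[nb$var != "response", ]
  yb <- nb[nb$var == "response", ]
  K <- vapply(1:4, function(j)
    ann_normalize(natural[, j], xb$min[j], xb$max[j]), numeric(nrow(natural)))
  if (!is.matrix(K)) K <- matrix(K, nrow = 1L)
  H <- tansig(K %*% t(model$input_weights) +
                matrix(model$input_bias, nrow(K), model$hidden_size, byrow = TRUE))
  y_norm <- drop(H %*% model$layer_weights) + model$layer_bias
  out <- ann_denormalize(y_norm, yb$min, yb$max)
  if (any(natural < matrix(xb$min, nrow(natural), 4, byrow = TRUE) - 1e-12) ||
      any(natural > matrix(xb$max, nrow(natural), 4, byrow = TRUE) + 1e-12))
    attr(out, "extrapolated") <- TRUE
  out
}

# ---- training ---------------------------------------------------------

# Nguyen-Widrow initialization: hidden-unit weight vectors scaled to
# magnitude 0.7 * h^(1/4) with biases spreading the active regions across
# the [-1,1] input cube. Markedly better-conditioned than plain uniform
# draws for tansig layers.
init_weights <- function(h) {
  W <- matrix(stats::runif(h * 4, -1, 1), h, 4)
  norms <- sqrt(rowSums(W^2))
  scale <- 0.7 * h^(1 / 4)
  W <- W * scale / norms
  b1 <- scale * stats::runif(h, -1, 1)
  list(W = W, b1 = b1,
       v = stats::runif(h, -0.5, 0.5),
       b2 = stats::runif(1, -0.5, 0.5))
}

# Full-batch gradient descent with momentum and a bold-driver step size:
# a step is accepted only if it does not increase the (optionally
# L2-penalized) training objective, else the step size is halved and the
# step retried. Deterministic given the initial weights. Weight decay
# keeps connection weights small so Garson attributions reflect the
# fitted function rather than noise-interpolating weight patterns.
train_net <- function(K, t, h, epochs, lr, momentum, decay = 0) {
  w <- init_weights(h)
  mom <- lapply(w, function(x) x * 0)
  n <- nrow(K)
  mse <- function(w) {
    H <- tansig(K %*% t(w$W) + matrix(w$b1, n, h, byrow = TRUE))
    mean((drop(H %*% w$v) + w$b2 - t)^2) +
      decay * (sum(w$W^2) + sum(w$v^2))
  }
  cur <- mse(w)
  trace <- numeric(epochs)
  for (it in seq_len(epochs)) {
    H <- tansig(K %*% t(w$W) + matrix(w$b1, n, h, byrow = TRUE))
    e <- drop(H %*% w$v) + w$b2 - t              # n
    g_v <- drop(crossprod(H, e)) * (2 / n) + 2 * decay * w$v
    g_b2 <- 2 * mean(e)
    D <- (e %o% w$v) * (1 - H^2)                 # n x h
    g_W <- crossprod(D, K) * (2 / n) + 2 * decay * w$W
    g_b1 <- colSums(D) * (2 / n)
    grad <- list(W = g_W, b1 = g_b1, v = g_v, b2 = g_b2)
    repeat {
      step <- Map(function(m, g) momentum * m - lr * g, mom, grad)
      cand <- Map(`+`, w, step)
      new <- mse(cand)
      if (!is.finite(new))
        flav_stop("training diverged (non-finite loss); try a smaller step size",
                  "flav_fit_error")
      if (new <= cur || lr < 1e-12) break
      lr <- lr / 2
      mom <- lapply(mom, function(x) x * 0)
    }
    if (new <= cur) {
      w <- cand; mom <- step; cur <- new
      lr <- lr * 1.05
    }
    trace[it] <- cur
  }
  list(w = w, mse = cur, trace = trace)
}

#' Train the feed-forward surrogate on a designed dataset
#'
#' Full-batch backpropagation (gradient descent with momentum and a
#' monotone step-acceptance rule) of the mean squared error on normalized
#' variables, with seeded random restarts. Candidate hidden-layer sizes are
#' compared on held-out test MSE and the best is returned. By the
#' published convention the first 80% of rows train and the remainder
#' test; set `shuffle = TRUE` to split at random (still seeded).
#'
#' @param design A `design_table` with complete responses.
#' @param hidden_candidates Integer vector of hidden-layer sizes to try
#'   (default 10, the published network size).
#' @param split Training fraction (default 0.8).
#' @param seed Master seed; all initialization randomness derives from it.
#' @param epochs,lr,momentum,restarts Optimizer settings.
#' @param weight_decay L2 penalty on connection weights (not biases);
#'   0 disables. Regularized nets give stabler Garson attributions.
#' @param shuffle Randomize the train/test split instead of taking the
#'   first rows.
#' @return List with `model` (an `ann_model`) and `report` (per-candidate
#'   train/test MSE, selected size, seed, epochs).
#' @export
ann_train <- function(design, hidden_candidates = 10L, split = 0.8,
                      seed = 1L, epochs = 1500L, lr = 0.05,
                      momentum = 0.9, restarts = 3L, shuffle = FALSE,
                      weight_decay = 0) {
  stopifnot(inherits(design, "design_table"))
  keep <- which(!is.na(design$response))
  n <- length(keep)
  n_train <- floor(split * n)
  if (n - n_train < 2L)
    flav_stop("need at least 2 test rows", "flav_config_error")
  ord <- if (shuffle) with_seed(split_seed(seed, 99L), sample(n)) else seq_len(n)
  idx <- keep[ord]
  tr <- idx[seq_len(n_train)]
  te <- idx[(n_train + 1L):n]

  nb <- norm_bounds_from(design$factors,
                         range(design$response[tr]))
  K_all <- vapply(1:4, function(j)
    ann_normalize(design$natural[, j], nb$min[j], nb$max[j]),
    numeric(nrow(design$natural)))
  t_all <- ann_normalize(design$response, nb$min[5], nb$max[5])

  rows <- list(); best <- NULL
  for (h in hidden_candidates) {
    fit_h <- NULL
    for (r in seq_len(restarts)) {
      fit <- with_seed(split_seed(seed, h * 131L + r),
                       train_net(K_all[tr, , drop = FALSE], t_all[tr],
                                 h, epochs, lr, momentum,
                                 decay = weight_decay))
      if (is.null(fit_h) || fit$mse < fit_h$mse) fit_h <- fit
    }
    w <- fit_h$w
    model_h <- ann_model(w$W, w$b1, w$v, w$b2, nb)
    pred_te <- ann_forward(model_h, design$natural[te, , drop = FALSE])
    test_mse <- mean((pred_te - design$response[te])^2)
    rows[[length(rows) + 1L]] <- data.frame(
      hidden = h, train_mse = fit_h$mse, test_mse = test_mse)
    if (is.null(best) || test_mse < best$test_mse)
      best <- list(model = model_h, test_mse = test_mse, hidden = h,
                   trace = fit_h$trace)
  }
  report <- list(candidates = do.call(rbind, rows),
                 selected = best$hidden, seed = seed, epochs = epochs,
                 train_rows = tr, test_rows = te,
                 train_trace = best$trace)
  list(model = best$model, report = report)
}

# ---- weight-table serialization (published layout) --------------------

#' Read / write network weights in the published table layout
#'
#' One row per hidden neuron: the four input weights (design order), the
#' input bias, the hidden-to-output layer weight; the scalar layer bias
#' sits in the first row only. `save_ann_weights()` followed by
#' `load_ann_weights()` is an identity on the weights.
#'
#' @param path CSV file in that layout.
#' @param norm_bounds Normalization bounds to attach; defaults to the
#'   published factor levels and the response range of the packaged 29-run
#'   dataset (the weight table itself carries no bounds).
#' @return `load_ann_weights()` returns an `ann_model`.
#' @export
load_ann_weights <- function(path, norm_bounds = NULL) {
  if (!file.exists(path))
    flav_stop(sprintf("file not found: %s", path), "flav_parse_error")
  lines <- readLines(path, encoding = "UTF-8")
  nfield <- lengths(strsplit(lines, ",", fixed = TRUE))
  ragged <- which(nfield[-1] > nfield[1]) + 1L
  if (length(ragged))
    flav_stop(sprintf("ragged weight table: row %d has extra fields", ragged[1]),
              "flav_parse_error")
  tab <- utils::read.csv(path, fileEncoding = "UTF-8")
  need <- c("time", "ethanol", "ratio", "power", "input_bias", "layer_weight",
            "layer_bias")
  if (!all(need %in% names(tab)))
    flav_stop(sprintf("weight table must have columns: %s",
                      paste(need, collapse = ", ")), "flav_parse_error")
  if (is.null(norm_bounds)) {
    d2 <- rosa_design()
    norm_bounds <- norm_bounds_from(default_factors(), range(d2$response))
  }
  ann_model(as.matrix(tab[, c("time", "ethanol", "ratio", "power")]),
            tab$input_bias, tab$layer_weight, tab$layer_bias[1], norm_bounds)
}

#' @rdname load_ann_weights
#' @param model An `ann_model` to serialize.
#' @export
save_ann_weights <- function(model, path) {
  stopifnot(inherits(model, "ann_model"))
  h <- model$hidden_size
  tab <- data.frame(
    neuron = seq_len(h),
    time = model$input_weights[, 1], ethanol = model$input_weights[, 2],
    ratio = model$input_weights[, 3], power = model$input_weights[, 4],
    input_bias = model$input_bias, layer_weight = model$layer_weights,
    layer_bias = c(model$layer_bias, rep(NA_real_, h - 1L))
  )
  utils::write.csv(tab, path, row.names = FALSE, na = "")
  invisible(path)
}

#' The published trained-network weight table
#'
#' Loads the packaged 10-hidden-neuron weight fixture. Note two oddities of
#' the published table, shipped as printed: the input-bias column is
#' symmetric about zero and several layer weights repeat.
#'
#' @inheritParams load_ann_weights
#' @return An `ann_model` with `hidden_size = 10`.
#' @export
rosa_ann <- function(norm_bounds = NULL) {
  path <- system.file("extdata", "rosa_ann_weights.csv",
                      package = "flavoptim", mustWork = TRUE)
  load_ann_weights(path, norm_bounds)
}
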