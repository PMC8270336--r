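toy_bounds <- function() {
  data.frame(var = c("time", "ethanol", "ratio", "power", "response"),
             min = c(20, 50, 5, 60, 0), max = c(40, 70, 15, 180, 20),
             stringsAsFactors = FALSE)
}

test_that("normalization implements the affine [-1,1] map and its inverse", {
  expect_equal(ann_normalize(3, 3, 7), -1)
  expect_equal(ann_normalize(5, 3, 7), 0)
  expect_equal(ann_normalize(7, 3, 7), 1)
  # optional prose-variant target range
  expect_equal(ann_normalize(3, 3, 7, range = c(0.1, 0.9)), 0.1)
  expect_equal(ann_normalize(7, 3, 7, range = c(0.1, 0.9)), 0.9)
  set.seed(2)
  x <- runif(20, -5, 5)
  expect_equal(ann_denormalize(ann_normalize(x, -5, 5), -5, 5), x)
  expect_error(ann_normalize(1, 2, 2), class = "flav_config_error")
})

test_that("tansig is the hyperbolic tangent", {
  expect_equal(tansig(0), 0)
  expect_equal(tansig(1), 0.761594, tolerance = 1e-6)  # tanh(1), closed form
  x <- seq(-3, 3, by = 0.25)
  expect_equal(tansig(-x), -tansig(x))
  expect_equal(tansig(x), tanh(x), tolerance = 1e-15)
  expect_true(all(abs(tansig(c(-50, 50))) <= 1))
})

test_that("forward pass: zero weights give a constant, hand computation matches", {
  nb <- toy_bounds()
  m0 <- ann_model(matrix(0, 3, 4), rep(0, 3), rep(0, 3), 0.25, nb)
  const <- ann_denormalize(0.25, 0, 20)
  for (x in list(c(20, 50, 5, 60), c(30, 60, 10, 120), c(40, 70, 15, 180)))
    expect_equal(drop(ann_forward(m0, x)), const)
  # single hidden unit, hand-evaluated chain
  m1 <- ann_model(matrix(c(1, 0.5, -0.25, 2), 1, 4), 0.1, 1.5, -0.2, nb)
  x <- c(25, 65, 12, 90)
  k <- c(2 * (25 - 20) / 20 - 1, 2 * (65 - 50) / 20 - 1,
         2 * (12 - 5) / 10 - 1, 2 * (90 - 60) / 120 - 1)
  y_norm <- 1.5 * tanh(sum(c(1, 0.5, -0.25, 2) * k) + 0.1) - 0.2
  expect_equal(drop(ann_forward(m1, x)), 0 + (y_norm + 1) / 2 * 20)
  # dimension mismatch
  expect_error(ann_forward(m1, c(1, 2, 3)), class = "flav_shape_error")
})

test_that("the packaged weight table loads to a 10-unit net with bounded output", {
  m <- rosa_ann()
  expect_identical(m$hidden_size, 10L)
  d <- fixture_design()
  preds <- ann_forward(m, d$natural)
  expect_true(all(is.finite(preds)))
  yr <- range(d$response)
  half <- diff(yr) / 2
  expect_true(all(preds > yr[1] - 50 * half & preds < yr[2] + 50 * half))
})

test_that("weight tables round-trip; ragged rows are rejected with a row index", {
  m <- rosa_ann()
  tmp <- withr::local_tempfile(fileext = ".csv")
  save_ann_weights(m, tmp)
  m2 <- load_ann_weights(tmp, norm_bounds = m$norm_bounds)
  expect_equal(m2$input_weights, m$input_weights)
  expect_equal(m2$input_bias, m$input_bias)
  expect_equal(m2$layer_weights, m$layer_weights)
  expect_equal(m2$layer_bias, m$layer_bias)
  writeLines(c("neuron,time,ethanol,ratio,power,input_bias,layer_weight,layer_bias",
               "1,0,0,0,0,0,1,0", "2,0,0,0,0,0,1,0,99"), tmp)
  err <- expect_error(load_ann_weights(tmp), class = "flav_parse_error")
  expect_match(conditionMessage(err), "row 3")
})

test_that("training represents a noiseless linear response and is deterministic", {
  d <- build_bbd(default_factors(), 5L)
  d$response <- 10 + 2 * d$coded[, 1] - 1 * d$coded[, 3]
  fit <- ann_train(d, hidden_candidates = 2L, seed = 4, epochs = 2500,
                   restarts = 2)
  expect_lt(fit$report$candidates$test_mse, 1e-3)
  # training objective is non-increasing over accepted iterations
  expect_true(all(diff(fit$report$train_trace) <= 1e-12))
  # bit-identical reports under the same seed
  fit2 <- ann_train(d, hidden_candidates = 2L, seed = 4, epochs = 2500,
                    restarts = 2)
  expect_identical(fit$report, fit2$report)
  expect_identical(fit$model, fit2$model)
  # different seed, different initialization path
  fit3 <- ann_train(d, hidden_candidates = 2L, seed = 5, epochs = 100)
  expect_false(identical(fit3$model$input_weights, fit$model$input_weights))
})

test_that("hidden-size selection minimizes test MSE among candidates", {
  d <- gen_bbd_response(noise_sd = 0.3, seed = 9)
  fit <- ann_train(d, hidden_candidates = c(2L, 5L), seed = 9, epochs = 600)
  cand <- fit$report$candidates
  expect_identical(fit$report$selected,
                   cand$hidden[which.min(cand$test_mse)])
})

test_that("perturbing one input of an all-zero-weight net never moves the output", {
  m0 <- ann_model(matrix(0, 4, 4), rep(0, 4), rep(0, 4), 0.1, toy_bounds())
  base <- drop(ann_forward(m0, c(30, 60, 10, 120)))
  set.seed(8)
  for (i in 1:10) {
    x <- c(30, 60, 10, 120)
    j <- sample(4, 1)
    x[j] <- x[j] + runif(1, -5, 5)
    expect_equal(drop(ann_forward(m0, x)), base)
  }
})

test_that("trained surrogate generalizes on seeded synthetic quadratics (aggregate)", {
  # Median held-out R2 over 50 seeded datasets; per-dataset R2 on 6 sparse
  # lattice points is inherently unstable (see methods vignette), so the
  # aggregate is asserted.
  r2s <- vapply(1:50, function(s) {
    d <- gen_bbd_response(noise_sd = 0.3, seed = s)
    fit <- ann_train(d, hidden_candidates = c(4L, 6L, 8L), epochs = 3000,
                     weight_decay = 1e-3, restarts = 2, seed = s,
                     shuffle = TRUE)
    te <- fit$report$test_rows
    pred <- ann_forward(fit$model, d$natural[te, , drop = FALSE])
    y <- d$response[te]
    1 - sum((pred - y)^2) / sum((y - mean(y))^2)
  }, 0)
  expect_gt(median(r2s), 0.8)
})
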