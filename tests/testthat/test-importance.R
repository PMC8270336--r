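toy_nb <- function() {
  data.frame(var = c("time", "ethanol", "ratio", "power", "response"),
             min = c(20, 50, 5, 60, 0), max = c(40, 70, 15, 180, 20),
             stringsAsFactors = FALSE)
}

test_that("Garson shares: symmetry, hand-computed toy, zero-unit safety", {
  # all |w| equal -> 25% each
  m_eq <- ann_model(matrix(1, 6, 4), rep(0, 6), rep(1, 6), 0, toy_nb())
  g <- garson(m_eq)
  expect_equal(unname(g$scores), rep(25, 4))
  expect_equal(sum(g$scores), 100, tolerance = 1e-8)
  # 2 active inputs, 2 hidden units, weights {1,2;3,4}, output {1,1}:
  # unit shares (1/3, 2/3) and (3/7, 4/7); contributions 16/21 and 26/21
  W <- rbind(c(1, 2, 0, 0), c(3, 4, 0, 0))
  m_toy <- ann_model(W, c(0, 0), c(1, 1), 0, toy_nb())
  g_toy <- garson(m_toy)
  expect_equal(unname(g_toy$scores[1:2]),
               c(16 / 42, 26 / 42) * 100, tolerance = 1e-10)
  expect_equal(unname(g_toy$scores[3:4]), c(0, 0))
  expect_identical(unname(g_toy$ranks[2]), 1L)
  # a hidden unit with all-zero input weights contributes nothing
  W2 <- rbind(W, 0)
  m_zero <- ann_model(W2, rep(0, 3), c(1, 1, 5), 0, toy_nb())
  expect_equal(garson(m_zero)$scores, g_toy$scores, tolerance = 1e-10)
})

test_that("Garson shares are invariant to positive rescaling of output weights", {
  m <- rosa_ann()
  g1 <- garson(m)
  m$layer_weights <- m$layer_weights * 7.3
  expect_equal(garson(m)$scores, g1$scores, tolerance = 1e-10)
})

test_that("Garson on the published weights ranks material-liquid ratio first", {
  g <- garson(rosa_ann())
  expect_identical(unname(g$ranks["ratio"]), 1L)
  expect_equal(sum(g$scores), 100, tolerance = 1e-8)
})

test_that("F-test ranking reproduces the published order and is scale invariant", {
  a <- rsm_anova(fit_quadratic(fixture_design()))
  r <- f_test_rank(a)
  expect_identical(unname(r$ranks),
                   c(3L, 4L, 1L, 2L))  # time, ethanol, ratio, power
  # invariant under monotone rescaling of F
  a2 <- a
  a2$F <- a2$F^2 + 1
  expect_identical(f_test_rank(a2)$ranks, r$ranks)
  # exact ties broken by factor order
  a3 <- a
  a3$F[a3$term %in% LETTERS[1:4]] <- 5
  expect_identical(unname(f_test_rank(a3)$ranks), 1:4)
})

test_that("CART: root splits, depth-0 mean, split optimality vs exhaustive oracle", {
  # single perfectly splitting feature
  X <- cbind(a = c(1, 1, 1, 5, 5, 5), b = c(2, 7, 4, 4, 7, 2))
  y <- c(0, 0, 0, 10, 10, 10)
  tr <- fit_cart(X, y, max_depth = 2)
  expect_false(tr$root$leaf)
  expect_identical(tr$root$feature, 1L)
  expect_equal(unname(predict(tr, X)), y)
  # depth 0 predicts the mean
  tr0 <- fit_cart(X, y, max_depth = 0)
  expect_true(tr0$root$leaf)
  expect_equal(unname(predict(tr0, X)), rep(mean(y), 6))
  # chosen first split achieves the exhaustively enumerated best decrease
  set.seed(21)
  for (rep in 1:10) {
    Xr <- matrix(runif(10 * 3), 10, 3)
    yr <- runif(10)
    tr1 <- fit_cart(Xr, yr, max_depth = 1, min_leaf = 1)
    oracle <- best_split_oracle(Xr, yr, min_leaf = 1)
    got <- if (tr1$root$leaf) 0 else sum(tr1$importance)
    expect_equal(got, oracle, tolerance = 1e-10)
  }
  # accepted splits never increase SSE: importances are non-negative
  tr2 <- fit_cart(matrix(runif(40), 10, 4), runif(10), max_depth = 3,
                  min_leaf = 2)
  expect_true(all(tr2$importance >= 0))
})

test_that("random forest ranks the published data and a dominant synthetic factor", {
  d <- fixture_design()
  r <- rf_importance(d, rf_config(seed = 1))
  expect_identical(unname(r$ranks["ratio"]), 1L)
  expect_equal(sum(r$scores), 100, tolerance = 1e-8)
  # determinism
  r2 <- rf_importance(d, rf_config(seed = 1))
  expect_identical(r$scores, r2$scores)
  # dominant factor wins across seeds (scaled: 20 seeds, smaller forest;
  # the 100-seed four-method version runs in the acceptance suite)
  wins <- sum(vapply(1:20, function(s) {
    dd <- gen_dominant_factor(dominant = 2L, seed = s)
    rf_importance(dd, rf_config(n_trees = 100L, seed = s))$ranks[2] == 1L
  }, TRUE))
  expect_gte(wins, 19)
})

test_that("forest importances carry no signal when the response is pure noise", {
  scores <- matrix(0, 10, 4)
  for (s in 1:10) {
    d <- build_bbd(default_factors(), 5L)
    set.seed(1000 + s)
    d$response <- stats::rnorm(29)  # no dependence on factors
    scores[s, ] <- rf_importance(d, rf_config(n_trees = 100L, seed = s))$scores
  }
  # mean importances roughly equal (no factor systematically dominates)
  expect_true(all(abs(colMeans(scores) - 25) < 12))
})

test_that("GBRT: ranking, constant model at zero rounds, monotone training loss", {
  d <- fixture_design()
  r <- gbrt_importance(d, gbrt_config(seed = 1))
  expect_identical(unname(r$ranks["ratio"]), 1L)
  loss <- attr(r, "loss")
  expect_true(all(diff(loss) <= 1e-12))
  # zero rounds: no importance signal, falls back to uniform scores
  r0 <- gbrt_importance(d, gbrt_config(n_trees = 0L, seed = 1))
  expect_equal(unname(r0$scores), rep(25, 4))
})

test_that("rank_table assembles and permutes consistently", {
  d <- fixture_design()
  a <- rsm_anova(fit_quadratic(d))
  res <- list(f_test = f_test_rank(a),
              rf = rf_importance(d, rf_config(n_trees = 50L, seed = 1)))
  rt <- rank_table(res)
  expect_identical(dim(rt), c(2L, 4L))
  expect_identical(rownames(rt), c("f_test", "rf"))
  expect_identical(rank_table(rev(res)), rt[2:1, ])
  expect_identical(rank_table(res["f_test"]),
                   rt[1, , drop = FALSE])
  expect_true(all(rt[, "ratio"] == 1L))
})
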