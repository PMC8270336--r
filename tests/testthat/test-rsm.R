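test_that("quadratic refit of the packaged dataset reproduces the published coefficients", {
  m <- fit_quadratic(fixture_design())
  expect_lt(abs(m$b0 - 10.30), 5e-3)
  expect_lte(abs(abs(m$b_lin[3]) - 1.47), 5e-3 + 1e-12)
  expect_lt(abs(m$b_lin[1] - 0.81), 5e-3)
  expect_lt(abs(m$b_lin[4] - 1.15), 5e-3)
  expect_lt(abs(m$b_quad[3] + 3.50), 5e-3)
})

test_that("OLS recovers a known noiseless quadratic exactly", {
  beta <- c(9, 0.5, -0.3, 1.2, -0.8, 0.2, -0.4, 0.05, 0, 0.7, -0.1,
            -1.1, 0.9, -2.2, 0.3)
  d <- gen_bbd_response(coefficients = beta, noise_sd = 0, seed = 1)
  m <- fit_quadratic(d)
  expect_equal(unname(m$coefficients), beta, tolerance = 1e-10)
})

test_that("linear coefficients equal the orthogonal-contrast formula on a complete BBD", {
  # b_A = (sum of y at A=+1 - sum at A=-1) / 12, a consequence of column
  # orthogonality; checked against the OLS fit on seeded noisy data
  d <- gen_bbd_response(noise_sd = 0.5, seed = 7)
  m <- fit_quadratic(d)
  for (j in 1:4) {
    contrast <- (sum(d$response[d$coded[, j] == 1]) -
                   sum(d$response[d$coded[, j] == -1])) / 12
    expect_equal(m$b_lin[j], contrast, tolerance = 1e-10)
  }
})

test_that("rank-deficient designs fail loudly with the aliased columns named", {
  d <- fixture_design()
  d$coded[, 2] <- d$coded[, 1]  # alias B onto A
  err <- expect_error(fit_quadratic(d), class = "flav_fit_error")
  expect_match(conditionMessage(err), "aliased")
  # too few rows
  d2 <- fixture_design()
  d2$response[1:20] <- NA
  expect_error(fit_quadratic(d2), class = "flav_fit_error")
})

test_that("prediction matches an independent term-by-term evaluator", {
  m <- fit_quadratic(fixture_design())
  expect_equal(drop(predict(m, rep(0, 4))), m$b0)
  set.seed(3)
  for (i in 1:10) {
    x <- runif(4, -1, 1)
    expect_equal(drop(predict(m, x)),
                 poly_eval_oracle(unname(m$coefficients), x),
                 tolerance = 1e-12)
  }
  # extrapolation is flagged, not blocked
  expect_true(isTRUE(attr(predict(m, c(2, 0, 0, 0)), "extrapolated")))
})

test_that("prediction at the published optimum reproduces the published maximum", {
  m <- fit_quadratic(fixture_design())
  pred <- drop(predict(m, code_point(c(40, 50.9, 8.82, 148.87),
                                     default_factors())))
  expect_equal(round(pred, 2), 11.07)
})

test_that("ANOVA reproduces the published table and stays additive", {
  m <- fit_quadratic(fixture_design())
  a <- rsm_anova(m)
  g <- function(term, col) a[[col]][a$term == term]
  expect_lt(abs(g("Model", "F") - 42.61), 5e-3)
  expect_lt(abs(g("Model", "SS") - 196.58), 5e-3)
  expect_lt(abs(g("A", "SS") - 7.79), 5e-3)
  expect_lt(abs(g("B", "SS") - 1.88), 5e-3)
  expect_lt(abs(g("C", "SS") - 25.75), 5e-3)
  expect_lt(abs(g("D", "SS") - 15.96), 5e-3)
  expect_lt(abs(g("AB", "SS") - 8.12), 5e-3)
  expect_lt(abs(g("AC", "SS") - 9.36), 5e-3)
  expect_lt(abs(g("PureError", "SS") - 0.78), 5e-3)
  expect_lt(abs(g("LackOfFit", "F") - 1.98), 5e-3)
  expect_lt(abs(g("C", "F") - 78.15), 0.05)
  # additivity of SS and df
  expect_equal(g("Model", "SS") + g("Residual", "SS"), g("Total", "SS"),
               tolerance = 1e-8)
  expect_equal(g("LackOfFit", "SS") + g("PureError", "SS"),
               g("Residual", "SS"), tolerance = 1e-8)
  expect_identical(g("Model", "df") + g("Residual", "df"), g("Total", "df"))
  expect_identical(g("LackOfFit", "df") + g("PureError", "df"),
                   g("Residual", "df"))
})

test_that("ANOVA additivity holds on seeded synthetic fits; noiseless residual is zero", {
  for (s in 1:5) {
    d <- gen_bbd_response(noise_sd = 0.4, seed = s)
    a <- rsm_anova(fit_quadratic(d))
    g <- function(term, col) a[[col]][a$term == term]
    expect_equal(g("Model", "SS") + g("Residual", "SS"), g("Total", "SS"),
                 tolerance = 1e-8)
    expect_equal(g("LackOfFit", "SS") + g("PureError", "SS"),
                 g("Residual", "SS"), tolerance = 1e-8)
  }
  d0 <- gen_bbd_response(noise_sd = 0, seed = 1)
  a0 <- rsm_anova(fit_quadratic(d0))
  expect_lt(a0$SS[a0$term == "Residual"], 1e-16)
  expect_equal(r_squared(fit_quadratic(d0))$r2, 1, tolerance = 1e-12)
})

test_that("linear-term partial SS equals the contrast formula on a complete BBD", {
  # (sum x_j y)^2 / 12 versus the reduced-model refit inside rsm_anova
  d <- gen_bbd_response(noise_sd = 0.3, seed = 42)
  a <- rsm_anova(fit_quadratic(d))
  for (j in 1:4) {
    ss_contrast <- sum(d$coded[, j] * d$response)^2 / 12
    expect_equal(a$SS[a$term == LETTERS[j]], ss_contrast, tolerance = 1e-8)
  }
})

test_that("lack of fit is unavailable (NA), not zero, without replicates", {
  d <- build_bbd(default_factors(), n_center = 1L)
  set.seed(5)
  d$response <- 10 + rnorm(nrow(d$coded))
  a <- rsm_anova(fit_quadratic(d))
  expect_true(is.na(a$SS[a$term == "LackOfFit"]))
  expect_true(is.na(a$SS[a$term == "PureError"]))
})

test_that("r_squared agrees with its complement identity and handles constants", {
  m <- fit_quadratic(fixture_design())
  rs <- r_squared(m)
  expect_equal(round(rs$r2, 4), 0.9771)
  a <- rsm_anova(m)
  ss_res <- a$SS[a$term == "Residual"]; ss_tot <- a$SS[a$term == "Total"]
  expect_equal(rs$r2, 1 - ss_res / ss_tot, tolerance = 1e-12)
  d <- fixture_design(); d$response[] <- 5
  expect_true(is.na(r_squared(fit_quadratic(d))$r2))
})

test_that("cube optimizer recovers analytic optima and matches a grid oracle", {
  # concave separable paraboloid with interior vertex
  beta <- c(10, 0.6, -0.4, 0.8, 0.2, 0, 0, 0, 0, 0, 0, -1, -1, -2, -0.5)
  d <- gen_bbd_response(coefficients = beta, noise_sd = 0, seed = 1)
  m <- fit_quadratic(d)
  opt <- optimize_on_cube(m)
  vertex <- c(0.3, -0.2, 0.2, 0.2)  # -b/2a per coordinate
  expect_equal(opt$coded, vertex, tolerance = 1e-6)
  expect_equal(opt$predicted, poly_eval_oracle(beta, vertex),
               tolerance = 1e-9)
  # fixture fit: beats the published optimum and the dense grid
  mf <- fit_quadratic(fixture_design())
  optf <- optimize_on_cube(mf)
  expect_gte(optf$predicted, 11.06)
  grid_best <- grid_max_oracle(function(p) predict(mf, p), 21L)
  expect_gte(optf$predicted, grid_best - 1e-4)
  expect_true(all(abs(optf$coded) <= 1 + 1e-12))
})

test_that("absolute error is the plain symmetric difference", {
  expect_equal(absolute_error(11.0688, 10.5571), 0.5117)
  expect_equal(absolute_error(3, 3), 0)
  expect_equal(absolute_error(2, 5), absolute_error(5, 2))
})
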