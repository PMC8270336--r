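# Second-order response-surface model on coded variables.
#
# Term order is fixed throughout the package:
#   intercept, A, B, C, D, AB, AC, AD, BC, BD, CD, A^2, B^2, C^2, D^2
# where A..D are the four factors in design order.

quad_term_codes <- function(k = 4L) {
  letters_k <- LETTERS[seq_len(k)]
  ints <- utils::combn(k, 2L)
  c(letters_k,
    apply(ints, 2L, function(ij) paste0(letters_k[ij[1]], letters_k[ij[2]])),
    paste0(letters_k, "2"))
}

# Model matrix for the full quadratic on coded settings (no intercept col).
quad_model_matrix <- function(coded) {
  k <- ncol(coded)
  ints <- utils::combn(k, 2L)
  XI <- matrix(NA_real_, nrow(coded), ncol(ints))
  for (p in seq_len(ncol(ints)))
    XI[, p] <- coded[, ints[1, p]] * coded[, ints[2, p]]
  X <- cbind(coded, XI, coded^2)
  colnames(X) <- quad_term_codes(k)
  X
}

#' Fit the full second-order polynomial to a designed response
#'
#' Ordinary least squares of the measured response on the 15-term quadratic
#' in coded variables: intercept, four linear, six two-way interaction and
#' four pure-quadratic terms.
#'
#' @param design A `design_table` with at least 15 complete runs.
#' @return A `quadratic_model` with components `b0`, `b_lin`, `b_int`,
#'   `b_quad`, the factor specs, and the fitting data.
#' @examples
#' m <- fit_quadratic(rosa_design())
#' round(m$b0, 2)  # 10.30
#' @export
fit_quadratic <- function(design) {
  stopifnot(inherits(design, "design_table"))
  keep <- !is.na(design$response)
  if (sum(keep) < 15L)
    flav_stop("need >= 15 runs with responses to fit the quadratic",
              "flav_fit_error")
  X <- cbind(`(Intercept)` = 1, quad_model_matrix(design$coded[keep, , drop = FALSE]))
  y <- design$response[keep]
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    aliased <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    flav_stop(sprintf("singular design: aliased columns %s",
                      paste(aliased, collapse = ", ")), "flav_fit_error")
  }
  beta <- qr.coef(qx, y)
  tc <- quad_term_codes()
  structure(list(
    b0 = unname(beta[1]),
    b_lin = unname(beta[2:5]),
    b_int = unname(beta[6:11]),
    b_quad = unname(beta[12:15]),
    coefficients = stats::setNames(unname(beta), c("(Intercept)", tc)),
    factors = design$factors,
    coded = design$coded[keep, , drop = FALSE],
    response = y
  ), class = "quadratic_model")
}

#' @export
print.quadratic_model <- function(x, ...) {
  cat("Second-order response-surface model (coded units)\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Evaluate a quadratic response-surface model
#'
#' @param object A `quadratic_model`.
#' @param coded Coded point (length-4 vector) or matrix of points (one row
#'   each). Points outside the [-1,1] cube are allowed; the result then
#'   carries an `extrapolated` attribute.
#' @param ... Unused.
#' @return Predicted response(s), in the response's original units (%).
#' @export
predict.quadratic_model <- function(object, coded, ...) {
  if (!is.matrix(coded)) coded <- matrix(coded, nrow = 1L)
  stopifnot(ncol(coded) == 4L)
  X <- cbind(1, quad_model_matrix(coded))
  out <- drop(X %*% object$coefficients)
  if (any(abs(coded) > 1 + 1e-12))
    attr(out, "extrapolated") <- TRUE
  out
}

replicate_groups <- function(coded) {
  apply(coded, 1L, paste, collapse = "/")
}

#' ANOVA for a quadratic response-surface fit
#'
#' Variance decomposition in the convention of response-surface software:
#' per-term partial (Type-III) sums of squares obtained by removing each of
#' the 14 non-intercept terms from the full model, a joint 14-degree Model
#' row, and a residual split into lack of fit and pure error using the
#' replicated runs. When no runs are replicated the lack-of-fit rows are
#' reported as `NA` (unavailable), not zero.
#'
#' @param model A `quadratic_model` from [fit_quadratic()].
#' @param design The design it was fitted to; defaults to the data stored
#'   in the model.
#' @return An `anova_table` data.frame (source, term, SS, df, MS, F, p)
#'   with a `totals` attribute.
#' @examples
#' a <- rsm_anova(fit_quadratic(rosa_design()))
#' round(a$F[a$term == "Model"], 2)  # 42.61
#' @export
rsm_anova <- function(model, design = NULL) {
  stopifnot(inherits(model, "quadratic_model"))
  coded <- if (is.null(design)) model$coded else design$coded[!is.na(design$response), , drop = FALSE]
  y <- if (is.null(design)) model$response else design$response[!is.na(design$response)]
  n <- length(y)
  X <- cbind(1, quad_model_matrix(coded))
  p_full <- ncol(X)
  ss_res <- sum(qr.resid(qr(X), y)^2)
  ss_tot <- sum((y - mean(y))^2)
  ss_mod <- ss_tot - ss_res
  df_res <- n - p_full
  df_mod <- p_full - 1L
  ms_res <- ss_res / df_res

  tc <- quad_term_codes()
  ss_term <- vapply(seq_along(tc), function(j) {
    Xr <- X[, -(j + 1L), drop = FALSE]
    sum(qr.resid(qr(Xr), y)^2) - ss_res
  }, 0)

  # pure error: within-group variation over replicated settings
  grp <- replicate_groups(coded)
  tab <- table(grp)
  has_reps <- any(tab > 1L)
  if (has_reps) {
    ss_pe <- sum(tapply(y, grp, function(v) sum((v - mean(v))^2)))
    df_pe <- n - length(tab)
    ss_lof <- ss_res - ss_pe
    df_lof <- df_res - df_pe
  } else {
    ss_pe <- df_pe <- ss_lof <- df_lof <- NA_real_
  }

  row <- function(source, term, ss, df) {
    ms <- if (is.na(ss) || is.na(df) || df == 0) NA_real_ else ss / df
    data.frame(source = source, term = term, SS = ss, df = df, MS = ms,
               F = NA_real_, p = NA_real_, stringsAsFactors = FALSE)
  }
  fac_names <- vapply(model$factors, function(f) f$name, "")
  term_labels <- c(paste0(LETTERS[1:4], "-", fac_names), tc[5:10],
                   paste0(LETTERS[1:4], "^2"))
  out <- rbind(
    row("Model", "Model", ss_mod, df_mod),
    do.call(rbind, Map(row, term_labels, tc,
                       ss_term, rep(1L, length(tc)))),
    row("Residual", "Residual", ss_res, df_res),
    row("Lack of Fit", "LackOfFit", ss_lof,
        if (has_reps) df_lof else NA_real_),
    row("Pure Error", "PureError", ss_pe,
        if (has_reps) df_pe else NA_real_),
    row("Cor Total", "Total", ss_tot, n - 1L)
  )
  rownames(out) <- NULL
  # F and p against residual MS for model + terms; LOF against pure error
  idx <- which(out$term %in% c("Model", tc))
  out$F[idx] <- out$MS[idx] / ms_res
  out$p[idx] <- stats::pf(out$F[idx], out$df[idx], df_res, lower.tail = FALSE)
  if (has_reps && df_lof > 0 && ss_pe > 0) {
    i <- which(out$term == "LackOfFit")
    out$F[i] <- out$MS[i] / (ss_pe / df_pe)
    out$p[i] <- stats::pf(out$F[i], df_lof, df_pe, lower.tail = FALSE)
  }
  structure(out, class = c("anova_table", "data.frame"),
            totals = c(SS_total = ss_tot, df_total = n - 1L))
}

#' @export
`[.anova_table` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) class(out) <- "data.frame"
  out
}

#' @export
print.anova_table <- function(x, ...) {
  df <- as.data.frame(x)
  df$SS <- signif(df$SS, 6); df$MS <- signif(df$MS, 6)
  df$F <- signif(df$F, 5); df$p <- signif(df$p, 4)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Coefficient of determination of a quadratic fit
#'
#' `R2 = SS_model / SS_total`, with the usual adjusted variant. For a
#' constant response (zero total SS) both are undefined and returned as
#' `NA`.
#'
#' @inheritParams rsm_anova
#' @return Named list `r2`, `adj_r2`.
#' @export
r_squared <- function(model, design = NULL) {
  coded <- if (is.null(design)) model$coded else design$coded[!is.na(design$response), , drop = FALSE]
  y <- if (is.null(design)) model$response else design$response[!is.na(design$response)]
  X <- cbind(1, quad_model_matrix(coded))
  ss_res <- sum(qr.resid(qr(X), y)^2)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot <= 0) return(list(r2 = NA_real_, adj_r2 = NA_real_))
  n <- length(y); p <- ncol(X)
  r2 <- 1 - ss_res / ss_tot
  list(r2 = r2, adj_r2 = 1 - (ss_res / (n - p)) / (ss_tot / (n - 1)))
}

new_optimum_result <- function(coded, factors, predicted, method) {
  nm <- vapply(factors, function(f) f$name, "")
  structure(list(coded = coded,
                 natural = stats::setNames(decode_point(coded, factors), nm),
                 predicted = predicted, method = method),
            class = "optimum_result")
}

#' @export
print.optimum_result <- function(x, ...) {
  nm <- names(x$natural) %||% paste0("x", seq_along(x$natural))
  cat(sprintf("%s optimum: predicted %.4f %%\n", x$method, x$predicted))
  cat("  natural:", paste(sprintf("%s=%.4g", nm, x$natural), collapse = ", "), "\n")
  cat("  coded:  ", paste(sprintf("%+.4f", x$coded), collapse = ", "), "\n")
  invisible(x)
}

#' Deterministic box-constrained maximization of a response surface
#'
#' Multi-start local ascent: Nelder-Mead refinement launched from every
#' point of the 3^4 lattice \{-1,0,+1\}^4 (plus the cube centre), with
#' iterates evaluated at their projection onto the box so the returned
#' point always lies inside it. Ties within 1e-9 in objective value are
#' broken by the smallest coded Euclidean norm.
#'
#' @param model A `quadratic_model` (or any object with a `predict` method
#'   over coded 4-vectors).
#' @param lower,upper Box bounds in coded units (default the unit cube).
#' @return An `optimum_result` with `method = "RSM"`.
#' @export
optimize_on_cube <- function(model, lower = rep(-1, 4), upper = rep(1, 4)) {
  if (any(lower >= upper))
    flav_stop("invalid bounds: need lower < upper", "flav_config_error")
  obj <- function(x) predict(model, clip(x, lower, upper))
  starts <- as.matrix(expand.grid(rep(list(c(-1, 0, 1)), 4)))
  starts <- sweep(sweep(starts, 2, (upper - lower) / 2, "*"), 2,
                  (upper + lower) / 2, "+")
  best_val <- -Inf; best_pt <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- stats::optim(starts[i, ], function(x) -obj(x),
                        method = "Nelder-Mead",
                        control = list(maxit = 500, reltol = 1e-12))
    pt <- clip(fit$par, lower, upper)
    val <- drop(predict(model, pt))
    if (val > best_val + 1e-9 ||
        (val > best_val - 1e-9 && !is.null(best_pt) &&
         sum(pt^2) < sum(best_pt^2) - 1e-12)) {
      best_val <- val; best_pt <- pt
    }
  }
  # polish: restart the simplex from the incumbent until improvement stops
  repeat {
    fit <- stats::optim(best_pt, function(x) -obj(x), method = "Nelder-Mead",
                        control = list(maxit = 1000, reltol = 1e-14))
    pt <- clip(fit$par, lower, upper)
    val <- drop(predict(model, pt))
    if (val <= best_val + 1e-13) break
    best_val <- val; best_pt <- pt
  }
  new_optimum_result(unname(best_pt), model$factors, best_val, "RSM")
}

#' Absolute error between a model prediction and a validation experiment
#'
#' @param prediction,experiment Response values (%).
#' @return `|prediction - experiment|`.
#' @examples
#' absolute_error(11.0688, 10.5571)  # 0.5117
#' @export
absolute_error <- function(prediction, experiment) abs(prediction - experiment)
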