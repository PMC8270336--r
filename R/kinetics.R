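# First-order extraction kinetics (Fick's first law):
#   ln[Cinf / (Cinf - C)] = k t + ln[Cinf / (Cinf - C0)]
# fitted linearly on the log-ratio transform, plus an optional nonlinear
# sigmoid fit of the same transform.

#' Construct a time-concentration kinetic series
#'
#' @param times Sampling times (min), strictly increasing.
#' @param concentrations Flavonoid concentrations at those times, each
#'   strictly below `c_inf`.
#' @param c_inf Equilibrium concentration (same units); defaults to
#'   [pick_equilibrium()]'s rule applied after construction, so normally
#'   supply it explicitly.
#' @param c0 Initial concentration (default the first observation).
#' @return A `kinetic_series`.
#' @export
kinetic_series <- function(times, concentrations, c_inf,
                           c0 = concentrations[1]) {
  if (length(times) != length(concentrations))
    flav_stop("times and concentrations lengths differ", "flav_shape_error")
  if (is.unsorted(times, strictly = TRUE))
    flav_stop("times must be strictly increasing", "flav_config_error")
  bad <- which(concentrations >= c_inf)
  if (length(bad))
    flav_stop(sprintf(
      "concentration at t = %g reaches or exceeds the equilibrium value",
      times[bad[1]]), "flav_domain_error")
  structure(list(times = as.numeric(times),
                 concentrations = as.numeric(concentrations),
                 c0 = c0, c_inf = c_inf), class = "kinetic_series")
}

#' Default equilibrium-concentration rule
#'
#' The concentration at the final sampling time (the protocol samples out
#' to 130 min, past the ~120 min equilibrium plateau). Overridable by
#' passing `c_inf` to [kinetic_series()] directly.
#'
#' @param times,concentrations The raw series.
#' @return The last concentration.
#' @export
pick_equilibrium <- function(times, concentrations) {
  stopifnot(length(times) == length(concentrations), length(times) >= 1L)
  concentrations[which.max(times)]
}

#' Log-ratio transform of a kinetic series
#'
#' `y_i = ln(Cinf / (Cinf - C_i))`, the left side of the first-order
#' model; linear in time when the model holds.
#'
#' @param series A `kinetic_series`.
#' @return data.frame with `time` and `lnratio`.
#' @export
kinetic_transform <- function(series) {
  stopifnot(inherits(series, "kinetic_series"))
  data.frame(time = series$times,
             lnratio = log(series$c_inf / (series$c_inf - series$concentrations)))
}

inverse_transform <- function(lnratio, c_inf) c_inf * (1 - exp(-lnratio))

#' Fit the first-order kinetic model linearly
#'
#' OLS of the log-ratio transform on time; the slope is the extraction
#' rate constant k (per min) and the intercept estimates
#' `ln[Cinf/(Cinf - C0)]`.
#'
#' @param series A `kinetic_series`.
#' @return A `kinetic_fit` with `k`, `intercept`, `r2`.
#' @export
fit_first_order <- function(series) {
  tr <- kinetic_transform(series)
  if (nrow(tr) < 2L)
    flav_stop("need >= 2 time points", "flav_fit_error")
  fit <- stats::lm(lnratio ~ time, data = tr)
  ss_res <- sum(stats::resid(fit)^2)
  ss_tot <- sum((tr$lnratio - mean(tr$lnratio))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot
        else if (ss_res < 1e-24) 1 else NA_real_
  structure(list(k = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
                 r2 = r2, nonlinear = NULL), class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("first-order kinetics: ln[Cinf/(Cinf-C)] = %.5f t + %.4f (R2 = %.4f)\n",
              x$k, x$intercept, x$r2))
  if (!is.null(x$nonlinear)) {
    p <- x$nonlinear
    cat(sprintf("  nonlinear (%s): y0 = %.5f, xc = %.4f, W = %.5f, A = %.5f%s\n",
                p$form, p$y0, p$xc, p$W, p$A,
                if (isTRUE(p$degenerate)) " [degenerate]" else ""))
  }
  invisible(x)
}

boltzmann <- function(t, y0, xc, W, A) A + (y0 - A) / (1 + exp((t - xc) / W))

#' Fit a sigmoid to the kinetic log-ratio curve
#'
#' Least-squares fit of a Boltzmann sigmoid
#' `y(t) = A + (y0 - A) / (1 + exp((t - xc)/W))` to the log-ratio
#' transform, by deterministic multi-start Nelder-Mead. One start is the
#' constant model (y0 = A = mean), so the residual sum never exceeds the
#' constant model's. A fit that fails to improve on the constant model, or
#' a constant series, is flagged `degenerate`.
#'
#' @param series A `kinetic_series`.
#' @param form Sigmoid family; only `"boltzmann"` is implemented.
#' @return A `kinetic_fit` whose `nonlinear` component holds
#'   `y0, xc, W, A`, the residual SS, convergence info and flags; `k`,
#'   `intercept`, `r2` come from the linear fit of the same series.
#' @export
fit_nonlinear <- function(series, form = "boltzmann") {
  if (!identical(form, "boltzmann"))
    flav_stop(sprintf("unknown nonlinear form '%s'", form), "flav_config_error")
  tr <- kinetic_transform(series)
  y <- tr$lnratio; t <- tr$time
  sse <- function(p) {
    r <- y - boltzmann(t, p[1], p[2], p[3], p[4])
    sum(r^2)
  }
  const_sse <- sum((y - mean(y))^2)
  rng <- diff(range(y))
  span <- diff(range(t))
  starts <- list(
    c(mean(y), mean(t), span / 4, mean(y)),                  # constant-ish
    c(min(y), mean(t), span / 4, max(y)),                    # rising sigmoid
    c(min(y) - rng, mean(t), span / 2, max(y) + rng),        # wide
    c(min(y), min(t), span / 8, max(y))                      # early inflection
  )
  best <- list(par = starts[[1]], value = sse(starts[[1]]), convergence = 0L)
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(s, sse, method = "Nelder-Mead",
                   control = list(maxit = 5000, reltol = 1e-14)),
      error = function(e) NULL)
    if (!is.null(fit) && is.finite(fit$value) && fit$value < best$value)
      best <- fit
  }
  # polish: restart the simplex from the incumbent until it stops improving
  repeat {
    fit <- tryCatch(
      stats::optim(best$par, sse, method = "Nelder-Mead",
                   control = list(maxit = 5000, reltol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit) || fit$value >= best$value - 1e-15) break
    best <- fit
  }
  # never report a fit worse than the constant model
  if (best$value > const_sse + 1e-12) {
    best <- list(par = c(mean(y), mean(t), span / 4, mean(y)),
                 value = const_sse, convergence = 1L)
  }
  degenerate <- const_sse < 1e-20 || best$value > const_sse - 1e-12
  lin <- fit_first_order(series)
  lin$nonlinear <- list(form = form, y0 = best$par[1], xc = best$par[2],
                        W = best$par[3], A = best$par[4],
                        ss_res = best$value,
                        converged = identical(best$convergence, 0L),
                        degenerate = degenerate)
  lin
}
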