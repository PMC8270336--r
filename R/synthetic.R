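# Seeded generators for every input the pipeline consumes, each a pure
# function of its arguments (one derived RNG stream per generator) with
# known ground truth, so zero-noise output is exactly invertible by the
# matching fitting operation.

#' Published second-order coefficients as a ground-truth vector
#'
#' The 15 coefficients of the published fitted polynomial, in the
#' package's fixed term order; the default truth for [gen_bbd_response()].
#'
#' @return Named numeric vector of length 15.
#' @export
rosa_coefficients <- function() {
  stats::setNames(
    c(10.30, 0.81, 0.40, -1.47, 1.15,
      -1.43, -1.53, -0.048, 0.20, -1.23, -0.59,
      -0.68, -1.55, -3.50, -3.03),
    c("(Intercept)", quad_term_codes()))
}

#' Simulate a Box-Behnken experiment from a known quadratic surface
#'
#' Builds the deterministic design and draws the response as the true
#' polynomial value plus i.i.d. Gaussian noise. Replicated centre runs
#' share the same mean (the polynomial value at the origin). The default
#' noise sd of 0.3% efficiency matches the order of the published
#' pure-error mean square (~0.19, sd ~0.44).
#'
#' @param coefficients Length-15 truth vector in the package term order
#'   (default [rosa_coefficients()]).
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param n_center Centre replicates.
#' @param factors Factor specs.
#' @param seed RNG seed (mandatory).
#' @return A `design_table` with simulated responses; the truth is
#'   attached as attribute `true_coefficients`.
#' @export
gen_bbd_response <- function(coefficients = rosa_coefficients(),
                             noise_sd = 0.3, n_center = 5L,
                             factors = default_factors(), seed) {
  stopifnot(length(coefficients) == 15L, noise_sd >= 0)
  d <- build_bbd(factors, n_center)
  X <- cbind(1, quad_model_matrix(d$coded))
  mu <- drop(X %*% as.numeric(coefficients))
  d$response <- mu + with_seed(split_seed(seed, 1L),
                               stats::rnorm(length(mu), 0, noise_sd))
  attr(d, "true_coefficients") <- coefficients
  d
}

#' Simulate a first-order extraction kinetic series
#'
#' Concentrations follow `C_t = Cinf * (1 - exp(-(k t + a0)))` plus
#' Gaussian noise, truncated to stay below `Cinf`. Defaults are the
#' published fitted slope and intercept over 10-130 min.
#'
#' @param k Rate constant (per min).
#' @param intercept `a0 = ln[Cinf/(Cinf - C0)]`.
#' @param times Sampling times (min).
#' @param c_inf Equilibrium concentration.
#' @param noise_sd Noise sd in concentration units.
#' @param seed RNG seed.
#' @return A `kinetic_series` with attributes `true_k`,
#'   `true_intercept`.
#' @export
gen_kinetic_series <- function(k = 0.01372, intercept = -0.6274,
                               times = seq(10, 130, by = 10), c_inf = 10,
                               noise_sd = 0, seed = 1L) {
  stopifnot(noise_sd >= 0)
  mu <- c_inf * (1 - exp(-(k * times + intercept)))
  eps <- with_seed(split_seed(seed, 2L),
                   stats::rnorm(length(times), 0, noise_sd))
  conc <- pmin(mu + eps, c_inf * (1 - 1e-9))
  s <- kinetic_series(times, conc, c_inf = c_inf)
  attr(s, "true_k") <- k
  attr(s, "true_intercept") <- intercept
  s
}

#' Simulate rutin calibration points
#'
#' Absorbances on a straight line (defaults: the published calibration
#' slope and intercept) over a 0-0.1 mg/mL six-point dilution series,
#' plus optional Gaussian noise.
#'
#' @param slope,intercept True line.
#' @param concentrations Standard concentrations (mg/mL).
#' @param noise_sd Absorbance noise sd.
#' @param seed RNG seed.
#' @return List `concentrations`, `absorbances` with the truth attached.
#' @export
gen_standard_curve_points <- function(slope = 5.0629, intercept = 0.1885,
                                      concentrations = seq(0, 0.1,
                                                           length.out = 6),
                                      noise_sd = 0, seed = 1L) {
  stopifnot(noise_sd >= 0)
  ab <- slope * concentrations + intercept +
    with_seed(split_seed(seed, 3L),
              stats::rnorm(length(concentrations), 0, noise_sd))
  structure(list(concentrations = concentrations, absorbances = ab),
            true_slope = slope, true_intercept = intercept)
}

#' Simulate radical-scavenging dilution ladders
#'
#' Emulates an assay dilution series (default 0.01-0.1 mg/mL) with a
#' saturating monotone true efficiency curve
#' `K(c) = k_max * c / (c + c50)` (so K(0) = 0), converting the intended
#' efficiency into a consistent absorbance triple per concentration and
#' adding noise to the sample-control absorbance.
#'
#' @param assay Assay type.
#' @param concentrations Extract concentrations (mg/mL).
#' @param k_max,c50 True curve parameters (% and mg/mL).
#' @param noise_sd Absorbance noise sd.
#' @param seed RNG seed.
#' @return List of [assay_measurement()]s with attribute
#'   `true_efficiency`.
#' @export
gen_assay_measurements <- function(assay = c("dpph", "superoxide", "hydroxyl"),
                                   concentrations = seq(0.01, 0.1, by = 0.01),
                                   k_max = 90, c50 = 0.03, noise_sd = 0,
                                   seed = 1L) {
  assay <- match.arg(assay)
  stopifnot(noise_sd >= 0)
  K <- k_max * concentrations / (concentrations + c50)
  eps <- with_seed(split_seed(seed, 4L),
                   stats::rnorm(length(concentrations), 0, noise_sd))
  out <- vector("list", length(concentrations))
  for (i in seq_along(concentrations)) {
    if (assay == "hydroxyl") {
      ap <- 0.2; abk <- 1.0
      as_ <- ap + K[i] / 100 * (abk - ap) + eps[i]
      out[[i]] <- assay_measurement("hydroxyl", blank = ap,
                                    sample_control = max(as_, 0),
                                    experimental_control = abk,
                                    concentration = concentrations[i])
    } else {
      a0 <- 0.8
      a2 <- 0.05 * concentrations[i] / max(concentrations)  # extract colour
      a1 <- a0 + a2 - K[i] / 100 * a0 + eps[i]
      out[[i]] <- assay_measurement(assay, blank = a0,
                                    sample_control = max(a1, 0),
                                    experimental_control = a2,
                                    concentration = concentrations[i])
    }
  }
  attr(out, "true_efficiency") <- K
  out
}

#' Simulate a design with one dominant factor
#'
#' Linear response over the Box-Behnken design in which one factor's
#' coefficient is ten times the others' - the canonical fixture for
#' importance-ranking tests.
#'
#' @param dominant Index (1-4) of the dominant factor.
#' @param effect Linear effect of the dominant factor (coded units);
#'   the other factors get `effect / 10`.
#' @param noise_sd Response noise sd.
#' @param factors Factor specs.
#' @param seed RNG seed.
#' @return A `design_table`; attribute `dominant` records the index.
#' @export
gen_dominant_factor <- function(dominant = 3L, effect = 2, noise_sd = 0.3,
                                factors = default_factors(), seed) {
  stopifnot(dominant %in% 1:4, noise_sd >= 0)
  b <- rep(effect / 10, 4)
  b[dominant] <- effect
  d <- build_bbd(factors, 5L)
  mu <- 10 + drop(d$coded %*% b)
  d$response <- mu + with_seed(split_seed(seed, 5L),
                               stats::rnorm(length(mu), 0, noise_sd))
  attr(d, "dominant") <- dominant
  d
}
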