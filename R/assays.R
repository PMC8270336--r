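# Quantification and antioxidant statistics: the rutin calibration line,
# total-flavonoid yield, and the three radical-scavenging efficiencies
# (DPPH, superoxide anion, hydroxyl).

#' Fit a rutin standard curve
#'
#' Ordinary least squares of absorbance on concentration. The fitted line
#' inverts absorbances to rutin-equivalent concentrations via
#' [absorbance_to_concentration()].
#'
#' @param concentrations Standard concentrations (mg/mL), >= 3 points with
#'   at least two distinct values.
#' @param absorbances Matching absorbances.
#' @return A `standard_curve` with `slope`, `intercept`, `r2`.
#' @export
fit_standard_curve <- function(concentrations, absorbances) {
  if (length(concentrations) != length(absorbances))
    flav_stop("concentration and absorbance lengths differ", "flav_shape_error")
  if (length(concentrations) < 3L)
    flav_stop("need >= 3 calibration points", "flav_fit_error")
  if (length(unique(concentrations)) < 2L)
    flav_stop("calibration concentrations are rank deficient (all equal)",
              "flav_fit_error")
  fit <- stats::lm(absorbances ~ concentrations)
  ss_res <- sum(stats::resid(fit)^2)
  ss_tot <- sum((absorbances - mean(absorbances))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]), r2 = r2),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("standard curve: A = %.4f * C + %.4f (R2 = %.4f)\n",
              x$slope, x$intercept, x$r2))
  invisible(x)
}

#' @rdname fit_standard_curve
#' @param curve A `standard_curve`.
#' @param absorbance Absorbance value(s) to invert.
#' @export
absorbance_to_concentration <- function(curve, absorbance) {
  stopifnot(inherits(curve, "standard_curve"))
  (absorbance - curve$intercept) / curve$slope
}

#' Total-flavonoid yield
#'
#' `W% = C * V / m * 100`: mass concentration of flavonoids in the extract
#' times extract volume, per gram of plant material.
#'
#' @param C Mass concentration of flavonoids (g/mL).
#' @param V Total extract volume (mL).
#' @param m Mass of plant material (g), > 0.
#' @return Yield in %.
#' @examples
#' flavonoid_yield(0.001, 100, 1)  # 10
#' @export
flavonoid_yield <- function(C, V, m) {
  if (any(m <= 0))
    flav_stop("material mass must be positive", "flav_config_error")
  C * V / m * 100
}

#' A single radical-scavenging measurement
#'
#' Absorbance triple for one assay at one extract concentration. Roles
#' follow the assay protocols: `blank` is the radical system without
#' extract (A0 / B0 / Ap), `sample_control` the system plus extract
#' (A1 / B1 / As), `experimental_control` corrects for the extract's own
#' absorbance (A2 / B2 / Ab).
#'
#' @param assay `"dpph"`, `"superoxide"` or `"hydroxyl"`.
#' @param blank,sample_control,experimental_control Absorbances (>= 0).
#' @param concentration Extract concentration (mg/mL), optional.
#' @return An `assay_measurement`.
#' @export
assay_measurement <- function(assay = c("dpph", "superoxide", "hydroxyl"),
                              blank, sample_control, experimental_control,
                              concentration = NA_real_) {
  assay <- match.arg(assay)
  ab <- c(blank, sample_control, experimental_control)
  if (any(!is.finite(ab)) || any(ab < 0))
    flav_stop("absorbances must be finite and >= 0", "flav_config_error")
  structure(list(assay = assay, blank = blank,
                 sample_control = sample_control,
                 experimental_control = experimental_control,
                 concentration = concentration),
            class = "assay_measurement")
}

#' Radical-scavenging efficiencies
#'
#' DPPH and superoxide share the form
#' `K% = (A0 - (A1 - A2)) / A0 * 100`; the hydroxyl assay uses
#' `K% = (As - Ap) / (Ab - Ap) * 100` with its own legend (blank Ap,
#' sample As, experimental control Ab). Values are deliberately not
#' clamped to [0, 100]: out-of-range efficiencies flag assay problems and
#' are returned as-is with an `out_of_range` attribute.
#'
#' @param m An [assay_measurement()] of the matching assay type.
#' @return Scavenging efficiency in %.
#' @examples
#' scavenging_dpph(assay_measurement("dpph", 0.8, 0.5, 0.1))  # 50
#' @export
scavenging_dpph <- function(m) {
  stopifnot(inherits(m, "assay_measurement"))
  if (m$assay != "dpph")
    flav_stop("measurement is not a DPPH assay", "flav_config_error")
  if (m$blank <= 0)
    flav_stop("blank absorbance must be positive", "flav_config_error")
  flag_range((m$blank - (m$sample_control - m$experimental_control)) /
               m$blank * 100)
}

#' @rdname scavenging_dpph
#' @export
scavenging_superoxide <- function(m) {
  stopifnot(inherits(m, "assay_measurement"))
  if (m$assay != "superoxide")
    flav_stop("measurement is not a superoxide assay", "flav_config_error")
  if (m$blank <= 0)
    flav_stop("blank absorbance must be positive", "flav_config_error")
  flag_range((m$blank - (m$sample_control - m$experimental_control)) /
               m$blank * 100)
}

#' @rdname scavenging_dpph
#' @export
scavenging_hydroxyl <- function(m) {
  stopifnot(inherits(m, "assay_measurement"))
  if (m$assay != "hydroxyl")
    flav_stop("measurement is not a hydroxyl assay", "flav_config_error")
  if (m$experimental_control == m$blank)
    flav_stop("hydroxyl assay needs Ab != Ap", "flav_config_error")
  flag_range((m$sample_control - m$blank) /
               (m$experimental_control - m$blank) * 100)
}

flag_range <- function(k) {
  if (k < 0 || k > 100) attr(k, "out_of_range") <- TRUE
  k
}

scavenging <- function(m) {
  switch(m$assay,
         dpph = scavenging_dpph(m),
         superoxide = scavenging_superoxide(m),
         hydroxyl = scavenging_hydroxyl(m))
}

#' Dose-response table for a set of scavenging measurements
#'
#' Computes each measurement's efficiency, sorts by concentration, and
#' reports (without enforcing) whether efficiency is monotone
#' non-decreasing in concentration.
#'
#' @param measurements List of [assay_measurement()]s of one assay type.
#' @return data.frame (`concentration`, `efficiency`) with attribute
#'   `monotone`.
#' @export
dose_response_curve <- function(measurements) {
  stopifnot(length(measurements) >= 1L,
            all(vapply(measurements, inherits, TRUE, "assay_measurement")))
  assays <- vapply(measurements, function(m) m$assay, "")
  if (length(unique(assays)) != 1L)
    flav_stop("measurements mix assay types", "flav_config_error")
  conc <- vapply(measurements, function(m) m$concentration, 0)
  eff <- vapply(measurements, function(m) as.numeric(scavenging(m)), 0)
  ord <- order(conc)
  out <- data.frame(concentration = conc[ord], efficiency = eff[ord])
  attr(out, "monotone") <- !is.unsorted(out$efficiency)
  out
}
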