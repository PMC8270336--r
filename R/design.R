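#' Define an experimental factor
#'
#' A factor is described by its natural low/centre/high levels; coding maps
#' these onto -1/0/+1. The centre must lie strictly between the extremes
#' (for the packaged levels it is exactly the midpoint).
#'
#' @param name Factor name (used as the design-table column header).
#' @param low,center,high Natural levels. `center` defaults to the midpoint.
#' @param unit Measurement unit, for display only.
#' @return An object of class `factor_spec`.
#' @examples
#' factor_spec("time", 20, 30, 40, unit = "min")
#' @export
factor_spec <- function(name, low, center = (low + high) / 2, high, unit = "") {
  stopifnot(is.character(name), length(name) == 1L)
  vals <- c(low = low, center = center, high = high)
  if (any(!is.finite(vals)))
    flav_stop("factor levels must be finite numbers", "flav_config_error")
  if (!(low < center && center < high))
    flav_stop(sprintf("factor '%s': need low < center < high", name),
              "flav_config_error")
  structure(list(name = name, unit = unit, low = low, center = center,
                 high = high), class = "factor_spec")
}

#' The four ultrasonic-extraction factors at their published levels
#'
#' Extraction time 20/30/40 min, ethanol concentration 50/60/70 %,
#' material-liquid ratio 5/10/15 mL solvent per g material, and ultrasonic
#' power 60/120/180 W. The ratio is coded by its denominator, so a ratio of
#' "1:15" codes to +1.
#'
#' @return A named list of four [factor_spec()] objects.
#' @export
default_factors <- function() {
  list(
    time    = factor_spec("time",    20,  30,  40, unit = "min"),
    ethanol = factor_spec("ethanol", 50,  60,  70, unit = "%"),
    ratio   = factor_spec("ratio",    5,  10,  15, unit = "mL/g"),
    power   = factor_spec("power",   60, 120, 180, unit = "W")
  )
}

half_width <- function(f) (f$high - f$low) / 2

#' Convert natural factor settings to coded units (and back)
#'
#' Coding is the affine map `(x - center) / ((high - low)/2)`, so the
#' low/centre/high levels become -1/0/+1. `decode_point()` is the exact
#' inverse.
#'
#' @param natural,coded Numeric vector (one value per factor) or a matrix
#'   with one column per factor.
#' @param factors List of [factor_spec()]s, e.g. [default_factors()].
#' @return Vector or matrix of the same shape, in the other unit system.
#' @examples
#' code_point(c(30, 60, 10, 120), default_factors())  # the centre -> 0,0,0,0
#' @export
code_point <- function(natural, factors) {
  check_factors(factors)
  ctr <- vapply(factors, function(f) f$center, 0)
  hw <- vapply(factors, half_width, 0)
  if (any(hw <= 0))
    flav_stop("degenerate factor: zero-width range", "flav_config_error")
  if (is.matrix(natural)) {
    stopifnot(ncol(natural) == length(factors))
    sweep(sweep(natural, 2, ctr), 2, hw, "/")
  } else {
    stopifnot(length(natural) == length(factors))
    unname((natural - ctr) / hw)
  }
}

#' @rdname code_point
#' @export
decode_point <- function(coded, factors) {
  check_factors(factors)
  ctr <- vapply(factors, function(f) f$center, 0)
  hw <- vapply(factors, half_width, 0)
  if (is.matrix(coded)) {
    sweep(sweep(coded, 2, hw, "*"), 2, ctr, "+")
  } else {
    unname(coded * hw + ctr)
  }
}

check_factors <- function(factors, n = NULL) {
  if (!is.list(factors) || !all(vapply(factors, inherits, TRUE, "factor_spec")))
    flav_stop("`factors` must be a list of factor_spec objects",
              "flav_config_error")
  if (!is.null(n) && length(factors) != n)
    flav_stop(sprintf("unsupported design: %d factors supplied, %d required",
                      length(factors), n), "flav_design_error")
  invisible(factors)
}

new_design_table <- function(factors, coded, response = NULL) {
  natural <- decode_point(coded, factors)
  nm <- vapply(factors, function(f) f$name, "")
  colnames(coded) <- colnames(natural) <- nm
  structure(list(
    factors = factors,
    coded = coded,
    natural = natural,
    response = response %||% rep(NA_real_, nrow(coded))
  ), class = "design_table")
}

#' Build a four-factor Box-Behnken design
#'
#' The design holds the 24 edge runs - every unordered factor pair at the
#' four (+-1, +-1) combinations with the remaining factors at the centre -
#' followed by `n_center` replicated centre runs. Run order is
#' deterministic: pairs in lexicographic order, the (-1,-1), (-1,+1),
#' (+1,-1), (+1,+1) combinations within each pair, centres last. With five
#' centre runs this is the published 29-run plan.
#'
#' @param factors List of exactly four [factor_spec()]s.
#' @param n_center Number of replicated centre runs (>= 1).
#' @return A `design_table` with an all-`NA` response column.
#' @examples
#' d <- build_bbd(default_factors(), n_center = 5)
#' nrow(d$coded)  # 29
#' @export
build_bbd <- function(factors = default_factors(), n_center = 5L) {
  check_factors(factors, n = 4L)
  if (n_center < 1L)
    flav_stop("n_center must be >= 1", "flav_config_error")
  pairs <- utils::combn(4L, 2L)
  lv <- as.matrix(expand.grid(a = c(-1, 1), b = c(-1, 1)))[, 2:1]  # (-1,-1),(-1,1),(1,-1),(1,1)
  lv <- lv[order(lv[, 1], lv[, 2]), , drop = FALSE]
  rows <- vector("list", ncol(pairs))
  for (p in seq_len(ncol(pairs))) {
    m <- matrix(0, nrow = 4L, ncol = 4L)
    m[, pairs[1, p]] <- lv[, 1]
    m[, pairs[2, p]] <- lv[, 2]
    rows[[p]] <- m
  }
  coded <- rbind(do.call(rbind, rows), matrix(0, nrow = n_center, ncol = 4L))
  new_design_table(factors, coded)
}

#' @export
print.design_table <- function(x, ...) {
  cat(sprintf("Box-Behnken design table: %d runs, %d factors (%s)\n",
              nrow(x$coded), length(x$factors),
              paste(colnames(x$coded), collapse = ", ")))
  cat(sprintf("  responses present: %d of %d\n",
              sum(!is.na(x$response)), length(x$response)))
  invisible(x)
}

#' @export
as.data.frame.design_table <- function(x, ..., units = c("natural", "coded")) {
  units <- match.arg(units)
  m <- if (units == "natural") x$natural else x$coded
  out <- as.data.frame(m)
  out$response <- x$response
  out
}

is_center_run <- function(design) rowSums(design$coded != 0) == 0L

#' Check the structural invariants of a Box-Behnken design table
#'
#' Verifies run count, that every non-centre run sets exactly two factors
#' off-centre, that each coded column sums to zero, and that coded entries
#' are in \{-1, 0, +1\}.
#'
#' @param design A `design_table`.
#' @return `TRUE` (invisibly); otherwise an error describing the violation.
#' @export
validate_bbd <- function(design) {
  stopifnot(inherits(design, "design_table"))
  cd <- design$coded
  if (!all(cd %in% c(-1, 0, 1)))
    flav_stop("coded levels outside {-1,0,+1}", "flav_design_error")
  nz <- rowSums(cd != 0)
  if (!all(nz %in% c(0L, 2L)))
    flav_stop("non-centre runs must set exactly two factors off-centre",
              "flav_design_error")
  if (any(abs(colSums(cd)) > 1e-12))
    flav_stop("coded columns must sum to zero", "flav_design_error")
  n_edge <- sum(nz == 2L)
  if (n_edge != 24L)
    flav_stop(sprintf("expected 24 edge runs, found %d", n_edge),
              "flav_design_error")
  invisible(TRUE)
}

#' Read / write a design table as delimited text
#'
#' The dialect is fixed: comma-separated, UTF-8, '.' decimal, a header row
#' of factor names followed by `response`. Missing responses are allowed.
#'
#' @param path File path.
#' @param factors Factor specs used to code the natural levels; when `NULL`
#'   each column must take exactly three distinct values, from which the
#'   low/centre/high levels are inferred.
#' @return `read_design()` returns a `design_table`; `write_design()`
#'   returns `path` invisibly.
#' @export
read_design <- function(path, factors = NULL) {
  if (!file.exists(path))
    flav_stop(sprintf("file not found: %s", path), "flav_parse_error")
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, fileEncoding = "UTF-8")
  if (ncol(raw) < 2L)
    flav_stop("design file needs factor columns plus `response`",
              "flav_parse_error")
  if (!"response" %in% names(raw))
    flav_stop("design file is missing a `response` column", "flav_parse_error")
  fac_names <- setdiff(names(raw), "response")
  num <- raw
  for (j in names(raw)) {
    v <- trimws(raw[[j]])
    v[v == ""] <- NA
    suppressWarnings(x <- as.numeric(v))
    bad <- which(!is.na(v) & is.na(x))
    if (length(bad))
      flav_stop(sprintf("non-numeric value '%s' in column '%s', row %d",
                        v[bad[1]], j, bad[1]), "flav_parse_error")
    num[[j]] <- x
  }
  nat <- as.matrix(num[fac_names])
  if (is.null(factors)) {
    factors <- lapply(fac_names, function(j) {
      lev <- sort(unique(nat[, j]))
      if (length(lev) != 3L)
        flav_stop(sprintf(
          "cannot infer levels for '%s': %d distinct values (need 3)",
          j, length(lev)), "flav_parse_error")
      factor_spec(j, lev[1], lev[2], lev[3])
    })
    names(factors) <- fac_names
  }
  check_factors(factors)
  d <- new_design_table(factors, code_point(nat, factors),
                        response = num$response)
  d
}

#' @rdname read_design
#' @param design A `design_table` to serialize.
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "design_table"))
  df <- as.data.frame(design, units = "natural")
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.csv(format(df, trim = TRUE, scientific = FALSE), con,
                   row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Packaged fixtures: the published 29-run design and validation table
#'
#' `rosa_design()` returns the published four-factor Box-Behnken run table
#' with measured extraction efficiencies (%). `rosa_validation()` returns
#' the published optimum-validation rows (model tag, natural settings,
#' experimental and predicted efficiency).
#'
#' @return A `design_table`, respectively a data.frame.
#' @export
rosa_design <- function() {
  path <- system.file("extdata", "rosa_bbd.csv", package = "flavoptim",
                      mustWork = TRUE)
  read_design(path, factors = default_factors())
}

#' @rdname rosa_design
#' @export
rosa_validation <- function() {
  path <- system.file("extdata", "rosa_validation.csv",
                      package = "flavoptim", mustWork = TRUE)
  utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
}
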