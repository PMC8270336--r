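# Population metaheuristics over a box: a real-coded genetic algorithm
# (tournament selection, blend crossover, Gaussian mutation, elitism) and
# a particle swarm with inertia-weight velocity updates. Both maximize an
# arbitrary objective over coded factor space and are bit-reproducible
# given their seed.

#' Optimizer configurations
#'
#' The source leaves hyperparameters unstated; these defaults are
#' conventional: GA with population 50 over 100 generations, crossover
#' probability 0.9, Gaussian mutation sd 0.1 coded units, tournament size
#' 3, one elite; PSO with 30 particles over 100 iterations and the
#' standard constriction-equivalent values (inertia 0.729,
#' c1 = c2 = 1.49445).
#'
#' @param population,generations GA population size (>= 2) and generation
#'   count.
#' @param crossover_rate Probability a selected pair is blended, in [0,1].
#' @param mutation_sd Initial Gaussian mutation standard deviation (coded
#'   units).
#' @param mutation_decay Per-generation geometric decay of the mutation sd
#'   (in (0, 1]); lets late generations refine the incumbent.
#' @param tournament_size,elitism Selection pressure and elite count.
#' @param swarm,iterations PSO swarm size (>= 2) and iteration count.
#' @param inertia Velocity inertia weight, in (0, 1].
#' @param c1,c2 Personal-best and global-best acceleration coefficients.
#' @param v_max Velocity clamp (coded units per iteration).
#' @param seed RNG seed.
#' @return A config list.
#' @export
ga_config <- function(population = 50L, generations = 100L,
                      crossover_rate = 0.9, mutation_sd = 0.1,
                      mutation_decay = 0.95,
                      tournament_size = 3L, elitism = 1L, seed = 1L) {
  if (population < 2L)
    flav_stop("GA population must be >= 2", "flav_config_error")
  if (crossover_rate < 0 || crossover_rate > 1)
    flav_stop("crossover_rate must lie in [0,1]", "flav_config_error")
  if (mutation_decay <= 0 || mutation_decay > 1)
    flav_stop("mutation_decay must lie in (0,1]", "flav_config_error")
  list(population = as.integer(population),
       generations = as.integer(generations),
       crossover_rate = crossover_rate, mutation_sd = mutation_sd,
       mutation_decay = mutation_decay,
       tournament_size = as.integer(tournament_size),
       elitism = as.integer(elitism), seed = seed)
}

#' @rdname ga_config
#' @export
pso_config <- function(swarm = 30L, iterations = 100L, inertia = 0.729,
                       c1 = 1.49445, c2 = 1.49445, v_max = 0.5, seed = 1L) {
  if (swarm < 2L)
    flav_stop("PSO swarm must be >= 2", "flav_config_error")
  if (inertia <= 0 || inertia > 1)
    flav_stop("inertia must lie in (0,1]", "flav_config_error")
  list(swarm = as.integer(swarm), iterations = as.integer(iterations),
       inertia = inertia, c1 = c1, c2 = c2, v_max = v_max, seed = seed)
}

check_box <- function(lower, upper) {
  if (length(lower) != length(upper) || any(!is.finite(c(lower, upper))) ||
      any(lower >= upper))
    flav_stop("invalid bounds: need finite lower < upper", "flav_config_error")
}

#' Maximize an objective over a box with a real-coded genetic algorithm
#'
#' Tournament selection, BLX-alpha blend crossover (alpha = 0.5), Gaussian
#' mutation with clipping to the box, and elitist survival of the best
#' individuals. The best point ever evaluated is returned, together with
#' the per-generation best-so-far trajectory (attribute `trajectory`),
#' which is non-decreasing by construction.
#'
#' @param objective Function of a numeric vector, finite on the box.
#' @param lower,upper Box bounds.
#' @param config A [ga_config()].
#' @param factors Optional factor specs used to decode the optimum into
#'   natural units (defaults to reporting the coded point twice).
#' @return An `optimum_result` with `method = "GA"`.
#' @export
ga_maximize <- function(objective, lower = rep(-1, 4), upper = rep(1, 4),
                        config = ga_config(), factors = NULL) {
  check_box(lower, upper)
  d <- length(lower)
  with_seed(config$seed, {
    pop <- matrix(stats::runif(config$population * d, lower, upper),
                  ncol = d, byrow = TRUE)
    fit <- apply(pop, 1L, objective)
    if (any(!is.finite(fit)))
      flav_stop("objective not finite on bounds", "flav_fit_error")
    best_i <- which.max(fit)
    best_pt <- pop[best_i, ]; best_val <- fit[best_i]
    traj <- numeric(config$generations)
    tournament <- function() {
      cand <- sample.int(config$population, config$tournament_size,
                         replace = TRUE)
      cand[which.max(fit[cand])]
    }
    for (g in seq_len(config$generations)) {
      sd_g <- config$mutation_sd * config$mutation_decay^(g - 1L)
      elite_idx <- order(fit, decreasing = TRUE)[seq_len(config$elitism)]
      children <- matrix(NA_real_, config$population, d)
      children[seq_len(config$elitism), ] <- pop[elite_idx, , drop = FALSE]
      i <- config$elitism
      while (i < config$population) {
        p1 <- pop[tournament(), ]; p2 <- pop[tournament(), ]
        if (stats::runif(1) < config$crossover_rate) {
          # BLX-0.5: sample each gene uniformly on the blended interval
          lo <- pmin(p1, p2); hi <- pmax(p1, p2); w <- hi - lo
          c1 <- stats::runif(d, lo - 0.5 * w, hi + 0.5 * w)
          c2 <- stats::runif(d, lo - 0.5 * w, hi + 0.5 * w)
        } else {
          c1 <- p1; c2 <- p2
        }
        for (child in list(c1, c2)) {
          if (i >= config$population) break
          i <- i + 1L
          mut <- child + stats::rnorm(d, 0, sd_g)
          children[i, ] <- clip(mut, lower, upper)
        }
      }
      pop <- children
      fit <- apply(pop, 1L, objective)
      gi <- which.max(fit)
      if (fit[gi] > best_val) { best_val <- fit[gi]; best_pt <- pop[gi, ] }
      traj[g] <- best_val
    }
    out <- if (is.null(factors))
      structure(list(coded = best_pt, natural = best_pt,
                     predicted = best_val, method = "GA"),
                class = "optimum_result")
    else new_optimum_result(best_pt, factors, best_val, "GA")
    attr(out, "trajectory") <- traj
    out
  })
}

#' Maximize an objective over a box with particle swarm optimization
#'
#' Velocity update `v <- w v + c1 r1 (pbest - x) + c2 r2 (gbest - x)` with
#' per-component velocity clamping to `v_max` and position clipping to the
#' box. Returns the global best with its non-decreasing trajectory.
#'
#' @inheritParams ga_maximize
#' @param config A [pso_config()].
#' @return An `optimum_result` with `method = "PSO"`.
#' @export
pso_maximize <- function(objective, lower = rep(-1, 4), upper = rep(1, 4),
                         config = pso_config(), factors = NULL) {
  check_box(lower, upper)
  d <- length(lower)
  with_seed(config$seed, {
    x <- matrix(stats::runif(config$swarm * d, lower, upper),
                ncol = d, byrow = TRUE)
    v <- matrix(stats::runif(config$swarm * d, -config$v_max, config$v_max),
                ncol = d, byrow = TRUE)
    fit <- apply(x, 1L, objective)
    if (any(!is.finite(fit)))
      flav_stop("objective not finite on bounds", "flav_fit_error")
    pbest <- x; pbest_val <- fit
    gi <- which.max(fit)
    gbest <- x[gi, ]; gbest_val <- fit[gi]
    traj <- numeric(config$iterations)
    for (it in seq_len(config$iterations)) {
      r1 <- matrix(stats::runif(config$swarm * d), ncol = d)
      r2 <- matrix(stats::runif(config$swarm * d), ncol = d)
      v <- config$inertia * v +
        config$c1 * r1 * (pbest - x) +
        config$c2 * r2 * (sweep(-x, 2, gbest, "+"))
      v <- clip(v, -config$v_max, config$v_max)
      x <- clip(x + v, lower, upper)
      fit <- apply(x, 1L, objective)
      better <- fit > pbest_val
      pbest[better, ] <- x[better, , drop = FALSE]
      pbest_val[better] <- fit[better]
      gi <- which.max(pbest_val)
      if (pbest_val[gi] > gbest_val) {
        gbest_val <- pbest_val[gi]; gbest <- pbest[gi, ]
      }
      traj[it] <- gbest_val
    }
    out <- if (is.null(factors))
      structure(list(coded = gbest, natural = gbest,
                     predicted = gbest_val, method = "PSO"),
                class = "optimum_result")
    else new_optimum_result(gbest, factors, gbest_val, "PSO")
    attr(out, "trajectory") <- traj
    out
  })
}

#' End-to-end surrogate optimization with optional validation
#'
#' Fits the chosen surrogate (quadratic response surface, or trained
#' neural network) to the design, maximizes it over the coded cube with
#' the chosen metaheuristic, decodes the optimum to natural units, and -
#' when a validation measurement is supplied - reports the absolute error
#' between prediction and experiment, in the layout of the published
#' model-comparison table.
#'
#' @param design A `design_table` with responses.
#' @param surrogate `"rsm"` or `"ann"`.
#' @param method `"ga"` or `"pso"`.
#' @param ga,pso Optimizer configs.
#' @param ann_args List of extra arguments passed to [ann_train()].
#' @param validate Optional experimental response (%) at the found
#'   optimum.
#' @return List: `optimum` (an `optimum_result` tagged e.g. `"ANN-GA"`),
#'   `prediction`, `experiment`, `absolute_error` (the latter two `NA`
#'   without validation).
#' @export
surrogate_optimize <- function(design, surrogate = c("rsm", "ann"),
                               method = c("ga", "pso"),
                               ga = ga_config(), pso = pso_config(),
                               ann_args = list(), validate = NULL) {
  surrogate <- match.arg(surrogate)
  method <- match.arg(method)
  factors <- design$factors
  if (surrogate == "rsm") {
    fitted <- fit_quadratic(design)
    obj <- function(x) drop(predict(fitted, x))
  } else {
    trained <- do.call(ann_train, c(list(design = design), ann_args))
    fitted <- trained$model
    obj <- function(x) drop(ann_forward(fitted, decode_point(x, factors)))
  }
  opt <- if (method == "ga")
    ga_maximize(obj, config = ga, factors = factors)
  else
    pso_maximize(obj, config = pso, factors = factors)
  opt$method <- paste0(toupper(surrogate), "-", toupper(method))
  err <- if (is.null(validate)) NA_real_
         else absolute_error(opt$predicted, validate)
  list(optimum = opt, surrogate = fitted, prediction = opt$predicted,
       experiment = validate %||% NA_real_, absolute_error = err)
}
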