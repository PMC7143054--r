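#' SAGA optimizer configuration
#'
#' The hybrid simulated-annealing/genetic-algorithm optimizer maintains a
#' population of parameter vectors on the unit box; each member is an
#' annealing chain. Each step, a child is produced from a chain by block
#' crossover with a second parent (a random member, or the best-so-far
#' vector half the time), then one coordinate is mutated: usually a uniform
#' perturbation at the current temperature scale, occasionally a fresh
#' uniform draw (a jump that can leave a local mode after cooling). The
#' child replaces its parent chain always if better, or with the Metropolis
#' probability `exp(-delta/T)` if worse. Crossover ramps in linearly over
#' the run so early steps explore independently and late steps recombine
#' converged blocks; in the final quarter a fraction of steps refine the
#' incumbent best vector directly. The temperature follows a geometric
#' schedule, restarted `anneal_cycles` times. The number of steps is the
#' single knob that controls the degree of optimization, which is what the
#' over-optimization harness varies.
#'
#' @param steps number of candidate evaluations after population
#'   initialization.
#' @param population_size population size (default 20).
#' @param crossover_rate final per-block probability of inheriting from the
#'   second parent (default 0.5); in model fits a block is one time point's
#'   parameter set, so good per-time-point solutions are exchanged as
#'   units.
#' @param start_temperature initial perturbation scale / annealing
#'   temperature (default 0.5, half the box width).
#' @param cooling per-step geometric decay of the temperature; the default
#'   brings the final temperature to about `1e-3` of the start.
#' @param anneal_cycles number of annealing restarts: the cooling schedule
#'   is repeated this many times over the step budget (best-so-far is kept
#'   across restarts), which protects against the population getting
#'   trapped in a local mode (default 3).
#' @param seed integer seed; results are bit-reproducible given
#'   `(seed, config, data)` and do not touch R's RNG state.
#' @return a `saga_config`.
#' @export
saga_config <- function(steps, population_size = 20L, crossover_rate = 0.5,
                        start_temperature = 0.5, cooling = NULL,
                        anneal_cycles = 3L, seed = 1L) {
  steps <- as.integer(steps)
  if (is.na(steps) || steps < 1L) stop("'steps' must be >= 1", call. = FALSE)
  if (population_size < 2L) stop("'population_size' must be >= 2",
                                 call. = FALSE)
  if (crossover_rate < 0 || crossover_rate > 1)
    stop("'crossover_rate' must be in [0, 1]", call. = FALSE)
  if (start_temperature <= 0)
    stop("'start_temperature' must be positive", call. = FALSE)
  if (is.null(cooling)) cooling <- (1e-3)^(1 / steps)
  structure(list(steps = steps, population_size = as.integer(population_size),
                 crossover_rate = crossover_rate,
                 start_temperature = start_temperature,
                 cooling = cooling, anneal_cycles = as.integer(anneal_cycles),
                 seed = as.integer(seed)),
            class = "saga_config")
}

#' Bounded local optimizer configuration
#'
#' Describes a deterministic local optimization on the box `[0, 1]^k` from
#' a seeded uniform random start. Built-in methods are `"l-bfgs-b"`
#' (via [stats::optim()]; `tolerance` maps to `factr * .Machine$double.eps`)
#' and `"nlminb"` (the PORT routines via [stats::nlminb()]; `tolerance`
#' maps to `rel.tol`). A custom method may be supplied as a function
#' `function(fn, start, config)` returning `list(par, loss, converged,
#' iterations)`, which keeps the optimizer contract pluggable.
#'
#' @param method `"l-bfgs-b"`, `"nlminb"`, or a function (see above).
#' @param tolerance relative stopping tolerance (the `ftol` knob); a looser
#'   tolerance stops optimization earlier.
#' @param max_iterations iteration cap.
#' @param seed integer seed for the random start point.
#' @return a `local_config`.
#' @export
local_config <- function(method = "l-bfgs-b", tolerance = 1e-6,
                         max_iterations = 1000L, seed = 1L) {
  if (!is.function(method)) {
    method <- match.arg(method, c("l-bfgs-b", "nlminb"))
  }
  if (tolerance <= 0) stop("'tolerance' must be positive", call. = FALSE)
  structure(list(method = method, tolerance = tolerance,
                 max_iterations = as.integer(max_iterations),
                 seed = as.integer(seed)),
            class = "local_config")
}

#' Run the SAGA optimizer on an arbitrary objective
#'
#' @param loss_fn function taking a numeric vector in `[0, 1]^dimension`
#'   and returning a scalar loss; non-finite values reject the candidate.
#' @param dimension number of parameters.
#' @param config a [saga_config()].
#' @return list with `par` (best vector), `loss` (best loss), `trajectory`
#'   (best-so-far loss after each step, non-increasing), and `rejected`
#'   (count of non-finite candidates).
#' @export
saga_optimize <- function(loss_fn, dimension, config) {
  stopifnot(inherits(config, "saga_config"), dimension >= 1L)
  cpp_saga_generic(loss_fn, as.integer(dimension), config$steps,
                   config$population_size, config$crossover_rate,
                   config$start_temperature, config$cooling,
                   as.double(config$seed), config$anneal_cycles)
}

# deterministic uniform start point without touching the global RNG
.seeded_start <- function(dimension, seed) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  stats::runif(dimension)
}

#' Run a bounded local optimizer
#'
#' @param loss_fn objective on `[0, 1]^dimension`.
#' @param dimension number of parameters.
#' @param config a [local_config()].
#' @return list with `par`, `loss`, `converged` (logical; an optimizer
#'   failure status is flagged here rather than raised, so repeated runs can
#'   proceed), `iterations`, and `message`.
#' @export
local_optimize <- function(loss_fn, dimension, config) {
  stopifnot(inherits(config, "local_config"), dimension >= 1L)
  start <- .seeded_start(dimension, config$seed)
  safe_fn <- function(x) {
    v <- loss_fn(x)
    if (!is.finite(v)) .Machine$double.xmax else v
  }
  res <- tryCatch({
    if (is.function(config$method)) {
      config$method(safe_fn, start, config)
    } else if (config$method == "l-bfgs-b") {
      o <- stats::optim(start, safe_fn, method = "L-BFGS-B",
                        lower = 0, upper = 1,
                        control = list(
                          factr = config$tolerance / .Machine$double.eps,
                          maxit = config$max_iterations))
      list(par = o$par, loss = o$value, converged = o$convergence == 0L,
           iterations = o$counts[[1L]],
           message = o$message %||% "")
    } else {
      o <- stats::nlminb(start, safe_fn, lower = 0, upper = 1,
                         control = list(rel.tol = config$tolerance,
                                        iter.max = config$max_iterations))
      list(par = o$par, loss = o$objective, converged = o$convergence == 0L,
           iterations = o$iterations, message = o$message %||% "")
    }
  }, error = function(e)
    list(par = start,
         loss = tryCatch(safe_fn(start), error = function(e2) NA_real_),
         converged = FALSE, iterations = 0L,
         message = conditionMessage(e)))
  res$par <- pmin(pmax(res$par, 0), 1)
  res
}

.optimizer_label <- function(config) {
  if (inherits(config, "saga_config"))
    sprintf("saga(steps=%d)", config$steps)
  else if (is.function(config$method))
    sprintf("custom(tol=%g)", config$tolerance)
  else
    sprintf("%s(tol=%g)", config$method, config$tolerance)
}

#' Fit a moiety model to a dataset
#'
#' Optimizes one free-parameter vector per time point (labeling states are
#' time-dependent), jointly over the concatenated parameter space of
#' dimension `k * n_timepoints`, against the sum of per-profile losses.
#' Observed profiles are densified to isotope counts `0..capacity` with
#' missing counts as 0.
#'
#' @param model a `moiety_model`.
#' @param dataset a non-empty `isotopologue_dataset` of normalized profiles.
#' @param objective an [objective_spec()] or objective name. For
#'   `"aic_diff"` without an explicit `k`, the total parameter count
#'   `model$k * n_timepoints` is used.
#' @param optimizer a [saga_config()] or [local_config()].
#' @return an `optimization_result`: list with `model` (name), `par`
#'   (`k x T` matrix of free parameters, one column per time point),
#'   `loss`, `rss` (recomputed as the summed squared residual at the
#'   optimum), `objective`, `optimizer`, `n` (data points fitted), `seed`,
#'   `converged`, and `time_labels`.
#' @export
fit_model <- function(model, dataset, objective, optimizer) {
  stopifnot(inherits(model, "moiety_model"),
            inherits(dataset, "isotopologue_dataset"))
  if (length(dataset$profiles) == 0L)
    stop("cannot fit an empty dataset", call. = FALSE)
  if (!all(vapply(dataset$profiles, function(p) isTRUE(p$normalized),
                  TRUE)))
    stop("all profiles must be normalized before fitting (see renormalize)",
         call. = FALSE)
  if (is.character(objective) && objective == "aic_diff")
    objective <- objective_spec("aic_diff",
                                k = model$k * length(dataset$profiles))
  if (is.character(objective)) objective <- objective_spec(objective)
  stopifnot(inherits(objective, "objective_spec"))
  T <- length(dataset$profiles)
  aic_k <- objective$k %||% (model$k * T)

  obs <- .dataset_matrix(dataset, model$capacity)
  spec <- .model_cspec(model)
  obj_id <- .objective_id(objective$name)
  dimension <- model$k * T

  if (inherits(optimizer, "saga_config")) {
    res <- cpp_saga_fit(spec, obs, obj_id, objective$epsilon, aic_k,
                        optimizer$steps, optimizer$population_size,
                        optimizer$crossover_rate,
                        optimizer$start_temperature, optimizer$cooling,
                        as.double(optimizer$seed), optimizer$anneal_cycles)
    converged <- TRUE
    seed <- optimizer$seed
  } else if (inherits(optimizer, "local_config")) {
    fn <- function(x) cpp_model_loss(spec, obs, x, obj_id,
                                     objective$epsilon, aic_k)
    res <- local_optimize(fn, dimension, optimizer)
    converged <- res$converged
    seed <- optimizer$seed
  } else stop("'optimizer' must be a saga_config or local_config",
              call. = FALSE)

  par <- matrix(res$par, nrow = model$k, ncol = T,
                dimnames = list(model$param_names,
                                vapply(dataset$profiles, `[[`, "",
                                       "time_label")))
  structure(list(
    model = model$name,
    par = par,
    loss = res$loss,
    rss = cpp_model_loss(spec, obs, res$par, 2L, objective$epsilon, aic_k),
    objective = objective$name,
    optimizer = .optimizer_label(optimizer),
    n = length(obs),
    k_total = model$k * T,
    seed = seed,
    converged = converged,
    time_labels = vapply(dataset$profiles, `[[`, "", "time_label")),
    class = "optimization_result")
}

#' @export
print.optimization_result <- function(x, ...) {
  cat(sprintf("Fit of '%s' (%s, %s): loss = %.6g, rss = %.6g%s\n",
              x$model, x$objective, x$optimizer, x$loss, x$rss,
              if (!isTRUE(x$converged)) " [not converged]" else ""))
  invisible(x)
}

#' Repeat a model fit with consecutive seeds
#'
#' Runs [fit_model()] `repeats` times with seeds `base_seed, base_seed + 1,
#' ...`; used to average stochastic optimization results before model
#' scoring.
#'
#' @inheritParams fit_model
#' @param repeats number of independent optimizations.
#' @param base_seed seed of the first repetition.
#' @return list of `optimization_result`, in seed order.
#' @export
fit_repeated <- function(model, dataset, objective, optimizer,
                         repeats, base_seed = 1L) {
  stopifnot(repeats >= 1L)
  lapply(seq_len(repeats) - 1L, function(i) {
    optimizer$seed <- as.integer(base_seed) + i
    fit_model(model, dataset, objective, optimizer)
  })
}
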