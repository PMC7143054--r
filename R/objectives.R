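#' Objective function specification
#'
#' Four objective forms compare observed and calculated isotopologue
#' intensities during optimization:
#'
#' * `abs_diff` — sum of absolute differences; suits additive error.
#' * `abs_diff_logs` — sum of absolute differences of natural logs; suits
#'   proportional error. Both arguments are floored at `epsilon` before the
#'   log so zero intensities (common at early time points) stay finite.
#' * `square_diff` — residual sum of squares.
#' * `aic_diff` — `2k + n*log(RSS/n)`, mimicking the selection criterion
#'   inside the optimization itself; needs the parameter count `k`.
#'
#' @param name one of `"abs_diff"`, `"abs_diff_logs"`, `"square_diff"`,
#'   `"aic_diff"`.
#' @param epsilon positive log floor for `abs_diff_logs` (default `1e-12`).
#' @param k parameter count entering `aic_diff`; ignored otherwise.
#' @return an `objective_spec`.
#' @export
objective_spec <- function(name = c("abs_diff", "abs_diff_logs",
                                    "square_diff", "aic_diff"),
                           epsilon = 1e-12, k = NULL) {
  name <- match.arg(name)
  if (!is.numeric(epsilon) || epsilon <= 0)
    stop("'epsilon' must be a positive real", call. = FALSE)
  if (name == "aic_diff" && is.null(k))
    stop("'aic_diff' requires the parameter count k", call. = FALSE)
  structure(list(name = name, epsilon = epsilon, k = k),
            class = "objective_spec")
}

#' Evaluate an objective function
#'
#' @param spec an [objective_spec()] (or an objective name, in which case a
#'   default spec is built; `aic_diff` then needs `k` via the spec).
#' @param obs,calc numeric intensity vectors of equal length.
#' @return the scalar loss. `abs_diff`, `abs_diff_logs` and `square_diff`
#'   are non-negative and zero iff the vectors agree (up to log flooring);
#'   `aic_diff` may be negative.
#' @export
loss <- function(spec, obs, calc) {
  if (is.character(spec)) spec <- objective_spec(spec)
  stopifnot(inherits(spec, "objective_spec"))
  if (length(obs) != length(calc))
    stop(sprintf("length mismatch: obs has %d entries, calc has %d",
                 length(obs), length(calc)), call. = FALSE)
  if (length(obs) < 1L) stop("empty intensity vectors", call. = FALSE)
  switch(spec$name,
    abs_diff = sum(abs(obs - calc)),
    abs_diff_logs = sum(abs(log(pmax(obs, spec$epsilon)) -
                            log(pmax(calc, spec$epsilon)))),
    square_diff = sum((obs - calc)^2),
    aic_diff = {
      r <- rss(obs, calc)
      n <- length(obs)
      if (r <= 0)
        stop("aic_diff undefined at RSS = 0", call. = FALSE)
      2 * spec$k + n * log(r / n)
    })
}

#' Residual sum of squares
#'
#' @param obs,calc numeric vectors of equal length.
#' @return `sum((obs - calc)^2)`; identical to the `square_diff` loss.
#' @export
rss <- function(obs, calc) {
  if (length(obs) != length(calc))
    stop(sprintf("length mismatch: obs has %d entries, calc has %d",
                 length(obs), length(calc)), call. = FALSE)
  sum((obs - calc)^2)
}

.objective_id <- function(name) {
  match(name, c("abs_diff", "abs_diff_logs", "square_diff", "aic_diff")) - 1L
}
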