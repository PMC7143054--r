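#' Optimization-step sweep over candidate models
#'
#' Runs the full fit-score-select pipeline at each step budget of a grid:
#' every candidate model is fitted `repeats` times with the SAGA optimizer
#' at that budget, scored, and ranked by the selection criterion. The sweep
#' records which model is selected at each budget, its mean loss and
#' criterion value, and — relative to a reference model (normally the
#' ground-truth or expert-derived model) — the *failure step*: the smallest
#' budget at which selection abandons the reference. Rising step budgets
#' drive the loss down until the fits chase measurement error, which is the
#' over-optimization mechanism this harness exposes.
#'
#' @param models list of `moiety_model` candidates.
#' @param dataset normalized `isotopologue_dataset`.
#' @param objective objective name or [objective_spec()].
#' @param steps_grid strictly increasing integer vector of step budgets.
#' @param repeats optimizations per model per budget.
#' @param reference name of the reference model (default: first model).
#' @param criterion selection criterion (default `"AICc"`).
#' @param base_seed seed root; each (budget, model) cell uses a distinct
#'   derived seed block.
#' @param saga a [saga_config()] template whose `steps` and `seed` are
#'   overridden per cell (controls population size etc.).
#' @return a `sweep_result`: list with `grid`, `table` (data.frame with
#'   columns `steps`, `selected`, `mean_loss`, `criterion_value`),
#'   `reference`, `criterion`, and `failure_step` (integer or `NA` if
#'   selection never fails within the grid).
#' @export
step_sweep <- function(models, dataset, objective, steps_grid,
                       repeats = 1L, reference = NULL,
                       criterion = "AICc", base_seed = 1L,
                       saga = saga_config(steps = 1L)) {
  stopifnot(length(models) >= 1L, length(steps_grid) >= 1L)
  if (is.unsorted(steps_grid, strictly = TRUE))
    stop("'steps_grid' must be strictly increasing", call. = FALSE)
  model_names <- vapply(models, `[[`, "", "name")
  if (is.null(reference)) reference <- model_names[1L]
  if (!reference %in% model_names)
    stop("reference model is not among the candidates", call. = FALSE)

  rows <- vector("list", length(steps_grid))
  for (gi in seq_along(steps_grid)) {
    scores <- lapply(seq_along(models), function(mi) {
      cfg <- saga
      cfg$steps <- as.integer(steps_grid[gi])
      cfg$cooling <- (1e-3)^(1 / cfg$steps)
      seed0 <- as.integer(base_seed) +
        ((gi - 1L) * length(models) + (mi - 1L)) * as.integer(repeats)
      score_model(fit_repeated(models[[mi]], dataset, objective, cfg,
                               repeats = repeats, base_seed = seed0))
    })
    rep_ <- select_model(scores, criterion)
    sel <- rep_$selected
    sc <- scores[[match(sel, vapply(scores, `[[`, "", "model"))]]
    rows[[gi]] <- data.frame(
      steps = steps_grid[gi], selected = sel, mean_loss = sc$mean_loss,
      criterion_value = rep_$table$value[1L], stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  res <- structure(list(grid = steps_grid, table = tab,
                        reference = reference, criterion = criterion,
                        failure_step = NA_integer_),
                   class = "sweep_result")
  res$failure_step <- failure_point(res)
  res
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("Step sweep (%s, reference '%s'): failure step %s\n",
              x$criterion, x$reference,
              if (is.na(x$failure_step)) "none" else x$failure_step))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Failure point of a step sweep
#'
#' @param sweep a `sweep_result`.
#' @return the smallest grid budget whose selected model differs from the
#'   reference, or `NA` if the reference is selected throughout.
#' @export
failure_point <- function(sweep) {
  stopifnot(inherits(sweep, "sweep_result"))
  bad <- which(sweep$table$selected != sweep$reference)
  if (length(bad) == 0L) NA_integer_ else as.integer(sweep$table$steps[min(bad)])
}

#' Replicated failure-point summary over dataset variants
#'
#' For each dataset variant, repeats the step sweep `replicates` times
#' (fresh data noise and optimization seeds each time) and summarizes when
#' model selection starts to fail. Replicates whose selection never fails
#' within the grid are right-censored at the grid maximum and flagged, and
#' the median of (possibly censored) log10 failure steps is reported —
#' comparisons between variants use these medians.
#'
#' @param models candidate `moiety_model` list.
#' @param variants named list; each element is either a fixed normalized
#'   dataset or a generator `function(seed)` returning one (so each
#'   replicate sees fresh noise).
#' @param objective objective name or spec.
#' @param steps_grid step budgets for the sweep.
#' @param repeats optimizations per model per budget.
#' @param replicates sweep replicates per variant.
#' @param reference reference model name.
#' @param criterion selection criterion.
#' @param base_seed seed root.
#' @return a named list of `failure_summary` objects, each with
#'   `failure_steps` (per replicate, censored values at `max(grid)`),
#'   `censored` (logical), and `median_log10`.
#' @export
failure_summary <- function(models, variants, objective, steps_grid,
                            repeats = 1L, replicates = 10L,
                            reference = NULL, criterion = "AICc",
                            base_seed = 1L) {
  stopifnot(replicates >= 1L)
  out <- lapply(seq_along(variants), function(vi) {
    variant <- variants[[vi]]
    steps <- integer(replicates)
    cens <- logical(replicates)
    for (r in seq_len(replicates)) {
      seed <- as.integer(base_seed) + (vi - 1L) * 100003L + (r - 1L) * 997L
      ds <- if (is.function(variant)) variant(seed) else variant
      sw <- step_sweep(models, ds, objective, steps_grid, repeats = repeats,
                       reference = reference, criterion = criterion,
                       base_seed = seed + 1L)
      if (is.na(sw$failure_step)) {
        steps[r] <- max(steps_grid); cens[r] <- TRUE
      } else {
        steps[r] <- sw$failure_step; cens[r] <- FALSE
      }
    }
    structure(list(failure_steps = steps, censored = cens,
                   median_log10 = stats::median(log10(steps))),
              class = "failure_summary")
  })
  names(out) <- names(variants)
  out
}

#' @export
print.failure_summary <- function(x, ...) {
  cat(sprintf(
    "Failure summary: median log10(step) = %.3f (%d/%d censored)\n",
    x$median_log10, sum(x$censored), length(x$censored)))
  invisible(x)
}

#' Compare model rankings across selection criteria
#'
#' Fits every candidate model once per repeat, scores it, and tabulates its
#' AIC, AICc and BIC values with the rank each criterion assigns — the
#' standard check that the top-ranked models are consistent across
#' criteria.
#'
#' @param models candidate `moiety_model` list.
#' @param dataset normalized `isotopologue_dataset`.
#' @param objective objective name or spec.
#' @param optimizer a [saga_config()] or [local_config()] template.
#' @param repeats optimizations per model.
#' @param base_seed seed root.
#' @return data.frame with columns `model`, `aic`, `rank_aic`, `aicc`,
#'   `rank_aicc`, `bic`, `rank_bic`, ordered by AICc rank.
#' @export
criterion_comparison <- function(models, dataset, objective, optimizer,
                                 repeats = 1L, base_seed = 1L) {
  scores <- lapply(seq_along(models), function(mi) {
    opt <- optimizer
    seed0 <- as.integer(base_seed) + (mi - 1L) * as.integer(repeats)
    score_model(fit_repeated(models[[mi]], dataset, objective, opt,
                             repeats = repeats, base_seed = seed0))
  })
  tab <- data.frame(
    model = vapply(scores, `[[`, "", "model"),
    aic = vapply(scores, `[[`, 0, "aic"),
    aicc = vapply(scores, `[[`, 0, "aicc"),
    bic = vapply(scores, `[[`, 0, "bic"),
    stringsAsFactors = FALSE)
  tab$rank_aic <- rank(tab$aic, ties.method = "first")
  tab$rank_aicc <- rank(tab$aicc, ties.method = "first")
  tab$rank_bic <- rank(tab$bic, ties.method = "first")
  tab <- tab[order(tab$rank_aicc),
             c("model", "aic", "rank_aic", "aicc", "rank_aicc",
               "bic", "rank_bic")]
  rownames(tab) <- NULL
  tab
}
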