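#' Information criteria for model selection
#'
#' Closed forms on the residual sum of squares:
#' `AIC = 2k + n*log(RSS/n)`,
#' `AICc = AIC + (2k^2 + 2k)/(n - k - 1)` (small-sample correction),
#' `BIC = n*log(RSS/n) + k*log(n)`. Lower is better.
#'
#' @param k number of free parameters entering the criterion.
#' @param n number of data points.
#' @param rss residual sum of squares (must be positive).
#' @return the criterion value.
#' @export
aic <- function(k, n, rss) {
  if (any(rss <= 0)) stop("criterion undefined at RSS <= 0", call. = FALSE)
  if (any(n < 1)) stop("'n' must be >= 1", call. = FALSE)
  2 * k + n * log(rss / n)
}

#' @rdname aic
#' @export
aicc <- function(k, n, rss) {
  if (any(n <= k + 1))
    stop("AICc requires n > k + 1", call. = FALSE)
  aic(k, n, rss) + (2 * k^2 + 2 * k) / (n - k - 1)
}

#' @rdname aic
#' @export
bic <- function(k, n, rss) {
  if (any(rss <= 0)) stop("criterion undefined at RSS <= 0", call. = FALSE)
  if (any(n < 1)) stop("'n' must be >= 1", call. = FALSE)
  n * log(rss / n) + k * log(n)
}

#' Score a model over repeated fits
#'
#' Averages the residual sum of squares (and loss) over the repeated
#' stochastic optimizations of one model, then computes AIC, AICc and BIC
#' from the mean RSS. Averaging RSS before the criterion (rather than
#' averaging per-run criteria) is stable under the log transform.
#'
#' The parameter count `k` totals each time point's parameter set
#' separately (labeling fractions are time-dependent), and `n` counts every
#' (time point, isotope count `0..capacity`) pair fitted, zeros included,
#' so `n` is identical across candidate models of equal capacity.
#'
#' @param results non-empty list of `optimization_result` for one model and
#'   objective (see [fit_repeated()]).
#' @param n number of data points; defaults to the count recorded in the
#'   fits.
#' @return a `model_score`: list with `model`, `k`, `n`, `mean_loss`,
#'   `mean_rss`, `aic`, `aicc`, `bic`, and `repeats`.
#' @export
score_model <- function(results, n = NULL) {
  if (length(results) == 0L) stop("no results to score", call. = FALSE)
  models <- unique(vapply(results, `[[`, "", "model"))
  objectives <- unique(vapply(results, `[[`, "", "objective"))
  if (length(models) != 1L || length(objectives) != 1L)
    stop("results must share one model and one objective", call. = FALSE)
  k <- results[[1L]]$k_total
  if (is.null(n)) n <- results[[1L]]$n
  mean_rss <- mean(vapply(results, `[[`, 0, "rss"))
  mean_loss <- mean(vapply(results, `[[`, 0, "loss"))
  structure(list(model = models, k = k, n = n,
                 mean_loss = mean_loss, mean_rss = mean_rss,
                 aic = aic(k, n, mean_rss),
                 aicc = aicc(k, n, mean_rss),
                 bic = bic(k, n, mean_rss),
                 repeats = length(results)),
            class = "model_score")
}

#' @export
print.model_score <- function(x, ...) {
  cat(sprintf(
    "Score '%s': k=%d n=%d mean_loss=%.6g mean_rss=%.6g AIC=%.4f AICc=%.4f BIC=%.4f\n",
    x$model, x$k, x$n, x$mean_loss, x$mean_rss, x$aic, x$aicc, x$bic))
  invisible(x)
}

#' Pool split (per-time-point) optimizations into one score
#'
#' When each time point is optimized independently (split mode, e.g. to
#' fan time points out across CPU cores), the per-time-point results are
#' pooled for selection: total RSS is the sum of per-time-point mean RSS,
#' and `n` and `k` are summed likewise, so split totals equal combined-mode
#' counting on the same data.
#'
#' @param per_timepoint list with one element per time point, each a list
#'   of `optimization_result` for the same model.
#' @return a `model_score` built from the pooled totals.
#' @export
combine_split_scores <- function(per_timepoint) {
  if (length(per_timepoint) == 0L)
    stop("no per-time-point results", call. = FALSE)
  scores <- lapply(per_timepoint, score_model)
  models <- unique(vapply(scores, `[[`, "", "model"))
  if (length(models) != 1L)
    stop("per-time-point results fit different models", call. = FALSE)
  k <- sum(vapply(scores, `[[`, 0, "k"))
  n <- sum(vapply(scores, `[[`, 0, "n"))
  mean_rss <- sum(vapply(scores, `[[`, 0, "mean_rss"))
  mean_loss <- sum(vapply(scores, `[[`, 0, "mean_loss"))
  structure(list(model = models, k = k, n = n,
                 mean_loss = mean_loss, mean_rss = mean_rss,
                 aic = aic(k, n, mean_rss),
                 aicc = aicc(k, n, mean_rss),
                 bic = bic(k, n, mean_rss),
                 repeats = scores[[1L]]$repeats),
            class = "model_score")
}

#' Rank models by an information criterion
#'
#' Sorts candidate model scores in ascending criterion order (lower is
#' better); the rank-1 model is the selected one. Exact ties are broken
#' lexicographically by model name with a warning.
#'
#' @param scores list of `model_score` objects computed on the same data.
#' @param criterion `"AICc"` (default), `"AIC"`, or `"BIC"`.
#' @return a `selection_report`: list with `criterion`, `table` (data.frame
#'   with columns `model`, `value`, `rank`), and `selected` (model name at
#'   rank 1).
#' @export
select_model <- function(scores, criterion = c("AICc", "AIC", "BIC")) {
  criterion <- match.arg(criterion)
  if (length(scores) < 1L) stop("no scores to rank", call. = FALSE)
  field <- c(AICc = "aicc", AIC = "aic", BIC = "bic")[[criterion]]
  tab <- data.frame(
    model = vapply(scores, `[[`, "", "model"),
    value = vapply(scores, `[[`, 0, field),
    stringsAsFactors = FALSE)
  if (anyDuplicated(tab$value))
    warning("tied criterion values; breaking ties by model name",
            call. = FALSE)
  ord <- order(tab$value, tab$model)
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  structure(list(criterion = criterion, table = tab,
                 selected = tab$model[1L]),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("Model selection by %s (selected: %s)\n", x$criterion,
              x$selected))
  print(x$table, row.names = FALSE)
  invisible(x)
}
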