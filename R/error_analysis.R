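#' Pair replicate measurements
#'
#' Aligns two replicate datasets on shared (time label, isotope count)
#' keys for one metabolite, producing the paired values used in
#' replicate-vs-replicate error diagnostics. Unpaired entries are dropped
#' with a message reporting the count.
#'
#' @param dataset_a,dataset_b `isotopologue_dataset` replicates with
#'   matching metabolite and time labels.
#' @param labels optional subset of time labels to pair.
#' @return a `replicate_pairs` data.frame with columns `metabolite`,
#'   `time_label`, `isotope_count`, `a`, `b`.
#' @export
pair_replicates <- function(dataset_a, dataset_b, labels = NULL) {
  stopifnot(inherits(dataset_a, "isotopologue_dataset"),
            inherits(dataset_b, "isotopologue_dataset"))
  flat <- function(ds) do.call(rbind, lapply(ds$profiles, function(p)
    data.frame(metabolite = p$metabolite, time_label = p$time_label,
               isotope_count = as.integer(names(p$intensities)),
               value = unname(p$intensities), stringsAsFactors = FALSE)))
  fa <- flat(dataset_a); fb <- flat(dataset_b)
  if (!is.null(labels)) {
    fa <- fa[fa$time_label %in% labels, ]
    fb <- fb[fb$time_label %in% labels, ]
  }
  merged <- merge(fa, fb,
                  by = c("metabolite", "time_label", "isotope_count"),
                  suffixes = c("_a", "_b"))
  if (nrow(merged) == 0L)
    stop("replicates share no (metabolite, time, isotope count) keys",
         call. = FALSE)
  dropped <- nrow(fa) + nrow(fb) - 2L * nrow(merged)
  if (dropped > 0L)
    message(sprintf("pair_replicates: dropped %d unpaired entries", dropped))
  out <- data.frame(metabolite = merged$metabolite,
                    time_label = merged$time_label,
                    isotope_count = merged$isotope_count,
                    a = merged$value_a, b = merged$value_b,
                    stringsAsFactors = FALSE)
  class(out) <- c("replicate_pairs", "data.frame")
  out
}

#' Spread-versus-signal trend of replicate pairs
#'
#' Quantifies the visual replicate-scatter diagnosis of error structure:
#' the Spearman rank correlation between the pair mean (signal) and the
#' absolute pair difference (spread), on the raw or the log scale.
#' Proportional error shows spread growing with signal on the raw scale
#' (positive raw-scale trend) while collapsing to a line after the log
#' transform; additive error deviates uniformly from the identity line on
#' the raw scale but shows spread growing as signal *decreases* on the log
#' scale (negative log-scale trend).
#'
#' @param pairs a `replicate_pairs` object with at least 10 pairs.
#' @param scale `"raw"` or `"log"`.
#' @param epsilon floor applied before taking logs.
#' @return the Spearman correlation (0 when all pairs agree exactly).
#' @export
spread_trend <- function(pairs, scale = c("raw", "log"), epsilon = 1e-12) {
  scale <- match.arg(scale)
  stopifnot(inherits(pairs, "replicate_pairs"))
  if (nrow(pairs) < 10L)
    stop("need at least 10 replicate pairs", call. = FALSE)
  a <- pairs$a; b <- pairs$b
  if (scale == "log") {
    a <- log(pmax(a, epsilon)); b <- log(pmax(b, epsilon))
  }
  spread <- abs(a - b)
  if (all(spread == 0)) return(0)
  suppressWarnings(stats::cor((a + b) / 2, spread, method = "spearman"))
}

#' Classify the dominant replicate error structure
#'
#' Convenience wrapper: compares the raw-scale trend (evidence for
#' proportional error) against the negated log-scale trend (evidence for
#' additive error) and reports the stronger signal.
#'
#' @param pairs a `replicate_pairs` object.
#' @param threshold minimum trend magnitude to call either type.
#' @return `"proportional"`, `"additive"`, or `"none"`.
#' @export
diagnose_error <- function(pairs, threshold = 0.1) {
  raw <- spread_trend(pairs, "raw")
  lg <- -spread_trend(pairs, "log")
  if (is.na(raw)) raw <- 0
  if (is.na(lg)) lg <- 0
  if (max(raw, lg) < threshold) return("none")
  if (raw >= lg) "proportional" else "additive"
}

#' Replicate scatter panels
#'
#' Writes the standard 2x2 replicate-vs-replicate diagnostic figure: raw
#' and renormalized data, each on raw and log scales, with the identity
#' line.
#'
#' @param pairs_raw replicate pairs computed on the raw-intensity data.
#' @param pairs_norm replicate pairs computed on the renormalized data.
#' @param path output file; the extension picks the graphics device
#'   (`.png`, `.pdf`, ...).
#' @param epsilon floor applied before taking logs.
#' @return `path`, invisibly.
#' @export
error_plots <- function(pairs_raw, pairs_norm, path, epsilon = 1e-12) {
  panel <- function(p, label, logscale) {
    a <- p$a; b <- p$b
    if (logscale) { a <- log10(pmax(a, epsilon)); b <- log10(pmax(b, epsilon)) }
    data.frame(panel = label, a = a, b = b)
  }
  df <- rbind(panel(pairs_raw, "A: raw, linear", FALSE),
              panel(pairs_raw, "B: raw, log10", TRUE),
              panel(pairs_norm, "C: renormalized, linear", FALSE),
              panel(pairs_norm, "D: renormalized, log10", TRUE))
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = a, y = b)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey50") +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(x = "replicate A", y = "replicate B") +
    ggplot2::theme_bw()
  ggplot2::ggsave(path, gg, width = 7, height = 6, dpi = 150)
  invisible(path)
}
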