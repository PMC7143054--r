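#' Construct an isotopologue profile
#'
#' One observed relative-intensity vector for one metabolite at one time
#' point, indexed by isotope count (mass shift). Mass spectrometry reports
#' only observed peaks, so indices may be sparse; missing isotope counts are
#' treated as intensity 0 when fitting.
#'
#' @param metabolite metabolite name.
#' @param time_label time point label, e.g. `"34h"`.
#' @param intensities named numeric vector; names are isotope counts
#'   (`"0"`, `"1"`, ...), values non-negative intensities.
#' @param normalized logical; `TRUE` asserts the intensities sum to 1.
#' @return an `isotopologue_profile`.
#' @export
isotopologue_profile <- function(metabolite, time_label, intensities,
                                 normalized = FALSE) {
  counts <- suppressWarnings(as.integer(names(intensities)))
  if (anyNA(counts) || any(counts < 0L))
    stop("intensity names must be non-negative integer isotope counts",
         call. = FALSE)
  if (anyDuplicated(counts))
    stop("duplicate isotope counts in profile", call. = FALSE)
  if (anyNA(intensities) || any(intensities < 0))
    stop(sprintf("negative intensity in profile %s/%s", metabolite,
                 time_label), call. = FALSE)
  if (normalized && abs(sum(intensities) - 1) > 1e-9)
    stop("profile flagged normalized but intensities do not sum to 1",
         call. = FALSE)
  structure(list(metabolite = metabolite, time_label = time_label,
                 intensities = intensities[order(counts)],
                 normalized = normalized),
            class = "isotopologue_profile")
}

#' Construct an isotopologue dataset
#'
#' @param name dataset name (used as a prefix when merging).
#' @param profiles list of [isotopologue_profile()] objects; time labels
#'   must be unique per metabolite.
#' @param platform,tracer free-text source metadata.
#' @return an `isotopologue_dataset`.
#' @export
isotopologue_dataset <- function(name, profiles, platform = NULL,
                                 tracer = NULL) {
  key <- vapply(profiles, function(p)
    paste0(p$metabolite, "\r", p$time_label), "")
  if (anyDuplicated(key))
    stop("duplicate time_label for a metabolite", call. = FALSE)
  structure(list(name = name, profiles = profiles,
                 platform = platform, tracer = tracer),
            class = "isotopologue_dataset")
}

#' @export
print.isotopologue_dataset <- function(x, ...) {
  cat(sprintf("Isotopologue dataset '%s': %d profile(s)\n", x$name,
              length(x$profiles)))
  for (p in x$profiles)
    cat(sprintf("  %s @ %s: %d isotopologue(s)%s\n", p$metabolite,
                p$time_label, length(p$intensities),
                if (isTRUE(p$normalized)) " [normalized]" else ""))
  invisible(x)
}

#' Time labels of a dataset
#' @param dataset an `isotopologue_dataset`.
#' @return character vector in profile order.
#' @export
time_labels <- function(dataset) {
  vapply(dataset$profiles, `[[`, "", "time_label")
}

#' Read / write isotopologue datasets
#'
#' JSON schema: `{"name": str, "profiles": [{"metabolite": str,
#' "time_label": str, "intensities": {"0": float, ...}}]}`. CSV dialect:
#' UTF-8 with header `metabolite,time_label,isotope_count,intensity`. The
#' format is chosen by file extension (`.csv` vs anything else = JSON).
#' `write_dataset` followed by `read_dataset` is an identity up to decimal
#' representation.
#'
#' @param document file path or JSON string (for reading).
#' @return `read_dataset`: an `isotopologue_dataset`.
#' @export
read_dataset <- function(document) {
  if (is.character(document) && length(document) == 1L &&
      grepl("\\.csv$", document, ignore.case = TRUE)) {
    tab <- utils::read.csv(document, stringsAsFactors = FALSE)
    need <- c("metabolite", "time_label", "isotope_count", "intensity")
    if (!all(need %in% names(tab)))
      stop("CSV must have columns metabolite,time_label,isotope_count,intensity",
           call. = FALSE)
    split_key <- paste0(tab$metabolite, "\r", tab$time_label)
    profiles <- lapply(split(tab, factor(split_key, unique(split_key))),
      function(g) isotopologue_profile(
        g$metabolite[1L], g$time_label[1L],
        stats::setNames(g$intensity, g$isotope_count)))
    names(profiles) <- NULL
    return(isotopologue_dataset(
      sub("\\.csv$", "", basename(document), ignore.case = TRUE), profiles))
  }
  doc <- if (is.list(document)) document else
    jsonlite::fromJSON(document, simplifyVector = FALSE)
  if (is.null(doc$name)) stop("field 'name': missing", call. = FALSE)
  profiles <- lapply(doc$profiles %||% list(), function(p) {
    if (is.null(p$metabolite) || is.null(p$time_label))
      stop("field 'profiles[]': metabolite and time_label required",
           call. = FALSE)
    isotopologue_profile(p$metabolite, p$time_label,
                         unlist(p$intensities),
                         normalized = isTRUE(p$normalized))
  })
  isotopologue_dataset(doc$name, profiles,
                       platform = doc$platform, tracer = doc$tracer)
}

#' @rdname read_dataset
#' @param dataset an `isotopologue_dataset`.
#' @param path output path; `.csv` selects the flat CSV dialect, otherwise
#'   JSON is written. If `NULL`, the JSON string is returned.
#' @export
write_dataset <- function(dataset, path = NULL) {
  stopifnot(inherits(dataset, "isotopologue_dataset"))
  if (!is.null(path) && grepl("\\.csv$", path, ignore.case = TRUE)) {
    rows <- do.call(rbind, lapply(dataset$profiles, function(p)
      data.frame(metabolite = p$metabolite, time_label = p$time_label,
                 isotope_count = as.integer(names(p$intensities)),
                 intensity = unname(p$intensities))))
    utils::write.csv(rows, path, row.names = FALSE)
    return(invisible(path))
  }
  doc <- list(name = dataset$name,
              platform = dataset$platform, tracer = dataset$tracer,
              profiles = lapply(dataset$profiles, function(p)
                list(metabolite = p$metabolite, time_label = p$time_label,
                     intensities = as.list(p$intensities),
                     normalized = p$normalized)))
  doc <- doc[!vapply(doc, is.null, TRUE)]
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' Renormalize a profile to relative intensities
#'
#' Divides every intensity by the profile total so they sum to 1;
#' idempotent on already-normalized profiles.
#'
#' @param profile an `isotopologue_profile` (or a dataset, in which case
#'   every profile is renormalized).
#' @return the renormalized object with the `normalized` flag set.
#' @export
renormalize <- function(profile) {
  if (inherits(profile, "isotopologue_dataset")) {
    profile$profiles <- lapply(profile$profiles, renormalize)
    return(profile)
  }
  stopifnot(inherits(profile, "isotopologue_profile"))
  tot <- sum(profile$intensities)
  if (tot <= 0)
    stop("cannot normalize an all-zero profile", call. = FALSE)
  profile$intensities <- profile$intensities / tot
  profile$normalized <- TRUE
  profile
}

#' Subset a dataset by time label
#'
#' @param dataset an `isotopologue_dataset`.
#' @param labels time labels to keep, in dataset order.
#' @return the subset dataset.
#' @export
subset_timepoints <- function(dataset, labels) {
  stopifnot(inherits(dataset, "isotopologue_dataset"))
  have <- time_labels(dataset)
  bad <- setdiff(labels, have)
  if (length(bad))
    stop(sprintf("unknown time label(s) %s; available: %s",
                 paste(bad, collapse = ", "),
                 paste(unique(have), collapse = ", ")), call. = FALSE)
  dataset$profiles <- dataset$profiles[have %in% labels]
  dataset
}

#' Merge datasets into one
#'
#' Concatenates profiles; time labels are prefixed with the source dataset
#' name (`"FTICR.34h"`) so merged labels stay unique, and the provenance is
#' recorded in the merged dataset's platform field.
#'
#' @param datasets list of `isotopologue_dataset` objects.
#' @param name name for the merged dataset.
#' @return the merged `isotopologue_dataset`.
#' @export
merge_datasets <- function(datasets, name = "merged") {
  stopifnot(length(datasets) >= 1L)
  profiles <- list()
  for (ds in datasets) {
    stopifnot(inherits(ds, "isotopologue_dataset"))
    profiles <- c(profiles, lapply(ds$profiles, function(p) {
      p$time_label <- paste0(ds$name, ".", p$time_label)
      p
    }))
  }
  isotopologue_dataset(name, profiles,
    platform = paste(vapply(datasets, `[[`, "", "name"), collapse = "+"))
}

# Dense observation vector 0..capacity for fitting; unobserved counts are 0.
.profile_vector <- function(profile, capacity) {
  v <- numeric(capacity + 1L)
  counts <- as.integer(names(profile$intensities))
  if (any(counts > capacity))
    stop(sprintf(
      "profile %s/%s has isotope count %d beyond model capacity %d",
      profile$metabolite, profile$time_label, max(counts), capacity),
      call. = FALSE)
  v[counts + 1L] <- profile$intensities
  v
}

# capacity+1 x T matrix of observations for one dataset
.dataset_matrix <- function(dataset, capacity) {
  vapply(dataset$profiles, .profile_vector, numeric(capacity + 1L),
         capacity = capacity)
}
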