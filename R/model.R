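#' @useDynLib moietyfit, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Construct a moiety model
#'
#' A moiety model decomposes a metabolite into biochemical substructures
#' (moieties) that acquire isotope label as units. Each moiety has two or
#' more labeling states, each contributing a fixed number of heavy atoms;
#' the fractional abundances of the states of one moiety sum to 1, so a
#' moiety with `s` states contributes `s - 1` free parameters. Sharing
#' constraints force several states (possibly across moieties) to carry a
#' single common fraction, removing one parameter per additional member.
#'
#' The first state of every moiety is its *dependent* state: its fraction is
#' determined by the sum-to-one constraint and it carries no free parameter.
#' Free parameters are ordered by moiety order, then state order, skipping
#' dependent states and non-representative members of sharing constraints;
#' the representative of a constraint is its first member in that order.
#'
#' @param name model label (opaque; structure is carried explicitly).
#' @param moieties list of moieties, each `list(name =, states =)` where
#'   `states` is a named integer vector mapping state label to isotope count
#'   (first state = dependent state).
#' @param sharing list of sharing constraints; each constraint is a list of
#'   `c(moiety, state_label)` pairs whose fractions are forced equal.
#' @return an object of class `moiety_model` with elements `name`,
#'   `moieties`, `sharing`, `k` (free parameter count), `capacity` (maximum
#'   isotope content), `param_names`, and an internal free-parameter index
#'   map.
#' @examples
#' m <- moiety_model("toy", list(
#'   list(name = "a", states = c(a0 = 0, a1 = 1)),
#'   list(name = "b", states = c(b0 = 0, b1 = 1))))
#' m$k        # 2
#' m$capacity # 2
#' @export
moiety_model <- function(name, moieties, sharing = list()) {
  if (!is.character(name) || length(name) != 1L)
    stop("model 'name' must be a single string", call. = FALSE)
  if (length(moieties) < 1L)
    stop("model must contain at least one moiety", call. = FALSE)

  moieties <- lapply(moieties, function(m) {
    if (is.null(m$name) || !nzchar(m$name))
      stop("field 'moieties[].name': missing moiety name", call. = FALSE)
    st <- m$states
    if (length(st) < 2L)
      stop(sprintf("moiety '%s': needs at least 2 states", m$name),
           call. = FALSE)
    counts <- as.integer(st)
    labels <- names(st)
    if (is.null(labels) || anyNA(labels) || any(!nzchar(labels)))
      stop(sprintf("moiety '%s': states must be a named vector", m$name),
           call. = FALSE)
    if (anyDuplicated(labels))
      stop(sprintf("moiety '%s': duplicate state labels", m$name),
           call. = FALSE)
    if (anyNA(counts) || any(counts < 0L))
      stop(sprintf("moiety '%s': isotope_count must be a non-negative integer",
                   m$name), call. = FALSE)
    if (anyDuplicated(counts))
      stop(sprintf("moiety '%s': state isotope_counts must be distinct",
                   m$name), call. = FALSE)
    list(name = m$name, labels = labels, counts = counts)
  })
  mnames <- vapply(moieties, `[[`, "", "name")
  if (anyDuplicated(mnames))
    stop("duplicate moiety names", call. = FALSE)

  # validate sharing constraints
  sharing <- lapply(sharing, function(con) {
    pairs <- lapply(con, function(p) {
      p <- as.character(p)
      if (length(p) != 2L)
        stop("field 'sharing': each member must be a (moiety, state) pair",
             call. = FALSE)
      mi <- match(p[1L], mnames)
      if (is.na(mi))
        stop(sprintf("sharing refers to unknown moiety '%s'", p[1L]),
             call. = FALSE)
      si <- match(p[2L], moieties[[mi]]$labels)
      if (is.na(si))
        stop(sprintf("sharing refers to unknown state '%s' of moiety '%s'",
                     p[2L], p[1L]), call. = FALSE)
      if (si == 1L)
        stop(sprintf(
          "sharing may not include a moiety's dependent (first) state: %s.%s",
          p[1L], p[2L]), call. = FALSE)
      c(mi, si)
    })
    if (length(pairs) < 2L)
      stop("a sharing constraint needs at least 2 members", call. = FALSE)
    do.call(rbind, pairs)
  })
  if (length(sharing)) {
    keys <- unlist(lapply(sharing, function(m) paste(m[, 1L], m[, 2L])))
    if (anyDuplicated(keys))
      stop("a state appears in more than one sharing constraint",
           call. = FALSE)
  }

  # D3 ordering: walk moieties/states, assign free-parameter indices;
  # shared states all point at the representative's index.
  pmap <- lapply(moieties, function(m) integer(length(m$counts)))
  pnames <- character(0)
  con_idx <- rep(NA_integer_, length(sharing))  # index assigned per constraint
  next_idx <- 0L
  for (mi in seq_along(moieties)) {
    nst <- length(moieties[[mi]]$counts)
    for (si in seq_len(nst)) {
      if (si == 1L) { pmap[[mi]][si] <- 0L; next }  # dependent
      ci <- which(vapply(sharing, function(con)
        any(con[, 1L] == mi & con[, 2L] == si), logical(1)))
      if (length(ci)) {
        if (is.na(con_idx[ci])) {            # first member met = representative
          next_idx <- next_idx + 1L
          con_idx[ci] <- next_idx
          pnames <- c(pnames, paste0(mnames[mi], ".",
                                     moieties[[mi]]$labels[si]))
        }
        pmap[[mi]][si] <- con_idx[ci]
      } else {
        next_idx <- next_idx + 1L
        pmap[[mi]][si] <- next_idx
        pnames <- c(pnames, paste0(mnames[mi], ".", moieties[[mi]]$labels[si]))
      }
    }
  }
  k <- next_idx
  if (k < 1L)
    stop("model has no free parameters", call. = FALSE)
  capacity <- sum(vapply(moieties, function(m) max(m$counts), 0L))

  structure(list(name = name, moieties = moieties, sharing = sharing,
                 k = k, capacity = as.integer(capacity),
                 param_names = pnames, param_map = pmap),
            class = "moiety_model")
}

#' @export
print.moiety_model <- function(x, ...) {
  cat(sprintf("Moiety model '%s': %d moieties, k = %d, capacity = %d\n",
              x$name, length(x$moieties), x$k, x$capacity))
  for (m in x$moieties)
    cat(sprintf("  %s: %s\n", m$name,
                paste0(m$labels, "=", m$counts, collapse = " ")))
  if (length(x$sharing))
    cat(sprintf("  %d sharing constraint(s)\n", length(x$sharing)))
  invisible(x)
}

#' Parse moiety models from JSON
#'
#' Reads the model schema
#' `{"name": str, "moieties": [{"name": str, "states":
#' [{"label": str, "isotope_count": int}]}], "sharing":
#' [[["moiety","label"], ...]]}`. A file may hold one model object or a list
#' of them.
#'
#' @param document a file path, a JSON string, or an already-parsed list.
#' @return a `moiety_model`, or a list of them if the document holds a list.
#' @export
parse_model <- function(document) {
  doc <- if (is.character(document) && length(document) == 1L) {
    jsonlite::fromJSON(document, simplifyVector = FALSE)
  } else if (is.list(document)) {
    document
  } else stop("'document' must be a path, JSON string, or list",
              call. = FALSE)
  if (is.null(names(doc)))
    return(lapply(doc, parse_model))   # unnamed list = list of models
  .model_from_list(doc)
}

.model_from_list <- function(doc) {
  if (is.null(doc$name))
    stop("field 'name': missing", call. = FALSE)
  if (is.null(doc$moieties))
    stop("field 'moieties': missing", call. = FALSE)
  moieties <- lapply(doc$moieties, function(m) {
    if (is.null(m$states))
      stop("field 'moieties[].states': missing", call. = FALSE)
    counts <- vapply(m$states, function(s) {
      if (is.null(s$isotope_count))
        stop("field 'states[].isotope_count': missing", call. = FALSE)
      as.integer(s$isotope_count)
    }, 0L)
    labels <- vapply(m$states, function(s) {
      if (is.null(s$label))
        stop("field 'states[].label': missing", call. = FALSE)
      as.character(s$label)
    }, "")
    names(counts) <- labels
    list(name = m$name, states = counts)
  })
  sharing <- lapply(doc$sharing %||% list(), function(con)
    lapply(con, function(p) as.character(unlist(p))))
  moiety_model(as.character(doc$name), moieties, sharing)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize a moiety model to the JSON schema
#'
#' @param model a `moiety_model`.
#' @param path optional file path; if omitted the JSON string is returned.
#' @return `path` invisibly, or a JSON string.
#' @export
write_model <- function(model, path = NULL) {
  stopifnot(inherits(model, "moiety_model"))
  doc <- list(
    name = model$name,
    moieties = lapply(model$moieties, function(m) list(
      name = m$name,
      states = lapply(seq_along(m$counts), function(i)
        list(label = m$labels[i], isotope_count = m$counts[i])))),
    sharing = lapply(model$sharing, function(con) {
      mn <- vapply(model$moieties, `[[`, "", "name")
      lapply(seq_len(nrow(con)), function(r)
        c(mn[con[r, 1L]], model$moieties[[con[r, 1L]]]$labels[con[r, 2L]]))
    }))
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' Expand free parameters into per-state fractions
#'
#' Maps the `k` free parameters of a model (each in `[0, 1]`) to the full
#' set of state fractions: shared states copy their representative's value
#' and each moiety's dependent (first) state is set to one minus the sum of
#' the others. During optimization the free parameters of one moiety may sum
#' above 1; in that case the dependent state is clamped at 0 and the
#' moiety's fractions are renormalized by their sum, which keeps the
#' objective defined on the whole unit box without constraint machinery.
#'
#' @param model a `moiety_model`.
#' @param free numeric vector of length `model$k`, all values in `[0, 1]`.
#' @return a `state_assignment`: a list (one element per moiety) of named
#'   fraction vectors, each summing to 1.
#' @export
expand_parameters <- function(model, free) {
  stopifnot(inherits(model, "moiety_model"))
  if (length(free) != model$k)
    stop(sprintf("expected %d free parameters, got %d", model$k,
                 length(free)), call. = FALSE)
  if (anyNA(free) || any(free < 0 | free > 1))
    stop("free parameters must lie in [0, 1]", call. = FALSE)
  out <- vector("list", length(model$moieties))
  names(out) <- vapply(model$moieties, `[[`, "", "name")
  for (mi in seq_along(model$moieties)) {
    idx <- model$param_map[[mi]]
    fr <- numeric(length(idx))
    fr[idx > 0L] <- free[idx[idx > 0L]]
    dep <- 1 - sum(fr[-1L])
    if (dep < 0) {                       # clamp-and-renormalize rule
      fr[1L] <- 0
      fr <- fr / sum(fr)
    } else fr[1L] <- dep
    names(fr) <- model$moieties[[mi]]$labels
    out[[mi]] <- fr
  }
  structure(out, class = "state_assignment")
}

#' Enumerate pseudo-isotopomer combinations
#'
#' Lists every combination of one state per moiety, in lexicographic order
#' (last moiety varying fastest), with the combination's total isotope
#' content. If `assignment` is given, the product of the chosen fractions is
#' added as column `value`.
#'
#' @param model a `moiety_model`.
#' @param assignment optional `state_assignment`.
#' @return a data.frame with one column per moiety (chosen state label),
#'   `isotope_content`, and optionally `value`.
#' @export
enumerate_combinations <- function(model, assignment = NULL) {
  stopifnot(inherits(model, "moiety_model"))
  nst <- lapply(model$moieties, function(m) seq_along(m$counts))
  grid <- expand.grid(rev(nst), KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, rev(seq_along(grid)), drop = FALSE]  # last moiety fastest
  content <- integer(nrow(grid))
  out <- as.data.frame(lapply(seq_along(model$moieties), function(mi)
    model$moieties[[mi]]$labels[grid[[mi]]]))
  names(out) <- vapply(model$moieties, `[[`, "", "name")
  for (mi in seq_along(model$moieties))
    content <- content + model$moieties[[mi]]$counts[grid[[mi]]]
  out$isotope_content <- content
  if (!is.null(assignment)) {
    value <- rep(1, nrow(grid))
    for (mi in seq_along(model$moieties))
      value <- value * assignment[[mi]][grid[[mi]]]
    out$value <- value
  }
  out
}

#' Calculate the isotopologue intensity vector
#'
#' Implements the moiety intensity equations: the calculated relative
#' intensity at isotope count `x` is the sum, over all combinations of one
#' state per moiety whose isotope contents add to `x`, of the product of the
#' chosen state fractions. Computed by convolving the per-moiety isotope
#' count distributions, which is algebraically identical to the
#' combination-sum definition.
#'
#' @param model a `moiety_model`.
#' @param assignment a `state_assignment` (see [expand_parameters()]), or a
#'   numeric vector of `model$k` free parameters which is expanded first.
#' @return numeric vector of length `model$capacity + 1`, indexed by isotope
#'   count `0..capacity`; sums to 1.
#' @export
calc_isotopologues <- function(model, assignment) {
  stopifnot(inherits(model, "moiety_model"))
  if (is.numeric(assignment))
    assignment <- expand_parameters(model, assignment)
  acc <- 1
  for (mi in seq_along(model$moieties)) {
    m <- model$moieties[[mi]]
    dist <- numeric(max(m$counts) + 1L)
    dist[m$counts + 1L] <- assignment[[mi]]
    acc <- convolve_dists(acc, dist)
  }
  # convolution length is capacity + 1 by construction
  stats::setNames(acc, 0:(length(acc) - 1L))
}

convolve_dists <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a))
    if (a[i] != 0)
      out[i:(i + length(b) - 1L)] <- out[i:(i + length(b) - 1L)] + a[i] * b
  out
}

#' The expert-derived UDP-GlcNAc moiety model
#'
#' UDP-GlcNAc divides into four moieties — glucose, ribose, acetyl and
#' uracil — that incorporate carbon-13 from uniformly labeled glucose
#' through human central metabolism. Glucose is labeled all-or-nothing
#' (0 or 6 carbons), ribose 0 or 5, acetyl 0 or 2, and uracil carries 0 to 3
#' labeled carbons, giving 1 + 1 + 1 + 3 = 6 free parameters.
#'
#' @return a `moiety_model` with `k = 6` and capacity 16.
#' @export
udp_glcnac_expert_model <- function() {
  moiety_model("6_G1R1A1U3", list(
    list(name = "glucose", states = c(g0 = 0, g6 = 6)),
    list(name = "ribose",  states = c(r0 = 0, r5 = 5)),
    list(name = "acetyl",  states = c(a0 = 0, a2 = 2)),
    list(name = "uracil",  states = c(u0 = 0, u1 = 1, u2 = 2, u3 = 3))))
}

# Compact representation handed to the C++ fitting path.
.model_cspec <- function(model) {
  list(counts = lapply(model$moieties, `[[`, "counts"),
       pidx = lapply(model$param_map, function(p) as.integer(p) - 1L),
       k = as.integer(model$k), capacity = as.integer(model$capacity))
}
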