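#' Noise model for synthetic isotopologue data
#'
#' Observed relative intensities carry additive error (detector noise,
#' roughly constant across the intensity range) and/or proportional error
#' (scaling with signal, typical of raw MS intensities). Simulated
#' intensity `I` becomes `I * (1 + cv * e1) + sd * e2` with independent
#' standard normal `e1`, `e2`; negative values are clipped to 0 and the
#' profile renormalized, mimicking the relative-intensity datasets that are
#' actually fitted.
#'
#' @param additive_sd standard deviation of additive noise (intensity
#'   units on the normalized scale), `>= 0`.
#' @param proportional_cv coefficient of variation of proportional noise,
#'   `>= 0`.
#' @param seed integer seed.
#' @return a `noise_model`.
#' @export
noise_model <- function(additive_sd = 0, proportional_cv = 0, seed = 1L) {
  if (additive_sd < 0 || proportional_cv < 0)
    stop("noise magnitudes must be >= 0", call. = FALSE)
  structure(list(additive_sd = additive_sd,
                 proportional_cv = proportional_cv,
                 seed = as.integer(seed)),
            class = "noise_model")
}

# run expr with a private RNG stream, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

#' Simulate an isotopologue dataset with known ground truth
#'
#' Computes noise-free intensity profiles from the model at the true
#' parameters, perturbs them under the noise model, clips negative values
#' to zero, and renormalizes. The ground truth travels with the dataset so
#' parameter-recovery and model-selection experiments can verify against
#' it.
#'
#' @param model a `moiety_model` (the ground-truth model).
#' @param truth true free parameters: a `k x T` matrix or a list of length
#'   `T` of `k`-vectors, one per time point.
#' @param noise a [noise_model()].
#' @param time_labels labels for the time points (default `"t1"..."tT"`).
#' @param metabolite metabolite name for the profiles.
#' @param name dataset name.
#' @return list with `dataset` (an `isotopologue_dataset`, normalized) and
#'   `truth` (the `k x T` matrix used).
#' @export
simulate_dataset <- function(model, truth, noise = noise_model(),
                             time_labels = NULL, metabolite = "synthetic",
                             name = "synthetic") {
  stopifnot(inherits(model, "moiety_model"), inherits(noise, "noise_model"))
  if (is.list(truth)) truth <- do.call(cbind, truth)
  truth <- as.matrix(truth)
  if (nrow(truth) != model$k)
    stop(sprintf("truth must have %d rows (one per free parameter)",
                 model$k), call. = FALSE)
  if (anyNA(truth) || any(truth < 0 | truth > 1))
    stop("true parameters must lie in [0, 1]", call. = FALSE)
  T <- ncol(truth)
  if (is.null(time_labels)) time_labels <- paste0("t", seq_len(T))
  rownames(truth) <- model$param_names
  colnames(truth) <- time_labels

  profiles <- .with_seed(noise$seed, lapply(seq_len(T), function(t) {
    I <- calc_isotopologues(model, truth[, t])
    nb <- length(I)
    if (noise$proportional_cv > 0)
      I <- I * (1 + noise$proportional_cv * stats::rnorm(nb))
    if (noise$additive_sd > 0)
      I <- I + noise$additive_sd * stats::rnorm(nb)
    I <- pmax(I, 0)
    if (sum(I) <= 0)
      stop("noise wiped out an entire profile; lower the noise level",
           call. = FALSE)
    p <- isotopologue_profile(metabolite, time_labels[t],
                              stats::setNames(I, 0:(nb - 1L)))
    renormalize(p)
  }))
  list(dataset = isotopologue_dataset(name, profiles,
                                      platform = "synthetic",
                                      tracer = "simulated"),
       truth = truth)
}

#' Perturb a moiety model into structural candidates
#'
#' Generates hypothetical competitor models by small structural edits of a
#' base model, mirroring how candidate model sets are hand-crafted around
#' an expert-derived model. Supported rule types:
#'
#' * `add_state(moiety, label, isotope_count)` — one extra labeling state
#'   (one extra parameter).
#' * `remove_state(moiety, label)` — drop a non-dependent state.
#' * `share_states(members)` — force listed `(moiety, label)` pairs to one
#'   shared fraction.
#' * `split_shared(index)` — remove the `index`-th sharing constraint.
#'
#' Rules that would produce an invalid model (e.g. a moiety with fewer than
#' 2 states) are skipped with a warning. Candidates are uniquely named by
#' suffixing the rule description; the base model is never in the output.
#'
#' @param base a `moiety_model`.
#' @param rules list of rules, each `list(type = , ...)` as above.
#' @return list of valid `moiety_model` candidates.
#' @export
perturb_model <- function(base, rules) {
  stopifnot(inherits(base, "moiety_model"))
  out <- list()
  for (rule in rules) {
    cand <- tryCatch(.apply_rule(base, rule), error = function(e) {
      warning(sprintf("perturbation '%s' skipped: %s",
                      rule$type, conditionMessage(e)), call. = FALSE)
      NULL
    })
    if (!is.null(cand)) out <- c(out, list(cand))
  }
  nm <- vapply(out, `[[`, "", "name")
  if (anyDuplicated(nm))
    stop("perturbation rules produced duplicate candidate names",
         call. = FALSE)
  out
}

.apply_rule <- function(base, rule) {
  moieties <- lapply(base$moieties, function(m)
    list(name = m$name, states = stats::setNames(m$counts, m$labels)))
  mnames <- vapply(moieties, function(m) m$name, "")
  sharing <- lapply(base$sharing, function(con)
    lapply(seq_len(nrow(con)), function(r)
      c(mnames[con[r, 1L]], base$moieties[[con[r, 1L]]]$labels[con[r, 2L]])))

  suffix <- switch(rule$type,
    add_state = {
      mi <- match(rule$moiety, mnames)
      if (is.na(mi)) stop("unknown moiety ", rule$moiety)
      st <- moieties[[mi]]$states
      st[rule$label] <- as.integer(rule$isotope_count)
      moieties[[mi]]$states <- st
      paste0("add-", rule$label)
    },
    remove_state = {
      mi <- match(rule$moiety, mnames)
      if (is.na(mi)) stop("unknown moiety ", rule$moiety)
      st <- moieties[[mi]]$states
      si <- match(rule$label, names(st))
      if (is.na(si)) stop("unknown state ", rule$label)
      if (si == 1L) stop("cannot remove the dependent state")
      if (length(st) <= 2L) stop("moiety would have fewer than 2 states")
      moieties[[mi]]$states <- st[-si]
      paste0("rm-", rule$label)
    },
    share_states = {
      sharing <- c(sharing, list(rule$members))
      paste0("share-", paste(vapply(rule$members, `[`, "", 2L),
                             collapse = "-"))
    },
    split_shared = {
      if (rule$index > length(sharing)) stop("no such sharing constraint")
      sharing <- sharing[-rule$index]
      paste0("split-", rule$index)
    },
    stop("unknown rule type ", rule$type))
  moiety_model(paste0(base$name, "_", suffix), moieties, sharing)
}

#' Stock perturbations of the UDP-GlcNAc expert model
#'
#' Five structural edits of the expert-derived model used throughout the
#' selection and over-optimization experiments: an intermediate glucose
#' state (g5), an intermediate ribose state (r4), an intermediate acetyl
#' state (a1), removal of the two-carbon uracil state (u2), and sharing of
#' the fully labeled glucose and ribose fractions.
#'
#' @return list of 5 rule lists for [perturb_model()].
#' @export
udp_glcnac_perturbations <- function() {
  list(
    list(type = "add_state", moiety = "glucose", label = "g5",
         isotope_count = 5),
    list(type = "add_state", moiety = "ribose", label = "r4",
         isotope_count = 4),
    list(type = "add_state", moiety = "acetyl", label = "a1",
         isotope_count = 1),
    list(type = "remove_state", moiety = "uracil", label = "u2"),
    list(type = "share_states",
         members = list(c("glucose", "g6"), c("ribose", "r5"))))
}

#' Canonical ground-truth labeling schedule for the expert model
#'
#' A biologically structured time course of fractional enrichments for the
#' expert-derived UDP-GlcNAc model, used as the default ground truth in
#' synthetic experiments. Glucose, ribose and acetyl — close to the
#' labeled glucose source via glycolysis, the pentose phosphate pathway and
#' pyruvate dehydrogenase — enrich quickly; uracil, made by slow multi-step
#' de-novo pyrimidine synthesis, stays sparsely labeled with mass spread
#' over its partial states.
#'
#' @param timepoints number of time points (1 to 3; columns are taken from
#'   the 3-point course in order).
#' @return a `6 x timepoints` matrix of free parameters (rows ordered
#'   g6, r5, a2, u1, u2, u3).
#' @export
udp_glcnac_truth <- function(timepoints = 3L) {
  stopifnot(timepoints >= 1L, timepoints <= 3L)
  truth <- cbind(c(0.30, 0.25, 0.20, 0.06, 0.04, 0.03),
                 c(0.55, 0.50, 0.40, 0.12, 0.08, 0.06),
                 c(0.75, 0.70, 0.60, 0.18, 0.12, 0.09))
  rownames(truth) <- c("glucose.g6", "ribose.r5", "acetyl.a2",
                       "uracil.u1", "uracil.u2", "uracil.u3")
  colnames(truth) <- paste0("t", 1:3)
  truth[, seq_len(timepoints), drop = FALSE]
}

#' Candidate model set for selection and over-optimization experiments
#'
#' The expert-derived model plus five hypothetical competitors, each adding
#' one intermediate labeling state to a moiety (seven free parameters
#' instead of six). Hand-crafted competitor sets for this metabolite are
#' built the same way: structurally plausible variants that carry at least
#' as many parameters as the expert model, so that the extra parameters can
#' soak up measurement error under aggressive optimization — the mechanism
#' the over-optimization harness studies. The first element is the expert
#' (reference) model.
#'
#' @return list of 6 `moiety_model` objects.
#' @export
udp_glcnac_candidate_models <- function() {
  base <- udp_glcnac_expert_model()
  rules <- list(
    list(type = "add_state", moiety = "glucose", label = "g5",
         isotope_count = 5),
    list(type = "add_state", moiety = "glucose", label = "g4",
         isotope_count = 4),
    list(type = "add_state", moiety = "ribose", label = "r4",
         isotope_count = 4),
    list(type = "add_state", moiety = "ribose", label = "r3",
         isotope_count = 3),
    list(type = "add_state", moiety = "acetyl", label = "a1",
         isotope_count = 1))
  c(list(base), perturb_model(base, rules))
}

#' Simulate a schedule of informative and uninformative time points
#'
#' Early time points of a labeling time course often carry no tracer yet:
#' all intensity sits in the unlabeled isotopologue, so they contribute
#' measurement error but no labeling information. The schedule marks each
#' time point as `"unlabeled"` (all free parameters 0, so the noise-free
#' profile has all mass at isotope count 0) or gives its true parameter
#' vector.
#'
#' @param model a `moiety_model`.
#' @param schedule list, one entry per time point: the string `"unlabeled"`
#'   or a numeric `k`-vector of true parameters.
#' @param noise a [noise_model()].
#' @param time_labels optional labels.
#' @return as [simulate_dataset()]: list with `dataset` and `truth`.
#' @export
informative_and_uninformative_timepoints <- function(model, schedule,
                                                     noise = noise_model(),
                                                     time_labels = NULL) {
  truth <- vapply(schedule, function(s) {
    if (identical(s, "unlabeled")) numeric(model$k) else as.numeric(s)
  }, numeric(model$k))
  simulate_dataset(model, truth, noise, time_labels = time_labels)
}
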