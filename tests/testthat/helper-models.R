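# Shared fixtures: small models, random model generation, and the
# brute-force intensity oracle that enumerates the Cartesian product of
# states (independent of the convolution implementation under test).

toy_two_moiety <- function() {
  moiety_model("toy2", list(
    list(name = "a", states = c(a0 = 0, a1 = 1)),
    list(name = "b", states = c(b0 = 0, b1 = 1))))
}

toy_three_state <- function() {
  moiety_model("toy3", list(
    list(name = "s", states = c(s0 = 0, s1 = 1, s2 = 2))))
}

# random valid model with <= max_moieties moieties, <= max_states states
random_model <- function(max_moieties = 5, max_states = 5) {
  nm <- sample(max_moieties, 1)
  moieties <- lapply(seq_len(nm), function(i) {
    ns <- sample(2:max_states, 1)
    counts <- sort(sample(0:9, ns))
    states <- stats::setNames(counts, paste0("m", i, "s", seq_len(ns)))
    list(name = paste0("m", i), states = states)
  })
  moiety_model(paste0("rand", sample.int(1e6, 1)), moieties)
}

# random valid free-parameter vector (per-moiety sums <= 1)
random_free <- function(model) {
  free <- numeric(model$k)
  for (mi in seq_along(model$moieties)) {
    idx <- model$param_map[[mi]]
    slots <- idx[idx > 0L]
    w <- stats::runif(length(slots) + 1L)
    free[slots] <- (w / sum(w))[seq_along(slots)]
  }
  free
}

# brute-force oracle for the intensity equations: sum the products of the
# chosen state fractions over the full Cartesian product of states
brute_force_isotopologues <- function(model, assignment) {
  grids <- lapply(model$moieties, function(m) seq_along(m$counts))
  grid <- expand.grid(grids, KEEP.OUT.ATTRS = FALSE)
  out <- numeric(model$capacity + 1L)
  for (r in seq_len(nrow(grid))) {
    content <- 0L
    value <- 1
    for (mi in seq_along(model$moieties)) {
      si <- grid[r, mi]
      content <- content + model$moieties[[mi]]$counts[si]
      value <- value * assignment[[mi]][si]
    }
    out[content + 1L] <- out[content + 1L] + value
  }
  out
}

# small normalized dataset simulated from the expert model
expert_fixture <- function(noise_sd = 0, seed = 5L, timepoints = 3L) {
  m <- udp_glcnac_expert_model()
  simulate_dataset(m, udp_glcnac_truth(timepoints),
                   noise_model(additive_sd = noise_sd, seed = seed))
}
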