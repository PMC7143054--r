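test_that("zero-noise simulation reproduces the intensity equations", {
  m <- udp_glcnac_expert_model()
  truth <- udp_glcnac_truth()
  sim <- simulate_dataset(m, truth, noise_model(seed = 1))
  expect_length(sim$dataset$profiles, 3)
  for (t in 1:3) {
    obs <- moietyfit:::.profile_vector(sim$dataset$profiles[[t]], 16)
    expect_equal(obs, unname(calc_isotopologues(m, truth[, t])),
                 tolerance = 1e-12)
  }
  expect_equal(sim$truth, truth, ignore_attr = TRUE)
})

test_that("noisy profiles stay normalized and differ from truth", {
  m <- udp_glcnac_expert_model()
  truth <- udp_glcnac_truth()
  sim <- simulate_dataset(m, truth, noise_model(additive_sd = 0.01, seed = 2))
  for (t in 1:3) {
    p <- sim$dataset$profiles[[t]]
    expect_true(p$normalized)
    expect_equal(sum(p$intensities), 1, tolerance = 1e-9)
    obs <- moietyfit:::.profile_vector(p, 16)
    expect_gt(max(abs(obs - unname(calc_isotopologues(m, truth[, t])))), 0)
    expect_true(all(obs >= 0))
  }
  # identical seed reproduces the dataset; different seed does not
  again <- simulate_dataset(m, truth, noise_model(additive_sd = 0.01, seed = 2))
  expect_identical(again$dataset$profiles[[1]]$intensities,
                   sim$dataset$profiles[[1]]$intensities)
  other <- simulate_dataset(m, truth, noise_model(additive_sd = 0.01, seed = 3))
  expect_false(identical(other$dataset$profiles[[1]]$intensities,
                         sim$dataset$profiles[[1]]$intensities))
})

test_that("proportional noise scales with intensity", {
  m <- udp_glcnac_expert_model()
  truth <- udp_glcnac_truth()
  sim <- simulate_dataset(m, truth, noise_model(proportional_cv = 0.1,
                                                seed = 4))
  expect_equal(sum(sim$dataset$profiles[[1]]$intensities), 1,
               tolerance = 1e-9)
  expect_error(noise_model(additive_sd = -1), ">= 0")
})

test_that("invalid truth parameters are rejected", {
  m <- udp_glcnac_expert_model()
  expect_error(simulate_dataset(m, matrix(0.5, 4, 3), noise_model()),
               "6 rows")
  expect_error(simulate_dataset(m, matrix(1.5, 6, 3), noise_model()),
               "\\[0, 1\\]")
})

test_that("perturbation rules produce valid, uniquely named candidates", {
  base <- udp_glcnac_expert_model()
  cands <- perturb_model(base, udp_glcnac_perturbations())
  expect_length(cands, 5)
  expect_false(base$name %in% vapply(cands, `[[`, "", "name"))
  expect_equal(anyDuplicated(vapply(cands, `[[`, "", "name")), 0L)
  ks <- vapply(cands, `[[`, 0L, "k")
  expect_equal(sort(ks), c(5L, 5L, 7L, 7L, 7L))  # add-state +1, remove/share -1

  # a g5 state gives the 7-parameter glucose variant
  g5 <- cands[[1]]
  expect_equal(g5$k, 7)
  expect_true("g5" %in% g5$moieties[[1]]$labels)

  # removing a state from a 2-state moiety is skipped with a warning
  expect_warning(
    none <- perturb_model(base, list(
      list(type = "remove_state", moiety = "glucose", label = "g6"))),
    "skipped")
  expect_length(none, 0)
})

test_that("the harness candidate set is the expert plus five k=7 variants", {
  cands <- udp_glcnac_candidate_models()
  expect_length(cands, 6)
  expect_equal(cands[[1]]$name, "6_G1R1A1U3")
  expect_equal(vapply(cands, `[[`, 0L, "k"), c(6L, rep(7L, 5)))
  expect_true(all(vapply(cands, `[[`, 0L, "capacity") == 16L))
})

test_that("unlabeled time points concentrate mass at x = 0", {
  m <- udp_glcnac_expert_model()
  truth <- udp_glcnac_truth()
  sched <- list("unlabeled", truth[, 1], "unlabeled", truth[, 2])
  sim <- informative_and_uninformative_timepoints(m, sched, noise_model(seed = 9))
  expect_length(sim$dataset$profiles, 4)
  for (t in c(1, 3)) {
    obs <- moietyfit:::.profile_vector(sim$dataset$profiles[[t]], 16)
    expect_equal(obs[1], 1)
    expect_equal(sum(obs[-1]), 0)
  }
  expect_equal(sim$truth[, 1], rep(0, 6), ignore_attr = TRUE)
})

test_that("zero-noise fits recover the generating parameters", {
  m <- udp_glcnac_expert_model()
  truth <- udp_glcnac_truth(timepoints = 1)
  sim <- simulate_dataset(m, truth, noise_model(seed = 1))
  f <- fit_model(m, sim$dataset, "abs_diff", saga_config(10000, seed = 3))
  expect_equal(unname(f$par), unname(truth), tolerance = 0.02)
})
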