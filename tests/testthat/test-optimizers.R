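sphere <- function(x) sum((x - 0.5)^2)

test_that("saga_optimize honors budget, determinism, and monotone trajectory", {
  cfg <- saga_config(steps = 500, seed = 7)
  r1 <- saga_optimize(sphere, 3, cfg)
  r2 <- saga_optimize(sphere, 3, cfg)
  expect_identical(r1$par, r2$par)           # same seed, bit-identical
  expect_identical(r1$loss, r2$loss)
  expect_length(r1$trajectory, 500)          # one entry per candidate
  expect_true(all(diff(r1$trajectory) <= 0)) # best-so-far non-increasing
  r3 <- saga_optimize(sphere, 3, saga_config(steps = 500, seed = 8))
  expect_false(identical(r1$par, r3$par))
  # steps = 1 still returns a valid result
  tiny <- saga_optimize(sphere, 3, saga_config(steps = 1, seed = 1))
  expect_length(tiny$trajectory, 1)
  expect_true(is.finite(tiny$loss))
})

test_that("saga_optimize solves a convex target", {
  losses <- vapply(1:10, function(s)
    saga_optimize(sphere, 3, saga_config(steps = 5000, seed = s))$loss, 0)
  expect_lt(median(losses), 1e-4)
  expect_lt(max(losses), 1e-2)
})

test_that("non-finite losses reject candidates; all-non-finite errors", {
  holed <- function(x) if (x[1] > 0.9) NaN else sphere(x)
  r <- saga_optimize(holed, 2, saga_config(steps = 2000, seed = 3))
  expect_true(is.finite(r$loss))
  expect_gte(r$rejected, 0)
  expect_error(
    saga_optimize(function(x) NaN, 2, saga_config(steps = 50, seed = 1)),
    "no finite value")
})

test_that("local optimizers find a convex optimum within bounds", {
  for (method in c("l-bfgs-b", "nlminb")) {
    r <- local_optimize(sphere, 4, local_config(method, 1e-8, seed = 2))
    expect_true(r$converged)
    expect_equal(r$par, rep(0.5, 4), tolerance = 1e-4)
    expect_true(all(r$par >= 0 & r$par <= 1))
  }
})

test_that("looser tolerance never beats tighter tolerance from one start", {
  fix <- expert_fixture()
  m <- udp_glcnac_expert_model()
  for (s in 1:5) {
    tight <- fit_model(m, fix$dataset, "square_diff",
                       local_config("l-bfgs-b", 1e-6, seed = s))
    loose <- fit_model(m, fix$dataset, "square_diff",
                       local_config("l-bfgs-b", 1e-2, seed = s))
    expect_gte(loose$loss, tight$loss - 1e-12)
  }
})

test_that("optimizer failures are flagged, not raised", {
  bad <- function(x) stop("boom")
  r <- local_optimize(bad, 2, local_config("l-bfgs-b", seed = 1))
  expect_false(r$converged)
  expect_match(r$message, "boom")
})

test_that("fit_model recovers a closed-form single-moiety optimum", {
  m <- moiety_model("one", list(list(name = "s", states = c(s0 = 0, s1 = 1))))
  ds <- isotopologue_dataset("d", list(
    renormalize(isotopologue_profile("x", "t1", c(`0` = 0.6, `1` = 0.4)))))
  f <- fit_model(m, ds, "abs_diff", saga_config(2000, seed = 1))
  expect_equal(unname(f$par[1, 1]), 0.4, tolerance = 1e-3)
  expect_lt(f$loss, 1e-3)
})

test_that("fit results are self-consistent with the objective", {
  fix <- expert_fixture(noise_sd = 0.01)
  m <- udp_glcnac_expert_model()
  f <- fit_model(m, fix$dataset, "abs_diff", saga_config(3000, seed = 4))
  # recompute the loss and rss from the returned parameters in R
  recomputed <- sum(vapply(seq_along(fix$dataset$profiles), function(t) {
    obs <- moietyfit:::.profile_vector(fix$dataset$profiles[[t]], m$capacity)
    loss("abs_diff", obs, unname(calc_isotopologues(m, f$par[, t])))
  }, 0))
  expect_equal(f$loss, recomputed, tolerance = 1e-12)
  rerss <- sum(vapply(seq_along(fix$dataset$profiles), function(t) {
    obs <- moietyfit:::.profile_vector(fix$dataset$profiles[[t]], m$capacity)
    rss(obs, unname(calc_isotopologues(m, f$par[, t])))
  }, 0))
  expect_equal(f$rss, rerss, tolerance = 1e-12)
  expect_equal(dim(f$par), c(6L, 3L))
  expect_true(all(f$par >= 0 & f$par <= 1))
})

test_that("fit_model validates its inputs", {
  m <- udp_glcnac_expert_model()
  expect_error(fit_model(m, isotopologue_dataset("e", list()), "abs_diff",
                         saga_config(10)), "empty")
  raw <- isotopologue_dataset("r", list(
    isotopologue_profile("x", "t1", c(`0` = 2, `1` = 2))))
  expect_error(fit_model(m, raw, "abs_diff", saga_config(10)), "normalized")
})

test_that("fit_repeated runs seeded repetitions deterministically", {
  fix <- expert_fixture()
  m <- udp_glcnac_expert_model()
  reps <- fit_repeated(m, fix$dataset, "abs_diff", saga_config(500),
                       repeats = 3, base_seed = 11)
  expect_length(reps, 3)
  expect_equal(vapply(reps, `[[`, 0L, "seed"), c(11L, 12L, 13L))
  single <- fit_model(m, fix$dataset, "abs_diff", saga_config(500, seed = 11))
  expect_identical(reps[[1]]$par, single$par)
  expect_identical(reps[[1]]$loss, single$loss)
})

test_that("mean loss does not increase with a larger step budget", {
  fix <- expert_fixture(noise_sd = 0.01)
  m <- udp_glcnac_expert_model()
  small <- vapply(fit_repeated(m, fix$dataset, "abs_diff", saga_config(1000),
                               repeats = 12, base_seed = 1), `[[`, 0, "loss")
  large <- vapply(fit_repeated(m, fix$dataset, "abs_diff", saga_config(10000),
                               repeats = 12, base_seed = 1), `[[`, 0, "loss")
  expect_lt(wilcox.test(small, large, paired = TRUE,
                        alternative = "greater")$p.value, 0.05)
})

test_that("aic_diff objective drives a joint (non-separable) fit", {
  fix <- expert_fixture(noise_sd = 0.01)
  m <- udp_glcnac_expert_model()
  f <- fit_model(m, fix$dataset, "aic_diff", saga_config(5000, seed = 2))
  n <- 3 * 17
  expect_equal(f$loss, 2 * 18 + n * log(f$rss / n), tolerance = 1e-10)
})
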